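#' @title Clone-level state and fate rules
#' @description A clone is the unit of simulation: a homogeneous population of
#'   B cells sharing one receptor. Fate rules move clones vertically on the
#'   antigen-affinity plane (divide / die, which changes local free antigen)
#'   or horizontally (receptor editing, isotype switch, somatic hypermutation,
#'   which change intrinsic or apparent affinity).
#' @name agents
NULL

B_CELL_STAGES <- c("PRE_BI", "LARGE_PRE_BII", "SMALL_PRE_BII", "IMMATURE",
                   "TRANSITIONAL", "FOLLICULAR_BII", "B1", "MZB", "GC_B",
                   "MEMORY", "PLASMABLAST", "LLPC")
BM_EDITING_STAGES <- c("PRE_BI", "LARGE_PRE_BII", "SMALL_PRE_BII", "IMMATURE")
ISOTYPES <- c("IgM", "IgD", "IgG", "IgA", "IgE")
UNSWITCHED_ISOTYPES <- c("IgM", "IgD")
SWITCHED_ISOTYPES <- c("IgG", "IgA", "IgE")
NICHE_KINDS <- c("BONE_MARROW", "BLOOD", "FOLLICLE", "GC", "MEMORY_NICHE")
FATE_ACTIONS <- c("DIE", "REST_G0", "PERSIST_G1", "DIVIDE", "EDIT_RECEPTOR",
                  "SWITCH_ISOTYPE", "ENTER_GC", "EXIT_AS")
CYCLE_STATES <- c("G0", "G1", "DIVIDING")

#' Construct a B-cell clone
#'
#' Intrinsic affinity is stored internally as log10(K_D) so that eleven
#' decades of the working range never underflow; `kd_intrinsic()` and
#' `kd_apparent()` convert at the boundary. The apparent dissociation constant
#' is `kd_intrinsic / apparent_factor`: factors above 1 mean stronger apparent
#' engagement (e.g. after isotype switch), factors below 1 mean damped
#' engagement (the marginal-zone adjustment). Terminally differentiated LLPC
#' clones contribute no paratope.
#'
#' @param clone_id opaque identifier
#' @param kd_intrinsic intrinsic dissociation constant, molar, > 0
#' @param apparent_factor dimensionless engagement modifier, > 0
#' @param n_cells cell count, integer >= 0
#' @param bcr_per_cell paratopes displayed per cell
#' @param stage developmental stage label
#' @param isotype heavy-chain isotype label
#' @param mut_h,mut_l accumulated heavy/light-chain variable-region mutations
#' @param edit_attempts_left remaining receptor-editing rearrangements
#' @param cycle_state cell-cycle label
#' @return a `b_cell_clone`
#' @export
b_cell_clone <- function(clone_id, kd_intrinsic, apparent_factor = 1,
                         n_cells = 1L, bcr_per_cell = 1e5,
                         stage = "IMMATURE", isotype = "IgM",
                         mut_h = 0L, mut_l = 0L, edit_attempts_left = 3L,
                         cycle_state = "G0") {
  .check_molar(kd_intrinsic, "kd_intrinsic", allow_zero = FALSE)
  stopifnot(length(kd_intrinsic) == 1)
  if (!is.finite(apparent_factor) || apparent_factor <= 0) {
    stop("apparent_factor must be > 0", call. = FALSE)
  }
  stage <- match.arg(stage, B_CELL_STAGES)
  isotype <- match.arg(isotype, ISOTYPES)
  cycle_state <- match.arg(cycle_state, CYCLE_STATES)
  if (n_cells < 0 || mut_h < 0 || mut_l < 0 || edit_attempts_left < 0) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(
    clone_id = as.character(clone_id),
    log10_kd = log10(kd_intrinsic),
    apparent_factor = apparent_factor,
    n_cells = as.numeric(n_cells),
    bcr_per_cell = bcr_per_cell,
    stage = stage,
    isotype = isotype,
    mut_h = as.integer(mut_h),
    mut_l = as.integer(mut_l),
    edit_attempts_left = as.integer(edit_attempts_left),
    cycle_state = cycle_state
  ), class = "b_cell_clone")
}

#' @rdname b_cell_clone
#' @param clone a `b_cell_clone`
#' @export
kd_intrinsic <- function(clone) 10^clone$log10_kd

#' @rdname b_cell_clone
#' @export
kd_apparent <- function(clone) 10^clone$log10_kd / clone$apparent_factor

#' @rdname b_cell_clone
#' @export
paratope_count <- function(clone) {
  if (clone$stage == "LLPC") return(0) # terminal differentiation loses the BCR
  clone$n_cells * clone$bcr_per_cell
}

#' @export
format.b_cell_clone <- function(x, ...) {
  sprintf("<b_cell_clone %s> stage=%s isotype=%s n=%g kd=%.3e (apparent %.3e) mut=%d/%d",
          x$clone_id, x$stage, x$isotype, x$n_cells,
          kd_intrinsic(x), kd_apparent(x), x$mut_h, x$mut_l)
}

#' @export
print.b_cell_clone <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' A fate action decided for a clone
#'
#' @param action one of DIE, REST_G0, PERSIST_G1, DIVIDE, EDIT_RECEPTOR,
#'   SWITCH_ISOTYPE, ENTER_GC, EXIT_AS
#' @param new_stage stage the clone differentiates into (EXIT_AS / B1), or NULL
#' @param factor_scale multiplier applied to `apparent_factor` on application
#'   (marginal-zone apparent-affinity modulation), or NULL
#' @return a `fate_action`
#' @export
fate_action <- function(action, new_stage = NULL, factor_scale = NULL) {
  action <- match.arg(action, FATE_ACTIONS)
  structure(list(action = action, new_stage = new_stage,
                 factor_scale = factor_scale),
            class = "fate_action")
}

#' @rdname fate_action
#' @param fa a `fate_action`
#' @export
fate_label <- function(fa) {
  if (is.null(fa$new_stage)) fa$action else paste0(fa$action, ":", fa$new_stage)
}

#' Decide the fate of a clone from its BCR engagement
#'
#' The deterministic fate machine of the model: clones in the comfort zone
#' rest in G0; neglected clones die; under-engaged clones in the bone marrow
#' spend receptor-editing attempts before dying; over-engaged clones divide
#' (and with a second signal switch isotype in blood or seed a germinal center
#' from a follicle); saturated clones in the bone marrow are clonally deleted
#' as aggressive self-binders. B1 clones in blood persist in G1 regardless of
#' over-engagement; LLPC are antigen-independent. Immature/transitional clones
#' in blood are routed through [classify_blood_fate()], which needs the
#' log-ratio, so `simulate()` calls that entry point directly.
#'
#' @param clone a [b_cell_clone()]
#' @param engagement an engagement class label (see [classify_engagement()])
#' @param niche_kind one of BONE_MARROW, BLOOD, FOLLICLE, GC, MEMORY_NICHE
#' @param second_signal logical; T-cell help / danger-signal gate
#' @return a [fate_action()]
#' @export
decide_fate <- function(clone, engagement, niche_kind, second_signal = FALSE) {
  stopifnot(inherits(clone, "b_cell_clone"), clone$n_cells > 0)
  engagement <- as.character(engagement)
  if (!engagement %in% ENGAGEMENT_LEVELS) {
    stop("unknown engagement class: ", engagement, call. = FALSE)
  }
  if (!niche_kind %in% NICHE_KINDS) {
    stop("unknown niche kind: ", niche_kind, call. = FALSE)
  }
  if (!clone$stage %in% B_CELL_STAGES) {
    stop("unknown stage: ", clone$stage, call. = FALSE)
  }
  # terminally differentiated cells have no BCR and escape antigen regulation
  if (clone$stage == "LLPC") return(fate_action("REST_G0"))
  # B1 cells self-replenish in blood, staying activated in G1
  if (clone$stage == "B1" && niche_kind == "BLOOD") {
    if (engagement == "NEGLECT") return(fate_action("DIE"))
    return(fate_action("PERSIST_G1"))
  }
  switch(engagement,
    COMFORT = fate_action("REST_G0"),
    NEGLECT = fate_action("DIE"),
    UNDER = {
      if (niche_kind == "BONE_MARROW" && clone$stage %in% BM_EDITING_STAGES &&
          clone$edit_attempts_left > 0) {
        fate_action("EDIT_RECEPTOR")
      } else if (niche_kind == "GC") {
        fate_action("PERSIST_G1") # still competing, not yet neglected
      } else {
        fate_action("DIE")
      }
    },
    OVER = {
      if (second_signal && niche_kind == "FOLLICLE") {
        fate_action("ENTER_GC")
      } else if (second_signal && niche_kind == "BLOOD") {
        fate_action("SWITCH_ISOTYPE")
      } else {
        fate_action("DIVIDE")
      }
    },
    SATURATED = {
      if (niche_kind == "BONE_MARROW") fate_action("DIE") # clonal deletion
      else fate_action("DIVIDE")
    },
    stop("unhandled engagement class: ", engagement, call. = FALSE)
  )
}

#' Double a clone's cell count
#'
#' Synchronous doubling; the paratope pool doubles with it. A configured
#' population cap bounds memory: at the cap the clone is returned unchanged
#' (or clamped) with a warning rather than overflowing.
#'
#' @param clone a [b_cell_clone()] with `n_cells >= 1`
#' @param mode `"double"` (default) or `"increment"` (single-cell mode)
#' @param population_cap maximum cells per clone
#' @return the clone after division
#' @export
divide_clone <- function(clone, mode = c("double", "increment"),
                         population_cap = 2^20) {
  stopifnot(inherits(clone, "b_cell_clone"), clone$n_cells >= 1)
  mode <- match.arg(mode)
  target <- if (mode == "double") clone$n_cells * 2 else clone$n_cells + 1
  if (target > population_cap) {
    warning(sprintf("clone %s at population cap (%g); clamped", clone$clone_id,
                    population_cap), call. = FALSE)
    target <- max(clone$n_cells, min(target, population_cap))
  }
  clone$n_cells <- target
  clone$cycle_state <- "DIVIDING"
  clone
}

#' Receptor editing: rearrange an alternate chain
#'
#' Resamples the intrinsic K_D from the germline distribution (log-uniform on
#' the germline recognition range), spends one editing attempt and resets the
#' hypermutation counters, modelling replacement of a light (or second heavy)
#' chain by further rearrangement. Uses the session RNG; seed upstream for
#' replay.
#'
#' @param clone a [b_cell_clone()] with `edit_attempts_left > 0`
#' @param germline_bounds K_D range of germline receptors, molar
#' @return the edited clone
#' @export
receptor_edit <- function(clone, germline_bounds = c(1e-10, 1e-6)) {
  stopifnot(inherits(clone, "b_cell_clone"))
  if (clone$edit_attempts_left <= 0) {
    stop("receptor_edit called with no editing attempts left", call. = FALSE)
  }
  stopifnot(length(germline_bounds) == 2, all(germline_bounds > 0),
            germline_bounds[1] < germline_bounds[2])
  clone$log10_kd <- stats::runif(1, log10(germline_bounds[1]),
                                 log10(germline_bounds[2]))
  clone$edit_attempts_left <- clone$edit_attempts_left - 1L
  clone$mut_h <- 0L
  clone$mut_l <- 0L
  clone
}

#' Switch the heavy-chain isotype
#'
#' Class-switched BCR engage antigen more sensitively; this is modelled as an
#' apparent-affinity gain: `apparent_factor` is multiplied by `switch_gain`,
#' so the apparent K_D drops while the intrinsic K_D is untouched. Switching
#' an already-switched clone is a warning no-op.
#'
#' @param clone a [b_cell_clone()] with isotype IgM or IgD
#' @param target_isotype one of IgG, IgA, IgE
#' @param switch_gain apparent-affinity gain factor, default 10
#' @return the switched clone
#' @export
isotype_switch <- function(clone, target_isotype = "IgG", switch_gain = 10) {
  stopifnot(inherits(clone, "b_cell_clone"))
  target_isotype <- match.arg(target_isotype, SWITCHED_ISOTYPES)
  if (!clone$isotype %in% UNSWITCHED_ISOTYPES) {
    warning(sprintf("clone %s already switched (%s); no-op", clone$clone_id,
                    clone$isotype), call. = FALSE)
    return(clone)
  }
  stopifnot(is.finite(switch_gain), switch_gain > 0)
  clone$isotype <- target_isotype
  clone$apparent_factor <- clone$apparent_factor * switch_gain
  clone
}

#' Somatic hypermutation parameters
#'
#' Per mutation event: probability `p_lethal` of a crippling mutation (the
#' lineage dies), otherwise a deleterious (+step in log10 K_D, probability
#' `p_del` renormalized over non-lethal outcomes) or beneficial (-step) shift
#' of the mutated chain, with half-normal step size `sigma_step` log10 units.
#' Heavy chain is hit with probability `p_heavy` unless its counter is at
#' cap. Mutation counters are hard-capped at `cap_h` / `cap_l`.
#'
#' @param p_lethal,p_del,p_heavy,sigma_step,cap_h,cap_l see description
#' @return an `shm_params` list
#' @export
shm_params <- function(p_lethal = 0.3, p_del = 0.5, p_heavy = 0.6,
                       sigma_step = 0.4, cap_h = 30L, cap_l = 20L) {
  stopifnot(p_lethal >= 0, p_del >= 0, p_lethal + p_del <= 1,
            p_heavy >= 0, p_heavy <= 1, sigma_step > 0, cap_h >= 0, cap_l >= 0)
  structure(list(p_lethal = p_lethal, p_del = p_del, p_heavy = p_heavy,
                 sigma_step = sigma_step,
                 cap_h = as.integer(cap_h), cap_l = as.integer(cap_l)),
            class = "shm_params")
}

#' Apply one somatic hypermutation event to a germinal-center clone
#'
#' Returns `NULL` when the mutation is lethal (the mutated lineage dies);
#' returns the clone unchanged when both chain counters are at their caps
#' (no further mutation possible); otherwise returns the clone with one
#' counter incremented and log10(K_D) shifted, clamped to the working range.
#' Most mutations decrease affinity (raise K_D); selection, not mutation,
#' drives maturation. Draw order is fixed (lethality, chain, direction, step)
#' for replay determinism.
#'
#' @param clone a [b_cell_clone()] in stage GC_B
#' @param shm an [shm_params()]
#' @return mutated clone, unchanged clone, or `NULL` (lethal)
#' @export
shm_mutate <- function(clone, shm = shm_params()) {
  stopifnot(inherits(clone, "b_cell_clone"), inherits(shm, "shm_params"))
  if (clone$stage != "GC_B") {
    stop("shm_mutate applies to GC_B clones only, got stage ", clone$stage,
         call. = FALSE)
  }
  if (clone$mut_h >= shm$cap_h && clone$mut_l >= shm$cap_l) {
    return(clone) # both chains exhausted: passes through unmutated
  }
  if (stats::runif(1) < shm$p_lethal) return(NULL)
  chain <- if (clone$mut_h >= shm$cap_h) {
    "L"
  } else if (clone$mut_l >= shm$cap_l) {
    "H"
  } else if (stats::runif(1) < shm$p_heavy) "H" else "L"
  p_del_given_viable <- shm$p_del / (1 - shm$p_lethal)
  deleterious <- stats::runif(1) < p_del_given_viable
  step <- abs(stats::rnorm(1, 0, shm$sigma_step))
  clone$log10_kd <- clone$log10_kd + if (deleterious) step else -step
  rng <- log10(KD_WORKING_RANGE)
  clone$log10_kd <- min(max(clone$log10_kd, rng[["kd_min"]]), rng[["kd_max"]])
  if (chain == "H") clone$mut_h <- clone$mut_h + 1L else clone$mut_l <- clone$mut_l + 1L
  clone
}

#' Fate of an immature/transitional clone in blood
#'
#' Blood is an inexhaustible antigen pool, so division cannot lower \[Ag\];
#' alternative fates arise instead. Neglected and under-engaged emigrants
#' die; clones in the comfort band rest; moderate over-engagement (log-ratio
#' in (delta_comfort, delta_b1\]) yields the self-replenishing B1 fate
#' (PERSIST_G1, stage B1); stronger over-engagement with a second signal
#' yields the marginal-zone fate, implemented as a one-off apparent-affinity
#' adjustment (`factor_scale = 10^-round(log_ratio)`) that raises the
#' apparent K_D until the clone sits inside the comfort band; without a
#' second signal the clone divides and class-switches (primary
#' thymus-independent response).
#'
#' @param clone a [b_cell_clone()] in stage IMMATURE or TRANSITIONAL
#' @param engagement engagement class label
#' @param second_signal logical
#' @param log_ratio log10(ag_free / kd_apparent) in blood
#' @param band an [engagement_band()]
#' @return a [fate_action()]
#' @export
classify_blood_fate <- function(clone, engagement, second_signal, log_ratio,
                                band = engagement_band()) {
  stopifnot(inherits(clone, "b_cell_clone"), inherits(band, "engagement_band"))
  if (!clone$stage %in% c("IMMATURE", "TRANSITIONAL")) {
    stop("classify_blood_fate applies to IMMATURE/TRANSITIONAL clones, got ",
         clone$stage, call. = FALSE)
  }
  engagement <- as.character(engagement)
  if (!engagement %in% ENGAGEMENT_LEVELS) {
    stop("unknown engagement class: ", engagement, call. = FALSE)
  }
  if (engagement == "NEGLECT") return(fate_action("DIE"))
  if (engagement == "COMFORT") return(fate_action("REST_G0"))
  if (engagement == "UNDER") return(fate_action("DIE"))
  # OVER or SATURATED: branch on how far above the band the clone sits
  stopifnot(is.finite(log_ratio), log_ratio > 0)
  if (log_ratio <= band$delta_b1) {
    return(fate_action("PERSIST_G1", new_stage = "B1"))
  }
  if (second_signal) {
    # damp apparent affinity so the post-adjustment log-ratio falls in band
    return(fate_action("EXIT_AS", new_stage = "MZB",
                       factor_scale = 10^(-round(log_ratio))))
  }
  fate_action("DIVIDE") # primary TI response; engine also class-switches
}

#' Apply a fate action's differentiation side effects to a clone
#'
#' Stage changes and apparent-factor scaling carried by the action; the
#' population-level effects (death, division, pool updates) are the engine's
#' job.
#'
#' @param clone a [b_cell_clone()]
#' @param fa a [fate_action()]
#' @return the updated clone
#' @export
apply_fate_differentiation <- function(clone, fa) {
  stopifnot(inherits(fa, "fate_action"))
  if (!is.null(fa$factor_scale)) {
    clone$apparent_factor <- clone$apparent_factor * fa$factor_scale
  }
  if (!is.null(fa$new_stage)) clone$stage <- fa$new_stage
  if (fa$action == "REST_G0") clone$cycle_state <- "G0"
  if (fa$action %in% c("PERSIST_G1", "ENTER_GC")) clone$cycle_state <- "G1"
  clone
}
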