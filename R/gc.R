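#' @title Germinal-center mutation-selection engine
#' @description One germinal center is a depletable pool of a single cognate
#'   antigen plus a set of competing GC_B clones. Each cycle is one light-zone
#'   plus dark-zone pass: clones capture antigen in proportion to their size
#'   and occupancy, divide in proportion to capture, hypermutate their
#'   daughters, and are then selected against the shrinking pool. Clones
#'   falling to neglect die; clones reaching the comfort band exit to memory,
#'   plasmablast or long-lived plasma-cell fates.
#' @name gc_maturation
NULL

#' Germinal-center parameters
#'
#' @param f_present fraction of the pool displayed for capture per cycle
#' @param alpha divisions per reference capture (divisions =
#'   `min(div_cap, floor(alpha * captured / capture_ref))`)
#' @param div_cap maximum divisions per clone per cycle
#' @param capture_ref reference capture in moles; `NULL` (default) derives it
#'   each cycle as `alpha * f_present * pool / (2 * n_clones)`, i.e. an equal
#'   split of the currently displayed antigen earns two divisions — so a lone
#'   founder performs exactly two divisions in cycle 1, and competition stays
#'   relative as the pool shrinks and the clone list grows
#' @param pool_decay per-cycle fractional antigen loss to antibody-mediated
#'   clearance (applied after capture)
#' @param residual_frac pool fraction (of the initial pool) below which a
#'   comfort-zone exit becomes an antibody-secreting fate rather than memory
#' @param max_cycles cycles per germinal center per dose
#' @param max_clones clone-list cap; past it the lowest-weight clones are
#'   culled (light-zone carrying capacity)
#' @param volume germinal-center volume, liters
#' @param dose_conc initial cognate antigen concentration per dose, molar
#' @param founder_n fresh founders recruited per dose
#' @param germline_bounds founder K_D range, molar
#' @param matured_floor hard lower clamp on exported K_D, molar
#' @param matured_ceiling clones above this K_D fail selection (never exit)
#' @param capture_mode `"proportional"` (deterministic split) or
#'   `"multinomial"` (stochastic granule split)
#' @param second_signal logical; T-cell help gate required for hypermutation
#' @return a `gc_params` list
#' @export
gc_params <- function(f_present = 0.5, alpha = 4, div_cap = 6,
                      capture_ref = NULL, pool_decay = 0.1,
                      residual_frac = 0.01, max_cycles = 15, max_clones = 120,
                      volume = 1e-7, dose_conc = 1e-6, founder_n = 20,
                      germline_bounds = c(1e-10, 1e-6),
                      matured_floor = 2.0e-12, matured_ceiling = 1.0e-7,
                      capture_mode = c("proportional", "multinomial"),
                      second_signal = TRUE) {
  capture_mode <- match.arg(capture_mode)
  stopifnot(f_present > 0, f_present <= 1, alpha > 0, div_cap >= 0,
            pool_decay >= 0, pool_decay < 1, residual_frac > 0,
            max_cycles >= 1, max_clones >= 1, volume > 0, dose_conc > 0,
            founder_n >= 1, matured_floor > 0,
            matured_floor < matured_ceiling)
  structure(list(f_present = f_present, alpha = alpha, div_cap = div_cap,
                 capture_ref = capture_ref, pool_decay = pool_decay,
                 residual_frac = residual_frac, max_cycles = max_cycles,
                 max_clones = max_clones, volume = volume,
                 dose_conc = dose_conc, founder_n = founder_n,
                 germline_bounds = germline_bounds,
                 matured_floor = matured_floor,
                 matured_ceiling = matured_ceiling,
                 capture_mode = capture_mode,
                 second_signal = second_signal),
            class = "gc_params")
}

#' Germinal-center state
#'
#' @param pool_total cognate antigen pool, moles, >= 0
#' @param clones list of [b_cell_clone()]s in stage GC_B
#' @param volume liters
#' @param cycle_index completed cycles
#' @return a `gc_state`
#' @export
gc_state <- function(pool_total, clones, volume, cycle_index = 0L) {
  stopifnot(pool_total >= 0, volume > 0, is.list(clones))
  for (cl in clones) stopifnot(inherits(cl, "b_cell_clone"),
                               cl$stage == "GC_B")
  structure(list(
    pool_total = pool_total,
    pool_initial = pool_total,
    volume = volume,
    clones = clones,
    cycle_index = as.integer(cycle_index),
    exited = list(memory = list(), plasma = list(), llpc = list()),
    history = list(),
    terminated = FALSE
  ), class = "gc_state")
}

#' Light-zone antigen capture
#'
#' A fraction `f_present` of the pool is displayed each cycle and allocated
#' across clones proportionally to the weight `n_cells * occupancy(conc, kd)`:
#' higher-affinity clones, and larger clones, capture more antigen at the same
#' pool concentration. If every weight is zero nothing is captured. The
#' stochastic mode splits the displayed antigen into 1000 granules assigned
#' multinomially by the same weights.
#'
#' @param clones list of GC clones
#' @param pool_total pool, moles
#' @param volume liters
#' @param f_present displayed fraction
#' @param capture_mode `"proportional"` or `"multinomial"`
#' @return numeric vector of captured moles, one per clone,
#'   summing to at most `f_present * pool_total`
#' @export
capture_antigen <- function(clones, pool_total, volume, f_present = 0.5,
                            capture_mode = "proportional") {
  stopifnot(pool_total >= 0)
  if (length(clones) == 0) return(numeric(0))
  conc <- pool_total / volume
  w <- vapply(clones, function(cl) {
    cl$n_cells * occupancy(conc, kd_apparent(cl))
  }, numeric(1))
  available <- f_present * pool_total
  if (all(w == 0) || available == 0) return(rep(0, length(clones)))
  if (capture_mode == "multinomial") {
    granules <- stats::rmultinom(1, size = 1000, prob = w / sum(w))[, 1]
    return(available * granules / 1000)
  }
  available * w / sum(w)
}

#' Divisions earned by captured antigen
#'
#' Dark-zone division count is regulated by the amount of antigen captured in
#' the light zone: linear in capture with a hard cap,
#' `min(div_cap, floor(alpha * captured / capture_ref))`. Monotone
#' non-decreasing in capture; zero capture earns zero divisions.
#'
#' @param captured moles captured, >= 0 (vectorized)
#' @param alpha divisions per reference capture
#' @param capture_ref reference capture, moles, > 0
#' @param div_cap cap on divisions
#' @return integer vector of division counts
#' @export
division_count <- function(captured, alpha = 4, capture_ref, div_cap = 6) {
  if (any(!is.finite(captured)) || any(captured < 0)) {
    stop("captured must be finite and >= 0", call. = FALSE)
  }
  stopifnot(capture_ref > 0)
  as.integer(pmin(div_cap, floor(alpha * captured / capture_ref)))
}

.derive_capture_ref <- function(params, pool, n_clones) {
  if (!is.null(params$capture_ref)) return(params$capture_ref)
  params$alpha * params$f_present * pool / (2 * max(1, n_clones))
}

#' Run one germinal-center cycle
#'
#' Capture, then for each clone its earned number of division rounds: each
#' round doubles the clone and hands the daughter cohort one hypermutation
#' draw — lethal mutations kill the cohort, viable mutations split it off as
#' a new clone with shifted K_D, cap-exhausted cohorts fold back into the
#' parent. The pool loses the captured antigen plus a decay fraction. Clones
#' whose engagement at the new pool concentration is NEGLECT die; clones
#' reaching COMFORT (and at or below the maturation ceiling) exit — to MEMORY
#' while the pool is above the residual threshold, afterwards to LLPC if the
#' clone made this cycle's largest capture ("the last antigen molecules"),
#' else PLASMABLAST. If the clone list exceeds `max_clones`, lowest-weight
#' clones are culled.
#'
#' @param state a [gc_state()]
#' @param band an [engagement_band()]
#' @param shm an [shm_params()]
#' @param params a [gc_params()]
#' @param capture_ref reference capture for this cycle, moles; defaults to
#'   the equal-share derivation described under [gc_params()]
#' @return the updated `gc_state`
#' @export
gc_cycle <- function(state, band = engagement_band(), shm = shm_params(),
                     params = gc_params(),
                     capture_ref = .derive_capture_ref(params,
                                                       state$pool_total,
                                                       length(state$clones))) {
  stopifnot(inherits(state, "gc_state"))
  if (length(state$clones) == 0) {
    state$terminated <- TRUE
    return(state)
  }
  cyc <- state$cycle_index + 1L
  captured <- capture_antigen(state$clones, state$pool_total, state$volume,
                              params$f_present, params$capture_mode)
  divisions <- division_count(captured, params$alpha, capture_ref,
                              params$div_cap)

  survivors <- list()
  h_id <- character(length(state$clones))
  h_n <- numeric(length(state$clones))
  h_kd <- numeric(length(state$clones))
  h_mh <- integer(length(state$clones))
  h_ml <- integer(length(state$clones))
  for (k in seq_along(state$clones)) {
    parent <- state$clones[[k]]
    d <- divisions[k]
    offspring <- list()
    if (d > 0 && params$second_signal) {
      for (r in seq_len(d)) {
        n_before <- parent$n_cells
        doubled <- suppressWarnings(divide_clone(parent))
        gained <- doubled$n_cells - n_before
        if (gained <= 0) break
        daughter <- parent
        daughter$n_cells <- gained
        daughter$clone_id <- paste0(parent$clone_id, ".", cyc, ".", r)
        at_caps <- daughter$mut_h >= shm$cap_h && daughter$mut_l >= shm$cap_l
        mutated <- shm_mutate(daughter, shm)
        if (is.null(mutated)) {
          # lethal mutation: daughter cohort dies, parent keeps its cells
          next
        }
        if (at_caps) {
          # no mutation possible: daughters indistinguishable, fold back
          parent$n_cells <- parent$n_cells + gained
        } else {
          offspring[[length(offspring) + 1L]] <- mutated
        }
      }
    } else if (d > 0) {
      # no T-cell help: expansion without hypermutation
      for (r in seq_len(d)) parent <- suppressWarnings(divide_clone(parent))
    }
    h_id[k] <- parent$clone_id
    h_n[k] <- parent$n_cells
    h_kd[k] <- kd_apparent(parent)
    h_mh[k] <- parent$mut_h
    h_ml[k] <- parent$mut_l
    survivors[[length(survivors) + 1L]] <- parent
    for (off in offspring) survivors[[length(survivors) + 1L]] <- off
  }
  capture_by_id <- stats::setNames(captured,
                                   vapply(state$clones, `[[`, "", "clone_id"))

  # pool bookkeeping: captured antigen is consumed; decay models clearance
  consumed <- sum(captured)
  pool <- max(0, state$pool_total - consumed)
  pool <- pool * (1 - params$pool_decay)

  # selection against the post-capture pool
  conc <- pool / state$volume
  residual_threshold <- params$residual_frac * state$pool_initial
  top_capture_id <- if (any(captured > 0)) {
    names(capture_by_id)[which.max(capture_by_id)]
  } else {
    NA_character_
  }
  keep <- list()
  for (cl in survivors) {
    cls <- .engagement_label(conc, kd_apparent(cl), band)
    if (cls == "NEGLECT") next # dies during selection
    if (cls == "COMFORT") {
      if (kd_intrinsic(cl) > params$matured_ceiling) {
        keep[[length(keep) + 1L]] <- cl # fails selection for export; lingers
        next
      }
      cl$log10_kd <- max(cl$log10_kd, log10(params$matured_floor))
      if (pool > residual_threshold) {
        cl$stage <- "MEMORY"
        cl$cycle_state <- "G0"
        state$exited$memory[[length(state$exited$memory) + 1L]] <- cl
      } else if (!is.na(top_capture_id) && cl$clone_id == top_capture_id) {
        cl$stage <- "LLPC"
        state$exited$llpc[[length(state$exited$llpc) + 1L]] <- cl
      } else {
        cl$stage <- "PLASMABLAST"
        state$exited$plasma[[length(state$exited$plasma) + 1L]] <- cl
      }
      next
    }
    keep[[length(keep) + 1L]] <- cl
  }

  # light-zone carrying capacity: cull lowest-weight clones deterministically
  if (length(keep) > params$max_clones) {
    w <- vapply(keep, function(cl) cl$n_cells * occupancy(conc, kd_apparent(cl)),
                numeric(1))
    ord <- order(w, decreasing = TRUE)
    keep <- keep[sort(ord[seq_len(params$max_clones)])]
  }

  state$pool_total <- pool
  state$clones <- keep
  state$cycle_index <- cyc
  state$history[[length(state$history) + 1L]] <- data.frame(
    cycle = cyc, clone_id = h_id, n_cells = h_n, kd_apparent = h_kd,
    captured_moles = captured, divisions = divisions, mut_h = h_mh,
    mut_l = h_ml, stringsAsFactors = FALSE
  )
  state$terminated <- length(keep) == 0
  state
}

#' Draw germinal-center founder clones from the germline range
#'
#' @param n number of founders
#' @param germline_bounds K_D bounds, molar
#' @param prefix id prefix
#' @return list of [b_cell_clone()]s in stage GC_B
#' @export
draw_founders <- function(n, germline_bounds = c(1e-10, 1e-6),
                          prefix = "f") {
  lapply(seq_len(n), function(i) {
    kd <- 10^stats::runif(1, log10(germline_bounds[1]),
                          log10(germline_bounds[2]))
    b_cell_clone(sprintf("%s%03d", prefix, i), kd, stage = "GC_B",
                 cycle_state = "G1")
  })
}

#' Run a repeated-immunization schedule
#'
#' One germinal center per dose; each subsequent germinal center is seeded
#' with the memory output of the previous one (re-entering as GC_B with their
#' matured receptors) plus fresh germline founders. Returns the pooled
#' maturation output across all doses.
#'
#' @param founders optional list of founder clones for the first dose;
#'   `NULL` draws `params$founder_n` from the germline range
#' @param schedule data.frame with columns `dose_conc` (molar) and `n_cycles`;
#'   default three equal doses of `params$dose_conc` for `params$max_cycles`
#'   cycles each
#' @param params a [gc_params()]
#' @param band an [engagement_band()]
#' @param shm an [shm_params()]
#' @return a `maturation_output`: lists `memory`, `plasma`, `llpc` plus a
#'   `summary` (see [maturation_summary()]) and per-cycle `history`
#' @export
run_immunization_schedule <- function(founders = NULL,
                                      schedule = default_schedule(params),
                                      params = gc_params(),
                                      band = engagement_band(),
                                      shm = shm_params()) {
  stopifnot(inherits(params, "gc_params"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0 ||
      !all(c("dose_conc", "n_cycles") %in% names(schedule))) {
    stop("schedule must be a non-empty data.frame with dose_conc and n_cycles",
         call. = FALSE)
  }
  out <- list(memory = list(), plasma = list(), llpc = list())
  history <- list()
  carryover <- list()
  for (dose in seq_len(nrow(schedule))) {
    fresh <- if (dose == 1 && !is.null(founders)) {
      founders
    } else {
      draw_founders(params$founder_n, params$germline_bounds,
                    prefix = sprintf("d%d.f", dose))
    }
    reentry <- lapply(carryover, function(cl) {
      cl$stage <- "GC_B"
      cl$cycle_state <- "G1"
      cl$apparent_factor <- 1
      cl
    })
    clones <- c(reentry, fresh)
    pool0 <- schedule$dose_conc[dose] * params$volume
    st <- gc_state(pool0, clones, params$volume)
    for (i in seq_len(schedule$n_cycles[dose])) {
      st <- gc_cycle(st, band, shm, params)
      if (st$terminated) break
    }
    out$memory <- c(out$memory, st$exited$memory)
    out$plasma <- c(out$plasma, st$exited$plasma)
    out$llpc <- c(out$llpc, st$exited$llpc)
    history[[dose]] <- if (length(st$history)) do.call(rbind, st$history)
    carryover <- st$exited$memory
  }
  structure(list(memory = out$memory, plasma = out$plasma, llpc = out$llpc,
                 summary = maturation_summary(out), history = history),
            class = "maturation_output")
}

#' @rdname run_immunization_schedule
#' @export
default_schedule <- function(params = gc_params()) {
  data.frame(dose_conc = rep(params$dose_conc, 3),
             n_cycles = rep(params$max_cycles, 3))
}

#' Summarize a maturation output
#'
#' @param out a `maturation_output` or a bare list with `memory`, `plasma`,
#'   `llpc` clone lists
#' @return list with clone count, geometric-mean / min / max K_D, and
#'   per-clone mutation counts
#' @export
maturation_summary <- function(out) {
  clones <- c(out$memory, out$plasma, out$llpc)
  if (length(clones) == 0) {
    return(list(n_clones = 0L, kd_geomean = NA_real_, kd_min = NA_real_,
                kd_max = NA_real_, mut_h = integer(0), mut_l = integer(0)))
  }
  kd <- vapply(clones, kd_intrinsic, numeric(1))
  list(
    n_clones = length(clones),
    kd_geomean = 10^mean(log10(kd)),
    kd_min = min(kd),
    kd_max = max(kd),
    mut_h = vapply(clones, `[[`, integer(1), "mut_h"),
    mut_l = vapply(clones, `[[`, integer(1), "mut_l")
  )
}

#' @export
format.maturation_output <- function(x, ...) {
  s <- x$summary
  sprintf(paste0("<maturation_output> %d clones (mem %d / plasma %d / llpc %d), ",
                 "K_D geomean %.3e M in [%.3e, %.3e]"),
          s$n_clones, length(x$memory), length(x$plasma), length(x$llpc),
          s$kd_geomean, s$kd_min, s$kd_max)
}

#' @export
print.maturation_output <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize a maturation output
#'
#' JSON for the clone arrays plus summary; CSV for the per-cycle history with
#' header `cycle, clone_id, n_cells, kd_apparent, captured_moles, divisions,
#' mut_h, mut_l`.
#'
#' @param out a `maturation_output`
#' @param json_path,csv_path output paths (NULL to skip either)
#' @return invisibly, the paths written
#' @export
write_maturation_output <- function(out, json_path = NULL, csv_path = NULL) {
  written <- character(0)
  if (!is.null(json_path)) {
    clone_df <- function(lst) {
      if (length(lst) == 0) return(data.frame())
      data.frame(
        clone_id = vapply(lst, `[[`, "", "clone_id"),
        kd_intrinsic = vapply(lst, kd_intrinsic, numeric(1)),
        isotype = vapply(lst, `[[`, "", "isotype"),
        n_cells = vapply(lst, `[[`, numeric(1), "n_cells"),
        mut_h = vapply(lst, `[[`, integer(1), "mut_h"),
        mut_l = vapply(lst, `[[`, integer(1), "mut_l"),
        stringsAsFactors = FALSE
      )
    }
    payload <- list(
      memory = clone_df(out$memory), plasma = clone_df(out$plasma),
      llpc = clone_df(out$llpc),
      summary = out$summary[c("n_clones", "kd_geomean", "kd_min", "kd_max")]
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    hist <- do.call(rbind, Filter(Negate(is.null), out$history))
    if (is.null(hist)) {
      hist <- data.frame(cycle = integer(0), clone_id = character(0),
                         n_cells = numeric(0), kd_apparent = numeric(0),
                         captured_moles = numeric(0), divisions = integer(0),
                         mut_h = integer(0), mut_l = integer(0))
    }
    utils::write.csv(hist, csv_path, row.names = FALSE, quote = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
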