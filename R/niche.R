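#' @title Compartment models: antigen panels and pool dynamics
#' @description A niche is an anatomical compartment with a volume and an
#'   antigen panel. Depletable niches (bone marrow, follicle, germinal
#'   center, memory sites) track the total epitope amount in moles, so B-cell
#'   binding and consumption move the free concentration; the blood is an
#'   inexhaustible pool whose concentrations never change, whatever the
#'   paratope load.
#' @name niches
NULL

#' Generate a synthetic antigen panel
#'
#' Concentrations are drawn log-uniformly, emulating the mM-to-pM span of the
#' blood proteome/glycome. For depletable panels the molar amount is
#' `concentration * volume`; replenished species carry a fixed concentration
#' and an infinite effective supply.
#'
#' @param n_species number of antigen species, >= 1
#' @param conc_low,conc_high concentration bounds, molar, 0 < low < high
#' @param replenished logical; TRUE for inexhaustible (blood-like) species
#' @param volume niche volume in liters (used for the mole count)
#' @param ids optional character ids; default `ag001`, `ag002`, ...
#' @return a data.frame with columns `ag_id`, `concentration_molar`,
#'   `replenished`, `total_epitope` (moles; `NA` for replenished species)
#' @export
make_antigen_panel <- function(n_species, conc_low = 1e-12, conc_high = 1e-3,
                               replenished = FALSE, volume = 1, ids = NULL) {
  stopifnot(n_species >= 1, volume > 0)
  if (!is.finite(conc_low) || !is.finite(conc_high) ||
      conc_low <= 0 || conc_low >= conc_high) {
    stop("require 0 < conc_low < conc_high", call. = FALSE)
  }
  conc <- 10^stats::runif(n_species, log10(conc_low), log10(conc_high))
  if (is.null(ids)) ids <- sprintf("ag%03d", seq_len(n_species))
  stopifnot(length(ids) == n_species, !anyDuplicated(ids))
  data.frame(
    ag_id = as.character(ids),
    concentration_molar = conc,
    replenished = rep_len(as.logical(replenished), n_species),
    total_epitope = ifelse(rep_len(replenished, n_species), NA_real_,
                           conc * volume),
    stringsAsFactors = FALSE
  )
}

#' Construct a niche
#'
#' @param kind one of BONE_MARROW, BLOOD, FOLLICLE, GC, MEMORY_NICHE
#' @param volume liters, > 0 (blood defaults to 5 L)
#' @param panel an antigen panel data.frame (see [make_antigen_panel()])
#' @param band an [engagement_band()]
#' @param non_cognate_rich logical; memory niches grant survival from the
#'   best log-ratio over the whole panel, not just the cognate species
#' @return a `niche`
#' @export
niche <- function(kind, volume = if (kind == "BLOOD") 5.0 else 1e-3,
                  panel, band = engagement_band(),
                  non_cognate_rich = kind == "MEMORY_NICHE") {
  if (!kind %in% NICHE_KINDS) stop("unknown niche kind: ", kind, call. = FALSE)
  stopifnot(is.numeric(volume), volume > 0, is.data.frame(panel))
  need <- c("ag_id", "concentration_molar", "replenished", "total_epitope")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (kind == "BLOOD" && !all(panel$replenished)) {
    stop("all BLOOD species must be replenished (inexhaustible pool)",
         call. = FALSE)
  }
  structure(list(kind = kind, volume = volume, panel = panel, band = band,
                 non_cognate_rich = non_cognate_rich),
            class = "niche")
}

#' @export
format.niche <- function(x, ...) {
  sprintf("<niche %s> volume=%g L, %d species (%d replenished)", x$kind,
          x$volume, nrow(x$panel), sum(x$panel$replenished))
}

#' @export
print.niche <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.panel_row <- function(nch, ag_id) {
  i <- match(ag_id, nch$panel$ag_id)
  if (is.na(i)) stop("no species '", ag_id, "' in ", nch$kind, call. = FALSE)
  i
}

#' Species concentration currently in a niche (total, before binding)
#' @param nch a [niche()]
#' @param ag_id species id
#' @return molar concentration
#' @export
species_concentration <- function(nch, ag_id) {
  i <- .panel_row(nch, ag_id)
  if (nch$panel$replenished[i]) {
    nch$panel$concentration_molar[i]
  } else {
    nch$panel$total_epitope[i] / nch$volume
  }
}

#' Free antigen concentration seen by a paratope load
#'
#' In an inexhaustible niche the free concentration is the fixed species
#' concentration: cell divisions cannot move it. In a depletable niche the
#' species equilibrates against the summed cognate paratope via
#' [solve_equilibrium()], so proliferation lowers free antigen.
#'
#' @param nch a [niche()]
#' @param ag_id species id
#' @param total_paratope summed paratope concentration, molar
#' @param kd_apparent apparent dissociation constant of the binding clones
#' @return free antigen concentration, molar
#' @export
free_antigen <- function(nch, ag_id, total_paratope, kd_apparent) {
  i <- .panel_row(nch, ag_id)
  if (nch$panel$replenished[i]) {
    return(nch$panel$concentration_molar[i])
  }
  conc <- nch$panel$total_epitope[i] / nch$volume
  solve_equilibrium(conc, total_paratope, kd_apparent)$ag_free
}

#' Update a niche's antigen pools
#'
#' Depletable species balance: consumed (division-driven uptake) and
#' antibody-mediated clearance leave the pool, antigen released by dying
#' cells returns to it. Flows exceeding the pool floor it at zero with a
#' warning. Replenished species are never altered.
#'
#' @param nch a [niche()]
#' @param consumed,released_by_death,cleared_by_antibody moles, >= 0;
#'   recycled over panel rows (use `ag_id` to address one species)
#' @param ag_id optional single species to update
#' @return the updated niche
#' @export
update_antigen_pool <- function(nch, consumed, released_by_death = 0,
                                cleared_by_antibody = 0, ag_id = NULL) {
  stopifnot(inherits(nch, "niche"))
  if (any(consumed < 0) || any(released_by_death < 0) ||
      any(cleared_by_antibody < 0)) {
    stop("pool flows must be >= 0", call. = FALSE)
  }
  rows <- if (is.null(ag_id)) seq_len(nrow(nch$panel)) else .panel_row(nch, ag_id)
  consumed <- rep_len(consumed, length(rows))
  released <- rep_len(released_by_death, length(rows))
  cleared <- rep_len(cleared_by_antibody, length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    if (nch$panel$replenished[i]) next
    new_total <- nch$panel$total_epitope[i] - consumed[j] - cleared[j] + released[j]
    if (new_total < 0) {
      warning(sprintf("flows exceed pool for species %s; floored at 0",
                      nch$panel$ag_id[i]), call. = FALSE)
      new_total <- 0
    }
    nch$panel$total_epitope[i] <- new_total
    nch$panel$concentration_molar[i] <- new_total / nch$volume
  }
  nch
}

#' Write / read an antigen panel as delimited text
#'
#' Header `ag_id, concentration_molar, replenished`; concentrations are
#' serialized with 17 significant digits so a write-read round trip is
#' bit-identical.
#'
#' @param panel a panel data.frame
#' @param path file path
#' @param sep field separator (default TAB)
#' @return `path` invisibly / the panel data.frame
#' @export
write_antigen_panel <- function(panel, path, sep = "\t") {
  out <- data.frame(
    ag_id = panel$ag_id,
    concentration_molar = sprintf("%.17g", panel$concentration_molar),
    replenished = panel$replenished,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_antigen_panel
#' @param volume volume used to derive mole counts for depletable species
#' @export
read_antigen_panel <- function(path, sep = "\t", volume = 1) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = c("character", "numeric", "logical"),
                          stringsAsFactors = FALSE)
  need <- c("ag_id", "concentration_molar", "replenished")
  if (!identical(names(df), need)) {
    stop("antigen panel must have header: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$total_epitope <- ifelse(df$replenished, NA_real_,
                             df$concentration_molar * volume)
  df
}
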