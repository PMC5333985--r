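#' @title Two-component receptor-ligand equilibrium binding
#' @description Closed-form mass-action binding between free antigen (epitope)
#'   and surface BCR (paratope), plus classification of BCR engagement into
#'   fate-relevant zones. All concentrations are molar (mol/L). Avidity and
#'   kinetics are deliberately out of scope: binding is per-epitope,
#'   per-paratope, at equilibrium.
#' @name binding
NULL

#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Working range of the affinity/concentration plane, in molar.
#'
#' Both the apparent dissociation constant and free antigen concentration are
#' mapped on \[1e-14, 1e-3\] M. Values outside trigger a warning (never an
#' error) from [affinity()].
#' @export
KD_WORKING_RANGE <- c(kd_min = 1e-14, kd_max = 1e-3)

.check_molar <- function(x, what, allow_zero = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be finite numeric, got: %s", what,
                 paste(utils::head(x), collapse = ", ")), call. = FALSE)
  }
  if (allow_zero) {
    if (any(x < 0)) stop(sprintf("%s must be >= 0", what), call. = FALSE)
  } else {
    if (any(x <= 0)) stop(sprintf("%s must be > 0", what), call. = FALSE)
  }
  invisible(x)
}

#' Validate a dissociation constant
#'
#' Errors on non-positive or non-finite values; warns (does not error) when
#' the value falls outside the working range of the simulator's plane.
#'
#' @param kd dissociation constant(s), molar
#' @return `kd`, invisibly validated
#' @export
affinity <- function(kd) {
  .check_molar(kd, "kd", allow_zero = FALSE)
  if (any(kd < KD_WORKING_RANGE[["kd_min"]] | kd > KD_WORKING_RANGE[["kd_max"]])) {
    warning(sprintf("kd outside working range [%g, %g] M",
                    KD_WORKING_RANGE[["kd_min"]], KD_WORKING_RANGE[["kd_max"]]),
            call. = FALSE)
  }
  kd
}

#' Fractional BCR occupancy at equilibrium
#'
#' theta = \[Ag\] / (\[Ag\] + K_D): the fraction of paratope bound by free
#' antigen at the stated free-antigen concentration. Occupancy is exactly 0.5
#' when `ag_free == kd`, strictly increasing in `ag_free` and strictly
#' decreasing in `kd`. Vectorized with recycling.
#'
#' @param ag_free free antigen (epitope) concentration, molar, >= 0
#' @param kd apparent dissociation constant, molar, > 0
#' @return occupancy fraction(s) in \[0, 1\]
#' @examples
#' occupancy(1e-9, 1e-9) # 0.5
#' occupancy(9e-9, 1e-9) # 0.9
#' @export
occupancy <- function(ag_free, kd) {
  .check_molar(ag_free, "ag_free")
  .check_molar(kd, "kd", allow_zero = FALSE)
  ag_free / (ag_free + kd)
}

#' Solve the two-component binding equilibrium
#'
#' Given total epitope `ag_total` (A), total paratope `bcr_total` (B) and
#' dissociation constant `kd` (K), the complex concentration is the smaller
#' root of x^2 - (A+B+K)x + AB = 0. It is computed in the cancellation-free
#' form x = 2AB / (S + sqrt(S^2 - 4AB)) with S = A+B+K, which stays accurate
#' when K is many orders of magnitude below A and B.
#'
#' @param ag_total total epitope concentration, molar, >= 0
#' @param bcr_total total paratope concentration, molar, >= 0
#' @param kd dissociation constant, molar, > 0
#' @return an `equilibrium_state`: list with `ag_free`, `bcr_free`, `complex`
#'   (molar) satisfying the conservation identities
#'   `ag_free + complex == ag_total` and `bcr_free + complex == bcr_total`.
#' @examples
#' solve_equilibrium(1e-9, 1e-9, 1e-9)$complex / 1e-9 # (3 - sqrt(5))/2
#' @export
solve_equilibrium <- function(ag_total, bcr_total, kd) {
  .check_molar(ag_total, "ag_total")
  .check_molar(bcr_total, "bcr_total")
  .check_molar(kd, "kd", allow_zero = FALSE)
  s <- ag_total + bcr_total + kd
  ab <- ag_total * bcr_total
  disc <- s * s - 4 * ab
  # disc >= K^2 + 2K(A+B) + (A-B)^2 >= 0 analytically; guard fp noise
  disc[disc < 0] <- 0
  x <- ifelse(ab == 0, 0, 2 * ab / (s + sqrt(disc)))
  structure(
    list(ag_free = ag_total - x, bcr_free = bcr_total - x, complex = x),
    class = "equilibrium_state"
  )
}

#' @export
format.equilibrium_state <- function(x, ...) {
  sprintf("<equilibrium_state> ag_free=%.6e bcr_free=%.6e complex=%.6e",
          x$ag_free, x$bcr_free, x$complex)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

ENGAGEMENT_LEVELS <- c("NEGLECT", "UNDER", "COMFORT", "OVER", "SATURATED")

#' Engagement band parameters
#'
#' The comfort zone is the diagonal band |log10(\[Ag\]/K_D)| <= `delta_comfort`
#' on the log-log plane, bracketing 50% occupancy. Outside it, occupancy below
#' `theta_neglect` is neglect (no survival signal) and above `theta_saturated`
#' is saturation (unresponsive). The construction requires the neglect and
#' saturation thresholds to lie strictly outside the occupancy attained at the
#' band edges, so the five classes partition the plane.
#'
#' @param delta_comfort half-width of the comfort band, log10 units, > 0
#' @param theta_neglect occupancy below which engagement is NEGLECT
#' @param theta_saturated occupancy above which engagement is SATURATED
#' @param delta_b1 log-ratio bound separating moderate over-engagement
#'   (the B1 band in blood) from strong activation, log10 units
#' @return an `engagement_band` list
#' @export
engagement_band <- function(delta_comfort = 0.5, theta_neglect = 0.01,
                            theta_saturated = 0.99, delta_b1 = 1.5) {
  if (!is.finite(delta_comfort) || delta_comfort <= 0) {
    stop("delta_comfort must be > 0", call. = FALSE)
  }
  theta_edge_lo <- 1 / (1 + 10^delta_comfort)
  theta_edge_hi <- 10^delta_comfort / (1 + 10^delta_comfort)
  if (!is.finite(theta_neglect) || theta_neglect <= 0 ||
      theta_neglect >= theta_edge_lo) {
    stop(sprintf(
      "theta_neglect must lie in (0, %.4f), the occupancy at the lower band edge",
      theta_edge_lo), call. = FALSE)
  }
  if (!is.finite(theta_saturated) || theta_saturated >= 1 ||
      theta_saturated <= theta_edge_hi) {
    stop(sprintf(
      "theta_saturated must lie in (%.4f, 1), above the occupancy at the upper band edge",
      theta_edge_hi), call. = FALSE)
  }
  if (!is.finite(delta_b1) || delta_b1 <= delta_comfort) {
    stop("delta_b1 must exceed delta_comfort", call. = FALSE)
  }
  structure(list(delta_comfort = delta_comfort,
                 theta_neglect = theta_neglect,
                 theta_saturated = theta_saturated,
                 delta_b1 = delta_b1),
            class = "engagement_band")
}

#' Classify BCR engagement
#'
#' Deterministic classification of a (free antigen, apparent K_D) pair into
#' one of NEGLECT < UNDER < COMFORT < OVER < SATURATED. COMFORT iff
#' |log10(ag/kd)| <= delta_comfort; NEGLECT iff occupancy < theta_neglect;
#' SATURATED iff occupancy > theta_saturated; otherwise UNDER or OVER by the
#' sign of the log-ratio. `ag_free == 0` maps to NEGLECT by convention (the
#' log-ratio is undefined but there is no engagement at all).
#'
#' @param ag_free free antigen concentration, molar, >= 0
#' @param kd_apparent apparent dissociation constant, molar, > 0
#' @param band an [engagement_band()]
#' @return ordered factor over the five engagement levels (vectorized)
#' @export
classify_engagement <- function(ag_free, kd_apparent, band = engagement_band()) {
  stopifnot(inherits(band, "engagement_band"))
  .check_molar(ag_free, "ag_free")
  .check_molar(kd_apparent, "kd_apparent", allow_zero = FALSE)
  n <- max(length(ag_free), length(kd_apparent))
  ag <- rep_len(ag_free, n)
  kd <- rep_len(kd_apparent, n)
  theta <- ag / (ag + kd)
  out <- character(n)
  zero <- ag == 0
  lr <- ifelse(zero, -Inf, log10(ag / kd))
  out[theta < band$theta_neglect | zero] <- "NEGLECT"
  sat <- theta > band$theta_saturated & !zero
  out[sat] <- "SATURATED"
  rest <- out == ""
  out[rest & abs(lr) <= band$delta_comfort] <- "COMFORT"
  out[rest & out == "" & lr < 0] <- "UNDER"
  out[rest & out == "" & lr > 0] <- "OVER"
  factor(out, levels = ENGAGEMENT_LEVELS, ordered = TRUE)
}

# scalar fast path used in simulation inner loops; same rules as
# classify_engagement without factor/validation overhead
.engagement_label <- function(ag, kd, band) {
  if (ag == 0) return("NEGLECT")
  theta <- ag / (ag + kd)
  if (theta < band$theta_neglect) return("NEGLECT")
  if (theta > band$theta_saturated) return("SATURATED")
  lr <- log10(ag / kd)
  if (abs(lr) <= band$delta_comfort) return("COMFORT")
  if (lr < 0) "UNDER" else "OVER"
}

#' Convert a molecule count in a volume to molarity
#'
#' @param n_molecules number of molecules, >= 0
#' @param volume volume in liters, > 0
#' @return concentration in mol/L
#' @examples
#' molarity_from_count(10, 1e-8) # ten molecules in ten nanoliters
#' @export
molarity_from_count <- function(n_molecules, volume) {
  if (!is.numeric(n_molecules) || any(!is.finite(n_molecules)) || any(n_molecules < 0)) {
    stop("n_molecules must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be finite and > 0", call. = FALSE)
  }
  n_molecules / (AVOGADRO * volume)
}
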