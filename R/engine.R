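#' @title Discrete-time scheduler and outputs
#' @description Ties niches and clones together in a synchronous per-step
#'   loop: compute free antigen, classify engagement, decide and apply fates,
#'   update pools, record one trajectory row per (step, clone). Time is an
#'   abstract decision epoch; no wall-clock unit is implied.
#' @name engine_io
NULL

.trajectory_skeleton <- function() {
  data.frame(step = integer(0), niche = character(0), clone_id = character(0),
             stage = character(0), n_cells = numeric(0),
             kd_apparent = numeric(0), occupancy = numeric(0),
             ag_free = numeric(0), action = character(0),
             stringsAsFactors = FALSE)
}

.build_world <- function(cfg) {
  band <- .band_from_config(cfg)
  set.seed(substream_seed(cfg$seed, "panels"))
  blood_panel <- make_antigen_panel(cfg$blood$n_species, cfg$blood$conc_low,
                                    cfg$blood$conc_high, replenished = TRUE,
                                    volume = cfg$blood$volume)
  # bone-marrow / follicular display mirrors the blood panel composition at a
  # configurable capture efficiency; the mechanism (C1q/FcmuR) is out of scope
  mirror <- function(eff, volume) {
    p <- blood_panel
    p$replenished <- FALSE
    p$concentration_molar <- p$concentration_molar * eff
    p$total_epitope <- p$concentration_molar * volume
    p
  }
  niches <- list(
    BONE_MARROW = niche("BONE_MARROW", cfg$bone_marrow$volume,
                        mirror(cfg$bone_marrow$display_efficiency,
                               cfg$bone_marrow$volume), band),
    BLOOD = niche("BLOOD", cfg$blood$volume, blood_panel, band),
    FOLLICLE = niche("FOLLICLE", cfg$follicle$volume,
                     mirror(cfg$follicle$display_efficiency,
                            cfg$follicle$volume), band)
  )
  set.seed(substream_seed(cfg$seed, "founders"))
  clones <- lapply(seq_len(cfg$clones$n_founders), function(i) {
    kd <- 10^stats::runif(1, log10(cfg$germline$kd_min),
                          log10(cfg$germline$kd_max))
    b_cell_clone(sprintf("c%03d", i), kd,
                 bcr_per_cell = cfg$agents$bcr_per_cell,
                 stage = "IMMATURE",
                 edit_attempts_left = cfg$agents$edit_attempts)
  })
  cognate <- sample(blood_panel$ag_id, cfg$clones$n_founders, replace = TRUE)
  locations <- rep(cfg$clones$start_niche, cfg$clones$n_founders)
  list(niches = niches, clones = clones, cognate = cognate,
       location = locations, band = band)
}

.effective_kd <- function(clones_idx, clones) {
  # one species equilibrates against the summed paratope; with heterogeneous
  # receptors we use the paratope-weighted mean log10 apparent K_D
  w <- vapply(clones_idx, function(i) paratope_count(clones[[i]]), numeric(1))
  l <- vapply(clones_idx, function(i) log10(kd_apparent(clones[[i]])), numeric(1))
  if (sum(w) == 0) return(10^mean(l))
  10^(sum(w * l) / sum(w))
}

#' Run the simulator
#'
#' Synchronous per-step loop over the bone marrow, blood and follicle niches.
#' Emigration: an IMMATURE clone resting in the bone-marrow comfort zone
#' emigrates to blood; an immature clone resting in blood becomes
#' TRANSITIONAL and homes to a follicle. B1 clones persist in G1 and divide
#' every `agents$b1_division_period` steps. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a validated configuration (see [default_config()],
#'   [validate_config()])
#' @return list with `trajectory` (data.frame of per-step records), `clones`
#'   (final clone list), `location` (final niche per clone), `niches`
#'   (final niche states) and `summary`
#' @export
simulate <- function(cfg = default_config()) {
  validate_config(cfg)
  world <- .build_world(cfg)
  niches <- world$niches
  clones <- world$clones
  cognate <- world$cognate
  location <- world$location
  band <- world$band
  records <- list()
  set.seed(substream_seed(cfg$seed, "fates"))

  for (step in seq_len(cfg$n_steps)) {
    if (length(clones) == 0) break
    alive <- rep(TRUE, length(clones))
    for (nk in names(niches)) {
      here <- which(location == nk & alive)
      if (length(here) == 0) next
      nch <- niches[[nk]]
      consumed_by <- stats::setNames(rep(0, nrow(nch$panel)), nch$panel$ag_id)
      released_by <- consumed_by
      for (i in here) {
        cl <- clones[[i]]
        ag_id <- cognate[i]
        mates <- here[cognate[here] == ag_id]
        total_paratope <- sum(vapply(mates, function(j)
          paratope_count(clones[[j]]), numeric(1))) / (AVOGADRO * nch$volume)
        kd_eff <- .effective_kd(mates, clones)
        agf <- free_antigen(nch, ag_id, total_paratope, kd_eff)
        kd_app <- kd_apparent(cl)
        cls <- classify_engagement(agf, kd_app, band)
        theta <- occupancy(agf, kd_app)
        second <- isTRUE(cfg$clones$second_signal)
        fa <- if (nk == "BLOOD" && cl$stage %in% c("IMMATURE", "TRANSITIONAL")) {
          lr <- if (agf > 0) log10(agf / kd_app) else -Inf
          classify_blood_fate(cl, cls, second, lr, band)
        } else {
          decide_fate(cl, cls, nk, second)
        }
        # B1 cadence: persists in G1, dividing from time to time
        if (cl$stage == "B1" && fa$action == "PERSIST_G1" &&
            step %% cfg$agents$b1_division_period == 0) {
          fa <- fate_action("DIVIDE", new_stage = NULL)
        }
        records[[length(records) + 1L]] <- data.frame(
          step = step, niche = nk, clone_id = cl$clone_id, stage = cl$stage,
          n_cells = cl$n_cells, kd_apparent = kd_app, occupancy = theta,
          ag_free = agf, action = fate_label(fa), stringsAsFactors = FALSE
        )
        cl <- apply_fate_differentiation(cl, fa)
        if (fa$action == "DIE") {
          alive[i] <- FALSE
          eq <- solve_equilibrium(species_concentration(nch, ag_id),
                                  total_paratope, kd_eff)
          released_by[ag_id] <- released_by[ag_id] + eq$complex * nch$volume
        } else if (fa$action %in% c("DIVIDE", "SWITCH_ISOTYPE")) {
          if (fa$action == "SWITCH_ISOTYPE") {
            cl <- isotype_switch(cl, "IgG", cfg$agents$switch_gain)
          }
          n_before <- cl$n_cells
          cl <- suppressWarnings(
            divide_clone(cl, cfg$agents$division_mode,
                         cfg$agents$population_cap))
          # dividing clones consume the complex newly formed by their daughter
          # receptors; standing complex is only sequestered (reversible binding)
          if (!nch$panel$replenished[.panel_row(nch, ag_id)]) {
            A <- species_concentration(nch, ag_id)
            x0 <- solve_equilibrium(A, total_paratope, kd_eff)$complex
            added <- (cl$n_cells - n_before) * cl$bcr_per_cell /
              (AVOGADRO * nch$volume)
            x1 <- solve_equilibrium(A, total_paratope + added, kd_eff)$complex
            consumed_by[ag_id] <- consumed_by[ag_id] +
              max(0, x1 - x0) * nch$volume
          }
        } else if (fa$action == "EDIT_RECEPTOR") {
          cl <- receptor_edit(cl, c(cfg$germline$kd_min, cfg$germline$kd_max))
        } else if (fa$action == "REST_G0") {
          if (nk == "BONE_MARROW" && cl$stage == "IMMATURE") {
            location[i] <- "BLOOD" # emigrate once selected into comfort
          } else if (nk == "BLOOD" && cl$stage == "IMMATURE") {
            cl$stage <- "TRANSITIONAL"
            location[i] <- "FOLLICLE"
          }
        }
        clones[[i]] <- cl
      }
      if (any(consumed_by > 0) || any(released_by > 0)) {
        niches[[nk]] <- update_antigen_pool(nch, consumed_by, released_by)
      }
    }
    if (!all(alive)) {
      clones <- clones[alive]
      cognate <- cognate[alive]
      location <- location[alive]
    }
  }

  trajectory <- if (length(records)) {
    do.call(rbind, records)
  } else {
    .trajectory_skeleton()
  }
  summary <- list(
    n_steps = cfg$n_steps,
    n_clones_final = length(clones),
    stages = if (length(clones)) {
      as.list(table(vapply(clones, `[[`, "", "stage")))
    } else {
      stats::setNames(list(), character(0))
    },
    seed = cfg$seed
  )
  list(trajectory = trajectory, clones = clones, location = location,
       niches = niches, summary = summary)
}

#' Engagement phase map over the affinity-concentration plane
#'
#' Classifies every (free antigen, apparent K_D) grid point; the comfort zone
#' appears as a contiguous diagonal band of width `2 * delta_comfort` decades.
#'
#' @param grid_ag,grid_kd positive molar grid values (log-spaced recommended)
#' @param band an [engagement_band()]
#' @return character matrix, rows indexed by `grid_ag`, columns by `grid_kd`
#' @export
phase_map <- function(grid_ag, grid_kd, band = engagement_band()) {
  if (length(grid_ag) == 0 || length(grid_kd) == 0) {
    stop("phase_map requires non-empty grids", call. = FALSE)
  }
  .check_molar(grid_ag, "grid_ag")
  .check_molar(grid_kd, "grid_kd", allow_zero = FALSE)
  m <- matrix(NA_character_, length(grid_ag), length(grid_kd),
              dimnames = list(sprintf("%.3e", grid_ag),
                              sprintf("%.3e", grid_kd)))
  for (j in seq_along(grid_kd)) {
    m[, j] <- as.character(classify_engagement(grid_ag, grid_kd[j], band))
  }
  m
}

#' Decade grid helper
#' @param from,to molar bounds
#' @param per_decade grid points per decade
#' @return log-spaced molar values
#' @export
decade_grid <- function(from = 1e-14, to = 1e-3, per_decade = 1) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

.fmt_sci9 <- function(x) sprintf("%.8e", x)

#' Write simulation outputs
#'
#' Trajectory CSV (fixed header, comma-separated, LF, UTF-8, floats in
#' scientific notation with 9 significant digits for replay-diffing),
#' summary JSON, and optionally a phase-map TSV grid.
#'
#' @param records trajectory data.frame (see [simulate()])
#' @param summary summary list
#' @param out_dir output directory (created if missing)
#' @param phase optional phase-map matrix from [phase_map()]
#' @return named character vector of files written
#' @export
write_outputs <- function(records, summary, out_dir, phase = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  traj_path <- file.path(out_dir, "trajectory.csv")
  df <- records
  for (col in c("n_cells", "kd_apparent", "occupancy", "ag_free")) {
    df[[col]] <- .fmt_sci9(df[[col]])
  }
  con <- file(traj_path, open = "wb") # LF endings on every platform
  tryCatch({
    writeLines(paste(names(df), collapse = ","), con)
    if (nrow(df)) {
      writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
    }
  }, finally = close(con))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(trajectory = traj_path, summary = summary_path)
  if (!is.null(phase)) {
    phase_path <- file.path(out_dir, "phase_map.tsv")
    utils::write.table(phase, phase_path, sep = "\t", quote = FALSE,
                       col.names = NA)
    files <- c(files, phase_map = phase_path)
  }
  files
}

#' Read back a trajectory CSV written by [write_outputs()]
#' @param path file path
#' @return trajectory data.frame with numeric columns restored
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("n_cells", "kd_apparent", "occupancy", "ag_free")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
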