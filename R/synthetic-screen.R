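## Synthetic genome-scale screen tables with known ground truth:
## plate offsets, smooth covariate trends (cell size, cell count, well
## order), planted mutant effects and residual noise.

#' Specification of a simulated ER-expansion screen
#'
#' One row is generated per (plate, well, field). Each plate carries
#' `wells_per_plate` mutant wells plus `n_controls_per_plate` untreated
#' wild-type control wells; every well is imaged in `fields_per_well`
#' fields of view.
#'
#' @param n_plates number of plates (default 16).
#' @param wells_per_plate mutant wells per plate (default 300).
#' @param fields_per_well fields of view per well (default 2).
#' @param n_controls_per_plate wild-type control wells per plate (default 2).
#' @param plate_offset_sd SD of per-plate additive offsets, in metric units.
#' @param covariate_effects list of smooth-trend amplitudes (metric units)
#'   for `size`, `count` and `order`; sinusoidal shapes over the covariate
#'   range.
#' @param residual_sd residual field-to-field SD of each metric.
#' @param planted_hits data frame with columns `mutant`, `z_peripheral`,
#'   `z_profile`, `z_gaps`: planted effect sizes in units of `residual_sd`.
#'   Mutant ids are "p<plate>_m<well>".
#' @param seed integer seed.
#' @return object of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_plates = 16,
                            wells_per_plate = 300,
                            fields_per_well = 2,
                            n_controls_per_plate = 2,
                            plate_offset_sd = 0.03,
                            covariate_effects = list(size = 0.015, count = 0.015,
                                                     order = 0.015),
                            residual_sd = 0.05,
                            planted_hits = NULL,
                            seed = 1) {
  spec <- structure(as.list(environment()), class = "screen_sim_spec")
  assert_that(spec$plate_offset_sd >= 0 && spec$residual_sd >= 0,
              "all SDs must be >= 0")
  assert_that(spec$fields_per_well >= 1, "fields_per_well must be >= 1")
  if (!is.null(planted_hits)) {
    valid <- unlist(lapply(seq_len(n_plates), function(p)
      sprintf("p%02d_m%03d", p, seq_len(wells_per_plate))))
    assert_that(all(planted_hits$mutant %in% valid),
                "planted hit ids must be simulated mutant ids")
  }
  spec
}

# the three metrics at wild-type-like levels (fractions / gaps per um)
screen_metric_means <- c(peripheral_er_size = 0.45,
                         er_profile_size = 0.15,
                         er_gaps_per_um = 0.8)

#' Simulate a screen measurement table
#'
#' Each metric value is the global mean plus a plate offset, smooth
#' covariate trends in mean cell area, cell count and well order, any
#' planted mutant effect (in residual-SD units) and Gaussian residual
#' noise. Marker intensity gets the same plate/size/count structure.
#'
#' @param spec a [screen_sim_spec()].
#' @return list with `table` (one row per plate/well/field) and `truth`
#'   (the planted-hit table, possibly empty).
#' @export
simulate_screen_table <- function(spec) {
  with_seed(derive_seed(spec$seed, 11L), simulate_screen_impl(spec))
}

simulate_screen_impl <- function(spec) {
  hits <- spec$planted_hits
  plates <- list()
  for (p in seq_len(spec$n_plates)) {
    n_wells <- spec$wells_per_plate + spec$n_controls_per_plate
    nf <- spec$fields_per_well
    n <- n_wells * nf
    is_control <- c(rep(TRUE, spec$n_controls_per_plate),
                    rep(FALSE, spec$wells_per_plate))
    mutant <- c(rep("control", spec$n_controls_per_plate),
                sprintf("p%02d_m%03d", p, seq_len(spec$wells_per_plate)))
    ord <- sample.int(n_wells)               # imaging order of the wells
    plate_off <- rnorm(3, 0, spec$plate_offset_sd)
    plate_off_int <- rnorm(1, 0, 10)
    wi <- rep(seq_len(n_wells), each = nf)   # row -> well index
    cnt <- pmax(5, round(rnorm(n, 150, 40)))
    area <- rnorm(n, 1200, 120)
    sz <- (area - 1200) / 120                # standardized covariates
    ct <- (cnt - 150) / 40
    wo <- ord[wi] / n_wells
    trend <- spec$covariate_effects$size * sin(sz) +
      spec$covariate_effects$count * sin(ct) +
      spec$covariate_effects$order * sin(2 * pi * wo)
    eff <- matrix(0, n, 3)
    if (!is.null(hits) && nrow(hits) > 0) {
      hm <- match(mutant[wi], hits$mutant)
      sel <- !is.na(hm)
      eff[sel, ] <- as.matrix(hits[hm[sel], c("z_peripheral", "z_profile",
                                              "z_gaps")]) * spec$residual_sd
    }
    noise <- matrix(rnorm(3 * n, 0, spec$residual_sd), n, 3)
    vals <- matrix(screen_metric_means, n, 3, byrow = TRUE) +
      matrix(plate_off, n, 3, byrow = TRUE) + trend + eff + noise
    intensity <- 100 + plate_off_int + 5 * sin(sz) + 4 * sin(ct) +
      rnorm(n, 0, 3)
    plates[[p]] <- data.frame(
      plate = sprintf("P%02d", p), well = wi, well_order = ord[wi],
      field = rep(seq_len(nf), n_wells), mutant = mutant[wi],
      is_control = is_control[wi], cell_count = cnt, mean_cell_area = area,
      mean_marker_intensity = intensity,
      peripheral_er_size = vals[, 1], er_profile_size = vals[, 2],
      er_gaps_per_um = vals[, 3])
  }
  tab <- do.call(rbind, plates)
  rownames(tab) <- NULL
  truth <- if (is.null(hits))
    data.frame(mutant = character(0), z_peripheral = numeric(0),
               z_profile = numeric(0), z_gaps = numeric(0)) else hits
  list(table = tab, truth = truth)
}
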