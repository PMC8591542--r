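## Screen scoring: plate normalization, local-regression covariate
## correction, background-population Z scores, per-sample aggregation and
## 2-of-3-metric hit calling.

#' Parameters of the screen-scoring procedure
#'
#' @param loess_span span of the locally weighted linear regression used
#'   for covariate correction (default 0.3).
#' @param loess_iterations robustness (redescending) iterations (default 2).
#' @param bp_sd_limit background population: mutants within this many SDs
#'   of the plate-mean corrected marker intensity (default 1.5).
#' @param min_cell_count fields with fewer analyzed cells are dropped
#'   before scoring (default 25).
#' @param z_threshold hit threshold magnitude (default 2): peripheral ER
#'   size and ER profile size flag at Z < -2, ER gaps at Z > 2.
#' @param min_flags metrics that must pass for a hit (default 2 of 3).
#' @return object of class `screen_params`.
#' @export
screen_params <- function(loess_span = 0.3, loess_iterations = 2,
                          bp_sd_limit = 1.5, min_cell_count = 25,
                          z_threshold = 2, min_flags = 2) {
  structure(as.list(environment()), class = "screen_params")
}

screen_metric_cols <- c("peripheral_er_size", "er_profile_size", "er_gaps_per_um")

#' Local-regression covariate correction
#'
#' Subtracts a locally weighted quadratic (degree 2, tricube weights,
#' redescending robustness) fit of `values` on `covariate`. With fewer than
#' 10 points the values are returned unchanged with a warning.
#'
#' @param values numeric response.
#' @param covariate numeric covariate, finite.
#' @param span loess span (default 0.3).
#' @param iterations robustness iterations (default 2).
#' @return residuals (same length as `values`).
#' @export
loess_correct <- function(values, covariate, span = 0.3, iterations = 2) {
  if (length(values) < 10) {
    warning("fewer than 10 points: local regression skipped")
    return(values)
  }
  assert_that(all(is.finite(covariate)), "covariate must be finite")
  fit <- loess(values ~ covariate, span = span, degree = 2,
               family = "symmetric",
               control = loess.control(iterations = iterations,
                                       surface = "interpolate"))
  values - fitted(fit)
}

#' Normalize marker intensity across plates and covariates
#'
#' Per-plate mean centering of the marker intensity, followed by sequential
#' local-regression correction against mean cell area and cell count within
#' each plate. Plates with fewer than 10 rows are centered only.
#'
#' @param table a screen table (see [simulate_screen_table()] for the
#'   column schema).
#' @param params a [screen_params()].
#' @return `table` with an added `intensity_corrected` column.
#' @export
normalize_intensity <- function(table, params = screen_params()) {
  out <- table
  out$intensity_corrected <- NA_real_
  for (p in unique(table$plate)) {
    i <- which(table$plate == p)
    v <- table$mean_marker_intensity[i] - mean(table$mean_marker_intensity[i])
    if (length(i) >= 10) {
      v <- loess_correct(v, table$mean_cell_area[i], params$loess_span,
                         params$loess_iterations)
      v <- loess_correct(v, table$cell_count[i], params$loess_span,
                         params$loess_iterations)
    } else {
      message("plate ", p, " has fewer than 10 rows: centered only")
    }
    out$intensity_corrected[i] <- v
  }
  out
}

#' Define a plate's background population
#'
#' Members are the plate's rows whose corrected marker intensity lies
#' within `bp_sd_limit` standard deviations of the plate mean; the
#' background mean and SD of each ER metric are computed over the members.
#'
#' @param table screen table with `intensity_corrected`
#'   (see [normalize_intensity()]).
#' @param plate plate id.
#' @param params a [screen_params()].
#' @return object of class `background_population`: list with `plate`,
#'   `member_rows` (row indices into `table`), `bp_mean`, `bp_sd` (named
#'   per-metric vectors).
#' @export
define_background_population <- function(table, plate,
                                         params = screen_params()) {
  i <- which(table$plate == plate)
  assert_that(length(i) > 0, paste("no rows for plate", plate))
  v <- table$intensity_corrected[i]
  keep <- abs(v - mean(v)) <= params$bp_sd_limit * sd(v)
  members <- i[keep]
  assert_that(length(members) >= 3, "background population has < 3 members")
  bp_mean <- vapply(screen_metric_cols, function(m) mean(table[[m]][members]),
                    numeric(1))
  bp_sd <- vapply(screen_metric_cols, function(m) sd(table[[m]][members]),
                  numeric(1))
  assert_that(all(bp_sd > 0), "background population has zero metric SD")
  structure(list(plate = plate, member_rows = members,
                 bp_mean = bp_mean, bp_sd = bp_sd),
            class = "background_population")
}

#' Per-field Z scores with well-order and cell-count correction
#'
#' Z = (value - BP mean) / BP SD per metric using the row's plate
#' background population, then per-plate local-regression correction of
#' each Z against well order, then against cell count.
#'
#' @param table screen table with `intensity_corrected`.
#' @param bps list of `background_population` objects, one per plate (by
#'   default computed from `table`).
#' @param params a [screen_params()].
#' @return `table` with added `z_peripheral`, `z_profile`, `z_gaps`.
#' @export
compute_zscores <- function(table, bps = NULL, params = screen_params()) {
  plates <- unique(table$plate)
  if (is.null(bps)) {
    bps <- lapply(plates, define_background_population, table = table,
                  params = params)
    names(bps) <- plates
  }
  zcols <- c(z_peripheral = "peripheral_er_size",
             z_profile = "er_profile_size", z_gaps = "er_gaps_per_um")
  out <- table
  for (zc in names(zcols)) out[[zc]] <- NA_real_
  for (p in plates) {
    i <- which(table$plate == p)
    bp <- bps[[p]]
    for (zc in names(zcols)) {
      m <- zcols[[zc]]
      z <- (table[[m]][i] - bp$bp_mean[[m]]) / bp$bp_sd[[m]]
      if (length(i) >= 10) {
        z <- loess_correct(z, table$well_order[i], params$loess_span,
                           params$loess_iterations)
        z <- loess_correct(z, table$cell_count[i], params$loess_span,
                           params$loess_iterations)
      }
      out[[zc]][i] <- z
    }
  }
  out
}

#' Aggregate per-field Z scores per sample
#'
#' For each sample (plate, well) and metric, retains the field-level Z of
#' maximal absolute value with its sign preserved, so negative
#' (underexpansion) scores are not masked.
#'
#' @param ztable output of [compute_zscores()].
#' @return data frame with one row per sample: plate, well, mutant,
#'   is_control, n_fields and the three aggregated Z scores.
#' @export
aggregate_per_sample <- function(ztable) {
  key <- interaction(ztable$plate, ztable$well, drop = TRUE)
  idx <- split(seq_len(nrow(ztable)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  signed_absmax <- function(col)
    vapply(idx, function(i) col[i][which.max(abs(col[i]))], numeric(1))
  out <- data.frame(
    plate = ztable$plate[first], well = ztable$well[first],
    mutant = ztable$mutant[first], is_control = ztable$is_control[first],
    n_fields = lengths(idx),
    z_peripheral = signed_absmax(ztable$z_peripheral),
    z_profile = signed_absmax(ztable$z_profile),
    z_gaps = signed_absmax(ztable$z_gaps))
  rownames(out) <- NULL
  out[order(out$plate, out$well), , drop = FALSE]
}

#' Call ER-expansion hits
#'
#' Flags peripheral ER size and ER profile size at Z < -threshold and ER
#' gaps at Z > threshold (strict inequalities); a sample is a hit when at
#' least `min_flags` of the three metrics flag.
#'
#' @param records aggregated Z records from [aggregate_per_sample()].
#' @param params a [screen_params()].
#' @return `records` with added flag columns and `is_hit`.
#' @export
call_hits <- function(records, params = screen_params()) {
  t <- params$z_threshold
  records$flag_peripheral <- records$z_peripheral < -t
  records$flag_profile <- records$z_profile < -t
  records$flag_gaps <- records$z_gaps > t
  nflag <- records$flag_peripheral + records$flag_profile + records$flag_gaps
  records$n_flags <- nflag
  records$is_hit <- nflag >= params$min_flags
  records
}

#' Score a whole screen table
#'
#' Drops fields below the minimum cell count, normalizes marker intensity,
#' defines per-plate background populations, computes corrected per-field
#' Z scores, aggregates per sample and calls hits.
#'
#' @param table screen table (schema of [simulate_screen_table()]).
#' @param params a [screen_params()].
#' @return list with `fields` (per-field Z table), `samples` (aggregated
#'   records with hit flags) and `background_populations`.
#' @export
score_screen <- function(table, params = screen_params()) {
  table <- table[table$cell_count >= params$min_cell_count, , drop = FALSE]
  assert_that(nrow(table) > 0, "no fields pass the minimum cell count")
  table <- normalize_intensity(table, params)
  plates <- unique(table$plate)
  bps <- lapply(plates, define_background_population, table = table,
                params = params)
  names(bps) <- plates
  ztab <- compute_zscores(table, bps, params)
  samples <- call_hits(aggregate_per_sample(ztab), params)
  list(fields = ztab, samples = samples, background_populations = bps)
}
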