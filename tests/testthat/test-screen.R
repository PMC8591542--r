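# Screen scoring: local regression, normalization, background populations,
# Z scores, aggregation and hit calling.

test_that("local regression removes smooth trends and shifts exactly", {
  set.seed(4)
  x <- runif(1000, 0, 6)
  y <- sin(x) + rnorm(1000, 0, 0.3)
  r <- loess_correct(y, x)
  expect_lt(abs(cor(r, sin(x))), 0.05)
  expect_lt(abs(mean(r)), 0.02)
  expect_lt(max(abs(loess_correct(y + 11, x) - r)), 1e-10)

  # independent covariate: the fit is flat, residuals are centered values
  y2 <- rnorm(500)
  x2 <- runif(500)
  r2 <- loess_correct(y2, x2)
  expect_lt(abs(coef(lm((y2 - r2) ~ x2))[2]), 0.1)

  expect_warning(r3 <- loess_correct(1:5, 1:5), "fewer than 10")
  expect_identical(r3, 1:5)
})

test_that("intensity normalization centers plates and absorbs plate offsets", {
  spec <- screen_sim_spec(n_plates = 4, wells_per_plate = 80,
                          covariate_effects = list(size = 0, count = 0, order = 0),
                          seed = 19)
  tab <- simulate_screen_table(spec)$table
  norm <- normalize_intensity(tab)
  by_plate <- tapply(norm$intensity_corrected, norm$plate, mean)
  expect_true(all(abs(by_plate) < 0.5))   # plate offsets (sd 10) removed
  # row order does not matter
  set.seed(1)
  perm <- sample(nrow(tab))
  norm2 <- normalize_intensity(tab[perm, ])
  expect_equal(norm2$intensity_corrected[order(perm)],
               norm$intensity_corrected, tolerance = 1e-12)
})

test_that("background population keeps a homogeneous plate and excludes an
           intensity outlier", {
  spec <- screen_sim_spec(n_plates = 1, wells_per_plate = 100, seed = 23)
  tab <- normalize_intensity(simulate_screen_table(spec)$table)
  bp <- define_background_population(tab, "P01")
  expect_gt(length(bp$member_rows) / nrow(tab), 0.8)

  tab2 <- tab
  i <- which(tab2$mutant == "p01_m050")
  # central covariates so the outlier sits in a dense local-fit region
  tab2$mean_cell_area[i] <- median(tab2$mean_cell_area)
  tab2$cell_count[i] <- median(tab2$cell_count)
  tab2$mean_marker_intensity[i] <- mean(tab2$mean_marker_intensity) +
    6 * sd(tab2$mean_marker_intensity)
  tab2 <- normalize_intensity(tab2[, setdiff(names(tab2), "intensity_corrected")])
  bp2 <- define_background_population(tab2, "P01")
  expect_false(any(i %in% bp2$member_rows))
  expect_true(all(bp2$bp_sd > 0))
})

test_that("a row at the background mean scores zero before corrections", {
  # a plate too small for loess keeps raw Z = (x - bp_mean) / bp_sd
  tab <- data.frame(plate = "P01", well = 1:8, well_order = 1:8, field = 1,
                    mutant = sprintf("m%d", 1:8), is_control = FALSE,
                    cell_count = 100, mean_cell_area = 1000,
                    mean_marker_intensity = 100,
                    peripheral_er_size = c(0.4, 0.5, 0.45, 0.45, 0.42, 0.48, 0.44, 0.46),
                    er_profile_size = seq(0.12, 0.19, length.out = 8),
                    er_gaps_per_um = seq(0.7, 0.9, length.out = 8))
  tab$intensity_corrected <- 0
  bp <- define_background_population(tab, "P01")
  suppressWarnings(z <- compute_zscores(tab, setNames(list(bp), "P01")))
  i <- which.min(abs(tab$peripheral_er_size - bp$bp_mean["peripheral_er_size"]))
  expect_equal(z$z_peripheral[i],
               (tab$peripheral_er_size[i] - bp$bp_mean["peripheral_er_size"]) /
                 bp$bp_sd["peripheral_er_size"],
               ignore_attr = TRUE)
})

test_that("aggregation keeps the signed maximum-magnitude field score", {
  zt <- data.frame(plate = "P01", well = c(1, 2, 2, 3, 3),
                   mutant = c("a", "b", "b", "c", "c"), is_control = FALSE,
                   z_peripheral = c(-1.2, -2.6, -0.3, 1.0, -3.0),
                   z_profile = 0, z_gaps = 0)
  agg <- aggregate_per_sample(zt)
  expect_equal(agg$z_peripheral[agg$mutant == "a"], -1.2)
  expect_equal(agg$z_peripheral[agg$mutant == "b"], -2.6)
  expect_equal(agg$z_peripheral[agg$mutant == "c"], -3.0)
  expect_equal(agg$n_fields[agg$mutant == "b"], 2)
})

test_that("hit calling uses strict thresholds and the 2-of-3 rule", {
  rec <- data.frame(mutant = c("a", "b", "c"),
                    z_peripheral = c(-2.5, -2.5, -1.9),
                    z_profile = c(-2.1, -1.0, -1.9),
                    z_gaps = c(1.0, 1.0, 1.9))
  hits <- call_hits(rec)
  expect_equal(hits$is_hit, c(TRUE, FALSE, FALSE))
  expect_equal(hits$n_flags, c(2, 1, 0))
})

test_that("adding per-plate constants leaves aggregated Z unchanged", {
  spec <- screen_sim_spec(n_plates = 4, wells_per_plate = 60, seed = 2)
  tab <- simulate_screen_table(spec)$table
  r1 <- score_screen(tab)
  t2 <- tab
  offs <- c(P01 = 0.7, P02 = -1.3, P03 = 2.2, P04 = 0.1)
  for (p in names(offs)) {
    i <- t2$plate == p
    t2$mean_marker_intensity[i] <- t2$mean_marker_intensity[i] + offs[[p]] * 10
    for (m in c("peripheral_er_size", "er_profile_size", "er_gaps_per_um"))
      t2[[m]][i] <- t2[[m]][i] + offs[[p]]
  }
  r2 <- score_screen(t2)
  for (zc in c("z_peripheral", "z_profile", "z_gaps"))
    expect_lt(max(abs(r1$samples[[zc]] - r2$samples[[zc]])), 1e-6)
})

test_that("scoring is invariant to row order and drops low-count fields", {
  spec <- screen_sim_spec(n_plates = 3, wells_per_plate = 50, seed = 29)
  tab <- simulate_screen_table(spec)$table
  r1 <- score_screen(tab)
  set.seed(3)
  r2 <- score_screen(tab[sample(nrow(tab)), ])
  expect_equal(r1$samples$z_peripheral, r2$samples$z_peripheral,
               tolerance = 1e-10)
  expect_true(all(r1$fields$cell_count >= screen_params()$min_cell_count))
})
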