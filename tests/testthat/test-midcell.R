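# Mid-section pipeline: focus selection, border detection, segmentation,
# refinement and the three ER metrics.

test_that("best-slice selection follows the SD rule with low-index ties", {
  expect_equal(select_best_slice(matrix(runif(64), 8, 8)), 1L)
  expect_equal(select_best_slice(array(0.5, c(8, 8, 4))), 1L)
  f <- render_mid_field(small_mid_spec(seed = 4))
  expect_equal(select_best_slice(f$channels$bfp), f$focus_slice)
})

test_that("border enhancement is empty on constant images, binary, and
           invariant to global intensity scaling", {
  p <- midcell_params()
  expect_false(any(enhance_cell_borders(matrix(0.3, 64, 64), p)))
  f <- render_mid_field(small_mid_spec(seed = 9,
                                       noise = list(gaussian_sd = 0, poisson_scale = 0)))
  bfp <- f$channels$bfp[, , f$focus_slice]
  b1 <- enhance_cell_borders(bfp, p)
  expect_type(b1, "logical")
  expect_identical(b1, enhance_cell_borders(bfp * 10, p))
  # border mask lies within 2 px of >= 90% of the true outlines
  tc <- f$truth_cells > 0
  outline <- tc & !ermorph:::erode_disc(tc, 1.5)
  near <- ermorph:::dilate_disc(b1, 2)
  expect_gte(mean(near[outline]), 0.9)
})

test_that("segmentation recovers the planted cells", {
  for (seed in c(9, 21)) {
    f <- render_mid_field(field_spec(section = "mid", n_cells = 8, seed = seed))
    p <- midcell_params()
    bfp <- f$channels$bfp[, , f$focus_slice]
    labs <- segment_cells(enhance_cell_borders(bfp, p), bfp, p)
    n <- max(labs)
    expect_lte(abs(n - 8), 1)   # within 10% of the planted count
    ious <- vapply(seq_len(n), function(id) {
      own <- labs == id
      max(vapply(seq_len(8), function(t) {
        tr <- f$truth_cells == t
        sum(own & tr) / sum(own | tr)
      }, numeric(1)))
    }, numeric(1))
    expect_gte(mean(ious > 0.5), 0.8)
  }
})

test_that("the MAD intensity filter removes dark objects and keeps a
           homogeneous population", {
  # six circular cells, five bright and one dark beyond mad_k * MAD
  spec <- field_spec(section = "mid", image_size = c(220, 220), n_cells = 6,
                     cell_radius_range = c(14, 16), seed = 2)
  labels <- generate_cell_geometry(spec)
  border <- labels > 0 & !ermorph:::erode_disc(labels > 0, 2)
  bright <- c(0.80, 0.81, 0.79, 0.80, 0.82, 0.80)
  p <- midcell_params(min_cell_area = 100)
  mk_bfp <- function(vals) {
    bfp <- matrix(0, 220, 220)
    for (i in 1:6) bfp[labels == i] <- vals[i]
    bfp
  }
  labs_all <- segment_cells(border, mk_bfp(bright), p)
  expect_equal(max(labs_all), 6L)
  dark <- bright
  dark[4] <- 0.70   # far below median - mad_k * MAD of the object means
  labs_dark <- segment_cells(border, mk_bfp(dark), p)
  expect_equal(max(labs_dark), 5L)
  # the surviving labels avoid the dark cell's area
  expect_equal(sum(labs_dark[labels == 4] > 0), 0)
})

test_that("refinement fits the true cell ellipse and builds a 5-px band", {
  f <- render_mid_field(small_mid_spec(seed = 12))
  recs <- refine_cells(f$truth_cells, f$channels$sec63, f$channels$rtn1)
  expect_equal(length(recs), 4)
  for (r in recs) {
    truth <- f$cells[f$cells$id == r$label, ]
    expect_lt(abs(r$border_ellipse$axes[1] / truth$a - 1), 0.1)
    expect_lt(abs(r$border_ellipse$axes[2] / truth$b - 1), 0.1)
    # radial width of the band is periphery_width within discretization
    ell <- r$border_ellipse
    qy <- row(r$periphery_band) - ell$center[2]
    qx <- col(r$periphery_band) - ell$center[1]
    rho <- sqrt(pmax(ell$A[1, 1] * qx^2 + 2 * ell$A[1, 2] * qx * qy +
                       ell$A[2, 2] * qy^2, 0))
    rd <- sqrt(qx^2 + qy^2) * (1 / pmax(rho, 1e-9) - 1)
    expect_lte(max(rd[r$periphery_band]), 5)
    expect_lte(min(rd[r$periphery_band]), 1)
  }
})

test_that("cells without ER signal are dropped with a message", {
  labels <- matrix(0L, 64, 64)
  labels[20:40, 20:40] <- 1L
  blank <- matrix(0, 64, 64)
  expect_message(recs <- refine_cells(labels, blank, blank), "dropped")
  expect_length(recs, 0)
})

test_that("ER metrics take their closed-form values on constructed bands", {
  fx <- make_band_fixture()
  m_full <- compute_er_metrics(fx$cell, fx$full)
  expect_equal(m_full$peripheral_er_size, 1.0)
  expect_equal(m_full$er_profile_size, 1.0)
  expect_equal(m_full$er_gaps_per_um, 0)

  m_arcs <- compute_er_metrics(fx$cell, fx$arcs)
  expect_equal(m_arcs$peripheral_er_size, 0.5)
  expect_equal(m_arcs$er_profile_size, 0.25)
  expect_equal(m_arcs$n_gaps, 2)
  expect_equal(m_arcs$er_gaps_per_um, 2 / m_arcs$periphery_um)

  m_empty <- compute_er_metrics(fx$cell, fx$empty)
  expect_equal(m_empty$peripheral_er_size, 0)
  expect_equal(m_empty$er_profile_size, 0)
  expect_equal(m_empty$n_gaps, 1)
})

test_that("metric bounds and monotonicity hold on random ER masks", {
  fx <- make_band_fixture()
  set.seed(7)
  for (i in 1:15) {
    er <- matrix(runif(length(fx$full)) < runif(1, 0.1, 0.9),
                 nrow(fx$full), ncol(fx$full))
    m <- compute_er_metrics(fx$cell, er)
    expect_gte(m$peripheral_er_size, 0); expect_lte(m$peripheral_er_size, 1)
    expect_gte(m$er_profile_size, 0); expect_lte(m$er_profile_size, 1)
    expect_gte(m$er_gaps_per_um, 0)
    if (m$peripheral_er_size == 1) expect_equal(m$er_gaps_per_um, 0)
    # adding ER pixels inside the band never decreases coverage
    er2 <- er
    add <- which(fx$full & !er)
    if (length(add) > 0) er2[sample(add, min(20, length(add)))] <- TRUE
    expect_gte(compute_er_metrics(fx$cell, er2)$peripheral_er_size,
               m$peripheral_er_size)
  }
})

test_that("population filter keeps identical cells, drops outliers and is
           monotone in the SD limit", {
  base <- data.frame(cell = 1:100, cell_area = rnorm(100, 1000, 30),
                     roundness = rnorm(100, 0.95, 0.01),
                     peripheral_er_size = rnorm(100, 0.5, 0.05))
  same <- base; same$cell_area <- 1000; same$roundness <- 0.9
  same$peripheral_er_size <- 0.5
  expect_equal(nrow(filter_population(same)), 100)

  out <- base
  out$cell_area[7] <- mean(base$cell_area) + 5 * sd(base$cell_area)
  kept <- filter_population(out, midcell_params(population_sd_limit = 2.5))
  expect_false(7 %in% kept$cell)

  k1 <- filter_population(out, midcell_params(population_sd_limit = 2.5))
  k2 <- filter_population(out, midcell_params(population_sd_limit = 1.5))
  expect_true(all(k2$cell %in% k1$cell))
})

test_that("the full pipeline is deterministic on fixed images", {
  f <- render_mid_field(small_mid_spec(seed = 31))
  r1 <- analyze_mid_field(f$channels$bfp, f$channels$sec63, f$channels$rtn1)
  r2 <- analyze_mid_field(f$channels$bfp, f$channels$sec63, f$channels$rtn1)
  expect_identical(r1$measurements, r2$measurements)
})
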