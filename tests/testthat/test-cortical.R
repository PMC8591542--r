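# Cortical classifier: background subtraction, ring-kernel segmentation,
# tubule/sheet/cluster classification, per-cell assignment.

test_that("rolling-ball subtraction zeroes constants, keeps spot peaks on a
           smooth gradient, and never goes negative", {
  expect_equal(max(abs(rolling_ball_background(matrix(0.7, 64, 64), 50))), 0)

  H <- 128; W <- 128
  grad <- outer(seq(0, 0.3, length.out = H), seq(0, 0.2, length.out = W), "+")
  img <- grad
  set.seed(1)
  pts <- cbind(sample(20:108, 12), sample(20:108, 12))
  for (i in 1:12)
    img[pts[i, 1] + (-1:1), pts[i, 2] + (-1:1)] <-
      img[pts[i, 1] + (-1:1), pts[i, 2] + (-1:1)] + 0.5
  out <- rolling_ball_background(img, 50)
  peaks <- vapply(1:12, function(i) out[pts[i, 1], pts[i, 2]], numeric(1))
  expect_true(all(abs(peaks - 0.5) < 0.025))

  rnd <- matrix(runif(32 * 32), 32, 32)
  expect_gte(min(rolling_ball_background(rnd, 10)), 0)
})

test_that("bright-field preprocessing keeps shape, zeroes constants and
           highlights cell outlines", {
  cst <- preprocess_brightfield(matrix(0.4, 60, 60))
  expect_equal(dim(cst), c(60, 60))
  expect_equal(max(abs(cst)), 0)

  f <- render_cortical_field(small_cortical_spec(seed = 3))
  v <- preprocess_brightfield(f$channels$bf[, , 1])
  tc <- f$truth_cells > 0
  outline <- tc & !ermorph:::erode_disc(tc, 2)
  expect_gte(mean(v[outline] >= quantile(v, 0.9)), 0.8)
})

test_that("ring kernels are normalized annuli with empty centers", {
  k1 <- ring_kernel(1)
  ctr <- (dim(k1) + 1) / 2
  expect_equal(k1[ctr[1], ctr[2]], 0)
  expect_equal(sum(k1 > 0), 8)           # the 8-neighborhood ring
  expect_equal(sum(k1), 1)
  for (r in c(2, 3.5, 6)) expect_equal(sum(ring_kernel(r)), 1)
  expect_error(ring_kernel(0.5), ">= 1")
  # mean-preserving: convolving a constant reproduces it
  cst <- matrix(0.37, 32, 32)
  conv <- as.matrix(EBImage::filter2(cst, ring_kernel(3)))
  expect_lt(max(abs(conv - 0.37)), 1e-10)
})

test_that("feature segmentation finds ridges, warns on constants, and is
           monotone in the background multiplier", {
  expect_warning(m0 <- feature_segment(matrix(0.5, 40, 40), 2, 0.02, 1),
                 "constant")
  expect_false(any(m0))

  img <- matrix(0.05, 60, 60)
  img[, 30:31] <- 0.8                    # bright 2-px ridge
  m <- feature_segment(img, 2, 0.02, 1)
  expect_gte(mean(m[5:55, 30:31]), 0.9)
  expect_equal(sum(m[, c(1:25, 36:60)]), 0)

  m_hi <- feature_segment(img, 2, 0.02, 1.3)
  expect_true(all(which(m_hi) %in% which(m)))  # raising bg only shrinks
})

test_that("channel segmentation unions its two passes; a tubule-only field
           has little large-pass-exclusive area", {
  blank <- matrix(0, 50, 50)
  cm <- suppressWarnings(segment_channel(blank))   # warns once per pass
  expect_false(any(cm$total_mask))

  f <- render_cortical_field(small_cortical_spec(
    seed = 14, target_tubule_fraction = 0.3, target_sheet_fraction = 0))
  ch <- normalize01(f$channels$sec63[, , 1])
  cm <- segment_channel(ch, classifier_params(), "general")
  expect_identical(cm$total_mask, cm$small_feature_mask | cm$large_feature_mask)
  excl <- sum(cm$large_feature_mask & !cm$small_feature_mask)
  expect_lt(excl / sum(cm$total_mask), 0.1)
})

test_that("classification partitions the general-marker mask exactly and
           respects the cluster rules", {
  mk_masks <- function(m) structure(list(small_feature_mask = m,
                                         large_feature_mask = m,
                                         total_mask = m), class = "channel_masks")
  d <- c(80, 80)
  sheet <- ermorph:::ellipse_interior(d, c(25, 25), diag(2) / 9^2)
  tub <- matrix(FALSE, d[1], d[2]); tub[60, 10:70] <- TRUE
  tub <- ermorph:::dilate_disc(tub, 1.5)
  sec <- mk_masks(sheet | tub)
  rim <- sheet & !ermorph:::erode_disc(sheet, 1.6)

  # rim-only curvature marker: the patch is a sheet
  cls <- classify_cortical(sec, mk_masks(rim | tub), trimming_factor = 3)
  expect_true(all(cls$sheet_mask[ermorph:::erode_disc(sheet, 2)]))
  expect_false(any(cls$cluster_mask))
  # curvature marker fills the patch: tubular cluster, classified tubule
  cls2 <- classify_cortical(sec, mk_masks(sheet | tub), trimming_factor = 3)
  expect_true(all(cls2$tubule_mask[sheet]))
  expect_false(any(cls2$sheet_mask[sheet]))
  expect_true(all(cls2$cluster_mask == (cls2$cluster_mask & cls2$tubule_mask)))
  # empty curvature channel: clusters empty, sheets = provisional sheets
  cls3 <- classify_cortical(sec, mk_masks(matrix(FALSE, d[1], d[2])), 3)
  expect_false(any(cls3$cluster_mask))
  expect_identical(cls3$sheet_mask, cls$sheet_mask)

  for (cl in list(cls, cls2, cls3)) {
    expect_identical(cl$tubule_mask | cl$sheet_mask, sec$total_mask)
    expect_false(any(cl$tubule_mask & cl$sheet_mask))
  }
})

test_that("provisional sheet area never grows with the trimming factor", {
  f <- render_cortical_field(small_cortical_spec(seed = 15))
  ch <- normalize01(f$channels$sec63[, , 1])
  rt <- normalize01(f$channels$rtn1[, , 1])
  sm <- segment_channel(ch, classifier_params(), "general")
  rm_ <- segment_channel(rt, classifier_params(), "curvature")
  areas <- vapply(c(0, 1, 2, 3, 4, 6), function(tf) {
    cl <- classify_cortical(sm, rm_, tf)
    sum(cl$sheet_mask | cl$cluster_mask)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("per-cell assignment partitions areas exactly and recounts match", {
  f <- render_cortical_field(small_cortical_spec(seed = 16))
  res <- analyze_cortical_field(f$channels$sec63[, , 1], f$channels$rtn1[, , 1],
                                cell_labels = f$truth_cells)
  tab <- res$per_cell
  sec_total <- res$masks$sec63$total_mask
  for (i in seq_len(nrow(tab))) {
    inside <- f$truth_cells == tab$cell[i]
    expect_equal(tab$tubule_area[i] + tab$sheet_area[i],
                 sum(sec_total & inside))
    expect_equal(tab$tubule_fraction[i], tab$tubule_area[i] / sum(inside))
  }
  # empty label mask gives an empty table
  none <- assign_to_cells(res$classification,
                          matrix(0L, nrow(sec_total), ncol(sec_total)))
  expect_equal(nrow(none), 0)
})

test_that("population medians behave like medians", {
  one <- data.frame(cell = 1, tubule_fraction = 0.4, sheet_fraction = 0.2,
                    cluster_fraction = 0, cluster_area = 10)
  s1 <- summarize_population(one)
  expect_equal(s1$median_sheet_fraction, 0.2)
  two <- rbind(one, within(one, { sheet_fraction <- 0.4; cell <- 2 }))
  expect_equal(summarize_population(two)$median_sheet_fraction, 0.3)
  dup <- summarize_population(rbind(two, two))
  expect_equal(dup$median_sheet_fraction, 0.3)
  expect_error(summarize_population(one[0, ]), "empty")
})

test_that("per-cell fractions are nearly invariant to intensity scaling", {
  f <- render_cortical_field(small_cortical_spec(seed = 12))
  a1 <- analyze_cortical_field(f$channels$sec63[, , 1], f$channels$rtn1[, , 1],
                               cell_labels = f$truth_cells)
  a2 <- analyze_cortical_field(f$channels$sec63[, , 1] * 4.2,
                               f$channels$rtn1[, , 1] * 4.2,
                               cell_labels = f$truth_cells)
  expect_lt(max(abs(a1$per_cell$sheet_fraction - a2$per_cell$sheet_fraction),
                abs(a1$per_cell$tubule_fraction - a2$per_cell$tubule_fraction)),
            0.01)
})
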