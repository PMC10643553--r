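test_that("exact 1-D 2-means attains the global optimum", {
  r <- two_means_1d(c(0, 0, 0, 10, 10, 10))
  expect_equal(r$labels, c(0, 0, 0, 1, 1, 1))
  expect_equal(r$centroids, c(0, 10))
  expect_equal(r$inertia, 0)

  # {1,2} vs {8}: SSE 0.5 beats {1} vs {2,8}: SSE 18
  r2 <- two_means_1d(c(1, 2, 8))
  expect_equal(r2$labels, c(0, 0, 1))
  expect_equal(r2$inertia, 0.5)

  set.seed(17)
  for (rep in 1:20) {
    v <- c(rnorm(15, 0), rnorm(15, 6))
    r3 <- two_means_1d(v)
    r4 <- two_means_1d(v, method = "lloyd", seed = rep)
    expect_equal(r3$inertia, r4$tot <- r4$inertia, tolerance = 1e-8)
    expect_identical(r3$labels, r4$labels)
  }
  expect_error(two_means_1d(rep(2, 5)), "degenerate")
  expect_error(two_means_1d(3), ">= 2")
})

test_that("cluster selection rules pick the physical cluster", {
  g <- grid_for(9, nc = 3)
  toy <- to_grid_map(c(1, 1, 1, 1, 0.1, 1, 1, 1, 1), g, "absorption_sum")
  m <- roi_from_absorption(toy)
  expect_equal(which(m$selected), 5L)
  expect_identical(m$provenance[[5L]], "absorption")

  uni <- to_grid_map(rep(1, 9), g, "absorption_sum")
  expect_warning(me <- roi_from_absorption(uni), "no RoI")
  expect_false(any(me$selected))

  ring <- matrix(1, 3, 3); ring[2, 2] <- 0
  mg <- to_grid_map(as.vector(t(ring)), g, "com_magnitude")
  ms <- roi_from_scattering(mg)
  expect_equal(sum(ms$selected), 8L)
  expect_false(ms$selected[2, 2])

  expect_error(roi_from_absorption(mg), "channel")
  expect_error(roi_from_scattering(toy), "channel")
})

test_that("union counts overlapping selections once", {
  # in-field accounting: |A| = 1832, |B| = 2998, |A and B| = 1570
  nr <- 85L; nc <- 188L  # 15,980 cells
  sel_a <- matrix(FALSE, nr, nc); sel_b <- matrix(FALSE, nr, nc)
  sel_a[seq_len(1832)] <- TRUE
  sel_b[seq(1832 - 1570 + 1, length.out = 2998)] <- TRUE
  u <- combine_union(roi_mask(sel_a), roi_mask(sel_b))
  expect_equal(sum(u$selected), 3260L)

  a <- roi_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  b <- roi_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  expect_equal(sum(combine_union(a, b)$selected), 2L)
  expect_equal(combine_union(a, a)$selected, a$selected)
  expect_error(combine_union(a, roi_mask(matrix(FALSE, 3, 3))), "grids")
})

test_that("pipeline with one segment equals the whole-pattern recipe", {
  s <- random_stack(16, 12, 12, seed = 55)
  # add contrast so clustering is non-degenerate
  s$patterns[, , 1:4] <- s$patterns[, , 1:4] * 0.2
  g <- grid_for(16, nc = 4)
  got <- run_pipeline(s, g, n_segments = 1L)

  # defaults: ln on the absorption channel, raw filtered magnitudes
  com <- t(sapply(1:16, function(k) center_of_mass(s$patterns[, , k], 0)))
  mag <- com_magnitude(standardize_com(com))
  manual <- combine_union(
    roi_from_absorption(
      log_condition(mean_filter_3x3(to_grid_map(pattern_sum(s), g,
                                                "absorption_sum")))),
    roi_from_scattering(
      mean_filter_3x3(to_grid_map(mag, g, "com_magnitude"))))
  expect_identical(got$selected, manual$selected)
  expect_identical(got$provenance, manual$provenance)
})

test_that("pipeline masks contain every per-segment contribution", {
  rs <- reference_sim()
  mk <- reference_masks()
  # OR-monotonicity: the n=8 mask contains each single segment's mask
  segs <- make_segments(c(64, 64), segment_spec(8))
  sf <- segment_features(rs$sim$stack, segs)
  for (s in c(1, 5)) {
    mag <- com_magnitude(standardize_com(cbind(sf$com_x[s, ],
                                               sf$com_y[s, ])))
    one <- suppressWarnings(ptyroi:::.segment_roi(
      sf$T[s, ], mag, rs$scene$grid, TRUE, FALSE,
      sprintf("absorption:s%d", s - 1), sprintf("scattering:s%d", s - 1)))
    expect_true(all(mk$n8$selected[one$selected]))
  }
})

test_that("pipeline is equivariant under scan-id permutation", {
  s <- random_stack(12, 10, 10, seed = 77)
  s$patterns[, , 1:3] <- s$patterns[, , 1:3] * 0.1
  pos <- expand.grid(x = 0:3, y = 0:2)
  set.seed(78)
  perm <- sample(12)
  g1 <- build_grid(pos)
  g2 <- build_grid(pos[perm, ])
  s2 <- diffraction_stack(s$patterns[, , perm])
  m1 <- run_pipeline(s, g1, 4L)
  m2 <- run_pipeline(s2, g2, 4L)
  expect_identical(m1$selected, m2$selected)
})

test_that("dark patterns get zero magnitude; an all-dark stack finds no RoI", {
  a <- array(runif(8 * 8 * 6), c(8, 8, 6))
  a[, , 4] <- 0
  s <- diffraction_stack(a)
  raw <- t(sapply(1:6, function(k) {
    p <- s$patterns[, , k]
    if (sum(p) == 0) c(NA_real_, NA_real_) else center_of_mass(p, 0)
  }))
  mag <- com_magnitude(standardize_com(raw))
  expect_equal(mag[4], 0)
  expect_true(all(mag[-4] > 0))

  dark <- diffraction_stack(array(0, c(4, 4, 4)))
  g <- grid_for(4, nc = 2)
  w <- testthat::capture_warnings(m <- run_pipeline(dark, g, 1L))
  expect_true(any(grepl("no RoI|skipped", w)))
  expect_false(any(m$selected))
})
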