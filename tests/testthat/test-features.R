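test_that("pattern totals match brute-force summation and are linear", {
  expect_equal(pattern_sum(diffraction_stack(array(1, c(3, 3, 1)))), 9)
  expect_equal(pattern_sum(diffraction_stack(array(0, c(3, 3, 1)))), 0)
  s <- random_stack(3, 16, 16, seed = 11)
  expect_equal(pattern_sum(s),
               apply(s$patterns, 3, brute_sum), tolerance = 1e-12)
  p <- s$patterns[, , 1]; q <- s$patterns[, , 2]
  expect_equal(sum(2 * p + 3 * q), 2 * sum(p) + 3 * sum(q),
               tolerance = 1e-12)
})

test_that("center of mass follows the weighted-mean definition", {
  expect_equal(center_of_mass(matrix(1, 3, 3), index_origin = 1),
               c(O_x = 2, O_y = 2))
  p <- matrix(0, 4, 4); p[1, 3] <- 5  # row 1, col 3 (1-based)
  expect_equal(center_of_mass(p, index_origin = 1), c(O_x = 3, O_y = 1))
  set.seed(3)
  q <- matrix(runif(16), 4, 4)
  expect_equal(unname(center_of_mass(q, 0)), brute_com(q, 0),
               tolerance = 1e-12)
  expect_error(center_of_mass(matrix(0, 3, 3)), "undefined")
  # mirror symmetry about the vertical axis pins O_x to the center column
  sym <- q + q[, 4:1]
  expect_equal(unname(center_of_mass(sym, 0))[1], 1.5, tolerance = 1e-12)
})

test_that("CoM standardization yields zero mean, unit variance, and is
           origin-invariant", {
  cs <- standardize_com(rbind(c(0, 0), c(2, 2)))
  expect_equal(unname(cs$standardized), rbind(c(-1, -1), c(1, 1)))

  same <- standardize_com(matrix(1.5, 4, 2))
  expect_true(all(same$degenerate))
  expect_true(all(same$standardized == 0))

  set.seed(8)
  raw <- matrix(rnorm(100, sd = 3), 50, 2)
  st <- standardize_com(raw)$standardized
  expect_lt(max(abs(colMeans(st))), 1e-9)
  expect_lt(max(abs(colMeans(st^2) - 1)), 1e-9)

  # Eq-2 standardization cancels the indexing-origin offset
  s <- random_stack(6, 8, 8, seed = 21)
  com0 <- t(sapply(1:6, function(k) center_of_mass(s$patterns[, , k], 0)))
  com1 <- t(sapply(1:6, function(k) center_of_mass(s$patterns[, , k], 1)))
  expect_equal(standardize_com(com0)$standardized,
               standardize_com(com1)$standardized, tolerance = 1e-12)

  # undefined rows are excluded from moments and standardized to (0,0)
  raw[3, ] <- NA
  st2 <- standardize_com(raw)
  expect_equal(unname(st2$standardized[3, ]), c(0, 0))
  expect_equal(st2$n_undefined, 1L)
})

test_that("CoM magnitude is the rowwise Euclidean norm", {
  cs <- standardize_com(rbind(c(0, 0), c(2, 2)))
  cs$standardized <- rbind(c(3, 4), c(0, 0))
  expect_equal(com_magnitude(cs), c(5, 0))
  set.seed(2)
  cs$standardized <- matrix(rnorm(20), 10, 2)
  expect_equal(com_magnitude(cs),
               sqrt(cs$standardized[, 1]^2 + cs$standardized[, 2]^2))
})

test_that("gridding places values at scan positions and marks EMPTY", {
  g <- grid_for(4, nc = 2)
  m <- to_grid_map(c(1, 2, 3, 4), g, "absorption_sum")
  expect_equal(m$values, rbind(c(1, 2), c(3, 4)))
  expect_error(to_grid_map(1:3, g, "absorption_sum"), "3 values")

  g3 <- build_grid(rbind(c(0, 0), c(1, 0), c(0, 1)))
  m3 <- to_grid_map(c(5, 6, 7), g3, "com_magnitude")
  expect_equal(sum(is.na(m3$values)), 1L)

  set.seed(4)
  perm <- sample(4)
  gp <- build_grid(expand.grid(x = 0:1, y = 0:1)[perm, ])
  mp <- to_grid_map(c(1, 2, 3, 4)[perm], gp, "absorption_sum")
  expect_equal(mp$values, m$values)
})

test_that("3x3 mean filter averages replicate-padded neighborhoods", {
  g <- grid_for(9, nc = 3)
  const <- to_grid_map(rep(2.5, 9), g, "absorption_sum")
  expect_equal(mean_filter_3x3(const)$values, const$values)

  center9 <- to_grid_map(c(0, 0, 0, 0, 9, 0, 0, 0, 0), g, "absorption_sum")
  expect_equal(mean_filter_3x3(center9)$values[2, 2], 1)

  set.seed(10)
  g7 <- grid_for(49, nc = 7)
  v <- runif(49)
  m <- to_grid_map(v, g7, "absorption_sum")
  f <- mean_filter_3x3(m)
  # oracle: explicit window loop with index clamping
  for (i in c(1, 3, 5, 7)) for (j in c(1, 4, 7)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1)
      acc <- acc + m$values[min(max(i + di, 1), 7), min(max(j + dj, 1), 7)]
    expect_equal(f$values[i, j], acc / 9, tolerance = 1e-12)
  }

  # missing cells are excluded from windows and stay missing
  gm <- build_grid(expand.grid(x = 0:2, y = 0:2)[-5, ])
  mm <- mean_filter_3x3(to_grid_map(rep(1, 8), gm, "absorption_sum"))
  expect_true(is.na(mm$values[2, 2]))
  expect_equal(mm$values[1, 1], 1)
})

test_that("log conditioning uses a data-relative floor", {
  g <- grid_for(2, nc = 2)
  # grid_for(2, nc = 2) is 1x2
  m <- to_grid_map(c(exp(1), exp(2)), g, "absorption_sum")
  expect_equal(log_condition(m)$values, matrix(c(1, 2), 1, 2))
  m2 <- to_grid_map(c(1, exp(2)), g, "absorption_sum")
  expect_equal(log_condition(m2)$values, matrix(c(0, 2), 1, 2))
  m3 <- to_grid_map(c(0, 10), g, "absorption_sum")
  expect_equal(log_condition(m3)$values[1, 1], log(0.01))
  m0 <- to_grid_map(c(0, 0), g, "absorption_sum")
  expect_error(log_condition(m0), "all-zero")
})
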