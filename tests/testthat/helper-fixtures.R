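# Shared fixtures. The reference simulation is expensive enough to build
# once and reuse across test files (same R session).

random_stack <- function(K = 5, N = 8, M = 8, seed = 42) {
  set.seed(seed)
  diffraction_stack(array(runif(N * M * K), c(N, M, K)))
}

# grid for a K-pattern stack laid out row-major on nr x nc cells
grid_for <- function(K, nc = ceiling(sqrt(K)), step = 1) {
  nr <- ceiling(K / nc)
  stopifnot(nr * nc == K)
  pos <- expand.grid(x = (seq_len(nc) - 1) * step,
                     y = (seq_len(nr) - 1) * step)
  build_grid(pos)
}

.fixture_env <- new.env(parent = emptyenv())

reference_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    scene <- make_scene("reference", seed = 0)
    .fixture_env$scene <- scene
    .fixture_env$sim <- simulate_scene(scene, seed = 1)
  }
  list(scene = .fixture_env$scene, sim = .fixture_env$sim)
}

reference_masks <- function() {
  if (is.null(.fixture_env$masks)) {
    rs <- reference_sim()
    .fixture_env$masks <- suppressWarnings(list(
      n1 = run_pipeline(rs$sim$stack, rs$scene$grid, 1L),
      n8 = run_pipeline(rs$sim$stack, rs$scene$grid, 8L),
      n40 = run_pipeline(rs$sim$stack, rs$scene$grid, 40L)))
  }
  .fixture_env$masks
}

# independent brute-force oracles -------------------------------------------

brute_sum <- function(p) {
  s <- 0
  for (j in seq_len(nrow(p))) for (i in seq_len(ncol(p))) s <- s + p[j, i]
  s
}

brute_com <- function(p, origin = 0) {
  tot <- sum(p)
  ox <- 0; oy <- 0
  for (j in seq_len(nrow(p))) for (i in seq_len(ncol(p))) {
    ox <- ox + (i - 1 + origin) * p[j, i]
    oy <- oy + (j - 1 + origin) * p[j, i]
  }
  c(ox, oy) / tot
}

# optimal 2-partition SSE by enumerating every subset (n <= 12 feasible)
brute_two_means <- function(v) {
  n <- length(v)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)))
    a <- v[grp]; b <- v[!grp]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best) best <- sse
  }
  best
}

# flood fill from the boundary over background, 4-connected (queue BFS)
brute_fill <- function(sel) {
  nr <- nrow(sel); nc <- ncol(sel)
  seen <- matrix(FALSE, nr, nc)
  queue <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i == 1 || i == nr || j == 1 || j == nc) && !sel[i, j] &&
        !seen[i, j]) {
      seen[i, j] <- TRUE
      queue[[length(queue) + 1L]] <- c(i, j)
    }
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ni <- cur[1L] + d[1L]; nj <- cur[2L] + d[2L]
      if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
          !sel[ni, nj] && !seen[ni, nj]) {
        seen[ni, nj] <- TRUE
        queue[[length(queue) + 1L]] <- c(ni, nj)
      }
    }
  }
  sel | (!sel & !seen)
}

random_roi <- function(nr, nc, p = 0.3, seed = 1) {
  set.seed(seed)
  roi_mask(matrix(runif(nr * nc) < p, nr, nc))
}
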