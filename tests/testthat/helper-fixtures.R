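# Fixtures and independent oracles shared across the test files.
# Everything is generated in code; no data files.

# A zero-noise mononucleosome parameter set with fully deterministic
# unwrapping (point-mass deltas via sd ~ 0 and clamping).
mono_params_fixed <- function(d_en = 0L, d_ex = 0L, alpha = 39, beta = -9,
                              noise_sd = 0) {
  synthetic_params(
    template = build_template(1),
    alpha = list(weights = 1, means = alpha, sds = 1e-9),
    beta = list(mean = beta, sd = 1e-9),
    delta_entry = list(mean = d_en, sd = 0),
    delta_exit = list(mean = d_ex, sd = 0),
    noise_sd = noise_sd,
    delta_clamp = c(-40L, 10L),
    name = "test_fixed")
}

# Brute-force minimum-RMSD superposition over proper rotations:
# multi-start quasi-Newton on the axis-angle parameterisation. Slow and
# simple; used only as an oracle on tiny instances.
brute_force_rmsd <- function(a, b, n_starts = 12) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rot_from_v <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    R <- rot_from_v(v)
    sqrt(mean(rowSums((a0 %*% t(R) - b0)^2)))
  }
  set.seed(4242)
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# Naive O(n^3) single-linkage agglomeration returning sorted merge heights.
brute_force_single_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- min(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Minimum spanning tree edge weights (Prim), for the single-linkage
# equivalence property.
mst_edge_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  key <- d[1, ]
  out <- numeric(0)
  for (step in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(key[!in_tree])]
    out <- c(out, key[j])
    in_tree[j] <- TRUE
    key <- pmin(key, d[j, ])
  }
  sort(out)
}
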