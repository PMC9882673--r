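# Distribution statistics: mixture fits, KDE, Boltzmann two-state gaps,
# the random-plane sine null, and Pearson correlation.

#' Fit a one- or two-component Gaussian mixture
#'
#' Maximum-likelihood fit via EM (mclust, unequal variances); with
#' `k = "auto"` the component count is selected by BIC. Components are
#' ordered by descending weight. The fitted means are the peak positions
#' and the weights the state populations used downstream as the two-state
#' `p_i`/`p_j`.
#'
#' @param values numeric sample (angles in degrees, treated as linear).
#' @param k `1`, `2`, or `"auto"`.
#' @return list of class `nuca_mixture`: `k`, `weights`, `means`, `sds`,
#'   `bic` (per candidate k), `n`.
#' @export
fit_mixture <- function(values, k = "auto") {
  values <- as.numeric(values[is.finite(values)])
  n <- length(values)
  if (n < 8L) stop("sample-too-small: need at least 8 values")
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (!k %in% 1:2) stop("k must be 1, 2 or 'auto'")
    if (k == 2L && n < 20L)
      stop("sample-too-small: need at least 20 values for k = 2")
  }
  G <- if (identical(k, "auto")) 1:2 else k
  # bind mclustBIC locally: Mclust resolves it in the calling frame
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(values, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  kk <- fit$G
  w <- as.numeric(fit$parameters$pro)
  mu <- as.numeric(fit$parameters$mean)
  sd_ <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd_) == 1L) sd_ <- rep(sd_, kk)
  ord <- order(w, decreasing = TRUE)
  structure(list(k = kk, weights = w[ord], means = mu[ord], sds = sd_[ord],
                 bic = fit$BIC, n = n), class = "nuca_mixture")
}

#' @export
print.nuca_mixture <- function(x, ...) {
  cat(sprintf("<nuca_mixture> k=%d, n=%d\n", x$k, x$n))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, mean %.2f, sd %.2f\n",
                i, x$weights[i], x$means[i], x$sds[i]))
  invisible(x)
}

#' Gaussian kernel density estimate
#'
#' @param values numeric sample (n >= 5).
#' @param bandwidth `"auto"` (Silverman's rule) or a positive number.
#' @param n_grid evaluation grid size.
#' @return list of class `nuca_kde`: `grid`, `density`, `bandwidth`.
#' @export
kde_curve <- function(values, bandwidth = "auto", n_grid = 512L) {
  values <- as.numeric(values[is.finite(values)])
  if (length(values) < 5L) stop("sample-too-small: need at least 5 values")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values)
        else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  d <- stats::density(values, bw = bw, n = n_grid, cut = 4)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "nuca_kde")
}

#' Write a KDE curve to CSV
#'
#' @param kde a `nuca_kde`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kde_csv <- function(kde, path) {
  stopifnot(inherits(kde, "nuca_kde"))
  utils::write.csv(data.frame(grid = kde$grid, density = kde$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' Two-state Boltzmann energy gap
#'
#' Converts two state populations into the energy difference
#' `dU = -ln(p_i / p_j)` in units of kT. The populations are typically the
#' two mixture weights of a bimodal wrapping-angle distribution and need
#' not sum to one.
#'
#' @param p_i,p_j populations, each strictly in (0, 1).
#' @return list: `p_i`, `p_j`, `delta_u_kbt`.
#' @examples
#' boltzmann_gap(0.38, 0.62)$delta_u_kbt  # ~0.49 kT
#' @export
boltzmann_gap <- function(p_i, p_j) {
  if (!is.finite(p_i) || !is.finite(p_j) ||
      p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1)
    stop("populations must lie strictly in (0, 1)")
  list(p_i = p_i, p_j = p_j, delta_u_kbt = -log(p_i / p_j))
}

#' Kolmogorov-Smirnov test against the random-plane sine null
#'
#' Two randomly oriented planes meet at a dihedral angle phi in [0, 90]
#' degrees with density sin(phi) (the area element of the unit hemisphere),
#' i.e. null CDF `F(phi) = 1 - cos(phi)`. The one-sample KS statistic
#' against this null measures how far a measured dihedral distribution is
#' from "no preferred orientation".
#'
#' @param dihedrals_deg sample of dihedral angles in degrees, in [0, 90],
#'   n >= 10.
#' @return list: `statistic` (D), `p_value` (asymptotic), `n`.
#' @export
sin_null_test <- function(dihedrals_deg) {
  x <- as.numeric(dihedrals_deg)
  if (length(x) < 10L) stop("need at least 10 dihedral angles")
  if (any(!is.finite(x)) || any(x < 0 | x > 90))
    stop("dihedral angles must lie in [0, 90] degrees")
  ks <- suppressWarnings(stats::ks.test(x / DEG, function(q) 1 - cos(q),
                                        exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value, n = length(x))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined-correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
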