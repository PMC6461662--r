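# Functional analysis of attenuation histograms.
#
# The chain is: histogram -> smooth density on [-1000, 500] HU -> quantile
# function -> log-quantile-density (LQD) curve. Densities live on a
# constrained manifold (non-negative, unit mass), so linear FPCA is done in
# the LQD domain, where the constraint disappears; modes of variation are
# mapped back through the inverse transform, which guarantees valid
# densities.

default_hu_support <- c(-1000, 500)

#' Uniform HU evaluation grid
#' @param grid_size number of grid points (default 151)
#' @param support HU interval, default \[-1000, 500\]
#' @return numeric vector
#' @export
hu_grid <- function(grid_size = 151L, support = default_hu_support) {
  seq(support[1], support[2], length.out = grid_size)
}

new_density <- function(grid, values) {
  structure(list(grid = grid, values = values), class = "ssn_density")
}

#' Smooth an attenuation histogram into a density curve
#'
#' Gaussian kernel smoother on the bin centers (count-weighted) with
#' boundary reflection at both support endpoints, so no mass leaks outside
#' \[-1000, 500\] HU. The result is floored at `delta`, renormalized to unit
#' trapezoidal mass, and returned on a uniform grid. Deterministic.
#'
#' @param hist an `ssn_histogram`
#' @param bandwidth kernel SD in HU, or `"auto"` for Silverman's rule on the
#'   count-weighted sample
#' @param delta strictly positive density floor (per HU); required
#'   downstream by the log-quantile-density transform
#' @param grid_size evaluation grid size
#' @return an `ssn_density` with unit integral and values >= a positive floor
#' @export
smooth_histogram_to_density <- function(hist, bandwidth = "auto",
                                        delta = 1e-5, grid_size = 151L) {
  if (hist$total_voxels < 1) stop("empty histogram")
  stopifnot(delta > 0, delta < 1 / 1500)
  a <- default_hu_support[1]; b <- default_hu_support[2]
  w <- hist$counts / hist$total_voxels
  if (identical(bandwidth, "auto")) {
    mom <- c(mean = sum(w * hist$bin_centers),
             sd = sqrt(sum(w * (hist$bin_centers - sum(w * hist$bin_centers))^2)))
    iqr <- diff(histogram_quantiles(hist, c(0.25, 0.75)))
    sigma <- min(mom[["sd"]], iqr / 1.349)
    if (sigma <= 0) sigma <- diff(hist$bin_centers[1:2])
    bandwidth <- 0.9 * sigma * hist$total_voxels^(-1 / 5)
  }
  stopifnot(bandwidth > 0)
  x <- hu_grid(grid_size)
  keep <- hist$counts > 0
  c_j <- hist$bin_centers[keep]
  w_j <- w[keep]
  f <- numeric(length(x))
  # kernel plus its reflections about both boundaries
  for (j in seq_along(c_j)) {
    f <- f + w_j[j] * (stats::dnorm(x, c_j[j], bandwidth) +
                         stats::dnorm(x, 2 * a - c_j[j], bandwidth) +
                         stats::dnorm(x, 2 * b - c_j[j], bandwidth))
  }
  f <- f / trapz(x, f)
  f <- pmax(f, delta)
  f <- f / trapz(x, f)
  new_density(x, f)
}

check_density <- function(density, tol = 1e-6) {
  if (!inherits(density, "ssn_density")) stop("not a density curve")
  if (abs(trapz(density$grid, density$values) - 1) > tol)
    stop("density is not normalized to unit mass")
  if (any(density$values < 0)) stop("density has negative values")
  invisible(density)
}

#' Invert a density curve into its quantile function
#'
#' Builds the CDF by trapezoidal integration and inverts it by monotone
#' linear interpolation onto a uniform probability grid. Endpoints are
#' pinned to the HU support bounds.
#'
#' @param density an `ssn_density` (unit mass)
#' @param pgrid_size probability grid size (default 101)
#' @return list(pgrid, values) of class `ssn_quantile`; values are
#'   non-decreasing HU
#' @export
density_to_quantile <- function(density, pgrid_size = 101L) {
  check_density(density)
  cdf <- cumtrapz(density$grid, density$values)
  cdf <- cdf / cdf[length(cdf)]
  p <- seq(0, 1, length.out = pgrid_size)
  # cdf is strictly increasing because the density is floored > 0
  q <- stats::approx(cdf, density$grid, xout = p, ties = "ordered")$y
  q[1] <- density$grid[1]
  q[pgrid_size] <- density$grid[length(density$grid)]
  structure(list(pgrid = p, values = cummax(q)), class = "ssn_quantile")
}

#' Log-quantile-density transform of a density curve
#'
#' Maps a density f to the curve `-log f(Q(p))` on a uniform probability
#' grid, the log of the quantile density q(p) = dQ/dp. The density floor
#' guarantees the log is finite everywhere.
#'
#' @inheritParams density_to_quantile
#' @return list(pgrid, values) of class `ssn_lqd`
#' @export
lqd_transform <- function(density, pgrid_size = 101L) {
  check_density(density)
  if (any(density$values <= 0))
    stop("density must be strictly positive (apply the floor first)")
  qf <- density_to_quantile(density, pgrid_size)
  fQ <- stats::approx(density$grid, density$values, xout = qf$values)$y
  structure(list(pgrid = qf$pgrid, values = -log(fQ)), class = "ssn_lqd")
}

#' Invert a log-quantile-density curve back to a density
#'
#' Integrates the quantile density q(p) = exp(lqd) into a quantile function,
#' rescales its range to the full HU support (width 1500), and maps back to
#' a density on the uniform HU grid. Because q(p) can change by orders of
#' magnitude between neighboring grid points near the support boundary, the
#' sampled curve is first refined with a cubic spline in the (smooth) LQD
#' domain and then integrated with log-linear (exponential-fit) quadrature,
#' which is exact for linear LQD segments. Reconstruction is sharp for
#' densities bounded away from the floor; where a density rides the floor
#' over a long HU stretch, the boundary spike of q(p) is not resolvable
#' from the sampled curve and the round trip is only approximate there.
#'
#' @param lqd an `ssn_lqd` (finite values)
#' @param grid_size HU grid size of the returned density
#' @param refine spline refinement factor for the quadrature grid
#' @return an `ssn_density` with unit integral
#' @export
inverse_lqd <- function(lqd, grid_size = 151L, refine = 20L) {
  if (any(!is.finite(lqd$values))) stop("LQD curve must be finite")
  a <- default_hu_support[1]; b <- default_hu_support[2]
  pf <- seq(0, 1, length.out = (length(lqd$pgrid) - 1) * refine + 1)
  l <- stats::spline(lqd$pgrid, lqd$values, xout = pf, method = "natural")$y
  dl <- diff(l)
  dp <- diff(pf)
  # exact integral of exp(linear) on each interval
  seg <- ifelse(abs(dl) < 1e-12,
                dp * exp(utils::head(l, -1)) * (1 + dl / 2),
                dp * (exp(utils::tail(l, -1)) - exp(utils::head(l, -1))) / dl)
  Q <- c(0, cumsum(seg))
  width <- Q[length(Q)]
  scale <- (b - a) / width
  Q <- a + Q * scale
  f_at_Q <- 1 / (exp(l) * scale)
  x <- hu_grid(grid_size)
  f <- stats::approx(Q, f_at_Q, xout = x, ties = "ordered", rule = 2)$y
  f <- f / trapz(x, f)
  new_density(x, f)
}

#' LQD curves for every nodule of a cohort
#'
#' @param cohort an `ssn_cohort`
#' @param bandwidth,delta,grid_size passed to [smooth_histogram_to_density()]
#' @param pgrid_size probability grid size
#' @return an n x M matrix of LQD values with attribute `pgrid`
#' @export
cohort_lqd <- function(cohort, bandwidth = "auto", delta = 1e-5,
                       grid_size = 151L, pgrid_size = 101L) {
  curves <- lapply(cohort, function(r) {
    d <- smooth_histogram_to_density(r$histogram, bandwidth, delta, grid_size)
    lqd_transform(d, pgrid_size)$values
  })
  X <- do.call(rbind, curves)
  rownames(X) <- vapply(cohort, function(r) r$nodule_id, character(1))
  attr(X, "pgrid") <- seq(0, 1, length.out = pgrid_size)
  X
}

#' Functional PCA of log-quantile-density curves
#'
#' Eigendecomposition of the sample covariance operator of the curves under
#' the trapezoidal inner product on the probability grid. Components are
#' ordered by eigenvalue; each eigenfunction's sign is fixed so that its
#' integral (inner product with the constant upward-shift direction) is
#' positive, with ties broken by a positive value at p = 0.5.
#'
#' @param X n x M matrix of LQD curves (rows = nodules) with attribute
#'   `pgrid`, as returned by [cohort_lqd()], or a plain matrix plus `pgrid`
#' @param var_threshold keep the smallest K with cumulative variance
#'   explained >= this threshold (default 0.85), with a minimum of 2
#' @param K fixed number of components (overrides `var_threshold`)
#' @param pgrid probability grid (defaults to `attr(X, "pgrid")`)
#' @return an `ssn_fpca` model: `pgrid`, `mean_lqd`, `eigenfunctions`
#'   (M x K, orthonormal under the trapezoidal inner product), `eigenvalues`
#'   (all M, non-increasing), `var_explained` (first K fractions), `scores`
#'   (n x K, centered), `K`
#' @export
fit_fpca <- function(X, var_threshold = 0.85, K = NULL, pgrid = NULL) {
  if (is.null(pgrid)) pgrid <- attr(X, "pgrid")
  stopifnot(!is.null(pgrid), ncol(X) == length(pgrid))
  n <- nrow(X)
  if (n < 3) stop("FPCA needs at least 3 curves")
  w <- trapz_weights(pgrid)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (n - 1)
  B <- sqrt(w)
  eig <- eigen(t(S * B) * B, symmetric = TRUE) # B S B with B diagonal
  lambda <- pmax(eig$values, 0)
  phi <- eig$vectors / B # orthonormal under sum(w * phi_i * phi_j)
  ve_all <- lambda / sum(lambda)
  if (is.null(K)) {
    K <- max(2L, which(cumsum(ve_all) >= var_threshold)[1])
  }
  K <- min(K, ncol(phi))
  phi <- phi[, seq_len(K), drop = FALSE]
  # sign convention: positive mean level, then positive midpoint value
  for (k in seq_len(K)) {
    s <- sum(w * phi[, k])
    if (abs(s) < 1e-8) s <- phi[which.min(abs(pgrid - 0.5)), k]
    if (s < 0) phi[, k] <- -phi[, k]
  }
  scores <- Xc %*% (w * phi)
  structure(list(pgrid = pgrid, mean_lqd = mu,
                 eigenfunctions = phi, eigenvalues = lambda,
                 var_explained = ve_all[seq_len(K)], scores = scores,
                 K = K, weights = w),
            class = "ssn_fpca")
}

#' Project an LQD curve onto a fitted FPCA model
#'
#' @param model an `ssn_fpca`
#' @param lqd_values numeric vector (or matrix, rows = curves) on the model's
#'   probability grid
#' @return score vector (or matrix) with K columns
#' @export
project_scores <- function(model, lqd_values) {
  if (is.null(dim(lqd_values))) lqd_values <- matrix(lqd_values, nrow = 1)
  if (ncol(lqd_values) != length(model$pgrid))
    stop("curve grid does not match the model's probability grid")
  Xc <- sweep(lqd_values, 2, model$mean_lqd)
  sc <- Xc %*% (model$weights * model$eigenfunctions)
  if (nrow(sc) == 1) drop(sc) else sc
}

#' Modes of variation of the attenuation density
#'
#' For component k, walks the LQD space along the k-th eigenfunction from
#' the mean curve by the empirical score quantiles and maps each curve back
#' to density space, visualizing how the attenuation distribution deforms
#' along that mode.
#'
#' @param model an `ssn_fpca`
#' @param k component index (<= K)
#' @param quantile_levels score quantile levels (default 10th to 90th
#'   percentile)
#' @param grid_size HU grid of the returned densities
#' @return named list of `ssn_density`, one per level
#' @export
mode_of_variation <- function(model, k,
                              quantile_levels = c(0.1, 0.25, 0.5, 0.75, 0.9),
                              grid_size = 151L) {
  if (k > model$K || k < 1) stop("component index out of range")
  stopifnot(all(quantile_levels > 0), all(quantile_levels < 1))
  s <- stats::quantile(model$scores[, k], quantile_levels, names = FALSE)
  out <- lapply(s, function(si) {
    lqd <- structure(list(pgrid = model$pgrid,
                          values = model$mean_lqd + si * model$eigenfunctions[, k]),
                     class = "ssn_lqd")
    inverse_lqd(lqd, grid_size)
  })
  names(out) <- sprintf("q%g", quantile_levels)
  out
}

#' Join FPC scores onto a feature table
#' @param feature_table data.frame from [assemble_feature_table()]
#' @param model an `ssn_fpca` fitted on the same cohort, in the same order
#' @return the feature table with columns `fpc1`, `fpc2`, ...
#' @export
add_fpc_scores <- function(feature_table, model) {
  if (nrow(feature_table) != nrow(model$scores))
    stop("feature table and FPCA scores have different sizes")
  sc <- model$scores
  colnames(sc) <- paste0("fpc", seq_len(ncol(sc)))
  cbind(feature_table, as.data.frame(sc))
}

#' Export an FPCA model as JSON
#' @param model an `ssn_fpca`
#' @param path output file
#' @export
write_fpca_json <- function(model, path) {
  jsonlite::write_json(
    list(pgrid = model$pgrid, mean_lqd = model$mean_lqd,
         eigenfunctions = model$eigenfunctions,
         eigenvalues = model$eigenvalues,
         var_explained = model$var_explained,
         scores = model$scores, K = model$K),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an FPCA model written by [write_fpca_json()]
#' @param path JSON file
#' @return an `ssn_fpca`
#' @export
read_fpca_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$eigenfunctions <- as.matrix(m$eigenfunctions)
  m$scores <- as.matrix(m$scores)
  m$weights <- trapz_weights(m$pgrid)
  structure(m, class = "ssn_fpca")
}
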