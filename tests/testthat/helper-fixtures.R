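# Shared fixtures and independent oracles, built in code at test time.

# One default-size cohort plus its feature table and FPCA, computed lazily
# once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(generator_config(seed = 42L))
    .fixture_env$ft <- assemble_feature_table(.fixture_env$cohort)
    X <- cohort_lqd(.fixture_env$cohort)
    .fixture_env$fpca <- fit_fpca(X)
    .fixture_env$ft_fpc <- add_fpc_scores(.fixture_env$ft, .fixture_env$fpca)
  }
  list(cohort = .fixture_env$cohort, ft = .fixture_env$ft,
       fpca = .fixture_env$fpca, ft_fpc = .fixture_env$ft_fpc)
}

# Build a histogram object directly from (centers, counts).
make_hist <- function(centers, counts) {
  structure(list(bin_centers = centers, counts = as.integer(counts),
                 total_voxels = as.integer(sum(counts))),
            class = "ssn_histogram")
}

make_density <- function(grid, values) {
  structure(list(grid = grid, values = values), class = "ssn_density")
}

# Floored, renormalized truncated Gaussian on the default HU grid.
trunc_gauss_density <- function(mean, sd, delta = 1e-5, grid_size = 151L) {
  x <- hu_grid(grid_size)
  w <- ssnradiomics:::trapz_weights(x)
  f <- dnorm(x, mean, sd)
  f <- pmax(f / sum(w * f), delta)
  make_density(x, f / sum(w * f))
}

trapz_oracle <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Brute-force AUC: pairwise counting over all positive/negative pairs with
# ties counted 1/2. Independent of the rank-based implementation.
auc_bruteforce <- function(values, labels) {
  y <- as.integer(labels == 1 | labels == "T2")
  pos <- values[y == 1]
  neg <- values[y == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Flat-sample moments oracle: expand histogram counts into a sample of bin
# centers and take population moments.
moments_bruteforce <- function(hist) {
  x <- rep(hist$bin_centers, hist$counts)
  m <- mean(x)
  v <- mean((x - m)^2)
  c(mean = m, sd = sqrt(v), skewness = mean((x - m)^3) / v^1.5,
    kurtosis = mean((x - m)^4) / v^2)
}

# Independent quantile oracle: piecewise-linear CDF over bin edges
# (mass uniform within each bin), inverted with approx(). Assumes no
# internal empty bins so the CDF is strictly increasing.
quantiles_bruteforce <- function(hist, probs) {
  h <- diff(hist$bin_centers[1:2])
  keep <- hist$counts > 0
  centers <- hist$bin_centers[keep]
  edges <- c(centers - h / 2, centers[length(centers)] + h / 2)
  cdf <- c(0, cumsum(hist$counts[keep])) / sum(hist$counts)
  approx(cdf, edges, xout = probs)$y
}
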