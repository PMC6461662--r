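tz <- function(d) trapz_oracle(d$grid, d$values)

test_that("histogram smoothing yields a normalized, floored, deterministic density", {
  cohort <- default_cohort_fixture()$cohort
  for (r in cohort[1:5]) {
    d <- smooth_histogram_to_density(r$histogram)
    expect_equal(tz(d), 1, tolerance = 1e-8)
    expect_true(all(d$values > 0))
    expect_identical(d, smooth_histogram_to_density(r$histogram))
  }
  expect_error(smooth_histogram_to_density(make_hist(c(-500, -400), c(0, 0))),
               "empty")
})

test_that("smoothing limits: tiny bandwidth recovers the histogram envelope, uniform stays flat", {
  x151 <- seq(-1000, 500, 10)
  # a histogram proportional to an already-smooth density
  env <- dnorm(x151, -400, 180)
  h <- make_hist(x151, round(env / max(env) * 1000))
  d <- smooth_histogram_to_density(h, bandwidth = 1)
  envelope <- h$counts / (sum(h$counts) * 10) # per-HU normalization
  l1 <- trapz_oracle(x151, abs(d$values - envelope))
  expect_lt(l1, 0.02)

  hu <- make_hist(x151, rep(100, 151))
  du <- smooth_histogram_to_density(hu, bandwidth = 30)
  interior <- du$grid > -950 & du$grid < 450
  expect_lt(max(abs(du$values[interior] - 1 / 1500)) * 1500, 0.05)
})

test_that("quantile inversion matches closed forms and a fine-grid oracle", {
  x <- hu_grid()
  uni <- make_density(x, rep(1 / 1500, 151))
  q <- density_to_quantile(uni)
  expect_equal(q$values, -1000 + 1500 * q$pgrid, tolerance = 1e-9)

  sym <- trunc_gauss_density(-250, 120)
  expect_equal(density_to_quantile(sym)$values[51], -250, tolerance = 1e-6)

  d <- trunc_gauss_density(-400, 100)
  # fine-grid numeric CDF inversion oracle
  xf <- seq(-1000, 500, 0.25)
  ff <- approx(d$grid, d$values, xf)$y
  cdf <- cumsum(c(0, diff(xf) * (head(ff, -1) + tail(ff, -1)) / 2))
  cdf <- cdf / max(cdf)
  oracle <- approx(cdf, xf, 0.75, ties = "ordered")$y
  expect_equal(density_to_quantile(d)$values[76], oracle, tolerance = 1)

  bad <- make_density(x, rep(1 / 1500, 151) * 2)
  expect_error(density_to_quantile(bad), "not normalized")
})

test_that("the LQD of a uniform density is the constant log support width", {
  x <- hu_grid()
  uni <- make_density(x, rep(1 / 1500, 151))
  l <- lqd_transform(uni)
  expect_equal(l$values, rep(log(1500), 101), tolerance = 1e-9)
})

test_that("LQD transform round-trips and shifts act as pure width rescalings", {
  d <- trunc_gauss_density(-250, 400)
  expect_gt(min(d$values), 1e-5) # in the transform's well-posed regime
  back <- inverse_lqd(lqd_transform(d))
  expect_lt(trapz_oracle(d$grid, abs(d$values - back$values)), 1e-3)

  # adding a constant to the LQD rescales q(p) uniformly; after support
  # renormalization the density is unchanged and mass is still 1
  l <- lqd_transform(d)
  lshift <- l; lshift$values <- l$values + 0.7
  d1 <- inverse_lqd(l); d2 <- inverse_lqd(lshift)
  expect_equal(tz(d2), 1, tolerance = 1e-8)
  expect_lt(max(abs(d1$values - d2$values)), 1e-10)
})

test_that("rank-one curve families yield a single component with the generating eigenfunction", {
  pgrid <- seq(0, 1, length.out = 101)
  w <- ssnradiomics:::trapz_weights(pgrid)
  phi <- sin(2 * pi * pgrid)
  phi <- phi / sqrt(sum(w * phi^2))
  a <- seq(-2, 2, length.out = 15)
  X <- outer(rep(1, 15), 7 + pgrid) + outer(a, phi)
  m <- fit_fpca(X, pgrid = pgrid)
  expect_gte(m$var_explained[1], 1 - 1e-6)
  expect_gte(abs(sum(w * m$eigenfunctions[, 1] * phi)), 0.999)

  expect_error(fit_fpca(X[1:2, ], pgrid = pgrid), "at least 3")
  expect_error(project_scores(m, rep(0, 51)), "grid")
})

test_that("FPCA matches a brute-force covariance eigendecomposition", {
  pgrid <- seq(0, 1, length.out = 21)
  w <- ssnradiomics:::trapz_weights(pgrid)
  X <- withr::with_seed(13, matrix(rnorm(20 * 21), 20, 21) +
                          outer(rep(1, 20), 5 * pgrid))
  m <- fit_fpca(X, pgrid = pgrid, K = 5)

  # independent route: eigenvalues of the weighted Gram matrix of the
  # centered curves (duality between n x n and M x M formulations)
  Xc <- sweep(X, 2, colMeans(X))
  G <- Xc %*% (w * t(Xc)) / (nrow(X) - 1)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(m$eigenvalues[1:19], ev[1:19], tolerance = 1e-8)

  # variance accounting: total integrated variance equals the eigenvalue sum
  total_var <- sum(w * apply(X, 2, var))
  expect_equal(sum(m$eigenvalues), total_var, tolerance = 1e-6)

  # orthonormality under the trapezoidal inner product
  Gram <- t(m$eigenfunctions) %*% (w * m$eigenfunctions)
  expect_lt(max(abs(Gram - diag(5))), 1e-6)

  # centered scores with diagonal covariance equal to the eigenvalues
  expect_lt(max(abs(colMeans(m$scores))), 1e-8)
  C <- cov(m$scores)
  expect_lt(max(abs(C - diag(m$eigenvalues[1:5]))), 1e-6)

  # duplicating every curve rescales eigenvalues by the covariance
  # normalization factor 2(n-1)/(2n-1) and keeps the eigenfunctions
  m2 <- fit_fpca(rbind(X, X), pgrid = pgrid, K = 5)
  n <- nrow(X)
  expect_equal(m2$eigenvalues[1:10],
               m$eigenvalues[1:10] * 2 * (n - 1) / (2 * n - 1),
               tolerance = 1e-8)
  expect_equal(abs(diag(t(m2$eigenfunctions) %*% (w * m$eigenfunctions))),
               rep(1, 5), tolerance = 1e-8)
})

test_that("a known two-eigenfunction model is recovered from finite samples", {
  pgrid <- seq(0, 1, length.out = 101)
  w <- ssnradiomics:::trapz_weights(pgrid)
  # Legendre-type orthonormal pair on [0, 1]
  phi1 <- sqrt(3) * (2 * pgrid - 1)
  phi2 <- sqrt(5) * (6 * pgrid^2 - 6 * pgrid + 1)
  lam <- c(4, 1)
  X <- withr::with_seed(17, {
    s1 <- rnorm(200, 0, sqrt(lam[1])); s2 <- rnorm(200, 0, sqrt(lam[2]))
    outer(rep(1, 200), 7 + 0 * pgrid) + outer(s1, phi1) + outer(s2, phi2)
  })
  m <- fit_fpca(X, pgrid = pgrid, K = 2)
  ve <- m$eigenvalues[1:2] / sum(m$eigenvalues)
  expect_equal(ve[1], 0.8, tolerance = 0.05 / 0.8)
  # principal angle between the fitted and generating 2-dim subspaces
  A <- cbind(phi1, phi2) * sqrt(w)
  B <- m$eigenfunctions * sqrt(w)
  sv <- pmin(svd(t(qr.Q(qr(A))) %*% qr.Q(qr(B)))$d, 1)
  angle <- acos(min(sv)) * 180 / pi
  expect_lt(angle, 5)
})

test_that("score projection is exact on training curves and nested in K", {
  fix <- default_cohort_fixture()
  m <- fix$fpca
  X <- cohort_lqd(fix$cohort)
  expect_equal(project_scores(m, X), unname(m$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(project_scores(m, m$mean_lqd), rep(0, m$K), tolerance = 1e-10,
               ignore_attr = TRUE)
  synth <- m$mean_lqd + 2 * m$eigenfunctions[, 1]
  expect_equal(project_scores(m, synth), c(2, rep(0, m$K - 1)),
               tolerance = 1e-6, ignore_attr = TRUE)

  # reconstruction error never grows with more components
  w <- m$weights
  for (i in c(1, 25, 80)) {
    xc <- X[i, ] - m$mean_lqd
    sc <- project_scores(m, X[i, ])
    err <- sapply(seq_len(m$K), function(kk) {
      recon <- m$eigenfunctions[, seq_len(kk), drop = FALSE] %*% sc[seq_len(kk)]
      sum(w * (xc - recon)^2)
    })
    expect_true(all(diff(err) <= 1e-10))
  }
})

test_that("the first functional component carries the class contrast", {
  ft <- default_cohort_fixture()$ft_fpc
  y <- as.integer(ft$class_label == "T2")
  expect_gt(abs(cor(ft$fpc1, y)), abs(cor(ft$fpc2, y)))
})

test_that("modes of variation are valid densities and widen along mode 1", {
  m <- default_cohort_fixture()$fpca
  mv <- mode_of_variation(m, 1)
  for (d in mv) expect_equal(tz(d), 1, tolerance = 1e-8)
  iqr_of <- function(d) {
    q <- density_to_quantile(d)
    approx(q$pgrid, q$values, 0.75)$y - approx(q$pgrid, q$values, 0.25)$y
  }
  # attenuation heterogeneity (density IQR) increases along the first mode
  expect_gt(iqr_of(mv$q0.9), iqr_of(mv$q0.1))
  expect_error(mode_of_variation(m, m$K + 1), "out of range")

  # a component with (near) zero eigenvalue leaves the density unchanged
  pgrid <- seq(0, 1, length.out = 101)
  X <- outer(rep(1, 10), rep(log(1500), 101)) +
    outer(seq(-0.5, 0.5, length.out = 10), sin(2 * pi * pgrid))
  m0 <- fit_fpca(X, pgrid = pgrid, K = 2)
  mv0 <- mode_of_variation(m0, 2)
  for (d in mv0[-1]) expect_equal(d$values, mv0[[1]]$values, tolerance = 1e-6)
})

test_that("FPCA model JSON export round-trips", {
  m <- default_cohort_fixture()$fpca
  path <- withr::local_tempfile(fileext = ".json")
  write_fpca_json(m, path)
  back <- read_fpca_json(path)
  expect_equal(back$mean_lqd, m$mean_lqd, tolerance = 1e-12)
  expect_equal(back$eigenfunctions, m$eigenfunctions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$scores, m$scores, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$K, m$K)
})
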