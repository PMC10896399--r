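test_that("alpha equals KR-20 on binary items and honors closed forms", {
  set.seed(12)
  items <- matrix(rbinom(500 * 12, 1, 0.4), 500, 12)
  items[1, 1] <- 1 - items[1, 1]  # guard against degenerate columns
  expect_equal(as.numeric(cronbach_alpha(items)), kr20(items),
               tolerance = 1e-12)
  # k identical columns are perfectly consistent
  same <- matrix(rep(rbinom(100, 1, 0.5), 4), ncol = 4)
  expect_equal(as.numeric(cronbach_alpha(same)), 1)
  # parallel items with inter-item correlation r: Spearman-Brown
  r <- 0.3
  n <- 1e4
  f <- rnorm(n)
  par_items <- sqrt(r) * f + sqrt(1 - r) * matrix(rnorm(n * 12), n, 12)
  expect_equal(as.numeric(cronbach_alpha(par_items)),
               12 * r / (1 + 11 * r), tolerance = 0.02)
  # independent columns have near-zero alpha
  ind <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(as.numeric(cronbach_alpha(ind))), 0.05)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
})

test_that("KMO matches partial-correlation brute force", {
  # 2x2 closed case: the only partial correlation equals the correlation,
  # so KMO = r^2 / (r^2 + r^2) = 0.5 whatever r != 0
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(kmo(R2), 0.5)
  # one-factor structure, uniform loading 0.7: residual-regression oracle
  set.seed(3)
  k <- 12
  n <- 2000
  X <- 0.7 * rnorm(n) %o% rep(1, k) +
    sqrt(1 - 0.49) * matrix(rnorm(n * k), n, k)
  R <- cor(X)
  q2 <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ri <- resid(lm(X[, i] ~ X[, -c(i, j)]))
    rj <- resid(lm(X[, j] ~ X[, -c(i, j)]))
    q2 <- q2 + cor(ri, rj)^2
  }
  r2 <- sum(R[upper.tri(R)]^2)
  expect_equal(kmo(R), r2 / (r2 + q2), tolerance = 1e-8)
  expect_error(kmo(diag(5)), "KMO undefined")
})

test_that("Bartlett sphericity follows the log-determinant formula", {
  expect_equal(bartlett_sphericity(diag(12), 413)$statistic, 0)
  expect_equal(bartlett_sphericity(diag(12), 413)$df, 66)
  set.seed(4)
  X <- matrix(rnorm(413 * 12), 413, 12)
  R <- cor(X)
  got <- bartlett_sphericity(R, 413)
  # independent route: determinant via the eigenvalue product
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  want <- -(413 - 1 - (2 * 12 + 5) / 6) * sum(log(lambda))
  expect_equal(got$statistic, want, tolerance = 1e-8)
})

test_that("PCA eigenstructure conserves trace and matches compound symmetry", {
  expect_equal(pca_eigen(diag(12))$eigenvalues, rep(1, 12))
  rho <- 0.4
  R <- matrix(rho, 12, 12); diag(R) <- 1
  e <- pca_eigen(R)
  expect_equal(e$eigenvalues[1], 1 + 11 * rho)
  expect_equal(e$eigenvalues[-1], rep(1 - rho, 11))
  expect_equal(sum(e$eigenvalues), 12)
  expect_equal(kaiser_retain(e$eigenvalues), 1)
  expect_error(pca_eigen(matrix(1:4, 2)), "symmetric")
  # loadings reproduce R for a full-rank decomposition
  set.seed(5)
  S <- cor(matrix(rnorm(600), 50, 12))
  pe <- pca_eigen(S)
  expect_equal(pe$loadings %*% t(pe$loadings), S, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("Kaiser retention counts eigenvalues strictly above one", {
  expect_equal(kaiser_retain(c(3.6, 1.8, 0.9, 0.5)), 2)
  expect_equal(kaiser_retain(rep(1, 12)), 0)
})

test_that("parallel analysis is seeded and separates signal from noise", {
  set.seed(6)
  noise_eig <- pca_eigen(cor(matrix(rnorm(413 * 12), 413, 12)))$eigenvalues
  pa <- parallel_analysis(noise_eig, 413, reps = 300, seed = 10)
  expect_lte(pa$n_retained, 1)
  expect_gt(pa$random_means[1], 1)
  expect_lt(pa$random_means[12], 1)
  pa2 <- parallel_analysis(noise_eig, 413, reps = 300, seed = 10)
  expect_identical(pa$random_means, pa2$random_means)
})

test_that("promax recovers planted oblique structure", {
  X <- make_factor_items(2000, phi_off = 0.5)
  pe <- pca_eigen(cor(X))
  sol <- promax_rotate(pe$loadings[, 1:3], kappa = 4)
  expect_equal(diag(sol$phi), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(abs(sol$phi[upper.tri(sol$phi)] - 0.5) < 0.1))
  # items co-assign with their generating blocks
  rep_ <- structure_report(sol)
  expect_equal(length(unique(rep_$factor[1:4])), 1)
  expect_equal(length(unique(rep_$factor[5:8])), 1)
  expect_equal(length(unique(rep_$factor[9:12])), 1)
  # orthogonal factors give near-zero factor correlations
  X0 <- make_factor_items(2000, phi_off = 0, seed = 7)
  sol0 <- promax_rotate(pca_eigen(cor(X0))$loadings[, 1:3], kappa = 4)
  expect_true(all(abs(sol0$phi[upper.tri(sol0$phi)]) < 0.05))
  # kappa = 1 collapses to the varimax (orthogonal) solution
  sol1 <- promax_rotate(pe$loadings[, 1:3], kappa = 1)
  expect_equal(sol1$phi, diag(3), ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(promax_rotate(pe$loadings[, 1, drop = FALSE]),
               "single factor")
})

test_that("promax agrees with the reference implementation", {
  X <- make_factor_items(1500, phi_off = 0.4, seed = 99)
  pe <- pca_eigen(cor(X))
  sol <- promax_rotate(pe$loadings[, 1:3], kappa = 4)
  ref <- stats::promax(pe$loadings[, 1:3], m = 4)
  expect_equal(abs(unclass(ref$loadings)), abs(sol$pattern),
               ignore_attr = TRUE, tolerance = 1e-4)
  phi_ref <- solve(crossprod(ref$rotmat))
  expect_equal(abs(phi_ref), abs(sol$phi), ignore_attr = TRUE,
               tolerance = 1e-4)
})

test_that("structure_report breaks ties toward the lower factor index", {
  sol <- list(pattern = matrix(c(0.5, 0.5, -0.5, 0.3), 2, 2,
                               dimnames = list(c("i1", "i2"), NULL)))
  class(sol) <- "ndpae_factors"
  rep_ <- structure_report(sol)
  expect_equal(rep_$factor, c(1L, 1L))
  expect_true(rep_$tie[1])
  expect_false(rep_$tie[2])
})

test_that("the full battery runs on a synthetic criterion matrix", {
  coh <- generate_cohort(synth_config(seed = 314))
  fit <- ndpae(coh, synth_registry(), tau = 1, models = "AF2of4")
  ps <- ndpae_psychometrics(fit$matrices[["1"]], reps = 200, seed = 1)
  expect_gt(as.numeric(ps$alpha), 0.5)
  expect_equal(as.numeric(ps$alpha),
               kr20(unclass(fit$matrices[["1"]])[
                 complete.cases(unclass(fit$matrices[["1"]])), ]),
               tolerance = 1e-12)
  expect_gt(ps$kmo, 0.5)
  expect_lt(ps$bartlett$p.value, 1e-10)
  expect_equal(sum(ps$eigenvalues), 12, tolerance = 1e-10)
  expect_gte(ps$kaiser_n, 1)
  expect_output(print(ps), "Cronbach")
})
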