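# Reliability and structure analyses on the 12 binary criterion
# indicators: Cronbach's alpha / KR-20, sampling adequacy (KMO), Bartlett's
# sphericity, principal components with Kaiser retention and Horn's
# parallel analysis, and promax rotation of the varimax solution.

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' computed on complete cases (listwise deletion).
#'
#' @param items Numeric matrix or data frame, subjects x k items (k >= 2).
#' @return Alpha (scalar), with attributes `n` (complete cases used) and
#'   `k`.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  stopifnot(ncol(items) >= 2L)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) < 2L) stop("need at least 2 complete cases")
  k <- ncol(items)
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total score has zero variance")
  a <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
  structure(a, n = nrow(items), k = k)
}

#' Kuder-Richardson formula 20
#'
#' Reliability of dichotomous items: `k/(k-1) * (1 - sum(p*q) / var_T)`
#' with `p` the item endorsement proportions, `q = 1 - p`, and `var_T` the
#' population variance of the total score. Algebraically identical to
#' [cronbach_alpha()] on 0/1 items.
#'
#' @param items Binary (0/1) matrix, subjects x k.
#' @return KR-20 (scalar).
#' @export
kr20 <- function(items) {
  items <- as.matrix(items)
  stopifnot(ncol(items) >= 2L, all(items %in% c(0, 1, NA)))
  items <- items[stats::complete.cases(items), , drop = FALSE]
  n <- nrow(items)
  if (n < 2L) stop("need at least 2 complete cases")
  k <- ncol(items)
  p <- colMeans(items)
  tot <- rowSums(items)
  vt <- mean((tot - mean(tot))^2)  # population variance
  if (vt == 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(p * (1 - p)) / vt)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over the off-diagonal, where
#' `r` are the observed correlations and `q` the anti-image partial
#' correlations obtained from the inverse of `R`.
#'
#' @param R Correlation matrix (symmetric, unit diagonal, invertible).
#' @return KMO in \[0, 1\].
#' @export
kmo <- function(R) {
  stopifnot(is.matrix(R), isSymmetric(unname(R)),
            all(abs(diag(R) - 1) < 1e-8))
  S <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular: KMO undefined"))
  d <- 1 / sqrt(diag(S))
  Q <- -S * tcrossprod(d)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  if (r2 + q2 == 0)
    stop("no shared variance among items: KMO undefined (0/0)")
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi^2 = -(n - 1 - (2k + 5)/6) * log(det(R))` on `k(k-1)/2` degrees of
#' freedom.
#'
#' @param R Correlation matrix.
#' @param n Sample size the matrix was computed from (`n > k`).
#' @return A list: `statistic`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(R, n) {
  k <- ncol(R)
  stopifnot(isSymmetric(unname(R)), n > k)
  dt <- det(R)
  if (dt <= 0) stop("non-positive determinant: test undefined")
  stat <- -(n - 1 - (2 * k + 5) / 6) * log(dt)
  df <- k * (k - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Principal components of a correlation matrix
#'
#' Eigendecomposition of `R`; unrotated component loadings are the
#' eigenvectors scaled by the square roots of their eigenvalues, so that
#' the eigenvalues sum to the number of items (the trace).
#'
#' @param R Symmetric positive semi-definite correlation matrix.
#' @return A list: `eigenvalues` (descending), `vectors`, `loadings`.
#' @export
pca_eigen <- function(R) {
  if (!is.matrix(R) || !isSymmetric(unname(R)))
    stop("R must be a symmetric matrix")
  e <- eigen(R, symmetric = TRUE)
  loadings <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncol(R))
  rownames(loadings) <- rownames(e$vectors) <- colnames(R)
  list(eigenvalues = e$values, vectors = e$vectors, loadings = loadings)
}

#' Kaiser eigenvalue-greater-than-one retention
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @return Number of components with eigenvalue strictly greater than 1
#'   (ties at exactly 1 are not retained).
#' @export
kaiser_retain <- function(eigenvalues) sum(eigenvalues > 1)

#' Horn's parallel analysis
#'
#' Compares observed eigenvalues with the mean eigenvalues of `reps`
#' random standard-normal datasets of the same dimensions; components are
#' retained while the observed eigenvalue exceeds the corresponding random
#' mean (stopping at the first failure).
#'
#' @param eigenvalues Observed eigenvalues (descending).
#' @param n Sample size of the observed data.
#' @param reps Number of random datasets (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `n_retained`, `random_means` (mean random eigenvalues),
#'   `reps`.
#' @export
parallel_analysis <- function(eigenvalues, n, reps = 1000L, seed = NULL) {
  k <- length(eigenvalues)
  stopifnot(reps >= 100L, n > k)
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(k)
  for (r in seq_len(reps)) {
    X <- matrix(stats::rnorm(n * k), n, k)
    acc <- acc + eigen(stats::cor(X), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  means <- acc / reps
  list(n_retained = sum(cumprod(eigenvalues > means)),
       random_means = means, reps = reps)
}

#' Promax rotation of a component/factor solution
#'
#' Varimax rotation (Kaiser row-normalized, tolerance 1e-6) followed by the
#' promax oblique step: each varimax loading is raised to the power `kappa`
#' (sign preserved) to form a simple-structure target, the target is fit by
#' oblique procrustes, and the transform is column-normalized so the factor
#' correlation matrix `Phi` has unit diagonal.
#'
#' @param loadings Unrotated k x m loading matrix, m >= 2.
#' @param kappa Promax power (default 4).
#' @param eigenvalues Optional eigenvalues to carry into the result.
#' @return A list of class `ndpae_factors`: `pattern` (k x m), `structure`
#'   (`pattern %*% phi`), `phi` (m x m factor correlations),
#'   `variance_explained` (percent per factor, from oblique SS loadings),
#'   `eigenvalues`, `n_retained`, `kappa`.
#' @export
promax_rotate <- function(loadings, kappa = 4, eigenvalues = NULL) {
  loadings <- as.matrix(loadings)
  m <- ncol(loadings)
  if (m < 2L) stop("rotation undefined for a single factor")
  vm <- stats::varimax(loadings, normalize = TRUE, eps = 1e-6)
  X <- unclass(vm$loadings)
  Q <- X * abs(X)^(kappa - 1)
  U <- solve(crossprod(X), crossprod(X, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), m)
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  pattern <- X %*% U
  # factor signs are arbitrary; orient each so its dominant loadings are
  # positive, and carry the reflection into phi
  flip <- ifelse(colSums(pattern^3) < 0, -1, 1)
  pattern <- sweep(pattern, 2, flip, `*`)
  phi <- phi * tcrossprod(flip)
  struct <- pattern %*% phi
  ss <- colSums(pattern * struct)
  dimnames(pattern) <- dimnames(struct) <-
    list(rownames(loadings), paste0("F", seq_len(m)))
  dimnames(phi) <- list(colnames(pattern), colnames(pattern))
  structure(list(pattern = pattern, structure = struct, phi = phi,
                 variance_explained = 100 * ss / nrow(loadings),
                 eigenvalues = eigenvalues, n_retained = m, kappa = kappa,
                 varimax = X),
            class = "ndpae_factors")
}

#' Assign items to factors by dominant pattern loading
#'
#' Each item is assigned to the factor on which its pattern loading has the
#' largest absolute value; exact ties go to the lower factor index and are
#' reported in the `tie` column.
#'
#' @param solution An `ndpae_factors` object.
#' @param labels Optional item labels (default pattern rownames).
#' @return A data frame: `item`, `factor`, `loading`, `tie`.
#' @export
structure_report <- function(solution, labels = NULL) {
  P <- solution$pattern
  if (is.null(labels)) labels <- rownames(P)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(P)))
  absP <- abs(P)
  fac <- apply(absP, 1, which.max)  # which.max takes the first on ties
  tie <- apply(absP, 1, function(r) sum(r == max(r)) > 1L)
  data.frame(item = labels, factor = as.integer(fac),
             loading = P[cbind(seq_len(nrow(P)), fac)], tie = tie,
             stringsAsFactors = FALSE)
}

#' Full psychometric battery on a criterion matrix
#'
#' Restricts a ternary criterion matrix to complete cases and runs the
#' reliability and structure battery: Cronbach's alpha, KMO, Bartlett's
#' sphericity, principal components on the Pearson correlation matrix of
#' the 0/1 indicators, Kaiser retention confirmed by parallel analysis,
#' and promax rotation of the retained components.
#'
#' @param cmat An `ndpae_cmat` (or plain 0/1 matrix with NAs).
#' @param n_factors Number of components to rotate; default the Kaiser
#'   count.
#' @param kappa Promax power.
#' @param reps Parallel-analysis replicates.
#' @param seed Seed for the parallel-analysis simulation.
#' @return A list of class `ndpae_psych`: `alpha`, `kmo`, `bartlett`,
#'   `eigenvalues`, `kaiser_n`, `parallel`, `factors` (an `ndpae_factors`,
#'   or NULL if fewer than 2 components retained), `assignment`,
#'   `n_complete`.
#' @export
ndpae_psychometrics <- function(cmat, n_factors = NULL, kappa = 4,
                                reps = 1000L, seed = NULL) {
  items <- unclass(cmat)[, , drop = FALSE]
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) <= ncol(items))
    stop("not enough complete cases (", nrow(items), ") for ",
         ncol(items), " items")
  keep <- apply(items, 2, stats::var) > 0
  if (!all(keep))
    warning("dropping zero-variance item(s): ",
            paste(colnames(items)[!keep], collapse = ", "))
  items <- items[, keep, drop = FALSE]
  alpha <- cronbach_alpha(items)
  R <- stats::cor(items)
  km <- kmo(R)
  bart <- bartlett_sphericity(R, nrow(items))
  pe <- pca_eigen(R)
  kaiser_n <- kaiser_retain(pe$eigenvalues)
  pa <- parallel_analysis(pe$eigenvalues, nrow(items), reps = reps,
                          seed = seed)
  k_use <- if (is.null(n_factors)) kaiser_n else n_factors
  factors <- NULL
  assignment <- NULL
  if (k_use >= 2L) {
    factors <- promax_rotate(pe$loadings[, seq_len(k_use), drop = FALSE],
                             kappa = kappa, eigenvalues = pe$eigenvalues)
    assignment <- structure_report(factors)
  }
  structure(list(alpha = alpha, kmo = km, bartlett = bart,
                 eigenvalues = pe$eigenvalues, kaiser_n = kaiser_n,
                 parallel = pa, factors = factors,
                 assignment = assignment, n_complete = nrow(items)),
            class = "ndpae_psych")
}

#' @export
print.ndpae_psych <- function(x, ...) {
  cat("Binary-item psychometrics (complete cases n =", x$n_complete, ")\n")
  cat(sprintf("  Cronbach's alpha : %.3f\n", as.numeric(x$alpha)))
  cat(sprintf("  KMO              : %.3f\n", x$kmo))
  cat(sprintf("  Bartlett         : chi2(%d) = %.3f, p = %.3g\n",
              x$bartlett$df, x$bartlett$statistic, x$bartlett$p.value))
  cat(sprintf("  Kaiser retention : %d component(s); parallel analysis: %d\n",
              x$kaiser_n, x$parallel$n_retained))
  if (!is.null(x$factors)) {
    cat("  Factor correlations (promax, kappa =", x$factors$kappa, "):\n")
    print(round(x$factors$phi, 3))
  }
  invisible(x)
}
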