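test_that("standardization rescales and orients every supported scale", {
  expect_equal(standardize_score(70, "standard_100_15", "higher_better"), -2)
  expect_equal(standardize_score(50, "t_50_10", "higher_worse"), 0)
  expect_equal(standardize_score(70, "t_50_10", "higher_worse"), -2)
  expect_equal(standardize_score(4, "scaled_10_3", "higher_better"), -2)
  expect_equal(standardize_score(-1.3, "z", "higher_worse"), 1.3)
  # involution: re-orienting twice returns the original value
  z <- rnorm(20)
  expect_equal(-standardize_score(-z, "z", "higher_worse"),
               standardize_score(z, "z", "higher_worse"))
  expect_equal(standardize_score(c(1, 0, NA), "binary", "binary_impaired"),
               c(1, 0, NA))
  expect_error(standardize_score(2, "binary", "binary_impaired"),
               "not in \\{0, 1\\}")
})

test_that("impairment coding uses an inclusive threshold", {
  expect_equal(code_impairment(-2.0, 2.0), 1L)
  expect_equal(code_impairment(-0.99, 1.0), 0L)
  expect_equal(code_impairment(-1.0, 1.0), 1L)
  # binary flags ignore tau entirely
  expect_equal(code_impairment(1, 2.0, binary = TRUE), 1L)
  expect_equal(code_impairment(0, 0.5, binary = TRUE), 0L)
})

test_that("criterion coding follows the any-measure rule with U fallback", {
  expect_equal(code_criterion(code_impairment(c(-0.5, -1.2), 1.0)), 1L)
  expect_equal(code_criterion(c(0L, NA)), 0L)
  expect_equal(code_criterion(c(NA_integer_, NA_integer_)), NA_integer_)
})

test_that("criterion_matrix codes a minimal cohort correctly", {
  df <- data.frame(subject_id = "a", group = "AE", age = 9, sex = "male",
                   wisc_fsiq = 70, stringsAsFactors = FALSE)
  m <- criterion_matrix(df, ndpae_registry(), tau = 2)
  expect_equal(unname(m["a", "global_intellectual"]), 1L)
  expect_true(all(is.na(m["a", setdiff(colnames(m),
                                       "global_intellectual")])))
  # z = -2 is also below the milder 1.0 SD cutoff
  m1 <- criterion_matrix(df, ndpae_registry(), tau = 1)
  expect_equal(unname(m1["a", "global_intellectual"]), 1L)
  df$wisc_fsiq <- 90  # z = -0.67: impaired at no threshold
  m2 <- criterion_matrix(df, ndpae_registry(), tau = 1)
  expect_equal(unname(m2["a", "global_intellectual"]), 0L)
  expect_error(criterion_matrix(cbind(df, rogue = 1), ndpae_registry(),
                                tau = 1), "rogue")
  empty <- df[0, ]
  expect_equal(nrow(criterion_matrix(empty, ndpae_registry(), tau = 1)), 0L)
})

test_that("criterion impairment is monotone non-increasing in tau", {
  coh <- generate_cohort(synth_config(n_ae = 150, n_con = 150, seed = 11))
  m10 <- criterion_matrix(coh, synth_registry(), tau = 1)
  m15 <- criterion_matrix(coh, synth_registry(), tau = 1.5)
  m20 <- criterion_matrix(coh, synth_registry(), tau = 2)
  for (crit in colnames(m10)) {
    s10 <- which(m10[, crit] == 1L)
    s15 <- which(m15[, crit] == 1L)
    s20 <- which(m20[, crit] == 1L)
    expect_true(all(s20 %in% s15))
    expect_true(all(s15 %in% s10))
  }
})

test_that("criterion_matrix agrees with per-cell brute force", {
  coh <- generate_cohort(synth_config(n_ae = 25, n_con = 25, seed = 5))
  reg <- synth_registry()
  tau <- 1.5
  m <- criterion_matrix(coh, reg, tau = tau)
  for (i in seq_len(nrow(coh))) {
    for (crit in ndpae_criteria()$criterion) {
      specs <- reg[reg$criterion == crit, ]
      codes <- integer(0)
      for (j in seq_len(nrow(specs))) {
        raw <- coh[[specs$measure_id[j]]][i]
        if (is.na(raw)) next
        z <- standardize_score(raw, specs$scale[j], specs$orientation[j])
        codes <- c(codes, as.integer(z <= -tau))
      }
      expected <- if (!length(codes)) NA_integer_
                  else as.integer(any(codes == 1L))
      expect_identical(unname(m[i, crit]), expected)
    }
  }
})

test_that("whole-domain-unobserved subjects are excluded with a reason", {
  m <- matrix(0L, 3, 12)
  m[2, 6:8] <- NA_integer_   # all three SR criteria unobserved
  m[3, ] <- NA_integer_
  m[3, c(1, 6, 9)] <- 0L     # exactly one observed criterion per domain
  cm <- as_cmat(m, group = c("AE", "AE", "CON"))
  res <- apply_exclusions(cm)
  expect_equal(res$log$subject_id, "S002")
  expect_equal(res$log$domain, "SR")
  expect_equal(rownames(res$matrix), c("S001", "S003"))
  expect_equal(as.character(attr(res$matrix, "group")), c("AE", "CON"))
  # a matrix with no unobserved cells passes through unchanged
  full <- as_cmat(matrix(rbinom(36, 1, 0.5), 3, 12))
  res2 <- apply_exclusions(full)
  expect_equal(nrow(res2$log), 0L)
  expect_equal(unclass(res2$matrix), unclass(full), ignore_attr = TRUE)
})
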