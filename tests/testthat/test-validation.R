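test_that("endorsement percentages use evaluable denominators", {
  df <- tiny_cohort()
  # subject a (AE): impaired everywhere; b (AE) and c (CON): nowhere
  reg <- synth_registry()
  for (j in seq_len(nrow(reg))) {
    df[1, reg$measure_id[j]] <- switch(reg$scale[j],
      standard_100_15 = if (reg$orientation[j] == "higher_better") 55 else 145,
      t_50_10 = if (reg$orientation[j] == "higher_better") 20 else 80,
      scaled_10_3 = 1)
  }
  fit <- ndpae(df, reg, tau = 1, models = c("AF2of4", "AF1"))
  er <- endorsement_rates(fit)
  expect_true(all(er$criteria$AE == 50))    # 1 of 2 AE impaired
  expect_true(all(er$criteria$CON == 0))
  expect_true(all(er$diagnosis$AE == 50))
  expect_true(all(er$diagnosis$CON == 0))
  # unobserved criterion drops out of the denominator
  df2 <- df
  df2$sim_motor <- NA_real_
  df2$sim_motor[1] <- 50   # standard scale, z = -10/3: impaired
  fit2 <- ndpae(df2, reg, tau = 1, models = "AF2of4")
  er2 <- endorsement_rates(fit2)
  motor <- er2$criteria[er2$criteria$criterion == "motor", ]
  expect_equal(motor$n_AE, 1L)
  expect_equal(motor$AE, 100)
})

test_that("count reconstruction rounds half away from zero", {
  tab <- counts_from_rates(69.2, 486, 22.6, 679)
  expect_equal(unname(tab[1, ]), c(336L, 150L))
  expect_equal(unname(tab[2, ]), c(153L, 526L))
  expect_equal(unname(counts_from_rates(0, 10, 100, 10)[, 1]), c(0L, 10L))
  expect_equal(unname(counts_from_rates(50, 3, 50, 5)[1, 1]), 2L)
})

test_that("chi-square matches the expected-counts oracle and chisq.test", {
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 1L, 2, 2)
    got <- chi_square_2x2(tab)
    expect_equal(got$statistic, oracle_chisq(tab), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-12)
    # invariance under row and column permutation
    expect_equal(chi_square_2x2(tab[2:1, ])$statistic, got$statistic)
    expect_equal(chi_square_2x2(tab[, 2:1])$statistic, got$statistic)
  }
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("confusion metrics equal brute-force counting", {
  set.seed(15)
  coh <- generate_cohort(synth_config(n_ae = 30, n_con = 20, seed = 15))
  fit <- ndpae(coh, synth_registry(), models = "AF2of4")
  cm <- confusion_metrics(fit$grid, tau = 1, model = "AF2of4")
  sl <- fit$grid[fit$grid$tau == 1 & fit$grid$model == "AF2of4", ]
  tp <- fn <- tn <- fp <- 0
  for (i in seq_len(nrow(sl))) {
    if (sl$group[i] == "AE") {
      if (sl$ndpae[i]) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (sl$ndpae[i]) fp <- fp + 1 else tn <- tn + 1
    }
  }
  expect_equal(cm$sensitivity, 100 * tp / (tp + fn))
  expect_equal(cm$specificity, 100 * tn / (tn + fp))
  expect_equal(cm$accuracy, 100 * (tp + tn) / nrow(sl))
  # accuracy is exactly the prevalence-weighted combination
  expect_equal(cm$accuracy,
               (cm$sensitivity * cm$n_ae + cm$specificity * cm$n_con) /
                 (cm$n_ae + cm$n_con))
  # a grid that reproduces the labels is perfect
  perfect <- sl
  perfect$ndpae <- perfect$group == "AE"
  pm <- confusion_metrics(perfect, tau = 1, model = "AF2of4")
  expect_equal(c(pm$sensitivity, pm$specificity, pm$accuracy),
               c(100, 100, 100))
})

test_that("AUC equals the pairwise oracle, with ties and symmetry", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    scores <- sample(0:5, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- roc_auc(scores, labels)
    expect_equal(got$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    # flipping labels maps AUC to 1 - AUC
    expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - got$auc,
                 tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(2, 2, 1, 1), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with an external ROC implementation", {
  set.seed(99)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  got <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("logistic fit recovers known coefficients and flags separation", {
  # closed-form intercept at prevalence 1/4
  d0 <- data.frame(y = rep(c(1, 0), c(25, 75)))
  f0 <- logistic_fit(y ~ 1, d0)
  expect_equal(unname(f0$coefficients), log(1 / 3), tolerance = 1e-8)
  # planted age coefficient within its own 95% CI at n = 5000
  set.seed(31)
  n <- 5000
  age <- runif(n, 5, 17)
  sex <- rbinom(n, 1, 0.45)
  eta <- -1 + 0.08 * age - 0.2 * sex
  d <- data.frame(y = rbinom(n, 1, plogis(eta)), age = age, sex = sex)
  f <- logistic_fit(y ~ age + sex, d)
  ci_age <- log(f$ci["age", ])
  expect_gt(0.08, ci_age[["lower"]])
  expect_lt(0.08, ci_age[["upper"]])
  # sex factor coding: female = 1
  d$sex <- ifelse(d$sex == 1, "female", "male")
  f2 <- logistic_fit(y ~ age + sex, d)
  expect_equal(unname(f2$coefficients["sex"]),
               unname(f$coefficients["sex"]))
  # degenerate outcomes
  expect_error(logistic_fit(y ~ 1, data.frame(y = rep(1, 50))),
               "single class")
  sep <- data.frame(y = rep(c(0, 1), each = 50), x = rep(c(0, 1), each = 50))
  expect_error(logistic_fit(y ~ x, sep), "separation|converge")
})
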