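test_that("domain rules honor the published any-of and 2-of-4 logic", {
  expect_true(score_ni(c(0, 1, 0, 0, 0)))
  expect_false(score_ni(c(0, 0, 0, 0, 0)))
  expect_true(score_ni(c(NA, NA, NA, NA, 1)))
  expect_true(score_sr(c(1, 0, 0)))
  expect_false(score_sr(c(NA, 0, NA)))
  expect_true(score_af_2of4(1, 0, 1, 0))
  expect_false(score_af_2of4(1, 1, 0, 0))   # second clause unmet
  expect_false(score_af_2of4(0, 0, 1, 1))   # first clause unmet
  expect_true(score_af_1(0, 0, 1))
  expect_false(score_af_1(0, 0, 0))         # motor never counts under AF1
  expect_true(classify_ndpae(TRUE, TRUE, TRUE))
  expect_false(classify_ndpae(TRUE, TRUE, FALSE))
})

test_that("unobserved criteria never endorse a clause", {
  # U in motor: the second AF 2/4 clause depends on daily living alone
  expect_true(score_af_2of4(1, 0, 1, NA))
  expect_false(score_af_2of4(1, 0, 0, NA))
  expect_false(score_af_2of4(NA, NA, 1, 1))
})

test_that("engine matches the exhaustive truth-table oracle with U mixed in", {
  # all 2^12 binary patterns are covered by the acceptance suite; here,
  # random ternary patterns exercise the unobserved-value handling
  set.seed(404)
  crits <- ndpae_criteria()$criterion
  for (rep in 1:200) {
    x <- sample(c(0L, 1L, NA_integer_), 12, replace = TRUE)
    names(x) <- crits
    cm <- as_cmat(matrix(x, 1, 12))
    grid <- diagnosis_grid(list("1" = cm), models = c("AF2of4", "AF1"))
    for (model in c("AF2of4", "AF1")) {
      want <- oracle_diagnosis(as.list(x), model)
      got <- grid[grid$model == model, ]
      expect_equal(c(ni = got$ni, sr = got$sr, af = got$af,
                     ndpae = got$ndpae), want)
    }
  }
})

test_that("AF1 endorsement contains AF2of4 endorsement", {
  coh <- generate_cohort(synth_config(n_ae = 200, n_con = 200, seed = 9))
  fit <- ndpae(coh, synth_registry(), models = c("AF2of4", "AF1"))
  for (t in fit$tau) {
    sl <- fit$grid[fit$grid$tau == t, ]
    af24 <- sl$af[sl$model == "AF2of4"]
    af1 <- sl$af[sl$model == "AF1"]
    expect_true(all(af1[af24]))
    expect_true(all(sl$ndpae[sl$model == "AF1"][
      sl$ndpae[sl$model == "AF2of4"]]))
  }
})

test_that("diagnosis rate is bounded by every domain rate and monotone in tau", {
  coh <- generate_cohort(synth_config(n_ae = 250, n_con = 250, seed = 21))
  fit <- ndpae(coh, synth_registry(), models = c("AF2of4", "AF1"))
  for (m in c("AF2of4", "AF1")) {
    rates <- sapply(fit$tau, function(t) {
      sl <- fit$grid[fit$grid$tau == t & fit$grid$model == m, ]
      c(nd = mean(sl$ndpae), ni = mean(sl$ni), sr = mean(sl$sr),
        af = mean(sl$af))
    })
    expect_true(all(rates["nd", ] <= apply(rates[c("ni", "sr", "af"), ],
                                           2, min)))
    expect_true(all(diff(rates["nd", order(fit$tau)]) <= 0))
  }
})

test_that("hybrid grid differs from AF2of4@1.0 only through the IQ cell", {
  coh <- generate_cohort(synth_config(n_ae = 300, n_con = 300, seed = 33))
  fit <- ndpae(coh, synth_registry())
  g24 <- fit$grid[fit$grid$model == "AF2of4" & fit$grid$tau == 1, ]
  ghy <- fit$grid[fit$grid$model == "hybridIQ", ]
  iqz <- standardize_score(coh$sim_iq, "standard_100_15", "higher_better")
  iqz <- iqz[match(g24$subject_id, coh$subject_id)]
  same_iq_cell <- is.na(iqz) | iqz <= -2 | iqz > -1
  expect_true(all(g24$ndpae[same_iq_cell] == ghy$ndpae[same_iq_cell]))
  # where they disagree, the IQ z must lie in (-2, -1]
  diff_rows <- which(g24$ndpae != ghy$ndpae)
  expect_true(all(iqz[diff_rows] > -2 & iqz[diff_rows] <= -1))
  # hybrid can only lose diagnoses relative to AF2of4 at 1.0 SD
  expect_true(all(ghy$ndpae[diff_rows] == FALSE))
})
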