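# Quantile matching, blood-to-iron conversion, and pooling.

test_that("lognormal_from_range solves the two percentile equations", {
  p <- lognormal_from_range(2, 50, 0.025, 0.975)
  expect_equal(p$mu, 2.3026, tolerance = 1e-4)
  expect_equal(p$sigma, 0.8212, tolerance = 1e-4)
  # both percentile equations must hold
  expect_equal(pnorm((log(2) - p$mu) / p$sigma), 0.025, tolerance = 1e-6)
  expect_equal(pnorm((log(50) - p$mu) / p$sigma), 0.975, tolerance = 1e-6)
  # symmetric ranks put mu at the log-midpoint
  for (ab in list(c(3, 40), c(0.5, 2), c(10, 200))) {
    q <- lognormal_from_range(ab[1], ab[2])
    expect_equal(q$mu, mean(log(ab)))
  }
})

test_that("lognormal_from_range round-trips any (mu, sigma) to 1e-9", {
  set.seed(41)
  for (i in 1:25) {
    mu <- runif(1, -2, 4)
    sigma <- runif(1, 0.05, 2)
    p <- runif(1, 0.001, 0.4)
    q <- runif(1, 0.6, 0.999)
    lo <- qlnorm(p, mu, sigma)
    hi <- qlnorm(q, mu, sigma)
    est <- lognormal_from_range(lo, hi, p, q)
    expect_equal(est$mu, mu, tolerance = 1e-9)
    expect_equal(est$sigma, sigma, tolerance = 1e-9)
  }
})

test_that("lognormal_from_range rejects degenerate and invalid input", {
  expect_error(lognormal_from_range(exp(1), exp(1), 0.4, 0.6), "degenerate")
  expect_error(lognormal_from_range(-1, 5), "positive")
  expect_error(lognormal_from_range(0, 5), "positive")
  expect_error(lognormal_from_range(5, 2), ">=")
  expect_error(lognormal_from_range(2, 5, 0.975, 0.025), "0 < p < q < 1")
})

test_that("blood_to_iron matches hand arithmetic and is linear", {
  expect_equal(blood_to_iron(30), 30 * 0.135 * 3.39 / 28)
  expect_equal(blood_to_iron(30), 0.490, tolerance = 1e-3)
  expect_equal(blood_to_iron(0), 0)
  # linear in blood loss and in Hb concentration
  expect_equal(blood_to_iron(60), 2 * blood_to_iron(30))
  expect_equal(blood_to_iron(30, hb_conc = 270), 2 * blood_to_iron(30))
  expect_error(blood_to_iron(30, cycle_days = 0), "positive")
  expect_error(blood_to_iron(-5), "non-negative")
})

test_that("pool_lognormal is a weighted mean with sane bounds", {
  one <- lognormal_params(1.7, 0.9)
  expect_equal(pool_lognormal(list(one), 12), one)
  two <- pool_lognormal(list(lognormal_params(1, 0.5),
                             lognormal_params(3, 1.5)), n = c(10, 30))
  expect_equal(two$mu, 2.5)
  expect_equal(two$sigma, 1.25)
  # equal n reduces to the unweighted mean; pooled mu within per-study range
  set.seed(7)
  params <- lapply(1:6, function(i) lognormal_params(runif(1, 0, 3),
                                                     runif(1, 0.2, 1.5)))
  eq <- pool_lognormal(params, rep(20, 6))
  expect_equal(eq$mu, mean(vapply(params, `[[`, numeric(1), "mu")))
  mus <- vapply(params, `[[`, numeric(1), "mu")
  wt <- pool_lognormal(params, sample(5:50, 6))
  expect_gte(wt$mu, min(mus))
  expect_lte(wt$mu, max(mus))
  # variance pooling differs and is >= sd pooling (Jensen)
  v <- pool_lognormal(params, rep(20, 6), sigma_method = "variance")
  expect_gte(v$sigma, eq$sigma)
  expect_error(pool_lognormal(list(), integer()), "no studies")
  expect_error(pool_lognormal(list(lognormal_params(1, 1, "mg/cycle"),
                                   lognormal_params(1, 1, "mL/cycle")),
                              c(5, 5)), "mixed units")
})

test_that("packaged synthetic study table pools to (2.13, 1.04) exactly", {
  fit <- estimate_menstrual_loss(menstrual_studies_fixture())
  expect_equal(fit$pooled$mu, 2.13, tolerance = 1e-6)
  expect_equal(fit$pooled$sigma, 1.04, tolerance = 1e-6)
  expect_equal(fit$pooled$unit, "mg/cycle")
  expect_setequal(unique(fit$per_study$measure), c("iron_loss", "blood_loss"))
})

test_that("blood- and iron-loss input paths agree on the same study", {
  # the same underlying distribution reported both ways must give the same
  # estimate (the conversion is monotone, so quantiles commute)
  mu <- 2.0
  sigma <- 0.9
  lo <- qlnorm(0.025, mu, sigma)
  hi <- qlnorm(0.975, mu, sigma)
  conv <- 0.135 * 3.39
  df <- menstrual_studies(data.frame(
    study_id = c("iron", "blood"), n = c(50, 50),
    measure = c("iron_loss", "blood_loss"),
    lower = c(lo, lo / conv), upper = c(hi, hi / conv)))
  fit <- estimate_menstrual_loss(df)
  expect_equal(fit$per_study$mu[1], fit$per_study$mu[2], tolerance = 1e-9)
  expect_equal(fit$per_study$sigma[1], fit$per_study$sigma[2],
               tolerance = 1e-9)
  expect_equal(conversion_bias(lognormal_params(mu, sigma, "mg/cycle"),
                               lognormal_params(mu, sigma, "mg/cycle")), 0)
})

test_that("menstrual study validation fills defaults and catches errors", {
  df <- data.frame(study_id = "a", n = 10, measure = "iron_loss",
                   lower = 2, upper = 30)
  st <- menstrual_studies(df)
  expect_equal(st$p, 0.025)
  expect_equal(st$q, 0.975)
  expect_equal(st$hb_conc, 135)
  df$measure <- "weight_loss"
  expect_error(menstrual_studies(df), "measure")
  expect_error(menstrual_studies(data.frame(study_id = "a", n = 10,
                                            measure = "iron_loss",
                                            lower = 5, upper = 2)),
               "lower")
})

test_that("absorption pooling weights strata by inverse SE then population", {
  single <- absorption_studies(data.frame(
    study_id = "s", n = 20, anemia_status = "anemic", cereal = "rice",
    mean_abs = 9.1, sd_abs = 2))
  w_all_anemic_rice <- population_weights(1, c(rice = 1, wheat = 0,
                                               millet = 0))
  expect_equal(as.numeric(pool_absorption(single, w_all_anemic_rice)), 9.1)
  # equal SE -> arithmetic mean within the stratum
  pair <- absorption_studies(data.frame(
    study_id = c("a", "b"), n = c(25, 25),
    anemia_status = "anemic", cereal = "rice",
    mean_abs = c(6, 10), sd_abs = c(3, 3)))
  expect_equal(as.numeric(pool_absorption(pair, w_all_anemic_rice)), 8)
  # empty stratum with nonzero weight errors unless renormalised
  expect_error(pool_absorption(single, population_weights(1, c(rice = 0.5,
                                                               wheat = 0.5,
                                                               millet = 0)),
                               renormalize = FALSE),
               "no study in stratum")
})

test_that("packaged absorption table with default weights lands near 8.7%", {
  pooled <- pool_absorption(read_absorption_studies(), population_weights())
  expect_gt(as.numeric(pooled), 7.5)
  expect_lt(as.numeric(pooled), 10)
  strata <- attr(pooled, "strata")
  expect_true(all(c("anemic", "normal") %in% strata$anemia_status))
})
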