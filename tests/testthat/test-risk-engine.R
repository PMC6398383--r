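# Probability approach, cut-point approximation, TUL exceedance, and the
# per-group scenario table.

req_small <- derive_requirement(n_draws = 1e5, seed = 21)

test_that("probability approach matches the lognormal-lognormal oracle", {
  # closed form: P(X < R) = Phi((mu_R - mu_X)/sqrt(sig_R^2 + sig_X^2))
  fr <- req_small$fitted
  for (mu_x in c(2.2, 2.8)) {
    for (sig_x in c(0.3, 0.5)) {
      intake <- intake_distribution("g", "lognormal",
                                    c(mu = mu_x, sigma = sig_x))
      r <- risk_of_inadequacy(intake, req_small, n_sim = 1e5,
                              seed = 1000 + round(100 * mu_x + 10 * sig_x))
      oracle <- 100 * pnorm((fr$mu - mu_x) / sqrt(fr$sigma^2 + sig_x^2))
      expect_lt(abs(as.numeric(r) - oracle), 3 * attr(r, "mc_se"))
    }
  }
})

test_that("a point-mass intake at the EAR carries 50% risk", {
  ear <- ear_rda(req_small)[["ear"]]
  spike <- intake_distribution("pm", "normal", c(mean = ear, sd = 1e-9))
  r <- risk_of_inadequacy(spike, req_small, n_sim = 1e5, seed = 4)
  expect_equal(as.numeric(r), 50, tolerance = 0.01)
  expect_equal(risk_of_inadequacy_cutpoint(
    intake_distribution("m", "lognormal", c(mu = log(ear), sigma = 0.3)),
    ear), 50)
})

test_that("cut-point method evaluates the intake CDF at the EAR", {
  intake <- intake_distribution("g", "lognormal", c(mu = 2.5, sigma = 0.3))
  expect_equal(risk_of_inadequacy_cutpoint(intake, 14.4),
               100 * pnorm((log(14.4) - 2.5) / 0.3))
  expect_error(risk_of_inadequacy_cutpoint(intake, -3), "positive")
})

test_that("cut-point approximates the probability method when valid", {
  # classical validity: symmetric requirement & intake, intake variance
  # dominating; agreement to < 1 percentage point
  req_norm <- req_small
  # narrow requirement around its median: emulate with a tight lognormal
  req_norm$fitted <- lognormal_params(log(14), 0.05, "mg/d")
  intake <- intake_distribution("g", "normal", c(mean = 16, sd = 6))
  prob <- as.numeric(risk_of_inadequacy(intake, req_norm, 2e5, seed = 8))
  cut <- risk_of_inadequacy_cutpoint(intake, 14)
  expect_lt(abs(prob - cut), 1)
})

test_that("risks are monotone in added dose for every family", {
  doses <- c(0, 5, 10, 24)
  fams <- list(
    intake_distribution("ln", "lognormal", c(mu = 2.4, sigma = 0.45)),
    intake_distribution("ga", "gamma", c(shape = 6, rate = 0.5)),
    intake_distribution("no", "normal", c(mean = 13, sd = 4)))
  for (f in fams) {
    inad <- vapply(doses, function(d) {
      as.numeric(risk_of_inadequacy(shift_intake(f, d), req_small,
                                    n_sim = 1e5, seed = 31))
    }, numeric(1))
    expect_true(all(diff(inad) <= 0))
    exc <- vapply(doses, function(d) {
      risk_of_excess(f, risk_scenario("d", fortification = d,
                                      supplementation = 0))
    }, numeric(1))
    expect_true(all(diff(exc) >= 0))
  }
})

test_that("excess risk is the closed-form shifted tail probability", {
  intake <- intake_distribution("g", "lognormal", c(mu = 2.6, sigma = 0.4))
  sc <- risk_scenario()
  expect_equal(risk_of_excess(intake, sc),
               100 * (1 - plnorm(45 - 24, 2.6, 0.4)))
  # bounded intake below the shifted TUL -> zero risk
  low <- intake_distribution("lo", "normal", c(mean = 5, sd = 0.5))
  expect_equal(risk_of_excess(low, risk_scenario("s", 1, 1, tul = 45)), 0,
               tolerance = 1e-10)
  # infinite TUL limit
  expect_equal(risk_of_excess(intake, risk_scenario("t", 0, 0, tul = 1e9)),
               0, tolerance = 1e-12)
})

test_that("scenario_table reports per-group and summary risks reproducibly", {
  sv <- generate_intake_survey(n_groups = 4, n_per_group = 500, seed = 13)
  fits <- fit_intake_groups(sv)$fits
  tab1 <- scenario_table(fits, req_small, n_sim = 1e5, seed = 3)
  tab2 <- scenario_table(fits, req_small, n_sim = 1e5, seed = 3)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 4)
  num <- vapply(tab1, is.numeric, logical(1))
  expect_true(all(as.matrix(tab1[num]) >= 0 & as.matrix(tab1[num]) <= 100))
  # dosing reduces inadequacy and never reduces excess, per group
  expect_true(all(tab1$risk_inadequate_fortification <=
                    tab1$risk_inadequate_baseline + 1e-9))
  expect_true(all(
    tab1$`risk_excess_fortification+supplementation` >=
      tab1$risk_excess_fortification - 1e-9))
  s <- attr(tab1, "summary")
  expect_true(all(c("column", "median", "q25", "q75") %in% names(s)))
})

test_that("published state risk columns summarise to the reported medians", {
  tab <- state_risk_estimates()
  expect_equal(nrow(tab), 35)
  s <- summarize_risk_table(tab)
  base <- s[s$column == "risk_inadequate_new_ear", ]
  expect_equal(base$median, 65)
  expect_equal(c(base$q25, base$q75), c(48, 78))
})
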