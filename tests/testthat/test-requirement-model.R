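# Factorial requirement: basal component, Monte Carlo convolution,
# bioavailability adjustment, EAR/RDA extraction.

test_that("basal loss distribution reproduces 0.77 +/- 0.25 mg/d", {
  b <- basal_loss_distribution(basal_loss_model())
  expect_identical(b$family, "normal")
  expect_equal(b$mean, 0.77)
  expect_equal(round(b$sd, 2), 0.25)
  # exact product-of-independents identity adds the (small) cross term
  bp <- basal_loss_distribution(basal_loss_model(cv_method = "product"))
  expect_gt(bp$sd, b$sd)
  expect_equal(bp$sd, 0.77 * sqrt(0.292^2 + 0.156^2 + 0.292^2 * 0.156^2))
  # degenerate weight CV: combined CV collapses to the per-kg CV
  b0 <- basal_loss_distribution(basal_loss_model(cv_weight = 1e-12))
  expect_equal(b0$sd / b0$mean, 0.292, tolerance = 1e-9)
})

test_that("convolution conserves the sum of component means", {
  comps <- list(basal_loss_distribution(basal_loss_model()),
                loss_component("menstrual", "lognormal",
                               params = lognormal_params(2.13, 1.04,
                                                         "mg/cycle"),
                               per_cycle = TRUE, cycle_days = 28))
  x <- convolve_requirement(comps, n_draws = 2e5, seed = 5)
  closed_form <- 0.77 + exp(2.13 + 1.04^2 / 2) / 28
  mc_se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - closed_form), 3 * mc_se)
  expect_true(all(x > 0))
})

test_that("convolution is reproducible under a fixed seed", {
  comps <- list(basal_loss_distribution(basal_loss_model()))
  a <- convolve_requirement(comps, n_draws = 1e4, seed = 99)
  b <- convolve_requirement(comps, n_draws = 1e4, seed = 99)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(convolve_requirement(comps, n_draws = 5000), ">= 1e4")
  # does not clobber the caller's RNG stream
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(convolve_requirement(comps, n_draws = 1e4, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Monte Carlo percentiles of a pure lognormal match closed form", {
  comp <- loss_component("m", "lognormal",
                         params = lognormal_params(2.13, 1.04, "mg/cycle"))
  x <- convolve_requirement(list(comp), n_draws = 1e6, seed = 17)
  for (p in c(0.1, 0.5, 0.9, 0.975)) {
    q_mc <- quantile(x, p, names = FALSE)
    q_cf <- qlnorm(p, 2.13, 1.04)
    # bootstrap-free SE of a sample quantile via the density at the quantile
    se <- sqrt(p * (1 - p) / length(x)) / dlnorm(q_cf, 2.13, 1.04)
    expect_lt(abs(q_mc - q_cf), 3 * se)
  }
})

test_that("to_dietary scales samples and fits a lognormal summary", {
  x <- structure(rlnorm(5e4, 1, 0.3), seed = 3L)
  d1 <- to_dietary(x, bioavailability = 1)
  expect_equal(d1$samples, as.numeric(x))
  d08 <- to_dietary(x, 0.08)
  expect_equal(d08$samples, as.numeric(x) / 0.08)
  # halving bioavailability doubles every percentile
  d04 <- to_dietary(x, 0.04)
  expect_equal(quantile(d04$samples, c(0.1, 0.5, 0.9)),
               2 * quantile(d08$samples, c(0.1, 0.5, 0.9)))
  expect_equal(d04$fitted$mu, d08$fitted$mu + log(2))
  expect_equal(d04$fitted$sigma, d08$fitted$sigma)
  expect_error(to_dietary(x, 0), "bioavailability")
  expect_error(to_dietary(x, 1.2), "bioavailability")
  expect_error(to_dietary(c(-1, 2), 0.5), "positive")
})

test_that("EAR/RDA extraction is ordered and internally consistent", {
  req <- derive_requirement(n_draws = 2e5, seed = 11)
  er95 <- ear_rda(req, 0.95)
  er975 <- ear_rda(req, 0.975)
  expect_lt(er95[["ear"]], er95[["rda"]])
  expect_gte(er975[["rda"]], er95[["rda"]])
  # fitted-lognormal reading: RDA(0.975)/EAR = exp(1.96 sigma) by definition,
  # and the empirical reading agrees with it within 5% relative tolerance
  emp <- ear_rda(req, 0.975, method = "empirical")
  expect_equal(er975[["rda"]] / er975[["ear"]],
               exp(qnorm(0.975) * req$fitted$sigma), tolerance = 1e-9)
  expect_equal(emp[["ear"]], er975[["ear"]], tolerance = 0.05)
  # fitted mu/sigma reproduce the sample median within Monte Carlo error
  expect_equal(exp(req$fitted$mu), median(req$samples), tolerance = 0.03)
})

test_that("requirement JSON summary round-trips", {
  req <- derive_requirement(n_draws = 1e4 * 2, seed = 2)
  path <- tempfile(fileext = ".json")
  write_requirement_summary(req, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$ear, unname(ear_rda(req)[["ear"]]))
  expect_equal(js$n_draws, 2e4)
  expect_equal(js$seed, 2)
})
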