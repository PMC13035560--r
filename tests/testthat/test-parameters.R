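test_that("beta fits from mean and 95% CI preserve the mean and hit the interval", {
  d <- fit_beta_mean_ci(0.940, 0.910, 0.960)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.940, tolerance = 1e-10)
  q <- qbeta(c(0.025, 0.975), d$shape1, d$shape2)
  expect_lt(max(abs(q - c(0.910, 0.960))), 0.005)

  d <- fit_beta_mean_ci(0.983, 0.974, 0.993)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.983, tolerance = 1e-10)
  q <- qbeta(c(0.025, 0.975), d$shape1, d$shape2)
  expect_lt(max(abs(q - c(0.974, 0.993))), 0.005)

  # A symmetric interval around 0.5 gives a symmetric beta.
  d <- fit_beta_mean_ci(0.5, 0.4, 0.6)
  expect_equal(d$shape1, d$shape2, tolerance = 1e-6)
})

test_that("strongly asymmetric intervals keep an exact mean and a small residual", {
  # With the mean pinned there is one free parameter for two quantile targets:
  # the wide midazolam interval retains a residual on its upper end.
  d <- fit_beta_mean_ci(0.792, 0.206, 0.982)
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.792, tolerance = 1e-10)
  q <- qbeta(c(0.025, 0.975), d$shape1, d$shape2)
  expect_lt(abs(q[1] - 0.206), 0.005)
  expect_lt(abs(q[2] - 0.982), 0.02)
})

test_that("beta fitting rejects or degrades degenerate inputs as specified", {
  expect_error(fit_beta_mean_ci(0.5, 0.6, 0.9), "outside its confidence interval")
  expect_warning(d <- fit_beta_mean_ci(0.7, 0.7, 0.7), "zero-width")
  expect_identical(d$family, "fixed")
  expect_equal(d$value, 0.7)
})

test_that("gamma fits reproduce the requested mean and spread", {
  d <- fit_gamma_mean_range(39.00, default_cv = 0.2)
  expect_equal(d$shape, 25)
  expect_equal(d$scale, 1.56)

  d <- fit_gamma_mean_range(71.50, 52.00, 195.00)
  sd <- (195 - 52) / (2 * 1.96)
  expect_equal(sd, 36.48, tolerance = 1e-4)
  expect_equal(d$shape, (71.50 / sd)^2)
  expect_equal(d$shape * d$scale, 71.50, tolerance = 1e-12)

  expect_error(fit_gamma_mean_range(-3), "positive")

  # cv -> 0 limit: draws concentrate at the mean.
  d <- fit_gamma_mean_range(50, default_cv = 1e-4)
  set.seed(1)
  x <- rgamma(2000, shape = d$shape, scale = d$scale)
  expect_lt(sd(x), 1e-3 * 50)
})

test_that("parameter sampling is seeded, bounded and mean-faithful", {
  reg <- table1_registry()
  n <- 10000
  draws <- sample_parameters(reg, n, seed = 7)
  expect_identical(draws, sample_parameters(reg, n, seed = 7))

  diag <- fit_diagnostics(reg)
  # family-wise 3-SE bound over the ~25 simultaneous mean checks
  zbound <- qnorm(1 - (2 * pnorm(-3)) / nrow(diag) / 2)
  for (i in seq_len(nrow(diag))) {
    col <- draws[[diag$name[i]]]
    if (diag$family[i] == "fixed") {
      expect_equal(var(col), 0)
      next
    }
    target <- diag$dist_mean[i]
    if (diag$family[i] == "normal") {
      # the sampling floor truncates the normal: compare to the truncated mean
      s <- reg$specs[[diag$name[i]]]$distribution
      a <- (max(s$floor, 0) - s$mean) / s$sd
      target <- s$mean + s$sd * dnorm(a) / (1 - pnorm(a))
    }
    se <- diag$dist_sd[i] / sqrt(n)
    expect_lt(abs(mean(col) - target), zbound * se,
              label = paste("mean recovery for", diag$name[i]))
  }
  probs <- names(reg$specs)[vapply(reg$specs, function(s) s$role, "") == "probability"]
  for (p in probs) expect_true(all(draws[[p]] >= 0 & draws[[p]] <= 1))
  expect_true(all(draws$mri_duration_min >= 5))
  expect_true(all(draws$weight_kg >= 5))
})

test_that("fit-then-sample round trip recovers the published probability rows", {
  reg <- table1_registry()
  n <- 200000
  draws <- sample_parameters(reg, n, seed = 31)
  rows <- list(p_triclofos = c(0.940, 0.910, 0.960),
               p_propofol = c(0.983, 0.974, 0.993))
  for (nm in names(rows)) {
    x <- draws[[nm]]
    expect_equal(mean(x), rows[[nm]][1], tolerance = 0.002)
    q <- quantile(x, c(0.025, 0.975), names = FALSE)
    d <- reg$specs[[nm]]$distribution
    expect_equal(q, qbeta(c(0.025, 0.975), d$shape1, d$shape2), tolerance = 0.005)
  }
})

test_that("base values report the deterministic case and accept overrides", {
  reg <- table1_registry()
  v <- base_values(reg)
  expect_equal(unname(v["fee_iv_sedation_anesth"]), 71.50)
  expect_equal(unname(v["fee_mri"]), 105.30)
  v2 <- base_values(reg, overrides = c(fee_iv_sedation_anesth = 270))
  expect_equal(unname(v2["fee_iv_sedation_anesth"]), 270)
  expect_equal(unname(v2["fee_mri"]), 105.30)
  expect_error(base_values(reg, overrides = c(no_such = 1)), "no_such")
})

test_that("currency conversion is exact and unrounded", {
  expect_equal(convert_currency(11000), 71.50)
  expect_equal(convert_currency(60000), 390.00)
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(7200), 46.80)
})

test_that("the packaged registry mirrors the published parameter table", {
  reg <- table1_registry()
  roles <- vapply(reg$specs, function(s) s$role, "")
  expect_equal(sum(roles == "fee"), 6)         # 5 procedure fees + consultation
  expect_equal(sum(roles == "drug_price"), 7)
  expect_equal(sum(roles == "dose"), 7)        # oral bolus + 3 x (loading, maintenance)
  expect_equal(sum(roles == "probability"), 5)
  expect_equal(reg$settings$exchange_rate, 0.0065)
  expect_equal(reg$settings$discount_rate, 0)
  # the all-success GA rate cannot carry a beta and is held fixed
  expect_identical(reg$specs$p_general_anesthesia$distribution$family, "fixed")
})

test_that("config loading validates schema, converts JPY, reads JSON too", {
  dir <- withr::local_tempdir()
  write_cfg <- function(params, file = "r.yaml") {
    path <- file.path(dir, file)
    yaml::write_yaml(list(settings = list(exchange_rate_usd_per_jpy = 0.0065),
                          parameters = params), path)
    path
  }
  ok <- list(list(name = "fee_x", unit = "USD", currency = "JPY", value = 11000,
                  distribution = "gamma", role = "fee"))
  reg <- read_registry(write_cfg(ok))
  expect_equal(unname(base_values(reg)["fee_x"]), 71.50)

  bad_prob <- list(list(name = "p_x", value = 1.2, distribution = "beta",
                        role = "probability"))
  expect_error(read_registry(write_cfg(bad_prob)), "\\[0, 1\\]")

  unknown <- list(list(name = "x", value = 1, distribution = "fixed",
                       role = "other", typo_key = 3))
  expect_error(read_registry(write_cfg(unknown)), "typo_key")

  no_currency <- list(list(name = "fee_y", value = 10, distribution = "gamma",
                           role = "fee"))
  expect_error(read_registry(write_cfg(no_currency)), "currency")

  jpath <- file.path(dir, "r.json")
  jsonlite::write_json(list(settings = list(exchange_rate_usd_per_jpy = 0.0065),
                            parameters = ok), jpath, auto_unbox = TRUE)
  regj <- read_registry(jpath)
  expect_equal(base_values(regj), base_values(reg))
})
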