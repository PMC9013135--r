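test_that("generation is bit-reproducible and single-country reduces", {
  cfg <- small_config()
  a <- generate_multicountry(cfg, 101)
  b <- generate_multicountry(cfg, 101)
  expect_identical(a, b)

  cfg1 <- small_config(n_countries = 1L)
  mc <- generate_multicountry(cfg1, 202)
  direct <- generate_survey(cfg1, 1L, wealthineq:::derive_seed(202, 1L))
  expect_identical(mc[[1]], direct)
})

test_that("records honour the structural invariants", {
  cfg <- small_config(n_countries = 2L)
  df <- bind_surveys(generate_multicountry(cfg, 7))
  expect_true(all(df$weight > 0))
  expect_true(all(df$wealth_quintile %in% 1:5))
  expect_true(all(vapply(default_covariates(), `[[`, character(1), "name")
                  %in% names(df)))
  ## weights normalized to mean 1 within country
  for (cid in unique(df$country_id))
    expect_equal(mean(df$weight[df$country_id == cid]), 1, tolerance = 1e-12)
  ## weighted quintile shares ~20% each within country
  for (cid in unique(df$country_id)) {
    d <- df[df$country_id == cid, ]
    sh <- vapply(1:5, function(q)
      sum(d$weight[d$wealth_quintile == q]) / sum(d$weight), numeric(1))
    expect_true(all(abs(sh - 0.2) < 0.02))
  }
})

test_that("null model: poor and non-poor rates differ only by noise", {
  cfg <- null_config(clusters_per_country = 60L, births_per_cluster = 100L)
  df <- generate_survey(cfg, 1L, 5)
  poor <- df$wealth_quintile <= 2
  pg <- weighted_prevalence(df$died[poor], df$weight[poor])
  ng <- weighted_prevalence(df$died[!poor], df$weight[!poor])
  se <- sqrt(pg$se^2 + ng$se^2)
  expect_lt(abs(pg$rate - ng$rate), 3 * se)
})

test_that("intercept-only model recovers its analytic death rate", {
  cfg <- null_config(clusters_per_country = 200L, births_per_cluster = 500L)
  df <- generate_survey(cfg, 1L, 12)
  est <- weighted_prevalence(df$died, df$weight)
  mc_se <- 1000 * sqrt(0.05 * 0.95 / est$n_eff)
  expect_lt(abs(est$rate - 50), 3 * mc_se)
})

test_that("poor-effect odds ratio is recovered at scale (MC oracle)", {
  cfg <- pop_config(n_countries = 1L, clusters_per_country = 200L,
                    births_per_cluster = 1000L, covariates = list(),
                    coefficients = list(intercept = qlogis(0.04),
                                        poor = log(1.5), covariates = list()),
                    cluster_re_sd = 0, country_effect_sd = 0,
                    weight_sigma = 0)
  df <- generate_survey(cfg, 1L, 31)
  tab <- wealth_death_table(df)
  or_hat <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_hat) - log(1.5)), 3 * se_log)
})

test_that("expected risk difference increases with the poor effect", {
  mk <- function(bp) pop_config(
    n_countries = 1L, clusters_per_country = 100L, births_per_cluster = 400L,
    covariates = list(),
    coefficients = list(intercept = qlogis(0.04), poor = bp,
                        covariates = list()),
    cluster_re_sd = 0, country_effect_sd = 0, weight_sigma = 0)
  rd_at <- function(bp) country_risk_difference(
    generate_survey(mk(bp), 1L, 77))$rd
  expect_gt(rd_at(log(2.0)), rd_at(log(1.2)))
})

test_that("config validation rejects bad specifications", {
  expect_error(covariate_spec("x", c("a", "b"), c(0.5, 0.6), c(0.5, 0.5)),
               "probs_poor")
  expect_error(pop_config(n_countries = 0), "counts")
  expect_error(pop_config(cluster_re_sd = -1), ">= 0")
  expect_error(pop_config(
    covariates = list(covariate_spec("x", c("a", "b"), c(.5, .5), c(.5, .5))),
    coefficients = list(intercept = 0, poor = 0,
                        covariates = list(x = c(zz = 1)))),
    "unknown levels")
  expect_error(pop_config(
    covariates = list(covariate_spec("x", c("a", "b"), c(.5, .5), c(.5, .5))),
    coefficients = list(intercept = 0, poor = 0,
                        covariates = list(y = c(a = 1)))),
    "undeclared")
})

test_that("true_contributions: nulls, closed form, telescoping", {
  ## identical covariate distributions across groups -> all zero
  cfg0 <- pop_config(
    n_countries = 1L, clusters_per_country = 5L, births_per_cluster = 10L,
    covariates = list(covariate_spec("x", c("a", "b"), c(.5, .5), c(.5, .5))),
    coefficients = list(intercept = -2, poor = 0.3,
                        covariates = list(x = c(a = 0, b = 1))),
    cluster_re_sd = 0, country_effect_sd = 0)
  tc0 <- true_contributions(cfg0, mc_n = 2e4, seed = 5)
  expect_lt(abs(tc0[["x"]]), 0.005)  # 0 up to Monte-Carlo error

  ## single binary covariate: 0.6 * (F(a+b) - F(a)) closed form
  alpha <- qlogis(0.05); beta <- 0.8
  cfg1 <- pop_config(
    n_countries = 1L, clusters_per_country = 5L, births_per_cluster = 10L,
    covariates = list(covariate_spec("x", c("lo", "hi"), c(.2, .8), c(.8, .2))),
    coefficients = list(intercept = alpha, poor = 0.2,
                        covariates = list(x = c(lo = 0, hi = beta))),
    cluster_re_sd = 0, country_effect_sd = 0)
  tc1 <- true_contributions(cfg1, mc_n = 4e5, seed = 8)
  closed <- 0.6 * (plogis(alpha + beta) - plogis(alpha))
  expect_equal(unname(tc1["x"]), closed, tolerance = 0.03)

  ## two independent covariates: contributions sum to the explained gap
  cfg2 <- pop_config(
    n_countries = 1L, clusters_per_country = 5L, births_per_cluster = 10L,
    covariates = list(
      covariate_spec("x", c("lo", "hi"), c(.3, .7), c(.7, .3)),
      covariate_spec("z", c("u", "v"), c(.6, .4), c(.4, .6))),
    coefficients = list(intercept = -2.5, poor = 0.1,
                        covariates = list(x = c(lo = 0, hi = 0.6),
                                          z = c(u = 0, v = -0.4))),
    cluster_re_sd = 0.2, country_effect_sd = 0)
  tc2 <- true_contributions(cfg2, mc_n = 5e4, seed = 9)
  expect_equal(sum(tc2), attr(tc2, "explained"), tolerance = 1e-12)
})

test_that("records and configs round-trip losslessly through disk", {
  cfg <- small_config(n_countries = 2L)
  df <- bind_surveys(generate_multicountry(cfg, 55))
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(df, f)
  back <- read_records(f)
  expect_identical(df, back)

  fj <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, fj)
  cfg2 <- read_config(fj)
  expect_equal(cfg, cfg2)
})
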