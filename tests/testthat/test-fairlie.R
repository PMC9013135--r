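test_that("pooled logit reproduces closed-form fits", {
  ## intercept-only with weighted death share 0.25
  y <- c(1, 0, 0, 0, 1, 0)
  w <- c(1, 1, 1, 1, 0.5, 1.5)   # weighted death share = 1.5/6 = 0.25
  m0 <- fit_pooled_logit(NULL, y, w)
  expect_equal(unname(m0$coefficients["(Intercept)"]), qlogis(0.25),
               tolerance = 1e-8)

  ## single binary covariate, saturated 2x2 with group rates 0.2 / 0.8
  x <- rep(c(0, 1), each = 10)
  y1 <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(8, 2)))
  m1 <- fit_pooled_logit(cbind(x = x), y1)
  expect_equal(unname(m1$coefficients["x"]), qlogis(0.8) - qlogis(0.2),
               tolerance = 1e-7)
  expect_equal(unname(m1$coefficients["(Intercept)"]), qlogis(0.2),
               tolerance = 1e-7)

  ## integer weights equal the row-expanded unweighted fit (glm oracle)
  set.seed(12)
  X <- cbind(a = rbinom(8, 1, .5), b = rnorm(8))
  y2 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  w2 <- c(3, 1, 2, 1, 4, 2, 1, 2)
  mw <- fit_pooled_logit(X, y2, w2)
  idx <- rep(seq_len(8), w2)
  oracle <- stats::glm(y2[idx] ~ X[idx, ], family = stats::binomial())
  expect_equal(unname(mw$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)

  ## validation
  expect_error(fit_pooled_logit(cbind(x = x), rep(0, 20)), "both outcome")
  expect_error(fit_pooled_logit(cbind(a = x, b = x), y1), "collinear")
})

test_that("rank matching honours its contracts", {
  model <- structure(list(coefficients = c(`(Intercept)` = 0, x = 1),
                          layout = list(x = "x"), converged = TRUE),
                     class = "logit_model")
  ## sizes 100 vs 60 -> exactly 60 pairs drawn from the larger group
  Xp <- cbind(x = rnorm(100)); Xn <- cbind(x = rnorm(60))
  mt <- match_samples(Xp, Xn, model, seed = 4)
  expect_identical(nrow(mt$A), 60L)
  expect_identical(nrow(mt$B), 60L)
  expect_length(unique(mt$idx_A), 60L)   # without replacement

  ## 5-vs-5 toy with distinct predictions matches the sort-and-zip oracle
  Xa <- cbind(x = c(3, 1, 5, 2, 4)); Xb <- cbind(x = c(10, 8, 6, 9, 7))
  mt2 <- match_samples(Xa, Xb, model, seed = 1)
  expect_identical(mt2$idx_A, order(Xa[, "x"]))
  expect_identical(mt2$idx_B, order(Xb[, "x"]))

  ## identical covariates in both groups -> zero contributions
  Xs <- cbind(x = c(0, 1, 0, 1))
  mt3 <- match_samples(Xs, Xs, model, seed = 2)
  ct <- sequential_contributions(mt3, model, "x")
  expect_identical(unname(ct[["x"]]), 0)
  expect_identical(attr(ct, "explained"), 0)
})

test_that("sequential substitution matches the hand logistic example", {
  model <- structure(list(coefficients = c(`(Intercept)` = 0, x = 1),
                          layout = list(x = "x"), converged = TRUE),
                     class = "logit_model")
  pairs <- list(A = cbind(x = c(1, 1, 1, 0)), B = cbind(x = c(0, 0, 1, 0)))
  ct <- sequential_contributions(pairs, model, "x")
  expect_equal(unname(ct[["x"]]), 0.25 * 2 * (plogis(1) - plogis(0)),
               tolerance = 1e-12)
  expect_equal(unname(ct[["x"]]), 0.11553, tolerance = 1e-4)
  expect_equal(attr(ct, "explained"), unname(ct[["x"]]))
})

test_that("orderings split but never change the explained gap", {
  model <- structure(list(
    coefficients = c(`(Intercept)` = -1, x = 0.8, z = -0.5),
    layout = list(x = "x", z = "z"), converged = TRUE),
    class = "logit_model")
  set.seed(31)
  pairs <- list(A = cbind(x = rbinom(20, 1, .7), z = rbinom(20, 1, .3)),
                B = cbind(x = rbinom(20, 1, .3), z = rbinom(20, 1, .6)))
  c12 <- sequential_contributions(pairs, model, c("x", "z"))
  c21 <- sequential_contributions(pairs, model, c("z", "x"))
  expect_equal(sum(c12), sum(c21), tolerance = 1e-14)
  expect_equal(attr(c12, "explained"), attr(c21, "explained"),
               tolerance = 1e-14)
  ## independent brute-force oracle for both orderings
  beta <- list(x = c(x = 0.8), z = c(z = -0.5))
  expect_equal(unclass(c12)[c("x", "z")],
               oracle_sequential(-1, beta, pairs$A, pairs$B, c("x", "z"))[c("x", "z")],
               tolerance = 1e-12)
  expect_equal(unclass(c21)[c("z", "x")],
               oracle_sequential(-1, beta, pairs$A, pairs$B, c("z", "x"))[c("z", "x")],
               tolerance = 1e-12)
  ## label swap at fixed coefficients negates the explained gap exactly
  cswap <- sequential_contributions(list(A = pairs$B, B = pairs$A), model,
                                    c("x", "z"))
  expect_equal(attr(cswap, "explained"), -attr(c12, "explained"))
  expect_error(sequential_contributions(pairs, model, c("x", "x")),
               "permutation")
})

test_that("decomposition invariants on generated data", {
  df <- bind_surveys(generate_multicountry(small_config(2L), 77))
  covs <- c("maternal_education", "residence", "water_source")
  fd <- fairlie_decompose(df, covs, n_orderings = 8L, n_subsamples = 2L,
                          seed = 5, keep_replications = TRUE)
  ## telescoping per replication, exact to float tolerance
  err <- abs(rowSums(fd$replications) - fd$replication_explained)
  expect_lt(max(err), 1e-10 * max(1, abs(fd$explained)))
  ## explained identical across orderings within a subsample draw
  per_sub <- split(fd$replication_explained,
                   rep(seq_len(fd$n_subsamples), each = fd$n_orderings))
  for (v in per_sub) expect_identical(diff(range(v)), 0)
  ## total gap equals the weighted group means difference
  poor <- df$wealth_quintile <= 2
  expect_equal(fd$total_gap,
               weighted.mean(df$died[poor], df$weight[poor]) -
                 weighted.mean(df$died[!poor], df$weight[!poor]))
  ## reproducible
  fd2 <- fairlie_decompose(df, covs, n_orderings = 8L, n_subsamples = 2L,
                           seed = 5)
  expect_equal(fd$contributions, fd2$contributions)
})

test_that("degenerate model: intercept-only coefficients give zero everywhere", {
  model <- structure(list(coefficients = c(`(Intercept)` = -2, x = 0, z = 0),
                          layout = list(x = "x", z = "z"), converged = TRUE),
                     class = "logit_model")
  set.seed(44)
  pairs <- list(A = cbind(x = rbinom(15, 1, .8), z = rbinom(15, 1, .2)),
                B = cbind(x = rbinom(15, 1, .2), z = rbinom(15, 1, .7)))
  ct <- sequential_contributions(pairs, model, c("x", "z"))
  expect_identical(unname(ct[["x"]]), 0)
  expect_identical(unname(ct[["z"]]), 0)
  expect_identical(attr(ct, "explained"), 0)
})

test_that("pure group-effect gap leaves the explained part near zero", {
  cfg <- pop_config(
    n_countries = 1L, clusters_per_country = 40L, births_per_cluster = 250L,
    covariates = list(covariate_spec("x", c("a", "b"), c(.5, .5), c(.5, .5))),
    coefficients = list(intercept = qlogis(0.05), poor = log(2),
                        covariates = list(x = c(a = 0, b = 0.4))),
    cluster_re_sd = 0, country_effect_sd = 0)
  df <- generate_survey(cfg, 1L, 88)
  fd <- fairlie_decompose(df, "x", n_orderings = 2L, n_subsamples = 3L,
                          seed = 6)
  expect_gt(fd$total_gap, 0.02)
  expect_lt(abs(fd$explained), 0.2 * abs(fd$total_gap))
})

test_that("contribution table reshapes and guards zero gaps", {
  s <- generate_multicountry(small_config(3L), 15)
  res <- lapply(s, fairlie_decompose, covariates = c("residence", "water_source"),
                n_orderings = 4L, n_subsamples = 1L, seed = 2)
  ct <- contribution_table(res)
  expect_identical(rownames(ct$wide), names(s))
  ## wide matrix is the long table rearranged
  for (i in seq_len(nrow(ct$long)))
    expect_identical(ct$wide[ct$long$country_id[i], ct$long$covariate[i]],
                     ct$long$pct_of_gap[i])
  ## single-covariate full-explanation consistency
  one <- res[[1]]$contributions
  expect_equal(sum(one$pct_of_explained), 100, tolerance = 1e-6)

  ## zero total gap: percents undefined, absolute contributions kept
  df0 <- toy_8()
  df0$died <- c(1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L)
  df0$x1 <- rep(c("a", "b"), 4)
  fd0 <- fairlie_decompose(df0, "x1", n_orderings = 2L, seed = 9)
  expect_equal(fd0$total_gap, 0)
  expect_true(all(is.na(fd0$contributions$pct_of_gap)))
  expect_true(is.finite(fd0$contributions$contribution[1]))
})
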