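test_that("fits are deterministic and recover a null response", {
  d <- sim_cell_dataset(effect = 0, sigma_u = 0.01, sigma_w = 0.01, sigma = 0.02,
                        seed = 51)
  fit <- quick_fit(d, seed = 5)
  fit2 <- quick_fit(d, seed = 5)
  expect_identical(fit$draws, fit2$draws)
  expect_lt(max(abs(coef(fit))), 0.05)
  expect_true(all(c("beta[1]", "beta[2]", "sigma", "sigma_u", "sigma_w") %in%
                    colnames(fit$draws)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
})

test_that("a strong simulated condition effect is recovered with credible intervals covering truth", {
  d <- sim_cell_dataset(effect = 0, n_participants = 40, sigma_u = 0.3,
                        sigma_w = 0.05, sigma = 0.4, seed = 52)
  d$value <- d$value + ifelse(d$condition == "1", 0.3, -0.3)
  fit <- quick_fit(d, seed = 6)
  s <- summary(fit)$table
  b1 <- s[s$parameter == "beta[1]", ]
  b2 <- s[s$parameter == "beta[2]", ]
  expect_true(b1$ci_lower < 0.3 && 0.3 < b1$ci_upper)
  expect_true(b2$ci_lower < -0.3 && -0.3 < b2$ci_upper)
  expect_lt(abs(b1$estimate - 0.3), 0.15)
})

test_that("contrast grammar, telescoping, duality and error handling", {
  d <- sim_cell_dataset(effect = 0.8, seed = 53)
  fit <- quick_fit(d, seed = 7)
  ct <- contrasts_hbm(fit)
  expect_true(all(c("c12", "c1t12", "c1t23", "c1t13", "c12t1", "c2t34") %in% ct$label))
  # draw-wise telescoping: c1t12 + c1t23 = c1t13 (to float rounding)
  d12 <- bowmimic:::contrast_draws(fit, "c1t12")
  d23 <- bowmimic:::contrast_draws(fit, "c1t23")
  d13 <- bowmimic:::contrast_draws(fit, "c1t13")
  expect_lt(max(abs(d12 + d23 - d13)), 1e-12)
  # duality: P(A - B > 0) = 1 - P(B - A > 0) on the same draws
  expect_identical(mean(d12 > 0), 1 - mean(-d12 > 0))
  expect_error(contrasts_hbm(fit, "c19"), "out of range")
  expect_error(contrasts_hbm(fit, "nonsense"), "unknown contrast label")
  # all-positive and symmetric draw sets
  expect_identical(mean(abs(d12) + 1 > 0), 1)
})

test_that("posterior R2: conditional >= marginal always; near zero for pure noise", {
  noise <- sim_cell_dataset(effect = 0, sigma_u = 0.01, sigma_w = 0.01, sigma = 1,
                            seed = 54)
  fit_n <- quick_fit(noise, seed = 8)
  r2n <- bayes_r2(fit_n)
  expect_lt(r2n$conditional, 0.3)
  expect_lt(r2n$marginal, 0.1)
  expect_true(all(r2n$draws$conditional >= r2n$draws$marginal))

  # strong group structure, no group variance in truth -> conditional ~ marginal
  flat <- sim_cell_dataset(effect = 1.5, sigma_u = 1e-3, sigma_w = 1e-3,
                           sigma = 0.3, seed = 55)
  fit_f <- quick_fit(flat, seed = 9)
  r2f <- bayes_r2(fit_f)
  expect_lt(r2f$conditional - r2f$marginal, 0.15)
  expect_gt(r2f$marginal, 0.2)
})

test_that("posterior predictive checks separate well-specified from heavy-tailed data", {
  good <- sim_cell_dataset(effect = 0.5, seed = 56)
  fit_g <- quick_fit(good, seed = 10)
  ppc_g <- posterior_predictive_check(fit_g, seed = 2)
  expect_identical(nrow(ppc_g$stats), 7L)
  med <- ppc_g$stats[ppc_g$stats$statistic == "median", ]
  expect_true(med$observed >= med$rep_q05 && med$observed <= med$rep_q95)

  heavy <- good
  set.seed(57)
  heavy$value <- 0.2 * rt(nrow(heavy), df = 1)
  fit_h <- quick_fit(heavy, seed = 11)
  ppc_h <- posterior_predictive_check(fit_h, seed = 3)
  extreme <- ppc_h$stats[ppc_h$stats$statistic %in% c("min", "max"), ]
  expect_true(any(extreme$observed < extreme$rep_q05 | extreme$observed > extreme$rep_q95))
})

test_that("marginal likelihood is stable and self-comparison gives log BF near 0", {
  d <- sim_cell_dataset(effect = 0.5, seed = 58)
  fit_a <- quick_fit(d, seed = 12)
  fit_b <- quick_fit(d, seed = 13)   # same model, different chain seed
  ml1 <- marginal_likelihood(fit_a, seed = 1)
  ml2 <- marginal_likelihood(fit_b, seed = 2)
  expect_gt(ml1$ess, 100)
  expect_lt(abs(ml1$logml - ml2$logml), 0.1)

  d$x <- rnorm(nrow(d))
  fit_c <- quick_fit(d, covariate = "x", seed = 14)
  cmp <- compare_models(fit_a, fit_c, seed = 3)
  expect_gt(cmp$bf, 1)   # null covariate: simpler model wins
  expect_length(cmp$elpd_diff, 1)
  expect_error(compare_models(fit_a, quick_fit(sim_cell_dataset(seed = 59), seed = 1)),
               "same data")
})

test_that("a strong injected covariate effect flips the Bayes factor", {
  d <- sim_cell_dataset(effect = 0, sigma_u = 0.1, sigma_w = 0.05, sigma = 0.3,
                        seed = 60)
  set.seed(61)
  d$x <- rnorm(nrow(d))
  d$value <- d$value + 1.0 * sd(d$value) * d$x
  fit_s <- quick_fit(d, seed = 15)
  fit_c <- quick_fit(d, covariate = "x", seed = 16)
  cmp <- compare_models(fit_s, fit_c, seed = 4)
  expect_lt(cmp$bf, 1)
  expect_lt(cmp$elpd_diff, 0)
})

test_that("hbm_fit S3 surface behaves like a model object", {
  d <- sim_cell_dataset(effect = 0.6, seed = 62)
  fit <- quick_fit(d, seed = 17)
  expect_named(coef(fit), c("condition1", "condition2"))
  f <- fitted(fit)
  expect_length(f, nrow(d))
  expect_equal(residuals(fit), d$value - f)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(nrow(d), 3L))
  expect_output(print(fit), "hbm_fit")
  expect_output(print(summary(fit)), "Posterior summary")
})
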