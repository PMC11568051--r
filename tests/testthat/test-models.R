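test_that("McFadden R2 is zero for the null model and grows with signal", {
  set.seed(51)
  y <- sv_transform(runif(200), 200)
  expect_equal(mcfadden_r2(y, rep(mean(y), 200)), 0)
  # adding a real covariate cannot decrease it
  x <- rnorm(200)
  y2 <- sv_transform(pmin(pmax(plogis(x) + rnorm(200, 0, 0.05), 0), 1), 200)
  f0 <- glm(y2 ~ 1, family = quasibinomial)
  f1 <- glm(y2 ~ x, family = quasibinomial)
  r0 <- mcfadden_r2(y2, fitted(f0))
  r1 <- mcfadden_r2(y2, fitted(f1))
  expect_equal(r0, 0)
  expect_gt(r1, r0)
})

test_that("quasi-binomial fit recovers a planted negative Spurt-2 effect", {
  set.seed(2026)
  beta <- c(0.4, -1.5, -0.6, 0.3, 0.2, -0.1)  # int, sp2, sp3, aoa2, f, l
  tab <- simulate_proportional_table(2000, beta)
  fit <- fit_proportional_model(tab, "degree_gain")
  expect_s3_class(fit, "phonogrow_glm")
  co <- fit$coefficients
  expect_lt(co["Spurt2", "Estimate"], 0)
  expect_gt(abs(co["Spurt2", "t value"]), 2)
  expect_equal(unname(co[, "Estimate"]), beta, tolerance = 0.25)
  expect_true(fit$mcfadden_r2 > 0 && fit$mcfadden_r2 < 1)
  expect_true(all(fit$odds_ratios$std_odds_ratio > 0))
  expect_true(!is.null(fit$vif))
  expect_output(print(fit), "McFadden")
})

test_that("standardized odds ratios map onto the Cohen-style labels", {
  labels <- phonogrow:::or_effect_label(c(1.1, 2, 4, 10, 0.06))
  expect_equal(as.character(labels),
               c("Very small", "Small", "Medium", "Large", "Large"))
})

test_that("ZINB fit estimates near-zero inflation when there are no zeros", {
  set.seed(61)
  # large count mean + high theta: the NB component itself yields no zeros
  tab <- simulate_zinb_table(1500,
                             beta_count = c(4, 0.2, 0.1, 0.1, 0.05, 0),
                             beta_zero = c(-20, 0, 0, 0, 0, 0),
                             theta = 10)
  expect_true(all(tab$wd_new_int > 0))   # the linear predictor admits none
  fit <- fit_zinb_model(tab)
  pz <- plogis(fit$zero_coefficients["(Intercept)", "Estimate"])
  expect_lt(pz, 0.01)
})

test_that("ZINB simulation recovers the generating parameters within 2 SE", {
  set.seed(71)
  bc <- c(2.0, 0.5, -0.3, 0.2, 0.15, -0.1)
  bz <- c(-1.0, -0.8, 0.6, 0.3, 0, 0)
  tab <- simulate_zinb_table(5000, bc, bz, theta = 2)
  fit <- fit_zinb_model(tab)
  cc <- fit$count_coefficients
  zc <- fit$zero_coefficients
  expect_true(all(abs(cc[, "Estimate"] - bc) <= 2 * cc[, "Std. Error"]))
  expect_true(all(abs(zc[, "Estimate"] - bz) <= 2 * zc[, "Std. Error"]))
  expect_error(fit_zinb_model(transform(tab, wd_new_int = wd_new_int + 0.5)),
               "integer")
})

test_that("pairwise spurt contrasts are antisymmetric response-scale effects", {
  set.seed(81)
  # spurt 1 sits ~0.5 above the rest on the proportion scale
  n <- 1500
  spurt <- sample(1:3, n, replace = TRUE)
  mu <- ifelse(spurt == 1, 0.7, 0.2)
  y <- rbinom(n, 40, mu) / 40
  tab <- data.frame(spurt = spurt, aoa = sample(1:2, n, TRUE),
                    freq_log = rnorm(n), length = rnorm(n),
                    sv_degree_gain = sv_transform(y, n))
  fit <- fit_proportional_model(tab, "degree_gain")
  ct <- pairwise_spurt_contrasts(fit)
  expect_equal(nrow(ct), 3L)                      # 3 spurt pairs
  expect_true(all(abs(ct$estimate) <= 1))
  s12 <- ct$estimate[ct$contrast == "Spurt1 - Spurt2"]
  s23 <- ct$estimate[ct$contrast == "Spurt2 - Spurt3"]
  expect_equal(s12, 0.5, tolerance = 0.05)
  expect_equal(s23, 0, tolerance = 0.05)
  expect_lt(ct$p_value[ct$contrast == "Spurt1 - Spurt2"], 0.001)
  expect_gt(ct$p_value[ct$contrast == "Spurt2 - Spurt3"], 0.1)
})

test_that("degenerate inputs are rejected with clear messages", {
  tab <- data.frame(spurt = rep(1:2, 10), aoa = 1L, freq_log = rnorm(20),
                    length = rnorm(20), sv_degree_gain = rep(0.4, 20))
  expect_error(fit_proportional_model(tab, "degree_gain"), "constant DV")
  tab$sv_degree_gain <- rep(c(0, 0.5), 10)
  expect_error(fit_proportional_model(tab, "degree_gain"), "strictly")
  expect_error(fit_proportional_model(data.frame(a = 1), "degree_gain"),
               "lacks column")
})
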