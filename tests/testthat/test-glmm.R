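# The random-intercept binomial GLMM: oracle equivalence (dense integration,
# plain logistic regression), quadrature stability, calibration of Wald and
# likelihood-ratio inference, and the S3 surface.

test_that("marginal log-likelihood matches dense numerical integration", {
  d <- rint_data(101, G = 3, ni = 4, sigma = 0.8)
  X <- cbind(1, d$x)
  fit <- fit_glmm(y ~ x + (1 | g), d)
  for (theta in list(c(0.3, -0.5, log(0.8)), c(-0.2, 0.9, log(1.5)))) {
    ours <- wardtrig:::glmm_loglik_at(fit, beta = theta[1:2],
                                      log_sigma = theta[3])
    oracle <- trapezoid_loglik(theta[1:2], exp(theta[3]), X, d$y, d$g)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("with no group heterogeneity the fit collapses to plain glm", {
  set.seed(202)
  n <- 1500; G <- 50
  x <- rnorm(n); g <- rep(1:G, length.out = n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))  # sigma_b = 0 truth
  d <- data.frame(y, x, g)
  fit <- fit_glmm(y ~ x + (1 | g), d)
  ref <- glm(y ~ x, binomial, d)
  expect_lt(fit$sigma_b, 0.05)
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("estimates are stable in the quadrature order", {
  d <- rint_data(103, G = 15, ni = 12)
  f25 <- fit_glmm(y ~ x + (1 | g), d, nAGQ = 25)
  f51 <- fit_glmm(y ~ x + (1 | g), d, nAGQ = 51)
  expect_lt(max(abs(coef(f25) - coef(f51))), 1e-5)
  expect_lt(abs(f25$sigma_b - f51$sigma_b), 1e-5)
  ll51 <- wardtrig:::glmm_loglik_at(f25, nAGQ = 51)
  expect_lt(abs(ll51 - f25$loglik), 1e-5)
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- rint_data(104, G = 25, ni = 20, beta = c(-0.6, 0.7), sigma = 1.2)
  ours <- fit_glmm(y ~ x + (1 | g), d, nAGQ = 25)
  ref <- lme4::glmer(y ~ x + (1 | g), d, family = binomial, nAGQ = 25)
  expect_lt(max(abs(coef(ours) - lme4::fixef(ref))), 1e-3)
  expect_lt(abs(ours$sigma_b - sqrt(unlist(lme4::VarCorr(ref)))), 1e-3)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("Wald p-values are uniform under a permutation null", {
  d <- rint_data(105, G = 10, ni = 20, beta = c(-0.3, 0), sigma = 0.8)
  set.seed(106)
  pvals <- replicate(400, {
    d$x <- sample(d$x)
    fit_glmm(y ~ x + (1 | g), d, nAGQ = 9)$p_value[["x"]]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("deterministic given the data, no stochastic optimization", {
  d <- rint_data(107, G = 12, ni = 10)
  f1 <- fit_glmm(y ~ x + (1 | g), d)
  set.seed(999)  # RNG state must be irrelevant
  f2 <- fit_glmm(y ~ x + (1 | g), d)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("degenerate outcomes are rejected or flagged", {
  d <- rint_data(108, G = 6, ni = 8)
  d$y1 <- 1
  expect_error(fit_glmm(y1 ~ x + (1 | g), d), "single class")
  # complete separation: flagged as non-converged with runaway estimate
  d$ys <- as.integer(d$x > 0)
  fs <- suppressWarnings(fit_glmm(ys ~ x + (1 | g), d))
  expect_false(fs$converged)
})

test_that("the LRT behaves as an ANOVA gate", {
  d <- rint_data(109, G = 15, ni = 15, beta = c(-0.3, 0.9))
  f1 <- fit_glmm(y ~ x + (1 | g), d)
  # identical specs: zero deviance change, p = 1, drop
  same <- lrt(f1, f1)
  expect_equal(same$delta_deviance, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$keep)
  # a genuine signal is kept with a tiny p
  f0 <- fit_glmm(y ~ 1 + (1 | g), d)
  lr <- lrt(f0, f1)
  expect_equal(lr$delta_df, 1L)
  expect_lt(lr$p_value, 0.001)
  expect_true(lr$keep)
  expect_gte(f1$loglik, f0$loglik - 1e-8)  # nesting monotonicity
  # anova() method routes to the same test
  av <- anova(f0, f1)
  expect_equal(av$p_value, lr$p_value)
  # non-nested specs are rejected
  d$w <- rnorm(nrow(d))
  fw <- fit_glmm(y ~ w + (1 | g), d)
  expect_error(lrt(fw, f1), "not nested")
  # differing row sets are rejected
  f1b <- fit_glmm(y ~ x + (1 | g), d[-(1:10), ])
  expect_error(lrt(f1b, f1), "different rows")
})

test_that("LRT type-I error is near nominal for a pure-noise addition", {
  set.seed(110)
  rej <- replicate(200, {
    d <- rint_data(sample.int(1e6, 1), G = 15, ni = 20,
                   beta = c(-0.5, 0.6))
    d$noise <- rnorm(nrow(d))
    f0 <- fit_glmm(y ~ x + (1 | g), d, nAGQ = 9)
    f1 <- fit_glmm(y ~ x + noise + (1 | g), d, nAGQ = 9)
    lrt(f0, f1)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.105)
})

test_that("odds ratios exponentiate the estimate and its CI", {
  d <- rint_data(111, G = 10, ni = 10)
  f <- fit_glmm(y ~ x + (1 | g), d)
  o <- odds_ratio(f, "x")
  expect_equal(unname(o["or"]), exp(unname(coef(f)["x"])))
  expect_equal(unname(o[c("lower", "upper")]),
               unname(exp(f$ci["x", ])))
  expect_error(odds_ratio(f, "zz"), "unknown term")
  # exp(0.68) ~ 1.974: the verbal-agitation odds almost double per SD
  expect_equal(exp(0.68), 1.9738777, tolerance = 1e-6)
  # CI transform is monotone
  expect_equal(exp(c(-1.12, -0.10)), c(0.3262787, 0.9048374),
               tolerance = 1e-6)
})

test_that("the CI is estimate +/- 1.96 SE and deviance is -2 logLik", {
  d <- rint_data(112, G = 10, ni = 10)
  f <- fit_glmm(y ~ x + (1 | g), d)
  expect_equal(f$ci[, "lower"], f$beta - 1.96 * f$se)
  expect_equal(f$ci[, "upper"], f$beta + 1.96 * f$se)
  expect_equal(f$deviance, -2 * f$loglik)
  expect_gte(f$sigma_b, 0)
})

test_that("the S3 surface behaves like a fitted model object", {
  d <- rint_data(113, G = 10, ni = 12)
  f <- fit_glmm(y ~ x + (1 | g), d)
  expect_output(print(f), "Gauss-Hermite")
  expect_output(print(summary(f)), "Random intercept")
  expect_equal(dim(summary(f)$coefficients), c(2L, 6L))
  expect_equal(attr(logLik(f), "df"), 3L)
  expect_length(fitted(f), f$n_obs)
  expect_true(all(fitted(f) > 0 & fitted(f) < 1))
  # predictions: population vs conditional, link vs response
  pl <- predict(f, type = "link", re = "population")
  expect_equal(plogis(pl), predict(f, type = "response", re = "population"))
  nd <- data.frame(x = c(-1, 0, 1), g = c(1, 1, 99))  # 99 unseen
  expect_length(predict(f, nd), 3L)
  # residual types are consistent
  expect_equal(residuals(f, "response"), f$y - fitted(f))
  expect_equal(sign(residuals(f, "deviance")), sign(residuals(f, "pearson")))
  # simulate returns valid binary outcomes of the right shape
  sm <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sm), c(f$n_obs, 3L))
  expect_true(all(unlist(sm) %in% 0:1))
  expect_equal(vcov(f)["x", "x"], f$se[["x"]]^2, tolerance = 1e-10)
  expect_equal(unname(confint(f)["x", ]), unname(f$ci["x", ]))
  tf <- tempfile(fileext = ".pdf"); grDevices::pdf(tf)
  expect_silent(plot(f)); grDevices::dev.off(); unlink(tf)
})

test_that("fits are invariant to shifting a raw feature by a constant", {
  ds <- simulate_ward(quick_config(114))
  fx <- extract_features(ds, lengths = 21)
  ft <- as.data.frame(fx$features[fx$features$pass == TRUE,
                                  c("maj_room", "pass", "sound_sd",
                                    "motor", "patient_id", "time_group")])
  fit_on <- function(shift) {
    ft$sound_sd <- ft$sound_sd + shift
    z <- standardize_features(ft)$features
    fit_glmm(motor ~ z_sound_sd + time_group + (1 | patient_id),
             as.data.frame(z), nAGQ = 9)
  }
  f0 <- fit_on(0); f1 <- fit_on(500)
  expect_lt(max(abs(coef(f0) - coef(f1))), 1e-6)
  expect_lt(abs(f0$loglik - f1$loglik), 1e-6)
})

test_that("model-5 style fits recover the planted effects over replicates", {
  reps <- 40
  est <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("sound", "light", "sigma")))
  for (r in seq_len(reps)) {
    ds <- simulate_ward(sim_config(seed = 5000 + r, n_patients = 25,
                                   days = 3, sample_period = 15,
                                   smoothing_span = 15))
    fx <- extract_features(ds, lengths = 21)
    d <- as.data.frame(fx$features)
    d <- d[d$pass & is.finite(d$z_sound_sd) & is.finite(d$z_light_mean), ]
    fv <- fit_glmm(verbal ~ z_sound_sd + time_group + maj_room_group +
                     (1 | patient_id), d, nAGQ = 9)
    fm <- fit_glmm(motor ~ z_light_mean + time_group + maj_room_group +
                     (1 | patient_id), d, nAGQ = 9)
    est[r, ] <- c(coef(fv)[["z_sound_sd"]], coef(fm)[["z_light_mean"]],
                  fm$sigma_b)
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, "sound"]) - 0.68), 2 * mc_se["sound"])
  expect_lt(abs(mean(est[, "light"]) - (-0.61)), 2 * mc_se["light"])
  expect_lt(abs(mean(est[, "sigma"]) - 1.0), 2.5 * mc_se["sigma"])
})
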