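# Window-length sweep, window/feature selection rules and the forward
# build-up mechanics.

# a hand-built coefficient grid exercising the selection rules exactly
fake_grid <- function() {
  g <- data.table::CJ(length_min = c(12, 21, 30),
                      modality = c("light", "sound", "temperature"),
                      feature = c("min", "max", "mean", "median", "sd"),
                      outcome = c("agitation", "motor", "verbal"),
                      sorted = FALSE)
  g$beta <- 0.01
  g$se <- 0.05
  g$p <- 0.9
  g$converged <- TRUE
  g$n <- 500L
  g
}

test_that("select_window counts significant across-length maxima", {
  g <- fake_grid()
  # plant maxima: 3 cells peak at 21 significantly, 1 cell at 12
  g[g$length_min == 21 & g$modality == "sound" & g$feature == "sd",
    c("beta", "p")] <- list(0.7, 1e-5)
  g[g$length_min == 21 & g$modality == "light" & g$feature == "mean" &
      g$outcome == "motor", c("beta", "p")] <- list(-0.5, 1e-3)
  g[g$length_min == 12 & g$modality == "light" & g$feature == "min" &
      g$outcome == "verbal", c("beta", "p")] <- list(0.3, 0.01)
  w <- select_window(g)
  expect_equal(as.numeric(w), 21)
  sc <- attr(w, "scores")
  expect_gt(sc[["21"]], sc[["12"]])  # four strong cells outweigh one
  expect_equal(sc[["30"]], 0)
  expect_gt(sc[["12"]], 0)

  # equal scores tie-break towards the longer window
  g2 <- fake_grid()
  g2[g2$length_min == 12 & g2$modality == "sound" & g2$feature == "sd" &
       g2$outcome == "verbal", c("beta", "p")] <- list(0.7, 1e-5)
  g2[g2$length_min == 30 & g2$modality == "light" & g2$feature == "mean" &
       g2$outcome == "motor", c("beta", "p")] <- list(-0.7, 1e-5)
  expect_equal(as.numeric(select_window(g2)), 30)

  # nothing significant anywhere: configured default with a warning
  expect_warning(w0 <- select_window(fake_grid(), default = 21),
                 "default")
  expect_equal(as.numeric(w0), 21)
})

test_that("select_features takes the largest |beta| with a fixed tie order", {
  g <- fake_grid()
  g[g$length_min == 21 & g$modality == "sound" & g$feature == "sd",
    c("beta", "p")] <- list(0.65, 1e-4)
  g[g$length_min == 21 & g$modality == "light" & g$feature == "mean" &
      g$outcome == "motor", c("beta", "p")] <- list(-0.45, 0.04)
  # duplicated-column tie within light for verbal: mean and median equal
  g[g$length_min == 21 & g$modality == "light" &
      g$feature %in% c("mean", "median") & g$outcome == "verbal",
    c("beta", "p")] <- list(0.2, 0.2)
  sel <- select_features(g, 21)
  tb <- sel$table
  expect_equal(tb$feature[tb$outcome == "verbal" & tb$modality == "sound"],
               factor("sd", levels = c("min", "max", "mean", "median", "sd")))
  expect_equal(as.character(
    tb$feature[tb$outcome == "motor" & tb$modality == "light"]), "mean")
  # tie resolved by the fixed feature order: mean precedes median
  expect_equal(as.character(
    tb$feature[tb$outcome == "verbal" & tb$modality == "light"]), "mean")
  # temperature has no significant cell for any outcome: dropped wholesale
  expect_equal(sel$dropped, "temperature")
  expect_false(any(tb$selected[tb$modality == "temperature"]))
})

test_that("a single supplied length restricts the grid and is returned", {
  ds <- simulate_ward(quick_config(121))
  fx <- extract_features(ds, lengths = 21)
  g <- sweep_windows(fx, nAGQ = 1)
  expect_equal(nrow(g), 45L)  # 15 features x 3 outcomes, one length
  expect_true(all(g$length_min == 21))
  expect_equal(as.numeric(select_window(g)), 21)
})

test_that("sweep records non-converged cells as missing, never imputed", {
  ds <- simulate_ward(quick_config(122))
  fx <- extract_features(ds, lengths = 9)
  g <- sweep_windows(fx, nAGQ = 1)
  expect_true(all(is.na(g$beta[!g$converged])))
  expect_true(all(is.finite(g$beta[g$converged])))
})

test_that("planted causal signal dilutes away from the causal window", {
  # plant only the sound-SD effect; sweep a window inside the causal span
  # against one far before it
  ds <- simulate_ward(model_config(123,
    beta = list(agitation = c(sound_sd = 0.9), motor = numeric(0),
                verbal = c(sound_sd = 0.9))))
  fx <- extract_features(ds, lengths = c(3, 21))
  g <- sweep_windows(fx, nAGQ = 1)
  b21 <- abs(g$beta[g$length_min == 21 & g$modality == "sound" &
                      g$feature == "sd" & g$outcome == "verbal"])
  b3 <- abs(g$beta[g$length_min == 3 & g$modality == "sound" &
                     g$feature == "sd" & g$outcome == "verbal"])
  # the 3-min window [15,12) min before the survey overlaps the causal
  # window only partially: its coefficient is diluted
  expect_gt(b21, b3)
})

test_that("forward build-up shares rows, gates terms, and reports the table", {
  ds <- simulate_ward(model_config(124))
  fx <- extract_features(ds, lengths = 21)
  g <- sweep_windows(fx, nAGQ = 1)
  sel <- select_features(g, 21)
  bu <- forward_build(fx$features, sel, "motor", nAGQ = 9)
  expect_s3_class(bu, "ward_buildup")
  at <- bu$anova_table
  expect_equal(at$model,
               c("1", "2", "3", "4", "5", "5", "5", "6", "7", "8", "9"))
  # every comparison was computed on the identical row set
  ns <- vapply(Filter(Negate(is.null), bu$fits), function(f) f$n_obs,
               numeric(1))
  expect_equal(length(unique(ns)), 1L)
  # context kept regardless; environmental terms only on significant LRT
  expect_true(all(c("time_group", "maj_room_group") %in% bu$kept_terms))
  p_light <- at$p[at$model == "4"]
  expect_equal(any(grepl("z_light", bu$kept_terms)), p_light < 0.05)
  # the final refit exists and nests inside the fitted sequence
  expect_false(is.null(bu$fits$final))
  expect_output(print(bu), "build-up")
})

test_that("build-up with a dropped modality runs the remaining branches", {
  g <- fake_grid()
  g[g$length_min == 21 & g$modality == "sound" & g$feature == "sd",
    c("beta", "p")] <- list(0.65, 1e-4)
  sel <- select_features(g, 21)  # light and temperature dropped
  expect_setequal(sel$dropped, c("light", "temperature"))
  ds <- simulate_ward(quick_config(125))
  fx <- extract_features(ds, lengths = 21)
  bu <- forward_build(fx$features, sel, "verbal", nAGQ = 9)
  expect_null(bu$fits[["4"]])  # light models skipped
  expect_null(bu$fits[["8"]])
  expect_false(is.null(bu$fits[["3"]]))  # sound branch still runs
  expect_true(all(is.na(bu$anova_table$p[bu$anova_table$model %in%
                                           c("4", "8", "9")])))
})
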