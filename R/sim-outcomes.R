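# Agitation outcomes from the causal pre-survey window.
#
# For every scheduled survey the generator extracts the environmental
# features of the causal window (the same extraction code the analysis
# pipeline uses) and standardizes them with *law-level* per-room moments
# calibrated from the generative process itself -- not with the empirical
# moments the pipeline later estimates. Outcomes are then Bernoulli draws
# from logistic models with a shared patient random intercept.

.lin_pred <- function(alpha, beta, zmat, tg, room_grp, cfg, b) {
  eta <- rep(alpha, length(tg)) + b
  if (length(beta)) {
    for (nm in names(beta)) {
      if (!nm %in% colnames(zmat))
        stop("no standardized feature named ", nm)
      eta <- eta + beta[[nm]] * zmat[, nm]
    }
  }
  tg_eff <- c(tg1 = 0, cfg$tg_effects)[paste0("tg", tg)]
  rm_eff <- cfg$room_effects[as.character(room_grp)]
  rm_eff[is.na(rm_eff)] <- 0  # off-map majority: reference level
  eta + tg_eff + rm_eff
}

#' Generate survey outcomes from the causal window
#'
#' Computes the true standardized features of the causal window (33 to 12
#' minutes before each survey under the defaults) for every scheduled survey,
#' draws one random intercept per patient, and samples the agitation
#' outcomes:
#'
#' * `outcome_mode = "subtypes"` (default): motor and verbal agitation are
#'   Bernoulli draws from their own logistic predictors (verbal additionally
#'   receives `kappa * motor`, inducing co-occurrence on top of the shared
#'   intercept); rare resistance-to-care and aggression events are added
#'   independently; overall agitation is the OR of the four subtype
#'   indicators.
#' * `outcome_mode = "direct"`: overall agitation is drawn from its own
#'   logistic predictor and, within agitated surveys, subtype scores are
#'   allocated motor-only / verbal-only / both / other with the configured
#'   mixture.
#'
#' Present subtypes receive a PAS severity drawn uniformly from 1-4; absent
#' ones are 0. Surveys whose causal window would start before the study does
#' are dropped with a message.
#'
#' @param dataset in-progress study list with `layout`, `config`,
#'   `ward_params`, `sensors`, `traces` and `surveys` (timestamps only).
#' @param config the [sim_config()] (defaults to `dataset$config`).
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @param b optional named vector of patient random intercepts (names =
#'   patient ids); drawn from `Normal(0, sigma_b^2)` when `NULL`.
#' @return List with `surveys` (the survey table plus `pas_motor`,
#'   `pas_verbal`, `pas_resist`, `pas_aggr`) and `truth` (random intercepts,
#'   true standardized features, linear predictors and law moments).
#' @export
generate_outcomes <- function(dataset, config = dataset$config, seed = NULL,
                              b = NULL) {
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  surveys <- as.data.table(dataset$surveys)
  co <- causal_offsets(cfg)
  drop <- surveys$time - co[["start"]] * 60 < 0
  if (any(drop)) {
    message(sum(drop), " survey(s) dropped: causal window precedes study start")
    surveys <- surveys[!drop]
  }
  if (!nrow(surveys)) stop("no surveys left to generate outcomes for")
  if (!"survey_id" %in% names(surveys))
    surveys[, survey_id := seq_len(.N)]

  law <- if (cfg$truth_standardization == "law")
    calibrate_room_moments(dataset$layout, cfg, dataset$ward_params)
  else NULL

  tmp <- copy(surveys)
  tmp[, `:=`(pas_motor = 0L, pas_verbal = 0L, pas_resist = 0L,
             pas_aggr = 0L)]
  ds <- dataset
  ds$surveys <- tmp
  fx <- extract_features(ds, lengths = cfg$causal_length_min,
                         buffer = cfg$buffer_min)
  ft <- fx$features[match(surveys$survey_id, fx$features$survey_id)]

  # standardize the raw window features within majority room, either against
  # this replicate's realized moments or against law-calibrated ones
  keys <- paste0(rep(.MODALITIES, each = length(.FEATURES)), "_",
                 rep(.FEATURES, length(.MODALITIES)))
  zmat <- matrix(0, nrow(ft), length(keys), dimnames = list(NULL, keys))
  sensored <- dataset$layout$rooms$room_id[dataset$layout$rooms$n_sensors > 0]
  for (kk in keys) {
    parts <- strsplit(kk, "_", fixed = TRUE)[[1]]
    m <- parts[1]; f <- paste(parts[-1], collapse = "_")
    if (is.null(law)) {
      x <- ft[[kk]]
      grp_room <- ifelse(ft$maj_room %in% sensored, ft$maj_room,
                         "nonsensored")
      mu <- ave(x, grp_room, FUN = function(v) mean(v, na.rm = TRUE))
      sg <- ave(x, grp_room, FUN = function(v) sd(v, na.rm = TRUE))
      z <- (x - mu) / sg
    } else {
      lm_ <- law[law$modality == m & law$feature == f]
      i <- match(ft$maj_room, lm_$room_id)
      z <- (ft[[kk]] - lm_$law_mean[i]) / lm_$law_sd[i]
    }
    z[!is.finite(z)] <- 0  # off-map / sensorless majority: baseline
    zmat[, kk] <- z
  }

  pts <- sort(unique(surveys$patient_id))
  if (is.null(b)) {
    b_pat <- rnorm(length(pts), 0, cfg$sigma_b)
    names(b_pat) <- as.character(pts)
  } else {
    b_pat <- b
    if (is.null(names(b_pat))) names(b_pat) <- as.character(pts)
  }
  b <- unname(b_pat[as.character(surveys$patient_id)])
  tg <- as.integer(as.character(ft$time_group))
  n <- nrow(surveys)

  if (cfg$outcome_mode == "subtypes") {
    eta_m <- .lin_pred(cfg$alpha[["motor"]], cfg$beta$motor, zmat, tg,
                       ft$maj_room_group, cfg, b)
    motor <- rbinom(n, 1L, plogis(eta_m))
    eta_v <- .lin_pred(cfg$alpha[["verbal"]], cfg$beta$verbal, zmat, tg,
                       ft$maj_room_group, cfg, b) + cfg$kappa * motor
    verbal <- rbinom(n, 1L, plogis(eta_v))
    resist <- rbinom(n, 1L, cfg$p_resist)
    aggr <- rbinom(n, 1L, cfg$p_aggr)
    eta_a <- NULL
  } else {
    eta_a <- .lin_pred(cfg$alpha[["agitation"]], cfg$beta$agitation, zmat,
                       tg, ft$maj_room_group, cfg, b)
    agitated <- rbinom(n, 1L, plogis(eta_a))
    cat_ <- rep("none", n)
    na <- sum(agitated)
    if (na > 0)
      cat_[agitated == 1L] <- sample(c("motor", "verbal", "both", "other"),
                                     na, replace = TRUE,
                                     prob = c(86, 34, 66, 5) / 191)
    motor <- as.integer(cat_ %in% c("motor", "both"))
    verbal <- as.integer(cat_ %in% c("verbal", "both"))
    resist <- as.integer(cat_ == "other")
    aggr <- integer(n)
    eta_m <- eta_v <- NULL
  }

  sev <- function(present) as.integer(present * (1L + floor(runif(n) * 4)))
  out <- copy(surveys)
  out[, `:=`(pas_motor = sev(motor), pas_verbal = sev(verbal),
             pas_resist = sev(resist), pas_aggr = sev(aggr))]

  truth <- list(
    b = b_pat, law_moments = law,
    z = data.table(survey_id = surveys$survey_id,
                   maj_room = ft$maj_room, time_group = tg, zmat),
    eta = list(motor = eta_m, verbal = eta_v, agitation = eta_a)
  )
  list(surveys = out, truth = truth)
}
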