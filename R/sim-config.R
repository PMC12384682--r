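#' Simulation configuration for the synthetic ward
#'
#' Collects every generative parameter of the synthetic study: cohort size and
#' duration, sensor sampling, the experience-sampling prompt schedule, the
#' per-modality room processes (light, sound, temperature), patient movement,
#' the causal pre-survey window and the logistic outcome model whose
#' coefficients downstream stages try to recover.
#'
#' Environmental levels are calibrated so that the pooled light distribution
#' over a simulated week has a median of roughly 22 lux with an interquartile
#' range of roughly 7-64 lux, sound sits in a plausible 40-60 dBA band with
#' intermittent bursts, and temperature drifts slowly around 22 degrees C.
#'
#' @param ... overrides for any default listed below; unknown names error.
#' @return An object of class `sim_config` (a named list).
#'
#' @section Key fields:
#' \describe{
#'   \item{n_patients, days}{cohort size (default 37) and days of observation
#'     per patient (default 7, one week each).}
#'   \item{sample_period}{sensor sampling period in seconds (default 1, so the
#'     5-second smoother spans 5 samples).}
#'   \item{prompts_per_day, prompt_window}{scheduled surveys per day (9) and
#'     the clock window in hours (8 to 20) they are stratified over.}
#'   \item{buffer_min, causal_length_min}{gap between the analysed window and
#'     the survey (12 min) and the length of the causal window (21 min), i.e.
#'     the window 33 to 12 minutes before each survey drives the outcomes.}
#'   \item{beta}{named per-outcome coefficient vectors on *standardized*
#'     window features, e.g. `list(motor = c(light_mean = -0.61),
#'     verbal = c(sound_sd = 0.68))`; names follow `<modality>_<feature>`.}
#'   \item{alpha}{per-outcome intercepts on the log-odds scale.}
#'   \item{tg_effects, room_effects}{time-of-day group (reference group 1) and
#'     majority-room group (reference living room) effects shared by all
#'     outcomes.}
#'   \item{sigma_b}{SD of the patient-level random intercept shared by the
#'     subtypes.}
#'   \item{kappa}{direct motor-to-verbal coupling inducing subtype
#'     co-occurrence beyond the shared intercept.}
#'   \item{outcome_mode}{`"subtypes"` (default): motor and verbal drawn from
#'     their own logistic models and overall agitation is the OR of all
#'     subtype indicators; `"direct"`: overall agitation drawn from its own
#'     logistic model, subtype scores allocated within agitated surveys.}
#'   \item{off_map_frac}{long-run fraction of time the patient is untracked.}
#'   \item{self_initiated_rate}{expected number of additional nurse-initiated
#'     surveys per patient-day, triggered preferentially when the latent
#'     agitation predictor is high; 0 disables them (default).}
#' }
#' @examples
#' cfg <- sim_config(n_patients = 5, days = 2, sample_period = 5)
#' cfg$prompts_per_day
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_patients = 37L,
    days = 7L,
    sample_period = 1,
    smoothing_span = 5,
    prompts_per_day = 9L,
    prompt_window = c(8, 20),
    buffer_min = 12,
    causal_length_min = 21,
    start_date = "2021-06-07",
    tz = "UTC",

    # patient movement (semi-Markov over rooms + off-map), seconds
    dwell_mean = c(living_room = 2400, dining_room = 1800, hallway = 360,
                   patient_room = 2700, other = 1200),
    room_weights = c(living_room = 0.33, dining_room = 0.20, hallway = 0.10,
                     patient_room = 0.27, other = 0.10),
    off_map_frac = 0.18,
    off_map_dwell = 900,

    # light: lognormal level with diurnal profile, slow AR(1), fast noise
    light = list(
      night_lux = 4.5,
      day_lux = c(living_room = 75, dining_room = 92, hallway = 48,
                  patient_room = 48, other = 62),
      room_lsd = 0.18,    # between-room lognormal spread of the day level
      slow_sd = 0.45, slow_tau = 420,
      noise_sd = 0.25,    # fast log-scale noise
      meas_lsd = 0.08     # per-enclosure measurement noise (log scale)
    ),
    # sound (leqDBA): Gaussian base + slow drift + heteroscedastic fast noise
    # + Poisson bursts
    sound = list(
      base_dba = c(living_room = 48, dining_room = 50, hallway = 44,
                   patient_room = 40, other = 44),
      room_sd = 1.2,
      diurnal_gain = 5,
      slow_sd = 1.0, slow_tau = 600,
      fast_sd = 1.3, fast_lsd = 0.55, fast_tau = 480,
      burst_rate_day = 8 / 3600,  # bursts per second at full daylight
      burst_rate_night = 0.5 / 3600,
      burst_dur = 20, burst_amp = 8, burst_amp_sd = 2,
      meas_sd = 0.4
    ),
    # temperature: slow drift around ~22 C
    temperature = list(
      base_c = 21.8, room_sd = 0.05, diurnal_amp = 0.5,
      slow_sd = 0.3, slow_tau = 1800,
      noise_sd = 0.12, meas_sd = 0.05
    ),

    # outcome model on standardized causal-window features
    alpha = c(agitation = -1.70, motor = -2.50, verbal = -3.35),
    beta = list(
      agitation = c(sound_sd = 0.452, light_mean = -0.449),
      motor = c(light_mean = -0.61),
      verbal = c(sound_sd = 0.68)
    ),
    tg_effects = c(tg2 = 0.55, tg3 = 0.90, tg4 = 0.40),
    room_effects = c(living_room = 0, dining_room = 0.30, hallway = 0.95,
                     patient_room = 0.35, other = 0.20),
    sigma_b = 1.0,
    kappa = 0.4,
    p_resist = 0.005,
    p_aggr = 0.004,
    outcome_mode = "subtypes",
    # how the generator standardizes its causal features: "empirical" uses
    # the realized replicate's within-room moments (the scale the analysis
    # itself works on); "law" uses single-room moments calibrated from the
    # generative process, which mis-scales windows spanning several rooms
    truth_standardization = "empirical",
    self_initiated_rate = 0,

    # windows per room used to calibrate law-level feature moments
    n_cal = 256L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, dots)
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$days <- as.integer(cfg$days)
  cfg$prompts_per_day <- as.integer(cfg$prompts_per_day)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1L || cfg$days < 1L)
    stop("n_patients and days must be positive")
  if (cfg$sample_period <= 0)
    stop("sample_period must be positive")
  if (cfg$smoothing_span %% cfg$sample_period != 0)
    stop("sample_period must divide the smoothing span")
  co <- causal_offsets(cfg)
  if (!(co["start"] > co["end"] && co["end"] >= 0))
    stop("causal window start offset must exceed the end offset (>= 0)")
  if (diff(cfg$prompt_window) <= 0)
    stop("prompt_window must have positive duration")
  sds <- c(cfg$light$slow_sd, cfg$light$noise_sd, cfg$light$meas_lsd,
           cfg$sound$slow_sd, cfg$sound$fast_sd, cfg$sound$meas_sd,
           cfg$temperature$slow_sd, cfg$temperature$noise_sd,
           cfg$temperature$meas_sd, cfg$sigma_b)
  if (any(sds < 0)) stop("noise SDs must be non-negative")
  if (cfg$off_map_frac < 0 || cfg$off_map_frac >= 1)
    stop("off_map_frac must be in [0, 1)")
  if (!cfg$outcome_mode %in% c("subtypes", "direct"))
    stop("outcome_mode must be 'subtypes' or 'direct'")
  if (!cfg$truth_standardization %in% c("empirical", "law"))
    stop("truth_standardization must be 'empirical' or 'law'")
  cfg
}

# causal window offsets (minutes before the survey): [start, end)
causal_offsets <- function(cfg) {
  c(start = cfg$buffer_min + cfg$causal_length_min, end = cfg$buffer_min)
}

#' @export
print.sim_config <- function(x, ...) {
  co <- causal_offsets(x)
  cat("Synthetic ward configuration\n")
  cat("  cohort: ", x$n_patients, " patients x ", x$days, " days, ",
      x$prompts_per_day, " prompts/day in [",
      x$prompt_window[1], "h, ", x$prompt_window[2], "h)\n", sep = "")
  cat("  sensors: 1 reading /", x$sample_period, "s, smoothing span",
      x$smoothing_span, "s\n")
  cat("  causal window: [t-", co["start"], " min, t-", co["end"],
      " min), outcome mode '", x$outcome_mode, "'\n", sep = "")
  cat("  planted effects:",
      paste(vapply(names(x$beta), function(o) {
        b <- x$beta[[o]]
        if (!length(b)) return(paste0(o, ": none"))
        paste0(o, ": ", paste(names(b), round(b, 3), sep = "=",
                              collapse = ", "))
      }, character(1)), collapse = "; "), "\n")
  invisible(x)
}
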