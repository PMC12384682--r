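#' Schedule the semirandom daily survey prompts
#'
#' The prompt window (default 8 AM to 8 PM) is split into
#' `config$prompts_per_day` equal sub-bins and one prompt is placed uniformly
#' at random on the 1-minute grid inside each bin ("semirandomly
#' distributed"): prompts are spread over the day but their exact times are
#' unpredictable. No minimum spacing is enforced, so consecutive pre-survey
#' windows may overlap, as they can in practice.
#'
#' @param day 0-based study day.
#' @param config a [sim_config()].
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return Numeric vector of `prompts_per_day` timestamps in seconds since
#'   study start, strictly inside the day's prompt window.
#' @export
schedule_emas <- function(day, config, seed = NULL) {
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$prompts_per_day
  w0 <- cfg$prompt_window[1] * 3600
  w1 <- cfg$prompt_window[2] * 3600
  width <- (w1 - w0) / k
  if (width < 60)
    stop("prompts_per_day exceeds the number of 1-minute sub-bins in the window")
  out <- numeric(k)
  for (i in seq_len(k)) {
    lo <- w0 + (i - 1) * width
    hi <- w0 + i * width
    mins <- seq(60 * ceiling(lo / 60), hi - 1e-9, by = 60)
    mins <- mins[mins >= lo & mins < hi]
    out[i] <- mins[sample.int(length(mins), 1L)]
  }
  day * 86400 + out
}
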