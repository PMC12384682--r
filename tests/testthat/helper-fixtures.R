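# Fixtures built in code: a tiny hand-made ward with constant room levels
# (so expected window contents are known exactly), and small simulation
# configurations used across tests.

library(data.table)

# layout: A (1 sensor), B (2 sensors), C (no sensor) + one room per
# remaining group so the layout invariants hold
tiny_layout <- function() {
  ward_layout(data.frame(
    room_id = c("A", "B", "C", "hall", "din", "oth"),
    room_group = c("living_room", "patient_room", "patient_room",
                   "hallway", "dining_room", "other"),
    n_sensors = c(1L, 2L, 0L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  ))
}

# constant-level sensor table on a 1 Hz grid over [0, span): room A = base,
# B's two enclosures = base + 10 and base + 12 (fused mean base + 11)
tiny_sensors <- function(span = 3 * 3600, period = 1,
                         base = c(light = 10, sound = 40,
                                  temperature = 21)) {
  tt <- seq(0, span - period, by = period)
  rows <- list()
  for (m in names(base)) {
    rows[[length(rows) + 1L]] <- data.table(
      time = tt, sensor_id = "A_s1", room_id = "A", modality = m,
      value = base[[m]])
    rows[[length(rows) + 1L]] <- data.table(
      time = tt, sensor_id = "B_s1", room_id = "B", modality = m,
      value = base[[m]] + 10)
    rows[[length(rows) + 1L]] <- data.table(
      time = tt, sensor_id = "B_s2", room_id = "B", modality = m,
      value = base[[m]] + 12)
    for (r in c("hall", "din", "oth"))
      rows[[length(rows) + 1L]] <- data.table(
        time = tt, sensor_id = paste0(r, "_s1"), room_id = r, modality = m,
        value = base[[m]] + 5)
  }
  rbindlist(rows)
}

tiny_dataset <- function(trace, span = 3 * 3600, period = 1) {
  list(layout = tiny_layout(),
       config = sim_config(n_patients = 1, days = 1, sample_period = period,
                           smoothing_span = max(5, period)),
       sensors = tiny_sensors(span, period),
       traces = as.data.table(trace),
       surveys = data.table(survey_id = 1L, patient_id = 1L, time = 0))
}

# small, fast simulation configs (coarse sampling keeps test volume low)
quick_config <- function(seed, ...) {
  sim_config(seed = seed, n_patients = 12, days = 2, sample_period = 10,
             smoothing_span = 10, ...)
}

# moderate scale used where model fits need some power
model_config <- function(seed, ...) {
  sim_config(seed = seed, n_patients = 40, days = 4, sample_period = 10,
             smoothing_span = 10, ...)
}

# random-intercept logistic test data with known parameters
rint_data <- function(seed, G = 20, ni = 15, beta = c(-0.4, 0.8),
                      sigma = 1) {
  set.seed(seed)
  g <- rep(seq_len(G), each = ni)
  x <- rnorm(G * ni)
  b <- rnorm(G, 0, sigma)
  eta <- beta[1] + beta[2] * x + b[g]
  data.frame(y = rbinom(G * ni, 1, plogis(eta)), x = x, g = g)
}

# brute-force marginal log-likelihood by dense trapezoid integration over the
# random intercept (independent oracle for the quadrature implementation)
trapezoid_loglik <- function(beta, sigma, X, y, g, half_width = 10,
                             n_grid = 20001) {
  eta0 <- drop(X %*% beta)
  bs <- seq(-half_width * sigma, half_width * sigma, length.out = n_grid)
  h <- bs[2] - bs[1]
  total <- 0
  for (gi in unique(g)) {
    idx <- which(g == gi)
    lp <- vapply(bs, function(b) {
      e <- eta0[idx] + b
      sum(y[idx] * e - log1p(exp(e))) + dnorm(b, 0, sigma, log = TRUE)
    }, numeric(1))
    m <- max(lp)
    w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
    total <- total + m + log(sum(w * exp(lp - m)) * h)
  }
  total
}
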