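# Shared builders and independent oracles for the test suite.

default_design <- function(...) assay_design(...)

noiseless_truth <- function(papp, seed = 1L) {
  transport_truth(papp, papp, noise_cv = 0, seed = seed)
}

# Independent oracle for the sampling-with-replacement correction: an
# explicit event-by-event mass ledger. At each sampling event the mass in
# the receiver (V_r * C_k) plus everything withdrawn so far is the total
# transported mass; afterwards V_s * C_k leaves the system.
ledger_cumulative_mass <- function(conc, v_receiver, v_sample) {
  removed_total <- 0
  mass <- numeric(length(conc))
  for (k in seq_along(conc)) {
    mass[k] <- v_receiver * conc[k] + removed_total
    removed_total <- removed_total + v_sample * conc[k]
  }
  mass
}

# Closed-form OLS oracle (sum formulas, no lm()).
ols_oracle <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(t)
  resid <- y - intercept - slope * t
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, r_squared = r2, slope_se = se)
}

# Random sampling schedule for property tests.
random_schedule <- function() {
  n <- sample(3:8, 1)
  list(time = sort(sample(1:500, n)),
       conc = stats::runif(n, 0, 50),
       v_r = stats::runif(1, 0.5, 3),
       v_s_frac = stats::runif(1, 0.05, 0.8))
}
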