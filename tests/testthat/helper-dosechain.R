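# Shared helpers: fixtures are built in code, never stored.

hours_after <- function(anchor, h) {
  as.POSIXct(anchor, tz = "UTC") + h * 3600
}

make_log <- function(id, hours, anchor = "2023-01-01 08:00:00", tau = 24) {
  ingestion_log(id, hours_after(anchor, hours), tau = tau, anchor = anchor)
}

# Build a dose_seq directly from an "SFSF" string (zero deviations / excess
# unless given).
make_seq <- function(events, deviations = NULL, excess = NULL, tau = 24,
                     id = "T") {
  ev <- strsplit(events, "")[[1]]
  ns <- sum(ev == "S")
  if (is.null(deviations)) deviations <- rep(0, ns)
  if (is.null(excess)) excess <- rep(0L, ns)
  dosechain:::new_dose_seq(id, ev, deviations, excess, tau)
}

# Write a small ingestion-event CSV and return its path.
write_event_csv <- function(rows) {
  p <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp", rows), p)
  p
}

# Independent Mann-Whitney oracle: exhaustive permutation of the group labels.
mw_permutation_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  list(u = u_obs,
       p_two = mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9),
       p_one_less = mean(all_u <= u_obs + 1e-9))
}

# Independent von Mises MLE oracle: grid maximization of the log-likelihood.
vm_grid_oracle <- function(theta, n_psi = 4001, n_omega = 3000) {
  Cc <- mean(cos(theta)); Ss <- mean(sin(theta))
  psis <- seq(-pi, pi, length.out = n_psi)
  rpart <- cos(psis) * Cc + sin(psis) * Ss
  psi_hat <- psis[which.max(rpart)]
  rmax <- max(rpart)
  omegas <- exp(seq(log(0.05), log(100), length.out = n_omega))
  ll <- omegas * rmax - (log(besselI(omegas, 0, expon.scaled = TRUE)) + omegas)
  list(psi = psi_hat, omega = omegas[which.max(ll)])
}

# Independent Markov MLE oracle: grid maximization of the exact likelihood.
markov_grid_oracle <- function(counts, step = 0.005) {
  grid <- seq(step, 1 - step, by = step)
  term <- function(n, p) if (n == 0) rep(0, length(p)) else n * log(p)
  ll_ss <- term(counts$n_ss, grid) + term(counts$n_sf, 1 - grid)
  ll_fs <- term(counts$n_fs, grid) + term(counts$n_ff, 1 - grid)
  list(p_ss = grid[which.max(ll_ss)], p_fs = grid[which.max(ll_fs)],
       step = step)
}
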