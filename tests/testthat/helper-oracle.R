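# Independent fixed-step Runge-Kutta (RK4) integrator over the R-level
# transwell_rhs(), with the same sampling protocol as simulate_transwell().
# Deliberately brute-force and solver-free: it cross-checks the adaptive
# stiff integration and the compiled kernel.
rk4_transwell <- function(kinetics, design, compound, h = 0.02) {
  d <- design
  donor_ap <- d$donor_side == "apical"
  dose <- d$donor_conc * (if (donor_ap) d$V_A else d$V_B)
  y <- c(if (donor_ap) dose else 0, 0, if (donor_ap) 0 else dose)
  rem <- 0
  sample_event <- function(y, chamber_idx, vol, V) {
    removed <- y[chamber_idx] * vol / V
    y[chamber_idx] <- y[chamber_idx] - removed
    list(y = y, removed = removed)
  }
  i_d <- if (donor_ap) 1L else 3L
  i_r <- if (donor_ap) 3L else 1L
  V_d <- if (donor_ap) d$V_A else d$V_B
  V_r <- if (donor_ap) d$V_B else d$V_A

  ev <- sample_event(y, i_d, d$donor_sample_vol, V_d)
  y <- ev$y; rem <- rem + ev$removed
  st <- d$sample_times[d$sample_times > 0]
  out <- list()
  t <- 0
  for (t_next in st) {
    steps <- round((t_next - t) / h)
    for (s in seq_len(steps)) {
      k1 <- transwell_rhs(y, kinetics, d, compound)
      k2 <- transwell_rhs(pmax(y + h / 2 * k1, 0), kinetics, d, compound)
      k3 <- transwell_rhs(pmax(y + h / 2 * k2, 0), kinetics, d, compound)
      k4 <- transwell_rhs(pmax(y + h * k3, 0), kinetics, d, compound)
      y <- unname(pmax(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0))
    }
    t <- t_next
    out[[length(out) + 1]] <- c(time = t, X_A = y[1], X_C = y[2], X_B = y[3])
    ev <- sample_event(y, i_d, d$donor_sample_vol, V_d)
    y <- ev$y; rem <- rem + ev$removed
    ev <- sample_event(y, i_r, d$receiver_sample_vol, V_r)
    y <- ev$y; rem <- rem + ev$removed
  }
  do.call(rbind, out)
}

# pre-sampling amounts from a simulate_transwell() trajectory at a sample
# time (the row recorded before the sampling event was applied)
traj_pre_sample <- function(traj, t) {
  rows <- which(traj$time == t)
  traj[rows[1], ]
}
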