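# shared fixtures, built in code

# coarser sampling than the generator default keeps multi-replicate tests fast
fast_preset <- function(name, ...) {
  slb_preset(name, dt = 0.1, ...)
}

# single-harmonic piecewise-linear trace: ramp at `slope` Hz/min from t_start
# for `down` minutes, linear recovery to `f_final`, then flat
ramp_trace <- function(slope = -10, t_start = 1, down = 2, f_final = -10,
                       t_end = 12, dt = 0.1, harmonic = 3L) {
  t <- seq(0, t_end, by = dt)
  f_min_val <- slope * down
  f <- ifelse(t < t_start, 0,
       ifelse(t <= t_start + down, slope * (t - t_start),
       pmin(f_min_val + (f_final - f_min_val) *
              (t - t_start - down) / down, f_final)))
  qcmd_trace(tibble::tibble(time_min = t, harmonic = harmonic,
                            delta_f = f, delta_D = 0),
             meta = list(t_start = t_start, t_rinse = t_end - 2,
                         t_end = t_end))
}

table4_rows <- function() {
  tibble::tibble(
    label = c("PC", "9:1 PG/LPG", "8:2 PG/LPG", "7:3 PG/LPG", "6:4 PG/LPG"),
    delta_f = c(-26, -25, -24, -24, -18),
    mixture = list(
      lipid_mixture(c(PC = 1)),
      lipid_mixture(c(PG = 0.9, LPG = 0.1)),
      lipid_mixture(c(PG = 0.8, LPG = 0.2)),
      lipid_mixture(c(PG = 0.7, LPG = 0.3)),
      lipid_mixture(c(PG = 0.6, LPG = 0.4))
    )
  )
}

# printed reference values for the five compositions
table4_expected <- function() {
  tibble::tibble(
    label = c("PC", "9:1 PG/LPG", "8:2 PG/LPG", "7:3 PG/LPG", "6:4 PG/LPG"),
    M_L = c(1.28e-12, 1.25e-12, 1.21e-12, 1.16e-12, 1.12e-12),
    N_L = c(1.41, 1.37, 1.35, 1.40, 0.98),
    a_L = c(0.71, 0.73, 0.74, 0.71, 1.02),
    v_L = c(0.96, 0.91, 0.86, 0.81, 0.76),
    h_L = c(2.71, 2.49, 2.32, 2.27, 1.49)
  )
}
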