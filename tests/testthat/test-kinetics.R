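test_that("initial slope is exact on a linear ramp to a minimum", {
  tr <- ramp_trace(slope = -10)
  m <- trace_markers(tr)
  expect_equal(initial_slope(tr, m), -10, tolerance = 1e-6)
})

test_that("a flat trace reports zero slope with a no-adsorption warning", {
  t <- seq(0, 10, by = 0.1)
  tr <- qcmd_trace(tibble::tibble(time_min = t, harmonic = 3L,
                                  delta_f = 0, delta_D = 0))
  expect_warning(s <- initial_slope(tr, flow_markers(1, 8)), "no adsorption")
  expect_equal(s, 0)
})

test_that("two-step preset slope is close to the secant f_min/t_min", {
  tr <- simulate_trace(slb_preset("PC"))
  s <- initial_slope(tr)
  expect_equal(s, -72 / 2.5, tolerance = 0.1)
})

test_that("slope window errors when shorter than 3 samples", {
  t <- seq(0, 10, by = 2)
  f <- c(0, 0, 0, 0, 0, -50)  # step right before the end of flow
  tr <- qcmd_trace(tibble::tibble(time_min = t, harmonic = 3L,
                                  delta_f = f, delta_D = 0))
  expect_error(initial_slope(tr, flow_markers(8, 10)), "3 samples")
})

test_that("frequency-minimum detection finds the rupture minimum", {
  mn <- detect_frequency_minimum(simulate_trace(slb_preset("PC")),
                                 harmonic = 3, prominence = 10)
  expect_equal(nrow(mn), 1)
  expect_equal(mn$t_min, 7.5, tolerance = 0.3)
  expect_equal(mn$f_min, -72, tolerance = 3)
})

test_that("monotone and noise-only traces yield no minimum", {
  one_step <- simulate_trace(slb_preset("PG-LPG-10"))
  expect_equal(nrow(detect_frequency_minimum(one_step, 3, 10)), 0)

  t <- seq(0, 30, by = 0.05)
  noise <- withr::with_seed(99, stats::rnorm(length(t), 0, 0.5))
  tr <- qcmd_trace(tibble::tibble(time_min = t, harmonic = 3L,
                                  delta_f = noise, delta_D = 0))
  expect_equal(nrow(detect_frequency_minimum(tr, 3, 10)), 0)
})

test_that("overtone spread behaves on identical, separated and baselined harmonics", {
  t <- seq(0, 10, by = 0.1)
  same <- qcmd_trace(tibble::tibble(
    time_min = rep(t, 2), harmonic = rep(c(3L, 11L), each = length(t)),
    delta_f = rep(-20, 2 * length(t)), delta_D = 0))
  expect_equal(overtone_spread(same, c(0, 10)), 0)

  tr <- simulate_trace(slb_preset("PG"))
  base <- overtone_spread(rebaseline(tr, c(0, 4.5)), c(0, 4.5))
  expect_equal(base, 0, tolerance = 1e-9)

  single <- qcmd_trace(tibble::tibble(time_min = t, harmonic = 3L,
                                      delta_f = 0, delta_D = 0))
  expect_error(overtone_spread(single, c(0, 10)), ">= 2 harmonics")
})

test_that("phase trajectories read adsorption/rupture/bilayer directions", {
  two_step <- phase_trajectory(simulate_trace(slb_preset("PC")), 3)
  moving <- as.character(two_step$direction[two_step$direction != "stationary"])
  runs <- rle(moving)$values
  expect_equal(runs[1], "NE")
  expect_true("SW" %in% runs)
  # rupture follows adsorption
  expect_gt(min(which(moving == "SW")), max(which(moving == "NE")) - 1)

  one_step <- phase_trajectory(simulate_trace(slb_preset("PG-LPG-10")), 3)
  moving1 <- one_step$direction[one_step$direction != "stationary"]
  expect_identical(names(which.max(table(moving1))), "E")

  t <- seq(0, 5, by = 0.1)
  flat <- qcmd_trace(tibble::tibble(time_min = t, harmonic = 3L,
                                    delta_f = -20, delta_D = 1))
  expect_true(all(phase_trajectory(flat, 3)$direction == "stationary"))

  short <- qcmd_trace(tibble::tibble(time_min = 0:2, harmonic = 3L,
                                     delta_f = 0, delta_D = 0))
  expect_error(phase_trajectory(short, 3, smooth_window = 5), "fewer samples")
})

test_that("each scenario preset classifies to its generating label", {
  labels <- slb_preset_labels()
  for (name in names(labels)) {
    sig <- classify_signature(simulate_trace(fast_preset(name)))
    expect_identical(sig$label, unname(labels[name]), label = name)
  }
})

test_that("classification populates all descriptors and the rigid flag", {
  sig <- classify_signature(simulate_trace(fast_preset("PC")))
  g <- glance(sig)
  expect_named(g, c("label", "f_final", "D_final", "f_min", "t_min",
                    "initial_slope", "overtone_spread_final",
                    "rinse_delta_f", "rinse_delta_D", "rigid"))
  expect_identical(sig$rigid, sig$D_final < 1)
  expect_lt(sig$f_min, sig$f_final)

  td <- tidy(sig)
  expect_true(all(c("metric", "value") %in% names(td)))

  soft <- classify_signature(simulate_trace(fast_preset("PG")))
  expect_false(soft$rigid)
  expect_true(is.na(soft$f_min))
})

test_that("no prominent minimum implies the label is never two_step_slb", {
  tr <- simulate_trace(fast_preset("PC"))
  for (p in c(10, 60, 200)) {
    th <- signature_thresholds(prominence = p)
    mn <- detect_frequency_minimum(tr, 3, prominence = p,
                                   window = c(5, 45))
    sig <- classify_signature(tr, thresholds = th)
    if (nrow(mn) == 0) expect_false(sig$label == "two_step_slb")
  }
})

test_that("initial slope is invariant under offset and time translation", {
  tr <- simulate_trace(fast_preset("PC", noise_sd_f = 0.2, seed = 3))
  m <- trace_markers(tr)
  s0 <- initial_slope(tr, m)

  offset <- qcmd_trace(dplyr::mutate(tr, delta_f = delta_f + 7),
                       meta = trace_meta(tr))
  expect_equal(initial_slope(offset, m), s0, tolerance = 1e-9)

  shifted <- qcmd_trace(dplyr::mutate(tr, time_min = time_min + 13),
                        meta = trace_meta(tr))
  m2 <- flow_markers(m$t_start + 13, m$t_rinse + 13)
  expect_equal(initial_slope(shifted, m2), s0, tolerance = 1e-9)
})

test_that("markers outside the trace are rejected", {
  tr <- simulate_trace(fast_preset("PC"))
  expect_error(classify_signature(tr, flow_markers(5, 400)), "outside")
  expect_error(initial_slope(tr, flow_markers(-20, 45)), "outside")
})
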