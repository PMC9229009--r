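test_that("Sauerbrey conversion matches hand values", {
  expect_equal(sauerbrey_mass(-25, 17.8), 445)
  expect_equal(sauerbrey_mass(0, 17.8), 0)
  expect_equal(sauerbrey_mass(-26, 17.8), 462.8)
})

test_that("rigidity criterion is strict at 1e-6", {
  expect_true(sauerbrey_applicable(0.6))
  expect_false(sauerbrey_applicable(3.8))
  expect_false(sauerbrey_applicable(1.0))  # boundary excluded
})

test_that("mixture averages are mole-fraction weighted", {
  avg <- mixture_average(lipid_mixture(c(PG = 0.9, LPG = 0.1)))
  expect_equal(avg$mw_avg, 754.4)
  expect_equal(avg$v_tail_avg, 0.91)

  pure <- mixture_average(lipid_mixture(c(LPG = 1)))
  expect_equal(pure$mw_avg, 506)
  expect_equal(pure$v_tail_avg, 0.46)

  six_four <- mixture_average(lipid_mixture(c(PG = 0.6, LPG = 0.4)))
  expect_equal(six_four$mw_avg, 671.6)
  expect_equal(six_four$v_tail_avg, 0.76)
})

test_that("mixture constructor validates fractions and species", {
  expect_error(lipid_mixture(numeric(0)), "empty")
  expect_error(lipid_mixture(c(PG = 0.5, LPG = 0.4)), "sum to 1")
  expect_error(lipid_mixture(c(PG = 1.2, LPG = -0.2)), "\\(0, 1\\]")
  expect_error(lipid_mixture(c(DOPC = 1)), "unknown species")
})

test_that("the worked packing chain reproduces the reported example", {
  res <- packing_from_frequency(-25, lipid_mixture(c(PG = 0.9, LPG = 0.1)))
  expect_equal(res$areal_mass, 445)
  expect_equal(res$corrected_mass, 343)
  expect_equal(res$M_L, 1.25e-12, tolerance = 0.005 / 1.25)
  expect_equal(res$density_total, 2.74, tolerance = 0.005 / 2.74)
  expect_equal(res$N_L, 1.37, tolerance = 0.005 / 1.37)
  expect_equal(res$a_L, 0.73, tolerance = 0.005 / 0.73)
  expect_equal(res$h_L, 2.49, tolerance = 0.005 / 2.49)
})

test_that("the full composition table reproduces every printed value", {
  tbl <- packing_table(table4_rows())
  exp <- table4_expected()
  expect_equal(tbl$label, exp$label)
  expect_equal(tbl$M_L, exp$M_L, tolerance = 0.005 / 1.2)
  for (col in c("N_L", "a_L", "h_L")) {
    expect_true(all(abs(tbl[[col]] - exp[[col]]) <= 0.005 + 1e-12),
                info = col)
  }
  expect_true(all(abs(tbl$v_L_avg - exp$v_L) <= 0.005 + 1e-12))

  fmt <- format_packing_table(tbl)
  expect_equal(fmt$N_L, exp$N_L)
  expect_equal(fmt$a_L, exp$a_L)
  expect_equal(fmt$h_L, exp$h_L)
  expect_equal(fmt$M_L, exp$M_L)
})

test_that("packing identities hold and match a one-expression oracle", {
  withr::with_seed(123, {
    n <- 200
    delta_f <- runif(n, -80, -10)
    frac <- runif(n, 0.01, 0.99)
    keep <- sauerbrey_mass(delta_f) > 102
    delta_f <- delta_f[keep]
    frac <- frac[keep]
    for (i in seq_along(delta_f)) {
      mix <- lipid_mixture(c(PG = frac[i], LPG = 1 - frac[i]))
      res <- packing_from_frequency(delta_f[i], mix)
      expect_equal(res$a_L * res$N_L, 1, tolerance = 1e-12)
      expect_equal(res$h_L * res$a_L, 2 * res$v_L_avg, tolerance = 1e-12)
      expect_equal(res$density_total, 2 * res$N_L, tolerance = 1e-12)

      # independent single-expression recomputation of the whole chain
      mw <- frac[i] * 782 + (1 - frac[i]) * 506
      vL <- frac[i] * 0.96 + (1 - frac[i]) * 0.46
      h_direct <- 2 * vL *
        ((-17.8 * delta_f[i] - 102) / (2 * (mw / 6.02214e23 * 1e9) * 1e14))
      expect_equal(res$h_L, h_direct, tolerance = 1e-12)
    }
  })
})

test_that("packing is monotone in |delta_f| at fixed mixture", {
  mix <- lipid_mixture(c(PG = 0.9, LPG = 0.1))
  fs <- seq(-60, -10, by = 5)
  res <- purrr::map_dfr(fs, function(f) {
    tibble::as_tibble(packing_from_frequency(f, mix))
  })
  # fs increasing means |delta_f| decreasing
  expect_true(all(diff(res$N_L) < 0))
  expect_true(all(diff(res$a_L) > 0))
  expect_true(all(diff(res$h_L) < 0))
})

test_that("films lighter than the water layer are rejected but isolated in batches", {
  mix <- lipid_mixture(c(PG = 1))
  boundary <- -102 / 17.8
  expect_error(packing_from_frequency(boundary, mix), "corrected mass <= 0")

  rows <- tibble::tibble(label = c("ok", "too light"),
                         delta_f = c(-25, -3),
                         mixture = list(mix, mix))
  tbl <- packing_table(rows)
  expect_true(is.na(tbl$N_L[2]))
  expect_match(tbl$note[2], "corrected mass")
  expect_false(is.na(tbl$N_L[1]))
  expect_equal(packing_table(rows[0, ]) |> nrow(), 0)
})

test_that("an inapplicable Sauerbrey film computes with a warning attached", {
  res <- packing_from_frequency(-52, lipid_mixture(c(PG = 1)), D_final = 3.8)
  expect_match(attr(res, "warnings"), "Sauerbrey")
  expect_gt(res$N_L, 0)
  res2 <- packing_from_frequency(-26, lipid_mixture(c(PC = 1)), D_final = 0.6)
  expect_length(attr(res2, "warnings"), 0)
})

test_that("mixtures load from YAML with species overrides", {
  path <- system.file("extdata", "lipids.yaml", package = "qslb")
  mix <- read_mixture(path)
  avg <- mixture_average(mix)
  expect_equal(avg$mw_avg, 754.4)
  expect_equal(avg$v_tail_avg, 0.91)
  markers <- read_flow_markers(path)
  expect_equal(markers$t_rinse, 45)
})
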