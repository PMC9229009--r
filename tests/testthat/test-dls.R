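test_that("two-bin conversions match the hand-evaluated weighting", {
  nd <- size_distribution(c(1, 2), c(1, 1), "number")
  int <- convert_distribution(nd, "intensity")
  expect_equal(int$value, c(100 * 1 / 65, 100 * 64 / 65), tolerance = 1e-12)
  vol <- convert_distribution(nd, "volume")
  expect_equal(vol$value, c(100 / 9, 800 / 9), tolerance = 1e-12)
})

test_that("a single bin is 100% in every basis", {
  d <- size_distribution(50, 123, "number")
  for (b in c("number", "volume", "intensity")) {
    expect_equal(convert_distribution(d, b)$value,
                 if (b == "number") 123 else 100)
  }
  dn <- normalize_distribution(d)
  expect_equal(convert_distribution(dn, "intensity")$value, 100)
})

test_that("conversions normalize, preserve zeros and invert exactly", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      nbin <- sample(3:30, 1)
      d <- sort(runif(nbin, 5, 500))
      v <- runif(nbin)
      v[sample(nbin, 1)] <- 0
      dist <- normalize_distribution(size_distribution(d, v, "number"))
      for (b in c("volume", "intensity")) {
        conv <- convert_distribution(dist, b)
        expect_equal(sum(conv$value), 100, tolerance = 1e-9)
        expect_identical(conv$value == 0, dist$value == 0)
        back <- convert_distribution(conv, "number")
        expect_equal(back$value, dist$value, tolerance = 1e-9)
      }
    }
  })
})

test_that("intensity weights large particles more than volume than number", {
  nd <- normalize_distribution(size_distribution(c(20, 80), c(1, 1), "number"))
  pN <- nd$value[2]
  pV <- convert_distribution(nd, "volume")$value[2]
  pI <- convert_distribution(nd, "intensity")$value[2]
  expect_gte(pI, pV)
  expect_gte(pV, pN)
})

test_that("converting to the own basis is the identity", {
  nd <- size_distribution(c(10, 20), c(3, 7), "volume")
  expect_identical(convert_distribution(nd, "volume"), nd)
})

test_that("degenerate conversions are rejected", {
  zero <- size_distribution(c(1, 2), c(0, 0), "number")
  expect_error(convert_distribution(zero, "volume"), "zero total weight")
  expect_error(size_distribution(c(2, 1), c(1, 1), "number"), "increasing")
  expect_error(size_distribution(c(1, 2), c(1, 1), "number",
                                 normalized = TRUE), "sum to 100")
})

test_that("mode detection finds the expected peaks", {
  d <- exp(seq(log(10), log(300), length.out = 50))
  uni <- size_distribution(d, stats::dlnorm(d, log(45), 0.25), "intensity")
  m <- detect_modes(uni)
  expect_equal(nrow(m), 1)
  expect_equal(m$d_mode, 45, tolerance = 5)

  bi <- size_distribution(d, stats::dlnorm(d, log(40), 0.2) +
                            stats::dlnorm(d, log(120), 0.2), "intensity")
  m2 <- detect_modes(bi)
  expect_equal(nrow(m2), 2)
  expect_equal(sort(m2$d_mode), c(40, 120), tolerance = 0.15)

  empty <- size_distribution(d, rep(0, length(d)), "intensity")
  expect_equal(nrow(detect_modes(empty)), 0)
})

test_that("identical time courses are stable", {
  d <- exp(seq(log(10), log(300), length.out = 50))
  day <- function(t) size_distribution(d, stats::dlnorm(d, log(45), 0.25),
                                       "intensity", timestamp = t)
  s <- stability_assessment(list(day(0), day(1), day(2)))
  expect_identical(stability_verdict(s), "stable")
  expect_false(any(s$aggregating))
})

test_that("a primary-mode shift beyond tolerance flags aggregation", {
  d <- exp(seq(log(10), log(400), length.out = 60))
  mk <- function(center, t) size_distribution(
    d, stats::dlnorm(d, log(center), 0.25), "intensity", timestamp = t)
  s <- stability_assessment(list(mk(45, 0), mk(90, 1)), shift_tol = 25)
  expect_identical(stability_verdict(s), "aggregating")
  expect_true(s$mode_shift[2])
  expect_false(s$aggregating[1])
})

test_that("an emerging secondary peak flags aggregation via the new-peak rule", {
  d <- exp(seq(log(10), log(600), length.out = 60))
  base <- stats::dlnorm(d, log(45), 0.2)
  with_peak <- 0.8 * base / sum(base) + 0.2 * stats::dlnorm(d, log(250), 0.15) /
    sum(stats::dlnorm(d, log(250), 0.15))
  s <- stability_assessment(list(
    size_distribution(d, base, "intensity", timestamp = 0),
    size_distribution(d, base, "intensity", timestamp = 1),
    size_distribution(d, with_peak, "intensity", timestamp = 2)
  ), new_peak_fraction = 5)
  expect_identical(stability_verdict(s), "aggregating")
  expect_false(s$new_peak[2])
  expect_true(s$new_peak[3])
})

test_that("stability assessment validates its inputs", {
  d <- c(10, 20, 40)
  a <- size_distribution(d, c(1, 2, 1), "intensity")
  b <- size_distribution(d, c(1, 2, 1), "volume")
  expect_error(stability_assessment(list(a)), "two time points")
  expect_error(stability_assessment(list(a, b)), "mismatched bases")
})

test_that("size distributions round trip through their CSV dialect", {
  d <- size_distribution(c(10, 20, 40), c(5, 90, 5), "intensity",
                         normalized = TRUE, timestamp = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dls(d, path)
  back <- read_dls(path)
  expect_equal(back$value, d$value)
  expect_identical(dist_basis(back), "intensity")
  expect_equal(dist_timestamp(back), 2)
})
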