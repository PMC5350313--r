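series_from_tac <- function(tacs) {
  # tacs: list of per-pixel TACs laid on a tiny grid (recycled row-major)
  Q <- length(tacs[[1]])
  arr <- array(0, c(Q, 2, 2))
  for (p in 1:4) {
    tac <- tacs[[(p - 1) %% length(tacs) + 1]]
    i <- (p - 1) %/% 2 + 1; j <- (p - 1) %% 2 + 1
    arr[, i, j] <- tac
  }
  gated_series(arr)
}

test_that("phase convention anchors at a cosine peaking at frame 0", {
  Q <- 15
  base <- 10 + cos(2 * pi * (0:(Q - 1)) / Q)
  img <- phase_image(series_from_tac(list(base)))
  expect_equal(max(abs(img$phase_deg)), 0, tolerance = 1e-9)

  shifted <- 10 + cos(2 * pi * ((0:(Q - 1)) - 3) / Q)
  img <- phase_image(series_from_tac(list(shifted)))
  expect_equal(img$phase_deg[1, 1], 360 * 3 / Q, tolerance = 1e-9)
})

test_that("integer circular shifts obey the shift theorem", {
  Q <- 16
  set.seed(3)
  tac <- rpois(Q, 50)
  img0 <- phase_image(series_from_tac(list(tac)))
  for (sh in c(1, 5, 9)) {
    imgs <- phase_image(series_from_tac(list(tac[((0:(Q - 1) - sh) %% Q) + 1])))
    d <- (imgs$phase_deg[1, 1] - img0$phase_deg[1, 1]) %% 360
    expect_equal(d, 360 * sh / Q, tolerance = 1e-8)
  }
})

test_that("phase image ignores uniform intensity scaling; constant TACs invalid", {
  s <- generate_series(quick_params(seed = 6, lvrv_delay_deg = 25))
  img1 <- phase_image(s)
  s2 <- s; s2$counts <- s$counts * 7.5
  img2 <- phase_image(s2)
  expect_equal(img1$phase_deg, img2$phase_deg, tolerance = 1e-10)
  expect_identical(img1$valid, img2$valid)

  flat <- phase_image(gated_series(array(5, c(8, 3, 3))))
  expect_false(any(flat$valid))
})

test_that("phase histogram statistics: degenerate, uniform and arc cases", {
  img <- structure(list(phase_deg = matrix(30, 4, 4),
                        amplitude = matrix(1, 4, 4),
                        valid = matrix(TRUE, 4, 4), grid = c(4, 4)),
                   class = "phase_image")
  st <- phase_stats(img, matrix(TRUE, 4, 4))
  expect_equal(st$mean_phase_deg, 30)
  expect_equal(st$sd_deg, 0)
  expect_equal(st$width95_deg, 0)

  # four-point uniform: narrowest 95% arc spans three clusters = 270 degrees
  ph <- rep(c(0, 90, 180, 270), each = 25)
  img <- structure(list(phase_deg = matrix(ph, 10, 10),
                        amplitude = matrix(1, 10, 10),
                        valid = matrix(TRUE, 10, 10), grid = c(10, 10)),
                   class = "phase_image")
  expect_equal(phase_stats(img, matrix(TRUE, 10, 10))$width95_deg, 270)

  expect_error(phase_stats(img, matrix(FALSE, 10, 10)), "empty")
  img$valid[] <- FALSE
  expect_error(phase_stats(img, matrix(TRUE, 10, 10)), "no valid")
})

test_that("injected interventricular delay is recovered from region phases", {
  lab <- default_masks$labels
  for (d in c(0, 40)) {
    p <- subject_params(lvrv_delay_deg = d, ilv_spread_deg = 4, seed = 17)
    pre <- preprocess_frames(generate_series(p))
    img <- phase_image(pre)
    lv <- phase_stats(img, lab == 1L)
    rv <- phase_stats(img, lab == 2L)
    rec <- phase_difference_deg(rv$mean_phase_deg, lv$mean_phase_deg) *
      cycle_fraction(pre)
    expect_lt(abs(rec - d), 5)
  }
})

test_that("intra-LV phase dispersion tracks the injected spread", {
  lab <- default_masks$labels
  p <- subject_params(ilv_spread_deg = 25, ef_true = 0.3,
                      group = "nonisch_narrow", seed = 23)
  pre <- preprocess_frames(generate_series(p))
  st <- phase_stats(phase_image(pre), lab == 1L)
  expect_lt(abs(st$sd_deg * cycle_fraction(pre) - 25) / 25, 0.30)
})

test_that("LVEF arithmetic and invariances", {
  # max 100, min 40, no background -> 60%
  tac <- c(100, 80, 55, 40, 60, 90)
  arr <- array(0, c(6, 2, 2))
  for (q in 1:6) arr[q, , ] <- tac[q] / 4  # ROI sum over 4 pixels = tac
  s <- gated_series(arr)
  expect_equal(compute_lvef(s, matrix(TRUE, 2, 2)), 60)

  # akinetic limit: ED == ES -> 0%
  expect_equal(compute_lvef(gated_series(array(50, c(6, 2, 2))),
                            matrix(TRUE, 2, 2)), 0)

  # scale invariance, and mask dilation into zero-count pixels (no bg corr.)
  s2 <- gated_series(arr * 3)
  expect_equal(compute_lvef(s2, matrix(TRUE, 2, 2)), 60)
  arr0 <- array(0, c(6, 3, 2)); arr0[, 1:2, ] <- arr
  small <- matrix(c(TRUE, TRUE, FALSE), 3, 2)
  big <- matrix(TRUE, 3, 2)
  expect_equal(compute_lvef(gated_series(arr0), small),
               compute_lvef(gated_series(arr0), big))

  # background correction: ED==BG is an error
  sbg <- gated_series(array(c(rep(10, 6), rep(10, 6), rep(10, 6), rep(10, 6)),
                            c(6, 2, 2)))
  lv <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  bg <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  expect_error(compute_lvef(sbg, lv, bg), "undefined")
})
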