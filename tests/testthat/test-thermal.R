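test_that("the default 0-100 C scan at 0.5 C has exactly 201 points", {
  curve <- partition_over_temperature("GGAAACC", 0, 100, 0.5)
  expect_equal(nrow(curve), 201)
  expect_equal(curve$temperature[2] - curve$temperature[1], 0.5)
})

test_that("an unpairable sequence has lnQ identically zero", {
  curve <- partition_over_temperature("AAAAAAAA", 0, 100, 5)
  expect_true(all(curve$lnQ == 0))
  cv <- heat_capacity(curve)
  expect_true(all(cv$C[is.finite(cv$C)] == 0))
})

test_that("lnQ at a grid temperature equals the fold engine exactly", {
  s <- make_fixture("hairpin")$seq
  curve <- partition_over_temperature(s, 30, 50, 5)
  f <- fold_rna(s, temperature = 40)
  expect_identical(curve$lnQ[curve$temperature == 40], f$lnQ)
})

test_that("lnQ(T) is grid-converged (half-step refinement)", {
  s <- make_fixture("hairpin")$seq
  c1 <- partition_over_temperature(s, 60, 90, 2)
  c2 <- partition_over_temperature(s, 60, 90, 1)
  shared <- match(c1$temperature, c2$temperature)
  expect_identical(c1$lnQ, c2$lnQ[shared])
  # continuity: adjacent lnQ values change smoothly
  expect_lt(max(abs(diff(c1$lnQ))), 1)
})

test_that("the two-state synthetic system melts at the closed-form Tm", {
  dH <- -40; dS <- -0.12; R <- 1.987e-3
  grid <- seq(0, 100, by = 0.5)
  tk <- grid + 273.15
  curve <- tibble::tibble(temperature = grid,
                          lnQ = log1p(exp(-(dH - tk * dS) / (R * tk))))
  cv <- heat_capacity(curve)
  peaks <- find_melting_peaks(cv)
  expect_equal(nrow(peaks), 1)
  tm <- dH / dS - 273.15
  expect_lt(abs(peaks$t_peak - tm), 0.5)
  # the transition integral recovers |dH| (two-state enthalpy conservation)
  win <- which(cv$temperature >= peaks$t_peak - 25 &
                 cv$temperature <= peaks$t_peak + 25 & is.finite(cv$C))
  integral <- sum(diff(cv$temperature[win]) *
                    (head(cv$C[win], -1) + tail(cv$C[win], -1)) / 2)
  expect_lt(abs(integral - abs(dH)) / abs(dH), 0.05)
  # halving the grid step barely moves C
  grid2 <- seq(0, 100, by = 0.25)
  tk2 <- grid2 + 273.15
  cv2 <- heat_capacity(tibble::tibble(
    temperature = grid2, lnQ = log1p(exp(-(dH - tk2 * dS) / (R * tk2)))))
  shared <- match(cv$temperature, cv2$temperature)
  expect_lt(max(abs(cv$C - cv2$C[shared]), na.rm = TRUE),
            1e-3 * max(cv$C, na.rm = TRUE))
})

test_that("a constant lnQ has zero heat capacity and no peaks", {
  curve <- tibble::tibble(temperature = seq(0, 20, 2), lnQ = 3.7)
  cv <- heat_capacity(curve)
  expect_true(all(cv$C[is.finite(cv$C)] == 0))
  expect_equal(nrow(find_melting_peaks(cv)), 0)
})

test_that("monotone heat capacity yields no peaks", {
  cv <- tibble::tibble(temperature = 1:10, C = as.numeric(1:10))
  expect_equal(nrow(find_melting_peaks(cv)), 0)
})

test_that("too few grid points are refused", {
  expect_error(heat_capacity(tibble::tibble(temperature = 1:3, lnQ = 1:3)),
               class = "vfold_grid_error")
  expect_error(partition_over_temperature("GGAAACC", 50, 40, 1),
               class = "vfold_grid_error")
})

test_that("the bistable fixture melts in two transitions ordered by helix stability", {
  fx <- make_fixture("bistable")
  m <- melting_curve(fx$seq)
  expect_equal(nrow(m$peaks), 2)
  # independent per-helix two-state temperatures from the parameter tables
  helix_w <- fx$structure[1:7, , drop = FALSE]
  helix_g <- fx$structure[8:12, , drop = FALSE]
  tm_w <- helix_two_state_tm(fx$seq, helix_w, loop_len = 4)
  tm_g <- helix_two_state_tm(fx$seq, helix_g, loop_len = 6)
  expect_lt(tm_w, tm_g)
  # lower peak = the less stable (AU-rich) helix, higher = the GC helix
  expect_lt(abs(m$peaks$t_peak[1] - tm_w), 12)
  expect_lt(abs(m$peaks$t_peak[2] - tm_g), 12)
})

test_that("the bistable peak count is invariant to the grid step", {
  fx <- make_fixture("bistable")
  for (step in c(0.25, 0.5, 1.0)) {
    m <- melting_curve(fx$seq, t_step = step)
    expect_equal(nrow(m$peaks), 2)
  }
})

test_that("melting-curve tidiers and plots work", {
  m <- melting_curve(make_fixture("hairpin")$seq, t_step = 5)
  expect_true(all(c("temperature", "lnQ", "C") %in% names(tidy(m))))
  expect_s3_class(autoplot(m), "ggplot")
  expect_equal(glance(m)$n_peaks, nrow(m$peaks))
})
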