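test_that("production and oracle enumerators agree on small loops", {
  for (L in 3:5) {
    b <- loop_both("hairpin", L)
    expect_identical(b$production$omega_closed, b$oracle$omega_closed)
    expect_identical(b$production$omega_open, b$oracle$omega_open)
  }
  for (sz in list(c(1, 1), c(2, 0), c(0, 3), c(2, 2))) {
    b <- loop_both("internal", sz)
    expect_identical(b$production$omega_closed, b$oracle$omega_closed)
    expect_identical(b$production$omega_open, b$oracle$omega_open)
  }
  for (sz in list(c(2, 2), c(3, 3), c(1, 4))) {
    b <- loop_both("pk", sz, cap = 6)
    expect_identical(b$production$omega_closed, b$oracle$omega_closed)
  }
})

test_that("free-chain counts respect the coordination bound z(z-1)^(n-1)", {
  # the diamond lattice has girth 6: every non-backtracking walk shorter
  # than 6 steps is self-avoiding, so the bound is met with equality there
  for (n in c(2, 3, 5)) {
    expect_equal(saw_both(n)[["production"]], 4 * 3^(n - 1))
  }
  # from 6 steps on, closing hexagons are excluded and the count drops
  for (n in c(6, 7, 9)) {
    cnt <- saw_both(n)[["production"]]
    expect_lt(cnt, 4 * 3^(n - 1))
    expect_gt(cnt, 0)
  }
})

test_that("a zero-length loop between coincident closure points counts one chain", {
  cnt <- enumerate_loop("internal", c(0, 0))
  expect_equal(cnt$omega_closed, 1)
  expect_equal(cnt$omega_open, 1)
})

test_that("loop entropy is ln(omega_closed/omega_open), never positive", {
  expect_equal(loop_entropy(list(omega_closed = 10, omega_open = 10)), 0)
  expect_equal(loop_entropy(list(omega_closed = 10, omega_open = 10 * exp(1))),
               -1, tolerance = 1e-12)
  expect_identical(loop_entropy(list(omega_closed = 0, omega_open = 5)), -Inf)
  expect_error(loop_entropy(list(omega_closed = 1, omega_open = 0)),
               class = "vfold_invalid_loop")
  ent <- loop_entropy_table()
  expect_true(all(ent$entries$entropy <= 0))
})

test_that("enumeration beyond the cap is refused with guidance", {
  expect_error(enumerate_loop("hairpin", 9, max_size_cap = 8),
               "extrapolate", class = "vfold_enumeration_cap")
})

test_that("extrapolation returns enumerated entries unchanged and decays beyond", {
  ent <- loop_entropy_table()
  e6 <- ent$entries$entropy[ent$entries$loop_type == "hairpin" &
                              ent$entries$size1 == 6]
  got <- extrapolate_entropy(ent, "hairpin", 6)
  expect_identical(got$entropy, e6)
  expect_identical(got$provenance, "enumerated")
  # fitted exponent positive, so dS(2L) < dS(L) in the extrapolated regime
  expect_gt(ent$fits$hairpin[["c"]], 0)
  s20 <- extrapolate_entropy(ent, "hairpin", 20)
  s40 <- extrapolate_entropy(ent, "hairpin", 40)
  expect_identical(s20$provenance, "extrapolated")
  expect_lt(s40$entropy, s20$entropy)
})

test_that("hairpin entropies are non-increasing beyond the entropy-maximal size", {
  ent <- loop_entropy_table()
  hp <- ent$entries[ent$entries$loop_type == "hairpin", ]
  hp <- hp[order(hp$size1), ]
  L0 <- hp$size1[which.max(hp$entropy)]
  tail_s <- hp$entropy[hp$size1 >= L0]
  expect_true(all(diff(tail_s) <= 0))
  # Jacobson-Stockmayer behavior: dS vs ln L close to linear on the tail
  fit <- lm(entropy ~ log(size1), data = hp[hp$size1 >= L0, ])
  expect_lt(coef(fit)[2], 0)
  expect_lt(max(abs(residuals(fit))), 0.15)
})

test_that("mismatch constraints never increase the loop entropy", {
  plain <- loop_entropy(enumerate_loop("hairpin", 6))
  for (mm in list(cbind(1, 5), cbind(1, 6), cbind(2, 6))) {
    s <- mismatch_loop_entropy("hairpin", 6, mm)
    expect_lte(s, plain)
  }
  plain_i <- loop_entropy(enumerate_loop("internal", c(3, 3)))
  s_i <- mismatch_loop_entropy("internal", c(3, 3), cbind(2, 2))
  expect_lte(s_i, plain_i)
  # empty constraint set reduces to the plain loop
  expect_equal(mismatch_loop_entropy("hairpin", 6, NULL), plain)
})

test_that("constrained enumeration matches the oracle enumerator", {
  for (case in list(list("hairpin", 5, cbind(1, 5)),
                    list("hairpin", 6, cbind(2, 6)),
                    list("internal", c(2, 2), cbind(1, 2)),
                    list("internal", c(3, 1), cbind(2, 1)))) {
    b <- loop_both(case[[1]], case[[2]], mm = case[[3]])
    expect_identical(b$production$omega_closed, b$oracle$omega_closed)
  }
})

test_that("mismatch-position symmetry of the closure template holds", {
  # inverting the walk through the closure bond maps (u,v) -> (L+1-v, L+1-u)
  a <- enumerate_loop("hairpin", 7, mismatch_positions = cbind(1, 5))
  b <- enumerate_loop("hairpin", 7, mismatch_positions = cbind(3, 7))
  expect_identical(a$omega_closed, b$omega_closed)
})

test_that("table regeneration is bit-identical and round-trips through text", {
  small <- build_entropy_tables(max_total = 4, pk_max_loop = 2,
                                pk_max_helix = 2, mismatches = FALSE)
  small2 <- build_entropy_tables(max_total = 4, pk_max_loop = 2,
                                 pk_max_helix = 2, mismatches = FALSE)
  expect_identical(small$entries, small2$entries)
  # enumerated entries agree with the shipped table
  ent <- loop_entropy_table()
  for (r in seq_len(nrow(small$entries))) {
    row <- small$entries[r, ]
    hit <- ent$entries[ent$entries$loop_type == row$loop_type &
                         ent$entries$size1 == row$size1 &
                         ent$entries$size2 == row$size2, ]
    expect_equal(hit$omega_closed, row$omega_closed)
    expect_equal(hit$omega_open, row$omega_open)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_table(small, path)
  back <- read_entropy_table(path)
  expect_equal(back$entries$entropy, small$entries$entropy, tolerance = 1e-10)
  expect_identical(back$entries$omega_closed, small$entries$omega_closed)
})
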