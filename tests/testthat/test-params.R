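test_that("stack free energy vanishes at the compensation temperature", {
  p <- energy_params("turner04")
  dH <- p$stack$dH["GC", "CG"]
  dS <- p$stack$dS["GC", "CG"]
  t_comp <- dH / dS - 273.15
  expect_equal(stack_free_energy("GC", "GC", t_comp, p), 0, tolerance = 1e-10)
})

test_that("stack lookup is invariant under strand rotation of the key", {
  for (dia in c("turner04", "mfold23")) {
    p <- energy_params(dia)
    combos <- expand.grid(o = c("GC", "CG", "AU", "GU"),
                          i = c("GC", "UA", "UG", "AU"),
                          stringsAsFactors = FALSE)
    for (k in seq_len(nrow(combos))) {
      o <- combos$o[k]; i <- combos$i[k]
      rot_o <- paste0(substr(i, 2, 2), substr(i, 1, 1))
      rot_i <- paste0(substr(o, 2, 2), substr(o, 1, 1))
      expect_equal(stack_free_energy(o, i, 37, p),
                   stack_free_energy(rot_o, rot_i, 37, p))
    }
  }
})

test_that("embedded tables reconstruct the published dG37 entries", {
  # dG37 = dH - 310.15 * dS must reproduce the stored 37C table to 0.01
  for (dia in c("turner04", "mfold23")) {
    p <- energy_params(dia)
    recon <- p$stack$dH - 310.15 * p$stack$dS
    expect_true(all(abs(recon - p$stack$dG37) < 0.01))
  }
  # spot values: outer G.C on inner G.C is the 5'GG/3'CC stack, outer G.C
  # on inner C.G the 5'GC/3'CG stack
  expect_equal(stack_free_energy("GC", "GC", 37, "turner04"), -3.30,
               tolerance = 1e-6)
  expect_equal(stack_free_energy("GC", "CG", 37, "turner04"), -3.40,
               tolerance = 1e-6)
  # the 1986 compilation's 5'GC/3'CG stack
  expect_equal(stack_free_energy("GC", "CG", 37, "mfold23"), -3.40,
               tolerance = 1e-6)
})

test_that("the two dialects are genuinely distinct", {
  p1 <- energy_params("turner04")
  p2 <- energy_params("mfold23")
  expect_true(any(abs(p1$stack$dG37 - p2$stack$dG37) > 0.05))
})

test_that("dG(T) is linear in T with slope -dS", {
  p <- energy_params("turner04")
  g10 <- stack_free_energy("CG", "CG", 10, p)
  g60 <- stack_free_energy("CG", "CG", 60, p)
  dS <- p$stack$dS["CG", "GC"]
  expect_equal((g60 - g10) / 50, -dS, tolerance = 1e-12)
})

test_that("unknown stack keys raise a parameter-missing error naming the key", {
  expect_error(stack_free_energy("GA", "GC"), "GA",
               class = "vfold_parameter_missing")
})

test_that("loop free energy follows -T*R*S plus closing stacks", {
  ent <- loop_entropy_table()
  S <- extrapolate_entropy(ent, "hairpin", 4)$entropy
  g <- loop_free_energy("hairpin", 4, temperature = 37)
  expect_equal(g, -310.15 * 1.987e-3 * S, tolerance = 1e-10)
  # with a closing stack the stack term adds on top
  g2 <- loop_free_energy("hairpin", 4, closing_stacks = list(c("GC", "GC")),
                         temperature = 37)
  expect_equal(g2 - g, stack_free_energy("GC", "GC", 37), tolerance = 1e-10)
})

test_that("loops below the minimum size are rejected", {
  expect_error(loop_free_energy("hairpin", 2), class = "vfold_invalid_loop")
  expect_error(loop_free_energy("internal", c(0, 1)),
               class = "vfold_invalid_loop")
  expect_error(loop_free_energy("bulge", 0), class = "vfold_invalid_loop")
})

test_that("temperatures outside -10..150 C are rejected", {
  expect_error(stack_free_energy("GC", "GC", -20),
               class = "vfold_temperature_error")
  expect_error(stack_free_energy("GC", "GC", 200),
               class = "vfold_temperature_error")
})

test_that("parameter export writes a readable stack table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  export_params("turner04", path)
  df <- read.delim(path)
  expect_equal(nrow(df), 36)
  expect_true(all(abs(df$dH - 310.15 * df$dS - df$dG37) < 0.01))
})
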