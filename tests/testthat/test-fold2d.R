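test_that("an unpairable sequence has Q = 1 and an empty probability matrix", {
  f <- fold_rna("AAAAAAAA")
  expect_equal(f$Q, 1)
  expect_true(all(f$bpp == 0))
  expect_equal(nrow(f$helices), 0)
  expect_equal(nrow(f$dominant$pairs), 0)
})

test_that("the DP matches exhaustive enumeration on a designed hairpin", {
  fd <- fold_rna("GGGAAAACCC")
  fo <- exhaustive_fold("GGGAAAACCC")
  expect_equal(fd$Q, fo$Q, tolerance = 1e-9)
  expect_lt(max(abs(fd$bpp - fo$bpp)), 1e-9)
  # the ensemble of this sequence enumerates to exactly 6 structures
  # (open chain + five helix placements), counted by hand from the list of
  # valid >= 2-pair runs with a >= 3 nt hairpin gap
  expect_equal(fo$n_structures, 6)
})

test_that("DP equals the oracle across random sequences, modes and dialects", {
  for (k in 1:24) {
    n <- 8 + (k * 7) %% 11
    s <- make_fixture("random", length = n, seed = 1000 + k)$seq
    mode <- c("none", "junction1", "any")[(k %% 3) + 1]
    dia <- c("turner04", "mfold23")[(k %% 2) + 1]
    fd <- fold_rna(s, params = dia, pseudoknot = mode)
    fo <- exhaustive_fold(s, params = dia, pseudoknot = mode)
    expect_equal(fd$Q, fo$Q, tolerance = 1e-9)
    expect_lt(max(abs(fd$bpp - fo$bpp)), 1e-9)
  }
})

test_that("oracle structure probabilities are normalized", {
  fo <- exhaustive_fold("GCGCAAAAGCGC", pseudoknot = "none")
  total <- sum(vapply(fo$structures, function(x) x$weight, 0)) / fo$Qn
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("the open chain is the zero of the structure free energy", {
  expect_equal(structure_free_energy("GGGAAAACCC", matrix(integer(0), 0, 2)), 0)
})

test_that("a single-hairpin free energy decomposes into stack and loop terms", {
  s <- "GGGAAAACCC"
  pairs <- cbind(1:3, 10:8)
  g <- structure_free_energy(s, pairs, temperature = 37,
                             mismatches = "none")
  manual <- stack_free_energy("GC", "GC", 37) +
    stack_free_energy("GC", "GC", 37) +
    loop_free_energy("hairpin", 4, temperature = 37)
  expect_equal(g, manual, tolerance = 1e-9)
})

test_that("structure free energy is linear in temperature", {
  s <- "GGGAAAACCC"
  pairs <- cbind(1:3, 10:8)
  g20 <- structure_free_energy(s, pairs, temperature = 20, mismatches = "none")
  g60 <- structure_free_energy(s, pairs, temperature = 60, mismatches = "none")
  # dG(T) = dH - T dS, so the difference over 40 K gives the total dS
  p <- energy_params("turner04")
  dS_stacks <- 2 * p$stack$dS["GC", "CG"]
  S_loop <- extrapolate_entropy(loop_entropy_table(), "hairpin", 4)$entropy
  dS_total <- dS_stacks + p$gas_constant * S_loop
  expect_equal(g60 - g20, -40 * dS_total, tolerance = 1e-9)
})

test_that("disallowed pairs are rejected", {
  expect_error(structure_free_energy("GGGAAAACCC", cbind(c(4, 5), c(7, 6))),
               class = "vfold_invalid_structure")
  expect_error(validate_structure("GGGAACCC", "((((.)))"),
               class = "vfold_parse_error")
})

test_that("poly-A loops admit only the plain variant", {
  v <- enumerate_mismatch_variants("GGGAAAAAAACCC",
                                   list(type = "hairpin", closing = c(3, 11)))
  expect_equal(nrow(v), 1)
  expect_true(is.na(v$u[1]))
})

test_that("mismatch variants add non-negative ensemble weight", {
  s <- "GGGGCAUGCACCC"
  v <- enumerate_mismatch_variants(s, list(type = "hairpin", closing = c(3, 11)))
  expect_gt(nrow(v), 1)
  expect_gte(sum(v$weight), v$weight[1])
  # every variant entropy is below the plain loop's
  expect_true(all(v$dS[-1] <= v$dS[1]))
})

test_that("helix probabilities read off the probability matrix", {
  f <- fold_rna("GGGAAAACCC")
  h <- f$helices
  expect_gte(nrow(h), 1)
  expect_equal(h$i[1], 1)
  expect_equal(h$j[1], 10)
  expect_equal(h$length[1], 3)
  expect_equal(h$prob[1], mean(f$bpp[cbind(1:3, 10:8)]), tolerance = 1e-12)
  # all-zero matrix gives an empty list
  expect_equal(nrow(helix_probabilities(matrix(0, 8, 8))), 0)
})

test_that("the dominant structure uses strictly P > 0.5", {
  fake <- list(bpp = matrix(0, 10, 10))
  fake$bpp[1, 10] <- fake$bpp[10, 1] <- 0.5
  fake$bpp[2, 9] <- fake$bpp[9, 2] <- 0.5
  ds <- dominant_structures(fake)
  expect_equal(nrow(ds$dominant$pairs), 0)
})

test_that("two helix levels yield a dominant set and one alternative", {
  fake <- list(bpp = matrix(0, 12, 12))
  for (t in 0:2) {
    fake$bpp[1 + t, 12 - t] <- fake$bpp[12 - t, 1 + t] <- 0.7
    fake$bpp[4 + t, 9 - t] <- 0   # keep the alternative elsewhere
  }
  fake$bpp[2, 6] <- fake$bpp[6, 2] <- 0.28
  fake$bpp[3, 5] <- fake$bpp[5, 3] <- 0.28
  ds <- dominant_structures(fake)
  expect_equal(nrow(ds$dominant$pairs), 3)
  expect_equal(ds$dominant$probability, 0.7)
  expect_equal(length(ds$alternatives), 1)
  expect_equal(ds$alternatives[[1]]$probability, 0.28, tolerance = 1e-12)
})

test_that("every row of the probability matrix sums to at most one", {
  for (seed in 1:5) {
    s <- make_fixture("random", length = 30, seed = seed)$seq
    f <- fold_rna(s, pseudoknot = "junction1")
    expect_lt(max(rowSums(f$bpp)), 1 + 1e-12)
  }
})

test_that("pseudoknot modes nest as ensembles: Q(any) >= Q(junction1) >= Q(none)", {
  seqs <- c(as.character(make_fixture("pseudoknot", stem = 3, loop = 3)$seq),
            as.character(make_fixture("bistable")$seq),
            as.character(make_fixture("random", length = 24, seed = 3)$seq))
  for (s in seqs) {
    qn <- fold_rna(s, pseudoknot = "none")$Q
    qj <- fold_rna(s, pseudoknot = "junction1")$Q
    qa <- fold_rna(s, pseudoknot = "any")$Q
    expect_gte(qj, qn)
    expect_gte(qa, qj)
  }
  # a sequence that cannot form crossing helices gives identical Q
  s0 <- "GGGAAAACCC"
  expect_equal(fold_rna(s0, pseudoknot = "any")$Q,
               fold_rna(s0, pseudoknot = "none")$Q, tolerance = 1e-12)
})

test_that("pairing probabilities vanish monotonically past the last transition", {
  s <- make_fixture("hairpin", stem = 4, loop = 4)$seq
  peaks <- melting_curve(s, t_step = 1)$peaks
  t_last <- max(peaks$t_peak)
  temps <- seq(max(t_last + 5, 95), 140, by = 5)
  maxp <- vapply(temps, function(tc) max(fold_rna(s, temperature = tc)$bpp), 0)
  expect_true(all(diff(maxp) < 0))
  expect_lt(maxp[length(maxp)], 0.05)
})

test_that("the balanced bistable fixture has exactly symmetric helix sets", {
  fx <- make_fixture("bistable", balanced = TRUE)
  f <- fold_rna(fx$seq)
  pA <- mean(f$bpp[fx$structure])
  pB <- mean(f$bpp[fx$structure_alt])
  expect_gt(pA, 0.1)
  expect_lt(abs(pA - pB), 1e-6)
})

test_that("the feasibility limit for mode 'any' suggests alternatives", {
  s <- make_fixture("random", length = 70, seed = 5)$seq
  expect_error(fold_rna(s, pseudoknot = "any"), "junction1",
               class = "vfold_feasibility_error")
})

test_that("tidiers and plots expose the fold result", {
  f <- fold_rna("GGGAAAACCC")
  td <- tidy(f)
  expect_true(all(c("i", "j", "prob", "in_dominant") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n, 10)
  expect_s3_class(autoplot(f), "ggplot")
})
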