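test_that("a single hairpin decomposes into one helix and one loop", {
  m <- decompose_structure("GGGAAAACCC", "(((....)))")
  expect_setequal(m$kind, c("HELIX", "HAIRPIN_LOOP"))
  expect_true(motif_eligibility(m)$overall_supported)
})

test_that("two hairpins joined by a single strand expose an open motif", {
  m <- decompose_structure("GGGAAAACCCAAAGGGAAAACCC",
                           "(((....)))...(((....)))")
  counts <- table(m$kind)
  expect_equal(unname(counts["HELIX"]), 2)
  expect_equal(unname(counts["HAIRPIN_LOOP"]), 2)
  expect_equal(unname(counts["OPEN_MOTIF"]), 1)
  rep <- motif_eligibility(m)
  expect_false(rep$overall_supported)
  expect_true(any(grepl("tails", rep$recommendations)))
})

test_that("internal loops, bulges and tails are classified", {
  m <- decompose_structure("GGGAGGGAAAACCCACCC", "(((.(((....))).)))")
  expect_true("INTERNAL_LOOP" %in% m$kind)
  m2 <- decompose_structure("GGGAGGGAAAACCCCCC", "(((.(((....))))))")
  expect_true("BULGE" %in% m2$kind)
  m3 <- decompose_structure("AAGGGAAAACCCAA", "..(((....)))..")
  expect_equal(sum(m3$kind == "OPEN_MOTIF"), 2)
  rep <- motif_eligibility(m3)
  expect_false(rep$overall_supported)
})

test_that("junction branch counts gate template eligibility at 2 < N < 8", {
  hp <- "GCGAAAACGC"; hdb <- "(((....)))"
  clover <- function(k) {
    list(seq = paste0("GGGG", strrep(paste0("A", hp), k), "A", "CCCC"),
         db = paste0("((((", strrep(paste0(".", hdb), k), ".", "))))"))
  }
  c3 <- clover(2)
  m3 <- decompose_structure(c3$seq, c3$db)
  expect_equal(m3$branch_count[m3$kind == "NWAY_JUNCTION"], 3)
  expect_true(motif_eligibility(m3)$overall_supported)
  c8 <- clover(7)
  m8 <- decompose_structure(c8$seq, c8$db)
  expect_equal(m8$branch_count[m8$kind == "NWAY_JUNCTION"], 8)
  rep <- motif_eligibility(m8)
  expect_false(rep$overall_supported)
  expect_true(any(grepl("8 or more", rep$recommendations)))
})

test_that("crossing helices are reported as a pseudoknot motif", {
  fx <- make_fixture("pseudoknot", stem = 3, loop = 3)
  m <- decompose_structure(fx$seq, fx$structure)
  expect_true("PSEUDOKNOT" %in% m$kind)
  expect_true(motif_eligibility(m)$overall_supported)
})

test_that("every nucleotide belongs to at least one motif", {
  cases <- list(
    list("GGGAAAACCC", "(((....)))"),
    list("GGGAAAACCCAAAGGGAAAACCC", "(((....)))...(((....)))"),
    list("AAGGGAGGGAAAACCCCCCAA", "..(((.(((....))))))..")
  )
  for (cs in cases) {
    m <- decompose_structure(cs[[1]], cs[[2]])
    covered <- unlist(lapply(m$strands, function(ss)
      unlist(lapply(ss, function(s) if (s[2] >= s[1]) s[1]:s[2] else integer(0)))))
    expect_setequal(covered, seq_len(nchar(cs[[1]])))
  }
})

test_that("decomposition is invariant under 5'<->3' relabeling of a palindrome", {
  s <- "GGAAAACCAAAAGG"
  db <- "((....))......"
  m1 <- decompose_structure(s, db)
  # relabel: reverse the sequence and the structure
  s2 <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  pairs <- parse_dotbracket(db)
  n <- nchar(s)
  pairs2 <- cbind(n + 1 - pairs[, 2], n + 1 - pairs[, 1])
  m2 <- decompose_structure(s2, pairs2)
  expect_equal(sort(m1$kind), sort(m2$kind))
  expect_equal(sort(m1$branch_count), sort(m2$branch_count))
})

test_that("tail-free nested structures use only the closed motif vocabulary", {
  cases <- list(
    list("GGGAAAACCC", "(((....)))"),
    list("GGGAGGGAAAACCCACCC", "(((.(((....))).)))")
  )
  for (cs in cases) {
    m <- decompose_structure(cs[[1]], cs[[2]])
    expect_true(all(m$kind %in% c("HELIX", "HAIRPIN_LOOP", "INTERNAL_LOOP",
                                  "BULGE", "NWAY_JUNCTION")))
  }
})
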