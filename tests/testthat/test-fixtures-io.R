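test_that("fixture construction is deterministic and annotated structures are valid", {
  expect_identical(as.character(make_fixture("hairpin", stem = 3, loop = 4)$seq),
                   "GCGAAAACGC")
  r1 <- make_fixture("random", length = 25, seed = 42)
  r2 <- make_fixture("random", length = 25, seed = 42)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  r3 <- make_fixture("random", length = 25, seed = 43)
  expect_false(identical(as.character(r1$seq), as.character(r3$seq)))
  for (fx in list(make_fixture("hairpin"), make_fixture("bistable"),
                  make_fixture("bistable", balanced = TRUE),
                  make_fixture("pseudoknot", stem = 3, loop = 3))) {
    expect_silent(validate_structure(fx$seq, fx$structure))
  }
})

test_that("impossible fixture sizes are rejected", {
  expect_error(make_fixture("hairpin", stem = 1), class = "vfold_generation_error")
  expect_error(make_fixture("hairpin", loop = 2), class = "vfold_generation_error")
  expect_error(make_fixture("pseudoknot", stem = 1),
               class = "vfold_generation_error")
})

test_that("sequence reading folds case and normalizes the DNA alphabet", {
  expect_identical(as.character(suppressMessages(rna_sequence("acgu"))), "ACGU")
  expect_message(s <- rna_sequence("ACGT"), "T to U")
  expect_identical(as.character(s), "ACGU")
  expect_error(rna_sequence("ACGX"), "position 4", class = "vfold_parse_error")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy hairpin", "GGGAAAA", "CCC"), fa)
  expect_identical(as.character(read_rna(fa)), "GGGAAAACCC")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("ggcaaaagcc", txt)
  expect_identical(as.character(read_rna(txt)), "GGCAAAAGCC")
})

test_that("sequences beyond the length limit need an explicit override", {
  long <- strrep("A", 150)
  expect_error(rna_sequence(long), class = "vfold_length_error")
  expect_warning(s <- rna_sequence(long, allow_long = TRUE), "150")
  expect_equal(attr(s, "n"), 150)
})

test_that("dot-bracket parsing handles pseudoknot layers and errors", {
  p <- parse_dotbracket("((..[[..))..]]")
  expect_equal(nrow(p), 4)
  expect_true(all(c("1,10", "2,9", "5,14", "6,13") %in%
                    paste(p[, 1], p[, 2], sep = ",")))
  expect_error(parse_dotbracket("((..)"), class = "vfold_parse_error")
  expect_error(parse_dotbracket("((.x))"), class = "vfold_parse_error")
  fx <- make_fixture("pseudoknot", stem = 3, loop = 3)
  db <- pairs_to_dotbracket(fx$structure, attr(fx$seq, "n"))
  expect_true(grepl("\\[", db))
  back <- parse_dotbracket(db)
  expect_equal(back[order(back[, 1]), ], fx$structure[order(fx$structure[, 1]), ])
})

test_that("CT files round-trip the pair set exactly", {
  fx <- make_fixture("bistable")
  ct <- withr::local_tempfile(fileext = ".ct")
  write_ct(fx$seq, fx$structure, ct)
  back <- read_ct(ct)
  expect_identical(as.character(back$seq), as.character(fx$seq))
  expect_equal(back$pairs, fx$structure)
})

test_that("the three 2D output files and the melting text round-trip byte-identically", {
  f <- fold_rna(make_fixture("bistable")$seq)
  tmp <- withr::local_tempdir()
  bpp1 <- file.path(tmp, "bpp1.txt"); bpp2 <- file.path(tmp, "bpp2.txt")
  write_bpp(f, bpp1)
  tab <- read_bpp(bpp1)
  write_bpp(local({
    m <- matrix(0, f$n, f$n)
    m[cbind(tab$i, tab$j)] <- tab$prob
    m + t(m)
  }), bpp2)
  expect_identical(readBin(bpp1, "raw", file.size(bpp1)),
                   readBin(bpp2, "raw", file.size(bpp2)))

  hel1 <- file.path(tmp, "h1.txt"); hel2 <- file.path(tmp, "h2.txt")
  write_helices(f, hel1)
  write_helices(read_helices(hel1), hel2)
  expect_identical(readLines(hel1), readLines(hel2))

  st <- file.path(tmp, "structures.txt")
  write_structure(f, st, ct_path = file.path(tmp, "dom.ct"))
  lines <- readLines(st)
  expect_true(any(grepl("dominant", lines)))
  dom_db <- strsplit(lines[2], " ")[[1]][1]
  expect_equal(parse_dotbracket(dom_db), f$dominant$pairs)

  m <- melting_curve(make_fixture("hairpin")$seq, t_step = 5)
  mel1 <- file.path(tmp, "m1.txt"); mel2 <- file.path(tmp, "m2.txt")
  write_melting(m, mel1, lnq_path = file.path(tmp, "lnq.txt"))
  back <- read_melting(mel1)
  back$lnQ <- NA
  write_melting(tibble::tibble(temperature = back$temperature,
                               lnQ = 0, C = back$C), mel2)
  expect_identical(readLines(mel1), readLines(mel2))
})

test_that("writers emit identical bytes for identical input", {
  f <- fold_rna("GGCAAAAGCC")
  tmp <- withr::local_tempdir()
  a <- file.path(tmp, "a.txt"); b <- file.path(tmp, "b.txt")
  write_bpp(f, a); write_bpp(f, b)
  expect_identical(readLines(a), readLines(b))
})

test_that("configuration files accept only known keys", {
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("temperature: 25", "params: mfold23", "pseudoknot: none"), cfg)
  got <- read_config(cfg)
  expect_equal(got$temperature, 25)
  expect_equal(got$params, "mfold23")
  writeLines(c("temprature: 25"), cfg)
  expect_error(read_config(cfg), "temprature", class = "vfold_parse_error")
})
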