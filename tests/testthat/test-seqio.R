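test_that("FASTA reading parses records in order and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$seq, "ACGT")

  writeLines(c(">a desc", "acg", "t", ">b", "AC"), f)
  recs <- read_fasta(f)
  expect_equal(vapply(recs, `[[`, "", "id"), c("a", "b"))
  expect_equal(recs[[1]]$seq, "ACGT")  # upcased, lines joined
  expect_equal(nchar(recs[[2]]$seq), 2L)  # unequal lengths fine here

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "FASTA")
  writeLines(c(">x", "ACGQ"), f)
  expect_error(read_fasta(f), "invalid characters")
})

test_that("FASTA write/read round-trips, wrapping at 70 columns", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- stats::setNames(c(paste(rep("ACGT", 40), collapse = ""), "AC-T"),
                          c("long", "short"))
  write_fasta(seqs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 70L))
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "seq"), unname(seqs))
})

test_that("alignment loader enforces rectangular rows and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-T", ">b", "ACGT"), f)
  aln <- read_alignment(f)
  expect_equal(dim(aln), c(2L, 4L))
  expect_equal(unname(aln["a", 3L]), "-")

  writeLines(c(">a", "AC-T", ">b", "ACGTT"), f)
  expect_error(read_alignment(f), "unequal row lengths.*a.*4")

  # 29-row simulated alignment round-trips through write+read unchanged
  tr <- ape::rtree(29, br = 0.02)
  aln <- simulate_alignment(tr, 180, seed = 7)
  write_alignment(aln, f)
  expect_identical(read_alignment(f), aln)
})

test_that("GenBank coordinates convert at the boundary and round-trip", {
  gb <- withr::local_tempfile(fileext = ".gb")
  p0 <- plastome(
    seq_record("tst", paste(rep("ACGT", 30), collapse = ""), circular = TRUE),
    feature_table(name = c("gA", "gB", "gC", "gC", "psX"),
                  kind = c("PCG", "tRNA", "rRNA", "rRNA", "pseudogene"),
                  start = c(9L, 30L, 50L, 70L, 100L),
                  end = c(20L, 40L, 60L, 80L, 110L),
                  strand = c("+", "-", "+", "+", "+"),
                  copy = c(1L, 2L, 3L, 3L, 4L),
                  part = c(1L, 1L, 1L, 2L, 1L)))
  write_genbank(p0, gb)
  txt <- readLines(gb)
  expect_true(any(grepl("10\\.\\.20", txt)))              # 0-based 9 -> 10
  expect_true(any(grepl("complement\\(31\\.\\.40\\)", txt)))
  expect_true(any(grepl("join\\(51\\.\\.60,71\\.\\.80\\)", txt)))
  p1 <- read_genbank(gb)
  expect_equal(p1$record$seq, p0$record$seq)
  expect_true(p1$record$circular)
  cols <- c("name", "kind", "start", "end", "strand", "part")
  expect_equal(p1$features[, cols], p0$features[, cols],
               ignore_attr = TRUE)
})

test_that("GenBank parser converts the documented coordinate examples", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       demo 40 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             10..20",
    '                     /gene="fwd"',
    "     CDS             complement(5..8)",
    '                     /gene="rev"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//"), gb)
  p <- read_genbank(gb)
  fwd <- p$features[p$features$name == "fwd", ]
  rev <- p$features[p$features$name == "rev", ]
  expect_equal(c(fwd$start, fwd$end, fwd$strand), c("9", "20", "+"))
  expect_equal(c(rev$start, rev$end, rev$strand), c("4", "8", "-"))
})

test_that("malformed GenBank locations error with the feature name", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       demo 20 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..x20",
    '                     /gene="broken"',
    "ORIGIN",
    "        1 acgtacgtac acgtacgtac",
    "//"), gb)
  expect_error(read_genbank(gb), "broken")
})

test_that("simulator GenBank output parses back to the truth feature table", {
  sim <- simulate_plastome_set(default_sim_config(11))
  gb <- withr::local_tempfile(fileext = ".gb")
  tx <- "IV2"
  write_genbank(sim$plastomes[[tx]], gb)
  back <- read_genbank(gb)
  cols <- c("name", "kind", "start", "end", "strand")
  expect_equal(back$features[, cols], sim$plastomes[[tx]]$features[, cols],
               ignore_attr = TRUE)
  expect_equal(back$record$seq, sim$plastomes[[tx]]$record$seq)
})

test_that("label sanitization is reversible and collision-free", {
  labs <- c("Taxillus chinensis A", "Taxillus_chinensis(A)", "T. tsaii")
  map <- sanitize_labels(labs)
  expect_false(any(grepl("[ (),;:]", map$sanitized)))
  expect_false(anyDuplicated(map$sanitized) > 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_label_map(map, f)
  expect_equal(read_label_map(f), map)
})
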