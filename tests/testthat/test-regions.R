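test_that("gene extraction honors strand and exon order", {
  p <- toy_plastome()
  s <- p$record$seq
  # plus-strand single exon
  expect_equal(extract_gene(p, "geneA")$seq, substr(s, 1, 12))
  # minus strand: reverse complement of the slice
  expect_equal(extract_gene(p, "geneB")$seq, revcomp(substr(s, 25, 36)))
  # two-exon join: exon1 + exon2
  expect_equal(extract_gene(p, "geneC")$seq,
               paste0(substr(s, 41, 44), substr(s, 49, 54)))
  expect_error(extract_gene(p, "nope"), "geneA.*geneB.*geneC")
})

test_that("pseudogene-flagged features warn but extract", {
  p <- toy_plastome()
  p$features$kind[p$features$name == "geneA"] <- "pseudogene"
  expect_warning(rec <- extract_gene(p, "geneA"), "pseudogene")
  expect_equal(rec$seq, substr(p$record$seq, 1, 12))
})

test_that("IGS extraction is strictly between flanks and wraps the origin", {
  n <- 400L
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  p <- plastome(seq_record("c", s, circular = TRUE),
                feature_table(name = c("L", "R", "W"), kind = "PCG",
                              start = c(60L, 150L, n - 30L),
                              end = c(100L, 200L, n - 10L)))
  # left ends at 100, right starts at 150 -> 50 bp slice
  igs <- extract_igs(p, "L", "R")
  expect_equal(igs$seq, substr(s, 101, 150))
  expect_equal(nchar(igs$seq), 50L)
  # wrap-around: left ends at n-10, right starts at 5
  p2 <- plastome(seq_record("c", s, circular = TRUE),
                 feature_table(name = c("W", "E"), kind = "PCG",
                               start = c(n - 30L, 5L), end = c(n - 10L, 40L)))
  igs2 <- extract_igs(p2, "W", "E")
  expect_equal(nchar(igs2$seq), 15L)
  expect_equal(igs2$seq, paste0(substr(s, n - 9, n), substr(s, 1, 5)))
  # conservation on the circle: spacer + flanks + remaining arc = genome
  arc_back <- nchar(extract_igs(p2, "E", "W")$seq)
  expect_equal(15L + 20L + 35L + arc_back, n)
  # overlapping flanks error
  p3 <- plastome(seq_record("c", s, circular = TRUE),
                 feature_table(name = c("A", "B"), kind = "PCG",
                               start = c(10L, 30L), end = c(50L, 80L)))
  expect_error(extract_igs(p3, "A", "B"), "overlap")
})

test_that("planted regions are recovered exactly from simulated plastomes", {
  sim <- simulate_plastome_set(default_sim_config(5))
  alns <- sim$truth$alignments
  for (tx in c("I2", "SC1", "CH3")) {
    p <- sim$plastomes[[tx]]
    expect_equal(extract_gene(p, "accD")$seq,
                 paste(alns[["accD"]][tx, ], collapse = ""))
    expect_equal(extract_igs(p, "trnL", "trnF")$seq,
                 paste(alns[["trnL-trnF"]][tx, ], collapse = ""))
    expect_equal(extract_igs(p, "rpl14", "rps3")$seq,
                 paste(alns[["rpl14-rps3"]][tx, ], collapse = ""))
  }
})

test_that("shared-region sets drop regions missing in any taxon, with report", {
  sim <- simulate_plastome_set(default_sim_config(6))
  specs <- list(region_spec("accD", "gene"),
                region_spec("trnH-psbA", "igs", c("trnH", "psbA")),
                region_spec("infA", "gene"),
                region_spec("rbcL+accD", "concat", c("rbcL", "accD")))
  rs <- build_region_set(sim$plastomes, specs)
  # accD present everywhere
  expect_true("accD" %in% names(rs$regions))
  expect_length(rs$regions[["accD"]], 32L)
  # trnH lost in I1 -> trnH-psbA dropped, reported for that taxon
  expect_false("trnH-psbA" %in% names(rs$regions))
  expect_true(any(rs$dropped$region == "trnH-psbA" & rs$dropped$taxon == "I1"))
  # infA lost on the outgroup stem and in I1
  expect_false("infA" %in% names(rs$regions))
  expect_setequal(rs$dropped$taxon[rs$dropped$region == "infA"],
                  c("SC1", "SC2", "SC3", "I1"))
  # concat = member concatenation
  expect_equal(rs$regions[["rbcL+accD"]][["II1"]],
               paste0(paste(sim$truth$alignments[["rbcL"]]["II1", ],
                            collapse = ""),
                      paste(sim$truth$alignments[["accD"]]["II1", ],
                            collapse = "")))
})

test_that("region spec TSV round-trips", {
  specs <- list(region_spec("accD", "gene"),
                region_spec("trnL-trnF", "igs", c("trnL", "trnF")),
                region_spec("rbcL+accD", "concat", c("rbcL", "accD")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_specs(specs, f)
  back <- read_region_specs(f)
  expect_equal(back, specs)
})

test_that("concatenation appends columns, records partitions, is additive", {
  a <- as_alignment(c(x = "ACG", y = "ACA"))
  b <- as_alignment(c(y = "TTTT", x = "TTGA"))
  cc <- concatenate_alignments(list(A = a, B = b))
  expect_equal(dim(cc), c(2L, 7L))
  expect_equal(attr(cc, "partitions")$end, c(3L, 7L))
  expect_equal(paste(cc["y", ], collapse = ""), "ACATTTT")  # row matching
  # identity: concatenation with an empty alignment
  e <- a[, 0, drop = FALSE]
  expect_equal(unclass(concatenate_alignments(list(a, e)))[, 1:3], a,
               ignore_attr = TRUE)
  # taxon mismatch names the difference
  z <- as_alignment(c(x = "AA", q = "CC"))
  expect_error(concatenate_alignments(list(a, z)), "q")
  # PI count of concat = sum of member PI counts (direct recount oracle)
  m1 <- random_alignment(6, 40, seed = 21)
  m2 <- random_alignment(6, 25, seed = 22)
  cc2 <- concatenate_alignments(list(m1, m2))
  expect_equal(site_classes(cc2)$parsimony_informative,
               oracle_site_classes(m1)$parsimony_informative +
                 oracle_site_classes(m2)$parsimony_informative)
})
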