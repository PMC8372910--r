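test_that("parsimony event mapping handles the canonical patterns", {
  t <- root_with_outgroup(read_newick("((A,B),(C,D));"), "A")
  pm <- matrix("intact", 4, 3,
               dimnames = list(c("A", "B", "C", "D"), c("g1", "g2", "g3")))
  pm[c("C", "D"), "g1"] <- "absent"     # single loss on the CD stem
  pm[c("B", "D"), "g3"] <- "absent"     # two independent losses
  em <- map_events(t, pm, outgroup = "A")
  # g1: one loss on the stem of {C,D}
  ev1 <- em$events[em$events$gene == "g1", ]
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$tips_under_branch, "C;D")
  expect_equal(c(ev1$from, ev1$to), c("intact", "absent"))
  # g2 intact everywhere: no events
  expect_equal(em$changes_per_gene[["g2"]], 0L)
  expect_false(any(em$events$gene == "g2"))
  # g3: absent in non-sisters B and D -> two tip-branch events (DELTRAN)
  ev3 <- em$events[em$events$gene == "g3", ]
  expect_equal(nrow(ev3), 2L)
  expect_setequal(ev3$tips_under_branch, c("B", "D"))
  expect_error(map_events(ape::drop.tip(t, "A"), pm[-1, , drop = FALSE]),
               NA)
  expect_error(map_events(t, pm[-1, , drop = FALSE]), "A")
})

test_that("event counts equal the exhaustive-enumeration minimum", {
  states <- c("intact", "pseudogene", "absent")
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:7, 1)
    t <- ape::rtree(n)
    og <- t$tip.label[[1]]
    pm <- matrix(sample(states, n * 3, replace = TRUE,
                        prob = c(0.5, 0.25, 0.25)), n, 3,
                 dimnames = list(t$tip.label, paste0("g", 1:3)))
    em <- map_events(t, pm, outgroup = og)
    for (g in colnames(pm)) {
      root_state <- if (pm[og, g] == "intact") 1L else NULL
      expect_equal(em$changes_per_gene[[g]],
                   oracle_fitch_min(t, pm[, g], root_state),
                   info = paste("seed", seed, g))
    }
  }
})

test_that("presence matrix TSV round-trips", {
  pm <- matrix(c("intact", "pseudogene", "absent", "intact"), 2, 2,
               dimnames = list(c("t1", "t2"), c("gA", "gB")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(pm, f)
  expect_equal(read_presence_matrix(f), pm)
})

test_that("planted IRs are located exactly", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  # 5 kb + 2 kb repeat + 1 kb + revcomp(repeat); blocker bases stop chance
  # extension of the maximal match at the inner boundaries
  R <- rand(2000)
  mid <- paste0("CC", rand(996), "AA")
  g <- paste0(rand(5000), R, mid, revcomp(R))
  ir <- find_ir(seq_record("toy", g, circular = TRUE), min_len = 1000)
  expect_equal(unname(ir$LSC), c(0L, 5000L))
  expect_equal(unname(ir$IRb), c(5000L, 7000L))
  expect_equal(unname(ir$SSC), c(7000L, 8000L))
  expect_equal(unname(ir$IRa), c(8000L, 10000L))
  expect_equal(ir$ir_length, 2000L)
  expect_equal(ir$origin_offset, 0L)
  # extending the repeat by one matching base shifts the boundary by one
  g2 <- paste0(rand(5000), R, "G", "CC", rand(993), "AA", "C", revcomp(R))
  ir2 <- find_ir(seq_record("toy", g2, circular = TRUE), min_len = 1000)
  expect_equal(ir2$ir_length, 2001L)
  expect_equal(unname(ir2$IRb), c(5000L, 7001L))
  # no long inverted repeat -> error
  expect_error(find_ir(seq_record("r", rand(6000), circular = TRUE),
                       min_len = 1000), "no IR detected")
})

test_that("IR invariants hold on simulated plastomes", {
  sim <- simulate_plastome_set(default_sim_config(23))
  for (tx in c("I1", "SC2")) {
    p <- sim$plastomes[[tx]]
    ir <- find_ir(p, min_len = 1000)
    tr <- sim$truth$ir[[tx]]
    expect_equal(unname(ir$IRb), tr$IRb)
    expect_equal(unname(ir$IRa), tr$IRa)
    # IRa is exactly the reverse complement of IRb
    expect_identical(ir_span_seq(p, ir, "IRa"),
                     revcomp(ir_span_seq(p, ir, "IRb")))
    # the four spans tile the genome
    lens <- c(diff(ir$LSC), diff(ir$IRb), diff(ir$SSC), diff(ir$IRa))
    expect_equal(sum(lens), nchar(p$record$seq))
  }
})

test_that("junction genes are reported with offsets, origin wrap included", {
  set.seed(19)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  R <- rand(1200)
  g <- paste0(rand(3000), R, paste0("CC", rand(796), "AA"), revcomp(R))
  n <- nchar(g)
  ft <- feature_table(
    name = c("rpl2", "ycf1", "ori"),
    kind = c("PCG", "PCG", "PCG"),
    # rpl2 straddles LSC/IRb at 3000; ycf1 straddles SSC/IRa at 5000
    start = c(2900L, 4900L, 0L), end = c(3100L, 5100L, 50L),
    strand = c("+", "+", "+"))
  # add a two-part feature crossing the origin (IRa/LSC junction at 0)
  ft2 <- rbind(ft, data.frame(name = "wrap", kind = "PCG",
                              start = c(n - 30L, 0L), end = c(n, 20L),
                              strand = "+", copy = 99L, part = c(1L, 2L)))
  p <- plastome(seq_record("jx", g, circular = TRUE),
                feature_table(ft2$name, ft2$kind, ft2$start, ft2$end,
                              ft2$strand, ft2$copy, ft2$part))
  ir <- find_ir(p, min_len = 1000)
  jg <- junction_genes(p, ir)
  expect_equal(jg$name[jg$junction == "LSC/IRb"], "rpl2")
  expect_equal(jg$offset[jg$junction == "LSC/IRb"], 100L)
  expect_equal(jg$name[jg$junction == "SSC/IRa"], "ycf1")
  expect_equal(jg$name[jg$junction == "IRa/LSC"], "wrap")
  expect_equal(jg$offset[jg$junction == "IRa/LSC"], 30L)
  # IRb/SSC junction falls in intergenic space -> no rows
  expect_false("IRb/SSC" %in% jg$junction)
})
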