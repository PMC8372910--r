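test_that("Newick parse/write round-trips on canonical form", {
  t <- read_newick("((A,B),(C,D));")
  expect_equal(sort(t$tip.label), c("A", "B", "C", "D"))
  txt <- write_newick(t)
  expect_identical(write_newick(read_newick(txt)), txt)
  # child order canonicalization: rotations serialize identically
  expect_identical(write_newick(read_newick("((D,C),(B,A));")), txt)
  # support values and branch lengths survive
  t2 <- read_newick("((A:0.1,B:0.2)100:0.01,C:0.3);")
  out <- write_newick(t2)
  expect_match(out, "\\)100:0.01")
  expect_match(out, "A:0.1")
  expect_error(read_newick("((A,B,(C;"), "invalid Newick")
  expect_error(read_newick("((A,B),(A,C));"), "duplicate leaf")
})

test_that("NJ solves the 3-taxon star exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t <- neighbor_joining(d)
  # closed form: la = (dab+dac-dbc)/2 = 1, lb = 2, lc = 3
  el <- stats::setNames(t$edge.length, t$tip.label[t$edge[, 2]])
  expect_equal(el[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("NJ recovers additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) -> split AB|CD with exact path lengths
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5; d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6; d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  t <- neighbor_joining(d)
  expect_true("A|B" %in% tree_splits(t) || "C|D" %in% tree_splits(t))
  expect_equal(as.matrix(stats::cophenetic(t))[rownames(d), rownames(d)], d)
  dm_na <- d; dm_na[1, 2] <- dm_na[2, 1] <- NA
  expect_error(neighbor_joining(dm_na), "undefined")
})

test_that("NJ equals the least-squares-best enumerated topology (n=5)", {
  topos <- enumerate_topologies(c("a", "b", "c", "d", "e"))
  expect_length(topos, 15L)
  for (seed in 1:4) {
    set.seed(seed)
    true <- ape::rtree(5, tip.label = c("a", "b", "c", "d", "e"))
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 1)
    dm <- as.matrix(stats::cophenetic(true))
    nj <- neighbor_joining(dm)
    res <- vapply(topos, ols_residual, 0, dm = dm)
    best <- topos[[which.min(res)]]
    expect_equal(rf_distance(nj, best), 0L)
    expect_equal(rf_distance(nj, true), 0L)
    expect_setequal(nj$tip.label, true$tip.label)  # leaf conservation
  }
})

test_that("outgroup rooting behaves and is idempotent", {
  t <- read_newick("((A,B),(C,O));")
  r <- root_with_outgroup(t, "O")
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  expect_true(match("O", r$tip.label) %in% kids)
  expect_true(is_monophyletic(r, c("A", "B", "C")))
  # invariant to input rotation
  r2 <- root_with_outgroup(read_newick("((O,C),(B,A));"), "O")
  expect_identical(write_newick(r2), write_newick(r))
  # rerooting twice is idempotent on random trees
  for (seed in 1:5) {
    set.seed(seed)
    rt <- ape::rtree(8)
    og <- sample(rt$tip.label, 1)
    r1 <- root_with_outgroup(rt, og)
    expect_identical(write_newick(root_with_outgroup(r1, og)),
                     write_newick(r1))
  }
  expect_error(root_with_outgroup(t, "Z"), "unknown taxon")
  # non-separable multi-taxon outgroup
  expect_error(root_with_outgroup(read_newick("((A,O1),(O2,B));"),
                                  c("O1", "O2")), "not monophyletic")
})

test_that("monophyly matches the MRCA oracle exhaustively", {
  t <- root_with_outgroup(read_newick("((A,B),(C,D));"), "D")
  expect_true(is_monophyletic(t, c("A", "B")))
  expect_false(is_monophyletic(t, c("A", "C")))
  expect_error(is_monophyletic(t, c("A", "Z")), "Z")
  for (seed in 1:6) {
    set.seed(seed)
    rt <- ape::rtree(5)
    subsets <- unlist(lapply(1:4, function(k)
      utils::combn(rt$tip.label, k, simplify = FALSE)), recursive = FALSE)
    for (s in subsets)
      expect_equal(is_monophyletic(rt, s), oracle_monophyletic(rt, s),
                   info = paste(seed, paste(s, collapse = ",")))
  }
})

test_that("RF distance agrees with ape and with itself", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    expect_equal(rf_distance(t1, t1), 0L)
    expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
    expect_equal(rf_distance(t1, t2),
                 as.integer(ape::dist.topo(ape::unroot(t1),
                                           ape::unroot(t2))))
  }
  expect_error(rf_distance(ape::rtree(4), ape::rtree(5)), "leaf sets")
})

test_that("backbone matching collapses clades and compares topologies", {
  cl <- paired_clade_def()
  ref <- paired_clade_tree("(((I,II),III),IV)")
  expect_true(backbone_match(ref, ref, cl))
  # clades intact but backbone rearranged -> no match
  alt <- paired_clade_tree("((I,(II,III)),IV)")
  expect_false(backbone_match(alt, ref, cl))
  # one clade broken -> false regardless of backbone: exchange II2 and III1
  tl <- ref$tip.label
  swapped <- ref
  swapped$tip.label[match(c("II2", "III1"), tl)] <- c("III1", "II2")
  expect_false(backbone_match(swapped, ref, cl))
  # reference inconsistent with the clades is an error
  expect_error(backbone_match(ref, swapped, cl), "reference")
  expect_error(backbone_match(ape::drop.tip(ref, "I1"), ref, cl),
               "missing taxa: I1")
})
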