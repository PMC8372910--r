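# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity from first principles (or from ape, which never
# serves as the checked path), so the package implementation is tested
# against a second route.

random_alignment <- function(n, L, seed, gap_frac = 0, amb_frac = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (gap_frac > 0) m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  if (amb_frac > 0) m[sample(length(m), round(amb_frac * length(m)))] <- "N"
  rownames(m) <- paste0("t", seq_len(n))
  m
}

# low-divergence alignment: rows are independent mutations of one ancestor,
# so corrected distances stay well below saturation
similar_alignment <- function(n, L, seed, p = 0.1, gap_frac = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  root <- sample(pool, L, replace = TRUE)
  m <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- root
    mut <- stats::runif(L) < p
    x[mut] <- sample(pool, sum(mut), replace = TRUE)
    x
  }))
  if (gap_frac > 0) m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  rownames(m) <- paste0("t", seq_len(n))
  m
}

# pi by literal pair-by-pair recount
oracle_pi <- function(aln) {
  n <- nrow(aln); tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- aln[i, ]; b <- aln[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!sum(ok)) next
    tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
    np <- np + 1
  }
  if (np == 0) stop("no comparable sites")
  tot / np
}

oracle_site_classes <- function(aln) {
  pi_n <- 0; var_n <- 0; inv_n <- 0; empty_n <- 0
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j][aln[, j] %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) == 0) empty_n <- empty_n + 1
    else if (length(tab) == 1) inv_n <- inv_n + 1
    else {
      var_n <- var_n + 1
      if (sum(tab >= 2) >= 2) pi_n <- pi_n + 1
    }
  }
  list(invariant = inv_n, variable = var_n, parsimony_informative = pi_n,
       gap_or_ambiguous_only = empty_n)
}

oracle_k2p <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  pur <- c("A", "G")
  ts <- sum(a != b & (a %in% pur) == (b %in% pur))
  tv <- sum(a != b) - ts
  -0.5 * log(1 - 2 * ts / n - tv / n) - 0.25 * log(1 - 2 * tv / n)
}

# monophyly via ape's MRCA machinery
oracle_monophyletic <- function(tree, taxa) {
  if (length(taxa) <= 1) return(TRUE)
  mrca <- ape::getMRCA(tree, taxa)
  clade <- ape::extract.clade(tree, mrca)
  setequal(clade$tip.label, taxa)
}

# minimum 3-state parsimony changes by exhaustive internal-state enumeration
oracle_fitch_min <- function(tree, states, root_state = NULL) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[[1]]
  best <- Inf
  grid <- expand.grid(rep(list(1:3), length(internal)))
  for (r in seq_len(nrow(grid))) {
    assign <- integer(ntip + tree$Nnode)
    assign[internal] <- as.integer(grid[r, ])
    assign[seq_len(ntip)] <-
      match(states[tree$tip.label], c("intact", "pseudogene", "absent"))
    if (!is.null(root_state) && assign[root] != root_state) next
    ch <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# all unrooted topologies on a label set, by sequential leaf addition
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  base <- sprintf("(%s,%s,%s);", labels[1], labels[2], labels[3])
  trees <- list(ape::read.tree(text = base))
  for (k in seq_along(labels)[-(1:3)]) {
    nxt <- list()
    for (t in trees) {
      for (e in seq_len(nrow(t$edge))) {
        t2 <- suppressWarnings(
          ape::bind.tree(t, ape::read.tree(text = sprintf("(%s:1);",
                                                          labels[k])),
                         where = t$edge[e, 2], position = 0.5))
        t2$edge.length <- NULL
        nxt[[length(nxt) + 1]] <- ape::unroot(t2)
      }
    }
    trees <- nxt
  }
  trees
}

# ordinary least-squares fit of a distance matrix on a fixed topology
ols_residual <- function(topo, dm) {
  topo$edge.length <- rep(1, nrow(topo$edge))
  labs <- rownames(dm)
  pairs <- utils::combn(labs, 2)
  # design matrix: which edges lie on the path between each pair
  X <- matrix(0, ncol(pairs), nrow(topo$edge))
  ntip <- length(topo$tip.label)
  paths <- ape::nodepath(topo)
  for (p in seq_len(ncol(pairs))) {
    i <- match(pairs[1, p], topo$tip.label)
    j <- match(pairs[2, p], topo$tip.label)
    np <- ape::nodepath(topo, i, j)
    eidx <- vapply(seq_len(length(np) - 1), function(q) {
      which((topo$edge[, 1] == np[q] & topo$edge[, 2] == np[q + 1]) |
              (topo$edge[, 2] == np[q] & topo$edge[, 1] == np[q + 1]))
    }, 0L)
    X[p, eidx] <- 1
  }
  y <- dm[cbind(pairs[1, ], pairs[2, ])]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# small rooted "study-shaped" trees for scoring tests: five 2-taxon clades
paired_clade_tree <- function(backbone = "(((I,II),III),IV)") {
  expand <- function(txt) {
    for (nm in c("I", "II", "III", "IV", "S"))
      txt <- gsub(paste0("\\b", nm, "\\b"),
                  sprintf("(%s1:0.01,%s2:0.01):0.05", nm, nm), txt)
    txt
  }
  ape::read.tree(text = sprintf("(%s:0.05,(CH1:0.02,%s:0.02):0.05);",
                                expand("S"), expand(backbone)))
}

paired_clade_def <- function() {
  clade_definition(
    clades = list(I = c("I1", "I2"), II = c("II1", "II2"),
                  III = c("III1", "III2"), IV = c("IV1", "IV2"),
                  Scurrula = c("S1", "S2")),
    outgroup = c("S1", "S2"), excluded = "CH1")
}

toy_plastome <- function() {
  # 60 bp circular toy genome with known features
  s <- paste0("AAACCCGGGTTT", "ACGTACGTACGT", "TTTGGGCCCAAA",
              "ACACACACACAC", "GTGTGTGTGTGT")
  ft <- feature_table(
    name = c("geneA", "geneB", "geneC", "geneC"),
    kind = c("PCG", "PCG", "PCG", "PCG"),
    start = c(0L, 24L, 40L, 48L), end = c(12L, 36L, 44L, 54L),
    strand = c("+", "-", "+", "+"),
    copy = c(1L, 2L, 3L, 3L), part = c(1L, 1L, 1L, 2L))
  plastome(seq_record("toy", s, circular = TRUE), ft)
}
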