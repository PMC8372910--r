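# Plastome-set simulator with known truth: sequence evolution under the
# Kimura two-parameter model, quadripartite genome assembly with planted gene
# losses, and a ready-to-run benchmark fixture.

.k2p_change_probs <- function(d, kappa) {
  # probability of a transition (P) and of all transversions (Q) after
  # d expected substitutions/site under the two-parameter model
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Q <- 0.5 - 0.5 * exp(-4 * beta * d)
  c(P = P, Q = Q)
}

#' Expected proportion of differing sites after a given divergence
#'
#' Closed form under the two-parameter model; used as the analytic truth for
#' π-recovery checks.
#'
#' @param d Path length in expected substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @return Expected per-site difference probability.
#' @export
expected_site_difference <- function(d, kappa = 2) {
  pq <- vapply(d, .k2p_change_probs, c(P = 0, Q = 0), kappa = kappa)
  unname(pq["P", ] + pq["Q", ])
}

#' Expected nucleotide diversity of sequences evolved along a tree
#'
#' Mean over unordered tip pairs of the expected per-site difference at their
#' path length (scaled by `rate_mult`).
#'
#' @param tree `phylo` tree with branch lengths.
#' @param kappa Transition/transversion rate ratio.
#' @param rate_mult Region rate multiplier.
#' @return Expected π.
#' @export
expected_pi <- function(tree, kappa = 2, rate_mult = 1) {
  d <- stats::cophenetic(tree) * rate_mult
  mean(expected_site_difference(d[lower.tri(d)], kappa))
}

.evolve_seq <- function(parent, d, kappa) {
  # parent: integer vector over 1..4 = A,C,G,T; returns child vector
  if (d <= 0) return(parent)
  pq <- .k2p_change_probs(d, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)            # A<->G, C<->T
  tv_partners <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
  child <- parent
  u <- stats::runif(length(parent))
  mut_ts <- u < pq[["P"]]
  mut_tv1 <- !mut_ts & u < pq[["P"]] + pq[["Q"]] / 2
  mut_tv2 <- !mut_ts & !mut_tv1 & u < pq[["P"]] + pq[["Q"]]
  child[mut_ts] <- ts_partner[parent[mut_ts]]
  for (b in 1:4) {
    child[mut_tv1 & parent == b] <- tv_partners[[b]][[1]]
    child[mut_tv2 & parent == b] <- tv_partners[[b]][[2]]
  }
  child
}

#' Simulate an ungapped alignment along a tree
#'
#' The root sequence is drawn uniformly over A,C,G,T and evolved independently
#' down the tree under the Kimura two-parameter rate matrix, with each branch
#' contributing `branch length * rate_mult` expected substitutions per site.
#' Deterministic given `seed`.
#'
#' @param tree `phylo` tree with branch lengths (substitutions/site).
#' @param length Number of sites.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param rate_mult Rate multiplier applied to every branch (default 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Character matrix alignment (tips x sites).
#' @export
simulate_alignment <- function(tree, length, kappa = 2, rate_mult = 1,
                               seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- base::length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[[1]]
  seqs <- vector("list", nn)
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    el <- pre$edge.length[[e]]
    if (is.na(el)) stop("tree has a missing branch length")
    seqs[[ch]] <- .evolve_seq(seqs[[p]], el * rate_mult, kappa)
  }
  m <- do.call(rbind, lapply(seq_len(ntip), function(i)
    DNA_BASES[seqs[[i]]]))
  rownames(m) <- tree$tip.label
  m
}

# ---- configuration and genome assembly -------------------------------------

#' Simulator configuration
#'
#' @param tree Species tree (`phylo`, branch lengths in substitutions/site).
#' @param clades A [clade_definition()].
#' @param regions Data frame with columns `name`, `kind`
#'   (`PCG`/`tRNA`/`rRNA`/`IGS`), `length` (bp), `rate` (multiplier),
#'   `placement` (`LSC`/`IR`/`SSC`), `strand` (`+`/`-`). Genome order is row
#'   order within each placement block.
#' @param kappa Transition/transversion rate ratio.
#' @param losses List of planted events, each
#'   `list(taxa = <labels defining the clade whose stem carries the event>,
#'   gene = <name>, state = "absent"|"pseudogene")`.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree, clades, regions, kappa = 2, losses = list(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(all(c("name", "kind", "length", "rate", "placement", "strand")
                %in% names(regions)))
  if (any(regions$length <= 0) || any(regions$rate < 0) || kappa <= 0)
    stop("lengths must be > 0, rates >= 0, kappa > 0")
  for (ev in losses) {
    if (!all(ev$taxa %in% tree$tip.label))
      stop("loss event on unknown branch: taxa ",
           paste(setdiff(ev$taxa, tree$tip.label), collapse = ", "))
    if (!ev$gene %in% regions$name[regions$kind != "IGS"])
      stop("loss event for unknown gene: ", ev$gene)
    if (!ev$state %in% c("absent", "pseudogene"))
      stop("loss state must be 'absent' or 'pseudogene'")
  }
  structure(list(tree = tree, clades = clades, regions = regions,
                 kappa = kappa, losses = losses, seed = as.integer(seed)),
            class = "sim_config")
}

.SSC_LINKER_HEAD <- "CC"   # fixed linkers blocking chance extension of the
.SSC_LINKER_TAIL <- "AA"   # planted IR beyond its true boundary

#' Simulate a set of annotated plastomes with known truth
#'
#' Per-region alignments are simulated along the species tree; per taxon the
#' regions are concatenated in config order into an LSC / IRb / SSC / IRa
#' architecture (the IR block is the per-taxon IR-placement sequence, inserted
#' once forward and once reverse-complemented). Planted losses remove (or mark
#' as pseudogene) the gene in every taxon descending from the event branch.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, per-taxon GenBank and
#'   genome FASTA files, per-region alignment FASTAs and a truth JSON are
#'   written.
#' @return A list with `plastomes` (named list of [plastome()]s) and `truth`
#'   (list: `tree`, `alignments`, `presence`, `events`, `ir`, `kappa`,
#'   `regions`).
#' @export
simulate_plastome_set <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxa <- cfg$tree$tip.label
  reg <- cfg$regions
  reg$placement <- factor(reg$placement, levels = c("LSC", "IR", "SSC"))
  reg <- reg[order(reg$placement), , drop = FALSE]
  alns <- list()
  for (i in seq_len(nrow(reg)))
    alns[[reg$name[[i]]]] <- simulate_alignment(
      cfg$tree, reg$length[[i]], kappa = cfg$kappa,
      rate_mult = reg$rate[[i]])
  genes <- reg$name[reg$kind != "IGS"]
  presence <- matrix("intact", length(taxa), length(genes),
                     dimnames = list(taxa, genes))
  events <- list()
  for (ev in cfg$losses) {
    presence[ev$taxa, ev$gene] <- ev$state
    events[[length(events) + 1L]] <- data.frame(
      tips_under_branch = paste(sort(ev$taxa), collapse = ";"),
      gene = ev$gene, from = "intact", to = ev$state,
      stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(tips_under_branch = character(0), gene = character(0),
               from = character(0), to = character(0))

  plastomes <- list(); ir_truth <- list()
  for (tx in taxa) {
    segs <- character(0); pos <- 0L
    frow <- list(); copy <- 0L
    add_feature <- function(name, kind, len, strand) {
      copy <<- copy + 1L
      frow[[length(frow) + 1L]] <<- data.frame(
        name = name, kind = kind, start = pos, end = pos + len,
        strand = strand, copy = copy, part = 1L, stringsAsFactors = FALSE)
    }
    add_region <- function(i) {
      nm <- reg$name[[i]]
      row_seq <- paste(alns[[nm]][tx, ], collapse = "")
      if (reg$kind[[i]] == "IGS") {
        segs <<- c(segs, row_seq); pos <<- pos + nchar(row_seq)
        return(invisible(NULL))
      }
      state <- presence[tx, nm]
      if (state == "absent") return(invisible(NULL))
      kind <- if (state == "pseudogene") "pseudogene" else reg$kind[[i]]
      out_seq <- if (reg$strand[[i]] == "-") revcomp(row_seq) else row_seq
      add_feature(nm, kind, nchar(out_seq), reg$strand[[i]])
      segs <<- c(segs, out_seq); pos <<- pos + nchar(out_seq)
      invisible(NULL)
    }
    for (i in which(reg$placement == "LSC")) add_region(i)
    irb_start <- pos
    ir_rows <- which(reg$placement == "IR")
    ir_feat_from <- length(frow) + 1L
    for (i in ir_rows) add_region(i)
    irb_end <- pos
    irb_len <- irb_end - irb_start
    # SSC with fixed linkers so the maximal exact IR match stops at the
    # planted boundary in every taxon
    segs <- c(segs, .SSC_LINKER_HEAD); pos <- pos + nchar(.SSC_LINKER_HEAD)
    for (i in which(reg$placement == "SSC")) add_region(i)
    segs <- c(segs, .SSC_LINKER_TAIL); pos <- pos + nchar(.SSC_LINKER_TAIL)
    ira_start <- pos
    irb_seq <- substr(paste(segs, collapse = ""), irb_start + 1L, irb_end)
    if (irb_len > 0L) {
      segs <- c(segs, revcomp(irb_seq))
      # mirror the IR-block features into IRa on the opposite strand
      if (length(frow) >= ir_feat_from) {
        for (fi in ir_feat_from:length(frow)) {
          f <- frow[[fi]]
          if (f$start >= irb_start && f$end <= irb_end) {
            copy <- copy + 1L
            frow[[length(frow) + 1L]] <- data.frame(
              name = f$name, kind = f$kind,
              start = ira_start + (irb_len - (f$end - irb_start)),
              end = ira_start + (irb_len - (f$start - irb_start)),
              strand = if (f$strand == "+") "-" else "+",
              copy = copy, part = 1L, stringsAsFactors = FALSE)
          }
        }
      }
      pos <- pos + irb_len
    }
    genome <- paste(segs, collapse = "")
    ft <- do.call(rbind, frow)
    plastomes[[tx]] <- plastome(
      seq_record(tx, genome, circular = TRUE),
      feature_table(ft$name, ft$kind, ft$start, ft$end, ft$strand,
                    ft$copy, ft$part))
    ir_truth[[tx]] <- list(LSC = c(0L, irb_start),
                           IRb = c(irb_start, irb_end),
                           SSC = c(irb_end, ira_start),
                           IRa = c(ira_start, nchar(genome)),
                           ir_length = irb_len)
  }
  truth <- list(tree = cfg$tree, alignments = alns, presence = presence,
                events = events, ir = ir_truth, kappa = cfg$kappa,
                regions = reg)
  out <- list(plastomes = plastomes, truth = truth)
  if (!is.null(dir)) .write_sim_output(out, cfg, dir)
  out
}

.write_sim_output <- function(out, cfg, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  for (tx in names(out$plastomes)) {
    write_genbank(out$plastomes[[tx]], file.path(dir, "genomes",
                                                 paste0(tx, ".gb")))
    write_fasta(stats::setNames(out$plastomes[[tx]]$record$seq, tx),
                file.path(dir, "genomes", paste0(tx, ".fasta")))
  }
  for (nm in names(out$truth$alignments))
    write_alignment(out$truth$alignments[[nm]],
                    file.path(dir, "alignments", paste0(nm, ".fasta")))
  write_newick(out$truth$tree, file.path(dir, "reference.nwk"))
  write_clades(cfg$clades, file.path(dir, "clades.json"))
  write_presence_matrix(out$truth$presence, file.path(dir, "presence.tsv"))
  jsonlite::write_json(
    list(seed = cfg$seed, kappa = cfg$kappa,
         ir = out$truth$ir,
         events = out$truth$events,
         regions = out$truth$regions),
    file.path(dir, "truth.json"), pretty = TRUE, auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

# ---- default benchmark world -----------------------------------------------

.comb_newick <- function(labels, tip_len, int_len) {
  # left-leaning comb with uniform tip and internal edge lengths
  if (length(labels) == 1L) return(sprintf("%s:%.6f", labels, tip_len))
  s <- sprintf("%s:%.6f", labels[[1]], tip_len)
  for (i in 2L:length(labels)) {
    s <- sprintf("(%s,%s:%.6f):%.6f", s, labels[[i]], tip_len, int_len)
  }
  # the outermost edge length is replaced by the caller's stem
  sub("):[0-9.]+$", ")", s)
}

#' Default benchmark species tree
#'
#' A 32-taxon rooted tree emulating the motivating mistletoe system: 29 ingroup accessions in
#' five clades (I: 9, II: 6, III: 5, IV: 4 taxa, and a fifth five-accession
#' clade excluded from scoring) plus a three-taxon near-outgroup genus. The
#' seven edges the utility test scores (four clade stems, the near-outgroup
#' stem and the two ingroup backbone edges) all carry 8e-4
#' substitutions/site, so a long fast region resolves each of them nearly
#' always while a short one misses at least one in roughly half of
#' replicates. Path lengths give within-clade distances < 0.01, maximum
#' within-ingroup distances near 0.017, ingroup-outgroup distances of
#' 0.029-0.035, and a plastome-average expected diversity near 0.013
#' substitutions/site at rate multiplier 1.
#'
#' @return A rooted `phylo` tree with branch lengths.
#' @export
benchmark_tree <- function() {
  b <- 0.0008
  lab <- function(p, n) sprintf("%s%d", p, seq_len(n))
  cl <- function(p, n) .comb_newick(lab(p, n), 0.002, 0.0005)
  core <- sprintf("(((%s:%.6f,%s:%.6f):%.6f,%s:%.6f):%.6f,%s:%.6f):0.0015",
                  cl("I", 9L), b, cl("II", 6L), b, b, cl("III", 5L), b, b,
                  cl("IV", 4L), b)
  ingroup <- sprintf("(%s:0.004,%s)", cl("CH", 5L), core)
  txt <- sprintf("(%s:%.6f,%s:0.012);", cl("SC", 3L), b + 0.010, ingroup)
  read_newick(txt)
}

#' Default benchmark clade definitions
#'
#' Clades I-IV and the near-outgroup genus ("Scurrula"-analogue) are scored;
#' the outgroup used for rooting is that same three-taxon clade; the
#' three-accession fifth clade is excluded from scoring.
#'
#' @return A [clade_definition()].
#' @export
benchmark_clades <- function() {
  lab <- function(p, n) sprintf("%s%d", p, seq_len(n))
  clade_definition(
    clades = list(I = lab("I", 9L), II = lab("II", 6L), III = lab("III", 5L),
                  IV = lab("IV", 4L), Scurrula = lab("SC", 3L)),
    outgroup = lab("SC", 3L),
    excluded = lab("CH", 5L))
}

#' Default benchmark region table
#'
#' Analogues of the canonical candidate barcode regions: short fast intergenic spacers
#' (rates 4-8x the plastome average, parsimony-informative proportions around
#' 0.08-0.25), slower protein-coding genes (0.5-1.5x, PI proportions around
#' 0.01-0.10), an rRNA in the inverted repeat, and two SSC genes.
#'
#' @return A data.frame accepted by [sim_config()].
#' @export
benchmark_regions <- function() {
  tab <- rbind(
    c("trnH",       "tRNA",   80, 0.8, "LSC", "+"),
    c("trnH-psbA",  "IGS",   305, 8.0, "LSC", "+"),
    c("psbA",       "PCG",  1050, 0.8, "LSC", "-"),
    c("infA",       "PCG",   230, 0.8, "LSC", "+"),
    c("rbcL",       "PCG",  1400, 0.5, "LSC", "+"),
    c("accD",       "PCG",  1500, 1.5, "LSC", "+"),
    c("matK",       "PCG",  1580, 1.0, "LSC", "+"),
    c("rpoB",       "PCG",  1000, 0.8, "LSC", "+"),
    c("rpoB-trnC",  "IGS",   810, 6.0, "LSC", "+"),
    c("trnC",       "tRNA",   70, 0.8, "LSC", "+"),
    c("rpl14",      "PCG",   400, 0.8, "LSC", "+"),
    c("rpl14-rps3", "IGS",  1660, 5.0, "LSC", "+"),
    c("rps3",       "PCG",   650, 0.8, "LSC", "+"),
    c("trnL",       "tRNA",   80, 0.8, "LSC", "+"),
    c("trnL-trnF",  "IGS",   640, 4.0, "LSC", "+"),
    c("trnF",       "tRNA",   70, 0.8, "LSC", "+"),
    c("rrn16",      "rRNA", 1490, 0.3, "IR",  "+"),
    c("ccsA",       "PCG",   960, 1.2, "SSC", "+"),
    c("rpl32",      "PCG",   170, 0.8, "SSC", "+"))
  data.frame(name = tab[, 1L], kind = tab[, 2L],
             length = as.integer(tab[, 3L]), rate = as.numeric(tab[, 4L]),
             placement = tab[, 5L], strand = tab[, 6L],
             stringsAsFactors = FALSE)
}

#' Default benchmark planted losses
#'
#' Emulates the motivating system's gene-content pattern: loss of `infA` on the
#' near-outgroup stem and independently in one clade-I taxon, loss of `trnH`
#' in that same taxon (so the `trnH-psbA` spacer drops out of the shared
#' set), and pseudogenization of `rpl32` on the clade-IV stem.
#'
#' @return A list of planted events for [sim_config()].
#' @export
benchmark_losses <- function() {
  list(
    list(taxa = sprintf("SC%d", 1:3), gene = "infA", state = "absent"),
    list(taxa = "I1", gene = "infA", state = "absent"),
    list(taxa = "I1", gene = "trnH", state = "absent"),
    list(taxa = sprintf("IV%d", 1:4), gene = "rpl32", state = "pseudogene"))
}

#' Default simulator configuration
#'
#' @param seed Integer seed.
#' @return A [sim_config()] combining [benchmark_tree()],
#'   [benchmark_clades()], [benchmark_regions()] and [benchmark_losses()]
#'   with kappa = 2.
#' @export
default_sim_config <- function(seed) {
  sim_config(tree = benchmark_tree(), clades = benchmark_clades(),
             regions = benchmark_regions(), kappa = 2,
             losses = benchmark_losses(), seed = seed)
}

#' Build the end-to-end benchmark fixture
#'
#' Simulates the plastome set and emits a ready-to-run directory: per-region
#' alignments, per-taxon GenBank/FASTA genomes, the reference tree, clade
#' definitions, presence matrix and truth JSON. Identical seeds give
#' byte-identical fixtures.
#'
#' @param cfg A [sim_config()]; defaults to [default_sim_config()] with
#'   `seed`.
#' @param dir Output directory (created).
#' @param seed Used only when `cfg` is missing.
#' @return The [simulate_plastome_set()] result, invisibly, with the
#'   directory path attached as attribute `dir`.
#' @export
make_benchmark <- function(dir, cfg = NULL, seed = 1L) {
  if (is.null(cfg)) cfg <- default_sim_config(seed)
  out <- simulate_plastome_set(cfg, dir = dir)
  jsonlite::write_json(
    list(tool = "plastomeHotspots",
         version = as.character(utils::packageVersion("plastomeHotspots")),
         seed = cfg$seed, taxa = length(cfg$tree$tip.label),
         regions = nrow(cfg$regions)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  attr(out, "dir") <- dir
  invisible(out)
}

#' Score benchmark candidate regions against the reference tree
#'
#' For each candidate region an NJ tree is built from its K2P distance matrix
#' and scored with the six-point utility test against the true species tree.
#' `"rbcL+accD"`-style names concatenate member alignments.
#'
#' @param sim A [simulate_plastome_set()] / [make_benchmark()] result.
#' @param clades A [clade_definition()]; defaults to [benchmark_clades()].
#' @param candidates Character vector of region names (use `+` to
#'   concatenate).
#' @return A [rank_regions()] table.
#' @export
score_benchmark <- function(sim, clades = benchmark_clades(),
                            candidates = c("rpl14-rps3", "rpoB-trnC",
                                           "trnL-trnF", "trnH-psbA", "matK",
                                           "accD", "rbcL", "rbcL+accD")) {
  alns <- sim$truth$alignments
  scores <- lapply(candidates, function(nm) {
    members <- strsplit(nm, "+", fixed = TRUE)[[1]]
    missing <- setdiff(members, names(alns))
    if (length(missing))
      stop("unknown region(s): ", paste(missing, collapse = ", "))
    aln <- if (length(members) > 1L)
      concatenate_alignments(stats::setNames(alns[members], members))
    else alns[[members]]
    dm <- distance_matrix(aln, model = "K2P")
    cand <- neighbor_joining(dm)
    st <- region_stats(nm, aln)
    score_region(cand, sim$truth$tree, clades, region = nm,
                 alignment_length = st$alignment_length,
                 prop_pi = st$prop_pi)
  })
  rank_regions(scores)
}
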