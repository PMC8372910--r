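# Tree machinery: Newick I/O (via ape's phylo container), an internal
# neighbor-joining builder, outgroup rooting, bipartitions/RF, monophyly and
# backbone-topology comparison.

#' Read a Newick tree
#'
#' Accepts a file path or a Newick string. Branch lengths, internal support
#' labels and quoted labels are supported (ape parser). Duplicate leaf labels
#' are an error.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An ape `phylo` tree.
#' @export
read_newick <- function(x) {
  t <- tryCatch(
    if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
      ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) stop("invalid Newick: ", conditionMessage(e)))
  if (is.null(t)) stop("invalid Newick (unbalanced parentheses?)")
  if (inherits(t, "multiPhylo")) t <- t[[1]]
  dup <- unique(t$tip.label[duplicated(t$tip.label)])
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  t
}

.min_desc_label <- function(t, children) {
  ntip <- length(t$tip.label)
  memo <- character(ntip + t$Nnode)
  rec <- function(node) {
    if (nzchar(memo[[node]])) return(memo[[node]])
    v <- if (node <= ntip) t$tip.label[[node]]
         else min(vapply(children[[as.character(node)]], rec, ""))
    memo[[node]] <<- v
    v
  }
  rec
}

#' Write a tree as canonical Newick
#'
#' Children of every node are ordered by their minimal descendant leaf label,
#' so equal topologies serialize identically. Branch lengths and internal
#' (support) labels are preserved.
#'
#' @param t A `phylo` tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(t, path = NULL, digits = 10L) {
  ntip <- length(t$tip.label)
  children <- split(t$edge[, 2L], t$edge[, 1L])
  minlab <- .min_desc_label(t, children)
  parent_edge <- match(seq_len(ntip + t$Nnode), t$edge[, 2L])
  lenstr <- function(node) {
    e <- parent_edge[[node]]
    if (is.na(e) || is.null(t$edge.length)) ""
    else paste0(":", sprintf("%.*g", digits, t$edge.length[[e]]))
  }
  rec <- function(node) {
    if (node <= ntip) return(paste0(t$tip.label[[node]], lenstr(node)))
    kids <- children[[as.character(node)]]
    kids <- kids[order(vapply(kids, minlab, ""))]
    lab <- if (!is.null(t$node.label)) t$node.label[[node - ntip]] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")", lab,
           lenstr(node))
  }
  root <- setdiff(t$edge[, 1L], t$edge[, 2L])[[1]]
  txt <- paste0(rec(root), ";")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Nontrivial bipartitions of a tree
#'
#' Splits are canonicalized to the side not containing the lexicographically
#' smallest leaf and encoded as `|`-joined sorted label strings; trivial
#' splits (single leaf / all-but-one) are omitted, so rooted and unrooted
#' representations of the same topology yield the same set.
#'
#' @param t A `phylo` tree.
#' @return Character vector of canonical split encodings.
#' @export
tree_splits <- function(t) {
  ntip <- length(t$tip.label)
  if (ntip < 4L) return(character(0))
  pp <- ape::prop.part(t)
  anchor <- min(t$tip.label)
  enc <- vapply(pp, function(idx) {
    side <- t$tip.label[idx]
    if (anchor %in% side) side <- setdiff(t$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(enc[!is.na(enc)])
}

#' Robinson-Foulds distance
#'
#' Number of nontrivial bipartitions present in exactly one of the two trees;
#' 0 means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken by
#' the lowest (row, col) index pair; negative branch lengths are clamped to 0
#' with the deficit moved to the sister edge.
#'
#' @param dm Symmetric numeric distance matrix with taxon dimnames (>= 3
#'   taxa, no `NA`).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  d <- unclass(dm)
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  sub <- labels   # newick fragment per active node
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", sub[[i]], fmt(li), sub[[j]], fmt(lj))
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    sub <- c(sub[keep], merged)
    rownames(d2) <- colnames(d2) <- as.character(seq_len(n - 1L))
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[[1]], fmt(la),
                 sub[[2]], fmt(lb), sub[[3]], fmt(lc))
  read_newick(txt)
}

#' Root a tree on the edge separating an outgroup
#'
#' @param t A `phylo` tree.
#' @param outgroup Character vector of outgroup leaf labels.
#' @return A rooted `phylo` tree with the root on the outgroup edge.
#' @export
root_with_outgroup <- function(t, outgroup) {
  missing <- setdiff(outgroup, t$tip.label)
  if (length(missing))
    stop("unknown taxon/taxa: ", paste(missing, collapse = ", "))
  if (setequal(outgroup, t$tip.label))
    stop("outgroup cannot contain every leaf")
  if (length(outgroup) > 1L && length(t$tip.label) - length(outgroup) > 1L) {
    enc <- paste(sort(outgroup), collapse = "|")
    enc_c <- paste(sort(setdiff(t$tip.label, outgroup)), collapse = "|")
    if (!any(tree_splits(t) %in% c(enc, enc_c)))
      stop("outgroup not monophyletic on any rooting")
  }
  ape::root(ape::unroot(t), outgroup = outgroup, resolve.root = TRUE)
}

.leaf_sets <- function(t) {
  # descendant tip-label sets for internal nodes of a rooted tree
  lapply(ape::prop.part(t), function(idx) t$tip.label[idx])
}

#' Test monophyly of a taxon set on a rooted tree
#'
#' TRUE iff some node's descendant leaf set equals the set exactly (a single
#' leaf is monophyletic by definition).
#'
#' @param t A rooted `phylo` tree.
#' @param taxa Character vector of leaf labels.
#' @return Logical.
#' @export
is_monophyletic <- function(t, taxa) {
  unknown <- setdiff(taxa, t$tip.label)
  if (length(unknown))
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) <= 1L) return(TRUE)
  for (s in .leaf_sets(t)) if (setequal(s, taxa)) return(TRUE)
  FALSE
}

#' Clade definitions for utility scoring
#'
#' @param clades Named list of taxon-label vectors (pairwise disjoint).
#' @param outgroup Character vector of outgroup taxa (may coincide with one
#'   of the named clades, e.g. when the near-outgroup genus is itself scored).
#' @param excluded Taxa pruned from every tree before scoring.
#' @return A list of class `clade_definition`.
#' @export
clade_definition <- function(clades, outgroup, excluded = character(0)) {
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("clades must be a named list")
  all_taxa <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("clades must be pairwise disjoint; duplicated: ",
         paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "))
  og_in <- vapply(clades, function(s) any(outgroup %in% s), TRUE)
  if (any(og_in) && !any(vapply(clades, function(s) setequal(s, outgroup),
                                TRUE)))
    stop("outgroup must be disjoint from the clades or equal to one of them")
  if (length(intersect(excluded, c(all_taxa, outgroup))))
    stop("excluded taxa overlap the clades/outgroup: ",
         paste(intersect(excluded, c(all_taxa, outgroup)), collapse = ", "))
  structure(list(clades = clades, outgroup = outgroup, excluded = excluded),
            class = "clade_definition")
}

#' Read / write clade definitions as JSON
#'
#' @param path JSON path.
#' @return A [clade_definition()] (read) or `path` (write).
#' @export
read_clades <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clade_definition(as.list(x$clades), x$outgroup,
                   x$excluded %||% character(0))
}

#' @rdname read_clades
#' @param clades A [clade_definition()].
#' @export
write_clades <- function(clades, path) {
  jsonlite::write_json(list(clades = clades$clades,
                            outgroup = clades$outgroup,
                            excluded = clades$excluded),
                       path, pretty = TRUE)
  invisible(path)
}

.prune <- function(t, drop) {
  drop <- intersect(drop, t$tip.label)
  if (!length(drop)) return(t)
  ape::drop.tip(t, drop)
}

.root_or_null <- function(t, outgroup) {
  tryCatch(root_with_outgroup(t, outgroup), error = function(e) NULL)
}

.collapse_backbone <- function(t, clades) {
  # assumes every clade monophyletic in t; excluded already pruned
  keep_map <- character(0)
  for (nm in names(clades$clades)) {
    members <- sort(clades$clades[[nm]])
    keep_map[[members[[1]]]] <- nm
    t <- .prune(t, members[-1L])
  }
  og <- sort(clades$outgroup)
  if (!og[[1]] %in% names(keep_map)) {
    keep_map[[og[[1]]]] <- "OUTGROUP"
    t <- .prune(t, og[-1L])
  }
  t <- .prune(t, setdiff(t$tip.label, names(keep_map)))
  t$tip.label <- unname(keep_map[t$tip.label])
  t
}

#' Compare candidate backbone topology against a reference
#'
#' Operationalization of an "overall topology" match: every defined clade must
#' be monophyletic in both trees; each clade (and the outgroup) is then
#' collapsed to a single placeholder leaf, leaves outside all groups are
#' pruned, and the match holds iff the two collapsed unrooted topologies have
#' Robinson-Foulds distance 0. A candidate with any broken clade fails
#' outright; a reference inconsistent with the clade definitions is an error.
#'
#' @param candidate,reference `phylo` trees containing all clade and outgroup
#'   taxa.
#' @param clades A [clade_definition()].
#' @return Logical.
#' @export
backbone_match <- function(candidate, reference, clades) {
  need <- c(unlist(clades$clades, use.names = FALSE), clades$outgroup)
  for (t in list(candidate, reference)) {
    missing <- setdiff(need, t$tip.label)
    if (length(missing))
      stop("tree is missing taxa: ", paste(missing, collapse = ", "))
  }
  candidate <- .prune(candidate, clades$excluded)
  reference <- .prune(reference, clades$excluded)
  ref_rooted <- .root_or_null(reference, clades$outgroup)
  if (is.null(ref_rooted))
    stop("reference tree: outgroup not monophyletic on any rooting")
  for (nm in names(clades$clades))
    if (!is_monophyletic(ref_rooted, clades$clades[[nm]]))
      stop("reference tree inconsistent with clade '", nm, "'")
  cand_rooted <- .root_or_null(candidate, clades$outgroup)
  if (is.null(cand_rooted)) return(FALSE)
  for (nm in names(clades$clades))
    if (!is_monophyletic(cand_rooted, clades$clades[[nm]])) return(FALSE)
  c1 <- .collapse_backbone(cand_rooted, clades)
  c2 <- .collapse_backbone(ref_rooted, clades)
  rf_distance(ape::unroot(c1), ape::unroot(c2)) == 0L
}
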