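# Alignment variability statistics: nucleotide diversity (global and sliding
# window), site classification, and per-region summaries.

.unambiguous <- function(aln) {
  # logical matrix: TRUE where the cell is an unambiguous base
  matrix(aln %in% DNA_BASES, nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Sliding-window configuration
#'
#' Defaults follow the common population-genetics convention of 500 bp windows advanced in
#' 100 bp steps.
#'
#' @param window_length Window length in alignment columns (default 500).
#' @param step Step size in columns (default 100).
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_length = 500L, step = 100L) {
  window_length <- as.integer(window_length); step <- as.integer(step)
  if (step < 1L || window_length < step)
    stop("need window_length >= step >= 1")
  structure(list(window_length = window_length, step = step),
            class = "window_config")
}

#' Nucleotide diversity of an alignment
#'
#' π is the average over all unordered taxon pairs of (pairwise differences /
#' pairwise compared sites). Under `gap_mode = "pairwise"` (the default) a
#' column is compared for a pair only when both rows carry an unambiguous
#' base; pairs with zero comparable sites are excluded from the average. Under
#' `"complete"` every column containing any gap or ambiguity is removed before
#' counting.
#'
#' @param aln Alignment matrix (>= 2 taxa).
#' @param columns Optional integer vector of column indices (1-based) to use.
#' @param gap_mode `"pairwise"` or `"complete"` deletion.
#' @return π, a single number in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln, columns = NULL,
                                 gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  if (nrow(aln) < 2L) stop("need at least 2 taxa")
  if (!is.null(columns)) aln <- aln[, columns, drop = FALSE]
  ok <- .unambiguous(aln)
  if (gap_mode == "complete") {
    keep <- colSums(ok) == nrow(aln)
    aln <- aln[, keep, drop = FALSE]; ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(aln); tot <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L) next
    tot <- tot + sum(aln[i, comp] != aln[j, comp]) / nc
    npairs <- npairs + 1L
  }
  if (npairs == 0L) stop("no comparable sites")
  tot / npairs
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows start at columns 0, step, 2*step, ... (0-based); only full windows
#' are reported. Windows in which no taxon pair has a comparable site get
#' `NA` with a warning.
#'
#' @param aln Alignment matrix.
#' @param cfg A [window_config()].
#' @param gap_mode Passed to [nucleotide_diversity()].
#' @return A data.frame of class `diversity_profile` with 0-based half-open
#'   `window_start`, `window_end` and `pi`.
#' @export
sliding_window_pi <- function(aln, cfg = window_config(),
                              gap_mode = "pairwise") {
  L <- ncol(aln); w <- cfg$window_length
  if (L < w)
    stop("alignment (", L, " columns) shorter than one window (", w, ")")
  starts <- seq(0L, L - w, by = cfg$step)
  pi <- vapply(starts, function(s) {
    tryCatch(nucleotide_diversity(aln, columns = (s + 1L):(s + w),
                                  gap_mode = gap_mode),
             error = function(e) NA_real_)
  }, 0)
  if (anyNA(pi)) warning(sum(is.na(pi)), " window(s) had no comparable sites")
  structure(data.frame(window_start = starts, window_end = starts + w,
                       pi = pi),
            class = c("diversity_profile", "data.frame"))
}

#' Classify alignment columns
#'
#' A column is *variable* when at least two distinct unambiguous bases occur,
#' and *parsimony-informative* when at least two distinct unambiguous bases
#' each occur in at least two taxa. Gaps and ambiguity codes never count as
#' states.
#'
#' @param aln Alignment matrix (>= 2 taxa).
#' @return A list with counts `invariant`, `variable`, `parsimony_informative`
#'   (a subset of variable), `gap_or_ambiguous_only`, and the per-column class
#'   factor `classes` (levels: invariant, variable, pi, empty; `pi` columns are
#'   also variable but labeled `pi`).
#' @export
site_classes <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 taxa")
  cls <- vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    col <- col[col %in% DNA_BASES]
    if (!length(col)) return("empty")
    tab <- table(col)
    if (length(tab) < 2L) return("invariant")
    if (sum(tab >= 2L) >= 2L) "pi" else "variable"
  }, "")
  list(invariant = sum(cls == "invariant"),
       variable = sum(cls %in% c("variable", "pi")),
       parsimony_informative = sum(cls == "pi"),
       gap_or_ambiguous_only = sum(cls == "empty"),
       classes = factor(cls, levels = c("invariant", "variable", "pi",
                                        "empty")))
}

#' Per-region variability summary
#'
#' Bundles alignment length and the proportions of variable and
#' parsimony-informative sites (relative to alignment length); proportions are
#' kept at full precision and rounded only for presentation.
#'
#' @param name Region label.
#' @param aln Alignment matrix.
#' @return A one-row data.frame of class `region_stats` with `name`,
#'   `alignment_length`, `prop_variable`, `prop_pi`, `n_taxa`.
#' @export
region_stats <- function(name, aln) {
  sc <- site_classes(aln)
  L <- ncol(aln)
  out <- data.frame(name = name, alignment_length = L,
                    prop_variable = sc$variable / L,
                    prop_pi = sc$parsimony_informative / L,
                    n_taxa = nrow(aln), stringsAsFactors = FALSE)
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Write a diversity profile or region-stats table as TSV
#'
#' @param x A `diversity_profile` or a (stacked) `region_stats` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  df <- as.data.frame(x)
  df$classes <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
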