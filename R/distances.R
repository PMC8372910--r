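# Pairwise genetic distances: Kimura 2-parameter and p-distance, full
# matrices, and the two-triangle combined table.

.pair_counts <- function(a, b) {
  # a, b: character vectors of aligned residues
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  ts <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                (a %in% c("C", "T") & b %in% c("C", "T")))
  list(n = n, transitions = sum(ts), transversions = sum(diff) - sum(ts))
}

.as_chars <- function(x) if (is.character(x) && length(x) == 1L)
  strsplit(toupper(x), "")[[1]] else toupper(x)

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Over the columns where both rows carry an unambiguous base, with transition
#' proportion P and transversion proportion Q, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When the log arguments are
#' non-positive the distance is saturated: `NA` is returned with a warning.
#'
#' @param a,b Aligned sequences (strings or character vectors, equal length).
#' @return The K2P distance in substitutions/site; `NA` when saturated.
#' @export
k2p <- function(a, b) {
  a <- .as_chars(a); b <- .as_chars(b)
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ct <- .pair_counts(a, b)
  if (ct$n == 0L) stop("no comparable sites")
  P <- ct$transitions / ct$n; Q <- ct$transversions / ct$n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 4),
            ", 1-2Q = ", signif(w2, 4))
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' p-distance between two aligned sequences
#'
#' Proportion of differing sites over pairwise-comparable columns.
#'
#' @inheritParams k2p
#' @return The uncorrected distance.
#' @export
p_distance <- function(a, b) {
  a <- .as_chars(a); b <- .as_chars(b)
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ct <- .pair_counts(a, b)
  if (ct$n == 0L) stop("no comparable sites")
  (ct$transitions + ct$transversions) / ct$n
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln Alignment matrix (>= 2 taxa).
#' @param model `"K2P"` or `"p"`.
#' @param deletion `"pairwise"` (default) compares, per pair, the columns where
#'   both rows are unambiguous; `"complete"` first removes every column with
#'   any gap/ambiguity.
#' @return A symmetric numeric matrix with taxa as dimnames, `model` and
#'   `deletion` attributes, and class `dist_matrix`. Saturated K2P pairs are
#'   `NA`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model); deletion <- match.arg(deletion)
  if (nrow(aln) < 2L) stop("need at least 2 taxa")
  if (deletion == "complete") {
    keep <- colSums(.unambiguous(aln)) == nrow(aln)
    aln <- aln[, keep, drop = FALSE]
  }
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  fn <- if (model == "K2P") k2p else p_distance
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- fn(aln[i, ], aln[j, ])
  }
  structure(d, model = model, deletion = deletion,
            class = c("dist_matrix", "matrix"))
}

#' Summarize a distance matrix
#'
#' @param d A matrix from [distance_matrix()].
#' @return A list with `min`, `max` (off-diagonal values) and the taxon pairs
#'   attaining them.
#' @export
summarize_distances <- function(d) {
  m <- unclass(d); diag(m) <- NA
  lo <- which(m == min(m, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  hi <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(min = min(m, na.rm = TRUE),
       min_pair = rownames(m)[sort(lo)],
       max = max(m, na.rm = TRUE),
       max_pair = rownames(m)[sort(hi)],
       n_undefined = sum(is.na(m)) / 2L)
}

#' Combine two distance matrices into one two-triangle table
#'
#' Mirrors the common comparative-heatmap layout: the lower-left triangle from
#' one matrix (e.g. whole-plastome distances) and the upper-right triangle
#' from another (e.g. nuclear rDNA distances), with an empty diagonal.
#'
#' @param lower,upper Distance matrices with identical taxa in identical
#'   order.
#' @return A square numeric matrix with `NA` diagonal.
#' @export
combined_matrix_table <- function(lower, upper) {
  if (!identical(rownames(lower), rownames(upper)))
    stop("taxon mismatch between matrices: ",
         paste(c(setdiff(rownames(lower), rownames(upper)),
                 setdiff(rownames(upper), rownames(lower))), collapse = ", "))
  out <- matrix(NA_real_, nrow(lower), ncol(lower),
                dimnames = dimnames(lower))
  out[lower.tri(out)] <- unclass(lower)[lower.tri(lower)]
  out[upper.tri(out)] <- unclass(upper)[upper.tri(upper)]
  out
}

#' Write / read a square distance table as TSV
#'
#' Values are written at 4 decimal places (the conventional reporting
#' precision for K2P tables); the first column holds taxon labels.
#'
#' @param d Square numeric matrix with dimnames.
#' @param path TSV path.
#' @param digits Decimal places on write.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_tsv <- function(d, path, digits = 4L) {
  df <- data.frame(taxon = rownames(d),
                   format(round(unclass(d), digits), nsmall = digits,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("taxon", colnames(d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param d Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[[i]], width = -12),
                     paste(sprintf("%.6f", unclass(d)[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}
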