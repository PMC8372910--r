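# Region extraction: genes, intergenic spacers, shared-region sets and
# concatenation. All coordinate arithmetic is 0-based half-open on the circle.

#' Define a region to extract
#'
#' @param name Region label, e.g. `"accD"` or `"trnL-trnF"`.
#' @param mode One of `"gene"`, `"igs"`, `"concat"`.
#' @param parts For `igs` the two flanking feature names `(left, right)`;
#'   for `concat` the ordered member region names; ignored for `gene`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, mode = c("gene", "igs", "concat"),
                        parts = character(0)) {
  mode <- match.arg(mode)
  if (mode == "igs" && length(parts) != 2L)
    stop("igs region '", name, "' needs exactly two flanking feature names")
  if (mode == "concat" && length(parts) < 2L)
    stop("concat region '", name, "' needs at least two member regions")
  structure(list(name = name, mode = mode, parts = as.character(parts)),
            class = "region_spec")
}

.circ_slice <- function(seq, start, end, n) {
  # [start, end) walking the plus strand, wrapping through the origin
  if (start <= end) {
    if (start == end) "" else substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, end))
  }
}

.feature_copies <- function(p, name) {
  rows <- p$features[p$features$name == name, , drop = FALSE]
  if (!nrow(rows))
    stop("no feature named '", name, "'; available: ",
         paste(sort(unique(p$features$name)), collapse = ", "))
  split(rows, rows$copy)
}

#' Extract a named gene from an annotated plastome
#'
#' Returns the plus-strand-oriented gene sequence: minus-strand features are
#' reverse-complemented and multi-exon features concatenated in exon order.
#' For genes duplicated in the inverted repeat, `ir_policy` selects the copy:
#' `"first"` takes the first copy in feature order; `"lsc-copy"` takes the
#' first copy lying outside the IR spans when the plastome carries an `ir`
#' attribute (see [find_ir()]), and otherwise falls back to `"first"`.
#'
#' @param p A [plastome()].
#' @param name Gene name.
#' @param ir_policy Copy-selection policy, `"first"` or `"lsc-copy"`.
#' @return A [seq_record()] named `<plastome id>|<gene>` with provenance
#'   attributes `start`, `end`, `strand`.
#' @export
extract_gene <- function(p, name, ir_policy = c("first", "lsc-copy")) {
  ir_policy <- match.arg(ir_policy)
  copies <- .feature_copies(p, name)
  pick <- copies[[1]]
  if (length(copies) > 1L && ir_policy == "lsc-copy") {
    ir <- attr(p, "ir")
    if (!is.null(ir)) {
      inside <- vapply(copies, function(rows) {
        mid <- (min(rows$start) + max(rows$end)) / 2
        (mid >= ir$IRb[[1]] && mid < ir$IRb[[2]]) ||
          (mid >= ir$IRa[[1]] && mid < ir$IRa[[2]])
      }, TRUE)
      if (any(!inside)) pick <- copies[[which(!inside)[[1]]]]
    }
  }
  pick <- pick[order(pick$part), , drop = FALSE]
  if (any(pick$kind == "pseudogene"))
    warning("feature '", name, "' in ", p$record$id,
            " is flagged as a pseudogene")
  s <- paste(substring(p$record$seq, pick$start + 1L, pick$end), collapse = "")
  if (pick$strand[[1]] == "-") s <- revcomp(s)
  rec <- seq_record(paste0(p$record$id, "|", name), s)
  attr(rec, "start") <- min(pick$start); attr(rec, "end") <- max(pick$end)
  attr(rec, "strand") <- pick$strand[[1]]
  rec
}

#' Extract an intergenic spacer
#'
#' Returns the sequence strictly between the end of `left` and the start of
#' `right`, walking the circle in the plus direction (crossing the origin when
#' needed). A zero-length spacer is allowed.
#'
#' @param p A [plastome()].
#' @param left,right Names of the flanking features.
#' @return A [seq_record()] named `<plastome id>|<left>-<right>`.
#' @export
extract_igs <- function(p, left, right) {
  n <- nchar(p$record$seq)
  lf <- .feature_copies(p, left)[[1]]
  rf <- .feature_copies(p, right)[[1]]
  lstart <- min(lf$start); lend <- max(lf$end)
  rstart <- min(rf$start); rend <- max(rf$end)
  overlap <- max(lstart, rstart) < min(lend, rend)
  if (overlap)
    stop("flanking features overlap: ", left, " [", lstart, ",", lend, ") and ",
         right, " [", rstart, ",", rend, ")")
  s <- .circ_slice(p$record$seq, lend %% n, rstart, n)
  rec <- seq_record(paste0(p$record$id, "|", left, "-", right),
                    if (nzchar(s)) s else "N")
  if (!nzchar(s)) rec$seq <- ""   # allow the empty spacer past validation
  attr(rec, "start") <- lend %% n; attr(rec, "end") <- rstart
  attr(rec, "strand") <- "+"
  rec
}

.extract_one <- function(p, spec, ir_policy) {
  switch(spec$mode,
    gene = extract_gene(p, spec$name, ir_policy),
    igs = extract_igs(p, spec$parts[[1]], spec$parts[[2]]),
    concat = {
      segs <- vapply(spec$parts, function(nm)
        extract_gene(p, nm, ir_policy)$seq, "")
      rec <- seq_record(paste0(p$record$id, "|", spec$name),
                        paste(segs, collapse = ""))
      rec
    })
}

#' Build the shared-region set across plastomes
#'
#' Extracts every requested region from every plastome and keeps only the
#' regions present in all taxa; absences are reported, not fatal.
#'
#' @param plastomes List of [plastome()]s (at least 2).
#' @param specs List of [region_spec()]s.
#' @param ir_policy Passed to [extract_gene()].
#' @return A list of class `region_set` with elements `regions` (named list of
#'   named sequence vectors, taxa as names), `dropped` (data.frame of region,
#'   taxon, reason), and `provenance` (data.frame of region, taxon, start, end,
#'   strand).
#' @export
build_region_set <- function(plastomes, specs, ir_policy = "first") {
  if (length(plastomes) < 2L) stop("need at least 2 plastomes")
  if (inherits(specs, "region_spec")) specs <- list(specs)
  taxa <- vapply(plastomes, function(p) p$record$id, "")
  if (anyDuplicated(taxa)) stop("duplicate plastome ids")
  regions <- list(); dropped <- list(); prov <- list()
  for (spec in specs) {
    seqs <- character(0); ok <- TRUE
    for (i in seq_along(plastomes)) {
      rec <- tryCatch(
        withCallingHandlers(
          .extract_one(plastomes[[i]], spec, ir_policy),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(rec, "error")) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          region = spec$name, taxon = taxa[[i]],
          reason = conditionMessage(rec), stringsAsFactors = FALSE)
        ok <- FALSE
      } else {
        seqs[[taxa[[i]]]] <- rec$seq
        prov[[length(prov) + 1L]] <- data.frame(
          region = spec$name, taxon = taxa[[i]],
          start = attr(rec, "start") %||% NA_integer_,
          end = attr(rec, "end") %||% NA_integer_,
          strand = attr(rec, "strand") %||% NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    if (ok) regions[[spec$name]] <- seqs
  }
  structure(list(
    regions = regions,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(region = character(0), taxon = character(0),
                 reason = character(0)),
    provenance = if (length(prov)) do.call(rbind, prov) else NULL),
    class = "region_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate alignments column-wise
#'
#' All alignments must share the same taxon set; rows are matched by label and
#' appended in list order. Partition boundaries are recorded in the
#' `partitions` attribute (0-based half-open column spans).
#'
#' @param alignments Ordered list of alignment matrices (possibly named).
#' @return One alignment matrix with a `partitions` attribute.
#' @export
concatenate_alignments <- function(alignments) {
  alignments <- alignments[vapply(alignments, ncol, 0L) >= 0L]
  if (!length(alignments)) stop("nothing to concatenate")
  taxa <- rownames(alignments[[1]])
  for (i in seq_along(alignments)) {
    ti <- rownames(alignments[[i]])
    if (!setequal(ti, taxa)) {
      diff <- c(setdiff(taxa, ti), setdiff(ti, taxa))
      stop("taxon set mismatch at alignment ", i, ": ",
           paste(diff, collapse = ", "))
    }
  }
  mats <- lapply(alignments, function(a) a[taxa, , drop = FALSE])
  out <- do.call(cbind, mats)
  widths <- vapply(alignments, ncol, 0L)
  ends <- cumsum(widths)
  attr(out, "partitions") <- data.frame(
    name = names(alignments) %||% paste0("part", seq_along(alignments)),
    start = c(0L, ends[-length(ends)]), end = ends,
    stringsAsFactors = FALSE)
  out
}

#' Read / write region specs as TSV
#'
#' Columns: `name`, `mode`, `parts` (comma-separated; empty for genes).
#'
#' @param path TSV path.
#' @return A list of [region_spec()]s (read) or `path` (write).
#' @export
read_region_specs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    parts <- if (is.na(df$parts[[i]]) || !nzchar(df$parts[[i]])) character(0)
             else strsplit(df$parts[[i]], ",", fixed = TRUE)[[1]]
    region_spec(df$name[[i]], df$mode[[i]], trimws(parts))
  })
}

#' @rdname read_region_specs
#' @param specs List of [region_spec()]s.
#' @export
write_region_specs <- function(specs, path) {
  df <- data.frame(
    name = vapply(specs, `[[`, "", "name"),
    mode = vapply(specs, `[[`, "", "mode"),
    parts = vapply(specs, function(s) paste(s$parts, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
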