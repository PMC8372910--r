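# Sequence containers and FASTA / GenBank flat-file I/O.
#
# Internal coordinates are 0-based half-open throughout the package; GenBank's
# 1-based inclusive convention is converted at the I/O boundary only.

DNA_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")
DNA_BASES <- c("A", "C", "G", "T")

#' Create a sequence record
#'
#' A sequence record holds one DNA sequence with a taxon/accession label and a
#' circularity flag. Sequences are stored uppercase and may contain IUPAC
#' ambiguity codes and gap characters.
#'
#' @param id Nonempty label, unique within any set of records.
#' @param seq DNA string over `A,C,G,T,N`, IUPAC ambiguity codes and `-`.
#' @param circular Logical; `TRUE` for circular molecules such as plastomes.
#' @return An object of class `seq_record` with fields `id`, `seq`, `circular`.
#' @export
seq_record <- function(id, seq, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a nonempty string")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence for '", id, "' must be a nonempty string")
  seq <- toupper(gsub("[[:space:]]", "", seq))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_ALPHABET)
  if (length(bad))
    stop("record '", id, "' contains invalid characters: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Handles IUPAC ambiguity codes; gaps are preserved.
#'
#' @param s A DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", toupper(s))
  vapply(comp, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file.
#' @param circular Circularity flag applied to all records.
#' @return A list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop("not a FASTA file (empty or missing '>' header): ", path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)   # first token is the label
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  if (length(seqs) != length(ids))
    stop("FASTA record without sequence in ", path)
  mapply(seq_record, ids, seqs,
         MoreArgs = list(circular = circular),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x A list of [seq_record()]s, or a named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.list(x) && length(x) && inherits(x[[1]], "seq_record")) {
    ids <- vapply(x, `[[`, "", "id"); seqs <- vapply(x, `[[`, "", "seq")
  } else if (is.character(x) && !is.null(names(x))) {
    ids <- names(x); seqs <- unname(x)
  } else stop("x must be seq_records or a named character vector")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build an alignment from equal-length sequences
#'
#' The alignment container is a character matrix (taxa x columns) with taxon
#' labels as rownames; all downstream statistics operate on it.
#'
#' @param seqs Named character vector of equal-length (gapped) sequences.
#' @return Character matrix with one row per taxon.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named")
  if (length(seqs) < 2L) stop("an alignment needs at least 2 taxa")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- names(seqs)[lens != lens[[1]]][[1]]
    stop("unequal row lengths: '", names(seqs)[[1]], "' has ", lens[[1]],
         " but '", off, "' has ", lens[nchar(seqs) != lens[[1]]][[1]])
  }
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to strings
#'
#' @param aln Character matrix alignment.
#' @return Named character vector of row strings.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}

#' Read a FASTA alignment
#'
#' @param path FASTA path with equal-length gapped rows.
#' @return Character matrix alignment (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  as_alignment(stats::setNames(vapply(recs, `[[`, "", "seq"),
                               vapply(recs, `[[`, "", "id")))
}

#' Write an alignment to FASTA
#'
#' @param aln Character matrix alignment.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  write_fasta(alignment_strings(aln), path, width = width)
}

#' Sanitize taxon labels for Newick output
#'
#' Replaces whitespace and Newick metacharacters with underscores and returns
#' a reversible mapping. The mapping can be written as a two-column TSV.
#'
#' @param labels Character vector of labels.
#' @return A data.frame with columns `original` and `sanitized`.
#' @export
sanitize_labels <- function(labels) {
  san <- gsub("[][[:space:](),;:']+", "_", labels)
  # de-duplicate collisions deterministically
  while (any(duplicated(san))) {
    i <- which(duplicated(san))[[1]]
    san[[i]] <- paste0(san[[i]], "_", i)
  }
  data.frame(original = labels, sanitized = san, stringsAsFactors = FALSE)
}

#' Write / read a label-mapping table
#'
#' @param map Data frame from [sanitize_labels()].
#' @param path TSV path.
#' @return `path` (write) or the mapping data frame (read).
#' @export
write_label_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# ---- features and annotated plastomes --------------------------------------

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "pseudogene", "other")

#' Create a feature table
#'
#' Features use 0-based half-open plus-strand coordinates. Multi-exon features
#' are rows sharing `name` and `copy`; duplicate copies of a gene (e.g. the two
#' inverted-repeat copies) are rows sharing `name` with distinct `copy` ids.
#'
#' @param name Feature label(s).
#' @param kind One of `PCG, tRNA, rRNA, pseudogene, other` (recycled).
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` (recycled).
#' @param copy Integer copy/exon-group id; defaults to one id per row.
#' @param part Exon part index within a copy (1 for single-exon features).
#' @return A `data.frame` feature table, sorted by `start`.
#' @export
feature_table <- function(name, kind = "other", start, end, strand = "+",
                          copy = seq_along(name), part = 1L) {
  ft <- data.frame(name = as.character(name),
                   kind = rep_len(kind, length(name)),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(strand, length(name)),
                   copy = rep_len(as.integer(copy), length(name)),
                   part = rep_len(as.integer(part), length(name)),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(ft$name))) stop("feature names must be nonempty")
  if (!all(ft$kind %in% FEATURE_KINDS))
    stop("feature kind must be one of: ", paste(FEATURE_KINDS, collapse = ", "))
  if (any(ft$start < 0L) || any(ft$start >= ft$end))
    stop("features need 0 <= start < end")
  if (!all(ft$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ft[order(ft$start, ft$part), , drop = FALSE]
}

#' Create an annotated plastome
#'
#' @param record A [seq_record()] (circular by default).
#' @param features A feature table from [feature_table()].
#' @return An object of class `plastome` with `record` and `features`.
#' @export
plastome <- function(record, features) {
  stopifnot(inherits(record, "seq_record"))
  n <- nchar(record$seq)
  if (nrow(features) && any(features$end > n))
    stop("feature '", features$name[features$end > n][[1]],
         "' extends past sequence end (", n, " bp)")
  features <- features[order(features$start, features$part), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(record = record, features = features), class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp, %d feature rows\n", x$record$id,
              nchar(x$record$seq), nrow(x$features)))
  invisible(x)
}

# ---- GenBank flat-file I/O --------------------------------------------------
# Minimal reader/writer for the feature-table subset the simulator emits:
# LOCUS, FEATURES with gene/CDS/tRNA/rRNA/misc_feature keys, /gene and /pseudo
# qualifiers, join() and complement() locations, ORIGIN block.

.gb_parse_location <- function(loc, name) {
  strand <- "+"
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", parts))
  single <- regmatches(parts, regexec("^([0-9]+)$", parts))
  out <- lapply(seq_along(parts), function(i) {
    if (length(m[[i]]) == 3L) {
      c(as.integer(m[[i]][[2]]) - 1L, as.integer(m[[i]][[3]]))
    } else if (length(single[[i]]) == 2L) {
      p <- as.integer(single[[i]][[2]]); c(p - 1L, p)
    } else stop("malformed location for feature '", name, "': ", loc)
  })
  list(strand = strand, parts = out)
}

#' Read a GenBank flat file as an annotated plastome
#'
#' Parses the sequence and the `gene`/`CDS`/`tRNA`/`rRNA`/`misc_feature`
#' entries of the feature table. 1-based inclusive GenBank coordinates are
#' converted to 0-based half-open; `join()` locations become exon parts sharing
#' a name and copy id; `complement()` sets the minus strand; `/pseudo` marks
#' the pseudogene kind. `gene` entries shadowed by a CDS/tRNA/rRNA of the same
#' name are dropped.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[[1]]), "[[:space:]]+")[[1]][[2]]
        else sub("\\.[^.]*$", "", basename(path))
  circular <- length(locus) && grepl("circular", locus[[1]], ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart))
    stop("not a GenBank flat file (missing FEATURES/ORIGIN): ", path)
  feat_lines <- lines[(fstart[[1]] + 1L):(ostart[[1]] - 1L)]
  seq_lines <- lines[(ostart[[1]] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z-]", "", paste(seq_lines, collapse = "")))

  # split the feature table into (key, location+qualifier) blocks
  is_key <- grepl("^ {5}[A-Za-z]", feat_lines)
  blocks <- split(feat_lines, cumsum(is_key))
  if (length(blocks) && !is_key[[1]]) blocks <- blocks[-1L]

  rows <- list(); copy_id <- 0L
  for (b in blocks) {
    key <- sub("^ {5}([A-Za-z_']+).*$", "\\1", b[[1]])
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "misc_feature")) next
    qual_start <- grep("^ {21}/", b)
    loc_end <- if (length(qual_start)) qual_start[[1]] - 1L else length(b)
    loc <- paste(trimws(sub("^ {5}[A-Za-z_']+", "", b[seq_len(loc_end)])),
                 collapse = "")
    quals <- trimws(b[grepl("^ {21}/", b)])
    gname <- sub('^/(gene|label)="?([^"]*)"?$', "\\2",
                 grep('^/(gene|label)=', quals, value = TRUE))
    gname <- if (length(gname)) gname[[1]] else key
    pseudo <- any(grepl("^/pseudo\\b", quals))
    parsed <- .gb_parse_location(loc, gname)
    kind <- if (pseudo) "pseudogene"
            else switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                        gene = "other", "other")
    copy_id <- copy_id + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      name = gname, kind = kind,
      start = vapply(parsed$parts, `[[`, 0L, 1L),
      end = vapply(parsed$parts, `[[`, 0L, 2L),
      strand = parsed$strand, copy = copy_id,
      part = seq_along(parsed$parts), stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    ft <- do.call(rbind, rows)
    # drop bare 'gene' rows shadowed by a typed feature of the same name
    typed <- unique(ft$name[ft$kind != "other"])
    ft <- ft[!(ft$kind == "other" & ft$name %in% typed), , drop = FALSE]
    ft <- feature_table(ft$name, ft$kind, ft$start, ft$end, ft$strand,
                        ft$copy, ft$part)
  } else {
    ft <- feature_table(character(0), character(0), integer(0), integer(0))
  }
  plastome(seq_record(id, seq, circular = circular), ft)
}

#' Write an annotated plastome as a GenBank flat file
#'
#' Minimal writer covering what [read_genbank()] parses; write-then-read
#' preserves sequence, feature names, kinds, coordinates and strands.
#'
#' @param p A [plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$record$seq)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     p$record$id, n,
                     if (p$record$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s plastome.", p$record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  ft <- p$features
  if (nrow(ft)) {
    for (cp in unique(ft$copy)) {
      rows <- ft[ft$copy == cp, , drop = FALSE]
      rows <- rows[order(rows$part), , drop = FALSE]
      key <- switch(rows$kind[[1]], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    pseudogene = "gene", "misc_feature")
      spans <- sprintf("%d..%d", rows$start + 1L, rows$end)
      loc <- if (length(spans) > 1L)
        sprintf("join(%s)", paste(spans, collapse = ",")) else spans
      if (rows$strand[[1]] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', rows$name[[1]]), con)
      if (rows$kind[[1]] == "pseudogene")
        writeLines("                     /pseudo", con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(p$record$seq)
  for (i in seq(1L, n, by = 60L)) {
    starts <- seq(i, min(i + 59L, n), by = 10L)
    chunk <- substring(s, starts, pmin(starts + 9L, n))
    writeLines(sprintf("%9d %s", i, paste(chunk, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
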