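# Structural analyses: parsimony mapping of gene loss / pseudogenization onto
# a tree, inverted-repeat boundary detection and junction-gene reporting.

GENE_STATES <- c("intact", "pseudogene", "absent")

#' Read / write a gene presence matrix
#'
#' TSV with taxa as rows and genes as columns; cell states are `1` (intact),
#' `P` (pseudogene), `0` (absent).
#'
#' @param path TSV path.
#' @return Character matrix of states (`intact`/`pseudogene`/`absent`) with
#'   taxa as rownames (read), or `path` (write).
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df)
  dec <- c(`1` = "intact", P = "pseudogene", `0` = "absent")
  bad <- setdiff(unique(as.vector(m)), names(dec))
  if (length(bad)) stop("invalid presence states: ", paste(bad, collapse = ", "))
  out <- matrix(dec[m], nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

#' @rdname read_presence_matrix
#' @param pm Character matrix of states.
#' @export
write_presence_matrix <- function(pm, path) {
  enc <- c(intact = "1", pseudogene = "P", absent = "0")
  m <- matrix(enc[pm], nrow(pm), ncol(pm), dimnames = dimnames(pm))
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.node_tip_sets <- function(t) {
  ntip <- length(t$tip.label)
  sets <- vector("list", ntip + t$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- t$tip.label[[i]]
  post <- ape::reorder.phylo(t, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Map gene loss / pseudogenization events onto a rooted tree by parsimony
#'
#' Unordered 3-state (intact / pseudogene / absent) parsimony with equal
#' costs. Per gene, a minimum-change assignment of states to internal nodes is
#' computed (Sankoff recursion); the root is fixed to `intact` whenever every
#' outgroup leaf is intact (otherwise the minimum-cost state, ties broken in
#' the order intact < pseudogene < absent). Among multiple most-parsimonious
#' assignments the one delaying changes toward the tips (DELTRAN: prefer the
#' parent's state when it attains the minimum) is reported and the number of
#' ambiguous nodes is logged per gene.
#'
#' @param tree Rooted `phylo` tree; leaves must appear in `pm`.
#' @param pm Presence matrix (taxa x genes) over
#'   `intact`/`pseudogene`/`absent`.
#' @param outgroup Optional outgroup leaf labels used to anchor the root
#'   state.
#' @return A list of class `event_map`: `events` (data.frame with columns
#'   `gene`, `node`, `tips_under_branch`, `from`, `to`), `changes_per_gene`
#'   (named integer vector), `ambiguous_nodes` (named integer vector), and
#'   `node_states` (matrix, nodes x genes).
#' @export
map_events <- function(tree, pm, outgroup = character(0)) {
  missing <- setdiff(tree$tip.label, rownames(pm))
  if (length(missing))
    stop("leaf missing from presence matrix: ",
         paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[[1]]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  tip_sets <- .node_tip_sets(tree)
  events <- list(); changes <- integer(0); ambig <- integer(0)
  node_states <- matrix(NA_character_, nn, ncol(pm),
                        dimnames = list(NULL, colnames(pm)))
  for (g in colnames(pm)) {
    # Sankoff bottom-up (equal unit costs over the three unordered states)
    subcost <- matrix(NA_real_, nn, 3L)
    rec <- function(node) {
      if (node <= ntip) {
        s <- pm[tree$tip.label[[node]], g]
        subcost[node, ] <<- ifelse(GENE_STATES == s, 0, Inf)
        return(invisible(NULL))
      }
      kids <- children[[as.character(node)]]
      for (k in kids) rec(k)
      total <- numeric(3L)
      for (si in 1:3) {
        tot <- 0
        for (k in kids)
          tot <- tot + min(subcost[k, ] + (seq_len(3L) != si))
        total[[si]] <- tot
      }
      subcost[node, ] <<- total
      invisible(NULL)
    }
    rec(root)
    og_intact <- length(outgroup) &&
      all(pm[intersect(outgroup, rownames(pm)), g] == "intact")
    root_state <- if (og_intact && length(intersect(outgroup,
                                                    tree$tip.label))) 1L
                  else which.min(subcost[root, ])
    n_amb <- 0L
    assign_states <- integer(nn)
    assign_states[[root]] <- root_state
    walk <- function(node) {
      if (node <= ntip) return(invisible(NULL))
      ps <- assign_states[[node]]
      for (k in children[[as.character(node)]]) {
        opts <- subcost[k, ] + (seq_len(3L) != ps)
        best <- which(opts == min(opts))
        if (length(best) > 1L) n_amb <<- n_amb + 1L
        pick <- if (ps %in% best) ps else best[[1]]  # DELTRAN preference
        assign_states[[k]] <<- pick
        walk(k)
      }
      invisible(NULL)
    }
    walk(root)
    node_states[, g] <- GENE_STATES[assign_states]
    ch_count <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      if (assign_states[[p]] != assign_states[[ch]]) {
        ch_count <- ch_count + 1L
        events[[length(events) + 1L]] <- data.frame(
          gene = g, node = ch,
          tips_under_branch = paste(sort(tip_sets[[ch]]), collapse = ";"),
          from = GENE_STATES[[assign_states[[p]]]],
          to = GENE_STATES[[assign_states[[ch]]]],
          stringsAsFactors = FALSE)
      }
    }
    changes[[g]] <- ch_count
    ambig[[g]] <- n_amb
  }
  structure(list(
    events = if (length(events)) do.call(rbind, events) else
      data.frame(gene = character(0), node = integer(0),
                 tips_under_branch = character(0), from = character(0),
                 to = character(0)),
    changes_per_gene = changes, ambiguous_nodes = ambig,
    node_states = node_states), class = "event_map")
}

# ---- inverted repeat detection ---------------------------------------------

#' Locate the inverted-repeat pair of a circular plastome
#'
#' Finds the longest pair of disjoint, maximal, exactly reverse-complementary
#' repeats of length >= `min_len` (seed-and-extend on exact k-mer matches
#' between the sequence and its reverse complement). The shorter arc between
#' the two copies is labeled SSC and the longer LSC. Coordinates are reported
#' rotated so that the LSC starts at position 0 (`origin_offset` records the
#' rotation applied; 0 when the input already starts at the LSC).
#'
#' @param record A [seq_record()] (circular sequence) or a [plastome()].
#' @param min_len Minimum IR length in bp (default 1000; plastome IRs are far
#'   longer, and the threshold avoids tRNA-scale false hits).
#' @return A list of class `ir_structure` with 0-based half-open spans `LSC`,
#'   `IRb`, `SSC`, `IRa` (tiling the rotated genome), `ir_length`, and
#'   `origin_offset`.
#' @export
find_ir <- function(record, min_len = 1000L) {
  if (inherits(record, "plastome")) record <- record$record
  s <- record$seq
  n <- nchar(s)
  rc <- revcomp(s)
  k <- min(31L, as.integer(min_len))
  if (n < 2L * min_len) stop("no IR detected (sequence too short)")
  starts <- seq_len(n - k + 1L)
  kS <- substring(s, starts, starts + k - 1L)
  kR <- substring(rc, starts, starts + k - 1L)
  posS <- split(starts, kS)
  posS <- posS[lengths(posS) <= 8L]   # low-complexity guard
  hitR <- which(kR %in% names(posS))
  if (!length(hitR)) stop("no IR detected")
  pairs_i <- integer(0); pairs_p <- integer(0)
  for (p in hitR) {
    is <- posS[[kR[[p]]]]
    pairs_i <- c(pairs_i, is)
    pairs_p <- c(pairs_p, rep.int(p, length(is)))
  }
  diag <- pairs_p - pairs_i
  best <- NULL
  for (dg in unique(diag)) {
    is <- sort(pairs_i[diag == dg])
    runs <- split(is, cumsum(c(1L, diff(is) != 1L)))
    for (run in runs) {
      L <- run[[length(run)]] - run[[1]] + k
      if (L < min_len) next
      a0 <- run[[1]] - 1L                 # 0-based start in s
      p0 <- run[[1]] + dg - 1L            # 0-based start in rc
      b0 <- n - p0 - L                    # corresponding 0-based start in s
      aspan <- c(a0, a0 + L); bspan <- c(b0, b0 + L)
      if (aspan[[1]] > bspan[[1]]) { tmp <- aspan; aspan <- bspan; bspan <- tmp }
      if (aspan[[2]] > bspan[[1]]) next   # overlapping (palindrome) hit
      if (is.null(best) || L > best$L)
        best <- list(L = L, a = aspan, b = bspan)
    }
  }
  if (is.null(best)) stop("no IR detected")
  gap_ab <- best$b[[1]] - best$a[[2]]            # arc between copies
  gap_ba <- n - best$b[[2]] + best$a[[1]]        # arc wrapping the origin
  # rotate so the (longer) LSC arc starts at 0
  if (gap_ab <= gap_ba) {
    # SSC is the arc between the copies; LSC wraps through the origin
    rot <- best$b[[2]] %% n
    lsc_len <- gap_ba
    spans <- list(LSC = c(0L, lsc_len),
                  IRb = c(lsc_len, lsc_len + best$L),
                  SSC = c(lsc_len + best$L, lsc_len + best$L + gap_ab),
                  IRa = c(lsc_len + best$L + gap_ab,
                          lsc_len + 2L * best$L + gap_ab))
  } else {
    # LSC is the arc between the copies; SSC wraps through the origin
    rot <- best$a[[2]]
    lsc_len <- gap_ab
    spans <- list(LSC = c(0L, lsc_len),
                  IRb = c(lsc_len, lsc_len + best$L),
                  SSC = c(lsc_len + best$L, lsc_len + best$L + gap_ba),
                  IRa = c(lsc_len + best$L + gap_ba,
                          lsc_len + 2L * best$L + gap_ba))
  }
  structure(c(spans, list(ir_length = best$L, origin_offset = rot %% n,
                          genome_length = n)),
            class = "ir_structure")
}

#' @export
print.ir_structure <- function(x, ...) {
  cat(sprintf(paste0("<ir_structure> LSC [%d,%d) IRb [%d,%d) SSC [%d,%d) ",
                     "IRa [%d,%d); IR %d bp; rotation %d\n"),
              x$LSC[[1]], x$LSC[[2]], x$IRb[[1]], x$IRb[[2]],
              x$SSC[[1]], x$SSC[[2]], x$IRa[[1]], x$IRa[[2]],
              x$ir_length, x$origin_offset))
  invisible(x)
}

#' Extract a span of an `ir_structure` from the original sequence
#'
#' @param record A [seq_record()] or [plastome()] the structure was computed
#'   from.
#' @param ir An [find_ir()] result.
#' @param span One of `"LSC"`, `"IRb"`, `"SSC"`, `"IRa"`.
#' @return The span's sequence (plus strand of the original coordinates).
#' @export
ir_span_seq <- function(record, ir, span = c("LSC", "IRb", "SSC", "IRa")) {
  span <- match.arg(span)
  if (inherits(record, "plastome")) record <- record$record
  n <- nchar(record$seq)
  sp <- ir[[span]]
  start <- (sp[[1]] + ir$origin_offset) %% n
  end <- (sp[[2]] + ir$origin_offset) %% n
  if (end == 0L) end <- n
  .circ_slice(record$seq, start, end, n)
}

.feature_groups <- function(p) {
  ft <- p$features
  split(ft, paste(ft$name, ft$copy, sep = "\r"))
}

#' Report the features spanning each IR junction
#'
#' For each of the four junctions (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) the
#' features whose span contains the junction are reported with the 0-based
#' offset of the junction into the feature. Features crossing the origin
#' (represented as same-name parts abutting positions 0 and genome length)
#' are handled. Junctions in intergenic space yield no rows.
#'
#' @param p A [plastome()].
#' @param ir An [find_ir()] result for `p`'s sequence.
#' @return A data.frame with columns `junction`, `name`, `kind`, `offset`.
#' @export
junction_genes <- function(p, ir) {
  n <- nchar(p$record$seq)
  # junction coordinates in original (unrotated) coordinates
  jx <- c(`LSC/IRb` = (ir$IRb[[1]] + ir$origin_offset) %% n,
          `IRb/SSC` = (ir$SSC[[1]] + ir$origin_offset) %% n,
          `SSC/IRa` = (ir$IRa[[1]] + ir$origin_offset) %% n,
          `IRa/LSC` = ir$origin_offset %% n)
  rows <- list()
  for (grp in .feature_groups(p)) {
    grp <- grp[order(grp$part), , drop = FALSE]
    covered <- unlist(lapply(seq_len(nrow(grp)), function(i)
      seq.int(grp$start[[i]], grp$end[[i]] - 1L)))
    for (jn in names(jx)) {
      c0 <- jx[[jn]]
      before <- (c0 - 1L) %% n
      if ((c0 %in% covered) && (before %in% covered)) {
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, name = grp$name[[1]], kind = grp$kind[[1]],
          offset = match(c0, covered) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(junction = character(0), name = character(0),
                      kind = character(0), offset = integer(0)))
  out <- do.call(rbind, rows)
  out[order(match(out$junction, names(jx)), out$name), , drop = FALSE]
}
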