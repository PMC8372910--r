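# The six-point phylogenetic utility test: per-clade monophyly indicators
# plus a backbone-topology point, and ranking of candidate regions.

#' Score a candidate region tree against the reference topology
#'
#' Each named clade contributes one 0/1 monophyly indicator (with the
#' canonical five-clade definition: clades I-IV plus the near-outgroup genus,
#' five points) and the overall-backbone match contributes one more, for a
#' maximum score of `length(clades$clades) + 1` (six with five clades).
#' Excluded taxa are pruned before any scoring; monophyly is assessed on the
#' candidate rooted by the designated outgroup. When the outgroup itself is
#' not separable on the candidate, the tree is rooted on the first outgroup
#' taxon instead and any clade equal to the outgroup set scores 0.
#'
#' @param candidate Candidate region tree (`phylo`).
#' @param reference Reference (e.g. whole-plastome) tree (`phylo`).
#' @param clades A [clade_definition()].
#' @param region Optional region label carried into the result.
#' @param alignment_length,prop_pi Optional region statistics carried into the
#'   result (used for ranking tie-breaks).
#' @return An object of class `utility_score`: list with `region`,
#'   `indicators` (named 0/1 vector per clade), `topology` (0/1), `total`,
#'   `alignment_length`, `prop_pi`.
#' @export
score_region <- function(candidate, reference, clades, region = NA_character_,
                         alignment_length = NA_integer_, prop_pi = NA_real_) {
  need <- c(unlist(clades$clades, use.names = FALSE), clades$outgroup)
  missing <- setdiff(need, candidate$tip.label)
  if (length(missing))
    stop("candidate tree is missing taxa: ", paste(missing, collapse = ", "))
  cand <- .prune(candidate, clades$excluded)
  rooted <- .root_or_null(cand, clades$outgroup)
  og_fallback <- is.null(rooted)
  if (og_fallback)
    rooted <- root_with_outgroup(cand, sort(clades$outgroup)[[1]])
  indicators <- vapply(clades$clades, function(set) {
    if (og_fallback && setequal(set, clades$outgroup)) return(0L)
    as.integer(is_monophyletic(rooted, set))
  }, 0L)
  topo <- as.integer(backbone_match(candidate, reference, clades))
  structure(list(region = region, indicators = indicators, topology = topo,
                 total = sum(indicators) + topo,
                 alignment_length = alignment_length, prop_pi = prop_pi),
            class = "utility_score")
}

#' @export
print.utility_score <- function(x, ...) {
  cat(sprintf("<utility_score> %s: total %d/%d (%s; topology %d)\n",
              x$region %||% "?", x$total, length(x$indicators) + 1L,
              paste(names(x$indicators), x$indicators, sep = "=",
                    collapse = " "), x$topology))
  invisible(x)
}

#' Rank scored regions
#'
#' Sorted by total score (descending), then proportion of
#' parsimony-informative sites (descending), then region name; emits a
#' Table-1-shaped data frame: region, alignment length, proportion PI, one
#' column per clade indicator, topology, total.
#'
#' @param scores List of [score_region()] results.
#' @return A data.frame, one row per region, best first.
#' @export
rank_regions <- function(scores) {
  if (!length(scores)) stop("need at least one score")
  regions <- vapply(scores, `[[`, "", "region")
  if (anyDuplicated(regions))
    stop("duplicate region names: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  ind <- do.call(rbind, lapply(scores, `[[`, "indicators"))
  df <- data.frame(region = regions,
                   alignment_length = vapply(scores, `[[`, 0L,
                                             "alignment_length"),
                   prop_pi = vapply(scores, `[[`, 0, "prop_pi"),
                   ind,
                   topology = vapply(scores, `[[`, 0L, "topology"),
                   total = vapply(scores, `[[`, 0L, "total"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  pi_key <- ifelse(is.na(df$prop_pi), -Inf, df$prop_pi)
  df <- df[order(-df$total, -pi_key, df$region), , drop = FALSE]
  rownames(df) <- NULL
  df
}
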