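# Per-taxon response to PMA treatment: the normalized abundance change
# between PMA-free and PMA-treated arms of a sample type, the accompanying
# fold ratio used to flag >100-fold shifts, and the cross-type ranking of
# PMA-responsive (largest changes) and PMA-resilient (smallest) taxa.

#' Per-taxon normalized abundance change for one sample type
#'
#' For each taxon, `abund_free` and `abund_pma` are arithmetic means of its
#' relative abundance over the type's PMA-free and PMA-treated samples.
#' The normalized change is
#' `(abund_free - abund_pma) / max(abund_free, floor)` — positive when the
#' taxon is depleted by treatment. The fold ratio is
#' `max(abund_free, floor) / max(abund_pma, floor)` or its reciprocal,
#' whichever is >= 1; `large_change` flags ratios above 100. Taxa whose mean
#' is zero in one arm are censored (`undetectable_before` /
#' `undetectable_after`) rather than dropped, with the floor standing in for
#' the undetectable mean.
#'
#' @param table an [abundance_table] (counts are converted per sample).
#' @param meta sample metadata data.frame.
#' @param sample_type which type to analyse; both arms must be present.
#' @param floor detection floor for zero means (default 1e-6, one order
#'   below the smallest relative abundance of practical interest, ~1e-5).
#' @return data.frame with columns `taxon_id`, `sample_type`, `abund_free`,
#'   `abund_pma`, `change`, `ratio`, `censored`, `large_change`.
#' @export
fold_change <- function(table, meta, sample_type, floor = 1e-6) {
  stopifnot(inherits(table, "abundance_table"), floor > 0)
  rel <- to_relative(table)
  msub <- meta[meta$sample_type == sample_type, , drop = FALSE]
  free_ids <- intersect(msub$sample_id[!msub$pma_treated], sample_ids(rel))
  pma_ids <- intersect(msub$sample_id[msub$pma_treated], sample_ids(rel))
  if (length(free_ids) == 0) stop("missing PMA-free arm for type '", sample_type, "'")
  if (length(pma_ids) == 0) stop("missing PMA-treated arm for type '", sample_type, "'")
  free <- colMeans(rel$values[free_ids, , drop = FALSE])
  pma <- colMeans(rel$values[pma_ids, , drop = FALSE])
  change <- (free - pma) / pmax(free, floor)
  r <- pmax(free, floor) / pmax(pma, floor)
  ratio <- pmax(r, 1 / r)
  censored <- ifelse(free == 0, "undetectable_before",
                     ifelse(pma == 0, "undetectable_after", "none"))
  data.frame(taxon_id = taxon_ids(rel), sample_type = sample_type,
             abund_free = unname(free), abund_pma = unname(pma),
             change = unname(change), ratio = unname(ratio),
             censored = unname(censored),
             large_change = unname(ratio > 100),
             row.names = NULL)
}

#' Rank PMA-responsive and PMA-resilient taxa across sample types
#'
#' Each taxon is scored by the mean of `|change|` over the sample types in
#' which it is detected in at least one arm. Taxa scored in at least
#' `min_types` types are eligible; the `top_n` with the largest scores form
#' the responsive list (descending) and, among the remaining eligible taxa,
#' the `top_n` smallest form the resilient list (ascending). Ties break
#' lexicographically by taxon ID, so the ranking is deterministic.
#'
#' @param records row-bound output of [fold_change()] over one or more
#'   sample types.
#' @param top_n list length cap (default 30).
#' @param min_types minimum number of sample types a taxon must be scored
#'   in (default 2).
#' @return a `response_ranking`: list with `responsive`, `resilient`
#'   (character vectors), and `scores` (per-taxon data.frame with
#'   `mean_abs_change` and `n_types`).
#' @export
rank_responses <- function(records, top_n = 30, min_types = 2) {
  stopifnot(is.data.frame(records), top_n >= 1, min_types >= 1)
  detected <- records$abund_free > 0 | records$abund_pma > 0
  rec <- records[detected, , drop = FALSE]
  if (nrow(rec) == 0)
    return(structure(list(responsive = character(0), resilient = character(0),
                          scores = data.frame(taxon_id = character(0),
                                              mean_abs_change = numeric(0),
                                              n_types = integer(0)),
                          top_n = top_n, min_types = min_types),
                     class = "response_ranking"))
  sc <- stats::aggregate(abs(rec$change),
                         by = list(taxon_id = rec$taxon_id), FUN = mean)
  names(sc)[2] <- "mean_abs_change"
  nt <- stats::aggregate(rec$sample_type,
                         by = list(taxon_id = rec$taxon_id),
                         FUN = function(x) length(unique(x)))
  sc$n_types <- nt$x[match(sc$taxon_id, nt$taxon_id)]
  eligible <- sc[sc$n_types >= min_types, , drop = FALSE]
  ord_desc <- eligible[order(-eligible$mean_abs_change, eligible$taxon_id), ]
  responsive <- utils::head(ord_desc$taxon_id, top_n)
  rest <- eligible[!(eligible$taxon_id %in% responsive), , drop = FALSE]
  ord_asc <- rest[order(rest$mean_abs_change, rest$taxon_id), ]
  resilient <- utils::head(ord_asc$taxon_id, top_n)
  structure(list(responsive = responsive, resilient = resilient,
                 scores = sc[order(sc$taxon_id), ],
                 top_n = top_n, min_types = min_types),
            class = "response_ranking")
}

#' @export
print.response_ranking <- function(x, ...) {
  cat(sprintf("response_ranking (top_n = %d, min_types = %d)\n",
              x$top_n, x$min_types))
  show <- function(lbl, ids) {
    cat(sprintf("  %s (%d): %s%s\n", lbl, length(ids),
                paste(utils::head(ids, 5), collapse = ", "),
                if (length(ids) > 5) ", ..." else ""))
  }
  show("PMA-responsive", x$responsive)
  show("PMA-resilient", x$resilient)
  invisible(x)
}
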