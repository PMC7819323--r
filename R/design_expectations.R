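# Deterministic arithmetic for designed mixtures: what composition an ideal
# PMA treatment (all dead-cell signal removed, no live cell touched) should
# leave, and how far an observed profile sits from it.

#' Expected composition after ideal PMA treatment
#'
#' Under ideal treatment every dead component disappears and live
#' components are untouched, so the expected profile is the live cell
#' fractions renormalized. With `copy_weighted = TRUE` the weights are live
#' cell fraction times 16S copy number before renormalizing, which is what
#' an amplicon readout converges to. `expected_signal_reduction` is the dead
#' share of the pre-treatment community (copy-weighted if flagged) — the
#' fraction of amplifiable signal the treatment should remove.
#'
#' @param design a [community_design].
#' @param copy_weighted weight fractions by 16S copy number.
#' @return an `expected_profile`: list with `fractions` (named, summing to 1
#'   unless empty), `empty` (TRUE iff all components are dead or the design
#'   has no cells), and `expected_signal_reduction` in [0, 1].
#' @export
expected_post_pma <- function(design, copy_weighted = FALSE) {
  stopifnot(inherits(design, "community_design"))
  comp <- design$components
  weight <- function(rows) {
    w <- rows$cell_fraction
    if (copy_weighted) w <- w * design$copy_number[rows$taxon_id]
    tapply(w, rows$taxon_id, sum)
  }
  if (nrow(comp) == 0) {
    return(structure(list(fractions = stats::setNames(numeric(0), character(0)),
                          empty = TRUE, expected_signal_reduction = 1),
                     class = "expected_profile"))
  }
  total_w <- sum(weight(comp))
  live <- comp[comp$state == "live", , drop = FALSE]
  if (nrow(live) == 0) {
    return(structure(list(fractions = stats::setNames(numeric(0), character(0)),
                          empty = TRUE, expected_signal_reduction = 1),
                     class = "expected_profile"))
  }
  lw <- weight(live)
  fractions <- lw / sum(lw)
  reduction <- 1 - sum(lw) / total_w
  structure(list(fractions = c(fractions), empty = FALSE,
                 expected_signal_reduction = reduction),
            class = "expected_profile")
}

#' @export
print.expected_profile <- function(x, ...) {
  if (x$empty) {
    cat("expected_profile: empty (no viable signal expected after treatment)\n")
  } else {
    cat("expected_profile:\n")
    for (t in names(x$fractions))
      cat(sprintf("  %-40s %6.2f%%\n", t, 100 * x$fractions[t]))
  }
  cat(sprintf("expected signal reduction: %.1f%%\n",
              100 * x$expected_signal_reduction))
  invisible(x)
}

#' Deviation of an observed profile from an expectation
#'
#' Per-taxon absolute deviations and the total variation distance
#' `TV = 0.5 * sum(|obs - exp|)` between an observed sample's relative
#' abundances and an expected profile, over the union of their taxa. For an
#' empty expected profile the comparison reports instead the total observed
#' read mass on the design's taxa (any signal is excess).
#'
#' @param observed an [abundance_table]; `sample` selects the row (default
#'   first).
#' @param expected an `expected_profile` from [expected_post_pma()].
#' @param sample sample ID or index.
#' @return list with `deviations` (named numeric) and `tv_distance`.
#' @export
compare_observed_expected <- function(observed, expected, sample = 1) {
  stopifnot(inherits(observed, "abundance_table"),
            inherits(expected, "expected_profile"))
  obs <- to_relative(observed)$values[sample, , drop = FALSE]
  obs <- stats::setNames(as.numeric(obs), colnames(obs))
  if (expected$empty) {
    dev <- obs[obs > 0]
    return(list(deviations = dev, tv_distance = NA_real_,
                observed_mass = sum(obs)))
  }
  taxa <- union(names(obs), names(expected$fractions))
  o <- stats::setNames(numeric(length(taxa)), taxa)
  e <- o
  o[names(obs)] <- obs
  e[names(expected$fractions)] <- expected$fractions
  dev <- abs(o - e)
  list(deviations = dev, tv_distance = 0.5 * sum(dev))
}
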