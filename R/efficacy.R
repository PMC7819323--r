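# The spike-in PMA efficacy statistic. A known 1:1 live:dead reference
# culture is spiked into each community; over the four arms of the
# (spike x treatment) factorial the per-arm signal is
#   mean(reference relative abundance) * mean(log10 16S copies by qPCR)
# and efficacy = 1 - (D - B)/(C - A). Exactly the dead half of the spike
# removed gives 0.5; below 0.5 means incomplete relic-DNA depletion, above
# 0.5 toxicity to viable cells. Values outside [0, 1] are possible and are
# deliberately not clamped.

#' Four-arm spike-in signal quadruplet
#'
#' @param A,B,C,D arm signals: A = plain, B = PMA-treated, C = spiked,
#'   D = spiked + PMA-treated. All finite and non-negative.
#' @param sample_type,reference_taxon optional labels carried along.
#' @return a `quadruplet_signal` object.
#' @export
quadruplet_signal <- function(A, B, C, D, sample_type = NA_character_,
                              reference_taxon = NA_character_) {
  v <- c(A = A, B = B, C = C, D = D)
  if (any(!is.finite(v))) stop("arm signals must be finite")
  if (any(v < 0)) stop("arm signals must be non-negative")
  structure(list(A = A, B = B, C = C, D = D, sample_type = sample_type,
                 reference_taxon = reference_taxon),
            class = "quadruplet_signal")
}

#' @export
print.quadruplet_signal <- function(x, ...) {
  cat(sprintf("quadruplet_signal%s: A=%.4g B=%.4g C=%.4g D=%.4g\n",
              if (is.na(x$sample_type)) "" else paste0(" [", x$sample_type, "]"),
              x$A, x$B, x$C, x$D))
  invisible(x)
}

.classify_efficacy <- function(value, tolerance = 0.05) {
  if (is.na(value)) return("undefined")
  if (abs(value - 0.5) <= tolerance) return("ideal")
  if (value < 0.5) return("incomplete")
  "toxic"
}

#' PMA efficacy from a signal quadruplet
#'
#' `efficacy = 1 - (D - B)/(C - A)`: the removed fraction of the spiked
#' reference signal, net of background. Requires a positive spike signal
#' (`C > A`). The value is not clamped — estimates slightly above 1 (all
#' spike signal plus some background removed) or below 0 do occur.
#'
#' @param q a [quadruplet_signal].
#' @param tolerance half-width of the band around 0.5 classified as
#'   `"ideal"`; below it is `"incomplete"` (relic DNA left behind), above it
#'   `"toxic"` (viable cells removed).
#' @return an `efficacy_estimate`: list with `value`, `classification`,
#'   `reference_taxon`, `sample_type`, `signal`.
#' @export
pma_efficacy <- function(q, tolerance = 0.05) {
  stopifnot(inherits(q, "quadruplet_signal"))
  if (q$C <= q$A)
    stop("undefined efficacy: spike signal not detected above background (C <= A)")
  value <- 1 - (q$D - q$B) / (q$C - q$A)
  structure(list(value = value,
                 classification = .classify_efficacy(value, tolerance),
                 reference_taxon = q$reference_taxon,
                 sample_type = q$sample_type, signal = q),
            class = "efficacy_estimate")
}

#' @export
print.efficacy_estimate <- function(x, ...) {
  cat(sprintf("PMA efficacy%s: %s (%s)\n",
              if (is.na(x$sample_type)) "" else paste0(" [", x$sample_type, "]"),
              if (is.na(x$value)) "undefined" else sprintf("%.3f", x$value),
              x$classification))
  invisible(x)
}

.match_reference_taxa <- function(table, reference_taxon) {
  ids <- taxon_ids(table)
  hay <- ids
  if (!is.null(table$taxonomy)) {
    tx <- table$taxonomy[ids]
    hay <- ifelse(is.na(tx) | !nzchar(tx), ids, paste(ids, tx, sep = ";"))
  }
  hit <- grepl(tolower(reference_taxon), tolower(hay), fixed = TRUE)
  ids[hit]
}

#' Build the efficacy quadruplet for one sample type
#'
#' For each arm of the factorial, the signal is the mean relative abundance
#' of the reference taxon over that arm's samples times the mean log10 16S
#' copies from qPCR (mean of each factor, not mean of products). The
#' reference is matched case-insensitively as a substring of the taxon ID or
#' its lineage at any rank, so `"Enterobacteriaceae"` aggregates the whole
#' family. Below-detection qPCR entries contribute 0 to the copy mean.
#'
#' @param table an [abundance_table] covering the type's samples.
#' @param meta sample metadata data.frame (see [read_sample_metadata()]).
#' @param qpcr qPCR totals data.frame (see [read_qpcr_table()]).
#' @param sample_type which type to build.
#' @param reference_taxon lineage substring identifying the spiked
#'   reference.
#' @return a [quadruplet_signal].
#' @export
build_quadruplet <- function(table, meta, qpcr, sample_type,
                             reference_taxon = "Enterobacteriaceae") {
  stopifnot(inherits(table, "abundance_table"))
  rel <- to_relative(table)
  ref_ids <- .match_reference_taxa(rel, reference_taxon)
  if (length(ref_ids) == 0)
    stop("reference taxon '", reference_taxon, "' not found in taxon namespace")
  msub <- meta[meta$sample_type == sample_type, , drop = FALSE]
  if (nrow(msub) == 0) stop("no samples of type '", sample_type, "'")
  arms <- list(A = c(FALSE, FALSE), B = c(FALSE, TRUE),
               C = c(TRUE, FALSE), D = c(TRUE, TRUE))
  arm_labels <- c(A = "plain", B = "PMA-treated", C = "spiked",
                  D = "spiked+PMA-treated")
  sig <- numeric(4)
  names(sig) <- names(arms)
  for (a in names(arms)) {
    sel <- msub$spiked == arms[[a]][1] & msub$pma_treated == arms[[a]][2]
    sids <- msub$sample_id[sel]
    if (length(sids) == 0)
      stop("missing arm for type '", sample_type, "': ", arm_labels[a])
    sids_in <- intersect(sids, sample_ids(rel))
    if (length(sids_in) == 0)
      stop("arm '", arm_labels[a], "' samples absent from abundance table")
    abund <- rowSums(rel$values[sids_in, ref_ids, drop = FALSE])
    qsub <- qpcr[match(sids_in, qpcr$sample_id), , drop = FALSE]
    if (anyNA(qsub$sample_id))
      stop("qPCR values missing for arm '", arm_labels[a], "'")
    copies <- ifelse(qsub$below_detection, 0, qsub$copies_log10)
    sig[a] <- mean(abund) * mean(copies)
  }
  quadruplet_signal(sig[["A"]], sig[["B"]], sig[["C"]], sig[["D"]],
                    sample_type = sample_type,
                    reference_taxon = reference_taxon)
}

#' Per-sample-type PMA efficacies
#'
#' Applies [build_quadruplet()] + [pma_efficacy()] independently to every
#' sample type in the metadata. Types whose efficacy is undefined (missing
#' arm, or spike not detected above background) are reported with an NA
#' value and classification `"undefined"` rather than dropped.
#'
#' @inheritParams build_quadruplet
#' @param tolerance passed to [pma_efficacy()].
#' @return an `efficacy_set`: named list of `efficacy_estimate` objects.
#' @export
efficacy_by_type <- function(table, meta, qpcr,
                             reference_taxon = "Enterobacteriaceae",
                             tolerance = 0.05) {
  types <- unique(meta$sample_type)
  out <- lapply(types, function(tt) {
    tryCatch(
      pma_efficacy(build_quadruplet(table, meta, qpcr, tt, reference_taxon),
                   tolerance = tolerance),
      error = function(e) {
        structure(list(value = NA_real_, classification = "undefined",
                       reference_taxon = reference_taxon, sample_type = tt,
                       signal = NULL, message = conditionMessage(e)),
                  class = "efficacy_estimate")
      })
  })
  names(out) <- types
  structure(out, class = "efficacy_set")
}

#' @export
print.efficacy_set <- function(x, ...) {
  cat("PMA efficacy by sample type:\n")
  for (e in x) {
    cat(sprintf("  %-12s %s (%s)\n", e$sample_type,
                if (is.na(e$value)) "undefined" else sprintf("%.3f", e$value),
                e$classification))
  }
  invisible(x)
}

#' @export
summary.efficacy_set <- function(object, ...) {
  data.frame(sample_type = vapply(object, function(e) e$sample_type, character(1)),
             efficacy = vapply(object, function(e) e$value, numeric(1)),
             classification = vapply(object, function(e) e$classification,
                                     character(1)),
             row.names = NULL)
}
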