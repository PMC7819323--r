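#' Samples-by-taxa abundance table
#'
#' The central container of the package: a numeric matrix with samples as
#' rows and taxa as columns, either raw read counts (`mode = "counts"`) or
#' per-sample relative abundances (`mode = "relative"`), optionally carrying
#' a Greengenes-style lineage string per taxon.
#'
#' @param values numeric matrix, samples x taxa, non-negative. Row names are
#'   sample IDs, column names taxon IDs (both required and unique).
#' @param mode `"counts"` or `"relative"`; if `NULL`, inferred: a matrix of
#'   whole numbers is treated as counts, anything else as relative.
#' @param taxonomy optional named character vector mapping taxon IDs to
#'   semicolon-separated lineage strings (`k__...;p__...;...`).
#' @param tol tolerance on per-sample sums for relative tables. All-zero
#'   rows are allowed (samples with no signal) and flagged empty.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `mode`, `taxonomy`.
#' @export
abundance_table <- function(values, mode = NULL, taxonomy = NULL, tol = 1e-5) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have sample IDs as row names")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have taxon IDs as column names")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (is.null(mode)) {
    mode <- if (all(abs(values - round(values)) < 1e-9)) "counts" else "relative"
  }
  mode <- match.arg(mode, c("counts", "relative"))
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(rs > 0 & abs(rs - 1) > tol)
    if (length(bad) > 0)
      stop("relative abundance rows do not sum to 1: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[colnames(values)]
    names(taxonomy) <- colnames(values)
  }
  structure(list(values = values, mode = mode, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s%s)\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  empt <- sum(rowSums(x$values) == 0)
  if (empt > 0) cat(sprintf("  %d empty sample(s)\n", empt))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample and taxon identifiers
#' @param table an [abundance_table]
#' @return character vector of IDs.
#' @export
sample_ids <- function(table) rownames(table$values)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table$values)

#' Convert a count table to relative abundances
#'
#' Each sample (row) is divided by its total. All-zero samples stay all-zero
#' rather than becoming NaN; they represent "no signal" libraries.
#'
#' @param table an [abundance_table]
#' @return an [abundance_table] in relative mode.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  v <- table$values
  tot <- rowSums(v)
  nz <- tot > 0
  v[nz, ] <- v[nz, , drop = FALSE] / tot[nz]
  abundance_table(v, mode = "relative", taxonomy = table$taxonomy)
}
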