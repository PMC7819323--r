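# IO for abundance tables, sample metadata and qPCR totals, plus the two
# table-preparation steps used throughout: genus collapsing and the
# prevalence/abundance filter.

#' Read an abundance table
#'
#' Reads a taxa-as-rows table into an [abundance_table]. The TSV dialect is
#' UTF-8, tab-separated, first header cell `#OTU ID` (a plain taxon-ID
#' header is also accepted), one column per sample, and an optional final
#' `taxonomy` column holding semicolon-separated lineages. BIOM 1.0 JSON is
#' accepted read-only through the biomformat package.
#'
#' Mode is inferred from the values: whole numbers are counts, anything else
#' relative (per-sample sums then checked against 1).
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom_json"`.
#' @return an [abundance_table].
#' @seealso [write_abundance_table()]
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM JSON requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    taxonomy <- NULL
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    if (!is.null(om)) {
      if (is.data.frame(om)) {
        taxonomy <- apply(om, 1, paste, collapse = ";")
      } else if (is.list(om)) {
        taxonomy <- vapply(om, function(x) paste(unlist(x), collapse = ";"), character(1))
      }
      names(taxonomy) <- rownames(m)
    }
    return(abundance_table(t(m), taxonomy = taxonomy))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("table must have a taxon-ID column and at least one sample")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate taxon IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy <- NULL
  datacols <- names(df)[-1]
  if (tolower(datacols[length(datacols)]) == "taxonomy") {
    taxonomy <- df[[length(datacols) + 1]]
    names(taxonomy) <- ids
    datacols <- datacols[-length(datacols)]
  }
  if (length(datacols) == 0) stop("no sample columns in ", path)
  if (anyDuplicated(datacols))
    stop("duplicate sample IDs: ",
         paste(unique(datacols[duplicated(datacols)]), collapse = ", "))
  m <- vapply(datacols, function(cn) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(x)) {
      i <- which(is.na(x))[1]
      stop(sprintf("non-numeric value '%s' at taxon '%s', sample '%s'",
                   df[[cn]][i], ids[i], cn))
    }
    x
  }, numeric(length(ids)))
  m <- matrix(m, nrow = length(ids), dimnames = list(ids, datacols))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 ids[neg[1, 1]], datacols[neg[1, 2]]))
  abundance_table(t(m), taxonomy = taxonomy)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()] for the TSV dialect: taxa as rows in
#' input order, `#OTU ID` header, optional trailing `taxonomy` column.
#' Counts are written as integers and relative abundances with 17
#' significant digits, so a read/write round trip reproduces the values
#' bit-exactly.
#'
#' @param table an [abundance_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  m <- t(table$values)  # taxa x samples
  fmt <- if (table$mode == "counts") {
    function(x) sprintf("%d", as.integer(round(x)))
  } else {
    function(x) sprintf("%.17g", x)
  }
  body <- apply(m, 2, fmt)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  lines <- apply(cbind(rownames(m), body), 1, paste, collapse = "\t")
  header <- paste(c("#OTU ID", colnames(m)), collapse = "\t")
  if (!is.null(table$taxonomy)) {
    header <- paste(header, "taxonomy", sep = "\t")
    lines <- paste(lines, table$taxonomy[rownames(m)], sep = "\t")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

# ---- lineage handling -------------------------------------------------------

.rank_prefixes <- c("k", "p", "c", "o", "f", "g", "s")

# Parse "k__Bacteria;p__...;g__Escherichia" into a named vector of assigned
# ranks; empty assignments ("g__") and missing ranks are dropped.
.parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  out <- character(0)
  for (p in parts) {
    if (grepl("^[a-z]__", p)) {
      rank <- substr(p, 1, 1)
      name <- substring(p, 4)
      if (nzchar(name)) out[rank] <- name
    } else if (nzchar(p)) {
      # bare name with no rank prefix: treat as progressively deeper ranks
      rank <- .rank_prefixes[length(out) + 1]
      out[rank] <- p
    }
  }
  out
}

#' Collapse OTUs to genus level
#'
#' OTUs are condensed to their genus; when a genus is not assigned, the OTU
#' is summed at its terminal (deepest assigned) taxonomic level instead.
#' Collapsed taxa are labelled with Greengenes-style rank prefixes
#' (`g__Escherichia`, `f__Enterobacteriaceae`, ...). Per-sample totals are
#' conserved exactly.
#'
#' @param table an [abundance_table] with taxonomy for every OTU.
#' @return an [abundance_table] over collapsed taxa; the taxonomy slot holds
#'   each collapsed clade's lineage truncated at its terminal rank.
#' @export
collapse_to_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy))
    stop("collapse_to_genus requires taxonomy")
  missing <- taxon_ids(table)[is.na(table$taxonomy) | !nzchar(table$taxonomy)]
  if (length(missing) > 0)
    stop("missing taxonomy for OTU(s): ", paste(missing, collapse = ", "))
  parsed <- lapply(table$taxonomy, .parse_lineage)
  labels <- character(length(parsed))
  lineages <- character(length(parsed))
  for (i in seq_along(parsed)) {
    ranks <- parsed[[i]]
    # genus if assigned, otherwise the deepest assigned rank above genus
    usable <- ranks[names(ranks) %in% .rank_prefixes[1:6]]
    if (length(usable) == 0)
      stop("OTU '", taxon_ids(table)[i], "' has no assigned rank in lineage '",
           table$taxonomy[i], "'")
    if ("g" %in% names(usable)) {
      labels[i] <- paste0("g__", usable[["g"]])
    } else {
      term <- names(usable)[length(usable)]
      labels[i] <- paste0(term, "__", usable[[term]])
    }
    keep <- seq_len(match(names(usable)[length(usable)], .rank_prefixes))
    pres <- .rank_prefixes[keep]
    lineages[i] <- paste(paste0(pres, "__",
                                ifelse(pres %in% names(ranks), ranks[pres], "")),
                         collapse = ";")
  }
  uniq <- unique(labels)
  v <- table$values
  out <- matrix(0, nrow = nrow(v), ncol = length(uniq),
                dimnames = list(rownames(v), uniq))
  for (j in seq_along(labels)) out[, labels[j]] <- out[, labels[j]] + v[, j]
  tax <- lineages[match(uniq, labels)]
  names(tax) <- uniq
  abundance_table(out, mode = table$mode, taxonomy = tax, tol = Inf)
}

#' Prevalence/abundance filter parameters
#'
#' Defaults encode the standard amplicon-survey filter: a taxon is kept when
#' its relative abundance strictly exceeds 0.01% (`min_rel_abund = 1e-4`) in
#' at least 10% of all samples (`min_prevalence = 0.10`, counted as
#' `ceiling(min_prevalence * n_samples)` samples).
#'
#' @param min_rel_abund strict lower bound on relative abundance.
#' @param min_prevalence required fraction of samples.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_rel_abund = 1e-4, min_prevalence = 0.10) {
  stopifnot(min_rel_abund >= 0, min_rel_abund < 1,
            min_prevalence > 0, min_prevalence <= 1)
  structure(list(min_rel_abund = min_rel_abund, min_prevalence = min_prevalence),
            class = "filter_params")
}

#' Filter rare, low-prevalence taxa
#'
#' A taxon is kept iff the number of samples where its relative abundance
#' strictly exceeds `params$min_rel_abund` is at least
#' `ceiling(params$min_prevalence * n_samples)`. Count tables are converted
#' per sample to relative abundances for the test; the returned table keeps
#' the input mode's values. Rows are not renormalized unless
#' `renormalize = TRUE`.
#'
#' @param table an [abundance_table].
#' @param params a [filter_params] object.
#' @param renormalize rescale each surviving sample row to sum to 1
#'   (relative mode only).
#' @return the filtered [abundance_table].
#' @export
filter_taxa <- function(table, params = filter_params(), renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"), inherits(params, "filter_params"))
  if (nrow(table$values) == 0 || ncol(table$values) == 0)
    stop("cannot filter an empty table")
  rel <- to_relative(table)$values
  n <- nrow(rel)
  need <- ceiling(params$min_prevalence * n)
  prev <- colSums(rel > params$min_rel_abund)
  keep <- prev >= need
  if (!any(keep)) {
    warning("all taxa removed by filter")
  }
  v <- table$values[, keep, drop = FALSE]
  tax <- if (is.null(table$taxonomy)) NULL else table$taxonomy[keep]
  mode <- table$mode
  if (renormalize) {
    if (mode == "counts") {
      v <- to_relative(abundance_table(v, mode = "counts", taxonomy = tax))$values
      mode <- "relative"
    }
    tot <- rowSums(v)
    nz <- tot > 0
    v[nz, ] <- v[nz, , drop = FALSE] / tot[nz]
  }
  abundance_table(v, mode = mode, taxonomy = tax, tol = Inf)
}

# ---- metadata and qPCR tables ----------------------------------------------

.as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) stop("column '", col, "' is not interpretable as TRUE/FALSE")
  out
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `sample_type`, `pma_treated`, `spiked`,
#' `replicate`. Treatment flags accept TRUE/FALSE, 1/0, yes/no.
#'
#' @param path file to read.
#' @return a data.frame with typed columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  req <- c("sample_id", "sample_type", "pma_treated", "spiked", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  df$pma_treated <- .as_flag(df$pma_treated, "pma_treated")
  df$spiked <- .as_flag(df$spiked, "spiked")
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1)) stop("replicate must be >= 1")
  df[, c(req, setdiff(names(df), req))]
}

#' Read a qPCR totals table
#'
#' TSV with columns `sample_id` and `copies_log10` (log10 total 16S rRNA
#' gene copies). Empty/NA entries, or an optional logical `below_detection`
#' column, mark samples below the detection limit; their `copies_log10` is
#' set NA rather than -Inf.
#'
#' @param path file to read.
#' @return a data.frame with columns `sample_id`, `copies_log10`,
#'   `below_detection`.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  req <- c("sample_id", "copies_log10")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  df$copies_log10 <- suppressWarnings(as.numeric(df$copies_log10))
  if ("below_detection" %in% names(df)) {
    df$below_detection <- .as_flag(df$below_detection, "below_detection")
  } else {
    df$below_detection <- is.na(df$copies_log10)
  }
  df$below_detection <- df$below_detection | is.na(df$copies_log10)
  df$copies_log10[df$below_detection] <- NA_real_
  if (any(!is.finite(df$copies_log10) & !df$below_detection))
    stop("non-finite copies_log10 for detected sample")
  df[, c("sample_id", "copies_log10", "below_detection")]
}

#' Write sample metadata / qPCR tables
#'
#' Plain TSV writers mirroring [read_sample_metadata()] and
#' [read_qpcr_table()].
#'
#' @param df the data.frame to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
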