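# Shared fixtures, all built in code.

spike_taxon <- "f__Enterobacteriaceae;g__Escherichia"

# small counts table: taxa columns, samples rows
toy_counts <- function() {
  m <- matrix(c(10, 0, 5,
                2, 8, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("taxA", "taxB", "taxC")))
  abundance_table(m, mode = "counts")
}

# 5 OTUs collapsing to 3 terminal clades
toy_otu_table <- function() {
  m <- matrix(c(0.20, 0.30, 0.10, 0.25, 0.15,
                0.05, 0.45, 0.20, 0.10, 0.20), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("OTU", 1:5)))
  tax <- c(
    OTU1 = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Escherichia;s__coli",
    OTU2 = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__Escherichia",
    OTU3 = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae;g__",
    OTU4 = "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Streptococcaceae;g__Streptococcus",
    OTU5 = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacteriales;f__Enterobacteriaceae"
  )
  abundance_table(m, mode = "relative", taxonomy = tax)
}

# four-arm single-type experiment assembled by hand: one sample per arm
toy_quadruplet_data <- function(abunds = c(0, 0, 0.5, 0.25), copies = rep(4, 4)) {
  sids <- c("t_plain_1", "t_pma_1", "t_spike_1", "t_spike_pma_1")
  m <- cbind(ref = abunds, other = 1 - abunds)
  rownames(m) <- sids
  colnames(m) <- c("f__Enterobacteriaceae;g__Escherichia", "g__Other")
  meta <- data.frame(sample_id = sids, sample_type = "t",
                     pma_treated = c(FALSE, TRUE, FALSE, TRUE),
                     spiked = c(FALSE, FALSE, TRUE, TRUE), replicate = 1L)
  qpcr <- data.frame(sample_id = sids, copies_log10 = copies,
                     below_detection = FALSE)
  list(table = abundance_table(m, mode = "relative"), meta = meta, qpcr = qpcr)
}

# metadata frame for n replicates x 2 arms of one type (no spike)
paired_meta <- function(type, n, prefix = type) {
  data.frame(
    sample_id = c(sprintf("%s_free_%d", prefix, seq_len(n)),
                  sprintf("%s_pma_%d", prefix, seq_len(n))),
    sample_type = type,
    pma_treated = rep(c(FALSE, TRUE), each = n),
    spiked = FALSE,
    replicate = rep(seq_len(n), 2))
}

# relative table from a named-list of sample -> named abundance vector
rel_table_from <- function(rows, taxa) {
  m <- t(vapply(rows, function(r) {
    out <- stats::setNames(numeric(length(taxa)), taxa)
    out[names(r)] <- r
    out
  }, numeric(length(taxa))))
  rownames(m) <- names(rows)
  abundance_table(m, mode = "relative", tol = 1e-9)
}
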