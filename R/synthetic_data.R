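# Generative model of live/dead communities under PMA treatment with
# amplicon + qPCR readouts. Ground truth is a community design (taxon,
# viability state, cell fraction); PMA acts by binomially thinning dead and
# (toxically) live cells; sequencing draws reads multinomially with 16S
# copy-number weighting and per-read contamination; qPCR reports log10
# total copies with lognormal noise.

#' Declare a live/dead community design
#'
#' @param components data.frame with columns `taxon_id`, `state` ("live" or
#'   "dead") and `cell_fraction`; fractions must sum to 1 (or the frame may
#'   be empty for a no-cells design).
#' @param copy_number named vector of 16S rRNA gene copies per cell, one
#'   entry per taxon in `components`.
#' @param total_cells total cell count of the community (> 0, or 0 with an
#'   empty component frame).
#' @return a `community_design` object.
#' @export
community_design <- function(components, copy_number, total_cells) {
  components <- as.data.frame(components)
  if (nrow(components) == 0) {
    components <- data.frame(taxon_id = character(0), state = character(0),
                             cell_fraction = numeric(0))
    if (total_cells != 0) stop("empty component list requires total_cells = 0")
  } else {
    stopifnot(all(c("taxon_id", "state", "cell_fraction") %in% names(components)))
    if (!all(components$state %in% c("live", "dead")))
      stop("state must be 'live' or 'dead'")
    if (abs(sum(components$cell_fraction) - 1) > 1e-9)
      stop("cell fractions must sum to 1")
    if (any(components$cell_fraction < 0)) stop("negative cell fraction")
    if (total_cells <= 0) stop("total_cells must be > 0")
    missing <- setdiff(unique(components$taxon_id), names(copy_number))
    if (length(missing) > 0)
      stop("copy_number missing for taxon(s): ", paste(missing, collapse = ", "))
    if (any(copy_number <= 0)) stop("copy numbers must be positive")
  }
  structure(list(components = components, copy_number = copy_number,
                 total_cells = total_cells),
            class = "community_design")
}

#' @export
print.community_design <- function(x, ...) {
  cat(sprintf("community_design: %d component(s), %.4g cells\n",
              nrow(x$components), x$total_cells))
  if (nrow(x$components) > 0) {
    df <- x$components
    df$cell_fraction <- signif(df$cell_fraction, 4)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

is_empty_design <- function(design) {
  nrow(design$components) == 0 || design$total_cells == 0
}

#' PMA action model
#'
#' Per-taxon probabilities that PMA removes signal from dead cells
#' (`p_dead_removed`; 1 = complete relic-DNA depletion) and, toxically, from
#' live cells (`p_live_removed`). Either argument may be a single unnamed
#' probability applied to every taxon, or a named vector with an optional
#' `.default` entry for taxa not listed. `matrix_attenuation` in [0, 1]
#' multiplies the dead-cell removal probability, modelling sample matrices
#' (e.g. soil particles, host DNA) that shield relic DNA from intercalation.
#'
#' @param p_dead_removed,p_live_removed probabilities as described above.
#' @param matrix_attenuation scalar in [0, 1].
#' @return a `pma_action_model` object.
#' @export
pma_action_model <- function(p_dead_removed = 1, p_live_removed = 0,
                             matrix_attenuation = 1) {
  chk <- function(p, what) {
    if (any(p < 0 | p > 1)) stop(what, " must lie in [0, 1]")
    p
  }
  chk(p_dead_removed, "p_dead_removed")
  chk(p_live_removed, "p_live_removed")
  stopifnot(length(matrix_attenuation) == 1,
            matrix_attenuation >= 0, matrix_attenuation <= 1)
  structure(list(p_dead_removed = p_dead_removed,
                 p_live_removed = p_live_removed,
                 matrix_attenuation = matrix_attenuation),
            class = "pma_action_model")
}

.prob_for <- function(p, taxon) {
  if (is.null(names(p))) {
    if (length(p) != 1) stop("unnamed removal probability must be a scalar")
    return(p[[1]])
  }
  if (taxon %in% names(p)) return(p[[taxon]])
  if (".default" %in% names(p)) return(p[[".default"]])
  stop("no removal probability for taxon '", taxon, "' and no .default entry")
}

#' Sequencing / readout model
#'
#' @param depth reads per sample (>= 1).
#' @param contamination_rate probability that any single read is replaced by
#'   a draw from the contaminant pool (bleed-through between libraries).
#' @param contaminant_pool named vector of contaminant taxon weights
#'   (normalized internally); may be empty when `contamination_rate = 0`.
#' @param qpcr_sigma_log10 s.d. of the lognormal qPCR noise on log10 copies.
#' @return a `sequencing_model` object.
#' @export
sequencing_model <- function(depth = 1e5, contamination_rate = 0,
                             contaminant_pool = numeric(0),
                             qpcr_sigma_log10 = 0) {
  stopifnot(depth >= 1, contamination_rate >= 0, contamination_rate <= 1,
            qpcr_sigma_log10 >= 0)
  if (length(contaminant_pool) > 0) {
    if (is.null(names(contaminant_pool))) stop("contaminant_pool must be named")
    if (any(contaminant_pool < 0)) stop("negative contaminant weight")
    contaminant_pool <- contaminant_pool / sum(contaminant_pool)
  } else if (contamination_rate > 0) {
    stop("contamination_rate > 0 requires a non-empty contaminant_pool")
  }
  structure(list(depth = as.integer(depth),
                 contamination_rate = contamination_rate,
                 contaminant_pool = contaminant_pool,
                 qpcr_sigma_log10 = qpcr_sigma_log10),
            class = "sequencing_model")
}

#' Spike-in specification
#'
#' A known quantity of a reference organism added to a sample; the default
#' is the Enterobacteriaceae spike at a 1:1 live:dead ratio used to
#' calibrate PMA efficacy.
#'
#' @param taxon_id identifier of the spiked organism.
#' @param live_cells,dead_cells cell counts (> 0).
#' @param copy_number 16S copies per cell of the spiked organism.
#' @return a `spike_in_spec` object.
#' @export
spike_in_spec <- function(taxon_id = "f__Enterobacteriaceae;g__Escherichia",
                          live_cells, dead_cells = live_cells,
                          copy_number = 7) {
  stopifnot(live_cells > 0, dead_cells > 0, copy_number > 0)
  structure(list(taxon_id = taxon_id, live_cells = live_cells,
                 dead_cells = dead_cells, copy_number = copy_number),
            class = "spike_in_spec")
}

#' Apply stochastic PMA treatment to a community
#'
#' Each (taxon, state) component's cell mass is binomially thinned with
#' retention probability `1 - p`, where `p` is the (matrix-attenuated)
#' dead-cell removal probability for dead components and the toxicity
#' probability for live ones. Fractions are renormalized over surviving
#' mass; `total_cells` is scaled by overall survival. If everything is
#' removed the result is the empty design.
#'
#' @param design a [community_design].
#' @param model a [pma_action_model].
#' @param seed optional integer seed for reproducibility.
#' @return a [community_design] describing the post-treatment community.
#' @export
apply_pma <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "community_design"),
            inherits(model, "pma_action_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is_empty_design(design)) return(design)
  comp <- design$components
  surv <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    p <- if (comp$state[i] == "dead") {
      model$matrix_attenuation * .prob_for(model$p_dead_removed, comp$taxon_id[i])
    } else {
      .prob_for(model$p_live_removed, comp$taxon_id[i])
    }
    mass <- round(comp$cell_fraction[i] * design$total_cells)
    surv[i] <- stats::rbinom(1, mass, 1 - p)
  }
  total <- sum(surv)
  if (total == 0)
    return(community_design(data.frame(), design$copy_number, 0))
  keep <- surv > 0
  comp <- comp[keep, , drop = FALSE]
  comp$cell_fraction <- surv[keep] / total
  community_design(comp, design$copy_number, total)
}

#' Simulate the 16S amplicon readout of one community
#'
#' Reads are drawn multinomially with taxon weights proportional to cell
#' mass times 16S copy number; each read is independently replaced by a
#' contaminant-pool draw with probability `contamination_rate`. An empty
#' design yields pure contaminant reads — the near-empty-library regime
#' where bleed-through fills the library.
#'
#' @param design a [community_design] (live and dead cells both amplify; use
#'   [apply_pma()] first for a treated sample).
#' @param seqmodel a [sequencing_model].
#' @param sample_id row name of the resulting one-sample table.
#' @param seed optional integer seed.
#' @return an [abundance_table] of counts with a single sample.
#' @export
sequence_community <- function(design, seqmodel, sample_id = "sample_1",
                               seed = NULL) {
  stopifnot(inherits(design, "community_design"),
            inherits(seqmodel, "sequencing_model"))
  if (!is.null(seed)) set.seed(seed)
  depth <- seqmodel$depth
  pool <- seqmodel$contaminant_pool
  if (is_empty_design(design)) {
    w <- numeric(0)
  } else {
    comp <- design$components
    mass <- comp$cell_fraction * design$total_cells
    w <- tapply(mass * design$copy_number[comp$taxon_id], comp$taxon_id, sum)
    w <- w[w > 0]
  }
  taxa <- union(names(w), names(pool))
  counts <- stats::setNames(integer(length(taxa)), taxa)
  if (length(w) == 0) {
    n_cont <- if (length(pool) > 0) depth else 0L
  } else {
    n_cont <- stats::rbinom(1, depth, seqmodel$contamination_rate)
  }
  n_comm <- depth - n_cont
  if (length(w) == 0 && length(pool) == 0) n_comm <- 0L
  if (n_comm > 0 && length(w) > 0) {
    draw <- stats::rmultinom(1, n_comm, w / sum(w))[, 1]
    counts[names(w)] <- counts[names(w)] + draw
  }
  if (n_cont > 0) {
    draw <- stats::rmultinom(1, n_cont, pool)[, 1]
    counts[names(pool)] <- counts[names(pool)] + draw
  }
  m <- matrix(counts, nrow = 1, dimnames = list(sample_id, taxa))
  abundance_table(m, mode = "counts")
}

#' Simulate the qPCR total-copies readout of one community
#'
#' `copies_log10 = log10(sum(cell mass x copy number)) + N(0, sigma)`.
#' An empty design reports below-detection (NA).
#'
#' @param design a [community_design].
#' @param seqmodel a [sequencing_model] (supplies `qpcr_sigma_log10`).
#' @param sample_id sample identifier for the returned row.
#' @param seed optional integer seed.
#' @return one-row data.frame with `sample_id`, `copies_log10`,
#'   `below_detection`.
#' @export
qpcr_total <- function(design, seqmodel, sample_id = "sample_1", seed = NULL) {
  stopifnot(inherits(design, "community_design"),
            inherits(seqmodel, "sequencing_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is_empty_design(design)) {
    return(data.frame(sample_id = sample_id, copies_log10 = NA_real_,
                      below_detection = TRUE))
  }
  comp <- design$components
  total <- sum(comp$cell_fraction * design$total_cells *
                 design$copy_number[comp$taxon_id])
  if (total <= 0) {
    return(data.frame(sample_id = sample_id, copies_log10 = NA_real_,
                      below_detection = TRUE))
  }
  x <- log10(total) + stats::rnorm(1, 0, seqmodel$qpcr_sigma_log10)
  data.frame(sample_id = sample_id, copies_log10 = x, below_detection = FALSE)
}

# Default 16S rRNA operon copy numbers for the two-strain mixtures
# (literature values: E. coli 7 operons, S. sanguinis 4).
.fig1_copy_numbers <- c(Escherichia_coli = 7, Streptococcus_sanguinis = 4)

#' The ten two-strain live/dead calibration mixtures
#'
#' Ten designs over live/heat-killed *Escherichia coli* (E) and
#' *Streptococcus sanguinis* (S), each at 1e5 cells: (1) 100% live E;
#' (2) 100% dead E; (3) 100% live S; (4) 100% dead S; (5) 50/50 live E /
#' live S; (6) 50/50 dead E / dead S; (7) 50% live E, 25% live S, 25% dead
#' S; (8) 25% live + 25% dead E, 50% live S; (9) 50% live E, 50% dead S;
#' (10) 50% dead E, 50% live S.
#'
#' @param total_cells cells per mixture (default 1e5, i.e. 1e5 CFU/ml).
#' @return named list of 10 [community_design] objects (`group_1` ...
#'   `group_10`).
#' @export
make_fig1_designs <- function(total_cells = 1e5) {
  E <- "Escherichia_coli"; S <- "Streptococcus_sanguinis"
  mk <- function(taxa, states, fracs) {
    community_design(data.frame(taxon_id = taxa, state = states,
                                cell_fraction = fracs),
                     .fig1_copy_numbers, total_cells)
  }
  designs <- list(
    mk(E, "live", 1),
    mk(E, "dead", 1),
    mk(S, "live", 1),
    mk(S, "dead", 1),
    mk(c(E, S), c("live", "live"), c(0.5, 0.5)),
    mk(c(E, S), c("dead", "dead"), c(0.5, 0.5)),
    mk(c(E, S, S), c("live", "live", "dead"), c(0.5, 0.25, 0.25)),
    mk(c(E, E, S), c("live", "dead", "live"), c(0.25, 0.25, 0.5)),
    mk(c(E, S), c("live", "dead"), c(0.5, 0.5)),
    mk(c(E, S), c("dead", "live"), c(0.5, 0.5))
  )
  names(designs) <- paste0("group_", 1:10)
  designs
}

#' Build the four-arm spike-in factorial from a background community
#'
#' Returns the four experimental arms needed by the efficacy estimator:
#' plain control, PMA-treated, spiked, and spiked + PMA-treated. The two
#' spike arms add the spike's live and dead cells to the background; PMA is
#' applied later (by the caller / [simulate_spike_experiment()]) to the
#' designs whose `pma_treated` flag is set.
#'
#' @param background a [community_design] (typically all-live).
#' @param spike a [spike_in_spec].
#' @return named list of four arms; each element has `design`, `spiked`,
#'   `pma_treated`.
#' @export
make_spiked_scenario <- function(background, spike) {
  stopifnot(inherits(background, "community_design"),
            inherits(spike, "spike_in_spec"))
  add_spike <- function(bg) {
    comp <- bg$components
    mass <- if (nrow(comp) > 0) comp$cell_fraction * bg$total_cells else numeric(0)
    comp2 <- rbind(comp[, c("taxon_id", "state", "cell_fraction")],
                   data.frame(taxon_id = rep(spike$taxon_id, 2),
                              state = c("live", "dead"),
                              cell_fraction = c(spike$live_cells, spike$dead_cells)))
    total <- sum(mass) + spike$live_cells + spike$dead_cells
    comp2$cell_fraction <- c(mass, spike$live_cells, spike$dead_cells) / total
    cn <- bg$copy_number
    cn[spike$taxon_id] <- spike$copy_number
    community_design(comp2, cn, total)
  }
  list(
    plain     = list(design = background,        spiked = FALSE, pma_treated = FALSE),
    pma       = list(design = background,        spiked = FALSE, pma_treated = TRUE),
    spike     = list(design = add_spike(background), spiked = TRUE, pma_treated = FALSE),
    spike_pma = list(design = add_spike(background), spiked = TRUE, pma_treated = TRUE)
  )
}

#' Log-series background community
#'
#' Draws a complex all-live background with a long-tailed (Fisher
#' log-series) rank-abundance shape: taxon `k` of `richness` gets weight
#' `x^k / k`. Emulates realistic sample backgrounds — low-biomass swab
#' surfaces (~50 taxa, 1e3 cells) or high-biomass soil/saliva (~500 taxa,
#' 1e7 cells) — without claiming any particular real taxon.
#'
#' @param richness number of taxa.
#' @param total_cells total background cells.
#' @param x log-series parameter in (0, 1); larger is more even.
#' @param prefix taxon-ID prefix.
#' @param copy_range integer range of 16S copy numbers assigned uniformly.
#' @param seed optional integer seed (controls copy-number assignment).
#' @return a [community_design] with all components live.
#' @export
log_series_background <- function(richness, total_cells, x = 0.995,
                                  prefix = "bg_taxon", copy_range = c(1, 10),
                                  seed = NULL) {
  stopifnot(richness >= 1, total_cells > 0, x > 0, x < 1)
  if (!is.null(seed)) set.seed(seed)
  k <- seq_len(richness)
  w <- x^k / k
  w <- w / sum(w)
  ids <- sprintf("%s_%03d", prefix, k)
  cn <- stats::setNames(sample(seq(copy_range[1], copy_range[2]), richness,
                               replace = TRUE), ids)
  community_design(data.frame(taxon_id = ids, state = "live", cell_fraction = w),
                   cn, total_cells)
}

#' Simulate a full four-arm spike-in experiment for one sample type
#'
#' Runs [make_spiked_scenario()], applies [apply_pma()] to the treated arms,
#' and sequences + qPCRs `n_replicates` independent samples per arm. Sample
#' IDs are `<type>_<arm>_<replicate>`.
#'
#' @param background a [community_design].
#' @param spike a [spike_in_spec].
#' @param pma_model a [pma_action_model].
#' @param seqmodel a [sequencing_model].
#' @param sample_type label recorded in the metadata.
#' @param n_replicates biological replicates per arm.
#' @param seed integer seed; every replicate derives its own stream from it.
#' @return list with `table` (counts [abundance_table]), `meta`
#'   (sample metadata data.frame) and `qpcr` (qPCR totals data.frame).
#' @export
simulate_spike_experiment <- function(background, spike, pma_model, seqmodel,
                                      sample_type = "sample", n_replicates = 4,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arms <- make_spiked_scenario(background, spike)
  tabs <- list(); meta <- list(); qpcr <- list()
  for (arm_name in names(arms)) {
    arm <- arms[[arm_name]]
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_%s_%d", sample_type, arm_name, r)
      d <- arm$design
      if (arm$pma_treated) d <- apply_pma(d, pma_model)
      tabs[[sid]] <- sequence_community(d, seqmodel, sample_id = sid)
      qpcr[[sid]] <- qpcr_total(d, seqmodel, sample_id = sid)
      meta[[sid]] <- data.frame(sample_id = sid, sample_type = sample_type,
                                pma_treated = arm$pma_treated,
                                spiked = arm$spiked, replicate = r)
    }
  }
  list(table = bind_sample_tables(tabs),
       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       qpcr = do.call(rbind, c(qpcr, list(make.row.names = FALSE))))
}

#' Stack one-sample count tables over a shared taxon namespace
#'
#' @param tables list of [abundance_table] objects in counts mode.
#' @return a single counts [abundance_table]; absent taxa get zero counts.
#' @export
bind_sample_tables <- function(tables) {
  stopifnot(length(tables) > 0)
  taxa <- Reduce(union, lapply(tables, taxon_ids))
  rows <- lapply(tables, function(t) {
    out <- stats::setNames(numeric(length(taxa)), taxa)
    out[taxon_ids(t)] <- t$values[1, ]
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(tables, function(t) sample_ids(t)[1], character(1))
  colnames(m) <- taxa
  abundance_table(m, mode = "counts")
}
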