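test_that("PMA thinning removes dead signal exactly at the limits", {
  d <- community_design(
    data.frame(taxon_id = "A", state = c("live", "dead"),
               cell_fraction = c(0.5, 0.5)),
    c(A = 7), 1e4)

  perfect <- apply_pma(d, pma_action_model(p_dead_removed = 1, p_live_removed = 0),
                       seed = 1)
  expect_equal(perfect$total_cells, 5e3)
  expect_identical(perfect$components$state, "live")
  expect_equal(perfect$components$cell_fraction, 1)

  noop <- apply_pma(d, pma_action_model(p_dead_removed = 0, p_live_removed = 0),
                    seed = 1)
  expect_equal(noop$total_cells, d$total_cells)
  expect_equal(noop$components$cell_fraction, d$components$cell_fraction)

  all_gone <- apply_pma(
    community_design(data.frame(taxon_id = "A", state = "dead", cell_fraction = 1),
                     c(A = 7), 1e4),
    pma_action_model(p_dead_removed = 1), seed = 1)
  expect_equal(all_gone$total_cells, 0)
  expect_equal(nrow(all_gone$components), 0)
})

test_that("partial removal matches the binomial expectation", {
  d <- community_design(
    data.frame(taxon_id = "A", state = c("live", "dead"),
               cell_fraction = c(0.5, 0.5)),
    c(A = 7), 1e6)
  out <- apply_pma(d, pma_action_model(p_dead_removed = 0.7, p_live_removed = 0),
                   seed = 11)
  dead_mass <- with(out$components,
                    sum(cell_fraction[state == "dead"]) * out$total_cells)
  frac <- dead_mass / 5e5
  sigma <- sqrt(0.7 * 0.3 / 5e5)
  expect_lt(abs(frac - 0.30), 3 * sigma)
  # survival never exceeds the initial mass
  expect_lte(out$total_cells, d$total_cells)
})

test_that("sequencing weights reads by cell mass x copy number", {
  one <- community_design(data.frame(taxon_id = "A", state = "live",
                                     cell_fraction = 1), c(A = 7), 1e5)
  sm0 <- sequencing_model(depth = 1000)
  tab <- sequence_community(one, sm0, seed = 3)
  expect_equal(sum(tab$values), 1000)
  expect_equal(unname(tab$values[1, "A"]), 1000)

  # 50/50 cell mix, copy numbers 7 and 4 -> read fraction of A = 7/11
  mix <- community_design(
    data.frame(taxon_id = c("A", "B"), state = "live",
               cell_fraction = c(0.5, 0.5)),
    c(A = 7, B = 4), 1e6)
  sm <- sequencing_model(depth = 1e5)
  tab <- sequence_community(mix, sm, seed = 4)
  p <- 7 / 11
  frac <- tab$values[1, "A"] / 1e5
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_equal(sum(tab$values), 1e5)
})

test_that("an empty design yields a library filled by bleed-through", {
  empty <- community_design(data.frame(), c(A = 7), 0)
  sm <- sequencing_model(depth = 1e4, contamination_rate = 0.01,
                         contaminant_pool = c(contam_x = 0.5, contam_y = 0.5))
  tab <- sequence_community(empty, sm, seed = 5)
  expect_equal(sum(tab$values), 1e4)
  expect_setequal(names(which(tab$values[1, ] > 0)), c("contam_x", "contam_y"))
})

test_that("qPCR readout follows log10 total copies with lognormal noise", {
  d <- community_design(data.frame(taxon_id = "A", state = "live",
                                   cell_fraction = 1), c(A = 7), 1e6)
  sm0 <- sequencing_model(depth = 10, qpcr_sigma_log10 = 0)
  q <- qpcr_total(d, sm0, seed = 1)
  expect_equal(q$copies_log10, log10(7e6), tolerance = 1e-12)
  expect_false(q$below_detection)

  empty <- community_design(data.frame(), c(A = 7), 0)
  expect_true(qpcr_total(empty, sm0)$below_detection)

  sm <- sequencing_model(depth = 10, qpcr_sigma_log10 = 0.1)
  set.seed(9)
  xs <- replicate(1000, qpcr_total(d, sm)$copies_log10)
  expect_lt(abs(sd(xs) - 0.1) / 0.1, 0.10)
})

test_that("the ten two-strain calibration designs match their captions", {
  ds <- make_fig1_designs()
  expect_length(ds, 10)
  expect_true(all(vapply(ds, function(d) d$total_cells, numeric(1)) == 1e5))

  g5 <- ds$group_5$components
  expect_setequal(g5$taxon_id, c("Escherichia_coli", "Streptococcus_sanguinis"))
  expect_true(all(g5$state == "live"))
  expect_equal(g5$cell_fraction, c(0.5, 0.5))

  g2 <- ds$group_2$components
  expect_equal(g2$taxon_id, "Escherichia_coli")
  expect_equal(g2$state, "dead")
  expect_equal(g2$cell_fraction, 1)
})

test_that("the spiked scenario builds the four-arm factorial with conservation", {
  bg <- log_series_background(20, 1e3, seed = 2)
  sp <- spike_in_spec(live_cells = 250, dead_cells = 250)
  arms <- make_spiked_scenario(bg, sp)
  expect_length(arms, 4)
  expect_named(arms, c("plain", "pma", "spike", "spike_pma"))
  expect_equal(arms$spike$design$total_cells, 1e3 + 500)
  spike_comp <- arms$spike$design$components
  spk <- spike_comp[spike_comp$taxon_id == sp$taxon_id, ]
  expect_equal(spk$cell_fraction[spk$state == "live"],
               spk$cell_fraction[spk$state == "dead"])  # 1:1 live:dead
  expect_false(arms$plain$pma_treated)
  expect_true(arms$spike_pma$spiked && arms$spike_pma$pma_treated)
})

test_that("identical seeds give identical simulated experiments", {
  bg <- log_series_background(30, 1e3, seed = 2)
  sp <- spike_in_spec(live_cells = 250, dead_cells = 250)
  pm <- pma_action_model(p_dead_removed = 0.9, p_live_removed = 0.05)
  sm <- sequencing_model(depth = 2000, contamination_rate = 0.01,
                         contaminant_pool = c(contam_x = 1),
                         qpcr_sigma_log10 = 0.1)
  s1 <- simulate_spike_experiment(bg, sp, pm, sm, "screen", 2, seed = 77)
  s2 <- simulate_spike_experiment(bg, sp, pm, sm, "screen", 2, seed = 77)
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$qpcr, s2$qpcr)
  s3 <- simulate_spike_experiment(bg, sp, pm, sm, "screen", 2, seed = 78)
  expect_false(identical(s1$table$values, s3$table$values))
})
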