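test_that("generated networks are trees with the configured geometry", {
  cfg <- simulationConfig(seed = 9, n_populations = 5, n_sections = 3,
                          connectivity_counts = c(connected = 5,
                                                  culvert_diversion = 0,
                                                  low_flow = 0, waterfall = 0))
  net <- generateNetwork(cfg)
  expect_equal(nrow(net@edges), nrow(net@nodes) - 1)
  g <- riverGSI:::.net_graph(net)
  expect_true(igraph::is_connected(g))
  expect_true(all(net@edges$length > 0))
  expect_equal(nrow(net@sections), 3)

  # single tributary: mouth -> point distance is the connecting edge length
  cfg1 <- simulationConfig(seed = 2, n_populations = 1, n_sections = 1,
                           connectivity_counts = c(connected = 1,
                                                   culvert_diversion = 0,
                                                   low_flow = 0, waterfall = 0))
  net1 <- generateNetwork(cfg1)
  pop <- net1@populations
  e <- net1@edges[net1@edges$to == pop$point_node, ]
  expect_equal(watercourseDistance(net1, pop$mouth_node, pop$point_node),
               e$length)

  # determinism and seed sensitivity
  expect_identical(generateNetwork(cfg)@nodes, generateNetwork(cfg)@nodes)
  cfgb <- cfg; cfgb$seed <- 10L
  expect_false(identical(generateNetwork(cfgb)@nodes, net@nodes))

  # the default (study-scale) configuration builds: 52 tributaries, 6 sections
  net52 <- generateNetwork(simulationConfig(seed = 1))
  expect_equal(nrow(net52@populations), 52)
  expect_equal(nrow(net52@sections), 6)
  expect_equal(nrow(net52@edges), nrow(net52@nodes) - 1)
})

test_that("covariates match connectivity counts and are seed-reproducible", {
  cfg <- simulationConfig(seed = 3)
  net <- generateNetwork(cfg)
  tr <- generateCovariates(net, cfg)
  expect_equal(as.vector(table(tr$connectivity)[names(cfg$connectivity_counts)]),
               as.vector(cfg$connectivity_counts))
  expect_true(all(tr$groundwater >= 0 & tr$groundwater <= 1))
  expect_identical(generateCovariates(net, cfg), tr)
  cfgb <- cfg; cfgb$seed <- 4L
  expect_false(identical(generateCovariates(net, cfgb)$groundwater,
                         tr$groundwater))

  all_conn <- simulationConfig(seed = 3, n_populations = 4,
                               connectivity_counts = c(connected = 4,
                                                       culvert_diversion = 0,
                                                       low_flow = 0,
                                                       waterfall = 0))
  tr2 <- generateCovariates(generateNetwork(all_conn), all_conn)
  expect_equal(length(unique(as.character(tr2$connectivity))), 1)

  bad <- cfg; bad$connectivity_counts["connected"] <- 10L
  expect_error(generateCovariates(net, bad), "sum")
})

test_that("allele-frequency structure follows the F-model", {
  # theta -> 0 limit: population frequencies collapse on the ancestral ones
  cfg0 <- simulationConfig(seed = 5, n_populations = 1, n_loci = 1000,
                           theta_fst = 1e-6,
                           connectivity_counts = c(connected = 1,
                                                   culvert_diversion = 0,
                                                   low_flow = 0, waterfall = 0))
  f0 <- generateAlleleFrequencies(cfg0)
  expect_lt(max(abs(f0[1, ] - attr(f0, "ancestral"))), 0.01)

  # moment check: across-population variance ~ theta p (1 - p) at K = 200
  cfgv <- simulationConfig(seed = 6, n_populations = 200, n_loci = 300,
                           theta_fst = 0.05,
                           connectivity_counts = c(connected = 200,
                                                   culvert_diversion = 0,
                                                   low_flow = 0, waterfall = 0))
  fv <- generateAlleleFrequencies(cfgv)
  p <- attr(fv, "ancestral")
  vr <- apply(fv, 2, var)
  ratio <- vr / (0.05 * p * (1 - p))
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)

  # Weir-Cockerham global estimate recovers theta = 0.04 across replicates
  est <- vapply(1:5, function(r) {
    cfg <- simulationConfig(seed = 100 + r, n_populations = 8, n_loci = 266,
                            theta_fst = 0.04, n_per_collection = c(50, 50),
                            sib_family_rate = 0, missing_rate = 0,
                            connectivity_counts = c(connected = 8,
                                                    culvert_diversion = 0,
                                                    low_flow = 0,
                                                    waterfall = 0))
    weirCockerhamFst(simulateGenotypes(generateAlleleFrequencies(cfg), cfg))$global
  }, numeric(1))
  expect_lt(max(abs(est - 0.04)), 0.01)

  # realized differentiation increases with theta
  realized <- vapply(c(0.01, 0.04, 0.10), function(th) {
    cfg <- simulationConfig(seed = 50, n_populations = 6, n_loci = 200,
                            theta_fst = th, n_per_collection = c(40, 40),
                            sib_family_rate = 0, missing_rate = 0,
                            connectivity_counts = c(connected = 6,
                                                    culvert_diversion = 0,
                                                    low_flow = 0,
                                                    waterfall = 0))
    weirCockerhamFst(simulateGenotypes(generateAlleleFrequencies(cfg), cfg))$global
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
})

test_that("baseline genotypes obey Hardy-Weinberg and record sib families", {
  freqs <- matrix(0.5, 1, 60, dimnames = list("P01", sprintf("L%03d", 1:60)))
  cfg <- simulationConfig(seed = 8, n_populations = 1, n_loci = 60,
                          n_per_collection = c(1000, 1000),
                          sib_family_rate = 0, missing_rate = 0,
                          connectivity_counts = c(connected = 1,
                                                  culvert_diversion = 0,
                                                  low_flow = 0, waterfall = 0))
  G <- simulateGenotypes(freqs, cfg)
  d <- refDosage(G)$dosage
  expect_lt(abs(mean(d == 1) - 0.5), 0.02)       # heterozygote fraction 2pq
  expect_true(all(is.na(sampleInfo(G)$family)))  # no families at rate 0

  # allele-frequency estimates converge to truth
  cfg2 <- simulationConfig(seed = 9, n_populations = 1, n_loci = 100,
                           n_per_collection = c(500, 500),
                           sib_family_rate = 0, missing_rate = 0,
                           connectivity_counts = c(connected = 1,
                                                   culvert_diversion = 0,
                                                   low_flow = 0,
                                                   waterfall = 0))
  f2 <- generateAlleleFrequencies(cfg2)
  G2 <- simulateGenotypes(f2, cfg2)
  est <- colMeans(refDosage(G2)$dosage) / 2
  expect_lt(max(abs(est - f2[1, ])), 0.02 + 3 * sqrt(0.25 / 1000))

  # sib families appear at the configured rate with recorded labels
  cfg3 <- simulationConfig(seed = 10, n_populations = 2, n_loci = 50,
                           n_per_collection = c(40, 40), sib_family_rate = 0.3,
                           connectivity_counts = c(connected = 2,
                                                   culvert_diversion = 0,
                                                   low_flow = 0,
                                                   waterfall = 0))
  G3 <- simulateGenotypes(generateAlleleFrequencies(cfg3), cfg3)
  fam <- sampleInfo(G3)$family
  expect_gt(sum(!is.na(fam)), 0)
  expect_true(all(table(fam) >= 2))
})

test_that("true contributions follow the forward model", {
  cfg <- simulationConfig(seed = 12, n_populations = 12, n_loci = 50,
                          connectivity_counts = c(connected = 12,
                                                  culvert_diversion = 0,
                                                  low_flow = 0, waterfall = 0))
  net <- generateNetwork(cfg)
  tr <- generateCovariates(net, cfg)
  ct <- simulateTrueContributions(tr, net, cfg)
  # exact simplex per section-year
  sums <- apply(ct$contributions, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)

  # intercept-only coefficients: expected mu identical within a section
  cfg0 <- cfg
  cfg0$zib_coefficients <- zibCoefficients(
    beta_distance = 0, beta_area = 0, beta_groundwater = 0,
    beta_connectivity = c(culvert_diversion = 0, low_flow = 0, waterfall = 0),
    sd_unit = 0, lat_slope = 0, sd_region = 0)
  tr0 <- generateCovariates(net, cfg0)
  ct0 <- simulateTrueContributions(tr0, net, cfg0)
  mu_by_sec <- split(ct0$expected_mu, ct0$covariates$section)
  for (m in mu_by_sec) expect_lt(diff(range(m)), 1e-12)

  # negative distance effect: expected mu decreases with distance everywhere
  by_sec <- split(seq_len(nrow(ct$covariates)), ct$covariates$section)
  for (idx in by_sec) {
    rho <- cor(ct$covariates$distance_km[idx], ct$expected_mu[idx],
               method = "spearman")
    expect_lt(rho, 0)
  }
})

test_that("mixture simulation draws origins from the true proportions", {
  K <- 3
  freqs <- matrix(runif(K * 40, 0.2, 0.8), K, 40,
                  dimnames = list(sprintf("P%02d", 1:K),
                                  sprintf("L%03d", 1:40)))
  cfg <- simulationConfig(seed = 14, n_populations = K, n_loci = 40,
                          n_sections = 1, n_years = 1,
                          mixture_size_per_year = 1000, missing_rate = 0,
                          connectivity_counts = c(connected = K,
                                                  culvert_diversion = 0,
                                                  low_flow = 0, waterfall = 0))
  pi <- c(0.6, 0.3, 0.1)
  ctr <- array(pi, dim = c(K, 1, 1),
               dimnames = list(rownames(freqs), "A", "2020"))
  mix <- simulateMixture(ctr, freqs, cfg)
  counts <- table(factor(sampleInfo(mix)$true_origin, rownames(freqs)))
  for (k in seq_len(K)) {
    bounds <- qbinom(c(0.005, 0.995), 1000, pi[k])
    expect_gte(counts[k], bounds[1])
    expect_lte(counts[k], bounds[2])
  }

  # point-mass contributions: all labels equal
  ctr1 <- array(c(1, 0, 0), dim = c(K, 1, 1),
                dimnames = dimnames(ctr))
  mix1 <- simulateMixture(ctr1, freqs, cfg)
  expect_true(all(sampleInfo(mix1)$true_origin == "P01"))

  # default stratification: 6 sections x 3 years
  cfg_def <- simulationConfig(seed = 15, n_populations = 4, n_loci = 30,
                              mixture_size_per_year = 120,
                              connectivity_counts = c(connected = 4,
                                                      culvert_diversion = 0,
                                                      low_flow = 0,
                                                      waterfall = 0))
  net <- generateNetwork(cfg_def)
  tr <- generateCovariates(net, cfg_def)
  ct <- simulateTrueContributions(tr, net, cfg_def)
  f <- generateAlleleFrequencies(cfg_def)
  mix3 <- simulateMixture(ct$contributions, f, cfg_def)
  info <- sampleInfo(mix3)
  expect_equal(length(unique(paste(info$section, info$year))), 18)

  # bit-reproducibility of the full chain
  s1 <- simulateRiverscape(cfg_def)
  s2 <- simulateRiverscape(cfg_def)
  expect_identical(s1$baseline@allele1, s2$baseline@allele1)
  expect_identical(s1$contributions$contributions,
                   s2$contributions$contributions)
})
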