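test_that("unit posterior frequencies apply conjugate smoothing", {
  d <- rbind(c(2, 2, NA), c(2, 1, NA))
  G <- gm_from_dosage(d, collection = "A")
  units <- baselineUnits(G)
  f <- unitPosteriorFreqs(units)
  # counts (4, 0) over 2 ind -> (4.5)/5; (3, 1) -> 3.5/5; no data -> 0.5
  expect_equal(as.numeric(f), c(4.5 / 5, 3.5 / 5, 0.5))
  expect_equal(unname(unitPosteriorFreqs(units, prior = 0.5)[1, 1]),
               (4 + 0.5) / (4 + 1))
  # counts (10, 0): the documented closed form
  d10 <- matrix(2L, 5, 1)
  u10 <- baselineUnits(gm_from_dosage(d10))
  expect_equal(unname(unitPosteriorFreqs(u10)[1, 1]), 10.5 / 11)
})

test_that("genotype log-likelihoods match direct enumeration", {
  # single heterozygous locus at p = 0.5 -> log(0.5)
  db <- matrix(c(2L, 0L), 2, 1)       # balanced counts -> posterior mean 0.5
  units <- baselineUnits(gm_from_dosage(db))
  Gh <- gm_from_dosage(matrix(1L, 1, 1), collection = "q", role = "mixture",
                       section = "A", year = 2020L)
  expect_equal(as.numeric(genotypeLoglik(Gh, units)), log(0.5))

  # two-locus toy against the oracle
  base <- tiny_baseline(seed = 51, K = 2, L = 2, n = 10)
  f <- unitPosteriorFreqs(base$units)
  g <- c(2L, 1L)
  Gm <- gm_from_dosage(matrix(g, 1), role = "mixture", section = "A",
                       year = 2020L)
  ll <- genotypeLoglik(Gm, base$units)
  for (u in 1:2)
    expect_equal(ll[1, u], oracle_hwe_loglik(g, f[u, ]), tolerance = 1e-12)

  # adding a missing locus leaves the value unchanged
  units3 <- baselineUnits(gm_from_dosage(rbind(c(2L, 1L, 1L), c(0L, 1L, 1L)),
                                         collection = "A"))
  f3 <- unitPosteriorFreqs(units3)
  Gm2 <- gm_from_dosage(matrix(c(2L, 1L, NA), 1), role = "mixture",
                        section = "A", year = 2020L)
  expect_equal(as.numeric(genotypeLoglik(Gm2, units3)),
               oracle_hwe_loglik(c(2L, 1L), f3[1, 1:2]), tolerance = 1e-12)

  # all loci missing is an error
  Gna <- gm_from_dosage(matrix(NA_integer_, 1, 2), role = "mixture")
  expect_error(genotypeLoglik(Gna, base$units), "no called loci")
})

test_that("the Gibbs mixture recovers proportions of distinct stocks", {
  set.seed(52)
  # disjoint fixed alleles, 70/30 mixture
  dA <- matrix(2L, 15, 30); dB <- matrix(0L, 15, 30)
  units <- baselineUnits(gm_from_dosage(rbind(dA, dB),
                                        collection = rep(c("A", "B"),
                                                         each = 15)))
  n <- 200
  orig <- rbinom(n, 1, 0.3)
  dm <- matrix(ifelse(rep(orig, 30) == 0, 2L, 0L), n, 30)
  Gm <- gm_from_dosage(dm, role = "mixture", section = "A", year = 2020L)
  fit <- fitMixture(units, Gm, sweeps = 1000, burn = 250, seed = 1)
  expect_lt(abs(mixingProportions(fit)["A"] - mean(orig == 0)), 0.05)
  expect_true(all(abs(rowSums(fit@indiv_posteriors) - 1) < 1e-8))

  # EM fixed point agrees with the Gibbs posterior mean
  ll <- genotypeLoglik(Gm, units)
  em <- oracle_em_pi(ll)
  expect_lt(max(abs(em - fit@pi_mean)), 0.02)
})

test_that("mixture estimates are seed-stable and label-equivariant", {
  set.seed(53)
  base <- tiny_baseline(seed = 54, K = 3, L = 266, n = 30, theta = 0.08)
  cfg <- base$cfg
  cfg$n_sections <- 1L; cfg$n_years <- 1L; cfg$mixture_size_per_year <- 1000L
  pi_true <- c(0.6, 0.3, 0.1)
  ctr <- array(pi_true, dim = c(3, 1, 1),
               dimnames = list(rownames(base$freqs), "A", "2020"))
  mix <- simulateMixture(ctr, base$freqs, cfg)
  f1 <- fitMixture(base$units, mix, sweeps = 1500, burn = 400, seed = 11)
  f2 <- fitMixture(base$units, mix, sweeps = 1500, burn = 400, seed = 99)
  expect_lt(max(abs(f1@pi_mean - f2@pi_mean)), 0.02)
  expect_lt(mean(abs(f1@pi_mean - pi_true)), 0.03)

  # permuting unit order permutes the estimates consistently
  perm <- c(3, 1, 2)
  units_p <- base$units
  units_p@units <- units_p@units[perm, ]
  units_p@ref_counts <- units_p@ref_counts[perm, ]
  units_p@tot_counts <- units_p@tot_counts[perm, ]
  f3 <- fitMixture(units_p, mix, sweeps = 1500, burn = 400, seed = 11)
  expect_lt(max(abs(f3@pi_mean[match(f1@unit_ids, f3@unit_ids)] - f1@pi_mean)),
            0.02)
})

test_that("bootstrap correction is conservative for well-separated stocks", {
  set.seed(55)
  dA <- matrix(2L, 12, 25); dB <- matrix(0L, 12, 25)
  units <- baselineUnits(gm_from_dosage(rbind(dA, dB),
                                        collection = rep(c("A", "B"),
                                                         each = 12)))
  n <- 150
  orig <- rbinom(n, 1, 0.35)
  dm <- matrix(ifelse(rep(orig, 25) == 0, 2L, 0L), n, 25)
  Gm <- gm_from_dosage(dm, role = "mixture", section = "A", year = 2020L)
  fit <- fitMixture(units, Gm, sweeps = 800, burn = 200, seed = 2)
  fit <- bootstrapCorrect(fit, units, B = 40, seed = 3)
  expect_lt(max(abs(fit@pi_corrected - fit@pi_mean)), 0.01)
  expect_gte(cor(fit@pi_corrected, fit@pi_mean), 0.95)
  expect_equal(sum(fit@pi_corrected), 1, tolerance = 1e-12)
})

test_that("z-scores have the exact two-point closed form at one locus", {
  # unit A has posterior-mean frequency exactly 0.5; the heterozygous
  # individual assigns there and its log-likelihood takes the two-point
  # distribution whose standardized value is exactly 1
  db <- rbind(2L, 0L, 2L, 2L)
  units <- baselineUnits(gm_from_dosage(matrix(db, 4, 1),
                                        collection = c("A", "A", "B", "B")))
  expect_equal(unname(unitPosteriorFreqs(units)["A", 1]), 0.5)
  Gh <- gm_from_dosage(matrix(1L, 1, 1), role = "mixture", section = "A",
                       year = 2020L)
  fit <- fitMixture(units, Gh, sweeps = 200, burn = 50, seed = 1)
  zs <- zScores(Gh, fit, units)
  expect_equal(zs$assigned_unit, "A")
  expect_equal(zs$z, 1.0, tolerance = 1e-10)

  # the flag implements the two-standard-deviation empirical rule exactly
  set.seed(9)
  base <- tiny_baseline(seed = 91, K = 2, L = 120, n = 20)
  ctr <- array(c(0.5, 0.5), dim = c(2, 1, 1),
               dimnames = list(rownames(base$freqs), "A", "2020"))
  cfg <- base$cfg
  cfg$n_sections <- 1L; cfg$n_years <- 1L; cfg$mixture_size_per_year <- 60L
  mix <- simulateMixture(ctr, base$freqs, cfg)
  fm <- fitMixture(base$units, mix, sweeps = 400, burn = 100, seed = 2)
  zz <- zScores(mix, fm, base$units)
  expect_equal(zz$flagged_missing_source,
               abs(zz$z - mean(zz$z)) > 2 * sd(zz$z))
})

test_that("dispersal summaries use network distances and the probability cutoff", {
  net <- toy_network()
  dA <- matrix(2L, 10, 20); dB <- matrix(0L, 10, 20)
  G <- gm_from_dosage(rbind(dA, dB), collection = rep(c("P1", "P2"), each = 10))
  units <- baselineUnits(G, point_nodes = c(P1 = "f", P2 = "h"))
  # mixture captured in section A (midpoint node "b"), all from P1
  Gm <- gm_from_dosage(matrix(2L, 8, 20), role = "mixture", section = "A",
                       year = 2020L)
  fit <- fitMixture(units, Gm, sweeps = 400, burn = 100, seed = 4)
  disp <- dispersalSummary(list(fit), net, units, prob_threshold = 0.7)
  want <- watercourseDistance(net, "f", "b")   # e->f path to section A midpoint
  expect_equal(unique(disp$individuals$distance_km), want)
  expect_equal(disp$median_km, want)

  # threshold 1.0: empty summary
  disp2 <- dispersalSummary(list(fit), net, units, prob_threshold = 1.0)
  expect_equal(nrow(disp2$individuals), 0)
  expect_true(is.na(disp2$median_km))
})
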