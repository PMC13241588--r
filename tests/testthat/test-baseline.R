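test_that("Weir-Cockerham theta matches a brute-force oracle exactly", {
  # fixed 2 populations x 4 individuals x 2 loci fixture
  d1 <- rbind(c(2, 1), c(1, 1), c(2, 0), c(1, 2))
  d2 <- rbind(c(0, 2), c(1, 2), c(0, 1), c(0, 2))
  G <- gm_from_dosage(rbind(d1, d2), collection = rep(c("A", "B"), each = 4))
  fst <- weirCockerhamFst(G)
  expect_equal(fst$global, oracle_wc_theta(list(d1, d2)), tolerance = 1e-10)
  expect_equal(fst$pairwise["A", "B"], fst$global, tolerance = 1e-12)

  # with missing data
  d1b <- d1; d1b[1, 1] <- NA
  Gb <- gm_from_dosage(rbind(d1b, d2), collection = rep(c("A", "B"), each = 4))
  expect_equal(weirCockerhamFst(Gb)$global, oracle_wc_theta(list(d1b, d2)),
               tolerance = 1e-10)

  # matrix structure
  base <- tiny_baseline(seed = 41, K = 3, L = 80, n = 20)
  pw <- weirCockerhamFst(base$G)$pairwise
  expect_equal(pw, t(pw))
  expect_true(all(diag(pw) == 0))
})

test_that("near-identical groups show near-zero differentiation", {
  set.seed(42)
  d <- matrix(rbinom(2 * 500 * 60, 2, rep(runif(60, 0.2, 0.8), each = 1000)),
              1000, 60)
  G <- gm_from_dosage(d, collection = rep(c("A", "B"), 500))
  expect_lte(weirCockerhamFst(G)$global, 0.005)
})

test_that("merging identical-frequency collections leaves other pairs unchanged", {
  set.seed(43)
  base <- tiny_baseline(seed = 44, K = 3, L = 150, n = 24)
  info <- sampleInfo(base$G)
  # split P01 into two collections with the same underlying frequencies
  grouping <- info$collection_id
  grouping[info$collection_id == "P01"] <-
    rep(c("P01x", "P01y"), length.out = sum(info$collection_id == "P01"))
  G <- base$G; G@info$collection_id <- grouping
  before <- weirCockerhamFst(G, grouping)$pairwise
  merged <- ifelse(grouping %in% c("P01x", "P01y"), "P01", grouping)
  after <- weirCockerhamFst(G, merged)$pairwise
  expect_lt(abs(before["P02", "P03"] - after["P02", "P03"]), 1e-6)
})

test_that("leave-one-out self-assignment matches an enumeration oracle", {
  # tiny 3-individual baseline, hand-checkable
  d <- rbind(c(2, 0, 1), c(1, 1, 2), c(0, 2, 0))
  G <- gm_from_dosage(d, collection = c("A", "A", "B"))
  sa <- selfAssignment(G)
  for (i in 1:3) {
    want <- oracle_loo_posterior(d, c("A", "A", "B"), i)
    expect_equal(as.numeric(sa$posteriors[i, c("A", "B")]),
                 as.numeric(want[c("A", "B")]), tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(sa$posteriors) - 1) < 1e-10))
  expect_true(all(abs(rowSums(sa$confusion) - 1) < 1e-10))

  # disjoint fixed alleles: perfect self-assignment
  dA <- matrix(2L, 6, 10); dB <- matrix(0L, 6, 10)
  Gd <- gm_from_dosage(rbind(dA, dB), collection = rep(c("A", "B"), each = 6))
  sad <- selfAssignment(Gd)
  expect_equal(unname(sad$self_rates), c(1, 1), tolerance = 1e-6)
  expect_equal(sad$weighted_mean, 1, tolerance = 1e-6)
})


test_that("aggregation merges confusable same-stream collections and only those", {
  # same population sampled twice on one stream: merge expected
  G <- make_agg_baseline(61, same_pop = TRUE, same_stream = TRUE)
  agg <- aggregateCollections(G)
  expect_equal(length(agg$groups), 2)
  expect_true(any(vapply(agg$groups, function(g) setequal(g, c("A1", "A2")),
                         logical(1))))
  merged_theta <- agg$history$theta[1]
  expect_lt(merged_theta, 0.01)

  # well-differentiated collections (theta > 0.01): never merged
  G2 <- make_agg_baseline(62, same_pop = FALSE, same_stream = TRUE)
  agg2 <- aggregateCollections(G2)
  fst2 <- weirCockerhamFst(G2)
  expect_gt(fst2$pairwise["A1", "A2"], 0.01)
  expect_equal(length(agg2$groups), 3)

  # same population but different streams: not merged
  G3 <- make_agg_baseline(61, same_pop = TRUE, same_stream = FALSE)
  agg3 <- aggregateCollections(G3)
  expect_equal(length(agg3$groups), 3)

  # merging strictly reduces the group count, so aggregation terminates
  expect_lte(length(agg$groups), 3 - nrow(agg$history))
})

test_that("small unmerged collections are excluded with a report", {
  set.seed(71)
  d <- matrix(rbinom(23 * 50, 2, 0.5), 23, 50)
  G <- gm_from_dosage(d, collection = c(rep("A", 5), rep("B", 6),
                                        rep("C", 4), rep("D", 8)))
  groups <- list(A = "A", B = "B", CD = c("C", "D"))
  res <- excludeSmallCollections(groups, G, max_n = 5)
  # A has n = 5 -> excluded; B has n = 6 -> kept; C (n = 4) inside a merged
  # unit -> kept
  expect_setequal(names(res$groups), c("B", "CD"))
  expect_equal(res$report$collection_id, "A")
  expect_equal(res$report$n, 5L)

  res2 <- excludeSmallCollections(list(B = "B", D = "D"), G, max_n = 5)
  expect_equal(nrow(res2$report), 0)
})

test_that("reference bias assessment is unbiased for identifiable baselines", {
  # two fully differentiated units
  dA <- matrix(2L, 20, 40); dB <- matrix(0L, 20, 40)
  G <- gm_from_dosage(rbind(dA, dB), collection = rep(c("A", "B"), each = 20))
  units <- baselineUnits(G)
  res <- assessReferenceLoo(units, n_sims = 30, mixture_size = 200, seed = 3,
                            sweeps = 400, burn = 100)
  expect_lt(max(abs(res$summary$mean_residual)), 0.005)
  # residuals sum to ~0 within each simulation (both vectors on the simplex)
  expect_lt(max(abs(rowSums(res$residuals))), 1e-8)
})
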