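test_that("watercourse distances equal exhaustive tree-path sums", {
  net <- toy_network()
  ids <- net@nodes$node
  for (a in c("a", "f", "h", "i")) for (b in c("b", "j", "g", "d")) {
    expect_equal(watercourseDistance(net, a, b),
                 oracle_tree_distance(net@edges, a, b))
  }
  expect_equal(watercourseDistance(net, "e", "e"), 0)
  D <- distanceMatrix(net, ids, "watercourse")
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))

  # four-point condition holds on a tree metric
  q <- c("f", "h", "i", "j")
  s1 <- D["f", "h"] + D["i", "j"]
  s2 <- D["f", "i"] + D["h", "j"]
  s3 <- D["f", "j"] + D["h", "i"]
  sums <- sort(c(s1, s2, s3))
  expect_equal(sums[2], sums[3], tolerance = 1e-12)

  expect_error(watercourseDistance(net, "a", "zz"), "snapped")
})

test_that("the empirical semivariogram matches an all-pairs oracle exactly", {
  set.seed(61)
  net <- toy_network()
  ids <- net@nodes$node
  vals <- setNames(rnorm(length(ids)), ids)
  D <- distanceMatrix(net, ids, "watercourse")
  sv <- empiricalSemivariogram(vals, D, n_bins = 5, min_pairs = 10)
  want <- oracle_semivariogram(vals, D, c(sv$lower, sv$upper[nrow(sv)]))
  expect_equal(sv$gamma, want$gamma)
  expect_equal(sv$n_pairs, want$n_pairs)
  expect_equal(sum(sv$n_pairs), choose(length(ids), 2))
  expect_true(any(sv$low_support))
  expect_equal(attr(sv, "span"), 0.7)

  # constant values: gamma identically zero
  sv0 <- empiricalSemivariogram(setNames(rep(2, length(ids)), ids), D,
                                n_bins = 4)
  expect_true(all(sv0$gamma[!is.na(sv0$gamma)] == 0))

  # euclidean metric and equal-count binning are also supported
  De <- distanceMatrix(net, ids, "euclidean")
  sve <- empiricalSemivariogram(vals, De, n_bins = 3,
                                binning = "equal_count")
  expect_equal(sum(sve$n_pairs), choose(length(ids), 2))
  expect_equal(attr(sve, "metric"), "euclidean")
})

test_that("gradient fields give monotone semivariograms; patches add an inflection", {
  set.seed(62)
  # pure linear gradient on a line of points
  n <- 40
  nodes <- data.frame(node = paste0("n", 1:n), x = 0, y = seq(0, 80,
                                                              length.out = n))
  edges <- data.frame(from = nodes$node[-n], to = nodes$node[-1],
                      length = diff(nodes$y))
  net <- new("StreamNetwork", nodes = nodes, edges = edges,
             sections = data.frame(section = "A",
                                   midpoint_node = nodes$node[1]),
             populations = data.frame(pop_id = character(),
                                      mouth_node = character(),
                                      point_node = character()),
             main_stem = nodes$node)
  De <- distanceMatrix(net, nodes$node, "euclidean")
  grad <- setNames(0.05 * nodes$y, nodes$node)
  svg <- empiricalSemivariogram(grad, De, n_bins = 12, min_pairs = 5)
  ok <- !svg$low_support & !is.na(svg$gamma)
  rho <- cor(svg$mean_distance[ok], svg$gamma[ok], method = "spearman")
  expect_gt(rho, 0.9)
  # a pure gradient triggers no inflection call
  expect_false(semivariogramInflection(svg)$detected)

  # gradient + regional patches: the smoothed slope halves at some interior
  # distance (fine-scale patchiness), flagged by the inflection proxy
  region <- rep(1:8, each = 5)
  patch <- rnorm(8, 0, 1.5)[region]
  vals <- setNames(0.02 * nodes$y + patch + rnorm(n, 0, 0.1), nodes$node)
  Dw <- distanceMatrix(net, nodes$node, "watercourse")
  svp <- empiricalSemivariogram(vals, Dw, n_bins = 12, min_pairs = 5)
  infl <- semivariogramInflection(svp)
  expect_true(infl$detected)
  expect_gt(infl$inflection_km, 0)
})

test_that("latitude trends and region summaries read the generator's structure", {
  # constant intercepts: zero slope, interval covering 0
  lat <- seq(40, 44, length.out = 10)
  tr0 <- latitudeTrend(rep(0.7, 10), lat)
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
  expect_true(tr0$ci[1] <= 0 && 0 <= tr0$ci[2])

  # location equivariance of the slope
  set.seed(63)
  v <- rnorm(10)
  expect_equal(latitudeTrend(v, lat)$slope,
               latitudeTrend(v + 5, lat)$slope, tolerance = 1e-12)
  expect_error(latitudeTrend(v, rep(1, 10)), "zero variance")

  # the generator bakes a south-high gradient into the true unit intercepts
  cfg <- simulationConfig(seed = 64)
  net <- generateNetwork(cfg)
  tr <- generateCovariates(net, cfg)
  lt <- latitudeTrend(tr$alpha_unit_true, tr$northing_km)
  expect_lt(lt$slope, 0)
  expect_lt(lt$ci[2], 0)

  # regions: between-region variance exceeds within-region variance
  rs <- regionSummary(tr$alpha_unit_true, tr$region_id, tr$northing_km)
  expect_equal(sum(rs$n), nrow(tr))
  expect_gt(attr(rs, "f_ratio"), 1)
  # region rows are ordered north to south
  cen <- tapply(tr$northing_km, tr$region_id, mean)
  expect_equal(rs$region, names(sort(-cen)))

  # permuting unit order leaves the table unchanged
  perm <- sample(nrow(tr))
  rs2 <- regionSummary(tr$alpha_unit_true[perm], tr$region_id[perm],
                       tr$northing_km[perm])
  expect_equal(rs2, rs, tolerance = 1e-12)

  # single region: table row equals the global summary
  rs1 <- regionSummary(v, rep("R1", 10))
  expect_equal(rs1$mean, mean(v))
  expect_equal(rs1$sd, sd(v))
})
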