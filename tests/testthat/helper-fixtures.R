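# small in-code fixtures shared across test files

# build a GenotypeMatrix from a dosage matrix (0/1/2 ref copies, NA missing)
gm_from_dosage <- function(d, collection = "C1", role = "baseline",
                           section = NA_character_, year = NA_integer_,
                           ids = NULL, stream = NULL) {
  n <- nrow(d); L <- ncol(d)
  if (is.null(colnames(d))) colnames(d) <- sprintf("L%03d", seq_len(L))
  a1 <- ifelse(d >= 1, "1", "2"); a2 <- ifelse(d == 2, "1", "2")
  a1[is.na(d)] <- NA; a2[is.na(d)] <- NA
  dimnames(a1) <- dimnames(a2) <- dimnames(d)
  info <- data.frame(
    individual_id = ids %||% sprintf("%s_i%02d", rep(collection, length.out = n),
                                     seq_len(n)),
    collection_id = rep(collection, length.out = n),
    role = role, section = section, year = year,
    stringsAsFactors = FALSE)
  if (!is.null(stream)) info$stream_id <- rep(stream, length.out = n)
  GenotypeMatrix(a1, a2, info)
}

`%||%` <- riverGSI:::`%||%`

# simulate a small baseline + units at a given differentiation
tiny_baseline <- function(seed = 1, K = 4, L = 120, n = 30, theta = 0.08,
                          missing = 0) {
  cfg <- simulationConfig(seed = seed, n_populations = K, n_loci = L,
                          theta_fst = theta, n_per_collection = c(n, n),
                          sib_family_rate = 0, missing_rate = missing,
                          connectivity_counts = setNames(
                            c(K, 0, 0, 0),
                            c("connected", "culvert_diversion", "low_flow",
                              "waterfall")))
  freqs <- generateAlleleFrequencies(cfg)
  G <- simulateGenotypes(freqs, cfg)
  list(cfg = cfg, freqs = freqs, G = G, units = baselineUnits(G))
}

# a small fixed tree network for distance tests
toy_network <- function() {
  nodes <- data.frame(node = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
                      x = c(0, 0, 0, 0, 1, 2, -1, -2, 1, -1),
                      y = c(9, 6, 3, 0, 6.5, 7, 2.5, 2, 0.5, 8))
  edges <- data.frame(from = c("a", "b", "c", "b", "e", "c", "g", "d", "a"),
                      to   = c("b", "c", "d", "e", "f", "g", "h", "i", "j"),
                      length = c(3, 3, 3, 1.2, 1.5, 1.1, 1.3, 1.4, 2.2))
  sections <- data.frame(section = c("A", "B"), midpoint_node = c("b", "c"))
  populations <- data.frame(pop_id = c("P1", "P2"),
                            mouth_node = c("b", "c"),
                            point_node = c("f", "h"))
  new("StreamNetwork", nodes = nodes, edges = edges, sections = sections,
      populations = populations, main_stem = c("a", "b", "c", "d"))
}

# baseline trio for aggregation-rule tests: two collections that may share
# a population and/or stream, plus a distinct third population
make_agg_baseline <- function(seed, same_pop = TRUE, same_stream = TRUE,
                              theta = 0.05) {
  set.seed(seed)
  L <- 150
  anc <- runif(L, 0.2, 0.8)
  scale <- (1 - theta) / theta
  fpop <- function() pmin(pmax(rbeta(L, anc * scale, (1 - anc) * scale),
                               1e-4), 1 - 1e-4)
  fA <- fpop(); fB <- fpop()
  fA2 <- if (same_pop) fA else fpop()
  draw <- function(f, n = 25) matrix(rbinom(n * L, 2, rep(f, each = n)), n, L)
  d <- rbind(draw(fA), draw(fA2), draw(fB))
  streams <- c(A1 = "S1", A2 = if (same_stream) "S1" else "S2", B = "S3")
  G <- gm_from_dosage(d, collection = rep(c("A1", "A2", "B"), each = 25),
                      stream = rep(streams, each = 25))
  G
}
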