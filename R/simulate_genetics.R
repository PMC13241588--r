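#' Generate structured population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each population's frequency
#' is Beta-distributed around the ancestral value with variance
#' \code{theta * p * (1 - p)} (the standard F-model), matching a target global
#' FST. Frequencies are clipped away from 0 and 1 by 1e-4.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param seed optional seed override
#' @return matrix (populations x loci) of reference-allele frequencies, with
#'   ancestral frequencies in \code{attr(, "ancestral")}
#' @export
generateAlleleFrequencies <- function(cfg, seed = cfg$seed + 2L) {
  set.seed(seed)
  K <- cfg$n_populations; L <- cfg$n_loci; th <- cfg$theta_fst
  p <- runif(L, 0.05, 0.95)
  scale <- (1 - th) / th
  a <- matrix(p * scale, K, L, byrow = TRUE)
  b <- matrix((1 - p) * scale, K, L, byrow = TRUE)
  f <- matrix(rbeta(K * L, a, b), K, L)
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  dimnames(f) <- list(sprintf("P%02d", seq_len(K)),
                      sprintf("L%03d", seq_len(L)))
  attr(f, "ancestral") <- p
  f
}

# dosage (0/1/2 ref copies) -> two-allele-code matrices; codes "1" = ref, "2" = alt
.dosage_to_calls <- function(d) {
  a1 <- ifelse(d >= 1, "1", "2")
  a2 <- ifelse(d == 2, "1", "2")
  a1[is.na(d)] <- NA; a2[is.na(d)] <- NA
  dimnames(a1) <- dimnames(a2) <- dimnames(d)
  list(a1 = a1, a2 = a2)
}

#' Simulate baseline genotypes under Hardy-Weinberg with full-sib families
#'
#' Independent individuals are binomial Hardy-Weinberg draws from their
#' population's allele frequencies. A configured fraction of individuals is
#' generated as full-sib families: two unobserved parents are drawn under HWE
#' and offspring inherit one allele from each parent (Mendelian sampling).
#' Family labels are recorded in the \code{family} metadata column.
#'
#' @param freqs frequency matrix from \code{\link{generateAlleleFrequencies}}
#' @param cfg a \code{\link{simulationConfig}}
#' @param seed optional seed override
#' @return a \linkS4class{GenotypeMatrix} with role "baseline"; extra info
#'   columns \code{family} and \code{stream_id}
#' @export
simulateGenotypes <- function(freqs, cfg, seed = cfg$seed + 3L) {
  set.seed(seed)
  K <- nrow(freqs); L <- ncol(freqs)
  split_pops <- rownames(freqs)[seq_len(min(cfg$split_populations, K))]
  blocks <- list()
  for (k in seq_len(K)) {
    pop <- rownames(freqs)[k]
    n_k <- cfg$n_per_collection[1] +
      sample.int(cfg$n_per_collection[2] - cfg$n_per_collection[1] + 1L, 1L) - 1L
    p <- freqs[k, ]
    n_sib <- round(cfg$sib_family_rate * n_k)
    fam_sizes <- integer()
    while (sum(fam_sizes) < n_sib)
      fam_sizes <- c(fam_sizes, sample(2:5, 1L))
    d <- matrix(NA_integer_, n_k, L)
    fam <- rep(NA_character_, n_k)
    row <- 1L
    for (fi in seq_along(fam_sizes)) {
      fs <- min(fam_sizes[fi], n_k - row + 1L)
      if (fs < 2) break
      # two parents, then Mendelian offspring
      par1 <- rbinom(L, 2L, p); par2 <- rbinom(L, 2L, p)
      for (o in seq_len(fs)) {
        g1 <- rbinom(L, 1L, par1 / 2)     # allele transmitted by parent 1
        g2 <- rbinom(L, 1L, par2 / 2)
        d[row, ] <- g1 + g2
        fam[row] <- sprintf("%s_fam%d", pop, fi)
        row <- row + 1L
      }
    }
    n_ind <- n_k - row + 1L
    if (n_ind > 0) {
      d[row:n_k, ] <- matrix(rbinom(n_ind * L, 2L, rep(p, each = n_ind)),
                             n_ind, L)
    }
    if (cfg$missing_rate > 0)
      d[matrix(runif(n_k * L) < cfg$missing_rate, n_k, L)] <- NA_integer_
    colnames(d) <- colnames(freqs)
    coll <- rep(pop, n_k)
    if (pop %in% split_pops)
      coll <- paste0(pop, rep(c("a", "b"), length.out = n_k))
    blocks[[k]] <- list(d = d, info = data.frame(
      individual_id = sprintf("%s_i%03d", pop, seq_len(n_k)),
      collection_id = coll, role = "baseline",
      section = NA_character_, year = NA_integer_,
      family = fam, stream_id = pop, stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, lapply(blocks, `[[`, "d"))
  info <- do.call(rbind, lapply(blocks, `[[`, "info"))
  calls <- .dosage_to_calls(d)
  GenotypeMatrix(calls$a1, calls$a2, info)
}

#' Simulate section-year mixture genotypes with known origins
#'
#' Mixture individuals are allocated evenly among sections within each year,
#' origins are drawn multinomially from the true per-section contribution
#' vectors, and genotypes are Hardy-Weinberg draws from the origin
#' population's allele frequencies. True origin labels are kept in the
#' \code{true_origin} metadata column for recovery tests.
#'
#' @param contributions array (populations x sections x years) of true mixing
#'   proportions, e.g. from \code{\link{simulateTrueContributions}}
#' @param freqs frequency matrix (populations x loci)
#' @param cfg a \code{\link{simulationConfig}}
#' @param seed optional seed override
#' @return a \linkS4class{GenotypeMatrix} with role "mixture"; extra info
#'   column \code{true_origin}
#' @export
simulateMixture <- function(contributions, freqs, cfg, seed = cfg$seed + 4L) {
  set.seed(seed)
  K <- nrow(freqs); L <- ncol(freqs)
  S <- dim(contributions)[2]; Y <- dim(contributions)[3]
  blocks <- list()
  for (y in seq_len(Y)) {
    n_by_sec <- drop(rmultinom(1, cfg$mixture_size_per_year, rep(1 / S, S)))
    for (s in seq_len(S)) {
      n <- n_by_sec[s]
      if (n == 0) next
      pi_true <- contributions[, s, y]
      origin <- sample.int(K, n, replace = TRUE, prob = pi_true)
      d <- matrix(rbinom(n * L, 2L, freqs[origin, , drop = FALSE]), n, L)
      if (cfg$missing_rate > 0)
        d[matrix(runif(n * L) < cfg$missing_rate, n, L)] <- NA_integer_
      colnames(d) <- colnames(freqs)
      sec <- LETTERS[s]; yr <- 2019L + y
      blocks[[length(blocks) + 1L]] <- list(d = d, info = data.frame(
        individual_id = sprintf("mx_%s_%d_%04d", sec, yr, seq_len(n)),
        collection_id = NA_character_, role = "mixture",
        section = sec, year = yr,
        true_origin = rownames(freqs)[origin], stringsAsFactors = FALSE))
    }
  }
  d <- do.call(rbind, lapply(blocks, `[[`, "d"))
  info <- do.call(rbind, lapply(blocks, `[[`, "info"))
  calls <- .dosage_to_calls(d)
  GenotypeMatrix(calls$a1, calls$a2, info)
}
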