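#' Pairwise relatedness from the IBD-category moment equations
#'
#' Implements the Wang (2002) moment estimator of pairwise relatedness for
#' biallelic loci. At each locus the joint genotype of a dyad falls into
#' similarity categories (identical; one homozygote/one heterozygote sharing
#' an allele; no shared allele), whose expectations are linear in the
#' two-gene and four-gene IBD coefficients phi and Delta:
#' \deqn{P1 = b + c\,\phi + (1-b)\,\Delta, \qquad P2 = d + e\,\phi - d\,\Delta}
#' with allele-frequency coefficients \code{b = 2*a2^2 - a4},
#' \code{c = a2 - b}, \code{d = 4*(a3 - a4)}, \code{e = 2*(a2 - 3*a3 + 2*a4)}
#' (\code{a_m} = sum of allele frequencies to the m-th power). Category
#' indicators and coefficients are averaged over usable loci and the 2x2
#' system solved exactly; relatedness is \code{r = phi/2 + Delta}. For SNPs
#' the third (three-allele) category is impossible, so the biallelic system
#' is exactly determined and no locus weighting is needed.
#'
#' @param d1,d2 reference-allele dosage vectors (0/1/2, NA = missing) for the
#'   two individuals
#' @param freqs per-locus reference-allele frequencies used as the estimator's
#'   reference distribution
#' @return list: \code{r}, \code{phi}, \code{delta}, \code{n_loci_used}
#' @export
wangRelatedness <- function(d1, d2, freqs) {
  use <- !is.na(d1) & !is.na(d2) & freqs > 0 & freqs < 1
  if (!any(use)) stop("no usable loci: all missing or monomorphic")
  co <- .wang_coef(freqs[use])
  g1 <- d1[use]; g2 <- d2[use]
  s1 <- as.numeric(g1 == g2)
  s2 <- as.numeric((g1 == 1) != (g2 == 1))
  P1 <- mean(s1); P2 <- mean(s2)
  b <- mean(co$b); cc <- mean(co$c); d <- mean(co$d); e <- mean(co$e)
  # [c  (1-b); e  -d] %*% (phi, Delta) = (P1 - b, P2 - d)
  det <- cc * (-d) - (1 - b) * e
  phi <- ((P1 - b) * (-d) - (1 - b) * (P2 - d)) / det
  delta <- (cc * (P2 - d) - e * (P1 - b)) / det
  list(r = phi / 2 + delta, phi = phi, delta = delta,
       n_loci_used = sum(use))
}

.wang_coef <- function(p) {
  a2 <- p^2 + (1 - p)^2
  a3 <- p^3 + (1 - p)^3
  a4 <- p^4 + (1 - p)^4
  b <- 2 * a2^2 - a4
  list(b = b, c = a2 - b, d = 4 * (a3 - a4), e = 2 * (a2 - 3 * a3 + 2 * a4))
}

#' All within-collection pairwise relatedness estimates
#'
#' Reference allele frequencies are computed per collection from all of its
#' individuals (including each evaluated pair). Pairs are only formed within
#' collections; cross-collection relatives are out of scope.
#'
#' @param G a baseline \linkS4class{GenotypeMatrix}
#' @param collections optional subset of collection ids
#' @return data.frame: \code{collection_id}, \code{individual_a},
#'   \code{individual_b}, \code{r}, \code{n_loci_used}
#' @export
pairwiseRelatedness <- function(G, collections = NULL) {
  info <- sampleInfo(G)
  colls <- collections %||% unique(info$collection_id)
  rd <- refDosage(G)
  out <- list()
  for (cl in colls) {
    idx <- which(info$collection_id == cl)
    if (length(idx) < 2) next
    d <- rd$dosage[idx, , drop = FALSE]
    p <- colMeans(d, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0.5
    ids <- info$individual_id[idx]
    pr <- utils::combn(length(idx), 2)
    res <- apply(pr, 2, function(ij) {
      w <- wangRelatedness(d[ij[1], ], d[ij[2], ], p)
      c(w$r, w$n_loci_used)
    })
    out[[cl]] <- data.frame(collection_id = cl,
                            individual_a = ids[pr[1, ]],
                            individual_b = ids[pr[2, ]],
                            r = res[1, ], n_loci_used = as.integer(res[2, ]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group individuals into full-sib families
#'
#' Families are the connected components of the graph whose edges join pairs
#' with relatedness strictly greater than the threshold (default 0.4, the
#' full-sib classification cutoff). Unconnected individuals form singleton
#' families.
#'
#' @param pairs data.frame from \code{\link{pairwiseRelatedness}} (one
#'   collection at a time, or with a \code{collection_id} column; components
#'   never span collections because pairs are within-collection)
#' @param threshold strict lower bound on \code{r} for a full-sib edge
#' @return data.frame: \code{family_id}, \code{individual_id}
#' @export
buildSibFamilies <- function(pairs, threshold = 0.4) {
  ids <- unique(c(pairs$individual_a, pairs$individual_b))
  edges <- pairs[pairs$r > threshold, c("individual_a", "individual_b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  data.frame(family_id = sprintf("fam%03d", comp[ids]),
             individual_id = ids, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Prune full-sib families to at most two members
#'
#' Families larger than two are reduced to the two members with the highest
#' genotyping call rate (ties broken by lexicographically smallest
#' individual id); families of one or two are kept whole.
#'
#' @param families data.frame from \code{\link{buildSibFamilies}}
#' @param G the \linkS4class{GenotypeMatrix} the families were built from
#' @return character vector of retained individual ids
#' @export
pruneFamilies <- function(families, G) {
  cr <- callRate(G)
  keep <- lapply(split(families$individual_id, families$family_id),
                 function(members) {
    if (length(members) <= 2) return(members)
    ord <- order(-cr[members], members)
    members[ord][1:2]
  })
  sort(unlist(keep, use.names = FALSE))
}

#' Apply the full sibling filter to a baseline
#'
#' Convenience wrapper: estimates within-collection relatedness, builds
#' families at the threshold, prunes to two per family and returns the
#' filtered baseline plus the intermediate tables.
#'
#' @param G a baseline \linkS4class{GenotypeMatrix}
#' @param threshold full-sib classification threshold (default 0.4)
#' @return list: \code{genotypes}, \code{pairs}, \code{families},
#'   \code{retained_ids}
#' @export
siblingFilter <- function(G, threshold = 0.4) {
  pairs <- pairwiseRelatedness(G)
  fams <- buildSibFamilies(pairs, threshold)
  retained <- pruneFamilies(fams, G)
  solo <- setdiff(sampleInfo(G)$individual_id, fams$individual_id)
  keep <- sampleInfo(G)$individual_id %in% c(retained, solo)
  list(genotypes = G[keep, ], pairs = pairs, families = fams,
       retained_ids = sort(c(retained, solo)))
}
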