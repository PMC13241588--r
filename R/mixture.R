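#' Dirichlet-posterior mean allele frequencies for reporting units
#'
#' Conjugate smoothing of baseline counts: frequency = (count + prior) /
#' (total + sum of priors), with prior 1/(number of alleles) per allele (0.5
#' for SNPs). With no observations a SNP locus gets (0.5, 0.5).
#'
#' @param units a \linkS4class{BaselineUnits}
#' @param prior per-allele prior weight (default 0.5)
#' @return matrix (units x loci) of reference-allele frequencies
#' @export
unitPosteriorFreqs <- function(units, prior = 0.5) {
  (units@ref_counts + prior) / (units@tot_counts + 2 * prior)
}

# Hardy-Weinberg genotype log-likelihood matrix (individuals x units) from a
# reference-allele dosage matrix and per-unit frequencies. Missing loci are
# skipped; the log(2) heterozygote term is included.
.loglik_matrix <- function(dosage, freqs) {
  if (any(rowSums(!is.na(dosage)) == 0))
    stop("individual(s) with no called loci: ",
         paste(head(rownames(dosage)[rowSums(!is.na(dosage)) == 0]),
               collapse = ", "))
  Dm <- dosage; Dm[is.na(Dm)] <- 0L
  Tm <- 2L - dosage; Tm[is.na(Tm)] <- 0L
  nhet <- rowSums(dosage == 1, na.rm = TRUE)
  ll <- Dm %*% t(log(freqs)) + Tm %*% t(log(1 - freqs)) + nhet * log(2)
  if (any(!is.finite(ll)))
    stop("non-finite genotype log-likelihood (zero frequency?)")
  colnames(ll) <- rownames(freqs)
  ll
}

#' Genotype log-likelihood of mixture individuals under each unit
#'
#' Sum over called loci of the Hardy-Weinberg genotype log-probability
#' (p^2 / 2pq / q^2) at each unit's Dirichlet-posterior mean frequencies.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param units a \linkS4class{BaselineUnits}
#' @return matrix (individuals x units)
#' @export
genotypeLoglik <- function(G, units) {
  rd <- refDosage(G, units@alleles)
  .loglik_matrix(rd$dosage, unitPosteriorFreqs(units))
}

# Conditional Gibbs sampler for mixing proportions given a fixed
# log-likelihood matrix. Returns pi draws (post burn-in), posterior mean
# responsibilities and the posterior mean pi.
.gibbs_pi <- function(ll, sweeps, burn, prior) {
  n <- nrow(ll); U <- ncol(ll)
  lmax <- apply(ll, 1, max)
  lik <- exp(ll - lmax)                       # n x U, scaled likelihoods
  pi_cur <- rep(1 / U, U)
  keep <- sweeps - burn
  pi_draws <- matrix(0, keep, U, dimnames = list(NULL, colnames(ll)))
  resp_acc <- matrix(0, n, U)
  for (t in seq_len(sweeps)) {
    resp <- lik * rep(pi_cur, each = n)
    resp <- resp / rowSums(resp)
    z <- sample_rows(resp)
    counts <- tabulate(z, nbins = U)
    pi_cur <- rdirichlet1(prior + counts)
    if (t > burn) {
      pi_draws[t - burn, ] <- pi_cur
      resp_acc <- resp_acc + resp
    }
  }
  resp <- resp_acc / keep
  dimnames(resp) <- dimnames(ll)
  list(pi_draws = pi_draws, pi_mean = colMeans(pi_draws), resp = resp)
}

#' Fit the Bayesian mixture model for one section-year stratum
#'
#' Conditional genetic stock identification: baseline allele frequencies are
#' fixed at their Dirichlet-posterior means and a Gibbs sampler alternates
#' latent origins z_i ~ Categorical(pi_u L_iu / sum) with
#' pi ~ Dirichlet(1/U + counts). Individual posteriors are posterior-mean
#' responsibilities; mixing proportions are the post-burn-in mean of the pi
#' draws.
#'
#' @param units a \linkS4class{BaselineUnits}
#' @param G mixture \linkS4class{GenotypeMatrix} (one stratum; use
#'   \code{\link{splitStrata}} to partition a multi-stratum mixture)
#' @param sweeps,burn Gibbs sweeps and burn-in (defaults 2000 / 500)
#' @param seed integer seed
#' @return a \linkS4class{MixtureFit}
#' @export
fitMixture <- function(units, G, sweeps = 2000L, burn = 500L, seed = 1L) {
  stopifnot(nrow(units@units) >= 2, nIndividuals(G) >= 1)
  set.seed(seed)
  ll <- genotypeLoglik(G, units)
  U <- ncol(ll)
  gs <- .gibbs_pi(ll, sweeps, burn, prior = rep(1 / U, U))
  info <- sampleInfo(G)
  new("MixtureFit",
      stratum = list(section = info$section[1] %||% NA_character_,
                     year = info$year[1] %||% NA_integer_),
      unit_ids = unitIds(units),
      pi_mean = unname(gs$pi_mean), pi_draws = gs$pi_draws,
      indiv_posteriors = gs$resp, pi_corrected = numeric(0),
      z_scores = data.frame(),
      meta = list(sweeps = sweeps, burn = burn, seed = seed,
                  prior = paste0("Dirichlet(1/", U, ")")))
}

#' Split a mixture GenotypeMatrix into section-year strata
#'
#' @param G a mixture \linkS4class{GenotypeMatrix}
#' @return named list of \code{GenotypeMatrix}, names "section_year"
#' @export
splitStrata <- function(G) {
  info <- sampleInfo(G)
  key <- paste(info$section, info$year, sep = "_")
  lapply(split(seq_len(nIndividuals(G)), key), function(i) G[i, ])
}

# Gene-drop a simulated mixture individual set from baseline allele pools:
# origins 'orig' (unit indices), counts X/TT from the units. Returns the
# dosage matrix and the leave-one-out-corrected log-likelihood matrix.
.genedrop_loglik <- function(units, orig, freqs = unitPosteriorFreqs(units)) {
  X <- units@ref_counts; TT <- units@tot_counts
  L <- ncol(X); n <- length(orig)
  d <- matrix(0L, n, L)
  for (u in unique(orig)) {
    rows <- which(orig == u)
    ok <- TT[u, ] >= 2
    for (i in rows) {
      di <- rep(NA_integer_, L)
      di[ok] <- rhyper(sum(ok), X[u, ok], TT[u, ok] - X[u, ok], 2)
      d[i, ] <- di
    }
  }
  ll <- .loglik_matrix(d, freqs)
  # leave the drawn alleles out of the origin unit's own counts
  for (i in seq_len(n)) {
    u <- orig[i]
    di <- d[i, ]; called <- !is.na(di)
    p <- (X[u, called] - di[called] + 0.5) / (TT[u, called] - 2 + 1)
    dc <- di[called]
    ll[i, u] <- sum(dc * log(p) + (2 - dc) * log(1 - p) + (dc == 1) * log(2))
  }
  list(dosage = d, loglik = ll)
}

#' Parametric-bootstrap bias correction of mixing proportions
#'
#' Simulates B mixtures of the stratum's size by gene-dropping from the
#' baseline allele pools with true proportions equal to the fitted posterior
#' mean (each simulated individual's alleles are left out of its own unit's
#' counts when its likelihood is evaluated), re-estimates each, and
#' subtracts the mean estimation bias. The corrected vector is clipped at
#' zero and renormalized.
#'
#' @param fit a \linkS4class{MixtureFit}
#' @param units the \linkS4class{BaselineUnits} used for the fit
#' @param B bootstrap replicates (default 100)
#' @param seed integer seed
#' @param sweeps,burn Gibbs settings for the bootstrap re-estimates
#' @return the \code{MixtureFit} with \code{pi_corrected} filled in
#' @export
bootstrapCorrect <- function(fit, units, B = 100L, seed = 1L,
                             sweeps = 600L, burn = 150L) {
  set.seed(seed)
  n <- nrow(fit@indiv_posteriors)
  U <- length(fit@unit_ids)
  pi0 <- fit@pi_mean
  freqs <- unitPosteriorFreqs(units)
  est <- matrix(0, B, U)
  for (b in seq_len(B)) {
    orig <- sample.int(U, n, replace = TRUE, prob = pi0)
    gd <- .genedrop_loglik(units, orig, freqs)
    est[b, ] <- .gibbs_pi(gd$loglik, sweeps, burn, rep(1 / U, U))$pi_mean
  }
  bias <- colMeans(est) - pi0
  corrected <- pmax(pi0 - bias, 0)
  corrected <- corrected / sum(corrected)
  fit@pi_corrected <- corrected
  fit@meta$bootstrap <- list(B = B, seed = seed, sweeps = sweeps, burn = burn)
  validObject(fit)
  fit
}

#' z-scores of mixture individuals under their assigned unit
#'
#' z = (observed log-likelihood - mu) / sigma where mu and sigma^2 are the
#' exact mean and variance of the Hardy-Weinberg genotype log-probability
#' summed over the individual's called loci, at the assigned (maximum
#' posterior) unit's frequencies. Individuals whose z lies more than two
#' empirical standard deviations from the stratum mean are flagged as
#' potentially originating outside the baseline.
#'
#' @param G the stratum's mixture \linkS4class{GenotypeMatrix}
#' @param fit the stratum's \linkS4class{MixtureFit}
#' @param units the \linkS4class{BaselineUnits}
#' @return data.frame: individual_id, assigned_unit, max_posterior, z,
#'   flagged_missing_source
#' @export
zScores <- function(G, fit, units) {
  rd <- refDosage(G, units@alleles)
  d <- rd$dosage
  freqs <- unitPosteriorFreqs(units)
  assigned <- max.col(fit@indiv_posteriors)
  n <- nrow(d)
  z <- numeric(n)
  for (i in seq_len(n)) {
    p <- freqs[assigned[i], ]
    called <- !is.na(d[i, ])
    p <- p[called]; q <- 1 - p
    lp <- cbind(2 * log(p), log(2 * p * q), 2 * log(q))
    pr <- cbind(p^2, 2 * p * q, q^2)
    mu_l <- rowSums(pr * lp)
    var_l <- rowSums(pr * lp^2) - mu_l^2
    dc <- d[i, called]
    obs <- sum(dc * log(p) + (2 - dc) * log(q) + (dc == 1) * log(2))
    sig <- sqrt(sum(var_l))
    if (sig == 0) {
      rg_warn("all loci fixed for individual %s; z undefined", rownames(d)[i])
      z[i] <- NA_real_
      next
    }
    z[i] <- (obs - sum(mu_l)) / sig
  }
  mz <- mean(z, na.rm = TRUE); sz <- sd(z, na.rm = TRUE)
  data.frame(individual_id = sampleInfo(G)$individual_id,
             assigned_unit = fit@unit_ids[assigned],
             max_posterior = fit@indiv_posteriors[cbind(seq_len(n), assigned)],
             z = z,
             flagged_missing_source = !is.na(z) & abs(z - mz) > 2 * sz,
             stringsAsFactors = FALSE)
}

#' Dispersal distances from section of capture to assigned origin
#'
#' For individuals assigned to a single unit with posterior above the
#' threshold, the flow-line distance between the capture section's midpoint
#' and the origin unit's network point.
#'
#' @param fits list of \linkS4class{MixtureFit} (one per stratum)
#' @param net a \linkS4class{StreamNetwork}
#' @param units a \linkS4class{BaselineUnits} with network points
#' @param prob_threshold minimum maximum-posterior (default 0.7)
#' @return list: \code{individuals} (data.frame with distance_km),
#'   \code{median_km}, \code{max_km}, \code{prob_threshold}
#' @export
dispersalSummary <- function(fits, net, units, prob_threshold = 0.7) {
  pts <- setNames(units@units$point_node, units@units$unit_id)
  rows <- list()
  for (fit in fits) {
    post <- fit@indiv_posteriors
    if (!nrow(post)) next
    a <- max.col(post)
    mp <- post[cbind(seq_len(nrow(post)), a)]
    keep <- mp > prob_threshold
    if (!any(keep)) next
    unit <- fit@unit_ids[a[keep]]
    sec <- fit@stratum$section
    mid <- net@sections$midpoint_node[net@sections$section == sec]
    pn <- pts[unit]
    ok <- !is.na(pn)
    if (any(!ok)) rg_warn("%d assignments to units without network points excluded",
                          sum(!ok))
    if (!any(ok)) next
    dist <- watercourseDistance(net, unique(pn[ok]), mid)
    if (!is.matrix(dist)) dist <- matrix(dist, 1, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = rownames(post)[keep][ok],
      section = sec, year = fit@stratum$year,
      origin_unit = unit[ok],
      max_posterior = mp[keep][ok],
      distance_km = dist[match(pn[ok], unique(pn[ok])), 1],
      stringsAsFactors = FALSE)
  }
  ind <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(), section = character(),
               year = integer(), origin_unit = character(),
               max_posterior = numeric(), distance_km = numeric())
  list(individuals = ind,
       median_km = if (nrow(ind)) median(ind$distance_km) else NA_real_,
       max_km = if (nrow(ind)) max(ind$distance_km) else NA_real_,
       prob_threshold = prob_threshold)
}

#' Baseline accuracy assessment by leave-one-out mixture simulation
#'
#' For each simulation, true mixing proportions are drawn from a flat
#' Dirichlet over units, a mixture of \code{mixture_size} individuals is
#' gene-dropped from the baseline allele pools (each individual's alleles
#' left out of its own unit when evaluated), proportions are re-estimated
#' with the Gibbs mixture engine, and residuals (true - estimated) are
#' accumulated per unit.
#'
#' @param units a \linkS4class{BaselineUnits}
#' @param n_sims number of simulated mixtures (study-scale default 500)
#' @param mixture_size individuals per simulated mixture (default 1000)
#' @param seed integer seed
#' @param sweeps,burn Gibbs settings for each re-estimate
#' @return list: \code{summary} (per-unit mean, sd, and whether the
#'   mean +/- sd interval overlaps 0), \code{residuals} (sims x units)
#' @export
assessReferenceLoo <- function(units, n_sims = 500L, mixture_size = 1000L,
                               seed = 1L, sweeps = 600L, burn = 150L) {
  stopifnot(nrow(units@units) >= 2)
  set.seed(seed)
  U <- nrow(units@units)
  freqs <- unitPosteriorFreqs(units)
  resid <- matrix(0, n_sims, U, dimnames = list(NULL, unitIds(units)))
  for (s in seq_len(n_sims)) {
    pi_true <- rdirichlet1(rep(1, U))
    orig <- sample.int(U, mixture_size, replace = TRUE, prob = pi_true)
    gd <- .genedrop_loglik(units, orig, freqs)
    est <- .gibbs_pi(gd$loglik, sweeps, burn, rep(1 / U, U))$pi_mean
    resid[s, ] <- pi_true - est
  }
  m <- colMeans(resid); sdev <- apply(resid, 2, sd)
  list(summary = data.frame(unit_id = unitIds(units), mean_residual = m,
                            sd_residual = sdev,
                            overlaps_zero = (m - sdev) <= 0 & 0 <= (m + sdev),
                            row.names = NULL),
       residuals = resid)
}
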