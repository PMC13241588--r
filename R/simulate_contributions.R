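#' Coefficients of the zero-inflated beta forward model
#'
#' The contribution of source population r to section s (and year y) is
#' generated from a zero-inflated beta model: a structural zero occurs with
#' probability omega (logit-linear in covariates), otherwise the contribution
#' is Beta-distributed with mean mu (logit-linear, with section and unit
#' intercepts and a section-varying groundwater slope) and precision phi
#' (log-linear). Continuous covariates enter standardized.
#'
#' Default magnitudes encode the qualitative pattern the model is meant to
#' produce: contributions decline with distance, increase with catchment area
#' and groundwater, and barriers (waterfall most of all) reduce them.
#'
#' @param alpha_mu global logit-mean intercept (contributions of order 1/R).
#' @param beta_distance,beta_area,beta_groundwater slopes on the standardized
#'   covariates in the mean model; \code{beta_groundwater} may be a scalar or
#'   one value per section.
#' @param beta_connectivity named offsets (reference "connected") in the mean
#'   model.
#' @param alpha_omega,beta_omega_distance,beta_omega_area,beta_omega_groundwater,beta_omega_connectivity
#'   zero-probability model (logit link).
#' @param alpha_phi,beta_phi_distance,beta_phi_area,beta_phi_groundwater,beta_phi_connectivity
#'   precision model (log link).
#' @param sd_section,sd_unit random-intercept standard deviations.
#' @param lat_slope slope of the true unit intercepts on the standardized
#'   latitude proxy (negative: southerly tributaries contribute more).
#' @param sd_region standard deviation of regional patches in the true unit
#'   intercepts.
#' @return list of class \code{zib_coefficients}
#' @export
zibCoefficients <- function(alpha_mu = -3,
                            beta_distance = -0.8,
                            beta_area = 0.5,
                            beta_groundwater = 0.3,
                            beta_connectivity = c(culvert_diversion = -1,
                                                  low_flow = -1,
                                                  waterfall = -1.5),
                            alpha_omega = qlogis(0.2),
                            beta_omega_distance = 0.8,
                            beta_omega_area = -0.5,
                            beta_omega_groundwater = 0,
                            beta_omega_connectivity = c(culvert_diversion = 0,
                                                        low_flow = 0,
                                                        waterfall = 0),
                            alpha_phi = 4,
                            beta_phi_distance = 0.3,
                            beta_phi_area = -0.2,
                            beta_phi_groundwater = -0.1,
                            beta_phi_connectivity = c(culvert_diversion = 0,
                                                      low_flow = 0,
                                                      waterfall = 0),
                            sd_section = 0.3,
                            sd_unit = 0.3,
                            lat_slope = -0.5,
                            sd_region = 0.4) {
  coef <- list(alpha_mu = alpha_mu, beta_distance = beta_distance,
               beta_area = beta_area, beta_groundwater = beta_groundwater,
               beta_connectivity = beta_connectivity,
               alpha_omega = alpha_omega,
               beta_omega_distance = beta_omega_distance,
               beta_omega_area = beta_omega_area,
               beta_omega_groundwater = beta_omega_groundwater,
               beta_omega_connectivity = beta_omega_connectivity,
               alpha_phi = alpha_phi, beta_phi_distance = beta_phi_distance,
               beta_phi_area = beta_phi_area,
               beta_phi_groundwater = beta_phi_groundwater,
               beta_phi_connectivity = beta_phi_connectivity,
               sd_section = sd_section, sd_unit = sd_unit,
               lat_slope = lat_slope, sd_region = sd_region)
  stopifnot(all(vapply(coef, function(x) all(is.finite(x)), logical(1))))
  class(coef) <- "zib_coefficients"
  coef
}

# assemble the long covariate table for the forward model: one row per
# (population, section), with standardized distance, log-area and groundwater
.covariate_table <- function(truth, net) {
  S <- nrow(net@sections)
  mids <- net@sections$midpoint_node
  D <- watercourseDistance(net, truth$point_node, mids)  # R x S km
  long <- expand.grid(r = seq_len(nrow(truth)), s = seq_len(S))
  df <- data.frame(pop_id = truth$pop_id[long$r],
                   section = net@sections$section[long$s],
                   distance_km = D[cbind(long$r, long$s)],
                   area_km2 = truth$area_km2[long$r],
                   groundwater = truth$groundwater[long$r],
                   connectivity = truth$connectivity[long$r],
                   stringsAsFactors = FALSE)
  zd <- standardize(df$distance_km)
  za <- standardize(log(df$area_km2))
  zg <- standardize(df$groundwater)
  df$z_distance <- zd$z; df$z_area <- za$z; df$z_groundwater <- zg$z
  attr(df, "scaling") <- list(distance = zd[c("mean", "sd")],
                              area = za[c("mean", "sd")],
                              groundwater = zg[c("mean", "sd")])
  df
}

# evaluate (omega, mu, phi) for the forward model on the long covariate table
.forward_predictors <- function(cov, coef, alpha_section, alpha_unit) {
  S <- length(alpha_section)
  sidx <- as.integer(factor(cov$section))
  ridx <- as.integer(factor(cov$pop_id))
  b3 <- rep(coef$beta_groundwater, length.out = S)
  cn <- as.character(cov$connectivity)
  conn_mu <- ifelse(cn == "connected", 0, coef$beta_connectivity[cn])
  conn_om <- ifelse(cn == "connected", 0, coef$beta_omega_connectivity[cn])
  conn_ph <- ifelse(cn == "connected", 0, coef$beta_phi_connectivity[cn])
  eta_mu <- coef$alpha_mu + alpha_section[sidx] + alpha_unit[ridx] +
    coef$beta_distance * cov$z_distance + coef$beta_area * cov$z_area +
    b3[sidx] * cov$z_groundwater + conn_mu
  eta_om <- coef$alpha_omega + coef$beta_omega_distance * cov$z_distance +
    coef$beta_omega_area * cov$z_area +
    coef$beta_omega_groundwater * cov$z_groundwater + conn_om
  eta_ph <- coef$alpha_phi + coef$beta_phi_distance * cov$z_distance +
    coef$beta_phi_area * cov$z_area +
    coef$beta_phi_groundwater * cov$z_groundwater + conn_ph
  list(omega = plogis(eta_om), mu = plogis(eta_mu), phi = exp(eta_ph))
}

#' Simulate true tributary contributions from the forward model
#'
#' For every (population, section) cell — replicated per year when
#' \code{year_mode = "iid"}, held constant otherwise — a structural zero is
#' drawn with probability omega, otherwise a Beta(mu*phi, (1-mu)*phi) value.
#' Nonzero entries are renormalized within each section(-year) to form exact
#' mixing proportions; the pre-normalization draws are kept as the
#' regression-scale truth. A section whose draws are all zero is resampled
#' with a warning.
#'
#' @param truth covariate table from \code{\link{generateCovariates}}
#' @param net the \linkS4class{StreamNetwork}
#' @param cfg a \code{\link{simulationConfig}}
#' @param seed optional seed override
#' @return list: \code{contributions} (populations x sections x years array
#'   of simplex vectors), \code{p_pre} (pre-normalization draws, long
#'   data.frame with covariates), \code{covariates} (per population-section
#'   table), \code{alpha_section}, \code{expected_mu}
#' @export
simulateTrueContributions <- function(truth, net, cfg, seed = cfg$seed + 5L) {
  set.seed(seed)
  coef <- cfg$zib_coefficients
  S <- nrow(net@sections); R <- nrow(truth); Y <- cfg$n_years
  cov <- .covariate_table(truth, net)
  alpha_section <- rnorm(S, 0, coef$sd_section)
  pred <- .forward_predictors(cov, coef, alpha_section, truth$alpha_unit_true)
  n_draw_years <- if (cfg$year_mode == "iid") Y else 1L
  contributions <- array(0, dim = c(R, S, Y),
                         dimnames = list(truth$pop_id, net@sections$section,
                                         2019L + seq_len(Y)))
  pre <- list()
  sidx <- as.integer(factor(cov$section))
  for (y in seq_len(n_draw_years)) {
    p <- numeric(nrow(cov))
    for (s in seq_len(S)) {
      rows <- which(sidx == s)
      repeat {
        z <- rbinom(length(rows), 1L, pred$omega[rows])
        draw <- ifelse(z == 1L, 0,
                       rbeta(length(rows), pred$mu[rows] * pred$phi[rows],
                             (1 - pred$mu[rows]) * pred$phi[rows]))
        if (any(draw > 0)) break
        rg_warn("all-zero section %s resampled", net@sections$section[s])
      }
      p[rows] <- draw
      contributions[, s, if (cfg$year_mode == "iid") y else seq_len(Y)] <-
        draw / sum(draw)
    }
    yrs <- if (cfg$year_mode == "iid") 2019L + y else NA_integer_
    pre[[y]] <- data.frame(cov, year = yrs, p_pre = p,
                           stringsAsFactors = FALSE)
  }
  p_pre <- do.call(rbind, pre)
  list(contributions = contributions, p_pre = p_pre, covariates = cov,
       alpha_section = alpha_section, expected_mu = pred$mu,
       expected_omega = pred$omega)
}

#' Simulate a synthetic riverscape end to end
#'
#' Runs the full generator chain: network, covariates, allele frequencies,
#' baseline genotypes, true contributions and mixture genotypes. Everything
#' is reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @return list with elements \code{network}, \code{truth} (covariates and
#'   true intercepts per population), \code{freqs}, \code{baseline},
#'   \code{mixture}, \code{contributions} (output of
#'   \code{\link{simulateTrueContributions}}), and \code{config}
#' @export
simulateRiverscape <- function(cfg = simulationConfig()) {
  net <- generateNetwork(cfg)
  truth <- generateCovariates(net, cfg)
  freqs <- generateAlleleFrequencies(cfg)
  baseline <- simulateGenotypes(freqs, cfg)
  contrib <- simulateTrueContributions(truth, net, cfg)
  mixture <- simulateMixture(contrib$contributions, freqs, cfg)
  list(network = net, truth = truth, freqs = freqs, baseline = baseline,
       mixture = mixture, contributions = contrib, config = cfg)
}

#' Simulate a dataset directly from the zero-inflated beta model
#'
#' Draws contributions for a fully crossed (population, section, year) design
#' given a covariate table and coefficients — the self-simulation used for
#' coverage and posterior-predictive calibration of \code{\link{fitZib}}.
#'
#' @param cov covariate table with columns \code{pop_id}, \code{section},
#'   \code{z_distance}, \code{z_area}, \code{z_groundwater},
#'   \code{connectivity}
#' @param coef a \code{\link{zibCoefficients}} list
#' @param n_years number of iid yearly replicates
#' @param alpha_section,alpha_unit optional fixed intercept vectors; drawn
#'   from their standard deviations when NULL
#' @param seed integer seed
#' @return data.frame of observations (r, s, y, p and covariates) with the
#'   intercepts used attached as attributes
#' @export
simulateZibData <- function(cov, coef = zibCoefficients(), n_years = 3L,
                            alpha_section = NULL, alpha_unit = NULL,
                            seed = 1L) {
  set.seed(seed)
  S <- length(unique(cov$section)); R <- length(unique(cov$pop_id))
  if (is.null(alpha_section)) alpha_section <- rnorm(S, 0, coef$sd_section)
  if (is.null(alpha_unit)) alpha_unit <- rnorm(R, 0, coef$sd_unit)
  pred <- .forward_predictors(cov, coef, alpha_section, alpha_unit)
  out <- list()
  for (y in seq_len(n_years)) {
    z <- rbinom(nrow(cov), 1L, pred$omega)
    p <- ifelse(z == 1L, 0,
                rbeta(nrow(cov), pred$mu * pred$phi, (1 - pred$mu) * pred$phi))
    out[[y]] <- data.frame(cov, year = y, p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha_section") <- alpha_section
  attr(res, "alpha_unit") <- alpha_unit
  res
}
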