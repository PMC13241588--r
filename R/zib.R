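#' Zero-inflated beta density
#'
#' Piecewise density for a proportion with inflation at zero: probability
#' omega of an exact zero, otherwise a Beta density in mean-precision
#' parameterization (shape1 = mu*phi, shape2 = (1-mu)*phi) on (0, 1).
#'
#' @param p values in [0, 1); vectorized
#' @param omega zero-inflation probability in [0, 1]
#' @param mu,phi Beta mean in (0, 1) and precision > 0
#' @return density values (a point mass omega at 0; (1-omega) times the Beta
#'   density on the interior)
#' @export
zibDensity <- function(p, omega, mu, phi) {
  stopifnot(all(omega >= 0 & omega <= 1), all(mu > 0 & mu < 1), all(phi > 0))
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  ifelse(p == 0, omega,
         (1 - omega) * dbeta(p, mu * phi, (1 - mu) * phi))
}

#' Linear predictors of the contribution model
#'
#' Evaluates (omega, mu, phi) for observations with standardized covariates
#' under a coefficient set: logit-linear mean with section and unit
#' intercepts and a section-varying groundwater slope, logit-linear zero
#' probability, log-linear precision.
#'
#' @param cov data.frame with columns \code{pop_id}, \code{section},
#'   \code{z_distance}, \code{z_area}, \code{z_groundwater},
#'   \code{connectivity}
#' @param coef a \code{\link{zibCoefficients}} list
#' @param alpha_section,alpha_unit intercept vectors (default all zero)
#' @return data.frame with columns \code{omega}, \code{mu}, \code{phi}
#' @export
linearPredictors <- function(cov, coef,
                             alpha_section = NULL, alpha_unit = NULL) {
  lev <- as.character(cov$connectivity)
  known <- c("connected", names(coef$beta_connectivity))
  if (!all(lev %in% known))
    stop("unknown connectivity level: ",
         paste(setdiff(lev, known), collapse = ", "))
  S <- length(unique(cov$section)); R <- length(unique(cov$pop_id))
  if (is.null(alpha_section)) alpha_section <- numeric(S)
  if (is.null(alpha_unit)) alpha_unit <- numeric(R)
  pred <- .forward_predictors(cov, coef, alpha_section, alpha_unit)
  data.frame(omega = pred$omega, mu = pred$mu, phi = pred$phi)
}

# build the three design matrices from an observation table
.zib_design <- function(data) {
  sec <- factor(data$section)
  unit <- factor(data$pop_id)
  conn <- factor(as.character(data$connectivity),
                 levels = c("connected", "culvert_diversion", "low_flow",
                            "waterfall"))
  conn <- droplevels(conn)
  Cm <- if (nlevels(conn) > 1)
    model.matrix(~conn)[, -1, drop = FALSE] else
    matrix(0, nrow(data), 0)
  if (ncol(Cm)) colnames(Cm) <- sub("^conn", "conn_", colnames(Cm))
  Gsec <- sapply(levels(sec), function(s)
    data$z_groundwater * (sec == s))
  colnames(Gsec) <- paste0("beta_groundwater[", levels(sec), "]")
  Xmu <- cbind(alpha_mu = 1, beta_distance = data$z_distance,
               beta_area = data$z_area, Gsec, Cm)
  Xbase <- cbind(1, data$z_distance, data$z_area, data$z_groundwater, Cm)
  list(Xmu = Xmu, Xph = Xbase, Xom = Xbase,
       sec = as.integer(sec), unit = as.integer(unit),
       sections = levels(sec), units = levels(unit),
       conn_names = colnames(Cm))
}

.zib_par_names <- function(ds) {
  conn <- if (length(ds$conn_names)) paste0("beta_mu_", ds$conn_names) else character()
  base <- function(pre) c(paste0("alpha_", pre),
                          paste0("beta_", pre, "_distance"),
                          paste0("beta_", pre, "_area"),
                          paste0("beta_", pre, "_groundwater"),
                          if (length(ds$conn_names))
                            paste0("beta_", pre, "_", ds$conn_names))
  c(colnames(ds$Xmu)[1:(3 + length(ds$sections))], conn,
    paste0("alpha_section[", ds$sections, "]"),
    paste0("alpha_unit[", ds$units, "]"),
    base("phi"), base("omega"),
    "sd_section", "sd_unit")
}

#' Fit the hierarchical zero-inflated beta contribution model
#'
#' Joint Bayesian fit of the three linear predictors: logit mean (global
#' intercept, section and unit random intercepts, distance, area,
#' section-varying groundwater slope, connectivity contrasts), logit zero
#' probability and log precision (intercept plus the four covariates each).
#' Continuous covariates are z-score standardized over the dataset (area on
#' the log scale) unless \code{z_*} columns are supplied. Sampling is by a
#' componentwise adaptive random-walk Metropolis sampler (compiled),
#' initialized from generalized-linear-model fits and run as several
#' independent chains; split-Rhat and effective sample sizes are reported
#' for every parameter, and the fit is returned with a warning (not
#' discarded) when any split-Rhat is 1.01 or more.
#'
#' Priors: normal(0, 5) on all fixed effects, hierarchical normal(0, sd) on
#' section and unit intercepts with half-normal(0, 2) scales.
#'
#' @param data data.frame with columns \code{pop_id}, \code{section},
#'   \code{year}, \code{p} (contribution in [0, 1)), covariates either raw
#'   (\code{distance_km}, \code{area_km2}, \code{groundwater}) or
#'   standardized (\code{z_distance}, \code{z_area}, \code{z_groundwater}),
#'   and \code{connectivity}
#' @param chains,warmup,iter MCMC chains (default 4), warmup and retained
#'   iterations per chain (defaults 2000 / 2000)
#' @param seed integer seed
#' @param prior_sd fixed-effect prior standard deviation
#' @return a \linkS4class{ZibFit}
#' @export
fitZib <- function(data, chains = 4L, warmup = 2000L, iter = 2000L,
                   seed = 1L, prior_sd = 5) {
  data <- as.data.frame(data)
  stopifnot(all(c("pop_id", "section", "p") %in% names(data)))
  if (any(data$p < 0 | data$p > 1)) stop("p must lie in [0, 1]")
  if (any(data$p == 1)) {
    rg_warn("%d contribution(s) equal to 1 squeezed to 1 - 1e-6", sum(data$p == 1))
    data$p[data$p == 1] <- 1 - 1e-6
  }
  scaling <- list()
  if (is.null(data$z_distance)) {
    zd <- standardize(data$distance_km); data$z_distance <- zd$z
    za <- standardize(log(data$area_km2)); data$z_area <- za$z
    zg <- standardize(data$groundwater); data$z_groundwater <- zg$z
    scaling <- list(distance = zd[c("mean", "sd")], area = za[c("mean", "sd")],
                    groundwater = zg[c("mean", "sd")])
  }
  if (length(unique(data$section)) < 2 || length(unique(data$pop_id)) < 2)
    stop("need at least two sections and two units")
  z <- as.integer(data$p == 0)
  if (all(z == 0) || all(z == 1))
    stop("need both zero and nonzero contributions")
  ds <- .zib_design(data)
  pos <- which(z == 0L)
  lp <- log(data$p[pos]); l1p <- log1p(-data$p[pos])
  Xmu <- ds$Xmu[pos, , drop = FALSE]
  Xph <- ds$Xom[pos, , drop = FALSE]
  S <- length(ds$sections); R <- length(ds$units)

  # initialization from working GLMs, jittered per chain
  om_glm <- suppressWarnings(glm.fit(ds$Xom, z, family = binomial()))
  yl <- qlogis(pmin(pmax(data$p[pos], 1e-5), 1 - 1e-5))
  mu_lm <- stats::lm.fit(Xmu, yl)
  res_var <- var(mu_lm$residuals)
  phi0 <- log(max(1 / max(res_var, 1e-3) * 4, 2))
  base_init <- c(ifelse(is.na(mu_lm$coefficients), 0, mu_lm$coefficients),
                 rep(0, S), rep(0, R),
                 c(phi0, rep(0, ncol(Xph) - 1)),
                 ifelse(is.na(om_glm$coefficients), 0, om_glm$coefficients),
                 log(0.3), log(0.3))

  # unit-level mean-model columns (constant within unit): eligible for
  # likelihood-invariant translation moves against the unit intercepts
  trans_cols <- list(); trans_vals <- NULL
  unit_level <- function(x) {
    per_unit <- tapply(x, ds$unit, function(v)
      if (length(unique(v)) == 1L) v[1] else NA_real_)
    if (anyNA(per_unit) || length(per_unit) != R) return(NULL)
    as.numeric(per_unit[as.character(1:R)])
  }
  for (j in 2:ncol(ds$Xmu)) {
    v <- unit_level(ds$Xmu[, j])
    if (!is.null(v)) {
      trans_cols[[length(trans_cols) + 1L]] <- j - 1L
      trans_vals <- cbind(trans_vals, v)
    }
  }
  # the per-section groundwater columns sum to the unit-level groundwater
  # covariate: shifting all their slopes together is also likelihood-
  # invariant through the unit intercepts
  gw_cols <- grep("^beta_groundwater\\[", colnames(ds$Xmu))
  if (length(gw_cols) > 1) {
    v <- unit_level(rowSums(ds$Xmu[, gw_cols, drop = FALSE]))
    if (!is.null(v)) {
      trans_cols[[length(trans_cols) + 1L]] <- as.integer(gw_cols - 1L)
      trans_vals <- cbind(trans_vals, v)
    }
  }
  if (is.null(trans_vals)) trans_vals <- matrix(0, R, 0)
  trans_cols <- lapply(trans_cols, as.integer)

  set.seed(seed)
  all_draws <- list(); all_pw <- list()
  for (ch in seq_len(chains)) {
    init <- base_init + rnorm(length(base_init), 0, 0.3)
    fit <- cpp_zib_mcmc(Xmu, Xph, ds$Xom, z, ds$sec[pos] - 1L,
                        ds$unit[pos] - 1L, lp, l1p, S, R, init,
                        sweeps = warmup + iter, burn = warmup,
                        trans_cols = trans_cols, trans_vals = trans_vals,
                        prior_sd = prior_sd)
    pwb <- cpp_zib_pointwise_beta(fit$draws, Xmu, Xph, ds$sec[pos] - 1L,
                                  ds$unit[pos] - 1L, lp, l1p, S, R)
    pw <- fit$pointwise_bern
    pw[, pos] <- pw[, pos] + pwb
    all_draws[[ch]] <- fit$draws
    all_pw[[ch]] <- pw
  }
  draws <- do.call(rbind, all_draws)
  colnames(draws) <- .zib_par_names(ds)
  chain <- rep(seq_len(chains), each = iter)
  diag <- mcmc_diagnostics(draws, chain)
  if (any(diag$rhat >= 1.01, na.rm = TRUE))
    rg_warn("convergence warning: %d parameter(s) with split-Rhat >= 1.01",
            sum(diag$rhat >= 1.01, na.rm = TRUE))
  new("ZibFit", draws = draws, chain = as.integer(chain),
      pars = colnames(draws), data = data, scaling = scaling,
      diagnostics = diag, pointwise_loglik = do.call(rbind, all_pw),
      meta = list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                  priors = sprintf("normal(0, %g) fixed effects; half-normal(0, 2) RE scales",
                                   prior_sd),
                  sections = ds$sections, units = ds$units,
                  conn_names = ds$conn_names))
}

# evaluate (omega, mu, phi) for every draw at given design rows
.zib_predict_draws <- function(fit, Xmu_row, Xph_row, Xom_row, sec = NULL,
                               unit = NULL, thin_to = 1000L) {
  d <- fit@draws
  if (nrow(d) > thin_to)
    d <- d[seq(1, nrow(d), length.out = thin_to), , drop = FALSE]
  S <- length(fit@meta$sections); R <- length(fit@meta$units)
  Pmu <- ncol(Xmu_row); Pph <- ncol(Xph_row)
  bmu <- d[, seq_len(Pmu), drop = FALSE]
  asec <- d[, Pmu + seq_len(S), drop = FALSE]
  aunit <- d[, Pmu + S + seq_len(R), drop = FALSE]
  bph <- d[, Pmu + S + R + seq_len(Pph), drop = FALSE]
  bom <- d[, Pmu + S + R + Pph + seq_len(Pph), drop = FALSE]
  eta_mu <- bmu %*% t(Xmu_row)
  if (!is.null(sec)) eta_mu <- eta_mu + asec[, sec, drop = FALSE]
  if (!is.null(unit)) eta_mu <- eta_mu + aunit[, unit, drop = FALSE]
  list(mu = plogis(eta_mu), phi = exp(bph %*% t(Xph_row)),
       omega = plogis(bom %*% t(Xom_row)), draws = d)
}

#' Posterior predictive checks for a contribution-model fit
#'
#' Replicates the dataset from posterior draws and compares test statistics
#' (proportion of zeros, mean of the nonzero contributions, maximum
#' contribution) to the observed data, overall and per section-year
#' stratum. Bayesian p-values are the fraction of replicates whose statistic
#' is at least the observed value.
#'
#' @param fit a \linkS4class{ZibFit}
#' @param n_rep number of replicate datasets (default 500)
#' @param seed integer seed
#' @return data.frame: stratum ("all" or section_year), statistic, observed,
#'   replicate mean, Bayesian p-value
#' @export
posteriorPredictiveCheck <- function(fit, n_rep = 500L, seed = 1L) {
  set.seed(seed)
  data <- fit@data
  ds <- .zib_design(data)
  pred <- .zib_predict_draws(fit, ds$Xmu, ds$Xom, ds$Xom,
                             sec = ds$sec, unit = ds$unit,
                             thin_to = n_rep)
  nd <- nrow(pred$mu)
  n <- nrow(data)
  reps <- seq_len(min(n_rep, nd))
  stat_fun <- function(p) c(prop_zero = mean(p == 0),
                            mean_nonzero = if (any(p > 0)) mean(p[p > 0]) else NA_real_,
                            max_p = max(p))
  strata <- paste(data$section, data$year, sep = "_")
  grp <- c(list(all = seq_len(n)), split(seq_len(n), strata))
  obs_stats <- lapply(grp, function(i) stat_fun(data$p[i]))
  acc <- lapply(grp, function(i) matrix(0, length(reps), 3))
  for (t in seq_along(reps)) {
    d <- reps[t]
    z <- rbinom(n, 1, pred$omega[d, ])
    p_rep <- ifelse(z == 1, 0,
                    rbeta(n, pred$mu[d, ] * pred$phi[d, ],
                          (1 - pred$mu[d, ]) * pred$phi[d, ]))
    for (g in seq_along(grp))
      acc[[g]][t, ] <- stat_fun(p_rep[grp[[g]]])
  }
  out <- list()
  for (g in seq_along(grp)) {
    m <- acc[[g]]
    out[[g]] <- data.frame(stratum = names(grp)[g],
                           statistic = names(obs_stats[[g]]),
                           observed = as.numeric(obs_stats[[g]]),
                           rep_mean = colMeans(m, na.rm = TRUE),
                           bayes_p = colMeans(m >= rep(obs_stats[[g]],
                                                       each = nrow(m)),
                                              na.rm = TRUE),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Posterior effect curves (and connectivity marginal effects)
#'
#' For a continuous covariate, a grid over its observed range with the other
#' continuous covariates held at their mean (zero after standardization),
#' conditional on a connectivity level; posterior median and 95\% credible
#' band of the Beta mean mu and of the zero probability omega. For
#' \code{variable = "groundwater"} one curve per section (the slope is
#' section-varying); for \code{variable = "connectivity"} the marginal
#' effect of each level at mean covariates.
#'
#' @param fit a \linkS4class{ZibFit}
#' @param variable one of "distance", "area", "groundwater", "connectivity"
#' @param connectivity conditioning level for continuous-variable curves
#' @param n_grid grid resolution
#' @return data.frame with the grid (raw and standardized), optional
#'   section, and posterior quantiles of mu and omega
#' @export
effectCurves <- function(fit, variable = c("distance", "area", "groundwater",
                                           "connectivity"),
                         connectivity = "connected", n_grid = 40L) {
  variable <- match.arg(variable)
  data <- fit@data
  ds <- .zib_design(data)
  S <- length(fit@meta$sections)
  conn_cols <- function(level) {
    v <- numeric(length(ds$conn_names))
    hit <- grepl(level, ds$conn_names, fixed = TRUE)
    v[hit] <- 1
    v
  }
  qs <- function(m) t(apply(m, 2, quantile, c(0.025, 0.5, 0.975)))
  build_rows <- function(zd, za, zg, sec_idx, level) {
    # groundwater enters through its per-section column; zg is only nonzero
    # for groundwater curves, which are drawn per section
    Gsec <- matrix(0, length(zd), S)
    if (!is.null(sec_idx)) Gsec[, sec_idx] <- zg
    Xmu <- cbind(1, zd, za, Gsec, matrix(conn_cols(level), length(zd),
                                         length(ds$conn_names), byrow = TRUE))
    Xb <- cbind(1, zd, za, zg, matrix(conn_cols(level), length(zd),
                                      length(ds$conn_names), byrow = TRUE))
    list(Xmu = Xmu, Xb = Xb)
  }
  out <- list()
  if (variable == "connectivity") {
    levs <- c("connected",
              sub("^conn_", "", ds$conn_names))
    for (lv in levs) {
      X <- build_rows(0, 0, 0, NULL, lv)
      pr <- .zib_predict_draws(fit, X$Xmu, X$Xb, X$Xb)
      qm <- qs(pr$mu); qo <- qs(pr$omega)
      out[[lv]] <- data.frame(connectivity = lv,
                              mu_lo = qm[, 1], mu_med = qm[, 2], mu_hi = qm[, 3],
                              omega_lo = qo[, 1], omega_med = qo[, 2],
                              omega_hi = qo[, 3])
    }
    return(do.call(rbind, c(out, make.row.names = FALSE)))
  }
  zcol <- switch(variable, distance = "z_distance", area = "z_area",
                 groundwater = "z_groundwater")
  zgrid <- seq(min(data[[zcol]]), max(data[[zcol]]), length.out = n_grid)
  raw <- if (length(fit@scaling)) {
    sc <- fit@scaling[[variable]]
    g <- zgrid * sc$sd + sc$mean
    if (variable == "area") exp(g) else g
  } else zgrid
  secs <- if (variable == "groundwater") seq_len(S) else list(NULL)
  for (si in seq_along(secs)) {
    sec_idx <- if (variable == "groundwater") secs[[si]] else NULL
    zd <- if (variable == "distance") zgrid else rep(0, n_grid)
    za <- if (variable == "area") zgrid else rep(0, n_grid)
    zg <- if (variable == "groundwater") zgrid else rep(0, n_grid)
    X <- build_rows(zd, za, zg, sec_idx, connectivity)
    pr <- .zib_predict_draws(fit, X$Xmu, X$Xb, X$Xb,
                             sec = if (!is.null(sec_idx))
                               rep(sec_idx, n_grid) else NULL)
    qm <- qs(pr$mu); qo <- qs(pr$omega)
    out[[si]] <- data.frame(variable = variable,
                            section = if (!is.null(sec_idx))
                              fit@meta$sections[sec_idx] else NA_character_,
                            connectivity = connectivity,
                            value = raw, z_value = zgrid,
                            mu_lo = qm[, 1], mu_med = qm[, 2], mu_hi = qm[, 3],
                            omega_lo = qo[, 1], omega_med = qo[, 2],
                            omega_hi = qo[, 3])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
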