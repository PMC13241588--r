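#' Design matrix for a composition hypothesis
#'
#' Five nested hypotheses about spatiotemporal variation in main-stem
#' composition: (1) constant (intercept only); (2) varies by section; (3) by
#' year; (4) by section and year (additive); (5) by section and year with a
#' section-by-year interaction (some sections vary more among years).
#' Treatment coding with the first section / first year as reference.
#' Columns that are identically zero on the observed design (an unsampled
#' section-year cell) are dropped; a rank-deficient result is an error.
#'
#' @param obs data.frame with \code{section} and \code{year} columns, one
#'   row per composition observation
#' @param hypothesis_id integer 1..5
#' @return model matrix with an \code{attr(, "hypothesis_id")}
#' @export
buildDesign <- function(obs, hypothesis_id) {
  stopifnot(hypothesis_id %in% 1:5, nrow(obs) >= 1)
  sec <- factor(obs$section); yr <- factor(obs$year)
  if (hypothesis_id %in% c(2, 4, 5) && nlevels(sec) < 2)
    stop("design for hypothesis ", hypothesis_id,
         " is rank deficient on these observations: need >= 2 sections")
  if (hypothesis_id %in% c(3, 4, 5) && nlevels(yr) < 2)
    stop("design for hypothesis ", hypothesis_id,
         " is rank deficient on these observations: need >= 2 years")
  X <- switch(hypothesis_id,
              model.matrix(~1, obs),
              model.matrix(~sec),
              model.matrix(~yr),
              model.matrix(~sec + yr),
              model.matrix(~sec * yr))
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  # an unsampled section-year cell aliases one interaction column; drop
  # aliased columns by QR pivoting so the design stays full rank
  q <- qr(X)
  if (q$rank < ncol(X)) {
    hid <- hypothesis_id
    X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("design for hypothesis ", hypothesis_id,
         " is rank deficient on these observations")
  attr(X, "hypothesis_id") <- as.integer(hypothesis_id)
  X
}

.dir_par_names <- function(X, K) {
  c(as.vector(outer(colnames(X), seq_len(K - 1),
                    function(p, c) paste0("beta[", p, ",", c, "]"))),
    "psi", "tau")
}

#' Fit the zero-and-one inflated Dirichlet composition model
#'
#' Each component of a composition is independently a structural zero with
#' probability psi; the surviving components, renormalized, follow a
#' Dirichlet whose mean is proportional to exp(design x beta) per component
#' (last component as reference) with total concentration tau. An
#' observation with all mass in one component is the all-others-zero case.
#' Sampling is componentwise adaptive Metropolis (compiled) with a
#' conjugate Gibbs update for psi; priors are normal(0, 5) on beta and on
#' log tau (flat-prior limits are improper, so weakly-informative proper
#' priors are used and recorded in the metadata).
#'
#' @param y composition matrix (observations x components), rows on the
#'   simplex, exact zeros allowed
#' @param design model matrix from \code{\link{buildDesign}}
#' @param chains MCMC chains (default 3)
#' @param warmup,iter burn-in and retained iterations per chain (defaults
#'   2000 / 2000)
#' @param seed integer seed
#' @return a \linkS4class{ZoiDirichletFit}
#' @export
fitZoiDirichlet <- function(y, design, chains = 3L, warmup = 2000L,
                            iter = 2000L, seed = 1L) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(design), all(y >= 0),
            all(abs(rowSums(y) - 1) < 1e-9))
  K <- ncol(y); P <- ncol(design)
  ispos <- matrix(as.integer(y > 0), nrow(y), K)
  lY <- ifelse(y > 0, log(y), 0)
  # moment-style initialization: intercept log-ratio to the last component
  mbar <- pmax(colMeans(y), 1e-3)
  beta0 <- matrix(0, P, K - 1)
  icol <- which(colnames(design) == "(Intercept)")
  if (length(icol)) beta0[icol, ] <- log(mbar[-K] / mbar[K])
  set.seed(seed)
  all_draws <- list(); all_pw <- list()
  for (ch in seq_len(chains)) {
    ib <- beta0 + matrix(rnorm(P * (K - 1), 0, 0.2), P, K - 1)
    fit <- cpp_zoidir_mcmc(lY, ispos, design, as.vector(ib),
                           init_logtau = log(20) + rnorm(1, 0, 0.2),
                           sweeps = warmup + iter, burn = warmup)
    all_draws[[ch]] <- fit$draws
    all_pw[[ch]] <- fit$pointwise
  }
  draws <- do.call(rbind, all_draws)
  colnames(draws) <- .dir_par_names(design, K)
  chain <- rep(seq_len(chains), each = iter)
  diag <- mcmc_diagnostics(draws, chain)
  if (any(diag$rhat >= 1.01, na.rm = TRUE))
    rg_warn("composition model: %d parameter(s) with split-Rhat >= 1.01",
            sum(diag$rhat >= 1.01, na.rm = TRUE))
  hid <- attr(design, "hypothesis_id") %||% NA_integer_
  new("ZoiDirichletFit", draws = draws, chain = as.integer(chain),
      pars = colnames(draws), y = y, design = design,
      hypothesis_id = as.integer(hid),
      pointwise_loglik = do.call(rbind, all_pw), diagnostics = diag,
      meta = list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                  priors = "normal(0, 5) on beta and log tau; Beta(1, 1) on psi"))
}

#' Compare composition models by exact leave-one-out cross-validation
#'
#' With only a handful of section-year observations, leave-one-out is done
#' by exact refits: for every observation the model is refit without it and
#' the log predictive density of the held-out composition is averaged over
#' the refit posterior. Models are ranked by elpd_loo; differences to the
#' best model carry pointwise standard errors, formatted like a model
#' selection table.
#'
#' @param fits list of \linkS4class{ZoiDirichletFit} on identical
#'   observations
#' @param chains,warmup,iter MCMC settings for the refits (defaults: each
#'   fit's own settings)
#' @param seed integer seed
#' @return data.frame: hypothesis_id, model, elpd_loo, se_elpd, elpd_diff,
#'   se_diff, sorted best first
#' @export
looCompare <- function(fits, chains = NULL, warmup = NULL, iter = NULL,
                       seed = 1L) {
  stopifnot(length(fits) >= 1)
  y0 <- fits[[1]]@y
  for (f in fits) if (!isTRUE(all.equal(f@y, y0)))
    stop("fits are not on identical observation sets")
  n <- nrow(y0)
  model_names <- c("Null", "Section", "Year", "Section + Year",
                   "Section + Year + Section x Year")
  pointwise <- matrix(0, n, length(fits))
  for (m in seq_along(fits)) {
    f <- fits[[m]]
    ch <- chains %||% f@meta$chains
    wu <- warmup %||% f@meta$warmup
    it <- iter %||% f@meta$iter
    hseed <- if (is.na(f@hypothesis_id)) m else f@hypothesis_id
    for (i in seq_len(n)) {
      refit <- fitZoiDirichlet(f@y[-i, , drop = FALSE],
                               .drop_attr_rows(f@design, i),
                               chains = ch, warmup = wu, iter = it,
                               seed = seed + 1000L * hseed + i)
      lpd <- cpp_zoidir_logpred(refit@draws, f@y[i, ], f@design[i, ],
                                ncol(f@y), ncol(f@design))
      mx <- max(lpd)
      pointwise[i, m] <- mx + log(mean(exp(lpd - mx)))
    }
  }
  elpd <- colSums(pointwise)
  se <- sqrt(n) * apply(pointwise, 2, sd)
  best <- which.max(elpd)
  diff <- elpd - elpd[best]
  se_diff <- sqrt(n) * apply(pointwise - pointwise[, best], 2, sd)
  hid <- vapply(fits, function(f) f@hypothesis_id, integer(1))
  out <- data.frame(hypothesis_id = hid,
                    model = ifelse(is.na(hid), "custom", model_names[hid]),
                    elpd_loo = elpd, se_elpd = se,
                    elpd_diff = diff, se_diff = se_diff)
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  out
}

.drop_attr_rows <- function(X, i) {
  hid <- attr(X, "hypothesis_id")
  X <- X[-i, , drop = FALSE]
  attr(X, "hypothesis_id") <- hid
  X
}

#' Simulate compositions from the zero-and-one inflated Dirichlet model
#'
#' @param design model matrix (observations x P)
#' @param beta coefficient matrix (P x (K-1)), last component reference
#' @param psi per-component structural-zero probability
#' @param tau total Dirichlet concentration
#' @param seed integer seed
#' @return composition matrix (observations x K); rows are exact simplex
#'   elements with structural zeros
#' @export
simulateZoiDirichlet <- function(design, beta, psi, tau, seed = 1L) {
  set.seed(seed)
  n <- nrow(design); K <- ncol(beta) + 1L
  eta <- cbind(design %*% beta, 0)
  y <- matrix(0, n, K)
  for (i in seq_len(n)) {
    repeat {
      alive <- runif(K) >= psi
      if (any(alive)) break
    }
    if (sum(alive) == 1) { y[i, alive] <- 1; next }
    w <- exp(eta[i, alive]); w <- w / sum(w)
    y[i, alive] <- rdirichlet1(tau * w)
  }
  y
}
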