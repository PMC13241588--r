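# internal helpers shared across modules

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score standardize, returning the scaling so it can be replayed on a grid
standardize <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) s <- 1
  list(z = (x - m) / s, mean = m, sd = s)
}

# draw one categorical index per row of a probability matrix (rows sum to 1)
sample_rows <- function(prob) {
  cp <- prob %*% upper.tri(diag(ncol(prob)), diag = TRUE)
  u <- runif(nrow(prob))
  as.integer(rowSums(u > cp)) + 1L
}

# Dirichlet draw via gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

# split-Rhat and bulk ESS via coda, given pooled draws and a chain index
mcmc_diagnostics <- function(draws, chain) {
  chains <- sort(unique(chain))
  # split each chain in half for split-Rhat
  lst <- list()
  for (ch in chains) {
    d <- draws[chain == ch, , drop = FALSE]
    h <- floor(nrow(d) / 2)
    lst[[length(lst) + 1L]] <- coda::mcmc(d[seq_len(h), , drop = FALSE])
    lst[[length(lst) + 1L]] <- coda::mcmc(d[(h + 1):(2 * h), , drop = FALSE])
  }
  ml <- coda::mcmc.list(lst)
  rhat <- tryCatch(
    coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(draws)))
  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(draws))),
                  error = function(e) rep(NA_real_, ncol(draws)))
  data.frame(parameter = colnames(draws), rhat = as.numeric(rhat),
             ess = ess, row.names = NULL)
}

# warn once with a consistent prefix
rg_warn <- function(...) warning(sprintf(...), call. = FALSE)
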