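# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementations they check.

# Weir & Cockerham (1984) theta from a list of per-group dosage matrices,
# transcribed literally per locus with explicit loops
oracle_wc_theta <- function(dosage_by_group) {
  r <- length(dosage_by_group)
  L <- ncol(dosage_by_group[[1]])
  num <- den <- 0
  for (l in seq_len(L)) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      g <- dosage_by_group[[k]][, l]
      g <- g[!is.na(g)]
      n[k] <- length(g)
      p[k] <- sum(g) / (2 * length(g))
      h[k] <- mean(g == 1)
    }
    if (any(n < 1)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc) || nc <= 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Hardy-Weinberg genotype log-probability by direct enumeration
oracle_hwe_loglik <- function(dosage, p) {
  ll <- 0
  for (l in seq_along(dosage)) {
    if (is.na(dosage[l])) next
    pr <- switch(dosage[l] + 1L,
                 (1 - p[l])^2,
                 2 * p[l] * (1 - p[l]),
                 p[l]^2)
    ll <- ll + log(pr)
  }
  unname(ll)
}

# leave-one-out self-assignment posterior for one individual by direct
# computation (uniform prior, Dirichlet-posterior mean frequencies)
oracle_loo_posterior <- function(dosages, groups, i) {
  gs <- sort(unique(groups))
  ll <- numeric(length(gs))
  for (gi in seq_along(gs)) {
    members <- which(groups == gs[gi])
    if (groups[i] == gs[gi]) members <- setdiff(members, i)
    ref <- tot <- numeric(ncol(dosages))
    for (m in members) for (l in seq_len(ncol(dosages))) {
      if (!is.na(dosages[m, l])) {
        ref[l] <- ref[l] + dosages[m, l]
        tot[l] <- tot[l] + 2
      }
    }
    p <- (ref + 0.5) / (tot + 1)
    ll[gi] <- oracle_hwe_loglik(dosages[i, ], p)
  }
  post <- exp(ll - max(ll))
  setNames(post / sum(post), gs)
}

# all-pairs semivariogram with a quadratic loop
oracle_semivariogram <- function(values, D, edges) {
  nb <- length(edges) - 1
  gamma <- numeric(nb); npairs <- integer(nb)
  n <- length(values)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- D[i, j]
    for (b in seq_len(nb)) {
      lo <- edges[b]; hi <- edges[b + 1]
      inb <- if (b == 1) h >= lo && h <= hi else h > lo && h <= hi
      if (inb) {
        gamma[b] <- gamma[b] + (values[i] - values[j])^2
        npairs[b] <- npairs[b] + 1
        break
      }
    }
  }
  list(gamma = ifelse(npairs > 0, gamma / (2 * npairs), NA_real_),
       n_pairs = npairs)
}

# tree path length by depth-first enumeration (no shortest-path machinery)
oracle_tree_distance <- function(edges, a, b) {
  if (a == b) return(0)
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]; w <- edges$length[k]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, w = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, w = w))
  }
  dfs <- function(node, target, visited, acc) {
    if (node == target) return(acc)
    nb <- adj[[node]]
    if (is.null(nb)) return(NA_real_)
    for (k in seq_len(nrow(nb))) {
      if (nb$to[k] %in% visited) next
      r <- dfs(nb$to[k], target, c(visited, nb$to[k]), acc + nb$w[k])
      if (!is.na(r)) return(r)
    }
    NA_real_
  }
  dfs(a, b, a, 0)
}

# EM fixed-point estimate of mixing proportions from a log-likelihood matrix
oracle_em_pi <- function(ll, iters = 500) {
  lik <- exp(ll - apply(ll, 1, max))
  U <- ncol(lik)
  pi <- rep(1 / U, U)
  for (t in seq_len(iters)) {
    resp <- lik * rep(pi, each = nrow(lik))
    resp <- resp / rowSums(resp)
    pi <- colMeans(resp)
  }
  pi
}
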