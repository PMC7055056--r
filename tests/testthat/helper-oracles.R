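# Independent reference implementations used as oracles. These are written
# deliberately in a different style from the package (explicit loops over a
# plain 0/1 matrix, no shared precomputation) so that agreement is a real
# dual-route check, not the same code twice.

# Bias-corrected Chao2 straight from the formula, looping over columns.
oracle_chao2 <- function(mat) {
  mat <- (mat > 0) * 1
  m <- nrow(mat)
  inc <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) inc[j] <- sum(mat[, j])
  inc <- inc[inc > 0]
  S_obs <- length(inc)
  if (S_obs == 0) return(0)
  if (m < 2) return(S_obs)
  Q1 <- 0; Q2 <- 0
  for (v in inc) {
    if (v == 1) Q1 <- Q1 + 1
    if (v == 2) Q2 <- Q2 + 1
  }
  S_obs + ((m - 1) / m) * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
}

# ICE per the standard (EstimateS) definition, looping throughout.
oracle_ice <- function(mat, cutoff = 10) {
  mat <- (mat > 0) * 1
  m <- nrow(mat)
  inc <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) inc[j] <- sum(mat[, j])
  obs <- which(inc > 0)
  S_obs <- length(obs)
  if (S_obs == 0) return(0)
  if (m < 2) return(S_obs)
  k <- min(cutoff, m)
  infreq <- obs[inc[obs] <= k]
  S_inf <- length(infreq)
  S_freq <- S_obs - S_inf
  if (S_inf == 0) return(S_obs)
  N_inf <- 0; Q1 <- 0; sum_jj1 <- 0
  for (j in infreq) {
    N_inf <- N_inf + inc[j]
    if (inc[j] == 1) Q1 <- Q1 + 1
    sum_jj1 <- sum_jj1 + inc[j] * (inc[j] - 1)
  }
  C_ice <- 1 - Q1 / N_inf
  if (C_ice <= 0) return(oracle_chao2(mat))
  m_inf <- 0
  for (i in seq_len(m)) if (sum(mat[i, infreq]) > 0) m_inf <- m_inf + 1
  gamma2 <- 0
  if (m_inf > 1)
    gamma2 <- max((S_inf / C_ice) * (m_inf / (m_inf - 1)) *
                    sum_jj1 / N_inf^2 - 1, 0)
  S_freq + S_inf / C_ice + (Q1 / C_ice) * gamma2
}

# Lognormal model solved by dense-grid quadrature plus bisection on the
# inverse width, completely independent of the closed-form erf route.
oracle_lognormal <- function(N, Nmax, Nmin = 1, n_grid = 20001) {
  xmin <- log(Nmin); xmax <- log(Nmax)
  x0 <- (xmin + xmax) / 2; D <- (xmax - xmin) / 2
  x <- seq(xmin, xmax, length.out = n_grid)
  h <- x[2] - x[1]
  trap <- function(f) h * (sum(f) - (f[1] + f[n_grid]) / 2)
  N_of_a <- function(a) {
    S0 <- exp(a^2 * D^2)
    trap(S0 * exp(x - a^2 * (x - x0)^2))
  }
  lo <- 1e-6; hi <- 60
  if (N_of_a(lo) > N) stop("oracle_lognormal: infeasible")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    Nm <- N_of_a(mid)          # can overflow to Inf/NaN at large widths:
    if (is.finite(Nm) && Nm < N) lo <- mid else hi <- mid  # treat as > N
  }
  a <- (lo + hi) / 2
  S0 <- exp(a^2 * D^2)
  list(a = a, S_total = trap(S0 * exp(-a^2 * (x - x0)^2)))
}

# Expected realized richness of a multinomial draw: sum over species of
# P(at least one individual) = 1 - (1 - p_i)^N.
oracle_expected_richness <- function(p, N) {
  sum(1 - (1 - p)^N)
}

# Small random incidence matrix generator for estimator fuzzing.
random_incidence <- function(n_units, n_taxa, fill = 0.3) {
  matrix(rbinom(n_units * n_taxa, 1, fill), nrow = n_units)
}

# Tiny long-format table fixture used across corpus_io tests.
toy_table <- function() {
  taxon_table(rbind(s1 = c(tA = 3, tB = 1), s2 = c(tA = 2, tB = 0)))
}
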