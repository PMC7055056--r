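#' Incidence frequency counts for richness estimation
#'
#' Reduces a unit-by-taxon presence matrix to the incidence frequency
#' counts Q_j = number of taxa present in exactly j of the m sampling
#' units. Q_1 (incidence singletons) and Q_2 (doubletons) drive Chao2; the
#' full spectrum up to the infrequent cutoff drives ICE.
#'
#' @param x an `incidence_matrix` (see [to_incidence()], [census_sites()])
#'   or a units-x-taxa matrix coercible to 0/1.
#' @return An object of class `incidence_freqs`: `m`, `S_obs`, `Q`
#'   (integer vector of length m, `Q[j]` = number of taxa in exactly j
#'   units), `col_incidence` (per-taxon unit counts, zeros removed), and
#'   `presence` (the matrix, retained so [ice()] can count the units that
#'   contain infrequent taxa).
#' @export
incidence_frequencies <- function(x) {
  pres <- if (inherits(x, "incidence_matrix")) x$presence else (x > 0) * 1
  m <- nrow(pres)
  if (is.null(m) || m < 1L) stop("incidence_frequencies: need at least one unit")
  ci_full <- if (inherits(pres, "Matrix")) Matrix::colSums(pres > 0) else
    colSums(pres > 0)
  pos <- which(ci_full > 0)
  ci <- ci_full[pos]
  Q <- tabulate(ci, nbins = m)
  structure(list(m = m, S_obs = length(ci), Q = Q, col_incidence = ci,
                 taxon_cols = pos, presence = pres),
            class = "incidence_freqs")
}

#' @export
print.incidence_freqs <- function(x, ...) {
  cat(sprintf("<incidence_freqs> m = %d, S_obs = %d, Q1 = %d, Q2 = %d\n",
              x$m, x$S_obs,
              if (x$m >= 1) x$Q[1] else 0L, if (x$m >= 2) x$Q[2] else 0L))
  invisible(x)
}

#' Chao2 incidence-based richness estimator
#'
#' Bias-corrected form (default):
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}
#' which is defined for all inputs and never below S_obs. The classic form
#' (`bias_corrected = FALSE`) uses \eqn{Q_1^2 / (2 Q_2)} when Q_2 > 0 and
#' falls back to the bias-corrected form when Q_2 = 0.
#'
#' @param freqs an `incidence_freqs` object (or anything accepted by
#'   [incidence_frequencies()]).
#' @param bias_corrected logical, default `TRUE`.
#' @return Estimated richness (numeric scalar, >= S_obs).
#' @details With a single sampling unit (m = 1) the correction factor is
#'   undefined; S_obs is returned with a warning. An empty matrix returns 0.
#' @export
chao2 <- function(freqs, bias_corrected = TRUE) {
  if (!inherits(freqs, "incidence_freqs")) freqs <- incidence_frequencies(freqs)
  if (freqs$S_obs == 0L) return(0)
  m <- freqs$m
  if (m < 2L) {
    warning("chao2: m = 1 sampling unit; returning S_obs")
    return(as.numeric(freqs$S_obs))
  }
  Q1 <- freqs$Q[1]
  Q2 <- freqs$Q[2]
  k <- (m - 1) / m
  if (bias_corrected || Q2 == 0) {
    freqs$S_obs + k * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  } else {
    freqs$S_obs + k * Q1^2 / (2 * Q2)
  }
}

#' ICE: incidence-based coverage estimator of richness
#'
#' Partitions taxa into frequent (incidence > `infrequent_cutoff`) and
#' infrequent classes, estimates the sample coverage of the infrequent class
#' as \eqn{C = 1 - Q_1 / N_{inf}} where \eqn{N_{inf} = \sum_{j \le k} j Q_j},
#' and returns
#' \deqn{\hat S = S_{freq} + S_{inf}/C + (Q_1/C)\,\gamma^2}
#' with \eqn{\gamma^2} the squared coefficient of variation of infrequent
#' incidences (floored at 0):
#' \deqn{\gamma^2 = \max\Big(\frac{S_{inf}}{C}\,
#'   \frac{m_{inf}}{m_{inf}-1}\,
#'   \frac{\sum_{j\le k} j(j-1) Q_j}{N_{inf}^2} - 1,\; 0\Big)}
#' where \eqn{m_{inf}} is the number of units containing at least one
#' infrequent taxon.
#'
#' @param freqs an `incidence_freqs` object retaining its presence matrix
#'   (needed for \eqn{m_{inf}}); plain matrices are converted.
#' @param infrequent_cutoff incidence cutoff k for the infrequent class,
#'   conventionally 10.
#' @return Estimated richness (numeric scalar).
#' @details When every infrequent taxon is a singleton the coverage estimate
#'   is 0 and ICE is undefined; the bias-corrected [chao2()] estimate is
#'   returned instead with a message. When \eqn{m_{inf} \le 1} the CV term
#'   is set to 0.
#' @export
ice <- function(freqs, infrequent_cutoff = 10) {
  if (!inherits(freqs, "incidence_freqs")) freqs <- incidence_frequencies(freqs)
  if (!is.numeric(infrequent_cutoff) || infrequent_cutoff < 1)
    stop("ice: infrequent_cutoff must be >= 1")
  if (freqs$S_obs == 0L) return(0)
  m <- freqs$m
  if (m < 2L) {
    warning("ice: m = 1 sampling unit; returning S_obs")
    return(as.numeric(freqs$S_obs))
  }
  k <- min(infrequent_cutoff, m)
  j <- seq_len(k)
  Qj <- freqs$Q[j]
  S_inf <- sum(Qj)
  S_freq <- freqs$S_obs - S_inf
  if (S_inf == 0L) return(as.numeric(freqs$S_obs))
  N_inf <- sum(j * Qj)
  Q1 <- freqs$Q[1]
  C_ice <- 1 - Q1 / N_inf
  if (C_ice <= 0) {
    message("ice: all infrequent taxa are singletons (coverage 0); falling back to chao2")
    return(chao2(freqs))
  }
  infreq_taxa <- freqs$col_incidence <= k
  m_inf <- if (!is.null(freqs$presence)) {
    pres_inf <- freqs$presence[, freqs$taxon_cols[infreq_taxa], drop = FALSE]
    sum((if (inherits(pres_inf, "Matrix")) Matrix::rowSums(pres_inf) else
      rowSums(pres_inf)) > 0)
  } else m
  gamma2 <- if (m_inf > 1L) {
    max(S_inf / C_ice * m_inf / (m_inf - 1) *
          sum(j * (j - 1) * Qj) / N_inf^2 - 1, 0)
  } else 0
  S_freq + S_inf / C_ice + Q1 / C_ice * gamma2
}
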