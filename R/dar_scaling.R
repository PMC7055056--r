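#' Fit a diversity-abundance relationship by stratified bootstrap
#'
#' Fits the power-law scaling of one SAD summary on total abundance N by
#' repeated ordinary least squares in log-log space. Each of `n_boot`
#' bootstrap replicates draws `n_per_boot` assemblages with replacement,
#' allocated as evenly as possible across non-empty strata (bins of
#' log10(N) of width `strata_width` decades) so that the fit is not
#' dominated by whichever abundance range is densest. Reported exponents
#' and intercepts are means over bootstraps with 95 percent percentile
#' intervals.
#'
#' Response transforms: richness, dominance and evenness are fit as
#' log10(response) on log10(N) (evenness lies in (0, 1], so its log is
#' well defined); rarity can be zero or negative and is fit untransformed
#' on log10(N).
#'
#' @param summaries data.frame from [summarize_corpus()] (needs columns
#'   `N` and the response column).
#' @param response one of `"richness"`, `"dominance"`, `"evenness"`,
#'   `"rarity"` (mapped to columns S, Nmax, evenness, rarity).
#' @param n_boot bootstrap replicates (default 1000; 10000 reproduces the
#'   heavyweight published setting).
#' @param n_per_boot assemblages per regression (default 500). If the
#'   corpus is smaller than this, draws are still with replacement from
#'   what exists (noted via message).
#' @param strata_width stratum width in decades of log10(N); `NULL` or
#'   `Inf` disables stratification.
#' @param seed integer seed.
#' @return An object of class `scaling_fit`: `response`, `exponent_mean`,
#'   `intercept_mean`, `exponent_ci`, `intercept_ci`, `r2_mean`, `n_boot`,
#'   `n_per_boot`, `strata` (breaks and occupancy), `boot` (per-bootstrap
#'   slope, intercept, residual variance `s2`, `xbar`, `Sxx`, `n`), `seed`,
#'   and `log_response` (whether the response was log10-transformed).
#' @export
fit_dar <- function(summaries,
                    response = c("richness", "dominance", "evenness", "rarity"),
                    n_boot = 1000L, n_per_boot = 500L,
                    strata_width = 1, seed = 1L) {
  response <- match.arg(response)
  if (inherits(summaries, "synthetic_corpus"))
    stop("fit_dar: pass summarize_corpus(corpus$table), not the corpus itself")
  col <- c(richness = "S", dominance = "Nmax", evenness = "evenness",
           rarity = "rarity")[[response]]
  if (!all(c("N", col) %in% names(summaries)))
    stop(sprintf("fit_dar: summaries must contain columns 'N' and '%s'", col))
  N <- summaries$N
  yraw <- summaries[[col]]
  keep <- is.finite(N) & N > 0 & is.finite(yraw)
  log_response <- response != "rarity"
  if (log_response) keep <- keep & yraw > 0
  if (sum(!keep))
    warning(sprintf("fit_dar: dropping %d unusable summaries", sum(!keep)))
  N <- N[keep]; yraw <- yraw[keep]
  if (length(unique(N)) < 2L)
    stop("fit_dar: need at least 2 distinct N values (slope undefined)")
  x <- log10(N)
  y <- if (log_response) log10(yraw) else yraw
  n_obs <- length(x)
  if (n_obs < n_per_boot)
    message(sprintf("fit_dar: corpus has %d summaries < n_per_boot = %d; drawing with replacement from what exists",
                    n_obs, n_per_boot))

  # stratum membership and per-stratum allocation
  if (is.null(strata_width) || !is.finite(strata_width)) {
    strata <- rep(1L, n_obs)
  } else {
    strata <- as.integer(factor(floor(x / strata_width)))
  }
  groups <- split(seq_len(n_obs), strata)
  k <- length(groups)
  alloc <- rep(n_per_boot %/% k, k)
  rem <- n_per_boot - sum(alloc)
  if (rem > 0) {
    sizes <- lengths(groups)
    alloc[order(sizes, decreasing = TRUE)[seq_len(rem)]] <-
      alloc[order(sizes, decreasing = TRUE)[seq_len(rem)]] + 1L
  }

  # draw all bootstrap indices at once, stratum by stratum
  idx <- with_seed(split_seed(seed, 7L), {
    blocks <- vector("list", k)
    for (g in seq_len(k)) {
      blocks[[g]] <- matrix(groups[[g]][sample.int(length(groups[[g]]),
                                                   alloc[g] * n_boot,
                                                   replace = TRUE)],
                            nrow = alloc[g])
    }
    do.call(rbind, blocks)
  })

  X <- matrix(x[idx], nrow = n_per_boot)
  Y <- matrix(y[idx], nrow = n_per_boot)
  n <- n_per_boot
  xm <- colMeans(X); ym <- colMeans(Y)
  Sxx <- colSums(X^2) - n * xm^2
  Sxy <- colSums(X * Y) - n * xm * ym
  Syy <- colSums(Y^2) - n * ym^2
  ok <- Sxx > 0
  slope <- ifelse(ok, Sxy / Sxx, NA_real_)
  intercept <- ym - slope * xm
  SSE <- pmax(Syy - slope * Sxy, 0)
  r2 <- ifelse(Syy > 0, 1 - SSE / Syy, NA_real_)
  s2 <- SSE / (n - 2)

  boot <- data.frame(slope = slope, intercept = intercept, s2 = s2,
                     xbar = xm, Sxx = Sxx, n = n)
  structure(list(response = response,
                 exponent_mean = mean(slope, na.rm = TRUE),
                 intercept_mean = mean(intercept, na.rm = TRUE),
                 exponent_ci = unname(quantile(slope, c(0.025, 0.975),
                                               na.rm = TRUE)),
                 intercept_ci = unname(quantile(intercept, c(0.025, 0.975),
                                                na.rm = TRUE)),
                 r2_mean = mean(r2, na.rm = TRUE),
                 n_boot = as.integer(n_boot),
                 n_per_boot = as.integer(n_per_boot),
                 strata = list(width = strata_width, n_strata = k,
                               sizes = unname(lengths(groups)),
                               alloc = alloc),
                 boot = boot,
                 log_response = log_response,
                 seed = as.integer(seed)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s ~ N: exponent %.4f [%.4f, %.4f], intercept %.4f, mean r2 %.3f (%d bootstraps x %d assemblages, %d strata)\n",
              x$response, x$exponent_mean, x$exponent_ci[1], x$exponent_ci[2],
              x$intercept_mean, x$r2_mean, x$n_boot, x$n_per_boot,
              x$strata$n_strata))
  invisible(x)
}

#' Predict dominance Nmax from a fitted dominance DAR
#'
#' Evaluates the mean power law `10^intercept * N^exponent` and clips the
#' prediction to at most N (the most abundant taxon cannot exceed the
#' total).
#'
#' @param fit a [fit_dar()] result with `response = "dominance"`.
#' @param N positive total abundance(s).
#' @return Predicted Nmax, same length as `N`.
#' @export
predict_nmax <- function(fit, N) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$response != "dominance")
    stop("predict_nmax: fit must have response = 'dominance'")
  if (any(!is.finite(N) | N <= 0)) stop("predict_nmax: N must be positive")
  pmin(10^fit$intercept_mean * N^fit$exponent_mean, N)
}

#' Bootstrap-averaged 95 percent prediction interval for a DAR
#'
#' For each bootstrap regression the standard OLS prediction interval for a
#' new observation at log10(N) is formed in the fitted (log) space,
#' \eqn{\hat y \pm t_{n-2}\, s \sqrt{1 + 1/n + (x - \bar x)^2 / S_{xx}}},
#' the bounds are averaged over bootstraps, and the result is
#' back-transformed to the response scale (except for rarity, which is fit
#' untransformed).
#'
#' @param fit a [fit_dar()] result.
#' @param N positive total abundance(s).
#' @param level coverage level in (0, 1); default 0.95.
#' @return data.frame with columns `N`, `fit` (point prediction from the
#'   mean coefficients), `lower`, `upper`.
#' @export
prediction_interval <- function(fit, N, level = 0.95) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("prediction_interval: level must be in (0, 1)")
  if (any(!is.finite(N) | N <= 0)) stop("prediction_interval: N must be positive")
  x <- log10(N)
  b <- fit$boot
  tq <- qt(1 - (1 - level) / 2, df = b$n - 2)
  out <- lapply(x, function(xi) {
    pred_b <- b$intercept + b$slope * xi
    se_b <- sqrt(pmax(b$s2, 0) * (1 + 1 / b$n + (xi - b$xbar)^2 / b$Sxx))
    c(lower = mean(pred_b - tq * se_b, na.rm = TRUE),
      upper = mean(pred_b + tq * se_b, na.rm = TRUE))
  })
  lo <- vapply(out, `[[`, numeric(1), "lower")
  hi <- vapply(out, `[[`, numeric(1), "upper")
  point <- fit$intercept_mean + fit$exponent_mean * x
  if (fit$log_response) {
    data.frame(N = N, fit = 10^point, lower = 10^lo, upper = 10^hi)
  } else {
    data.frame(N = N, fit = point, lower = lo, upper = hi)
  }
}
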