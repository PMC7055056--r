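#' Summarize one assemblage's species-abundance distribution
#'
#' Computes the diversity-abundance response variables for a single sample:
#' total abundance N, observed richness S, dominance Nmax (abundance of the
#' most abundant taxon), Simpson evenness, and rarity.
#'
#' Evenness is Simpson's measure \eqn{E = (1/\sum p_i^2)/S} over the
#' relative abundances of the taxa present; it is 1 exactly when all
#' abundances are equal. Rarity is the sample skewness of log10 abundances
#' of the taxa present (right-skew means a long tail of rare taxa); it is
#' defined as 0 when fewer than 3 taxa are present or all abundances are
#' equal. Skewness is location/scale invariant in log space, so the log
#' base is cosmetic.
#'
#' @param counts non-negative integer vector with at least one positive
#'   entry (zeros are ignored).
#' @param sample_id optional identifier carried into the output.
#' @return A one-row data.frame: `sample_id`, `N`, `S`, `Nmax`, `evenness`,
#'   `rarity`.
#' @examples
#' summarize_sample(c(4, 2, 2))
#' @export
summarize_sample <- function(counts, sample_id = NA_character_) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("summarize_sample: counts must be finite non-negative integers")
  pos <- counts[counts > 0]
  if (!length(pos)) stop("summarize_sample: all counts are zero")
  N <- sum(pos)
  S <- length(pos)
  p <- pos / N
  data.frame(sample_id = sample_id, N = N, S = S, Nmax = max(pos),
             evenness = (1 / sum(p^2)) / S,
             rarity = sample_skewness(log10(pos)),
             stringsAsFactors = FALSE)
}

#' Per-sample SAD summaries for a whole corpus
#'
#' Applies [summarize_sample()] to every sample of a count table, in table
#' order. The result is the input to [fit_dar()].
#'
#' @param x a [taxon_table].
#' @return A data.frame with one row per sample (columns as in
#'   [summarize_sample()]).
#' @export
summarize_corpus <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  cm <- x$counts
  n <- nrow(cm)
  out <- vector("list", n)
  # work down the sparse structure sample by sample; cm@x holds only
  # nonzero counts so each row extraction is cheap
  tm <- methods::as(cm, "TsparseMatrix")
  by_row <- split(tm@x, factor(tm@i + 1L, levels = seq_len(n)))
  ids <- rownames(cm)
  for (i in seq_len(n)) out[[i]] <- summarize_sample(by_row[[i]], ids[i])
  do.call(rbind, out)
}
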