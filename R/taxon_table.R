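#' Sample-by-taxon count table
#'
#' The universal exchange object of the package: a sparse matrix of
#' non-negative integer read/individual counts with samples as rows and taxa
#' as columns. Samples whose total count is zero are dropped with a warning
#' (every retained sample has N > 0); duplicated sample or taxon identifiers
#' are an error, as are negative or non-integer counts.
#'
#' @param counts numeric matrix, sparse `Matrix`, or data.frame of
#'   non-negative integer counts (samples x taxa).
#' @param sample_ids,taxon_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An object of class `taxon_table` with fields `counts`
#'   (a `dgCMatrix` with dimnames), plus accessors [sample_ids()],
#'   [taxon_ids()].
#' @examples
#' tt <- taxon_table(rbind(s1 = c(tA = 3, tB = 1), s2 = c(2, 0)))
#' sample_totals(tt)
#' @export
taxon_table <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(taxon_ids)) colnames(counts) <- taxon_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%d", seq_len(ncol(counts)))
  x <- counts@x
  if (length(x) && any(x < 0))
    stop("taxon_table: negative counts are not allowed")
  if (length(x) && any(x != round(x)))
    stop("taxon_table: counts must be integers (fractional abundances are rejected)")
  if (anyDuplicated(rownames(counts)))
    stop("taxon_table: duplicate sample identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("taxon_table: duplicate taxon identifiers")
  rs <- Matrix::rowSums(counts)
  if (any(rs == 0)) {
    warning(sprintf("dropping %d sample(s) with zero total count: %s",
                    sum(rs == 0),
                    paste(head(rownames(counts)[rs == 0], 5), collapse = ", ")))
    counts <- counts[rs > 0, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("taxon_table: no samples with positive totals")
  structure(list(counts = counts), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table> %d samples x %d taxa, %s total counts, %.1f%% nonzero\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @rdname taxon_table
#' @param x a `taxon_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname taxon_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @rdname taxon_table
#' @export
sample_totals <- function(x) Matrix::rowSums(x$counts)

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Read a sample-by-taxon count table from delimited text
#'
#' Two dialects are supported. *Wide*: a header row of taxon identifiers,
#' first column the sample identifier, integer cells. *Long*: three columns
#' `sample`, `taxon`, `count` (any header names; order is positional).
#' `dialect = "auto"` treats a 3-column file as long and anything else as
#' wide. Tab and comma separators are auto-detected by `data.table::fread`.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"wide"`, `"long"`.
#' @return a [taxon_table].
#' @details Malformed input is rejected with the offending row number:
#'   negative or non-integer counts, and duplicate (sample, taxon) pairs in
#'   the long dialect. Zero counts in the long dialect are accepted and
#'   stored implicitly. Samples with zero total are dropped with a warning.
#' @seealso [write_taxon_table()], [read_biom_table()]
#' @export
read_taxon_table <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = NULL, data.table = TRUE)
  if (ncol(dt) < 2L) stop("read_taxon_table: need at least two columns")
  if (dialect == "auto") dialect <- if (ncol(dt) == 3L) "long" else "wide"
  if (dialect == "long") {
    if (ncol(dt) != 3L)
      stop("read_taxon_table: long dialect requires exactly 3 columns")
    names(dt) <- c("sample", "taxon", "count")
    cnt <- dt$count
    bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
    if (length(bad))
      stop(sprintf("read_taxon_table: invalid count at data row %d (value %s)",
                   bad[1], format(cnt[bad[1]])))
    dup <- which(duplicated(dt[, c("sample", "taxon")]))
    if (length(dup))
      stop(sprintf("read_taxon_table: duplicate (sample, taxon) pair at data row %d (%s, %s)",
                   dup[1], dt$sample[dup[1]], dt$taxon[dup[1]]))
    samp <- factor(dt$sample, levels = unique(dt$sample))
    taxa <- factor(dt$taxon, levels = unique(dt$taxon))
    keep <- cnt > 0
    m <- Matrix::sparseMatrix(i = as.integer(samp)[keep],
                              j = as.integer(taxa)[keep],
                              x = as.numeric(cnt)[keep],
                              dims = c(nlevels(samp), nlevels(taxa)),
                              dimnames = list(levels(samp), levels(taxa)))
    taxon_table(m)
  } else {
    ids <- as.character(dt[[1]])
    mat <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(mat))
      stop("read_taxon_table: wide dialect requires numeric count cells")
    bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("read_taxon_table: invalid count at data row %d, column '%s'",
                   bad[1, 1], colnames(mat)[bad[1, 2]]))
    rownames(mat) <- ids
    taxon_table(mat)
  }
}

#' Write a count table as delimited text
#'
#' @param x a [taxon_table].
#' @param path output path.
#' @param dialect `"long"` (sample, taxon, count triplets of nonzero cells)
#'   or `"wide"` (dense matrix with header row).
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(x, path, dialect = c("long", "wide"), sep = "\t") {
  stopifnot(inherits(x, "taxon_table"))
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    tm <- methods::as(x$counts, "TsparseMatrix")
    ord <- order(tm@i, tm@j)
    dt <- data.table::data.table(sample = rownames(tm)[tm@i + 1L][ord],
                                 taxon = colnames(tm)[tm@j + 1L][ord],
                                 count = as.integer(tm@x)[ord])
    data.table::fwrite(dt, path, sep = sep)
  } else {
    dense <- as.matrix(x$counts)
    dt <- data.table::data.table(sample_id = rownames(dense))
    for (j in colnames(dense)) dt[[j]] <- as.integer(dense[, j])
    data.table::fwrite(dt, path, sep = sep)
  }
  invisible(path)
}

#' Import a BIOM-format table (convenience reader)
#'
#' Reads a sample-by-observation BIOM file via the `biomformat` package and
#' returns it as a [taxon_table] (samples as rows).
#'
#' @param path path to a BIOM file.
#' @return a [taxon_table].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("read_biom_table requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  taxon_table(t(m))
}

#' Convert counts to a site/sample-by-taxon incidence (presence) matrix
#'
#' Presence is `count >= threshold`. Taxa whose presence is all zero are
#' retained as columns and flagged in the `empty_taxa` field so that
#' incidence and count tables stay column-aligned.
#'
#' @param x a [taxon_table] or a numeric matrix of counts (units x taxa).
#' @param threshold detection threshold, a positive integer (default 1: one
#'   read counts as an occurrence).
#' @return An object of class `incidence_matrix`: fields `presence` (sparse
#'   0/1 `dgCMatrix`), `unit_ids`, `taxon_ids`, `m` (number of sampling
#'   units), `empty_taxa` (logical).
#' @export
to_incidence <- function(x, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop("to_incidence: threshold must be a single integer >= 1")
  counts <- if (inherits(x, "taxon_table")) x$counts else
    methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix")
  pres <- methods::as(counts >= threshold, "dMatrix") * 1
  pres <- methods::as(pres, "CsparseMatrix")
  incidence_matrix(pres)
}

# Internal constructor used by to_incidence() and census_sites().
incidence_matrix <- function(presence) {
  if (is.null(rownames(presence)))
    rownames(presence) <- sprintf("u%d", seq_len(nrow(presence)))
  structure(list(presence = presence,
                 unit_ids = rownames(presence),
                 taxon_ids = colnames(presence),
                 m = nrow(presence),
                 empty_taxa = Matrix::colSums(presence) == 0),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> m = %d units x %d taxa (%d with zero incidence)\n",
              x$m, length(x$empty_taxa), sum(x$empty_taxa)))
  invisible(x)
}

#' Tally taxa by the number of samples they occur in
#'
#' For each incidence class k >= 1, counts the taxa found in exactly k
#' samples, and reports the fraction of observed taxa confined to one or two
#' samples — the headline sparsity statistic for large 16S compilations.
#'
#' @param x a [taxon_table] (a read in a sample is an occurrence).
#' @return A list: `tally` (named integer vector, names are k), `n_observed`
#'   (taxa with at least one occurrence), `n_le2`, `frac_le2`.
#' @export
incidence_tally <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  k <- Matrix::colSums(x$counts > 0)
  k <- k[k > 0]
  tab <- table(k)
  tally <- as.integer(tab)
  names(tally) <- names(tab)
  n_obs <- length(k)
  n_le2 <- sum(k <= 2)
  list(tally = tally, n_observed = n_obs, n_le2 = n_le2,
       frac_le2 = if (n_obs) n_le2 / n_obs else NA_real_)
}

#' Pool a corpus into a single ranked abundance vector
#'
#' Sums counts over samples and returns the pooled species-abundance
#' distribution sorted in decreasing order; the first element is the pooled
#' Nmax and the sum is the corpus grand total N. Taxa with zero total are
#' dropped.
#'
#' @param x a [taxon_table].
#' @return Named numeric vector of taxon totals, sorted decreasing.
#' @export
pool_corpus <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  tot <- Matrix::colSums(x$counts)
  tot <- tot[tot > 0]
  if (!length(tot)) stop("pool_corpus: empty table")
  sort(tot, decreasing = TRUE)
}
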