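#' Run the four-scenario estimator-bias experiment
#'
#' Builds one landscape per scenario (even/uneven x uniform/aggregated)
#' with shared N, S and grid, runs the site-accumulation experiment on
#' each, and writes one TSV per scenario with a commented metadata header
#' (scenario, parameters, seed, config hash) so runs are auditable and
#' byte-stable.
#'
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the records.
#' @param n_individuals,pool_richness,grid,sad_sigma,aggregation_sd_range
#'   passed to [build_landscape()].
#' @param site_counts,n_replicates,nested passed to
#'   [accumulation_experiment()]; the default site counts end with the full
#'   census.
#' @param seed integer master seed; each scenario derives its own stream.
#' @return Invisibly, a named list of the four accumulation data.frames
#'   (names `even_uniform`, `uneven_uniform`, `even_aggregated`,
#'   `uneven_aggregated`), with file paths in `attr(, "paths")` when
#'   written.
#' @export
run_fig1 <- function(out_dir = NULL, n_individuals = 1e7,
                     pool_richness = 1e5, grid = c(10, 10),
                     sad_sigma = 2.5, aggregation_sd_range = c(0.01, 0.3),
                     site_counts = NULL, n_replicates = 5L,
                     nested = FALSE, seed = 1L) {
  ncell <- prod(grid)
  if (is.null(site_counts))
    site_counts <- sort(unique(pmin(c(1, 2, 5, 10, 20, 50, ncell), ncell)))
  scenarios <- list(even_uniform = c("even", "uniform"),
                    uneven_uniform = c("uneven", "uniform"),
                    even_aggregated = c("even", "aggregated"),
                    uneven_aggregated = c("uneven", "aggregated"))
  out <- list(); paths <- character()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    sc_seed <- split_seed(seed, 1000L + i)
    land <- build_landscape(sc[1], sc[2], n_individuals, pool_richness,
                            grid, sad_sigma, aggregation_sd_range,
                            seed = sc_seed)
    rec <- accumulation_experiment(land, site_counts, n_replicates,
                                   seed = split_seed(seed, 2000L + i),
                                   nested = nested)
    out[[names(scenarios)[i]]] <- rec
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir,
                        sprintf("accumulation_%s.tsv", names(scenarios)[i]))
      meta <- c(sprintf("# scenario=%s+%s", sc[1], sc[2]),
                sprintf("# n_individuals=%g pool_richness=%g grid=%dx%d",
                        n_individuals, pool_richness, grid[1], grid[2]),
                sprintf("# sad_sigma=%g aggregation_sd_range=%g,%g nested=%s",
                        sad_sigma, aggregation_sd_range[1],
                        aggregation_sd_range[2], nested),
                sprintf("# master_seed=%d scenario_seed=%d config_hash=%s",
                        as.integer(seed), sc_seed,
                        config_hash(paste(n_individuals, pool_richness,
                                          paste(grid, collapse = "x"),
                                          sad_sigma, seed))))
      writeLines(meta, path)
      suppressWarnings(
        utils::write.table(rec, path, sep = "\t", row.names = FALSE,
                           quote = FALSE, append = TRUE))
      paths <- c(paths, path)
    }
  }
  attr(out, "paths") <- paths
  invisible(out)
}

#' Run the census reanalysis pipeline over a count table
#'
#' The full corpus chain: per-sample SAD summaries, one stratified
#' bootstrapped scaling fit per response axis, and the two-input lognormal
#' richness prediction at the pooled-corpus scale via both Nmax pathways
#' (the pooled empirical Nmax, and the Nmax predicted by the dominance DAR
#' at the pooled N).
#'
#' @param x a [taxon_table], a [generate_corpus()] result, or a path to a
#'   count table readable by [read_taxon_table()].
#' @param out_dir optional output directory for TSV reports.
#' @param responses response axes to fit (default all four).
#' @param n_boot,n_per_boot,strata_width passed to [fit_dar()].
#' @param Nmin minimum abundance for the lognormal stage.
#' @param seed master seed.
#' @return A list: `summaries`, `fits` (named list of `scaling_fit`),
#'   `pooled` (pooled SAD vector), `prediction`
#'   (a `global_prediction_report`, or `NULL` when no dominance fit was
#'   requested and no pooled Nmax is available).
#' @export
run_census <- function(x, out_dir = NULL,
                       responses = c("richness", "dominance", "evenness",
                                     "rarity"),
                       n_boot = 1000L, n_per_boot = 500L, strata_width = 1,
                       Nmin = 1, seed = 1L) {
  tab <- if (inherits(x, "taxon_table")) x
  else if (inherits(x, "synthetic_corpus")) x$table
  else if (is.character(x) && length(x) == 1L) read_taxon_table(x)
  else stop("run_census: x must be a taxon_table, synthetic_corpus, or path")
  if (nrow(tab$counts) < 2L)
    stop("run_census: need at least 2 samples to fit scaling relationships")

  summaries <- summarize_corpus(tab)
  fits <- list()
  for (i in seq_along(responses)) {
    fits[[responses[i]]] <- fit_dar(summaries, responses[i],
                                    n_boot = n_boot,
                                    n_per_boot = n_per_boot,
                                    strata_width = strata_width,
                                    seed = split_seed(seed, 3000L + i))
  }
  pooled <- pool_corpus(tab)
  prediction <- predict_global_richness(
    N = sum(pooled), Nmax = pooled[1],
    dominance_fit = fits[["dominance"]], Nmin = Nmin)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(summaries, file.path(out_dir, "sad_summaries.tsv"),
                       sep = "\t")
    fit_rows <- do.call(rbind, lapply(fits, function(f) {
      data.frame(response = f$response, exponent_mean = f$exponent_mean,
                 exponent_lo = f$exponent_ci[1], exponent_hi = f$exponent_ci[2],
                 intercept_mean = f$intercept_mean,
                 intercept_lo = f$intercept_ci[1],
                 intercept_hi = f$intercept_ci[2],
                 r2_mean = f$r2_mean, n_boot = f$n_boot,
                 n_per_boot = f$n_per_boot, seed = f$seed)
    }))
    data.table::fwrite(fit_rows, file.path(out_dir, "dar_fits.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(prediction),
                       file.path(out_dir, "global_prediction.tsv"), sep = "\t")
  }
  list(summaries = summaries, fits = fits, pooled = pooled,
       prediction = prediction)
}
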