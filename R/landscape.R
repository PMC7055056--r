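#' Simulate a community of N individuals on a gridded 2-D landscape
#'
#' Distributes `n_individuals` belonging to a pool of `pool_richness`
#' species across the unit square, partitioned into `grid[1] x grid[2]`
#' half-open sites, under one of four scenarios crossing two abundance modes
#' with two spatial modes:
#'
#' * `abundance = "even"`: all species share relative abundance 1/S;
#'   `"uneven"`: relative abundances are lognormal(0, `sad_sigma`),
#'   normalized. Realized per-species counts are one multinomial draw of N,
#'   so rare pool species may realize zero individuals.
#' * `spatial = "uniform"`: each individual lands independently and
#'   uniformly; `"aggregated"`: each species gets a random center on the
#'   unit square and an isotropic normal spread drawn uniformly from
#'   `aggregation_sd_range`; individual coordinates are reflected at the
#'   boundaries (no edge pile-up, total count conserved).
#'
#' The even+uniform combination is the "everything is everywhere" benchmark
#' under which incidence-based estimators converge on true richness; the
#' uneven and aggregated combinations probe their bias under realistic
#' community structure.
#'
#' @param abundance `"even"` or `"uneven"`.
#' @param spatial `"uniform"` or `"aggregated"`.
#' @param n_individuals total individuals N to place.
#' @param pool_richness species pool size S.
#' @param grid integer vector `c(rows, cols)`; default 10 x 10 = 100 sites.
#' @param sad_sigma lognormal width (natural-log space) for uneven
#'   abundances; default 2.5.
#' @param aggregation_sd_range range for per-species spatial spread, in
#'   unit-square units; default `c(0.01, 0.3)`.
#' @param seed integer seed; the build is fully deterministic given it.
#' @return An object of class `landscape`: `site_by_species` (dense integer
#'   matrix, sites x species), `grid`, `scenario`, `n_individuals`,
#'   `pool_richness`, `realized_richness` (species with >= 1 individual),
#'   `species_totals`, `seed`, and the generating parameters.
#' @examples
#' l <- build_landscape("uneven", "aggregated", n_individuals = 1e4,
#'                      pool_richness = 100, seed = 1)
#' l$realized_richness
#' @export
build_landscape <- function(abundance = c("even", "uneven"),
                            spatial = c("uniform", "aggregated"),
                            n_individuals, pool_richness,
                            grid = c(10, 10), sad_sigma = 2.5,
                            aggregation_sd_range = c(0.01, 0.3),
                            seed = 1L) {
  abundance <- match.arg(abundance)
  spatial <- match.arg(spatial)
  N <- as.numeric(n_individuals)
  S <- as.integer(pool_richness)
  if (length(grid) != 2L || any(grid < 1)) stop("build_landscape: invalid grid")
  rows <- as.integer(grid[1]); cols <- as.integer(grid[2])
  ncell <- rows * cols
  if (S < 1L || N < S) stop("build_landscape: need n_individuals >= pool_richness >= 1")
  if (sad_sigma < 0) stop("build_landscape: sad_sigma must be >= 0")
  if (as.numeric(ncell) * S > 5e8)
    stop("build_landscape: grid x pool_richness too large for dense storage")

  with_seed(split_seed(seed, 101L), {
    p <- if (abundance == "even") rep.int(1, S) else rlnorm(S, 0, sad_sigma)
    p <- p / sum(p)
    n_k <- rmultinom(1, N, p)[, 1]
    species <- rep.int(seq_len(S), n_k)
    site <- if (spatial == "uniform") {
      sample.int(ncell, N, replace = TRUE)
    } else {
      cx <- runif(S); cy <- runif(S)
      sdk <- runif(S, aggregation_sd_range[1], aggregation_sd_range[2])
      x <- reflect_unit(rep.int(cx, n_k) + rnorm(N) * rep.int(sdk, n_k))
      y <- reflect_unit(rep.int(cy, n_k) + rnorm(N) * rep.int(sdk, n_k))
      pmin.int(floor(y * rows), rows - 1L) * cols +
        pmin.int(floor(x * cols), cols - 1L) + 1L
    }
    counts <- matrix(tabulate((species - 1L) * ncell + site,
                              nbins = as.numeric(S) * ncell),
                     nrow = ncell)
  })
  totals <- colSums(counts)
  structure(list(site_by_species = counts,
                 grid = c(rows = rows, cols = cols),
                 scenario = c(abundance = abundance, spatial = spatial),
                 n_individuals = N, pool_richness = S,
                 realized_richness = sum(totals > 0),
                 species_totals = totals,
                 relative_abundance = p,
                 sad_sigma = sad_sigma,
                 aggregation_sd_range = aggregation_sd_range,
                 seed = as.integer(seed)),
            class = "landscape")
}

# Fold coordinates into [0, 1] by reflection at 0 and 1 (period-2 folding);
# exact 1.0 is handled by site-index clamping in the caller.
reflect_unit <- function(v) {
  v <- v %% 2
  i <- v > 1
  v[i] <- 2 - v[i]
  v
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %s abundances, %s spatial; N = %s, pool S = %s (realized %s), %d x %d sites\n",
              x$scenario["abundance"], x$scenario["spatial"],
              format(x$n_individuals, big.mark = ","),
              format(x$pool_richness, big.mark = ","),
              format(x$realized_richness, big.mark = ","),
              x$grid["rows"], x$grid["cols"]))
  invisible(x)
}

#' Census a set of landscape sites
#'
#' A censused site contributes every individual inside its cell. Returns
#' the site-by-species incidence (presence = abundance >= 1) with the raw
#' abundance matrix attached.
#'
#' @param landscape a [build_landscape()] result.
#' @param site_ids unique site indices in `1:prod(grid)`.
#' @return an `incidence_matrix` with an extra `abundance` field.
#' @export
census_sites <- function(landscape, site_ids) {
  stopifnot(inherits(landscape, "landscape"))
  ncell <- prod(landscape$grid)
  site_ids <- as.integer(site_ids)
  if (!length(site_ids) || anyDuplicated(site_ids) ||
      any(site_ids < 1L | site_ids > ncell))
    stop("census_sites: site_ids must be unique indices within the grid")
  ab <- landscape$site_by_species[site_ids, , drop = FALSE]
  rownames(ab) <- sprintf("site%d", site_ids)
  inc <- incidence_matrix((ab > 0) * 1)
  inc$abundance <- ab
  inc
}

#' Site-accumulation experiment with richness estimators
#'
#' For each requested number of sites and each replicate, draws that many
#' sites uniformly without replacement, censuses them, and computes observed
#' richness, bias-corrected Chao2, and ICE. Draws at different accumulation
#' levels are independent by default (`nested = FALSE`); with
#' `nested = TRUE` each replicate uses prefixes of a single site
#' permutation, making observed richness monotone within a replicate.
#'
#' @param landscape a [build_landscape()] result.
#' @param site_counts strictly increasing site numbers within
#'   `1:prod(grid)`.
#' @param n_replicates replicates per level (>= 1).
#' @param seed integer seed.
#' @param nested logical; see above.
#' @param infrequent_cutoff passed to [ice()].
#' @return A data.frame with one row per replicate x level: `replicate`,
#'   `n_sites_sampled`, `observed_richness`, `chao2_estimate`,
#'   `ice_estimate`, `pool_richness`, `realized_richness`, `seed`.
#' @export
accumulation_experiment <- function(landscape, site_counts,
                                    n_replicates = 10L, seed = 1L,
                                    nested = FALSE,
                                    infrequent_cutoff = 10) {
  stopifnot(inherits(landscape, "landscape"))
  ncell <- prod(landscape$grid)
  site_counts <- as.integer(site_counts)
  if (!length(site_counts) || any(diff(site_counts) <= 0) ||
      any(site_counts < 1L | site_counts > ncell))
    stop("accumulation_experiment: site_counts must be strictly increasing within [1, n_sites]")
  if (n_replicates < 1L) stop("accumulation_experiment: n_replicates must be >= 1")

  rows <- vector("list", n_replicates * length(site_counts))
  r <- 0L
  for (rep_i in seq_len(n_replicates)) {
    rep_seed <- split_seed(seed, rep_i)
    perm <- if (nested) with_seed(rep_seed, sample.int(ncell)) else NULL
    for (li in seq_along(site_counts)) {
      n_sites <- site_counts[li]
      ids <- if (nested) perm[seq_len(n_sites)] else
        with_seed(split_seed(rep_seed, li), sample.int(ncell, n_sites))
      fr <- incidence_frequencies(census_sites(landscape, ids))
      est_chao2 <- suppressWarnings(chao2(fr))
      est_ice <- suppressWarnings(ice(fr, infrequent_cutoff))
      r <- r + 1L
      rows[[r]] <- data.frame(replicate = rep_i, n_sites_sampled = n_sites,
                              observed_richness = fr$S_obs,
                              chao2_estimate = est_chao2,
                              ice_estimate = est_ice,
                              pool_richness = landscape$pool_richness,
                              realized_richness = landscape$realized_richness,
                              seed = as.integer(seed))
    }
  }
  do.call(rbind, rows)
}
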