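#' Detect deep haplogroups within a species by single-linkage clustering
#'
#' Haplogroups are the connected components of the graph joining specimens
#' whose pairwise distance is at most `threshold`: two clusters are separated
#' only when every cross distance exceeds the threshold (single linkage), so
#' chains of shallow steps stay in one group.
#'
#' @param m Specimen-level distance matrix.
#' @param ids Specimen ids of one species (at least one).
#' @param threshold Linkage threshold as a proportion; default `0.015`
#'   (the 1.5% deep-divergence rule).
#' @return A list of class `haplogroup_partition`: `membership` (named
#'   integer vector), `n_clusters`, `min_between` (smallest between-cluster
#'   distance, `NA` for a single cluster) and `threshold`.
#' @export
detect_haplogroups <- function(m, ids, threshold = 0.015) {
  stopifnot(length(ids) >= 1L, threshold >= 0)
  sub <- m[ids, ids, drop = FALSE]
  if (anyNA(sub)) stop("missing distance within species")
  if (length(ids) == 1L) {
    membership <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(sub), method = "single")
    membership <- stats::cutree(hc, h = threshold)
  }
  k <- max(membership)
  min_between <- NA_real_
  if (k > 1L) {
    min_between <- min(vapply(seq_len(k - 1L), function(a) {
      min(sub[membership == a, membership > a, drop = FALSE])
    }, numeric(1)))
  }
  structure(list(membership = membership, n_clusters = k,
                 min_between = min_between, threshold = threshold),
            class = "haplogroup_partition")
}

#' Flag a species as highly variable
#'
#' A species is highly variable when it carries two or more haplogroups and
#' its maximum intraspecific distance strictly exceeds the threshold; a
#' species sitting exactly at the threshold is not flagged.  The flag is
#' monotone in `max_intra`.
#'
#' @param max_intra Maximum intraspecific distance (proportion).
#' @param n_haplogroups Number of haplogroups from [detect_haplogroups()].
#' @param threshold Variability threshold, default `0.015`.
#' @return Logical flag.
#' @export
flag_highly_variable <- function(max_intra, n_haplogroups,
                                 threshold = 0.015) {
  n_haplogroups >= 2L & max_intra > threshold
}

#' Per-species intraspecific summaries
#'
#' For every species represented by at least two specimens, computes the
#' mean and maximum of all within-species pairwise K2P distances, counts
#' deep haplogroups at the 1.5% single-linkage rule and flags highly
#' variable species.  Species with a single specimen contribute no profile
#' (their count is reported, not an error).
#'
#' @param lib A [region_library()].
#' @param threshold Deep-divergence threshold (proportion), default `0.015`.
#' @param dist Optional precomputed specimen-level matrix from
#'   [k2p_matrix()]; when `NULL`, within-species distances are computed
#'   directly species by species (much cheaper for large libraries).
#' @return A data frame of class `species_profiles` with columns `species`,
#'   `family`, `n_specimens`, `mean_intra`, `max_intra`, `n_haplogroups`,
#'   `min_between` and `highly_variable`; attribute `n_singletons` counts
#'   skipped single-specimen species.
#' @export
species_profiles <- function(lib, threshold = 0.015, dist = NULL) {
  stopifnot(inherits(lib, "region_library"))
  split_ids <- split(lib$records$specimen_id, lib$records$species)
  fam <- lib$records$family[!duplicated(lib$records$species)]
  names(fam) <- lib$records$species[!duplicated(lib$records$species)]
  multi <- names(split_ids)[lengths(split_ids) >= 2L]
  n_singletons <- sum(lengths(split_ids) < 2L)
  if (n_singletons)
    message(n_singletons, " species with a single specimen excluded ",
            "from intraspecific profiles")
  rows <- lapply(multi, function(sp) {
    ids <- split_ids[[sp]]
    sub <- if (is.null(dist)) k2p_matrix(subset_library(lib, ids))
           else dist[ids, ids, drop = FALSE]
    d <- sub[upper.tri(sub)]
    if (anyNA(d)) {
      warning("species ", sp, ": ", sum(is.na(d)),
              " undefined intraspecific distance(s) ignored")
      d <- d[!is.na(d)]
    }
    part <- detect_haplogroups(sub, ids, threshold)
    data.frame(species = sp, family = unname(fam[sp]),
               n_specimens = length(ids),
               mean_intra = mean(d), max_intra = max(d),
               n_haplogroups = part$n_clusters,
               min_between = part$min_between,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), family = character(),
                      n_specimens = integer(), mean_intra = numeric(),
                      max_intra = numeric(), n_haplogroups = integer(),
                      min_between = numeric(), stringsAsFactors = FALSE)
  out$highly_variable <- flag_highly_variable(out$max_intra,
                                              out$n_haplogroups, threshold)
  attr(out, "threshold") <- threshold
  attr(out, "n_singletons") <- n_singletons
  class(out) <- c("species_profiles", "data.frame")
  out
}

#' Regional average of intraspecific distances
#'
#' Averages the species-level mean intraspecific distances of a region, each
#' species weighted equally irrespective of its number of specimens, with
#' the sample standard deviation (n-1; reported as 0 for a single species).
#' Highly variable species can be excluded to measure the background level
#' of intraspecific variation.
#'
#' @param profiles A [species_profiles()] table.
#' @param exclude_variable Drop species flagged highly variable first?
#' @return A list of class `region_intra_summary` with
#'   `mean_of_species_means`, `sd`, `n_species`, `excluded_variable`.
#' @export
regional_intraspecific <- function(profiles, exclude_variable = FALSE) {
  x <- profiles$mean_intra
  if (exclude_variable) x <- x[!profiles$highly_variable]
  if (!length(x)) stop("no species left after exclusion")
  structure(list(mean_of_species_means = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 n_species = length(x),
                 excluded_variable = exclude_variable),
            class = "region_intra_summary")
}

#' @export
print.region_intra_summary <- function(x, ...) {
  cat(sprintf(
    "Mean intraspecific distance: %.2f%% +/- %.2f%% (%d species%s)\n",
    100 * x$mean_of_species_means, 100 * x$sd, x$n_species,
    if (x$excluded_variable) ", highly variable excluded" else ""))
  invisible(x)
}
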