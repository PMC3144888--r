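#' Configuration for a synthetic regional barcode library
#'
#' The defaults emulate a temperate avifaunal COI library: many species with
#' two specimens each, shallow within-species variation around 0.2%, a small
#' fraction of species split into two deep (3%) haplogroups, and congeneric
#' species whose ancestors diverge by a Gamma-distributed amount with mean
#' 6.1% and SD 3.7%.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (>= 2 so congener pairs
#'   exist).
#' @param specimens_per_species Specimens per species: a single integer or a
#'   function `n_species -> integer vector` for a distribution.
#' @param seq_length Alignment length in sites; default 648, the standard
#'   COI barcode.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process; default 5, a typical avian mitochondrial transition bias.
#' @param pair_divergence_mean,pair_divergence_sd Mean and SD of the Gamma
#'   distribution of congeneric ancestor splits (proportions).
#' @param intra_depth Expected within-species pairwise distance; specimens
#'   radiate from the species ancestor at half this depth (star phylogeny).
#' @param genus_depth Expected distance between the roots of two genera
#'   (the genus roots radiate from a single regional ancestor at half this
#'   depth); default 0.15, a typical between-genus COI divergence.  Keeps
#'   cross-genus comparisons inside the K2P domain.
#' @param variable_fraction Probability that a species carries a second,
#'   deep haplogroup.
#' @param variable_split_depth Distance between the two haplogroup ancestors
#'   of a variable species; must exceed 0.015 so the 1.5% rule can find it.
#' @param region Region label for the generated library.
#' @param seed Integer seed; the full library is a deterministic function of
#'   the configuration including the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genera = 100L, species_per_genus = 2L,
                         specimens_per_species = 2L, seq_length = 648L,
                         kappa = 5, pair_divergence_mean = 0.061,
                         pair_divergence_sd = 0.037, intra_depth = 0.002,
                         variable_fraction = 0.054,
                         variable_split_depth = 0.03,
                         genus_depth = 0.15,
                         region = "Synthetica", seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 2L, seq_length >= 1L,
            kappa > 0, pair_divergence_mean > 0, pair_divergence_sd > 0,
            intra_depth >= 0, variable_fraction >= 0, variable_fraction <= 1,
            variable_split_depth > 0.015, genus_depth >= 0)
  if (is.numeric(specimens_per_species))
    stopifnot(specimens_per_species >= 2L)
  structure(as.list(environment()), class = "synth_config")
}

#' Per-site transition and transversion probabilities of the K2P process
#'
#' Closed forms of the Kimura two-parameter Markov process at expected
#' divergence `d` with transition/transversion rate ratio `kappa`
#' (\eqn{\alpha/\beta}): with \eqn{\beta t = d/(\kappa+2)},
#' \deqn{p_{ts} = \tfrac14 - \tfrac12 e^{-2(\alpha+\beta)t}
#'       + \tfrac14 e^{-4\beta t}, \quad
#'       p_{tv} = \tfrac12 - \tfrac12 e^{-4\beta t}.}
#' Feeding these proportions back into the [k2p()] estimator returns `d`
#' exactly (inverse consistency), which is what makes simulated libraries a
#' parameter-recovery oracle for the whole pipeline.
#'
#' @param d Expected K2P distance (proportion), >= 0.
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return Named vector `c(p_transition, p_transversion)`.
#' @export
k2p_site_probs <- function(d, kappa = 5) {
  stopifnot(d >= 0, kappa > 0)
  bt <- d / (kappa + 2)       # beta * t
  at <- kappa * bt            # alpha * t
  c(p_transition = 0.25 - 0.5 * exp(-2 * (at + bt)) + 0.25 * exp(-4 * bt),
    p_transversion = 0.5 - 0.5 * exp(-4 * bt))
}

# one random ACGT sequence of length L (encoded 1..4 as in .encode_seqs)
.random_seq <- function(L) sample.int(4L, L, replace = TRUE)

# evolve an encoded sequence by expected distance d under the K2P kernel;
# the kernel composes additively along branches (Markov property), so
# root->tip paths give tips separated by the summed branch lengths
.evolve <- function(enc, d, kappa) {
  p <- k2p_site_probs(d, kappa)
  u <- stats::runif(length(enc))
  out <- enc
  ts <- u < p[1L]
  tv <- !ts & u < p[1L] + p[2L]
  # transition partner: A<->G is 1<->2, C<->T is 3<->4
  out[ts] <- ifelse(enc[ts] %% 2L == 1L, enc[ts] + 1L, enc[ts] - 1L)
  # transversion: one of the two bases of the other chemical type
  if (any(tv)) {
    other <- ifelse(enc[tv] <= 2L, 3L, 1L)   # first base of other type
    out[tv] <- other + (stats::runif(sum(tv)) < 0.5)
  }
  out
}

.decode_seq <- function(enc) {
  paste(c("A", "G", "C", "T")[enc], collapse = "")
}

#' Simulate one pair of sequences at a given expected distance
#'
#' Draws a random ancestor-free pair directly: the first sequence is uniform
#' over ACGT and the second is its image under the K2P kernel at distance
#' `d`, so the expected estimated K2P distance equals `d`.
#'
#' @param d Expected K2P distance (proportion).
#' @param seq_length Number of sites.
#' @param kappa Transition/transversion rate ratio.
#' @return Character vector of two aligned sequences.  Uses the R RNG;
#'   seed it (`set.seed`) for reproducibility.
#' @export
simulate_pair <- function(d, seq_length = 648L, kappa = 5) {
  a <- .random_seq(seq_length)
  b <- .evolve(a, d, kappa)
  c(.decode_seq(a), .decode_seq(b))
}

#' Simulate a regional barcode library with known truth
#'
#' Generates `n_genera * species_per_genus` species.  Within a genus the
#' species ancestors radiate in a star from the genus root, each at half a
#' Gamma-distributed split depth, so a pair of congeners is separated by the
#' average of its two draws.  Specimens radiate in a star from their species
#' ancestor at `intra_depth / 2`; a `variable_fraction` of species instead
#' carry two haplogroup ancestors `variable_split_depth` apart, with
#' specimens alternating between them.  The returned truth table makes the
#' library a parameter-recovery oracle for every pipeline stage.
#'
#' @param cfg A [synth_config()].
#' @return List with `library` (a [region_library()]) and `truth`, itself a
#'   list with `species` (per-species expected within distance, haplogroup
#'   count, split depth) and `pairs` (per congeneric species pair, the
#'   ancestor split `d_ancestor` and the expected specimen-level distance
#'   `d_expected`).
#' @export
simulate_region <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  shape <- (cfg$pair_divergence_mean / cfg$pair_divergence_sd)^2
  rate <- shape / cfg$pair_divergence_mean
  n_sp_total <- cfg$n_genera * cfg$species_per_genus
  n_spec <- if (is.function(cfg$specimens_per_species))
    cfg$specimens_per_species(n_sp_total)
  else rep(as.integer(cfg$specimens_per_species), n_sp_total)
  stopifnot(length(n_spec) == n_sp_total, all(n_spec >= 2L))
  gwidth <- max(2L, nchar(as.character(cfg$n_genera)))
  ids <- species <- genera <- families <- character(0)
  seqs <- list()
  sp_rows <- vector("list", n_sp_total)
  pair_rows <- list()
  sp_i <- 0L
  region_root <- .random_seq(cfg$seq_length)
  for (g in seq_len(cfg$n_genera)) {
    genus <- sprintf("Genus%0*d", gwidth, g)
    family <- sprintf("Family%02d", ((g - 1L) %% 20L) + 1L)
    root <- .evolve(region_root, cfg$genus_depth / 2, cfg$kappa)
    # half-depths of the species ancestors below the genus root: with two
    # species the single draw IS their split, so the pair distance follows
    # the configured distribution exactly; larger genera radiate in a star
    # with one draw per species (pair distance = mean of the two draws)
    half <- if (cfg$species_per_genus == 2L)
      rep(stats::rgamma(1L, shape, rate) / 2, 2L)
    else stats::rgamma(cfg$species_per_genus, shape, rate) / 2
    depth <- numeric(cfg$species_per_genus)  # expected tip depth below ancestor
    anc <- vector("list", cfg$species_per_genus)
    for (s in seq_len(cfg$species_per_genus)) {
      sp_i <- sp_i + 1L
      sp_name <- sprintf("%s sp%02d", genus, s)
      anc[[s]] <- .evolve(root, half[s], cfg$kappa)
      two_groups <- stats::runif(1) < cfg$variable_fraction
      k <- n_spec[sp_i]
      if (two_groups) {
        h1 <- .evolve(anc[[s]], cfg$variable_split_depth / 2, cfg$kappa)
        h2 <- .evolve(anc[[s]], cfg$variable_split_depth / 2, cfg$kappa)
        hap <- rep_len(1:2, k)
        tips <- lapply(seq_len(k), function(t)
          .evolve(if (hap[t] == 1L) h1 else h2,
                  cfg$intra_depth / 2, cfg$kappa))
        depth[s] <- cfg$variable_split_depth / 2 + cfg$intra_depth / 2
      } else {
        tips <- lapply(seq_len(k), function(t)
          .evolve(anc[[s]], cfg$intra_depth / 2, cfg$kappa))
        depth[s] <- cfg$intra_depth / 2
      }
      tip_ids <- sprintf("%s_%02d", gsub(" ", "_", sp_name), seq_len(k))
      ids <- c(ids, tip_ids)
      species <- c(species, rep(sp_name, k))
      genera <- c(genera, rep(genus, k))
      families <- c(families, rep(family, k))
      seqs <- c(seqs, lapply(tips, .decode_seq))
      sp_rows[[sp_i]] <- data.frame(
        species = sp_name, genus = genus,
        n_specimens = k,
        true_intra = cfg$intra_depth,
        n_haplogroups_true = if (two_groups) 2L else 1L,
        split_depth = if (two_groups) cfg$variable_split_depth else 0,
        stringsAsFactors = FALSE)
    }
    sp_names <- vapply(seq_len(cfg$species_per_genus),
                       function(s) sprintf("%s sp%02d", genus, s),
                       character(1))
    for (s1 in seq_len(cfg$species_per_genus - 1L))
      for (s2 in (s1 + 1L):cfg$species_per_genus)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          species_a = sp_names[s1], species_b = sp_names[s2], genus = genus,
          d_ancestor = half[s1] + half[s2],
          d_expected = half[s1] + half[s2] + depth[s1] + depth[s2],
          stringsAsFactors = FALSE)
  }
  records <- data.frame(specimen_id = ids, species = species,
                        genus = genera, family = families,
                        stringsAsFactors = FALSE)
  lib <- region_library(cfg$region, records,
                        stats::setNames(unlist(seqs), ids))
  truth <- list(species = do.call(rbind, sp_rows),
                pairs = do.call(rbind, pair_rows))
  list(library = lib, truth = truth)
}
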