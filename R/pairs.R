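#' Species-level distance matrix
#'
#' Aggregates a specimen-level K2P matrix into a species-by-species matrix
#' using [between_group_distance()] on every species pair.
#'
#' @param m Specimen-level distance matrix.
#' @param species_map Named character vector mapping specimen id to species
#'   (e.g. built from a library's records).
#' @param mode Aggregation of cross-specimen distances: `"mean"` (default)
#'   or `"min"`.
#' @return Symmetric species matrix with attributes `level = "species"` and
#'   `mode`.
#' @export
species_distance_matrix <- function(m, species_map,
                                    mode = c("mean", "min")) {
  mode <- match.arg(mode)
  ids <- rownames(m)
  stopifnot(all(ids %in% names(species_map)))
  by_sp <- split(ids, species_map[ids])
  sp <- names(by_sp)
  S <- length(sp)
  out <- matrix(0, S, S, dimnames = list(sp, sp))
  if (S >= 2L)
    for (i in seq_len(S - 1L)) for (j in (i + 1L):S)
      out[i, j] <- out[j, i] <-
        between_group_distance(m, by_sp[[i]], by_sp[[j]], mode)
  attr(out, "level") <- "species"
  attr(out, "mode") <- mode
  out
}

.new_pair_set <- function(df, species_universe, mode, source) {
  if (nrow(df)) {
    all_sp <- c(df$species_a, df$species_b)
    if (anyDuplicated(all_sp))
      stop("internal error: species repeated in pair set")
  }
  structure(df, species = species_universe, mode = mode, source = source,
            class = c("pair_set", "data.frame"))
}

#' Non-redundant nearest congeneric neighbour pairs
#'
#' Within each genus, a pair (A, B) qualifies when B is A's closest congener
#' and A is B's closest congener among the non-excluded species; qualifying
#' pairs are accepted greedily by ascending distance so no species appears
#' twice, which keeps the comparisons independent.  Highly variable species
#' are typically passed in `exclude` so their inflated lineages do not enter
#' the pair list.  Ties are broken towards the alphabetically first species.
#'
#' @param sm Species-level matrix from [species_distance_matrix()].
#' @param genus_map Named character vector mapping species to genus.
#' @param exclude Species names to leave out (e.g. highly variable species).
#' @return A data frame of class `pair_set` with columns `species_a`,
#'   `species_b`, `genus`, `distance`, `is_sister`, `source`.
#' @export
nearest_congener_pairs <- function(sm, genus_map, exclude = character()) {
  sp <- setdiff(rownames(sm), exclude)
  stopifnot(all(sp %in% names(genus_map)))
  rows <- list()
  for (g in sort(unique(genus_map[sp]))) {
    members <- sort(sp[genus_map[sp] == g])
    if (length(members) < 2L) next
    sub <- sm[members, members, drop = FALSE]
    diag(sub) <- Inf
    nearest <- apply(sub, 1L, function(r) members[which.min(r)])
    cand <- list()
    for (a in members) {
      b <- nearest[[a]]
      if (nearest[[b]] == a && a < b)
        cand[[length(cand) + 1L]] <- data.frame(
          species_a = a, species_b = b, genus = g,
          distance = sub[a, b], stringsAsFactors = FALSE)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance, cand$species_a), , drop = FALSE]
    used <- character()
    for (r in seq_len(nrow(cand))) {
      pr <- cand[r, ]
      if (pr$species_a %in% used || pr$species_b %in% used) next
      used <- c(used, pr$species_a, pr$species_b)
      rows[[length(rows) + 1L]] <- pr
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_a = character(), species_b = character(),
               genus = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df$is_sister <- rep(FALSE, nrow(df))
  df$source <- rep("nearest_congener", nrow(df))
  .new_pair_set(df, rownames(sm), attr(sm, "mode"), "nearest_congener")
}

#' Build a pair set directly from a sister-species list
#'
#' Looks each listed sister pair up in the species matrix and records its
#' between-group distance; pairs with a species absent from the data are
#' dropped with a warning.
#'
#' @param sm Species-level matrix from [species_distance_matrix()].
#' @param sister_list Data frame (or two-column matrix) whose first two
#'   columns give the species names of each unordered sister pair.
#' @return A `pair_set` with `source = "sister_list"` and `is_sister` true.
#' @export
sister_pairs <- function(sm, sister_list) {
  sl <- normalize_sister_list(sister_list)
  present <- sl$a %in% rownames(sm) & sl$b %in% rownames(sm)
  if (any(!present))
    warning(sum(!present), " sister pair(s) with species absent from the ",
            "data ignored")
  sl <- sl[present, , drop = FALSE]
  df <- data.frame(species_a = sl$a, species_b = sl$b,
                   genus = sub("[[:space:]].*$", "", sl$a),
                   distance = sm[cbind(sl$a, sl$b)],
                   is_sister = rep(TRUE, nrow(sl)),
                   source = rep("sister_list", nrow(sl)),
                   stringsAsFactors = FALSE)
  # keep the pair set non-redundant: first occurrence of a species wins
  seen <- character(); keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    keep[r] <- !(df$species_a[r] %in% seen) && !(df$species_b[r] %in% seen)
    if (keep[r]) seen <- c(seen, df$species_a[r], df$species_b[r])
  }
  if (any(!keep))
    warning(sum(!keep), " sister pair(s) dropped to keep species unique")
  df <- df[keep, , drop = FALSE]
  .new_pair_set(df, rownames(sm), attr(sm, "mode"), "sister_list")
}

# canonical unordered representation: a < b alphabetically
normalize_sister_list <- function(sister_list) {
  sl <- as.data.frame(sister_list, stringsAsFactors = FALSE)
  stopifnot(ncol(sl) >= 2L)
  a <- squish(as.character(sl[[1L]])); b <- squish(as.character(sl[[2L]]))
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

#' Annotate sister status on a pair set
#'
#' Marks `is_sister` for every pair that occurs (order-insensitively) in a
#' published sister-species list.  Listed species absent from the data are
#' ignored with a warning.
#'
#' @param ps A `pair_set`.
#' @param sister_list Two-column data frame of sister species names.
#' @return The pair set with `is_sister` updated.
#' @export
annotate_sisters <- function(ps, sister_list) {
  stopifnot(inherits(ps, "pair_set"))
  sl <- normalize_sister_list(sister_list)
  universe <- attr(ps, "species")
  missing <- !(sl$a %in% universe & sl$b %in% universe)
  if (any(missing))
    warning(sum(missing), " sister pair(s) with species absent from the ",
            "data ignored")
  sl <- sl[!missing, , drop = FALSE]
  key_ps <- paste(pmin(ps$species_a, ps$species_b),
                  pmax(ps$species_a, ps$species_b), sep = " || ")
  ps$is_sister <- key_ps %in% paste(sl$a, sl$b, sep = " || ")
  ps
}

.pair_subset <- function(ps, subset = c("all", "sisters_only")) {
  subset <- match.arg(subset)
  d <- ps$distance
  if (subset == "sisters_only") d <- d[ps$is_sister]
  d
}

#' Mean and spread of pair divergences
#'
#' @param ps A `pair_set`.
#' @param subset `"all"` pairs or `"sisters_only"`.
#' @return List with `mean`, `sd` (sample SD) and `n`.
#' @export
divergence_summary <- function(ps, subset = c("all", "sisters_only")) {
  d <- .pair_subset(ps, subset)
  if (!length(d)) stop("empty pair subset")
  list(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0,
       n = length(d))
}

#' Proportion of pairs below a divergence threshold
#'
#' Counts pairs diverging strictly less than the threshold (a pair exactly
#' at the threshold is not counted), the rule used for the "less than 1%"
#' recent-divergence comparisons.
#'
#' @param ps A `pair_set`.
#' @param threshold Divergence threshold (proportion), default `0.01`.
#' @param subset `"all"` or `"sisters_only"`.
#' @return List with `k` (count below), `n` and `proportion`.
#' @export
proportion_below <- function(ps, threshold = 0.01,
                             subset = c("all", "sisters_only")) {
  d <- .pair_subset(ps, subset)
  if (!length(d)) stop("empty pair subset")
  k <- sum(d < threshold)
  list(k = k, n = length(d), proportion = k / length(d))
}
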