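# Integer encoding used throughout: purines A=1, G=2; pyrimidines C=3, T=4;
# gaps, N and IUPAC partial ambiguities become NA and are deleted pairwise.
.encode_seqs <- function(seqs) {
  codes <- c(A = 1L, G = 2L, C = 3L, T = 4L)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  enc <- matrix(codes[m], nrow = nrow(m), dimnames = list(names(seqs), NULL))
  enc
}

#' Count transitions and transversions between two aligned sequences
#'
#' Compares two equal-length aligned sequences site by site under pairwise
#' deletion: any site where either sequence carries a gap or an ambiguity
#' (anything but `A,C,G,T`) is excluded.  Transitions are `A<->G` and
#' `C<->T`; every other mismatch is a transversion.
#'
#' @param a,b Aligned sequences (character strings of equal length).
#' @return A list of class `site_counts` with `n_compared`, `n_transitions`
#'   and `n_transversions`.
#' @export
count_site_differences <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nchar(a) == nchar(b))
  enc <- .encode_seqs(c(x = a, y = b))
  cmp <- !is.na(enc[1L, ]) & !is.na(enc[2L, ])
  if (!any(cmp)) stop("no comparable sites")
  x <- enc[1L, cmp]; y <- enc[2L, cmp]
  mism <- x != y
  ts <- mism & ((x <= 2L) == (y <= 2L))
  structure(list(n_compared = sum(cmp),
                 n_transitions = sum(ts),
                 n_transversions = sum(mism & !ts)),
            class = "site_counts")
}

#' Kimura two-parameter distance from site counts
#'
#' Evaluates the K2P estimator
#' \deqn{d = -\tfrac12 \ln\{(1 - 2P - Q)\sqrt{1 - 2Q}\}}
#' with transition proportion \eqn{P} and transversion proportion \eqn{Q}
#' taken over the compared sites.
#'
#' @param counts A `site_counts` object from [count_site_differences()], or a
#'   list with elements `n_compared`, `n_transitions`, `n_transversions`.
#' @return The distance as a proportion (multiply by 100 for percent).
#'   Errors with "K2P undefined (saturation)" when the log arguments are not
#'   positive.
#' @export
k2p <- function(counts) {
  P <- counts$n_transitions / counts$n_compared
  Q <- counts$n_transversions / counts$n_compared
  d <- .k2p_pq(P, Q)
  if (is.na(d)) stop("K2P undefined (saturation)")
  d
}

# vectorised core; returns NA where the estimator leaves its domain
.k2p_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(P))
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  d
}

#' Pairwise K2P distance matrix for a library
#'
#' Computes the full symmetric specimen-level K2P matrix under pairwise
#' deletion.  Pairs for which the estimator is undefined (saturation, or no
#' comparable sites) are recorded as `NA` and reported with a warning; they
#' are never clamped.
#'
#' @param lib A [region_library()] with at least two records.
#' @return A symmetric numeric matrix with specimen ids as dimnames, zero
#'   diagonal, and attributes `level = "specimen"` and `n_saturated`.
#' @export
k2p_matrix <- function(lib) {
  stopifnot(inherits(lib, "region_library"), nrow(lib$records) >= 2L)
  enc <- .encode_seqs(lib$sequences)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    a <- enc[i, ]
    Bt <- t(enc[idx, , drop = FALSE])       # sites x others; a recycles down
    cmp <- !is.na(a) & !is.na(Bt)
    mism <- cmp & (a != Bt)
    ts <- mism & ((a <= 2L) == (Bt <= 2L))
    ncmp <- colSums(cmp)
    nts <- colSums(ts)
    ntv <- colSums(mism) - nts
    d <- ifelse(ncmp > 0L, .k2p_pq(nts / ncmp, ntv / ncmp), NA_real_)
    D[i, idx] <- D[idx, i] <- d
  }
  n_sat <- sum(is.na(D[upper.tri(D)]))
  if (n_sat > 0L)
    warning(n_sat, " specimen pair(s) with undefined K2P distance ",
            "(saturation or no comparable sites); recorded as NA")
  attr(D, "level") <- "specimen"
  attr(D, "n_saturated") <- n_sat
  D
}

#' Between-group K2P distance
#'
#' Aggregates the cross distances between two disjoint specimen sets either
#' as the arithmetic mean over all cross pairs or as their minimum.
#'
#' @param m Specimen-level distance matrix from [k2p_matrix()].
#' @param ids_a,ids_b Disjoint, non-empty specimen id sets.
#' @param mode `"mean"` (all cross-specimen pairs averaged; default) or
#'   `"min"`.
#' @return A single distance (proportion).
#' @export
between_group_distance <- function(m, ids_a, ids_b,
                                   mode = c("mean", "min")) {
  mode <- match.arg(mode)
  stopifnot(length(ids_a) > 0L, length(ids_b) > 0L)
  if (length(intersect(ids_a, ids_b)))
    stop("specimen sets are not disjoint")
  sub <- m[ids_a, ids_b, drop = FALSE]
  if (anyNA(sub)) stop("missing cross distance between groups")
  if (mode == "mean") mean(sub) else min(sub)
}

#' Write a distance matrix as TSV or square PHYLIP
#'
#' @param m A square labelled distance matrix.
#' @param path Output file.
#' @param format `"tsv"` (labelled square table with header) or `"phylip"`
#'   (square PHYLIP distance format).
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(format(nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i],
                         format(m[i, ], digits = 10, trim = TRUE)),
                       collapse = "  "), con)
  }
  invisible(path)
}
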