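#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining with the Studier–Keppler selection criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}.  The agglomeration is fully
#' deterministic: when several pairs minimise \eqn{Q}, the lexicographically
#' smallest label pair is joined (internal nodes inherit the smaller child
#' label for this purpose), so permuting the input rows yields an isomorphic
#' tree.
#'
#' @param m Complete symmetric distance matrix with at least three labelled
#'   rows; missing entries are an error.
#' @param allow_negative Keep negative branch lengths?  By default they are
#'   clamped to zero (the number of clamped branches is in attribute
#'   `n_clamped` and reported via `message()`).
#' @return An unrooted `phylo` tree (ape) whose leaf set equals the matrix
#'   labels.
#' @export
nj_tree <- function(m, allow_negative = FALSE) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 3L)
  if (anyNA(m)) stop("distance matrix has missing entries")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  D <- unname(m)
  nodes <- sprintf("xTIPx%dx", seq_along(labels))  # growing Newick substrings
  keys <- labels                # tie-break key per active node
  n_clamped <- 0L
  clamp <- function(x) {
    if (!allow_negative && x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(keys[cand[, 1]], keys[cand[, 2]]),
                 pmax(keys[cand[, 1]], keys[cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], li, nodes[j], lj)
    new_key <- min(keys[i], keys[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    keys <- c(keys[keep], new_key)
  }
  # final three-way join: branch lengths from the three-point formulas
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[1], la, nodes[2], lb, nodes[3], lc)
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <-
    labels[as.integer(sub("^xTIPx([0-9]+)x$", "\\1", tree$tip.label))]
  if (n_clamped > 0L)
    message(n_clamped, " negative NJ branch length(s) clamped to zero")
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths.  Labels containing spaces or other
#' characters outside the safe Newick set are single-quoted (embedded
#' quotes doubled), so [read_newick()] round-trips topology, branch lengths
#' and labels exactly.
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  bad <- which(grepl("[^A-Za-z0-9_.|/-]", labs))
  ph <- sprintf("xQUOTEDTIPx%dx", bad)
  tree$tip.label[bad] <- ph
  nwk <- ape::write.tree(tree, digits = 12)
  for (k in seq_along(bad))
    nwk <- sub(ph[k], paste0("'", gsub("'", "''", labs[bad[k]]), "'"),
               nwk, fixed = TRUE)
  writeLines(nwk, path)
  invisible(path)
}

#' Read a Newick tree, honouring quoted labels
#'
#' Companion to [write_newick()]: single-quoted labels (with doubled
#' embedded quotes) are restored verbatim; everything else is parsed by
#' `ape::read.tree`.
#'
#' @param path Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  nwk <- paste(readLines(path), collapse = "")
  m <- gregexpr("'(''|[^'])*'", nwk)[[1L]]
  labs <- character(0)
  if (m[1L] != -1L) {
    labs <- regmatches(nwk, gregexpr("'(''|[^'])*'", nwk))[[1L]]
    for (k in seq_along(labs))
      nwk <- sub(labs[k], sprintf("xQUOTEDTIPx%dx", k), nwk, fixed = TRUE)
    labs <- gsub("''", "'", substr(labs, 2L, nchar(labs) - 1L))
  }
  tree <- ape::read.tree(text = nwk)
  ph <- match(tree$tip.label, sprintf("xQUOTEDTIPx%dx", seq_along(labs)))
  tree$tip.label[!is.na(ph)] <- labs[ph[!is.na(ph)]]
  tree
}
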