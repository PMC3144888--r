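# Shared fixture builders and independent oracles.

# A library built from explicit sequences; species defaults to one per
# specimen ("Genus## sp") so taxonomy is always consistent.
make_lib <- function(seqs, species = NULL, region = "Testland") {
  n <- length(seqs)
  ids <- sprintf("spec%02d", seq_len(n))
  names(seqs) <- ids
  if (is.null(species)) species <- sprintf("Genus%02d sp", seq_len(n))
  records <- data.frame(
    specimen_id = ids, species = species,
    genus = sub("[[:space:]].*$", "", species),
    family = "Familyidae", stringsAsFactors = FALSE)
  region_library(region, records, seqs)
}

# random ACGT string
random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# symmetric matrix with prescribed upper-triangle entries (column-major:
# (1,2), (1,3), (2,3), (1,4), ...)
fab_matrix <- function(d, labs = sprintf("s%d",
                       seq_len((1 + sqrt(1 + 8 * length(d))) / 2))) {
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[upper.tri(m)] <- d
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(labels, max_d = 0.2) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.001, max_d)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Independent oracle: enumerate all mutual-nearest congeneric pairs, then
# accept greedily by ascending distance so no species repeats.
brute_mutual_pairs <- function(sm, genus_map) {
  sp <- rownames(sm)
  cand <- list()
  for (a in sp) for (b in sp) {
    if (a >= b || genus_map[a] != genus_map[b]) next
    congener_a <- setdiff(sp[genus_map[sp] == genus_map[a]], a)
    congener_b <- setdiff(sp[genus_map[sp] == genus_map[b]], b)
    na <- congener_a[order(sm[a, congener_a], congener_a)][1L]
    nb <- congener_b[order(sm[b, congener_b], congener_b)][1L]
    if (na == b && nb == a)
      cand[[length(cand) + 1L]] <- list(a = a, b = b, d = sm[a, b])
  }
  if (!length(cand)) return(data.frame(species_a = character(),
                                       species_b = character(),
                                       distance = numeric()))
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "d"),
                     vapply(cand, `[[`, character(1), "a"))]
  used <- character(); out <- list()
  for (p in cand) {
    if (p$a %in% used || p$b %in% used) next
    used <- c(used, p$a, p$b)
    out[[length(out) + 1L]] <- data.frame(
      species_a = p$a, species_b = p$b, distance = p$d,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# convert a library to ape DNAbin for cross-checks
lib_to_dnabin <- function(lib) {
  ape::as.DNAbin(do.call(rbind, strsplit(tolower(lib$sequences), "")))
}
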