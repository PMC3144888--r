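test_that("site counting applies pairwise deletion and ts/tv definitions", {
  expect_equal(unclass(count_site_differences("ACGT", "ACGT")),
               list(n_compared = 4L, n_transitions = 0L,
                    n_transversions = 0L))
  # A->G is a transition
  expect_equal(unclass(count_site_differences("ACGT", "GCGT")),
               list(n_compared = 4L, n_transitions = 1L,
                    n_transversions = 0L))
  # gap site deleted pairwise; T<->A is a transversion
  expect_equal(unclass(count_site_differences("ACGT", "A-GA")),
               list(n_compared = 3L, n_transitions = 0L,
                    n_transversions = 1L))
  # N and IUPAC partials are deleted pairwise too
  expect_equal(count_site_differences("ACGT", "NCRT")$n_compared, 2L)
  expect_error(count_site_differences("NNNN", "ACGT"),
               "no comparable sites")
})

test_that("K2P estimator matches the closed form and flags saturation", {
  cnt <- function(n, ts, tv) list(n_compared = n, n_transitions = ts,
                                  n_transversions = tv)
  expect_equal(k2p(cnt(100, 0, 0)), 0)
  # -0.5 log(0.75) - 0.25 log(0.90), evaluated independently
  expect_equal(k2p(cnt(100, 10, 5)), 0.1701812, tolerance = 1e-6)
  # -0.5 log(0.25) - 0.25 log(0.5)
  expect_equal(k2p(cnt(100, 25, 25)), 0.8664340, tolerance = 1e-6)
  expect_error(k2p(cnt(100, 50, 10)), "saturation")
})

test_that("K2P correction inflates the p-distance and is monotone", {
  set.seed(21)
  for (rep in 1:200) {
    n <- 500L
    ts <- sample(0:80, 1); tv <- sample(0:80, 1)
    d <- tryCatch(k2p(list(n_compared = n, n_transitions = ts,
                           n_transversions = tv)), error = function(e) NA)
    if (is.na(d)) next
    expect_gte(d, (ts + tv) / n)
    d2 <- tryCatch(k2p(list(n_compared = n, n_transitions = ts + 1L,
                            n_transversions = tv)), error = function(e) NA)
    if (!is.na(d2)) expect_gt(d2, d)
  }
})

test_that("pairwise matrix equals brute force and the ape reference", {
  set.seed(31)
  sim <- simulate_region(synth_config(n_genera = 3, specimens_per_species = 2,
                                      seq_length = 400, seed = 31))
  lib <- sim$library
  m <- k2p_matrix(lib)
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  ids <- lib$records$specimen_id
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1L)) {
    expect_equal(m[ids[i], ids[j]],
                 k2p(count_site_differences(lib$sequences[[ids[i]]],
                                            lib$sequences[[ids[j]]])))
  }
  ref <- as.matrix(ape::dist.dna(lib_to_dnabin(lib), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(m), unname(ref[rownames(m), colnames(m)]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("identical sequences give a zero matrix", {
  s <- random_dna(200)
  m <- k2p_matrix(make_lib(c(s, s)))
  expect_equal(unname(m), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("between-group distance aggregates cross pairs", {
  labs <- c("a1", "a2", "b1")
  m <- matrix(0, 3, 3, dimnames = list(labs, labs))
  m["a1", "b1"] <- m["b1", "a1"] <- 0.02
  m["a2", "b1"] <- m["b1", "a2"] <- 0.04
  m["a1", "a2"] <- m["a2", "a1"] <- 0.001
  expect_equal(between_group_distance(m, c("a1", "a2"), "b1", "mean"), 0.03)
  expect_equal(between_group_distance(m, c("a1", "a2"), "b1", "min"), 0.02)
  # singletons: both modes give the single pairwise distance
  expect_equal(between_group_distance(m, "a1", "b1", "mean"),
               between_group_distance(m, "a1", "b1", "min"))
  expect_error(between_group_distance(m, c("a1", "b1"), "b1"), "disjoint")
  set.seed(5)
  for (rep in 1:20) {
    mm <- random_dist(letters[1:6])
    expect_lte(between_group_distance(mm, c("a", "b", "c"),
                                      c("d", "e", "f"), "min"),
               between_group_distance(mm, c("a", "b", "c"),
                                      c("d", "e", "f"), "mean"))
  }
})

test_that("saturated pairs become NA with a warning, never clamped", {
  a <- paste(rep("A", 60), collapse = "")
  b <- paste(rep("C", 60), collapse = "")
  lib <- make_lib(c(a, b, a))
  expect_warning(m <- k2p_matrix(lib), "undefined")
  expect_true(is.na(m["spec01", "spec02"]))
  expect_equal(m["spec01", "spec03"], 0)
  expect_equal(attr(m, "n_saturated"), 2L)
})

test_that("distance matrices serialize as TSV and square PHYLIP", {
  set.seed(6)
  m <- random_dist(c("s1", "s2", "s3"))
  tsv <- tempfile(); phy <- tempfile()
  write_distance_matrix(m, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(as.matrix(back[, -1]), unname(m), ignore_attr = TRUE,
               tolerance = 1e-12)
  write_distance_matrix(m, phy, "phylip")
  lines <- readLines(phy)
  expect_equal(as.integer(lines[1]), 3L)
  expect_length(lines, 4L)
})
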