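test_that("species matrix aggregates specimen distances per mode", {
  set.seed(61)
  sim <- simulate_region(synth_config(n_genera = 3,
                                      specimens_per_species = 3, seed = 61))
  lib <- sim$library
  m <- k2p_matrix(lib)
  species_map <- setNames(lib$records$species, lib$records$specimen_id)
  for (mode in c("mean", "min")) {
    sm <- species_distance_matrix(m, species_map, mode)
    expect_true(isSymmetric(unname(sm)))
    expect_equal(unname(diag(sm)), rep(0, nrow(sm)))
    # oracle: direct aggregation over all cross-specimen pairs
    sp <- rownames(sm)
    for (i in seq_along(sp)[-1]) for (j in seq_len(i - 1L)) {
      ids_i <- names(species_map)[species_map == sp[i]]
      ids_j <- names(species_map)[species_map == sp[j]]
      cross <- m[ids_i, ids_j]
      expect_equal(sm[sp[i], sp[j]],
                   if (mode == "mean") mean(cross) else min(cross))
    }
  }
  # two species x 1 specimen: the species distance is the specimen distance
  lib2 <- make_lib(c(random_dna(300), random_dna(300)),
                   species = c("Aus aus", "Aus bus"))
  m2 <- suppressWarnings(k2p_matrix(lib2))
  sm2 <- species_distance_matrix(
    m2, setNames(lib2$records$species, lib2$records$specimen_id))
  expect_equal(sm2["Aus aus", "Aus bus"], m2[1, 2])
})

test_that("a two-species genus yields exactly its pair", {
  labs <- c("Aus aus", "Aus bus")
  sm <- fab_matrix(0.04, labs)
  gm <- setNames(c("Aus", "Aus"), labs)
  ps <- nearest_congener_pairs(sm, gm)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$distance, 0.04)
  expect_equal(ps$genus, "Aus")
})

test_that("mutual-nearest matching leaves the odd species out", {
  labs <- c("Aus a", "Aus b", "Aus c")
  sm <- fab_matrix(c(0.02, 0.05, 0.03), labs)  # d(a,b)=.02 d(a,c)=.05 d(b,c)=.03
  ps <- nearest_congener_pairs(sm, setNames(rep("Aus", 3), labs))
  expect_equal(nrow(ps), 1L)
  expect_setequal(c(ps$species_a, ps$species_b), c("Aus a", "Aus b"))
})

test_that("pair extraction equals the brute-force oracle", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    labs <- sprintf("G%d sp%02d", sample(1:3, n, replace = TRUE), 1:n)
    sm <- random_dist(labs)
    gm <- setNames(sub(" .*", "", labs), labs)
    got <- nearest_congener_pairs(sm, gm)
    want <- brute_mutual_pairs(sm, gm)
    key <- function(df) sort(paste(pmin(df$species_a, df$species_b),
                                   pmax(df$species_a, df$species_b)))
    expect_equal(key(got), key(want))
    expect_equal(sort(got$distance), sort(want$distance))
    # no species twice, ever
    expect_false(anyDuplicated(c(got$species_a, got$species_b)) > 0)
  }
})

test_that("pair extraction is invariant to label permutation", {
  set.seed(63)
  labs <- sprintf("G%d sp%02d", rep(1:3, each = 3), 1:9)
  sm <- random_dist(labs)
  gm <- setNames(sub(" .*", "", labs), labs)
  perm <- sample(labs)
  p1 <- nearest_congener_pairs(sm, gm)
  p2 <- nearest_congener_pairs(sm[perm, perm], gm)
  o1 <- order(p1$species_a); o2 <- order(p2$species_a)
  expect_equal(p1[o1, ], p2[o2, ], ignore_attr = TRUE)
})

test_that("excluded (highly variable) species never enter pairs", {
  labs <- c("Aus a", "Aus b", "Aus c")
  sm <- fab_matrix(c(0.02, 0.05, 0.03), labs)
  ps <- nearest_congener_pairs(sm, setNames(rep("Aus", 3), labs),
                               exclude = "Aus a")
  expect_equal(nrow(ps), 1L)
  expect_setequal(c(ps$species_a, ps$species_b), c("Aus b", "Aus c"))
  # genus reduced below two species contributes nothing
  ps2 <- nearest_congener_pairs(sm, setNames(rep("Aus", 3), labs),
                                exclude = c("Aus a", "Aus b"))
  expect_equal(nrow(ps2), 0L)
})

test_that("sister annotation is order-insensitive and warns on unknowns", {
  labs <- c("Aus a", "Aus b", "Bus a", "Bus b")
  sm <- fab_matrix(c(0.02, 0.1, 0.1, 0.1, 0.1, 0.03), labs)
  gm <- setNames(sub(" .*", "", labs), labs)
  ps <- nearest_congener_pairs(sm, gm)
  expect_equal(nrow(ps), 2L)
  expect_false(any(ps$is_sister))
  # empty list: nothing annotated
  ps0 <- annotate_sisters(ps, data.frame(a = character(), b = character()))
  expect_false(any(ps0$is_sister))
  # reversed order still matches
  ps1 <- annotate_sisters(ps, data.frame(a = "Aus b", b = "Aus a"))
  expect_equal(sum(ps1$is_sister), 1L)
  expect_true(ps1$is_sister[ps1$species_a == "Aus a"])
  expect_warning(annotate_sisters(ps, data.frame(a = "Cus x", b = "Cus y")),
                 "absent")
})

test_that("sister pair sets pull distances from the species matrix", {
  labs <- c("Aus a", "Aus b", "Bus a", "Bus b")
  sm <- fab_matrix(c(0.02, 0.1, 0.1, 0.1, 0.1, 0.03), labs)
  sl <- data.frame(a = c("Aus b", "Cus x"), b = c("Aus a", "Cus y"))
  expect_warning(ps <- sister_pairs(sm, sl), "absent")
  expect_equal(nrow(ps), 1L)
  expect_true(all(ps$is_sister))
  expect_equal(ps$distance, 0.02)
})

test_that("divergence summaries and recent proportions are exact", {
  ps <- structure(data.frame(species_a = c("a", "c", "e"),
                             species_b = c("b", "d", "f"),
                             distance = c(0.02, 0.04, 0.01),
                             is_sister = c(TRUE, FALSE, TRUE)),
                  class = c("pair_set", "data.frame"))
  s <- divergence_summary(ps)
  expect_equal(s$mean, mean(c(0.02, 0.04, 0.01)))
  expect_equal(s$n, 3L)
  s2 <- divergence_summary(structure(
    data.frame(distance = c(0.02, 0.04), is_sister = FALSE),
    class = c("pair_set", "data.frame")))
  expect_equal(s2$mean, 0.03)
  expect_equal(s2$sd, 0.01414214, tolerance = 1e-6)
  ss <- divergence_summary(ps, "sisters_only")
  expect_equal(ss$n, 2L)
  expect_equal(ss$mean, 0.015)

  pb <- proportion_below(structure(
    data.frame(distance = c(0.005, 0.02, 0.03), is_sister = FALSE),
    class = c("pair_set", "data.frame")), 0.01)
  expect_equal(pb$k, 1L); expect_equal(pb$proportion, 1 / 3)
  # exactly at the threshold is not "less than"
  pb2 <- proportion_below(structure(
    data.frame(distance = c(0.01, 0.02), is_sister = FALSE),
    class = c("pair_set", "data.frame")), 0.01)
  expect_equal(pb2$k, 0L)
})

test_that("sisters chosen among closest relatives diverge less on average", {
  set.seed(64)
  sim <- simulate_region(synth_config(n_genera = 40, seed = 64))
  lib <- sim$library
  m <- k2p_matrix(lib)
  sm <- species_distance_matrix(
    m, setNames(lib$records$species, lib$records$specimen_id))
  gm <- setNames(lib$records$genus, lib$records$species)
  gm <- gm[!duplicated(names(gm))]
  nb <- nearest_congener_pairs(sm, gm)
  truth <- sim$truth$pairs
  low <- truth[order(truth$d_ancestor), ][1:15, ]
  sis <- sister_pairs(sm, low[, c("species_a", "species_b")])
  expect_lte(divergence_summary(sis)$mean, divergence_summary(nb)$mean)
})
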