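#' Analyse one regional barcode library
#'
#' Runs the per-region stages of the diversification pipeline: ambiguity
#' filtering, the specimen-level K2P matrix, per-species intraspecific
#' profiles with deep-haplogroup detection, regional intraspecific averages
#' with and without highly variable species, the species-level matrix,
#' non-redundant nearest-congeneric-neighbour pairs (highly variable
#' species excluded), sister-pair annotation, divergence summaries,
#' recent-divergence proportions and clock-based epoch classification of the
#' sister pairs.
#'
#' @param lib A [region_library()].
#' @param variable_threshold Deep-divergence / highly-variable threshold
#'   (proportion), default `0.015`.
#' @param recent_threshold Recent-divergence threshold (proportion),
#'   default `0.01`.
#' @param mode Between-species aggregation, `"mean"` (default) or `"min"`.
#' @param max_ambiguous_fraction Quality filter threshold, default `0.01`.
#' @param sister_list Optional two-column data frame of sister species.
#' @param clock A [clock_model()] for age/epoch summaries.
#' @param tree Build the species-level NJ tree?  Default `TRUE`.
#' @return A list of class `region_report`; see [barcode_survey()].
#' @export
analyze_region <- function(lib, variable_threshold = 0.015,
                           recent_threshold = 0.01,
                           mode = c("mean", "min"),
                           max_ambiguous_fraction = 0.01,
                           sister_list = NULL, clock = clock_model(),
                           tree = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "region_library"))
  n_read <- nrow(lib$records)
  lib <- filter_ambiguous(lib, max_ambiguous_fraction)
  m <- k2p_matrix(lib)
  profiles <- species_profiles(lib, variable_threshold, dist = m)
  intra_all <- regional_intraspecific(profiles, exclude_variable = FALSE)
  intra_bg <- if (any(!profiles$highly_variable))
    regional_intraspecific(profiles, exclude_variable = TRUE) else NULL
  species_map <- stats::setNames(lib$records$species,
                                 lib$records$specimen_id)
  genus_map <- stats::setNames(lib$records$genus, lib$records$species)
  genus_map <- genus_map[!duplicated(names(genus_map))]
  sm <- species_distance_matrix(m, species_map, mode)
  neighbours <- nearest_congener_pairs(
    sm, genus_map, exclude = profiles$species[profiles$highly_variable])
  sisters <- NULL
  if (!is.null(sister_list) && nrow(as.data.frame(sister_list))) {
    neighbours <- annotate_sisters(neighbours, sister_list)
    sisters <- sister_pairs(sm, sister_list)
  }
  nb_sum <- if (nrow(neighbours)) divergence_summary(neighbours) else NULL
  nb_below <- if (nrow(neighbours))
    proportion_below(neighbours, recent_threshold) else NULL
  si_sum <- if (!is.null(sisters) && nrow(sisters))
    divergence_summary(sisters) else NULL
  si_below <- if (!is.null(sisters) && nrow(sisters))
    proportion_below(sisters, recent_threshold) else NULL
  epochs <- if (!is.null(sisters) && nrow(sisters))
    table(factor(epoch_classify(100 * sisters$distance, clock),
                 levels = clock$epoch_labels)) else NULL
  species_tree <- if (tree && nrow(sm) >= 3L) nj_tree(sm) else NULL
  structure(list(
    region = lib$region, library = lib, dist = m, species_dist = sm,
    profiles = profiles, intra_all = intra_all, intra_background = intra_bg,
    neighbours = neighbours, sisters = sisters,
    neighbour_summary = nb_sum, neighbour_below = nb_below,
    sister_summary = si_sum, sister_below = si_below,
    epochs = epochs, clock = clock, tree = species_tree,
    counts = list(
      specimens_read = n_read,
      specimens_filtered = n_read - nrow(lib$records),
      specimens_kept = nrow(lib$records),
      species_multi = nrow(profiles),
      species_singleton = attr(profiles, "n_singletons"),
      highly_variable = sum(profiles$highly_variable),
      neighbour_pairs = nrow(neighbours),
      sister_pairs = if (is.null(sisters)) 0L else nrow(sisters)),
    options = list(variable_threshold = variable_threshold,
                   recent_threshold = recent_threshold, mode = mode,
                   max_ambiguous_fraction = max_ambiguous_fraction)),
    class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("Region:", x$region, "\n")
  with(x$counts, cat(sprintf(
    "  %d specimens read, %d filtered; %d species with >= 2 specimens\n",
    specimens_read, specimens_filtered, species_multi)))
  print(x$intra_all)
  cat(sprintf("  highly variable species: %d of %d (%.1f%%)\n",
              x$counts$highly_variable, x$counts$species_multi,
              100 * x$counts$highly_variable /
                max(1L, x$counts$species_multi)))
  if (!is.null(x$neighbour_summary))
    cat(sprintf(
      "  nearest congeners: %.1f%% +/- %.1f%% (n = %d), %.1f%% below %g%%\n",
      100 * x$neighbour_summary$mean, 100 * x$neighbour_summary$sd,
      x$neighbour_summary$n, 100 * x$neighbour_below$proportion,
      100 * x$options$recent_threshold))
  if (!is.null(x$sister_summary))
    cat(sprintf(
      "  sister pairs: %.1f%% +/- %.1f%% (n = %d), %.1f%% below %g%%\n",
      100 * x$sister_summary$mean, 100 * x$sister_summary$sd,
      x$sister_summary$n, 100 * x$sister_below$proportion,
      100 * x$options$recent_threshold))
  invisible(x)
}

#' Cross-region comparison of diversification metrics
#'
#' Reproduces the between-region inference of the pipeline: one-way ANOVA
#' with Scheffé contrasts on nearest-congener (and sister) distances,
#' two-sample Kolmogorov–Smirnov comparisons of the divergence
#' distributions, and 2x2 chi-squares on the proportions of recently
#' diverged pairs and of highly variable species.  Every chi-square input
#' count equals the corresponding count in the per-region reports.
#'
#' @param reports List of two or more `region_report` objects.
#' @return Data frame with columns `test`, `metric`, `comparison`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_regions <- function(reports) {
  stopifnot(length(reports) >= 2L,
            all(vapply(reports, inherits, logical(1), "region_report")))
  regions <- vapply(reports, `[[`, character(1), "region")
  names(reports) <- regions
  out <- list()
  add <- function(test, metric, comparison, statistic, df, p)
    out[[length(out) + 1L]] <<- data.frame(
      test = test, metric = metric, comparison = comparison,
      statistic = statistic, df = df, p_value = p,
      stringsAsFactors = FALSE)
  pair_names <- utils::combn(regions, 2L, simplify = FALSE)

  for (metric in c("neighbours", "sisters")) {
    groups <- lapply(reports, function(r) {
      ps <- r[[metric]]
      if (is.null(ps) || !nrow(ps)) NULL else ps$distance
    })
    groups <- Filter(function(g) !is.null(g) && length(g) >= 2L, groups)
    if (length(groups) >= 2L) {
      an <- one_way_anova(groups)
      add("anova", metric, paste(names(groups), collapse = " | "),
          unname(an$statistic),
          paste(an$parameter, collapse = ","), an$p.value)
      for (pn in utils::combn(names(groups), 2L, simplify = FALSE)) {
        sc <- scheffe_contrast(groups, pn[1L], pn[2L])
        add("scheffe", metric, paste(pn, collapse = " vs "),
            unname(sc$statistic),
            paste(sc$parameter, collapse = ","), sc$p.value)
        ks <- ks_two_sample(groups[[pn[1L]]], groups[[pn[2L]]])
        add("ks", metric, paste(pn, collapse = " vs "),
            unname(ks$statistic["Z"]), "", ks$p.value)
      }
      # recently diverged proportions, strict < threshold
      below <- lapply(names(groups), function(rg) {
        r <- reports[[rg]]
        if (metric == "neighbours") r$neighbour_below else r$sister_below
      })
      names(below) <- names(groups)
      for (pn in utils::combn(names(groups), 2L, simplify = FALSE)) {
        b1 <- below[[pn[1L]]]; b2 <- below[[pn[2L]]]
        if (is.null(b1) || is.null(b2)) next
        ch <- chi2_2x2(b1$k, b1$n - b1$k, b2$k, b2$n - b2$k)
        add("chi2", paste0(metric, "_below_threshold"),
            paste(pn, collapse = " vs "), unname(ch$statistic),
            "1", ch$p.value)
      }
    }
  }
  for (pn in pair_names) {
    r1 <- reports[[pn[1L]]]; r2 <- reports[[pn[2L]]]
    k1 <- r1$counts$highly_variable; n1 <- r1$counts$species_multi
    k2 <- r2$counts$highly_variable; n2 <- r2$counts$species_multi
    if (min(k1 + k2, (n1 - k1) + (n2 - k2)) > 0L) {
      ch <- chi2_2x2(k1, n1 - k1, k2, n2 - k2)
      add("chi2", "highly_variable_species",
          paste(pn, collapse = " vs "), unname(ch$statistic), "1",
          ch$p.value)
    }
  }
  do.call(rbind, out)
}

#' Run the full multi-region diversification survey
#'
#' The package's main entry point: analyses each regional library with
#' [analyze_region()] and compares the regions with [compare_regions()].
#'
#' @param libraries A [region_library()] or list of them (names default to
#'   their region labels).
#' @param sister_lists Optional named list (by region) of two-column sister
#'   data frames, or a single data frame applied to every region.
#' @param ... Options passed to [analyze_region()] (thresholds, `mode`,
#'   `clock`, `tree`).
#' @return An object of class `barcode_survey`: list with `reports` (one
#'   `region_report` per region) and `tests` (the cross-region table).
#' @seealso [write_report()] to export the tables, [simulate_region()] to
#'   generate input with known truth.
#' @export
barcode_survey <- function(libraries, sister_lists = NULL, ...) {
  if (inherits(libraries, "region_library")) libraries <- list(libraries)
  stopifnot(length(libraries) >= 1L,
            all(vapply(libraries, inherits, logical(1), "region_library")))
  regions <- vapply(libraries, `[[`, character(1), "region")
  reports <- lapply(seq_along(libraries), function(i) {
    sl <- if (is.data.frame(sister_lists)) sister_lists
          else sister_lists[[regions[i]]]
    analyze_region(libraries[[i]], sister_list = sl, ...)
  })
  names(reports) <- regions
  tests <- if (length(reports) >= 2L) compare_regions(reports) else NULL
  structure(list(reports = reports, tests = tests),
            class = "barcode_survey")
}

#' @export
print.barcode_survey <- function(x, ...) {
  cat("Barcode diversification survey:", length(x$reports), "region(s)\n\n")
  for (r in x$reports) { print(r); cat("\n") }
  if (!is.null(x$tests))
    cat("Cross-region tests:", nrow(x$tests),
        "(see summary() for the table)\n")
  invisible(x)
}

#' @export
summary.barcode_survey <- function(object, ...) {
  print(object)
  if (!is.null(object$tests)) {
    tt <- object$tests
    tt$statistic <- round(tt$statistic, 3)
    tt$p_value <- signif(tt$p_value, 3)
    print(tt, row.names = FALSE)
  }
  invisible(object)
}

#' Histogram of pair divergences per region
#'
#' @param x A `barcode_survey`.
#' @param metric `"neighbours"` or `"sisters"`.
#' @param breaks Histogram breaks in percent.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.barcode_survey <- function(x, metric = c("neighbours", "sisters"),
                                breaks = seq(0, 30, by = 1), ...) {
  metric <- match.arg(metric)
  keep <- Filter(function(r) !is.null(r[[metric]]) && nrow(r[[metric]]),
                 x$reports)
  if (!length(keep)) stop("no pairs to plot")
  old <- graphics::par(mfrow = c(length(keep), 1L))
  on.exit(graphics::par(old))
  for (r in keep) {
    d <- 100 * r[[metric]]$distance
    graphics::hist(d, breaks = breaks, main = r$region,
                   xlab = "K2P distance (%)", col = "grey80", ...)
  }
  invisible(x)
}

#' Write the survey's tables to a directory
#'
#' Emits, per region, the species table (family, species, maximum
#' intraspecific distance in percent), the full species profiles, the pair
#' tables and the intraspecific summaries, plus the cross-region test
#' table — all as UTF-8 TSV at full precision (human-readable rounding is
#' left to the print methods).
#'
#' @param survey A `barcode_survey`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(survey, dir) {
  stopifnot(inherits(survey, "barcode_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (r in survey$reports) {
    slug <- gsub("[^A-Za-z0-9]+", "_", r$region)
    vt <- r$profiles[r$profiles$highly_variable,
                     c("family", "species", "max_intra")]
    vt$max_intra_pct <- 100 * vt$max_intra
    wt(vt[order(vt$family, vt$species),
          c("family", "species", "max_intra_pct")],
       paste0(slug, "_variable_species.tsv"))
    wt(as.data.frame(r$profiles), paste0(slug, "_species_profiles.tsv"))
    wt(as.data.frame(r$neighbours), paste0(slug, "_neighbour_pairs.tsv"))
    if (!is.null(r$sisters))
      wt(as.data.frame(r$sisters), paste0(slug, "_sister_pairs.tsv"))
    intra <- data.frame(
      region = r$region,
      excluded_variable = c(FALSE, TRUE),
      mean_of_species_means = c(r$intra_all$mean_of_species_means,
        if (is.null(r$intra_background)) NA else
          r$intra_background$mean_of_species_means),
      sd = c(r$intra_all$sd,
        if (is.null(r$intra_background)) NA else r$intra_background$sd),
      n_species = c(r$intra_all$n_species,
        if (is.null(r$intra_background)) NA else
          r$intra_background$n_species))
    wt(intra, paste0(slug, "_intraspecific.tsv"))
    if (!is.null(r$tree))
      write_newick(r$tree, file.path(dir, paste0(slug, "_species_nj.nwk")))
  }
  if (!is.null(survey$tests)) wt(survey$tests, "cross_region_tests.tsv")
  invisible(dir)
}
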