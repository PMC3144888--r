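# All four tests return a classed "htest" so base R printing applies.
.div_test <- function(statistic, parameter, p.value, method, data.name, n) {
  structure(list(statistic = statistic, parameter = parameter,
                 p.value = p.value, method = method,
                 data.name = data.name, n = n),
            class = c("div_test", "htest"))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from the sums of squares:
#' \eqn{F = MS_{between} / MS_{within}} on \eqn{(k-1, N-k)} degrees of
#' freedom.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups
#'   of >= 2 values each).
#' @return An `htest`-style result with `statistic` (F), `parameter`
#'   (df pair) and `p.value`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  k <- length(groups)
  N <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) stop("zero within-group variance in every group")
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- msb / msw
  .div_test(c(F = f), c(df1 = k - 1L, df2 = N - k),
            stats::pf(f, k - 1, N - k, lower.tail = FALSE),
            "One-way ANOVA", deparse(substitute(groups)),
            lengths(groups))
}

#' Scheffé post-hoc contrast between two groups
#'
#' Conservative pairwise contrast following a one-way ANOVA:
#' \eqn{F_{ij} = (\bar x_i - \bar x_j)^2 / \{MS_{within}(1/n_i + 1/n_j)\}}
#' referred to \eqn{(k-1)\,F_{k-1,\,N-k}}, i.e.
#' \eqn{p = P\{F_{k-1,N-k} \ge F_{ij}/(k-1)\}}.  Always at least as large a
#' p-value as the unadjusted pairwise F test on the same data.
#'
#' @param groups Named list of numeric vectors (all groups, as for
#'   [one_way_anova()]; the pooled within-group variance uses them all).
#' @param i,j Indices (or names) of the two groups contrasted.
#' @return An `htest`-style result; `statistic` is the contrast F.
#' @export
scheffe_contrast <- function(groups, i, j) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  if (identical(i, j)) stop("i and j must differ")
  k <- length(groups)
  N <- sum(lengths(groups))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) stop("zero within-group variance in every group")
  msw <- ssw / (N - k)
  xi <- groups[[i]]; xj <- groups[[j]]
  f_ij <- (mean(xi) - mean(xj))^2 /
    (msw * (1 / length(xi) + 1 / length(xj)))
  .div_test(c(F = f_ij), c(df1 = k - 1L, df2 = N - k),
            stats::pf(f_ij / (k - 1), k - 1, N - k, lower.tail = FALSE),
            "Scheffe contrast", paste(i, "vs", j),
            c(length(xi), length(xj)))
}

#' Two-sample Kolmogorov–Smirnov test (asymptotic Z)
#'
#' \eqn{D = \sup_t |F_x(t) - F_y(t)|} over the empirical distribution
#' functions, with the scaled statistic
#' \eqn{Z = D \sqrt{n_x n_y / (n_x + n_y)}} and the asymptotic Kolmogorov
#' p-value \eqn{p = 2\sum_{j\ge1} (-1)^{j-1} e^{-2j^2Z^2}} (clamped to
#' [0, 1]) — the "Z" convention common in statistics packages.
#'
#' @param x,y Non-empty numeric samples.
#' @return An `htest`-style result; `statistic` carries both `D` and `Z`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  w <- sort(unique(c(x, y)))
  d <- max(abs(vapply(w, function(t) mean(x <= t) - mean(y <= t),
                      numeric(1))))
  z <- d * sqrt(length(x) * length(y) / (length(x) + length(y)))
  if (z < 1e-8) {
    p <- 1
  } else {
    j <- seq_len(100L)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * z^2))
    p <- min(max(p, 0), 1)
  }
  .div_test(c(D = d, Z = z), NULL, p,
            "Two-sample Kolmogorov-Smirnov test (asymptotic)",
            paste(deparse(substitute(x)), "vs", deparse(substitute(y))),
            c(length(x), length(y)))
}

#' 2x2 chi-square test of equal proportions
#'
#' Pearson chi-square for a 2x2 table without continuity correction:
#' \eqn{\chi^2 = N(ad - bc)^2 / \{(a+b)(c+d)(a+c)(b+d)\}} on 1 degree of
#' freedom.  Counts are (success, failure) for each of two groups, so
#' comparing 21 variable species of 389 against 21 of 528 is
#' `chi2_2x2(21, 368, 21, 507)`.
#'
#' @param a,b Successes and failures in group 1.
#' @param c,d Successes and failures in group 2.
#' @return An `htest`-style result with `statistic`, `parameter` (df = 1)
#'   and `p.value`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table")
  chi2 <- N * (a * d - b * c)^2 / prod(margins)
  .div_test(c(`X-squared` = chi2), c(df = 1L),
            stats::pchisq(chi2, 1, lower.tail = FALSE),
            "2x2 chi-square test (no continuity correction)",
            sprintf("%d/%d vs %d/%d", a, a + b, c, c + d),
            c(a + b, c + d))
}
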