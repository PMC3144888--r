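test_that("one-way ANOVA matches hand computation and base R", {
  # identical groups: no between-group variance
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- one_way_anova(g)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  # SSb = 2*1.5^2*... hand sums: means 2 and 5, grand 3.5;
  # SSb = 3*(1.5^2)+3*(1.5^2) = 13.5; SSw = 2+2 = 4; F = 13.5/(4/4) = ...
  r2 <- one_way_anova(list(x = c(1, 2, 3), y = c(4, 5, 6)))
  expect_equal(unname(r2$statistic), 13.5)
  expect_equal(unname(r2$parameter), c(1, 4))
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group")
  # reference oracle on random data
  set.seed(71)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:9, 1), mean = i))
    names(groups) <- paste0("g", seq_len(k))
    fit <- anova(lm(y ~ g, data.frame(
      y = unlist(groups),
      g = rep(names(groups), lengths(groups)))))
    mine <- one_way_anova(groups)
    expect_equal(unname(mine$statistic), fit$`F value`[1], tolerance = 1e-8)
    expect_equal(mine$p.value, fit$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("Scheffe contrasts are conservative pairwise comparisons", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(scheffe_contrast(g, "a", "b")$p.value, 1)
  tiny <- list(a = c(0, 0.001, -0.001), b = c(0, 0.001, -0.001),
               c = c(10, 10.001, 9.999))
  expect_lt(scheffe_contrast(tiny, "a", "c")$p.value, 1e-6)
  expect_error(scheffe_contrast(g, "a", "a"), "differ")
  # conservativeness: p >= unadjusted pairwise F on the same MSw
  set.seed(72)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(6, mean = i / 2))
    names(groups) <- c("a", "b", "c")
    sc <- scheffe_contrast(groups, "a", "c")
    k <- 3; N <- 18
    p_unadj <- pf(unname(sc$statistic), 1, N - k, lower.tail = FALSE)
    expect_gte(sc$p.value, p_unadj - 1e-12)
  }
})

test_that("KS statistic matches brute force and the asymptotic Z p-value", {
  r0 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r0$statistic["D"]), 0)
  expect_equal(r0$p.value, 1)
  r1 <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r1$statistic["D"]), 1)
  expect_equal(unname(r1$statistic["Z"]), sqrt(1.5))
  set.seed(73)
  # p-value oracle: the Kolmogorov law evaluated through its Jacobi theta
  # representation, an independent expansion of the same distribution
  kolmogorov_theta <- function(z) {
    k <- 1:50
    min(1, max(0, 1 - sqrt(2 * pi) / z *
                 sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * z^2)))))
  }
  for (rep in 1:50) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    mine <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(unname(mine$statistic["D"]), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p.value,
                 kolmogorov_theta(unname(mine$statistic["Z"])),
                 tolerance = 1e-8)
    # base R's psmirnov adds a finite-sample refinement on top of the
    # asymptotic law; the two agree closely but not to machine precision
    expect_equal(mine$p.value, ref$p.value, tolerance = 5e-4)
  }
})

test_that("2x2 chi-square matches base R and is symmetric", {
  set.seed(74)
  for (rep in 1:40) {
    t <- sample(1:60, 4)
    mine <- chi2_2x2(t[1], t[2], t[3], t[4])
    ref <- suppressWarnings(chisq.test(matrix(t, 2, byrow = TRUE),
                                       correct = FALSE))
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    # swap the two groups / swap the success and failure columns
    expect_equal(unname(chi2_2x2(t[3], t[4], t[1], t[2])$statistic),
                 unname(mine$statistic))
    expect_equal(unname(chi2_2x2(t[2], t[1], t[4], t[3])$statistic),
                 unname(mine$statistic))
  }
  expect_equal(unname(chi2_2x2(10, 10, 10, 10)$statistic), 0)
  expect_error(chi2_2x2(0, 0, 3, 4), "degenerate")
})

test_that("chi-square rejects at the nominal rate under the null", {
  set.seed(75)
  reps <- 2000
  k1 <- rbinom(reps, 400, 0.1)
  k2 <- rbinom(reps, 400, 0.1)
  p <- vapply(seq_len(reps), function(i)
    chi2_2x2(k1[i], 400 - k1[i], k2[i], 400 - k2[i])$p.value, numeric(1))
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * se + 0.005)
})
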