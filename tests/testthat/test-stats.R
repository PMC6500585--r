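test_that("Sturges width follows R / (1 + 3.322 log10 N)", {
  expect_equal(sturges_width(0, 100), 0)
  expect_equal(sturges_width(118 - 15, 594), 10.08, tolerance = 1e-3)
  expect_equal(sturges_width(220 - 20, 893), 18.51, tolerance = 1e-3)
  expect_error(sturges_width(10, 0), "n_items")
})

test_that("volume classes reproduce the printed 25 um^3 class limits", {
  b <- bin_classes(c(30, 80, 220, 45), width = 25, anchor = 20)
  expect_equal(nrow(b$classes), 8L)
  expect_equal(b$assignment, c(1L, 3L, 8L, 2L))   # 30->I, 80->III, 45->II
  expect_equal(b$classes$lower[1], 20)
  expect_equal(b$classes$upper[1], 45)
  expect_equal(b$classes$lower[3], 70)            # class III: 70-95
  # values below the anchor fold into class I
  expect_equal(bin_classes(c(15, 30), 25, 20)$assignment, c(1L, 1L))
})

test_that("classing partitions every value into exactly one class", {
  set.seed(41)
  v <- rlnorm(500, log(55), 0.5)
  b <- bin_classes(v)
  expect_equal(sum(b$classes$n), 500L)
  expect_true(all(b$assignment >= 1 & b$assignment <= nrow(b$classes)))
  k <- b$assignment
  below_ok <- v >= b$classes$lower[k] | k == 1L          # class I folds
  above_ok <- v < b$classes$upper[k] | k == nrow(b$classes)
  expect_true(all(below_ok & above_ok))
})

test_that("putative ploidy doubles with each class", {
  expect_equal(class_to_ploidy(1:4), c("2C", "4C", "8C", "16C"))
  expect_equal(class_to_ploidy(8), "256C")
  p <- as.numeric(sub("C", "", class_to_ploidy(1:8)))
  expect_equal(p[-1] / p[-8], rep(2, 7))
})

test_that("median test is exact for small samples and sane for identical ones", {
  mt <- median_test(1:4, 5:8)
  expect_equal(unname(mt$table), rbind(c(0, 4), c(4, 0)))
  expect_equal(mt$p_value, 2 / 70, tolerance = 1e-10)
  same <- median_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)
  expect_warning(median_test(rep(5, 4), rep(5, 4)), "degenerate")
})

test_that("median test agrees with hypergeometric enumeration (n <= 12)", {
  set.seed(43)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- runif(na); b <- runif(nb) + runif(1, -0.5, 0.5)
    mt <- median_test(a, b)
    expect_equal(mt$p_value, median_exact_oracle(mt$table), tolerance = 1e-9)
  }
})

test_that("median test holds its type-I error near 0.05", {
  set.seed(47)
  rej <- mean(replicate(400, {
    a <- rlnorm(500, log(40), 0.5); b <- rlnorm(500, log(40), 0.5)
    suppressWarnings(median_test(a, b)$p_value) < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("distribution fitting selects the generating family", {
  x <- sample_population("lognormal", list(meanlog = 3.7, sdlog = 0.4), 2000,
                         seed = 53)
  f <- fit_size_distribution(x)
  expect_equal(f$family, "lognormal")
  expect_lt(abs(f$params$sdlog - 0.4), 0.05)
  expect_lt(f$aic["lognormal"], f$aic["gamma"])
  g <- fit_size_distribution(sample_population("gamma",
                                               list(shape = 9, scale = 5),
                                               2000, seed = 59))
  expect_equal(g$family, "gamma")
  expect_error(fit_size_distribution(rlnorm(5)), "at least 10")
  expect_error(fit_size_distribution(c(rep(1, 20), -1)), "positive")
})

test_that("bootstrap moments recover the lognormal shape and are seeded", {
  x <- sample_population("lognormal", list(meanlog = log(40), sdlog = 0.5),
                         2000, seed = 61)
  bm <- bootstrap_moments(x, iterations = 400, seed = 67)
  agg <- bm$aggregate
  expect_lt(abs(agg$mean[agg$moment == "skewness"] -
                  lognormal_skewness(0.5)), 0.15)
  # consistency: aggregate mean-of-means within 2 bootstrap sd of the truth
  true_mean <- 40 * exp(0.5^2 / 2)
  expect_lt(abs(agg$mean[agg$moment == "mean"] - true_mean),
            2 * agg$sd[agg$moment == "mean"] + 0.02 * true_mean)
  bm2 <- bootstrap_moments(x, iterations = 400, seed = 67)
  expect_identical(bm$aggregate, bm2$aggregate)
  expect_error(bootstrap_moments(rep(10, 50), iterations = 50, seed = 1),
               "degenerated")
  expect_error(bootstrap_moments(c(-1, 2, 3)), "positive")
})

test_that("moment comparison finds no effect for identical groups", {
  set.seed(71)
  x <- rlnorm(30, 0, 0.3)
  cm <- compare_moments(list(g1 = x, g2 = x), "skewness")
  expect_lt(abs(diff(cm$group_means)), 1e-10)
  expect_error(compare_moments(list(a = 1:5)), "2 groups")
  expect_error(compare_moments(list(a = 1:5, b = 2)), "at least 2 summaries")
})

test_that("moment comparison controls false positives under the null", {
  set.seed(73)
  fp <- mean(replicate(100, {
    g1 <- replicate(10, e1071::skewness(rlnorm(200, 0, 0.5), type = 2))
    g2 <- replicate(10, e1071::skewness(rlnorm(200, 0, 0.5), type = 2))
    any(suppressWarnings(
      compare_moments(list(a = g1, b = g2), "skewness"))$pairwise$p_adj < 0.05)
  }))
  expect_lte(fp, 0.10)
})

test_that("moment comparison detects a real skewness difference", {
  set.seed(79)
  hits <- mean(replicate(20, {
    g1 <- replicate(30, e1071::skewness(rlnorm(500, 0, 0.3), type = 2))
    g2 <- replicate(30, e1071::skewness(rlnorm(500, 0, 0.8), type = 2))
    suppressWarnings(
      compare_moments(list(a = g1, b = g2), "skewness"))$pairwise$p_adj < 0.05
  }))
  expect_gte(hits, 0.9)
})

test_that("Kruskal-Wallis + Dunn handles ties, toys and transformations", {
  tied <- kruskal_dunn(list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)))
  expect_equal(tied$H, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_dunn(list(a = 1:3)), "2 groups")
  expect_error(kruskal_dunn(list(a = 1:3, b = numeric())), "non-empty")

  toy <- kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(toy$H, 7.2, tolerance = 1e-10)
  expect_equal(toy$H, kw_h_oracle(1:9, rep(letters[1:3], each = 3)))
  expect_true(all(toy$pairwise$p_adjusted <= 1))

  # rank-based: monotone transforms change nothing
  g <- list(a = rlnorm(20, 0, 1), b = rlnorm(20, 0.5, 1), c = rlnorm(20, 1, 1))
  kd1 <- kruskal_dunn(g)
  kd2 <- kruskal_dunn(lapply(g, exp))
  expect_equal(kd1$H, kd2$H)
  expect_equal(kd1$pairwise$p_adjusted, kd2$pairwise$p_adjusted)
})

test_that("Kruskal-Wallis matches exhaustive permutation on the 3x3 toy", {
  vals <- 1:9
  toy_h <- kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))$H
  combos_ab <- combn(9, 3)
  h_all <- numeric(0)
  grp <- character(9)
  for (c1 in seq_len(ncol(combos_ab))) {
    ga <- combos_ab[, c1]
    restv <- setdiff(1:9, ga)
    combos_b <- combn(restv, 3)
    for (c2 in seq_len(ncol(combos_b))) {
      gb <- combos_b[, c2]
      grp[] <- "c"; grp[ga] <- "a"; grp[gb] <- "b"
      h_all <- c(h_all, kw_h_oracle(vals, grp))
    }
  }
  expect_length(h_all, 1680L)
  p_perm <- mean(h_all >= toy_h - 1e-12)
  expect_equal(p_perm, 6 / 1680, tolerance = 1e-12)
  # the chi-square approximation and the exact permutation agree on the call
  expect_lt(kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))$p_value, 0.05)
  expect_lt(p_perm, 0.05)
})

test_that("a shifted group is detected and attributed by Dunn's test", {
  set.seed(83)
  hits <- replicate(20, {
    g <- list(a = rlnorm(50, log(40), 0.4), b = rlnorm(50, log(40), 0.4),
              c = rlnorm(50, log(60), 0.4))
    kd <- kruskal_dunn(g)
    sig_pairs <- kd$pairwise[kd$pairwise$p_adjusted < 0.05, ]
    kd$p_value < 0.05 && all(grepl("c", paste(sig_pairs$group1,
                                              sig_pairs$group2)))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("case-study summaries aggregate, test and letter the groups", {
  single <- summarize_case_study(
    data.frame(volume_um3 = rlnorm(20, log(40), 0.3),
               treatment = "uninoculated"), "treatment")
  expect_null(single$test)
  expect_equal(single$summary$letters, "a")
  expect_error(summarize_case_study(data.frame(volume_um3 = 1),
                                    "nonexistent"), "unknown")

  # planted 1.25-fold mean shift is recovered within 5%
  set.seed(89)
  m <- log(40.3)
  tbl <- data.frame(
    volume_um3 = c(rlnorm(500, m, 0.5), rlnorm(500, m + log(1.258), 0.5)),
    treatment = rep(c("uninoculated", "mycorrhizal"), each = 500))
  sc <- summarize_case_study(tbl, "treatment")
  ratio <- sc$summary$mean[sc$summary$group == "mycorrhizal"] /
    sc$summary$mean[sc$summary$group == "uninoculated"]
  expect_lt(abs(ratio - 1.258) / 1.258, 0.05)
  expect_lt(sc$test$p_value, 0.05)
  expect_false(sc$summary$letters[1] == sc$summary$letters[2])

  # permuted labels: rarely any significant pair
  set.seed(97)
  fp <- mean(replicate(20, {
    perm <- tbl
    perm$treatment <- sample(perm$treatment)
    any(summarize_case_study(perm, "treatment")$test$pairwise$p_adjusted <
          0.05)
  }))
  expect_lte(fp, 0.10)
})

test_that("moment summaries flag undefined shape statistics", {
  ms <- moment_summary(rep(3, 10))
  expect_true(is.na(ms$skewness) && is.na(ms$kurtosis))
  x <- rlnorm(5000, 0, 0.5)
  ms2 <- moment_summary(x)
  expect_equal(ms2$cv, sd(x) / mean(x))
  expect_equal(ms2$kurtosis, e1071::kurtosis(x, type = 2))
})
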