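#' Two-sample median test
#'
#' Mood's test: pool both samples, split at the grand median, and test the
#' resulting 2x2 above/not-above table -- exactly (hypergeometric, via
#' Fisher's test) when the pooled size is at most 200, otherwise chi-square
#' with continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max pooled-size cutoff for the exact branch.
#' @return List: `statistic` (chi-square, `NA` on the exact branch),
#'   `p_value`, `table` (2x2 counts), `method`.
#' @export
median_test <- function(a, b, exact_max = 200L) {
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- c(a, b)
  gm <- median(pooled)
  above <- c(sum(a > gm), sum(b > gm))
  not_above <- c(length(a), length(b)) - above
  tab <- rbind(above = above, not_above = not_above)
  colnames(tab) <- c("a", "b")
  if (sum(above) == 0 || sum(not_above) == 0) {
    warning("degenerate median split (ties at the grand median); p = 1")
    return(list(statistic = 0, p_value = 1, table = tab,
                method = "degenerate"))
  }
  if (length(pooled) <= exact_max) {
    p <- fisher.test(tab)$p.value
    list(statistic = NA_real_, p_value = p, table = tab, method = "exact")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab,
         method = "chi-square")
  }
}

#' Fit and compare lognormal and gamma size distributions
#'
#' Maximum-likelihood fits of both candidate families with Anderson-Darling
#' statistics and AIC for each; the family with the lower AIC is selected.
#'
#' @param values positive numeric vector, n >= 10.
#' @return List: `family` (selected), `params` (of the selected fit), `aic`
#'   and `ad` (named vectors over both families), `fits` (the two `fitdist`
#'   objects).
#' @export
fit_size_distribution <- function(values) {
  if (length(values) < 10) stop("need at least 10 values to fit")
  if (any(values <= 0)) stop("size values must be positive")
  f_ln <- fitdistrplus::fitdist(values, "lnorm")
  f_ga <- fitdistrplus::fitdist(values, "gamma")
  g_ln <- fitdistrplus::gofstat(f_ln)
  g_ga <- fitdistrplus::gofstat(f_ga)
  aic <- c(lognormal = f_ln$aic, gamma = f_ga$aic)
  ad <- c(lognormal = unname(g_ln$ad), gamma = unname(g_ga$ad))
  sel <- if (aic["lognormal"] <= aic["gamma"]) "lognormal" else "gamma"
  list(family = sel,
       params = as.list(if (sel == "lognormal") f_ln$estimate else f_ga$estimate),
       aic = aic, ad = ad, fits = list(lognormal = f_ln, gamma = f_ga))
}

#' Bootstrap refit-and-regenerate moment statistics
#'
#' Homogenises sample sizes before moment comparison: per iteration, resample
#' `resample_n` values with replacement, fit a lognormal by maximum
#' likelihood (closed form), draw `regen_n` fresh points from the fitted
#' density, and record that synthetic sample's moment statistics. Iterations
#' whose fit degenerates are skipped and counted; more than 5% skipped is an
#' error.
#'
#' @param values positive numeric vector.
#' @param iterations bootstrap iterations (default 1000).
#' @param resample_n resample size per iteration (default 500).
#' @param regen_n regenerated points per iteration (default 500).
#' @param seed integer seed; fixes the full procedure.
#' @return List: `iterations` (data.frame of per-iteration moment summaries),
#'   `aggregate` (mean and sd per moment across iterations), `n_skipped`,
#'   `seed`.
#' @export
bootstrap_moments <- function(values, iterations = 1000L, resample_n = 500L,
                              regen_n = 500L, seed = 1L) {
  stopifnot(length(values) > 0)
  if (any(values <= 0)) stop("values must be positive (sizes)")
  with_seed(seed, {
    rows <- vector("list", iterations)
    skipped <- 0L
    for (it in seq_len(iterations)) {
      res <- values[sample.int(length(values), resample_n, replace = TRUE)]
      lx <- log(res)
      mu <- mean(lx)
      sig <- sqrt(mean((lx - mu)^2))   # lognormal MLE of sdlog
      if (!is.finite(sig) || sig < 1e-10) { skipped <- skipped + 1L; next }
      regen <- rlnorm(regen_n, meanlog = mu, sdlog = sig)
      rows[[it]] <- cbind(iteration = it, moment_summary(regen))
    }
    if (skipped > 0.05 * iterations)
      stop(sprintf("lognormal refit degenerated in %d/%d iterations",
                   skipped, iterations))
    iters <- do.call(rbind, rows)
    moms <- c("mean", "sd", "cv", "skewness", "kurtosis")
    aggregate <- data.frame(
      moment = moms,
      mean = vapply(moms, function(m) mean(iters[[m]]), 0),
      sd = vapply(moms, function(m) sd(iters[[m]]), 0),
      row.names = NULL)
    list(iterations = iters, aggregate = aggregate, n_skipped = skipped,
         seed = seed)
  })
}

#' Compare a moment statistic between groups (linear model + Tukey)
#'
#' Each group's values are per-iteration (or per-sample) moment statistics.
#' Every group is screened with Shapiro-Wilk; if any fails at alpha = 0.05
#' and all values are non-negative, the response is square-root transformed.
#' A Gaussian linear model with the group factor is then fitted and all
#' pairwise contrasts are tested with Tukey's family-wise adjustment.
#'
#' @param summaries_by_group named list of numeric vectors (>= 2 groups, each
#'   >= 2 values).
#' @param moment label recorded in the output (`"skewness"` or `"kurtosis"`).
#' @return List: `moment`, `transformed` (logical), `group_means` (on the
#'   analysis scale), `anova_p`, `pairwise` (data.frame pair, diff, p_adj).
#' @export
compare_moments <- function(summaries_by_group,
                            moment = c("skewness", "kurtosis")) {
  moment <- match.arg(moment)
  if (length(summaries_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(summaries_by_group, length, 0L) < 2))
    stop("every group needs at least 2 summaries")
  sw_fail <- vapply(summaries_by_group, function(v) {
    if (length(v) < 3 || length(unique(v)) < 3 || length(v) > 5000) return(FALSE)
    shapiro.test(v)$p.value < 0.05
  }, logical(1))
  y <- unlist(summaries_by_group, use.names = FALSE)
  transformed <- FALSE
  if (any(sw_fail)) {
    if (all(y >= 0)) {
      y <- sqrt(y)
      transformed <- TRUE
    } else {
      warning("non-normal groups but negative values: no transform applied")
    }
  }
  grp <- factor(rep(names(summaries_by_group),
                    vapply(summaries_by_group, length, 0L)),
                levels = names(summaries_by_group))
  fit <- aov(y ~ grp)
  tuk <- TukeyHSD(fit)$grp
  pairwise <- data.frame(pair = rownames(tuk), diff = tuk[, "diff"],
                         p_adj = tuk[, "p adj"], row.names = NULL)
  list(moment = moment, transformed = transformed,
       group_means = tapply(y, grp, mean),
       anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       pairwise = pairwise)
}

#' Kruskal-Wallis test with Dunn's Bonferroni-corrected post-hoc
#'
#' Rank-based omnibus H test across groups; for each pair, Dunn's z statistic
#' on mean ranks with the tie correction, the two-sided p multiplied by the
#' number of pairs (capped at 1).
#'
#' @param groups named list of non-empty numeric vectors (>= 2 groups).
#' @return List: `H`, `p_value`, `pairwise` (data.frame group1, group2, z,
#'   p_unadjusted, p_adjusted).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  if (length(unique(x)) == 1L) {
    kw_h <- 0; kw_p <- 1   # maximally tied data carry no rank information
  } else {
    kw <- kruskal.test(x, g)
    kw_h <- unname(kw$statistic); kw_p <- kw$p.value
  }
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  npairs <- ncol(pairs)
  pw <- lapply(seq_len(npairs), function(p) {
    g1 <- pairs[1, p]; g2 <- pairs[2, p]
    se2 <- (n * (n + 1) / 12 - tie_corr) * (1 / sizes[[g1]] + 1 / sizes[[g2]])
    z <- if (se2 > 0) (mean_rank[[g1]] - mean_rank[[g2]]) / sqrt(se2) else 0
    p_un <- 2 * pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_unadjusted = p_un,
               p_adjusted = min(1, p_un * npairs))
  })
  list(H = kw_h, p_value = kw_p, pairwise = do.call(rbind, pw))
}

# compact letter display: groups that are NOT significantly different share a
# letter (greedy insert-absorb; adequate for the handful of groups used here)
compact_letters <- function(group_names, pairwise, alpha = 0.05) {
  sig <- matrix(FALSE, length(group_names), length(group_names),
                dimnames = list(group_names, group_names))
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$p_adjusted[r] < alpha) {
      sig[pairwise$group1[r], pairwise$group2[r]] <- TRUE
      sig[pairwise$group2[r], pairwise$group1[r]] <- TRUE
    }
  }
  sets <- list()
  for (gname in group_names) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(sig[gname, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], gname)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- gname
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  sets <- sets[keep]
  vapply(group_names, function(gname)
    paste(letters[which(vapply(sets, function(s) gname %in% s, logical(1)))],
          collapse = ""), "")
}

#' Per-group summary with nonparametric group comparison
#'
#' Aggregates a measurement table by the requested grouping fields (n, mean,
#' sd, median, quartiles per group) and, when more than one group is present,
#' runs [kruskal_dunn()] and derives compact-letter-display labels: groups
#' sharing a letter are not significantly different at alpha = 0.05.
#'
#' @param table data.frame of per-nucleus measurements (long format).
#' @param grouping character vector of column names to group by.
#' @param value column holding the measurement (default `"volume_um3"`).
#' @return List: `summary` (one row per group, with `letters`), `test` (the
#'   [kruskal_dunn()] result, or `NULL` for a single group).
#' @export
summarize_case_study <- function(table, grouping, value = "volume_um3") {
  missing_cols <- setdiff(c(grouping, value), names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  key <- interaction(table[grouping], sep = ":", drop = TRUE)
  vals <- split(table[[value]], key)
  summ <- data.frame(
    group = names(vals),
    n = vapply(vals, length, 0L),
    mean = vapply(vals, mean, 0),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_, 0),
    median = vapply(vals, median, 0),
    q1 = vapply(vals, function(v) unname(quantile(v, 0.25)), 0),
    q3 = vapply(vals, function(v) unname(quantile(v, 0.75)), 0),
    row.names = NULL)
  test <- NULL
  if (length(vals) > 1) {
    test <- kruskal_dunn(vals)
    summ$letters <- compact_letters(names(vals), test$pairwise)
  } else {
    summ$letters <- "a"
  }
  list(summary = summ, test = test)
}
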