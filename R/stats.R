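#' Within-subject coefficient of variation for test-retest pairs
#'
#' Uses the root-mean-square of paired differences:
#' `CV = 100 * s_w / xbar` with `s_w = sqrt(sum(d_i^2) / (2 n))`,
#' `d_i = x_i1 - x_i2`, and `xbar` the grand mean. Scale invariant.
#'
#' @param pairs Two-column matrix or data frame of (scan1, scan2) values.
#' @return CV in percent.
#' @export
within_subject_cv <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 2)
  d <- pairs[, 1] - pairs[, 2]
  xbar <- mean(pairs)
  if (xbar == 0) stop("zero grand mean")
  100 * sqrt(sum(d^2) / (2 * nrow(pairs))) / xbar
}

#' Two-sample variance-ratio (F) test
#'
#' `F = var(x) / var(y)` with `(n_x - 1, n_y - 1)` degrees of freedom,
#' two-sided p-value by doubling the smaller tail, and 95% CI
#' `(F / qf(0.975), F / qf(0.025))`.
#'
#' @param x,y Numeric samples (each length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `f_test_result` with `F`, `df1`, `df2`,
#'   `p_two_sided`, `ci95`.
#' @export
variance_ratio_test <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vy <- stats::var(y)
  if (vy == 0) stop("zero variance in y")
  F <- stats::var(x) / vy
  df1 <- length(x) - 1L
  df2 <- length(y) - 1L
  p <- 2 * min(stats::pf(F, df1, df2), stats::pf(F, df1, df2,
                                                 lower.tail = FALSE))
  p <- min(p, 1)
  structure(list(F = F, df1 = df1, df2 = df2, p_two_sided = p,
                 ci95 = f_ci(F, df1, df2, conf_level)),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.3f, %s CI (%.2f, %.2f)\n",
              x$df1, x$df2, x$F, x$p_two_sided, "95%",
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Confidence interval for a variance ratio
#'
#' `(F / q_{(1+level)/2}, F / q_{(1-level)/2})` with `q` the quantiles of the
#' F distribution with `(df1, df2)` degrees of freedom.
#'
#' @param F Observed variance ratio (> 0).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @param level Confidence level in (0, 1).
#' @export
f_ci <- function(F, df1, df2, level = 0.95) {
  stopifnot(F > 0, df1 >= 1, df2 >= 1, level > 0, level < 1)
  c(F / stats::qf((1 + level) / 2, df1, df2),
    F / stats::qf((1 - level) / 2, df1, df2))
}

#' Bland-Altman agreement summary for test-retest pairs
#'
#' @param pairs Two-column matrix/data frame of (scan1, scan2) values.
#' @return List with `mean_diff`, `loa_low`, `loa_high` (mean +/- 1.96 SD of
#'   differences) and a data frame `points` of per-pair means and diffs.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 2)
  d <- pairs[, 1] - pairs[, 2]
  m <- rowMeans(pairs)
  md <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       points = data.frame(mean = m, diff = d))
}

#' Normalize values to unit mean
#' @param values Numeric vector with nonzero mean.
#' @export
normalize_unit_mean <- function(values) {
  m <- mean(values)
  if (m == 0) stop("zero mean")
  values / m
}

#' Cohort-level reproducibility report
#'
#' From a tidy table of water-scaled estimates (columns subject, scan,
#' sequence, method, metabolite, estimate_iu), computes per
#' (sequence, metabolite, method): scan means +/- SD and pooled mean +/- SD;
#' within-subject CVs; Bland-Altman summaries; and, per
#' (sequence, metabolite) present for both methods, a PEAK-vs-LCM
#' variance-ratio test on unit-mean-normalized per-subject means (the three
#' method comparisons of the study design: MEGA GSH, HERMES GSH, HERMES
#' GABA+). Missing cells are reported, not fatal.
#'
#' @param table Data frame of quantification results.
#' @return List with data frames `table1` (scan/pooled means), `table2`
#'   (within-subject CVs), `ftests`, `bland_altman`, and `missing`.
#' @export
cohort_stats <- function(table) {
  need <- c("subject", "scan", "sequence", "method", "metabolite",
            "estimate_iu")
  stopifnot(all(need %in% names(table)))
  groups <- unique(table[c("sequence", "metabolite", "method")])
  groups <- groups[order(groups$sequence, groups$metabolite, groups$method), ]
  t1 <- list(); t2 <- list(); ba <- list(); missing <- list()

  pair_up <- function(sub) {
    scans <- sort(unique(sub$scan))[1:2]
    s1 <- sub[sub$scan == scans[1], c("subject", "estimate_iu")]
    s2 <- sub[sub$scan == scans[2], c("subject", "estimate_iu")]
    mg <- merge(s1, s2, by = "subject", suffixes = c("_1", "_2"))
    mg[order(mg$subject), ]
  }

  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- table[table$sequence == g$sequence &
                   table$metabolite == g$metabolite &
                   table$method == g$method, ]
    scans <- sort(unique(sub$scan))
    if (length(scans) < 2) {
      missing[[length(missing) + 1L]] <- g
      next
    }
    mg <- pair_up(sub)
    if (nrow(mg) < 2) {
      missing[[length(missing) + 1L]] <- g
      next
    }
    x1 <- mg$estimate_iu_1; x2 <- mg$estimate_iu_2
    t1[[i]] <- data.frame(
      g, n = nrow(mg),
      scan1_mean = mean(x1), scan1_sd = stats::sd(x1),
      scan2_mean = mean(x2), scan2_sd = stats::sd(x2),
      total_mean = mean(c(x1, x2)), total_sd = stats::sd(c(x1, x2)))
    t2[[i]] <- data.frame(g, cv_percent = within_subject_cv(cbind(x1, x2)))
    b <- bland_altman(cbind(x1, x2))
    ba[[i]] <- data.frame(g, mean_diff = b$mean_diff, loa_low = b$loa_low,
                          loa_high = b$loa_high)
  }

  fts <- list()
  cmps <- unique(table[c("sequence", "metabolite")])
  cmps <- cmps[order(cmps$sequence, cmps$metabolite), ]
  for (i in seq_len(nrow(cmps))) {
    g <- cmps[i, ]
    sub <- table[table$sequence == g$sequence &
                   table$metabolite == g$metabolite, ]
    if (!all(c("PEAK", "LCM") %in% sub$method)) next
    per_subj <- function(method) {
      s <- sub[sub$method == method, ]
      v <- tapply(s$estimate_iu, s$subject, mean)
      v[order(as.numeric(names(v)))]
    }
    pk <- per_subj("PEAK"); lc <- per_subj("LCM")
    common <- intersect(names(pk), names(lc))
    if (length(common) < 3) next
    xs <- normalize_unit_mean(pk[common])
    ys <- normalize_unit_mean(lc[common])
    ft <- if (stats::var(ys) == 0 && stats::var(xs) == 0) {
      # degenerate (variation-free) cohort: equal variances by construction
      structure(list(F = 1, df1 = length(xs) - 1L, df2 = length(ys) - 1L,
                     p_two_sided = 1,
                     ci95 = f_ci(1, length(xs) - 1L, length(ys) - 1L)),
                class = "f_test_result")
    } else {
      variance_ratio_test(xs, ys)
    }
    fts[[length(fts) + 1L]] <- data.frame(
      sequence = g$sequence, metabolite = g$metabolite,
      F = ft$F, df1 = ft$df1, df2 = ft$df2, p = ft$p_two_sided,
      ci_low = ft$ci95[1], ci_high = ft$ci95[2])
  }

  list(table1 = do.call(rbind, t1), table2 = do.call(rbind, t2),
       ftests = if (length(fts)) do.call(rbind, fts) else NULL,
       bland_altman = do.call(rbind, ba),
       missing = if (length(missing)) do.call(rbind, missing) else NULL)
}
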