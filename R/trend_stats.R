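#' @keywords internal
pairwise_score_matrix <- function(values) {
  # S[i, j] = 1 if values[j] > values[i], 1/2 on a tie
  outer(values, values, function(a, b) (b > a) + 0.5 * (b == a))
}

#' @keywords internal
multiset_permutations <- function(labels) {
  # all distinct arrangements of the label multiset, one per row
  tab <- table(labels)
  lev <- names(tab)
  n <- length(labels)
  rows <- list()
  rec2 <- function(remaining, filled) {
    if (length(remaining) == 1L) {
      filled[is.na(filled)] <- names(remaining)[1]
      rows[[length(rows) + 1L]] <<- filled
      return(invisible())
    }
    lev1 <- names(remaining)[1]
    k <- remaining[[1]]
    free <- which(is.na(filled))
    choose_sets <- utils::combn(free, k)
    for (ci in seq_len(ncol(choose_sets))) {
      f2 <- filled
      f2[choose_sets[, ci]] <- lev1
      rec2(remaining[-1], f2)
    }
    invisible()
  }
  counts <- as.integer(tab)
  names(counts) <- lev
  rec2(as.list(counts), rep(NA_character_, n))
  do.call(rbind, rows)
}

#' @keywords internal
n_arrangements <- function(group_sizes) {
  exp(lgamma(sum(group_sizes) + 1) - sum(lgamma(group_sizes + 1)))
}

#' @keywords internal
jt_statistic <- function(values, groups, levels) {
  jt <- 0
  for (a in seq_along(levels)[-length(levels)]) {
    xa <- values[groups == levels[a]]
    for (b in (a + 1):length(levels)) {
      xb <- values[groups == levels[b]]
      r <- rank(c(xa, xb))
      # Mann-Whitney count of b-wins with ties half-weighted
      jt <- jt + sum(r[length(xa) + seq_along(xb)]) -
        length(xb) * (length(xb) + 1) / 2
    }
  }
  jt
}

#' Jonckheere-Terpstra test for ordered alternatives
#'
#' Tests for a monotone trend in a quantitative outcome across ordered
#' groups. The statistic is the sum over ordered group pairs of
#' Mann-Whitney counts (ties half-weighted). For small samples (total
#' n <= `exact_n_max` and at most `exact_cap` distinct label
#' arrangements) the exact permutation null distribution is fully
#' enumerated; otherwise the tie-corrected normal approximation is used
#' (no continuity correction).
#'
#' @param values numeric outcome vector.
#' @param groups group labels; order taken from factor levels, or
#'   sorted unique order otherwise.
#' @param exact_n_max total-n gate for the exact path.
#' @param exact_cap maximum number of enumerated arrangements.
#' @return list of class `trend_result`: `statistic`, `max_pairs`,
#'   `mean_null`, `sd_null` (exact enumeration SD or the tie-corrected
#'   asymptotic SD), `z`, `p` (two-sided), `p_increasing` (one-sided),
#'   `method`, `group_n`.
#' @export
jonckheere_terpstra <- function(values, groups, exact_n_max = 20L,
                                exact_cap = 2e5) {
  if (!is.factor(groups)) groups <- factor(groups, levels = sort(unique(groups)))
  groups <- droplevels(groups)
  levels <- levels(groups)
  if (length(levels) < 2L) stop("need at least two groups")
  n_i <- as.integer(table(groups))
  if (any(n_i == 0L)) stop("empty group")
  n <- length(values)
  stopifnot(n == length(groups))
  jt <- jt_statistic(values, groups, levels)
  max_pairs <- sum(outer(n_i, n_i)[upper.tri(diag(length(n_i)))])
  mean_null <- (n^2 - sum(n_i^2)) / 4

  exact_ok <- n <= exact_n_max &&
    n_arrangements(n_i) <= exact_cap
  if (exact_ok) {
    perms <- multiset_permutations(as.character(groups))
    stats <- apply(perms, 1, function(g) {
      jt_statistic(values, factor(g, levels = levels), levels)
    })
    eps <- 1e-9
    p_up <- mean(stats >= jt - eps)
    p_dn <- mean(stats <= jt + eps)
    p <- min(1, 2 * min(p_up, p_dn))
    sd_null <- stats::sd(stats) * sqrt((length(stats) - 1) / length(stats))
    z <- if (sd_null > 0) (jt - mean_null) / sd_null else 0
    method <- "exact enumeration"
  } else {
    t_j <- as.integer(table(values))
    N <- n
    v1 <- (N * (N - 1) * (2 * N + 5) -
             sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
             sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72
    v2 <- sum(n_i * (n_i - 1) * (n_i - 2)) *
      sum(t_j * (t_j - 1) * (t_j - 2)) /
      (36 * N * (N - 1) * (N - 2))
    v3 <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1)) /
      (8 * N * (N - 1))
    v <- v1 + v2 + v3
    sd_null <- sqrt(max(v, 0))
    if (v <= 0) {
      z <- 0
      p <- 1
      p_up <- 1
    } else {
      z <- (jt - mean_null) / sd_null
      p <- 2 * stats::pnorm(-abs(z))
      p_up <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation"
  }
  structure(list(
    statistic = jt, max_pairs = max_pairs, mean_null = mean_null,
    sd_null = sd_null, z = z, p = p, p_increasing = p_up,
    method = method,
    group_n = stats::setNames(n_i, levels)
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test (", x$method, ")\n", sep = "")
  cat(sprintf("  JT = %.1f of %d cross-group pairs, z = %.3f, p = %.4g\n",
              x$statistic, x$max_pairs, x$z, x$p))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U counts pairs where the first sample exceeds the second (ties
#' half-weighted). Small samples (combined n <= `exact_n_max`) are
#' handled exactly: via the null distribution of the rank-sum when there
#' are no ties, by full enumeration of group assignments otherwise.
#' Larger samples use the tie-corrected normal approximation (no
#' continuity correction). Two-sided p is twice the smaller tail,
#' capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_n_max combined-size gate for the exact path.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_n_max = 20L) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 # x-wins
  n <- nx + ny
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (n <= exact_n_max) {
    if (!has_ties) {
      # exact null distribution of the Wilcoxon count statistic
      p_lo <- stats::pwilcox(floor(U + 1e-9), nx, ny)
      p_hi <- 1 - stats::pwilcox(ceiling(U - 1e-9) - 1, nx, ny)
      p <- min(1, 2 * min(p_lo, p_hi))
      method <- "exact distribution"
    } else {
      # with ties: two-group exact case of the JT enumeration; the
      # two-sided p is orientation-invariant
      jt <- jonckheere_terpstra(c(x, y),
                                factor(rep(c("a", "b"), c(nx, ny)),
                                       levels = c("a", "b")),
                                exact_n_max = exact_n_max)
      p <- jt$p
      method <- "exact enumeration"
    }
  } else {
    t_j <- as.integer(table(c(x, y)))
    mu <- nx * ny / 2
    v <- nx * ny / 12 * ((n + 1) - sum(t_j^3 - t_j) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Rank-based two-step normalization
#'
#' Step 1 converts values to fractional ranks and percentiles (ties share
#' mid-ranks; the Hazen plotting position (r - 0.5)/n keeps percentiles
#' strictly inside (0, 1)). Step 2 applies the inverse standard-normal
#' CDF and rescales the result to the input mean and standard deviation.
#' The transform is monotone, so rank order (including ties) is exactly
#' preserved.
#'
#' @param values numeric vector, n >= 3, not all equal.
#' @return transformed numeric vector.
#' @export
templeton_normalize <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  if (stats::var(values) == 0) stop("constant input cannot be normalized")
  r <- rank(values, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / n)
  m <- mean(values)
  s <- stats::sd(values)
  m + s * (z - mean(z)) / stats::sd(z)
}

#' Bonferroni-corrected significance threshold
#'
#' The working threshold is alpha divided by the number of independent
#' polymorphisms in the score; the displayed threshold is rounded to
#' three decimals (e.g. 0.05 / 3 -> 0.017) while flagging always uses
#' the unrounded value.
#'
#' @param alpha nominal level in (0, 1).
#' @param n_polymorphisms number of independent polymorphisms (>= 1).
#' @return list with `threshold` (unrounded) and `displayed`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_polymorphisms = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_polymorphisms < 1) stop("n_polymorphisms must be >= 1")
  th <- alpha / n_polymorphisms
  list(threshold = th, displayed = round(th, 3))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction; df = (r-1)(c-1). Zero row or column
#' marginals are an error.
#'
#' @param table matrix of non-negative counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) <= 0) {
    stop("table must hold non-negative counts with a positive total")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column marginal")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  chi2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' @keywords internal
shapiro_gate <- function(values, alpha = 0.05) {
  v <- values[is.finite(values)]
  if (length(v) < 3L || stats::var(v) == 0) return(FALSE)
  if (length(v) > 5000L) {
    # Shapiro-Wilk is defined for n <= 5000; thin deterministically
    v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
  }
  stats::shapiro.test(v)$p.value < alpha
}

#' Trend table of a quantitative outcome across score categories
#'
#' For each LTPA outcome: group sizes, group means with normal 95%
#' confidence intervals, and the Jonckheere-Terpstra p for trend across
#' ordered score categories. Values failing a Shapiro-Wilk normality
#' gate (alpha 0.05) are passed through [templeton_normalize()] before
#' the mean/CI summary (the trend test itself is rank-based and uses the
#' raw values). `include_zeros = FALSE` restricts each outcome's summary
#' and test to participants (binary outcome 1).
#'
#' @param table phenotype data.frame with `ltpa_<oc>` and value columns.
#' @param categories ordered factor from [categorize_scores()], aligned
#'   with `table` rows.
#' @param outcomes outcome names.
#' @param value_prefix `"met_"` or `"days_"`.
#' @param include_zeros include non-participants (value 0) in each
#'   outcome's groups.
#' @param bonferroni_n denominator for the trend-test correction.
#' @param alpha nominal level.
#' @return data.frame, one row per outcome x category plus trend columns.
#' @export
trend_table <- function(table, categories, outcomes = ltpa_outcomes(),
                        value_prefix = "met_", include_zeros = TRUE,
                        bonferroni_n = 3, alpha = 0.05) {
  stopifnot(nrow(table) == length(categories))
  corr <- bonferroni_alpha(alpha, bonferroni_n)
  rows <- list()
  for (oc in outcomes) {
    vals <- table[[paste0(value_prefix, oc)]]
    if (is.null(vals)) stop("missing column: ", value_prefix, oc)
    keep <- if (include_zeros) rep(TRUE, nrow(table)) else
      table[[paste0("ltpa_", oc)]] == 1L
    v <- vals[keep]
    g <- droplevels(categories[keep])
    jt <- jonckheere_terpstra(v, g)
    transformed <- shapiro_gate(v, alpha)
    v_sum <- if (transformed) templeton_normalize(v) else v
    for (lev in levels(g)) {
      gv <- v_sum[g == lev]
      se <- stats::sd(gv) / sqrt(length(gv))
      rows[[paste(oc, lev)]] <- data.frame(
        outcome = oc, category = lev, n = length(gv),
        mean = mean(gv),
        ci95_low = mean(gv) - 1.96 * se,
        ci95_high = mean(gv) + 1.96 * se,
        transformed = transformed,
        p_trend = jt$p,
        significant_after_correction = jt$p < corr$threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni") <- corr
  out
}
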