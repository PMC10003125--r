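# Independent oracles used across tests: each recomputes a statistic by
# the most direct route available (textbook arithmetic, exhaustive
# enumeration, or a base-R reference implementation), never by calling
# the code path under test.

# Pearson HWE chi-square straight from expected counts
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# raw JT statistic: pairwise loop, ties half-weighted
oracle_jt_stat <- function(values, groups, levels) {
  jt <- 0
  for (a in seq_along(levels)) {
    for (b in seq_along(levels)) {
      if (a >= b) next
      for (x in values[groups == levels[a]]) {
        for (y in values[groups == levels[b]]) {
          jt <- jt + (y > x) + 0.5 * (y == x)
        }
      }
    }
  }
  jt
}

# exhaustive permutation distribution of the JT statistic: every
# distinct assignment of the observed values to the group layout
oracle_jt_exact <- function(values, groups) {
  groups <- as.character(groups)
  levels <- sort(unique(groups))
  sizes <- as.integer(table(factor(groups, levels = levels)))
  n <- length(values)
  assignments <- list()
  build <- function(free, remaining_levels, remaining_sizes, current) {
    if (length(remaining_levels) == 1L) {
      current[free] <- remaining_levels[1]
      assignments[[length(assignments) + 1L]] <<- current
      return(invisible())
    }
    sets <- combn(free, remaining_sizes[1])
    for (i in seq_len(ncol(sets))) {
      cur2 <- current
      cur2[sets[, i]] <- remaining_levels[1]
      build(setdiff(free, sets[, i]), remaining_levels[-1],
            remaining_sizes[-1], cur2)
    }
    invisible()
  }
  build(seq_len(n), levels, sizes, rep(NA_character_, n))
  stats <- vapply(assignments, function(g) {
    oracle_jt_stat(values, g, levels)
  }, 0)
  obs <- oracle_jt_stat(values, groups, levels)
  eps <- 1e-9
  list(
    stat = obs,
    dist = stats,
    p_increasing = mean(stats >= obs - eps),
    p_two_sided = min(1, 2 * min(mean(stats >= obs - eps),
                                 mean(stats <= obs + eps)))
  )
}

# Mann-Whitney U (x-wins) by direct pair counting, exact p by the
# two-group case of the JT enumeration
oracle_mw <- function(x, y) {
  U <- 0
  for (xi in x) for (yj in y) U <- U + (xi > yj) + 0.5 * (xi == yj)
  ex <- oracle_jt_exact(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
  list(U = U, p = ex$p_two_sided)
}

# brute-force merge oracle for integer-score categorization: replays the
# stated rule (merge the smaller-count extreme bin inward until the
# target group count, then absorb under-filled bins) on the empirical
# distribution
oracle_merge_bins <- function(scores, n_groups, min_frac) {
  vals <- sort(unique(scores))
  bins <- lapply(vals, function(v) v)
  count <- function(b) sum(scores %in% b)
  while (length(bins) > n_groups) {
    if (count(bins[[1]]) <= count(bins[[length(bins)]])) {
      bins[[2]] <- c(bins[[1]], bins[[2]])
      bins <- bins[-1]
    } else {
      k <- length(bins)
      bins[[k - 1]] <- c(bins[[k - 1]], bins[[k]])
      bins <- bins[-k]
    }
  }
  repeat {
    fr <- vapply(bins, count, 0) / length(scores)
    if (all(fr >= min_frac) || length(bins) == 1L) break
    d <- which.min(fr)
    if (d == 1L) {
      bins[[2]] <- c(bins[[1]], bins[[2]])
      bins <- bins[-1]
    } else if (d == length(bins)) {
      bins[[d - 1]] <- c(bins[[d - 1]], bins[[d]])
      bins <- bins[-d]
    } else {
      if (count(bins[[d - 1]]) <= count(bins[[d + 1]])) {
        bins[[d - 1]] <- c(bins[[d - 1]], bins[[d]])
      } else {
        bins[[d + 1]] <- c(bins[[d]], bins[[d + 1]])
      }
      bins <- bins[-d]
    }
  }
  vapply(bins, function(b) {
    if (length(b) == 1L) as.character(b) else
      paste0(min(b), "-", max(b))
  }, "")
}

# tiny two-population config for fast pipeline tests
small_sim_config <- function(seed = 7L, n = c(150L, 140L), ...) {
  sim_config(n_per_population = n, seed = seed, ...)
}
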