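#' Unweighted effect-allele count score
#'
#' The genetic risk score of an individual is the plain sum of
#' effect-allele counts over the contributing SNP set: homozygous effect
#' genotypes contribute 2, heterozygotes 1, others 0, so the score lies
#' in 0..2K for K SNPs. Every allele is assumed to act in the same
#' direction with the same weight. Missing genotypes are not imputed:
#' individuals with any missing contributing genotype must be excluded
#' before scoring.
#'
#' @param genotypes a [genotype_matrix()] or coded matrix.
#' @param snp_set character vector of contributing SNP ids (non-empty).
#' @return integer vector of per-individual scores with the SNP set as
#'   attribute `snp_set`.
#' @export
count_score <- function(genotypes, snp_set) {
  if (length(snp_set) == 0L) stop("empty SNP set: no score defined")
  missing_snps <- setdiff(snp_set, colnames(genotypes))
  if (length(missing_snps)) {
    stop("SNP(s) not in genotype matrix: ",
         paste(missing_snps, collapse = ", "))
  }
  sub <- genotypes[, snp_set, drop = FALSE]
  if (anyNA(sub)) {
    stop("missing genotypes in scoring set; individuals with any ",
         "missing SNP genotype are excluded from score analyses")
  }
  structure(as.integer(rowSums(sub)), snp_set = snp_set)
}

#' Rank candidate SNPs for score optimization
#'
#' Ascending by association p-value; ties broken by larger absolute
#' log odds ratio, then lexical SNP id.
#'
#' @param assoc an association table restricted to one outcome (one row
#'   per SNP with `predictor_id`, `p_wald`, `odds_ratio`).
#' @return character vector of SNP ids in test order.
#' @export
rank_candidates <- function(assoc) {
  ord <- order(assoc$p_wald, -abs(log(assoc$odds_ratio)),
               assoc$predictor_id)
  assoc$predictor_id[ord]
}

#' Forward optimization of the count score
#'
#' Candidates are tested in ascending order of their single-SNP adjusted
#' p-value. The score starts as the top-ranked SNP's genotypes (included
#' unconditionally). Each subsequent SNP is tentatively added to the
#' scoring set; the trial score is refitted (adjusted logistic of the
#' general-LTPA outcome on the score) and the SNP is accepted only if the
#' fit strictly improves on the best model so far on both criteria:
#' p-value strictly decreases AND Cox-Snell R-squared strictly increases.
#' Ties or one-sided improvements are rejections.
#'
#' @param genotypes complete-genotype [genotype_matrix()].
#' @param outcome binary general-LTPA vector.
#' @param covariates covariate data.frame (seven-covariate adjustment
#'   set, including ethnicity for a combined two-population sample).
#' @param candidate_assoc association table for the same outcome used to
#'   order the candidates (typically adjusted single-SNP fits on the
#'   combined sample).
#' @param adjusted adjust the score fits for the covariate set.
#' @return object of class `pgs_model`: `candidate_order`, `accepted`,
#'   `trajectory` (one row per candidate with p/R-squared before and
#'   after and the decision), `n_candidates`, `scores` (final score
#'   vector).
#' @export
optimize_pgs <- function(genotypes, outcome, covariates, candidate_assoc,
                         adjusted = TRUE) {
  if (nrow(candidate_assoc) == 0L) stop("empty candidate list")
  order_ids <- rank_candidates(candidate_assoc)
  score_fit <- function(snp_set) {
    sc <- count_score(genotypes, snp_set)
    fit <- snp_association(sc, outcome, covariates, adjusted = adjusted,
                           predictor_id = "score",
                           outcome_id = "general")
    list(p = fit$p_wald, r2 = fit$cox_snell_r2)
  }
  accepted <- order_ids[1]
  best <- tryCatch(score_fit(accepted), error = function(e) {
    stop("score fit failed at SNP ", accepted, ": ",
         conditionMessage(e), call. = FALSE)
  })
  trajectory <- data.frame(
    snp_id = order_ids[1], p_before = NA_real_, p_after = best$p,
    r2_before = NA_real_, r2_after = best$r2, accepted = TRUE,
    stringsAsFactors = FALSE
  )
  for (s in order_ids[-1]) {
    trial <- tryCatch(score_fit(c(accepted, s)), error = function(e) {
      stop("score fit failed at SNP ", s, ": ", conditionMessage(e),
           call. = FALSE)
    })
    ok <- (trial$p < best$p) && (trial$r2 > best$r2)
    trajectory <- rbind(trajectory, data.frame(
      snp_id = s, p_before = best$p, p_after = trial$p,
      r2_before = best$r2, r2_after = trial$r2, accepted = ok,
      stringsAsFactors = FALSE
    ))
    if (ok) {
      accepted <- c(accepted, s)
      best <- trial
    }
  }
  structure(list(
    candidate_order = order_ids,
    accepted = accepted,
    trajectory = trajectory,
    n_candidates = length(order_ids),
    scores = count_score(genotypes, accepted)
  ), class = "pgs_model")
}

#' @export
print.pgs_model <- function(x, ...) {
  cat("optimized polygenic score\n")
  cat(sprintf("  candidates tested: %d\n", x$n_candidates))
  cat(sprintf("  accepted set (%d): %s\n", length(x$accepted),
              paste(x$accepted, collapse = ", ")))
  last <- x$trajectory[nrow(x$trajectory), ]
  final <- x$trajectory[x$trajectory$accepted, ]
  final <- final[nrow(final), ]
  cat(sprintf("  final model: p = %.4g, Cox-Snell R2 = %.4g\n",
              final$p_after, final$r2_after))
  invisible(x)
}

#' Bin integer scores into ordered predisposition categories
#'
#' Starts from one bin per distinct score value and merges adjacent
#' extreme bins until at most `n_groups` bins remain and every bin holds
#' at least `min_group_frac` of the individuals: while the bin count
#' exceeds `n_groups`, the extreme (lowest or highest) bin with the
#' smaller count is merged inward (lower tail first on ties); afterwards
#' any under-filled extreme bin keeps merging inward, dropping below
#' `n_groups` bins with a warning if needed. On a uniform score over
#' 0..5 this yields the four groups 0-1, 2, 3, 4-5.
#'
#' @param scores integer score vector.
#' @param n_groups target number of ordered categories.
#' @param min_group_frac minimum fraction of individuals per category.
#' @return ordered factor of category labels (e.g. `"0-1"`, `"2"`), with
#'   attribute `boundaries` (data.frame of lo/hi score per category).
#' @export
categorize_scores <- function(scores, n_groups = 4, min_group_frac = 0.10) {
  scores <- as.integer(scores)
  n <- length(scores)
  if (n < n_groups) stop("fewer individuals than requested groups")
  vals <- sort(unique(scores))
  if (length(vals) == 1L) {
    stop("constant scores: no ordered categories possible")
  }
  if (length(vals) < n_groups) {
    warning("only ", length(vals), " distinct score values; ",
            "returning fewer groups than requested")
    n_groups <- length(vals)
  }
  counts <- as.numeric(table(factor(scores, levels = vals)))
  # bins as index ranges into vals
  bins <- lapply(seq_along(vals), function(i) c(i, i))
  bin_count <- function(b) sum(counts[b[1]:b[2]])
  merge_low <- function(bins) {
    bins[[2]] <- c(bins[[1]][1], bins[[2]][2])
    bins[-1]
  }
  merge_high <- function(bins) {
    k <- length(bins)
    bins[[k - 1]] <- c(bins[[k - 1]][1], bins[[k]][2])
    bins[-k]
  }
  while (length(bins) > n_groups) {
    lo <- bin_count(bins[[1]])
    hi <- bin_count(bins[[length(bins)]])
    bins <- if (lo <= hi) merge_low(bins) else merge_high(bins)
  }
  repeat {
    fracs <- vapply(bins, bin_count, 0) / n
    if (all(fracs >= min_group_frac) || length(bins) == 1L) break
    deficient <- which(fracs < min_group_frac)
    # merge the most deficient bin toward its smaller-count neighbour
    d <- deficient[which.min(fracs[deficient])]
    if (d == 1L) {
      bins <- merge_low(bins)
    } else if (d == length(bins)) {
      bins <- merge_high(bins)
    } else {
      left_n <- bin_count(bins[[d - 1L]])
      right_n <- bin_count(bins[[d + 1L]])
      if (left_n <= right_n) {
        bins[[d - 1L]] <- c(bins[[d - 1L]][1], bins[[d]][2])
      } else {
        bins[[d + 1L]] <- c(bins[[d]][1], bins[[d + 1L]][2])
      }
      bins <- bins[-d]
    }
  }
  if (length(bins) < n_groups) {
    warning("minimum group fraction forced ", length(bins),
            " groups (requested ", n_groups, ")")
  }
  label_of <- function(b) {
    lo <- vals[b[1]]
    hi <- vals[b[2]]
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }
  labels <- vapply(bins, label_of, "")
  cut_idx <- findInterval(scores,
                          vapply(bins, function(b) vals[b[1]], 0))
  out <- factor(labels[cut_idx], levels = labels, ordered = TRUE)
  attr(out, "boundaries") <- data.frame(
    category = labels,
    lo = vapply(bins, function(b) vals[b[1]], 0),
    hi = vapply(bins, function(b) vals[b[2]], 0),
    n = vapply(bins, bin_count, 0),
    stringsAsFactors = FALSE
  )
  out
}
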