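#' Effect-allele frequencies per SNP and group
#'
#' Frequency = (sum of effect-allele counts over non-missing individuals)
#' / (2 x number of non-missing individuals). Missing genotypes reduce the
#' denominator; a SNP entirely missing within a group is an error.
#'
#' @param genotypes a [genotype_matrix()] or 0/1/2/NA matrix.
#' @param group per-individual group labels; defaults to the matrix's
#'   population attribute, else a single group.
#' @return data.frame with columns `snp_id`, `group`, `n_genotyped`,
#'   `freq`.
#' @export
allele_frequencies <- function(genotypes, group = NULL) {
  group <- group %||% gm_population(genotypes) %||%
    rep("all", nrow(genotypes))
  stopifnot(length(group) == nrow(genotypes))
  snps <- colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes)))
  out <- do.call(rbind, lapply(unique(group), function(g) {
    sub <- genotypes[group == g, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    if (any(n_ok == 0L)) {
      stop("SNP(s) with all genotypes missing in group '", g, "': ",
           paste(snps[n_ok == 0L], collapse = ", "))
    }
    data.frame(snp_id = snps, group = g, n_genotyped = as.integer(n_ok),
               freq = colSums(sub, na.rm = TRUE) / (2 * n_ok),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against expected counts p^2, 2pq, q^2 at the estimated allele
#' frequency. A monomorphic SNP (p = 0 or 1) has no valid expectation and
#' is flagged rather than tested; by convention such a SNP is reported but
#' never excluded on HWE grounds.
#'
#' @param n_hom_effect,n_het,n_hom_other genotype counts (effect-allele
#'   homozygote, heterozygote, other homozygote).
#' @return list with `chi2`, `p`, `monomorphic` flag and the estimated
#'   effect-allele frequency `freq`.
#' @export
hwe_chisq <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  p <- (2 * n_hom_effect + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = NA_real_, p = NA_real_, monomorphic = TRUE,
                freq = p))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE, freq = p)
}

#' @keywords internal
genotype_counts <- function(g) {
  g <- g[!is.na(g)]
  c(n_hom_effect = sum(g == 2L), n_het = sum(g == 1L),
    n_hom_other = sum(g == 0L))
}

#' Between-population allele-frequency chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' effect/other allele counts in two groups. Allele counts are 2x the
#' genotyped individuals. If one allele is absent from both groups the
#' table is degenerate; identical monomorphic groups return chi2 = 0,
#' p = 1.
#'
#' @param counts_a,counts_b length-2 vectors (effect, other) of allele
#'   counts per group.
#' @return list with `chi2` and `p`.
#' @export
compare_freqs <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L,
            all(c(counts_a, counts_b) >= 0))
  tab <- rbind(counts_a, counts_b)
  if (any(rowSums(tab) == 0)) stop("empty group in allele-count table")
  col_tot <- colSums(tab)
  if (any(col_tot == 0)) {
    # one allele absent everywhere: no frequency difference detectable
    return(list(chi2 = 0, p = 1))
  }
  expected <- outer(rowSums(tab), col_tot) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Power for detecting an allele-frequency difference
#'
#' Two-sided normal-approximation power for the difference of two
#' proportions applied to allele counts (2n alleles per group of n
#' individuals), with unpooled variance. At freqA = freqB the power
#' equals the significance level.
#'
#' @param freq_a,freq_b effect-allele frequencies per group.
#' @param n_a,n_b individuals per group.
#' @param alpha two-sided significance level in (0, 1).
#' @return power (probability).
#' @export
power_allele_diff <- function(freq_a, freq_b, n_a, n_b, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  assert_probability(c(freq_a, freq_b), "allele frequencies")
  stopifnot(n_a >= 1, n_b >= 1)
  m_a <- 2 * n_a
  m_b <- 2 * n_b
  se <- sqrt(freq_a * (1 - freq_a) / m_a + freq_b * (1 - freq_b) / m_b)
  z_crit <- stats::qnorm(1 - alpha / 2)
  if (se == 0) return(if (freq_a == freq_b) alpha else 1)
  delta <- abs(freq_a - freq_b) / se
  stats::pnorm(delta - z_crit) + stats::pnorm(-delta - z_crit)
}

#' Two-locus linkage disequilibrium by EM on unphased genotypes
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; A and B the
#' effect alleles) by expectation-maximisation over the two-locus
#' multinomial likelihood. Only double heterozygotes are phase-ambiguous;
#' the E-step splits them between coupling (AB/ab) and repulsion (Ab/aB)
#' in proportion to the current haplotype-frequency products. Starts from
#' linkage equilibrium; converged when the largest haplotype-frequency
#' change is below `tol`. Individuals missing at either locus are dropped
#' pairwise. If either locus is monomorphic LD is undefined and the
#' result is flagged; a degenerate fit with no information (e.g. all
#' individuals double-heterozygous) stays at the equilibrium start.
#'
#' @param genotypes_a,genotypes_b 0/1/2/NA effect-allele counts.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return list of class `ld_pair`: `hap_freqs` (AB, Ab, aB, ab), `D`,
#'   `D_prime`, `r2`, `em_iterations`, `n_used`, `monomorphic` flag.
#' @export
ld_em <- function(genotypes_a, genotypes_b, tol = 1e-8, max_iter = 1000L) {
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b)
  ga <- as.integer(genotypes_a[keep])
  gb <- as.integer(genotypes_b[keep])
  n <- length(ga)
  if (n == 0L) stop("no individuals genotyped at both loci")
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(structure(list(
      hap_freqs = stats::setNames(rep(NA_real_, 4),
                                  c("AB", "Ab", "aB", "ab")),
      D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
      em_iterations = 0L, n_used = n, monomorphic = TRUE
    ), class = "ld_pair"))
  }
  # 3x3 genotype table; cell (i+1, j+1) holds count of (g_a = i, g_b = j)
  tab <- matrix(0L, 3L, 3L)
  for (k in seq_len(n)) {
    tab[ga[k] + 1L, gb[k] + 1L] <- tab[ga[k] + 1L, gb[k] + 1L] + 1L
  }
  n_dh <- tab[2L, 2L] # double heterozygotes, the only ambiguous cell
  # unambiguous haplotype counts contributed by the other eight cells
  base <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  h <- c(AB = pA * pB, Ab = pA * (1 - pB),
         aB = (1 - pA) * pB, ab = (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cis <- h[["AB"]] * h[["ab"]]
    trans <- h[["Ab"]] * h[["aB"]]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new_counts <- base + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- new_counts / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol || iter >= max_iter) break
  }
  D <- h[["AB"]] - pA * pB
  d_max <- if (D >= 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  structure(list(
    hap_freqs = h,
    D = D,
    D_prime = if (d_max > 0) abs(D) / d_max else 0,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    em_iterations = iter,
    n_used = n,
    monomorphic = FALSE
  ), class = "ld_pair")
}

#' Pairwise LD matrix for a panel
#'
#' Runs [ld_em()] on every SNP pair and returns a long-format table, plus
#' a square r-squared matrix as an attribute.
#'
#' @param genotypes a [genotype_matrix()].
#' @param r2_link_threshold r-squared at or above which a pair is flagged
#'   as linked.
#' @return data.frame (snp_a, snp_b, D, D_prime, r2, linked, n_used).
#' @export
ld_matrix <- function(genotypes, r2_link_threshold = 0.8) {
  snps <- colnames(genotypes)
  pairs <- utils::combn(seq_along(snps), 2)
  rows <- apply(pairs, 2, function(ij) {
    fit <- ld_em(genotypes[, ij[1]], genotypes[, ij[2]])
    data.frame(snp_a = snps[ij[1]], snp_b = snps[ij[2]],
               D = fit$D, D_prime = fit$D_prime, r2 = fit$r2,
               linked = isTRUE(fit$r2 >= r2_link_threshold),
               n_used = fit$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- diag(1, length(snps))
  dimnames(m) <- list(snps, snps)
  for (k in seq_len(nrow(out))) {
    m[out$snp_a[k], out$snp_b[k]] <- m[out$snp_b[k], out$snp_a[k]] <- out$r2[k]
  }
  attr(out, "r2_matrix") <- m
  out
}

#' Panel QC report with HWE exclusion
#'
#' Per SNP: effect-allele frequency in each population, the HWE
#' chi-square in each population, the between-population allele-frequency
#' test, the power to detect the observed frequency difference, and the
#' exclusion flag. A SNP is excluded iff its HWE p-value falls below
#' `hwe_alpha` in either population; monomorphic SNPs are flagged but not
#' excluded on HWE grounds.
#'
#' @param genotypes a [genotype_matrix()] carrying population labels (or
#'   pass `group`).
#' @param group optional per-individual population labels.
#' @param hwe_alpha HWE exclusion threshold per population.
#' @param alpha significance level used for the power computation.
#' @return data.frame of class `qc_report`, one row per SNP.
#' @export
qc_report <- function(genotypes, group = NULL, hwe_alpha = 0.05,
                      alpha = 0.05) {
  group <- group %||% gm_population(genotypes) %||%
    rep("all", nrow(genotypes))
  groups <- unique(group)
  if (length(groups) > 2L) stop("qc_report supports at most two groups")
  snps <- colnames(genotypes)
  rows <- lapply(snps, function(s) {
    row <- list(snp_id = s)
    hwe_p <- numeric(0)
    for (gi in seq_along(groups)) {
      g <- genotypes[group == groups[gi], s]
      cnt <- genotype_counts(g)
      hw <- hwe_chisq(cnt[1], cnt[2], cnt[3])
      row[[paste0("freq_", groups[gi])]] <- hw$freq
      row[[paste0("n_", groups[gi])]] <- sum(cnt)
      row[[paste0("hwe_chi2_", groups[gi])]] <- hw$chi2
      row[[paste0("hwe_p_", groups[gi])]] <- hw$p
      row[[paste0("monomorphic_", groups[gi])]] <- hw$monomorphic
      hwe_p <- c(hwe_p, hw$p)
    }
    if (length(groups) == 2L) {
      ga <- genotypes[group == groups[1], s]
      gb <- genotypes[group == groups[2], s]
      n_a <- sum(!is.na(ga))
      n_b <- sum(!is.na(gb))
      ca <- c(sum(ga, na.rm = TRUE), 2 * n_a - sum(ga, na.rm = TRUE))
      cb <- c(sum(gb, na.rm = TRUE), 2 * n_b - sum(gb, na.rm = TRUE))
      cmp <- compare_freqs(ca, cb)
      row$freq_diff_chi2 <- cmp$chi2
      row$freq_diff_p <- cmp$p
      row$power <- power_allele_diff(ca[1] / (2 * n_a), cb[1] / (2 * n_b),
                                     n_a, n_b, alpha)
    }
    excl <- any(!is.na(hwe_p) & hwe_p < hwe_alpha)
    row$excluded <- excl
    row$exclusion_reason <- if (excl) {
      bad <- groups[which(!is.na(hwe_p) & hwe_p < hwe_alpha)]
      paste0("HWE deviation (p < ", hwe_alpha, ") in ",
             paste(bad, collapse = ", "))
    } else ""
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}
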