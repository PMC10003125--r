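make_gm <- function(codes, ids = colnames(codes)) {
  alle <- c("A", "C", "G", "T")
  panel <- snp_panel(ids, chrom = seq_along(ids), pos = seq_along(ids),
                     effect_allele = rep("A", length(ids)),
                     other_allele = rep("G", length(ids)))
  genotype_matrix(codes, panel)
}

test_that("count score is the plain effect-allele sum with hard bounds", {
  codes <- rbind(c(2L, 1L, 0L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  colnames(codes) <- c("s1", "s2", "s3")
  gm <- make_gm(codes)
  sc <- count_score(gm, c("s1", "s2", "s3"))
  expect_identical(as.integer(sc), c(3L, 6L, 0L))
  expect_true(all(sc >= 0 & sc <= 2 * 3))
})

test_that("count score is additive over disjoint SNP sets", {
  set.seed(6)
  codes <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6,
                  dimnames = list(NULL, paste0("s", 1:6)))
  gm <- make_gm(codes)
  a <- count_score(gm, c("s1", "s2"))
  b <- count_score(gm, c("s4", "s6"))
  ab <- count_score(gm, c("s1", "s2", "s4", "s6"))
  expect_identical(as.integer(ab), as.integer(a) + as.integer(b))
})

test_that("missing genotypes and empty sets are scoring errors", {
  codes <- matrix(c(1L, NA, 2L, 0L), 2, 2,
                  dimnames = list(NULL, c("s1", "s2")))
  gm <- make_gm(codes)
  expect_error(count_score(gm, c("s1", "s2")), "excluded")
  expect_error(count_score(gm, character(0)), "empty")
  expect_error(count_score(gm, "s9"), "not in genotype")
})

test_that("candidates rank by ascending p with documented tie-breaks", {
  assoc <- data.frame(
    predictor_id = c("a", "b", "c", "d"),
    p_wald = c(0.5, 0.01, 0.5, 0.5),
    odds_ratio = c(1.2, 1.5, 0.5, 1.2),
    stringsAsFactors = FALSE
  )
  # b first (smallest p); among ties |log OR| 0.693 (c) beats 0.182 (a, d);
  # a before d lexically
  expect_equal(rank_candidates(assoc), c("b", "c", "a", "d"))
})

test_that("a single candidate is accepted unconditionally", {
  set.seed(14)
  codes <- matrix(rbinom(300, 2, 0.4), ncol = 1,
                  dimnames = list(NULL, "s1"))
  gm <- make_gm(codes)
  y <- rbinom(300, 1, 0.5)
  assoc <- snp_association(gm[, "s1"], y, adjusted = FALSE,
                           predictor_id = "s1")
  model <- optimize_pgs(gm, y, covariates = NULL, assoc,
                        adjusted = FALSE)
  expect_equal(model$accepted, "s1")
  expect_true(model$trajectory$accepted[1])
  expect_error(optimize_pgs(gm, y, NULL, assoc[0, ], adjusted = FALSE),
               "empty candidate")
})

test_that("a SNP that weakens the score fit is recorded and excluded", {
  set.seed(25)
  n <- 600
  g1 <- rbinom(n, 2, 0.5)
  y <- rbinom(n, 1, plogis(-0.6 + 0.8 * g1))
  g2 <- rbinom(n, 2, 0.5) # pure noise diluting the score
  codes <- cbind(s1 = g1, s2 = g2)
  gm <- make_gm(codes)
  assoc <- rbind(
    snp_association(g1, y, adjusted = FALSE, predictor_id = "s1"),
    snp_association(g2, y, adjusted = FALSE, predictor_id = "s2")
  )
  model <- optimize_pgs(gm, y, NULL, assoc, adjusted = FALSE)
  # direct refits: the trial score must genuinely be worse
  p1 <- snp_association(count_score(gm, "s1"), y,
                        adjusted = FALSE)$p_wald
  p12 <- snp_association(count_score(gm, c("s1", "s2")), y,
                         adjusted = FALSE)$p_wald
  expect_gt(p12, p1)
  expect_equal(model$accepted, "s1")
  expect_false(model$trajectory$accepted[model$trajectory$snp_id == "s2"])
  expect_equal(model$trajectory$p_after[2], p12, tolerance = 1e-12)
})

test_that("optimization is deterministic and every acceptance improves both criteria", {
  co <- simulate_cohort(small_sim_config(seed = 61L, n = c(300L, 280L)))
  assoc <- association_table(co$genotypes, co$table,
                             outcomes = "general", adjusted = TRUE)
  m1 <- optimize_pgs(co$genotypes, co$table$ltpa_general, co$table, assoc)
  m2 <- optimize_pgs(co$genotypes, co$table$ltpa_general, co$table, assoc)
  expect_identical(m1$accepted, m2$accepted)
  expect_identical(m1$trajectory, m2$trajectory)
  acc <- m1$trajectory[-1, ][m1$trajectory$accepted[-1], ]
  if (nrow(acc)) {
    expect_true(all(acc$p_after < acc$p_before))
    expect_true(all(acc$r2_after > acc$r2_before))
  }
  expect_setequal(union(m1$accepted, m1$candidate_order),
                  m1$candidate_order)
})

test_that("uniform integer scores merge into the oracle's four tail groups", {
  scores <- rep(0:5, each = 100)
  cats <- categorize_scores(scores, n_groups = 4, min_group_frac = 0.10)
  expect_equal(levels(cats), c("0-1", "2", "3", "4-5"))
  expect_equal(levels(cats),
               oracle_merge_bins(scores, 4, 0.10))
  b <- attr(cats, "boundaries")
  expect_equal(b$n, c(200, 100, 100, 200))
  expect_true(all(b$n / length(scores) >= 0.10))
})

test_that("categorization handles identity, skew and degenerate inputs", {
  four <- rep(1:4, each = 30)
  expect_equal(levels(categorize_scores(four, 4)),
               c("1", "2", "3", "4"))
  expect_error(categorize_scores(rep(2L, 50), 4), "constant")
  expect_warning(categorize_scores(rep(1:3, each = 20), 4),
                 "distinct score values")
  # right-skewed scores: merged label set must match the oracle
  set.seed(9)
  skew <- rbinom(500, 8, 0.25)
  got <- categorize_scores(skew, 4, 0.10)
  expect_equal(levels(got), oracle_merge_bins(skew, 4, 0.10))
})
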