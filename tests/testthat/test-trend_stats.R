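test_that("a perfectly separated ordered layout gives JT at its maximum", {
  values <- c(1, 2, 3, 4, 5, 6)
  groups <- factor(rep(c("g1", "g2", "g3"), each = 2),
                   levels = c("g1", "g2", "g3"))
  res <- jonckheere_terpstra(values, groups)
  expect_equal(res$statistic, 12)
  expect_equal(res$max_pairs, 12)
  expect_equal(res$method, "exact enumeration")
  expect_equal(res$p_increasing, 1 / 90, tolerance = 1e-12)
})

test_that("tie saturation and group-order reversal behave symmetrically", {
  same <- jonckheere_terpstra(rep(3, 12), rep(1:3, each = 4))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  set.seed(2)
  v <- rnorm(60)
  g <- factor(rep(c("a", "b", "c"), each = 20),
              levels = c("a", "b", "c"))
  fwd <- jonckheere_terpstra(v, g)
  rev <- jonckheere_terpstra(v, factor(g, levels = c("c", "b", "a")))
  expect_equal(fwd$z, -rev$z, tolerance = 1e-9)
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  expect_error(jonckheere_terpstra(v, rep("a", 60)), "two groups")
})

test_that("JT exact p matches the independent enumeration oracle", {
  set.seed(31)
  for (i in 1:6) {
    sizes <- sample(2:4, 3, replace = TRUE)
    v <- sample(1:5, sum(sizes), replace = TRUE) # ties likely
    g <- rep(paste0("g", 1:3), sizes)
    got <- jonckheere_terpstra(v, factor(g, levels = paste0("g", 1:3)))
    want <- oracle_jt_exact(v, g)
    expect_equal(got$statistic, want$stat)
    expect_equal(got$p, want$p_two_sided, tolerance = 1e-9)
    expect_equal(got$p_increasing, want$p_increasing, tolerance = 1e-9)
  }
})

test_that("JT normal approximation tracks the exact mid-p at small n", {
  # the null distribution is discrete, so the approximation is judged
  # against the exact mid-p (half the atom at the observed value), the
  # standard continuity convention for discrete statistics
  set.seed(47)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    sizes <- sample(3:5, k, replace = TRUE)
    if (sum(sizes) > 12) sizes <- pmin(sizes, 4)
    v <- rnorm(sum(sizes)) # continuous, untied
    g <- factor(rep(paste0("g", seq_len(k)), sizes))
    ap <- jonckheere_terpstra(v, g, exact_n_max = 0L)
    expect_equal(ap$method, "normal approximation")
    ex <- oracle_jt_exact(v, as.character(g))
    eps <- 1e-9
    mid <- mean(ex$dist > ex$stat + eps) +
      0.5 * mean(abs(ex$dist - ex$stat) <= eps)
    expect_lt(abs(mid - ap$p_increasing), 0.02 + 1e-12)
  }
})

test_that("Mann-Whitney matches hand cases and the enumeration oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  ident <- mann_whitney_u(c(2, 2, 5), c(2, 2, 5))
  expect_equal(ident$p, 1)

  set.seed(53)
  for (i in 1:10) {
    nx <- sample(2:4, 1)
    ny <- sample(2:4, 1)
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE)
    got <- mann_whitney_u(x, y)
    want <- oracle_mw(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    swapped <- mann_whitney_u(y, x)
    expect_equal(got$p, swapped$p, tolerance = 1e-9)
  }
})

test_that("large-sample Mann-Whitney agrees with the base-R reference", {
  set.seed(59)
  x <- rlnorm(80)
  y <- rlnorm(70, meanlog = 0.4)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("two-step normalization preserves ranks and moments, gains normality", {
  set.seed(61)
  x <- rlnorm(400)
  z <- templeton_normalize(x)
  expect_equal(cor(x, z, method = "spearman"), 1)
  expect_equal(mean(z), mean(x), tolerance = 1e-9)
  expect_equal(sd(z), sd(x), tolerance = 1e-9)
  expect_error(templeton_normalize(rep(1, 10)), "constant")
  expect_error(templeton_normalize(c(1, 2)), "at least 3")

  ok <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    shapiro.test(templeton_normalize(rlnorm(5000)))$p.value >= 0.01
  }, NA)
  expect_gte(mean(ok), 0.95)
})

test_that("Bonferroni threshold divides alpha and rounds for display", {
  b3 <- bonferroni_alpha(0.05, 3)
  expect_equal(b3$displayed, 0.017)
  expect_equal(b3$threshold, 0.05 / 3)
  expect_equal(bonferroni_alpha(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_alpha(0.05, 7)$threshold, 0.05 / 7)
  expect_error(bonferroni_alpha(0.05, 0), "n_polymorphisms")
})

test_that("contingency chi-square matches the textbook oracle", {
  # vehicle use among men: 118/145 vs 21/79
  tab <- rbind(c(118, 145 - 118), c(21, 79 - 21))
  got <- chisq_contingency(tab)
  expect_lt(got$p, 0.001)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)

  same <- chisq_contingency(rbind(c(10, 20, 30), c(10, 20, 30)))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(chisq_contingency(rbind(c(0, 0), c(3, 4))), "marginal")

  set.seed(67)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 30) + 1, 2, 3)
    got <- chisq_contingency(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("trend tables summarise categories and flag corrected significance", {
  co <- simulate_cohort(small_sim_config(seed = 71L, n = c(320L, 300L)))
  sc <- count_score(co$genotypes,
                    c("rs10887741", "rs6022999", "rs7023003"))
  cats <- categorize_scores(sc, 4)
  tt <- trend_table(co$table, cats, bonferroni_n = 3)
  expect_equal(sort(unique(tt$outcome)), sort(ltpa_outcomes()))
  expect_true(all(tt$ci95_low <= tt$mean & tt$mean <= tt$ci95_high))
  expect_true(all(tt$n >= 1))
  corr <- attr(tt, "bonferroni")
  expect_equal(tt$significant_after_correction,
               tt$p_trend < corr$threshold)
  # participants-only variant drops the zero-inflation mass
  tp <- trend_table(co$table, cats, include_zeros = FALSE,
                    bonferroni_n = 3)
  n_general <- sum(co$table$ltpa_general)
  expect_equal(sum(tp$n[tp$outcome == "general"]), n_general)
})
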