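test_that("degenerate allele frequencies produce constant genotypes", {
  cfg <- sim_config(n_per_population = c(100L, 50L), seed = 1L)
  cfg$effect_allele_freq[1, ] <- 0
  cfg$effect_allele_freq[2, ] <- 1
  g1 <- simulate_genotypes(cfg, 1L)
  g2 <- simulate_genotypes(cfg, 2L)
  expect_true(all(g1 == 0L))
  expect_true(all(g2 == 2L))
})

test_that("genotype proportions follow binomial expectation at freq 0.5", {
  cfg <- sim_config(n_per_population = c(10000L, 10L), seed = 11L)
  cfg$effect_allele_freq[1, ] <- 0.5
  g <- simulate_genotypes(cfg, 1L)
  props <- table(factor(g[, 1], levels = 0:2)) / nrow(g)
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / nrow(g))
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("empirical allele frequency converges to the configured one", {
  cfg <- sim_config(n_per_population = c(5000L, 10L), seed = 5L)
  g <- simulate_genotypes(cfg, 1L)
  f_cfg <- cfg$effect_allele_freq[1, ]
  f_emp <- colMeans(g) / 2
  tol <- 3 * sqrt(f_cfg * (1 - f_cfg) / (2 * nrow(g)))
  expect_true(all(abs(f_emp - f_cfg) < tol))
})

test_that("unknown population index and invalid parameters error", {
  cfg <- sim_config(seed = 1L)
  expect_error(simulate_genotypes(cfg, 3L), "population index")
  expect_error(simulate_covariates(cfg, 0L), "population index")
  bad <- default_covariate_params()
  bad$age_sd <- c(0, 11.5)
  expect_error(sim_config(covariate_params = bad), "SD")
  expect_error(sim_config(effect_allele_freq = matrix(1.2, 2, 7)),
               "\\[0, 1\\]")
  bad_edu <- default_covariate_params()
  bad_edu$education_probs[[1]] <- c(0.5, 0.2, 0.2)
  expect_error(sim_config(covariate_params = bad_edu), "summing to 1")
})

test_that("outcome model referencing an absent SNP or covariate errors", {
  om <- default_outcome_model(ltpa_panel())
  om$general$snp_beta <- c(om$general$snp_beta, rs999 = 0.1)
  expect_error(sim_config(outcome_model = om), "absent SNP")
  om2 <- default_outcome_model(ltpa_panel())
  om2$walking$covar_beta <- c(om2$walking$covar_beta, income = 0.1)
  expect_error(sim_config(outcome_model = om2), "absent covariate")
})

test_that("covariate draws are reproducible and respect stated shares", {
  cfg <- sim_config(n_per_population = c(5000L, 10L), seed = 3L)
  cfg$covariate_params$education_probs[[1]] <- c(0.9, 0.1, 0.0)
  c1 <- simulate_covariates(cfg, 1L)
  c2 <- simulate_covariates(cfg, 1L)
  expect_identical(c1, c2)
  shares <- table(factor(c1$education, levels = 0:2)) / nrow(c1)
  se <- sqrt(c(0.9, 0.1, 0) * c(0.1, 0.9, 1) / nrow(c1))
  expect_true(all(abs(shares - c(0.9, 0.1, 0)) <= 3 * se))
  expect_true(all(c1$age >= 20 & c1$age <= 64))
  expect_true(all(c1$bmi >= 15 & c1$bmi <= 60))
})

test_that("null outcome model gives 50% prevalence", {
  cfg <- sim_config(n_per_population = c(10000L, 10L), seed = 9L)
  for (oc in ltpa_outcomes()) {
    cfg$outcome_model[[oc]]$intercept <- 0
    cfg$outcome_model[[oc]]$snp_beta[] <- 0
    cfg$outcome_model[[oc]]$covar_beta[] <- 0
  }
  g <- simulate_genotypes(cfg, 1L)
  cv <- simulate_covariates(cfg, 1L)
  ph <- simulate_phenotypes(g, cv, cfg)
  prev <- mean(ph$ltpa_general)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / nrow(ph)))
})

test_that("activity volume is zero exactly for non-participants", {
  co <- simulate_cohort(small_sim_config(seed = 21L))
  for (oc in ltpa_outcomes()) {
    y <- co$table[[paste0("ltpa_", oc)]]
    met <- co$table[[paste0("met_", oc)]]
    days <- co$table[[paste0("days_", oc)]]
    expect_true(all(met[y == 0] == 0))
    expect_true(all(days[y == 0] == 0))
    expect_true(all(met[y == 1] > 0))
    expect_true(all(days >= 0 & days <= 7))
  }
  expect_true(all(unclass(co$genotypes) %in% 0:2))
})

test_that("a larger per-allele effect weakly increases carrier prevalence", {
  base <- sim_config(n_per_population = c(50000L, 10L), seed = 17L)
  prev_for <- function(beta) {
    cfg <- base
    cfg$outcome_model$general$snp_beta[] <- 0
    cfg$outcome_model$general$snp_beta["rs10887741"] <- beta
    g <- simulate_genotypes(cfg, 1L)
    cv <- simulate_covariates(cfg, 1L)
    ph <- simulate_phenotypes(g, cv, cfg)
    carriers <- g[, "rs10887741"] > 0
    mean(ph$ltpa_general[carriers])
  }
  p0 <- prev_for(0)
  p1 <- prev_for(log(1.5))
  p2 <- prev_for(log(2.5))
  expect_true(p1 >= p0)
  expect_true(p2 >= p1)
})

test_that("the whole cohort is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 33L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
})

test_that("inbreeding option depresses heterozygosity for the HWE path", {
  cfg <- sim_config(n_per_population = c(4000L, 10L),
                    inbreeding = c(0.5, 0), seed = 19L)
  g <- simulate_genotypes(cfg, 1L)
  f <- cfg$effect_allele_freq[1, 1]
  het <- mean(g[, 1] == 1L)
  expect_lt(het, 2 * f * (1 - f) * 0.75)
})
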