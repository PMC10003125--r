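#' Simulation configuration for a two-population LTPA cohort
#'
#' Bundles everything the generator needs: per-population sample sizes,
#' the SNP panel with per-population effect-allele frequencies, covariate
#' distributions, the logistic outcome models for the four LTPA outcomes
#' (in general, vigorous, moderate, walking), and the activity-volume
#' models (log-normal MET-min/week and binomial days/week, both
#' conditional on participation). Defaults reproduce the structure of the
#' two study populations: 330 Hungarian-general and 314 Roma adults aged
#' 20-64 genotyped at seven candidate SNPs, with divergent allele
#' frequencies at four of them and small per-allele effects on
#' participation (odds ratios around 1.2-1.5 for the three score SNPs).
#'
#' Covariate coefficients act on centred scales: age - 42 years,
#' BMI - 27 kg/m^2, waist - 95 cm; sex (male), vehicle use and ethnicity
#' (second population) are 0/1 indicators; education is ordinal 0/1/2.
#'
#' @param n_per_population integer vector of length 2 (both >= 1).
#' @param panel a [snp_panel()].
#' @param effect_allele_freq numeric matrix, 2 rows (populations) x
#'   one column per panel SNP, entries in \[0, 1\].
#' @param covariate_params list with per-population entries `age_mean`,
#'   `age_sd`, `sex_prop` (male proportion), `education_probs` (3-vector
#'   summing to 1), `vehicle_prob`, `bmi_mean`, `bmi_sd`, `waist_mean`,
#'   `waist_sd`; vectors of length 2.
#' @param outcome_model named list, one entry per outcome, each with
#'   `intercept` (log-odds), `snp_beta` (named per-allele log-OR vector,
#'   names in the panel), and `covar_beta` (named vector over `age`,
#'   `sex`, `education`, `vehicle`, `bmi`, `waist`, `ethnicity`).
#' @param met_model named list per outcome: `meanlog`, `sdlog` of
#'   MET-min/week given participation.
#' @param days_model named list per outcome: `mean_days` in (0, 7\];
#'   days/week given participation is binomial(7, mean_days/7).
#' @param inbreeding inbreeding coefficient F in \[0, 1\]: length-2
#'   vector (one per population, applied to all SNPs) or a 2 x SNP
#'   matrix for per-SNP control. Default 0 = Hardy-Weinberg
#'   proportions; nonzero values generate heterozygote-deficient
#'   genotypes, used to exercise the HWE exclusion path.
#' @param seed master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_population = c(330L, 314L),
                       panel = ltpa_panel(),
                       effect_allele_freq = default_allele_freqs(panel),
                       covariate_params = default_covariate_params(),
                       outcome_model = default_outcome_model(panel),
                       met_model = default_met_model(),
                       days_model = default_days_model(),
                       inbreeding = c(0, 0),
                       seed = 20230226L) {
  n_per_population <- as.integer(n_per_population)
  if (length(n_per_population) != 2L || any(n_per_population < 1L)) {
    stop("n_per_population must be two integers >= 1")
  }
  effect_allele_freq <- as.matrix(effect_allele_freq)
  if (nrow(effect_allele_freq) != 2L ||
      ncol(effect_allele_freq) != nrow(panel)) {
    stop("effect_allele_freq must be 2 populations x panel SNPs")
  }
  assert_probability(effect_allele_freq, "effect allele frequencies")
  colnames(effect_allele_freq) <- panel$snp_id
  for (p in 1:2) {
    ep <- covariate_params$education_probs[[p]]
    if (length(ep) != 3L || abs(sum(ep) - 1) > 1e-8 || any(ep < 0)) {
      stop("education probabilities must be 3 non-negative values summing to 1")
    }
  }
  with(covariate_params, {
    if (any(c(age_sd, bmi_sd, waist_sd) <= 0)) {
      stop("covariate SDs must be positive")
    }
    assert_probability(c(sex_prop, vehicle_prob), "covariate probabilities")
  })
  assert_probability(inbreeding, "inbreeding coefficients")
  if (is.matrix(inbreeding)) {
    if (nrow(inbreeding) != 2L || ncol(inbreeding) != nrow(panel)) {
      stop("inbreeding matrix must be 2 populations x panel SNPs")
    }
    colnames(inbreeding) <- panel$snp_id
  } else {
    if (length(inbreeding) != 2L) {
      stop("inbreeding must be length 2 (or a 2 x SNP matrix)")
    }
    inbreeding <- matrix(inbreeding, nrow = 2L, ncol = nrow(panel),
                         dimnames = list(NULL, panel$snp_id))
  }
  for (oc in ltpa_outcomes()) {
    m <- outcome_model[[oc]]
    if (is.null(m)) stop("outcome_model missing outcome: ", oc)
    extra <- setdiff(names(m$snp_beta), panel$snp_id)
    if (length(extra)) {
      stop("outcome_model references absent SNP(s): ",
           paste(extra, collapse = ", "))
    }
    extra <- setdiff(names(m$covar_beta), sim_covariate_names())
    if (length(extra)) {
      stop("outcome_model references absent covariate(s): ",
           paste(extra, collapse = ", "))
    }
    dm <- days_model[[oc]]
    if (dm$mean_days <= 0 || dm$mean_days > 7) {
      stop("mean_days must lie in (0, 7]")
    }
    if (met_model[[oc]]$sdlog <= 0) stop("met sdlog must be positive")
  }
  structure(list(
    n_per_population = n_per_population,
    panel = panel,
    effect_allele_freq = effect_allele_freq,
    covariate_params = covariate_params,
    outcome_model = outcome_model,
    met_model = met_model,
    days_model = days_model,
    inbreeding = inbreeding,
    population_labels = c("pop1", "pop2"),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
ltpa_outcomes <- function() c("general", "vigorous", "moderate", "walking")

#' @keywords internal
sim_covariate_names <- function() {
  c("age", "sex", "education", "vehicle", "bmi", "waist", "ethnicity")
}

#' Default per-population effect-allele frequencies
#'
#' Population 1 plays the general-population role, population 2 the Roma
#' role. Frequencies are chosen so that four SNPs (rs10252228, rs12612420,
#' rs459465, rs10887741) diverge clearly between populations and the three
#' score SNPs give expected unweighted scores near 2.7 vs 2.2.
#'
#' @param panel a [snp_panel()].
#' @return 2 x nSNP probability matrix.
#' @export
default_allele_freqs <- function(panel) {
  f <- rbind(
    pop1 = c(rs10252228 = 0.45, rs12612420 = 0.35, rs7023003 = 0.35,
             rs459465 = 0.30, rs6022999 = 0.45, rs10887741 = 0.55,
             rs8097348 = 0.30),
    pop2 = c(rs10252228 = 0.30, rs12612420 = 0.22, rs7023003 = 0.30,
             rs459465 = 0.45, rs6022999 = 0.37, rs10887741 = 0.42,
             rs8097348 = 0.28)
  )
  f[, panel$snp_id, drop = FALSE]
}

#' @keywords internal
default_covariate_params <- function() {
  list(
    age_mean = c(44, 43), age_sd = c(11.5, 11.5),
    sex_prop = c(0.44, 0.25),
    education_probs = list(c(0.20, 0.61, 0.19), c(0.88, 0.115, 0.005)),
    vehicle_prob = c(0.74, 0.25),
    bmi_mean = c(27.3, 27.5), bmi_sd = c(5, 5),
    waist_mean = c(96.5, 95.0), waist_sd = c(13, 13)
  )
}

#' @keywords internal
default_outcome_model <- function(panel) {
  zero_beta <- stats::setNames(rep(0, nrow(panel)), panel$snp_id)
  causal <- function(...) {
    b <- zero_beta
    v <- c(...)
    b[names(v)] <- v
    b
  }
  covar <- function(age, sex, education, vehicle, bmi, waist, ethnicity) {
    c(age = age, sex = sex, education = education, vehicle = vehicle,
      bmi = bmi, waist = waist, ethnicity = ethnicity)
  }
  list(
    general = list(
      intercept = -0.25,
      snp_beta = causal(rs10887741 = log(1.48), rs6022999 = log(1.29),
                        rs7023003 = log(1.25)),
      covar_beta = covar(-0.010, 0.00, 0.25, 0.20, -0.02, -0.005, -0.10)
    ),
    vigorous = list(
      intercept = -1.15,
      snp_beta = causal(rs10887741 = log(1.25)),
      covar_beta = covar(-0.020, 0.30, 0.30, 0.10, -0.02, -0.005, -1.20)
    ),
    moderate = list(
      intercept = -0.70,
      snp_beta = causal(rs10887741 = log(1.23)),
      covar_beta = covar(-0.010, 0.10, 0.25, 0.10, -0.02, -0.005, -0.80)
    ),
    walking = list(
      intercept = 0.20,
      snp_beta = causal(rs10887741 = log(1.15)),
      covar_beta = covar(0.005, -0.20, 0.10, 0.00, 0.00, 0.000, -0.10)
    )
  )
}

#' @keywords internal
default_met_model <- function() {
  list(
    general = list(meanlog = 7.0, sdlog = 1.0),
    vigorous = list(meanlog = 6.3, sdlog = 1.0),
    moderate = list(meanlog = 6.0, sdlog = 1.0),
    walking = list(meanlog = 5.6, sdlog = 0.9)
  )
}

#' @keywords internal
default_days_model <- function() {
  list(
    general = list(mean_days = 3.5),
    vigorous = list(mean_days = 2.2),
    moderate = list(mean_days = 2.5),
    walking = list(mean_days = 3.5)
  )
}

#' Simulate a genotype matrix for one population
#'
#' Each SNP is sampled independently; under the default inbreeding
#' coefficient F = 0 a genotype is the sum of two Bernoulli(freq) allele
#' draws, so within-population genotype frequencies follow Hardy-Weinberg
#' proportions. With F > 0, heterozygosity is reduced to 2pq(1 - F).
#'
#' @param config a [sim_config()].
#' @param population_index 1 or 2.
#' @param n optional override of the configured sample size.
#' @param seed optional override of the stage seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, population_index, n = NULL,
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!population_index %in% c(1L, 2L)) {
    stop("unknown population index: ", population_index)
  }
  n <- n %||% config$n_per_population[population_index]
  seed <- seed %||% child_seed(config$seed, population_index)
  set.seed(seed)
  freqs <- config$effect_allele_freq[population_index, ]
  codes <- vapply(seq_along(freqs), function(j) {
    f <- freqs[j]
    # genotype probabilities under per-SNP inbreeding coefficient F
    F <- config$inbreeding[population_index, j]
    p2 <- f^2 + F * f * (1 - f)
    p1 <- 2 * f * (1 - f) * (1 - F)
    sample.int(3L, n, replace = TRUE,
               prob = c(1 - p1 - p2, p1, p2)) - 1L
  }, integer(n))
  if (n == 1L) codes <- matrix(codes, nrow = 1L)
  colnames(codes) <- names(freqs)
  genotype_matrix(codes, config$panel,
                  population = rep(config$population_labels[population_index], n))
}

#' Simulate the covariate block for one population
#'
#' Age, BMI and waist circumference are truncated normals (age bounded to
#' the recruitment window 20-64 years, BMI to 15-60 kg/m^2, waist to
#' 50-200 cm); sex and vehicle use are Bernoulli; education is a 3-level
#' multinomial coded 0/1/2 (primary/secondary/higher).
#'
#' @inheritParams simulate_genotypes
#' @return data.frame with columns `population`, `age`, `sex`,
#'   `education`, `vehicle`, `bmi`, `waist`, `ethnicity`.
#' @export
simulate_covariates <- function(config, population_index, n = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!population_index %in% c(1L, 2L)) {
    stop("unknown population index: ", population_index)
  }
  n <- n %||% config$n_per_population[population_index]
  seed <- seed %||% child_seed(config$seed, 10L + population_index)
  set.seed(seed)
  cp <- config$covariate_params
  p <- population_index
  rtruncnorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  data.frame(
    population = rep(config$population_labels[p], n),
    age = rtruncnorm(n, cp$age_mean[p], cp$age_sd[p], 20, 64),
    sex = stats::rbinom(n, 1L, cp$sex_prop[p]),
    education = sample(0:2, n, replace = TRUE,
                       prob = cp$education_probs[[p]]),
    vehicle = stats::rbinom(n, 1L, cp$vehicle_prob[p]),
    bmi = rtruncnorm(n, cp$bmi_mean[p], cp$bmi_sd[p], 15, 60),
    waist = rtruncnorm(n, cp$waist_mean[p], cp$waist_sd[p], 50, 200),
    ethnicity = rep(p - 1L, n),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
outcome_linear_predictor <- function(genotypes, covariates, model) {
  eta <- rep(model$intercept, nrow(covariates))
  for (s in names(model$snp_beta)) {
    b <- model$snp_beta[[s]]
    if (b != 0) eta <- eta + b * as.numeric(genotypes[, s])
  }
  cb <- model$covar_beta
  eta +
    cb[["age"]] * (covariates$age - 42) +
    cb[["sex"]] * covariates$sex +
    cb[["education"]] * covariates$education +
    cb[["vehicle"]] * covariates$vehicle +
    cb[["bmi"]] * (covariates$bmi - 27) +
    cb[["waist"]] * (covariates$waist - 95) +
    cb[["ethnicity"]] * covariates$ethnicity
}

#' Simulate LTPA phenotypes given genotypes and covariates
#'
#' Each of the four binary outcomes is Bernoulli with probability
#' inverse-logit of its configured linear predictor. Conditional on
#' participation, MET-min/week is log-normal and days/week is
#' binomial(7, mean_days/7); both are exactly zero for non-participants
#' (zero-inflation contract).
#'
#' @param genotypes a [genotype_matrix()].
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @param seed optional stage seed override.
#' @return `covariates` extended with `ltpa_<outcome>`, `met_<outcome>`
#'   and `days_<outcome>` columns.
#' @export
simulate_phenotypes <- function(genotypes, covariates, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            nrow(genotypes) == nrow(covariates))
  seed <- seed %||% child_seed(config$seed, 20L)
  set.seed(seed)
  out <- covariates
  n <- nrow(covariates)
  for (oc in ltpa_outcomes()) {
    eta <- outcome_linear_predictor(genotypes, covariates,
                                    config$outcome_model[[oc]])
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    mm <- config$met_model[[oc]]
    met <- ifelse(y == 1L,
                  stats::rlnorm(n, mm$meanlog, mm$sdlog), 0)
    days <- ifelse(y == 1L,
                   stats::rbinom(n, 7L, config$days_model[[oc]]$mean_days / 7),
                   0L)
    out[[paste0("ltpa_", oc)]] <- y
    out[[paste0("met_", oc)]] <- met
    out[[paste0("days_", oc)]] <- as.integer(days)
  }
  out
}

#' Simulate a complete two-population cohort
#'
#' Runs the genotype, covariate and phenotype stages for both populations
#' under the child-seed scheme and returns the combined cohort.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort` with elements `genotypes`
#'   (a [genotype_matrix()] over both populations) and `table`
#'   (the phenotype/covariate data.frame, one row per individual).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g1 <- simulate_genotypes(config, 1L)
  g2 <- simulate_genotypes(config, 2L)
  codes <- rbind(unclass(g1), unclass(g2))
  attributes(codes) <- list(dim = dim(codes))
  gm <- genotype_matrix(codes, config$panel,
                        population = c(gm_population(g1), gm_population(g2)))
  covs <- rbind(simulate_covariates(config, 1L),
                simulate_covariates(config, 2L))
  tab <- simulate_phenotypes(gm, covs, config)
  tab <- cbind(id = sprintf("ind%04d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(gm) <- tab$id
  structure(list(genotypes = gm, table = tab), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals (%s), %d SNPs\n",
              nrow(x$table),
              paste(table(x$table$population), collapse = " + "),
              ncol(x$genotypes)))
  invisible(x)
}

#' Simulate a pair of linked loci from phased haplotypes
#'
#' Draws 2n haplotypes from the four two-locus haplotype frequencies
#' (AB, Ab, aB, ab, where A/B are the effect alleles) and collapses each
#' individual's two haplotypes to unphased genotype codes. Exists to
#' exercise the EM linkage-disequilibrium estimator against known truth.
#'
#' @param n individuals.
#' @param hap_freqs numeric length-4 vector (AB, Ab, aB, ab) summing to 1.
#' @param seed integer seed.
#' @return list with integer vectors `g_a`, `g_b` and the truth
#'   `hap_freqs`.
#' @export
simulate_linked_pair <- function(n, hap_freqs, seed = 1L) {
  stopifnot(length(hap_freqs) == 4L, abs(sum(hap_freqs) - 1) < 1e-8,
            all(hap_freqs >= 0))
  set.seed(seed)
  hap <- sample.int(4L, 2L * n, replace = TRUE, prob = hap_freqs)
  h1 <- hap[seq_len(n)]
  h2 <- hap[n + seq_len(n)]
  # haplotypes 1,2 carry allele A at locus a; 1,3 carry allele B at locus b
  g_a <- (h1 %in% c(1L, 2L)) + (h2 %in% c(1L, 2L))
  g_b <- (h1 %in% c(1L, 3L)) + (h2 %in% c(1L, 3L))
  list(g_a = as.integer(g_a), g_b = as.integer(g_b),
       hap_freqs = stats::setNames(hap_freqs, c("AB", "Ab", "aB", "ab")))
}
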