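#' Run configuration
#'
#' Exactly one input source: either `genotype_path` + `phenotype_path`,
#' or a simulation block (a [sim_config()]). Remaining fields control the
#' analysis: significance levels, score categorization, output directory.
#'
#' @param simulation a [sim_config()], or `NULL` when reading files.
#' @param genotype_path,phenotype_path input files (VCF/CSV and CSV).
#' @param panel a [snp_panel()] (required with file input).
#' @param hwe_alpha per-population HWE exclusion threshold.
#' @param alpha nominal significance level.
#' @param n_groups,min_group_frac score categorization parameters.
#' @param output_dir directory for report files, or `NULL` to skip
#'   writing.
#' @param seed master seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, genotype_path = NULL,
                       phenotype_path = NULL, panel = NULL,
                       hwe_alpha = 0.05, alpha = 0.05, n_groups = 4,
                       min_group_frac = 0.10, output_dir = NULL,
                       seed = 20230226L) {
  has_files <- !is.null(genotype_path) || !is.null(phenotype_path)
  if (is.null(simulation) == !has_files) {
    stop("exactly one of simulation block or input paths must be given")
  }
  if (has_files && (is.null(genotype_path) || is.null(phenotype_path) ||
                    is.null(panel))) {
    stop("file input needs genotype_path, phenotype_path and panel")
  }
  structure(list(
    simulation = simulation, genotype_path = genotype_path,
    phenotype_path = phenotype_path, panel = panel,
    hwe_alpha = hwe_alpha, alpha = alpha, n_groups = n_groups,
    min_group_frac = min_group_frac, output_dir = output_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value schema (`schema_version: 1`). Recognised keys:
#' `genotype_path`, `phenotype_path`, `simulate` (logical),
#' `n_per_population`, `hwe_alpha`, `alpha`, `n_groups`,
#' `min_group_frac`, `output_dir`, `seed`. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("schema_version", "genotype_path", "phenotype_path",
             "simulate", "n_per_population", "hwe_alpha", "alpha",
             "n_groups", "min_group_frac", "output_dir", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!identical(raw$schema_version %||% 1L, 1L) &&
      !identical(raw$schema_version, 1)) {
    stop("unsupported schema_version")
  }
  sim <- NULL
  if (isTRUE(raw$simulate)) {
    sim <- sim_config(
      n_per_population = raw$n_per_population %||% c(330L, 314L),
      seed = raw$seed %||% 20230226L
    )
  }
  run_config(
    simulation = sim,
    genotype_path = raw$genotype_path,
    phenotype_path = raw$phenotype_path,
    panel = if (is.null(sim)) ltpa_panel() else NULL,
    hwe_alpha = raw$hwe_alpha %||% 0.05,
    alpha = raw$alpha %||% 0.05,
    n_groups = raw$n_groups %||% 4,
    min_group_frac = raw$min_group_frac %||% 0.10,
    output_dir = raw$output_dir,
    seed = raw$seed %||% 20230226L
  )
}

#' Score association table across outcomes (univariate and adjusted)
#'
#' @param scores integer score vector from [count_score()].
#' @param table phenotype data.frame aligned with `scores`.
#' @param outcomes outcome names.
#' @return data.frame, one row per outcome x adjustment.
#' @export
score_association_table <- function(scores, table,
                                    outcomes = ltpa_outcomes()) {
  rows <- list()
  for (oc in outcomes) {
    y <- table[[paste0("ltpa_", oc)]]
    for (adj in c(FALSE, TRUE)) {
      rows[[paste(oc, adj)]] <- snp_association(
        scores, y, covariates = table, adjusted = adj,
        predictor_id = "oPGS", outcome_id = oc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full candidate-SNP to trend-analysis pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) panel QC with HWE-based
#' exclusion, pairwise LD, between-population frequency tests and power;
#' (3) exclusion of individuals with any missing genotype; (4) adjusted
#' per-SNP logistic association for each LTPA outcome; (5) forward
#' score optimization on general LTPA; (6) score association per outcome
#' (univariate and adjusted); (7) score categorization and
#' Jonckheere-Terpstra trend tables for MET-min/week and days/week (both
#' including and excluding non-participants); (8) per-population score
#' distribution and Mann-Whitney comparison. Outputs are deterministic
#' under a fixed config seed. When `output_dir` is set, TSV reports and
#' a JSON run summary are written.
#'
#' @param config a [run_config()].
#' @return list of class `ltpa_run` with all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$simulation)) {
      simulate_cohort(config$simulation)
    } else {
      gm <- read_genotypes(config$genotype_path, config$panel)
      tab <- read_phenotypes(config$phenotype_path)
      if (nrow(gm) != nrow(tab)) {
        stop("genotype and phenotype tables have different sizes")
      }
      gm2 <- genotype_matrix(unclass(gm)[, , drop = FALSE], config$panel,
                             population = tab$population)
      rownames(gm2) <- tab$id
      structure(list(genotypes = gm2, table = tab), class = "cohort")
    }
  })
  qc <- stage("qc", qc_report(cohort$genotypes,
                              hwe_alpha = config$hwe_alpha,
                              alpha = config$alpha))
  ld <- stage("ld", ld_matrix(cohort$genotypes))
  kept_snps <- qc$snp_id[!qc$excluded]
  if (length(kept_snps) == 0L) stop("pipeline stage 'qc': all SNPs excluded")
  panel_kept <- gm_panel(cohort$genotypes)
  panel_kept <- panel_kept[panel_kept$snp_id %in% kept_snps, ]
  class(panel_kept) <- c("snp_panel", "data.frame")
  gm_kept <- genotype_matrix(
    unclass(cohort$genotypes)[, kept_snps, drop = FALSE], panel_kept,
    population = gm_population(cohort$genotypes))

  # individuals with any missing genotype are excluded from all
  # genotype-based analyses
  complete <- !apply(is.na(gm_kept), 1, any)
  gm_cc <- genotype_matrix(unclass(gm_kept)[complete, , drop = FALSE],
                           panel_kept,
                           population = gm_population(gm_kept)[complete])
  tab_cc <- cohort$table[complete, , drop = FALSE]

  assoc <- stage("association",
                 association_table(gm_cc, tab_cc, adjusted = TRUE))
  assoc_general <- assoc[assoc$outcome_id == "general", ]
  pgs <- stage("optimize",
               optimize_pgs(gm_cc, tab_cc$ltpa_general, tab_cc,
                            assoc_general))
  score_assoc <- stage("score_association",
                       score_association_table(pgs$scores, tab_cc))
  categories <- stage("categorize",
                      categorize_scores(pgs$scores, config$n_groups,
                                        config$min_group_frac))
  bonf_n <- length(pgs$accepted)
  trends <- stage("trend", list(
    met = trend_table(tab_cc, categories, value_prefix = "met_",
                      include_zeros = TRUE, bonferroni_n = bonf_n,
                      alpha = config$alpha),
    met_participants = trend_table(tab_cc, categories,
                                   value_prefix = "met_",
                                   include_zeros = FALSE,
                                   bonferroni_n = bonf_n,
                                   alpha = config$alpha),
    days = trend_table(tab_cc, categories, value_prefix = "days_",
                       include_zeros = TRUE, bonferroni_n = bonf_n,
                       alpha = config$alpha)
  ))
  score_dist <- stage("score_distribution", {
    pops <- unique(tab_cc$population)
    dist <- table(population = tab_cc$population, score = pgs$scores)
    by_pop <- lapply(pops, function(p) pgs$scores[tab_cc$population == p])
    names(by_pop) <- pops
    cmp <- if (length(pops) == 2L) {
      mann_whitney_u(by_pop[[1]], by_pop[[2]])
    } else NULL
    list(
      counts = dist,
      means = vapply(by_pop, mean, 0),
      sds = vapply(by_pop, stats::sd, 0),
      mann_whitney = cmp
    )
  })
  run <- structure(list(
    config = config,
    n_individuals = nrow(cohort$table),
    n_complete_genotypes = nrow(tab_cc),
    qc = qc, ld = ld, kept_snps = kept_snps,
    association = assoc, pgs = pgs, score_association = score_assoc,
    categories = categories,
    category_boundaries = attr(categories, "boundaries"),
    trends = trends, score_distribution = score_dist,
    bonferroni = bonferroni_alpha(config$alpha, bonf_n)
  ), class = "ltpa_run")
  if (!is.null(config$output_dir)) {
    write_run_outputs(run, config$output_dir)
  }
  run
}

#' @export
print.ltpa_run <- function(x, ...) {
  cat("LTPA polygenic-score run\n")
  cat(sprintf("  individuals: %d (%d with complete genotypes)\n",
              x$n_individuals, x$n_complete_genotypes))
  cat(sprintf("  SNPs kept after HWE QC: %d of %d\n",
              length(x$kept_snps), nrow(x$qc)))
  print(x$pgs)
  sa <- x$score_association
  g <- sa[sa$outcome_id == "general" & sa$adjusted, ]
  cat(sprintf("  adjusted score OR (general LTPA): %.2f (%.2f-%.2f), p = %.4g\n",
              g$odds_ratio, g$ci95_low, g$ci95_high, g$p_wald))
  cat(sprintf("  score means: %s\n",
              paste(sprintf("%s %.2f", names(x$score_distribution$means),
                            x$score_distribution$means), collapse = ", ")))
  invisible(x)
}

#' @keywords internal
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  w(run$qc, "qc_report.tsv")
  w(run$ld, "ld_pairs.tsv")
  w(run$association, "snp_association.tsv")
  w(run$pgs$trajectory, "pgs_trajectory.tsv")
  w(run$score_association, "score_association.tsv")
  w(run$trends$met, "trend_met.tsv")
  w(run$trends$met_participants, "trend_met_participants.tsv")
  w(run$trends$days, "trend_days.tsv")
  w(run$category_boundaries, "score_categories.tsv")
  summary <- list(
    seed = run$config$seed,
    n_individuals = run$n_individuals,
    n_complete_genotypes = run$n_complete_genotypes,
    kept_snps = run$kept_snps,
    accepted_snps = run$pgs$accepted,
    score_means = as.list(run$score_distribution$means),
    score_sds = as.list(run$score_distribution$sds),
    score_counts = as.data.frame(run$score_distribution$counts),
    bonferroni_displayed = run$bonferroni$displayed
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
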