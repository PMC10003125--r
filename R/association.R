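#' Maximum-likelihood logistic regression on a design matrix
#'
#' Fits by iteratively reweighted least squares (via [stats::glm.fit()])
#' and returns coefficients, the covariance matrix (inverse observed
#' information at the optimum) and the maximised Bernoulli log-likelihood.
#' The fit is validated: the score (gradient) norm must be below 1e-6 at
#' return, rank-deficient designs are an error, and complete or
#' quasi-complete separation is surfaced as an explicit error naming the
#' offending predictor rather than returned as a divergent fit.
#'
#' @param outcome 0/1 vector.
#' @param design numeric matrix including an intercept column; columns
#'   must be named.
#' @return list with `coefficients`, `covariance`, `loglik`, `n`.
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    stop("design matrix columns must be named")
  }
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- length(y)
  if (nrow(design) != n) stop("design rows must match outcome length")
  if (n <= ncol(design)) stop("more parameters than observations")
  if (all(y == 1) || all(y == 0)) {
    stop("separation: outcome is constant (all ",
         if (all(y == 1)) "1" else "0", ")")
  }
  non_const <- apply(design, 2, function(col) stats::var(col) > 0)
  intercept_like <- apply(design, 2, function(col) all(col == col[1]))
  if (sum(intercept_like) > 1 ||
      any(!non_const & !intercept_like)) {
    stop("constant non-intercept column in design")
  }
  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design matrix")
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  grad <- drop(crossprod(design, y - mu))
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  # separation shows as runaway coefficients, a near-perfect fit, or a
  # gradient the IRLS steps can no longer reduce
  if (any(abs(beta) > 15) || loglik > -1e-6 ||
      max(abs(grad)) > 1e-6 || !fit$converged) {
    worst <- colnames(design)[which.max(abs(beta))]
    stop("separation or non-convergence detected (predictor: ", worst, ")")
  }
  w <- mu * (1 - mu)
  info <- crossprod(design * w, design)
  covariance <- solve(info)
  dimnames(covariance) <- list(colnames(design), colnames(design))
  list(coefficients = stats::setNames(beta, colnames(design)),
       covariance = covariance, loglik = loglik, n = n)
}

#' Cox-Snell pseudo R-squared for nested logistic models
#'
#' R^2 = 1 - exp(2 (LL0 - LL1) / n). Requires the full model to nest the
#' null (LL1 >= LL0); the theoretical ceiling 1 - exp(2 LL0 / n) is below
#' 1 for binary outcomes.
#'
#' @param loglik_null,loglik_full log-likelihoods of nested fits.
#' @param n sample size.
#' @return R-squared value in \[0, 1).
#' @export
cox_snell_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop("n must be >= 1")
  if (loglik_full < loglik_null - 1e-10) {
    stop("loglik_full < loglik_null: models are not nested as assumed")
  }
  1 - exp(2 * (loglik_null - loglik_full) / n)
}

#' @keywords internal
adjusted_covariate_set <- function() {
  c("age", "sex", "ethnicity", "education", "vehicle", "bmi", "waist")
}

#' @keywords internal
build_design <- function(predictor, predictor_name, covariates = NULL,
                         covariate_set = adjusted_covariate_set()) {
  X <- cbind(`(Intercept)` = 1, predictor)
  colnames(X)[2] <- predictor_name
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariate_set, names(covariates))
    if (length(missing_cov)) {
      stop("covariate table lacks: ", paste(missing_cov, collapse = ", "))
    }
    X <- cbind(X, as.matrix(covariates[covariate_set]))
  }
  X
}

#' Logistic association of one predictor with a binary LTPA outcome
#'
#' Fits outcome ~ predictor (per effect allele for a SNP column, per
#' point for a score), optionally adjusted for the seven-covariate set
#' (age, sex, ethnicity, education, vehicle use, BMI, waist
#' circumference). Reports the per-unit odds ratio with 95% Wald CI and
#' p-value, log-likelihoods of the fitted and the predictor-free null
#' model (same covariates), and the Cox-Snell R-squared of the fitted
#' model against the intercept-only model.
#'
#' @param predictor numeric vector (0/1/2 genotype codes or integer
#'   scores); must not contain NA.
#' @param outcome 0/1 vector.
#' @param covariates data.frame with the adjustment covariates (required
#'   when `adjusted = TRUE`).
#' @param adjusted logical; adjust for the seven-covariate set.
#' @param predictor_id,outcome_id labels carried into the result.
#' @return one-row data.frame of class `association_result`.
#' @export
snp_association <- function(predictor, outcome, covariates = NULL,
                            adjusted = TRUE, predictor_id = "predictor",
                            outcome_id = "outcome") {
  if (anyNA(predictor)) {
    stop("predictor contains missing values; individuals with missing ",
         "genotypes must be excluded upstream")
  }
  if (stats::var(as.numeric(predictor)) == 0) {
    stop("monomorphic predictor '", predictor_id, "': no association fit")
  }
  if (adjusted && is.null(covariates)) {
    stop("adjusted fit requires covariates")
  }
  covset <- if (adjusted) adjusted_covariate_set() else character(0)
  X <- build_design(as.numeric(predictor), predictor_id,
                    if (adjusted) covariates else NULL, covset)
  fit <- fit_logistic(outcome, X)
  X0 <- X[, setdiff(colnames(X), predictor_id), drop = FALSE]
  fit0 <- fit_logistic(outcome, X0)
  null1 <- fit_logistic(outcome,
                        matrix(1, length(outcome), 1,
                               dimnames = list(NULL, "(Intercept)")))
  beta <- fit$coefficients[[predictor_id]]
  se <- sqrt(fit$covariance[predictor_id, predictor_id])
  z <- beta / se
  out <- data.frame(
    predictor_id = predictor_id,
    outcome_id = outcome_id,
    odds_ratio = exp(beta),
    ci95_low = exp(beta - 1.96 * se),
    ci95_high = exp(beta + 1.96 * se),
    p_wald = 2 * stats::pnorm(-abs(z)),
    loglik_full = fit$loglik,
    loglik_null = fit0$loglik,
    cox_snell_r2 = cox_snell_r2(null1$loglik, fit$loglik, fit$n),
    n_used = fit$n,
    adjusted = adjusted,
    covariate_set = paste(covset, collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

#' Per-SNP association table across outcomes
#'
#' Runs [snp_association()] for every SNP column against every requested
#' LTPA outcome on the complete-genotype sample.
#'
#' @param genotypes a [genotype_matrix()] with no missing genotypes
#'   (exclude upstream).
#' @param table phenotype/covariate data.frame aligned with `genotypes`.
#' @param outcomes outcome names (columns `ltpa_<name>` in `table`).
#' @param adjusted adjust for the seven-covariate set.
#' @return data.frame, one row per SNP x outcome.
#' @export
association_table <- function(genotypes, table,
                              outcomes = ltpa_outcomes(),
                              adjusted = TRUE) {
  rows <- list()
  for (oc in outcomes) {
    y <- table[[paste0("ltpa_", oc)]]
    if (is.null(y)) stop("missing outcome column: ltpa_", oc)
    for (s in colnames(genotypes)) {
      rows[[paste(s, oc)]] <- snp_association(
        genotypes[, s], y, covariates = table, adjusted = adjusted,
        predictor_id = s, outcome_id = oc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
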