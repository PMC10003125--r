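#' Write a genotype matrix as a minimal VCF
#'
#' Emits a GT-only VCF (one record per panel SNP, REF = other allele,
#' ALT = effect allele, unphased diploid genotypes, missing as `./.`).
#' Sample columns are the genotype-matrix row names, or `S<i>` when
#' unnamed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  panel <- gm_panel(genotypes)
  samples <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  gt_of <- function(code) {
    c("0/0", "0/1", "1/1")[code + 1L]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ltpaPGS",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  records <- vapply(seq_len(nrow(panel)), function(i) {
    codes <- genotypes[, i]
    gt <- ifelse(is.na(codes), "./.", gt_of(codes))
    paste(c(panel$chrom[i], panel$pos[i], panel$snp_id[i],
            panel$other_allele[i], panel$effect_allele[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read genotypes from VCF or CSV, oriented to effect-allele counts
#'
#' VCF records must be biallelic SNVs with a GT field; genotype codes are
#' re-oriented so that the stored value counts the panel's effect allele
#' (ALT-allele count when effect = ALT, 2 minus it when effect = REF).
#' A CSV must carry a header of panel SNP ids and 0/1/2 codes (empty or
#' `NA` for missing); codes in a CSV are assumed already oriented to the
#' effect allele. Every panel SNP must be present; an effect allele
#' matching neither REF nor ALT is an error naming the SNP.
#'
#' @param path `.vcf` or `.csv` file.
#' @param panel a [snp_panel()].
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path, panel)
  } else {
    read_genotypes_csv(path, panel)
  }
}

#' @keywords internal
read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, colnames(fix) %||%
                                  c("CHROM", "POS", "ID", "REF", "ALT",
                                    "QUAL", "FILTER")))
  ids <- fix[, "ID"]
  absent <- setdiff(panel$snp_id, ids)
  if (length(absent)) {
    stop("panel SNP(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  n_samp <- ncol(gt)
  codes <- matrix(NA_integer_, nrow = n_samp, ncol = nrow(panel),
                  dimnames = list(colnames(gt), panel$snp_id))
  for (i in seq_len(nrow(panel))) {
    row <- which(ids == panel$snp_id[i])[1]
    ref <- fix[row, "REF"]
    alt <- fix[row, "ALT"]
    if (is.na(alt) || grepl(",", alt)) {
      stop("multi-allelic record at ", panel$snp_id[i])
    }
    g <- gt[row, ]
    alt_count <- ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
                        vapply(strsplit(gsub("\\|", "/", g), "/"),
                               function(a) sum(a == "1"), 0L))
    if (panel$effect_allele[i] == alt) {
      codes[, i] <- alt_count
    } else if (panel$effect_allele[i] == ref) {
      codes[, i] <- 2L - alt_count
    } else {
      stop("effect allele ", panel$effect_allele[i], " of ",
           panel$snp_id[i], " matches neither REF (", ref,
           ") nor ALT (", alt, ")")
    }
  }
  genotype_matrix(codes, panel)
}

#' @keywords internal
read_genotypes_csv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  absent <- setdiff(panel$snp_id, names(df))
  if (length(absent)) {
    stop("panel SNP(s) absent from CSV: ", paste(absent, collapse = ", "))
  }
  codes <- as.matrix(df[panel$snp_id])
  storage.mode(codes) <- "integer"
  gm <- genotype_matrix(codes, panel)
  if ("id" %in% names(df)) rownames(gm) <- df$id
  gm
}

#' @keywords internal
phenotype_columns <- function() {
  c("id", "population", "age", "sex", "education", "vehicle", "bmi",
    "waist", "ethnicity",
    paste0("ltpa_", ltpa_outcomes()),
    paste0("met_", ltpa_outcomes()),
    paste0("days_", ltpa_outcomes()))
}

#' Write the phenotype/covariate table as CSV
#'
#' @param table cohort data.frame (see [read_phenotypes()] for the
#'   documented header).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table[phenotype_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a phenotype/covariate table
#'
#' Expects the documented header: `id`, `population`, covariates (`age`,
#' `sex`, `education`, `vehicle`, `bmi`, `waist`, `ethnicity`), the four
#' binary LTPA outcomes `ltpa_general`/`ltpa_vigorous`/`ltpa_moderate`/
#' `ltpa_walking`, and matching `met_*` (MET-min/week, >= 0) and
#' `days_*` (0-7) columns. A positive MET or days value alongside a zero
#' binary outcome is an inconsistency error. Rows missing any required
#' covariate are excluded, with the retained count recorded in attribute
#' `n_excluded_missing_covariates`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- phenotype_columns()
  absent <- setdiff(required, names(df))
  if (length(absent)) {
    stop("phenotype table lacks column(s): ",
         paste(absent, collapse = ", "))
  }
  for (oc in ltpa_outcomes()) {
    y <- df[[paste0("ltpa_", oc)]]
    if (!all(y %in% c(0, 1))) {
      stop("binary outcome ltpa_", oc, " must be 0/1")
    }
    met <- df[[paste0("met_", oc)]]
    days <- df[[paste0("days_", oc)]]
    if (any(!is.finite(met)) || any(met < 0)) {
      stop("malformed met_", oc, " values")
    }
    if (any(!is.finite(days)) || any(days < 0 | days > 7)) {
      stop("days_", oc, " must lie in [0, 7]")
    }
    bad <- y == 0 & (met > 0 | days > 0)
    if (any(bad)) {
      stop("inconsistent rows (", sum(bad), "): positive met_", oc,
           " or days_", oc, " with ltpa_", oc, " = 0")
    }
  }
  covars <- c("age", "sex", "education", "vehicle", "bmi", "waist",
              "ethnicity")
  complete <- stats::complete.cases(df[covars])
  out <- df[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_missing_covariates") <- sum(!complete)
  out
}
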