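#' Candidate SNP panel metadata
#'
#' A panel is a data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#' (1-based, GRCh38 labels carried as opaque metadata), `effect_allele`
#' (the allele oriented a priori as promoting leisure-time physical
#' activity), `other_allele`, and a free-text `note`. Genotypes are coded
#' 0/1/2 as counts of the effect allele; orientation is fixed in the panel,
#' never re-estimated from data.
#'
#' @param snp_id character vector of unique rs-identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based positions.
#' @param effect_allele,other_allele single-base alleles (A/C/G/T), distinct
#'   within each SNP.
#' @param note provenance note per SNP.
#' @return a `data.frame` of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chrom, pos, effect_allele, other_allele,
                      note = "") {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) stop("duplicate SNP ids in panel")
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  bases <- c("A", "C", "G", "T")
  if (!all(effect_allele %in% bases) || !all(other_allele %in% bases)) {
    stop("alleles must be single bases A/C/G/T")
  }
  if (any(effect_allele == other_allele)) {
    stop("effect and other allele must differ for every SNP")
  }
  out <- data.frame(
    snp_id = snp_id,
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = effect_allele,
    other_allele = other_allele,
    note = rep_len(as.character(note), length(snp_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Default seven-SNP LTPA candidate panel
#'
#' The seven polymorphisms retained for analysis after the original
#' literature-derived panel was pruned on Hardy-Weinberg grounds, with
#' GRCh38 coordinates and the LTPA-promoting allele as the effect allele.
#' The non-effect alleles are synthetic placeholders (the source tables
#' print only the effect allele); they matter only for VCF orientation
#' round-trips, never for any statistic.
#'
#' @return a [snp_panel()].
#' @export
ltpa_panel <- function() {
  snp_panel(
    snp_id = c("rs10252228", "rs12612420", "rs7023003", "rs459465",
               "rs6022999", "rs10887741", "rs8097348"),
    chrom = c("7", "2", "9", "20", "20", "10", "18"),
    pos = c(34900427L, 200293399L, 105118389L, 54806483L,
            54171474L, 87683553L, 1595020L),
    effect_allele = c("G", "G", "G", "G", "A", "C", "A"),
    other_allele = c("A", "A", "A", "A", "G", "T", "G"),
    note = "effect allele from candidate panel; other allele synthetic placeholder"
  )
}

#' Genotype matrix container
#'
#' Individuals x SNPs matrix of effect-allele counts in {0, 1, 2}, `NA` for
#' missing, with the SNP panel attached as an attribute. Column names are
#' the panel's SNP ids.
#'
#' @param codes integer matrix (individuals x SNPs) of values in
#'   {0, 1, 2, NA}.
#' @param panel a [snp_panel()] with one row per column of `codes`.
#' @param population optional per-individual population labels (recycled
#'   checkable length).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, panel, population = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (ncol(codes) != nrow(panel)) {
    stop("panel must describe exactly the SNP columns of the genotype matrix")
  }
  ok <- is.na(codes) | (codes >= 0L & codes <= 2L)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  colnames(codes) <- panel$snp_id
  if (!is.null(population)) {
    if (length(population) != nrow(codes)) {
      stop("population labels must match the number of individuals")
    }
    population <- as.character(population)
  }
  structure(codes, panel = panel, population = population,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x), ncol(x)))
  cat("SNPs:", paste(colnames(x), collapse = ", "), "\n")
  miss <- sum(is.na(x))
  cat(sprintf("missing genotypes: %d (%.2f%%)\n", miss,
              100 * miss / length(x)))
  invisible(x)
}

#' @keywords internal
gm_panel <- function(gm) attr(gm, "panel")

#' @keywords internal
gm_population <- function(gm) attr(gm, "population")
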