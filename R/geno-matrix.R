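#' Genotype matrix container
#'
#' A light container for hard-called genotype dosages together with variant
#' and sample metadata.  Dosage is the count of `allele1` (the "counted"
#' allele, mirroring the PLINK A1 convention), so values are 0, 1, 2 or `NA`
#' for missing.  Samples are rows, variants are columns.
#'
#' @param dosage integer/numeric matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param variants tibble with columns `id`, `chrom`, `bp` (1-based),
#'   `allele1`, `allele2`; one row per dosage column.
#' @param samples tibble with column `id` (unique) and any extra metadata
#'   (e.g. `population` for a labelled reference panel); one row per dosage
#'   row.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `variants`, `samples`.
#' @export
geno_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (nrow(variants) != ncol(dosage)) {
    abort("`variants` must have one row per dosage column")
  }
  if (nrow(samples) != nrow(dosage)) {
    abort("`samples` must have one row per dosage row")
  }
  need <- c("id", "chrom", "bp", "allele1", "allele2")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    abort(paste0("`variants` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"id" %in% names(samples)) abort("`samples` lacks an `id` column")
  if (anyDuplicated(samples$id)) abort("sample ids must be unique")
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) abort("dosage values must be 0, 1, 2 or NA")
  if (any(variants$allele1 == variants$allele2)) {
    abort("allele1 and allele2 must differ for every variant")
  }
  rownames(dosage) <- samples$id
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  mr <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage: %.2f%%\n", 100 * mr))
  extra <- setdiff(names(x$samples), "id")
  if (length(extra) > 0) {
    cat("  sample metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

n_samples <- function(g) nrow(g$dosage)
n_variants <- function(g) ncol(g$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i sample selector (ids, logical or integer indices).
#' @param j variant selector (ids, logical or integer indices).
#' @param ... unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$variants$id)
  geno_matrix(x$dosage[i, j, drop = FALSE],
              x$variants[j, , drop = FALSE],
              x$samples[i, , drop = FALSE])
}

#' Per-variant and per-sample missingness
#'
#' @param g a [geno_matrix()].
#' @return A tibble (`id`, `missing_rate`).
#' @export
variant_missingness <- function(g) {
  tibble(id = g$variants$id,
         missing_rate = unname(colMeans(is.na(g$dosage))))
}

#' @rdname variant_missingness
#' @export
sample_missingness <- function(g) {
  tibble(id = g$samples$id,
         missing_rate = unname(rowMeans(is.na(g$dosage))))
}

#' Allele frequency of the counted allele
#'
#' Frequency of `allele1` computed on non-missing dosages.
#'
#' @param g a [geno_matrix()].
#' @return A tibble (`id`, `freq`, `maf`, `n_obs`).
#' @export
allele_freq <- function(g) {
  n_obs <- colSums(!is.na(g$dosage))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  tibble(id = g$variants$id, freq = unname(p),
         maf = unname(pmin(p, 1 - p)), n_obs = unname(n_obs))
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of each variant by twice its counted-allele
#' frequency.  Variants with no observed calls are imputed to 0.
#'
#' @param g a [geno_matrix()].
#' @return A `geno_matrix` with no missing dosages.
#' @export
mean_impute <- function(g) {
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  g$dosage <- d
  g
}

#' Fraction of heterozygous calls per sample
#'
#' @param g a [geno_matrix()].
#' @return A tibble (`id`, `het_rate`) over non-missing calls.
#' @export
het_rate <- function(g) {
  obs <- rowSums(!is.na(g$dosage))
  het <- rowSums(g$dosage == 1, na.rm = TRUE)
  tibble(id = g$samples$id,
         het_rate = unname(ifelse(obs > 0, het / obs, NA_real_)))
}
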