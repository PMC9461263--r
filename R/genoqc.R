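qc_report_row <- function(rule, unit, n_input, n_removed, threshold = NA_real_) {
  tibble(rule = rule, unit = unit, n_input = n_input,
         n_removed = n_removed, n_retained = n_input - n_removed,
         threshold = threshold)
}

#' Variant-level quality control
#'
#' Removes unmapped variants (missing chromosome or position),
#' strand-ambiguous variants (A/T and C/G allele pairs, which cannot be
#' oriented across arrays), and variants whose missing-call rate exceeds
#' `max_missing` (strict `>`).
#'
#' @param g a [geno_matrix()].
#' @param max_missing maximum tolerated per-variant missing rate.
#' @param drop_strand_ambiguous drop A/T and C/G variants?
#' @param drop_unmapped drop variants lacking chrom/bp?
#' @return A list: `genotypes` (filtered `geno_matrix`) and `report`
#'   (tibble, one row per rule; removed + retained reconcile exactly).
#' @export
qc_variants <- function(g, max_missing = 0.05, drop_strand_ambiguous = TRUE,
                        drop_unmapped = TRUE) {
  report <- list()
  if (drop_unmapped) {
    unmapped <- is.na(g$variants$chrom) | is.na(g$variants$bp)
    report <- c(report, list(qc_report_row("unmapped", "variant",
                                           ncol(g$dosage), sum(unmapped))))
    if (any(unmapped)) g <- g[, !unmapped]
  }
  if (drop_strand_ambiguous) {
    pair <- paste0(pmin(g$variants$allele1, g$variants$allele2),
                   pmax(g$variants$allele1, g$variants$allele2))
    ambig <- pair %in% c("AT", "CG")
    report <- c(report, list(qc_report_row("strand_ambiguous", "variant",
                                           ncol(g$dosage), sum(ambig))))
    if (any(ambig)) g <- g[, !ambig]
  }
  mr <- colMeans(is.na(g$dosage))
  high <- mr > max_missing
  report <- c(report, list(qc_report_row("variant_missingness", "variant",
                                         ncol(g$dosage), sum(high),
                                         max_missing)))
  if (any(high)) g <- g[, !high]
  list(genotypes = g, report = dplyr::bind_rows(report))
}

#' Sample-level missingness filter
#'
#' @param g a [geno_matrix()].
#' @param max_missing samples with missing rate strictly above this are
#'   removed.
#' @return A list: `genotypes`, `report`.
#' @export
qc_samples <- function(g, max_missing = 0.05) {
  mr <- rowMeans(is.na(g$dosage))
  high <- mr > max_missing
  report <- qc_report_row("sample_missingness", "sample",
                          nrow(g$dosage), sum(high), max_missing)
  if (any(high)) g <- g[!high, ]
  list(genotypes = g, report = report)
}

#' Minor-allele-frequency filter
#'
#' MAF is computed on non-missing dosages; variants with MAF strictly below
#' `min_maf` are removed (so "MAF > 1%" means `min_maf = 0.01` keeps a
#' variant at exactly 0.01).
#'
#' @param g a [geno_matrix()].
#' @param min_maf minimum minor allele frequency.
#' @return A list: `genotypes`, `report`.
#' @export
maf_filter <- function(g, min_maf) {
  af <- allele_freq(g)
  low <- !is.na(af$maf) & af$maf < min_maf
  low[is.na(af$maf)] <- TRUE                   # no observed calls
  report <- qc_report_row("maf", "variant", ncol(g$dosage), sum(low), min_maf)
  if (any(low)) g <- g[, !low]
  list(genotypes = g, report = report)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' (hom1, het, hom2) against Hardy-Weinberg expectations at the observed
#' allele frequency, without continuity correction.  Monomorphic variants
#' are in perfect (degenerate) equilibrium and get p = 1.
#'
#' @param g a [geno_matrix()].
#' @return A tibble (`id`, `n_hom1`, `n_het`, `n_hom2`, `chisq`, `p`).
#' @export
hwe_test <- function(g) {
  d <- g$dosage
  n2 <- colSums(d == 2, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  e2 <- n * p^2
  e1 <- n * 2 * p * (1 - p)
  e0 <- n * (1 - p)^2
  chisq <- rep(0, length(n))
  poly <- !is.na(p) & p > 0 & p < 1 & n > 0
  chisq[poly] <- (n2[poly] - e2[poly])^2 / e2[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n0[poly] - e0[poly])^2 / e0[poly]
  pval <- ifelse(poly, pchisq(chisq, df = 1, lower.tail = FALSE), 1)
  tibble(id = g$variants$id, n_hom1 = unname(n0), n_het = unname(n1),
         n_hom2 = unname(n2), chisq = unname(chisq), p = unname(pval))
}

#' Apply an HWE p-value filter
#'
#' @param g a [geno_matrix()].
#' @param p_min variants with HWE p strictly below this are removed.
#' @return A list: `genotypes`, `report`.
#' @export
hwe_filter <- function(g, p_min) {
  hw <- hwe_test(g)
  fail <- hw$p < p_min
  report <- qc_report_row("hwe", "variant", ncol(g$dosage), sum(fail), p_min)
  if (any(fail)) g <- g[, !fail]
  list(genotypes = g, report = report)
}

#' Heterozygosity outliers within a group
#'
#' Flags samples whose heterozygous-call fraction lies outside
#' mean +/- `n_sd` standard deviations, computed within the supplied group.
#' With zero spread (SD = 0) no sample is flagged.
#'
#' @param g a [geno_matrix()] restricted to one group.
#' @param n_sd number of standard deviations.
#' @return Character vector of flagged sample ids.
#' @export
heterozygosity_outliers <- function(g, n_sd = 3) {
  if (nrow(g$dosage) < 3) {
    warn("fewer than 3 samples; no heterozygosity outliers flagged")
    return(character())
  }
  hr <- het_rate(g)
  s <- sd(hr$het_rate, na.rm = TRUE)
  if (!is.finite(s) || s == 0 || !is.finite(n_sd)) return(character())
  m <- mean(hr$het_rate, na.rm = TRUE)
  hr$id[!is.na(hr$het_rate) &
          (hr$het_rate < m - n_sd * s | hr$het_rate > m + n_sd * s)]
}

#' Mendel-error filtering placeholder
#'
#' Mendel-error screening needs pedigree structure; synthetic cohorts here
#' are founders-only, so with no pedigree this is a documented no-op that
#' returns the input unchanged with a warning.
#'
#' @param g a [geno_matrix()].
#' @param pedigree optional pedigree table; only `NULL` is supported.
#' @return `g`, unchanged.
#' @export
mendel_filter <- function(g, pedigree = NULL) {
  if (is.null(pedigree)) {
    warn("no pedigree supplied; Mendel-error filtering is a no-op")
    return(g)
  }
  abort("pedigree-based Mendel filtering is not implemented")
}

#' Align a study matrix to a reference panel and merge
#'
#' Intersects on (chrom, bp).  Variants with identical allele pairs are
#' kept as-is; variants whose allele1/allele2 are swapped between the two
#' sets have the study dosage recoded g -> 2 - g; variants with any
#' non-ACGT allele or irreconcilable allele sets are dropped.  The merged
#' matrix stacks panel samples below study samples and uses the panel's
#' allele orientation.
#'
#' @param study,panel [geno_matrix()] objects.
#' @return A list: `genotypes` (merged `geno_matrix`; the `samples` tibble
#'   gains a `source` column in \{"study", "panel"\}) and `report`.
#' @export
align_to_reference <- function(study, panel) {
  sv <- study$variants
  pv <- panel$variants
  key_s <- paste(sv$chrom, sv$bp, sep = ":")
  key_p <- paste(pv$chrom, pv$bp, sep = ":")
  common <- intersect(key_s, key_p)
  if (length(common) == 0) abort("no overlapping variants between study and panel")
  is_ <- match(common, key_s)
  ip <- match(common, key_p)
  acgt <- c("A", "C", "G", "T")
  a1s <- sv$allele1[is_]; a2s <- sv$allele2[is_]
  a1p <- pv$allele1[ip];  a2p <- pv$allele2[ip]
  ok_acgt <- a1s %in% acgt & a2s %in% acgt & a1p %in% acgt & a2p %in% acgt
  same <- a1s == a1p & a2s == a2p
  swapped <- a1s == a2p & a2s == a1p
  keep <- ok_acgt & (same | swapped)
  n_drop <- length(common) - sum(keep)
  is_ <- is_[keep]; ip <- ip[keep]; swapped <- swapped[keep]
  if (length(is_) == 0) abort("no reconcilable overlapping variants")
  ds <- study$dosage[, is_, drop = FALSE]
  if (any(swapped)) {
    ds[, swapped] <- 2 - ds[, swapped]
  }
  dp <- panel$dosage[, ip, drop = FALSE]
  variants <- pv[ip, ]
  colnames(ds) <- variants$id
  samples <- dplyr::bind_rows(
    dplyr::mutate(study$samples, source = "study"),
    dplyr::mutate(panel$samples, source = "panel")
  )
  merged <- geno_matrix(rbind(ds, dp), variants, samples)
  report <- dplyr::bind_rows(
    qc_report_row("overlap", "variant", length(key_s),
                  length(key_s) - length(common)),
    qc_report_row("allele_mismatch_or_non_acgt", "variant",
                  length(common), n_drop)
  )
  list(genotypes = merged, report = report, n_flipped = sum(swapped))
}
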