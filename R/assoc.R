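#' Logistic regression fit with Wald inference
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (the `glm.fit` engine), returning log-odds coefficients, Wald
#' standard errors and two-sided p-values, odds ratios with 95% CIs, and
#' case/control counts.  Complete separation (diverging coefficients,
#' |beta| > 20) and non-convergence are flagged and leave the p-values
#' missing rather than aborting.
#'
#' @param y binary outcome (0/1, or logical).
#' @param x covariate matrix or data frame (no intercept column; one is
#'   added).  Must be finite and of full column rank.
#' @return A `logistic_fit` list: `coefficients` tibble (`term`, `beta`,
#'   `se`, `z`, `p`, `or`, `ci_low`, `ci_high`), `n_cases`, `n_controls`,
#'   `converged`, `flag` ("" / "separation" / "nonconverged").
#' @export
fit_logistic <- function(y, x) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x)) abort("y and x disagree on n")
  if (length(y) < 10) abort("need n >= 10 observations")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")
  if (length(unique(y)) < 2) abort("degenerate outcome: y is constant")
  if (!all(is.finite(x))) abort("covariates must be finite")
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design")
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 100,
                                                      epsilon = 1e-8))
  )
  p_rank <- fit$qr$rank
  beta <- fit$coefficients
  covmat <- chol2inv(fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE])
  se <- sqrt(diag(covmat))
  flag <- ""
  if (!fit$converged) flag <- "nonconverged"
  if (any(abs(beta) > 20)) flag <- "separation"
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (flag != "") p <- rep(NA_real_, length(p))
  coefs <- tibble(term = colnames(X), beta = unname(beta), se = unname(se),
                  z = unname(z), p = unname(p),
                  or = exp(unname(beta)),
                  ci_low = exp(unname(beta) - 1.96 * unname(se)),
                  ci_high = exp(unname(beta) + 1.96 * unname(se)))
  structure(list(coefficients = coefs,
                 n_cases = sum(y == 1), n_controls = sum(y == 0),
                 converged = fit$converged, flag = flag),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d cases / %d controls%s\n", x$n_cases,
              x$n_controls, if (x$flag == "") "" else paste0(" [", x$flag, "]")))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) x$coefficients

#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_controls = x$n_controls,
         converged = x$converged, flag = x$flag)
}

# one scan cell: fit and extract the focal term, never aborting the scan
scan_cell <- function(y, x, focal) {
  res <- tryCatch({
    f <- fit_logistic(y, x)
    row <- f$coefficients[f$coefficients$term == focal, ]
    tibble(beta = row$beta, se = row$se, p = row$p, or = row$or,
           ci_low = row$ci_low, ci_high = row$ci_high,
           n_cases = f$n_cases, n_controls = f$n_controls, flag = f$flag)
  }, error = function(e) {
    tibble(beta = NA_real_, se = NA_real_, p = NA_real_, or = NA_real_,
           ci_low = NA_real_, ci_high = NA_real_,
           n_cases = sum(y == 1), n_controls = sum(y == 0),
           flag = conditionMessage(e))
  })
  res
}

# shared covariate assembly: age, sex (Female = 1), optional SIRE factor
# with the largest group as reference, optional PC block
base_covariates <- function(dat, use_sex = TRUE, adjust_sire = FALSE,
                            pc_cols = NULL) {
  x <- cbind(age = dat$age)
  if (use_sex) x <- cbind(x, sexFemale = as.numeric(dat$sex == "Female"))
  if (adjust_sire) {
    ref <- names(sort(table(dat$sire), decreasing = TRUE))[1]
    lv <- c(ref, setdiff(sort(unique(dat$sire)), ref))
    f <- factor(dat$sire, levels = lv)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0("sire", lv[-1])
    x <- cbind(x, mm)
  }
  if (!is.null(pc_cols)) x <- cbind(x, as.matrix(dat[, pc_cols]))
  x
}

restrict_sex <- function(dat, flag) {
  if (is.null(flag) || flag == "none") return(list(dat = dat, use_sex = TRUE))
  want <- if (flag == "male") "Male" else "Female"
  list(dat = dat[dat$sex == want, , drop = FALSE], use_sex = FALSE)
}

#' Phecode vs genetically-inferred-ancestry scan
#'
#' For every testable (group, phecode) pair, fits the one-vs-rest logistic
#' model \eqn{logit(phecode) = b0 + b1 GIA_group + b2 sex + b3 age}
#' (optionally + SIRE) over all assigned individuals, where the covariate
#' of interest is the indicator of membership in the group.  Ambiguous
#' samples are excluded from "rest" by default.  Sex-specific phecodes are
#' fit within the matching sex without the sex covariate.  The Bonferroni
#' threshold is alpha divided by the number of tests performed.
#'
#' @param statuses case/control tibble from [define_cases()].
#' @param gia assignment tibble (`id`, `gia`).
#' @param demographics tibble (`person_id`, `age`, `sex`, `sire`).
#' @param adjust_sire add the SIRE factor?
#' @param min_cases per-group case count must be strictly above this.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param include_ambiguous keep Ambiguous samples in the "rest" set?
#' @param sex_specific optional tibble (`phecode`, `sex_specific`).
#' @return A `scan_result` tibble, one row per (group, phecode) with
#'   effect/SE/p/OR/CI and counts; attributes `n_tests`, `threshold`,
#'   `alpha`.
#' @export
phecode_gia_scan <- function(statuses, gia, demographics, adjust_sire = FALSE,
                             min_cases = 50, alpha = 0.05,
                             include_ambiguous = FALSE, sex_specific = NULL) {
  gia_tbl <- dplyr::rename(gia[, c("id", "gia")], person_id = "id")
  if (!include_ambiguous) {
    gia_tbl <- filter(gia_tbl, !startsWith(.data$gia, "Ambiguous"))
  }
  dat0 <- demographics %>%
    inner_join(gia_tbl, by = "person_id")
  groups <- sort(unique(dat0$gia))
  testable <- filter_testable(statuses,
                              dplyr::select(dat0, "person_id", group = "gia"),
                              min_cases = min_cases)
  sx <- sex_flag_lookup(sex_specific)
  rows <- purrr::pmap_dfr(testable, function(group, phecode, n_cases) {
    st <- statuses[statuses$phecode == phecode &
                     statuses$status != "excluded", ]
    dat <- inner_join(dat0, st, by = "person_id")
    rs <- restrict_sex(dat, sx(phecode))
    dat <- rs$dat
    y <- as.numeric(dat$status == "case")
    x <- cbind(gia_group = as.numeric(dat$gia == group),
               base_covariates(dat, use_sex = rs$use_sex,
                               adjust_sire = adjust_sire))
    cell <- scan_cell(y, x, "gia_group")
    dplyr::bind_cols(tibble(group = group, phecode = phecode), cell)
  })
  new_scan_result(rows, alpha = alpha)
}

sex_flag_lookup <- function(sex_specific) {
  if (is.null(sex_specific)) return(function(ph) "none")
  map <- setNames(sex_specific$sex_specific, sex_specific$phecode)
  function(ph) {
    v <- map[[ph]]
    if (is.null(v) || is.na(v)) "none" else v
  }
}

new_scan_result <- function(rows, alpha, n_tests = NULL) {
  n_tests <- n_tests %||% nrow(rows)
  attr(rows, "n_tests") <- n_tests
  attr(rows, "alpha") <- alpha
  attr(rows, "threshold") <- if (n_tests > 0) bonferroni(alpha, n_tests) else NA_real_
  class(rows) <- c("scan_result", class(rows))
  rows
}

#' Phecode vs admixture-proportion scan within SIRE groups
#'
#' Within each SIRE group separately, tests each phecode against each
#' ancestry-proportion component:
#' \eqn{logit(phecode) = b0 + b1 q_k + b2 sex + b3 age}, over individuals
#' of that SIRE only.  Only phecodes with strictly more than `min_cases`
#' cases in the SIRE are tested.  Cells whose proportion is constant
#' within the SIRE fail with a degenerate-design flag and a missing p.
#'
#' @param statuses case/control tibble from [define_cases()].
#' @param q tibble (`person_id`, `q1`, ..., `qK`) of admixture proportions.
#' @param demographics tibble (`person_id`, `age`, `sex`, `sire`).
#' @param min_cases strict per-SIRE case minimum (default 10).
#' @param alpha Bonferroni family-wise rate.
#' @param components which components to test (default: all `q*` columns).
#' @param sex_specific optional tibble (`phecode`, `sex_specific`).
#' @return A `scan_result` tibble, one row per (sire, phecode, component).
#' @export
admixture_phecode_scan <- function(statuses, q, demographics, min_cases = 10,
                                   alpha = 0.05, components = NULL,
                                   sex_specific = NULL) {
  q_cols <- components %||% grep("^q\\d+$", names(q), value = TRUE)
  dat0 <- inner_join(demographics, q, by = "person_id")
  testable <- filter_testable(statuses,
                              dplyr::select(dat0, "person_id", group = "sire"),
                              min_cases = min_cases)
  sx <- sex_flag_lookup(sex_specific)
  grid <- tidyr::expand_grid(testable, component = q_cols)
  rows <- purrr::pmap_dfr(grid, function(group, phecode, n_cases, component) {
    st <- statuses[statuses$phecode == phecode &
                     statuses$status != "excluded", ]
    dat <- inner_join(dat0[dat0$sire == group, ], st, by = "person_id")
    rs <- restrict_sex(dat, sx(phecode))
    dat <- rs$dat
    y <- as.numeric(dat$status == "case")
    x <- cbind(admix_prop = dat[[component]],
               base_covariates(dat, use_sex = rs$use_sex))
    if (nrow(dat) > 0 && var(dat[[component]]) == 0) {
      cell <- tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     n_cases = sum(y == 1), n_controls = sum(y == 0),
                     flag = "degenerate design: constant proportion")
    } else {
      cell <- scan_cell(y, x, "admix_prop")
    }
    dplyr::bind_cols(tibble(sire = group, phecode = phecode,
                            component = component), cell)
  })
  new_scan_result(rows, alpha = alpha)
}

#' Per-ancestry-group GWAS
#'
#' Runs the per-group genotype QC (heterozygosity outliers at +/- `het_sd`
#' SD, HWE p < `hwe_p`, in-group MAF > `min_maf`), then fits an additive
#' logistic model per variant with age, sex and the supplied PCs as
#' covariates.  Per-variant fit failures yield a missing p rather than
#' aborting.  The genomic-control inflation factor of the scan is attached
#' as attribute `lambda_gc`.
#'
#' @param g [geno_matrix()] for the samples of one GIA group.
#' @param phenotype tibble (`person_id`, `status`) with "case"/"control".
#' @param demographics tibble (`person_id`, `age`, `sex`).
#' @param pcs tibble (`person_id`, `PC1`..`PC10`) computed within the group.
#' @param min_maf in-group MAF must be strictly above this (default 0.01).
#' @param hwe_p variants with HWE p strictly below this are dropped.
#' @param het_sd heterozygosity outlier cutoff in SDs.
#' @param min_cases group must have strictly more cases than this.
#' @param genomewide_p genome-wide significance threshold (default 5e-8).
#' @return A `scan_result` tibble, one row per variant (`variant_id`,
#'   `chrom`, `bp`, effect columns); attributes `lambda_gc`, `threshold`
#'   (= `genomewide_p`), `n_tests`, `qc_report`.
#' @export
gwas_scan <- function(g, phenotype, demographics, pcs, min_maf = 0.01,
                      hwe_p = 1e-12, het_sd = 3, min_cases = 50,
                      genomewide_p = 5e-8) {
  out_ids <- heterozygosity_outliers(g, n_sd = het_sd)
  if (length(out_ids) > 0) g <- g[setdiff(g$samples$id, out_ids), ]
  hw <- hwe_filter(g, hwe_p)
  g <- hw$genotypes
  mf <- maf_filter(g, min_maf + 1e-12)          # strict "MAF > min_maf"
  g <- mf$genotypes
  dat <- demographics %>%
    inner_join(phenotype, by = "person_id") %>%
    inner_join(pcs, by = "person_id") %>%
    filter(.data$status %in% c("case", "control"))
  dat <- dat[dat$person_id %in% g$samples$id, ]
  n_cases <- sum(dat$status == "case")
  if (n_cases <= min_cases) {
    abort(sprintf("only %d cases; need strictly more than %d",
                  n_cases, min_cases))
  }
  pc_cols <- grep("^PC\\d+$", names(dat), value = TRUE)
  y <- as.numeric(dat$status == "case")
  base_x <- base_covariates(dat, use_sex = TRUE, pc_cols = pc_cols)
  dos <- g$dosage[match(dat$person_id, g$samples$id), , drop = FALSE]
  rows <- purrr::map_dfr(seq_len(ncol(dos)), function(j) {
    dj <- dos[, j]
    ok <- !is.na(dj)
    cell <- scan_cell(y[ok], cbind(dosage = dj[ok],
                                   base_x[ok, , drop = FALSE]), "dosage")
    dplyr::bind_cols(tibble(variant_id = g$variants$id[j],
                            chrom = g$variants$chrom[j],
                            bp = g$variants$bp[j]), cell)
  })
  res <- new_scan_result(rows, alpha = genomewide_p, n_tests = nrow(rows))
  attr(res, "threshold") <- genomewide_p
  attr(res, "lambda_gc") <- lambda_gc(rows$p[!is.na(rows$p)])
  attr(res, "qc_report") <- dplyr::bind_rows(hw$report, mf$report)
  res
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-group log-odds estimates with weights \eqn{w_g = 1/SE_g^2}:
#' combined beta = sum(w b)/sum(w), SE = 1/sqrt(sum(w)), Wald p.  Variants
#' present in fewer than two groups are dropped.
#'
#' @param results tibble with columns `variant_id`, `group`, `beta`, `se`
#'   (stack the per-group scans; rows with missing beta/se are ignored).
#' @return Tibble (`variant_id`, `beta`, `se`, `z`, `p`, `n_groups`).
#' @export
meta_fixed_effects <- function(results) {
  ok <- !is.na(results$beta) & !is.na(results$se)
  results <- results[ok, ]
  if (any(results$se <= 0)) abort("standard errors must be positive")
  results %>%
    group_by(.data$variant_id) %>%
    summarise(beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
              se = 1 / sqrt(sum(1 / .data$se^2)),
              n_groups = dplyr::n(), .groups = "drop") %>%
    filter(.data$n_groups >= 2) %>%
    mutate(z = .data$beta / .data$se,
           p = 2 * stats::pnorm(-abs(.data$z))) %>%
    dplyr::select("variant_id", "beta", "se", "z", "p", "n_groups")
}

#' Phenome-wide association scan at one variant
#'
#' Tests one variant's dosage against every testable phecode in a group,
#' with age, sex and within-group PCs as covariates; sex-specific phecodes
#' are fit within the matching sex without the sex covariate.  Two
#' thresholds are reported: `alpha / n_phecodes` and
#' `genomewide_p / n_phecodes`.
#'
#' @param dosage named numeric vector (person id -> dosage 0..2).
#' @param statuses case/control tibble from [define_cases()].
#' @param demographics tibble (`person_id`, `age`, `sex`).
#' @param pcs tibble (`person_id`, `PC1`..); computed within the group.
#' @param sex_specific optional tibble (`phecode`, `sex_specific`).
#' @param min_cases strict case minimum per phecode (default 50).
#' @param alpha nominal rate for the primary threshold.
#' @param genomewide_p numerator of the stringent threshold.
#' @return A `scan_result` tibble, one row per phecode; attributes
#'   `threshold` (primary), `threshold_stringent`, `n_tests`.
#' @export
phewas <- function(dosage, statuses, demographics, pcs, sex_specific = NULL,
                   min_cases = 50, alpha = 0.05, genomewide_p = 5e-8) {
  dat0 <- demographics %>%
    inner_join(pcs, by = "person_id") %>%
    mutate(dosage = unname(dosage[.data$person_id])) %>%
    filter(!is.na(.data$dosage))
  pc_cols <- grep("^PC\\d+$", names(dat0), value = TRUE)
  sx <- sex_flag_lookup(sex_specific)
  case_n <- statuses %>%
    filter(.data$status == "case",
           .data$person_id %in% dat0$person_id) %>%
    count(.data$phecode, name = "n_cases") %>%
    filter(.data$n_cases > min_cases)
  rows <- purrr::map_dfr(case_n$phecode, function(ph) {
    st <- statuses[statuses$phecode == ph & statuses$status != "excluded", ]
    dat <- inner_join(dat0, st, by = "person_id")
    rs <- restrict_sex(dat, sx(ph))
    dat <- rs$dat
    y <- as.numeric(dat$status == "case")
    x <- cbind(dosage = dat$dosage,
               base_covariates(dat, use_sex = rs$use_sex, pc_cols = pc_cols))
    dplyr::bind_cols(tibble(phecode = ph), scan_cell(y, x, "dosage"))
  })
  res <- new_scan_result(rows, alpha = alpha)
  attr(res, "threshold_stringent") <-
    if (nrow(rows) > 0) bonferroni(genomewide_p, nrow(rows)) else NA_real_
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni <- function(alpha, n_tests) {
  if (length(n_tests) != 1 || n_tests < 1) abort("n_tests must be >= 1")
  alpha / n_tests
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the chi-square(1) median 0.4549.
#'
#' @param p p-values in (0, 1].
#' @return lambda-GC (1 under a well-calibrated null).
#' @export
lambda_gc <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Effective sample size of a case-control analysis
#'
#' Harmonic-mean form \eqn{N_{eff} = 2 / (1/N_{cases} + 1/N_{controls})},
#' which equals the total N when cases and controls are balanced and
#' shrinks towards the rarer class otherwise.
#'
#' @param n_cases,n_controls counts (>= 1).
#' @return Effective sample size.
#' @export
n_effective <- function(n_cases, n_controls) {
  if (any(n_cases < 1) || any(n_controls < 1)) {
    abort("case and control counts must be >= 1")
  }
  2 / (1 / n_cases + 1 / n_controls)
}

#' PheWAS / scan plot
#'
#' -log10 p per test unit with the scan's Bonferroni threshold(s) drawn as
#' horizontal lines.
#'
#' @param object a `scan_result`.
#' @param ... unused.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- as_tibble(object)
  df$unit <- if ("phecode" %in% names(df)) df$phecode else
    if ("variant_id" %in% names(df)) df$variant_id else as.character(seq_len(nrow(df)))
  df <- df[!is.na(df$p), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$unit,
                                        y = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  thr <- attr(object, "threshold")
  if (!is.null(thr) && is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "red")
  }
  thr2 <- attr(object, "threshold_stringent")
  if (!is.null(thr2) && is.finite(thr2)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr2),
                                 linetype = "dotted", colour = "red")
  }
  p
}
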