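#' Pairwise-r2 LD pruning (sliding window)
#'
#' Mirrors the classic window/step/r2 pruning: within each window of
#' `window_variants` consecutive variants (per chromosome, position order),
#' any still-retained pair with squared Pearson correlation of dosages
#' strictly above `r2_max` loses its later member; the window then advances
#' by `step` variants.  Dosages are mean-imputed before correlation.
#' Removing the *later* variant of a violating pair is this
#' implementation's deterministic tie-break and is shared by the brute-force
#' oracle used in the tests.
#'
#' @param g a [geno_matrix()] with variants sorted by (chrom, bp).
#' @param window_variants,step window size and slide in variant counts.
#' @param r2_max maximum tolerated squared correlation.
#' @return Character vector of retained variant ids (input order).
#' @export
ld_prune_pairwise <- function(g, window_variants = 100, step = 5,
                              r2_max = 0.1) {
  d <- mean_impute(g)$dosage
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    mc <- length(idx)
    for (s in seq(1, max(mc - 1, 1), by = step)) {
      w <- idx[s:min(s + window_variants - 1, mc)]
      live <- w[keep[w]]
      if (length(live) < 2) next
      R2 <- suppressWarnings(cor(d[, live, drop = FALSE])^2)
      R2[!is.finite(R2)] <- 0                # zero-variance columns
      for (a in seq_len(length(live) - 1)) {
        if (!keep[live[a]]) next
        for (b in (a + 1):length(live)) {
          if (!keep[live[b]]) next
          if (R2[a, b] > r2_max) keep[live[b]] <- FALSE
        }
      }
    }
  }
  g$variants$id[keep]
}

window_vif <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) {
    solve(R + diag(1e-8, nrow(R)))
  })
  diag(inv)
}

#' Variance-inflation-factor LD pruning (sliding window)
#'
#' Within each window, the variance inflation factor of every retained
#' variant (1/(1 - R^2) from regressing its dosage on the other retained
#' window variants) is computed from the inverse correlation matrix; while
#' any VIF exceeds `vif_max` the variant with the largest VIF is removed
#' (ties towards the later variant).  A tiny ridge is added when the window
#' correlation matrix is singular, which sends the VIF of exact copies to a
#' very large finite value.
#'
#' @param g a [geno_matrix()] with variants sorted by (chrom, bp).
#' @param window_variants,step window size and slide in variant counts.
#' @param vif_max maximum tolerated VIF.
#' @return Character vector of retained variant ids (input order).
#' @export
ld_prune_vif <- function(g, window_variants = 200, step = 5, vif_max = 1.15) {
  d <- mean_impute(g)$dosage
  keep <- rep(TRUE, ncol(d))
  sds <- apply(d, 2, sd)
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    mc <- length(idx)
    for (s in seq(1, max(mc - 1, 1), by = step)) {
      w <- idx[s:min(s + window_variants - 1, mc)]
      repeat {
        live <- w[keep[w] & sds[w] > 0]
        if (length(live) < 2) break
        R <- cor(d[, live, drop = FALSE])
        vif <- window_vif(R)
        if (max(vif) <= vif_max) break
        worst <- live[max(which(vif == max(vif)))]
        keep[worst] <- FALSE
      }
    }
  }
  g$variants$id[keep]
}

#' Physical-distance pruning
#'
#' Greedy left-to-right retention keeping variants at least `min_bp` apart
#' within each chromosome (the first variant of a chromosome is always
#' kept).
#'
#' @param g a [geno_matrix()] with variants sorted by (chrom, bp).
#' @param min_bp minimum base-pair spacing between retained variants.
#' @return Character vector of retained variant ids (input order).
#' @export
prune_bp_spacing <- function(g, min_bp = 2000) {
  keep <- rep(FALSE, nrow(g$variants))
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (g$variants$bp[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- g$variants$bp[i]
      }
    }
  }
  g$variants$id[keep]
}
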