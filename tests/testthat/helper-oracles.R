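# Independent brute-force oracles and tiny fixture builders used across
# the suite.  These deliberately re-derive results by the most naive route
# available so the package implementations are checked against something
# that shares no code with them.

make_geno <- function(d, chrom = NULL, bp = NULL, a1 = "A", a2 = "G",
                      ids = NULL) {
  d <- as.matrix(d)
  m <- ncol(d)
  tibble::tibble(
    id = paste0("v", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    bp = bp %||% (seq_len(m) * 1000L),
    allele1 = rep_len(a1, m),
    allele2 = rep_len(a2, m)
  ) -> variants
  samples <- tibble::tibble(id = ids %||% paste0("s", seq_len(nrow(d))))
  geno_matrix(d, variants, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hudson-style Fst, ratio of averages over variants (textbook estimator,
# independent of the generator's Balding-Nichols parameterisation)
hudson_fst <- function(g, pop) {
  stopifnot(length(unique(pop)) == 2)
  lv <- unique(pop)
  d1 <- g$dosage[pop == lv[1], , drop = FALSE]
  d2 <- g$dosage[pop == lv[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1)); n2 <- 2 * colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / n1
  p2 <- colSums(d2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# naive r2 on mean-imputed dosages via lm()
oracle_r2 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  summary(stats::lm(y ~ x))$r.squared
}

# brute-force pairwise pruning with the same window/step/tie-break
# (remove the later variant), but naive pair loops and lm-based r2
oracle_prune_pairwise <- function(g, window, step, r2_max) {
  d <- mean_impute(g)$dosage
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    for (s in seq(1, max(length(idx) - 1, 1), by = step)) {
      w <- idx[s:min(s + window - 1, length(idx))]
      for (i in w) {
        for (j in w) {
          if (i < j && keep[i] && keep[j] &&
              oracle_r2(d[, i], d[, j]) > r2_max) {
            keep[j] <- FALSE
          }
        }
      }
    }
  }
  g$variants$id[keep]
}

# brute-force VIF pruning: lm of each variant on the other retained window
# variants
oracle_prune_vif <- function(g, window, step, vif_max) {
  d <- mean_impute(g)$dosage
  keep <- rep(TRUE, ncol(d))
  vif_of <- function(cols, target) {
    others <- setdiff(cols, target)
    if (length(others) == 0) return(1)
    fit <- stats::lm(d[, target] ~ d[, others, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) return(Inf)
    1 / (1 - r2)
  }
  sds <- apply(d, 2, stats::sd)
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    for (s in seq(1, max(length(idx) - 1, 1), by = step)) {
      w <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        live <- w[keep[w] & sds[w] > 0]
        if (length(live) < 2) break
        vifs <- vapply(live, function(v) vif_of(live, v), numeric(1))
        if (max(vifs) <= vif_max) break
        keep[live[max(which(vifs == max(vifs)))]] <- FALSE
      }
    }
  }
  g$variants$id[keep]
}

# exhaustive maximum independent set on a tiny graph (node names, edge df)
oracle_max_independent_set <- function(nodes, edges) {
  best <- character()
  for (size in length(nodes):0) {
    combos <- utils::combn(nodes, size, simplify = FALSE)
    ok <- NULL
    for (s in combos) {
      conflict <- any(edges$id1 %in% s & edges$id2 %in% s)
      if (!conflict) { ok <- s; break }
    }
    if (!is.null(ok)) { best <- ok; break }
  }
  best
}

# greedy bp-spacing oracle written independently
oracle_bp_spacing <- function(chrom, bp, min_bp) {
  keep <- logical(length(bp))
  for (c in unique(chrom)) {
    ix <- which(chrom == c)
    last_kept <- NULL
    for (i in ix) {
      if (is.null(last_kept) || bp[i] - last_kept >= min_bp) {
        keep[i] <- TRUE
        last_kept <- bp[i]
      }
    }
  }
  keep
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
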