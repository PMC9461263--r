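#' Pairwise kinship estimation
#'
#' Default backend is the KING-robust between-family estimator, which uses
#' heterozygote concordance and opposite-homozygote counts and is robust to
#' population structure:
#' \deqn{\hat\varphi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}}}
#' with all counts restricted to variants observed in both samples.
#' Expected values: ~0.5 for duplicates/MZ twins, ~0.25 first degree,
#' ~0.125 second degree, ~0 unrelated.  Degree cutoffs follow the usual
#' powers-of-two convention: degree-2 at 0.0884, degree-3 at 0.0442.
#'
#' The alternative `method = "grm"` backend is the allele-frequency-based
#' genetic-relationship-matrix estimate (half the standardized GRM entry);
#' it is accurate in a homogeneous sample but biased under structure.
#'
#' @param g a [geno_matrix()].
#' @param method `"king"` (default) or `"grm"`.
#' @return A `kinship_tbl` tibble with one row per unordered pair:
#'   `id1`, `id2`, `phi`, `n_snps` (co-observed variants).  Pairs with no
#'   co-observed variants get `phi = NA` with a warning.
#' @export
estimate_kinship <- function(g, method = c("king", "grm")) {
  method <- match.arg(method)
  n <- nrow(g$dosage)
  if (n < 2) abort("need at least 2 samples")
  d <- g$dosage
  O <- !is.na(d)
  storage.mode(O) <- "double"
  if (method == "king") {
    H <- (d == 1); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
    A <- (d == 0); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
    B <- (d == 2); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
    het_het <- tcrossprod(H)
    opp_hom <- tcrossprod(A, B)
    opp_hom <- opp_hom + t(opp_hom)
    het_i <- tcrossprod(H, O)              # [i,j]: het in i & observed in j
    den <- het_i + t(het_i)
    phi <- (het_het - 2 * opp_hom) / den
  } else {
    af <- allele_freq(g)$freq
    x <- sweep(mean_impute(g)$dosage, 2, 2 * af, "-")
    sc <- sqrt(2 * af * (1 - af))
    ok <- sc > 0
    x <- sweep(x[, ok, drop = FALSE], 2, sc[ok], "/")
    phi <- tcrossprod(x) / (2 * sum(ok))
  }
  n_snps <- tcrossprod(O)
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble(id1 = g$samples$id[ut[, 1]], id2 = g$samples$id[ut[, 2]],
                phi = phi[ut], n_snps = as.integer(n_snps[ut]))
  if (any(!is.finite(out$phi))) {
    warn(sprintf("%d pair(s) with no usable co-observed variants; phi set NA",
                 sum(!is.finite(out$phi))))
    out$phi[!is.finite(out$phi)] <- NA_real_
  }
  class(out) <- c("kinship_tbl", class(out))
  out
}

#' Remove duplicate samples
#'
#' Pairs at or above `dup_threshold` are grouped transitively (connected
#' components of the duplicate graph) and a single sample is kept per group.
#' `drop_policy = "keep_cleaner"` (default) keeps the sample with the lowest
#' missing rate; `"drop_cleaner"` reproduces the literal reading of removing
#' the lowest-missing-rate member.  Ties break towards the
#' lexicographically first sample id.
#'
#' @param g a [geno_matrix()].
#' @param kin kinship table from [estimate_kinship()] on the same samples.
#' @param dup_threshold kinship at/above which a pair is called duplicate
#'   (0.354 is the usual MZ/duplicate cutoff, i.e. 2^(-3/2)).
#' @param drop_policy `"keep_cleaner"` or `"drop_cleaner"`.
#' @return A list: `genotypes` (deduplicated), `removed` (character ids),
#'   `report`.
#' @export
remove_duplicates <- function(g, kin, dup_threshold = 0.354,
                              drop_policy = c("keep_cleaner", "drop_cleaner")) {
  drop_policy <- match.arg(drop_policy)
  dup <- kin[!is.na(kin$phi) & kin$phi >= dup_threshold, ]
  removed <- character()
  if (nrow(dup) > 0) {
    gr <- igraph::graph_from_data_frame(dup[, c("id1", "id2")],
                                        directed = FALSE)
    comp <- igraph::components(gr)$membership
    mr <- setNames(rowMeans(is.na(g$dosage)), g$samples$id)
    for (cc in unique(comp)) {
      members <- sort(names(comp)[comp == cc])
      ord <- order(mr[members], members)     # cleanest first, id tie-break
      keep <- if (drop_policy == "keep_cleaner") members[ord[1]] else
        members[ord[length(ord)]]
      removed <- c(removed, setdiff(members, keep))
    }
  }
  report <- qc_report_row("duplicates", "sample", nrow(g$dosage),
                          length(removed), dup_threshold)
  if (length(removed) > 0) g <- g[setdiff(g$samples$id, removed), ]
  list(genotypes = g, removed = removed, report = report)
}

#' Maximal unrelated sample set
#'
#' Builds the relatedness graph over pairs with kinship at/above
#' `threshold` and greedily deletes the highest-degree node until no edge
#' remains, so the returned set contains no pair at or above the cutoff.
#' Degree ties break towards removing the lexicographically last id, making
#' the selection deterministic.
#'
#' @param kin kinship table from [estimate_kinship()].
#' @param threshold inclusion cutoff; samples in pairs with
#'   `phi >= threshold` are in conflict (default 0.0884, the degree-2
#'   boundary).
#' @param ids optional full sample id universe; defaults to all ids in
#'   `kin`.  Samples with no conflicting pair are always retained.
#' @return Character vector of retained sample ids (sorted).
#' @export
unrelated_set <- function(kin, threshold = 0.0884, ids = NULL) {
  ids <- ids %||% sort(unique(c(kin$id1, kin$id2)))
  rel <- kin[!is.na(kin$phi) & kin$phi >= threshold, c("id1", "id2")]
  if (nrow(rel) == 0) return(sort(ids))
  adj <- split(c(rel$id2, rel$id1), c(rel$id1, rel$id2))
  deg <- vapply(adj, length, integer(1))
  alive <- setNames(rep(TRUE, length(ids)), ids)
  while (any(deg > 0)) {
    cand <- names(deg)[deg == max(deg)]
    victim <- cand[order(cand)][length(cand)]
    alive[victim] <- FALSE
    for (nb in adj[[victim]]) {
      if (!is.null(adj[[nb]])) {
        adj[[nb]] <- setdiff(adj[[nb]], victim)
        deg[nb] <- length(adj[[nb]])
      }
    }
    adj[[victim]] <- character()
    deg[victim] <- 0L
  }
  sort(names(alive)[alive])
}
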