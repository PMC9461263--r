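#' K-nearest-neighbour class membership fractions
#'
#' For every query point, the fraction of its `k` nearest training points
#' (Euclidean distance in the supplied coordinate space) carrying each
#' class label.  This neighbour-vote fraction is the "cluster membership"
#' used by the GIA assignment rules.
#'
#' @param train numeric matrix of training coordinates.
#' @param labels class label per training row.
#' @param query numeric matrix of query coordinates (same columns).
#' @param k neighbourhood size; every class must have at least `k`
#'   training points.
#' @return Matrix, queries x classes, of vote fractions (rows sum to 1).
#' @export
knn_membership <- function(train, labels, query, k) {
  train <- as.matrix(train); query <- as.matrix(query)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("class '%s' has fewer than k = %d training samples",
                  names(tab)[which.min(tab)], k))
  }
  classes <- sort(unique(labels))
  tn <- rowSums(train^2)
  out <- matrix(0, nrow(query), length(classes),
                dimnames = list(NULL, classes))
  # squared distances via the expansion ||q - t||^2 = ||q||^2 + ||t||^2 - 2 q.t
  d2 <- outer(rowSums(query^2), tn, "+") - 2 * tcrossprod(query, train)
  for (i in seq_len(nrow(query))) {
    nb <- labels[order(d2[i, ])[seq_len(k)]]
    f <- table(factor(nb, levels = classes)) / k
    out[i, ] <- as.numeric(f)
  }
  out
}

#' Select the KNN neighbourhood size by cross-validation
#'
#' 10-fold cross-validation on the labelled training points: each fold is
#' predicted from the remaining folds at every candidate `k`, and the `k`
#' with the highest mean held-out accuracy wins; ties break towards the
#' smaller `k` (smoother decision boundary, deterministic).
#'
#' @param train coordinates matrix; `labels` class per row.
#' @param labels class labels.
#' @param k_grid candidate neighbourhood sizes (default 5, 10, 15, 20).
#' @param n_folds folds (default 10).
#' @param seed RNG seed for the fold split.
#' @return The selected `k` with attribute `cv_accuracy` (named vector).
#' @export
select_k_cv <- function(train, labels, k_grid = c(5, 10, 15, 20),
                        n_folds = 10, seed = 1) {
  train <- as.matrix(train)
  labels <- as.character(labels)
  n <- nrow(train)
  tab <- table(labels)
  max_train <- min(tab - ceiling(tab / n_folds))
  k_grid <- k_grid[k_grid <= max_train]
  if (length(k_grid) == 0) abort("no candidate k fits the smallest class")
  set.seed(seed)
  # stratified folds so every training fold keeps >= k members per class
  fold <- integer(n)
  for (cl in names(tab)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  acc <- matrix(NA_real_, n_folds, length(k_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (j in seq_along(k_grid)) {
      m <- knn_membership(train[tr, , drop = FALSE], labels[tr],
                          train[!tr, , drop = FALSE], k_grid[j])
      pred <- colnames(m)[max.col(m, ties.method = "first")]
      acc[f, j] <- mean(pred == labels[!tr])
    }
  }
  mean_acc <- colMeans(acc)
  k <- k_grid[which.max(mean_acc)]       # which.max -> first, i.e. smallest k
  attr(k, "cv_accuracy") <- setNames(mean_acc, k_grid)
  k
}

#' Continental GIA assignment by per-ancestry KNN
#'
#' One KNN classifier per ancestry, each run in that ancestry's designated
#' pair of principal components (the PCs that best separate it from the
#' remaining panel).  A study sample's membership in an ancestry is the
#' fraction of its k nearest panel neighbours carrying that ancestry's
#' label; the sample is assigned a GIA label iff **exactly one** ancestry's
#' membership exceeds `threshold` — no qualifying ancestry, or more than
#' one, yields `"Ambiguous"`.
#'
#' @param scores score tibble from [fit_pca()] on the merged study+panel
#'   matrix; must contain a `source` column ("study"/"panel") and, for
#'   panel rows, the label column named by `label_col`.
#' @param pc_pairs named list: ancestry label -> integer vector of the PCs
#'   its classifier uses (default: PCs 1-2 for every label; override to
#'   reproduce designs where admixed groups use later PCs).
#' @param threshold membership needed for assignment (default 0.50).
#' @param k_grid candidate k values for [select_k_cv()].
#' @param gia_map optional named character renaming panel ancestries to GIA
#'   labels in the output (e.g. `c(European = "EA")`).
#' @param label_col name of the panel label column (default "population").
#' @param seed seed for the CV fold split.
#' @return A `gia_assignment` tibble: `id`, `gia`, `membership` (of the
#'   assigned ancestry; for Ambiguous, the maximum membership seen), and
#'   one `membership_<ancestry>` column per ancestry, plus a `k` attribute
#'   (named per-ancestry).
#' @export
assign_continental_gia <- function(scores, pc_pairs = NULL, threshold = 0.50,
                                   k_grid = c(5, 10, 15, 20),
                                   gia_map = NULL, label_col = "population",
                                   seed = 1) {
  stopifnot(is.data.frame(scores), "source" %in% names(scores))
  panel <- scores[scores$source == "panel", ]
  study <- scores[scores$source == "study", ]
  labels <- as.character(panel[[label_col]])
  ancestries <- sort(unique(labels))
  pc_pairs <- pc_pairs %||%
    setNames(rep(list(c(1, 2)), length(ancestries)), ancestries)
  memb <- matrix(NA_real_, nrow(study), length(ancestries),
                 dimnames = list(NULL, ancestries))
  ks <- setNames(integer(length(ancestries)), ancestries)
  for (anc in ancestries) {
    pcs <- paste0("PC", pc_pairs[[anc]])
    tr <- as.matrix(panel[, pcs])
    qy <- as.matrix(study[, pcs])
    k <- select_k_cv(tr, labels, k_grid = k_grid, seed = seed)
    ks[anc] <- as.integer(k)
    m <- knn_membership(tr, labels, qy, as.integer(k))
    memb[, anc] <- m[, anc]
  }
  n_above <- rowSums(memb > threshold)
  winner <- colnames(memb)[max.col(memb, ties.method = "first")]
  gia <- ifelse(n_above == 1, winner, "Ambiguous")
  if (!is.null(gia_map)) {
    mapped <- gia_map[gia]
    gia <- ifelse(is.na(mapped), gia, mapped)
  }
  best <- memb[cbind(seq_len(nrow(memb)), max.col(memb, ties.method = "first"))]
  out <- tibble(id = study$id, gia = gia, membership = best)
  colnames(memb) <- paste0("membership_", colnames(memb))
  out <- dplyr::bind_cols(out, as_tibble(memb))
  attr(out, "k") <- ks
  attr(out, "threshold") <- threshold
  class(out) <- c("gia_assignment", class(out))
  out
}

#' Subcontinental GIA assignment within one continental group
#'
#' A single KNN classifier on PCs 1-4 (by default), labelled either by
#' reference-panel subpopulations or by study SIRE groups; in SIRE mode,
#' label classes with `min_group` or fewer members are dropped before
#' training.  A sample is assigned its top class iff that class's
#' neighbour-vote fraction exceeds `threshold` (default 0.90), otherwise
#' it is reported as `"Ambiguous <group>"`.
#'
#' @param scores score tibble (as from [fit_pca()]) for the samples of one
#'   continental GIA group plus its labelled training samples.
#' @param labels named character: training sample id -> class label
#'   (panel subpopulation or SIRE).  Samples of `scores` not in `names(labels)`
#'   are the queries.
#' @param group_name continental group name used in the Ambiguous label.
#' @param threshold membership needed for assignment (default 0.90).
#' @param min_group label classes must have more than this many training
#'   samples (default 20) or they are dropped.
#' @param pcs which PCs the classifier uses (default 1:4).
#' @param k_grid candidate k values.
#' @param seed seed for the CV fold split.
#' @return A `gia_assignment` tibble: `id`, `gia`, `membership`.
#' @export
assign_subcontinental_gia <- function(scores, labels, group_name = "group",
                                      threshold = 0.90, min_group = 20,
                                      pcs = 1:4, k_grid = c(5, 10, 15, 20),
                                      seed = 1) {
  keep_classes <- names(table(labels))[table(labels) > min_group]
  if (length(keep_classes) == 0) {
    abort(sprintf("no label class has more than %d samples", min_group))
  }
  labels <- labels[labels %in% keep_classes]
  pc_cols <- paste0("PC", pcs)
  tr_rows <- scores$id %in% names(labels)
  train <- as.matrix(scores[tr_rows, pc_cols])
  train_lab <- unname(labels[scores$id[tr_rows]])
  query <- as.matrix(scores[!tr_rows, pc_cols])
  k <- select_k_cv(train, train_lab, k_grid = k_grid, seed = seed)
  m <- knn_membership(train, train_lab, query, as.integer(k))
  best_ix <- max.col(m, ties.method = "first")
  best <- m[cbind(seq_len(nrow(m)), best_ix)]
  gia <- ifelse(best > threshold, colnames(m)[best_ix],
                paste("Ambiguous", group_name))
  out <- tibble(id = scores$id[!tr_rows], gia = gia, membership = best)
  attr(out, "k") <- as.integer(k)
  attr(out, "threshold") <- threshold
  attr(out, "classes") <- keep_classes
  class(out) <- c("gia_assignment", class(out))
  out
}
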