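admixture_loglik <- function(G0, G2, P) {
  sum(G0 * log(P) + G2 * log1p(-P))
}

# one EM block update of (Q, F); clamped away from the boundary so the
# log-likelihood stays finite
admixture_em_step <- function(G0, G2, Q, F) {
  eps <- 1e-9
  P <- pmin(pmax(Q %*% F, eps), 1 - eps)
  U <- G0 / P
  V <- G2 / (1 - P)
  K <- ncol(Q)
  Qn <- Q
  Fn <- F
  for (k in seq_len(K)) {
    tU <- crossprod(Q[, k], U)[1, ]               # length M
    tV <- crossprod(Q[, k], V)[1, ]
    num <- F[k, ] * tU
    den <- num + (1 - F[k, ]) * tV
    Fn[k, ] <- pmin(pmax(ifelse(den > 0, num / den, F[k, ]), eps), 1 - eps)
    Qn[, k] <- Q[, k] * (U %*% F[k, ] + V %*% (1 - F[k, ]))
  }
  Qn <- pmin(pmax(Qn / rowSums(Qn), eps), 1)
  list(Q = Qn / rowSums(Qn), F = Fn)
}

admixture_ll_of <- function(G0, G2, Q, F) {
  eps <- 1e-9
  admixture_loglik(G0, G2, pmin(pmax(Q %*% F, eps), 1 - eps))
}

# SQUAREM-accelerated EM: each cycle takes two plain EM steps, extrapolates
# along the observed parameter trajectory, stabilises with one further EM
# step, and falls back to the plain double step whenever the accelerated
# point does not improve the log-likelihood -- so the recorded trace is
# non-decreasing by construction while convergence is typically an order
# of magnitude faster than plain EM
admixture_em_run <- function(G0, G2, Q, F, tol, max_iter, accelerate = TRUE) {
  eps <- 1e-9
  trace <- numeric(0)
  ll <- admixture_ll_of(G0, G2, Q, F)
  converged <- FALSE
  project <- function(th) {
    th$Q <- pmin(pmax(th$Q, eps), 1)
    th$Q <- th$Q / rowSums(th$Q)
    th$F <- pmin(pmax(th$F, eps), 1 - eps)
    th
  }
  for (it in seq_len(max_iter)) {
    t1 <- admixture_em_step(G0, G2, Q, F)
    if (!accelerate) {
      Q <- t1$Q; F <- t1$F
      ll_new <- admixture_ll_of(G0, G2, Q, F)
    } else {
      t2 <- admixture_em_step(G0, G2, t1$Q, t1$F)
      rQ <- t1$Q - Q; rF <- t1$F - F
      vQ <- t2$Q - t1$Q - rQ; vF <- t2$F - t1$F - rF
      vnorm <- sqrt(sum(vQ^2) + sum(vF^2))
      ll2 <- admixture_ll_of(G0, G2, t2$Q, t2$F)
      ll_new <- ll2
      Qb <- t2$Q; Fb <- t2$F
      if (vnorm > 0) {
        alpha <- max(-sqrt(sum(rQ^2) + sum(rF^2)) / vnorm, -64)
        alpha <- min(alpha, -1)
        cand <- project(list(Q = Q - 2 * alpha * rQ + alpha^2 * vQ,
                             F = F - 2 * alpha * rF + alpha^2 * vF))
        cand <- admixture_em_step(G0, G2, cand$Q, cand$F)
        ll_cand <- admixture_ll_of(G0, G2, cand$Q, cand$F)
        if (is.finite(ll_cand) && ll_cand > ll2) {
          Qb <- cand$Q; Fb <- cand$F; ll_new <- ll_cand
        }
      }
      Q <- Qb; F <- Fb
    }
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol && it > 1) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(Q = Q, F = F, loglik = ll, trace = trace, converged = converged)
}

#' Unsupervised admixture estimation by binomial-mixture EM
#'
#' Maximizes the admixture log-likelihood
#' \deqn{\sum_{ij} g_{ij}\log\big(\textstyle\sum_k q_{ik} f_{kj}\big) +
#'       (2-g_{ij})\log\big(\sum_k q_{ik}(1-f_{kj})\big)}
#' over per-sample ancestry proportions Q (N x K, rows on the simplex) and
#' per-component allele frequencies F (K x M), by block EM updates from
#' random Dirichlet/Uniform starts.  EM makes the log-likelihood
#' non-decreasing at every iteration.  Missing dosages contribute nothing
#' to the likelihood.  Several random restarts are run for a short burn-in
#' and the best is continued to convergence.
#'
#' @param g a [geno_matrix()], ideally pre-filtered (non-ACGT removed,
#'   MAF and spacing filters applied).
#' @param K number of ancestral components.
#' @param seed RNG seed (controls all restarts).
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap; hitting it returns the best fit with a
#'   warning and `converged = FALSE`.
#' @param n_init number of random restarts.
#' @param init_iter burn-in EM iterations given to each restart before the
#'   best is selected.
#' @return An `admixture_fit`: `Q`, `F`, `loglik`, `trace` (per-iteration
#'   log-likelihood of the winning run), `K`, `converged`, `component_labels`
#'   (NULL until [label_admixture_components()]).
#' @export
fit_admixture <- function(g, K, seed = 1, tol = 1e-6, max_iter = 2000,
                          n_init = 5, init_iter = 30) {
  stopifnot(K >= 1)
  d <- g$dosage
  G0 <- d; G0[is.na(G0)] <- 0
  G2 <- 2 - d; G2[is.na(G2)] <- 0
  N <- nrow(d); M <- ncol(d)
  if (K == 1) {
    f <- colSums(G0) / (colSums(G0) + colSums(G2))
    F <- matrix(pmin(pmax(f, 1e-9), 1 - 1e-9), 1, M)
    Q <- matrix(1, N, 1)
    ll <- admixture_loglik(G0, G2, pmin(pmax(Q %*% F, 1e-9), 1 - 1e-9))
    return(structure(list(Q = Q, F = F, loglik = ll, trace = ll, K = 1L,
                          converged = TRUE, component_labels = NULL,
                          sample_id = g$samples$id,
                          variant_id = g$variants$id),
                     class = "admixture_fit"))
  }
  set.seed(seed)
  starts <- lapply(seq_len(n_init), function(s) {
    list(Q = rdirichlet(N, rep(1, K)),
         F = matrix(runif(K * M, 0.05, 0.95), K, M))
  })
  burns <- lapply(starts, function(st) {
    admixture_em_run(G0, G2, st$Q, st$F, tol = tol, max_iter = init_iter)
  })
  best <- which.max(vapply(burns, `[[`, numeric(1), "loglik"))
  fit <- admixture_em_run(G0, G2, burns[[best]]$Q, burns[[best]]$F,
                          tol = tol, max_iter = max_iter)
  fit$trace <- c(burns[[best]]$trace, fit$trace)
  if (!fit$converged) {
    warn(sprintf("admixture EM did not reach tol = %g within %d iterations",
                 tol, max_iter))
  }
  structure(c(fit, list(K = as.integer(K), component_labels = NULL,
                        sample_id = g$samples$id,
                        variant_id = g$variants$id)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d, %d samples, %d variants, loglik=%.2f%s\n",
              x$K, nrow(x$Q), ncol(x$F), x$loglik,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (!is.null(x$component_labels)) {
    cat("  components: ", paste(x$component_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Best component permutation against a reference
#'
#' Admixture components are identifiable only up to permutation.  This
#' exhaustively searches the K! permutations (K <= 8) for the one whose
#' reordered `Q` has the smallest mean absolute error against `Q_ref`.
#'
#' @param Q,Q_ref N x K proportion matrices.
#' @return Integer permutation `perm` with attribute `mae` such that
#'   `Q[, perm]` best matches `Q_ref`.
#' @export
match_components <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(K == ncol(Q_ref), K <= 8)
  perms <- permutations_of(K)
  maes <- vapply(perms, function(p) mean(abs(Q[, p] - Q_ref)), numeric(1))
  best <- which.min(maes)
  structure(perms[[best]], mae = maes[best])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- permutations_of(n - 1)
  out <- list()
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Label admixture components by SIRE majorities
#'
#' Applies priority rules of the form "the component on which most members
#' of SIRE group X load dominantly gets label L".  Rules are applied in
#' order, each restricted to components not yet labelled; a tie for the
#' majority leaves the component unlabelled with a warning.  The default
#' rules reproduce a K=4 continental labelling: majority NH-White ->
#' European, NH-AfAm -> African, NH-Asian -> East Asian, and the component
#' with the most HL-Other + HL-White dominant loadings -> Native American.
#'
#' @param fit an [fit_admixture()] result.
#' @param sire tibble (`person_id`, `sire`) covering `fit`'s samples.
#' @param rules named list, label -> character vector of SIRE groups whose
#'   dominant-component counts are summed.
#' @return `fit` with `component_labels` filled (NA where unlabelled).
#' @export
label_admixture_components <- function(fit, sire,
                                       rules = list(
                                         "European" = "NH-White",
                                         "African" = "NH-AfAm",
                                         "East Asian" = "NH-Asian",
                                         "Native American" = c("HL-Other", "HL-White"))) {
  stopifnot(inherits(fit, "admixture_fit"))
  sire_of <- setNames(sire$sire, sire$person_id)
  samp_sire <- unname(sire_of[fit$sample_id])
  dom <- max.col(fit$Q, ties.method = "first")
  labels <- rep(NA_character_, fit$K)
  for (lab in names(rules)) {
    groups <- rules[[lab]]
    open <- which(is.na(labels))
    if (length(open) == 0) break
    counts <- vapply(open, function(k) {
      sum(dom == k & samp_sire %in% groups, na.rm = TRUE)
    }, numeric(1))
    if (all(counts == 0)) next
    top <- which(counts == max(counts))
    if (length(top) > 1) {
      warn(sprintf("tie between components for label '%s'; label withheld", lab))
      next
    }
    labels[open[top]] <- lab
  }
  fit$component_labels <- labels
  fit
}

#' Tidy an admixture fit into long format
#'
#' @param x an `admixture_fit`.
#' @param ... unused.
#' @return Tibble (`id`, `component`, `label`, `proportion`).
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  K <- x$K
  labels <- x$component_labels %||% rep(NA_character_, K)
  purrr::map_dfr(seq_len(K), function(k) {
    tibble(id = x$sample_id, component = k,
           label = labels[k],
           proportion = x$Q[, k])
  })
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, n_samples = nrow(x$Q), n_variants = ncol(x$F),
         loglik = x$loglik, n_iter = length(x$trace),
         converged = isTRUE(x$converged))
}

#' Stacked-bar admixture plot
#'
#' @param object an `admixture_fit`.
#' @param order_by component index whose proportion orders the samples.
#' @param ... unused.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, order_by = 1, ...) {
  long <- tidy.admixture_fit(object)
  ord <- order(object$Q[, order_by])
  long$id <- factor(long$id, levels = object$sample_id[ord])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$proportion,
                                     fill = factor(.data$component))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = "component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
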