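test_that("PCA standardization centres variants and decorrelates scores", {
  set.seed(1)
  d <- matrix(rbinom(80 * 60, 2, runif(60, 0.2, 0.8)), 80, 60)
  g <- make_geno(d)
  pca <- fit_pca(g, n_pc = 5)
  # standardized columns have mean zero by construction
  p <- colMeans(d) / 2
  x <- sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(max(abs(colMeans(x))), 0, tolerance = 1e-12)
  # score covariance is diagonal
  s <- as.matrix(pca$scores[, paste0("PC", 1:5)])
  cv <- cov(s)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6)
  # loadings orthonormal
  vtv <- crossprod(pca$loadings)
  expect_equal(vtv, diag(5), tolerance = 1e-8)
  expect_error(fit_pca(g, n_pc = 100), "rank")
})

test_that("PC1 separates two diverged populations almost perfectly", {
  model <- population_model(K = 2, M = 1000, fst = 0.1, seed = 7)
  panel <- simulate_reference_panel(model, 150, seed = 8)
  pca <- fit_pca(panel, n_pc = 2)
  pc1 <- pca$scores$PC1
  pop <- panel$samples$population
  side <- pc1 > median(pc1)
  concord <- max(mean(side == (pop == "pop1")), mean(side == (pop == "pop2")))
  expect_gte(concord, 0.99)
})

test_that("KNN membership fractions follow hand-placed neighbourhoods", {
  train <- rbind(matrix(c(0, 0), 1), matrix(c(0.1, 0), 1),
                 matrix(c(10, 0), 1), matrix(c(10.1, 0), 1),
                 matrix(c(10.2, 0), 1))
  labels <- c("A", "A", "B", "B", "B")
  m <- knn_membership(train, labels, matrix(c(5.2, 0), 1), k = 2)
  expect_equal(unname(m[1, ]), c(0, 1))     # two nearest are the B side
  m2 <- knn_membership(train, labels, matrix(c(0, 0), 1), k = 2)
  expect_equal(unname(m2[1, ]), c(1, 0))
  expect_error(knn_membership(train, labels, matrix(c(0, 0), 1), k = 3),
               "fewer than k")
  # cross-check vote winner against the class package on a bigger draw
  skip_if_not_installed("class")
  set.seed(2)
  tr <- matrix(rnorm(200), 100, 2)
  lab <- ifelse(tr[, 1] + rnorm(100, sd = 0.2) > 0, "R", "L")
  qy <- matrix(rnorm(60), 30, 2)
  mm <- knn_membership(tr, lab, qy, k = 7)
  ours <- colnames(mm)[max.col(mm, ties.method = "first")]
  theirs <- as.character(class::knn(tr, qy, factor(lab), k = 7))
  expect_gte(mean(ours == theirs), 0.95)
})

# panel geometry used by the decision-rule tests: three tight clusters in
# PC1-2, plus five stray labelled points around the origin engineered to
# give a query the neighbour mix (2 A, 2 B, 1 C)
rule_scores <- function() {
  set.seed(3)
  cl <- function(cx, cy, n, lab, pre) {
    tibble::tibble(id = paste0(pre, seq_len(n)), source = "panel",
                   population = lab,
                   PC1 = rnorm(n, cx, 0.05), PC2 = rnorm(n, cy, 0.05),
                   PC3 = rnorm(n, 0, 0.05), PC4 = rnorm(n, 0, 0.05),
                   PC5 = rnorm(n, 0, 0.05))
  }
  panel <- dplyr::bind_rows(
    cl(30, 0, 30, "A", "a"), cl(0, 30, 30, "B", "b"), cl(-30, -30, 30, "C", "c"),
    tibble::tibble(id = paste0("stray", 1:5), source = "panel",
                   population = c("A", "A", "B", "B", "C"),
                   PC1 = c(0.3, -0.3, 0, 0, 0.2),
                   PC2 = c(0, 0, 0.3, -0.3, 0.2),
                   PC3 = 0, PC4 = 0, PC5 = 0))
  panel
}

test_that("the one-cluster membership rule assigns, splits and abstains correctly", {
  panel <- rule_scores()
  study <- tibble::tibble(
    id = c("inA", "mid"), source = "study", population = NA_character_,
    PC1 = c(30, 0), PC2 = c(0, 0), PC3 = 0, PC4 = 0, PC5 = 0)
  res <- assign_continental_gia(dplyr::bind_rows(panel, study),
                                k_grid = c(5), seed = 1)
  expect_identical(res$gia[res$id == "inA"], "A")
  expect_equal(res$membership[res$id == "inA"], 1.0)
  # the engineered query sees memberships (0.4, 0.4, 0.2): no cluster > 0.5
  mid <- res[res$id == "mid", ]
  expect_identical(mid$gia, "Ambiguous")
  expect_equal(unname(unlist(mid[, paste0("membership_", c("A", "B", "C"))])),
               c(0.4, 0.4, 0.2))
})

test_that("membership above 0.5 in two classifiers yields Ambiguous", {
  # orthogonal PC pairs: A's classifier looks at PC1-2, B's at PC3-4; the
  # query sits inside A's cluster in PC1-2 and inside B's in PC3-4
  set.seed(4)
  mk <- function(n, pre, lab, c12, c34) {
    tibble::tibble(id = paste0(pre, seq_len(n)), source = "panel",
                   population = lab,
                   PC1 = rnorm(n, c12[1], 0.1), PC2 = rnorm(n, c12[2], 0.1),
                   PC3 = rnorm(n, c34[1], 0.1), PC4 = rnorm(n, c34[2], 0.1))
  }
  panel <- dplyr::bind_rows(mk(30, "a", "A", c(0, 0), c(40, 40)),
                            mk(30, "b", "B", c(40, 40), c(0, 0)))
  study <- tibble::tibble(id = "q", source = "study",
                          population = NA_character_,
                          PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0)
  res <- assign_continental_gia(
    dplyr::bind_rows(panel, study),
    pc_pairs = list(A = c(1, 2), B = c(3, 4)),
    k_grid = c(5), seed = 1)
  expect_gt(res$membership_A, 0.5)
  expect_gt(res$membership_B, 0.5)
  expect_identical(res$gia, "Ambiguous")
})

test_that("GIA assignment recovers held-out panel populations and is threshold-monotone", {
  sim <- sim_gia_setting(K = 3, fst = 0.1, M = 800, n_train = 120,
                         n_holdout = 30, n_study = 300, seed = 11, n_pc = 6)
  res <- assign_continental_gia(sim$pca$scores, seed = 1)
  ho <- res[startsWith(res$id, "ho_"), ]
  truth <- sim$holdout_truth[ho$id]
  expect_gte(mean(ho$gia == truth), 0.99)
  expect_lt(mean(ho$gia == "Ambiguous"), 0.01)
  # raising the membership threshold never decreases the Ambiguous count
  ambi <- vapply(c(0.5, 0.7, 0.9), function(th) {
    r <- assign_continental_gia(sim$pca$scores, threshold = th, seed = 1)
    sum(r$gia == "Ambiguous")
  }, numeric(1))
  expect_true(all(diff(ambi) >= 0))
})

test_that("subcontinental assignment applies the 0.90 rule and drops small SIRE classes", {
  set.seed(5)
  mkpts <- function(n, cx, pre) {
    tibble::tibble(id = paste0(pre, seq_len(n)),
                   PC1 = rnorm(n, cx, 0.1), PC2 = rnorm(n, 0, 0.1),
                   PC3 = rnorm(n, 0, 0.1), PC4 = rnorm(n, 0, 0.1))
  }
  scores <- dplyr::bind_rows(
    mkpts(40, 0, "x"), mkpts(40, 20, "y"), mkpts(15, 40, "z"),
    tibble::tibble(id = c("q_in", "q_edge"),
                   PC1 = c(0, 10), PC2 = 0, PC3 = 0, PC4 = 0))
  labels <- c(setNames(rep("Chinese", 40), paste0("x", 1:40)),
              setNames(rep("Japanese", 40), paste0("y", 1:40)),
              setNames(rep("Thai", 15), paste0("z", 1:15)))
  res <- assign_subcontinental_gia(scores, labels, group_name = "EAA",
                                   k_grid = c(5), seed = 1)
  # the N = 15 class is dropped from the label set entirely
  expect_false("Thai" %in% attr(res, "classes"))
  expect_identical(res$gia[res$id == "q_in"], "Chinese")
  # midpoint query cannot exceed 0.90 membership
  expect_identical(res$gia[res$id == "q_edge"], "Ambiguous EAA")
  expect_lte(res$membership[res$id == "q_edge"], 0.90)
  expect_error(assign_subcontinental_gia(scores,
                                         labels[labels == "Thai"],
                                         min_group = 20), "no label class")
})

test_that("the 0.90 boundary is strict: 0.95 assigned, 0.85 ambiguous", {
  set.seed(6)
  # engineer k = 20 neighbourhoods with exactly 1 (resp. 3) off-class
  # points planted next to the query inside an otherwise pure cluster
  boundary_case <- function(n_planted) {
    a <- tibble::tibble(id = paste0("a", 1:40),
                        PC1 = rnorm(40, 0, 0.2), PC2 = rnorm(40, 0, 0.2),
                        PC3 = 0, PC4 = 0)
    b <- tibble::tibble(id = paste0("b", 1:40),
                        PC1 = rnorm(40, 50, 0.2), PC2 = rnorm(40, 0, 0.2),
                        PC3 = 0, PC4 = 0)
    planted <- tibble::tibble(id = paste0("pl", seq_len(n_planted)),
                              PC1 = 0.01 * seq_len(n_planted), PC2 = 0,
                              PC3 = 0, PC4 = 0)
    q <- tibble::tibble(id = "q", PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0)
    scores <- dplyr::bind_rows(a, b, planted, q)
    labels <- c(setNames(rep("A", 40), a$id), setNames(rep("B", 40), b$id),
                setNames(rep("B", n_planted), planted$id))
    assign_subcontinental_gia(scores, labels, group_name = "G",
                              k_grid = c(20), seed = 1)
  }
  r95 <- boundary_case(1)     # 19/20 = 0.95 > 0.90 -> assigned
  expect_identical(r95$gia[r95$id == "q"], "A")
  expect_equal(r95$membership[r95$id == "q"], 0.95)
  r85 <- boundary_case(3)     # 17/20 = 0.85 <= 0.90 -> ambiguous
  expect_identical(r85$gia[r85$id == "q"], "Ambiguous G")
  expect_equal(r85$membership[r85$id == "q"], 0.85)
})
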