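test_that("logistic fit recovers a planted effect and validates input", {
  set.seed(1)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  eta <- -1 + log(2) * x
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(y, cbind(exposure = x))
  b <- fit$coefficients[fit$coefficients$term == "exposure", ]
  expect_lt(abs(b$beta - log(2)), 0.15)
  expect_equal(b$or, exp(b$beta))
  expect_equal(b$ci_low, exp(b$beta - 1.96 * b$se))
  expect_true(b$p < 0.001)
  expect_error(fit_logistic(rep(1, 100), cbind(x = rnorm(100))), "degenerate")
  expect_error(fit_logistic(rbinom(100, 1, 0.5),
                            cbind(a = 1:100, b = 2 * (1:100))),
               "rank-deficient")
  expect_error(fit_logistic(c(0, 1, 1), cbind(x = 1:3)), "n >= 10")
})

test_that("swapping case/control coding flips every beta and keeps p", {
  set.seed(2)
  n <- 400
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, 1]))
  f1 <- fit_logistic(y, x)
  f2 <- fit_logistic(1 - y, x)
  expect_equal(f1$coefficients$beta, -f2$coefficients$beta, tolerance = 1e-6)
  expect_equal(f1$coefficients$p, f2$coefficients$p, tolerance = 1e-6)
})

test_that("complete separation is flagged with missing p-values", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  fit <- fit_logistic(y, cbind(sep = x))
  expect_identical(fit$flag, "separation")
  expect_true(all(is.na(fit$coefficients$p)))
})

test_that("type-I error of the logistic test is calibrated under the null", {
  set.seed(3)
  n <- 300
  rejections <- vapply(1:1000, function(i) {
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.3)
    f <- fit_logistic(y, cbind(x = x))
    f$coefficients$p[f$coefficients$term == "x"] < 0.05
  }, logical(1))
  ci <- binom.test(sum(rejections), 1000)$conf.int
  expect_gte(0.05, ci[1])
  expect_lte(0.05, ci[2])
})

test_that("fixed-effects meta-analysis matches hand arithmetic", {
  # identical inputs: beta unchanged, SE shrinks by sqrt(2)
  r1 <- tibble::tibble(variant_id = "v", group = c("a", "b"),
                       beta = 0.3, se = 0.1)
  m1 <- meta_fixed_effects(r1)
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.1 / sqrt(2))
  # hand inverse-variance: (0.4, 0.1) + (0.2, 0.2) -> 0.36, 0.0894
  r2 <- tibble::tibble(variant_id = "v", group = c("a", "b"),
                       beta = c(0.4, 0.2), se = c(0.1, 0.2))
  m2 <- meta_fixed_effects(r2)
  expect_equal(signif(m2$beta, 3), 0.36)
  expect_equal(signif(m2$se, 3), 0.0894)
  # combined SE never exceeds the best single-group SE
  expect_lt(m2$se, 0.1)
  # a variant in one group only is dropped
  r3 <- tibble::tibble(variant_id = c("v", "w"), group = c("a", "a"),
                       beta = 0.1, se = 0.1)
  expect_equal(nrow(meta_fixed_effects(r3)), 0)
  expect_error(meta_fixed_effects(tibble::tibble(
    variant_id = "v", group = c("a", "b"), beta = 0.1, se = c(0, 0.1))),
    "positive")
})

test_that("threshold arithmetic and lambda-GC behave as closed forms", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "n_tests")
  # exactly uniform p-value quantiles give lambda 1
  p <- (1:10000 - 0.5) / 10000
  expect_equal(lambda_gc(p), 1, tolerance = 0.01)
  expect_gt(lambda_gc(p / 2), 1)
  set.seed(4)
  expect_true(abs(lambda_gc(runif(10000)) - 1) < 0.05)
  expect_error(lambda_gc(numeric(0)), "empty")
  expect_error(lambda_gc(c(0.5, 0)), "p-values")
})

test_that("effective sample size follows the harmonic form", {
  # harmonic form: balanced counts give back the per-arm count
  expect_equal(n_effective(500, 500), 500)
  expect_equal(round(n_effective(100, 10000), 2), 198.02)
  set.seed(5)
  a <- sample(1:1000, 20); b <- sample(1:1000, 20)
  expect_true(all(n_effective(a, b) <= a + b))
  expect_error(n_effective(0, 10), ">= 1")
})


test_that("the GIA-phecode scan recovers a planted odds ratio with the right sign", {
  sim <- sim_scan_cohort(n_per_group = 400, planted = log(3), seed = 11,
                         prevalence = 0.15)
  scan <- phecode_gia_scan(sim$statuses, sim$gia, sim$demographics,
                           min_cases = 50)
  expect_equal(attr(scan, "threshold"),
               0.05 / attr(scan, "n_tests"))
  hit <- scan[scan$group == "EA" & scan$phecode == sim$phecodes[1], ]
  expect_lt(hit$p, attr(scan, "threshold"))
  expect_gt(hit$beta, 0)
  expect_lt(abs(hit$beta - log(3)), 0.5)
})

test_that("SIRE adjustment changes the design but keeps the planted signal detectable", {
  sim <- sim_scan_cohort(n_per_group = 400, planted = log(3), seed = 12,
                         prevalence = 0.15)
  scan <- phecode_gia_scan(sim$statuses, sim$gia, sim$demographics,
                           adjust_sire = TRUE, min_cases = 50)
  hit <- scan[scan$group == "EA" & scan$phecode == sim$phecodes[1], ]
  expect_lt(hit$p, attr(scan, "threshold"))
})

test_that("admixture-proportion scan finds planted effects and flags constant proportions", {
  set.seed(13)
  n <- 900
  demographics <- tibble::tibble(
    person_id = sprintf("p%04d", 1:n),
    age = runif(n, 18, 90),
    sex = sample(c("Male", "Female"), n, replace = TRUE),
    sire = rep(c("SA", "SB", "SC"), each = 300))
  q1 <- runif(n)
  q <- tibble::tibble(person_id = demographics$person_id,
                      q1 = q1, q2 = 1 - q1)
  # within SC the proportion is constant -> degenerate cell
  q$q1[demographics$sire == "SC"] <- 0.5
  q$q2[demographics$sire == "SC"] <- 0.5
  statuses <- tibble::tibble(
    person_id = demographics$person_id, phecode = "100.1",
    count = NA_integer_,
    status = ifelse(runif(n) < plogis(-0.5 - 1.5 * q$q1), "case", "control"))
  scan <- admixture_phecode_scan(statuses, q, demographics, min_cases = 10)
  a_row <- scan[scan$sire == "SA" & scan$component == "q1", ]
  expect_lt(a_row$beta, 0)                  # planted negative effect
  c_row <- scan[scan$sire == "SC" & scan$component == "q1", ]
  expect_true(is.na(c_row$p))
  expect_match(c_row$flag, "degenerate|constant")
})

test_that("GWAS applies in-group QC, recovers a planted variant and stays calibrated", {
  set.seed(14)
  n <- 1500; m <- 300
  p <- runif(m, 0.05, 0.5)
  p[1] <- 0.3                                # causal variant
  p[2] <- 0.005                              # fails the MAF > 1% rule
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  g <- make_geno(d, ids = sprintf("p%04d", 1:n))
  demographics <- tibble::tibble(person_id = g$samples$id,
                                 age = runif(n, 18, 90),
                                 sex = sample(c("Male", "Female"), n,
                                              replace = TRUE))
  pcs <- tibble::tibble(person_id = g$samples$id,
                        PC1 = rnorm(n), PC2 = rnorm(n))
  eta <- -1.2 + log(1.8) * d[, 1]
  phenotype <- tibble::tibble(
    person_id = g$samples$id,
    status = ifelse(runif(n) < plogis(eta), "case", "control"))
  scan <- gwas_scan(g, phenotype, demographics, pcs, min_cases = 50)
  expect_false("v2" %in% scan$variant_id)     # low-MAF variant excluded
  expect_identical(scan$variant_id[which.min(scan$p)], "v1")
  expect_gt(scan$beta[scan$variant_id == "v1"], 0)
  lam <- lambda_gc(scan$p[scan$variant_id != "v1" & !is.na(scan$p)])
  expect_gt(lam, 0.85)
  expect_lt(lam, 1.15)
  # too few cases aborts
  few <- phenotype
  few$status[-(1:40)] <- "control"
  expect_error(gwas_scan(g, few, demographics, pcs, min_cases = 50), "cases")
})

test_that("PheWAS reports both thresholds and honours sex-specific phecodes", {
  set.seed(15)
  n <- 800
  ids <- sprintf("p%04d", 1:n)
  demographics <- tibble::tibble(person_id = ids, age = runif(n, 18, 90),
                                 sex = rep(c("Male", "Female"), each = n / 2))
  pcs <- tibble::tibble(person_id = ids, PC1 = rnorm(n), PC2 = rnorm(n))
  dosage <- setNames(rbinom(n, 2, 0.4), ids)
  phecodes <- c("100.1", "200.2", "300.3")
  statuses <- purrr::map_dfr(phecodes, function(ph) {
    eta <- if (ph == "100.1") -1 + log(2.5) * dosage else -1
    tibble::tibble(person_id = ids, phecode = ph, count = NA_integer_,
                   status = ifelse(runif(n) < plogis(eta), "case", "control"))
  })
  sexspec <- tibble::tibble(phecode = phecodes,
                            sex_specific = c("none", "female", "none"))
  res <- phewas(dosage, statuses, demographics, pcs, sex_specific = sexspec,
                min_cases = 50)
  expect_equal(attr(res, "threshold"), 0.05 / nrow(res))
  expect_equal(attr(res, "threshold_stringent"), 5e-8 / nrow(res))
  expect_identical(res$phecode[which.min(res$p)], "100.1")
  # the female-specific phecode was fit in women only
  f_row <- res[res$phecode == "200.2", ]
  expect_lte(f_row$n_cases + f_row$n_controls, n / 2)
})
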