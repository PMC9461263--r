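test_that("reference panel generation is reproducible and valid", {
  model <- population_model(K = 2, M = 300, fst = 0.1, seed = 7)
  p1 <- simulate_reference_panel(model, 20, seed = 3)
  p2 <- simulate_reference_panel(model, 20, seed = 3)
  expect_identical(p1$dosage, p2$dosage)
  p3 <- simulate_reference_panel(model, 20, seed = 4)
  expect_false(identical(p1$dosage, p3$dosage))
  expect_true(all(p1$dosage %in% 0:2))
  expect_equal(sort(unique(p1$samples$population)), c("pop1", "pop2"))
  # positions strictly increasing within chromosome
  by_chr <- split(model$variants$bp, model$variants$chrom)
  expect_true(all(vapply(by_chr, function(x) all(diff(x) > 0), logical(1))))
})

test_that("invalid divergence parameters are rejected", {
  expect_error(population_model(2, 100, fst = 0), "fst")
  expect_error(population_model(2, 100, fst = 1), "fst")
})

test_that("vanishing divergence collapses populations onto the ancestral frequencies", {
  model <- population_model(K = 3, M = 2000, fst = 1e-4, seed = 1)
  dev <- abs(sweep(model$F_pop, 2, model$p_anc))
  expect_lt(mean(dev), 0.01)
})

test_that("simulated divergence matches an independent Hudson Fst estimate", {
  model <- population_model(K = 2, M = 2000, fst = 0.1, seed = 11)
  panel <- simulate_reference_panel(model, 200, seed = 12)
  fst_hat <- hudson_fst(panel, panel$samples$population)
  expect_lt(abs(fst_hat - 0.1), 0.03)
})

test_that("admixed cohort respects the Dirichlet group structure", {
  model <- population_model(K = 3, M = 200, fst = 0.1, seed = 2)
  spec <- cohort_spec(tibble::tibble(
    group = c("conc", "sym"),
    n = c(300, 300),
    sire = c("S1", "S2"),
    language = "English",
    alpha = list(c(100, 0.01, 0.01), c(1, 1, 1))
  ))
  sim <- simulate_admixed_cohort(model, spec, seed = 5)
  q <- as.matrix(sim$truth[, c("q1", "q2", "q3")])
  expect_equal(rowSums(q), rep(1, 600), tolerance = 1e-12)
  expect_gt(mean(q[sim$truth$group == "conc", 1]), 0.99)
  expect_equal(unname(colMeans(q[sim$truth$group == "sym", ])),
               rep(1 / 3, 3), tolerance = 0.06)
  expect_true(all(sim$genotypes$dosage %in% 0:2))
})

test_that("alpha of the wrong length is rejected", {
  model <- population_model(K = 3, M = 50, fst = 0.1, seed = 2)
  spec <- cohort_spec(tibble::tibble(group = "g", n = 10, sire = "S",
                                     language = "E", alpha = list(c(1, 1))))
  expect_error(simulate_admixed_cohort(model, spec), "length K")
})

test_that("SIRE label noise hits the requested rate", {
  model <- population_model(K = 2, M = 50, fst = 0.2, seed = 3)
  spec <- cohort_spec(tibble::tibble(
    group = c("a", "b"), n = c(500, 500), sire = c("SA", "SB"),
    language = "English", alpha = list(c(50, 0.1), c(0.1, 50))
  ), label_noise_rate = 0.1)
  # pool several cohorts so the estimate of the flip rate is tight
  n_mismatch <- 0L
  for (s in 1:5) {
    sim <- simulate_admixed_cohort(model, spec, seed = 8 + s)
    truth_sire <- ifelse(sim$truth$group == "a", "SA", "SB")
    n_mismatch <- n_mismatch + sum(sim$demographics$sire != truth_sire)
  }
  ci <- binom.test(n_mismatch, 5000)$conf.int
  expect_gte(0.1, ci[1])
  expect_lte(0.1, ci[2])
})

make_small_cohort <- function(n = 400, K = 2, seed = 21) {
  model <- population_model(K = K, M = 60, fst = 0.15, seed = seed)
  spec <- cohort_spec(tibble::tibble(
    group = paste0("g", seq_len(K)), n = rep(n / K, K),
    sire = paste0("S", seq_len(K)), language = "English",
    alpha = lapply(seq_len(K), function(k) ifelse(seq_len(K) == k, 20, 0.2))
  ))
  simulate_admixed_cohort(model, spec, seed = seed + 1)
}

test_that("encounter generation honours the logistic model and case construction", {
  sim <- make_small_cohort(n = 1000)
  ont <- synth_ontology(5, n_male = 1, n_female = 1, seed = 2)
  phecodes <- unique(ont$phecode)
  sexmap <- setNames(
    ont$sex_specific[match(phecodes, ont$phecode)], phecodes)
  pm <- phenotype_model(phecodes, beta0 = -1, sex_specific = sexmap)
  enc <- simulate_encounters(sim$truth, sim$demographics, pm, ont, seed = 4)
  # every case has at least one mapped occurrence
  counts <- count_occurrences(enc$encounters, ont, scope = "all")
  cases <- enc$case_truth[enc$case_truth$is_case, ]
  got <- dplyr::left_join(cases, counts, by = c("person_id", "phecode"))
  expect_true(all(!is.na(got$count) & got$count >= 1))
  # controls have no occurrence of their phecode
  ctrl <- enc$case_truth[!enc$case_truth$is_case, ]
  none <- dplyr::inner_join(ctrl, counts, by = c("person_id", "phecode"))
  expect_equal(nrow(none), 0)
  # null group effect: prevalence equal across groups within sampling error
  ph_none <- phecodes[sexmap == "none"][1]
  ct <- dplyr::inner_join(enc$case_truth[enc$case_truth$phecode == ph_none, ],
                          dplyr::rename(sim$truth[, c("id", "group")],
                                        person_id = "id"),
                          by = "person_id")
  prev <- tapply(ct$is_case, ct$group, mean)
  expect_lt(abs(diff(prev)), 0.08)
  # sex-specific phecodes appear only in the matching sex
  ph_f <- phecodes[sexmap == "female"][1]
  f_cases <- enc$case_truth[enc$case_truth$phecode == ph_f &
                              enc$case_truth$is_case, ]
  sex_of <- setNames(sim$demographics$sex, sim$demographics$person_id)
  expect_true(all(sex_of[f_cases$person_id] == "Female"))
})

test_that("IBD segment simulation respects community structure", {
  truth <- tibble::tibble(id = paste0("p", 1:60),
                          community = rep(1:3, each = 20))
  seg <- simulate_ibd_segments(truth, within_rate = 1.5, between_rate = 0,
                               seed = 6)
  expect_true(all(seg$cm > 0))
  comm_of <- setNames(truth$community, truth$id)
  expect_true(all(comm_of[seg$id1] == comm_of[seg$id2]))
  expect_error(simulate_ibd_segments(truth, within_rate = 0.1,
                                     between_rate = 0.2), "within_rate")
})
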