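# Shared reference-panel / study-cohort simulation used by the GIA tests
# and the acceptance suite.  Panel: K populations at the given divergence,
# n_train labelled samples per population plus n_holdout held-out samples
# per population treated as queries with known truth; study: admixed
# cohort of n_study samples.  Returns joint-PCA scores ready for the
# assignment functions (held-out and study rows carry source = "study").
sim_gia_setting <- function(K = 5, fst = 0.1, M = 1500, n_train = 200,
                            n_holdout = 40, n_study = 1000, seed = 42,
                            n_pc = 10) {
  model <- population_model(K = K, M = M, fst = fst, seed = seed)
  panel_all <- simulate_reference_panel(model, n_train + n_holdout,
                                        seed = seed + 1)
  hold_ix <- unlist(lapply(seq_len(K), function(k) {
    (k - 1) * (n_train + n_holdout) + n_train + seq_len(n_holdout)
  }))
  holdout <- panel_all[hold_ix, ]
  train <- panel_all[setdiff(seq_len(nrow(panel_all$dosage)), hold_ix), ]
  spec <- cohort_spec(tibble::tibble(
    group = paste0("grp", seq_len(K)),
    n = rep(n_study / K, K),
    sire = paste0("SIRE", seq_len(K)),
    language = "English",
    alpha = lapply(seq_len(K), function(k) ifelse(seq_len(K) == k, 15, 0.1))
  ))
  cohort <- simulate_admixed_cohort(model, spec, seed = seed + 2)
  # joint matrix: panel (labelled) + holdout + study as unlabelled queries
  queries <- geno_matrix(rbind(holdout$dosage, cohort$genotypes$dosage),
                         model$variants,
                         dplyr::bind_rows(
                           tibble::tibble(id = paste0("ho_", holdout$samples$id)),
                           cohort$genotypes$samples))
  merged <- align_to_reference(queries, train)$genotypes
  pca <- fit_pca(merged, n_pc = n_pc)
  list(model = model, train = train, holdout = holdout, cohort = cohort,
       pca = pca,
       holdout_truth = setNames(holdout$samples$population,
                                paste0("ho_", holdout$samples$id)))
}

sim_scan_cohort <- function(n_per_group = 300, n_phecodes = 8,
                            planted = NULL, seed = 10, prevalence = 0.35) {
  set.seed(seed)
  groups <- c("EA", "AA", "HL", "EAA")
  n <- n_per_group * length(groups)
  demographics <- tibble::tibble(
    person_id = sprintf("p%04d", 1:n),
    age = runif(n, 18, 90),
    sex = sample(c("Male", "Female"), n, replace = TRUE),
    sire = sample(paste0("S", 1:3), n, replace = TRUE))
  gia <- tibble::tibble(id = demographics$person_id,
                        gia = rep(groups, each = n_per_group))
  phecodes <- sprintf("%05.1f", 1:n_phecodes * 7 + 0.1)
  statuses <- purrr::map_dfr(phecodes, function(ph) {
    eta <- qlogis(prevalence)
    if (!is.null(planted) && ph == phecodes[1]) {
      eta <- eta + planted * (gia$gia == "EA")
    }
    tibble::tibble(person_id = demographics$person_id, phecode = ph,
                   count = NA_integer_,
                   status = ifelse(runif(n) < plogis(eta), "case", "control"))
  })
  list(demographics = demographics, gia = gia, statuses = statuses,
       phecodes = phecodes)
}

make_clique_edges <- function(members, weight = 10) {
  pairs <- t(combn(members, 2))
  tibble::tibble(id1 = pairs[, 1], id2 = pairs[, 2], total_cm = weight)
}
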