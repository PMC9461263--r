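#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one place, with
#' defaults matching the standard analysis: kinship inclusion < 0.0884
#' (degree-2) and relative filtering at 0.0442 (degree-3), >0.50
#' continental and >0.90 subcontinental membership, case minima 50/20/10,
#' KNN k grid \{5, 10, 15, 20\}, admixture K grid \{4, 5, 6\}, alpha 0.05
#' and genome-wide 5e-8.  Values supplied through `...` override defaults
#' (nested lists are merged).
#'
#' @param ... named overrides, e.g. `synth = list(M = 500)`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  base <- list(
    seed = 1,
    synth = list(
      K = 5, M = 2000, fst = 0.1, n_per_pop = 200, n_per_group = 200,
      alpha_own = 8, alpha_other = 0.25, label_noise_rate = 0.05,
      n_phecodes = 20, missing_rate = 0.002,
      ibd_within_rate = 2, ibd_between_rate = 0.05
    ),
    qc = list(
      variant_max_missing = 0.05, sample_max_missing = 0.05,
      dup_threshold = 0.354, kin_unrelated = 0.0884, kin_degree3 = 0.0442
    ),
    pca = list(
      maf = 0.15, geno = 0.05, hwe_p = 0.001,
      vif_window = 200, vif_step = 5, vif_max = 1.15,
      pair_window = 100, pair_step = 5, pair_r2 = 0.1, n_pc = 10
    ),
    gia = list(
      threshold = 0.50, sub_threshold = 0.90, k_grid = c(5, 10, 15, 20),
      min_group = 20
    ),
    admixture = list(K_grid = c(4, 5, 6), maf = 0.05, bp_space = 2000,
                     tol = 1e-6, max_iter = 2000, n_init = 5),
    phecode = list(min_occurrences = 1, scope = "all",
                   min_cases_gia = 50, min_cases_sub = 20,
                   min_cases_sire = 10),
    ibd = list(min_size = 100, min_degree = 30),
    assoc = list(alpha = 0.05, genomewide_p = 5e-8,
                 gwas_min_maf = 0.01, gwas_hwe_p = 1e-12, gwas_het_sd = 3,
                 gwas_min_cases = 50, run_gwas = FALSE),
    stages = list(synth = TRUE, qc = TRUE, ancestry = TRUE,
                  admixture = TRUE, ibd = TRUE, phenotypes = TRUE,
                  assoc = TRUE)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  structure(base, class = "run_config")
}

default_cohort_spec <- function(cfg) {
  K <- cfg$synth$K
  groups <- tibble(
    group = paste0("grp", seq_len(K)),
    n = rep(cfg$synth$n_per_group, K),
    sire = paste0("SIRE", seq_len(K)),
    language = "English",
    alpha = purrr::map(seq_len(K), function(k) {
      a <- rep(cfg$synth$alpha_other, K)
      a[k] <- cfg$synth$alpha_own
      a
    })
  )
  cohort_spec(groups, label_noise_rate = cfg$synth$label_noise_rate)
}

default_phenotype_model <- function(cfg, ontology) {
  phecodes <- unique(ontology$phecode)
  sex_spec <- ontology %>%
    distinct(.data$phecode, .data$sex_specific)
  beta_group <- list()
  # one planted ancestry-differential phecode; the rest are null in group
  beta_group[[phecodes[1]]] <- c(grp1 = log(3))
  phenotype_model(
    phecodes,
    beta0 = -2.0,
    beta_group = beta_group,
    beta_sex = 0.2, beta_age = 0.3,
    sex_specific = setNames(sex_spec$sex_specific, sex_spec$phecode)
  )
}

write_stage <- function(x, dir, name) {
  readr::write_tsv(as_tibble(x), file.path(dir, paste0(name, ".tsv")))
}

#' Run the pipeline end-to-end
#'
#' Executes synthetic-data generation (or ingestion of files already in
#' `dir`), genotype QC, reference-anchored PCA + GIA assignment, admixture
#' estimation, IBD community detection, phecode construction, and the
#' ancestry-aware association scans, writing every stage output as TSV (or
#' PLINK for genotypes) into `dir` together with a JSON manifest capturing
#' the resolved configuration, seed and config hash.  A stage toggled off
#' in `config$stages` is loaded from its files in `dir` when present, and
#' the run fails fast when a downstream stage needs missing outputs.
#'
#' @param config a [run_config()].
#' @param dir run directory (created if needed).
#' @return A list with the in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("giabank_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list(dir = dir)

  ## ---- synthetic data -------------------------------------------------
  if (config$stages$synth) {
    model <- population_model(config$synth$K, config$synth$M,
                              fst = config$synth$fst, seed = seed)
    panel <- simulate_reference_panel(model, config$synth$n_per_pop,
                                      seed = seed + 1)
    spec <- default_cohort_spec(config)
    cohort <- simulate_admixed_cohort(model, spec, seed = seed + 2,
                                      missing_rate = config$synth$missing_rate)
    ontology <- synth_ontology(config$synth$n_phecodes, seed = seed + 3)
    pheno <- default_phenotype_model(config, ontology)
    encs <- simulate_encounters(cohort$truth, cohort$demographics, pheno,
                                ontology, seed = seed + 4)
    segments <- simulate_ibd_segments(cohort$truth,
                                      within_rate = config$synth$ibd_within_rate,
                                      between_rate = config$synth$ibd_between_rate,
                                      seed = seed + 5)
    write_plink(cohort$genotypes, file.path(dir, "study"))
    write_plink(panel, file.path(dir, "panel"))
    write_stage(cohort$demographics, dir, "demographics")
    write_stage(cohort$truth, dir, "truth")
    write_stage(ontology, dir, "ontology")
    write_stage(encs$encounters, dir, "encounters")
    write_stage(segments, dir, "ibd_segments")
    res$panel <- panel; res$cohort <- cohort; res$ontology <- ontology
    res$encounters <- encs$encounters; res$segments <- segments
  } else {
    need <- file.path(dir, c("study.bed", "panel.bed", "demographics.tsv",
                             "ontology.tsv", "encounters.tsv",
                             "ibd_segments.tsv"))
    if (!all(file.exists(need))) {
      abort("synth stage disabled and its outputs are missing from `dir`")
    }
    res$panel <- read_plink(file.path(dir, "panel"))
    res$panel$samples$population <-
      readr::read_tsv(file.path(dir, "panel_labels.tsv"),
                      show_col_types = FALSE)$population
    res$cohort <- list(genotypes = read_plink(file.path(dir, "study")),
                       demographics = readr::read_tsv(
                         file.path(dir, "demographics.tsv"),
                         show_col_types = FALSE))
    res$ontology <- readr::read_tsv(file.path(dir, "ontology.tsv"),
                                    show_col_types = FALSE)
    res$encounters <- readr::read_tsv(file.path(dir, "encounters.tsv"),
                                      show_col_types = FALSE)
    res$segments <- readr::read_tsv(file.path(dir, "ibd_segments.tsv"),
                                    show_col_types = FALSE)
  }
  if (config$stages$synth) {
    write_stage(res$panel$samples, dir, "panel_labels")
  }

  ## ---- genotype QC ----------------------------------------------------
  if (config$stages$qc) {
    vq <- qc_variants(res$cohort$genotypes,
                      max_missing = config$qc$variant_max_missing)
    sq <- qc_samples(vq$genotypes,
                     max_missing = config$qc$sample_max_missing)
    kin <- estimate_kinship(sq$genotypes)
    dd <- remove_duplicates(sq$genotypes, kin,
                            dup_threshold = config$qc$dup_threshold)
    unrel <- unrelated_set(kin, threshold = config$qc$kin_unrelated,
                           ids = dd$genotypes$samples$id)
    res$qc <- list(genotypes = dd$genotypes, kinship = kin,
                   unrelated = unrel,
                   report = dplyr::bind_rows(vq$report, sq$report, dd$report))
    write_stage(kin, dir, "kinship")
    write_stage(res$qc$report, dir, "qc_report")
    writeLines(unrel, file.path(dir, "unrelated_ids.txt"))
  } else {
    abort_if_missing(dir, "kinship.tsv", "qc")
    res$qc <- list(genotypes = res$cohort$genotypes,
                   kinship = readr::read_tsv(file.path(dir, "kinship.tsv"),
                                             show_col_types = FALSE),
                   unrelated = readLines(file.path(dir, "unrelated_ids.txt")))
  }

  ## ---- ancestry: joint PCA + GIA --------------------------------------
  if (config$stages$ancestry) {
    prep <- res$qc$genotypes %>%
      maf_filter(config$pca$maf)
    prep <- hwe_filter(prep$genotypes, config$pca$hwe_p)
    merged <- align_to_reference(prep$genotypes, res$panel)
    keep1 <- ld_prune_vif(merged$genotypes, config$pca$vif_window,
                          config$pca$vif_step, config$pca$vif_max)
    pruned <- merged$genotypes[, keep1]
    keep2 <- ld_prune_pairwise(pruned, config$pca$pair_window,
                               config$pca$pair_step, config$pca$pair_r2)
    pruned <- pruned[, keep2]
    pca <- fit_pca(pruned, n_pc = config$pca$n_pc)
    gia <- assign_continental_gia(pca$scores,
                                  threshold = config$gia$threshold,
                                  k_grid = config$gia$k_grid,
                                  seed = seed)
    res$pca <- pca
    res$gia <- gia
    write_stage(pca$scores, dir, "pca_scores")
    write_stage(gia, dir, "gia")
  } else {
    abort_if_missing(dir, "gia.tsv", "ancestry")
    res$gia <- readr::read_tsv(file.path(dir, "gia.tsv"),
                               show_col_types = FALSE)
  }

  ## ---- admixture ------------------------------------------------------
  if (config$stages$admixture) {
    am <- maf_filter(res$qc$genotypes, config$admixture$maf)
    keep <- prune_bp_spacing(am$genotypes, config$admixture$bp_space)
    am_g <- am$genotypes[, keep]
    fits <- lapply(config$admixture$K_grid, function(K) {
      fit_admixture(am_g, K = K, seed = seed,
                    tol = config$admixture$tol,
                    max_iter = config$admixture$max_iter,
                    n_init = config$admixture$n_init)
    })
    names(fits) <- paste0("K", config$admixture$K_grid)
    res$admixture <- fits
    qmain <- fits[[1]]
    q_tbl <- as_tibble(qmain$Q, .name_repair = ~paste0("q", seq_len(qmain$K)))
    q_tbl <- dplyr::bind_cols(tibble(person_id = qmain$sample_id), q_tbl)
    res$q <- q_tbl
    write_stage(q_tbl, dir, "admixture_q")
  } else {
    abort_if_missing(dir, "admixture_q.tsv", "admixture")
    res$q <- readr::read_tsv(file.path(dir, "admixture_q.tsv"),
                             show_col_types = FALSE)
  }

  ## ---- IBD communities ------------------------------------------------
  if (config$stages$ibd) {
    edges <- total_pairwise_ibd(res$segments)
    edges <- filter_relatives(edges, res$qc$kinship,
                              phi_cutoff = config$qc$kin_degree3)
    comm <- detect_communities(edges, seed = seed)
    rep_tbl <- summarize_communities(comm, edges,
                                     min_size = config$ibd$min_size,
                                     min_degree = config$ibd$min_degree)
    res$ibd <- list(edges = edges, communities = comm, report = rep_tbl)
    write_stage(edges, dir, "ibd_edges")
    write_stage(comm, dir, "ibd_communities")
  }

  ## ---- phecodes -------------------------------------------------------
  if (config$stages$phenotypes) {
    counts <- count_occurrences(res$encounters, res$ontology,
                                scope = config$phecode$scope)
    statuses <- define_cases(counts, res$cohort$demographics$person_id,
                             min_occurrences = config$phecode$min_occurrences)
    res$phecodes <- statuses
    write_stage(statuses, dir, "phecode_statuses")
  } else {
    abort_if_missing(dir, "phecode_statuses.tsv", "phenotypes")
    res$phecodes <- readr::read_tsv(file.path(dir, "phecode_statuses.tsv"),
                                    show_col_types = FALSE)
  }

  ## ---- association scans ----------------------------------------------
  if (config$stages$assoc) {
    sexspec <- distinct(res$ontology, .data$phecode, .data$sex_specific)
    gia_scan <- phecode_gia_scan(res$phecodes, res$gia,
                                 res$cohort$demographics,
                                 min_cases = config$phecode$min_cases_gia,
                                 alpha = config$assoc$alpha,
                                 sex_specific = sexspec)
    adm_scan <- admixture_phecode_scan(res$phecodes, res$q,
                                       res$cohort$demographics,
                                       min_cases = config$phecode$min_cases_sire,
                                       alpha = config$assoc$alpha,
                                       sex_specific = sexspec)
    res$assoc <- list(gia_scan = gia_scan, admixture_scan = adm_scan)
    write_stage(gia_scan, dir, "scan_gia")
    write_stage(adm_scan, dir, "scan_admixture")
    if (isTRUE(config$assoc$run_gwas)) {
      grp_tab <- table(res$gia$gia[res$gia$gia != "Ambiguous"])
      grp <- names(sort(grp_tab, decreasing = TRUE))[1]
      ids <- intersect(res$gia$id[res$gia$gia == grp],
                       res$qc$genotypes$samples$id)
      g_grp <- res$qc$genotypes[ids, ]
      pcs <- fit_pca(g_grp, n_pc = config$pca$n_pc)$scores %>%
        rename(person_id = "id")
      case_counts <- res$phecodes %>%
        filter(.data$status == "case", .data$person_id %in% ids) %>%
        count(.data$phecode, sort = TRUE)
      ph <- case_counts$phecode[1]
      phenotype <- res$phecodes %>%
        filter(.data$phecode == ph) %>%
        dplyr::select("person_id", "status")
      gw <- gwas_scan(g_grp, phenotype, res$cohort$demographics, pcs,
                      min_maf = config$assoc$gwas_min_maf,
                      hwe_p = config$assoc$gwas_hwe_p,
                      het_sd = config$assoc$gwas_het_sd,
                      min_cases = config$assoc$gwas_min_cases,
                      genomewide_p = config$assoc$genomewide_p)
      top <- gw$variant_id[which.min(gw$p)]
      dos <- setNames(g_grp$dosage[, top], g_grp$samples$id)
      pw <- phewas(dos, res$phecodes, res$cohort$demographics, pcs,
                   sex_specific = sexspec,
                   min_cases = config$assoc$gwas_min_cases,
                   alpha = config$assoc$alpha,
                   genomewide_p = config$assoc$genomewide_p)
      res$assoc$gwas <- gw
      res$assoc$phewas <- pw
      write_stage(gw, dir, "scan_gwas")
      write_stage(pw, dir, "scan_phewas")
    }
  }

  manifest <- list(
    package = "giabank",
    version = as.character(utils::packageVersion("giabank")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    thresholds = list(
      kin_unrelated = config$qc$kin_unrelated,
      kin_degree3 = config$qc$kin_degree3,
      gia_membership = config$gia$threshold,
      sub_gia_membership = config$gia$sub_threshold,
      min_cases_gia = config$phecode$min_cases_gia,
      min_cases_sub = config$phecode$min_cases_sub,
      min_cases_sire = config$phecode$min_cases_sire,
      alpha = config$assoc$alpha,
      genomewide_p = config$assoc$genomewide_p,
      k_grid = config$gia$k_grid,
      K_grid = config$admixture$K_grid
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res
}

abort_if_missing <- function(dir, file, stage) {
  if (!file.exists(file.path(dir, file))) {
    abort(sprintf("stage '%s' disabled and %s is missing from `dir`",
                  stage, file))
  }
}
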