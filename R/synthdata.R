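#' Ancestral population model for simulation
#'
#' Defines K ancestral populations diverged from a common ancestral allele
#' frequency spectrum under the Balding-Nichols model: per-population
#' frequencies are Beta-distributed around the ancestral frequency `p` with
#' shape1 = p(1-F)/F and shape2 = (1-p)(1-F)/F, so that E[p_k] = p and the
#' dispersion across populations is governed by the divergence parameter F
#' (an Fst-like quantity in (0, 1)).
#'
#' @param K number of ancestral populations (>= 1).
#' @param M number of variants.
#' @param fst divergence parameter, scalar or length-K vector, each in (0, 1).
#' @param ancestral_range range the ancestral frequencies are drawn from;
#'   kept away from 0/1 so simulated variants are informative.
#' @param n_chrom number of chromosomes the variants are spread over.
#' @param bp_spacing mean spacing in bp between adjacent variants.
#' @param seed RNG seed.
#'
#' @return A `population_model` list with the ancestral frequencies `p_anc`,
#'   the K x M per-population frequency matrix `F_pop`, and a `variants`
#'   tibble (id, chrom, bp, allele1, allele2).
#' @export
population_model <- function(K, M, fst = 0.1,
                             ancestral_range = c(0.05, 0.95),
                             n_chrom = 2, bp_spacing = 5000, seed = 1) {
  stopifnot(K >= 1, M >= 1)
  fst <- rep_len(fst, K)
  if (any(fst <= 0 | fst >= 1)) abort("`fst` must lie strictly in (0, 1)")
  if (ancestral_range[1] < 0.05 - 1e-12 || ancestral_range[2] > 0.95 + 1e-12) {
    abort("`ancestral_range` must lie within (0.05, 0.95)")
  }
  set.seed(seed)
  p_anc <- runif(M, ancestral_range[1], ancestral_range[2])
  F_pop <- matrix(NA_real_, K, M)
  for (k in seq_len(K)) {
    f <- fst[k]
    F_pop[k, ] <- rbeta(M, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  chrom <- sort(rep_len(seq_len(n_chrom), M))
  bp <- unlist(lapply(split(seq_len(M), chrom), function(ix) {
    cumsum(1 + rpois(length(ix), bp_spacing - 1))
  }), use.names = FALSE)
  # alleles drawn as a non-ambiguous pair by default; a little A/T and C/G
  # contamination can be injected downstream when QC needs positive cases
  pairs <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, M, replace = TRUE)
  variants <- tibble(
    id = paste0("var", seq_len(M)),
    chrom = chrom, bp = bp,
    allele1 = pairs[pick, 1], allele2 = pairs[pick, 2]
  )
  structure(list(K = K, M = M, fst = fst, p_anc = p_anc, F_pop = F_pop,
                 variants = variants, seed = seed),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> K=%d populations, M=%d variants, fst=%s\n",
              x$K, x$M, paste(signif(x$fst, 3), collapse = "/")))
  invisible(x)
}

#' Cohort specification for an admixed study population
#'
#' Each labelled group draws its individual admixture proportions from a
#' Dirichlet distribution; self-identified race/ethnicity (SIRE) and
#' preferred language are attached per group, with a tunable rate at which
#' the recorded SIRE disagrees with the individual's dominant ancestry.
#'
#' @param groups tibble with one row per group: `group`, `n`, `sire`,
#'   `language`, and a list-column `alpha` of length-K Dirichlet parameters.
#' @param label_noise_rate probability that a sample's recorded SIRE is
#'   flipped to another group's SIRE.
#' @param age_range ages are drawn uniformly on this interval.
#' @param p_female probability of Female sex.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, label_noise_rate = 0,
                        age_range = c(18, 90), p_female = 0.5) {
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "n", "sire", "alpha") %in% names(groups)))
  if (!"language" %in% names(groups)) groups$language <- "English"
  if (any(vapply(groups$alpha, function(a) any(a <= 0), logical(1)))) {
    abort("all Dirichlet `alpha` entries must be > 0")
  }
  if (label_noise_rate < 0 || label_noise_rate > 1) {
    abort("`label_noise_rate` must be in [0, 1]")
  }
  structure(list(groups = groups, label_noise_rate = label_noise_rate,
                 age_range = age_range, p_female = p_female),
            class = "cohort_spec")
}

#' Simulate a labelled reference panel
#'
#' Draws `n_per_pop` individuals from each ancestral population of `model`,
#' with genotypes Binomial(2, p_k) at each variant; the population label is
#' attached to the sample metadata (as `population`), standing in for a
#' labelled public panel.
#'
#' @param model a [population_model()].
#' @param n_per_pop samples per population (scalar or length-K).
#' @param seed RNG seed.
#' @param missing_rate optional fraction of dosages set missing (default 0).
#' @param pop_names optional population labels (default pop1..popK).
#'
#' @return A labelled [geno_matrix()].
#' @export
simulate_reference_panel <- function(model, n_per_pop, seed = 1,
                                     missing_rate = 0, pop_names = NULL) {
  stopifnot(inherits(model, "population_model"), all(n_per_pop >= 1))
  n_per_pop <- rep_len(n_per_pop, model$K)
  pop_names <- pop_names %||% paste0("pop", seq_len(model$K))
  set.seed(seed)
  N <- sum(n_per_pop)
  d <- matrix(NA_real_, N, model$M)
  pops <- rep(pop_names, n_per_pop)
  row <- 1
  for (k in seq_len(model$K)) {
    for (s in seq_len(n_per_pop[k])) {
      d[row, ] <- rbinom(model$M, 2, model$F_pop[k, ])
      row <- row + 1
    }
  }
  if (missing_rate > 0) {
    d[matrix(runif(length(d)) < missing_rate, nrow(d))] <- NA
  }
  samples <- tibble(id = sprintf("ref%04d", seq_len(N)), population = pops)
  geno_matrix(d, model$variants, samples)
}

#' Simulate an admixed study cohort with demographics
#'
#' Per-sample admixture proportions q_i are Dirichlet draws from the sample's
#' group; genotypes are Binomial(2, sum_k q_ik f_kj).  Demographics (age,
#' sex, SIRE, preferred language) are attached, with SIRE flipped to a
#' random other group's label at `label_noise_rate`.
#'
#' @param model a [population_model()].
#' @param spec a [cohort_spec()]; `alpha` vectors must have length `model$K`.
#' @param seed RNG seed.
#' @param missing_rate optional fraction of dosages set missing.
#'
#' @return A list with `genotypes` ([geno_matrix()]), `truth` (tibble:
#'   `id`, `group`, `q.1..q.K`, `dominant_pop`, `community`) and
#'   `demographics` (tibble: `person_id`, `age`, `sex`, `sire`, `language`).
#' @export
simulate_admixed_cohort <- function(model, spec, seed = 1, missing_rate = 0) {
  stopifnot(inherits(model, "population_model"), inherits(spec, "cohort_spec"))
  if (nrow(spec$groups) == 0) abort("`spec` must contain at least one group")
  bad_len <- vapply(spec$groups$alpha, length, integer(1)) != model$K
  if (any(bad_len)) abort("every `alpha` must have length K")
  set.seed(seed)
  N <- sum(spec$groups$n)
  Q <- matrix(NA_real_, N, model$K)
  grp <- rep(spec$groups$group, spec$groups$n)
  row <- 1
  for (gi in seq_len(nrow(spec$groups))) {
    ng <- spec$groups$n[gi]
    Q[row:(row + ng - 1), ] <- rdirichlet(ng, spec$groups$alpha[[gi]])
    row <- row + ng
  }
  P <- Q %*% model$F_pop                      # N x M individual-specific freqs
  d <- matrix(rbinom(N * model$M, 2, P), N, model$M)
  if (missing_rate > 0) {
    d[matrix(runif(length(d)) < missing_rate, N)] <- NA
  }
  ids <- sprintf("study%05d", seq_len(N))
  sire_of_group <- setNames(spec$groups$sire, spec$groups$group)
  lang_of_group <- setNames(spec$groups$language, spec$groups$group)
  sire <- unname(sire_of_group[grp])
  flip <- runif(N) < spec$label_noise_rate
  if (any(flip) && length(unique(spec$groups$sire)) > 1) {
    sire[flip] <- vapply(sire[flip], function(s) {
      sample(setdiff(unique(spec$groups$sire), s), 1)
    }, character(1))
  }
  demographics <- tibble(
    person_id = ids,
    age = runif(N, spec$age_range[1], spec$age_range[2]),
    sex = ifelse(runif(N) < spec$p_female, "Female", "Male"),
    sire = sire,
    language = unname(lang_of_group[grp])
  )
  truth <- tibble(id = ids, group = grp)
  colnames(Q) <- paste0("q", seq_len(model$K))
  truth <- dplyr::bind_cols(truth, as_tibble(Q))
  truth$dominant_pop <- paste0("pop", max.col(Q))
  truth$community <- as.integer(factor(grp, levels = spec$groups$group))
  genotypes <- geno_matrix(d, model$variants, tibble(id = ids))
  list(genotypes = genotypes, truth = truth, demographics = demographics)
}

#' Miniature synthetic phecode ontology
#'
#' Builds an ICD -> phecode map over a synthetic code space: each phecode
#' owns 1-3 ICD-10-style codes, and a configurable number of phecodes are
#' marked sex-specific.
#'
#' @param n_phecodes number of phecodes.
#' @param n_male,n_female how many phecodes are male-/female-specific.
#' @param seed RNG seed.
#' @return A tibble (`icd_code`, `icd_version`, `phecode`, `phecode_label`,
#'   `sex_specific` in \{none, male, female\}).
#' @export
synth_ontology <- function(n_phecodes = 20, n_male = 1, n_female = 2, seed = 1) {
  stopifnot(n_male + n_female <= n_phecodes)
  set.seed(seed)
  phecode <- sprintf("%05.1f", seq_len(n_phecodes) * 8 + 0.1)
  sex_specific <- rep("none", n_phecodes)
  if (n_male > 0) sex_specific[seq_len(n_male)] <- "male"
  if (n_female > 0) sex_specific[n_male + seq_len(n_female)] <- "female"
  n_icd <- sample(1:3, n_phecodes, replace = TRUE)
  purrr::map_dfr(seq_len(n_phecodes), function(i) {
    tibble(
      icd_code = sprintf("Z%02d.%d", i, seq_len(n_icd[i])),
      icd_version = "ICD10",
      phecode = phecode[i],
      phecode_label = paste0("synthetic phenotype ", phecode[i]),
      sex_specific = sex_specific[i]
    )
  })
}

#' Phenotype generating model
#'
#' Per-phecode logistic model for case status:
#' logit P(case) = b0 + b1[group] + b2 * I(sex = Female) + b3 * age_std +
#' sum over causal variants of beta_snp * dosage.  Ages are standardised to
#' (age - 50)/20 inside the generator so intercepts stay interpretable as
#' baseline log-odds.
#'
#' @param phecodes character vector of phecode ids the model covers.
#' @param beta0 baseline log-odds (scalar or per-phecode).
#' @param beta_group named list: phecode -> named numeric of per-group
#'   log-odds shifts (groups absent default to 0).
#' @param beta_sex,beta_age scalar log-odds for Female sex and standardised
#'   age (recycled per phecode).
#' @param causal named list: phecode -> tibble(variant_id, beta).
#' @param sex_specific named character: phecode -> "none"/"male"/"female".
#' @return A `phenotype_model` list.
#' @export
phenotype_model <- function(phecodes, beta0 = -2.2, beta_group = list(),
                            beta_sex = 0, beta_age = 0, causal = list(),
                            sex_specific = NULL) {
  n <- length(phecodes)
  mdl <- list(
    phecodes = phecodes,
    beta0 = rep_len(beta0, n),
    beta_group = beta_group,
    beta_sex = rep_len(beta_sex, n),
    beta_age = rep_len(beta_age, n),
    causal = causal,
    sex_specific = sex_specific %||% setNames(rep("none", n), phecodes)
  )
  structure(mdl, class = "phenotype_model")
}

#' Simulate encounter-level ICD records
#'
#' Draws case status per (person, phecode) from the phenotype model, then
#' gives every case one or more encounters carrying a mapped ICD code,
#' spread over visit-like and message-like encounter types.  Controls
#' receive no encounter for that phecode.  Sex-specific phecodes are only
#' generated in the matching sex.
#'
#' @param truth truth table from [simulate_admixed_cohort()] (uses `id`,
#'   `group`).
#' @param demographics demographics tibble (uses `person_id`, `age`, `sex`).
#' @param pheno_model a [phenotype_model()].
#' @param ontology ontology tibble as from [synth_ontology()]; must map every
#'   generated ICD.
#' @param genotypes optional [geno_matrix()], required when the model has
#'   causal variants.
#' @param mean_extra_occurrences mean number of additional occurrences per
#'   case beyond the guaranteed first (Poisson).
#' @param p_visit probability an occurrence is attached to a visit-type
#'   encounter (appointment/office/hospital/procedure) rather than a
#'   message-like one.
#' @param seed RNG seed.
#'
#' @return A list: `encounters` tibble (`person_id`, `encounter_id`, `date`,
#'   `encounter_type`, `icd_code`, `icd_version`) and `case_truth` tibble
#'   (`person_id`, `phecode`, `p_case`, `is_case`).
#' @export
simulate_encounters <- function(truth, demographics, pheno_model, ontology,
                                genotypes = NULL, mean_extra_occurrences = 1.5,
                                p_visit = 0.8, seed = 1) {
  stopifnot(inherits(pheno_model, "phenotype_model"))
  if (!all(pheno_model$phecodes %in% ontology$phecode)) {
    abort("every modelled phecode needs at least one ICD in `ontology`")
  }
  set.seed(seed)
  dem <- dplyr::left_join(demographics,
                          dplyr::select(truth, person_id = "id", "group"),
                          by = "person_id")
  age_std <- (dem$age - 50) / 20
  female <- as.numeric(dem$sex == "Female")
  visit_types <- c("appointment", "office", "hospital", "procedure")
  message_types <- c("message", "phone", "lab", "note")
  case_truth <- vector("list", length(pheno_model$phecodes))
  enc <- vector("list", length(pheno_model$phecodes))
  for (i in seq_along(pheno_model$phecodes)) {
    ph <- pheno_model$phecodes[i]
    eta <- pheno_model$beta0[i] +
      pheno_model$beta_sex[i] * female +
      pheno_model$beta_age[i] * age_std
    bg <- pheno_model$beta_group[[ph]]
    if (!is.null(bg)) {
      shift <- bg[dem$group]
      shift[is.na(shift)] <- 0
      eta <- eta + unname(shift)
    }
    cz <- pheno_model$causal[[ph]]
    if (!is.null(cz)) {
      if (is.null(genotypes)) abort("causal variants require `genotypes`")
      for (r in seq_len(nrow(cz))) {
        dos <- genotypes$dosage[, cz$variant_id[r]]
        dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
        eta <- eta + cz$beta[r] * dos[match(dem$person_id,
                                            genotypes$samples$id)]
      }
    }
    p <- stats::plogis(eta)
    sx <- pheno_model$sex_specific[[ph]] %||% "none"
    if (sx == "male") p[dem$sex != "Male"] <- 0
    if (sx == "female") p[dem$sex != "Female"] <- 0
    is_case <- runif(nrow(dem)) < p
    case_truth[[i]] <- tibble(person_id = dem$person_id, phecode = ph,
                              p_case = p, is_case = is_case)
    cases <- which(is_case)
    if (length(cases) > 0) {
      n_occ <- 1 + rpois(length(cases), mean_extra_occurrences)
      icds <- ontology[ontology$phecode == ph, ]
      rows <- purrr::map_dfr(seq_along(cases), function(ci) {
        k <- n_occ[ci]
        is_v <- runif(k) < p_visit
        tibble(
          person_id = dem$person_id[cases[ci]],
          encounter_type = ifelse(is_v,
                                  sample(visit_types, k, replace = TRUE),
                                  sample(message_types, k, replace = TRUE)),
          icd_code = icds$icd_code[sample.int(nrow(icds), k, replace = TRUE)],
          icd_version = icds$icd_version[1]
        )
      })
      enc[[i]] <- rows
    }
  }
  encounters <- dplyr::bind_rows(enc)
  if (nrow(encounters) == 0) {
    encounters <- tibble(person_id = character(), encounter_id = character(),
                         date = as.Date(character()),
                         encounter_type = character(),
                         icd_code = character(), icd_version = character())
  } else {
    encounters$encounter_id <- sprintf("enc%07d", seq_len(nrow(encounters)))
    encounters$date <- as.Date("2020-01-01") +
      sample.int(700, nrow(encounters), replace = TRUE)
    encounters <- dplyr::select(encounters, "person_id", "encounter_id",
                                "date", "encounter_type", "icd_code",
                                "icd_version")
  }
  list(encounters = encounters, case_truth = dplyr::bind_rows(case_truth))
}

#' Simulate community-structured IBD segments
#'
#' Pairs in the same true community share more segments in expectation:
#' per-pair segment counts are Poisson with rate `within_rate` inside a
#' community and `between_rate` across communities; segment lengths are
#' exponential with mean `mean_cm` (floored at 1 cM).
#'
#' @param truth truth table with `id` and `community`.
#' @param within_rate,between_rate expected segments per pair; must satisfy
#'   `within_rate > between_rate >= 0`.
#' @param mean_cm mean segment length in cM.
#' @param seed RNG seed.
#' @return Segment tibble (`id1`, `id2`, `chrom`, `start_bp`, `end_bp`, `cm`),
#'   coordinates 1-based inclusive.
#' @export
simulate_ibd_segments <- function(truth, within_rate = 2, between_rate = 0.05,
                                  mean_cm = 10, seed = 1) {
  if (!(within_rate > between_rate && between_rate >= 0)) {
    abort("need `within_rate` > `between_rate` >= 0")
  }
  set.seed(seed)
  ids <- truth$id
  comm <- truth$community
  n <- length(ids)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  same <- comm[pairs[, 1]] == comm[pairs[, 2]]
  rate <- ifelse(same, within_rate, between_rate)
  n_seg <- rpois(nrow(pairs), rate)
  keep <- which(n_seg > 0)
  if (length(keep) == 0) {
    return(tibble(id1 = character(), id2 = character(), chrom = integer(),
                  start_bp = integer(), end_bp = integer(), cm = numeric()))
  }
  total <- sum(n_seg[keep])
  i1 <- rep(pairs[keep, 1], n_seg[keep])
  i2 <- rep(pairs[keep, 2], n_seg[keep])
  cm <- 1 + rexp(total, 1 / max(mean_cm - 1, 0.5))
  chrom <- sample.int(22, total, replace = TRUE)
  start <- sample.int(2e8, total, replace = TRUE)
  tibble(id1 = ids[i1], id2 = ids[i2], chrom = chrom,
         start_bp = start, end_bp = start + round(cm * 1e6) - 1, cm = cm)
}
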