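VISIT_TYPES <- c("appointment", "office", "hospital", "procedure")

#' Count phecode occurrences per person
#'
#' A phecode occurrence is a *distinct encounter* carrying at least one ICD
#' code mapped to that phecode; several mapped ICD rows on one encounter
#' still count once.  `scope = "visit"` restricts to encounters of
#' appointment/office/hospital/procedure type (the stricter visit-derived
#' definition); `scope = "all"` counts every encounter type.  Unmapped ICD
#' codes are ignored and tallied in the `unmapped` attribute.
#'
#' @param encounters tibble (`person_id`, `encounter_id`, `encounter_type`,
#'   `icd_code`, `icd_version`, ...).
#' @param ontology tibble (`icd_code`, `icd_version`, `phecode`, ...).
#' @param scope `"all"` or `"visit"`.
#' @return Tibble (`person_id`, `phecode`, `count`); absent combinations
#'   have an implicit count of 0.
#' @export
count_occurrences <- function(encounters, ontology, scope = c("all", "visit")) {
  scope <- match.arg(scope)
  mapped <- inner_join(encounters,
                       dplyr::select(ontology, "icd_code", "icd_version",
                                     "phecode"),
                       by = c("icd_code", "icd_version"))
  n_unmapped <- nrow(encounters) - nrow(
    dplyr::semi_join(encounters, ontology, by = c("icd_code", "icd_version")))
  if (scope == "visit") {
    mapped <- filter(mapped, .data$encounter_type %in% VISIT_TYPES)
  }
  out <- mapped %>%
    distinct(.data$person_id, .data$phecode, .data$encounter_id) %>%
    count(.data$person_id, .data$phecode, name = "count")
  attr(out, "unmapped") <- n_unmapped
  attr(out, "scope") <- scope
  out
}

#' Case/control status from occurrence counts
#'
#' Persons with `count >= min_occurrences` are cases; persons with zero
#' occurrences are controls.  With `min_occurrences > 1`, persons whose
#' count falls strictly between 0 and the minimum are, by default, excluded
#' (neither case nor control); `partial = "control"` assigns them to
#' controls instead.
#'
#' @param counts tibble from [count_occurrences()].
#' @param persons character vector of every person in the cohort (needed to
#'   enumerate the zero-count controls).
#' @param min_occurrences occurrences required to be a case.
#' @param partial `"exclude"` (default) or `"control"`.
#' @return Tibble (`person_id`, `phecode`, `count`, `status` in
#'   \{"case", "control", "excluded"\}) covering every person x phecode.
#' @export
define_cases <- function(counts, persons, min_occurrences = 1,
                         partial = c("exclude", "control")) {
  partial <- match.arg(partial)
  phecodes <- sort(unique(counts$phecode))
  full <- tidyr::expand_grid(person_id = persons, phecode = phecodes) %>%
    left_join(counts, by = c("person_id", "phecode")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  full$status <- dplyr::case_when(
    full$count >= min_occurrences ~ "case",
    full$count == 0 ~ "control",
    partial == "control" ~ "control",
    TRUE ~ "excluded"
  )
  full
}

#' Case retention as the occurrence requirement grows
#'
#' For each encounter scope and each minimum-occurrence requirement, the
#' proportion of cases retained relative to the 1-occurrence definition,
#' per phecode.  Phecodes with no 1-occurrence cases under a scope get a
#' missing proportion.
#'
#' @param encounters,ontology as in [count_occurrences()].
#' @param persons cohort person ids.
#' @param min_grid integer vector of minimum occurrence requirements.
#' @param scopes subset of `c("all", "visit")`.
#' @return Tibble (`scope`, `min_occurrences`, `phecode`, `n_cases`,
#'   `proportion_retained`).
#' @export
retention_curve <- function(encounters, ontology, persons,
                            min_grid = 1:5, scopes = c("all", "visit")) {
  purrr::map_dfr(scopes, function(sc) {
    counts <- count_occurrences(encounters, ontology, scope = sc)
    base <- counts %>%
      filter(.data$count >= 1) %>%
      count(.data$phecode, name = "n_base")
    purrr::map_dfr(min_grid, function(m) {
      counts %>%
        filter(.data$count >= m) %>%
        count(.data$phecode, name = "n_cases") %>%
        dplyr::full_join(base, by = "phecode") %>%
        mutate(n_cases = dplyr::coalesce(.data$n_cases, 0L),
               scope = sc, min_occurrences = m,
               proportion_retained = dplyr::if_else(
                 .data$n_base > 0, .data$n_cases / .data$n_base, NA_real_)) %>%
        dplyr::select("scope", "min_occurrences", "phecode", "n_cases",
                      "proportion_retained")
    })
  })
}

#' Phecodes testable within each group
#'
#' Keeps, per group, the phecodes whose case count is strictly greater
#' than `min_cases` in that group.
#'
#' @param statuses tibble from [define_cases()].
#' @param groups tibble (`person_id`, `group`).
#' @param min_cases strict lower bound on the per-group case count.
#' @return Tibble (`group`, `phecode`, `n_cases`) of testable pairs.
#' @export
filter_testable <- function(statuses, groups, min_cases = 50) {
  statuses %>%
    inner_join(groups, by = "person_id") %>%
    filter(.data$status == "case") %>%
    count(.data$group, .data$phecode, name = "n_cases") %>%
    filter(.data$n_cases > min_cases)
}
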