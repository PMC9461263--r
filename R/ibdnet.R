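#' Total genome-wide IBD per pair
#'
#' Sums segment lengths (cM) over all segments of each unordered pair,
#' yielding the weighted edge list of the IBD sharing graph.
#'
#' @param segments tibble with `id1`, `id2`, `cm` (and optionally
#'   chrom/start/end, which are ignored here).
#' @return Tibble (`id1`, `id2`, `total_cm`, `n_segments`) with
#'   `id1 < id2`, one row per pair that shares at least one segment.
#' @export
total_pairwise_ibd <- function(segments) {
  if (any(segments$cm <= 0)) abort("segment lengths must be positive cM")
  if (any(segments$id1 == segments$id2)) abort("self-pair segments are invalid")
  segments %>%
    mutate(a = pmin(.data$id1, .data$id2), b = pmax(.data$id1, .data$id2)) %>%
    group_by(.data$a, .data$b) %>%
    summarise(total_cm = sum(.data$cm), n_segments = dplyr::n(),
              .groups = "drop") %>%
    rename(id1 = "a", id2 = "b")
}

#' Drop edges between close relatives
#'
#' Removes pairs whose kinship coefficient is at or above the supplied
#' cutoff (default 0.0442, the degree-3 boundary, so "third degree or
#' closer" is excluded).  Pairs absent from the kinship table are kept.
#'
#' @param edges edge list from [total_pairwise_ibd()].
#' @param kin kinship table from [estimate_kinship()].
#' @param phi_cutoff kinship at/above which a pair is removed.
#' @return Filtered edge list (always a subset of the input).
#' @export
filter_relatives <- function(edges, kin, phi_cutoff = 0.0442) {
  rel <- kin[!is.na(kin$phi) & kin$phi >= phi_cutoff, ]
  rel_key <- c(paste(rel$id1, rel$id2), paste(rel$id2, rel$id1))
  edges[!(paste(edges$id1, edges$id2) %in% rel_key), ]
}

#' Detect IBD communities
#'
#' Runs flow-based (map-equation / InfoMap) community detection on the
#' weighted undirected sharing graph; the partition is deterministic given
#' the seed.
#'
#' @param edges edge list with `id1`, `id2`, `total_cm` (edge weight).
#' @param seed RNG seed.
#' @return A `community_assignment` tibble (`id`, `community`) with
#'   attributes `codelength` and `sizes`.
#' @export
detect_communities <- function(edges, seed = 1) {
  if (nrow(edges) == 0) abort("empty graph")
  gr <- igraph::graph_from_data_frame(
    data.frame(from = edges$id1, to = edges$id2, weight = edges$total_cm),
    directed = FALSE
  )
  set.seed(seed)
  cl <- igraph::cluster_infomap(gr, e.weights = igraph::E(gr)$weight)
  out <- tibble(id = igraph::V(gr)$name,
                community = as.integer(igraph::membership(cl)))
  attr(out, "codelength") <- igraph::code_len(cl)
  attr(out, "sizes") <- sort(table(out$community), decreasing = TRUE)
  class(out) <- c("community_assignment", class(out))
  out
}

#' Report communities above size and degree cutoffs
#'
#' Builds the reporting view of a community assignment: communities with
#' more than `min_size` members, restricted to nodes with graph degree of
#' at least `min_degree` (computed on the post-filter graph).  The
#' underlying assignment is not modified.  `degree_comparator = ">"`
#' switches to a strictly-greater degree rule.
#'
#' @param assign a [detect_communities()] result.
#' @param edges the edge list the communities were detected on.
#' @param min_size report only communities with size strictly above this.
#' @param min_degree nodes need degree >= this (or > with comparator ">").
#' @param degree_comparator `">="` (default) or `">"`.
#' @return Tibble (`id`, `community`, `degree`) of reported nodes.
#' @export
summarize_communities <- function(assign, edges, min_size = 100,
                                  min_degree = 30,
                                  degree_comparator = c(">=", ">")) {
  degree_comparator <- match.arg(degree_comparator)
  deg_tbl <- tibble(id = c(edges$id1, edges$id2)) %>%
    count(.data$id, name = "degree")
  out <- assign %>%
    left_join(deg_tbl, by = "id") %>%
    mutate(degree = dplyr::coalesce(.data$degree, 0L)) %>%
    group_by(.data$community) %>%
    filter(dplyr::n() > min_size) %>%
    ungroup()
  if (degree_comparator == ">=") {
    out <- filter(out, .data$degree >= min_degree)
  } else {
    out <- filter(out, .data$degree > min_degree)
  }
  as_tibble(out)
}
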