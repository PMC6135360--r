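#' Similarity thresholds for relationship calling
#'
#' Defaults reflect calibration against documented clone sets of dominant
#' marker data: similarity at or above `clone` (0.90) generally signifies
#' clonality or duplication; `[borderline, clone)` (0.88--0.90) deserves
#' manual review because some true clone sets (notably triploid ones) score
#' in this band; `[close, borderline)` marks relationships closer than a
#' standard parent-offspring or full-sibling pair.
#'
#' @param clone,close,borderline Numeric thresholds with
#'   `0 < close <= borderline <= clone <= 1`.
#' @return A named list of class `similarity_thresholds`.
#' @export
similarity_thresholds <- function(clone = 0.90, close = 0.80, borderline = 0.88) {
  if (!(close > 0 && close <= borderline && borderline <= clone && clone <= 1)) {
    abort("Need 0 < close <= borderline <= clone <= 1.")
  }
  structure(list(clone = clone, close = close, borderline = borderline),
            class = "similarity_thresholds")
}

#' Classify accession pairs by similarity band
#'
#' The clone band is closed at the bottom (`[clone, 1]`), the borderline
#' band is `[borderline, clone)` and the close-relation band is
#' `[close, borderline)`; everything below is `standard`.  A score on the
#' clone boundary is therefore called `clone_or_duplicate` and must be
#' resolved by SSR/ploidy evidence downstream, not silently demoted.
#'
#' @param pairs A `similarity_pairs` tibble from [pairwise_jaccard()].
#' @param thresholds A [similarity_thresholds()] object.
#' @return `pairs` with an added ordered factor column `category` in
#'   `{clone_or_duplicate, borderline_clone, close_relation, standard}`.
#' @export
classify_pairs <- function(pairs, thresholds = similarity_thresholds()) {
  s <- pairs$jaccard
  category <- dplyr::case_when(
    is.na(s) ~ NA_character_,
    s >= thresholds$clone ~ "clone_or_duplicate",
    s >= thresholds$borderline ~ "borderline_clone",
    s >= thresholds$close ~ "close_relation",
    TRUE ~ "standard"
  )
  out <- mutate(pairs, category = factor(category, levels = c(
    "standard", "close_relation", "borderline_clone", "clone_or_duplicate"
  ), ordered = TRUE))
  class(out) <- class(pairs)
  attr(out, "accession_ids") <- attr(pairs, "accession_ids")
  out
}

#' Collapse clonal and duplicate accessions to representative genotypes
#'
#' Builds single-linkage components over pairs scoring at or above the
#' clone threshold and keeps one representative per component.  Pairs that
#' are indistinguishable by dominant markers but clearly distinct by
#' independent evidence are *not* merged: an edge is severed (and recorded
#' as a conflict with a `collecting_error_suspect` flag) when the two
#' accessions differ at `min_ssr_conflicts` or more co-scored SSR loci, or
#' when their known ploidies differ.
#'
#' @param pairs A `similarity_pairs` tibble over the full collection.
#' @param meta Optional [accession_meta()] (supplies ploidy).
#' @param ssr Optional [ssr_profiles()] for conflict detection.
#' @param thresholds A [similarity_thresholds()].
#' @param keep Optional character vector of preferred representatives; for
#'   components containing one, it overrides the default choice
#'   (lexicographically lowest accession id).
#' @param min_ssr_conflicts Number of differing SSR loci that severs a
#'   clone edge (default 2).
#' @return A list of class `clone_collapse`:
#'   * `components`: tibble (`accession_id`, `component`, `representative`,
#'     `is_representative`),
#'   * `representatives`: character vector,
#'   * `conflicts`: tibble of severed edges (`acc_i`, `acc_j`, `jaccard`,
#'     `reason`, `flag`).
#' @export
collapse_clones <- function(pairs, meta = NULL, ssr = NULL,
                            thresholds = similarity_thresholds(),
                            keep = NULL, min_ssr_conflicts = 2L) {
  ids <- attr(pairs, "accession_ids") %||% sort(unique(c(pairs$acc_i, pairs$acc_j)))
  cand <- filter(pairs, !is.na(.data$jaccard), .data$jaccard >= thresholds$clone)

  conflicts <- tibble(acc_i = character(), acc_j = character(),
                      jaccard = double(), reason = character(), flag = character())
  if (nrow(cand) > 0L) {
    reason <- rep(NA_character_, nrow(cand))
    if (!is.null(meta)) {
      pl <- setNames(meta$ploidy, meta$accession_id)
      pi <- pl[cand$acc_i]
      pj <- pl[cand$acc_j]
      reason[!is.na(pi) & !is.na(pj) & pi != pj] <- "ploidy_mismatch"
    }
    if (!is.null(ssr)) {
      need <- which(is.na(reason))
      ndiff <- map_int(need, function(k) {
        ssr_allele_differences(ssr, cand$acc_i[k], cand$acc_j[k])
      })
      reason[need[ndiff >= min_ssr_conflicts]] <- "ssr_conflict"
    }
    conflicts <- cand[!is.na(reason), c("acc_i", "acc_j", "jaccard")]
    conflicts$reason <- reason[!is.na(reason)]
    conflicts$flag <- "collecting_error_suspect"
    cand <- cand[is.na(reason), , drop = FALSE]
  }

  comp <- single_linkage_components(ids, cand)
  components <- tibble(accession_id = ids, component = comp) %>%
    group_by(.data$component) %>%
    mutate(representative = {
      hit <- intersect(keep %||% character(), .data$accession_id)
      if (length(hit)) hit[1L] else min(.data$accession_id)
    }) %>%
    ungroup() %>%
    mutate(is_representative = .data$accession_id == .data$representative)

  structure(list(components = components,
                 representatives = components$representative[components$is_representative],
                 conflicts = conflicts),
            class = "clone_collapse")
}

# deterministic single-linkage components over an edge list
single_linkage_components <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("acc_i", "acc_j")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  m <- igraph::components(g)$membership[ids]
  # relabel so component numbering follows the lowest member id
  first <- vapply(split(ids, m), min, character(1))
  match(first[as.character(m)], sort(unique(first)))
}

#' @method tidy clone_collapse
#' @export
tidy.clone_collapse <- function(x, ...) x$components

#' Find groups of accessions more closely related than first degree
#'
#' On the clone-collapsed collection, builds single-linkage components over
#' pairs scoring in `[close, clone)`.  A component is reported with its
#' edge list, ploidy profile and a class: `diploid_sibling_group` when all
#' known ploidies are diploid, `heteroploid_group` when at least one member
#' is polyploid, `mixed_unknown` otherwise.  Single linkage is used because
#' such groups are typically held together by a shared (gamete-donating)
#' member even when peripheral pairs score below the threshold.
#'
#' @param pairs A `similarity_pairs` tibble restricted to clone
#'   representatives (see [collapse_clones()] and [filter_similarity()]).
#' @param meta Optional [accession_meta()] supplying ploidy.
#' @param thresholds A [similarity_thresholds()].
#' @return Tibble with one row per group: `group_id`, `members` (list),
#'   `n_members`, `edges` (list of tibbles), `ploidy_profile` (list of
#'   named counts, unknown ploidy under `"unknown"`), `group_class`.
#' @export
find_close_groups <- function(pairs, meta = NULL,
                              thresholds = similarity_thresholds()) {
  edges <- filter(pairs, !is.na(.data$jaccard),
                  .data$jaccard >= thresholds$close,
                  .data$jaccard < thresholds$clone)
  if (nrow(edges) == 0L) {
    return(tibble(group_id = integer(), members = list(), n_members = integer(),
                  edges = list(), ploidy_profile = list(), group_class = character()))
  }
  ids <- sort(unique(c(edges$acc_i, edges$acc_j)))
  comp <- single_linkage_components(ids, edges)
  pl <- if (!is.null(meta)) setNames(meta$ploidy, meta$accession_id) else
    setNames(rep(NA_integer_, length(ids)), ids)
  purrr::map_dfr(sort(unique(comp)), function(k) {
    members <- ids[comp == k]
    e <- filter(edges, .data$acc_i %in% members, .data$acc_j %in% members)
    p <- pl[members]
    prof <- table(ifelse(is.na(p), "unknown", as.character(p)))
    cls <- if (any(!is.na(p) & p > 2L)) "heteroploid_group"
      else if (all(!is.na(p)) && all(p == 2L)) "diploid_sibling_group"
      else "mixed_unknown"
    n_mem <- length(members)
    tibble(group_id = k, members = list(members), n_members = n_mem,
           edges = list(e), ploidy_profile = list(prof), group_class = cls)
  })
}

#' Similarity summaries for documented relationship tiers
#'
#' Derives pair sets from documented parentage and reports per-tier sample
#' size, mean, SD, minimum and maximum similarity:
#' * `population`: all scored pairs;
#' * `siblings`: pairs sharing at least one documented parent (half- or
#'   full-siblings);
#' * `parent_offspring`: pairs where one member is a documented parent of
#'   the other;
#' * `full_siblings`: pairs sharing both documented parents.
#'
#' @param pairs A `similarity_pairs` tibble (normally clone-collapsed).
#' @param meta An [accession_meta()] with `parent1`/`parent2` naming other
#'   accessions (by id or cultivar name).
#' @return Tibble with columns `tier`, `n`, `mean`, `sd`, `min`, `max`
#'   (empty tiers reported with `n = 0`).
#' @export
tier_summaries <- function(pairs, meta) {
  key <- setNames(meta$accession_id, meta$accession_id)
  if ("cultivar_name" %in% names(meta)) {
    cn <- meta$cultivar_name
    ok <- !is.na(cn) & !duplicated(cn)
    key <- c(key, setNames(meta$accession_id[ok], cn[ok]))
  }
  par <- function(p) unname(key[p])
  p1 <- par(meta$parent1)
  p2 <- par(meta$parent2)
  parents <- setNames(map2(p1, p2, function(a, b) sort(c(a, b))), meta$accession_id)

  pi <- parents[pairs$acc_i]
  pj <- parents[pairs$acc_j]
  shared <- map2_int_safe(pi, pj, function(a, b) length(intersect(a, b)))
  is_po <- map_lgl(seq_len(nrow(pairs)), function(k) {
    pairs$acc_j[k] %in% (pi[[k]] %||% character()) ||
      pairs$acc_i[k] %in% (pj[[k]] %||% character())
  })
  is_fs <- !is_po & shared >= 2L
  is_sib <- !is_po & shared >= 1L

  tier_tbl <- list(
    population = rep(TRUE, nrow(pairs)),
    siblings = is_sib,
    parent_offspring = is_po,
    full_siblings = is_fs
  )
  purrr::imap_dfr(tier_tbl, function(sel, nm) {
    v <- pairs$jaccard[sel & !is.na(pairs$jaccard)]
    tibble(tier = nm, n = length(v),
           mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1L) sd(v) else NA_real_,
           min = if (length(v)) min(v) else NA_real_,
           max = if (length(v)) max(v) else NA_real_)
  })
}

map2_int_safe <- function(a, b, f) {
  vapply(seq_along(a), function(k) {
    if (is.null(a[[k]]) || is.null(b[[k]])) 0L else as.integer(f(a[[k]], b[[k]]))
  }, integer(1))
}
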