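#' Run the full collection analysis
#'
#' Orchestrates the end-to-end chain: marker screening, pairwise Jaccard
#' similarity, clone/duplicate collapse (with SSR- and ploidy-based
#' conflict retention), close-relation grouping, ploidy partition, SSR
#' parentage verification and relationship-tier summaries.
#'
#' Within each heteroploid close group, only lower-ploidy to higher-ploidy
#' parentage is tested (diploid members as unreduced-gamete donors for
#' triploid members, triploid members as triploid-gamete donors for
#' tetraploids); equal-ploidy polyploid members are left to sibling-level
#' interpretation.  For diploid sibling groups, members with exactly one
#' documented parent trigger an exclusion search for the missing parent
#' over the whole genotyped panel; a pedigree is only auto-asserted when
#' exactly one candidate survives.
#'
#' @param markers A [marker_matrix()] or path readable by
#'   [read_marker_matrix()].
#' @param meta An [accession_meta()] (or path); optional but required for
#'   ploidy partition and tier summaries.
#' @param ssr An [ssr_profiles()] (or path); optional -- without it the
#'   pipeline completes through the close-group stage with a warning.
#' @param thresholds A [similarity_thresholds()].
#' @param batches Optional accession batch assignment for
#'   [screen_markers()]; `NULL` screens as a single batch.
#' @param screen Whether to run marker screening (default `TRUE`).
#' @param redundancy,keep Passed to [screen_markers()].
#' @param ssr_tolerance Tolerance for the heteroploid complement checks
#'   (default 1 missing allele per pair).
#' @param keep_representatives Optional keep-list for [collapse_clones()].
#' @return A `dartkin_pipeline` list: `screening`, `pairs`, `calls`,
#'   `clone_stats`, `collapse`, `close_groups`, `heteroploid_assessments`,
#'   `exclusion_searches`, `tier_summary`, `manifest`.
#' @export
run_pipeline <- function(markers, meta = NULL, ssr = NULL,
                         thresholds = similarity_thresholds(),
                         batches = NULL, screen = TRUE,
                         redundancy = "identical_scores", keep = NULL,
                         ssr_tolerance = 1L, keep_representatives = NULL) {
  if (is.character(markers)) markers <- read_marker_matrix(markers)
  if (is.character(meta)) meta <- read_accession_meta(meta)
  if (is.character(ssr)) ssr <- read_ssr_table(ssr)
  if (!is.null(ssr) && nrow(ssr) == 0L) ssr <- NULL
  if (is.null(ssr)) warn("No SSR data: parentage verification stages skipped.")

  if (screen) {
    markers <- screen_markers(markers, batches = batches,
                              redundancy = redundancy, keep = keep)
  }
  screening <- screening_report(markers)

  pairs <- pairwise_jaccard(markers)
  calls <- classify_pairs(pairs, thresholds)

  clone_stats <- NULL
  if (!is.null(meta) && any(!is.na(meta$clone_group))) {
    grp <- filter(meta, !is.na(.data$clone_group))
    clone_stats <- group_stats(pairs, tibble(accession_id = grp$accession_id,
                                             group = grp$clone_group)) %>%
      rename(cultivar = "group", n_clones = "n_members",
             max = "max_within", min = "min_within",
             max_non_clone = "max_vs_nonmember") %>%
      select("cultivar", "n_clones", "max", "min", "max_non_clone")
  }

  collapse <- collapse_clones(pairs, meta = meta, ssr = ssr,
                              thresholds = thresholds,
                              keep = keep_representatives)
  reduced <- filter_similarity(pairs, collapse$representatives)
  groups <- find_close_groups(reduced, meta = meta, thresholds = thresholds)

  het <- tibble()
  excl <- tibble()
  if (!is.null(ssr) && nrow(groups) > 0L) {
    pl <- if (!is.null(meta)) setNames(meta$ploidy, meta$accession_id) else NULL
    has_ssr <- unique(ssr$accession_id)
    for (gi in seq_len(nrow(groups))) {
      members <- groups$members[[gi]]
      mp <- if (!is.null(pl)) pl[members] else rep(NA_integer_, length(members))
      if (groups$group_class[gi] == "heteroploid_group") {
        combos <- expand.grid(parent = members, offspring = members,
                              stringsAsFactors = FALSE)
        combos <- combos[combos$parent != combos$offspring, ]
        for (k in seq_len(nrow(combos))) {
          pp <- mp[combos$parent[k]]
          po <- mp[combos$offspring[k]]
          if (is.na(pp) || is.na(po)) next
          if (!(combos$parent[k] %in% has_ssr && combos$offspring[k] %in% has_ssr)) next
          model <- if (pp == 2L && po == 3L) "unreduced_diploid"
            else if (pp == 3L && po == 4L) "triploid"
            else next
          a <- tryCatch(
            assess_parentage(ssr, combos$parent[k], combos$offspring[k],
                             model = model, tolerance = ssr_tolerance),
            error = function(e) NULL)
          if (is.null(a)) next
          g <- glance(a)
          g$group_id <- groups$group_id[gi]
          if (!is.null(meta)) {
            g$timeline <- timeline_check(meta, combos$parent[k],
                                         combos$offspring[k])$status
          }
          het <- bind_rows(het, g)
        }
      } else if (!is.null(meta)) {
        for (m in members) {
          row <- meta[meta$accession_id == m, ]
          if (nrow(row) != 1L) next
          known <- stats::na.omit(c(row$parent1, row$parent2))
          known <- known[known %in% has_ssr]
          if (length(known) != 1L || !(m %in% has_ssr)) next
          panel <- setdiff(has_ssr, c(m, known))
          cand <- tryCatch(
            infer_missing_parent(ssr, m, known, panel, model = "haploid"),
            error = function(e) NULL)
          if (is.null(cand)) next
          surv <- cand$candidate_id[cand$survives]
          excl <- bind_rows(excl, tibble(
            group_id = groups$group_id[gi], offspring_id = m,
            known_parent_id = known, n_candidates = nrow(cand),
            n_survivors = length(surv),
            unique_survivor = attr(cand, "unique_survivor"),
            survivors = list(surv)))
        }
      }
    }
  }

  tiers <- if (!is.null(meta)) tier_summaries(reduced, meta) else NULL

  manifest <- tibble(
    parameter = c("package_version", "n_accessions", "n_markers_screened",
                  "clone_threshold", "close_threshold", "borderline_threshold",
                  "redundancy_mode", "ssr_tolerance", "ssr_supplied"),
    value = as.character(c(as.character(utils::packageVersion("dartkin")),
                           length(attr(pairs, "accession_ids")),
                           length(marker_ids(markers)),
                           thresholds$clone, thresholds$close,
                           thresholds$borderline, redundancy, ssr_tolerance,
                           !is.null(ssr))))

  structure(list(screening = screening, pairs = pairs, calls = calls,
                 clone_stats = clone_stats, collapse = collapse,
                 close_groups = groups, heteroploid_assessments = het,
                 exclusion_searches = excl, tier_summary = tiers,
                 manifest = manifest),
            class = "dartkin_pipeline")
}

#' @export
print.dartkin_pipeline <- function(x, ...) {
  n_acc <- length(attr(x$pairs, "accession_ids"))
  cat("<dartkin_pipeline>\n")
  cat(sprintf("  %d accessions, %d clone representatives, %d close group(s)\n",
              n_acc, length(x$collapse$representatives), nrow(x$close_groups)))
  if (nrow(x$heteroploid_assessments %||% tibble())) {
    ok <- sum(x$heteroploid_assessments$overall != "excluded")
    cat(sprintf("  heteroploid parentage tests: %d (%d plausible)\n",
                nrow(x$heteroploid_assessments), ok))
  }
  invisible(x)
}

#' Write the report bundle shaped like the collection-analysis tables
#'
#' One CSV per table: clone statistics (cultivar, number of clones,
#' max/min within-clone similarity and the maximum similarity against any
#' non-clone), pair calls, close groups with membership and ploidy
#' partition, heteroploid assessments with per-locus category counts,
#' exclusion-search outcomes, tier summaries, screening report and run
#' manifest.  Similarity is printed to three decimals.
#'
#' @param results A `dartkin_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
report_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, name), na = "")
  }
  r3 <- function(x) round(x, 3)
  w(results$screening, "screening.csv")
  w(mutate(as_tibble(results$pairs), jaccard = r3(.data$jaccard)), "similarity_long.csv")
  w(mutate(as_tibble(results$calls), jaccard = r3(.data$jaccard),
           category = as.character(.data$category)), "pair_calls.csv")
  if (!is.null(results$clone_stats)) {
    w(mutate(results$clone_stats, across(c("max", "min", "max_non_clone"), r3)),
      "clone_stats.csv")
  }
  w(results$collapse$components, "clone_components.csv")
  w(results$collapse$conflicts, "clone_conflicts.csv")
  groups_flat <- if (nrow(results$close_groups)) {
    mutate(results$close_groups,
           members = map_chr(.data$members, paste, collapse = ";"),
           ploidy_profile = map_chr(.data$ploidy_profile, function(p) {
             paste(sprintf("%s:%d", names(p), as.integer(p)), collapse = ";")
           })) %>% select(-"edges")
  } else {
    tibble(group_id = integer(), members = character(), n_members = integer(),
           ploidy_profile = character(), group_class = character())
  }
  w(groups_flat, "close_groups.csv")
  w(as_tibble(results$heteroploid_assessments), "heteroploid_assessments.csv")
  excl <- as_tibble(results$exclusion_searches)
  if ("survivors" %in% names(excl)) {
    excl <- mutate(excl, survivors = map_chr(.data$survivors, paste, collapse = ";"))
  }
  w(excl, "exclusion_searches.csv")
  if (!is.null(results$tier_summary)) {
    w(mutate(results$tier_summary, across(c("mean", "sd", "min", "max"), r3)),
      "tier_summary.csv")
  }
  w(results$manifest, "manifest.csv")
  invisible(dir)
}
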