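make_pairs <- function(df) {
  ids <- sort(unique(c(df$acc_i, df$acc_j)))
  if (!"n_shared" %in% names(df)) df$n_shared <- 500L
  class(df) <- c("similarity_pairs", class(tibble::tibble()))
  attr(df, "accession_ids") <- ids
  df
}

test_that("pair categories follow the closed/half-open band semantics", {
  p <- make_pairs(tibble::tibble(
    acc_i = "X", acc_j = c("A", "B", "C", "D", "E", "F"),
    jaccard = c(0.902, 0.90, 0.885, 0.85, 0.80, 0.79)))
  cl <- classify_pairs(p)
  expect_identical(as.character(cl$category),
                   c("clone_or_duplicate", "clone_or_duplicate",
                     "borderline_clone", "close_relation", "close_relation",
                     "standard"))
})

test_that("clone collapse partitions the collection deterministically", {
  withr::with_seed(41, {
    cfg <- sim_config(seed = 41, n_founders = 10, n_clone_groups = 1,
                      clones_per_group = 4, n_families = 1,
                      n_half_sib_families = 0, n_triploid_families = 0,
                      n_tetraploids = 0)
    b <- simulate_collection(cfg)
    p <- pairwise_jaccard(b$markers)
    cc <- collapse_clones(p, meta = b$meta, ssr = b$ssr)
    comp <- tidy(cc)

    # planted 5-member clone set (source + 4 clones) -> one component
    fam <- comp[grepl("^F001", comp$accession_id), ]
    expect_identical(length(unique(fam$component)), 1L)
    expect_identical(unique(fam$representative), "F001")

    # partition: every accession appears exactly once
    expect_identical(sort(comp$accession_id),
                     sort(attr(p, "accession_ids")))

    # row order of the similarity table does not change the partition
    shuf <- p[sample(nrow(p)), ]
    attr(shuf, "accession_ids") <- attr(p, "accession_ids")
    class(shuf) <- class(p)
    cc2 <- collapse_clones(shuf, meta = b$meta, ssr = b$ssr)
    expect_identical(dplyr::arrange(tidy(cc2), accession_id),
                     dplyr::arrange(comp, accession_id))
  })
})

test_that("marker-identical pairs with conflicting SSR are retained separately", {
  p <- make_pairs(tibble::tibble(acc_i = "A", acc_j = "B", jaccard = 0.99))
  ssr <- toy_ssr(list(
    list("A", "L1", c(100L, 104L)), list("B", "L1", c(102L, 106L)),
    list("A", "L2", c(200L, 204L)), list("B", "L2", c(202L, 206L)),
    list("A", "L3", c(300L, 304L)), list("B", "L3", c(300L, 304L))))
  cc <- collapse_clones(p, ssr = ssr)
  expect_identical(sort(cc$representatives), c("A", "B"))
  expect_identical(cc$conflicts$reason, "ssr_conflict")
  expect_identical(cc$conflicts$flag, "collecting_error_suspect")

  # below the conflict threshold (1 differing locus) the pair merges
  ssr1 <- toy_ssr(list(
    list("A", "L1", c(100L, 104L)), list("B", "L1", c(102L, 106L)),
    list("A", "L2", c(200L, 204L)), list("B", "L2", c(200L, 204L))))
  cc1 <- collapse_clones(p, ssr = ssr1)
  expect_identical(cc1$representatives, "A")
})

test_that("known ploidy differences block clone merging", {
  p <- make_pairs(tibble::tibble(acc_i = "P2", acc_j = "P3", jaccard = 0.905))
  meta <- accession_meta(tibble::tibble(accession_id = c("P2", "P3"),
                                        ploidy = c(2L, 3L)))
  cc <- collapse_clones(p, meta = meta)
  expect_identical(sort(cc$representatives), c("P2", "P3"))
  expect_identical(cc$conflicts$reason, "ploidy_mismatch")
})

test_that("no clone-band edges means every accession represents itself", {
  p <- make_pairs(tibble::tibble(acc_i = c("A", "A"), acc_j = c("B", "C"),
                                 jaccard = c(0.5, 0.6)))
  cc <- collapse_clones(p)
  expect_identical(sort(cc$representatives), c("A", "B", "C"))
})

test_that("close groups form by single linkage within the [close, clone) band", {
  p <- make_pairs(tibble::tibble(
    acc_i = c("P", "P", "O1", "A"),
    acc_j = c("O1", "O2", "O2", "B"),
    jaccard = c(0.85, 0.83, 0.76, 0.95)))
  g <- find_close_groups(p)
  expect_identical(nrow(g), 1L)                # A-B edge is clone band, excluded
  expect_setequal(g$members[[1]], c("P", "O1", "O2"))
  expect_true(all(purrr::map_dbl(g$edges, ~ max(.x$jaccard)) < 0.90))

  meta <- accession_meta(tibble::tibble(accession_id = c("P", "O1", "O2"),
                                        ploidy = c(2L, 3L, 3L)))
  g2 <- find_close_groups(p, meta = meta)
  expect_identical(g2$group_class, "heteroploid_group")

  # independent accessions: no edges, no groups
  lonely <- make_pairs(tibble::tibble(acc_i = "A", acc_j = "B", jaccard = 0.5))
  expect_identical(nrow(find_close_groups(lonely)), 0L)
})

test_that("planted unrelated accessions never collapse and planted clones always do", {
  # error-free limit: flips and missingness off
  results <- purrr::map_lgl(1:10, function(s) {
    cfg <- sim_config(seed = 300 + s, n_founders = 8, clone_flip_rate = 0,
                      missing_rate = 0, n_clone_groups = 2, clones_per_group = 2,
                      n_families = 0, n_half_sib_families = 0,
                      n_triploid_families = 0, n_tetraploids = 0)
    b <- simulate_collection(cfg)
    cc <- collapse_clones(pairwise_jaccard(b$markers), meta = b$meta, ssr = b$ssr)
    comp <- tidy(cc)
    founders_separate <- dplyr::n_distinct(
      comp$component[comp$accession_id %in% sprintf("F%03d", 1:8)]) == 8
    clones_joined <- all(vapply(1:2, function(g) {
      src <- sprintf("F%03d", g)
      members <- comp$component[grepl(paste0("^", src), comp$accession_id)]
      length(unique(members)) == 1L
    }, logical(1)))
    founders_separate && clones_joined
  })
  expect_true(all(results))
})

test_that("relationship tiers order as expected and full-sib mean matches the oracle", {
  withr::with_seed(55, {
    cfg <- sim_config(seed = 55, n_founders = 30, n_families = 10,
                      n_full_sibs = 4, n_half_sib_families = 3,
                      n_clone_groups = 0, n_triploid_families = 0,
                      n_tetraploids = 0, missing_rate = 0)
    b <- simulate_collection(cfg)
    p <- pairwise_jaccard(b$markers)
    tiers <- tier_summaries(p, b$meta)
    m <- setNames(tiers$mean, tiers$tier)
    expect_lt(m["population"], m["siblings"])
    expect_lt(m["siblings"], m["parent_offspring"])
    expect_lt(m["parent_offspring"], m["full_siblings"])

    # analytic genotype-sharing oracle for the full-sib tier mean
    oracle <- expected_fullsib_jaccard(b$truth$dart_p)
    expect_lt(abs(m[["full_siblings"]] - oracle), 0.03)
  })
})

test_that("tier summaries degrade to the population tier without documented parents", {
  withr::with_seed(8, {
    mm <- random_marker_fixture(6, 30)
    p <- pairwise_jaccard(mm)
    meta <- accession_meta(tibble::tibble(accession_id = mm$accession_id))
    tiers <- tier_summaries(p, meta)
    expect_identical(tiers$n[tiers$tier != "population"], rep(0L, 3))
    expect_gt(tiers$n[tiers$tier == "population"], 0L)
  })
})
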