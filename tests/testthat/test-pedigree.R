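pair_ssr <- function(parent, offspring, loci = NULL) {
  if (is.null(loci)) loci <- sprintf("L%02d", seq_along(parent))
  toy_ssr(c(
    purrr::imap(parent, function(a, i) list("P", loci[[i]], a)),
    purrr::imap(offspring, function(a, i) list("O", loci[[i]], a))
  ))
}

test_that("diploid parent-offspring compatibility follows the sharing rule", {
  ssr <- pair_ssr(list(c(118L, 120L)), list(c(120L, 124L)))
  a <- po_compatible(ssr, "P", "O")
  expect_identical(a$overall, "plausible")
  expect_identical(tidy(a)$residual[[1]], 124L)

  ssr2 <- pair_ssr(list(c(118L, 120L)), list(c(122L, 124L)))
  expect_identical(po_compatible(ssr2, "P", "O")$overall, "excluded")

  # no commonly scored locus -> indeterminate error
  ssr3 <- toy_ssr(list(list("P", "L1", c(100L, 102L)),
                       list("O", "L2", c(100L, 102L))))
  expect_error(po_compatible(ssr3, "P", "O"), "indeterminate")
})

test_that("the diploid complement rule scores triploid offspring loci", {
  # heterozygous parent contained -> consistent with residual
  ssr <- pair_ssr(list(c(118L, 120L)), list(c(118L, 120L, 126L)))
  a <- diploid_complement_in_triploid(ssr, "P", "O")
  expect_identical(a$overall, "plausible")
  expect_identical(tidy(a)$status, "consistent")
  expect_identical(tidy(a)$residual[[1]], 126L)

  # single reported parent size, offspring shows fewer than 3 distinct sizes
  ssr2 <- pair_ssr(list(118L), list(c(118L, 126L)))
  expect_identical(tidy(diploid_complement_in_triploid(ssr2, "P", "O"))$status,
                   "consistent_homozygous_ambiguous")

  # parent with 3 alleles violates the ploidy contract
  ssr3 <- pair_ssr(list(c(118L, 120L, 122L)), list(c(118L, 120L, 126L)))
  expect_error(diploid_complement_in_triploid(ssr3, "P", "O"), "at most 2")
})

test_that("one missing parent allele across 12 loci is tolerated exactly once", {
  par <- lapply(1:12, function(l) c(100L + 20L * l, 102L + 20L * l))
  off <- lapply(par, function(a) c(a, a[2] + 6L))
  off[[7]] <- setdiff(off[[7]], par[[7]][1])      # one parental allele lost
  a <- diploid_complement_in_triploid(pair_ssr(par, off), "P", "O", tolerance = 1)
  expect_identical(a$overall, "plausible_with_tolerance")
  expect_identical(a$n_tolerated, 1L)

  strict <- diploid_complement_in_triploid(pair_ssr(par, off), "P", "O",
                                           tolerance = 0)
  expect_identical(strict$overall, "excluded")

  # two lost alleles exceed the default budget
  off[[9]] <- setdiff(off[[9]], par[[9]][1])
  a2 <- diploid_complement_in_triploid(pair_ssr(par, off), "P", "O", tolerance = 1)
  expect_identical(a2$overall, "excluded")
})

test_that("adding offspring alleles never turns a consistent locus inconsistent", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      par <- list(sort(sample(seq(100L, 120L, 2L), 2L)))
      off <- list(sort(c(par[[1]], sample(seq(140L, 160L, 2L), 1L))))
      a <- diploid_complement_in_triploid(pair_ssr(par, off), "P", "O")
      off_more <- list(sort(c(off[[1]], 198L)))
      b <- diploid_complement_in_triploid(pair_ssr(par, off_more), "P", "O")
      ranks <- c(inconsistent = 0, tolerated_missing = 1,
                 consistent_homozygous_ambiguous = 2, consistent = 3)
      expect_gte(ranks[tidy(b)$status], ranks[tidy(a)$status])
    }
  })
})

test_that("a true simulated parent is never excluded in the error-free limit", {
  for (s in 1:5) {
    cfg <- sim_config(seed = 400 + s, n_founders = 12, missing_rate = 0,
                      unreduced_homozygosity_loss = 0, n_clone_groups = 0,
                      n_families = 2, n_half_sib_families = 0,
                      n_triploid_families = 1, n_triploid_offspring = 3,
                      n_tetraploids = 1)
    b <- simulate_collection(cfg)
    pm <- b$truth$parent_map
    for (k in seq_len(nrow(pm))) {
      model <- switch(pm$gamete_maternal[k], haploid = "haploid",
                      unreduced_diploid = "unreduced_diploid",
                      triploid = "triploid")
      a <- assess_parentage(b$ssr, pm$mother[k], pm$offspring[k],
                            model = model, tolerance = 0)
      expect_identical(a$overall, "plausible")
      if (pm$gamete_paternal[k] == "haploid" && model == "haploid") {
        expect_identical(po_compatible(b$ssr, pm$father[k], pm$offspring[k])$overall,
                         "plausible")
      }
    }
  }
})

test_that("exclusion search forces a unique survivor on a crafted panel", {
  ssr <- toy_ssr(list(
    list("M",  "L1", c(100L, 102L)), list("M",  "L2", c(200L, 202L)),
    list("O",  "L1", c(100L, 110L)), list("O",  "L2", c(200L, 204L)),
    list("C1", "L1", c(110L, 112L)), list("C1", "L2", c(204L, 206L)),
    list("C2", "L1", c(104L, 112L)), list("C2", "L2", c(204L, 206L))))
  res <- infer_missing_parent(ssr, "O", "M", c("C1", "C2"))
  expect_identical(attr(res, "unique_survivor"), "C1")
  expect_false(res$survives[res$candidate_id == "C2"])

  # removing the only plausible father leaves no candidate
  res2 <- infer_missing_parent(ssr, "O", "M", "C2")
  expect_identical(sum(res2$survives), 0L)
  expect_true(is.na(attr(res2, "unique_survivor")))

  # an excluded known parent is refused outright
  ssr_bad <- toy_ssr(list(
    list("M", "L1", c(100L, 102L)), list("O", "L1", c(110L, 112L)),
    list("C1", "L1", c(110L, 112L))))
  expect_error(infer_missing_parent(ssr_bad, "O", "M", "C1"), "excluded")
})

test_that("the exclusion survivor set only shrinks as loci are added", {
  withr::with_seed(88, {
    cfg <- sim_config(seed = 88, n_founders = 60, missing_rate = 0,
                      n_clone_groups = 0, n_families = 1, n_full_sibs = 1,
                      n_half_sib_families = 0, n_triploid_families = 0,
                      n_tetraploids = 0)
    b <- simulate_collection(cfg)
    trio <- b$truth$parent_map[1, ]
    panel <- sprintf("F%03d", 1:60)
    loci <- sort(unique(b$ssr$locus))
    prev <- NULL
    for (k in c(2, 4, 8, 12)) {
      sub <- b$ssr[b$ssr$locus %in% loci[seq_len(k)], ]
      attr(sub, "accession_ids") <- NULL
      res <- infer_missing_parent(sub, trio$offspring, trio$mother, panel)
      surv <- res$candidate_id[res$survives]
      expect_true(trio$father %in% surv)   # completeness: true father survives
      if (!is.null(prev)) expect_true(all(surv %in% prev))
      prev <- surv
    }
  })
})

test_that("triploid-complement categories count crafted tetraploid loci", {
  # single crafted locus per category
  ssr_full <- pair_ssr(list(c(100L, 102L, 104L)), list(c(100L, 102L, 104L, 110L)))
  g <- glance(triploid_complement_in_tetraploid(ssr_full, "P", "O"))
  expect_identical(g$n_full_complement, 1L)

  ssr_ind <- pair_ssr(list(c(100L, 102L)), list(c(100L, 102L, 110L, 112L)))
  g2 <- glance(triploid_complement_in_tetraploid(ssr_ind, "P", "O"))
  expect_identical(g2$n_indistinguishable, 1L)

  # 12-locus profile with 5 full / 4 indistinguishable / 3 partial
  par <- c(lapply(1:5, function(l) 100L + 30L * l + c(0L, 2L, 4L)),
           lapply(6:9, function(l) 100L + 30L * l + c(0L, 2L)),
           lapply(10:12, function(l) 100L + 30L * l + c(0L, 2L, 4L)))
  off <- c(lapply(par[1:5], function(a) c(a, max(a) + 10L)),
           lapply(par[6:9], function(a) c(a, max(a) + 10L)),
           lapply(par[10:12], function(a) c(a[1:2], max(a) + 10L)))
  a <- triploid_complement_in_tetraploid(pair_ssr(par, off), "P", "O",
                                         tolerance = 3)
  g3 <- glance(a)
  expect_identical(c(g3$n_full_complement, g3$n_indistinguishable,
                     g3$n_partial, g3$n_category_inconsistent),
                   c(5L, 4L, 3L, 0L))
})

test_that("full-sibling plausibility counts the alleles a single father could supply", {
  base <- list(
    list("P", "L1", c(100L, 102L)),
    list("A", "L1", c(100L, 124L)),
    list("B", "L1", c(102L, 124L)))
  v <- full_sib_plausible(toy_ssr(base), "A", "B", "P")
  expect_true(v$plausible)   # both residuals are {124}

  tri <- list(
    list("P", "L1", c(100L, 102L)),
    list("A", "L1", c(100L, 124L)),
    list("B", "L1", c(100L, 102L, 126L)),
    list("B", "L2", c(200L, 202L, 204L)),
    list("A", "L2", c(200L, 208L)),
    list("P", "L2", c(200L, 202L)))
  v2 <- full_sib_plausible(toy_ssr(tri), "A", "B", "P")
  expect_true(v2$plausible)  # triploid B assessed under the unreduced model

  clash <- list(
    list("P", "L1", c(100L, 102L)),
    list("A", "L1", c(100L, 124L)),
    list("B", "L1", c(100L, 102L, 126L, 128L)))
  v3 <- full_sib_plausible(toy_ssr(clash), "A", "B", "P")
  expect_false(v3$plausible) # {124} + {126,128}: three alleles required
})

test_that("timeline checks flag reversed dates and pass unknowns through", {
  meta <- accession_meta(tibble::tibble(
    accession_id = c("old", "young", "undated"),
    date_of_origin = c("pre 1750", "1897", NA)))
  expect_identical(timeline_check(meta, "old", "young")$status, "ok")
  expect_identical(timeline_check(meta, "young", "old")$status, "conflict")
  expect_identical(timeline_check(meta, "undated", "young")$status, "unknown")
})
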