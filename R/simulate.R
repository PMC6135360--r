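#' Configuration for the pedigree simulator
#'
#' The simulator emulates a clonally propagated germplasm collection
#' genotyped with dominant biallelic markers (rendered as band
#' presence/absence, blind to dosage) and a small codominant SSR panel.
#' Defaults reflect the study conditions the package is calibrated for:
#' 562 dominant markers, 12 SSR loci on different chromosomes (so linkage
#' is irrelevant and loci are simulated independently), somatic clone
#' divergence tuned so that clone pairs score in the 0.97--1 replicate
#' similarity band, and triploids formed by a maternal unreduced
#' (first-division-restitution) gamete that retains parental
#' heterozygosity except for a small per-locus homozygosity loss
#' emulating crossover events.
#'
#' @param seed Integer RNG seed.
#' @param n_founders Number of unrelated diploid founders.
#' @param n_dart_loci Number of dominant marker loci (default 562).
#' @param n_ssr_loci Number of SSR loci (default 12).
#' @param ssr_alleles_per_locus Distinct allele sizes per SSR locus
#'   (default 8, spaced 2 bp apart).
#' @param dart_presence_freq Range of per-locus presence-allele
#'   frequencies, drawn uniformly (default `c(0.05, 0.95)`).
#' @param clone_flip_rate Per-marker probability that a clone's rendered
#'   band state differs from its source (somatic mutation / scoring error;
#'   default 0.005).
#' @param missing_rate Per-call missing probability at rendering (default
#'   0.01).
#' @param unreduced_homozygosity_loss Per-locus probability that an
#'   unreduced gamete carries two copies of one parental allele instead of
#'   both alleles (default 0.05).
#' @param n_redundant_markers Redundant duplicate marker columns appended
#'   at rendering (default 0).
#' @param corrupt_parent_rate Probability that a documented parent in the
#'   rendered metadata is replaced by a random other accession, to
#'   exercise mis-documentation handling (default 0).
#' @param n_clone_groups,clones_per_group Planted clone sets.
#' @param n_families,n_full_sibs Diploid full-sib families (random founder
#'   pairs) and offspring per family.
#' @param n_half_sib_families Additional families sharing a mother with an
#'   existing family.
#' @param n_triploid_families,n_triploid_offspring Triploid sets: one
#'   diploid mother contributing an unreduced diploid gamete to each of
#'   `n_triploid_offspring` offspring, each with a distinct diploid father
#'   contributing a haploid gamete.
#' @param n_tetraploids Tetraploids formed from a triploid gamete of a
#'   planted triploid plus a haploid founder gamete.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_founders = 40L, n_dart_loci = 562L,
                       n_ssr_loci = 12L, ssr_alleles_per_locus = 8L,
                       dart_presence_freq = c(0.05, 0.95),
                       clone_flip_rate = 0.005, missing_rate = 0.01,
                       unreduced_homozygosity_loss = 0.05,
                       n_redundant_markers = 0L, corrupt_parent_rate = 0,
                       n_clone_groups = 2L, clones_per_group = 3L,
                       n_families = 3L, n_full_sibs = 3L,
                       n_half_sib_families = 1L,
                       n_triploid_families = 1L, n_triploid_offspring = 8L,
                       n_tetraploids = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$clone_flip_rate, cfg$missing_rate,
             cfg$unreduced_homozygosity_loss, cfg$corrupt_parent_rate,
             cfg$dart_presence_freq)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (cfg$n_dart_loci < 1L) abort("Need at least one dominant marker locus.")
  structure(cfg, class = "sim_config")
}

new_truth <- function(config) {
  lo <- config$dart_presence_freq[1L]
  hi <- config$dart_presence_freq[2L]
  dart_p <- runif(config$n_dart_loci, lo, hi)
  ssr_freq <- lapply(seq_len(config$n_ssr_loci), function(l) {
    sizes <- 100L + 20L * (l - 1L) + 2L * seq(0L, config$ssr_alleles_per_locus - 1L)
    w <- rexp_dirichlet(config$ssr_alleles_per_locus)
    setNames(w, sizes)
  })
  names(ssr_freq) <- sprintf("SSR%02d", seq_len(config$n_ssr_loci))
  list(config = config, dart_p = dart_p, ssr_freq = ssr_freq,
       individuals = list(),
       parent_map = tibble(offspring = character(), mother = character(),
                           father = character(), gamete_maternal = character(),
                           gamete_paternal = character()),
       clone_map = tibble(accession_id = character(), source_id = character(),
                          clone_group = character(), flips = list()))
}

# symmetric Dirichlet(1) draw via normalised exponentials
rexp_dirichlet <- function(k) {
  w <- stats::rexp(k)
  w / sum(w)
}

draw_founder_genotype <- function(truth) {
  cfg <- truth$config
  dart <- rbinom(cfg$n_dart_loci, 2L, truth$dart_p) # presence-allele copies
  ssr <- lapply(truth$ssr_freq, function(f) {
    sort(as.integer(sample(names(f), 2L, replace = TRUE, prob = f)))
  })
  list(ploidy = 2L, dart = dart, ssr = ssr)
}

#' Simulate unrelated diploid founders
#'
#' Founders are drawn in Hardy--Weinberg proportions: dominant-marker
#' presence alleles at per-locus frequencies uniform in the configured
#' range, SSR alleles from symmetric-Dirichlet locus frequencies.  The
#' rendered dominant band frequency therefore follows the closed form
#' `1 - (1 - p)^c` for `c` allele copies.
#'
#' @param config A [sim_config()] (its `seed` fixes the RNG, so repeated
#'   calls are reproducible).
#' @param n Number of founders (defaults to `config$n_founders`).
#' @return A truth object (list) holding allele frequencies and founder
#'   genotypes; extend it with [sim_cross()] and [sim_clone()].
#' @export
simulate_founders <- function(config, n = config$n_founders) {
  withr::with_seed(config$seed, {
    truth <- new_truth(config)
    for (i in seq_len(n)) {
      id <- sprintf("F%03d", i)
      truth$individuals[[id]] <- c(list(id = id, role = "founder"),
                                   draw_founder_genotype(truth))
    }
    truth
  })
}

make_gamete <- function(ind, model, lambda) {
  if (model == "haploid") {
    if (ind$ploidy != 2L) abort("haploid gamete requires a diploid parent")
    dart <- rbinom(length(ind$dart), 1L, ind$dart / 2)
    ssr <- lapply(ind$ssr, function(a) a[sample.int(2L, 1L)])
  } else if (model == "unreduced_diploid") {
    if (ind$ploidy != 2L) abort("unreduced_diploid gamete requires a diploid parent")
    loss <- runif(length(ind$dart)) < lambda
    dart <- ind$dart
    dart[loss] <- 2L * rbinom(sum(loss), 1L, ind$dart[loss] / 2)
    ssr <- lapply(ind$ssr, function(a) {
      if (runif(1L) < lambda) rep(a[sample.int(2L, 1L)], 2L) else a
    })
  } else if (model == "triploid") {
    if (ind$ploidy != 3L) abort("triploid gamete requires a triploid parent")
    dart <- ind$dart
    ssr <- ind$ssr
  } else {
    abort(paste0("Unknown gamete model: ", model))
  }
  size <- c(haploid = 1L, unreduced_diploid = 2L, triploid = 3L)[[model]]
  list(dart = dart, ssr = ssr, size = size)
}

#' Cross two individuals under named gamete models
#'
#' Gamete models: `haploid` (one allele per locus from a diploid parent),
#' `unreduced_diploid` (both alleles retained, except that with
#' probability `unreduced_homozygosity_loss` a locus carries two copies of
#' one randomly chosen allele -- crossover-loss emulation under
#' first-division restitution) and `triploid` (the full complement of a
#' triploid parent).  Offspring ploidy is the sum of the gamete sizes.
#'
#' @param truth A truth object from [simulate_founders()].
#' @param mother_id,father_id Parent ids present in `truth`.
#' @param id New offspring id.
#' @param gamete_maternal,gamete_paternal Gamete model per parent.
#' @return The updated truth object.
#' @export
sim_cross <- function(truth, mother_id, father_id, id,
                      gamete_maternal = "haploid", gamete_paternal = "haploid") {
  lambda <- truth$config$unreduced_homozygosity_loss
  gm <- make_gamete(truth$individuals[[mother_id]], gamete_maternal, lambda)
  gp <- make_gamete(truth$individuals[[father_id]], gamete_paternal, lambda)
  ind <- list(id = id, role = "offspring",
              ploidy = gm$size + gp$size,
              dart = gm$dart + gp$dart,
              ssr = map2(gm$ssr, gp$ssr, function(a, b) sort(c(a, b))))
  truth$individuals[[id]] <- ind
  truth$parent_map <- bind_rows(truth$parent_map, tibble(
    offspring = id, mother = mother_id, father = father_id,
    gamete_maternal = gamete_maternal, gamete_paternal = gamete_paternal))
  truth
}

#' Plant a clone (somatic mutant / sport) of an existing individual
#'
#' The clone shares its source's genotype exactly; divergence is modelled
#' at the dominant-marker rendering level, where each band state flips
#' independently with `flip_rate`.  SSR profiles are unchanged.  Flip
#' events are logged in the truth object.
#'
#' @param truth A truth object.
#' @param source_id Individual to clone.
#' @param id New accession id.
#' @param flip_rate Per-marker flip probability (defaults to
#'   `config$clone_flip_rate`).
#' @param clone_group Group label (defaults to the source id).
#' @return The updated truth object.
#' @export
sim_clone <- function(truth, source_id, id,
                      flip_rate = truth$config$clone_flip_rate,
                      clone_group = source_id) {
  src <- truth$individuals[[source_id]]
  if (is.null(src)) abort(paste0("Unknown source: ", source_id))
  flips <- which(runif(truth$config$n_dart_loci) < flip_rate)
  ind <- src
  ind$id <- id
  ind$role <- "clone"
  truth$individuals[[id]] <- ind
  truth$clone_map <- bind_rows(truth$clone_map, tibble(
    accession_id = id, source_id = source_id, clone_group = clone_group,
    flips = list(flips)))
  truth
}

#' Render a truth object as analysis-ready tables
#'
#' Dominant rendering: a marker band is present iff the individual carries
#' at least one presence allele across all chromosome copies (ploidy
#' aware); clone flip events then invert the recorded states; missing
#' calls are injected at `missing_rate` (never leaving an accession fully
#' missing); redundant duplicate marker columns may be appended.  SSR
#' profiles report distinct allele sizes (dosage-blind, as capillary
#' electrophoresis does).  Metadata carries true ploidy, clone groups and
#' documented parents, optionally corrupted at `corrupt_parent_rate`.
#'
#' @param truth A truth object.
#' @return List with `markers` ([marker_matrix()]), `meta`
#'   ([accession_meta()]), `ssr` ([ssr_profiles()]) and `truth` (the input,
#'   carrying the planted pedigree and clone/flip log).
#' @export
render_collection <- function(truth) {
  cfg <- truth$config
  inds <- truth$individuals
  ids <- names(inds)
  n_loci <- cfg$n_dart_loci
  band <- t(vapply(inds, function(x) as.integer(x$dart > 0L), integer(n_loci)))
  rownames(band) <- ids
  colnames(band) <- sprintf("M%04d", seq_len(n_loci))
  for (k in seq_len(nrow(truth$clone_map))) {
    fl <- truth$clone_map$flips[[k]]
    if (length(fl)) {
      r <- truth$clone_map$accession_id[k]
      band[r, fl] <- 1L - band[r, fl]
    }
  }
  if (cfg$n_redundant_markers > 0L) {
    src <- seq_len(min(cfg$n_redundant_markers, ncol(band)))
    dup <- band[, src, drop = FALSE]
    colnames(dup) <- paste0("R", colnames(band)[src])
    band <- cbind(band, dup)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(length(band)) < cfg$missing_rate, nrow(band))
    for (i in seq_len(nrow(band))) {           # keep >= 1 observed call each
      if (all(miss[i, ])) miss[i, sample.int(ncol(band), 1L)] <- FALSE
    }
    band[miss] <- NA_integer_
  }
  markers <- marker_matrix(band)

  pm <- truth$parent_map
  mother <- setNames(pm$mother, pm$offspring)
  father <- setNames(pm$father, pm$offspring)
  src <- setNames(truth$clone_map$source_id, truth$clone_map$accession_id)
  cg <- setNames(truth$clone_map$clone_group, truth$clone_map$accession_id)
  p1 <- unname(mother[ids])
  p2 <- unname(father[ids])
  if (cfg$corrupt_parent_rate > 0) {
    documented <- which(!is.na(p1))
    flip <- documented[runif(length(documented)) < cfg$corrupt_parent_rate]
    for (i in flip) p1[i] <- sample(setdiff(ids, c(ids[i], p1[i])), 1L)
  }
  meta <- accession_meta(tibble(
    accession_id = ids, cultivar_name = ids,
    ploidy = map_int(inds, "ploidy"),
    parent1 = p1, parent2 = p2,
    clone_group = ifelse(ids %in% names(cg), cg[ids],
                         ifelse(ids %in% truth$clone_map$source_id, ids, NA)),
    subset_flag = !(ids %in% names(src))))

  ssr <- ssr_profiles(purrr::map_dfr(inds, function(x) {
    tibble(accession_id = x$id, locus = names(x$ssr),
           alleles = lapply(x$ssr, function(a) sort(unique(a))))
  }))

  list(markers = markers, meta = meta, ssr = ssr, truth = truth)
}

#' Simulate a full collection with planted truth
#'
#' Builds founders, clone sets, diploid full-sib and half-sib families,
#' unreduced-gamete triploid sets (one diploid mother, several triploid
#' offspring by distinct fathers) and triploid-gamete tetraploids, then
#' renders everything with [render_collection()].  Output is a pure
#' function of the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return The [render_collection()] bundle.
#' @export
simulate_collection <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    truth <- new_truth(config)
    for (i in seq_len(config$n_founders)) {
      id <- sprintf("F%03d", i)
      truth$individuals[[id]] <- c(list(id = id, role = "founder"),
                                   draw_founder_genotype(truth))
    }
    founders <- names(truth$individuals)

    for (g in seq_len(config$n_clone_groups)) {
      src <- founders[g]
      for (c in seq_len(config$clones_per_group)) {
        truth <- sim_clone(truth, src, sprintf("%s_clone%d", src, c))
      }
    }

    pick2 <- function() sample(founders, 2L)
    fam_mothers <- character()
    for (f in seq_len(config$n_families)) {
      pr <- pick2()
      fam_mothers <- c(fam_mothers, pr[1L])
      for (o in seq_len(config$n_full_sibs)) {
        truth <- sim_cross(truth, pr[1L], pr[2L], sprintf("FS%02d_%d", f, o))
      }
    }
    for (h in seq_len(config$n_half_sib_families)) {
      mo <- if (length(fam_mothers)) fam_mothers[1L + (h - 1L) %% length(fam_mothers)]
        else sample(founders, 1L)
      fa <- sample(setdiff(founders, mo), 1L)
      for (o in seq_len(config$n_full_sibs)) {
        truth <- sim_cross(truth, mo, fa, sprintf("HS%02d_%d", h, o))
      }
    }

    tri_ids <- character()
    for (t in seq_len(config$n_triploid_families)) {
      used <- unique(c(fam_mothers))
      mo <- sample(setdiff(founders, used), 1L)
      fam_mothers <- c(fam_mothers, mo)
      pool <- setdiff(founders, mo)
      fathers <- sample(pool, config$n_triploid_offspring,
                        replace = length(pool) < config$n_triploid_offspring)
      for (o in seq_len(config$n_triploid_offspring)) {
        id <- sprintf("TR%02d_%d", t, o)
        truth <- sim_cross(truth, mo, fathers[o], id,
                           gamete_maternal = "unreduced_diploid",
                           gamete_paternal = "haploid")
        tri_ids <- c(tri_ids, id)
      }
    }
    for (q in seq_len(config$n_tetraploids)) {
      if (length(tri_ids) == 0L) break
      mo <- tri_ids[1L + (q - 1L) %% length(tri_ids)]
      fa <- sample(founders, 1L)
      truth <- sim_cross(truth, mo, fa, sprintf("TT%02d", q),
                         gamete_maternal = "triploid",
                         gamete_paternal = "haploid")
    }

    render_collection(truth)
  })
}

#' Simulate replicate clustering-run log probabilities with a known elbow
#'
#' Mean ln probability is piecewise linear in K with a slope break at
#' `true_k`; replicate noise is Gaussian with a standard deviation that
#' grows for K beyond the elbow, as is typical of over-fitted admixture
#' runs.  Emitted in the runs schema consumed by [compute_delta_k()].
#'
#' @param true_k Elbow position (must be interior to `k_range`).
#' @param k_range Integer ladder of K values (default `1:10`).
#' @param n_replicates Replicates per K (default 10).
#' @param seed RNG seed.
#' @param slope_before,slope_after Mean lnP slopes below/above the elbow.
#' @param noise_sd Baseline replicate SD.
#' @param noise_growth Additional SD per K step beyond the elbow.
#' @return A `structure_runs` tibble.
#' @export
simulate_structure_logs <- function(true_k, k_range = 1:10, n_replicates = 10L,
                                    seed = 1L, slope_before = 200,
                                    slope_after = 5, noise_sd = 2,
                                    noise_growth = 1) {
  if (!(true_k > min(k_range) && true_k < max(k_range))) {
    abort("`true_k` must be interior to `k_range`.")
  }
  withr::with_seed(seed, {
    mean_lnp <- function(k) {
      -1e4 + slope_before * (pmin(k, true_k) - min(k_range)) +
        slope_after * pmax(k - true_k, 0)
    }
    grid <- tibble(
      K = rep(as.integer(k_range), times = n_replicates),
      replicate = rep(sprintf("r%02d", seq_len(n_replicates)),
                      each = length(k_range)))
    sdv <- noise_sd + noise_growth * pmax(grid$K - true_k, 0)
    grid$lnP <- mean_lnp(grid$K) + rnorm(nrow(grid), 0, sdv)
    structure_runs(grid)
  })
}
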