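#' Ploidy-aware SSR parentage assessment
#'
#' Tests whether a putative parent could have contributed a gamete to an
#' offspring under a named gamete model, locus by locus, using exclusion
#' logic on codominant allele sizes:
#'
#' * `haploid` -- a diploid parent transmits one allele per locus; a locus
#'   is consistent iff the offspring shares at least one allele with the
#'   parent.
#' * `unreduced_diploid` -- the parent transmits its full diploid
#'   complement (first-division restitution), so a heterozygous parent's
#'   two alleles must both appear in the (triploid) offspring.  A parent
#'   reporting a single size is possibly homozygous; such loci are scored
#'   `consistent_homozygous_ambiguous` when containment holds but cannot
#'   be proven.  A single absent parent allele is `tolerated_missing`
#'   while the tolerance budget lasts (mirroring rare allele loss by
#'   crossing over during restitution), otherwise `inconsistent`.
#' * `triploid` -- a triploid parent transmits its full complement to a
#'   tetraploid offspring; loci are additionally categorised as
#'   `full_complement` (all three distinct parent alleles present),
#'   `indistinguishable` (parent shows fewer than three distinct sizes,
#'   all present), `partial` (exactly one absent) or `inconsistent`.
#'
#' Loci missing in either profile are `no_data` and excluded from all
#' counts -- missing data never act as wildcard matches.  Allele equality
#' is exact integer match; see `shift_warn` for annotation of near-miss
#' single-repeat (2 bp) shifts.
#'
#' @param ssr An [ssr_profiles()] tibble.
#' @param parent_id,offspring_id Accessions to test.
#' @param model `"haploid"`, `"unreduced_diploid"` or `"triploid"`.
#' @param tolerance Number of tolerable events (inconsistent loci under
#'   `haploid`; single-missing-allele loci under the polyploid models)
#'   before exclusion.  Defaults: 0 for `haploid`, 1 otherwise.
#' @param shift_warn When `TRUE` (default) an inconsistent locus whose
#'   offspring carries an allele exactly 2 bp from a required parent
#'   allele is annotated `shift_2bp = TRUE` in the verdicts; annotation
#'   only, never a rescue.
#' @return A `parentage_assessment` object; see [tidy()] for per-locus
#'   verdicts and [glance()] for the one-row summary.  The `overall` field
#'   is `"plausible"`, `"plausible_with_tolerance"` or `"excluded"`.
#' @export
assess_parentage <- function(ssr, parent_id, offspring_id,
                             model = c("haploid", "unreduced_diploid", "triploid"),
                             tolerance = NULL, shift_warn = TRUE) {
  model <- match.arg(model)
  tolerance <- as.integer(tolerance %||% if (model == "haploid") 0L else 1L)
  par <- ssr_profile(ssr, parent_id)
  off <- ssr_profile(ssr, offspring_id)
  loci <- sort(union(names(par), names(off)))
  if (length(loci) == 0L) abort("No SSR data for this pair.")

  max_par <- c(haploid = 2L, unreduced_diploid = 2L, triploid = 3L)[[model]]
  verdicts <- purrr::map_dfr(loci, function(l) {
    p <- unique(par[[l]] %||% integer())
    o <- unique(off[[l]] %||% integer())
    if (length(p) > max_par) {
      abort(sprintf("Parent '%s' shows %d alleles at %s; model '%s' allows at most %d.",
                    parent_id, length(p), l, model, max_par))
    }
    v <- locus_verdict(p, o, model)
    v$locus <- l
    v$shift_2bp <- shift_warn && v$status == "inconsistent" &&
      length(p) && length(o) && any(abs(outer(p, o, "-")) == 2L)
    v
  })
  verdicts <- select(verdicts, "locus", dplyr::everything())

  scored <- verdicts$status != "no_data"
  if (!any(scored)) abort("No commonly scored locus; parentage indeterminate.")
  tolerable <- if (model == "haploid") verdicts$status == "inconsistent"
    else verdicts$status == "tolerated_missing"
  n_events <- sum(tolerable)
  n_tolerated <- min(n_events, tolerance)
  n_inconsistent <- sum(verdicts$status == "inconsistent" & !tolerable) +
    max(0L, n_events - tolerance)
  overall <- if (n_inconsistent > 0L) "excluded"
    else if (n_tolerated > 0L) "plausible_with_tolerance" else "plausible"

  structure(list(offspring_id = offspring_id, parent_id = parent_id,
                 model = model, tolerance = tolerance, verdicts = verdicts,
                 n_scored = sum(scored), n_inconsistent = n_inconsistent,
                 n_tolerated = n_tolerated, overall = overall),
            class = "parentage_assessment")
}

# single-locus verdict; p and o are distinct sorted allele sizes
locus_verdict <- function(p, o, model) {
  out <- tibble(status = "no_data", category = NA_character_,
                residual = list(integer()), residual_forced = FALSE)
  if (length(p) == 0L || length(o) == 0L) return(out)
  if (model == "haploid") {
    shared <- intersect(o, p)
    if (length(shared) == 0L) {
      out$status <- "inconsistent"
    } else if (length(o) == 1L) {
      out$status <- "consistent_homozygous_ambiguous"
      out$residual <- list(o)         # father must also carry this size
      out$residual_forced <- TRUE
    } else {
      extra <- setdiff(o, p)
      out$status <- "consistent"
      if (length(extra) > 0L) {
        out$residual <- list(extra)
        out$residual_forced <- TRUE
      } else {
        out$residual <- list(o)       # either allele may be paternal
        out$residual_forced <- FALSE
      }
    }
  } else if (model == "unreduced_diploid") {
    absent <- setdiff(p, o)
    extra <- setdiff(o, p)
    if (length(absent) == 0L) {
      if (length(p) == 1L) {
        out$status <- if (length(o) < 3L) "consistent_homozygous_ambiguous" else "consistent"
        out$residual <- list(extra)
        out$residual_forced <- length(extra) <= 1L && length(o) >= 2L
      } else {
        out$status <- "consistent"
        out$residual <- list(extra)
        out$residual_forced <- TRUE
      }
    } else if (length(absent) == 1L) {
      out$status <- "tolerated_missing"
      out$residual <- list(extra)
    } else {
      out$status <- "inconsistent"
    }
  } else { # triploid gamete into tetraploid offspring
    absent <- setdiff(p, o)
    extra <- setdiff(o, p)
    if (length(absent) == 0L) {
      if (length(p) == 3L) {
        out$status <- "consistent"
        out$category <- "full_complement"
      } else {
        out$status <- "consistent_homozygous_ambiguous"
        out$category <- "indistinguishable"
      }
      out$residual <- list(extra)
      out$residual_forced <- length(p) == 3L
    } else if (length(absent) == 1L) {
      out$status <- "tolerated_missing"
      out$category <- "partial"
      out$residual <- list(extra)
    } else {
      out$status <- "inconsistent"
      out$category <- "inconsistent"
    }
  }
  out
}

#' @export
print.parentage_assessment <- function(x, ...) {
  cat(sprintf("<parentage_assessment> %s -> %s [%s gamete]\n",
              x$parent_id, x$offspring_id, x$model))
  cat(sprintf("  overall: %s (%d scored loci, %d inconsistent, %d tolerated of %d)\n",
              x$overall, x$n_scored, x$n_inconsistent, x$n_tolerated, x$tolerance))
  invisible(x)
}

#' @method tidy parentage_assessment
#' @export
tidy.parentage_assessment <- function(x, ...) {
  mutate(x$verdicts, parent_id = x$parent_id, offspring_id = x$offspring_id,
         model = x$model)
}

#' @method glance parentage_assessment
#' @export
glance.parentage_assessment <- function(x, ...) {
  cats <- x$verdicts$category
  tibble(parent_id = x$parent_id, offspring_id = x$offspring_id,
         model = x$model, overall = x$overall, n_scored = x$n_scored,
         n_inconsistent = x$n_inconsistent, n_tolerated = x$n_tolerated,
         n_full_complement = sum(cats == "full_complement", na.rm = TRUE),
         n_indistinguishable = sum(cats == "indistinguishable", na.rm = TRUE),
         n_partial = sum(cats == "partial", na.rm = TRUE),
         n_category_inconsistent = sum(cats == "inconsistent", na.rm = TRUE))
}

#' @rdname assess_parentage
#' @export
po_compatible <- function(ssr, parent_id, offspring_id, tolerance = 0L, ...) {
  assess_parentage(ssr, parent_id, offspring_id, model = "haploid",
                   tolerance = tolerance, ...)
}

#' @rdname assess_parentage
#' @export
diploid_complement_in_triploid <- function(ssr, parent_id, offspring_id,
                                           tolerance = 1L, ...) {
  assess_parentage(ssr, parent_id, offspring_id, model = "unreduced_diploid",
                   tolerance = tolerance, ...)
}

#' @rdname assess_parentage
#' @export
triploid_complement_in_tetraploid <- function(ssr, parent_id, offspring_id,
                                              tolerance = 0L, ...) {
  assess_parentage(ssr, parent_id, offspring_id, model = "triploid",
                   tolerance = tolerance, ...)
}

#' Exclusion-based search for a missing second parent
#'
#' Given an offspring and one accepted parent (under a gamete model), the
#' alleles the other parent must have supplied are computed per locus and
#' every panel member is screened for the ability to supply them.  A
#' candidate survives when no scored locus excludes it; exactly one
#' survivor is the classical exclusion standard for proposing a pedigree.
#'
#' @param ssr An [ssr_profiles()] tibble.
#' @param offspring_id,known_parent_id The trio's known half.
#' @param panel Character vector of candidate accession ids (the offspring
#'   and known parent are dropped automatically).
#' @param model Gamete model of the *known* parent (the candidate is
#'   always assumed to contribute a haploid gamete).
#' @param known_tolerance Tolerance passed to the known-parent check.
#' @return Tibble with one row per candidate: `candidate_id`,
#'   `n_loci_scored`, `n_consistent`, `n_inconsistent`, `survives`,
#'   ordered by (`n_consistent` desc, id asc) among survivors first;
#'   attribute `unique_survivor` is the single surviving id or `NA`.
#' @export
infer_missing_parent <- function(ssr, offspring_id, known_parent_id, panel,
                                 model = c("haploid", "unreduced_diploid"),
                                 known_tolerance = NULL) {
  model <- match.arg(model)
  known <- assess_parentage(ssr, known_parent_id, offspring_id, model = model,
                            tolerance = known_tolerance)
  if (known$overall == "excluded") {
    abort(sprintf("Known parent '%s' is itself excluded for '%s' (%d inconsistent loci).",
                  known_parent_id, offspring_id, known$n_inconsistent))
  }
  mother <- ssr_profile(ssr, known_parent_id)
  off <- ssr_profile(ssr, offspring_id)
  loci <- intersect(names(mother)[lengths(mother) > 0], names(off)[lengths(off) > 0])
  panel <- setdiff(unique(panel), c(offspring_id, known_parent_id))

  res <- purrr::map_dfr(panel, function(cid) {
    cand <- ssr_profile(ssr, cid)
    stat <- vapply(loci, function(l) {
      co <- unique(cand[[l]] %||% integer())
      if (length(co) == 0L) return(NA)           # candidate unscored: excluded from counts
      candidate_locus_ok(unique(mother[[l]]), unique(off[[l]]), co, model)
    }, logical(1))
    tibble(candidate_id = cid,
           n_loci_scored = sum(!is.na(stat)),
           n_consistent = sum(stat, na.rm = TRUE),
           n_inconsistent = sum(!stat, na.rm = TRUE),
           survives = sum(!stat, na.rm = TRUE) == 0L & sum(!is.na(stat)) > 0L)
  })
  res <- arrange(res, dplyr::desc(.data$survives), dplyr::desc(.data$n_consistent),
                 .data$candidate_id)
  survivors <- res$candidate_id[res$survives]
  attr(res, "unique_survivor") <- if (length(survivors) == 1L) survivors else NA_character_
  attr(res, "known_parent_assessment") <- known
  res
}

# can candidate `cand` supply the paternal gamete at one locus?
candidate_locus_ok <- function(m, o, cand, model) {
  if (model == "haploid") {
    if (length(o) == 1L) return(o %in% m && o %in% cand)
    any(vapply(o, function(f) {
      f %in% cand && length(intersect(setdiff(o, f), m)) == length(setdiff(o, f))
    }, logical(1)))
  } else {
    r <- setdiff(o, m)
    if (length(r) == 0L) return(length(intersect(cand, o)) > 0L)
    if (length(r) == 1L) return(r %in% cand)
    FALSE
  }
}

#' Can two accessions be full siblings through a shared parent?
#'
#' Accepts the shared parent for both offspring (gamete model chosen per
#' offspring: `unreduced_diploid` when the offspring shows three alleles
#' anywhere or is known triploid, `haploid` otherwise), then unifies the
#' per-locus residual allele sets owed by the second parent.  The pair is
#' plausible as full siblings iff at most two distinct alleles are
#' required at every locus -- the capacity of a single diploid genotype.
#' Ambiguous residuals (where any offspring allele could be paternal) add
#' no requirements.
#'
#' @inheritParams infer_missing_parent
#' @param id_a,id_b The putative siblings.
#' @param shared_parent_id The documented/accepted common parent.
#' @param ploidy Optional named vector of known ploidies.
#' @param panel Optional candidate panel; when given, the exclusion search
#'   is run jointly and ids able to father *both* are reported.
#' @return List of class `full_sib_verdict`: `plausible` (logical), `loci`
#'   (tibble with per-locus required alleles), `assessment_a`,
#'   `assessment_b`, and `joint_candidates` (or `NULL`).
#' @export
full_sib_plausible <- function(ssr, id_a, id_b, shared_parent_id,
                               ploidy = NULL, panel = NULL) {
  model_for <- function(id) {
    pl <- if (!is.null(ploidy)) ploidy[[id]] %||% NA_integer_ else NA_integer_
    prof <- ssr_profile(ssr, id)
    if ((!is.na(pl) && pl >= 3L) || any(lengths(prof) >= 3L)) "unreduced_diploid" else "haploid"
  }
  ma <- model_for(id_a)
  mb <- model_for(id_b)
  aa <- assess_parentage(ssr, shared_parent_id, id_a, model = ma)
  ab <- assess_parentage(ssr, shared_parent_id, id_b, model = mb)
  if (aa$overall == "excluded" || ab$overall == "excluded") {
    abort(sprintf("Shared parent '%s' is excluded for %s.", shared_parent_id,
                  if (aa$overall == "excluded") id_a else id_b))
  }
  forced <- function(assess) {
    v <- assess$verdicts
    setNames(map2(v$residual, v$residual_forced, function(r, f) if (f) r else integer()),
             v$locus)
  }
  ra <- forced(aa)
  rb <- forced(ab)
  loci <- sort(union(names(ra), names(rb)))
  loci_tbl <- purrr::map_dfr(loci, function(l) {
    req <- sort(union(ra[[l]] %||% integer(), rb[[l]] %||% integer()))
    tibble(locus = l, required = list(req), n_required = length(req),
           ok = length(req) <= 2L)
  })
  joint <- NULL
  if (!is.null(panel)) {
    ca <- infer_missing_parent(ssr, id_a, shared_parent_id, panel, model = ma)
    cb <- infer_missing_parent(ssr, id_b, shared_parent_id, panel, model = mb)
    joint <- intersect(ca$candidate_id[ca$survives], cb$candidate_id[cb$survives])
  }
  structure(list(plausible = all(loci_tbl$ok), loci = loci_tbl,
                 assessment_a = aa, assessment_b = ab,
                 joint_candidates = joint),
            class = "full_sib_verdict")
}

#' Check documented dates against a proposed parent-offspring direction
#'
#' A parent recorded later than its proposed offspring is flagged as a
#' timeline conflict -- a flag for investigation, never an exclusion,
#' because many records are `pre`-dated upper bounds and cultivars are
#' frequently far older than their first record.
#'
#' @param meta An [accession_meta()].
#' @param parent_id,offspring_id Accessions to compare.
#' @return Tibble with `status` (`"ok"`, `"conflict"`, `"unknown"`), the
#'   parsed years and `pre` flags.
#' @export
timeline_check <- function(meta, parent_id, offspring_id) {
  row <- function(id) meta[meta$accession_id == id, ]
  yp <- parse_origin_year(row(parent_id)$date_of_origin)
  yo <- parse_origin_year(row(offspring_id)$date_of_origin)
  status <- if (nrow(yp) == 0L || nrow(yo) == 0L || is.na(yp$year) || is.na(yo$year)) {
    "unknown"
  } else if (yp$year > yo$year) "conflict" else "ok"
  tibble(parent_id = parent_id, offspring_id = offspring_id, status = status,
         parent_year = if (nrow(yp)) yp$year else NA_integer_,
         parent_pre = if (nrow(yp)) yp$pre else NA,
         offspring_year = if (nrow(yo)) yo$year else NA_integer_,
         offspring_pre = if (nrow(yo)) yo$pre else NA)
}
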