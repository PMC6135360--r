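#' Jaccard similarity between two dominant call vectors
#'
#' Over the markers observed in both accessions, with `a` the count of
#' shared band presences and `b`, `c` the counts present in only one
#' accession, the coefficient is `a / (a + b + c)`.  Joint absences carry
#' no information about shared ancestry for dominant markers and do not
#' contribute.  Markers missing in either accession are dropped
#' (pairwise-complete scoring).
#'
#' @param x,y Equal-length vectors of 0/1/`NA` calls.
#' @return A single value in `[0, 1]`, or `NA` when no co-observed marker
#'   shows a band in either accession.
#' @examples
#' jaccard(c(1, 1, 0, 1), c(1, 0, 0, 1)) # 2/3
#' jaccard(c(1, NA, 0), c(1, 1, 0))      # computed on 2 markers -> 1
#' @export
jaccard <- function(x, y) {
  if (length(x) != length(y)) abort("Call vectors must have equal length.")
  obs <- !is.na(x) & !is.na(y)
  x <- x[obs]
  y <- y[obs]
  u <- sum(x == 1L | y == 1L)
  if (u == 0L) return(NA_real_)
  sum(x == 1L & y == 1L) / u
}

#' All pairwise Jaccard similarities for a marker matrix
#'
#' Scores every unordered pair of accessions with [jaccard()] and records
#' the number of co-observed markers per pair so that low-overlap pairs can
#' be filtered downstream.
#'
#' @param x A [marker_matrix()] with at least two accessions.
#' @return A `similarity_pairs` tibble with columns `acc_i`, `acc_j`
#'   (`acc_i < acc_j` in the accession ordering of `x`), `jaccard` and
#'   `n_shared`.  The full symmetric matrix is available via
#'   [similarity_matrix()].
#' @export
pairwise_jaccard <- function(x) {
  calls <- as_call_matrix(x)
  if (nrow(calls) < 2L) abort("Need at least two accessions.")
  obs <- !is.na(calls)
  pres <- calls == 1L & obs
  storage.mode(pres) <- "double"
  storage.mode(obs) <- "double"
  a <- tcrossprod(pres)                       # shared presences on co-observed markers
  po <- tcrossprod(pres, obs)                 # present in row-acc, observed in col-acc
  union <- po + t(po) - a                     # a + b + c
  n_shared <- tcrossprod(obs)
  S <- ifelse(union > 0, a / union, NA_real_)
  ids <- rownames(calls)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  out <- tibble(
    acc_i = ids[idx[, 1L]],
    acc_j = ids[idx[, 2L]],
    jaccard = S[idx],
    n_shared = as.integer(n_shared[idx])
  )
  class(out) <- c("similarity_pairs", class(tibble()))
  attr(out, "accession_ids") <- ids
  out
}

#' Square similarity matrix from pairwise scores
#'
#' @param pairs A `similarity_pairs` tibble from [pairwise_jaccard()].
#' @return Symmetric numeric matrix with unit diagonal (set `NA` on the
#'   diagonal only for accessions that never show a band).
#' @export
similarity_matrix <- function(pairs) {
  ids <- attr(pairs, "accession_ids") %||% sort(unique(c(pairs$acc_i, pairs$acc_j)))
  S <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$acc_i, ids)
  j <- match(pairs$acc_j, ids)
  S[cbind(i, j)] <- pairs$jaccard
  S[cbind(j, i)] <- pairs$jaccard
  diag(S) <- 1
  S
}

#' Restrict pairwise similarities to a subset of accessions
#'
#' @param pairs A `similarity_pairs` tibble.
#' @param ids Accessions to keep.
#' @return The filtered `similarity_pairs` tibble.
#' @export
filter_similarity <- function(pairs, ids) {
  out <- filter(pairs, .data$acc_i %in% ids & .data$acc_j %in% ids)
  class(out) <- class(pairs)
  attr(out, "accession_ids") <- intersect(attr(pairs, "accession_ids") %||% ids, ids)
  out
}

#' Within-group and group-versus-rest similarity summaries
#'
#' For each labelled group (for example a documented clone set of a
#' cultivar) reports the minimum, mean and maximum within-group similarity
#' and the maximum similarity of any member against any non-member -- the
#' comparison used to calibrate a clonality threshold.
#'
#' @param pairs A `similarity_pairs` tibble covering all accessions of
#'   interest.
#' @param groups Tibble with columns `accession_id` and `group`, or a named
#'   character vector (`accession_id` -> group).  Unlabelled accessions
#'   count only as non-members.
#' @return Tibble with one row per group: `group`, `n_members`,
#'   `min_within`, `mean_within`, `max_within`, `max_vs_nonmember`.
#'   Within-group statistics are `NA` for singleton groups; the
#'   versus-non-member maximum is `NA` when there is no non-member.
#' @export
group_stats <- function(pairs, groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble(accession_id = names(groups), group = unname(groups))
  }
  ids <- attr(pairs, "accession_ids") %||% unique(c(pairs$acc_i, pairs$acc_j))
  lab <- setNames(groups$group, groups$accession_id)[ids]
  gi <- lab[pairs$acc_i]
  gj <- lab[pairs$acc_j]
  purrr::map_dfr(sort(unique(groups$group)), function(g) {
    members <- ids[!is.na(lab) & lab == g]
    within <- pairs$jaccard[!is.na(gi) & !is.na(gj) & gi == g & gj == g]
    cross <- pairs$jaccard[xor(!is.na(gi) & gi == g, !is.na(gj) & gj == g)]
    tibble(
      group = g, n_members = length(members),
      min_within = if (length(within)) min(within, na.rm = TRUE) else NA_real_,
      mean_within = if (length(within)) mean(within, na.rm = TRUE) else NA_real_,
      max_within = if (length(within)) max(within, na.rm = TRUE) else NA_real_,
      max_vs_nonmember = if (length(cross)) max(cross, na.rm = TRUE) else NA_real_
    )
  })
}

#' Kernel density profile of similarity scores
#'
#' Gaussian kernel density estimate with the bandwidth interpreted as the
#' kernel standard deviation, evaluated on a regular grid of `n_grid`
#' points spanning `[min - 3h, max + 3h]`.  The bandwidth is applied on
#' whatever scale the values are passed in (a bandwidth of 0.75 matches
#' percent-style 0--100 scales; use e.g. 0.0075 on the raw 0--1 scale).
#'
#' @param values Numeric vector (at least two finite values).
#' @param bandwidth Kernel standard deviation (default 0.75).
#' @param n_grid Number of grid points (default 512).
#' @return A `density_profile` tibble with columns `grid` and `density`;
#'   attribute `degenerate` is `TRUE` when all values are identical.
#' @export
density_profile <- function(values, bandwidth = 0.75, n_grid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort("Need at least two finite values.")
  degenerate <- length(unique(values)) == 1L
  d <- density(values, bw = bandwidth, kernel = "gaussian", n = n_grid,
               from = min(values) - 3 * bandwidth,
               to = max(values) + 3 * bandwidth)
  out <- tibble(grid = d$x, density = d$y)
  class(out) <- c("density_profile", class(tibble()))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "degenerate") <- degenerate
  out
}

#' Write pairwise similarities to disk
#'
#' Both a long form (`acc_i`, `acc_j`, `jaccard`, `n_shared`) and a square
#' matrix form with an accession header are supported; similarity is
#' printed to three decimals in the square form, matching the precision at
#' which clonality thresholds are interpreted.
#'
#' @param pairs A `similarity_pairs` tibble.
#' @param path Output path.
#' @param shape `"long"` or `"square"`.
#' @export
write_similarity <- function(pairs, path, shape = c("long", "square")) {
  shape <- match.arg(shape)
  if (shape == "long") {
    readr::write_csv(pairs, path)
  } else {
    S <- round(similarity_matrix(pairs), 3)
    readr::write_csv(as_tibble(S, rownames = "accession_id"), path)
  }
  invisible(path)
}
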