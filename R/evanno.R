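#' Read replicate clustering-run summaries
#'
#' Expects a delimited table with columns `K` (number of clusters),
#' `replicate` (label) and `lnP` (estimated ln probability of the data for
#' that run).  Rows are validated and sorted by `K`; a `K` with a single
#' replicate is accepted but flagged, because the delta-K denominator (a
#' replicate standard deviation) is undefined there.
#'
#' @param path CSV/TSV path (`.gz` accepted).
#' @return A `structure_runs` tibble (`K`, `replicate`, `lnP`) with
#'   attribute `single_replicate_K` listing flagged K values.
#' @export
read_structure_runs <- function(path) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  structure_runs(raw)
}

#' @rdname read_structure_runs
#' @param df Data frame with columns `K`, `replicate`, `lnP`.
#' @export
structure_runs <- function(df) {
  df <- as_tibble(df)
  if (!all(c("K", "replicate", "lnP") %in% names(df))) {
    abort("Columns `K`, `replicate`, `lnP` required.")
  }
  df <- mutate(df, K = as.integer(.data$K), replicate = as.character(.data$replicate),
               lnP = as.double(.data$lnP)) %>% arrange(.data$K, .data$replicate)
  if (any(df$K < 1L)) abort("K must be >= 1.")
  if (anyDuplicated(df[c("K", "replicate")])) {
    abort("Duplicate (K, replicate) rows.")
  }
  singles <- df %>% count(.data$K) %>% filter(n == 1L) %>% pull(.data$K)
  if (length(singles)) {
    warn(paste0("Single replicate at K = ", paste(singles, collapse = ", "),
                "; delta-K undefined there."))
  }
  class(df) <- c("structure_runs", class(tibble()))
  attr(df, "single_replicate_K") <- singles
  df
}

#' @rdname read_structure_runs
#' @param x A `structure_runs` tibble.
#' @export
write_structure_runs <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Evanno delta-K from replicate clustering runs
#'
#' For each interior K of a consecutive ladder, the per-replicate second
#' difference `L''_r(K) = L_r(K+1) - 2 L_r(K) + L_r(K-1)` is computed and
#' `deltaK(K) = mean_r |L''_r(K)| / sd_r(L_r(K))`.  Endpoints carry no
#' delta-K; a K with zero replicate standard deviation or fewer than two
#' replicates is flagged and left `NA`.  All local maxima are reported
#' with a prominence measure (peak value over the median defined delta-K),
#' because secondary peaks can capture finer structure than the global
#' argmax alone.
#'
#' @param runs A `structure_runs` tibble spanning at least three
#'   consecutive K values.
#' @return A `delta_k` object with fields `by_k` (per-K tibble: `K`,
#'   `n_replicates`, `mean_lnP`, `sd_lnP`, `mean_abs_l2`, `delta_k`,
#'   `flag`), `peaks` (tibble ranked by delta-K) and `runs`.
#' @export
compute_delta_k <- function(runs) {
  runs <- structure_runs(as_tibble(runs))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) abort("Need at least three K values.")
  if (!identical(ks, seq(min(ks), max(ks)))) {
    abort(paste0("K ladder has gaps: ", paste(ks, collapse = ", ")))
  }
  by_rep <- split(runs, runs$replicate)

  by_k <- purrr::map_dfr(ks, function(k) {
    l <- runs$lnP[runs$K == k]
    interior <- k > min(ks) & k < max(ks)
    l2 <- if (interior) {
      v <- map_dbl(by_rep, function(d) {
        trip <- d$lnP[match(c(k - 1L, k, k + 1L), d$K)]
        if (anyNA(trip)) NA_real_ else trip[3L] - 2 * trip[2L] + trip[1L]
      })
      v[!is.na(v)]
    } else numeric()
    s <- if (length(l) > 1L) sd(l) else NA_real_
    flag <- if (!interior) "endpoint"
      else if (length(l) < 2L) "single_replicate"
      else if (isTRUE(s == 0)) "zero_sd"
      else NA_character_
    tibble(K = k, n_replicates = length(l), mean_lnP = mean(l), sd_lnP = s,
           mean_abs_l2 = if (length(l2)) mean(abs(l2)) else NA_real_,
           delta_k = if (is.na(flag) && length(l2)) mean(abs(l2)) / s else NA_real_,
           flag = flag)
  })

  dk <- by_k$delta_k
  def <- which(!is.na(dk))
  is_peak <- vapply(seq_along(dk), function(i) {
    if (is.na(dk[i])) return(FALSE)
    left <- if (i > 1L) dk[i - 1L] else NA_real_
    right <- if (i < length(dk)) dk[i + 1L] else NA_real_
    (is.na(left) || dk[i] >= left) && (is.na(right) || dk[i] >= right)
  }, logical(1))
  med <- median(dk[def])
  peaks <- by_k[is_peak, c("K", "delta_k")] %>%
    mutate(prominence = if (isTRUE(med > 0)) .data$delta_k / med else NA_real_) %>%
    arrange(dplyr::desc(.data$delta_k))

  structure(list(by_k = by_k, peaks = peaks, runs = runs), class = "delta_k")
}

#' @export
print.delta_k <- function(x, ...) {
  cat("<delta_k> Evanno diagnostics over K =", min(x$by_k$K), "..", max(x$by_k$K), "\n")
  if (nrow(x$peaks)) {
    cat("  best K by delta-K:", x$peaks$K[1L],
        sprintf("(deltaK = %.3f)\n", x$peaks$delta_k[1L]))
  }
  invisible(x)
}

#' @method tidy delta_k
#' @export
tidy.delta_k <- function(x, ...) x$by_k

#' @method glance delta_k
#' @export
glance.delta_k <- function(x, ...) {
  tibble(best_k = if (nrow(x$peaks)) x$peaks$K[1L] else NA_integer_,
         best_delta_k = if (nrow(x$peaks)) x$peaks$delta_k[1L] else NA_real_,
         n_peaks = nrow(x$peaks),
         k_min = min(x$by_k$K), k_max = max(x$by_k$K))
}

#' Plateau criterion on the mean ln probability
#'
#' Operationalises "the point at which increases in K cease to lead to
#' meaningful changes in the ln probability" as the smallest K at which
#' the next relative gain
#' `(mean_lnP(K+1) - mean_lnP(K)) / |mean_lnP(K+1) - mean_lnP(1)|`
#' drops below `rel_tol`.
#'
#' @param runs A `structure_runs` tibble.
#' @param rel_tol Relative-gain tolerance (default 0.01).
#' @return Tibble with `plateau_k` (`NA` when growth never flattens) and
#'   the `rel_tol` used.
#' @export
plateau_k <- function(runs, rel_tol = 0.01) {
  runs <- structure_runs(as_tibble(runs))
  m <- runs %>% group_by(.data$K) %>% summarise(m = mean(.data$lnP)) %>% arrange(.data$K)
  ks <- m$K
  hit <- NA_integer_
  for (i in seq_len(nrow(m) - 1L)) {
    denom <- abs(m$m[i + 1L] - m$m[1L])
    if (denom == 0) next
    if ((m$m[i + 1L] - m$m[i]) / denom < rel_tol) { hit <- ks[i]; break }
  }
  tibble(plateau_k = hit, rel_tol = rel_tol)
}
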