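#' Construct a marker matrix of dominant presence/absence calls
#'
#' A `marker_matrix` is a tibble whose first column, `accession_id`, holds
#' unique accession identifiers and whose remaining columns are markers
#' scored as `1L` (band present), `0L` (band absent) or `NA` (not reported).
#' Dominant markers such as DArT are blind to allele dosage, so a single
#' presence allele in a diploid, triploid or tetraploid all score `1`.
#'
#' @param calls A matrix (accessions in rows, markers in columns, with
#'   dimnames) or a data frame with an `accession_id` column; values must be
#'   0, 1 or `NA`.
#' @return A `marker_matrix` tibble.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, NA, 0), nrow = 2,
#'             dimnames = list(c("A1", "A2"), c("m1", "m2", "m3")))
#' marker_matrix(m)
#' @export
marker_matrix <- function(calls) {
  if (is.matrix(calls)) {
    if (is.null(rownames(calls)) || is.null(colnames(calls))) {
      abort("`calls` matrix must carry accession rownames and marker colnames.")
    }
    if (anyDuplicated(colnames(calls))) {
      dup <- unique(colnames(calls)[duplicated(colnames(calls))])
      abort(paste0("Duplicate marker id(s): ", paste(dup, collapse = ", ")))
    }
    df <- as_tibble(calls, rownames = "accession_id")
  } else {
    df <- as_tibble(calls)
    if (!"accession_id" %in% names(df)) {
      abort("`calls` data frame must have an `accession_id` column.")
    }
    df <- select(df, "accession_id", dplyr::everything())
  }
  df <- mutate(df,
    accession_id = as.character(.data$accession_id),
    across(-"accession_id", as.integer)
  )
  validate_marker_matrix(df)
  class(df) <- c("marker_matrix", class(tibble()))
  df
}

validate_marker_matrix <- function(df) {
  ids <- df[["accession_id"]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate accession id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mk <- names(df)[names(df) != "accession_id"]
  if (anyDuplicated(mk)) {
    abort(paste0("Duplicate marker id(s): ",
                 paste(unique(mk[duplicated(mk)]), collapse = ", ")))
  }
  if (length(mk) == 0L) abort("Marker matrix has no marker columns.")
  vals <- as.matrix(df[mk])
  bad <- !(vals %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    idx <- which(bad)[1L]
    abort(sprintf("Non-binary call %s at accession '%s', marker '%s'.",
                  vals[idx], ids[(idx - 1L) %% nrow(df) + 1L],
                  mk[(idx - 1L) %/% nrow(df) + 1L]))
  }
  all_na <- rowSums(!is.na(vals)) == 0L
  if (any(all_na)) {
    abort(paste0("Accession(s) with no non-missing call: ",
                 paste(ids[all_na], collapse = ", ")))
  }
  invisible(df)
}

#' Accessor helpers for marker matrices
#'
#' @param x A [marker_matrix()].
#' @return `marker_ids()` returns marker column names; `as_call_matrix()`
#'   returns an integer matrix with accession rownames.
#' @export
marker_ids <- function(x) setdiff(names(x), "accession_id")

#' @rdname marker_ids
#' @export
as_call_matrix <- function(x) {
  m <- as.matrix(x[marker_ids(x)])
  storage.mode(m) <- "integer"
  rownames(m) <- x[["accession_id"]]
  m
}

#' Read a dominant marker matrix from delimited text
#'
#' Expects a header row of marker ids and a first column of accession ids.
#' The token dialect is configurable because scoring pipelines differ in how
#' they encode absence and missingness; gzip-compressed files are accepted.
#'
#' @param path File path (plain or `.gz`).
#' @param present,absent Tokens coding band presence/absence.
#' @param missing Character vector of tokens treated as missing.
#' @param delim Field delimiter; guessed from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, present = "1", absent = "0",
                               missing = c("", "NA", "-"), delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE, progress = FALSE)
  names(raw)[1L] <- "accession_id"
  mk <- setdiff(names(raw), "accession_id")
  decode <- function(v, marker) {
    out <- rep(NA_integer_, length(v))
    out[v %in% present] <- 1L
    out[v %in% absent] <- 0L
    bad <- !(v %in% c(present, absent, missing)) & !is.na(v)
    if (any(bad)) {
      abort(sprintf("Non-binary token '%s' at accession '%s', marker '%s'.",
                    v[which(bad)[1L]], raw$accession_id[which(bad)[1L]], marker))
    }
    out
  }
  for (m in mk) raw[[m]] <- decode(raw[[m]], m)
  marker_matrix(raw)
}

#' Write a marker matrix as delimited text
#'
#' Inverse of [read_marker_matrix()] under the default dialect: present is
#' `1`, absent `0`, missing `NA`.
#'
#' @param x A [marker_matrix()].
#' @param path Output path; `.csv` gives comma-delimited output, otherwise
#'   tab-delimited.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(x, path) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::write_delim(x, path, delim = delim, na = "NA")
  invisible(path)
}

#' Screen markers for batch coverage and redundancy
#'
#' Mirrors the two-stage screening used for multi-batch dominant marker
#' data: first retain only markers that reported (at least one non-missing
#' call) within every genotyping batch of accessions, then remove redundant
#' markers.  Redundancy is either collapsed over identical call vectors
#' (keeping the lexicographically first marker id of each identical set) or
#' imposed through an explicit keep-list when external information about
#' marker redundancy is available.
#'
#' @param x A [marker_matrix()].
#' @param batches Optional named character vector or tibble
#'   (`accession_id`, `batch`) assigning accessions to genotyping batches;
#'   `NULL` treats the whole collection as one batch.
#' @param redundancy `"identical_scores"` (default) or `"provided_list"`.
#' @param keep Character vector of marker ids to retain when
#'   `redundancy = "provided_list"`.
#' @return A screened `marker_matrix`; the per-stage marker counts are
#'   attached as attribute `"screening_report"` (a tibble with columns
#'   `stage`, `markers_in`, `markers_out`) and retrievable with
#'   [screening_report()].
#' @export
screen_markers <- function(x, batches = NULL,
                           redundancy = c("identical_scores", "provided_list"),
                           keep = NULL) {
  redundancy <- match.arg(redundancy)
  calls <- as_call_matrix(x)
  report <- list()

  if (is.data.frame(batches)) {
    batches <- setNames(as.character(batches$batch), batches$accession_id)
  }
  n_in <- ncol(calls)
  if (!is.null(batches)) {
    b <- batches[rownames(calls)]
    if (anyNA(b)) abort("Every accession needs a batch label.")
    ok <- Reduce(`&`, lapply(split(seq_len(nrow(calls)), b), function(idx) {
      colSums(!is.na(calls[idx, , drop = FALSE])) > 0L
    }))
  } else {
    ok <- colSums(!is.na(calls)) > 0L
  }
  calls <- calls[, ok, drop = FALSE]
  report$batch <- tibble(stage = "batch_coverage", markers_in = n_in,
                         markers_out = ncol(calls))

  n_in <- ncol(calls)
  if (redundancy == "identical_scores") {
    ord <- order(colnames(calls))
    key <- apply(calls[, ord, drop = FALSE], 2L, function(v) {
      paste(ifelse(is.na(v), "N", v), collapse = "")
    })
    keep_ids <- colnames(calls)[ord][!duplicated(key)]
  } else {
    if (is.null(keep)) abort("`keep` list required for redundancy = 'provided_list'.")
    keep_ids <- intersect(colnames(calls), keep)
  }
  calls <- calls[, colnames(calls) %in% keep_ids, drop = FALSE]
  report$red <- tibble(stage = paste0("redundancy_", redundancy),
                       markers_in = n_in, markers_out = ncol(calls))

  if (ncol(calls) == 0L) abort("No markers survive screening.")
  out <- marker_matrix(calls)
  attr(out, "screening_report") <- bind_rows(report)
  out
}

#' @rdname screen_markers
#' @export
screening_report <- function(x) {
  attr(x, "screening_report") %||%
    tibble(stage = character(), markers_in = integer(), markers_out = integer())
}
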