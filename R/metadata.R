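#' Construct and validate an accession metadata table
#'
#' Metadata carries the documentary record against which genetic inferences
#' are compared: provenance, documented parents, known ploidy and clonal
#' group membership.  Dates are kept as free text because historic records
#' are frequently of the form `"pre 1750"`; [parse_origin_year()] extracts
#' the year and a `pre` flag for timeline checks.
#'
#' @param df Data frame with at least `accession_id`.  Recognised columns:
#'   `cultivar_name`, `country` (ISO 3166 alpha-2 or empty),
#'   `date_of_origin` (free text), `ploidy` (2, 3, 4 or `NA` for unknown),
#'   `parent1`, `parent2` (documented parents), `clone_group`,
#'   `subset_flag` (logical, member of the non-clonal subset).  Missing
#'   columns are added empty.
#' @return An `accession_meta` tibble.
#' @export
accession_meta <- function(df) {
  df <- as_tibble(df)
  if (!"accession_id" %in% names(df)) abort("`accession_id` column required.")
  defaults <- list(cultivar_name = NA_character_, country = NA_character_,
                   date_of_origin = NA_character_, ploidy = NA_integer_,
                   parent1 = NA_character_, parent2 = NA_character_,
                   clone_group = NA_character_, subset_flag = NA)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df <- mutate(df,
    accession_id = as.character(.data$accession_id),
    ploidy = as.integer(.data$ploidy),
    subset_flag = as.logical(.data$subset_flag)
  )
  if (anyDuplicated(df$accession_id)) abort("Duplicate accession ids in metadata.")
  if (any(!is.na(df$ploidy) & !df$ploidy %in% 2:4)) {
    abort("`ploidy` must be 2, 3, 4 or NA (unknown).")
  }
  self_parent <- !is.na(df$parent1) & df$parent1 == df$accession_id |
    !is.na(df$parent2) & df$parent2 == df$accession_id
  if (any(self_parent)) {
    abort(paste0("Accession listed as its own parent: ",
                 paste(df$accession_id[self_parent], collapse = ", ")))
  }
  class(df) <- c("accession_meta", class(tibble()))
  df
}

#' @rdname accession_meta
#' @param path Delimited file (`.csv` comma, otherwise tab; `.gz` accepted).
#' @export
read_accession_meta <- function(path) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  accession_meta(readr::read_delim(path, delim = delim, show_col_types = FALSE,
                                   progress = FALSE,
                                   col_types = readr::cols(.default = "c")))
}

#' @rdname accession_meta
#' @param x An `accession_meta` tibble (for writing).
#' @export
write_accession_meta <- function(x, path) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

#' Extract the year (and a "pre" qualifier) from a free-text origin date
#'
#' @param date Character vector such as `"1897"`, `"pre 1750"`, `"c.1820"`.
#' @return Tibble with columns `year` (integer, `NA` when no 3--4 digit year
#'   is present) and `pre` (logical: the record is an upper bound, the
#'   cultivar may be older).
#' @examples
#' parse_origin_year(c("pre 1750", "1897", ""))
#' @export
parse_origin_year <- function(date) {
  date <- as.character(date)
  has <- !is.na(date) & grepl("\\d{3,4}", date)
  yr <- rep(NA_integer_, length(date))
  yr[has] <- as.integer(sub(".*?(\\d{3,4}).*", "\\1", date[has]))
  tibble(year = yr, pre = !is.na(date) & grepl("pre", date, ignore.case = TRUE))
}
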