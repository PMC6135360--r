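#' SSR genotype tables
#'
#' SSR (microsatellite) profiles are stored long: one row per accession and
#' locus, with the observed allele sizes (bp) in a list-column `alleles`.
#' Capillary electrophoresis reports distinct fragment sizes without
#' dosage, so a single reported size means "at least one copy, possibly
#' homozygous" -- copy number is never inferred at read time; downstream
#' parentage rules resolve the ambiguity explicitly.
#'
#' @param df Data frame with columns `accession_id`, `locus` and either a
#'   list-column `alleles` of integer vectors or allele size columns
#'   `allele1`...`allele4` (blank/`NA` = missing).
#' @param ploidy Optional named integer vector (`accession_id` -> ploidy)
#'   used to flag records whose allele count exceeds the known ploidy; such
#'   records are kept but marked `truncated = TRUE` and a warning is
#'   raised.
#' @return An `ssr_profiles` tibble with columns `accession_id`, `locus`,
#'   `alleles` (sorted integer vector per row; `integer(0)` = missing) and
#'   `truncated`.
#' @export
ssr_profiles <- function(df, ploidy = NULL) {
  df <- as_tibble(df)
  if (!all(c("accession_id", "locus") %in% names(df))) {
    abort("`accession_id` and `locus` columns required.")
  }
  if (!"alleles" %in% names(df)) {
    acols <- grep("^allele[0-9]+$", names(df), value = TRUE)
    if (length(acols) == 0L) abort("No `alleles` list-column or allele1..allele4 columns.")
    sizes <- suppressWarnings(
      lapply(seq_len(nrow(df)), function(i) {
        v <- as.integer(unlist(df[i, acols], use.names = FALSE))
        sort(v[!is.na(v)])
      })
    )
    df <- df[setdiff(names(df), acols)]
    df$alleles <- sizes
  } else {
    df$alleles <- lapply(df$alleles, function(v) sort(as.integer(v[!is.na(v)])))
  }
  df <- mutate(df, accession_id = as.character(.data$accession_id),
               locus = as.character(.data$locus))
  if (anyDuplicated(df[c("accession_id", "locus")])) {
    abort("Duplicate (accession_id, locus) rows in SSR table.")
  }
  if (any(unlist(df$alleles) <= 0L)) abort("Allele sizes must be positive integers.")
  df$truncated <- FALSE
  if (!is.null(ploidy)) {
    pl <- ploidy[df$accession_id]
    over <- !is.na(pl) & lengths(df$alleles) > pl
    if (any(over)) {
      df$truncated[over] <- TRUE
      warn(sprintf("%d SSR record(s) carry more alleles than the known ploidy; flagged `truncated`.",
                   sum(over)))
    }
  }
  out <- select(df, "accession_id", "locus", "alleles", "truncated")
  class(out) <- c("ssr_profiles", class(tibble()))
  out
}

#' Read / write SSR genotype tables
#'
#' Delimited text with columns `accession_id`, `locus`, `allele1` ...
#' `allele4` (up to four sizes per locus; blanks are missing).  Gzip input
#' is accepted.
#'
#' @param path File path.
#' @param ploidy Passed to [ssr_profiles()].
#' @return An `ssr_profiles` tibble.
#' @export
read_ssr_table <- function(path, ploidy = NULL) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  ssr_profiles(raw, ploidy = ploidy)
}

#' @rdname read_ssr_table
#' @param x An `ssr_profiles` tibble.
#' @export
write_ssr_table <- function(x, path) {
  kmax <- max(4L, max(lengths(x$alleles)))
  wide <- tibble(accession_id = x$accession_id, locus = x$locus)
  for (k in seq_len(kmax)) {
    wide[[paste0("allele", k)]] <- map_int(x$alleles, function(v) {
      if (length(v) >= k) v[k] else NA_integer_
    })
  }
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::write_delim(wide, path, delim = delim, na = "")
  invisible(path)
}

#' Extract one accession's SSR profile as a named list
#'
#' @param ssr An `ssr_profiles` tibble.
#' @param accession_id Accession to extract.
#' @return Named list `locus -> integer vector` of distinct observed allele
#'   sizes (empty vector = locus not scored).
#' @export
ssr_profile <- function(ssr, accession_id) {
  rows <- ssr[ssr$accession_id == accession_id, ]
  setNames(rows$alleles, rows$locus)
}

#' Count SSR loci at which two accessions differ
#'
#' Two profiles differ at a locus when both are scored and their distinct
#' allele-size sets are unequal.  Used to distinguish true clones from
#' accessions that are indistinguishable by dominant markers but carry
#' different SSR genotypes (collecting-error suspects).
#'
#' @inheritParams ssr_profile
#' @param id_a,id_b Accessions to compare.
#' @return Integer count of differing, co-scored loci.
#' @export
ssr_allele_differences <- function(ssr, id_a, id_b) {
  a <- ssr_profile(ssr, id_a)
  b <- ssr_profile(ssr, id_b)
  shared <- intersect(names(a), names(b))
  shared <- shared[lengths(a[shared]) > 0 & lengths(b[shared]) > 0]
  sum(map_lgl(shared, function(l) !identical(unique(a[[l]]), unique(b[[l]]))))
}
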