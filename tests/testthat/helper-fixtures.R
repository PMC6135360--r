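# Small in-code fixtures and independent oracles shared across tests.

toy_marker_matrix <- function() {
  marker_matrix(matrix(
    c(1L, 0L, 1L, 1L,
      1L, 1L, 0L, 1L,
      0L, NA, 1L, 0L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A1", "A2", "A3"), c("m1", "m2", "m3", "m4"))
  ))
}

# brute-force per-pair Jaccard: the independent oracle for pairwise_jaccard
oracle_jaccard_matrix <- function(mm) {
  calls <- as_call_matrix(mm)
  n <- nrow(calls)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      x <- calls[i, ]
      y <- calls[j, ]
      obs <- !is.na(x) & !is.na(y)
      a <- b <- cc <- 0
      for (k in which(obs)) {
        if (x[k] == 1 && y[k] == 1) a <- a + 1
        else if (x[k] == 1 && y[k] == 0) b <- b + 1
        else if (x[k] == 0 && y[k] == 1) cc <- cc + 1
      }
      S[i, j] <- if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
    }
  }
  S
}

random_marker_fixture <- function(n_acc = 20, n_marker = 50, missing = 0.05) {
  m <- matrix(rbinom(n_acc * n_marker, 1, runif(n_marker, 0.1, 0.9)),
              nrow = n_acc, byrow = TRUE)
  m[runif(length(m)) < missing] <- NA
  # guarantee one observed call per accession
  for (i in seq_len(n_acc)) if (all(is.na(m[i, ]))) m[i, 1] <- 1L
  dimnames(m) <- list(sprintf("A%03d", seq_len(n_acc)),
                      sprintf("m%03d", seq_len(n_marker)))
  marker_matrix(m)
}

# closed-form expected Jaccard between dominant-rendered full siblings,
# derived from per-locus presence-allele frequencies under random mating
expected_fullsib_jaccard <- function(p) {
  q <- 1 - (1 - p)^2                      # dominant band frequency
  both <- 1 - 2 * (1 - p)^2 + ((1 - p) * (1 - 0.5 * p))^2
  sum(both) / sum(2 * q - both)
}

toy_ssr <- function(rows) {
  # rows: list of list(accession_id, locus, alleles)
  ssr_profiles(tibble::tibble(
    accession_id = vapply(rows, `[[`, "", 1),
    locus = vapply(rows, `[[`, "", 2),
    alleles = lapply(rows, `[[`, 3)
  ))
}
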