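#' Estimate the read-composition distributions from filtered hits
#'
#' For each reference m, the probability that a read drawn from m has the
#' distinct sequence k is approximated by the ratio of high-quality hit
#' counts:
#'
#'   phi[k, m] = (# occurrences of distinct read k hitting m) /
#'               (# occurrences hitting m)
#'
#' Both counts use occurrence (not distinct-sequence) multiplicity, and each
#' (occurrence, reference) pair counts once however many alignment lines it
#' produced. Columns of references with no hits are all zero; every other
#' column sums to one.
#'
#' @param read_table A `read_table`.
#' @param hits High-quality hits (pass through [filter_high_quality()] first).
#' @param refset The `ref_set`, which supplies the column order and the
#'   reference lengths used later for length-corrected abundances.
#' @return A `phi_matrix`: sparse K x M matrix plus species ids and lengths.
#' @export
estimate_phi <- function(read_table, hits, refset) {
  stopifnot(inherits(read_table, "read_table"), inherits(refset, "ref_set"))
  m_of <- match(hits$reference_id, refset$species_id)
  if (anyNA(m_of)) {
    abort(sprintf("hit on unknown reference '%s'.",
                  hits$reference_id[which(is.na(m_of))[1L]]))
  }
  k_of <- match(hits$occurrence_id, read_table$occurrences$occurrence_id)
  if (anyNA(k_of)) {
    abort(sprintf("hit for unknown read occurrence '%s'.",
                  hits$occurrence_id[which(is.na(k_of))[1L]]))
  }

  K <- read_table$n_distinct
  M <- nrow(refset)

  # set semantics per (occurrence, reference): count each pair once
  pairs <- dplyr::distinct(tibble::tibble(
    occurrence = hits$occurrence_id,
    m = m_of
  ))
  pairs$k <- read_table$occurrences$k[
    match(pairs$occurrence, read_table$occurrences$occurrence_id)]

  denom <- dplyr::count(pairs, .data$m, name = "n_ref")
  numer <- dplyr::count(pairs, .data$k, .data$m, name = "n_km") |>
    dplyr::left_join(denom, by = "m") |>
    dplyr::mutate(phi = .data$n_km / .data$n_ref)

  phi <- Matrix::sparseMatrix(i = numer$k, j = numer$m, x = numer$phi,
                              dims = c(K, M),
                              dimnames = list(NULL, refset$species_id))
  structure(
    list(phi = phi,
         species_id = refset$species_id,
         lengths = setNames(refset$length, refset$species_id),
         n_distinct = K, n_species = M),
    class = "phi_matrix"
  )
}

# per-distinct-read candidate references (column indices with phi > 0),
# in CSR layout for the sampler
phi_candidates <- function(phi_matrix) {
  m <- as(Matrix::t(phi_matrix$phi), "CsparseMatrix") # transpose: rows = k
  list(ptr = m@p, ref = m@i, phi = m@x)               # 0-based
}

#' @export
print.phi_matrix <- function(x, ...) {
  nz <- Matrix::nnzero(x$phi)
  cat(sprintf("<phi_matrix> %d distinct reads x %d references (%d nonzero)\n",
              x$n_distinct, x$n_species, nz))
  invisible(x)
}

#' Tidy the sparse read-composition matrix
#'
#' @param x A `phi_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero entry: `k` (distinct-read
#'   index), `species_id`, `phi`. This is also the debug TSV layout written
#'   by [write_phi_tsv()].
#' @export
tidy.phi_matrix <- function(x, ...) {
  s <- Matrix::summary(x$phi)
  tibble::tibble(k = as.integer(s$i),
                 species_id = x$species_id[s$j],
                 phi = s$x) |>
    dplyr::arrange(.data$k, match(.data$species_id, x$species_id))
}

#' Dump a phi matrix to TSV (one row per nonzero entry)
#' @param phi_matrix A `phi_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phi_tsv <- function(phi_matrix, path) {
  tb <- tidy.phi_matrix(phi_matrix)
  writeLines(c("distinct_read_index\treference_id\tphi",
               sprintf("%d\t%s\t%.15g", tb$k, tb$species_id, tb$phi)),
             path)
  invisible(path)
}
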