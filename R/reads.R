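#' Collapse read occurrences to distinct sequences
#'
#' The mixture model distinguishes the N read occurrences from the K distinct
#' read sequences: the read-composition probabilities are indexed by distinct
#' sequence, while every occurrence carries its own hidden origin label. This
#' constructor performs the collapse by exact string identity.
#'
#' @param reads One of: a data frame with columns `read_id` and `sequence`; a
#'   character vector of sequences (names used as ids when present); or a
#'   path to a FASTA/FASTQ file (`.fastq`/`.fq`, optionally gzipped, is read
#'   as FASTQ).
#' @return A `read_table` with elements `distinct` (tibble `k`, `sequence`,
#'   `multiplicity`), `occurrences` (tibble `occurrence_id`, `k`), and counts
#'   `n_occurrences` (N) and `n_distinct` (K).
#' @examples
#' rt <- build_read_table(c(r1 = "AAA", r2 = "AAA", r3 = "CCC"))
#' rt$n_distinct # 2
#' @export
build_read_table <- function(reads) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0L) abort("no reads: the read set is empty.")
  if (anyDuplicated(reads$read_id)) {
    abort(sprintf("duplicate read id: '%s'.",
                  reads$read_id[duplicated(reads$read_id)][1L]))
  }
  k_of <- match(reads$sequence, unique(reads$sequence))
  distinct <- tibble::tibble(
    k = seq_along(unique(reads$sequence)),
    sequence = unique(reads$sequence)
  )
  distinct$multiplicity <- tabulate(k_of, nbins = nrow(distinct))
  structure(
    list(
      distinct = distinct,
      occurrences = tibble::tibble(occurrence_id = reads$read_id, k = k_of),
      n_occurrences = nrow(reads),
      n_distinct = nrow(distinct)
    ),
    class = "read_table"
  )
}

as_read_tbl <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads)) "fastq" else "fasta"
    seqs <- Biostrings::readDNAStringSet(reads, format = fmt)
    ids <- sub("\\s.*$", "", names(seqs))
    return(tibble::tibble(read_id = ids,
                          sequence = toupper(unname(as.character(seqs)))))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
    return(tibble::tibble(read_id = ids, sequence = toupper(unname(reads))))
  }
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads))) {
      abort("a read data frame needs columns `read_id` and `sequence`.")
    }
    return(tibble::tibble(read_id = as.character(reads$read_id),
                          sequence = toupper(reads$sequence)))
  }
  abort("`reads` must be a data frame, a character vector, or a file path.")
}

#' @export
print.read_table <- function(x, ...) {
  cat(sprintf("<read_table> %d occurrences collapsed to %d distinct sequences\n",
              x$n_occurrences, x$n_distinct))
  print(head(x$distinct, 5L))
  invisible(x)
}
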