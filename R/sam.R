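#' Parse SAM alignments against a reference set
#'
#' Reads every mapped alignment record (primary, secondary and supplementary
#' alike) into a hit table; quality filtering is a separate, explicit step
#' ([filter_high_quality()]). The edit distance is taken from the `NM` tag
#' when present, otherwise reconstructed from the `MD` tag plus CIGAR indels.
#'
#' @param path A SAM (or BAM) file whose reference names are a subset of
#'   `refset$species_id`.
#' @param refset A `ref_set`.
#' @return A tibble of hits with columns `occurrence_id`, `reference_id`,
#'   `edit_distance` and `alignment_length` (aligned query bases from the
#'   CIGAR; the read length when the CIGAR is absent).
#' @export
parse_sam <- function(path, refset) {
  stopifnot(inherits(refset, "ref_set"))
  if (!file.exists(path)) abort(sprintf("SAM file not found: '%s'.", path))

  bam <- if (grepl("\\.bam$", path)) {
    path
  } else {
    tryCatch(
      Rsamtools::asBam(path, destination = tempfile(), indexDestination = FALSE),
      error = function(e) abort(sprintf("failed to parse SAM '%s': %s",
                                        path, conditionMessage(e)))
    )
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  unknown <- setdiff(names(targets), refset$species_id)
  if (length(unknown) > 0L) {
    abort(sprintf("SAM reference name(s) not in the reference set: %s",
                  paste(sprintf("'%s'", unknown), collapse = ", ")))
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar", "seq"),
    tag = c("NM", "MD")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  mapped <- bitwAnd(rec$flag, 4L) == 0L
  if (!any(mapped)) {
    return(tibble::tibble(occurrence_id = character(), reference_id = character(),
                          edit_distance = integer(), alignment_length = integer()))
  }

  qname <- rec$qname[mapped]
  rname <- as.character(rec$rname[mapped])
  cigar <- rec$cigar[mapped]
  # a tag absent from every record comes back NULL rather than NA
  nm <- (rec$tag$NM %||% rep(NA_integer_, length(rec$flag)))[mapped]
  md <- (rec$tag$MD %||% rep(NA_character_, length(rec$flag)))[mapped]
  qlen <- Biostrings::width(rec$seq)[mapped]

  alen <- cigar_query_length(cigar)
  alen[is.na(alen)] <- qlen[is.na(alen)]
  if (anyNA(alen) || any(alen < 1L)) {
    abort("alignment with undeterminable aligned length (no CIGAR and no SEQ).")
  }

  need_md <- is.na(nm)
  if (any(need_md)) {
    if (anyNA(md[need_md])) {
      abort("alignment without NM or MD tag: cannot determine the edit distance.")
    }
    nm[need_md] <- md_edit_distance(md[need_md]) + cigar_indel_bases(cigar[need_md])
  }

  tibble::tibble(
    occurrence_id = qname,
    reference_id = rname,
    edit_distance = as.integer(nm),
    alignment_length = as.integer(alen)
  )
}

# aligned query bases: sum of M/=/X/I operation lengths; NA for '*'
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    keep <- grepl("[MI=X]$", ops)
    sum(as.integer(sub("[A-Z=]$", "", ops[keep])))
  }, integer(1L), USE.NAMES = FALSE)
}

# inserted + deleted bases from CIGAR (the indel part of an NM-style distance)
cigar_indel_bases <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    keep <- grepl("[ID]$", ops)
    sum(as.integer(sub("[A-Z]$", "", ops[keep])))
  }, integer(1L), USE.NAMES = FALSE)
}

# substitutions encoded in an MD tag (single reference letters outside
# ^-prefixed deletion runs)
md_edit_distance <- function(md) {
  vapply(md, function(m) {
    toks <- regmatches(m, gregexpr("\\^[A-Z]+|[A-Z]|[0-9]+", m))[[1L]]
    sum(grepl("^[A-Z]$", toks))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Keep only high-quality hits
#'
#' A hit is high quality when its edit-distance rate, `edit_distance /
#' alignment_length`, does not exceed `max_error_rate`. This is the "high
#' quality" filter feeding the read-composition estimate; MAPQ is not used
#' because multi-mapping output (required here) makes it uninformative.
#'
#' @param hits Hit tibble from [parse_sam()] or [simulate_alignment()].
#' @param max_error_rate Maximum tolerated edit-distance rate, in `[0, 1]`
#'   (default 0.10).
#' @return The retained rows of `hits`.
#' @export
filter_high_quality <- function(hits, max_error_rate = 0.1) {
  if (!is.numeric(max_error_rate) || max_error_rate < 0 || max_error_rate > 1) {
    abort("`max_error_rate` must be in [0, 1].")
  }
  dplyr::filter(hits, .data$edit_distance / .data$alignment_length <= max_error_rate)
}

#' Write hits as a SAM file
#'
#' Emits a valid SAM with `@SQ` headers and `NM` tags. Per read, the hit with
#' the smallest edit distance is written as the primary record and the rest
#' as secondary (flag 0x100); reads without hits get an unmapped record.
#'
#' @param hits Hit tibble with columns `occurrence_id`, `reference_id`,
#'   `edit_distance`, `pos` (0-based) and `is_reverse`.
#' @param reads Data frame with `read_id` and `sequence` for every read.
#' @param refset The `ref_set` the hits refer to.
#' @param path Output path.
#' @param include_unmapped Write flag-4 records for hitless reads (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reads, refset, path, include_unmapped = TRUE) {
  stopifnot(inherits(refset, "ref_set"))
  reads <- as_read_tbl(reads)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", refset$species_id, refset$length))

  hits <- dplyr::mutate(hits,
                        .ref_rank = match(.data$reference_id, refset$species_id))
  if (anyNA(hits$.ref_rank)) {
    abort("hit references a species_id absent from `refset`.")
  }
  hits <- dplyr::arrange(hits, match(.data$occurrence_id, reads$read_id),
                         .data$edit_distance, .data$.ref_rank) |>
    dplyr::group_by(.data$occurrence_id) |>
    dplyr::mutate(.primary = dplyr::row_number() == 1L) |>
    dplyr::ungroup()

  seq_of <- setNames(reads$sequence, reads$read_id)
  seq_out <- ifelse(hits$.primary,
                    ifelse(hits$is_reverse,
                           revcomp(seq_of[hits$occurrence_id]),
                           seq_of[hits$occurrence_id]),
                    "*")
  flags <- ifelse(hits$.primary, 0L, 256L) + ifelse(hits$is_reverse, 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   hits$occurrence_id, flags, hits$reference_id,
                   hits$pos + 1L, nchar(seq_of[hits$occurrence_id]),
                   seq_out, hits$edit_distance)

  body <- lines
  if (include_unmapped) {
    unhit <- setdiff(reads$read_id, hits$occurrence_id)
    if (length(unhit) > 0L) {
      body <- c(body, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                              unhit, seq_of[unhit]))
    }
  }
  # keep read order stable for byte-identical reruns
  writeLines(c(header, body), path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
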