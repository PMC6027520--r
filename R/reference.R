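#' Build a concatenated core-genome reference set
#'
#' Concatenates each species' core genes, in the order given, into a single
#' reference sequence. The per-species base length and the 0-based offset of
#' each gene within the concatenation are recorded; abundance estimates are
#' length-corrected with these lengths downstream.
#'
#' @param gene_sets A data frame with one row per gene, columns `species_id`
#'   and `sequence` (gene order within a species is row order), or a named
#'   list of character vectors of gene sequences (names are species ids).
#' @param spacer Number of `N` characters inserted between consecutive genes
#'   (default 0, i.e. direct concatenation). A nonzero spacer suppresses
#'   alignments spanning gene junctions; spacer bases count towards the
#'   reference length.
#'
#' @return A `ref_set`: a tibble with columns `species_id`, `sequence`,
#'   `length` (bases, including any `N` and spacer characters) and `offsets`
#'   (list column of 0-based gene start positions).
#'
#' @examples
#' genes <- tibble::tibble(
#'   species_id = c("sp1", "sp1", "sp2"),
#'   sequence = c("ACGT", "GGCC", "TTAATTAA")
#' )
#' build_reference(genes)
#' @export
build_reference <- function(gene_sets, spacer = 0L) {
  gene_sets <- as_gene_tbl(gene_sets)
  if (nrow(gene_sets) == 0L) {
    abort("`gene_sets` is empty: at least one species with one gene is required.")
  }
  stopifnot(spacer >= 0L)

  gene_sets$sequence <- toupper(gene_sets$sequence)
  bad_len <- nchar(gene_sets$sequence) < 1L
  if (any(bad_len)) {
    abort(sprintf("species '%s' has an empty gene sequence.",
                  gene_sets$species_id[which(bad_len)[1L]]))
  }
  bad_chr <- grepl("[^ACGTN]", gene_sets$sequence)
  if (any(bad_chr)) {
    abort(sprintf(
      "species '%s' has a gene with characters outside the A/C/G/T/N alphabet.",
      gene_sets$species_id[which(bad_chr)[1L]]))
  }
  if (any(gene_sets$species_id == "" | is.na(gene_sets$species_id))) {
    abort("every gene needs a non-empty `species_id`.")
  }
  # a species' genes must form one contiguous block; a second block is a
  # duplicate species entry
  runs <- rle(gene_sets$species_id)$values
  if (anyDuplicated(runs)) {
    abort(sprintf("duplicate species_id: '%s'.", runs[duplicated(runs)][1L]))
  }

  sep <- strrep("N", spacer)
  # preserve first-appearance order of species
  ids <- unique(gene_sets$species_id)
  out <- dplyr::group_by(gene_sets, species_id = factor(.data$species_id, levels = ids)) |>
    dplyr::summarise(
      offsets = list(as.integer(
        cumsum(c(0L, head(nchar(.data$sequence), -1L) + spacer)))),
      sequence = paste(.data$sequence, collapse = sep),
      .groups = "drop"
    ) |>
    dplyr::mutate(species_id = as.character(.data$species_id),
                  length = nchar(.data$sequence)) |>
    dplyr::select("species_id", "sequence", "length", "offsets")

  new_ref_set(out)
}

new_ref_set <- function(tbl) {
  structure(tbl, class = c("ref_set", class(tibble::tibble())))
}

as_gene_tbl <- function(gene_sets) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    if (length(gene_sets) == 0L) {
      abort("`gene_sets` is empty: at least one species with one gene is required.")
    }
    if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
      abort("a list of gene sets must be named by species id.")
    }
    if (anyDuplicated(names(gene_sets))) {
      abort(sprintf("duplicate species_id: '%s'.",
                    names(gene_sets)[duplicated(names(gene_sets))][1L]))
    }
    empty <- lengths(gene_sets) == 0L
    if (any(empty)) {
      abort(sprintf("species '%s' has an empty gene list.",
                    names(gene_sets)[empty][1L]))
    }
    gene_sets <- tibble::tibble(
      species_id = rep(names(gene_sets), lengths(gene_sets)),
      sequence = unlist(gene_sets, use.names = FALSE)
    )
  }
  if (!is.data.frame(gene_sets) ||
      !all(c("species_id", "sequence") %in% names(gene_sets))) {
    abort("`gene_sets` must be a data frame with columns `species_id` and `sequence`.")
  }
  tibble::as_tibble(gene_sets[, c("species_id", "sequence")])
}

#' Write a reference set as multi-FASTA (one record per species)
#'
#' @param refset A `ref_set` from [build_reference()] or [load_reference()].
#' @param path Output FASTA path.
#' @param lengths_path Optional path for a two-column TSV
#'   (`species_id`, `length`).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refset, path, lengths_path = NULL) {
  stopifnot(inherits(refset, "ref_set"))
  seqs <- Biostrings::DNAStringSet(setNames(refset$sequence, refset$species_id))
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(lengths_path)) {
    writeLines(c("species_id\tlength",
                 sprintf("%s\t%d", refset$species_id, refset$length)),
               lengths_path)
  }
  invisible(path)
}

#' Load a reference set from multi-FASTA
#'
#' Each record is taken as one species' concatenated core-genome sequence
#' (record id = species id). Gene boundaries are not stored in FASTA, so the
#' loaded set carries a single offset `0` per species; sequences, ids and
#' lengths round-trip exactly through [write_reference_fasta()].
#'
#' @param path FASTA file with one record per species.
#' @return A `ref_set` tibble.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("reference FASTA not found: '%s'.", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("failed to parse FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (length(seqs) == 0L) abort(sprintf("FASTA '%s' contains no records.", path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate species_id in '%s': '%s'.",
                  path, ids[duplicated(ids)][1L]))
  }
  seq_chr <- unname(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", seq_chr)
  if (any(bad)) {
    abort(sprintf(
      "record '%s' in '%s' has characters outside the A/C/G/T/N alphabet.",
      ids[which(bad)[1L]], path))
  }
  if (any(nchar(seq_chr) == 0L)) {
    abort(sprintf("record '%s' in '%s' is empty.",
                  ids[which(nchar(seq_chr) == 0L)[1L]], path))
  }
  new_ref_set(tibble::tibble(
    species_id = ids,
    sequence = unname(seq_chr),
    length = nchar(seq_chr),
    offsets = lapply(seq_along(ids), function(i) 0L)
  ))
}

#' Read per-species gene sequences from FASTA
#'
#' Two layouts are supported: one multi-FASTA per species (pass a named
#' vector of paths, names = species ids), or a single multi-FASTA plus a
#' gene-to-species map.
#'
#' @param paths Named character vector of FASTA paths (one per species), or a
#'   single path when `species_map` is given.
#' @param species_map For the single-file layout: a data frame with columns
#'   `gene_id` and `species_id`, or the path of a two-column TSV.
#' @return A tibble with columns `species_id`, `gene_id`, `sequence`,
#'   suitable for [build_reference()].
#' @export
read_gene_sets <- function(paths, species_map = NULL) {
  if (is.null(species_map)) {
    if (is.null(names(paths)) || any(names(paths) == "")) {
      abort("`paths` must be named by species id when no `species_map` is given.")
    }
    purrr::map2_dfr(paths, names(paths), function(p, sp) {
      seqs <- Biostrings::readDNAStringSet(p)
      tibble::tibble(species_id = sp,
                     gene_id = sub("\\s.*$", "", names(seqs)),
                     sequence = toupper(unname(as.character(seqs))))
    })
  } else {
    if (length(paths) != 1L) abort("give a single FASTA path with `species_map`.")
    if (is.character(species_map)) {
      species_map <- read.delim(species_map, header = TRUE,
                                stringsAsFactors = FALSE)
    }
    if (!all(c("gene_id", "species_id") %in% names(species_map))) {
      abort("`species_map` needs columns `gene_id` and `species_id`.")
    }
    seqs <- Biostrings::readDNAStringSet(paths)
    genes <- tibble::tibble(gene_id = sub("\\s.*$", "", names(seqs)),
                            sequence = toupper(unname(as.character(seqs))))
    missing <- setdiff(genes$gene_id, species_map$gene_id)
    if (length(missing) > 0L) {
      abort(sprintf("gene '%s' has no species in the map.", missing[1L]))
    }
    dplyr::inner_join(genes, tibble::as_tibble(species_map), by = "gene_id") |>
      dplyr::select("species_id", "gene_id", "sequence")
  }
}
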