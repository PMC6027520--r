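#' Convert relative abundances to mixture weights
#'
#' A species' share of reads grows with both its organism abundance and its
#' reference length: `theta[i] = a[i] * l[i] / sum(a * l)`. This is the exact
#' inverse of [theta_to_abundance()].
#'
#' @param abundance Relative abundances summing to one.
#' @param lengths Reference base lengths, all > 0.
#' @return Mixture weights summing to one.
#' @examples
#' abundance_to_theta(c(0.75, 0.25), c(100, 300)) # 0.5, 0.5
#' @export
abundance_to_theta <- function(abundance, lengths) {
  if (length(abundance) != length(lengths)) {
    abort("`abundance` and `lengths` must have the same length.")
  }
  if (any(lengths <= 0)) abort("reference lengths must be > 0.")
  if (abs(sum(abundance) - 1) > 1e-6) abort("`abundance` must sum to 1.")
  w <- abundance * lengths
  w / sum(w)
}

#' Substitution error model for simulated reads
#'
#' Errors are i.i.d. per-base substitutions to a uniformly chosen different
#' base. `profile` optionally replaces the flat rate with a position-dependent
#' per-base rate vector of length `read_length` (a hook for Illumina-like
#' 3'-degrading profiles); indels are not simulated.
#'
#' @param substitution_rate Per-base substitution probability in `[0, 1)`
#'   (default 0.01).
#' @param read_length Read length in bases (default 100).
#' @param profile Optional numeric vector of per-position rates overriding
#'   `substitution_rate`.
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 0.01, read_length = 100L,
                        profile = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1, read_length >= 1L)
  if (!is.null(profile)) {
    stopifnot(length(profile) == read_length, all(profile >= 0), all(profile < 1))
  }
  structure(list(substitution_rate = substitution_rate,
                 read_length = as.integer(read_length),
                 profile = profile),
            class = "error_model")
}

#' Ground-truth community composition
#'
#' @param abundance Preset relative abundances, one per species in `refset`
#'   (sums to one; names optional).
#' @param refset A `ref_set`.
#' @return A `community_truth` with the preset abundances and the implied
#'   mixture weights `theta` (proportional to abundance times reference
#'   length).
#' @export
community_truth <- function(abundance, refset) {
  stopifnot(inherits(refset, "ref_set"))
  if (length(abundance) != nrow(refset)) {
    abort("`abundance` must have one entry per reference species.")
  }
  abundance <- abundance / sum(abundance)
  structure(list(
    abundance = setNames(as.numeric(abundance), refset$species_id),
    theta = setNames(abundance_to_theta(abundance, refset$length),
                     refset$species_id),
    lengths = setNames(refset$length, refset$species_id)
  ), class = "community_truth")
}

#' Simulate single-ended shotgun reads from a community
#'
#' For each read: draw the source species from the mixture weights, draw a
#' uniform 0-based start over `[0, l - read_length]`, copy `read_length`
#' bases (optionally reverse-complemented), and apply i.i.d. substitutions.
#' Origin labels are recorded as ground truth.
#'
#' @param refset A `ref_set`; every reference must be at least one read long.
#' @param truth A [community_truth()].
#' @param n_reads Number of reads (>= 1).
#' @param error An [error_model()].
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param reverse_complement When `TRUE`, each read is reverse-complemented
#'   with probability 0.5 (default `FALSE`: forward strand only).
#' @return A tibble with `read_id`, `sequence`, `origin_species`, `start`
#'   (0-based) and `is_reverse`.
#' @export
simulate_reads <- function(refset, truth, n_reads, error = error_model(),
                           seed = NULL, reverse_complement = FALSE) {
  stopifnot(inherits(refset, "ref_set"), inherits(truth, "community_truth"),
            n_reads >= 1L)
  L <- error$read_length
  if (any(refset$length < L)) {
    abort(sprintf("reference '%s' (%d bp) is shorter than the read length %d.",
                  refset$species_id[which(refset$length < L)[1L]],
                  min(refset$length), L))
  }
  if (!is.null(seed)) set.seed(seed)

  origin <- sample.int(nrow(refset), n_reads, replace = TRUE,
                       prob = truth$theta)
  start <- floor(runif(n_reads) * (refset$length[origin] - L + 1L))
  seqs <- substring(refset$sequence[origin], start + 1L, start + L)

  if (reverse_complement) {
    flip <- runif(n_reads) < 0.5
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  } else {
    flip <- rep(FALSE, n_reads)
  }

  rate <- if (is.null(error$profile)) {
    error$substitution_rate
  } else {
    rep(error$profile, times = n_reads)
  }
  if (is.null(error$profile) && error$substitution_rate > 0 || !is.null(error$profile)) {
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
    hit <- runif(length(chars)) < rate
    hit <- hit & chars %in% c("A", "C", "G", "T") # leave N untouched
    if (any(hit)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(chars[hit], bases) - 1L
      shift <- sample.int(3L, sum(hit), replace = TRUE) # never the same base
      chars[hit] <- bases[((cur + shift) %% 4L) + 1L]
      all_seq <- paste(chars, collapse = "")
      seqs <- substring(all_seq, seq(1L, by = L, length.out = n_reads),
                        seq(L, by = L, length.out = n_reads))
    }
  }

  tibble::tibble(
    read_id = sprintf("read_%d", seq_len(n_reads)),
    sequence = seqs,
    origin_species = refset$species_id[origin],
    start = as.integer(start),
    is_reverse = flip
  )
}

#' Align reads to references with the internal matcher
#'
#' Ungapped matcher used to run the pipeline end to end without an external
#' mapper. A hit is reported for a (read, reference) pair when some offset
#' aligns the read with mismatch rate at most `max_error_rate`; the best
#' offset per pair is kept. The default seeded k-mer route is exactly
#' equivalent to the exhaustive scan (q-gram lemma); `method = "exhaustive"`
#' forces the brute-force scan, useful as an oracle on small inputs.
#'
#' @param reads Read tibble (from [simulate_reads()]), character vector, or
#'   FASTA/FASTQ path — anything [build_read_table()] accepts.
#' @param refset A `ref_set`.
#' @param max_error_rate Maximum mismatch rate (default 0.1).
#' @param both_strands Also match the reverse complement of each read
#'   (default `TRUE`, mirroring real mappers).
#' @param method `"kmer"` (default) or `"exhaustive"`.
#' @return Hit tibble with `occurrence_id`, `reference_id`, `edit_distance`,
#'   `alignment_length`, `pos` (0-based) and `is_reverse`, compatible with
#'   [filter_high_quality()], [estimate_phi()] and [write_sam()].
#' @export
simulate_alignment <- function(reads, refset, max_error_rate = 0.1,
                               both_strands = TRUE,
                               method = c("kmer", "exhaustive")) {
  stopifnot(inherits(refset, "ref_set"))
  method <- match.arg(method)
  reads <- as_read_tbl(reads)
  fn <- if (method == "kmer") match_reads_kmer_cpp else match_reads_exhaustive_cpp
  df <- fn(reads$sequence, refset$sequence, max_error_rate, both_strands)
  tibble::tibble(
    occurrence_id = reads$read_id[df$read_index],
    reference_id = refset$species_id[df$ref_index],
    edit_distance = df$mismatches,
    alignment_length = df$read_length,
    pos = df$pos,
    is_reverse = df$is_reverse
  )
}

#' Generate a complete synthetic test community
#'
#' Builds random reference "core genomes" in which a chosen fraction of each
#' species' blocks is copied verbatim from a common pool — emulating core
#' genes shared between related clades, the source of multi-mapping reads —
#' then simulates a read set with known ground truth. Fully reproducible from
#' `seed`.
#'
#' @param n_species Number of reference species (default 10).
#' @param ref_length Approximate reference length in bases (default 50000;
#'   rounded to whole blocks).
#' @param shared_fraction Fraction of blocks copied from the shared pool, in
#'   `[0, 1)` (default 0.2).
#' @param abundance Preset relative abundances (default: Zipf-like `1/i`,
#'   normalised — an uneven community).
#' @param n_reads Number of reads to simulate (default 50000).
#' @param error An [error_model()].
#' @param block_size Gene/block size in bases (default 1000).
#' @param seed Integer seed (required: fixtures are meant to be reproducible).
#' @return A list with `refset`, `reads` (tibble incl. `origin_species`),
#'   `truth` (a `community_truth`), and the generating parameters.
#' @export
make_fixture <- function(n_species = 10L, ref_length = 50000L,
                         shared_fraction = 0.2, abundance = NULL,
                         n_reads = 50000L, error = error_model(),
                         block_size = 1000L, seed) {
  stopifnot(shared_fraction >= 0, shared_fraction < 1, n_species >= 1L)
  if (missing(seed)) abort("`seed` is required for reproducible fixtures.")
  set.seed(seed)

  if (is.null(abundance)) {
    abundance <- (1 / seq_len(n_species)) / sum(1 / seq_len(n_species))
  }
  if (length(abundance) != n_species) {
    abort("`abundance` must have length `n_species`.")
  }

  n_blocks <- max(1L, round(ref_length / block_size))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  # shared pool of block-sized segments, drawn from by every species
  n_pool <- max(n_blocks, 2L)
  pool <- vapply(seq_len(n_pool), function(i) rand_seq(block_size),
                 character(1L))

  gene_tbl <- purrr::map_dfr(seq_len(n_species), function(s) {
    n_shared <- round(shared_fraction * n_blocks)
    is_shared <- seq_len(n_blocks) %in% sample.int(n_blocks, n_shared)
    blocks <- vapply(seq_len(n_blocks), function(b) {
      if (is_shared[b]) pool[[sample.int(n_pool, 1L)]] else rand_seq(block_size)
    }, character(1L))
    tibble::tibble(species_id = sprintf("species_%02d", s), sequence = blocks)
  })

  refset <- build_reference(gene_tbl)
  truth <- community_truth(abundance, refset)
  reads <- simulate_reads(refset, truth, n_reads, error = error, seed = NULL)

  list(refset = refset, reads = reads, truth = truth, error = error,
       params = list(n_species = n_species, ref_length = ref_length,
                     shared_fraction = shared_fraction,
                     block_size = block_size, n_reads = n_reads, seed = seed))
}

#' Write simulated reads as FASTA or FASTQ
#'
#' @param reads Read tibble with `read_id` and `sequence`.
#' @param path Output path; FASTQ (constant Phred-33 quality `I`) when it
#'   ends in `.fastq`/`.fq`, FASTA otherwise.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  reads <- as_read_tbl(reads)
  if (grepl("\\.(fastq|fq)$", path)) {
    writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                               "+", strrep("I", nchar(reads$sequence)))),
               path)
  } else {
    writeLines(as.vector(rbind(paste0(">", reads$read_id), reads$sequence)),
               path)
  }
  invisible(path)
}

#' Write the per-read origin truth table
#' @param reads Read tibble from [simulate_reads()] (has `origin_species`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  writeLines(c("read_id\torigin_species",
               sprintf("%s\t%s", reads$read_id, reads$origin_species)),
             path)
  invisible(path)
}
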