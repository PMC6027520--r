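test_that("abundance-to-theta conversion and its round trip", {
  expect_equal(abundance_to_theta(c(0.75, 0.25), c(100, 300)), c(0.5, 0.5))
  expect_equal(abundance_to_theta(c(0.3, 0.7), c(10, 10)), c(0.3, 0.7))
  a <- c(0.1, 0.2, 0.3, 0.4); l <- c(5, 50, 500, 5000)
  expect_equal(abundance_to_theta(theta_to_abundance(a, l), l), a)
  expect_error(abundance_to_theta(c(0.5, 0.6), c(1, 1)), "sum to 1")
})

test_that("degenerate mixtures put every read on the lone species", {
  refs <- build_reference(list(one = strrep("ACGT", 100),
                               two = strrep("GGTA", 100)))
  truth <- community_truth(c(1, 0), refs)
  reads <- simulate_reads(refs, truth, 50, error_model(0, 50), seed = 1)
  expect_true(all(reads$origin_species == "one"))
})

test_that("error-free reads are exact substrings of their source", {
  refs <- build_reference(list(s1 = strrep("ACGTTGCA", 50),
                               s2 = strrep("GGATCCAT", 50)))
  truth <- community_truth(c(0.5, 0.5), refs)
  reads <- simulate_reads(refs, truth, 40, error_model(0, 60), seed = 2)
  src <- setNames(refs$sequence, refs$species_id)
  hit <- vapply(seq_len(nrow(reads)), function(i) {
    substring(src[[reads$origin_species[i]]],
              reads$start[i] + 1, reads$start[i] + 60) == reads$sequence[i]
  }, logical(1))
  expect_true(all(hit))
})

test_that("substitutions occur at close to the requested rate", {
  refs <- build_reference(list(s = strrep("ACGT", 2500)))
  truth <- community_truth(1, refs)
  reads <- simulate_reads(refs, truth, 2000, error_model(0.05, 100), seed = 3)
  # compare against the error-free copy of the same draw
  clean <- simulate_reads(refs, truth, 2000, error_model(0, 100), seed = 3)
  mm <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$sequence, clean$sequence))
  rate <- mm / (2000 * 100)
  # 4-sigma binomial band around 0.05
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 2e5))
})

test_that("origin fractions follow the mixture weights (binomial bound)", {
  refs <- build_reference(list(a = strrep("ACGT", 500),
                               b = strrep("TGCA", 500)))
  truth <- community_truth(c(0.5, 0.5), refs)
  reads <- simulate_reads(refs, truth, 10000, error_model(0.01, 100), seed = 4)
  f <- mean(reads$origin_species == "a")
  expect_lt(abs(f - 0.5), 0.02) # 4 binomial standard deviations
})

test_that("reads shorter than any reference are required", {
  refs <- build_reference(list(tiny = "ACGTACGT"))
  truth <- community_truth(1, refs)
  expect_error(simulate_reads(refs, truth, 5, error_model(0, 100), seed = 1),
               "shorter")
})

test_that("the matcher finds a drawn read on its source reference", {
  fx <- make_fixture(n_species = 2, ref_length = 4000, shared_fraction = 0,
                     n_reads = 50, error = error_model(0, 100), seed = 11)
  hits <- simulate_alignment(fx$reads, fx$refset, max_error_rate = 0)
  # every error-free read hits its own source
  own <- dplyr::semi_join(
    hits, tibble::tibble(occurrence_id = fx$reads$read_id,
                         reference_id = fx$reads$origin_species),
    by = c("occurrence_id", "reference_id"))
  expect_equal(nrow(own), 50L)
  # and with no shared sequence, nothing multi-maps at threshold 0
  expect_equal(nrow(hits), 50L)
})

test_that("random reads unrelated to the references find no exact hits", {
  fx <- make_fixture(n_species = 2, ref_length = 3000, shared_fraction = 0,
                     n_reads = 10, seed = 12)
  set.seed(99)
  noise <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  }, "")
  hits <- simulate_alignment(noise, fx$refset, max_error_rate = 0)
  expect_equal(nrow(hits), 0L)
})

test_that("sequence shared verbatim by two references multi-maps", {
  shared <- strrep("ACGGTTCA", 25) # 200 bp common block
  refs <- build_reference(list(
    r1 = c(strrep("TTAACCGG", 50), shared),
    r2 = c(shared, strrep("CATGCATG", 50))
  ))
  read <- substring(shared, 10, 109)
  hits <- simulate_alignment(c(q = read), refs, max_error_rate = 0)
  expect_equal(sort(hits$reference_id), c("r1", "r2"))
  expect_equal(hits$edit_distance, c(0L, 0L))
})

test_that("shared blocks in fixtures create ambiguous reads", {
  fx <- make_fixture(n_species = 4, ref_length = 4000, shared_fraction = 0.5,
                     n_reads = 400, error = error_model(0, 100), seed = 13)
  hits <- simulate_alignment(fx$reads, fx$refset, max_error_rate = 0)
  per_read <- dplyr::count(hits, occurrence_id)
  expect_gt(max(per_read$n), 1L)
})

test_that("the k-mer matcher equals the exhaustive scan", {
  fx <- make_fixture(n_species = 3, ref_length = 2500, shared_fraction = 0.3,
                     n_reads = 150, seed = 14)
  h_kmer <- simulate_alignment(fx$reads, fx$refset, max_error_rate = 0.1,
                               method = "kmer")
  h_full <- simulate_alignment(fx$reads, fx$refset, max_error_rate = 0.1,
                               method = "exhaustive")
  expect_identical(h_kmer, h_full)
})

test_that("the matcher recovers the true origin for nearly all reads", {
  fx <- make_fixture(n_species = 4, ref_length = 10000, shared_fraction = 0.2,
                     n_reads = 1000, error = error_model(0.01, 100), seed = 15)
  hits <- simulate_alignment(fx$reads, fx$refset, max_error_rate = 0.1)
  own <- dplyr::semi_join(
    hits, tibble::tibble(occurrence_id = fx$reads$read_id,
                         reference_id = fx$reads$origin_species),
    by = c("occurrence_id", "reference_id"))
  expect_gte(nrow(own) / nrow(fx$reads), 0.99)
})

test_that("fixtures are byte-identical under the same seed", {
  f1 <- make_fixture(n_species = 2, ref_length = 2000, n_reads = 20, seed = 7)
  f2 <- make_fixture(n_species = 2, ref_length = 2000, n_reads = 20, seed = 7)
  expect_identical(f1$refset, f2$refset)
  expect_identical(f1$reads, f2$reads)
  fa1 <- tempfile(); fa2 <- tempfile()
  write_reference_fasta(f1$refset, fa1)
  write_reference_fasta(f2$refset, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_error(make_fixture(n_species = 2), "seed")
})

test_that("reads round-trip through FASTA/FASTQ and the truth TSV", {
  fx <- make_fixture(n_species = 2, ref_length = 2000, n_reads = 15, seed = 8)
  fa <- tempfile(fileext = ".fasta")
  fq <- tempfile(fileext = ".fastq")
  write_reads(fx$reads, fa)
  write_reads(fx$reads, fq)
  expect_equal(build_read_table(fa)$n_occurrences, 15L)
  expect_equal(build_read_table(fq)$distinct$sequence,
               build_read_table(fa)$distinct$sequence)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(fx$reads, tsv)
  tb <- read.delim(tsv)
  expect_equal(tb$origin_species, fx$reads$origin_species)
})

test_that("reverse-complement sampling is matched on the reverse strand", {
  set.seed(31)
  refs <- build_reference(list(
    s = paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")))
  truth <- community_truth(1, refs)
  reads <- simulate_reads(refs, truth, 100, error_model(0, 80), seed = 21,
                          reverse_complement = TRUE)
  expect_true(any(reads$is_reverse) && any(!reads$is_reverse))
  hits <- simulate_alignment(reads, refs, max_error_rate = 0)
  expect_equal(nrow(hits), 100L)
  expect_equal(sort(unique(hits$is_reverse)), c(FALSE, TRUE))
})
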