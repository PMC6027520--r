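# small in-code fixtures shared across tests

tiny_refset <- function() {
  build_reference(list(
    sp1 = c("ACGTACGTACGTACGTACGT", "GGGGCCCCGGGGCCCC"),
    sp2 = c("TTTTAAAATTTTAAAATTTTAAAA")
  ))
}

# a read table + phi matrix built from explicit hits, for sampler tests
phi_from_hits <- function(sequences, hits, refset) {
  rt <- build_read_table(sequences)
  list(read_table = rt, phi = estimate_phi(rt, hits, refset))
}

# random small sampler instance: M references, N occurrences, random sparse
# candidate sets with random phi (estimated through the public hit path so
# column normalisation holds by construction)
random_instance <- function(M, N, seed) {
  set.seed(seed)
  refs <- build_reference(setNames(
    lapply(seq_len(M), function(i) paste(sample(c("A", "C", "G", "T"), 30,
                                                replace = TRUE), collapse = "")),
    sprintf("ref%d", seq_len(M))
  ))
  # a small sequence pool so duplicate read sequences occur
  pool <- replicate(max(2L, N - 2L),
                    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                          collapse = ""))
  sequences <- setNames(sample(pool, N, replace = TRUE),
                        sprintf("occ%d", seq_len(N)))
  rt <- build_read_table(sequences)
  # candidate refs drawn per distinct sequence so identical sequences share
  # candidates (as real alignments would)
  cand_of_k <- lapply(seq_len(rt$n_distinct), function(k) {
    sort(sample.int(M, sample.int(M, 1L)))
  })
  hits <- purrr::map_dfr(seq_len(nrow(rt$occurrences)), function(i) {
    k <- rt$occurrences$k[i]
    tibble::tibble(occurrence_id = rt$occurrences$occurrence_id[i],
                   reference_id = refs$species_id[cand_of_k[[k]]],
                   edit_distance = 0L, alignment_length = 8L)
  })
  list(read_table = rt, phi = estimate_phi(rt, hits, refs), refset = refs)
}

# write a SAM file from explicit lines (header derived from a refset)
write_sam_lines <- function(lines, refset, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", refset$species_id, refset$length))
  writeLines(c(header, lines), path)
  path
}
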