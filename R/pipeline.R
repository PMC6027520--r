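#' Pipeline configuration
#'
#' Bundles the file paths and parameters for [run_pipeline()]. Use
#' [read_pipeline_config()] to load the same fields from a flat
#' `key = value` text file.
#'
#' @param reference Path to the reference multi-FASTA (one record per
#'   species).
#' @param reads Path to the reads FASTA/FASTQ.
#' @param sam Path to the SAM/BAM alignments of `reads` against `reference`.
#' @param output Path of the abundance TSV to write (optional).
#' @param taxonomy Optional path of a two-column TSV (`species_id`, `taxon`)
#'   for the taxonomic roll-up, or a data frame.
#' @param max_error_rate High-quality hit threshold (default 0.1).
#' @param alpha Dirichlet hyperparameter(s) (default 1: flat prior).
#' @param burn_in_sweeps,kept_samples,thinning,seed Passed to
#'   [gibbs_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference, reads, sam, output = NULL,
                            taxonomy = NULL, max_error_rate = 0.1, alpha = 1,
                            burn_in_sweeps = 1000L, kept_samples = 1000L,
                            thinning = 1L, seed = NULL) {
  structure(list(reference = reference, reads = reads, sam = sam,
                 output = output, taxonomy = taxonomy,
                 max_error_rate = max_error_rate, alpha = alpha,
                 burn_in_sweeps = burn_in_sweeps,
                 kept_samples = kept_samples, thinning = thinning,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines look like `reference = refs.fasta`; `#` starts a comment. Keys match
#' the arguments of [pipeline_config()]; unknown keys are an error. Values
#' given as `...` override nothing — pass overrides as arguments instead.
#'
#' @param path Config file path.
#' @param ... Named overrides taking precedence over the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("config file not found: '%s'.", path))
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("malformed config line: '%s'.", lines[bad][1L]))
  vals <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  numeric_keys <- c("max_error_rate", "alpha", "burn_in_sweeps",
                    "kept_samples", "thinning", "seed")
  vals[names(vals) %in% numeric_keys] <-
    lapply(vals[names(vals) %in% numeric_keys], as.numeric)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the full estimation pipeline
#'
#' Parse alignments, filter to high-quality hits, collapse reads, estimate
#' the read-composition distributions, run collapsed Gibbs sampling, convert
#' to relative abundances, optionally roll up to taxa, and write a TSV report
#' with a run-metadata header. The run is a pure function of inputs, config
#' and seed; identical seeds give byte-identical output files.
#'
#' @param config A [pipeline_config()].
#' @return The `coremix_fit`, invisibly, with the taxon table (if any)
#'   attached as `$taxa` and the output path as `$output`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  for (p in c(config$reference, config$reads, config$sam)) {
    if (!file.exists(p)) abort(sprintf("input file not found: '%s'.", p))
  }

  refset <- stage("load_reference", load_reference(config$reference))
  message(sprintf("loaded %d reference species (%d..%d bp)",
                  nrow(refset), min(refset$length), max(refset$length)))

  read_table <- stage("build_read_table", build_read_table(config$reads))
  message(sprintf("%d read occurrences, %d distinct sequences",
                  read_table$n_occurrences, read_table$n_distinct))

  hits <- stage("parse_sam", parse_sam(config$sam, refset))
  hq <- stage("filter_high_quality",
              filter_high_quality(hits, config$max_error_rate))
  message(sprintf("%d alignments, %d pass the %.3g error-rate filter",
                  nrow(hits), nrow(hq), config$max_error_rate))

  phi <- stage("estimate_phi", estimate_phi(read_table, hq, refset))
  fit <- stage("run_gibbs", run_gibbs(
    read_table, phi, alpha = config$alpha,
    config = gibbs_config(burn_in_sweeps = config$burn_in_sweeps,
                          kept_samples = config$kept_samples,
                          thinning = config$thinning,
                          seed = config$seed)))
  message(sprintf("unassigned read fraction: %.4g", fit$unassigned_fraction))

  if (!is.null(config$taxonomy)) {
    taxonomy <- config$taxonomy
    if (is.character(taxonomy)) {
      taxonomy <- stage("taxonomy", {
        tb <- read.delim(taxonomy, header = TRUE, stringsAsFactors = FALSE)
        names(tb)[1:2] <- c("species_id", "taxon")
        tb
      })
    }
    fit$taxa <- stage("aggregate_abundance", aggregate_abundance(
      tibble::tibble(species_id = fit$species$species_id,
                     abundance = fit$species$abundance_hat),
      taxonomy))
  }

  if (!is.null(config$output)) {
    stage("write_output", write_abundance_tsv(fit, config$output))
    fit$output <- config$output
  }
  invisible(fit)
}

#' Write the abundance report TSV
#'
#' Header comment lines record the seed, the hyperparameters, the sweep
#' counts and the unassigned-read fraction; then one row per species with
#' `mean_count`, `theta_hat` and `abundance_hat`. Number formatting is fixed
#' (15 significant digits) so reruns with the same seed are byte-identical.
#'
#' @param fit A `coremix_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "coremix_fit"))
  cfg <- fit$config
  header <- c(
    sprintf("# seed=%s", if (is.null(cfg$seed)) "NA" else cfg$seed),
    sprintf("# alpha=%s", paste(format(fit$alpha, digits = 15), collapse = ",")),
    sprintf("# burn_in_sweeps=%d kept_samples=%d thinning=%d",
            cfg$burn_in_sweeps, cfg$kept_samples, cfg$thinning),
    sprintf("# n_reads=%d unassigned_fraction=%.15g",
            fit$n_total, fit$unassigned_fraction),
    "reference_id\tmean_count\ttheta_hat\tabundance_hat"
  )
  rows <- sprintf("%s\t%.15g\t%.15g\t%.15g",
                  fit$species$species_id, fit$species$mean_count,
                  fit$species$theta_hat, fit$species$abundance_hat)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Relative root-mean-square error of an abundance estimate
#'
#' `100 * sqrt(mean(((est - true) / true)^2))`, in percent. When both vectors
#' are named they are aligned by name, so the metric is invariant under a
#' common permutation.
#'
#' @param estimated Estimated relative abundances.
#' @param truth True (preset) relative abundances; strictly positive.
#' @return RRMSE in percent (scalar).
#' @examples
#' evaluate_rrmse(c(0.55, 0.45), c(0.5, 0.5)) # 10
#' @export
evaluate_rrmse <- function(estimated, truth) {
  if (is.data.frame(estimated)) estimated <- tbl_to_named(estimated)
  if (is.data.frame(truth)) truth <- tbl_to_named(truth)
  if (length(estimated) != length(truth)) {
    abort("`estimated` and `truth` must have the same length.")
  }
  if (!is.null(names(estimated)) && !is.null(names(truth))) {
    if (!setequal(names(estimated), names(truth))) {
      abort("`estimated` and `truth` name different species.")
    }
    estimated <- estimated[names(truth)]
  }
  if (any(truth <= 0)) abort("`truth` must be strictly positive everywhere.")
  100 * sqrt(mean(((estimated - truth) / truth)^2))
}

tbl_to_named <- function(tb) {
  num <- vapply(tb, is.numeric, logical(1L))
  chr <- vapply(tb, is.character, logical(1L))
  v <- tb[[which(num)[1L]]]
  if (any(chr)) names(v) <- tb[[which(chr)[1L]]]
  v
}

#' Spearman-correlation distance between abundance profiles
#'
#' `d(s, t) = 1 - SpearmanRankCorrelation(profile_s, profile_t)`; identical
#' rankings give 0, exactly reversed rankings give 2. A constant profile has
#' no defined rank correlation and is an error.
#'
#' @param profiles Samples-by-species matrix or data frame (numeric columns
#'   are the species; an optional character column supplies sample names), or
#'   a list of equal-length named vectors.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(profiles) {
  mat <- profiles_to_matrix(profiles)
  if (nrow(mat) < 2L) abort("at least two profiles are required.")
  flat <- apply(mat, 1L, function(x) length(unique(x)) == 1L)
  if (any(flat)) {
    abort(sprintf("profile '%s' is constant: Spearman correlation undefined.",
                  rownames(mat)[which(flat)[1L]]))
  }
  d <- 1 - cor(t(mat), method = "spearman")
  diag(d) <- 0
  d
}

profiles_to_matrix <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    mat <- do.call(rbind, profiles)
    if (is.null(rownames(mat))) {
      rownames(mat) <- names(profiles) %||% sprintf("sample_%d", seq_len(nrow(mat)))
    }
    return(mat)
  }
  if (is.data.frame(profiles)) {
    chr <- vapply(profiles, is.character, logical(1L))
    nm <- if (any(chr)) profiles[[which(chr)[1L]]]
    mat <- as.matrix(profiles[, !chr, drop = FALSE])
    rownames(mat) <- nm %||% sprintf("sample_%d", seq_len(nrow(mat)))
    return(mat)
  }
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- sprintf("sample_%d", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  abort("`profiles` must be a matrix, data frame, or list of vectors.")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
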