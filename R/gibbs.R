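#' Sampler configuration
#'
#' @param burn_in_sweeps Sweeps discarded before collecting samples
#'   (default 1000).
#' @param kept_samples Number of count snapshots averaged for the posterior
#'   mean (default 1000).
#' @param thinning Keep one snapshot every `thinning` sweeps (default 1).
#' @param seed Integer seed; when non-`NULL`, [run_gibbs()] seeds R's RNG so
#'   the whole run (initialisation and sweeps) is reproducible.
#' @param convergence_tolerance Optional positive tolerance. When set, the
#'   kept samples are checked post hoc: the relative change of the
#'   running-mean mixture weights over the last 100 kept sweeps must fall
#'   below it, otherwise [run_gibbs()] warns and flags the fit as
#'   unconverged. The sample count itself is never changed, so fits stay
#'   reproducible.
#' @param keep_trace Keep the per-sample count matrix in the fit (default
#'   `FALSE`; needed only for diagnostics).
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(burn_in_sweeps = 1000L, kept_samples = 1000L,
                         thinning = 1L, seed = NULL,
                         convergence_tolerance = NULL, keep_trace = FALSE) {
  stopifnot(burn_in_sweeps >= 0L, kept_samples >= 1L, thinning >= 1L,
            is.null(convergence_tolerance) || convergence_tolerance > 0)
  structure(list(burn_in_sweeps = as.integer(burn_in_sweeps),
                 kept_samples = as.integer(kept_samples),
                 thinning = as.integer(thinning),
                 seed = if (!is.null(seed)) as.integer(seed),
                 convergence_tolerance = convergence_tolerance,
                 keep_trace = isTRUE(keep_trace)),
            class = "gibbs_config")
}

#' Initialise the hidden origin labels
#'
#' Each occurrence's label is drawn uniformly at random among its candidate
#' references (the references with positive read-composition probability for
#' its distinct sequence). Occurrences without candidates must be excluded
#' before calling; encountering one is an error.
#'
#' @param read_table A `read_table`.
#' @param phi_matrix A `phi_matrix` over the same distinct reads.
#' @param seed Optional integer seed.
#' @return An `assignment_state`: list with `z` (1-based species index per
#'   occurrence) and `n` (named per-species counts).
#' @export
initialize_state <- function(read_table, phi_matrix, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cand <- phi_candidates(phi_matrix)
  k_of <- read_table$occurrences$k
  n_cand <- cand$ptr[k_of + 1L] - cand$ptr[k_of]
  if (any(n_cand == 0L)) {
    abort(sprintf(
      "occurrence '%s' has no candidate reference; exclude hitless reads before sampling.",
      read_table$occurrences$occurrence_id[which(n_cand == 0L)[1L]]))
  }
  pick <- cand$ptr[k_of] + floor(runif(length(k_of)) * n_cand) # 0-based
  z <- cand$ref[pick + 1L] + 1L
  n <- tabulate(z, nbins = phi_matrix$n_species)
  structure(list(z = z, n = setNames(n, phi_matrix$species_id),
                 occurrence_id = read_table$occurrences$occurrence_id,
                 k = k_of),
            class = "assignment_state")
}

#' Full conditional distribution of one hidden label
#'
#' The collapsed full conditional for occurrence `i` is proportional, over
#' its candidate references t, to `phi[k_i, t] * (n[t, -i] + alpha[t])`,
#' where `n[t, -i]` counts the other occurrences currently assigned to t.
#' Non-candidate references get probability zero.
#'
#' @param i Occurrence index (position in `state$z`).
#' @param state An `assignment_state` (counts include occurrence `i`; it is
#'   removed internally).
#' @param phi_matrix A `phi_matrix`.
#' @param alpha Dirichlet hyperparameters (scalar recycled to M, or length-M
#'   vector); all positive.
#' @return A named probability vector of length M.
#' @export
full_conditional <- function(i, state, phi_matrix, alpha = 1) {
  alpha <- check_alpha(alpha, phi_matrix$n_species)
  n_noti <- unname(state$n)
  n_noti[state$z[i]] <- n_noti[state$z[i]] - 1L
  phi_row <- as.numeric(phi_matrix$phi[state$k[i], ])
  w <- phi_row * (n_noti + alpha)
  if (sum(w) <= 0) abort("all candidate weights are zero for this occurrence.")
  setNames(w / sum(w), phi_matrix$species_id)
}

check_alpha <- function(alpha, M) {
  if (length(alpha) == 1L) alpha <- rep(alpha, M)
  if (length(alpha) != M) abort(sprintf("`alpha` must have length 1 or %d.", M))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) abort("all alpha must be > 0.")
  as.numeric(alpha)
}

#' Collapsed Gibbs sampling of read-origin labels
#'
#' Runs systematic-scan collapsed Gibbs sweeps over the hidden origin labels
#' (visiting occurrences in index order: decrement the label's count, draw
#' from the full conditional, increment), averages the per-species counts
#' over the kept snapshots, and converts the mean counts to mixture weights
#' (posterior mean of the Dirichlet) and to length-corrected relative
#' abundances.
#'
#' Occurrences whose distinct sequence has no candidate reference are
#' excluded and reported as the unassigned fraction; the generative model has
#' no outlier component. References with no assigned reads keep their
#' prior-driven weight; see [drop_undetected()] to zero and renormalise them
#' for reporting.
#'
#' @inheritParams full_conditional
#' @param read_table A `read_table`.
#' @param config A [gibbs_config()].
#' @return A `coremix_fit` with the species summary (mean counts, mixture
#'   weights `theta_hat`, abundances `abundance_hat`), run metadata, and
#'   optionally the kept-sample trace. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @examples
#' fx <- make_fixture(n_species = 3, ref_length = 2000, n_reads = 200, seed = 7)
#' rt <- build_read_table(fx$reads)
#' hits <- simulate_alignment(fx$reads, fx$refset)
#' phi <- estimate_phi(rt, filter_high_quality(hits), fx$refset)
#' fit <- run_gibbs(rt, phi, config = gibbs_config(100, 100, seed = 1))
#' tidy(fit)
#' @export
run_gibbs <- function(read_table, phi_matrix, alpha = 1,
                      config = gibbs_config()) {
  stopifnot(inherits(read_table, "read_table"),
            inherits(phi_matrix, "phi_matrix"))
  M <- phi_matrix$n_species
  alpha <- check_alpha(alpha, M)

  cand <- phi_candidates(phi_matrix)
  k_all <- read_table$occurrences$k
  n_cand <- cand$ptr[k_all + 1L] - cand$ptr[k_all]
  included <- n_cand > 0L
  n_total <- read_table$n_occurrences
  if (!any(included)) {
    abort("no occurrence has a candidate reference; nothing to sample.")
  }
  unassigned_fraction <- 1 - sum(included) / n_total

  sub <- read_table
  sub$occurrences <- read_table$occurrences[included, ]
  sub$n_occurrences <- sum(included)

  if (!is.null(config$seed)) set.seed(config$seed)
  state0 <- initialize_state(sub, phi_matrix, seed = NULL)

  res <- gibbs_cpp(occ_k = sub$occurrences$k - 1L,
                   cand_ptr = cand$ptr, cand_ref = cand$ref,
                   cand_phi = cand$phi, alpha = alpha, n_ref = M,
                   z0 = state0$z - 1L,
                   burn_in = config$burn_in_sweeps,
                   kept_samples = config$kept_samples,
                   thinning = config$thinning,
                   keep_trace = config$keep_trace ||
                     !is.null(config$convergence_tolerance))

  mean_counts <- setNames(res$mean_counts, phi_matrix$species_id)
  theta_hat <- estimate_theta(mean_counts, alpha)
  abundance_hat <- theta_to_abundance(theta_hat, phi_matrix$lengths)

  converged <- NA
  if (!is.null(config$convergence_tolerance)) {
    converged <- check_convergence(res$trace, alpha,
                                   config$convergence_tolerance)
    if (!converged) {
      warning("running-mean mixture weights still moving more than ",
              "`convergence_tolerance` over the last 100 kept sweeps; ",
              "consider a longer burn-in.", call. = FALSE)
    }
  }

  structure(
    list(
      species = tibble::tibble(
        species_id = phi_matrix$species_id,
        length = unname(phi_matrix$lengths),
        mean_count = unname(mean_counts),
        theta_hat = unname(theta_hat),
        abundance_hat = unname(abundance_hat)
      ),
      mean_counts = mean_counts,
      theta_hat = theta_hat,
      abundance_hat = abundance_hat,
      alpha = setNames(alpha, phi_matrix$species_id),
      config = config,
      n_occurrences = sub$n_occurrences,
      n_total = n_total,
      unassigned_fraction = unassigned_fraction,
      converged = converged,
      trace = if (config$keep_trace) res$trace
    ),
    class = "coremix_fit"
  )
}

# relative change of running-mean theta over the last 100 kept sweeps
check_convergence <- function(trace, alpha, tol) {
  n <- nrow(trace)
  if (n < 2L) return(TRUE)
  lag <- min(100L, n - 1L)
  theta_at <- function(m) {
    v <- colMeans(trace[seq_len(m), , drop = FALSE]) + alpha
    v / sum(v)
  }
  a <- theta_at(n - lag)
  b <- theta_at(n)
  max(abs(b - a) / pmax(a, .Machine$double.eps)) < tol
}

#' Posterior mean of the mixture weights
#'
#' Dirichlet-multinomial conjugacy gives the posterior of the mixture weights
#' given counts n as Dirichlet(n + alpha); its mean is
#' `theta[k] = (n[k] + alpha[k]) / sum(n + alpha)`.
#'
#' @param mean_counts Non-negative (possibly averaged) per-species counts.
#' @param alpha Dirichlet hyperparameters (scalar or per-species), all > 0.
#' @return Mixture weight vector summing to one (names kept).
#' @examples
#' estimate_theta(c(3, 1), alpha = 1) # 2/3, 1/3
#' @export
estimate_theta <- function(mean_counts, alpha = 1) {
  alpha <- check_alpha(alpha, length(mean_counts))
  if (any(mean_counts < 0)) abort("`mean_counts` must be non-negative.")
  v <- mean_counts + alpha
  v / sum(v)
}

#' Convert mixture weights to relative abundances
#'
#' A longer reference attracts proportionally more reads at equal organism
#' abundance, so the mixture weight is deflated by the reference length:
#' `a[i] = (theta[i] / l[i]) / sum(theta / l)`.
#'
#' @param theta Mixture weights summing to one.
#' @param lengths Reference base lengths, all > 0.
#' @return Relative abundance vector summing to one.
#' @examples
#' theta_to_abundance(c(0.5, 0.5), c(100, 300)) # 0.75, 0.25
#' @export
theta_to_abundance <- function(theta, lengths) {
  if (length(theta) != length(lengths)) {
    abort("`theta` and `lengths` must have the same length.")
  }
  if (any(lengths <= 0)) abort("reference lengths must be > 0.")
  w <- theta / lengths
  w / sum(w)
}

#' Exact posterior by enumeration (small-instance oracle)
#'
#' Enumerates every assignment of the hidden labels, weighting assignment z
#' by `prod_i phi[k_i, z_i] * Delta(n(z) + alpha) / Delta(alpha)` where
#' `Delta(v) = prod Gamma(v) / Gamma(sum v)` is the Dirichlet normaliser.
#' Only assignments within each occurrence's candidate set carry positive
#' weight, so the enumeration runs over the candidate product set; the
#' result is identical to enumerating all M^N assignments.
#'
#' @inheritParams run_gibbs
#' @param max_states Guard on the number of enumerated assignments
#'   (default 1e6).
#' @return List with `expected_counts` (exact posterior mean counts, named),
#'   `marginals` (N x M matrix of per-occurrence assignment posteriors) and
#'   `log_normalizer`.
#' @export
exact_posterior_oracle <- function(read_table, phi_matrix, alpha = 1,
                                   max_states = 1e6) {
  M <- phi_matrix$n_species
  alpha <- check_alpha(alpha, M)
  cand <- phi_candidates(phi_matrix)
  k_of <- read_table$occurrences$k
  N <- length(k_of)

  cand_ref <- lapply(k_of, function(k) {
    idx <- seq.int(cand$ptr[k] + 1L, length.out = cand$ptr[k + 1L] - cand$ptr[k])
    if (length(idx) == 0L) abort("occurrence without candidates.")
    cand$ref[idx] + 1L
  })
  cand_phi <- lapply(k_of, function(k) {
    idx <- seq.int(cand$ptr[k] + 1L, length.out = cand$ptr[k + 1L] - cand$ptr[k])
    cand$phi[idx]
  })

  n_states <- prod(lengths(cand_ref))
  if (n_states > max_states || M^N > 1e8) {
    abort(sprintf(
      "instance too large for enumeration (%g assignments); use run_gibbs().",
      n_states))
  }

  grid <- expand.grid(lapply(seq_len(N), function(i) seq_along(cand_ref[[i]])),
                      KEEP.OUT.ATTRS = FALSE)
  lgamma_alpha <- sum(lgamma(alpha)) - lgamma(sum(alpha))

  log_w <- numeric(nrow(grid))
  counts <- matrix(0L, nrow(grid), M)
  for (i in seq_len(N)) {
    sel <- grid[[i]]
    log_w <- log_w + log(cand_phi[[i]][sel])
    z_i <- cand_ref[[i]][sel]
    counts[cbind(seq_len(nrow(grid)), z_i)] <-
      counts[cbind(seq_len(nrow(grid)), z_i)] + 1L
  }
  log_delta <- rowSums(lgamma(counts + matrix(alpha, nrow(grid), M, byrow = TRUE))) -
    lgamma(rowSums(counts) + sum(alpha))
  log_w <- log_w + log_delta - lgamma_alpha

  lse <- max(log_w) + log(sum(exp(log_w - max(log_w))))
  post <- exp(log_w - lse)

  expected_counts <- setNames(as.numeric(crossprod(post, counts)),
                              phi_matrix$species_id)
  marginals <- matrix(0, N, M, dimnames = list(NULL, phi_matrix$species_id))
  for (i in seq_len(N)) {
    z_i <- cand_ref[[i]][grid[[i]]]
    for (t in unique(z_i)) {
      marginals[i, t] <- sum(post[z_i == t])
    }
  }
  list(expected_counts = expected_counts, marginals = marginals,
       log_normalizer = lse)
}

#' Roll species abundances up to higher taxa
#'
#' @param abundance Data frame with columns `species_id` and `abundance`
#'   (e.g. `tidy(fit)[, c("species_id", "abundance_hat")]` renamed), or a
#'   named numeric vector.
#' @param taxonomy Data frame with columns `species_id` and `taxon`, or a
#'   named character vector (names = species ids).
#' @return A tibble (`taxon`, `abundance`) whose abundances sum to the input
#'   total.
#' @export
aggregate_abundance <- function(abundance, taxonomy) {
  if (is.numeric(abundance)) {
    abundance <- tibble::tibble(species_id = names(abundance),
                                abundance = unname(abundance))
  }
  if (is.character(taxonomy) && !is.data.frame(taxonomy)) {
    taxonomy <- tibble::tibble(species_id = names(taxonomy),
                               taxon = unname(taxonomy))
  }
  if (!all(c("species_id", "abundance") %in% names(abundance))) {
    abort("`abundance` needs columns `species_id` and `abundance`.")
  }
  if (!all(c("species_id", "taxon") %in% names(taxonomy))) {
    abort("`taxonomy` needs columns `species_id` and `taxon`.")
  }
  missing <- setdiff(abundance$species_id, taxonomy$species_id)
  if (length(missing) > 0L) {
    abort(sprintf("no taxon mapping for reference(s): %s",
                  paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  dplyr::left_join(tibble::as_tibble(abundance),
                   tibble::as_tibble(taxonomy)[, c("species_id", "taxon")],
                   by = "species_id") |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
}

#' Zero out undetected references and renormalise
#'
#' References that received (almost) no reads still carry prior-driven
#' weight. For reporting, this helper zeroes species whose posterior mean
#' count is below `min_count` and renormalises the remaining abundances.
#'
#' @param fit A `coremix_fit`.
#' @param min_count Mean-count threshold below which a species is reported
#'   as absent (default 0.5 reads).
#' @return The fit with adjusted `abundance_hat` (and species table).
#' @export
drop_undetected <- function(fit, min_count = 0.5) {
  stopifnot(inherits(fit, "coremix_fit"))
  keep <- fit$mean_counts >= min_count
  if (!any(keep)) abort("all species fall below `min_count`.")
  a <- fit$abundance_hat
  a[!keep] <- 0
  a <- a / sum(a)
  fit$abundance_hat <- a
  fit$species$abundance_hat <- unname(a)
  fit
}
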