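#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps over hidden read-origin labels.
//
// Distinct read sequences share a candidate row (CSR layout over K distinct
// reads); every read occurrence carries its own label z_i.  One sweep visits
// occurrences in index order: decrement the current label's count, draw a new
// label from p(t) proportional to phi[k, t] * (n[t] + alpha[t]) over the
// candidate set, increment.  Counts are recorded every `thinning` sweeps
// after `burn_in` sweeps; the posterior mean count vector is the average of
// the kept snapshots.
//
// occ_k      0-based distinct-read index per occurrence (length N)
// cand_ptr   length K+1, 0-based offsets into cand_ref / cand_phi
// cand_ref   0-based reference index of each candidate
// cand_phi   phi value of each candidate (> 0)
// z0         0-based initial label per occurrence
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_cpp(const IntegerVector& occ_k,
               const IntegerVector& cand_ptr,
               const IntegerVector& cand_ref,
               const NumericVector& cand_phi,
               const NumericVector& alpha,
               const int n_ref,
               const IntegerVector& z0,
               const int burn_in,
               const int kept_samples,
               const int thinning,
               const bool keep_trace) {
  const int n_occ = occ_k.size();
  if (n_occ == 0) stop("no read occurrences to sample");

  std::vector<int> z(z0.begin(), z0.end());
  std::vector<double> n(n_ref, 0.0);
  for (int i = 0; i < n_occ; ++i) {
    if (z[i] < 0 || z[i] >= n_ref) stop("initial label out of range");
    n[z[i]] += 1.0;
  }

  std::vector<double> sum_counts(n_ref, 0.0);
  NumericMatrix trace(keep_trace ? kept_samples : 0, n_ref);
  std::vector<double> w;

  const int total_sweeps = burn_in + kept_samples * thinning;
  int n_kept = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int i = 0; i < n_occ; ++i) {
      const int k = occ_k[i];
      const int lo = cand_ptr[k], hi = cand_ptr[k + 1];
      const int width = hi - lo;
      if (width == 1) {
        // forced assignment; nothing to sample
        continue;
      }
      n[z[i]] -= 1.0;
      w.resize(width);
      double tot = 0.0;
      for (int c = 0; c < width; ++c) {
        const int t = cand_ref[lo + c];
        tot += cand_phi[lo + c] * (n[t] + alpha[t]);
        w[c] = tot;
      }
      const double u = unif_rand() * tot;
      int pick = width - 1;
      for (int c = 0; c < width; ++c) {
        if (u < w[c]) { pick = c; break; }
      }
      z[i] = cand_ref[lo + pick];
      n[z[i]] += 1.0;
    }
    const int after = sweep - burn_in + 1;
    if (after >= 1 && after % thinning == 0 && n_kept < kept_samples) {
      for (int t = 0; t < n_ref; ++t) {
        sum_counts[t] += n[t];
        if (keep_trace) trace(n_kept, t) = n[t];
      }
      ++n_kept;
    }
    if (sweep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector mean_counts(n_ref);
  for (int t = 0; t < n_ref; ++t) mean_counts[t] = sum_counts[t] / n_kept;

  IntegerVector z_out(n_occ);
  for (int i = 0; i < n_occ; ++i) z_out[i] = z[i] + 1;

  return List::create(_["mean_counts"] = mean_counts,
                      _["n_kept"] = n_kept,
                      _["z"] = z_out,
                      _["trace"] = trace);
}
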