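#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Ungapped read-to-reference matcher.
//
// A read of length L hits a reference at offset o (0-based) if the Hamming
// distance between the read and the reference window [o, o+L) is at most
// floor(L * max_error_rate).  Per (read, reference) pair the single best
// offset (fewest mismatches; ties -> smallest offset; forward strand
// preferred) is reported.
//
// The k-mer route uses the q-gram lemma for Hamming distance: an alignment
// with at most e mismatches shares at least one exact k-mer with the
// reference on the same diagonal whenever k <= floor(L / (e + 1)), so
// querying every read k-mer against an index of all reference k-mers and
// verifying each candidate diagonal is exactly equivalent to the exhaustive
// scan.  Windows containing non-ACGT characters are handled by the verify
// step (any non-ACGT position counts as a mismatch); k-mers containing them
// are not indexed.

static inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string rev_comp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char b = s[s.size() - 1 - i];
    switch (b) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// mismatches of read vs ref[o..o+L), counting non-ACGT as mismatch;
// aborts once the count exceeds max_mm (returns max_mm + 1).
static inline int count_mismatches(const std::string& read,
                                   const std::string& ref,
                                   const size_t o, const int max_mm) {
  int mm = 0;
  const size_t L = read.size();
  for (size_t p = 0; p < L; ++p) {
    const int a = base_code(read[p]);
    const int b = base_code(ref[o + p]);
    if (a < 0 || b < 0 || a != b) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

struct Hit {
  int read;      // 0-based
  int ref;       // 0-based
  int pos;       // 0-based offset
  int mm;
  bool reverse;
  int read_len;
};

static DataFrame hits_to_df(const std::vector<Hit>& hits) {
  const int n = hits.size();
  IntegerVector read(n), ref(n), pos(n), mm(n), len(n);
  LogicalVector rev(n);
  for (int i = 0; i < n; ++i) {
    read[i] = hits[i].read + 1;
    ref[i] = hits[i].ref + 1;
    pos[i] = hits[i].pos;
    mm[i] = hits[i].mm;
    rev[i] = hits[i].reverse;
    len[i] = hits[i].read_len;
  }
  return DataFrame::create(_["read_index"] = read, _["ref_index"] = ref,
                           _["pos"] = pos, _["mismatches"] = mm,
                           _["is_reverse"] = rev, _["read_length"] = len);
}

// best-per-reference bookkeeping for one read orientation
static void scan_candidates(const std::string& query, bool reverse,
                            const std::vector<std::pair<int, int> >& cands,
                            const std::vector<std::string>& refs,
                            const int max_mm,
                            std::vector<int>& best_mm, std::vector<int>& best_pos,
                            std::vector<bool>& best_rev, std::vector<int>& touched) {
  const size_t L = query.size();
  for (size_t c = 0; c < cands.size(); ++c) {
    const int r = cands[c].first;
    const int o = cands[c].second;
    if (o < 0 || (size_t)o + L > refs[r].size()) continue;
    const int mm = count_mismatches(query, refs[r], o, max_mm);
    if (mm > max_mm) continue;
    if (best_mm[r] == INT_MAX) touched.push_back(r);
    if (mm < best_mm[r] ||
        (mm == best_mm[r] && !reverse && best_rev[r]) ||
        (mm == best_mm[r] && reverse == best_rev[r] && o < best_pos[r])) {
      best_mm[r] = mm;
      best_pos[r] = o;
      best_rev[r] = reverse;
    }
  }
}

// [[Rcpp::export]]
DataFrame match_reads_exhaustive_cpp(const CharacterVector& reads,
                                     const CharacterVector& refs,
                                     const double max_error_rate,
                                     const bool both_strands) {
  const int n_ref = refs.size();
  std::vector<std::string> R(n_ref);
  for (int r = 0; r < n_ref; ++r) R[r] = as<std::string>(refs[r]);

  std::vector<Hit> hits;
  for (int i = 0; i < reads.size(); ++i) {
    const std::string fwd = as<std::string>(reads[i]);
    const size_t L = fwd.size();
    const int max_mm = (int)std::floor(L * max_error_rate);
    std::vector<std::string> queries;
    queries.push_back(fwd);
    if (both_strands) queries.push_back(rev_comp(fwd));
    for (int r = 0; r < n_ref; ++r) {
      int bmm = INT_MAX, bpos = -1;
      bool brev = false;
      if (R[r].size() < L) continue;
      for (size_t q = 0; q < queries.size(); ++q) {
        for (size_t o = 0; o + L <= R[r].size(); ++o) {
          const int mm = count_mismatches(queries[q], R[r], o, max_mm);
          if (mm <= max_mm && (mm < bmm || (mm == bmm && q == 0 && brev))) {
            bmm = mm;
            bpos = (int)o;
            brev = (q == 1);
          }
        }
      }
      if (bmm != INT_MAX) {
        Hit h = {i, r, bpos, bmm, brev, (int)L};
        hits.push_back(h);
      }
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return hits_to_df(hits);
}

// [[Rcpp::export]]
DataFrame match_reads_kmer_cpp(const CharacterVector& reads,
                               const CharacterVector& refs,
                               const double max_error_rate,
                               const bool both_strands) {
  const int n_ref = refs.size();
  std::vector<std::string> R(n_ref);
  for (int r = 0; r < n_ref; ++r) R[r] = as<std::string>(refs[r]);

  if (reads.size() == 0) return hits_to_df(std::vector<Hit>());

  // seed length from the q-gram lemma over the shortest read
  size_t min_len = SIZE_MAX;
  for (int i = 0; i < reads.size(); ++i) {
    const size_t L = (size_t)LENGTH(STRING_ELT(reads, i));
    if (L < min_len) min_len = L;
  }
  if (min_len == 0) stop("empty read sequence");
  const int e_min = (int)std::floor(min_len * max_error_rate);
  int k = (int)(min_len / (e_min + 1));
  if (k > 31) k = 31;
  if (k < 4) {
    // seeds too short to pay off; exhaustive scan is exact and cheap here
    return match_reads_exhaustive_cpp(reads, refs, max_error_rate, both_strands);
  }

  // index all reference k-mers: packed 2-bit key -> vector of (ref, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < n_ref; ++r) {
    uint64_t key = 0;
    int run = 0;
    for (size_t p = 0; p < R[r].size(); ++p) {
      const int b = base_code(R[r][p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back(std::make_pair(r, (int)(p + 1 - k)));
    }
  }

  std::vector<int> best_mm(n_ref, INT_MAX), best_pos(n_ref, -1);
  std::vector<bool> best_rev(n_ref, false);
  std::vector<int> touched;
  std::vector<Hit> hits;
  std::vector<uint64_t> seen;  // packed (ref << 32 | diag) per orientation

  for (int i = 0; i < reads.size(); ++i) {
    const std::string fwd = as<std::string>(reads[i]);
    const size_t L = fwd.size();
    const int max_mm = (int)std::floor(L * max_error_rate);
    touched.clear();
    std::vector<std::string> queries;
    queries.push_back(fwd);
    if (both_strands) queries.push_back(rev_comp(fwd));

    for (size_t q = 0; q < queries.size(); ++q) {
      const std::string& query = queries[q];
      // gather candidate (ref, diagonal) pairs from every k-mer of the read
      seen.clear();
      uint64_t key = 0;
      int run = 0;
      for (size_t p = 0; p < L; ++p) {
        const int b = base_code(query[p]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator
            it = index.find(key);
        if (it == index.end()) continue;
        const int kpos = (int)(p + 1 - k);
        for (size_t h = 0; h < it->second.size(); ++h) {
          const int r = it->second[h].first;
          const int diag = it->second[h].second - kpos;
          if (diag < 0 || (size_t)diag + L > R[r].size()) continue;
          seen.push_back(((uint64_t)r << 32) | (uint32_t)diag);
        }
      }
      // dedupe diagonals before verification
      if (!seen.empty()) {
        std::sort(seen.begin(), seen.end());
        seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
        std::vector<std::pair<int, int> > uniq(seen.size());
        for (size_t s = 0; s < seen.size(); ++s)
          uniq[s] = std::make_pair((int)(seen[s] >> 32), (int)(uint32_t)seen[s]);
        scan_candidates(query, q == 1, uniq, R, max_mm,
                        best_mm, best_pos, best_rev, touched);
      }
    }
    std::sort(touched.begin(), touched.end());
    for (size_t t = 0; t < touched.size(); ++t) {
      const int r = touched[t];
      Hit h = {i, r, best_pos[r], best_mm[r], best_rev[r], (int)L};
      hits.push_back(h);
      best_mm[r] = INT_MAX;
      best_pos[r] = -1;
      best_rev[r] = false;
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return hits_to_df(hits);
}
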