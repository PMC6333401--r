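// k-mer index and equivalence-class read classification.
//
// Transcript k-mers are stored canonically (lexicographic min of the k-mer
// and its reverse complement, on a 2-bit encoding), so classification is
// strand-invariant by construction. k is capped at 31 so a k-mer fits in a
// 64-bit word.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  // canonical k-mer -> id of a transcript set in `sets`
  std::unordered_map<uint64_t, int32_t> table;
  // pool of distinct transcript-id sets (0-based, sorted)
  std::vector<std::vector<int>> sets;
};

// Enumerate canonical k-mers of `seq`, calling f(code) for each window that
// contains only A/C/G/T. Returns false if a non-ACGT byte was seen.
template <typename F>
bool for_each_canonical(const std::string& seq, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  bool clean = true;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) {
      clean = false;
      run = 0;
      fwd = rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++run >= k) f(fwd < rev ? fwd : rev);
  }
  return clean;
}

}  // namespace

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  int n = seqs.size();
  // canonical k-mer -> sorted unique transcript list (0-based)
  std::unordered_map<uint64_t, std::vector<int>> tmp;
  for (int t = 0; t < n; ++t) {
    std::string s = as<std::string>(seqs[t]);
    if ((int)s.size() < k)
      stop("transcript %d is shorter than k = %d", t + 1, k);
    bool clean = for_each_canonical(s, k, [&](uint64_t code) {
      std::vector<int>& v = tmp[code];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
    if (!clean) stop("transcript %d contains non-ACGT characters", t + 1);
  }
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->table.reserve(tmp.size() * 2);
  std::map<std::vector<int>, int32_t> set_ids;
  for (auto& kv : tmp) {
    auto it = set_ids.find(kv.second);
    int32_t id;
    if (it == set_ids.end()) {
      id = (int32_t)idx->sets.size();
      idx->sets.push_back(kv.second);
      set_ids.emplace(kv.second, id);
    } else {
      id = it->second;
    }
    idx->table.emplace(kv.first, id);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_stats")]]
List kmer_index_stats(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)idx->table.size(),
                      _["n_distinct_sets"] = (int)idx->sets.size());
}

// Transcript sets (1-based indices) for each k-mer of each query sequence;
// used by tests to inspect membership.
// [[Rcpp::export(name = ".kmer_index_lookup")]]
List kmer_index_lookup(SEXP xp, CharacterVector queries) {
  XPtr<KmerIndex> idx(xp);
  int nq = queries.size();
  List out(nq);
  for (int i = 0; i < nq; ++i) {
    std::string s = as<std::string>(queries[i]);
    std::vector<std::vector<int>> hits;
    for_each_canonical(s, idx->k, [&](uint64_t code) {
      auto it = idx->table.find(code);
      if (it == idx->table.end()) {
        hits.push_back(std::vector<int>());
      } else {
        hits.push_back(idx->sets[it->second]);
      }
    });
    List li(hits.size());
    for (size_t j = 0; j < hits.size(); ++j) {
      IntegerVector v(hits[j].size());
      for (size_t m = 0; m < hits[j].size(); ++m) v[m] = hits[j][m] + 1;
      li[j] = v;
    }
    out[i] = li;
  }
  return out;
}

// [[Rcpp::export(name = ".classify_reads_cpp")]]
List classify_reads_cpp(SEXP xp, CharacterVector reads) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  // EC key = sorted 0-based transcript vector
  std::map<std::vector<int>, double> ec;
  double unassigned = 0;
  int n_short = 0;
  std::vector<int> cur, nxt;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) {
      ++n_short;
      unassigned += 1;
      continue;
    }
    bool any = false, empty = false;
    cur.clear();
    for_each_canonical(s, k, [&](uint64_t code) {
      if (empty) return;
      auto it = idx->table.find(code);
      if (it == idx->table.end()) return;  // k-mer absent from index: skip
      const std::vector<int>& hit = idx->sets[it->second];
      if (!any) {
        cur = hit;
        any = true;
      } else {
        nxt.clear();
        size_t a = 0, b = 0;
        while (a < cur.size() && b < hit.size()) {
          if (cur[a] < hit[b]) ++a;
          else if (cur[a] > hit[b]) ++b;
          else { nxt.push_back(cur[a]); ++a; ++b; }
        }
        cur.swap(nxt);
      }
      if (any && cur.empty()) empty = true;
    });
    if (!any || cur.empty()) {
      unassigned += 1;
    } else {
      ec[cur] += 1;
    }
  }
  int nec = (int)ec.size();
  List classes(nec);
  NumericVector counts(nec);
  int j = 0;
  for (auto& kv : ec) {
    IntegerVector v(kv.first.size());
    for (size_t m = 0; m < kv.first.size(); ++m) v[m] = kv.first[m] + 1;
    classes[j] = v;
    counts[j] = kv.second;
    ++j;
  }
  return List::create(_["classes"] = classes, _["counts"] = counts,
                      _["unassigned"] = unassigned, _["n_short"] = n_short);
}
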