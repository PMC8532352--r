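// K-mer index and equivalence-class read assignment.
//
// Sequences (assembled contigs + reference transcripts) are decomposed into
// overlapping k-mers stored in a hash table mapping each k-mer to the sorted
// set of sequences containing it.  A read is assigned, in each orientation,
// to the intersection of the id-sets of its k-mers that are present in the
// index (absent k-mers are skipped so substitution errors do not destroy the
// assignment).  2-bit encoding restricts k to <= 31, which covers the
// default (31) and everything short-read pseudo-alignment uses in practice.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <iterator>

using namespace Rcpp;

namespace {

struct VecHash {
  size_t operator()(const std::vector<int>& v) const {
    size_t h = 1469598103u ^ v.size();
    for (int x : v) h = h * 1000003u + static_cast<size_t>(x);
    return h;
  }
};

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, int32_t> table;  // k-mer -> interned set id
  std::vector<std::vector<int>> sets;           // set id -> sorted 0-based seq indices
  std::vector<std::string> ids;
  std::vector<bool> is_contig;
  std::vector<int> lengths;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// intersect cur (sorted) with nxt (sorted) in place
inline void isect(std::vector<int>& cur, const std::vector<int>& nxt) {
  size_t a = 0, b = 0, w = 0;
  while (a < cur.size() && b < nxt.size()) {
    if (cur[a] < nxt[b]) ++a;
    else if (nxt[b] < cur[a]) ++b;
    else { cur[w++] = cur[a]; ++a; ++b; }
  }
  cur.resize(w);
}

// One orientation's running assignment state.
struct OrientState {
  int present = 0;
  int last_sid = -1;
  bool init = false;
  std::vector<int> ec;
  void hit(const KmerIndex& idx, int sid) {
    ++present;
    if (sid == last_sid) return;
    last_sid = sid;
    if (!init) { ec = idx.sets[sid]; init = true; }
    else if (!ec.empty()) isect(ec, idx.sets[sid]);
  }
};

// Assign one read; returns true and fills out_ec when assigned.
bool assign_one(const KmerIndex& idx, const char* s, int len, double min_frac,
                std::vector<int>& out_ec) {
  const int k = idx.k;
  if (len < k) return false;
  const int n_kmers = len - k + 1;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t f = 0, r = 0;
  int valid = 0;
  OrientState fw, rv;
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; continue; }
    f = ((f << 2) | static_cast<uint64_t>(b)) & mask;
    r = (r >> 2) | (static_cast<uint64_t>(3 - b) << shift);
    if (++valid < k) continue;
    auto it = idx.table.find(f);
    if (it != idx.table.end()) fw.hit(idx, it->second);
    it = idx.table.find(r);
    if (it != idx.table.end()) rv.hit(idx, it->second);
  }
  const double need = min_frac * n_kmers;
  bool okF = fw.init && !fw.ec.empty() && fw.present >= need;
  bool okR = rv.init && !rv.ec.empty() && rv.present >= need;
  if (okF && okR && fw.present == rv.present) {
    // read equally compatible with both orientations (e.g. reverse reads of
    // an unstranded library): its EC is the union of the two compatible sets
    out_ec.clear();
    std::set_union(fw.ec.begin(), fw.ec.end(), rv.ec.begin(), rv.ec.end(),
                   std::back_inserter(out_ec));
    return true;
  }
  if (okF && (!okR || fw.present >= rv.present)) { out_ec = fw.ec; return true; }
  if (okR) { out_ec = rv.ec; return true; }
  return false;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs,
                     LogicalVector is_contig, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex* idx = new KmerIndex();
  XPtr<KmerIndex> ptr(idx, true);
  idx->k = k;
  const int n = seqs.size();
  idx->ids.reserve(n);
  idx->is_contig.reserve(n);
  idx->lengths.reserve(n);
  std::unordered_map<uint64_t, std::vector<int>> raw;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    idx->ids.push_back(std::string(CHAR(STRING_ELT(ids, i))));
    idx->is_contig.push_back(is_contig[i] != 0);
    idx->lengths.push_back(len);
    if (len < k) continue;
    uint64_t f = 0;
    int valid = 0;
    for (int p = 0; p < len; ++p) {
      int b = base_code(s[p]);
      if (b < 0) { valid = 0; continue; }
      f = ((f << 2) | static_cast<uint64_t>(b)) & mask;
      if (++valid < k) continue;
      std::vector<int>& v = raw[f];
      if (v.empty() || v.back() != i) v.push_back(i);
    }
  }
  // intern id-sets so identical sets share storage and repeated hits are cheap
  std::unordered_map<std::vector<int>, int32_t, VecHash> dict;
  idx->table.reserve(raw.size() * 2);
  for (auto& kv : raw) {
    auto it = dict.find(kv.second);
    int32_t sid;
    if (it == dict.end()) {
      sid = static_cast<int32_t>(idx->sets.size());
      idx->sets.push_back(kv.second);
      dict.emplace(std::move(kv.second), sid);
    } else {
      sid = it->second;
    }
    idx->table[kv.first] = sid;
  }
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = static_cast<double>(idx->table.size()),
                      _["n_sets"] = static_cast<double>(idx->sets.size()),
                      _["ids"] = wrap(idx->ids),
                      _["is_contig"] = wrap(idx->is_contig),
                      _["lengths"] = wrap(idx->lengths));
}

// [[Rcpp::export(name = ".cpp_lookup_kmer")]]
IntegerVector cpp_lookup_kmer(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if (static_cast<int>(kmer.size()) != idx->k) stop("k-mer length must equal index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return IntegerVector(0);
    code = (code << 2) | static_cast<uint64_t>(b);
  }
  auto it = idx->table.find(code);
  if (it == idx->table.end()) return IntegerVector(0);
  const std::vector<int>& v = idx->sets[it->second];
  IntegerVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".cpp_assign_reads")]]
List cpp_assign_reads(SEXP xp, CharacterVector reads, double min_frac) {
  XPtr<KmerIndex> idx(xp);
  const int n = reads.size();
  List out(n);
  std::vector<int> ec;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (assign_one(*idx, s, len, min_frac, ec)) {
      IntegerVector m(ec.size());
      for (size_t j = 0; j < ec.size(); ++j) m[j] = ec[j] + 1;
      out[i] = m;
    } else {
      out[i] = R_NilValue;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_count_ecs")]]
List cpp_count_ecs(SEXP xp, CharacterVector reads, double min_frac) {
  XPtr<KmerIndex> idx(xp);
  const int n = reads.size();
  std::unordered_map<std::vector<int>, double, VecHash> counts;
  double n_assigned = 0, n_unassigned = 0;
  std::vector<int> ec;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (assign_one(*idx, s, len, min_frac, ec)) {
      counts[ec] += 1;
      n_assigned += 1;
    } else {
      n_unassigned += 1;
    }
  }
  // deterministic output order: sort ECs lexicographically by member indices
  std::vector<const std::vector<int>*> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(&kv.first);
  std::sort(keys.begin(), keys.end(),
            [](const std::vector<int>* a, const std::vector<int>* b) { return *a < *b; });
  List members(keys.size());
  NumericVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    const std::vector<int>& v = *keys[i];
    IntegerVector m(v.size());
    for (size_t j = 0; j < v.size(); ++j) m[j] = v[j] + 1;
    members[i] = m;
    cnt[i] = counts[v];
  }
  return List::create(_["members"] = members, _["count"] = cnt,
                      _["n_assigned"] = n_assigned, _["n_unassigned"] = n_unassigned);
}
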