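// Two-pass engine: pileup accumulation, double-sided context counting over
// padded effective reads, and the second-pass denoising sweep. Coordinates
// are 1-based SAM positions throughout; query indices are 0-based.
#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <cmath>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static const char BASE_CHAR[4] = {'A', 'C', 'G', 'T'};

struct CigarItem { char op; int len; };

static std::vector<CigarItem> parse_cigar_cpp(const char *cg) {
  std::vector<CigarItem> out;
  int len = 0;
  for (const char *p = cg; *p; ++p) {
    if (*p >= '0' && *p <= '9') {
      len = len * 10 + (*p - '0');
    } else {
      if (len <= 0) stop("malformed CIGAR string: %s", cg);
      out.push_back({*p, len});
      len = 0;
    }
  }
  if (len != 0) stop("malformed CIGAR string: %s", cg);
  return out;
}

// One entry of an effective read: soft clips dropped, insertions kept,
// optionally padded at both ends with sequence-estimate bases.
struct EffEntry {
  int code;        // 0..3, or -1 for N/ambiguous
  int bin;         // 1..8 for read bases, 0 for pads
  int read_index;  // 0-based index into SEQ, -1 for pads
  long ref_pos;    // 1-based reference position, -1 for insertions/pads
};

// bin_of_phred: length-94 lookup, bin_of_phred[q] in 1..8 for q in 0..93.
static std::vector<EffEntry> effective_read_cpp(const char *seq,
                                                const char *qual, long pos,
                                                const std::vector<CigarItem> &cig,
                                                const IntegerVector &bin_of_phred) {
  std::vector<EffEntry> eff;
  eff.reserve(std::strlen(seq));
  int qi = 0;
  long rp = pos;
  for (const CigarItem &ci : cig) {
    switch (ci.op) {
      case 'M': case '=': case 'X':
        for (int t = 0; t < ci.len; ++t) {
          int q = qual[qi] - 33;
          if (q < 0 || q > 93) stop("Phred score out of range: %d", q);
          eff.push_back({base_code(seq[qi]), bin_of_phred[q], qi, rp});
          ++qi; ++rp;
        }
        break;
      case 'I':
        for (int t = 0; t < ci.len; ++t) {
          int q = qual[qi] - 33;
          if (q < 0 || q > 93) stop("Phred score out of range: %d", q);
          eff.push_back({base_code(seq[qi]), bin_of_phred[q], qi, -1});
          ++qi;
        }
        break;
      case 'S':
        qi += ci.len;
        break;
      case 'D': case 'N':
        rp += ci.len;
        break;
      case 'H': case 'P':
        break;
      default:
        stop("unsupported CIGAR op: %c", ci.op);
    }
  }
  return eff;
}

// Pad with up to k sequence-estimate bases on each side, truncating at the
// first undefined estimate position; no pad on a side that starts/ends with
// an insertion. x_hat holds base codes (-1 undefined) for reference
// positions x_start .. x_start + length - 1 (1-based).
static void pad_eff(std::vector<EffEntry> &eff, int k,
                    const IntegerVector &x_hat, long x_start) {
  if (eff.empty() || k <= 0) return;
  long nx = x_hat.size();
  std::vector<EffEntry> pre;
  if (eff.front().ref_pos > 0) {
    long j = eff.front().ref_pos;
    for (int t = 1; t <= k; ++t) {
      long p = j - t;
      long idx = p - x_start;
      if (idx < 0 || idx >= nx || x_hat[idx] < 0) break;
      pre.push_back({x_hat[idx], 0, -1, p});
    }
    std::reverse(pre.begin(), pre.end());
  }
  std::vector<EffEntry> post;
  if (eff.back().ref_pos > 0) {
    long j = eff.back().ref_pos;
    for (int t = 1; t <= k; ++t) {
      long p = j + t;
      long idx = p - x_start;
      if (idx < 0 || idx >= nx || x_hat[idx] < 0) break;
      post.push_back({x_hat[idx], 0, -1, p});
    }
  }
  if (!pre.empty()) eff.insert(eff.begin(), pre.begin(), pre.end());
  if (!post.empty()) eff.insert(eff.end(), post.begin(), post.end());
}

// [[Rcpp::export]]
IntegerMatrix pileup_counts_cpp(IntegerVector pos, CharacterVector cigar,
                                CharacterVector seq, CharacterVector qual,
                                IntegerVector bin_of_phred, int ref_start,
                                int ref_len) {
  IntegerMatrix counts(32, ref_len);
  int n = pos.size();
  for (int i = 0; i < n; ++i) {
    std::vector<CigarItem> cig = parse_cigar_cpp(CHAR(STRING_ELT(cigar, i)));
    const char *s = CHAR(STRING_ELT(seq, i));
    const char *qu = CHAR(STRING_ELT(qual, i));
    int qi = 0;
    long rp = pos[i];
    for (const CigarItem &ci : cig) {
      switch (ci.op) {
        case 'M': case '=': case 'X':
          for (int t = 0; t < ci.len; ++t) {
            int code = base_code(s[qi]);
            if (code >= 0) {
              int q = qu[qi] - 33;
              if (q < 0 || q > 93) stop("Phred score out of range: %d", q);
              long col = rp - ref_start;
              if (col < 0 || col >= ref_len) stop("pileup position out of range");
              ++counts(8 * code + bin_of_phred[q] - 1, col);
            }
            ++qi; ++rp;
          }
          break;
        case 'I': case 'S': qi += ci.len; break;
        case 'D': case 'N': rp += ci.len; break;
        case 'H': case 'P': break;
        default: stop("unsupported CIGAR op: %c", ci.op);
      }
    }
  }
  return counts;
}

typedef std::unordered_map<std::string, std::array<long, 32>> ContextMap;

static void count_read_contexts(const std::vector<EffEntry> &eff, int k,
                                ContextMap &store) {
  long n = (long)eff.size();
  if (n < 2 * k + 1) return;
  std::string key(2 * k, 'N');
  for (long c = k; c < n - k; ++c) {
    const EffEntry &ce = eff[c];
    if (ce.read_index < 0 || ce.code < 0 || ce.bin < 1) continue;
    bool ok = true;
    for (int t = 1; t <= k && ok; ++t) {
      if (eff[c - t].code < 0 || eff[c + t].code < 0) ok = false;
    }
    if (!ok) continue;
    for (int t = 0; t < k; ++t) {
      key[t] = BASE_CHAR[eff[c - k + t].code];
      key[k + t] = BASE_CHAR[eff[c + 1 + t].code];
    }
    auto it = store.find(key);
    if (it == store.end()) {
      std::array<long, 32> v{};
      v[8 * ce.code + ce.bin - 1] = 1;
      store.emplace(key, v);
    } else {
      ++it->second[8 * ce.code + ce.bin - 1];
    }
  }
}

// [[Rcpp::export]]
List count_contexts_cpp(IntegerVector pos, CharacterVector cigar,
                        CharacterVector seq, CharacterVector qual,
                        IntegerVector bin_of_phred, IntegerVector x_hat,
                        int x_start, int k) {
  ContextMap store;
  int n = pos.size();
  for (int i = 0; i < n; ++i) {
    std::vector<CigarItem> cig = parse_cigar_cpp(CHAR(STRING_ELT(cigar, i)));
    std::vector<EffEntry> eff = effective_read_cpp(
        CHAR(STRING_ELT(seq, i)), CHAR(STRING_ELT(qual, i)), pos[i], cig,
        bin_of_phred);
    pad_eff(eff, k, x_hat, x_start);
    count_read_contexts(eff, k, store);
  }
  CharacterVector keys(store.size());
  IntegerMatrix counts(32, store.size());
  R_xlen_t j = 0;
  for (auto &kv : store) {
    keys[j] = kv.first;
    for (int s = 0; s < 32; ++s) counts(s, j) = (int)kv.second[s];
    ++j;
  }
  return List::create(_["keys"] = keys, _["counts"] = counts);
}

// Merge a batch of per-reference context counts (keys may repeat across
// batches when statistics are pooled).
// [[Rcpp::export]]
List merge_contexts_cpp(List keys_list, List counts_list) {
  ContextMap store;
  int nb = keys_list.size();
  for (int b = 0; b < nb; ++b) {
    CharacterVector keys = keys_list[b];
    IntegerMatrix counts = counts_list[b];
    for (R_xlen_t j = 0; j < keys.size(); ++j) {
      std::string key = as<std::string>(keys[j]);
      auto it = store.find(key);
      if (it == store.end()) {
        std::array<long, 32> v{};
        for (int s = 0; s < 32; ++s) v[s] = counts(s, j);
        store.emplace(key, v);
      } else {
        for (int s = 0; s < 32; ++s) it->second[s] += counts(s, j);
      }
    }
  }
  CharacterVector keys(store.size());
  IntegerMatrix counts(32, store.size());
  R_xlen_t j = 0;
  for (auto &kv : store) {
    keys[j] = kv.first;
    for (int s = 0; s < 32; ++s) counts(s, j) = (int)kv.second[s];
    ++j;
  }
  return List::create(_["keys"] = keys, _["counts"] = counts);
}

// Second pass: apply the channel-inverted posterior at every eligible
// position of every read and rewrite SEQ/QUAL. G = (Pi Pi^T)^+ Pi (4x32),
// Pi the channel estimate (4x32). attempt[q] is TRUE when the confidence
// probability of Phred q is below the t_p gate.
// [[Rcpp::export]]
List denoise_reads_cpp(IntegerVector pos, CharacterVector cigar,
                       CharacterVector seq, CharacterVector qual,
                       IntegerVector bin_of_phred, IntegerVector x_hat,
                       int x_start, int k, CharacterVector store_keys,
                       IntegerMatrix store_counts, NumericMatrix G,
                       NumericMatrix Pi, LogicalVector attempt, int q_cap) {
  std::unordered_map<std::string, R_xlen_t> index;
  index.reserve(store_keys.size() * 2 + 1);
  for (R_xlen_t j = 0; j < store_keys.size(); ++j) {
    index.emplace(as<std::string>(store_keys[j]), j);
  }
  int n = pos.size();
  CharacterVector out_seq(n), out_qual(n);
  long examined = 0, attempted = 0, changed = 0, quals_updated = 0;
  std::string key;
  for (int i = 0; i < n; ++i) {
    std::vector<CigarItem> cig = parse_cigar_cpp(CHAR(STRING_ELT(cigar, i)));
    std::string s = CHAR(STRING_ELT(seq, i));
    std::string qu = CHAR(STRING_ELT(qual, i));
    std::vector<EffEntry> eff = effective_read_cpp(s.c_str(), qu.c_str(),
                                                   pos[i], cig, bin_of_phred);
    pad_eff(eff, k, x_hat, x_start);
    long ne = (long)eff.size();
    key.assign(2 * k, 'N');
    for (long c = 0; c < ne; ++c) {
      const EffEntry &ce = eff[c];
      if (ce.read_index < 0 || ce.code < 0) continue;  // pads, ambiguous
      ++examined;
      int q = qu[ce.read_index] - 33;
      if (!attempt[q]) continue;  // confidence already >= t_p
      if (c - k < 0 || c + k >= ne) continue;
      bool ok = true;
      for (int t = 1; t <= k && ok; ++t) {
        if (eff[c - t].code < 0 || eff[c + t].code < 0) ok = false;
      }
      if (!ok) continue;
      for (int t = 0; t < k; ++t) {
        key[t] = BASE_CHAR[eff[c - k + t].code];
        key[k + t] = BASE_CHAR[eff[c + 1 + t].code];
      }
      auto it = index.find(key);
      if (it == index.end()) continue;
      R_xlen_t col = it->second;
      double u[4];
      for (int b = 0; b < 4; ++b) {
        double acc = 0.0;
        for (int sym = 0; sym < 32; ++sym) {
          acc += G(b, sym) * store_counts(sym, col);
        }
        u[b] = acc > 0.0 ? acc : 0.0;  // clamp negatives
      }
      int obs = 8 * ce.code + ce.bin - 1;
      double qhat[4];
      double tot = 0.0;
      for (int b = 0; b < 4; ++b) {
        qhat[b] = Pi(b, obs) * u[b];
        tot += qhat[b];
      }
      if (!(tot > 0.0)) continue;  // degenerate posterior: leave untouched
      for (int b = 0; b < 4; ++b) qhat[b] /= tot;
      // argmax, ties resolved towards the original base, then A<C<G<T
      int best = ce.code;
      double bestv = qhat[ce.code];
      for (int b = 0; b < 4; ++b) {
        if (qhat[b] > bestv) { best = b; bestv = qhat[b]; }
      }
      double p_max = qhat[best];
      bool base_changed = best != ce.code;
      double p_i = 1.0 - std::pow(10.0, -q / 10.0);
      double p_new = base_changed ? p_max : (p_i + p_max) / 2.0;
      int qt;
      if (p_new >= 1.0) {
        qt = q_cap;
      } else {
        qt = (int)std::floor(-10.0 * std::log10(1.0 - p_new) + 0.5);
        if (qt > q_cap) qt = q_cap;
        if (qt < 0) qt = 0;
      }
      ++attempted;
      if (base_changed) {
        s[ce.read_index] = BASE_CHAR[best];
        ++changed;
      }
      qu[ce.read_index] = (char)(qt + 33);
      ++quals_updated;
    }
    out_seq[i] = s;
    out_qual[i] = qu;
  }
  return List::create(
      _["seq"] = out_seq, _["qual"] = out_qual,
      _["bases_examined"] = (double)examined,
      _["bases_attempted"] = (double)attempted,
      _["bases_changed"] = (double)changed,
      _["quals_updated"] = (double)quals_updated);
}
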