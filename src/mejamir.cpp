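#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Pair weights for the nested-structure fold: GC=3, AU=2, GU=1, else 0.
// Sequences are DNA-alphabet (U already mapped to T upstream).
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Maximum-weight nested base pairing (Nussinov-style) with a minimum
// hairpin loop of `min_loop` unpaired bases. Deterministic traceback:
// at each interval prefer pairing the left end over leaving it unpaired,
// and among equal-scoring partners prefer the outermost (largest k).
// [[Rcpp::export]]
List fold_nested_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = W[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int cand = w + (k > i + 1 ? W[i + 1][k - 1] : 0) +
                   (k < j ? W[k + 1][j] : 0);
        if (cand > best) best = cand;
      }
      W[i][j] = best;
    }
  }
  // traceback
  std::vector<int> pi, pj, pw;
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = W[i][j];
    int chosen = -1, chosen_w = 0;
    for (int k = j; k >= i + min_loop + 1; --k) { // outermost partner first
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int cand = w + (k > i + 1 ? W[i + 1][k - 1] : 0) +
                 (k < j ? W[k + 1][j] : 0);
      if (cand == target) { chosen = k; chosen_w = w; break; }
    }
    if (chosen >= 0) {
      pi.push_back(i + 1); pj.push_back(chosen + 1); pw.push_back(chosen_w);
      if (chosen > i + 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) stack.push_back(std::make_pair(chosen + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  int total = (n > 0) ? W[0][n - 1] : 0;
  return List::create(_["score"] = -total,
                      _["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["weight"] = wrap(pw));
}

// Best gap-free alignment of each tag against a set of mature references.
// Offsets of the tag start relative to the mature start are limited to
// [-max_shift, max_shift], and the tag 3' end must land within max_shift of
// the mature 3' end. Tag bases overhanging the mature count as mismatches.
// Returns the first (lowest-index) reference achieving the minimum mismatch
// count (<= max_mm), or 0 when none qualifies.
// [[Rcpp::export]]
DataFrame match_mature_cpp(CharacterVector tags, CharacterVector matures,
                           int max_mm = 2, int max_shift = 2) {
  int nt = tags.size(), nm = matures.size();
  IntegerVector ref_idx(nt), mism(nt);
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int Lt = tag.size();
    int best_ref = 0, best_mm = max_mm + 1;
    for (int m = 0; m < nm; ++m) {
      std::string mat = as<std::string>(matures[m]);
      int Lm = mat.size();
      for (int off = -max_shift; off <= max_shift; ++off) {
        if (std::abs(off + Lt - Lm) > max_shift) continue;
        int mm = 0;
        for (int p = 0; p < Lt && mm <= max_mm; ++p) {
          int q = p + off;
          if (q < 0 || q >= Lm || tag[p] != mat[q]) ++mm;
        }
        if (mm < best_mm) { best_mm = mm; best_ref = m + 1; }
      }
    }
    ref_idx[t] = (best_mm <= max_mm) ? best_ref : 0;
    mism[t] = (best_mm <= max_mm) ? best_mm : NA_INTEGER;
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["mismatches"] = mism);
}

// All exact sense-strand occurrences of each tag in each contig.
// 1-based start positions.
// [[Rcpp::export]]
DataFrame map_exact_cpp(CharacterVector tags, CharacterVector contigs) {
  std::vector<int> ti, ci, st;
  for (int t = 0; t < tags.size(); ++t) {
    std::string tag = as<std::string>(tags[t]);
    for (int c = 0; c < contigs.size(); ++c) {
      std::string ctg = as<std::string>(contigs[c]);
      size_t pos = ctg.find(tag, 0);
      while (pos != std::string::npos) {
        ti.push_back(t + 1); ci.push_back(c + 1);
        st.push_back((int)pos + 1);
        pos = ctg.find(tag, pos + 1);
      }
    }
  }
  return DataFrame::create(_["tag_idx"] = wrap(ti), _["contig_idx"] = wrap(ci),
                           _["start"] = wrap(st));
}

// miRNA position i (1 = 5' end) pairs with window position L - i + 1
// (antiparallel duplex on the mRNA sense strand). State per position:
// 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch.
static inline int duplex_state(char m, char w) {
  if ((m == 'A' && w == 'T') || (m == 'T' && w == 'A') ||
      (m == 'G' && w == 'C') || (m == 'C' && w == 'G')) return 2;
  if ((m == 'G' && w == 'T') || (m == 'T' && w == 'G')) return 1;
  return 0;
}

// Slide an ungapped duplex window of the miRNA's length over a contig and
// report every start whose mismatch score (#mismatch + 0.5 #GU) does not
// exceed max_score. 1-based starts.
// [[Rcpp::export]]
DataFrame scan_duplex_cpp(std::string mirna, std::string contig,
                          double max_score = 4.0) {
  int L = mirna.size(), N = contig.size();
  std::vector<int> starts; std::vector<double> scores;
  for (int s = 0; s + L <= N; ++s) {
    double sc = 0.0;
    for (int i = 0; i < L; ++i) {
      int st = duplex_state(mirna[i], contig[s + L - 1 - i]);
      if (st == 0) sc += 1.0; else if (st == 1) sc += 0.5;
      if (sc > max_score) break;
    }
    if (sc <= max_score) { starts.push_back(s + 1); scores.push_back(sc); }
  }
  return DataFrame::create(_["start"] = wrap(starts),
                           _["score"] = wrap(scores));
}
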