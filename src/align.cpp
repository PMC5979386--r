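#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Penalty of the duplex column formed by miRNA base m (RNA: A,C,G,U) read
// 5'->3' against the transcript base t (DNA: A,C,G,T) on the sense strand.
// Match (Watson-Crick) 0, G:U wobble 0.5, mismatch 1.
static inline double col_penalty(char m, char t) {
  switch (m) {
    case 'A': return (t == 'T') ? 0.0 : 1.0;
    case 'C': return (t == 'G') ? 0.0 : 1.0;
    case 'G': return (t == 'C') ? 0.0 : (t == 'T' ? 0.5 : 1.0);
    case 'U': return (t == 'A') ? 0.0 : (t == 'G' ? 0.5 : 1.0);
  }
  return 1.0;
}

static void window_scores(const char* mir, int L, const char* tx, int n,
                          const std::vector<double>& wt,
                          std::vector<double>& out) {
  int nw = n - L + 1;
  out.assign(nw > 0 ? nw : 0, 0.0);
  for (int w = 0; w < nw; ++w) {
    double sc = 0.0;
    // miRNA position k (0-based) pairs transcript position w + (L-1-k)
    for (int k = 0; k < L; ++k)
      sc += wt[k] * col_penalty(mir[k], tx[w + (L - 1 - k)]);
    out[w] = sc;
  }
}

static std::vector<double> core_weights(int L, int core_from, int core_to,
                                        double core_mult) {
  std::vector<double> wt(L, 1.0);
  for (int k = core_from - 1; k < core_to && k < L; ++k) wt[k] = core_mult;
  return wt;
}

// Allen penalty score of every length-L window of tx (sense strand).
// [[Rcpp::export(name = ".allen_scan_cpp")]]
NumericVector allen_scan_cpp(std::string mirna, std::string tx,
                             int core_from, int core_to, double core_mult) {
  int L = mirna.size(), n = tx.size();
  std::vector<double> wt = core_weights(L, core_from, core_to, core_mult);
  std::vector<double> out;
  window_scores(mirna.c_str(), L, tx.c_str(), n, wt, out);
  return NumericVector(out.begin(), out.end());
}

// Permutation p-value for one cleavage site. Shuffles the miRNA
// (mononucleotide, Fisher-Yates driven by R's RNG) n_perm times and counts
// shuffles for which some window has score <= obs_score AND the degradome
// profile count at that window's cleavage position is >= tags_at_site.
// cleavage position of window w (1-based) = w + L - cut_pos, with cut_pos
// the miRNA nucleotide (1-based from the 5' end) opposite the cut.
// [[Rcpp::export(name = ".site_pvalue_cpp")]]
double site_pvalue_cpp(std::string mirna, std::string tx,
                       NumericVector profile, double obs_score,
                       double tags_at_site, int n_perm, int cut_pos,
                       int core_from, int core_to, double core_mult) {
  int L = mirna.size(), n = tx.size();
  int nw = n - L + 1;
  std::vector<double> wt = core_weights(L, core_from, core_to, core_mult);
  std::vector<char> m(mirna.begin(), mirna.end());
  RNGScope scope;
  int hits = 0;
  const double eps = 1e-9;
  for (int r = 0; r < n_perm; ++r) {
    for (int k = L - 1; k > 0; --k) {  // Fisher-Yates
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      char tmp = m[k]; m[k] = m[j]; m[j] = tmp;
    }
    bool ok = false;
    for (int w = 0; w < nw && !ok; ++w) {
      int cpos = w + L - cut_pos;  // 0-based transcript index
      if (cpos < 0 || cpos >= n) continue;
      if (profile[cpos] + eps < tags_at_site) continue;
      double sc = 0.0;
      for (int k = 0; k < L; ++k) {
        sc += wt[k] * col_penalty(m[k], tx[w + (L - 1 - k)]);
        if (sc > obs_score + eps) break;
      }
      if (sc <= obs_score + eps) ok = true;
    }
    if (ok) ++hits;
  }
  return (1.0 + hits) / (double)(n_perm + 1);
}

// Best gap-free template assignment for each tag. Offsets shift the tag
// start relative to the template start; the tag may overhang the template
// by at most max_overhang nt on either side. Mismatches are counted over
// the overlapping span only.
// Returns, per tag: template index (1-based, 0 = unassigned), mismatches,
// overlap length.
// [[Rcpp::export(name = ".assign_templates_cpp")]]
List assign_templates_cpp(CharacterVector tags, CharacterVector templates,
                          int max_mismatch, int max_overhang) {
  int nt = tags.size(), ntp = templates.size();
  IntegerVector best_t(nt, 0), best_mm(nt, NA_INTEGER), best_ov(nt, 0);
  std::vector<std::string> tp(ntp);
  for (int j = 0; j < ntp; ++j) tp[j] = as<std::string>(templates[j]);
  for (int i = 0; i < nt; ++i) {
    std::string tg = as<std::string>(tags[i]);
    int Lt = tg.size();
    int bt = 0, bmm = INT_MAX, bov = -1;
    for (int j = 0; j < ntp; ++j) {
      int LT = tp[j].size();
      for (int d = -max_overhang; d <= max_overhang; ++d) {
        // tag position p (0-based) sits at template position p + d
        int end_over = d + Lt - LT;  // 3' overhang of tag past template
        if (end_over > max_overhang || end_over < -max_overhang) continue;
        int p0 = std::max(0, -d), p1 = std::min(Lt, LT - d);
        int ov = p1 - p0;
        if (ov <= 0) continue;
        int mm = 0;
        for (int p = p0; p < p1 && mm <= max_mismatch; ++p)
          if (tg[p] != tp[j][p + d]) ++mm;
        if (mm > max_mismatch) continue;
        if (mm < bmm || (mm == bmm && ov > bov)) {
          bmm = mm; bov = ov; bt = j + 1;
        }
      }
    }
    if (bt > 0) { best_t[i] = bt; best_mm[i] = bmm; best_ov[i] = bov; }
  }
  return List::create(_["template"] = best_t, _["mismatches"] = best_mm,
                      _["overlap"] = best_ov);
}

// Longest mismatch-free full-overlap between tag and mature over all
// ungapped offsets (the whole overlapping span must be identical).
// [[Rcpp::export(name = ".best_clean_overlap_cpp")]]
int best_clean_overlap_cpp(std::string tag, std::string mature) {
  int Lt = tag.size(), Lm = mature.size();
  int best = 0;
  for (int d = -(Lt - 1); d <= Lm - 1; ++d) {
    // tag position p aligns mature position p + d
    int p0 = std::max(0, -d), p1 = std::min(Lt, Lm - d);
    int ov = p1 - p0;
    if (ov <= best) continue;
    bool clean = true;
    for (int p = p0; p < p1; ++p)
      if (tag[p] != mature[p + d]) { clean = false; break; }
    if (clean) best = ov;
  }
  return best;
}
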