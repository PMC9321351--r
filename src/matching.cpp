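// Fast mutual-information block matching.
//
// Patches are compared through plug-in entropies of quantized intensity
// histograms. Patch sizes are small (<= 9x9), so per-pair histograms are
// built by sorting the gathered codes instead of touching a bins^2 table.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double entropy_sorted(std::vector<int>& v) {
  std::sort(v.begin(), v.end());
  const double n = static_cast<double>(v.size());
  double H = 0.0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    const double p = (j - i) / n;
    H -= p * std::log2(p);
    i = j;
  }
  return H;
}

// Mirrors normalized_mi() in R: NMI = MI / max(eps, min(Ha, Hb)), with the
// constant-vs-constant convention (1 if equal bins, 0 otherwise).
static double nmi_codes(const std::vector<int>& a, const std::vector<int>& b,
                        int bins) {
  std::vector<int> sa(a), sb(b), sj(a.size());
  for (size_t i = 0; i < a.size(); ++i) sj[i] = a[i] * bins + b[i];
  const double ha = entropy_sorted(sa);
  const double hb = entropy_sorted(sb);
  if (ha == 0.0 && hb == 0.0) return a[0] == b[0] ? 1.0 : 0.0;
  const double hab = entropy_sorted(sj);
  double mi = ha + hb - hab;
  if (mi < 0.0) mi = 0.0;
  double denom = std::max(1e-16, std::min(ha, hb));
  double nmi = mi / denom;
  return nmi > 1.0 ? 1.0 : nmi;
}

// [[Rcpp::export]]
double nmi_cpp(IntegerVector a, IntegerVector b, int bins) {
  if (a.size() != b.size()) stop("patches must have the same shape");
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  return nmi_codes(va, vb, bins);
}

struct Cand {
  double nmi;
  int r, c;
};

// For each reference origin (0-based rows of `refs`), rank every candidate
// patch whose centre pixel carries `cluster` in `labels` (optionally within
// a Chebyshev `radius` of the reference centre) by NMI descending, ties by
// (row, col) scan order, keep those >= threshold, truncate to k_max - 1.
// Returns, per reference, a list(origins = k x 2 integer matrix incl. the
// reference first, nmi = numeric vector incl. the leading 1.0).
// [[Rcpp::export]]
List match_patches_cpp(IntegerMatrix qimg, IntegerMatrix labels, int cluster,
                       IntegerMatrix refs, int patch, int k_max,
                       double threshold, double radius, int bins) {
  const int H = qimg.nrow(), W = qimg.ncol();
  const int half = patch / 2;
  const int n2 = patch * patch;
  List out(refs.nrow());

  std::vector<int> rcodes(n2), ccodes(n2);
  for (int ri = 0; ri < refs.nrow(); ++ri) {
    const int r0 = refs(ri, 0), c0 = refs(ri, 1);   // 0-based origins
    for (int j = 0, m = 0; j < patch; ++j)
      for (int i = 0; i < patch; ++i, ++m) rcodes[m] = qimg(r0 + i, c0 + j);

    int rlo = 0, rhi = H - patch, clo = 0, chi = W - patch;
    if (R_finite(radius)) {
      const int rad = static_cast<int>(radius);
      rlo = std::max(0, r0 - rad);
      rhi = std::min(H - patch, r0 + rad);
      clo = std::max(0, c0 - rad);
      chi = std::min(W - patch, c0 + rad);
    }

    std::vector<Cand> cands;
    for (int rr = rlo; rr <= rhi; ++rr) {
      for (int cc = clo; cc <= chi; ++cc) {
        if (rr == r0 && cc == c0) continue;
        if (labels(rr + half, cc + half) != cluster) continue;
        for (int j = 0, m = 0; j < patch; ++j)
          for (int i = 0; i < patch; ++i, ++m) ccodes[m] = qimg(rr + i, cc + j);
        // snap to 12 decimals so float-level differences between equally
        // informative patches do not perturb the deterministic tie-break
        const double nmi =
            std::nearbyint(nmi_codes(rcodes, ccodes, bins) * 1e12) / 1e12;
        if (nmi >= threshold) cands.push_back({nmi, rr, cc});
      }
    }
    const size_t keep = std::min(cands.size(),
                                 static_cast<size_t>(std::max(0, k_max - 1)));
    std::partial_sort(cands.begin(), cands.begin() + keep, cands.end(),
                      [](const Cand& a, const Cand& b) {
                        if (a.nmi != b.nmi) return a.nmi > b.nmi;
                        if (a.r != b.r) return a.r < b.r;
                        return a.c < b.c;
                      });

    IntegerMatrix origins(keep + 1, 2);
    NumericVector nmis(keep + 1);
    origins(0, 0) = r0; origins(0, 1) = c0; nmis[0] = 1.0;
    for (size_t m = 0; m < keep; ++m) {
      origins(m + 1, 0) = cands[m].r;
      origins(m + 1, 1) = cands[m].c;
      nmis[m + 1] = cands[m].nmi;
    }
    out[ri] = List::create(Named("origins") = origins, Named("nmi") = nmis);
  }
  return out;
}
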