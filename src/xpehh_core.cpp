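#include <Rcpp.h>
using namespace Rcpp;

// Haplotype identity classes for one panel, refined marker by marker.
// Group ids stay compact (0..k-1); refinement by a binary allele column is
// a single counting pass.
struct GroupState {
  std::vector<int> g;
  std::vector<int> remap;
  int k;

  void init(int n) {
    g.assign(n, 0);
    k = 1;
  }

  void refine(const int* alleles) {
    remap.assign(2 * k, -1);
    int nk = 0;
    for (size_t i = 0; i < g.size(); ++i) {
      int key = 2 * g[i] + alleles[i];
      if (remap[key] < 0) remap[key] = nk++;
      g[i] = remap[key];
    }
    k = nk;
  }

  double ehh() const {
    std::vector<int> cnt(k, 0);
    for (size_t i = 0; i < g.size(); ++i) cnt[g[i]]++;
    double n = (double)g.size();
    double s = 0;
    for (int j = 0; j < k; ++j) s += (double)cnt[j] * (cnt[j] - 1);
    return s / (n * (n - 1));
  }
};

// One side of the shared-boundary EHH integration for one core site.
// Walks outward refining observed / reference / pooled groupings in step;
// integration stops after the first marker where pooled EHH < cutoff
// (that marker is included), or at the chromosome end (truncated).
static void side_integrals(const IntegerMatrix& Hobs,
                           const IntegerMatrix& Href,
                           const IntegerVector& pos,
                           int core, int step, double cutoff,
                           double* I_obs, double* I_ref, bool* truncated) {
  int n1 = Hobs.nrow(), n2 = Href.nrow(), m = pos.size();
  GroupState g1, g2, gc;
  g1.init(n1); g2.init(n2); gc.init(n1 + n2);
  std::vector<int> comb(n1 + n2);
  const int* c1 = &Hobs(0, core);
  const int* c2 = &Href(0, core);
  for (int i = 0; i < n1; ++i) comb[i] = c1[i];
  for (int i = 0; i < n2; ++i) comb[n1 + i] = c2[i];
  g1.refine(c1); g2.refine(c2); gc.refine(comb.data());
  double last_d = 0, e1_prev = 1, e2_prev = 1, I1 = 0, I2 = 0;
  *truncated = false;
  for (int j = core + step;; j += step) {
    if (j < 0 || j >= m) { *truncated = true; break; }
    const int* a1 = &Hobs(0, j);
    const int* a2 = &Href(0, j);
    for (int i = 0; i < n1; ++i) comb[i] = a1[i];
    for (int i = 0; i < n2; ++i) comb[n1 + i] = a2[i];
    gc.refine(comb.data());
    double hc = gc.ehh();
    g1.refine(a1); g2.refine(a2);
    double e1 = g1.ehh(), e2 = g2.ehh();
    double d = fabs((double)pos[j] - (double)pos[core]);
    I1 += (d - last_d) * (e1_prev + e1) / 2.0;
    I2 += (d - last_d) * (e2_prev + e2) / 2.0;
    last_d = d; e1_prev = e1; e2_prev = e2;
    if (hc < cutoff) break;
  }
  *I_obs = I1;
  *I_ref = I2;
}

// [[Rcpp::export(name = ".xpehh_chrom_cpp")]]
List xpehh_chrom_cpp(IntegerMatrix Hobs, IntegerMatrix Href,
                     IntegerVector pos, double cutoff) {
  int m = pos.size();
  NumericVector raw(m, NA_REAL);
  LogicalVector truncated(m), scorable(m);
  for (int core = 0; core < m; ++core) {
    double IobsL, IrefL, IobsR, IrefR;
    bool tL, tR;
    side_integrals(Hobs, Href, pos, core, -1, cutoff, &IobsL, &IrefL, &tL);
    side_integrals(Hobs, Href, pos, core, +1, cutoff, &IobsR, &IrefR, &tR);
    double I_obs = IobsL + IobsR, I_ref = IrefL + IrefR;
    truncated[core] = tL || tR;
    if (I_obs > 0 && I_ref > 0) {
      scorable[core] = true;
      raw[core] = log(I_obs / I_ref);
    }
  }
  return List::create(_["raw"] = raw, _["truncated"] = truncated,
                      _["scorable"] = scorable);
}
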