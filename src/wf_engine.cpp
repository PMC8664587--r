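#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Forward-time Wright-Fisher engine for one or two demes of diploid,
// randomly mating hermaphrodites with nonoverlapping generations.
//
// The R-facing haplotype representation is a pair of L x 2N column-major
// arrays: v1 holds the allelic effect on trait 1 (or the 0/1 state of a
// neutral marker), v2 the effect on trait 2. Internally v2 is stored
// compactly with one row per locus that actually carries a trait-2 value
// (most loci in an association-mapping genome are neutral markers).
// Column 2*i + h is haplotype h of individual i.
//
// Locus role codes: 0 neutral, 1 qtl trait1, 2 qtl trait2, 3 qtl pleiotropic,
//                   4 qtn trait1, 5 qtn trait2, 6 qtn pleiotropic.

namespace {

struct Genome {
  int L;                              // loci
  int L2;                             // loci carrying a trait-2 value
  std::vector<int> role;
  std::vector<double> pos;            // cM within chromosome
  std::vector<int> chr_start, chr_end;  // locus ranges per chromosome
  std::vector<int> v2_start, v2_end;    // compact v2 ranges per chromosome
  std::vector<double> chr_len;        // map length (cM)
  std::vector<int> v2row;             // locus -> compact v2 row (-1 if none)
  std::vector<int> causal;            // causal locus indices
  std::vector<int> neutral;           // neutral locus indices
  std::vector<int> causal_t1;         // loci affecting trait 1 (v1 rows)
  std::vector<int> causal_t2c;        // compact v2 rows of trait-2 loci
};

struct Deme {
  int N;
  std::vector<double> v1;             // L  x 2N
  std::vector<double> v2;             // L2 x 2N (compact)
  std::vector<double> z1, z2;         // phenotypes, length N
  double basal1, basal2;
  double oinv11, oinv12, oinv22;      // Omega^-1 (selection off if all 0)
  double th1, th2;                    // local optima
  bool sel_on;
};

// Floyd's algorithm: k distinct uniform indices out of n (k << n typical)
inline void sample_distinct(int n, int k, std::vector<int> &out) {
  out.clear();
  for (int j = n - k; j < n; ++j) {
    int t = (int)std::floor(unif_rand() * (j + 1));
    if (t > j) t = j;
    bool seen = false;
    for (int v : out) if (v == t) { seen = true; break; }
    out.push_back(seen ? j : t);
  }
}

class Engine {
public:
  Genome gnm;
  double mu, alpha, neutral_mu;
  std::vector<double> cx;             // crossover position scratch
  std::vector<int> idx;               // mutation index scratch

  // One recombined, mutated gamete from parent `p` of deme `d` into the
  // buffers g1 (length L) and g2 (length L2, compact trait-2 values).
  void make_gamete(const Deme &d, int p, double *g1, double *g2) {
    const Genome &g = gnm;
    const double *a1 = &d.v1[(size_t)g.L * (2 * p)];
    const double *b1 = &d.v1[(size_t)g.L * (2 * p + 1)];
    const double *a2 = g.L2 ? &d.v2[(size_t)g.L2 * (2 * p)] : nullptr;
    const double *b2 = g.L2 ? &d.v2[(size_t)g.L2 * (2 * p + 1)] : nullptr;
    int nchr = (int)g.chr_start.size();
    for (int c = 0; c < nchr; ++c) {
      int s = g.chr_start[c], e = g.chr_end[c];
      int s2 = g.v2_start[c], e2 = g.v2_end[c];
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      int ncx = 0;
      if (g.chr_len[c] > 0.0)
        ncx = (int)R::rpois(g.chr_len[c] / 100.0);
      if (ncx == 0) {
        const double *s1p = strand ? b1 : a1;
        std::copy(s1p + s, s1p + e, g1 + s);
        if (e2 > s2) {
          const double *s2p = strand ? b2 : a2;
          std::copy(s2p + s2, s2p + e2, g2 + s2);
        }
      } else {
        cx.clear();
        for (int j = 0; j < ncx; ++j) cx.push_back(unif_rand() * g.chr_len[c]);
        std::sort(cx.begin(), cx.end());
        size_t ic = 0;
        for (int l = s; l < e; ++l) {
          while (ic < cx.size() && cx[ic] < g.pos[l]) { strand ^= 1; ++ic; }
          g1[l] = strand ? b1[l] : a1[l];
          int r2 = g.v2row[l];
          if (r2 >= 0) g2[r2] = strand ? b2[r2] : a2[r2];
        }
      }
    }
    // causal mutations
    int nc = (int)g.causal.size();
    if (nc > 0 && mu > 0.0) {
      int k = (int)R::rbinom((double)nc, mu);
      if (k > 0) {
        sample_distinct(nc, k, idx);
        for (int j : idx) {
          int l = g.causal[j];
          int r2 = g.v2row[l];
          switch (g.role[l]) {
          case 1: g1[l] += norm_rand() * alpha; break;
          case 2: g2[r2] += norm_rand() * alpha; break;
          case 3: g1[l] += norm_rand() * alpha;
                  g2[r2] += norm_rand() * alpha; break;
          case 4: g1[l] = -g1[l]; break;
          case 5: g2[r2] = -g2[r2]; break;
          case 6: g1[l] = -g1[l]; g2[r2] = -g2[r2]; break;
          }
        }
      }
    }
    // neutral marker mutations (reversible 0 <-> 1)
    int nn = (int)g.neutral.size();
    if (nn > 0 && neutral_mu > 0.0) {
      int k = (int)R::rbinom((double)nn, neutral_mu);
      if (k > 0) {
        sample_distinct(nn, k, idx);
        for (int j : idx) {
          int l = g.neutral[j];
          g1[l] = 1.0 - g1[l];
        }
      }
    }
  }

  // Next generation of deme `d` into `nxt`. Both parents come from `src`
  // with probability m, otherwise from `d`. Returns the migrant fraction.
  double step(const Deme &d, const Deme *src, double m, Deme &nxt) {
    int L = gnm.L, L2 = gnm.L2, N = d.N;
    std::vector<double> g1(L), g2(std::max(L2, 1)),
                        h1(L), h2(std::max(L2, 1));
    int accepted = 0, migrants = 0;
    double attempts = 0.0, wsum = 0.0;
    while (accepted < N) {
      const Deme *pool = &d;
      bool migrant = false;
      if (m > 0.0 && src != nullptr && unif_rand() < m) { pool = src; migrant = true; }
      int p1 = (int)std::floor(unif_rand() * pool->N);
      int p2 = (int)std::floor(unif_rand() * pool->N);  // selfing permitted
      if (p1 >= pool->N) p1 = pool->N - 1;
      if (p2 >= pool->N) p2 = pool->N - 1;
      make_gamete(*pool, p1, g1.data(), g2.data());
      make_gamete(*pool, p2, h1.data(), h2.data());
      double z1 = d.basal1, z2 = d.basal2;
      for (int l : gnm.causal_t1) z1 += g1[l] + h1[l];
      for (int r : gnm.causal_t2c) z2 += g2[r] + h2[r];
      double w = 1.0;
      if (d.sel_on) {
        double d1 = z1 - d.th1, d2 = z2 - d.th2;
        double q = d.oinv11 * d1 * d1 + 2.0 * d.oinv12 * d1 * d2 +
                   d.oinv22 * d2 * d2;
        w = std::exp(-0.5 * q);
      }
      attempts += 1.0; wsum += w;
      if (w >= 1.0 || unif_rand() < w) {
        std::copy(g1.begin(), g1.end(), &nxt.v1[(size_t)L * (2 * accepted)]);
        std::copy(h1.begin(), h1.end(),
                  &nxt.v1[(size_t)L * (2 * accepted + 1)]);
        if (L2) {
          std::copy(g2.begin(), g2.begin() + L2,
                    &nxt.v2[(size_t)L2 * (2 * accepted)]);
          std::copy(h2.begin(), h2.begin() + L2,
                    &nxt.v2[(size_t)L2 * (2 * accepted + 1)]);
        }
        nxt.z1[accepted] = z1; nxt.z2[accepted] = z2;
        if (migrant) ++migrants;
        ++accepted;
      }
      if (attempts >= 1e6 && wsum / attempts < 1e-12)
        stop("mean fitness collapsed below 1e-12; population regulation cannot terminate");
    }
    return (double)migrants / (double)N;
  }
};

int count_segregating(const Deme &d, const Genome &g) {
  int n2 = 2 * d.N, cnt = 0;
  for (int l : g.causal) {
    int r2 = g.v2row[l];
    double ref1 = d.v1[l];
    double ref2 = (r2 >= 0) ? d.v2[r2] : 0.0;
    for (int h = 1; h < n2; ++h) {
      bool diff = d.v1[(size_t)g.L * h + l] != ref1;
      if (!diff && r2 >= 0) diff = d.v2[(size_t)g.L2 * h + r2] != ref2;
      if (diff) { ++cnt; break; }
    }
  }
  return cnt;
}

void moments(const Deme &d, double out[5]) {
  int N = d.N;
  double m1 = 0, m2 = 0;
  for (int i = 0; i < N; ++i) { m1 += d.z1[i]; m2 += d.z2[i]; }
  m1 /= N; m2 /= N;
  double s11 = 0, s22 = 0, s12 = 0;
  for (int i = 0; i < N; ++i) {
    double a = d.z1[i] - m1, b = d.z2[i] - m2;
    s11 += a * a; s22 += b * b; s12 += a * b;
  }
  double den = (N > 1) ? (N - 1.0) : 1.0;
  out[0] = m1; out[1] = m2; out[2] = s11 / den; out[3] = s22 / den;
  out[4] = s12 / den;
}

Deme deme_from_R(const Genome &g,
                 const NumericMatrix &v1, const NumericMatrix &v2,
                 const NumericVector &phen1, const NumericVector &phen2,
                 const NumericVector &basal, const NumericMatrix &oinv,
                 const NumericVector &theta) {
  Deme d;
  d.N = v1.ncol() / 2;
  d.v1.assign(v1.begin(), v1.end());
  d.v2.resize((size_t)g.L2 * 2 * d.N);
  for (int h = 0; h < 2 * d.N; ++h)
    for (int l = 0; l < g.L; ++l)
      if (g.v2row[l] >= 0)
        d.v2[(size_t)g.L2 * h + g.v2row[l]] = v2(l, h);
  d.z1.assign(phen1.begin(), phen1.end());
  d.z2.assign(phen2.begin(), phen2.end());
  d.basal1 = basal[0]; d.basal2 = basal[1];
  d.oinv11 = oinv(0, 0); d.oinv12 = oinv(0, 1); d.oinv22 = oinv(1, 1);
  d.th1 = theta[0]; d.th2 = theta[1];
  d.sel_on = (d.oinv11 != 0.0 || d.oinv12 != 0.0 || d.oinv22 != 0.0);
  return d;
}

void deme_to_R(const Genome &g, const Deme &d, List &res,
               const char *k1, const char *k2, const char *kp) {
  NumericMatrix o1(g.L, 2 * d.N), o2(g.L, 2 * d.N);
  std::copy(d.v1.begin(), d.v1.end(), o1.begin());
  for (int h = 0; h < 2 * d.N; ++h)
    for (int l = 0; l < g.L; ++l)
      if (g.v2row[l] >= 0)
        o2(l, h) = d.v2[(size_t)g.L2 * h + g.v2row[l]];
  NumericMatrix phen(d.N, 2);
  for (int i = 0; i < d.N; ++i) { phen(i, 0) = d.z1[i]; phen(i, 1) = d.z2[i]; }
  res[k1] = o1; res[k2] = o2; res[kp] = phen;
}

} // namespace

// [[Rcpp::export(name = ".wf_engine")]]
List wf_engine(NumericMatrix v1, NumericMatrix v2,
               NumericVector phen1, NumericVector phen2,
               NumericVector basal, NumericMatrix oinv, NumericVector theta,
               IntegerVector role, NumericVector pos,
               IntegerVector chr_start, IntegerVector chr_end,
               NumericVector chr_len,
               double mu, double alpha, double neutral_mu,
               int generations, int record_every,
               double m,
               Nullable<List> source = R_NilValue) {
  Engine eng;
  Genome &g = eng.gnm;
  g.L = v1.nrow();
  g.role.assign(role.begin(), role.end());
  g.pos.assign(pos.begin(), pos.end());
  g.chr_start.assign(chr_start.begin(), chr_start.end());
  g.chr_end.assign(chr_end.begin(), chr_end.end());
  g.chr_len.assign(chr_len.begin(), chr_len.end());
  g.v2row.assign(g.L, -1);
  g.L2 = 0;
  for (int l = 0; l < g.L; ++l) {
    int r = g.role[l];
    if (r == 0) g.neutral.push_back(l); else g.causal.push_back(l);
    if (r == 1 || r == 3 || r == 4 || r == 6) g.causal_t1.push_back(l);
    if (r == 2 || r == 3 || r == 5 || r == 6) {
      g.v2row[l] = g.L2++;
      g.causal_t2c.push_back(g.v2row[l]);
    }
  }
  int nchr = (int)g.chr_start.size();
  g.v2_start.resize(nchr); g.v2_end.resize(nchr);
  for (int c = 0; c < nchr; ++c) {
    int s2 = g.L2, e2 = 0;
    for (int l = g.chr_start[c]; l < g.chr_end[c]; ++l)
      if (g.v2row[l] >= 0) {
        s2 = std::min(s2, g.v2row[l]);
        e2 = std::max(e2, g.v2row[l] + 1);
      }
    g.v2_start[c] = (e2 > 0) ? s2 : 0;
    g.v2_end[c] = e2;
  }
  eng.mu = mu; eng.alpha = alpha; eng.neutral_mu = neutral_mu;

  Deme focal = deme_from_R(g, v1, v2, phen1, phen2, basal, oinv, theta);
  bool two_demes = (m > 0.0 && source.isNotNull());
  Deme srcd;
  if (two_demes) {
    List s(source);
    srcd = deme_from_R(g, s["v1"], s["v2"], s["phen1"], s["phen2"],
                       s["basal"], s["oinv"], s["theta"]);
  }

  Deme focal_next = focal, src_next = srcd;

  int nrec = 0;
  for (int t = 1; t <= generations; ++t)
    if (t % record_every == 0 || t == generations) ++nrec;
  NumericMatrix traj(std::max(nrec, 0), 9);
  colnames(traj) = CharacterVector::create(
    "generation", "mean_z1", "mean_z2", "var1", "var2", "cov",
    "gcor", "n_qtl_segregating", "migrant_fraction");

  int rec = 0;
  for (int t = 1; t <= generations; ++t) {
    double mig = 0.0;
    if (two_demes) {
      eng.step(srcd, nullptr, 0.0, src_next);
      mig = eng.step(focal, &srcd, m, focal_next);
      std::swap(srcd.v1, src_next.v1); std::swap(srcd.v2, src_next.v2);
      std::swap(srcd.z1, src_next.z1); std::swap(srcd.z2, src_next.z2);
    } else {
      mig = eng.step(focal, nullptr, 0.0, focal_next);
    }
    std::swap(focal.v1, focal_next.v1); std::swap(focal.v2, focal_next.v2);
    std::swap(focal.z1, focal_next.z1); std::swap(focal.z2, focal_next.z2);

    if (t % record_every == 0 || t == generations) {
      double mm[5];
      moments(focal, mm);
      traj(rec, 0) = t;
      traj(rec, 1) = mm[0]; traj(rec, 2) = mm[1];
      traj(rec, 3) = mm[2]; traj(rec, 4) = mm[3]; traj(rec, 5) = mm[4];
      traj(rec, 6) = (mm[2] > 0.0 && mm[3] > 0.0)
                       ? mm[4] / std::sqrt(mm[2] * mm[3]) : 0.0;
      traj(rec, 7) = count_segregating(focal, g);
      traj(rec, 8) = mig;
      ++rec;
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List res = List::create(_["trajectory"] = traj);
  deme_to_R(g, focal, res, "v1", "v2", "phen");
  if (two_demes)
    deme_to_R(g, srcd, res, "source_v1", "source_v2", "source_phen");
  return res;
}
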