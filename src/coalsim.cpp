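// Coalescent machinery: ancestral recombination graph with piecewise
// exponential/constant demography (Hudson-style, ms time units of 4N0
// generations), branch-record genealogies for fixed-S nulls and SSR
// simulation, and a fast per-dataset summary-statistic path for ABC
// reference tables.
//
// Conventions (verified against E[S] = theta * sum 1/i and msprime in the
// test suite): with time t in units of 4N0 generations,
//   * coalescence rate for k lineages is k(k-1) / Nrel(t),
//   * recombination rate is rho_locus * (breakable span fraction),
//   * mutation rate is theta_locus * (ancestral material fraction),
// where theta_locus = 4 N0 mu L and rho_locus = 4 N0 r L.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int MAXW = 4; // bitmask words -> up to 256 chromosomes

typedef std::array<uint64_t, MAXW> Mask;

static inline int popcount_mask(const Mask& m, int nw) {
  int c = 0;
  for (int w = 0; w < nw; ++w) {
#ifdef __GNUC__
    c += __builtin_popcountll(m[w]);
#else
    uint64_t x = m[w];
    while (x) { x &= x - 1; ++c; }
#endif
  }
  return c;
}

struct Seg {
  double l, r;
  Mask mask;
};

typedef std::vector<Seg> Lineage;

struct Demography {
  std::vector<double> t0;     // segment start times, ascending, t0[0] == 0
  std::vector<double> size;   // relative size at segment start
  std::vector<double> alpha;  // N(t) = size * exp(-alpha * (t - t0)) in segment
};

// Waiting time to next coalescence for k lineages starting at time t,
// by inversion of the integrated hazard (closed form per segment).
static double coal_wait(const Demography& d, double t, double kk) {
  if (kk <= 0) return R_PosInf;
  double E = exp_rand();
  int nseg = (int)d.t0.size();
  int i = nseg - 1;
  while (i > 0 && d.t0[i] > t) --i;
  double cur = t;
  while (i < nseg) {
    double segEnd = (i + 1 < nseg) ? d.t0[i + 1] : R_PosInf;
    double a = d.alpha[i], Nrel = d.size[i];
    double x0 = cur - d.t0[i];
    if (a == 0.0) {
      double rate = kk / Nrel;
      if (segEnd == R_PosInf) return cur + E / rate - t;
      double cap = rate * (segEnd - cur);
      if (E <= cap) return cur + E / rate - t;
      E -= cap;
    } else {
      // hazard(s) = kk/Nrel * exp(a * (s - t0))
      double x1 = (segEnd == R_PosInf) ? R_PosInf : segEnd - d.t0[i];
      double H;
      if (x1 == R_PosInf) {
        H = (a > 0) ? R_PosInf
                    : kk / Nrel * (0.0 - std::exp(a * x0)) / a;
      } else {
        H = kk / Nrel * (std::exp(a * x1) - std::exp(a * x0)) / a;
      }
      if (E <= H) {
        double val = std::exp(a * x0) + E * a * Nrel / kk;
        double x = std::log(val) / a;
        return (d.t0[i] + x) - t;
      }
      E -= H;
    }
    cur = segEnd;
    ++i;
  }
  return R_PosInf;
}

static Demography make_demog(const NumericVector& t0,
                             const NumericVector& size,
                             const NumericVector& alpha) {
  Demography d;
  d.t0 = as<std::vector<double> >(t0);
  d.size = as<std::vector<double> >(size);
  d.alpha = as<std::vector<double> >(alpha);
  return d;
}

// Merge two lineages; segments whose merged mask covers the full sample have
// reached their local MRCA and are dropped.
static Lineage merge_lineages(const Lineage& A, const Lineage& B,
                              int n, int nw) {
  Lineage out;
  out.reserve(A.size() + B.size());
  size_t ia = 0, ib = 0;
  double cur = std::min(A.empty() ? R_PosInf : A[0].l,
                        B.empty() ? R_PosInf : B[0].l);
  while (ia < A.size() || ib < B.size()) {
    bool inA = ia < A.size() && A[ia].l <= cur && cur < A[ia].r;
    bool inB = ib < B.size() && B[ib].l <= cur && cur < B[ib].r;
    if (!inA && !inB) {
      // jump to next segment start
      double nxt = R_PosInf;
      if (ia < A.size()) nxt = std::min(nxt, A[ia].l);
      if (ib < B.size()) nxt = std::min(nxt, B[ib].l);
      cur = nxt;
      continue;
    }
    // elementary interval end
    double end = R_PosInf;
    if (inA) end = std::min(end, A[ia].r);
    else if (ia < A.size()) end = std::min(end, A[ia].l);
    if (inB) end = std::min(end, B[ib].r);
    else if (ib < B.size()) end = std::min(end, B[ib].l);
    Seg s;
    s.l = cur; s.r = end;
    s.mask.fill(0);
    if (inA) for (int w = 0; w < nw; ++w) s.mask[w] |= A[ia].mask[w];
    if (inB) for (int w = 0; w < nw; ++w) s.mask[w] |= B[ib].mask[w];
    if (popcount_mask(s.mask, nw) < n) {
      if (!out.empty() && out.back().r == s.l && out.back().mask == s.mask)
        out.back().r = s.r; // coalesce adjacent identical pieces
      else
        out.push_back(s);
    }
    cur = end;
    if (ia < A.size() && A[ia].r <= cur) ++ia;
    if (ib < B.size() && B[ib].r <= cur) ++ib;
  }
  return out;
}

struct Mut { double pos; Mask mask; };

// Simulate one locus under the ARG; returns 0/1 haplotype matrix (rows =
// chromosomes, ancestral = 0) and relative positions in [0,1).
static void sim_locus_core(int n, double theta_locus, double rho_locus,
                           const Demography& demog, std::vector<Mut>& muts) {
  const int nw = (n + 63) / 64;
  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    Seg s; s.l = 0.0; s.r = 1.0; s.mask.fill(0);
    s.mask[i / 64] = (uint64_t)1 << (i % 64);
    lin[i].push_back(s);
  }
  auto material = [](const Lineage& l) {
    double m = 0.0;
    for (size_t j = 0; j < l.size(); ++j) m += l[j].r - l[j].l;
    return m;
  };
  auto span = [](const Lineage& l) {
    return l.empty() ? 0.0 : l.back().r - l.front().l;
  };
  // ancestral material and breakable span, maintained incrementally
  double M = (double)n, B = (double)n;
  double t = 0.0;
  while (true) {
    int k = (int)lin.size();
    if (k <= 1) break;
    if (M <= 1e-12) break;
    double rate_rec = rho_locus * B;
    double t_rec = (rate_rec > 0) ? exp_rand() / rate_rec : R_PosInf;
    double t_coal = coal_wait(demog, t, (double)k * (k - 1));
    double dt = std::min(t_rec, t_coal);
    if (!R_FINITE(dt)) stop("coalescent simulation failed to converge");
    // drop mutations on the interval (t, t+dt)
    if (theta_locus > 0) {
      int nmut = (int)R::rpois(theta_locus * M * dt);
      for (int m = 0; m < nmut; ++m) {
        double u = unif_rand() * M, acc = 0.0;
        bool placed = false;
        const Seg* last = nullptr;
        for (int i = 0; i < k && !placed; ++i) {
          for (size_t j = 0; j < lin[i].size(); ++j) {
            const Seg& s = lin[i][j];
            last = &s;
            double len = s.r - s.l;
            if (u < acc + len) {
              muts.push_back(Mut{s.l + (u - acc), s.mask});
              placed = true; break;
            }
            acc += len;
          }
        }
        if (!placed && last)  // guard against float drift in M
          muts.push_back(Mut{last->l, last->mask});
      }
    }
    t += dt;
    if (t_rec < t_coal) {
      // recombination: pick lineage proportional to span, break uniformly
      double u = unif_rand() * B, acc = 0.0;
      int pick = k - 1;
      for (int i = 0; i < k; ++i) {
        double span = lin[i].back().r - lin[i].front().l;
        if (u < acc + span) { pick = i; break; }
        acc += span;
      }
      double lo = lin[pick].front().l, hi = lin[pick].back().r;
      double bp = lo + unif_rand() * (hi - lo);
      Lineage left, right;
      for (size_t j = 0; j < lin[pick].size(); ++j) {
        const Seg& s = lin[pick][j];
        if (s.r <= bp) left.push_back(s);
        else if (s.l >= bp) right.push_back(s);
        else {
          Seg a = s, b = s;
          a.r = bp; b.l = bp;
          left.push_back(a); right.push_back(b);
        }
      }
      if (left.empty() || right.empty()) continue; // break outside material
      B += span(left) + span(right) - span(lin[pick]);
      lin[pick] = std::move(left);
      lin.push_back(std::move(right));
    } else {
      // coalescence: merge two random distinct lineages
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      Lineage merged = merge_lineages(lin[i], lin[j], n, nw);
      M += material(merged) - material(lin[i]) - material(lin[j]);
      B += span(merged) - span(lin[i]) - span(lin[j]);
      int hi = std::max(i, j), lo2 = std::min(i, j);
      lin.erase(lin.begin() + hi);
      lin.erase(lin.begin() + lo2);
      if (!merged.empty()) lin.push_back(std::move(merged));
    }
  }
}

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(int n, double theta_locus, double rho_locus,
                   NumericVector demog_t0, NumericVector demog_size,
                   NumericVector demog_alpha) {
  if (n < 2 || n > 64 * MAXW) stop("n must be in [2, 256]");
  Demography demog = make_demog(demog_t0, demog_size, demog_alpha);
  std::vector<Mut> muts;
  sim_locus_core(n, theta_locus, rho_locus, demog, muts);
  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  int S = (int)muts.size();
  IntegerMatrix hap(n, S);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].pos;
    for (int i = 0; i < n; ++i)
      hap(i, s) = (muts[s].mask[i / 64] >> (i % 64)) & 1;
  }
  return List::create(_["haplotypes"] = hap, _["positions"] = pos);
}

// Plain coalescent genealogy (no recombination): branch records with leaf
// masks, for fixed-S mutation placement and SSR stepwise mutation.
// [[Rcpp::export(name = ".coal_branches_cpp")]]
List coal_branches_cpp(int n, NumericVector demog_t0, NumericVector demog_size,
                       NumericVector demog_alpha) {
  if (n < 2 || n > 64 * MAXW) stop("n must be in [2, 256]");
  Demography demog = make_demog(demog_t0, demog_size, demog_alpha);
  std::vector<Mask> mask(n);
  std::vector<double> birth(n, 0.0);
  for (int i = 0; i < n; ++i) {
    mask[i].fill(0);
    mask[i][i / 64] = (uint64_t)1 << (i % 64);
  }
  int nb = 2 * n - 2;
  NumericVector dur(nb);
  LogicalMatrix leaves(nb, n);
  int bi = 0;
  double t = 0.0;
  while ((int)mask.size() > 1) {
    int k = (int)mask.size();
    double dt = coal_wait(demog, t, (double)k * (k - 1));
    if (!R_FINITE(dt)) stop("coalescent simulation failed to converge");
    t += dt;
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    for (int idx : {i, j}) {
      dur[bi] = t - birth[idx];
      for (int c = 0; c < n; ++c)
        leaves(bi, c) = (mask[idx][c / 64] >> (c % 64)) & 1;
      ++bi;
    }
    Mask merged;
    for (int w = 0; w < MAXW; ++w) merged[w] = mask[i][w] | mask[j][w];
    int hi = std::max(i, j), lo = std::min(i, j);
    mask.erase(mask.begin() + hi);
    mask.erase(mask.begin() + lo);
    birth.erase(birth.begin() + hi);
    birth.erase(birth.begin() + lo);
    mask.push_back(merged);
    birth.push_back(t);
  }
  return List::create(_["duration"] = dur, _["leaves"] = leaves,
                      _["tmrca"] = t);
}

// ---- fast per-dataset ABC summaries --------------------------------------

static double harmonic(int m) {
  double a = 0.0;
  for (int i = 1; i <= m; ++i) a += 1.0 / i;
  return a;
}
static double harmonic2(int m) {
  double b = 0.0;
  for (int i = 1; i <= m; ++i) b += 1.0 / ((double)i * i);
  return b;
}

// Tajima's D from S and pi (locus scale), Tajima (1989) constants.
static double tajima_d_from(int n, int S, double pi_locus) {
  if (S < 1 || n < 4) return NA_REAL;
  double a1 = harmonic(n - 1), a2 = harmonic2(n - 1);
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double V = e1 * S + e2 * (double)S * (S - 1);
  if (V <= 0) return NA_REAL;
  return (pi_locus - S / a1) / std::sqrt(V);
}

// Standardized Fay & Wu H (Zeng et al. 2006), derived counts known (0 = anc).
static double fay_wu_h_from(int n, int S, double pi_locus, double thetaL) {
  if (S < 1 || n < 4) return NA_REAL;
  double an = harmonic(n - 1), bn = harmonic2(n - 1);
  double bn1 = bn + 1.0 / ((double)n * n);
  double th = S / an;
  double th2 = (double)S * (S - 1) / (an * an + bn);
  double var = (n - 2.0) / (6.0 * (n - 1.0)) * th +
    (18.0 * n * n * (3.0 * n + 2.0) * bn1 -
     (88.0 * n * n * n + 9.0 * n * n - 13.0 * n + 6.0)) /
      (9.0 * n * (n - 1.0) * (n - 1.0)) * th2;
  if (var <= 0) return NA_REAL;
  return (pi_locus - thetaL) / std::sqrt(var);
}

// Mean r^2 over all pairs of segregating sites, from derived-allele masks.
static double zns_from(const std::vector<Mut>& muts, int n, int nw) {
  int S = (int)muts.size();
  if (S < 2) return NA_REAL;
  double tot = 0.0;
  long np = 0;
  for (int i = 0; i < S; ++i) {
    int ci = popcount_mask(muts[i].mask, nw);
    double pA = (double)ci / n;
    for (int j = i + 1; j < S; ++j) {
      int cj = popcount_mask(muts[j].mask, nw);
      double pB = (double)cj / n;
      Mask both;
      for (int w = 0; w < nw; ++w) both[w] = muts[i].mask[w] & muts[j].mask[w];
      for (int w = nw; w < MAXW; ++w) both[w] = 0;
      double pAB = (double)popcount_mask(both, nw) / n;
      double D = pAB - pA * pB;
      double den = pA * (1 - pA) * pB * (1 - pB);
      tot += (den > 0) ? D * D / den : 0.0;
      ++np;
    }
  }
  return tot / np;
}

// Simulate a multilocus dataset and return the 4 ABC summaries
// (mean theta_w per site, mean Tajima's D, mean standardized H, mean ZnS)
// plus missingness counts. Undefined components contribute 0 (flagged).
// [[Rcpp::export(name = ".dataset_summaries_cpp")]]
NumericVector dataset_summaries_cpp(int n, NumericVector L,
                                    double theta_site, double rho_site,
                                    NumericVector demog_t0,
                                    NumericVector demog_size,
                                    NumericVector demog_alpha) {
  Demography demog = make_demog(demog_t0, demog_size, demog_alpha);
  const int nw = (n + 63) / 64;
  int nloc = L.size();
  double an = harmonic(n - 1);
  double sw = 0, sd = 0, sh = 0, sz = 0;
  int miss_d = 0, miss_h = 0, miss_z = 0;
  for (int loc = 0; loc < nloc; ++loc) {
    std::vector<Mut> muts;
    sim_locus_core(n, theta_site * L[loc], rho_site * L[loc], demog, muts);
    int S = (int)muts.size();
    double pi = 0.0, thL = 0.0;
    for (int s = 0; s < S; ++s) {
      int c = popcount_mask(muts[s].mask, nw);
      pi += 2.0 * c * (n - c) / ((double)n * (n - 1));
      thL += (double)c / (n - 1);
    }
    sw += S / (an * L[loc]);
    double d = tajima_d_from(n, S, pi);
    if (ISNA(d)) { ++miss_d; } else sd += d;
    double h = fay_wu_h_from(n, S, pi, thL);
    if (ISNA(h)) { ++miss_h; } else sh += h;
    double z = zns_from(muts, n, nw);
    if (ISNA(z)) { ++miss_z; } else sz += z;
  }
  return NumericVector::create(
    _["theta_w"] = sw / nloc, _["tajima_d"] = sd / nloc,
    _["fay_wu_h"] = sh / nloc, _["zns"] = sz / nloc,
    _["miss_d"] = miss_d, _["miss_h"] = miss_h, _["miss_z"] = miss_z);
}
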