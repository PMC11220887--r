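// Dual-space phase-retrieval trial loop.
//
// The reciprocal-space state is carried on the full FFT grid; the unique
// (Laue-asymmetric) reflection list addresses grid coefficients through
// flattened member arrays built once per problem on the R side:
//   member_off  : offsets (0-based, length n_u + 1) into the entry arrays
//   member_idx  : 0-based linear grid index of each symmetry/Friedel image
//   member_ph   : unit phase p_j = exp(-2*pi*i h.t_j) of the image
//   member_conj : 1 if the image is a Friedel mate (value conjugated)
//   member_wt   : scatter weight, 1 / (number of entries sharing the index)
// Scatter with these weights is the orthogonal projection onto the
// symmetry-consistent (hence Hermitian) coefficient subspace, so symmetry
// is enforced in reciprocal space at every cycle, including for
// phase-restricted reflections.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <memory>
#include <random>
#include <vector>
#include "fft3.h"

using namespace Rcpp;
using sadret::cplx;
using sadret::FFT3D;

namespace {

inline double unif01(std::mt19937& rng) {
  return rng() * (1.0 / 4294967296.0);
}

struct Members {
  const int* off;
  const int* idx;
  const int* cj;
  const double* wt;
  std::vector<cplx> ph;
  int n_u;
};

Members make_members(const IntegerVector& off, const IntegerVector& idx,
                     const ComplexVector& ph, const IntegerVector& cj,
                     const NumericVector& wt) {
  Members m;
  m.off = INTEGER(off);
  m.idx = INTEGER(idx);
  m.cj = INTEGER(cj);
  m.wt = REAL(wt);
  m.n_u = off.size() - 1;
  m.ph.resize(ph.size());
  for (int j = 0; j < ph.size(); ++j) m.ph[j] = cplx(ph[j].r, ph[j].i);
  return m;
}

// Laue reduction: phase-aligned average of all images of each unique.
void reduce_grid(const Members& m, const std::vector<cplx>& G,
                 std::vector<cplx>& F) {
  for (int u = 0; u < m.n_u; ++u) {
    cplx acc(0.0, 0.0);
    const int j0 = m.off[u], j1 = m.off[u + 1];
    for (int j = j0; j < j1; ++j) {
      cplx v = G[m.idx[j]];
      if (m.cj[j]) v = std::conj(v);
      acc += v * std::conj(m.ph[j]);
    }
    F[u] = acc / (double)(j1 - j0);
  }
}

// Symmetry expansion: scatter uniques to all images (weighted where images
// coincide); everything not reached -- beyond-limit, absent, F(0) -- is zero.
void scatter_grid(const Members& m, const std::vector<cplx>& F,
                  std::vector<cplx>& G) {
  std::fill(G.begin(), G.end(), cplx(0.0, 0.0));
  for (int u = 0; u < m.n_u; ++u) {
    const cplx f = F[u];
    for (int j = m.off[u]; j < m.off[u + 1]; ++j) {
      cplx v = f * m.ph[j];
      if (m.cj[j]) v = std::conj(v);
      G[m.idx[j]] += m.wt[j] * v;
    }
  }
}

double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  const size_t n = x.size();
  if (n < 2) return 0.0;
  double mx = 0, my = 0;
  for (size_t i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (size_t i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return 0.0;
  return sxy / std::sqrt(sxx * syy);
}

// Tangent-formula refinement of the strong set, triplet sums by FFT:
// the squared strong-only E-map has Fourier coefficients
// G(h) = sum_k E(k) E(h-k) over the symmetry-expanded strong set.
void tangent_apply(const Members& m, std::vector<cplx>& F,
                   const std::vector<int>& strong,
                   const NumericVector& E_obs,
                   std::vector<cplx>& work, std::vector<double>& workr,
                   const sadret::HermFFT& herm) {
  const size_t ns = strong.size();
  if (ns == 0) return;
  std::vector<cplx> Fs(m.n_u, cplx(0.0, 0.0));
  double esum2 = 0.0;
  for (size_t s = 0; s < ns; ++s) {
    Fs[strong[s]] = F[strong[s]];
    esum2 += E_obs[strong[s]] * E_obs[strong[s]];
  }
  scatter_grid(m, Fs, work);
  herm.synthesize(work.data(), workr.data());
  for (size_t i = 0; i < work.size(); ++i) {
    const double e = workr[i];
    workr[i] = e * e;
  }
  herm.analyze(workr.data(), work.data());
  std::vector<cplx> G(m.n_u);
  reduce_grid(m, work, G);
  const double gzero = 1e-9 * esum2; // FFT roundoff is not signal
  std::vector<double> M(ns), phi_tf(ns);
  double mmax = 0.0;
  for (size_t s = 0; s < ns; ++s) {
    const int u = strong[s];
    const double g = std::abs(G[u]);
    M[s] = (g > gzero) ? E_obs[u] * g : 0.0;
    phi_tf[s] = (g > gzero) ? std::atan2(G[u].imag(), G[u].real()) : 0.0;
    if (M[s] > mmax) mmax = M[s];
  }
  if (mmax <= 0) return;
  for (size_t s = 0; s < ns; ++s) {
    const int u = strong[s];
    const double g = std::abs(G[u]);
    if (g <= gzero) continue; // undefined triplet sum: phase kept
    const double alpha = M[s] / mmax;
    const double amp = std::abs(F[u]);
    const double phi_c = std::atan2(F[u].imag(), F[u].real());
    const cplx dir = (1.0 - alpha) * cplx(std::cos(phi_c), std::sin(phi_c)) +
                     alpha * cplx(std::cos(phi_tf[s]), std::sin(phi_tf[s]));
    const double ad = std::abs(dir);
    if (ad > 0) F[u] = amp * dir / ad;
  }
}

// threshold with exactly k = floor(frac*N) points in the low branch
// (delta_mode 0) or N - floor(frac*N) (delta_mode 1)
double density_threshold(const std::vector<double>& a, double frac,
                         int delta_mode, std::vector<double>& scratch) {
  const long N = (long)a.size();
  long k = (long)std::floor(frac * (double)N);
  if (delta_mode == 1) k = N - k;
  if (k <= 0) return -std::numeric_limits<double>::infinity();
  if (k >= N) return std::numeric_limits<double>::infinity();
  scratch = a;
  std::nth_element(scratch.begin(), scratch.begin() + k, scratch.end());
  return scratch[k];
}

} // namespace

// [[Rcpp::export]]
ComplexVector fft3_cpp(ComplexVector z, IntegerVector dims, int sign) {
  if (dims.size() != 3) stop("dims must have length 3");
  const long N = (long)dims[0] * dims[1] * dims[2];
  if ((long)z.size() != N) stop("length(z) != prod(dims)");
  std::vector<cplx> buf(N);
  for (long i = 0; i < N; ++i) buf[i] = cplx(z[i].r, z[i].i);
  FFT3D plan(dims[0], dims[1], dims[2], sign);
  plan.run(buf.data());
  ComplexVector out(N);
  for (long i = 0; i < N; ++i) { out[i].r = buf[i].real(); out[i].i = buf[i].imag(); }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector random_phases_cpp(int n, int seed) {
  std::mt19937 rng((uint32_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 2.0 * M_PI * unif01(rng);
  return out;
}

// [[Rcpp::export]]
ComplexVector tangent_apply_cpp(ComplexVector F, IntegerVector dims,
                                IntegerVector member_off, IntegerVector member_idx,
                                ComplexVector member_ph, IntegerVector member_conj,
                                NumericVector member_wt, NumericVector E_obs,
                                IntegerVector strong_idx) {
  Members m = make_members(member_off, member_idx, member_ph, member_conj, member_wt);
  std::vector<cplx> Fv(m.n_u);
  for (int u = 0; u < m.n_u; ++u) Fv[u] = cplx(F[u].r, F[u].i);
  sadret::HermFFT herm(dims[0], dims[1], dims[2]);
  const long tn = (long)dims[0] * dims[1] * dims[2];
  std::vector<cplx> work(tn);
  std::vector<double> workr(tn);
  std::vector<int> strong(strong_idx.begin(), strong_idx.end());
  tangent_apply(m, Fv, strong, E_obs, work, workr, herm);
  ComplexVector out(m.n_u);
  for (int u = 0; u < m.n_u; ++u) { out[u].r = Fv[u].real(); out[u].i = Fv[u].imag(); }
  return out;
}

// [[Rcpp::export]]
List run_trial_cpp(IntegerVector dims,
                   IntegerVector member_off, IntegerVector member_idx,
                   ComplexVector member_ph, IntegerVector member_conj,
                   NumericVector member_wt,
                   NumericVector E_obs, LogicalVector obs, LogicalVector weak,
                   IntegerVector strong_idx,
                   int algorithm, double beta, double perturb_frac,
                   int delta_mode, int n_iter, int tf_start, int tf_stride,
                   double pihalf_sign, bool weak_keep_calc,
                   bool weak_dynamic, int n_weak,
                   int seed, NumericVector phases_init, bool return_density,
                   IntegerVector tf_dims, IntegerVector tf_member_idx,
                   NumericVector tf_member_wt) {
  Members m = make_members(member_off, member_idx, member_ph, member_conj, member_wt);
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  sadret::HermFFT herm(n1, n2, n3);

  std::vector<cplx> G(N), work;
  std::vector<cplx> F(m.n_u);
  std::vector<double> rho(N), rho_t(N), absr(N), scratch, workr;
  std::vector<int> strong(strong_idx.begin(), strong_idx.end());
  const bool use_pihalf = algorithm >= 2;
  const bool use_tf = algorithm >= 3 && strong.size() > 0;
  // tangent convolution runs on its own alias-free grid
  Members tf_m = m;
  std::unique_ptr<sadret::HermFFT> tf_herm;
  if (use_tf) {
    tf_m.idx = INTEGER(tf_member_idx);
    tf_m.wt = REAL(tf_member_wt);
    tf_herm.reset(new sadret::HermFFT(tf_dims[0], tf_dims[1], tf_dims[2]));
    const long tn = (long)tf_dims[0] * tf_dims[1] * tf_dims[2];
    work.resize(tn);
    workr.resize(tn);
  }

  std::vector<int> obs_u;
  for (int u = 0; u < m.n_u; ++u) if (obs[u]) obs_u.push_back(u);
  std::vector<double> eo(obs_u.size()), ec(obs_u.size());
  std::vector<double> wamp(obs_u.size()), wscratch;
  std::vector<char> dynweak(obs_u.size(), 0);
  for (size_t i = 0; i < obs_u.size(); ++i) eo[i] = E_obs[obs_u[i]];

  // initial map: observed E with random (or supplied) phases, free set zero
  {
    std::mt19937 rng((uint32_t)seed);
    for (int u = 0; u < m.n_u; ++u) {
      double phi = 2.0 * M_PI * unif01(rng);
      if (phases_init.size() == m.n_u) phi = phases_init[u];
      F[u] = obs[u] ? E_obs[u] * cplx(std::cos(phi), std::sin(phi))
                    : cplx(0.0, 0.0);
    }
    scatter_grid(m, F, G);
    herm.synthesize(G.data(), rho.data());
    for (long i = 0; i < N; ++i) rho[i] /= (double)N;
  }

  NumericVector cc_trace(n_iter);
  double max_imag_ratio = 0.0, max_abs_mean = 0.0;
  bool ok = true;
  const cplx shift(std::cos(pihalf_sign * M_PI / 2.0),
                   std::sin(pihalf_sign * M_PI / 2.0));

  for (int it = 1; it <= n_iter + 1; ++it) {
    // (b) analysis + Laue reduction
    herm.analyze(rho.data(), G.data());
    reduce_grid(m, G, F);
    if (it > 1) {
      for (size_t i = 0; i < obs_u.size(); ++i) ec[i] = std::abs(F[obs_u[i]]);
      cc_trace[it - 2] = pearson(eo, ec);
    }
    if (it == n_iter + 1) break;

    // weak set: fixed from E_obs ranking, or re-ranked each cycle from
    // the calculated moduli (weak_mode = "dynamic")
    if (use_pihalf && weak_dynamic) {
      for (size_t i = 0; i < obs_u.size(); ++i)
        wamp[i] = std::abs(F[obs_u[i]]);
      wscratch = wamp;
      long kk = n_weak;
      if (kk > (long)wscratch.size()) kk = wscratch.size();
      double thr = -1.0;
      if (kk > 0 && kk < (long)wscratch.size()) {
        std::nth_element(wscratch.begin(), wscratch.begin() + kk,
                         wscratch.end());
        thr = wscratch[kk];
      } else if (kk >= (long)wscratch.size()) {
        thr = std::numeric_limits<double>::infinity();
      }
      long marked = 0;
      for (size_t i = 0; i < obs_u.size(); ++i) {
        const bool w = wamp[i] < thr && marked < n_weak;
        dynweak[i] = w;
        if (w) ++marked;
      }
    }
    // (c) moduli replacement (free reflections untouched)
    for (size_t i = 0; i < obs_u.size(); ++i) {
      const int u = obs_u[i];
      const bool isw = weak_dynamic ? (dynweak[i] != 0) : (weak[u] != 0);
      if (weak_keep_calc && use_pihalf && isw) continue;
      const double amp = std::abs(F[u]);
      F[u] = (amp > 0) ? F[u] * (E_obs[u] / amp)
                       : cplx(E_obs[u], 0.0);
    }
    // (d) pi-half perturbation of the weak set
    if (use_pihalf)
      for (size_t i = 0; i < obs_u.size(); ++i) {
        const bool isw = weak_dynamic ? (dynweak[i] != 0)
                                      : (weak[obs_u[i]] != 0);
        if (isw) F[obs_u[i]] *= shift;
      }
    // (d) tangent refinement of the strong set on schedule
    if (use_tf && it >= tf_start && (it - tf_start) % tf_stride == 0)
      tangent_apply(tf_m, F, strong, E_obs, work, workr, *tf_herm);

    // (e) expansion + synthesis; Hermitian asymmetry of the scattered
    // coefficients is the reality diagnostic (the synthesis discards the
    // anti-Hermitian component, so it is measured in reciprocal space)
    scatter_grid(m, F, G);
    double fmax = 0.0;
    for (int u = 0; u < m.n_u; ++u) {
      const double g = std::abs(F[u]);
      if (g > fmax) fmax = g;
    }
    const double asym = herm.asymmetry(G.data());
    if (fmax > 0 && asym / fmax > max_imag_ratio)
      max_imag_ratio = asym / fmax;
    herm.synthesize(G.data(), rho_t.data());
    double mx_re = 0.0, mean = 0.0;
    for (long i = 0; i < N; ++i) {
      const double v = rho_t[i] / (double)N;
      rho_t[i] = v;
      const double ar = std::fabs(v);
      absr[i] = ar;
      if (ar > mx_re) mx_re = ar;
      mean += v;
    }
    mean /= (double)N;
    if (std::fabs(mean) > max_abs_mean) max_abs_mean = std::fabs(mean);
    if (!std::isfinite(mx_re)) { ok = false; break; }

    // (f) real-space constraint
    if (algorithm == 0) { // charge flipping baseline, no positivity
      const double delta = density_threshold(absr, perturb_frac, delta_mode, scratch);
      for (long i = 0; i < N; ++i)
        rho[i] = (rho_t[i] >= delta) ? rho_t[i] : -rho_t[i];
    } else { // RAAR with |.| before and after
      const double delta = density_threshold(absr, perturb_frac, delta_mode, scratch);
      for (long i = 0; i < N; ++i) {
        const double a = absr[i];
        const double v = (a >= delta) ? a : beta * rho[i] + (1.0 - 2.0 * beta) * a;
        rho[i] = std::fabs(v);
      }
    }
  }

  NumericVector phases(m.n_u), e_calc(m.n_u);
  for (int u = 0; u < m.n_u; ++u) {
    phases[u] = std::atan2(F[u].imag(), F[u].real());
    e_calc[u] = std::abs(F[u]);
  }
  List out = List::create(
      _["cc_trace"] = cc_trace, _["phases"] = phases, _["e_calc"] = e_calc,
      _["max_imag_ratio"] = max_imag_ratio, _["max_abs_mean"] = max_abs_mean,
      _["ok"] = ok);
  if (return_density) {
    NumericVector d(N);
    std::copy(rho.begin(), rho.end(), d.begin());
    d.attr("dim") = dims;
    out["density"] = d;
  }
  return out;
}
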