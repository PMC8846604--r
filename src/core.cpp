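// Numerical kernels: windowed-sinc resampling, NCC similarity grids,
// sub-sample peak refinement, Bayesian regularization of lag surfaces,
// and RF speckle rendering.  All grids are stored column-major as in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Hann-windowed sinc, half-width `taps` samples; h(0)=1, h(n)=0 at other integers.
static inline double wsinc(double x, int taps) {
  double ax = std::fabs(x);
  if (ax >= taps) return 0.0;
  if (ax < 1e-12) return 1.0;
  if (std::fabs(x - std::nearbyint(x)) < 1e-12) return 0.0;  // exact at nodes
  double s = std::sin(M_PI * x) / (M_PI * x);
  double w = 0.5 * (1.0 + std::cos(M_PI * x / taps));
  return s * w;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// ---------------------------------------------------------------------------
// Windowed-sinc up-sampling along rows then columns.  Output grid positions are
// k/f on the input index axis, k = 0..n*f-1; original samples are preserved at
// their nodes.  Edges handled by replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2d(const NumericMatrix& m, int fa, int fl, int taps) {
  int nr = m.nrow(), nc = m.ncol();
  int nro = nr * fa, nco = nc * fl;
  // axial pass
  NumericMatrix tmp(nro, nc);
  for (int c = 0; c < nc; ++c) {
    for (int k = 0; k < nro; ++k) {
      double x = (double)k / fa;
      if (fa == 1) { tmp(k, c) = m(k, c); continue; }
      int lo = (int)std::ceil(x - taps), hi = (int)std::floor(x + taps);
      double acc = 0.0;
      for (int i = lo; i <= hi; ++i)
        acc += m(clampi(i, 0, nr - 1), c) * wsinc(x - i, taps);
      tmp(k, c) = acc;
    }
  }
  if (fl == 1) return tmp;
  NumericMatrix out(nro, nco);
  for (int r = 0; r < nro; ++r) {
    for (int k = 0; k < nco; ++k) {
      double x = (double)k / fl;
      int lo = (int)std::ceil(x - taps), hi = (int)std::floor(x + taps);
      double acc = 0.0;
      for (int j = lo; j <= hi; ++j)
        acc += tmp(r, clampi(j, 0, nc - 1)) * wsinc(x - j, taps);
      out(r, k) = acc;
    }
  }
  return out;
}

// Anti-aliased decimation: windowed-sinc low-pass at cutoff 1/f (kernel sum
// normalized to 1 so DC is preserved), then every f-th sample.
static void lowpass_axis(const NumericMatrix& in, NumericMatrix& out,
                         int f, int taps, bool rows) {
  int half = taps * f;
  std::vector<double> g(2 * half + 1);
  double s = 0.0;
  for (int n = -half; n <= half; ++n) {
    double v = wsinc((double)n / f, taps) / f;
    g[n + half] = v; s += v;
  }
  for (double& v : g) v /= s;
  int nr = in.nrow(), nc = in.ncol();
  if (rows) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double acc = 0.0;
        for (int n = -half; n <= half; ++n)
          acc += in(clampi(r + n, 0, nr - 1), c) * g[n + half];
        out(r, c) = acc;
      }
  } else {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double acc = 0.0;
        for (int n = -half; n <= half; ++n)
          acc += in(r, clampi(c + n, 0, nc - 1)) * g[n + half];
        out(r, c) = acc;
      }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_decimate2d(const NumericMatrix& m, int fa, int fl, int taps) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix work = clone(m);
  if (fa > 1) {
    NumericMatrix t(nr, nc);
    lowpass_axis(work, t, fa, taps, true);
    work = t;
  }
  if (fl > 1) {
    NumericMatrix t(nr, nc);
    lowpass_axis(work, t, fl, taps, false);
    work = t;
  }
  int nro = (nr - 1) / fa + 1, nco = (nc - 1) / fl + 1;
  NumericMatrix out(nro, nco);
  for (int c = 0; c < nco; ++c)
    for (int r = 0; r < nro; ++r)
      out(r, c) = work(r * fa, c * fl);
  return out;
}

// ---------------------------------------------------------------------------
// Zero-normalized cross-correlation over a lag grid for a set of blocks.
// centres are 0-based kernel-centre indices into `pre`; offa/offl shift the
// lag window per block (search seeded by a coarser level).  Lags whose window
// leaves the frame get value 0 and flag the block; zero-variance kernels or
// windows likewise yield 0 and a flag.
// [[Rcpp::export]]
List cpp_smi_grid(const NumericMatrix& pre, const NumericMatrix& post,
                  const IntegerVector& ctr_r, const IntegerVector& ctr_c,
                  int ka, int kl, int ha, int hl,
                  const IntegerVector& offa, const IntegerVector& offl) {
  int nb = ctr_r.size();
  int la = 2 * ha + 1, ll = 2 * hl + 1;
  int hka = (ka - 1) / 2, hkl = (kl - 1) / 2;
  int nr = pre.nrow(), nc = pre.ncol();
  NumericVector vals(Dimension(la, ll, nb));
  LogicalVector flags(nb);
  int K = ka * kl;
  for (int b = 0; b < nb; ++b) {
    int r0 = ctr_r[b] - hka, c0 = ctr_c[b] - hkl;
    bool flag = false;
    if (r0 < 0 || c0 < 0 || r0 + ka > nr || c0 + kl > nc) {
      flags[b] = true;  // kernel itself out of frame: leave zeros
      continue;
    }
    double amean = 0.0;
    for (int j = 0; j < kl; ++j)
      for (int i = 0; i < ka; ++i) amean += pre(r0 + i, c0 + j);
    amean /= K;
    double avar = 0.0;
    for (int j = 0; j < kl; ++j)
      for (int i = 0; i < ka; ++i) {
        double d = pre(r0 + i, c0 + j) - amean;
        avar += d * d;
      }
    if (avar < 1e-300) { flags[b] = true; continue; }
    for (int jl = 0; jl < ll; ++jl) {
      int dl = offl[b] + jl - hl;
      for (int il = 0; il < la; ++il) {
        int da = offa[b] + il - ha;
        int rr = r0 + da, cc = c0 + dl;
        if (rr < 0 || cc < 0 || rr + ka > nr || cc + kl > nc) {
          flag = true;  // window clipped off-frame
          continue;     // value stays 0
        }
        double bmean = 0.0;
        for (int j = 0; j < kl; ++j)
          for (int i = 0; i < ka; ++i) bmean += post(rr + i, cc + j);
        bmean /= K;
        double num = 0.0, bvar = 0.0;
        for (int j = 0; j < kl; ++j)
          for (int i = 0; i < ka; ++i) {
            double u = pre(r0 + i, c0 + j) - amean;
            double v = post(rr + i, cc + j) - bmean;
            num += u * v; bvar += v * v;
          }
        if (bvar < 1e-300) { flag = true; continue; }
        vals[il + la * (jl + ll * b)] = num / std::sqrt(avar * bvar);
      }
    }
    flags[b] = flag;
  }
  return List::create(_["values"] = vals, _["flags"] = flags);
}

// ---------------------------------------------------------------------------
// Sub-sample peak of a lag surface by two-stage evaluation of its 2-D
// windowed-sinc interpolant (coarse 0.1-lag pass over +/-1 lag, then a
// `step`-lag pass over +/-10*step).  Ties at the integer stage break to the
// smallest Euclidean displacement magnitude, then smallest axial lag.
// When `guard` is true and the integer peak reaches 1 within 1e-9 the match is
// exact (perfect correlation) and refinement is skipped.  Boundary maxima and
// flat surfaces return the integer result with flag 2 / 1.
// Returns c(axial, lateral, flag) displacement including the lag offset.
// [[Rcpp::export]]
NumericVector cpp_subsample_peak(const NumericMatrix& s, int offa, int offl,
                                 double step, int taps, bool guard) {
  int m = s.nrow(), n = s.ncol();
  int ha = (m - 1) / 2, hl = (n - 1) / 2;
  int bi = 0, bj = 0;
  double bv = -std::numeric_limits<double>::infinity(), bmag = 0, blag = 0;
  bool flat = true;
  double v0 = s(0, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      double v = s(i, j);
      if (std::fabs(v - v0) > 0) flat = false;
      double da = offa + i - ha, dl = offl + j - hl;
      double mag = da * da + dl * dl;
      if (v > bv || (v == bv && (mag < bmag || (mag == bmag && std::fabs(da) < blag)))) {
        bv = v; bi = i; bj = j; bmag = mag; blag = std::fabs(da);
      }
    }
  double ia = offa + bi - ha, il = offl + bj - hl;
  if (flat) return NumericVector::create(0.0, 0.0, 1.0);
  if (guard && bv >= 1.0 - 1e-9)
    return NumericVector::create(ia, il, 0.0);
  if (bi == 0 || bi == m - 1 || bj == 0 || bj == n - 1)
    return NumericVector::create(ia, il, 2.0);

  // separable interpolant evaluation: S = Wa %*% s %*% t(Wl).  The kernel
  // half-width is capped per axis at the available surface support --
  // letting it overhang the surface edge truncates the sinc asymmetrically
  // and biases the refined peak.
  int taps_a = std::min(taps, m - 1) > 0 ? std::min(taps, m - 1) : 1;
  int taps_l = std::min(taps, n - 1) > 0 ? std::min(taps, n - 1) : 1;
  auto refine = [&](double ca, double cl, double half, double st,
                    double& oa, double& ol) {
    int np = (int)std::round(2 * half / st) + 1;
    std::vector<double> xs(np), ys(np);
    for (int k = 0; k < np; ++k) { xs[k] = ca - half + k * st; ys[k] = cl - half + k * st; }
    std::vector<double> Wa(np * m), Wl(np * n);
    for (int k = 0; k < np; ++k) {
      for (int i = 0; i < m; ++i) Wa[k + np * i] = wsinc(xs[k] - i, taps_a);
      for (int j = 0; j < n; ++j) Wl[k + np * j] = wsinc(ys[k] - j, taps_l);
    }
    std::vector<double> T(np * n, 0.0);  // Wa %*% s
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i) {
        double sv = s(i, j);
        if (sv == 0.0) continue;
        for (int k = 0; k < np; ++k) T[k + np * j] += Wa[k + np * i] * sv;
      }
    double best = -std::numeric_limits<double>::infinity();
    double ba = ca, bl = cl, bm = 1e300;
    for (int q = 0; q < np; ++q)
      for (int k = 0; k < np; ++k) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += T[k + np * j] * Wl[q + np * j];
        double da = offa + xs[k] - ha, dl = offl + ys[q] - hl;
        double mag = da * da + dl * dl;
        if (acc > best || (acc == best && mag < bm)) {
          best = acc; ba = xs[k]; bl = ys[q]; bm = mag;
        }
      }
    oa = ba; ol = bl;
  };
  double a1, l1, a2, l2;
  refine((double)bi, (double)bj, 1.0, 0.1, a1, l1);
  refine(a1, l1, 10.0 * step, step, a2, l2);
  return NumericVector::create(offa + a2 - ha, offl + l2 - hl, 0.0);
}

// ---------------------------------------------------------------------------
// Bilinear resample of `frame` at (r + da, c + dl) with edge clamping;
// used for companding (align-and-stretch).
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& frame,
                                const NumericMatrix& da, const NumericMatrix& dl) {
  int nr = frame.nrow(), nc = frame.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double rr = r + da(r, c), cc = c + dl(r, c);
      if (rr < 0) rr = 0; if (rr > nr - 1) rr = nr - 1;
      if (cc < 0) cc = 0; if (cc > nc - 1) cc = nc - 1;
      int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
      int r1 = clampi(r0 + 1, 0, nr - 1), c1 = clampi(c0 + 1, 0, nc - 1);
      double fr = rr - r0, fc = cc - c0;
      out(r, c) = (1 - fr) * ((1 - fc) * frame(r0, c0) + fc * frame(r0, c1)) +
                  fr * ((1 - fc) * frame(r1, c0) + fc * frame(r1, c1));
    }
  return out;
}

// ---------------------------------------------------------------------------
// Bayesian likelihood from one neighbouring PDF surface:
//   L(u) = max over v with |v - u| <= 3 sigma (per axis) of
//          pdf(v) * exp(-(dv_a^2/(2 sa^2) + dv_l^2/(2 sl^2)))
// floored at `floor_v`.  doffa/doffl are the neighbour's lag offset minus the
// current block's, so lag differences compare absolute displacements.
// sigma = Inf gives a flat weight over the whole grid.
static void lik_neighbor(const double* nb, int la, int ll,
                         int doffa, int doffl, double sa, double sl,
                         double floor_v, double* out) {
  bool inf_a = !R_FINITE(sa), inf_l = !R_FINITE(sl);
  double ba = inf_a ? 0.0 : 3.0 * sa, bl = inf_l ? 0.0 : 3.0 * sl;
  for (int ju = 0; ju < ll; ++ju)
    for (int iu = 0; iu < la; ++iu) {
      double best = 0.0;
      int ivlo = 0, ivhi = la - 1, jvlo = 0, jvhi = ll - 1;
      if (!inf_a) {
        ivlo = (int)std::ceil(iu - doffa - ba); ivhi = (int)std::floor(iu - doffa + ba);
        ivlo = clampi(ivlo, 0, la - 1); ivhi = clampi(ivhi, 0, la - 1);
        if (iu - doffa - ba > la - 1 || iu - doffa + ba < 0) { ivlo = 1; ivhi = 0; }
      }
      if (!inf_l) {
        jvlo = (int)std::ceil(ju - doffl - bl); jvhi = (int)std::floor(ju - doffl + bl);
        jvlo = clampi(jvlo, 0, ll - 1); jvhi = clampi(jvhi, 0, ll - 1);
        if (ju - doffl - bl > ll - 1 || ju - doffl + bl < 0) { jvlo = 1; jvhi = 0; }
      }
      for (int jv = jvlo; jv <= jvhi; ++jv) {
        double dl2 = (double)(jv + doffl - ju);
        double wl = inf_l ? 1.0 : std::exp(-dl2 * dl2 / (2.0 * sl * sl));
        for (int iv = ivlo; iv <= ivhi; ++iv) {
          double da2 = (double)(iv + doffa - iu);
          double wa = inf_a ? 1.0 : std::exp(-da2 * da2 / (2.0 * sa * sa));
          double v = nb[iv + la * jv] * wa * wl;
          if (v > best) best = v;
        }
      }
      out[iu + la * ju] = best < floor_v ? floor_v : best;
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_lik_neighbor(const NumericMatrix& nb, int doffa, int doffl,
                               double sa, double sl, double floor_v) {
  int la = nb.nrow(), ll = nb.ncol();
  NumericMatrix out(la, ll);
  lik_neighbor(nb.begin(), la, ll, doffa, doffl, sa, sl, floor_v, out.begin());
  return out;
}

// helper: normalize a lag surface in place to sum 1 (log-domain input)
static void log_normalize(std::vector<double>& lp, double* out, int nlag) {
  double mx = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < nlag; ++k) if (lp[k] > mx) mx = lp[k];
  double s = 0.0;
  for (int k = 0; k < nlag; ++k) { out[k] = std::exp(lp[k] - mx); s += out[k]; }
  for (int k = 0; k < nlag; ++k) out[k] /= s;
}

// ---------------------------------------------------------------------------
// Synchronous SBR over a block grid.  pdf: array (la, ll, nbr, nbc); offsets
// per block.  Each iteration: posterior = prior * prod over available spatial
// neighbours of lik_neighbor, accumulated in the log domain, renormalized.
// [[Rcpp::export]]
NumericVector cpp_sbr_grid(const NumericVector& pdf,
                           const IntegerMatrix& offa, const IntegerMatrix& offl,
                           double sa, double sl, int iters, double floor_v) {
  IntegerVector dim = pdf.attr("dim");
  int la = dim[0], ll = dim[1], nbr = dim[2], nbc = dim[3];
  int nlag = la * ll;
  NumericVector cur = clone(pdf);
  NumericVector nxt(pdf.size());
  std::vector<double> lp(nlag), lik(nlag);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int it = 0; it < iters; ++it) {
    for (int bc = 0; bc < nbc; ++bc)
      for (int br = 0; br < nbr; ++br) {
        const double* pr = &cur[nlag * (br + nbr * bc)];
        for (int k = 0; k < nlag; ++k)
          lp[k] = std::log(pr[k] > 1e-300 ? pr[k] : 1e-300);
        for (int q = 0; q < 4; ++q) {
          int rr = br + dr[q], cc = bc + dc[q];
          if (rr < 0 || rr >= nbr || cc < 0 || cc >= nbc) continue;
          const double* nb = &cur[nlag * (rr + nbr * cc)];
          lik_neighbor(nb, la, ll, offa(rr, cc) - offa(br, bc),
                       offl(rr, cc) - offl(br, bc), sa, sl, floor_v, lik.data());
          for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
        }
        log_normalize(lp, &nxt[nlag * (br + nbr * bc)], nlag);
      }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  cur.attr("dim") = dim;
  return cur;
}

// Temporal combination stage (used by STBR-1): posterior = prior(t) *
// lik(past) * lik(future) per block, log-domain, renormalized.  Missing
// neighbours (has_* false) contribute nothing.
// [[Rcpp::export]]
NumericVector cpp_temporal_grid(const NumericVector& cur,
                                Nullable<NumericVector> past_, Nullable<NumericVector> fut_,
                                const IntegerMatrix& offa, const IntegerMatrix& offl,
                                Nullable<IntegerMatrix> offa_p_, Nullable<IntegerMatrix> offl_p_,
                                Nullable<IntegerMatrix> offa_f_, Nullable<IntegerMatrix> offl_f_,
                                double sta, double stl, double floor_v) {
  IntegerVector dim = cur.attr("dim");
  int la = dim[0], ll = dim[1], nbr = dim[2], nbc = dim[3];
  int nlag = la * ll;
  NumericVector out(cur.size());
  std::vector<double> lp(nlag), lik(nlag);
  bool hp = past_.isNotNull(), hf = fut_.isNotNull();
  NumericVector past, fut; IntegerMatrix oap, olp, oaf, olf;
  if (hp) { past = past_.get(); oap = offa_p_.get(); olp = offl_p_.get(); }
  if (hf) { fut = fut_.get(); oaf = offa_f_.get(); olf = offl_f_.get(); }
  for (int bc = 0; bc < nbc; ++bc)
    for (int br = 0; br < nbr; ++br) {
      int b = br + nbr * bc;
      const double* pr = &cur[nlag * b];
      for (int k = 0; k < nlag; ++k)
        lp[k] = std::log(pr[k] > 1e-300 ? pr[k] : 1e-300);
      if (hp) {
        lik_neighbor(&past[nlag * b], la, ll, oap(br, bc) - offa(br, bc),
                     olp(br, bc) - offl(br, bc), sta, stl, floor_v, lik.data());
        for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
      }
      if (hf) {
        lik_neighbor(&fut[nlag * b], la, ll, oaf(br, bc) - offa(br, bc),
                     olf(br, bc) - offl(br, bc), sta, stl, floor_v, lik.data());
        for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
      }
      log_normalize(lp, &out[nlag * b], nlag);
    }
  out.attr("dim") = dim;
  return out;
}

// Simultaneous spatiotemporal regularization (STBR-2): posterior = prior(t) *
// prod spatial lik (sigma_eps-coupled) * lik(past) * lik(future)
// (sigma_t-coupled); temporal neighbours stay the unregularized grids across
// iterations, spatial likelihoods come from the pre-iteration t grid.
// [[Rcpp::export]]
NumericVector cpp_stbr2_grid(const NumericVector& pdf,
                             Nullable<NumericVector> past_, Nullable<NumericVector> fut_,
                             const IntegerMatrix& offa, const IntegerMatrix& offl,
                             Nullable<IntegerMatrix> offa_p_, Nullable<IntegerMatrix> offl_p_,
                             Nullable<IntegerMatrix> offa_f_, Nullable<IntegerMatrix> offl_f_,
                             double sa, double sl, double sta, double stl,
                             int iters, double floor_v) {
  IntegerVector dim = pdf.attr("dim");
  int la = dim[0], ll = dim[1], nbr = dim[2], nbc = dim[3];
  int nlag = la * ll;
  NumericVector cur = clone(pdf), nxt(pdf.size());
  std::vector<double> lp(nlag), lik(nlag);
  bool hp = past_.isNotNull(), hf = fut_.isNotNull();
  NumericVector past, fut; IntegerMatrix oap, olp, oaf, olf;
  if (hp) { past = past_.get(); oap = offa_p_.get(); olp = offl_p_.get(); }
  if (hf) { fut = fut_.get(); oaf = offa_f_.get(); olf = offl_f_.get(); }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int it = 0; it < iters; ++it) {
    for (int bc = 0; bc < nbc; ++bc)
      for (int br = 0; br < nbr; ++br) {
        int b = br + nbr * bc;
        const double* pr = &cur[nlag * b];
        for (int k = 0; k < nlag; ++k)
          lp[k] = std::log(pr[k] > 1e-300 ? pr[k] : 1e-300);
        for (int q = 0; q < 4; ++q) {
          int rr = br + dr[q], cc = bc + dc[q];
          if (rr < 0 || rr >= nbr || cc < 0 || cc >= nbc) continue;
          lik_neighbor(&cur[nlag * (rr + nbr * cc)], la, ll,
                       offa(rr, cc) - offa(br, bc), offl(rr, cc) - offl(br, bc),
                       sa, sl, floor_v, lik.data());
          for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
        }
        if (hp) {
          lik_neighbor(&past[nlag * b], la, ll, oap(br, bc) - offa(br, bc),
                       olp(br, bc) - offl(br, bc), sta, stl, floor_v, lik.data());
          for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
        }
        if (hf) {
          lik_neighbor(&fut[nlag * b], la, ll, oaf(br, bc) - offa(br, bc),
                       olf(br, bc) - offl(br, bc), sta, stl, floor_v, lik.data());
          for (int k = 0; k < nlag; ++k) lp[k] += std::log(lik[k]);
        }
        log_normalize(lp, &nxt[nlag * b], nlag);
      }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  cur.attr("dim") = dim;
  return cur;
}

// ---------------------------------------------------------------------------
// Bilinear interpolation of block-grid values at scattered query points.
// cr/cc are strictly increasing grid coordinates; queries outside the grid
// clamp to the edge value.
// [[Rcpp::export]]
NumericVector cpp_interp_grid(const NumericMatrix& vals,
                              const NumericVector& cr, const NumericVector& cc,
                              const NumericVector& qr, const NumericVector& qc) {
  int nr = cr.size(), nc = cc.size(), nq = qr.size();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double r = qr[q], c = qc[q];
    int i = (int)(std::upper_bound(cr.begin(), cr.end(), r) - cr.begin()) - 1;
    int j = (int)(std::upper_bound(cc.begin(), cc.end(), c) - cc.begin()) - 1;
    i = clampi(i, 0, nr - 2 >= 0 ? nr - 2 : 0);
    j = clampi(j, 0, nc - 2 >= 0 ? nc - 2 : 0);
    double fr = 0.0, fc = 0.0;
    if (nr > 1) fr = (r - cr[i]) / (cr[i + 1] - cr[i]);
    if (nc > 1) fc = (c - cc[j]) / (cc[j + 1] - cc[j]);
    if (fr < 0) fr = 0; if (fr > 1) fr = 1;
    if (fc < 0) fc = 0; if (fc > 1) fc = 1;
    int i1 = nr > 1 ? i + 1 : i, j1 = nc > 1 ? j + 1 : j;
    out[q] = (1 - fr) * ((1 - fc) * vals(i, j) + fc * vals(i, j1)) +
             fr * ((1 - fc) * vals(i1, j) + fc * vals(i1, j1));
  }
  return out;
}

// ---------------------------------------------------------------------------
// RF speckle rendering: sum of separable point-spread functions
// (Gaussian envelope x cosine carrier axially, Gaussian laterally) at each
// scatterer position (in fractional sample / line units).
// [[Rcpp::export]]
NumericMatrix cpp_render_rf(const NumericVector& zs, const NumericVector& xs,
                            const NumericVector& amp, int n_samp, int n_lines,
                            double carrier, double sig_a, double sig_l) {
  NumericMatrix out(n_samp, n_lines);
  double ra = 4.0 * sig_a, rl = 4.0 * sig_l;
  int ns = zs.size();
  for (int s = 0; s < ns; ++s) {
    int r0 = (int)std::ceil(zs[s] - ra), r1 = (int)std::floor(zs[s] + ra);
    int c0 = (int)std::ceil(xs[s] - rl), c1 = (int)std::floor(xs[s] + rl);
    if (r1 < 0 || r0 > n_samp - 1 || c1 < 0 || c0 > n_lines - 1) continue;
    r0 = clampi(r0, 0, n_samp - 1); r1 = clampi(r1, 0, n_samp - 1);
    c0 = clampi(c0, 0, n_lines - 1); c1 = clampi(c1, 0, n_lines - 1);
    for (int c = c0; c <= c1; ++c) {
      double dc = c - xs[s];
      double wl = std::exp(-dc * dc / (2.0 * sig_l * sig_l));
      for (int r = r0; r <= r1; ++r) {
        double dr = r - zs[s];
        out(r, c) += amp[s] * wl *
          std::exp(-dr * dr / (2.0 * sig_a * sig_a)) * std::cos(carrier * dr);
      }
    }
  }
  return out;
}
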