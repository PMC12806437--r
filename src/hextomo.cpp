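// Compiled core: hexplane scene evaluation with analytic gradients, ray
// quadrature rendering, the Adam training loop, a dense reference projector,
// slice-wise backprojection, and 3D connected-component labelling.
//
// Conventions (shared with the R layer; see R/forward.R):
//   * volume normalized to [-1,1]^3, time to [-1,1];
//   * theta = 0 sends rays along +y; rotation is CCW about +z;
//   * detector columns map to the rotated lateral (+x at theta=0) axis,
//     detector rows map to +z;
//   * plane order: xy, zt, xz, yt, yz, xt  (coordinate pairs).

#include <RcppArmadillo.h>
#include <random>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Scene {
  std::vector<arma::cube> P;   // six planes, each n1 x n2 x F
  std::vector<arma::mat>  W;   // MLP weights, out x in
  std::vector<arma::vec>  b;   // biases
  int fusion;                  // 0 = concat (6F), 1 = paired-product (3F)
  int act;                     // 0 = softplus, 1 = linear
  int F, D, outc, nlayer;      // nlayer = number of weight matrices
};

// deep copies: the as<> exporters may alias R memory, and the training loop
// updates parameters in place, so the caller's objects must never be shared
arma::cube cubeCopy(SEXP x) {
  NumericVector v(x);
  IntegerVector d = v.attr("dim");
  return arma::cube(v.begin(), d[0], d[1], d.size() > 2 ? d[2] : 1, true);
}

arma::mat matCopy(SEXP x) {
  NumericMatrix m(x);
  return arma::mat(m.begin(), m.nrow(), m.ncol(), true);
}

arma::vec vecCopy(SEXP x) {
  NumericVector v(x);
  return arma::vec(v.begin(), v.size(), true);
}

Scene unpackScene(const List& planes, const List& W, const List& b,
                  int fusion, int act) {
  Scene s;
  s.P.reserve(6);
  for (int i = 0; i < 6; ++i) s.P.push_back(cubeCopy(planes[i]));
  const int L = W.size();
  for (int i = 0; i < L; ++i) {
    s.W.push_back(matCopy(W[i]));
    s.b.push_back(vecCopy(b[i]));
  }
  s.fusion = fusion;
  s.act    = act;
  s.F      = s.P[0].n_slices;
  s.D      = (fusion == 0) ? 6 * s.F : 3 * s.F;
  s.outc   = s.W.back().n_rows;
  s.nlayer = L;
  return s;
}

// bilinear interpolation bookkeeping for one plane over a batch of points
struct InterpCache {
  arma::uvec i0, j0;   // lower corner indices
  arma::vec  fi, fj;   // fractional offsets in [0,1]
};

// map u in [-1,1] (clamped) to grid coordinate on n nodes
inline void gridCoord(double u, int n, arma::uword& i0, double& fi) {
  double g = (u + 1.0) * 0.5 * (n - 1);
  if (g < 0.0) g = 0.0;
  if (g > n - 1.0) g = (double)(n - 1);
  int i = (int)std::floor(g);
  if (i > n - 2) i = n - 2;
  i0 = (arma::uword)i;
  fi = g - i;
}

// which point coordinates feed plane p (order xy, zt, xz, yt, yz, xt)
inline void planeCoords(int p, double x, double y, double z, double t,
                        double& u, double& v) {
  switch (p) {
    case 0: u = x; v = y; break;
    case 1: u = z; v = t; break;
    case 2: u = x; v = z; break;
    case 3: u = y; v = t; break;
    case 4: u = y; v = z; break;
    default: u = x; v = t; break;
  }
}

// interpolate all six planes at the batch of points (B x 4, cols x,y,z,t);
// fills planeFeat[p] (F x B) and caches
void interpPlanes(const Scene& s, const arma::mat& pts,
                  std::vector<arma::mat>& planeFeat,
                  std::vector<InterpCache>& cache) {
  const arma::uword B = pts.n_rows;
  const int F = s.F;
  planeFeat.assign(6, arma::mat(F, B));
  cache.assign(6, InterpCache());
  for (int p = 0; p < 6; ++p) {
    const arma::cube& pl = s.P[p];
    const int n1 = pl.n_rows, n2 = pl.n_cols;
    InterpCache& c = cache[p];
    c.i0.set_size(B); c.j0.set_size(B);
    c.fi.set_size(B); c.fj.set_size(B);
    arma::mat& feat = planeFeat[p];
    const double* base = pl.memptr();
    const arma::uword stride = (arma::uword)n1 * n2;
    double* fout = feat.memptr();
    for (arma::uword n = 0; n < B; ++n) {
      double u, v;
      planeCoords(p, pts.at(n, 0), pts.at(n, 1), pts.at(n, 2), pts.at(n, 3),
                  u, v);
      arma::uword i0, j0; double fi, fj;
      gridCoord(u, n1, i0, fi);
      gridCoord(v, n2, j0, fj);
      c.i0(n) = i0; c.j0(n) = j0; c.fi(n) = fi; c.fj(n) = fj;
      const double w00 = (1 - fi) * (1 - fj), w10 = fi * (1 - fj),
                   w01 = (1 - fi) * fj,       w11 = fi * fj;
      const double* p00 = base + i0 + (arma::uword)n1 * j0;
      double* fo = fout + (arma::uword)F * n;
      for (int k = 0; k < F; ++k) {
        const double* q = p00 + stride * (arma::uword)k;
        fo[k] = w00 * q[0] + w10 * q[1] + w01 * q[n1] + w11 * q[n1 + 1];
      }
    }
  }
}

// fuse per-plane features into the descriptor matrix (D x B)
arma::mat fuseFeatures(const Scene& s, const std::vector<arma::mat>& pf) {
  const arma::uword B = pf[0].n_cols;
  arma::mat X(s.D, B);
  if (s.fusion == 0) {
    for (int p = 0; p < 6; ++p)
      X.rows(p * s.F, (p + 1) * s.F - 1) = pf[p];
  } else {
    for (int q = 0; q < 3; ++q)
      X.rows(q * s.F, (q + 1) * s.F - 1) = pf[2 * q] % pf[2 * q + 1];
  }
  return X;
}

inline double softplus(double u) {
  return (u > 30.0) ? u : std::log1p(std::exp(u));
}
inline double sigmoidf(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// MLP forward; caches activations (A[0] = input) and pre-activation U of the
// output layer for the backward pass
struct MlpCache {
  std::vector<arma::mat> A;  // activations per layer, A[0]=X
  arma::mat U;               // output pre-activation (outc x B)
};

arma::mat mlpForward(const Scene& s, const arma::mat& X, MlpCache* mc) {
  arma::mat A = X;
  if (mc) { mc->A.clear(); mc->A.push_back(A); }
  for (int l = 0; l < s.nlayer - 1; ++l) {
    arma::mat Z = s.W[l] * A;
    Z.each_col() += s.b[l];
    A = arma::clamp(Z, 0.0, arma::datum::inf);   // ReLU
    if (mc) mc->A.push_back(A);
  }
  arma::mat U = s.W[s.nlayer - 1] * A;
  U.each_col() += s.b[s.nlayer - 1];
  if (mc) mc->U = U;
  arma::mat Y(U.n_rows, U.n_cols);
  if (s.act == 0) {
    for (arma::uword j = 0; j < U.n_elem; ++j) Y(j) = softplus(U(j));
  } else {
    Y = U;
  }
  return Y;
}

struct Grads {
  std::vector<arma::cube> gP;
  std::vector<arma::mat>  gW;
  std::vector<arma::vec>  gb;
};

void zeroGrads(const Scene& s, Grads& g) {
  g.gP.clear(); g.gW.clear(); g.gb.clear();
  for (int p = 0; p < 6; ++p)
    g.gP.push_back(arma::zeros<arma::cube>(s.P[p].n_rows, s.P[p].n_cols, s.F));
  for (int l = 0; l < s.nlayer; ++l) {
    g.gW.push_back(arma::zeros<arma::mat>(s.W[l].n_rows, s.W[l].n_cols));
    g.gb.push_back(arma::zeros<arma::vec>(s.b[l].n_elem));
  }
}

// backward through MLP and plane interpolation; dY is outc x B
void backward(const Scene& s, const MlpCache& mc,
              const std::vector<arma::mat>& planeFeat,
              const std::vector<InterpCache>& cache,
              const arma::mat& dY, Grads& g) {
  const arma::uword B = dY.n_cols;
  arma::mat delta(dY.n_rows, B);
  if (s.act == 0) {
    for (arma::uword j = 0; j < dY.n_elem; ++j)
      delta(j) = dY(j) * sigmoidf(mc.U(j));
  } else {
    delta = dY;
  }
  for (int l = s.nlayer - 1; l >= 0; --l) {
    g.gW[l] += delta * mc.A[l].t();
    g.gb[l] += arma::sum(delta, 1);
    if (l > 0) {
      arma::mat dA = s.W[l].t() * delta;
      delta = dA % arma::conv_to<arma::mat>::from(mc.A[l] > 0.0);
    } else {
      arma::mat dX = s.W[0].t() * delta;   // D x B
      // un-fuse into per-plane feature gradients
      std::vector<arma::mat> dPF(6);
      if (s.fusion == 0) {
        for (int p = 0; p < 6; ++p)
          dPF[p] = dX.rows(p * s.F, (p + 1) * s.F - 1);
      } else {
        for (int q = 0; q < 3; ++q) {
          arma::mat dq = dX.rows(q * s.F, (q + 1) * s.F - 1);
          dPF[2 * q]     = dq % planeFeat[2 * q + 1];
          dPF[2 * q + 1] = dq % planeFeat[2 * q];
        }
      }
      // scatter through the bilinear weights
      for (int p = 0; p < 6; ++p) {
        const InterpCache& c = cache[p];
        arma::cube& gp = g.gP[p];
        const arma::uword n1 = gp.n_rows;
        const arma::uword stride = n1 * gp.n_cols;
        double* base = gp.memptr();
        const double* dsrc = dPF[p].memptr();
        for (arma::uword n = 0; n < B; ++n) {
          const arma::uword i0 = c.i0(n), j0 = c.j0(n);
          const double fi = c.fi(n), fj = c.fj(n);
          const double w00 = (1 - fi) * (1 - fj), w10 = fi * (1 - fj),
                       w01 = (1 - fi) * fj,       w11 = fi * fj;
          double* p00 = base + i0 + n1 * j0;
          const double* dn = dsrc + (arma::uword)s.F * n;
          for (int k = 0; k < s.F; ++k) {
            double* q = p00 + stride * (arma::uword)k;
            const double d = dn[k];
            q[0] += w00 * d; q[1] += w10 * d;
            q[n1] += w01 * d; q[n1 + 1] += w11 * d;
          }
        }
      }
    }
  }
}

// slab intersection of ray with the [-1,1]^3 cube; returns false on miss
bool cubeIntersect(const arma::rowvec3& o, const arma::rowvec3& d,
                   double& t0, double& t1) {
  t0 = -arma::datum::inf; t1 = arma::datum::inf;
  for (int a = 0; a < 3; ++a) {
    if (std::abs(d(a)) < 1e-12) {
      if (o(a) < -1.0 || o(a) > 1.0) return false;
    } else {
      double ta = (-1.0 - o(a)) / d(a), tb = (1.0 - o(a)) / d(a);
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  return t1 > t0;
}

// regularizer: tv = mean over planes of (mean squared forward difference over
// both axes and all channels); l1 = mean over planes of mean |value|
void regularizer(const Scene& s, double& tv, double& l1) {
  tv = 0.0; l1 = 0.0;
  for (int p = 0; p < 6; ++p) {
    const arma::cube& pl = s.P[p];
    const int n1 = pl.n_rows, n2 = pl.n_cols, F = pl.n_slices;
    double acc = 0.0;
    for (int k = 0; k < F; ++k) {
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i + 1 < n1; ++i) {
          double d = pl(i + 1, j, k) - pl(i, j, k); acc += d * d;
        }
      for (int j = 0; j + 1 < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double d = pl(i, j + 1, k) - pl(i, j, k); acc += d * d;
        }
    }
    const double nd = (double)F * ((n1 - 1) * n2 + n1 * (n2 - 1));
    tv += acc / nd;
    l1 += arma::accu(arma::abs(pl)) / (double)pl.n_elem;
  }
  tv /= 6.0; l1 /= 6.0;
}

void regularizerGrad(const Scene& s, double wTv, double wL1, Grads& g) {
  for (int p = 0; p < 6; ++p) {
    const arma::cube& pl = s.P[p];
    arma::cube& gp = g.gP[p];
    const int n1 = pl.n_rows, n2 = pl.n_cols, F = pl.n_slices;
    const double nd = (double)F * ((n1 - 1) * n2 + n1 * (n2 - 1));
    const double ctv = wTv / (6.0 * nd);
    const double cl1 = wL1 / (6.0 * (double)pl.n_elem);
    for (int k = 0; k < F; ++k) {
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i + 1 < n1; ++i) {
          const double d = pl(i + 1, j, k) - pl(i, j, k);
          gp(i + 1, j, k) += 2.0 * ctv * d;
          gp(i,     j, k) -= 2.0 * ctv * d;
        }
      for (int j = 0; j + 1 < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const double d = pl(i, j + 1, k) - pl(i, j, k);
          gp(i, j + 1, k) += 2.0 * ctv * d;
          gp(i, j,     k) -= 2.0 * ctv * d;
        }
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const double v = pl(i, j, k);
          gp(i, j, k) += cl1 * ((v > 0) - (v < 0));
        }
    }
  }
}

// forward (and optional backward) pass over a batch of rays:
// per ray, n_samp quadrature points; per-ray quadrature weight chord/n_samp.
// On return pred is outc x B. When grads != nullptr, targets must hold one
// value per ray and channel selects the loss channel; returns the data term.
double rayBatch(const Scene& s,
                const arma::mat& origins, const arma::mat& dirs,
                const arma::vec& tnorm, int nSamp, bool stratified,
                std::mt19937_64* rng, arma::mat& pred,
                const arma::vec* targets, int channel, Grads* grads) {
  const arma::uword B = origins.n_rows;
  pred.zeros(s.outc, B);
  std::vector<arma::uword> rayOf;   // sample -> ray
  arma::mat pts(B * (arma::uword)nSamp, 4);
  arma::vec wq(B * (arma::uword)nSamp, arma::fill::zeros);
  rayOf.reserve(B * nSamp);
  arma::uword m = 0;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (arma::uword r = 0; r < B; ++r) {
    arma::rowvec3 o = origins.row(r), d = dirs.row(r);
    double t0, t1;
    if (!cubeIntersect(o, d, t0, t1)) continue;
    const double chord = t1 - t0, h = chord / nSamp;
    for (int i = 0; i < nSamp; ++i) {
      const double u = stratified && rng ? U(*rng) : 0.5;
      const double tt = t0 + (i + u) * h;
      pts(m, 0) = o(0) + tt * d(0);
      pts(m, 1) = o(1) + tt * d(1);
      pts(m, 2) = o(2) + tt * d(2);
      pts(m, 3) = tnorm(r);
      wq(m) = h;
      rayOf.push_back(r);
      ++m;
    }
  }
  pts.resize(m, 4);
  wq.resize(m);
  if (m == 0) return targets ? arma::mean(arma::square(*targets)) : 0.0;

  std::vector<arma::mat> planeFeat;
  std::vector<InterpCache> cache;
  interpPlanes(s, pts, planeFeat, cache);
  arma::mat X = fuseFeatures(s, planeFeat);
  MlpCache mc;
  arma::mat Y = mlpForward(s, X, grads ? &mc : nullptr);
  for (arma::uword j = 0; j < m; ++j)
    for (int c = 0; c < s.outc; ++c)
      pred(c, rayOf[j]) += wq(j) * Y(c, j);

  double data = 0.0;
  if (targets) {
    arma::vec res(B);
    for (arma::uword r = 0; r < B; ++r)
      res(r) = pred(channel, r) - (*targets)(r);
    data = arma::mean(arma::square(res));
    if (grads) {
      arma::mat dY(s.outc, m, arma::fill::zeros);
      const double c2 = 2.0 / (double)B;
      for (arma::uword j = 0; j < m; ++j)
        dY(channel, j) = c2 * res(rayOf[j]) * wq(j);
      backward(s, mc, planeFeat, cache, dY, *grads);
    }
  }
  return data;
}

struct Adam {
  std::vector<arma::cube> mP, vP;
  std::vector<arma::mat>  mW, vW;
  std::vector<arma::vec>  mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  void init(const Scene& s) {
    for (int p = 0; p < 6; ++p) {
      mP.push_back(arma::zeros<arma::cube>(s.P[p].n_rows, s.P[p].n_cols, s.F));
      vP.push_back(arma::zeros<arma::cube>(s.P[p].n_rows, s.P[p].n_cols, s.F));
    }
    for (int l = 0; l < s.nlayer; ++l) {
      mW.push_back(arma::zeros<arma::mat>(s.W[l].n_rows, s.W[l].n_cols));
      vW.push_back(arma::zeros<arma::mat>(s.W[l].n_rows, s.W[l].n_cols));
      mb.push_back(arma::zeros<arma::vec>(s.b[l].n_elem));
      vb.push_back(arma::zeros<arma::vec>(s.b[l].n_elem));
    }
  }
  template <typename T>
  void upd(T& x, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double c1 = 1.0 - std::pow(b1, (double)step);
    const double c2 = 1.0 - std::pow(b2, (double)step);
    x -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void apply(Scene& s, const Grads& g, double lrP, double lrM) {
    ++step;
    for (int p = 0; p < 6; ++p) upd(s.P[p], mP[p], vP[p], g.gP[p], lrP);
    for (int l = 0; l < s.nlayer; ++l) {
      upd(s.W[l], mW[l], vW[l], g.gW[l], lrM);
      upd(s.b[l], mb[l], vb[l], g.gb[l], lrM);
    }
  }
};

List packScene(const Scene& s) {
  List planes(6), W(s.nlayer), b(s.nlayer);
  for (int p = 0; p < 6; ++p) planes[p] = wrap(s.P[p]);
  for (int l = 0; l < s.nlayer; ++l) { W[l] = wrap(s.W[l]); b[l] = wrap(s.b[l]); }
  return List::create(_["planes"] = planes, _["W"] = W, _["b"] = b);
}

} // namespace

// [[Rcpp::export]]
arma::mat cpp_scene_features(List planes, int fusion, arma::mat pts, int F) {
  Scene s;
  for (int i = 0; i < 6; ++i) s.P.push_back(cubeCopy(planes[i]));
  s.fusion = fusion; s.F = F; s.D = (fusion == 0) ? 6 * F : 3 * F;
  std::vector<arma::mat> pf; std::vector<InterpCache> cache;
  interpPlanes(s, pts, pf, cache);
  return fuseFeatures(s, pf).t();   // B x D
}

// [[Rcpp::export]]
arma::mat cpp_mlp_decode(List W, List b, arma::mat descriptors, int act) {
  Scene s;
  const int L = W.size();
  for (int i = 0; i < L; ++i) {
    s.W.push_back(as<arma::mat>(W[i]));
    s.b.push_back(as<arma::vec>(b[i]));
  }
  s.nlayer = L; s.act = act; s.outc = s.W.back().n_rows;
  return mlpForward(s, descriptors.t(), nullptr).t();   // B x outc
}

// [[Rcpp::export]]
arma::mat cpp_scene_eval(List planes, List W, List b, int fusion, int act,
                         arma::mat pts) {
  Scene s = unpackScene(planes, W, b, fusion, act);
  std::vector<arma::mat> pf; std::vector<InterpCache> cache;
  interpPlanes(s, pts, pf, cache);
  arma::mat X = fuseFeatures(s, pf);
  return mlpForward(s, X, nullptr).t();   // B x outc
}

// [[Rcpp::export]]
arma::mat cpp_render_rays(List planes, List W, List b, int fusion, int act,
                          arma::mat origins, arma::mat dirs, arma::vec tnorm,
                          int n_samples, bool stratified, double seed) {
  Scene s = unpackScene(planes, W, b, fusion, act);
  std::mt19937_64 rng((uint64_t)seed);
  arma::mat pred;
  rayBatch(s, origins, dirs, tnorm, n_samples, stratified,
           stratified ? &rng : nullptr, pred, nullptr, 0, nullptr);
  return pred.t();   // B x outc
}

// [[Rcpp::export]]
List cpp_loss_grad(List planes, List W, List b, int fusion, int act,
                   arma::mat origins, arma::mat dirs, arma::vec tnorm,
                   arma::vec targets, int channel, int n_samples,
                   double lambda_reg, double w_tv, double w_l1) {
  Scene s = unpackScene(planes, W, b, fusion, act);
  Grads g; zeroGrads(s, g);
  arma::mat pred;
  double data = rayBatch(s, origins, dirs, tnorm, n_samples, false, nullptr,
                         pred, &targets, channel, &g);
  double tv, l1; regularizer(s, tv, l1);
  const double reg = w_tv * tv + w_l1 * l1;
  regularizerGrad(s, lambda_reg * w_tv, lambda_reg * w_l1, g);
  List gP(6), gWl(s.nlayer), gbl(s.nlayer);
  for (int p = 0; p < 6; ++p) gP[p] = wrap(g.gP[p]);
  for (int l = 0; l < s.nlayer; ++l) { gWl[l] = wrap(g.gW[l]); gbl[l] = wrap(g.gb[l]); }
  return List::create(_["data"] = data, _["reg"] = reg,
                      _["total"] = data + lambda_reg * reg,
                      _["pred"] = pred.t(),
                      _["grad_planes"] = gP, _["grad_W"] = gWl, _["grad_b"] = gbl);
}

// [[Rcpp::export]]
List cpp_fit(List planes, List W, List b, int fusion, int act,
             arma::cube targets,            // rows x cols x frames
             arma::vec theta_rad, arma::vec tnorm, int channel,
             double pixel_row, double pixel_col,
             int iterations, int rays_per_batch, int n_samples,
             double lr_planes, double lr_mlp, bool cosine_decay,
             double lambda_reg, double w_tv, double w_l1,
             double seed, int log_every) {
  Scene s = unpackScene(planes, W, b, fusion, act);
  Adam opt; opt.init(s);
  std::mt19937_64 rng((uint64_t)seed);
  const int rows = targets.n_rows, cols = targets.n_cols,
            nframes = targets.n_slices;
  const int npix = rows * cols;
  const int batch = std::min(rays_per_batch, npix);
  std::uniform_int_distribution<int> pickFrame(0, nframes - 1);
  std::vector<int> pixIdx(npix);

  std::vector<double> hIt, hData, hReg, hTot, hTime;
  const auto tStart = std::chrono::steady_clock::now();

  arma::mat origins(batch, 3), dirs(batch, 3);
  arma::vec tv(batch), tg(batch);

  for (int it = 0; it < iterations; ++it) {
    const int f = pickFrame(rng);
    const double th = theta_rad(f);
    const double dx = -std::sin(th), dy = std::cos(th);
    const double lx =  std::cos(th), ly = std::sin(th);
    // partial Fisher-Yates draw of `batch` pixels without replacement
    for (int i = 0; i < npix; ++i) pixIdx[i] = i;
    for (int i = 0; i < batch; ++i) {
      std::uniform_int_distribution<int> U(i, npix - 1);
      std::swap(pixIdx[i], pixIdx[U(rng)]);
      const int pr = pixIdx[i] % rows, pc = pixIdx[i] / rows;
      const double sc = (pc - (cols - 1) * 0.5) * pixel_col;
      const double sz = (pr - (rows - 1) * 0.5) * pixel_row;
      origins(i, 0) = sc * lx - 2.0 * dx;
      origins(i, 1) = sc * ly - 2.0 * dy;
      origins(i, 2) = sz;
      dirs(i, 0) = dx; dirs(i, 1) = dy; dirs(i, 2) = 0.0;
      tv(i) = tnorm(f);
      tg(i) = targets(pr, pc, f);
    }
    Grads g; zeroGrads(s, g);
    arma::mat pred;
    const double data = rayBatch(s, origins, dirs, tv, n_samples, true, &rng,
                                 pred, &tg, channel, &g);
    double tvv, l1v; regularizer(s, tvv, l1v);
    const double reg = w_tv * tvv + w_l1 * l1v;
    const double total = data + lambda_reg * reg;
    if (!std::isfinite(total))
      stop("non-finite loss at iteration %d", it + 1);
    regularizerGrad(s, lambda_reg * w_tv, lambda_reg * w_l1, g);
    double decay = 1.0;
    if (cosine_decay && iterations > 1)
      decay = 0.1 + 0.45 * (1.0 + std::cos(M_PI * it / (iterations - 1.0)));
    opt.apply(s, g, lr_planes * decay, lr_mlp * decay);
    if ((it + 1) % log_every == 0 || it == 0 || it == iterations - 1) {
      const auto now = std::chrono::steady_clock::now();
      hIt.push_back(it + 1); hData.push_back(data); hReg.push_back(reg);
      hTot.push_back(total);
      hTime.push_back(std::chrono::duration<double>(now - tStart).count());
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  List out = packScene(s);
  out["history"] = DataFrame::create(
      _["iteration"] = hIt, _["data_loss"] = hData, _["reg_loss"] = hReg,
      _["total_loss"] = hTot, _["elapsed_s"] = hTime);
  return out;
}

// dense reference projector: trilinear sampling of a voxel grid (cell-centred
// on [-1,1]^3, zero outside) at fixed midpoint steps along each detector ray
// [[Rcpp::export]]
arma::mat cpp_project_volume(arma::cube vol, double theta_rad,
                             int rows, int cols,
                             double pixel_row, double pixel_col, double step,
                             bool clamp_edges) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  const double dx = -std::sin(theta_rad), dy = std::cos(theta_rad);
  const double lx =  std::cos(theta_rad), ly = std::sin(theta_rad);
  arma::mat out(rows, cols, arma::fill::zeros);
  auto sample = [&](double x, double y, double z) -> double {
    const double gx = (x + 1.0) * 0.5 * nx - 0.5;
    const double gy = (y + 1.0) * 0.5 * ny - 0.5;
    const double gz = (z + 1.0) * 0.5 * nz - 0.5;
    const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
              k0 = (int)std::floor(gz);
    const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double v = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (clamp_edges) {
            i = std::min(std::max(i, 0), nx - 1);
            j = std::min(std::max(j, 0), ny - 1);
            k = std::min(std::max(k, 0), nz - 1);
          } else if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
            continue;
          }
          const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                           (dk ? fz : 1 - fz);
          v += w * vol(i, j, k);
        }
    return v;
  };
  for (int pc = 0; pc < cols; ++pc) {
    const double sc = (pc - (cols - 1) * 0.5) * pixel_col;
    for (int pr = 0; pr < rows; ++pr) {
      const double sz = (pr - (rows - 1) * 0.5) * pixel_row;
      arma::rowvec3 o = {sc * lx - 2.0 * dx, sc * ly - 2.0 * dy, sz};
      arma::rowvec3 d = {dx, dy, 0.0};
      double t0, t1;
      if (!cubeIntersect(o, d, t0, t1)) continue;
      const double chord = t1 - t0;
      const int ns = std::max(1, (int)std::ceil(chord / step));
      const double h = chord / ns;
      double acc = 0.0;
      for (int i = 0; i < ns; ++i) {
        const double tt = t0 + (i + 0.5) * h;
        acc += sample(o(0) + tt * d(0), o(1) + tt * d(1), sz);
      }
      out(pr, pc) = acc * h;
    }
  }
  return out;
}

// slice-wise parallel-beam backprojection of ramp-filtered projections;
// sino is n_angles x detector_cols, output slice is N x N (x by y),
// weighted pi / n_angles
// [[Rcpp::export]]
arma::mat cpp_backproject(arma::mat fsino, arma::vec theta_rad, int N,
                          double pixel_col) {
  const int nang = fsino.n_rows, C = fsino.n_cols;
  arma::mat out(N, N, arma::fill::zeros);
  const double w = M_PI / nang;
  for (int a = 0; a < nang; ++a) {
    const double ct = std::cos(theta_rad(a)), st = std::sin(theta_rad(a));
    for (int j = 0; j < N; ++j) {
      const double y = -1.0 + (j + 0.5) * 2.0 / N;
      for (int i = 0; i < N; ++i) {
        const double x = -1.0 + (i + 0.5) * 2.0 / N;
        const double ss = x * ct + y * st;
        const double g = ss / pixel_col + (C - 1) * 0.5;
        const int c0 = (int)std::floor(g);
        const double f = g - c0;
        double v = 0.0;
        if (c0 >= 0 && c0 < C) v += (1 - f) * fsino(a, c0);
        if (c0 + 1 >= 0 && c0 + 1 < C) v += f * fsino(a, c0 + 1);
        out(i, j) += w * v;
      }
    }
  }
  return out;
}

// 6-connected 3D component labelling
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int q = idx(i, j, k);
        if (!mask[q] || lab[q]) continue;
        ++next;
        stack.push_back(q);
        lab[q] = next;
        while (!stack.empty()) {
          const int cur = stack.back(); stack.pop_back();
          const int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
          const int di[6] = {1, -1, 0, 0, 0, 0};
          const int dj[6] = {0, 0, 1, -1, 0, 0};
          const int dk[6] = {0, 0, 0, 0, 1, -1};
          for (int m = 0; m < 6; ++m) {
            const int ii = ci + di[m], jj = cj + dj[m], kk = ck + dk[m];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const int qq = idx(ii, jj, kk);
            if (mask[qq] && !lab[qq]) { lab[qq] = next; stack.push_back(qq); }
          }
        }
      }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}
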