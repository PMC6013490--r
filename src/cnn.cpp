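// Compact single-precision 3D convolutional network engine.
//
// Layout: an activation tensor for a batch of B patches of shape
// (nx, ny, nz) with C channels is an arma::fmat of size (B*nx*ny*nz, C);
// rows are sample-major voxel indices (x fastest), columns are channels.
// Convolutions (3x3x3, zero padding 1 on every face) are computed as
// im2col + GEMM: Col (N x C*27) times W (C*27 x Cout) -> Z (N x Cout).
// Hidden layers apply batch normalization and ReLU; the final layer has one
// feature map and (optionally) an elementwise residual addition of the
// network input, so a zeroed final layer reproduces the input exactly.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Layer {
  fmat W;               // (Cin*27) x Cout
  fvec b;               // Cout
  bool bn;
  fvec g, be, rm, rv;   // gamma, beta, running mean/var
  // Adam first/second moments
  fmat mW, vW;
  fvec mb, vb, mg, vg, mbe, vbe;
};

struct Net {
  std::vector<Layer> layers;
  bool residual;
  float bn_eps = 1e-5f;
  float bn_momentum = 0.1f;
};

static const int OFF[27][3] = {
    {-1, -1, -1}, {0, -1, -1}, {1, -1, -1}, {-1, 0, -1}, {0, 0, -1},
    {1, 0, -1},   {-1, 1, -1}, {0, 1, -1},  {1, 1, -1},  {-1, -1, 0},
    {0, -1, 0},   {1, -1, 0},  {-1, 0, 0},  {0, 0, 0},   {1, 0, 0},
    {-1, 1, 0},   {0, 1, 0},   {1, 1, 0},   {-1, -1, 1}, {0, -1, 1},
    {1, -1, 1},   {-1, 0, 1},  {0, 0, 1},   {1, 0, 1},   {-1, 1, 1},
    {0, 1, 1},    {1, 1, 1}};

// scratch storage reused across layers and batches (single-threaded R):
// one im2col buffer per layer (so the backward pass can reuse the forward
// pass's columns) plus one shared buffer for the column gradients
static std::vector<std::vector<float> > g_colbufs;
static std::vector<float> g_dcolbuf;

static fmat col_alias(std::vector<float> &buf, arma::uword nr,
                      arma::uword nc) {
  if (buf.size() < nr * nc) buf.resize(nr * nc);
  return fmat(buf.data(), nr, nc, false, true);
}

// Col[p, c*27+k] = X[p + off_k, c], zero outside the patch.
static void im2col(const fmat &X, fmat &Col, int nx, int ny, int nz, int B) {
  const int N = nx * ny * nz;
  const int C = X.n_cols;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 27; ++k) {
      const int dx = OFF[k][0], dy = OFF[k][1], dz = OFF[k][2];
      const float *src0 = X.colptr(c);
      float *dst0 = Col.colptr((arma::uword)c * 27 + k);
      for (int s = 0; s < B; ++s) {
        const float *src = src0 + (size_t)s * N;
        float *dst = dst0 + (size_t)s * N;
        for (int z = 0; z < nz; ++z) {
          int sz = z + dz;
          float *dplane = dst + (size_t)z * nx * ny;
          if (sz < 0 || sz >= nz) {
            std::fill(dplane, dplane + (size_t)nx * ny, 0.0f);
            continue;
          }
          const float *splane = src + (size_t)sz * nx * ny;
          for (int y = 0; y < ny; ++y) {
            int sy = y + dy;
            float *drow = dplane + (size_t)y * nx;
            if (sy < 0 || sy >= ny) {
              std::fill(drow, drow + nx, 0.0f);
              continue;
            }
            const float *srow = splane + (size_t)sy * nx;
            if (dx == 0) {
              std::copy(srow, srow + nx, drow);
            } else if (dx == 1) {
              std::copy(srow + 1, srow + nx, drow);
              drow[nx - 1] = 0.0f;
            } else {  // dx == -1
              drow[0] = 0.0f;
              std::copy(srow, srow + nx - 1, drow + 1);
            }
          }
        }
      }
    }
  }
}

// dX[q, c] += dCol[q - off_k, c*27+k]
static void col2im_acc(const fmat &dCol, fmat &dX, int nx, int ny, int nz,
                       int B) {
  const int N = nx * ny * nz;
  const int C = dX.n_cols;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 27; ++k) {
      const int dx = -OFF[k][0], dy = -OFF[k][1], dz = -OFF[k][2];
      const float *src0 = dCol.colptr((arma::uword)c * 27 + k);
      float *dst0 = dX.colptr(c);
      for (int s = 0; s < B; ++s) {
        const float *src = src0 + (size_t)s * N;
        float *dst = dst0 + (size_t)s * N;
        for (int z = 0; z < nz; ++z) {
          int sz = z + dz;
          if (sz < 0 || sz >= nz) continue;
          const float *splane = src + (size_t)sz * nx * ny;
          float *dplane = dst + (size_t)z * nx * ny;
          for (int y = 0; y < ny; ++y) {
            int sy = y + dy;
            if (sy < 0 || sy >= ny) continue;
            const float *srow = splane + (size_t)sy * nx;
            float *drow = dplane + (size_t)y * nx;
            int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            for (int x = x0; x < x1; ++x) drow[x] += srow[x + dx];
          }
        }
      }
    }
  }
}

static Net net_from_r(List weights, bool residual, double bn_momentum) {
  Net net;
  net.residual = residual;
  net.bn_momentum = (float)bn_momentum;
  int L = weights.size();
  for (int l = 0; l < L; ++l) {
    List ly = weights[l];
    Layer lay;
    NumericMatrix W = ly["W"];
    lay.W = arma::conv_to<fmat>::from(as<arma::mat>(W));
    lay.b = arma::conv_to<fvec>::from(as<arma::vec>(ly["b"]));
    lay.bn = ly.containsElementNamed("gamma") && !Rf_isNull(ly["gamma"]);
    if (lay.bn) {
      lay.g = arma::conv_to<fvec>::from(as<arma::vec>(ly["gamma"]));
      lay.be = arma::conv_to<fvec>::from(as<arma::vec>(ly["beta"]));
      lay.rm = arma::conv_to<fvec>::from(as<arma::vec>(ly["run_mean"]));
      lay.rv = arma::conv_to<fvec>::from(as<arma::vec>(ly["run_var"]));
    }
    net.layers.push_back(lay);
  }
  return net;
}

static List net_to_r(const Net &net, List original) {
  List out = clone(original);
  for (size_t l = 0; l < net.layers.size(); ++l) {
    List ly = out[l];
    const Layer &lay = net.layers[l];
    NumericMatrix W(lay.W.n_rows, lay.W.n_cols);
    for (arma::uword j = 0; j < lay.W.n_cols; ++j)
      for (arma::uword i = 0; i < lay.W.n_rows; ++i) W(i, j) = lay.W(i, j);
    ly["W"] = W;
    ly["b"] = NumericVector(lay.b.begin(), lay.b.end());
    if (lay.bn) {
      ly["gamma"] = NumericVector(lay.g.begin(), lay.g.end());
      ly["beta"] = NumericVector(lay.be.begin(), lay.be.end());
      ly["run_mean"] = NumericVector(lay.rm.begin(), lay.rm.end());
      ly["run_var"] = NumericVector(lay.rv.begin(), lay.rv.end());
    }
    out[l] = ly;
  }
  return out;
}

struct FwdCache {
  std::vector<fmat> A;     // activations, A[0] = input
  std::vector<fmat> Xhat;  // BN normalized pre-activations
  std::vector<fvec> istd;  // BN inverse std per channel
  fmat out;
};

static void forward_pass(Net &net, const fmat &X0, int nx, int ny, int nz,
                         int B, bool training, bool keep_cache,
                         FwdCache &cache) {
  int L = net.layers.size();
  cache.A.assign(L, fmat());
  cache.Xhat.assign(L, fmat());
  cache.istd.assign(L, fvec());
  fmat A = X0;
  for (int l = 0; l < L; ++l) {
    Layer &lay = net.layers[l];
    if (keep_cache) cache.A[l] = A;
    if ((int)g_colbufs.size() <= l) g_colbufs.resize(l + 1);
    fmat Col = col_alias(g_colbufs[l], A.n_rows, (arma::uword)A.n_cols * 27);
    im2col(A, Col, nx, ny, nz, B);
    fmat Z = Col * lay.W;
    Z.each_row() += lay.b.t();
    bool last = (l == L - 1);
    if (!last) {
      if (lay.bn) {
        arma::uword N = Z.n_rows;
        if (training) {
          fvec mu = arma::conv_to<fvec>::from(arma::mean(Z, 0).t());
          fvec va = arma::conv_to<fvec>::from(arma::var(Z, 1, 0).t());
          fvec istd = 1.0f / arma::sqrt(va + net.bn_eps);
          Z.each_row() -= mu.t();
          Z.each_row() %= istd.t();
          if (keep_cache) {
            cache.Xhat[l] = Z;
            cache.istd[l] = istd;
          }
          lay.rm = (1.0f - net.bn_momentum) * lay.rm + net.bn_momentum * mu;
          lay.rv = (1.0f - net.bn_momentum) * lay.rv + net.bn_momentum * va;
          (void)N;
        } else {
          fvec istd = 1.0f / arma::sqrt(lay.rv + net.bn_eps);
          Z.each_row() -= lay.rm.t();
          Z.each_row() %= istd.t();
        }
        Z.each_row() %= lay.g.t();
        Z.each_row() += lay.be.t();
      }
      A = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
    } else {
      if (net.residual) Z += X0;
      cache.out = Z;
    }
  }
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db, dg, dbe;
  double sqnorm() const {
    double s = 0;
    for (size_t l = 0; l < dW.size(); ++l) {
      s += arma::accu(arma::square(arma::conv_to<arma::mat>::from(dW[l])));
      s += arma::accu(arma::square(arma::conv_to<arma::vec>::from(db[l])));
      if (dg[l].n_elem) {
        s += arma::accu(arma::square(arma::conv_to<arma::vec>::from(dg[l])));
        s += arma::accu(arma::square(arma::conv_to<arma::vec>::from(dbe[l])));
      }
    }
    return s;
  }
};

static void backward_pass(Net &net, const FwdCache &cache, const fmat &lab,
                          int nx, int ny, int nz, int B, Grads &gr) {
  int L = net.layers.size();
  gr.dW.assign(L, fmat());
  gr.db.assign(L, fvec());
  gr.dg.assign(L, fvec());
  gr.dbe.assign(L, fvec());
  double Ntot = (double)cache.out.n_rows;
  fmat dZ = (2.0 / Ntot) * (cache.out - lab);
  for (int l = L - 1; l >= 0; --l) {
    Layer &lay = net.layers[l];
    // reuse the forward pass's im2col columns for this batch
    fmat Col = col_alias(g_colbufs[l], cache.A[l].n_rows,
                         (arma::uword)cache.A[l].n_cols * 27);
    gr.dW[l] = Col.t() * dZ;
    gr.db[l] = arma::sum(dZ, 0).t();
    if (!lay.bn) {
      gr.dg[l].reset();
      gr.dbe[l].reset();
    }
    if (l == 0) break;
    fmat dCol = col_alias(g_dcolbuf, dZ.n_rows,
                          (arma::uword)cache.A[l].n_cols * 27);
    dCol = dZ * lay.W.t();
    fmat dA(cache.A[l].n_rows, cache.A[l].n_cols);
    col2im_acc(dCol, dA, nx, ny, nz, B);
    // through ReLU of layer l-1 (zero gradient where activation was zero)
    {
      const float *ap = cache.A[l].memptr();
      float *dp = dA.memptr();
      const arma::uword n = dA.n_elem;
      for (arma::uword i = 0; i < n; ++i)
        if (ap[i] <= 0.0f) dp[i] = 0.0f;
    }
    Layer &prev = net.layers[l - 1];
    if (prev.bn) {
      const fmat &xhat = cache.Xhat[l - 1];
      const fvec &istd = cache.istd[l - 1];
      arma::uword N = dA.n_rows;
      gr.dg[l - 1] = arma::sum(dA % xhat, 0).t();
      gr.dbe[l - 1] = arma::sum(dA, 0).t();
      fmat dxhat = dA;
      dxhat.each_row() %= prev.g.t();
      fvec s1 = arma::sum(dxhat, 0).t();
      fvec s2 = arma::sum(dxhat % xhat, 0).t();
      dZ = dxhat;
      dZ.each_row() -= (s1.t() / (float)N);
      dZ -= xhat.each_row() % (s2.t() / (float)N);
      dZ.each_row() %= istd.t();
    } else {
      dZ = dA;
    }
  }
}

static void adam_step(Net &net, Grads &gr, double lr, double clip, long long &t,
                      double beta1, double beta2, double eps) {
  // global-norm gradient clipping
  double norm = std::sqrt(gr.sqnorm());
  float scale = 1.0f;
  if (clip > 0 && norm > clip) scale = (float)(clip / norm);
  t += 1;
  double bc1 = 1.0 - std::pow(beta1, (double)t);
  double bc2 = 1.0 - std::pow(beta2, (double)t);
  double alpha = lr * std::sqrt(bc2) / bc1;
  for (size_t l = 0; l < net.layers.size(); ++l) {
    Layer &lay = net.layers[l];
    if (lay.mW.n_elem == 0) {
      lay.mW = arma::zeros<fmat>(arma::size(lay.W));
      lay.vW = arma::zeros<fmat>(arma::size(lay.W));
      lay.mb = arma::zeros<fvec>(lay.b.n_elem);
      lay.vb = arma::zeros<fvec>(lay.b.n_elem);
      if (lay.bn) {
        lay.mg = arma::zeros<fvec>(lay.g.n_elem);
        lay.vg = arma::zeros<fvec>(lay.g.n_elem);
        lay.mbe = arma::zeros<fvec>(lay.be.n_elem);
        lay.vbe = arma::zeros<fvec>(lay.be.n_elem);
      }
    }
    fmat gW = gr.dW[l] * scale;
    fvec gb = gr.db[l] * scale;
    lay.mW = (float)beta1 * lay.mW + (float)(1 - beta1) * gW;
    lay.vW = (float)beta2 * lay.vW + (float)(1 - beta2) * arma::square(gW);
    lay.W -= (float)alpha * lay.mW / (arma::sqrt(lay.vW) + (float)eps);
    lay.mb = (float)beta1 * lay.mb + (float)(1 - beta1) * gb;
    lay.vb = (float)beta2 * lay.vb + (float)(1 - beta2) * arma::square(gb);
    lay.b -= (float)alpha * lay.mb / (arma::sqrt(lay.vb) + (float)eps);
    if (lay.bn && gr.dg[l].n_elem) {
      fvec gg = gr.dg[l] * scale;
      fvec gbe = gr.dbe[l] * scale;
      lay.mg = (float)beta1 * lay.mg + (float)(1 - beta1) * gg;
      lay.vg = (float)beta2 * lay.vg + (float)(1 - beta2) * arma::square(gg);
      lay.g -= (float)alpha * lay.mg / (arma::sqrt(lay.vg) + (float)eps);
      lay.mbe = (float)beta1 * lay.mbe + (float)(1 - beta1) * gbe;
      lay.vbe =
          (float)beta2 * lay.vbe + (float)(1 - beta2) * arma::square(gbe);
      lay.be -= (float)alpha * lay.mbe / (arma::sqrt(lay.vbe) + (float)eps);
    }
  }
}

// Extract co-located patches into (B*P^3 x 1) input/label matrices.
static void fill_batch(const std::vector<arma::fcube> &vin,
                       const std::vector<arma::fcube> &vlab,
                       const IntegerMatrix &origins,
                       const std::vector<int> &rows, size_t first, size_t last,
                       int P, fmat &X0, fmat &Lb) {
  int B = (int)(last - first);
  X0.set_size((arma::uword)B * P * P * P, 1);
  Lb.set_size((arma::uword)B * P * P * P, 1);
  for (int s = 0; s < B; ++s) {
    int r = rows[first + s];
    int v = origins(r, 0) - 1;
    int ox = origins(r, 1) - 1, oy = origins(r, 2) - 1, oz = origins(r, 3) - 1;
    float *xp = X0.colptr(0) + (size_t)s * P * P * P;
    float *lp = Lb.colptr(0) + (size_t)s * P * P * P;
    const arma::fcube &ci = vin[v];
    const arma::fcube &cl = vlab[v];
    size_t i = 0;
    for (int z = 0; z < P; ++z)
      for (int y = 0; y < P; ++y)
        for (int x = 0; x < P; ++x, ++i) {
          xp[i] = ci(ox + x, oy + y, oz + z);
          lp[i] = cl(ox + x, oy + y, oz + z);
        }
  }
}

static std::vector<arma::fcube> cubes_from_r(List vols) {
  std::vector<arma::fcube> out;
  for (int i = 0; i < vols.size(); ++i) {
    NumericVector v = vols[i];
    IntegerVector d = v.attr("dim");
    arma::fcube c(d[0], d[1], d[2]);
    std::copy(v.begin(), v.end(), c.begin());
    out.push_back(std::move(c));
  }
  return out;
}

static double eval_loss(Net &net, const std::vector<arma::fcube> &vin,
                        const std::vector<arma::fcube> &vlab,
                        const IntegerMatrix &origins, int P, int batch) {
  int n = origins.nrow();
  if (n == 0) return NA_REAL;
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  double tot = 0;
  long cnt = 0;
  FwdCache cache;
  for (int start = 0; start < n; start += batch) {
    int end = std::min(n, start + batch);
    fmat X0, Lb;
    fill_batch(vin, vlab, origins, rows, start, end, P, X0, Lb);
    forward_pass(net, X0, P, P, P, end - start, false, false, cache);
    tot += arma::accu(arma::square(cache.out - Lb));
    cnt += cache.out.n_rows;
  }
  return tot / (double)cnt;
}

// [[Rcpp::export]]
List cnn_train_cpp(List vols_in, List vols_lab, IntegerMatrix origins,
                   IntegerMatrix val_origins, List weights, List cfg) {
  double lr0 = as<double>(cfg["learning_rate"]);
  double decay_factor = as<double>(cfg["lr_decay_factor"]);
  int decay_every = as<int>(cfg["lr_decay_every_epochs"]);
  double clip = as<double>(cfg["grad_clip"]);
  int batch = as<int>(cfg["batch_size"]);
  int epochs = as<int>(cfg["n_epochs"]);
  int patience = as<int>(cfg["patience"]);
  double min_delta = as<double>(cfg["min_delta"]);
  int P = as<int>(cfg["patch_size"]);
  bool residual = as<bool>(cfg["residual_add"]);
  double bn_momentum = as<double>(cfg["bn_momentum"]);
  unsigned int seed = (unsigned int)as<int>(cfg["rng_seed"]);
  bool verbose = as<bool>(cfg["verbose"]);

  Net net = net_from_r(weights, residual, bn_momentum);
  std::vector<arma::fcube> vin = cubes_from_r(vols_in);
  std::vector<arma::fcube> vlab = cubes_from_r(vols_lab);

  int n = origins.nrow();
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::mt19937 rng(seed);

  std::vector<double> tr_loss, va_loss, lrs;
  long long t = 0;
  double best_val = R_PosInf;
  int since_improve = 0;
  std::string stop_reason = "max_epochs";
  int stop_epoch = epochs;
  FwdCache cache;
  Grads gr;
  bool has_val = val_origins.nrow() > 0;

  for (int e = 1; e <= epochs; ++e) {
    double lr = lr0 * std::pow(1.0 / decay_factor, (double)(e / decay_every));
    std::shuffle(rows.begin(), rows.end(), rng);
    double esum = 0;
    long ecnt = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      fmat X0, Lb;
      fill_batch(vin, vlab, origins, rows, start, end, P, X0, Lb);
      forward_pass(net, X0, P, P, P, end - start, true, true, cache);
      double loss = arma::accu(arma::square(cache.out - Lb)) /
                    (double)cache.out.n_rows;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", e);
      esum += loss * cache.out.n_rows;
      ecnt += cache.out.n_rows;
      backward_pass(net, cache, Lb, P, P, P, end - start, gr);
      adam_step(net, gr, lr, clip, t, 0.9, 0.999, 1e-8);
    }
    double etr = esum / (double)ecnt;
    double eva = has_val ? eval_loss(net, vin, vlab, val_origins, P, batch)
                         : NA_REAL;
    tr_loss.push_back(etr);
    va_loss.push_back(eva);
    lrs.push_back(lr);
    if (verbose)
      Rprintf("epoch %d  lr %.2e  train %.3e  val %.3e\n", e, lr, etr, eva);
    if (has_val) {
      if (eva < best_val * (1.0 - min_delta)) {
        best_val = eva;
        since_improve = 0;
      } else {
        since_improve += 1;
        if (since_improve >= patience) {
          stop_reason = "validation_saturation";
          stop_epoch = e;
          break;
        }
      }
    }
    stop_epoch = e;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["weights"] = net_to_r(net, weights),
      _["train_loss"] = NumericVector(tr_loss.begin(), tr_loss.end()),
      _["val_loss"] = NumericVector(va_loss.begin(), va_loss.end()),
      _["lr"] = NumericVector(lrs.begin(), lrs.end()),
      _["stop_epoch"] = stop_epoch, _["stop_reason"] = stop_reason);
}

// Whole-block forward pass of one single-channel volume (inference by
// default: batch norm uses accumulated statistics).
// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List weights, NumericVector vol, bool residual,
                              double bn_momentum = 0.1) {
  IntegerVector d = vol.attr("dim");
  Net net = net_from_r(weights, residual, bn_momentum);
  fmat X0((arma::uword)vol.size(), 1);
  std::copy(vol.begin(), vol.end(), X0.begin());
  FwdCache cache;
  forward_pass(net, X0, d[0], d[1], d[2], 1, false, false, cache);
  NumericVector out(vol.size());
  std::copy(cache.out.begin(), cache.out.end(), out.begin());
  out.attr("dim") = d;
  return out;
}

// Scale a flat list of numeric gradients so that their joint L2 norm does
// not exceed max_norm (the clipping rule used inside the training loop).
// [[Rcpp::export]]
List cpp_clip_global_norm(List grads, double max_norm) {
  double sq = 0;
  for (int i = 0; i < grads.size(); ++i) {
    NumericVector g = grads[i];
    for (R_xlen_t j = 0; j < g.size(); ++j) sq += g[j] * g[j];
  }
  double norm = std::sqrt(sq);
  double scale = (max_norm > 0 && norm > max_norm) ? max_norm / norm : 1.0;
  List out = clone(grads);
  for (int i = 0; i < out.size(); ++i) {
    NumericVector g = out[i];
    for (R_xlen_t j = 0; j < g.size(); ++j) g[j] *= scale;
  }
  out.attr("norm_before") = norm;
  out.attr("norm_after") = norm * scale;
  return out;
}
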