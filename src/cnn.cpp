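// Small convolutional regression network: valid 3x3 convolutions (ReLU),
// one 2x2 max-pool after the first convolution, dropout before flattening,
// one ReLU dense layer and a linear scalar output.  Trained with Adam on
// MSE + L2 weight decay.  Convolutions are im2col + GEMM.
//
// Activation layout: a batch of B feature maps with Cin channels of size
// hi x wi is an (Cin x hi*wi*B) matrix whose column b*hi*wi + c*hi + r is
// the channel vector at pixel (r, c) of sample b.  Flattening a sample is
// then a contiguous memory view.
//
// All randomness (weight init, epoch shuffling, dropout) comes from the R
// RNG, so set.seed() makes training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

struct Spec {
  int n_conv;
  std::vector<int> filters;
  int dense;
  double dropout, l2;
  int C, H, W;
  std::vector<int> hin, win, cin;   // per conv layer input dims
  int flat;
};

static Spec parse_spec(const List& s) {
  Spec sp;
  sp.n_conv = as<int>(s["n_conv"]);
  sp.filters = as<std::vector<int>>(s["filters"]);
  sp.dense = as<int>(s["dense"]);
  sp.dropout = as<double>(s["dropout"]);
  sp.l2 = as<double>(s["l2"]);
  sp.C = as<int>(s["C"]); sp.H = as<int>(s["H"]); sp.W = as<int>(s["W"]);
  if ((int)sp.filters.size() != sp.n_conv)
    stop("filters must have one entry per convolution layer");
  int h = sp.H, w = sp.W, c = sp.C;
  for (int l = 0; l < sp.n_conv; ++l) {
    sp.hin.push_back(h); sp.win.push_back(w); sp.cin.push_back(c);
    h -= 2; w -= 2;
    if (h < 1 || w < 1) stop("input too small for the network depth");
    if (l == 0) { h /= 2; w /= 2; if (h < 1 || w < 1) stop("input too small for pooling"); }
    c = sp.filters[l];
  }
  sp.flat = c * h * w;
  return sp;
}

struct Weights {
  std::vector<mat> Wc; std::vector<vec> bc;
  mat Wd; vec bd; mat Wo; double bo;
};

static Weights weights_from_list(const List& w) {
  Weights out;
  List Wc = w["Wc"], bc = w["bc"];
  for (int i = 0; i < Wc.size(); ++i) {
    out.Wc.push_back(as<mat>(Wc[i]));
    out.bc.push_back(as<vec>(bc[i]));
  }
  out.Wd = as<mat>(w["Wd"]); out.bd = as<vec>(w["bd"]);
  out.Wo = as<mat>(w["Wo"]); out.bo = as<double>(w["bo"]);
  return out;
}

static List weights_to_list(const Weights& w) {
  List Wc(w.Wc.size()), bc(w.bc.size());
  for (size_t i = 0; i < w.Wc.size(); ++i) { Wc[i] = w.Wc[i]; bc[i] = w.bc[i]; }
  return List::create(_["Wc"] = Wc, _["bc"] = bc, _["Wd"] = w.Wd,
                      _["bd"] = w.bd, _["Wo"] = w.Wo, _["bo"] = w.bo);
}

static void im2col(const mat& A, int Cin, int hi, int wi, int B, mat& Col) {
  int ho = hi - 2, wo = wi - 2;
  Col.set_size((uword)Cin * 9, (uword)ho * wo * B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < wo; ++co) {
      for (int ro = 0; ro < ho; ++ro) {
        double* dst = Col.colptr((uword)b * ho * wo + (uword)co * ho + ro);
        for (int k = 0; k < 9; ++k) {
          int dr = k % 3, dc = k / 3;
          const double* src =
            A.colptr((uword)b * hi * wi + (uword)(co + dc) * hi + (ro + dr));
          std::memcpy(dst + (size_t)k * Cin, src, sizeof(double) * Cin);
        }
      }
    }
  }
}

static void col2im(const mat& dCol, int Cin, int hi, int wi, int B, mat& dA) {
  int ho = hi - 2, wo = wi - 2;
  dA.zeros((uword)Cin, (uword)hi * wi * B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < wo; ++co) {
      for (int ro = 0; ro < ho; ++ro) {
        const double* src = dCol.colptr((uword)b * ho * wo + (uword)co * ho + ro);
        for (int k = 0; k < 9; ++k) {
          int dr = k % 3, dc = k / 3;
          double* dst =
            dA.colptr((uword)b * hi * wi + (uword)(co + dc) * hi + (ro + dr));
          const double* s = src + (size_t)k * Cin;
          for (int c = 0; c < Cin; ++c) dst[c] += s[c];
        }
      }
    }
  }
}

static void pool_fwd(const mat& A, int F, int hi, int wi, int B,
                     mat& Out, arma::Mat<unsigned char>& argm) {
  int ho = hi / 2, wo = wi / 2;
  Out.set_size((uword)F, (uword)ho * wo * B);
  argm.set_size((uword)F, (uword)ho * wo * B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < wo; ++co) {
      for (int ro = 0; ro < ho; ++ro) {
        uword base = (uword)b * hi * wi + (uword)(2 * co) * hi + 2 * ro;
        const double* c0 = A.colptr(base);
        const double* c1 = A.colptr(base + 1);
        const double* c2 = A.colptr(base + hi);
        const double* c3 = A.colptr(base + hi + 1);
        uword oc = (uword)b * ho * wo + (uword)co * ho + ro;
        double* out = Out.colptr(oc);
        unsigned char* am = argm.colptr(oc);
        for (int f = 0; f < F; ++f) {
          double v = c0[f]; unsigned char a = 0;
          if (c1[f] > v) { v = c1[f]; a = 1; }
          if (c2[f] > v) { v = c2[f]; a = 2; }
          if (c3[f] > v) { v = c3[f]; a = 3; }
          out[f] = v; am[f] = a;
        }
      }
    }
  }
}

static void pool_bwd(const mat& dOut, const arma::Mat<unsigned char>& argm,
                     int F, int hi, int wi, int B, mat& dA) {
  int ho = hi / 2, wo = wi / 2;
  dA.zeros((uword)F, (uword)hi * wi * B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < wo; ++co) {
      for (int ro = 0; ro < ho; ++ro) {
        uword base = (uword)b * hi * wi + (uword)(2 * co) * hi + 2 * ro;
        uword oc = (uword)b * ho * wo + (uword)co * ho + ro;
        const double* g = dOut.colptr(oc);
        const unsigned char* am = argm.colptr(oc);
        for (int f = 0; f < F; ++f) {
          uword tc = base + (am[f] == 1 ? 1 : am[f] == 2 ? hi :
                             am[f] == 3 ? hi + 1 : 0);
          dA.colptr(tc)[f] += g[f];
        }
      }
    }
  }
}

static void gather_batch(const IntegerVector& x, const IntegerVector& dims,
                         const std::vector<int>& idx, mat& A0) {
  int N = dims[0], C = dims[1], H = dims[2], W = dims[3];
  int B = (int)idx.size();
  A0.set_size((uword)C, (uword)H * W * B);
  const int* xp = INTEGER(x);
  for (int b = 0; b < B; ++b) {
    int n = idx[b];
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = A0.colptr((uword)b * H * W + (uword)w * H + h);
        for (int c = 0; c < C; ++c)
          col[c] = (double)xp[(size_t)n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w))];
      }
    }
  }
}

struct Cache {
  std::vector<mat> Col;   // per conv layer
  std::vector<mat> Act;   // post-relu conv activations (conv1: pre-pool)
  mat Pool;               // pooled conv1 activation
  arma::Mat<unsigned char> poolarg;
  mat drop_mask;          // 0 or 1/keep, same shape as last stage output
  mat X;                  // flattened (flat x B)
  mat H1;                 // dense hidden, post-relu
  rowvec pred;
};

static void forward(const Weights& w, const Spec& sp, const mat& A0, int B,
                    bool train_mode, Cache& cc) {
  cc.Col.assign(sp.n_conv, mat());
  cc.Act.assign(sp.n_conv, mat());
  const mat* cur = &A0;
  for (int l = 0; l < sp.n_conv; ++l) {
    im2col(*cur, sp.cin[l], sp.hin[l], sp.win[l], B, cc.Col[l]);
    mat Z = w.Wc[l] * cc.Col[l];
    Z.each_col() += w.bc[l];
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    cc.Act[l] = std::move(Z);
    if (l == 0) {
      pool_fwd(cc.Act[0], sp.filters[0], sp.hin[0] - 2, sp.win[0] - 2, B,
               cc.Pool, cc.poolarg);
      cur = &cc.Pool;
    } else {
      cur = &cc.Act[l];
    }
  }
  const mat& last = (sp.n_conv == 1) ? cc.Pool : cc.Act[sp.n_conv - 1];
  mat dropped;
  if (train_mode && sp.dropout > 0) {
    double keep = 1.0 - sp.dropout;
    cc.drop_mask.set_size(last.n_rows, last.n_cols);
    for (uword i = 0; i < cc.drop_mask.n_elem; ++i)
      cc.drop_mask[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    dropped = last % cc.drop_mask;
  } else {
    cc.drop_mask.reset();
    dropped = last;
  }
  cc.X = mat(dropped.memptr(), sp.flat, B);   // contiguous per-sample blocks
  cc.H1 = w.Wd * cc.X;
  cc.H1.each_col() += w.bd;
  cc.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.pred = w.Wo * cc.H1 + w.bo;
}

static double l2_penalty(const Weights& w, double l2) {
  if (l2 <= 0) return 0.0;
  double s = 0;
  for (const mat& m : w.Wc) s += arma::accu(arma::square(m));
  s += arma::accu(arma::square(w.Wd)) + arma::accu(arma::square(w.Wo));
  return l2 * s;
}

// dpred: gradient of the loss wrt predictions (1 x B)
static void backward(const Weights& w, const Spec& sp, const Cache& cc,
                     const rowvec& dpred, int B, double l2, Weights& g) {
  g.Wc.assign(sp.n_conv, mat());
  g.bc.assign(sp.n_conv, vec());
  g.Wo = dpred * cc.H1.t() + 2 * l2 * w.Wo;
  g.bo = arma::accu(dpred);
  mat dH1 = w.Wo.t() * dpred;
  dH1 %= arma::conv_to<mat>::from(cc.H1 > 0);
  g.Wd = dH1 * cc.X.t() + 2 * l2 * w.Wd;
  g.bd = arma::sum(dH1, 1);
  mat dX = w.Wd.t() * dH1;                       // flat x B
  const mat& last = (sp.n_conv == 1) ? cc.Pool : cc.Act[sp.n_conv - 1];
  mat dLast = mat(dX.memptr(), last.n_rows, last.n_cols);
  if (cc.drop_mask.n_elem) dLast %= cc.drop_mask;
  for (int l = sp.n_conv - 1; l >= 1; --l) {
    mat dZ = dLast % arma::conv_to<mat>::from(cc.Act[l] > 0);
    g.Wc[l] = dZ * cc.Col[l].t() + 2 * l2 * w.Wc[l];
    g.bc[l] = arma::sum(dZ, 1);
    mat dCol = w.Wc[l].t() * dZ;
    mat dPrev;
    col2im(dCol, sp.cin[l], sp.hin[l], sp.win[l], B, dPrev);
    dLast = std::move(dPrev);
  }
  // dLast is now the gradient wrt the pooled conv1 output
  mat dZ1;
  pool_bwd(dLast, cc.poolarg, sp.filters[0], sp.hin[0] - 2, sp.win[0] - 2, B, dZ1);
  dZ1 %= arma::conv_to<mat>::from(cc.Act[0] > 0);
  g.Wc[0] = dZ1 * cc.Col[0].t() + 2 * l2 * w.Wc[0];
  g.bc[0] = arma::sum(dZ1, 1);
}

// [[Rcpp::export]]
List cpp_cnn_init(List spec) {
  Spec sp = parse_spec(spec);
  Weights w;
  for (int l = 0; l < sp.n_conv; ++l) {
    int fan_in = 9 * sp.cin[l];
    double sd = std::sqrt(2.0 / fan_in);
    mat W(sp.filters[l], fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = norm_rand() * sd;
    w.Wc.push_back(W);
    w.bc.push_back(vec(sp.filters[l], arma::fill::zeros));
  }
  {
    double sd = std::sqrt(2.0 / sp.flat);
    w.Wd.set_size(sp.dense, sp.flat);
    for (uword i = 0; i < w.Wd.n_elem; ++i) w.Wd[i] = norm_rand() * sd;
    w.bd = vec(sp.dense, arma::fill::zeros);
  }
  {
    double sd = std::sqrt(1.0 / sp.dense);
    w.Wo.set_size(1, sp.dense);
    for (uword i = 0; i < w.Wo.n_elem; ++i) w.Wo[i] = norm_rand() * sd;
    w.bo = 0.0;
  }
  return weights_to_list(w);
}

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(IntegerVector x, IntegerVector idx, List spec,
                              List weights, int batch = 256) {
  Spec sp = parse_spec(spec);
  Weights w = weights_from_list(weights);
  IntegerVector dims = x.attr("dim");
  int n = idx.size();
  NumericVector out(n);
  Cache cc;
  mat A0;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    std::vector<int> ids(idx.begin() + s, idx.begin() + e);
    gather_batch(x, dims, ids, A0);
    forward(w, sp, A0, e - s, false, cc);
    for (int i = s; i < e; ++i) out[i] = cc.pred[i - s];
  }
  return out;
}

// Loss (MSE + L2 penalty) and exact gradients on one batch, dropout off.
// Exposed for finite-difference verification of the backward pass.
// [[Rcpp::export]]
List cpp_cnn_lossgrad(IntegerVector x, IntegerVector idx, NumericVector y,
                      List spec, List weights) {
  Spec sp = parse_spec(spec);
  Weights w = weights_from_list(weights);
  IntegerVector dims = x.attr("dim");
  std::vector<int> ids(idx.begin(), idx.end());
  int B = (int)ids.size();
  mat A0;
  gather_batch(x, dims, ids, A0);
  Spec sp_nodrop = sp; sp_nodrop.dropout = 0;
  Cache cc;
  forward(w, sp_nodrop, A0, B, false, cc);
  rowvec yy(B);
  for (int i = 0; i < B; ++i) yy[i] = y[ids[i]];
  rowvec resid = cc.pred - yy;
  double loss = arma::accu(arma::square(resid)) / B + l2_penalty(w, sp.l2);
  rowvec dpred = 2.0 * resid / B;
  Weights g;
  backward(w, sp, cc, dpred, B, sp.l2, g);
  return List::create(_["loss"] = loss, _["grad"] = weights_to_list(g));
}

struct Adam {
  Weights m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Weights& w) {
    m = w; v = w;
    for (auto& x : m.Wc) x.zeros();
    for (auto& x : m.bc) x.zeros();
    m.Wd.zeros(); m.bd.zeros(); m.Wo.zeros(); m.bo = 0;
    for (auto& x : v.Wc) x.zeros();
    for (auto& x : v.bc) x.zeros();
    v.Wd.zeros(); v.bd.zeros(); v.Wo.zeros(); v.bo = 0;
  }
  template <class T>
  void upd(T& w, T& mm, T& vv, const T& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }
  void upd_s(double& w, double& mm, double& vv, double g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * g * g;
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (std::sqrt(vv / c2) + eps);
  }
  void step(Weights& w, const Weights& g, double lr) {
    ++t;
    for (size_t l = 0; l < w.Wc.size(); ++l) {
      upd(w.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], lr);
      upd(w.bc[l], m.bc[l], v.bc[l], g.bc[l], lr);
    }
    upd(w.Wd, m.Wd, v.Wd, g.Wd, lr);
    upd(w.bd, m.bd, v.bd, g.bd, lr);
    upd(w.Wo, m.Wo, v.Wo, g.Wo, lr);
    upd_s(w.bo, m.bo, v.bo, g.bo, lr);
  }
};

static double eval_mse(const Weights& w, const Spec& sp, const IntegerVector& x,
                       const IntegerVector& dims, const NumericVector& y,
                       const std::vector<int>& idx, int batch) {
  Cache cc;
  mat A0;
  double sse = 0;
  int n = (int)idx.size();
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch);
    std::vector<int> ids(idx.begin() + s, idx.begin() + e);
    gather_batch(x, dims, ids, A0);
    forward(w, sp, A0, e - s, false, cc);
    for (int i = 0; i < e - s; ++i) {
      double r = cc.pred[i] - y[ids[i]];
      sse += r * r;
    }
  }
  return sse / n;
}

// [[Rcpp::export]]
List cpp_cnn_train(IntegerVector x, NumericVector y, IntegerVector train_idx,
                   IntegerVector val_idx, List spec, List weights, double lr,
                   int batch, int epochs, int patience, double lr_factor,
                   int lr_patience, bool verbose) {
  Spec sp = parse_spec(spec);
  Weights w = weights_from_list(weights);
  IntegerVector dims = x.attr("dim");
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  Adam opt;
  opt.init(w);
  std::vector<double> hist_train, hist_val;
  double best_val = R_PosInf;
  Weights best = w;
  int best_epoch = 0, stall = 0, lr_stall = 0;
  Cache cc;
  mat A0;
  Weights g;
  int n = (int)tr.size();
  for (int ep = 1; ep <= epochs; ++ep) {
    // Fisher-Yates shuffle driven by the R RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(tr[i], tr[j]);
    }
    double run_mse = 0;
    long seen = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      int B = e - s;
      std::vector<int> ids(tr.begin() + s, tr.begin() + e);
      gather_batch(x, dims, ids, A0);
      forward(w, sp, A0, B, true, cc);
      rowvec yy(B);
      for (int i = 0; i < B; ++i) yy[i] = y[ids[i]];
      rowvec resid = cc.pred - yy;
      run_mse += arma::accu(arma::square(resid));
      seen += B;
      rowvec dpred = 2.0 * resid / B;
      backward(w, sp, cc, dpred, B, sp.l2, g);
      opt.step(w, g, lr);
    }
    double tr_mse = run_mse / seen;
    hist_train.push_back(tr_mse);
    double va_mse = NA_REAL;
    if (!va.empty()) {
      va_mse = eval_mse(w, sp, x, dims, y, va, std::max(batch, 128));
      hist_val.push_back(va_mse);
      if (va_mse < best_val - 1e-9) {
        best_val = va_mse;
        best = w;
        best_epoch = ep;
        stall = 0;
        lr_stall = 0;
      } else {
        ++lr_stall;
        if (lr_patience > 0 && lr_stall >= lr_patience && lr_factor < 1) {
          lr *= lr_factor;
          lr_stall = 0;
          if (verbose) Rprintf("  lr -> %g\n", lr);
        }
        if (++stall >= patience && patience > 0) {
          if (verbose) Rprintf("early stop at epoch %d (best %d)\n", ep, best_epoch);
          break;
        }
      }
    }
    if (verbose)
      Rprintf("epoch %3d  train MSE %.5f  val MSE %s\n", ep, tr_mse,
              ISNA(va_mse) ? "NA" : std::to_string(va_mse).c_str());
    Rcpp::checkUserInterrupt();
  }
  if (va.empty()) { best = w; best_epoch = (int)hist_train.size(); }
  return List::create(
    _["weights"] = weights_to_list(best),
    _["train_mse"] = hist_train,
    _["val_mse"] = hist_val,
    _["best_epoch"] = best_epoch,
    _["best_val"] = best_val);
}
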