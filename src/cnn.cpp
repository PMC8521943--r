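#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Slim CNN: repeated [conv 3x3 (same padding) -> batchnorm -> ReLU ->
// maxpool 2x2] blocks, then flatten -> dense -> ReLU -> dropout -> dense
// -> softmax. Activations are stored channel-by-rows, with columns indexed
// sample-major: column j = b*(H*W) + y*W + x. Convolutions are computed as
// one GEMM per layer over an im2col expansion of the whole mini-batch.

// im2col rows are laid out kernel-major (row = k*C + c, k = ky*3+kx) so
// that each (output column, kernel tap) pair is one contiguous C-element
// block copied straight from an input column. Weight matrices use the
// matching column order; the layout is internal to the engine.
static arma::mat im2col3(const arma::mat& X, int C, int H, int W, int B) {
  arma::mat out(9 * C, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    size_t base = (size_t)b * H * W;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        double* oc = out.colptr(base + (size_t)y * W + x);
        for (int ky = 0; ky < 3; ++ky) {
          int ys = y + ky - 1;
          if (ys < 0 || ys >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            int xs = x + kx - 1;
            if (xs < 0 || xs >= W) continue;
            std::memcpy(oc + (size_t)(ky * 3 + kx) * C,
                        X.colptr(base + (size_t)ys * W + xs),
                        C * sizeof(double));
          }
        }
      }
    }
  }
  return out;
}

static arma::mat col2im3(const arma::mat& dcols, int C, int H, int W, int B) {
  arma::mat dX(C, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    size_t base = (size_t)b * H * W;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        const double* dc = dcols.colptr(base + (size_t)y * W + x);
        for (int ky = 0; ky < 3; ++ky) {
          int ys = y + ky - 1;
          if (ys < 0 || ys >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            int xs = x + kx - 1;
            if (xs < 0 || xs >= W) continue;
            double* dst = dX.colptr(base + (size_t)ys * W + xs);
            const double* src = dc + (size_t)(ky * 3 + kx) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dX;
}

static void maxpool2(const arma::mat& X, int C, int H, int W, int B,
                     arma::mat& out, arma::umat& arg) {
  int Ho = H / 2, Wo = W / 2;
  out.set_size(C, (size_t)Ho * Wo * B);
  arg.set_size(C, (size_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b) {
    size_t bi = (size_t)b * H * W, bo = (size_t)b * Ho * Wo;
    for (int yo = 0; yo < Ho; ++yo) {
      for (int xo = 0; xo < Wo; ++xo) {
        size_t jo = bo + (size_t)yo * Wo + xo;
        size_t j00 = bi + (size_t)(2 * yo) * W + 2 * xo;
        size_t cand[4] = {j00, j00 + 1, j00 + W, j00 + W + 1};
        const double* p[4] = {X.colptr(cand[0]), X.colptr(cand[1]),
                              X.colptr(cand[2]), X.colptr(cand[3])};
        double* oc = out.colptr(jo);
        arma::uword* ac = arg.colptr(jo);
        for (int c = 0; c < C; ++c) {
          double best = p[0][c]; size_t bj = cand[0];
          for (int q = 1; q < 4; ++q)
            if (p[q][c] > best) { best = p[q][c]; bj = cand[q]; }
          oc[c] = best;
          ac[c] = bj;
        }
      }
    }
  }
}

struct LayerCache {
  arma::mat cols, xhat, relu_out;
  arma::vec invstd;
  arma::umat poolarg;
  int H, W;          // spatial dims at layer input
};

// One full pass over a mini-batch. Returns loss, class probabilities,
// updated batchnorm running statistics and (optionally) gradients for
// every parameter, using the batch statistics when training = true.
// [[Rcpp::export]]
List cnn_pass(List params, List running, arma::mat X, IntegerVector y,
              List dims, Nullable<NumericMatrix> dropout_mask,
              bool training, double bn_momentum, bool want_grads) {
  int H = as<int>(dims["H"]), W = as<int>(dims["W"]);
  IntegerVector channels = dims["channels"];
  int nconv = channels.size();
  int B = (int)(X.n_cols / ((size_t)H * W));
  const double eps = 1e-5;

  std::vector<arma::mat> Wc(nconv);
  std::vector<arma::vec> bc(nconv), gam(nconv), bet(nconv), rm(nconv), rv(nconv);
  for (int l = 0; l < nconv; ++l) {
    std::string s = std::to_string(l + 1);
    Wc[l] = as<arma::mat>(params["Wc" + s]);
    bc[l] = as<arma::vec>(params["bc" + s]);
    gam[l] = as<arma::vec>(params["gamma" + s]);
    bet[l] = as<arma::vec>(params["beta" + s]);
    rm[l] = as<arma::vec>(running["rm" + s]);
    rv[l] = as<arma::vec>(running["rv" + s]);
  }
  arma::mat Wf1 = as<arma::mat>(params["Wf1"]);
  arma::vec bf1 = as<arma::vec>(params["bf1"]);
  arma::mat Wf2 = as<arma::mat>(params["Wf2"]);
  arma::vec bf2 = as<arma::vec>(params["bf2"]);

  std::vector<LayerCache> cache(nconv);
  arma::mat cur = X;
  int curC = X.n_rows, curH = H, curW = W;

  for (int l = 0; l < nconv; ++l) {
    LayerCache& cc = cache[l];
    cc.H = curH; cc.W = curW;
    cc.cols = im2col3(cur, curC, curH, curW, B);
    arma::mat Z = Wc[l] * cc.cols;
    Z.each_col() += bc[l];
    int Cout = Z.n_rows;
    size_t J = Z.n_cols;
    arma::vec mu(Cout), var(Cout);
    if (training) {
      // single-pass channel statistics, accumulated column-wise
      arma::vec s1(Cout, arma::fill::zeros), s2(Cout, arma::fill::zeros);
      for (size_t j = 0; j < J; ++j) {
        const double* zc = Z.colptr(j);
        for (int c = 0; c < Cout; ++c) {
          s1(c) += zc[c];
          s2(c) += zc[c] * zc[c];
        }
      }
      mu = s1 / (double)J;
      var = s2 / (double)J - arma::square(mu);
      var.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      rm[l] = bn_momentum * rm[l] + (1.0 - bn_momentum) * mu;
      rv[l] = bn_momentum * rv[l] + (1.0 - bn_momentum) * var;
    } else {
      mu = rm[l]; var = rv[l];
    }
    cc.invstd = 1.0 / arma::sqrt(var + eps);
    // fused normalise + scale/shift + ReLU; Z becomes xhat, A the block
    // output (post-ReLU, pre-pool)
    arma::mat A(Cout, J);
    {
      const double* mup = mu.memptr();
      const double* isp = cc.invstd.memptr();
      const double* gp = gam[l].memptr();
      const double* bp = bet[l].memptr();
      for (size_t j = 0; j < J; ++j) {
        double* zc = Z.colptr(j);
        double* ac = A.colptr(j);
        for (int c = 0; c < Cout; ++c) {
          double xh = (zc[c] - mup[c]) * isp[c];
          zc[c] = xh;
          double a = gp[c] * xh + bp[c];
          ac[c] = a > 0.0 ? a : 0.0;
        }
      }
    }
    cc.xhat = std::move(Z);
    cc.relu_out = std::move(A);
    arma::mat pooled; arma::umat parg;
    maxpool2(cc.relu_out, Cout, curH, curW, B, pooled, parg);
    cc.poolarg = std::move(parg);
    cur = std::move(pooled); curC = Cout; curH /= 2; curW /= 2;
  }

  // flatten: F(c*S + s, b) = cur(c, b*S + s), S = curH*curW
  int S = curH * curW;
  arma::mat F(curC * S, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < curC; ++c)
      for (int s = 0; s < S; ++s)
        F((size_t)c * S + s, b) = cur(c, (size_t)b * S + s);

  arma::mat Z1 = Wf1 * F;
  Z1.each_col() += bf1;
  arma::mat A1 = Z1;
  A1.for_each([](double& v) { if (v < 0.0) v = 0.0; });
  arma::mat D = A1;
  arma::mat dmask;
  bool have_mask = dropout_mask.isNotNull();
  if (have_mask) {
    dmask = as<arma::mat>(dropout_mask.get());
    D %= dmask;
  }
  arma::mat Z2 = Wf2 * D;
  Z2.each_col() += bf2;

  // stable softmax per column
  arma::mat P = Z2;
  for (int b = 0; b < B; ++b) {
    arma::vec col = P.col(b);
    col -= col.max();
    col = arma::exp(col);
    P.col(b) = col / arma::accu(col);
  }

  double loss = NA_REAL;
  if (y.size() == B) {
    loss = 0.0;
    for (int b = 0; b < B; ++b)
      loss -= std::log(std::max(P(y[b] - 1, b), 1e-300));
    loss /= B;
  }

  List run_out(2 * nconv);
  CharacterVector run_names(2 * nconv);
  for (int l = 0; l < nconv; ++l) {
    std::string s = std::to_string(l + 1);
    run_out[2 * l] = rm[l];     run_names[2 * l] = "rm" + s;
    run_out[2 * l + 1] = rv[l]; run_names[2 * l + 1] = "rv" + s;
  }
  run_out.attr("names") = run_names;

  if (!want_grads) {
    return List::create(_["loss"] = loss, _["probs"] = P,
                        _["running"] = run_out);
  }

  // ---- backward ----
  arma::mat dZ2 = P;
  for (int b = 0; b < B; ++b) dZ2(y[b] - 1, b) -= 1.0;
  dZ2 /= B;

  arma::mat dWf2 = dZ2 * D.t();
  arma::vec dbf2 = arma::sum(dZ2, 1);
  arma::mat dD = Wf2.t() * dZ2;
  if (have_mask) dD %= dmask;
  arma::mat dZ1 = dD;
  dZ1.elem(arma::find(Z1 <= 0.0)).zeros();
  arma::mat dWf1 = dZ1 * F.t();
  arma::vec dbf1 = arma::sum(dZ1, 1);
  arma::mat dF = Wf1.t() * dZ1;

  // unflatten
  arma::mat dcur(curC, (size_t)S * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < curC; ++c)
      for (int s = 0; s < S; ++s)
        dcur(c, (size_t)b * S + s) = dF((size_t)c * S + s, b);

  std::vector<arma::mat> dWc(nconv);
  std::vector<arma::vec> dbc(nconv), dgam(nconv), dbet(nconv);

  for (int l = nconv - 1; l >= 0; --l) {
    LayerCache& cc = cache[l];
    int Cout = channels[l];
    int Hin = cc.H, Win = cc.W;
    // unpool: scatter gradients to stored argmax positions
    arma::mat dA(Cout, (size_t)Hin * Win * B, arma::fill::zeros);
    double* dAp = dA.memptr();
    for (arma::uword j = 0; j < dcur.n_cols; ++j) {
      const double* dj = dcur.colptr(j);
      const arma::uword* aj = cc.poolarg.colptr(j);
      for (int c = 0; c < Cout; ++c)
        dAp[aj[c] * Cout + c] += dj[c];
    }
    // ReLU mask and batchnorm reductions in one pass
    size_t J = dA.n_cols;
    arma::vec sg(Cout, arma::fill::zeros), sb(Cout, arma::fill::zeros);
    for (size_t j = 0; j < J; ++j) {
      double* dj = dA.colptr(j);
      const double* rj = cc.relu_out.colptr(j);
      const double* xj = cc.xhat.colptr(j);
      for (int c = 0; c < Cout; ++c) {
        if (rj[c] <= 0.0) dj[c] = 0.0;
        sg(c) += dj[c] * xj[c];
        sb(c) += dj[c];
      }
    }
    dgam[l] = sg;
    dbet[l] = sb;
    // batchnorm backward (per channel over batch * space), fused in place:
    // dZ = gamma*invstd * (dA - mean(dA) - xhat * mean(dA*xhat))
    {
      arma::vec scale = gam[l] % cc.invstd;
      arma::vec m1 = training ? arma::vec(sb / (double)J)
                              : arma::vec(Cout, arma::fill::zeros);
      arma::vec m2 = training ? arma::vec(sg / (double)J)
                              : arma::vec(Cout, arma::fill::zeros);
      const double* m1p = m1.memptr();
      const double* m2p = m2.memptr();
      const double* sp = scale.memptr();
      for (size_t j = 0; j < J; ++j) {
        double* dj = dA.colptr(j);
        const double* xj = cc.xhat.colptr(j);
        for (int c = 0; c < Cout; ++c)
          dj[c] = sp[c] * (dj[c] - m1p[c] - xj[c] * m2p[c]);
      }
    }
    arma::mat& dZ = dA;
    dWc[l] = dZ * cc.cols.t();
    dbc[l] = arma::sum(dZ, 1);
    if (l > 0) {
      arma::mat dcols = Wc[l].t() * dZ;
      int Cin = channels[l - 1];
      dcur = col2im3(dcols, Cin, Hin, Win, B);
    }
  }

  int ng = 4 * nconv + 4;
  List grads(ng);
  CharacterVector gnames(ng);
  for (int l = 0; l < nconv; ++l) {
    std::string s = std::to_string(l + 1);
    grads[4 * l] = dWc[l];       gnames[4 * l] = "Wc" + s;
    grads[4 * l + 1] = dbc[l];   gnames[4 * l + 1] = "bc" + s;
    grads[4 * l + 2] = dgam[l];  gnames[4 * l + 2] = "gamma" + s;
    grads[4 * l + 3] = dbet[l];  gnames[4 * l + 3] = "beta" + s;
  }
  grads[4 * nconv] = dWf1;     gnames[4 * nconv] = "Wf1";
  grads[4 * nconv + 1] = dbf1; gnames[4 * nconv + 1] = "bf1";
  grads[4 * nconv + 2] = dWf2; gnames[4 * nconv + 2] = "Wf2";
  grads[4 * nconv + 3] = dbf2; gnames[4 * nconv + 3] = "bf2";
  grads.attr("names") = gnames;

  return List::create(_["loss"] = loss, _["probs"] = P,
                      _["grads"] = grads, _["running"] = run_out);
}
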