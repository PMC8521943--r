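#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Matching pursuit over a shift-invariant unit-norm dictionary.
//
// The correlation table C[t, m] = <residual, atom_m shifted to t> is
// initialised by direct inner products and maintained incrementally: after
// subtracting a_k * atom_{m*} at t*, only offsets overlapping the selected
// atom change, by a_k times the atom-atom cross-correlation. The Gram
// cross-correlation table is precomputed once per dictionary, so each
// iteration costs O(M * Lmax) for the update plus the argmax bookkeeping.
// The table is stored offset-major (one contiguous column per filter).
//
// Offsets are restricted to placements with the atom fully inside the
// signal, so every candidate keeps unit norm and its correlation IS the
// least-squares amplitude.

// gram[i*M+j] holds g_{ij}(d) = sum_u a_i[u] * a_j[u - d] for
// d = -(Lj-1) .. (Li-1), stored at index d + Lj - 1.
// [[Rcpp::export]]
List mp_gram_table(List atoms) {
  int M = atoms.size();
  std::vector<arma::vec> A(M);
  for (int i = 0; i < M; ++i) A[i] = as<arma::vec>(atoms[i]);
  List out(M * M);
  for (int i = 0; i < M; ++i) {
    int Li = A[i].n_elem;
    const double* ai = A[i].memptr();
    for (int j = 0; j < M; ++j) {
      int Lj = A[j].n_elem;
      const double* aj = A[j].memptr();
      arma::vec g(Li + Lj - 1, arma::fill::zeros);
      double* gp = g.memptr();
      for (int d = -(Lj - 1); d <= Li - 1; ++d) {
        int u0 = std::max(0, d);
        int u1 = std::min(Li - 1, Lj - 1 + d);
        double s = 0.0;
        const double* x = ai + u0;
        const double* y = aj + (u0 - d);
        for (int u = u1 - u0; u >= 0; --u) s += x[u] * y[u];
        gp[d + Lj - 1] = s;
      }
      out[i * M + j] = g;
    }
  }
  return out;
}

// [[Rcpp::export]]
List mp_encode_cpp(NumericVector signal, List atoms, List gram, int K,
                   double stop_ratio) {
  int N = signal.size();
  int M = atoms.size();
  std::vector<arma::vec> A(M);
  for (int i = 0; i < M; ++i) A[i] = as<arma::vec>(atoms[i]);
  std::vector<arma::vec> G(M * M);
  for (int i = 0; i < M * M; ++i) G[i] = as<arma::vec>(gram[i]);

  arma::vec res(signal.begin(), N);
  double e0 = arma::dot(res, res);

  // valid offsets per filter: 0 .. N - L_m (inclusive); filters longer than
  // the signal are unusable
  std::vector<int> nvalid(M);
  int maxvalid = 0, nusable = 0;
  for (int m = 0; m < M; ++m) {
    int L = A[m].n_elem;
    nvalid[m] = (L <= N) ? (N - L + 1) : 0;
    if (nvalid[m] > 0) ++nusable;
    maxvalid = std::max(maxvalid, nvalid[m]);
  }
  if (nusable == 0)
    stop("signal shorter than every dictionary atom");

  // correlation table (offset-major: column m contiguous), initialised by
  // direct inner products against the residual
  arma::mat C(maxvalid, M, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    const double* a = A[m].memptr();
    int L = A[m].n_elem;
    double* cm = C.colptr(m);
    const double* rp = res.memptr();
    for (int t = 0; t < nvalid[m]; ++t) {
      double s = 0.0;
      const double* r = rp + t;
      for (int u = 0; u < L; ++u) s += r[u] * a[u];
      cm[t] = s;
    }
  }

  // per-column running maxima of |C| (ties resolved toward the smallest
  // offset by strict comparison in ascending scans)
  std::vector<double> colbest(M, -1.0);
  std::vector<int> colarg(M, -1);
  auto rescan_col = [&](int m) {
    const double* cm = C.colptr(m);
    double best = -1.0; int arg = -1;
    for (int t = 0; t < nvalid[m]; ++t) {
      double v = std::abs(cm[t]);
      if (v > best) { best = v; arg = t; }
    }
    colbest[m] = best; colarg[m] = arg;
  };
  for (int m = 0; m < M; ++m) if (nvalid[m] > 0) rescan_col(m);

  std::vector<int> sel_f, sel_t;
  std::vector<double> sel_a, epath;
  double eres = e0;
  double thresh = stop_ratio * e0;

  for (int k = 0; k < K; ++k) {
    if (eres <= thresh) break;
    // global argmax; ties broken toward the lowest filter index
    int bm = -1, bt = -1; double bv = -1.0;
    for (int m = 0; m < M; ++m) {
      if (nvalid[m] == 0) continue;
      if (colbest[m] > bv) { bv = colbest[m]; bm = m; bt = colarg[m]; }
    }
    if (bm < 0 || bv <= 0.0) break;
    double amp = C(bt, bm);
    sel_f.push_back(bm); sel_t.push_back(bt); sel_a.push_back(amp);

    // subtract from the actual residual (kept for the exact energy path)
    {
      const double* a = A[bm].memptr();
      double* r = res.memptr() + bt;
      for (int u = (int)A[bm].n_elem - 1; u >= 0; --u) r[u] -= amp * a[u];
    }
    eres = arma::dot(res, res);
    epath.push_back(eres);

    // incremental update of all columns over the overlap window
    int Lsel = A[bm].n_elem;
    for (int m = 0; m < M; ++m) {
      if (nvalid[m] == 0) continue;
      int Lm = A[m].n_elem;
      // d = bt - t must lie in [-(Lsel-1), Lm-1]
      int t0 = std::max(0, bt - (Lm - 1));
      int t1 = std::min(nvalid[m] - 1, bt + Lsel - 1);
      if (t0 > t1) continue;
      const double* g = G[m * M + bm].memptr() + (Lsel - 1) + bt;
      double* cm = C.colptr(m);
      double wmax = -1.0; int warg = -1;
      for (int t = t0; t <= t1; ++t) {
        cm[t] -= amp * g[-t];
        double v = std::abs(cm[t]);
        if (v > wmax) { wmax = v; warg = t; }
      }
      if (colarg[m] >= t0 && colarg[m] <= t1) {
        // the previous column max was inside the touched window
        if (wmax >= colbest[m]) { colbest[m] = wmax; colarg[m] = warg; }
        else rescan_col(m);
      } else if (wmax > colbest[m]) {
        colbest[m] = wmax; colarg[m] = warg;
      }
    }
  }

  return List::create(
    _["filter_index"] = IntegerVector(sel_f.begin(), sel_f.end()),
    _["time_offset"] = IntegerVector(sel_t.begin(), sel_t.end()),
    _["amplitude"] = NumericVector(sel_a.begin(), sel_a.end()),
    _["energy_path"] = NumericVector(epath.begin(), epath.end()),
    _["initial_energy"] = e0,
    _["residual_energy"] = eres);
}
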