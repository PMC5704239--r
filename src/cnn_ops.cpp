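// Batched forward/backward passes of the character-level temporal CNN.
//
// Layout conventions (must match the R side):
//  * a batch of one-hot frames is carried as an L x n integer token matrix
//    (0-based symbol indices, -1 = blank column) and expanded here;
//  * activations of a conv stage live in a (features x m*n) matrix whose
//    column s*m + y is output position y of sample s -- identical memory
//    layout to an arma::cube(features, m, n);
//  * conv weights are (features x inCh*k) with column index px*inCh + ic,
//    where px = x-1 traverses the kernel f(x), x = 1..k;
//  * a conv/pool stage maps input position p = y*d + (k-1) - px for output
//    y (0-based), i.e. h(y) = sum_x f(x) g(y*d - x + c) with c = k - d + 1
//    in 1-based notation (true convolution: kernel reversed over window).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Cfg {
  int D, L, C;
  std::vector<int> convF, convK, convD, poolK, poolD, fcW;
  double dropout;
};

Cfg parseCfg(const Rcpp::List& cfg) {
  Cfg c;
  c.D = Rcpp::as<int>(cfg["D"]);
  c.L = Rcpp::as<int>(cfg["L"]);
  c.C = Rcpp::as<int>(cfg["C"]);
  c.convF = Rcpp::as<std::vector<int>>(cfg["convFeatures"]);
  c.convK = Rcpp::as<std::vector<int>>(cfg["convKernels"]);
  c.convD = Rcpp::as<std::vector<int>>(cfg["convStrides"]);
  c.poolK = Rcpp::as<std::vector<int>>(cfg["poolWidths"]);
  c.poolD = Rcpp::as<std::vector<int>>(cfg["poolStrides"]);
  c.fcW  = Rcpp::as<std::vector<int>>(cfg["fcWidths"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  return c;
}

struct Params {
  std::vector<mat> convW; std::vector<vec> convB;
  std::vector<mat> fcW;   std::vector<vec> fcB;
  mat outW; vec outB;
};

Params parseParams(const Rcpp::List& params) {
  Params p;
  Rcpp::List conv = params["conv"], fc = params["fc"], out = params["out"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List l = conv[i];
    p.convW.push_back(Rcpp::as<mat>(l["W"]));
    p.convB.push_back(Rcpp::as<vec>(l["b"]));
  }
  for (int i = 0; i < fc.size(); ++i) {
    Rcpp::List l = fc[i];
    p.fcW.push_back(Rcpp::as<mat>(l["W"]));
    p.fcB.push_back(Rcpp::as<vec>(l["b"]));
  }
  Rcpp::List o = out;
  p.outW = Rcpp::as<mat>(o["W"]);
  p.outB = Rcpp::as<vec>(o["b"]);
  return p;
}

// First conv layer applied directly to the token stream: the one-hot input
// makes the im2col product a gather-sum of W columns (column px*D + t of W
// is the kernel tap px for symbol t), avoiding the dense D-channel GEMM.
mat convFirstLayer(const imat& tok, const mat& W, const vec& b,
                   int D, int k, int d, int& mOut) {
  const int L = tok.n_rows, n = tok.n_cols, F = W.n_rows;
  if (L < k) Rcpp::stop("frame length %d shorter than kernel %d", L, k);
  const int m = (L - k) / d + 1;
  mOut = m;
  mat H(F, (uword)m * n);
  for (int s = 0; s < n; ++s)
    for (int y = 0; y < m; ++y) {
      const uword oc = (uword)s * m + y;
      H.col(oc) = b;
      for (int px = 0; px < k; ++px) {
        const int t = tok(y * d + (k - 1) - px, s);
        if (t < 0) continue;
        if (t >= D) Rcpp::stop("token %d out of range 0..%d", t, D - 1);
        H.col(oc) += W.col((uword)px * D + t);
      }
    }
  return H;
}

// gradient of the first conv layer's weights (scatter of dH by token)
void convFirstLayerGradW(const imat& tok, const mat& dH, int D, int k, int d,
                         mat& dW) {
  const int L = tok.n_rows, n = tok.n_cols;
  const int m = (L - k) / d + 1;
  for (int s = 0; s < n; ++s)
    for (int y = 0; y < m; ++y) {
      const uword oc = (uword)s * m + y;
      for (int px = 0; px < k; ++px) {
        const int t = tok(y * d + (k - 1) - px, s);
        if (t >= 0) dW.col((uword)px * D + t) += dH.col(oc);
      }
    }
}

// im2col over a batch held as (ch x len*n); result (ch*k x m*n)
mat im2col(const mat& X, int ch, int len, int n, int k, int d, int& mOut) {
  if (len < k) Rcpp::stop("feature length %d shorter than kernel %d", len, k);
  const int m = (len - k) / d + 1;
  mOut = m;
  mat col((uword)ch * k, (uword)m * n);
  for (int s = 0; s < n; ++s)
    for (int y = 0; y < m; ++y) {
      double* dst = col.colptr((uword)s * m + y);
      for (int px = 0; px < k; ++px) {
        const int p = y * d + (k - 1) - px;
        std::memcpy(dst + (uword)px * ch, X.colptr((uword)s * len + p),
                    sizeof(double) * ch);
      }
    }
  return col;
}

// scatter-add of dcol back onto the input layout
void col2im(const mat& dcol, int ch, int len, int n, int k, int d, mat& dX) {
  const int m = (len - k) / d + 1;
  for (int s = 0; s < n; ++s)
    for (int y = 0; y < m; ++y) {
      const double* src = dcol.colptr((uword)s * m + y);
      for (int px = 0; px < k; ++px) {
        const int p = y * d + (k - 1) - px;
        double* dst = dX.colptr((uword)s * len + p);
        for (int ic = 0; ic < ch; ++ic) dst[ic] += src[(uword)px * ch + ic];
      }
    }
}

// max-pool; records per-row source column for backward
mat maxPool(const mat& A, int F, int len, int n, int k, int d,
            int& mOut, umat& argIdx) {
  if (len < k) Rcpp::stop("feature length %d shorter than pool width %d", len, k);
  const int m = (len - k) / d + 1;
  mOut = m;
  mat out(F, (uword)m * n);
  argIdx.set_size(F, (uword)m * n);
  for (int s = 0; s < n; ++s)
    for (int y = 0; y < m; ++y) {
      const uword oc = (uword)s * m + y;
      for (int f = 0; f < F; ++f) {
        double best = -datum::inf; uword bi = 0;
        for (int px = 0; px < k; ++px) {
          const uword ic = (uword)s * len + y * d + (k - 1) - px;
          const double v = A(f, ic);
          if (v > best) { best = v; bi = ic; }
        }
        out(f, oc) = best; argIdx(f, oc) = bi;
      }
    }
  return out;
}

struct ForwardCache {
  std::vector<mat> cols;      // im2col of each conv layer's input
  std::vector<mat> convAct;   // post-ReLU conv outputs
  std::vector<mat> stageOut;  // post-pool (or conv) output of each layer
  std::vector<umat> poolArg;
  std::vector<int> convLen, outLen;
  std::vector<mat> fcAct;     // post-ReLU (and dropout) fc activations
  mat flat;                   // flattened conv features (width x n)
  mat probs;                  // C x n
};

// full forward pass; dropMasks may be empty (inference)
void forwardPass(const Params& p, const Cfg& c, const imat& tok,
                 const std::vector<mat>& dropMasks, ForwardCache& fc) {
  const int n = tok.n_cols;
  mat X;
  int ch = c.D, len = c.L;
  for (size_t i = 0; i < p.convW.size(); ++i) {
    int m = 0;
    mat col, H;
    if (i == 0) {          // sparse path: gather W columns by token index
      H = convFirstLayer(tok, p.convW[0], p.convB[0], c.D, c.convK[0],
                         c.convD[0], m);
    } else {
      col = im2col(X, ch, len, n, c.convK[i], c.convD[i], m);
      H = p.convW[i] * col;
      H.each_col() += p.convB[i];
    }
    H.transform([](double v) { return v > 0.0 ? v : 0.0; });
    fc.cols.push_back(std::move(col));
    fc.convAct.push_back(H);
    fc.convLen.push_back(m);
    int outLen = m;
    if (c.poolK[i] > 0) {
      umat arg;
      int mp = 0;
      mat P = maxPool(H, c.convF[i], m, n, c.poolK[i], c.poolD[i], mp, arg);
      fc.poolArg.push_back(std::move(arg));
      outLen = mp;
      fc.stageOut.push_back(std::move(P));
    } else {
      fc.poolArg.push_back(umat());
      fc.stageOut.push_back(H);
    }
    fc.outLen.push_back(outLen);
    X = fc.stageOut.back();
    ch = c.convF[i]; len = outLen;
  }
  // flatten: (F x len*n) columns regrouped into (F*len x n); same memory
  fc.flat = mat(const_cast<double*>(X.memptr()), (uword)ch * len, n);
  mat A = fc.flat;
  for (size_t i = 0; i < p.fcW.size(); ++i) {
    mat Z = p.fcW[i] * A;
    Z.each_col() += p.fcB[i];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (!dropMasks.empty()) Z %= dropMasks[i];
    fc.fcAct.push_back(Z);
    A = fc.fcAct.back();
  }
  mat logits = p.outW * A;
  logits.each_col() += p.outB;
  logits.each_row() -= max(logits, 0);
  mat E = exp(logits);
  fc.probs = E.each_row() / sum(E, 0);
}

}  // namespace

// Forward pass over a token batch; returns n x C probability matrix.
// [[Rcpp::export]]
arma::mat cnn_predict_cpp(Rcpp::List params, arma::imat tok, Rcpp::List cfg) {
  Params p = parseParams(params);
  Cfg c = parseCfg(cfg);
  ForwardCache f;
  forwardPass(p, c, tok, std::vector<mat>(), f);
  return f.probs.t();
}

// Single conv layer forward on one multi-channel signal (testing hook):
// G is (inCh x len), W is (F x inCh*k); returns (F x m).
// [[Rcpp::export]]
arma::mat cnn_conv_layer_cpp(arma::mat G, arma::mat W, arma::vec b,
                             int k, int d) {
  int m = 0;
  mat col = im2col(G, G.n_rows, G.n_cols, 1, k, d, m);
  mat H = W * col;
  H.each_col() += b;
  return H;
}

// Loss, accuracy count and all parameter gradients for one mini-batch.
// y is 1-based labels; dropMasks: one (width x n) matrix per fc layer with
// entries 0 or 1/(1-p) (inverted dropout), generated R-side for seeding.
// [[Rcpp::export]]
Rcpp::List cnn_batch_grad_cpp(Rcpp::List params, arma::imat tok,
                              arma::ivec y, Rcpp::List cfg,
                              Rcpp::List dropMasks) {
  Params p = parseParams(params);
  Cfg c = parseCfg(cfg);
  const int n = tok.n_cols;
  if ((int)y.n_elem != n) Rcpp::stop("labels and batch size differ");
  std::vector<mat> masks;
  for (int i = 0; i < dropMasks.size(); ++i)
    masks.push_back(Rcpp::as<mat>(dropMasks[i]));
  if (!masks.empty() && masks.size() != p.fcW.size())
    Rcpp::stop("need one dropout mask per fully-connected layer");

  ForwardCache f;
  forwardPass(p, c, tok, masks, f);

  // loss + correct count
  double loss = 0.0; int nCorrect = 0;
  mat dLogits = f.probs;
  for (int s = 0; s < n; ++s) {
    const int cls = y[s] - 1;
    if (cls < 0 || cls >= c.C) Rcpp::stop("label %d out of range 1..%d", y[s], c.C);
    loss += -std::log(std::max(f.probs(cls, s), 1e-12));
    if ((int)f.probs.col(s).index_max() == cls) ++nCorrect;
    dLogits(cls, s) -= 1.0;
  }
  loss /= n;
  dLogits /= n;

  // output layer
  const mat& Alast = f.fcAct.empty() ? f.flat : f.fcAct.back();
  mat dOutW = dLogits * Alast.t();
  vec dOutB = sum(dLogits, 1);
  mat dA = p.outW.t() * dLogits;

  // fully-connected layers
  std::vector<mat> dFcW(p.fcW.size());
  std::vector<vec> dFcB(p.fcW.size());
  for (int i = (int)p.fcW.size() - 1; i >= 0; --i) {
    if (!masks.empty()) dA %= masks[i];
    dA.elem(find(f.fcAct[i] == 0.0)).zeros();   // ReLU gate
    const mat& Ain = (i == 0) ? f.flat : f.fcAct[i - 1];
    dFcW[i] = dA * Ain.t();
    dFcB[i] = sum(dA, 1);
    dA = p.fcW[i].t() * dA;
  }

  // un-flatten into the last conv stage's (F x len*n) layout
  const int nConv = (int)p.convW.size();
  int Fl = c.convF[nConv - 1], lenl = f.outLen[nConv - 1];
  mat dX(const_cast<double*>(dA.memptr()), Fl, (uword)lenl * n);

  std::vector<mat> dConvW(nConv);
  std::vector<vec> dConvB(nConv);
  for (int i = nConv - 1; i >= 0; --i) {
    mat dH;
    if (c.poolK[i] > 0) {   // route gradients through pooling argmax
      dH.zeros(c.convF[i], (uword)f.convLen[i] * n);
      const umat& arg = f.poolArg[i];
      for (uword j = 0; j < dX.n_cols; ++j)
        for (int fRow = 0; fRow < c.convF[i]; ++fRow)
          dH(fRow, arg(fRow, j)) += dX(fRow, j);
    } else {
      dH = dX;
    }
    dH.elem(find(f.convAct[i] == 0.0)).zeros();  // ReLU gate
    if (i == 0) {
      dConvW[0].zeros(p.convW[0].n_rows, p.convW[0].n_cols);
      convFirstLayerGradW(tok, dH, c.D, c.convK[0], c.convD[0], dConvW[0]);
    } else {
      dConvW[i] = dH * f.cols[i].t();
    }
    dConvB[i] = sum(dH, 1);
    if (i > 0) {
      const int chPrev = c.convF[i - 1], lenPrev = f.outLen[i - 1];
      mat dcol = p.convW[i].t() * dH;
      dX.zeros(chPrev, (uword)lenPrev * n);
      col2im(dcol, chPrev, lenPrev, n, c.convK[i], c.convD[i], dX);
    }
  }

  Rcpp::List gConv(nConv), gFc((int)p.fcW.size());
  for (int i = 0; i < nConv; ++i)
    gConv[i] = Rcpp::List::create(Rcpp::Named("W") = dConvW[i],
                                  Rcpp::Named("b") = dConvB[i]);
  for (size_t i = 0; i < p.fcW.size(); ++i)
    gFc[i] = Rcpp::List::create(Rcpp::Named("W") = dFcW[i],
                                Rcpp::Named("b") = dFcB[i]);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("nCorrect") = nCorrect,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("conv") = gConv,
      Rcpp::Named("fc") = gFc,
      Rcpp::Named("out") = Rcpp::List::create(Rcpp::Named("W") = dOutW,
                                              Rcpp::Named("b") = dOutB)));
}
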