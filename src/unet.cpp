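// Compact CPU U-net: slice-wise forward/backward passes over feature maps
// stored as (channels x H*W) matrices, spatial index p = x + H*y matching
// R's column-major array layout. Convolutions are 3x3 same-padding via
// im2col + GEMM (kernel-column layout q*C + c, q = kernel position, so
// im2col reduces to contiguous block copies); pooling is 2x2 max;
// upsampling is nearest-neighbour 2x followed by a 3x3 conv. Heads:
// 5-class softmax cross-entropy or per-ROI sigmoid with multi-label
// cross-entropy. Arithmetic is single precision internally (standard for
// network training); parameters and gradients cross to R as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef arma::fmat fm;
typedef arma::fvec fv;

static fm im2col3(const fm& X, int H, int W) {
  const int C = X.n_rows;
  fm K(C * 9, H * W, arma::fill::zeros);
  for (int dy = -1; dy <= 1; ++dy) {
    for (int dx = -1; dx <= 1; ++dx) {
      const int q = (dy + 1) * 3 + (dx + 1);
      const int r0 = q * C, r1 = r0 + C - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(H - 1, H - 1 - dx);
      for (int y = 0; y < W; ++y) {
        const int ys = y + dy;
        if (ys < 0 || ys >= W) continue;
        K.submat(r0, x0 + H * y, r1, x1 + H * y) =
          X.cols(x0 + dx + H * ys, x1 + dx + H * ys);
      }
    }
  }
  return K;
}

static fm col2im3(const fm& dK, int H, int W, int C) {
  fm dX(C, H * W, arma::fill::zeros);
  for (int dy = -1; dy <= 1; ++dy) {
    for (int dx = -1; dx <= 1; ++dx) {
      const int q = (dy + 1) * 3 + (dx + 1);
      const int r0 = q * C, r1 = r0 + C - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(H - 1, H - 1 - dx);
      for (int y = 0; y < W; ++y) {
        const int ys = y + dy;
        if (ys < 0 || ys >= W) continue;
        dX.cols(x0 + dx + H * ys, x1 + dx + H * ys) +=
          dK.submat(r0, x0 + H * y, r1, x1 + H * y);
      }
    }
  }
  return dX;
}

struct ConvCache {
  fm K;     // im2col of the layer input
  fm post;  // post-activation output (ReLU mask)
};

static fm conv3_fwd(const fm& X, int H, int W, const fm& Wm, const fv& b,
                    bool relu, ConvCache& cc, bool record) {
  fm K = im2col3(X, H, W);
  fm Y = Wm * K;
  Y.each_col() += b;
  if (relu) Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (record) { cc.K = std::move(K); cc.post = Y; }
  return Y;
}

static fm conv3_bwd(const fm& dYin, int H, int W, const fm& Wm, bool relu,
                    const ConvCache& cc, fm& dW, fv& db) {
  fm dY = dYin;
  if (relu) dY %= arma::conv_to<fm>::from(cc.post > 0);
  dW = dY * cc.K.t();
  db = arma::sum(dY, 1);
  fm dK = Wm.t() * dY;
  return col2im3(dK, H, W, Wm.n_cols / 9);
}

static fm pool2_fwd(const fm& X, int H, int W, arma::umat& idx,
                    bool record) {
  const int C = X.n_rows, Ho = H / 2, Wo = W / 2;
  fm Y(C, Ho * Wo);
  if (record) idx.set_size(C, Ho * Wo);
  for (int y = 0; y < Wo; ++y) {
    for (int x = 0; x < Ho; ++x) {
      const int p = x + Ho * y;
      const int p00 = 2 * x + H * (2 * y);
      const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
      for (int c = 0; c < C; ++c) {
        float best = X(c, cand[0]);
        int bi = cand[0];
        for (int k = 1; k < 4; ++k) {
          if (X(c, cand[k]) > best) { best = X(c, cand[k]); bi = cand[k]; }
        }
        Y(c, p) = best;
        if (record) idx(c, p) = bi;
      }
    }
  }
  return Y;
}

static fm pool2_bwd(const fm& dY, int H, int W, const arma::umat& idx) {
  // H, W: input (pre-pool) spatial dims
  const int C = dY.n_rows, Ho = H / 2, Wo = W / 2;
  fm dX(C, H * W, arma::fill::zeros);
  for (int p = 0; p < Ho * Wo; ++p)
    for (int c = 0; c < C; ++c) dX(c, idx(c, p)) += dY(c, p);
  return dX;
}

static fm up2_fwd(const fm& X, int H, int W) {
  const int C = X.n_rows, Ho = 2 * H, Wo = 2 * W;
  fm Y(C, Ho * Wo);
  for (int y = 0; y < Wo; ++y)
    for (int x = 0; x < Ho; ++x)
      Y.col(x + Ho * y) = X.col((x / 2) + H * (y / 2));
  return Y;
}

static fm up2_bwd(const fm& dY, int H, int W) {
  // H, W: input (pre-upsample) spatial dims
  const int C = dY.n_rows, Ho = 2 * H, Wo = 2 * W;
  fm dX(C, H * W, arma::fill::zeros);
  for (int y = 0; y < Wo; ++y)
    for (int x = 0; x < Ho; ++x)
      dX.col((x / 2) + H * (y / 2)) += dY.col(x + Ho * y);
  return dX;
}

typedef std::vector<fm> ParamSet;  // biases stored as 1-column matrices

static ParamSet paramsToFloat(const List& params) {
  ParamSet out;
  out.reserve(params.size());
  for (int i = 0; i < params.size(); ++i) {
    RObject o = params[i];
    if (Rf_isMatrix(o)) {
      out.push_back(arma::conv_to<fm>::from(as<arma::mat>(o)));
    } else {
      arma::vec v = as<arma::vec>(o);
      out.push_back(arma::conv_to<fm>::from(arma::mat(v)));
    }
  }
  return out;
}

struct Caches {
  std::vector<ConvCache> conv;  // forward order
  std::vector<arma::umat> poolIdx;
  std::vector<fm> skips;
  fm outX;
};

static fm unet_forward(const ParamSet& P, int depth, const fm& x,
                       int H, int W, Caches& cc, bool record) {
  arma::uword pi = 0;
  fm cur = x;
  int h = H, w = W;
  cc.skips.resize(depth);
  if (record) cc.poolIdx.resize(depth);

  ConvCache dummy;
  for (int i = 0; i < depth; ++i) {
    ConvCache cA, cB;
    cur = conv3_fwd(cur, h, w, P[pi], P[pi + 1].col(0), true,
                    record ? cA : dummy, record);
    cur = conv3_fwd(cur, h, w, P[pi + 2], P[pi + 3].col(0), true,
                    record ? cB : dummy, record);
    pi += 4;
    if (record) {
      cc.conv.push_back(std::move(cA));
      cc.conv.push_back(std::move(cB));
    }
    cc.skips[i] = cur;
    arma::umat idx;
    cur = pool2_fwd(cur, h, w, idx, record);
    if (record) cc.poolIdx[i] = std::move(idx);
    h /= 2; w /= 2;
  }

  {
    ConvCache cA, cB;
    cur = conv3_fwd(cur, h, w, P[pi], P[pi + 1].col(0), true,
                    record ? cA : dummy, record);
    cur = conv3_fwd(cur, h, w, P[pi + 2], P[pi + 3].col(0), true,
                    record ? cB : dummy, record);
    pi += 4;
    if (record) {
      cc.conv.push_back(std::move(cA));
      cc.conv.push_back(std::move(cB));
    }
  }

  for (int i = depth - 1; i >= 0; --i) {
    cur = up2_fwd(cur, h, w);
    h *= 2; w *= 2;
    ConvCache cU, cA, cB;
    cur = conv3_fwd(cur, h, w, P[pi], P[pi + 1].col(0), true,
                    record ? cU : dummy, record);
    cur = arma::join_cols(cc.skips[i], cur);
    cur = conv3_fwd(cur, h, w, P[pi + 2], P[pi + 3].col(0), true,
                    record ? cA : dummy, record);
    cur = conv3_fwd(cur, h, w, P[pi + 4], P[pi + 5].col(0), true,
                    record ? cB : dummy, record);
    pi += 6;
    if (record) {
      cc.conv.push_back(std::move(cU));
      cc.conv.push_back(std::move(cA));
      cc.conv.push_back(std::move(cB));
    }
  }

  fm z = P[pi] * cur;
  z.each_col() += P[pi + 1].col(0);
  if (record) cc.outX = cur;
  return z;
}

static double head_loss(const fm& z, const arma::ivec& y, int head, fm* dZ) {
  const int n = z.n_cols;
  double loss = 0.0;
  if (head == 0) {  // softmax cross-entropy; y in 0..nclass-1
    fm P = z;
    P.each_row() -= arma::max(P, 0);
    P = arma::exp(P);
    arma::frowvec s = arma::sum(P, 0);
    P.each_row() /= s;
    for (int p = 0; p < n; ++p) {
      float pr = P(y[p], p);
      loss -= std::log(pr > 1e-30f ? pr : 1e-30f);
    }
    loss /= n;
    if (dZ) {
      *dZ = P;
      for (int p = 0; p < n; ++p) (*dZ)(y[p], p) -= 1.0f;
      *dZ /= (float)n;
    }
  } else {  // per-ROI sigmoid, multi-label cross-entropy; y in 0..nroi
    const int C = z.n_rows;
    fm Y(C, n, arma::fill::zeros);
    for (int p = 0; p < n; ++p)
      if (y[p] >= 1 && y[p] <= C) Y(y[p] - 1, p) = 1.0f;
    for (int p = 0; p < n; ++p) {
      for (int c = 0; c < C; ++c) {
        double zz = z(c, p);
        loss += std::max(zz, 0.0) - zz * Y(c, p) +
                std::log1p(std::exp(-std::fabs(zz)));
      }
    }
    loss /= n;
    if (dZ) {
      fm P = 1.0f / (1.0f + arma::exp(-z));
      *dZ = (P - Y) / (float)n;
    }
  }
  return loss;
}

static void unet_backward(const ParamSet& P, int depth, const fm& dZ,
                          int H, int W, Caches& cc, ParamSet& G) {
  const int np = P.size();
  G.assign(np, fm());

  int pi = np - 2;
  G[pi] = dZ * cc.outX.t();
  G[pi + 1] = fm(arma::sum(dZ, 1));
  fm dCur = P[pi].t() * dZ;

  int ci = cc.conv.size() - 1;
  for (int lvl = 0; lvl < depth; ++lvl) {
    pi = 4 * depth + 4 + 6 * (depth - 1 - lvl);
    const int hh = H >> lvl, ww = W >> lvl;
    fm dWB, dWA, dWU;
    fv dbB, dbA, dbU;
    fm d1 = conv3_bwd(dCur, hh, ww, P[pi + 4], true, cc.conv[ci--],
                      dWB, dbB);
    fm d2 = conv3_bwd(d1, hh, ww, P[pi + 2], true, cc.conv[ci--],
                      dWA, dbA);
    const int cSkip = cc.skips[lvl].n_rows;
    fm dSkip = d2.rows(0, cSkip - 1);
    fm dUpOut = d2.rows(cSkip, d2.n_rows - 1);
    fm d3 = conv3_bwd(dUpOut, hh, ww, P[pi], true, cc.conv[ci--],
                      dWU, dbU);
    G[pi] = std::move(dWU); G[pi + 1] = fm(dbU);
    G[pi + 2] = std::move(dWA); G[pi + 3] = fm(dbA);
    G[pi + 4] = std::move(dWB); G[pi + 5] = fm(dbB);
    dCur = up2_bwd(d3, hh / 2, ww / 2);
    cc.skips[lvl] = std::move(dSkip);  // stash for the encoder pass
  }

  {
    const int hh = H >> depth, ww = W >> depth;
    pi = 4 * depth;
    fm dWB, dWA;
    fv dbB, dbA;
    fm d1 = conv3_bwd(dCur, hh, ww, P[pi + 2], true, cc.conv[ci--],
                      dWB, dbB);
    fm d2 = conv3_bwd(d1, hh, ww, P[pi], true, cc.conv[ci--],
                      dWA, dbA);
    G[pi] = std::move(dWA); G[pi + 1] = fm(dbA);
    G[pi + 2] = std::move(dWB); G[pi + 3] = fm(dbB);
    dCur = std::move(d2);
  }

  for (int i = depth - 1; i >= 0; --i) {
    const int hh = H >> i, ww = W >> i;
    pi = 4 * i;
    fm dPost = pool2_bwd(dCur, hh, ww, cc.poolIdx[i]);
    dPost += cc.skips[i];
    fm dWB, dWA;
    fv dbB, dbA;
    fm d1 = conv3_bwd(dPost, hh, ww, P[pi + 2], true, cc.conv[2 * i + 1],
                      dWB, dbB);
    fm d2 = conv3_bwd(d1, hh, ww, P[pi], true, cc.conv[2 * i],
                      dWA, dbA);
    G[pi] = std::move(dWA); G[pi + 1] = fm(dbA);
    G[pi + 2] = std::move(dWB); G[pi + 3] = fm(dbB);
    dCur = std::move(d2);
  }
}

// mean loss and summed gradients over a batch of slices
// [[Rcpp::export]]
List cpp_unet_batch_grad(List params, IntegerVector arch, List xs, List ys,
                         int H, int W, int head) {
  const int depth = arch[0];
  ParamSet P = paramsToFloat(params);
  const int nb = xs.size();
  ParamSet acc;
  double loss = 0.0;
  for (int b = 0; b < nb; ++b) {
    fm x = arma::conv_to<fm>::from(as<arma::mat>(xs[b]));
    arma::ivec y = as<arma::ivec>(ys[b]);
    Caches cc;
    fm z = unet_forward(P, depth, x, H, W, cc, true);
    fm dZ;
    loss += head_loss(z, y, head, &dZ);
    ParamSet G;
    unet_backward(P, depth, dZ, H, W, cc, G);
    if (b == 0) acc = std::move(G);
    else for (size_t j = 0; j < acc.size(); ++j) acc[j] += G[j];
  }
  loss /= nb;
  List grads(acc.size());
  for (size_t j = 0; j < acc.size(); ++j) {
    if (acc[j].n_cols == 1) {
      grads[j] = wrap(arma::conv_to<arma::vec>::from(acc[j].col(0)));
    } else {
      grads[j] = wrap(arma::conv_to<arma::mat>::from(acc[j]));
    }
  }
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// mean loss over a set of slices (no gradients)
// [[Rcpp::export]]
double cpp_unet_batch_loss(List params, IntegerVector arch, List xs,
                           List ys, int H, int W, int head) {
  const int depth = arch[0];
  ParamSet P = paramsToFloat(params);
  double loss = 0.0;
  for (int b = 0; b < xs.size(); ++b) {
    fm x = arma::conv_to<fm>::from(as<arma::mat>(xs[b]));
    arma::ivec y = as<arma::ivec>(ys[b]);
    Caches cc;
    fm z = unet_forward(P, depth, x, H, W, cc, false);
    loss += head_loss(z, y, head, nullptr);
  }
  return loss / xs.size();
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(List params, IntegerVector arch,
                               NumericMatrix x, int H, int W, int head) {
  const int depth = arch[0];
  ParamSet P = paramsToFloat(params);
  fm X = arma::conv_to<fm>::from(
    arma::mat(x.begin(), x.nrow(), x.ncol(), false));
  Caches cc;
  fm z = unet_forward(P, depth, X, H, W, cc, false);
  fm Pr;
  if (head == 0) {
    Pr = z;
    Pr.each_row() -= arma::max(Pr, 0);
    Pr = arma::exp(Pr);
    arma::frowvec s = arma::sum(Pr, 0);
    Pr.each_row() /= s;
  } else {
    Pr = 1.0f / (1.0f + arma::exp(-z));
  }
  return wrap(arma::conv_to<arma::mat>::from(Pr));
}
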