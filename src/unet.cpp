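// Encoder-decoder (U-Net) for single-channel image-to-image regression.
// Tensors are arma::cube(H, W, C); convolutions are 3x3 same-padding,
// realised as im2col + GEMM; 2x2 max pooling; x2 bilinear upsampling;
// skip connections by channel concatenation; final 1x1 linear conv.
// Weights travel as an R list of list(W, b) in a fixed order (see
// unet_layer_shapes() on the R side).  All arithmetic is double precision
// and fully deterministic.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

// ---- primitives -----------------------------------------------------------

// Patch matrix for 3x3 same-padding conv: row = y + x*H, col = c*9 + (dy+1)*3 + (dx+1)
static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat P(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            P(y + x * H, k) = X(sy, sx, c);
          }
        }
      }
  return P;
}

// Adjoint of im2col3: scatter-add patch-gradients back onto the input grid.
static cube col2im3(const mat& dP, int H, int W, int C) {
  cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            dX(sy, sx, c) += dP(y + x * H, k);
          }
        }
      }
  return dX;
}

static cube mat_to_cube(const mat& M, int H, int W) {
  cube out(H, W, M.n_cols);
  for (arma::uword c = 0; c < M.n_cols; ++c)
    out.slice(c) = arma::reshape(M.col(c), H, W);
  return out;
}

static mat cube_to_mat(const cube& X) {
  mat M(X.n_rows * X.n_cols, X.n_slices);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    M.col(c) = arma::vectorise(X.slice(c));
  return M;
}

struct ConvCache { mat P; };  // patch matrix of the conv input

static cube conv3_fwd(const cube& X, const mat& W, const vec& b, ConvCache& cc) {
  cc.P = im2col3(X);
  mat O = cc.P * W;
  O.each_row() += b.t();
  return mat_to_cube(O, X.n_rows, X.n_cols);
}

static cube conv3_bwd(const mat& dO, const ConvCache& cc, const mat& W,
                      int H, int Wd, int Cin, mat& dW, vec& db) {
  dW = cc.P.t() * dO;
  db = arma::sum(dO, 0).t();
  return col2im3(dO * W.t(), H, Wd, Cin);
}

static void relu_inplace(cube& X) { X.transform([](double v) { return v > 0.0 ? v : 0.0; }); }

// 2x2 max pooling; argmax stores the linear index into X for backprop.
static cube maxpool2(const cube& X, arma::ucube& arg) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int h = H / 2, w = W / 2;
  cube out(h, w, C);
  arg.set_size(h, w, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        double best = -arma::datum::inf; arma::uword bi = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            const int yy = 2 * y + dy, xx = 2 * x + dx;
            const double v = X(yy, xx, c);
            if (v > best) { best = v; bi = yy + xx * (arma::uword)H + c * (arma::uword)(H * W); }
          }
        out(y, x, c) = best; arg(y, x, c) = bi;
      }
  return out;
}

static cube maxpool2_bwd(const cube& dOut, const arma::ucube& arg, int H, int W) {
  cube dX(H, W, dOut.n_slices, arma::fill::zeros);
  for (arma::uword i = 0; i < dOut.n_elem; ++i) dX(arg(i)) += dOut(i);
  return dX;
}

// x2 bilinear upsampling, half-pixel-center convention, clamped borders.
static inline void up_coef(int o, int n, int& i0, int& i1, double& w1) {
  const double f = (o + 0.5) / 2.0 - 0.5;
  const int fl = (int)std::floor(f);
  w1 = f - fl;
  i0 = std::min(std::max(fl, 0), n - 1);
  i1 = std::min(std::max(fl + 1, 0), n - 1);
}

static cube upsample2(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < 2 * W; ++ox) {
      int x0, x1; double wx;
      up_coef(ox, W, x0, x1, wx);
      for (int oy = 0; oy < 2 * H; ++oy) {
        int y0, y1; double wy;
        up_coef(oy, H, y0, y1, wy);
        out(oy, ox, c) = (1 - wy) * (1 - wx) * X(y0, x0, c) + (1 - wy) * wx * X(y0, x1, c)
                       + wy * (1 - wx) * X(y1, x0, c) + wy * wx * X(y1, x1, c);
      }
    }
  return out;
}

static cube upsample2_bwd(const cube& dOut, int H, int W) {
  const int C = dOut.n_slices;
  cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < 2 * W; ++ox) {
      int x0, x1; double wx;
      up_coef(ox, W, x0, x1, wx);
      for (int oy = 0; oy < 2 * H; ++oy) {
        int y0, y1; double wy;
        up_coef(oy, H, y0, y1, wy);
        const double g = dOut(oy, ox, c);
        dX(y0, x0, c) += (1 - wy) * (1 - wx) * g;
        dX(y0, x1, c) += (1 - wy) * wx * g;
        dX(y1, x0, c) += wy * (1 - wx) * g;
        dX(y1, x1, c) += wy * wx * g;
      }
    }
  return dX;
}

static cube concat_ch(const cube& A, const cube& B) {
  cube out(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  out.slices(0, A.n_slices - 1) = A;
  out.slices(A.n_slices, out.n_slices - 1) = B;
  return out;
}

// ---- network --------------------------------------------------------------

struct Layer { mat W; vec b; };

static std::vector<Layer> unpack_weights(const List& weights) {
  std::vector<Layer> L;
  for (int i = 0; i < weights.size(); ++i) {
    List wl = weights[i];
    L.push_back({ as<mat>(wl["W"]), as<vec>(wl["b"]) });
  }
  return L;
}

struct Cache {
  std::vector<cube> skip;          // post double-conv per encoder level
  std::vector<cube> enc_in, enc_mid;
  std::vector<ConvCache> cc1, cc2; // per double conv (enc..., bottleneck, dec...)
  std::vector<cube> dc_in, dc_mid, dc_out;
  std::vector<arma::ucube> poolarg;
  std::vector<arma::uvec> pooldim;
  cube final_in;
};

// One conv-relu-conv-relu block; caches enough for backprop.
static cube double_conv(const cube& X, const Layer& l1, const Layer& l2, Cache& C) {
  ConvCache c1, c2;
  cube mid = conv3_fwd(X, l1.W, l1.b, c1);
  relu_inplace(mid);
  cube out = conv3_fwd(mid, l2.W, l2.b, c2);
  relu_inplace(out);
  C.dc_in.push_back(X); C.dc_mid.push_back(mid); C.dc_out.push_back(out);
  C.cc1.push_back(c1); C.cc2.push_back(c2);
  return out;
}

static cube unet_forward_one(const std::vector<Layer>& L, const cube& x,
                             int depth, Cache& C) {
  cube cur = x;
  int li = 0;
  for (int d = 0; d < depth; ++d) {
    cur = double_conv(cur, L[li], L[li + 1], C); li += 2;
    C.skip.push_back(cur);
    arma::ucube arg;
    arma::uvec dims = { cur.n_rows, cur.n_cols };
    cur = maxpool2(cur, arg);
    C.poolarg.push_back(arg); C.pooldim.push_back(dims);
  }
  cur = double_conv(cur, L[li], L[li + 1], C); li += 2;
  for (int d = depth - 1; d >= 0; --d) {
    cube up = upsample2(cur);
    cube cat = concat_ch(C.skip[d], up);
    cur = double_conv(cat, L[li], L[li + 1], C); li += 2;
  }
  // final 1x1 linear conv
  C.final_in = cur;
  const Layer& fl = L[li];
  mat O = cube_to_mat(cur) * fl.W;
  O.each_row() += fl.b.t();
  return mat_to_cube(O, cur.n_rows, cur.n_cols);
}

// Backward through one double conv given dOut (w.r.t. its post-relu output);
// dc index idx addresses the caches pushed during the forward pass.
static cube double_conv_bwd(Cache& C, size_t idx, const Layer& l1, const Layer& l2,
                            const cube& dOut, mat& dW1, vec& db1, mat& dW2, vec& db2) {
  const cube& mid = C.dc_mid[idx];
  const cube& out = C.dc_out[idx];
  const cube& in  = C.dc_in[idx];
  cube d = dOut;
  for (arma::uword i = 0; i < d.n_elem; ++i) if (out(i) <= 0.0) d(i) = 0.0;
  cube dMid = conv3_bwd(cube_to_mat(d), C.cc2[idx], l2.W,
                        mid.n_rows, mid.n_cols, mid.n_slices, dW2, db2);
  for (arma::uword i = 0; i < dMid.n_elem; ++i) if (mid(i) <= 0.0) dMid(i) = 0.0;
  return conv3_bwd(cube_to_mat(dMid), C.cc1[idx], l1.W,
                   in.n_rows, in.n_cols, in.n_slices, dW1, db1);
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(List weights, NumericMatrix x, int depth) {
  std::vector<Layer> L = unpack_weights(weights);
  cube X(x.nrow(), x.ncol(), 1);
  X.slice(0) = as<mat>(x);
  Cache C;
  cube out = unet_forward_one(L, X, depth, C);
  return wrap(out.slice(0));
}

// Mean-squared-error loss and gradients over a batch of (input, target)
// single-channel patches.  Returns list(loss, grads) with grads in the same
// layout as `weights`.
// [[Rcpp::export]]
List cpp_unet_loss_grad(List weights, List xbatch, List ybatch, int depth) {
  std::vector<Layer> L = unpack_weights(weights);
  const int B = xbatch.size();
  std::vector<mat> gW(L.size());
  std::vector<vec> gb(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    gW[i].zeros(L[i].W.n_rows, L[i].W.n_cols);
    gb[i].zeros(L[i].b.n_elem);
  }
  double loss = 0.0;
  double npix_total = 0.0;
  for (int s = 0; s < B; ++s) {
    NumericMatrix xm = xbatch[s];
    npix_total += (double)xm.nrow() * xm.ncol();
  }
  for (int s = 0; s < B; ++s) {
    NumericMatrix xm = xbatch[s], ym = ybatch[s];
    cube X(xm.nrow(), xm.ncol(), 1);
    X.slice(0) = as<mat>(xm);
    mat Y = as<mat>(ym);
    Cache C;
    cube pred = unet_forward_one(L, X, depth, C);
    mat R = pred.slice(0) - Y;
    loss += arma::accu(R % R);
    // d loss / d pred
    cube dPred(R.n_rows, R.n_cols, 1);
    dPred.slice(0) = (2.0 / npix_total) * R;

    const int li_final = (int)L.size() - 1;
    // final 1x1 conv backward
    mat dO = cube_to_mat(dPred);
    mat Fin = cube_to_mat(C.final_in);
    gW[li_final] += Fin.t() * dO;
    gb[li_final] += arma::sum(dO, 0).t();
    mat dFin = dO * L[li_final].W.t();
    cube d = mat_to_cube(dFin, C.final_in.n_rows, C.final_in.n_cols);

    // decoder double convs: cache indices depth+1 .. depth+depth (after enc 0..depth-1, bottleneck depth)
    int li = li_final - 2;            // weight index of current decoder block's first conv
    size_t ci = C.dc_in.size() - 1;   // cache index of current decoder block
    for (int dd = 0; dd < depth; ++dd) {
      mat dW1, dW2; vec db1, db2;
      cube dCat = double_conv_bwd(C, ci, L[li], L[li + 1], d, dW1, db1, dW2, db2);
      gW[li] += dW1; gb[li] += db1; gW[li + 1] += dW2; gb[li + 1] += db2;
      const int dlevel = dd;                       // 0 = top decoder level
      const cube& sk = C.skip[dlevel];
      // split concat: first sk.n_slices channels -> skip grad, rest -> upsample grad
      cube dSkip = dCat.slices(0, sk.n_slices - 1);
      cube dUp = dCat.slices(sk.n_slices, dCat.n_slices - 1);
      cube dBelow = upsample2_bwd(dUp, dUp.n_rows / 2, dUp.n_cols / 2);
      // accumulate skip gradient: flows back through the encoder level below;
      // stash it by adding when we reach that encoder block (store in map)
      // We process decoder top-down, so remember dSkip per level:
      C.skip[dlevel] = dSkip;  // reuse storage: skip grads now live here
      d = dBelow;
      li -= 2; --ci;
    }
    // bottleneck
    {
      mat dW1, dW2; vec db1, db2;
      cube dIn = double_conv_bwd(C, ci, L[li], L[li + 1], d, dW1, db1, dW2, db2);
      gW[li] += dW1; gb[li] += db1; gW[li + 1] += dW2; gb[li + 1] += db2;
      d = dIn;
      li -= 2; --ci;
    }
    // encoder, bottom-up
    for (int dd = depth - 1; dd >= 0; --dd) {
      // d currently holds gradient w.r.t. pooled output of encoder level dd
      cube dPool = maxpool2_bwd(d, C.poolarg[dd], C.pooldim[dd](0), C.pooldim[dd](1));
      dPool += C.skip[dd];  // skip-connection gradient stored above
      mat dW1, dW2; vec db1, db2;
      cube dIn = double_conv_bwd(C, ci, L[li], L[li + 1], dPool, dW1, db1, dW2, db2);
      gW[li] += dW1; gb[li] += db1; gW[li + 1] += dW2; gb[li + 1] += db2;
      d = dIn;
      li -= 2; --ci;
    }
  }
  loss /= npix_total;
  List grads(L.size());
  for (size_t i = 0; i < L.size(); ++i)
    grads[i] = List::create(_["W"] = gW[i], _["b"] = gb[i]);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
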