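// Encoder-decoder (U-Net) forward and backward passes.
//
// Layout conventions:
//   * activations are arma::cube(H, W, C), matching R arrays dim(H, W, C);
//   * a convolution weight is an R array dim(kh, kw, cin, cout); in memory
//     (column-major) column `cout` of the (kh*kw*cin x cout) matrix view is
//     contiguous, so the matrix view is free;
//   * all spatial convolutions are stride-1 SAME (zero padded, odd kernels),
//     upsampling is a 2x2 stride-2 transposed convolution, pooling is 2x2 max;
//   * output channel 0 (R: [,,1]) is the target-class ("foreground") score,
//     channel 1 is "everything else".
//
// The weight list order is fixed (see unet_weight_spec() on the R side):
//   enc{1..D}_conv1, enc{1..D}_conv2, bot_conv1, bot_conv2,
//   dec{D..1}_up, dec{D..1}_conv1, dec{D..1}_conv2, out.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct ConvW {
  mat Wm;     // (kh*kw*cin) x cout
  rowvec b;   // cout
  int kh, kw, cin, cout;
};

ConvW read_conv(const List& layer) {
  NumericVector Wv = layer["W"];
  NumericVector bv = layer["b"];
  IntegerVector d = Wv.attr("dim");
  if (d.size() != 4) stop("conv weight must be a 4-d array (kh, kw, cin, cout)");
  ConvW c;
  c.kh = d[0]; c.kw = d[1]; c.cin = d[2]; c.cout = d[3];
  c.Wm = mat(Wv.begin(), (uword)(c.kh * c.kw * c.cin), (uword)c.cout);
  c.b = rowvec(bv.begin(), (uword)c.cout);
  return c;
}

// SAME-padded patch matrix: row = pixel (col-major i + H*j), col = (dh, dw, c).
mat im2col(const cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat out(H * W, kh * kw * C);
  mat P(H + kh - 1, W + kw - 1);
  for (int c = 0; c < C; ++c) {
    P.zeros();
    P(span(ph, ph + H - 1), span(pw, pw + W - 1)) = x.slice(c);
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        int q = dh + kh * (dw + kw * c);
        out.col(q) = vectorise(P(span(dh, dh + H - 1), span(dw, dw + W - 1)));
      }
  }
  return out;
}

cube col2im(const mat& dcols, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  cube dx(H, W, C);
  mat Pd(H + kh - 1, W + kw - 1);
  for (int c = 0; c < C; ++c) {
    Pd.zeros();
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        int q = dh + kh * (dw + kw * c);
        Pd(span(dh, dh + H - 1), span(dw, dw + W - 1)) +=
            reshape(dcols.col(q), H, W);
      }
    dx.slice(c) = Pd(span(ph, ph + H - 1), span(pw, pw + W - 1));
  }
  return dx;
}

cube conv_fw(const cube& x, const ConvW& w, mat& cols_store, bool relu) {
  cols_store = im2col(x, w.kh, w.kw);
  mat Y = cols_store * w.Wm;
  Y.each_row() += w.b;
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return cube(Y.memptr(), x.n_rows, x.n_cols, w.cout);
}

// dpost: gradient wrt this layer's (post-activation) output.
// post: the stored post-activation output, NULL when the layer has no ReLU.
cube conv_bw(const cube& dpost, const cube* post, const mat& cols,
             const ConvW& w, mat& dWm, rowvec& db) {
  const int H = dpost.n_rows, W = dpost.n_cols;
  mat dY(const_cast<double*>(dpost.memptr()), H * W, w.cout, true);
  if (post) {
    const mat postm(const_cast<double*>(post->memptr()), H * W, w.cout, false);
    dY.elem(find(postm == 0)).zeros();
  }
  dWm = cols.t() * dY;
  db = sum(dY, 0);
  return col2im(dY * w.Wm.t(), H, W, w.cin, w.kh, w.kw);
}

cube pool_fw(const cube& x, Cube<uword>& arg) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  arg.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v00 = x(2 * i, 2 * j, c), v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        double m = v00; uword a = 0;
        if (v10 > m) { m = v10; a = 1; }
        if (v01 > m) { m = v01; a = 2; }
        if (v11 > m) { m = v11; a = 3; }
        y(i, j, c) = m;
        arg(i, j, c) = a;
      }
  return y;
}

cube pool_bw(const cube& dy, const Cube<uword>& arg) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        uword a = arg(i, j, c);
        dx(2 * i + (a & 1u), 2 * j + (a >> 1), c) = dy(i, j, c);
      }
  return dx;
}

mat tconv_sub(const ConvW& w, int dh, int dw) {
  mat Wsub(w.cin, w.cout);
  for (int co = 0; co < w.cout; ++co)
    for (int ci = 0; ci < w.cin; ++ci)
      Wsub(ci, co) = w.Wm(dh + 2 * dw + 4 * ci, co);
  return Wsub;
}

// 2x2 stride-2 transposed convolution: each input pixel paints a 2x2 block.
cube tconv_fw(const cube& x, const ConvW& w, bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  const mat X(const_cast<double*>(x.memptr()), H * W, w.cin, false);
  cube y(2 * H, 2 * W, w.cout, fill::zeros);
  for (int dw = 0; dw < 2; ++dw)
    for (int dh = 0; dh < 2; ++dh) {
      mat Ys = X * tconv_sub(w, dh, dw);
      for (int co = 0; co < w.cout; ++co) {
        const mat Ym(Ys.colptr(co), H, W, false);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + dh, 2 * j + dw, co) = Ym(i, j);
      }
    }
  for (int co = 0; co < w.cout; ++co) y.slice(co) += w.b(co);
  if (relu) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return y;
}

cube tconv_bw(const cube& dpost, const cube& post, const cube& xin,
              const ConvW& w, mat& dWm, rowvec& db) {
  const int H2 = dpost.n_rows, W2 = dpost.n_cols;
  const int H = H2 / 2, W = W2 / 2;
  cube dy = dpost;
  {
    mat dYv(dy.memptr(), H2 * W2, w.cout, false);
    const mat postm(const_cast<double*>(post.memptr()), H2 * W2, w.cout, false);
    dYv.elem(find(postm == 0)).zeros();
    db = sum(dYv, 0);
  }
  const mat X(const_cast<double*>(xin.memptr()), H * W, w.cin, false);
  dWm.zeros(4 * w.cin, w.cout);
  cube dx(H, W, w.cin, fill::zeros);
  mat dXv(dx.memptr(), H * W, w.cin, false);
  for (int dw = 0; dw < 2; ++dw)
    for (int dh = 0; dh < 2; ++dh) {
      mat dYs(H * W, w.cout);
      for (int co = 0; co < w.cout; ++co) {
        mat dYm(dYs.colptr(co), H, W, false);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dYm(i, j) = dy(2 * i + dh, 2 * j + dw, co);
      }
      mat dWsub = X.t() * dYs;
      for (int co = 0; co < w.cout; ++co)
        for (int ci = 0; ci < w.cin; ++ci)
          dWm(dh + 2 * dw + 4 * ci, co) += dWsub(ci, co);
      dXv += dYs * tconv_sub(w, dh, dw).t();
    }
  return dx;
}

} // namespace

// Run the network on one tile. If `target_` is supplied, also compute the
// pixel-wise weighted softmax cross-entropy (weight r_fg on target-class
// pixels, r_bg elsewhere, summed over pixels) and, when want_grad, the
// gradients of that loss wrt every weight. L2 regularization is handled by
// the caller (it does not depend on the forward pass).
// [[Rcpp::export]]
List unet_apply_cpp(List weights, NumericVector x_, int depth,
                    Nullable<NumericMatrix> target_ = R_NilValue,
                    double r_fg = 1.0, double r_bg = 1.0,
                    bool want_grad = false) {
  IntegerVector xd = x_.attr("dim");
  if (xd.size() != 3) stop("input tile must be a 3-d array (H, W, channels)");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  if (depth < 1) stop("depth must be >= 1");
  if (H % (1 << depth) != 0 || W % (1 << depth) != 0)
    stop("tile side must be divisible by 2^depth");

  const int nw = weights.size();
  if (nw != 5 * depth + 3) stop("weight list length does not match depth");
  std::vector<ConvW> Ws(nw);
  for (int k = 0; k < nw; ++k) Ws[k] = read_conv(weights[k]);
  if (Ws[0].cin != Cin) stop("input channel count does not match first layer");

  cube x(x_.begin(), H, W, Cin);
  std::vector<mat> cols(nw);
  std::vector<cube> outs(nw);
  std::vector<cube> tconv_in(nw);
  std::vector<cube> skips(depth);
  std::vector<Cube<uword>> poolarg(depth);

  // ---- forward ----
  cube a = x;
  int li = 0;
  for (int d = 0; d < depth; ++d) {
    a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
    a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
    skips[d] = a;
    a = pool_fw(a, poolarg[d]);
  }
  a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
  a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
  for (int d = depth - 1; d >= 0; --d) {
    tconv_in[li] = a;
    a = tconv_fw(a, Ws[li], true); outs[li] = a; ++li;
    a = join_slices(skips[d], a);   // [skip, upsampled] along channels
    a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
    a = conv_fw(a, Ws[li], cols[li], true); outs[li] = a; ++li;
  }
  a = conv_fw(a, Ws[li], cols[li], false); outs[li] = a; ++li; // 1x1, 2 ch
  const cube& logits = outs[nw - 1];
  if (!logits.is_finite()) stop("non-finite network output");

  NumericVector logits_out(logits.memptr(), logits.memptr() + logits.n_elem);
  logits_out.attr("dim") = IntegerVector::create(H, W, 2);

  if (target_.isNull())
    return List::create(_["logits"] = logits_out);

  NumericMatrix tg(target_);
  if ((int)tg.nrow() != H || (int)tg.ncol() != W)
    stop("target mask dimensions do not match the tile");

  // ---- weighted softmax cross-entropy (sum over pixels) ----
  double loss = 0.0;
  cube dlog(H, W, 2, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double sf = logits(i, j, 0), sb = logits(i, j, 1);
      const double m = std::max(sf, sb);
      const double logZ = m + std::log(std::exp(sf - m) + std::exp(sb - m));
      const double pf = std::exp(sf - logZ);
      const bool fg = tg(i, j) != 0;
      const double r = fg ? r_fg : r_bg;
      loss += r * (logZ - (fg ? sf : sb));
      if (want_grad) {
        dlog(i, j, 0) = r * (pf - (fg ? 1.0 : 0.0));
        dlog(i, j, 1) = r * ((1.0 - pf) - (fg ? 0.0 : 1.0));
      }
    }
  if (!std::isfinite(loss)) stop("non-finite loss");

  if (!want_grad)
    return List::create(_["logits"] = logits_out, _["loss"] = loss);

  // ---- backward ----
  std::vector<mat> dW(nw);
  std::vector<rowvec> db(nw);
  std::vector<cube> skip_grad(depth);

  cube da = dlog;
  li = nw - 1;
  da = conv_bw(da, nullptr, cols[li], Ws[li], dW[li], db[li]); --li;
  for (int d = 0; d < depth; ++d) {  // undo decoder blocks, innermost-first order reversed
    da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
    da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
    const int cs = skips[d].n_slices;
    skip_grad[d] = da.slices(0, cs - 1);
    cube dup = da.slices(cs, da.n_slices - 1);
    da = tconv_bw(dup, outs[li], tconv_in[li], Ws[li], dW[li], db[li]); --li;
  }
  da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
  da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
  for (int d = depth - 1; d >= 0; --d) {
    da = pool_bw(da, poolarg[d]);
    da += skip_grad[d];
    da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
    da = conv_bw(da, &outs[li], cols[li], Ws[li], dW[li], db[li]); --li;
  }

  List grads(nw);
  for (int k = 0; k < nw; ++k) {
    NumericVector Wg(dW[k].memptr(), dW[k].memptr() + dW[k].n_elem);
    Wg.attr("dim") = IntegerVector::create(Ws[k].kh, Ws[k].kw, Ws[k].cin, Ws[k].cout);
    NumericVector bg(db[k].memptr(), db[k].memptr() + db[k].n_elem);
    grads[k] = List::create(_["W"] = Wg, _["b"] = bg);
  }
  grads.attr("names") = weights.attr("names");
  return List::create(_["logits"] = logits_out, _["loss"] = loss,
                      _["grads"] = grads);
}
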