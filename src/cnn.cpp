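// Small VGG-style convolutional network: 3x3 same-padding convolutions with
// ReLU, 2x2 max-pooling after each block, one ReLU dense layer (the
// penultimate "feature" layer) and a softmax output. All randomness (weight
// initialisation, minibatch order) is supplied from R so results are
// reproducible from a single seed. Single-threaded; matrix work goes through
// the BLAS that R links.
//
// Activations are kept pixel-major: an (h*w*nb) x channels matrix whose rows
// are image-major, column-major pixels. In this layout im2col reduces to
// contiguous column-run copies and each convolution is one tall-skinny GEMM,
// which is what makes CPU training fast enough for desk-scale work.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct NetParams {
  std::vector<arma::mat> Wc;  // per conv layer: (c_in * 9) x c_out
  std::vector<arma::vec> bc;  // c_out
  arma::mat W1;               // penultimate: P x flat
  arma::vec b1;
  arma::mat W2;               // output: K x P
  arma::vec b2;
};

NetParams params_from_list(const List& p, int n_conv) {
  NetParams np;
  List Wc = p["Wc"], bc = p["bc"];
  for (int l = 0; l < n_conv; ++l) {
    np.Wc.push_back(as<arma::mat>(Wc[l]));
    np.bc.push_back(as<arma::vec>(bc[l]));
  }
  np.W1 = as<arma::mat>(p["W1"]);
  np.b1 = as<arma::vec>(p["b1"]);
  np.W2 = as<arma::mat>(p["W2"]);
  np.b2 = as<arma::vec>(p["b2"]);
  return np;
}

List params_to_list(const NetParams& np) {
  List Wc(np.Wc.size()), bc(np.bc.size());
  for (size_t l = 0; l < np.Wc.size(); ++l) {
    Wc[l] = wrap(np.Wc[l]);
    bc[l] = wrap(np.bc[l]);
  }
  return List::create(_["Wc"] = Wc, _["bc"] = bc,
                      _["W1"] = wrap(np.W1), _["b1"] = wrap(np.b1),
                      _["W2"] = wrap(np.W2), _["b2"] = wrap(np.b2));
}

// im2col in pixel-major layout: act is (h*w*nb) x cin; out is
// (h*w*nb) x (cin*9) with column k*cin+ch holding the (dr,dc) shift of
// channel ch (k = 3*(dc+1) + dr+1). Border pixels read as zero.
void im2col3(const arma::mat& act, int h, int w, int nb, arma::mat& col) {
  const int cin = act.n_cols;
  const size_t hw = static_cast<size_t>(h) * w;
  col.zeros(hw * nb, static_cast<size_t>(cin) * 9);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = 3 * (dc + 1) + (dr + 1);
      const int r_lo = std::max(0, -dr);          // valid out-row range
      const int r_hi = std::min(h, h - dr);
      const int len = r_hi - r_lo;
      if (len <= 0) continue;
      for (int ch = 0; ch < cin; ++ch) {
        const double* src0 = act.colptr(ch);
        double* dst0 = col.colptr(static_cast<size_t>(k) * cin + ch);
        for (int img = 0; img < nb; ++img) {
          const size_t off = static_cast<size_t>(img) * hw;
          for (int c2 = 0; c2 < w; ++c2) {
            const int cc = c2 + dc;
            if (cc < 0 || cc >= w) continue;
            std::memcpy(dst0 + off + static_cast<size_t>(c2) * h + r_lo,
                        src0 + off + static_cast<size_t>(cc) * h + r_lo + dr,
                        sizeof(double) * len);
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col3
void col2im3(const arma::mat& dcol, int h, int w, int nb, arma::mat& dact) {
  const int cin = dact.n_cols;
  const size_t hw = static_cast<size_t>(h) * w;
  dact.zeros();
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = 3 * (dc + 1) + (dr + 1);
      const int r_lo = std::max(0, -dr);
      const int r_hi = std::min(h, h - dr);
      const int len = r_hi - r_lo;
      if (len <= 0) continue;
      for (int ch = 0; ch < cin; ++ch) {
        const double* src0 = dcol.colptr(static_cast<size_t>(k) * cin + ch);
        double* dst0 = dact.colptr(ch);
        for (int img = 0; img < nb; ++img) {
          const size_t off = static_cast<size_t>(img) * hw;
          for (int c2 = 0; c2 < w; ++c2) {
            const int cc = c2 + dc;
            if (cc < 0 || cc >= w) continue;
            double* dst = dst0 + off + static_cast<size_t>(cc) * h + r_lo + dr;
            const double* src = src0 + off + static_cast<size_t>(c2) * h + r_lo;
            for (int i = 0; i < len; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

// 2x2 max pool (stride 2) in pixel-major layout; argmax row index recorded
void maxpool2(const arma::mat& act, int h, int w, int nb,
              arma::mat& out, arma::umat& idx) {
  const int c = act.n_cols;
  const int h2 = h / 2, w2 = w / 2;
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hw2 = static_cast<size_t>(h2) * w2;
  out.set_size(hw2 * nb, c);
  idx.set_size(hw2 * nb, c);
  for (int ch = 0; ch < c; ++ch) {
    const double* src = act.colptr(ch);
    double* dst = out.colptr(ch);
    arma::uword* di = idx.colptr(ch);
    for (int img = 0; img < nb; ++img) {
      const size_t off = static_cast<size_t>(img) * hw;
      const size_t off2 = static_cast<size_t>(img) * hw2;
      for (int c2 = 0; c2 < w2; ++c2) {
        const size_t base0 = off + static_cast<size_t>(2 * c2) * h;
        const size_t base1 = off + static_cast<size_t>(2 * c2 + 1) * h;
        const size_t obase = off2 + static_cast<size_t>(c2) * h2;
        for (int r2 = 0; r2 < h2; ++r2) {
          const size_t px[4] = {base0 + 2 * r2, base0 + 2 * r2 + 1,
                                base1 + 2 * r2, base1 + 2 * r2 + 1};
          double best = src[px[0]];
          size_t bi = px[0];
          for (int q = 1; q < 4; ++q)
            if (src[px[q]] > best) { best = src[px[q]]; bi = px[q]; }
          dst[obase + r2] = best;
          di[obase + r2] = bi;
        }
      }
    }
  }
}

struct ForwardCache {
  std::vector<arma::mat> cols;    // im2col matrices per conv layer
  std::vector<arma::mat> convact; // post-ReLU pre-pool activations
  std::vector<arma::umat> poolidx;
  arma::mat flat;                 // flat x nb
  arma::mat a1;                   // penultimate post-ReLU: P x nb
  arma::mat probs;                // K x nb
};

// X: d x nb slice (d = h*w*c0, channel-stacked column-major images)
void forward_pass(const NetParams& np, const arma::mat& X, int h, int w,
                  int c0, ForwardCache& fc, bool keep_cache) {
  const int nb = X.n_cols;
  const int n_conv = np.Wc.size();
  const size_t hw = static_cast<size_t>(h) * w;
  arma::mat act(hw * nb, c0);
  for (int img = 0; img < nb; ++img)
    for (int ch = 0; ch < c0; ++ch)
      std::memcpy(act.colptr(ch) + static_cast<size_t>(img) * hw,
                  X.colptr(img) + static_cast<size_t>(ch) * hw,
                  sizeof(double) * hw);

  int hh = h, ww = w;
  if (keep_cache) {
    fc.cols.resize(n_conv);
    fc.convact.resize(n_conv);
    fc.poolidx.resize(n_conv);
  }
  arma::mat colbuf;
  arma::umat idxbuf;
  for (int l = 0; l < n_conv; ++l) {
    arma::mat& col = keep_cache ? fc.cols[l] : colbuf;
    im2col3(act, hh, ww, nb, col);
    arma::mat z = col * np.Wc[l];
    z.each_row() += np.bc[l].t();
    z.for_each([](double& v) { if (v < 0.0) v = 0.0; });
    arma::umat& pidx = keep_cache ? fc.poolidx[l] : idxbuf;
    arma::mat pooled;
    maxpool2(z, hh, ww, nb, pooled, pidx);
    if (keep_cache) fc.convact[l] = std::move(z);
    act = std::move(pooled);
    hh /= 2; ww /= 2;
  }
  // flatten: per image, channel-major vector of the pooled map
  const int cB = act.n_cols;
  const size_t hw2 = static_cast<size_t>(hh) * ww;
  fc.flat.set_size(hw2 * cB, nb);
  for (int img = 0; img < nb; ++img) {
    double* dst = fc.flat.colptr(img);
    for (int ch = 0; ch < cB; ++ch)
      std::memcpy(dst + static_cast<size_t>(ch) * hw2,
                  act.colptr(ch) + static_cast<size_t>(img) * hw2,
                  sizeof(double) * hw2);
  }
  fc.a1 = np.W1 * fc.flat;
  fc.a1.each_col() += np.b1;
  fc.a1.for_each([](double& v) { if (v < 0.0) v = 0.0; });
  arma::mat z2 = np.W2 * fc.a1;
  z2.each_col() += np.b2;
  z2.each_row() -= arma::max(z2, 0);
  fc.probs = arma::exp(z2);
  fc.probs.each_row() /= arma::sum(fc.probs, 0);
}

struct Grads {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  arma::mat W1; arma::vec b1; arma::mat W2; arma::vec b2;
};

void backward_pass(const NetParams& np, const ForwardCache& fc,
                   const arma::uvec& y, int h, int w, int nb, Grads& g) {
  const int n_conv = np.Wc.size();
  arma::mat dz2 = fc.probs;  // K x nb
  for (int i = 0; i < nb; ++i) dz2(y(i), i) -= 1.0;
  dz2 /= static_cast<double>(nb);
  g.W2 = dz2 * fc.a1.t();
  g.b2 = arma::sum(dz2, 1);
  arma::mat da1 = np.W2.t() * dz2;
  da1.elem(arma::find(fc.a1 <= 0.0)).zeros();
  g.W1 = da1 * fc.flat.t();
  g.b1 = arma::sum(da1, 1);
  arma::mat dflat = np.W1.t() * da1;

  int hh = h, ww = w;
  for (int l = 0; l < n_conv; ++l) { hh /= 2; ww /= 2; }
  const int cB = np.Wc[n_conv - 1].n_cols;
  const size_t hw2 = static_cast<size_t>(hh) * ww;
  // un-flatten into pixel-major pooled-gradient layout
  arma::mat dact(hw2 * nb, cB);
  for (int img = 0; img < nb; ++img) {
    const double* src = dflat.colptr(img);
    for (int ch = 0; ch < cB; ++ch)
      std::memcpy(dact.colptr(ch) + static_cast<size_t>(img) * hw2,
                  src + static_cast<size_t>(ch) * hw2,
                  sizeof(double) * hw2);
  }

  g.Wc.assign(n_conv, arma::mat());
  g.bc.assign(n_conv, arma::vec());
  for (int l = n_conv - 1; l >= 0; --l) {
    const int hin = hh * 2, win = ww * 2;
    const int cout = np.Wc[l].n_cols;
    // unpool through the recorded argmax
    arma::mat dz(static_cast<size_t>(hin) * win * nb, cout,
                 arma::fill::zeros);
    const arma::umat& pidx = fc.poolidx[l];
    for (int ch = 0; ch < cout; ++ch) {
      double* dst = dz.colptr(ch);
      const double* src = dact.colptr(ch);
      const arma::uword* pi = pidx.colptr(ch);
      const size_t nrow = dact.n_rows;
      for (size_t i = 0; i < nrow; ++i) dst[pi[i]] += src[i];
    }
    // ReLU gate
    dz.elem(arma::find(fc.convact[l] <= 0.0)).zeros();
    g.Wc[l] = fc.cols[l].t() * dz;
    g.bc[l] = arma::sum(dz, 0).t();
    if (l > 0) {
      arma::mat dcol = dz * np.Wc[l].t();
      const int cin = np.Wc[l - 1].n_cols;
      dact.set_size(static_cast<size_t>(hin) * win * nb, cin);
      col2im3(dcol, hin, win, nb, dact);
      hh = hin; ww = win;
    }
  }
}

struct AdamState {
  std::vector<arma::mat> mWc, vWc;
  std::vector<arma::vec> mbc, vbc;
  arma::mat mW1, vW1, mW2, vW2;
  arma::vec mb1, vb1, mb2, vb2;
  long t = 0;
  void init(const NetParams& np) {
    for (auto& W : np.Wc) {
      mWc.push_back(arma::zeros<arma::mat>(W.n_rows, W.n_cols));
      vWc.push_back(arma::zeros<arma::mat>(W.n_rows, W.n_cols));
    }
    for (auto& b : np.bc) {
      mbc.push_back(arma::zeros<arma::vec>(b.n_elem));
      vbc.push_back(arma::zeros<arma::vec>(b.n_elem));
    }
    mW1 = arma::zeros<arma::mat>(np.W1.n_rows, np.W1.n_cols); vW1 = mW1;
    mW2 = arma::zeros<arma::mat>(np.W2.n_rows, np.W2.n_cols); vW2 = mW2;
    mb1 = arma::zeros<arma::vec>(np.b1.n_elem); vb1 = mb1;
    mb2 = arma::zeros<arma::vec>(np.b2.n_elem); vb2 = mb2;
  }
};

template <typename T>
void adam_update(T& param, T& m, T& v, const T& grad, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * (grad % grad);
  const double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)t)) /
                      (1.0 - std::pow(b1, (double)t));
  param -= corr * (m / (arma::sqrt(v) + eps));
}

double eval_set(const NetParams& np, const arma::mat& X, const arma::uvec& y,
                int h, int w, int c0, int batch, double* loss_out) {
  const int n = X.n_cols;
  int correct = 0;
  double loss = 0.0;
  ForwardCache fc;
  for (int s = 0; s < n; s += batch) {
    const int e = std::min(n, s + batch);
    forward_pass(np, X.cols(s, e - 1), h, w, c0, fc, false);
    for (int i = 0; i < e - s; ++i) {
      if (fc.probs.col(i).index_max() == y(s + i)) ++correct;
      loss -= std::log(std::max(fc.probs(y(s + i), i), 1e-300));
    }
  }
  if (loss_out) *loss_out = loss / n;
  return static_cast<double>(correct) / n;
}

}  // namespace

// [[Rcpp::export]]
List cnn_forward_cpp(List params, const arma::mat& X, int h, int w, int c0,
                     int n_conv, bool features, int batch = 64) {
  NetParams np = params_from_list(params, n_conv);
  const int n = X.n_cols;
  arma::mat probs(np.W2.n_rows, n);
  arma::mat feat;
  if (features) feat.set_size(np.W1.n_rows, n);
  ForwardCache fc;
  for (int s = 0; s < n; s += batch) {
    const int e = std::min(n, s + batch);
    forward_pass(np, X.cols(s, e - 1), h, w, c0, fc, false);
    probs.cols(s, e - 1) = fc.probs;
    if (features) feat.cols(s, e - 1) = fc.a1;
  }
  if (features)
    return List::create(_["probs"] = wrap(probs.t()),
                        _["features"] = wrap(feat.t()));
  return List::create(_["probs"] = wrap(probs.t()));
}

// perms: n_train x max_epochs matrix of 1-based shuffled indices drawn in R.
// [[Rcpp::export]]
List cnn_train_cpp(List params, const arma::mat& Xtr, const arma::uvec& ytr,
                   const arma::mat& Xval, const arma::uvec& yval,
                   int h, int w, int c0, int n_conv,
                   double lr, int batch, int max_epochs, int patience,
                   const arma::umat& perms) {
  NetParams np = params_from_list(params, n_conv);
  AdamState adam;
  adam.init(np);
  const int ntr = Xtr.n_cols;
  const bool has_val = Xval.n_cols > 0;

  NetParams best = np;
  double best_val = -1.0;
  int best_epoch = 0, since_best = 0;
  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;

  ForwardCache fc;
  Grads g;
  arma::mat Xb(Xtr.n_rows, std::min(batch, ntr));
  for (int ep = 0; ep < max_epochs; ++ep) {
    double ep_loss = 0.0;
    int ep_correct = 0;
    for (int s = 0; s < ntr; s += batch) {
      const int e = std::min(ntr, s + batch);
      const int nb = e - s;
      Xb.set_size(Xtr.n_rows, nb);
      arma::uvec yb(nb);
      for (int i = 0; i < nb; ++i) {
        const arma::uword src = perms(s + i, ep) - 1;
        Xb.col(i) = Xtr.col(src);
        yb(i) = ytr(src);
      }
      forward_pass(np, Xb, h, w, c0, fc, true);
      for (int i = 0; i < nb; ++i) {
        ep_loss -= std::log(std::max(fc.probs(yb(i), i), 1e-300));
        if (fc.probs.col(i).index_max() == yb(i)) ++ep_correct;
      }
      backward_pass(np, fc, yb, h, w, nb, g);
      ++adam.t;
      for (int l = 0; l < n_conv; ++l) {
        adam_update(np.Wc[l], adam.mWc[l], adam.vWc[l], g.Wc[l], lr, adam.t);
        adam_update(np.bc[l], adam.mbc[l], adam.vbc[l], g.bc[l], lr, adam.t);
      }
      adam_update(np.W1, adam.mW1, adam.vW1, g.W1, lr, adam.t);
      adam_update(np.b1, adam.mb1, adam.vb1, g.b1, lr, adam.t);
      adam_update(np.W2, adam.mW2, adam.vW2, g.W2, lr, adam.t);
      adam_update(np.b2, adam.mb2, adam.vb2, g.b2, lr, adam.t);
    }
    tr_loss.push_back(ep_loss / ntr);
    tr_acc.push_back(static_cast<double>(ep_correct) / ntr);
    if (has_val) {
      double vl = 0.0;
      const double va = eval_set(np, Xval, yval, h, w, c0, batch, &vl);
      va_loss.push_back(vl);
      va_acc.push_back(va);
      if (va > best_val + 1e-12) {
        best_val = va;
        best = np;
        best_epoch = ep + 1;
        since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    } else {
      best = np;
      best_epoch = ep + 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["params"] = params_to_list(best),
      _["best_epoch"] = best_epoch,
      _["train_loss"] = wrap(tr_loss), _["train_acc"] = wrap(tr_acc),
      _["val_loss"] = wrap(va_loss), _["val_acc"] = wrap(va_acc));
}
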