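// Compact CNN engine: conv (same padding, arbitrary stride) via im2col +
// single-precision BLAS gemm, 2x2 max pooling, ReLU, dense layers, inverted
// dropout, softmax cross-entropy, and Adam/SGD/RMSProp/AdaGrad updates.
// Activation layout is channel-fastest: idx = ch + C*(y + H*x); a sample is
// one column of an (C*H*W) x B matrix.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::as;

enum LType { CONV = 0, RELU, POOL, FLATTEN, DENSE, DROPOUT };

struct Layer {
  int type;
  // spatial bookkeeping (conv/pool)
  int k = 3, stride = 1, pad = 0;
  int cin = 0, cout = 0, hin = 0, win = 0, hout = 0, wout = 0;
  int nin = 0, nout = 0; // dense
  double rate = 0.0;     // dropout
  int widx = -1;         // index into the weight list, -1 if none
};

struct Net {
  std::vector<Layer> layers;
  std::vector<fmat> W;
  std::vector<fvec> b;
  int input_dim = 0, n_classes = 0;
};

static std::vector<Layer> parse_arch(List arch, int side, int channels) {
  std::vector<Layer> ls;
  int h = side, w = side, c = channels;
  bool flat = false;
  int nfeat = 0, widx = 0;
  for (int i = 0; i < arch.size(); ++i) {
    List sp = arch[i];
    std::string type = as<std::string>(sp["type"]);
    Layer L;
    if (type == "conv") {
      L.type = CONV;
      L.k = sp.containsElementNamed("kernel") ? as<int>(sp["kernel"]) : 3;
      L.stride = sp.containsElementNamed("stride") ? as<int>(sp["stride"]) : 1;
      L.cin = c; L.cout = as<int>(sp["filters"]);
      L.hin = h; L.win = w;
      L.hout = (h + L.stride - 1) / L.stride; // ceil(h/stride), "same" padding
      L.wout = (w + L.stride - 1) / L.stride;
      int pad_total = std::max((L.hout - 1) * L.stride + L.k - h, 0);
      L.pad = pad_total / 2;
      L.widx = widx++;
      h = L.hout; w = L.wout; c = L.cout;
    } else if (type == "relu") {
      L.type = RELU;
    } else if (type == "pool") {
      L.type = POOL;
      L.k = sp.containsElementNamed("size") ? as<int>(sp["size"]) : 2;
      L.stride = L.k;
      L.cin = c; L.hin = h; L.win = w;
      L.hout = h / L.k; L.wout = w / L.k; // floor: trailing rows/cols dropped
      h = L.hout; w = L.wout;
    } else if (type == "flatten") {
      L.type = FLATTEN;
      flat = true; nfeat = c * h * w;
    } else if (type == "dense") {
      L.type = DENSE;
      L.nin = flat ? nfeat : c * h * w;
      L.nout = as<int>(sp["units"]);
      L.widx = widx++;
      flat = true; nfeat = L.nout;
    } else if (type == "dropout") {
      L.type = DROPOUT;
      L.rate = as<double>(sp["rate"]);
    } else {
      Rcpp::stop("unknown layer type: %s", type.c_str());
    }
    ls.push_back(L);
  }
  return ls;
}

static Net make_net(List arch, List weights, int side, int channels) {
  Net net;
  net.layers = parse_arch(arch, side, channels);
  net.input_dim = side * side * channels;
  for (auto &L : net.layers) {
    if (L.widx >= 0) {
      List wl = weights[L.widx];
      net.W.push_back(conv_to<fmat>::from(as<mat>(wl["W"])));
      net.b.push_back(conv_to<fvec>::from(as<vec>(wl["b"])));
    }
    if (L.type == DENSE) net.n_classes = L.nout;
  }
  return net;
}

// im2col for one sample: col p = oy + hout*ox; row = ch + cin*(ky + k*kx)
static void im2col(const float *x, float *col, const Layer &L) {
  const int kk = L.k * L.k;
  for (int ox = 0; ox < L.wout; ++ox) {
    for (int oy = 0; oy < L.hout; ++oy) {
      float *dst = col + (size_t)(oy + (size_t)L.hout * ox) * (kk * L.cin);
      for (int kx = 0; kx < L.k; ++kx) {
        const int ix = ox * L.stride - L.pad + kx;
        for (int ky = 0; ky < L.k; ++ky) {
          const int iy = oy * L.stride - L.pad + ky;
          float *d = dst + (size_t)L.cin * (ky + L.k * kx);
          if (ix < 0 || ix >= L.win || iy < 0 || iy >= L.hin) {
            std::fill(d, d + L.cin, 0.0f);
          } else {
            const float *s = x + (size_t)L.cin * (iy + (size_t)L.hin * ix);
            std::copy(s, s + L.cin, d);
          }
        }
      }
    }
  }
}

static void col2im_add(float *x, const float *col, const Layer &L) {
  const int kk = L.k * L.k;
  for (int ox = 0; ox < L.wout; ++ox) {
    for (int oy = 0; oy < L.hout; ++oy) {
      const float *src = col + (size_t)(oy + (size_t)L.hout * ox) * (kk * L.cin);
      for (int kx = 0; kx < L.k; ++kx) {
        const int ix = ox * L.stride - L.pad + kx;
        if (ix < 0 || ix >= L.win) continue;
        for (int ky = 0; ky < L.k; ++ky) {
          const int iy = oy * L.stride - L.pad + ky;
          if (iy < 0 || iy >= L.hin) continue;
          float *d = x + (size_t)L.cin * (iy + (size_t)L.hin * ix);
          const float *s = src + (size_t)L.cin * (ky + L.k * kx);
          for (int ch = 0; ch < L.cin; ++ch) d[ch] += s[ch];
        }
      }
    }
  }
}

struct Cache {
  std::vector<fmat> acts;   // acts[i] = input to layer i; acts.back() = logits
  std::vector<fmat> cols;   // im2col matrices per conv layer index
  std::vector<umat> argmax; // pool argmax (flat input index) per pool layer
  std::vector<fmat> dropmask;
};

static fmat forward(const Net &net, const fmat &X, bool training,
                    std::mt19937 *rng, Cache *cache) {
  const int B = X.n_cols;
  fmat a = X;
  if (cache) cache->acts.clear();
  for (size_t li = 0; li < net.layers.size(); ++li) {
    const Layer &L = net.layers[li];
    if (cache) cache->acts.push_back(a);
    if (L.type == CONV) {
      const int hw = L.hout * L.wout, kkc = L.k * L.k * L.cin;
      fmat cols(kkc, (size_t)hw * B);
      for (int s = 0; s < B; ++s)
        im2col(a.colptr(s), cols.colptr((size_t)s * hw), L);
      fmat O = net.W[L.widx] * cols;         // cout x (hw*B)
      O.each_col() += net.b[L.widx];
      // ch-fastest layout: (cout x hw*B) and (cout*hw x B) share memory order
      O.reshape(L.cout * hw, B);
      if (cache) cache->cols.push_back(std::move(cols));
      a = std::move(O);
    } else if (L.type == RELU) {
      a.transform([](float v) { return v > 0 ? v : 0.0f; });
    } else if (L.type == POOL) {
      const int hw = L.hout * L.wout;
      fmat out(L.cin * hw, B, fill::zeros);
      umat amx;
      if (cache) amx.set_size(L.cin * hw, B);
      for (int s = 0; s < B; ++s) {
        const float *x = a.colptr(s);
        float *o = out.colptr(s);
        for (int ox = 0; ox < L.wout; ++ox)
          for (int oy = 0; oy < L.hout; ++oy)
            for (int ch = 0; ch < L.cin; ++ch) {
              float best = -std::numeric_limits<float>::infinity();
              size_t bidx = 0;
              for (int dx = 0; dx < L.k; ++dx)
                for (int dy = 0; dy < L.k; ++dy) {
                  const size_t idx = ch + (size_t)L.cin *
                    ((oy * L.k + dy) + (size_t)L.hin * (ox * L.k + dx));
                  if (x[idx] > best) { best = x[idx]; bidx = idx; }
                }
              const size_t oidx = ch + (size_t)L.cin * (oy + (size_t)L.hout * ox);
              o[oidx] = best;
              if (cache) amx(oidx, s) = bidx;
            }
      }
      if (cache) cache->argmax.push_back(std::move(amx));
      a = std::move(out);
    } else if (L.type == FLATTEN) {
      // layout is already a flat column per sample
    } else if (L.type == DENSE) {
      fmat out = net.W[L.widx] * a;
      out.each_col() += net.b[L.widx];
      a = std::move(out);
    } else if (L.type == DROPOUT) {
      if (training && L.rate > 0) {
        std::uniform_real_distribution<float> U(0.0f, 1.0f);
        fmat mask(a.n_rows, a.n_cols);
        const float keep = 1.0f - (float)L.rate;
        for (uword q = 0; q < mask.n_elem; ++q)
          mask(q) = (U(*rng) < keep) ? 1.0f / keep : 0.0f;
        a %= mask;
        if (cache) cache->dropmask.push_back(std::move(mask));
      } else if (cache) {
        cache->dropmask.push_back(fmat());
      }
    }
  }
  return a; // logits
}

static fmat softmax_cols(const fmat &logits) {
  fmat p = logits;
  p.each_row() -= max(p, 0);
  p = exp(p);
  p.each_row() /= sum(p, 0);
  return p;
}

// backward pass: returns gradients per weight tensor
static void backward(const Net &net, Cache &cache, fmat delta,
                     std::vector<fmat> &gW, std::vector<fvec> &gb) {
  int ci = (int)cache.cols.size() - 1;
  int pi = (int)cache.argmax.size() - 1;
  int di = (int)cache.dropmask.size() - 1;
  for (int li = (int)net.layers.size() - 1; li >= 0; --li) {
    const Layer &L = net.layers[li];
    const fmat &ain = cache.acts[li];
    if (L.type == DENSE) {
      gW[L.widx] = delta * ain.t();
      gb[L.widx] = sum(delta, 1);
      delta = net.W[L.widx].t() * delta;
    } else if (L.type == RELU) {
      // ain is pre-activation input; mask on positives
      delta %= conv_to<fmat>::from(ain > 0);
    } else if (L.type == DROPOUT) {
      const fmat &m = cache.dropmask[di--];
      if (m.n_elem) delta %= m;
    } else if (L.type == FLATTEN) {
      // no-op
    } else if (L.type == POOL) {
      const umat &amx = cache.argmax[pi--];
      const int B = delta.n_cols;
      fmat out(L.cin * L.hin * L.win, B, fill::zeros);
      for (int s = 0; s < B; ++s) {
        float *o = out.colptr(s);
        const float *d = delta.colptr(s);
        for (uword q = 0; q < amx.n_rows; ++q) o[amx(q, s)] += d[q];
      }
      delta = std::move(out);
    } else if (L.type == CONV) {
      const int hw = L.hout * L.wout, B = delta.n_cols;
      const fmat &cols = cache.cols[ci--];
      // same memory order: (cout*hw x B) -> (cout x hw*B)
      delta.reshape(L.cout, (size_t)hw * B);
      gW[L.widx] = delta * cols.t();
      gb[L.widx] = sum(delta, 1);
      if (li == 0) break; // input gradients are never needed
      fmat dCols = net.W[L.widx].t() * delta;
      fmat out(L.cin * L.hin * L.win, B, fill::zeros);
      for (int s = 0; s < B; ++s)
        col2im_add(out.colptr(s),
                   dCols.colptr((size_t)s * hw), L);
      delta = std::move(out);
    }
  }
}

struct OptState {
  int kind; // 0 sgd, 1 adam, 2 rmsprop, 3 adagrad
  double lr, beta1, beta2, eps = 1e-7;
  long t = 0;
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
};

static void opt_init(OptState &st, const Net &net) {
  for (size_t i = 0; i < net.W.size(); ++i) {
    st.mW.push_back(fmat(size(net.W[i]), fill::zeros));
    st.vW.push_back(fmat(size(net.W[i]), fill::zeros));
    st.mb.push_back(fvec(size(net.b[i]), fill::zeros));
    st.vb.push_back(fvec(size(net.b[i]), fill::zeros));
  }
}

template <class MAT>
static void opt_update_one(OptState &st, MAT &w, const MAT &g, MAT &m, MAT &v) {
  const float lr = (float)st.lr;
  if (st.kind == 0) {
    w -= lr * g;
  } else if (st.kind == 1) {
    m = (float)st.beta1 * m + (1.0f - (float)st.beta1) * g;
    v = (float)st.beta2 * v + (1.0f - (float)st.beta2) * square(g);
    const double bc1 = 1.0 - std::pow(st.beta1, (double)st.t);
    const double bc2 = 1.0 - std::pow(st.beta2, (double)st.t);
    MAT mhat = m / (float)bc1, vhat = v / (float)bc2;
    w -= lr * mhat / (sqrt(vhat) + (float)st.eps);
  } else if (st.kind == 2) {
    v = 0.9f * v + 0.1f * square(g);
    w -= lr * g / (sqrt(v) + (float)st.eps);
  } else {
    v += square(g);
    w -= lr * g / (sqrt(v) + (float)st.eps);
  }
}

static void opt_step(OptState &st, Net &net, std::vector<fmat> &gW,
                     std::vector<fvec> &gb) {
  st.t += 1;
  for (size_t i = 0; i < net.W.size(); ++i) {
    opt_update_one(st, net.W[i], gW[i], st.mW[i], st.vW[i]);
    opt_update_one(st, net.b[i], gb[i], st.mb[i], st.vb[i]);
  }
}

static List weights_to_r(const Net &net) {
  List out(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i)
    out[i] = List::create(Rcpp::_["W"] = conv_to<mat>::from(net.W[i]),
                          Rcpp::_["b"] = conv_to<vec>::from(net.b[i]));
  return out;
}

// He-normal weight initialization, zero biases; deterministic in `seed`.
// [[Rcpp::export(name = ".cpp_cnn_init")]]
List cpp_cnn_init(List arch, int side, int channels, int seed) {
  std::vector<Layer> ls = parse_arch(arch, side, channels);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  List out;
  for (auto &L : ls) {
    if (L.widx < 0) continue;
    int rows, cols, fan_in;
    if (L.type == CONV) {
      rows = L.cout; cols = L.k * L.k * L.cin; fan_in = cols;
    } else {
      rows = L.nout; cols = L.nin; fan_in = cols;
    }
    mat W(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword q = 0; q < W.n_elem; ++q) W(q) = sd * N01(rng);
    out.push_back(List::create(Rcpp::_["W"] = W,
                               Rcpp::_["b"] = vec(rows, fill::zeros)));
  }
  return out;
}

static double batch_loss_acc(const fmat &P, const ivec &y, double &acc) {
  const int B = P.n_cols;
  double loss = 0; int correct = 0;
  for (int s = 0; s < B; ++s) {
    const float p = std::max(P(y[s], s), 1e-12f);
    loss += -std::log((double)p);
    uword am; P.col(s).max(am);
    if ((int)am == y[s]) ++correct;
  }
  acc = (double)correct / B;
  return loss / B;
}

// X: d x n (columns are samples), y: 0-based class index.
// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(List arch, List weights, arma::mat X, arma::ivec y,
                   arma::mat Xval, arma::ivec yval, int side, int channels,
                   List opts) {
  Net net = make_net(arch, weights, side, channels);
  const int n = X.n_cols, epochs = as<int>(opts["epochs"]);
  const int batch = as<int>(opts["batch_size"]);
  std::string oname = as<std::string>(opts["optimizer"]);
  OptState st;
  st.kind = oname == "sgd" ? 0 : oname == "adam" ? 1 : oname == "rmsprop" ? 2 : 3;
  st.lr = as<double>(opts["learning_rate"]);
  st.beta1 = as<double>(opts["beta1"]);
  st.beta2 = as<double>(opts["beta2"]);
  opt_init(st, net);
  std::mt19937 rng((unsigned)as<int>(opts["seed"]));

  fmat Xf = conv_to<fmat>::from(X);
  fmat Xvf = conv_to<fmat>::from(Xval);
  const int nval = Xvf.n_cols;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<fmat> gW(net.W.size());
  std::vector<fvec> gb(net.W.size());
  mat history(epochs, 4); // train_loss, train_acc, val_loss, val_acc

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double eloss = 0, eacc = 0; int nb = 0;
    for (int start = 0; start < n; start += batch) {
      const int B = std::min(batch, n - start);
      fmat Xb(Xf.n_rows, B);
      ivec yb(B);
      for (int s = 0; s < B; ++s) {
        Xb.col(s) = Xf.col(idx[start + s]);
        yb[s] = y[idx[start + s]];
      }
      Cache cache;
      fmat logits = forward(net, Xb, true, &rng, &cache);
      fmat P = softmax_cols(logits);
      double acc;
      eloss += batch_loss_acc(P, yb, acc);
      eacc += acc; ++nb;
      fmat delta = P;
      for (int s = 0; s < B; ++s) delta(yb[s], s) -= 1.0f;
      delta /= (float)B;
      backward(net, cache, delta, gW, gb);
      opt_step(st, net, gW, gb);
    }
    history(e, 0) = eloss / nb;
    history(e, 1) = eacc / nb;
    // validation pass
    double vloss = 0, vacc = 0;
    if (nval > 0) {
      int vb = 0;
      for (int start = 0; start < nval; start += 64) {
        const int B = std::min(64, nval - start);
        fmat Xb = Xvf.cols(start, start + B - 1);
        ivec yb = yval.subvec(start, start + B - 1);
        fmat P = softmax_cols(forward(net, Xb, false, nullptr, nullptr));
        double acc;
        const double l = batch_loss_acc(P, yb, acc);
        vloss += l * B; vacc += acc * B; vb += B;
      }
      vloss /= vb; vacc /= vb;
    }
    history(e, 2) = vloss;
    history(e, 3) = vacc;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Rcpp::_["weights"] = weights_to_r(net),
                      Rcpp::_["history"] = history);
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
arma::mat cpp_cnn_predict(List arch, List weights, arma::mat X, int side,
                          int channels) {
  Net net = make_net(arch, weights, side, channels);
  const int n = X.n_cols;
  fmat Xf = conv_to<fmat>::from(X);
  mat out(net.n_classes, n);
  for (int start = 0; start < n; start += 64) {
    const int B = std::min(64, n - start);
    fmat P = softmax_cols(forward(net, Xf.cols(start, start + B - 1),
                                  false, nullptr, nullptr));
    out.cols(start, start + B - 1) = conv_to<mat>::from(P);
  }
  return out;
}

// Activations at the flatten layer (the conv/pool feature vector).
// [[Rcpp::export(name = ".cpp_cnn_features")]]
arma::mat cpp_cnn_features(List arch, List weights, arma::mat X, int side,
                           int channels) {
  Net net = make_net(arch, weights, side, channels);
  // truncate at the flatten layer; weight indices of the prefix stay valid
  Net trunc;
  trunc.W = net.W; trunc.b = net.b;
  for (auto &L : net.layers) {
    if (L.type == FLATTEN) break;
    trunc.layers.push_back(L);
  }
  fmat F = forward(trunc, conv_to<fmat>::from(X), false, nullptr, nullptr);
  return conv_to<mat>::from(F);
}
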