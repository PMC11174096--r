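// Compact 2D convolutional network for residue contact-map classification.
//
// Architecture (fixed topology, configurable sizes): four 3x3 "same" conv
// layers with ReLU and 2x2 max pooling after each, then two ReLU dense
// layers with inverted dropout, then a linear classification layer with
// softmax cross-entropy.  Convolutions are evaluated as im2col + GEMM in
// single precision so training stays practical on one CPU core.
//
// All randomness (weight init, shuffling, dropout) flows from one explicit
// 64-bit seed, so training is bit-reproducible for a given seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::uword;

struct CnnShape {
  int H, W, n_classes;
  int cf[4];    // conv filter counts
  int dn[2];    // dense layer sizes
  float dropout;
  // derived per-conv-block spatial dims (input of block l)
  int h[5], w[5], cin[5]; // index 0..3 conv inputs, 4 = flatten input dims
};

static CnnShape make_shape(const Rcpp::List &config) {
  CnnShape s;
  s.H = Rcpp::as<int>(config["height"]);
  s.W = Rcpp::as<int>(config["width"]);
  s.n_classes = Rcpp::as<int>(config["n_classes"]);
  Rcpp::IntegerVector cf = config["conv_filters"];
  Rcpp::IntegerVector dn = config["dense_units"];
  if (cf.size() != 4 || dn.size() != 2)
    Rcpp::stop("expected 4 conv layers and 2 dense layers");
  for (int i = 0; i < 4; ++i) s.cf[i] = cf[i];
  for (int i = 0; i < 2; ++i) s.dn[i] = dn[i];
  s.dropout = Rcpp::as<double>(config["dropout"]);
  if ((s.H % 16) != 0 || (s.W % 16) != 0 || s.H < 16 || s.W < 16)
    Rcpp::stop("image size %dx%d cannot pass four 2x2 poolings; "
               "dimensions must be multiples of 16", s.H, s.W);
  int h = s.H, w = s.W, c = 1;
  for (int l = 0; l < 4; ++l) {
    s.h[l] = h; s.w[l] = w; s.cin[l] = c;
    h /= 2; w /= 2; c = s.cf[l];
  }
  s.h[4] = h; s.w[4] = w; s.cin[4] = c;
  return s;
}

struct CnnParams {
  fmat Wc[4]; fvec bc[4];
  fmat Wd[3]; fvec bd[3];
  std::vector<fmat *> mats() {
    return {&Wc[0], &Wc[1], &Wc[2], &Wc[3], &Wd[0], &Wd[1], &Wd[2]};
  }
  std::vector<fvec *> vecs() {
    return {&bc[0], &bc[1], &bc[2], &bc[3], &bd[0], &bd[1], &bd[2]};
  }
};

static void init_params(CnnParams &p, const CnnShape &s, std::mt19937_64 &rng) {
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  auto he = [&](fmat &m, int rows, int cols, int fan_in) {
    m.set_size(rows, cols);
    float sd = std::sqrt(2.0f / fan_in);
    for (uword i = 0; i < m.n_elem; ++i) m[i] = sd * gauss(rng);
  };
  for (int l = 0; l < 4; ++l) {
    int fan = s.cin[l] * 9;
    he(p.Wc[l], s.cf[l], fan, fan);
    p.bc[l].zeros(s.cf[l]);
  }
  int flat = s.cin[4] * s.h[4] * s.w[4];
  int dims[4] = {flat, s.dn[0], s.dn[1], s.n_classes};
  for (int l = 0; l < 3; ++l) {
    he(p.Wd[l], dims[l + 1], dims[l], dims[l]);
    p.bd[l].zeros(dims[l + 1]);
  }
}

static CnnParams params_from_list(const Rcpp::List &lst) {
  CnnParams p;
  const char *wn[4] = {"Wc1", "Wc2", "Wc3", "Wc4"};
  const char *bn[4] = {"bc1", "bc2", "bc3", "bc4"};
  const char *wd[3] = {"Wd1", "Wd2", "Wd3"};
  const char *bdn[3] = {"bd1", "bd2", "bd3"};
  for (int l = 0; l < 4; ++l) {
    p.Wc[l] = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst[wn[l]]));
    p.bc[l] = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst[bn[l]]));
  }
  for (int l = 0; l < 3; ++l) {
    p.Wd[l] = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lst[wd[l]]));
    p.bd[l] = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lst[bdn[l]]));
  }
  return p;
}

static Rcpp::List params_to_list(const CnnParams &p) {
  auto M = [](const fmat &m) {
    return Rcpp::wrap(arma::conv_to<arma::mat>::from(m));
  };
  auto V = [](const fvec &v) {
    return Rcpp::wrap(arma::conv_to<arma::vec>::from(v));
  };
  return Rcpp::List::create(
      Rcpp::Named("Wc1") = M(p.Wc[0]), Rcpp::Named("Wc2") = M(p.Wc[1]),
      Rcpp::Named("Wc3") = M(p.Wc[2]), Rcpp::Named("Wc4") = M(p.Wc[3]),
      Rcpp::Named("bc1") = V(p.bc[0]), Rcpp::Named("bc2") = V(p.bc[1]),
      Rcpp::Named("bc3") = V(p.bc[2]), Rcpp::Named("bc4") = V(p.bc[3]),
      Rcpp::Named("Wd1") = M(p.Wd[0]), Rcpp::Named("Wd2") = M(p.Wd[1]),
      Rcpp::Named("Wd3") = M(p.Wd[2]), Rcpp::Named("bd1") = V(p.bd[0]),
      Rcpp::Named("bd2") = V(p.bd[1]), Rcpp::Named("bd3") = V(p.bd[2]));
}

// A: (C*H*W) x B activations -> K: (C*9) x (H*W*B) patch matrix, zero padded
static void im2col(const fmat &A, int C, int H, int W, int B, fmat &K) {
  K.set_size(C * 9, H * W * B);
  for (int b = 0; b < B; ++b) {
    const float *acol = A.colptr(b);
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        uword col = (uword)b * H * W + (uword)r * W + c;
        float *kcol = K.colptr(col);
        for (int ch = 0; ch < C; ++ch) {
          const float *ain = acol + (uword)ch * H * W;
          float *kout = kcol + ch * 9;
          for (int kr = -1; kr <= 1; ++kr) {
            int rr = r + kr;
            for (int kc = -1; kc <= 1; ++kc) {
              int cc = c + kc;
              *kout++ = (rr >= 0 && rr < H && cc >= 0 && cc < W)
                            ? ain[(uword)rr * W + cc]
                            : 0.0f;
            }
          }
        }
      }
    }
  }
}

// reverse of im2col: scatter-add K gradients back onto the activation grid
static void col2im(const fmat &K, int C, int H, int W, int B, fmat &A) {
  A.zeros(C * H * W, B);
  for (int b = 0; b < B; ++b) {
    float *acol = A.colptr(b);
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        uword col = (uword)b * H * W + (uword)r * W + c;
        const float *kcol = K.colptr(col);
        for (int ch = 0; ch < C; ++ch) {
          float *aout = acol + (uword)ch * H * W;
          const float *kin = kcol + ch * 9;
          for (int kr = -1; kr <= 1; ++kr) {
            int rr = r + kr;
            for (int kc = -1; kc <= 1; ++kc) {
              int cc = c + kc;
              float v = *kin++;
              if (rr >= 0 && rr < H && cc >= 0 && cc < W)
                aout[(uword)rr * W + cc] += v;
            }
          }
        }
      }
    }
  }
}

struct Cache {
  fmat A[5];            // activations entering each conv block; A[4] = flatten
  fmat K[4];            // im2col matrices
  fmat Y[4];            // post-ReLU conv maps, F x (H*W*B)
  arma::umat amax[4];   // pool argmax (column index into Y)
  fmat Z1, Z2;          // post-ReLU (and post-dropout) dense activations
  fmat M1, M2;          // dropout masks
  fmat logits, probs;
};

static void forward(const CnnParams &p, const CnnShape &s, const fmat &X,
                    bool use_dropout, std::mt19937_64 *rng, Cache &cc) {
  int B = X.n_cols;
  cc.A[0] = X;
  for (int l = 0; l < 4; ++l) {
    int H = s.h[l], W = s.w[l], C = s.cin[l], F = s.cf[l];
    im2col(cc.A[l], C, H, W, B, cc.K[l]);
    cc.Y[l] = p.Wc[l] * cc.K[l];
    cc.Y[l].each_col() += p.bc[l];
    cc.Y[l].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    // 2x2 max pool into channel-major layout for the next block
    int H2 = H / 2, W2 = W / 2;
    cc.A[l + 1].set_size((uword)F * H2 * W2, B);
    cc.amax[l].set_size((uword)F * H2 * W2, B);
    for (int b = 0; b < B; ++b) {
      uword base = (uword)b * H * W;
      for (int f = 0; f < F; ++f) {
        const fmat &Y = cc.Y[l];
        for (int r2 = 0; r2 < H2; ++r2) {
          for (int c2 = 0; c2 < W2; ++c2) {
            uword i00 = base + (uword)(2 * r2) * W + 2 * c2;
            uword cand[4] = {i00, i00 + 1, i00 + W, i00 + W + 1};
            uword best = cand[0];
            float bv = Y((uword)f, cand[0]);
            for (int q = 1; q < 4; ++q) {
              float v = Y((uword)f, cand[q]);
              if (v > bv) { bv = v; best = cand[q]; }
            }
            uword out = (uword)f * H2 * W2 + (uword)r2 * W2 + c2;
            cc.A[l + 1](out, b) = bv;
            cc.amax[l](out, b) = best;
          }
        }
      }
    }
  }
  // dense head
  float keep = 1.0f - s.dropout;
  auto dropmask = [&](fmat &M, uword nr, uword nc) {
    M.set_size(nr, nc);
    if (use_dropout && s.dropout > 0.0f) {
      std::uniform_real_distribution<float> unif(0.0f, 1.0f);
      for (uword i = 0; i < M.n_elem; ++i)
        M[i] = unif(*rng) < keep ? 1.0f / keep : 0.0f;
    } else {
      M.ones();
    }
  };
  cc.Z1 = p.Wd[0] * cc.A[4];
  cc.Z1.each_col() += p.bd[0];
  cc.Z1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  dropmask(cc.M1, cc.Z1.n_rows, cc.Z1.n_cols);
  cc.Z1 %= cc.M1;
  cc.Z2 = p.Wd[1] * cc.Z1;
  cc.Z2.each_col() += p.bd[1];
  cc.Z2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  dropmask(cc.M2, cc.Z2.n_rows, cc.Z2.n_cols);
  cc.Z2 %= cc.M2;
  cc.logits = p.Wd[2] * cc.Z2;
  cc.logits.each_col() += p.bd[2];
  // softmax (stabilized)
  cc.probs = cc.logits;
  for (uword b = 0; b < cc.probs.n_cols; ++b) {
    fvec col = cc.probs.col(b);
    col -= col.max();
    col = arma::exp(col);
    cc.probs.col(b) = col / arma::accu(col);
  }
}

// backward from dLogits; fills grads g and (optionally) the input gradient
static void backward(const CnnParams &p, const CnnShape &s, const Cache &cc,
                     const fmat &dLogits, CnnParams &g, fmat *dInput) {
  int B = dLogits.n_cols;
  g.Wd[2] = dLogits * cc.Z2.t();
  g.bd[2] = arma::sum(dLogits, 1);
  fmat dZ2 = p.Wd[2].t() * dLogits;
  dZ2 %= cc.M2;
  dZ2.elem(arma::find(cc.Z2 <= 0.0f)).zeros();
  g.Wd[1] = dZ2 * cc.Z1.t();
  g.bd[1] = arma::sum(dZ2, 1);
  fmat dZ1 = p.Wd[1].t() * dZ2;
  dZ1 %= cc.M1;
  dZ1.elem(arma::find(cc.Z1 <= 0.0f)).zeros();
  g.Wd[0] = dZ1 * cc.A[4].t();
  g.bd[0] = arma::sum(dZ1, 1);
  fmat dA = p.Wd[0].t() * dZ1; // gradient on flatten = A[4]

  for (int l = 3; l >= 0; --l) {
    int H = s.h[l], W = s.w[l], C = s.cin[l], F = s.cf[l];
    // un-pool: scatter dA through the recorded argmax
    fmat dY(F, (uword)H * W * B, arma::fill::zeros);
    int H2 = H / 2, W2 = W / 2;
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F; ++f) {
        for (uword q = 0; q < (uword)H2 * W2; ++q) {
          uword out = (uword)f * H2 * W2 + q;
          dY((uword)f, cc.amax[l](out, b)) += dA(out, b);
        }
      }
    }
    dY.elem(arma::find(cc.Y[l] <= 0.0f)).zeros();
    g.Wc[l] = dY * cc.K[l].t();
    g.bc[l] = arma::sum(dY, 1);
    if (l > 0 || dInput != nullptr) {
      fmat dK = p.Wc[l].t() * dY;
      fmat dAprev;
      col2im(dK, C, H, W, B, dAprev);
      if (l > 0) dA = std::move(dAprev);
      else if (dInput != nullptr) *dInput = std::move(dAprev);
    }
  }
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat &X, Rcpp::IntegerVector y,
                         Rcpp::IntegerVector train_idx,
                         Rcpp::IntegerVector val_idx, Rcpp::List config,
                         int epochs, int batch_size, double learning_rate,
                         int seed, double early_stop_acc) {
  CnnShape s = make_shape(config);
  if ((uword)X.n_rows != (uword)s.H * s.W)
    Rcpp::stop("image pixel count does not match configured size");
  fmat Xf = arma::conv_to<fmat>::from(X);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  CnnParams p;
  init_params(p, s, rng);

  // Adam state
  CnnParams m, v;
  init_params(m, s, rng); // allocate shapes, then zero
  init_params(v, s, rng);
  for (auto *w : m.mats()) w->zeros();
  for (auto *w : v.mats()) w->zeros();
  for (auto *b : m.vecs()) b->zeros();
  for (auto *b : v.vecs()) b->zeros();

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float lr = (float)learning_rate;
  long t = 0;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());

  auto evaluate = [&](const std::vector<int> &idx, double &loss, double &acc) {
    loss = 0.0; long correct = 0;
    const int eb = 256;
    Cache cc;
    for (size_t start = 0; start < idx.size(); start += eb) {
      size_t stop = std::min(idx.size(), start + eb);
      int B = stop - start;
      fmat Xb(Xf.n_rows, B);
      for (int b = 0; b < B; ++b) Xb.col(b) = Xf.col(idx[start + b]);
      forward(p, s, Xb, false, nullptr, cc);
      for (int b = 0; b < B; ++b) {
        int lab = y[idx[start + b]];
        loss -= std::log(std::max(cc.probs(lab, b), 1e-12f));
        if ((int)cc.probs.col(b).index_max() == lab) ++correct;
      }
    }
    loss /= idx.size();
    acc = (double)correct / idx.size();
  };

  int n_epochs_run = 0;
  std::vector<double> h_trl, h_tra, h_vll, h_vla;
  Cache cc;
  CnnParams g;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0.0; long ep_correct = 0;
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      size_t stop = std::min(tr.size(), start + (size_t)batch_size);
      int B = stop - start;
      fmat Xb(Xf.n_rows, B);
      for (int b = 0; b < B; ++b) Xb.col(b) = Xf.col(tr[start + b]);
      forward(p, s, Xb, true, &rng, cc);
      fmat dL = cc.probs;
      for (int b = 0; b < B; ++b) {
        int lab = y[tr[start + b]];
        dL(lab, b) -= 1.0f;
        ep_loss -= std::log(std::max(cc.probs(lab, b), 1e-12f));
        if ((int)cc.probs.col(b).index_max() == lab) ++ep_correct;
      }
      dL /= (float)B;
      backward(p, s, cc, dL, g, nullptr);
      ++t;
      float bc1 = 1.0f - std::pow(b1, (float)t);
      float bc2 = 1.0f - std::pow(b2, (float)t);
      auto pw = p.mats(), gw = g.mats(), mw = m.mats(), vw = v.mats();
      for (size_t i = 0; i < pw.size(); ++i) {
        *mw[i] = b1 * (*mw[i]) + (1.0f - b1) * (*gw[i]);
        *vw[i] = b2 * (*vw[i]) + (1.0f - b2) * arma::square(*gw[i]);
        *pw[i] -= lr * ((*mw[i]) / bc1) / (arma::sqrt((*vw[i]) / bc2) + eps);
      }
      auto pb = p.vecs(), gb = g.vecs(), mb = m.vecs(), vb = v.vecs();
      for (size_t i = 0; i < pb.size(); ++i) {
        *mb[i] = b1 * (*mb[i]) + (1.0f - b1) * (*gb[i]);
        *vb[i] = b2 * (*vb[i]) + (1.0f - b2) * arma::square(*gb[i]);
        *pb[i] -= lr * ((*mb[i]) / bc1) / (arma::sqrt((*vb[i]) / bc2) + eps);
      }
    }
    double vl = 0.0, va_acc = 0.0;
    evaluate(va, vl, va_acc);
    h_trl.push_back(ep_loss / tr.size());
    h_tra.push_back((double)ep_correct / tr.size());
    h_vll.push_back(vl);
    h_vla.push_back(va_acc);
    n_epochs_run = ep + 1;
    Rcpp::checkUserInterrupt();
    if (early_stop_acc > 0.0 && va_acc >= early_stop_acc) break;
  }

  Rcpp::DataFrame hist = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq_len(n_epochs_run),
      Rcpp::Named("train_loss") = h_trl, Rcpp::Named("train_accuracy") = h_tra,
      Rcpp::Named("val_loss") = h_vll, Rcpp::Named("val_accuracy") = h_vla);
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p),
                            Rcpp::Named("history") = hist,
                            Rcpp::Named("epochs_run") = n_epochs_run);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(Rcpp::List params, const arma::mat &X,
                          Rcpp::List config) {
  CnnShape s = make_shape(config);
  CnnParams p = params_from_list(params);
  fmat Xf = arma::conv_to<fmat>::from(X);
  arma::mat out(s.n_classes, X.n_cols);
  const int eb = 256;
  Cache cc;
  for (uword start = 0; start < Xf.n_cols; start += eb) {
    uword stop = std::min(Xf.n_cols, start + eb);
    fmat Xb = Xf.cols(start, stop - 1);
    forward(p, s, Xb, false, nullptr, cc);
    out.cols(start, stop - 1) = arma::conv_to<arma::mat>::from(cc.probs);
  }
  return out;
}

// gradient of the pre-softmax class score with respect to the input pixels
// [[Rcpp::export(name = ".cnn_input_grad_cpp")]]
arma::vec cnn_input_grad_cpp(Rcpp::List params, const arma::vec &x,
                             int target_class, Rcpp::List config) {
  CnnShape s = make_shape(config);
  CnnParams p = params_from_list(params);
  fmat Xb = arma::conv_to<fmat>::from(arma::mat(x));
  Cache cc;
  forward(p, s, Xb, false, nullptr, cc);
  fmat dL(s.n_classes, 1, arma::fill::zeros);
  dL(target_class, 0) = 1.0f;
  CnnParams g;
  fmat dInput;
  backward(p, s, cc, dL, g, &dInput);
  return arma::conv_to<arma::vec>::from(fvec(dInput.col(0)));
}

// loss and parameter gradients on one batch without dropout; used by the
// finite-difference gradient checks in the test suite
// [[Rcpp::export(name = ".cnn_loss_grad_cpp")]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List params, const arma::mat &X,
                             Rcpp::IntegerVector y, Rcpp::List config,
                             bool want_grads) {
  CnnShape s = make_shape(config);
  CnnParams p = params_from_list(params);
  fmat Xb = arma::conv_to<fmat>::from(X);
  Cache cc;
  forward(p, s, Xb, false, nullptr, cc);
  int B = Xb.n_cols;
  double loss = 0.0;
  fmat dL = cc.probs;
  for (int b = 0; b < B; ++b) {
    dL(y[b], b) -= 1.0f;
    loss -= std::log(std::max(cc.probs(y[b], b), 1e-12f));
  }
  loss /= B;
  if (!want_grads)
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  dL /= (float)B;
  CnnParams g;
  backward(p, s, cc, dL, g, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(g));
}
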