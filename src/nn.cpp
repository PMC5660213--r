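// Siamese CNN engine: im2col convolution, batch normalization, overlapping
// max-pooling, tanh activations, inverted dropout, contrastive loss, and the
// full analytic backward pass.
//
// The engine is templated on the floating type and compiled twice: the
// single-precision instantiation is the training workhorse (the large
// feature-map GEMMs and their memory traffic dominate, and fp32 halves
// both), while the double-precision instantiation serves numerical
// verification (finite-difference gradient checks) and any caller that asks
// for it. Both share every line of algorithm code.
#include <RcppArmadillo.h>
#include <malloc.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::uword;

static const double BN_EPS = 1e-5;

// Large feature-map buffers are allocated and freed every call; keeping
// them on the program break instead of per-allocation mmap avoids
// re-faulting hundreds of MB of pages each training iteration.
static bool keep_heap_warm_done = []() {
  mallopt(M_MMAP_THRESHOLD, 1536 * 1024 * 1024);
  return true;
}();

struct ArchC {
  int side, K, kernel, pool, pool_stride;
  std::vector<int> conv_filters, fc_sizes, conv_sides;
  int flatten;
};

static ArchC parse_arch(const List& arch) {
  ArchC a;
  a.side = as<int>(arch["input_side"]);
  a.K = as<int>(arch["K"]);
  a.kernel = as<int>(arch["kernel"]);
  a.pool = as<int>(arch["pool"]);
  a.pool_stride = as<int>(arch["pool_stride"]);
  a.conv_filters = as<std::vector<int>>(arch["conv_filters"]);
  a.fc_sizes = as<std::vector<int>>(arch["fc_sizes"]);
  int s = a.side;
  for (size_t l = 0; l < a.conv_filters.size(); ++l) {
    if (s < a.pool)
      stop("architecture infeasible: map smaller than pool window at stage %d",
           (int)l + 1);
    s = (s - a.pool) / a.pool_stride + 1;
    a.conv_sides.push_back(s);
  }
  a.flatten = a.conv_filters.back() * s * s;
  return a;
}

template <typename eT>
static arma::Mat<eT> getM(const List& w, const std::string& nm) {
  return arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(w[nm]));
}
template <typename eT>
static arma::Col<eT> getV(const List& w, const std::string& nm) {
  return arma::conv_to<arma::Col<eT>>::from(as<arma::vec>(w[nm]));
}

// A: C x (H*W*B) channel-major feature maps -> Col: (C*k*k) x (H*W*B),
// zero padding (top/left = pad, bottom/right = k-1-pad) preserving size.
template <typename eT>
static arma::Mat<eT> im2col(const arma::Mat<eT>& A, int H, int W, int B,
                            int k, int pad) {
  const int C = A.n_rows;
  arma::Mat<eT> Col((size_t)C * k * k, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int roff = ki - pad, coff = kj - pad;
        const size_t r0 = (size_t)C * (ki + k * kj);
        const size_t dst_stride = (size_t)C * k * k;
        for (int j = 0; j < W; ++j) {
          const int sj = j + coff;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -roff), i1 = std::min(H, H - roff);
          // source and destination both advance with fixed stride in i
          const eT* src = A.colptr(base + (i0 + roff) + (size_t)H * sj);
          eT* dst = Col.colptr(base + i0 + (size_t)H * j) + r0;
          for (int i = i0; i < i1; ++i, src += C, dst += dst_stride) {
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
  return Col;
}

// Transpose of im2col: scatter-add dCol back onto the input feature map.
template <typename eT>
static void col2im_add(const arma::Mat<eT>& dCol, arma::Mat<eT>& dA, int H,
                       int W, int B, int k, int pad) {
  const int C = dA.n_rows;
  const size_t src_stride = dCol.n_rows;
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int roff = ki - pad, coff = kj - pad;
        const size_t r0 = (size_t)C * (ki + k * kj);
        for (int j = 0; j < W; ++j) {
          const int sj = j + coff;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -roff), i1 = std::min(H, H - roff);
          const eT* src = dCol.colptr(base + i0 + (size_t)H * j) + r0;
          eT* dst = dA.colptr(base + (i0 + roff) + (size_t)H * sj);
          for (int i = i0; i < i1; ++i, src += src_stride, dst += C) {
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

template <typename eT>
static void maxpool(const arma::Mat<eT>& T, int H, int W, int B, int pw,
                    int ps, arma::Mat<eT>& P, arma::Mat<uword>& AM) {
  const int Hp = (H - pw) / ps + 1, Wp = (W - pw) / ps + 1, C = T.n_rows;
  P.set_size(C, (size_t)Hp * Wp * B);
  AM.set_size(C, (size_t)Hp * Wp * B);
  for (int b = 0; b < B; ++b) {
    const size_t baseI = (size_t)b * H * W, baseO = (size_t)b * Hp * Wp;
    for (int jp = 0; jp < Wp; ++jp) {
      for (int ip = 0; ip < Hp; ++ip) {
        const size_t oc = baseO + ip + (size_t)Hp * jp;
        eT* pP = P.colptr(oc);
        uword* pA = AM.colptr(oc);
        bool first = true;
        for (int dj = 0; dj < pw; ++dj) {
          const int j = jp * ps + dj;
          for (int di = 0; di < pw; ++di) {
            const int i = ip * ps + di;
            const size_t ic = baseI + i + (size_t)H * j;
            const eT* pT = T.colptr(ic);
            if (first) {
              for (int c = 0; c < C; ++c) { pP[c] = pT[c]; pA[c] = ic; }
              first = false;
            } else {
              for (int c = 0; c < C; ++c)
                if (pT[c] > pP[c]) { pP[c] = pT[c]; pA[c] = ic; }
            }
          }
        }
      }
    }
  }
}

template <typename eT>
struct BNCache {
  arma::Mat<eT> zhat;
  arma::Col<eT> invstd, gamma, mean, var;
};

template <typename eT>
static arma::Mat<eT> bn_forward(arma::Mat<eT>&& Z, const arma::Col<eT>& gamma,
                                const arma::Col<eT>& beta,
                                const arma::Col<eT>& rmean,
                                const arma::Col<eT>& rvar, bool training,
                                BNCache<eT>* cache) {
  if (training) {
    arma::Col<eT> mu = arma::mean(Z, 1);
    Z.each_col() -= mu;
    arma::Col<eT> var = arma::mean(arma::square(Z), 1);
    arma::Col<eT> invstd = 1 / arma::sqrt(var + (eT)BN_EPS);
    Z.each_col() %= invstd;  // Z now holds zhat
    if (cache) {
      cache->zhat = Z; cache->invstd = invstd; cache->gamma = gamma;
      cache->mean = mu; cache->var = var;
    }
    Z.each_col() %= gamma;
    Z.each_col() += beta;
    return std::move(Z);
  }
  arma::Col<eT> invstd = 1 / arma::sqrt(rvar + (eT)BN_EPS);
  Z.each_col() -= rmean;
  Z.each_col() %= invstd % gamma;
  Z.each_col() += beta;
  return std::move(Z);
}

// Gradient through batch-statistics normalization.
template <typename eT>
static arma::Mat<eT> bn_backward(const arma::Mat<eT>& dzb,
                                 const BNCache<eT>& c, arma::Col<eT>& ggamma,
                                 arma::Col<eT>& gbeta) {
  ggamma = arma::sum(dzb % c.zhat, 1);
  gbeta = arma::sum(dzb, 1);
  arma::Mat<eT> dzhat = dzb.each_col() % c.gamma;
  arma::Col<eT> m1 = arma::mean(dzhat, 1);
  arma::Col<eT> m2 = arma::mean(dzhat % c.zhat, 1);
  dzhat.each_col() -= m1;
  dzhat -= c.zhat.each_col() % m2;
  dzhat.each_col() %= c.invstd;
  return dzhat;
}

template <typename eT>
struct ConvCache {
  arma::Mat<eT> Col, P;  // im2col input; pooled tanh output
  arma::Mat<uword> AM;   // pool argmax (source column per pooled entry)
  BNCache<eT> bn;
  int H, W;              // pre-pool map side
};

template <typename eT>
struct FcCache {
  arma::Mat<eT> Ain, T, mask;  // input, tanh activations, dropout mask
  BNCache<eT> bn;
  bool has_mask;
};

template <typename eT>
struct Caches {
  std::vector<ConvCache<eT>> conv;
  std::vector<FcCache<eT>> fc;
  arma::Mat<eT> A7, E;  // embedding-layer input and output
};

// Full forward pass. X0: 1 x (side*side*B). masks: per hidden fc layer a
// (units x B) matrix of 0 / (1/(1-p)) entries, or empty list for no dropout.
template <typename eT>
static arma::Mat<eT> forward_pass(const List& w, const ArchC& a,
                                  arma::Mat<eT>&& X0, int B, bool training,
                                  const List& masks, Caches<eT>* C,
                                  List* stats_out) {
  const int k = a.kernel, pad = (a.kernel - 1) / 2;
  arma::Mat<eT> A = std::move(X0);
  int H = a.side, W = a.side;
  if (C) C->conv.resize(a.conv_filters.size());
  for (size_t l = 0; l < a.conv_filters.size(); ++l) {
    std::string nm = "conv" + std::to_string(l + 1);
    arma::Mat<eT> Wm = getM<eT>(w, nm + ".W");
    arma::Col<eT> b = getV<eT>(w, nm + ".b");
    arma::Mat<eT> Col = im2col(A, H, W, B, k, pad);
    A.reset();
    arma::Mat<eT> Z = Wm * Col;
    Z.each_col() += b;
    BNCache<eT> bnc;
    arma::Mat<eT> Zb = bn_forward(std::move(Z),
                                  getV<eT>(w, nm + ".gamma"),
                                  getV<eT>(w, nm + ".beta"),
                                  getV<eT>(w, nm + ".rmean"),
                                  getV<eT>(w, nm + ".rvar"), training,
                                  (C || stats_out) ? &bnc : nullptr);
    // tanh is monotone increasing, so pooling commutes with it; pooling
    // the pre-activation first avoids a full-map tanh and its cache
    arma::Mat<eT> Ppre;
    arma::Mat<uword> AM;
    maxpool(Zb, H, W, B, a.pool, a.pool_stride, Ppre, AM);
    Zb.reset();
    arma::Mat<eT> P = arma::tanh(Ppre);
    Ppre.reset();
    if (stats_out && training) {
      (*stats_out)[nm + ".mean"] =
          wrap(arma::conv_to<arma::vec>::from(bnc.mean));
      (*stats_out)[nm + ".var"] =
          wrap(arma::conv_to<arma::vec>::from(bnc.var));
    }
    if (C) {
      ConvCache<eT>& cc = C->conv[l];
      cc.Col = std::move(Col); cc.P = P; cc.AM = std::move(AM);
      cc.bn = std::move(bnc); cc.H = H; cc.W = W;
    }
    A = std::move(P);
    H = a.conv_sides[l]; W = a.conv_sides[l];
  }
  // flatten: per image, the C x (H*W) block column-major (channel fastest)
  const int S = H * W, Cch = a.conv_filters.back();
  arma::Mat<eT> F(a.flatten, B);
  for (int b = 0; b < B; ++b) {
    std::memcpy(F.colptr(b), A.colptr((size_t)b * S),
                (size_t)Cch * S * sizeof(eT));
  }
  A.reset();
  arma::Mat<eT> Acur = std::move(F);
  if (C) C->fc.resize(a.fc_sizes.size());
  const bool use_masks = masks.size() > 0;
  for (size_t l = 0; l < a.fc_sizes.size(); ++l) {
    std::string nm = "fc" + std::to_string(l + 1 + a.conv_filters.size());
    arma::Mat<eT> Wm = getM<eT>(w, nm + ".W");
    arma::Col<eT> b = getV<eT>(w, nm + ".b");
    arma::Mat<eT> Z = Wm * Acur;
    Z.each_col() += b;
    BNCache<eT> bnc;
    arma::Mat<eT> Zb = bn_forward(std::move(Z),
                                  getV<eT>(w, nm + ".gamma"),
                                  getV<eT>(w, nm + ".beta"),
                                  getV<eT>(w, nm + ".rmean"),
                                  getV<eT>(w, nm + ".rvar"), training,
                                  (C || stats_out) ? &bnc : nullptr);
    arma::Mat<eT> T = arma::tanh(Zb);
    arma::Mat<eT> Out;
    arma::Mat<eT> mask;
    if (use_masks) {
      mask = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(masks[l]));
      Out = T % mask;
    } else {
      Out = T;
    }
    if (stats_out && training) {
      (*stats_out)[nm + ".mean"] =
          wrap(arma::conv_to<arma::vec>::from(bnc.mean));
      (*stats_out)[nm + ".var"] =
          wrap(arma::conv_to<arma::vec>::from(bnc.var));
    }
    if (C) {
      FcCache<eT>& fc = C->fc[l];
      fc.Ain = std::move(Acur); fc.T = std::move(T); fc.bn = std::move(bnc);
      fc.has_mask = use_masks;
      if (use_masks) fc.mask = std::move(mask);
    }
    Acur = std::move(Out);
  }
  arma::Mat<eT> W8 = getM<eT>(w, "fc8.W");
  arma::Col<eT> b8 = getV<eT>(w, "fc8.b");
  arma::Mat<eT> Z8 = W8 * Acur;
  Z8.each_col() += b8;
  arma::Mat<eT> E = arma::tanh(Z8);
  if (C) { C->A7 = std::move(Acur); C->E = E; }
  return E;
}

template <typename eT>
static void put_grad(List& grads, const std::string& nm,
                     const arma::Mat<eT>& g) {
  grads[nm] = wrap(arma::conv_to<arma::mat>::from(g));
}
template <typename eT>
static void put_grad_v(List& grads, const std::string& nm,
                       const arma::Col<eT>& g) {
  grads[nm] = wrap(arma::conv_to<arma::vec>::from(g));
}

// Backward pass from dE (K x B); fills grads with tensors shaped like the
// trainable weights.
template <typename eT>
static void backward_pass(const List& w, const ArchC& a, Caches<eT>& C,
                          const arma::Mat<eT>& dE, int B, List& grads) {
  arma::Mat<eT> dZ8 = dE % (1 - arma::square(C.E));
  put_grad(grads, "fc8.W", arma::Mat<eT>(dZ8 * C.A7.t()));
  put_grad_v(grads, "fc8.b", arma::Col<eT>(arma::sum(dZ8, 1)));
  arma::Mat<eT> dA = getM<eT>(w, "fc8.W").t() * dZ8;
  for (int l = (int)a.fc_sizes.size() - 1; l >= 0; --l) {
    std::string nm = "fc" + std::to_string(l + 1 + a.conv_filters.size());
    FcCache<eT>& fc = C.fc[l];
    arma::Mat<eT> dT = fc.has_mask ? arma::Mat<eT>(dA % fc.mask) : dA;
    arma::Mat<eT> dZb = dT % (1 - arma::square(fc.T));
    arma::Col<eT> ggamma, gbeta;
    arma::Mat<eT> dz = bn_backward(dZb, fc.bn, ggamma, gbeta);
    put_grad(grads, nm + ".W", arma::Mat<eT>(dz * fc.Ain.t()));
    put_grad_v(grads, nm + ".b", arma::Col<eT>(arma::sum(dz, 1)));
    put_grad_v(grads, nm + ".gamma", ggamma);
    put_grad_v(grads, nm + ".beta", gbeta);
    dA = getM<eT>(w, nm + ".W").t() * dz;
  }
  // unflatten into pooled conv output
  const int Sl = a.conv_sides.back();
  const int Cch = a.conv_filters.back();
  arma::Mat<eT> dP(Cch, (size_t)Sl * Sl * B);
  for (int b = 0; b < B; ++b) {
    std::memcpy(dP.colptr((size_t)b * Sl * Sl), dA.colptr(b),
                (size_t)Cch * Sl * Sl * sizeof(eT));
  }
  const int k = a.kernel, pad = (a.kernel - 1) / 2;
  for (int l = (int)a.conv_filters.size() - 1; l >= 0; --l) {
    std::string nm = "conv" + std::to_string(l + 1);
    ConvCache<eT>& cc = C.conv[l];
    // gradient reaches only argmax positions; apply the tanh derivative
    // (on the pooled outputs) while scattering (windows overlap: add)
    arma::Mat<eT> dZb(cc.bn.zhat.n_rows, cc.bn.zhat.n_cols,
                      arma::fill::zeros);
    for (uword oc = 0; oc < dP.n_cols; ++oc) {
      const eT* p = dP.colptr(oc);
      const eT* pp = cc.P.colptr(oc);
      const uword* am = cc.AM.colptr(oc);
      for (uword c = 0; c < dZb.n_rows; ++c)
        dZb(c, am[c]) += p[c] * (1 - pp[c] * pp[c]);
    }
    dP.reset();
    cc.P.reset();
    arma::Col<eT> ggamma, gbeta;
    arma::Mat<eT> dz = bn_backward(dZb, cc.bn, ggamma, gbeta);
    dZb.reset();
    cc.bn.zhat.reset();
    put_grad(grads, nm + ".W", arma::Mat<eT>(dz * cc.Col.t()));
    put_grad_v(grads, nm + ".b", arma::Col<eT>(arma::sum(dz, 1)));
    put_grad_v(grads, nm + ".gamma", ggamma);
    put_grad_v(grads, nm + ".beta", gbeta);
    cc.Col.reset();
    if (l > 0) {
      // backward-data: dA_prev = col2im(W^T dz); not needed at layer 1
      // (its inputs are the images themselves)
      arma::Mat<eT> dCol = getM<eT>(w, nm + ".W").t() * dz;
      dz.reset();
      arma::Mat<eT> dAprev(a.conv_filters[l - 1], (size_t)cc.H * cc.W * B,
                           arma::fill::zeros);
      col2im_add(dCol, dAprev, cc.H, cc.W, B, k, pad);
      dP = std::move(dAprev);
    }
  }
}

template <typename eT>
static arma::Mat<eT> images_to_row(const NumericVector& x, int side, int& B) {
  const size_t n = x.size();
  const size_t per = (size_t)side * side;
  if (n % per != 0) stop("image array size is not a multiple of input_side^2");
  B = (int)(n / per);
  arma::Mat<eT> X(1, n);
  const double* p = x.begin();
  eT* q = X.memptr();
  for (size_t i = 0; i < n; ++i) q[i] = (eT)p[i];
  return X;
}

template <typename eT>
static NumericMatrix embed_impl(const List& weights, const List& arch,
                                const NumericVector& images, bool training,
                                const List& masks) {
  ArchC a = parse_arch(arch);
  int B = 0;
  arma::Mat<eT> X = images_to_row<eT>(images, a.side, B);
  arma::Mat<eT> E = forward_pass<eT>(weights, a, std::move(X), B, training,
                                     masks, nullptr, nullptr);
  return wrap(arma::conv_to<arma::mat>::from(E));
}

// [[Rcpp::export]]
NumericMatrix cpp_embed(List weights, List arch, NumericVector images,
                        bool training, List masks, bool use_double) {
  return use_double
             ? embed_impl<double>(weights, arch, images, training, masks)
             : embed_impl<float>(weights, arch, images, training, masks);
}

template <typename eT>
static List loss_grad_impl(const List& weights, const List& arch,
                           const NumericVector& left,
                           const NumericVector& right,
                           const LogicalVector& same, double margin,
                           const List& masks, bool training, bool want_grad) {
  ArchC a = parse_arch(arch);
  int Bl = 0, Br = 0;
  arma::Mat<eT> XL = images_to_row<eT>(left, a.side, Bl);
  arma::Mat<eT> XR = images_to_row<eT>(right, a.side, Br);
  if (Bl != Br || Bl != same.size())
    stop("left/right images and same flags must align");
  if (want_grad && !training)
    stop("gradients are defined for the training-mode (batch-statistics) pass");
  const int n = Bl, B = 2 * n;
  arma::Mat<eT> X(1, XL.n_cols + XR.n_cols);
  X.cols(0, XL.n_cols - 1) = XL;
  X.cols(XL.n_cols, X.n_cols - 1) = XR;
  XL.reset(); XR.reset();
  Caches<eT> C;
  List stats;
  arma::Mat<eT> E = forward_pass<eT>(weights, a, std::move(X), B, training,
                                     masks, want_grad ? &C : nullptr,
                                     training ? &stats : nullptr);
  const eT m = (eT)margin;
  double loss = 0.0;
  arma::Mat<eT> dE(E.n_rows, E.n_cols, arma::fill::zeros);
  NumericVector dists(n);
  for (int i = 0; i < n; ++i) {
    arma::Col<eT> diff = E.col(i) - E.col(n + i);
    eT d = arma::norm(diff, 2);
    dists[i] = d;
    eT gd = 0;  // dL_i/dd
    if (same[i]) {
      if (d > m) { loss += 0.5 * (double)(d - m) * (d - m); gd = d - m; }
    } else {
      if (d < m) { loss += 0.5 * (double)(m - d) * (m - d); gd = -(m - d); }
    }
    if (want_grad && gd != 0 && d > 0) {
      arma::Col<eT> g = (gd / d / (eT)n) * diff;
      dE.col(i) += g;
      dE.col(n + i) -= g;
    }
  }
  loss /= n;
  List out = List::create(_["loss"] = loss, _["distances"] = dists,
                          _["stats"] = stats);
  if (want_grad) {
    List grads;
    backward_pass<eT>(weights, a, C, dE, B, grads);
    out["grads"] = grads;
  }
  return out;
}

// Contrastive loss over embedded pairs; optionally the full analytic
// gradient and the batch-norm batch statistics (for running-average
// updates).
// [[Rcpp::export]]
List cpp_loss_grad(List weights, List arch, NumericVector left,
                   NumericVector right, LogicalVector same, double margin,
                   List masks, bool training, bool want_grad,
                   bool use_double) {
  return use_double
             ? loss_grad_impl<double>(weights, arch, left, right, same,
                                      margin, masks, training, want_grad)
             : loss_grad_impl<float>(weights, arch, left, right, same, margin,
                                     masks, training, want_grad);
}
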