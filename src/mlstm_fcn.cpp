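// MLSTM-FCN time-series classifier: two stacked LSTM layers (hidden state
// read at each sequence's true length) in parallel with three temporal
// convolution blocks (batch norm + ReLU, squeeze-excite after blocks 1 and 2),
// concatenated into a softmax head. Forward, manual backprop and Adam are
// implemented here; all randomness (shuffling, dropout) comes from a local
// mt19937 stream so training is bit-reproducible for a given seed.
//
// The network is templated on the element type: training/prediction run in
// single precision (the arithmetic bottleneck is the recurrent GEMM chain),
// while the gradient-check entry point instantiates the identical code in
// double precision so finite differences are meaningful.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

namespace {

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.1;

struct RNG {
  std::mt19937 eng;
  explicit RNG(uint32_t seed) : eng(seed) {}
  double unif() { return eng() * (1.0 / 4294967296.0); }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

template <typename eT>
struct Net {
  using TMat = arma::Mat<eT>;
  using TRow = arma::Row<eT>;
  using TVec = arma::Col<eT>;
  using TCube = arma::Cube<eT>;

  struct Params {
    TMat W1, W2, Wc1, Wc2, Wc3, Ws1a, Ws1b, Ws2a, Ws2b, Wh;
    TRow b1, b2, bc1, bc2, bc3, bs1a, bs1b, bs2a, bs2b, bh;
    TRow g1, be1, g2, be2, g3, be3;
    TRow rm1, rv1, rm2, rv2, rm3, rv3;
  };

  struct Dims { int C, H, K, F1, F2, F3, k1, k2, k3; };

  struct LstmCache {
    TCube A, i, f, g, o, c_new, c_prev;
    TMat h_final;
  };

  struct BnCache {
    TRow mean_, invstd;
    TMat xhat;
  };

  struct SeCache {
    TMat s, u, v;
    TCube a_in;
  };

  struct FwdCache {
    LstmCache l1, l2;
    TCube drop1;
    TMat drop_h_mask, drop_gap;
    TMat M1, M2, M3;
    BnCache bn1, bn2, bn3;
    TMat relu1, relu2, relu3;
    SeCache se1, se2;
    TCube a1s, a2s;
    TMat gap, concat, probs;
    TCube Xc;
  };

  static TMat sigm(const TMat& x) {
    return eT(1) / (eT(1) + arma::exp(-x));
  }

  static TMat relu(const TMat& x) {
    TMat r = x;
    r.elem(arma::find(r < eT(0))).zeros();
    return r;
  }

  // ---- LSTM ----------------------------------------------------------------

  static TCube lstm_forward(const TCube& X_seq, const TMat& mask,
                            const TMat& W, const TRow& b, int H,
                            LstmCache& cc) {
    const int B = X_seq.n_rows, in = X_seq.n_cols, T = X_seq.n_slices;
    TCube Hseq(B, H, T, arma::fill::zeros);
    cc.A.set_size(B, in + H, T);
    cc.i.set_size(B, H, T); cc.f.set_size(B, H, T); cc.g.set_size(B, H, T);
    cc.o.set_size(B, H, T);
    cc.c_new.set_size(B, H, T); cc.c_prev.set_size(B, H, T);
    TMat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      TMat A(B, in + H);
      A.cols(0, in - 1) = X_seq.slice(t);
      A.cols(in, in + H - 1) = h;
      TMat Z = A * W;
      Z.each_row() += b;
      TMat ig = sigm(Z.cols(0, H - 1));
      TMat fg = sigm(Z.cols(H, 2 * H - 1));
      TMat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
      TMat og = sigm(Z.cols(3 * H, 4 * H - 1));
      TMat cn = fg % c + ig % gg;
      TMat hn = og % arma::tanh(cn);
      TMat mm = arma::repmat(mask.col(t), 1, H);
      cc.A.slice(t) = A;
      cc.i.slice(t) = ig; cc.f.slice(t) = fg; cc.g.slice(t) = gg;
      cc.o.slice(t) = og; cc.c_prev.slice(t) = c; cc.c_new.slice(t) = cn;
      h = mm % hn + (eT(1) - mm) % h;
      c = mm % cn + (eT(1) - mm) % c;
      Hseq.slice(t) = h;
    }
    cc.h_final = h;
    return Hseq;
  }

  static TCube lstm_backward(const TCube& dHseq, const TMat& mask,
                             const TMat& W, int H, const LstmCache& cc,
                             TMat& dW, TRow& db) {
    const int B = dHseq.n_rows, T = dHseq.n_slices;
    const int in = cc.A.n_cols - H;
    TCube dX(B, in, T, arma::fill::zeros);
    TMat dh_carry(B, H, arma::fill::zeros), dc_carry(B, H, arma::fill::zeros);
    dW.zeros(W.n_rows, W.n_cols);
    db.zeros(4 * H);
    for (int t = T - 1; t >= 0; --t) {
      TMat mm = arma::repmat(mask.col(t), 1, H);
      TMat dh_tot = dHseq.slice(t) + dh_carry;
      TMat dh_new = mm % dh_tot;
      TMat dh_prev = (eT(1) - mm) % dh_tot;
      TMat dc_new = mm % dc_carry;
      TMat dc_prev_mask = (eT(1) - mm) % dc_carry;
      const TMat& ig = cc.i.slice(t); const TMat& fg = cc.f.slice(t);
      const TMat& gg = cc.g.slice(t); const TMat& og = cc.o.slice(t);
      const TMat& cp = cc.c_prev.slice(t); const TMat& cn = cc.c_new.slice(t);
      TMat tc = arma::tanh(cn);
      dc_new += dh_new % og % (eT(1) - tc % tc);
      TMat dog = dh_new % tc;
      TMat dig = dc_new % gg;
      TMat dgg = dc_new % ig;
      TMat dfg = dc_new % cp;
      TMat dc_prev = dc_new % fg + dc_prev_mask;
      TMat dZ(B, 4 * H);
      dZ.cols(0, H - 1) = dig % ig % (eT(1) - ig);
      dZ.cols(H, 2 * H - 1) = dfg % fg % (eT(1) - fg);
      dZ.cols(2 * H, 3 * H - 1) = dgg % (eT(1) - gg % gg);
      dZ.cols(3 * H, 4 * H - 1) = dog % og % (eT(1) - og);
      dW += cc.A.slice(t).t() * dZ;
      db += arma::sum(dZ, 0);
      TMat dA = dZ * W.t();
      dX.slice(t) = dA.cols(0, in - 1);
      dh_carry = dA.cols(in, in + H - 1) + dh_prev;
      dc_carry = dc_prev;
    }
    return dX;
  }

  // ---- convolution ---------------------------------------------------------

  static TMat im2col(const TCube& X, int k) {
    const int B = X.n_rows, T = X.n_cols, IC = X.n_slices;
    const int pad = (k - 1) / 2;
    TMat M(B * T, k * IC, arma::fill::zeros);
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int t_lo = std::max(0, -off), t_hi = std::min(T, T - off);
      for (int ic = 0; ic < IC; ++ic) {
        for (int t = t_lo; t < t_hi; ++t) {
          M.col(j * IC + ic).subvec(t * B, t * B + B - 1) =
              X.slice(ic).col(t + off);
        }
      }
    }
    return M;
  }

  static void col2im_add(TCube& dX, const TMat& dM, int k) {
    const int B = dX.n_rows, T = dX.n_cols, IC = dX.n_slices;
    const int pad = (k - 1) / 2;
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int t_lo = std::max(0, -off), t_hi = std::min(T, T - off);
      for (int ic = 0; ic < IC; ++ic) {
        for (int t = t_lo; t < t_hi; ++t) {
          dX.slice(ic).col(t + off) +=
              dM.col(j * IC + ic).subvec(t * B, t * B + B - 1);
        }
      }
    }
  }

  static TCube to_cube(const TMat& M, int B, int T) {
    const int OC = M.n_cols;
    TCube out(B, T, OC);
    for (int oc = 0; oc < OC; ++oc) {
      out.slice(oc) = arma::reshape(M.col(oc), B, T);
    }
    return out;
  }

  static TMat to_mat(const TCube& X) {
    const int B = X.n_rows, T = X.n_cols, OC = X.n_slices;
    TMat M(B * T, OC);
    for (int oc = 0; oc < OC; ++oc) M.col(oc) = arma::vectorise(X.slice(oc));
    return M;
  }

  static TMat bn_forward(const TMat& Xm, const TRow& gamma, const TRow& beta,
                         BnCache& cc, TRow& rmean, TRow& rvar,
                         bool update_running) {
    cc.mean_ = arma::mean(Xm, 0);
    TRow var_ = arma::mean(arma::square(Xm.each_row() - cc.mean_), 0);
    cc.invstd = eT(1) / arma::sqrt(var_ + eT(BN_EPS));
    cc.xhat = (Xm.each_row() - cc.mean_).each_row() % cc.invstd;
    if (update_running) {
      rmean = eT(1 - BN_MOMENTUM) * rmean + eT(BN_MOMENTUM) * cc.mean_;
      rvar = eT(1 - BN_MOMENTUM) * rvar + eT(BN_MOMENTUM) * var_;
    }
    TMat out = cc.xhat.each_row() % gamma;
    out.each_row() += beta;
    return out;
  }

  static TMat bn_backward(const TMat& dY, const TRow& gamma,
                          const BnCache& cc, TRow& dgamma, TRow& dbeta) {
    const eT N = eT(dY.n_rows);
    dbeta = arma::sum(dY, 0);
    dgamma = arma::sum(dY % cc.xhat, 0);
    TMat dxhat = dY.each_row() % gamma;
    TRow s1 = arma::sum(dxhat, 0);
    TRow s2 = arma::sum(dxhat % cc.xhat, 0);
    TMat dX = dxhat;
    dX.each_row() -= s1 / N;
    dX -= cc.xhat.each_row() % (s2 / N);
    dX.each_row() %= cc.invstd;
    return dX;
  }

  static TCube se_forward(const TCube& A, const TMat& W1, const TRow& b1,
                          const TMat& W2, const TRow& b2, SeCache& cc) {
    const int B = A.n_rows, T = A.n_cols, C = A.n_slices;
    cc.a_in = A;
    cc.s.set_size(B, C);
    for (int c = 0; c < C; ++c) cc.s.col(c) = arma::mean(A.slice(c), 1);
    TMat u_pre = cc.s * W1; u_pre.each_row() += b1;
    cc.u = relu(u_pre);
    TMat v_pre = cc.u * W2; v_pre.each_row() += b2;
    cc.v = sigm(v_pre);
    TCube out(B, T, C);
    for (int c = 0; c < C; ++c) {
      out.slice(c) = A.slice(c).each_col() % cc.v.col(c);
    }
    return out;
  }

  static TCube se_backward(const TCube& dOut, const TMat& W1, const TMat& W2,
                           const SeCache& cc, TMat& dW1, TRow& db1, TMat& dW2,
                           TRow& db2) {
    const int B = dOut.n_rows, T = dOut.n_cols, C = dOut.n_slices;
    TCube dA(B, T, C);
    TMat dv(B, C);
    for (int c = 0; c < C; ++c) {
      dA.slice(c) = dOut.slice(c).each_col() % cc.v.col(c);
      dv.col(c) = arma::sum(dOut.slice(c) % cc.a_in.slice(c), 1);
    }
    TMat dv_pre = dv % cc.v % (eT(1) - cc.v);
    dW2 = cc.u.t() * dv_pre;
    db2 = arma::sum(dv_pre, 0);
    TMat du = dv_pre * W2.t();
    du.elem(arma::find(cc.u == eT(0))).zeros();
    dW1 = cc.s.t() * du;
    db1 = arma::sum(du, 0);
    TMat ds = du * W1.t();
    for (int c = 0; c < C; ++c) {
      dA.slice(c).each_col() += ds.col(c) / eT(T);
    }
    return dA;
  }

  // ---- pack / unpack -------------------------------------------------------

  static Params unpack(const Rcpp::List& p) {
    Params P;
    auto M = [&](const char* n) {
      return arma::conv_to<TMat>::from(Rcpp::as<arma::mat>(p[n]));
    };
    auto R = [&](const char* n) {
      return arma::conv_to<TRow>::from(Rcpp::as<arma::rowvec>(p[n]));
    };
    P.W1 = M("W1"); P.b1 = R("b1"); P.W2 = M("W2"); P.b2 = R("b2");
    P.Wc1 = M("Wc1"); P.bc1 = R("bc1"); P.Wc2 = M("Wc2"); P.bc2 = R("bc2");
    P.Wc3 = M("Wc3"); P.bc3 = R("bc3");
    P.g1 = R("g1"); P.be1 = R("be1"); P.g2 = R("g2"); P.be2 = R("be2");
    P.g3 = R("g3"); P.be3 = R("be3");
    P.Ws1a = M("Ws1a"); P.bs1a = R("bs1a"); P.Ws1b = M("Ws1b");
    P.bs1b = R("bs1b");
    P.Ws2a = M("Ws2a"); P.bs2a = R("bs2a"); P.Ws2b = M("Ws2b");
    P.bs2b = R("bs2b");
    P.Wh = M("Wh"); P.bh = R("bh");
    P.rm1 = R("rm1"); P.rv1 = R("rv1"); P.rm2 = R("rm2"); P.rv2 = R("rv2");
    P.rm3 = R("rm3"); P.rv3 = R("rv3");
    return P;
  }

  static Rcpp::List pack(const Params& P) {
    auto M = [](const TMat& x) {
      return Rcpp::wrap(arma::conv_to<arma::mat>::from(x));
    };
    auto R = [](const TRow& x) {
      return Rcpp::wrap(arma::conv_to<arma::rowvec>::from(x));
    };
    return Rcpp::List::create(
        Rcpp::Named("W1") = M(P.W1), Rcpp::Named("b1") = R(P.b1),
        Rcpp::Named("W2") = M(P.W2), Rcpp::Named("b2") = R(P.b2),
        Rcpp::Named("Wc1") = M(P.Wc1), Rcpp::Named("bc1") = R(P.bc1),
        Rcpp::Named("g1") = R(P.g1), Rcpp::Named("be1") = R(P.be1),
        Rcpp::Named("Ws1a") = M(P.Ws1a), Rcpp::Named("bs1a") = R(P.bs1a),
        Rcpp::Named("Ws1b") = M(P.Ws1b), Rcpp::Named("bs1b") = R(P.bs1b),
        Rcpp::Named("Wc2") = M(P.Wc2), Rcpp::Named("bc2") = R(P.bc2),
        Rcpp::Named("g2") = R(P.g2), Rcpp::Named("be2") = R(P.be2),
        Rcpp::Named("Ws2a") = M(P.Ws2a), Rcpp::Named("bs2a") = R(P.bs2a),
        Rcpp::Named("Ws2b") = M(P.Ws2b), Rcpp::Named("bs2b") = R(P.bs2b),
        Rcpp::Named("Wc3") = M(P.Wc3), Rcpp::Named("bc3") = R(P.bc3),
        Rcpp::Named("g3") = R(P.g3), Rcpp::Named("be3") = R(P.be3),
        Rcpp::Named("Wh") = M(P.Wh), Rcpp::Named("bh") = R(P.bh),
        Rcpp::Named("rm1") = R(P.rm1), Rcpp::Named("rv1") = R(P.rv1),
        Rcpp::Named("rm2") = R(P.rm2), Rcpp::Named("rv2") = R(P.rv2),
        Rcpp::Named("rm3") = R(P.rm3), Rcpp::Named("rv3") = R(P.rv3));
  }

  static Dims infer_dims(const Params& P, int C) {
    Dims d;
    d.C = C;
    d.H = P.W1.n_cols / 4;
    d.F1 = P.Wc1.n_cols; d.F2 = P.Wc2.n_cols; d.F3 = P.Wc3.n_cols;
    d.k1 = P.Wc1.n_rows / C; d.k2 = P.Wc2.n_rows / d.F1;
    d.k3 = P.Wc3.n_rows / d.F2;
    d.K = P.Wh.n_cols;
    return d;
  }

  // ---- forward / backward --------------------------------------------------

  static TMat make_mask(const arma::uvec& len, int B, int T) {
    TMat mask(B, T, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (arma::uword t = 0; t < len(b) && t < (arma::uword)T; ++t) {
        mask(b, t) = eT(1);
      }
    }
    return mask;
  }

  static double forward(const TCube& X, const arma::uvec& len,
                        const arma::ivec& y, Params& P, const Dims& d,
                        bool train, double p_rnn, double p_fcn, RNG* rng,
                        FwdCache& cc, TMat& dlogits_out, bool want_grad) {
    const int B = X.n_rows, T = X.n_slices;
    TMat mask = make_mask(len, B, T);
    // recurrent branch
    TCube H1 = lstm_forward(X, mask, P.W1, P.b1, d.H, cc.l1);
    TCube H1d = H1;
    if (train && p_rnn > 0) {
      cc.drop1.set_size(arma::size(H1));
      for (arma::uword i = 0; i < H1.n_elem; ++i) {
        cc.drop1(i) = rng->unif() < p_rnn ? eT(0) : eT(1.0 / (1.0 - p_rnn));
      }
      H1d = H1 % cc.drop1;
    }
    lstm_forward(H1d, mask, P.W2, P.b2, d.H, cc.l2);
    TMat h_last = cc.l2.h_final;
    if (train && p_rnn > 0) {
      cc.drop_h_mask.set_size(arma::size(h_last));
      for (arma::uword i = 0; i < h_last.n_elem; ++i) {
        cc.drop_h_mask(i) =
            rng->unif() < p_rnn ? eT(0) : eT(1.0 / (1.0 - p_rnn));
      }
      h_last %= cc.drop_h_mask;
    }
    // convolutional branch (B x T x C layout)
    cc.Xc.set_size(B, T, d.C);
    for (int c = 0; c < d.C; ++c) {
      for (int t = 0; t < T; ++t) cc.Xc.slice(c).col(t) = X.slice(t).col(c);
    }
    auto conv_block = [&](const TCube& Ain, const TMat& Wc, const TRow& bc,
                          const TRow& g, const TRow& be, TRow& rm, TRow& rv,
                          int k, TMat& Mstore, BnCache& bnc, TMat& relustore) {
      Mstore = im2col(Ain, k);
      TMat Z = Mstore * Wc;
      Z.each_row() += bc;
      TMat Y;
      if (train) {
        Y = bn_forward(Z, g, be, bnc, rm, rv, true);
      } else {
        TRow invstd = eT(1) / arma::sqrt(rv + eT(BN_EPS));
        Y = (Z.each_row() - rm).each_row() % (invstd % g);
        Y.each_row() += be;
      }
      relustore = relu(Y);
      return to_cube(relustore, B, T);
    };
    TCube a1 = conv_block(cc.Xc, P.Wc1, P.bc1, P.g1, P.be1, P.rm1, P.rv1,
                          d.k1, cc.M1, cc.bn1, cc.relu1);
    cc.a1s = se_forward(a1, P.Ws1a, P.bs1a, P.Ws1b, P.bs1b, cc.se1);
    TCube a2 = conv_block(cc.a1s, P.Wc2, P.bc2, P.g2, P.be2, P.rm2, P.rv2,
                          d.k2, cc.M2, cc.bn2, cc.relu2);
    cc.a2s = se_forward(a2, P.Ws2a, P.bs2a, P.Ws2b, P.bs2b, cc.se2);
    TCube a3 = conv_block(cc.a2s, P.Wc3, P.bc3, P.g3, P.be3, P.rm3, P.rv3,
                          d.k3, cc.M3, cc.bn3, cc.relu3);
    // masked global average pooling
    cc.gap.set_size(B, d.F3);
    for (int c = 0; c < d.F3; ++c) {
      for (int b = 0; b < B; ++b) {
        const int L = std::min<int>(len(b), T);
        cc.gap(b, c) = arma::mean(a3.slice(c).row(b).subvec(0, L - 1));
      }
    }
    TMat gap_d = cc.gap;
    if (train && p_fcn > 0) {
      cc.drop_gap.set_size(arma::size(gap_d));
      for (arma::uword i = 0; i < gap_d.n_elem; ++i) {
        cc.drop_gap(i) = rng->unif() < p_fcn ? eT(0) : eT(1.0 / (1.0 - p_fcn));
      }
      gap_d %= cc.drop_gap;
    }
    // head
    cc.concat.set_size(B, d.H + d.F3);
    cc.concat.cols(0, d.H - 1) = h_last;
    cc.concat.cols(d.H, d.H + d.F3 - 1) = gap_d;
    TMat logits = cc.concat * P.Wh;
    logits.each_row() += P.bh;
    TMat shifted = logits.each_col() - arma::max(logits, 1);
    TMat expz = arma::exp(shifted);
    cc.probs = expz.each_col() / arma::sum(expz, 1);
    double loss = 0.0;
    for (int b = 0; b < B; ++b) {
      loss -= std::log(std::max<double>(cc.probs(b, y(b)), 1e-12));
    }
    loss /= B;
    if (want_grad) {
      dlogits_out = cc.probs;
      for (int b = 0; b < B; ++b) dlogits_out(b, y(b)) -= eT(1);
      dlogits_out /= eT(B);
    }
    return loss;
  }

  static void zero_like(Params& Q) {
    Q.W1.zeros(); Q.b1.zeros(); Q.W2.zeros(); Q.b2.zeros();
    Q.Wc1.zeros(); Q.bc1.zeros(); Q.Wc2.zeros(); Q.bc2.zeros();
    Q.Wc3.zeros(); Q.bc3.zeros(); Q.g1.zeros(); Q.be1.zeros();
    Q.g2.zeros(); Q.be2.zeros(); Q.g3.zeros(); Q.be3.zeros();
    Q.Ws1a.zeros(); Q.bs1a.zeros(); Q.Ws1b.zeros(); Q.bs1b.zeros();
    Q.Ws2a.zeros(); Q.bs2a.zeros(); Q.Ws2b.zeros(); Q.bs2b.zeros();
    Q.Wh.zeros(); Q.bh.zeros();
  }

  static void backward(const TCube& X, const arma::uvec& len, Params& P,
                       const Dims& d, bool train_dropout, double p_rnn,
                       double p_fcn, const FwdCache& cc, const TMat& dlogits,
                       Params& G) {
    const int B = X.n_rows, T = X.n_slices;
    TMat mask = make_mask(len, B, T);
    G.Wh = cc.concat.t() * dlogits;
    G.bh = arma::sum(dlogits, 0);
    TMat dconcat = dlogits * P.Wh.t();
    TMat dh_last = dconcat.cols(0, d.H - 1);
    TMat dgap = dconcat.cols(d.H, d.H + d.F3 - 1);
    if (train_dropout && p_rnn > 0) dh_last %= cc.drop_h_mask;
    if (train_dropout && p_fcn > 0) dgap %= cc.drop_gap;
    // conv branch
    TCube da3(B, T, d.F3, arma::fill::zeros);
    for (int c = 0; c < d.F3; ++c) {
      for (int b = 0; b < B; ++b) {
        const int L = std::min<int>(len(b), T);
        for (int t = 0; t < L; ++t) {
          da3(b, t, c) += dgap(b, c) / eT(L);
        }
      }
    }
    auto conv_block_bwd = [&](const TCube& dOut, const TMat& relustore,
                              const BnCache& bnc, const TMat& Wc,
                              const TMat& M, const TRow& g, int k, int in_ch,
                              TMat& dWc, TRow& dbc, TRow& dg, TRow& dbe) {
      TMat dY = to_mat(dOut);
      dY.elem(arma::find(relustore == eT(0))).zeros();
      TMat dZ = bn_backward(dY, g, bnc, dg, dbe);
      dWc = M.t() * dZ;
      dbc = arma::sum(dZ, 0);
      TMat dM = dZ * Wc.t();
      TCube dIn(dOut.n_rows, dOut.n_cols, in_ch, arma::fill::zeros);
      col2im_add(dIn, dM, k);
      return dIn;
    };
    TCube da2s = conv_block_bwd(da3, cc.relu3, cc.bn3, P.Wc3, cc.M3, P.g3,
                                d.k3, d.F2, G.Wc3, G.bc3, G.g3, G.be3);
    TCube da2 = se_backward(da2s, P.Ws2a, P.Ws2b, cc.se2, G.Ws2a, G.bs2a,
                            G.Ws2b, G.bs2b);
    TCube da1s = conv_block_bwd(da2, cc.relu2, cc.bn2, P.Wc2, cc.M2, P.g2,
                                d.k2, d.F1, G.Wc2, G.bc2, G.g2, G.be2);
    TCube da1 = se_backward(da1s, P.Ws1a, P.Ws1b, cc.se1, G.Ws1a, G.bs1a,
                            G.Ws1b, G.bs1b);
    conv_block_bwd(da1, cc.relu1, cc.bn1, P.Wc1, cc.M1, P.g1, d.k1, d.C,
                   G.Wc1, G.bc1, G.g1, G.be1);
    // recurrent branch
    TCube dH2(B, d.H, T, arma::fill::zeros);
    dH2.slice(T - 1) = dh_last;
    TCube dH1d = lstm_backward(dH2, mask, P.W2, d.H, cc.l2, G.W2, G.b2);
    if (train_dropout && p_rnn > 0) dH1d %= cc.drop1;
    lstm_backward(dH1d, mask, P.W1, d.H, cc.l1, G.W1, G.b1);
  }

  // ---- Adam ----------------------------------------------------------------

  template <typename A>
  static void adam1(A& w, const A& g, A& m, A& v, double lr, int t) {
    const eT b1 = eT(0.9), b2 = eT(0.999), eps = eT(1e-8);
    m = b1 * m + (eT(1) - b1) * g;
    v = b2 * v + (eT(1) - b2) * arma::square(g);
    A mh = m / eT(1 - std::pow(0.9, t));
    A vh = v / eT(1 - std::pow(0.999, t));
    w -= eT(lr) * mh / (arma::sqrt(vh) + eps);
  }

  static void adam_all(Params& P, const Params& G, Params& M, Params& V,
                       double lr, int t) {
    adam1(P.W1, G.W1, M.W1, V.W1, lr, t); adam1(P.b1, G.b1, M.b1, V.b1, lr, t);
    adam1(P.W2, G.W2, M.W2, V.W2, lr, t); adam1(P.b2, G.b2, M.b2, V.b2, lr, t);
    adam1(P.Wc1, G.Wc1, M.Wc1, V.Wc1, lr, t);
    adam1(P.bc1, G.bc1, M.bc1, V.bc1, lr, t);
    adam1(P.Wc2, G.Wc2, M.Wc2, V.Wc2, lr, t);
    adam1(P.bc2, G.bc2, M.bc2, V.bc2, lr, t);
    adam1(P.Wc3, G.Wc3, M.Wc3, V.Wc3, lr, t);
    adam1(P.bc3, G.bc3, M.bc3, V.bc3, lr, t);
    adam1(P.g1, G.g1, M.g1, V.g1, lr, t);
    adam1(P.be1, G.be1, M.be1, V.be1, lr, t);
    adam1(P.g2, G.g2, M.g2, V.g2, lr, t);
    adam1(P.be2, G.be2, M.be2, V.be2, lr, t);
    adam1(P.g3, G.g3, M.g3, V.g3, lr, t);
    adam1(P.be3, G.be3, M.be3, V.be3, lr, t);
    adam1(P.Ws1a, G.Ws1a, M.Ws1a, V.Ws1a, lr, t);
    adam1(P.bs1a, G.bs1a, M.bs1a, V.bs1a, lr, t);
    adam1(P.Ws1b, G.Ws1b, M.Ws1b, V.Ws1b, lr, t);
    adam1(P.bs1b, G.bs1b, M.bs1b, V.bs1b, lr, t);
    adam1(P.Ws2a, G.Ws2a, M.Ws2a, V.Ws2a, lr, t);
    adam1(P.bs2a, G.bs2a, M.bs2a, V.bs2a, lr, t);
    adam1(P.Ws2b, G.Ws2b, M.Ws2b, V.Ws2b, lr, t);
    adam1(P.bs2b, G.bs2b, M.bs2b, V.bs2b, lr, t);
    adam1(P.Wh, G.Wh, M.Wh, V.Wh, lr, t); adam1(P.bh, G.bh, M.bh, V.bh, lr, t);
  }

  static Rcpp::List train(const arma::cube& Xd, const arma::uvec& len,
                          const arma::ivec& y, const Rcpp::List& params,
                          int epochs, int batch_size, double lr, double p_rnn,
                          double p_fcn, int seed) {
    TCube X = arma::conv_to<TCube>::from(Xd);
    Params P = unpack(params);
    const int n = X.n_rows, C = X.n_cols, T = X.n_slices;
    Dims d = infer_dims(P, C);
    RNG rng(static_cast<uint32_t>(seed));
    Params M = P, V = P, G = P;
    zero_like(M); zero_like(V);
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::vector<double> losses;
    int step = 0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int i = n - 1; i > 0; --i) {
        std::swap(order[i], order[rng.below(i + 1)]);
      }
      double ep_loss = 0.0;
      int n_batches = 0;
      for (int s = 0; s < n; s += batch_size) {
        const int e = std::min(n, s + batch_size);
        const int B = e - s;
        TCube Xb(B, C, T);
        arma::uvec lb(B);
        arma::ivec yb(B);
        for (int b = 0; b < B; ++b) {
          Xb.row(b) = X.row(order[s + b]);
          lb(b) = len(order[s + b]);
          yb(b) = y(order[s + b]);
        }
        FwdCache cc;
        TMat dlogits;
        double loss = forward(Xb, lb, yb, P, d, true, p_rnn, p_fcn, &rng, cc,
                              dlogits, true);
        zero_like(G);
        backward(Xb, lb, P, d, true, p_rnn, p_fcn, cc, dlogits, G);
        ++step;
        adam_all(P, G, M, V, lr, step);
        ep_loss += loss;
        ++n_batches;
      }
      losses.push_back(ep_loss / n_batches);
    }
    return Rcpp::List::create(Rcpp::Named("params") = pack(P),
                              Rcpp::Named("losses") = losses);
  }

  static arma::mat predict(const arma::cube& Xd, const arma::uvec& len,
                           const Rcpp::List& params) {
    TCube X = arma::conv_to<TCube>::from(Xd);
    Params P = unpack(params);
    Dims d = infer_dims(P, X.n_cols);
    FwdCache cc;
    TMat dlogits;
    arma::ivec y(X.n_rows, arma::fill::zeros);
    forward(X, len, y, P, d, false, 0.0, 0.0, nullptr, cc, dlogits, false);
    return arma::conv_to<arma::mat>::from(cc.probs);
  }

  static Rcpp::List loss_grad(const arma::cube& Xd, const arma::uvec& len,
                              const arma::ivec& y, const Rcpp::List& params) {
    TCube X = arma::conv_to<TCube>::from(Xd);
    Params P = unpack(params);
    Dims d = infer_dims(P, X.n_cols);
    FwdCache cc;
    TMat dlogits;
    double loss = forward(X, len, y, P, d, true, 0.0, 0.0, nullptr, cc,
                          dlogits, true);
    Params G = P;
    zero_like(G);
    backward(X, len, P, d, false, 0.0, 0.0, cc, dlogits, G);
    return Rcpp::List::create(
        Rcpp::Named("loss") = loss, Rcpp::Named("grads") = pack(G),
        Rcpp::Named("probs") = arma::conv_to<arma::mat>::from(cc.probs));
  }
};

}  // namespace

// Training and prediction run in single precision; the gradient-check entry
// point runs the identical code in double precision.

// [[Rcpp::export]]
Rcpp::List cpp_mlstm_train(const arma::cube& X, const arma::uvec& len,
                           const arma::ivec& y, const Rcpp::List& params,
                           int epochs, int batch_size, double lr,
                           double p_rnn, double p_fcn, int seed) {
  return Net<float>::train(X, len, y, params, epochs, batch_size, lr, p_rnn,
                           p_fcn, seed);
}

// [[Rcpp::export]]
arma::mat cpp_mlstm_predict(const arma::cube& X, const arma::uvec& len,
                            const Rcpp::List& params) {
  return Net<float>::predict(X, len, params);
}

// [[Rcpp::export]]
Rcpp::List cpp_mlstm_loss_grad(const arma::cube& X, const arma::uvec& len,
                               const arma::ivec& y, const Rcpp::List& params) {
  return Net<double>::loss_grad(X, len, y, params);
}
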