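// Bilayer (bi)directional LSTM sequence regressor: forward pass and
// backpropagation through time, called from the R training loop. Gate order
// in all stacked 4H blocks is input, forget, cell, output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static cube revcube(const cube& x) {
  cube out(size(x));
  const uword T = x.n_slices;
  for (uword t = 0; t < T; ++t) out.slice(t) = x.slice(T - 1 - t);
  return out;
}

struct DirCache {
  cube G;  // activated gates (4H x B x T)
  cube C;  // cell states
  cube H;  // hidden outputs
};

// single-direction LSTM over X (I x B x T) in processing order
static DirCache dir_forward(const cube& X, const mat& Wx, const mat& Wh,
                            const vec& b) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = Wh.n_cols;
  mat Xf(const_cast<double*>(X.memptr()), I, B * T, false, true);
  mat Zbase = Wx * Xf;  // 4H x BT
  DirCache cc;
  cc.G.set_size(4 * H, B, T);
  cc.C.set_size(H, B, T);
  cc.H.set_size(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat z = Zbase.cols(t * B, (t + 1) * B - 1) + Wh * h;
    z.each_col() += b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.G.slice(t) = join_cols(gi, gf, gg, go);
    cc.C.slice(t) = c;
    cc.H.slice(t) = h;
  }
  return cc;
}

struct DirGrads {
  mat dWx, dWh;
  vec db;
  cube dX;
};

// backprop one direction; X and dH in processing order
static DirGrads dir_backward(const cube& X, const mat& Wx, const mat& Wh,
                             const DirCache& cc, const cube& dH) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = Wh.n_cols;
  cube dZ(4 * H, B, T);
  mat dh_rec(H, B, fill::zeros), dc(H, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat gi = cc.G.slice(t).rows(0, H - 1);
    const mat gf = cc.G.slice(t).rows(H, 2 * H - 1);
    const mat gg = cc.G.slice(t).rows(2 * H, 3 * H - 1);
    const mat go = cc.G.slice(t).rows(3 * H, 4 * H - 1);
    mat dh = dH.slice(t) + dh_rec;
    mat tc = tanh(cc.C.slice(t));
    mat do_ = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat cprev = (t > 0) ? cc.C.slice(t - 1) : mat(H, B, fill::zeros);
    mat di = dc % gg;
    mat df = dc % cprev;
    mat dg = dc % gi;
    dZ.slice(t) = join_cols(di % gi % (1.0 - gi), df % gf % (1.0 - gf),
                            dg % (1.0 - gg % gg), do_ % go % (1.0 - go));
    dh_rec = Wh.t() * dZ.slice(t);
    dc = dc % gf;
  }
  mat dZf(dZ.memptr(), 4 * H, B * T, false, true);
  mat Xf(const_cast<double*>(X.memptr()), I, B * T, false, true);
  DirGrads g;
  g.dWx = dZf * Xf.t();
  // recurrent grad: pair dZ_t with h_{t-1} (zero at t = 0)
  cube Hprev(H, B, T, fill::zeros);
  for (uword t = 1; t < T; ++t) Hprev.slice(t) = cc.H.slice(t - 1);
  mat Hpf(Hprev.memptr(), H, B * T, false, true);
  g.dWh = dZf * Hpf.t();
  g.db = sum(dZf, 1);
  mat dXf = Wx.t() * dZf;
  g.dX = cube(dXf.memptr(), I, B, T);
  return g;
}

struct LayerCache {
  DirCache fwd, bwd;   // bwd in processing (reversed-time) order
  cube in_fwd, in_bwd; // layer inputs in each processing order
  cube out;            // real-time-ordered output (DH x B x T)
};

static LayerCache layer_forward(const cube& X, const mat& Wxf, const mat& Whf,
                                const vec& bf, const mat& Wxb, const mat& Whb,
                                const vec& bb, bool bidir) {
  LayerCache lc;
  lc.in_fwd = X;
  lc.fwd = dir_forward(X, Wxf, Whf, bf);
  const uword H = Whf.n_cols, B = X.n_cols, T = X.n_slices;
  if (bidir) {
    lc.in_bwd = revcube(X);
    lc.bwd = dir_forward(lc.in_bwd, Wxb, Whb, bb);
    cube Hb_rt = revcube(lc.bwd.H);
    lc.out.set_size(2 * H, B, T);
    for (uword t = 0; t < T; ++t) {
      lc.out.slice(t) = join_cols(lc.fwd.H.slice(t), Hb_rt.slice(t));
    }
  } else {
    lc.out = lc.fwd.H;
  }
  return lc;
}

static Rcpp::List run_net(const cube& X, const Rcpp::List& params,
                          const Rcpp::List& masks, int n_layers, bool bidir,
                          const std::string& head, bool want_grad,
                          SEXP Ysexp) {
  const uword B = X.n_cols, T = X.n_slices;
  const int D = bidir ? 2 : 1;
  std::vector<LayerCache> layers(n_layers);
  std::vector<cube> dropped(n_layers);  // post-dropout layer outputs
  cube cur = X;
  auto P = [&](int l, const char* d, const char* w) {
    std::string key = "l" + std::to_string(l) + d + std::string("_") + w;
    return Rcpp::as<mat>(params[key]);
  };
  std::vector<mat> Wxf(n_layers), Whf(n_layers), Wxb(n_layers), Whb(n_layers);
  std::vector<vec> bf(n_layers), bb(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    Wxf[l] = P(l + 1, "f", "Wx"); Whf[l] = P(l + 1, "f", "Wh");
    bf[l] = vec(Rcpp::as<vec>(params["l" + std::to_string(l + 1) + "f_b"]));
    if (bidir) {
      Wxb[l] = P(l + 1, "b", "Wx"); Whb[l] = P(l + 1, "b", "Wh");
      bb[l] = vec(Rcpp::as<vec>(params["l" + std::to_string(l + 1) + "b_b"]));
    } else {
      Wxb[l] = Wxf[l]; Whb[l] = Whf[l]; bb[l] = bf[l];
    }
    layers[l] = layer_forward(cur, Wxf[l], Whf[l], bf[l], Wxb[l], Whb[l],
                              bb[l], bidir);
    cur = layers[l].out;
    if (l < n_layers - 1 && masks.size() > l) {
      cube m = Rcpp::as<cube>(masks[l]);
      cur = cur % m;
    }
    dropped[l] = cur;
  }
  const uword H = Whf[0].n_cols;
  const uword DH = D * H;
  mat fcW = Rcpp::as<mat>(params["fc_W"]);
  vec fcb = Rcpp::as<vec>(params["fc_b"]);
  const uword O = fcW.n_rows;

  mat predflat;  // O x (BT) for curve, O x B for peak
  mat hlast;
  if (head == "curve") {
    mat Hf(cur.memptr(), DH, B * T, false, true);
    predflat = fcW * Hf;
    predflat.each_col() += fcb;
  } else {
    if (bidir) {
      cube Hb_rt = revcube(layers[n_layers - 1].bwd.H);
      hlast = join_cols(layers[n_layers - 1].fwd.H.slice(T - 1),
                        Hb_rt.slice(0));
    } else {
      hlast = layers[n_layers - 1].fwd.H.slice(T - 1);
    }
    predflat = fcW * hlast;
    predflat.each_col() += fcb;
  }

  if (!want_grad) {
    if (head == "curve") {
      cube pred(predflat.memptr(), O, B, T);
      return Rcpp::List::create(Rcpp::Named("pred") = pred);
    }
    return Rcpp::List::create(Rcpp::Named("pred") = predflat);
  }

  // ----- loss and gradients -----
  mat Yflat;
  if (head == "curve") {
    cube Y = Rcpp::as<cube>(Ysexp);
    Yflat = mat(Y.memptr(), O, B * T);
  } else {
    Yflat = Rcpp::as<mat>(Ysexp);
  }
  mat diff = predflat - Yflat;
  double n_el = (double)diff.n_elem;
  double loss = accu(diff % diff) / n_el;
  mat dP = (2.0 / n_el) * diff;

  const int total = n_layers * 3 * D + 2;
  Rcpp::List grads(total);
  Rcpp::CharacterVector gnames(total);
  int gi = 0;
  auto push = [&](const std::string& nm, SEXP val) {
    grads[gi] = val; gnames[gi] = nm; ++gi;
  };
  cube dOut(DH, B, T, fill::zeros);
  if (head == "curve") {
    mat Hf(dropped[n_layers - 1].memptr(), DH, B * T, false, true);
    push("fc_W", Rcpp::wrap(mat(dP * Hf.t())));
    push("fc_b", Rcpp::wrap(vec(sum(dP, 1))));
    mat dHf = fcW.t() * dP;  // DH x BT
    dOut = cube(dHf.memptr(), DH, B, T);
  } else {
    push("fc_W", Rcpp::wrap(mat(dP * hlast.t())));
    push("fc_b", Rcpp::wrap(vec(sum(dP, 1))));
    mat dhl = fcW.t() * dP;  // DH x B
    dOut.slice(T - 1).rows(0, H - 1) = dhl.rows(0, H - 1);
    if (bidir) dOut.slice(0).rows(H, DH - 1) = dhl.rows(H, DH - 1);
  }

  for (int l = n_layers - 1; l >= 0; --l) {
    if (l < n_layers - 1 && masks.size() > l) {
      cube m = Rcpp::as<cube>(masks[l]);
      dOut = dOut % m;
    }
    cube dXsum;
    if (bidir) {
      cube dHf(H, B, T), dHb_rt(H, B, T);
      for (uword t = 0; t < T; ++t) {
        dHf.slice(t) = dOut.slice(t).rows(0, H - 1);
        dHb_rt.slice(t) = dOut.slice(t).rows(H, 2 * H - 1);
      }
      DirGrads gf = dir_backward(layers[l].in_fwd, Wxf[l], Whf[l],
                                 layers[l].fwd, dHf);
      DirGrads gb = dir_backward(layers[l].in_bwd, Wxb[l], Whb[l],
                                 layers[l].bwd, revcube(dHb_rt));
      dXsum = gf.dX + revcube(gb.dX);
      std::string p = "l" + std::to_string(l + 1);
      push(p + "f_Wx", Rcpp::wrap(gf.dWx));
      push(p + "f_Wh", Rcpp::wrap(gf.dWh));
      push(p + "f_b", Rcpp::wrap(gf.db));
      push(p + "b_Wx", Rcpp::wrap(gb.dWx));
      push(p + "b_Wh", Rcpp::wrap(gb.dWh));
      push(p + "b_b", Rcpp::wrap(gb.db));
    } else {
      DirGrads gf = dir_backward(layers[l].in_fwd, Wxf[l], Whf[l],
                                 layers[l].fwd, dOut);
      dXsum = gf.dX;
      std::string p = "l" + std::to_string(l + 1);
      push(p + "f_Wx", Rcpp::wrap(gf.dWx));
      push(p + "f_Wh", Rcpp::wrap(gf.dWh));
      push(p + "f_b", Rcpp::wrap(gf.db));
    }
    if (l > 0) {
      const uword DHl = dropped[l - 1].n_rows;
      dOut = dXsum;
      (void)DHl;
    }
  }

  grads.attr("names") = gnames;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("grads") = grads);
  if (head == "curve") {
    out["pred"] = cube(predflat.memptr(), O, B, T);
  } else {
    out["pred"] = predflat;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::cube& X, const Rcpp::List& params,
                            const Rcpp::List& masks, int n_layers, bool bidir,
                            const std::string& head) {
  return run_net(X, params, masks, n_layers, bidir, head, false,
                 R_NilValue);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_loss_grad(const arma::cube& X, SEXP Y,
                              const Rcpp::List& params, const Rcpp::List& masks,
                              int n_layers, bool bidir,
                              const std::string& head) {
  return run_net(X, params, masks, n_layers, bidir, head, true, Y);
}
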