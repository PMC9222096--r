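// Core numerics: connected-component labeling for blob extraction and the
// edge-conditioned graph convolutional network (forward, backward, batching).
//
// Node-feature matrices are handled transposed (features x nodes) so that
// per-edge and per-node slices are contiguous in Armadillo's column-major
// storage.  A minibatch of graphs is concatenated into one block-diagonal
// graph, so every layer runs as a handful of dense GEMMs over the whole
// batch; the readout, head and loss are then evaluated per graph segment.
//
// The edge-conditioned filter
//   Theta_e = reshape(W2' tanh(W1' L_e + c1) + c2, d_out, d_in)
// is never materialised per edge: writing B_h = reshape(W2 row h, d_out,
// d_in) and C = reshape(c2), the message along edge e = (j -> i) is
//   m_e = sum_h z_{e,h} (B_h x_j) + C x_j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected components (stack-based flood fill), 4- or 8-connectivity.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cg_label_components")]]
IntegerMatrix cg_label_components(IntegerMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int m = 0; m < nn; ++m) {
          int r2 = cr + dr[m], c2 = cc + dc[m];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Parameter and data bundles
// ---------------------------------------------------------------------------
struct EccLayer {
  arma::mat W1t;     // h x 3
  arma::vec c1;      // h
  arma::mat W2;      // h x (dout*din)
  arma::vec c2;      // dout*din
  arma::vec b;       // dout
  arma::mat Bstack;  // (h*dout) x din (vertically stacked reshaped W2 rows)
  arma::mat C;       // dout x din      (reshaped c2)
  int din, dout, h;
};

static EccLayer make_layer(const arma::mat &W1, const arma::vec &c1,
                           const arma::mat &W2, const arma::vec &c2,
                           const arma::vec &b) {
  EccLayer L;
  L.W1t = W1.t();
  L.c1 = c1;
  L.W2 = W2;
  L.c2 = c2;
  L.b = b;
  L.h = W2.n_rows;
  L.dout = b.n_elem;
  L.din = c2.n_elem / L.dout;
  L.Bstack.set_size(L.h * L.dout, L.din);
  for (int k = 0; k < L.h; ++k)
    L.Bstack.rows(k * L.dout, (k + 1) * L.dout - 1) =
        arma::reshape(W2.row(k).t(), L.dout, L.din);
  L.C = arma::reshape(c2, L.dout, L.din);
  return L;
}

struct ModelParams {
  bool use_emb = false;
  arma::mat Wemb;  // 2 x de
  arma::vec bemb;
  std::vector<EccLayer> layers;
  arma::mat Whid, Wout;
  arma::vec chid, cout_;
};

static ModelParams parse_params(const List &params, int n_layers,
                                bool use_emb) {
  ModelParams P;
  P.use_emb = use_emb;
  if (use_emb) {
    P.Wemb = as<arma::mat>(params["Wemb"]);
    P.bemb = as<arma::vec>(params["bemb"]);
  }
  char buf[16];
  for (int l = 0; l < n_layers; ++l) {
    snprintf(buf, sizeof(buf), "_%d", l + 1);
    P.layers.push_back(make_layer(
        as<arma::mat>(params[std::string("W1") + buf]),
        as<arma::vec>(params[std::string("c1") + buf]),
        as<arma::mat>(params[std::string("W2") + buf]),
        as<arma::vec>(params[std::string("c2") + buf]),
        as<arma::vec>(params[std::string("b") + buf])));
  }
  P.Whid = as<arma::mat>(params["Whid"]);
  P.chid = as<arma::vec>(params["chid"]);
  P.Wout = as<arma::mat>(params["Wout"]);
  P.cout_ = as<arma::vec>(params["cout"]);
  return P;
}

// a minibatch of graphs concatenated into one block-diagonal graph
struct BlockGraph {
  int B = 0;                       // graphs in the block
  arma::mat Xt;                    // dfeat x N_total
  arma::mat St;                    // 2 x N_total
  arma::uvec src, dst;             // directed edges, global node ids
  arma::mat ELt;                   // 3 x E_total
  arma::vec deg;                   // N_total
  arma::ivec y;                    // per graph (-1 = unlabeled)
  arma::uvec node_lo, node_hi;     // per-graph node ranges [lo, hi]
  std::vector<arma::uvec> keep;    // per-graph flatten indices (global ids)
};

static BlockGraph build_block(const List &graphs) {
  BlockGraph BG;
  BG.B = graphs.size();
  int n_tot = 0, e_tot = 0;
  std::vector<arma::mat> Xts(BG.B), Sts(BG.B), ELts(BG.B);
  std::vector<arma::ivec> srcs(BG.B), dsts(BG.B), keeps(BG.B);
  std::vector<arma::vec> degs(BG.B);
  BG.y.set_size(BG.B);
  BG.node_lo.set_size(BG.B);
  BG.node_hi.set_size(BG.B);
  for (int g = 0; g < BG.B; ++g) {
    List gr = graphs[g];
    Xts[g] = as<arma::mat>(gr["Xt"]);
    Sts[g] = as<arma::mat>(gr["St"]);
    srcs[g] = as<arma::ivec>(gr["src"]);
    dsts[g] = as<arma::ivec>(gr["dst"]);
    keeps[g] = as<arma::ivec>(gr["keep"]);
    ELts[g] = as<arma::mat>(gr["ELt"]);
    degs[g] = as<arma::vec>(gr["deg"]);
    BG.y[g] = as<int>(gr["y"]);
    n_tot += Xts[g].n_cols;
    e_tot += srcs[g].n_elem;
  }
  const int dfeat = Xts[0].n_rows;
  BG.Xt.set_size(dfeat, n_tot);
  BG.St.set_size(2, n_tot);
  BG.deg.set_size(n_tot);
  BG.src.set_size(e_tot);
  BG.dst.set_size(e_tot);
  BG.ELt.set_size(3, e_tot);
  BG.keep.resize(BG.B);
  int no = 0, eo = 0;
  for (int g = 0; g < BG.B; ++g) {
    const int n = Xts[g].n_cols, e = srcs[g].n_elem;
    BG.Xt.cols(no, no + n - 1) = Xts[g];
    BG.St.cols(no, no + n - 1) = Sts[g];
    BG.deg.subvec(no, no + n - 1) = degs[g];
    for (int i = 0; i < e; ++i) {
      BG.src[eo + i] = srcs[g][i] + no;
      BG.dst[eo + i] = dsts[g][i] + no;
    }
    BG.ELt.cols(eo, eo + e - 1) = ELts[g];
    BG.keep[g] = arma::conv_to<arma::uvec>::from(keeps[g] + no);
    BG.node_lo[g] = no;
    BG.node_hi[g] = no + n - 1;
    no += n;
    eo += e;
  }
  return BG;
}

struct Config {
  int n_layers, readout, nmax;
  double gamma, eps;
  arma::vec alpha;
  bool use_emb;
};

static Config parse_config(const List &config) {
  Config C;
  C.n_layers = as<int>(config["n_layers"]);
  C.readout = as<int>(config["readout"]);
  C.nmax = as<int>(config["nmax"]);
  C.gamma = as<double>(config["gamma"]);
  C.eps = as<double>(config["eps"]);
  C.alpha = as<arma::vec>(config["alpha"]);
  C.use_emb = as<int>(config["use_emb"]) != 0;
  return C;
}

struct LayerCache {
  arma::mat Zt;    // h x E
  arma::mat Pre;   // dout x N (pre-activation)
  arma::mat Gsrc;  // (h*dout) x E (stacked B_k * H_in, gathered at sources)
};

struct PassCache {
  std::vector<arma::mat> Hs;   // H0..HL post-activation
  std::vector<LayerCache> lc;
  arma::mat R;                 // representation, Dr x B
  arma::mat Hpre, Hid, Logits, Probs;   // head, per-graph columns
};

// ECC layer pre-activation on a block graph (Eq.-style neighbourhood mean)
static arma::mat ecc_pre(const EccLayer &L, const BlockGraph &Gd,
                         const arma::mat &Hin, LayerCache &C) {
  const int N = Hin.n_cols;
  const arma::uword E = Gd.src.n_elem;
  C.Zt = L.W1t * Gd.ELt;
  C.Zt.each_col() += L.c1;
  C.Zt = arma::tanh(C.Zt);
  // stacked basis responses, gathered at edge sources
  arma::mat Gstack = L.Bstack * Hin;                 // (h*dout) x N
  C.Gsrc = Gstack.cols(Gd.src);                      // (h*dout) x E
  arma::mat Mt = (L.C * Hin).eval().cols(Gd.src);    // dout x E
  for (int k = 0; k < L.h; ++k) {
    Mt += C.Gsrc.rows(k * L.dout, (k + 1) * L.dout - 1).eval().each_row() %
          C.Zt.row(k);
  }
  arma::mat P(L.dout, N, arma::fill::zeros);
  const int dout = L.dout;
  for (arma::uword e = 0; e < E; ++e) {
    double *pp = P.colptr(Gd.dst[e]);
    const double *mp = Mt.colptr(e);
    for (int r = 0; r < dout; ++r) pp[r] += mp[r];
  }
  P.each_row() /= Gd.deg.t();
  P.each_col() += L.b;
  C.Pre = P;
  return P;
}

static void forward_pass(const ModelParams &P, const BlockGraph &Gd,
                         const Config &cfg, PassCache &C) {
  arma::mat H0;
  if (P.use_emb) {
    arma::mat Xe = P.Wemb.t() * Gd.St;
    Xe.each_col() += P.bemb;
    H0 = arma::join_cols(Gd.Xt, Xe);
  } else {
    H0 = Gd.Xt;
  }
  const int nl = cfg.n_layers;
  C.Hs.assign(nl + 1, arma::mat());
  C.lc.assign(nl, LayerCache());
  C.Hs[0] = std::move(H0);
  for (int l = 0; l < nl; ++l) {
    arma::mat pre = ecc_pre(P.layers[l], Gd, C.Hs[l], C.lc[l]);
    C.Hs[l + 1] = arma::clamp(pre, 0.0, arma::datum::inf);
  }
  const arma::mat &HL = C.Hs[nl];
  const int D = HL.n_rows;
  const int Dr = (cfg.readout == 0) ? D : cfg.nmax * D;
  C.R.zeros(Dr, Gd.B);
  for (int g = 0; g < Gd.B; ++g) {
    if (cfg.readout == 0) {
      C.R.col(g) = arma::mean(HL.cols(Gd.node_lo[g], Gd.node_hi[g]), 1);
    } else {
      const arma::uvec &kp = Gd.keep[g];
      for (arma::uword s = 0; s < kp.n_elem; ++s)
        C.R.col(g).subvec(s * D, s * D + D - 1) = HL.col(kp[s]);
    }
  }
  C.Hpre = P.Whid.t() * C.R;
  C.Hpre.each_col() += P.chid;
  C.Hid = arma::clamp(C.Hpre, 0.0, arma::datum::inf);
  C.Logits = P.Wout.t() * C.Hid;
  C.Logits.each_col() += P.cout_;
  C.Probs = 1.0 / (1.0 + arma::exp(-C.Logits));
}

// focal loss and gradient wrt logits for one probability column
static double focal_terms(const arma::vec &p, int y, double gamma,
                          const arma::vec &alpha, double eps,
                          arma::vec &dlogit) {
  const int K = p.n_elem;
  double loss = 0.0;
  dlogit.zeros(K);
  for (int c = 0; c < K; ++c) {
    const double yc = (c == y) ? 1.0 : 0.0;
    double pt = yc > 0.5 ? p[c] : 1.0 - p[c];
    double ptc = std::min(std::max(pt, eps), 1.0 - eps);
    loss += alpha[c] * std::pow(1.0 - ptc, gamma) * (-std::log(ptc));
    // d/dpt of -(1-pt)^g log pt, evaluated at the clamped pt
    double fp = alpha[c] * (gamma * std::pow(1.0 - ptc, gamma - 1.0) *
                                std::log(ptc) -
                            std::pow(1.0 - ptc, gamma) / ptc);
    double dpt_dp = yc > 0.5 ? 1.0 : -1.0;
    dlogit[c] = fp * dpt_dp * p[c] * (1.0 - p[c]);
  }
  return loss;
}

struct ModelGrads {
  arma::mat Wemb;
  arma::vec bemb;
  struct L {
    arma::mat W1, W2;
    arma::vec c1, c2, b;
  };
  std::vector<L> layers;
  arma::mat Whid, Wout;
  arma::vec chid, cout_;
  void init(const ModelParams &P) {
    if (P.use_emb) {
      Wemb.zeros(P.Wemb.n_rows, P.Wemb.n_cols);
      bemb.zeros(P.bemb.n_elem);
    }
    layers.resize(P.layers.size());
    for (size_t l = 0; l < P.layers.size(); ++l) {
      const EccLayer &E = P.layers[l];
      layers[l].W1.zeros(3, E.h);
      layers[l].c1.zeros(E.h);
      layers[l].W2.zeros(E.h, E.dout * E.din);
      layers[l].c2.zeros(E.dout * E.din);
      layers[l].b.zeros(E.dout);
    }
    Whid.zeros(P.Whid.n_rows, P.Whid.n_cols);
    chid.zeros(P.chid.n_elem);
    Wout.zeros(P.Wout.n_rows, P.Wout.n_cols);
    cout_.zeros(P.cout_.n_elem);
  }
};

// backward through the whole block given d(loss)/d(logits) per graph column
static void backward_pass(const ModelParams &P, const BlockGraph &Gd,
                          const Config &cfg, const PassCache &C,
                          const arma::mat &dLogits, ModelGrads &G,
                          arma::mat *dH0_out = nullptr) {
  const int nl = cfg.n_layers;
  G.Wout += C.Hid * dLogits.t();
  G.cout_ += arma::sum(dLogits, 1);
  arma::mat dHid = P.Wout * dLogits;
  arma::mat dHpre = dHid % arma::conv_to<arma::mat>::from(C.Hpre > 0);
  G.Whid += C.R * dHpre.t();
  G.chid += arma::sum(dHpre, 1);
  arma::mat dR = P.Whid * dHpre;          // Dr x B

  const arma::mat &HL = C.Hs[nl];
  const int N = HL.n_cols, D = HL.n_rows;
  arma::mat dH(D, N, arma::fill::zeros);
  for (int g = 0; g < Gd.B; ++g) {
    if (cfg.readout == 0) {
      const double n_g = Gd.node_hi[g] - Gd.node_lo[g] + 1;
      dH.cols(Gd.node_lo[g], Gd.node_hi[g]).each_col() += dR.col(g) / n_g;
    } else {
      const arma::uvec &kp = Gd.keep[g];
      for (arma::uword s = 0; s < kp.n_elem; ++s)
        dH.col(kp[s]) += dR.col(g).subvec(s * D, s * D + D - 1);
    }
  }

  const arma::uword E = Gd.src.n_elem;
  arma::rowvec inv_deg = (1.0 / Gd.deg).t();
  for (int l = nl - 1; l >= 0; --l) {
    const EccLayer &L = P.layers[l];
    const LayerCache &lc = C.lc[l];
    const arma::mat &Hin = C.Hs[l];
    ModelGrads::L &gl = G.layers[l];

    arma::mat dP = dH % arma::conv_to<arma::mat>::from(lc.Pre > 0);
    gl.b += arma::sum(dP, 1);
    arma::mat dPn = dP.each_row() % inv_deg;
    arma::mat dMt = dPn.cols(Gd.dst);              // dout x E
    arma::mat Xsrc = Hin.cols(Gd.src);             // din x E

    arma::mat dC = dMt * Xsrc.t();                 // dout x din
    gl.c2 += arma::vectorise(dC);

    // stacked dM scaled by the hidden activations, and dZ(k, e) =
    // dm_e . (B_k x_src(e)) via block sums over the cached Gsrc
    const int dout = L.dout;
    arma::mat Sstack(L.h * dout, E);
    arma::mat dZt(L.h, E);
    for (int k = 0; k < L.h; ++k) {
      Sstack.rows(k * dout, (k + 1) * dout - 1) =
          dMt.each_row() % lc.Zt.row(k);
      dZt.row(k) = arma::sum(
          dMt % lc.Gsrc.rows(k * dout, (k + 1) * dout - 1), 0);
    }
    arma::mat dW2stack = Sstack * Xsrc.t();        // (h*dout) x din
    for (int k = 0; k < L.h; ++k) {
      gl.W2.row(k) += arma::vectorise(
          dW2stack.rows(k * dout, (k + 1) * dout - 1)).t();
    }
    arma::mat dXsrc = L.C.t() * dMt + L.Bstack.t() * Sstack;  // din x E
    arma::mat dA = dZt % (1.0 - lc.Zt % lc.Zt);
    gl.W1 += (dA * Gd.ELt.t()).t();                // 3 x h
    gl.c1 += arma::sum(dA, 1);

    arma::mat dHin(Hin.n_rows, N, arma::fill::zeros);
    const int din = Hin.n_rows;
    for (arma::uword e = 0; e < E; ++e) {
      double *hp = dHin.colptr(Gd.src[e]);
      const double *xp = dXsrc.colptr(e);
      for (int r = 0; r < din; ++r) hp[r] += xp[r];
    }
    dH = std::move(dHin);
  }

  if (dH0_out) *dH0_out = dH;
  if (P.use_emb) {
    const int dfeat = Gd.Xt.n_rows;
    arma::mat dXe = dH.rows(dfeat, dH.n_rows - 1);
    G.Wemb += (dXe * Gd.St.t()).t();
    G.bemb += arma::sum(dXe, 1);
  }
}

static List grads_to_list(const ModelGrads &G, CharacterVector nms) {
  List out;
  for (int i = 0; i < nms.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    arma::mat M;
    if (nm == "Wemb") M = G.Wemb;
    else if (nm == "bemb") M = arma::mat(G.bemb);
    else if (nm == "Whid") M = G.Whid;
    else if (nm == "chid") M = arma::mat(G.chid);
    else if (nm == "Wout") M = G.Wout;
    else if (nm == "cout") M = arma::mat(G.cout_);
    else {
      size_t us = nm.rfind('_');
      int idx = 0;
      for (size_t k = us + 1; k < nm.size(); ++k) idx = idx * 10 + (nm[k] - '0');
      int l = idx - 1;
      std::string base = nm.substr(0, us);
      if (base == "W1") M = G.layers[l].W1;
      else if (base == "c1") M = arma::mat(G.layers[l].c1);
      else if (base == "W2") M = G.layers[l].W2;
      else if (base == "c2") M = arma::mat(G.layers[l].c2);
      else if (base == "b") M = arma::mat(G.layers[l].b);
      else stop("unknown parameter name: " + nm);
    }
    out.push_back(wrap(M));
  }
  out.names() = nms;
  return out;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cg_ecc_forward")]]
NumericMatrix cg_ecc_forward(NumericMatrix X, IntegerVector src,
                             IntegerVector dst, NumericMatrix EL,
                             NumericVector deg, NumericMatrix W1,
                             NumericMatrix c1, NumericMatrix W2,
                             NumericMatrix c2, NumericMatrix b) {
  EccLayer L = make_layer(as<arma::mat>(W1), as<arma::vec>(c1),
                          as<arma::mat>(W2), as<arma::vec>(c2),
                          as<arma::vec>(b));
  BlockGraph Gd;
  Gd.B = 1;
  Gd.src = arma::conv_to<arma::uvec>::from(as<arma::ivec>(src));
  Gd.dst = arma::conv_to<arma::uvec>::from(as<arma::ivec>(dst));
  Gd.ELt = arma::trans(as<arma::mat>(EL));
  Gd.deg = as<arma::vec>(deg);
  arma::mat Ht = arma::trans(as<arma::mat>(X));
  LayerCache lc;
  arma::mat P = ecc_pre(L, Gd, Ht, lc);
  return wrap(arma::mat(P.t()));
}

// [[Rcpp::export(name = ".cg_batch_grad")]]
List cg_batch_grad(List params, List graphs, List config) {
  Config cfg = parse_config(config);
  ModelParams P = parse_params(params, cfg.n_layers, cfg.use_emb);
  BlockGraph Gd = build_block(graphs);
  PassCache C;
  forward_pass(P, Gd, cfg, C);

  double loss = 0.0;
  int correct = 0;
  arma::mat dLogits(C.Logits.n_rows, Gd.B);
  arma::vec dlogit;
  for (int g = 0; g < Gd.B; ++g) {
    loss += focal_terms(C.Probs.col(g), Gd.y[g], cfg.gamma, cfg.alpha,
                        cfg.eps, dlogit);
    if ((int)arma::vec(C.Probs.col(g)).index_max() == Gd.y[g]) ++correct;
    dLogits.col(g) = dlogit;
  }
  ModelGrads G;
  G.init(P);
  backward_pass(P, Gd, cfg, C, dLogits, G);
  return List::create(_["loss"] = loss, _["correct"] = correct,
                      _["n"] = Gd.B,
                      _["grads"] = grads_to_list(G, params.names()));
}

// [[Rcpp::export(name = ".cg_forward")]]
List cg_forward(List params, List graph, List config) {
  Config cfg = parse_config(config);
  ModelParams P = parse_params(params, cfg.n_layers, cfg.use_emb);
  BlockGraph Gd = build_block(List::create(graph));
  PassCache C;
  forward_pass(P, Gd, cfg, C);
  return List::create(
      _["H_last"] = wrap(arma::mat(arma::trans(C.Hs[cfg.n_layers]))),
      _["rep"] = wrap(arma::vec(C.R.col(0))),
      _["hpre"] = wrap(arma::vec(C.Hpre.col(0))),
      _["hid"] = wrap(arma::vec(C.Hid.col(0))),
      _["logits"] = wrap(arma::vec(C.Logits.col(0))),
      _["probs"] = wrap(arma::vec(C.Probs.col(0))));
}

// gradient of one class logit with respect to the fused input node features
// (patch/geometric features plus spatial embedding), for saliency hooks at
// the input layer
// [[Rcpp::export(name = ".cg_input_grad")]]
List cg_input_grad(List params, List graph, List config, int target_class) {
  Config cfg = parse_config(config);
  ModelParams P = parse_params(params, cfg.n_layers, cfg.use_emb);
  BlockGraph Gd = build_block(List::create(graph));
  PassCache C;
  forward_pass(P, Gd, cfg, C);
  arma::mat dLogits(C.Logits.n_rows, 1, arma::fill::zeros);
  dLogits(target_class, 0) = 1.0;
  ModelGrads G;
  G.init(P);
  arma::mat dH0;
  backward_pass(P, Gd, cfg, C, dLogits, G, &dH0);
  return List::create(_["H0"] = wrap(arma::mat(C.Hs[0].t())),
                      _["dH0"] = wrap(arma::mat(dH0.t())),
                      _["probs"] = wrap(arma::vec(C.Probs.col(0))));
}

// [[Rcpp::export(name = ".cg_batch_eval")]]
List cg_batch_eval(List params, List graphs, List config) {
  Config cfg = parse_config(config);
  ModelParams P = parse_params(params, cfg.n_layers, cfg.use_emb);
  const int n = graphs.size();
  arma::mat probs(n, P.cout_.n_elem);
  double loss = 0.0;
  int correct = 0;
  // evaluate in blocks to bound memory
  const int chunk = 256;
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(n, lo + chunk);
    List sub(hi - lo);
    for (int g = lo; g < hi; ++g) sub[g - lo] = graphs[g];
    BlockGraph Gd = build_block(sub);
    PassCache C;
    forward_pass(P, Gd, cfg, C);
    for (int g = 0; g < Gd.B; ++g) {
      probs.row(lo + g) = C.Probs.col(g).t();
      if (Gd.y[g] >= 0) {
        arma::vec dl;
        loss += focal_terms(C.Probs.col(g), Gd.y[g], cfg.gamma, cfg.alpha,
                            cfg.eps, dl);
        if ((int)arma::vec(C.Probs.col(g)).index_max() == Gd.y[g]) ++correct;
      }
    }
  }
  return List::create(_["probs"] = wrap(probs), _["loss"] = loss,
                      _["correct"] = correct);
}
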