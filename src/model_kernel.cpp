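// Fast path for model training and greedy decoding.
//
// This mirrors the reference R implementation in R/nn.R and R/model.R
// exactly (pre-norm transformer encoder + two decoders, permutation-min
// loss); the R path remains the readable reference and is used whenever
// dropout is active. Tests assert that both paths produce matching losses
// and gradients.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Cfg {
  int g, r, d, E, Dd, he, hd, le, ld, ff, V, maxT;
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.g = cfg["g"]; c.r = cfg["r"]; c.d = cfg["d"]; c.E = cfg["E"];
  c.Dd = cfg["Dd"]; c.he = cfg["he"]; c.hd = cfg["hd"];
  c.le = cfg["le"]; c.ld = cfg["ld"]; c.ff = cfg["ff"];
  c.V = cfg["V"]; c.maxT = cfg["maxT"];
  return c;
}

// parameter store: named flat list of matrices (vectors are 1-col matrices)
struct Params {
  std::map<std::string, mat> p;
  std::map<std::string, mat> g;   // gradients, same shapes
  mat& at(const std::string& k) {
    auto it = p.find(k);
    if (it == p.end()) stop("missing parameter: " + k);
    return it->second;
  }
  mat& grad(const std::string& k) { return g[k]; }
  void init_grads() {
    for (auto& kv : p) g[kv.first] = mat(kv.second.n_rows, kv.second.n_cols,
                                         arma::fill::zeros);
  }
};

Params read_params(const List& flat) {
  Params P;
  CharacterVector nm = flat.names();
  for (int i = 0; i < flat.size(); ++i) {
    RObject o = flat[i];
    std::string key = as<std::string>(nm[i]);
    if (Rf_isMatrix(o)) {
      P.p[key] = as<mat>(o);
    } else {
      NumericVector v(o);
      P.p[key] = mat(as<vec>(v));
    }
  }
  return P;
}

// ---- primitives ------------------------------------------------------------

struct LinCache { mat X; };

mat lin_fwd(Params& P, const std::string& k, const mat& X, LinCache& c) {
  c.X = X;
  mat Y = X * P.at(k + ".W");
  Y.each_row() += P.at(k + ".b").t();
  return Y;
}

mat lin_bwd(Params& P, const std::string& k, const LinCache& c,
            const mat& dY) {
  P.grad(k + ".W") += c.X.t() * dY;
  P.grad(k + ".b") += arma::sum(dY, 0).t();
  return dY * P.at(k + ".W").t();
}

struct LnCache { mat Xh; vec inv; };

mat ln_fwd(Params& P, const std::string& k, const mat& X, LnCache& c,
           double eps = 1e-5) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = arma::mean(Xc % Xc, 1);
  c.inv = 1.0 / arma::sqrt(v + eps);
  c.Xh = Xc.each_col() % c.inv;
  rowvec gr = P.at(k + ".g").col(0).t();
  rowvec br = P.at(k + ".b").col(0).t();
  mat Y = c.Xh.each_row() % gr;
  Y.each_row() += br;
  return Y;
}

mat ln_bwd(Params& P, const std::string& k, const LnCache& c, const mat& dY) {
  P.grad(k + ".g") += arma::sum(dY % c.Xh, 0).t();
  P.grad(k + ".b") += arma::sum(dY, 0).t();
  rowvec gr2 = P.at(k + ".g").col(0).t();
  mat dXh = dY.each_row() % gr2;
  vec m1 = arma::mean(dXh, 1);
  vec m2 = arma::mean(dXh % c.Xh, 1);
  mat dX = dXh.each_col() - m1;
  dX -= c.Xh.each_col() % m2;
  dX.each_col() %= c.inv;
  return dX;
}

struct GeluCache { mat X; };

mat gelu_fwd(const mat& X, GeluCache& c) {
  c.X = X;
  return X % (0.5 * (1.0 + arma::erf(X / std::sqrt(2.0))));
}

mat gelu_bwd(const GeluCache& c, const mat& dY) {
  mat Phi = 0.5 * (1.0 + arma::erf(c.X / std::sqrt(2.0)));
  mat phi = arma::exp(-0.5 * c.X % c.X) / std::sqrt(2.0 * M_PI);
  return dY % (Phi + c.X % phi);
}

mat softmax_rows(const mat& S) {
  mat E = arma::exp(S.each_col() - arma::max(S, 1));
  return E.each_col() / arma::sum(E, 1);
}

struct MhaCache {
  LinCache cq, ck, cv, co;
  mat Q, K, V, O;
  std::vector<mat> A;
};

mat mha_fwd(Params& P, const std::string& k, const mat& Xq, const mat& Xkv,
            int nhead, bool causal, MhaCache& c) {
  int D = Xq.n_cols, hd = D / nhead;
  double scale = 1.0 / std::sqrt((double)hd);
  c.Q = lin_fwd(P, k + ".q", Xq, c.cq);
  c.K = lin_fwd(P, k + ".k", Xkv, c.ck);
  c.V = lin_fwd(P, k + ".v", Xkv, c.cv);
  c.O = mat(Xq.n_rows, D);
  c.A.resize(nhead);
  for (int h = 0; h < nhead; ++h) {
    arma::span idx(h * hd, (h + 1) * hd - 1);
    mat S = c.Q.cols(idx) * c.K.cols(idx).t() * scale;
    if (causal)
      for (arma::uword i = 0; i < S.n_rows; ++i)
        for (arma::uword j = i + 1; j < S.n_cols; ++j)
          S(i, j) = -arma::datum::inf;
    c.A[h] = softmax_rows(S);
    c.O.cols(idx) = c.A[h] * c.V.cols(idx);
  }
  return lin_fwd(P, k + ".o", c.O, c.co);
}

// returns dXq; adds dXkv into the supplied accumulator
mat mha_bwd(Params& P, const std::string& k, MhaCache& c, const mat& dY,
            int nhead, mat& dXkv_acc) {
  int D = c.Q.n_cols, hd = D / nhead;
  double scale = 1.0 / std::sqrt((double)hd);
  mat dO = lin_bwd(P, k + ".o", c.co, dY);
  mat dQ(c.Q.n_rows, D, arma::fill::zeros);
  mat dK(c.K.n_rows, D, arma::fill::zeros);
  mat dV(c.V.n_rows, D, arma::fill::zeros);
  for (int h = 0; h < nhead; ++h) {
    arma::span idx(h * hd, (h + 1) * hd - 1);
    mat dOh = dO.cols(idx);
    mat dA = dOh * c.V.cols(idx).t();
    dV.cols(idx) = c.A[h].t() * dOh;
    mat AdA = c.A[h] % dA;
    mat dS = AdA - (c.A[h].each_col() % arma::sum(AdA, 1));
    dQ.cols(idx) = dS * c.K.cols(idx) * scale;
    dK.cols(idx) = dS.t() * c.Q.cols(idx) * scale;
  }
  mat dXq = lin_bwd(P, k + ".q", c.cq, dQ);
  dXkv_acc += lin_bwd(P, k + ".k", c.ck, dK);
  dXkv_acc += lin_bwd(P, k + ".v", c.cv, dV);
  return dXq;
}

struct FfCache { LinCache c1, c2; GeluCache cg; };

mat ff_fwd(Params& P, const std::string& k, const mat& X, FfCache& c) {
  mat a = lin_fwd(P, k + ".l1", X, c.c1);
  mat g = gelu_fwd(a, c.cg);
  return lin_fwd(P, k + ".l2", g, c.c2);
}

mat ff_bwd(Params& P, const std::string& k, FfCache& c, const mat& dY) {
  mat dg = lin_bwd(P, k + ".l2", c.c2, dY);
  mat da = gelu_bwd(c.cg, dg);
  return lin_bwd(P, k + ".l1", c.c1, da);
}

// ---- encoder ---------------------------------------------------------------

struct EncLayerCache { LnCache n1, n2; MhaCache at; FfCache ff; };

struct EncCache {
  LinCache emb, proj;
  LnCache fin;
  vec mask;
  mat X;                 // [g*r, 10]
  std::vector<EncLayerCache> layers;
};

std::string encl(int l, const char* part) {
  return "enc.l" + std::to_string(l + 1) + "." + part;
}

mat enc_fwd(Params& P, const Cfg& c, const mat& X, const mat& pe2d,
            EncCache& cc) {
  cc.X = X;
  cc.mask = arma::conv_to<vec>::from(arma::sum(arma::abs(X), 1) > 0);
  mat E1 = lin_fwd(P, "embed", X, cc.emb) + pe2d;
  E1.each_col() %= cc.mask;
  // flatten: F(p, (j)*d + k) = E1(p + j*g, k)
  mat F(c.g, c.r * c.d);
  for (int j = 0; j < c.r; ++j)
    F.cols(j * c.d, (j + 1) * c.d - 1) = E1.rows(j * c.g, (j + 1) * c.g - 1);
  mat H = lin_fwd(P, "proj", F, cc.proj);
  cc.layers.resize(c.le);
  for (int l = 0; l < c.le; ++l) {
    EncLayerCache& lc = cc.layers[l];
    mat n1 = ln_fwd(P, encl(l, "ln1"), H, lc.n1);
    H += mha_fwd(P, encl(l, "attn"), n1, n1, c.he, false, lc.at);
    mat n2 = ln_fwd(P, encl(l, "ln2"), H, lc.n2);
    H += ff_fwd(P, encl(l, "ff"), n2, lc.ff);
  }
  return ln_fwd(P, "enc_final", H, cc.fin);
}

void enc_bwd(Params& P, const Cfg& c, EncCache& cc, const mat& dY) {
  mat dH = ln_bwd(P, "enc_final", cc.fin, dY);
  for (int l = c.le - 1; l >= 0; --l) {
    EncLayerCache& lc = cc.layers[l];
    mat dn2 = ff_bwd(P, encl(l, "ff"), lc.ff, dH);
    dH += ln_bwd(P, encl(l, "ln2"), lc.n2, dn2);
    mat dkv(c.g, c.E, arma::fill::zeros);
    mat dq = mha_bwd(P, encl(l, "attn"), lc.at, dH, c.he, dkv);
    dH += ln_bwd(P, encl(l, "ln1"), lc.n1, dq + dkv);
  }
  mat dF = lin_bwd(P, "proj", cc.proj, dH);
  mat dE1(c.g * c.r, c.d);
  for (int j = 0; j < c.r; ++j)
    dE1.rows(j * c.g, (j + 1) * c.g - 1) = dF.cols(j * c.d, (j + 1) * c.d - 1);
  dE1.each_col() %= cc.mask;
  lin_bwd(P, "embed", cc.emb, dE1);
}

// ---- decoder ---------------------------------------------------------------

struct DecLayerCache { LnCache n1, n2, n3; MhaCache sa, ca; FfCache ff; };

struct DecCache {
  LnCache fin;
  LinCache out;
  std::vector<DecLayerCache> layers;
  std::vector<int> ids;
  int L;
};

std::string decl(const std::string& dec, int l, const char* part) {
  return dec + ".layers.l" + std::to_string(l + 1) + "." + part;
}

// input_ids: 0-based previous tokens; returns logits [L+1, V]
mat dec_fwd(Params& P, const Cfg& c, const std::string& dec, const mat& M,
            const std::vector<int>& ids, const mat& pe_dec, DecCache& cc) {
  int L = (int)ids.size() + 1;
  cc.L = L;
  cc.ids = ids;
  mat X(L, c.Dd);
  X.row(0) = P.at(dec + ".start").col(0).t();
  const mat& tok = P.at(dec + ".tok");
  for (int t = 1; t < L; ++t) X.row(t) = tok.row(ids[t - 1]);
  X += pe_dec.rows(0, L - 1);
  cc.layers.resize(c.ld);
  for (int l = 0; l < c.ld; ++l) {
    DecLayerCache& lc = cc.layers[l];
    mat n1 = ln_fwd(P, decl(dec, l, "ln1"), X, lc.n1);
    X += mha_fwd(P, decl(dec, l, "self"), n1, n1, c.hd, true, lc.sa);
    mat n2 = ln_fwd(P, decl(dec, l, "ln2"), X, lc.n2);
    X += mha_fwd(P, decl(dec, l, "cross"), n2, M, c.hd, false, lc.ca);
    mat n3 = ln_fwd(P, decl(dec, l, "ln3"), X, lc.n3);
    X += ff_fwd(P, decl(dec, l, "ff"), n3, lc.ff);
  }
  mat fin = ln_fwd(P, dec + ".final", X, cc.fin);
  return lin_fwd(P, dec + ".out", fin, cc.out);
}

// returns dM accumulated into dM_acc
void dec_bwd(Params& P, const Cfg& c, const std::string& dec, DecCache& cc,
             const mat& dLogits, mat& dM_acc) {
  mat dfin = lin_bwd(P, dec + ".out", cc.out, dLogits);
  mat dX = ln_bwd(P, dec + ".final", cc.fin, dfin);
  for (int l = c.ld - 1; l >= 0; --l) {
    DecLayerCache& lc = cc.layers[l];
    mat dn3 = ff_bwd(P, decl(dec, l, "ff"), lc.ff, dX);
    dX += ln_bwd(P, decl(dec, l, "ln3"), lc.n3, dn3);
    mat dq = mha_bwd(P, decl(dec, l, "cross"), lc.ca, dX, c.hd, dM_acc);
    dX += ln_bwd(P, decl(dec, l, "ln2"), lc.n2, dq);
    mat dkv(cc.L, c.Dd, arma::fill::zeros);
    mat dq2 = mha_bwd(P, decl(dec, l, "self"), lc.sa, dX, c.hd, dkv);
    dX += ln_bwd(P, decl(dec, l, "ln1"), lc.n1, dq2 + dkv);
  }
  P.grad(dec + ".start") += dX.row(0).t();
  mat& dtok = P.grad(dec + ".tok");
  for (int t = 1; t < cc.L; ++t) dtok.row(cc.ids[t - 1]) += dX.row(t);
}

// token cross-entropy (mean over steps); fills dLogits
double ce_loss(const mat& logits, const std::vector<int>& tgt, mat& dLogits) {
  int L = logits.n_rows;
  vec mx = arma::max(logits, 1);
  vec lse = mx + arma::log(arma::sum(arma::exp(logits.each_col() - mx), 1));
  double loss = 0;
  mat Pm = arma::exp(logits.each_col() - lse);
  for (int i = 0; i < L; ++i) {
    loss += lse(i) - logits(i, tgt[i]);
    Pm(i, tgt[i]) -= 1.0;
  }
  dLogits = Pm / L;
  return loss / L;
}

double ce_only(const mat& logits, const std::vector<int>& tgt) {
  mat dummy;
  return ce_loss(logits, tgt, dummy);
}

std::vector<int> ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

}  // namespace

// Batched training gradient: sums losses and gradients over a list of
// examples (X matrices [g*r, 10], token targets), using the permutation-min
// pairing per example.
// [[Rcpp::export(name = ".nn_batch_grad_cpp")]]
List nn_batch_grad_cpp(List flat_params, List Xs, List t0s, List t1s,
                       List cfg, NumericMatrix pe2d_, NumericMatrix pe_mem_,
                       NumericMatrix pe_dec_) {
  Cfg c = read_cfg(cfg);
  Params P = read_params(flat_params);
  P.init_grads();
  mat pe2d = as<mat>(pe2d_), pe_mem = as<mat>(pe_mem_),
      pe_dec = as<mat>(pe_dec_);
  int n = Xs.size();
  double total_loss = 0;
  for (int e = 0; e < n; ++e) {
    mat X = as<mat>(Xs[e]);
    std::vector<int> t0 = ivec(t0s[e]), t1 = ivec(t1s[e]);
    std::vector<int> in0(t0.begin(), t0.end() - 1);
    std::vector<int> in1(t1.begin(), t1.end() - 1);
    EncCache ec;
    mat H = enc_fwd(P, c, X, pe2d, ec);
    LinCache memc;
    mat M = lin_fwd(P, "mem", H, memc) + pe_mem;
    DecCache d0, d1;
    mat dl0, dl1;
    double loss;
    if (t0 == t1) {
      mat l0 = dec_fwd(P, c, "dec0", M, in0, pe_dec, d0);
      mat l1 = dec_fwd(P, c, "dec1", M, in1, pe_dec, d1);
      loss = ce_loss(l0, t0, dl0) + ce_loss(l1, t1, dl1);
    } else {
      DecCache a0, a1, b0, b1;
      mat la0 = dec_fwd(P, c, "dec0", M, in0, pe_dec, a0);
      mat la1 = dec_fwd(P, c, "dec1", M, in1, pe_dec, a1);
      mat lb0 = dec_fwd(P, c, "dec0", M, in1, pe_dec, b0);
      mat lb1 = dec_fwd(P, c, "dec1", M, in0, pe_dec, b1);
      double straight = ce_only(la0, t0) + ce_only(la1, t1);
      double crossed = ce_only(lb0, t1) + ce_only(lb1, t0);
      if (straight <= crossed) {
        loss = ce_loss(la0, t0, dl0) + ce_loss(la1, t1, dl1);
        d0 = a0; d1 = a1;
      } else {
        loss = ce_loss(lb0, t1, dl0) + ce_loss(lb1, t0, dl1);
        d0 = b0; d1 = b1;
      }
    }
    total_loss += loss;
    mat dM(c.g, c.Dd, arma::fill::zeros);
    dec_bwd(P, c, "dec0", d0, dl0, dM);
    dec_bwd(P, c, "dec1", d1, dl1, dM);
    mat dH = lin_bwd(P, "mem", memc, dM);
    enc_bwd(P, c, ec, dH);
  }
  // export gradients with the same names
  List out;
  CharacterVector nm = flat_params.names();
  List gl(flat_params.size());
  for (int i = 0; i < flat_params.size(); ++i) {
    std::string key = as<std::string>(nm[i]);
    RObject o = flat_params[i];
    const mat& gm = P.g[key];
    if (Rf_isMatrix(o)) {
      gl[i] = wrap(gm);
    } else {
      gl[i] = NumericVector(gm.begin(), gm.end());
    }
  }
  gl.names() = nm;
  return List::create(_["loss"] = total_loss, _["n"] = n, _["grads"] = gl);
}

// Greedy decoding for one encoded window (both decoders).
// [[Rcpp::export(name = ".nn_greedy_cpp")]]
List nn_greedy_cpp(List flat_params, NumericMatrix X_, List cfg,
                   NumericMatrix pe2d_, NumericMatrix pe_mem_,
                   NumericMatrix pe_dec_, int nTokens) {
  Cfg c = read_cfg(cfg);
  Params P = read_params(flat_params);
  P.init_grads();  // unused but keeps struct valid
  mat pe2d = as<mat>(pe2d_), pe_mem = as<mat>(pe_mem_),
      pe_dec = as<mat>(pe_dec_);
  mat X = as<mat>(X_);
  EncCache ec;
  mat H = enc_fwd(P, c, X, pe2d, ec);
  LinCache memc;
  mat M = lin_fwd(P, "mem", H, memc) + pe_mem;
  IntegerVector ids0(nTokens), ids1(nTokens);
  NumericVector pr0(nTokens), pr1(nTokens);
  for (int dec = 0; dec < 2; ++dec) {
    std::string key = dec == 0 ? "dec0" : "dec1";
    std::vector<int> ids;
    for (int t = 0; t < nTokens; ++t) {
      DecCache dc;
      mat logits = dec_fwd(P, c, key, M, ids, pe_dec, dc);
      rowvec last = logits.row(logits.n_rows - 1);
      rowvec p = arma::exp(last - last.max());
      p /= arma::accu(p);
      arma::uword best = p.index_max();   // first max = lowest token id
      ids.push_back((int)best);
      if (dec == 0) { ids0[t] = (int)best; pr0[t] = p(best); }
      else { ids1[t] = (int)best; pr1[t] = p(best); }
    }
  }
  return List::create(_["ids0"] = ids0, _["probs0"] = pr0,
                      _["ids1"] = ids1, _["probs1"] = pr1);
}
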