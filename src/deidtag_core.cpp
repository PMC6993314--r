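// Numerical core for the de-identification tagger.
//
// Layout conventions (column-major, Armadillo):
//   * sequences are stored one column per time step
//   * emissions are T x L (row t = scores over labels for token t)
//   * CRF transitions are (L+2) x (L+2); row = from, col = to;
//     index L is the virtual start state, L+1 the stop state
//   * label index 0 is the not-PHI tag "O"; Viterbi ties resolve to the
//     lowest label index
// All randomness (dropout masks, negative sampling) is drawn from R's RNG so
// set.seed() on the R side fully determines results.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline double logsumexp(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(x - m)));
}

// ---------------------------------------------------------------------------
// Linear-chain CRF
// ---------------------------------------------------------------------------

static double crf_logZ_(const mat& emis, const mat& trans) {
  const uword T = emis.n_rows, L = emis.n_cols;
  const uword S = L, E = L + 1;
  vec alpha = trans.submat(S, 0, S, L - 1).t() + emis.row(0).t();
  for (uword t = 1; t < T; ++t) {
    vec nxt(L);
    for (uword j = 0; j < L; ++j)
      nxt(j) = logsumexp(alpha + trans.submat(0, j, L - 1, j)) + emis(t, j);
    alpha = nxt;
  }
  return logsumexp(alpha + trans.submat(0, E, L - 1, E));
}

static double crf_path_score_(const mat& emis, const arma::ivec& y,
                              const mat& trans) {
  const uword T = emis.n_rows, L = emis.n_cols;
  const uword S = L, E = L + 1;
  double s = trans(S, (uword)y(0)) + emis(0, (uword)y(0));
  for (uword t = 1; t < T; ++t)
    s += trans((uword)y(t - 1), (uword)y(t)) + emis(t, (uword)y(t));
  s += trans((uword)y(T - 1), E);
  return s;
}

// [[Rcpp::export]]
double cpp_crf_logZ(const arma::mat& emissions, const arma::mat& trans) {
  return crf_logZ_(emissions, trans);
}

// [[Rcpp::export]]
double cpp_crf_loglik(const arma::mat& emissions, const arma::ivec& labels,
                      const arma::mat& trans) {
  return crf_path_score_(emissions, labels, trans) - crf_logZ_(emissions, trans);
}

// Gradient of the negative log-likelihood: expected minus observed counts.
// [[Rcpp::export]]
List cpp_crf_grad(const arma::mat& emissions, const arma::ivec& labels,
                  const arma::mat& trans) {
  const uword T = emissions.n_rows, L = emissions.n_cols;
  const uword S = L, E = L + 1;

  mat alpha(T, L), beta(T, L);
  alpha.row(0) = trans.submat(S, 0, S, L - 1) + emissions.row(0);
  for (uword t = 1; t < T; ++t)
    for (uword j = 0; j < L; ++j)
      alpha(t, j) = logsumexp(alpha.row(t - 1).t() + trans.submat(0, j, L - 1, j)) +
                    emissions(t, j);
  beta.row(T - 1) = trans.submat(0, E, L - 1, E).t();
  for (uword t = T - 1; t > 0; --t)
    for (uword i = 0; i < L; ++i)
      beta(t - 1, i) = logsumexp(beta.row(t).t() + trans.submat(i, 0, i, L - 1).t() +
                                 emissions.row(t).t());
  double logZ = logsumexp(alpha.row(T - 1).t() + trans.submat(0, E, L - 1, E));

  mat d_emis(T, L);
  for (uword t = 0; t < T; ++t)
    for (uword j = 0; j < L; ++j)
      d_emis(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);

  mat d_trans(L + 2, L + 2, arma::fill::zeros);
  // start and stop expectations
  for (uword j = 0; j < L; ++j) {
    d_trans(S, j) += std::exp(trans(S, j) + emissions(0, j) + beta(0, j) - logZ);
    d_trans(j, E) += std::exp(alpha(T - 1, j) + trans(j, E) - logZ);
  }
  for (uword t = 0; t + 1 < T; ++t)
    for (uword i = 0; i < L; ++i)
      for (uword j = 0; j < L; ++j)
        d_trans(i, j) += std::exp(alpha(t, i) + trans(i, j) +
                                  emissions(t + 1, j) + beta(t + 1, j) - logZ);

  // subtract observed
  d_emis(0, (uword)labels(0)) -= 0.0; // placeholder for clarity
  for (uword t = 0; t < T; ++t) d_emis(t, (uword)labels(t)) -= 1.0;
  d_trans(S, (uword)labels(0)) -= 1.0;
  for (uword t = 1; t < T; ++t) d_trans((uword)labels(t - 1), (uword)labels(t)) -= 1.0;
  d_trans((uword)labels(T - 1), E) -= 1.0;

  double nll = logZ - crf_path_score_(emissions, labels, trans);
  return List::create(_["d_emissions"] = d_emis, _["d_trans"] = d_trans,
                      _["nll"] = nll);
}

// [[Rcpp::export]]
List cpp_crf_viterbi(const arma::mat& emissions, const arma::mat& trans) {
  const uword T = emissions.n_rows, L = emissions.n_cols;
  const uword S = L, E = L + 1;
  mat delta(T, L);
  arma::umat bp(T, L, arma::fill::zeros);
  delta.row(0) = trans.submat(S, 0, S, L - 1) + emissions.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword j = 0; j < L; ++j) {
      double best = -arma::datum::inf;
      uword arg = 0;
      for (uword i = 0; i < L; ++i) {
        double s = delta(t - 1, i) + trans(i, j);
        if (s > best) { best = s; arg = i; }   // strict > keeps lowest index on ties
      }
      delta(t, j) = best + emissions(t, j);
      bp(t, j) = arg;
    }
  }
  double best = -arma::datum::inf;
  uword arg = 0;
  for (uword j = 0; j < L; ++j) {
    double s = delta(T - 1, j) + trans(j, E);
    if (s > best) { best = s; arg = j; }
  }
  arma::ivec path(T);
  path(T - 1) = (int)arg;
  for (uword t = T - 1; t > 0; --t) path(t - 1) = (int)bp(t, (uword)path(t));
  return List::create(_["path"] = path, _["score"] = best);
}

// ---------------------------------------------------------------------------
// Recurrent layers (LSTM or plain tanh RNN), with BPTT
// ---------------------------------------------------------------------------

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct RecurCache {
  mat X;            // D x T inputs as seen (already in processing order)
  mat I, F, G, O;   // gates (lstm)
  mat A;            // pre-activation (rnn)
  mat C, H;         // cell (lstm) and hidden states, H x T in processing order
};

// Forward pass over X (D x T). If reverse, processes columns T-1..0 but the
// returned Hout column t still corresponds to input position t.
static void recur_forward(const mat& W, const mat& U, const vec& b,
                          const mat& X, bool lstm, bool reverse,
                          mat& Hout, RecurCache& cc) {
  const uword T = X.n_cols;
  const uword Hn = U.n_cols;
  cc.X.set_size(X.n_rows, T);
  cc.H.set_size(Hn, T);
  if (lstm) {
    cc.I.set_size(Hn, T); cc.F.set_size(Hn, T);
    cc.G.set_size(Hn, T); cc.O.set_size(Hn, T); cc.C.set_size(Hn, T);
  } else {
    cc.A.set_size(Hn, T);
  }
  vec h(Hn, arma::fill::zeros), c(Hn, arma::fill::zeros);
  Hout.set_size(Hn, T);
  for (uword k = 0; k < T; ++k) {
    uword t = reverse ? (T - 1 - k) : k;
    vec x = X.col(t);
    cc.X.col(k) = x;
    if (lstm) {
      vec a = W * x + U * h + b;
      vec i = sigm(a.subvec(0, Hn - 1));
      vec f = sigm(a.subvec(Hn, 2 * Hn - 1));
      vec g = arma::tanh(a.subvec(2 * Hn, 3 * Hn - 1));
      vec o = sigm(a.subvec(3 * Hn, 4 * Hn - 1));
      c = f % c + i % g;
      h = o % arma::tanh(c);
      cc.I.col(k) = i; cc.F.col(k) = f; cc.G.col(k) = g; cc.O.col(k) = o;
      cc.C.col(k) = c;
    } else {
      vec a = W * x + U * h + b;
      h = arma::tanh(a);
      cc.A.col(k) = a;
    }
    cc.H.col(k) = h;
    Hout.col(t) = h;
  }
}

// Backward pass; dHout is H x T indexed by input position. Accumulates into
// dW,dU,db and returns dX (indexed by input position).
static void recur_backward(const mat& W, const mat& U, const mat& dHout,
                           bool lstm, bool reverse, const RecurCache& cc,
                           mat& dW, mat& dU, vec& db, mat& dX) {
  const uword T = cc.X.n_cols;
  const uword Hn = U.n_cols;
  dX.zeros(cc.X.n_rows, T);
  vec dh_next(Hn, arma::fill::zeros), dc_next(Hn, arma::fill::zeros);
  for (uword k = T; k-- > 0;) {
    uword t = reverse ? (T - 1 - k) : k;
    vec dh = dHout.col(t) + dh_next;
    vec hprev = (k == 0) ? vec(Hn, arma::fill::zeros) : vec(cc.H.col(k - 1));
    vec da;
    if (lstm) {
      vec i = cc.I.col(k), f = cc.F.col(k), g = cc.G.col(k), o = cc.O.col(k);
      vec c = cc.C.col(k);
      vec cprev = (k == 0) ? vec(Hn, arma::fill::zeros) : vec(cc.C.col(k - 1));
      vec tc = arma::tanh(c);
      vec dc = dc_next + dh % o % (1.0 - tc % tc);
      vec da_o = (dh % tc) % o % (1.0 - o);
      vec da_i = (dc % g) % i % (1.0 - i);
      vec da_g = (dc % i) % (1.0 - g % g);
      vec da_f = (dc % cprev) % f % (1.0 - f);
      dc_next = dc % f;
      da = arma::join_cols(arma::join_cols(da_i, da_f), arma::join_cols(da_g, da_o));
    } else {
      vec h = cc.H.col(k);
      da = dh % (1.0 - h % h);
      dc_next.zeros();
    }
    dW += da * cc.X.col(k).t();
    dU += da * hprev.t();
    db += da;
    dX.col(t) += W.t() * da;
    dh_next = U.t() * da;
  }
}

// ---------------------------------------------------------------------------
// Full tagger: char BiRNN -> token BiRNN -> projection -> CRF
// ---------------------------------------------------------------------------

struct NoteInput {
  mat emb;                       // De x T pretrained embeddings
  std::vector<arma::uvec> chars; // per-token 0-based char indices
  mat feats;                     // 6 x T casing/spacing features
};

static NoteInput unpack_note(const List& note) {
  NoteInput ni;
  ni.emb = as<mat>(note["emb"]);
  ni.feats = as<mat>(note["feats"]);
  List ch = note["chars"];
  ni.chars.resize(ch.size());
  for (int k = 0; k < ch.size(); ++k) {
    IntegerVector v = ch[k];
    arma::uvec u(v.size());
    for (int j = 0; j < v.size(); ++j) u(j) = (uword)v[j];
    ni.chars[k] = u;
  }
  return ni;
}

struct NoteFwd {
  mat Xin;                 // Din x T concatenated input (after dropout)
  mat M1;                  // input dropout mask
  mat Hf, Hb;              // token-level hidden states
  RecurCache ctf, ctb;     // token-level caches
  mat Ctx;                 // 2Ht x T context after dropout
  mat M2;                  // context dropout mask
  mat emis;                // T x L
  // char level caches, one per token
  std::vector<RecurCache> ccf, ccb;
  std::vector<mat> Hcf, Hcb;
};

static mat dropout_mask(uword r, uword c, double p) {
  mat m(r, c);
  if (p <= 0.0) { m.ones(); return m; }
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i)
      m(i, j) = (unif_rand() >= p) ? 1.0 / (1.0 - p) : 0.0;
  return m;
}

static void note_forward(const List& P, const NoteInput& ni, bool lstm,
                         double dropout, NoteFwd& fw) {
  const mat C_emb = as<mat>(P["C_emb"]);
  const mat Wc_f = as<mat>(P["Wc_f"]), Uc_f = as<mat>(P["Uc_f"]);
  const vec bc_f = as<vec>(P["bc_f"]);
  const mat Wc_b = as<mat>(P["Wc_b"]), Uc_b = as<mat>(P["Uc_b"]);
  const vec bc_b = as<vec>(P["bc_b"]);
  const mat Pc = as<mat>(P["Pc"]); const vec pc = as<vec>(P["pc"]);
  const mat Wt_f = as<mat>(P["Wt_f"]), Ut_f = as<mat>(P["Ut_f"]);
  const vec bt_f = as<vec>(P["bt_f"]);
  const mat Wt_b = as<mat>(P["Wt_b"]), Ut_b = as<mat>(P["Ut_b"]);
  const vec bt_b = as<vec>(P["bt_b"]);
  const mat Wo = as<mat>(P["Wo"]); const vec bo = as<vec>(P["bo"]);

  const uword T = ni.emb.n_cols;
  const uword Hc = Uc_f.n_cols;
  const uword Dch = Pc.n_rows;

  // char encodings
  mat charout(Dch, T);
  fw.ccf.resize(T); fw.ccb.resize(T); fw.Hcf.resize(T); fw.Hcb.resize(T);
  for (uword t = 0; t < T; ++t) {
    mat Xc = C_emb.cols(ni.chars[t]);
    recur_forward(Wc_f, Uc_f, bc_f, Xc, lstm, false, fw.Hcf[t], fw.ccf[t]);
    recur_forward(Wc_b, Uc_b, bc_b, Xc, lstm, true, fw.Hcb[t], fw.ccb[t]);
    vec cat = arma::join_cols(fw.Hcf[t].col(Xc.n_cols - 1), fw.Hcb[t].col(0));
    charout.col(t) = Pc * cat + pc;
  }

  mat Xin = arma::join_cols(arma::join_cols(ni.emb, charout), ni.feats);
  fw.M1 = dropout_mask(Xin.n_rows, T, dropout);
  fw.Xin = Xin % fw.M1;

  recur_forward(Wt_f, Ut_f, bt_f, fw.Xin, lstm, false, fw.Hf, fw.ctf);
  recur_forward(Wt_b, Ut_b, bt_b, fw.Xin, lstm, true, fw.Hb, fw.ctb);
  mat ctx = arma::join_cols(fw.Hf, fw.Hb);
  fw.M2 = dropout_mask(ctx.n_rows, T, dropout);
  fw.Ctx = ctx % fw.M2;
  fw.emis = (Wo * fw.Ctx).t();
  fw.emis.each_row() += bo.t();
}

// emissions; dropout > 0 draws masks from the R RNG (training diagnostics)
// [[Rcpp::export]]
arma::mat cpp_emissions(const List& params, const List& note, bool lstm,
                        double dropout = 0.0) {
  NoteInput ni = unpack_note(note);
  if (ni.emb.n_cols == 0) stop("empty token sequence");
  NoteFwd fw;
  note_forward(params, ni, lstm, dropout, fw);
  return fw.emis;
}

// char-level encoding of a single token (char index vector, 0-based)
// [[Rcpp::export]]
arma::vec cpp_char_encode(const List& params, const IntegerVector& chars,
                          bool lstm) {
  if (chars.size() == 0) stop("empty character sequence");
  const mat C_emb = as<mat>(params["C_emb"]);
  arma::uvec idx(chars.size());
  for (int j = 0; j < chars.size(); ++j) idx(j) = (uword)chars[j];
  mat Xc = C_emb.cols(idx);
  mat Hf, Hb;
  RecurCache cf, cb;
  recur_forward(as<mat>(params["Wc_f"]), as<mat>(params["Uc_f"]),
                as<vec>(params["bc_f"]), Xc, lstm, false, Hf, cf);
  recur_forward(as<mat>(params["Wc_b"]), as<mat>(params["Uc_b"]),
                as<vec>(params["bc_b"]), Xc, lstm, true, Hb, cb);
  vec cat = arma::join_cols(Hf.col(Xc.n_cols - 1), Hb.col(0));
  return as<mat>(params["Pc"]) * cat + as<vec>(params["pc"]);
}

// One-note loss and parameter gradients (accumulated into `grads`, a list of
// preallocated matrices matching `params`). Returns the NLL; if train_emb,
// writes d(embedding input) into demb (De x T).
static double note_grad(const List& P, List& G, const NoteInput& ni,
                        const arma::ivec& labels, bool lstm, double dropout,
                        bool train_emb, mat& demb) {
  NoteFwd fw;
  note_forward(P, ni, lstm, dropout, fw);

  List cg = cpp_crf_grad(fw.emis, labels, as<mat>(P["trans"]));
  mat d_emis = as<mat>(cg["d_emissions"]);
  double nll = as<double>(cg["nll"]);
  { mat dtr = as<mat>(G["trans"]); dtr += as<mat>(cg["d_trans"]);
    G["trans"] = dtr; }

  const mat Wo = as<mat>(P["Wo"]);
  mat dE = d_emis.t();                       // L x T
  { mat dWo = as<mat>(G["Wo"]); dWo += dE * fw.Ctx.t(); G["Wo"] = dWo; }
  { vec dbo = as<vec>(G["bo"]); dbo += arma::sum(dE, 1); G["bo"] = dbo; }
  mat dCtx = (Wo.t() * dE) % fw.M2;          // 2Ht x T

  const uword Ht = as<mat>(P["Ut_f"]).n_cols;
  mat dHf = dCtx.rows(0, Ht - 1);
  mat dHb = dCtx.rows(Ht, 2 * Ht - 1);

  mat dWt_f = as<mat>(G["Wt_f"]), dUt_f = as<mat>(G["Ut_f"]);
  vec dbt_f = as<vec>(G["bt_f"]);
  mat dWt_b = as<mat>(G["Wt_b"]), dUt_b = as<mat>(G["Ut_b"]);
  vec dbt_b = as<vec>(G["bt_b"]);
  mat dX1, dX2;
  recur_backward(as<mat>(P["Wt_f"]), as<mat>(P["Ut_f"]), dHf, lstm, false,
                 fw.ctf, dWt_f, dUt_f, dbt_f, dX1);
  recur_backward(as<mat>(P["Wt_b"]), as<mat>(P["Ut_b"]), dHb, lstm, true,
                 fw.ctb, dWt_b, dUt_b, dbt_b, dX2);
  G["Wt_f"] = dWt_f; G["Ut_f"] = dUt_f; G["bt_f"] = dbt_f;
  G["Wt_b"] = dWt_b; G["Ut_b"] = dUt_b; G["bt_b"] = dbt_b;

  mat dXin = (dX1 + dX2) % fw.M1;
  const uword De = ni.emb.n_rows;
  const mat Pc = as<mat>(P["Pc"]);
  const uword Dch = Pc.n_rows;
  if (train_emb) demb = dXin.rows(0, De - 1);
  mat dCharout = dXin.rows(De, De + Dch - 1);

  mat dPc = as<mat>(G["Pc"]); vec dpc = as<vec>(G["pc"]);
  mat dWc_f = as<mat>(G["Wc_f"]), dUc_f = as<mat>(G["Uc_f"]);
  vec dbc_f = as<vec>(G["bc_f"]);
  mat dWc_b = as<mat>(G["Wc_b"]), dUc_b = as<mat>(G["Uc_b"]);
  vec dbc_b = as<vec>(G["bc_b"]);
  mat dCemb = as<mat>(G["C_emb"]);
  const uword Hcn = as<mat>(P["Uc_f"]).n_cols;
  const uword T = ni.emb.n_cols;

  for (uword t = 0; t < T; ++t) {
    const uword n = fw.Hcf[t].n_cols;
    vec dcat = Pc.t() * dCharout.col(t);
    vec catv = arma::join_cols(fw.Hcf[t].col(n - 1), fw.Hcb[t].col(0));
    dPc += dCharout.col(t) * catv.t();
    dpc += dCharout.col(t);
    mat dHcf(Hcn, n, arma::fill::zeros), dHcb(Hcn, n, arma::fill::zeros);
    dHcf.col(n - 1) = dcat.subvec(0, Hcn - 1);
    dHcb.col(0) = dcat.subvec(Hcn, 2 * Hcn - 1);
    mat dXc1, dXc2;
    recur_backward(as<mat>(P["Wc_f"]), as<mat>(P["Uc_f"]), dHcf, lstm, false,
                   fw.ccf[t], dWc_f, dUc_f, dbc_f, dXc1);
    recur_backward(as<mat>(P["Wc_b"]), as<mat>(P["Uc_b"]), dHcb, lstm, true,
                   fw.ccb[t], dWc_b, dUc_b, dbc_b, dXc2);
    mat dXc = dXc1 + dXc2;
    for (uword j = 0; j < n; ++j) dCemb.col(ni.chars[t](j)) += dXc.col(j);
  }
  G["Pc"] = dPc; G["pc"] = dpc;
  G["Wc_f"] = dWc_f; G["Uc_f"] = dUc_f; G["bc_f"] = dbc_f;
  G["Wc_b"] = dWc_b; G["Uc_b"] = dUc_b; G["bc_b"] = dbc_b;
  G["C_emb"] = dCemb;
  return nll;
}

// Mean loss and summed gradients over a batch of notes.
// notes: list of List(emb, chars, feats, labels)
// [[Rcpp::export]]
List cpp_batch_grad(const List& params, const List& notes, bool lstm,
                    double dropout, bool train_emb) {
  CharacterVector nm = params.names();
  List G(params.size());
  G.names() = nm;
  for (int i = 0; i < params.size(); ++i) {
    SEXP p = params[i];
    if (Rf_isMatrix(p)) {
      mat m = as<mat>(p); G[i] = mat(m.n_rows, m.n_cols, arma::fill::zeros);
    } else {
      vec v = as<vec>(p); G[i] = vec(v.n_elem, arma::fill::zeros);
    }
  }
  double total = 0.0;
  List dembs(notes.size());
  for (int i = 0; i < notes.size(); ++i) {
    List note = notes[i];
    NoteInput ni = unpack_note(note);
    arma::ivec labels = as<arma::ivec>(note["labels"]);
    mat demb;
    total += note_grad(params, G, ni, labels, lstm, dropout, train_emb, demb);
    if (train_emb) dembs[i] = demb;
  }
  double n = (double)notes.size();
  for (int i = 0; i < G.size(); ++i) {
    if (Rf_isMatrix((SEXP)G[i])) { mat m = as<mat>(G[i]); m /= n; G[i] = m; }
    else { vec v = as<vec>(G[i]); v /= n; G[i] = v; }
  }
  return List::create(_["loss"] = total / n, _["grads"] = G,
                      _["demb"] = dembs);
}

// ---------------------------------------------------------------------------
// Skip-gram with negative sampling (single-threaded, R RNG)
// ---------------------------------------------------------------------------

// sentences: list of 0-based integer vectors; counts: vocab frequencies
// [[Rcpp::export]]
arma::mat cpp_skipgram(const List& sentences, const arma::vec& counts,
                       int dim, int window, int negative, int epochs,
                       double lr0) {
  const uword V = counts.n_elem;
  // unigram^(3/4) table for negative sampling
  vec probs = arma::pow(counts, 0.75);
  vec cum = arma::cumsum(probs / arma::accu(probs));
  auto draw_neg = [&]() -> uword {
    double u = unif_rand();
    uword lo = 0, hi = V - 1;
    while (lo < hi) { uword mid = (lo + hi) / 2; if (cum(mid) < u) lo = mid + 1; else hi = mid; }
    return lo;
  };
  mat Win(dim, V), Wout(dim, V, arma::fill::zeros);
  for (uword j = 0; j < V; ++j)
    for (int d = 0; d < dim; ++d)
      Win(d, j) = (unif_rand() - 0.5) / dim;

  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += ((IntegerVector)sentences[s]).size();
  long long seen = 0;
  const long long budget = total_tokens * (long long)epochs;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int n = sent.size();
      for (int t = 0; t < n; ++t, ++seen) {
        double lr = lr0 * std::max(1.0 - (double)seen / (double)budget, 1e-4);
        int b = 1 + (int)(unif_rand() * window);
        if (b > window) b = window;
        uword center = (uword)sent[t];
        for (int c = t - b; c <= t + b; ++c) {
          if (c < 0 || c >= n || c == t) continue;
          uword ctx = (uword)sent[c];
          vec vin = Win.col(center);
          vec gin(dim, arma::fill::zeros);
          for (int k = 0; k <= negative; ++k) {
            uword target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = draw_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = arma::dot(vin, Wout.col(target));
            double g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
            gin += g * Wout.col(target);
            Wout.col(target) += g * vin;
          }
          Win.col(center) += gin;
        }
      }
    }
  }
  return Win;
}

// Gradient check helper: loss only for a single note (used in tests).
// [[Rcpp::export]]
double cpp_note_loss(const List& params, const List& note, bool lstm) {
  NoteInput ni = unpack_note(note);
  NoteFwd fw;
  note_forward(params, ni, lstm, 0.0, fw);
  return -cpp_crf_loglik(fw.emis, as<arma::ivec>(note["labels"]),
                         as<mat>(params["trans"]));
}
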