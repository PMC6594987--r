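// BiLSTM-CRF sequence tagger with character-level word representations.
//
// Architecture: per word, a character BiLSTM produces the concatenation of
// the two final hidden states; this is concatenated with the word embedding,
// passed through (inverted) dropout, then a word-level BiLSTM, a linear
// projection to per-label emissions, and a linear-chain CRF layer whose
// negative log-likelihood is the training loss. Optimized with Adam plus
// weight decay. All randomness (init, dropout masks, shuffling) flows from
// one seeded Mersenne Twister, so runs are reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Cemb;                       // d_c x n_chars
  mat cf_W, cf_U; vec cf_b;       // char LSTM forward
  mat cb_W, cb_U; vec cb_b;       // char LSTM backward
  mat Wemb;                       // d_w x n_words
  mat wf_W, wf_U; vec wf_b;       // word LSTM forward
  mat wb_W, wb_U; vec wb_b;       // word LSTM backward
  mat out_W; vec out_b;           // 2*h_w -> L
  mat crf_trans; vec crf_init;    // L x L, L

  std::vector<mat*> mats() {
    return {&Cemb, &cf_W, &cf_U, &cb_W, &cb_U, &Wemb,
            &wf_W, &wf_U, &wb_W, &wb_U, &out_W, &crf_trans};
  }
  std::vector<vec*> vecs() {
    return {&cf_b, &cb_b, &wf_b, &wb_b, &out_b, &crf_init};
  }
};

Params from_list(const Rcpp::List& l) {
  Params p;
  p.Cemb = Rcpp::as<mat>(l["Cemb"]);
  p.cf_W = Rcpp::as<mat>(l["cf_W"]); p.cf_U = Rcpp::as<mat>(l["cf_U"]);
  p.cf_b = Rcpp::as<vec>(l["cf_b"]);
  p.cb_W = Rcpp::as<mat>(l["cb_W"]); p.cb_U = Rcpp::as<mat>(l["cb_U"]);
  p.cb_b = Rcpp::as<vec>(l["cb_b"]);
  p.Wemb = Rcpp::as<mat>(l["Wemb"]);
  p.wf_W = Rcpp::as<mat>(l["wf_W"]); p.wf_U = Rcpp::as<mat>(l["wf_U"]);
  p.wf_b = Rcpp::as<vec>(l["wf_b"]);
  p.wb_W = Rcpp::as<mat>(l["wb_W"]); p.wb_U = Rcpp::as<mat>(l["wb_U"]);
  p.wb_b = Rcpp::as<vec>(l["wb_b"]);
  p.out_W = Rcpp::as<mat>(l["out_W"]); p.out_b = Rcpp::as<vec>(l["out_b"]);
  p.crf_trans = Rcpp::as<mat>(l["crf_trans"]);
  p.crf_init = Rcpp::as<vec>(l["crf_init"]);
  return p;
}

Rcpp::List to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("Cemb") = p.Cemb,
    Rcpp::Named("cf_W") = p.cf_W, Rcpp::Named("cf_U") = p.cf_U,
    Rcpp::Named("cf_b") = p.cf_b,
    Rcpp::Named("cb_W") = p.cb_W, Rcpp::Named("cb_U") = p.cb_U,
    Rcpp::Named("cb_b") = p.cb_b,
    Rcpp::Named("Wemb") = p.Wemb,
    Rcpp::Named("wf_W") = p.wf_W, Rcpp::Named("wf_U") = p.wf_U,
    Rcpp::Named("wf_b") = p.wf_b,
    Rcpp::Named("wb_W") = p.wb_W, Rcpp::Named("wb_U") = p.wb_U,
    Rcpp::Named("wb_b") = p.wb_b,
    Rcpp::Named("out_W") = p.out_W, Rcpp::Named("out_b") = p.out_b,
    Rcpp::Named("crf_trans") = p.crf_trans,
    Rcpp::Named("crf_init") = p.crf_init);
}

Params zeros_like(const Params& p) {
  Params g = p;
  for (mat* m : g.mats()) m->zeros();
  for (vec* v : g.vecs()) v->zeros();
  return g;
}

// ---- LSTM -------------------------------------------------------------

struct LSTMCache {
  mat X;             // d x T inputs
  mat i, f, o, g, c, h;  // h x T activations
};

LSTMCache lstm_forward(const mat& W, const mat& U, const vec& b, const mat& X) {
  const uword H = U.n_cols, T = X.n_cols;
  LSTMCache cc;
  cc.X = X;
  cc.i.set_size(H, T); cc.f.set_size(H, T); cc.o.set_size(H, T);
  cc.g.set_size(H, T); cc.c.set_size(H, T); cc.h.set_size(H, T);
  vec hprev(H, fill::zeros), cprev(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec a = W * X.col(t) + U * hprev + b;
    vec ig = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
    vec fg = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
    vec og = 1.0 / (1.0 + exp(-a.subvec(2 * H, 3 * H - 1)));
    vec gg = tanh(a.subvec(3 * H, 4 * H - 1));
    vec ct = fg % cprev + ig % gg;
    vec ht = og % tanh(ct);
    cc.i.col(t) = ig; cc.f.col(t) = fg; cc.o.col(t) = og; cc.g.col(t) = gg;
    cc.c.col(t) = ct; cc.h.col(t) = ht;
    hprev = ht; cprev = ct;
  }
  return cc;
}

// dH: h x T upstream gradient on every h_t. Accumulates into dW,dU,db;
// returns dX (d x T).
mat lstm_backward(const mat& W, const mat& U, const LSTMCache& cc,
                  const mat& dH, mat& dW, mat& dU, vec& db) {
  const uword H = U.n_cols, T = cc.X.n_cols, D = cc.X.n_rows;
  mat dX(D, T, fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    vec dh = dH.col(tt) + dh_next;
    vec tc = tanh(cc.c.col(tt));
    vec dov = dh % tc;
    vec dc = dc_next + dh % cc.o.col(tt) % (1.0 - tc % tc);
    vec cprev = (tt == 0) ? vec(H, fill::zeros) : vec(cc.c.col(tt - 1));
    vec div = dc % cc.g.col(tt);
    vec dgv = dc % cc.i.col(tt);
    vec dfv = dc % cprev;
    dc_next = dc % cc.f.col(tt);
    vec da(4 * H);
    da.subvec(0, H - 1)          = div % cc.i.col(tt) % (1.0 - cc.i.col(tt));
    da.subvec(H, 2 * H - 1)      = dfv % cc.f.col(tt) % (1.0 - cc.f.col(tt));
    da.subvec(2 * H, 3 * H - 1)  = dov % cc.o.col(tt) % (1.0 - cc.o.col(tt));
    da.subvec(3 * H, 4 * H - 1)  = dgv % (1.0 - cc.g.col(tt) % cc.g.col(tt));
    vec hprev = (tt == 0) ? vec(H, fill::zeros) : vec(cc.h.col(tt - 1));
    dW += da * cc.X.col(tt).t();
    dU += da * hprev.t();
    db += da;
    dX.col(tt) = W.t() * da;
    dh_next = U.t() * da;
  }
  return dX;
}

// ---- CRF layer --------------------------------------------------------

double logsumexp(const vec& v) {
  double m = v.max();
  return m + std::log(accu(exp(v - m)));
}

// E: L x T emissions. Returns logZ; fills alpha, beta.
double crf_forward_backward(const mat& E, const mat& trans, const vec& init,
                            mat& alpha, mat& beta) {
  const uword L = E.n_rows, T = E.n_cols;
  alpha.set_size(L, T); beta.set_size(L, T);
  alpha.col(0) = init + E.col(0);
  for (uword t = 1; t < T; ++t)
    for (uword y = 0; y < L; ++y)
      alpha(y, t) = E(y, t) + logsumexp(alpha.col(t - 1) + trans.col(y));
  beta.col(T - 1).zeros();
  for (uword t = T - 1; t-- > 0;)
    for (uword y = 0; y < L; ++y)
      beta(y, t) = logsumexp(trans.row(y).t() + E.col(t + 1) + beta.col(t + 1));
  return logsumexp(alpha.col(T - 1));
}

double crf_path_score(const mat& E, const mat& trans, const vec& init,
                      const std::vector<int>& y) {
  double s = init(y[0]) + E(y[0], 0);
  for (size_t t = 1; t < y.size(); ++t)
    s += trans(y[t - 1], y[t]) + E(y[t], t);
  return s;
}

// loss and gradients w.r.t. emissions / transitions / init
double crf_loss_grad(const mat& E, const mat& trans, const vec& init,
                     const std::vector<int>& y, mat& dE, mat& dtrans,
                     vec& dinit) {
  const uword L = E.n_rows, T = E.n_cols;
  mat alpha, beta;
  double logZ = crf_forward_backward(E, trans, init, alpha, beta);
  mat M = exp(alpha + beta - logZ);  // node marginals
  dE = M;
  for (uword t = 0; t < T; ++t) dE(y[t], t) -= 1.0;
  dinit += M.col(0);
  dinit(y[0]) -= 1.0;
  for (uword t = 1; t < T; ++t) {
    for (uword a = 0; a < L; ++a)
      for (uword b2 = 0; b2 < L; ++b2)
        dtrans(a, b2) += std::exp(alpha(a, t - 1) + trans(a, b2) + E(b2, t) +
                                  beta(b2, t) - logZ);
    dtrans(y[t - 1], y[t]) -= 1.0;
  }
  return logZ - crf_path_score(E, trans, init, y);
}

std::vector<int> crf_viterbi(const mat& E, const mat& trans, const vec& init) {
  const uword L = E.n_rows, T = E.n_cols;
  mat delta(L, T);
  umat back(L, T);
  delta.col(0) = init + E.col(0);
  for (uword t = 1; t < T; ++t) {
    for (uword y = 0; y < L; ++y) {
      vec cand = delta.col(t - 1) + trans.col(y);
      uword best = 0;
      for (uword a = 1; a < L; ++a) if (cand(a) > cand(best)) best = a;
      delta(y, t) = cand(best) + E(y, t);
      back(y, t) = best;
    }
  }
  uword last = 0;
  for (uword y = 1; y < L; ++y) if (delta(y, T - 1) > delta(last, T - 1)) last = y;
  std::vector<int> path(T);
  path[T - 1] = (int)last;
  for (uword t = T - 1; t-- > 0;) {
    last = back(last, t + 1);
    path[t] = (int)last;
  }
  return path;
}

// ---- per-sentence forward/backward ------------------------------------

struct Sentence {
  std::vector<int> words;                 // 0-based word ids
  std::vector<std::vector<int>> chars;    // per word, 0-based char ids
  std::vector<int> labels;                // 0-based label ids
};

struct FwdCache {
  std::vector<LSTMCache> cf, cb;   // char LSTMs per word
  mat Xcat;        // D x T concatenated word representation (pre-dropout)
  mat mask;        // D x T effective dropout mask (already scaled)
  LSTMCache wf, wb;
  mat H2;          // 2*h_w x T
  mat E;           // L x T emissions
};

void forward_sentence(const Params& p, const Sentence& s, double dropout,
                      std::mt19937_64* rng, FwdCache& fc) {
  const uword T = s.words.size();
  const uword d_w = p.Wemb.n_rows, h_c = p.cf_U.n_cols, h_w = p.wf_U.n_cols;
  const uword D = d_w + 2 * h_c;
  fc.cf.resize(T); fc.cb.resize(T);
  fc.Xcat.set_size(D, T);
  for (uword t = 0; t < T; ++t) {
    const std::vector<int>& cs = s.chars[t];
    mat C(p.Cemb.n_rows, cs.size());
    for (size_t k = 0; k < cs.size(); ++k) C.col(k) = p.Cemb.col(cs[k]);
    mat Crev = fliplr(C);
    fc.cf[t] = lstm_forward(p.cf_W, p.cf_U, p.cf_b, C);
    fc.cb[t] = lstm_forward(p.cb_W, p.cb_U, p.cb_b, Crev);
    fc.Xcat.col(t).subvec(0, d_w - 1) = p.Wemb.col(s.words[t]);
    fc.Xcat.col(t).subvec(d_w, d_w + h_c - 1) = fc.cf[t].h.col(cs.size() - 1);
    fc.Xcat.col(t).subvec(d_w + h_c, D - 1) = fc.cb[t].h.col(cs.size() - 1);
  }
  if (dropout > 0.0 && rng != nullptr) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    fc.mask.set_size(D, T);
    const double keep = 1.0 - dropout;
    for (uword j = 0; j < T; ++j)
      for (uword i2 = 0; i2 < D; ++i2)
        fc.mask(i2, j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
  } else {
    fc.mask = mat(D, T, fill::ones);
  }
  mat Xdrop = fc.Xcat % fc.mask;
  fc.wf = lstm_forward(p.wf_W, p.wf_U, p.wf_b, Xdrop);
  fc.wb = lstm_forward(p.wb_W, p.wb_U, p.wb_b, fliplr(Xdrop));
  fc.H2.set_size(2 * h_w, T);
  fc.H2.rows(0, h_w - 1) = fc.wf.h;
  fc.H2.rows(h_w, 2 * h_w - 1) = fliplr(fc.wb.h);
  fc.E = p.out_W * fc.H2;
  fc.E.each_col() += p.out_b;
}

double backward_sentence(const Params& p, const Sentence& s, FwdCache& fc,
                         Params& g) {
  const uword T = s.words.size();
  const uword d_w = p.Wemb.n_rows, h_c = p.cf_U.n_cols, h_w = p.wf_U.n_cols;
  const uword D = d_w + 2 * h_c;
  mat dE;
  double loss = crf_loss_grad(fc.E, p.crf_trans, p.crf_init, s.labels,
                              dE, g.crf_trans, g.crf_init);
  g.out_W += dE * fc.H2.t();
  g.out_b += sum(dE, 1);
  mat dH2 = p.out_W.t() * dE;          // 2*h_w x T
  mat dHf = dH2.rows(0, h_w - 1);
  mat dHb = fliplr(mat(dH2.rows(h_w, 2 * h_w - 1)));
  mat dXf = lstm_backward(p.wf_W, p.wf_U, fc.wf, dHf, g.wf_W, g.wf_U, g.wf_b);
  mat dXb = lstm_backward(p.wb_W, p.wb_U, fc.wb, dHb, g.wb_W, g.wb_U, g.wb_b);
  mat dXdrop = dXf + fliplr(dXb);
  mat dX = dXdrop % fc.mask;
  for (uword t = 0; t < T; ++t) {
    g.Wemb.col(s.words[t]) += dX.col(t).subvec(0, d_w - 1);
    const std::vector<int>& cs = s.chars[t];
    const uword Tc = cs.size();
    mat dHc(h_c, Tc, fill::zeros);
    dHc.col(Tc - 1) = dX.col(t).subvec(d_w, d_w + h_c - 1);
    mat dCf = lstm_backward(p.cf_W, p.cf_U, fc.cf[t], dHc,
                            g.cf_W, g.cf_U, g.cf_b);
    dHc.col(Tc - 1) = dX.col(t).subvec(d_w + h_c, D - 1);
    mat dCb = lstm_backward(p.cb_W, p.cb_U, fc.cb[t], dHc,
                            g.cb_W, g.cb_U, g.cb_b);
    mat dC = dCf + fliplr(dCb);
    for (size_t k = 0; k < cs.size(); ++k) g.Cemb.col(cs[k]) += dC.col(k);
  }
  return loss;
}

std::vector<Sentence> parse_sentences(const Rcpp::List& words,
                                      const Rcpp::List& chars,
                                      const Rcpp::List& labels) {
  std::vector<Sentence> out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    Rcpp::IntegerVector w = words[i];
    Rcpp::List cl = chars[i];
    Sentence s;
    for (int v : w) s.words.push_back(v - 1);
    for (R_xlen_t j = 0; j < cl.size(); ++j) {
      Rcpp::IntegerVector cv = cl[j];
      if (cv.size() == 0) Rcpp::stop("word with no characters");
      std::vector<int> cc;
      for (int v : cv) cc.push_back(v - 1);
      s.chars.push_back(cc);
    }
    if (labels.size() > 0) {
      Rcpp::IntegerVector lv = labels[i];
      for (int v : lv) s.labels.push_back(v - 1);
    }
    out[i] = s;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List nn_init_params_cpp(int n_words, int n_chars, int d_w, int d_c,
                              int h_c, int h_w, int n_labels, int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  auto rmat = [&](int r, int cN, double sd) {
    mat m(r, cN);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i2 = 0; i2 < m.n_rows; ++i2) m(i2, j) = sd * norm(rng);
    return m;
  };
  int D = d_w + 2 * h_c;
  Params p;
  p.Cemb = rmat(d_c, n_chars, 0.1);
  double sc = 1.0 / std::sqrt((double)d_c), su = 1.0 / std::sqrt((double)h_c);
  p.cf_W = rmat(4 * h_c, d_c, sc); p.cf_U = rmat(4 * h_c, h_c, su);
  p.cf_b = vec(4 * h_c, fill::zeros);
  p.cb_W = rmat(4 * h_c, d_c, sc); p.cb_U = rmat(4 * h_c, h_c, su);
  p.cb_b = vec(4 * h_c, fill::zeros);
  p.Wemb = rmat(d_w, n_words, 0.1);
  double sw = 1.0 / std::sqrt((double)D), swu = 1.0 / std::sqrt((double)h_w);
  p.wf_W = rmat(4 * h_w, D, sw); p.wf_U = rmat(4 * h_w, h_w, swu);
  p.wf_b = vec(4 * h_w, fill::zeros);
  p.wb_W = rmat(4 * h_w, D, sw); p.wb_U = rmat(4 * h_w, h_w, swu);
  p.wb_b = vec(4 * h_w, fill::zeros);
  p.out_W = rmat(n_labels, 2 * h_w, 1.0 / std::sqrt(2.0 * h_w));
  p.out_b = vec(n_labels, fill::zeros);
  p.crf_trans = mat(n_labels, n_labels, fill::zeros);
  p.crf_init = vec(n_labels, fill::zeros);
  return to_list(p);
}

// [[Rcpp::export]]
Rcpp::List nn_loss_grad_cpp(const Rcpp::List& params, const Rcpp::List& words,
                            const Rcpp::List& chars, const Rcpp::List& labels,
                            double dropout, int drop_seed) {
  Params p = from_list(params);
  Params g = zeros_like(p);
  std::mt19937_64 rng(drop_seed);
  std::mt19937_64* rptr = dropout > 0 ? &rng : nullptr;
  std::vector<Sentence> sents = parse_sentences(words, chars, labels);
  double loss = 0.0;
  for (const Sentence& s : sents) {
    if (s.words.empty()) continue;
    FwdCache fc;
    forward_sentence(p, s, dropout, rptr, fc);
    loss += backward_sentence(p, s, fc, g);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = to_list(g));
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(const Rcpp::List& params, const Rcpp::List& words,
                        const Rcpp::List& chars, const Rcpp::List& labels,
                        const Rcpp::List& config) {
  Params p = from_list(params);
  const int epochs = Rcpp::as<int>(config["epochs"]);
  const int batch = Rcpp::as<int>(config["batch"]);
  const double lr = Rcpp::as<double>(config["learning_rate"]);
  const double wd = Rcpp::as<double>(config["weight_decay"]);
  const double dropout = Rcpp::as<double>(config["dropout"]);
  const int seed = Rcpp::as<int>(config["seed"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<Sentence> sents = parse_sentences(words, chars, labels);
  std::mt19937_64 rng(seed);
  Params m = zeros_like(p), v = zeros_like(p);
  long step = 0;
  std::vector<size_t> order(sents.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;
  Rcpp::NumericVector epoch_losses(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (size_t start = 0; start < order.size(); start += batch) {
      Params g = zeros_like(p);
      size_t stop = std::min(order.size(), start + batch);
      for (size_t k = start; k < stop; ++k) {
        const Sentence& s = sents[order[k]];
        if (s.words.empty()) continue;
        FwdCache fc;
        forward_sentence(p, s, dropout, &rng, fc);
        total += backward_sentence(p, s, fc, g);
      }
      // weight decay is added to the raw gradient before the Adam update
      ++step;
      double corr1 = 1.0 - std::pow(b1, (double)step);
      double corr2 = 1.0 - std::pow(b2, (double)step);
      auto pm = p.mats(); auto gm = g.mats(); auto mm = m.mats(); auto vm = v.mats();
      for (size_t i = 0; i < pm.size(); ++i) {
        mat gg = *gm[i] + wd * (*pm[i]);
        *mm[i] = b1 * (*mm[i]) + (1 - b1) * gg;
        *vm[i] = b2 * (*vm[i]) + (1 - b2) * (gg % gg);
        *pm[i] -= lr * ((*mm[i]) / corr1) / (sqrt((*vm[i]) / corr2) + eps);
      }
      auto pv = p.vecs(); auto gv = g.vecs(); auto mv = m.vecs(); auto vv = v.vecs();
      for (size_t i = 0; i < pv.size(); ++i) {
        vec gg = *gv[i] + wd * (*pv[i]);
        *mv[i] = b1 * (*mv[i]) + (1 - b1) * gg;
        *vv[i] = b2 * (*vv[i]) + (1 - b2) * (gg % gg);
        *pv[i] -= lr * ((*mv[i]) / corr1) / (sqrt((*vv[i]) / corr2) + eps);
      }
      Rcpp::checkUserInterrupt();
    }
    epoch_losses[ep] = total;
  }
  return Rcpp::List::create(Rcpp::Named("params") = to_list(p),
                            Rcpp::Named("epoch_losses") = epoch_losses);
}

// [[Rcpp::export]]
Rcpp::List nn_forward_cpp(const Rcpp::List& params, const Rcpp::List& words,
                          const Rcpp::List& chars) {
  Params p = from_list(params);
  Rcpp::List empty;
  std::vector<Sentence> sents = parse_sentences(words, chars, empty);
  Rcpp::List out(sents.size());
  for (size_t i = 0; i < sents.size(); ++i) {
    FwdCache fc;
    forward_sentence(p, sents[i], 0.0, nullptr, fc);
    out[i] = Rcpp::List::create(Rcpp::Named("emissions") = fc.E.t(),
                                Rcpp::Named("repr") = fc.Xcat);
  }
  return Rcpp::List::create(Rcpp::Named("sentences") = out,
                            Rcpp::Named("trans") = p.crf_trans,
                            Rcpp::Named("init") = p.crf_init);
}

// [[Rcpp::export]]
Rcpp::List nn_predict_cpp(const Rcpp::List& params, const Rcpp::List& words,
                          const Rcpp::List& chars) {
  Params p = from_list(params);
  Rcpp::List empty;
  std::vector<Sentence> sents = parse_sentences(words, chars, empty);
  Rcpp::List out(sents.size());
  for (size_t i = 0; i < sents.size(); ++i) {
    if (sents[i].words.empty()) {
      out[i] = Rcpp::IntegerVector(0);
      continue;
    }
    FwdCache fc;
    forward_sentence(p, sents[i], 0.0, nullptr, fc);
    std::vector<int> path = crf_viterbi(fc.E, p.crf_trans, p.crf_init);
    Rcpp::IntegerVector lv(path.size());
    for (size_t t = 0; t < path.size(); ++t) lv[t] = path[t] + 1;
    out[i] = lv;
  }
  return out;
}
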