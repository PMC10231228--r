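// Training core of the hierarchical attention network: one compiled pass
// computes the batch forward (word bi-GRU -> word attention -> sentence
// bi-GRU -> sentence attention -> softmax) and, on request, the analytic
// gradient of the negative log-likelihood with respect to every parameter
// array. The pure-R reference in R/han-core.R defines the semantics; this
// file must agree with it to double precision (enforced by the test suite
// and a finite-difference gradient check).
//
// Conventions (matching the R side): row-vector algebra x*W + h*U + b;
// valid positions form a contiguous prefix at both hierarchy levels; masked
// positions output zeros; class columns are (CTRL, AD).
//
// Layout: per hierarchy level, all sequences are stacked into "big"
// matrices of N*T rows (row block t*N..t*N+N-1 holds step t), so the
// input-side projections, the attention projections and the weight
// gradients each take a single large GEMM; only the recurrent terms run
// stepwise.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GruW {
  mat Wz, Uz, Wr, Ur, Wc, Uc;
  rowvec bz, br, bc;
};

struct GruG {
  mat Wz, Uz, Wr, Ur, Wc, Uc;
  rowvec bz, br, bc;
  void init(const GruW& p) {
    Wz.zeros(size(p.Wz)); Uz.zeros(size(p.Uz)); bz.zeros(size(p.bz));
    Wr.zeros(size(p.Wr)); Ur.zeros(size(p.Ur)); br.zeros(size(p.br));
    Wc.zeros(size(p.Wc)); Uc.zeros(size(p.Uc)); bc.zeros(size(p.bc));
  }
};

GruW get_gru(const Rcpp::List& flat, const std::string& pre) {
  GruW g;
  g.Wz = Rcpp::as<mat>(flat[pre + "_Wz"]);
  g.Uz = Rcpp::as<mat>(flat[pre + "_Uz"]);
  g.bz = Rcpp::as<rowvec>(flat[pre + "_bz"]);
  g.Wr = Rcpp::as<mat>(flat[pre + "_Wr"]);
  g.Ur = Rcpp::as<mat>(flat[pre + "_Ur"]);
  g.br = Rcpp::as<rowvec>(flat[pre + "_br"]);
  g.Wc = Rcpp::as<mat>(flat[pre + "_Wc"]);
  g.Uc = Rcpp::as<mat>(flat[pre + "_Uc"]);
  g.bc = Rcpp::as<rowvec>(flat[pre + "_bc"]);
  return g;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
inline span rows_at(int t, int N) { return span(t * N, t * N + N - 1); }

// Stored forward state of one GRU direction: raw gates and the *gated*
// hidden state after each step (masked rows carry the previous state).
struct GruTrace {
  cube Z, R, C, H;  // each N x u x T, indexed by true time t
};

// Forward over N stacked sequences. Xbig is (N*T) x d; mask is N x T with
// contiguous-prefix validity; `order` is the execution order in time.
void gru_forward(const mat& Xbig, const mat& mask, const GruW& p,
                 const std::vector<int>& order, GruTrace& tr) {
  const uword N = mask.n_rows, T = mask.n_cols, u = p.Uz.n_rows;
  tr.Z.set_size(N, u, T); tr.R.set_size(N, u, T);
  tr.C.set_size(N, u, T); tr.H.set_size(N, u, T);
  mat Az = Xbig * p.Wz; Az.each_row() += p.bz;
  mat Ar = Xbig * p.Wr; Ar.each_row() += p.br;
  mat Ac = Xbig * p.Wc; Ac.each_row() += p.bc;
  mat h(N, u, fill::zeros);
  for (size_t k = 0; k < order.size(); ++k) {
    const int t = order[k];
    const vec m = mask.col(t);
    mat z = sigm(Az.rows(rows_at(t, N)) + h * p.Uz);
    mat r = sigm(Ar.rows(rows_at(t, N)) + h * p.Ur);
    mat c = tanh(Ac.rows(rows_at(t, N)) + (r % h) * p.Uc);
    mat hnew = (1.0 - z) % h + z % c;
    h = hnew.each_col() % m + h.each_col() % (1.0 - m);
    tr.Z.slice(t) = z; tr.R.slice(t) = r; tr.C.slice(t) = c;
    tr.H.slice(t) = h;
  }
}

// Backward through one GRU direction. dOut holds the gradient on the
// zero-masked per-position output (tr.H % mask), stacked like Xbig.
// Accumulates parameter gradients into g and input gradients into dXbig.
void gru_backward(const mat& Xbig, const mat& mask, const GruW& p,
                  const std::vector<int>& order, const GruTrace& tr,
                  const mat& dOut, GruG& g, mat& dXbig) {
  const uword N = mask.n_rows, u = p.Uz.n_rows;
  const int T = static_cast<int>(order.size());
  mat DAz(dOut.n_rows, u, fill::zeros);
  mat DAr(dOut.n_rows, u, fill::zeros);
  mat DAc(dOut.n_rows, u, fill::zeros);
  mat dh(N, u, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    const int t = order[k];
    const vec m = mask.col(t);
    const mat hprev = (k == 0) ? mat(N, u, fill::zeros)
                               : mat(tr.H.slice(order[k - 1]));
    dh += dOut.rows(rows_at(t, N)).eval().each_col() % m;
    const mat dhg = dh.each_col() % m;      // gradient through the GRU step
    mat dhprev = dh.each_col() % (1.0 - m); // carried past masked rows
    const mat& z = tr.Z.slice(t);
    const mat& r = tr.R.slice(t);
    const mat& c = tr.C.slice(t);
    const mat dc = dhg % z % (1.0 - c % c);
    const mat dz = dhg % (c - hprev);
    dhprev += dhg % (1.0 - z);
    const mat daz = dz % z % (1.0 - z);
    const mat drh = dc * p.Uc.t();
    const mat dr = drh % hprev;
    dhprev += drh % r;
    const mat dar = dr % r % (1.0 - r);
    g.Uz += hprev.t() * daz;
    g.Ur += hprev.t() * dar;
    g.Uc += (r % hprev).t() * dc;
    DAz.rows(rows_at(t, N)) = daz;
    DAr.rows(rows_at(t, N)) = dar;
    DAc.rows(rows_at(t, N)) = dc;
    dh = dhprev + daz * p.Uz.t() + dar * p.Ur.t();
  }
  g.Wz += Xbig.t() * DAz;  g.Wr += Xbig.t() * DAr;  g.Wc += Xbig.t() * DAc;
  g.bz += sum(DAz, 0);     g.br += sum(DAr, 0);     g.bc += sum(DAc, 0);
  dXbig += DAz * p.Wz.t() + DAr * p.Wr.t() + DAc * p.Wc.t();
}

// Masked row-wise softmax over scores; invalid entries get weight 0.
mat masked_softmax(mat e, const mat& mask) {
  e.elem(find(mask == 0.0)).fill(-datum::inf);
  const vec mx = max(e, 1);
  e.each_col() -= mx;
  mat w = exp(e);
  w.elem(find(mask == 0.0)).zeros();
  const vec s = sum(w, 1);
  w.each_col() /= s;
  return w;
}

// Concatenated, zero-masked bi-GRU outputs stacked into (N*T) x 2u.
mat stack_outputs(const GruTrace& trf, const GruTrace& trb, const mat& mask) {
  const uword N = mask.n_rows, T = mask.n_cols, u = trf.H.n_cols;
  mat H(N * T, 2 * u);
  for (uword t = 0; t < T; ++t) {
    H(rows_at(t, N), span(0, u - 1)) =
        trf.H.slice(t).each_col() % mask.col(t);
    H(rows_at(t, N), span(u, 2 * u - 1)) =
        trb.H.slice(t).each_col() % mask.col(t);
  }
  return H;
}

}  // namespace

// One full pass over a padded batch.
//
// flat:   named list of parameter arrays (see .flatten_params on the R side)
// ids:    B x L x T integer array of 0-based token indices (pad = 0)
// wlen:   B x L valid word counts per sentence (0 for padding sentences)
// slen:   length-B valid sentence counts
// labels: length-B class labels, 0 = CTRL, 1 = AD, -1 = unlabeled
// [[Rcpp::export]]
Rcpp::List cpp_han_pass(Rcpp::List flat, Rcpp::IntegerVector ids,
                        Rcpp::IntegerMatrix wlen, Rcpp::IntegerVector slen,
                        Rcpp::IntegerVector labels,
                        double dropout, bool training, double seed,
                        bool uniform_word, bool uniform_sent,
                        bool compute_grad, bool mean_loss) {
  const Rcpp::IntegerVector dims = ids.attr("dim");
  const int B = dims[0], L = dims[1], T = dims[2];

  const mat E = Rcpp::as<mat>(flat["embedding"]);
  const GruW wgf = get_gru(flat, "wgf"), wgb = get_gru(flat, "wgb");
  const GruW sgf = get_gru(flat, "sgf"), sgb = get_gru(flat, "sgb");
  const mat waW = Rcpp::as<mat>(flat["wa_W"]);
  const rowvec wab = Rcpp::as<rowvec>(flat["wa_b"]);
  const vec wactx = Rcpp::as<vec>(flat["wa_ctx"]);
  const mat saW = Rcpp::as<mat>(flat["sa_W"]);
  const rowvec sab = Rcpp::as<rowvec>(flat["sa_b"]);
  const vec sactx = Rcpp::as<vec>(flat["sa_ctx"]);
  const mat clsW = Rcpp::as<mat>(flat["cls_W"]);
  const rowvec clsb = Rcpp::as<rowvec>(flat["cls_b"]);

  const uword d = E.n_cols, u = wgf.Uz.n_rows, u2 = 2 * u;

  // ---- flatten valid sentences --------------------------------------------
  int S = 0;
  for (int b = 0; b < B; ++b) S += slen[b];
  if (S == 0) Rcpp::stop("empty-sequence error: no valid sentences");
  imat smap(B, L); smap.fill(-1);
  imat sid(S, T, fill::zeros);
  mat mw(S, T, fill::zeros);
  {
    int s = 0;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < slen[b]; ++i, ++s) {
        smap(b, i) = s;
        const int n = wlen(b, i);
        if (n < 1) Rcpp::stop("empty-sequence error: sentence with no words");
        for (int t = 0; t < n && t < T; ++t) {
          sid(s, t) = ids[b + static_cast<long>(B) * (i + static_cast<long>(L) * t)];
          mw(s, t) = 1.0;
        }
      }
    }
  }
  mat ms(B, L, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < slen[b]; ++i) ms(b, i) = 1.0;

  // ---- dropout masks (inverted dropout, own deterministic generator) ------
  const bool use_drop = training && dropout > 0.0;
  const double keep = 1.0 - dropout;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  auto dmask = [&](uword nr, uword nc) {
    mat M(nr, nc, fill::ones);
    if (!use_drop) return M;
    double* ptr = M.memptr();
    const uword n = nr * nc;
    for (uword i = 0; i < n; ++i) {
      const double v = (rng() >> 11) * (1.0 / 9007199254740992.0);
      ptr[i] = v < keep ? 1.0 / keep : 0.0;
    }
    return M;
  };

  // ---- word level ---------------------------------------------------------
  mat Xw(S * T, d);
  const mat Dx = dmask(S * T, d);
  for (int t = 0; t < T; ++t) {
    uvec rows(S);
    for (int s = 0; s < S; ++s)
      rows(s) = mw(s, t) > 0 ? static_cast<uword>(sid(s, t)) : 0;
    Xw.rows(rows_at(t, S)) =
        (E.rows(rows) % Dx.rows(rows_at(t, S))).eval().each_col() % mw.col(t);
  }

  std::vector<int> fwd_ow(T), bwd_ow(T);
  for (int t = 0; t < T; ++t) { fwd_ow[t] = t; bwd_ow[t] = T - 1 - t; }

  GruTrace trf, trb;
  gru_forward(Xw, mw, wgf, fwd_ow, trf);
  gru_forward(Xw, mw, wgb, bwd_ow, trb);

  const mat Dh = dmask(S * T, u2);
  const mat Hd = stack_outputs(trf, trb, mw) % Dh;  // (S*T) x 2u

  // word attention
  mat Mw(S, T);
  mat SprojW;
  if (uniform_word) {
    Mw = mw.each_col() / sum(mw, 1);
  } else {
    SprojW = Hd * waW; SprojW.each_row() += wab; SprojW = tanh(SprojW);
    const vec e_all = SprojW * wactx;
    mat Ew(S, T);
    for (int t = 0; t < T; ++t) Ew.col(t) = e_all(rows_at(t, S));
    Mw = masked_softmax(Ew, mw);
  }
  mat P(S, u2, fill::zeros);
  for (int t = 0; t < T; ++t)
    P += Hd.rows(rows_at(t, S)).eval().each_col() % Mw.col(t);
  const mat Dp = dmask(S, u2);
  const mat Pd = P % Dp;

  // ---- sentence level -----------------------------------------------------
  mat Xs(B * L, u2, fill::zeros);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < B; ++b)
      if (smap(b, i) >= 0)
        Xs.row(i * B + b) = Pd.row(smap(b, i));

  GruTrace tsf, tsb;
  std::vector<int> fwd_os(L), bwd_os(L);
  for (int i = 0; i < L; ++i) { fwd_os[i] = i; bwd_os[i] = L - 1 - i; }
  gru_forward(Xs, ms, sgf, fwd_os, tsf);
  gru_forward(Xs, ms, sgb, bwd_os, tsb);

  const mat Hs = stack_outputs(tsf, tsb, ms);  // (B*L) x 2u

  mat Ms(B, L);
  mat SprojS;
  if (uniform_sent) {
    Ms = ms.each_col() / sum(ms, 1);
  } else {
    SprojS = Hs * saW; SprojS.each_row() += sab; SprojS = tanh(SprojS);
    const vec e_all = SprojS * sactx;
    mat Es(B, L);
    for (int i = 0; i < L; ++i) Es.col(i) = e_all(rows_at(i, B));
    Ms = masked_softmax(Es, ms);
  }
  mat pdoc(B, u2, fill::zeros);
  for (int i = 0; i < L; ++i)
    pdoc += Hs.rows(rows_at(i, B)).eval().each_col() % Ms.col(i);
  const mat Ddoc = dmask(B, u2);
  const mat pdocd = pdoc % Ddoc;

  // ---- classifier and loss ------------------------------------------------
  mat logits = pdocd * clsW; logits.each_row() += clsb;
  if (!logits.is_finite()) Rcpp::stop("numeric error: non-finite logits");
  mat probs(B, 2);
  for (int b = 0; b < B; ++b) {
    rowvec lg = logits.row(b);
    lg -= lg.max();
    rowvec ex = exp(lg);
    probs.row(b) = ex / accu(ex);
  }
  double loss = 0.0;
  int n_labeled = 0;
  for (int b = 0; b < B; ++b) {
    if (labels[b] < 0) continue;
    ++n_labeled;
    loss -= std::log(std::max(probs(b, labels[b]), 1e-12));
  }
  if (mean_loss && n_labeled > 0) loss /= n_labeled;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("probs") = probs);
  if (!compute_grad) return out;
  if (n_labeled != B)
    Rcpp::stop("gradient requested but some documents are unlabeled");

  // ---- backward -----------------------------------------------------------
  const double scale = mean_loss ? 1.0 / B : 1.0;
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) dlogits(b, labels[b]) -= 1.0;
  dlogits *= scale;

  mat g_clsW = pdocd.t() * dlogits;
  rowvec g_clsb = sum(dlogits, 0);
  mat dpdoc = (dlogits * clsW.t()) % Ddoc;

  mat dHs(B * L, u2, fill::zeros);
  mat g_saW(size(saW), fill::zeros);
  rowvec g_sab(size(sab), fill::zeros);
  vec g_sactx(size(sactx), fill::zeros);
  if (uniform_sent) {
    for (int i = 0; i < L; ++i)
      dHs.rows(rows_at(i, B)) = dpdoc.each_col() % Ms.col(i);
  } else {
    mat dm(B, L);
    for (int i = 0; i < L; ++i) {
      dm.col(i) = sum(dpdoc % Hs.rows(rows_at(i, B)), 1);
      dHs.rows(rows_at(i, B)) = dpdoc.each_col() % Ms.col(i);
    }
    const vec rs = sum(Ms % dm, 1);
    const mat de = Ms % (dm.each_col() - rs);
    vec de_all(B * L);
    for (int i = 0; i < L; ++i) de_all(rows_at(i, B)) = de.col(i);
    mat da = de_all * sactx.t();
    da %= (1.0 - SprojS % SprojS);
    g_sactx = SprojS.t() * de_all;
    g_saW = Hs.t() * da;
    g_sab = sum(da, 0);
    dHs += da * saW.t();
  }

  // sentence bi-GRU backward
  GruG g_sgf, g_sgb; g_sgf.init(sgf); g_sgb.init(sgb);
  mat dXs(B * L, u2, fill::zeros);
  gru_backward(Xs, ms, sgf, fwd_os, tsf,
               dHs.cols(0, u - 1), g_sgf, dXs);
  gru_backward(Xs, ms, sgb, bwd_os, tsb,
               dHs.cols(u, u2 - 1), g_sgb, dXs);

  // scatter sentence-input gradients back to sentence vectors
  mat dP(S, u2, fill::zeros);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < B; ++b)
      if (smap(b, i) >= 0) dP.row(smap(b, i)) += dXs.row(i * B + b);
  dP %= Dp;

  // word attention backward
  mat dHd(S * T, u2, fill::zeros);
  mat g_waW(size(waW), fill::zeros);
  rowvec g_wab(size(wab), fill::zeros);
  vec g_wactx(size(wactx), fill::zeros);
  if (uniform_word) {
    for (int t = 0; t < T; ++t)
      dHd.rows(rows_at(t, S)) = dP.each_col() % Mw.col(t);
  } else {
    mat dm(S, T);
    for (int t = 0; t < T; ++t) {
      dm.col(t) = sum(dP % Hd.rows(rows_at(t, S)), 1);
      dHd.rows(rows_at(t, S)) = dP.each_col() % Mw.col(t);
    }
    const vec rs = sum(Mw % dm, 1);
    const mat de = Mw % (dm.each_col() - rs);
    vec de_all(S * T);
    for (int t = 0; t < T; ++t) de_all(rows_at(t, S)) = de.col(t);
    mat da = de_all * wactx.t();
    da %= (1.0 - SprojW % SprojW);
    g_wactx = SprojW.t() * de_all;
    g_waW = Hd.t() * da;
    g_wab = sum(da, 0);
    dHd += da * waW.t();
  }
  dHd %= Dh;

  // word bi-GRU backward
  GruG g_wgf, g_wgb; g_wgf.init(wgf); g_wgb.init(wgb);
  mat dXw(S * T, d, fill::zeros);
  gru_backward(Xw, mw, wgf, fwd_ow, trf,
               dHd.cols(0, u - 1), g_wgf, dXw);
  gru_backward(Xw, mw, wgb, bwd_ow, trb,
               dHd.cols(u, u2 - 1), g_wgb, dXw);
  dXw %= Dx;

  // embedding gradient
  mat g_E(size(E), fill::zeros);
  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < S; ++s)
      if (mw(s, t) > 0) g_E.row(sid(s, t)) += dXw.row(t * S + s);
  }
  g_E.row(0).zeros();  // padding row stays zero

  auto gru_list = [](const GruG& g) {
    return Rcpp::List::create(
        Rcpp::Named("Wz") = g.Wz, Rcpp::Named("Uz") = g.Uz,
        Rcpp::Named("bz") = g.bz, Rcpp::Named("Wr") = g.Wr,
        Rcpp::Named("Ur") = g.Ur, Rcpp::Named("br") = g.br,
        Rcpp::Named("Wc") = g.Wc, Rcpp::Named("Uc") = g.Uc,
        Rcpp::Named("bc") = g.bc);
  };
  out["grads"] = Rcpp::List::create(
      Rcpp::Named("embedding") = g_E,
      Rcpp::Named("wgf") = gru_list(g_wgf),
      Rcpp::Named("wgb") = gru_list(g_wgb),
      Rcpp::Named("sgf") = gru_list(g_sgf),
      Rcpp::Named("sgb") = gru_list(g_sgb),
      Rcpp::Named("wa_W") = g_waW, Rcpp::Named("wa_b") = g_wab,
      Rcpp::Named("wa_ctx") = g_wactx,
      Rcpp::Named("sa_W") = g_saW, Rcpp::Named("sa_b") = g_sab,
      Rcpp::Named("sa_ctx") = g_sactx,
      Rcpp::Named("cls_W") = g_clsW, Rcpp::Named("cls_b") = g_clsb);
  return out;
}
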