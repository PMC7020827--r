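// Hot training kernels: full-stack (encoders + LSTM + linear head) squared
// loss with analytic gradients, and the denoising-autoencoder loss. These
// mirror the reference R implementations (.stack_loss_grads_r,
// .dae_loss_grads_r), which the test suite checks against finite
// differences and against these kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat addb(const mat& M, const rowvec& b) {
  return M.each_row() + b;
}

static mat sigm(const mat& Z) {
  return 1.0 / (1.0 + exp(-Z));
}

// [[Rcpp::export(name = ".stack_loss_grads_cpp")]]
Rcpp::List stack_loss_grads_cpp(Rcpp::List params, const arma::mat& feats,
                                const arma::vec& targets,
                                const arma::imat& seq_mat, double wd,
                                bool encode) {
  const uword B = seq_mat.n_rows, Tn = seq_mat.n_cols;
  Rcpp::List lw = params["lstm"];
  Rcpp::List out = params["out"];

  mat Wxi = lw["Wxi"], Whi = lw["Whi"], Wxf = lw["Wxf"], Whf = lw["Whf"];
  mat Wxo = lw["Wxo"], Who = lw["Who"], Wxc = lw["Wxc"], Whc = lw["Whc"];
  rowvec bi = Rcpp::as<rowvec>(lw["bi"]), bf = Rcpp::as<rowvec>(lw["bf"]);
  rowvec bo = Rcpp::as<rowvec>(lw["bo"]), bc = Rcpp::as<rowvec>(lw["bc"]);
  mat Wy = out["W"];
  double by = Rcpp::as<vec>(out["b"])(0);

  const uword dh = Whi.n_cols;
  mat Wx = join_rows(join_rows(Wxi, Wxf), join_rows(Wxo, Wxc));
  mat Wh = join_rows(join_rows(Whi, Whf), join_rows(Who, Whc));
  rowvec bg = join_rows(join_rows(bi, bf), join_rows(bo, bc));

  mat A1, A2, Z;
  mat e1W, e2W;
  rowvec e1b, e2b;
  if (encode) {
    Rcpp::List enc1 = params["enc1"], enc2 = params["enc2"];
    e1W = Rcpp::as<mat>(enc1["W"]); e1b = Rcpp::as<rowvec>(enc1["b"]);
    e2W = Rcpp::as<mat>(enc2["W"]); e2b = Rcpp::as<rowvec>(enc2["b"]);
    A1 = sigm(addb(feats * e1W, e1b));
    A2 = sigm(addb(A1 * e2W, e2b));
    Z = A2;
  } else {
    Z = feats;
  }

  // forward
  cube gi(B, dh, Tn), gf(B, dh, Tn), go(B, dh, Tn), gg(B, dh, Tn);
  cube cs(B, dh, Tn), tc(B, dh, Tn), hs(B, dh, Tn);
  std::vector<mat> xs(Tn);
  mat h(B, dh, fill::zeros), cc(B, dh, fill::zeros);
  mat errs(B, Tn);
  double loss = 0.0;
  for (uword t = 0; t < Tn; ++t) {
    mat X_t(B, Z.n_cols);
    for (uword b2 = 0; b2 < B; ++b2) X_t.row(b2) = Z.row(seq_mat(b2, t) - 1);
    xs[t] = X_t;
    mat za = addb(X_t * Wx + h * Wh, bg);
    mat i_t = sigm(za.cols(0, dh - 1));
    mat f_t = sigm(za.cols(dh, 2 * dh - 1));
    mat o_t = sigm(za.cols(2 * dh, 3 * dh - 1));
    mat g_t = tanh(za.cols(3 * dh, 4 * dh - 1));
    mat c_t = f_t % cc + i_t % g_t;
    mat tc_t = tanh(c_t);
    mat h_t = o_t % tc_t;
    vec y_t = h_t * Wy + by;
    for (uword b2 = 0; b2 < B; ++b2) {
      double e = y_t(b2) - targets(seq_mat(b2, t) - 1);
      errs(b2, t) = e;
      loss += e * e;
    }
    gi.slice(t) = i_t; gf.slice(t) = f_t; go.slice(t) = o_t; gg.slice(t) = g_t;
    cs.slice(t) = c_t; tc.slice(t) = tc_t; hs.slice(t) = h_t;
    h = h_t; cc = c_t;
  }
  const double denom = (double)(B * Tn);
  loss /= denom;

  // backward
  mat gWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat gWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec gbg(4 * dh, fill::zeros);
  mat gWy(Wy.n_rows, 1, fill::zeros);
  double gby = 0.0;
  mat dZ(Z.n_rows, Z.n_cols, fill::zeros);
  mat dh_next(B, dh, fill::zeros), dc_next(B, dh, fill::zeros);
  for (uword tt = Tn; tt-- > 0;) {
    vec dy = 2.0 * errs.col(tt) / denom;
    gWy += hs.slice(tt).t() * dy;
    gby += accu(dy);
    mat dh2 = dh_next + dy * Wy.t();
    mat do_ = dh2 % tc.slice(tt);
    mat dc = dc_next + dh2 % go.slice(tt) % (1.0 - square(tc.slice(tt)));
    mat c_prev = (tt == 0) ? mat(B, dh, fill::zeros) : cs.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(B, dh, fill::zeros) : hs.slice(tt - 1);
    dc_next = dc % gf.slice(tt);
    mat dz(B, 4 * dh);
    dz.cols(0, dh - 1) = dc % gg.slice(tt) % gi.slice(tt) % (1.0 - gi.slice(tt));
    dz.cols(dh, 2 * dh - 1) = dc % c_prev % gf.slice(tt) % (1.0 - gf.slice(tt));
    dz.cols(2 * dh, 3 * dh - 1) = do_ % go.slice(tt) % (1.0 - go.slice(tt));
    dz.cols(3 * dh, 4 * dh - 1) = dc % gi.slice(tt) % (1.0 - square(gg.slice(tt)));
    gWx += xs[tt].t() * dz;
    gWh += h_prev.t() * dz;
    gbg += sum(dz, 0);
    dh_next = dz * Wh.t();
    mat dx = dz * Wx.t();
    for (uword b2 = 0; b2 < B; ++b2) dZ.row(seq_mat(b2, tt) - 1) += dx.row(b2);
  }

  Rcpp::List genc1, genc2;
  if (encode) {
    mat dZ2 = dZ % A2 % (1.0 - A2);
    mat gW2 = A1.t() * dZ2 + 2.0 * wd * e2W;
    rowvec gb2 = sum(dZ2, 0);
    mat dA1 = dZ2 * e2W.t();
    mat dZ1 = dA1 % A1 % (1.0 - A1);
    mat gW1 = feats.t() * dZ1 + 2.0 * wd * e1W;
    rowvec gb1 = sum(dZ1, 0);
    loss += wd * (accu(square(e1W)) + accu(square(e2W)));
    genc1 = Rcpp::List::create(Rcpp::Named("W") = gW1,
                               Rcpp::Named("b") = Rcpp::NumericVector(gb1.begin(), gb1.end()));
    genc2 = Rcpp::List::create(Rcpp::Named("W") = gW2,
                               Rcpp::Named("b") = Rcpp::NumericVector(gb2.begin(), gb2.end()));
  }

  // weight decay on all LSTM weight matrices and the output weights
  gWx.cols(0, dh - 1)          += 2.0 * wd * Wxi;
  gWx.cols(dh, 2 * dh - 1)     += 2.0 * wd * Wxf;
  gWx.cols(2 * dh, 3 * dh - 1) += 2.0 * wd * Wxo;
  gWx.cols(3 * dh, 4 * dh - 1) += 2.0 * wd * Wxc;
  gWh.cols(0, dh - 1)          += 2.0 * wd * Whi;
  gWh.cols(dh, 2 * dh - 1)     += 2.0 * wd * Whf;
  gWh.cols(2 * dh, 3 * dh - 1) += 2.0 * wd * Who;
  gWh.cols(3 * dh, 4 * dh - 1) += 2.0 * wd * Whc;
  loss += wd * (accu(square(Wxi)) + accu(square(Whi)) + accu(square(Wxf)) +
                accu(square(Whf)) + accu(square(Wxo)) + accu(square(Who)) +
                accu(square(Wxc)) + accu(square(Whc)) + accu(square(Wy)));
  gWy += 2.0 * wd * Wy;

  auto rv = [](const rowvec& v) {
    return Rcpp::NumericVector(v.begin(), v.end());
  };
  Rcpp::List glstm = Rcpp::List::create(
    Rcpp::Named("Wxi") = mat(gWx.cols(0, dh - 1)),
    Rcpp::Named("Whi") = mat(gWh.cols(0, dh - 1)),
    Rcpp::Named("bi") = rv(gbg.cols(0, dh - 1)),
    Rcpp::Named("Wxf") = mat(gWx.cols(dh, 2 * dh - 1)),
    Rcpp::Named("Whf") = mat(gWh.cols(dh, 2 * dh - 1)),
    Rcpp::Named("bf") = rv(gbg.cols(dh, 2 * dh - 1)),
    Rcpp::Named("Wxo") = mat(gWx.cols(2 * dh, 3 * dh - 1)),
    Rcpp::Named("Who") = mat(gWh.cols(2 * dh, 3 * dh - 1)),
    Rcpp::Named("bo") = rv(gbg.cols(2 * dh, 3 * dh - 1)),
    Rcpp::Named("Wxc") = mat(gWx.cols(3 * dh, 4 * dh - 1)),
    Rcpp::Named("Whc") = mat(gWh.cols(3 * dh, 4 * dh - 1)),
    Rcpp::Named("bc") = rv(gbg.cols(3 * dh, 4 * dh - 1)));
  Rcpp::List gout = Rcpp::List::create(
    Rcpp::Named("W") = gWy, Rcpp::Named("b") = gby);

  Rcpp::List grads;
  if (encode) {
    grads = Rcpp::List::create(Rcpp::Named("enc1") = genc1,
                               Rcpp::Named("enc2") = genc2,
                               Rcpp::Named("lstm") = glstm,
                               Rcpp::Named("out") = gout);
  } else {
    grads = Rcpp::List::create(Rcpp::Named("lstm") = glstm,
                               Rcpp::Named("out") = gout);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export(name = ".dae_loss_grads_cpp")]]
Rcpp::List dae_loss_grads_cpp(Rcpp::List p, const arma::mat& x_corrupt,
                              const arma::mat& x_clean, double rho,
                              double beta, double wd) {
  mat W1 = p["W1"], W2 = p["W2"];
  rowvec b1 = Rcpp::as<rowvec>(p["b1"]), b2 = Rcpp::as<rowvec>(p["b2"]);
  const double n = (double)x_corrupt.n_rows, d = (double)x_clean.n_cols;
  mat H = sigm(addb(x_corrupt * W1, b1));
  mat err = addb(H * W2, b2) - x_clean;
  double loss = accu(square(err)) / (n * d);
  rowvec rho_hat = clamp(mean(H, 0), 1e-8, 1.0 - 1e-8);
  loss += beta * accu(rho * log(rho / rho_hat) +
                      (1.0 - rho) * log((1.0 - rho) / (1.0 - rho_hat)));
  loss += wd * (accu(square(W1)) + accu(square(W2)));
  mat dXhat = 2.0 * err / (n * d);
  mat gW2 = H.t() * dXhat + 2.0 * wd * W2;
  rowvec gb2 = sum(dXhat, 0);
  mat dH = dXhat * W2.t();
  dH.each_row() += beta * (-rho / rho_hat + (1.0 - rho) / (1.0 - rho_hat)) / n;
  mat dZ1 = dH % H % (1.0 - H);
  mat gW1 = x_corrupt.t() * dZ1 + 2.0 * wd * W1;
  rowvec gb1 = sum(dZ1, 0);
  double hidden_mean = accu(H) / (double)H.n_elem;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = gW1,
      Rcpp::Named("b1") = Rcpp::NumericVector(gb1.begin(), gb1.end()),
      Rcpp::Named("W2") = gW2,
      Rcpp::Named("b2") = Rcpp::NumericVector(gb2.begin(), gb2.end())),
    Rcpp::Named("hidden_mean") = hidden_mean);
}
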