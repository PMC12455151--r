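#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Incremental (sample-by-sample) error back-propagation for a one-hidden-
// layer tanh MLP with linear output, momentum, adaptive learning rate and
// patience-based early stopping on a validation set. The RNG is a local
// mt19937 so results are bit-reproducible for a given seed regardless of
// R's RNG state.
//
// X: N x I inputs, Y: N x M targets. train_idx / val_idx are 0-based rows.
// Returns the weights at the best validation MSE.
// [[Rcpp::export]]
List train_ebp_cpp(NumericMatrix X, NumericMatrix Y,
                   IntegerVector train_idx, IntegerVector val_idx,
                   int hidden, double eta0, double momentum,
                   int max_epochs, int patience,
                   double init_lo, double init_hi, int seed) {
  const int I = X.ncol(), M = Y.ncol(), H = hidden;
  const int N = X.nrow();
  const int ntr = train_idx.size(), nval = val_idx.size();
  const double *pX = REAL(X), *pY = REAL(Y);

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(init_lo, init_hi);

  std::vector<double> Win(H * I), bh(H), Wout(M * H), bo(M);
  for (auto &w : Win) w = unif(rng);
  for (auto &w : bh) w = unif(rng);
  for (auto &w : Wout) w = unif(rng);
  for (auto &w : bo) w = unif(rng);

  std::vector<double> vWin(H * I, 0.0), vbh(H, 0.0), vWout(M * H, 0.0), vbo(M, 0.0);
  std::vector<double> h(H), dh(H), e(M), xb(I);
  std::vector<int> order(train_idx.begin(), train_idx.end());

  double eta = eta0;
  double prev_mse = R_PosInf, best_val = R_PosInf;
  std::vector<double> bWin(Win), bbh(bh), bWout(Wout), bbo(bo);
  std::vector<double> hist_train, hist_val, hist_eta;
  int since_best = 0, epochs_run = 0;
  bool diverged = false;

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (int s = 0; s < ntr; ++s) {
      const int n = order[s];
      // gather the sample row once (X is column-major)
      for (int i = 0; i < I; ++i) xb[i] = pX[n + N * i];
      // forward
      for (int j = 0; j < H; ++j) {
        double a = bh[j];
        const double *wj = &Win[j * I];
        for (int i = 0; i < I; ++i) a += wj[i] * xb[i];
        h[j] = std::tanh(a);
      }
      for (int m = 0; m < M; ++m) {
        double y = bo[m];
        for (int j = 0; j < H; ++j) y += Wout[m * H + j] * h[j];
        e[m] = y - pY[n + N * m];
        sse += e[m] * e[m];
      }
      // backward
      for (int j = 0; j < H; ++j) {
        double g = 0.0;
        for (int m = 0; m < M; ++m) g += Wout[m * H + j] * e[m];
        dh[j] = g * (1.0 - h[j] * h[j]);
      }
      for (int m = 0; m < M; ++m) {
        for (int j = 0; j < H; ++j) {
          double upd = momentum * vWout[m * H + j] - eta * e[m] * h[j];
          vWout[m * H + j] = upd;
          Wout[m * H + j] += upd;
        }
        double updb = momentum * vbo[m] - eta * e[m];
        vbo[m] = updb;
        bo[m] += updb;
      }
      for (int j = 0; j < H; ++j) {
        double *wj = &Win[j * I], *vj = &vWin[j * I];
        const double ed = eta * dh[j];
        for (int i = 0; i < I; ++i) {
          double upd = momentum * vj[i] - ed * xb[i];
          vj[i] = upd;
          wj[i] += upd;
        }
        double updb = momentum * vbh[j] - eta * dh[j];
        vbh[j] = updb;
        bh[j] += updb;
      }
    }
    double mse = sse / (static_cast<double>(ntr) * M);
    epochs_run = ep + 1;
    if (!std::isfinite(mse)) { diverged = true; hist_train.push_back(mse); break; }

    // validation pass (no updates)
    double vsse = 0.0;
    for (int s = 0; s < nval; ++s) {
      const int n = val_idx[s];
      for (int i = 0; i < I; ++i) xb[i] = pX[n + N * i];
      for (int j = 0; j < H; ++j) {
        double a = bh[j];
        const double *wj = &Win[j * I];
        for (int i = 0; i < I; ++i) a += wj[i] * xb[i];
        h[j] = std::tanh(a);
      }
      for (int m = 0; m < M; ++m) {
        double y = bo[m];
        for (int j = 0; j < H; ++j) y += Wout[m * H + j] * h[j];
        double d = y - pY[n + N * m];
        vsse += d * d;
      }
    }
    double vmse = nval > 0 ? vsse / (static_cast<double>(nval) * M) : mse;

    hist_train.push_back(mse);
    hist_val.push_back(vmse);
    hist_eta.push_back(eta);

    if (vmse < best_val) {
      best_val = vmse;
      bWin = Win; bbh = bh; bWout = Wout; bbo = bo;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    eta *= (mse < prev_mse) ? 1.05 : 0.7;
    prev_mse = mse;
  }

  NumericMatrix rWin(H, I), rWout(M, H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < I; ++i) rWin(j, i) = bWin[j * I + i];
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < H; ++j) rWout(m, j) = bWout[m * H + j];

  return List::create(
    _["W_in"] = rWin, _["b_hidden"] = NumericVector(bbh.begin(), bbh.end()),
    _["W_out"] = rWout, _["b_out"] = NumericVector(bbo.begin(), bbo.end()),
    _["mse_train_history"] = NumericVector(hist_train.begin(), hist_train.end()),
    _["mse_val_history"] = NumericVector(hist_val.begin(), hist_val.end()),
    _["eta_history"] = NumericVector(hist_eta.begin(), hist_eta.end()),
    _["best_val_mse"] = best_val, _["n_epochs"] = epochs_run,
    _["diverged"] = diverged);
}
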