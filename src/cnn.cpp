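// Small 1-D convolutional network over embedded k-mer grids:
// conv(k3) -> relu -> maxpool2 -> conv(k3) -> relu -> maxpool2 ->
// dense -> relu -> dropout -> sigmoid. Adam + binary cross-entropy,
// early stopping on validation loss with best-weight restore.
// Hand-written forward/backward; deterministic for a fixed seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

namespace {

struct Spec {
  int T;        // input rows (max_len tokens)
  int E;        // embedding dim
  int F1, F2;   // conv filters
  int H;        // dense units
  double dropout;
  int T1, T1p, T2, T2p, V;  // derived sizes
};

struct Params {
  arma::mat W1, W2, Wd;       // (3E x F1), (3F1 x F2), (H x V)
  arma::rowvec b1, b2;        // (F1), (F2)
  arma::vec bd, wo;           // (H), (H)
  double bo;
};

Spec make_spec(int T, int E, int F1, int F2, int H, double dropout) {
  Spec s;
  s.T = T; s.E = E; s.F1 = F1; s.F2 = F2; s.H = H; s.dropout = dropout;
  s.T1 = T - 2;
  s.T1p = s.T1 / 2;
  s.T2 = s.T1p - 2;
  s.T2p = s.T2 / 2;
  if (s.T2p < 1) stop("max_len too small for two conv/pool stages");
  s.V = s.T2p * F2;
  return s;
}

// im2col for kernel 3, stride 1: rows t = [x.row(t), x.row(t+1), x.row(t+2)]
arma::mat patches(const arma::mat& x) {
  int T = x.n_rows, C = x.n_cols;
  arma::mat p(T - 2, 3 * C);
  p.cols(0, C - 1) = x.rows(0, T - 3);
  p.cols(C, 2 * C - 1) = x.rows(1, T - 2);
  p.cols(2 * C, 3 * C - 1) = x.rows(2, T - 1);
  return p;
}

// max pool over row pairs; arg(t, c) in {0,1} records the winner offset
arma::mat pool2(const arma::mat& a, arma::umat& arg) {
  int Tp = a.n_rows / 2, C = a.n_cols;
  arma::mat out(Tp, C);
  arg.set_size(Tp, C);
  for (int t = 0; t < Tp; ++t) {
    for (int c = 0; c < C; ++c) {
      double v0 = a(2 * t, c), v1 = a(2 * t + 1, c);
      if (v0 >= v1) { out(t, c) = v0; arg(t, c) = 0; }
      else          { out(t, c) = v1; arg(t, c) = 1; }
    }
  }
  return out;
}

struct Cache {
  arma::mat P1, Z1, A1p, P2, Z2, A2p;
  arma::umat arg1, arg2;
  arma::vec v, hpre, h, mask;
  double z, p;
};

double forward(const Params& par, const Spec& sp, const arma::mat& P1,
               Cache& c, bool training, double keep, std::mt19937& rng) {
  c.P1 = P1;
  c.Z1 = P1 * par.W1;
  c.Z1.each_row() += par.b1;
  arma::mat A1 = arma::clamp(c.Z1, 0.0, arma::datum::inf);
  c.A1p = pool2(A1, c.arg1);
  c.P2 = patches(c.A1p);
  c.Z2 = c.P2 * par.W2;
  c.Z2.each_row() += par.b2;
  arma::mat A2 = arma::clamp(c.Z2, 0.0, arma::datum::inf);
  c.A2p = pool2(A2, c.arg2);
  c.v = arma::vectorise(c.A2p);
  c.hpre = par.Wd * c.v + par.bd;
  c.h = arma::clamp(c.hpre, 0.0, arma::datum::inf);
  if (training && keep < 1.0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    c.mask.set_size(c.h.n_elem);
    for (arma::uword i = 0; i < c.h.n_elem; ++i)
      c.mask(i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    c.h %= c.mask;
  }
  c.z = arma::dot(par.wo, c.h) + par.bo;
  c.p = 1.0 / (1.0 + std::exp(-c.z));
  return c.p;
}

struct Grads {
  arma::mat W1, W2, Wd;
  arma::rowvec b1, b2;
  arma::vec bd, wo;
  double bo;
  void zero(const Params& p) {
    W1.zeros(arma::size(p.W1)); W2.zeros(arma::size(p.W2));
    Wd.zeros(arma::size(p.Wd));
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem);
    bd.zeros(p.bd.n_elem); wo.zeros(p.wo.n_elem);
    bo = 0.0;
  }
};

void backward(const Params& par, const Spec& sp, const Cache& c, double y,
              bool used_dropout, Grads& g) {
  double dz = c.p - y;
  g.wo += dz * c.h;
  g.bo += dz;
  arma::vec dh = dz * par.wo;
  if (used_dropout) dh %= c.mask;
  arma::vec dhpre = dh % arma::conv_to<arma::vec>::from(c.hpre > 0);
  g.Wd += dhpre * c.v.t();
  g.bd += dhpre;
  arma::vec dv = par.Wd.t() * dhpre;
  arma::mat dA2p = arma::reshape(dv, sp.T2p, sp.F2);
  arma::mat dA2(sp.T2, sp.F2, arma::fill::zeros);
  for (int t = 0; t < sp.T2p; ++t)
    for (int cc = 0; cc < sp.F2; ++cc)
      dA2(2 * t + c.arg2(t, cc), cc) = dA2p(t, cc);
  arma::mat dZ2 = dA2 % arma::conv_to<arma::mat>::from(c.Z2 > 0);
  g.W2 += c.P2.t() * dZ2;
  g.b2 += arma::sum(dZ2, 0);
  arma::mat dP2 = dZ2 * par.W2.t();
  arma::mat dA1p(sp.T1p, sp.F1, arma::fill::zeros);
  for (int t = 0; t < sp.T2; ++t) {
    dA1p.row(t)     += dP2(t, arma::span(0, sp.F1 - 1));
    dA1p.row(t + 1) += dP2(t, arma::span(sp.F1, 2 * sp.F1 - 1));
    dA1p.row(t + 2) += dP2(t, arma::span(2 * sp.F1, 3 * sp.F1 - 1));
  }
  arma::mat dA1(sp.T1, sp.F1, arma::fill::zeros);
  for (int t = 0; t < sp.T1p; ++t)
    for (int cc = 0; cc < sp.F1; ++cc)
      dA1(2 * t + c.arg1(t, cc), cc) = dA1p(t, cc);
  arma::mat dZ1 = dA1 % arma::conv_to<arma::mat>::from(c.Z1 > 0);
  g.W1 += c.P1.t() * dZ1;
  g.b1 += arma::sum(dZ1, 0);
}

struct Adam {
  double lr, b1, b2, eps;
  long t = 0;
  Grads m, v;
  void init(const Params& p, double lr_) {
    lr = lr_; b1 = 0.9; b2 = 0.999; eps = 1e-8;
    m.zero(p); v.zero(p);
  }
  template <typename T>
  void upd(T& w, T& mw, T& vw, const T& gw) {
    mw = b1 * mw + (1 - b1) * gw;
    vw = b2 * vw + (1 - b2) * (gw % gw);
    w -= lr * (mw / (1 - std::pow(b1, (double)t))) /
         (arma::sqrt(vw / (1 - std::pow(b2, (double)t))) + eps);
  }
  void step(Params& p, const Grads& g) {
    ++t;
    upd(p.W1, m.W1, v.W1, g.W1);
    upd(p.W2, m.W2, v.W2, g.W2);
    upd(p.Wd, m.Wd, v.Wd, g.Wd);
    upd(p.b1, m.b1, v.b1, g.b1);
    upd(p.b2, m.b2, v.b2, g.b2);
    upd(p.bd, m.bd, v.bd, g.bd);
    upd(p.wo, m.wo, v.wo, g.wo);
    // scalar bias
    m.bo = b1 * m.bo + (1 - b1) * g.bo;
    v.bo = b2 * v.bo + (1 - b2) * g.bo * g.bo;
    p.bo -= lr * (m.bo / (1 - std::pow(b1, (double)t))) /
            (std::sqrt(v.bo / (1 - std::pow(b2, (double)t))) + eps);
  }
};

std::vector<arma::mat> precompute_patches(const List& X) {
  std::vector<arma::mat> out;
  out.reserve(X.size());
  for (int i = 0; i < X.size(); ++i) {
    arma::mat x = as<arma::mat>(X[i]);
    out.push_back(patches(x));
  }
  return out;
}

double bce(double p, double y) {
  double eps = 1e-12;
  return -(y * std::log(p + eps) + (1 - y) * std::log(1 - p + eps));
}

Params init_params(const Spec& sp, std::mt19937& rng) {
  std::normal_distribution<double> norm(0.0, 1.0);
  auto he = [&](int rows, int cols, int fan_in) {
    arma::mat m(rows, cols);
    double s = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = norm(rng) * s;
    return m;
  };
  Params p;
  p.W1 = he(3 * sp.E, sp.F1, 3 * sp.E);
  p.W2 = he(3 * sp.F1, sp.F2, 3 * sp.F1);
  p.Wd = he(sp.H, sp.V, sp.V);
  p.b1.zeros(sp.F1); p.b2.zeros(sp.F2);
  p.bd.zeros(sp.H);
  arma::mat wo = he(sp.H, 1, sp.H);
  p.wo = wo.col(0);
  p.bo = 0.0;
  return p;
}

List params_to_list(const Params& p) {
  return List::create(_["W1"] = p.W1, _["b1"] = p.b1, _["W2"] = p.W2,
                      _["b2"] = p.b2, _["Wd"] = p.Wd, _["bd"] = p.bd,
                      _["wo"] = p.wo, _["bo"] = p.bo);
}

Params params_from_list(const List& l) {
  Params p;
  p.W1 = as<arma::mat>(l["W1"]);
  p.b1 = as<arma::rowvec>(l["b1"]);
  p.W2 = as<arma::mat>(l["W2"]);
  p.b2 = as<arma::rowvec>(l["b2"]);
  p.Wd = as<arma::mat>(l["Wd"]);
  p.bd = as<arma::vec>(l["bd"]);
  p.wo = as<arma::vec>(l["wo"]);
  p.bo = as<double>(l["bo"]);
  return p;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(List Xtrain, NumericVector ytrain, List Xval,
                   NumericVector yval, int emb_dim, int f1, int f2, int dense,
                   double dropout, double lr, int max_epochs, int patience,
                   int batch_size, int seed) {
  if (Xtrain.size() == 0) stop("empty training set");
  arma::mat x0 = as<arma::mat>(Xtrain[0]);
  Spec sp = make_spec(x0.n_rows, emb_dim, f1, f2, dense, dropout);
  if ((int)x0.n_cols != emb_dim) stop("embedding dim mismatch");

  std::mt19937 rng(static_cast<unsigned>(seed));
  Params par = init_params(sp, rng);
  Adam opt;
  opt.init(par, lr);

  std::vector<arma::mat> Ptr = precompute_patches(Xtrain);
  std::vector<arma::mat> Pva = precompute_patches(Xval);
  int n = Ptr.size(), nv = Pva.size();
  double keep = 1.0 - dropout;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Cache c;
  Grads g;
  double best_val = arma::datum::inf;
  List best = params_to_list(par);
  int best_epoch = 0, bad = 0;
  std::vector<double> train_log, val_log;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      g.zero(par);
      for (int b = start; b < end; ++b) {
        int i = order[b];
        double p = forward(par, sp, Ptr[i], c, true, keep, rng);
        tr_loss += bce(p, ytrain[i]);
        backward(par, sp, c, ytrain[i], keep < 1.0, g);
      }
      double scale = 1.0 / (end - start);
      g.W1 *= scale; g.W2 *= scale; g.Wd *= scale;
      g.b1 *= scale; g.b2 *= scale; g.bd *= scale; g.wo *= scale;
      g.bo *= scale;
      opt.step(par, g);
    }
    tr_loss /= n;
    double va_loss = 0.0;
    for (int i = 0; i < nv; ++i) {
      double p = forward(par, sp, Pva[i], c, false, 1.0, rng);
      va_loss += bce(p, yval[i]);
    }
    va_loss /= std::max(nv, 1);
    if (!std::isfinite(tr_loss) || !std::isfinite(va_loss))
      stop("divergent (non-finite) loss at epoch %d", ep);
    train_log.push_back(tr_loss);
    val_log.push_back(va_loss);
    if (va_loss < best_val - 1e-6) {
      best_val = va_loss;
      best = params_to_list(par);
      best_epoch = ep;
      bad = 0;
    } else if (++bad >= patience) {
      break;
    }
  }
  return List::create(_["weights"] = best, _["best_epoch"] = best_epoch,
                      _["train_loss"] = train_log, _["val_loss"] = val_log,
                      _["max_len"] = sp.T, _["emb_dim"] = sp.E);
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
NumericVector cpp_cnn_predict(List weights, List X, int emb_dim, int f1,
                              int f2, int dense) {
  if (X.size() == 0) return NumericVector(0);
  arma::mat x0 = as<arma::mat>(X[0]);
  Spec sp = make_spec(x0.n_rows, emb_dim, f1, f2, dense, 0.0);
  Params par = params_from_list(weights);
  std::mt19937 rng(1);
  Cache c;
  NumericVector out(X.size());
  for (int i = 0; i < X.size(); ++i) {
    arma::mat p1 = patches(as<arma::mat>(X[i]));
    out[i] = forward(par, sp, p1, c, false, 1.0, rng);
  }
  return out;
}
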