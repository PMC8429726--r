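// Deep double Q-learning training loop on the two-compartment bone-marrow
// environment. The environment is exact: per dose level the state advances
// by a precomputed matrix exponential and the reward integral is a linear
// functional of the state. The network is a two-hidden-layer ReLU MLP with
// a linear output head, trained by Adam on the squared TD error of the
// selected action, with an experience-replay buffer and a periodically
// hard-copied target network. Randomness (exploration, replay sampling)
// comes from R's RNG so runs are reproducible under set.seed().
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct Net {
  arma::mat W1, W2, W3;
  arma::vec b1, b2, b3;
};

static inline void relu_inplace(arma::mat &z) {
  z.for_each([](arma::mat::elem_type &v) { if (v < 0) v = 0; });
}

static void forward(const Net &n, const arma::mat &X, arma::mat &H1,
                    arma::mat &H2, arma::mat &Q) {
  H1 = n.W1 * X;
  H1.each_col() += n.b1;
  relu_inplace(H1);
  H2 = n.W2 * H1;
  H2.each_col() += n.b2;
  relu_inplace(H2);
  Q = n.W3 * H2;
  Q.each_col() += n.b3;
}

static arma::mat qvalues(const Net &n, const arma::mat &X) {
  arma::mat H1, H2, Q;
  forward(n, X, H1, H2, Q);
  return Q;
}

struct Adam {
  arma::mat mW1, vW1, mW2, vW2, mW3, vW3;
  arma::vec mb1, vb1, mb2, vb2, mb3, vb3;
  long it = 0;
};

static void adam_step(arma::mat &w, arma::mat &m, arma::mat &v,
                      const arma::mat &g, double lr, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * arma::square(g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
}

static void adam_step(arma::vec &w, arma::vec &m, arma::vec &v,
                      const arma::vec &g, double lr, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * arma::square(g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
}

// uniform sample of `size` distinct indices from 0..n-1 (batch << n)
static void sample_distinct(int n, int size, arma::uvec &out) {
  for (int i = 0; i < size; ++i) {
    bool fresh;
    do {
      unsigned cand = (unsigned)(unif_rand() * n);
      if (cand >= (unsigned)n) cand = n - 1;
      fresh = true;
      for (int j = 0; j < i; ++j)
        if (out[j] == cand) { fresh = false; break; }
      if (fresh) out[i] = cand;
    } while (!fresh);
  }
}

// [[Rcpp::export(name = ".ddqn_train_cpp")]]
List ddqn_train_cpp(List env, List init_weights, List cfg) {
  arma::cube A = as<arma::cube>(env["A"]);          // 2 x 2 x n_actions
  arma::mat rvec = as<arma::mat>(env["rvec"]);      // n_actions x 2
  arma::vec kpen = as<arma::vec>(env["kpen"]);      // n_actions
  arma::vec x0 = as<arma::vec>(env["x0"]);
  const int horizon = as<int>(env["horizon"]);
  const int wl = as<int>(env["wl"]);
  const int n_actions = A.n_slices;
  const int d = wl + 1;

  Net net, tgt;
  net.W1 = as<arma::mat>(init_weights["W1"]);
  net.b1 = as<arma::vec>(init_weights["b1"]);
  net.W2 = as<arma::mat>(init_weights["W2"]);
  net.b2 = as<arma::vec>(init_weights["b2"]);
  net.W3 = as<arma::mat>(init_weights["W3"]);
  net.b3 = as<arma::vec>(init_weights["b3"]);
  tgt = net;

  const double lr = as<double>(cfg["lr"]);
  const double discount = as<double>(cfg["discount"]);
  const int batch = as<int>(cfg["batch"]);
  const int warmup = as<int>(cfg["exploratory_steps"]);
  const double eps_start = as<double>(cfg["eps_start"]);
  const double eps_end = as<double>(cfg["eps_end"]);
  const double anneal = as<double>(cfg["eps_anneal_steps"]);
  const int max_resets = as<int>(cfg["max_resets"]);
  const int patience = as<int>(cfg["patience"]);
  const int sync = as<int>(cfg["target_sync_period"]);
  const int cap = as<int>(cfg["buffer_capacity"]);

  arma::mat bufS(d, cap), bufS2(d, cap);
  arma::ivec bufA(cap);
  arma::vec bufR(cap);
  arma::ivec bufD(cap);
  int bn = 0, bpos = -1;

  std::vector<double> ep_returns, ep_losses;
  ep_returns.reserve(max_resets);
  ep_losses.reserve(max_resets);

  arma::vec x = x0;
  arma::vec hist(horizon + 1);
  hist[0] = arma::accu(x);
  int t = 0;
  double ep_ret = 0, loss_sum = 0;
  int loss_n = 0;
  long gstep = 0;
  int resets = 0, best_episode = 0;
  double best = -arma::datum::inf;
  bool diverged = false;

  arma::vec s(d), s2(d);
  arma::uvec bidx(batch);
  arma::mat H1, H2, Q, tH1, tH2, tQ;

  Adam opt;
  opt.mW1.zeros(arma::size(net.W1)); opt.vW1.zeros(arma::size(net.W1));
  opt.mW2.zeros(arma::size(net.W2)); opt.vW2.zeros(arma::size(net.W2));
  opt.mW3.zeros(arma::size(net.W3)); opt.vW3.zeros(arma::size(net.W3));
  opt.mb1.zeros(net.b1.n_elem); opt.vb1.zeros(net.b1.n_elem);
  opt.mb2.zeros(net.b2.n_elem); opt.vb2.zeros(net.b2.n_elem);
  opt.mb3.zeros(net.b3.n_elem); opt.vb3.zeros(net.b3.n_elem);

  auto make_obs = [&](int day, arma::vec &out) {
    out[0] = day;
    for (int j = 0; j < wl; ++j) {
      int dd = day - j;
      out[j + 1] = (dd >= 0) ? hist[dd] : 1.0;
    }
  };

  while (resets < max_resets && !diverged) {
    make_obs(t, s);
    long astep = gstep - warmup;
    double eps = (astep < 0) ? eps_start
      : std::max(eps_end, eps_start - (eps_start - eps_end) * astep / anneal);
    int ai;
    if (unif_rand() < eps) {
      ai = (int)(unif_rand() * n_actions);
      if (ai >= n_actions) ai = n_actions - 1;
    } else {
      arma::mat q = qvalues(net, s);
      ai = (int)q.col(0).index_max();
    }
    double reward = arma::dot(rvec.row(ai).t(), x) + kpen[ai];
    x = A.slice(ai) * x;
    ++t;
    hist[t] = arma::accu(x);
    make_obs(t, s2);
    bool done = (t == horizon);

    bpos = (bpos + 1) % cap;
    if (bn < cap) ++bn;
    bufS.col(bpos) = s;
    bufS2.col(bpos) = s2;
    bufA[bpos] = ai;
    bufR[bpos] = reward;
    bufD[bpos] = done ? 1 : 0;
    ep_ret += reward;
    ++gstep;

    if (gstep > warmup && bn >= batch) {
      sample_distinct(bn, batch, bidx);
      arma::mat S = bufS.cols(bidx), S2 = bufS2.cols(bidx);
      // double-Q target: online net selects the next action, target net
      // evaluates it; terminal transitions use the reward alone
      arma::mat q2on = qvalues(net, S2);
      arma::mat q2t = qvalues(tgt, S2);
      arma::vec y(batch);
      for (int i = 0; i < batch; ++i) {
        unsigned b = bidx[i];
        if (bufD[b]) {
          y[i] = bufR[b];
        } else {
          arma::uword a2 = q2on.col(i).index_max();
          y[i] = bufR[b] + discount * q2t(a2, i);
        }
      }
      forward(net, S, H1, H2, Q);
      arma::mat dZ(n_actions, batch, arma::fill::zeros);
      double loss = 0;
      for (int i = 0; i < batch; ++i) {
        double err = Q(bufA[bidx[i]], i) - y[i];
        loss += err * err;
        dZ(bufA[bidx[i]], i) = 2.0 * err / batch;
      }
      loss /= batch;
      if (!std::isfinite(loss)) { diverged = true; break; }
      loss_sum += loss;
      ++loss_n;

      arma::mat gW3 = dZ * H2.t();
      arma::vec gb3 = arma::sum(dZ, 1);
      arma::mat d2 = (net.W3.t() * dZ) % (H2 > 0);
      arma::mat gW2 = d2 * H1.t();
      arma::vec gb2 = arma::sum(d2, 1);
      arma::mat d1 = (net.W2.t() * d2) % (H1 > 0);
      arma::mat gW1 = d1 * S.t();
      arma::vec gb1 = arma::sum(d1, 1);

      ++opt.it;
      double c1 = 1.0 - std::pow(0.9, (double)opt.it);
      double c2 = 1.0 - std::pow(0.999, (double)opt.it);
      adam_step(net.W1, opt.mW1, opt.vW1, gW1, lr, c1, c2);
      adam_step(net.b1, opt.mb1, opt.vb1, gb1, lr, c1, c2);
      adam_step(net.W2, opt.mW2, opt.vW2, gW2, lr, c1, c2);
      adam_step(net.b2, opt.mb2, opt.vb2, gb2, lr, c1, c2);
      adam_step(net.W3, opt.mW3, opt.vW3, gW3, lr, c1, c2);
      adam_step(net.b3, opt.mb3, opt.vb3, gb3, lr, c1, c2);

      if (gstep % sync == 0) tgt = net;
    }

    if (done) {
      ++resets;
      ep_returns.push_back(ep_ret);
      ep_losses.push_back(loss_n > 0 ? loss_sum / loss_n : NA_REAL);
      if (ep_ret > best) {
        best = ep_ret;
        best_episode = resets;
      }
      if (resets - best_episode >= patience) break;
      x = x0;
      hist[0] = arma::accu(x);
      t = 0;
      ep_ret = 0;
      loss_sum = 0;
      loss_n = 0;
      if (resets % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
    _["W1"] = net.W1, _["b1"] = net.b1,
    _["W2"] = net.W2, _["b2"] = net.b2,
    _["W3"] = net.W3, _["b3"] = net.b3,
    _["episode_returns"] = ep_returns,
    _["episode_losses"] = ep_losses,
    _["episodes"] = (int)ep_returns.size(),
    _["steps"] = (double)gstep,
    _["best_return"] = best,
    _["best_episode"] = best_episode,
    _["diverged"] = diverged);
}
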