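// Advantage actor-critic training loop on the latent stage simulator.
//
// n-step synchronous A2C: the agent rolls `n_step` environment steps under
// the current stochastic policy, computes bootstrapped n-step returns and
// advantages, and takes one batched Adam update of the actor and critic per
// rollout window. All configuration, network initialisation and result
// handling stay in R; random draws go through R's RNG so set.seed()
// controls training exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(arma::uword r, arma::uword c) {
    m.zeros(r, c);
    v.zeros(r, c);
  }
  void step(mat &p, const mat &g, double lr) {
    ++t;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

// 3-layer MLP (two ReLU hidden layers, linear head); samples are rows
struct Mlp {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
  Adam aW1, aW2, aW3, ab1, ab2, ab3;

  void from_list(const Rcpp::List &net) {
    Rcpp::List W = net["W"], b = net["b"];
    W1 = Rcpp::as<mat>(W[0]); W2 = Rcpp::as<mat>(W[1]); W3 = Rcpp::as<mat>(W[2]);
    b1 = arma::conv_to<rowvec>::from(Rcpp::as<vec>(b[0]));
    b2 = arma::conv_to<rowvec>::from(Rcpp::as<vec>(b[1]));
    b3 = arma::conv_to<rowvec>::from(Rcpp::as<vec>(b[2]));
    aW1.init(W1.n_rows, W1.n_cols); aW2.init(W2.n_rows, W2.n_cols);
    aW3.init(W3.n_rows, W3.n_cols);
    ab1.init(1, b1.n_elem); ab2.init(1, b2.n_elem); ab3.init(1, b3.n_elem);
  }
  Rcpp::List to_list() const {
    return Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::List::create(W1, W2, W3),
        Rcpp::Named("b") = Rcpp::List::create(
            arma::conv_to<vec>::from(b1), arma::conv_to<vec>::from(b2),
            arma::conv_to<vec>::from(b3)));
  }
  mat forward(const mat &X, mat &H1, mat &H2) const {
    H1 = X * W1;
    H1.each_row() += b1;
    H1.transform([](double x) { return x > 0 ? x : 0.0; });
    H2 = H1 * W2;
    H2.each_row() += b2;
    H2.transform([](double x) { return x > 0 ? x : 0.0; });
    mat out = H2 * W3;
    out.each_row() += b3;
    return out;
  }
  // single-sample forward without gradient bookkeeping
  rowvec forward1(const rowvec &x) const {
    rowvec h1 = x * W1 + b1;
    h1.transform([](double v) { return v > 0 ? v : 0.0; });
    rowvec h2 = h1 * W2 + b2;
    h2.transform([](double v) { return v > 0 ? v : 0.0; });
    return h2 * W3 + b3;
  }
  void update(const mat &X, const mat &H1, const mat &H2, const mat &Dout,
              double lr) {
    mat gW3 = H2.t() * Dout;
    mat d2 = Dout * W3.t();
    d2.elem(arma::find(H2 <= 0)).zeros();
    mat gW2 = H1.t() * d2;
    mat d1 = d2 * W2.t();
    d1.elem(arma::find(H1 <= 0)).zeros();
    mat gW1 = X.t() * d1;
    aW3.step(W3, gW3, lr);
    aW2.step(W2, gW2, lr);
    aW1.step(W1, gW1, lr);
    mat mb;
    mb = b3; ab3.step(mb, arma::sum(Dout, 0), lr); b3 = mb.row(0);
    mb = b2; ab2.step(mb, arma::sum(d2, 0), lr);   b2 = mb.row(0);
    mb = b1; ab1.step(mb, arma::sum(d1, 0), lr);   b1 = mb.row(0);
  }
  vec params() const {
    return arma::join_vert(
        arma::join_vert(arma::vectorise(W1), arma::vectorise(W2)),
        arma::join_vert(arma::vectorise(W3),
                        arma::join_vert(arma::join_vert(b1.t(), b2.t()), b3.t())));
  }
  void set_params(const vec &p) {
    arma::uword k = 0;
    auto take_mat = [&](mat &M) {
      M = arma::reshape(p.subvec(k, k + M.n_elem - 1), M.n_rows, M.n_cols);
      k += M.n_elem;
    };
    auto take_row = [&](rowvec &v) {
      v = p.subvec(k, k + v.n_elem - 1).t();
      k += v.n_elem;
    };
    take_mat(W1); take_mat(W2); take_mat(W3);
    take_row(b1); take_row(b2); take_row(b3);
  }
};

rowvec softmax_row(const rowvec &logits) {
  rowvec e = arma::exp(logits - logits.max());
  return e / arma::accu(e);
}

void project_simplex4(vec &z) {
  for (int i = 0; i < 4; ++i)
    if (z(i) < 0) z(i) = 0;
  z /= arma::accu(z);
}

// one environment step under the treatment-effect modulation
vec env_step(const vec &z, double e, double d, const vec &kn, const vec &kab,
             double dt) {
  const double sg = (z(3) <= 0.5) ? 1.0 : -1.0;
  const double k1 = kn(0) + kab(0);
  const double k2 = kn(1) + std::max(0.0, kab(1) + 0.1 * sg * std::sin(2 * M_PI * e));
  const double k3 = kn(2) + std::max(0.0, kab(2) + 0.1 * sg * std::sin(2 * M_PI * d));
  vec z2(4);
  z2(0) = z(0) - dt * k1 * z(0);
  z2(1) = z(1) + dt * (k1 * z(0) - k2 * z(1));
  z2(2) = z(2) + dt * (k2 * z(1) - k3 * z(2));
  z2(3) = z(3) + dt * k3 * z(2);
  project_simplex4(z2);
  return z2;
}

vec ref_step(const vec &z, const mat &Mref, double dt) {
  vec z2 = z + dt * (Mref * z);
  project_simplex4(z2);
  return z2;
}

double greedy_heal_time(const Mlp &actor, const vec &grid_e, const vec &grid_d,
                        const vec &kn, const vec &kab, double dt, double thr,
                        int max_steps) {
  vec z = {1, 0, 0, 0};
  double t = 0;
  for (int s = 0; s < max_steps; ++s) {
    rowvec logits = actor.forward1(z.t());
    arma::uword a = logits.index_max();
    vec z2 = env_step(z, grid_e(a), grid_d(a), kn, kab, dt);
    if (z2(3) >= thr)
      return t + dt * (thr - z(3)) / (z2(3) - z(3));
    z = z2;
    t += dt;
  }
  return NA_REAL;
}

}  // namespace

// [[Rcpp::export(name = ".a2c_train_cpp")]]
Rcpp::List a2c_train_cpp(Rcpp::List actor_init, Rcpp::List critic_init,
                         arma::vec kn, arma::vec kab, double dt, double thr,
                         arma::mat Mref, arma::vec grid_e, arma::vec grid_d,
                         int reward_mode, double eta, double gamma,
                         double lr_actor, double lr_critic,
                         double entropy_coef, bool entropy_anneal,
                         int episodes, int steps,
                         int n_step, int eval_every, int eval_rollouts,
                         int burn_in) {
  Mlp actor, critic;
  actor.from_list(actor_init);
  critic.from_list(critic_init);
  const int nA = grid_e.n_elem;

  vec polyak_sum = arma::zeros<vec>(actor.params().n_elem);
  int polyak_n = 0;

  Rcpp::NumericVector ep_return(episodes);
  std::vector<double> eval_ep, eval_heal;

  Rcpp::RNGScope scope;

  mat X(n_step, 4), H1, H2, CH1, CH2;
  arma::ivec act_idx(n_step);
  vec rew(n_step);

  for (int ep = 1; ep <= episodes; ++ep) {
    // linear entropy annealing lets the policy commit late in training
    const double ent_c = entropy_anneal
        ? entropy_coef * (1.0 - (double)(ep - 1) / episodes)
        : entropy_coef;
    vec z = {1, 0, 0, 0};
    double ret = 0, disc = 1;
    int done_steps = 0;
    while (done_steps < steps) {
      const int L = std::min(n_step, steps - done_steps);
      // ---- rollout window under the current stochastic policy ----
      for (int k = 0; k < L; ++k) {
        X.row(k) = z.t();
        rowvec pr = softmax_row(actor.forward1(z.t()));
        double u = R::unif_rand(), acc = 0;
        int a = nA - 1;
        for (int j = 0; j < nA; ++j) {
          acc += pr(j);
          if (u <= acc) { a = j; break; }
        }
        act_idx(k) = a;
        vec zref = ref_step(z, Mref, dt);
        vec z2 = env_step(z, grid_e(a), grid_d(a), kn, kab, dt);
        double r = (reward_mode == 1)
                       ? std::exp(-eta * arma::accu(arma::square(zref - z2)))
                       : ((z2(3) < thr) ? -1.0 : 0.0);
        rew(k) = r;
        ret += disc * r;
        disc *= gamma;
        z = z2;
      }
      done_steps += L;

      // ---- n-step returns with critic bootstrap at the window end ----
      const mat Xw = X.rows(0, L - 1);
      vec v = critic.forward(Xw, CH1, CH2).col(0);
      double boot = arma::as_scalar(critic.forward1(z.t()));
      vec G(L);
      double g = boot;
      for (int k = L - 1; k >= 0; --k) {
        g = rew(k) + gamma * g;
        G(k) = g;
      }
      vec adv = G - v;

      // ---- critic: mean squared error against the n-step returns ----
      mat dV = 2.0 * (v - G) / L;
      critic.update(Xw, CH1, CH2, dV, lr_critic);

      // ---- actor: advantage-weighted log-prob ascent + entropy bonus ----
      mat logits = actor.forward(Xw, H1, H2);
      mat Dl(L, nA);
      for (int k = 0; k < L; ++k) {
        rowvec pr = softmax_row(logits.row(k));
        rowvec logp = arma::log(pr);
        rowvec dlogp = -pr;
        dlogp(act_idx(k)) += 1.0;
        rowvec dent = -pr % (logp + 1) + pr * arma::accu(pr % (logp + 1));
        Dl.row(k) = -(dlogp * adv(k) + ent_c * dent) / L;
      }
      actor.update(Xw, H1, H2, Dl, lr_actor);
    }
    ep_return[ep - 1] = ret;
    if (ep > burn_in) {
      polyak_sum += actor.params();
      ++polyak_n;
    }
    if (eval_every > 0 && ep % eval_every == 0) {
      double h = 0;
      for (int j = 0; j < eval_rollouts; ++j)
        h += greedy_heal_time(actor, grid_e, grid_d, kn, kab, dt, thr, steps);
      eval_ep.push_back(ep);
      eval_heal.push_back(h / eval_rollouts);
    }
  }

  Rcpp::List actor_final = actor.to_list();
  Mlp polyak = actor;
  if (polyak_n > 0) polyak.set_params(polyak_sum / polyak_n);

  return Rcpp::List::create(
      Rcpp::Named("actor") = polyak.to_list(),
      Rcpp::Named("actor_final") = actor_final,
      Rcpp::Named("critic") = critic.to_list(),
      Rcpp::Named("episode_return") = ep_return,
      Rcpp::Named("eval_episode") = eval_ep,
      Rcpp::Named("eval_healing_days") = eval_heal);
}

// [[Rcpp::export(name = ".a2c_eval_cpp")]]
double a2c_eval_cpp(Rcpp::List actor_list, arma::vec kn, arma::vec kab,
                    double dt, double thr, arma::vec grid_e, arma::vec grid_d,
                    int max_steps) {
  Mlp actor;
  actor.from_list(actor_list);
  return greedy_heal_time(actor, grid_e, grid_d, kn, kab, dt, thr, max_steps);
}
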