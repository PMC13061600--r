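#include <Rcpp.h>
using namespace Rcpp;

// Per-trial likelihood filters for all candidate models. These mirror the
// R-level single-step functions exactly; fitting and the validation
// harnesses call these for speed.

static const double P_FLOOR = 1e-12;

static inline NumericVector softmax_v(const NumericVector& x, double temp) {
  int n = x.size();
  NumericVector z(n);
  double mx = temp * x[0];
  for (int i = 1; i < n; ++i) mx = std::max(mx, temp * x[i]);
  double s = 0.0;
  for (int i = 0; i < n; ++i) { z[i] = std::exp(temp * x[i] - mx); s += z[i]; }
  for (int i = 0; i < n; ++i) z[i] /= s;
  return z;
}

static inline NumericVector matvec(const NumericMatrix& pi,
                                   const NumericVector& p) {
  int n = pi.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += pi(i, j) * p[j];
    out[i] = s;
  }
  return out;
}

// level-k opponent prediction: base attraction by parity (even -> a_opp,
// odd -> a_self), then k noisy best-response iterations.
static NumericVector level_pred(int k, const NumericVector& a_self,
                                const NumericVector& a_opp,
                                const NumericMatrix& pis, double beta) {
  NumericVector p = softmax_v((k % 2 == 0) ? a_opp : a_self, beta);
  for (int i = 0; i < k; ++i) p = softmax_v(matvec(pis, p), beta);
  return p;
}

// [[Rcpp::export]]
List chase_filter_cpp(List blocks, NumericMatrix pi, double alpha,
                      double beta, double gamma, double lambda, int kappa,
                      bool want_derivs) {
  int n = pi.nrow();
  NumericMatrix pis(clone(pi));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (pis(i, j) == -1.0) pis(i, j) = -lambda;

  int ntot = 0;
  for (int b = 0; b < blocks.size(); ++b)
    ntot += as<IntegerMatrix>(blocks[b]).nrow();

  NumericVector cv(want_derivs ? ntot : 0), ape(want_derivs ? ntot : 0),
      bu(want_derivs ? ntot : 0), p_own(want_derivs ? ntot : 0);
  IntegerVector modal(want_derivs ? ntot : 0);
  double ll = 0.0;
  int row = 0;

  for (int b = 0; b < blocks.size(); ++b) {
    IntegerMatrix acts = blocks[b];
    NumericVector a_self(n, 1.0 / n), a_opp(n, 1.0 / n);
    NumericVector bel(kappa, 1.0 / kappa);
    for (int t = 0; t < acts.nrow(); ++t) {
      int own = acts(t, 0), opp = acts(t, 1);
      // (i) per-level predictions, integrated policy
      std::vector<NumericVector> preds(kappa);
      NumericVector pred_opp(n, 0.0);
      for (int k = 0; k < kappa; ++k) {
        preds[k] = level_pred(k, a_self, a_opp, pis, beta);
        for (int i = 0; i < n; ++i) pred_opp[i] += bel[k] * preds[k][i];
      }
      NumericVector ev = matvec(pis, pred_opp);
      NumericVector pol = softmax_v(ev, beta);
      ll += std::log(std::max(pol[own], P_FLOOR));
      int arg = 0;
      for (int k = 1; k < kappa; ++k) if (bel[k] > bel[arg]) arg = k;
      // (ii) feedback: APE, level likelihood, distorted Bayes update
      NumericVector L(kappa);
      for (int k = 0; k < kappa; ++k) L[k] = preds[k][opp];
      NumericVector lhat = softmax_v(L, gamma);
      NumericVector post(kappa);
      double s = 0.0;
      for (int k = 0; k < kappa; ++k) { post[k] = lhat[k] * bel[k]; s += post[k]; }
      double kl = 0.0;
      for (int k = 0; k < kappa; ++k) {
        post[k] /= s;
        if (post[k] > 0) kl += post[k] * std::log(post[k] / bel[k]);
      }
      if (kl < 0) kl = 0;  // KL >= 0; guards rounding at identity updates
      if (want_derivs) {
        cv[row] = ev[own];
        ape[row] = 1.0 - pred_opp[opp];
        bu[row] = kl;
        p_own[row] = pol[own];
        modal[row] = arg + 1;
      }
      bel = post;
      // (iii) attraction learning from both observed actions
      for (int i = 0; i < n; ++i) {
        a_self[i] += alpha * ((i == own ? 1.0 : 0.0) - a_self[i]);
        a_opp[i]  += alpha * ((i == opp ? 1.0 : 0.0) - a_opp[i]);
      }
      ++row;
    }
  }
  if (want_derivs)
    return List::create(_["loglik"] = ll, _["cv"] = cv, _["ape"] = ape,
                        _["bu"] = bu, _["p_own"] = p_own, _["modal"] = modal);
  return List::create(_["loglik"] = ll);
}

// [[Rcpp::export]]
double rl_loglik_cpp(List blocks, NumericMatrix pi, double alpha,
                     double beta, bool decay_unchosen) {
  int n = pi.nrow();
  NumericVector q0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += pi(i, j);
    q0[i] = s / n;  // expected payoff vs a uniformly random opponent
  }
  double ll = 0.0;
  for (int b = 0; b < blocks.size(); ++b) {
    IntegerMatrix acts = blocks[b];
    NumericVector q(clone(q0));
    for (int t = 0; t < acts.nrow(); ++t) {
      int own = acts(t, 0), opp = acts(t, 1);
      NumericVector pol = softmax_v(q, beta);
      ll += std::log(std::max(pol[own], P_FLOOR));
      double pay = pi(own, opp);
      if (decay_unchosen) {
        for (int i = 0; i < n; ++i)
          q[i] += alpha * ((i == own ? pay : 0.0) - q[i]);
      } else {
        q[own] += alpha * (pay - q[own]);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double ewa_loglik_cpp(List blocks, NumericMatrix pi, double delta,
                      double phi, double rho, double beta) {
  int n = pi.nrow();
  NumericVector a0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += pi(i, j);
    a0[i] = s / n;
  }
  double ll = 0.0;
  for (int b = 0; b < blocks.size(); ++b) {
    IntegerMatrix acts = blocks[b];
    NumericVector a(clone(a0));
    double nexp = 0.0;  // experience-equivalent, starts at zero
    for (int t = 0; t < acts.nrow(); ++t) {
      int own = acts(t, 0), opp = acts(t, 1);
      NumericVector pol = softmax_v(a, beta);
      ll += std::log(std::max(pol[own], P_FLOOR));
      double n1 = rho * nexp + 1.0;
      for (int i = 0; i < n; ++i) {
        double w = delta + (1.0 - delta) * (i == own ? 1.0 : 0.0);
        a[i] = (phi * nexp * a[i] + w * pi(i, opp)) / n1;
      }
      nexp = n1;
    }
  }
  return ll;
}

// Self-tuning EWA: phi(t) from a surprise index comparing cumulative and
// recent-window opponent action frequencies; per-action attention
// delta_j(t) = 1 iff the foregone payoff weakly exceeds the realized one;
// rho = phi(t). Only beta is free.
// [[Rcpp::export]]
double stewa_loglik_cpp(List blocks, NumericMatrix pi, double beta,
                        int window) {
  int n = pi.nrow();
  NumericVector a0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += pi(i, j);
    a0[i] = s / n;
  }
  double ll = 0.0;
  for (int b = 0; b < blocks.size(); ++b) {
    IntegerMatrix acts = blocks[b];
    int T = acts.nrow();
    NumericVector a(clone(a0));
    double nexp = 0.0;
    std::vector<int> opp_hist;
    NumericVector counts(n, 0.0);
    for (int t = 0; t < T; ++t) {
      int own = acts(t, 0), opp = acts(t, 1);
      NumericVector pol = softmax_v(a, beta);
      ll += std::log(std::max(pol[own], P_FLOOR));
      // change detector over opponent history including this trial
      opp_hist.push_back(opp);
      counts[opp] += 1.0;
      int tt = t + 1;
      int w = std::min(window, tt);
      NumericVector recent(n, 0.0);
      for (int u = tt - w; u < tt; ++u) recent[opp_hist[u]] += 1.0 / w;
      double surprise = 0.0;
      for (int i = 0; i < n; ++i) {
        double diff = counts[i] / tt - recent[i];
        surprise += diff * diff;
      }
      double phit = 1.0 - 0.5 * surprise;
      double realized = pi(own, opp);
      double n1 = phit * nexp + 1.0;  // rho = phi(t)
      for (int i = 0; i < n; ++i) {
        double w_i = (i == own || pi(i, opp) >= realized) ? 1.0 : 0.0;
        a[i] = (phit * nexp * a[i] + w_i * pi(i, opp)) / n1;
      }
      nexp = n1;
    }
  }
  return ll;
}

// argmax set as a (possibly split) one-hot; ties share mass uniformly
static NumericVector argmax_split(const NumericVector& ev,
                                  std::vector<int>* set = nullptr) {
  int n = ev.size();
  double mx = ev[0];
  for (int i = 1; i < n; ++i) mx = std::max(mx, ev[i]);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i)
    if (ev[i] >= mx - 1e-12) idx.push_back(i);
  NumericVector p(n, 0.0);
  for (size_t i = 0; i < idx.size(); ++i) p[idx[i]] = 1.0 / idx.size();
  if (set) *set = idx;
  return p;
}

// Confidence-based theory-of-mind model with fixed own level k.
// [[Rcpp::export]]
List tomk_filter_cpp(List blocks, NumericMatrix pi, double alpha,
                     double beta, int k, double c_opp, double c_init) {
  int n = pi.nrow();
  double ll = 0.0;
  for (int b = 0; b < blocks.size(); ++b) {
    IntegerMatrix acts = blocks[b];
    NumericVector a_self(n, 1.0 / n), a_opp(n, 1.0 / n);
    NumericVector conf(k > 0 ? k : 0, c_init);
    for (int t = 0; t < acts.nrow(); ++t) {
      int own = acts(t, 0), opp = acts(t, 1);
      // EV chains: own (confidence-weighted) and the opponent's
      // simulation (fixed confidence c_opp at every level)
      NumericVector ev_me = matvec(pi, a_opp);       // level 0
      NumericVector ev_opp = matvec(pi, a_self);     // opponent level 0
      NumericVector ev_me_sim(clone(ev_me));         // me, as the opponent models me
      std::vector<std::vector<int> > opp_argmax(k > 0 ? k : 0);
      for (int j = 1; j <= k; ++j) {
        std::vector<int> set;
        NumericVector p_opp = argmax_split(ev_opp, &set);
        opp_argmax[j - 1] = set;
        NumericVector br = matvec(pi, p_opp);
        NumericVector ev_me_new(n);
        for (int i = 0; i < n; ++i)
          ev_me_new[i] = conf[j - 1] * br[i] + (1.0 - conf[j - 1]) * ev_me[i];
        // opponent's next level responds to their argmax model of me
        NumericVector p_me = argmax_split(ev_me_sim);
        NumericVector br_opp = matvec(pi, p_me);
        NumericVector ev_opp_new(n), ev_me_sim_new(n);
        for (int i = 0; i < n; ++i) {
          ev_opp_new[i] = c_opp * br_opp[i] + (1.0 - c_opp) * ev_opp[i];
          ev_me_sim_new[i] = c_opp * br[i] + (1.0 - c_opp) * ev_me_sim[i];
        }
        ev_me = ev_me_new;
        ev_opp = ev_opp_new;
        ev_me_sim = ev_me_sim_new;
      }
      NumericVector pol = softmax_v(ev_me, beta);
      ll += std::log(std::max(pol[own], P_FLOOR));
      // confidence updates: credit only the lowest opponent level whose
      // argmax prediction covers the observed action; higher matching
      // levels stay constant; everything else decays
      if (k > 0) {
        std::vector<bool> matched(k, false);
        for (int j = 0; j < k; ++j)
          for (size_t u = 0; u < opp_argmax[j].size(); ++u)
            if (opp_argmax[j][u] == opp) matched[j] = true;
        int lowest = -1;
        for (int j = 0; j < k; ++j) if (matched[j]) { lowest = j; break; }
        for (int j = 0; j < k; ++j) {
          if (matched[j] && j > lowest) continue;   // explained by lower level
          double ip = (matched[j] && j == lowest) ? 1.0 : 0.0;
          conf[j] = (1.0 - alpha) * conf[j] + alpha * ip;
        }
      }
      for (int i = 0; i < n; ++i) {
        a_self[i] += alpha * ((i == own ? 1.0 : 0.0) - a_self[i]);
        a_opp[i]  += alpha * ((i == opp ? 1.0 : 0.0) - a_opp[i]);
      }
    }
  }
  return List::create(_["loglik"] = ll);
}
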