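#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shared log-likelihood of the three coupled blocks of the indirect
// comparison model (flat Dirichlet priors contribute a constant):
//   x_C1 ~ Mult(p_C1), x_C2 ~ Mult(p_C2), x_T2 ~ Mult(p_T2)
// with p_T2_j proportional to p_ind_j * p_C2_j / p_C1_j.
// (x_T1 ~ Mult(p_T1) factorises out and is sampled by exact Gibbs.)
static double loglik_coupled(const std::vector<double>& pC1,
                             const std::vector<double>& pC2,
                             const std::vector<double>& pind,
                             const IntegerVector& xC1,
                             const IntegerVector& xC2,
                             const IntegerVector& xT2) {
  const int k = (int)pC1.size();
  double ll = 0.0, S = 0.0;
  std::vector<double> u(k);
  for (int j = 0; j < k; ++j) {
    ll += xC1[j] * std::log(pC1[j]) + xC2[j] * std::log(pC2[j]);
    u[j] = pind[j] * pC2[j] / pC1[j];
    S += u[j];
  }
  const double logS = std::log(S);
  for (int j = 0; j < k; ++j) ll += xT2[j] * (std::log(u[j]) - logS);
  return ll;
}

// softmax with a fixed reference coordinate (theta[ref] == 0 implicitly)
static void theta_to_p(const std::vector<double>& theta, int ref,
                       std::vector<double>& p) {
  const int k = (int)p.size();
  double mx = 0.0;
  int t = 0;
  std::vector<double> full(k);
  for (int j = 0; j < k; ++j) {
    full[j] = (j == ref) ? 0.0 : theta[t++];
    if (full[j] > mx) mx = full[j];
  }
  double s = 0.0;
  for (int j = 0; j < k; ++j) { p[j] = std::exp(full[j] - mx); s += p[j]; }
  for (int j = 0; j < k; ++j) p[j] /= s;
}

static double log_jacobian(const std::vector<double>& p) {
  double s = 0.0;
  for (size_t j = 0; j < p.size(); ++j) s += std::log(p[j]);
  return s;
}

// [[Rcpp::export]]
List mnitc_sample_cpp(IntegerVector xC1, IntegerVector xT1,
                      IntegerVector xC2, IntegerVector xT2,
                      int draws, int burn_in,
                      NumericVector init_pC1, NumericVector init_pC2,
                      NumericVector init_pind,
                      double init_step, bool adapt) {
  const int k = xC1.size();
  const int d = k - 1;
  const double target_acc = 0.30;

  // reference coordinate per block: the best-identified category
  auto ref_of = [&](const IntegerVector& x) {
    int r = 0;
    for (int j = 1; j < k; ++j) if (x[j] > x[r]) r = j;
    return r;
  };
  const int refC1 = ref_of(xC1), refC2 = ref_of(xC2), refT2 = ref_of(xT2);

  auto p_to_theta = [&](const NumericVector& p, int ref) {
    std::vector<double> th(d);
    int t = 0;
    for (int j = 0; j < k; ++j)
      if (j != ref) th[t++] = std::log(p[j]) - std::log(p[ref]);
    return th;
  };

  std::vector<double> thC1 = p_to_theta(init_pC1, refC1);
  std::vector<double> thC2 = p_to_theta(init_pC2, refC2);
  std::vector<double> thIn = p_to_theta(init_pind, refT2);
  std::vector<double> pC1(k), pC2(k), pind(k), pT1(k);
  theta_to_p(thC1, refC1, pC1);
  theta_to_p(thC2, refC2, pC2);
  theta_to_p(thIn, refT2, pind);

  double ll = loglik_coupled(pC1, pC2, pind, xC1, xC2, xT2);
  double stepC1 = init_step, stepC2 = init_step, stepIn = init_step;
  double accC1 = 0.0, accC2 = 0.0, accIn = 0.0;

  NumericMatrix outC1(draws, k), outT1(draws, k), outC2(draws, k),
      outInd(draws, k);

  std::vector<double> prop(d), pprop(k);
  const int total = burn_in + draws;
  for (int it = 0; it < total; ++it) {
    // exact Gibbs for the conjugate treatment block of trial 1
    double sT1 = 0.0;
    for (int j = 0; j < k; ++j) { pT1[j] = R::rgamma(xT1[j] + 1.0, 1.0); sT1 += pT1[j]; }
    for (int j = 0; j < k; ++j) pT1[j] /= sT1;

    // random-walk Metropolis per coupled block on alr coordinates
    struct Blk { std::vector<double>* th; std::vector<double>* p; int ref;
                 double* step; double* acc; };
    Blk blocks[3] = {{&thC1, &pC1, refC1, &stepC1, &accC1},
                     {&thC2, &pC2, refC2, &stepC2, &accC2},
                     {&thIn, &pind, refT2, &stepIn, &accIn}};
    for (int b = 0; b < 3; ++b) {
      for (int j = 0; j < d; ++j)
        prop[j] = (*blocks[b].th)[j] + (*blocks[b].step) * R::norm_rand();
      theta_to_p(prop, blocks[b].ref, pprop);
      double ll_new;
      if (b == 0) ll_new = loglik_coupled(pprop, pC2, pind, xC1, xC2, xT2);
      else if (b == 1) ll_new = loglik_coupled(pC1, pprop, pind, xC1, xC2, xT2);
      else ll_new = loglik_coupled(pC1, pC2, pprop, xC1, xC2, xT2);
      const double log_ratio = (ll_new + log_jacobian(pprop)) -
                               (ll + log_jacobian(*blocks[b].p));
      const bool accept = std::log(R::unif_rand()) < log_ratio;
      if (accept) {
        *blocks[b].th = prop;
        *blocks[b].p = pprop;
        ll = ll_new;
      }
      if (it < burn_in && adapt) {
        const double gamma = 10.0 / (100.0 + it);
        *blocks[b].step *= std::exp(gamma * ((accept ? 1.0 : 0.0) - target_acc));
      } else if (it >= burn_in) {
        *blocks[b].acc += accept ? 1.0 : 0.0;
      }
    }

    if (it >= burn_in) {
      const int r = it - burn_in;
      for (int j = 0; j < k; ++j) {
        outC1(r, j) = pC1[j];
        outT1(r, j) = pT1[j];
        outC2(r, j) = pC2[j];
        outInd(r, j) = pind[j];
      }
    }
    if ((it & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["p_C1"] = outC1, _["p_T1"] = outT1, _["p_C2"] = outC2,
      _["p_ind"] = outInd,
      _["acceptance"] = NumericVector::create(accC1 / draws, accC2 / draws,
                                              accIn / draws),
      _["steps"] = NumericVector::create(stepC1, stepC2, stepIn));
}
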