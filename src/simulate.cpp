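#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time Metropolis chain over the four species
// {closed,open} x {protonated,deprotonated}. Protonation flips are
// attempted every mc_interval steps with acceptance min(1, 10^(pH-pK_conf))
// for deprotonation (and the reciprocal for reprotonation); conformational
// flips are attempted with probability p_conf_attempt per step with
// acceptance min(1, K) for closed->open, K = K_H (protonated) or K_D
// (deprotonated). Uses R's RNG so results are reproducible via set.seed().

// [[Rcpp::export]]
List simulate_chain_cpp(double pk_closed, double pk_open,
                        double kd, double kh, double ph,
                        int n_steps, int mc_interval, double p_conf_attempt,
                        int start_open, int start_protonated) {
  IntegerVector open_out(n_steps), prot_out(n_steps);
  int open = start_open, prot = start_protonated;

  const double acc_dep_closed = std::min(1.0, std::pow(10.0, ph - pk_closed));
  const double acc_pro_closed = std::min(1.0, std::pow(10.0, pk_closed - ph));
  const double acc_dep_open   = std::min(1.0, std::pow(10.0, ph - pk_open));
  const double acc_pro_open   = std::min(1.0, std::pow(10.0, pk_open - ph));
  const double acc_co_prot = std::min(1.0, kh);
  const double acc_oc_prot = std::min(1.0, 1.0 / kh);
  const double acc_co_dep  = std::min(1.0, kd);
  const double acc_oc_dep  = std::min(1.0, 1.0 / kd);

  for (int i = 0; i < n_steps; ++i) {
    if (mc_interval > 0 && ((i + 1) % mc_interval) == 0) {
      double a = open ? (prot ? acc_dep_open : acc_pro_open)
                      : (prot ? acc_dep_closed : acc_pro_closed);
      if (unif_rand() < a) prot = 1 - prot;
    }
    if (p_conf_attempt > 0.0 && unif_rand() < p_conf_attempt) {
      double a = prot ? (open ? acc_oc_prot : acc_co_prot)
                      : (open ? acc_oc_dep  : acc_co_dep);
      if (unif_rand() < a) open = 1 - open;
    }
    open_out[i] = open;
    prot_out[i] = prot;
  }
  return List::create(_["open"] = open_out, _["protonated"] = prot_out);
}
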