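#include <Rcpp.h>
using namespace Rcpp;

// Event-driven simulation of one formin-bound filament under constant
// conditions.  Rates are re-evaluated after every event, so the
// length-proportional force protocol is exact (force is piecewise constant
// between events).  Uses R's RNG: reproducibility is governed by set.seed()
// on the calling side.
//
// force_mode: 0 = zero, 1 = constant, 2 = length-proportional (kappa * L)
// route codes: 0 = censored at horizon, 1 = open route, 2 = transition route
//
// k_add0    : p_open-free addition rate, k_on*actin*(1+boost)*(1-pi_solution)
// k_offO0eff: p_open-free open-route rate, k_offO0*multipliers*(1-pi_solution)
// Both are multiplied by the instantaneous open-state occupancy p_open(f).

static const double SUBUNIT_UM = 0.0027; // 2.7 nm per subunit

// [[Rcpp::export]]
List sim_filament_cpp(double k_add0, double K_co, double delta_step,
                      double k_offO0eff, double delta_O,
                      double k_offT0eff, double delta_T, double k_decay,
                      double pi_fh1, double kBT,
                      int force_mode, double f_const, double kappa,
                      double t0, double L0, double horizon,
                      bool record, bool explicit_transition) {
  if (horizon <= t0) stop("sim_filament_cpp: horizon must exceed start time");
  double t = t0, L = L0;
  std::vector<double> ev_t, ev_L;
  if (record) { ev_t.push_back(t); ev_L.push_back(L); }

  int route = 0;            // censored unless a dissociation happens
  bool dissociated = false;
  const double dmax = std::max(std::max(delta_O, delta_T), delta_step);
  long iter = 0, iter_max = 200000000L;

  while (true) {
    if (++iter > iter_max) stop("sim_filament_cpp: event budget exceeded");
    double f = (force_mode == 0) ? 0.0 :
               (force_mode == 1) ? f_const : kappa * L;
    if (f * dmax / kBT > 700.0)
      stop("sim_filament_cpp: f*delta/kBT > 700 (unphysical parameters)");
    double po = 1.0 / (1.0 + K_co * std::exp(-f * delta_step / kBT));
    double r_add  = po * k_add0;
    double r_open = po * k_offO0eff * std::exp(f * delta_O / kBT);
    double r_tot  = r_add + r_open;
    if (r_tot <= 0.0) { t = horizon; break; }    // nothing can happen
    t += R::exp_rand() / r_tot;
    if (t >= horizon) { t = horizon; break; }    // censored
    if (R::unif_rand() * r_tot < r_open) {       // open-route dissociation
      route = 1; dissociated = true;
      if (record) { ev_t.push_back(t); ev_L.push_back(L); }
      break;
    }
    // subunit addition
    L += SUBUNIT_UM;
    if (record) { ev_t.push_back(t); ev_L.push_back(L); }
    // transition-state trial at the post-addition force
    double fT = (force_mode == 0) ? 0.0 :
                (force_mode == 1) ? f_const : kappa * L;
    double kT = k_offT0eff * std::exp(fT * delta_T / kBT);
    double p_exit_diss = kT / (kT + k_decay);
    if (explicit_transition) {
      // dwell in the transition state before it resolves
      t += R::exp_rand() / (kT + k_decay);
      if (t >= horizon) { t = horizon; break; }
    }
    if (R::unif_rand() < p_exit_diss * (1.0 - pi_fh1)) {
      route = 2; dissociated = true;
      if (record) { ev_t.push_back(t); ev_L.push_back(L); }
      break;
    }
  }

  return List::create(
    _["t_end"] = t,
    _["L_end"] = L,
    _["dissociated"] = dissociated,
    _["route"] = route,
    _["event_times"] = record ? wrap(ev_t) : R_NilValue,
    _["lengths"] = record ? wrap(ev_L) : R_NilValue);
}
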