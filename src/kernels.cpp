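#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the coupled food (F), wild-type (B), mutant (M) system
// on a uniform cell-centred grid over [0, L].
//
// Conservative finite-volume form: for each species the cell update is
// (flux_in - flux_out)/dx plus the local reaction term.  Advection is
// first-order upwind (v >= 0), diffusion uses central two-point fluxes.
// Boundary faces carry the physical fluxes: the x = 0 face has total flux
// vFin for food and 0 for bacteria (no bacterial inflow); the x = L face
// has zero diffusive flux and free advective outflow v * c_n.
//
// y is laid out as c(F, B, M), each of length n.
// [[Rcpp::export]]
NumericVector gut_rhs_cpp(NumericVector y, int n, double dx, double v,
                          double D, double r, double k, double vFin,
                          double alpha) {
  if ((int)y.size() != 3 * n) stop("state length must be 3 * n_cells");
  NumericVector dy(3 * n);
  const double *F = y.begin();
  const double *B = y.begin() + n;
  const double *M = y.begin() + 2 * n;
  double *dF = dy.begin();
  double *dB = dy.begin() + n;
  double *dM = dy.begin() + 2 * n;
  const double Ddx = D / dx;

  // transport: species s with prescribed total flux at the inlet face
  for (int s = 0; s < 3; ++s) {
    const double *c = y.begin() + s * n;
    double *dc = dy.begin() + s * n;
    double flux_left = (s == 0) ? vFin : 0.0;  // inlet face
    for (int i = 0; i < n; ++i) {
      double flux_right;
      if (i < n - 1) {
        flux_right = v * c[i] - Ddx * (c[i + 1] - c[i]);
      } else {
        flux_right = v * c[i];  // outlet: zero diffusive flux, free outflow
      }
      dc[i] = (flux_left - flux_right) / dx;
      flux_left = flux_right;
    }
  }

  // reaction: Monod growth r*F/(k+F), food consumption scaled by 1/alpha
  for (int i = 0; i < n; ++i) {
    double Fp = F[i] > 0.0 ? F[i] : 0.0;  // guard tiny negatives from the stiff stepper
    double mono = Fp / (k + Fp);
    dF[i] -= (r / alpha) * (B[i] + M[i]) * mono;
    dB[i] += r * mono * B[i];
    dM[i] += r * mono * M[i];
  }
  return dy;
}

// One stochastic replicate of the individual-based compartment model.
//
// Bacteria are integer counts per compartment.  Per time step dt each
// individual divides with probability rho_i * dt (rho_i = r F_i/(k+F_i)),
// hops right with probability (D/dx^2 + v/dx) * dt and left with
// probability (D/dx^2) * dt (biased hopping whose compartment master
// equation has the upwind finite-volume scheme as its mean field).
// The first compartment has no left hop (zero bacterial flux at the
// entrance); the last hops right at rate v/dx only (zero diffusive
// outflow), and such a hop removes the individual from the system.
// Food is a deterministic per-compartment field updated with the same
// upwind transport; consumption is tied to realised divisions so that
// food consumed equals births/alpha exactly.
//
// Runs until t_final, or earlier if the mutant lineage goes extinct
// (only when mutants were introduced).  Uses R's RNG (seed from R).
// [[Rcpp::export]]
List stochastic_replicate_cpp(IntegerVector B_init, IntegerVector M_init,
                              NumericVector F_init, double dx, double v,
                              double D, double r, double k, double vFin,
                              double alpha, double S, double dt,
                              double t_final, bool closed, bool fixed_food,
                              double pop_cap) {
  int n = B_init.size();
  if ((int)M_init.size() != n || (int)F_init.size() != n)
    stop("B, M, F must have equal length");
  std::vector<double> F(F_init.begin(), F_init.end());
  std::vector<double> Fnew(n);
  std::vector<int> B(B_init.begin(), B_init.end());
  std::vector<int> M(M_init.begin(), M_init.end());
  std::vector<int> Bn(n), Mn(n);

  const double h_diff = D / (dx * dx);
  const double h_adv = closed ? 0.0 : v / dx;
  const double p_right_int = (h_diff + h_adv) * dt;
  const double p_left_int = h_diff * dt;
  const double p_exit = closed ? 0.0 : (v / dx) * dt;  // last compartment
  if (p_right_int + p_left_int > 0.5 || r * dt > 0.5)
    stop("dt too large for the per-step event probabilities");

  bool track_mutant = false;
  long M_tot = 0, B_tot = 0;
  for (int i = 0; i < n; ++i) { M_tot += M[i]; B_tot += B[i]; }
  if (M_tot > 0) track_mutant = true;
  const long init_tot = M_tot + B_tot;

  double t = 0.0;
  long births_total = 0;  // food consumed is births/alpha exactly, by construction
  long n_steps = 0;

  while (t < t_final) {
    // division probabilities from the current food field
    std::fill(Bn.begin(), Bn.end(), 0);
    std::fill(Mn.begin(), Mn.end(), 0);
    std::vector<long> births(n, 0);
    for (int type = 0; type < 2; ++type) {
      std::vector<int> &pop = (type == 0) ? B : M;
      std::vector<int> &nxt = (type == 0) ? Bn : Mn;
      for (int i = 0; i < n; ++i) {
        int ni = pop[i];
        if (ni == 0) continue;
        double Fp = F[i] > 0.0 ? F[i] : 0.0;
        double p_div = r * (Fp / (k + Fp)) * dt;
        double pr = (i == n - 1) ? p_exit : p_right_int;
        double pl = (i == 0) ? 0.0 : p_left_int;
        // exact multinomial move-right / move-left / stay
        int n_right = (int)R::rbinom(ni, pr);
        int n_left = 0;
        if (pl > 0.0 && ni - n_right > 0)
          n_left = (int)R::rbinom(ni - n_right, pl / (1.0 - pr));
        int n_div = (p_div > 0.0) ? (int)R::rbinom(ni, p_div) : 0;
        int stay = ni - n_right - n_left;
        nxt[i] += stay + n_div;  // newborns stay in the parent compartment
        if (i < n - 1) nxt[i + 1] += n_right;  // from the last cell: exits
        if (i > 0) nxt[i - 1] += n_left;
        births[i] += n_div;
        births_total += n_div;
      }
    }
    B.swap(Bn);
    M.swap(Mn);

    if (!fixed_food) {
      // upwind transport + inflow + consumption tied to realised births
      double flux_left = vFin;
      for (int i = 0; i < n; ++i) {
        double flux_right = (i < n - 1)
          ? v * F[i] - (D / dx) * (F[i + 1] - F[i])
          : v * F[i];
        double dFi = (flux_left - flux_right) / dx;
        Fnew[i] = F[i] + dt * dFi - (double)births[i] / (alpha * S * dx);
        if (Fnew[i] < 0.0) Fnew[i] = 0.0;
        flux_left = flux_right;
      }
      F.swap(Fnew);
    }
    t += dt;
    ++n_steps;

    M_tot = 0; B_tot = 0;
    for (int i = 0; i < n; ++i) { M_tot += M[i]; B_tot += B[i]; }
    if (track_mutant && M_tot == 0) break;      // lineage extinct
    if (M_tot + B_tot > pop_cap * init_tot && pop_cap > 0)
      stop("population exceeded the hard cap; reduce alpha or horizon");
  }

  double ratio = (M_tot + B_tot > 0)
    ? (double)M_tot / (double)(M_tot + B_tot) : 0.0;
  return List::create(
    _["B"] = IntegerVector(B.begin(), B.end()),
    _["M"] = IntegerVector(M.begin(), M.end()),
    _["F"] = NumericVector(F.begin(), F.end()),
    _["t_final"] = t,
    _["n_steps"] = n_steps,
    _["B_total"] = (double)B_tot,
    _["M_total"] = (double)M_tot,
    _["final_ratio"] = ratio,
    _["extinct"] = track_mutant && (M_tot == 0),
    _["births"] = (double)births_total);
}
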