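#include <Rcpp.h>
using namespace Rcpp;

// Stable Volterra recursion for the inner kernel of the Laplace functional:
//   G(tau) = e^{-v F(tau)} [ gamma int_0^tau e^{-gamma(tau-y)} e^{v F(y)} dy
//                            + e^{-gamma tau} ],
// with F the cumulative integral of the delay-filtered exponent (one column
// per Laplace variable). Worked in shifted form so every factor is <= 1.
// [[Rcpp::export]]
NumericMatrix cpp_volterra_G(NumericMatrix Fint, double gamma, double v,
                             double h) {
  const int n = Fint.nrow(), m = Fint.ncol();
  NumericMatrix G(n, m);
  const double eg = std::exp(-gamma * h);
  for (int c = 0; c < m; ++c) {
    double J = 0.0;
    G(0, c) = 1.0;
    for (int j = 1; j < n; ++j) {
      const double dF = Fint(j, c) - Fint(j - 1, c);
      const double e = eg * std::exp(-v * dF);
      J = e * J + 0.5 * h * (1.0 + e);
      G(j, c) = gamma * J + std::exp(-gamma * (j * h) - v * Fint(j, c));
    }
  }
  return G;
}

static inline double rexp_unit() {
  double u = unif_rand();
  while (u <= 0.0) u = unif_rand();
  return -std::log(u);
}

// Exact (direct-method) SSA for the bursty-substrate enzymatic reaction:
//   batch arrival: S += batch            at rate input_rate
//   binding:       S + E -> SE           at k_on * S * E / vol
//   unbinding:     SE -> S + E           at k_off * SE
//   catalysis:     SE -> E (+1 product)  at k_cat * SE
// Substrate leaves the system only through catalysis. States are sampled
// right-continuously at the supplied grid times.
// [[Rcpp::export]]
List cpp_ssa_enzyme(double k_on, double k_off, double k_cat, int batch,
                    double input_rate, int n_enz, double vol, double s0,
                    double horizon, NumericVector grid, bool record_events) {
  const int ng = grid.size();
  NumericVector gS(ng), gC(ng), gP(ng);
  std::vector<double> ev_t, ev_S, ev_C, ev_P;
  double t = 0.0, S = s0, C = 0.0, P = 0.0;
  int gi = 0;
  long long n_events = 0;
  const long long max_events = 200000000LL;
  if (record_events) {
    ev_t.push_back(0.0); ev_S.push_back(S); ev_C.push_back(C); ev_P.push_back(P);
  }
  while (t < horizon) {
    const double a1 = input_rate;
    const double a2 = k_on * S * (n_enz - C) / vol;
    const double a3 = k_off * C;
    const double a4 = k_cat * C;
    const double atot = a1 + a2 + a3 + a4;
    if (!R_finite(atot) || atot < 0)
      stop("non-finite propensity at t=%g (S=%g, SE=%g)", t, S, C);
    double next_t = (atot == 0.0) ? horizon : t + rexp_unit() / atot;
    if (next_t > horizon) next_t = horizon;
    while (gi < ng && grid[gi] < next_t) {
      gS[gi] = S; gC[gi] = C; gP[gi] = P; ++gi;
    }
    t = next_t;
    if (t >= horizon) break;
    const double r = unif_rand() * atot;
    if (r < a1)                { S += batch; }
    else if (r < a1 + a2)      { S -= 1; C += 1; }
    else if (r < a1 + a2 + a3) { S += 1; C -= 1; }
    else                       { C -= 1; P += 1; }
    if (++n_events > max_events) stop("event cap exceeded");
    if (record_events) {
      ev_t.push_back(t); ev_S.push_back(S); ev_C.push_back(C); ev_P.push_back(P);
    }
  }
  while (gi < ng) { gS[gi] = S; gC[gi] = C; gP[gi] = P; ++gi; }
  List out = List::create(_["S"] = gS, _["SE"] = gC, _["P"] = gP,
                          _["n_events"] = (double)n_events);
  if (record_events)
    out["events"] = DataFrame::create(_["time"] = ev_t, _["S"] = ev_S,
                                      _["SE"] = ev_C, _["P"] = ev_P);
  return out;
}

// Exact SSA for the TF expression cascade:
//   transcription (a_tf), mRNA decay (gamma_m each), translation (v_tf per
//   mRNA -> immature stage 1), kappa sequential maturation steps, dilution of
//   free mature TF (gamma_p each; or continuous decay of the concentration
//   when dilution_continuous, matching the analytic kernel model), and
//   TF-DNA binding at a single operator:
//     binding = 0: none
//     binding = 1: sequential  TF + O <-> TF.DNA <-> TF.O
//     binding = 2: sequential plus an independent direct route TF + O <-> TF.O
// Operator state: 0 free, 1 nonspecifically bound, 2 specifically bound.
// [[Rcpp::export]]
List cpp_ssa_genereg(double a_tf, double gamma_m, double v_tf,
                     NumericVector mat_rates, double gamma_p, double vol,
                     double ns_on, double ns_off, double sp_on, double sp_off,
                     double d_on, double d_off, int binding,
                     bool dilution_continuous, double horizon,
                     NumericVector grid, bool record_events) {
  const int ng = grid.size();
  const int kappa = mat_rates.size();
  NumericVector gM(ng), gI(ng), gPF(ng), gOP(ng), gRHO(ng), gCUM(ng);
  std::vector<double> ev_t, ev_M, ev_I, ev_PF, ev_OP, ev_RHO, ev_CUM;
  double t = 0.0, M = 0.0, PF = 0.0, rho = 0.0, CUM = 0.0;
  std::vector<double> imm(kappa, 0.0);
  int op = 0, gi = 0;
  long long n_events = 0;
  const long long max_events = 200000000LL;
  std::vector<double> a(6 + kappa + 4, 0.0);
  auto imm_total = [&]() {
    double s = 0; for (int i = 0; i < kappa; ++i) s += imm[i]; return s;
  };
  auto push_event = [&]() {
    ev_t.push_back(t); ev_M.push_back(M); ev_I.push_back(imm_total());
    ev_PF.push_back(PF); ev_OP.push_back((double)op);
    ev_RHO.push_back(dilution_continuous ? rho : PF / vol);
    ev_CUM.push_back(CUM);
  };
  if (record_events) push_event();
  while (t < horizon) {
    int na = 0;
    a[na++] = a_tf;                                   // 0: transcription
    a[na++] = gamma_m * M;                            // 1: mRNA decay
    a[na++] = v_tf * M;                               // 2: translation
    for (int i = 0; i < kappa; ++i) a[na++] = mat_rates[i] * imm[i];
    const int i_dil = na;
    a[na++] = dilution_continuous ? 0.0 : gamma_p * PF;
    const int i_bind = na;
    if (binding >= 1) {
      a[na++] = (op == 0) ? ns_on * PF / vol : 0.0;   // ns binding
      a[na++] = (op == 1) ? ns_off : 0.0;             // ns unbinding
      a[na++] = (op == 1) ? sp_on : 0.0;              // ns -> specific
      a[na++] = (op == 2) ? sp_off : 0.0;             // specific -> ns
      if (binding == 2) {
        a[na++] = (op == 0) ? d_on * PF / vol : 0.0;  // direct binding
        a[na++] = (op == 2) ? d_off : 0.0;            // direct release
      }
    }
    double atot = 0.0;
    for (int i = 0; i < na; ++i) atot += a[i];
    if (!R_finite(atot) || atot < 0)
      stop("non-finite propensity at t=%g", t);
    double next_t = (atot == 0.0) ? horizon : t + rexp_unit() / atot;
    if (next_t > horizon) next_t = horizon;
    while (gi < ng && grid[gi] < next_t) {
      gM[gi] = M; gI[gi] = imm_total(); gPF[gi] = PF; gOP[gi] = op;
      gRHO[gi] = dilution_continuous
                   ? rho * std::exp(-gamma_p * (grid[gi] - t)) : PF / vol;
      gCUM[gi] = CUM;
      ++gi;
    }
    if (dilution_continuous) rho *= std::exp(-gamma_p * (next_t - t));
    t = next_t;
    if (t >= horizon) break;
    double r = unif_rand() * atot;
    int k = 0;
    while (k < na - 1 && r >= a[k]) { r -= a[k]; ++k; }
    if (k == 0) { M += 1; }
    else if (k == 1) { M -= 1; }
    else if (k == 2) {
      if (kappa > 0) imm[0] += 1;
      else { PF += 1; CUM += 1; rho += 1.0 / vol; }
    } else if (k >= 3 && k < 3 + kappa) {
      const int st = k - 3;
      imm[st] -= 1;
      if (st + 1 < kappa) imm[st + 1] += 1;
      else { PF += 1; CUM += 1; rho += 1.0 / vol; }
    } else if (k == i_dil) { PF -= 1; }
    else {
      const int bk = k - i_bind;
      if (bk == 0)      { PF -= 1; op = 1; }
      else if (bk == 1) { PF += 1; op = 0; }
      else if (bk == 2) { op = 2; }
      else if (bk == 3) { op = 1; }
      else if (bk == 4) { PF -= 1; op = 2; }
      else              { PF += 1; op = 0; }
    }
    if (++n_events > max_events) stop("event cap exceeded");
    if (record_events) push_event();
  }
  while (gi < ng) {
    gM[gi] = M; gI[gi] = imm_total(); gPF[gi] = PF; gOP[gi] = op;
    gRHO[gi] = dilution_continuous
                 ? rho * std::exp(-gamma_p * (grid[gi] - t)) : PF / vol;
    gCUM[gi] = CUM;
    ++gi;
  }
  List out = List::create(_["M"] = gM, _["I"] = gI, _["PF"] = gPF,
                          _["OP"] = gOP, _["RHO"] = gRHO, _["CUM"] = gCUM,
                          _["n_events"] = (double)n_events);
  if (record_events)
    out["events"] = DataFrame::create(
      _["time"] = ev_t, _["mRNA"] = ev_M, _["immature"] = ev_I,
      _["mature_free"] = ev_PF, _["operator"] = ev_OP, _["rho"] = ev_RHO,
      _["matured_total"] = ev_CUM);
  return out;
}
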