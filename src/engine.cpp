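#include <Rcpp.h>
using namespace Rcpp;

// Model families (must match R-side coding in model_spec()).
#define FAM_RW   0
#define FAM_DB   1
#define FAM_MB   2
#define FAM_VS   3
#define FAM_META 4

// Probability floor inside the log; keeps boundary parameters finite.
static const double P_FLOOR = 1e-12;

// pi(self) = 1 / (1 + exp(beta * (V(other) - V(self) - lambda(self) * kappa)))
// lambda(self) = +1 if self is the last performed action, -1 if the other one
// is, 0 when no action has been performed yet in this context.
static inline double softmax_p(double v_self, double v_other, double lam,
                               double beta, double kappa) {
  double x = beta * (v_other - v_self - lam * kappa);
  if (x > 700.0) x = 700.0;
  if (x < -700.0) x = -700.0;
  return 1.0 / (1.0 + std::exp(x));
}

static inline double lambda_of(int opt, int last) {
  if (last == 0) return 0.0;
  return (opt == last) ? 1.0 : -1.0;
}

// One pass of a learner model over a trial sequence.
//
// context: 1-based context index per trial (a context = one symbol pair).
// type:    0 = private, 1 = observational.
// demo:    1/2 on observational trials (1 = option_a), 0 otherwise.
// choice:  1/2 on private trials (evaluation mode), 0 otherwise.
// outcome: +1/-1 on private trials (evaluation mode), 0 otherwise.
// pa, pb:  per-trial win probability of option a / b (used when simulating).
// params:  alpha_p, alpha_i, alpha_d, alpha_m, beta, kappa (in that order).
// urand:   n x 2 uniforms used when simulate = true (choice, outcome).
//
// Returns the NLL over private trials plus, when simulating, the sampled
// choices/outcomes; always returns the per-private-trial probability of
// option a and the running per-state imitation rate (metaVS).
// [[Rcpp::export]]
List rl_engine_cpp(IntegerVector context, IntegerVector type,
                   IntegerVector demo, IntegerVector choice,
                   NumericVector outcome, NumericVector pa, NumericVector pb,
                   int n_contexts, int family, int variant,
                   NumericVector params, bool symmetric_private,
                   bool obs_sets_last, bool simulate, NumericMatrix urand) {
  const int n = context.size();
  const double ap = params[0], ai = params[1], ad = params[2],
               am = params[3], beta = params[4], kappa = params[5];

  // Per-context state.
  std::vector<double> Q1(n_contexts, 0.0), Q2(n_contexts, 0.0);
  std::vector<double> T1(n_contexts, 0.0), T2(n_contexts, 0.0); // DB value trace
  std::vector<double> P1(n_contexts, 0.5);                      // DB policy trace
  std::vector<int>    trace_on(n_contexts, 0);
  std::vector<double> piD1(n_contexts, 0.5);                    // MB1-3
  std::vector<double> QD1(n_contexts, 0.0), QD2(n_contexts, 0.0); // MB4-9
  std::vector<double> ais(n_contexts, 0.0);                     // metaVS
  std::vector<int>    last(n_contexts, 0);

  IntegerVector out_choice(n, NA_INTEGER);
  NumericVector out_outcome(n, NA_REAL);
  NumericVector out_p1(n, NA_REAL);
  NumericVector out_ais(n, NA_REAL);
  double nll = 0.0;

  const int db_kind = (family == FAM_DB) ? (variant - 1) % 3 : 0;   // 0 PU, 1 VU, 2 SVU
  const bool db_accum = (family == FAM_DB) && variant > 3;
  const int mb_model = (family == FAM_MB) ? (variant - 1) / 3 : 0;  // demonstrator model update
  const int mb_bias = (family == FAM_MB) ? (variant - 1) % 3 : 0;   // bias step

  for (int t = 0; t < n; ++t) {
    const int cx = context[t] - 1;
    if (cx < 0 || cx >= n_contexts) stop("context index out of range at trial %d", t + 1);

    if (type[t] == 1) {
      // ---- observational trial: integrate the demonstration d ----
      const int d = demo[t];
      if (d != 1 && d != 2) stop("observational trial %d has no demonstration", t + 1);
      const int db_ = 3 - d;

      switch (family) {
      case FAM_RW:
        break; // social information ignored
      case FAM_DB: {
        if (!db_accum || !trace_on[cx]) {
          // re-derive the decision trace from Q (DB1-3 every time,
          // DB4-6 only when no trace is active)
          if (db_kind == 0) {
            P1[cx] = softmax_p(Q1[cx], Q2[cx], lambda_of(1, last[cx]), beta, kappa);
          } else {
            T1[cx] = Q1[cx];
            T2[cx] = Q2[cx];
          }
        }
        if (db_kind == 0) {
          double pd = (d == 1) ? P1[cx] : 1.0 - P1[cx];
          pd += ai * (1.0 - pd);
          P1[cx] = (d == 1) ? pd : 1.0 - pd;
        } else {
          double &Td = (d == 1) ? T1[cx] : T2[cx];
          Td += ai * (1.0 - Td);
          if (db_kind == 2) {
            double &Tu = (db_ == 1) ? T1[cx] : T2[cx];
            Tu += ai * (-1.0 - Tu);
          }
        }
        trace_on[cx] = 1;
        break;
      }
      case FAM_MB: {
        if (mb_model == 0) {
          double pd = (d == 1) ? piD1[cx] : 1.0 - piD1[cx];
          pd += ad * (1.0 - pd);
          piD1[cx] = (d == 1) ? pd : 1.0 - pd;
        } else {
          double &Qd = (d == 1) ? QD1[cx] : QD2[cx];
          Qd += ad * (1.0 - Qd);
          if (mb_model == 2) {
            double &Qu = (db_ == 1) ? QD1[cx] : QD2[cx];
            Qu += ad * (-1.0 - Qu);
          }
        }
        break;
      }
      case FAM_VS: {
        double &Qd = (d == 1) ? Q1[cx] : Q2[cx];
        Qd += ai * (1.0 - Qd);
        if (variant == 2) {
          double &Qu = (db_ == 1) ? Q1[cx] : Q2[cx];
          Qu += ai * (-1.0 - Qu);
        }
        break;
      }
      case FAM_META: {
        const double Qd0 = (d == 1) ? Q1[cx] : Q2[cx];
        const double Qu0 = (db_ == 1) ? Q1[cx] : Q2[cx];
        const double tau = (Qd0 >= Qu0) ? 1.0 : 0.0; // agreement; ties count
        ais[cx] += am * (tau - ais[cx]);
        double &Qd = (d == 1) ? Q1[cx] : Q2[cx];
        Qd += ais[cx] * (1.0 - Qd);
        double &Qu = (db_ == 1) ? Q1[cx] : Q2[cx];
        Qu += ais[cx] * (-1.0 - Qu);
        break;
      }
      default:
        stop("unknown model family code %d", family);
      }
      if (obs_sets_last) last[cx] = d; // matching response: the key was pressed
      out_ais[t] = ais[cx];
    } else {
      // ---- private trial: evaluate the policy, then learn from (c, r) ----
      double p1; // probability of choosing option a
      switch (family) {
      case FAM_RW:
      case FAM_VS:
      case FAM_META:
        p1 = softmax_p(Q1[cx], Q2[cx], lambda_of(1, last[cx]), beta, kappa);
        break;
      case FAM_DB:
        if (trace_on[cx]) {
          if (db_kind == 0) {
            p1 = P1[cx]; // kappa already applied when the trace was derived
          } else {
            p1 = softmax_p(T1[cx], T2[cx], lambda_of(1, last[cx]), beta, kappa);
          }
        } else {
          p1 = softmax_p(Q1[cx], Q2[cx], lambda_of(1, last[cx]), beta, kappa);
        }
        break;
      case FAM_MB: {
        const double pref1 = (mb_model == 0) ? (piD1[cx] - 0.5) : (QD1[cx] - QD2[cx]);
        if (pref1 == 0.0) {
          p1 = softmax_p(Q1[cx], Q2[cx], lambda_of(1, last[cx]), beta, kappa);
        } else {
          const int dstar = (pref1 > 0.0) ? 1 : 2;
          if (mb_bias == 0) {
            p1 = softmax_p(Q1[cx], Q2[cx], lambda_of(1, last[cx]), beta, kappa);
            double pd = (dstar == 1) ? p1 : 1.0 - p1;
            pd += ai * (1.0 - pd);
            p1 = (dstar == 1) ? pd : 1.0 - pd;
          } else {
            double t1 = Q1[cx], t2 = Q2[cx];
            double &td = (dstar == 1) ? t1 : t2;
            td += ai * (1.0 - td);
            if (mb_bias == 2) {
              double &tu = (dstar == 1) ? t2 : t1;
              tu += ai * (-1.0 - tu);
            }
            p1 = softmax_p(t1, t2, lambda_of(1, last[cx]), beta, kappa);
          }
        }
        break;
      }
      default:
        stop("unknown model family code %d", family);
      }
      if (!std::isfinite(p1)) stop("non-finite choice probability at trial %d", t + 1);
      out_p1[t] = p1;

      int c;
      double r;
      if (simulate) {
        c = (urand(t, 0) < p1) ? 1 : 2;
        const double pwin = (c == 1) ? pa[t] : pb[t];
        r = (urand(t, 1) < pwin) ? 1.0 : -1.0;
        out_choice[t] = c;
        out_outcome[t] = r;
      } else {
        c = choice[t];
        if (c != 1 && c != 2) stop("private trial %d has no choice", t + 1);
        r = outcome[t];
        if (r != 1.0 && r != -1.0) stop("private trial %d has outcome outside {+1,-1}", t + 1);
      }

      const double pc = (c == 1) ? p1 : 1.0 - p1;
      nll -= std::log(std::max(pc, P_FLOOR));

      double &Qc = (c == 1) ? Q1[cx] : Q2[cx];
      Qc += ap * (r - Qc);
      if (symmetric_private) {
        double &Qu = (c == 1) ? Q2[cx] : Q1[cx];
        Qu += ap * (-r - Qu);
      }
      last[cx] = c;
      trace_on[cx] = 0; // DB traces do not survive a private choice
      out_ais[t] = ais[cx];
    }
  }

  return List::create(_["nll"] = nll, _["choice"] = out_choice,
                      _["outcome"] = out_outcome, _["p_a"] = out_p1,
                      _["alpha_i_state"] = out_ais);
}
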