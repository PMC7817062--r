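// Gillespie direct-method simulation of the discrete switch.
// Reactions (counts n_X active, n_Y inactive, system size Omega):
//   R1 activation   Y -> X       propensity f(n_X, a) n_Y / eps
//   R2 inactivation X -> Y       propensity g(n_X) n_X / eps
//   R3 production   0 -> Y       propensity k_X Omega
//   R4 degradation of inactive   propensity n_X n_Y / Omega (consumes one Y)
//   R5 degradation of active     propensity n_X (n_X - 1) / Omega (consumes one X)
// Concentration-scale parameters are Omega-scaled: K, K' -> Omega K,
// kappa -> kappa / Omega, X_c -> Omega X_c. R4/R5 are omitted for the
// transition model (no degradation).
#include <Rcpp.h>
using namespace Rcpp;

// parameter vector layout shared with the deterministic models (models.c)
// [[Rcpp::export]]
List ssa_simulate_cpp(NumericVector parms, double omega,
                      double nx0, double ny0, NumericVector times,
                      bool degradation, double threshold_count)
{
    const double b = parms[0], K = parms[1], n = parms[2];
    const double a_prime = parms[3], b_prime = parms[4], K_prime = parms[5];
    const double m = parms[6], eps = parms[7], kX = parms[8];
    const double a_static = parms[9];
    const bool modulated = parms[10] > 0.5;
    const double a_bar = parms[11], delta_a = parms[12];
    const double kappa = parms[13] / omega, Xc = omega * parms[14];
    const double Kn = std::pow(omega * K, n);
    const double Km = std::pow(omega * K_prime, m);

    const int nt = times.size();
    NumericVector out_nx(nt), out_ny(nt);
    double nx = nx0, ny = ny0;
    double t = times[0];
    int irec = 0;
    double first_passage = NA_REAL;
    if (threshold_count >= 0 && nx >= threshold_count) first_passage = t;

    const double t_end = times[nt - 1];
    while (true) {
        double a = a_static;
        if (modulated)
            a = a_bar + delta_a * std::tanh(kappa * (nx + ny - Xc));
        const double xn = std::pow(nx, n);
        const double f = a + b * xn / (Kn + xn);
        const double g = a_prime + b_prime * Km / (Km + std::pow(nx, m));
        double a1 = f * ny / eps;
        if (a1 < 0) a1 = 0; // modulated a can be negative at tiny counts
        const double a2 = g * nx / eps;
        const double a3 = kX * omega;
        const double a4 = degradation ? nx * ny / omega : 0.0;
        const double a5 = degradation ? nx * (nx - 1.0) / omega : 0.0;
        const double atot = a1 + a2 + a3 + a4 + a5;
        if (atot <= 0) { t = t_end; }
        else t += R::rexp(1.0 / atot);

        while (irec < nt && times[irec] <= t) {
            out_nx[irec] = nx;
            out_ny[irec] = ny;
            ++irec;
        }
        if (t >= t_end || irec >= nt) break;

        const double u = R::runif(0.0, atot);
        if (u < a1)                { nx += 1; ny -= 1; }
        else if (u < a1 + a2)      { nx -= 1; ny += 1; }
        else if (u < a1 + a2 + a3) { ny += 1; }
        else if (u < a1 + a2 + a3 + a4) { ny -= 1; }
        else                       { nx -= 1; }

        if (threshold_count >= 0 && !R_finite(first_passage) &&
            nx >= threshold_count)
            first_passage = t;
    }
    while (irec < nt) { out_nx[irec] = nx; out_ny[irec] = ny; ++irec; }

    return List::create(_["n_X"] = out_nx, _["n_Y"] = out_ny,
                        _["first_passage"] = first_passage);
}
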