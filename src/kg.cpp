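// Kremer-Grest bead-spring model: pair + FENE + bending forces, Langevin
// dynamics (BAOAB), and the primitive-path contraction minimizer.
// Reduced units throughout: sigma = epsilon = m = kB = 1.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double lj_cutoff;   // pair cutoff (2.5 for full LJ, 2^(1/6) for WCA)
  double feneK;       // FENE spring constant
  double feneR0;      // FENE maximum extension
  double kappa;       // bending prefactor (multiplies kB T)
  double temp;        // temperature entering the bending energy
  bool   wca_only;    // purely repulsive pair term (shifted, truncated)
  bool   inter_only;  // pair term only between different chains (PPA)
  bool   bend_on;
};

inline void min_image(double *d, const double *box) {
  if (box) {
    for (int k = 0; k < 3; ++k) d[k] -= box[k] * std::round(d[k] / box[k]);
  }
}

// accumulate forces and energies; returns false on FENE overstretch
bool forces(const NumericMatrix &x, const IntegerVector &chain,
            const double *box, const Params &p, NumericMatrix &f,
            double *e_pair, double *e_fene, double *e_bend,
            int *bad_bond) {
  const int n = x.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  *e_pair = *e_fene = *e_bend = 0.0;
  const double rc2 = p.lj_cutoff * p.lj_cutoff;
  const double irc6 = 1.0 / (rc2 * rc2 * rc2);
  const double eshift = 4.0 * (irc6 * irc6 - irc6);  // U(rc) -> 0

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same = chain[i] == chain[j];
      if (p.inter_only && same) continue;
      double d[3] = {x(i,0) - x(j,0), x(i,1) - x(j,1), x(i,2) - x(j,2)};
      min_image(d, box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 > rc2 || r2 <= 0) continue;
      double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
      *e_pair += 4.0 * (ir6 * ir6 - ir6) - eshift;
      double fr = 24.0 * (2.0 * ir6 * ir6 - ir6) * ir2;  // (1/r dU/dr) sign
      for (int k = 0; k < 3; ++k) {
        f(i,k) += fr * d[k];
        f(j,k) -= fr * d[k];
      }
    }
  }

  // FENE bonds along each backbone
  for (int i = 0; i < n - 1; ++i) {
    if (chain[i] != chain[i+1]) continue;
    double d[3] = {x(i+1,0) - x(i,0), x(i+1,1) - x(i,1), x(i+1,2) - x(i,2)};
    min_image(d, box);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    double R02 = p.feneR0 * p.feneR0;
    if (r2 >= R02) { *bad_bond = i + 1; return false; }
    *e_fene += -0.5 * p.feneK * R02 * std::log(1.0 - r2 / R02);
    double fr = -p.feneK / (1.0 - r2 / R02);   // along d, attractive
    for (int k = 0; k < 3; ++k) {
      f(i,k)   -= fr * d[k];
      f(i+1,k) += fr * d[k];
    }
  }

  // bending between successive bonds
  if (p.bend_on && p.kappa > 0) {
    const double kb = p.kappa * p.temp;
    for (int i = 1; i < n - 1; ++i) {
      if (chain[i-1] != chain[i] || chain[i] != chain[i+1]) continue;
      double b1[3] = {x(i,0)-x(i-1,0), x(i,1)-x(i-1,1), x(i,2)-x(i-1,2)};
      double b2[3] = {x(i+1,0)-x(i,0), x(i+1,1)-x(i,1), x(i+1,2)-x(i,2)};
      min_image(b1, box);
      min_image(b2, box);
      double n1 = std::sqrt(b1[0]*b1[0]+b1[1]*b1[1]+b1[2]*b1[2]);
      double n2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
      double ct = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (n1 * n2);
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      *e_bend += kb * (1.0 - ct);
      for (int k = 0; k < 3; ++k) {
        double u1 = b1[k] / n1, u2 = b2[k] / n2;
        double g1 = (u2 - ct * u1) / n1;   // d cos / d b1
        double g2 = (u1 - ct * u2) / n2;   // d cos / d b2
        f(i-1,k) += -kb * g1;
        f(i,  k) +=  kb * (g1 - g2);
        f(i+1,k) +=  kb * g2;
      }
    }
  }
  return true;
}

Params make_params(double lj_cutoff, double feneK, double feneR0,
                   double kappa, double temp, bool wca_only,
                   bool inter_only, bool bend_on) {
  Params p;
  p.lj_cutoff = wca_only ? std::pow(2.0, 1.0 / 6.0) : lj_cutoff;
  p.feneK = feneK; p.feneR0 = feneR0; p.kappa = kappa; p.temp = temp;
  p.wca_only = wca_only; p.inter_only = inter_only; p.bend_on = bend_on;
  return p;
}

}  // namespace

// [[Rcpp::export]]
List kg_energy_forces(NumericMatrix x, IntegerVector chain,
                      Nullable<NumericVector> box_, double lj_cutoff,
                      double feneK, double feneR0, double kappa,
                      double temp, bool wca_only = false,
                      bool inter_only = false, bool bend_on = true) {
  Params p = make_params(lj_cutoff, feneK, feneR0, kappa, temp,
                         wca_only, inter_only, bend_on);
  const double *box = nullptr;
  NumericVector bx;
  if (box_.isNotNull()) { bx = box_.get(); box = REAL(bx); }
  NumericMatrix f(x.nrow(), 3);
  double ep, ef, eb; int bad = 0;
  if (!forces(x, chain, box, p, f, &ep, &ef, &eb, &bad))
    stop("FENE bond %d stretched beyond R0; timestep too large", bad);
  return List::create(_["pair"] = ep, _["fene"] = ef, _["bend"] = eb,
                      _["forces"] = f);
}

// [[Rcpp::export]]
List kg_run(NumericMatrix x, NumericMatrix v, IntegerVector chain,
            Nullable<NumericVector> box_, double lj_cutoff, double feneK,
            double feneR0, double kappa, double temp, double gamma,
            double dt, int steps, int stride) {
  Params p = make_params(lj_cutoff, feneK, feneR0, kappa, temp,
                         false, false, true);
  const double *box = nullptr;
  NumericVector bx;
  if (box_.isNotNull()) { bx = box_.get(); box = REAL(bx); }
  const int n = x.nrow();
  NumericMatrix f(n, 3);
  double ep, ef, eb; int bad = 0;
  if (!forces(x, chain, box, p, f, &ep, &ef, &eb, &bad))
    stop("FENE bond %d stretched beyond R0 in the initial state", bad);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(temp);
  const int nframes = steps / stride;
  NumericVector frames(static_cast<R_xlen_t>(nframes) * n * 3);
  NumericVector ftimes(nframes), ke(nframes), epair(nframes),
      efene(nframes), ebend(nframes);
  int fi = 0;

  GetRNGstate();
  for (int s = 1; s <= steps; ++s) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v(i,k) += 0.5 * dt * f(i,k);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) x(i,k) += 0.5 * dt * v(i,k);
    if (gamma > 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v(i,k) = c1 * v(i,k) + c2 * norm_rand();
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) x(i,k) += 0.5 * dt * v(i,k);
    if (!forces(x, chain, box, p, f, &ep, &ef, &eb, &bad)) {
      PutRNGstate();
      stop("FENE bond %d stretched beyond R0 at step %d; timestep too large",
           bad, s);
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v(i,k) += 0.5 * dt * f(i,k);
    if (s % stride == 0 && fi < nframes) {
      double kes = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) kes += 0.5 * v(i,k) * v(i,k);
      ke[fi] = kes;
      epair[fi] = ep; efene[fi] = ef; ebend[fi] = eb;
      ftimes[fi] = s * dt;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[static_cast<R_xlen_t>(fi) * n * 3 + i * 3 + k] = x(i,k);
      ++fi;
    }
  }
  PutRNGstate();
  frames.attr("dim") = IntegerVector::create(3, n, nframes);
  return List::create(_["frames"] = frames, _["times"] = ftimes,
                      _["kinetic"] = ke, _["pair"] = epair,
                      _["fene"] = efene, _["bend"] = ebend,
                      _["x"] = x, _["v"] = v);
}

// Primitive path contraction: damped steepest descent with a hard cap on
// the per-bead displacement per iteration (the no-strand-passage guard);
// chain endpoints are frozen.  FENE bonds pull the contour taut while the
// purely repulsive interchain pair term preserves mutual excluded volume.
// [[Rcpp::export]]
List kg_ppa(NumericMatrix x, IntegerVector chain,
            Nullable<NumericVector> box_, double feneK, double feneR0,
            double tol, int max_iter, double step_cap) {
  Params p = make_params(0, feneK, feneR0, 0, 1, true, true, false);
  const double *box = nullptr;
  NumericVector bx;
  if (box_.isNotNull()) { bx = box_.get(); box = REAL(bx); }
  const int n = x.nrow();
  NumericMatrix f(n, 3);
  std::vector<bool> frozen(n, false);
  for (int i = 0; i < n; ++i) {
    if (i == 0 || chain[i] != chain[i-1]) frozen[i] = true;
    if (i == n - 1 || chain[i] != chain[i+1]) frozen[i] = true;
  }
  double ep, ef, eb; int bad = 0;
  double maxf = 0, prev_maxf = R_PosInf;
  double alpha_cap = 0.02;                // backed off when the residual grows
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    if (!forces(x, chain, box, p, f, &ep, &ef, &eb, &bad))
      stop("FENE bond %d beyond R0 during PPA", bad);
    maxf = 0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double fm = std::sqrt(f(i,0)*f(i,0)+f(i,1)*f(i,1)+f(i,2)*f(i,2));
      if (fm > maxf) maxf = fm;
    }
    if (maxf < tol) break;
    if (maxf > prev_maxf && alpha_cap > 1e-4) alpha_cap *= 0.7;
    prev_maxf = maxf;
    double alpha = step_cap / std::max(maxf, 1e-12);
    if (alpha > alpha_cap) alpha = alpha_cap;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int k = 0; k < 3; ++k) x(i,k) += alpha * f(i,k);
    }
  }
  return List::create(_["x"] = x, _["iterations"] = it,
                      _["max_force"] = maxf, _["converged"] = maxf < tol);
}
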