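// Stiff integration of the mass-action reaction network.
//
// The ODE right-hand side is assembled from a reaction list (order 0, 1 or 2
// with rate constants in #/cell units) and a sparse stoichiometry triplet
// list. Because the rate laws are polynomial the Jacobian is analytic, which
// makes a Rosenbrock method attractive: L-stable, no Newton iteration, one
// LU factorization per step. We use the 4-stage Kaps-Rentrop scheme with
// Shampine's coefficients and embedded 3rd-order error estimate. The system
// is autonomous (events are handled by the R driver between integration
// legs), so the time-derivative terms vanish.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  ivec order;   // 0, 1, 2
  uvec i1, i2;  // reactant indices (0-based; i2 used when order == 2)
  vec rate;
  uvec s_r, s_s; // stoichiometry triplets: reaction, species
  vec s_c;       // coefficient
  int n_sp;
};

Net unpack(const Rcpp::List& model) {
  Net net;
  net.order = Rcpp::as<ivec>(model["order"]);
  net.i1 = Rcpp::as<uvec>(model["i1"]);
  net.i2 = Rcpp::as<uvec>(model["i2"]);
  net.rate = Rcpp::as<vec>(model["rate"]);
  net.s_r = Rcpp::as<uvec>(model["s_rxn"]);
  net.s_s = Rcpp::as<uvec>(model["s_sp"]);
  net.s_c = Rcpp::as<vec>(model["s_coef"]);
  net.n_sp = Rcpp::as<int>(model["n_sp"]);
  return net;
}

void velocities(const Net& net, const vec& y, vec& v) {
  const int m = net.rate.n_elem;
  for (int j = 0; j < m; ++j) {
    double val = net.rate[j];
    if (net.order[j] >= 1) val *= y[net.i1[j]];
    if (net.order[j] == 2) val *= y[net.i2[j]];
    v[j] = val;
  }
}

void rhs(const Net& net, const vec& y, vec& f, vec& v) {
  velocities(net, y, v);
  f.zeros();
  for (uword t = 0; t < net.s_r.n_elem; ++t)
    f[net.s_s[t]] += net.s_c[t] * v[net.s_r[t]];
}

void jacobian(const Net& net, const vec& y, mat& J) {
  J.zeros();
  const uword nt = net.s_r.n_elem;
  // dv_j/dy_k accumulated through stoichiometry
  for (uword t = 0; t < nt; ++t) {
    const uword j = net.s_r[t];
    const double c = net.s_c[t];
    const uword s = net.s_s[t];
    if (net.order[j] == 1) {
      J(s, net.i1[j]) += c * net.rate[j];
    } else if (net.order[j] == 2) {
      J(s, net.i1[j]) += c * net.rate[j] * y[net.i2[j]];
      J(s, net.i2[j]) += c * net.rate[j] * y[net.i1[j]];
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mass_action_rhs")]]
arma::vec mass_action_rhs(const Rcpp::List& model, const arma::vec& y) {
  Net net = unpack(model);
  vec f(net.n_sp), v(net.rate.n_elem);
  rhs(net, y, f, v);
  return f;
}

//' @noRd
// [[Rcpp::export(name = ".mass_action_jacobian")]]
arma::mat mass_action_jacobian(const Rcpp::List& model, const arma::vec& y) {
  Net net = unpack(model);
  mat J(net.n_sp, net.n_sp);
  jacobian(net, y, J);
  return J;
}

//' @noRd
// [[Rcpp::export(name = ".reaction_velocities")]]
arma::vec reaction_velocities(const Rcpp::List& model, const arma::vec& y) {
  Net net = unpack(model);
  vec v(net.rate.n_elem);
  velocities(net, y, v);
  return v;
}

// Kaps-Rentrop coefficients (Shampine parameterization, as in the classic
// GRK4 implementations).
static const double GAM = 0.5, A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0,
  C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0, C41 = -112.0 / 125.0,
  C42 = -54.0 / 125.0, C43 = -2.0 / 5.0, B1 = 19.0 / 9.0, B2 = 1.0 / 2.0,
  B3 = 25.0 / 108.0, B4 = 125.0 / 108.0, E1 = 17.0 / 54.0, E2 = 7.0 / 36.0,
  E3 = 0.0, E4 = 125.0 / 108.0;

//' @noRd
// [[Rcpp::export(name = ".rosenbrock_integrate")]]
Rcpp::List rosenbrock_integrate(const Rcpp::List& model,
                                const arma::vec& y0,
                                const arma::vec& times,
                                const double rtol,
                                const double atol,
                                const double hmax,
                                const double hmin) {
  Net net = unpack(model);
  const int n = net.n_sp;
  const int nt = times.n_elem;
  mat out(nt, n);
  vec y = y0;
  double t = times[0];
  out.row(0) = y.t();

  vec f(n), v(net.rate.n_elem), g1(n), g2(n), g3(n), g4(n), ytmp(n), err(n);
  mat J(n, n), A(n, n), L, U, P;
  double h = std::min(hmax, std::max(hmin, 1.0));
  int it = 1;
  long n_steps = 0, n_reject = 0;

  while (it < nt) {
    const double t_target = times[it];
    if (t + h > t_target) h = t_target - t;
    if (h < hmin) h = hmin;
    bool accepted = false;
    int tries = 0;
    while (!accepted) {
      if (++tries > 200)
        Rcpp::stop("rosenbrock: step failure at t = %f (h = %g)", t, h);
      rhs(net, y, f, v);
      jacobian(net, y, J);
      A = -J;
      A.diag() += 1.0 / (GAM * h);
      bool ok = lu(L, U, P, A);
      if (!ok || !U.diag().is_finite() || arma::any(arma::abs(U.diag()) < 1e-300)) {
        h *= 0.5; n_reject++; continue;
      }
      auto slv = [&](const vec& b) -> vec {
        vec pb = P * b;
        vec z = solve(trimatl(L), pb);
        return solve(trimatu(U), z);
      };
      g1 = slv(f);
      ytmp = y + A21 * g1;
      rhs(net, ytmp, f, v);
      g2 = slv(f + (C21 / h) * g1);
      ytmp = y + A31 * g1 + A32 * g2;
      rhs(net, ytmp, f, v);
      g3 = slv(f + (C31 * g1 + C32 * g2) / h);
      // fourth stage reuses the third-stage argument
      g4 = slv(f + (C41 * g1 + C42 * g2 + C43 * g3) / h);
      vec ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
      err = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;
      if (!ynew.is_finite()) { h *= 0.5; n_reject++; continue; }
      vec sc = atol + rtol * arma::max(arma::abs(y), arma::abs(ynew));
      double enorm = std::sqrt(arma::mean(arma::square(err / sc)));
      // large negative excursions are treated as failed steps
      double ymin = ynew.min();
      if (ymin < -10.0 * atol && enorm <= 1.0) {
        h *= 0.5; n_reject++; continue;
      }
      if (enorm <= 1.0) {
        t += h;
        // clip only sub-tolerance negativity
        for (int i = 0; i < n; ++i)
          if (ynew[i] < 0 && ynew[i] > -10.0 * atol) ynew[i] = 0.0;
        y = ynew;
        n_steps++;
        accepted = true;
        double fac = 0.9 * std::pow(std::max(enorm, 1e-10), -0.25);
        h = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
      } else {
        n_reject++;
        double fac = 0.9 * std::pow(enorm, -1.0 / 3.0);
        h *= std::min(0.5, std::max(0.1, fac));
        if (h < hmin)
          Rcpp::stop("rosenbrock: step size underflow at t = %f", t);
      }
    }
    if (t >= t_target - 1e-9 * std::max(1.0, std::abs(t_target))) {
      out.row(it) = y.t();
      ++it;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("n_steps") = (double)n_steps,
                            Rcpp::Named("n_reject") = (double)n_reject);
}

//' @noRd
// [[Rcpp::export(name = ".steady_newton")]]
Rcpp::List steady_newton(const Rcpp::List& model,
                         const arma::vec& y0,
                         const arma::uvec& keep,  // 0-based live indices
                         const double tol,
                         const int maxit) {
  Net net = unpack(model);
  const int n = net.n_sp;
  vec y = y0, f(n), v(net.rate.n_elem);
  mat J(n, n);
  bool converged = false;
  double resid = datum::inf;
  for (int iter = 0; iter < maxit; ++iter) {
    rhs(net, y, f, v);
    vec fk = f.elem(keep);
    resid = norm(fk, "inf");
    if (resid < tol) { converged = true; break; }
    jacobian(net, y, J);
    mat Jk = J.submat(keep, keep);
    vec step;
    if (!solve(step, Jk, -fk)) break;
    // full Newton step, clamped to the nonnegative orthant; the burn-in
    // integration supplies a starting point inside the basin of attraction
    vec ytrial = clamp(y.elem(keep) + step, 0.0, datum::inf);
    y.elem(keep) = ytrial;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("resid") = resid);
}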