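// Langevin dynamics on analytic model potentials, optionally on a
// GaMD-boosted surface.  BAOAB splitting; with zero collision frequency the
// scheme reduces to velocity Verlet, which is what the energy-conservation
// checks exercise.  Units are AKMA-like: energies kcal/mol, lengths Angstrom,
// masses amu; kB = 0.0019872 kcal/mol/K.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

static const double KB = 0.0019872;

// potential ids: 1 = harmonic (ks per dim), 2 = double well 1D (h, a),
// 3 = double well in x (h, a) + harmonic in y (ky)
static double pot_energy(int id, const arma::vec &x, const arma::vec &par) {
  switch (id) {
  case 1: {
    double e = 0.0;
    for (arma::uword d = 0; d < x.n_elem; ++d) e += 0.5 * par[d] * x[d] * x[d];
    return e;
  }
  case 2: {
    double u = x[0] / par[1];
    double t = u * u - 1.0;
    return par[0] * t * t;
  }
  case 3: {
    double u = x[0] / par[1];
    double t = u * u - 1.0;
    return par[0] * t * t + 0.5 * par[2] * x[1] * x[1];
  }
  }
  Rcpp::stop("unknown potential id");
}

static void pot_force(int id, const arma::vec &x, const arma::vec &par,
                      arma::vec &f) {
  switch (id) {
  case 1:
    for (arma::uword d = 0; d < x.n_elem; ++d) f[d] = -par[d] * x[d];
    return;
  case 2: {
    double a2 = par[1] * par[1];
    double u2 = x[0] * x[0] / a2;
    f[0] = -4.0 * par[0] * x[0] * (u2 - 1.0) / a2;
    return;
  }
  case 3: {
    double a2 = par[1] * par[1];
    double u2 = x[0] * x[0] / a2;
    f[0] = -4.0 * par[0] * x[0] * (u2 - 1.0) / a2;
    f[1] = -par[2] * x[1];
    return;
  }
  }
  Rcpp::stop("unknown potential id");
}

// [[Rcpp::export(name = ".langevin_cpp")]]
Rcpp::List langevin_cpp(int pot_id, arma::vec pot_par, arma::vec x0,
                        double mass, double temperature, double friction,
                        double timestep, int n_steps, int stride,
                        bool boosted, double E, double k, int seed,
                        double domain_limit) {
  const arma::uword dim = x0.n_elem;
  arma::vec x = x0, v(dim), f(dim), fb(dim);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double kT = KB * temperature;
  // Maxwell-distributed initial velocities (zeroed when thermostat is off so
  // that microcanonical runs start from the caller-controlled state)
  for (arma::uword d = 0; d < dim; ++d)
    v[d] = (friction > 0.0 || temperature > 0.0)
               ? std::sqrt(kT / mass) * gauss(rng)
               : 0.0;

  const double c1 = std::exp(-friction * timestep);
  const double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));

  const int n_rec = n_steps / stride;
  arma::mat coords(n_rec, dim);
  arma::vec Vrec(n_rec), dVrec(n_rec);

  double V = pot_energy(pot_id, x, pot_par);
  pot_force(pot_id, x, pot_par, f);
  auto boost_scale = [&](double Vcur) {
    if (!boosted || Vcur >= E) return 1.0;
    return 1.0 - k * (E - Vcur);
  };
  fb = f * boost_scale(V);

  int rec = 0;
  for (int step = 0; step < n_steps; ++step) {
    // B
    v += 0.5 * timestep * fb / mass;
    // A
    x += 0.5 * timestep * v;
    // O
    if (friction > 0.0) {
      for (arma::uword d = 0; d < dim; ++d)
        v[d] = c1 * v[d] + c2 * gauss(rng);
    }
    // A
    x += 0.5 * timestep * v;
    // B
    V = pot_energy(pot_id, x, pot_par);
    pot_force(pot_id, x, pot_par, f);
    fb = f * boost_scale(V);
    v += 0.5 * timestep * fb / mass;

    if (!x.is_finite() || arma::abs(x).max() > domain_limit)
      Rcpp::stop("trajectory diverged at step %d (|x| > %g)", step + 1,
                 domain_limit);

    if ((step + 1) % stride == 0) {
      double dV = (boosted && V < E) ? 0.5 * k * (E - V) * (E - V) : 0.0;
      coords.row(rec) = x.t();
      Vrec[rec] = V;
      dVrec[rec] = dV;
      ++rec;
    }
  }

  // total (kinetic + potential) energy at the final state, for conservation
  double ekin = 0.5 * mass * arma::dot(v, v);
  return Rcpp::List::create(
      Rcpp::Named("coords") = coords, Rcpp::Named("V") = Vrec,
      Rcpp::Named("dV") = dVrec, Rcpp::Named("final_energy") = ekin + V,
      Rcpp::Named("final_x") = x);
}

// [[Rcpp::export(name = ".pot_eval_cpp")]]
Rcpp::List pot_eval_cpp(int pot_id, arma::vec pot_par, arma::mat X) {
  arma::vec e(X.n_rows);
  arma::mat g(X.n_rows, X.n_cols);
  arma::vec f(X.n_cols);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec x = X.row(i).t();
    e[i] = pot_energy(pot_id, x, pot_par);
    pot_force(pot_id, x, pot_par, f);
    g.row(i) = -f.t();
  }
  return Rcpp::List::create(Rcpp::Named("energy") = e,
                            Rcpp::Named("gradient") = g);
}
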