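// Mass-action right-hand side for the MSN signalling network.
//
// The network is compiled once into flat index arrays (elementary steps with
// substrate index lists and a sparse stoichiometry); the two boundary species
// (Ca2+ and dopamine) are closed-form forcing functions evaluated here so the
// stiff solver never has to resolve them as states.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Forcing {
  // type: 0 tonic, 1 spike train of double-exponential transients,
  //       2 single double-exponential transient, 3 square pulse
  int type = 0;
  double base = 0.0;
  double amp = 0.0;           // transient amplitude above base (type 2)
  double k1 = 1.0, k2 = 0.5;  // rise (k1) and decay (k2) rate constants
  double t0 = 0.0, dur = 0.0, level = 0.0;
  std::vector<double> onsets, amps;  // spike train (type 1), absolute amps

  static double shape(double dt, double k1, double k2) {
    // double-exponential normalised to unit peak; k1 > k2 assumed,
    // k1 == k2 handled by the alpha-function limit
    if (dt < 0.0) return 0.0;
    if (std::abs(k1 - k2) < 1e-12 * k1) {
      return k1 * dt * std::exp(1.0 - k1 * dt);
    }
    double tp = std::log(k1 / k2) / (k1 - k2);
    double gmax = std::exp(-k2 * tp) - std::exp(-k1 * tp);
    return (std::exp(-k2 * dt) - std::exp(-k1 * dt)) / gmax;
  }

  double value(double t) const {
    switch (type) {
      case 0: return base;
      case 1: {
        double v = base;
        for (size_t j = 0; j < onsets.size(); ++j) {
          double dt = t - onsets[j];
          if (dt >= 0.0 && dt * k2 < 40.0) v += amps[j] * shape(dt, k1, k2);
        }
        return v;
      }
      case 2: return base + amp * shape(t - t0, k1, k2);
      case 3: return (t >= t0 && t < t0 + dur) ? base + level : base;
    }
    return base;
  }
};

struct Model {
  int nspec = 0, nsteps = 0;
  std::vector<double> k;
  std::vector<int> subptr, subidx;           // CSR substrate lists per step
  std::vector<int> stptr, stspec;            // CSR stoichiometry per step
  std::vector<double> stdelta;
  Forcing ca, da;
};

static Forcing forcing_from_list(List f) {
  Forcing out;
  out.type = as<int>(f["type"]);
  out.base = as<double>(f["base"]);
  if (f.containsElementNamed("amp")) out.amp = as<double>(f["amp"]);
  if (f.containsElementNamed("k1")) out.k1 = as<double>(f["k1"]);
  if (f.containsElementNamed("k2")) out.k2 = as<double>(f["k2"]);
  if (f.containsElementNamed("t0")) out.t0 = as<double>(f["t0"]);
  if (f.containsElementNamed("dur")) out.dur = as<double>(f["dur"]);
  if (f.containsElementNamed("level")) out.level = as<double>(f["level"]);
  if (f.containsElementNamed("onsets")) {
    out.onsets = as<std::vector<double>>(f["onsets"]);
    out.amps = as<std::vector<double>>(f["amps"]);
  }
  return out;
}

// [[Rcpp::export]]
SEXP model_build(int nspec, NumericVector k, IntegerVector subptr,
                 IntegerVector subidx, IntegerVector stptr,
                 IntegerVector stspec, NumericVector stdelta, List ca,
                 List da) {
  Model* m = new Model();
  m->nspec = nspec;
  m->nsteps = k.size();
  m->k = as<std::vector<double>>(k);
  m->subptr = as<std::vector<int>>(subptr);
  m->subidx = as<std::vector<int>>(subidx);
  m->stptr = as<std::vector<int>>(stptr);
  m->stspec = as<std::vector<int>>(stspec);
  m->stdelta = as<std::vector<double>>(stdelta);
  m->ca = forcing_from_list(ca);
  m->da = forcing_from_list(da);
  XPtr<Model> p(m, true);
  return p;
}

// [[Rcpp::export]]
void model_set_k(SEXP ptr, NumericVector k) {
  XPtr<Model> m(ptr);
  m->k = as<std::vector<double>>(k);
}

// [[Rcpp::export]]
void model_set_forcing(SEXP ptr, std::string which, List f) {
  XPtr<Model> m(ptr);
  if (which == "ca") m->ca = forcing_from_list(f);
  else m->da = forcing_from_list(f);
}

// [[Rcpp::export]]
NumericVector forcing_eval(SEXP ptr, NumericVector t) {
  XPtr<Model> m(ptr);
  NumericVector out(2 * t.size());
  for (int i = 0; i < t.size(); ++i) {
    out[2 * i] = m->ca.value(t[i]);
    out[2 * i + 1] = m->da.value(t[i]);
  }
  out.attr("dim") = Dimension(2, t.size());
  return out;
}

// [[Rcpp::export]]
NumericVector rhs_eval(SEXP ptr, double t, NumericVector y) {
  XPtr<Model> m(ptr);
  const int n = m->nspec;
  NumericVector dy(n);
  const double cav = m->ca.value(t);
  const double dav = m->da.value(t);
  for (int s = 0; s < m->nsteps; ++s) {
    double r = m->k[s];
    if (r == 0.0) continue;
    for (int j = m->subptr[s]; j < m->subptr[s + 1]; ++j) {
      const int idx = m->subidx[j];
      double v = (idx < n) ? y[idx] : (idx == n ? cav : dav);
      if (v < 0.0) v = 0.0;
      r *= v;
    }
    for (int j = m->stptr[s]; j < m->stptr[s + 1]; ++j)
      dy[m->stspec[j]] += m->stdelta[j] * r;
  }
  return dy;
}

// [[Rcpp::export]]
NumericVector step_rates(SEXP ptr, double t, NumericVector y) {
  XPtr<Model> m(ptr);
  const int n = m->nspec;
  NumericVector out(m->nsteps);
  const double cav = m->ca.value(t);
  const double dav = m->da.value(t);
  for (int s = 0; s < m->nsteps; ++s) {
    double r = m->k[s];
    for (int j = m->subptr[s]; j < m->subptr[s + 1]; ++j) {
      const int idx = m->subidx[j];
      double v = (idx < n) ? y[idx] : (idx == n ? cav : dav);
      if (v < 0.0) v = 0.0;
      r *= v;
    }
    out[s] = r;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix jac_eval(SEXP ptr, double t, NumericVector y) {
  XPtr<Model> m(ptr);
  const int n = m->nspec;
  NumericMatrix J(n, n);
  const double cav = m->ca.value(t);
  const double dav = m->da.value(t);
  std::vector<double> conc(n + 2);
  for (int i = 0; i < n; ++i) conc[i] = y[i] < 0.0 ? 0.0 : y[i];
  conc[n] = cav; conc[n + 1] = dav;
  for (int s = 0; s < m->nsteps; ++s) {
    const double k = m->k[s];
    if (k == 0.0) continue;
    const int sb = m->subptr[s], se = m->subptr[s + 1];
    // partial derivative of the step rate w.r.t. each state substrate:
    // differentiate one occurrence, multiply the rest
    for (int jj = sb; jj < se; ++jj) {
      const int col = m->subidx[jj];
      if (col >= n) continue;  // forcing species carry no state derivative
      double part = k;
      bool skipped = false;
      for (int j2 = sb; j2 < se; ++j2) {
        if (j2 == jj) { skipped = true; continue; }
        part *= conc[m->subidx[j2]];
      }
      (void)skipped;
      for (int j = m->stptr[s]; j < m->stptr[s + 1]; ++j)
        J(m->stspec[j], col) += m->stdelta[j] * part;
    }
  }
  return J;
}
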