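// Fixed-step explicit RK4 integrator over a table-encoded reaction network.
// This is the independent cross-check path: it shares no integration code
// with the adaptive stiff solver used for production runs.

#include <Rcpp.h>
using namespace Rcpp;

// Rate-law variant codes (see build_cpp_tables() on the R side):
// 1 MassAction            par: k            spec: up to 3 substrates
// 2 MM (Vmax form)        par: Vmax, Km     spec: S
// 3 MM (kcat*E form)      par: kcat, Km     spec: S, E          (x volume)
// 4 MM partitioned        par: kcat, Km     spec: S, S2, E      (x volume)
// 5 Passive diffusion     par: k            spec: out, in
// 6 Hill synthesis        par: basal, Vmax, K, n, scale  spec: A (x volume)
// 7 First-order decay     par: k            spec: S             (x volume)
// 8 Constant source       par: k
static inline double flux_of(int variant, const double* p, const int* s,
                             double vol, const std::vector<double>& y) {
  switch (variant) {
    case 1: {
      double v = p[0] * vol;
      for (int j = 0; j < 3; ++j) {
        if (s[j] >= 0) v *= y[s[j]];
      }
      return v;
    }
    case 2: {
      double S = y[s[0]];
      return p[0] * S / (p[1] + S);
    }
    case 3: {
      double S = y[s[0]];
      return p[0] * y[s[1]] * vol * S / (p[1] + S);
    }
    case 4: {
      double S = y[s[0]], S2 = y[s[1]], E = y[s[2]];
      double tot = S + S2;
      if (tot <= 0.0) return 0.0;
      return p[0] * E * (S / tot) * vol * S / (p[1] + S);
    }
    case 5:
      return p[0] * (y[s[0]] - y[s[1]]);
    case 6: {
      double A = y[s[0]];
      double act = 0.0;
      if (A > 0.0) {
        double An = std::pow(A, p[3]);
        act = An / (std::pow(p[2], p[3]) + An);
      }
      return p[4] * (p[0] + p[1] * act) * vol;
    }
    case 7:
      return p[0] * y[s[0]] * vol;
    case 8:
      return p[0];
    default:
      return 0.0;
  }
}

struct Network {
  int n_reac;
  const int* variant;
  const double* par;   // n_reac x 5, column-major
  const int* spec;     // n_reac x 3, column-major
  const double* vol;
  int n_trip;
  const int* trip_r;
  const int* trip_s;
  const double* trip_m;
  int n_track;            // number of cumulative tracker states
  int n_track_rows;       // rows in the tracker table
  const int* track_slot;
  const int* track_type;  // 0 net flux, 1 gross inward diffusion
  const int* track_reac;
  const double* track_weight;
  int n_core;             // states before trackers
  int nr;                 // rows of the par/spec matrices
};

static void deriv(const Network& net, const std::vector<double>& y_raw,
                  std::vector<double>& yc, std::vector<double>& flux,
                  std::vector<double>& dy) {
  // clamp concentrations at zero for flux evaluation (solver-noise guard,
  // mirroring the R right-hand side)
  for (size_t j = 0; j < y_raw.size(); ++j) {
    yc[j] = y_raw[j] > 0.0 ? y_raw[j] : 0.0;
  }
  const std::vector<double>& y = yc;
  for (int i = 0; i < net.n_reac; ++i) {
    double p[5];
    int s[3];
    for (int j = 0; j < 5; ++j) p[j] = net.par[i + net.nr * j];
    for (int j = 0; j < 3; ++j) s[j] = net.spec[i + net.nr * j];
    flux[i] = flux_of(net.variant[i], p, s, net.vol[i], y);
  }
  std::fill(dy.begin(), dy.end(), 0.0);
  for (int k = 0; k < net.n_trip; ++k) {
    dy[net.trip_s[k]] += net.trip_m[k] * flux[net.trip_r[k]];
  }
  for (int k = 0; k < net.n_track_rows; ++k) {
    int r = net.track_reac[k];
    double v;
    if (net.track_type[k] == 1) {
      // gross inward part of a diffusion flux: k * [outside]
      double p0 = net.par[r];
      int out = net.spec[r];
      v = p0 * y[out];
    } else {
      v = flux[r];
    }
    dy[net.n_core + net.track_slot[k]] += net.track_weight[k] * v;
  }
}

// [[Rcpp::export]]
NumericMatrix rk4_integrate(NumericVector y0, double step, int n_records,
                            int record_every, IntegerVector variant,
                            NumericMatrix par, IntegerMatrix spec,
                            NumericVector vol, IntegerVector trip_r,
                            IntegerVector trip_s, NumericVector trip_m,
                            int n_track, IntegerVector track_slot,
                            IntegerVector track_type,
                            IntegerVector track_reac,
                            NumericVector track_weight) {
  const int n = y0.size();
  const int n_track_rows = track_type.size();

  Network net;
  net.n_reac = variant.size();
  net.variant = INTEGER(variant);
  net.par = REAL(par);
  net.spec = INTEGER(spec);
  net.vol = REAL(vol);
  net.n_trip = trip_r.size();
  net.trip_r = INTEGER(trip_r);
  net.trip_s = INTEGER(trip_s);
  net.trip_m = REAL(trip_m);
  net.n_track = n_track;
  net.n_track_rows = n_track_rows;
  net.track_slot = n_track_rows ? INTEGER(track_slot) : nullptr;
  net.track_type = n_track_rows ? INTEGER(track_type) : nullptr;
  net.track_reac = n_track_rows ? INTEGER(track_reac) : nullptr;
  net.track_weight = n_track_rows ? REAL(track_weight) : nullptr;
  net.n_core = n - n_track;
  net.nr = net.n_reac;

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), yc(n);
  std::vector<double> flux(net.n_reac);

  NumericMatrix out(n_records + 1, n);
  for (int j = 0; j < n; ++j) out(0, j) = y[j];

  const double h = step;
  for (int rec = 1; rec <= n_records; ++rec) {
    for (int s = 0; s < record_every; ++s) {
      deriv(net, y, yc, flux, k1);
      for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      deriv(net, tmp, yc, flux, k2);
      for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      deriv(net, tmp, yc, flux, k3);
      for (int j = 0; j < n; ++j) tmp[j] = y[j] + h * k3[j];
      deriv(net, tmp, yc, flux, k4);
      for (int j = 0; j < n; ++j) {
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      }
    }
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(y[j])) stop("rk4 integration diverged");
      out(rec, j) = y[j];
    }
    if (rec % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
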