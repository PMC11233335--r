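#include <Rcpp.h>
using namespace Rcpp;

// Closed-form finishing-time density/CDF for one linear ballistic
// accumulator: start ~ U(0, A), drift ~ N(v, s), boundary b = A + B.
// Negative drifts never reach the boundary, so the raw CDF is defective
// with mass Phi(v/s) at infinity; the truncated convention conditions each
// accumulator on a positive drift (divide by Phi(v/s)).

static const double LOG_FLOOR = -700.0;

// standard normal pdf/cdf; the cdf goes through erfc (full double
// precision) with hard tail shortcuts
static inline double dnorm1(double x) {
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}
static inline double pnorm1(double x) {
  if (x < -37.5) return 0.0;
  if (x > 8.3) return 1.0;
  return 0.5 * std::erfc(-x * 0.7071067811865476);
}

static inline double lba_pdf1(double t, double A, double b, double v,
                              double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  if (ts < 1e-12) return 0.0;
  // degenerate start point: T = b / drift
  if (A < 1e-8 * b) {
    double x = (t * v - b) / ts;
    return dnorm1(x) * b / (ts * t);
  }
  double chi = (b - A - t * v) / ts;
  double omg = (b - t * v) / ts;
  double f = (-v * pnorm1(chi) +
              s * dnorm1(chi) +
              v * pnorm1(omg) -
              s * dnorm1(omg)) / A;
  return f > 0.0 ? f : 0.0;
}

static inline double lba_cdf1(double t, double A, double b, double v,
                              double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  if (ts < 1e-12) return 0.0;
  double F;
  if (A < 1e-8 * b) {
    F = pnorm1((t * v - b) / ts);
  } else {
    double chi = (b - A - t * v) / ts;
    double omg = (b - t * v) / ts;
    F = 1.0 + ((b - A - t * v) / A) * pnorm1(chi)
            - ((b - t * v) / A) * pnorm1(omg)
            + (ts / A) * dnorm1(chi)
            - (ts / A) * dnorm1(omg);
  }
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

// [[Rcpp::export(name = ".lba_pdf_cpp")]]
NumericVector lba_pdf_cpp(NumericVector t, double A, double b, double v,
                          double s, bool truncated) {
  int n = t.size();
  NumericVector out(n);
  double pos = truncated ? pnorm1(v / s) : 1.0;
  for (int i = 0; i < n; ++i) out[i] = lba_pdf1(t[i], A, b, v, s) / pos;
  return out;
}

// [[Rcpp::export(name = ".lba_cdf_cpp")]]
NumericVector lba_cdf_cpp(NumericVector t, double A, double b, double v,
                          double s, bool truncated) {
  int n = t.size();
  NumericVector out(n);
  double pos = truncated ? pnorm1(v / s) : 1.0;
  for (int i = 0; i < n; ++i) {
    double F = lba_cdf1(t[i], A, b, v, s) / pos;
    out[i] = F > 1.0 ? 1.0 : F;
  }
  return out;
}

// Joint density of (winner, rt) for the two-accumulator race in one cell.
// par holds A, B, t0, sv, v_norm, v_ab; winner: 0 = normative, 1 = aberrant.
static inline double race_dens1(double rt, int winner, double A, double B,
                                double t0, double s, double vn, double va,
                                bool truncated) {
  double dt = rt - t0;
  if (dt <= 0.0) return 0.0;
  double b = A + B;
  double vw = winner == 0 ? vn : va;
  double vl = winner == 0 ? va : vn;
  double fw = lba_pdf1(dt, A, b, vw, s);
  double Fl = lba_cdf1(dt, A, b, vl, s);
  if (truncated) {
    fw /= pnorm1(vw / s);
    Fl /= pnorm1(vl / s);
    if (Fl > 1.0) Fl = 1.0;
  }
  return fw * (1.0 - Fl);
}

// [[Rcpp::export(name = ".race_density_cpp")]]
NumericVector race_density_cpp(NumericVector rt, IntegerVector winner,
                               IntegerVector cell, NumericMatrix par,
                               bool truncated) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = cell[i];
    out[i] = race_dens1(rt[i], winner[i], par(k, 0), par(k, 1), par(k, 2),
                        par(k, 3), par(k, 4), par(k, 5), truncated);
  }
  return out;
}

// [[Rcpp::export(name = ".race_loglik_cpp")]]
double race_loglik_cpp(NumericVector rt, IntegerVector winner,
                       IntegerVector cell, NumericMatrix par,
                       bool truncated) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = cell[i];
    double d = race_dens1(rt[i], winner[i], par(k, 0), par(k, 1), par(k, 2),
                          par(k, 3), par(k, 4), par(k, 5), truncated);
    double ld = d > 0.0 ? std::log(d) : LOG_FLOOR;
    ll += ld < LOG_FLOOR ? LOG_FLOOR : ld;
  }
  return ll;
}

// Log-likelihood of one subject's trials for many parameter vectors at
// once (one row per MCMC chain/draw). cellpar has 24 columns: for cell k
// (0..3), columns 6k..6k+5 hold A, B, t0, sv, v_norm, v_ab.
// [[Rcpp::export(name = ".race_loglik_rows_cpp")]]
NumericVector race_loglik_rows_cpp(NumericMatrix cellpar, NumericVector rt,
                                   IntegerVector winner, IntegerVector cell,
                                   bool truncated) {
  int C = cellpar.nrow();
  int n = rt.size();
  NumericVector out(C);
  double Ak[4], bk[4], t0k[4], sk[4], vnk[4], vak[4], pnk[4], pak[4];
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 4; ++k) {
      int k6 = 6 * k;
      Ak[k] = cellpar(c, k6);
      bk[k] = cellpar(c, k6) + cellpar(c, k6 + 1);
      t0k[k] = cellpar(c, k6 + 2);
      sk[k] = cellpar(c, k6 + 3);
      vnk[k] = cellpar(c, k6 + 4);
      vak[k] = cellpar(c, k6 + 5);
      pnk[k] = truncated ? pnorm1(vnk[k] / sk[k]) : 1.0;
      pak[k] = truncated ? pnorm1(vak[k] / sk[k]) : 1.0;
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      int k = cell[i];
      double dt = rt[i] - t0k[k];
      double d = 0.0;
      if (dt > 0.0) {
        double vw, vl, pw, pl;
        if (winner[i] == 0) {
          vw = vnk[k]; vl = vak[k]; pw = pnk[k]; pl = pak[k];
        } else {
          vw = vak[k]; vl = vnk[k]; pw = pak[k]; pl = pnk[k];
        }
        double fw = lba_pdf1(dt, Ak[k], bk[k], vw, sk[k]) / pw;
        double Fl = lba_cdf1(dt, Ak[k], bk[k], vl, sk[k]) / pl;
        if (Fl > 1.0) Fl = 1.0;
        d = fw * (1.0 - Fl);
      }
      double ld = d > 0.0 ? std::log(d) : LOG_FLOOR;
      ll += ld < LOG_FLOOR ? LOG_FLOOR : ld;
    }
    out[c] = ll;
  }
  return out;
}
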