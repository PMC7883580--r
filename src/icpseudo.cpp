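// Illness-death likelihood core: restricted cubic spline basis on log time,
// per-dataset cache of basis values at quadrature nodes, trajectory-wise
// likelihood contributions with analytic gradients.  The cache makes the
// jackknife (n leave-one-out refits per dataset) affordable: basis values and
// quadrature layouts depend only on the data and the knots, never on the
// coefficients, so they are computed once and every refit skips one subject.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SCLAMP = 690.0;    // exp() overflow guard on the log-cumhaz scale
static const int MAXP = 16;            // max spline dimension per transition

static inline double cexp(double s) { return std::exp(s > SCLAMP ? SCLAMP : s); }

static inline double dot(const double* b, const double* g, int p) {
  double s = 0.0;
  for (int i = 0; i < p; ++i) s += b[i] * g[i];
  return s;
}

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes and weights on [0, 1]
// ---------------------------------------------------------------------------
static void gl01(int n, std::vector<double>& x, std::vector<double>& w) {
  x.assign(n, 0.0); w.assign(n, 0.0);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1 = 2.0, pp = 0.0;
    while (std::fabs(z - z1) > 1e-15) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z; z = z1 - p1 / pp;
    }
    x[i] = 0.5 * (1.0 - z);
    x[n - 1 - i] = 0.5 * (1.0 + z);
    w[i] = 1.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

// [[Rcpp::export]]
List cpp_gl_nodes(int n) {
  std::vector<double> x, w;
  gl01(n, x, w);
  return List::create(_["nodes"] = NumericVector(x.begin(), x.end()),
                      _["weights"] = NumericVector(w.begin(), w.end()));
}

// ---------------------------------------------------------------------------
// Restricted cubic spline basis in x = ln(t)
// ---------------------------------------------------------------------------
struct TSpec {
  std::vector<double> ik, lam;
  double b0, b1;
  int dim;
};

static TSpec make_spec(NumericVector ik, NumericVector bk) {
  TSpec s;
  s.b0 = bk[0]; s.b1 = bk[1];
  for (R_xlen_t j = 0; j < ik.size(); ++j) {
    s.ik.push_back(ik[j]);
    s.lam.push_back((s.b1 - ik[j]) / (s.b1 - s.b0));
  }
  s.dim = 2 + (int)ik.size();
  if (s.dim > MAXP) stop("too many internal knots (basis dimension > %d)", MAXP);
  return s;
}

static inline void basis_at(const TSpec& s, double x, double* B) {
  B[0] = 1.0; B[1] = x;
  for (size_t j = 0; j < s.ik.size(); ++j) {
    double v = 0.0;
    double a = x - s.ik[j], p = x - s.b0, q = x - s.b1;
    if (a > 0) v += a * a * a;
    if (p > 0) v -= s.lam[j] * p * p * p;
    if (q > 0) v -= (1.0 - s.lam[j]) * q * q * q;
    B[2 + j] = v;
  }
}

static inline void dbasis_at(const TSpec& s, double x, double* D) {
  D[0] = 0.0; D[1] = 1.0;
  for (size_t j = 0; j < s.ik.size(); ++j) {
    double v = 0.0;
    double a = x - s.ik[j], p = x - s.b0, q = x - s.b1;
    if (a > 0) v += 3.0 * a * a;
    if (p > 0) v -= 3.0 * s.lam[j] * p * p;
    if (q > 0) v -= 3.0 * (1.0 - s.lam[j]) * q * q;
    D[2 + j] = v;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ncs_basis(NumericVector x, NumericVector ik, NumericVector bk) {
  TSpec s = make_spec(ik, bk);
  NumericMatrix out(x.size(), s.dim);
  std::vector<double> B(s.dim);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    basis_at(s, x[i], B.data());
    for (int j = 0; j < s.dim; ++j) out(i, j) = B[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ncs_basis_deriv(NumericVector x, NumericVector ik, NumericVector bk) {
  TSpec s = make_spec(ik, bk);
  NumericMatrix out(x.size(), s.dim);
  std::vector<double> D(s.dim);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    dbasis_at(s, x[i], D.data());
    for (int j = 0; j < s.dim; ++j) out(i, j) = D[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dataset cache
// ---------------------------------------------------------------------------
// Trajectory forms: type 1 = exact event, type 2 = no observed event,
// type 3 = interval-censored event.  d2 distinguishes death from censoring.
struct Subj {
  int type, d2;
  double t1, t2;
  std::vector<double> B01x1, D01x1, B02x1, B12x1;   // type 1, at ln t1
  std::vector<double> B01x2, B02x2, D02x2;          // type 2, at ln t2
  std::vector<double> B12x2, D12x2;                 // all types, at ln t2
  int nq;                                           // quadrature nodes (types 2, 3)
  std::vector<double> qw, qinvu, qB01, qD01, qB02, qB12;
};

struct Cache {
  TSpec s1, s2, s3;
  int p1, p2, p3, n;
  std::vector<Subj> subj;
};

// [[Rcpp::export]]
SEXP cpp_build_cache(NumericVector l1, NumericVector t1, NumericVector t2,
                     IntegerVector d1, IntegerVector exact, IntegerVector d2,
                     List iknots, List bknots, int nnodes) {
  Cache* C = new Cache;
  C->s1 = make_spec(iknots[0], bknots[0]);
  C->s2 = make_spec(iknots[1], bknots[1]);
  C->s3 = make_spec(iknots[2], bknots[2]);
  C->p1 = C->s1.dim; C->p2 = C->s2.dim; C->p3 = C->s3.dim;
  C->n = (int)l1.size();

  std::vector<double> gx, gw;
  gl01(nnodes, gx, gw);

  std::vector<double> buf(MAXP);
  C->subj.resize(C->n);
  for (int i = 0; i < C->n; ++i) {
    Subj& S = C->subj[i];
    S.d2 = d2[i];
    S.t1 = t1[i]; S.t2 = t2[i];
    S.type = (d1[i] == 0) ? 2 : (exact[i] == 1 ? 1 : 3);
    double x2 = std::log(t2[i]);

    auto fill = [&](const TSpec& sp, double x, std::vector<double>& dst, bool deriv) {
      dst.resize(sp.dim);
      if (deriv) dbasis_at(sp, x, dst.data()); else basis_at(sp, x, dst.data());
    };

    fill(C->s3, x2, S.B12x2, false);
    fill(C->s3, x2, S.D12x2, true);

    double a = NA_REAL, b = NA_REAL;
    if (S.type == 1) {
      double x1 = std::log(t1[i]);
      fill(C->s1, x1, S.B01x1, false);
      fill(C->s1, x1, S.D01x1, true);
      fill(C->s2, x1, S.B02x1, false);
      fill(C->s3, x1, S.B12x1, false);
      S.nq = 0;
    } else if (S.type == 2) {
      fill(C->s1, x2, S.B01x2, false);
      fill(C->s2, x2, S.B02x2, false);
      fill(C->s2, x2, S.D02x2, true);
      a = l1[i]; b = t2[i];
      S.nq = (a < b) ? nnodes : 0;
    } else {
      a = l1[i]; b = t1[i];
      S.nq = (a < b) ? nnodes : 0;
      if (S.nq == 0) stop("interval-censored record %d has zero-length interval", i + 1);
    }

    if (S.nq > 0) {
      // u = a + (b - a) w^2 regularizes the integrable left-endpoint
      // singularity of h01 (~ u^{b-1}, b < 1) when a = 0.
      S.qw.resize(S.nq); S.qinvu.resize(S.nq);
      S.qB01.resize((size_t)S.nq * C->p1);
      S.qD01.resize((size_t)S.nq * C->p1);
      S.qB02.resize((size_t)S.nq * C->p2);
      S.qB12.resize((size_t)S.nq * C->p3);
      for (int k = 0; k < S.nq; ++k) {
        double w = gx[k];
        double u = a + (b - a) * w * w;
        if (u <= 0) u = 1e-300;
        S.qw[k] = gw[k] * 2.0 * (b - a) * w;
        S.qinvu[k] = 1.0 / u;
        double xu = std::log(u);
        basis_at(C->s1, xu, buf.data());
        for (int j = 0; j < C->p1; ++j) S.qB01[(size_t)k * C->p1 + j] = buf[j];
        dbasis_at(C->s1, xu, buf.data());
        for (int j = 0; j < C->p1; ++j) S.qD01[(size_t)k * C->p1 + j] = buf[j];
        basis_at(C->s2, xu, buf.data());
        for (int j = 0; j < C->p2; ++j) S.qB02[(size_t)k * C->p2 + j] = buf[j];
        basis_at(C->s3, xu, buf.data());
        for (int j = 0; j < C->p3; ++j) S.qB12[(size_t)k * C->p3 + j] = buf[j];
      }
    }
  }
  XPtr<Cache> ptr(C, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_cache_dims(SEXP ptr) {
  XPtr<Cache> C(ptr);
  return IntegerVector::create(C->p1, C->p2, C->p3, C->n);
}

// ---------------------------------------------------------------------------
// Per-subject log contribution (and gradient)
// ---------------------------------------------------------------------------
static double subj_ll(const Cache& C, const Subj& S,
                      const double* g1, const double* g2, const double* g3,
                      double* G) {
  const int p1 = C.p1, p2 = C.p2, p3 = C.p3;
  const double ninf = R_NegInf;
  double* G1 = G;
  double* G2 = G ? G + p1 : 0;
  double* G3 = G ? G + p1 + p2 : 0;

  if (S.type == 1) {
    double s01 = dot(S.B01x1.data(), g1, p1);
    double sp01 = dot(S.D01x1.data(), g1, p1);
    if (sp01 <= 0) return ninf;                      // negative hazard at exact event
    double H01 = cexp(s01);
    double H02 = cexp(dot(S.B02x1.data(), g2, p2));
    double H12a = cexp(dot(S.B12x1.data(), g3, p3));
    double s12b = dot(S.B12x2.data(), g3, p3);
    double H12b = cexp(s12b);
    double ll = -H01 - H02 + std::log(sp01) - std::log(S.t1) + s01 - (H12b - H12a);
    double sp12 = 0.0;
    if (S.d2) {
      sp12 = dot(S.D12x2.data(), g3, p3);
      if (sp12 <= 0) return ninf;                    // negative hazard at exact death
      ll += std::log(sp12) - std::log(S.t2) + s12b;
    }
    if (!std::isfinite(ll)) return ninf;
    if (G) {
      for (int i = 0; i < p1; ++i)
        G1[i] += S.B01x1[i] * (1.0 - H01) + S.D01x1[i] / sp01;
      for (int i = 0; i < p2; ++i)
        G2[i] += -H02 * S.B02x1[i];
      for (int i = 0; i < p3; ++i)
        G3[i] += H12a * S.B12x1[i] - H12b * S.B12x2[i];
      if (S.d2)
        for (int i = 0; i < p3; ++i)
          G3[i] += S.B12x2[i] + S.D12x2[i] / sp12;
    }
    return ll;
  }

  // types 2 and 3 share the integral term
  double A = 0.0, S2 = 0.0, H01b = 0.0, H02b = 0.0, sp02 = 0.0, h02 = 1.0;
  if (S.type == 2) {
    H01b = cexp(dot(S.B01x2.data(), g1, p1));
    H02b = cexp(dot(S.B02x2.data(), g2, p2));
    S2 = std::exp(-(H01b + H02b));
    A = S2;
    if (S.d2) {
      sp02 = dot(S.D02x2.data(), g2, p2);
      h02 = sp02 * H02b / S.t2;
      A *= h02;                                      // may be negative; total must be > 0
    }
  }

  double J = 0.0, Cc = 0.0, H12b = 0.0, sp12 = 0.0, h12 = 1.0;
  double dJ1[MAXP] = {0}, dJ2[MAXP] = {0}, dJ3[MAXP] = {0};
  if (S.nq > 0) {
    double s12b = dot(S.B12x2.data(), g3, p3);
    H12b = cexp(s12b);
    for (int k = 0; k < S.nq; ++k) {
      const double* B01u = &S.qB01[(size_t)k * p1];
      const double* D01u = &S.qD01[(size_t)k * p1];
      const double* B02u = &S.qB02[(size_t)k * p2];
      const double* B12u = &S.qB12[(size_t)k * p3];
      double s01u = dot(B01u, g1, p1);
      double sp01u = dot(D01u, g1, p1);
      double H01u = cexp(s01u);
      double h01u = sp01u * H01u * S.qinvu[k];
      double H02u = cexp(dot(B02u, g2, p2));
      double Su = std::exp(-(H01u + H02u));
      double H12u = cexp(dot(B12u, g3, p3));
      double ed = H12u - H12b;
      double E = std::exp(ed > SCLAMP ? SCLAMP : ed);
      double f = Su * h01u * E;
      J += S.qw[k] * f;
      if (G) {
        double c1 = S.qw[k] * E * Su;
        for (int i = 0; i < p1; ++i)
          dJ1[i] += c1 * (h01u * (1.0 - H01u) * B01u[i] + H01u * S.qinvu[k] * D01u[i]);
        double c2 = -S.qw[k] * f * H02u;
        for (int i = 0; i < p2; ++i)
          dJ2[i] += c2 * B02u[i];
        double c3 = S.qw[k] * f;
        for (int i = 0; i < p3; ++i)
          dJ3[i] += c3 * (H12u * B12u[i] - H12b * S.B12x2[i]);
      }
    }
    if (S.d2) {
      sp12 = dot(S.D12x2.data(), g3, p3);
      h12 = sp12 * H12b / S.t2;
    }
    Cc = J * h12;
  }

  double L = A + Cc;
  if (!(L > 0.0) || !std::isfinite(L)) return ninf;
  if (G) {
    if (S.type == 2) {
      for (int i = 0; i < p1; ++i)
        G1[i] += -A * H01b * S.B01x2[i] / L;
      if (S.d2) {
        for (int i = 0; i < p2; ++i)
          G2[i] += (A * (1.0 - H02b) * S.B02x2[i] + S2 * (H02b / S.t2) * S.D02x2[i]) / L;
      } else {
        for (int i = 0; i < p2; ++i)
          G2[i] += -A * H02b * S.B02x2[i] / L;
      }
    }
    if (S.nq > 0) {
      for (int i = 0; i < p1; ++i) G1[i] += h12 * dJ1[i] / L;
      for (int i = 0; i < p2; ++i) G2[i] += h12 * dJ2[i] / L;
      for (int i = 0; i < p3; ++i) G3[i] += h12 * dJ3[i] / L;
      if (S.d2)
        for (int i = 0; i < p3; ++i)
          G3[i] += (h12 * S.B12x2[i] + (H12b / S.t2) * S.D12x2[i]) * J / L;
    }
  }
  return std::log(L);
}

// [[Rcpp::export]]
double cpp_idm_loglik(SEXP ptr, NumericVector gamma, int skip) {
  XPtr<Cache> C(ptr);
  if ((int)gamma.size() != C->p1 + C->p2 + C->p3)
    stop("coefficient vector has wrong length");
  const double* g1 = gamma.begin();
  const double* g2 = g1 + C->p1;
  const double* g3 = g2 + C->p2;
  double ll = 0.0;
  for (int i = 0; i < C->n; ++i) {
    if (i + 1 == skip) continue;
    double li = subj_ll(*C, C->subj[i], g1, g2, g3, 0);
    if (li == R_NegInf) return R_NegInf;
    ll += li;
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_idm_loglik_grad(SEXP ptr, NumericVector gamma, int skip) {
  XPtr<Cache> C(ptr);
  int p = C->p1 + C->p2 + C->p3;
  if ((int)gamma.size() != p) stop("coefficient vector has wrong length");
  const double* g1 = gamma.begin();
  const double* g2 = g1 + C->p1;
  const double* g3 = g2 + C->p2;
  NumericVector grad(p);
  double ll = 0.0;
  for (int i = 0; i < C->n; ++i) {
    if (i + 1 == skip) continue;
    double li = subj_ll(*C, C->subj[i], g1, g2, g3, grad.begin());
    if (li == R_NegInf)
      return List::create(_["loglik"] = R_NegInf, _["gradient"] = NumericVector(p));
    ll += li;
  }
  return List::create(_["loglik"] = ll, _["gradient"] = grad);
}

// [[Rcpp::export]]
NumericVector cpp_contributions(SEXP ptr, NumericVector gamma) {
  XPtr<Cache> C(ptr);
  if ((int)gamma.size() != C->p1 + C->p2 + C->p3)
    stop("coefficient vector has wrong length");
  const double* g1 = gamma.begin();
  const double* g2 = g1 + C->p1;
  const double* g3 = g2 + C->p2;
  NumericVector out(C->n);
  for (int i = 0; i < C->n; ++i) {
    double li = subj_ll(*C, C->subj[i], g1, g2, g3, 0);
    out[i] = (li == R_NegInf) ? 0.0 : std::exp(li);
  }
  return out;
}
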