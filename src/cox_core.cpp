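// Cox partial-likelihood machinery: objective value, score, observed
// information, Firth-modified score (analytic third-moment risk-set sums),
// and a step-clipped, step-halving Newton-Raphson driver supporting fixed
// (profiled-out) coordinates.  Breslow risk sets; subjects censored at t
// remain at risk for events at t.
//
// The evaluator groups subjects by distinct covariate pattern (binary
// marker/treatment designs have at most four), so a risk-set sweep costs
// O(1) per subject plus O(q * p^3) per distinct event time.  Determinants
// and inverses of the (at most 3 x 3) information are closed-form to keep
// LAPACK out of the inner loop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace arma;

struct SortedData {
  mat X;        // n x p, sorted by decreasing time
  vec t;        // sorted times
  ivec d;       // event indicators, same order
  uvec pid;     // pattern index per subject
  mat P;        // q x p distinct covariate rows
  uword n, p, q;
};

static void prepare(const mat &X, const vec &time, const ivec &status,
                    SortedData &S) {
  uvec ord = sort_index(time, "descend");
  S.X = X.rows(ord);
  S.t = time(ord);
  S.d = status(ord);
  S.n = X.n_rows;
  S.p = X.n_cols;

  std::map<std::vector<double>, uword> seen;
  S.pid.set_size(S.n);
  std::vector<std::vector<double>> pats;
  std::vector<double> key(S.p);
  for (uword i = 0; i < S.n; ++i) {
    for (uword a = 0; a < S.p; ++a) key[a] = S.X(i, a);
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen.emplace(key, pats.size());
      S.pid(i) = pats.size();
      pats.push_back(key);
    } else {
      S.pid(i) = it->second;
    }
  }
  S.q = pats.size();
  S.P.set_size(S.q, S.p);
  for (uword j = 0; j < S.q; ++j)
    for (uword a = 0; a < S.p; ++a) S.P(j, a) = pats[j][a];
}

// determinant and inverse of a symmetric positive-definite matrix,
// closed-form up to 3 x 3 (general fallback through arma)
static bool sym_inv_det(const mat &A, mat &Ainv, double &det) {
  const uword p = A.n_rows;
  if (p == 1) {
    det = A(0, 0);
    if (det <= 0) return false;
    Ainv(0, 0) = 1.0 / det;
    return true;
  }
  if (p == 2) {
    det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    if (det <= 0) return false;
    Ainv(0, 0) = A(1, 1) / det;
    Ainv(1, 1) = A(0, 0) / det;
    Ainv(0, 1) = Ainv(1, 0) = -A(0, 1) / det;
    return true;
  }
  if (p == 3) {
    const double a = A(0, 0), b = A(0, 1), c = A(0, 2);
    const double d = A(1, 1), e = A(1, 2), f = A(2, 2);
    const double c00 = d * f - e * e;
    const double c01 = c * e - b * f;
    const double c02 = b * e - c * d;
    det = a * c00 + b * c01 + c * c02;
    if (det <= 0) return false;
    Ainv(0, 0) = c00 / det;
    Ainv(0, 1) = Ainv(1, 0) = c01 / det;
    Ainv(0, 2) = Ainv(2, 0) = c02 / det;
    Ainv(1, 1) = (a * f - c * c) / det;
    Ainv(1, 2) = Ainv(2, 1) = (b * c - a * e) / det;
    Ainv(2, 2) = (a * d - b * b) / det;
    return true;
  }
  det = arma::det(A);
  if (det <= 0) return false;
  return inv_sympd(Ainv, symmatu(A));
}

struct CoxEval {
  double loglik;  // unpenalized partial log-likelihood
  double obj;     // objective: loglik (+ 0.5 log det I if firth)
  vec score;      // gradient of loglik
  vec gobj;       // gradient of objective (modified score if firth)
  mat info;       // observed information (= -Hessian of loglik)
  bool ok;        // information nonsingular and everything finite
  void init(uword p) {
    score.set_size(p);
    gobj.set_size(p);
    info.set_size(p, p);
  }
};

struct Workspace {
  vec wpat, eta, cnt, s1, m, sum_x;
  mat s2, S2n, Iinv;
  cube s3, dinfo;
  void init(uword p, uword q, bool firth) {
    wpat.set_size(q); eta.set_size(q); cnt.set_size(q);
    s1.set_size(p); m.set_size(p); sum_x.set_size(p);
    s2.set_size(p, p); S2n.set_size(p, p); Iinv.set_size(p, p);
    if (firth) { s3.set_size(p, p, p); dinfo.set_size(p, p, p); }
  }
};

static void cox_eval(const SortedData &S, const vec &beta, const bool firth,
                     Workspace &W, CoxEval &out) {
  const uword n = S.n, p = S.p, q = S.q;
  for (uword j = 0; j < q; ++j) {
    W.eta(j) = dot(S.P.row(j), beta);
    W.wpat(j) = std::exp(W.eta(j));
  }
  W.cnt.zeros();

  out.loglik = 0.0;
  out.score.zeros();
  out.info.zeros();
  if (firth) W.dinfo.zeros();
  out.ok = true;

  uword i = 0;
  while (i < n) {
    const double t = S.t(i);
    uword j = i;
    uword nev = 0;
    double sum_eta = 0.0;
    W.sum_x.zeros();
    // enter every subject tied at t into the risk set before any event at t
    while (j < n && S.t(j) == t) {
      const uword g = S.pid(j);
      W.cnt(g) += 1.0;
      if (S.d(j) == 1) {
        ++nev;
        sum_eta += W.eta(g);
        for (uword a = 0; a < p; ++a) W.sum_x(a) += S.P(g, a);
      }
      ++j;
    }
    if (nev > 0) {
      // risk-set moments from the pattern counts
      double s0 = 0.0;
      W.s1.zeros();
      W.s2.zeros();
      if (firth) W.s3.zeros();
      for (uword g = 0; g < q; ++g) {
        const double cw = W.cnt(g) * W.wpat(g);
        if (cw == 0.0) continue;
        s0 += cw;
        for (uword a = 0; a < p; ++a) {
          const double xa = S.P(g, a);
          if (xa == 0.0) continue;
          const double cwa = cw * xa;
          W.s1(a) += cwa;
          for (uword b = 0; b < p; ++b) {
            const double xb = S.P(g, b);
            if (xb == 0.0) continue;
            W.s2(a, b) += cwa * xb;
            if (firth)
              for (uword c = 0; c < p; ++c)
                W.s3(a, b, c) += cwa * xb * S.P(g, c);
          }
        }
      }
      out.loglik += sum_eta - nev * std::log(s0);
      for (uword a = 0; a < p; ++a) W.m(a) = W.s1(a) / s0;
      for (uword a = 0; a < p; ++a) {
        out.score(a) += W.sum_x(a) - nev * W.m(a);
        for (uword b = 0; b < p; ++b) {
          W.S2n(a, b) = W.s2(a, b) / s0;
          out.info(a, b) += nev * (W.S2n(a, b) - W.m(a) * W.m(b));
        }
      }
      if (firth) {
        for (uword c = 0; c < p; ++c)
          for (uword a = 0; a < p; ++a)
            for (uword b = 0; b < p; ++b)
              W.dinfo(a, b, c) += nev *
                (W.s3(a, b, c) / s0 - W.S2n(a, b) * W.m(c) -
                 W.S2n(a, c) * W.m(b) - W.m(a) * W.S2n(b, c) +
                 2.0 * W.m(a) * W.m(b) * W.m(c));
      }
    }
    i = j;
  }

  out.obj = out.loglik;
  for (uword a = 0; a < p; ++a) out.gobj(a) = out.score(a);
  if (firth) {
    double det;
    if (!sym_inv_det(out.info, W.Iinv, det)) {
      out.ok = false;
      return;
    }
    out.obj += 0.5 * std::log(det);
    for (uword a = 0; a < p; ++a) {
      double tr = 0.0;
      for (uword b = 0; b < p; ++b)
        for (uword c = 0; c < p; ++c)
          tr += W.Iinv(b, c) * W.dinfo(c, b, a);
      out.gobj(a) += 0.5 * tr;
    }
  }
  if (!std::isfinite(out.obj) || !out.gobj.is_finite()) out.ok = false;
}

// [[Rcpp::export]]
Rcpp::List cox_eval_cpp(const arma::mat &X, const arma::vec &time,
                        const arma::ivec &status, const arma::vec &beta,
                        const bool firth) {
  SortedData S;
  prepare(X, time, status, S);
  Workspace W;
  W.init(S.p, S.q, firth);
  CoxEval ev;
  ev.init(S.p);
  cox_eval(S, beta, firth, W, ev);
  return Rcpp::List::create(
      Rcpp::Named("loglik") = ev.loglik, Rcpp::Named("objective") = ev.obj,
      Rcpp::Named("score") = ev.score, Rcpp::Named("grad_objective") = ev.gobj,
      Rcpp::Named("info") = ev.info, Rcpp::Named("ok") = ev.ok);
}

// Newton-Raphson with per-coordinate step clipping and step-halving.
// free(k) == 0 keeps coordinate k fixed at its beta_init value (profiling).
// [[Rcpp::export]]
Rcpp::List cox_newton_cpp(const arma::mat &X, const arma::vec &time,
                          const arma::ivec &status, const arma::vec &beta_init,
                          const arma::ivec &free, const bool firth,
                          const int maxiter, const double maxstep,
                          const double tol) {
  SortedData S;
  prepare(X, time, status, S);
  Workspace W;
  W.init(S.p, S.q, firth);

  const uword p = X.n_cols;
  uvec idx = find(free == 1);
  const uword pf = idx.n_elem;
  vec beta = beta_init, beta_try = beta_init;
  mat Iff(pf, pf), Iffinv(pf, pf);
  vec step(pf);
  CoxEval ev, ev_new;
  ev.init(p);
  ev_new.init(p);
  bool converged = false, singular = false;
  int iter = 0;

  cox_eval(S, beta, firth, W, ev);
  if (!ev.ok) singular = true;

  for (iter = 0; !singular; ++iter) {
    if (pf == 0 || norm(ev.gobj(idx), "inf") < tol) {
      converged = true;
      break;
    }
    if (iter == maxiter) break;  // step budget exhausted: not converged
    for (uword a = 0; a < pf; ++a)
      for (uword b = 0; b < pf; ++b) Iff(a, b) = ev.info(idx(a), idx(b));
    double det;
    if (!sym_inv_det(Iff, Iffinv, det)) {
      singular = true;
      break;
    }
    double amax = 0.0;
    for (uword a = 0; a < pf; ++a) {
      double s = 0.0;
      for (uword b = 0; b < pf; ++b) s += Iffinv(a, b) * ev.gobj(idx(b));
      step(a) = s;
      amax = std::max(amax, std::fabs(s));
    }
    // bound the step size: rescale the whole Newton increment so its
    // largest coordinate is maxstep; rescaling (unlike per-coordinate
    // clipping) preserves the ascent direction
    if (amax > maxstep) step *= maxstep / amax;
    // step-halving: the information underestimates the curvature of the
    // penalized objective, so an unguarded step can overshoot and cycle
    for (int h = 0; h < 12; ++h) {
      beta_try = beta;
      for (uword a = 0; a < pf; ++a) beta_try(idx(a)) += step(a);
      cox_eval(S, beta_try, firth, W, ev_new);
      if (ev_new.ok && ev_new.obj >= ev.obj - 1e-12) break;
      step *= 0.5;
    }
    if (!ev_new.ok) { singular = true; break; }
    beta = beta_try;
    std::swap(ev, ev_new);
  }

  mat vcov(p, p);
  double detv;
  bool vcov_ok = !singular && sym_inv_det(ev.info, vcov, detv);
  if (!vcov_ok) vcov.fill(datum::nan);

  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta, Rcpp::Named("loglik") = ev.loglik,
      Rcpp::Named("objective") = ev.obj, Rcpp::Named("score") = ev.gobj,
      Rcpp::Named("info") = ev.info, Rcpp::Named("vcov") = vcov,
      Rcpp::Named("converged") = converged, Rcpp::Named("iterations") = iter,
      Rcpp::Named("singular") = singular);
}
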