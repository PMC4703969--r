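// Compiled numerical core: projection of points onto the convex hull of
// candidate vertices (margin-of-error), exhaustive vertex-subset search,
// per-gene non-negative least squares, and affinity propagation message
// passing. All loops here are hot paths: the vertex search visits up to
// C(M,K) subsets and APC is O(N^2) per iteration.

#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Minimize a' Q a - 2 q' a  s.t.  sum(a) = 1, a >= 0   (primal active set).
// Q is the Gram matrix of the candidate vertices, q the cross products with
// the point being projected. Returns the optimal objective; alpha_out (size
// K) receives the optimal weights. Squared margin = c + objective where c is
// the squared norm of the point.
double simplex_qp(const mat& Q, const vec& q, vec& alpha_out) {
  const uword K = Q.n_rows;
  if (K == 1) { alpha_out = vec(1, fill::ones); return Q(0, 0) - 2.0 * q(0); }

  // start from the single best vertex
  vec diagc = Q.diag() - 2.0 * q;
  uword j0 = diagc.index_min();
  vec alpha(K, fill::zeros);
  alpha(j0) = 1.0;
  std::vector<uword> S;
  S.push_back(j0);
  std::vector<bool> inS(K, false);
  inS[j0] = true;

  const double tol = 1e-12;
  const uword max_iter = 30 * K + 50;

  for (uword it = 0; it < max_iter; ++it) {
    const uword ns = S.size();
    // KKT system for the equality-constrained subproblem on support S
    mat Ksys(ns + 1, ns + 1, fill::zeros);
    vec rhs(ns + 1, fill::zeros);
    for (uword a = 0; a < ns; ++a) {
      for (uword b = 0; b < ns; ++b) Ksys(a, b) = 2.0 * Q(S[a], S[b]);
      Ksys(a, ns) = 1.0;
      Ksys(ns, a) = 1.0;
      rhs(a) = 2.0 * q(S[a]);
    }
    rhs(ns) = 1.0;
    vec sol;
    bool ok = solve(sol, Ksys, rhs, solve_opts::no_approx);
    if (!ok) {
      for (uword a = 0; a < ns; ++a) Ksys(a, a) += 1e-10;
      ok = solve(sol, Ksys, rhs);
      if (!ok) break;  // keep current feasible alpha
    }
    vec beta = sol.head(ns);
    double lambda = sol(ns);

    if (beta.min() >= -tol) {
      // feasible on support; check optimality over the excluded vertices
      alpha.zeros();
      for (uword a = 0; a < ns; ++a) alpha(S[a]) = std::max(beta(a), 0.0);
      alpha /= accu(alpha);
      vec d = 2.0 * (Q * alpha - q);
      double best_v = -1e-10;
      sword best_k = -1;
      for (uword k = 0; k < K; ++k) {
        if (inS[k]) continue;
        double v = d(k) + lambda;
        if (v < best_v) { best_v = v; best_k = (sword)k; }
      }
      if (best_k < 0) break;  // KKT satisfied
      inS[(uword)best_k] = true;
      S.push_back((uword)best_k);
    } else {
      // step toward beta until the first coordinate hits zero, drop it
      double t = 1.0;
      for (uword a = 0; a < ns; ++a) {
        if (beta(a) < 0) {
          double cur = alpha(S[a]);
          double step = cur / (cur - beta(a));
          if (step < t) t = step;
        }
      }
      for (uword a = 0; a < ns; ++a)
        alpha(S[a]) = alpha(S[a]) + t * (beta(a) - alpha(S[a]));
      std::vector<uword> S2;
      for (uword a = 0; a < ns; ++a) {
        if (alpha(S[a]) > tol) S2.push_back(S[a]);
        else { inS[S[a]] = false; alpha(S[a]) = 0.0; }
      }
      if (S2.empty()) { uword jm = 0; double bm = 1e300;
        for (uword a = 0; a < ns; ++a) if (diagc(S[a]) < bm) { bm = diagc(S[a]); jm = S[a]; }
        S2.push_back(jm); inS[jm] = true; alpha(jm) = 1.0; }
      S = S2;
      double ssum = accu(alpha);
      if (ssum > 0) alpha /= ssum;
    }
  }
  alpha_out = alpha;
  return as_scalar(alpha.t() * Q * alpha) - 2.0 * dot(q, alpha);
}

}  // namespace

// Project each row of P onto the convex hull of the rows of V.
// Returns margins (Euclidean distances), barycentric weights and
// reconstructions.
// [[Rcpp::export(name = "cpp_hull_project")]]
Rcpp::List cpp_hull_project(const arma::mat& V, const arma::mat& P) {
  const uword K = V.n_rows, n = P.n_rows;
  mat Q = V * V.t();
  mat alphas(n, K, fill::zeros);
  vec margins(n, fill::zeros);
  mat recon(n, P.n_cols, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    vec p = P.row(i).t();
    vec q = V * p;
    vec a;
    simplex_qp(Q, q, a);
    rowvec rec = (V.t() * a).t();
    // explicit residual: free of the catastrophic cancellation that the
    // Gram-form objective suffers for interior points
    margins(i) = norm(P.row(i) - rec, 2);
    alphas.row(i) = a.t();
    recon.row(i) = rec;
  }
  return Rcpp::List::create(Rcpp::Named("margin") = margins,
                            Rcpp::Named("alpha") = alphas,
                            Rcpp::Named("recon") = recon);
}

// Exhaustive search over all C(M,K) vertex subsets of the M cluster centers
// (rows of C). For each subset the exterior margins (distances of the
// remaining centers to the subset's convex hull) are summed; the subset with
// the minimal sum wins. Lexicographic enumeration + strict improvement by
// more than `tie_tol` implements the smallest-index-set tie break. Subsets
// whose Gram matrix is rank deficient (Cholesky pivot below rank_tol) are
// skipped.
// [[Rcpp::export(name = "cpp_find_vertices")]]
Rcpp::List cpp_find_vertices(const arma::mat& C, const int K,
                             const double rank_tol = 1e-8,
                             const double tie_tol = 1e-12) {
  const uword M = C.n_rows;
  const uword Ku = (uword)K;
  mat G = C * C.t();

  std::vector<uword> idx(Ku);
  for (uword a = 0; a < Ku; ++a) idx[a] = a;

  double best = datum::inf;
  std::vector<uword> best_idx;
  unsigned long long n_eval = 0, n_skipped = 0;

  mat Q(Ku, Ku);
  vec q(Ku), a_tmp;

  bool done = (Ku > M);
  while (!done) {
    ++n_eval;
    for (uword a = 0; a < Ku; ++a)
      for (uword b = 0; b < Ku; ++b) Q(a, b) = G(idx[a], idx[b]);

    // rank screen via Cholesky of the subset Gram
    bool okrank = true;
    {
      mat R;
      if (!chol(R, Q)) okrank = false;
      else if (R.diag().min() < rank_tol) okrank = false;
    }
    if (!okrank) {
      ++n_skipped;
    } else {
      double s = 0.0;
      bool aborted = false;
      uword pos = 0;
      for (uword m = 0; m < M; ++m) {
        if (pos < Ku && idx[pos] == m) { ++pos; continue; }
        for (uword aa = 0; aa < Ku; ++aa) q(aa) = G(idx[aa], m);
        double obj = simplex_qp(Q, q, a_tmp);
        double m2 = G(m, m) + obj;
        if (m2 < 1e-12) {
          // near-interior point: the Gram form cancels catastrophically,
          // recompute from the explicit residual
          rowvec rec(C.n_cols, fill::zeros);
          for (uword aa = 0; aa < Ku; ++aa)
            rec += a_tmp(aa) * C.row(idx[aa]);
          s += norm(C.row(m) - rec, 2);
        } else {
          s += std::sqrt(m2);
        }
        if (s >= best - tie_tol) { aborted = true; break; }
      }
      if (!aborted && s < best - tie_tol) {
        best = s;
        best_idx.assign(idx.begin(), idx.end());
      }
    }

    // next lexicographic combination
    sword a = (sword)Ku - 1;
    while (a >= 0 && idx[a] == M - Ku + (uword)a) --a;
    if (a < 0) done = true;
    else {
      ++idx[a];
      for (uword b = (uword)a + 1; b < Ku; ++b) idx[b] = idx[b - 1] + 1;
    }
    if ((n_eval & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::IntegerVector out_idx(best_idx.size());
  for (size_t a = 0; a < best_idx.size(); ++a) out_idx[a] = (int)best_idx[a] + 1;
  return Rcpp::List::create(Rcpp::Named("vertex_idx") = out_idx,
                            Rcpp::Named("fit_error") = best,
                            Rcpp::Named("n_evaluated") = (double)n_eval,
                            Rcpp::Named("n_rank_skipped") = (double)n_skipped);
}

// Lawson-Hanson style NNLS solved per column of B: min ||A s - b||, s >= 0.
// [[Rcpp::export(name = "cpp_nnls")]]
arma::mat cpp_nnls(const arma::mat& A, const arma::mat& B,
                   const double tol = 1e-10) {
  const uword K = A.n_cols, n = B.n_cols;
  mat AtA = A.t() * A;
  mat AtB = A.t() * B;
  mat S(K, n, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    vec s(K, fill::zeros);
    std::vector<bool> passive(K, false);
    vec w = AtB.col(j);  // gradient at s = 0
    double wtol = tol * std::max(1.0, std::abs(w.max()));
    uword iters = 0, max_outer = 5 * K + 20;
    while (iters++ < max_outer) {
      sword kbest = -1; double wbest = wtol;
      for (uword k = 0; k < K; ++k)
        if (!passive[k] && w(k) > wbest) { wbest = w(k); kbest = (sword)k; }
      if (kbest < 0) break;
      passive[(uword)kbest] = true;
      // inner loop: solve on passive set, clip infeasible entries
      for (uword inner = 0; inner < 4 * K + 10; ++inner) {
        std::vector<uword> P;
        for (uword k = 0; k < K; ++k) if (passive[k]) P.push_back(k);
        uvec Pv(P.size());
        for (size_t a = 0; a < P.size(); ++a) Pv(a) = P[a];
        vec z;
        mat sub = AtA.submat(Pv, Pv);
        vec rhs_p = vec(AtB.col(j)).elem(Pv);
        if (!solve(z, sub, rhs_p, solve_opts::no_approx)) {
          sub.diag() += 1e-12;
          solve(z, sub, rhs_p);
        }
        if (z.min() > 0) {
          s.zeros();
          for (size_t a = 0; a < P.size(); ++a) s(P[a]) = z(a);
          break;
        }
        double t = 1.0;
        for (size_t a = 0; a < P.size(); ++a)
          if (z(a) <= 0) {
            double cur = s(P[a]);
            double step = cur / (cur - z(a));
            if (step < t) t = step;
          }
        for (size_t a = 0; a < P.size(); ++a) {
          s(P[a]) = s(P[a]) + t * (z(a) - s(P[a]));
          if (s(P[a]) <= tol) { s(P[a]) = 0.0; passive[P[a]] = false; }
        }
      }
      w = AtB.col(j) - AtA * s;
    }
    S.col(j) = s;
  }
  return S;
}

// Affinity propagation on rows of X with negative squared Euclidean
// similarity. Deterministic: a tiny index-keyed perturbation (no RNG)
// breaks exact message-passing symmetries such as duplicated points.
// Message matrices may be warm-started (msg_init from a previous call) so
// the preference-tuning bisection converges in few iterations per step.
// Returns 1-based exemplar row indices (ascending), per-row cluster
// assignment into that exemplar list, and the final messages.
// [[Rcpp::export(name = "cpp_apc")]]
Rcpp::List cpp_apc(const arma::mat& X, const arma::vec& preference,
                   const double damping, const int max_iter,
                   const int stable_iter,
                   Rcpp::Nullable<Rcpp::List> msg_init = R_NilValue) {
#ifdef __SSE2__
  // messages decay toward denormals on near-duplicate data, stalling the
  // FPU; flush-to-zero keeps iteration cost data-independent
  unsigned int csr_state = _mm_getcsr();
  _mm_setcsr(csr_state | 0x8040);  // FTZ | DAZ
#endif
  const uword N = X.n_rows;
  vec pref = (preference.n_elem == N) ? preference
             : vec(N, fill::value(preference(0)));
  mat S(N, N);
  {
    vec nrm = sum(square(X), 1);
    S = 2.0 * X * X.t();
    S.each_col() -= nrm;
    S.each_row() -= nrm.t();
    S.diag() = pref;
  }
  // deterministic symmetry-breaking jitter
  {
    double scale = 1e-6 * (mean(abs(pref)) + 1.0);
    unsigned long long state = 88172645463325252ULL;
    double* sp = S.memptr();
    for (uword idx = 0; idx < N * N; ++idx) {
      state ^= state << 13; state ^= state >> 7; state ^= state << 17;
      if (idx / N != idx % N)
        sp[idx] += scale * (double)(state % 1000003ULL) / 1000003.0;
    }
  }

  mat R(N, N, fill::zeros), A(N, N, fill::zeros);
  if (msg_init.isNotNull()) {
    Rcpp::List mi(msg_init);
    mat R0 = Rcpp::as<mat>(mi["R"]);
    if (R0.n_rows == N) {
      R = R0;
      A = Rcpp::as<mat>(mi["A"]);
    }
  }
  const double lam = damping;
  std::vector<bool> ex_prev(N, false);
  int stable = 0, it = 0;
  bool converged = false;
  vec m1(N), m2(N);
  uvec k1(N);
  // messages decay with time constant 1/log(1/damping); do not trust an
  // apparently stable exemplar set before the transient has died down
  const int burn_in = (int)std::ceil(-4.6 / std::log(lam));

  for (it = 1; it <= max_iter; ++it) {
    // responsibilities: per-row top-2 of A+S found by column-contiguous scan
    m1.fill(-datum::inf);
    m2.fill(-datum::inf);
    for (uword k = 0; k < N; ++k) {
      const double* ac = A.colptr(k);
      const double* sc = S.colptr(k);
      for (uword i = 0; i < N; ++i) {
        double v = ac[i] + sc[i];
        if (v > m1(i)) { m2(i) = m1(i); m1(i) = v; k1(i) = k; }
        else if (v > m2(i)) m2(i) = v;
      }
    }
    for (uword k = 0; k < N; ++k) {
      double* rc = R.colptr(k);
      const double* sc = S.colptr(k);
      for (uword i = 0; i < N; ++i) {
        double sub = (k1(i) == k) ? m2(i) : m1(i);
        rc[i] = lam * rc[i] + (1.0 - lam) * (sc[i] - sub);
      }
    }
    // availabilities, column at a time
    for (uword k = 0; k < N; ++k) {
      double* rc = R.colptr(k);
      double* ac = A.colptr(k);
      double colsum = rc[k];
      for (uword i = 0; i < N; ++i)
        if (i != k) colsum += std::max(rc[i], 0.0);
      for (uword i = 0; i < N; ++i) {
        double anew;
        if (i == k) anew = colsum - rc[k];
        else {
          double rp = std::max(rc[i], 0.0);
          anew = colsum - rp;
          if (anew > 0.0) anew = 0.0;
        }
        ac[i] = lam * ac[i] + (1.0 - lam) * anew;
      }
    }
    // exemplar stability check
    bool any_ex = false, changed = false;
    for (uword k = 0; k < N; ++k) {
      bool e = (A(k, k) + R(k, k)) > 0;
      if (e) any_ex = true;
      if (e != ex_prev[k]) { changed = true; ex_prev[k] = e; }
    }
    if (any_ex && !changed && it > burn_in) {
      if (++stable >= stable_iter) { converged = true; break; }
    } else stable = 0;
    if ((it & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<uword> ex;
  for (uword k = 0; k < N; ++k) if (ex_prev[k]) ex.push_back(k);
  if (ex.empty()) {
    vec crit = A.diag() + R.diag();
    ex.push_back(crit.index_max());
    converged = false;
  }

  // nearest-exemplar assignment on true distances; ties -> lower cluster idx
  const uword M = ex.size();
  Rcpp::IntegerVector assign(N);
  for (uword i = 0; i < N; ++i) {
    double bd = datum::inf; uword bc = 0;
    for (uword c = 0; c < M; ++c) {
      double d = accu(square(X.row(i) - X.row(ex[c])));
      if (d < bd - 1e-15) { bd = d; bc = c; }
    }
    assign[i] = (int)bc + 1;
  }
  for (uword c = 0; c < M; ++c) assign[ex[c]] = (int)c + 1;

  Rcpp::IntegerVector exemplars(M);
  for (uword c = 0; c < M; ++c) exemplars[c] = (int)ex[c] + 1;
#ifdef __SSE2__
  _mm_setcsr(csr_state);
#endif
  return Rcpp::List::create(Rcpp::Named("exemplars") = exemplars,
                            Rcpp::Named("assignment") = assign,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("messages") =
                              Rcpp::List::create(Rcpp::Named("R") = R,
                                                 Rcpp::Named("A") = A));
}
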