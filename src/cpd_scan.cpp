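// Core CPD-DM scan loop. Per evaluation time: Hankel window pair,
// self-tuning Gaussian affinity over the past window's columns, spectrum of
// the symmetric conjugate of the Markov operator, affine k-NN out-of-sample
// map of the current window, and the change score for every (r_hat, alpha)
// combination. Mirrors the R reference scanner (scan_cpd_dm_r) exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

// Columns of the multichannel Hankel window starting at 1-based index
// `first` (per channel), r columns of length h per channel.
mat hankel_window(const mat& X, int first, int h, int r) {
  const int m = X.n_cols;
  mat P(h, r * m);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < r; ++c)
      P.col(j * r + c) = X.col(j).subvec(first - 1 + c, first - 1 + c + h - 1);
  return P;
}

// lambda^alpha with negative eigenvalues clipped to 0 for fractional alpha.
vec power_lam(const vec& lam, double alpha) {
  const bool integer_alpha = std::floor(alpha) == alpha;
  vec out(lam.n_elem);
  for (uword i = 0; i < lam.n_elem; ++i) {
    if (!integer_alpha && lam[i] < 0)
      out[i] = 0.0;
    else
      out[i] = std::pow(lam[i], alpha);
  }
  return out;
}

}  // namespace

// Running means over each row's k smallest entries: out(k-1, i) is the mean
// distance from row point i to its k nearest reference points, k = 1..kmax.
// [[Rcpp::export(name = ".cpp_knn_running_means")]]
arma::mat cpp_knn_running_means(const arma::mat& D, const int kmax) {
  const int n = D.n_rows;
  mat out(kmax, n);
  std::vector<double> row(D.n_cols);
  for (int i = 0; i < n; ++i) {
    for (uword j = 0; j < D.n_cols; ++j) row[j] = D(i, j);
    std::partial_sort(row.begin(), row.begin() + kmax, row.end());
    double acc = 0.0;
    for (int k = 0; k < kmax; ++k) {
      acc += row[k];
      out(k, i) = acc / (k + 1);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_scan_cpd_dm")]]
arma::mat cpp_scan_cpd_dm(const arma::mat& X, const arma::ivec& t_eval,
                          const int h, const int r1, const int L,
                          const arma::ivec& rh_combo,
                          const arma::vec& alpha_combo, const int K,
                          const int k_map, const bool two_factor) {
  const int m = X.n_cols;
  const int r = r1 * m;
  const int rmax = rh_combo.max();
  const int ncombo = rh_combo.n_elem;
  mat scores(t_eval.n_elem, ncombo);
  scores.fill(datum::nan);

  mat KKT(k_map + 1, k_map + 1, fill::zeros);
  KKT.row(k_map).head(k_map).fill(1.0);
  KKT.col(k_map).head(k_map).fill(1.0);

  for (uword ti = 0; ti < t_eval.n_elem; ++ti) {
    const int t = t_eval[ti];
    const int p_first = t - r1 - h + 1;
    const int q_first = p_first + L;
    try {
      mat P = hankel_window(X, p_first, h, r1);
      mat Q = hankel_window(X, q_first, h, r1);

      mat G = P.t() * P;
      vec np = G.diag();
      mat d2P = -2.0 * G;
      d2P.each_col() += np;
      d2P.each_row() += np.t();
      d2P.transform([](double v) { return v < 0 ? 0.0 : v; });

      // local scales: distance to the K-th nearest neighbour, self excluded
      vec sigma(r);
      std::vector<double> row(r - 1);
      for (int i = 0; i < r; ++i) {
        int c = 0;
        for (int j = 0; j < r; ++j)
          if (j != i) row[c++] = d2P(i, j);
        std::nth_element(row.begin(), row.begin() + (K - 1), row.end());
        sigma[i] = std::max(std::sqrt(row[K - 1]), 1e-12);
      }

      mat W(r, r);
      const double fac = two_factor ? 2.0 : 1.0;
      for (int i = 0; i < r; ++i) {
        W(i, i) = 1.0;
        for (int j = i + 1; j < r; ++j) {
          const double w = std::exp(-d2P(i, j) / (fac * sigma[i] * sigma[j]));
          W(i, j) = w;
          W(j, i) = w;
        }
      }

      vec b = sum(W, 1);
      vec isq = 1.0 / sqrt(b);
      mat A = W % (isq * isq.t());
      vec lam_all;
      mat V;
      if (!eig_sym(lam_all, V, A)) throw std::runtime_error("eig_sym failed");

      // order by |lambda| descending (stable), drop the trivial pair
      uvec ord = stable_sort_index(abs(lam_all), "descend");
      vec lam(rmax);
      mat phi(r, rmax);
      const double sb = std::sqrt(accu(b));
      for (int j = 0; j < rmax; ++j) {
        const uword jj = ord[j + 1];
        lam[j] = lam_all[jj];
        phi.col(j) = V.col(jj) % isq * sb;
      }

      // affine k-NN out-of-sample extension of Q's columns
      mat CQP = Q.t() * P;
      vec nq = sum(square(Q), 0).t();
      mat Qphi(r, rmax);
      std::vector<int> idx(r);
      for (int i = 0; i < r; ++i) {
        vec d2 = np - 2.0 * CQP.row(i).t() + nq[i];
        d2.transform([](double v) { return v < 0 ? 0.0 : v; });
        uword jmin = d2.index_min();
        if (d2[jmin] < 1e-24) {
          Qphi.row(i) = phi.row(jmin);
          continue;
        }
        std::iota(idx.begin(), idx.end(), 0);
        std::stable_sort(idx.begin(), idx.end(),
                         [&](int a, int c) { return d2[a] < d2[c]; });
        uvec nb(k_map);
        for (int j = 0; j < k_map; ++j) nb[j] = idx[j];
        KKT.submat(0, 0, k_map - 1, k_map - 1) = 2.0 * G.submat(nb, nb);
        vec rhs(k_map + 1);
        vec cqp_i = CQP.row(i).t();
        rhs.head(k_map) = 2.0 * cqp_i.elem(nb);
        rhs[k_map] = 1.0;
        vec w;
        bool ok = solve(w, KKT, rhs, solve_opts::no_approx);
        if (!ok || !w.head(k_map).is_finite())
          Qphi.row(i) = mean(phi.rows(nb), 0);
        else
          Qphi.row(i) = w.head(k_map).t() * phi.rows(nb);
      }

      vec base2 = sum(square(phi - Qphi), 0).t();
      for (int ci = 0; ci < ncombo; ++ci) {
        vec la = power_lam(lam, alpha_combo[ci]);
        double s = 0.0;
        for (int j = 0; j < rh_combo[ci]; ++j)
          s += base2[j] * la[j] * la[j];
        scores(ti, ci) = std::sqrt(s);
      }
    } catch (...) {
      // leave this row NaN: per-time failures degrade, never abort
    }
  }
  return scores;
}
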