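// Fast inner loop of the pattern-decoding pipeline. One call performs one
// iteration of: per-pattern bootstrap sums -> PCA on the bootstrapped
// training set -> least-squares projection of both sets -> kNN
// classification of the bootstrapped test responses. All randomness
// (split assignment and bootstrap row indices) is drawn in R and passed in,
// so results are governed by R's RNG alone and the R reference
// implementation can be run on identical draws.

#include <RcppArmadillo.h>
#include <algorithm>
#include <numeric>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// sum rows of `resp` given a (n_boot x group_size) matrix of 1-based row
// indices; one output row per bootstrap replicate
static arma::mat boot_sums(const arma::mat& resp, const IntegerMatrix& idx) {
  const int n_boot = idx.nrow(), m = idx.ncol(), d = resp.n_cols;
  arma::mat out(n_boot, d, arma::fill::zeros);
  for (int b = 0; b < n_boot; ++b) {
    for (int j = 0; j < m; ++j) {
      out.row(b) += resp.row(idx(b, j) - 1);
    }
  }
  return out;
}

// predicted class (0-based) for one test point given its k nearest
// neighbours: relative majority, ties broken by smaller summed distance,
// then by the class of the single nearest tied neighbour
static int majority_vote(const arma::uvec& nn, const arma::vec& nn_dist,
                         const arma::ivec& train_lab, int n_class) {
  arma::ivec counts(n_class, arma::fill::zeros);
  arma::vec sumdist(n_class, arma::fill::zeros);
  for (arma::uword i = 0; i < nn.n_elem; ++i) {
    int c = train_lab(nn(i));
    counts(c) += 1;
    sumdist(c) += std::sqrt(std::max(nn_dist(i), 0.0));
  }
  int best = counts.index_max();
  int maxc = counts(best);
  std::vector<int> tied;
  for (int c = 0; c < n_class; ++c)
    if (counts(c) == maxc) tied.push_back(c);
  if (tied.size() == 1) return tied[0];
  double bestd = R_PosInf;
  std::vector<int> tied2;
  for (int c : tied) {
    if (sumdist(c) < bestd - 1e-12) {
      bestd = sumdist(c);
      tied2.clear();
      tied2.push_back(c);
    } else if (sumdist(c) <= bestd + 1e-12) {
      tied2.push_back(c);
    }
  }
  if (tied2.size() == 1) return tied2[0];
  // nearest single neighbour among the still-tied classes
  for (arma::uword i = 0; i < nn.n_elem; ++i) {
    int c = train_lab(nn(i));
    for (int t : tied2) if (t == c) return c;
  }
  return tied2[0];
}

// [[Rcpp::export]]
List decode_iteration_cpp(const arma::mat& resp,
                          List boot_train_idx, List boot_test_idx,
                          double variance_explained, int k, int n_class) {
  // bootstrapped sets; labels are implied by block order (pattern-major)
  std::vector<arma::mat> tr_blocks, te_blocks;
  int n_train = 0, n_test = 0;
  for (int p = 0; p < n_class; ++p) {
    tr_blocks.push_back(boot_sums(resp, boot_train_idx[p]));
    te_blocks.push_back(boot_sums(resp, boot_test_idx[p]));
    n_train += tr_blocks[p].n_rows;
    n_test += te_blocks[p].n_rows;
  }
  const int d = resp.n_cols;
  arma::mat X(n_train, d), Y(n_test, d);
  arma::ivec lab_train(n_train), lab_test(n_test);
  int it = 0, ie = 0;
  for (int p = 0; p < n_class; ++p) {
    X.rows(it, it + tr_blocks[p].n_rows - 1) = tr_blocks[p];
    lab_train.subvec(it, it + tr_blocks[p].n_rows - 1).fill(p);
    it += tr_blocks[p].n_rows;
    Y.rows(ie, ie + te_blocks[p].n_rows - 1) = te_blocks[p];
    lab_test.subvec(ie, ie + te_blocks[p].n_rows - 1).fill(p);
    ie += te_blocks[p].n_rows;
  }

  // PCA on the bootstrapped training set (centering on its mean)
  arma::rowvec ctr = arma::mean(X, 0);
  X.each_row() -= ctr;
  Y.each_row() -= ctr;
  arma::mat G = X.t() * X;
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, G);  // ascending
  const double total = arma::accu(arma::clamp(eigval, 0.0, arma::datum::inf));
  int n_comp = 1;
  if (total > 0) {
    double cum = 0.0;
    n_comp = 0;
    for (int i = d - 1; i >= 0; --i) {
      cum += std::max(eigval(i), 0.0);
      ++n_comp;
      if (cum / total >= variance_explained) break;
    }
  }
  arma::mat V(d, n_comp);
  for (int j = 0; j < n_comp; ++j) V.col(j) = eigvec.col(d - 1 - j);

  arma::mat S = X * V;   // train scores
  arma::mat T = Y * V;   // test scores

  // squared distances test x train via the Gram expansion
  arma::vec s2 = arma::sum(arma::square(S), 1);
  arma::vec t2 = arma::sum(arma::square(T), 1);
  arma::mat D = -2.0 * (T * S.t());
  D.each_row() += s2.t();
  D.each_col() += t2;

  // transpose so one test point's distances are contiguous
  arma::mat Dt = D.t();              // n_train x n_test
  arma::imat confusion(n_class, n_class, arma::fill::zeros);
  std::vector<int> order(n_train);
  for (int i = 0; i < n_test; ++i) {
    const double* row = Dt.colptr(i);
    // partial selection of the k smallest distances, ties by lower index
    std::iota(order.begin(), order.end(), 0);
    auto cmp = [&](int a, int b) {
      return row[a] < row[b] || (row[a] == row[b] && a < b);
    };
    std::nth_element(order.begin(), order.begin() + k, order.end(), cmp);
    std::sort(order.begin(), order.begin() + k, cmp);
    arma::uvec nn(k);
    arma::vec nd(k);
    for (int j = 0; j < k; ++j) {
      nn(j) = order[j];
      nd(j) = row[order[j]];
    }
    int pred = majority_vote(nn, nd, lab_train, n_class);
    confusion(lab_test(i), pred) += 1;
  }

  return List::create(_["confusion"] = wrap(confusion),
                      _["n_components"] = n_comp);
}
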