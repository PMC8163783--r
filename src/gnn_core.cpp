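// Dense forward/backward core of the GN-block simulator. The network is
// small (width 32) but is applied to tens of thousands of node rows per
// batch, so the elementwise work (bias broadcast, ReLU, masks) runs over
// raw pointers here; matrix products go through BLAS. Activations are
// cached on the C++ side between the forward and backward calls to avoid
// copying them through R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::vector<std::vector<arma::mat> > ActCache;

static arma::mat view(SEXP s) {
  NumericMatrix m(s);
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

static inline void add_bias_relu(arma::mat& Z, const arma::rowvec& b,
                                 bool relu) {
  const arma::uword n = Z.n_rows, k = Z.n_cols;
  double* p = Z.memptr();
  const double* bp = b.memptr();
  for (arma::uword j = 0; j < k; ++j) {
    const double bj = bp[j];
    double* col = p + j * n;
    if (relu) {
      for (arma::uword i = 0; i < n; ++i) {
        double v = col[i] + bj;
        col[i] = v > 0 ? v : 0.0;
      }
    } else {
      for (arma::uword i = 0; i < n; ++i) col[i] += bj;
    }
  }
}

// forward through one MLP; acts receives [input, layer1, ..., output] and
// the returned reference points at the stored output (no copies)
static const arma::mat& mlp_fwd_cached(const List& layers, arma::mat&& X,
                                       std::vector<arma::mat>& acts) {
  int nl = layers.size();
  acts.reserve(nl + 1);
  acts.push_back(std::move(X));
  for (int l = 0; l < nl; ++l) {
    List lay = layers[l];
    arma::mat W = view(lay["W"]);
    arma::rowvec b = as<arma::rowvec>(lay["b"]);
    arma::mat Z = acts.back() * W;
    add_bias_relu(Z, b, l < nl - 1);
    acts.push_back(std::move(Z));
  }
  return acts.back();
}

static arma::mat mlp_fwd_plain(const List& layers, arma::mat&& X) {
  int nl = layers.size();
  arma::mat h = std::move(X);
  for (int l = 0; l < nl; ++l) {
    List lay = layers[l];
    arma::mat W = view(lay["W"]);
    arma::rowvec b = as<arma::rowvec>(lay["b"]);
    arma::mat Z = h * W;
    add_bias_relu(Z, b, l < nl - 1);
    h = std::move(Z);
  }
  return h;
}

// backward through one MLP; returns the gradient at the input
static arma::mat mlp_bwd(const List& layers,
                         const std::vector<arma::mat>& acts,
                         arma::mat d, List& grads) {
  int nl = layers.size();
  for (int l = nl - 1; l >= 0; --l) {
    if (l < nl - 1) {
      const double* a = acts[l + 1].memptr();
      double* dp = d.memptr();
      const arma::uword ne = d.n_elem;
      for (arma::uword i = 0; i < ne; ++i) {
        if (a[i] <= 0) dp[i] = 0.0;
      }
    }
    arma::mat gW = acts[l].t() * d;
    arma::rowvec gb = arma::sum(d, 0);
    grads[l] = List::create(_["W"] = wrap(gW),
                            _["b"] = NumericVector(gb.begin(), gb.end()));
    List lay = layers[l];
    arma::mat W = view(lay["W"]);
    d = d * W.t();
  }
  return d;
}

// [[Rcpp::export(name = ".sim_fwd_cpp")]]
List sim_fwd_cpp(List blocks, List dec, const arma::mat& X,
                 const arma::mat& E, bool keep_cache) {
  int L = blocks.size();
  XPtr<ActCache> cache(new ActCache(), true);
  if (keep_cache) cache->resize(L + 1);
  const arma::mat* h = &X;
  arma::mat hplain;
  for (int l = 0; l < L; ++l) {
    arma::mat in = arma::join_rows(*h, E);
    if (keep_cache) {
      h = &mlp_fwd_cached(blocks[l], std::move(in), (*cache)[l]);
    } else {
      hplain = mlp_fwd_plain(blocks[l], std::move(in));
      h = &hplain;
    }
  }
  arma::mat pred;
  if (keep_cache) {
    arma::mat in = *h;  // decoder input (copy; also kept as block output)
    pred = mlp_fwd_cached(dec, std::move(in), (*cache)[L]);
  } else {
    arma::mat in = std::move(hplain);
    pred = mlp_fwd_plain(dec, std::move(in));
  }
  return List::create(_["pred"] = wrap(pred), _["cache"] = cache);
}

// [[Rcpp::export(name = ".sim_bwd_cpp")]]
List sim_bwd_cpp(List blocks, List dec, SEXP cache_ptr,
                 const arma::mat& dPred, int n_edge) {
  XPtr<ActCache> cache(cache_ptr);
  int L = blocks.size();
  List gdec(as<List>(dec).size());
  arma::mat d = mlp_bwd(dec, (*cache)[L], dPred, gdec);
  List gblocks(L);
  for (int l = L - 1; l >= 0; --l) {
    List gb(as<List>(blocks[l]).size());
    d = mlp_bwd(blocks[l], (*cache)[l], d, gb);
    gblocks[l] = gb;
    d = d.head_cols(d.n_cols - n_edge);
  }
  return List::create(_["blocks"] = gblocks, _["dec"] = gdec);
}

// [[Rcpp::export(name = ".mlp_fwd_cpp")]]
List mlp_fwd_cpp(List layers, const arma::mat& X, bool keep_cache) {
  XPtr<ActCache> cache(new ActCache(), true);
  arma::mat in = X;
  if (keep_cache) {
    cache->resize(1);
    arma::mat out = mlp_fwd_cached(layers, std::move(in), (*cache)[0]);
    return List::create(_["out"] = wrap(out), _["cache"] = cache);
  }
  arma::mat out = mlp_fwd_plain(layers, std::move(in));
  return List::create(_["out"] = wrap(out), _["cache"] = cache);
}

// [[Rcpp::export(name = ".mlp_bwd_cpp")]]
List mlp_bwd_cpp(List layers, SEXP cache_ptr, const arma::mat& dOut) {
  XPtr<ActCache> cache(cache_ptr);
  List grads(as<List>(layers).size());
  arma::mat dX = mlp_bwd(layers, (*cache)[0], dOut, grads);
  return List::create(_["grads"] = grads, _["dX"] = wrap(dX));
}
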