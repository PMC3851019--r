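#include <Rcpp.h>
using namespace Rcpp;

// Collapsed joint log p(w, z | alpha, beta) from the current count state.
static double joint_log_lik(const IntegerMatrix& ndk,
                            const IntegerMatrix& nkw,
                            const IntegerVector& nd,
                            const IntegerVector& nk,
                            double alpha, double beta) {
  const int D = ndk.nrow(), K = ndk.ncol(), V = nkw.ncol();
  double ll = 0.0;
  const double lgA = lgamma(alpha), lgB = lgamma(beta);
  for (int d = 0; d < D; ++d) {
    ll += lgamma(K * alpha) - lgamma(nd[d] + K * alpha);
    for (int k = 0; k < K; ++k)
      ll += lgamma(ndk(d, k) + alpha) - lgA;
  }
  for (int k = 0; k < K; ++k) {
    ll += lgamma(V * beta) - lgamma(nk[k] + V * beta);
    for (int w = 0; w < V; ++w)
      ll += lgamma(nkw(k, w) + beta) - lgB;
  }
  return ll;
}

// Collapsed Gibbs sampler for LDA.
//
// doc, term: 0-based per-token indices (fixed order: documents in corpus
// order, tokens within a document in term-catalog order). Uses R's RNG so
// set.seed() at the R level fixes the whole trajectory.
//
// Returns final assignments (1-based), posterior-mean CPTs averaged over
// retained samples with per-sample Dirichlet smoothing, the per-sweep joint
// log likelihood trace, and per-token marginal topic frequencies across
// retained samples (for comparison against exhaustive enumeration).
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector term,
                   int D, int V, int K,
                   double alpha, double beta,
                   int n_iter, int burn_in, int sample_lag) {
  const int N = doc.size();
  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nd(D), nk(K), z(N);
  std::vector<double> probs(K);
  int* pndk = ndk.begin();          // D x K, column-major: [d + k*D]
  int* pnkw = nkw.begin();          // K x V, column-major: [k + w*K]
  int* pnd = nd.begin();
  int* pnk = nk.begin();
  int* pz = z.begin();
  const int* pdoc = doc.begin();
  const int* pterm = term.begin();
  const double Vbeta = V * beta;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    pz[i] = k;
    ++pndk[pdoc[i] + k * D]; ++pnkw[k + pterm[i] * K];
    ++pnd[pdoc[i]]; ++pnk[k];
  }

  NumericMatrix doc_topic(D, K), topic_word(K, V), token_post(N, K);
  NumericVector loglik(n_iter);
  int n_retained = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = pdoc[i], w = pterm[i];
      int k = pz[i];
      const int wK = w * K;
      --pndk[d + k * D]; --pnkw[k + wK]; --pnk[k];
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        // nd[d]-1 is constant in j; dropped from the denominator
        probs[j] = (pndk[d + j * D] + alpha) * (pnkw[j + wK] + beta) /
                   (pnk[j] + Vbeta);
        tot += probs[j];
      }
      double u = unif_rand() * tot, acc = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        acc += probs[j];
        if (u < acc) { k = j; break; }
      }
      pz[i] = k;
      ++pndk[d + k * D]; ++pnkw[k + wK]; ++pnk[k];
    }
    loglik[it] = joint_log_lik(ndk, nkw, nd, nk, alpha, beta);
    if (it >= burn_in && (it - burn_in) % sample_lag == 0) {
      ++n_retained;
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          doc_topic(d, k) += (ndk(d, k) + alpha) / (nd[d] + K * alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          topic_word(k, w) += (nkw(k, w) + beta) / (nk[k] + V * beta);
      for (int i = 0; i < N; ++i)
        token_post(i, z[i]) += 1.0;
    }
  }

  if (n_retained > 0) {
    const double inv = 1.0 / n_retained;
    for (R_xlen_t i = 0; i < doc_topic.size(); ++i) doc_topic[i] *= inv;
    for (R_xlen_t i = 0; i < topic_word.size(); ++i) topic_word[i] *= inv;
    for (R_xlen_t i = 0; i < token_post.size(); ++i) token_post[i] *= inv;
  }
  IntegerVector z1(N);
  for (int i = 0; i < N; ++i) z1[i] = z[i] + 1;
  return List::create(
    _["z"] = z1,
    _["doc_topic"] = doc_topic,
    _["topic_word"] = topic_word,
    _["token_posterior"] = token_post,
    _["log_likelihood_trace"] = loglik,
    _["n_retained"] = n_retained);
}
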