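// Direct-assignment Gibbs sampler for the hierarchical Dirichlet process
// topic model. One corpus-level DP (concentration gamma, symmetric
// Dirichlet(eta) base measure over V terms) supplies atoms to per-document
// DPs (concentration alpha0). State kept as per-token topic assignments
// plus the count statistics; the global stick beta is resampled each sweep
// from Chinese-restaurant table counts. Uses R's RNG throughout so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct State {
  int V, D, K;
  std::vector<std::vector<int>> nkw; // [k][w]
  std::vector<int> nk;               // [k]
  std::vector<std::vector<int>> ndk; // [d][k], always size K
  std::vector<double> beta;          // [k]
  double beta_u;                     // stick mass of unrepresented topics
  std::vector<int> z;                // [token]
};

void add_topic(State &s) {
  s.K += 1;
  s.nkw.emplace_back(s.V, 0);
  s.nk.push_back(0);
  for (int d = 0; d < s.D; ++d) s.ndk[d].push_back(0);
}

// remove empty topic k by swapping with the last topic, relabelling tokens
void drop_topic(State &s, int k) {
  int last = s.K - 1;
  s.beta_u += s.beta[k];
  if (k != last) {
    s.nkw[k].swap(s.nkw[last]);
    s.nk[k] = s.nk[last];
    s.beta[k] = s.beta[last];
    for (int d = 0; d < s.D; ++d) s.ndk[d][k] = s.ndk[d][last];
    for (size_t i = 0; i < s.z.size(); ++i)
      if (s.z[i] == last) s.z[i] = k;
  }
  s.nkw.pop_back();
  s.nk.pop_back();
  s.beta.pop_back();
  for (int d = 0; d < s.D; ++d) s.ndk[d].pop_back();
  s.K -= 1;
}

// sample one token's topic given the rest; returns the (possibly new) topic
int sample_token(State &s, int d, int w, double alpha0, double eta,
                 double gamma0, std::vector<double> &prob) {
  prob.resize(s.K + 1);
  double tot = 0.0;
  double Veta = s.V * eta;
  for (int k = 0; k < s.K; ++k) {
    double p = (s.ndk[d][k] + alpha0 * s.beta[k]) *
               (s.nkw[k][w] + eta) / (s.nk[k] + Veta);
    prob[k] = p;
    tot += p;
  }
  double pnew = alpha0 * s.beta_u / s.V;
  prob[s.K] = pnew;
  tot += pnew;

  double u = unif_rand() * tot;
  int k = 0;
  double acc = prob[0];
  while (u > acc && k < s.K) {
    ++k;
    acc += prob[k];
  }
  if (k == s.K) { // instantiate a new topic, splitting the leftover stick
    add_topic(s);
    double b = R::rbeta(1.0, gamma0);
    s.beta.push_back(b * s.beta_u);
    s.beta_u *= (1.0 - b);
  }
  s.ndk[d][k] += 1;
  s.nkw[k][w] += 1;
  s.nk[k] += 1;
  return k;
}

// number of tables seating n customers at a dish with concentration a
// (Chinese restaurant table / Antoniak draw)
int sample_crt(int n, double a) {
  int m = 0;
  for (int j = 0; j < n; ++j)
    if (unif_rand() < a / (a + j)) ++m;
  return m;
}

} // namespace

// [[Rcpp::export(name = ".hdp_gibbs_cpp")]]
List hdp_gibbs_cpp(IntegerVector doc, IntegerVector word, int n_docs, int V,
                   double gamma0, double alpha0, double eta, int n_iter,
                   bool sample_conc, IntegerVector heldout_word) {
  const int N = doc.size();
  State s;
  s.V = V;
  s.D = n_docs;
  s.K = 0;
  s.beta_u = 1.0;
  s.ndk.assign(n_docs, std::vector<int>());
  s.z.assign(N, -1);

  std::vector<double> prob;
  prob.reserve(64);

  // incremental initialization: each token sampled from its conditional
  // given the tokens added so far
  for (int i = 0; i < N; ++i)
    s.z[i] = sample_token(s, doc[i], word[i], alpha0, eta, gamma0, prob);

  std::vector<int> ndoc(n_docs, 0);
  for (int i = 0; i < N; ++i) ndoc[doc[i]] += 1;

  const int H = heldout_word.size();
  NumericVector heldout_trace(n_iter, NA_REAL);
  IntegerVector K_trace(n_iter);
  NumericVector gamma_trace(n_iter), alpha_trace(n_iter);

  for (int iter = 0; iter < n_iter; ++iter) {
    // (a) token-level topic assignments
    for (int i = 0; i < N; ++i) {
      int d = doc[i], w = word[i], k = s.z[i];
      s.ndk[d][k] -= 1;
      s.nkw[k][w] -= 1;
      s.nk[k] -= 1;
      if (s.nk[k] == 0) drop_topic(s, k);
      s.z[i] = sample_token(s, d, w, alpha0, eta, gamma0, prob);
    }

    // (b) table counts and global stick
    std::vector<int> m(s.K, 0);
    int T = 0;
    for (int d = 0; d < n_docs; ++d)
      for (int k = 0; k < s.K; ++k)
        if (s.ndk[d][k] > 0) {
          int md = sample_crt(s.ndk[d][k], alpha0 * s.beta[k]);
          m[k] += md;
          T += md;
        }
    {
      std::vector<double> g(s.K + 1);
      double gt = 0.0;
      for (int k = 0; k < s.K; ++k) {
        g[k] = R::rgamma(std::max(m[k], 1), 1.0);
        gt += g[k];
      }
      g[s.K] = R::rgamma(gamma0, 1.0);
      gt += g[s.K];
      for (int k = 0; k < s.K; ++k) s.beta[k] = g[k] / gt;
      s.beta_u = g[s.K] / gt;
    }

    // (c) optional concentration resampling under vague Gamma(1,1) priors
    if (sample_conc) {
      // alpha0 (Teh et al. auxiliary-variable scheme)
      double sum_log_w = 0.0;
      int sum_s = 0;
      for (int d = 0; d < n_docs; ++d) {
        if (ndoc[d] == 0) continue;
        double wd = R::rbeta(alpha0 + 1.0, (double)ndoc[d]);
        sum_log_w += std::log(wd);
        if (unif_rand() < ndoc[d] / (ndoc[d] + alpha0)) sum_s += 1;
      }
      alpha0 = R::rgamma(1.0 + T - sum_s, 1.0 / (1.0 - sum_log_w));
      // gamma (Escobar-West, the corpus DP seats T tables at K dishes)
      if (T > 0) {
        double x = R::rbeta(gamma0 + 1.0, (double)T);
        double pi_num = (1.0 + s.K - 1.0);
        double pi_den = pi_num + T * (1.0 - std::log(x));
        double shape = (unif_rand() < pi_num / pi_den) ? (1.0 + s.K)
                                                       : (1.0 + s.K - 1.0);
        gamma0 = R::rgamma(shape, 1.0 / (1.0 - std::log(x)));
      }
    }

    // (d) diagnostics
    K_trace[iter] = s.K;
    gamma_trace[iter] = gamma0;
    alpha_trace[iter] = alpha0;
    if (H > 0) {
      double ll = 0.0;
      double n_tot = (double)N;
      double Veta = V * eta;
      for (int h = 0; h < H; ++h) {
        int w = heldout_word[h];
        double pw = 0.0;
        for (int k = 0; k < s.K; ++k)
          pw += (s.nk[k] / n_tot) * (s.nkw[k][w] + eta) / (s.nk[k] + Veta);
        ll += std::log(pw);
      }
      heldout_trace[iter] = ll;
    }

    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix nkw(s.K, V);
  for (int k = 0; k < s.K; ++k)
    for (int w = 0; w < V; ++w) nkw(k, w) = s.nkw[k][w];
  IntegerMatrix ndk(n_docs, s.K);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < s.K; ++k) ndk(d, k) = s.ndk[d][k];
  IntegerVector nk(s.K);
  for (int k = 0; k < s.K; ++k) nk[k] = s.nk[k];
  NumericVector beta(s.K + 1);
  for (int k = 0; k < s.K; ++k) beta[k] = s.beta[k];
  beta[s.K] = s.beta_u;
  IntegerVector z(N);
  for (int i = 0; i < N; ++i) z[i] = s.z[i] + 1;

  return List::create(
    _["K"] = s.K, _["z"] = z, _["n_kw"] = nkw, _["n_k"] = nk,
    _["n_dk"] = ndk, _["beta"] = beta,
    _["K_trace"] = K_trace, _["heldout_trace"] = heldout_trace,
    _["gamma"] = gamma0, _["alpha0"] = alpha0,
    _["gamma_trace"] = gamma_trace, _["alpha_trace"] = alpha_trace);
}
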