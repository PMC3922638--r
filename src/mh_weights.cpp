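#include <Rcpp.h>
using namespace Rcpp;

// Genotype-marginalized binomial log-likelihood of one SNV in one sample at
// population frequency phi. log_w are log mixture weights over genotype
// states, mu_v the per-state reference-allele probabilities of the variant
// population, lch the log binomial coefficient for (b, d).
static double snv_ll(double b, double d, double mu_r,
                     const NumericVector& mu_v, const NumericVector& log_w,
                     double lch, double phi) {
  const int G = mu_v.size();
  double m = R_NegInf;
  std::vector<double> terms(G);
  for (int g = 0; g < G; ++g) {
    double p_ref = (1.0 - phi) * mu_r + phi * mu_v[g];
    double p_var = 1.0 - p_ref;
    if (p_var < 1e-10) p_var = 1e-10;
    if (p_var > 1.0 - 1e-10) p_var = 1.0 - 1e-10;
    double t = log_w[g] + lch + b * std::log(p_var) + (d - b) * std::log1p(-p_var);
    terms[g] = t;
    if (t > m) m = t;
  }
  double s = 0.0;
  for (int g = 0; g < G; ++g) s += std::exp(terms[g] - m);
  return m + std::log(s);
}

// phi from eta by subtree sums: `order` lists nodes children-before-parents
static void phi_from_eta(const std::vector<double>& eta,
                         const IntegerVector& parent,
                         const IntegerVector& order,
                         std::vector<double>& phi) {
  const int K = eta.size();
  for (int v = 0; v < K; ++v) phi[v] = eta[v];
  for (int k = 0; k < K; ++k) {
    int v = order[k] - 1;
    int p = parent[v];
    if (p > 0) phi[p - 1] += phi[v];
  }
}

// log density of the breadth-first sequential Uniform(0, eta_parent) prior:
// when child i of v draws, the available parent mass is eta_v plus the eta of
// the children not yet drawn; each draw contributes -log(available).
static double eta_prior_ld(const std::vector<double>& eta,
                           const List& children) {
  const int K = eta.size();
  double ld = 0.0;
  for (int v = 0; v < K; ++v) {
    IntegerVector ch = children[v];
    const int m = ch.size();
    if (m == 0) continue;
    double avail = eta[v];
    for (int i = 0; i < m; ++i) avail += eta[ch[i] - 1];
    for (int i = 0; i < m; ++i) {
      if (avail < 1e-300) return R_NegInf;
      ld -= std::log(avail);
      avail -= eta[ch[i] - 1];
    }
  }
  return ld;
}

static double data_ll(const std::vector<double>& phi, int t,
                      const IntegerVector& z,
                      const NumericMatrix& b, const NumericMatrix& d,
                      const NumericVector& mu_r, const List& mu_v,
                      const List& log_w, const NumericMatrix& lch) {
  const int N = z.size();
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    NumericVector mv = mu_v[i];
    NumericVector lw = log_w[i];
    ll += snv_ll(b(i, t), d(i, t), mu_r[i], mv, lw, lch(i, t), phi[z[i] - 1]);
  }
  return ll;
}

static double dirichlet_ld(const std::vector<double>& x,
                           const std::vector<double>& a) {
  double ld = 0.0, asum = 0.0;
  for (size_t j = 0; j < x.size(); ++j) {
    ld += (a[j] - 1.0) * std::log(x[j]) - R::lgammafn(a[j]);
    asum += a[j];
  }
  return ld + R::lgammafn(asum);
}

// Joint Metropolis-Hastings over the per-sample auxiliary-weight simplices.
// Proposal: eta* ~ Dirichlet(sigma * eta + floor), per sample, accepted with
// a single global move on the product of per-sample posteriors
// (likelihood x sequential-uniform prior), with the asymmetric proposal
// densities in the ratio. Uses R's RNG.
// [[Rcpp::export]]
List mh_weights_cpp(NumericMatrix eta0, IntegerVector parent, List children,
                    IntegerVector order, IntegerVector z,
                    NumericMatrix b, NumericMatrix d, NumericMatrix lch,
                    NumericVector mu_r, List mu_v, List log_w,
                    double sigma, double floor_, int n_iters,
                    int thin = 0) {
  RNGScope scope;
  const int K = eta0.nrow();
  const int S = eta0.ncol();
  std::vector<std::vector<double>> eta(S, std::vector<double>(K));
  for (int t = 0; t < S; ++t)
    for (int v = 0; v < K; ++v) eta[t][v] = eta0(v, t);

  std::vector<double> phi(K);
  std::vector<double> target(S);
  for (int t = 0; t < S; ++t) {
    phi_from_eta(eta[t], parent, order, phi);
    target[t] = eta_prior_ld(eta[t], children) +
      data_ll(phi, t, z, b, d, mu_r, mu_v, log_w, lch);
  }

  int n_rec = (thin > 0) ? n_iters / thin : 0;
  NumericMatrix trace(n_rec, (thin > 0) ? K * S : 0);
  int rec = 0;
  int accepts = 0;
  std::vector<std::vector<double>> prop(S, std::vector<double>(K));
  std::vector<double> a_cur(K), a_prop(K), target_prop(S);

  for (int it = 0; it < n_iters; ++it) {
    double log_ratio = 0.0;
    bool ok = true;
    for (int t = 0; t < S && ok; ++t) {
      double asum = 0.0;
      for (int v = 0; v < K; ++v) {
        a_cur[v] = sigma * eta[t][v] + floor_;
        double g = R::rgamma(a_cur[v], 1.0);
        prop[t][v] = g;
        asum += g;
      }
      if (asum <= 0) { ok = false; break; }
      double renorm = 0.0;
      for (int v = 0; v < K; ++v) {
        prop[t][v] /= asum;
        if (prop[t][v] < 1e-12) prop[t][v] = 1e-12;
        renorm += prop[t][v];
      }
      for (int v = 0; v < K; ++v) prop[t][v] /= renorm;
      for (int v = 0; v < K; ++v) a_prop[v] = sigma * prop[t][v] + floor_;

      phi_from_eta(prop[t], parent, order, phi);
      target_prop[t] = eta_prior_ld(prop[t], children) +
        data_ll(phi, t, z, b, d, mu_r, mu_v, log_w, lch);
      // target ratio + reverse/forward proposal densities
      log_ratio += target_prop[t] - target[t];
      log_ratio += dirichlet_ld(eta[t], a_prop) - dirichlet_ld(prop[t], a_cur);
    }
    if (ok && std::log(R::runif(0.0, 1.0)) < log_ratio) {
      for (int t = 0; t < S; ++t) {
        eta[t] = prop[t];
        target[t] = target_prop[t];
      }
      ++accepts;
    }
    if (thin > 0 && (it + 1) % thin == 0 && rec < n_rec) {
      for (int t = 0; t < S; ++t)
        for (int v = 0; v < K; ++v) trace(rec, t * K + v) = eta[t][v];
      ++rec;
    }
  }

  NumericMatrix eta_out(K, S);
  for (int t = 0; t < S; ++t)
    for (int v = 0; v < K; ++v) eta_out(v, t) = eta[t][v];
  List out = List::create(_["eta"] = eta_out,
                          _["accept_rate"] = double(accepts) / n_iters);
  if (thin > 0) out["trace"] = trace;
  return out;
}

// Batch complete-data log-likelihood helper: per-SNV, per-sample
// genotype-marginalized binomial log-likelihood at given phi values.
// [[Rcpp::export]]
NumericMatrix snv_loglik_matrix_cpp(NumericMatrix phi, IntegerVector z,
                                    NumericMatrix b, NumericMatrix d,
                                    NumericMatrix lch, NumericVector mu_r,
                                    List mu_v, List log_w) {
  const int N = z.size();
  const int S = b.ncol();
  NumericMatrix out(N, S);
  for (int i = 0; i < N; ++i) {
    NumericVector mv = mu_v[i];
    NumericVector lw = log_w[i];
    for (int t = 0; t < S; ++t) {
      out(i, t) = snv_ll(b(i, t), d(i, t), mu_r[i], mv, lw, lch(i, t),
                         phi(z[i] - 1, t));
    }
  }
  return out;
}

// Candidate-profile likelihood: for each row of `phi` (a candidate's
// per-sample frequencies), the genotype-marginalized log-likelihood of one
// SNV summed over samples.
// [[Rcpp::export]]
NumericVector snv_ll_profile_cpp(NumericVector b, NumericVector d,
                                 NumericVector lch, double mu_r,
                                 NumericVector mu_v, NumericVector log_w,
                                 NumericMatrix phi) {
  const int R = phi.nrow();
  const int S = b.size();
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    double ll = 0.0;
    for (int t = 0; t < S; ++t) {
      ll += snv_ll(b[t], d[t], mu_r, mu_v, log_w, lch[t], phi(r, t));
    }
    out[r] = ll;
  }
  return out;
}
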