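#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweep kernel for Dirichlet-multinomial source tracking.
//
// Each sink sequence token i carries a latent source label z_i over J known
// sources plus an Unknown source (index J). The full conditional is
//
//   P(z_i = v | z_-i) \propto
//     (n[t,v] + c-[t,v] + alpha_v) / (N_v + C-_v + T * alpha_v) * (C-_v + beta)
//
// where n are fixed training counts (zero for Unknown), c-/C- are the
// current sink assignment counts excluding token i, T the taxon count,
// alpha_v = alpha_known for known sources and alpha_unknown for Unknown.
// When track_training is false the sink counts c do not feed back into the
// known sources' taxon distributions (they always do for Unknown, which has
// no training data).
//
// Initialization: with init_known, token labels start distributed over the
// known sources proportional to each source's smoothed taxon likelihood and
// the Unknown source starts empty, so it only accumulates sequences the
// known sources cannot explain; otherwise labels start uniform over all
// V sources (Unknown included).
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// Returns a (n_draws x J+1) matrix of retained mixing-proportion draws.
// [[Rcpp::export]]
NumericMatrix st_gibbs(IntegerVector tokens, NumericMatrix train,
                       double alpha_known, double alpha_unknown, double beta,
                       int burn_in, int n_draws, int thin,
                       bool track_training, bool init_known = true) {
  const int N = tokens.size();
  const int T = train.nrow();
  const int J = train.ncol();
  const int V = J + 1;

  std::vector<double> N_v(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int t = 0; t < T; ++t) N_v[j] += train(t, j);

  std::vector<double> c_tv((size_t)T * V, 0.0);
  std::vector<double> C_v(V, 0.0);
  std::vector<int> z(N);

  // initial assignment
  std::vector<double> p0(V);
  for (int i = 0; i < N; ++i) {
    int v;
    if (init_known) {
      const int t = tokens[i];
      double tot = 0.0;
      for (int j = 0; j < J; ++j) {
        p0[j] = (train(t, j) + alpha_known) / (N_v[j] + T * alpha_known);
        tot += p0[j];
      }
      double u = unif_rand() * tot;
      v = 0;
      double acc = p0[0];
      while (u > acc && v < J - 1) acc += p0[++v];
    } else {
      v = (int)(unif_rand() * V);
      if (v >= V) v = V - 1;
    }
    z[i] = v;
    c_tv[(size_t)tokens[i] * V + v] += 1.0;
    C_v[v] += 1.0;
  }

  NumericMatrix draws(n_draws, V);
  std::vector<double> prob(V);
  const int n_sweeps = burn_in + n_draws * thin;
  int kept = 0;

  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      const int t = tokens[i];
      const int v_old = z[i];
      c_tv[(size_t)t * V + v_old] -= 1.0;
      C_v[v_old] -= 1.0;

      double tot = 0.0;
      for (int v = 0; v < V; ++v) {
        const bool unknown = (v == J);
        const double alpha_v = unknown ? alpha_unknown : alpha_known;
        const bool use_c = track_training || unknown;
        const double num = (unknown ? 0.0 : train(t, v)) +
                           (use_c ? c_tv[(size_t)t * V + v] : 0.0) + alpha_v;
        const double den = (unknown ? 0.0 : N_v[v]) +
                           (use_c ? C_v[v] : 0.0) + T * alpha_v;
        prob[v] = num / den * (C_v[v] + beta);
        tot += prob[v];
      }
      double u = unif_rand() * tot;
      int v_new = 0;
      double acc = prob[0];
      while (u > acc && v_new < V - 1) acc += prob[++v_new];

      z[i] = v_new;
      c_tv[(size_t)t * V + v_new] += 1.0;
      C_v[v_new] += 1.0;
    }
    if (s >= burn_in && (s - burn_in + 1) % thin == 0 && kept < n_draws) {
      for (int v = 0; v < V; ++v) draws(kept, v) = C_v[v] / N;
      ++kept;
    }
  }
  return draws;
}
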