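#include <Rcpp.h>
using namespace Rcpp;

// Metropolis sampling of protonation microstates for a set of
// ionisable sites coupled by a (symmetric, zero-diagonal) pairwise
// interaction matrix W (kJ/mol per unit-charge product), scaled by a
// coupling parameter lambda. Site charges follow the convention
// q_i = prot_i - is_acid_i (acid: 0/-1, base: +1/0). The ideal
// (non-interacting) energy of a protonated site i at a given pH is
// ln(10) * RT * (pH - pKa_i).
//
// Moves: single-site flips, plus paired flips for site pairs with
// |W_ij| above pair_threshold (helps strongly coupled pairs such as
// buried salt bridges cross between the two ++/-- and +-/-+ basins).
//
// Returns per-site mean protonation with batch-means standard
// errors, and the mean (unscaled) interaction energy <E_int> with
// its standard error, as needed for thermodynamic integration over
// lambda. Uses R's RNG so results are reproducible via set.seed().

// [[Rcpp::export]]
List mc_protonation_kernel(NumericMatrix W, NumericVector pKa,
                           LogicalVector is_acid, double pH, double RT,
                           double lambda, int n_sweeps, int n_equil,
                           double pair_threshold, int n_batches) {
  const int N = pKa.size();
  const double ln10 = 2.302585092994046;

  std::vector<double> cideal(N);
  for (int i = 0; i < N; ++i) cideal[i] = ln10 * RT * (pH - pKa[i]);

  // coupled pairs
  std::vector<std::pair<int,int> > pairs;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (std::fabs(W(i, j)) > pair_threshold)
        pairs.push_back(std::make_pair(i, j));

  // initial state: protonated iff pH < pKa (ideal ground state)
  std::vector<int> prot(N);
  std::vector<double> q(N);
  for (int i = 0; i < N; ++i) {
    prot[i] = pH < pKa[i] ? 1 : 0;
    q[i] = prot[i] - (is_acid[i] ? 1.0 : 0.0);
  }

  double e_int = 0.0;  // unscaled interaction energy of current state
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) e_int += W(i, j) * q[i] * q[j];

  // field on site i from all others (unscaled)
  std::vector<double> field(N);
  auto recompute_field = [&](int i) {
    double f = 0.0;
    for (int j = 0; j < N; ++j) if (j != i) f += W(i, j) * q[j];
    return f;
  };

  auto try_flip = [&](int i) {
    double dprot = 1.0 - 2.0 * prot[i];
    double dE = cideal[i] * dprot + lambda * dprot * recompute_field(i);
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / RT)) {
      e_int += dprot * recompute_field(i);
      prot[i] = 1 - prot[i];
      q[i] += dprot;
    }
  };

  auto try_pair_flip = [&](int i, int j) {
    double di = 1.0 - 2.0 * prot[i], dj = 1.0 - 2.0 * prot[j];
    double fi = recompute_field(i), fj = recompute_field(j);
    // dE_int = di*fi + dj*fj + di*dj*W_ij (cross term counted once)
    double dEint = di * fi + dj * fj + di * dj * W(i, j);
    double dE = cideal[i] * di + cideal[j] * dj + lambda * dEint;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE / RT)) {
      e_int += dEint;
      prot[i] = 1 - prot[i]; q[i] += di;
      prot[j] = 1 - prot[j]; q[j] += dj;
    }
  };

  const int n_rec = n_sweeps - n_equil;
  if (n_batches > n_rec) n_batches = n_rec > 0 ? n_rec : 1;
  NumericMatrix batch_prot(n_batches, N);
  NumericVector batch_eint(n_batches);
  std::vector<int> batch_n(n_batches, 0);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int k = 0; k < N; ++k) {
      int i = (int)(unif_rand() * N);
      if (i >= N) i = N - 1;
      try_flip(i);
    }
    for (size_t p = 0; p < pairs.size(); ++p)
      try_pair_flip(pairs[p].first, pairs[p].second);
    if (sweep >= n_equil) {
      int b = (int)(((long long)(sweep - n_equil)) * n_batches / n_rec);
      if (b >= n_batches) b = n_batches - 1;
      for (int i = 0; i < N; ++i) batch_prot(b, i) += prot[i];
      batch_eint[b] += e_int;
      batch_n[b] += 1;
    }
  }

  NumericVector mean_prot(N), se_prot(N);
  double mean_ei = 0.0, se_ei = 0.0;
  for (int b = 0; b < n_batches; ++b) {
    for (int i = 0; i < N; ++i) batch_prot(b, i) /= batch_n[b];
    batch_eint[b] /= batch_n[b];
  }
  for (int i = 0; i < N; ++i) {
    double m = 0.0;
    for (int b = 0; b < n_batches; ++b) m += batch_prot(b, i);
    m /= n_batches;
    double v = 0.0;
    for (int b = 0; b < n_batches; ++b)
      v += (batch_prot(b, i) - m) * (batch_prot(b, i) - m);
    mean_prot[i] = m;
    se_prot[i] = n_batches > 1 ?
      std::sqrt(v / (n_batches - 1) / n_batches) : NA_REAL;
  }
  for (int b = 0; b < n_batches; ++b) mean_ei += batch_eint[b];
  mean_ei /= n_batches;
  for (int b = 0; b < n_batches; ++b)
    se_ei += (batch_eint[b] - mean_ei) * (batch_eint[b] - mean_ei);
  se_ei = n_batches > 1 ?
    std::sqrt(se_ei / (n_batches - 1) / n_batches) : NA_REAL;

  return List::create(_["mean_prot"] = mean_prot, _["se_prot"] = se_prot,
                      _["mean_eint"] = mean_ei, _["se_eint"] = se_ei);
}
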