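#include <Rcpp.h>
using namespace Rcpp;

// Rostro-caudal colonization of a segmented gut by founder cells carrying a
// wild-type or mutant genotype. Per step, cells act in randomized order:
// survive (Bernoulli), divide (offspring in the same segment if below the
// carrying capacity), migrate one segment caudally (if the target segment has
// room). Migration is crowding-driven: the per-cell caudal move probability
// is p_advance scaled by the local occupancy fraction, so sparsely populated
// segments retain their cells (proliferation-pressure front advance) and the
// rostral gut stays colonized. Mutant probabilities are the baseline times a
// multiplier, clipped to [0, 1]. The single mutation is introduced by
// flipping one uniformly chosen living cell at the end of step t_mut
// (t_mut = 0 flips a founder before the first step). Uses R's RNG throughout,
// so set.seed() in R fixes the run.

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List colonize_cpp(int n_segments, int carrying_capacity, int n_founders,
                  int n_steps, double p_divide, double p_advance,
                  double p_survive, double mult_divide, double mult_advance,
                  double mult_survive, int t_mut, bool superstar,
                  double superstar_alpha) {
  std::vector<int> seg, geno, clone;
  std::vector<double> divmult;
  seg.reserve(4 * n_segments * carrying_capacity);
  geno.reserve(seg.capacity());
  clone.reserve(seg.capacity());
  divmult.reserve(seg.capacity());

  std::vector<int> occ(n_segments, 0);
  for (int i = 0; i < n_founders; ++i) {
    seg.push_back(0);
    geno.push_back(0);
    clone.push_back(i);
    // heavy-tailed (Pareto) founder division multipliers in superstar mode
    double m = superstar ? std::pow(unif_rand(), -1.0 / superstar_alpha) : 1.0;
    divmult.push_back(m);
  }
  occ[0] = n_founders;

  IntegerMatrix wt(n_steps + 1, n_segments);
  IntegerMatrix mut(n_steps + 1, n_segments);
  IntegerVector wavefront(n_steps + 1);

  auto flip_one = [&](void) {
    int n = (int)seg.size();
    if (n == 0) return;
    int pick = (int)std::floor(unif_rand() * n);
    if (pick >= n) pick = n - 1;
    geno[pick] = 1;
  };

  auto record = [&](int t, int &running_front) {
    std::vector<int> w(n_segments, 0), m(n_segments, 0);
    for (size_t i = 0; i < seg.size(); ++i) {
      if (geno[i] == 1) m[seg[i]]++; else w[seg[i]]++;
    }
    int front = -1;
    for (int s = n_segments - 1; s >= 0; --s) {
      if (w[s] + m[s] > 0) { front = s; break; }
    }
    if (front + 1 > running_front) running_front = front + 1;
    for (int s = 0; s < n_segments; ++s) {
      wt(t, s) = w[s];
      mut(t, s) = m[s];
    }
    wavefront[t] = running_front;  // most caudal segment ever occupied (1-based)
  };

  if (t_mut == 0) flip_one();
  int running_front = 0;
  record(0, running_front);

  for (int t = 1; t <= n_steps; ++t) {
    int n = (int)seg.size();
    // randomized processing order (Fisher-Yates)
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    std::vector<char> dead(n, 0);
    std::vector<int> child_seg, child_geno, child_clone;
    std::vector<double> child_mult;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      bool m = geno[i] == 1;
      double ps = clip01(p_survive * (m ? mult_survive : 1.0));
      if (unif_rand() >= ps) {
        dead[i] = 1;
        occ[seg[i]]--;
        continue;
      }
      double pd = clip01(p_divide * divmult[i] * (m ? mult_divide : 1.0));
      if (unif_rand() < pd && occ[seg[i]] < carrying_capacity) {
        child_seg.push_back(seg[i]);
        child_geno.push_back(geno[i]);
        child_clone.push_back(clone[i]);
        child_mult.push_back(divmult[i]);
        occ[seg[i]]++;
      }
      double crowd = (double)occ[seg[i]] / (double)carrying_capacity;
      double pa = clip01(p_advance * crowd * (m ? mult_advance : 1.0));
      if (seg[i] + 1 < n_segments && unif_rand() < pa &&
          occ[seg[i] + 1] < carrying_capacity) {
        occ[seg[i]]--;
        seg[i]++;
        occ[seg[i]]++;
      }
    }
    // compact survivors + offspring
    std::vector<int> nseg, ngeno, nclone;
    std::vector<double> nmult;
    for (int i = 0; i < n; ++i) {
      if (!dead[i]) {
        nseg.push_back(seg[i]);
        ngeno.push_back(geno[i]);
        nclone.push_back(clone[i]);
        nmult.push_back(divmult[i]);
      }
    }
    for (size_t i = 0; i < child_seg.size(); ++i) {
      nseg.push_back(child_seg[i]);
      ngeno.push_back(child_geno[i]);
      nclone.push_back(child_clone[i]);
      nmult.push_back(child_mult[i]);
    }
    seg.swap(nseg); geno.swap(ngeno); clone.swap(nclone); divmult.swap(nmult);
    if (t == t_mut) flip_one();
    record(t, running_front);
  }

  IntegerVector clone_sizes(n_founders);
  for (size_t i = 0; i < seg.size(); ++i) clone_sizes[clone[i]]++;

  return List::create(_["wt"] = wt, _["mut"] = mut,
                      _["wavefront"] = wavefront,
                      _["clone_sizes"] = clone_sizes);
}
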