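#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Structured coalescent for one non-recombining locus.
//
// Populations are integer ids 0..(n_pops-1); tips of the species tree come
// first, ancestral populations follow. Demographic events are processed
// backward in time (present = 0):
//   type 0 (split): lineages in child pops a and b move to parent pop c
//   type 1 (pulse): each lineage in recipient a moves to donor b with prob p
// Between events, each population with k lineages and diploid size Ne
// coalesces pairs at rate choose(k,2) / (2 Ne) per generation.
//
// Mutations are dropped on the realized genealogy under infinite sites:
// S ~ Poisson(theta * total branch length), each mutation on a branch chosen
// proportionally to its length, yielding one new biallelic site carried by
// the tips below that branch.
//
// Returns the 0/1 site-by-lineage matrix, per-pulse "traced" flags (did any
// sampled lineage take the pulse edge), and the realized total branch length.

// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector lin_pop0,
                   NumericVector ne,
                   NumericVector ev_time,
                   IntegerVector ev_type,
                   IntegerVector ev_a,
                   IntegerVector ev_b,
                   IntegerVector ev_c,
                   NumericVector ev_p,
                   double theta) {
  const int n = lin_pop0.size();
  const int n_pops = ne.size();
  const int n_ev = ev_time.size();
  if (n < 2) stop("need at least two lineages");

  const int n_nodes = 2 * n - 1;
  std::vector<double> node_time(n_nodes, 0.0);
  std::vector<int> parent(n_nodes, -1), left(n_nodes, -1), right(n_nodes, -1);

  // active lineages: node id + current population
  std::vector<int> act_node(n), act_pop(n);
  for (int i = 0; i < n; ++i) { act_node[i] = i; act_pop[i] = lin_pop0[i]; }
  int n_act = n;
  int next_node = n;

  int n_pulses = 0;
  for (int e = 0; e < n_ev; ++e) if (ev_type[e] == 1) ++n_pulses;
  LogicalVector pulse_hit(n_pulses);
  IntegerVector pulse_moved(n_pulses), pulse_present(n_pulses);
  int pulse_idx = 0;

  double t = 0.0;
  int ev = 0;
  std::vector<int> kcount(n_pops);

  while (n_act > 1) {
    // total coalescent rate over populations
    std::fill(kcount.begin(), kcount.end(), 0);
    for (int i = 0; i < n_act; ++i) ++kcount[act_pop[i]];
    double rate = 0.0;
    for (int p = 0; p < n_pops; ++p) {
      int k = kcount[p];
      if (k > 1) rate += 0.5 * k * (k - 1) / (2.0 * ne[p]);
    }

    double t_coal = R_PosInf;
    if (rate > 0) t_coal = t + exp_rand() / rate;

    if (ev < n_ev && ev_time[ev] <= t_coal) {
      // advance to next demographic event
      t = ev_time[ev];
      if (ev_type[ev] == 0) {
        const int a = ev_a[ev], b = ev_b[ev], c = ev_c[ev];
        for (int i = 0; i < n_act; ++i)
          if (act_pop[i] == a || act_pop[i] == b) act_pop[i] = c;
      } else {
        const int a = ev_a[ev], b = ev_b[ev];
        const double p = ev_p[ev];
        int moved = 0, present = 0;
        for (int i = 0; i < n_act; ++i) {
          if (act_pop[i] == a) {
            ++present;
            if (unif_rand() < p) { act_pop[i] = b; ++moved; }
          }
        }
        pulse_hit[pulse_idx] = moved > 0;
        pulse_moved[pulse_idx] = moved;
        pulse_present[pulse_idx] = present;
        ++pulse_idx;
      }
      ++ev;
      continue;
    }

    if (!R_finite(t_coal)) stop("coalescent stalled: no rate and no events left");
    t = t_coal;

    // choose population proportional to its pair rate
    double u = unif_rand() * rate, acc = 0.0;
    int pop = -1;
    for (int p = 0; p < n_pops; ++p) {
      int k = kcount[p];
      if (k > 1) {
        acc += 0.5 * k * (k - 1) / (2.0 * ne[p]);
        if (u <= acc) { pop = p; break; }
      }
    }
    if (pop < 0) continue;  // numerical edge; redraw

    // choose an unordered pair uniformly within pop
    int k = kcount[pop];
    int i1 = (int)(unif_rand() * k), i2 = (int)(unif_rand() * (k - 1));
    if (i2 >= i1) ++i2;
    int seen = 0, a_idx = -1, b_idx = -1;
    for (int i = 0; i < n_act; ++i) {
      if (act_pop[i] == pop) {
        if (seen == i1) a_idx = i;
        if (seen == i2) b_idx = i;
        ++seen;
      }
    }

    int v = next_node++;
    node_time[v] = t;
    left[v] = act_node[a_idx];
    right[v] = act_node[b_idx];
    parent[left[v]] = v;
    parent[right[v]] = v;

    // replace a_idx with merged node, drop b_idx
    act_node[a_idx] = v;
    act_node[b_idx] = act_node[n_act - 1];
    act_pop[b_idx] = act_pop[n_act - 1];
    --n_act;
  }

  // branch lengths and tip masks
  const int words = (n + 63) / 64;
  std::vector<uint64_t> mask((size_t)n_nodes * words, 0u);
  for (int i = 0; i < n; ++i) mask[(size_t)i * words + i / 64] = 1ull << (i % 64);
  for (int v = n; v < n_nodes; ++v)
    for (int w = 0; w < words; ++w)
      mask[(size_t)v * words + w] =
        mask[(size_t)left[v] * words + w] | mask[(size_t)right[v] * words + w];

  std::vector<double> brlen(n_nodes, 0.0);
  double total_len = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) {
      brlen[v] = node_time[parent[v]] - node_time[v];
      total_len += brlen[v];
    }
  }

  int S = (int)R::rpois(theta * total_len);
  IntegerMatrix geno(S, n);
  for (int s = 0; s < S; ++s) {
    double u = unif_rand() * total_len, acc = 0.0;
    int v = n_nodes - 1;
    for (int j = 0; j < n_nodes; ++j) {
      acc += brlen[j];
      if (u <= acc && brlen[j] > 0) { v = j; break; }
    }
    for (int i = 0; i < n; ++i)
      if (mask[(size_t)v * words + i / 64] & (1ull << (i % 64))) geno(s, i) = 1;
  }

  return List::create(_["geno"] = geno,
                      _["pulse_hit"] = pulse_hit,
                      _["pulse_moved"] = pulse_moved,
                      _["pulse_present"] = pulse_present,
                      _["total_length"] = total_len,
                      _["tmrca"] = node_time[n_nodes - 1]);
}
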