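#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// --- small deterministic RNG (splitmix64-seeded xoshiro256+) ------------
// The sampler runs one independent chain per temperature, seeded from
// (seed, temperature index); results are therefore reproducible and
// independent of evaluation order and of R's global RNG state.

struct Xoshiro {
    uint64_t s[4];
    explicit Xoshiro(uint64_t seed) {
        uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
        for (int i = 0; i < 4; ++i) {
            uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    uint64_t next() {
        uint64_t result = s[0] + s[3];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    double runif() {  // uniform in [0, 1)
        return (next() >> 11) * 0x1.0p-53;
    }
    int rint(int q) {  // uniform integer in [0, q)
        int v = (int)(runif() * q);
        return v >= q ? q - 1 : v;
    }
};

static inline uint64_t chain_seed(double seed, int index) {
    return (uint64_t)seed * 0x100000001B3ULL + (uint64_t)index;
}

// --- union-find ----------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &rnk,
                     int a, int b) {
    a = uf_find(parent, a);
    b = uf_find(parent, b);
    if (a == b) return;
    if (rnk[a] < rnk[b]) std::swap(a, b);
    parent[b] = a;
    if (rnk[a] == rnk[b]) rnk[a]++;
}

// --- Swendsen-Wang core --------------------------------------------------
// One chain of a q-state Potts model with couplings `w` on the edge list:
// edges whose incident spins agree are frozen with probability
// 1 - exp(-w/T); each frozen component then flips to a uniformly random
// state. Accumulates, per edge, the post-burn-in frequency with which its
// endpoints share a spin (optionally the sweep-by-sweep trace).

static void sw_chain(const IntegerMatrix &edges, const NumericVector &w,
                     int n_nodes, int q, double temperature, int sweeps,
                     int burn_in, Xoshiro &rng, std::vector<double> &agree,
                     IntegerMatrix *trace) {
    const int m = edges.nrow();
    // plain arrays: the sweep loop is the hot path
    std::vector<int> ea(m), eb(m);
    for (int e = 0; e < m; ++e) { ea[e] = edges(e, 0); eb[e] = edges(e, 1); }
    std::vector<int> spin(n_nodes);
    for (int i = 0; i < n_nodes; ++i) spin[i] = rng.rint(q);
    std::vector<double> pfreeze(m);
    for (int e = 0; e < m; ++e)
        pfreeze[e] = 1.0 - std::exp(-w[e] / temperature);
    std::vector<int> parent(n_nodes), rnk(n_nodes), newspin(n_nodes);
    agree.assign(m, 0.0);
    int n_samples = 0, row = 0;
    for (int s = 0; s < sweeps; ++s) {
        for (int i = 0; i < n_nodes; ++i) { parent[i] = i; rnk[i] = 0; }
        for (int e = 0; e < m; ++e) {
            if (spin[ea[e]] == spin[eb[e]] && rng.runif() < pfreeze[e])
                uf_union(parent, rnk, ea[e], eb[e]);
        }
        std::fill(newspin.begin(), newspin.end(), -1);
        for (int i = 0; i < n_nodes; ++i) {
            int r = uf_find(parent, i);
            if (newspin[r] < 0) newspin[r] = rng.rint(q);
            spin[i] = newspin[r];
        }
        if (s >= burn_in) {
            ++n_samples;
            for (int e = 0; e < m; ++e) {
                int eq = spin[ea[e]] == spin[eb[e]] ? 1 : 0;
                agree[e] += eq;
                if (trace) (*trace)(row, e) = eq;
            }
            ++row;
        }
    }
    for (int e = 0; e < m; ++e) agree[e] /= n_samples;
}

// Canonical component labels (1-based, ordered by smallest member index)
// for the subgraph of edges with corrected correlation above `threshold`.
static void label_components(const IntegerMatrix &edges,
                             const std::vector<double> &G, double threshold,
                             int n_nodes, std::vector<int> &labels,
                             int &max_size) {
    std::vector<int> parent(n_nodes), rnk(n_nodes);
    for (int i = 0; i < n_nodes; ++i) { parent[i] = i; rnk[i] = 0; }
    for (int e = 0; e < (int)G.size(); ++e)
        if (G[e] > threshold)
            uf_union(parent, rnk, edges(e, 0), edges(e, 1));
    labels.assign(n_nodes, 0);
    std::vector<int> lab_of_root(n_nodes, 0), size_of(n_nodes + 1, 0);
    int next = 0;
    for (int i = 0; i < n_nodes; ++i) {
        int r = uf_find(parent, i);
        if (lab_of_root[r] == 0) lab_of_root[r] = ++next;
        labels[i] = lab_of_root[r];
        ++size_of[labels[i]];
    }
    max_size = 0;
    for (int l = 1; l <= next; ++l)
        if (size_of[l] > max_size) max_size = size_of[l];
}

// Full temperature profile: for each temperature, sample the Potts model,
// estimate the corrected pair correlation G = (q*freq - 1)/(q - 1), and
// report the partition induced by edges with G > link_threshold. T = 0
// rows are written analytically (one all-item cluster).
// [[Rcpp::export]]
List sw_profile_cpp(IntegerMatrix edges, NumericVector w, int n_nodes,
                    int q, NumericVector temperatures, int sweeps,
                    int burn_in, double link_threshold, double seed) {
    if (burn_in >= sweeps) stop("burn_in must be smaller than sweeps");
    const int nt = temperatures.size();
    IntegerMatrix membership(nt, n_nodes);
    IntegerVector max_size(nt);
    std::vector<double> agree;
    std::vector<int> labels;
    for (int ti = 0; ti < nt; ++ti) {
        double tt = temperatures[ti];
        if (tt <= 0) {
            for (int i = 0; i < n_nodes; ++i) membership(ti, i) = 1;
            max_size[ti] = n_nodes;
            continue;
        }
        Xoshiro rng(chain_seed(seed, ti + 1));
        sw_chain(edges, w, n_nodes, q, tt, sweeps, burn_in, rng, agree,
                 nullptr);
        std::vector<double> G(agree.size());
        for (size_t e = 0; e < agree.size(); ++e)
            G[e] = (q * agree[e] - 1.0) / (q - 1.0);
        int ms;
        label_components(edges, G, link_threshold, n_nodes, labels, ms);
        for (int i = 0; i < n_nodes; ++i) membership(ti, i) = labels[i];
        max_size[ti] = ms;
    }
    return List::create(Named("membership") = membership,
                        Named("max_cluster_size") = max_size);
}

// Per-edge spin-agreement frequency of a single chain (diagnostics and
// estimator validation).
// [[Rcpp::export]]
NumericVector sw_agreement(IntegerMatrix edges, NumericVector w, int n_nodes,
                           int q, double temperature, int sweeps,
                           int burn_in, double seed) {
    Xoshiro rng(chain_seed(seed, 1));
    std::vector<double> agree;
    sw_chain(edges, w, n_nodes, q, temperature, sweeps, burn_in, rng, agree,
             nullptr);
    return NumericVector(agree.begin(), agree.end());
}

// Sweep-by-edge agreement indicator trace (for batch-means error bars).
// [[Rcpp::export]]
IntegerMatrix sw_agreement_trace(IntegerMatrix edges, NumericVector w,
                                 int n_nodes, int q, double temperature,
                                 int sweeps, int burn_in, double seed) {
    if (burn_in >= sweeps) stop("burn_in must be smaller than sweeps");
    Xoshiro rng(chain_seed(seed, 1));
    std::vector<double> agree;
    IntegerMatrix trace(sweeps - burn_in, edges.nrow());
    sw_chain(edges, w, n_nodes, q, temperature, sweeps, burn_in, rng, agree,
             &trace);
    return trace;
}
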