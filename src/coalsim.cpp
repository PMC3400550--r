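// Event-driven structured coalescent for two paralogous loci linked by
// interlocus gene conversion.
//
// Model: n_A + n_B sampled haplotypes at loci A and B, each locus L discrete
// sites. Backward in time a lineage carries segments of ancestral material,
// each segment labelled with the set of sampled haplotypes descending from
// it. Lineages reside in one locus; gene conversion moves a geometric tract
// of a lineage's material to the other locus (an ARG-style split into a
// tract lineage and a remainder lineage). Pairs of lineages resident in the
// same locus coalesce at rate 1 per pair (times f in the ancestral epoch,
// i.e. a population f-fold smaller before the expansion). At the
// duplication time all locus-B material relabels to A: the duplicate does
// not exist earlier. Mutations are Poisson on (branch length x ancestral
// sites) at rate theta/2 per site per 2N generations, mapped to distinct
// uniform sites (infinite sites on L positions, collisions resampled).
//
// Internal time unit: 2N generations. Callers convert from 4N units.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  int beg, end;       // 1-based inclusive sites
  uint64_t set;       // descendant sample mask
};
typedef std::vector<Seg> SegList;

struct Lin {
  int locus;          // 0 = A, 1 = B
  SegList segs;
  double material;    // total site count across segs
};

double seg_material(const SegList& s) {
  double m = 0;
  for (const Seg& x : s) m += x.end - x.beg + 1;
  return m;
}

// Union-merge two ancestral-material segment lists. Segments whose
// descendant set reaches the full sample are at their MRCA: their sites get
// tmrca recorded and the material is discarded.
SegList merge_segs(const SegList& A, const SegList& B, uint64_t full,
                   double t, std::vector<double>& tmrca) {
  SegList out;
  size_t i = 0, j = 0;
  int ai = A.empty() ? 0 : A[0].beg;
  int bi = B.empty() ? 0 : B[0].beg;
  auto push = [&](int b, int e, uint64_t s) {
    if (b > e) return;
    if (s == full) {
      for (int p = b; p <= e; ++p) tmrca[p - 1] = t;
      return;
    }
    if (!out.empty() && out.back().end == b - 1 && out.back().set == s)
      out.back().end = e;
    else
      out.push_back({b, e, s});
  };
  while (i < A.size() && j < B.size()) {
    if (ai > A[i].end) { ++i; if (i < A.size()) ai = A[i].beg; continue; }
    if (bi > B[j].end) { ++j; if (j < B.size()) bi = B[j].beg; continue; }
    if (A[i].end < bi) { push(ai, A[i].end, A[i].set); ++i; if (i < A.size()) ai = A[i].beg; continue; }
    if (B[j].end < ai) { push(bi, B[j].end, B[j].set); ++j; if (j < B.size()) bi = B[j].beg; continue; }
    if (ai < bi) { push(ai, bi - 1, A[i].set); ai = bi; continue; }
    if (bi < ai) { push(bi, ai - 1, B[j].set); bi = ai; continue; }
    int e = std::min(A[i].end, B[j].end);
    push(ai, e, A[i].set | B[j].set);
    ai = e + 1;
    bi = e + 1;
  }
  while (i < A.size()) {
    push(std::max(ai, A[i].beg), A[i].end, A[i].set);
    ++i;
    if (i < A.size()) ai = A[i].beg;
  }
  while (j < B.size()) {
    push(std::max(bi, B[j].beg), B[j].end, B[j].set);
    ++j;
    if (j < B.size()) bi = B[j].beg;
  }
  return out;
}

// Split a segment list at a conversion tract [u, v].
void split_tract(const SegList& s, int u, int v,
                 SegList& inside, SegList& outside) {
  for (const Seg& x : s) {
    if (x.end < u || x.beg > v) { outside.push_back(x); continue; }
    if (x.beg < u) outside.push_back({x.beg, u - 1, x.set});
    inside.push_back({std::max(x.beg, u), std::min(x.end, v), x.set});
    if (x.end > v) outside.push_back({v + 1, x.end, x.set});
  }
}

}  // namespace

// [[Rcpp::export]]
List sim_duplicate_cpp(int nA, int nB, int L, double theta, double C,
                       double lambda, double td2, double f, double te2,
                       double max_events) {
  const int n = nA + nB;
  if (n < 2 || n > 64) stop("total sample size must be in [2, 64]");
  if (L < 1) stop("L must be >= 1");
  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  const double theta2 = theta / 2.0;         // per site per 2N generations
  const double conv_per_lin = (C > 0) ? (double)L * C / (2.0 * lambda) : 0.0;
  const double geo_p = (lambda > 1.0) ? 1.0 / lambda : 1.0;

  std::vector<Lin> lins;
  lins.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Lin l;
    l.locus = (i < nA) ? 0 : 1;
    l.segs.push_back({1, L, 1ULL << i});
    l.material = L;
    lins.push_back(l);
  }
  std::vector<double> tmrca(L, 0.0);
  std::vector<int> mutsite;
  std::vector<uint64_t> mutset;
  std::vector<char> used(L, 0);

  double t = 0.0;
  bool dup_done = (td2 <= 0.0);
  if (dup_done) for (Lin& l : lins) l.locus = 0;
  double n_events = 0;

  auto place_mutations = [&](double dt, double M) {
    if (theta2 <= 0 || M <= 0 || dt <= 0) return;
    double mean = theta2 * M * dt;
    if (mean > 5e7)
      stop("expected mutation count too large; reduce theta or event times");
    int nm = (int)R::rpois(mean);
    for (int m = 0; m < nm; ++m) {
      for (int attempt = 0; attempt < 1000; ++attempt) {
        double w = unif_rand() * M;
        int site = -1;
        uint64_t set = 0;
        for (const Lin& l : lins) {
          if (w >= l.material) { w -= l.material; continue; }
          for (const Seg& x : l.segs) {
            double len = x.end - x.beg + 1;
            if (w >= len) { w -= len; continue; }
            site = x.beg + (int)w;
            if (site > x.end) site = x.end;
            set = x.set;
            break;
          }
          break;
        }
        if (site < 1) break;  // numerical edge: drop
        if (!used[site - 1]) {
          used[site - 1] = 1;
          mutsite.push_back(site);
          mutset.push_back(set);
          break;
        }
        // collision with an existing mutation: resample placement
      }
    }
  };

  while (true) {
    // prune empty lineages
    lins.erase(std::remove_if(lins.begin(), lins.end(),
                              [](const Lin& l) { return l.segs.empty(); }),
               lins.end());
    if (lins.empty()) break;

    int kA = 0, kB = 0;
    double M = 0;
    for (const Lin& l : lins) {
      if (l.locus == 0) ++kA; else ++kB;
      M += l.material;
    }
    const bool two = !dup_done;
    const double coalmult = (t >= te2) ? f : 1.0;
    const double pairsA = kA * (kA - 1) / 2.0;
    const double pairsB = kB * (kB - 1) / 2.0;
    const double rc = coalmult * (pairsA + pairsB);
    const double rg = two ? conv_per_lin * lins.size() : 0.0;
    const double tot = rc + rg;

    double tb = R_PosInf;
    if (t < te2) tb = te2;
    if (two && td2 < tb) tb = td2;

    if (tot <= 0) {
      if (!R_finite(tb))
        stop("internal error: no events possible but ancestral material remains");
      place_mutations(tb - t, M);
      t = tb;
      if (two && t >= td2) {
        for (Lin& l : lins) l.locus = 0;
        dup_done = true;
      }
      continue;
    }

    double dt = exp_rand() / tot;
    if (t + dt >= tb) {
      place_mutations(tb - t, M);
      t = tb;
      if (two && t >= td2) {
        for (Lin& l : lins) l.locus = 0;
        dup_done = true;
      }
      continue;
    }

    place_mutations(dt, M);
    t += dt;
    if (++n_events > max_events)
      stop("event budget exceeded; check simulation parameters");

    double u = unif_rand() * tot;
    if (u < rc) {
      // coalescence: choose locus weighted by pair count, then a pair
      int locus = (unif_rand() * (pairsA + pairsB) < pairsA) ? 0 : 1;
      std::vector<int> idx;
      for (size_t q = 0; q < lins.size(); ++q)
        if (lins[q].locus == locus) idx.push_back((int)q);
      int k = (int)idx.size();
      int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      SegList merged = merge_segs(lins[ia].segs, lins[ib].segs, full, t, tmrca);
      lins[ia].segs = merged;
      lins[ia].material = seg_material(merged);
      lins[ib].segs.clear();
      lins[ib].material = 0;
    } else {
      // gene conversion: uniform lineage, uniform tract start, geometric
      // length truncated at the locus end; covered material switches locus
      int q = (int)(unif_rand() * lins.size());
      if (q >= (int)lins.size()) q = (int)lins.size() - 1;
      int start = 1 + (int)(unif_rand() * L);
      if (start > L) start = L;
      int len = 1;
      if (geo_p < 1.0) len = 1 + (int)R::rgeom(geo_p);
      int vend = start + len - 1;
      if (vend > L) vend = L;
      SegList inside, outside;
      split_tract(lins[q].segs, start, vend, inside, outside);
      if (inside.empty()) continue;       // tract hit no ancestral material
      if (outside.empty()) {
        lins[q].locus = 1 - lins[q].locus; // whole lineage switches
        continue;
      }
      Lin nl;
      nl.locus = 1 - lins[q].locus;
      nl.segs = inside;
      nl.material = seg_material(inside);
      lins[q].segs = outside;
      lins[q].material = seg_material(outside);
      lins.push_back(nl);
    }
  }

  // order mutations by site
  const int S = (int)mutsite.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mutsite[a] < mutsite[b]; });
  IntegerVector positions(S);
  IntegerMatrix mat(n, S);
  for (int c = 0; c < S; ++c) {
    positions[c] = mutsite[ord[c]];
    uint64_t s = mutset[ord[c]];
    for (int r = 0; r < n; ++r)
      if (s & (1ULL << r)) mat(r, c) = 1;
  }
  return List::create(_["positions"] = positions, _["mat"] = mat,
                      _["tmrca"] = NumericVector(tmrca.begin(), tmrca.end()));
}
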