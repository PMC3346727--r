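// Random-forest engine for case-control dosage data.
//
// Genotypes are additive minor-allele counts in {0,1,2}, so every split is one
// of two ordered cuts (g<=0 vs g>0, g<=1 vs g>1) and split search reduces to
// class counts per genotype value.  Trees are grown on n-sample bootstraps
// (with replacement) under a strict Gini improvement rule, OOB majority votes
// break ties toward the control class, and permutation variable importance is
// the Breiman/Random Jungle standardized Z: per-tree OOB accuracy decrease
// after within-OOB permutation of one variable, averaged over trees and
// divided by its standard error.  All randomness flows from one integer seed
// through streams keyed by (seed, stream, index), so fits are bit-reproducible
// and independent of execution order.
//
// Layout: genotypes are held once per call as a byte matrix with one column
// per SNP; the phenotype enters the growing loop only through the packed
// sample list, so the matrix is shared across all phenotype permutations and
// both forest stages without copying.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// xorshift64* stream; state derived from up to three keys by splitmix mixing
struct Rng {
  uint64_t s;
  Rng(uint64_t a, uint64_t b = 0, uint64_t c = 0) {
    s = mix64(a + 0x632BE59BD9B4E019ULL);
    s = mix64(s ^ (b * 0xC2B2AE3D27D4EB4FULL + 0x9E3779B97F4A7C15ULL));
    s = mix64(s ^ (c * 0xD6E8FEB86659FD93ULL + 0xA0761D6478BD642FULL));
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t z = s;
    z ^= z << 13; z ^= z >> 7; z ^= z << 17;
    s = z;
    return z * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n) (multiply-shift; bias negligible for n << 2^32)
  inline uint32_t bounded(uint32_t n) {
    return (uint32_t)(((uint64_t)(uint32_t)next() * (uint64_t)n) >> 32);
  }
};

struct ForestOut {
  double oob_error;
  int n_oob_samples;        // samples with at least one OOB vote
  std::vector<double> z;    // standardized importance, one per fitted feature
  std::vector<int> case_votes, tot_votes;
};

// one tree as a flat node vector; leaf: feat == -1 and split holds the class
struct Node { int feat, left, right; uint8_t split; };
struct TreeBuf {
  std::vector<Node> nodes;
  void clear() { nodes.clear(); }
  int add_node() { nodes.push_back(Node{-1, -1, -1, 0}); return (int)nodes.size() - 1; }
};

struct StackItem { int b, e, wn, n1, idx; };

// exact a*b > c*d for non-negative 64-bit factors: double screen (exact for
// products below 2^53, i.e. every realistic sample size), __int128 on near-ties
static inline bool prod_gt(long long a, long long b, long long c, long long d) {
  double x = (double)a * (double)b, y = (double)c * (double)d;
  if (x > y + 4.0 || y > x + 4.0) return x > y;
  return (__int128)a * b > (__int128)c * d;
}

// X2: packed table, one 2n-byte block per original SNP column;
// cols: the p fitted features as indices into X2 blocks.
static void fit_forest_core(const uint8_t* X2, int n, const int* cols, int p,
                            const int* y, int ntrees, int mtry, int minnode,
                            uint64_t seed, bool importance, ForestOut& out) {
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (minnode < 1) minnode = 1;
  const size_t n2 = (size_t)n;

  out.case_votes.assign(n, 0);
  out.tot_votes.assign(n, 0);
  out.z.assign(p, 0.0);

  std::vector<int> samp(n), inbag(n);
  std::vector<int> feats(p);
  std::vector<StackItem> stack;
  TreeBuf tree;
  std::vector<int> oob; oob.reserve(n);
  std::vector<uint8_t> base_correct; base_correct.reserve(n);
  std::vector<int> pathbuf, path_off;
  std::vector<std::vector<std::pair<int,int> > > inv(importance ? p : 0);
  std::vector<int> usedfeats, pool, undo;
  std::vector<uint8_t> used(importance ? p : 0, 0);
  std::vector<double> sumd(p, 0.0), sumd2(p, 0.0);

  for (int t = 0; t < ntrees; ++t) {
    uint64_t tree_seed = mix64(seed ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(t + 1)));
    Rng rng(tree_seed, 1);
    for (int f = 0; f < p; ++f) feats[f] = f;

    // bootstrap with replacement; the node loops then run over the distinct
    // in-bag samples with their multiplicities, packed as
    // (sample << 6) | (weight << 1) | class  (weight saturates far above any
    // realistically attainable bootstrap count)
    std::fill(inbag.begin(), inbag.end(), 0);
    int root_n1 = 0;
    for (int i = 0; i < n; ++i) {
      int s = (int)rng.bounded((uint32_t)n);
      root_n1 += y[s];
      inbag[s]++;
    }
    int ndistinct = 0;
    for (int s = 0; s < n; ++s) {
      if (inbag[s] == 0) continue;
      int w = inbag[s] < 31 ? inbag[s] : 31;
      samp[ndistinct++] = (s << 6) | (w << 1) | y[s];
    }

    // grow tree
    tree.nodes.reserve(1024);
    tree.clear();
    stack.clear();
    int root = tree.add_node();
    stack.push_back({0, ndistinct, n, root_n1, root});
    while (!stack.empty()) {
      StackItem it = stack.back(); stack.pop_back();
      int b = it.b, e = it.e, nn = it.wn, n1 = it.n1;
      bool make_leaf = (n1 == 0 || n1 == nn || nn < 2 * minnode || nn < 2);
      int bfeat = -1; uint8_t bsplit = 0;
      long long bval = 0, bden = 1;
      if (!make_leaf && nn == 2) {
        // two samples, one per class (a doubleton is always same-class, hence
        // already a leaf): the only valid splits are perfect ones, so take the
        // first candidate whose genotypes differ
        int sa = samp[b] >> 6, sb = samp[b + 1] >> 6;
        for (int k = 0; k < mtry; ++k) {
          int j = k + (int)rng.bounded((uint32_t)(p - k));
          int tmp = feats[k]; feats[k] = feats[j]; feats[j] = tmp;
          int f = feats[k];
          const uint8_t* xf2 = X2 + (size_t)cols[f] * n2;
          uint8_t ga = xf2[sa], gb = xf2[sb];
          if (ga != gb) {
            bfeat = f;
            bsplit = (uint8_t)((ga > gb ? gb : ga) == 0 && (ga > gb ? ga : gb) == 2 ? 1 : (ga > gb ? gb : ga));
            bval = 2; bden = 1;
            break;
          }
        }
        if (bfeat < 0) make_leaf = true;
      } else if (!make_leaf) {
        long long fP = (long long)n1 * n1 + (long long)(nn - n1) * (nn - n1);
        // draw the mtry candidates up front so their columns can be prefetched
        // while earlier candidates are being scored
        int cand[64]; int ncand = mtry <= 64 ? mtry : 64;
        for (int k = 0; k < ncand; ++k) {
          int j = k + (int)rng.bounded((uint32_t)(p - k));
          int tmp = feats[k]; feats[k] = feats[j]; feats[j] = tmp;
          cand[k] = feats[k];
          __builtin_prefetch(X2 + (size_t)cols[feats[k]] * n2 + (samp[b] >> 6));
        }
        for (int k = 64; k < mtry; ++k) { // mtry > 64: draw the remainder plainly
          int j = k + (int)rng.bounded((uint32_t)(p - k));
          int tmp = feats[k]; feats[k] = feats[j]; feats[j] = tmp;
        }
        for (int k = 0; k < mtry; ++k) {
          int f = (k < 64) ? cand[k] : feats[k];
          const uint8_t* __restrict__ xf2 = X2 + (size_t)cols[f] * n2;
          const int* __restrict__ sm = samp.data();
          // class counts per genotype; for larger nodes two interleaved
          // counter sets keep the increment chains independent
          int c6[6];
          if (e - b < 24) {
            int ca[6] = {0,0,0,0,0,0};
            for (int i = b; i < e; ++i) {
              int v = sm[i];
              ca[(((int)xf2[v >> 6]) << 1) | (v & 1)] += (v >> 1) & 31;
            }
            for (int q = 0; q < 6; ++q) c6[q] = ca[q];
          } else {
            int ca[6] = {0,0,0,0,0,0}, cb[6] = {0,0,0,0,0,0};
            int i = b;
            for (; i + 1 < e; i += 2) {
              int v0 = sm[i], v1 = sm[i + 1];
              ca[(((int)xf2[v0 >> 6]) << 1) | (v0 & 1)] += (v0 >> 1) & 31;
              cb[(((int)xf2[v1 >> 6]) << 1) | (v1 & 1)] += (v1 >> 1) & 31;
            }
            if (i < e) { int v = sm[i]; ca[(((int)xf2[v >> 6]) << 1) | (v & 1)] += (v >> 1) & 31; }
            for (int q = 0; q < 6; ++q) c6[q] = ca[q] + cb[q];
          }
          bool improved = false;
          for (int sp = 0; sp < 2; ++sp) {
            int nL  = (sp == 0) ? c6[0] + c6[1]
                                : c6[0] + c6[1] + c6[2] + c6[3];
            int nL1 = (sp == 0) ? c6[1] : c6[1] + c6[3];
            int nR  = nn - nL, nR1 = n1 - nL1;
            if (nL < minnode || nR < minnode || nL == 0 || nR == 0) continue;
            long long fL = (long long)nL1 * nL1 + (long long)(nL - nL1) * (nL - nL1);
            long long fR = (long long)nR1 * nR1 + (long long)(nR - nR1) * (nR - nR1);
            long long val = fL * nR + fR * nL;       // candidate score / (nL*nR)
            long long den = (long long)nL * nR;
            // strict improvement over the unsplit node
            if (!prod_gt(val, nn, fP, den)) continue;
            if (bfeat < 0 || prod_gt(val, bden, bval, den)) {
              bfeat = f; bsplit = (uint8_t)sp; bval = val; bden = den;
              improved = true;
            }
          }
          // a split with both children pure cannot be beaten (ties keep the
          // first candidate), so stop scanning further candidates
          if (improved && bval == (long long)nn * bden) break;
        }
        if (bfeat < 0) make_leaf = true;
      }
      if (make_leaf) {
        tree.nodes[it.idx].feat = -1;
        tree.nodes[it.idx].split = (2 * n1 > nn) ? 1 : 0;  // vote tie -> control
        continue;
      }
      // partition samples: left = g <= bsplit, i.e. packed value <= 2*bsplit+1
      const uint8_t* xf2 = X2 + (size_t)cols[bfeat] * n2;
      const uint8_t cut = bsplit;
      int mid = b, nL1 = 0, wnL = 0;
      for (int i = b; i < e; ++i) {
        int v = samp[i];
        if (xf2[v >> 6] <= cut) {
          samp[i] = samp[mid]; samp[mid] = v;
          int w = (v >> 1) & 31;
          wnL += w;
          nL1 += (v & 1) ? w : 0;
          mid++;
        }
      }
      int lid = tree.add_node(), rid = tree.add_node();
      tree.nodes[it.idx].feat = bfeat;
      tree.nodes[it.idx].split = bsplit;
      tree.nodes[it.idx].left = lid;
      tree.nodes[it.idx].right = rid;
      stack.push_back({b, mid, wnL, nL1, lid});
      stack.push_back({mid, e, nn - wnL, n1 - nL1, rid});
    }

    // OOB predictions (and recorded paths when importance is on)
    oob.clear();
    for (int s = 0; s < n; ++s) if (inbag[s] == 0) oob.push_back(s);
    int noob = (int)oob.size();
    if (noob == 0) continue;

    base_correct.assign(noob, 0);
    if (importance) { pathbuf.clear(); path_off.assign(noob + 1, 0); usedfeats.clear(); }
    for (int i = 0; i < noob; ++i) {
      int s = oob[i];
      int node = 0;
      if (importance) path_off[i] = (int)pathbuf.size();
      while (tree.nodes[node].feat >= 0) {
        if (importance) pathbuf.push_back(node);
        const Node& nd = tree.nodes[node];
        uint8_t g = X2[(size_t)cols[nd.feat] * n2 + s];
        node = (g <= nd.split) ? nd.left : nd.right;
      }
      int pred = tree.nodes[node].split;
      out.case_votes[s] += pred;
      out.tot_votes[s]++;
      base_correct[i] = (pred == y[s]) ? 1 : 0;
    }
    if (!importance) continue;
    path_off[noob] = (int)pathbuf.size();

    // inverted index: first node per (sample, feature) on the sample's path
    for (int i = 0; i < noob; ++i) {
      int seen[64]; int nseen = 0;
      for (int q = path_off[i]; q < path_off[i + 1]; ++q) {
        int f = tree.nodes[pathbuf[q]].feat;
        bool dup = false;
        for (int u = 0; u < nseen; ++u) if (seen[u] == f) { dup = true; break; }
        if (!dup && nseen >= 64) // very deep path: check the inv list directly
          dup = !inv[f].empty() && inv[f].back().first == i;
        if (dup) continue;
        if (nseen < 64) seen[nseen++] = f;
        if (!used[f]) { used[f] = 1; usedfeats.push_back(f); }
        inv[f].push_back(std::make_pair(i, q));
      }
    }

    // Permutation importance per feature used by this tree.  OOB samples whose
    // path never queries the feature keep their prediction, so only the
    // recorded (sample, first node) pairs need re-routing, and their permuted
    // genotypes are drawn lazily as a without-replacement sample from the OOB
    // set (distributionally identical to reading a full uniform permutation).
    pool.resize(noob);
    for (int i = 0; i < noob; ++i) pool[i] = i;
    for (size_t uf = 0; uf < usedfeats.size(); ++uf) {
      int f = usedfeats[uf];
      const uint8_t* xf2 = X2 + (size_t)cols[f] * n2;
      Rng r(tree_seed, 0xA11CEULL, (uint64_t)f);
      int psize = noob;
      undo.clear();
      int delta = 0;
      const std::vector<std::pair<int,int> >& lst = inv[f];
      for (size_t q = 0; q < lst.size(); ++q) {
        int i = lst[q].first, qstart = lst[q].second;
        int s = oob[i];
        int j = (int)r.bounded((uint32_t)psize);
        int v = pool[j];
        pool[j] = pool[psize - 1]; pool[psize - 1] = v; psize--;
        undo.push_back(j);
        uint8_t gperm = xf2[oob[v]];
        uint8_t gorig = xf2[s];
        if (gperm == gorig) continue;  // same genotype -> same leaf
        // routing is unchanged until the permuted value first takes the other
        // branch at a node split on this feature; scan the recorded path
        int divchild = -1;
        for (int q2 = qstart; q2 < path_off[i + 1]; ++q2) {
          const Node& pn = tree.nodes[pathbuf[q2]];
          if (pn.feat != f) continue;
          if ((gorig <= pn.split) != (gperm <= pn.split)) {
            divchild = (gperm <= pn.split) ? pn.left : pn.right;
            break;
          }
        }
        if (divchild < 0) continue;    // every decision unchanged -> same leaf
        int nd2 = divchild;
        while (tree.nodes[nd2].feat >= 0) {
          const Node& pn = tree.nodes[nd2];
          uint8_t g = (pn.feat == f) ? gperm
                                     : X2[(size_t)cols[pn.feat] * n2 + s];
          nd2 = (g <= pn.split) ? pn.left : pn.right;
        }
        int pred2 = tree.nodes[nd2].split;
        delta += (int)base_correct[i] - (int)(pred2 == y[s] ? 1 : 0);
      }
      // roll the swap-removals back so the pool is pristine for the next feature
      for (int q = (int)undo.size() - 1; q >= 0; --q) {
        int j = undo[q];
        int v = pool[psize]; pool[psize] = pool[j]; pool[j] = v;
        psize++;
      }
      double d = (double)delta / (double)noob;
      sumd[f] += d;
      sumd2[f] += d * d;
      inv[f].clear();
      used[f] = 0;
    }
  }

  // OOB error from majority votes; ties go to class 0 (control)
  int nvoted = 0, nwrong = 0;
  for (int s = 0; s < n; ++s) {
    if (out.tot_votes[s] == 0) continue;
    nvoted++;
    int pred = (2 * out.case_votes[s] > out.tot_votes[s]) ? 1 : 0;
    if (pred != y[s]) nwrong++;
  }
  out.n_oob_samples = nvoted;
  out.oob_error = nvoted > 0 ? (double)nwrong / (double)nvoted : NA_REAL;

  if (importance) {
    double T = (double)ntrees;
    for (int f = 0; f < p; ++f) {
      double mean = sumd[f] / T;
      double var = (sumd2[f] - T * mean * mean) / (T - 1.0);
      if (!(var > 0.0) || ntrees < 2) { out.z[f] = 0.0; continue; }
      out.z[f] = mean / std::sqrt(var / T);
    }
  }
}

// pack an n x p dosage matrix into the 2n-bytes-per-column table
static std::vector<uint8_t> pack_genotypes(const IntegerMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<uint8_t> x2((size_t)n * p);
  for (int f = 0; f < p; ++f) {
    uint8_t* dst = &x2[(size_t)f * n];
    for (int s = 0; s < n; ++s) {
      int v = X(s, f);
      if (v == NA_INTEGER || v < 0 || v > 2)
        stop("genotype dosages must be 0, 1 or 2 with no missing values");
      dst[s] = (uint8_t)v;
    }
  }
  return x2;
}

static void check_y(const IntegerVector& y) {
  int n0 = 0, n1 = 0;
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] == 0) n0++;
    else if (y[i] == 1) n1++;
    else stop("phenotype must be coded 0 (control) / 1 (case)");
  }
  if (n0 == 0 || n1 == 0) stop("phenotype must contain both cases and controls");
}

// [[Rcpp::export]]
List cpp_fit_forest(IntegerMatrix X, IntegerVector y, int ntrees, int mtry,
                    int minnode, double seed, bool importance) {
  int n = X.nrow(), p = X.ncol();
  if (p < 1) stop("at least one SNP is required");
  check_y(y);
  std::vector<uint8_t> x2 = pack_genotypes(X);
  std::vector<int> yy(y.begin(), y.end());
  std::vector<int> cols(p);
  for (int f = 0; f < p; ++f) cols[f] = f;
  ForestOut out;
  fit_forest_core(x2.data(), n, cols.data(), p, yy.data(), ntrees, mtry,
                  minnode, (uint64_t)(int64_t)seed, importance, out);
  return List::create(
    _["oob_error"] = out.oob_error,
    _["n_oob_samples"] = out.n_oob_samples,
    _["importance_z"] = importance ? SEXP(NumericVector(out.z.begin(), out.z.end()))
                                   : R_NilValue,
    _["case_votes"] = IntegerVector(out.case_votes.begin(), out.case_votes.end()),
    _["tot_votes"] = IntegerVector(out.tot_votes.begin(), out.tot_votes.end()),
    _["n_trees_used"] = ntrees);
}

// Run the two-stage (or single-stage) pathway pipeline once on a phenotype.
// mtry <= 0 means floor(sqrt(p_stage)), recomputed per stage.
static double run_two_stage(const uint8_t* X2, int n, int p, const int* yy,
                            int ntrees, int mtry, int minnode,
                            double threshold, bool use_threshold, int fallback,
                            uint64_t seed, int rep,
                            int* n_stage2, std::vector<double>* z_out,
                            std::vector<int>* sel_out) {
  uint64_t s1 = mix64(seed ^ 0x1000193ULL) ^ mix64((uint64_t)rep * 0x100000001B3ULL + 1);
  uint64_t s2 = mix64(seed ^ 0x7FEFFFFFULL) ^ mix64((uint64_t)rep * 0x100000001B3ULL + 2);
  std::vector<int> allcols(p);
  for (int f = 0; f < p; ++f) allcols[f] = f;
  ForestOut out;
  if (!use_threshold) {
    // single-stage: one forest on all SNPs, seeded like a stage-2 fit so that
    // threshold = -Inf and threshold = NULL give identical scores
    int m = (mtry <= 0) ? std::max(1, (int)std::floor(std::sqrt((double)p))) : std::min(mtry, p);
    fit_forest_core(X2, n, allcols.data(), p, yy, ntrees, m, minnode, s2, false, out);
    if (n_stage2) *n_stage2 = p;
    if (sel_out) *sel_out = allcols;
    return out.oob_error;
  }
  int m1 = (mtry <= 0) ? std::max(1, (int)std::floor(std::sqrt((double)p))) : std::min(mtry, p);
  fit_forest_core(X2, n, allcols.data(), p, yy, ntrees, m1, minnode, s1, true, out);
  std::vector<int> sel;
  for (int f = 0; f < p; ++f) if (out.z[f] > threshold) sel.push_back(f);
  if (sel.empty()) {
    if (fallback == 1) { // top_one: highest Z, ties to the smallest index
      int best = 0;
      for (int f = 1; f < p; ++f) if (out.z[f] > out.z[best]) best = f;
      sel.push_back(best);
    } else {             // all_snps: stage 2 falls back to the full stage-1 set
      sel = allcols;
    }
  }
  if (z_out) *z_out = out.z;
  if (sel_out) *sel_out = sel;
  int ps = (int)sel.size();
  if (n_stage2) *n_stage2 = ps;
  ForestOut out2;
  int m2 = (mtry <= 0) ? std::max(1, (int)std::floor(std::sqrt((double)ps))) : std::min(mtry, ps);
  fit_forest_core(X2, n, sel.data(), ps, yy, ntrees, m2, minnode, s2, false, out2);
  return out2.oob_error;
}

// [[Rcpp::export]]
List cpp_trf_test(IntegerMatrix X, IntegerVector y, int ntrees, int mtry,
                  int minnode, double threshold, bool use_threshold,
                  int fallback, int K, double seed) {
  int n = X.nrow(), p = X.ncol();
  if (p < 1) stop("at least one SNP is required");
  check_y(y);
  std::vector<uint8_t> x2 = pack_genotypes(X);
  std::vector<int> y0(y.begin(), y.end());
  uint64_t sd = (uint64_t)(int64_t)seed;

  int n_stage2 = 0;
  std::vector<double> z_obs;
  std::vector<int> sel_obs;
  double R = run_two_stage(x2.data(), n, p, y0.data(), ntrees, mtry, minnode,
                           threshold, use_threshold, fallback, sd, 0,
                           &n_stage2, &z_obs, &sel_obs);

  NumericVector Rperm(K);
  std::vector<int> yp(n);
  for (int i = 1; i <= K; ++i) {
    // fresh permutation of the original phenotype for each replicate
    Rng r(sd, 0xFEEDULL, (uint64_t)i);
    yp = y0;
    for (int k = n - 1; k > 0; --k) {
      int j = (int)r.bounded((uint32_t)(k + 1));
      int tmp = yp[k]; yp[k] = yp[j]; yp[j] = tmp;
    }
    Rperm[i - 1] = run_two_stage(x2.data(), n, p, yp.data(), ntrees, mtry,
                                 minnode, threshold, use_threshold, fallback,
                                 sd, i, NULL, NULL, NULL);
    if ((i & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector sel(sel_obs.size());
  for (size_t k = 0; k < sel_obs.size(); ++k) sel[k] = sel_obs[k] + 1;
  return List::create(
    _["R"] = R,
    _["R_perm"] = Rperm,
    _["n_snps_stage1"] = p,
    _["n_snps_stage2"] = n_stage2,
    _["importance_z"] = use_threshold ? SEXP(NumericVector(z_obs.begin(), z_obs.end()))
                                      : R_NilValue,
    _["selected"] = sel);
}
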