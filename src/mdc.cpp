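#include <Rcpp.h>
using namespace Rcpp;

// Deep-coalescence kernel.
//
// A gene tree is passed as two integer vectors over its nodes (0-based,
// postorder: children always precede parents):
//   po         postorder node indices
//   parent     parent node index per node (-1 for the root)
//   leafAllele allele index per node (-1 for internal nodes)
// Lineage labels are bits 0..L-1 (L <= 30).  For a lineage subset A the
// number of gene lineages exiting the species-tree cluster A equals the
// number of gene-tree nodes whose leaf set maps inside A and whose parent's
// leaf set does not (maximal A-clades).  Extra lineages = k(A) - 1.

static void node_masks(const IntegerVector &po, const IntegerVector &parent,
                       const IntegerVector &leafAllele,
                       const IntegerVector &lineage, std::vector<int> &mask) {
  int n = po.size();
  std::fill(mask.begin(), mask.end(), 0);
  for (int i = 0; i < n; i++) {
    int v = po[i];
    if (leafAllele[v] >= 0) mask[v] = 1 << lineage[leafAllele[v]];
    if (parent[v] >= 0) mask[parent[v]] |= mask[v];
  }
}

// Extra-lineage vector over all 2^L lineage subsets, summed over the trees
// of one locus with weights w, for one allele -> lineage assignment.
//
// For a subset A the number of gene lineages exiting it is
//   k(A) = #{v : mask(v) subset of A} - #{v non-root : mask(parent(v)) subset of A}
// (each maximal A-clade nets exactly one), so k over all subsets is a
// subset-sum (zeta transform) of counts keyed by node masks.  Extra
// lineages are max(k - 1, 0); k(A) = 0 only for subsets of the lineages
// absent from a tree, which receive an explicit correction.
// [[Rcpp::export(name = ".locus_K")]]
NumericVector locus_K(List po, List parent, List leafAllele,
                      NumericVector w, IntegerVector lineage, int L) {
  int nsub = 1 << L;
  NumericVector K(nsub);
  double W = 0.0;
  int ntree = po.size();
  std::vector< std::pair<int, double> > absent;
  for (int t = 0; t < ntree; t++) {
    IntegerVector po_t = po[t], pa_t = parent[t], la_t = leafAllele[t];
    int n = po_t.size();
    std::vector<int> mask(n);
    node_masks(po_t, pa_t, la_t, lineage, mask);
    int present = 0;
    for (int v = 0; v < n; v++) {
      if (mask[v] == 0) continue;
      present |= mask[v];
      K[mask[v]] += w[t];
      int p = pa_t[v];
      if (p >= 0) K[mask[p]] -= w[t];
    }
    W += w[t];
    int abs_mask = (~present) & (nsub - 1);
    if (abs_mask) absent.push_back(std::make_pair(abs_mask, w[t]));
  }
  for (int i = 0; i < L; i++) {             // zeta transform
    int bit = 1 << i;
    for (int A = 0; A < nsub; A++) {
      if (A & bit) K[A] += K[A ^ bit];
    }
  }
  for (int A = 1; A < nsub; A++) K[A] -= W; // k(A) - 1 per tree
  K[0] = 0.0;
  // subsets made only of absent lineages have k = 0, not k = 1
  for (size_t q = 0; q < absent.size(); q++) {
    int am = absent[q].first;
    for (int sub = am; sub > 0; sub = (sub - 1) & am) {
      K[sub] += absent[q].second;
    }
  }
  return K;
}

// Extra-lineage count for a single tree and a single cluster subset.
// [[Rcpp::export(name = ".tree_cluster_k")]]
int tree_cluster_k(IntegerVector po, IntegerVector parent,
                   IntegerVector leafAllele, IntegerVector lineage,
                   int L, int A) {
  int n = po.size();
  std::vector<int> mask(n);
  node_masks(po, parent, leafAllele, lineage, mask);
  int k = 0;
  for (int v = 0; v < n; v++) {
    if ((mask[v] & ~A) == 0 && mask[v] != 0) {
      int p = parent[v];
      if (p < 0 || (mask[p] & ~A) != 0) k++;
    }
  }
  return k;
}

// Exact minimum-deep-coalescence species tree by dynamic programming over
// lineage subsets: best(A) = K[A] + min over bipartitions A = S | A\S of
// best(S) + best(A\S).  Every cluster of a rooted binary tree on the full
// label set is visited exactly once, so best(full) is the exact optimum.
// Returns the optimal score and, per subset, the chosen child subset
// (0 for singletons) for backtracking.
// [[Rcpp::export(name = ".dp_min_tree")]]
List dp_min_tree(NumericVector K) {
  int nsub = K.size();
  std::vector<double> best(nsub, 0.0);
  IntegerVector choice(nsub);
  for (int A = 1; A < nsub; A++) {
    if ((A & (A - 1)) == 0) { best[A] = K[A]; choice[A] = 0; continue; }
    double b = R_PosInf; int arg = 0;
    for (int sub = (A - 1) & A; sub > 0; sub = (sub - 1) & A) {
      int rest = A ^ sub;
      if (sub < rest) continue;  // each bipartition once
      double v = best[sub] + best[rest];
      if (v < b) { b = v; arg = sub; }
    }
    best[A] = K[A] + b;
    choice[A] = arg;
  }
  return List::create(_["score"] = best[nsub - 1], _["choice"] = choice,
                      _["best"] = NumericVector(best.begin(), best.end()));
}
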