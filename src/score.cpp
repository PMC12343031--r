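// Quartet-score counting kernel.
//
// Every resolved quartet ab|cd induced by a gene tree has a unique internal
// path whose endpoints are the gene-tree nodes where {a,b} and {c,d} merge.
// Likewise it is anchored at exactly two internal nodes of a binary species
// tree (where the two pairs coalesce).  Summing, over ordered pairs (p,q) of
// gene-tree internal nodes, products of per-component taxon masses therefore
// counts each agreeing quartet once per species-tree anchor; the total over
// anchors is divided by two by the caller.
//
// Masses carry three kinds of per-leaf weight multiplicatively:
//   * 1/n_s (n_s = individuals of species s in the tree): averages over
//     choices of one individual per species;
//   * exp(-dist(leaf, node)) in hybrid mode: factorizes the quartet length
//     penalty exp(-L), L = sum of the four terminal path lengths;
// and the support product along the p..q path supplies the support weight.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PTree {
  int I;                     // number of internal nodes
  int nSpecies;
  std::vector<int> compOff;  // I+1 offsets into mass rows
  NumericMatrix M0;          // (totalComps x nSpecies) multiplicity masses
  NumericMatrix ME;          // exp(-dist)-weighted masses
  NumericMatrix pathW;       // I x I support products
  IntegerMatrix towards;     // I x I local comp index of p containing q
};

static PTree unpack(const List& t) {
  PTree p;
  p.I = as<int>(t["I"]);
  p.nSpecies = as<int>(t["nSpecies"]);
  p.compOff = as<std::vector<int>>(t["compOff"]);
  p.M0 = as<NumericMatrix>(t["M0"]);
  p.ME = as<NumericMatrix>(t["ME"]);
  p.pathW = as<NumericMatrix>(t["pathW"]);
  p.towards = as<IntegerMatrix>(t["towards"]);
  return p;
}

// [[Rcpp::export]]
List qs_preprocess(IntegerMatrix edge, int ntip, int nnode,
                   IntegerVector leafSpecies, NumericVector supports,
                   NumericVector lengths, int nSpecies) {
  int nNode = ntip + nnode;
  int nEdge = edge.nrow();
  // adjacency
  std::vector<std::vector<int>> adj(nNode), adjE(nNode);
  for (int e = 0; e < nEdge; ++e) {
    int a = edge(e, 0) - 1, b = edge(e, 1) - 1;
    adj[a].push_back(b); adjE[a].push_back(e);
    adj[b].push_back(a); adjE[b].push_back(e);
  }
  // multiplicity 1/n_s
  std::vector<double> mult(ntip, 1.0);
  std::vector<int> cnt(nSpecies, 0);
  for (int i = 0; i < ntip; ++i) cnt[leafSpecies[i] - 1]++;
  for (int i = 0; i < ntip; ++i) mult[i] = 1.0 / cnt[leafSpecies[i] - 1];

  int I = nnode;
  std::vector<int> compOff(I + 1, 0);
  for (int ii = 0; ii < I; ++ii)
    compOff[ii + 1] = compOff[ii] + (int)adj[ntip + ii].size();
  int totC = compOff[I];
  NumericMatrix M0(totC, nSpecies), ME(totC, nSpecies);
  NumericMatrix pathW(I, I);
  IntegerMatrix towards(I, I);

  std::vector<int> stack; stack.reserve(nNode);
  std::vector<double> dstack; dstack.reserve(nNode);
  std::vector<int> from; from.reserve(nNode);

  for (int ii = 0; ii < I; ++ii) {
    int p = ntip + ii;
    int nc = (int)adj[p].size();
    for (int c = 0; c < nc; ++c) {
      int row = compOff[ii] + c;
      // DFS into component c collecting leaves with distance from p
      stack.clear(); dstack.clear(); from.clear();
      stack.push_back(adj[p][c]);
      dstack.push_back(lengths[adjE[p][c]]);
      from.push_back(p);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        double d = dstack.back(); dstack.pop_back();
        int fr = from.back(); from.pop_back();
        if (v < ntip) {
          int s = leafSpecies[v] - 1;
          M0(row, s) += mult[v];
          ME(row, s) += std::exp(-d) * mult[v];
        } else {
          for (size_t k = 0; k < adj[v].size(); ++k) {
            int w = adj[v][k];
            if (w == fr) continue;
            stack.push_back(w);
            dstack.push_back(d + lengths[adjE[v][k]]);
            from.push_back(v);
          }
        }
      }
    }
    // BFS over internal nodes for path support products + direction
    std::vector<double> prod(nNode, -1.0);
    std::vector<int> dir(nNode, -1);
    prod[p] = 1.0;
    std::vector<int> queue; queue.push_back(p);
    std::vector<int> par(nNode, -1);
    size_t qh = 0;
    while (qh < queue.size()) {
      int v = queue[qh++];
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (w < ntip || prod[w] >= 0.0) continue;
        prod[w] = prod[v] * supports[adjE[v][k]];
        dir[w] = (v == p) ? (int)k : dir[v];
        par[w] = v;
        queue.push_back(w);
      }
    }
    for (int jj = 0; jj < I; ++jj) {
      int q = ntip + jj;
      if (jj == ii) { pathW(ii, jj) = 1.0; towards(ii, jj) = -1; continue; }
      pathW(ii, jj) = prod[q];
      towards(ii, jj) = dir[q];
    }
  }
  return List::create(_["I"] = I, _["nSpecies"] = nSpecies,
                      _["compOff"] = compOff, _["M0"] = M0, _["ME"] = ME,
                      _["pathW"] = pathW, _["towards"] = towards);
}

// per-(node, excluded comp) block aggregates
struct SideAgg {
  double S[4];       // total mass per block
  double C01, C02, C12, C03, C13, C23;  // cross terms sum_i x_i y_i
  double pair_[4];   // within-block distinct-species cross-component pairs
};

// compute aggregates at internal node ii of tree, excluding comp `excl`,
// for blocks[] in 0..nb-1 (>=nb means excluded species)
static void side_agg(const PTree& t, const NumericMatrix& M, int ii, int excl,
                     const int* blocks, int nb, SideAgg& a, bool needPairs) {
  for (int b = 0; b < 4; ++b) { a.S[b] = 0; a.pair_[b] = 0; }
  a.C01 = a.C02 = a.C12 = a.C03 = a.C13 = a.C23 = 0;
  int ns = t.nSpecies;
  int lo = t.compOff[ii], hi = t.compOff[ii + 1];
  double sq[4] = {0, 0, 0, 0};     // sum_i (comp block mass)^2
  // per-species totals across comps (for same-species pair correction)
  // accumulate sum_s T_s^2 and sum_s sum_i m_is^2 on the fly
  std::vector<double> Ts;
  if (needPairs) Ts.assign(ns, 0.0);
  double sumTsq[4] = {0, 0, 0, 0}, summsq[4] = {0, 0, 0, 0};
  for (int r = lo; r < hi; ++r) {
    if (r - lo == excl) continue;
    double x[4] = {0, 0, 0, 0};
    for (int s = 0; s < ns; ++s) {
      int b = blocks[s];
      if (b >= nb) continue;
      double m = M(r, s);
      if (m == 0.0) continue;
      x[b] += m;
      if (needPairs) { Ts[s] += m; summsq[b] += m * m; }
    }
    for (int b = 0; b < 4; ++b) { a.S[b] += x[b]; sq[b] += x[b] * x[b]; }
    a.C01 += x[0] * x[1]; a.C02 += x[0] * x[2]; a.C12 += x[1] * x[2];
    a.C03 += x[0] * x[3]; a.C13 += x[1] * x[3]; a.C23 += x[2] * x[3];
  }
  if (needPairs) {
    for (int s = 0; s < ns; ++s) {
      int b = blocks[s];
      if (b >= nb || Ts[s] == 0.0) continue;
      sumTsq[b] += Ts[s] * Ts[s];
    }
    for (int b = 0; b < nb; ++b)
      a.pair_[b] = 0.5 * ((a.S[b] * a.S[b] - sq[b]) - (sumTsq[b] - summsq[b]));
  }
}

static inline double split01(const SideAgg& a) { return a.S[0] * a.S[1] - a.C01; }
static inline double split02(const SideAgg& a) { return a.S[0] * a.S[2] - a.C02; }
static inline double split12(const SideAgg& a) { return a.S[1] * a.S[2] - a.C12; }

// gain of one tripartition against one preprocessed tree
static double tree_gain(const PTree& t, const NumericMatrix& M, bool useW,
                        const int* blocks, long long* ops) {
  double g = 0.0;
  for (int ii = 0; ii < t.I; ++ii) {
    for (int jj = 0; jj < t.I; ++jj) {
      if (ii == jj) continue;
      double W = useW ? t.pathW(ii, jj) : 1.0;
      if (W == 0.0) continue;
      SideAgg ap, aq;
      side_agg(t, M, ii, t.towards(ii, jj), blocks, 3, ap, false);
      side_agg(t, M, jj, t.towards(jj, ii), blocks, 3, aq, true);
      g += W * (split01(ap) * aq.pair_[2] +
                split02(ap) * aq.pair_[1] +
                split12(ap) * aq.pair_[0]);
      if (ops) ++*ops;
    }
  }
  return g;
}

// weighted mass of all resolved quartets (species restricted by keep[])
static double tree_denom(const PTree& t, const NumericMatrix& M, bool useW,
                         const std::vector<int>& keep, long long* ops) {
  int ns = t.nSpecies;
  double total = 0.0;
  // P_s and P_st per (node, excluded comp) are recomputed per ordered pair
  std::vector<double> TsP(ns), TsQ(ns);
  std::vector<double> mP(ns), mQ(ns);
  for (int ii = 0; ii < t.I; ++ii) {
    for (int jj = 0; jj < t.I; ++jj) {
      if (ii == jj) continue;
      double W = useW ? t.pathW(ii, jj) : 1.0;
      if (W == 0.0) continue;
      if (ops) ++*ops;
      // aggregates at p (excl toward q) and q (excl toward p)
      double pairP = 0, pairQ = 0;
      std::vector<double> PsP(ns, 0.0), PsQ(ns, 0.0);
      // same-pair correction needs P_st on both sides; accumulate product
      // sum_{s<t} PstP*PstQ directly
      double cross2 = 0.0;
      // build per-side data
      int loP = t.compOff[ii], hiP = t.compOff[ii + 1];
      int loQ = t.compOff[jj], hiQ = t.compOff[jj + 1];
      int exP = t.towards(ii, jj), exQ = t.towards(jj, ii);
      std::fill(TsP.begin(), TsP.end(), 0.0);
      std::fill(TsQ.begin(), TsQ.end(), 0.0);
      double RP = 0, RQ = 0, sqP = 0, sqQ = 0, msqP = 0, msqQ = 0;
      std::vector<double> riP, riQ;
      for (int r = loP; r < hiP; ++r) {
        if (r - loP == exP) { riP.push_back(-1); continue; }
        double ri = 0;
        for (int s = 0; s < ns; ++s) {
          if (!keep[s]) continue;
          double m = M(r, s);
          if (m == 0) continue;
          ri += m; TsP[s] += m; msqP += m * m;
        }
        riP.push_back(ri); RP += ri; sqP += ri * ri;
      }
      for (int r = loQ; r < hiQ; ++r) {
        if (r - loQ == exQ) { riQ.push_back(-1); continue; }
        double ri = 0;
        for (int s = 0; s < ns; ++s) {
          if (!keep[s]) continue;
          double m = M(r, s);
          if (m == 0) continue;
          ri += m; TsQ[s] += m; msqQ += m * m;
        }
        riQ.push_back(ri); RQ += ri; sqQ += ri * ri;
      }
      double TsqP = 0, TsqQ = 0;
      for (int s = 0; s < ns; ++s) { TsqP += TsP[s] * TsP[s]; TsqQ += TsQ[s] * TsQ[s]; }
      pairP = 0.5 * ((RP * RP - sqP) - (TsqP - msqP));
      pairQ = 0.5 * ((RQ * RQ - sqQ) - (TsqQ - msqQ));
      if (pairP == 0.0 || pairQ == 0.0) continue;
      // shared-species corrections (nonzero only with multiple individuals)
      bool anyShared = false;
      for (int s = 0; s < ns; ++s)
        if (TsP[s] > 0 && TsQ[s] > 0) { anyShared = true; break; }
      double corr1 = 0.0;
      if (anyShared) {
        for (int s = 0; s < ns; ++s) {
          if (TsP[s] == 0 && TsQ[s] == 0) continue;
          // P_s = T_s*(R - T_s) - sum_i m_is*(r_i - m_is)
          double accP = 0, accQ = 0;
          int c = 0;
          for (int r = loP; r < hiP; ++r, ++c) {
            if (c == exP) continue;
            double m = M(r, s);
            if (m) accP += m * (riP[c] - m);
          }
          c = 0;
          for (int r = loQ; r < hiQ; ++r, ++c) {
            if (c == exQ) continue;
            double m = M(r, s);
            if (m) accQ += m * (riQ[c] - m);
          }
          if (!keep[s]) continue;
          PsP[s] = TsP[s] * (RP - TsP[s]) - accP;
          PsQ[s] = TsQ[s] * (RQ - TsQ[s]) - accQ;
          corr1 += PsP[s] * PsQ[s];
        }
        // sum_{s<u} P_st products
        for (int s = 0; s < ns; ++s) {
          if (!keep[s] || TsP[s] == 0 || TsQ[s] == 0) continue;
          for (int u = s + 1; u < ns; ++u) {
            if (!keep[u]) continue;
            double dotP = 0, dotQ = 0;
            int c = 0;
            for (int r = loP; r < hiP; ++r, ++c) {
              if (c == exP) continue;
              dotP += M(r, s) * M(r, u);
            }
            c = 0;
            for (int r = loQ; r < hiQ; ++r, ++c) {
              if (c == exQ) continue;
              dotQ += M(r, s) * M(r, u);
            }
            double PstP = TsP[s] * TsP[u] - dotP;
            double PstQ = TsQ[s] * TsQ[u] - dotQ;
            if (PstP != 0 && PstQ != 0) cross2 += PstP * PstQ;
          }
        }
      }
      total += W * (pairP * pairQ - corr1 + cross2);
    }
  }
  return 0.5 * total;
}

static const NumericMatrix& mass_for(const PTree& t, int mode) {
  return (mode == 2) ? t.ME : t.M0;
}

// [[Rcpp::export]]
List qs_score(List trees, IntegerMatrix trips, int mode, bool want_denom,
              IntegerVector present) {
  long long ops = 0;
  double value = 0.0, denom = 0.0;
  int K = trees.size();
  int nTr = trips.nrow();
  std::vector<int> keep(present.begin(), present.end());
  std::vector<int> blocks(trips.ncol());
  for (int k = 0; k < K; ++k) {
    PTree t = unpack(trees[k]);
    const NumericMatrix& M = mass_for(t, mode);
    bool useW = mode >= 1;
    for (int r = 0; r < nTr; ++r) {
      for (int s = 0; s < trips.ncol(); ++s) blocks[s] = trips(r, s);
      value += tree_gain(t, M, useW, blocks.data(), &ops);
    }
    if (want_denom) denom += tree_denom(t, M, useW, keep, &ops);
  }
  return List::create(_["value"] = value / 2.0, _["denom"] = denom,
                      _["ops"] = (double)ops);
}

// [[Rcpp::export]]
double qs_gain(List trees, IntegerVector blocks, int mode) {
  double g = 0.0;
  std::vector<int> b(blocks.begin(), blocks.end());
  for (int k = 0; k < trees.size(); ++k) {
    PTree t = unpack(trees[k]);
    g += tree_gain(t, mass_for(t, mode), mode >= 1, b.data(), nullptr);
  }
  return g;
}

// [[Rcpp::export]]
NumericVector qs_branch_freq(List trees, IntegerVector blocks4, int mode) {
  // blocks 0,1 = one side of the branch, 2,3 = other side, 4 = absent
  double m1 = 0, m2 = 0, m3 = 0;
  std::vector<int> b(blocks4.begin(), blocks4.end());
  for (int k = 0; k < trees.size(); ++k) {
    PTree t = unpack(trees[k]);
    const NumericMatrix& M = mass_for(t, mode);
    bool useW = mode >= 1;
    for (int ii = 0; ii < t.I; ++ii) {
      for (int jj = 0; jj < t.I; ++jj) {
        if (ii == jj) continue;
        double W = useW ? t.pathW(ii, jj) : 1.0;
        if (W == 0.0) continue;
        SideAgg ap, aq;
        side_agg(t, M, ii, t.towards(ii, jj), b.data(), 4, ap, false);
        side_agg(t, M, jj, t.towards(jj, ii), b.data(), 4, aq, false);
        // f1: {A,B} merge at p, {C,D} at q ; f2: {A,C} | {B,D} ; f3: {A,D} | {B,C}
        m1 += W * (ap.S[0] * ap.S[1] - ap.C01) * (aq.S[2] * aq.S[3] - aq.C23);
        m2 += W * (ap.S[0] * ap.S[2] - ap.C02) * (aq.S[1] * aq.S[3] - aq.C13);
        m3 += W * (ap.S[0] * ap.S[3] - ap.C03) * (aq.S[1] * aq.S[2] - aq.C12);
      }
    }
  }
  return NumericVector::create(m1, m2, m3);
}
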