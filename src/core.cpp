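// Core of the generator: canonical labeling of element-colored multigraphs
// (McKay-style partition refinement with individualization backtracking) and
// the canonical-augmentation search engine.  Graphs are small (molecular),
// so dense n x n order matrices are used throughout.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <map>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// Canonical labeling
// ---------------------------------------------------------------------------

// Refinement signature contribution of one incident bond of a given order:
// per-order counts are packed into one int per target cell, one nibble per
// order value (orders run 1..6: 1..3 plain, 4..6 fragment-owned bonds in
// ownership-aware mode; counts are bounded by n <= 15).
inline int order_code(int o) { return 1 << (4 * (o - 1)); }

struct Canonizer {
  int n;
  const std::vector<int>* col;
  const std::vector<int>* adj; // n*n bond orders
  std::vector<int> bestCode;
  std::vector<int> bestPerm; // label (0-based) -> vertex
  bool haveBest;

  // Equitable refinement: split cells by the multiset of (target cell,
  // bond order) over incident bonds until stable.  Sub-cells are ordered by
  // signature, which depends only on cell indices, so the ordering is
  // isomorphism-invariant.
  void refine(std::vector<std::vector<int> >& P) const {
    bool changed = true;
    std::vector<int> cellOf(n);
    while (changed) {
      changed = false;
      for (size_t c = 0; c < P.size(); ++c)
        for (size_t k = 0; k < P[c].size(); ++k) cellOf[P[c][k]] = (int)c;
      std::vector<std::vector<int> > newP;
      newP.reserve(P.size());
      for (size_t c = 0; c < P.size(); ++c) {
        std::vector<int>& cell = P[c];
        if (cell.size() == 1) { newP.push_back(cell); continue; }
        std::map<std::vector<int>, std::vector<int> > groups;
        for (size_t k = 0; k < cell.size(); ++k) {
          int v = cell[k];
          std::vector<int> sig(P.size(), 0);
          const int* row = &(*adj)[(size_t)v * n];
          for (int w = 0; w < n; ++w)
            if (row[w] > 0) sig[cellOf[w]] += order_code(row[w]);
          groups[sig].push_back(v);
        }
        if (groups.size() > 1) changed = true;
        for (std::map<std::vector<int>, std::vector<int> >::iterator it =
                 groups.begin();
             it != groups.end(); ++it)
          newP.push_back(it->second);
      }
      P.swap(newP);
    }
  }

  void encode(const std::vector<int>& perm, std::vector<int>& code) const {
    code.clear();
    code.push_back(n);
    for (int l = 0; l < n; ++l) code.push_back((*col)[perm[l]]);
    for (int i = 0; i < n; ++i) {
      const int* row = &(*adj)[(size_t)perm[i] * n];
      for (int j = i + 1; j < n; ++j) {
        int o = row[perm[j]];
        if (o > 0) {
          code.push_back(i + 1);
          code.push_back(j + 1);
          code.push_back(o);
        }
      }
    }
  }

  void search(std::vector<std::vector<int> > P) {
    refine(P);
    int target = -1;
    for (size_t c = 0; c < P.size(); ++c)
      if (P[c].size() > 1) { target = (int)c; break; }
    if (target < 0) {
      std::vector<int> perm(n);
      for (int l = 0; l < n; ++l) perm[l] = P[l][0];
      std::vector<int> code;
      encode(perm, code);
      if (!haveBest || code < bestCode) {
        bestCode.swap(code);
        bestPerm = perm;
        haveBest = true;
      }
      return;
    }
    const std::vector<int> cell = P[target];
    std::vector<int> tried;
    for (size_t idx = 0; idx < cell.size(); ++idx) {
      int v = cell[idx];
      // Twin pruning: if swapping v with an already-explored u of the same
      // cell is an automorphism (identical adjacency rows off {u,v}), the
      // branches are equivalent and v can be skipped.
      bool twin = false;
      for (size_t t = 0; t < tried.size() && !twin; ++t) {
        int u = tried[t];
        bool same = true;
        const int* ru = &(*adj)[(size_t)u * n];
        const int* rv = &(*adj)[(size_t)v * n];
        for (int w = 0; w < n; ++w) {
          if (w == u || w == v) continue;
          if (ru[w] != rv[w]) { same = false; break; }
        }
        twin = same;
      }
      if (twin) continue;
      tried.push_back(v);
      std::vector<std::vector<int> > P2;
      P2.reserve(P.size() + 1);
      for (size_t c = 0; c < P.size(); ++c) {
        if ((int)c == target) {
          P2.push_back(std::vector<int>(1, v));
          std::vector<int> rest;
          for (size_t k = 0; k < cell.size(); ++k)
            if (cell[k] != v) rest.push_back(cell[k]);
          P2.push_back(rest);
        } else {
          P2.push_back(P[c]);
        }
      }
      search(P2);
    }
  }
};

// Canonical form: code (lexicographically minimal encoding over all
// labelings consistent with the color classes) and perm (label -> vertex).
void canon_multigraph(int n, const std::vector<int>& col,
                      const std::vector<int>& adj, std::vector<int>& code,
                      std::vector<int>& perm) {
  Canonizer cz;
  cz.n = n;
  cz.col = &col;
  cz.adj = &adj;
  cz.haveBest = false;
  // initial partition: color classes in ascending color order
  std::map<int, std::vector<int> > byCol;
  for (int v = 0; v < n; ++v) byCol[col[v]].push_back(v);
  std::vector<std::vector<int> > P;
  for (std::map<int, std::vector<int> >::iterator it = byCol.begin();
       it != byCol.end(); ++it)
    P.push_back(it->second);
  cz.search(P);
  code.swap(cz.bestCode);
  perm.swap(cz.bestPerm);
}

// ---------------------------------------------------------------------------
// Generation engine
// ---------------------------------------------------------------------------

struct ValenceState {
  int valence, any, doubles, triples, hexact; // -1 = unconstrained
};

struct Engine {
  int n;
  std::vector<int> elem; // atom -> element-table row
  std::vector<int> md;   // atom -> maximum valence
  std::vector<std::vector<ValenceState> > states; // per element-table row
  std::vector<int> adj, frag; // n*n
  // canonization view of the adjacency: in fragment mode, bonds still owned
  // by a prescribed fragment (order equal to the prescription) carry
  // pseudo-orders 4..6 so that sibling deduplication and the augmentation
  // test respect fragment ownership; otherwise identical to adj
  std::vector<int> adjC;
  bool useFrags;
  int hTarget, Bmax;
  bool emit;
  long long maxCount; // safety valve (<=0: unlimited)

  std::vector<int> deg;
  std::vector<int> colGen; // generation colors = element row
  int B;

  long long count, nodes, extTested, dupSkipped;
  unsigned long tick;
  // run-level deduplication of finished molecules: with a fixed fragment
  // embedding, symmetric placements can reach the same final structure on
  // distinct search branches
  std::set<std::vector<int> > emittedGlobal;

  void bump(int a, int b, int d) {
    size_t ab = (size_t)a * n + b, ba = (size_t)b * n + a;
    adj[ab] += d;
    adj[ba] += d;
    deg[a] += d;
    deg[b] += d;
    B += d;
    int o = adj[ab];
    int e = o;
    if (useFrags && frag[ab] > 0 && o == frag[ab]) e = o + 3;
    adjC[ab] = e;
    adjC[ba] = e;
  }

  // emitted molecules, atoms in final canonical label order
  std::vector<std::vector<int> > outElem, outBondI, outBondJ, outBondO,
      outVal, outH;

  bool connected() const {
    std::vector<int> stack(1, 0), seen(n, 0);
    seen[0] = 1;
    int cnt = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      const int* row = &adj[(size_t)v * n];
      for (int w = 0; w < n; ++w)
        if (row[w] > 0 && !seen[w]) {
          seen[w] = 1;
          ++cnt;
          stack.push_back(w);
        }
    }
    return cnt == n;
  }

  // admissible (valence, implicit H) choices for atom v given current bonds
  void admissible(int v, std::vector<std::pair<int, int> >& out) const {
    out.clear();
    const int* row = &adj[(size_t)v * n];
    int tot = 0, n2 = 0, n3 = 0;
    for (int w = 0; w < n; ++w) {
      tot += row[w];
      if (row[w] == 2) ++n2;
      else if (row[w] == 3) ++n3;
    }
    const std::vector<ValenceState>& ss = states[elem[v]];
    for (size_t k = 0; k < ss.size(); ++k) {
      const ValenceState& s = ss[k];
      if (s.valence < tot) continue;
      if (!s.any) {
        if (s.doubles >= 0 && s.doubles != n2) continue;
        if (s.triples >= 0 && s.triples != n3) continue;
        if (s.hexact >= 0 && s.hexact != s.valence - tot) continue;
      }
      // several alternative patterns may share one valence
      bool dup = false;
      for (size_t q = 0; q < out.size() && !dup; ++q)
        dup = out[q].first == s.valence;
      if (!dup) out.push_back(std::make_pair(s.valence, s.valence - tot));
    }
  }

  void emit_molecule(const std::vector<int>& val, const std::vector<int>& hs,
                     const std::vector<int>& perm) {
    std::vector<int> labelOf(n);
    for (int l = 0; l < n; ++l) labelOf[perm[l]] = l;
    std::vector<int> e(n), vv(n), hh(n), bi, bj, bo;
    for (int l = 0; l < n; ++l) {
      e[l] = elem[perm[l]];
      vv[l] = val[perm[l]];
      hh[l] = hs[perm[l]];
    }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int o = adj[(size_t)perm[i] * n + perm[j]];
        if (o > 0) {
          bi.push_back(i + 1);
          bj.push_back(j + 1);
          bo.push_back(o);
        }
      }
    outElem.push_back(e);
    outVal.push_back(vv);
    outH.push_back(hh);
    outBondI.push_back(bi);
    outBondJ.push_back(bj);
    outBondO.push_back(bo);
  }

  // finished test + emission: every hydrogen assignment reaching the target
  // total is a candidate molecule; distinct final-colored canonical forms
  // are counted (automorphic reassignments collapse to one molecule)
  void process_node() {
    if (!connected()) return;
    std::vector<std::vector<std::pair<int, int> > > perAtom(n);
    for (int v = 0; v < n; ++v) {
      admissible(v, perAtom[v]);
      if (perAtom[v].empty()) return;
    }
    std::vector<int> minH(n), maxH(n);
    for (int v = 0; v < n; ++v) {
      int lo = perAtom[v][0].second, hi = perAtom[v][0].second;
      for (size_t k = 1; k < perAtom[v].size(); ++k) {
        lo = std::min(lo, perAtom[v][k].second);
        hi = std::max(hi, perAtom[v][k].second);
      }
      minH[v] = lo;
      maxH[v] = hi;
    }
    std::vector<int> sufMin(n + 1, 0), sufMax(n + 1, 0);
    for (int v = n - 1; v >= 0; --v) {
      sufMin[v] = sufMin[v + 1] + minH[v];
      sufMax[v] = sufMax[v + 1] + maxH[v];
    }
    std::set<std::vector<int> > finalSeen;
    std::vector<int> val(n), hs(n);
    // iterative DFS over per-atom state choices
    std::vector<size_t> choice(n, 0);
    int v = 0, tot = 0;
    while (v >= 0) {
      if (v == n) {
        if (tot == hTarget) {
          std::vector<int> colF(n);
          for (int a = 0; a < n; ++a)
            colF[a] = (elem[a] * 1000) + val[a] * 10 + hs[a];
          std::vector<int> code, perm;
          canon_multigraph(n, colF, adj, code, perm);
          if (finalSeen.insert(code).second &&
              (!useFrags || emittedGlobal.insert(code).second)) {
            ++count;
            if (emit) emit_molecule(val, hs, perm);
          }
        }
        --v;
        if (v >= 0) tot -= hs[v];
        continue;
      }
      bool descended = false;
      while (choice[v] < perAtom[v].size()) {
        size_t k = choice[v]++;
        int h = perAtom[v][k].second;
        if (tot + h + sufMin[v + 1] > hTarget) continue;
        if (tot + h + sufMax[v + 1] < hTarget) continue;
        val[v] = perAtom[v][k].first;
        hs[v] = h;
        tot += h;
        ++v;
        descended = true;
        break;
      }
      if (!descended) {
        choice[v] = 0;
        --v;
        if (v >= 0) tot -= hs[v];
      }
    }
  }

  // Canonical-augmentation test (fragment-aware): walk the canonical edge
  // sequence of the child backwards, skip bonds still owned by a prescribed
  // fragment (pair prescribed and current order not above the prescription),
  // delete the first deletable bond and compare with the parent's canonical
  // code.  If nothing is deletable the child is the seeded root: accept.
  bool canonical_augmentation(const std::vector<int>& code,
                              const std::vector<int>& perm,
                              const std::vector<int>& codeM, int addedA,
                              int addedB) {
    int header = 1 + n;
    int ntrip = (int)(code.size() - header) / 3;
    int u = -1, w = -1;
    for (int t = ntrip - 1; t >= 0; --t) {
      if (code[header + 3 * t + 2] > 3) continue; // fragment-owned bond
      u = perm[code[header + 3 * t] - 1];
      w = perm[code[header + 3 * t + 1] - 1];
      break;
    }
    if (u < 0) return true;
    // deleting the bond that was just added recreates the parent verbatim
    if ((u == addedA && w == addedB) || (u == addedB && w == addedA))
      return true;
    bump(u, w, -1);
    std::vector<int> code2, perm2;
    canon_multigraph(n, colGen, adjC, code2, perm2);
    bump(u, w, +1);
    return code2 == codeM;
  }

  void generate(const std::vector<int>& codeM) {
    ++nodes;
    if (++tick % 2048 == 0) Rcpp::checkUserInterrupt();
    if (maxCount > 0 && count >= maxCount) return;
    process_node();
    if (B >= Bmax) return;
    std::set<std::vector<int> > seen;
    for (int a = 0; a < n; ++a) {
      if (deg[a] >= md[a]) continue;
      for (int b = a + 1; b < n; ++b) {
        if (deg[b] >= md[b]) continue;
        size_t ab = (size_t)a * n + b, ba = (size_t)b * n + a;
        if (adj[ab] >= 3) continue;
        ++extTested;
        bump(a, b, +1);
        std::vector<int> code, perm;
        canon_multigraph(n, colGen, adjC, code, perm);
        if (!seen.insert(code).second) {
          ++dupSkipped;
        } else if (canonical_augmentation(code, perm, codeM, a, b)) {
          generate(code);
        }
        bump(a, b, -1);
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".canon_cpp")]]
List canon_cpp(IntegerMatrix adj, IntegerVector colors) {
  int n = adj.nrow();
  std::vector<int> A((size_t)n * n), col(n);
  for (int i = 0; i < n; ++i) {
    col[i] = colors[i];
    for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = adj(i, j);
  }
  std::vector<int> code, perm;
  canon_multigraph(n, col, A, code, perm);
  IntegerVector labels(n);
  for (int l = 0; l < n; ++l) labels[perm[l]] = l + 1;
  return List::create(_["labels"] = labels,
                      _["code"] = IntegerVector(code.begin(), code.end()));
}

// [[Rcpp::export(name = ".engine_generate_cpp")]]
List engine_generate_cpp(IntegerVector elem, IntegerVector md_, List states_,
                         IntegerMatrix frag_, bool use_frags, int h_target,
                         bool emit, double max_count) {
  Engine E;
  E.n = elem.size();
  int n = E.n;
  E.elem.assign(elem.begin(), elem.end());
  E.md.assign(md_.begin(), md_.end());
  E.states.resize(states_.size());
  for (int e = 0; e < states_.size(); ++e) {
    IntegerMatrix m = states_[e];
    for (int r = 0; r < m.nrow(); ++r) {
      ValenceState s;
      s.valence = m(r, 0);
      s.any = m(r, 1);
      s.doubles = m(r, 2);
      s.triples = m(r, 3);
      s.hexact = m(r, 4);
      E.states[e].push_back(s);
    }
  }
  E.adj.assign((size_t)n * n, 0);
  E.frag.assign((size_t)n * n, 0);
  E.adjC.assign((size_t)n * n, 0);
  E.useFrags = use_frags;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int f = frag_(i, j);
      E.frag[(size_t)i * n + j] = f;
      E.adj[(size_t)i * n + j] = f; // root: prescribed bonds placed
      E.adjC[(size_t)i * n + j] = (use_frags && f > 0) ? f + 3 : f;
    }
  E.hTarget = h_target;
  E.emit = emit;
  E.maxCount = (long long)max_count;
  E.deg.assign(n, 0);
  E.B = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) E.deg[i] += E.adj[(size_t)i * n + j];
  for (int i = 0; i < n; ++i) {
    E.B += E.deg[i];
    if (E.deg[i] > E.md[i])
      stop("prescribed fragment bonds exceed the maximum degree of atom %d",
           i + 1);
  }
  E.B /= 2;
  int sumMd = 0;
  for (int i = 0; i < n; ++i) sumMd += E.md[i];
  E.Bmax = (sumMd - h_target) / 2; // H budget: finished graphs never exceed it
  if (sumMd - h_target < 0) E.Bmax = -1;
  E.colGen.assign(elem.begin(), elem.end());
  E.count = E.nodes = E.extTested = E.dupSkipped = 0;
  E.tick = 0;

  if (E.Bmax >= E.B) {
    std::vector<int> code, perm;
    canon_multigraph(n, E.colGen, E.adjC, code, perm);
    E.generate(code);
  }

  List mols;
  if (emit) {
    int k = (int)E.outElem.size();
    List lm(k);
    for (int m = 0; m < k; ++m) {
      lm[m] = List::create(
          _["elem"] = IntegerVector(E.outElem[m].begin(), E.outElem[m].end()),
          _["valence"] = IntegerVector(E.outVal[m].begin(), E.outVal[m].end()),
          _["implicit_h"] = IntegerVector(E.outH[m].begin(), E.outH[m].end()),
          _["bond_i"] = IntegerVector(E.outBondI[m].begin(), E.outBondI[m].end()),
          _["bond_j"] = IntegerVector(E.outBondJ[m].begin(), E.outBondJ[m].end()),
          _["bond_order"] =
              IntegerVector(E.outBondO[m].begin(), E.outBondO[m].end()));
    }
    mols = lm;
  }
  return List::create(
      _["count"] = (double)E.count, _["nodes"] = (double)E.nodes,
      _["extensions_tested"] = (double)E.extTested,
      _["duplicates_suppressed"] = (double)E.dupSkipped,
      _["molecules"] = mols);
}
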