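// Cubic-lattice Monte Carlo kernel for bead-tether multivalent polymers.
//
// Beads live on a periodic L x L x L lattice, one bead per site. Chain
// connectivity between consecutive beads is either face adjacency (explicit
// linker beads) or a Chebyshev square-well cap (implicit linker segments).
// Complementary interaction domains (S and P) in face-adjacent sites may be
// flagged as bound; only flagged bonds carry energy (u_SP, in kB*T).
//
// Five move types evolve the system under a modified Metropolis criterion
// min{1, w * exp(-dE)}; w carries the Hastings correction for the
// state-count asymmetries of torsional/crankshaft (Np/Nc) and reptation
// ((Np*Vp)/(Nc*Vc)) moves. All randomness is drawn from R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int DX[6] = { 1, -1, 0, 0, 0, 0 };
static const int DY[6] = { 0, 0, 1, -1, 0, 0 };
static const int DZ[6] = { 0, 0, 0, 0, 1, -1 };

enum MoveType { M_FLIP = 0, M_PIVOT = 1, M_CRANK = 2, M_CLUSTER = 3, M_REPT = 4 };
enum LinkType { LK_NONE = 0, LK_ADJ = 1, LK_CHEB = 2 };
enum BeadKind { K_S = 0, K_P = 1, K_L = 2 };

static inline int wrapc(int a, int L) { a %= L; if (a < 0) a += L; return a; }

// minimum-image per-dimension distance
static inline int mdist1(int a, int b, int L) {
  int d = a - b; d %= L; if (d < 0) d += L;
  return (d > L - d) ? (L - d) : d;
}

struct Sys {
  int L, nb, nm;
  std::vector<int> x, y, z;        // coordinates in [0, L)
  std::vector<int> kind;           // K_S / K_P / K_L
  std::vector<int> mol;            // 0-based molecule id (beads contiguous)
  std::vector<int> partner;        // bound bead index or -1
  std::vector<int> molStart, molEnd;     // bead range [start, end)
  std::vector<int> linkType, linkCap;    // constraint bead i -> bead i+1
  std::vector<int> molLinkN, molLinkE;   // homogeneous linker per molecule, -1 if n/a
  std::vector<int> occ;            // site -> bead index or -1
  double uSP;
  double E;
  // move eligibility
  std::vector<int> domains, endBeads, interiorBeads, reptMols;
  // scratch for cluster BFS
  std::vector<int> molStamp;
  int stamp;

  int site(int xx, int yy, int zz) const {
    return wrapc(xx, L) + L * (wrapc(yy, L) + L * wrapc(zz, L));
  }
  bool adjacent(int a, int b) const {
    int m = mdist1(x[a], x[b], L) + mdist1(y[a], y[b], L) + mdist1(z[a], z[b], L);
    return m == 1;
  }
  int chebBead(int a, int b) const {
    int d = mdist1(x[a], x[b], L);
    int d2 = mdist1(y[a], y[b], L); if (d2 > d) d = d2;
    int d3 = mdist1(z[a], z[b], L); if (d3 > d) d = d3;
    return d;
  }
  double bondE(int p) const { return (p >= 0) ? uSP : 0.0; }
};

static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static Sys buildSys(const List& st) {
  Sys s;
  s.L = as<int>(st["L"]);
  IntegerMatrix co = st["coords"];           // 0-based
  s.nb = co.nrow();
  s.x.resize(s.nb); s.y.resize(s.nb); s.z.resize(s.nb);
  for (int i = 0; i < s.nb; ++i) { s.x[i] = co(i, 0); s.y[i] = co(i, 1); s.z[i] = co(i, 2); }
  s.kind = as<std::vector<int> >(st["kind"]);
  s.mol = as<std::vector<int> >(st["mol"]);         // 0-based
  s.partner = as<std::vector<int> >(st["partner"]); // 0-based, -1 none
  s.molStart = as<std::vector<int> >(st["molStart"]);
  s.molEnd = as<std::vector<int> >(st["molEnd"]);
  s.linkType = as<std::vector<int> >(st["linkType"]);
  s.linkCap = as<std::vector<int> >(st["linkCap"]);
  s.molLinkN = as<std::vector<int> >(st["molLinkN"]);
  s.molLinkE = as<std::vector<int> >(st["molLinkE"]);
  s.uSP = as<double>(st["uSP"]);
  s.nm = (int)s.molStart.size();
  s.occ.assign((size_t)s.L * s.L * s.L, -1);
  for (int i = 0; i < s.nb; ++i) {
    int sid = s.site(s.x[i], s.y[i], s.z[i]);
    if (s.occ[sid] >= 0) stop("site double occupancy in input state");
    s.occ[sid] = i;
  }
  s.E = 0.0;
  for (int i = 0; i < s.nb; ++i)
    if (s.partner[i] > i) s.E += s.uSP;
  for (int m = 0; m < s.nm; ++m) {
    int a = s.molStart[m], b = s.molEnd[m];
    for (int i = a; i < b; ++i) if (s.kind[i] != K_L) s.domains.push_back(i);
    if (b - a >= 2) { s.endBeads.push_back(a); s.endBeads.push_back(b - 1); }
    for (int i = a + 1; i < b - 1; ++i) s.interiorBeads.push_back(i);
    // reptation needs >= 2 domains, one domain kind, and a homogeneous
    // linker spec (the reordering relies on a positionally invariant
    // kind/link pattern)
    int ndom = 0; bool homoKind = true; int k0 = -1;
    for (int i = a; i < b; ++i) if (s.kind[i] != K_L) {
      ++ndom;
      if (k0 < 0) k0 = s.kind[i];
      else if (s.kind[i] != k0) homoKind = false;
    }
    if (ndom >= 2 && homoKind && s.molLinkN[m] >= 1) s.reptMols.push_back(m);
  }
  s.molStamp.assign(s.nm, -1);
  s.stamp = 0;
  return s;
}

// admissible binding candidates for a domain of kind k placed at (px,py,pz);
// the domain itself (bead d) must already be logically detached (its bond
// freed). Neighbor sites are deduplicated so small boxes are handled.
static void bindCandidates(const Sys& s, int d, int k, int px, int py, int pz,
                           std::vector<int>& out) {
  out.clear();
  int want = (k == K_S) ? K_P : K_S;
  int seen[6]; int nseen = 0;
  for (int t = 0; t < 6; ++t) {
    int sid = s.site(px + DX[t], py + DY[t], pz + DZ[t]);
    bool dup = false;
    for (int u = 0; u < nseen; ++u) if (seen[u] == sid) { dup = true; break; }
    if (dup) continue;
    seen[nseen++] = sid;
    int b = s.occ[sid];
    if (b >= 0 && b != d && s.kind[b] == want && s.partner[b] < 0) out.push_back(b);
  }
}

struct Prop {
  int type = -1;
  bool feasible = false;     // false: immediate rejection (overlap / no candidate)
  double dE = 0.0, w = 1.0;
  int Nc = 1, Np = 1;
  double Vc = 1.0, Vp = 1.0;
  int bead = -1;
  int oldPartner = -1, newPartner = -1;
  int ox = 0, oy = 0, oz = 0, nx = 0, ny = 0, nz = 0;
  // cluster translation
  std::vector<int> clusterBeads;
  int dx = 0, dy = 0, dz = 0;
  // reptation
  int rmol = -1; bool fromHead = false; int segLen = 0;
  std::vector<int> segPos;   // enumeration order, 3 ints per bead, domain last
};

static void proposeFlip(Sys& s, Prop& p) {
  p.type = M_FLIP;
  if (s.domains.empty()) return;
  int d = s.domains[rint_n((int)s.domains.size())];
  p.bead = d;
  int op = s.partner[d];
  p.oldPartner = op;
  if (op >= 0) { s.partner[op] = -1; s.partner[d] = -1; }
  std::vector<int> cand;
  bindCandidates(s, d, s.kind[d], s.x[d], s.y[d], s.z[d], cand);
  int N = 1 + (int)cand.size();
  int j = rint_n(N);
  p.newPartner = (j == 0) ? -1 : cand[j - 1];
  if (op >= 0) { s.partner[op] = d; s.partner[d] = op; }
  p.Nc = p.Np = N;
  p.dE = s.bondE(p.newPartner) - s.bondE(op);
  p.w = 1.0;
  p.ox = p.nx = s.x[d]; p.oy = p.ny = s.y[d]; p.oz = p.nz = s.z[d];
  p.feasible = true;
}

// shared tail of pivot/crankshaft: bead b moving to (nx,ny,nz); handles
// occupancy, binding redraw for domains, dE and w.
static void finishSingleBeadMove(Sys& s, Prop& p, int b, int nx, int ny, int nz) {
  p.bead = b;
  p.ox = s.x[b]; p.oy = s.y[b]; p.oz = s.z[b];
  nx = wrapc(nx, s.L); ny = wrapc(ny, s.L); nz = wrapc(nz, s.L);
  p.nx = nx; p.ny = ny; p.nz = nz;
  int sid = s.site(nx, ny, nz);
  int occb = s.occ[sid];
  if (occb >= 0 && occb != b) return;  // steric overlap: immediate rejection
  if (s.kind[b] != K_L) {
    int op = s.partner[b];
    p.oldPartner = op;
    if (op >= 0) { s.partner[op] = -1; s.partner[b] = -1; }
    std::vector<int> candC, candP;
    bindCandidates(s, b, s.kind[b], p.ox, p.oy, p.oz, candC);
    bindCandidates(s, b, s.kind[b], nx, ny, nz, candP);
    p.Nc = 1 + (int)candC.size();
    p.Np = 1 + (int)candP.size();
    int j = rint_n(p.Np);
    p.newPartner = (j == 0) ? -1 : candP[j - 1];
    if (op >= 0) { s.partner[op] = b; s.partner[b] = op; }
    p.dE = s.bondE(p.newPartner) - s.bondE(op);
    p.w = (double)p.Np / (double)p.Nc;
  } else {
    p.dE = 0.0; p.w = 1.0;
  }
  p.feasible = true;
}

static void proposePivot(Sys& s, Prop& p) {
  p.type = M_PIVOT;
  if (s.endBeads.empty()) return;
  int b = s.endBeads[rint_n((int)s.endBeads.size())];
  int m = s.mol[b];
  int anchor, lt, cap;
  if (b == s.molStart[m]) { anchor = b + 1; lt = s.linkType[b]; cap = s.linkCap[b]; }
  else { anchor = b - 1; lt = s.linkType[anchor]; cap = s.linkCap[anchor]; }
  int nx, ny, nz;
  if (lt == LK_ADJ) {
    int t = rint_n(6);
    nx = s.x[anchor] + DX[t]; ny = s.y[anchor] + DY[t]; nz = s.z[anchor] + DZ[t];
  } else {
    int span = 2 * cap + 1;
    nx = s.x[anchor] + rint_n(span) - cap;
    ny = s.y[anchor] + rint_n(span) - cap;
    nz = s.z[anchor] + rint_n(span) - cap;
  }
  finishSingleBeadMove(s, p, b, nx, ny, nz);
}

static void proposeCrank(Sys& s, Prop& p) {
  p.type = M_CRANK;
  if (s.interiorBeads.empty()) return;
  int b = s.interiorBeads[rint_n((int)s.interiorBeads.size())];
  int pr = b - 1, nx_ = b + 1;
  int ltp = s.linkType[pr], capp = s.linkCap[pr];
  int ltn = s.linkType[b],  capn = s.linkCap[b];
  if (ltp == LK_ADJ || ltn == LK_ADJ) {
    // one constraint is face adjacency: enumerate its 6 candidates and
    // filter by the other constraint
    int aRef = (ltp == LK_ADJ) ? pr : nx_;
    int oRef = (ltp == LK_ADJ) ? nx_ : pr;
    int olt = (ltp == LK_ADJ) ? ltn : ltp;
    int ocap = (ltp == LK_ADJ) ? capn : capp;
    std::vector<int> cand;
    for (int t = 0; t < 6; ++t) {
      int cx = wrapc(s.x[aRef] + DX[t], s.L);
      int cy = wrapc(s.y[aRef] + DY[t], s.L);
      int cz = wrapc(s.z[aRef] + DZ[t], s.L);
      int d1 = mdist1(cx, s.x[oRef], s.L), d2 = mdist1(cy, s.y[oRef], s.L),
          d3 = mdist1(cz, s.z[oRef], s.L);
      bool ok;
      if (olt == LK_ADJ) ok = (d1 + d2 + d3 == 1);
      else {
        int mx = d1; if (d2 > mx) mx = d2; if (d3 > mx) mx = d3;
        ok = (mx <= ocap);
      }
      if (ok) { cand.push_back(cx); cand.push_back(cy); cand.push_back(cz); }
    }
    int nc = (int)cand.size() / 3;
    if (nc == 0) return;
    int j = rint_n(nc);
    finishSingleBeadMove(s, p, b, cand[3 * j], cand[3 * j + 1], cand[3 * j + 2]);
  } else {
    // both constraints are Chebyshev wells: the intersection factorizes
    // per dimension, so sample each dimension uniformly from its offset
    // list (uniform over the product set, identical to full enumeration)
    int nc[3]; int pick[3];
    const std::vector<int>* pc[3] = { &s.x, &s.y, &s.z };
    for (int d = 0; d < 3; ++d) {
      int pv = (*pc[d])[pr], nv = (*pc[d])[nx_];
      int cnt = 0;
      for (int a = -capp; a <= capp; ++a)
        if (mdist1(wrapc(pv + a, s.L), nv, s.L) <= capn) ++cnt;
      if (cnt == 0) return;
      int j = rint_n(cnt);
      int chosen = 0; cnt = 0;
      for (int a = -capp; a <= capp; ++a)
        if (mdist1(wrapc(pv + a, s.L), nv, s.L) <= capn) {
          if (cnt == j) { chosen = wrapc(pv + a, s.L); break; }
          ++cnt;
        }
      nc[d] = cnt; pick[d] = chosen;
    }
    (void)nc;
    finishSingleBeadMove(s, p, b, pick[0], pick[1], pick[2]);
  }
}

static void clusterOf(Sys& s, int m0, std::vector<int>& molsOut) {
  molsOut.clear();
  ++s.stamp;
  std::vector<int> stack; stack.push_back(m0);
  s.molStamp[m0] = s.stamp;
  while (!stack.empty()) {
    int m = stack.back(); stack.pop_back();
    molsOut.push_back(m);
    for (int i = s.molStart[m]; i < s.molEnd[m]; ++i) {
      int pt = s.partner[i];
      if (pt >= 0) {
        int pm = s.mol[pt];
        if (s.molStamp[pm] != s.stamp) { s.molStamp[pm] = s.stamp; stack.push_back(pm); }
      }
    }
  }
}

static void proposeCluster(Sys& s, Prop& p) {
  p.type = M_CLUSTER;
  int m0 = rint_n(s.nm);
  std::vector<int> mols;
  clusterOf(s, m0, mols);
  int t = rint_n(6);
  p.dx = DX[t]; p.dy = DY[t]; p.dz = DZ[t];
  p.clusterBeads.clear();
  for (size_t k = 0; k < mols.size(); ++k)
    for (int i = s.molStart[mols[k]]; i < s.molEnd[mols[k]]; ++i)
      p.clusterBeads.push_back(i);
  // steric check: a target site may hold only a cluster member
  for (size_t k = 0; k < p.clusterBeads.size(); ++k) {
    int i = p.clusterBeads[k];
    int sid = s.site(s.x[i] + p.dx, s.y[i] + p.dy, s.z[i] + p.dz);
    int ob = s.occ[sid];
    if (ob >= 0 && s.molStamp[s.mol[ob]] != s.stamp) return;  // rejection
  }
  p.dE = 0.0; p.w = 1.0;
  p.feasible = true;
}

// Enumerate placements of a (linker beads + domain) segment rooted at an
// anchor bead; links[i] = {type, cap} from the previously placed bead (or the
// anchor) to segment bead i. Placements must be on free sites and
// self-avoiding within the segment. Two passes: countSeg totals the valid
// placements (the terminal link is counted flat, without recursion); pickSeg
// retrieves the j-th placement in the same traversal order, so a uniform j
// yields a uniform placement.

static bool segFree(const Sys& s, int cx, int cy, int cz,
                    const std::vector<int>& cur, size_t li) {
  if (s.occ[s.site(cx, cy, cz)] >= 0) return false;
  for (size_t k = 0; k < li; ++k)
    if (cur[3 * k] == cx && cur[3 * k + 1] == cy && cur[3 * k + 2] == cz)
      return false;
  return true;
}

static long countSeg(const Sys& s, int ax, int ay, int az,
                     const std::vector<std::pair<int,int> >& links, size_t li,
                     std::vector<int>& cur) {
  int lt = links[li].first, cap = links[li].second;
  int px = ax, py = ay, pz = az;
  if (li > 0) {
    size_t base = 3 * (li - 1);
    px = cur[base]; py = cur[base + 1]; pz = cur[base + 2];
  }
  long tot = 0;
  bool terminal = (li + 1 == links.size());
  if (lt == LK_ADJ) {
    for (int t = 0; t < 6; ++t) {
      int cx = wrapc(px + DX[t], s.L), cy = wrapc(py + DY[t], s.L),
          cz = wrapc(pz + DZ[t], s.L);
      if (!segFree(s, cx, cy, cz, cur, li)) continue;
      if (terminal) ++tot;
      else {
        cur.push_back(cx); cur.push_back(cy); cur.push_back(cz);
        tot += countSeg(s, ax, ay, az, links, li + 1, cur);
        cur.pop_back(); cur.pop_back(); cur.pop_back();
      }
    }
  } else {
    for (int a = -cap; a <= cap; ++a)
      for (int b = -cap; b <= cap; ++b)
        for (int c = -cap; c <= cap; ++c) {
          int cx = wrapc(px + a, s.L), cy = wrapc(py + b, s.L),
              cz = wrapc(pz + c, s.L);
          if (!segFree(s, cx, cy, cz, cur, li)) continue;
          if (terminal) ++tot;
          else {
            cur.push_back(cx); cur.push_back(cy); cur.push_back(cz);
            tot += countSeg(s, ax, ay, az, links, li + 1, cur);
            cur.pop_back(); cur.pop_back(); cur.pop_back();
          }
        }
  }
  return tot;
}

// walks the same order as countSeg; decrements j at each terminal leaf and
// fills cur with the j-th placement. Returns true once found.
static bool pickSeg(const Sys& s, int ax, int ay, int az,
                    const std::vector<std::pair<int,int> >& links, size_t li,
                    std::vector<int>& cur, long& j) {
  int lt = links[li].first, cap = links[li].second;
  int px = ax, py = ay, pz = az;
  if (li > 0) {
    size_t base = 3 * (li - 1);
    px = cur[base]; py = cur[base + 1]; pz = cur[base + 2];
  }
  bool terminal = (li + 1 == links.size());
  auto visit = [&](int cx, int cy, int cz) -> bool {
    if (!segFree(s, cx, cy, cz, cur, li)) return false;
    if (terminal) {
      if (j == 0) {
        cur.push_back(cx); cur.push_back(cy); cur.push_back(cz);
        return true;
      }
      --j;
      return false;
    }
    cur.push_back(cx); cur.push_back(cy); cur.push_back(cz);
    if (pickSeg(s, ax, ay, az, links, li + 1, cur, j)) return true;
    cur.pop_back(); cur.pop_back(); cur.pop_back();
    return false;
  };
  if (lt == LK_ADJ) {
    for (int t = 0; t < 6; ++t)
      if (visit(wrapc(px + DX[t], s.L), wrapc(py + DY[t], s.L),
                wrapc(pz + DZ[t], s.L))) return true;
  } else {
    for (int a = -cap; a <= cap; ++a)
      for (int b = -cap; b <= cap; ++b)
        for (int c = -cap; c <= cap; ++c)
          if (visit(wrapc(px + a, s.L), wrapc(py + b, s.L),
                    wrapc(pz + c, s.L))) return true;
  }
  return false;
}

static void segLinks(int n, int e, bool outwardFromDomainSide,
                     std::vector<std::pair<int,int> >& links) {
  // outwardFromDomainSide: anchor is the linker's upstream domain, beads
  // enumerate as L1..Le then the domain (ADJ chain then terminal link).
  // Otherwise the anchor sits on the far side: terminal link first, beads
  // enumerate as Le..L1 then the domain.
  links.clear();
  std::pair<int,int> terminal = (e == n) ? std::make_pair((int)LK_ADJ, 0)
                                         : std::make_pair((int)LK_CHEB, n - e);
  if (outwardFromDomainSide) {
    for (int k = 0; k < e; ++k) links.push_back(std::make_pair((int)LK_ADJ, 0));
    links.push_back(terminal);
  } else {
    links.push_back(terminal);
    for (int k = 0; k < e; ++k) links.push_back(std::make_pair((int)LK_ADJ, 0));
  }
}

static void proposeRept(Sys& s, Prop& p) {
  p.type = M_REPT;
  if (s.reptMols.empty()) return;
  int m = s.reptMols[rint_n((int)s.reptMols.size())];
  int n = s.molLinkN[m], e = s.molLinkE[m];
  int seg = 1 + e;
  int st = s.molStart[m], en = s.molEnd[m];
  bool fromHead = (unif_rand() < 0.5);
  p.rmol = m; p.fromHead = fromHead; p.segLen = seg;

  int dOld, anchorOldSide, anchorNewSide;
  if (fromHead) {
    dOld = st;                 // removed end domain
    anchorOldSide = st + seg;  // first remaining domain
    anchorNewSide = en - 1;    // append after the tail domain
  } else {
    dOld = en - 1;
    anchorOldSide = en - 1 - seg;
    anchorNewSide = st;
  }
  // detach the moving domain's bond and vacate the old segment
  int op = s.partner[dOld];
  p.oldPartner = op;
  if (op >= 0) { s.partner[op] = -1; s.partner[dOld] = -1; }
  int segLo = fromHead ? st : en - seg;
  std::vector<int> oldSites(seg);
  for (int k = 0; k < seg; ++k) {
    int i = segLo + k;
    oldSites[k] = s.site(s.x[i], s.y[i], s.z[i]);
    s.occ[oldSites[k]] = -1;
  }

  long Vp = 0, Vc = 0;
  if (e == 0) {
    // single implicit link: count free sites in the Chebyshev cube
    // around each anchor with flat loops (no placement collection)
    auto countCube = [&](int ab) {
      long c = 0;
      for (int a = -n; a <= n; ++a)
        for (int bb = -n; bb <= n; ++bb)
          for (int cc = -n; cc <= n; ++cc)
            if (s.occ[s.site(s.x[ab] + a, s.y[ab] + bb, s.z[ab] + cc)] < 0) ++c;
      return c;
    };
    Vp = countCube(anchorNewSide);
    if (Vp == 0) {
      for (int k = 0; k < seg; ++k) s.occ[oldSites[k]] = segLo + k;
      if (op >= 0) { s.partner[op] = dOld; s.partner[dOld] = op; }
      return;
    }
    Vc = countCube(anchorOldSide);
    long j = (long)(unif_rand() * Vp); if (j >= Vp) j = Vp - 1;
    long c = 0; int fx = 0, fy = 0, fz = 0; bool found = false;
    for (int a = -n; a <= n && !found; ++a)
      for (int bb = -n; bb <= n && !found; ++bb)
        for (int cc = -n; cc <= n && !found; ++cc) {
          int sx = wrapc(s.x[anchorNewSide] + a, s.L);
          int sy = wrapc(s.y[anchorNewSide] + bb, s.L);
          int sz = wrapc(s.z[anchorNewSide] + cc, s.L);
          if (s.occ[s.site(sx, sy, sz)] < 0) {
            if (c == j) { fx = sx; fy = sy; fz = sz; found = true; }
            ++c;
          }
        }
    p.segPos.assign(3, 0);
    p.segPos[0] = fx; p.segPos[1] = fy; p.segPos[2] = fz;
  } else {
    std::vector<std::pair<int,int> > linksNew, linksOld;
    // new end: appending at tail enumerates from the upstream domain
    // outward; appending at head enumerates inward (terminal link first)
    segLinks(n, e, fromHead, linksNew);
    segLinks(n, e, !fromHead, linksOld);
    std::vector<int> cur; cur.reserve(3 * (size_t)seg);
    Vp = countSeg(s, s.x[anchorNewSide], s.y[anchorNewSide],
                  s.z[anchorNewSide], linksNew, 0, cur);
    if (Vp == 0) {
      // restore and reject
      for (int k = 0; k < seg; ++k) s.occ[oldSites[k]] = segLo + k;
      if (op >= 0) { s.partner[op] = dOld; s.partner[dOld] = op; }
      return;
    }
    Vc = countSeg(s, s.x[anchorOldSide], s.y[anchorOldSide],
                  s.z[anchorOldSide], linksOld, 0, cur);
    // Vc >= 1 always: the current placement is one of the enumerated ones
    long j = (long)(unif_rand() * Vp); if (j >= Vp) j = Vp - 1;
    cur.clear();
    pickSeg(s, s.x[anchorNewSide], s.y[anchorNewSide], s.z[anchorNewSide],
            linksNew, 0, cur, j);
    p.segPos = cur;
  }
  // binding states of the moved domain at old and new positions
  int ndx = p.segPos[3 * (seg - 1)], ndy = p.segPos[3 * (seg - 1) + 1],
      ndz = p.segPos[3 * (seg - 1) + 2];
  std::vector<int> candC, candP;
  bindCandidates(s, dOld, s.kind[dOld], s.x[dOld], s.y[dOld], s.z[dOld], candC);
  bindCandidates(s, dOld, s.kind[dOld], ndx, ndy, ndz, candP);
  p.Nc = 1 + (int)candC.size();
  p.Np = 1 + (int)candP.size();
  int jj = rint_n(p.Np);
  p.newPartner = (jj == 0) ? -1 : candP[jj - 1];
  p.Vc = (double)Vc; p.Vp = (double)Vp;
  p.dE = s.bondE(p.newPartner) - s.bondE(op);
  p.w = ((double)p.Np * p.Vp) / ((double)p.Nc * p.Vc);
  p.bead = dOld;
  // restore state (propose must not mutate)
  for (int k = 0; k < seg; ++k) s.occ[oldSites[k]] = segLo + k;
  if (op >= 0) { s.partner[op] = dOld; s.partner[dOld] = op; }
  p.feasible = true;
}

static void applyProp(Sys& s, const Prop& p) {
  switch (p.type) {
  case M_FLIP: {
    int d = p.bead;
    if (p.oldPartner >= 0) s.partner[p.oldPartner] = -1;
    s.partner[d] = p.newPartner;
    if (p.newPartner >= 0) s.partner[p.newPartner] = d;
    break;
  }
  case M_PIVOT:
  case M_CRANK: {
    int b = p.bead;
    s.occ[s.site(p.ox, p.oy, p.oz)] = -1;
    s.x[b] = p.nx; s.y[b] = p.ny; s.z[b] = p.nz;
    s.occ[s.site(p.nx, p.ny, p.nz)] = b;
    if (s.kind[b] != K_L) {
      if (p.oldPartner >= 0) s.partner[p.oldPartner] = -1;
      s.partner[b] = p.newPartner;
      if (p.newPartner >= 0) s.partner[p.newPartner] = b;
    }
    break;
  }
  case M_CLUSTER: {
    for (size_t k = 0; k < p.clusterBeads.size(); ++k) {
      int i = p.clusterBeads[k];
      s.occ[s.site(s.x[i], s.y[i], s.z[i])] = -1;
    }
    for (size_t k = 0; k < p.clusterBeads.size(); ++k) {
      int i = p.clusterBeads[k];
      s.x[i] = wrapc(s.x[i] + p.dx, s.L);
      s.y[i] = wrapc(s.y[i] + p.dy, s.L);
      s.z[i] = wrapc(s.z[i] + p.dz, s.L);
      s.occ[s.site(s.x[i], s.y[i], s.z[i])] = i;
    }
    break;
  }
  case M_REPT: {
    int m = p.rmol, seg = p.segLen;
    int st = s.molStart[m], en = s.molEnd[m];
    int dOld = p.fromHead ? st : en - 1;
    if (p.oldPartner >= 0) { s.partner[p.oldPartner] = -1; s.partner[dOld] = -1; }
    int segLo = p.fromHead ? st : en - seg;
    for (int k = 0; k < seg; ++k) {
      int i = segLo + k;
      s.occ[s.site(s.x[i], s.y[i], s.z[i])] = -1;
    }
    // shift the surviving block, remapping bond indices
    int nshift = (en - st) - seg;
    std::vector<int> bx(nshift), by(nshift), bz(nshift), bp(nshift);
    int blockLo = p.fromHead ? st + seg : st;
    for (int k = 0; k < nshift; ++k) {
      int i = blockLo + k;
      bx[k] = s.x[i]; by[k] = s.y[i]; bz[k] = s.z[i]; bp[k] = s.partner[i];
    }
    int newLo = p.fromHead ? st : st + seg;
    int shift = newLo - blockLo;  // -seg (head removal) or +seg (tail removal)
    for (int k = 0; k < nshift; ++k) {
      int ni = newLo + k;
      s.x[ni] = bx[k]; s.y[ni] = by[k]; s.z[ni] = bz[k];
      s.occ[s.site(bx[k], by[k], bz[k])] = ni;
      int pp = bp[k];
      if (pp >= blockLo && pp < blockLo + nshift) {
        s.partner[ni] = pp + shift;
      } else {
        s.partner[ni] = pp;
        if (pp >= 0) s.partner[pp] = ni;
      }
    }
    // install the new segment; enumeration order holds the domain last
    int newSegLo = p.fromHead ? en - seg : st;
    for (int k = 0; k < seg; ++k) {
      // memory order: appended-at-tail = enumeration order (L1..Le, D);
      // appended-at-head = (D, L1..Le) with enumeration (Le..L1, D)
      int memIdx, enuIdx;
      if (p.fromHead) { memIdx = newSegLo + k; enuIdx = k; }
      else {
        if (k == 0) { memIdx = newSegLo; enuIdx = seg - 1; }      // domain
        else { memIdx = newSegLo + k; enuIdx = seg - 1 - k; }     // L_k
      }
      s.x[memIdx] = p.segPos[3 * enuIdx];
      s.y[memIdx] = p.segPos[3 * enuIdx + 1];
      s.z[memIdx] = p.segPos[3 * enuIdx + 2];
      s.partner[memIdx] = -1;
      s.occ[s.site(s.x[memIdx], s.y[memIdx], s.z[memIdx])] = memIdx;
    }
    int dNew = p.fromHead ? en - 1 : st;
    s.partner[dNew] = p.newPartner;
    if (p.newPartner >= 0) s.partner[p.newPartner] = dNew;
    break;
  }
  }
  s.E += p.dE;
}

// largest bound cluster of molecules (intermolecular bonds define edges)
static double phiLargest(Sys& s, int* nnOut) {
  ++s.stamp;
  int best = 0;
  std::vector<int> stack;
  for (int m0 = 0; m0 < s.nm; ++m0) {
    if (s.molStamp[m0] == s.stamp) continue;
    int sz = 0;
    stack.clear(); stack.push_back(m0); s.molStamp[m0] = s.stamp;
    while (!stack.empty()) {
      int m = stack.back(); stack.pop_back();
      ++sz;
      for (int i = s.molStart[m]; i < s.molEnd[m]; ++i) {
        int pt = s.partner[i];
        if (pt >= 0) {
          int pm = s.mol[pt];
          if (pm != m && s.molStamp[pm] != s.stamp) {
            s.molStamp[pm] = s.stamp; stack.push_back(pm);
          }
        }
      }
    }
    if (sz > best) best = sz;
  }
  if (nnOut) *nnOut = best;
  return (double)best / (double)s.nm;
}

// radius of gyration over all beads with a circular-mean center of mass, so
// droplets spanning the periodic boundary are measured correctly
static double rgBeads(const Sys& s) {
  const double twopi = 2.0 * M_PI;
  double com[3];
  const std::vector<int>* cc[3] = { &s.x, &s.y, &s.z };
  for (int d = 0; d < 3; ++d) {
    double C = 0, S = 0;
    for (int i = 0; i < s.nb; ++i) {
      double th = twopi * (*cc[d])[i] / s.L;
      C += std::cos(th); S += std::sin(th);
    }
    com[d] = std::atan2(S, C) * s.L / twopi;
  }
  double acc = 0;
  for (int i = 0; i < s.nb; ++i) {
    double dd[3] = { s.x[i] - com[0], s.y[i] - com[1], s.z[i] - com[2] };
    for (int d = 0; d < 3; ++d) {
      while (dd[d] > s.L / 2.0) dd[d] -= s.L;
      while (dd[d] < -s.L / 2.0) dd[d] += s.L;
      acc += dd[d] * dd[d];
    }
  }
  return std::sqrt(acc / s.nb);
}

static double energyFromScratch(const Sys& s) {
  double E = 0;
  for (int i = 0; i < s.nb; ++i)
    if (s.partner[i] > i) E += s.uSP;
  return E;
}

static void proposeByType(Sys& s, int type, Prop& p) {
  switch (type) {
  case M_FLIP: proposeFlip(s, p); break;
  case M_PIVOT: proposePivot(s, p); break;
  case M_CRANK: proposeCrank(s, p); break;
  case M_CLUSTER: proposeCluster(s, p); break;
  case M_REPT: proposeRept(s, p); break;
  default: stop("unknown move type");
  }
}

// [[Rcpp::export]]
List cpp_run_mc(List state, double nSteps, NumericVector moveWeights,
                int sampleStride, bool keepFrames) {
  Sys s = buildSys(state);
  if (moveWeights.size() != 5) stop("moveWeights must have length 5");
  double wsum = 0;
  double cw[5];
  bool applicable[5] = {
    !s.domains.empty(), !s.endBeads.empty(), !s.interiorBeads.empty(),
    s.nm > 0, !s.reptMols.empty()
  };
  for (int t = 0; t < 5; ++t) {
    double wt = (applicable[t] ? moveWeights[t] : 0.0);
    wsum += wt;
    cw[t] = wsum;
  }
  if (wsum <= 0) stop("no applicable move type has positive weight");

  long long NS = (long long)nSteps;
  int nsamp = (sampleStride > 0) ? (int)(NS / sampleStride) : 0;
  NumericVector sStep(nsamp), sE(nsamp), sPhi(nsamp), sRho(nsamp), sRg(nsamp);
  IntegerVector sNN(nsamp);
  List frames(keepFrames ? nsamp : 0);
  double Rlat = std::sqrt(3.0 * (s.L * (double)s.L - 1.0) / 12.0);
  std::vector<long long> attempts(5, 0), accepts(5, 0);

  Prop p;
  int isamp = 0;
  for (long long step = 1; step <= NS; ++step) {
    double u = unif_rand() * wsum;
    int type = 0;
    while (type < 4 && u > cw[type]) ++type;
    ++attempts[type];
    p = Prop();
    proposeByType(s, type, p);
    if (p.feasible) {
      bool acc;
      double arg = p.w * std::exp(-p.dE);
      if (arg >= 1.0) acc = true;
      else acc = (unif_rand() < arg);
      if (acc) { applyProp(s, p); ++accepts[type]; }
    }
    if (sampleStride > 0 && step % sampleStride == 0 && isamp < nsamp) {
      int nn = 0;
      double phi = phiLargest(s, &nn);
      double rg = (s.nb > 1) ? rgBeads(s) : 0.0;
      sStep[isamp] = (double)step;
      sE[isamp] = s.E;
      sPhi[isamp] = phi;
      sNN[isamp] = nn;
      sRg[isamp] = rg;
      sRho[isamp] = (rg > 0) ? Rlat / rg : NA_REAL;
      if (keepFrames) {
        IntegerMatrix fr(s.nb, 4);
        for (int i = 0; i < s.nb; ++i) {
          fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i];
          fr(i, 3) = s.partner[i];
        }
        frames[isamp] = fr;
      }
      ++isamp;
    }
  }

  IntegerMatrix coords(s.nb, 3);
  IntegerVector partner(s.nb);
  for (int i = 0; i < s.nb; ++i) {
    coords(i, 0) = s.x[i]; coords(i, 1) = s.y[i]; coords(i, 2) = s.z[i];
    partner[i] = s.partner[i];
  }
  NumericMatrix acc(5, 2);
  for (int t = 0; t < 5; ++t) { acc(t, 0) = (double)attempts[t]; acc(t, 1) = (double)accepts[t]; }
  return List::create(
    _["coords"] = coords, _["partner"] = partner,
    _["energy"] = s.E, _["energyCheck"] = energyFromScratch(s),
    _["samples"] = DataFrame::create(
      _["step"] = sStep, _["energy"] = sE, _["phiC"] = sPhi, _["NN"] = sNN,
      _["Rg"] = sRg, _["rho"] = sRho),
    _["acceptance"] = acc,
    _["frames"] = frames);
}

// [[Rcpp::export]]
List cpp_propose(List state, int moveType) {
  Sys s = buildSys(state);
  Prop p;
  proposeByType(s, moveType, p);
  IntegerMatrix segPos(0, 3);
  if (p.type == M_REPT && p.feasible) {
    segPos = IntegerMatrix(p.segLen, 3);
    for (int k = 0; k < p.segLen; ++k)
      for (int d = 0; d < 3; ++d) segPos(k, d) = p.segPos[3 * k + d];
  }
  IntegerVector cl(p.clusterBeads.begin(), p.clusterBeads.end());
  return List::create(
    _["type"] = p.type, _["feasible"] = p.feasible,
    _["dE"] = p.dE, _["w"] = p.w,
    _["Nc"] = p.Nc, _["Np"] = p.Np, _["Vc"] = p.Vc, _["Vp"] = p.Vp,
    _["bead"] = p.bead, _["oldPartner"] = p.oldPartner,
    _["newPartner"] = p.newPartner,
    _["oldPos"] = IntegerVector::create(p.ox, p.oy, p.oz),
    _["newPos"] = IntegerVector::create(p.nx, p.ny, p.nz),
    _["clusterBeads"] = cl,
    _["delta"] = IntegerVector::create(p.dx, p.dy, p.dz),
    _["mol"] = p.rmol, _["fromHead"] = p.fromHead, _["segLen"] = p.segLen,
    _["segPos"] = segPos);
}

// [[Rcpp::export]]
List cpp_cluster_stats(List state) {
  Sys s = buildSys(state);
  int nn = 0;
  double phi = phiLargest(s, &nn);
  double rg = (s.nb > 1) ? rgBeads(s) : 0.0;
  double Rlat = std::sqrt(3.0 * (s.L * (double)s.L - 1.0) / 12.0);
  return List::create(_["phiC"] = phi, _["NN"] = nn, _["Rg"] = rg,
                      _["rho"] = (rg > 0) ? Rlat / rg : NA_REAL);
}
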