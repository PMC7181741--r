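// Coalescent-with-recombination engine (Hudson ARG, event driven).
//
// Demography (backwards in time, all rates per generation, Ne diploid):
//   pop 0 = Papuan-side source panel (e.g. "Gidra")
//   pop 1 = Asian-side source panel  (e.g. "CHB")
//   pop 2 = admixed deme             (e.g. "Munda")
//   pop 3 = optional outgroup
//   pop 4 = optional Asian-source sister deme (F4-ratio source proxy)
//   at t_adm  every pop-2 lineage moves to pop 0 w.p. m_papuan else pop 1
//   at t_ap   pop 4 merges into pop 1 (only if n_ap > 0; default t_adm)
//   at t_div  pop 1 merges into pop 0
//   at t_out  pop 3 merges into pop 0 (only if n_out > 0)
//
// Lineages carry their ancestral material as disjoint segments, each with a
// bitset of descendant samples.  Segments whose descendant set reaches the
// full sample are at their MRCA and are discarded.  Mutations are dropped on
// the fly: between events the total ancestral length is exposed for time dt,
// so the mutation count is Poisson(mu * totLen * dt) and each mutation lands
// uniformly on the live material, inheriting that segment's descendant set.
// Uses R's RNG, so set.seed() on the R side gives full reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;                 // [l, r) in bp, continuous
  std::vector<uint64_t> d;     // descendant bitset
};

struct Lin {
  int pop;
  std::vector<Seg> segs;       // disjoint, sorted by l
};

struct Mut {
  double pos;
  std::vector<uint64_t> d;
};

struct DemEvent {
  double time;
  int kind;   // 0 = pulse, 1 = merge pop1->0, 2 = merge pop3->0, 3 = merge pop4->1
};

struct Tract {                 // true ancestry of admixed material at the pulse
  int hap;                     // admixed haplotype index (0-based within pop 2)
  double l, r;
  int anc;                     // 1 = Papuan side, 0 = Asian side
};

inline double matLen(const Lin& L) {
  double s = 0;
  for (const Seg& g : L.segs) s += g.r - g.l;
  return s;
}

inline double spanOf(const Lin& L) {
  if (L.segs.empty()) return 0.0;
  return L.segs.back().r - L.segs.front().l;
}

inline bool isFull(const std::vector<uint64_t>& d, const std::vector<uint64_t>& full,
                   int nW) {
  for (int w = 0; w < nW; ++w)
    if (d[w] != full[w]) return false;
  return true;
}

// merge the segment lists of two coalescing lineages; overlapping material
// unions its descendant sets, and fully-coalesced pieces are dropped
std::vector<Seg> mergeSegs(std::vector<Seg> A, std::vector<Seg> B,
                           const std::vector<uint64_t>& full, int nW) {
  std::vector<Seg> out;
  out.reserve(A.size() + B.size());
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    Seg& a = A[i];
    Seg& b = B[j];
    if (a.r <= b.l) { out.push_back(a); ++i; continue; }
    if (b.r <= a.l) { out.push_back(b); ++j; continue; }
    if (a.l < b.l) { out.push_back(Seg{a.l, b.l, a.d}); a.l = b.l; }
    else if (b.l < a.l) { out.push_back(Seg{b.l, a.l, b.d}); b.l = a.l; }
    double r = std::min(a.r, b.r);
    Seg m;
    m.l = a.l; m.r = r;
    m.d.resize(nW);
    for (int w = 0; w < nW; ++w) m.d[w] = a.d[w] | b.d[w];
    if (!isFull(m.d, full, nW)) out.push_back(std::move(m));
    if (a.r == r && b.r == r) { ++i; ++j; }
    else if (a.r == r) { ++i; b.l = r; }
    else { ++j; a.l = r; }
  }
  while (i < A.size()) out.push_back(A[i++]);
  while (j < B.size()) out.push_back(B[j++]);
  // compact adjacent pieces with identical descendants
  std::vector<Seg> cmp;
  cmp.reserve(out.size());
  for (Seg& s : out) {
    if (!cmp.empty() && cmp.back().r == s.l && cmp.back().d == s.d)
      cmp.back().r = s.r;
    else
      cmp.push_back(std::move(s));
  }
  return cmp;
}

} // namespace

// [[Rcpp::export(name = ".sim_window_cpp")]]
List sim_window_cpp(double L, double Ne, double mu, double rec,
                    double t_adm, double m_papuan, double t_div,
                    int n_p, int n_adm, int n_a,
                    int n_out, double t_out,
                    int n_ap, double t_ap) {
  const int nSamp = n_p + n_adm + n_a + n_out + n_ap;
  if (nSamp < 2) stop("need at least two sampled chromosomes");
  const int nW = (nSamp + 63) / 64;

  std::vector<uint64_t> full(nW, 0);
  for (int s = 0; s < nSamp; ++s) full[s / 64] |= (uint64_t(1) << (s % 64));

  // sample layout: [0, n_p) pop0, [n_p, n_p+n_adm) pop2, then pop1, then pop3
  std::vector<Lin> live;
  live.reserve(2 * nSamp);
  for (int s = 0; s < nSamp; ++s) {
    Lin l;
    if (s < n_p) l.pop = 0;
    else if (s < n_p + n_adm) l.pop = 2;
    else if (s < n_p + n_adm + n_a) l.pop = 1;
    else if (s < n_p + n_adm + n_a + n_out) l.pop = 3;
    else l.pop = 4;
    Seg g;
    g.l = 0.0; g.r = L;
    g.d.assign(nW, 0);
    g.d[s / 64] |= (uint64_t(1) << (s % 64));
    l.segs.push_back(std::move(g));
    live.push_back(std::move(l));
  }

  std::vector<DemEvent> evs;
  if (n_adm > 0) evs.push_back(DemEvent{t_adm, 0});
  evs.push_back(DemEvent{t_div, 1});
  if (n_out > 0) evs.push_back(DemEvent{t_out, 2});
  if (n_ap > 0) evs.push_back(DemEvent{t_ap, 3});
  std::sort(evs.begin(), evs.end(),
            [](const DemEvent& a, const DemEvent& b) { return a.time < b.time; });
  size_t nextEv = 0;

  double totLen = double(nSamp) * L;
  std::vector<Mut> muts;
  std::vector<Tract> tracts;

  auto dropMuts = [&](double dt) {
    if (mu <= 0 || totLen <= 0 || dt <= 0) return;
    int K = (int) R::rpois(mu * totLen * dt);
    for (int k = 0; k < K; ++k) {
      double target = R::runif(0.0, totLen);
      double cum = 0;
      bool placed = false;
      for (const Lin& l : live) {
        for (const Seg& g : l.segs) {
          double len = g.r - g.l;
          if (target <= cum + len) {
            muts.push_back(Mut{g.l + (target - cum), g.d});
            placed = true;
            break;
          }
          cum += len;
        }
        if (placed) break;
      }
      if (!placed && !live.empty() && !live.back().segs.empty()) {
        const Seg& g = live.back().segs.back();
        muts.push_back(Mut{g.r - 1e-9, g.d});
      }
    }
  };

  double t = 0.0;
  const long maxIter = 50000000L;
  long iter = 0;

  while (!live.empty()) {
    if (++iter > maxIter) stop("coalescent simulation exceeded the event budget");

    // apply any demographic event already due (handles t == event time, t 0)
    int k[5] = {0, 0, 0, 0, 0};
    for (const Lin& l : live) ++k[l.pop];

    double coalRate = 0;
    for (int p = 0; p < 5; ++p)
      coalRate += double(k[p]) * (k[p] - 1) / 2.0 / (2.0 * Ne);
    double spanSum = 0;
    for (const Lin& l : live) spanSum += spanOf(l);
    double recRate = rec * spanSum;
    double tot = coalRate + recRate;

    double dt = (tot > 0) ? R::rexp(1.0 / tot) : R_PosInf;

    if (nextEv < evs.size() && t + dt >= evs[nextEv].time) {
      double f = evs[nextEv].time;
      if (f > t) { dropMuts(f - t); t = f; }
      int kind = evs[nextEv].kind;
      ++nextEv;
      if (kind == 0) {
        for (Lin& l : live)
          if (l.pop == 2) {
            int dest = (R::unif_rand() < m_papuan) ? 0 : 1;
            // record the true ancestry of every admixed sample's material
            // carried by this lineage (pre-pulse, only pop-2 samples can be
            // in its descendant sets)
            for (const Seg& g : l.segs)
              for (int s = n_p; s < n_p + n_adm; ++s)
                if ((g.d[s / 64] >> (s % 64)) & 1)
                  tracts.push_back(Tract{s - n_p, g.l, g.r,
                                         dest == 0 ? 1 : 0});
            l.pop = dest;
          }
      } else if (kind == 1) {
        for (Lin& l : live) if (l.pop == 1) l.pop = 0;
      } else if (kind == 2) {
        for (Lin& l : live) if (l.pop == 3) l.pop = 0;
      } else {
        for (Lin& l : live) if (l.pop == 4) l.pop = 1;
      }
      continue;
    }
    if (!R_FINITE(dt)) stop("no events possible but lineages remain");

    dropMuts(dt);
    t += dt;

    if (R::unif_rand() * tot < coalRate) {
      // coalescence: choose population proportional to k(k-1)
      double u = R::unif_rand() * coalRate;
      int pop = 0;
      for (int p = 0; p < 5; ++p) {
        double rp = double(k[p]) * (k[p] - 1) / 2.0 / (2.0 * Ne);
        if (u < rp) { pop = p; break; }
        u -= rp;
      }
      std::vector<int> idx;
      for (int i = 0; i < (int) live.size(); ++i)
        if (live[i].pop == pop) idx.push_back(i);
      int ia = (int) std::floor(R::runif(0, idx.size()));
      int ib = (int) std::floor(R::runif(0, idx.size() - 1));
      if (ia >= (int) idx.size()) ia = idx.size() - 1;
      if (ib >= ia) ++ib;
      int i1 = idx[ia], i2 = idx[ib];
      double oldLen = matLen(live[i1]) + matLen(live[i2]);
      Lin merged;
      merged.pop = pop;
      merged.segs = mergeSegs(std::move(live[i1].segs), std::move(live[i2].segs),
                              full, nW);
      totLen += matLen(merged) - oldLen;
      if (i1 > i2) std::swap(i1, i2);
      live.erase(live.begin() + i2);
      live.erase(live.begin() + i1);
      if (!merged.segs.empty()) live.push_back(std::move(merged));
    } else {
      // recombination: choose lineage proportional to its breakable span
      double u = R::unif_rand() * spanSum;
      int li = -1;
      for (int i = 0; i < (int) live.size(); ++i) {
        double sp = spanOf(live[i]);
        if (u < sp) { li = i; break; }
        u -= sp;
      }
      if (li < 0) continue;
      Lin& l = live[li];
      double lo = l.segs.front().l, hi = l.segs.back().r;
      double bp = R::runif(lo, hi);
      Lin left, right;
      left.pop = right.pop = l.pop;
      for (Seg& g : l.segs) {
        if (g.r <= bp) left.segs.push_back(std::move(g));
        else if (g.l >= bp) right.segs.push_back(std::move(g));
        else {
          left.segs.push_back(Seg{g.l, bp, g.d});
          right.segs.push_back(Seg{bp, g.r, std::move(g.d)});
        }
      }
      if (left.segs.empty() || right.segs.empty()) {
        // breakpoint landed on a segment boundary gap edge: no-op
        Lin whole;
        whole.pop = l.pop;
        for (Seg& g : left.segs) whole.segs.push_back(std::move(g));
        for (Seg& g : right.segs) whole.segs.push_back(std::move(g));
        live[li] = std::move(whole);
      } else {
        live[li] = std::move(left);
        live.push_back(std::move(right));
      }
    }
  }

  // assemble sites, collapsing duplicate integer positions
  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  std::vector<int> keep;
  std::vector<int> posOut;
  int lastPos = -1;
  for (int i = 0; i < (int) muts.size(); ++i) {
    int ip = (int) std::floor(muts[i].pos) + 1;
    if (ip < 1) ip = 1;
    if (ip > (int) L) ip = (int) L;
    if (ip == lastPos) continue;
    keep.push_back(i);
    posOut.push_back(ip);
    lastPos = ip;
  }
  int S = (int) keep.size();
  IntegerMatrix H(nSamp, S);
  for (int j = 0; j < S; ++j) {
    const std::vector<uint64_t>& d = muts[keep[j]].d;
    for (int s = 0; s < nSamp; ++s)
      H(s, j) = (d[s / 64] >> (s % 64)) & 1;
  }
  int nT = (int) tracts.size();
  IntegerVector tHap(nT), tAnc(nT);
  NumericVector tL(nT), tR(nT);
  for (int i = 0; i < nT; ++i) {
    tHap[i] = tracts[i].hap + 1;
    tAnc[i] = tracts[i].anc;
    tL[i] = tracts[i].l;
    tR[i] = tracts[i].r;
  }
  return List::create(_["positions"] = wrap(posOut), _["haplotypes"] = H,
                      _["tractHap"] = tHap, _["tractL"] = tL,
                      _["tractR"] = tR, _["tractAnc"] = tAnc);
}
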