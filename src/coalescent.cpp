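// Structured coalescent with recombination, exponential growth, migration and
// timed demographic events, parameterized in ms/msms units:
//   time in 4*N_ref generations; deme sizes relative to N_ref;
//   growth alpha such that x_i(t) = x_i(t0) * exp(-alpha * (t - t0));
//   migration M[i][j] = 4*N_ref*m_ij (per-lineage backward rate i -> j);
//   theta = 4*N_ref*mu*L, rho = 4*N_ref*r*L for the whole locus, mapped
//   to the unit interval [0,1).
// Ancestral material is tracked per lineage as half-open segments, each
// carrying the bit set of descendant samples; segments reaching the full
// sample (local MRCA) are retired.  Mutations follow the infinite-sites
// model and are dropped on lineages continuously in time.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

static inline int popcount_bits(const Bits& b) {
  int c = 0;
  for (uint64_t w : b) c += __builtin_popcountll(w);
  return c;
}

struct Seg {
  double l, r;   // [l, r) on [0,1)
  Bits b;
  int cnt;       // cached popcount of b
};

struct Lin {
  int pop;
  std::vector<Seg> segs;
  double len() const {
    double s = 0;
    for (const Seg& sg : segs) s += sg.r - sg.l;
    return s;
  }
  double span() const {
    if (segs.empty()) return 0.0;
    return segs.back().r - segs.front().l;
  }
};

struct Mut {
  double pos;
  Bits b;
};

struct DemEvent {
  double time;
  int type;   // 1=join(i->j) 2=size(i,x; growth reset) 3=growth(i,x) 4=mig(i,j,x)
  int i, j;
  double x;
};

// Merge two sorted segment lists; segments whose union covers all n samples
// are retired (local MRCA reached).  Adjacent segments with identical bit
// sets are compacted.
static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B,
                                   int n) {
  std::vector<double> cuts;
  cuts.reserve(2 * (A.size() + B.size()));
  for (const Seg& s : A) { cuts.push_back(s.l); cuts.push_back(s.r); }
  for (const Seg& s : B) { cuts.push_back(s.l); cuts.push_back(s.r); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());

  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t k = 0; k + 1 < cuts.size(); ++k) {
    double l = cuts[k], r = cuts[k + 1];
    double mid = 0.5 * (l + r);
    while (ia < A.size() && A[ia].r <= mid) ++ia;
    while (ib < B.size() && B[ib].r <= mid) ++ib;
    bool inA = ia < A.size() && A[ia].l <= mid && mid < A[ia].r;
    bool inB = ib < B.size() && B[ib].l <= mid && mid < B[ib].r;
    if (!inA && !inB) continue;
    Seg ns;
    ns.l = l; ns.r = r;
    if (inA && inB) {
      ns.b = A[ia].b;
      for (size_t w = 0; w < ns.b.size(); ++w) ns.b[w] |= B[ib].b[w];
      ns.cnt = popcount_bits(ns.b);
      if (ns.cnt >= n) continue;  // reached MRCA here
    } else if (inA) {
      ns.b = A[ia].b; ns.cnt = A[ia].cnt;
    } else {
      ns.b = B[ib].b; ns.cnt = B[ib].cnt;
    }
    if (!out.empty() && out.back().r == ns.l && out.back().b == ns.b) {
      out.back().r = ns.r;
    } else {
      out.push_back(std::move(ns));
    }
  }
  return out;
}

static void drop_mutations(std::vector<Lin>& lins, double dt, double theta,
                           std::vector<Mut>& muts) {
  if (theta <= 0 || dt <= 0) return;
  for (const Lin& ln : lins) {
    double len = ln.len();
    if (len <= 0) continue;
    int m = (int) R::rpois(theta * dt * len);
    for (int k = 0; k < m; ++k) {
      double u = unif_rand() * len;
      double acc = 0;
      for (const Seg& sg : ln.segs) {
        double w = sg.r - sg.l;
        if (u < acc + w) {
          Mut mu;
          mu.pos = sg.l + (u - acc);
          mu.b = sg.b;
          muts.push_back(std::move(mu));
          break;
        }
        acc += w;
      }
    }
  }
}

// One replicate; returns mutations (positions + carrier bit sets).
static void sim_one(const std::vector<int>& nsam, double theta, double rho,
                    std::vector<double> xset, std::vector<double> alpha,
                    std::vector<std::vector<double> > M,
                    const std::vector<DemEvent>& events,
                    std::vector<Mut>& muts) {
  int npop = (int) nsam.size();
  int n = 0;
  for (int s : nsam) n += s;
  int nb = (n + 63) / 64;

  std::vector<Lin> lins;
  lins.reserve(2 * n);
  int id = 0;
  for (int p = 0; p < npop; ++p) {
    for (int s = 0; s < nsam[p]; ++s, ++id) {
      Lin ln;
      ln.pop = p;
      Seg sg;
      sg.l = 0.0; sg.r = 1.0;
      sg.b.assign(nb, 0);
      sg.b[id / 64] |= (uint64_t)1 << (id % 64);
      sg.cnt = 1;
      ln.segs.push_back(std::move(sg));
      lins.push_back(std::move(ln));
    }
  }

  double t = 0.0;
  std::vector<double> tset(npop, 0.0);
  size_t ev = 0;
  long iter = 0;

  while (!lins.empty()) {
    if (++iter % 4096 == 0) Rcpp::checkUserInterrupt();
    if (iter > 100000000L) Rcpp::stop("coalescent simulation exceeded event budget");

    std::vector<int> k(npop, 0);
    for (const Lin& ln : lins) k[ln.pop]++;

    // coalescence proposals (growth-aware closed-form inversion)
    double w_coal = R_PosInf; int coal_pop = -1;
    for (int p = 0; p < npop; ++p) {
      if (k[p] < 2) continue;
      double xi = xset[p] * std::exp(-alpha[p] * (t - tset[p]));
      double c = (double) k[p] * (k[p] - 1) / xi;
      double E = exp_rand();
      double w;
      if (alpha[p] == 0.0) {
        w = E / c;
      } else {
        double arg = 1.0 + alpha[p] * E / c;
        w = (arg <= 0.0) ? R_PosInf : std::log(arg) / alpha[p];
      }
      if (w < w_coal) { w_coal = w; coal_pop = p; }
    }

    // migration
    double Rm = 0;
    for (int p = 0; p < npop; ++p) {
      if (k[p] == 0) continue;
      double rowsum = 0;
      for (int q = 0; q < npop; ++q) rowsum += M[p][q];
      Rm += k[p] * rowsum;
    }
    double w_mig = (Rm > 0) ? exp_rand() / Rm : R_PosInf;

    // recombination
    double Sspan = 0;
    if (rho > 0) for (const Lin& ln : lins) Sspan += ln.span();
    double Rr = rho * Sspan;
    double w_rec = (Rr > 0) ? exp_rand() / Rr : R_PosInf;

    double w = std::min(w_coal, std::min(w_mig, w_rec));
    double tnext = t + w;

    if (ev < events.size() && events[ev].time <= tnext) {
      double te = events[ev].time;
      drop_mutations(lins, te - t, theta, muts);
      t = te;
      while (ev < events.size() && events[ev].time <= te) {
        const DemEvent& e = events[ev];
        if (e.type == 1) {          // join: lineages in i move to j
          for (Lin& ln : lins) if (ln.pop == e.i) ln.pop = e.j;
          for (int q = 0; q < npop; ++q) { M[e.i][q] = 0.0; M[q][e.i] = 0.0; }
        } else if (e.type == 2) {   // size change, growth reset
          xset[e.i] = e.x; tset[e.i] = t; alpha[e.i] = 0.0;
        } else if (e.type == 3) {   // growth change
          xset[e.i] = xset[e.i] * std::exp(-alpha[e.i] * (t - tset[e.i]));
          tset[e.i] = t; alpha[e.i] = e.x;
        } else if (e.type == 4) {   // migration entry change
          M[e.i][e.j] = e.x;
        }
        ++ev;
      }
      continue;
    }

    if (!R_FINITE(w)) Rcpp::stop("no possible event: check demographic model");
    drop_mutations(lins, w, theta, muts);
    t = tnext;

    if (w == w_coal) {
      // pick two distinct lineages in coal_pop
      int kk = k[coal_pop];
      int a = (int) std::floor(unif_rand() * kk);
      int b = (int) std::floor(unif_rand() * (kk - 1));
      if (b >= a) b += 1;
      int ia = -1, ib = -1, seen = 0;
      for (size_t q = 0; q < lins.size(); ++q) {
        if (lins[q].pop == coal_pop) {
          if (seen == a) ia = (int) q;
          if (seen == b) ib = (int) q;
          ++seen;
        }
      }
      Lin merged;
      merged.pop = coal_pop;
      merged.segs = merge_segs(lins[ia].segs, lins[ib].segs, n);
      // remove ia, ib (larger index first), append merged if material remains
      if (ia < ib) std::swap(ia, ib);
      lins.erase(lins.begin() + ia);
      lins.erase(lins.begin() + ib);
      if (!merged.segs.empty()) lins.push_back(std::move(merged));
    } else if (w == w_mig) {
      double u = unif_rand() * Rm;
      double acc = 0;
      int src = -1, dst = -1;
      for (int p = 0; p < npop && src < 0; ++p) {
        if (k[p] == 0) continue;
        for (int q = 0; q < npop; ++q) {
          acc += k[p] * M[p][q];
          if (u < acc) { src = p; dst = q; break; }
        }
      }
      if (src >= 0) {
        int pick = (int) std::floor(unif_rand() * k[src]);
        int seen = 0;
        for (Lin& ln : lins) {
          if (ln.pop == src) {
            if (seen == pick) { ln.pop = dst; break; }
            ++seen;
          }
        }
      }
    } else {
      // recombination: lineage weighted by span, breakpoint uniform in span
      double u = unif_rand() * Sspan;
      double acc = 0;
      int pick = -1;
      for (size_t q = 0; q < lins.size(); ++q) {
        acc += lins[q].span();
        if (u < acc) { pick = (int) q; break; }
      }
      if (pick >= 0) {
        Lin& ln = lins[pick];
        double lo = ln.segs.front().l, hi = ln.segs.back().r;
        double bp = lo + unif_rand() * (hi - lo);
        std::vector<Seg> left, right;
        for (Seg& sg : ln.segs) {
          if (sg.r <= bp) left.push_back(sg);
          else if (sg.l >= bp) right.push_back(sg);
          else {
            Seg a = sg, b = sg;
            a.r = bp; b.l = bp;
            left.push_back(std::move(a));
            right.push_back(std::move(b));
          }
        }
        if (!left.empty() && !right.empty()) {
          Lin nl;
          nl.pop = ln.pop;
          nl.segs = std::move(right);
          ln.segs = std::move(left);
          lins.push_back(std::move(nl));
        }
      }
    }
  }
}

//' @name sim_coalescent_cpp
//' @title Low-level coalescent engine (internal)
//' @keywords internal
// [[Rcpp::export]]
List sim_coalescent_cpp(IntegerVector sample_sizes, double theta, double rho,
                        NumericVector pop_sizes, NumericVector growth,
                        NumericMatrix migration,
                        DataFrame events, int n_reps) {
  int npop = sample_sizes.size();
  std::vector<int> nsam(npop);
  int n = 0;
  for (int p = 0; p < npop; ++p) { nsam[p] = sample_sizes[p]; n += nsam[p]; }
  if (n < 2) stop("need at least 2 sampled chromosomes");

  std::vector<DemEvent> evs;
  if (events.nrows() > 0) {
    NumericVector et = events["time"];
    IntegerVector ty = events["type"];
    IntegerVector ei = events["i"];
    IntegerVector ej = events["j"];
    NumericVector ex = events["x"];
    for (int r = 0; r < events.nrows(); ++r) {
      DemEvent e;
      e.time = et[r]; e.type = ty[r];
      e.i = ei[r] - 1; e.j = ej[r] - 1;  // 1-based demes from R
      e.x = ex[r];
      evs.push_back(e);
    }
    std::stable_sort(evs.begin(), evs.end(),
                     [](const DemEvent& a, const DemEvent& b) { return a.time < b.time; });
  }

  List out(n_reps);
  for (int rep = 0; rep < n_reps; ++rep) {
    std::vector<double> xset(npop), alpha(npop);
    std::vector<std::vector<double> > M(npop, std::vector<double>(npop, 0.0));
    for (int p = 0; p < npop; ++p) {
      xset[p] = pop_sizes[p];
      alpha[p] = growth[p];
      for (int q = 0; q < npop; ++q) M[p][q] = migration(p, q);
    }
    std::vector<Mut> muts;
    sim_one(nsam, theta, rho, xset, alpha, M, evs, muts);
    std::sort(muts.begin(), muts.end(),
              [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
    int S = (int) muts.size();
    NumericVector pos(S);
    IntegerMatrix geno(n, S);
    for (int s = 0; s < S; ++s) {
      pos[s] = muts[s].pos;
      const Bits& b = muts[s].b;
      for (int i = 0; i < n; ++i) {
        if (b[i / 64] & ((uint64_t)1 << (i % 64))) geno(i, s) = 1;
      }
    }
    out[rep] = List::create(_["positions"] = pos, _["genotypes"] = geno);
  }
  return out;
}
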