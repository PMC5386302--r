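#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Lander-Green inheritance-vector machinery for one family.
//
// Members are in topological order (parents before children). Founder j
// (j-th founder in member order) owns allele slots 2j and 2j+1; nonfounder k
// (k-th nonfounder in member order) owns meiosis bits 2k (paternal) and
// 2k+1 (maternal): bit 0 transmits the parent's paternal slot.
//
// Emission sums over assignments of biallelic founder alleles to slots that
// are consistent with the observed genotypes, by constraint propagation over
// the founder allele graph with branching on unresolved heterozygotes.

namespace {

struct Family {
  int nInd, nFounder, nNonf, nBits;
  std::vector<int> fa, mo;      // 0-based member index, -1 = founder
  std::vector<int> fIdx, kIdx;  // founder / nonfounder ordinal, -1 otherwise
  Family(const IntegerVector& fav, const IntegerVector& mov) {
    nInd = fav.size();
    fa.assign(fav.begin(), fav.end());
    mo.assign(mov.begin(), mov.end());
    fIdx.assign(nInd, -1);
    kIdx.assign(nInd, -1);
    nFounder = 0; nNonf = 0;
    for (int i = 0; i < nInd; ++i) {
      if (fa[i] < 0) fIdx[i] = nFounder++;
      else kIdx[i] = nNonf++;
    }
    nBits = 2 * nNonf;
  }
  // allele slots of every member under inheritance vector v
  void slots(uint32_t v, int* pat, int* mat) const {
    for (int i = 0; i < nInd; ++i) {
      if (fa[i] < 0) {
        pat[i] = 2 * fIdx[i];
        mat[i] = 2 * fIdx[i] + 1;
      } else {
        int k = kIdx[i];
        pat[i] = ((v >> (2 * k)) & 1u) ? mat[fa[i]] : pat[fa[i]];
        mat[i] = ((v >> (2 * k + 1)) & 1u) ? mat[mo[i]] : pat[mo[i]];
      }
    }
  }
};

// Allocation-free constraint solver over the founder allele graph: slots are
// assigned biallelic alleles by propagation (with an undo stack) and
// branching on unresolved heterozygotes.
struct Emitter {
  int nSlot = 0, nc = 0, nu = 0;
  double q1 = 0.5, q2 = 0.5;
  int s1[64], s2[64];
  int8_t gg[64];
  int8_t allele[64];
  int undo[64];

  void reset(int slots, double freq2) {
    nSlot = slots; nc = 0; nu = 0;
    q2 = freq2; q1 = 1.0 - freq2;
    std::fill(allele, allele + nSlot, (int8_t)-1);
  }
  void addConstraint(int a, int b, int g) { s1[nc] = a; s2[nc] = b; gg[nc] = g; ++nc; }
  inline void assign(int s, int8_t v) { allele[s] = v; undo[nu++] = s; }
  inline void undoTo(int mark) { while (nu > mark) allele[undo[--nu]] = -1; }

  bool propagate() {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int c = 0; c < nc; ++c) {
        int8_t a = allele[s1[c]], b = allele[s2[c]];
        if (gg[c] != 1) {
          int8_t req = gg[c] == 2 ? 1 : 0;
          if ((a >= 0 && a != req) || (b >= 0 && b != req)) return false;
          if (a < 0) { assign(s1[c], req); changed = true; }
          if (allele[s2[c]] < 0) { assign(s2[c], req); changed = true; }
        } else {
          if (s1[c] == s2[c]) return false;
          if (a >= 0 && b >= 0) { if (a + b != 1) return false; }
          else if (a >= 0) { assign(s2[c], 1 - a); changed = true; }
          else if (b >= 0) { assign(s1[c], 1 - b); changed = true; }
        }
      }
    }
    return true;
  }

  double rec() {
    int mark = nu;
    if (!propagate()) { undoTo(mark); return 0.0; }
    for (int c = 0; c < nc; ++c)
      if (gg[c] == 1 && allele[s1[c]] < 0) {
        int mark2 = nu;
        assign(s1[c], 0);
        double p0 = rec();
        undoTo(mark2);
        assign(s1[c], 1);
        double p1 = rec();
        undoTo(mark);
        return p0 + p1;
      }
    double p = 1.0;
    for (int s = 0; s < nSlot; ++s) {
      if (allele[s] == 0) p *= q1;
      else if (allele[s] == 1) p *= q2;
    }
    undoTo(mark);
    return p;
  }
};

double emission(const Family& fam, uint32_t v, const int* genoCol,
                double freq2, int* pat, int* mat) {
  fam.slots(v, pat, mat);
  static thread_local Emitter em;
  em.reset(2 * fam.nFounder, freq2);
  for (int i = 0; i < fam.nInd; ++i) {
    int gi = genoCol[i];
    if (gi == NA_INTEGER || gi < 0) continue;
    em.addConstraint(pat[i], mat[i], gi);
  }
  if (em.nc == 0) return 1.0;
  return em.rec();
}

// in-place single-bit transition mixing: f <- (1-theta) f + theta swap_bit(f)
void mixBit(std::vector<double>& f, int bit, double theta, size_t S) {
  const size_t stride = size_t(1) << bit;
  for (size_t base = 0; base < S; base += 2 * stride) {
    for (size_t i = base; i < base + stride; ++i) {
      double a = f[i], b = f[i + stride];
      f[i] = (1 - theta) * a + theta * b;
      f[i + stride] = (1 - theta) * b + theta * a;
    }
  }
}

void transition(std::vector<double>& f, int nBits, double theta) {
  if (theta <= 0) return;
  for (int b = 0; b < nBits; ++b) mixBit(f, b, theta, f.size());
}

void normalize(std::vector<double>& f) {
  double s = 0;
  for (double x : f) s += x;
  if (s <= 0) stop("zero-probability genotype configuration (Mendelian error?)");
  for (double& x : f) x /= s;
}

double pairShare(const int* pat, const int* mat, int i, int j) {
  int c = ((pat[i] == pat[j]) | (pat[i] == mat[j])) +
          ((mat[i] == pat[j]) | (mat[i] == mat[j]));
  return 0.5 * c;
}

} // namespace

// Exact multipoint IBD by forward-backward over all inheritance vectors.
// geno: nInd x nMark dosages; markerOf: per position, column in geno or -1
// for an uninformative grid point; theta: nPos-1 recombination fractions;
// freq2: per-marker frequency of the counted allele among founders.
// pairs: nPairs x 2 member indices (0-based). Returns nPairs x nPos pihat.
// [[Rcpp::export]]
NumericMatrix ibdExactCpp(IntegerVector fa, IntegerVector mo,
                          IntegerMatrix geno, NumericVector freq2,
                          NumericVector theta, IntegerVector markerOf,
                          IntegerMatrix pairs) {
  Family fam(fa, mo);
  const int nPos = markerOf.size();
  const int nPairs = pairs.nrow();
  if (fam.nBits > 30) stop("state space too large for exact computation");
  const size_t S = size_t(1) << fam.nBits;

  std::vector<int> pat(fam.nInd), mat(fam.nInd);

  // share matrix S x nPairs and per-marker emissions
  std::vector<double> share(S * nPairs);
  for (size_t v = 0; v < S; ++v) {
    fam.slots((uint32_t)v, pat.data(), mat.data());
    for (int p = 0; p < nPairs; ++p)
      share[v + S * p] = pairShare(pat.data(), mat.data(),
                                   pairs(p, 0), pairs(p, 1));
  }
  const int nMark = geno.ncol();
  std::vector<std::vector<double>> E(nMark);
  std::vector<int> gcol(fam.nInd);
  for (int m = 0; m < nMark; ++m) {
    E[m].resize(S);
    for (int i = 0; i < fam.nInd; ++i) gcol[i] = geno(i, m);
    for (size_t v = 0; v < S; ++v)
      E[m][v] = emission(fam, (uint32_t)v, gcol.data(), freq2[m],
                         pat.data(), mat.data());
  }

  // forward
  std::vector<std::vector<double>> alpha(nPos);
  std::vector<double> f(S, 1.0 / S);
  for (int t = 0; t < nPos; ++t) {
    if (t > 0) transition(f, fam.nBits, theta[t - 1]);
    if (markerOf[t] >= 0) {
      const std::vector<double>& e = E[markerOf[t]];
      for (size_t v = 0; v < S; ++v) f[v] *= e[v];
    }
    normalize(f);
    alpha[t] = f;
  }
  // backward + posterior
  NumericMatrix pihat(nPairs, nPos);
  std::vector<double> b(S, 1.0);
  for (int t = nPos - 1; t >= 0; --t) {
    std::vector<double> post(S);
    double s = 0;
    for (size_t v = 0; v < S; ++v) { post[v] = alpha[t][v] * b[v]; s += post[v]; }
    for (size_t v = 0; v < S; ++v) post[v] /= s;
    for (int p = 0; p < nPairs; ++p) {
      double acc = 0;
      const double* sh = &share[S * p];
      for (size_t v = 0; v < S; ++v) acc += post[v] * sh[v];
      pihat(p, t) = acc;
    }
    if (t > 0) {
      if (markerOf[t] >= 0) {
        const std::vector<double>& e = E[markerOf[t]];
        for (size_t v = 0; v < S; ++v) b[v] *= e[v];
      }
      transition(b, fam.nBits, theta[t - 1]);
      normalize(b);
    }
  }
  return pihat;
}

// Monte-Carlo multipoint IBD: blocked meiosis Gibbs sampler. Each sweep
// jointly updates, for every parent in turn, all meiosis bits transmitting
// that parent's alleles, by forward-filtering backward-sampling of the
// 2^k-state chain along the chromosome conditional on all other bits.
// Blocking by parent lets founder phase switch between loci, which the
// single-meiosis sampler cannot do (it is reducible). Uses the R RNG.
// [[Rcpp::export]]
NumericMatrix ibdGibbsCpp(IntegerVector fa, IntegerVector mo,
                          IntegerMatrix geno, NumericVector freq2,
                          NumericVector theta, IntegerVector markerOf,
                          IntegerMatrix pairs, int sweeps, int burn) {
  Family fam(fa, mo);
  const int nPos = markerOf.size();
  const int nPairs = pairs.nrow();
  const int B = fam.nBits;
  std::vector<int> pat(fam.nInd), mat(fam.nInd);

  // genotype columns by position (empty for grid points)
  const int nMark = geno.ncol();
  std::vector<std::vector<int>> G(nMark);
  for (int m = 0; m < nMark; ++m) {
    G[m].resize(fam.nInd);
    for (int i = 0; i < fam.nInd; ++i) G[m][i] = geno(i, m);
  }

  // group meiosis bits by the parent whose alleles they transmit
  std::vector<std::vector<int>> blocks(fam.nInd);
  for (int i = 0; i < fam.nInd; ++i) {
    if (fam.fa[i] < 0) continue;
    int k = fam.kIdx[i];
    blocks[fam.fa[i]].push_back(2 * k);
    blocks[fam.mo[i]].push_back(2 * k + 1);
  }
  std::vector<std::vector<int>> blk;
  const int blockCap = 6;            // split very large sibships
  for (auto& bl : blocks) {
    for (size_t s = 0; s < bl.size(); s += blockCap)
      blk.emplace_back(bl.begin() + s,
                       bl.begin() + std::min(bl.size(), s + blockCap));
  }
  // per-individual blocks (paternal + maternal meiosis of each nonfounder):
  // lets a child switch grandparental origin on both sides jointly, a mode
  // that parent blocks alone cannot traverse
  for (int i = 0; i < fam.nInd; ++i)
    if (fam.fa[i] >= 0)
      blk.push_back({2 * fam.kIdx[i], 2 * fam.kIdx[i] + 1});

  // initial state: prior random walk per bit
  std::vector<uint32_t> v(nPos, 0);
  for (int b = 0; b < B; ++b) {
    int cur = R::unif_rand() < 0.5;
    for (int t = 0; t < nPos; ++t) {
      if (t > 0 && R::unif_rand() < theta[t - 1]) cur ^= 1;
      if (cur) v[t] |= (1u << b);
    }
  }

  NumericMatrix acc(nPairs, nPos);
  int kept = 0;
  const int Smax = 1 << blockCap;
  std::vector<double> Fbuf((size_t)nPos * Smax);
  std::vector<double> f(Smax);

  for (int sweep = 0; sweep < sweeps + burn; ++sweep) {
    for (const std::vector<int>& bits : blk) {
      const int k = bits.size();
      const int S = 1 << k;
      uint32_t mask = 0;
      for (int b : bits) mask |= (1u << b);
      auto scatter = [&](int s) {
        uint32_t w = 0;
        for (int j = 0; j < k; ++j) if (s & (1 << j)) w |= (1u << bits[j]);
        return w;
      };
      // forward filter over the 2^k block states
      f.assign(S, 1.0 / S);
      for (int t = 0; t < nPos; ++t) {
        if (t > 0) {
          double th = theta[t - 1];
          for (int j = 0; j < k; ++j) mixBit(f, j, th, S);
        }
        if (markerOf[t] >= 0) {
          const std::vector<int>& gc = G[markerOf[t]];
          double fq = freq2[markerOf[t]];
          uint32_t rest = v[t] & ~mask;
          double tot = 0;
          for (int s = 0; s < S; ++s) {
            f[s] *= emission(fam, rest | scatter(s), gc.data(), fq,
                             pat.data(), mat.data());
            tot += f[s];
          }
          if (tot <= 0)               // unreachable configuration: keep moving
            for (int s = 0; s < S; ++s) f[s] = 1.0 / S;
        }
        double tot = 0;
        for (int s = 0; s < S; ++s) tot += f[s];
        double* Ft = &Fbuf[(size_t)t * Smax];
        for (int s = 0; s < S; ++s) { f[s] /= tot; Ft[s] = f[s]; }
      }
      // backward sample
      auto draw = [&](const std::vector<double>& w) {
        double tot = 0;
        for (double x : w) tot += x;
        double u = R::unif_rand() * tot, c = 0;
        for (size_t s = 0; s < w.size(); ++s) { c += w[s]; if (u <= c) return (int)s; }
        return (int)w.size() - 1;
      };
      auto Fat = [&](int t) { return &Fbuf[(size_t)t * Smax]; };
      int cur = draw(std::vector<double>(Fat(nPos - 1), Fat(nPos - 1) + S));
      v[nPos - 1] = (v[nPos - 1] & ~mask) | scatter(cur);
      std::vector<double> w(S);
      for (int t = nPos - 2; t >= 0; --t) {
        double th = theta[t];
        const double* Ft = Fat(t);
        for (int s = 0; s < S; ++s) {
          int d = 0, x = s ^ cur;
          while (x) { d += x & 1; x >>= 1; }
          w[s] = Ft[s] * std::pow(th, d) * std::pow(1 - th, k - d);
        }
        cur = draw(w);
        v[t] = (v[t] & ~mask) | scatter(cur);
      }
    }
    if (sweep >= burn) {
      ++kept;
      for (int t = 0; t < nPos; ++t) {
        fam.slots(v[t], pat.data(), mat.data());
        for (int p = 0; p < nPairs; ++p)
          acc(p, t) += pairShare(pat.data(), mat.data(),
                                 pairs(p, 0), pairs(p, 1));
      }
    }
  }
  for (int p = 0; p < nPairs; ++p)
    for (int t = 0; t < nPos; ++t) acc(p, t) /= kept;
  return acc;
}
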