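// Dynamic-programming kernels: hairpin folding (max-stability nested
// structure with a per-stack energy table), intermolecular duplex energy,
// position-weighted local alignment, and read-cleaning scanners.
// Energies are handled internally as integers in units of 0.1 kcal/mol so
// that co-optimality comparisons are exact.
#include <Rcpp.h>
#include <cctype>
#include <climits>
using namespace Rcpp;

static const int BIG = INT_MAX / 4;

static inline int baseCode(char c) {
  switch (toupper(c)) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T':
  case 'U': return 3;
  }
  return -1;
}

// Watson-Crick (A:U, C:G) plus G:U wobble
static inline bool canPair(int a, int b) {
  if (a < 0 || b < 0) return false;
  return (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2);
}

// ---------------------------------------------------------------------------
// Hairpin folding
// ---------------------------------------------------------------------------
// stack10: length-16 integer vector, entry [a*4+b] = energy (x10 kcal/mol)
// contributed by a stack whose outer (5'-side) pair is (a, b). DP minimises
// total energy; among co-optimal energies it maximises pair count; the
// traceback prefers 5'-most closing pairs.

struct FoldCtx {
  int n, minloop;
  std::vector<int> s;
  const int* stk;
  std::vector<int> WE, WP, VE, VP; // energy / pair-count tables
  int idx(int i, int j) const { return i * n + j; }
  bool pairOK(int i, int j) const {
    return j - i - 1 >= minloop && canPair(s[i], s[j]);
  }
};

// lexicographic: smaller energy wins, then larger pair count
static inline bool better(int e1, int p1, int e2, int p2) {
  return e1 < e2 || (e1 == e2 && p1 > p2);
}

static void foldFill(FoldCtx& C) {
  int n = C.n;
  C.WE.assign(n * n, 0); C.WP.assign(n * n, 0);
  C.VE.assign(n * n, BIG); C.VP.assign(n * n, -1);
  for (int span = C.minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j): (i,j) paired
      if (C.pairOK(i, j)) {
        int e, p;
        if (j - 1 - (i + 1) >= 0) {
          e = C.WE[C.idx(i + 1, j - 1)];
          p = C.WP[C.idx(i + 1, j - 1)];
        } else { e = 0; p = 0; }
        int be = e, bp = p + 1;
        if (C.pairOK(i + 1, j - 1)) {
          int e2 = C.stk[C.s[i] * 4 + C.s[j]] + C.VE[C.idx(i + 1, j - 1)];
          int p2 = 1 + C.VP[C.idx(i + 1, j - 1)];
          if (better(e2, p2, be, bp)) { be = e2; bp = p2; }
        }
        C.VE[C.idx(i, j)] = be; C.VP[C.idx(i, j)] = bp;
      }
      // W(i,j)
      int be = C.WE[C.idx(i, j - 1)], bp = C.WP[C.idx(i, j - 1)];
      for (int k = i; k <= j - C.minloop - 1; ++k) {
        if (!C.pairOK(k, j)) continue;
        int e = C.VE[C.idx(k, j)], p = C.VP[C.idx(k, j)];
        if (k > i) { e += C.WE[C.idx(i, k - 1)]; p += C.WP[C.idx(i, k - 1)]; }
        if (better(e, p, be, bp)) { be = e; bp = p; }
      }
      C.WE[C.idx(i, j)] = be; C.WP[C.idx(i, j)] = bp;
    }
  }
}

static void traceW(FoldCtx& C, int i, int j, std::string& db);

static void traceV(FoldCtx& C, int i, int j, std::string& db) {
  db[i] = '('; db[j] = ')';
  if (j - 1 - (i + 1) < 0) return;
  int targetE = C.VE[C.idx(i, j)], targetP = C.VP[C.idx(i, j)];
  if (C.pairOK(i + 1, j - 1)) {
    int e2 = C.stk[C.s[i] * 4 + C.s[j]] + C.VE[C.idx(i + 1, j - 1)];
    int p2 = 1 + C.VP[C.idx(i + 1, j - 1)];
    // prefer the stacked continuation when co-optimal (5'-most pairing)
    if (e2 == targetE && p2 == targetP) { traceV(C, i + 1, j - 1, db); return; }
  }
  traceW(C, i + 1, j - 1, db);
}

static void traceW(FoldCtx& C, int i, int j, std::string& db) {
  if (j - i < 0) return;
  if (j - i < C.minloop + 1) return;
  int tE = C.WE[C.idx(i, j)], tP = C.WP[C.idx(i, j)];
  // 5'-most: scan candidate closing pairs (k, j) with smallest k first
  for (int k = i; k <= j - C.minloop - 1; ++k) {
    if (!C.pairOK(k, j)) continue;
    int e = C.VE[C.idx(k, j)], p = C.VP[C.idx(k, j)];
    if (k > i) { e += C.WE[C.idx(i, k - 1)]; p += C.WP[C.idx(i, k - 1)]; }
    if (e == tE && p == tP) {
      if (k > i) traceW(C, i, k - 1, db);
      traceV(C, k, j, db);
      return;
    }
  }
  traceW(C, i, j - 1, db);
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, IntegerVector stack10, int min_loop) {
  int n = seq.size();
  FoldCtx C;
  C.n = n; C.minloop = min_loop; C.stk = stack10.begin();
  C.s.resize(n);
  for (int i = 0; i < n; ++i) {
    C.s[i] = baseCode(seq[i]);
    if (C.s[i] < 0) stop("invalid character in sequence: '%s'",
                         std::string(1, seq[i]).c_str());
  }
  std::string db(n, '.');
  int e = 0, p = 0;
  if (n > C.minloop + 1) {
    foldFill(C);
    e = C.WE[C.idx(0, n - 1)];
    p = C.WP[C.idx(0, n - 1)];
    traceW(C, 0, n - 1, db);
  }
  return List::create(_["structure"] = db, _["mfe"] = e / 10.0,
                      _["n_pairs"] = p);
}

// Vectorised MFE-only version used by the shuffle test: energy tables only
// (no pair-count tie-breaking, no traceback), with pairable partners
// precomputed per position.
// [[Rcpp::export]]
NumericVector fold_mfe_cpp(CharacterVector seqs, IntegerVector stack10,
                           int min_loop) {
  int m = seqs.size();
  NumericVector out(m);
  const int* stk = stack10.begin();
  for (int q = 0; q < m; ++q) {
    std::string seq = as<std::string>(seqs[q]);
    int n = seq.size();
    if (n <= min_loop + 1) { out[q] = 0.0; continue; }
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = baseCode(seq[i]);
    // partners[j]: positions k < j with canPair(s[k], s[j])
    std::vector<std::vector<int>> partners(n);
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < j; ++k)
        if (canPair(s[k], s[j])) partners[j].push_back(k);
    std::vector<int> W(n * n, 0), V(n * n, BIG);
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (canPair(s[i], s[j])) {
          int e = (j - i >= 2) ? W[(i + 1) * n + (j - 1)] : 0;
          if (j - 1 - (i + 1) - 1 >= min_loop && canPair(s[i + 1], s[j - 1])) {
            int e2 = stk[s[i] * 4 + s[j]] + V[(i + 1) * n + (j - 1)];
            if (e2 < e) e = e2;
          }
          V[i * n + j] = e;
        }
        int be = W[i * n + (j - 1)];
        for (int k : partners[j]) {
          if (k < i || k > j - min_loop - 1) continue;
          int e = V[k * n + j];
          if (k > i) e += W[i * n + (k - 1)];
          if (e < be) be = e;
        }
        W[i * n + j] = be;
      }
    }
    out[q] = W[n - 1] / 10.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Intermolecular duplex scan
// ---------------------------------------------------------------------------
// miRNA 5'->3' hybridised antiparallel to a target window. Pairs are
// monotone; stacks (both strands advance by 1) contribute the stack-table
// energy keyed by the previous pair; bulges / internal loops cost
// loop_pen10 x skipped nt. Isolated pairs contribute 0.

// [[Rcpp::export]]
DataFrame duplex_scan_cpp(std::string mirna, std::string utr,
                          IntegerVector stack10, int loop_pen10,
                          double energy_max, int max_skip, int min_pairs) {
  int m = mirna.size(), n = utr.size();
  std::vector<int> a(m), bR(n); // bR: reversed target
  for (int i = 0; i < m; ++i) a[i] = baseCode(mirna[i]);
  for (int j = 0; j < n; ++j) bR[j] = baseCode(utr[n - 1 - j]);
  // H[i][j]: best energy of a duplex whose last pair is (a_i, bR_j);
  // NP tracks the pair count of that optimal path
  std::vector<int> H(m * n, BIG), SJ(m * n, -1), NP(m * n, 0);
  const int* stk = stack10.begin();
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      if (!canPair(a[i], bR[j])) continue;
      int best = 0, sj = j, np = 1; // a pair may start a duplex at zero cost
      for (int di = 1; di <= max_skip + 1 && i - di >= 0; ++di) {
        for (int dj = 1; dj <= max_skip + 1 && j - dj >= 0; ++dj) {
          int pi = i - di, pj = j - dj;
          if (H[pi * n + pj] >= BIG) continue;
          int cost;
          if (di == 1 && dj == 1)
            cost = stk[a[pi] * 4 + bR[pj]];
          else
            cost = loop_pen10 * ((di - 1) + (dj - 1));
          int e = H[pi * n + pj] + cost;
          if (e < best) {
            best = e; sj = SJ[pi * n + pj]; np = NP[pi * n + pj] + 1;
          }
        }
      }
      H[i * n + j] = best; SJ[i * n + j] = sj; NP[i * n + j] = np;
    }
  }
  // candidate endpoints below threshold (and engaging enough of the miRNA),
  // greedily made non-overlapping
  int emax10 = (int)std::lround(energy_max * 10);
  std::vector<std::tuple<int, int, int>> cand; // (energy, utrStart, utrEnd)
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      int e = H[i * n + j];
      if (e >= BIG || e > emax10 || NP[i * n + j] < min_pairs) continue;
      int j0 = SJ[i * n + j];
      // reversed coords j0..j  ->  utr positions (n-1-j) .. (n-1-j0)
      cand.push_back(std::make_tuple(e, n - 1 - j, n - j0));
    }
  std::sort(cand.begin(), cand.end());
  std::vector<int> st, en; std::vector<double> ev;
  for (auto& c : cand) {
    int s = std::get<1>(c), e = std::get<2>(c);
    bool clash = false;
    for (size_t k = 0; k < st.size(); ++k)
      if (s < en[k] && st[k] < e) { clash = true; break; }
    if (clash) continue;
    st.push_back(s); en.push_back(e); ev.push_back(std::get<0>(c) / 10.0);
  }
  return DataFrame::create(_["start"] = wrap(st), _["end"] = wrap(en),
                           _["energy"] = wrap(ev));
}

// ---------------------------------------------------------------------------
// Position-weighted local alignment (miRNA reverse complement vs target)
// ---------------------------------------------------------------------------
// Substitution: +5 Watson-Crick, +1 G:U wobble, -4 mismatch; scores at miRNA
// seed positions (2-8) doubled. Gap: 8 at opening plus 2 per gapped nt.

static inline int subScore(int q, int t) {
  // q is the complement of the miRNA base; q==t means Watson-Crick pairing
  if (q == t) return 5;
  // G:U wobble between miRNA base (3-q for WC complement... handled directly):
  // miRNA G vs target T -> q = C, t = T ; miRNA U vs target G -> q = A, t = G
  if ((q == 1 && t == 3) || (q == 0 && t == 2)) return 1;
  return -4;
}

// [[Rcpp::export]]
DataFrame align_scan_cpp(std::string mirna, std::string utr, double threshold,
                         int max_sites) {
  int L = mirna.size(), n = utr.size();
  std::vector<int> q(L), t(n);
  // reverse complement of the miRNA as the query
  for (int i = 0; i < L; ++i) {
    int c = baseCode(mirna[L - 1 - i]);
    q[i] = (c == 2) ? 1 : (c == 1) ? 2 : (c == 0) ? 3 : 0; // complement
  }
  for (int j = 0; j < n; ++j) t[j] = baseCode(utr[j]);
  std::vector<int> seedMul(L);
  for (int i = 0; i < L; ++i) {
    int mpos = L - i; // 1-based miRNA position of query index i
    seedMul[i] = (mpos >= 2 && mpos <= 8) ? 2 : 1;
  }
  const int GO = 10, GE = 2; // first gapped nt costs 10, each further 2
  std::vector<bool> masked(n, false);
  std::vector<int> st, en; std::vector<double> sc;
  for (int iter = 0; iter < max_sites; ++iter) {
    // M/Ix/Iy with start-column tracking
    std::vector<int> M((L + 1) * (n + 1), 0), Ix((L + 1) * (n + 1), -BIG),
        Iy((L + 1) * (n + 1), -BIG);
    std::vector<int> SM((L + 1) * (n + 1), 0), SX((L + 1) * (n + 1), 0),
        SY((L + 1) * (n + 1), 0);
    int best = 0, bi = -1, bj = -1;
    for (int i = 1; i <= L; ++i) {
      for (int j = 1; j <= n; ++j) {
        int id = i * (n + 1) + j;
        int up = (i - 1) * (n + 1) + j, lf = i * (n + 1) + (j - 1),
            dg = (i - 1) * (n + 1) + (j - 1);
        // Ix: gap in target (consume query)
        int o = M[up] - GO, e = Ix[up] - GE;
        if (o >= e) { Ix[id] = o; SX[id] = SM[up]; }
        else { Ix[id] = e; SX[id] = SX[up]; }
        // Iy: gap in query (consume target)
        o = M[lf] - GO; e = Iy[lf] - GE;
        if (o >= e) { Iy[id] = o; SY[id] = SM[lf]; }
        else { Iy[id] = e; SY[id] = SY[lf]; }
        // M: align q[i-1] with t[j-1]
        int s = masked[j - 1] ? -BIG : subScore(q[i - 1], t[j - 1]) *
                                          seedMul[i - 1];
        int mm = M[dg], sdg = SM[dg];
        if (Ix[dg] > mm) { mm = Ix[dg]; sdg = SX[dg]; }
        if (Iy[dg] > mm) { mm = Iy[dg]; sdg = SY[dg]; }
        int val; int start;
        if (mm <= 0) { val = s; start = j - 1; }
        else { val = mm + s; start = sdg; }
        if (val < 0) { val = 0; start = j; } // local reset
        M[id] = val; SM[id] = start;
        if (val > best) { best = val; bi = i; bj = j; }
      }
    }
    if (best < threshold) break;
    int id = bi * (n + 1) + bj;
    int s0 = SM[id];
    st.push_back(s0); en.push_back(bj); sc.push_back(best);
    for (int j = s0; j < bj; ++j) masked[j] = true;
  }
  return DataFrame::create(_["start"] = wrap(st), _["end"] = wrap(en),
                           _["score"] = wrap(sc));
}

// ---------------------------------------------------------------------------
// Read-cleaning scanners
// ---------------------------------------------------------------------------

// First position (0-based) with a prefix match of the 3' adapter of length
// >= min_match and <= max_mismatch mismatches; -1 if none.
// [[Rcpp::export]]
IntegerVector adapter3_pos_cpp(CharacterVector seqs, std::string adapter,
                               int min_match, int max_mismatch) {
  int N = seqs.size(), alen = adapter.size();
  IntegerVector out(N);
  for (int r = 0; r < N; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    int hit = -1;
    for (int p = 0; p + min_match <= len; ++p) {
      int m = std::min(alen, len - p);
      int mis = 0;
      for (int k = 0; k < m; ++k) {
        if (s[p + k] != adapter[k] && ++mis > max_mismatch) break;
      }
      if (mis <= max_mismatch) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Fraction of bases whose Phred+33 quality is below `thresh`.
// [[Rcpp::export]]
NumericVector frac_below_q_cpp(CharacterVector quals, int thresh) {
  int N = quals.size();
  NumericVector out(N);
  for (int r = 0; r < N; ++r) {
    const char* s = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(quals, r));
    int low = 0;
    for (int k = 0; k < len; ++k)
      if (s[k] - 33 < thresh) ++low;
    out[r] = len ? (double)low / len : 0.0;
  }
  return out;
}
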