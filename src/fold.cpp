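#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbor minimum-free-energy folding (Zuker-style DP).
// Model: stacking energies for the six canonical pairs (AT/TA/GC/CG/GT/TG
// on the DNA alphabet, i.e. AU/UA/GC/CG/GU/UG on RNA), linear hairpin,
// bulge and internal-loop penalties, affine multiloop, pseudoknot-free,
// hairpin loops of at least 3 unpaired nucleotides, interior loops capped
// at max_internal total unpaired nucleotides.

static const double INF = 1e9;
static const double EPS = 1e-9;

static inline int pair_index(char a, char b) {
  switch (a) {
  case 'A': return b == 'T' ? 0 : -1;
  case 'T': return b == 'A' ? 1 : (b == 'G' ? 5 : -1);
  case 'G': return b == 'C' ? 2 : (b == 'T' ? 4 : -1);
  case 'C': return b == 'G' ? 3 : -1;
  }
  return -1;
}

struct FoldParams {
  double stack[6][6];
  double hairpin_a, hairpin_b;
  double bulge_a, bulge_b;
  double internal_a, internal_b;
  double ml_a, ml_b, ml_c;
  int max_internal;
};

struct FoldState {
  int n;
  const std::string &s;
  const FoldParams &P;
  std::vector<double> V, M, M1, W;
  FoldState(const std::string &seq, const FoldParams &p)
    : n(seq.size()), s(seq), P(p),
      V(n * n, INF), M(n * n, INF), M1(n * n, INF), W(n + 1, 0.0) {}
  inline double &v(int i, int j)  { return V[i * n + j]; }
  inline double &m(int i, int j)  { return M[i * n + j]; }
  inline double &m1(int i, int j) { return M1[i * n + j]; }
  inline double hairpin(int l) const { return P.hairpin_a + P.hairpin_b * l; }
  inline double loop_pen(int l1, int l2) const {
    if (l1 == 0 || l2 == 0)
      return P.bulge_a + P.bulge_b * (l1 + l2);
    return P.internal_a + P.internal_b * (l1 + l2);
  }
};

static void fill_tables(FoldState &F) {
  const int n = F.n;
  const FoldParams &P = F.P;
  for (int d = 4; d < n; ++d) {          // j - i >= 4 (hairpin >= 3)
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pi = pair_index(F.s[i], F.s[j]);
      if (pi >= 0) {
        double best = F.hairpin(j - i - 1);
        // stack + interior loops
        for (int k = i + 1; k <= j - 5 && k - i - 1 <= P.max_internal; ++k) {
          for (int l = j - 1; l >= k + 4; --l) {
            int l1 = k - i - 1, l2 = j - l - 1;
            if (l1 + l2 > P.max_internal) break;
            double vkl = F.v(k, l);
            if (vkl >= INF) continue;
            double e;
            if (l1 == 0 && l2 == 0) {
              int qi = pair_index(F.s[k], F.s[l]);
              e = P.stack[pi][qi] + vkl;   // qi >= 0 since vkl finite
            } else {
              e = F.loop_pen(l1, l2) + vkl;
            }
            if (e < best) best = e;
          }
        }
        // multiloop: closing pair + >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          double a = F.m(i + 1, k - 1), b = F.m1(k, j - 1);
          if (a >= INF || b >= INF) continue;
          double e = P.ml_a + P.ml_b + a + b;
          if (e < best) best = e;
        }
        F.v(i, j) = best;
      }
      // M1: exactly one branch, starting at i, trailing unpaired allowed
      {
        double best = INF;
        if (F.v(i, j) < INF) best = F.v(i, j) + P.ml_b;
        if (j > i && F.m1(i, j - 1) < INF)
          best = std::min(best, F.m1(i, j - 1) + P.ml_c);
        F.m1(i, j) = best;
      }
      // M: >= 1 branch anywhere in [i, j]
      {
        double best = INF;
        if (F.v(i, j) < INF) best = F.v(i, j) + P.ml_b;
        if (j > i) {
          if (F.m(i, j - 1) < INF)
            best = std::min(best, F.m(i, j - 1) + P.ml_c);
          if (F.m(i + 1, j) < INF)
            best = std::min(best, F.m(i + 1, j) + P.ml_c);
          for (int k = i + 1; k <= j; ++k) {
            double a = F.m(i, k - 1), b = F.v(k, j);
            if (a >= INF || b >= INF) continue;
            best = std::min(best, a + b + P.ml_b);
          }
        }
        F.m(i, j) = best;
      }
    }
  }
  // exterior: W[j+1] = best energy of prefix s[0..j]
  for (int j = 0; j < n; ++j) {
    double best = F.W[j];                 // j unpaired
    for (int i = 0; i <= j; ++i) {
      double vij = F.v(i, j);
      if (vij >= INF) continue;
      double e = (i > 0 ? F.W[i] : 0.0) + vij;
      if (e < best) best = e;
    }
    F.W[j + 1] = best;
  }
}

// ---- traceback (fixed deterministic preference order) ----

struct TB { int i, j, which; };          // which: 0=W, 1=V, 2=M, 3=M1

static void traceback(FoldState &F, std::string &db) {
  const int n = F.n;
  const FoldParams &P = F.P;
  db.assign(n, '.');
  std::vector<TB> stack;
  stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    TB t = stack.back(); stack.pop_back();
    int i = t.i, j = t.j;
    if (j < i) continue;
    if (t.which == 0) {                  // exterior over s[i..j] (i == 0)
      int jj = j;
      while (jj >= 0) {
        double target = F.W[jj + 1];
        bool done = false;
        for (int k = 0; k <= jj; ++k) {  // prefer pairing leftmost k
          double vkj = F.v(k, jj);
          if (vkj >= INF) continue;
          double e = (k > 0 ? F.W[k] : 0.0) + vkj;
          if (std::fabs(e - target) < EPS) {
            stack.push_back({k, jj, 1});
            jj = k - 1;
            done = true;
            break;
          }
        }
        if (!done) --jj;                 // jj unpaired
      }
    } else if (t.which == 1) {           // V(i,j): i pairs j
      db[i] = '('; db[j] = ')';
      double target = F.v(i, j);
      int pi = pair_index(F.s[i], F.s[j]);
      bool done = false;
      // stack / interior, smallest (l1, l2) first
      for (int k = i + 1; !done && k <= j - 5 && k - i - 1 <= P.max_internal; ++k) {
        for (int l = j - 1; l >= k + 4; --l) {
          int l1 = k - i - 1, l2 = j - l - 1;
          if (l1 + l2 > P.max_internal) break;
          double vkl = F.v(k, l);
          if (vkl >= INF) continue;
          double e = (l1 == 0 && l2 == 0)
            ? P.stack[pi][pair_index(F.s[k], F.s[l])] + vkl
            : F.loop_pen(l1, l2) + vkl;
          if (std::fabs(e - target) < EPS) {
            stack.push_back({k, l, 1});
            done = true;
            break;
          }
        }
      }
      if (!done) {
        for (int k = i + 2; k <= j - 2; ++k) {
          double a = F.m(i + 1, k - 1), b = F.m1(k, j - 1);
          if (a >= INF || b >= INF) continue;
          if (std::fabs(P.ml_a + P.ml_b + a + b - target) < EPS) {
            stack.push_back({i + 1, k - 1, 2});
            stack.push_back({k, j - 1, 3});
            done = true;
            break;
          }
        }
      }
      // otherwise hairpin: nothing to push
    } else if (t.which == 2) {           // M(i,j)
      double target = F.m(i, j);
      if (F.v(i, j) < INF &&
          std::fabs(F.v(i, j) + P.ml_b - target) < EPS) {
        stack.push_back({i, j, 1});
        continue;
      }
      bool done = false;
      for (int k = i + 1; k <= j; ++k) {
        double a = F.m(i, k - 1), b = F.v(k, j);
        if (a >= INF || b >= INF) continue;
        if (std::fabs(a + b + P.ml_b - target) < EPS) {
          stack.push_back({i, k - 1, 2});
          stack.push_back({k, j, 1});
          done = true;
          break;
        }
      }
      if (!done && j > i && F.m(i + 1, j) < INF &&
          std::fabs(F.m(i + 1, j) + P.ml_c - target) < EPS) {
        stack.push_back({i + 1, j, 2});
        done = true;
      }
      if (!done && j > i && F.m(i, j - 1) < INF &&
          std::fabs(F.m(i, j - 1) + P.ml_c - target) < EPS) {
        stack.push_back({i, j - 1, 2});
      }
    } else {                             // M1(i,j): branch starts at i
      double target = F.m1(i, j);
      if (F.v(i, j) < INF &&
          std::fabs(F.v(i, j) + P.ml_b - target) < EPS) {
        stack.push_back({i, j, 1});
      } else if (j > i) {
        stack.push_back({i, j - 1, 3});
      }
    }
  }
}

static FoldParams make_params(NumericMatrix stack_table, NumericVector loops) {
  FoldParams P;
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      P.stack[a][b] = stack_table(a, b);
  P.hairpin_a = loops["hairpin_a"];   P.hairpin_b = loops["hairpin_b"];
  P.bulge_a = loops["bulge_a"];       P.bulge_b = loops["bulge_b"];
  P.internal_a = loops["internal_a"]; P.internal_b = loops["internal_b"];
  P.ml_a = loops["multi_a"]; P.ml_b = loops["multi_b"];
  P.ml_c = loops["multi_c"];
  P.max_internal = (int) loops["max_internal"];
  return P;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string sequence, NumericMatrix stack_table,
                  NumericVector loops) {
  FoldParams P = make_params(stack_table, loops);
  int n = sequence.size();
  if (n == 0)
    return List::create(_["energy"] = 0.0, _["dotbracket"] = "");
  FoldState F(sequence, P);
  fill_tables(F);
  double mfe = F.W[n];
  std::string db;
  traceback(F, db);
  return List::create(_["energy"] = mfe, _["dotbracket"] = db);
}

// [[Rcpp::export(name = ".fold_energy_cpp")]]
NumericVector fold_energy_cpp(CharacterVector sequences,
                              NumericMatrix stack_table,
                              NumericVector loops) {
  FoldParams P = make_params(stack_table, loops);
  int m = sequences.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    std::string seq = as<std::string>(sequences[q]);
    if (seq.empty()) { out[q] = 0.0; continue; }
    FoldState F(seq, P);
    fill_tables(F);
    out[q] = F.W[seq.size()];
  }
  return out;
}

// ---- ungapped mismatch scanner (Bowtie-like, substitution only) ----

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'T': return 'A';
  case 'G': return 'C'; case 'C': return 'G';
  default: return 'N';
  }
}

// [[Rcpp::export(name = ".scan_tags_cpp")]]
DataFrame scan_tags_cpp(CharacterVector tags, CharacterVector refs,
                        int max_mismatch, bool both_strands, bool best_only) {
  std::vector<std::string> R(refs.size());
  for (int r = 0; r < refs.size(); ++r) R[r] = as<std::string>(refs[r]);
  std::vector<int> o_tag, o_ref, o_pos, o_mm;
  std::vector<std::string> o_strand;
  for (int t = 0; t < tags.size(); ++t) {
    std::string fw = as<std::string>(tags[t]);
    std::string rc(fw.rbegin(), fw.rend());
    for (size_t k = 0; k < rc.size(); ++k) rc[k] = comp_base(rc[k]);
    int limit = max_mismatch;
    std::vector<int> h_ref, h_pos, h_mm;
    std::vector<std::string> h_strand;
    int n_strands = both_strands ? 2 : 1;
    for (int sdx = 0; sdx < n_strands; ++sdx) {
      const std::string &q = sdx == 0 ? fw : rc;
      const std::string strand = sdx == 0 ? "+" : "-";
      int ql = q.size();
      for (size_t r = 0; r < R.size(); ++r) {
        const std::string &ref = R[r];
        int rl = ref.size();
        for (int p = 0; p + ql <= rl; ++p) {
          int mm = 0;
          const char *a = q.data(), *b = ref.data() + p;
          for (int k = 0; k < ql; ++k) {
            if (a[k] != b[k] && ++mm > limit) break;
          }
          if (mm <= limit) {
            if (best_only && mm < limit) {
              // tighter best found: drop previous worse hits
              limit = mm;
              size_t w = 0;
              for (size_t z = 0; z < h_mm.size(); ++z) {
                if (h_mm[z] <= mm) {
                  h_ref[w] = h_ref[z]; h_pos[w] = h_pos[z];
                  h_mm[w] = h_mm[z]; h_strand[w] = h_strand[z];
                  ++w;
                }
              }
              h_ref.resize(w); h_pos.resize(w);
              h_mm.resize(w); h_strand.resize(w);
            }
            h_ref.push_back(r + 1);
            h_pos.push_back(p);
            h_mm.push_back(mm);
            h_strand.push_back(strand);
          }
        }
      }
    }
    for (size_t z = 0; z < h_mm.size(); ++z) {
      if (best_only && h_mm[z] > limit) continue;
      o_tag.push_back(t + 1);
      o_ref.push_back(h_ref[z]);
      o_pos.push_back(h_pos[z]);
      o_mm.push_back(h_mm[z]);
      o_strand.push_back(h_strand[z]);
    }
  }
  return DataFrame::create(_["tag"] = o_tag, _["ref"] = o_ref,
                           _["pos"] = o_pos, _["strand"] = o_strand,
                           _["mismatches"] = o_mm,
                           _["stringsAsFactors"] = false);
}
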