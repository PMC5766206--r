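#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
using namespace Rcpp;

// Minimum-free-energy folding of one or more concatenated RNA strands under a
// stacking-only nearest-neighbour model.  Pseudoknot-free structures only.
//
// Energy model: every pair of adjacent base pairs (a stack) contributes a
// table value; isolated pairs and loops contribute 0.  Hairpin loops must
// enclose >= hairpin_min unpaired nucleotides unless a strand nick lies
// inside the loop.  Stacks are not credited across a nick (coaxial stacking
// over the nick is not modelled).
//
// Hard constraints supported per position:
//   forced_unpaired[i]  -> i may not pair at all
//   forced_partner[i]=j -> i must pair exactly j (used to freeze the
//                          intermolecular pairs of earlier assembly events)
//
// Co-optimal structures are resolved deterministically: among all structures
// attaining the minimum energy (within a 1e-7 tolerance) the one with the
// lexicographically smallest dot-bracket string is returned ('(' < ')' < '.').
// The dot-bracket of a subsegment is a contiguous substring of the full
// string, so the lexicographic minimum composes over the DP decomposition.

static const double INF = 1e18;
static const double EPS = 1e-7;

struct Fold {
  int n;
  std::vector<int> s;            // base codes 0=A,1=C,2=G,3=U
  std::vector<bool> cutAt;       // cutAt[c]: nick between c-1 and c
  std::vector<bool> unp;         // forced unpaired
  std::vector<int> fp;           // forced partner or -1
  std::vector<std::vector<bool>> canPair;   // 4x4
  std::vector<std::vector<double>> stackE;  // 16x16 by pair code 4*a+b
  int hairpin_min;

  std::vector<std::vector<double>> W, V, Wne;
  std::vector<std::vector<char>> doneW, doneV, doneWne;
  std::map<std::pair<int,int>, std::string> memW, memV, memWne;

  bool cutIn(int lo, int hi) const {        // any nick at c with lo <= c <= hi
    for (int c = lo; c <= hi; ++c) if (c >= 0 && c < n && cutAt[c]) return true;
    return false;
  }
  bool pairable(int i, int j) const {
    if (i < 0 || j >= n || i >= j) return false;
    if (unp[i] || unp[j]) return false;
    if (fp[i] != -1 && fp[i] != j) return false;
    if (fp[j] != -1 && fp[j] != i) return false;
    if (!canPair[s[i]][s[j]]) return false;
    // too-tight pair: interior cannot be a legal hairpin nor hold pairs
    if (j - i - 1 < hairpin_min && !cutIn(i + 1, j)) return false;
    return true;
  }
  bool hairpinOK(int i, int j) const {
    for (int p = i + 1; p < j; ++p) if (fp[p] != -1) return false;
    return (j - i - 1 >= hairpin_min) || cutIn(i + 1, j);
  }
  bool stackOK(int i, int j) const {        // stack between (i,j) and (i+1,j-1)
    return !cutAt[i + 1] && !cutAt[j];
  }
  double stackVal(int i, int j) const {
    return stackE[4 * s[i] + s[j]][4 * s[i + 1] + s[j - 1]];
  }

  double getV(int i, int j);
  double getW(int i, int j);
  double getWne(int i, int j);
  std::string strV(int i, int j);
  std::string strW(int i, int j);
  std::string strWne(int i, int j);
};

double Fold::getV(int i, int j) {
  if (!pairable(i, j)) return INF;
  if (doneV[i][j]) return V[i][j];
  double best = INF;
  if (hairpinOK(i, j)) best = 0.0;
  if (pairable(i + 1, j - 1) && stackOK(i, j)) {
    double e = getV(i + 1, j - 1);
    if (e < INF / 2) best = std::min(best, e + stackVal(i, j));
  }
  double ene = getWne(i + 1, j - 1);
  if (ene < INF / 2) best = std::min(best, ene);
  doneV[i][j] = 1; V[i][j] = best;
  return best;
}

double Fold::getW(int i, int j) {
  if (i > j) return 0.0;
  if (doneW[i][j]) return W[i][j];
  double best = INF;
  if (fp[i] != -1) {
    if (fp[i] > i && fp[i] <= j) {
      double v = getV(i, fp[i]);
      if (v < INF / 2) {
        double w = getW(fp[i] + 1, j);
        if (w < INF / 2) best = v + w;
      }
    }
  } else {
    double w = getW(i + 1, j);           // i unpaired
    if (w < INF / 2) best = w;
    for (int k = i + 1; k <= j; ++k) {
      double v = getV(i, k);
      if (v >= INF / 2) continue;
      double wr = getW(k + 1, j);
      if (wr >= INF / 2) continue;
      best = std::min(best, v + wr);
    }
  }
  doneW[i][j] = 1; W[i][j] = best;
  return best;
}

double Fold::getWne(int i, int j) {
  if (i > j) return INF;
  if (doneWne[i][j]) return Wne[i][j];
  double best = INF;
  if (fp[i] != -1) {
    if (fp[i] > i && fp[i] <= j) {
      double v = getV(i, fp[i]);
      if (v < INF / 2) {
        double w = getW(fp[i] + 1, j);
        if (w < INF / 2) best = v + w;
      }
    }
  } else {
    double w = getWne(i + 1, j);
    if (w < INF / 2) best = w;
    for (int k = i + 1; k <= j; ++k) {
      double v = getV(i, k);
      if (v >= INF / 2) continue;
      double wr = getW(k + 1, j);
      if (wr >= INF / 2) continue;
      best = std::min(best, v + wr);
    }
  }
  doneWne[i][j] = 1; Wne[i][j] = best;
  return best;
}

static void consider(std::string &best, const std::string &cand) {
  if (best.empty() || cand < best) best = cand;
}

std::string Fold::strV(int i, int j) {
  auto key = std::make_pair(i, j);
  auto it = memV.find(key);
  if (it != memV.end()) return it->second;
  double target = getV(i, j);
  std::string best;
  if (hairpinOK(i, j) && 0.0 <= target + EPS)
    consider(best, "(" + std::string(j - i - 1, '.') + ")");
  if (pairable(i + 1, j - 1) && stackOK(i, j)) {
    double e = getV(i + 1, j - 1);
    if (e < INF / 2 && std::abs(e + stackVal(i, j) - target) < EPS)
      consider(best, "(" + strV(i + 1, j - 1) + ")");
  }
  double ene = getWne(i + 1, j - 1);
  if (ene < INF / 2 && std::abs(ene - target) < EPS)
    consider(best, "(" + strWne(i + 1, j - 1) + ")");
  memV[key] = best;
  return best;
}

std::string Fold::strW(int i, int j) {
  if (i > j) return "";
  auto key = std::make_pair(i, j);
  auto it = memW.find(key);
  if (it != memW.end()) return it->second;
  double target = getW(i, j);
  std::string best;
  if (fp[i] != -1) {
    best = strV(i, fp[i]) + strW(fp[i] + 1, j);
  } else {
    if (getW(i + 1, j) < INF / 2 && std::abs(getW(i + 1, j) - target) < EPS) {
      // '.' at i loses to any '(' candidate; only also consider pairings
      consider(best, "." + strW(i + 1, j));
    }
    for (int k = i + 1; k <= j; ++k) {
      double v = getV(i, k);
      if (v >= INF / 2) continue;
      double wr = getW(k + 1, j);
      if (wr >= INF / 2) continue;
      if (std::abs(v + wr - target) < EPS)
        consider(best, strV(i, k) + strW(k + 1, j));
    }
  }
  memW[key] = best;
  return best;
}

std::string Fold::strWne(int i, int j) {
  auto key = std::make_pair(i, j);
  auto it = memWne.find(key);
  if (it != memWne.end()) return it->second;
  double target = getWne(i, j);
  std::string best;
  if (fp[i] != -1) {
    best = strV(i, fp[i]) + strW(fp[i] + 1, j);
  } else {
    double w = getWne(i + 1, j);
    if (w < INF / 2 && std::abs(w - target) < EPS)
      consider(best, "." + strWne(i + 1, j));
    for (int k = i + 1; k <= j; ++k) {
      double v = getV(i, k);
      if (v >= INF / 2) continue;
      double wr = getW(k + 1, j);
      if (wr >= INF / 2) continue;
      if (std::abs(v + wr - target) < EPS)
        consider(best, strV(i, k) + strW(k + 1, j));
    }
  }
  memWne[key] = best;
  return best;
}

// [[Rcpp::export]]
List fold_engine_cpp(IntegerVector seq_codes,
                     IntegerVector cuts,
                     LogicalVector forced_unpaired,
                     IntegerVector forced_partner,
                     LogicalMatrix can_pair,
                     NumericMatrix stack_table,
                     int hairpin_min,
                     bool want_structure) {
  Fold f;
  f.n = seq_codes.size();
  f.hairpin_min = hairpin_min;
  f.s.assign(f.n, 0);
  for (int i = 0; i < f.n; ++i) f.s[i] = seq_codes[i];
  f.cutAt.assign(f.n, false);
  for (int k = 0; k < cuts.size(); ++k) {
    int c = cuts[k];
    if (c > 0 && c < f.n) f.cutAt[c] = true;
  }
  f.unp.assign(f.n, false);
  f.fp.assign(f.n, -1);
  for (int i = 0; i < f.n; ++i) {
    f.unp[i] = forced_unpaired[i];
    f.fp[i] = forced_partner[i];
  }
  f.canPair.assign(4, std::vector<bool>(4, false));
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      f.canPair[a][b] = can_pair(a, b);
  f.stackE.assign(16, std::vector<double>(16, 0.0));
  for (int a = 0; a < 16; ++a)
    for (int b = 0; b < 16; ++b)
      f.stackE[a][b] = stack_table(a, b);

  if (f.n == 0)
    return List::create(_["energy"] = 0.0, _["structure"] = "",
                        _["feasible"] = true);

  f.W.assign(f.n, std::vector<double>(f.n, 0.0));
  f.V.assign(f.n, std::vector<double>(f.n, 0.0));
  f.Wne.assign(f.n, std::vector<double>(f.n, 0.0));
  f.doneW.assign(f.n, std::vector<char>(f.n, 0));
  f.doneV.assign(f.n, std::vector<char>(f.n, 0));
  f.doneWne.assign(f.n, std::vector<char>(f.n, 0));

  double e = f.getW(0, f.n - 1);
  if (e >= INF / 2)
    return List::create(_["energy"] = NA_REAL, _["structure"] = NA_STRING,
                        _["feasible"] = false);
  if (!want_structure)
    return List::create(_["energy"] = e, _["structure"] = NA_STRING,
                        _["feasible"] = true);
  std::string db = f.strW(0, f.n - 1);
  return List::create(_["energy"] = e, _["structure"] = db,
                      _["feasible"] = true);
}
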