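#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direction offsets (drow, dcol) at unit step for 0, 45, 90, 135 degrees.
// Pairs are accumulated symmetrically so the sign convention is immaterial.
static const int DIRS[4][2] = { {0, 1}, {-1, 1}, {-1, 0}, {-1, -1} };

struct WinFeat {
  double mea, var, hom, con, dis, ent, sec, cor;
  bool corDefined;
};

// GLCM features for one window and one direction. Gray levels are 0-based
// (NA_INTEGER = invalid pixel); the feature formulas index levels 1..G.
// Returns false when the window holds no valid pixel pair for the direction.
static bool directionFeatures(const int* q, int nr,
                              int r0, int c0, int win,
                              int drow, int dcol, int G,
                              int* codes, WinFeat& out) {
  int nCodes = 0;
  const int rlo = std::max(r0, r0 - drow), rhi = std::min(r0 + win, r0 + win - drow);
  const int clo = std::max(c0, c0 - dcol), chi = std::min(c0 + win, c0 + win - dcol);
  for (int c = clo; c < chi; ++c) {
    const int* col = q + (size_t)c * nr;
    const int* colp = q + (size_t)(c + dcol) * nr;
    for (int r = rlo; r < rhi; ++r) {
      int a = col[r], b = colp[r + drow];
      if (a == NA_INTEGER || b == NA_INTEGER) continue;
      codes[nCodes++] = a * G + b;   // symmetric: both orderings
      codes[nCodes++] = b * G + a;
    }
  }
  if (nCodes == 0) return false;
  const double T = (double)nCodes;

  double mea = 0.0;
  for (int k = 0; k < nCodes; ++k) mea += (codes[k] / G) + 1;
  mea /= T;

  double var = 0.0, hom = 0.0, con = 0.0, dis = 0.0, corNum = 0.0;
  for (int k = 0; k < nCodes; ++k) {
    double i = (codes[k] / G) + 1, j = (codes[k] % G) + 1;
    double di = i - mea, dij = i - j;
    var += di * di;
    hom += 1.0 / (1.0 + dij * dij);
    con += dij * dij;
    dis += std::fabs(dij);
    corNum += di * (j - mea);
  }
  var /= T; hom /= T; con /= T; dis /= T; corNum /= T;

  // ENT and SEC need cell probabilities: group identical codes
  std::sort(codes, codes + nCodes);
  double ent = 0.0, sec = 0.0;
  int k = 0;
  while (k < nCodes) {
    int k2 = k;
    while (k2 < nCodes && codes[k2] == codes[k]) ++k2;
    double p = (double)(k2 - k) / T;
    sec += p * p;
    ent -= p * std::log(p);
    k = k2;
  }

  out.mea = mea; out.var = var; out.hom = hom; out.con = con;
  out.dis = dis; out.ent = ent; out.sec = sec;
  if (var > 0.0) { out.cor = corNum / var; out.corDefined = true; }
  else           { out.cor = 0.0;          out.corDefined = false; }
  return true;
}

//' @title Windowed GLCM texture features for one quantized band (C++ kernel)
//' @description Internal. Slides a square window over the quantized grid,
//'   builds the symmetric GLCM per direction, averages the eight texture
//'   metrics over the four directions per window, and averages admissible
//'   windows over the plot. Windows must contain at least
//'   `minValidFrac` valid pixels and at least one valid pair in every
//'   direction; window COR enters the plot mean only when defined (nonzero
//'   GLCM variance) in all four directions.
//' @keywords internal
//' @noRd
// [[Rcpp::export(name = ".cppBandTextures")]]
List cppBandTextures(IntegerMatrix qm, int G, int win, int offset,
                     double minValidFrac) {
  const int nr = qm.nrow(), nc = qm.ncol();
  const int minValid = (int)std::ceil(minValidFrac * win * win);
  const int* q = qm.begin();
  std::vector<int> codebuf(4 * (size_t)win * win + 8);
  int* codes = codebuf.data();

  // per-column count of valid pixels inside a sliding row-band, used for
  // the window validity fraction without rescanning 25 pixels per window
  std::vector<int> colValid(nc, 0);

  double sums[7] = {0, 0, 0, 0, 0, 0, 0};
  double corSum = 0.0;
  long nWin = 0, nCorWin = 0;

  for (int r0 = 0; r0 + win <= nr; ++r0) {
    for (int c = 0; c < nc; ++c) {
      const int* col = q + (size_t)c * nr;
      if (r0 == 0) {
        int cnt = 0;
        for (int r = 0; r < win; ++r) cnt += (col[r] != NA_INTEGER);
        colValid[c] = cnt;
      } else {
        colValid[c] += (col[r0 + win - 1] != NA_INTEGER) -
                       (col[r0 - 1] != NA_INTEGER);
      }
    }
    int bandValid = 0;
    for (int c = 0; c < win; ++c) bandValid += colValid[c];
    for (int c0 = 0; c0 + win <= nc; ++c0) {
      if (c0 > 0) bandValid += colValid[c0 + win - 1] - colValid[c0 - 1];
      if (bandValid < minValid) continue;

      WinFeat f[4];
      bool ok = true;
      for (int d = 0; d < 4 && ok; ++d)
        ok = directionFeatures(q, nr, r0, c0, win,
                               DIRS[d][0] * offset, DIRS[d][1] * offset,
                               G, codes, f[d]);
      if (!ok) continue;

      sums[0] += (f[0].mea + f[1].mea + f[2].mea + f[3].mea) / 4.0;
      sums[1] += (f[0].var + f[1].var + f[2].var + f[3].var) / 4.0;
      sums[2] += (f[0].hom + f[1].hom + f[2].hom + f[3].hom) / 4.0;
      sums[3] += (f[0].con + f[1].con + f[2].con + f[3].con) / 4.0;
      sums[4] += (f[0].dis + f[1].dis + f[2].dis + f[3].dis) / 4.0;
      sums[5] += (f[0].ent + f[1].ent + f[2].ent + f[3].ent) / 4.0;
      sums[6] += (f[0].sec + f[1].sec + f[2].sec + f[3].sec) / 4.0;
      if (f[0].corDefined && f[1].corDefined && f[2].corDefined &&
          f[3].corDefined) {
        corSum += (f[0].cor + f[1].cor + f[2].cor + f[3].cor) / 4.0;
        ++nCorWin;
      }
      ++nWin;
    }
  }

  NumericVector feat(8, NA_REAL);
  feat.names() = CharacterVector::create("MEA", "VAR", "HOM", "CON",
                                         "DIS", "ENT", "SEC", "COR");
  if (nWin > 0) {
    for (int m = 0; m < 7; ++m) feat[m] = sums[m] / nWin;
    feat[7] = (nCorWin > 0) ? corSum / nCorWin : NA_REAL;
  }
  return List::create(_["features"] = feat,
                      _["nWindows"] = (double)nWin,
                      _["nCorWindows"] = (double)nCorWin);
}
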