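#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment with traceback.
// Gap of length L costs gap_open + L * gap_extend (BLAST-style accounting).
// Sequences arrive integer-encoded (1-based indices into `submat`).

static const int ST_M = 0, ST_X = 1, ST_Y = 2; // X: gap in b, Y: gap in a

// [[Rcpp::export]]
List gotoh_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
               double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gapfirst = gap_open + gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: for each state, which state we came from (or -1 for stop)
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i) {
    M(i, 0) = (i == 0) ? 0.0 : NEG;
    X(i, 0) = local ? NEG : (i == 0 ? NEG : -(gap_open + i * gap_extend));
    Y(i, 0) = NEG;
    tX(i, 0) = ST_X;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = local ? NEG : -(gap_open + j * gap_extend);
    tY(0, j) = ST_Y;
  }

  double best = 0.0; int bi = 0, bj = 0, bstate = ST_M;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      // M
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double dbest = dM; int dfrom = ST_M;
      if (dX > dbest) { dbest = dX; dfrom = ST_X; }
      if (dY > dbest) { dbest = dY; dfrom = ST_Y; }
      if (local && 0.0 > dbest) { dbest = 0.0; dfrom = -1; }
      M(i, j) = dbest + s; tM(i, j) = dfrom;
      // X: consume a[i], gap in b
      double xo = M(i - 1, j) - gapfirst, xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = ST_M; }
      else          { X(i, j) = xe; tX(i, j) = ST_X; }
      // Y: consume b[j], gap in a
      double yo = M(i, j - 1) - gapfirst, ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = ST_M; }
      else          { Y(i, j) = ye; tY(i, j) = ST_Y; }
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; bstate = ST_M; }
    }
  }

  if (!local) {
    best = M(n, m); bstate = ST_M;
    if (X(n, m) > best) { best = X(n, m); bstate = ST_X; }
    if (Y(n, m) > best) { best = Y(n, m); bstate = ST_Y; }
    bi = n; bj = m;
  }

  // traceback; emit aligned index vectors, 0 marks a gap
  std::vector<int> ra, rb;
  int i = bi, j = bj, st = bstate;
  if (!(local && best <= 0.0)) {
    while (i > 0 || j > 0) {
      if (local && st == ST_M && tM(i, j) == -1) { ra.push_back(i); rb.push_back(j); --i; --j; break; }
      if (st == ST_M) {
        if (i == 0 || j == 0) break;
        int from = tM(i, j);
        ra.push_back(i); rb.push_back(j); --i; --j; st = from;
        if (local && st == -1) break;
      } else if (st == ST_X) {
        int from = tX(i, j);
        ra.push_back(i); rb.push_back(0); --i; st = from;
      } else {
        int from = tY(i, j);
        ra.push_back(0); rb.push_back(j); --j; st = from;
      }
      if (local && i == 0 && j == 0) break;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = local ? std::max(best, 0.0) : best,
                      _["a_pos"] = IntegerVector(ra.begin(), ra.end()),
                      _["b_pos"] = IntegerVector(rb.begin(), rb.end()));
}
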