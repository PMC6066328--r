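#include <Rcpp.h>
using namespace Rcpp;

// Sum of squared orthogonal distances from the (z, F) data points to the
// tether model polyline {(n*phi_j + F_j/kc + offset, F_j)}. The polyline is
// dense enough (a few hundred nodes) that projecting each data point onto the
// segments adjacent to its nearest node gives the orthogonal distance to the
// smooth curve to high accuracy. Hot loop of the total-least-squares fit.

// [[Rcpp::export]]
double tls_rss(double n, double offset, NumericVector zd, NumericVector fd,
               NumericVector fgrid, NumericVector phigrid, double kc) {
  const int g = fgrid.size();
  const int m = zd.size();
  std::vector<double> zg(g);
  for (int j = 0; j < g; ++j)
    zg[j] = n * phigrid[j] + fgrid[j] / kc + offset;

  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    const double zi = zd[i], fi = fd[i];
    double best = R_PosInf;
    int kbest = 0;
    for (int j = 0; j < g; ++j) {
      const double dz = zg[j] - zi;
      const double df = fgrid[j] - fi;
      const double d2 = dz * dz + df * df;
      if (d2 < best) { best = d2; kbest = j; }
    }
    // project onto the segments on either side of the nearest node
    const int lo = kbest > 0 ? kbest - 1 : 0;
    const int hi = kbest < g - 1 ? kbest : g - 2;
    for (int j = lo; j <= hi; ++j) {
      const double ax = zg[j], ay = fgrid[j];
      const double bx = zg[j + 1], by = fgrid[j + 1];
      const double vx = bx - ax, vy = by - ay;
      const double len2 = vx * vx + vy * vy;
      if (len2 <= 0.0) continue;
      double t = ((zi - ax) * vx + (fi - ay) * vy) / len2;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      const double px = ax + t * vx - zi;
      const double py = ay + t * vy - fi;
      const double d2 = px * px + py * py;
      if (d2 < best) best = d2;
    }
    total += best;
  }
  return total;
}
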