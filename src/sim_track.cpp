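#include <Rcpp.h>
using namespace Rcpp;

// Step-by-step telemetry simulator.
//
// phase[i] codes the regime available when moving towards fix i+1:
//   0 = encamped only (residency or off-season)
//   1 = spring movement window (score_spring drives travel-step selection)
//   2 = autumn movement window (score_autumn)
//
// Encamped steps: exponential length (mean enc_len), uniform heading.
// Travel steps: K candidate endpoints with exponential lengths (mean
// trav_len) and forward-concentrated turns (wrapped-normal sd turn_sd,
// radians, relative to the previous heading); one candidate is selected
// with probability proportional to exp(score(endpoint)), the same
// exponential form the step selection function assumes.
//
// Returns an (n x 3) matrix: x, y, regime (0 encamped, 1 travel).
// [[Rcpp::export]]
NumericMatrix sim_track_cpp(NumericMatrix score_spring,
                            NumericMatrix score_autumn,
                            IntegerVector phase,
                            double startx, double starty,
                            double x0, double y0, double cs,
                            int K, double p_travel,
                            double enc_len, double trav_len,
                            double turn_sd, int max_redraw) {
  int nr = score_spring.nrow(), nc = score_spring.ncol();
  int n = phase.size() + 1;  // fixes = steps + 1
  NumericMatrix out(n, 3);

  auto cell_score = [&](double x, double y, int ph, bool &ok) -> double {
    int col = (int)std::floor((x - x0) / cs);
    int row = (int)std::floor((y0 - y) / cs);
    if (row < 0 || row >= nr || col < 0 || col >= nc) { ok = false; return 0.0; }
    double s = (ph == 2) ? score_autumn(row, col) : score_spring(row, col);
    if (NumericMatrix::is_na(s)) { ok = false; return 0.0; }
    ok = true;
    return s;
  };

  double x = startx, y = starty;
  double heading = R::runif(0.0, 2.0 * M_PI);
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = NA_REAL;

  std::vector<double> cx(K), cy(K), cang(K), w(K);

  for (int i = 1; i < n; ++i) {
    int ph = phase[i - 1];
    bool travel = (ph > 0) && (R::runif(0.0, 1.0) < p_travel);
    if (!travel) {
      // encamped: short undirected move, stay put if no valid endpoint
      bool moved = false;
      for (int r = 0; r < max_redraw; ++r) {
        double len = R::rexp(enc_len);
        double ang = R::runif(0.0, 2.0 * M_PI);
        double nx = x + len * std::cos(ang), ny = y + len * std::sin(ang);
        bool ok;
        cell_score(nx, ny, ph, ok);
        if (ok) { x = nx; y = ny; heading = ang; moved = true; break; }
      }
      (void)moved;
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = 0.0;
    } else {
      double smax = R_NegInf;
      int nvalid = 0;
      for (int k = 0; k < K; ++k) {
        double len = R::rexp(trav_len);
        double ang = heading + R::rnorm(0.0, turn_sd);
        cx[k] = x + len * std::cos(ang);
        cy[k] = y + len * std::sin(ang);
        cang[k] = ang;
        bool ok;
        double s = cell_score(cx[k], cy[k], ph, ok);
        if (ok) { w[k] = s; if (s > smax) smax = s; ++nvalid; }
        else w[k] = R_NegInf;
      }
      if (nvalid == 0) {
        // boxed in: fall back to an encamped move
        out(i, 0) = x; out(i, 1) = y; out(i, 2) = 0.0;
        continue;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = std::isfinite(w[k]) ? std::exp(w[k] - smax) : 0.0;
        tot += w[k];
      }
      double u = R::runif(0.0, tot), acc = 0.0;
      int pick = 0;
      for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) { pick = k; break; } }
      x = cx[pick]; y = cy[pick]; heading = cang[pick];
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = 1.0;
    }
  }
  return out;
}
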