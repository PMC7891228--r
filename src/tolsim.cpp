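#include <Rcpp.h>
using namespace Rcpp;

// Toroidal wrap of a coordinate into [0, side).
static inline double wrap_coord(double v, double side) {
    v -= side * std::floor(v / side);
    if (v >= side) v = 0.0;  // guard against floating-point edge
    return v;
}

// One forager's annual foray: a random walk of `steps` steps of length
// `step_len`, with a hunt attempt at the end of each step.  An attempt in a
// cell holding n animals succeeds with probability n / (n + halfsat); a
// success removes one animal from the cell (only possible while n >= 1, so
// cells never go negative) and yields one food unit.  Mutates `cells`;
// start position is updated in place to the foray's end point.
static int foray_impl(NumericMatrix &cells, double &x, double &y,
                      int steps, double step_len, double halfsat) {
    const int side = cells.nrow();
    const double dside = (double) side;
    int harvest = 0;
    for (int s = 0; s < steps; ++s) {
        double ang = unif_rand() * 2.0 * M_PI;
        x = wrap_coord(x + step_len * std::cos(ang), dside);
        y = wrap_coord(y + step_len * std::sin(ang), dside);
        int ix = (int) std::floor(x); if (ix >= side) ix = side - 1;
        int iy = (int) std::floor(y); if (iy >= side) iy = side - 1;
        double n = cells(ix, iy);
        double u = unif_rand();
        if (n >= 1.0 && u * (n + halfsat) < n) {
            cells(ix, iy) = n - 1.0;
            ++harvest;
        }
    }
    return harvest;
}

// [[Rcpp::export]]
List foray_cpp(NumericMatrix cells, double x0, double y0, int steps,
               double step_len, double halfsat) {
    double x = x0, y = y0;
    int h = foray_impl(cells, x, y, steps, step_len, halfsat);
    return List::create(_["harvest"] = h, _["x"] = x, _["y"] = y);
}

// Run every eligible hunter's foray in individual order.  `hunter_gidx` holds
// 1-based indices into the group vectors; `cells` is mutated in place.
// Returns per-group harvest totals and each hunter's end position.
// [[Rcpp::export]]
List hunt_cpp(NumericMatrix cells, NumericVector gx, NumericVector gy,
              IntegerVector hunter_gidx, int steps, double step_len,
              double halfsat) {
    const int nh = hunter_gidx.size();
    const int ng = gx.size();
    NumericVector harvest(ng);
    NumericVector fx(nh), fy(nh);
    for (int i = 0; i < nh; ++i) {
        int g = hunter_gidx[i] - 1;
        double x = gx[g], y = gy[g];
        harvest[g] += foray_impl(cells, x, y, steps, step_len, halfsat);
        fx[i] = x;
        fy[i] = y;
    }
    return List::create(_["harvest"] = harvest, _["x"] = fx, _["y"] = fy);
}
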