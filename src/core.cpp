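#include <Rcpp.h>
using namespace Rcpp;

// Frame-level position generator for one session.
//
// state codes per frame: 0 = immobile (head/tail wobble), 1 = freeze
// (all points held), 2 = mobile (correlated random walk).
// speed_scale is the per-frame effective log-normal scale in cm/s (already
// includes pharmacodynamic suppression). All randomness comes from R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix sim_walk_core(IntegerVector state, NumericVector speed_scale,
                            double dt, double side, double turn_sd,
                            double thigmo, double sdlog, double posture_noise,
                            double body_length, double x0, double y0,
                            double h0) {
  int n = state.size();
  NumericMatrix out(n, 6); // head_x head_y center_x center_y tail_x tail_y
  double x = x0, y = y0, h = h0;
  double half = body_length / 2.0;
  double hx = 0, hy = 0, tx = 0, ty = 0;
  bool frozen_prev = false;

  for (int i = 0; i < n; ++i) {
    int s = state[i];
    if (s == 2) { // mobile: turn, pull toward nearest corner, step, reflect
      double cx = (x < side / 2.0) ? 0.0 : side;
      double cy = (y < side / 2.0) ? 0.0 : side;
      double target = std::atan2(cy - y, cx - x);
      double pull = std::sin(target - h);
      h += R::rnorm(0.0, turn_sd) + thigmo * pull * dt;
      double speed = std::exp(R::rnorm(std::log(speed_scale[i]), sdlog));
      double step = speed * dt;
      x += std::cos(h) * step;
      y += std::sin(h) * step;
      // reflecting walls (repeat in case a long step crosses twice)
      for (int k = 0; k < 4; ++k) {
        bool moved = false;
        if (x < 0)    { x = -x;            h = M_PI - h; moved = true; }
        if (x > side) { x = 2 * side - x;  h = M_PI - h; moved = true; }
        if (y < 0)    { y = -y;            h = -h;       moved = true; }
        if (y > side) { y = 2 * side - y;  h = -h;       moved = true; }
        if (!moved) break;
      }
      if (x < 0) x = 0; if (x > side) x = side;
      if (y < 0) y = 0; if (y > side) y = side;
      hx = x + half * std::cos(h) + R::rnorm(0.0, posture_noise);
      hy = y + half * std::sin(h) + R::rnorm(0.0, posture_noise);
      tx = x - half * std::cos(h);
      ty = y - half * std::sin(h);
      frozen_prev = false;
    } else if (s == 1) { // freeze: everything held from the first freeze frame
      if (!frozen_prev) {
        hx = x + half * std::cos(h);
        hy = y + half * std::sin(h);
        tx = x - half * std::cos(h);
        ty = y - half * std::sin(h);
        frozen_prev = true;
      }
    } else { // immobile, non-freeze: center fixed, head and tail wobble
      hx = x + half * std::cos(h) + R::rnorm(0.0, posture_noise);
      hy = y + half * std::sin(h) + R::rnorm(0.0, posture_noise);
      tx = x - half * std::cos(h) + R::rnorm(0.0, posture_noise);
      ty = y - half * std::sin(h) + R::rnorm(0.0, posture_noise);
      frozen_prev = false;
    }
    // keep all tracked points inside the arena
    double chx = std::min(std::max(hx, 0.0), side);
    double chy = std::min(std::max(hy, 0.0), side);
    double ctx = std::min(std::max(tx, 0.0), side);
    double cty = std::min(std::max(ty, 0.0), side);
    out(i, 0) = chx; out(i, 1) = chy;
    out(i, 2) = x;   out(i, 3) = y;
    out(i, 4) = ctx; out(i, 5) = cty;
  }
  return out;
}

// Signed full-turn counter: accumulate heading increments; every time the
// accumulator reaches +/- 2*pi, record one rotation of that sign and ratchet
// the accumulator back by 2*pi.
// [[Rcpp::export]]
IntegerVector count_rotations_core(NumericVector dtheta) {
  double acc = 0.0;
  int cw = 0, ccw = 0;
  // tiny tolerance so an exact full turn accumulated in floating point
  // (e.g. 180 steps of 4 degrees) still counts
  const double two_pi = 2.0 * M_PI;
  const double full = two_pi - 1e-9;
  int n = dtheta.size();
  for (int i = 0; i < n; ++i) {
    acc += dtheta[i];
    while (acc >= full)  { ++ccw; acc -= two_pi; }
    while (acc <= -full) { ++cw;  acc += two_pi; }
  }
  return IntegerVector::create(_["cw"] = cw, _["ccw"] = ccw);
}
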