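#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler loop for the two-cluster spindle model.
//
// Per step: attraction of each cluster to its fixed cortical anchor
// (soft-core well, minimum at ra), shared elastic restoring force k*w
// from spindle deflection, overdamped velocity (fV+fE)/damping, Euler
// update, per-coordinate Gaussian positional noise of SD sigma, exact
// re-projection of the cluster pair to chord length Lc, containment of
// both clusters inside the disc |x| <= R by a midpoint shift that
// preserves the chord, prescribed advance of the central-spindle point
// c by ucyto*dt along the ingression direction, and continuity-based
// update of that direction (chord normal with positive dot against the
// previous one).
//
// Noise uses R's RNG (R::norm_rand) so seeded runs are reproducible
// from set.seed() on the R side.

static inline double attr_deriv(double r, double A, double lam, double ra) {
  // dV/dr for V(r) = -A*(r - ra + lam)*exp(-r/lam)
  return -A * std::exp(-r / lam) * (ra - r) / lam;
}

// [[Rcpp::export]]
List sim_core(NumericVector x1_, NumericVector x2_, NumericVector c_,
              NumericVector a1_, NumericVector a2_, NumericVector dir_,
              double t0, double A, double lam, double ra, double k,
              double damping, double ucyto, double sigma, double dt,
              double tmax, double R, double Lc,
              double alpha_stop_deg, double r_escape, int thin,
              bool early_stop) {
  double x1x = x1_[0], x1y = x1_[1], x2x = x2_[0], x2y = x2_[1];
  double cx = c_[0], cy = c_[1];
  double a1x = a1_[0], a1y = a1_[1], a2x = a2_[0], a2y = a2_[1];
  double dirx = dir_[0], diry = dir_[1];
  double t = t0;

  long nmax = (long)std::ceil((tmax - t0) / dt + 0.5);
  if (nmax < 0) nmax = 0;
  long ncap = nmax / thin + 3;
  NumericMatrix rec(ncap, 7); // t, x1x, x1y, x2x, x2y, cx, cy
  long nrec = 0;
  double max_dr = 0.0;
  int reason = 0; // 0 = tmax, 1 = alpha below threshold, 2 = escape

  auto record = [&](void) {
    rec(nrec, 0) = t;
    rec(nrec, 1) = x1x; rec(nrec, 2) = x1y;
    rec(nrec, 3) = x2x; rec(nrec, 4) = x2y;
    rec(nrec, 5) = cx;  rec(nrec, 6) = cy;
    ++nrec;
  };
  record();

  long step = 0;
  while (t < tmax - 1e-12) {
    // forces at current state
    double r1dx = x1x - a1x, r1dy = x1y - a1y;
    double r2dx = x2x - a2x, r2dy = x2y - a2y;
    double r1 = std::sqrt(r1dx * r1dx + r1dy * r1dy);
    double r2 = std::sqrt(r2dx * r2dx + r2dy * r2dy);
    double f1x = 0.0, f1y = 0.0, f2x = 0.0, f2y = 0.0;
    if (r1 > 0.0) {
      double g = -attr_deriv(r1, A, lam, ra) / r1; // force along u_r
      f1x = g * r1dx; f1y = g * r1dy;
    }
    if (r2 > 0.0) {
      double g = -attr_deriv(r2, A, lam, ra) / r2;
      f2x = g * r2dx; f2y = g * r2dy;
    }
    // elastic force: k * perpendicular deflection of c from the chord
    double mx = 0.5 * (x1x + x2x), my = 0.5 * (x1y + x2y);
    double chx = x2x - x1x, chy = x2y - x1y;
    double chn = std::sqrt(chx * chx + chy * chy);
    double ux = chx / chn, uy = chy / chn;
    double wx = cx - mx, wy = cy - my;
    double wpar = wx * ux + wy * uy;
    double wpx = wx - wpar * ux, wpy = wy - wpar * uy;
    double fex = k * wpx, fey = k * wpy;

    // Euler update of cluster positions
    double inv = dt / damping;
    x1x += (f1x + fex) * inv; x1y += (f1y + fey) * inv;
    x2x += (f2x + fex) * inv; x2y += (f2y + fey) * inv;

    // positional noise, per coordinate, SD sigma per step
    if (sigma > 0.0) {
      x1x += sigma * R::norm_rand(); x1y += sigma * R::norm_rand();
      x2x += sigma * R::norm_rand(); x2y += sigma * R::norm_rand();
    }

    // re-project pair to fixed chord length about its midpoint
    mx = 0.5 * (x1x + x2x); my = 0.5 * (x1y + x2y);
    chx = x2x - x1x; chy = x2y - x1y;
    chn = std::sqrt(chx * chx + chy * chy);
    if (!(chn > 0.0)) stop("coincident clusters at step %ld", step);
    ux = chx / chn; uy = chy / chn;
    double h = 0.5 * Lc;
    // containment: scale the midpoint toward the origin so that both
    // endpoints mid +/- h*u stay inside |x| <= R; chord is preserved.
    double m2 = mx * mx + my * my;
    double md = std::fabs(mx * ux + my * uy);
    if (m2 + 2.0 * h * md + h * h > R * R && m2 > 0.0) {
      double disc = h * h * md * md + m2 * (R * R - h * h);
      double s = (-h * md + std::sqrt(disc)) / m2;
      if (s < 0.0) s = 0.0;
      if (s < 1.0) { mx *= s; my *= s; }
    }
    x1x = mx - h * ux; x1y = my - h * uy;
    x2x = mx + h * ux; x2y = my + h * uy;

    // prescribed ingression of the central-spindle point
    cx += ucyto * dt * dirx;
    cy += ucyto * dt * diry;

    // ingression direction: chord normal, continuity of orientation
    double nx = -uy, ny = ux;
    if (nx * dirx + ny * diry < 0.0) { nx = -nx; ny = -ny; }
    dirx = nx; diry = ny;

    t = t0 + (++step) * dt;

    if (!std::isfinite(x1x) || !std::isfinite(x1y) ||
        !std::isfinite(x2x) || !std::isfinite(x2y))
      stop("non-finite cluster position at step %ld", step);

    if (step % thin == 0 || t >= tmax - 1e-12) record();

    // bookkeeping for outcome classification and early termination
    r1dx = x1x - a1x; r1dy = x1y - a1y;
    r2dx = x2x - a2x; r2dy = x2y - a2y;
    r1 = std::sqrt(r1dx * r1dx + r1dy * r1dy);
    r2 = std::sqrt(r2dx * r2dx + r2dy * r2dy);
    double dr = std::fabs(r1 - r2);
    if (dr > max_dr) max_dr = dr;

    if (early_stop) {
      // provisional internalized cluster = larger cortex distance
      double d1 = R - std::sqrt(x1x * x1x + x1y * x1y);
      double d2 = R - std::sqrt(x2x * x2x + x2y * x2y);
      double ix = (d1 >= d2) ? x1x : x2x;
      double iy = (d1 >= d2) ? x1y : x2y;
      double v1x = ix - mx, v1y = iy - my;
      double v2x = -mx, v2y = -my;
      double n1 = std::sqrt(v1x * v1x + v1y * v1y);
      double n2 = std::sqrt(v2x * v2x + v2y * v2y);
      if (n1 > 0.0 && n2 > 0.0) {
        double cosb = (v1x * v2x + v1y * v2y) / (n1 * n2);
        if (cosb > 1.0) cosb = 1.0;
        if (cosb < -1.0) cosb = -1.0;
        double alpha = std::acos(cosb) * 180.0 / M_PI;
        if (alpha < alpha_stop_deg) { reason = 1; if (step % thin != 0) record(); break; }
      }
      if (r1 > r_escape || r2 > r_escape) { reason = 2; if (step % thin != 0) record(); break; }
    }
  }

  NumericMatrix out(nrec, 7);
  for (long i = 0; i < nrec; ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = rec(i, j);

  return List::create(
    _["frames"] = out,
    _["x1"] = NumericVector::create(x1x, x1y),
    _["x2"] = NumericVector::create(x2x, x2y),
    _["c"] = NumericVector::create(cx, cy),
    _["dir"] = NumericVector::create(dirx, diry),
    _["t"] = t,
    _["max_dr"] = max_dr,
    _["steps"] = (double)step,
    _["reason"] = reason);
}
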