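// Lagrangian tracker for neutrally buoyant algal-cell surrogates.
//
// Integrates dv/dt = C |u_f - v| (u_f - v) + r * (u . grad)u with the
// fluid velocity u_f = mean flow (bilinear) + discrete-random-walk
// fluctuation, classical RK4 with deterministic stability substepping
// (quadratic drag of 10 um particles is stiff: the linearised drag rate
// is 2 C |slip|). Walls reflect specularly. Uses R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Grid {
  const double *ud, *ul, *k, *eps;
  double d0, l0, h;
  int nd, nl;

  inline void locate(double dep, double lat, int &i0, int &j0,
                     double &wi, double &wj) const {
    double fi = (dep - d0) / h, fj = (lat - l0) / h;
    i0 = (int)std::floor(fi); j0 = (int)std::floor(fj);
    if (i0 < 0) i0 = 0; if (i0 > nd - 2) i0 = nd - 2;
    if (j0 < 0) j0 = 0; if (j0 > nl - 2) j0 = nl - 2;
    wi = fi - i0; wj = fj - j0;
    if (wi < 0) wi = 0; if (wi > 1) wi = 1;
    if (wj < 0) wj = 0; if (wj > 1) wj = 1;
  }
  inline double bilin(const double *m, int i0, int j0, double wi,
                      double wj) const {
    const double a = m[(size_t)j0 * nd + i0], b = m[(size_t)j0 * nd + i0 + 1];
    const double c = m[(size_t)(j0 + 1) * nd + i0],
                 d = m[(size_t)(j0 + 1) * nd + i0 + 1];
    return a * (1 - wi) * (1 - wj) + b * wi * (1 - wj) + c * (1 - wi) * wj +
           d * wi * wj;
  }
  // gradient of the bilinear patch itself (per metre, with h in mm), so
  // the material acceleration is exactly consistent with the velocity the
  // particle is advected by
  inline void patch_grad(const double *m, int i0, int j0, double wi,
                         double wj, double &gd, double &gl) const {
    const double a = m[(size_t)j0 * nd + i0], b = m[(size_t)j0 * nd + i0 + 1];
    const double c = m[(size_t)(j0 + 1) * nd + i0],
                 d = m[(size_t)(j0 + 1) * nd + i0 + 1];
    gd = ((b - a) * (1 - wj) + (d - c) * wj) / h * 1000.0;
    gl = ((c - a) * (1 - wi) + (d - b) * wi) / h * 1000.0;
  }
};

struct Geometry {
  int layout;  // 1 plain, 2 concentric, 3 tangent
  double outer_r, inner_r, inner_cd;
  bool fillet;
  double chord_depth;

  inline bool inside(double dep, double lat) const {
    if (dep * dep + lat * lat > outer_r * outer_r) return false;
    if (layout != 1) {
      double dd = dep - inner_cd;
      if (dd * dd + lat * lat < inner_r * inner_r) return false;
    }
    if (fillet && dep < chord_depth) return false;
    return true;
  }

  // specular reflection of position and velocity off the nearest violated
  // wall; returns false when the point cannot be brought back inside
  inline bool reflect(double &dep, double &lat, double &vd, double &vl) const {
    for (int it = 0; it < 8; ++it) {
      if (inside(dep, lat)) return true;
      double r = std::sqrt(dep * dep + lat * lat);
      if (r > outer_r) {
        double nd_ = dep / r, nl_ = lat / r;
        double over = r - outer_r;
        dep -= 2 * over * nd_; lat -= 2 * over * nl_;
        double vn = vd * nd_ + vl * nl_;
        if (vn > 0) { vd -= 2 * vn * nd_; vl -= 2 * vn * nl_; }
        continue;
      }
      if (layout != 1) {
        double dd = dep - inner_cd;
        double ri = std::sqrt(dd * dd + lat * lat);
        if (ri < inner_r && ri > 1e-12) {
          double nd_ = dd / ri, nl_ = lat / ri;
          double under = inner_r - ri;
          dep += 2 * under * nd_; lat += 2 * under * nl_;
          double vn = vd * nd_ + vl * nl_;
          if (vn < 0) { vd -= 2 * vn * nd_; vl -= 2 * vn * nl_; }
          continue;
        }
      }
      if (fillet && dep < chord_depth) {
        dep = 2 * chord_depth - dep;
        if (vd < 0) vd = -vd;
        continue;
      }
      break;  // no single wall violated yet still outside (corner)
    }
    return inside(dep, lat);
  }
};

struct Deriv { double xd, xl, ad, al; };

// derivative of the state (position mm, velocity m/s)
inline Deriv deriv(const Grid &g, double dep, double lat, double vd, double vl,
                   double fd, double fl, double C, double ratio) {
  int i0, j0; double wi, wj;
  g.locate(dep, lat, i0, j0, wi, wj);
  double ud = g.bilin(g.ud, i0, j0, wi, wj) + fd;
  double ul = g.bilin(g.ul, i0, j0, wi, wj) + fl;
  double sd = ud - vd, sl = ul - vl;
  double slip = std::sqrt(sd * sd + sl * sl);
  double gdd, gdl, gld, gll;
  g.patch_grad(g.ud, i0, j0, wi, wj, gdd, gdl);
  g.patch_grad(g.ul, i0, j0, wi, wj, gld, gll);
  double umd = ud - fd, uml = ul - fl;  // mean flow only for material accel
  Deriv out;
  out.xd = vd * 1000.0;  // m/s -> mm/s
  out.xl = vl * 1000.0;
  out.ad = C * slip * sd + ratio * (umd * gdd + uml * gdl);
  out.al = C * slip * sl + ratio * (umd * gld + uml * gll);
  return out;
}

}  // namespace

// [[Rcpp::export]]
List track_particles_cpp(NumericMatrix u_depth, NumericMatrix u_lateral,
                         NumericMatrix k, NumericMatrix eps,
                         NumericVector depth_ax, NumericVector lateral_ax,
                         double spacing, NumericMatrix init_pos,
                         NumericMatrix init_vel, double dt, double record_dt,
                         double max_time, double drag_c, double density_ratio,
                         int layout_code, double outer_r, double inner_r,
                         double inner_cd, bool fillet, double chord_depth,
                         bool use_drw) {
  const int np = init_pos.nrow();
  const int n_rec = (int)std::lround(max_time / record_dt);
  const int steps_per_rec = (int)std::lround(record_dt / dt);

  Grid g{u_depth.begin(), u_lateral.begin(), k.begin(), eps.begin(),
         depth_ax[0], lateral_ax[0], spacing,
         (int)depth_ax.size(), (int)lateral_ax.size()};
  Geometry geo{layout_code, outer_r, inner_r, inner_cd, fillet, chord_depth};

  NumericMatrix rec_d(np, n_rec), rec_l(np, n_rec);
  NumericMatrix rec_vd(np, n_rec), rec_vl(np, n_rec);
  NumericMatrix v_final(np, 2);
  RNGScope scope;

  for (int p = 0; p < np; ++p) {
    double dep = init_pos(p, 0), lat = init_pos(p, 1);
    double vd = init_vel(p, 0), vl = init_vel(p, 1);
    double fd = 0, fl = 0;        // current eddy fluctuation, m/s
    double eddy_left = 0;         // remaining eddy lifetime, s
    for (int r = 0; r < n_rec; ++r) {
      rec_d(p, r) = dep; rec_l(p, r) = lat;
      rec_vd(p, r) = vd; rec_vl(p, r) = vl;
      for (int s = 0; s < steps_per_rec; ++s) {
        if (use_drw) {
          if (eddy_left <= 0) {
            int i0, j0; double wi, wj;
            g.locate(dep, lat, i0, j0, wi, wj);
            double k_m = g.bilin(g.k, i0, j0, wi, wj) * 1e-4;
            double e_m = g.bilin(g.eps, i0, j0, wi, wj) * 1e-4;
            if (k_m < 0) k_m = 0;
            if (e_m < 1e-12) e_m = 1e-12;
            double sigma = std::sqrt(2.0 * k_m / 3.0);
            fd = norm_rand() * sigma;
            fl = norm_rand() * sigma;
            eddy_left = 2.0 * 0.15 * k_m / e_m;
            if (eddy_left < dt) eddy_left = dt;
          }
          eddy_left -= dt;
        }
        // stability-limited adaptive substepping for the stiff quadratic
        // drag: the linearised drag rate 2 C |slip| can jump after an eddy
        // resample or a wall reflection, so the substep is re-sized from
        // the current slip before every RK4 step
        {
          double remaining = dt;
          const double h_min = dt / 1e7;
          int guard = 0;
          while (remaining > 1e-15) {
            if (++guard > 20000000)
              stop("integration error: substep limit reached for particle "
                   "%d at record %d", p + 1, r + 1);
            int i0, j0; double wi, wj;
            g.locate(dep, lat, i0, j0, wi, wj);
            double sd = g.bilin(g.ud, i0, j0, wi, wj) + fd - vd;
            double sl = g.bilin(g.ul, i0, j0, wi, wj) + fl - vl;
            double rate = 2.0 * drag_c * std::sqrt(sd * sd + sl * sl);
            double h = remaining;
            if (rate > 0 && 0.3 / rate < h) h = 0.3 / rate;
            if (h < h_min) h = h_min;
            if (h > remaining) h = remaining;
            remaining -= h;
            double dep0 = dep, lat0 = lat;
            Deriv k1 = deriv(g, dep, lat, vd, vl, fd, fl, drag_c,
                             density_ratio);
            Deriv k2 = deriv(g, dep + 0.5 * h * k1.xd, lat + 0.5 * h * k1.xl,
                             vd + 0.5 * h * k1.ad, vl + 0.5 * h * k1.al, fd,
                             fl, drag_c, density_ratio);
            Deriv k3 = deriv(g, dep + 0.5 * h * k2.xd, lat + 0.5 * h * k2.xl,
                             vd + 0.5 * h * k2.ad, vl + 0.5 * h * k2.al, fd,
                             fl, drag_c, density_ratio);
            Deriv k4 = deriv(g, dep + h * k3.xd, lat + h * k3.xl,
                             vd + h * k3.ad, vl + h * k3.al, fd, fl, drag_c,
                             density_ratio);
            dep += h / 6.0 * (k1.xd + 2 * k2.xd + 2 * k3.xd + k4.xd);
            lat += h / 6.0 * (k1.xl + 2 * k2.xl + 2 * k3.xl + k4.xl);
            vd += h / 6.0 * (k1.ad + 2 * k2.ad + 2 * k3.ad + k4.ad);
            vl += h / 6.0 * (k1.al + 2 * k2.al + 2 * k3.al + k4.al);
            if (!std::isfinite(vd) || !std::isfinite(vl) ||
                !std::isfinite(dep) || !std::isfinite(lat))
              stop("integration error: non-finite state for particle %d at "
                   "record %d", p + 1, r + 1);
            if (!geo.inside(dep, lat)) {
              if (!geo.reflect(dep, lat, vd, vl)) {
                // corner pocket: multi-wall reflection failed, fall back to
                // the pre-step position with the approach velocity reversed
                dep = dep0; lat = lat0; vd = -vd; vl = -vl;
                if (!geo.inside(dep, lat))
                  stop("geometry error: particle %d escaped the culture "
                       "region after wall reflection", p + 1);
              }
            }
          }
        }
      }
    }
    v_final(p, 0) = vd; v_final(p, 1) = vl;
  }
  return List::create(_["depth"] = rec_d, _["lateral"] = rec_l,
                      _["v_depth"] = rec_vd, _["v_lateral"] = rec_vl,
                      _["v_final"] = v_final);
}
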