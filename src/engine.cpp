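// Overdamped Brownian-dynamics engine for filament/motor networks in a thin
// periodic slab. Filaments are inextensible bead-chains (equal spacing
// restored by re-projection each step); pair interactions are the
// piecewise-linear repulsion/attraction evaluated between vertices and
// segments of other filaments; motors are two-headed walkers with a linear
// force-velocity law and distinct side/end unbinding.
#include <Rcpp.h>
#include <vector>
#include <set>
#include <random>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Par {
  double dt, eta, kappa, seg_len, d0, d1, Kr, Ka;
  double k_on, r_bind, k_off_side, k_off_end, v_m, f_stall, k_link, D_motor;
  double alpha, Omega, kT, drag_c;
  double Lx, Ly, Lz;
};

Par read_par(const List& p) {
  Par q;
  q.dt = p["dt"]; q.eta = p["eta"]; q.kappa = p["kappa"];
  q.seg_len = p["seg_len"]; q.d0 = p["d0"]; q.d1 = p["d1"];
  q.Kr = p["Kr"]; q.Ka = p["Ka"]; q.k_on = p["k_on"]; q.r_bind = p["r_bind"];
  q.k_off_side = p["k_off_side"]; q.k_off_end = p["k_off_end"];
  q.v_m = p["v_m"]; q.f_stall = p["f_stall"]; q.k_link = p["k_link"];
  q.D_motor = p["D_motor"]; q.alpha = p["alpha"]; q.Omega = p["Omega"];
  q.kT = p["kT"]; q.drag_c = p["drag_c"];
  q.Lx = p["Lx"]; q.Ly = p["Ly"]; q.Lz = p["Lz"];
  return q;
}

inline double wrap1(double x, double L) { return x - L * std::floor(x / L); }
inline double mi1(double d, double L) { return d - L * std::nearbyint(d / L); }

// Flat filament storage with a fixed per-filament capacity.
struct Sys {
  int nf, cap;
  std::vector<int> nv;
  std::vector<double> L;
  std::vector<char> fixed_;
  std::vector<double> x, y, z;    // nf * cap
  std::vector<double> fx, fy, fz;
  int nm;
  std::vector<int> mfil;          // nm * 2, 0 = free
  std::vector<double> mabs;       // nm * 2
  std::vector<double> mpx, mpy, mpz;
  std::vector<double> fax;        // nm * 2, axial link force on each head
  double t;
  inline int id(int i, int k) const { return i * cap + k; }
  inline double sp(int i) const { return L[i] / (nv[i] - 1); }
  void head_pos(int i, double a, double* out) const {
    double s = sp(i);
    int k = (int)std::floor(a / s);
    if (k < 0) k = 0;
    if (k > nv[i] - 2) k = nv[i] - 2;
    double u = a / s - k;
    int o = id(i, k);
    out[0] = (1 - u) * x[o] + u * x[o + 1];
    out[1] = (1 - u) * y[o] + u * y[o + 1];
    out[2] = (1 - u) * z[o] + u * z[o + 1];
  }
};

Sys read_state(const List& st, const Par& par) {
  Sys s;
  IntegerVector nv = st["fil_nv"];
  NumericVector L = st["fil_L"];
  LogicalVector fx_ = st["fil_fixed"];
  NumericMatrix vert = st["vert"];
  s.nf = nv.size();
  s.t = as<double>(st["t"]);
  double tot = 0;
  int maxnv = 2;
  for (int i = 0; i < s.nf; ++i) { tot += L[i]; maxnv = std::max(maxnv, nv[i]); }
  double grow_each = std::max(0.0, par.Omega - tot) / s.nf;
  s.cap = maxnv + (int)std::ceil(grow_each / par.seg_len) + 4;
  s.nv.assign(nv.begin(), nv.end());
  s.L.assign(L.begin(), L.end());
  s.fixed_.resize(s.nf);
  for (int i = 0; i < s.nf; ++i) s.fixed_[i] = fx_[i] ? 1 : 0;
  s.x.assign(s.nf * s.cap, 0.0); s.y = s.x; s.z = s.x;
  s.fx = s.x; s.fy = s.x; s.fz = s.x;
  int r = 0;
  for (int i = 0; i < s.nf; ++i)
    for (int k = 0; k < s.nv[i]; ++k, ++r) {
      s.x[s.id(i, k)] = vert(r, 0);
      s.y[s.id(i, k)] = vert(r, 1);
      s.z[s.id(i, k)] = vert(r, 2);
    }
  IntegerMatrix mf = st["m_fil"];
  NumericMatrix ma = st["m_abs"], mp = st["m_pos"];
  s.nm = mf.nrow();
  s.mfil.resize(2 * s.nm); s.mabs.resize(2 * s.nm);
  s.mpx.resize(s.nm); s.mpy.resize(s.nm); s.mpz.resize(s.nm);
  s.fax.assign(2 * s.nm, 0.0);
  for (int m = 0; m < s.nm; ++m) {
    for (int h = 0; h < 2; ++h) {
      s.mfil[2 * m + h] = mf(m, h);
      s.mabs[2 * m + h] = ma(m, h);
    }
    if (mp.nrow() == s.nm) {
      s.mpx[m] = mp(m, 0); s.mpy[m] = mp(m, 1); s.mpz[m] = mp(m, 2);
    }
  }
  return s;
}

List write_state(const Sys& s, const NumericVector& box) {
  int ntot = 0;
  for (int i = 0; i < s.nf; ++i) ntot += s.nv[i];
  NumericMatrix vert(ntot, 3);
  IntegerVector nv(s.nf);
  NumericVector L(s.nf);
  LogicalVector fx_(s.nf);
  int r = 0;
  double tot = 0;
  for (int i = 0; i < s.nf; ++i) {
    nv[i] = s.nv[i]; L[i] = s.L[i]; fx_[i] = s.fixed_[i] != 0; tot += s.L[i];
    for (int k = 0; k < s.nv[i]; ++k, ++r) {
      vert(r, 0) = s.x[s.id(i, k)];
      vert(r, 1) = s.y[s.id(i, k)];
      vert(r, 2) = s.z[s.id(i, k)];
    }
  }
  IntegerMatrix mf(s.nm, 2);
  NumericMatrix ma(s.nm, 2), mp(s.nm, 3);
  for (int m = 0; m < s.nm; ++m) {
    for (int h = 0; h < 2; ++h) { mf(m, h) = s.mfil[2 * m + h]; ma(m, h) = s.mabs[2 * m + h]; }
    mp(m, 0) = s.mpx[m]; mp(m, 1) = s.mpy[m]; mp(m, 2) = s.mpz[m];
  }
  List out = List::create(
    _["t"] = s.t, _["box"] = box, _["fil_nv"] = nv, _["fil_L"] = L,
    _["fil_fixed"] = fx_, _["vert"] = vert, _["m_fil"] = mf,
    _["m_abs"] = ma, _["m_pos"] = mp, _["total_polymer"] = tot);
  out.attr("class") = "mt_state";
  return out;
}

// Uniform grid over wrapped x,y storing segment ids; cell >= seg/2 + range.
struct Grid {
  int nx, ny;
  double hx, hy, Lx, Ly;
  std::vector<int> cell_of;          // per segment
  std::vector<int> start, items;     // CSR
  std::vector<int> seg_fil, seg_idx; // segment table
  void build(const Sys& s, double range) {
    double mx = 0;
    for (int i = 0; i < s.nf; ++i) mx = std::max(mx, s.sp(i));
    double h0 = 0.75 * mx + range;
    nx = std::max(1, (int)std::floor(Lx / h0));
    ny = std::max(1, (int)std::floor(Ly / h0));
    hx = Lx / nx; hy = Ly / ny;
    seg_fil.clear(); seg_idx.clear();
    for (int i = 0; i < s.nf; ++i)
      for (int k = 0; k < s.nv[i] - 1; ++k) { seg_fil.push_back(i); seg_idx.push_back(k); }
    int ns = seg_fil.size();
    cell_of.resize(ns);
    std::vector<int> cnt(nx * ny + 1, 0);
    for (int q = 0; q < ns; ++q) {
      int i = seg_fil[q], k = seg_idx[q];
      double cxp = wrap1(0.5 * (s.x[s.id(i, k)] + s.x[s.id(i, k + 1)]), Lx);
      double cyp = wrap1(0.5 * (s.y[s.id(i, k)] + s.y[s.id(i, k + 1)]), Ly);
      int cx = std::min(nx - 1, (int)(cxp / hx));
      int cy = std::min(ny - 1, (int)(cyp / hy));
      cell_of[q] = cy * nx + cx;
      cnt[cell_of[q] + 1]++;
    }
    start.assign(nx * ny + 1, 0);
    for (int c = 0; c < nx * ny; ++c) start[c + 1] = start[c] + cnt[c + 1];
    items.resize(ns);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int q = 0; q < ns; ++q) items[fill[cell_of[q]]++] = q;
  }
  // unique neighbor cells of a wrapped point
  int neighbors(double px, double py, int* cells) const {
    int cx0 = std::min(nx - 1, (int)(wrap1(px, Lx) / hx));
    int cy0 = std::min(ny - 1, (int)(wrap1(py, Ly) / hy));
    int n = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = (cx0 + dx + nx) % nx, cy = (cy0 + dy + ny) % ny;
        int c = cy * nx + cx;
        bool seen = false;
        for (int u = 0; u < n; ++u) if (cells[u] == c) { seen = true; break; }
        if (!seen) cells[n++] = c;
      }
    return n;
  }
};

// closest point of segment (j,k) to P under min-image; returns squared dist
// and barycentric u in [0,1]; accept==false when the clamped endpoint should
// be attributed to a neighboring segment (u >= 1 on a non-terminal segment).
inline bool seg_closest(const Sys& s, int j, int k,
                        double px, double py, double pz,
                        double Lx, double Ly,
                        double& d2, double& u,
                        double& qx, double& qy, double& qz) {
  int o = s.id(j, k);
  double ax = px + mi1(s.x[o] - px, Lx);
  double ay = py + mi1(s.y[o] - py, Ly);
  double az = s.z[o];
  double ex = s.x[o + 1] - s.x[o];
  double ey = s.y[o + 1] - s.y[o];
  double ez = s.z[o + 1] - s.z[o];
  double ee = ex * ex + ey * ey + ez * ez;
  double t = ((px - ax) * ex + (py - ay) * ey + (pz - az) * ez) / ee;
  if (t >= 1.0) {
    if (k != s.nv[j] - 2) return false;
    t = 1.0;
  } else if (t < 0.0) {
    t = 0.0;
  }
  qx = ax + t * ex; qy = ay + t * ey; qz = az + t * ez;
  double dx = px - qx, dy = py - qy, dz = pz - qz;
  d2 = dx * dx + dy * dy + dz * dz;
  u = t;
  return true;
}

// piecewise-linear pair force magnitude, signed (+ attraction, - repulsion)
inline double pair_F(double d, const Par& p) {
  if (d <= p.d0) return p.Kr * (d - p.d0);
  if (d < p.d0 + p.d1 - 1e-12) return p.Ka * (d - p.d0);
  return 0.0;
}

void bending_forces(Sys& s, double kappa) {
  for (int i = 0; i < s.nf; ++i) {
    int n = s.nv[i];
    if (n < 3 || kappa <= 0) continue;
    double sp = s.sp(i);
    double k = kappa / (sp * sp * sp);
    for (int j = 1; j < n - 1; ++j) {
      int o = s.id(i, j);
      double bx = s.x[o - 1] - 2 * s.x[o] + s.x[o + 1];
      double by = s.y[o - 1] - 2 * s.y[o] + s.y[o + 1];
      double bz = s.z[o - 1] - 2 * s.z[o] + s.z[o + 1];
      s.fx[o - 1] -= k * bx; s.fy[o - 1] -= k * by; s.fz[o - 1] -= k * bz;
      s.fx[o]     += 2 * k * bx; s.fy[o] += 2 * k * by; s.fz[o] += 2 * k * bz;
      s.fx[o + 1] -= k * bx; s.fy[o + 1] -= k * by; s.fz[o + 1] -= k * bz;
    }
  }
}

// Vertex cell lists with cell size ~ the interaction range; each segment
// then scans only the cells its swath overlaps. This keeps the candidate
// set tight even in dense aster cores where a coarse segment grid degrades
// to near-all-pairs.
struct VGrid {
  int nx, ny;
  double hx, hy, Lx, Ly;
  std::vector<int> start, items, vfil, vidx;
  std::vector<double> wx, wy;   // wrapped coordinates per stored vertex
  std::vector<int> cxv, cyv;    // cell coordinates per stored vertex
  void build(const Sys& s, double range) {
    nx = std::max(1, (int)std::floor(Lx / range));
    ny = std::max(1, (int)std::floor(Ly / range));
    hx = Lx / nx; hy = Ly / ny;
    vfil.clear(); vidx.clear();
    for (int i = 0; i < s.nf; ++i)
      for (int k = 0; k < s.nv[i]; ++k) { vfil.push_back(i); vidx.push_back(k); }
    int n = vfil.size();
    std::vector<int> cell(n);
    std::vector<int> cnt(nx * ny + 1, 0);
    wx.resize(n); wy.resize(n); cxv.resize(n); cyv.resize(n);
    for (int q = 0; q < n; ++q) {
      int o = s.id(vfil[q], vidx[q]);
      wx[q] = wrap1(s.x[o], Lx);
      wy[q] = wrap1(s.y[o], Ly);
      int cx = std::min(nx - 1, (int)(wx[q] / hx));
      int cy = std::min(ny - 1, (int)(wy[q] / hy));
      cxv[q] = cx; cyv[q] = cy;
      cell[q] = cy * nx + cx;
      cnt[cell[q] + 1]++;
    }
    start.assign(nx * ny + 1, 0);
    for (int c = 0; c < nx * ny; ++c) start[c + 1] = start[c] + cnt[c + 1];
    items.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int q = 0; q < n; ++q) items[fill[cell[q]]++] = q;
  }
};

struct PairList {
  // candidate vertex-segment pairs within range + skin, with the periodic
  // image shift of the vertex frozen at build time (drift << box/2).
  // Rebuilt when any vertex has moved more than skin/2 from its position
  // at build time (classical Verlet criterion), when the vertex count
  // changes, or when filaments are recentred.
  struct P { int ov, oa, i, v, j, k; float shx, shy; };
  std::vector<P> pairs;
  double skin = 0.4;
  bool stale = true;
  std::vector<double> refx, refy, refz;
  std::vector<int> refnv;
  void snapshot_ref(const Sys& s) {
    refx = s.x; refy = s.y; refz = s.z; refnv = s.nv;
    stale = false;
  }
  void check(const Sys& s) {
    if (stale) return;
    if (refnv != s.nv) { stale = true; return; }
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < s.nf; ++i)
      for (int k = 0; k < s.nv[i]; ++k) {
        int o = s.id(i, k);
        double dx = s.x[o] - refx[o], dy = s.y[o] - refy[o],
               dz = s.z[o] - refz[o];
        if (dx * dx + dy * dy + dz * dz > lim2) { stale = true; return; }
      }
  }
};

void build_pairs(Sys& s, const Par& par, VGrid& vg, PairList& pl) {
  double range = par.d0 + par.d1;
  double reach = range + pl.skin;
  vg.Lx = par.Lx; vg.Ly = par.Ly;
  vg.build(s, reach + 0.02);
  pl.pairs.clear();
  pl.snapshot_ref(s);
  double r2 = reach * reach;
  for (int j = 0; j < s.nf; ++j) {
    for (int k = 0; k < s.nv[j] - 1; ++k) {
      int oa = s.id(j, k);
      double ax = s.x[oa], ay = s.y[oa], az = s.z[oa];
      double bx2 = s.x[oa + 1], by2 = s.y[oa + 1];
      double ex = bx2 - ax, ey = by2 - ay, ez = s.z[oa + 1] - az;
      double ee = ex * ex + ey * ey + ez * ez;
      double xmin = std::min(ax, bx2) - reach, xmax = std::max(ax, bx2) + reach;
      double ymin = std::min(ay, by2) - reach, ymax = std::max(ay, by2) + reach;
      int ix0 = (int)std::floor(xmin / vg.hx), ix1 = (int)std::floor(xmax / vg.hx);
      int iy0 = (int)std::floor(ymin / vg.hy), iy1 = (int)std::floor(ymax / vg.hy);
      if (ix1 - ix0 + 1 >= vg.nx) { ix0 = 0; ix1 = vg.nx - 1; }
      if (iy1 - iy0 + 1 >= vg.ny) { iy0 = 0; iy1 = vg.ny - 1; }
      for (int iy = iy0; iy <= iy1; ++iy) {
        int cy = ((iy % vg.ny) + vg.ny) % vg.ny;
        for (int ix = ix0; ix <= ix1; ++ix) {
          int cx = ((ix % vg.nx) + vg.nx) % vg.nx;
          int c = cy * vg.nx + cx;
          double shx = (double)((ix - cx) / vg.nx) * par.Lx;
          double shy = (double)((iy - cy) / vg.ny) * par.Ly;
          for (int q = vg.start[c]; q < vg.start[c + 1]; ++q) {
            int qi = vg.items[q];
            int i = vg.vfil[qi], v = vg.vidx[qi];
            if (j == i && k >= v - 3 && k <= v + 2) continue;
            int ov = s.id(i, v);
            double px = vg.wx[qi] + shx, py = vg.wy[qi] + shy, pz = s.z[ov];
            double t = ((px - ax) * ex + (py - ay) * ey + (pz - az) * ez) / ee;
            if (t < 0) t = 0; else if (t > 1) t = 1;
            double dx = px - (ax + t * ex), dy = py - (ay + t * ey),
                   dz = pz - (az + t * ez);
            if (dx * dx + dy * dy + dz * dz >= r2) continue;
            PairList::P pr;
            pr.ov = ov; pr.oa = oa; pr.i = i; pr.v = v; pr.j = j; pr.k = k;
            // image shift from the vertex's stored coords to the segment's
            // frame (includes the vertex's own wrap offset)
            pr.shx = (float)(vg.wx[qi] + shx - s.x[ov]);
            pr.shy = (float)(vg.wy[qi] + shy - s.y[ov]);
            pl.pairs.push_back(pr);
          }
        }
      }
    }
  }
}

void eval_pairs(Sys& s, const Par& par, const PairList& pl) {
  double range = par.d0 + par.d1;
  double r2 = range * range;
  for (const auto& pr : pl.pairs) {
    int oa = pr.oa, ov = pr.ov;
    double ax = s.x[oa], ay = s.y[oa], az = s.z[oa];
    double ex = s.x[oa + 1] - ax, ey = s.y[oa + 1] - ay, ez = s.z[oa + 1] - az;
    double px = s.x[ov] + pr.shx, py = s.y[ov] + pr.shy, pz = s.z[ov];
    double ee = ex * ex + ey * ey + ez * ez;
    double t = ((px - ax) * ex + (py - ay) * ey + (pz - az) * ez) / ee;
    if (t >= 1.0) {
      if (pr.k != s.nv[pr.j] - 2) continue;
      t = 1.0;
    } else if (t < 0.0) t = 0.0;
    double qx = ax + t * ex, qy = ay + t * ey, qz = az + t * ez;
    double dx = px - qx, dy = py - qy, dz = pz - qz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= r2 || d2 < 1e-18) continue;
    double d = std::sqrt(d2);
    double F = pair_F(d, par);
    if (F == 0.0) continue;
    // force on P is -F * nhat (Q to P); halved (symmetric double count)
    double nxh = dx / d, nyh = dy / d, nzh = dz / d;
    double f = -0.5 * F;
    s.fx[ov] += f * nxh; s.fy[ov] += f * nyh; s.fz[ov] += f * nzh;
    s.fx[oa] -= f * nxh * (1 - t); s.fy[oa] -= f * nyh * (1 - t);
    s.fz[oa] -= f * nzh * (1 - t);
    s.fx[oa + 1] -= f * nxh * t; s.fy[oa + 1] -= f * nyh * t;
    s.fz[oa + 1] -= f * nzh * t;
  }
}

void link_forces(Sys& s, const Par& par) {
  std::fill(s.fax.begin(), s.fax.end(), 0.0);
  for (int m = 0; m < s.nm; ++m) {
    int f1 = s.mfil[2 * m], f2 = s.mfil[2 * m + 1];
    if (f1 <= 0 || f2 <= 0) continue;
    int i1 = f1 - 1, i2 = f2 - 1;
    double p1[3], p2[3];
    s.head_pos(i1, s.mabs[2 * m], p1);
    s.head_pos(i2, s.mabs[2 * m + 1], p2);
    double dx = mi1(p2[0] - p1[0], par.Lx);
    double dy = mi1(p2[1] - p1[1], par.Ly);
    double dz = p2[2] - p1[2];
    double Fx = par.k_link * dx, Fy = par.k_link * dy, Fz = par.k_link * dz;
    // distribute +F to filament 1 at a1, -F to filament 2 at a2
    for (int h = 0; h < 2; ++h) {
      int i = h == 0 ? i1 : i2;
      double a = s.mabs[2 * m + h];
      double sgn = h == 0 ? 1.0 : -1.0;
      double sp = s.sp(i);
      int k = (int)std::floor(a / sp);
      if (k < 0) k = 0;
      if (k > s.nv[i] - 2) k = s.nv[i] - 2;
      double u = a / sp - k;
      int o = s.id(i, k);
      s.fx[o] += sgn * Fx * (1 - u); s.fy[o] += sgn * Fy * (1 - u);
      s.fz[o] += sgn * Fz * (1 - u);
      s.fx[o + 1] += sgn * Fx * u; s.fy[o + 1] += sgn * Fy * u;
      s.fz[o + 1] += sgn * Fz * u;
      // axial component (plus-end directed tangent)
      double tx = s.x[o + 1] - s.x[o], ty = s.y[o + 1] - s.y[o],
             tz = s.z[o + 1] - s.z[o];
      double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
      s.fax[2 * m + h] = sgn * (Fx * tx + Fy * ty + Fz * tz) / tn;
    }
  }
}

// resample filament i to nv_new equally spaced vertices of total length L
void reshape(Sys& s, int i, int nv_new, std::vector<double>& bx,
             std::vector<double>& by, std::vector<double>& bz,
             std::vector<double>& cl) {
  int n = s.nv[i];
  bx.resize(n); by.resize(n); bz.resize(n); cl.resize(n);
  cl[0] = 0;
  for (int k = 0; k < n; ++k) {
    int o = s.id(i, k);
    bx[k] = s.x[o]; by[k] = s.y[o]; bz[k] = s.z[o];
    if (k) {
      double dx = bx[k] - bx[k - 1], dy = by[k] - by[k - 1], dz = bz[k] - bz[k - 1];
      cl[k] = cl[k - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  double Lc = cl[n - 1];
  double spx = s.L[i] / (nv_new - 1);
  double wx = bx[0], wy = by[0], wz = bz[0];
  int o0 = s.id(i, 0);
  s.x[o0] = wx; s.y[o0] = wy; s.z[o0] = wz;
  double ssx = wx, ssy = wy, ssz = wz;   // centroid of the sampled targets
  double swx = wx, swy = wy, swz = wz;   // centroid of the rebuilt chain
  int seg = 0;
  double pdx = bx[1] - bx[0], pdy = by[1] - by[0], pdz = bz[1] - bz[0];
  for (int k = 1; k < nv_new; ++k) {
    double target = (double)k * Lc / (nv_new - 1);
    while (seg < n - 2 && cl[seg + 1] < target) ++seg;
    double den = cl[seg + 1] - cl[seg];
    double u = den > 0 ? (target - cl[seg]) / den : 0.0;
    double sxp = bx[seg] + u * (bx[seg + 1] - bx[seg]);
    double syp = by[seg] + u * (by[seg + 1] - by[seg]);
    double szp = bz[seg] + u * (bz[seg + 1] - bz[seg]);
    double dx = sxp - wx, dy = syp - wy, dz = szp - wz;
    double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (dn < 1e-12) { dx = pdx; dy = pdy; dz = pdz; dn = std::sqrt(dx * dx + dy * dy + dz * dz); }
    wx += spx * dx / dn; wy += spx * dy / dn; wz += spx * dz / dn;
    pdx = dx; pdy = dy; pdz = dz;
    int o = s.id(i, k);
    s.x[o] = wx; s.y[o] = wy; s.z[o] = wz;
    ssx += sxp; ssy += syp; ssz += szp;
    swx += wx; swy += wy; swz += wz;
  }
  // recentre on the sampled centroid: the one-sided rebuild otherwise
  // ratchets thermally bent chains toward the minus end
  double cxs = (ssx - swx) / nv_new, cys = (ssy - swy) / nv_new,
         czs = (ssz - swz) / nv_new;
  for (int k = 0; k < nv_new; ++k) {
    int o = s.id(i, k);
    s.x[o] += cxs; s.y[o] += cys; s.z[o] += czs;
  }
  s.nv[i] = nv_new;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_run(List state, List params, int n_steps, int seed,
             IntegerVector snapshot_steps) {
  Par par = read_par(params);
  Sys s = read_state(state, par);
  NumericVector box = state["box"];
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  Grid g;
  VGrid vgrid;
  PairList plist;
  double gamma = par.drag_c * 3.0 * M_PI * par.eta * par.seg_len;
  double noise = std::sqrt(2.0 * par.kT * par.dt / gamma);
  double p_on = 1.0 - std::exp(-par.k_on * par.dt);
  double p_side = 1.0 - std::exp(-par.k_off_side * par.dt);
  double p_end = 1.0 - std::exp(-par.k_off_end * par.dt);
  double dstep = std::sqrt(2.0 * par.D_motor * par.dt);
  long n_clamped = 0;
  std::vector<double> bx, by, bz, cl;
  std::vector<double> dxv, dyv, dzv, tx, ty, tz, diag, sub, rhs;
  std::set<int> snaps(snapshot_steps.begin(), snapshot_steps.end());
  List out_snaps;
  std::vector<int> snap_at;
  int cells[9];

  for (int step = 1; step <= n_steps; ++step) {
    // forces
    std::fill(s.fx.begin(), s.fx.end(), 0.0);
    std::fill(s.fy.begin(), s.fy.end(), 0.0);
    std::fill(s.fz.begin(), s.fz.end(), 0.0);
    bending_forces(s, par.kappa);
    if (plist.stale) {
      build_pairs(s, par, vgrid, plist);
      g.Lx = par.Lx; g.Ly = par.Ly;
      g.build(s, std::max(par.d0 + par.d1, par.r_bind));
    }
    eval_pairs(s, par, plist);
    link_forces(s, par);

    // overdamped update with thermal noise; the displacement field is
    // projected onto the inextensible subspace (no first-order segment
    // extension) by a tridiagonal Lagrange-multiplier solve per filament,
    // which keeps the chain's diffusion at the Einstein value for the
    // summed vertex drag; reflecting z walls
    for (int i = 0; i < s.nf; ++i) {
      if (s.fixed_[i]) continue;
      int n = s.nv[i];
      double spL = s.sp(i);
      dxv.resize(n); dyv.resize(n); dzv.resize(n);
      for (int k = 0; k < n; ++k) {
        int o = s.id(i, k);
        dxv[k] = s.fx[o] * par.dt / gamma;
        dyv[k] = s.fy[o] * par.dt / gamma;
        dzv[k] = s.fz[o] * par.dt / gamma;
        if (par.kT > 0) {
          dxv[k] += noise * N01(rng);
          dyv[k] += noise * N01(rng);
          dzv[k] += noise * N01(rng);
        }
      }
      if (n >= 2) {
        int ns = n - 1;
        tx.resize(ns); ty.resize(ns); tz.resize(ns);
        diag.resize(ns); sub.resize(ns); rhs.resize(ns);
        for (int k = 0; k < ns; ++k) {
          int o = s.id(i, k);
          double ex = s.x[o + 1] - s.x[o], ey = s.y[o + 1] - s.y[o],
                 ez = s.z[o + 1] - s.z[o];
          double en = std::sqrt(ex * ex + ey * ey + ez * ez);
          tx[k] = ex / en; ty[k] = ey / en; tz[k] = ez / en;
          rhs[k] = (dxv[k + 1] - dxv[k]) * tx[k] + (dyv[k + 1] - dyv[k]) * ty[k]
                 + (dzv[k + 1] - dzv[k]) * tz[k];
          diag[k] = 2.0;
          sub[k] = k ? -(tx[k - 1] * tx[k] + ty[k - 1] * ty[k] + tz[k - 1] * tz[k])
                     : 0.0;
        }
        // Thomas algorithm for the symmetric tridiagonal (T T^t) lambda = T d
        for (int k = 1; k < ns; ++k) {
          double w = sub[k] / diag[k - 1];
          diag[k] -= w * sub[k];
          rhs[k] -= w * rhs[k - 1];
        }
        rhs[ns - 1] /= diag[ns - 1];
        for (int k = ns - 2; k >= 0; --k)
          rhs[k] = (rhs[k] - sub[k + 1] * rhs[k + 1]) / diag[k];
        // d' = d - T^t lambda
        for (int k = 0; k < ns; ++k) {
          dxv[k] += rhs[k] * tx[k]; dyv[k] += rhs[k] * ty[k]; dzv[k] += rhs[k] * tz[k];
          dxv[k + 1] -= rhs[k] * tx[k]; dyv[k + 1] -= rhs[k] * ty[k];
          dzv[k + 1] -= rhs[k] * tz[k];
        }
      }
      for (int k = 0; k < n; ++k) {
        int o = s.id(i, k);
        double dx = dxv[k], dy = dyv[k], dz = dzv[k];
        double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (!(dn < 25.0 * spL))
          stop("unstable timestep: vertex displacement %.3g um at t = %.3f s (reduce dt or stiffness)", dn, s.t);
        // displacement limiter: transient force pile-ups (stacked motor
        // links) are integrated as a local adaptive substep instead of
        // letting explicit Euler overshoot
        if (dn > 0.2 * spL) {
          double f = 0.2 * spL / dn;
          dx *= f; dy *= f; dz *= f; ++n_clamped;
        }
        s.x[o] += dx; s.y[o] += dy;
        double zz = s.z[o] + dz;
        while (zz < 0 || zz > par.Lz) { zz = zz < 0 ? -zz : 2 * par.Lz - zz; }
        s.z[o] = zz;
      }
    }

    // tubulin-limited growth at plus ends
    double tot = 0;
    for (int i = 0; i < s.nf; ++i) tot += s.L[i];
    double vg = par.alpha * std::max(0.0, 1.0 - tot / par.Omega);
    double dL = vg * par.dt;
    for (int i = 0; i < s.nf; ++i) {
      if (dL > 0) {
        int o = s.id(i, s.nv[i] - 1);
        double tx = s.x[o] - s.x[o - 1], ty = s.y[o] - s.y[o - 1],
               tz = s.z[o] - s.z[o - 1];
        double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
        s.x[o] += dL * tx / tn; s.y[o] += dL * ty / tn; s.z[o] += dL * tz / tn;
        s.L[i] += dL;
      }
      int nv_new = s.nv[i];
      if (s.L[i] / (s.nv[i] - 1) > 1.5 * par.seg_len && s.nv[i] < s.cap)
        ++nv_new;
      if (!(s.fixed_[i] && dL == 0))
        reshape(s, i, nv_new, bx, by, bz, cl);
    }

    // motor kinetics: walk, unbind, bind, diffuse
    for (int m = 0; m < s.nm; ++m) {
      int f1 = s.mfil[2 * m], f2 = s.mfil[2 * m + 1];
      bool dbl = f1 > 0 && f2 > 0;
      for (int h = 0; h < 2; ++h) {
        int f = s.mfil[2 * m + h];
        if (f <= 0) continue;
        int i = f - 1;
        double fa = dbl ? s.fax[2 * m + h] : 0.0;
        double v = par.v_m * (1.0 + fa / par.f_stall);
        if (v < 0) v = 0;
        if (v > par.v_m) v = par.v_m;
        double a = s.mabs[2 * m + h] + v * par.dt;
        if (a >= s.L[i]) a = s.L[i];
        s.mabs[2 * m + h] = a;
      }
      for (int h = 0; h < 2; ++h) {
        int f = s.mfil[2 * m + h];
        if (f <= 0) continue;
        int i = f - 1;
        double a = s.mabs[2 * m + h];
        double p = (a >= s.L[i] - 1e-12) ? p_end : p_side;
        if (U01(rng) < p) {
          double wp[3];
          s.head_pos(i, a, wp);
          s.mfil[2 * m + h] = 0;
          s.mabs[2 * m + h] = 0;
          if (s.mfil[2 * m + (1 - h)] <= 0) {
            s.mpx[m] = wrap1(wp[0], par.Lx);
            s.mpy[m] = wrap1(wp[1], par.Ly);
            s.mpz[m] = std::min(std::max(wp[2], 0.0), par.Lz);
          }
        }
      }
      for (int h = 0; h < 2; ++h) {
        if (s.mfil[2 * m + h] > 0) continue;
        // draw the binding trial first: the neighbor search only matters
        // for the small fraction of heads that would bind this step
        bool roll = U01(rng) < p_on;
        if (!roll) continue;
        int pf = s.mfil[2 * m + (1 - h)];
        double P[3];
        if (pf > 0) s.head_pos(pf - 1, s.mabs[2 * m + (1 - h)], P);
        else { P[0] = s.mpx[m]; P[1] = s.mpy[m]; P[2] = s.mpz[m]; }
        // nearest filament point within r_bind, excluding the partner's
        double best_d2 = par.r_bind * par.r_bind;
        int best_f = -1; double best_a = 0;
        int nc = g.neighbors(P[0], P[1], cells);
        for (int c = 0; c < nc; ++c) {
          for (int q = g.start[cells[c]]; q < g.start[cells[c] + 1]; ++q) {
            int sgi = g.items[q];
            int j = g.seg_fil[sgi], k = g.seg_idx[sgi];
            if (j + 1 == pf) continue;
            double d2, u, qx, qy, qz;
            if (!seg_closest(s, j, k, P[0], P[1], P[2], par.Lx, par.Ly,
                             d2, u, qx, qy, qz))
              continue;
            if (d2 < best_d2) {
              best_d2 = d2; best_f = j;
              best_a = (k + u) * s.sp(j);
            }
          }
        }
        if (best_f >= 0) {
          s.mfil[2 * m + h] = best_f + 1;
          s.mabs[2 * m + h] = std::min(best_a, s.L[best_f]);
        }
      }
      if (s.mfil[2 * m] <= 0 && s.mfil[2 * m + 1] <= 0 && par.D_motor > 0) {
        s.mpx[m] = wrap1(s.mpx[m] + dstep * N01(rng), par.Lx);
        s.mpy[m] = wrap1(s.mpy[m] + dstep * N01(rng), par.Ly);
        double zz = s.mpz[m] + dstep * N01(rng);
        while (zz < 0 || zz > par.Lz) { zz = zz < 0 ? -zz : 2 * par.Lz - zz; }
        s.mpz[m] = zz;
      }
    }

    plist.check(s);
    // recenter drifting filaments onto the primary image (invalidates the
    // frozen pair-list image shifts)
    if (step % 512 == 0) {
      plist.stale = true;
      for (int i = 0; i < s.nf; ++i) {
        int o0 = s.id(i, 0), o1 = s.id(i, s.nv[i] - 1);
        double mx = 0.5 * (s.x[o0] + s.x[o1]);
        double my = 0.5 * (s.y[o0] + s.y[o1]);
        double sx = -par.Lx * std::floor(mx / par.Lx);
        double sy = -par.Ly * std::floor(my / par.Ly);
        if (sx != 0 || sy != 0)
          for (int k = 0; k < s.nv[i]; ++k) {
            s.x[s.id(i, k)] += sx; s.y[s.id(i, k)] += sy;
          }
      }
    }

    s.t += par.dt;
    if (snaps.count(step)) {
      out_snaps.push_back(write_state(s, box));
      snap_at.push_back(step);
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["state"] = write_state(s, box),
                      _["snapshots"] = out_snaps,
                      _["snapshot_steps"] = wrap(snap_at),
                      _["n_clamped"] = (double)n_clamped);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_steric_forces(List state, List params) {
  Par par = read_par(params);
  Sys s = read_state(state, par);
  VGrid vgrid;
  PairList plist;
  build_pairs(s, par, vgrid, plist);
  eval_pairs(s, par, plist);
  int ntot = 0;
  for (int i = 0; i < s.nf; ++i) ntot += s.nv[i];
  NumericMatrix F(ntot, 3);
  int r = 0;
  for (int i = 0; i < s.nf; ++i)
    for (int k = 0; k < s.nv[i]; ++k, ++r) {
      F(r, 0) = s.fx[s.id(i, k)];
      F(r, 1) = s.fy[s.id(i, k)];
      F(r, 2) = s.fz[s.id(i, k)];
    }
  return F;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_bending_forces(NumericMatrix vert, double spacing,
                                 double kappa) {
  int n = vert.nrow();
  NumericMatrix F(n, 3);
  if (n < 3 || kappa <= 0) return F;
  double k = kappa / (spacing * spacing * spacing);
  for (int j = 1; j < n - 1; ++j) {
    for (int c = 0; c < 3; ++c) {
      double b = vert(j - 1, c) - 2 * vert(j, c) + vert(j + 1, c);
      F(j - 1, c) -= k * b;
      F(j, c) += 2 * k * b;
      F(j + 1, c) -= k * b;
    }
  }
  return F;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_dwell_steps(int n, double p, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    long k = 1;
    while (U01(rng) >= p) ++k;
    out[i] = (double)k;
  }
  return out;
}
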