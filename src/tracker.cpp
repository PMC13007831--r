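#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Probabilistic streamline integration over a multi-lobe orientation field.
//
// Lobes are axial (a fiber population has no intrinsic sign): at each step
// the candidate set is every lobe whose amplitude reaches the cutoff and
// whose axis lies within the turning cone of the incoming direction; the
// next direction is drawn with probability proportional to amplitude.
// Uses R's RNG so set.seed() makes runs reproducible.

struct Grid {
  int nx, ny, nz, nl;
  const double *amps;   // [nx, ny, nz, nl]
  const double *dirs;   // [nx, ny, nz, nl, 3]
  double inv[12];       // world -> voxel affine, rows of 3x4
  double fwd[12];       // voxel -> world

  inline void w2v(const double *p, double *v) const {
    for (int r = 0; r < 3; ++r)
      v[r] = inv[r] * p[0] + inv[r + 3] * p[1] + inv[r + 6] * p[2] + inv[r + 9];
  }
  inline void v2w(const double *v, double *p) const {
    for (int r = 0; r < 3; ++r)
      p[r] = fwd[r] * v[0] + fwd[r + 3] * v[1] + fwd[r + 6] * v[2] + fwd[r + 9];
  }
  inline bool voxel_of(const double *p, int *ijk) const {
    double v[3];
    w2v(p, v);
    ijk[0] = (int)std::floor(v[0] + 0.5);
    ijk[1] = (int)std::floor(v[1] + 0.5);
    ijk[2] = (int)std::floor(v[2] + 0.5);
    return ijk[0] >= 0 && ijk[0] < nx && ijk[1] >= 0 && ijk[1] < ny &&
           ijk[2] >= 0 && ijk[2] < nz;
  }
  inline long amp_idx(const int *ijk, int l) const {
    return ijk[0] + (long)nx * (ijk[1] + (long)ny * (ijk[2] + (long)nz * l));
  }
  inline long dir_idx(const int *ijk, int l, int c) const {
    return ijk[0] + (long)nx * (ijk[1] + (long)ny * (ijk[2] + (long)nz * (l + (long)nl * c)));
  }
};

static int sample_weighted(const std::vector<double> &w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// one direction of integration; appends points after the start point
static void integrate(const Grid &g, const double *start, const double *d0,
                      double step, double cutoff, double cos_max, int max_steps,
                      std::vector<double> &pts) {
  double p[3] = {start[0], start[1], start[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  int ijk[3];
  for (int s = 0; s < max_steps; ++s) {
    double q[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
    if (!g.voxel_of(q, ijk)) break;
    std::vector<double> w;
    std::vector<int> lob;
    std::vector<int> sgn;
    for (int l = 0; l < g.nl; ++l) {
      double a = g.amps[g.amp_idx(ijk, l)];
      if (a < cutoff) continue;
      double lx = g.dirs[g.dir_idx(ijk, l, 0)];
      double ly = g.dirs[g.dir_idx(ijk, l, 1)];
      double lz = g.dirs[g.dir_idx(ijk, l, 2)];
      double dot = lx * d[0] + ly * d[1] + lz * d[2];
      double ad = std::fabs(dot);
      if (ad < cos_max) continue;
      w.push_back(a);
      lob.push_back(l);
      sgn.push_back(dot >= 0 ? 1 : -1);
    }
    if (w.empty()) break;
    int k = sample_weighted(w);
    int l = lob[k];
    double sg = (double)sgn[k];
    d[0] = sg * g.dirs[g.dir_idx(ijk, l, 0)];
    d[1] = sg * g.dirs[g.dir_idx(ijk, l, 1)];
    d[2] = sg * g.dirs[g.dir_idx(ijk, l, 2)];
    p[0] = p[0] + step * d[0];
    p[1] = p[1] + step * d[1];
    p[2] = p[2] + step * d[2];
    pts.push_back(p[0]);
    pts.push_back(p[1]);
    pts.push_back(p[2]);
  }
}

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(IntegerVector dims, NumericVector amps, NumericVector dirs,
               NumericMatrix affine, IntegerMatrix seed_vox,
               LogicalVector thalamus, LogicalVector brainstem,
               double step, double cutoff, double max_angle_deg,
               double max_length_mm, int n_select, int max_attempts) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2]; g.nl = dims[3];
  g.amps = amps.begin();
  g.dirs = dirs.begin();

  // invert the affine (4x4, last row 0 0 0 1 assumed checked in R)
  {
    double a[9], inv3[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) a[3 * r + c] = affine(r, c);
    double det = a[0] * (a[4] * a[8] - a[5] * a[7]) -
                 a[1] * (a[3] * a[8] - a[5] * a[6]) +
                 a[2] * (a[3] * a[7] - a[4] * a[6]);
    inv3[0] = (a[4] * a[8] - a[5] * a[7]) / det;
    inv3[1] = (a[2] * a[7] - a[1] * a[8]) / det;
    inv3[2] = (a[1] * a[5] - a[2] * a[4]) / det;
    inv3[3] = (a[5] * a[6] - a[3] * a[8]) / det;
    inv3[4] = (a[0] * a[8] - a[2] * a[6]) / det;
    inv3[5] = (a[2] * a[3] - a[0] * a[5]) / det;
    inv3[6] = (a[3] * a[7] - a[4] * a[6]) / det;
    inv3[7] = (a[1] * a[6] - a[0] * a[7]) / det;
    inv3[8] = (a[0] * a[4] - a[1] * a[3]) / det;
    for (int r = 0; r < 3; ++r) {
      for (int c = 0; c < 3; ++c) {
        g.fwd[r + 3 * c] = affine(r, c);
        g.inv[r + 3 * c] = inv3[3 * r + c];
      }
      g.fwd[r + 9] = affine(r, 3);
      g.inv[r + 9] = -(inv3[3 * r + 0] * affine(0, 3) +
                       inv3[3 * r + 1] * affine(1, 3) +
                       inv3[3 * r + 2] * affine(2, 3));
    }
  }

  int n_seed = seed_vox.nrow();
  double cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  int max_steps = (int)std::floor(max_length_mm / step);
  long nvox = (long)g.nx * g.ny * g.nz;

  RNGScope scope;
  List out(n_select);
  int retained = 0, attempts = 0;

  while (retained < n_select && attempts < max_attempts) {
    ++attempts;
    // random seed voxel, jittered uniformly within the voxel
    int si = (int)std::floor(unif_rand() * n_seed);
    if (si >= n_seed) si = n_seed - 1;
    double v[3] = {seed_vox(si, 0) + unif_rand() - 0.5,
                   seed_vox(si, 1) + unif_rand() - 0.5,
                   seed_vox(si, 2) + unif_rand() - 0.5};
    double p0[3];
    g.v2w(v, p0);
    int ijk[3];
    if (!g.voxel_of(p0, ijk)) continue;

    // initial direction among supra-cutoff lobes, weighted by amplitude
    std::vector<double> w;
    std::vector<int> lob;
    for (int l = 0; l < g.nl; ++l) {
      double a = g.amps[g.amp_idx(ijk, l)];
      if (a >= cutoff) { w.push_back(a); lob.push_back(l); }
    }
    if (w.empty()) continue;
    int l0 = lob[sample_weighted(w)];
    double d0[3] = {g.dirs[g.dir_idx(ijk, l0, 0)],
                    g.dirs[g.dir_idx(ijk, l0, 1)],
                    g.dirs[g.dir_idx(ijk, l0, 2)]};

    std::vector<double> fwd_pts, bwd_pts;
    integrate(g, p0, d0, step, cutoff, cos_max, max_steps, fwd_pts);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    integrate(g, p0, d0n, step, cutoff, cos_max, max_steps, bwd_pts);

    size_t nb = bwd_pts.size() / 3, nf = fwd_pts.size() / 3;
    size_t n = nb + 1 + nf;
    if (n < 2) continue;

    NumericMatrix sl((int)n, 3);
    for (size_t i = 0; i < nb; ++i) {          // backward pass, reversed
      size_t src = nb - 1 - i;
      sl((int)i, 0) = bwd_pts[3 * src];
      sl((int)i, 1) = bwd_pts[3 * src + 1];
      sl((int)i, 2) = bwd_pts[3 * src + 2];
    }
    sl((int)nb, 0) = p0[0]; sl((int)nb, 1) = p0[1]; sl((int)nb, 2) = p0[2];
    for (size_t i = 0; i < nf; ++i) {
      sl((int)(nb + 1 + i), 0) = fwd_pts[3 * i];
      sl((int)(nb + 1 + i), 1) = fwd_pts[3 * i + 1];
      sl((int)(nb + 1 + i), 2) = fwd_pts[3 * i + 2];
    }

    // retention: must visit the thalamus; endpoints must avoid the brainstem
    bool visits = false;
    for (size_t i = 0; i < n && !visits; ++i) {
      double pt[3] = {sl((int)i, 0), sl((int)i, 1), sl((int)i, 2)};
      if (g.voxel_of(pt, ijk)) {
        long li = ijk[0] + (long)g.nx * (ijk[1] + (long)g.ny * ijk[2]);
        if (li >= 0 && li < nvox && thalamus[li]) visits = true;
      }
    }
    if (!visits) continue;
    bool bad_end = false;
    for (int e = 0; e < 2; ++e) {
      int row = e == 0 ? 0 : (int)n - 1;
      double pt[3] = {sl(row, 0), sl(row, 1), sl(row, 2)};
      if (g.voxel_of(pt, ijk)) {
        long li = ijk[0] + (long)g.nx * (ijk[1] + (long)g.ny * ijk[2]);
        if (brainstem[li]) bad_end = true;
      }
    }
    if (bad_end) continue;

    out[retained] = sl;
    ++retained;
  }
  if (retained < n_select) {
    List trimmed(retained);
    for (int i = 0; i < retained; ++i) trimmed[i] = out[i];
    out = trimmed;
  }
  return List::create(_["streamlines"] = out,
                      _["n_retained"] = retained,
                      _["attempts"] = attempts);
}
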