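#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Streamline propagation core. Multi-peak deterministic tracking with the
// three stopping rules (anisotropy floor, per-voxel turn limit, brain-mask
// exit) plus an axial-dispersion probabilistic variant. Peaks are looked up
// at the nearest voxel (FACT-style); no interpolation of directions.

namespace {

struct FieldView {
  const double *peaks;   // (nx,ny,nz,3 slots,3 comps), zero norm = absent
  const double *fa;      // (nx,ny,nz)
  const int *brain;      // (nx,ny,nz) 0/1
  int nx, ny, nz;
  long nvox;

  bool in_grid(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  long lin(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
  // peak slot p (0..2), component c (0..2)
  double pk(long v, int p, int c) const {
    return peaks[v + nvox * ((long)p + 3L * (long)c)];
  }
  int n_peaks(long v) const {
    int n = 0;
    for (int p = 0; p < 3; ++p) {
      double s = 0;
      for (int c = 0; c < 3; ++c) { double x = pk(v, p, c); s += x * x; }
      if (s > 0.25) ++n; else break;  // slots are filled in order
    }
    return n;
  }
};

struct Affine {
  double m[3][4];   // voxel -> world
  double inv[3][4]; // world -> voxel
  void world_to_voxel(const double *w, double *v) const {
    for (int r = 0; r < 3; ++r)
      v[r] = inv[r][0] * w[0] + inv[r][1] * w[1] + inv[r][2] * w[2] + inv[r][3];
  }
};

inline void unit(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n > 0) { v[0] /= n; v[1] /= n; v[2] /= n; }
}

// Termination reasons
enum Reason { NONE = 0, LOW_ANISO = 1, SHARP_TURN = 2, OUT_OF_BRAIN = 3, MAX_LENGTH = 4 };

struct StepRNG {
  std::mt19937 gen;
  std::normal_distribution<double> nd;
  StepRNG(unsigned seed) : gen(seed), nd(0.0, 1.0) {}
};

// Perturb an axis direction with tangent-plane Gaussian noise of sd
// sigma = 1/sqrt(2*kappa) (axial Watson-like dispersion).
void perturb_axis(double *d, double kappa, StepRNG &rng) {
  double sigma = 1.0 / std::sqrt(2.0 * kappa);
  // build an orthonormal basis {e1, e2} of the tangent plane
  double a[3] = {1, 0, 0};
  if (std::fabs(d[0]) > 0.9) { a[0] = 0; a[1] = 1; }
  double e1[3] = {d[1] * a[2] - d[2] * a[1], d[2] * a[0] - d[0] * a[2],
                  d[0] * a[1] - d[1] * a[0]};
  unit(e1);
  double e2[3] = {d[1] * e1[2] - d[2] * e1[1], d[2] * e1[0] - d[0] * e1[2],
                  d[0] * e1[1] - d[1] * e1[0]};
  double z1 = sigma * rng.nd(rng.gen), z2 = sigma * rng.nd(rng.gen);
  for (int c = 0; c < 3; ++c) d[c] += z1 * e1[c] + z2 * e2[c];
  unit(d);
}

// Propagate one direction from p0 along d0. Appends points (excluding the
// seed point itself) to `pts`. Returns the termination reason.
int propagate_half(const FieldView &F, const Affine &A,
                   const double *p0, const double *d0,
                   double step, double cos_max_turn, double fa_min,
                   int max_steps,
                   bool probabilistic, double kappa, StepRNG *rng,
                   std::vector<double> &pts) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  double entry_dir[3] = {d0[0], d0[1], d0[2]};
  double v[3];
  A.world_to_voxel(p, v);
  int pv[3] = {(int)std::lround(v[0]), (int)std::lround(v[1]), (int)std::lround(v[2])};
  int nsteps = 0;
  for (;;) {
    A.world_to_voxel(p, v);
    int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]), k = (int)std::lround(v[2]);
    if (!F.in_grid(i, j, k)) return OUT_OF_BRAIN;
    long lv = F.lin(i, j, k);
    if (!F.brain[lv]) return OUT_OF_BRAIN;
    if (F.fa[lv] < fa_min) return LOW_ANISO;
    int np = F.n_peaks(lv);
    if (np == 0) return LOW_ANISO;
    // entered a new voxel: the incoming direction becomes the reference for
    // the per-voxel turn check
    if (i != pv[0] || j != pv[1] || k != pv[2]) {
      entry_dir[0] = d[0]; entry_dir[1] = d[1]; entry_dir[2] = d[2];
      pv[0] = i; pv[1] = j; pv[2] = k;
    }
    // pick the peak with maximal |dot| with the incoming direction
    int best = 0; double bestdot = -1.0;
    for (int pidx = 0; pidx < np; ++pidx) {
      double dot = 0;
      for (int c = 0; c < 3; ++c) dot += F.pk(lv, pidx, c) * d[c];
      if (std::fabs(dot) > bestdot + 1e-12) { bestdot = std::fabs(dot); best = pidx; }
    }
    double nd_[3];
    double dot = 0;
    for (int c = 0; c < 3; ++c) { nd_[c] = F.pk(lv, best, c); dot += nd_[c] * d[c]; }
    if (dot < 0) { nd_[0] = -nd_[0]; nd_[1] = -nd_[1]; nd_[2] = -nd_[2]; }
    unit(nd_);
    if (probabilistic) {
      perturb_axis(nd_, kappa, *rng);
      double d2 = nd_[0] * d[0] + nd_[1] * d[1] + nd_[2] * d[2];
      if (d2 < 0) { nd_[0] = -nd_[0]; nd_[1] = -nd_[1]; nd_[2] = -nd_[2]; }
    }
    double turndot = nd_[0] * entry_dir[0] + nd_[1] * entry_dir[1] + nd_[2] * entry_dir[2];
    if (turndot < cos_max_turn) return SHARP_TURN;
    d[0] = nd_[0]; d[1] = nd_[1]; d[2] = nd_[2];
    p[0] += step * d[0]; p[1] += step * d[1]; p[2] += step * d[2];
    pts.push_back(p[0]); pts.push_back(p[1]); pts.push_back(p[2]);
    if (++nsteps >= max_steps) return MAX_LENGTH;
  }
}

FieldView make_view(const NumericVector &peaks, const NumericVector &fa,
                    const IntegerVector &brain, const IntegerVector &dims) {
  FieldView F;
  F.nx = dims[0]; F.ny = dims[1]; F.nz = dims[2];
  F.nvox = (long)F.nx * F.ny * F.nz;
  F.peaks = REAL(peaks); F.fa = REAL(fa); F.brain = INTEGER(brain);
  return F;
}

Affine make_affine(const NumericMatrix &aff, const NumericMatrix &inv) {
  Affine A;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) { A.m[r][c] = aff(r, c); A.inv[r][c] = inv(r, c); }
  return A;
}

} // namespace

// Propagate a single streamline (both directions) from a world-space seed.
// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(NumericVector peaks, NumericVector fa, IntegerVector brain,
                   IntegerVector dims, NumericMatrix affine, NumericMatrix inv_affine,
                   NumericVector seed_world, NumericVector init_dir,
                   double step, double max_turn_deg, double fa_min,
                   int max_steps, bool bidirectional,
                   bool probabilistic, double kappa, int rng_seed) {
  FieldView F = make_view(peaks, fa, brain, dims);
  Affine A = make_affine(affine, inv_affine);
  double cmt = std::cos(max_turn_deg * M_PI / 180.0);
  StepRNG rng((unsigned)rng_seed);
  double p0[3] = {seed_world[0], seed_world[1], seed_world[2]};
  double d0[3] = {init_dir[0], init_dir[1], init_dir[2]};
  unit(d0);

  std::vector<double> fwd, bwd;
  int rf = propagate_half(F, A, p0, d0, step, cmt, fa_min, max_steps,
                          probabilistic, kappa, &rng, fwd);
  int rb = NONE;
  if (bidirectional) {
    double dneg[3] = {-d0[0], -d0[1], -d0[2]};
    rb = propagate_half(F, A, p0, dneg, step, cmt, fa_min, max_steps,
                        probabilistic, kappa, &rng, bwd);
  }
  int nb = bwd.size() / 3, nf = fwd.size() / 3;
  NumericMatrix out(nb + 1 + nf, 3);
  for (int i = 0; i < nb; ++i)          // backward half, reversed
    for (int c = 0; c < 3; ++c) out(i, c) = bwd[3 * (nb - 1 - i) + c];
  for (int c = 0; c < 3; ++c) out(nb, c) = p0[c];
  for (int i = 0; i < nf; ++i)
    for (int c = 0; c < 3; ++c) out(nb + 1 + i, c) = fwd[3 * i + c];
  return List::create(_["points"] = out,
                      _["reasons"] = IntegerVector::create(rb, rf));
}

// Track one streamline per (seed voxel, peak) pair; seeds at voxel centers.
// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericVector peaks, NumericVector fa, IntegerVector brain,
               IntegerVector dims, NumericMatrix affine, NumericMatrix inv_affine,
               IntegerMatrix seeds, IntegerVector seed_peak,
               double step, double max_turn_deg, double fa_min,
               double min_len_mm, int max_steps,
               bool probabilistic, double kappa, int rng_seed) {
  FieldView F = make_view(peaks, fa, brain, dims);
  Affine A = make_affine(affine, inv_affine);
  double cmt = std::cos(max_turn_deg * M_PI / 180.0);
  StepRNG rng((unsigned)rng_seed);
  int n = seeds.nrow();
  List slines(n);
  IntegerMatrix reasons(n, 2);
  LogicalVector keep(n);
  int discarded = 0;
  std::vector<double> fwd, bwd;
  for (int s = 0; s < n; ++s) {
    double p0[3], d0[3];
    for (int c = 0; c < 3; ++c)  // voxel center -> world
      p0[c] = A.m[c][0] * seeds(s, 0) + A.m[c][1] * seeds(s, 1) +
              A.m[c][2] * seeds(s, 2) + A.m[c][3];
    long lv = F.lin(seeds(s, 0), seeds(s, 1), seeds(s, 2));
    int pidx = seed_peak[s];
    for (int c = 0; c < 3; ++c) d0[c] = F.pk(lv, pidx, c);
    unit(d0);
    fwd.clear(); bwd.clear();
    int rf = propagate_half(F, A, p0, d0, step, cmt, fa_min, max_steps,
                            probabilistic, kappa, &rng, fwd);
    double dneg[3] = {-d0[0], -d0[1], -d0[2]};
    int rb = propagate_half(F, A, p0, dneg, step, cmt, fa_min, max_steps,
                            probabilistic, kappa, &rng, bwd);
    int nb = bwd.size() / 3, nf = fwd.size() / 3;
    NumericMatrix pts(nb + 1 + nf, 3);
    for (int i = 0; i < nb; ++i)
      for (int c = 0; c < 3; ++c) pts(i, c) = bwd[3 * (nb - 1 - i) + c];
    for (int c = 0; c < 3; ++c) pts(nb, c) = p0[c];
    for (int i = 0; i < nf; ++i)
      for (int c = 0; c < 3; ++c) pts(nb + 1 + i, c) = fwd[3 * i + c];
    slines[s] = pts;
    reasons(s, 0) = rb; reasons(s, 1) = rf;
    double len = step * (nb + nf);
    keep[s] = len >= min_len_mm;
    if (!keep[s]) ++discarded;
  }
  return List::create(_["streamlines"] = slines, _["reasons"] = reasons,
                      _["keep"] = keep, _["n_discarded"] = discarded);
}

// Fused probabilistic run: repeats every (seed voxel, peak) launch
// `iterations` times, retains streamlines whose two terminal voxels fall one
// in each ROI, and accumulates a per-voxel visitation count over retained
// streamlines without materialising them.
// [[Rcpp::export(name = ".prob_connection_cpp")]]
List prob_connection_cpp(NumericVector peaks, NumericVector fa, IntegerVector brain,
                         IntegerVector dims, NumericMatrix affine, NumericMatrix inv_affine,
                         IntegerMatrix seeds, IntegerVector seed_peak,
                         double step, double max_turn_deg, double fa_min,
                         double min_len_mm, int max_steps,
                         double kappa, int iterations, int rng_seed,
                         IntegerVector roi_a, IntegerVector roi_b) {
  FieldView F = make_view(peaks, fa, brain, dims);
  Affine A = make_affine(affine, inv_affine);
  double cmt = std::cos(max_turn_deg * M_PI / 180.0);
  StepRNG rng((unsigned)rng_seed);
  const int *ra = INTEGER(roi_a), *rb_ = INTEGER(roi_b);
  std::vector<int> visits(F.nvox, 0);
  std::vector<long> stamp(F.nvox, -1);
  long retained = 0, launched = 0, sl_id = 0;
  std::vector<double> fwd, bwd;
  int n = seeds.nrow();
  for (int s = 0; s < n; ++s) {
    double p0[3], d0seed[3];
    for (int c = 0; c < 3; ++c)
      p0[c] = A.m[c][0] * seeds(s, 0) + A.m[c][1] * seeds(s, 1) +
              A.m[c][2] * seeds(s, 2) + A.m[c][3];
    long lv0 = F.lin(seeds(s, 0), seeds(s, 1), seeds(s, 2));
    for (int c = 0; c < 3; ++c) d0seed[c] = F.pk(lv0, seed_peak[s], c);
    unit(d0seed);
    for (int it = 0; it < iterations; ++it) {
      ++launched; ++sl_id;
      fwd.clear(); bwd.clear();
      propagate_half(F, A, p0, d0seed, step, cmt, fa_min, max_steps, true, kappa, &rng, fwd);
      double dneg[3] = {-d0seed[0], -d0seed[1], -d0seed[2]};
      propagate_half(F, A, p0, dneg, step, cmt, fa_min, max_steps, true, kappa, &rng, bwd);
      int nb = bwd.size() / 3, nf = fwd.size() / 3;
      if (step * (nb + nf) < min_len_mm) continue;
      // terminal voxels
      const double *endA = nb > 0 ? &bwd[3 * (nb - 1)] : p0;
      const double *endB = nf > 0 ? &fwd[3 * (nf - 1)] : p0;
      double va[3], vb[3];
      A.world_to_voxel(endA, va); A.world_to_voxel(endB, vb);
      int ia = (int)std::lround(va[0]), ja = (int)std::lround(va[1]), ka = (int)std::lround(va[2]);
      int ib = (int)std::lround(vb[0]), jb = (int)std::lround(vb[1]), kb = (int)std::lround(vb[2]);
      bool inAa = F.in_grid(ia, ja, ka) && ra[F.lin(ia, ja, ka)];
      bool inAb = F.in_grid(ib, jb, kb) && ra[F.lin(ib, jb, kb)];
      bool inBa = F.in_grid(ia, ja, ka) && rb_[F.lin(ia, ja, ka)];
      bool inBb = F.in_grid(ib, jb, kb) && rb_[F.lin(ib, jb, kb)];
      if (!((inAa && inBb) || (inAb && inBa))) continue;
      ++retained;
      // accumulate distinct visited voxels (seed + both halves)
      double v[3];
      for (int part = 0; part < 3; ++part) {
        const std::vector<double> *half = part == 0 ? &bwd : &fwd;
        int np = part == 2 ? 1 : (int)(half->size() / 3);
        for (int i = 0; i < np; ++i) {
          const double *pt = part == 2 ? p0 : &(*half)[3 * i];
          A.world_to_voxel(pt, v);
          int ii = (int)std::lround(v[0]), jj = (int)std::lround(v[1]), kk = (int)std::lround(v[2]);
          if (!F.in_grid(ii, jj, kk)) continue;
          long l = F.lin(ii, jj, kk);
          if (stamp[l] != sl_id) { stamp[l] = sl_id; ++visits[l]; }
        }
      }
    }
  }
  NumericVector vout(F.nvox);
  for (long i = 0; i < F.nvox; ++i)
    vout[i] = retained > 0 ? (double)visits[i] / (double)retained : 0.0;
  return List::create(_["probability"] = vout,
                      _["retained"] = (double)retained,
                      _["launched"] = (double)launched);
}
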