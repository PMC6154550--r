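// Compiled core: BAOAB Langevin propagation on analytic Gaussian
// well/barrier landscapes, plus the well-tempered metadynamics loop with
// a gridded bias. Units: A, ps, amu, kcal/mol. All randomness comes from
// R's RNG (norm_rand), so set.seed() in R gives bit-identical runs.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCAL_AMU = 418.4;   // kcal/mol -> amu A^2 ps^-2
static const double KB = 0.0019872;     // kcal/mol/K

struct ToySys {
  int dims;
  int n_wells, n_barriers;
  NumericMatrix wc, bc;
  NumericVector wd, ww, wr, bh, bw, br;
  double L, wall_k, mass;
  NumericVector box_center, site_center;

  ToySys(const List& s)
    : dims(as<int>(s["dims"])),
      n_wells(as<int>(s["n_wells"])),
      n_barriers(as<int>(s["n_barriers"])),
      wc(as<NumericMatrix>(s["well_centers"])),
      bc(as<NumericMatrix>(s["barrier_centers"])),
      wd(as<NumericVector>(s["well_depths"])),
      ww(as<NumericVector>(s["well_widths"])),
      wr(as<NumericVector>(s["well_radii"])),
      bh(as<NumericVector>(s["barrier_heights"])),
      bw(as<NumericVector>(s["barrier_widths"])),
      br(as<NumericVector>(s["barrier_radii"])),
      L(as<double>(s["box_halflength"])),
      wall_k(as<double>(s["wall_k"])),
      mass(as<double>(s["mass"])),
      box_center(as<NumericVector>(s["box_center"])),
      site_center(as<NumericVector>(s["site_center"])) {}

  // interaction part (wells + barriers); optionally accumulate force.
  // Each term may be a point Gaussian (radius 0) or a spherical-shell
  // Gaussian in rho = |x - center|: amp * exp(-(rho - R)^2 / 2 sigma^2).
  double interaction(const double* x, double* f) const {
    double e = 0.0;
    for (int i = 0; i < n_wells + n_barriers; ++i) {
      bool well = i < n_wells;
      int j = well ? i : i - n_wells;
      const NumericMatrix& ctr = well ? wc : bc;
      double amp = well ? -wd[j] : bh[j];
      double sig = well ? ww[j] : bw[j];
      double R = well ? wr[j] : br[j];
      double r2 = 0.0;
      for (int k = 0; k < dims; ++k) {
        double d = x[k] - ctr(j, k);
        r2 += d * d;
      }
      double rho = std::sqrt(r2);
      double dev = rho - R;
      double g = std::exp(-dev * dev / (2.0 * sig * sig));
      e += amp * g;
      if (f && rho > 1e-10) {
        // dU/dx = amp * g * (-(rho-R)/sig^2) * (x-c)/rho; F = -dU/dx
        double coef = amp * g * dev / (sig * sig) / rho;
        for (int k = 0; k < dims; ++k)
          f[k] += coef * (x[k] - ctr(j, k));
      }
    }
    return e;
  }

  double confinement(const double* x, double* f) const {
    double e = 0.0;
    for (int k = 0; k < dims; ++k) {
      double d = x[k] - box_center[k];
      double over = std::fabs(d) - L;
      if (over > 0.0) {
        e += wall_k * over * over;
        if (f) f[k] -= 2.0 * wall_k * over * (d > 0 ? 1.0 : -1.0);
      }
    }
    return e;
  }

  double site_distance(const double* x) const {
    double r2 = 0.0;
    for (int k = 0; k < dims; ++k) {
      double d = x[k] - site_center[k];
      r2 += d * d;
    }
    return std::sqrt(r2);
  }
};

// ---------------------------------------------------------------------------
// Collective variables for the metadynamics loop.
// kind: 0 = coordinate (param axis), 1 = distance from a center,
//       2 = angle atan2 about a center in the (axis_a, axis_b) plane.
struct CVDef {
  int kind;
  int axis_a, axis_b;
  std::vector<double> center;
  bool periodic;

  double value(const double* x, int dims) const {
    if (kind == 0) return x[axis_a];
    if (kind == 1) {
      double r2 = 0.0;
      for (int k = 0; k < dims; ++k) {
        double d = x[k] - center[k];
        r2 += d * d;
      }
      return std::sqrt(r2);
    }
    return std::atan2(x[axis_b] - center[axis_b], x[axis_a] - center[axis_a]);
  }

  // gradient ds/dx into g (length dims)
  void grad(const double* x, int dims, double* g) const {
    for (int k = 0; k < dims; ++k) g[k] = 0.0;
    if (kind == 0) {
      g[axis_a] = 1.0;
    } else if (kind == 1) {
      double r = value(x, dims);
      if (r > 1e-10)
        for (int k = 0; k < dims; ++k) g[k] = (x[k] - center[k]) / r;
    } else {
      double dx = x[axis_a] - center[axis_a];
      double dy = x[axis_b] - center[axis_b];
      double r2 = dx * dx + dy * dy;
      if (r2 > 1e-20) {
        g[axis_a] = -dy / r2;
        g[axis_b] = dx / r2;
      }
    }
  }
};

static double wrap_delta(double d, bool periodic) {
  if (!periodic) return d;
  const double twopi = 2.0 * M_PI;
  while (d >= M_PI) d -= twopi;
  while (d < -M_PI) d += twopi;
  return d;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_segment(List sys_list, NumericVector x0, NumericVector v0,
                     double t0, int nsteps, double dt, double temperature,
                     double friction, int stride) {
  ToySys sys(sys_list);
  const int d = sys.dims;
  if (x0.size() != d || v0.size() != d)
    stop("state dimensionality does not match the system");
  if (nsteps < 1) stop("nsteps must be >= 1");
  if (stride < 1) stride = 1;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(d, 0.0);

  const double acc = KCAL_AMU / sys.mass;  // force (kcal/mol/A) -> A/ps^2
  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double vtherm = std::sqrt(KCAL_AMU * KB * temperature / sys.mass);

  int nrec = nsteps / stride + 1 + ((nsteps % stride) ? 1 : 0);
  NumericVector times(nrec), energies(nrec), inter(nrec), dist(nrec);
  NumericMatrix pos(nrec, d), vel(nrec, d);

  // initial force/energy
  std::fill(f.begin(), f.end(), 0.0);
  double ei = sys.interaction(x.data(), f.data());
  double ec = sys.confinement(x.data(), f.data());

  int irec = 0;
  auto record = [&](double t) {
    times[irec] = t;
    energies[irec] = ei + ec;
    inter[irec] = ei;
    dist[irec] = sys.site_distance(x.data());
    for (int k = 0; k < d; ++k) {
      pos(irec, k) = x[k];
      vel(irec, k) = v[k];
    }
    ++irec;
  };
  record(t0);

  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * f[k] * acc;
    // A
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    // O
    if (friction > 0.0) {
      for (int k = 0; k < d; ++k)
        v[k] = c1 * v[k] + c2 * vtherm * norm_rand();
    }
    // A
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    // B
    std::fill(f.begin(), f.end(), 0.0);
    ei = sys.interaction(x.data(), f.data());
    ec = sys.confinement(x.data(), f.data());
    if (!R_finite(ei + ec))
      stop("non-finite energy at step %d", step);
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * f[k] * acc;

    if (step % stride == 0 || step == nsteps) record(t0 + step * dt);
  }

  return List::create(
    _["times"] = times, _["positions"] = pos, _["velocities"] = vel,
    _["potential_energies"] = energies, _["interaction_energies"] = inter,
    _["distances"] = dist);
}

// ---------------------------------------------------------------------------
// Gridded bias over 1 or 2 CVs with analytic Gaussian deposits.
struct BiasGrid {
  int ncv;
  std::vector<int> n;          // nodes per CV
  std::vector<double> lo, hi, step;
  std::vector<bool> periodic;
  std::vector<double> V;       // bias values, row-major [i1 * n2 + i2]
  std::vector<double> G1, G2;  // dV/ds_k at nodes

  void init(int ncv_, const std::vector<int>& n_,
            const std::vector<double>& lo_, const std::vector<double>& hi_,
            const std::vector<bool>& per_) {
    ncv = ncv_; n = n_; lo = lo_; hi = hi_; periodic = per_;
    step.resize(ncv);
    for (int k = 0; k < ncv; ++k) step[k] = (hi[k] - lo[k]) / (n[k] - 1);
    size_t tot = (ncv == 1) ? n[0] : (size_t)n[0] * n[1];
    V.assign(tot, 0.0);
    G1.assign(tot, 0.0);
    if (ncv == 2) G2.assign(tot, 0.0);
  }

  double node(int k, int i) const { return lo[k] + i * step[k]; }

  void deposit(const double* c, const double* sig, double h) {
    if (ncv == 1) {
      for (int i = 0; i < n[0]; ++i) {
        double dlt = wrap_delta(node(0, i) - c[0], periodic[0]);
        double g = h * std::exp(-dlt * dlt / (2.0 * sig[0] * sig[0]));
        V[i] += g;
        G1[i] += -g * dlt / (sig[0] * sig[0]); // dV/ds = -g*(s-c)/sig^2
      }
    } else {
      for (int i = 0; i < n[0]; ++i) {
        double d1 = wrap_delta(node(0, i) - c[0], periodic[0]);
        double g1 = std::exp(-d1 * d1 / (2.0 * sig[0] * sig[0]));
        for (int j = 0; j < n[1]; ++j) {
          double d2 = wrap_delta(node(1, j) - c[1], periodic[1]);
          double g2 = std::exp(-d2 * d2 / (2.0 * sig[1] * sig[1]));
          size_t idx = (size_t)i * n[1] + j;
          double g = h * g1 * g2;
          V[idx] += g;
          G1[idx] += -g * d1 / (sig[0] * sig[0]);
          G2[idx] += -g * d2 / (sig[1] * sig[1]);
        }
      }
    }
  }

  int clamp_cell(int k, double s, double& frac) const {
    double u = (s - lo[k]) / step[k];
    int i = (int)std::floor(u);
    if (i < 0) { i = 0; frac = 0.0; }
    else if (i >= n[k] - 1) { i = n[k] - 2; frac = 1.0; }
    else frac = u - i;
    return i;
  }

  double value(const double* s) const {
    if (ncv == 1) {
      double fr; int i = clamp_cell(0, s[0], fr);
      return (1 - fr) * V[i] + fr * V[i + 1];
    }
    double f1, f2;
    int i = clamp_cell(0, s[0], f1);
    int j = clamp_cell(1, s[1], f2);
    size_t a = (size_t)i * n[1] + j;
    size_t b = (size_t)(i + 1) * n[1] + j;
    return (1 - f1) * ((1 - f2) * V[a] + f2 * V[a + 1]) +
           f1 * ((1 - f2) * V[b] + f2 * V[b + 1]);
  }

  void gradient(const double* s, double* out) const {
    if (ncv == 1) {
      double fr; int i = clamp_cell(0, s[0], fr);
      out[0] = (1 - fr) * G1[i] + fr * G1[i + 1];
    } else {
      double f1, f2;
      int i = clamp_cell(0, s[0], f1);
      int j = clamp_cell(1, s[1], f2);
      size_t a = (size_t)i * n[1] + j;
      size_t b = (size_t)(i + 1) * n[1] + j;
      out[0] = (1 - f1) * ((1 - f2) * G1[a] + f2 * G1[a + 1]) +
               f1 * ((1 - f2) * G1[b] + f2 * G1[b + 1]);
      out[1] = (1 - f1) * ((1 - f2) * G2[a] + f2 * G2[a + 1]) +
               f1 * ((1 - f2) * G2[b] + f2 * G2[b + 1]);
    }
  }
};

// [[Rcpp::export]]
List cpp_run_metad(List sys_list, NumericVector x0, NumericVector v0,
                   double t0, int nsteps, double dt, double temperature,
                   double friction, int record_stride,
                   List cv_list, NumericVector sigmas, double w0,
                   double bias_factor, int deposit_stride_steps,
                   NumericVector grid_lo, NumericVector grid_hi,
                   IntegerVector grid_n) {
  ToySys sys(sys_list);
  const int d = sys.dims;
  const int ncv = cv_list.size();
  if (ncv < 1 || ncv > 2) stop("1 or 2 collective variables supported");
  if (bias_factor <= 1.0) stop("bias_factor must be > 1");

  std::vector<CVDef> cvs(ncv);
  std::vector<bool> per(ncv);
  for (int k = 0; k < ncv; ++k) {
    List cl = cv_list[k];
    cvs[k].kind = as<int>(cl["kind"]);
    cvs[k].axis_a = as<int>(cl["axis_a"]);
    cvs[k].axis_b = as<int>(cl["axis_b"]);
    NumericVector ctr = cl["center"];
    cvs[k].center.assign(ctr.begin(), ctr.end());
    cvs[k].periodic = as<bool>(cl["periodic"]);
    per[k] = cvs[k].periodic;
  }

  BiasGrid grid;
  {
    std::vector<int> gn(grid_n.begin(), grid_n.end());
    std::vector<double> glo(grid_lo.begin(), grid_lo.end());
    std::vector<double> ghi(grid_hi.begin(), grid_hi.end());
    grid.init(ncv, gn, glo, ghi, per);
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(d, 0.0), cvgrad(d, 0.0);
  double s[2], dVds[2];

  const double acc = KCAL_AMU / sys.mass;
  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double vtherm = std::sqrt(KCAL_AMU * KB * temperature / sys.mass);
  const double dT = KB * (bias_factor - 1.0) * temperature; // kcal/mol

  int max_hills = (deposit_stride_steps > 0) ? nsteps / deposit_stride_steps : 0;
  NumericMatrix hill_centers(std::max(max_hills, 1), ncv);
  NumericVector hill_heights(std::max(max_hills, 1));
  NumericVector hill_times(std::max(max_hills, 1));
  int n_hills = 0;

  auto total_force = [&](double* fout, double& e_int, double& e_conf) {
    std::fill(fout, fout + d, 0.0);
    e_int = sys.interaction(x.data(), fout);
    e_conf = sys.confinement(x.data(), fout);
    for (int k = 0; k < ncv; ++k) s[k] = cvs[k].value(x.data(), d);
    grid.gradient(s, dVds);
    for (int k = 0; k < ncv; ++k) {
      cvs[k].grad(x.data(), d, cvgrad.data());
      for (int kk = 0; kk < d; ++kk) fout[kk] -= dVds[k] * cvgrad[kk];
    }
  };

  double ei, ec;
  total_force(f.data(), ei, ec);

  if (record_stride < 1) record_stride = 1;
  int nrec = nsteps / record_stride + 1 + ((nsteps % record_stride) ? 1 : 0);
  NumericVector times(nrec), energies(nrec), inter(nrec), dist(nrec);
  NumericMatrix pos(nrec, d), vel(nrec, d), cv_series(nrec, ncv);
  int irec = 0;
  auto record = [&](double t) {
    times[irec] = t;
    energies[irec] = ei + ec;
    inter[irec] = ei;
    dist[irec] = sys.site_distance(x.data());
    for (int k = 0; k < d; ++k) { pos(irec, k) = x[k]; vel(irec, k) = v[k]; }
    for (int k = 0; k < ncv; ++k)
      cv_series(irec, k) = cvs[k].value(x.data(), d);
    ++irec;
  };
  record(t0);

  for (int step = 1; step <= nsteps; ++step) {
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * f[k] * acc;
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    if (friction > 0.0)
      for (int k = 0; k < d; ++k)
        v[k] = c1 * v[k] + c2 * vtherm * norm_rand();
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    total_force(f.data(), ei, ec);
    if (!R_finite(ei + ec)) stop("non-finite energy at step %d", step);
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * f[k] * acc;

    // well-tempered deposit
    if (deposit_stride_steps > 0 && step % deposit_stride_steps == 0 &&
        n_hills < max_hills) {
      for (int k = 0; k < ncv; ++k) s[k] = cvs[k].value(x.data(), d);
      double Vs = grid.value(s);
      double h = w0 * std::exp(-Vs / dT);
      grid.deposit(s, REAL(sigmas), h);
      for (int k = 0; k < ncv; ++k) hill_centers(n_hills, k) = s[k];
      hill_heights[n_hills] = h;
      hill_times[n_hills] = t0 + step * dt;
      ++n_hills;
    }

    if (step % record_stride == 0 || step == nsteps) record(t0 + step * dt);
  }

  return List::create(
    _["times"] = times, _["positions"] = pos, _["velocities"] = vel,
    _["potential_energies"] = energies, _["interaction_energies"] = inter,
    _["distances"] = dist, _["cv_series"] = cv_series,
    _["hill_centers"] = hill_centers, _["hill_heights"] = hill_heights,
    _["hill_times"] = hill_times, _["n_hills"] = n_hills,
    _["grid_bias"] = NumericVector(grid.V.begin(), grid.V.end()));
}
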