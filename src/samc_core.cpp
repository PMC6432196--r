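// Compiled kernels: square-well energy, bond-preserving MC moves, the SAMC
// loop with adaptive integer energy grid, and the uniform-sampling oracle.
// All randomness comes from R's RNG (unif_rand / norm_rand), so runs are
// reproducible from set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Number of square-well contacts among non-bonded pairs (|i-j| >= 2), or -1
// if any such pair violates the hard core (r < 1).  Squared distances are
// compared against 1 and lambda^2; the well is inclusive at both ends.
static int contact_count(const double* x, const double* y, const double* z,
                         int n, double lam2) {
  int ct = 0;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1.0) return -1;
      if (r2 <= lam2) ++ct;
    }
  }
  return ct;
}

// [[Rcpp::export]]
int cpp_contact_count(NumericMatrix conf, double lambda) {
  int n = conf.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = conf(i,0); y[i] = conf(i,1); z[i] = conf(i,2); }
  return contact_count(x.data(), y.data(), z.data(), n, lambda * lambda);
}

// Binary contact indicator per non-bonded pair, row-major upper triangle.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_map(NumericMatrix conf, double lambda) {
  int n = conf.nrow();
  IntegerMatrix m(n, n);
  double lam2 = lambda * lambda;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = conf(i,0) - conf(j,0), dy = conf(i,1) - conf(j,1),
             dz = conf(i,2) - conf(j,2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= 1.0 && r2 <= lam2) { m(i, j) = 1; m(j, i) = 1; }
    }
  }
  return m;
}

static void rotate_about_axis(double& px, double& py, double& pz,
                              double ox, double oy, double oz,
                              double ux, double uy, double uz,
                              double c, double s) {
  // Rodrigues rotation of p about unit axis u anchored at o.
  double vx = px - ox, vy = py - oy, vz = pz - oz;
  double dot = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  px = ox + vx * c + cx * s + ux * dot * (1.0 - c);
  py = oy + vy * c + cy * s + uy * dot * (1.0 - c);
  pz = oz + vz * c + cz * s + uz * dot * (1.0 - c);
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_tail(NumericMatrix conf, int pivot, NumericVector axis,
                              double angle) {
  // pivot is 0-based; monomers pivot+1..n-1 rotate about axis through conf[pivot].
  int n = conf.nrow();
  NumericMatrix out = clone(conf);
  double c = std::cos(angle), s = std::sin(angle);
  double ox = conf(pivot,0), oy = conf(pivot,1), oz = conf(pivot,2);
  for (int i = pivot + 1; i < n; ++i) {
    double px = out(i,0), py = out(i,1), pz = out(i,2);
    rotate_about_axis(px, py, pz, ox, oy, oz, axis[0], axis[1], axis[2], c, s);
    out(i,0) = px; out(i,1) = py; out(i,2) = pz;
  }
  return out;
}

static void random_unit_vector(double& ux, double& uy, double& uz) {
  // Marsaglia via normals from R's RNG.
  ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (nrm < 1e-300) { ux = 1; uy = 0; uz = 0; return; }
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// Propose one move in place on (cx, cy, cz); kind: 0 pivot, 1 crankshaft,
// 2 end rotation.  All preserve bond lengths exactly (rigid rotations).
static void propose(std::vector<double>& cx, std::vector<double>& cy,
                    std::vector<double>& cz, int n,
                    const double* w, const double* maxang) {
  double u = unif_rand() * (w[0] + w[1] + w[2]);
  int kind = (u < w[0]) ? 0 : (u < w[0] + w[1]) ? 1 : 2;
  double ux, uy, uz;
  if (kind == 0) {
    // pivot: rotate tail i+1..n-1 (or head, mirrored) about random axis
    int piv = (int)(unif_rand() * (n - 1));     // 0..n-2
    if (piv > n - 2) piv = n - 2;
    bool head = unif_rand() < 0.5;
    random_unit_vector(ux, uy, uz);
    double ang = (2.0 * unif_rand() - 1.0) * maxang[0];
    double c = std::cos(ang), s = std::sin(ang);
    if (!head) {
      double ox = cx[piv], oy = cy[piv], oz = cz[piv];
      for (int i = piv + 1; i < n; ++i)
        rotate_about_axis(cx[i], cy[i], cz[i], ox, oy, oz, ux, uy, uz, c, s);
    } else {
      int p2 = piv + 1;                          // 1..n-1; rotate 0..p2-1
      double ox = cx[p2], oy = cy[p2], oz = cz[p2];
      for (int i = 0; i < p2; ++i)
        rotate_about_axis(cx[i], cy[i], cz[i], ox, oy, oz, ux, uy, uz, c, s);
    }
  } else if (kind == 1 && n >= 3) {
    // crankshaft: rotate interior monomer i about the (i-1, i+1) axis
    int i = 1 + (int)(unif_rand() * (n - 2));
    if (i > n - 2) i = n - 2;
    double ax = cx[i+1] - cx[i-1], ay = cy[i+1] - cy[i-1], az = cz[i+1] - cz[i-1];
    double nrm = std::sqrt(ax * ax + ay * ay + az * az);
    double ang = (2.0 * unif_rand() - 1.0) * maxang[1];
    if (nrm < 1e-12) {
      // chain folded exactly back: rotate monomer i on its sphere about i-1
      random_unit_vector(ux, uy, uz);
      rotate_about_axis(cx[i], cy[i], cz[i], cx[i-1], cy[i-1], cz[i-1],
                        ux, uy, uz, std::cos(ang), std::sin(ang));
    } else {
      rotate_about_axis(cx[i], cy[i], cz[i], cx[i-1], cy[i-1], cz[i-1],
                        ax / nrm, ay / nrm, az / nrm, std::cos(ang), std::sin(ang));
    }
  } else {
    // end rotation: rotate a terminal monomer about a random axis through
    // its bonded neighbour
    bool tail = unif_rand() < 0.5;
    int e = tail ? n - 1 : 0, nb = tail ? n - 2 : 1;
    random_unit_vector(ux, uy, uz);
    double ang = (2.0 * unif_rand() - 1.0) * maxang[2];
    rotate_about_axis(cx[e], cy[e], cz[e], cx[nb], cy[nb], cz[nb],
                      ux, uy, uz, std::cos(ang), std::sin(ang));
  }
}

// SAMC run.  Energies are exact integers E = -contacts; internal index is
// -E in 0..max_contacts.  grid adaptive: a bin enters the grid (M grows)
// when its energy is first reached by the post-decision state; fixed: all
// integers in [e_min, e_max] from the start.
// [[Rcpp::export]]
List cpp_run_samc(NumericMatrix conf0, double lambda,
                  double n_steps, double gamma0, double t0,
                  NumericVector weights, NumericVector max_angles,
                  std::string grid_policy, IntegerVector fixed_range,
                  double obs_from, int obs_stride, double t_offset,
                  double avg_from,
                  IntegerVector init_energies, NumericVector init_ln_g,
                  NumericVector init_visits, double init_base) {
  int n = conf0.nrow();
  double lam2 = lambda * lambda;
  int max_ct = (n - 1) * (n - 2) / 2;            // all pairs |i-j| >= 2
  std::vector<double> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) { cx[i] = conf0(i,0); cy[i] = conf0(i,1); cz[i] = conf0(i,2); }

  int e_cur = contact_count(cx.data(), cy.data(), cz.data(), n, lam2);
  if (e_cur < 0) stop("initial conformation violates the hard core");

  int nbin = max_ct + 1;                          // index k = contacts = -E
  std::vector<double> ln_g(nbin, 0.0);
  std::vector<double> visits(nbin, 0.0);
  std::vector<bool> in_grid(nbin, false);
  std::vector<int> grid;                          // indices currently in grid
  grid.reserve(nbin);
  if (init_energies.size() > 0) {                 // resume from a checkpoint
    for (int i = 0; i < init_energies.size(); ++i) {
      int k = -init_energies[i];
      if (k < 0 || k >= nbin) stop("checkpoint energy out of range");
      in_grid[k] = true; grid.push_back(k);
      ln_g[k] = init_ln_g[i]; visits[k] = init_visits[i];
    }
    if (!in_grid[e_cur] && grid_policy != "fixed") {
      in_grid[e_cur] = true; grid.push_back(e_cur);
    }
  } else if (grid_policy == "fixed") {
    int kmin = -fixed_range[1], kmax = -fixed_range[0]; // energies -> contact idx
    if (kmin < 0 || kmax < kmin) stop("invalid fixed grid range");
    for (int k = kmin; k <= kmax && k < nbin; ++k) { in_grid[k] = true; grid.push_back(k); }
  } else {
    in_grid[e_cur] = true; grid.push_back(e_cur);
  }

  // per-energy observables
  std::vector<double> obs_n(nbin, 0.0), rg2_mean(nbin, 0.0);
  std::vector<std::vector<double>> contact_ct(nbin);
  // Polyak-Ruppert time average of ln_g over the late phase: the SAMC
  // iterate fluctuates around the fixed point with sd ~ sqrt(gamma tau);
  // averaging the trajectory removes most of that variance.
  std::vector<double> avg_sum(nbin, 0.0), avg_n(nbin, 0.0);

  std::vector<double> px(n), py(n), pz(n);
  double acc = 0.0;
  // "base" is the value a bin would hold had it sat in the grid unvisited
  // since the start (it only ever received the -gamma/M subtractions).
  // Newly discovered bins enter at base, i.e. below every visited bin, which
  // keeps the flat-histogram pull toward unexplored energies; this matches
  // the behaviour of a full-range grid initialized at g0(E) = 1.
  double base = init_base;
  int max_ct_seen = e_cur;                        // most contacts = lowest E
  std::vector<double> gx(cx), gy(cy), gz(cz);    // ground-state snapshot

  long long steps = (long long) n_steps;
  for (long long t = 1; t <= steps; ++t) {
    double tt = t_offset + (double) t;
    double gam = (tt <= t0) ? gamma0 : gamma0 * t0 / tt;

    px = cx; py = cy; pz = cz;
    propose(px, py, pz, n, weights.begin(), max_angles.begin());
    int e_new = contact_count(px.data(), py.data(), pz.data(), n, lam2);
    if (e_new >= 0) {
      double lg_new = in_grid[e_new] ? ln_g[e_new] : base;
      double lg_old = ln_g[e_cur];
      if (lg_new <= lg_old || unif_rand() < std::exp(lg_old - lg_new)) {
        cx.swap(px); cy.swap(py); cz.swap(pz);
        e_cur = e_new;
        acc += 1.0;
      }
    }
    if (!in_grid[e_cur]) {
      if (grid_policy == "fixed")
        stop("visited energy %d lies outside the declared fixed grid", -e_cur);
      in_grid[e_cur] = true; grid.push_back(e_cur);
      ln_g[e_cur] = base;
    }
    // Eq. ln g(E) += gamma (delta_{E,E'} - 1/M) applied to every grid bin
    double m = (double) grid.size();
    double sub = gam / m;
    bool averaging = t >= (long long) avg_from;
    base -= sub;
    for (size_t gi = 0; gi < grid.size(); ++gi) ln_g[grid[gi]] -= sub;
    ln_g[e_cur] += gam;
    visits[e_cur] += 1.0;
    if (averaging) {
      for (size_t gi = 0; gi < grid.size(); ++gi) {
        int k = grid[gi];
        avg_sum[k] += ln_g[k]; avg_n[k] += 1.0;
      }
    }

    if (e_cur > max_ct_seen) {
      max_ct_seen = e_cur; gx = cx; gy = cy; gz = cz;
    }

    if (t >= (long long) obs_from && (t % obs_stride) == 0) {
      double mx = 0, my = 0, mz = 0;
      for (int i = 0; i < n; ++i) { mx += cx[i]; my += cy[i]; mz += cz[i]; }
      mx /= n; my /= n; mz /= n;
      double rg2 = 0;
      for (int i = 0; i < n; ++i) {
        double dx = cx[i] - mx, dy = cy[i] - my, dz = cz[i] - mz;
        rg2 += dx * dx + dy * dy + dz * dz;
      }
      rg2 /= n;
      double k = ++obs_n[e_cur];
      rg2_mean[e_cur] += (rg2 - rg2_mean[e_cur]) / k;
      if (contact_ct[e_cur].empty()) contact_ct[e_cur].assign((size_t) n * n, 0.0);
      std::vector<double>& cc = contact_ct[e_cur];
      for (int i = 0; i < n - 2; ++i)
        for (int j = i + 2; j < n; ++j) {
          double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= 1.0 && r2 <= lam2) { cc[i * n + j] += 1.0; cc[j * n + i] += 1.0; }
        }
    }
  }

  // collect grid bins sorted by energy (ascending E = descending contacts)
  std::vector<int> idx(grid);
  std::sort(idx.begin(), idx.end(), [](int a, int b) { return a > b; });
  int m = idx.size();
  IntegerVector energies(m);
  NumericVector lng(m), lng_avg(m), vis(m), on(m), rg2(m);
  List cmats(m);
  for (int i = 0; i < m; ++i) {
    int k = idx[i];
    energies[i] = -k;
    lng[i] = ln_g[k];
    lng_avg[i] = avg_n[k] > 0 ? avg_sum[k] / avg_n[k] : ln_g[k];
    vis[i] = visits[k];
    on[i] = obs_n[k];
    rg2[i] = rg2_mean[k];
    if (!contact_ct[k].empty() && obs_n[k] > 0) {
      NumericMatrix cm(n, n);
      for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b)
          cm(a, b) = contact_ct[k][(size_t) a * n + b] / obs_n[k];
      cmats[i] = cm;
    } else {
      cmats[i] = R_NilValue;
    }
  }
  NumericMatrix final_conf(n, 3), ground_conf(n, 3);
  for (int i = 0; i < n; ++i) {
    final_conf(i,0) = cx[i]; final_conf(i,1) = cy[i]; final_conf(i,2) = cz[i];
    ground_conf(i,0) = gx[i]; ground_conf(i,1) = gy[i]; ground_conf(i,2) = gz[i];
  }
  return List::create(
    _["energies"] = energies, _["ln_g"] = lng, _["ln_g_avg"] = lng_avg,
    _["visits"] = vis,
    _["obs_count"] = on, _["rg2_mean"] = rg2, _["contact_freq"] = cmats,
    _["acceptance_rate"] = acc / (double) steps,
    _["base"] = base,
    _["ground_energy"] = -(double) max_ct_seen,
    _["ground_conf"] = ground_conf, _["final_conf"] = final_conf);
}

// Uniform-measure oracle: successive bond directions drawn uniformly on the
// sphere; hard-core violators discarded; energies of survivors histogrammed.
// With fixed bond lengths the configuration integral factorizes over bond
// directions, so survivor frequencies are proportional to g(E) restricted to
// self-avoiding states.
// [[Rcpp::export]]
List cpp_uniform_dos(int n, double L, double lambda, double n_samples) {
  double lam2 = lambda * lambda;
  int max_ct = (n - 1) * (n - 2) / 2;
  std::vector<double> counts(max_ct + 1, 0.0);
  std::vector<double> cx(n), cy(n), cz(n);
  long long ns = (long long) n_samples;
  double n_valid = 0.0;
  for (long long s = 0; s < ns; ++s) {
    cx[0] = 0; cy[0] = 0; cz[0] = 0;
    bool ok = true;
    for (int i = 1; i < n; ++i) {
      double ux, uy, uz;
      random_unit_vector(ux, uy, uz);
      cx[i] = cx[i-1] + L * ux; cy[i] = cy[i-1] + L * uy; cz[i] = cz[i-1] + L * uz;
      // early hard-core check against all previous non-bonded monomers
      for (int j = 0; j <= i - 2; ++j) {
        double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
        if (dx * dx + dy * dy + dz * dz < 1.0) { ok = false; break; }
      }
      if (!ok) break;
    }
    if (!ok) continue;
    int ct = contact_count(cx.data(), cy.data(), cz.data(), n, lam2);
    counts[ct] += 1.0;
    n_valid += 1.0;
  }
  std::vector<int> lev;
  for (int k = max_ct; k >= 0; --k) if (counts[k] > 0) lev.push_back(k);
  int m = lev.size();
  IntegerVector energies(m);
  NumericVector cnt(m);
  for (int i = 0; i < m; ++i) { energies[i] = -lev[i]; cnt[i] = counts[lev[i]]; }
  return List::create(_["energies"] = energies, _["counts"] = cnt,
                      _["n_valid"] = n_valid, _["n_total"] = (double) ns);
}
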