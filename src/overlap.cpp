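#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order (pairwise-sum) Gaussian overlap volume between two
// atom-centred Gaussian densities:
//   V = sum_{i,j} p2 * (pi/(ai+aj))^{3/2} * exp(-ai*aj/(ai+aj) * d_ij^2)
// This equals the L2 inner product of the two summed densities.

static double overlap_core(const double* ax, int na, const double* aa,
                           const double* bx, int nb, const double* ba,
                           double p2, double* gb /* nb x 3, or NULL */) {
  const double pi = M_PI;
  double V = 0.0;
  if (gb) std::fill(gb, gb + 3 * nb, 0.0);
  for (int j = 0; j < nb; ++j) {
    const double bxj = bx[j], byj = bx[j + nb], bzj = bx[j + 2 * nb];
    const double alj = ba[j];
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int i = 0; i < na; ++i) {
      const double dx = bxj - ax[i];
      const double dy = byj - ax[i + na];
      const double dz = bzj - ax[i + 2 * na];
      const double s = aa[i] + alj;
      const double c = aa[i] * alj / s;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double k = p2 * std::pow(pi / s, 1.5) * std::exp(-c * d2);
      V += k;
      if (gb) {
        const double f = -2.0 * c * k;
        gx += f * dx; gy += f * dy; gz += f * dz;
      }
    }
    if (gb) { gb[j] = gx; gb[j + nb] = gy; gb[j + 2 * nb] = gz; }
  }
  return V;
}

// [[Rcpp::export]]
double cpp_overlap(NumericMatrix ax, NumericVector aalpha,
                   NumericMatrix bx, NumericVector balpha, double p2) {
  return overlap_core(ax.begin(), ax.nrow(), aalpha.begin(),
                      bx.begin(), bx.nrow(), balpha.begin(), p2, nullptr);
}

static void rodrigues(const double w[3], double R[9]) {
  const double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-14) {
    R[0] = 1; R[1] = 0; R[2] = 0;
    R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  const double kx = w[0] / th, ky = w[1] / th, kz = w[2] / th;
  const double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  // row-major
  R[0] = c + kx * kx * v;      R[1] = kx * ky * v - kz * s; R[2] = kx * kz * v + ky * s;
  R[3] = ky * kx * v + kz * s; R[4] = c + ky * ky * v;      R[5] = ky * kz * v - kx * s;
  R[6] = kz * kx * v - ky * s; R[7] = kz * ky * v + kx * s; R[8] = c + kz * kz * v;
}

struct OptResult {
  double V;
  double R[9];
  double t[3];
  bool converged;
  int iterations;
};

// Local maximization of the overlap volume over rigid motions of shape B.
// Steepest-ascent on a 6-parameter (rotation about the moving centroid,
// translation) relinearized each step, with an adaptive step size and
// backtracking. aligned_b = R %*% b0 + t.
static OptResult optimize_local(const double* ax, int na, const double* aa,
                                const double* b0, int nb, const double* ba,
                                double p2, int maxit, double tol) {
  std::vector<double> bx(b0, b0 + 3 * nb);
  std::vector<double> gb(3 * nb), btry(3 * nb);
  double Rtot[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double ttot[3] = {0, 0, 0};
  double V = overlap_core(ax, na, aa, bx.data(), nb, ba, p2, gb.data());
  double h = 0.0; // adaptive step scale, set from first gradient
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // centroid of current b
    double m[3] = {0, 0, 0};
    for (int j = 0; j < nb; ++j) {
      m[0] += bx[j]; m[1] += bx[j + nb]; m[2] += bx[j + 2 * nb];
    }
    m[0] /= nb; m[1] /= nb; m[2] /= nb;
    // gradient wrt translation and rotation (about m)
    double gt[3] = {0, 0, 0}, gw[3] = {0, 0, 0};
    for (int j = 0; j < nb; ++j) {
      const double gx = gb[j], gy = gb[j + nb], gz = gb[j + 2 * nb];
      gt[0] += gx; gt[1] += gy; gt[2] += gz;
      const double rx = bx[j] - m[0], ry = bx[j + nb] - m[1],
                   rz = bx[j + 2 * nb] - m[2];
      gw[0] += ry * gz - rz * gy;
      gw[1] += rz * gx - rx * gz;
      gw[2] += rx * gy - ry * gx;
    }
    const double gnorm = std::sqrt(gt[0] * gt[0] + gt[1] * gt[1] +
                                   gt[2] * gt[2] + gw[0] * gw[0] +
                                   gw[1] * gw[1] + gw[2] * gw[2]);
    if (gnorm < 1e-12 * (1.0 + V)) { converged = true; break; }
    if (h <= 0.0) h = 0.1 / gnorm;
    // cap rotation step at 0.5 rad
    double wn = h * std::sqrt(gw[0] * gw[0] + gw[1] * gw[1] + gw[2] * gw[2]);
    double scale = (wn > 0.5) ? 0.5 / wn : 1.0;
    bool accepted = false;
    double Vnew = V;
    for (int bt = 0; bt < 40; ++bt) {
      const double hs = h * scale;
      double w[3] = {hs * gw[0], hs * gw[1], hs * gw[2]};
      double t[3] = {hs * gt[0], hs * gt[1], hs * gt[2]};
      double Rw[9];
      rodrigues(w, Rw);
      for (int j = 0; j < nb; ++j) {
        const double rx = bx[j] - m[0], ry = bx[j + nb] - m[1],
                     rz = bx[j + 2 * nb] - m[2];
        btry[j] = Rw[0] * rx + Rw[1] * ry + Rw[2] * rz + m[0] + t[0];
        btry[j + nb] = Rw[3] * rx + Rw[4] * ry + Rw[5] * rz + m[1] + t[1];
        btry[j + 2 * nb] = Rw[6] * rx + Rw[7] * ry + Rw[8] * rz + m[2] + t[2];
      }
      Vnew = overlap_core(ax, na, aa, btry.data(), nb, ba, p2, gb.data());
      if (Vnew > V) {
        // accept: update accumulated transform
        double Rn[9], tn[3];
        for (int r = 0; r < 3; ++r) {
          for (int c2 = 0; c2 < 3; ++c2) {
            Rn[3 * r + c2] = Rw[3 * r] * Rtot[c2] + Rw[3 * r + 1] * Rtot[3 + c2] +
                             Rw[3 * r + 2] * Rtot[6 + c2];
          }
          tn[r] = Rw[3 * r] * ttot[0] + Rw[3 * r + 1] * ttot[1] +
                  Rw[3 * r + 2] * ttot[2] + m[r] + t[r] -
                  (Rw[3 * r] * m[0] + Rw[3 * r + 1] * m[1] + Rw[3 * r + 2] * m[2]);
        }
        std::copy(Rn, Rn + 9, Rtot);
        std::copy(tn, tn + 3, ttot);
        std::swap(bx, btry);
        accepted = true;
        h *= 1.6;
        break;
      }
      h *= 0.4;
      wn = h * std::sqrt(gw[0] * gw[0] + gw[1] * gw[1] + gw[2] * gw[2]);
      scale = (wn > 0.5) ? 0.5 / wn : 1.0;
    }
    if (!accepted) { converged = true; break; }
    if (Vnew - V <= tol * std::max(1.0, std::fabs(V))) {
      V = Vnew; converged = true; break;
    }
    V = Vnew;
  }
  OptResult res;
  res.V = V;
  std::copy(Rtot, Rtot + 9, res.R);
  std::copy(ttot, ttot + 3, res.t);
  res.converged = converged;
  res.iterations = it;
  return res;
}

// [[Rcpp::export]]
List cpp_optimize_overlap(NumericMatrix ax, NumericVector aalpha,
                          NumericMatrix bx0, NumericVector balpha,
                          double p2, int maxit = 200, double tol = 1e-6) {
  OptResult res = optimize_local(ax.begin(), ax.nrow(), aalpha.begin(),
                                 bx0.begin(), bx0.nrow(), balpha.begin(),
                                 p2, maxit, tol);
  NumericMatrix Rout(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c2 = 0; c2 < 3; ++c2) Rout(r, c2) = res.R[3 * r + c2];
  return List::create(_["V"] = res.V, _["R"] = Rout,
                      _["t"] = NumericVector::create(res.t[0], res.t[1],
                                                     res.t[2]),
                      _["converged"] = res.converged,
                      _["iterations"] = res.iterations);
}

// Runs the local optimizer from the four proper axis-flip starting poses of
// principal-frame-aligned inputs (both already centred and rotated to their
// principal frames). Returns the best overlap and the transform such that
// aligned_b = R %*% b0 + t with b0 the unflipped input.
// [[Rcpp::export]]
List cpp_optimize_overlap4(NumericMatrix ax, NumericVector aalpha,
                           NumericMatrix bx0, NumericVector balpha,
                           double p2, int maxit = 200, double tol = 1e-6) {
  const int nb = bx0.nrow();
  const double flips[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1},
                              {-1, -1, 1}};
  OptResult best;
  best.V = -1.0;
  int best_f = 0;
  std::vector<double> bstart(3 * nb);
  for (int f = 0; f < 4; ++f) {
    for (int c2 = 0; c2 < 3; ++c2) {
      const double s = flips[f][c2];
      for (int j = 0; j < nb; ++j) bstart[j + c2 * nb] = s * bx0[j + c2 * nb];
    }
    OptResult res = optimize_local(ax.begin(), ax.nrow(), aalpha.begin(),
                                   bstart.data(), nb, balpha.begin(), p2,
                                   maxit, tol);
    if (res.V > best.V) { best = res; best_f = f; }
  }
  // fold the winning flip into the rotation: R_out = R * F
  NumericMatrix Rout(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c2 = 0; c2 < 3; ++c2)
      Rout(r, c2) = best.R[3 * r + c2] * flips[best_f][c2];
  return List::create(_["V"] = best.V, _["R"] = Rout,
                      _["t"] = NumericVector::create(best.t[0], best.t[1],
                                                     best.t[2]),
                      _["converged"] = best.converged);
}
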