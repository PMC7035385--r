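#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Accumulate elliptical Gaussian spots into an image. Matrix is indexed
// [fast, slow] (nrow = n_fast); positions are 0-based fractional pixels.
// Each spot carries total integrated intensity `intensity[i]`; the Gaussian
// is truncated at `trunc` sigma and renormalized over the untruncated
// analytic integral (truncation loss < 0.4% at trunc = 4).
// [[Rcpp::export]]
NumericMatrix cpp_render_spots(int n_fast, int n_slow,
                               NumericVector x, NumericVector y,
                               NumericVector intensity,
                               NumericVector sx, NumericVector sy,
                               NumericVector theta, double trunc) {
  NumericMatrix img(n_fast, n_slow);
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    double sxi = sx[i], syi = sy[i];
    double ct = std::cos(theta[i]), st = std::sin(theta[i]);
    double ext = trunc * std::max(sxi, syi);
    int x0 = std::max(0, (int)std::floor(x[i] - ext));
    int x1 = std::min(n_fast - 1, (int)std::ceil(x[i] + ext));
    int y0 = std::max(0, (int)std::floor(y[i] - ext));
    int y1 = std::min(n_slow - 1, (int)std::ceil(y[i] + ext));
    if (x1 < x0 || y1 < y0) continue;
    double norm = intensity[i] / (2.0 * M_PI * sxi * syi);
    for (int yy = y0; yy <= y1; ++yy) {
      double dy = yy - y[i];
      for (int xx = x0; xx <= x1; ++xx) {
        double dx = xx - x[i];
        double u = ct * dx + st * dy;   // rotate into ellipse frame
        double v = -st * dx + ct * dy;
        double q = 0.5 * (u * u / (sxi * sxi) + v * v / (syi * syi));
        if (q > 0.5 * trunc * trunc) continue;
        img(xx, yy) += norm * std::exp(-q);
      }
    }
  }
  return img;
}

static inline void quat_to_mat(const double* q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// Score candidate orientations (rows of `quat`, w-x-y-z) against observed
// reciprocal vectors G (n x 3, lab frame). For orientation R the crystal-frame
// fractional indices are Binv %*% t(R) %*% g. Because a still pattern does
// not measure the component of g along the beam (only the on-Ewald
// projection is known), the indices are tested up to a free shift t * u,
// u = Binv R^T zhat, |t| <= zeta_max (the excitation window): a peak counts
// as matched when some lattice point lies within `tol` of the shifted
// fractional index (and is not the origin). Candidate shifts are solved on
// the component with the largest |u|.
// Returns an nq x 2 matrix: column 0 the match count, column 1 a smooth
// closeness score (sum over matched peaks of 1 - (residual/tol)^2), which
// keeps a usable gradient where the count saturates.
// score one rotation matrix R (row-major) against peak g-vectors
static void score_rotation(const double* R, const double* B,
                           const double* gx, const double* gy,
                           const double* gz, int ng, double tol,
                           double zeta_max, int* count, double* closeness) {
  // M = Binv * R^T  (crystal fractional coords of a lab vector)
  double M[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      M[3 * r + c] = B[3 * r + 0] * R[3 * c + 0] + B[3 * r + 1] * R[3 * c + 1] +
                     B[3 * r + 2] * R[3 * c + 2];
  double u[3] = { M[2], M[5], M[8] };
  int piv = 0;
  if (std::fabs(u[1]) > std::fabs(u[piv])) piv = 1;
  if (std::fabs(u[2]) > std::fabs(u[piv])) piv = 2;
  double upiv = u[piv];
  *count = 0; *closeness = 0.0;
  if (std::fabs(upiv) < 1e-12) return;
  int a1 = (piv + 1) % 3, a2 = (piv + 2) % 3;
  int s = 0;
  double close = 0.0;
  for (int j = 0; j < ng; ++j) {
    double f[3];
    f[0] = M[0] * gx[j] + M[1] * gy[j] + M[2] * gz[j];
    f[1] = M[3] * gx[j] + M[4] * gy[j] + M[5] * gz[j];
    f[2] = M[6] * gx[j] + M[7] * gy[j] + M[8] * gz[j];
    // interval of reachable pivot values
    double d1 = f[piv] - zeta_max * upiv, d2 = f[piv] + zeta_max * upiv;
    double lo = std::min(d1, d2) - tol, hi = std::max(d1, d2) + tol;
    double best = -1.0;
    for (int p = (int)std::ceil(lo); p <= (int)std::floor(hi); ++p) {
      double t = (p - f[piv]) / upiv;
      if (std::fabs(t) > zeta_max + tol / std::fabs(upiv)) continue;
      double v1 = f[a1] + t * u[a1];
      double v2 = f[a2] + t * u[a2];
      double r1 = std::fabs(v1 - std::round(v1));
      double r2 = std::fabs(v2 - std::round(v2));
      double r = std::max(r1, r2);
      if (r <= tol &&
          (std::abs(p) + std::fabs(std::round(v1)) +
           std::fabs(std::round(v2)) > 0.5)) {
        double w = 1.0 - (r / tol) * (r / tol);
        if (w > best) best = w;
      }
    }
    if (best >= 0.0) { ++s; close += best; }
  }
  *count = s; *closeness = close;
}

// [[Rcpp::export]]
NumericMatrix cpp_score_orientations(NumericMatrix quat, NumericMatrix binv,
                                     NumericMatrix G, double tol,
                                     double zeta_max) {
  int nq = quat.nrow(), ng = G.nrow();
  NumericMatrix score(nq, 2);
  double B[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) B[3 * r + c] = binv(r, c);
  std::vector<double> gx(ng), gy(ng), gz(ng);
  for (int j = 0; j < ng; ++j) { gx[j] = G(j, 0); gy[j] = G(j, 1); gz[j] = G(j, 2); }
  for (int i = 0; i < nq; ++i) {
    double q[4] = { quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3) };
    double R[9];
    quat_to_mat(q, R);
    int cnt; double close;
    score_rotation(R, B, gx.data(), gy.data(), gz.data(), ng, tol, zeta_max,
                   &cnt, &close);
    score(i, 0) = cnt;
    score(i, 1) = close;
  }
  return score;
}

static void rotvec_to_mat(const double* v, double R[9]) {
  double th = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (th < 1e-14) {
    R[0] = R[4] = R[8] = 1; R[1] = R[2] = R[3] = R[5] = R[6] = R[7] = 0;
    return;
  }
  double kx = v[0] / th, ky = v[1] / th, kz = v[2] / th;
  double c = std::cos(th), s = std::sin(th), C = 1 - c;
  R[0] = c + kx * kx * C;      R[1] = kx * ky * C - kz * s; R[2] = kx * kz * C + ky * s;
  R[3] = ky * kx * C + kz * s; R[4] = c + ky * ky * C;      R[5] = ky * kz * C - kx * s;
  R[6] = kz * kx * C - ky * s; R[7] = kz * ky * C + kx * s; R[8] = c + kz * kz * C;
}

static void mat_mul(const double* A, const double* Bm, double* C) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      C[3 * r + c] = A[3 * r + 0] * Bm[0 + c] + A[3 * r + 1] * Bm[3 + c] +
                     A[3 * r + 2] * Bm[6 + c];
}

// Greedy local orientation search for a batch of starting quaternions:
// 3x3x3 rotation-vector offsets with a step that halves per level and a
// per-level tolerance. Returns n x 11: the refined rotation matrix
// (row-major) plus the final count and closeness.
// [[Rcpp::export]]
NumericMatrix cpp_hill_climb(NumericMatrix quat, NumericMatrix binv,
                             NumericMatrix G, double step0,
                             NumericVector tols, int n_moves,
                             double zeta_max) {
  int nq = quat.nrow(), ng = G.nrow();
  int n_levels = tols.size();
  NumericMatrix out(nq, 11);
  double B[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) B[3 * r + c] = binv(r, c);
  std::vector<double> gx(ng), gy(ng), gz(ng);
  for (int j = 0; j < ng; ++j) { gx[j] = G(j, 0); gy[j] = G(j, 1); gz[j] = G(j, 2); }
  for (int i = 0; i < nq; ++i) {
    double q[4] = { quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3) };
    double R[9];
    quat_to_mat(q, R);
    double step = step0;
    int best_cnt = 0; double best_close = 0.0;
    for (int lev = 0; lev < n_levels; ++lev) {
      double tol = tols[lev];
      for (int move = 0; move < n_moves; ++move) {
        int best_o = -1;
        best_cnt = 0; best_close = -1.0;
        double bestR[9];
        for (int o = 0; o < 27; ++o) {
          double v[3] = { (double)(o % 3 - 1) * step,
                          (double)((o / 3) % 3 - 1) * step,
                          (double)(o / 9 - 1) * step };
          double D[9], Rc[9];
          rotvec_to_mat(v, D);
          mat_mul(D, R, Rc);
          int cnt; double close;
          score_rotation(Rc, B, gx.data(), gy.data(), gz.data(), ng, tol,
                         zeta_max, &cnt, &close);
          if (close > best_close) {
            best_close = close; best_cnt = cnt; best_o = o;
            for (int t = 0; t < 9; ++t) bestR[t] = Rc[t];
          }
        }
        for (int t = 0; t < 9; ++t) R[t] = bestR[t];
        if (best_o == 13) break;   // center offset: no improvement
      }
      step /= 2;
    }
    for (int t = 0; t < 9; ++t) out(i, t) = R[t];
    out(i, 9) = best_cnt;
    out(i, 10) = best_close;
  }
  return out;
}

// 8-connected component labeling of a logical mask (stored as int matrix),
// breadth-first. Returns integer matrix of labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(r0 + nr * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Background-corrected box integration at predicted positions.
// For each position: box = square of half-width box_r; annulus = pixels with
// ann_in < max(|dx|,|dy|) <= ann_out. Background = outlier-clipped mean of
// the annulus (pixels above median + 3 * max(1.4826 MAD, sqrt(median+0.5))
// rejected, which removes neighbouring-spot contamination; a plain median
// is biased low for the near-empty Poisson backgrounds of counting
// detectors). Returns columns:
// sum_box, n_box, n_box_masked, bg_mean, bg_sigma, n_ann_kept.
// [[Rcpp::export]]
NumericMatrix cpp_integrate_boxes(NumericMatrix img, LogicalMatrix valid,
                                  NumericVector x, NumericVector y,
                                  int box_r, int ann_in, int ann_out) {
  int nf = img.nrow(), ns = img.ncol(), n = x.size();
  NumericMatrix out(n, 6);
  std::vector<double> ann;
  ann.reserve((2 * ann_out + 1) * (2 * ann_out + 1));
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::round(x[i]), cy = (int)std::round(y[i]);
    double s = 0.0;
    int nbox = 0, nmask = 0;
    ann.clear();
    for (int dy = -ann_out; dy <= ann_out; ++dy) {
      for (int dx = -ann_out; dx <= ann_out; ++dx) {
        int xx = cx + dx, yy = cy + dy;
        int ring = std::max(std::abs(dx), std::abs(dy));
        bool inb = (xx >= 0 && xx < nf && yy >= 0 && yy < ns);
        if (ring <= box_r) {
          if (!inb || !valid(xx, yy)) { ++nmask; continue; }
          s += img(xx, yy);
          ++nbox;
        } else if (ring > ann_in && ring <= ann_out) {
          if (inb && valid(xx, yy)) ann.push_back(img(xx, yy));
        }
      }
    }
    double bg_mean = NA_REAL, bg_sigma = NA_REAL;
    int n_keep = 0;
    int na = (int)ann.size();
    if (na > 0) {
      std::vector<double> tmp(ann);
      size_t m = na / 2;
      std::nth_element(tmp.begin(), tmp.begin() + m, tmp.end());
      double med = tmp[m];
      if (na % 2 == 0) {
        std::nth_element(tmp.begin(), tmp.begin() + m - 1, tmp.begin() + m);
        med = 0.5 * (med + tmp[m - 1]);
      }
      for (int j = 0; j < na; ++j) tmp[j] = std::fabs(ann[j] - med);
      std::nth_element(tmp.begin(), tmp.begin() + m, tmp.end());
      double madv = tmp[m];
      if (na % 2 == 0) {
        std::nth_element(tmp.begin(), tmp.begin() + m - 1, tmp.begin() + m);
        madv = 0.5 * (madv + tmp[m - 1]);
      }
      double sp = std::max(1.4826 * madv, std::sqrt(std::max(med, 0.0) + 0.5));
      double cut = med + 3.0 * sp;
      double sum = 0.0, sum2 = 0.0;
      for (int j = 0; j < na; ++j) {
        if (ann[j] <= cut) { sum += ann[j]; sum2 += ann[j] * ann[j]; ++n_keep; }
      }
      if (n_keep > 0) {
        bg_mean = sum / n_keep;
        bg_sigma = n_keep > 1
          ? std::sqrt(std::max(sum2 / n_keep - bg_mean * bg_mean, 0.0))
          : 0.0;
      }
    }
    out(i, 0) = s; out(i, 1) = nbox; out(i, 2) = nmask;
    out(i, 3) = bg_mean; out(i, 4) = bg_sigma; out(i, 5) = n_keep;
  }
  return out;
}

// Nearest neighbor within tol: for each point (px, py), the index (1-based)
// of the closest (qx, qy), or 0 when none lies within tol. Squared distance
// returned alongside. Grid-hashed: only the 3x3 neighbourhood of cells of
// size tol is searched.
// [[Rcpp::export]]
NumericMatrix cpp_match_points(NumericVector px, NumericVector py,
                               NumericVector qx, NumericVector qy,
                               double tol) {
  int np = px.size(), nq = qx.size();
  NumericMatrix out(np, 2);
  double t2 = tol * tol;
  if (nq == 0) {
    for (int i = 0; i < np; ++i) { out(i, 0) = 0; out(i, 1) = NA_REAL; }
    return out;
  }
  double xmin = qx[0], ymin = qy[0], xmax = qx[0], ymax = qy[0];
  for (int j = 1; j < nq; ++j) {
    xmin = std::min(xmin, (double)qx[j]); xmax = std::max(xmax, (double)qx[j]);
    ymin = std::min(ymin, (double)qy[j]); ymax = std::max(ymax, (double)qy[j]);
  }
  double cell = std::max(tol, 1e-9);
  int ncx = (int)((xmax - xmin) / cell) + 1;
  int ncy = (int)((ymax - ymin) / cell) + 1;
  std::vector<std::vector<int> > bins((size_t)ncx * ncy);
  for (int j = 0; j < nq; ++j) {
    int cx = (int)((qx[j] - xmin) / cell), cy = (int)((qy[j] - ymin) / cell);
    bins[(size_t)cy * ncx + cx].push_back(j);
  }
  for (int i = 0; i < np; ++i) {
    double best = t2; int bj = 0;
    int cx = (int)std::floor((px[i] - xmin) / cell);
    int cy = (int)std::floor((py[i] - ymin) / cell);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int gx = cx + dx, gy = cy + dy;
        if (gx < 0 || gx >= ncx || gy < 0 || gy >= ncy) continue;
        const std::vector<int>& b = bins[(size_t)gy * ncx + gx];
        for (size_t k = 0; k < b.size(); ++k) {
          int j = b[k];
          double ddx = px[i] - qx[j], ddy = py[i] - qy[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= best) { best = d2; bj = j + 1; }
        }
      }
    }
    out(i, 0) = bj;
    out(i, 1) = bj ? best : NA_REAL;
  }
  return out;
}

// Distance from each point to its nearest *other* point in the same set.
// [[Rcpp::export]]
NumericVector cpp_min_self_dist(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
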