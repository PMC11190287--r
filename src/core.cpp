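// Orientation-space numerics: quaternion products, symmetry-reduced
// misorientation, kernel-density ODF evaluation on equal-volume grids,
// pairwise (kernel-series) Texture Index, spherical pole densities and
// misorientation-threshold grain labelling.
//
// Quaternions are scalar-first (w, x, y, z) rows of n x 4 matrices.
// Crystal symmetry acts by left multiplication: q ~ s (x) q.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline void qmul(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline double dot4(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2] + a[3] * b[3];
}

// scalar part of the product a (x) b without forming the product
static inline double wprod(const double* a, const double* b) {
  return a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
}

static void get_row(const NumericMatrix& m, int i, double* out) {
  out[0] = m(i, 0); out[1] = m(i, 1); out[2] = m(i, 2); out[3] = m(i, 3);
}

// cos(omega/2) of the symmetry-reduced misorientation between qa and qb:
// max over s of |w(conj(qa) (x) s (x) qb)|.  Both-sided symmetrization is
// equivalent by conjugation invariance of the rotation angle.
static double misori_coshalf(const double* qa, const double* qb,
                             const NumericMatrix& sym) {
  double ac[4] = { qa[0], -qa[1], -qa[2], -qa[3] };
  double best = 0.0;
  const int ns = sym.nrow();
  for (int s = 0; s < ns; ++s) {
    double sq[4] = { sym(s, 0), sym(s, 1), sym(s, 2), sym(s, 3) };
    double u[4];
    qmul(ac, sq, u);
    double w = std::fabs(wprod(u, qb));
    if (w > best) best = w;
  }
  return best > 1.0 ? 1.0 : best;
}

// misorientation angle in degrees via atan2 of the full best product, which
// keeps precision near zero where acos saturates
static double misori_angle_deg(const double* qa, const double* qb,
                               const NumericMatrix& sym) {
  double ac[4] = { qa[0], -qa[1], -qa[2], -qa[3] };
  double best = -1.0, bq[4] = { 1.0, 0.0, 0.0, 0.0 };
  const int ns = sym.nrow();
  for (int s = 0; s < ns; ++s) {
    double sq[4] = { sym(s, 0), sym(s, 1), sym(s, 2), sym(s, 3) };
    double u[4], p[4];
    qmul(ac, sq, u);
    qmul(u, qb, p);
    if (std::fabs(p[0]) > best) {
      best = std::fabs(p[0]);
      for (int j = 0; j < 4; ++j) bq[j] = p[j];
    }
  }
  double v = std::sqrt(bq[1] * bq[1] + bq[2] * bq[2] + bq[3] * bq[3]);
  return 2.0 * std::atan2(v, std::fabs(bq[0])) * 180.0 / M_PI;
}

// [[Rcpp::export]]
NumericVector misori_angles_cpp(NumericMatrix qa, NumericMatrix qb,
                                NumericMatrix sym) {
  const int n = qa.nrow();
  if (qb.nrow() != n) stop("qa and qb must have the same number of rows");
  NumericVector out(n);
  double a[4], b[4];
  for (int i = 0; i < n; ++i) {
    get_row(qa, i, a);
    get_row(qb, i, b);
    out[i] = misori_angle_deg(a, b, sym);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix fz_project_cpp(NumericMatrix q, NumericMatrix sym) {
  const int n = q.nrow(), ns = sym.nrow();
  NumericMatrix out(n, 4);
  double a[4], s[4], u[4], best[4];
  for (int i = 0; i < n; ++i) {
    get_row(q, i, a);
    double bw = -1.0;
    for (int k = 0; k < ns; ++k) {
      get_row(sym, k, s);
      qmul(s, a, u);
      if (std::fabs(u[0]) > bw) {
        bw = std::fabs(u[0]);
        for (int j = 0; j < 4; ++j) best[j] = u[j];
      }
    }
    double sgn = best[0] < 0 ? -1.0 : 1.0;
    for (int j = 0; j < 4; ++j) out(i, j) = sgn * best[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// ODF evaluation: f(node) = sum_i (w_i / ns) * Ck * |<node, s q_i>|^(2 kappa)
// A 4-D cell hash over the node quaternions limits kernel evaluation to
// node/component pairs within the kernel cutoff; kernels broader than the
// hash is worth (cell side > 0.5) fall back to a dense scan.
// ---------------------------------------------------------------------------

struct HashGrid4 {
  double h;
  int K;
  std::unordered_map<uint64_t, std::vector<int> > cells;

  uint64_t key(int a, int b, int c, int d) const {
    return (((static_cast<uint64_t>(a) * 2048u + b) * 2048u + c) * 2048u + d);
  }
  int cell_of(double x) const {
    int i = static_cast<int>(std::floor((x + 1.0) / h)) + 2;
    if (i < 0) i = 0;
    if (i > 2040) i = 2040;
    return i;
  }
  void insert(const double* q, int id) {
    for (int sgn = 0; sgn < 2; ++sgn) {
      double f = sgn ? -1.0 : 1.0;
      uint64_t k = key(cell_of(f * q[0]), cell_of(f * q[1]),
                       cell_of(f * q[2]), cell_of(f * q[3]));
      cells[k].push_back(id);
    }
  }
};

// [[Rcpp::export]]
NumericVector odf_eval_cpp(NumericMatrix nodes, NumericMatrix comps,
                           NumericVector wts, NumericMatrix sym,
                           double kappa, double Ck, double cutd2) {
  const int n = nodes.nrow(), m = comps.nrow(), ns = sym.nrow();
  NumericVector f(n);
  // minimal Euclidean distance between unit quaternions at |dot| = sqrt(cutd2)
  double cdot = std::sqrt(cutd2);
  double h = std::sqrt(std::max(0.0, 2.0 - 2.0 * cdot)) * 1.0001 + 1e-9;
  const bool brute = (h > 0.5);

  std::vector<double> scomp;  // symmetrized component copies, 4 per entry
  std::vector<double> sw;
  scomp.reserve(static_cast<size_t>(m) * ns * 4);
  sw.reserve(static_cast<size_t>(m) * ns);
  double q[4], s[4], u[4];
  for (int i = 0; i < m; ++i) {
    get_row(comps, i, q);
    for (int k = 0; k < ns; ++k) {
      get_row(sym, k, s);
      qmul(s, q, u);
      for (int j = 0; j < 4; ++j) scomp.push_back(u[j]);
      sw.push_back(wts[i] / ns);
    }
  }
  const size_t ncopy = sw.size();

  if (brute) {
    for (size_t c = 0; c < ncopy; ++c) {
      const double* qc = &scomp[4 * c];
      const double wc = sw[c] * Ck;
      for (int j = 0; j < n; ++j) {
        double d = qc[0] * nodes(j, 0) + qc[1] * nodes(j, 1) +
                   qc[2] * nodes(j, 2) + qc[3] * nodes(j, 3);
        double d2 = d * d;
        if (d2 >= cutd2) f[j] += wc * std::pow(d2, kappa);
      }
    }
    return f;
  }

  HashGrid4 grid;
  grid.h = h;
  grid.cells.reserve(static_cast<size_t>(n) / 4 + 16);
  std::vector<double> nq(static_cast<size_t>(n) * 4);
  for (int j = 0; j < n; ++j) {
    nq[4 * j + 0] = nodes(j, 0); nq[4 * j + 1] = nodes(j, 1);
    nq[4 * j + 2] = nodes(j, 2); nq[4 * j + 3] = nodes(j, 3);
    grid.insert(&nq[4 * j], j);
  }

  for (size_t c = 0; c < ncopy; ++c) {
    const double* qc = &scomp[4 * c];
    const double wc = sw[c] * Ck;
    int cc[4] = { grid.cell_of(qc[0]), grid.cell_of(qc[1]),
                  grid.cell_of(qc[2]), grid.cell_of(qc[3]) };
    for (int da = -1; da <= 1; ++da)
      for (int db = -1; db <= 1; ++db)
        for (int dc = -1; dc <= 1; ++dc)
          for (int dd = -1; dd <= 1; ++dd) {
            uint64_t k = grid.key(cc[0] + da, cc[1] + db, cc[2] + dc,
                                  cc[3] + dd);
            std::unordered_map<uint64_t, std::vector<int> >::const_iterator
              it = grid.cells.find(k);
            if (it == grid.cells.end()) continue;
            const std::vector<int>& ids = it->second;
            for (size_t t = 0; t < ids.size(); ++t) {
              int j = ids[t];
              double d = qc[0] * nq[4 * j] + qc[1] * nq[4 * j + 1] +
                         qc[2] * nq[4 * j + 2] + qc[3] * nq[4 * j + 3];
              double d2 = d * d;
              if (d2 >= cutd2) f[j] += wc * std::pow(d2, kappa);
            }
          }
  }
  return f;
}

// ---------------------------------------------------------------------------
// Pairwise Texture Index via the kernel self-convolution T(omega), supplied
// as values on a uniform grid in d2 = cos^2(omega/2) (tconv[0] is d2 = 0).
// TI = sum_ij w_i w_j (1/ns) sum_u T(angle(q_i^-1 u q_j)).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double pairwise_ti_cpp(NumericMatrix q, NumericVector w, NumericMatrix sym,
                       NumericVector tconv) {
  const int n = q.nrow(), ns = sym.nrow(), M = tconv.size();
  const double Mm1 = M - 1.0;
  // v[i, u] = conj(u) (x) q_i  so that w(q_i^-1 u q_j) = <v[i,u], q_j>
  std::vector<double> v(static_cast<size_t>(n) * ns * 4);
  double qi[4], uc[4];
  for (int i = 0; i < n; ++i) {
    get_row(q, i, qi);
    for (int u = 0; u < ns; ++u) {
      uc[0] = sym(u, 0); uc[1] = -sym(u, 1);
      uc[2] = -sym(u, 2); uc[3] = -sym(u, 3);
      qmul(uc, qi, &v[(static_cast<size_t>(i) * ns + u) * 4]);
    }
  }
  std::vector<double> qv(static_cast<size_t>(n) * 4);
  for (int i = 0; i < n; ++i) {
    qv[4 * i] = q(i, 0); qv[4 * i + 1] = q(i, 1);
    qv[4 * i + 2] = q(i, 2); qv[4 * i + 3] = q(i, 3);
  }

  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int u = 0; u < ns; ++u) {
      const double* vi = &v[(static_cast<size_t>(i) * ns + u) * 4];
      double acc = 0.0;
      for (int j = i; j < n; ++j) {
        double d = vi[0] * qv[4 * j] + vi[1] * qv[4 * j + 1] +
                   vi[2] * qv[4 * j + 2] + vi[3] * qv[4 * j + 3];
        double d2 = d * d;
        if (d2 > 1.0) d2 = 1.0;
        double x = d2 * Mm1;
        int i0 = static_cast<int>(x);
        if (i0 >= M - 1) i0 = M - 2;
        double fr = x - i0;
        double tv = tconv[i0] + (tconv[i0 + 1] - tconv[i0]) * fr;
        acc += (j == i ? 0.5 : 1.0) * w[j] * tv;
      }
      total += 2.0 * w[i] * acc;
    }
  }
  return total / ns;
}

// ---------------------------------------------------------------------------
// ODF evaluation on the Hopf-fibration product grid (Fibonacci sphere of n2
// z-axis images x n1 uniform spin angles).  The product structure gives an
// exact neighbor search: a kernel copy at p only reaches nodes whose sphere
// point lies within the kernel cutoff cap around the image of the crystal
// z-axis under p (a contiguous z-band of Fibonacci indices), and within each
// such sphere point the admissible spin angles form one circular window in
// which the quaternion dot product is rho * cos(psi/2 - phi) in closed form.
// Node row index = i * n1 + k (sphere index i outer, spin index k inner).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector odf_eval_hopf_cpp(NumericMatrix qa, int n1, NumericMatrix comps,
                                NumericVector wts, NumericMatrix sym,
                                double Ck, double cutd2,
                                NumericVector ktab) {
  const int n2 = qa.nrow(), ns = sym.nrow(), m = comps.nrow();
  const int K = ktab.size();
  const double kscale = (K - 1.0) / (1.0 - cutd2);
  NumericVector f(static_cast<R_xlen_t>(n2) * n1);
  const double cdot = std::sqrt(cutd2);
  const double wc = 2.0 * std::acos(std::min(1.0, cdot)); // kernel cutoff angle
  const double cosw = std::cos(std::min(M_PI, wc));       // sphere cap bound
  const double dpsi = 2.0 * M_PI / n1;

  // sphere unit vectors v_i = R(qa_i) z and conjugates of qa
  std::vector<double> vx(n2), vy(n2), vz(n2), qac(static_cast<size_t>(n2) * 4);
  for (int i = 0; i < n2; ++i) {
    double w = qa(i, 0), x = qa(i, 1), y = qa(i, 2), z = qa(i, 3);
    vx[i] = 2.0 * (x * z + w * y);
    vy[i] = 2.0 * (y * z - w * x);
    vz[i] = 1.0 - 2.0 * (x * x + y * y);
    qac[4 * i + 0] = w; qac[4 * i + 1] = -x;
    qac[4 * i + 2] = -y; qac[4 * i + 3] = -z;
  }

  double q[4], s[4], p[4], sq[4];
  for (int c = 0; c < m; ++c) {
    get_row(comps, c, q);
    const double wc_amp = wts[c] / ns * Ck;
    for (int si = 0; si < ns; ++si) {
      get_row(sym, si, s);
      qmul(s, q, p);
      // image of the crystal z-axis under p
      double px = 2.0 * (p[1] * p[3] + p[0] * p[2]);
      double py = 2.0 * (p[2] * p[3] - p[0] * p[1]);
      double pz = 1.0 - 2.0 * (p[1] * p[1] + p[2] * p[2]);
      // Fibonacci z-band: z_i = 1 - (2i+1)/n2, decreasing in i
      double thp = std::acos(std::max(-1.0, std::min(1.0, pz)));
      double zhi = std::cos(std::max(0.0, thp - wc));
      double zlo = std::cos(std::min(M_PI, thp + wc));
      int ilo = static_cast<int>(std::floor(((1.0 - zhi) * n2 - 1.0) / 2.0));
      int ihi = static_cast<int>(std::ceil(((1.0 - zlo) * n2 - 1.0) / 2.0));
      if (ilo < 0) ilo = 0;
      if (ihi > n2 - 1) ihi = n2 - 1;
      for (int i = ilo; i <= ihi; ++i) {
        if (vx[i] * px + vy[i] * py + vz[i] * pz < cosw) continue;
        qmul(&qac[4 * i], p, sq);       // conj(qa_i) (x) p
        double rho = std::sqrt(sq[0] * sq[0] + sq[3] * sq[3]);
        if (rho < cdot) continue;
        double phi = std::atan2(sq[3], sq[0]);
        double a = std::acos(std::min(1.0, cdot / rho)); // on psi/2 scale
        int klo = static_cast<int>(std::ceil((2.0 * (phi - a)) / dpsi - 0.5));
        int khi = static_cast<int>(std::floor((2.0 * (phi + a)) / dpsi - 0.5));
        for (int k = klo; k <= khi; ++k) {
          double t = (k + 0.5) * dpsi / 2.0 - phi;
          double d = rho * std::cos(t);
          double d2 = d * d;
          if (d2 < cutd2) continue;
          if (d2 > 1.0) d2 = 1.0;
          int km = k % n1; if (km < 0) km += n1;
          double xk = (d2 - cutd2) * kscale;
          int k0 = static_cast<int>(xk);
          if (k0 >= K - 1) k0 = K - 2;
          double kv = ktab[k0] + (ktab[k0 + 1] - ktab[k0]) * (xk - k0);
          f[static_cast<R_xlen_t>(i) * n1 + km] += wc_amp * kv;
        }
      }
    }
  }
  return f;
}

// Evaluate a zonal (character) series sum_l coef_l * sin((2l+1) w/2)/sin(w/2)
// [[Rcpp::export]]
NumericVector zonal_series_eval_cpp(NumericVector omega, NumericVector coef) {
  const int n = omega.size(), L = coef.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = omega[i] / 2.0;
    double su = std::sin(u);
    if (std::fabs(su) < 1e-9) {
      double acc = 0.0;
      for (int l = 0; l < L; ++l) acc += coef[l] * (2.0 * l + 1.0);
      out[i] = acc;
      continue;
    }
    double c2u = 2.0 * std::cos(2.0 * u);
    double sm1 = std::sin(u), s0 = std::sin(3.0 * u);
    double acc = coef[0] * sm1;
    if (L > 1) acc += coef[1] * s0;
    for (int l = 2; l < L; ++l) {
      double s1 = c2u * s0 - sm1;
      acc += coef[l] * s1;
      sm1 = s0; s0 = s1;
    }
    out[i] = acc / su;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Antipodally symmetric spherical kernel density in multiples of uniform
// density.  K(t) = Cs * ((1+t)/2)^kappa with Cs = kappa + 1; the density at a
// node is the weight-sum of (K(t) + K(-t))/2 over all directions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sphere_density_cpp(NumericMatrix nodes, NumericMatrix dirs,
                                 NumericVector wts, double kappa, double Cs,
                                 double cut) {
  const int n = nodes.nrow(), m = dirs.nrow();
  NumericVector f(n);
  std::vector<double> dx(m), dy(m), dz(m), dw(m);
  for (int j = 0; j < m; ++j) {
    dx[j] = dirs(j, 0); dy[j] = dirs(j, 1); dz[j] = dirs(j, 2);
    dw[j] = wts[j];
  }
  for (int i = 0; i < n; ++i) {
    double nx = nodes(i, 0), ny = nodes(i, 1), nz = nodes(i, 2);
    double acc = 0.0;
    for (int j = 0; j < m; ++j) {
      double t = nx * dx[j] + ny * dy[j] + nz * dz[j];
      double ta = std::fabs(t);
      if (ta > 1.0) ta = 1.0;
      double ap = (1.0 + ta) / 2.0;
      if (ap < cut) continue;
      double val = std::pow(ap, kappa) + std::pow(1.0 - ap, kappa);
      acc += dw[j] * 0.5 * Cs * val;
    }
    f[i] = acc;
  }
  return f;
}

// ---------------------------------------------------------------------------
// Grain labelling: flood fill over 4-connected indexed pixels whose
// misorientation is below the threshold; grains smaller than min_px are then
// discarded and the labelling is repeated on the surviving pixels.
// Deterministic in raster order.
// ---------------------------------------------------------------------------

static void flood_pass(int W, int H, const std::vector<char>& alive,
                       const NumericMatrix& q, const NumericMatrix& sym,
                       double thrw, std::vector<int>& labels, int& ngrain) {
  const int n = W * H;
  std::fill(labels.begin(), labels.end(), 0);
  ngrain = 0;
  std::vector<int> stack;
  double qa[4], qb[4];
  const int dxs[4] = { 1, -1, 0, 0 };
  const int dys[4] = { 0, 0, 1, -1 };
  for (int p = 0; p < n; ++p) {
    if (!alive[p] || labels[p] != 0) continue;
    ++ngrain;
    labels[p] = ngrain;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cx = cur % W, cy = cur / W;
      get_row(q, cur, qa);
      for (int k = 0; k < 4; ++k) {
        int nx2 = cx + dxs[k], ny2 = cy + dys[k];
        if (nx2 < 0 || nx2 >= W || ny2 < 0 || ny2 >= H) continue;
        int nb = ny2 * W + nx2;
        if (!alive[nb] || labels[nb] != 0) continue;
        get_row(q, nb, qb);
        if (misori_coshalf(qa, qb, sym) > thrw) {
          labels[nb] = ngrain;
          stack.push_back(nb);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List grain_label_cpp(int W, int H, LogicalVector indexed, NumericMatrix q,
                     NumericMatrix sym, double threshold_deg, int min_px) {
  const int n = W * H;
  double thrw = std::cos(threshold_deg * M_PI / 180.0 / 2.0);
  std::vector<char> alive(n);
  for (int i = 0; i < n; ++i) alive[i] = indexed[i] ? 1 : 0;
  std::vector<int> labels(n);
  int ngrain = 0;

  flood_pass(W, H, alive, q, sym, thrw, labels, ngrain);
  // discard grains below the pixel threshold, then label again
  std::vector<int> sizes(ngrain + 1, 0);
  for (int i = 0; i < n; ++i) if (labels[i] > 0) ++sizes[labels[i]];
  bool any_small = false;
  for (int g = 1; g <= ngrain; ++g)
    if (sizes[g] < min_px) { any_small = true; break; }
  if (any_small) {
    for (int i = 0; i < n; ++i)
      if (labels[i] > 0 && sizes[labels[i]] < min_px) alive[i] = 0;
    flood_pass(W, H, alive, q, sym, thrw, labels, ngrain);
  }

  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i];
  return List::create(_["labels"] = lab, _["n_grains"] = ngrain);
}

// Accumulate the 4x4 orientation scatter matrix of each grain after moving
// every member into the symmetry branch (and sign) closest to the grain seed.
// [[Rcpp::export]]
NumericMatrix grain_scatter_cpp(NumericMatrix q, IntegerVector labels,
                                NumericMatrix sym, int ngrain) {
  const int n = q.nrow(), ns = sym.nrow();
  NumericMatrix scat(ngrain, 16);
  std::vector<int> seed(ngrain + 1, -1);
  for (int i = 0; i < n; ++i) {
    int g = labels[i];
    if (g > 0 && seed[g] < 0) seed[g] = i;
  }
  double qs[4], qi[4], s[4], u[4], best[4];
  for (int i = 0; i < n; ++i) {
    int g = labels[i];
    if (g <= 0) continue;
    get_row(q, seed[g], qs);
    get_row(q, i, qi);
    double bw = -2.0;
    for (int k = 0; k < ns; ++k) {
      get_row(sym, k, s);
      qmul(s, qi, u);
      double d = dot4(u, qs);
      if (std::fabs(d) > bw) {
        bw = std::fabs(d);
        double sgn = d < 0 ? -1.0 : 1.0;
        for (int j = 0; j < 4; ++j) best[j] = sgn * u[j];
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        scat(g - 1, 4 * a + b) += best[a] * best[b];
  }
  return scat;
}
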