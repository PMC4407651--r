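// Voxel morphology primitives: exact Euclidean distance transform,
// local thickness (maximal inscribed sphere), connected components,
// capillary invasion, Gaussian smoothing, marching-tetrahedra surfaces.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher).
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  v.resize(n + 1);
  z.resize(n + 1);
  int q = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      s = ((f[i] + i * (double)i) - (f[v[q]] + v[q] * (double)v[q])) /
          (2.0 * i - 2.0 * v[q]);
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = DT_INF;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    double dx = i - (double)v[q];
    d[i] = dx * dx + f[v[q]];
  }
}

// Squared Euclidean distance from each TRUE voxel to the nearest FALSE
// voxel centre. FALSE voxels get 0; all-TRUE volumes get DT_INF.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? DT_INF : 0.0;
  std::vector<int> v;
  std::vector<double> z;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax);
  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* col = &out[(R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(col, f.data(), n1, v, z);
      std::copy(f.begin(), f.begin() + n1, col);
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j)
        f[j] = out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f.data(), d.data(), n2, v, z);
      for (int j = 0; j < n2; ++j)
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k)
        f[k] = out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f.data(), d.data(), n3, v, z);
      for (int k = 0; k < n3; ++k)
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = d[k];
    }
  return out;
}

// Local thickness: radius (in voxels) of the largest inscribed sphere
// covering each TRUE voxel. Radius convention: distance between voxel
// centres (a one-voxel-wide pore has radius 1); with this convention the
// union of maximal spheres covers the whole mask (morphological opening).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector dsq = cpp_edt_sq(mask, dim);
  NumericVector lt(N, 0.0);
  std::vector<R_xlen_t> idx;
  idx.reserve(N / 4);
  std::vector<double> rad(N, 0.0);
  for (R_xlen_t i = 0; i < N; ++i) {
    if (mask[i]) {
      rad[i] = std::sqrt(dsq[i]);
      idx.push_back(i);
    }
  }
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return rad[a] > rad[b]; });
  for (R_xlen_t t = 0; t < (R_xlen_t)idx.size(); ++t) {
    R_xlen_t p = idx[t];
    double r = rad[p];
    int k0 = p / ((R_xlen_t)n1 * n2);
    int rem = p - (R_xlen_t)k0 * n1 * n2;
    int j0 = rem / n1, i0 = rem % n1;
    int ri = (int)std::floor(r);
    double r2 = r * r;
    for (int dk = -ri; dk <= ri; ++dk) {
      int k = k0 + dk; if (k < 0 || k >= n3) continue;
      for (int dj = -ri; dj <= ri; ++dj) {
        int j = j0 + dj; if (j < 0 || j >= n2) continue;
        double dd = (double)dk * dk + (double)dj * dj;
        if (dd > r2) continue;
        int di_max = (int)std::floor(std::sqrt(r2 - dd));
        int ilo = std::max(0, i0 - di_max), ihi = std::min(n1 - 1, i0 + di_max);
        R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        for (int i = ilo; i <= ihi; ++i) {
          R_xlen_t q = base + i;
          if (mask[q] && lt[q] < r) lt[q] = r;
        }
      }
    }
  }
  return lt;
}

// Connected-component labelling, connectivity 6 or 26. Labels 1..K, 0 = bg.
// With wrap = true, opposite domain faces are identified (periodic topology).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity, bool wrap = false) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::vector<int> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
      }
  int nn = (int)offs.size() / 3;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int k0 = p / ((R_xlen_t)n1 * n2);
      int rem = p - (R_xlen_t)k0 * n1 * n2;
      int j0 = rem / n1, i0 = rem % n1;
      for (int t = 0; t < nn; ++t) {
        int i = i0 + offs[3 * t], j = j0 + offs[3 * t + 1], k = k0 + offs[3 * t + 2];
        if (wrap) {
          i = (i + n1) % n1; j = (j + n2) % n2; k = (k + n3) % n3;
        } else if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3)
          continue;
        R_xlen_t q = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Capillary invasion: air fills pore voxels with local radius >= rc that are
// 6-connected to the entry face through voxels meeting the same criterion.
// Previously drained air never reverts.
// [[Rcpp::export]]
LogicalVector cpp_invade(NumericVector radius, LogicalVector pore,
                         LogicalVector prev_air, double rc,
                         int axis, int side, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector air(N, FALSE);
  std::vector<R_xlen_t> stack;
  auto ok = [&](R_xlen_t q) { return pore[q] && radius[q] >= rc; };
  // seed from entry face
  int n[3] = {n1, n2, n3};
  int face = side == 0 ? 0 : n[axis] - 1;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int c[3] = {i, j, k};
        if (c[axis] != face) continue;
        R_xlen_t q = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (ok(q) && !air[q]) { air[q] = TRUE; stack.push_back(q); }
      }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    R_xlen_t p = stack.back(); stack.pop_back();
    int k0 = p / ((R_xlen_t)n1 * n2);
    int rem = p - (R_xlen_t)k0 * n1 * n2;
    int j0 = rem / n1, i0 = rem % n1;
    for (int t = 0; t < 6; ++t) {
      int i = i0 + off[t][0], j = j0 + off[t][1], k = k0 + off[t][2];
      if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) continue;
      R_xlen_t q = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      if (!air[q] && ok(q)) { air[q] = TRUE; stack.push_back(q); }
    }
  }
  for (R_xlen_t q = 0; q < N; ++q) if (prev_air[q]) air[q] = TRUE;
  return air;
}

// Separable Gaussian smoothing, zero-padded boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto& v : ker) v /= s;
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector a(clone(vol)), b(N);
  int n[3] = {n1, n2, n3};
  R_xlen_t str[3] = {1, n1, (R_xlen_t)n1 * n2};
  for (int ax = 0; ax < 3; ++ax) {
    for (R_xlen_t p = 0; p < N; ++p) {
      int k0 = p / str[2];
      R_xlen_t rem = p - (R_xlen_t)k0 * str[2];
      int j0 = rem / n1, i0 = rem % n1;
      int c[3] = {i0, j0, k0};
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ci = c[ax] + t;
        if (ci < 0 || ci >= n[ax]) continue;
        acc += ker[t + r] * a[p + (R_xlen_t)t * str[ax]];
      }
      b[p] = acc;
    }
    std::copy(b.begin(), b.end(), a.begin());
  }
  return a;
}

// Marching tetrahedra over the voxel-centre grid (Freudenthal split around
// the 0-6 diagonal). Returns total triangulated area (voxel units) and,
// optionally, the triangle soup (one row per vertex, 3 rows per triangle).
// [[Rcpp::export]]
List cpp_mtetra(NumericVector vol, IntegerVector dim, double level,
                bool triangles) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  // cube corner offsets, bit order (x, y, z)
  const int cx[8] = {0,1,1,0,0,1,1,0};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  std::vector<double> tri;
  double vx[8], px[8], py[8], pz[8];
  auto interp = [&](int a, int b, double* out) {
    double t = (level - vx[a]) / (vx[b] - vx[a]);
    out[0] = px[a] + t * (px[b] - px[a]);
    out[1] = py[a] + t * (py[b] - py[a]);
    out[2] = pz[a] + t * (pz[b] - pz[a]);
  };
  auto triarea = [](const double* a, const double* b, const double* c) {
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double w[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
    return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  };
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + cx[c], jj = j + cy[c], kk = k + cz[c];
          vx[c] = vol[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
          px[c] = ii; py[c] = jj; pz[c] = kk;
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int above[4], na = 0;
          for (int c = 0; c < 4; ++c) if (vx[T[c]] > level) above[na++] = c;
          if (na == 0 || na == 4) continue;
          double P[4][3];
          int ntri = 0;
          if (na == 1 || na == 3) {
            int odd = -1;
            if (na == 1) odd = above[0];
            else {  // the single vertex below
              bool ab[4] = {false,false,false,false};
              for (int c = 0; c < 3; ++c) ab[above[c]] = true;
              for (int c = 0; c < 4; ++c) if (!ab[c]) odd = c;
            }
            int q = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == odd) continue;
              interp(T[odd], T[c], P[q++]);
            }
            ntri = 1;
          } else {  // na == 2: quad through 4 edges
            int a0 = above[0], a1 = above[1];
            int below[2], nb = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a0 && c != a1) below[nb++] = c;
            interp(T[a0], T[below[0]], P[0]);
            interp(T[a0], T[below[1]], P[1]);
            interp(T[a1], T[below[1]], P[2]);
            interp(T[a1], T[below[0]], P[3]);
            ntri = 2;
          }
          area += triarea(P[0], P[1], P[2]);
          if (ntri == 2) area += triarea(P[0], P[2], P[3]);
          if (triangles) {
            for (int c = 0; c < 3; ++c)
              for (int d = 0; d < 3; ++d) tri.push_back(P[c][d]);
            if (ntri == 2) {
              const int id2[3] = {0, 2, 3};
              for (int c = 0; c < 3; ++c)
                for (int d = 0; d < 3; ++d) tri.push_back(P[id2[c]][d]);
            }
          }
        }
      }
  List out = List::create(_["area"] = area);
  if (triangles) {
    int nv = (int)tri.size() / 3;
    NumericMatrix m(3, nv);
    std::copy(tri.begin(), tri.end(), m.begin());
    out["vertices"] = m;  // columns are vertices; consecutive triples = triangles
  }
  return out;
}

// Counts of voxel faces between each pair of labels {0,1,2} (+3 = domain edge).
// [[Rcpp::export]]
NumericMatrix cpp_interface_faces(IntegerVector labels, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericMatrix cnt(4, 4);
  R_xlen_t str[3] = {1, n1, (R_xlen_t)n1 * n2};
  int n[3] = {n1, n2, n3};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t p = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        int c[3] = {i, j, k};
        int lp = labels[p];
        for (int ax = 0; ax < 3; ++ax) {
          int lq = (c[ax] + 1 < n[ax]) ? labels[p + str[ax]] : 3;
          if (lp != lq) { cnt(lp, lq) += 1; cnt(lq, lp) += 1; }
        }
      }
  return cnt;
}
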