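#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Integer level lattices use 0 for voxels outside the ROI and 1..L inside.
// Array axis order is (slice, row, column); the first index varies fastest
// (standard R column-major layout).

static void get_dims(const IntegerVector& x, int d[3]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2];
}

static inline int idx3(int i0, int i1, int i2, const int d[3]) {
  return i0 + d[0] * (i1 + d[1] * i2);
}

// the 13 unique 3D directions (positive half of the 26-neighbourhood)
static int n_dirs13(int dirs[13][3]) {
  int n = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (a > 0 || (a == 0 && b > 0) || (a == 0 && b == 0 && c > 0)) {
          dirs[n][0] = a; dirs[n][1] = b; dirs[n][2] = c; ++n;
        }
      }
  return n; // 13
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lev, int L) {
  int d[3]; get_dims(lev, d);
  int dirs[13][3]; n_dirs13(dirs);
  NumericVector out(L * L * 13);
  for (int i2 = 0; i2 < d[2]; ++i2)
    for (int i1 = 0; i1 < d[1]; ++i1)
      for (int i0 = 0; i0 < d[0]; ++i0) {
        int a = lev[idx3(i0, i1, i2, d)];
        if (a == 0) continue;
        for (int k = 0; k < 13; ++k) {
          int j0 = i0 + dirs[k][0], j1 = i1 + dirs[k][1], j2 = i2 + dirs[k][2];
          if (j0 < 0 || j0 >= d[0] || j1 < 0 || j1 >= d[1] || j2 < 0 || j2 >= d[2]) continue;
          int b = lev[idx3(j0, j1, j2, d)];
          if (b == 0) continue;
          out[(a - 1) + L * ((b - 1) + L * k)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(L, L, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lev, int L) {
  int d[3]; get_dims(lev, d);
  int dirs[13][3]; n_dirs13(dirs);
  int maxrun = std::max(d[0], std::max(d[1], d[2]));
  NumericVector out(L * maxrun * 13);
  for (int k = 0; k < 13; ++k) {
    int a0 = dirs[k][0], a1 = dirs[k][1], a2 = dirs[k][2];
    for (int i2 = 0; i2 < d[2]; ++i2)
      for (int i1 = 0; i1 < d[1]; ++i1)
        for (int i0 = 0; i0 < d[0]; ++i0) {
          int g = lev[idx3(i0, i1, i2, d)];
          if (g == 0) continue;
          // run start: predecessor out of lattice, out of ROI, or other level
          int p0 = i0 - a0, p1 = i1 - a1, p2 = i2 - a2;
          bool start = true;
          if (p0 >= 0 && p0 < d[0] && p1 >= 0 && p1 < d[1] && p2 >= 0 && p2 < d[2])
            start = (lev[idx3(p0, p1, p2, d)] != g);
          if (!start) continue;
          int len = 1;
          int q0 = i0 + a0, q1 = i1 + a1, q2 = i2 + a2;
          while (q0 >= 0 && q0 < d[0] && q1 >= 0 && q1 < d[1] && q2 >= 0 && q2 < d[2] &&
                 lev[idx3(q0, q1, q2, d)] == g) {
            ++len; q0 += a0; q1 += a1; q2 += a2;
          }
          out[(g - 1) + L * ((len - 1) + maxrun * k)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(L, maxrun, 13);
  return out;
}

// Connected components of equal-valued voxels (value 0 = background).
// conn: 26 = full 3D, 8 = in-plane only (neighbours within the same slice).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector lev, int conn) {
  int d[3]; get_dims(lev, d);
  int n = d[0] * d[1] * d[2];
  IntegerVector lab(n);
  lab.attr("dim") = lev.attr("dim");
  std::vector<int> off0, off1, off2;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (conn == 8 && a != 0) continue;
        off0.push_back(a); off1.push_back(b); off2.push_back(c);
      }
  int next = 0;
  std::vector<int> stack;
  for (int i2 = 0; i2 < d[2]; ++i2)
    for (int i1 = 0; i1 < d[1]; ++i1)
      for (int i0 = 0; i0 < d[0]; ++i0) {
        int i = idx3(i0, i1, i2, d);
        if (lev[i] == 0 || lab[i] != 0) continue;
        int g = lev[i];
        lab[i] = ++next;
        stack.clear(); stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int c0 = cur % d[0], rest = cur / d[0];
          int c1 = rest % d[1], c2 = rest / d[1];
          for (size_t k = 0; k < off0.size(); ++k) {
            int j0 = c0 + off0[k], j1 = c1 + off1[k], j2 = c2 + off2[k];
            if (j0 < 0 || j0 >= d[0] || j1 < 0 || j1 >= d[1] || j2 < 0 || j2 >= d[2]) continue;
            int j = idx3(j0, j1, j2, d);
            if (lev[j] == g && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// Dependence counts: for each ROI voxel, number of 26-neighbours inside the
// ROI whose level differs by at most alpha. Returns L x 27 count matrix
// (columns index dependence 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, int L, int alpha) {
  int d[3]; get_dims(lev, d);
  NumericMatrix out(L, 27);
  for (int i2 = 0; i2 < d[2]; ++i2)
    for (int i1 = 0; i1 < d[1]; ++i1)
      for (int i0 = 0; i0 < d[0]; ++i0) {
        int g = lev[idx3(i0, i1, i2, d)];
        if (g == 0) continue;
        int dep = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
              if (j0 < 0 || j0 >= d[0] || j1 < 0 || j1 >= d[1] || j2 < 0 || j2 >= d[2]) continue;
              int h = lev[idx3(j0, j1, j2, d)];
              if (h != 0 && std::abs(h - g) <= alpha) ++dep;
            }
        out(g - 1, dep) += 1.0;
      }
  return out;
}

// NGTDM accumulators: column 1 = n_i (voxels of level i that have at least
// one ROI neighbour), column 2 = s_i (sum of |i - mean neighbour level|).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, int L) {
  int d[3]; get_dims(lev, d);
  NumericMatrix out(L, 2);
  for (int i2 = 0; i2 < d[2]; ++i2)
    for (int i1 = 0; i1 < d[1]; ++i1)
      for (int i0 = 0; i0 < d[0]; ++i0) {
        int g = lev[idx3(i0, i1, i2, d)];
        if (g == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
              if (j0 < 0 || j0 >= d[0] || j1 < 0 || j1 >= d[1] || j2 < 0 || j2 >= d[2]) continue;
              int h = lev[idx3(j0, j1, j2, d)];
              if (h != 0) { sum += h; ++cnt; }
            }
        if (cnt > 0) {
          out(g - 1, 0) += 1.0;
          out(g - 1, 1) += std::fabs((double)g - sum / cnt);
        }
      }
  return out;
}

// Separable 1D convolution along one axis (1, 2 or 3) with symmetric
// (mirrored, edge-repeating) boundary handling; kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, NumericVector kernel, int axis) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  int d[3] = { dm[0], dm[1], dm[2] };
  int kl = kernel.size();
  if (kl % 2 != 1) stop("kernel length must be odd");
  int h = kl / 2;
  int ax = axis - 1;
  if (ax < 0 || ax > 2) stop("axis must be 1, 2 or 3");
  int n = d[ax];
  NumericVector out(x.size());
  out.attr("dim") = dm;
  int s[3];
  s[0] = 1; s[1] = d[0]; s[2] = d[0] * d[1];
  int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
  for (int ib = 0; ib < d[ob]; ++ib)
    for (int ia = 0; ia < d[oa]; ++ia) {
      int base = ia * s[oa] + ib * s[ob];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) {
          int j = i + k - h;
          if (j < 0) j = -1 - j;           // mirror
          if (j >= n) j = 2 * n - 1 - j;
          if (j < 0) j = 0; if (j >= n) j = n - 1; // tiny-axis guard
          acc += kernel[k] * x[base + j * s[ax]];
        }
        out[base + i * s[ax]] = acc;
      }
    }
  return out;
}

// Binary morphology with the 6-connected structuring element.
// op: 0 = dilate, 1 = erode.
// [[Rcpp::export]]
IntegerVector cpp_morph6(IntegerVector mask, int op) {
  int d[3]; get_dims(mask, d);
  IntegerVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  const int off[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  for (int i2 = 0; i2 < d[2]; ++i2)
    for (int i1 = 0; i1 < d[1]; ++i1)
      for (int i0 = 0; i0 < d[0]; ++i0) {
        int i = idx3(i0, i1, i2, d);
        bool any = mask[i] != 0, all = mask[i] != 0;
        for (int k = 0; k < 6; ++k) {
          int j0 = i0 + off[k][0], j1 = i1 + off[k][1], j2 = i2 + off[k][2];
          bool v = false;
          if (j0 >= 0 && j0 < d[0] && j1 >= 0 && j1 < d[1] && j2 >= 0 && j2 < d[2])
            v = mask[idx3(j0, j1, j2, d)] != 0;
          any = any || v; all = all && v;
        }
        out[i] = op == 0 ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}

struct MeshAcc {
  double area = 0.0, signed_vol6 = 0.0;
  // accumulate one triangle oriented so its normal has positive dot with
  // `outdir` (a direction pointing from inside to outside)
  void add(const double p0[3], const double p1[3], const double p2[3],
           const double centroid_to_out[3]) {
    double u[3] = { p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2] };
    double v[3] = { p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2] };
    double n[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
    double a = 0.5 * std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    area += a;
    double dp = n[0]*centroid_to_out[0] + n[1]*centroid_to_out[1] + n[2]*centroid_to_out[2];
    // signed volume of tet (origin, p0, p1, p2); flip if normal inward
    double det = p0[0]*(p1[1]*p2[2]-p1[2]*p2[1])
               - p0[1]*(p1[0]*p2[2]-p1[2]*p2[0])
               + p0[2]*(p1[0]*p2[1]-p1[1]*p2[0]);
    signed_vol6 += (dp >= 0) ? det : -det;
  }
};

// Marching-tetrahedra isosurface (Freudenthal 6-tet cube decomposition)
// of a scalar field at `iso`, with linear interpolation along tet edges.
// The field must be padded below `iso` by the caller. Returns c(area mm^2,
// enclosed volume mm^3); the volume comes from the divergence theorem over
// the consistently outward-oriented closed surface. spacing follows the
// (slice,row,col) axis order.
// [[Rcpp::export]]
NumericVector cpp_march_tets(NumericVector field, NumericVector spacing, double iso) {
  IntegerVector dm = field.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  int d[3] = { dm[0], dm[1], dm[2] };
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const int perms[6][3] = { {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0} };
  int tets[6][4][3];
  for (int p = 0; p < 6; ++p) {
    int v[4][3] = { {0,0,0},{0,0,0},{0,0,0},{1,1,1} };
    v[1][perms[p][0]] = 1;
    v[2][perms[p][0]] = 1; v[2][perms[p][1]] = 1;
    for (int a = 0; a < 4; ++a) for (int b = 0; b < 3; ++b) tets[p][a][b] = v[a][b];
  }
  MeshAcc acc;
  for (int i2 = 0; i2 + 1 < d[2]; ++i2)
    for (int i1 = 0; i1 + 1 < d[1]; ++i1)
      for (int i0 = 0; i0 + 1 < d[0]; ++i0) {
        double corner[2][2][2];
        int csum = 0;
        for (int a = 0; a < 2; ++a) for (int b = 0; b < 2; ++b) for (int c = 0; c < 2; ++c) {
          corner[a][b][c] = field[idx3(i0 + a, i1 + b, i2 + c, d)];
          csum += corner[a][b][c] > iso;
        }
        if (csum == 0 || csum == 8) continue;
        for (int p = 0; p < 6; ++p) {
          double val[4];
          double pt[4][3];
          int in[4], k = 0;
          for (int a = 0; a < 4; ++a) {
            val[a] = corner[tets[p][a][0]][tets[p][a][1]][tets[p][a][2]];
            in[a] = val[a] > iso;
            k += in[a];
            pt[a][0] = (i0 + tets[p][a][0]) * sp[0];
            pt[a][1] = (i1 + tets[p][a][1]) * sp[1];
            pt[a][2] = (i2 + tets[p][a][2]) * sp[2];
          }
          if (k == 0 || k == 4) continue;
          // crossing point on edge a-b (val[a] and val[b] straddle iso)
          auto cross_pt = [&](int a, int b, double out[3]) {
            double t = (iso - val[a]) / (val[b] - val[a]);
            for (int c = 0; c < 3; ++c) out[c] = pt[a][c] + t * (pt[b][c] - pt[a][c]);
          };
          if (k == 1 || k == 3) {
            int lone = -1;
            for (int a = 0; a < 4; ++a)
              if ((k == 1 && in[a]) || (k == 3 && !in[a])) lone = a;
            double m[3][3]; int mi = 0;
            double cen[3] = {0, 0, 0};
            for (int a = 0; a < 4; ++a) {
              if (a == lone) continue;
              cross_pt(lone, a, m[mi]);
              for (int c = 0; c < 3; ++c) cen[c] += m[mi][c] / 3.0;
              ++mi;
            }
            double dir[3];
            for (int c = 0; c < 3; ++c)
              dir[c] = (k == 1) ? cen[c] - pt[lone][c] : pt[lone][c] - cen[c];
            acc.add(m[0], m[1], m[2], dir);
          } else { // k == 2: quad between the four crossing edges
            int ins[2], outs[2], ni = 0, no = 0;
            for (int a = 0; a < 4; ++a) { if (in[a]) ins[ni++] = a; else outs[no++] = a; }
            double mac[3], mad[3], mbd[3], mbc[3];
            cross_pt(ins[0], outs[0], mac);
            cross_pt(ins[0], outs[1], mad);
            cross_pt(ins[1], outs[1], mbd);
            cross_pt(ins[1], outs[0], mbc);
            double cen[3], dir[3];
            for (int c = 0; c < 3; ++c) {
              cen[c] = (mac[c] + mad[c] + mbd[c] + mbc[c]) / 4.0;
              dir[c] = 0.5 * (pt[outs[0]][c] + pt[outs[1]][c]) - cen[c];
            }
            acc.add(mac, mad, mbd, dir);
            acc.add(mac, mbd, mbc, dir);
          }
        }
      }
  return NumericVector::create(acc.area, std::fabs(acc.signed_vol6) / 6.0);
}
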