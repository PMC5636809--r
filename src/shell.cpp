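// Discrete energetics of a closed triangulated membrane:
//   E = sum_i 2*kb*H_i^2*A_i  (bending, cotangent-Laplacian mean curvature)
//     + sum_f sigma_f*A_f     (surface tension, banded)
//     + sum_f (Ka/2*alpha^2 + mu*beta)*A0_f  (in-plane stretch and shear
//                                             relative to the reference mesh)
//     + kV/2*(V - V0)^2       (osmotic volume restoring)
// plus a soft centroid pin removing the rigid-translation null space.
//
// The gradient combines analytic terms (volume, pin) with central finite
// differences of the locally affected energy terms only: perturbing vertex v
// changes face terms of its incident faces and bending terms of v and its
// one-ring neighbours.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Mesh {
  int n, m;
  double* V;          // n x 3, column-major (R layout)
  const double* Vref; // n x 3
  const int* F;       // m x 3, column-major, 0-based
  const double* sigma;

  double x(int i, int d) const { return V[i + d * n]; }
  double xr(int i, int d) const { return Vref[i + d * n]; }
  int fv(int f, int k) const { return F[f + k * m]; }
};

inline void vsub(const Mesh& M, int a, int b, double* out) {
  for (int d = 0; d < 3; ++d) out[d] = M.x(a, d) - M.x(b, d);
}
inline void vsub_ref(const Mesh& M, int a, int b, double* out) {
  for (int d = 0; d < 3; ++d) out[d] = M.xr(a, d) - M.xr(b, d);
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

const double AREA_EPS = 1e-10;

// tension + stretch + shear energy of one face
inline double face_energy(const Mesh& M, int f, double Ka, double mu,
                          bool* degenerate) {
  int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
  double e1[3], e2[3], cr[3];
  vsub(M, b, a, e1); vsub(M, c, a, e2);
  cross3(e1, e2, cr);
  double A2 = std::sqrt(dot3(cr, cr));
  double A = 0.5 * A2;
  if (A < AREA_EPS) { *degenerate = true; return 0.0; }
  double r1[3], r2[3], cr0[3];
  vsub_ref(M, b, a, r1); vsub_ref(M, c, a, r2);
  cross3(r1, r2, cr0);
  double A0 = 0.5 * std::sqrt(dot3(cr0, cr0));
  if (A0 < AREA_EPS) { *degenerate = true; return 0.0; }
  double sf = (M.sigma[a] + M.sigma[b] + M.sigma[c]) / 3.0;
  double e_ten = sf * A;
  // Gram matrices of current and reference edge frames
  double g11 = dot3(e1, e1), g12 = dot3(e1, e2), g22 = dot3(e2, e2);
  double h11 = dot3(r1, r1), h12 = dot3(r1, r2), h22 = dot3(r2, r2);
  double detH = h11 * h22 - h12 * h12; // = (2*A0)^2
  // tr(C) with C = H^{-1} G; det(C) = (A/A0)^2
  double trC = (h22 * g11 - 2.0 * h12 * g12 + h11 * g22) / detH;
  double lam12 = A / A0;               // = lambda1*lambda2
  double alpha = lam12 - 1.0;          // area strain
  double beta = (trC - 2.0 * lam12) / (2.0 * lam12); // shear strain
  return e_ten + 0.5 * Ka * alpha * alpha * A0 + mu * beta * A0;
}

// split face energy into components (for reporting)
inline void face_energy_parts(const Mesh& M, int f, double Ka, double mu,
                              double* ten, double* str, double* shr,
                              bool* degenerate) {
  int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
  double e1[3], e2[3], cr[3];
  vsub(M, b, a, e1); vsub(M, c, a, e2);
  cross3(e1, e2, cr);
  double A = 0.5 * std::sqrt(dot3(cr, cr));
  if (A < AREA_EPS) { *degenerate = true; return; }
  double r1[3], r2[3], cr0[3];
  vsub_ref(M, b, a, r1); vsub_ref(M, c, a, r2);
  cross3(r1, r2, cr0);
  double A0 = 0.5 * std::sqrt(dot3(cr0, cr0));
  if (A0 < AREA_EPS) { *degenerate = true; return; }
  double sf = (M.sigma[a] + M.sigma[b] + M.sigma[c]) / 3.0;
  double g11 = dot3(e1, e1), g12 = dot3(e1, e2), g22 = dot3(e2, e2);
  double h11 = dot3(r1, r1), h12 = dot3(r1, r2), h22 = dot3(r2, r2);
  double detH = h11 * h22 - h12 * h12;
  double trC = (h22 * g11 - 2.0 * h12 * g12 + h11 * g22) / detH;
  double lam12 = A / A0;
  double alpha = lam12 - 1.0;
  double beta = (trC - 2.0 * lam12) / (2.0 * lam12);
  *ten += sf * A;
  *str += 0.5 * Ka * alpha * alpha * A0;
  *shr += mu * beta * A0;
}

// signed volume contribution of one face
inline double face_volume(const Mesh& M, int f) {
  int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
  double xb[3] = {M.x(b, 0), M.x(b, 1), M.x(b, 2)};
  double xc[3] = {M.x(c, 0), M.x(c, 1), M.x(c, 2)};
  double cr[3];
  cross3(xb, xc, cr);
  return (M.x(a, 0) * cr[0] + M.x(a, 1) * cr[1] + M.x(a, 2) * cr[2]) / 6.0;
}

// bending energy of a single vertex: kb * |S_i|^2 / (8 * A_i) with
// S_i = sum_j (cot alpha_ij + cot beta_ij)(x_i - x_j), A_i barycentric
inline double vertex_bending(const Mesh& M, int i,
                             const std::vector<int>& vf_ptr,
                             const std::vector<int>& vf_idx, double kb,
                             bool* degenerate) {
  double S[3] = {0, 0, 0};
  double Ai = 0.0;
  for (int p = vf_ptr[i]; p < vf_ptr[i + 1]; ++p) {
    int f = vf_idx[p];
    int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
    // order so that v0 == i
    int v0 = i, v1, v2;
    if (a == i) { v1 = b; v2 = c; }
    else if (b == i) { v1 = c; v2 = a; }
    else { v1 = a; v2 = b; }
    double e01[3], e02[3], e12[3], cr[3];
    vsub(M, v1, v0, e01);
    vsub(M, v2, v0, e02);
    vsub(M, v2, v1, e12);
    cross3(e01, e02, cr);
    double A2 = std::sqrt(dot3(cr, cr)); // = 2*Area for every corner
    if (A2 < 2 * AREA_EPS) { *degenerate = true; return 0.0; }
    Ai += 0.5 * A2 / 3.0;
    // cot at v2 (opposite edge (v0,v1)): (v0-v2).(v1-v2) / |cross|
    double a20[3], a21[3];
    for (int d = 0; d < 3; ++d) { a20[d] = -e02[d]; a21[d] = -e12[d]; }
    double cot2 = dot3(a20, a21) / A2;
    // cot at v1 (opposite edge (v0,v2)): (v0-v1).(v2-v1) / |cross|
    double a10[3];
    for (int d = 0; d < 3; ++d) a10[d] = -e01[d];
    double cot1 = dot3(a10, e12) / A2;
    for (int d = 0; d < 3; ++d) {
      S[d] += cot2 * (-e01[d]); // (x_i - x_{v1})
      S[d] += cot1 * (-e02[d]); // (x_i - x_{v2})
    }
  }
  if (Ai < AREA_EPS) { *degenerate = true; return 0.0; }
  return kb * dot3(S, S) / (8.0 * Ai);
}

void build_adjacency(int n, int m, const int* F, std::vector<int>& vf_ptr,
                     std::vector<int>& vf_idx, std::vector<int>& nb_ptr,
                     std::vector<int>& nb_idx) {
  std::vector<int> cnt(n, 0);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) cnt[F[f + k * m]]++;
  vf_ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) vf_ptr[i + 1] = vf_ptr[i] + cnt[i];
  vf_idx.assign(vf_ptr[n], 0);
  std::vector<int> fill(n, 0);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) {
      int v = F[f + k * m];
      vf_idx[vf_ptr[v] + fill[v]++] = f;
    }
  // neighbour sets including the vertex itself
  nb_ptr.assign(n + 1, 0);
  nb_idx.clear();
  std::vector<int> mark(n, -1);
  for (int i = 0; i < n; ++i) {
    nb_idx.push_back(i);
    mark[i] = i;
    for (int p = vf_ptr[i]; p < vf_ptr[i + 1]; ++p) {
      int f = vf_idx[p];
      for (int k = 0; k < 3; ++k) {
        int v = F[f + k * m];
        if (mark[v] != i) { mark[v] = i; nb_idx.push_back(v); }
      }
    }
    nb_ptr[i + 1] = (int)nb_idx.size();
    // reset marks for next vertex
    for (int p = nb_ptr[i]; p < nb_ptr[i + 1]; ++p) mark[nb_idx[p]] = -1;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_shell_energy(NumericMatrix V, IntegerMatrix F,
                               NumericMatrix Vref, NumericVector sigma,
                               double kb, double Ka, double mu, double kV,
                               double V0) {
  int n = V.nrow(), m = F.nrow();
  std::vector<int> F0(3 * m);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) F0[f + k * m] = F(f, k) - 1;
  Mesh M{n, m, REAL(V), REAL(Vref), F0.data(), REAL(sigma)};
  bool degen = false;
  double ten = 0, str = 0, shr = 0, vol = 0;
  for (int f = 0; f < m; ++f) {
    face_energy_parts(M, f, Ka, mu, &ten, &str, &shr, &degen);
    vol += face_volume(M, f);
  }
  std::vector<int> vf_ptr, vf_idx, nb_ptr, nb_idx;
  build_adjacency(n, m, F0.data(), vf_ptr, vf_idx, nb_ptr, nb_idx);
  double bend = 0;
  for (int i = 0; i < n; ++i)
    bend += vertex_bending(M, i, vf_ptr, vf_idx, kb, &degen);
  if (degen) stop("numerical degeneracy: triangle area below tolerance");
  double evol = 0.5 * kV * (vol - V0) * (vol - V0);
  NumericVector out = NumericVector::create(
      _["bending"] = bend, _["tension"] = ten, _["stretch"] = str,
      _["shear"] = shr, _["volume"] = evol,
      _["total"] = bend + ten + str + shr + evol);
  out.attr("enclosed_volume") = vol;
  return out;
}

// [[Rcpp::export]]
double cpp_shell_objective(NumericMatrix V, IntegerMatrix F,
                           NumericMatrix Vref, NumericVector sigma,
                           double kb, double Ka, double mu, double kV,
                           double V0, double kpin, NumericVector c0) {
  NumericVector e = cpp_shell_energy(V, F, Vref, sigma, kb, Ka, mu, kV, V0);
  int n = V.nrow();
  double pin = 0;
  for (int d = 0; d < 3; ++d) {
    double cd = 0;
    for (int i = 0; i < n; ++i) cd += V(i, d);
    cd = cd / n - c0[d];
    pin += cd * cd;
  }
  return e["total"] + 0.5 * kpin * pin;
}

// [[Rcpp::export]]
NumericVector cpp_shell_gradient(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix Vref, NumericVector sigma,
                                 double kb, double Ka, double mu, double kV,
                                 double V0, double kpin, NumericVector c0,
                                 double h) {
  int n = V.nrow(), m = F.nrow();
  std::vector<int> F0(3 * m);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) F0[f + k * m] = F(f, k) - 1;
  Mesh M{n, m, REAL(V), REAL(Vref), F0.data(), REAL(sigma)};
  std::vector<int> vf_ptr, vf_idx, nb_ptr, nb_idx;
  build_adjacency(n, m, F0.data(), vf_ptr, vf_idx, nb_ptr, nb_idx);

  bool degen = false;
  double vol = 0;
  for (int f = 0; f < m; ++f) vol += face_volume(M, f);
  double dEdV = kV * (vol - V0);

  double cent[3];
  for (int d = 0; d < 3; ++d) {
    double cd = 0;
    for (int i = 0; i < n; ++i) cd += V(i, d);
    cent[d] = cd / n;
  }

  NumericVector grad(3 * n);
  // local energy around vertex v: incident-face terms + one-ring bending,
  // volume handled analytically through dEdV * d(local volume)
  auto local_terms = [&](int v, double* e_out, double* vol_out) {
    double e = 0, lv = 0;
    for (int p = vf_ptr[v]; p < vf_ptr[v + 1]; ++p) {
      int f = vf_idx[p];
      e += face_energy(M, f, Ka, mu, &degen);
      lv += face_volume(M, f);
    }
    for (int p = nb_ptr[v]; p < nb_ptr[v + 1]; ++p)
      e += vertex_bending(M, nb_idx[p], vf_ptr, vf_idx, kb, &degen);
    *e_out = e;
    *vol_out = lv;
  };

  double* Vp = REAL(V);
  for (int v = 0; v < n; ++v) {
    for (int d = 0; d < 3; ++d) {
      double saved = Vp[v + d * n];
      double ep, em, vp, vm;
      Vp[v + d * n] = saved + h;
      local_terms(v, &ep, &vp);
      Vp[v + d * n] = saved - h;
      local_terms(v, &em, &vm);
      Vp[v + d * n] = saved;
      grad[v + d * n] = (ep - em) / (2 * h) + dEdV * (vp - vm) / (2 * h) +
                        kpin * (cent[d] - c0[d]) / n;
    }
  }
  if (degen) stop("numerical degeneracy: triangle area below tolerance");
  return grad;
}

// [[Rcpp::export]]
List cpp_mesh_curvature(NumericMatrix V, IntegerMatrix F) {
  int n = V.nrow(), m = F.nrow();
  std::vector<int> F0(3 * m);
  for (int f = 0; f < m; ++f)
    for (int k = 0; k < 3; ++k) F0[f + k * m] = F(f, k) - 1;
  NumericVector dummy(n);
  Mesh M{n, m, REAL(V), REAL(V), F0.data(), REAL(dummy)};
  std::vector<int> vf_ptr, vf_idx, nb_ptr, nb_idx;
  build_adjacency(n, m, F0.data(), vf_ptr, vf_idx, nb_ptr, nb_idx);
  NumericVector H(n), A(n);
  double vol = 0, area = 0;
  bool degen = false;
  for (int f = 0; f < m; ++f) {
    vol += face_volume(M, f);
    int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
    double e1[3], e2[3], cr[3];
    vsub(M, b, a, e1); vsub(M, c, a, e2);
    cross3(e1, e2, cr);
    area += 0.5 * std::sqrt(dot3(cr, cr));
  }
  for (int i = 0; i < n; ++i) {
    // recompute S_i and A_i as in vertex_bending, but return H
    double S[3] = {0, 0, 0};
    double Ai = 0.0;
    for (int p = vf_ptr[i]; p < vf_ptr[i + 1]; ++p) {
      int f = vf_idx[p];
      int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
      int v1, v2;
      if (a == i) { v1 = b; v2 = c; }
      else if (b == i) { v1 = c; v2 = a; }
      else { v1 = a; v2 = b; }
      double e01[3], e02[3], e12[3], cr[3];
      vsub(M, v1, i, e01); vsub(M, v2, i, e02); vsub(M, v2, v1, e12);
      cross3(e01, e02, cr);
      double A2 = std::sqrt(dot3(cr, cr));
      if (A2 < 2 * AREA_EPS) { degen = true; continue; }
      Ai += 0.5 * A2 / 3.0;
      double a20[3], a10[3];
      for (int d = 0; d < 3; ++d) { a20[d] = -e02[d]; a10[d] = -e01[d]; }
      double cot2 = dot3(a20, e12) * -1.0 / A2; // (v0-v2).(v1-v2)
      double cot1 = dot3(a10, e12) / A2;        // (v0-v1).(v2-v1)
      for (int d = 0; d < 3; ++d)
        S[d] += cot2 * (-e01[d]) + cot1 * (-e02[d]);
    }
    H[i] = (Ai > 0) ? std::sqrt(dot3(S, S)) / (4.0 * Ai) : NA_REAL;
    A[i] = Ai;
  }
  return List::create(_["H"] = H, _["A"] = A, _["volume"] = vol,
                      _["area"] = area, _["degenerate"] = degen);
}
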