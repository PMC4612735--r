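#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tangential electrostatic (Thomson-style) relaxation of unit vectors:
// every pair repels with an inverse-square force, points move along the
// sphere until the configuration is quasi-uniform. Deterministic for fixed
// iterations and step factor.
// [[Rcpp::export]]
NumericMatrix relax_directions_cpp(NumericMatrix pts, int iters,
                                   double step_factor) {
  const int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  const double d_mean = std::sqrt(4.0 * M_PI / n);  // mean spacing scale
  const double step = step_factor * d_mean * d_mean * d_mean;

  for (int it = 0; it < iters; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double d2 = dx * dx + dy * dy + dz * dz + 1e-12;
        double w = 1.0 / (d2 * std::sqrt(d2));
        fx[i] += dx * w; fy[i] += dy * w; fz[i] += dz * w;
        fx[j] -= dx * w; fy[j] -= dy * w; fz[j] -= dz * w;
      }
    }
    for (int i = 0; i < n; ++i) {
      double px = x[i] + step * fx[i];
      double py = y[i] + step * fy[i];
      double pz = z[i] + step * fz[i];
      double nrm = std::sqrt(px * px + py * py + pz * pz);
      x[i] = px / nrm; y[i] = py / nrm; z[i] = pz / nrm;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return out;
}

// Incremental 3D convex hull for points in convex position (unit vectors).
// Returns 1-based triangular faces oriented outward (away from the origin).
// [[Rcpp::export]]
IntegerMatrix convex_hull_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  struct Face { int a, b, c; double nx, ny, nz, d; bool alive; };
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
  }
  std::vector<Face> faces;
  faces.reserve(4 * n);

  auto make_face = [&](int a, int b, int c) {
    Face f;
    double ux = X[b] - X[a], uy = Y[b] - Y[a], uz = Z[b] - Z[a];
    double vx = X[c] - X[a], vy = Y[c] - Y[a], vz = Z[c] - Z[a];
    f.nx = uy * vz - uz * vy;
    f.ny = uz * vx - ux * vz;
    f.nz = ux * vy - uy * vx;
    f.d = f.nx * X[a] + f.ny * Y[a] + f.nz * Z[a];
    f.a = a; f.b = b; f.c = c; f.alive = true;
    return f;
  };
  auto visible = [&](const Face &f, int p) {
    return f.nx * X[p] + f.ny * Y[p] + f.nz * Z[p] - f.d > 1e-12;
  };

  // initial tetrahedron from the first four points that are non-coplanar
  int i3 = -1;
  {
    Face f0 = make_face(0, 1, 2);
    double nn = std::sqrt(f0.nx * f0.nx + f0.ny * f0.ny + f0.nz * f0.nz);
    if (nn < 1e-12) stop("degenerate initial points for the convex hull");
    for (int p = 3; p < n; ++p) {
      if (std::fabs(f0.nx * X[p] + f0.ny * Y[p] + f0.nz * Z[p] - f0.d) >
          1e-9) { i3 = p; break; }
    }
  }
  if (i3 < 0) stop("all points coplanar: no 3D hull");
  {
    // orient the base so the fourth point is behind it
    int a = 0, b = 1, c = 2;
    Face f0 = make_face(a, b, c);
    if (visible(f0, i3)) std::swap(b, c);
    faces.push_back(make_face(a, b, c));
    faces.push_back(make_face(a, c, i3));
    faces.push_back(make_face(c, b, i3));
    faces.push_back(make_face(b, a, i3));
  }

  for (int p = 3; p < n; ++p) {
    if (p == i3) continue;
    // collect visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (faces[f].alive && visible(faces[f], p)) vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // inside current hull (should not happen)
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face &f = faces[vis[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int q = 0; q < 3; ++q) edges.push_back(
          std::make_pair(e[q][0], e[q][1]));
      faces[vis[k]].alive = false;
    }
    for (size_t k = 0; k < edges.size(); ++k) {
      bool boundary = true;
      for (size_t l = 0; l < edges.size(); ++l) {
        if (edges[l].first == edges[k].second &&
            edges[l].second == edges[k].first) { boundary = false; break; }
      }
      if (boundary) {
        faces.push_back(make_face(edges[k].first, edges[k].second, p));
      }
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    // orient outward: the origin lies inside the hull of unit vectors
    bool outward = fc.d > 0;
    out(r, 0) = (outward ? fc.a : fc.a) + 1;
    out(r, 1) = (outward ? fc.b : fc.c) + 1;
    out(r, 2) = (outward ? fc.c : fc.b) + 1;
    ++r;
  }
  return out;
}
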