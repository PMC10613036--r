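// Isosurface extraction by marching tetrahedra: each grid cell is split into
// six tetrahedra around the main diagonal and the level surface of the
// trilinear samples is triangulated with consistent outward orientation.
// Vertices are shared (hashed on the grid edge they lie on), so solid masks
// produce watertight meshes.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct V3 { double z, y, x; };

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double level) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t NN = (size_t)nz * ny * nx;
  const double* fp = REAL(field);
  // corner offsets (dz, dy, dx)
  const int oz[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int oy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int ox[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                          {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  std::unordered_map<uint64_t, int> vmap;
  std::vector<V3> verts;
  std::vector<int> faces; // triples, 0-based
  double fv[8];
  size_t gid[8];
  V3 pos[8];

  auto edge_vertex = [&](int a, int b, const double* f, const size_t* g,
                         const V3* p) -> int {
    size_t ga = g[a], gb = g[b];
    double fa = f[a], fb = f[b];
    if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); }
    uint64_t key = (uint64_t)ga * (uint64_t)NN + (uint64_t)gb;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    const V3& pa = (g[a] <= g[b]) ? p[a] : p[b];
    const V3& pb = (g[a] <= g[b]) ? p[b] : p[a];
    V3 v;
    v.z = pa.z + t * (pb.z - pa.z);
    v.y = pa.y + t * (pb.y - pa.y);
    v.x = pa.x + t * (pb.x - pa.x);
    int id = (int)verts.size();
    verts.push_back(v);
    vmap[key] = id;
    return id;
  };

  auto add_tri = [&](int i0, int i1, int i2, double icz, double icy,
                     double icx) {
    // orient so the normal points away from the inside reference point
    const V3 &p0 = verts[i0], &p1 = verts[i1], &p2 = verts[i2];
    double az = p1.z - p0.z, ay = p1.y - p0.y, ax = p1.x - p0.x;
    double bz = p2.z - p0.z, by = p2.y - p0.y, bx = p2.x - p0.x;
    double nzc = ay * bx - ax * by;
    double nyc = ax * bz - az * bx;
    double nxc = az * by - ay * bz;
    double cz = (p0.z + p1.z + p2.z) / 3.0 - icz;
    double cy = (p0.y + p1.y + p2.y) / 3.0 - icy;
    double cx = (p0.x + p1.x + p2.x) / 3.0 - icx;
    if (nzc * cz + nyc * cy + nxc * cx < 0) std::swap(i1, i2);
    faces.push_back(i0);
    faces.push_back(i1);
    faces.push_back(i2);
  };

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int zc = 0; zc < nz - 1; ++zc) {
        size_t g0 = zc + (size_t)nz * (y + (size_t)ny * x);
        // quick uniform-cell rejection on the cube corners
        {
          const size_t sy = (size_t)nz, sx = (size_t)nz * ny;
          double f0 = fp[g0];
          bool in0 = f0 > level, mixed = false;
          const size_t offs[7] = {1, sy, sy + 1, sx, sx + 1, sx + sy,
                                  sx + sy + 1};
          for (int c = 0; c < 7 && !mixed; ++c)
            if ((fp[g0 + offs[c]] > level) != in0) mixed = true;
          if (!mixed) continue;
        }
        for (int c = 0; c < 8; ++c) {
          int z2 = zc + oz[c], y2 = y + oy[c], x2 = x + ox[c];
          size_t g = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
          gid[c] = g;
          fv[c] = fp[g];
          pos[c].z = z2; pos[c].y = y2; pos[c].x = x2;
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], ni = 0, out[4], no = 0;
          for (int k = 0; k < 4; ++k) {
            if (fv[T[k]] > level) in[ni++] = T[k]; else out[no++] = T[k];
          }
          if (ni == 0 || ni == 4) continue;
          // reference point inside the surface
          double icz = 0, icy = 0, icx = 0;
          for (int k = 0; k < ni; ++k) {
            icz += pos[in[k]].z; icy += pos[in[k]].y; icx += pos[in[k]].x;
          }
          icz /= ni; icy /= ni; icx /= ni;
          if (ni == 1) {
            int a = in[0];
            int v0 = edge_vertex(a, out[0], fv, gid, pos);
            int v1 = edge_vertex(a, out[1], fv, gid, pos);
            int v2 = edge_vertex(a, out[2], fv, gid, pos);
            add_tri(v0, v1, v2, icz, icy, icx);
          } else if (ni == 3) {
            int a = out[0];
            int v0 = edge_vertex(in[0], a, fv, gid, pos);
            int v1 = edge_vertex(in[1], a, fv, gid, pos);
            int v2 = edge_vertex(in[2], a, fv, gid, pos);
            add_tri(v0, v1, v2, icz, icy, icx);
          } else { // ni == 2
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int vac = edge_vertex(a, c, fv, gid, pos);
            int vad = edge_vertex(a, d, fv, gid, pos);
            int vbd = edge_vertex(b, d, fv, gid, pos);
            int vbc = edge_vertex(b, c, fv, gid, pos);
            add_tri(vac, vad, vbd, icz, icy, icx);
            add_tri(vac, vbd, vbc, icz, icy, icx);
          }
        }
      }

  int nv = (int)verts.size(), nf = (int)faces.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[i].z;
    V(i, 1) = verts[i].y;
    V(i, 2) = verts[i].x;
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i] + 1;
    F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// A mesh is watertight when every undirected edge borders exactly two faces.
// [[Rcpp::export]]
bool cpp_mesh_watertight(IntegerMatrix faces, int nverts) {
  std::unordered_map<uint64_t, int> cnt;
  int nf = faces.nrow();
  if (nf == 0) return false;
  for (int i = 0; i < nf; ++i) {
    int v[3] = {faces(i, 0) - 1, faces(i, 1) - 1, faces(i, 2) - 1};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      if (a > b) std::swap(a, b);
      uint64_t key = (uint64_t)a * (uint64_t)nverts + (uint64_t)b;
      cnt[key]++;
    }
  }
  for (auto& kv : cnt)
    if (kv.second != 2) return false;
  return true;
}

// Area and signed enclosed volume of a triangle soup (divergence theorem);
// vertices are (z, y, x) rows in mm.
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericMatrix V, IntegerMatrix F) {
  double area = 0.0, vol = 0.0;
  int nf = F.nrow();
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    double az = V(a, 0), ay = V(a, 1), ax = V(a, 2);
    double bz = V(b, 0), by = V(b, 1), bx = V(b, 2);
    double cz = V(c, 0), cy = V(c, 1), cx = V(c, 2);
    double uz = bz - az, uy = by - ay, ux = bx - ax;
    double vz = cz - az, vy = cy - ay, vx = cx - ax;
    double nz = uy * vx - ux * vy;
    double ny = ux * vz - uz * vx;
    double nx = uz * vy - uy * vz;
    area += 0.5 * std::sqrt(nz * nz + ny * ny + nx * nx);
    // scalar triple product a . (b x c)
    vol += (az * (by * cx - bx * cy) + ay * (bx * cz - bz * cx) +
            ax * (bz * cy - by * cz)) / 6.0;
  }
  return NumericVector::create(area, std::fabs(vol));
}
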