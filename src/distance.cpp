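#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// finite stand-in for "no feature yet": keeps the parabola arithmetic finite
// while dominating any real squared distance (extents are << 1e6 um)
static const double BIG = 1e30;

// Felzenszwalb & Huttenlocher 1D squared distance transform on a sampled
// line with physical sample spacing s. f holds squared distances on input.
static void dt1d(std::vector<double>& f, double s) {
    const int n = (int)f.size();
    if (n == 0) return;
    std::vector<int> v(n);
    std::vector<double> z(n + 1), d(n);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s2;
        while (true) {
            double qq = (double)q * s, vv = (double)v[k] * s;
            s2 = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
            if (s2 <= z[k]) --k; else break;
        }
        ++k;
        v[k] = q;
        z[k] = s2;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double qq = (double)q * s;
        while (z[k + 1] < qq) ++k;
        double dv = qq - (double)v[k] * s;
        d[q] = dv * dv + f[v[k]];
    }
    f.swap(d);
}

// Exact squared Euclidean distance (world units) from every voxel center to
// the nearest feature voxel center. dims/spacing ordered (z, y, x); the data
// vector uses R's column-major layout of a [z, y, x] array, i.e. z fastest.
// [[Rcpp::export]]
NumericVector cpp_edt2(LogicalVector feature, IntegerVector dims,
                       NumericVector spacing) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = feature[i] ? 0.0 : BIG;
    // index(i,j,k) = i + nz*(j + ny*k), i over z, j over y, k over x
    std::vector<double> line;
    // pass over z (fastest stride 1)
    line.resize(nz);
    for (int k = 0; k < nx; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
            bool any = false;
            for (int i = 0; i < nz; ++i) { line[i] = out[base + i]; if (line[i] < 1e29) any = true; }
            if (!any) continue;
            dt1d(line, sz);
            for (int i = 0; i < nz; ++i) out[base + i] = line[i];
        }
    // pass over y (stride nz)
    line.resize(ny);
    for (int k = 0; k < nx; ++k)
        for (int i = 0; i < nz; ++i) {
            R_xlen_t base = i + (R_xlen_t)nz * ny * k;
            bool any = false;
            for (int j = 0; j < ny; ++j) { line[j] = out[base + (R_xlen_t)nz * j]; if (line[j] < 1e29) any = true; }
            if (!any) continue;
            dt1d(line, sy);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nz * j] = line[j];
        }
    // pass over x (stride nz*ny)
    line.resize(nx);
    const R_xlen_t sxy = (R_xlen_t)nz * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nz; ++i) {
            R_xlen_t base = i + (R_xlen_t)nz * j;
            bool any = false;
            for (int k = 0; k < nx; ++k) { line[k] = out[base + sxy * k]; if (line[k] < 1e29) any = true; }
            if (!any) continue;
            dt1d(line, sx);
            for (int k = 0; k < nx; ++k) out[base + sxy * k] = line[k];
        }
    for (R_xlen_t i = 0; i < n; ++i)
        if (out[i] >= 1e29) out[i] = INF;
    return out;
}

// Local thickness by maximal inscribed sphere: every foreground voxel gets
// the diameter of the largest sphere (radius from the EDT ridge) that
// contains it. radius: per-voxel inscribed radius (world units), 0 outside.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector radius, IntegerVector dims,
                                  NumericVector spacing) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    NumericVector th(n);
    std::vector<R_xlen_t> idx;
    idx.reserve(n / 4);
    for (R_xlen_t i = 0; i < n; ++i)
        if (radius[i] > 0) idx.push_back(i);
    std::sort(idx.begin(), idx.end(),
              [&](R_xlen_t a, R_xlen_t b) { return radius[a] > radius[b]; });
    for (R_xlen_t c : idx) {
        const double r = radius[c];
        const double d2max = r * r + 1e-9;
        const int ci = (int)(c % nz);
        const int cj = (int)((c / nz) % ny);
        const int ck = (int)(c / ((R_xlen_t)nz * ny));
        const int ri = (int)std::floor(r / sz);
        const int rj = (int)std::floor(r / sy);
        const int rk = (int)std::floor(r / sx);
        const double two_r = 2.0 * r;
        for (int k = std::max(0, ck - rk); k <= std::min(nx - 1, ck + rk); ++k) {
            const double dx = (k - ck) * sx, dx2 = dx * dx;
            for (int j = std::max(0, cj - rj); j <= std::min(ny - 1, cj + rj); ++j) {
                const double dy = (j - cj) * sy, dxy2 = dx2 + dy * dy;
                if (dxy2 > d2max) continue;
                const R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
                for (int i = std::max(0, ci - ri); i <= std::min(nz - 1, ci + ri); ++i) {
                    const double dz = (i - ci) * sz;
                    if (dxy2 + dz * dz > d2max) continue;
                    const R_xlen_t p = base + i;
                    if (radius[p] > 0 && th[p] < two_r) th[p] = two_r;
                }
            }
        }
    }
    return th;
}

// Connected-component labelling of a 3D logical array; connectivity 6, 18 or
// 26 (use 8 for single-slice 2D data via connectivity=26, which degenerates
// to 8 in-plane). Labels are assigned in raster order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    IntegerVector lab(n);
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nzero = (dz != 0) + (dy != 0) + (dx != 0);
                if (nzero == 0) continue;
                if (connectivity == 6 && nzero > 1) continue;
                if (connectivity == 18 && nzero > 2) continue;
                offs.push_back({dz, dy, dx});
            }
    int next = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            const int pi = (int)(p % nz);
            const int pj = (int)((p / nz) % ny);
            const int pk = (int)(p / ((R_xlen_t)nz * ny));
            for (const auto& o : offs) {
                const int i = pi + o[0], j = pj + o[1], k = pk + o[2];
                if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx)
                    continue;
                const R_xlen_t q = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
                if (mask[q] && lab[q] == 0) {
                    lab[q] = next;
                    stack.push_back(q);
                }
            }
        }
    }
    return lab;
}
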