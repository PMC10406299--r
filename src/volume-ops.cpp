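#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Column-major linear index for a 3D grid.
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

static inline int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample at 0-based continuous coordinate (sx, sy, sz) with border
// replication.  *inside is set false when the point lies outside the grid.
static double sample_trilinear(const double *d, int nx, int ny, int nz,
                               double sx, double sy, double sz, bool *inside) {
    *inside = (sx >= 0.0 && sx <= nx - 1.0 &&
               sy >= 0.0 && sy <= ny - 1.0 &&
               sz >= 0.0 && sz <= nz - 1.0);
    double cx = std::min(std::max(sx, 0.0), (double)(nx - 1));
    double cy = std::min(std::max(sy, 0.0), (double)(ny - 1));
    double cz = std::min(std::max(sz, 0.0), (double)(nz - 1));
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    if (x0 == nx - 1 && nx > 1) x0--;
    if (y0 == ny - 1 && ny > 1) y0--;
    if (z0 == nz - 1 && nz > 1) z0--;
    int x1 = std::min(x0 + 1, nx - 1);
    int y1 = std::min(y0 + 1, ny - 1);
    int z1 = std::min(z0 + 1, nz - 1);
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double c000 = d[idx3(x0, y0, z0, nx, ny)], c100 = d[idx3(x1, y0, z0, nx, ny)];
    double c010 = d[idx3(x0, y1, z0, nx, ny)], c110 = d[idx3(x1, y1, z0, nx, ny)];
    double c001 = d[idx3(x0, y0, z1, nx, ny)], c101 = d[idx3(x1, y0, z1, nx, ny)];
    double c011 = d[idx3(x0, y1, z1, nx, ny)], c111 = d[idx3(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
}

// Backward warp: out(x) = I(x - w(x)), plus validity mask of in-grid samples.
// [[Rcpp::export]]
List c_warp_backward(NumericVector data, IntegerVector dims,
                     NumericVector u, NumericVector v, NumericVector t) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    IntegerVector valid(n);
    const double *d = REAL(data);
    const double *pu = REAL(u), *pv = REAL(v), *pt = REAL(t);
    double *po = REAL(out);
    int *pm = INTEGER(valid);
    R_xlen_t i = 0;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x, ++i) {
                bool inside;
                po[i] = sample_trilinear(d, nx, ny, nz,
                                         x - pu[i], y - pv[i], z - pt[i], &inside);
                pm[i] = inside ? 1 : 0;
            }
    return List::create(_["data"] = out, _["valid"] = valid);
}

// Grid-scaling resample: out(i) = I(i * scale) per axis, 0-based coordinates.
// [[Rcpp::export]]
NumericVector c_resample_scale(NumericVector data, IntegerVector dims,
                               IntegerVector outDims, NumericVector scale) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int mx = outDims[0], my = outDims[1], mz = outDims[2];
    NumericVector out((R_xlen_t)mx * my * mz);
    const double *d = REAL(data);
    double *po = REAL(out);
    R_xlen_t i = 0;
    bool inside;
    for (int z = 0; z < mz; ++z)
        for (int y = 0; y < my; ++y)
            for (int x = 0; x < mx; ++x, ++i)
                po[i] = sample_trilinear(d, nx, ny, nz,
                                         x * scale[0], y * scale[1], z * scale[2],
                                         &inside);
    return out;
}

// Affine resample: out(x) = I(A[,1:3] %*% x + A[,4]) in 0-based voxel coords.
// [[Rcpp::export]]
NumericVector c_warp_affine(NumericVector data, IntegerVector dims,
                            NumericMatrix A) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector out((R_xlen_t)nx * ny * nz);
    const double *d = REAL(data);
    double *po = REAL(out);
    R_xlen_t i = 0;
    bool inside;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x, ++i) {
                double sx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + A(0, 3);
                double sy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + A(1, 3);
                double sz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + A(2, 3);
                po[i] = sample_trilinear(d, nx, ny, nz, sx, sy, sz, &inside);
            }
    return out;
}

// 1D convolution along one axis with border replication (separable smoothing).
// [[Rcpp::export]]
NumericVector c_conv_dim(NumericVector data, IntegerVector dims,
                         NumericVector kernel, int along) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int K = kernel.size();
    int half = K / 2;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    const double *d = REAL(data);
    const double *k = REAL(kernel);
    double *po = REAL(out);
    int nd[3] = {nx, ny, nz};
    int N = nd[along];
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int c[3] = {x, y, z};
                double acc = 0.0;
                for (int j = 0; j < K; ++j) {
                    int p = clampi(c[along] + j - half, 0, N - 1);
                    int cc[3] = {x, y, z};
                    cc[along] = p;
                    acc += k[j] * d[idx3(cc[0], cc[1], cc[2], nx, ny)];
                }
                po[idx3(x, y, z, nx, ny)] = acc;
            }
    return out;
}

// Median filter over a (2r+1)^3 box restricted to in-mask voxels.  Voxels
// outside the mask, or with an empty in-mask window, return 0.
// [[Rcpp::export]]
NumericVector c_masked_median_filter(NumericVector data, IntegerVector mask,
                                     IntegerVector dims, int radius) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    const double *d = REAL(data);
    const int *m = INTEGER(mask);
    double *po = REAL(out);
    std::vector<double> buf;
    buf.reserve((size_t)(2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t i = idx3(x, y, z, nx, ny);
                if (!m[i]) { po[i] = 0.0; continue; }
                buf.clear();
                int z0 = std::max(z - radius, 0), z1 = std::min(z + radius, nz - 1);
                int y0 = std::max(y - radius, 0), y1 = std::min(y + radius, ny - 1);
                int x0 = std::max(x - radius, 0), x1 = std::min(x + radius, nx - 1);
                for (int zz = z0; zz <= z1; ++zz)
                    for (int yy = y0; yy <= y1; ++yy) {
                        R_xlen_t base = idx3(x0, yy, zz, nx, ny);
                        for (int xx = x0; xx <= x1; ++xx, ++base)
                            if (m[base]) buf.push_back(d[base]);
                    }
                if (buf.empty()) { po[i] = 0.0; continue; }
                size_t h = buf.size() / 2;
                std::nth_element(buf.begin(), buf.begin() + h, buf.end());
                double med = buf[h];
                if (buf.size() % 2 == 0) {
                    double lo = *std::max_element(buf.begin(), buf.begin() + h);
                    med = 0.5 * (med + lo);
                }
                po[i] = med;
            }
    return out;
}

// Connected-component labeling (connectivity 6, 18 or 26) by BFS flood fill.
// [[Rcpp::export]]
IntegerVector c_label_components(IntegerVector mask, IntegerVector dims,
                                 int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n);
    const int *m = INTEGER(mask);
    int *lab = INTEGER(labels);
    std::vector<int> offx, offy, offz;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (a == 0) continue;
                if ((connectivity == 6 && a > 1) ||
                    (connectivity == 18 && a > 2)) continue;
                offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
            }
    int nOff = (int)offx.size();
    int cur = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!m[i] || lab[i]) continue;
        ++cur;
        lab[i] = cur;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t p = stack.back(); stack.pop_back();
            int x = (int)(p % nx);
            int y = (int)((p / nx) % ny);
            int z = (int)(p / ((R_xlen_t)nx * ny));
            for (int j = 0; j < nOff; ++j) {
                int xx = x + offx[j], yy = y + offy[j], zz = z + offz[j];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t q = idx3(xx, yy, zz, nx, ny);
                if (m[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
            }
        }
    }
    return labels;
}

// Binary dilation by a Euclidean ball of the given voxel radius.
// [[Rcpp::export]]
IntegerVector c_dilate_ball(IntegerVector mask, IntegerVector dims,
                            double radius) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector out(n);
    const int *m = INTEGER(mask);
    int *po = INTEGER(out);
    int r = (int)std::floor(radius);
    double r2 = radius * radius;
    std::vector<int> offx, offy, offz;
    for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx)
                if ((double)(dx * dx + dy * dy + dz * dz) <= r2) {
                    offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
                }
    int nOff = (int)offx.size();
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t i = idx3(x, y, z, nx, ny);
                if (!m[i]) continue;
                for (int j = 0; j < nOff; ++j) {
                    int xx = x + offx[j], yy = y + offy[j], zz = z + offz[j];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                        zz < 0 || zz >= nz) continue;
                    po[idx3(xx, yy, zz, nx, ny)] = 1;
                }
            }
    return out;
}
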