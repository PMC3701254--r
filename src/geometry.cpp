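// Low-level voxel geometry kernels. All arrays are R column-major with
// dim = (nx, ny, nz), i.e. linear index = i + nx*(j + ny*k), 0-based here.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const double BIG = 1e30;

static inline double sq(double x) { return x * x; }

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// generalized to non-unit sample spacing w along the scanned axis.
// f holds squared distances on input; d receives the lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double qq = q * w;
        double s;
        for (;;) {
            double vv = v[k] * w;
            s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
            if (s <= z[k] && k > 0) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double qq = q * w;
        while (z[k + 1] < qq) ++k;
        double vv = v[k] * w;
        d[q] = sq(qq - vv) + f[v[k]];
    }
}

// Squared EDT to the nearest "feature" voxel center, anisotropic spacing.
static void edt_sq_3d(std::vector<double>& g, int nx, int ny, int nz,
                      double sx, double sy, double sz) {
    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);
    // along x
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            size_t base = (size_t)nx * (j + (size_t)ny * k);
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f, d, v, z, nx, sx);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    // along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            size_t base = i + (size_t)nx * ny * (size_t)k;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)nx * j];
            dt1d(f, d, v, z, ny, sy);
            for (int j = 0; j < ny; ++j) g[base + (size_t)nx * j] = d[j];
        }
    // along z
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            size_t base = i + (size_t)nx * j;
            size_t stride = (size_t)nx * ny;
            for (int k = 0; k < nz; ++k) f[k] = g[base + stride * k];
            dt1d(f, d, v, z, nz, sz);
            for (int k = 0; k < nz; ++k) g[base + stride * k] = d[k];
        }
}

// Signed EDT between voxel centers: + inside mask (distance to nearest
// background center), - outside (distance to nearest foreground center).
// [[Rcpp::export]]
NumericVector cpp_signed_edt(LogicalVector mask, IntegerVector dim,
                             NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    std::vector<double> din(n), dout(n);
    for (size_t t = 0; t < n; ++t) {
        bool fg = mask[t];
        din[t]  = fg ? BIG : 0.0;   // features = background
        dout[t] = fg ? 0.0 : BIG;   // features = foreground
    }
    edt_sq_3d(din, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
    edt_sq_3d(dout, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
    NumericVector out(n);
    for (size_t t = 0; t < n; ++t)
        out[t] = mask[t] ? std::sqrt(din[t]) : -std::sqrt(dout[t]);
    return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, per-axis sigma in voxel units, reflect boundary,
// kernel truncated at 4*sigma and renormalized to unit sum.
static inline int reflect_idx(int i, int n) {
    if (n == 1) return 0;
    int m = 2 * n;
    i = ((i % m) + m) % m;
    return (i < n) ? i : (m - 1 - i);
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, double sigma) {
    if (sigma <= 1e-12) return;
    int r = (int)std::ceil(4.0 * sigma);
    std::vector<double> w(2 * r + 1);
    double s = 0.0;
    for (int i = -r; i <= r; ++i) {
        w[i + r] = std::exp(-0.5 * sq(i / sigma));
        s += w[i + r];
    }
    for (double& wi : w) wi /= s;

    int nline = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    std::vector<double> line(nline), res(nline);
    size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : (size_t)nx * ny;
    int n1 = (axis == 0) ? ny : nx;
    int n2 = (axis == 2) ? ny : nz;
    for (int b = 0; b < n2; ++b)
        for (int a1 = 0; a1 < n1; ++a1) {
            size_t base;
            if (axis == 0)      base = (size_t)nx * (a1 + (size_t)ny * b);
            else if (axis == 1) base = a1 + (size_t)nx * ny * (size_t)b;
            else                base = a1 + (size_t)nx * b;
            for (int q = 0; q < nline; ++q) line[q] = a[base + stride * q];
            for (int q = 0; q < nline; ++q) {
                double acc = 0.0;
                for (int i = -r; i <= r; ++i)
                    acc += w[i + r] * line[reflect_idx(q + i, nline)];
                res[q] = acc;
            }
            for (int q = 0; q < nline; ++q) a[base + stride * q] = res[q];
        }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector arr, IntegerVector dim,
                              NumericVector sigma_vox) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    std::vector<double> a(arr.begin(), arr.end());
    blur_axis(a, nx, ny, nz, 0, sigma_vox[0]);
    blur_axis(a, nx, ny, nz, 1, sigma_vox[1]);
    blur_axis(a, nx, ny, nz, 2, sigma_vox[2]);
    NumericVector out(n);
    std::copy(a.begin(), a.end(), out.begin());
    return out;
}

// ---------------------------------------------------------------------------
// Tricubic (Catmull-Rom) sampling at continuous 0-based voxel coordinates.
// Points outside the array bounding box return 0 and are flagged oob.
// Edge neighborhoods use clamped (replicated) indices; grid values are
// reproduced exactly at voxel centers.
static inline void cr_weights(double t, double* w) {
    double t2 = t * t, t3 = t2 * t;
    w[0] = -0.5 * t3 + t2 - 0.5 * t;
    w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
    w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
    w[3] = 0.5 * t3 - 0.5 * t2;
}

static inline int clampi(int i, int lo, int hi) {
    return (i < lo) ? lo : (i > hi) ? hi : i;
}

// [[Rcpp::export]]
List cpp_tricubic(NumericVector arr, IntegerVector dim, NumericMatrix pts) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int np = pts.nrow();
    NumericVector val(np);
    LogicalVector oob(np);
    for (int p = 0; p < np; ++p) {
        double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
        if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
            x < 0 || y < 0 || z < 0 ||
            x > nx - 1 || y > ny - 1 || z > nz - 1) {
            val[p] = 0.0;
            oob[p] = true;
            continue;
        }
        int bx = clampi((int)std::floor(x), 0, nx - 1);
        int by = clampi((int)std::floor(y), 0, ny - 1);
        int bz = clampi((int)std::floor(z), 0, nz - 1);
        double wx[4], wy[4], wz[4];
        cr_weights(x - bx, wx);
        cr_weights(y - by, wy);
        cr_weights(z - bz, wz);
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) {
            int kz = clampi(bz - 1 + c, 0, nz - 1);
            double az = wz[c];
            if (az == 0.0) continue;
            for (int b = 0; b < 4; ++b) {
                int ky = clampi(by - 1 + b, 0, ny - 1);
                double ay = wy[b] * az;
                if (ay == 0.0) continue;
                size_t base = (size_t)nx * (ky + (size_t)ny * kz);
                for (int a = 0; a < 4; ++a) {
                    int kx = clampi(bx - 1 + a, 0, nx - 1);
                    acc += wx[a] * ay * arr[base + kx];
                }
            }
        }
        val[p] = acc;
        oob[p] = false;
    }
    return List::create(_["values"] = val, _["oob"] = oob);
}

// ---------------------------------------------------------------------------
// 26-connected component labeling of a 3D boolean mask.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    IntegerVector lab(n, 0);
    int next = 0;
    std::vector<size_t> stack;
    for (size_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            size_t t = stack.back();
            stack.pop_back();
            int i = (int)(t % nx);
            int j = (int)((t / nx) % ny);
            int k = (int)(t / ((size_t)nx * ny));
            for (int dk = -1; dk <= 1; ++dk)
                for (int dj = -1; dj <= 1; ++dj)
                    for (int di = -1; di <= 1; ++di) {
                        if (!di && !dj && !dk) continue;
                        int ii = i + di, jj = j + dj, kk = k + dk;
                        if (ii < 0 || jj < 0 || kk < 0 ||
                            ii >= nx || jj >= ny || kk >= nz) continue;
                        size_t u = ii + (size_t)nx * (jj + (size_t)ny * kk);
                        if (mask[u] && lab[u] == 0) {
                            lab[u] = next;
                            stack.push_back(u);
                        }
                    }
        }
    }
    lab.attr("n_components") = next;
    return lab;
}

// ---------------------------------------------------------------------------
// Minimum enclosing sphere (Welzl, move-to-front), deterministic.
struct Ball {
    double c[3];
    double r2;
};

static inline double dist2(const double* a, const double* b) {
    return sq(a[0] - b[0]) + sq(a[1] - b[1]) + sq(a[2] - b[2]);
}

static inline bool in_ball(const Ball& b, const double* p) {
    if (b.r2 < 0) return false;
    double eps = 1e-10 * (1.0 + b.r2);
    return dist2(b.c, p) <= b.r2 + eps;
}

static bool circumsphere2(const double* p, const double* q, Ball& b) {
    for (int d = 0; d < 3; ++d) b.c[d] = 0.5 * (p[d] + q[d]);
    b.r2 = dist2(b.c, p);
    return true;
}

static void cross3(const double* a, const double* b, double* c) {
    c[0] = a[1] * b[2] - a[2] * b[1];
    c[1] = a[2] * b[0] - a[0] * b[2];
    c[2] = a[0] * b[1] - a[1] * b[0];
}

static bool circumsphere3(const double* p, const double* q, const double* r,
                          Ball& b) {
    double a[3], v[3], axv[3];
    for (int d = 0; d < 3; ++d) { a[d] = q[d] - p[d]; v[d] = r[d] - p[d]; }
    cross3(a, v, axv);
    double den = 2.0 * (sq(axv[0]) + sq(axv[1]) + sq(axv[2]));
    double scale = (sq(a[0]) + sq(a[1]) + sq(a[2])) *
                   (sq(v[0]) + sq(v[1]) + sq(v[2]));
    if (den <= 1e-14 * (1.0 + scale)) return false;  // collinear
    double la = sq(a[0]) + sq(a[1]) + sq(a[2]);
    double lv = sq(v[0]) + sq(v[1]) + sq(v[2]);
    double u[3];
    for (int d = 0; d < 3; ++d) u[d] = la * v[d] - lv * a[d];
    double uxaxv[3];
    cross3(u, axv, uxaxv);
    for (int d = 0; d < 3; ++d) b.c[d] = p[d] + uxaxv[d] / den;
    b.r2 = dist2(b.c, p);
    return true;
}

static bool circumsphere4(const double* p0, const double* p1, const double* p2,
                          const double* p3, Ball& b) {
    double A[3][3], rhs[3];
    const double* ps[3] = { p1, p2, p3 };
    double n0 = sq(p0[0]) + sq(p0[1]) + sq(p0[2]);
    double scale = 0.0;
    for (int r = 0; r < 3; ++r) {
        for (int d = 0; d < 3; ++d) {
            A[r][d] = 2.0 * (ps[r][d] - p0[d]);
            scale = std::max(scale, std::fabs(A[r][d]));
        }
        rhs[r] = sq(ps[r][0]) + sq(ps[r][1]) + sq(ps[r][2]) - n0;
    }
    double det =
        A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
        A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
        A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    if (std::fabs(det) <= 1e-12 * (1.0 + scale * scale * scale)) return false;
    // Cramer
    for (int d = 0; d < 3; ++d) {
        double M[3][3];
        for (int r = 0; r < 3; ++r)
            for (int cc = 0; cc < 3; ++cc)
                M[r][cc] = (cc == d) ? rhs[r] : A[r][cc];
        double dd =
            M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
            M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
            M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
        b.c[d] = dd / det;
    }
    b.r2 = dist2(b.c, p0);
    return true;
}

// Smallest ball with all support points on (or within) its boundary set;
// robust to degenerate supports by subset enumeration.
static Ball ball_trivial(const std::vector<const double*>& S) {
    Ball best;
    best.c[0] = best.c[1] = best.c[2] = 0.0;
    best.r2 = -1.0;
    int m = (int)S.size();
    if (m == 0) return best;
    for (int bits = 1; bits < (1 << m); ++bits) {
        std::vector<const double*> sub;
        for (int i = 0; i < m; ++i)
            if (bits & (1 << i)) sub.push_back(S[i]);
        Ball b;
        bool ok = false;
        switch (sub.size()) {
        case 1:
            b.c[0] = sub[0][0]; b.c[1] = sub[0][1]; b.c[2] = sub[0][2];
            b.r2 = 0.0;
            ok = true;
            break;
        case 2: ok = circumsphere2(sub[0], sub[1], b); break;
        case 3: ok = circumsphere3(sub[0], sub[1], sub[2], b); break;
        case 4: ok = circumsphere4(sub[0], sub[1], sub[2], sub[3], b); break;
        }
        if (!ok) continue;
        bool encloses = true;
        for (int i = 0; i < m && encloses; ++i) encloses = in_ball(b, S[i]);
        if (encloses && (best.r2 < 0 || b.r2 < best.r2)) best = b;
    }
    return best;
}

static Ball welzl(std::vector<const double*>& pts, size_t end,
                  std::vector<const double*>& support) {
    Ball b = ball_trivial(support);
    if (support.size() == 4) return b;
    for (size_t i = 0; i < end; ++i) {
        const double* p = pts[i];
        if (!in_ball(b, p)) {
            support.push_back(p);
            b = welzl(pts, i, support);
            support.pop_back();
            for (size_t j = i; j > 0; --j) pts[j] = pts[j - 1];
            pts[0] = p;
        }
    }
    return b;
}

// [[Rcpp::export]]
List cpp_miniball(NumericMatrix pts) {
    int n = pts.nrow();
    if (n == 0) stop("miniball of an empty point set");
    std::vector<double> buf(3 * (size_t)n);
    std::vector<const double*> ptr(n);
    for (int i = 0; i < n; ++i) {
        buf[3 * (size_t)i + 0] = pts(i, 0);
        buf[3 * (size_t)i + 1] = pts(i, 1);
        buf[3 * (size_t)i + 2] = pts(i, 2);
        ptr[i] = &buf[3 * (size_t)i];
    }
    // deterministic LCG shuffle guards against adversarial lattice orders
    uint64_t state = 88172645463325252ULL;
    for (int i = n - 1; i > 0; --i) {
        state = state * 6364136223846793005ULL + 1442695040888963407ULL;
        int j = (int)(state % (uint64_t)(i + 1));
        std::swap(ptr[i], ptr[j]);
    }
    std::vector<const double*> support;
    Ball b = welzl(ptr, ptr.size(), support);
    return List::create(
        _["center"] = NumericVector::create(b.c[0], b.c[1], b.c[2]),
        _["radius"] = std::sqrt(std::max(0.0, b.r2)));
}

// ---------------------------------------------------------------------------
// Union footprint area of projected triangles, rasterized on a square grid of
// the given pitch: each triangle's exact clipped area is accumulated per cell
// and per-cell coverage is capped at the cell area. Exact for fold-free
// (injective) projections; caps double counting otherwise.
static double poly_area(const std::vector<double>& x,
                        const std::vector<double>& y) {
    double a = 0.0;
    int n = (int)x.size();
    for (int i = 0; i < n; ++i) {
        int j = (i + 1) % n;
        a += x[i] * y[j] - x[j] * y[i];
    }
    return 0.5 * std::fabs(a);
}

// clip polygon against half-plane keep: sgn*(coord - c) <= 0
static void clip_half(std::vector<double>& x, std::vector<double>& y,
                      int axis, double c, double sgn) {
    std::vector<double> nx_, ny_;
    int n = (int)x.size();
    if (n == 0) return;
    for (int i = 0; i < n; ++i) {
        int j = (i + 1) % n;
        double vi = axis == 0 ? x[i] : y[i];
        double vj = axis == 0 ? x[j] : y[j];
        double di = sgn * (vi - c), dj = sgn * (vj - c);
        bool ini = di <= 0, inj = dj <= 0;
        if (ini) { nx_.push_back(x[i]); ny_.push_back(y[i]); }
        if (ini != inj) {
            double t = di / (di - dj);
            nx_.push_back(x[i] + t * (x[j] - x[i]));
            ny_.push_back(y[i] + t * (y[j] - y[i]));
        }
    }
    x.swap(nx_);
    y.swap(ny_);
}

// [[Rcpp::export]]
double cpp_raster_union_area(NumericMatrix tri, double pitch) {
    int nt = tri.nrow();
    if (nt == 0) return 0.0;
    double minx = BIG, miny = BIG, maxx = -BIG, maxy = -BIG;
    for (int t = 0; t < nt; ++t)
        for (int v = 0; v < 3; ++v) {
            minx = std::min(minx, tri(t, 2 * v));
            maxx = std::max(maxx, tri(t, 2 * v));
            miny = std::min(miny, tri(t, 2 * v + 1));
            maxy = std::max(maxy, tri(t, 2 * v + 1));
        }
    int ncx = std::max(1, (int)std::ceil((maxx - minx) / pitch + 1e-9));
    int ncy = std::max(1, (int)std::ceil((maxy - miny) / pitch + 1e-9));
    std::vector<double> acc((size_t)ncx * ncy, 0.0);
    std::vector<double> px, py;
    for (int t = 0; t < nt; ++t) {
        double tminx = std::min({ tri(t, 0), tri(t, 2), tri(t, 4) });
        double tmaxx = std::max({ tri(t, 0), tri(t, 2), tri(t, 4) });
        double tminy = std::min({ tri(t, 1), tri(t, 3), tri(t, 5) });
        double tmaxy = std::max({ tri(t, 1), tri(t, 3), tri(t, 5) });
        int c0 = clampi((int)std::floor((tminx - minx) / pitch), 0, ncx - 1);
        int c1 = clampi((int)std::floor((tmaxx - minx) / pitch), 0, ncx - 1);
        int r0 = clampi((int)std::floor((tminy - miny) / pitch), 0, ncy - 1);
        int r1 = clampi((int)std::floor((tmaxy - miny) / pitch), 0, ncy - 1);
        for (int cy = r0; cy <= r1; ++cy)
            for (int cx = c0; cx <= c1; ++cx) {
                px.assign({ tri(t, 0), tri(t, 2), tri(t, 4) });
                py.assign({ tri(t, 1), tri(t, 3), tri(t, 5) });
                double x0 = minx + cx * pitch, x1 = x0 + pitch;
                double y0 = miny + cy * pitch, y1 = y0 + pitch;
                clip_half(px, py, 0, x0, -1.0);
                clip_half(px, py, 0, x1, 1.0);
                clip_half(px, py, 1, y0, -1.0);
                clip_half(px, py, 1, y1, 1.0);
                if (px.size() >= 3)
                    acc[cx + (size_t)ncx * cy] += poly_area(px, py);
            }
    }
    double cell = pitch * pitch, total = 0.0;
    for (double a : acc) total += std::min(a, cell);
    return total;
}
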