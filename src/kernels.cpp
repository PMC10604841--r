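#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Squared distance from point p to the segment a-b (3D).
static double dist2_point_segment(const double *p, const double *a,
                                  const double *b) {
    double d[3], ap[3];
    double len2 = 0.0, dot = 0.0;
    for (int k = 0; k < 3; ++k) {
        d[k] = b[k] - a[k];
        ap[k] = p[k] - a[k];
        len2 += d[k] * d[k];
        dot += ap[k] * d[k];
    }
    double t = (len2 > 0.0) ? dot / len2 : 0.0;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
        double e = ap[k] - t * d[k];
        s += e * e;
    }
    return s;
}

// Rasterize tubular segments into a voxel grid. A voxel is foreground iff
// its center lies within `radius` of the segment axis. Coordinates are in
// micrometers; axis order (z, y, x); voxel (i, j, k) has its center at
// ((i - 0.5) vz, (j - 0.5) vy, (k - 0.5) vx), 1-based.
// [[Rcpp::export]]
LogicalVector raster_segments_cpp(NumericMatrix p0, NumericMatrix p1,
                                  NumericVector radius, IntegerVector dims,
                                  NumericVector vox) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const double vz = vox[0], vy = vox[1], vx = vox[2];
    LogicalVector out((R_xlen_t)nz * ny * nx);
    const int nseg = p0.nrow();
    for (int s = 0; s < nseg; ++s) {
        double a[3] = {p0(s, 0), p0(s, 1), p0(s, 2)};
        double b[3] = {p1(s, 0), p1(s, 1), p1(s, 2)};
        const double r = radius[s], r2 = r * r;
        // voxel-index bounding box around the tube
        int lo[3], hi[3];
        const double v[3] = {vz, vy, vx};
        const int n[3] = {nz, ny, nx};
        for (int k = 0; k < 3; ++k) {
            double cmin = std::min(a[k], b[k]) - r;
            double cmax = std::max(a[k], b[k]) + r;
            lo[k] = std::max(1, (int)std::floor(cmin / v[k] + 0.5));
            hi[k] = std::min(n[k], (int)std::ceil(cmax / v[k] + 0.5));
        }
        double p[3];
        for (int k = lo[2]; k <= hi[2]; ++k) {
            p[2] = (k - 0.5) * vx;
            for (int j = lo[1]; j <= hi[1]; ++j) {
                p[1] = (j - 0.5) * vy;
                for (int i = lo[0]; i <= hi[0]; ++i) {
                    p[0] = (i - 0.5) * vz;
                    if (dist2_point_segment(p, a, b) <= r2) {
                        out[(R_xlen_t)(i - 1) +
                            (R_xlen_t)nz * ((j - 1) + (R_xlen_t)ny * (k - 1))] = true;
                    }
                }
            }
        }
    }
    return out;
}

// Connected-component labeling of a 3D binary mask (BFS), 6- or
// 26-connectivity. Returns integer labels, 0 for background; labels are
// assigned in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector label_components3d_cpp(LogicalVector mask, IntegerVector dims,
                                     int connectivity) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    IntegerVector labels(n);  // zero-initialized
    // neighbor offsets
    std::vector<int> dz, dy, dx;
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                if (connectivity == 6 &&
                    std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
                dz.push_back(a); dy.push_back(b); dx.push_back(c);
            }
    const int noff = (int)dz.size();
    std::vector<R_xlen_t> queue;
    int next_label = 0;
    for (R_xlen_t idx = 0; idx < n; ++idx) {
        if (!mask[idx] || labels[idx] != 0) continue;
        ++next_label;
        labels[idx] = next_label;
        queue.clear();
        queue.push_back(idx);
        while (!queue.empty()) {
            R_xlen_t cur = queue.back();
            queue.pop_back();
            int i = (int)(cur % nz);
            int rem = (int)(cur / nz);
            int j = rem % ny;
            int k = rem / ny;
            for (int o = 0; o < noff; ++o) {
                int ii = i + dz[o], jj = j + dy[o], kk = k + dx[o];
                if (ii < 0 || ii >= nz || jj < 0 || jj >= ny ||
                    kk < 0 || kk >= nx) continue;
                R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
                if (mask[nb] && labels[nb] == 0) {
                    labels[nb] = next_label;
                    queue.push_back(nb);
                }
            }
        }
    }
    return labels;
}
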