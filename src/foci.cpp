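#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighbour offsets for 6/18/26-connectivity on a 3D grid.
// 6: faces; 18: faces + edges; 26: full neighbourhood.
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dx,
                              std::vector<int> &dy,
                              std::vector<int> &dz) {
    dx.clear(); dy.clear(); dz.clear();
    for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
            for (int cx = -1; cx <= 1; ++cx) {
                int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
                if (manh == 0) continue;
                if (connectivity == 6 && manh > 1) continue;
                if (connectivity == 18 && manh > 2) continue;
                dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
            }
}

// Flood-fill labelling of {voi & value >= thr} in linear scan order, so
// label ids are ordered by each component's first voxel (column-major).
// Components smaller than min_size are relabelled to background; surviving
// labels are compacted to 1..K preserving scan order. Returns K via *count.
static void label_core(const double *vol, const int *voi,
                       int nx, int ny, int nz,
                       double thr, int connectivity, int min_size,
                       int *labels, int *count) {
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const int nxy = nx * ny;
    std::vector<int> dx, dy, dz;
    neighbour_offsets(connectivity, dx, dy, dz);
    const int ndir = (int)dx.size();

    for (R_xlen_t i = 0; i < n; ++i) labels[i] = 0;

    std::vector<R_xlen_t> stack;
    std::vector<int> sizes;        // sizes[k-1] = voxel count of label k
    int next = 0;

    for (R_xlen_t start = 0; start < n; ++start) {
        if (labels[start] != 0) continue;
        if (!voi[start] || vol[start] < thr) continue;
        ++next;
        int sz = 0;
        stack.clear();
        stack.push_back(start);
        labels[start] = next;
        while (!stack.empty()) {
            R_xlen_t i = stack.back();
            stack.pop_back();
            ++sz;
            int z = (int)(i / nxy);
            int rem = (int)(i % nxy);
            int y = rem / nx;
            int x = rem % nx;
            for (int d = 0; d < ndir; ++d) {
                int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz)
                    continue;
                R_xlen_t j = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
                if (labels[j] != 0) continue;
                if (!voi[j] || vol[j] < thr) continue;
                labels[j] = next;
                stack.push_back(j);
            }
        }
        sizes.push_back(sz);
    }

    // Compact labels, dropping components below min_size.
    std::vector<int> remap(next + 1, 0);
    int kept = 0;
    for (int k = 1; k <= next; ++k)
        if (sizes[k - 1] >= min_size) remap[k] = ++kept;
    if (kept != next)
        for (R_xlen_t i = 0; i < n; ++i) labels[i] = remap[labels[i]];
    *count = kept;
}

// [[Rcpp::export(name = ".cc_label")]]
List cc_label(NumericVector vol, LogicalVector voi, IntegerVector dims,
              double thr, int connectivity, int min_size) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    IntegerVector labels((R_xlen_t)nx * ny * nz);
    int count = 0;
    label_core(REAL(vol), LOGICAL(voi), nx, ny, nz,
               thr, connectivity, min_size, INTEGER(labels), &count);
    return List::create(_["labels"] = labels, _["count"] = count);
}

// Focus counts for a whole vector of thresholds (one labelling pass each;
// the label array is reused as scratch and discarded).
// [[Rcpp::export(name = ".nuf_sweep")]]
IntegerVector nuf_sweep(NumericVector vol, LogicalVector voi,
                        IntegerVector dims, NumericVector thresholds,
                        int connectivity, int min_size) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<int> labels((size_t)nx * ny * nz);
    IntegerVector out(thresholds.size());
    for (R_xlen_t t = 0; t < thresholds.size(); ++t) {
        int count = 0;
        label_core(REAL(vol), LOGICAL(voi), nx, ny, nz,
                   thresholds[t], connectivity, min_size,
                   labels.data(), &count);
        out[t] = count;
    }
    return out;
}

// Separable Gaussian convolution along one axis, zero-padded boundary.
static void blur_axis(std::vector<double> &a, int nx, int ny, int nz,
                      int axis, double sigma) {
    if (sigma <= 0) return;
    int radius = (int)std::ceil(3.0 * sigma);
    std::vector<double> kern(2 * radius + 1);
    double s = 0.0;
    for (int k = -radius; k <= radius; ++k) {
        kern[k + radius] = std::exp(-0.5 * k * k / (sigma * sigma));
        s += kern[k + radius];
    }
    for (double &w : kern) w /= s;

    const int nxy = nx * ny;
    const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    const R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : nxy);
    std::vector<double> line(len);

    // iterate over all 1D lines along `axis`
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    for (int j2 = 0; j2 < n2; ++j2) {
        for (int j1 = 0; j1 < n1; ++j1) {
            R_xlen_t base;
            if (axis == 0)      base = (R_xlen_t)j2 * nxy + (R_xlen_t)j1 * nx;
            else if (axis == 1) base = (R_xlen_t)j2 * nxy + j1;
            else                base = (R_xlen_t)j2 * nx + j1;
            for (int i = 0; i < len; ++i) line[i] = a[base + stride * i];
            for (int i = 0; i < len; ++i) {
                double acc = 0.0;
                int k0 = std::max(-radius, -i);
                int k1 = std::min(radius, len - 1 - i);
                for (int k = k0; k <= k1; ++k)
                    acc += line[i + k] * kern[k + radius];
                a[base + stride * i] = acc;
            }
        }
    }
}

// [[Rcpp::export(name = ".gauss_blur3d")]]
NumericVector gauss_blur3d(NumericVector vol, IntegerVector dims,
                           NumericVector sigma_vox) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<double> a(REAL(vol), REAL(vol) + (R_xlen_t)nx * ny * nz);
    blur_axis(a, nx, ny, nz, 0, sigma_vox[0]);
    blur_axis(a, nx, ny, nz, 1, sigma_vox[1]);
    blur_axis(a, nx, ny, nz, 2, sigma_vox[2]);
    NumericVector out(a.begin(), a.end());
    return out;
}
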