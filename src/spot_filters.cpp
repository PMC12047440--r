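#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reflect index into [0, n)
static inline int reflect(int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - i - 1;
    }
    return i;
}

// Separable Gaussian convolution along one axis of a 3D array stored
// column-major with dim (n0, n1, n2); axis in {0,1,2}. For axes 1 and 2
// the kernel taps are applied as contiguous vector updates over the
// fastest (z) dimension to stay memory-bandwidth friendly.
static void convolveAxis(std::vector<double> &src, std::vector<double> &dst,
                         int n0, int n1, int n2, int axis,
                         const std::vector<double> &k) {
    int r = ((int)k.size() - 1) / 2;
    if (axis == 0) {
        for (int x = 0; x < n2; ++x)
            for (int y = 0; y < n1; ++y) {
                size_t base = (size_t)n0 * (y + (size_t)n1 * x);
                for (int z = 0; z < n0; ++z) {
                    double acc = 0.0;
                    for (int t = -r; t <= r; ++t)
                        acc += k[t + r] * src[base + reflect(z + t, n0)];
                    dst[base + z] = acc;
                }
            }
    } else if (axis == 1) {
        for (int x = 0; x < n2; ++x)
            for (int y = 0; y < n1; ++y) {
                double *out = &dst[(size_t)n0 * (y + (size_t)n1 * x)];
                for (int z = 0; z < n0; ++z) out[z] = 0.0;
                for (int t = -r; t <= r; ++t) {
                    const double *in = &src[(size_t)n0 *
                        (reflect(y + t, n1) + (size_t)n1 * x)];
                    double w = k[t + r];
                    for (int z = 0; z < n0; ++z) out[z] += w * in[z];
                }
            }
    } else {
        size_t plane = (size_t)n0 * n1;
        for (int x = 0; x < n2; ++x) {
            double *out = &dst[plane * x];
            for (size_t i = 0; i < plane; ++i) out[i] = 0.0;
            for (int t = -r; t <= r; ++t) {
                const double *in = &src[plane * reflect(x + t, n2)];
                double w = k[t + r];
                for (size_t i = 0; i < plane; ++i) out[i] += w * in[i];
            }
        }
    }
}

static std::vector<double> gaussKernel(double sigma) {
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * r + 1);
    double s = 0.0;
    for (int t = -r; t <= r; ++t) {
        k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
        s += k[t + r];
    }
    for (auto &v : k) v /= s;
    return k;
}

// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d(NumericVector img, IntegerVector dims, double sigma) {
    int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    std::vector<double> a(img.begin(), img.end()), b(a.size());
    std::vector<double> k = gaussKernel(sigma);
    convolveAxis(a, b, n0, n1, n2, 0, k);
    convolveAxis(b, a, n0, n1, n2, 1, k);
    convolveAxis(a, b, n0, n1, n2, 2, k);
    NumericVector out(b.begin(), b.end());
    out.attr("dim") = dims;
    return out;
}

// Scale-normalized negative Laplacian of Gaussian: bright blobs give
// positive peaks. resp = -sigma^2 * Laplacian(G_sigma * img).
// [[Rcpp::export(name = ".logResponse3d")]]
NumericVector logResponse3d(NumericVector img, IntegerVector dims,
                            double sigma) {
    NumericVector sm = gauss3d(img, dims, sigma);
    int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    NumericVector out(sm.size());
    double s2 = sigma * sigma;
    for (int x = 0; x < n2; ++x) {
        for (int y = 0; y < n1; ++y) {
            for (int z = 0; z < n0; ++z) {
                size_t idx = (size_t)z + (size_t)n0 * (y + (size_t)n1 * x);
                double c = sm[idx];
                double lap = 0.0;
                lap += sm[(size_t)reflect(z - 1, n0) + (size_t)n0 * (y + (size_t)n1 * x)] - c;
                lap += sm[(size_t)reflect(z + 1, n0) + (size_t)n0 * (y + (size_t)n1 * x)] - c;
                lap += sm[(size_t)z + (size_t)n0 * (reflect(y - 1, n1) + (size_t)n1 * x)] - c;
                lap += sm[(size_t)z + (size_t)n0 * (reflect(y + 1, n1) + (size_t)n1 * x)] - c;
                lap += sm[(size_t)z + (size_t)n0 * (y + (size_t)n1 * reflect(x - 1, n2))] - c;
                lap += sm[(size_t)z + (size_t)n0 * (y + (size_t)n1 * reflect(x + 1, n2))] - c;
                out[idx] = -s2 * lap;
            }
        }
    }
    out.attr("dim") = dims;
    return out;
}

// 26-connected local maxima above a threshold. Returns a matrix with
// columns (z, y, x, value), 1-based coordinates.
// [[Rcpp::export(name = ".localMaxima3d")]]
NumericMatrix localMaxima3d(NumericVector resp, IntegerVector dims,
                            double threshold) {
    int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    std::vector<double> rows;
    for (int x = 0; x < n2; ++x) {
        for (int y = 0; y < n1; ++y) {
            for (int z = 0; z < n0; ++z) {
                size_t idx = (size_t)z + (size_t)n0 * (y + (size_t)n1 * x);
                double v = resp[idx];
                if (v <= threshold) continue;
                bool ismax = true;
                for (int dx = -1; dx <= 1 && ismax; ++dx)
                    for (int dy = -1; dy <= 1 && ismax; ++dy)
                        for (int dz = -1; dz <= 1; ++dz) {
                            if (!dx && !dy && !dz) continue;
                            int zz = z + dz, yy = y + dy, xx = x + dx;
                            if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 ||
                                xx < 0 || xx >= n2)
                                continue;
                            double w = resp[(size_t)zz +
                                (size_t)n0 * (yy + (size_t)n1 * xx)];
                            if (w > v) { ismax = false; break; }
                        }
                if (ismax) {
                    rows.push_back(z + 1.0);
                    rows.push_back(y + 1.0);
                    rows.push_back(x + 1.0);
                    rows.push_back(v);
                }
            }
        }
    }
    int nr = rows.size() / 4;
    NumericMatrix out(nr, 4);
    for (int i = 0; i < nr; ++i)
        for (int j = 0; j < 4; ++j) out(i, j) = rows[4 * i + j];
    colnames(out) = CharacterVector::create("z", "y", "x", "value");
    return out;
}
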