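#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <functional>
#include <climits>
#include <map>
using namespace Rcpp;

// 13 unique 3D directions (half of the 26-neighbourhood, no opposites)
static const int D13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int at(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + (long)ny * z);
}

// Grey-level co-occurrence counts, symmetric, summed over the 13 directions.
// lev: discretised grey levels, 0 = outside ROI.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector lev, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix P(ng, ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = lev[at(x, y, z, nx, ny)];
                if (li == 0) continue;
                for (int d = 0; d < 13; ++d) {
                    int x2 = x + D13[d][0], y2 = y + D13[d][1], z2 = z + D13[d][2];
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                        continue;
                    int lj = lev[at(x2, y2, z2, nx, ny)];
                    if (lj == 0) continue;
                    P(li - 1, lj - 1) += 1.0;
                    P(lj - 1, li - 1) += 1.0;
                }
            }
    return P;
}

// Run-length counts summed over the 13 directions. Columns are run lengths.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector lev, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int maxlen = std::max(nx, std::max(ny, nz));
    NumericMatrix P(ng, maxlen);
    for (int d = 0; d < 13; ++d) {
        int dx = D13[d][0], dy = D13[d][1], dz = D13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int li = lev[at(x, y, z, nx, ny)];
                    if (li == 0) continue;
                    // run start: predecessor out of bounds / outside ROI / different level
                    int xp = x - dx, yp = y - dy, zp = z - dz;
                    if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
                        lev[at(xp, yp, zp, nx, ny)] == li)
                        continue;
                    int len = 1;
                    int xc = x + dx, yc = y + dy, zc = z + dz;
                    while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz &&
                           lev[at(xc, yc, zc, nx, ny)] == li) {
                        ++len;
                        xc += dx; yc += dy; zc += dz;
                    }
                    P(li - 1, len - 1) += 1.0;
                }
    }
    return P;
}

// Size-zone enumeration: 26-connected components of equal grey level.
// Returns a 2-column matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lev, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> zlev, zsize;
    std::queue<long> q;
    for (long i = 0; i < n; ++i) {
        if (lev[i] == 0 || seen[i]) continue;
        int li = lev[i];
        int size = 0;
        seen[i] = 1;
        q.push(i);
        while (!q.empty()) {
            long c = q.front(); q.pop();
            ++size;
            int x = c % nx, y = (c / nx) % ny, z = c / ((long)nx * ny);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                            continue;
                        long j = at(x2, y2, z2, nx, ny);
                        if (!seen[j] && lev[j] == li) {
                            seen[j] = 1;
                            q.push(j);
                        }
                    }
        }
        zlev.push_back(li);
        zsize.push_back(size);
    }
    IntegerMatrix out(zlev.size(), 2);
    for (size_t k = 0; k < zlev.size(); ++k) {
        out(k, 0) = zlev[k];
        out(k, 1) = zsize[k];
    }
    return out;
}

// Dependence counts: per ROI voxel, number of 26-neighbours (in ROI) whose
// level differs by at most alpha. Returns ng x 27 count matrix P(level, d+1).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dim, int ng, int alpha) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix P(ng, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = lev[at(x, y, z, nx, ny)];
                if (li == 0) continue;
                int dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                                z2 < 0 || z2 >= nz)
                                continue;
                            int lj = lev[at(x2, y2, z2, nx, ny)];
                            if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
                        }
                P(li - 1, dep) += 1.0;
            }
    return P;
}

// Neighbourhood grey-tone difference: per level i, voxel count n_i and
// s_i = sum over voxels of |i - mean(valid 26-neighbour levels)|.
// Returns ng x 2 matrix (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix out(ng, 2);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = lev[at(x, y, z, nx, ny)];
                if (li == 0) continue;
                double s = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                                z2 < 0 || z2 >= nz)
                                continue;
                            int lj = lev[at(x2, y2, z2, nx, ny)];
                            if (lj != 0) { s += lj; ++cnt; }
                        }
                out(li - 1, 0) += 1.0;
                if (cnt > 0) out(li - 1, 1) += std::fabs(li - s / cnt);
            }
    return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), in place.
static void dt1d(std::vector<double> &f, double w2) {
    int n = f.size();
    std::vector<double> d(n);
    std::vector<int> v(n);
    std::vector<double> zb(n + 1);
    int k = 0;
    v[0] = 0;
    zb[0] = -INFINITY;
    zb[1] = INFINITY;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                (2.0 * w2 * q - 2.0 * w2 * v[k]);
            if (s <= zb[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        zb[k] = s;
        zb[k + 1] = INFINITY;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (zb[k + 1] < q) ++k;
        double dq = (double)q - v[k];
        d[q] = w2 * dq * dq + f[v[k]];
    }
    f = d;
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel, anisotropic.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    NumericVector D(n);
    const double BIG = 1e30;
    for (long i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : BIG;
    std::vector<double> line;
    // x pass
    line.resize(nx);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) line[x] = D[at(x, y, z, nx, ny)];
            dt1d(line, spacing[0] * spacing[0]);
            for (int x = 0; x < nx; ++x) D[at(x, y, z, nx, ny)] = line[x];
        }
    // y pass
    line.resize(ny);
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            for (int y = 0; y < ny; ++y) line[y] = D[at(x, y, z, nx, ny)];
            dt1d(line, spacing[1] * spacing[1]);
            for (int y = 0; y < ny; ++y) D[at(x, y, z, nx, ny)] = line[y];
        }
    // z pass
    line.resize(nz);
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            for (int z = 0; z < nz; ++z) line[z] = D[at(x, y, z, nx, ny)];
            dt1d(line, spacing[2] * spacing[2]);
            for (int z = 0; z < nz; ++z) D[at(x, y, z, nx, ny)] = line[z];
        }
    return D;
}

// 26-connected components of equal nonzero value. Returns component labels
// (1..ncomp, 0 outside).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector lab, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    IntegerVector out(n, 0);
    std::queue<long> q;
    int comp = 0;
    for (long i = 0; i < n; ++i) {
        if (lab[i] == 0 || out[i] != 0) continue;
        ++comp;
        int li = lab[i];
        out[i] = comp;
        q.push(i);
        while (!q.empty()) {
            long c = q.front(); q.pop();
            int x = c % nx, y = (c / nx) % ny, z = c / ((long)nx * ny);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                            z2 < 0 || z2 >= nz)
                            continue;
                        long j = at(x2, y2, z2, nx, ny);
                        if (out[j] == 0 && lab[j] == li) {
                            out[j] = comp;
                            q.push(j);
                        }
                    }
        }
    }
    return out;
}

// SLIC assignment step: for each cluster, scan a window around its spatial
// centre and keep the best (lowest-D) cluster per voxel.
// feat: nvox_total x nchan matrix flattened? Kept simple: channels passed as
// a list is awkward from C++; instead the full per-voxel channel matrix is
// passed (rows = voxels in the full grid order, only ROI rows used).
// [[Rcpp::export]]
List cpp_slic_assign(NumericMatrix chan, LogicalVector roi, IntegerVector dim,
                     NumericVector spacing, NumericMatrix centers,
                     double S, double m, int iters) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    int K = centers.nrow();
    int nc = chan.ncol();
    // centers: columns = nc channel means, then x,y,z in mm
    NumericMatrix ctr = clone(centers);
    IntegerVector assign(n, 0);
    NumericVector best(n);
    double m2 = m * m, S2 = S * S;
    for (int it = 0; it < iters; ++it) {
        for (long i = 0; i < n; ++i) best[i] = R_PosInf;
        for (long i = 0; i < n; ++i) assign[i] = 0;
        for (int k = 0; k < K; ++k) {
            double cx = ctr(k, nc), cy = ctr(k, nc + 1), cz = ctr(k, nc + 2);
            int x0 = std::max(0, (int)std::floor((cx - 2 * S) / spacing[0]));
            int x1 = std::min(nx - 1, (int)std::ceil((cx + 2 * S) / spacing[0]));
            int y0 = std::max(0, (int)std::floor((cy - 2 * S) / spacing[1]));
            int y1 = std::min(ny - 1, (int)std::ceil((cy + 2 * S) / spacing[1]));
            int z0 = std::max(0, (int)std::floor((cz - 2 * S) / spacing[2]));
            int z1 = std::min(nz - 1, (int)std::ceil((cz + 2 * S) / spacing[2]));
            for (int z = z0; z <= z1; ++z)
                for (int y = y0; y <= y1; ++y)
                    for (int x = x0; x <= x1; ++x) {
                        long i = at(x, y, z, nx, ny);
                        if (!roi[i]) continue;
                        double dc2 = 0.0;
                        for (int c = 0; c < nc; ++c) {
                            double d = chan(i, c) - ctr(k, c);
                            dc2 += d * d;
                        }
                        double dxs = x * spacing[0] - cx;
                        double dys = y * spacing[1] - cy;
                        double dzs = z * spacing[2] - cz;
                        double ds2 = dxs * dxs + dys * dys + dzs * dzs;
                        double D = dc2 + m2 * ds2 / S2;
                        if (D < best[i]) {
                            best[i] = D;
                            assign[i] = k + 1;
                        }
                    }
        }
        // any ROI voxel missed by every window: attach to nearest centre spatially
        for (long i = 0; i < n; ++i) {
            if (!roi[i] || assign[i] != 0) continue;
            int x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
            double bd = R_PosInf;
            int bk = 1;
            for (int k = 0; k < K; ++k) {
                double dxs = x * spacing[0] - ctr(k, nc);
                double dys = y * spacing[1] - ctr(k, nc + 1);
                double dzs = z * spacing[2] - ctr(k, nc + 2);
                double ds2 = dxs * dxs + dys * dys + dzs * dzs;
                if (ds2 < bd) { bd = ds2; bk = k + 1; }
            }
            assign[i] = bk;
        }
        // update centres
        std::vector<double> acc((nc + 3) * K, 0.0);
        std::vector<long> cnt(K, 0);
        for (long i = 0; i < n; ++i) {
            if (!roi[i]) continue;
            int k = assign[i] - 1;
            ++cnt[k];
            int x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
            for (int c = 0; c < nc; ++c) acc[k * (nc + 3) + c] += chan(i, c);
            acc[k * (nc + 3) + nc] += x * spacing[0];
            acc[k * (nc + 3) + nc + 1] += y * spacing[1];
            acc[k * (nc + 3) + nc + 2] += z * spacing[2];
        }
        for (int k = 0; k < K; ++k) {
            if (cnt[k] == 0) continue;  // empty cluster keeps its old centre
            for (int c = 0; c < nc + 3; ++c)
                ctr(k, c) = acc[k * (nc + 3) + c] / cnt[k];
        }
    }
    return List::create(_["labels"] = assign, _["centers"] = ctr);
}

// Merge connected components (labels 1..M, 0 outside) down to exactly K by
// repeatedly folding the smallest component into its face-adjacent
// neighbour with the largest shared boundary (ties: lower id). Components
// with no neighbour (disconnected region islands) are skipped. Returns
// labels compacted to 1..K' (K' == K on success) ordered by first voxel in
// array order.
// [[Rcpp::export]]
IntegerVector cpp_merge_to_k(IntegerVector comp, IntegerVector dim, int K) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    int M = 0;
    for (long i = 0; i < n; ++i) M = std::max(M, (int)comp[i]);
    std::vector<int> parent(M + 1);
    for (int i = 0; i <= M; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int a) {
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        return a;
    };
    std::vector<long> size(M + 1, 0);
    std::vector<std::map<int, int>> adj(M + 1);
    for (long i = 0; i < n; ++i) {
        int a = comp[i];
        if (a == 0) continue;
        ++size[a];
        int x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
        const int offs[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int d = 0; d < 3; ++d) {
            int x2 = x + offs[d][0], y2 = y + offs[d][1], z2 = z + offs[d][2];
            if (x2 >= nx || y2 >= ny || z2 >= nz) continue;
            int b = comp[x2 + nx * (y2 + (long)ny * z2)];
            if (b == 0 || b == a) continue;
            adj[a][b] += 1;
            adj[b][a] += 1;
        }
    }
    std::vector<char> active(M + 1, 0);
    int ncomp = 0;
    for (int i = 1; i <= M; ++i)
        if (size[i] > 0) { active[i] = 1; ++ncomp; }
    std::vector<char> stuck(M + 1, 0);
    while (ncomp > K) {
        int small = -1;
        long smin = LONG_MAX;
        for (int i = 1; i <= M; ++i)
            if (active[i] && !stuck[i] && size[i] < smin) { smin = size[i]; small = i; }
        if (small < 0) break;  // everything unmergeable
        int best = -1, bf = -1;
        for (std::map<int, int>::iterator it = adj[small].begin();
             it != adj[small].end(); ++it) {
            int b = find(it->first);
            if (b == small || !active[b]) continue;
            if (it->second > bf || (it->second == bf && b < best)) {
                bf = it->second; best = b;
            }
        }
        if (best < 0) { stuck[small] = 1; continue; }
        // merge small into best
        parent[small] = best;
        size[best] += size[small];
        active[small] = 0;
        for (std::map<int, int>::iterator it = adj[small].begin();
             it != adj[small].end(); ++it) {
            int b = find(it->first);
            if (b == best || !active[b]) continue;
            adj[best][b] += it->second;
            adj[b][best] += it->second;  // approximate symmetric update
        }
        --ncomp;
    }
    // compact labels by first-voxel order
    std::vector<int> remap(M + 1, 0);
    int next = 0;
    IntegerVector out(n, 0);
    for (long i = 0; i < n; ++i) {
        if (comp[i] == 0) continue;
        int r = find(comp[i]);
        if (remap[r] == 0) remap[r] = ++next;
        out[i] = remap[r];
    }
    return out;
}
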