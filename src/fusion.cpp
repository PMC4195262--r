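#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Patch-based label fusion kernels. Grids are column-major (R order),
// 0-based inside C++. Patches are cubic neighbourhoods clamped to the
// grid on the target side; a candidate centre is admitted only if every
// offset the target patch uses is in-bounds at the candidate too, so the
// two patch vectors always align (no padding is ever invented).

struct Grid { int nx, ny, nz; };

static inline int idx3(int x, int y, int z, const Grid &g) {
    return x + g.nx * (y + g.ny * z);
}

struct Cand {
    int x, y, z, s;
    double d2, ss, lab;
};

// structural similarity between two patches from their means and sds,
// with the degenerate conventions: a ratio term is 1 when both of its
// arguments are 0 and 0 when exactly one is.
static inline double ssTerm(double a, double b) {
    if (a == 0.0 && b == 0.0) return 1.0;
    if (a == 0.0 || b == 0.0) return 0.0;
    return 2.0 * a * b / (a * a + b * b);
}

// target patch description: per-axis offset ranges, the patch values,
// and the patch rows (contiguous x-runs) used to walk candidate patches
// cache-efficiently in the same x-fastest order
struct TargetPatch {
    int lox, hix, loy, hiy, loz, hiz;
    std::vector<int> rowOff;     // linear offset of each row's first voxel
    int rowLen;
    std::vector<double> vals;
    double mu, sd;
};

static void makeTargetPatch(const double *sub, const Grid &g,
                            int tx, int ty, int tz, int r, TargetPatch &tp) {
    tp.lox = std::max(-r, -tx); tp.hix = std::min(r, g.nx - 1 - tx);
    tp.loy = std::max(-r, -ty); tp.hiy = std::min(r, g.ny - 1 - ty);
    tp.loz = std::max(-r, -tz); tp.hiz = std::min(r, g.nz - 1 - tz);
    tp.rowLen = tp.hix - tp.lox + 1;
    tp.rowOff.clear(); tp.vals.clear();
    const int base = idx3(tx, ty, tz, g);
    double s1 = 0.0;
    for (int dz = tp.loz; dz <= tp.hiz; ++dz)
        for (int dy = tp.loy; dy <= tp.hiy; ++dy) {
            const int off = tp.lox + g.nx * (dy + g.ny * dz);
            tp.rowOff.push_back(off);
            const double *p = sub + base + off;
            for (int k = 0; k < tp.rowLen; ++k) {
                tp.vals.push_back(p[k]);
                s1 += p[k];
            }
        }
    const double n = (double)tp.vals.size();
    tp.mu = s1 / n;
    double s2 = 0.0;
    for (size_t k = 0; k < tp.vals.size(); ++k) {
        double d = tp.vals[k] - tp.mu;
        s2 += d * d;
    }
    tp.sd = std::sqrt(s2 / n);
}

// all candidates for one target location: every position inside the
// search box of each template whose patch aligns with the target's
static void collectCandidates(const TargetPatch &tp,
                              const double *tmpl, const double *labs,
                              int ntmpl, const Grid &g,
                              int tx, int ty, int tz, int sr,
                              std::vector<Cand> &out,
                              std::vector<double> &buf) {
    out.clear();
    const int nvox = g.nx * g.ny * g.nz;
    const int np = (int)tp.vals.size();
    const double n = (double)np;
    buf.resize(np);
    for (int s = 0; s < ntmpl; ++s) {
        const double *ts = tmpl + (size_t)s * nvox;
        const double *ls = labs + (size_t)s * nvox;
        for (int cz = tz - sr; cz <= tz + sr; ++cz) {
            if (cz + tp.loz < 0 || cz + tp.hiz >= g.nz) continue;
            for (int cy = ty - sr; cy <= ty + sr; ++cy) {
                if (cy + tp.loy < 0 || cy + tp.hiy >= g.ny) continue;
                for (int cx = tx - sr; cx <= tx + sr; ++cx) {
                    if (cx + tp.lox < 0 || cx + tp.hix >= g.nx) continue;
                    const int cbase = idx3(cx, cy, cz, g);
                    double s1 = 0.0, sd2 = 0.0;
                    int idx = 0;
                    for (size_t rw = 0; rw < tp.rowOff.size(); ++rw) {
                        const double *p = ts + cbase + tp.rowOff[rw];
                        for (int k = 0; k < tp.rowLen; ++k, ++idx) {
                            const double v = p[k];
                            buf[idx] = v;
                            s1 += v;
                            const double dd = v - tp.vals[idx];
                            sd2 += dd * dd;
                        }
                    }
                    const double mu = s1 / n;
                    double s2 = 0.0;
                    for (int k = 0; k < np; ++k) {
                        const double d = buf[k] - mu;
                        s2 += d * d;
                    }
                    const double sd = std::sqrt(s2 / n);
                    Cand c;
                    c.x = cx; c.y = cy; c.z = cz; c.s = s;
                    c.d2 = sd2 / n;
                    c.ss = ssTerm(tp.mu, mu) * ssTerm(tp.sd, sd);
                    c.lab = ls[cbase];
                    out.push_back(c);
                }
            }
        }
    }
}

static inline double adaptiveH(const std::vector<Cand> &cands,
                               double lambdaH, double epsilonH) {
    double mn = R_PosInf;
    for (size_t k = 0; k < cands.size(); ++k)
        if (cands[k].d2 < mn) mn = cands[k].d2;
    return lambdaH * mn + epsilonH;
}

static inline double weightOf(const Cand &c, int tx, int ty, int tz,
                              double h, double sigmaD, double ssThreshold,
                              const double *vs, bool classical) {
    if (c.ss < ssThreshold) return 0.0;
    if (classical) return std::exp(-c.d2 / (h * h));
    const double ddx = (c.x - tx) * vs[0];
    const double ddy = (c.y - ty) * vs[1];
    const double ddz = (c.z - tz) * vs[2];
    const double dist = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    return std::exp(-(dist / sigmaD + c.d2 / h));
}

// majority of candidate centre labels; ties break to 0
static inline double majorityLabel(const std::vector<Cand> &cands) {
    int ones = 0, zeros = 0;
    for (size_t k = 0; k < cands.size(); ++k) {
        if (cands[k].lab > 0.5) ++ones; else ++zeros;
    }
    return ones > zeros ? 1.0 : 0.0;
}

// [[Rcpp::export]]
List cppVoxelwiseFusion(NumericVector subject, IntegerVector sdim,
                        NumericVector tmpl, NumericVector labs, int ntmpl,
                        IntegerVector roi, int patchRadius, int searchRadius,
                        double lambdaH, double epsilonH, double sigmaD,
                        double ssThreshold, NumericVector voxelSize,
                        bool classical) {
    Grid g; g.nx = sdim[0]; g.ny = sdim[1]; g.nz = sdim[2];
    const int nvox = g.nx * g.ny * g.nz;
    NumericVector votes(nvox), mass(nvox);
    IntegerVector processed(nvox), fallback(nvox);
    const double *sub = REAL(subject);
    const double *tm = REAL(tmpl);
    const double *lb = REAL(labs);
    const double *vs = REAL(voxelSize);
    TargetPatch tp;
    std::vector<Cand> cands;
    std::vector<double> buf;
    for (int tz = 0; tz < g.nz; ++tz)
        for (int ty = 0; ty < g.ny; ++ty)
            for (int tx = 0; tx < g.nx; ++tx) {
                const int ti = idx3(tx, ty, tz, g);
                if (!roi[ti]) continue;
                makeTargetPatch(sub, g, tx, ty, tz, patchRadius, tp);
                collectCandidates(tp, tm, lb, ntmpl, g, tx, ty, tz,
                                  searchRadius, cands, buf);
                const double h = adaptiveH(cands, lambdaH, epsilonH);
                double num = 0.0, den = 0.0;
                for (size_t k = 0; k < cands.size(); ++k) {
                    const double w = weightOf(cands[k], tx, ty, tz, h,
                                              sigmaD, ssThreshold, vs,
                                              classical);
                    num += w * cands[k].lab;
                    den += w;
                }
                processed[ti] = 1;
                if (den > 0.0) {
                    votes[ti] = num / den;
                    mass[ti] = den;
                } else {
                    votes[ti] = majorityLabel(cands);
                    fallback[ti] = 1;
                }
            }
    return List::create(_["votes"] = votes, _["mass"] = mass,
                        _["processed"] = processed, _["fallback"] = fallback);
}

// [[Rcpp::export]]
List cppBlockwiseFusion(NumericVector subject, IntegerVector sdim,
                        NumericVector tmpl, NumericVector labs, int ntmpl,
                        IntegerVector roi,
                        IntegerVector cxs, IntegerVector cys,
                        IntegerVector czs,
                        int patchRadius, int searchRadius, int blockRadius,
                        double lambdaH, double epsilonH, double sigmaD,
                        double ssThreshold, NumericVector voxelSize,
                        bool classical) {
    Grid g; g.nx = sdim[0]; g.ny = sdim[1]; g.nz = sdim[2];
    const int nvox = g.nx * g.ny * g.nz;
    NumericVector votes(nvox), mass(nvox), num(nvox);
    IntegerVector processed(nvox), fallback(nvox);
    const double *sub = REAL(subject);
    const double *tm = REAL(tmpl);
    const double *lb = REAL(labs);
    const double *vs = REAL(voxelSize);
    const int b = blockRadius;
    TargetPatch tp;
    std::vector<Cand> cands;
    std::vector<double> buf;
    for (int iz = 0; iz < czs.size(); ++iz)
        for (int iy = 0; iy < cys.size(); ++iy)
            for (int ix = 0; ix < cxs.size(); ++ix) {
                const int tx = cxs[ix], ty = cys[iy], tz = czs[iz];
                // skip blocks that touch no roi voxel
                bool touches = false;
                for (int dz = -b; dz <= b && !touches; ++dz) {
                    const int pz = tz + dz;
                    if (pz < 0 || pz >= g.nz) continue;
                    for (int dy = -b; dy <= b && !touches; ++dy) {
                        const int py = ty + dy;
                        if (py < 0 || py >= g.ny) continue;
                        for (int dx = -b; dx <= b; ++dx) {
                            const int px = tx + dx;
                            if (px < 0 || px >= g.nx) continue;
                            if (roi[idx3(px, py, pz, g)]) { touches = true; break; }
                        }
                    }
                }
                if (!touches) continue;
                makeTargetPatch(sub, g, tx, ty, tz, patchRadius, tp);
                collectCandidates(tp, tm, lb, ntmpl, g, tx, ty, tz,
                                  searchRadius, cands, buf);
                const double h = adaptiveH(cands, lambdaH, epsilonH);
                for (size_t k = 0; k < cands.size(); ++k) {
                    const Cand &c = cands[k];
                    const double w = weightOf(c, tx, ty, tz, h, sigmaD,
                                              ssThreshold, vs, classical);
                    if (w <= 0.0) continue;
                    const int snv = c.s * nvox; // label block of this template
                    for (int dz = -b; dz <= b; ++dz) {
                        const int pz = tz + dz, qz = c.z + dz;
                        if (pz < 0 || pz >= g.nz || qz < 0 || qz >= g.nz)
                            continue;
                        for (int dy = -b; dy <= b; ++dy) {
                            const int py = ty + dy, qy = c.y + dy;
                            if (py < 0 || py >= g.ny || qy < 0 || qy >= g.ny)
                                continue;
                            for (int dx = -b; dx <= b; ++dx) {
                                const int px = tx + dx, qx = c.x + dx;
                                if (px < 0 || px >= g.nx ||
                                    qx < 0 || qx >= g.nx) continue;
                                const int pi = idx3(px, py, pz, g);
                                if (!roi[pi]) continue;
                                num[pi] += w * lb[snv + idx3(qx, qy, qz, g)];
                                mass[pi] += w;
                            }
                        }
                    }
                }
            }
    // votes where mass accumulated; majority-vote fallback elsewhere in roi
    for (int tz = 0; tz < g.nz; ++tz)
        for (int ty = 0; ty < g.ny; ++ty)
            for (int tx = 0; tx < g.nx; ++tx) {
                const int ti = idx3(tx, ty, tz, g);
                if (!roi[ti]) continue;
                processed[ti] = 1;
                if (mass[ti] > 0.0) {
                    votes[ti] = num[ti] / mass[ti];
                } else {
                    makeTargetPatch(sub, g, tx, ty, tz, patchRadius, tp);
                    collectCandidates(tp, tm, lb, ntmpl, g, tx, ty, tz,
                                      searchRadius, cands, buf);
                    votes[ti] = majorityLabel(cands);
                    fallback[ti] = 1;
                }
            }
    return List::create(_["votes"] = votes, _["mass"] = mass,
                        _["processed"] = processed, _["fallback"] = fallback);
}
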