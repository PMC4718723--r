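#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Exhaustive helix-to-rod assignment search.
//
// `coords` holds precomputed CA coordinates for every candidate placement of
// every segment: for segment h on rod r with direction d, the block starting
// at off[h + K*(r + n_rods*d)] contains n_reg*n_roll placements laid out as
// ((reg * n_roll + roll) * len_h + atom) * 3 + xyz.
//
// Each geometric assignment (injective rod tuple x direction word) is scored
// by a deterministic forward sweep: all segments start at the central
// register / first roll, then each segment in order is moved to the
// (register, roll) grid point maximising the number of satisfied pairs, ties
// towards smaller total distance, then smaller register, then smaller roll.
//
// pairs: n x 4 integer matrix (sa, ia, sb, ib), 0-based. sb == -1 marks a
// pair against the fixed partner coordinates (row ib of partner_xyz).
// const_nsat / const_dist are contributions of resolvable pairs that do not
// involve any segment (e.g. partner-partner pairs).
//
// Returns a matrix with one row per assignment in enumeration order:
// [n_satisfied, total_distance, reg_idx_1..K, roll_idx_1..K].

static inline double pair_dist(const std::vector<const double*>& cur,
                               const int* pr,
                               const NumericMatrix& partner) {
  const double* a = cur[pr[0]] + 3 * pr[1];
  double bx, by, bz;
  if (pr[2] >= 0) {
    const double* b = cur[pr[2]] + 3 * pr[3];
    bx = b[0]; by = b[1]; bz = b[2];
  } else {
    bx = partner(pr[3], 0); by = partner(pr[3], 1); bz = partner(pr[3], 2);
  }
  double dx = a[0] - bx, dy = a[1] - by, dz = a[2] - bz;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
NumericMatrix cpp_search_exhaustive(NumericVector coords, IntegerVector off,
                                    IntegerVector seg_len, int n_rods,
                                    int n_reg, int n_roll,
                                    IntegerMatrix pairs,
                                    NumericMatrix partner_xyz,
                                    double threshold,
                                    double const_nsat, double const_dist,
                                    int zero_reg, int zero_roll) {
  const int K = seg_len.size();
  const int n_pairs = pairs.nrow();
  const double* C = coords.begin();

  // flatten pair rows for cache-friendly access
  std::vector<int> P(4 * n_pairs);
  for (int p = 0; p < n_pairs; ++p)
    for (int c = 0; c < 4; ++c) P[4 * p + c] = pairs(p, c);

  // pairs grouped by involved segment
  std::vector<std::vector<int> > by_seg(K);
  for (int p = 0; p < n_pairs; ++p) {
    int sa = P[4 * p], sb = P[4 * p + 2];
    by_seg[sa].push_back(p);
    if (sb >= 0 && sb != sa) by_seg[sb].push_back(p);
  }

  long n_assign = 1;
  for (int i = 0; i < K; ++i) n_assign *= (n_rods - i);
  n_assign <<= K;
  NumericMatrix out(n_assign, 2 + 2 * K);

  std::vector<int> tuple(K), reg_i(K), roll_i(K);
  std::vector<bool> used(n_rods, false);
  std::vector<const double*> base_ptr(K), cur(K);
  long row = 0;

  // placement pointer for segment h at (reg, roll) given its block base
  auto plc = [&](int h, const double* base, int reg, int roll) {
    return base + (long)((reg * n_roll + roll)) * seg_len[h] * 3;
  };

  const double thr2 = threshold * threshold;
  // scratch for the fixed-endpoint view of one segment's pairs
  std::vector<double> fx; std::vector<int> fa;
  const int n_cand = n_reg * n_roll;
  std::vector<int> cand_n(n_cand);

  std::function<void(int)> rec = [&](int depth) {
    if (depth == K) {
      long n_dir = 1L << K;
      for (long m = 0; m < n_dir; ++m) {
        for (int h = 0; h < K; ++h) {
          int d = (m >> h) & 1L;
          base_ptr[h] = C + off[h + K * (tuple[h] + n_rods * d)];
          reg_i[h] = zero_reg;
          roll_i[h] = zero_roll;
          cur[h] = plc(h, base_ptr[h], zero_reg, zero_roll);
        }
        double tot_nsat = const_nsat, tot_dist = const_dist;
        for (int p = 0; p < n_pairs; ++p) {
          double d = pair_dist(cur, &P[4 * p], partner_xyz);
          tot_dist += d;
          if (d <= threshold) tot_nsat += 1;
        }
        for (int h = 0; h < K; ++h) {
          const std::vector<int>& ph = by_seg[h];
          const int np = ph.size();
          if (np == 0) continue;
          // freeze the non-h endpoint of each pair for this sweep
          fx.resize(3 * np); fa.resize(np);
          for (int q = 0; q < np; ++q) {
            const int* pr = &P[4 * ph[q]];
            int ia; double bx, by, bz;
            if (pr[0] == h) {
              ia = pr[1];
              if (pr[2] >= 0) {
                const double* b = cur[pr[2]] + 3 * pr[3];
                bx = b[0]; by = b[1]; bz = b[2];
              } else {
                bx = partner_xyz(pr[3], 0); by = partner_xyz(pr[3], 1);
                bz = partner_xyz(pr[3], 2);
              }
            } else {
              ia = pr[3];
              const double* b = cur[pr[0]] + 3 * pr[1];
              bx = b[0]; by = b[1]; bz = b[2];
            }
            fa[q] = 3 * ia;
            fx[3 * q] = bx; fx[3 * q + 1] = by; fx[3 * q + 2] = bz;
          }
          // current contribution of h's pairs
          double h_nsat = 0, h_dist = 0;
          {
            const double* a0 = cur[h];
            for (int q = 0; q < np; ++q) {
              const double* a = a0 + fa[q];
              double dx = a[0] - fx[3 * q], dy = a[1] - fx[3 * q + 1],
                     dz = a[2] - fx[3 * q + 2];
              double d2 = dx * dx + dy * dy + dz * dz;
              h_dist += std::sqrt(d2);
              if (d2 <= thr2) h_nsat += 1;
            }
          }
          double base_nsat = tot_nsat - h_nsat, base_dist = tot_dist - h_dist;
          const long stride = (long)seg_len[h] * 3;
          // pass 1: satisfied-pair counts on squared distances (no sqrt)
          int best_n = -1;
          for (int cnd = 0; cnd < n_cand; ++cnd) {
            const double* a0 = base_ptr[h] + cnd * stride;
            int c_n = 0;
            for (int q = 0; q < np; ++q) {
              const double* a = a0 + fa[q];
              double dx = a[0] - fx[3 * q], dy = a[1] - fx[3 * q + 1],
                     dz = a[2] - fx[3 * q + 2];
              if (dx * dx + dy * dy + dz * dz <= thr2) ++c_n;
            }
            cand_n[cnd] = c_n;
            if (c_n > best_n) best_n = c_n;
          }
          // pass 2: distance sums only for candidates tied at the maximum
          double best_dist = 0;
          int best_cand = -1;
          for (int cnd = 0; cnd < n_cand; ++cnd) {
            if (cand_n[cnd] != best_n) continue;
            const double* a0 = base_ptr[h] + cnd * stride;
            double c_dist = 0;
            for (int q = 0; q < np; ++q) {
              const double* a = a0 + fa[q];
              double dx = a[0] - fx[3 * q], dy = a[1] - fx[3 * q + 1],
                     dz = a[2] - fx[3 * q + 2];
              c_dist += std::sqrt(dx * dx + dy * dy + dz * dz);
            }
            if (best_cand < 0 || c_dist < best_dist - 1e-9) {
              best_dist = c_dist; best_cand = cnd;
            }
          }
          reg_i[h] = best_cand / n_roll; roll_i[h] = best_cand % n_roll;
          cur[h] = base_ptr[h] + best_cand * stride;
          tot_nsat = base_nsat + best_n;
          tot_dist = base_dist + best_dist;
        }
        out(row, 0) = tot_nsat;
        out(row, 1) = tot_dist;
        for (int h = 0; h < K; ++h) {
          out(row, 2 + h) = reg_i[h];
          out(row, 2 + K + h) = roll_i[h];
        }
        ++row;
      }
      return;
    }
    for (int r = 0; r < n_rods; ++r) {
      if (used[r]) continue;
      used[r] = true;
      tuple[depth] = r;
      rec(depth + 1);
      used[r] = false;
    }
  };
  rec(0);
  return out;
}

// Resample a map under an affine world-coordinate lookup with trilinear
// interpolation: out(i,j,k) = in(A * y + b) where y is the world coordinate
// of output voxel (i,j,k). Points outside the input grid contribute 0.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector grid, IntegerVector in_dim,
                                  NumericVector in_origin, double voxel,
                                  IntegerVector out_dim,
                                  NumericVector out_origin,
                                  NumericMatrix A, NumericVector b) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((long)ox * oy * oz);
  const double* g = grid.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  long idx = 0;
  for (int k = 0; k < oz; ++k) {
    double yz = out_origin[2] + k * voxel;
    for (int j = 0; j < oy; ++j) {
      double yy = out_origin[1] + j * voxel;
      for (int i = 0; i < ox; ++i, ++idx) {
        double yx = out_origin[0] + i * voxel;
        double wx = a00 * yx + a01 * yy + a02 * yz + b[0];
        double wy = a10 * yx + a11 * yy + a12 * yz + b[1];
        double wz = a20 * yx + a21 * yy + a22 * yz + b[2];
        double fx = (wx - in_origin[0]) / voxel;
        double fy = (wy - in_origin[1]) / voxel;
        double fz = (wz - in_origin[2]) / voxel;
        int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
            z0 = (int)std::floor(fz);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= nx - 1 || y0 >= ny - 1 ||
            z0 >= nz - 1) continue;
        double tx = fx - x0, ty = fy - y0, tz = fz - z0;
        long b000 = x0 + (long)nx * (y0 + (long)ny * z0);
        double c00 = g[b000] * (1 - tx) + g[b000 + 1] * tx;
        double c10 = g[b000 + nx] * (1 - tx) + g[b000 + nx + 1] * tx;
        double c01 = g[b000 + (long)nx * ny] * (1 - tx) +
                     g[b000 + (long)nx * ny + 1] * tx;
        double c11 = g[b000 + (long)nx * ny + nx] * (1 - tx) +
                     g[b000 + (long)nx * ny + nx + 1] * tx;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[idx] = c0 * (1 - tz) + c1 * tz;
      }
    }
  }
  return out;
}
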