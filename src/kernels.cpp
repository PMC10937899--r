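#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Layout conventions (match R column-major arrays):
//   feature maps are (H, W, C) or (H, W, C, B) arrays;
//   im2col emits a ((B*)OH*OW) x (k*k*C) matrix whose row order is
//   oh-major within ow within b, and whose column order matches an
//   R-flattened (k, k, C, Cout) weight array, so conv = cols %*% W.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int B,
                         int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  const int S = OH * OW;
  const int ncol = k * k * C;
  NumericMatrix out(S * B, ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t img = plane * C;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int col = ki + k * kj + k * k * c;
          double* dst = op + (R_xlen_t)col * (S * B) + (R_xlen_t)b * S;
          const double* src = xp + (R_xlen_t)b * img + (R_xlen_t)c * plane;
          for (int ow = 0; ow < OW; ++ow) {
            const int w_in = ow * stride - pad + kj;
            double* d2 = dst + ow * OH;
            if (w_in < 0 || w_in >= W) {
              for (int oh = 0; oh < OH; ++oh) d2[oh] = 0.0;
              continue;
            }
            const double* s2 = src + (R_xlen_t)w_in * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int h_in = oh * stride - pad + ki;
              d2[oh] = (h_in < 0 || h_in >= H) ? 0.0 : s2[h_in];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int B,
                         int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  const int S = OH * OW;
  NumericVector x((R_xlen_t)H * W * C * B);
  double* xp = x.begin();
  const double* op = cols.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t img = plane * C;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int col = ki + k * kj + k * k * c;
          const double* src = op + (R_xlen_t)col * (S * B) + (R_xlen_t)b * S;
          double* dst = xp + (R_xlen_t)b * img + (R_xlen_t)c * plane;
          for (int ow = 0; ow < OW; ++ow) {
            const int w_in = ow * stride - pad + kj;
            if (w_in < 0 || w_in >= W) continue;
            const double* s2 = src + ow * OH;
            double* d2 = dst + (R_xlen_t)w_in * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int h_in = oh * stride - pad + ki;
              if (h_in >= 0 && h_in < H) d2[h_in] += s2[oh];
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling over (H, W, C, B); returns values and 1-based argmax
// indices into the flattened input (for the backward scatter).
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int B,
                     int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector out((R_xlen_t)OH * OW * C * B);
  IntegerVector arg((R_xlen_t)OH * OW * C * B);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* src = xp + ((R_xlen_t)b * C + c) * plane;
      const R_xlen_t base = ((R_xlen_t)b * C + c) * plane;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = ow * stride - pad + kj;
            if (w_in < 0 || w_in >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h_in = oh * stride - pad + ki;
              if (h_in < 0 || h_in >= H) continue;
              const double v = src[(R_xlen_t)w_in * H + h_in];
              if (v > best) { best = v; besti = base + (R_xlen_t)w_in * H + h_in; }
            }
          }
          op[o] = best;
          ap[o] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg,
                      _["oh"] = OH, _["ow"] = OW);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd_cpp(NumericVector grad, IntegerVector argmax,
                              R_xlen_t input_len) {
  NumericVector dx(input_len);
  double* dp = dx.begin();
  const double* gp = grad.begin();
  const int* ap = argmax.begin();
  for (R_xlen_t i = 0; i < grad.size(); ++i) dp[ap[i] - 1] += gp[i];
  return dx;
}

// Rectangular assignment by shortest augmenting paths with potentials
// (Jonker-Volgenant style, as used for linear sum assignment problems).
// cost is nr x nc column-major, nr <= nc. Returns 1-based col4row.
// [[Rcpp::export(name = ".lsap")]]
IntegerVector lsap_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr > nc) stop("assignment requires nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i)
    if (!std::isfinite(cost[i])) stop("non-finite cost in assignment problem");
  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortest(nc);
  std::vector<int> path(nc, -1), col4row(nr, -1), row4col(nc, -1);
  std::vector<char> SR(nr), SC(nc);
  std::vector<int> remaining(nc);
  for (int curRow = 0; curRow < nr; ++curRow) {
    double minVal = 0.0;
    int i = curRow;
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(shortest.begin(), shortest.end(), INF);
    int num_remaining = nc;
    for (int j = 0; j < nc; ++j) remaining[j] = j;
    int sink = -1;
    while (sink == -1) {
      int index = -1;
      double lowest = INF;
      SR[i] = 1;
      for (int it = 0; it < num_remaining; ++it) {
        const int j = remaining[it];
        const double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { path[j] = i; shortest[j] = r; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          index = it;
        }
      }
      minVal = lowest;
      if (!std::isfinite(minVal)) stop("assignment problem is infeasible");
      const int j = remaining[index];
      if (row4col[j] == -1) sink = j; else i = row4col[j];
      SC[j] = 1;
      remaining[index] = remaining[--num_remaining];
    }
    u[curRow] += minVal;
    for (int ii = 0; ii < nr; ++ii)
      if (SR[ii] && ii != curRow) u[ii] += minVal - shortest[col4row[ii]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];
    int j = sink;
    while (true) {
      const int ii = path[j];
      row4col[j] = ii;
      std::swap(col4row[ii], j);
      if (ii == curRow) break;
    }
  }
  IntegerVector res(nr);
  for (int r = 0; r < nr; ++r) res[r] = col4row[r] + 1;
  return res;
}

// Fused multi-head scaled-dot-product attention over stacked sequences.
// q: ((B*Sq) x d), k/v: ((B*Sk) x d), heads split d evenly. Per-head
// blocks are packed into contiguous buffers before the inner loops.
// Returns the attention output and the per-(batch,head) probability rows
// needed for the backward pass.

static void pack_head(const double* m, int nrow, int r0, int S, int c0,
                      int dh, std::vector<double>& buf) {
  for (int t = 0; t < dh; ++t) {
    const double* col = m + (R_xlen_t)(c0 + t) * nrow + r0;
    for (int i = 0; i < S; ++i) buf[(R_xlen_t)i * dh + t] = col[i];
  }
}

static void unpack_head_add(double* m, int nrow, int r0, int S, int c0,
                            int dh, const std::vector<double>& buf) {
  for (int t = 0; t < dh; ++t) {
    double* col = m + (R_xlen_t)(c0 + t) * nrow + r0;
    for (int i = 0; i < S; ++i) col[i] += buf[(R_xlen_t)i * dh + t];
  }
}

// [[Rcpp::export(name = ".sdpa_fwd")]]
List sdpa_fwd_cpp(NumericMatrix q, NumericMatrix k, NumericMatrix v,
                  int nheads, int Sq, int Sk, int B) {
  const int d = q.ncol();
  const int dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix out(q.nrow(), d);
  NumericMatrix A((R_xlen_t)B * nheads * Sq, Sk);
  const int nq = q.nrow(), nk = k.nrow(), nA = A.nrow();
  std::vector<double> s(Sk), qb((R_xlen_t)Sq * dh), kb((R_xlen_t)Sk * dh),
      vb((R_xlen_t)Sk * dh), ob((R_xlen_t)Sq * dh);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nheads; ++h) {
      const int rq0 = b * Sq, rk0 = b * Sk, c0 = h * dh;
      const int a0 = (b * nheads + h) * Sq;
      pack_head(q.begin(), nq, rq0, Sq, c0, dh, qb);
      pack_head(k.begin(), nk, rk0, Sk, c0, dh, kb);
      pack_head(v.begin(), nk, rk0, Sk, c0, dh, vb);
      for (int i = 0; i < Sq; ++i) {
        const double* qi = &qb[(R_xlen_t)i * dh];
        double mx = -std::numeric_limits<double>::infinity();
        for (int j = 0; j < Sk; ++j) {
          const double* kj = &kb[(R_xlen_t)j * dh];
          double acc = 0.0;
          for (int t = 0; t < dh; ++t) acc += qi[t] * kj[t];
          s[j] = acc * scale;
          if (s[j] > mx) mx = s[j];
        }
        double tot = 0.0;
        for (int j = 0; j < Sk; ++j) { s[j] = std::exp(s[j] - mx); tot += s[j]; }
        double* oi = &ob[(R_xlen_t)i * dh];
        for (int t = 0; t < dh; ++t) oi[t] = 0.0;
        for (int j = 0; j < Sk; ++j) {
          const double a = s[j] / tot;
          A[a0 + i + (R_xlen_t)j * nA] = a;
          const double* vj = &vb[(R_xlen_t)j * dh];
          for (int t = 0; t < dh; ++t) oi[t] += a * vj[t];
        }
      }
      for (int t = 0; t < dh; ++t) {
        double* col = out.begin() + (R_xlen_t)(c0 + t) * nq + rq0;
        for (int i = 0; i < Sq; ++i) col[i] = ob[(R_xlen_t)i * dh + t];
      }
    }
  }
  return List::create(_["out"] = out, _["probs"] = A);
}

// [[Rcpp::export(name = ".sdpa_bwd")]]
List sdpa_bwd_cpp(NumericMatrix g, NumericMatrix q, NumericMatrix k,
                  NumericMatrix v, NumericMatrix A,
                  int nheads, int Sq, int Sk, int B) {
  const int d = q.ncol();
  const int dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix dq(q.nrow(), d), dk(k.nrow(), d), dv(k.nrow(), d);
  const int nq = q.nrow(), nk = k.nrow(), nA = A.nrow();
  std::vector<double> dA(Sk), dS(Sk), qb((R_xlen_t)Sq * dh),
      kb((R_xlen_t)Sk * dh), vb((R_xlen_t)Sk * dh), gb((R_xlen_t)Sq * dh),
      dqb((R_xlen_t)Sq * dh), dkb((R_xlen_t)Sk * dh), dvb((R_xlen_t)Sk * dh);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nheads; ++h) {
      const int rq0 = b * Sq, rk0 = b * Sk, c0 = h * dh;
      const int a0 = (b * nheads + h) * Sq;
      pack_head(q.begin(), nq, rq0, Sq, c0, dh, qb);
      pack_head(k.begin(), nk, rk0, Sk, c0, dh, kb);
      pack_head(v.begin(), nk, rk0, Sk, c0, dh, vb);
      pack_head(g.begin(), nq, rq0, Sq, c0, dh, gb);
      std::fill(dqb.begin(), dqb.end(), 0.0);
      std::fill(dkb.begin(), dkb.end(), 0.0);
      std::fill(dvb.begin(), dvb.end(), 0.0);
      for (int i = 0; i < Sq; ++i) {
        const double* gi = &gb[(R_xlen_t)i * dh];
        const double* qi = &qb[(R_xlen_t)i * dh];
        double dot = 0.0;
        for (int j = 0; j < Sk; ++j) {
          const double* vj = &vb[(R_xlen_t)j * dh];
          double acc = 0.0;
          for (int t = 0; t < dh; ++t) acc += gi[t] * vj[t];
          dA[j] = acc;
          dot += acc * A[a0 + i + (R_xlen_t)j * nA];
        }
        double* dqi = &dqb[(R_xlen_t)i * dh];
        for (int j = 0; j < Sk; ++j) {
          const double a = A[a0 + i + (R_xlen_t)j * nA];
          dS[j] = a * (dA[j] - dot);
          double* dvj = &dvb[(R_xlen_t)j * dh];
          for (int t = 0; t < dh; ++t) dvj[t] += a * gi[t];
          const double w = dS[j] * scale;
          const double* kj = &kb[(R_xlen_t)j * dh];
          double* dkj = &dkb[(R_xlen_t)j * dh];
          for (int t = 0; t < dh; ++t) {
            dqi[t] += w * kj[t];
            dkj[t] += w * qi[t];
          }
        }
      }
      unpack_head_add(dq.begin(), nq, rq0, Sq, c0, dh, dqb);
      unpack_head_add(dk.begin(), nk, rk0, Sk, c0, dh, dkb);
      unpack_head_add(dv.begin(), nk, rk0, Sk, c0, dh, dvb);
    }
  }
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}
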