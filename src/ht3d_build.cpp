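// Constructs the full HT3D spiking network in compressed sparse row form.
//
// Neuron blocks (0-based internally, ids exposed to R are 1-based):
//   hough      : (theta, d, row)            relay neurons, 1-pixel p-rows
//   subpattern : (theta, d, cell, {u,s,c})  vote-difference neurons
//   pattern    : (theta, d, cell, {p1n, p1f, p2n, p2f})
//   combiner   : (theta, d, cell, {sum_n, sum_f, prod_n, prod_f})
//   endpoint   : (x, y) image sheet, pure integrators (infinite threshold)
//
// Wiring implements: vote propagation up each d-column (1 tick per pixel
// row); paired excitatory/delayed-inhibitory synapses computing vote
// differences over pieces of length delta_p, (eta-1)*delta_p and
// eta*delta_p; endpoint (p1) and corner half-pattern (p2) combination;
// cross-orientation corner confirmation (sum/prod coincidence units); and
// reverse voting from detector cells onto the image-registered endpoint
// sheet.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int round_half_up(double x) {
  return (int)(x >= 0 ? std::floor(x + 0.5) : -std::floor(-x + 0.5));
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct BuildCtx {
  // pass 0 counts out-degrees, pass 1 fills slots
  int pass = 0;
  std::vector<int> deg;     // out-degree per pre neuron
  std::vector<int64_t> ptr; // CSR pointers
  std::vector<int64_t> cur; // fill cursors
  IntegerVector post;
  NumericVector weight;
  IntegerVector delay;
  void emit(int pre, int tgt, double w, int dly) {
    if (pass == 0) {
      ++deg[pre];
    } else {
      int64_t at = cur[pre]++;
      post[at] = tgt + 1; // 1-based for R
      weight[at] = w;
      delay[at] = dly;
    }
  }
};

// [[Rcpp::export]]
List ht3d_build_cpp(int W, int H, int n_theta, int n_d, int n_rows, int n_p,
                    int delta_d, int delta_p, double delta_theta, int eta,
                    double R, double w_cE, double rho_p1, double rho_p2,
                    double theta_p1, double theta_p2, double lambda,
                    double theta_pi, double lambda_pi, double lambda_e,
                    int off_lo, int off_hi) {
  const int dp = delta_p;
  const int64_t N_H = (int64_t)n_theta * n_d * n_rows;
  const int64_t N_POS = (int64_t)n_theta * n_d * n_p;
  const int64_t OFF_S = N_H;
  const int64_t OFF_P = OFF_S + 3 * N_POS;
  const int64_t OFF_C = OFF_P + 4 * N_POS;
  const int64_t OFF_E = OFF_C + 4 * N_POS;
  const int64_t N = OFF_E + (int64_t)W * H;
  if (N > INT32_MAX) stop("network too large");
  const int n = (int)N;

  auto hid = [&](int t, int d, int r) {
    return (int)(((int64_t)t * n_d + d) * n_rows + r);
  };
  auto sid = [&](int t, int d, int j, int type) {
    return (int)(OFF_S + (((int64_t)t * n_d + d) * n_p + j) * 3 + type);
  };
  auto pid = [&](int t, int d, int j, int k) {
    return (int)(OFF_P + (((int64_t)t * n_d + d) * n_p + j) * 4 + k);
  };
  auto cid = [&](int t, int d, int j, int k) {
    return (int)(OFF_C + (((int64_t)t * n_d + d) * n_p + j) * 4 + k);
  };
  auto eid = [&](int x, int y) { return (int)(OFF_E + (int64_t)y * W + x); };

  const double w_uI = -(double)eta * dp * w_cE;
  const double w_cI = -rho_p1 * w_cE;
  const double w_sI = -rho_p2 * w_cE;
  const int span_u = dp, span_s = (eta - 1) * dp, span_c = eta * dp;

  // precompute combiner rotations between layer pairs
  int n_off = (off_hi >= off_lo) ? off_hi - off_lo + 1 : 0;
  std::vector<double> rot_cos(n_theta * std::max(n_off, 1));
  std::vector<double> rot_sin(n_theta * std::max(n_off, 1));
  for (int ts = 0; ts < n_theta; ++ts) {
    for (int k = 0; k < n_off; ++k) {
      int tt = (ts + off_lo + k) % n_theta;
      double dlt = (tt - ts) * delta_theta;
      rot_cos[ts * n_off + k] = std::cos(dlt);
      rot_sin[ts * n_off + k] = std::sin(dlt);
    }
  }

  BuildCtx cx;
  cx.deg.assign(n, 0);

  for (cx.pass = 0; cx.pass <= 1; ++cx.pass) {
    if (cx.pass == 1) {
      cx.ptr.assign(n + 1, 0);
      for (int i = 0; i < n; ++i) cx.ptr[i + 1] = cx.ptr[i] + cx.deg[i];
      int64_t total = cx.ptr[n];
      if (total > INT32_MAX) stop("synapse count exceeds integer range");
      cx.post = IntegerVector((R_xlen_t)total);
      cx.weight = NumericVector((R_xlen_t)total);
      cx.delay = IntegerVector((R_xlen_t)total);
      cx.cur.assign(cx.ptr.begin(), cx.ptr.end() - 1);
    }

    for (int t = 0; t < n_theta; ++t) {
      for (int d = 0; d < n_d; ++d) {
        // vote propagation up the column, 1 tick per 1-pixel row
        for (int r = 0; r + 1 < n_rows; ++r)
          cx.emit(hid(t, d, r), hid(t, d, r + 1), 1.0, 1);
        for (int j = 0; j < n_p; ++j) {
          int rj = (j + 1) * dp - 1; // top row of cell j
          // subpattern difference pairs: excitation from h(rj), inhibition
          // of equal magnitude from h(rj - span), delayed by span ticks
          cx.emit(hid(t, d, rj), sid(t, d, j, 0), 1.0, 1);
          if (rj - span_u >= 0) cx.emit(hid(t, d, rj - span_u), sid(t, d, j, 0), -1.0, 1 + span_u);
          cx.emit(hid(t, d, rj), sid(t, d, j, 1), 1.0, 1);
          if (rj - span_s >= 0) cx.emit(hid(t, d, rj - span_s), sid(t, d, j, 1), -1.0, 1 + span_s);
          cx.emit(hid(t, d, rj), sid(t, d, j, 2), 1.0, 1);
          if (rj - span_c >= 0) cx.emit(hid(t, d, rj - span_c), sid(t, d, j, 2), -1.0, 1 + span_c);
        }
        if (d >= 1 && d + 1 < n_d) {
          for (int j = 0; j < n_p; ++j) {
            // endpoint pattern, normal: full piece = cells j-eta+1..j,
            // empty cell above = j+1
            if (j >= eta - 1 && j + 1 < n_p) {
              int p1 = pid(t, d, j, 0);
              for (int dd = -1; dd <= 1; ++dd)
                cx.emit(sid(t, d + dd, j + 1, 0), p1, w_uI, 1);
              cx.emit(sid(t, d, j, 2), p1, w_cE, 1);
              cx.emit(sid(t, d - 1, j, 2), p1, w_cI, 1);
              cx.emit(sid(t, d + 1, j, 2), p1, w_cI, 1);
            }
            // endpoint pattern, flipped: full piece = cells j..j+eta-1,
            // empty cell below = j-1
            if (j >= 1 && j + eta - 1 < n_p) {
              int p1 = pid(t, d, j, 1);
              for (int dd = -1; dd <= 1; ++dd)
                cx.emit(sid(t, d + dd, j - 1, 0), p1, w_uI, 1);
              cx.emit(sid(t, d, j + eta - 1, 2), p1, w_cE, 1);
              cx.emit(sid(t, d - 1, j + eta - 1, 2), p1, w_cI, 1);
              cx.emit(sid(t, d + 1, j + eta - 1, 2), p1, w_cI, 1);
            }
            // corner half-pattern, normal: central full piece at j, lateral
            // empty runs of eta-1 cells ending at cell j-1
            if (j >= eta - 1) {
              int p2 = pid(t, d, j, 2);
              cx.emit(sid(t, d, j, 2), p2, w_cE, 1);
              cx.emit(sid(t, d - 1, j - 1, 1), p2, w_sI, 1);
              cx.emit(sid(t, d + 1, j - 1, 1), p2, w_sI, 1);
            }
            // corner half-pattern, flipped
            if (j >= 1 && j + eta - 1 < n_p) {
              int p2 = pid(t, d, j, 3);
              cx.emit(sid(t, d, j + eta - 1, 2), p2, w_cE, 1);
              cx.emit(sid(t, d - 1, j + eta - 1, 1), p2, w_sI, 1);
              cx.emit(sid(t, d + 1, j + eta - 1, 1), p2, w_sI, 1);
            }
          }
        }
      }
    }

    // corner confirmation: each p2 output (either version) feeds the
    // pooling (sum) units of every layer at an in-range angular offset, at
    // the cell of the same image position. A strong inhibitory self-synapse
    // makes a sum unit report pooled remote support about once per run
    // rather than once per remote spike, so that the prod unit - local p2
    // plus own sum unit, threshold between one and two inputs - realizes
    // the product: it fires only when a local half-pattern coincides with
    // remote support from an in-range orientation.
    for (int ts = 0; ts < n_theta; ++ts) {
      for (int d = 0; d < n_d; ++d) {
        double ds = d * delta_d - R;
        for (int j = 0; j < n_p; ++j) {
          for (int v = 0; v < 2; ++v) {
            int p2 = pid(ts, d, j, 2 + v);
            // anchor row of the feature this cell describes
            int row = v == 0 ? (j + 1) * dp - 1 : j * dp;
            double ps = row - R;
            for (int k = 0; k < n_off; ++k) {
              int tt = (ts + off_lo + k) % n_theta;
              double c = rot_cos[ts * n_off + k], s = rot_sin[ts * n_off + k];
              double dt_ = ds * c + ps * s;
              double pt_ = -ds * s + ps * c;
              int d2 = clampi(round_half_up((dt_ + R) / delta_d), 0, n_d - 1);
              int r2 = clampi(round_half_up(pt_ + R), 0, n_rows - 1);
              int j2 = r2 / dp;
              cx.emit(p2, cid(tt, d2, j2, 0), w_cE, 1);
            }
            cx.emit(p2, cid(ts, d, j, 2 + v), 1.0, 2); // local input of prod
          }
          // both prod versions share one pooled sum unit (their input sets
          // are identical); the second sum slot is a structural placeholder
          cx.emit(cid(ts, d, j, 0), cid(ts, d, j, 0), w_uI, 1); // once-per-run cap
          cx.emit(cid(ts, d, j, 0), cid(ts, d, j, 2), 1.0, 1);
          cx.emit(cid(ts, d, j, 0), cid(ts, d, j, 3), 1.0, 1);
        }
      }
    }

    // reverse voting: each pixel's discrete Hough position per layer links
    // the four detector units of that cell to the pixel's endpoint neuron
    double cx0 = (W - 1) / 2.0, cy0 = (H - 1) / 2.0;
    for (int t = 0; t < n_theta; ++t) {
      double th = t * delta_theta;
      double ct = std::cos(th), st = std::sin(th);
      for (int y = 0; y < H; ++y) {
        for (int x = 0; x < W; ++x) {
          double xc = x - cx0, yc = y - cy0;
          double dd_ = xc * ct + yc * st;
          double pp_ = -xc * st + yc * ct;
          int d2 = clampi(round_half_up((dd_ + R) / delta_d), 0, n_d - 1);
          int r2 = clampi(round_half_up(pp_ + R), 0, n_rows - 1);
          int j2 = r2 / dp;
          int e = eid(x, y);
          cx.emit(pid(t, d2, j2, 0), e, 1.0, 1);
          cx.emit(pid(t, d2, j2, 1), e, 1.0, 1);
          cx.emit(cid(t, d2, j2, 2), e, 1.0, 1);
          cx.emit(cid(t, d2, j2, 3), e, 1.0, 1);
        }
      }
    }
  }

  NumericVector threshold(n), decayv(n);
  for (int64_t i = 0; i < N_H; ++i) { threshold[i] = 1.0; decayv[i] = lambda; }
  for (int64_t i = OFF_S; i < OFF_P; ++i) { threshold[i] = 1.0; decayv[i] = lambda; }
  for (int64_t i = OFF_P; i < OFF_C; ++i) {
    int k = (int)((i - OFF_P) % 4);
    threshold[i] = (k < 2) ? theta_p1 : theta_p2;
    decayv[i] = lambda;
  }
  for (int64_t i = OFF_C; i < OFF_E; ++i) {
    int k = (int)((i - OFF_C) % 4);
    threshold[i] = (k < 2) ? w_cE : theta_pi;
    decayv[i] = (k < 2) ? lambda : lambda_pi;
  }
  for (int64_t i = OFF_E; i < N; ++i) {
    threshold[i] = R_PosInf;
    decayv[i] = lambda_e;
  }

  IntegerVector ptr((R_xlen_t)(n + 1));
  for (int i = 0; i <= n; ++i) ptr[i] = (int)cx.ptr[i];

  return List::create(
      _["n_neurons"] = n, _["syn_ptr"] = ptr, _["syn_post"] = cx.post,
      _["syn_weight"] = cx.weight, _["syn_delay"] = cx.delay,
      _["threshold"] = threshold, _["decay"] = decayv,
      _["off_sub"] = (double)OFF_S, _["off_pattern"] = (double)OFF_P,
      _["off_combiner"] = (double)OFF_C, _["off_endpoint"] = (double)OFF_E);
}
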