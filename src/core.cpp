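#include <Rcpp.h>
using namespace Rcpp;

// Kalman-filter log-likelihood of the integrated Ornstein-Uhlenbeck
// (continuous-time correlated random walk) model, x and y treated as
// independent coordinates sharing (beta, sigma). State per coordinate is
// (position, velocity). Observations may be NA (prediction-only steps).
// hauled[i] flags the interval between time i and i+1: while hauled the
// velocity is pinned to zero and the position does not diffuse.
//
// times in hours, positions in km, err_sd in km.
// [[Rcpp::export]]
double ctcrw_loglik_cpp(NumericVector times, NumericVector ox, NumericVector oy,
                        IntegerVector hauled, double beta, double sigma,
                        double err_sd) {
  int n = times.size();
  double R = err_sd * err_sd;
  double s2 = sigma * sigma;
  // per-coordinate state mean and covariance
  double mx[2], my[2], Px[3], Py[3]; // P stored as (p11, p12, p22)
  double ll = 0.0;
  bool init = false;
  for (int i = 0; i < n; ++i) {
    bool obs = !NumericVector::is_na(ox[i]);
    if (!init) {
      if (!obs) continue; // wait for the first observation
      mx[0] = ox[i]; mx[1] = 0.0; my[0] = oy[i]; my[1] = 0.0;
      Px[0] = R; Px[1] = 0.0; Px[2] = s2 / (2.0 * beta);
      Py[0] = R; Py[1] = 0.0; Py[2] = s2 / (2.0 * beta);
      init = true;
    } else {
      // predict from previous time to this one
      double dt = times[i] - times[i - 1];
      double T00 = 1.0, T01, T11, q11, q12, q22;
      if (hauled[i - 1] == 1) {
        T01 = 0.0; T11 = 0.0; q11 = 0.0; q12 = 0.0; q22 = 0.0;
      } else {
        double eb = exp(-beta * dt);
        T01 = (1.0 - eb) / beta;
        T11 = eb;
        q22 = s2 * (1.0 - eb * eb) / (2.0 * beta);
        q12 = s2 * (1.0 - 2.0 * eb + eb * eb) / (2.0 * beta * beta);
        q11 = s2 / (beta * beta) *
              (dt - 2.0 * (1.0 - eb) / beta + (1.0 - eb * eb) / (2.0 * beta));
      }
      for (int c = 0; c < 2; ++c) {
        double *m = c ? my : mx;
        double *P = c ? Py : Px;
        double m0 = T00 * m[0] + T01 * m[1];
        double m1 = T11 * m[1];
        double a = P[0] + T01 * P[1], b = P[1] + T01 * P[2];
        double p00 = a + T01 * b + q11;
        double p01 = T11 * b + q12;
        double p11 = T11 * T11 * P[2] + q22;
        m[0] = m0; m[1] = m1; P[0] = p00; P[1] = p01; P[2] = p11;
      }
      if (obs) {
        // update both coordinates with the position observation
        double S = Px[0] + R;
        double vx = ox[i] - mx[0], vy = oy[i] - my[0];
        ll += -0.5 * (2.0 * log(2.0 * M_PI * S) + (vx * vx + vy * vy) / S);
        double kx0 = Px[0] / S, kx1 = Px[1] / S;
        mx[0] += kx0 * vx; mx[1] += kx1 * vx;
        my[0] += kx0 * vy; my[1] += kx1 * vy;
        double p00 = (1.0 - kx0) * Px[0];
        double p01 = (1.0 - kx0) * Px[1];
        double p11 = Px[2] - kx1 * Px[1];
        Px[0] = p00; Px[1] = p01; Px[2] = p11;
        Py[0] = p00; Py[1] = p01; Py[2] = p11;
      }
    }
  }
  if (!init) return NA_REAL;
  return ll;
}

// Forward-algorithm log-likelihood of an N-state HMM with time-varying
// transition matrices. logdens: T x N state-conditional log densities;
// trans: T x N x N row-stochastic matrices (trans[t](i,j) = P(s_t=j|s_{t-1}=i),
// entry t used for the step into time t; entry 0 ignored); delta: initial
// distribution.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logdens, NumericVector trans,
                       NumericVector delta) {
  int T = logdens.nrow(), N = logdens.ncol();
  std::vector<double> phi(N), nphi(N);
  double ll = 0.0;
  double mx = logdens(0, 0);
  for (int j = 1; j < N; ++j) mx = std::max(mx, logdens(0, j));
  double sum = 0.0;
  for (int j = 0; j < N; ++j) {
    phi[j] = delta[j] * exp(logdens(0, j) - mx);
    sum += phi[j];
  }
  ll += mx + log(sum);
  for (int j = 0; j < N; ++j) phi[j] /= sum;
  for (int t = 1; t < T; ++t) {
    mx = logdens(t, 0);
    for (int j = 1; j < N; ++j) mx = std::max(mx, logdens(t, j));
    sum = 0.0;
    for (int j = 0; j < N; ++j) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i)
        acc += phi[i] * trans[t + (size_t)T * (i + (size_t)N * j)];
      nphi[j] = acc * exp(logdens(t, j) - mx);
      sum += nphi[j];
    }
    if (sum <= 0.0 || !R_finite(sum)) return -1e300;
    ll += mx + log(sum);
    for (int j = 0; j < N; ++j) phi[j] = nphi[j] / sum;
  }
  return ll;
}

// Viterbi decoding under the same parameterisation; returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericVector trans,
                              NumericVector delta) {
  int T = logdens.nrow(), N = logdens.ncol();
  NumericMatrix v(T, N);
  IntegerMatrix bp(T, N);
  for (int j = 0; j < N; ++j)
    v(0, j) = log(delta[j] > 0 ? delta[j] : 1e-300) + logdens(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < N; ++i) {
        double tr = trans[t + (size_t)T * (i + (size_t)N * j)];
        double cand = v(t - 1, i) + log(tr > 0 ? tr : 1e-300);
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logdens(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int j = 0; j < N; ++j) if (v(T - 1, j) > best) { best = v(T - 1, j); arg = j; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Accumulate the time-integrated Gaussian bridge density of one track onto
// a regular grid. For each segment the bridge is discretised at nstep
// interior fractions; at each fraction an isotropic Gaussian with the given
// sd is added over cells within 4 sd, weighted by segment duration.
// xs, ys: cell-centre coordinates. seg_* give per-segment endpoints,
// durations (h) and motion variances (km^2/h); err_sd in km.
// [[Rcpp::export]]
NumericMatrix dbbmm_grid_cpp(NumericVector xs, NumericVector ys,
                             NumericVector x0, NumericVector y0,
                             NumericVector x1, NumericVector y1,
                             NumericVector dur, NumericVector sig2m,
                             double err_sd, int nstep) {
  int nx = xs.size(), ny = ys.size(), nseg = x0.size();
  NumericMatrix out(ny, nx);
  double cell = nx > 1 ? xs[1] - xs[0] : 1.0;
  for (int s = 0; s < nseg; ++s) {
    double w = dur[s] / nstep;
    for (int k = 0; k < nstep; ++k) {
      double a = (k + 0.5) / nstep;
      double mx = (1 - a) * x0[s] + a * x1[s];
      double my = (1 - a) * y0[s] + a * y1[s];
      double v = dur[s] * a * (1 - a) * sig2m[s] +
                 ((1 - a) * (1 - a) + a * a) * err_sd * err_sd;
      if (v <= 0) v = 1e-12;
      double lim = 4.0 * sqrt(v);
      int i0 = std::max(0, (int)floor((mx - lim - xs[0]) / cell));
      int i1 = std::min(nx - 1, (int)ceil((mx + lim - xs[0]) / cell));
      int j0 = std::max(0, (int)floor((my - lim - ys[0]) / cell));
      int j1 = std::min(ny - 1, (int)ceil((my + lim - ys[0]) / cell));
      double norm = w / (2.0 * M_PI * v);
      for (int j = j0; j <= j1; ++j) {
        double dy = ys[j] - my;
        for (int i = i0; i <= i1; ++i) {
          double dx = xs[i] - mx;
          out(j, i) += norm * exp(-0.5 * (dx * dx + dy * dy) / v);
        }
      }
    }
  }
  return out;
}
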