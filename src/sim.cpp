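// Coupled integrator: Bonhoeffer-van der Pol oscillator network driving and
// driven by a planar overdamped snake-like body.
//
// Neural side: tau x' = c(x - x^3/3 - y + z) + delta(Sf - x)
//              tau y' = (1/c)(x - b y + a) + eps * Sf
// with Sf the (1/K)-normalized weighted sum of presynaptic x, blended with
// bodily sensory feedback I for interface neurons via the sensor ratio alpha.
// RK4 on the full neural ODE (coupling recomputed at each substage); the
// sensory input I is held over one dt step.
//
// Body side: two-joint spring-damper muscles acting on hinge joints with
// overdamped angular dynamics; net rigid-body motion from a viscous
// anisotropic-friction (resistive-force) balance: with low tangential and
// high normal drag per link, the 3-dof (vx, vy, omega) that zeroes total
// force and torque is solved each step, so traveling body waves translate
// the head.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct BodyParams {
  int n_links;
  double link_len, gap, L0, kappa;
  double k_s, k_d, b_visc, joint_limit;
  double gain_motor, sigma_sensory;
  double c_t, c_n, c_rot;
};

static BodyParams body_from_list(const List& bp) {
  BodyParams b;
  b.n_links = as<int>(bp["n_links"]);
  b.link_len = as<double>(bp["link_len"]);
  b.gap = as<double>(bp["gap"]);
  b.L0 = as<double>(bp["L0"]);
  b.kappa = as<double>(bp["kappa"]);
  b.k_s = as<double>(bp["k_s"]);
  b.k_d = as<double>(bp["k_d"]);
  b.b_visc = as<double>(bp["b_visc"]);
  b.joint_limit = as<double>(bp["joint_limit"]);
  b.gain_motor = as<double>(bp["gain_motor"]);
  b.sigma_sensory = as<double>(bp["sigma_sensory"]);
  b.c_t = as<double>(bp["c_t"]);
  b.c_n = as<double>(bp["c_n"]);
  b.c_rot = as<double>(bp["c_rot"]);
  return b;
}

// muscle m (0-based) spans joints (q, q+1); first half left (+1), second
// half right (-1)
static inline void muscle_span(int m, int n_spans, int& q, double& side) {
  q = m % n_spans;
  side = (m < n_spans) ? 1.0 : -1.0;
}

static void muscle_lengths(const std::vector<double>& theta,
                           const BodyParams& b, std::vector<double>& L) {
  int n_spans = (int)theta.size() - 1;
  for (int m = 0; m < 2 * n_spans; ++m) {
    int q; double s;
    muscle_span(m, n_spans, q, s);
    double bend = 0.5 * (theta[q] + theta[q + 1]);
    double len = b.L0 * (1.0 - s * b.kappa * bend);
    if (len < 0.1 * b.L0) len = 0.1 * b.L0;
    L[m] = len;
  }
}

// one overdamped body step; updates theta, theta_dot, head (x, y, psi)
static void body_step_core(std::vector<double>& theta,
                           std::vector<double>& theta_dot,
                           double head[3],
                           const std::vector<double>& rest_len,
                           const BodyParams& b, double dt) {
  int n_joints = (int)theta.size();
  int n_spans = n_joints - 1;
  int n_muscles = 2 * n_spans;
  std::vector<double> L(n_muscles);
  muscle_lengths(theta, b, L);

  double arm = 0.5 * b.kappa * b.L0; // |dL/dtheta| per spanned joint
  std::vector<double> Q(n_joints, 0.0);
  for (int m = 0; m < n_muscles; ++m) {
    int q; double s;
    muscle_span(m, n_spans, q, s);
    double Ldot = -s * arm * (theta_dot[q] + theta_dot[q + 1]);
    double tension = b.k_s * (L[m] - rest_len[m]) + b.k_d * Ldot;
    // generalized force: Q_q = -tension * dL/dtheta_q = tension * s * arm
    Q[q] += tension * s * arm;
    Q[q + 1] += tension * s * arm;
  }

  std::vector<double> theta_new(n_joints);
  for (int q = 0; q < n_joints; ++q) {
    double td = Q[q] / b.b_visc;
    double th = theta[q] + dt * td;
    if (th > b.joint_limit) th = b.joint_limit;
    if (th < -b.joint_limit) th = -b.joint_limit;
    theta_dot[q] = (th - theta[q]) / dt;
    theta_new[q] = th;
  }

  // resistive-force balance in the body frame anchored at link 1
  int n_links = b.n_links;
  double dhalf = 0.5 * (b.link_len + b.gap);
  std::vector<double> phi(n_links, 0.0), phid(n_links, 0.0);
  std::vector<double> px(n_links, 0.0), py(n_links, 0.0);
  std::vector<double> pdx(n_links, 0.0), pdy(n_links, 0.0);
  for (int i = 1; i < n_links; ++i) {
    phi[i] = phi[i - 1] + theta_new[i - 1];
    phid[i] = phid[i - 1] + theta_dot[i - 1];
    double c0 = std::cos(phi[i - 1]), s0 = std::sin(phi[i - 1]);
    double c1 = std::cos(phi[i]), s1 = std::sin(phi[i]);
    px[i] = px[i - 1] + dhalf * (c0 + c1);
    py[i] = py[i - 1] + dhalf * (s0 + s1);
    pdx[i] = pdx[i - 1] - dhalf * (phid[i - 1] * s0 + phid[i] * s1);
    pdy[i] = pdy[i - 1] + dhalf * (phid[i - 1] * c0 + phid[i] * c1);
  }

  // assemble 3x3 system M [vx vy w]' = rhs
  double M[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double rhs[3] = {0, 0, 0};
  for (int i = 0; i < n_links; ++i) {
    double c = std::cos(phi[i]), s = std::sin(phi[i]);
    // drag tensor C_i = R diag(c_t, c_n) R^T
    double Cxx = b.c_t * c * c + b.c_n * s * s;
    double Cxy = (b.c_t - b.c_n) * c * s;
    double Cyy = b.c_t * s * s + b.c_n * c * c;
    double ax = -py[i], ay = px[i]; // J p_i
    // force rows
    M[0][0] += Cxx; M[0][1] += Cxy; M[0][2] += Cxx * ax + Cxy * ay;
    M[1][0] += Cxy; M[1][1] += Cyy; M[1][2] += Cxy * ax + Cyy * ay;
    rhs[0] -= Cxx * pdx[i] + Cxy * pdy[i];
    rhs[1] -= Cxy * pdx[i] + Cyy * pdy[i];
    // torque row: p x F, F = -C(...)
    // contribution of v: p x (C v) -> row entries
    M[2][0] += px[i] * Cxy - py[i] * Cxx;
    M[2][1] += px[i] * Cyy - py[i] * Cxy;
    M[2][2] += px[i] * (Cxy * ax + Cyy * ay) - py[i] * (Cxx * ax + Cxy * ay) + b.c_rot;
    rhs[2] -= px[i] * (Cxy * pdx[i] + Cyy * pdy[i]) -
              py[i] * (Cxx * pdx[i] + Cxy * pdy[i]) + b.c_rot * phid[i];
  }
  // solve by Cramer / Gaussian elimination (3x3)
  double a11 = M[0][0], a12 = M[0][1], a13 = M[0][2];
  double a21 = M[1][0], a22 = M[1][1], a23 = M[1][2];
  double a31 = M[2][0], a32 = M[2][1], a33 = M[2][2];
  double det = a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
               a13 * (a21 * a32 - a22 * a31);
  double vx = 0, vy = 0, w = 0;
  if (std::fabs(det) > 1e-14) {
    vx = (rhs[0] * (a22 * a33 - a23 * a32) - a12 * (rhs[1] * a33 - a23 * rhs[2]) +
          a13 * (rhs[1] * a32 - a22 * rhs[2])) / det;
    vy = (a11 * (rhs[1] * a33 - a23 * rhs[2]) - rhs[0] * (a21 * a33 - a23 * a31) +
          a13 * (a21 * rhs[2] - rhs[1] * a31)) / det;
    w = (a11 * (a22 * rhs[2] - rhs[1] * a32) - a12 * (a21 * rhs[2] - rhs[1] * a31) +
         rhs[0] * (a21 * a32 - a22 * a31)) / det;
  }
  double psi = head[2];
  head[0] += dt * (std::cos(psi) * vx - std::sin(psi) * vy);
  head[1] += dt * (std::sin(psi) * vx + std::cos(psi) * vy);
  head[2] += dt * w;
  theta = theta_new;
}

// [[Rcpp::export]]
List body_step_cpp(NumericVector theta, NumericVector theta_dot,
                   NumericVector head, NumericVector rest_len,
                   List body_params, double dt, int n_steps = 1) {
  BodyParams b = body_from_list(body_params);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> td(theta_dot.begin(), theta_dot.end());
  std::vector<double> rl(rest_len.begin(), rest_len.end());
  double hd[3] = {head[0], head[1], head[2]};
  for (int s = 0; s < n_steps; ++s) {
    body_step_core(th, td, hd, rl, b, dt);
    for (double v : th) {
      if (!std::isfinite(v)) stop("body state diverged (non-finite joint angle)");
    }
  }
  int n_spans = (int)th.size() - 1;
  std::vector<double> L(2 * n_spans);
  muscle_lengths(th, b, L);
  return List::create(
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["theta_dot"] = NumericVector(td.begin(), td.end()),
    _["head"] = NumericVector::create(hd[0], hd[1], hd[2]),
    _["muscle_len"] = NumericVector(L.begin(), L.end()));
}

struct NeuralNet {
  int n;
  // incoming edge lists per target node
  std::vector<std::vector<int>> src;
  std::vector<std::vector<double>> wgt;
  std::vector<double> invK;
};

static NeuralNet net_from_matrix(const NumericMatrix& W) {
  NeuralNet nn;
  nn.n = W.nrow();
  nn.src.resize(nn.n);
  nn.wgt.resize(nn.n);
  nn.invK.assign(nn.n, 0.0);
  for (int i = 0; i < nn.n; ++i) {
    for (int j = 0; j < nn.n; ++j) {
      if (j != i && W(j, i) != 0.0) {
        nn.src[i].push_back(j);
        nn.wgt[i].push_back(W(j, i));
      }
    }
    if (!nn.src[i].empty()) nn.invK[i] = 1.0 / (double)nn.src[i].size();
  }
  return nn;
}

struct BVP {
  double a, b, c, z, delta, eps, alpha, tau;
};

// derivative of the full neural state given current x, y and sensory input I
static void neural_deriv(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& I,
                         const std::vector<int>& iface, // muscle index per neuron, -1 hidden
                         const NeuralNet& nn, const BVP& p,
                         std::vector<double>& dx, std::vector<double>& dy) {
  int n = nn.n;
  for (int i = 0; i < n; ++i) {
    double net = 0.0;
    const std::vector<int>& s = nn.src[i];
    const std::vector<double>& wv = nn.wgt[i];
    for (size_t e = 0; e < s.size(); ++e) net += wv[e] * x[s[e]];
    net *= nn.invK[i];
    double sf;
    if (iface[i] >= 0) {
      sf = p.alpha * I[iface[i]] + (1.0 - p.alpha) * net;
    } else {
      sf = net;
    }
    double xi = x[i], yi = y[i];
    dx[i] = (p.c * (xi - xi * xi * xi / 3.0 - yi + p.z) + p.delta * (sf - xi)) / p.tau;
    dy[i] = ((xi - p.b * yi + p.a) / p.c + p.eps * sf) / p.tau;
  }
}

// [[Rcpp::export]]
List run_coupled_cpp(NumericMatrix W, IntegerVector interface_muscle,
                     List bvp_params, List body_params,
                     NumericVector x0, NumericVector y0,
                     double duration, double dt, int sample_every,
                     bool use_body, bool euler = false) {
  NeuralNet nn = net_from_matrix(W);
  BVP p;
  p.a = as<double>(bvp_params["a"]); p.b = as<double>(bvp_params["b"]);
  p.c = as<double>(bvp_params["c"]); p.z = as<double>(bvp_params["z"]);
  p.delta = as<double>(bvp_params["delta"]); p.eps = as<double>(bvp_params["eps"]);
  p.alpha = as<double>(bvp_params["alpha"]); p.tau = as<double>(bvp_params["tau"]);
  BodyParams b = body_from_list(body_params);

  int n = nn.n;
  int n_joints = b.n_links - 1;
  int n_muscles = 2 * (n_joints - 1);
  std::vector<int> iface(interface_muscle.begin(), interface_muscle.end());

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> theta(n_joints, 0.0), theta_dot(n_joints, 0.0);
  double head[3] = {0.0, 0.0, 0.0};
  std::vector<double> I(n_muscles, 0.0), L(n_muscles, b.L0);
  std::vector<double> rest(n_muscles, b.L0);

  int n_steps = (int)std::llround(duration / dt);
  int n_samples = n_steps / sample_every + 1;
  NumericMatrix X(n_samples, n), Y(n_samples, n);
  NumericMatrix TH(n_samples, n_joints), ML(n_samples, n_muscles);
  NumericMatrix HD(n_samples, 3);
  NumericVector tvec(n_samples);

  std::vector<double> k1x(n), k1y(n), k2x(n), k2y(n), k3x(n), k3y(n),
      k4x(n), k4y(n), xt(n), yt(n);

  bool diverged = false;
  int sample_row = 0;
  auto record = [&](int row, double t) {
    tvec[row] = t;
    for (int i = 0; i < n; ++i) { X(row, i) = x[i]; Y(row, i) = y[i]; }
    for (int q = 0; q < n_joints; ++q) TH(row, q) = theta[q];
    for (int m = 0; m < n_muscles; ++m) ML(row, m) = L[m];
    HD(row, 0) = head[0]; HD(row, 1) = head[1]; HD(row, 2) = head[2];
  };
  record(sample_row++, 0.0);

  for (int step = 1; step <= n_steps; ++step) {
    // sensory feedback from current body state, held over this step
    if (use_body) {
      muscle_lengths(theta, b, L);
      for (int m = 0; m < n_muscles; ++m) {
        double Im = b.sigma_sensory * (L[m] - b.L0) / b.L0;
        if (Im > 2.0) Im = 2.0;
        if (Im < -2.0) Im = -2.0;
        I[m] = Im;
      }
    }

    if (euler) {
      neural_deriv(x, y, I, iface, nn, p, k1x, k1y);
      for (int i = 0; i < n; ++i) { x[i] += dt * k1x[i]; y[i] += dt * k1y[i]; }
    } else {
      neural_deriv(x, y, I, iface, nn, p, k1x, k1y);
      for (int i = 0; i < n; ++i) { xt[i] = x[i] + 0.5 * dt * k1x[i]; yt[i] = y[i] + 0.5 * dt * k1y[i]; }
      neural_deriv(xt, yt, I, iface, nn, p, k2x, k2y);
      for (int i = 0; i < n; ++i) { xt[i] = x[i] + 0.5 * dt * k2x[i]; yt[i] = y[i] + 0.5 * dt * k2y[i]; }
      neural_deriv(xt, yt, I, iface, nn, p, k3x, k3y);
      for (int i = 0; i < n; ++i) { xt[i] = x[i] + dt * k3x[i]; yt[i] = y[i] + dt * k3y[i]; }
      neural_deriv(xt, yt, I, iface, nn, p, k4x, k4y);
      for (int i = 0; i < n; ++i) {
        x[i] += dt / 6.0 * (k1x[i] + 2 * k2x[i] + 2 * k3x[i] + k4x[i]);
        y[i] += dt / 6.0 * (k1y[i] + 2 * k2y[i] + 2 * k3y[i] + k4y[i]);
      }
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e3) { diverged = true; break; }
    }
    if (diverged) break;

    if (use_body) {
      // motor command: interface neuron k drives muscle iface[k]
      for (int i = 0; i < n; ++i) {
        if (iface[i] >= 0) {
          rest[iface[i]] = b.L0 * (1.0 + b.gain_motor * std::tanh(x[i]));
        }
      }
      body_step_core(theta, theta_dot, head, rest, b, dt);
      muscle_lengths(theta, b, L);
    }

    if (step % sample_every == 0) record(sample_row++, step * dt);
  }

  if (diverged && sample_row < n_samples) {
    X = X(Range(0, sample_row - 1), _);
    Y = Y(Range(0, sample_row - 1), _);
    TH = TH(Range(0, sample_row - 1), _);
    ML = ML(Range(0, sample_row - 1), _);
    HD = HD(Range(0, sample_row - 1), _);
    tvec = tvec[Range(0, sample_row - 1)];
  }

  return List::create(
    _["time"] = tvec, _["x"] = X, _["y"] = Y,
    _["theta"] = TH, _["muscle_len"] = ML, _["head"] = HD,
    _["diverged"] = diverged);
}
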