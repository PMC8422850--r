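// Current-clamp integrator and voltage-clamp replay for kneuron.
//
// States (HH gates and the reduced Markov pair (C, O)) are advanced exactly
// over each step at frozen voltage (gates: exponential relaxation; Markov:
// closed-form 2x2 matrix exponential), which removes the stiffness of the
// fast Na+ transition rates. The membrane voltage is advanced with a
// midpoint (RK2) step between two half-steps of the state update.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct TauS { int form; double fixedv, A, B, C, D, E, F, G; };
struct GateS { double V50, K; bool plus; TauS tau; };
struct ChanS {
  double gbar; int law; double E, VT; bool prefmV; int r;
  GateS m; std::vector<GateS> h; std::vector<double> w;
};
struct NatS { bool present; double gbar, E; int expo; double s[4], k[4], r[4]; };
struct ModelS { double Cm, gleak, Eleak, Ihold; std::vector<ChanS> ch; NatS nat; };

static GateS parse_gate(NumericVector v) {
  GateS g;
  g.V50 = v[0]; g.K = v[1]; g.plus = v[2] > 0.5;
  g.tau.form = (int)v[3]; g.tau.fixedv = v[4];
  g.tau.A = v[5]; g.tau.B = v[6]; g.tau.C = v[7]; g.tau.D = v[8];
  g.tau.E = v[9]; g.tau.F = v[10]; g.tau.G = v[11];
  return g;
}

static ModelS parse_model(List m) {
  ModelS M;
  M.Cm = as<double>(m["Cm"]); M.gleak = as<double>(m["g_leak"]);
  M.Eleak = as<double>(m["E_leak"]); M.Ihold = as<double>(m["Ihold"]);
  List chans = m["channels"];
  for (int i = 0; i < chans.size(); ++i) {
    List c = chans[i];
    ChanS C;
    C.gbar = as<double>(c["gbar"]); C.law = as<int>(c["law"]);
    C.E = as<double>(c["E"]); C.VT = as<double>(c["VT"]);
    C.prefmV = as<int>(c["pref_mV"]) > 0; C.r = as<int>(c["r"]);
    C.m = parse_gate(c["m"]);
    NumericMatrix h = c["h"];
    NumericVector w = c["w"];
    for (int j = 0; j < h.nrow(); ++j) {
      NumericVector row(h.ncol());
      for (int q = 0; q < h.ncol(); ++q) row[q] = h(j, q);
      C.h.push_back(parse_gate(row));
      C.w.push_back(w[j]);
    }
    M.ch.push_back(C);
  }
  M.nat.present = m.containsElementNamed("nat") && !Rf_isNull(m["nat"]);
  if (M.nat.present) {
    List n = m["nat"];
    M.nat.gbar = as<double>(n["gbar"]); M.nat.E = as<double>(n["E"]);
    M.nat.expo = as<int>(n["expo"]);
    NumericVector s = n["s"], k = n["k"], r = n["r"];
    for (int j = 0; j < 4; ++j) { M.nat.s[j] = s[j]; M.nat.k[j] = k[j]; M.nat.r[j] = r[j]; }
  }
  return M;
}

static inline double gss(const GateS &g, double V) {
  double x = g.plus ? V + g.V50 : V - g.V50;
  return 1.0 / (1.0 + std::exp(x / g.K));
}

static inline double gtau(const TauS &t, double V) {
  switch (t.form) {
  case 1: return t.fixedv;
  case 2: return t.A + t.B / (1.0 + std::exp((V - t.C) / t.D));
  case 3: return t.A + (t.B / (1.0 + std::exp((V - t.C) / t.D))) *
                       (t.E / (1.0 + std::exp((V - t.F) / t.G)));
  default: return t.E / (std::exp((t.A + V) / t.B) + std::exp((t.C + V) / t.D)) + t.F;
  }
}

static inline double drvf(const ChanS &c, double V) {
  if (c.law == 0) return V - c.E;
  if (std::fabs(V) < 1e-9) {
    double lim = std::expm1(-c.E / c.VT);
    return c.prefmV ? c.VT * lim : lim;
  }
  double num = std::expm1((V - c.E) / c.VT);
  double den = std::expm1(V / c.VT);
  double pref = c.prefmV ? V : V / c.VT;
  return pref * num / den;
}

static inline double ipow(double x, int n) {
  double out = 1.0;
  for (int i = 0; i < n; ++i) out *= x;
  return out;
}

static inline double rate(double s, double k, double r, double V) {
  return r / (1.0 + std::exp((V + s) / k));
}

// Summed membrane current (outward positive) at voltage V with states x.
static double ionic(const ModelS &M, double V, const double *x, bool leak) {
  double I = 0.0;
  int p = 0;
  for (size_t i = 0; i < M.ch.size(); ++i) {
    const ChanS &c = M.ch[i];
    double m = x[p++];
    double H = 1.0;
    if (!c.h.empty()) {
      H = 0.0;
      for (size_t j = 0; j < c.h.size(); ++j) H += c.w[j] * x[p++];
    }
    I += c.gbar * ipow(m, c.r) * H * drvf(c, V);
  }
  if (M.nat.present) {
    double O = x[p + 1];
    I += M.nat.gbar * ipow(O, M.nat.expo) * (V - M.nat.E);
  }
  if (leak) I += M.gleak * (V - M.Eleak);
  return I;
}

// Exact state advance over dt at frozen voltage.
static void advance(const ModelS &M, double V, double *x, double dt) {
  int p = 0;
  for (size_t i = 0; i < M.ch.size(); ++i) {
    const ChanS &c = M.ch[i];
    double inf = gss(c.m, V);
    x[p] = inf + (x[p] - inf) * std::exp(-dt / gtau(c.m.tau, V));
    ++p;
    for (size_t j = 0; j < c.h.size(); ++j) {
      double hinf = gss(c.h[j], V);
      x[p] = hinf + (x[p] - hinf) * std::exp(-dt / gtau(c.h[j].tau, V));
      ++p;
    }
  }
  if (M.nat.present) {
    double a = rate(M.nat.s[0], M.nat.k[0], M.nat.r[0], V);
    double b = rate(M.nat.s[1], M.nat.k[1], M.nat.r[1], V);
    double q1 = rate(M.nat.s[2], M.nat.k[2], M.nat.r[2], V);
    double q3 = rate(M.nat.s[3], M.nat.k[3], M.nat.r[3], V);
    double a11 = -(a + q3), a12 = b - q3, a21 = a, a22 = -(b + q1);
    double det = a11 * a22 - a12 * a21;
    double Cs = -a22 * q3 / det, Os = a21 * q3 / det;
    double mu = 0.5 * (a11 + a22), q2 = mu * mu - det;
    double ch, sh;
    if (q2 > 1e-24) {
      double q = std::sqrt(q2);
      ch = std::cosh(q * dt); sh = std::sinh(q * dt) / q;
    } else if (q2 < -1e-24) {
      double w = std::sqrt(-q2);
      ch = std::cos(w * dt); sh = std::sin(w * dt) / w;
    } else { ch = 1.0; sh = dt; }
    double e = std::exp(mu * dt);
    double E11 = e * (ch + sh * (a11 - mu)), E12 = e * sh * a12;
    double E21 = e * sh * a21, E22 = e * (ch + sh * (a22 - mu));
    double yC = x[p] - Cs, yO = x[p + 1] - Os;
    double Cn = Cs + E11 * yC + E12 * yO;
    double On = Os + E21 * yC + E22 * yO;
    if (Cn < 0) Cn = 0; if (On < 0) On = 0;
    if (Cn + On > 1.0) { double f = 1.0 / (Cn + On); Cn *= f; On *= f; }
    x[p] = Cn; x[p + 1] = On;
  }
}

static inline double applied(double t, const NumericVector &breaks,
                             const NumericVector &levels) {
  int i = breaks.size() - 1;
  while (i > 0 && t < breaks[i]) --i;
  return levels[i];
}

// [[Rcpp::export(name = ".cc_integrate_cpp")]]
List cc_integrate_cpp(List model, NumericVector x0, double V0,
                      double t_total, double dt, double dt_out,
                      NumericVector app_breaks, NumericVector app_levels) {
  ModelS M = parse_model(model);
  int nstate = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  int stride = (int)std::lround(dt_out / dt);
  if (stride < 1) stride = 1;
  long nsteps = (long)std::lround(t_total / dt);
  long nout = nsteps / stride + 1;
  NumericVector t_out(nout), V_out(nout);
  double V = V0;
  t_out[0] = 0.0; V_out[0] = V;
  long iout = 1;
  double halfdt = 0.5 * dt;
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    double Iapp = applied(t, app_breaks, app_levels);
    advance(M, V, x.data(), halfdt);
    double k1 = (-ionic(M, V, x.data(), true) + M.Ihold + Iapp) / M.Cm;
    double Vm = V + halfdt * k1;
    double k2 = (-ionic(M, Vm, x.data(), true) + M.Ihold + Iapp) / M.Cm;
    double Vn = V + dt * k2;
    if (!std::isfinite(Vn))
      stop("integration error: non-finite voltage at t = %f ms", t);
    advance(M, Vn, x.data(), halfdt);
    V = Vn;
    if ((s + 1) % stride == 0 && iout < nout) {
      t_out[iout] = (s + 1) * dt;
      V_out[iout] = V;
      ++iout;
    }
  }
  NumericVector xf(nstate);
  for (int i = 0; i < nstate; ++i) xf[i] = x[i];
  return List::create(_["t"] = t_out, _["V"] = V_out, _["state"] = xf);
}

// [[Rcpp::export(name = ".vc_replay_cpp")]]
NumericVector vc_replay_cpp(List model, NumericVector x0, NumericVector V,
                            double dt, bool include_leak) {
  ModelS M = parse_model(model);
  std::vector<double> x(x0.begin(), x0.end());
  int n = V.size();
  NumericVector I(n);
  I[0] = ionic(M, V[0], x.data(), include_leak);
  for (int i = 1; i < n; ++i) {
    advance(M, V[i], x.data(), dt);
    I[i] = ionic(M, V[i], x.data(), include_leak);
  }
  return I;
}
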