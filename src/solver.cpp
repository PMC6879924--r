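// 1D pulse wave propagation in a network of viscoelastic tapered tubes.
//
// Governing equations per segment (cross-sectionally averaged):
//   dA/dt + dQ/dx = 0
//   dQ/dt + d/dx(alpha Q^2/A) + (A/rho) dP/dx = -f_c (mu/rho) Q/A
// with the Voigt-type tube law
//   P = Pd + (beta/Ad)(sqrt(A) - sqrt(Ad)) + g_vis dA/dt ,
// beta = (4/3) sqrt(pi) Eh, g_vis = Gamma / (Ad sqrt(Ad)).
//
// Interior nodes: explicit MacCormack (predictor forward / corrector
// backward differences) on the elastic subsystem, which is conservative in
// mass with numerical flux Fhat_{i+1/2} = (Q_{i+1} + Qp_i)/2. Boundary
// nodes are closed with half-cell finite-volume continuity against that
// same numerical flux, coupled to the physical condition (prescribed
// inflow, RCR windkessel, or junction mass + total-pressure continuity
// solved by Newton), so global mass conservation holds by construction.
// The viscoelastic pressure contribution is applied by operator splitting
// as an implicit diffusion on Q (tridiagonal solve per segment).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Segment {
  int off;      // first node index in global arrays
  int n;        // number of nodes
  double dx;
};

// linear interpolation of the periodic inflow waveform
double inflow_at(const std::vector<double>& qt, const std::vector<double>& qy,
                 double period, double t) {
  double tau = t - period * std::floor(t / period);
  if (tau < 0) tau += period;
  if (tau >= period) tau = 0.0;
  size_t n = qt.size();
  double dt = qt[1] - qt[0];
  size_t i = (size_t)(tau / dt);
  if (i >= n - 1) {
    double w = (tau - qt[n - 1]) / (period - qt[n - 1]);
    return (1 - w) * qy[n - 1] + w * qy[0];
  }
  double w = (tau - qt[i]) / dt;
  return (1 - w) * qy[i] + w * qy[i + 1];
}

// solve a small dense linear system in place (partial pivoting)
bool solve_dense(std::vector<double>& J, std::vector<double>& r, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(J[col * n + col]);
    for (int row = col + 1; row < n; ++row) {
      double v = std::fabs(J[row * n + col]);
      if (v > best) { best = v; piv = row; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int k = 0; k < n; ++k) std::swap(J[col * n + k], J[piv * n + k]);
      std::swap(r[col], r[piv]);
    }
    double d = J[col * n + col];
    for (int row = col + 1; row < n; ++row) {
      double f = J[row * n + col] / d;
      if (f == 0.0) continue;
      for (int k = col; k < n; ++k) J[row * n + k] -= f * J[col * n + k];
      r[row] -= f * r[col];
    }
  }
  for (int row = n - 1; row >= 0; --row) {
    double s = r[row];
    for (int k = row + 1; k < n; ++k) s -= J[row * n + k] * r[k];
    r[row] = s / J[row * n + row];
  }
  return true;
}

struct Solver {
  // geometry / wall properties per node
  std::vector<double> Ad, beta, gvis, cf;
  std::vector<Segment> seg;
  double rho, mu, alpha, fric;  // fric = 8*pi (parabolic) or 22*pi (flat)
  double Pd;

  // topology
  int inlet_seg;
  std::vector<int> jn_parent;
  std::vector<std::vector<int>> jn_dtrs;

  // windkessel outlets
  std::vector<int> out_seg;
  std::vector<double> R1, R2, Cw, Pout, Pc;

  // state
  std::vector<double> A, Q, P, Ap, Qp, Pp, An, Qn;
  // per-segment near-boundary numerical fluxes of the current step
  std::vector<double> FL, FR;
  std::vector<double> tri_a, tri_b, tri_c, tri_d;

  double dt;

  double pel(int i, double a) const {
    return Pd + beta[i] / Ad[i] * (std::sqrt(a) - std::sqrt(Ad[i]));
  }
  double dpel(int i, double a) const {
    return beta[i] / (2.0 * Ad[i] * std::sqrt(a));
  }
  double cspeed(int i, double a) const { return cf[i] * std::pow(a, 0.25); }

  void check_state(double t) const {
    for (size_t s = 0; s < seg.size(); ++s) {
      for (int i = seg[s].off; i < seg[s].off + seg[s].n; ++i) {
        if (!std::isfinite(A[i]) || A[i] <= 0.0 || !std::isfinite(Q[i])) {
          stop("solver blow-up: non-physical state (segment %d, node %d, t = %g s, A = %g, Q = %g)",
               (int)s + 1, i - seg[s].off + 1, t, A[i], Q[i]);
        }
      }
    }
  }

  // ---- interior update (elastic subsystem) ---------------------------
  void interior_step() {
    for (size_t s = 0; s < seg.size(); ++s) {
      const Segment& sg = seg[s];
      double lam = dt / sg.dx;
      for (int i = sg.off; i < sg.off + sg.n; ++i) P[i] = pel(i, A[i]);
      // predictor: forward differences (last node held)
      for (int i = sg.off; i < sg.off + sg.n - 1; ++i) {
        double f0 = alpha * Q[i] * Q[i] / A[i];
        double f1 = alpha * Q[i + 1] * Q[i + 1] / A[i + 1];
        Ap[i] = A[i] - lam * (Q[i + 1] - Q[i]);
        Qp[i] = Q[i] - lam * (f1 - f0) - lam * (A[i] / rho) * (P[i + 1] - P[i])
                - dt * fric * (mu / rho) * Q[i] / A[i];
        if (Ap[i] <= 0) Ap[i] = 1e-3 * Ad[i];
      }
      int iN = sg.off + sg.n - 1;
      Ap[iN] = A[iN];
      Qp[iN] = Q[iN];
      for (int i = sg.off; i < sg.off + sg.n; ++i) Pp[i] = pel(i, Ap[i]);
      // corrector: backward differences, averaged
      for (int i = sg.off + 1; i < sg.off + sg.n - 1; ++i) {
        double f0 = alpha * Qp[i - 1] * Qp[i - 1] / Ap[i - 1];
        double f1 = alpha * Qp[i] * Qp[i] / Ap[i];
        An[i] = 0.5 * (A[i] + Ap[i] - lam * (Qp[i] - Qp[i - 1]));
        Qn[i] = 0.5 * (Q[i] + Qp[i] - lam * (f1 - f0)
                       - lam * (Ap[i] / rho) * (Pp[i] - Pp[i - 1])
                       - dt * fric * (mu / rho) * Qp[i] / Ap[i]);
      }
      // the scheme's numerical mass fluxes adjacent to the boundaries
      FL[s] = 0.5 * (Q[sg.off + 1] + Qp[sg.off]);
      FR[s] = 0.5 * (Q[iN] + Qp[iN - 1]);
    }
  }

  // viscoelastic diffusion on Q, implicit (boundary nodes held)
  void visco_step() {
    for (const Segment& sg : seg) {
      int n = sg.n;
      if (n < 3) continue;
      double idx2 = 1.0 / (sg.dx * sg.dx);
      tri_a.assign(n, 0.0); tri_b.assign(n, 0.0);
      tri_c.assign(n, 0.0); tri_d.assign(n, 0.0);
      tri_b[0] = 1.0; tri_d[0] = Qn[sg.off];
      tri_b[n - 1] = 1.0; tri_d[n - 1] = Qn[sg.off + n - 1];
      for (int k = 1; k < n - 1; ++k) {
        int i = sg.off + k;
        double m = dt * (A[i] / rho) * idx2;
        double gl = 0.5 * (gvis[i - 1] + gvis[i]);
        double gr = 0.5 * (gvis[i] + gvis[i + 1]);
        tri_a[k] = -m * gl;
        tri_c[k] = -m * gr;
        tri_b[k] = 1.0 + m * (gl + gr);
        tri_d[k] = Qn[i];
      }
      for (int k = 1; k < n; ++k) {
        double w = tri_a[k] / tri_b[k - 1];
        tri_b[k] -= w * tri_c[k - 1];
        tri_d[k] -= w * tri_d[k - 1];
      }
      Qn[sg.off + n - 1] = tri_d[n - 1] / tri_b[n - 1];
      for (int k = n - 2; k >= 0; --k) {
        tri_d[k] = (tri_d[k] - tri_c[k] * tri_d[k + 1]) / tri_b[k];
        Qn[sg.off + k] = tri_d[k];
      }
    }
  }

  // ---- boundary closures ---------------------------------------------
  // inlet: Q prescribed; A from half-cell continuity
  void inlet_bc(double qbc) {
    const Segment& sg = seg[inlet_seg];
    int i0 = sg.off;
    double lam2 = 2.0 * dt / sg.dx;
    Qn[i0] = qbc;
    An[i0] = A[i0] - lam2 * (FL[inlet_seg] - qbc);
  }

  // windkessel outlet: half-cell continuity + RCR coupling; scalar Newton
  // in Q (monotone)
  void outlet_bc(int k) {
    int s = out_seg[k];
    const Segment& sg = seg[s];
    int iN = sg.off + sg.n - 1;
    double lam2 = 2.0 * dt / sg.dx;
    double fr = FR[s];
    auto area_of = [&](double q) { return A[iN] - lam2 * (q - fr); };
    auto g = [&](double q) {
      double a = area_of(q);
      if (a <= 0) a = 1e-6 * Ad[iN];
      return q - (pel(iN, a) - Pc[k]) / R1[k];
    };
    double q = Q[iN];
    // bracket around the previous flow
    double span = std::max(std::fabs(q), 1e-7);
    double lo = q - 50 * span, hi = q + 50 * span;
    double glo = g(lo), ghi = g(hi);
    int guard = 0;
    while (glo * ghi > 0 && guard++ < 40) {
      lo -= 100 * span; hi += 100 * span; glo = g(lo); ghi = g(hi);
    }
    if (glo * ghi > 0) stop("solver blow-up: outlet %d coupling has no root", k + 1);
    for (int it = 0; it < 80; ++it) {
      q = 0.5 * (lo + hi);
      double gq = g(q);
      if (gq == 0) break;
      if (gq * glo > 0) { lo = q; glo = gq; } else { hi = q; }
    }
    double a = area_of(q);
    if (a <= 0) stop("solver blow-up: outlet %d area collapsed", k + 1);
    An[iN] = a;
    Qn[iN] = q;
    // compliant pressure: implicit Euler (unconditionally stable)
    Pc[k] = (Pc[k] + dt / Cw[k] * (q + Pout[k] / R2[k])) /
            (1.0 + dt / (R2[k] * Cw[k]));
  }

  // junction: unknown flows Q_v of the attached vessel endpoints; areas
  // substituted from half-cell continuity; mass + total-pressure Newton
  void junction_bc(int j) {
    int ps = jn_parent[j];
    const Segment& psg = seg[ps];
    const std::vector<int>& dtr = jn_dtrs[j];
    int m = 1 + (int)dtr.size();
    std::vector<int> node(m), sid(m);
    std::vector<double> lam2(m), fnear(m), sgn(m);
    node[0] = psg.off + psg.n - 1;
    sid[0] = ps;
    lam2[0] = 2.0 * dt / psg.dx;
    fnear[0] = FR[ps];
    sgn[0] = -1.0;  // parent end: dA = +lam2 (Fnear - Q)
    for (int d = 0; d < m - 1; ++d) {
      int s = dtr[d];
      node[d + 1] = seg[s].off;
      sid[d + 1] = s;
      lam2[d + 1] = 2.0 * dt / seg[s].dx;
      fnear[d + 1] = FL[s];
      sgn[d + 1] = +1.0; // daughter start: dA = +lam2 (Q - Fnear)
    }
    std::vector<double> q(m), a(m);
    for (int v = 0; v < m; ++v) q[v] = Q[node[v]];

    // half-cell continuity: parent end A + lam2 (Fnear - Q);
    // daughter start A + lam2 (Q - Fnear)
    auto area_v = [&](int v, double qv) {
      return (v == 0) ? A[node[0]] + lam2[0] * (fnear[0] - qv)
                      : A[node[v]] + lam2[v] * (qv - fnear[v]);
    };
    auto darea_v = [&](int v) { return (v == 0) ? -lam2[0] : lam2[v]; };

    std::vector<double> r(m), J(m * m);
    bool ok = false;
    for (int it = 0; it < 100; ++it) {
      for (int v = 0; v < m; ++v) {
        a[v] = area_v(v, q[v]);
        if (a[v] <= 0 || !std::isfinite(a[v])) a[v] = 1e-3 * Ad[node[v]];
      }
      std::fill(J.begin(), J.end(), 0.0);
      // row 0: mass
      r[0] = q[0];
      J[0] = 1.0;
      for (int v = 1; v < m; ++v) {
        r[0] -= q[v];
        J[v] = -1.0;
      }
      // rows v: total pressure continuity parent vs daughter v
      double up = q[0] / a[0];
      double dPdQ0 = dpel(node[0], a[0]) * darea_v(0);
      double dudq0 = (a[0] - q[0] * darea_v(0)) / (a[0] * a[0]);
      for (int v = 1; v < m; ++v) {
        double uv = q[v] / a[v];
        r[v] = pel(node[0], a[0]) + 0.5 * rho * up * up
             - pel(node[v], a[v]) - 0.5 * rho * uv * uv;
        double dPdQv = dpel(node[v], a[v]) * darea_v(v);
        double dudqv = (a[v] - q[v] * darea_v(v)) / (a[v] * a[v]);
        J[v * m + 0] = dPdQ0 + rho * up * dudq0;
        J[v * m + v] = -dPdQv - rho * uv * dudqv;
      }
      double cref = std::max(1.0, cspeed(node[0], Ad[node[0]]));
      double aref = Ad[node[0]];
      double rn = std::fabs(r[0]) / (aref * cref);
      for (int v = 1; v < m; ++v) {
        rn = std::max(rn, std::fabs(r[v]) / (rho * cref * cref));
      }
      if (rn < 1e-12) { ok = true; break; }
      std::vector<double> Jc(J), rc(r);
      if (!solve_dense(Jc, rc, m)) break;
      for (int v = 0; v < m; ++v) q[v] -= rc[v];
    }
    if (!ok) stop("solver error: junction %d Newton iteration did not converge", j + 1);
    for (int v = 0; v < m; ++v) {
      An[node[v]] = area_v(v, q[v]);
      Qn[node[v]] = q[v];
    }
  }

  void step(double t_new, const std::vector<double>& qt,
            const std::vector<double>& qy, double period) {
    interior_step();
    inlet_bc(inflow_at(qt, qy, period, t_new));
    for (size_t k = 0; k < out_seg.size(); ++k) outlet_bc((int)k);
    for (size_t j = 0; j < jn_parent.size(); ++j) junction_bc((int)j);
    visco_step();
    std::swap(A, An);
    std::swap(Q, Qn);
    check_state(t_new);
  }

  double conduit_volume() const {
    double v = 0.0;
    for (const Segment& sg : seg) {
      for (int i = sg.off; i < sg.off + sg.n - 1; ++i) {
        v += 0.5 * (A[i] + A[i + 1]) * sg.dx;
      }
    }
    return v;
  }

  double segment_volume(int s) const {
    const Segment& sg = seg[s];
    double v = 0.0;
    for (int i = sg.off; i < sg.off + sg.n - 1; ++i) {
      v += 0.5 * (A[i] + A[i + 1]) * sg.dx;
    }
    return v;
  }

  // total pressure (elastic + viscoelastic) at a node, dA/dt = -dQ/dx
  double ptotal(int s, int i) const {
    const Segment& sg = seg[s];
    double dqdx;
    if (i == sg.off) dqdx = (Q[i + 1] - Q[i]) / sg.dx;
    else if (i == sg.off + sg.n - 1) dqdx = (Q[i] - Q[i - 1]) / sg.dx;
    else dqdx = (Q[i + 1] - Q[i - 1]) / (2.0 * sg.dx);
    return pel(i, A[i]) - gvis[i] * dqdx;
  }
};

} // namespace

// [[Rcpp::export(name = ".pw_solve")]]
List pw_solve(IntegerVector seg_n, NumericVector seg_dx,
              NumericVector Ad, NumericVector beta, NumericVector gvis,
              double rho, double mu, double alpha, double fric, double Pd,
              int inlet_seg,
              IntegerVector jn_parent, List jn_daughters,
              IntegerVector out_seg, NumericVector R1, NumericVector R2,
              NumericVector Cw, NumericVector Pout, NumericVector Pc0,
              NumericVector inflow_t, NumericVector inflow_y, double period,
              double cfl, int max_cycles, double tol,
              IntegerVector site_seg, NumericVector site_frac,
              IntegerVector vol_seg) {
  Solver sv;
  int nseg = seg_n.size();
  sv.seg.resize(nseg);
  int off = 0;
  for (int s = 0; s < nseg; ++s) {
    sv.seg[s].off = off;
    sv.seg[s].n = seg_n[s];
    sv.seg[s].dx = seg_dx[s];
    off += seg_n[s];
  }
  int nnode = off;
  sv.Ad.assign(Ad.begin(), Ad.end());
  sv.beta.assign(beta.begin(), beta.end());
  sv.gvis.assign(gvis.begin(), gvis.end());
  sv.rho = rho; sv.mu = mu; sv.alpha = alpha; sv.fric = fric; sv.Pd = Pd;
  sv.inlet_seg = inlet_seg;
  sv.cf.resize(nnode);
  for (int i = 0; i < nnode; ++i) {
    sv.cf[i] = std::sqrt(sv.beta[i] / (2.0 * rho * sv.Ad[i]));
  }
  sv.jn_parent.assign(jn_parent.begin(), jn_parent.end());
  for (int j = 0; j < jn_parent.size(); ++j) {
    IntegerVector d = jn_daughters[j];
    sv.jn_dtrs.push_back(std::vector<int>(d.begin(), d.end()));
  }
  sv.out_seg.assign(out_seg.begin(), out_seg.end());
  sv.R1.assign(R1.begin(), R1.end());
  sv.R2.assign(R2.begin(), R2.end());
  sv.Cw.assign(Cw.begin(), Cw.end());
  sv.Pout.assign(Pout.begin(), Pout.end());
  sv.Pc.assign(Pc0.begin(), Pc0.end());

  sv.A.assign(sv.Ad.begin(), sv.Ad.end());
  sv.Q.assign(nnode, 0.0);
  sv.P.assign(nnode, 0.0);
  sv.Ap = sv.A; sv.Qp = sv.Q; sv.Pp = sv.P; sv.An = sv.A; sv.Qn = sv.Q;
  sv.FL.assign(nseg, 0.0);
  sv.FR.assign(nseg, 0.0);

  std::vector<double> qt(inflow_t.begin(), inflow_t.end());
  std::vector<double> qy(inflow_y.begin(), inflow_y.end());

  // time step: advective CFL with margin for systolic pressurisation and
  // flow velocity (the implicit viscoelastic split adds no constraint)
  double dtmin = 1e9;
  for (int s = 0; s < nseg; ++s) {
    const Segment& sg = sv.seg[s];
    for (int i = sg.off; i < sg.off + sg.n; ++i) {
      double cd = sv.cspeed(i, sv.Ad[i]);
      dtmin = std::min(dtmin, sg.dx / (2.0 + 1.2 * cd));
    }
  }
  int steps = (int)std::ceil(period / (cfl * dtmin));
  sv.dt = period / steps;

  int root_node = sv.seg[inlet_seg].off;
  std::vector<double> root_prev(steps), root_cur(steps);
  std::vector<double> residuals;
  bool converged = false;
  int cycles_run = 0;
  double t = 0.0;

  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    for (int k = 0; k < steps; ++k) {
      t += sv.dt;
      sv.step(t, qt, qy, period);
      root_cur[k] = sv.pel(root_node, sv.A[root_node]);
    }
    cycles_run = cyc + 1;
    if (cyc >= 1) {
      double dmax = 0.0, lo = root_cur[0], hi = root_cur[0];
      for (int k = 0; k < steps; ++k) {
        dmax = std::max(dmax, std::fabs(root_cur[k] - root_prev[k]));
        lo = std::min(lo, root_cur[k]);
        hi = std::max(hi, root_cur[k]);
      }
      double res = dmax / std::max(hi - lo, 1e-12);
      residuals.push_back(res);
      if (res < tol) { converged = true; }
    }
    std::swap(root_prev, root_cur);
    if (converged) break;
    Rcpp::checkUserInterrupt();
  }

  // recording cycle
  int nsite = site_seg.size();
  int nout = (int)sv.out_seg.size();
  int nvol = vol_seg.size();
  NumericMatrix recP(steps, nsite), recQ(steps, nsite), recA(steps, nsite),
      recU(steps, nsite);
  NumericMatrix recPc(steps, nout), recV(steps, nout);
  NumericMatrix recVol(steps, nvol);
  NumericVector rec_t(steps);

  double v_in = 0.0;
  std::vector<double> v_out(nout, 0.0);
  double vol0 = sv.conduit_volume();
  std::vector<double> wk0(nout);
  for (int k = 0; k < nout; ++k) wk0[k] = sv.Cw[k] * (sv.Pc[k] - sv.Pout[k]);

  std::vector<int> s_i0(nsite);
  std::vector<double> s_w(nsite);
  for (int s = 0; s < nsite; ++s) {
    const Segment& sg = sv.seg[site_seg[s]];
    double pos = site_frac[s] * (sg.n - 1);
    int i0 = std::min((int)pos, sg.n - 2);
    s_i0[s] = i0;
    s_w[s] = pos - i0;
  }

  double t0 = t;
  for (int k = 0; k < steps; ++k) {
    t += sv.dt;
    double qbc = inflow_at(qt, qy, period, t);
    sv.step(t, qt, qy, period);
    rec_t[k] = t - t0;
    v_in += qbc * sv.dt;
    for (int s = 0; s < nsite; ++s) {
      const Segment& sg = sv.seg[site_seg[s]];
      int i = sg.off + s_i0[s];
      double w = s_w[s];
      double a = (1 - w) * sv.A[i] + w * sv.A[i + 1];
      double q = (1 - w) * sv.Q[i] + w * sv.Q[i + 1];
      double p = (1 - w) * sv.ptotal(site_seg[s], i) +
                 w * sv.ptotal(site_seg[s], i + 1);
      recA(k, s) = a;
      recQ(k, s) = q;
      recP(k, s) = p;
      recU(k, s) = q / a;
    }
    for (int o = 0; o < nout; ++o) {
      const Segment& sg = sv.seg[sv.out_seg[o]];
      int iN = sg.off + sg.n - 1;
      v_out[o] += sv.Q[iN] * sv.dt;
      recPc(k, o) = sv.Pc[o];
      recV(k, o) = sv.Cw[o] * (sv.Pc[o] - sv.Pout[o]);
    }
    for (int v = 0; v < nvol; ++v) recVol(k, v) = sv.segment_volume(vol_seg[v]);
  }
  double d_conduit = sv.conduit_volume() - vol0;
  NumericVector d_wk(nout);
  for (int k = 0; k < nout; ++k) {
    d_wk[k] = sv.Cw[k] * (sv.Pc[k] - sv.Pout[k]) - wk0[k];
  }

  return List::create(
      _["t"] = rec_t, _["P"] = recP, _["Q"] = recQ, _["A"] = recA,
      _["U"] = recU, _["wk_Pc"] = recPc, _["wk_V"] = recV,
      _["seg_vol"] = recVol,
      _["n_cycles"] = cycles_run, _["converged"] = converged,
      _["residuals"] = NumericVector(residuals.begin(), residuals.end()),
      _["dt"] = sv.dt, _["steps_per_cycle"] = steps,
      _["mass"] = List::create(_["v_in"] = v_in,
                               _["v_out"] = NumericVector(v_out.begin(), v_out.end()),
                               _["d_conduit"] = d_conduit,
                               _["d_windkessel"] = d_wk));
}
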