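#include <Rcpp.h>
#include <unordered_map>
#include <functional>
using namespace Rcpp;

// Explicit upwind finite-volume advection + central axial diffusion on a
// network of 1-D control volumes.
//
// Faces are described by donor/receiver CV indices (0-based; from = -1 marks
// the inlet face, to = -2 an outlet face). The advective flow through face f
// at step k is Q[f] * mult[k] + Qosc[f] * osc[k] (pulsatile multiplier plus
// the compliance-driven oscillatory component). perm scales the diffusive
// conductance of a face and gates advection: perm == 0 models a fully
// occlusive thrombus face (no flux at all).
//
// Outlet backflow (oscillatory flow reversing at a leaf) re-enters at the
// leaf's own concentration: the distal compliance volume returns the fluid
// it just stored, which reproduces the reversibility of Stokes flow (zero
// net transport from pure oscillation).
//
// Records the CV concentrations every `record_every` steps (after stepping),
// starting with the initial state if record_initial is true.
// [[Rcpp::export]]
List advect_network_cpp(NumericVector conc0,
                        NumericVector vol,
                        IntegerVector face_from,
                        IntegerVector face_to,
                        NumericVector face_area,
                        NumericVector face_dx,
                        NumericVector face_Q,
                        NumericVector face_Qosc,
                        NumericVector face_perm,
                        double D,
                        double dt,
                        NumericVector mult,
                        NumericVector osc,
                        NumericVector cin,
                        int record_every,
                        bool record_initial,
                        double mass_in0,
                        double mass_out0) {
  const int ncv = conc0.size();
  const int nf = face_from.size();
  const int nsteps = mult.size();
  std::vector<double> c(conc0.begin(), conc0.end());
  std::vector<double> dc(ncv, 0.0);

  int nrec = nsteps / record_every + (record_initial ? 1 : 0);
  NumericMatrix rec(nrec, ncv);
  int irec = 0;
  if (record_initial) {
    for (int i = 0; i < ncv; ++i) rec(0, i) = c[i];
    irec = 1;
  }

  double mass_in = mass_in0, mass_out = mass_out0;

  for (int k = 0; k < nsteps; ++k) {
    const double m = mult[k], o = osc[k], ci = cin[k];
    std::fill(dc.begin(), dc.end(), 0.0);
    for (int f = 0; f < nf; ++f) {
      const double perm = face_perm[f];
      if (perm <= 0.0) continue;
      const double Q = face_Q[f] * m + face_Qosc[f] * o;
      const int a = face_from[f], b = face_to[f];
      double cup;
      if (Q >= 0.0) {
        cup = (a == -1) ? ci : c[a];
      } else {
        cup = (b == -2) ? c[a] : c[b];  // outlet backflow returns leaf conc
      }
      const double adv = Q * cup;
      double dif = 0.0;
      if (a >= 0 && b >= 0) {
        dif = D * perm * face_area[f] / face_dx[f] * (c[a] - c[b]);
      }
      const double flux = adv + dif;   // positive: a -> b
      if (a >= 0) dc[a] -= flux;
      else mass_in += flux * dt;
      if (b >= 0) dc[b] += flux;
      else mass_out += flux * dt;
    }
    for (int i = 0; i < ncv; ++i) {
      c[i] += dt * dc[i] / vol[i];
      if (c[i] < 0.0) c[i] = 0.0;
      else if (c[i] > 1.0) c[i] = 1.0;
    }
    if ((k + 1) % record_every == 0) {
      for (int i = 0; i < ncv; ++i) rec(irec, i) = c[i];
      ++irec;
    }
  }
  return List::create(_["records"] = rec,
                      _["conc"] = NumericVector(c.begin(), c.end()),
                      _["mass_in"] = mass_in,
                      _["mass_out"] = mass_out);
}

// 8-connectivity connected-component labelling of a pixel set given by
// (row, col) pairs (1-based, arbitrary order). Returns a component id per
// pixel (1-based, components numbered by first appearance).
// [[Rcpp::export]]
IntegerVector label8_cpp(IntegerVector row, IntegerVector col, int nrow) {
  const int n = row.size();
  std::unordered_map<long long, int> index;
  index.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    index[(long long)col[i] * (nrow + 2) + row[i]] = i;

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dcl = -1; dcl <= 1; ++dcl) {
        if (dr == 0 && dcl == 0) continue;
        auto it = index.find((long long)(col[i] + dcl) * (nrow + 2) + (row[i] + dr));
        if (it != index.end()) {
          int ra = find(i), rb = find(it->second);
          if (ra != rb) parent[rb] = ra;
        }
      }
    }
  }
  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}

// Piecewise-linear per-pixel calibration inversion. I is (time x pixel),
// knots is (nlevel x pixel) mean intensities oriented DECREASING with level,
// levels ascending. Values beyond the end knots clamp to the end levels.
// [[Rcpp::export]]
NumericMatrix invert_calibration_cpp(NumericMatrix I, NumericMatrix knots,
                                     NumericVector levels,
                                     LogicalVector valid) {
  const int nt = I.nrow(), np = I.ncol(), nl = levels.size();
  NumericMatrix out(nt, np);
  for (int p = 0; p < np; ++p) {
    if (!valid[p]) {
      for (int t = 0; t < nt; ++t) out(t, p) = NA_REAL;
      continue;
    }
    for (int t = 0; t < nt; ++t) {
      const double x = I(t, p);
      if (x >= knots(0, p)) { out(t, p) = levels[0]; continue; }
      if (x <= knots(nl - 1, p)) { out(t, p) = levels[nl - 1]; continue; }
      int j = 0;
      while (j < nl - 2 && x <= knots(j + 1, p)) ++j;
      const double hi = knots(j, p), lo = knots(j + 1, p);
      const double frac = (hi - x) / (hi - lo);
      out(t, p) = levels[j] + frac * (levels[j + 1] - levels[j]);
    }
  }
  return out;
}

// column maxima, NA-propagating
// [[Rcpp::export]]
NumericVector col_max_cpp(NumericMatrix X) {
  const int nt = X.nrow(), np = X.ncol();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double m = R_NegInf; bool na = false;
    for (int t = 0; t < nt; ++t) {
      const double v = X(t, p);
      if (ISNAN(v)) { na = true; break; }
      if (v > m) m = v;
    }
    out[p] = na ? NA_REAL : m;
  }
  return out;
}
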