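#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward-Euler integration of the four-field
// activator (A) / inhibitor (H) / substrate (S) / cytoskeleton (Y) system:
//
//   dA/dt = c A^2 S / H - mu A + (rho_A + delta_A) Y + D_A lap(A)
//   dH/dt = c A^2 S     - nu H + (rho_H + delta_H) Y + D_H lap(H)
//   dS/dt = c0 - gamma S - eps Y S                   + D_S lap(S)
//   dY/dt = d A - e Y + Y^2 / (1 + f Y^2)
//
// 5-point Laplacian / dx^2 with zero-flux (mirror) boundaries.
// H is clamped to h_floor inside the A-equation denominator only.
// Negative values are clamped to zero after each step (counted).
//
// Parameter vector layout (16):
//   0 c, 1 mu, 2 nu, 3 rho_A, 4 rho_H, 5 delta_A, 6 delta_H,
//   7 c0, 8 gamma, 9 epsilon, 10 D_A, 11 D_H, 12 D_S, 13 d, 14 e, 15 f

static void check_finite(const NumericMatrix& M, const char* name,
                         long step) {
  for (R_xlen_t i = 0; i < M.size(); ++i) {
    if (!R_finite(M[i])) {
      stop("non-finite value in field %s after step %ld", name, step);
    }
  }
}

// [[Rcpp::export]]
List rd_sim_cpp(NumericMatrix A0, NumericMatrix H0,
                NumericMatrix S0, NumericMatrix Y0,
                NumericVector par, double dx, double dt,
                int n_steps, int record_every, double h_floor,
                int check_every = 200) {
  const int nr = A0.nrow(), nc = A0.ncol();
  NumericMatrix A = clone(A0), H = clone(H0), S = clone(S0), Y = clone(Y0);
  NumericMatrix An(nr, nc), Hn(nr, nc), Sn(nr, nc), Yn(nr, nc);

  const double c = par[0], mu = par[1], nu = par[2];
  const double rA = par[3] + par[5], rH = par[4] + par[6];
  const double c0 = par[7], g = par[8], eps = par[9];
  const double DA = par[10], DH = par[11], DS = par[12];
  const double d = par[13], e = par[14], f = par[15];
  const double idx2 = 1.0 / (dx * dx);

  long clamps = 0;
  List snaps;
  IntegerVector snap_steps;

  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < nc; ++j) {
      const int jl = j > 0 ? j - 1 : j, jr = j < nc - 1 ? j + 1 : j;
      for (int i = 0; i < nr; ++i) {
        const int iu = i > 0 ? i - 1 : i, id = i < nr - 1 ? i + 1 : i;
        const double a = A(i, j), h = H(i, j), ss = S(i, j), y = Y(i, j);
        const double lapA =
            (A(iu, j) + A(id, j) + A(i, jl) + A(i, jr) - 4.0 * a) * idx2;
        const double lapH =
            (H(iu, j) + H(id, j) + H(i, jl) + H(i, jr) - 4.0 * h) * idx2;
        const double lapS =
            (S(iu, j) + S(id, j) + S(i, jl) + S(i, jr) - 4.0 * ss) * idx2;
        const double hd = h < h_floor ? h_floor : h;
        const double auto_cat = c * a * a * ss;
        double an = a + dt * (auto_cat / hd - mu * a + rA * y + DA * lapA);
        double hn = h + dt * (auto_cat - nu * h + rH * y + DH * lapH);
        double sn = ss + dt * (c0 - g * ss - eps * y * ss + DS * lapS);
        double yn = y + dt * (d * a - e * y + y * y / (1.0 + f * y * y));
        if (an < 0) { an = 0; ++clamps; }
        if (hn < 0) { hn = 0; ++clamps; }
        if (sn < 0) { sn = 0; ++clamps; }
        if (yn < 0) { yn = 0; ++clamps; }
        An(i, j) = an; Hn(i, j) = hn; Sn(i, j) = sn; Yn(i, j) = yn;
      }
    }
    std::swap(A, An); std::swap(H, Hn);
    std::swap(S, Sn); std::swap(Y, Yn);

    if (check_every > 0 && (s % check_every == 0 || s == n_steps)) {
      check_finite(A, "A", s); check_finite(H, "H", s);
      check_finite(S, "S", s); check_finite(Y, "Y", s);
    }
    if (record_every > 0 && s % record_every == 0 && s != n_steps) {
      snaps.push_back(List::create(_["A"] = clone(A), _["H"] = clone(H),
                                   _["S"] = clone(S), _["Y"] = clone(Y)));
      snap_steps.push_back(s);
    }
  }
  // final state always recorded (if any step was taken)
  if (n_steps > 0) {
    snaps.push_back(List::create(_["A"] = A, _["H"] = H,
                                 _["S"] = S, _["Y"] = Y));
    snap_steps.push_back(n_steps);
  }
  return List::create(_["snapshots"] = snaps, _["steps"] = snap_steps,
                      _["clamp_count"] = (double)clamps);
}
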