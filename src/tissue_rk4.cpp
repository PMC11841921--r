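#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classical RK4 for a lattice of cells coupled through
// neighbour-averaged trans-ligand (and trans-Notch) inputs. Species
// columns: D, J, C, N, S and, for the VEGF model, R, V. Trans inputs are
// recomputed at every RK4 stage from the stage state, so the coupled
// system is integrated consistently at O(h^4).

struct Pars {
  double bN, bR, beta, betaS, kho, khe, kt, kci, kv, alpha;
  double thD, lamD, nD, thR, lamR, nR;
};

static inline double hillf(double x, double th, double lam, double n) {
  double xn = std::pow(x, n), tn = std::pow(th, n);
  return (lam * xn + tn) / (xn + tn);
}

// derivative of the full lattice state; y and dy are n x ns (col-major)
static void rhs_all(const NumericMatrix::const_iterator /*unused*/,
                    const std::vector<double> &y, std::vector<double> &dy,
                    int n, int ns, int model, const Pars &P,
                    const std::vector<double> &bD_cell,
                    const std::vector<double> &bJ_cell,
                    const std::vector<int> &nb, const std::vector<int> &nb_start,
                    const std::vector<double> &div,
                    const std::vector<double> &dext_add,
                    const std::vector<double> &jext_add,
                    const std::vector<double> &vegf) {
  // column offsets
  const int oD = 0, oJ = n, oC = 2 * n, oN = 3 * n, oS = 4 * n;
  const int oR = 5 * n, oV = 6 * n;
  for (int i = 0; i < n; ++i) {
    double sD = 0.0, sJ = 0.0, sN = 0.0;
    for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
      int j = nb[k];
      sD += y[oD + j];
      sJ += y[oJ + j];
      sN += y[oN + j];
    }
    double Dext = sD / div[i] + dext_add[i];
    double Jext = sJ / div[i] + jext_add[i];
    double Next = sN / div[i];
    double D = y[oD + i], J = y[oJ + i], C = y[oC + i], N = y[oN + i],
           S = y[oS + i];
    double prodD = bD_cell[i];
    if (model == 2) prodD *= hillf(y[oV + i], P.thD, P.lamD, P.nD);
    dy[oD + i] = prodD - P.beta * D - 2.0 * P.kho * D * D -
                 P.khe * J * D - P.kt * Next * D;
    dy[oJ + i] = bJ_cell[i] - P.beta * J - P.khe * D * J -
                 P.alpha * P.kt * Next * J;
    dy[oC + i] = P.kho * D * D - P.beta * C - P.kci * N * C;
    dy[oN + i] = P.bN - P.beta * N - P.kci * C * N - P.kt * Dext * N -
                 P.alpha * P.kt * Jext * N;
    dy[oS + i] = P.kt * Dext * N + P.alpha * P.kt * Jext * N -
                 P.betaS * S;
    if (model == 2) {
      double R = y[oR + i], V = y[oV + i];
      dy[oR + i] = hillf(S, P.thR, P.lamR, P.nR) * P.bR - P.beta * R -
                   P.kv * vegf[i] * R;
      dy[oV + i] = P.kv * vegf[i] * R - P.betaS * V;
    }
  }
}

// [[Rcpp::export]]
List tissue_rk4_cpp(NumericMatrix y0, int model, List par,
                    NumericVector bD_cell, NumericVector bJ_cell,
                    IntegerVector nb_flat, IntegerVector nb_start,
                    NumericVector div, NumericVector dext_add,
                    NumericVector jext_add, NumericVector vegf,
                    double h, int n_steps, int check_every,
                    double steady_tol, int record_every) {
  const int n = y0.nrow(), ns = y0.ncol();
  const int m = n * ns;
  Pars P;
  P.bN = par["bN"]; P.bR = par["bR"]; P.beta = par["beta"];
  P.betaS = par["betaS"]; P.kho = par["kho"]; P.khe = par["khe"];
  P.kt = par["kt"]; P.kci = par["kci"]; P.kv = par["kv"];
  P.alpha = par["alpha"];
  P.thD = par["thD"]; P.lamD = par["lamD"]; P.nD = par["nD"];
  P.thR = par["thR"]; P.lamR = par["lamR"]; P.nR = par["nR"];

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> bd(bD_cell.begin(), bD_cell.end());
  std::vector<double> bj(bJ_cell.begin(), bJ_cell.end());
  std::vector<int> nb(nb_flat.begin(), nb_flat.end());
  std::vector<int> nbs(nb_start.begin(), nb_start.end());
  std::vector<double> dv(div.begin(), div.end());
  std::vector<double> da(dext_add.begin(), dext_add.end());
  std::vector<double> ja(jext_add.begin(), jext_add.end());
  std::vector<double> vg(vegf.begin(), vegf.end());

  std::vector<double> k1(m), k2(m), k3(m), k4(m), tmp(m);
  bool converged = false;
  int step = 0;

  int n_rec = record_every > 0 ? n_steps / record_every + 2 : 0;
  NumericMatrix rec(n_rec > 0 ? n_rec : 1, n_rec > 0 ? m : 1);
  NumericVector rec_t(n_rec > 0 ? n_rec : 1);
  int ri = 0;
  if (n_rec > 0) {
    for (int q = 0; q < m; ++q) rec(0, q) = y[q];
    rec_t[0] = 0.0;
    ri = 1;
  }

  auto deriv = [&](const std::vector<double> &yy, std::vector<double> &dd) {
    rhs_all(nullptr, yy, dd, n, ns, model, P, bd, bj, nb, nbs, dv, da, ja,
            vg);
  };

  while (step < n_steps) {
    deriv(y, k1);
    for (int q = 0; q < m; ++q) tmp[q] = y[q] + 0.5 * h * k1[q];
    deriv(tmp, k2);
    for (int q = 0; q < m; ++q) tmp[q] = y[q] + 0.5 * h * k2[q];
    deriv(tmp, k3);
    for (int q = 0; q < m; ++q) tmp[q] = y[q] + h * k3[q];
    deriv(tmp, k4);
    for (int q = 0; q < m; ++q) {
      y[q] += h / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
      if (!std::isfinite(y[q])) {
        stop("tissue_rk4: non-finite state in cell %d at t = %.4g h",
             q % n + 1, (step + 1) * h);
      }
      if (y[q] < 0.0) {
        if (y[q] < -1e-9) {
          stop("tissue_rk4: negative state (%.3e) in cell %d at t = %.4g h",
               y[q], q % n + 1, (step + 1) * h);
        }
        y[q] = 0.0;
      }
    }
    ++step;
    if (n_rec > 0 && step % record_every == 0 && ri < n_rec) {
      for (int q = 0; q < m; ++q) rec(ri, q) = y[q];
      rec_t[ri] = step * h;
      ++ri;
    }
    if (step % check_every == 0 || step == n_steps) {
      deriv(y, k1);
      double mx = 0.0;
      for (int q = 0; q < m; ++q) mx = std::max(mx, std::fabs(k1[q]));
      if (mx < steady_tol) { converged = true; break; }
    }
  }
  deriv(y, k1);
  double resid = 0.0;
  for (int q = 0; q < m; ++q) resid = std::max(resid, std::fabs(k1[q]));

  NumericMatrix out(n, ns);
  std::copy(y.begin(), y.end(), out.begin());
  List res = List::create(_["state"] = out, _["converged"] = converged,
                          _["final_residual"] = resid,
                          _["t_final"] = step * h);
  if (n_rec > 0) {
    if (rec_t[ri - 1] < step * h) {
      for (int q = 0; q < m; ++q) rec(ri, q) = y[q];
      rec_t[ri] = step * h;
      ++ri;
    }
    res["rec"] = rec(Range(0, ri - 1), Range(0, m - 1));
    res["rec_t"] = rec_t[Range(0, ri - 1)];
  }
  return res;
}
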