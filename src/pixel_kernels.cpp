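// Pixel-wise kernels for Mueller image cubes. Each kernel takes an
// n_pixels x 16 matrix of column-major-flattened 4x4 Mueller matrices and
// mirrors the single-matrix R implementations exactly; the R functions are
// the reference, these are the throughput path for whole images.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double NA_R = NA_REAL;

// ---- shared small helpers -------------------------------------------------

static mat unflatten(const rowvec& px) {
  return reshape(mat(px), 4, 4); // column-major, matches R's array layout
}

// Pauli tensor basis sigma_i (x) conj(sigma_j), built once.
static const std::vector<cx_mat>& pauli_basis() {
  static std::vector<cx_mat> basis;
  if (basis.empty()) {
    std::vector<cx_mat> s(4);
    s[0] = cx_mat(eye(2, 2), zeros(2, 2));
    s[1] = cx_mat(mat{{1, 0}, {0, -1}}, zeros(2, 2));
    s[2] = cx_mat(mat{{0, 1}, {1, 0}}, zeros(2, 2));
    s[3] = cx_mat(zeros(2, 2), mat{{0, 1}, {-1, 0}}); // i at (0,1), -i at (1,0)
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) basis.push_back(kron(s[i], conj(s[j])));
  }
  return basis;
}

static vec coherency_eigenvalues(const mat& M) {
  const std::vector<cx_mat>& basis = pauli_basis();
  cx_mat H(4, 4, fill::zeros);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) H += M(i, j) * basis[i * 4 + j];
  H *= 0.25;
  H = (H + H.t()) / 2.0;
  vec ev;
  eig_sym(ev, H);          // ascending
  return reverse(ev);      // descending, to match the R side
}

static double fold_axis(double th) {
  double y = th + M_PI / 2.0;
  double x = y - M_PI * std::floor(y / M_PI); // y mod pi, in [0, pi)
  x -= M_PI / 2.0;
  if (x <= -M_PI / 2.0 + 1e-15) x += M_PI;
  return x;
}

static mat diattenuator_from_vector(const vec& Dv) {
  double D = norm(Dv);
  mat MD = eye(4, 4);
  MD(0, span(1, 3)) = Dv.t();
  MD(span(1, 3), 0) = Dv;
  double s = std::sqrt(std::max(0.0, 1.0 - D * D));
  mat mD = s * eye(3, 3);
  if (D > 0) {
    vec dh = Dv / D;
    mD += (1.0 - s) * (dh * dh.t());
  }
  MD(span(1, 3), span(1, 3)) = mD;
  return MD;
}

static const mat G = diagmat(vec{1, -1, -1, -1});

// ---- realizability screen -------------------------------------------------

// [[Rcpp::export]]
Rcpp::LogicalVector screen_pixels_cpp(const arma::mat& px, const arma::vec& m00,
                                      double tol) {
  const uword n = px.n_rows;
  Rcpp::LogicalVector out(n);
  for (uword p = 0; p < n; ++p) {
    mat M = unflatten(px.row(p));
    if (!M.is_finite() || M(0, 0) <= 0) {
      out[p] = false;
      continue;
    }
    vec ev = coherency_eigenvalues(M);
    double tr = accu(ev);
    bool eig_ok = ev.min() >= -tol * std::max(std::abs(tr), 1e-300);
    mat nm = M / M(0, 0);
    double Dn = norm(nm(0, span(1, 3)));
    double Pn = norm(nm(span(1, 3), 0));
    double M00 = m00[p];
    bool pass_fwd = M00 * (1.0 + Dn) <= 1.0 + tol;
    bool pass_rev = M00 * (1.0 + Pn) <= 1.0 + tol;
    out[p] = eig_ok && pass_fwd && pass_rev;
  }
  return out;
}

// ---- purity / anisotropy --------------------------------------------------

// [[Rcpp::export]]
arma::mat purity_pixels_cpp(const arma::mat& px, const Rcpp::LogicalVector& mask) {
  const uword n = px.n_rows;
  mat out(n, 7);
  out.fill(NA_R);
  for (uword p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    mat M = unflatten(px.row(p));
    if (!M.is_finite() || M(0, 0) <= 0) continue;
    vec ev = coherency_eigenvalues(M);
    ev.elem(find(ev > -1e-9 && ev < 0)).zeros();
    double tr = accu(ev);
    if (tr <= 0) continue;
    vec lh = sort(ev / tr, "descend");
    double P1 = lh[0] - lh[1];
    double P2 = lh[0] + lh[1] - 2 * lh[2];
    double P3 = 1 - 4 * lh[3];
    double Pd = std::sqrt((2 * P1 * P1 + (2.0 / 3.0) * P2 * P2 + P3 * P3 / 3.0) / 3.0);
    out(p, 0) = P1; out(p, 1) = P2; out(p, 2) = P3; out(p, 3) = Pd;

    mat m = M / M(0, 0);
    vec k = {m(1, 1), m(2, 2), m(3, 3)};
    k /= std::sqrt(3.0);
    vec r = {m(2, 3), m(1, 3), m(1, 2)};
    vec q = {m(3, 2), m(3, 1), m(2, 1)};
    vec D = m(0, span(1, 3)).t();
    vec P = m(span(1, 3), 0);
    double Sigma = 3.0 * (1.0 - dot(k, k)) + 2.0 * dot(D, P) - 2.0 * dot(r, q);
    if (Sigma > 1e-12) {
      double aL = (std::pow(D[0] + P[0], 2) + std::pow(r[0] - q[0], 2) +
                   std::pow(D[1] + P[1], 2) + std::pow(r[1] - q[1], 2)) / Sigma;
      double aC = (std::pow(D[2] + P[2], 2) + std::pow(r[2] - q[2], 2)) / Sigma;
      out(p, 4) = aL; out(p, 5) = aC; out(p, 6) = std::sqrt(aL * aL + aC * aC);
    }
  }
  return out;
}

// ---- Lu-Chipman -----------------------------------------------------------

// [[Rcpp::export]]
arma::mat polar_pixels_cpp(const arma::mat& px, const Rcpp::LogicalVector& mask) {
  const uword n = px.n_rows;
  mat out(n, 5);
  out.fill(NA_R);
  for (uword p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    mat M = unflatten(px.row(p));
    if (!M.is_finite() || M(0, 0) <= 0) continue;
    mat m = M / M(0, 0);

    vec Dv = m(0, span(1, 3)).t();
    double D = norm(Dv);
    if (D >= 1 - 1e-9) {
      Dv *= (1 - 1e-9) / D;
      D = 1 - 1e-9;
    }
    mat MD = diattenuator_from_vector(Dv);
    mat Mp = m * inv(MD);
    mat mp = Mp(span(1, 3), span(1, 3));
    vec Pdel = Mp(span(1, 3), 0);

    mat mmT = mp * mp.t();
    vec lam;
    mat Vv;
    if (!eig_sym(lam, Vv, (mmT + mmT.t()) / 2.0)) continue;
    lam = clamp(lam, 0.0, datum::inf);
    double sgn = (det(mp) < 0) ? -1.0 : 1.0;
    mat mdelta = Vv * diagmat(sgn * sqrt(lam)) * Vv.t();

    mat mr;
    bool singular = sqrt(lam).min() < 1e-12;
    if (singular) {
      mr = eye(3, 3);
    } else {
      mr = solve(mdelta, mp);
    }
    double Delta = 1.0 - std::abs(trace(mdelta)) / 3.0;
    double trMR = 1.0 + trace(mr);
    double R = std::acos(std::min(1.0, std::max(-1.0, trMR / 2.0 - 1.0)));

    mat Mdelta = eye(4, 4);
    Mdelta(span(1, 3), 0) = Pdel;
    Mdelta(span(1, 3), span(1, 3)) = mdelta;
    mat MR = eye(4, 4);
    MR(span(1, 3), span(1, 3)) = mr;
    mat recon = Mdelta * MR * MD;
    double resid = norm(m - recon, "fro");

    // retarder split + axis
    double theta = NA_R;
    if (!singular && R > 1e-6 && R < M_PI - 1e-6) {
      mat b = mr;
      double psi = 0.5 * std::atan2(b(1, 0) - b(0, 1), b(0, 0) + b(1, 1));
      double c2 = std::cos(2 * psi), s2 = std::sin(2 * psi);
      mat rot = {{c2, -s2, 0}, {s2, c2, 0}, {0, 0, 1}};
      mat blr = b * rot.t(); // M_LR block = m_R * rot(-psi)
      double num = blr(2, 0) - blr(0, 2);
      double den = blr(1, 2) - blr(2, 1);
      if (std::abs(num) > 1e-9 || std::abs(den) > 1e-9)
        theta = fold_axis(0.5 * std::atan2(num, den));
    }
    out(p, 0) = Delta; out(p, 1) = R; out(p, 2) = D;
    out(p, 3) = theta; out(p, 4) = resid;
  }
  return out;
}

// ---- symmetric decomposition ----------------------------------------------

static bool diatt_from_eigen(const mat& A, vec& Dv) {
  cx_vec ev;
  cx_mat V;
  if (!eig_gen(ev, V, A)) return false;
  vec re = real(ev);
  double scale = std::max(abs(ev).max(), 1e-12);
  if (abs(imag(ev)).max() > 1e-6 * scale) return false;
  if (re.min() < -1e-6 * scale) return false;
  uvec lead = find(re >= re.max() - 1e-7 * scale);
  mat Vr = real(V.cols(lead));
  mat Q, Rq;
  if (!qr_econ(Q, Rq, Vr)) return false;
  vec e1 = {1, 0, 0, 0};
  vec s = Q * (Q.t() * e1);
  if (std::abs(s[0]) < 1e-9) return false;
  s /= s[0];
  Dv = s.subvec(1, 3);
  return true;
}

// [[Rcpp::export]]
arma::mat symmetric_pixels_cpp(const arma::mat& px, const Rcpp::LogicalVector& mask) {
  const uword n = px.n_rows;
  mat out(n, 4);
  out.fill(NA_R);
  for (uword p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    mat M = unflatten(px.row(p));
    if (!M.is_finite() || M(0, 0) <= 0) continue;
    mat m = M / M(0, 0);

    vec D1v, D2v;
    if (!diatt_from_eigen(m.t() * G * m * G, D1v)) continue;
    if (!diatt_from_eigen(m * G * m.t() * G, D2v)) continue;
    double D1 = norm(D1v), D2 = norm(D2v);
    if (D1 > 1 + 1e-6 || D2 > 1 + 1e-6) continue;
    if (D1 >= 1 - 1e-9) D1v *= (1 - 1e-9) / D1;
    if (D2 >= 1 - 1e-9) D2v *= (1 - 1e-9) / D2;

    mat MD1 = diattenuator_from_vector(D1v);
    mat MD2 = diattenuator_from_vector(D2v);
    mat Mp = inv(MD2) * m * inv(MD1);
    double d0 = Mp(0, 0);
    mat U, V;
    vec dd;
    if (!svd(U, dd, V, mat(Mp(span(1, 3), span(1, 3))))) continue;
    if (det(U) < 0) { U.col(2) *= -1; dd[2] *= -1; }
    if (det(V) < 0) { V.col(2) *= -1; dd[2] *= -1; }
    mat MRtot = U * V.t();
    double R = std::acos(std::min(1.0, std::max(-1.0, (1.0 + trace(MRtot)) / 2.0 - 1.0)));
    double Delta = 1.0 - std::abs(accu(dd)) / (3.0 * std::max(d0, 1e-300));
    out(p, 0) = Delta; out(p, 1) = R; out(p, 2) = D1; out(p, 3) = D2;
  }
  return out;
}

// ---- differential decomposition -------------------------------------------

// [[Rcpp::export]]
arma::mat differential_pixels_cpp(const arma::mat& px, const Rcpp::LogicalVector& mask) {
  const uword n = px.n_rows;
  mat out(n, 12);
  out.fill(NA_R);
  for (uword p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    mat M = unflatten(px.row(p));
    if (!M.is_finite() || M(0, 0) <= 0) continue;
    mat m = M / M(0, 0);

    cx_vec ev;
    cx_mat V;
    if (!eig_gen(ev, V, m)) continue;
    bool bad = false;
    for (uword k = 0; k < 4; ++k) {
      if (ev[k].real() <= 1e-12 && std::abs(ev[k].imag()) < 1e-12) bad = true;
    }
    if (bad) continue;
    cx_mat Lc;
    bool ok = true;
    try {
      Lc = V * diagmat(log(ev)) * inv(V);
    } catch (...) { ok = false; }
    if (!ok || !Lc.is_finite()) continue;
    mat L = real(Lc);

    mat LG = G * L.t() * G;
    mat Lm = (L - LG) / 2.0;
    mat Lu = (L + LG) / 2.0;

    out(p, 0) = -Lm(2, 3);            // LBH
    out(p, 1) = Lm(1, 3);             // LB45
    out(p, 2) = Lm(1, 2);             // CB
    out(p, 3) = -Lm(0, 1);            // LDH
    out(p, 4) = -Lm(0, 2);            // LD45
    out(p, 5) = Lm(0, 3);             // CD
    double d0 = Lu(0, 0), d1 = Lu(1, 1), d2 = Lu(2, 2), d3 = Lu(3, 3);
    out(p, 6) = d0 + d1 - d2 - d3;    // var_LH
    out(p, 7) = d0 - d1 + d2 - d3;    // var_L45
    out(p, 8) = d0 - d1 - d2 + d3;    // var_C
    out(p, 9) = 2 * Lu(1, 2);         // Re cov_LH_L45
    out(p, 10) = -2 * Lu(1, 3);       // Re cov_LH_C
    out(p, 11) = -2 * Lu(2, 3);       // Re cov_L45_C
  }
  return out;
}

// ---- phantom composition --------------------------------------------------

// [[Rcpp::export]]
arma::mat phantom_compose_cpp(const arma::vec& a, const arma::vec& r,
                              const arma::vec& D, const arma::vec& theta) {
  // per pixel: M = diag(1, a, a, a) * LR(r, theta) * MD(D, theta)
  const uword n = a.n_elem;
  mat out(n, 16);
  for (uword p = 0; p < n; ++p) {
    double c2 = std::cos(2 * theta[p]), s2 = std::sin(2 * theta[p]);
    mat rot = {{1, 0, 0, 0}, {0, c2, -s2, 0}, {0, s2, c2, 0}, {0, 0, 0, 1}};
    double cd = std::cos(r[p]), sd = std::sin(r[p]);
    mat LR0 = {{1, 0, 0, 0}, {0, 1, 0, 0}, {0, 0, cd, sd}, {0, 0, -sd, cd}};
    double s = std::sqrt(std::max(0.0, 1.0 - D[p] * D[p]));
    mat MD0 = {{1, D[p], 0, 0}, {D[p], 1, 0, 0}, {0, 0, s, 0}, {0, 0, 0, s}};
    mat M = diagmat(vec{1, a[p], a[p], a[p]}) * rot * LR0 * MD0 * rot.t();
    out.row(p) = vectorise(M).t();
  }
  return out;
}

// ---- Gaussian-fluctuation Monte Carlo -------------------------------------

// [[Rcpp::export]]
arma::mat fluctuation_mc_cpp(const arma::mat& Lm, const arma::mat& X) {
  // X: n x 6 generator coefficients (LDH, LD45, CD, LBH, LB45, CB)
  const uword n = X.n_rows;
  mat acc(4, 4, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double a = X(i, 0), b = X(i, 1), c = X(i, 2);
    double d = X(i, 3), e = X(i, 4), f = X(i, 5);
    mat dL = {{0, -a, -b, c},
              {-a, 0, f, e},
              {-b, -f, 0, -d},
              {c, -e, d, 0}};
    acc += expmat(Lm + dL);
  }
  return acc / double(n);
}
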