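// Low-level P1 finite-element kernels shared by the fluid, solid and
// mesh-motion solvers.  All coordinates are in SI metres; fields in SI.
// Vertex/cell indices arriving from R are 1-based.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// P1 geometry: per-cell shape-function gradients and signed volumes
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_p1_geometry(const arma::mat& V, const arma::imat& T) {
  const int m = T.n_rows;
  arma::vec vol(m);
  arma::mat G(m, 12); // gradients: 4 nodes x 3 components, node-major
  for (int e = 0; e < m; ++e) {
    arma::vec::fixed<3> x0 = V.row(T(e,0)-1).t();
    arma::mat::fixed<3,3> J;
    for (int a = 0; a < 3; ++a)
      J.col(a) = V.row(T(e,a+1)-1).t() - x0;
    double detJ = arma::det(J);
    vol(e) = detJ / 6.0;
    arma::mat::fixed<3,3> Ji = arma::inv(J);
    // gradient of barycentric coords 1..3 are rows of Ji, node 0 = -sum
    arma::vec::fixed<3> g0 = -arma::sum(Ji, 0).t();
    for (int k = 0; k < 3; ++k) G(e, k) = g0(k);
    for (int a = 0; a < 3; ++a)
      for (int k = 0; k < 3; ++k)
        G(e, 3*(a+1)+k) = Ji(a, k);
  }
  return List::create(_["vol"] = vol, _["grad"] = G);
}

// ---------------------------------------------------------------------------
// Stabilized incompressible Navier-Stokes (ALE), BDF time stepping,
// Picard-linearized convection, ASGS/SUPG-PSPG + grad-div stabilization.
// DOF layout: vx(1..n), vy(n+1..2n), vz(2n+1..3n), p(3n+1..4n).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_assemble_ns(const arma::mat& V, const arma::imat& T,
                     const arma::vec& vol, const arma::mat& G,
                     const arma::mat& v_pic, const arma::mat& v_mesh,
                     const arma::mat& hist, // BDF history field (velocity units)
                     double rho, double mu, double a0_over_dt,
                     double inv_dt, const arma::vec& fbody,
                     bool want_pattern = true) {
  const int m = T.n_rows, n = V.n_rows;
  const R_xlen_t nt = (R_xlen_t)m * 256;
  IntegerVector ii(want_pattern ? nt : 0), jj(want_pattern ? nt : 0);
  NumericVector xx(nt);
  int* iip = want_pattern ? INTEGER(ii) : nullptr;
  int* jjp = want_pattern ? INTEGER(jj) : nullptr;
  double* xxp = REAL(xx);
  arma::vec rhs(4*n, arma::fill::zeros);
  R_xlen_t pos = 0;

  double Ke[16][16], Fe[16];
  const double fb[3] = {fbody(0), fbody(1), fbody(2)};

  for (int e = 0; e < m; ++e) {
    const double Ve = vol(e);
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = T(e,a)-1;
    double g[4][3];
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k) g[a][k] = G(e, 3*a+k);
    double gg[4][4];
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        gg[a][b] = g[a][0]*g[b][0] + g[a][1]*g[b][1] + g[a][2]*g[b][2];

    // element convective velocity and history average
    double ae[3] = {0,0,0}, He[3] = {0,0,0};
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k) {
        ae[k] += 0.25*(v_pic(nd[a],k) - v_mesh(nd[a],k));
        He[k] += 0.25*hist(nd[a],k);
      }
    const double anorm = std::sqrt(ae[0]*ae[0]+ae[1]*ae[1]+ae[2]*ae[2]);
    const double h = std::cbrt(6.0*Ve/std::sqrt(2.0)); // regular-tet edge
    const double tauM = 1.0/(rho*a0_over_dt + 4.0*mu/(h*h) + 2.0*rho*anorm/h);
    const double tauC = h*h/(4.0*tauM);

    // convection coefficients c_b = a.grad(phi_b)
    double cb[4];
    for (int b = 0; b < 4; ++b)
      cb[b] = ae[0]*g[b][0] + ae[1]*g[b][1] + ae[2]*g[b][2];

    for (int r = 0; r < 16; ++r) { Fe[r] = 0; for (int c = 0; c < 16; ++c) Ke[r][c] = 0; }
    const double muVe = mu*Ve, tcVe = tauC*Ve;
    // local dof order: (a,i) = 3*a+i for a=0..3,i=0..2 (12), then p_a 12..15
    for (int a = 0; a < 4; ++a) {
      const double sa = tauM*rho*cb[a]; // SUPG weight coefficient
      for (int b = 0; b < 4; ++b) {
        const double Mab = Ve/20.0*(a==b ? 2.0 : 1.0);
        const double galM = rho*a0_over_dt*Mab                 // transient
                          + rho*cb[b]*Ve*0.25                  // convection
                          + sa*(rho*a0_over_dt*Ve*0.25 + rho*cb[b]*Ve); // SUPG
        const double visc_gg = muVe*gg[a][b];
        const double pspg_m = tauM*(rho*a0_over_dt*Ve*0.25 + rho*cb[b]*Ve);
        for (int i = 0; i < 3; ++i) {
          Ke[3*a+i][3*b+i] += galM + visc_gg;
          for (int j = 0; j < 3; ++j)
            Ke[3*a+i][3*b+j] += muVe*g[b][i]*g[a][j] + tcVe*g[a][i]*g[b][j];
          Ke[3*a+i][12+b] += -g[a][i]*Ve*0.25 + sa*g[b][i]*Ve;
          Ke[12+a][3*b+i] += g[b][i]*Ve*0.25 + pspg_m*g[a][i];
        }
        Ke[12+a][12+b] += tauM*gg[a][b]*Ve;
        for (int i = 0; i < 3; ++i)
          Fe[3*a+i] += rho*inv_dt*Mab*hist(nd[b],i);
      }
      for (int i = 0; i < 3; ++i) {
        Fe[3*a+i] += fb[i]*Ve*0.25 + sa*(rho*inv_dt*He[i] + fb[i])*Ve;
        Fe[12+a]  += tauM*g[a][i]*(rho*inv_dt*He[i] + fb[i])*Ve;
      }
    }

    // scatter
    int gdof[16];
    for (int a = 0; a < 4; ++a) {
      for (int i = 0; i < 3; ++i) gdof[3*a+i] = i*n + nd[a];
      gdof[12+a] = 3*n + nd[a];
    }
    if (want_pattern) {
      for (int r = 0; r < 16; ++r) {
        rhs(gdof[r]) += Fe[r];
        const int gr = gdof[r];
        for (int c = 0; c < 16; ++c) {
          iip[pos] = gr; jjp[pos] = gdof[c]; xxp[pos] = Ke[r][c]; ++pos;
        }
      }
    } else {
      for (int r = 0; r < 16; ++r) {
        rhs(gdof[r]) += Fe[r];
        for (int c = 0; c < 16; ++c) xxp[pos++] = Ke[r][c];
      }
    }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx, _["rhs"] = rhs);
}

// ---------------------------------------------------------------------------
// Scalar Laplacian with per-cell coefficient (mesh-motion diffusion)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_assemble_lap(const arma::imat& T, const arma::vec& vol,
                      const arma::mat& G, const arma::vec& coef) {
  const int m = T.n_rows;
  arma::uvec ii(m*16), jj(m*16);
  arma::vec xx(m*16);
  int pos = 0;
  for (int e = 0; e < m; ++e) {
    const double cVe = coef(e)*vol(e);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double k = 0;
        for (int kk = 0; kk < 3; ++kk) k += G(e,3*a+kk)*G(e,3*b+kk);
        ii(pos) = T(e,a)-1; jj(pos) = T(e,b)-1; xx(pos) = cVe*k; ++pos;
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// ---------------------------------------------------------------------------
// Consistent P1 mass matrix triplets (one scalar field)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_assemble_mass(const arma::imat& T, const arma::vec& vol) {
  const int m = T.n_rows;
  arma::uvec ii(m*16), jj(m*16);
  arma::vec xx(m*16);
  int pos = 0;
  for (int e = 0; e < m; ++e)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        ii(pos) = T(e,a)-1; jj(pos) = T(e,b)-1;
        xx(pos) = vol(e)/20.0*(a==b ? 2.0 : 1.0); ++pos;
      }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// ---------------------------------------------------------------------------
// Mixed u-p hyperelastic solid: neo-Hookean deviatoric + Simo-Taylor
// volumetric law.  Total-Lagrangian internal forces with element-wise
// constant F (P1 displacement); P1 pressure-like field ps.
// DOF layout: ux, uy, uz (3n), ps (3n+1..4n).
// Returns residual (internal - none external) and consistent tangent.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fem_assemble_solid(const arma::mat& V0, const arma::imat& T,
                        const arma::vec& vol0, const arma::mat& G0,
                        const arma::mat& u, const arma::vec& ps,
                        const arma::vec& mu_e, const arma::vec& kappa_e,
                        const arma::vec& tau_e, bool want_pattern = true) {
  const int m = T.n_rows, n = V0.n_rows;
  const R_xlen_t ntr = (R_xlen_t)m * 256;
  IntegerVector ii(want_pattern ? ntr : 0), jj(want_pattern ? ntr : 0);
  NumericVector xx(ntr);
  int* iip = want_pattern ? INTEGER(ii) : nullptr;
  int* jjp = want_pattern ? INTEGER(jj) : nullptr;
  double* xxp = REAL(xx);
  arma::vec res(4*n, arma::fill::zeros);
  R_xlen_t pos = 0;

  double Ke[16][16], Re[16];

  for (int e = 0; e < m; ++e) {
    const double Ve = vol0(e);
    const double mu = mu_e(e), kap = kappa_e(e), tau = tau_e(e);
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = T(e,a)-1;
    double g[4][3];
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k) g[a][k] = G0(e, 3*a+k);

    // deformation gradient (constant on the element)
    arma::mat::fixed<3,3> F;
    F.eye();
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int J = 0; J < 3; ++J)
          F(i,J) += u(nd[a],i)*g[a][J];
    const double Jdet = arma::det(F);
    if (Jdet <= 0.0)
      stop("element inversion: det F <= 0 in solid assembly (element %d)", e+1);
    arma::mat::fixed<3,3> Fi = arma::inv(F);      // Fi(J,i) = F^{-1}_{Ji}
    const double Jm23 = std::pow(Jdet, -2.0/3.0);
    const double I1 = arma::accu(F % F);          // tr(F^T F)

    const double pbar = 0.25*(ps(nd[0])+ps(nd[1])+ps(nd[2])+ps(nd[3]));
    const double Up  = 0.5*kap*(Jdet - 1.0/Jdet);          // U'(J)
    const double Upp = 0.5*kap*(1.0 + 1.0/(Jdet*Jdet));    // U''(J)

    // first Piola-Kirchhoff stress: deviatoric + mixed-pressure volumetric
    arma::mat::fixed<3,3> Pdev, FiT, P;
    FiT = Fi.t();                                  // FiT(i,J) = F^{-T}_{iJ}
    Pdev = mu*Jm23*(F - (I1/3.0)*FiT);
    P = Pdev + Jdet*pbar*FiT;

    for (int r = 0; r < 16; ++r) { Re[r] = 0; for (int c = 0; c < 16; ++c) Ke[r][c] = 0; }

    // internal force rows (a,i): Ve * P_{iJ} g_a[J]
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double r = 0;
        for (int J = 0; J < 3; ++J) r += P(i,J)*g[a][J];
        Re[3*a+i] = Ve*r;
      }
    // pressure rows (scaled by kappa for balanced magnitudes):
    // int phi_a (pbar_h - U'(J)) + kappa tau grad(phi_a).grad(ps)
    for (int a = 0; a < 4; ++a) {
      double r = 0;
      for (int b = 0; b < 4; ++b) {
        const double M4 = (a==b ? 2.0 : 1.0)/20.0;
        r += M4*ps(nd[b]);
      }
      r = Ve*(r - Up*0.25);
      double stab = 0;
      for (int k = 0; k < 3; ++k) {
        double dp = 0;
        for (int b = 0; b < 4; ++b) dp += ps(nd[b])*g[b][k];
        stab += g[a][k]*dp;
      }
      Re[12+a] = r + kap*tau*Ve*stab;
    }

    // tangent: A = dP/dF (deviatoric + pbar volumetric), precomputed once
    // A_{iJkL} = mu*Jm23*[ -(2/3)FiT(k,L)(F(i,J)-(I1/3)FiT(i,J))
    //                      + d_ik d_JL - (2/3)F(k,L)FiT(i,J)
    //                      + (I1/3)Fi(J,k)Fi(L,i) ]
    //          + pbar*Jdet*( FiT(i,J)FiT(k,L) - Fi(J,k)Fi(L,i) )
    double At[3][3][3][3];
    for (int i = 0; i < 3; ++i)
      for (int J = 0; J < 3; ++J)
        for (int k = 0; k < 3; ++k)
          for (int L = 0; L < 3; ++L)
            At[i][J][k][L] =
              mu*Jm23*( -(2.0/3.0)*FiT(k,L)*(F(i,J)-(I1/3.0)*FiT(i,J))
                        + ((i==k && J==L) ? 1.0 : 0.0)
                        - (2.0/3.0)*F(k,L)*FiT(i,J)
                        + (I1/3.0)*Fi(J,k)*Fi(L,i) )
              + pbar*Jdet*( FiT(i,J)*FiT(k,L) - Fi(J,k)*Fi(L,i) );
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 4; ++b)
          for (int k = 0; k < 3; ++k) {
            double kk = 0;
            for (int J = 0; J < 3; ++J) {
              const double gaJ = g[a][J];
              kk += gaJ*(At[i][J][k][0]*g[b][0] + At[i][J][k][1]*g[b][1]
                         + At[i][J][k][2]*g[b][2]);
            }
            Ke[3*a+i][3*b+k] += Ve*kk;
          }
    // K_up: d f_int / d ps_b = Ve/4 * Jdet * FiT(i,J) g_a[J]
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double r = 0;
        for (int J = 0; J < 3; ++J) r += FiT(i,J)*g[a][J];
        for (int b = 0; b < 4; ++b)
          Ke[3*a+i][12+b] += 0.25*Ve*Jdet*r;
      }
    // K_pu: -(Ve/4) U''(J) * Jdet * FiT(k,L) g_b[L]   (kappa-scaled row)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int k = 0; k < 3; ++k) {
          double r = 0;
          for (int L = 0; L < 3; ++L) r += FiT(k,L)*g[b][L];
          Ke[12+a][3*b+k] += -0.25*Ve*Upp*Jdet*r;
        }
    // K_pp: mass + stabilization (kappa-scaled row)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double gg = 0;
        for (int k = 0; k < 3; ++k) gg += g[a][k]*g[b][k];
        Ke[12+a][12+b] += Ve*((a==b ? 2.0 : 1.0)/20.0) + kap*tau*Ve*gg;
      }

    int gdof[16];
    for (int a = 0; a < 4; ++a) {
      for (int i = 0; i < 3; ++i) gdof[3*a+i] = i*n + nd[a];
      gdof[12+a] = 3*n + nd[a];
    }
    if (want_pattern) {
      for (int r = 0; r < 16; ++r) {
        res(gdof[r]) += Re[r];
        const int gr = gdof[r];
        for (int c = 0; c < 16; ++c) {
          iip[pos] = gr; jjp[pos] = gdof[c]; xxp[pos] = Ke[r][c]; ++pos;
        }
      }
    } else {
      for (int r = 0; r < 16; ++r) {
        res(gdof[r]) += Re[r];
        for (int c = 0; c < 16; ++c) xxp[pos++] = Ke[r][c];
      }
    }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx, _["res"] = res);
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle distances (used for the mesh-motion diffusion
// coefficient gamma = 1/d^2): for each query point, min distance over the
// whole triangle set.
// ---------------------------------------------------------------------------

static double tri_dist2(const arma::vec::fixed<3>& p,
                        const arma::vec::fixed<3>& a,
                        const arma::vec::fixed<3>& b,
                        const arma::vec::fixed<3>& c) {
  // Ericson, Real-Time Collision Detection
  arma::vec::fixed<3> ab = b-a, ac = c-a, ap = p-a;
  double d1 = arma::dot(ab,ap), d2 = arma::dot(ac,ap);
  if (d1 <= 0 && d2 <= 0) return arma::dot(p-a,p-a);
  arma::vec::fixed<3> bp = p-b;
  double d3 = arma::dot(ab,bp), d4 = arma::dot(ac,bp);
  if (d3 >= 0 && d4 <= d3) return arma::dot(p-b,p-b);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1/(d1-d3);
    arma::vec::fixed<3> q = a + v*ab;
    return arma::dot(p-q,p-q);
  }
  arma::vec::fixed<3> cp = p-c;
  double d5 = arma::dot(ab,cp), d6 = arma::dot(ac,cp);
  if (d6 >= 0 && d5 <= d6) return arma::dot(p-c,p-c);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2/(d2-d6);
    arma::vec::fixed<3> q = a + w*ac;
    return arma::dot(p-q,p-q);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    double w = (d4-d3)/((d4-d3)+(d5-d6));
    arma::vec::fixed<3> q = b + w*(c-b);
    return arma::dot(p-q,p-q);
  }
  double denom = 1.0/(va+vb+vc);
  double v = vb*denom, w = vc*denom;
  arma::vec::fixed<3> q = a + ab*v + ac*w;
  return arma::dot(p-q,p-q);
}

// [[Rcpp::export]]
arma::vec fem_point_surface_dist(const arma::mat& P, const arma::mat& V,
                                 const arma::imat& F) {
  const int np = P.n_rows, nf = F.n_rows;
  arma::vec out(np);
  for (int p = 0; p < np; ++p) {
    arma::vec::fixed<3> q = P.row(p).t();
    double best = arma::datum::inf;
    for (int f = 0; f < nf; ++f) {
      arma::vec::fixed<3> a = V.row(F(f,0)-1).t();
      arma::vec::fixed<3> b = V.row(F(f,1)-1).t();
      arma::vec::fixed<3> c = V.row(F(f,2)-1).t();
      double d2 = tri_dist2(q,a,b,c);
      if (d2 < best) best = d2;
    }
    out(p) = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Volume of the part of the mesh above the plane y = y0, exact per tet by
// geometric clipping (single-vertex cap or prismatic wedge with planar
// faces; robust to coincident vertex heights).
// ---------------------------------------------------------------------------

static inline double tet_abs_vol(const double* a, const double* b,
                                 const double* c, const double* d) {
  double u[3], v[3], w[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = b[k]-a[k]; v[k] = c[k]-a[k]; w[k] = d[k]-a[k];
  }
  double det = u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0])
             + u[2]*(v[0]*w[1]-v[1]*w[0]);
  return std::fabs(det)/6.0;
}

static inline void edge_cut(const double* p, const double* q, double dp,
                            double dq, double* x) {
  const double t = dp/(dp-dq);
  for (int k = 0; k < 3; ++k) x[k] = p[k] + t*(q[k]-p[k]);
}

// [[Rcpp::export]]
double fem_volume_above_plane(const arma::mat& V, const arma::imat& T,
                              const arma::vec& vol, double y0) {
  const int m = T.n_rows;
  double tot = 0;
  for (int e = 0; e < m; ++e) {
    double x[4][3], d[4];
    int pos[4], neg[4];
    int npos = 0, nneg = 0;
    for (int a = 0; a < 4; ++a) {
      for (int k = 0; k < 3; ++k) x[a][k] = V(T(e,a)-1, k);
      d[a] = x[a][1] - y0;
      if (d[a] > 0) pos[npos++] = a; else neg[nneg++] = a;
    }
    const double Ve = std::fabs(vol(e));
    if (npos == 0) continue;
    if (npos == 4) { tot += Ve; continue; }
    if (npos == 1) {
      // cap tetrahedron above the plane
      double c1[3], c2[3], c3[3];
      edge_cut(x[pos[0]], x[neg[0]], d[pos[0]], d[neg[0]], c1);
      edge_cut(x[pos[0]], x[neg[1]], d[pos[0]], d[neg[1]], c2);
      edge_cut(x[pos[0]], x[neg[2]], d[pos[0]], d[neg[2]], c3);
      tot += tet_abs_vol(x[pos[0]], c1, c2, c3);
    } else if (npos == 3) {
      // complement: cap below the plane
      double c1[3], c2[3], c3[3];
      edge_cut(x[neg[0]], x[pos[0]], d[neg[0]], d[pos[0]], c1);
      edge_cut(x[neg[0]], x[pos[1]], d[neg[0]], d[pos[1]], c2);
      edge_cut(x[neg[0]], x[pos[2]], d[neg[0]], d[pos[2]], c3);
      tot += Ve - tet_abs_vol(x[neg[0]], c1, c2, c3);
    } else {
      // wedge: vertices p1, p2 above; edge cuts X11, X12 (from p1) and
      // X21, X22 (from p2); all quad faces are planar, so a fixed
      // prism-style split into three tets is an exact partition
      double X11[3], X12[3], X21[3], X22[3];
      edge_cut(x[pos[0]], x[neg[0]], d[pos[0]], d[neg[0]], X11);
      edge_cut(x[pos[0]], x[neg[1]], d[pos[0]], d[neg[1]], X12);
      edge_cut(x[pos[1]], x[neg[0]], d[pos[1]], d[neg[0]], X21);
      edge_cut(x[pos[1]], x[neg[1]], d[pos[1]], d[neg[1]], X22);
      tot += tet_abs_vol(x[pos[0]], X11, X12, X22)
           + tet_abs_vol(x[pos[0]], X11, X22, X21)
           + tet_abs_vol(x[pos[0]], X21, X22, x[pos[1]]);
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// Integral of max(s, 0) over the plane y = y0 cut through the mesh, with s a
// P1 nodal field.  Used for the "upward-going flow" swirl-rate metric
// (s = v_y) and, with s = 1, for the cut area.
// ---------------------------------------------------------------------------

static double clipped_tri_integral(arma::vec::fixed<3> p[3], double s[3]) {
  // integral of max(linear s, 0) over triangle (exact)
  // clip polygon to s >= 0
  std::vector<arma::vec::fixed<3>> poly;
  std::vector<double> val;
  for (int i = 0; i < 3; ++i) {
    int j = (i+1)%3;
    if (s[i] >= 0) { poly.push_back(p[i]); val.push_back(s[i]); }
    if ((s[i] >= 0) != (s[j] >= 0)) {
      double t = s[i]/(s[i]-s[j]);
      arma::vec::fixed<3> q = p[i] + t*(p[j]-p[i]);
      poly.push_back(q); val.push_back(0.0);
    }
  }
  const int k = poly.size();
  if (k < 3) return 0.0;
  double tot = 0;
  for (int i = 1; i+1 < k; ++i) {
    arma::vec::fixed<3> e1 = poly[i]-poly[0], e2 = poly[i+1]-poly[0];
    double area = 0.5*arma::norm(arma::cross(e1,e2));
    tot += area*(val[0]+val[i]+val[i+1])/3.0;
  }
  return tot;
}

// [[Rcpp::export]]
double fem_plane_positive_flux(const arma::mat& V, const arma::imat& T,
                               const arma::vec& s, double y0) {
  const int m = T.n_rows;
  double tot = 0;
  for (int e = 0; e < m; ++e) {
    double d[4];
    int npos = 0, nneg = 0;
    arma::vec::fixed<3> x[4];
    double sv[4];
    for (int a = 0; a < 4; ++a) {
      x[a] = V.row(T(e,a)-1).t();
      d[a] = x[a](1) - y0;
      sv[a] = s(T(e,a)-1);
      if (d[a] > 0) ++npos; else ++nneg;
    }
    if (npos == 0 || nneg == 0) continue;
    // collect plane-edge intersection points
    std::vector<arma::vec::fixed<3>> pts;
    std::vector<double> vals;
    for (int a = 0; a < 4; ++a)
      for (int b = a+1; b < 4; ++b)
        if ((d[a] > 0) != (d[b] > 0)) {
          double t = d[a]/(d[a]-d[b]);
          pts.push_back(x[a] + t*(x[b]-x[a]));
          vals.push_back(sv[a] + t*(sv[b]-sv[a]));
        }
    if (pts.size() == 3) {
      arma::vec::fixed<3> q[3] = {pts[0], pts[1], pts[2]};
      double vv[3] = {vals[0], vals[1], vals[2]};
      tot += clipped_tri_integral(q, vv);
    } else if (pts.size() == 4) {
      // order the quad by angle about its centroid (it lies in plane y=y0)
      arma::vec::fixed<3> c = (pts[0]+pts[1]+pts[2]+pts[3])/4.0;
      double ang[4];
      int ord[4] = {0,1,2,3};
      for (int i = 0; i < 4; ++i)
        ang[i] = std::atan2(pts[i](2)-c(2), pts[i](0)-c(0));
      std::sort(ord, ord+4, [&](int a, int b){ return ang[a] < ang[b]; });
      for (int i = 1; i < 3; ++i) {
        arma::vec::fixed<3> q[3] = {pts[ord[0]], pts[ord[i]], pts[ord[i+1]]};
        double vv[3] = {vals[ord[0]], vals[ord[i]], vals[ord[i+1]]};
        tot += clipped_tri_integral(q, vv);
      }
    }
  }
  return tot;
}
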