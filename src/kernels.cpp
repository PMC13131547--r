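// Thin Rcpp exports over the shared kernels in kernels.h.  These back the
// user-facing force functions; the time-stepping engine (engine.cpp) calls the
// same inline kernels, so the tested path and the production path coincide.

#include "kernels.h"
using namespace Rcpp;

static NumericMatrix zero_like(int n) {
  NumericMatrix f(n, 3);
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_bend_forces(NumericMatrix pos, IntegerMatrix triples,
                              double kb, double rm) {
  int n = pos.nrow(), ntr = triples.nrow();
  NumericMatrix f = zero_like(n);
  if (ntr == 0) return f;
  const double* x = &pos(0, 0);
  const double* y = &pos(0, 1);
  const double* z = &pos(0, 2);
  for (int t = 0; t < ntr; ++t) {
    if (!mj::bend_triple(x, y, z, triples(t, 0), triples(t, 1), triples(t, 2),
                         kb, rm, &f(0, 0), &f(0, 1), &f(0, 2)))
      stop("degenerate geometry: coincident consecutive beads in a chain");
  }
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_spring_forces(NumericMatrix pos, IntegerMatrix bonds,
                                double ks, double rm) {
  int n = pos.nrow(), nb = bonds.nrow();
  NumericMatrix f = zero_like(n);
  const double* x = &pos(0, 0);
  const double* y = &pos(0, 1);
  const double* z = &pos(0, 2);
  for (int b = 0; b < nb; ++b) {
    if (!mj::pair_spring(x, y, z, bonds(b, 0), bonds(b, 1), ks, 2.0 * rm,
                         &f(0, 0), &f(0, 1), &f(0, 2)))
      stop("degenerate geometry: coincident bonded beads");
  }
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_steric_forces(NumericMatrix pos, IntegerVector chain,
                                IntegerVector ord, double kM, double rm,
                                bool use_cells) {
  int n = pos.nrow();
  NumericMatrix f = zero_like(n);
  if (n < 2) return f;
  mj::steric_all(&pos(0, 0), &pos(0, 1), &pos(0, 2), n, chain.begin(),
                 ord.begin(), kM, rm, &f(0, 0), &f(0, 1), &f(0, 2), use_cells);
  return f;
}

// [[Rcpp::export]]
List cpp_wca_forces(NumericMatrix bead_pos, NumericMatrix node_pos,
                    double phi0, double rm, double floor_frac, bool use_cells) {
  int nb = bead_pos.nrow(), nn = node_pos.nrow();
  NumericMatrix fb = zero_like(nb), fn = zero_like(nn);
  int n_clamped = 0;
  if (nb > 0 && nn > 0)
    mj::wca_all(&bead_pos(0, 0), &bead_pos(0, 1), &bead_pos(0, 2), nb,
                &node_pos(0, 0), &node_pos(0, 1), &node_pos(0, 2), nn,
                phi0, rm, floor_frac,
                &fb(0, 0), &fb(0, 1), &fb(0, 2),
                &fn(0, 0), &fn(0, 1), &fn(0, 2), &n_clamped, use_cells);
  return List::create(_["bead_forces"] = fb, _["node_forces"] = fn,
                      _["n_clamped"] = n_clamped);
}

// [[Rcpp::export]]
NumericMatrix cpp_membrane_bend_forces(NumericMatrix nodes, IntegerMatrix hinges,
                                       NumericVector w, NumericVector theta0,
                                       double kb) {
  int n = nodes.nrow(), nh = hinges.nrow();
  NumericMatrix f = zero_like(n);
  if (nh == 0) return f;
  std::vector<int> hi(nh), hj(nh), hk(nh), hl(nh);
  for (int h = 0; h < nh; ++h) {
    hi[h] = hinges(h, 0); hj[h] = hinges(h, 1);
    hk[h] = hinges(h, 2); hl[h] = hinges(h, 3);
  }
  if (!mj::hinge_forces(&nodes(0, 0), &nodes(0, 1), &nodes(0, 2),
                        hi.data(), hj.data(), hk.data(), hl.data(),
                        w.begin(), theta0.begin(), nh, kb,
                        &f(0, 0), &f(0, 1), &f(0, 2)))
    stop("degenerate geometry: zero-area face at a hinge");
  return f;
}

// [[Rcpp::export]]
List cpp_area_forces(NumericMatrix nodes, IntegerMatrix faces, double A0,
                     double kAE) {
  int n = nodes.nrow(), nf = faces.nrow();
  NumericMatrix f = zero_like(n);
  std::vector<int> fi(nf), fj(nf), fk(nf);
  for (int t = 0; t < nf; ++t) {
    fi[t] = faces(t, 0); fj[t] = faces(t, 1); fk[t] = faces(t, 2);
  }
  double A = mj::area_forces(&nodes(0, 0), &nodes(0, 1), &nodes(0, 2),
                             fi.data(), fj.data(), fk.data(), nf, A0, kAE,
                             &f(0, 0), &f(0, 1), &f(0, 2));
  if (A < 0) stop("degenerate geometry: zero-area face");
  return List::create(_["forces"] = f, _["area"] = A);
}

// [[Rcpp::export]]
NumericMatrix cpp_edge_forces(NumericMatrix nodes, IntegerMatrix edges,
                              NumericVector rest, NumericVector k) {
  int n = nodes.nrow(), ne = edges.nrow();
  NumericMatrix f = zero_like(n);
  std::vector<int> ea(ne), eb(ne);
  for (int e = 0; e < ne; ++e) { ea[e] = edges(e, 0); eb[e] = edges(e, 1); }
  if (!mj::edge_forces(&nodes(0, 0), &nodes(0, 1), &nodes(0, 2), ea.data(),
                       eb.data(), rest.begin(), k.begin(), ne,
                       &f(0, 0), &f(0, 1), &f(0, 2)))
    stop("degenerate geometry: coincident bonded nodes");
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_dihedrals(NumericMatrix nodes, IntegerMatrix hinges) {
  int nh = hinges.nrow();
  NumericVector th(nh);
  const double* x = &nodes(0, 0);
  const double* y = &nodes(0, 1);
  const double* z = &nodes(0, 2);
  for (int h = 0; h < nh; ++h) {
    th[h] = mj::dihedral(mj::get(x, y, z, hinges(h, 2)),
                         mj::get(x, y, z, hinges(h, 0)),
                         mj::get(x, y, z, hinges(h, 1)),
                         mj::get(x, y, z, hinges(h, 3)));
  }
  return th;
}
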