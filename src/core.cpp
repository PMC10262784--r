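// Numeric kernels: weighted Kabsch superposition, pairwise RMSD over frames,
// Shrake-Rupley point occlusion, and inter-selection contact counting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Optimal (proper-rotation) least-squares RMSD between two N x 3 point sets
// with non-negative per-point weights.  Reflections are corrected by flipping
// the smallest singular direction.
static double kabsch_rmsd_core(const mat& A, const mat& B, const vec& w) {
  const double wsum = accu(w);
  const rowvec cA = (w.t() * A) / wsum;
  const rowvec cB = (w.t() * B) / wsum;
  mat Ac = A.each_row() - cA;
  mat Bc = B.each_row() - cB;
  mat H = Ac.t() * (Bc.each_col() % w);   // 3 x 3 weighted covariance
  mat U, V;
  vec s;
  svd(U, s, V, H);
  double d = det(V * U.t());
  vec sgn = {1.0, 1.0, (d < 0.0) ? -1.0 : 1.0};
  // E0 = sum w (|a|^2 + |b|^2); rmsd^2 = (E0 - 2*sum(sgn*s)) / wsum
  double E0 = accu((sum(square(Ac), 1) + sum(square(Bc), 1)) % w);
  double msd = (E0 - 2.0 * accu(sgn % s)) / wsum;
  return (msd > 0.0) ? std::sqrt(msd) : 0.0;
}

// [[Rcpp::export(name = ".cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(const arma::mat& A, const arma::mat& B,
                       const arma::vec& w) {
  return kabsch_rmsd_core(A, B, w);
}

// frames: N x 3 x T cube of selected coordinates; returns T x T symmetric
// matrix of pairwise Kabsch-minimized RMSDs (fresh superposition per pair).
// [[Rcpp::export(name = ".cpp_pairwise_rmsd")]]
arma::mat cpp_pairwise_rmsd(const arma::cube& frames, const arma::vec& w) {
  const uword T = frames.n_slices;
  mat out(T, T, fill::zeros);
  for (uword i = 0; i + 1 < T; ++i) {
    const mat Ai = frames.slice(i);
    for (uword j = i + 1; j < T; ++j) {
      double r = kabsch_rmsd_core(Ai, frames.slice(j), w);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// RMSD of every frame against a fixed reference (refit per frame).
// [[Rcpp::export(name = ".cpp_rmsd_to_ref")]]
arma::vec cpp_rmsd_to_ref(const arma::cube& frames, const arma::mat& ref,
                          const arma::vec& w) {
  const uword T = frames.n_slices;
  vec out(T);
  for (uword i = 0; i < T; ++i)
    out(i) = kabsch_rmsd_core(frames.slice(i), ref, w);
  return out;
}

// Shrake-Rupley: per-atom solvent-accessible area.
// xyz: N x 3; radii: vdW radii; sphere: S x 3 unit sphere points.
// subset: 1-based indices of atoms whose area is wanted (all atoms occlude).
// [[Rcpp::export(name = ".cpp_sasa")]]
arma::vec cpp_sasa(const arma::mat& xyz, const arma::vec& radii,
                   const double probe, const arma::mat& sphere,
                   const arma::uvec& subset) {
  const uword S = sphere.n_rows;
  const uword N = xyz.n_rows;
  vec out(subset.n_elem, fill::zeros);
  const double fourpi = 4.0 * datum::pi;
  for (uword k = 0; k < subset.n_elem; ++k) {
    const uword i = subset(k) - 1;
    const double ri = radii(i) + probe;
    // neighbor candidates: centers within ri + rj (their expanded radius)
    std::vector<uword> nb;
    std::vector<double> nbr2;
    for (uword j = 0; j < N; ++j) {
      if (j == i) continue;
      const double rj = radii(j) + probe;
      const double d2 = accu(square(xyz.row(j) - xyz.row(i)));
      const double rr = ri + rj;
      if (d2 < rr * rr) {
        nb.push_back(j);
        nbr2.push_back(rj * rj);
      }
    }
    uword exposed = 0;
    for (uword s = 0; s < S; ++s) {
      const rowvec p = xyz.row(i) + ri * sphere.row(s);
      bool occl = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const double d2 = accu(square(p - xyz.row(nb[q])));
        if (d2 < nbr2[q]) { occl = true; break; }
      }
      if (!occl) ++exposed;
    }
    out(k) = fourpi * ri * ri * (double)exposed / (double)S;
  }
  return out;
}

// Number of inter-selection atom pairs within r_cut.
// [[Rcpp::export(name = ".cpp_contact_count")]]
int cpp_contact_count(const arma::mat& A, const arma::mat& B,
                      const double r_cut) {
  const double c2 = r_cut * r_cut;
  int n = 0;
  for (uword i = 0; i < A.n_rows; ++i)
    for (uword j = 0; j < B.n_rows; ++j)
      if (accu(square(A.row(i) - B.row(j))) <= c2) ++n;
  return n;
}
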