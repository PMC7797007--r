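// Hot loop of the stochastic imaging chain. Because the chain is linear,
// a clinical pixel of a motion-blurred, downsampled instance equals the
// weighted sum, over the motion PSF's splat points, of the box-filtered
// (block-mean) system-blurred phantom sampled (bilinearly) at the
// shifted block start -- the exact adjoint of bilinear kernel splatting
// followed by convolution and block averaging. This avoids per-instance
// FFTs entirely.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Cbox: (N-h+1)^2 block means of the padded system-blurred phantom,
//   Cbox(a, b) = mean over the h x h block whose 0-based start is (a, b).
// base: 0-based start index of the first clinical block in the padded
//   grid; clinical block ci starts at base + ci * h.
// points: splat displacements (hyper-pixel units) stacked over
//   instances, weights alongside; start: 0-based offset of each
//   instance's first point (length nInst + 1).
// Returns an (nClin * nClin) x nInst matrix of clinical images
// (column-major within instance).
// [[Rcpp::export]]
arma::mat cpp_motion_gather(const arma::mat& Cbox, int base, int h,
                            int nClin, const arma::mat& points,
                            const arma::vec& weights,
                            const arma::uvec& start) {
  const int nInst = start.n_elem - 1;
  const int dim = Cbox.n_rows;
  mat out(nClin * nClin, nInst, fill::zeros);
  ivec ix(nClin), iy(nClin);
  vec fx(nClin), fy(nClin);

  for (int inst = 0; inst < nInst; ++inst) {
    double tot = 0.0;
    for (uword p = start[inst]; p < start[inst + 1]; ++p) {
      const double px = points(p, 0), py = points(p, 1);
      const double w = weights[p];
      tot += w;
      for (int c = 0; c < nClin; ++c) {
        double ax = base + c * h - px;
        double ay = base + c * h - py;
        int i = (int)std::floor(ax);
        int j = (int)std::floor(ay);
        if (i < 0 || j < 0 || i + 1 >= dim || j + 1 >= dim)
          Rcpp::stop("motion displacement exceeds the padded margin");
        ix[c] = i; fx[c] = ax - i;
        iy[c] = j; fy[c] = ay - j;
      }
      double* col = out.colptr(inst);
      for (int cj = 0; cj < nClin; ++cj) {
        const int j = iy[cj];
        const double gy = fy[cj];
        const double* c0 = Cbox.colptr(j);
        const double* c1 = Cbox.colptr(j + 1);
        for (int ci = 0; ci < nClin; ++ci) {
          const int i = ix[ci];
          const double gx = fx[ci];
          double v = (1 - gx) * ((1 - gy) * c0[i] + gy * c1[i]) +
                     gx * ((1 - gy) * c0[i + 1] + gy * c1[i + 1]);
          col[cj * nClin + ci] += w * v;
        }
      }
    }
    out.col(inst) /= tot;
  }
  return out;
}

// Batch deterministic chain for template banks: for each padded hyper
// phantom (slice of `pads`), multiply its spectrum by the combined
// frequency-domain filter (2D MTF times optional motion-kernel
// spectrum), inverse-transform, crop the padding and block-average to
// the clinical grid. Returns one flattened clinical template per column.
// [[Rcpp::export]]
arma::mat cpp_ttf_chain(const arma::cube& pads, const arma::cx_mat& filt,
                        int off, int nHyper, int hyperFactor) {
  const int nT = pads.n_slices;
  const int nClin = nHyper / hyperFactor;
  mat out(nClin * nClin, nT);
  for (int t = 0; t < nT; ++t) {
    cx_mat F = fft2(conv_to<cx_mat>::from(pads.slice(t)));
    F %= filt;
    mat field = real(ifft2(F));
    double* col = out.colptr(t);
    for (int cj = 0; cj < nClin; ++cj)
      for (int ci = 0; ci < nClin; ++ci) {
        double s = 0.0;
        for (int j = 0; j < hyperFactor; ++j)
          for (int i = 0; i < hyperFactor; ++i)
            s += field(off + ci * hyperFactor + i,
                       off + cj * hyperFactor + j);
        col[cj * nClin + ci] = s / (hyperFactor * hyperFactor);
      }
  }
  return out;
}
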