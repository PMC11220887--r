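#ifndef SADRET_FFT3_H
#define SADRET_FFT3_H

#include <complex>
#include <vector>

namespace sadret {

typedef std::complex<double> cplx;

// One-dimensional complex DFT plan for a fixed length and exponent sign.
// Lengths must be 5-smooth (factors 2, 3, 5 only): the engine chooses its
// grid dimensions accordingly, so no generic-length (Bluestein) path exists.
class FFT1D {
public:
  FFT1D(int n, int sign);
  int size() const { return n_; }
  // out-of-place transform of a contiguous line; in != out
  void run(const cplx* in, cplx* out) const;
  // blocked transform: element j is a contiguous block of B values at
  // in + j*B; butterflies then run over whole blocks (vectorizable),
  // which is how the strided axes of the 3D transform are handled
  void runB(const cplx* in, cplx* out, int B) const;
  static bool smooth(int n);

private:
  void recB(const cplx* in, cplx* out, int n, long stride, int level,
            int B) const;
  int n_;
  int sign_;
  std::vector<int> factors_;
  std::vector<cplx> tw_; // tw_[j] = exp(sign * 2*pi*i * j / n)
};

// In-place 3D DFT over a column-major (R layout) array of dims n1 x n2 x n3.
// sign = -1: sum z[x] exp(-2*pi*i*h.x/N) (synthesis direction, unnormalized);
// sign = +1: the conjugate transform (analysis).  No 1/N scaling applied.
class FFT3D {
public:
  FFT3D(int n1, int n2, int n3, int sign);
  void run(cplx* z) const;
  long npts() const { return (long)n1_ * n2_ * n3_; }

private:
  int n1_, n2_, n3_;
  FFT1D p1_, p2_, p3_;
  mutable std::vector<cplx> buf_, buf2_;
};

// Real <-> Hermitian-complex 3D transforms exploiting F(-h) = conj F(h):
// axis 1 is folded through the even/odd packing trick (length n1/2
// complex transforms) and axes 2/3 only touch the n1/2 + 1 stored
// columns, roughly halving the work of the complex path.
class HermFFT {
public:
  HermFFT(int n1, int n2, int n3);
  // real map -> full complex grid, exponent +2*pi*i (analysis)
  void analyze(const double* x, cplx* G) const;
  // Hermitian complex grid -> real map, exponent -2*pi*i, unnormalized;
  // the anti-Hermitian component of G is ignored
  void synthesize(const cplx* G, double* x) const;
  // max |G[h] - conj(G[-h])| over the redundant half (Hermitian check)
  double asymmetry(const cplx* G) const;

private:
  int n1_, n2_, n3_, m_, w_;
  long n12_, N_;
  FFT1D pmf_, pmb_, p2f_, p2b_, p3f_, p3b_;
  std::vector<cplx> twf_, twb_; // e^{+-2*pi*i*h/n1}, h = 0..m
  mutable std::vector<cplx> packed_, buf_, line_, line2_;
};

} // namespace sadret

#endif
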