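#include "fft3.h"
#include <cmath>
#include <stdexcept>

namespace sadret {

bool FFT1D::smooth(int n) {
  if (n < 1) return false;
  for (int p : {2, 3, 5})
    while (n % p == 0) n /= p;
  return n == 1;
}

FFT1D::FFT1D(int n, int sign) : n_(n), sign_(sign) {
  if (!smooth(n)) throw std::invalid_argument("FFT length must be 5-smooth");
  int m = n;
  for (int p : {2, 3, 5})
    while (m % p == 0) { factors_.push_back(p); m /= p; }
  tw_.resize(n_);
  const double w = 2.0 * M_PI / n_ * (sign_ >= 0 ? 1.0 : -1.0);
  for (int j = 0; j < n_; ++j) tw_[j] = cplx(std::cos(w * j), std::sin(w * j));
}

void FFT1D::run(const cplx* in, cplx* out) const { recB(in, out, n_, 1, 0, 1); }
void FFT1D::runB(const cplx* in, cplx* out, int B) const {
  recB(in, out, n_, 1, 0, B);
}

// Decimation-in-time Cooley-Tukey: p sub-transforms of length m stored in
// consecutive blocks of `out`, then specialized p-point butterflies over
// whole B-blocks (the inner b-loops are contiguous and auto-vectorize).
// Twiddles come from the shared top-level table: exponent j/n maps to
// table index j * (n_/n), always < n_ for the indices used below.
void FFT1D::recB(const cplx* in, cplx* out, int n, long stride, int level,
                 int B) const {
  if (n == 1) {
    for (int b = 0; b < B; ++b) out[b] = in[b];
    return;
  }
  const int p = factors_[level];
  const int m = n / p;
  for (int r = 0; r < p; ++r)
    recB(in + (long)r * stride * B, out + (long)r * m * B, m, stride * p,
         level + 1, B);
  const int sc = n_ / n;
  if (p == 2) {
    for (int k = 0; k < m; ++k) {
      const cplx w = tw_[k * sc];
      cplx* x0 = out + (long)k * B;
      cplx* x1 = out + (long)(m + k) * B;
      for (int b = 0; b < B; ++b) {
        const cplx t = x1[b] * w;
        x1[b] = x0[b] - t;
        x0[b] += t;
      }
    }
  } else if (p == 3) {
    const cplx W1 = tw_[n_ / 3], W2 = tw_[2 * (n_ / 3)];
    for (int k = 0; k < m; ++k) {
      const cplx w1 = tw_[k * sc], w2 = tw_[2 * k * sc];
      cplx* x0 = out + (long)k * B;
      cplx* x1 = out + (long)(m + k) * B;
      cplx* x2 = out + (long)(2 * m + k) * B;
      for (int b = 0; b < B; ++b) {
        const cplx a0 = x0[b];
        const cplx t1 = x1[b] * w1;
        const cplx t2 = x2[b] * w2;
        x0[b] = a0 + t1 + t2;
        x1[b] = a0 + t1 * W1 + t2 * W2;
        x2[b] = a0 + t1 * W2 + t2 * W1;
      }
    }
  } else { // p == 5
    const cplx W1 = tw_[n_ / 5], W2 = tw_[2 * (n_ / 5)];
    const cplx W3 = tw_[3 * (n_ / 5)], W4 = tw_[4 * (n_ / 5)];
    for (int k = 0; k < m; ++k) {
      const cplx w1 = tw_[k * sc], w2 = tw_[2 * k * sc];
      const cplx w3 = tw_[3 * k * sc], w4 = tw_[4 * k * sc];
      cplx* x0 = out + (long)k * B;
      cplx* x1 = out + (long)(m + k) * B;
      cplx* x2 = out + (long)(2 * m + k) * B;
      cplx* x3 = out + (long)(3 * m + k) * B;
      cplx* x4 = out + (long)(4 * m + k) * B;
      for (int b = 0; b < B; ++b) {
        const cplx a0 = x0[b];
        const cplx t1 = x1[b] * w1;
        const cplx t2 = x2[b] * w2;
        const cplx t3 = x3[b] * w3;
        const cplx t4 = x4[b] * w4;
        x0[b] = a0 + t1 + t2 + t3 + t4;
        x1[b] = a0 + t1 * W1 + t2 * W2 + t3 * W3 + t4 * W4;
        x2[b] = a0 + t1 * W2 + t2 * W4 + t3 * W1 + t4 * W3;
        x3[b] = a0 + t1 * W3 + t2 * W1 + t3 * W4 + t4 * W2;
        x4[b] = a0 + t1 * W4 + t2 * W3 + t3 * W2 + t4 * W1;
      }
    }
  }
}

FFT3D::FFT3D(int n1, int n2, int n3, int sign)
    : n1_(n1), n2_(n2), n3_(n3),
      p1_(n1, sign), p2_(n2, sign), p3_(n3, sign) {
  buf_.resize((long)n1 * n2 * n3);
  buf2_.resize((long)n1 * n2);
}

void FFT3D::run(cplx* z) const {
  const long n12 = (long)n1_ * n2_;
  // axis 1: transpose each k-slab so the i elements become contiguous
  // blocks of n2, run the blocked transform, transpose back
  std::vector<cplx>& t = buf2_;
  for (int k = 0; k < n3_; ++k) {
    cplx* slab = z + (long)k * n12;
    for (int j = 0; j < n2_; ++j)
      for (int i = 0; i < n1_; ++i) t[j + (long)n2_ * i] = slab[i + (long)n1_ * j];
    p1_.runB(t.data(), buf_.data(), n2_);
    for (int j = 0; j < n2_; ++j)
      for (int i = 0; i < n1_; ++i) slab[i + (long)n1_ * j] = buf_[j + (long)n2_ * i];
  }
  // axis 2: within each k-slab, element j is a contiguous block of n1
  for (int k = 0; k < n3_; ++k) {
    cplx* slab = z + (long)k * n12;
    p2_.runB(slab, buf_.data(), n1_);
    for (long s = 0; s < n12; ++s) slab[s] = buf_[s];
  }
  // axis 3: element k is a contiguous block of n1*n2
  p3_.runB(z, buf_.data(), (int)n12);
  const long N = n12 * n3_;
  for (long s = 0; s < N; ++s) z[s] = buf_[s];
}

HermFFT::HermFFT(int n1, int n2, int n3)
    : n1_(n1), n2_(n2), n3_(n3), m_(n1 / 2), w_(n1 / 2 + 1),
      n12_((long)n1 * n2), N_((long)n1 * n2 * n3),
      pmf_(n1 / 2, +1), pmb_(n1 / 2, -1),
      p2f_(n2, +1), p2b_(n2, -1), p3f_(n3, +1), p3b_(n3, -1) {
  if (n1 % 2) throw std::invalid_argument("HermFFT needs even n1");
  twf_.resize(w_);
  twb_.resize(w_);
  for (int h = 0; h <= m_; ++h) {
    const double a = 2.0 * M_PI * h / n1_;
    twf_[h] = cplx(std::cos(a), std::sin(a));
    twb_[h] = std::conj(twf_[h]);
  }
  packed_.resize((long)w_ * n2_ * n3_);
  buf_.resize((long)w_ * n2_ * n3_);
  line_.resize(m_ > 0 ? m_ : 1);
  line2_.resize(m_ > 0 ? m_ : 1);
}

void HermFFT::analyze(const double* x, cplx* G) const {
  const long wn2 = (long)w_ * n2_;
  // axis 1: real-to-complex via even/odd packing, keep h = 0..m
  for (int k = 0; k < n3_; ++k)
    for (int j = 0; j < n2_; ++j) {
      const double* src = x + (long)j * n1_ + (long)k * n12_;
      for (int t = 0; t < m_; ++t)
        line_[t] = cplx(src[2 * t], src[2 * t + 1]);
      pmf_.run(line_.data(), line2_.data());
      cplx* dst = packed_.data() + (long)j * w_ + (long)k * wn2;
      for (int h = 0; h <= m_; ++h) {
        const cplx Zh = line2_[h % m_];
        const cplx Zc = std::conj(line2_[(m_ - h) % m_]);
        const cplx E = 0.5 * (Zh + Zc);
        const cplx O = cplx(0.0, -0.5) * (Zh - Zc);
        dst[h] = E + twf_[h] * O;
      }
    }
  // axes 2 and 3 on the packed columns (ping-pong, no copy-backs)
  for (int k = 0; k < n3_; ++k)
    p2f_.runB(packed_.data() + (long)k * wn2, buf_.data() + (long)k * wn2,
              w_);
  p3f_.runB(buf_.data(), packed_.data(), (int)wn2);
  std::swap(packed_, buf_); // results now in buf_, scratch in packed_
  // unpack with Hermitian mirror for i > m
  for (int k = 0; k < n3_; ++k) {
    const int km = (n3_ - k) % n3_;
    for (int j = 0; j < n2_; ++j) {
      const int jm = (n2_ - j) % n2_;
      cplx* dst = G + (long)j * n1_ + (long)k * n12_;
      const cplx* src = buf_.data() + (long)j * w_ + (long)k * wn2;
      const cplx* mir = buf_.data() + (long)jm * w_ + (long)km * wn2;
      for (int i = 0; i <= m_; ++i) dst[i] = src[i];
      for (int i = m_ + 1; i < n1_; ++i) dst[i] = std::conj(mir[n1_ - i]);
    }
  }
}

void HermFFT::synthesize(const cplx* G, double* x) const {
  const long wn2 = (long)w_ * n2_;
  for (int k = 0; k < n3_; ++k)
    for (int j = 0; j < n2_; ++j) {
      const cplx* src = G + (long)j * n1_ + (long)k * n12_;
      cplx* dst = packed_.data() + (long)j * w_ + (long)k * wn2;
      for (int i = 0; i <= m_; ++i) dst[i] = src[i];
    }
  p3b_.runB(packed_.data(), buf_.data(), (int)wn2);
  for (int k = 0; k < n3_; ++k)
    p2b_.runB(buf_.data() + (long)k * wn2, packed_.data() + (long)k * wn2,
              w_);
  // axis 1 complex-to-real: z[t] = x[2t] + i x[2t+1] is the length-m
  // inverse transform of C[h] = (X[h] + conj(X[m-h])) +
  // i u^h (X[h] - conj(X[m-h])), u = exp(-2*pi*i/n1)
  for (int k = 0; k < n3_; ++k)
    for (int j = 0; j < n2_; ++j) {
      const cplx* X = packed_.data() + (long)j * w_ + (long)k * wn2;
      for (int h = 0; h < m_; ++h) {
        const cplx A = X[h], B = std::conj(X[m_ - h]);
        line_[h] = (A + B) + cplx(0.0, 1.0) * twb_[h] * (A - B);
      }
      pmb_.run(line_.data(), line2_.data());
      double* dst = x + (long)j * n1_ + (long)k * n12_;
      for (int t = 0; t < m_; ++t) {
        dst[2 * t] = line2_[t].real();
        dst[2 * t + 1] = line2_[t].imag();
      }
    }
}

double HermFFT::asymmetry(const cplx* G) const {
  double mx = 0.0;
  for (int k = 0; k < n3_; ++k) {
    const int km = (n3_ - k) % n3_;
    for (int j = 0; j < n2_; ++j) {
      const int jm = (n2_ - j) % n2_;
      const cplx* a = G + (long)j * n1_ + (long)k * n12_;
      const cplx* b = G + (long)jm * n1_ + (long)km * n12_;
      for (int i = m_ + 1; i < n1_; ++i) {
        const double d = std::abs(a[i] - std::conj(b[n1_ - i]));
        if (d > mx) mx = d;
      }
    }
  }
  return mx;
}

} // namespace sadret
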