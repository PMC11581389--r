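// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Forward pass of the AlexNet front end up to the second max-pooling layer
// (pool2), for 227x227x3 inputs:
//
//   conv1  96 filters 11x11x3, stride 4, no padding  -> 55x55x96, ReLU
//   pool1  max 3x3, stride 2                         -> 27x27x96
//   conv2  256 filters 5x5x96, stride 1, padding 2   -> 27x27x256, ReLU
//   pool2  max 3x3, stride 2                         -> 13x13x256
//
// Convolutions are evaluated as im2col + sgemm (single precision; the
// activations feed rank-based statistics downstream, where float precision
// is ample).  Flattening order of the 13x13x256 output is column-major over
// (row, column, channel): feature index = row + 13*col + 169*channel,
// 0-based, constant across runs.
//
// `images`: (227*227) x B matrix, one single-plane image per column in R
// array order (row, col).  The network input replicates the grayscale
// plane to 3 identical channels, so conv1 is evaluated on the plane with
// the channel-summed kernel: `w1` is the (11,11,3,96) array with its 3
// channel blocks summed, reshaped column-major to 121x96.  `w2` is the
// (5,5,96,256) array reshaped to 2400x256.
// [[Rcpp::export]]
NumericMatrix cpp_extract_pool2(const NumericMatrix &images,
                                const NumericMatrix &w1,
                                const NumericVector &b1,
                                const NumericMatrix &w2,
                                const NumericVector &b2) {
  const int B = images.ncol();
  if (images.nrow() != 227 * 227)
    stop("images must have 227*227 rows");
  if (w1.nrow() != 121 || w1.ncol() != 96)
    stop("w1 must be 121 x 96");
  if (w2.nrow() != 2400 || w2.ncol() != 256)
    stop("w2 must be 2400 x 256");

  arma::fmat W1(121, 96), W2(2400, 256);
  for (int j = 0; j < 96; ++j)
    for (int i = 0; i < 121; ++i) W1(i, j) = (float)w1(i, j);
  for (int j = 0; j < 256; ++j)
    for (int i = 0; i < 2400; ++i) W2(i, j) = (float)w2(i, j);
  arma::frowvec B1(96), B2(256);
  for (int j = 0; j < 96; ++j) B1(j) = (float)b1[j];
  for (int j = 0; j < 256; ++j) B2(j) = (float)b2[j];

  // im2col index tables (into the image plane / padded pool1 array)
  arma::umat idx1(3025, 121);
  for (int j = 0; j < 11; ++j)
    for (int i = 0; i < 11; ++i) {
      const int colidx = i + 11 * j;
      for (int ox = 0; ox < 55; ++ox)
        for (int oy = 0; oy < 55; ++oy)
          idx1(oy + 55 * ox, colidx) =
              (4 * oy + i) + 227 * (4 * ox + j);
    }
  arma::umat idx2(729, 2400);  // into padded 31x31x96
  for (int ch = 0; ch < 96; ++ch)
    for (int j = 0; j < 5; ++j)
      for (int i = 0; i < 5; ++i) {
        const int colidx = i + 5 * j + 25 * ch;
        for (int ox = 0; ox < 27; ++ox)
          for (int oy = 0; oy < 27; ++oy)
            idx2(oy + 27 * ox, colidx) =
                (oy + i) + 31 * (ox + j) + 31 * 31 * ch;
      }

  NumericMatrix out(B, 13 * 13 * 256);
  arma::fvec img(227 * 227);
  arma::fmat P1(3025, 121), P2(729, 2400);
  arma::fvec pad(31 * 31 * 96);

  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < 227 * 227; ++i) img(i) = (float)images(i, b);

    for (arma::uword c = 0; c < 121; ++c)
      for (arma::uword r = 0; r < 3025; ++r) P1(r, c) = img(idx1(r, c));
    arma::fmat a1 = P1 * W1;          // 3025 x 96
    a1.each_row() += B1;
    a1.transform([](float v) { return v > 0.0f ? v : 0.0f; });

    // pool1 into zero-padded 31x31x96 (padding 2 for conv2)
    pad.zeros();
    for (int k = 0; k < 96; ++k)
      for (int x = 0; x < 27; ++x)
        for (int y = 0; y < 27; ++y) {
          float m = -1.0f;  // activations are >= 0 after ReLU
          for (int dx = 0; dx < 3; ++dx)
            for (int dy = 0; dy < 3; ++dy) {
              const float v = a1((2 * y + dy) + 55 * (2 * x + dx), k);
              if (v > m) m = v;
            }
          pad((y + 2) + 31 * (x + 2) + 31 * 31 * k) = m;
        }

    for (arma::uword c = 0; c < 2400; ++c)
      for (arma::uword r = 0; r < 729; ++r) P2(r, c) = pad(idx2(r, c));
    arma::fmat a2 = P2 * W2;          // 729 x 256
    a2.each_row() += B2;
    a2.transform([](float v) { return v > 0.0f ? v : 0.0f; });

    for (int k = 0; k < 256; ++k)
      for (int x = 0; x < 13; ++x)
        for (int y = 0; y < 13; ++y) {
          float m = -1.0f;
          for (int dx = 0; dx < 3; ++dx)
            for (int dy = 0; dy < 3; ++dy) {
              const float v = a2((2 * y + dy) + 27 * (2 * x + dx), k);
              if (v > m) m = v;
            }
          out(b, y + 13 * x + 169 * k) = (double)m;
        }
  }
  return out;
}
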