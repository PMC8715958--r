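// Compact 3-D convolutional classifier: single-precision forward/backward
// with im2col convolutions (GEMM via BLAS), batch normalisation, ReLU,
// 2x2x2 max pooling, an optional 1x1x1 convolution head, and a single-unit
// sigmoid dense output trained with Adam on binary cross-entropy.
//
// Volumes are flattened x-fastest (R column-major array order), so the
// im2col gather decomposes into contiguous x-runs handled by memcpy.
//
// Parameter list layout (flat, fixed order; one R list of numeric matrices):
//   for each block b, for each conv j: W (27*Cin x F), bias (1 x F),
//                                      gamma (1 x F), beta (1 x F)
//   then, if head_channels > 0:        Wh (C_last x H), bh (1 x H)
//   then:                              wd (feat_len x 1), bd (1 x 1)
// Running statistics list: per conv, rm (1 x F), rv (1 x F).
// Adam moment lists mirror the parameter list exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

static const float BN_EPS = 1e-5f;

struct Geom {
  int n_blocks, convs_per_block, head_channels, feat_len, V_last, C_last;
  std::vector<int> filters;  // per block
  std::vector<int> edges;    // grid edge at the input of each block
  std::vector<int> V;        // voxels at the input of each block
};

static Geom read_geom(List geom) {
  Geom g;
  g.n_blocks = as<int>(geom["n_blocks"]);
  g.convs_per_block = as<int>(geom["convs_per_block"]);
  g.head_channels = as<int>(geom["head_channels"]);
  g.feat_len = as<int>(geom["feat_len"]);
  g.filters = as<std::vector<int>>(geom["filters"]);
  g.edges = as<std::vector<int>>(geom["edges"]);
  for (int b = 0; b < g.n_blocks; ++b)
    g.V.push_back(g.edges[b] * g.edges[b] * g.edges[b]);
  g.V_last = g.V[g.n_blocks - 1] / 8;
  g.C_last = g.filters[g.n_blocks - 1];
  return g;
}

static std::vector<fmat> to_fmats(List x) {
  std::vector<fmat> out;
  out.reserve(x.size());
  for (int i = 0; i < x.size(); ++i) {
    NumericMatrix m = as<NumericMatrix>(x[i]);
    fmat f(m.nrow(), m.ncol());
    std::copy(m.begin(), m.end(), f.memptr());
    out.push_back(std::move(f));
  }
  return out;
}

static List to_rlist(const std::vector<fmat>& x, CharacterVector names) {
  List out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    NumericMatrix m(x[i].n_rows, x[i].n_cols);
    std::copy(x[i].begin(), x[i].end(), m.begin());
    out[i] = m;
  }
  out.attr("names") = names;
  return out;
}

// Gather 3x3x3 neighbourhoods (zero padding): A is (Bn*V x C) with voxels
// x-fastest, out is (Bn*V x 27*C); offset order dx fastest, then dy, dz.
static void im2col(const fmat& A, int n, int Bn, fmat& out) {
  const int C = A.n_cols, V = n * n * n;
  out.zeros((arma::uword)Bn * V, (arma::uword)27 * C);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int x0 = std::max(0, -dx), x1 = std::min(n, n - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(n, n - dy);
        const int z0 = std::max(0, -dz), z1 = std::min(n, n - dz);
        const int len = x1 - x0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          float* dstc = out.colptr((size_t)k * C + c);
          const float* srcc = A.colptr(c);
          for (int s = 0; s < Bn; ++s) {
            const size_t base = (size_t)s * V;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const size_t doff = base + ((size_t)z * n + y) * n + x0;
                const size_t soff = base + ((size_t)(z + dz) * n + (y + dy)) * n + x0 + dx;
                std::memcpy(dstc + doff, srcc + soff, len * sizeof(float));
              }
          }
        }
      }
}

// Scatter-add the im2col gradient back onto the input grid.
static void col2im(const fmat& dcol, int n, int Bn, int C, fmat& dA) {
  const int V = n * n * n;
  dA.zeros((arma::uword)Bn * V, C);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int x0 = std::max(0, -dx), x1 = std::min(n, n - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(n, n - dy);
        const int z0 = std::max(0, -dz), z1 = std::min(n, n - dz);
        const int len = x1 - x0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const float* srcc = dcol.colptr((size_t)k * C + c);
          float* dstc = dA.colptr(c);
          for (int s = 0; s < Bn; ++s) {
            const size_t base = (size_t)s * V;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const float* src = srcc + base + ((size_t)z * n + y) * n + x0;
                float* dst = dstc + base + ((size_t)(z + dz) * n + (y + dy)) * n + x0 + dx;
                for (int i = 0; i < len; ++i) dst[i] += src[i];
              }
          }
        }
      }
}

struct ConvCache {
  fmat Acol;     // im2col of the conv input
  fmat xhat;     // normalised pre-activation
  frowvec istd;  // 1/sqrt(var + eps)
  fmat relu;     // post-activation (for the ReLU mask)
};

struct PoolCache {
  arma::Mat<int> amax;  // winning source row per (output row, channel)
};

// 2x2x2 max pooling from edge n to edge n/2; records argmax rows if amax
// is non-null.
static void maxpool(const fmat& A, int n, int Bn, fmat& out, arma::Mat<int>* amax) {
  const int m = n / 2, V = n * n * n, Vp = m * m * m, C = A.n_cols;
  out.set_size((arma::uword)Bn * Vp, C);
  if (amax) amax->set_size((arma::uword)Bn * Vp, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    int* am = amax ? amax->colptr(c) : nullptr;
    for (int s = 0; s < Bn; ++s) {
      const size_t ib = (size_t)s * V, ob = (size_t)s * Vp;
      for (int k = 0; k < m; ++k)
        for (int j = 0; j < m; ++j) {
          const size_t r00 = ib + ((size_t)(2 * k) * n + 2 * j) * n;
          const size_t r10 = ib + ((size_t)(2 * k) * n + 2 * j + 1) * n;
          const size_t r01 = ib + ((size_t)(2 * k + 1) * n + 2 * j) * n;
          const size_t r11 = ib + ((size_t)(2 * k + 1) * n + 2 * j + 1) * n;
          const size_t obase = ob + ((size_t)k * m + j) * m;
          for (int i = 0; i < m; ++i) {
            const size_t cand[8] = {r00 + 2 * i, r00 + 2 * i + 1,
                                    r10 + 2 * i, r10 + 2 * i + 1,
                                    r01 + 2 * i, r01 + 2 * i + 1,
                                    r11 + 2 * i, r11 + 2 * i + 1};
            float best = src[cand[0]];
            int bestr = (int)cand[0];
            for (int q = 1; q < 8; ++q)
              if (src[cand[q]] > best) { best = src[cand[q]]; bestr = (int)cand[q]; }
            dst[obase + i] = best;
            if (am) am[obase + i] = bestr;
          }
        }
    }
  }
}

// Forward one batch. In training mode batch statistics are used and caches
// filled; in eval mode running statistics are used and caches left empty.
static void forward_batch(const std::vector<fmat>& P, std::vector<fmat>& RS,
                          const Geom& g, const fmat& X0, bool training,
                          float bn_momentum,
                          std::vector<ConvCache>& ccache,
                          std::vector<PoolCache>& pcache,
                          fmat& A_last, fmat& head_relu, fmat& feat,
                          arma::fvec& prob) {
  const int Bn = X0.n_cols;
  const int J = g.convs_per_block;
  fmat A((arma::uword)Bn * g.V[0], 1);
  for (int s = 0; s < Bn; ++s)
    std::copy(X0.colptr(s), X0.colptr(s) + g.V[0], A.colptr(0) + (size_t)s * g.V[0]);

  int pi = 0;  // parameter cursor
  int ci = 0;  // conv counter
  for (int b = 0; b < g.n_blocks; ++b) {
    for (int j = 0; j < J; ++j, ++ci) {
      const fmat& W = P[pi]; const fmat& bias = P[pi + 1];
      const fmat& gamma = P[pi + 2]; const fmat& beta = P[pi + 3];
      pi += 4;
      ConvCache& cc = ccache[ci];
      fmat localcol;
      fmat& Acol = training ? cc.Acol : localcol;
      im2col(A, g.edges[b], Bn, Acol);
      fmat Z = Acol * W;
      Z.each_row() += bias.row(0);
      const int F = Z.n_cols;
      frowvec mu(F), var(F);
      if (training) {
        mu = arma::mean(Z, 0);
        Z.each_row() -= mu;
        var = arma::mean(arma::square(Z), 0);  // biased batch variance
        RS[2 * ci].row(0) = (1.0f - bn_momentum) * RS[2 * ci].row(0) + bn_momentum * mu;
        RS[2 * ci + 1].row(0) = (1.0f - bn_momentum) * RS[2 * ci + 1].row(0) + bn_momentum * var;
      } else {
        mu = RS[2 * ci].row(0);
        var = RS[2 * ci + 1].row(0);
        Z.each_row() -= mu;
      }
      frowvec istd = 1.0f / arma::sqrt(var + BN_EPS);
      Z.each_row() %= istd;
      if (training) { cc.xhat = Z; cc.istd = istd; }
      Z.each_row() %= gamma.row(0);
      Z.each_row() += beta.row(0);
      Z.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      if (training) cc.relu = Z;
      A = std::move(Z);
    }
    fmat Pool;
    maxpool(A, g.edges[b], Bn, Pool, training ? &pcache[b].amax : nullptr);
    A = std::move(Pool);
  }
  A_last = std::move(A);

  fmat Ah;
  if (g.head_channels > 0) {
    const fmat& Wh = P[pi]; const fmat& bh = P[pi + 1];
    Ah = A_last * Wh;
    Ah.each_row() += bh.row(0);
    Ah.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    head_relu = Ah;
    pi += 2;
  } else {
    Ah = A_last;
  }
  const int H = Ah.n_cols;
  feat.set_size(g.feat_len, Bn);
  for (int s = 0; s < Bn; ++s)
    for (int h = 0; h < H; ++h)
      std::copy(Ah.colptr(h) + (size_t)s * g.V_last,
                Ah.colptr(h) + (size_t)s * g.V_last + g.V_last,
                feat.colptr(s) + (size_t)h * g.V_last);

  const fmat& wd = P[pi]; const float bd = P[pi + 1](0, 0);
  prob.set_size(Bn);
  for (int s = 0; s < Bn; ++s) {
    float z = arma::dot(wd.col(0), feat.col(s)) + bd;
    prob(s) = 1.0f / (1.0f + std::exp(-z));
  }
}

// [[Rcpp::export]]
List cnn_epoch_cpp(List params, List adam_m, List adam_v, List run_stats,
                   List geom, NumericMatrix X, NumericVector y,
                   IntegerVector order, double lr, int batch_size,
                   int adam_t, double bn_momentum) {
  Geom g = read_geom(geom);
  std::vector<fmat> P = to_fmats(params);
  std::vector<fmat> M = to_fmats(adam_m);
  std::vector<fmat> Vv = to_fmats(adam_v);
  std::vector<fmat> RS = to_fmats(run_stats);
  const int n = order.size();
  const int n_conv = g.n_blocks * g.convs_per_block;
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;

  double total_loss = 0.0;
  std::vector<ConvCache> ccache(n_conv);
  std::vector<PoolCache> pcache(g.n_blocks);
  std::vector<fmat> G(P.size());

  for (int start = 0; start < n; start += batch_size) {
    const int Bn = std::min(batch_size, n - start);
    fmat X0(g.V[0], Bn);
    arma::fvec yb(Bn);
    for (int s = 0; s < Bn; ++s) {
      const int col = order[start + s] - 1;
      const double* src = &X[(size_t)col * X.nrow()];
      for (int v = 0; v < g.V[0]; ++v) X0(v, s) = (float)src[v];
      yb(s) = (float)y[col];
    }

    fmat A_last, head_relu, feat;
    arma::fvec prob;
    forward_batch(P, RS, g, X0, true, (float)bn_momentum,
                  ccache, pcache, A_last, head_relu, feat, prob);

    for (int s = 0; s < Bn; ++s) {
      const float p = std::min(std::max(prob(s), 1e-7f), 1.0f - 1e-7f);
      total_loss += -(yb(s) * std::log(p) + (1.0f - yb(s)) * std::log(1.0f - p));
    }

    // ---- backward ----
    for (size_t i = 0; i < P.size(); ++i) G[i].zeros(P[i].n_rows, P[i].n_cols);
    const int pi_dense = (int)P.size() - 2;
    const int pi_head = g.head_channels > 0 ? pi_dense - 2 : -1;

    arma::fvec dz = (prob - yb) / (float)Bn;
    G[pi_dense].col(0) = feat * dz;
    G[pi_dense + 1](0, 0) = arma::accu(dz);
    fmat dfeat = P[pi_dense].col(0) * dz.t();  // feat_len x Bn

    const int H = g.head_channels > 0 ? g.head_channels : g.C_last;
    fmat dAh((arma::uword)Bn * g.V_last, H);
    for (int s = 0; s < Bn; ++s)
      for (int h = 0; h < H; ++h)
        std::copy(dfeat.colptr(s) + (size_t)h * g.V_last,
                  dfeat.colptr(s) + (size_t)h * g.V_last + g.V_last,
                  dAh.colptr(h) + (size_t)s * g.V_last);

    fmat dA;
    if (g.head_channels > 0) {
      const float* hr = head_relu.memptr();
      float* dp = dAh.memptr();
      for (size_t q = 0; q < dAh.n_elem; ++q) if (hr[q] <= 0.0f) dp[q] = 0.0f;
      G[pi_head] = A_last.t() * dAh;
      G[pi_head + 1].row(0) = arma::sum(dAh, 0);
      dA = dAh * P[pi_head].t();
    } else {
      dA = std::move(dAh);
    }

    int pi = n_conv * 4;  // cursor past the last conv's parameters
    int ci = n_conv;
    for (int b = g.n_blocks - 1; b >= 0; --b) {
      // pool backward: route gradients to the argmax rows
      const int V = g.V[b], Vp = V / 8, F = g.filters[b];
      fmat dPrev;
      dPrev.zeros((arma::uword)Bn * V, F);
      const PoolCache& pc = pcache[b];
      for (int c = 0; c < F; ++c) {
        const float* src = dA.colptr(c);
        float* dst = dPrev.colptr(c);
        const int* am = pc.amax.colptr(c);
        for (arma::uword r = 0; r < (arma::uword)Bn * Vp; ++r) dst[am[r]] += src[r];
      }
      dA = std::move(dPrev);
      for (int j = g.convs_per_block - 1; j >= 0; --j) {
        --ci; pi -= 4;
        const ConvCache& cc = ccache[ci];
        const fmat& gamma = P[pi + 2];
        const float N = (float)dA.n_rows;
        {
          const float* rl = cc.relu.memptr();
          float* dp = dA.memptr();
          for (size_t q = 0; q < dA.n_elem; ++q) if (rl[q] <= 0.0f) dp[q] = 0.0f;
        }
        // batch-norm backward
        G[pi + 2].row(0) = arma::sum(dA % cc.xhat, 0);
        G[pi + 3].row(0) = arma::sum(dA, 0);
        fmat dxhat = std::move(dA);
        dxhat.each_row() %= gamma.row(0);
        frowvec s1 = arma::sum(dxhat, 0);
        frowvec s2 = arma::sum(dxhat % cc.xhat, 0);
        fmat dZ = std::move(dxhat);  // dZ computed in place from dxhat
        dZ *= N;
        dZ.each_row() -= s1;
        dZ -= cc.xhat.each_row() % s2;
        dZ.each_row() %= (cc.istd / N);
        // conv backward
        G[pi] = cc.Acol.t() * dZ;
        G[pi + 1].row(0) = arma::sum(dZ, 0);
        const bool need_dA = !(b == 0 && j == 0);
        if (need_dA) {
          fmat dcol = dZ * P[pi].t();
          const int Cin = (int)P[pi].n_rows / 27;
          col2im(dcol, g.edges[b], Bn, Cin, dA);
        }
      }
    }

    // ---- Adam ----
    ++adam_t;
    const float c1 = 1.0f - std::pow(b1, (float)adam_t);
    const float c2 = 1.0f - std::pow(b2, (float)adam_t);
    for (size_t i = 0; i < P.size(); ++i) {
      M[i] = b1 * M[i] + (1.0f - b1) * G[i];
      Vv[i] = b2 * Vv[i] + (1.0f - b2) * (G[i] % G[i]);
      P[i] -= (float)lr * (M[i] / c1) / (arma::sqrt(Vv[i] / c2) + aeps);
    }
  }

  return List::create(
    _["params"] = to_rlist(P, params.names()),
    _["adam_m"] = to_rlist(M, adam_m.names()),
    _["adam_v"] = to_rlist(Vv, adam_v.names()),
    _["run_stats"] = to_rlist(RS, run_stats.names()),
    _["loss"] = total_loss / n,
    _["adam_t"] = adam_t
  );
}

// [[Rcpp::export]]
List cnn_infer_cpp(List params, List run_stats, List geom, NumericMatrix X,
                   bool want_features, int batch_size) {
  Geom g = read_geom(geom);
  std::vector<fmat> P = to_fmats(params);
  std::vector<fmat> RS = to_fmats(run_stats);
  const int n = X.ncol();
  NumericVector prob_out(n);
  NumericMatrix feat_out;
  if (want_features) feat_out = NumericMatrix(g.feat_len, n);

  std::vector<ConvCache> ccache(g.n_blocks * g.convs_per_block);
  std::vector<PoolCache> pcache(g.n_blocks);
  for (int start = 0; start < n; start += batch_size) {
    const int Bn = std::min(batch_size, n - start);
    fmat X0(g.V[0], Bn);
    for (int s = 0; s < Bn; ++s) {
      const double* src = &X[(size_t)(start + s) * X.nrow()];
      for (int v = 0; v < g.V[0]; ++v) X0(v, s) = (float)src[v];
    }
    fmat A_last, head_relu, feat;
    arma::fvec prob;
    forward_batch(P, RS, g, X0, false, 0.0f, ccache, pcache,
                  A_last, head_relu, feat, prob);
    for (int s = 0; s < Bn; ++s) {
      prob_out[start + s] = prob(s);
      if (want_features)
        for (int f = 0; f < g.feat_len; ++f) feat_out(f, start + s) = feat(f, s);
    }
  }
  return List::create(_["prob"] = prob_out,
                      _["features"] = want_features ? (SEXP)feat_out : R_NilValue);
}
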