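// 3D convolutional network for corneal volume classification.
//
// Topology: four valid 3x3x3 convolutions (ReLU) each followed by a 2x2x2
// max pool (stride 2), two fully connected ReLU layers, and a softmax
// output. Convolutions are evaluated as im2col + single-precision GEMM;
// everything is single-threaded and deterministic. Weights travel to and
// from R as double matrices; training runs entirely on float buffers.
//
// Feature maps are stored voxel-major: fmat (V x C), voxel linear index
// i1 + n1*(i2 + n2*i3). im2col column index = offset + 27*channel, matching
// the conv weight layout (27*C_in x C_out).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uvec;

struct Dims3 { int n1, n2, n3; int vox() const { return n1 * n2 * n3; } };

static Dims3 conv_out(const Dims3& d) { return {d.n1 - 2, d.n2 - 2, d.n3 - 2}; }
static Dims3 pool_out(const Dims3& d) { return {d.n1 / 2, d.n2 / 2, d.n3 / 2}; }

// Gather 3x3x3 patches of A (V x C) into P (V_out x 27*C).
static void im2col(const fmat& A, const Dims3& d, fmat& P) {
  Dims3 o = conv_out(d);
  const int C = (int)A.n_cols;
  const int m1 = o.n1;
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (int o3 = 0; o3 < 3; ++o3)
      for (int o2 = 0; o2 < 3; ++o2)
        for (int o1 = 0; o1 < 3; ++o1) {
          float* dst = P.colptr((o1 + 3 * (o2 + 3 * o3)) + 27 * c);
          for (int j3 = 0; j3 < o.n3; ++j3)
            for (int j2 = 0; j2 < o.n2; ++j2) {
              const float* s = src + o1 + d.n1 * ((j2 + o2) + (size_t)d.n2 * (j3 + o3));
              std::memcpy(dst + (size_t)m1 * (j2 + (size_t)o.n2 * j3), s,
                          sizeof(float) * m1);
            }
        }
  }
}

// Scatter-accumulate patch gradients back onto the input map.
static void col2im(const fmat& dP, const Dims3& d, fmat& dA) {
  Dims3 o = conv_out(d);
  const int C = (int)dA.n_cols;
  const int m1 = o.n1;
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    for (int o3 = 0; o3 < 3; ++o3)
      for (int o2 = 0; o2 < 3; ++o2)
        for (int o1 = 0; o1 < 3; ++o1) {
          const float* src = dP.colptr((o1 + 3 * (o2 + 3 * o3)) + 27 * c);
          for (int j3 = 0; j3 < o.n3; ++j3)
            for (int j2 = 0; j2 < o.n2; ++j2) {
              float* dd = dst + o1 + d.n1 * ((j2 + o2) + (size_t)d.n2 * (j3 + o3));
              const float* ss = src + (size_t)m1 * (j2 + (size_t)o.n2 * j3);
              for (int j1 = 0; j1 < m1; ++j1) dd[j1] += ss[j1];
            }
        }
  }
}

// 2x2x2 max pool, stride 2; records winner voxel indices for backprop.
static void maxpool(const fmat& A, const Dims3& d, fmat& O, arma::umat& idx) {
  Dims3 p = pool_out(d);
  const int C = (int)A.n_cols;
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = O.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int j3 = 0; j3 < p.n3; ++j3)
      for (int j2 = 0; j2 < p.n2; ++j2)
        for (int j1 = 0; j1 < p.n1; ++j1) {
          float best = -1e30f; size_t bi = 0;
          for (int k3 = 0; k3 < 2; ++k3)
            for (int k2 = 0; k2 < 2; ++k2)
              for (int k1 = 0; k1 < 2; ++k1) {
                size_t v = (2 * j1 + k1) +
                           (size_t)d.n1 * ((2 * j2 + k2) + (size_t)d.n2 * (2 * j3 + k3));
                if (src[v] > best) { best = src[v]; bi = v; }
              }
          size_t j = j1 + (size_t)p.n1 * (j2 + (size_t)p.n2 * j3);
          dst[j] = best; ix[j] = bi;
        }
  }
}

struct Net {
  int edge, fc_width, n_classes;
  arma::ivec channels;          // 4 conv output channel counts
  Dims3 din[4], dconv[4], dpool[4];
  int flat;                     // flattened feature length
  // parameters (float copies)
  fmat Wc[4]; fvec bc[4];
  fmat Wf[3]; fvec bf[3];
  // gradients
  fmat gWc[4]; fvec gbc[4];
  fmat gWf[3]; fvec gbf[3];
  // per-sample buffers
  fmat in[4];                   // conv inputs (V x C)
  fmat patches[4];              // im2col buffers
  fmat conv[4];                 // post-ReLU conv outputs
  fmat pool[4]; arma::umat pidx[4];
  fvec fcin[3], fcout[3];       // fc activations (fcout post-ReLU / logits)
  fmat dP, dY, dA;              // scratch for backward (resized per layer)
};

static void net_shapes(Net& net) {
  Dims3 d = {net.edge, net.edge, net.edge};
  for (int l = 0; l < 4; ++l) {
    net.din[l] = d;
    net.dconv[l] = conv_out(d);
    if (net.dconv[l].n1 < 1 || net.dconv[l].n2 < 1 || net.dconv[l].n3 < 1)
      stop("input_edge too small: convolution layer %d has no support", l + 1);
    net.dpool[l] = pool_out(net.dconv[l]);
    if (net.dpool[l].n1 < 1)
      stop("input_edge too small: pooling layer %d collapses", l + 1);
    d = net.dpool[l];
  }
  net.flat = d.vox() * (int)net.channels[3];
}

static void net_init(Net& net, const List& weights, int edge, IntegerVector channels,
                     int fc_width, int n_classes, bool alloc_train) {
  net.edge = edge; net.fc_width = fc_width; net.n_classes = n_classes;
  net.channels = arma::ivec(4);
  for (int i = 0; i < 4; ++i) net.channels[i] = channels[i];
  net_shapes(net);
  int wi = 0;
  for (int l = 0; l < 4; ++l) {
    NumericMatrix W = weights[wi++]; NumericVector b = weights[wi++];
    net.Wc[l] = arma::conv_to<fmat>::from(as<arma::mat>(W));
    net.bc[l] = arma::conv_to<fvec>::from(as<arma::vec>(b));
  }
  for (int l = 0; l < 3; ++l) {
    NumericMatrix W = weights[wi++]; NumericVector b = weights[wi++];
    net.Wf[l] = arma::conv_to<fmat>::from(as<arma::mat>(W));
    net.bf[l] = arma::conv_to<fvec>::from(as<arma::vec>(b));
  }
  int cin = 1;
  for (int l = 0; l < 4; ++l) {
    net.in[l].set_size(net.din[l].vox(), cin);
    net.patches[l].set_size(net.dconv[l].vox(), 27 * cin);
    net.conv[l].set_size(net.dconv[l].vox(), net.channels[l]);
    net.pool[l].set_size(net.dpool[l].vox(), net.channels[l]);
    net.pidx[l].set_size(net.dpool[l].vox(), net.channels[l]);
    if (alloc_train) { net.gWc[l].zeros(arma::size(net.Wc[l])); net.gbc[l].zeros(arma::size(net.bc[l])); }
    cin = (int)net.channels[l];
  }
  for (int l = 0; l < 3; ++l)
    if (alloc_train) { net.gWf[l].zeros(arma::size(net.Wf[l])); net.gbf[l].zeros(arma::size(net.bf[l])); }
}

// Forward pass; x length edge^3. Returns class probabilities.
static fvec net_forward(Net& net, const float* x) {
  std::memcpy(net.in[0].memptr(), x, sizeof(float) * net.in[0].n_elem);
  for (int l = 0; l < 4; ++l) {
    im2col(net.in[l], net.din[l], net.patches[l]);
    net.conv[l] = net.patches[l] * net.Wc[l];
    net.conv[l].each_row() += net.bc[l].t();
    net.conv[l].transform([](float v) { return v > 0.f ? v : 0.f; });
    maxpool(net.conv[l], net.dconv[l], net.pool[l], net.pidx[l]);
    if (l < 3) net.in[l + 1] = net.pool[l];
  }
  net.fcin[0] = fvec(net.pool[3].memptr(), net.flat);
  for (int l = 0; l < 3; ++l) {
    net.fcout[l] = net.Wf[l] * net.fcin[l] + net.bf[l];
    if (l < 2) {
      net.fcout[l].transform([](float v) { return v > 0.f ? v : 0.f; });
      net.fcin[l + 1] = net.fcout[l];
    }
  }
  fvec logits = net.fcout[2];
  float mx = logits.max();
  fvec p = arma::exp(logits - mx);
  return p / arma::accu(p);
}

// Backward pass from probabilities; accumulates gradients.
static void net_backward(Net& net, const fvec& p, int label) {
  fvec dlog = p;
  dlog[label] -= 1.f;
  fvec dcur = dlog;
  for (int l = 2; l >= 0; --l) {
    net.gWf[l] += dcur * net.fcin[l].t();
    net.gbf[l] += dcur;
    fvec dprev = net.Wf[l].t() * dcur;
    if (l > 0) {
      for (arma::uword i = 0; i < dprev.n_elem; ++i)
        if (net.fcout[l - 1][i] <= 0.f) dprev[i] = 0.f;
    }
    dcur = dprev;
  }
  // gradient w.r.t. the flattened pool-4 output
  fmat dpool = fmat(dcur.memptr(), net.dpool[3].vox(), net.channels[3]);
  for (int l = 3; l >= 0; --l) {
    // unpool
    net.dY.zeros(net.dconv[l].vox(), net.channels[l]);
    for (int c = 0; c < net.channels[l]; ++c) {
      const float* dp = dpool.colptr(c);
      const arma::uword* ix = net.pidx[l].colptr(c);
      float* dy = net.dY.colptr(c);
      for (int j = 0; j < net.dpool[l].vox(); ++j) dy[ix[j]] += dp[j];
    }
    // ReLU mask (in place; the obvious conv_to<fmat>(conv > 0) detour is
    // an order of magnitude slower on maps this large)
    {
      const float* cv = net.conv[l].memptr();
      float* dy = net.dY.memptr();
      const size_t ne = net.dY.n_elem;
      for (size_t i = 0; i < ne; ++i) if (cv[i] <= 0.f) dy[i] = 0.f;
    }
    net.gWc[l] += net.patches[l].t() * net.dY;
    net.gbc[l] += arma::sum(net.dY, 0).t();
    if (l > 0) {
      net.dP = net.dY * net.Wc[l].t();
      net.dA.set_size(net.din[l].vox(), (int)net.in[l].n_cols);
      col2im(net.dP, net.din[l], net.dA);
      dpool = net.dA;
    }
  }
}

static NumericVector vec_out(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

static List export_weights(const Net& net) {
  List out(14);
  int wi = 0;
  for (int l = 0; l < 4; ++l) {
    out[wi++] = wrap(arma::conv_to<arma::mat>::from(net.Wc[l]));
    out[wi++] = vec_out(net.bc[l]);
  }
  for (int l = 0; l < 3; ++l) {
    out[wi++] = wrap(arma::conv_to<arma::mat>::from(net.Wf[l]));
    out[wi++] = vec_out(net.bf[l]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List weights, NumericVector x, int edge,
                              IntegerVector channels, int fc_width, int n_classes) {
  Net net;
  net_init(net, weights, edge, channels, fc_width, n_classes, false);
  if ((int)x.size() != edge * edge * edge) stop("volume has wrong length for input_edge");
  std::vector<float> xf(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) xf[i] = (float)x[i];
  fvec p = net_forward(net, xf.data());
  return NumericVector(p.begin(), p.end());
}

// Mini-batch SGD training. `order` is an (n x epochs) matrix of 0-based
// visit orders, pre-drawn in R so all randomness flows through R's RNG.
// [[Rcpp::export]]
List cnn_train_cpp(List weights, List X, IntegerVector y, int edge,
                   IntegerVector channels, int fc_width, int n_classes,
                   double lr, int batch_size, int epochs, IntegerMatrix order,
                   bool early_stop, double early_stop_loss) {
  Net net;
  net_init(net, weights, edge, channels, fc_width, n_classes, true);
  int n = X.size();
  std::vector<std::vector<float>> Xf(n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X[i];
    if ((int)xi.size() != edge * edge * edge) stop("volume %d has wrong length", i + 1);
    Xf[i].resize(xi.size());
    for (R_xlen_t j = 0; j < xi.size(); ++j) Xf[i][j] = (float)xi[j];
  }
  NumericVector ep_loss(epochs, NA_REAL), ep_acc(epochs, NA_REAL);
  int epochs_run = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0; int correct = 0;
    int pos = 0;
    while (pos < n) {
      int bsz = std::min(batch_size, n - pos);
      for (int l = 0; l < 4; ++l) { net.gWc[l].zeros(); net.gbc[l].zeros(); }
      for (int l = 0; l < 3; ++l) { net.gWf[l].zeros(); net.gbf[l].zeros(); }
      for (int b = 0; b < bsz; ++b) {
        int i = order(pos + b, ep);
        fvec p = net_forward(net, Xf[i].data());
        int lab = y[i];
        loss_sum += -std::log(std::max((double)p[lab], 1e-12));
        if ((int)p.index_max() == lab) ++correct;
        net_backward(net, p, lab);
        Rcpp::checkUserInterrupt();
      }
      float scale = (float)(lr / bsz);
      for (int l = 0; l < 4; ++l) { net.Wc[l] -= scale * net.gWc[l]; net.bc[l] -= scale * net.gbc[l]; }
      for (int l = 0; l < 3; ++l) { net.Wf[l] -= scale * net.gWf[l]; net.bf[l] -= scale * net.gbf[l]; }
      pos += bsz;
    }
    ep_loss[ep] = loss_sum / n;
    ep_acc[ep] = (double)correct / n;
    epochs_run = ep + 1;
    if (early_stop && correct == n && ep_loss[ep] <= early_stop_loss) break;
  }
  return List::create(_["weights"] = export_weights(net),
                      _["loss"] = ep_loss, _["accuracy"] = ep_acc,
                      _["epochs_run"] = epochs_run);
}

// Layer output shapes for a given input edge (used by configuration
// validation and documentation).
// [[Rcpp::export]]
IntegerMatrix cnn_shapes_cpp(int edge) {
  IntegerMatrix out(8, 1);
  int d = edge;
  for (int l = 0; l < 4; ++l) {
    d -= 2;
    if (d < 1) stop("input_edge too small: convolution layer %d has no support", l + 1);
    out(2 * l, 0) = d;
    d /= 2;
    if (d < 1) stop("input_edge too small: pooling layer %d collapses", l + 1);
    out(2 * l + 1, 0) = d;
  }
  return out;
}
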