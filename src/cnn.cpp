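// Minimal CNN engine: convolution (im2col/GEMM), max pooling, fully
// connected layers, ReLU, softmax cross-entropy, SGD with momentum.
// Single-threaded and fully deterministic given the seed (own Fisher-Yates
// shuffle on a mt19937 stream; weight initialization happens in R).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;

struct LayerDef { int type, a, k, s, p; };  // type: 0 conv, 1 pool, 2 fc

static std::vector<LayerDef> parse_spec(const IntegerMatrix& spec) {
  std::vector<LayerDef> defs;
  for (int i = 0; i < spec.nrow(); ++i)
    defs.push_back({spec(i, 0), spec(i, 1), spec(i, 2), spec(i, 3),
                    spec(i, 4)});
  return defs;
}

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// columns are output positions (column-major over outH x outW), rows are the
// receptive field unrolled (row fastest, then col, then channel)
static mat im2col(const cube& x, int k, int s, int p, int outH, int outW) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(k * k * C, outH * outW);
  for (int oc = 0; oc < outW; ++oc) {
    for (int orow = 0; orow < outH; ++orow) {
      const int col_idx = oc * outH + orow;
      const int r0 = orow * s - p, c0 = oc * s - p;
      double* dst = cols.colptr(col_idx);
      int idx = 0;
      for (int ch = 0; ch < C; ++ch)
        for (int cc = 0; cc < k; ++cc)
          for (int rr = 0; rr < k; ++rr) {
            const int r = r0 + rr, c = c0 + cc;
            dst[idx++] = (r >= 0 && r < H && c >= 0 && c < W)
                           ? x(r, c, ch) : 0.0;
          }
    }
  }
  return cols;
}

static void col2im(const mat& dcols, cube& dx, int k, int s, int p,
                   int outH, int outW) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int oc = 0; oc < outW; ++oc) {
    for (int orow = 0; orow < outH; ++orow) {
      const int col_idx = oc * outH + orow;
      const int r0 = orow * s - p, c0 = oc * s - p;
      const double* src = dcols.colptr(col_idx);
      int idx = 0;
      for (int ch = 0; ch < C; ++ch)
        for (int cc = 0; cc < k; ++cc)
          for (int rr = 0; rr < k; ++rr) {
            const int r = r0 + rr, c = c0 + cc;
            if (r >= 0 && r < H && c >= 0 && c < W) dx(r, c, ch) += src[idx];
            ++idx;
          }
    }
  }
}

struct Net {
  std::vector<LayerDef> defs;
  int inH, inW, inC;
  std::vector<mat> W;   // per weighted layer
  std::vector<vec> b;
  // per-layer input dims (spatial layers); fc part tracked separately
  std::vector<int> dH, dW_, dC;

  void init_dims() {
    int h = inH, w = inW, c = inC;
    for (const auto& d : defs) {
      dH.push_back(h); dW_.push_back(w); dC.push_back(c);
      if (d.type == 0) {            // conv
        h = out_size(h, d.k, d.s, d.p);
        w = out_size(w, d.k, d.s, d.p);
        c = d.a;
      } else if (d.type == 1) {     // pool
        h = out_size(h, d.k, d.s, 0);
        w = out_size(w, d.k, d.s, 0);
      } else {                      // fc: flatten
        h = 1; w = 1; c = d.a;
      }
      if (h < 1 || w < 1)
        Rcpp::stop("layer output collapses to zero size");
    }
  }
};

struct Cache {
  std::vector<mat> conv_cols;     // per conv layer
  std::vector<cube> conv_out;     // post-ReLU output
  std::vector<Mat<uword>> pool_arg; // per pool layer: argmax linear idx per out elem
  std::vector<vec> fc_in;         // per fc layer
  std::vector<vec> fc_out;        // post-activation
  std::vector<cube> layer_in;     // spatial input per layer (empty for fc)
};

// forward pass; returns softmax probabilities (length = final units)
static vec forward(const Net& net, const cube& x0, Cache* cache) {
  cube x = x0;
  vec v;                 // flattened vector once we enter fc territory
  bool flat = false;
  int wi = 0, ci = 0, pi = 0, fi = 0;
  for (size_t li = 0; li < net.defs.size(); ++li) {
    const LayerDef& d = net.defs[li];
    if (d.type == 0) {
      const int outH = out_size(x.n_rows, d.k, d.s, d.p);
      const int outW = out_size(x.n_cols, d.k, d.s, d.p);
      mat cols = im2col(x, d.k, d.s, d.p, outH, outW);
      mat z = net.W[wi] * cols;
      z.each_col() += net.b[wi];
      z.transform([](double val) { return val > 0.0 ? val : 0.0; });
      cube out(outH, outW, d.a);
      for (int f = 0; f < d.a; ++f)
        out.slice(f) = reshape(z.row(f), outH, outW);
      if (cache) {
        cache->layer_in.push_back(x);
        cache->conv_cols.push_back(std::move(cols));
        cache->conv_out.push_back(out);
      }
      x = std::move(out);
      ++wi; ++ci;
    } else if (d.type == 1) {
      const int outH = out_size(x.n_rows, d.k, d.s, 0);
      const int outW = out_size(x.n_cols, d.k, d.s, 0);
      cube out(outH, outW, x.n_slices);
      Mat<uword> argm(outH * outW, x.n_slices);
      for (uword ch = 0; ch < x.n_slices; ++ch) {
        const mat& sl = x.slice(ch);
        for (int oc = 0; oc < outW; ++oc)
          for (int orow = 0; orow < outH; ++orow) {
            double best = -datum::inf; uword bidx = 0;
            for (int cc = 0; cc < d.k; ++cc)
              for (int rr = 0; rr < d.k; ++rr) {
                const int r = orow * d.s + rr, c = oc * d.s + cc;
                if (r < (int)sl.n_rows && c < (int)sl.n_cols &&
                    sl(r, c) > best) {
                  best = sl(r, c);
                  bidx = (uword)c * sl.n_rows + r;
                }
              }
            out(orow, oc, ch) = best;
            argm(oc * outH + orow, ch) = bidx;
          }
      }
      if (cache) {
        cache->layer_in.push_back(x);
        cache->pool_arg.push_back(std::move(argm));
      }
      x = std::move(out);
      ++pi;
    } else {  // fc
      if (!flat) { v = vectorise(x); flat = true; }
      vec z = net.W[wi] * v + net.b[wi];
      const bool last = (li == net.defs.size() - 1);
      if (!last) z.transform([](double val) { return val > 0.0 ? val : 0.0; });
      if (cache) {
        cache->layer_in.push_back(cube());
        cache->fc_in.push_back(v);
        cache->fc_out.push_back(z);
      }
      v = std::move(z);
      ++wi; ++fi;
    }
  }
  // softmax
  vec z = v - v.max();
  vec e = exp(z);
  return e / accu(e);
}

// backward pass; accumulates gradients into gW/gb; returns loss
static double backward(const Net& net, const Cache& cache, const vec& probs,
                       int label, std::vector<mat>& gW, std::vector<vec>& gb) {
  const double loss = -std::log(std::max(probs(label), 1e-12));
  // layer-wise indices of weighted / conv / pool / fc caches
  int wi = (int)net.W.size() - 1;
  int ci = (int)cache.conv_cols.size() - 1;
  int pi = (int)cache.pool_arg.size() - 1;
  int fi = (int)cache.fc_in.size() - 1;

  vec dv = probs;       // dL/dz at output (softmax + CE)
  dv(label) -= 1.0;
  cube dx;              // gradient in spatial form once we leave fc territory
  bool spatial = false;

  for (int li = (int)net.defs.size() - 1; li >= 0; --li) {
    const LayerDef& d = net.defs[li];
    if (d.type == 2) {
      const bool last = (li == (int)net.defs.size() - 1);
      vec dz = dv;
      if (!last) {       // ReLU mask of this layer's output
        const vec& out = cache.fc_out[fi];
        for (uword i = 0; i < dz.n_elem; ++i) if (out(i) <= 0.0) dz(i) = 0.0;
      }
      gW[wi] += dz * cache.fc_in[fi].t();
      gb[wi] += dz;
      dv = net.W[wi].t() * dz;
      --wi; --fi;
    } else if (d.type == 1) {
      if (!spatial) {
        // dv corresponds to the flattened pool output; reshape
        const cube& in = cache.layer_in[li];
        const int outH = out_size(in.n_rows, d.k, d.s, 0);
        const int outW = out_size(in.n_cols, d.k, d.s, 0);
        dx = cube(outH, outW, in.n_slices);
        std::memcpy(dx.memptr(), dv.memptr(), sizeof(double) * dv.n_elem);
        spatial = true;
      }
      const cube& in = cache.layer_in[li];
      cube dprev(in.n_rows, in.n_cols, in.n_slices, fill::zeros);
      const Mat<uword>& argm = cache.pool_arg[pi];
      const int outH = dx.n_rows, outW = dx.n_cols;
      for (uword ch = 0; ch < dx.n_slices; ++ch) {
        mat& dps = dprev.slice(ch);
        for (int oc = 0; oc < outW; ++oc)
          for (int orow = 0; orow < outH; ++orow)
            dps(argm(oc * outH + orow, ch)) += dx(orow, oc, ch);
      }
      dx = std::move(dprev);
      --pi;
    } else {  // conv
      if (!spatial) {
        const cube& out = cache.conv_out[ci];
        dx = cube(out.n_rows, out.n_cols, out.n_slices);
        std::memcpy(dx.memptr(), dv.memptr(), sizeof(double) * dv.n_elem);
        spatial = true;
      }
      const cube& out = cache.conv_out[ci];
      const int outH = out.n_rows, outW = out.n_cols, outC = out.n_slices;
      mat dz(outC, outH * outW);
      for (int f = 0; f < outC; ++f) {
        const mat& os = out.slice(f);
        const mat& ds = dx.slice(f);
        for (int j = 0; j < outH * outW; ++j)
          dz(f, j) = (os(j) > 0.0) ? ds(j) : 0.0;
      }
      gW[wi] += dz * cache.conv_cols[ci].t();
      gb[wi] += sum(dz, 1);
      const cube& in = cache.layer_in[li];
      if (li > 0) {   // no need to propagate into the input image
        mat dcols = net.W[wi].t() * dz;
        cube dprev(in.n_rows, in.n_cols, in.n_slices, fill::zeros);
        col2im(dcols, dprev, d.k, d.s, d.p, outH, outW);
        dx = std::move(dprev);
      }
      --wi; --ci;
    }
  }
  return loss;
}

static Net build_net(const IntegerMatrix& spec, const List& weights,
                     int inH, int inW, int inC) {
  Net net;
  net.defs = parse_spec(spec);
  net.inH = inH; net.inW = inW; net.inC = inC;
  net.init_dims();
  for (int i = 0; i < weights.size(); ++i) {
    List wl = weights[i];
    net.W.push_back(Rcpp::as<mat>(wl["W"]));
    net.b.push_back(Rcpp::as<vec>(wl["b"]));
  }
  return net;
}

static cube make_input(const cube& images, uword idx, int inC) {
  cube x(images.n_rows, images.n_cols, inC);
  for (int c = 0; c < inC; ++c) x.slice(c) = images.slice(idx);
  return x;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& images, const IntegerVector& labels,
                   const IntegerMatrix& spec, const List& weights_init,
                   int epochs, int batch, const NumericVector& lr,
                   double momentum, double weight_decay, double clip_norm,
                   int seed, int input_channels) {
  Net net = build_net(spec, weights_init, images.n_rows, images.n_cols,
                      input_channels);
  const int n = images.n_slices;
  if (n == 0) Rcpp::stop("empty training set");
  std::vector<mat> vel_W; std::vector<vec> vel_b;
  for (size_t i = 0; i < net.W.size(); ++i) {
    vel_W.push_back(mat(size(net.W[i]), fill::zeros));
    vel_b.push_back(vec(size(net.b[i]), fill::zeros));
  }
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector loss_hist(epochs), acc_hist(epochs);
  std::vector<mat> gW(net.W.size());
  std::vector<vec> gb(net.b.size());

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with explicit draws (portable determinism)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng() % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0; int ep_correct = 0;
    const double eta = lr[std::min(ep, (int)lr.size() - 1)];
    for (int start = 0; start < n; start += batch) {
      const int stop = std::min(start + batch, n);
      const int bs = stop - start;
      for (size_t i = 0; i < net.W.size(); ++i) {
        gW[i] = mat(size(net.W[i]), fill::zeros);
        gb[i] = vec(size(net.b[i]), fill::zeros);
      }
      for (int ii = start; ii < stop; ++ii) {
        const int idx = order[ii];
        cube x = make_input(images, idx, input_channels);
        Cache cache;
        vec probs = forward(net, x, &cache);
        ep_loss += backward(net, cache, probs, labels[idx], gW, gb);
        if ((int)probs.index_max() == labels[idx]) ++ep_correct;
      }
      // global gradient-norm clipping guards against early divergence
      double sq = 0.0;
      for (size_t i = 0; i < net.W.size(); ++i) {
        sq += accu(square(gW[i] / bs)) + accu(square(gb[i] / bs));
      }
      const double gnorm = std::sqrt(sq);
      const double scale = (clip_norm > 0.0 && gnorm > clip_norm)
                             ? clip_norm / gnorm : 1.0;
      for (size_t i = 0; i < net.W.size(); ++i) {
        mat gradW = scale * (gW[i] / bs) + weight_decay * net.W[i];
        vec gradb = scale * (gb[i] / bs);
        vel_W[i] = momentum * vel_W[i] - eta * gradW;
        vel_b[i] = momentum * vel_b[i] - eta * gradb;
        net.W[i] += vel_W[i];
        net.b[i] += vel_b[i];
      }
    }
    loss_hist[ep] = ep_loss / n;
    acc_hist[ep] = (double)ep_correct / n;
    Rcpp::checkUserInterrupt();
  }

  List wout(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i)
    wout[i] = List::create(Rcpp::Named("W") = net.W[i],
                           Rcpp::Named("b") = net.b[i]);
  return List::create(Rcpp::Named("weights") = wout,
                      Rcpp::Named("loss") = loss_hist,
                      Rcpp::Named("train_acc") = acc_hist);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::cube& images, const IntegerMatrix& spec,
                          const List& weights, int input_channels) {
  Net net = build_net(spec, weights, images.n_rows, images.n_cols,
                      input_channels);
  const int n = images.n_slices;
  const int nclass = net.b.back().n_elem;
  mat out(n, nclass);
  for (int i = 0; i < n; ++i) {
    cube x = make_input(images, i, input_channels);
    out.row(i) = forward(net, x, nullptr).t();
  }
  return out;
}

// loss and full gradient for one image; used for finite-difference checks
// [[Rcpp::export]]
List cnn_loss_grad_cpp(const arma::mat& image, int label,
                       const IntegerMatrix& spec, const List& weights,
                       int input_channels) {
  cube imgs(image.n_rows, image.n_cols, 1);
  imgs.slice(0) = image;
  Net net = build_net(spec, weights, image.n_rows, image.n_cols,
                      input_channels);
  std::vector<mat> gW(net.W.size());
  std::vector<vec> gb(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    gW[i] = mat(size(net.W[i]), fill::zeros);
    gb[i] = vec(size(net.b[i]), fill::zeros);
  }
  cube x = make_input(imgs, 0, input_channels);
  Cache cache;
  vec probs = forward(net, x, &cache);
  double loss = backward(net, cache, probs, label, gW, gb);
  List grads(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i)
    grads[i] = List::create(Rcpp::Named("dW") = gW[i],
                            Rcpp::Named("db") = gb[i]);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("probs") = probs,
                      Rcpp::Named("grads") = grads);
}
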