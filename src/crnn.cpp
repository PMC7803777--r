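// Compute backend for the segment classifier: shared convolutional encoder
// applied to each motion image of a segment, stacked LSTM over the 21-step
// feature sequence, dense head with sigmoid output.  Single precision for
// the heavy linear algebra; Adam moments kept in double.
//
// Data layout conventions (must stay consistent everywhere):
//  - an image batch is a (px*px) x (T*B) matrix, columns ordered
//    segment-major: column s*T + t is frame t of segment s;
//  - a feature map is a (C x H*W) matrix with spatial index col*H + row
//    (R column-major order of a H x W matrix);
//  - im2col row index is ch*k*k + dc*k + dr.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::u32;

struct NetSpec {
  int px = 0, T = 0, k = 0;
  std::vector<int> filters, units, fc;
  bool lstm_relu = true;
  double dropout = 0.2;
  std::vector<int> side; // spatial side entering each conv block; side.back() = final
  int D = 0;             // flattened per-frame feature length
};

static NetSpec parse_spec(const List& spec) {
  NetSpec s;
  s.px = as<int>(spec["input_px"]);
  s.T = as<int>(spec["n_frames"]);
  s.k = as<int>(spec["kernel"]);
  s.filters = as<std::vector<int>>(spec["conv_filters"]);
  s.units = as<std::vector<int>>(spec["lstm_units"]);
  s.fc = as<std::vector<int>>(spec["fc_widths"]);
  s.lstm_relu = as<bool>(spec["lstm_relu"]);
  s.dropout = as<double>(spec["dropout"]);
  if (s.k % 2 != 1) stop("kernel size must be odd");
  if (s.fc.empty() || s.fc.back() != 1) stop("last fc width must be 1");
  int side = s.px;
  for (size_t i = 0; i < s.filters.size(); ++i) {
    s.side.push_back(side);
    if (side % 2 != 0) stop("input_px must be divisible by 2^(number of conv blocks)");
    side /= 2;
  }
  s.side.push_back(side);
  s.D = side * side * s.filters.back();
  return s;
}

struct ParamSlot {
  std::string name;
  int nrow, ncol;
  long offset;
};

static std::vector<ParamSlot> layout_of(const NetSpec& s) {
  std::vector<ParamSlot> L;
  long off = 0;
  auto add = [&](const std::string& nm, int nr, int nc) {
    L.push_back({nm, nr, nc, off});
    off += (long)nr * nc;
  };
  int cin = 1;
  for (size_t i = 0; i < s.filters.size(); ++i) {
    int f = s.filters[i];
    add("conv" + std::to_string(i + 1) + "_W", f, s.k * s.k * cin);
    add("conv" + std::to_string(i + 1) + "_b", f, 1);
    cin = f;
  }
  int din = s.D;
  for (size_t i = 0; i < s.units.size(); ++i) {
    int u = s.units[i];
    add("lstm" + std::to_string(i + 1) + "_W", 4 * u, din + u);
    add("lstm" + std::to_string(i + 1) + "_b", 4 * u, 1);
    din = u;
  }
  for (size_t i = 0; i < s.fc.size(); ++i) {
    add("fc" + std::to_string(i + 1) + "_W", s.fc[i], din);
    add("fc" + std::to_string(i + 1) + "_b", s.fc[i], 1);
    din = s.fc[i];
  }
  return L;
}

static long n_params_of(const NetSpec& s) {
  auto L = layout_of(s);
  return L.back().offset + (long)L.back().nrow * L.back().ncol;
}

// [[Rcpp::export]]
DataFrame cpp_layout(List spec) {
  NetSpec s = parse_spec(spec);
  auto L = layout_of(s);
  int n = L.size();
  CharacterVector nm(n);
  IntegerVector nr(n), nc(n);
  NumericVector off(n);
  for (int i = 0; i < n; ++i) {
    nm[i] = L[i].name; nr[i] = L[i].nrow; nc[i] = L[i].ncol; off[i] = (double)L[i].offset;
  }
  return DataFrame::create(_["name"] = nm, _["nrow"] = nr, _["ncol"] = nc, _["offset"] = off);
}

// ---- weights view ---------------------------------------------------------

struct Weights {
  std::vector<fmat> Wc, bc; // conv
  std::vector<fmat> Wl, bl; // lstm
  std::vector<fmat> Wf, bf; // fc
};

static Weights unpack(const double* theta, const NetSpec& s) {
  Weights w;
  auto L = layout_of(s);
  size_t idx = 0;
  auto take = [&](void) {
    const ParamSlot& p = L[idx++];
    fmat M(p.nrow, p.ncol);
    const double* src = theta + p.offset;
    float* dst = M.memptr();
    long n = (long)p.nrow * p.ncol;
    for (long j = 0; j < n; ++j) dst[j] = (float)src[j];
    return M;
  };
  for (size_t i = 0; i < s.filters.size(); ++i) { w.Wc.push_back(take()); w.bc.push_back(take()); }
  for (size_t i = 0; i < s.units.size(); ++i) { w.Wl.push_back(take()); w.bl.push_back(take()); }
  for (size_t i = 0; i < s.fc.size(); ++i) { w.Wf.push_back(take()); w.bf.push_back(take()); }
  return w;
}

struct Grads {
  std::vector<fmat> Wc, bc, Wl, bl, Wf, bf;
  void zero_like(const Weights& w) {
    auto z = [](const std::vector<fmat>& src, std::vector<fmat>& dst) {
      dst.clear();
      for (const fmat& m : src) dst.push_back(arma::zeros<fmat>(m.n_rows, m.n_cols));
    };
    z(w.Wc, Wc); z(w.bc, bc); z(w.Wl, Wl); z(w.bl, bl); z(w.Wf, Wf); z(w.bf, bf);
  }
};

// ---- conv primitives ------------------------------------------------------

static void im2col(const fmat& X, int H, int k, fmat& Col) {
  // X: C x H*H  ->  Col: k*k*C x H*H; row index (dc*k + dr)*C + ch so each
  // neighbour's channel block is contiguous (interior columns are memcpys)
  const int C = X.n_rows, r0 = k / 2;
  Col.set_size(k * k * C, H * H);
  const float* xp = X.memptr();
  for (int c = 0; c < H; ++c) {
    int rlo = 0, rhi = H; // whole column
    bool cedge = (c < r0 || c >= H - r0);
    for (int r = rlo; r < rhi; ++r) {
      float* out = Col.colptr(c * H + r);
      bool edge = cedge || r < r0 || r >= H - r0;
      if (!edge) {
        const float* src = xp + (long)((c - r0) * H + (r - r0)) * C;
        for (int dc = 0; dc < k; ++dc) {
          std::memcpy(out + dc * k * C, src + (long)dc * H * C, (size_t)k * C * sizeof(float));
        }
      } else {
        for (int dc = 0; dc < k; ++dc) {
          int cc = c + dc - r0;
          for (int dr = 0; dr < k; ++dr) {
            int rr = r + dr - r0;
            float* o = out + (dc * k + dr) * C;
            if (rr >= 0 && rr < H && cc >= 0 && cc < H)
              std::memcpy(o, xp + (long)(cc * H + rr) * C, (size_t)C * sizeof(float));
            else
              std::memset(o, 0, (size_t)C * sizeof(float));
          }
        }
      }
    }
  }
}

static void col2im(const fmat& Col, int H, int k, fmat& X) {
  // scatter-add transpose of im2col; X: C x H*H (overwritten)
  const int C = Col.n_rows / (k * k), r0 = k / 2;
  X.zeros(C, H * H);
  float* xp = X.memptr();
  for (int c = 0; c < H; ++c) {
    for (int r = 0; r < H; ++r) {
      const float* in = Col.colptr(c * H + r);
      for (int dc = 0; dc < k; ++dc) {
        int cc = c + dc - r0;
        if (cc < 0 || cc >= H) continue;
        for (int dr = 0; dr < k; ++dr) {
          int rr = r + dr - r0;
          if (rr < 0 || rr >= H) continue;
          float* dst = xp + (long)(cc * H + rr) * C;
          const float* src = in + (dc * k + dr) * C;
          for (int ch = 0; ch < C; ++ch) dst[ch] += src[ch];
        }
      }
    }
  }
}

static void maxpool2(const fmat& Y, int H, fmat& P, arma::Mat<u32>* amax) {
  // Y: F x H*H -> P: F x (H/2)^2, argmax records source spatial index
  const int F = Y.n_rows, Hp = H / 2;
  P.set_size(F, Hp * Hp);
  if (amax) amax->set_size(F, Hp * Hp);
  for (int pc = 0; pc < Hp; ++pc) {
    for (int pr = 0; pr < Hp; ++pr) {
      int sp = pc * Hp + pr;
      int s00 = (2 * pc) * H + 2 * pr;
      int cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
      for (int f = 0; f < F; ++f) {
        float best = Y(f, cand[0]);
        int bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          float v = Y(f, cand[j]);
          if (v > best) { best = v; bi = cand[j]; }
        }
        P(f, sp) = best;
        if (amax) (*amax)(f, sp) = (u32)bi;
      }
    }
  }
}

// ---- forward pass ---------------------------------------------------------

struct LstmCache {
  std::vector<fmat> i, f, g, o, c, hc, h; // per time step, U x B
};

struct Cache {
  // conv: per layer, pooled output per image and argmax (only when training)
  std::vector<std::vector<fmat>> pooled;             // [layer][img]
  std::vector<std::vector<arma::Mat<u32>>> amax;     // [layer][img]
  std::vector<std::vector<fmat>> lstm_x;             // [layer][t]  inputs D_l x B
  std::vector<LstmCache> lstm;
  std::vector<fmat> fc_in;   // input to each fc layer
  std::vector<fmat> drop;    // dropout masks (already scaled), empty if none
  fvec probs;
};

static inline float act_fwd(float x, bool relu) { return relu ? (x > 0 ? x : 0.0f) : std::tanh(x); }

static void lstm_forward(const fmat& W, const fmat& b, const std::vector<fmat>& Xs,
                         bool relu, LstmCache& cc, std::vector<fmat>& Hs) {
  const int U = b.n_rows / 4, T = Xs.size(), B = Xs[0].n_cols;
  fmat h = arma::zeros<fmat>(U, B), c = arma::zeros<fmat>(U, B);
  Hs.clear();
  for (int t = 0; t < T; ++t) {
    fmat z = W.cols(0, Xs[t].n_rows - 1) * Xs[t] + W.cols(Xs[t].n_rows, W.n_cols - 1) * h;
    z.each_col() += fvec(b.col(0));
    fmat zi = z.rows(0, U - 1), zf = z.rows(U, 2 * U - 1),
         zg = z.rows(2 * U, 3 * U - 1), zo = z.rows(3 * U, 4 * U - 1);
    fmat i = 1.0f / (1.0f + arma::exp(-zi));
    fmat f = 1.0f / (1.0f + arma::exp(-zf));
    fmat o = 1.0f / (1.0f + arma::exp(-zo));
    fmat g = relu ? fmat(arma::clamp(zg, 0.0f, arma::datum::inf)) : fmat(arma::tanh(zg));
    c = f % c + i % g;
    fmat hc = relu ? fmat(arma::clamp(c, 0.0f, arma::datum::inf)) : fmat(arma::tanh(c));
    h = o % hc;
    cc.i.push_back(i); cc.f.push_back(f); cc.g.push_back(g); cc.o.push_back(o);
    cc.c.push_back(c); cc.hc.push_back(hc); cc.h.push_back(h);
    Hs.push_back(h);
  }
}

// Forward through the whole network.  x: (px*px) x (T*B).  When train=true,
// caches everything needed for backprop and applies inverted dropout with
// the given RNG.
static fvec net_forward(const Weights& w, const NetSpec& s, const fmat& x,
                        bool train, std::mt19937* rng, Cache* cache) {
  const int N = x.n_cols, T = s.T, B = N / T;
  if (N % T != 0) stop("batch column count not a multiple of n_frames");
  const int nconv = s.filters.size();

  if (cache) {
    cache->pooled.assign(nconv, {});
    cache->amax.assign(nconv, {});
  }
  // conv encoder, image by image
  fmat feats(s.D, N);
  fmat Col, Y, P, cur;
  for (int img = 0; img < N; ++img) {
    cur = fmat(x.colptr(img), 1, s.px * s.px); // 1 x HW view copy
    int H = s.px;
    for (int l = 0; l < nconv; ++l) {
      im2col(cur, H, s.k, Col);
      Y = w.Wc[l] * Col;
      Y.each_col() += fvec(w.bc[l].col(0));
      Y.transform([](float v) { return v > 0 ? v : 0.0f; });
      arma::Mat<u32> am;
      maxpool2(Y, H, P, (cache ? &am : nullptr));
      if (cache) {
        cache->pooled[l].push_back(P);
        cache->amax[l].push_back(std::move(am));
      }
      cur = P;
      H /= 2;
    }
    feats.col(img) = arma::vectorise(cur);
  }

  // lstm stack
  std::vector<fmat> Xs(T);
  for (int t = 0; t < T; ++t) {
    fmat Xt(s.D, B);
    for (int sgi = 0; sgi < B; ++sgi) Xt.col(sgi) = feats.col(sgi * T + t);
    Xs[t] = std::move(Xt);
  }
  if (cache) { cache->lstm_x.clear(); cache->lstm.clear(); }
  std::vector<fmat> Hs;
  for (size_t l = 0; l < s.units.size(); ++l) {
    LstmCache cc;
    if (cache) cache->lstm_x.push_back(Xs);
    lstm_forward(w.Wl[l], w.bl[l], Xs, s.lstm_relu, cc, Hs);
    if (cache) cache->lstm.push_back(std::move(cc));
    Xs = Hs;
  }
  fmat a = Hs.back(); // U x B, last step of last layer

  // dense head
  if (cache) { cache->fc_in.clear(); cache->drop.clear(); }
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const int nfc = s.fc.size();
  for (int l = 0; l < nfc; ++l) {
    if (cache) cache->fc_in.push_back(a);
    fmat z = w.Wf[l] * a;
    z.each_col() += fvec(w.bf[l].col(0));
    if (l < nfc - 1) {
      z.transform([](float v) { return v > 0 ? v : 0.0f; });
      if (l < 2 && s.dropout > 0 && train && rng) {
        fmat mask(z.n_rows, z.n_cols);
        float keep = 1.0f - (float)s.dropout;
        for (arma::uword j = 0; j < mask.n_elem; ++j)
          mask(j) = (unif(*rng) < keep) ? 1.0f / keep : 0.0f;
        z %= mask;
        if (cache) cache->drop.push_back(std::move(mask));
      } else if (cache) {
        cache->drop.push_back(fmat());
      }
    }
    a = std::move(z);
  }
  fvec probs(B);
  for (int sgi = 0; sgi < B; ++sgi) probs(sgi) = 1.0f / (1.0f + std::exp(-a(0, sgi)));
  if (cache) cache->probs = probs;
  return probs;
}

// ---- backward pass --------------------------------------------------------

static double net_backward(const Weights& w, const NetSpec& s, const fmat& x,
                           const fvec& y, Cache& cache, Grads& gr) {
  const int N = x.n_cols, T = s.T, B = N / T;
  const int nconv = s.filters.size(), nfc = s.fc.size(), nlstm = s.units.size();
  gr.zero_like(w);

  // loss and output gradient
  double loss = 0.0;
  fmat da(1, B);
  for (int sgi = 0; sgi < B; ++sgi) {
    double p = std::min(std::max((double)cache.probs(sgi), 1e-7), 1.0 - 1e-7);
    loss += -(y(sgi) * std::log(p) + (1.0 - y(sgi)) * std::log(1.0 - p));
    da(0, sgi) = (float)((p - y(sgi)) / B); // d loss / d logit
  }
  loss /= B;

  // dense head backward
  for (int l = nfc - 1; l >= 0; --l) {
    const fmat& ain = cache.fc_in[l];
    gr.Wf[l] += da * ain.t();
    gr.bf[l] += arma::sum(da, 1);
    fmat dain = w.Wf[l].t() * da;
    if (l > 0) {
      // through previous layer's relu (+ dropout mask)
      if (l - 1 < (int)cache.drop.size() && cache.drop[l - 1].n_elem > 0)
        dain %= cache.drop[l - 1];
      dain %= arma::conv_to<fmat>::from(ain > 0);
    }
    da = std::move(dain);
  }
  // da is now gradient w.r.t. last-step hidden state of last lstm layer (U x B)

  // lstm stack backward
  std::vector<fmat> dX; // gradient w.r.t. inputs of current layer, per t
  for (int l = nlstm - 1; l >= 0; --l) {
    const LstmCache& cc = cache.lstm[l];
    const std::vector<fmat>& Xs = cache.lstm_x[l];
    const fmat& W = w.Wl[l];
    const int U = s.units[l], Din = Xs[0].n_rows;
    fmat dh_rec = arma::zeros<fmat>(U, B), dc_next = arma::zeros<fmat>(U, B);
    std::vector<fmat> dXl(T);
    for (int t = T - 1; t >= 0; --t) {
      fmat dh = dh_rec;
      if (l == nlstm - 1) {
        if (t == T - 1) dh += da;
      } else {
        dh += dX[t];
      }
      fmat do_ = dh % cc.hc[t];
      fmat dhc = dh % cc.o[t];
      fmat dact_c = s.lstm_relu ? fmat(arma::conv_to<fmat>::from(cc.c[t] > 0))
                                : fmat(1.0f - cc.hc[t] % cc.hc[t]);
      fmat dc = dc_next + dhc % dact_c;
      fmat cprev = (t > 0) ? cc.c[t - 1] : arma::zeros<fmat>(U, B);
      fmat di = dc % cc.g[t];
      fmat dg = dc % cc.i[t];
      fmat df = dc % cprev;
      dc_next = dc % cc.f[t];
      fmat dz(4 * U, B);
      dz.rows(0, U - 1)        = di % cc.i[t] % (1.0f - cc.i[t]);
      dz.rows(U, 2 * U - 1)    = df % cc.f[t] % (1.0f - cc.f[t]);
      dz.rows(2 * U, 3 * U - 1) = s.lstm_relu
          ? fmat(dg % arma::conv_to<fmat>::from(cc.g[t] > 0))
          : fmat(dg % (1.0f - cc.g[t] % cc.g[t]));
      dz.rows(3 * U, 4 * U - 1) = do_ % cc.o[t] % (1.0f - cc.o[t]);
      fmat hprev = (t > 0) ? cc.h[t - 1] : arma::zeros<fmat>(U, B);
      gr.Wl[l].cols(0, Din - 1) += dz * Xs[t].t();
      gr.Wl[l].cols(Din, Din + U - 1) += dz * hprev.t();
      gr.bl[l] += arma::sum(dz, 1);
      dXl[t] = W.cols(0, Din - 1).t() * dz;
      dh_rec = W.cols(Din, Din + U - 1).t() * dz;
    }
    dX = std::move(dXl);
  }

  // scatter dX (T of D x B) back to per-image feature gradients
  fmat dfeats(s.D, N);
  for (int t = 0; t < T; ++t)
    for (int sgi = 0; sgi < B; ++sgi) dfeats.col(sgi * T + t) = dX[t].col(sgi);

  // conv backward, image by image
  fmat Col, dY, dP, dXimg;
  for (int img = 0; img < N; ++img) {
    // gradient w.r.t. final pooled map
    int Hfin = s.side.back();
    fmat dcur(dfeats.colptr(img), s.filters.back(), Hfin * Hfin); // reshape copy
    for (int l = nconv - 1; l >= 0; --l) {
      int H = s.side[l];            // spatial side entering this block
      const fmat& P = cache.pooled[l][img];
      const arma::Mat<u32>& am = cache.amax[l][img];
      // relu mask through surviving (argmax) unit
      fmat dPm = dcur % arma::conv_to<fmat>::from(P > 0);
      dY.zeros(P.n_rows, H * H);
      for (arma::uword sp = 0; sp < P.n_cols; ++sp)
        for (arma::uword f = 0; f < P.n_rows; ++f)
          dY(f, am(f, sp)) += dPm(f, sp);
      // input to this layer
      fmat Xin;
      if (l == 0) Xin = fmat(x.colptr(img), 1, s.px * s.px);
      else Xin = cache.pooled[l - 1][img];
      im2col(Xin, H, s.k, Col);
      gr.Wc[l] += dY * Col.t();
      gr.bc[l] += arma::sum(dY, 1);
      if (l > 0) {
        fmat dCol = w.Wc[l].t() * dY;
        col2im(dCol, H, s.k, dXimg);
        dcur = dXimg;
      }
    }
  }
  return loss;
}

// ---- flat gradient handling ----------------------------------------------

static void pack_grads(const Grads& gr, const NetSpec& s, fvec& g) {
  g.set_size(n_params_of(s));
  long off = 0;
  // must interleave exactly like layout_of: conv W,b pairs then lstm then fc
  for (size_t i = 0; i < gr.Wc.size(); ++i) {
    std::memcpy(g.memptr() + off, gr.Wc[i].memptr(), gr.Wc[i].n_elem * sizeof(float));
    off += gr.Wc[i].n_elem;
    std::memcpy(g.memptr() + off, gr.bc[i].memptr(), gr.bc[i].n_elem * sizeof(float));
    off += gr.bc[i].n_elem;
  }
  for (size_t i = 0; i < gr.Wl.size(); ++i) {
    std::memcpy(g.memptr() + off, gr.Wl[i].memptr(), gr.Wl[i].n_elem * sizeof(float));
    off += gr.Wl[i].n_elem;
    std::memcpy(g.memptr() + off, gr.bl[i].memptr(), gr.bl[i].n_elem * sizeof(float));
    off += gr.bl[i].n_elem;
  }
  for (size_t i = 0; i < gr.Wf.size(); ++i) {
    std::memcpy(g.memptr() + off, gr.Wf[i].memptr(), gr.Wf[i].n_elem * sizeof(float));
    off += gr.Wf[i].n_elem;
    std::memcpy(g.memptr() + off, gr.bf[i].memptr(), gr.bf[i].n_elem * sizeof(float));
    off += gr.bf[i].n_elem;
  }
  (void)s;
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector theta, List spec, NumericMatrix x) {
  NetSpec s = parse_spec(spec);
  if ((long)theta.size() != n_params_of(s)) stop("weight vector length does not match spec");
  if (x.nrow() != s.px * s.px)
    stop("wrong image size: got %d pixels per column, spec wants %d (%d x %d)",
         x.nrow(), s.px * s.px, s.px, s.px);
  Weights w = unpack(REAL(theta), s);
  fmat xf(x.nrow(), x.ncol());
  for (R_xlen_t j = 0; j < (R_xlen_t)x.nrow() * x.ncol(); ++j) xf(j) = (float)x[j];
  fvec p = net_forward(w, s, xf, false, nullptr, nullptr);
  NumericVector out(p.n_elem);
  for (arma::uword i = 0; i < p.n_elem; ++i) out[i] = (double)p(i);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_encoder(NumericVector theta, List spec, NumericMatrix x) {
  // per-frame convolutional features (D x n_images); ignores lstm/head
  NetSpec s = parse_spec(spec);
  if (x.nrow() != s.px * s.px) stop("wrong image size");
  Weights w = unpack(REAL(theta), s);
  const int N = x.ncol(), nconv = s.filters.size();
  NumericMatrix out(s.D, N);
  fmat Col, Y, P, cur;
  for (int img = 0; img < N; ++img) {
    cur.set_size(1, s.px * s.px);
    for (int j = 0; j < s.px * s.px; ++j) cur(j) = (float)x(j, img);
    int H = s.px;
    for (int l = 0; l < nconv; ++l) {
      im2col(cur, H, s.k, Col);
      Y = w.Wc[l] * Col;
      Y.each_col() += fvec(w.bc[l].col(0));
      Y.transform([](float v) { return v > 0 ? v : 0.0f; });
      maxpool2(Y, H, P, nullptr);
      cur = P;
      H /= 2;
    }
    fvec v = arma::vectorise(cur);
    for (int j = 0; j < s.D; ++j) out(j, img) = (double)v(j);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad(NumericVector theta, List spec, NumericMatrix x, NumericVector y,
                   int dropout_seed) {
  NetSpec s = parse_spec(spec);
  if ((long)theta.size() != n_params_of(s)) stop("weight vector length does not match spec");
  if (x.nrow() != s.px * s.px) stop("wrong image size");
  Weights w = unpack(REAL(theta), s);
  fmat xf(x.nrow(), x.ncol());
  for (R_xlen_t j = 0; j < (R_xlen_t)x.nrow() * x.ncol(); ++j) xf(j) = (float)x[j];
  fvec yf(y.size());
  for (int i = 0; i < y.size(); ++i) yf(i) = (float)y[i];
  Cache cache;
  std::mt19937 rng(dropout_seed >= 0 ? (unsigned)dropout_seed : 0u);
  bool train = dropout_seed >= 0;
  net_forward(w, s, xf, train, train ? &rng : nullptr, &cache);
  Grads gr;
  double loss = net_backward(w, s, xf, yf, cache, gr);
  fvec g;
  pack_grads(gr, s, g);
  NumericVector gout(g.n_elem);
  for (arma::uword i = 0; i < g.n_elem; ++i) gout[i] = (double)g(i);
  return List::create(_["loss"] = loss, _["grad"] = gout);
}

// [[Rcpp::export]]
double cpp_train_step(NumericVector theta, NumericVector m, NumericVector v, int step,
                      List spec, NumericMatrix x, NumericVector y,
                      double lr, double clip, int dropout_seed) {
  // One Adam step on a minibatch; theta/m/v are updated in place.
  NetSpec s = parse_spec(spec);
  long np = n_params_of(s);
  if ((long)theta.size() != np || (long)m.size() != np || (long)v.size() != np)
    stop("weight/moment vector length does not match spec");
  if (x.nrow() != s.px * s.px) stop("wrong image size");
  Weights w = unpack(REAL(theta), s);
  fmat xf(x.nrow(), x.ncol());
  for (R_xlen_t j = 0; j < (R_xlen_t)x.nrow() * x.ncol(); ++j) xf(j) = (float)x[j];
  fvec yf(y.size());
  for (int i = 0; i < y.size(); ++i) yf(i) = (float)y[i];

  Cache cache;
  std::mt19937 rng((unsigned)dropout_seed);
  net_forward(w, s, xf, true, &rng, &cache);
  Grads gr;
  double loss = net_backward(w, s, xf, yf, cache, gr);
  fvec g;
  pack_grads(gr, s, g);

  if (clip > 0) {
    double nrm = arma::norm(arma::conv_to<arma::vec>::from(g), 2);
    if (nrm > clip) g *= (float)(clip / nrm);
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double* th = REAL(theta);
  double* mm = REAL(m);
  double* vv = REAL(v);
  double bc1 = 1.0 - std::pow(b1, (double)step);
  double bc2 = 1.0 - std::pow(b2, (double)step);
  for (long j = 0; j < np; ++j) {
    double gj = (double)g(j);
    mm[j] = b1 * mm[j] + (1 - b1) * gj;
    vv[j] = b2 * vv[j] + (1 - b2) * gj * gj;
    th[j] -= lr * (mm[j] / bc1) / (std::sqrt(vv[j] / bc2) + eps);
  }
  return loss;
}

// ---- augmentation / resize kernels ----------------------------------------

// Nearest-neighbour rotation (degrees, counter-clockwise) of a binary image,
// corners filled with 0.
// [[Rcpp::export]]
IntegerMatrix cpp_rotate_nn(IntegerMatrix img, double angle_deg) {
  const int H = img.nrow(), W = img.ncol();
  const double th = angle_deg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      // inverse-rotate output pixel into source coordinates
      double xr = c - cx, yr = r - cy;
      double xs = ct * xr + st * yr + cx;
      double ys = -st * xr + ct * yr + cy;
      int ri = (int)std::lround(ys), ci = (int)std::lround(xs);
      out(r, c) = (ri >= 0 && ri < H && ci >= 0 && ci < W) ? img(ri, ci) : 0;
    }
  }
  return out;
}

// Bilinear resize of a numeric image to out_px x out_px.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_px) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_px, out_px);
  for (int c = 0; c < out_px; ++c) {
    double xs = (c + 0.5) * W / out_px - 0.5;
    int c0 = (int)std::floor(xs);
    double wx = xs - c0;
    int c0c = std::min(std::max(c0, 0), W - 1), c1c = std::min(std::max(c0 + 1, 0), W - 1);
    for (int r = 0; r < out_px; ++r) {
      double ys = (r + 0.5) * H / out_px - 0.5;
      int r0 = (int)std::floor(ys);
      double wy = ys - r0;
      int r0c = std::min(std::max(r0, 0), H - 1), r1c = std::min(std::max(r0 + 1, 0), H - 1);
      out(r, c) = (1 - wy) * ((1 - wx) * img(r0c, c0c) + wx * img(r0c, c1c)) +
                  wy * ((1 - wx) * img(r1c, c0c) + wx * img(r1c, c1c));
    }
  }
  return out;
}

// Shared-transform warp of a whole segment: optional flips and NN rotation of
// the source binary images (raw 0/1 matrices), then bilinear resize to
// out_px.  Returns (out_px*out_px) x n_images with values in [0,1].
// [[Rcpp::export]]
NumericMatrix cpp_warp_stack(List imgs, bool hflip, bool vflip, double angle_deg, int out_px) {
  const int n = imgs.size();
  RawMatrix first = imgs[0];
  const int H = first.nrow(), W = first.ncol();
  if (H != W) stop("motion images must be square");
  const double th = angle_deg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  const double cc0 = (H - 1) / 2.0;

  // Precompute, for each output pixel, the 4 bilinear taps as source indices
  // (already including flips and NN rotation), weightings shared across the stack.
  const int npx = out_px * out_px;
  std::vector<int> idx(npx * 4);
  std::vector<float> wgt(npx * 4);
  int p = 0;
  for (int c = 0; c < out_px; ++c) {
    double xs = (c + 0.5) * W / out_px - 0.5;
    int c0 = (int)std::floor(xs);
    double wx = xs - c0;
    for (int r = 0; r < out_px; ++r, ++p) {
      double ys = (r + 0.5) * H / out_px - 0.5;
      int r0 = (int)std::floor(ys);
      double wy = ys - r0;
      const int rr[2] = {std::min(std::max(r0, 0), H - 1), std::min(std::max(r0 + 1, 0), H - 1)};
      const int cCl[2] = {std::min(std::max(c0, 0), W - 1), std::min(std::max(c0 + 1, 0), W - 1)};
      const double ww[2] = {1 - wy, wy}, wc[2] = {1 - wx, wx};
      for (int j = 0; j < 4; ++j) {
        int ri = rr[j % 2], ci = cCl[j / 2];
        // rotated image pixel (ri, ci) <- NN source lookup
        double xr = ci - cc0, yr = ri - cc0;
        double xsr = ct * xr + st * yr + cc0;
        double ysr = -st * xr + ct * yr + cc0;
        int rs = (int)std::lround(ysr), cs = (int)std::lround(xsr);
        if (rs >= 0 && rs < H && cs >= 0 && cs < W) {
          if (hflip) cs = W - 1 - cs;
          if (vflip) rs = H - 1 - rs;
          idx[p * 4 + j] = cs * H + rs;
          wgt[p * 4 + j] = (float)(ww[j % 2] * wc[j / 2]);
        } else {
          idx[p * 4 + j] = -1;
          wgt[p * 4 + j] = 0.0f;
        }
      }
    }
  }
  NumericMatrix out(npx, n);
  for (int im = 0; im < n; ++im) {
    RawMatrix M = imgs[im];
    if (M.nrow() != H || M.ncol() != W) stop("all images in a segment must share dimensions");
    const Rbyte* src = &M[0];
    for (int q = 0; q < npx; ++q) {
      float acc = 0.0f;
      for (int j = 0; j < 4; ++j) {
        int id = idx[q * 4 + j];
        if (id >= 0 && src[id]) acc += wgt[q * 4 + j];
      }
      out(q, im) = acc;
    }
  }
  return out;
}
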