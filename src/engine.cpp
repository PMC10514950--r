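// Minimal CPU engine for encoder-decoder segmentation networks.
//
// A network is a flat list of nodes in topological order (built in R, see
// R/arch.R).  Activations are stored per node as an arma::cube with
// dimensions (H*W, C, N): one slice per sample, one column per channel,
// spatial index s = row + col*H (column-major, matching R matrices).
// All trainable parameters live in one flat double vector; convolution
// weights occupy (cin*k*k) x cout column-major blocks, batch-norm stores
// gamma then beta.  Batch-norm running statistics live in a separate flat
// "state" vector (mean then variance per node).
//
// Convolutions are im2col + one dgemm over the whole batch; the same
// mapping is rebuilt in the backward pass for the weight gradient and the
// col2im scatter.  The loss is a fused sigmoid + class-weighted binary
// cross-entropy on the logits of the (single-channel) head.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

enum OpType { OP_INPUT, OP_CONV, OP_BN, OP_RELU, OP_MAXPOOL, OP_AVGPOOL,
              OP_GAVGPOOL, OP_UPNN, OP_UPBIL, OP_CONCAT, OP_ADD, OP_BCAST,
              OP_DWCONV };

struct Node {
  OpType op;
  std::vector<int> in;          // 0-based node indices
  // conv
  int k = 0, stride = 1, pad = 0, dil = 1, cin = 0, cout = 0;
  bool bias = false;
  long long off = -1, offb = -1;
  // bn
  int c = 0;
  long long soff = -1;
  // pool / upsample
  int factor = 1;
  // resolved at run time
  int H = 0, W = 0, C = 0;
};

OpType parse_op(const std::string& s) {
  if (s == "input") return OP_INPUT;
  if (s == "conv") return OP_CONV;
  if (s == "bn") return OP_BN;
  if (s == "relu") return OP_RELU;
  if (s == "maxpool") return OP_MAXPOOL;
  if (s == "avgpool") return OP_AVGPOOL;
  if (s == "gavgpool") return OP_GAVGPOOL;
  if (s == "upnn") return OP_UPNN;
  if (s == "upbil") return OP_UPBIL;
  if (s == "concat") return OP_CONCAT;
  if (s == "add") return OP_ADD;
  if (s == "bcast") return OP_BCAST;
  if (s == "dwconv") return OP_DWCONV;
  stop("unknown op: " + s);
}

std::vector<Node> parse_nodes(const List& nodes) {
  std::vector<Node> out(nodes.size());
  for (int i = 0; i < nodes.size(); ++i) {
    List nd = nodes[i];
    Node n;
    n.op = parse_op(as<std::string>(nd["op"]));
    if (nd.containsElementNamed("in")) {
      IntegerVector iv = nd["in"];
      for (int j = 0; j < iv.size(); ++j) n.in.push_back(iv[j] - 1);
    }
    switch (n.op) {
    case OP_CONV:
      n.k = as<int>(nd["k"]); n.stride = as<int>(nd["stride"]);
      n.pad = as<int>(nd["pad"]); n.dil = as<int>(nd["dil"]);
      n.cin = as<int>(nd["cin"]); n.cout = as<int>(nd["cout"]);
      n.bias = as<bool>(nd["bias"]);
      n.off = (long long) as<double>(nd["off"]);
      n.offb = n.bias ? (long long) as<double>(nd["offb"]) : -1;
      break;
    case OP_BN:
      n.c = as<int>(nd["c"]);
      n.off = (long long) as<double>(nd["off"]);
      n.soff = (long long) as<double>(nd["soff"]);
      break;
    case OP_DWCONV:
      n.k = as<int>(nd["k"]); n.stride = as<int>(nd["stride"]);
      n.pad = as<int>(nd["pad"]); n.dil = as<int>(nd["dil"]);
      n.c = as<int>(nd["c"]);
      n.off = (long long) as<double>(nd["off"]);
      break;
    case OP_MAXPOOL:
    case OP_AVGPOOL:
      n.k = as<int>(nd["k"]); n.stride = as<int>(nd["stride"]);
      n.pad = nd.containsElementNamed("pad") ? as<int>(nd["pad"]) : 0;
      break;
    case OP_UPNN:
    case OP_UPBIL:
      n.factor = as<int>(nd["f"]);
      break;
    default: break;
    }
    out[i] = n;
  }
  return out;
}

inline int conv_out_dim(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// im2col for the whole batch: returns (cin*k*k) x (Hout*Wout*N)
arma::mat im2col_batch(const arma::cube& A, int H, int W, const Node& n,
                       int Ho, int Wo) {
  const int N = A.n_slices, ckk = n.cin * n.k * n.k, HWo = Ho * Wo;
  arma::mat M(ckk, (size_t) HWo * N, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    const arma::mat& X = A.slice(s);
    for (int ci = 0; ci < n.cin; ++ci) {
      const double* xc = X.colptr(ci);
      for (int kc = 0; kc < n.k; ++kc) {
        for (int kr = 0; kr < n.k; ++kr) {
          const int rrow = ci * n.k * n.k + kr * n.k + kc;
          for (int wo = 0; wo < Wo; ++wo) {
            const int cin_pos = wo * n.stride - n.pad + kc * n.dil;
            if (cin_pos < 0 || cin_pos >= W) continue;
            double* mcol = M.memptr() + (size_t)(s * HWo + wo * Ho) * ckk + rrow;
            const double* src = xc + (size_t) cin_pos * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int rin = ho * n.stride - n.pad + kr * n.dil;
              if (rin >= 0 && rin < H) mcol[(size_t) ho * ckk] = src[rin];
            }
          }
        }
      }
    }
  }
  return M;
}

// scatter dM (cin*k*k x Hout*Wout*N) back into input gradient cube
void col2im_batch(const arma::mat& dM, arma::cube& dA, int H, int W,
                  const Node& n, int Ho, int Wo) {
  const int N = dA.n_slices, ckk = n.cin * n.k * n.k, HWo = Ho * Wo;
  for (int s = 0; s < N; ++s) {
    arma::mat& dX = dA.slice(s);
    for (int ci = 0; ci < n.cin; ++ci) {
      double* xc = dX.colptr(ci);
      for (int kc = 0; kc < n.k; ++kc) {
        for (int kr = 0; kr < n.k; ++kr) {
          const int rrow = ci * n.k * n.k + kr * n.k + kc;
          for (int wo = 0; wo < Wo; ++wo) {
            const int cin_pos = wo * n.stride - n.pad + kc * n.dil;
            if (cin_pos < 0 || cin_pos >= W) continue;
            const double* mcol =
              dM.memptr() + (size_t)(s * HWo + wo * Ho) * ckk + rrow;
            double* dst = xc + (size_t) cin_pos * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int rin = ho * n.stride - n.pad + kr * n.dil;
              if (rin >= 0 && rin < H) dst[rin] += mcol[(size_t) ho * ckk];
            }
          }
        }
      }
    }
  }
}

struct RunContext {
  std::vector<arma::cube> act;
  std::vector<arma::cube> aux;    // argmax (maxpool) or xhat (bn)
  std::vector<arma::vec>  bn_invstd;
};

} // namespace

// Run a network.  dims = (H, W, C, N).  If target has length H*W*N the
// weighted-BCE loss is computed; if backward, gradients are returned.
// [[Rcpp::export]]
List cpp_net_run(List nodes_r, NumericVector params, NumericVector state,
                 NumericVector x, IntegerVector dims, bool training,
                 bool backward, NumericVector target, double pos_weight,
                 double bn_momentum = 0.1) {
  std::vector<Node> nodes = parse_nodes(nodes_r);
  const int H0 = dims[0], W0 = dims[1], C0 = dims[2], N = dims[3];
  const int nn = nodes.size();
  arma::vec P(params.begin(), params.size(), false);
  arma::vec S(state.begin(), state.size(), true); // copy; returned updated
  const double bn_eps = 1e-5;

  RunContext ctx;
  ctx.act.resize(nn);
  ctx.aux.resize(nn);
  ctx.bn_invstd.resize(nn);

  // ---------- forward ----------
  for (int i = 0; i < nn; ++i) {
    Node& n = nodes[i];
    switch (n.op) {
    case OP_INPUT: {
      n.H = H0; n.W = W0; n.C = C0;
      ctx.act[i] = arma::cube(x.begin(), (size_t) H0 * W0, C0, N);
      break;
    }
    case OP_CONV: {
      const Node& p = nodes[n.in[0]];
      if (p.C != n.cin) stop("conv channel mismatch at node %d", i + 1);
      n.H = conv_out_dim(p.H, n.k, n.stride, n.pad, n.dil);
      n.W = conv_out_dim(p.W, n.k, n.stride, n.pad, n.dil);
      n.C = n.cout;
      const int ckk = n.cin * n.k * n.k, HWo = n.H * n.W;
      arma::mat M = im2col_batch(ctx.act[n.in[0]], p.H, p.W, n, n.H, n.W);
      arma::mat Wm(const_cast<double*>(P.memptr()) + n.off, ckk, n.cout,
                   false, true);
      arma::mat O = Wm.t() * M;                 // cout x HWo*N
      if (n.bias) O.each_col() += arma::vec(
          const_cast<double*>(P.memptr()) + n.offb, n.cout, false, true);
      ctx.act[i].set_size((size_t) HWo, n.cout, N);
      for (int s = 0; s < N; ++s)
        ctx.act[i].slice(s) = O.cols((size_t) s * HWo, (size_t)(s + 1) * HWo - 1).t();
      break;
    }
    case OP_BN: {
      const Node& p = nodes[n.in[0]];
      n.H = p.H; n.W = p.W; n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      const size_t HW = (size_t) n.H * n.W, Nc = HW * N;
      arma::vec mean(n.C), var(n.C);
      if (training) {
        for (int c = 0; c < n.C; ++c) {
          double m = 0, v = 0;
          for (int s = 0; s < N; ++s) m += arma::accu(A.slice(s).col(c));
          m /= (double) Nc;
          for (int s = 0; s < N; ++s) {
            arma::vec d = A.slice(s).col(c) - m;
            v += arma::dot(d, d);
          }
          v /= (double) Nc;
          mean[c] = m; var[c] = v;
          const double unb = Nc > 1 ? v * (double) Nc / (double)(Nc - 1) : v;
          S[n.soff + c] = (1 - bn_momentum) * S[n.soff + c] + bn_momentum * m;
          S[n.soff + n.C + c] =
            (1 - bn_momentum) * S[n.soff + n.C + c] + bn_momentum * unb;
        }
      } else {
        for (int c = 0; c < n.C; ++c) {
          mean[c] = S[n.soff + c];
          var[c] = S[n.soff + n.C + c];
        }
      }
      arma::vec invstd = 1.0 / arma::sqrt(var + bn_eps);
      ctx.bn_invstd[i] = invstd;
      ctx.act[i].set_size(HW, n.C, N);
      ctx.aux[i].set_size(HW, n.C, N);  // xhat
      for (int s = 0; s < N; ++s) {
        for (int c = 0; c < n.C; ++c) {
          arma::vec xh = (A.slice(s).col(c) - mean[c]) * invstd[c];
          ctx.aux[i].slice(s).col(c) = xh;
          ctx.act[i].slice(s).col(c) = xh * P[n.off + c] + P[n.off + n.C + c];
        }
      }
      break;
    }
    case OP_RELU: {
      const Node& p = nodes[n.in[0]];
      n.H = p.H; n.W = p.W; n.C = p.C;
      ctx.act[i] = arma::clamp(ctx.act[n.in[0]], 0.0,
                               std::numeric_limits<double>::infinity());
      break;
    }
    case OP_MAXPOOL: {
      const Node& p = nodes[n.in[0]];
      n.H = conv_out_dim(p.H, n.k, n.stride, n.pad, 1);
      n.W = conv_out_dim(p.W, n.k, n.stride, n.pad, 1);
      n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      ctx.aux[i].set_size((size_t) n.H * n.W, n.C, N);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* xc = A.slice(s).colptr(c);
          double* oc = ctx.act[i].slice(s).colptr(c);
          double* ic = ctx.aux[i].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo)
            for (int ho = 0; ho < n.H; ++ho) {
              double best = -std::numeric_limits<double>::infinity();
              int besti = -1;
              for (int kc = 0; kc < n.k; ++kc) {
                const int cc = wo * n.stride - n.pad + kc;
                if (cc < 0 || cc >= p.W) continue;
                for (int kr = 0; kr < n.k; ++kr) {
                  const int rr = ho * n.stride - n.pad + kr;
                  if (rr < 0 || rr >= p.H) continue;
                  const double v = xc[(size_t) cc * p.H + rr];
                  if (v > best) { best = v; besti = cc * p.H + rr; }
                }
              }
              oc[(size_t) wo * n.H + ho] = best;
              ic[(size_t) wo * n.H + ho] = besti;
            }
        }
      break;
    }
    case OP_AVGPOOL: {
      const Node& p = nodes[n.in[0]];
      n.H = conv_out_dim(p.H, n.k, n.stride, 0, 1);
      n.W = conv_out_dim(p.W, n.k, n.stride, 0, 1);
      n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      const double inv = 1.0 / (n.k * n.k);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* xc = A.slice(s).colptr(c);
          double* oc = ctx.act[i].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo)
            for (int ho = 0; ho < n.H; ++ho) {
              double acc = 0;
              for (int kc = 0; kc < n.k; ++kc)
                for (int kr = 0; kr < n.k; ++kr)
                  acc += xc[(size_t)(wo * n.stride + kc) * p.H +
                            ho * n.stride + kr];
              oc[(size_t) wo * n.H + ho] = acc * inv;
            }
        }
      break;
    }
    case OP_GAVGPOOL: {
      const Node& p = nodes[n.in[0]];
      n.H = 1; n.W = 1; n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size(1, n.C, N);
      for (int s = 0; s < N; ++s)
        ctx.act[i].slice(s) = arma::mean(A.slice(s), 0);
      break;
    }
    case OP_UPNN: {
      const Node& p = nodes[n.in[0]];
      n.H = p.H * n.factor; n.W = p.W * n.factor; n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* xc = A.slice(s).colptr(c);
          double* oc = ctx.act[i].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo) {
            const double* src = xc + (size_t)(wo / n.factor) * p.H;
            for (int ho = 0; ho < n.H; ++ho)
              oc[(size_t) wo * n.H + ho] = src[ho / n.factor];
          }
        }
      break;
    }
    case OP_UPBIL: {
      const Node& p = nodes[n.in[0]];
      n.H = p.H * n.factor; n.W = p.W * n.factor; n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      std::vector<int> r0(n.H), r1(n.H), c0(n.W), c1(n.W);
      std::vector<double> wr(n.H), wc(n.W);
      for (int r = 0; r < n.H; ++r) {
        double sr = (r + 0.5) / n.factor - 0.5;
        sr = std::max(0.0, std::min(sr, (double) p.H - 1));
        r0[r] = (int) std::floor(sr);
        r1[r] = std::min(r0[r] + 1, p.H - 1);
        wr[r] = sr - r0[r];
      }
      for (int c = 0; c < n.W; ++c) {
        double sc = (c + 0.5) / n.factor - 0.5;
        sc = std::max(0.0, std::min(sc, (double) p.W - 1));
        c0[c] = (int) std::floor(sc);
        c1[c] = std::min(c0[c] + 1, p.W - 1);
        wc[c] = sc - c0[c];
      }
      for (int s = 0; s < N; ++s)
        for (int ch = 0; ch < n.C; ++ch) {
          const double* xc = A.slice(s).colptr(ch);
          double* oc = ctx.act[i].slice(s).colptr(ch);
          for (int c = 0; c < n.W; ++c)
            for (int r = 0; r < n.H; ++r) {
              const double v00 = xc[(size_t) c0[c] * p.H + r0[r]];
              const double v01 = xc[(size_t) c1[c] * p.H + r0[r]];
              const double v10 = xc[(size_t) c0[c] * p.H + r1[r]];
              const double v11 = xc[(size_t) c1[c] * p.H + r1[r]];
              oc[(size_t) c * n.H + r] =
                (1 - wr[r]) * ((1 - wc[c]) * v00 + wc[c] * v01) +
                wr[r] * ((1 - wc[c]) * v10 + wc[c] * v11);
            }
        }
      break;
    }
    case OP_CONCAT: {
      const Node& p0 = nodes[n.in[0]];
      n.H = p0.H; n.W = p0.W; n.C = 0;
      for (size_t j = 0; j < n.in.size(); ++j) {
        const Node& pj = nodes[n.in[j]];
        if (pj.H != n.H || pj.W != n.W)
          stop("concat spatial mismatch at node %d", i + 1);
        n.C += pj.C;
      }
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      int coff = 0;
      for (size_t j = 0; j < n.in.size(); ++j) {
        const Node& pj = nodes[n.in[j]];
        ctx.act[i].cols(coff, coff + pj.C - 1) = ctx.act[n.in[j]];
        coff += pj.C;
      }
      break;
    }
    case OP_ADD: {
      const Node& p = nodes[n.in[0]];
      n.H = p.H; n.W = p.W; n.C = p.C;
      ctx.act[i] = ctx.act[n.in[0]] + ctx.act[n.in[1]];
      break;
    }
    case OP_DWCONV: {
      // depthwise convolution (groups == channels), weights k*k per channel
      const Node& p = nodes[n.in[0]];
      if (p.C != n.c) stop("dwconv channel mismatch at node %d", i + 1);
      n.H = conv_out_dim(p.H, n.k, n.stride, n.pad, n.dil);
      n.W = conv_out_dim(p.W, n.k, n.stride, n.pad, n.dil);
      n.C = n.c;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* xc = A.slice(s).colptr(c);
          const double* wk = P.memptr() + n.off + (size_t) c * n.k * n.k;
          double* oc = ctx.act[i].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo)
            for (int ho = 0; ho < n.H; ++ho) {
              double acc = 0;
              for (int kc = 0; kc < n.k; ++kc) {
                const int cc = wo * n.stride - n.pad + kc * n.dil;
                if (cc < 0 || cc >= p.W) continue;
                for (int kr = 0; kr < n.k; ++kr) {
                  const int rr = ho * n.stride - n.pad + kr * n.dil;
                  if (rr < 0 || rr >= p.H) continue;
                  acc += wk[kr * n.k + kc] * xc[(size_t) cc * p.H + rr];
                }
              }
              oc[(size_t) wo * n.H + ho] = acc;
            }
        }
      break;
    }
    case OP_BCAST: {
      // broadcast a 1x1 spatial map (input 1) to the spatial size of a
      // reference node (input 2); only input 1 receives gradient
      const Node& p = nodes[n.in[0]];
      const Node& ref = nodes[n.in[1]];
      n.H = ref.H; n.W = ref.W; n.C = p.C;
      const arma::cube& A = ctx.act[n.in[0]];
      ctx.act[i].set_size((size_t) n.H * n.W, n.C, N);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c)
          ctx.act[i].slice(s).col(c).fill(A(0, c, s));
      break;
    }
    }
  }

  const Node& last = nodes[nn - 1];
  NumericVector out((size_t) last.H * last.W * last.C * N);
  std::copy(ctx.act[nn - 1].begin(), ctx.act[nn - 1].end(), out.begin());

  double loss = NA_REAL;
  List res = List::create(_["out"] = out, _["H"] = last.H, _["W"] = last.W,
                          _["C"] = last.C);

  const bool want_loss = target.size() > 0;
  arma::cube dlast;
  if (want_loss) {
    if (last.C != 1) stop("loss expects a single-channel head");
    const size_t HW = (size_t) last.H * last.W;
    if ((size_t) target.size() != HW * N) stop("target size mismatch");
    const arma::cube& Z = ctx.act[nn - 1];
    double acc = 0;
    if (backward) dlast.set_size(HW, 1, N);
    const double inv = 1.0 / ((double) HW * N);
    for (int s = 0; s < N; ++s) {
      const double* z = Z.slice(s).memptr();
      const double* t = target.begin() + HW * s;
      double* d = backward ? dlast.slice(s).memptr() : nullptr;
      for (size_t j = 0; j < HW; ++j) {
        const double zj = z[j], tj = t[j];
        const double sp_pos = std::max(-zj, 0.0) + std::log1p(std::exp(-std::fabs(zj)));
        const double sp_neg = std::max(zj, 0.0) + std::log1p(std::exp(-std::fabs(zj)));
        acc += pos_weight * tj * sp_pos + (1 - tj) * sp_neg;
        if (backward) {
          const double sig = 1.0 / (1.0 + std::exp(-zj));
          d[j] = (pos_weight * tj * (sig - 1.0) + (1 - tj) * sig) * inv;
        }
      }
    }
    loss = acc * inv;
    res["loss"] = loss;
  }

  if (!backward) {
    res["state"] = NumericVector(S.begin(), S.end());
    return res;
  }

  // ---------- backward ----------
  NumericVector grad(params.size());
  arma::vec G(grad.begin(), grad.size(), false);
  std::vector<arma::cube> dact(nn);
  dact[nn - 1] = dlast;

  for (int i = nn - 1; i >= 0; --i) {
    const Node& n = nodes[i];
    if (dact[i].n_elem == 0 || n.op == OP_INPUT) continue;
    const arma::cube& D = dact[i];
    auto ensure = [&](int j) {
      if (dact[j].n_elem == 0)
        dact[j].zeros((size_t) nodes[j].H * nodes[j].W, nodes[j].C, N);
    };
    switch (n.op) {
    case OP_CONV: {
      const Node& p = nodes[n.in[0]];
      const int ckk = n.cin * n.k * n.k, HWo = n.H * n.W;
      arma::mat dO(n.cout, (size_t) HWo * N);
      for (int s = 0; s < N; ++s)
        dO.cols((size_t) s * HWo, (size_t)(s + 1) * HWo - 1) = D.slice(s).t();
      arma::mat M = im2col_batch(ctx.act[n.in[0]], p.H, p.W, n, n.H, n.W);
      arma::mat dW = M * dO.t();                       // ckk x cout
      G.subvec(n.off, n.off + (size_t) ckk * n.cout - 1) +=
        arma::vectorise(dW);
      if (n.bias)
        G.subvec(n.offb, n.offb + n.cout - 1) += arma::sum(dO, 1);
      arma::mat Wm(const_cast<double*>(P.memptr()) + n.off, ckk, n.cout,
                   false, true);
      arma::mat dM = Wm * dO;                          // ckk x HWo*N
      ensure(n.in[0]);
      col2im_batch(dM, dact[n.in[0]], p.H, p.W, n, n.H, n.W);
      break;
    }
    case OP_BN: {
      const size_t Nc = (size_t) n.H * n.W * N;
      const arma::cube& XH = ctx.aux[i];
      const arma::vec& invstd = ctx.bn_invstd[i];
      ensure(n.in[0]);
      for (int c = 0; c < n.C; ++c) {
        double sum_d = 0, sum_dx = 0;
        for (int s = 0; s < N; ++s) {
          sum_d += arma::accu(D.slice(s).col(c));
          sum_dx += arma::dot(D.slice(s).col(c), XH.slice(s).col(c));
        }
        G[n.off + c] += sum_dx;          // dgamma
        G[n.off + n.C + c] += sum_d;     // dbeta
        const double g = P[n.off + c];
        const double k1 = g * invstd[c];
        for (int s = 0; s < N; ++s) {
          dact[n.in[0]].slice(s).col(c) += k1 * (D.slice(s).col(c)
            - sum_d / (double) Nc
            - XH.slice(s).col(c) * (sum_dx / (double) Nc));
        }
      }
      break;
    }
    case OP_RELU: {
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        dact[n.in[0]].slice(s) += D.slice(s) %
          arma::conv_to<arma::mat>::from(ctx.act[i].slice(s) > 0);
      break;
    }
    case OP_MAXPOOL: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* d = D.slice(s).colptr(c);
          const double* idx = ctx.aux[i].slice(s).colptr(c);
          double* o = dact[n.in[0]].slice(s).colptr(c);
          const size_t HWo = (size_t) n.H * n.W;
          (void) p;
          for (size_t j = 0; j < HWo; ++j)
            o[(size_t) idx[j]] += d[j];
        }
      break;
    }
    case OP_AVGPOOL: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      const double inv = 1.0 / (n.k * n.k);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* d = D.slice(s).colptr(c);
          double* o = dact[n.in[0]].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo)
            for (int ho = 0; ho < n.H; ++ho) {
              const double v = d[(size_t) wo * n.H + ho] * inv;
              for (int kc = 0; kc < n.k; ++kc)
                for (int kr = 0; kr < n.k; ++kr)
                  o[(size_t)(wo * n.stride + kc) * p.H +
                    ho * n.stride + kr] += v;
            }
        }
      break;
    }
    case OP_GAVGPOOL: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      const double inv = 1.0 / ((double) p.H * p.W);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c)
          dact[n.in[0]].slice(s).col(c) += D.slice(s)(0, c) * inv;
      break;
    }
    case OP_UPNN: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* d = D.slice(s).colptr(c);
          double* o = dact[n.in[0]].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo) {
            double* dst = o + (size_t)(wo / n.factor) * p.H;
            for (int ho = 0; ho < n.H; ++ho)
              dst[ho / n.factor] += d[(size_t) wo * n.H + ho];
          }
        }
      break;
    }
    case OP_UPBIL: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        for (int ch = 0; ch < n.C; ++ch) {
          const double* d = D.slice(s).colptr(ch);
          double* o = dact[n.in[0]].slice(s).colptr(ch);
          for (int c = 0; c < n.W; ++c) {
            double sc = (c + 0.5) / n.factor - 0.5;
            sc = std::max(0.0, std::min(sc, (double) p.W - 1));
            const int c0 = (int) std::floor(sc);
            const int c1 = std::min(c0 + 1, p.W - 1);
            const double wcc = sc - c0;
            for (int r = 0; r < n.H; ++r) {
              double sr = (r + 0.5) / n.factor - 0.5;
              sr = std::max(0.0, std::min(sr, (double) p.H - 1));
              const int r0 = (int) std::floor(sr);
              const int r1 = std::min(r0 + 1, p.H - 1);
              const double wrr = sr - r0;
              const double v = d[(size_t) c * n.H + r];
              o[(size_t) c0 * p.H + r0] += (1 - wrr) * (1 - wcc) * v;
              o[(size_t) c1 * p.H + r0] += (1 - wrr) * wcc * v;
              o[(size_t) c0 * p.H + r1] += wrr * (1 - wcc) * v;
              o[(size_t) c1 * p.H + r1] += wrr * wcc * v;
            }
          }
        }
      break;
    }
    case OP_CONCAT: {
      int coff = 0;
      for (size_t j = 0; j < n.in.size(); ++j) {
        const Node& pj = nodes[n.in[j]];
        ensure(n.in[j]);
        dact[n.in[j]] += D.cols(coff, coff + pj.C - 1);
        coff += pj.C;
      }
      break;
    }
    case OP_ADD: {
      ensure(n.in[0]); ensure(n.in[1]);
      dact[n.in[0]] += D;
      dact[n.in[1]] += D;
      break;
    }
    case OP_BCAST: {
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c)
          dact[n.in[0]](0, c, s) += arma::accu(D.slice(s).col(c));
      break;
    }
    case OP_DWCONV: {
      const Node& p = nodes[n.in[0]];
      ensure(n.in[0]);
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < n.C; ++c) {
          const double* xc = ctx.act[n.in[0]].slice(s).colptr(c);
          const double* wk = P.memptr() + n.off + (size_t) c * n.k * n.k;
          double* gw = G.memptr() + n.off + (size_t) c * n.k * n.k;
          const double* d = D.slice(s).colptr(c);
          double* dx = dact[n.in[0]].slice(s).colptr(c);
          for (int wo = 0; wo < n.W; ++wo)
            for (int ho = 0; ho < n.H; ++ho) {
              const double dv = d[(size_t) wo * n.H + ho];
              if (dv == 0) continue;
              for (int kc = 0; kc < n.k; ++kc) {
                const int cc = wo * n.stride - n.pad + kc * n.dil;
                if (cc < 0 || cc >= p.W) continue;
                for (int kr = 0; kr < n.k; ++kr) {
                  const int rr = ho * n.stride - n.pad + kr * n.dil;
                  if (rr < 0 || rr >= p.H) continue;
                  gw[kr * n.k + kc] += dv * xc[(size_t) cc * p.H + rr];
                  dx[(size_t) cc * p.H + rr] += dv * wk[kr * n.k + kc];
                }
              }
            }
        }
      break;
    }
    default: break;
    }
    dact[i].reset(); // free as we go
  }

  res["grad"] = grad;
  res["state"] = NumericVector(S.begin(), S.end());
  return res;
}

// Separable gaussian blur of one channel with reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return img;
  const int rad = std::max(1, (int) std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double ks = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += ker[i + rad];
  }
  for (double& v : ker) v /= ks;
  auto reflect = [](int i, int nmax) {
    if (i < 0) i = -i - 1;
    if (i >= nmax) i = 2 * nmax - i - 1;
    return std::max(0, std::min(i, nmax - 1));
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i)
        acc += ker[i + rad] * img(reflect(r + i, H), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i)
        acc += ker[i + rad] * tmp(r, reflect(c + i, W));
      out(r, c) = acc;
    }
  return out;
}
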