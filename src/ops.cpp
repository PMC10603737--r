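// Convolution and pooling kernels for the detector. Feature maps are R
// arrays with dim = c(C, H, W): element (c, h, w) sits at c + C*h + C*H*w
// (0-based), i.e. the channel index is fastest. Convolutions use
// im2col + GEMM; the patch-row order is (cin fastest, then kernel row ki,
// then kernel column kj), and weights are Cout x (Cin*kh*kw) matrices with
// columns in the same order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int C, int H, int W,
                   int kh, int kw, int stride, int pad,
                   arma::mat& cols, int Hout, int Wout) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      int n = ho + Hout * wo;
      double* colptr = cols.colptr(n);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki;
          double* dst = colptr + C * (ki + kh * kj);
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
            std::fill(dst, dst + C, 0.0);
          } else {
            const double* src = x + C * (hi + H * wi);
            std::copy(src, src + C, dst);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int C, int H, int W,
                   int kh, int kw, int stride, int pad,
                   double* dx, int Hout, int Wout) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      int n = ho + Hout * wo;
      const double* colptr = cols.colptr(n);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * stride - pad + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          const double* src = colptr + C * (ki + kh * kj);
          double* dst = dx + C * (hi + H * wi);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, int C, int H, int W,
                        NumericMatrix weight, NumericVector bias,
                        int kh, int kw, int stride, int pad) {
  int Hout = (H + 2 * pad - kh) / stride + 1;
  int Wout = (W + 2 * pad - kw) / stride + 1;
  int Cout = weight.nrow();
  int R = C * kh * kw;
  if (weight.ncol() != R) stop("weight column count does not match C*kh*kw");

  arma::mat cols(R, Hout * Wout);
  im2col(x.begin(), C, H, W, kh, kw, stride, pad, cols, Hout, Wout);
  arma::mat wmat(weight.begin(), Cout, R, false);
  arma::mat out = wmat * cols;
  out.each_col() += arma::vec(bias.begin(), Cout, false);

  NumericVector res(Cout * Hout * Wout);
  std::copy(out.memptr(), out.memptr() + res.size(), res.begin());
  res.attr("dim") = IntegerVector::create(Cout, Hout, Wout);
  return res;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, int C, int H, int W,
               NumericMatrix weight, NumericVector dout,
               int kh, int kw, int stride, int pad) {
  int Hout = (H + 2 * pad - kh) / stride + 1;
  int Wout = (W + 2 * pad - kw) / stride + 1;
  int Cout = weight.nrow();
  int R = C * kh * kw;
  int N = Hout * Wout;

  arma::mat cols(R, N);
  im2col(x.begin(), C, H, W, kh, kw, stride, pad, cols, Hout, Wout);
  arma::mat wmat(weight.begin(), Cout, R, false);
  arma::mat dout_m(dout.begin(), Cout, N, false);

  arma::mat dW = dout_m * cols.t();
  arma::vec db = arma::sum(dout_m, 1);
  arma::mat dcols = wmat.t() * dout_m;

  NumericVector dx(C * H * W);
  col2im(dcols, C, H, W, kh, kw, stride, pad, dx.begin(), Hout, Wout);
  dx.attr("dim") = IntegerVector::create(C, H, W);

  NumericMatrix dWr(Cout, R);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.memptr(), db.memptr() + Cout, dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// Max pooling with recorded argmax (linear input index per output element),
// padding with -Inf. Used by the serial pooling pyramid (k = 5, s = 1, p = 2).
// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int C, int H, int W,
                int k, int stride, int pad) {
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out(C * Hout * Wout);
  IntegerVector arg(C * Hout * Wout);
  const double* xp = x.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      for (int c = 0; c < C; ++c) {
        double best = -std::numeric_limits<double>::infinity();
        int bestIdx = -1;
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            int idx = c + C * (hi + H * wi);
            if (xp[idx] > best) { best = xp[idx]; bestIdx = idx; }
          }
        }
        int o = c + C * (ho + Hout * wo);
        out[o] = best;
        arg[o] = bestIdx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Hout, Wout);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector argmax, NumericVector dout,
                         int C, int H, int W) {
  NumericVector dx(C * H * W);
  for (int i = 0; i < argmax.size(); ++i) {
    if (argmax[i] >= 0) dx[argmax[i]] += dout[i];
  }
  dx.attr("dim") = IntegerVector::create(C, H, W);
  return dx;
}

// Localization-loss hot path for one scale: for each positive slot, decode
// the 4 raw box outputs, evaluate the (Focal-)CIoU loss against the
// assigned ground truth, and return the central-difference gradient of the
// CIoU term w.r.t. the raw outputs (the focal weight IoU^gamma is held
// constant per step), plus the detached IoU used as the confidence target.
static inline double sigmoid_c(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void decode_slot_c(const double* t4, double aw, double ah,
                          double stride, double row0, double col0,
                          double* box) {
  double bx = (2.0 * sigmoid_c(t4[0]) - 0.5 + col0) * stride;
  double by = (2.0 * sigmoid_c(t4[1]) - 0.5 + row0) * stride;
  double sw = 2.0 * sigmoid_c(t4[2]);
  double sh = 2.0 * sigmoid_c(t4[3]);
  double bw = aw * sw * sw, bh = ah * sh * sh;
  box[0] = bx - bw / 2; box[1] = by - bh / 2;
  box[2] = bx + bw / 2; box[3] = by + bh / 2;
}

static inline double iou_c(const double* p, const double* g) {
  double iw = std::min(p[2], g[2]) - std::max(p[0], g[0]);
  if (iw <= 0) return 0.0;
  double ih = std::min(p[3], g[3]) - std::max(p[1], g[1]);
  if (ih <= 0) return 0.0;
  double inter = iw * ih;
  double uni = (p[2] - p[0]) * (p[3] - p[1]) + (g[2] - g[0]) * (g[3] - g[1]) - inter;
  return inter / uni;
}

static double ciou_c(const double* p, const double* g) {
  double iou = iou_c(p, g);
  double dx = (p[0] + p[2]) - (g[0] + g[2]);
  double dy = (p[1] + p[3]) - (g[1] + g[3]);
  double rho2 = (dx * dx + dy * dy) / 4.0;
  double cw = std::max(p[2], g[2]) - std::min(p[0], g[0]);
  double ch = std::max(p[3], g[3]) - std::min(p[1], g[1]);
  double c2 = cw * cw + ch * ch;
  double dv = std::atan((g[2] - g[0]) / (g[3] - g[1])) -
              std::atan((p[2] - p[0]) / (p[3] - p[1]));
  double v = (4.0 / (M_PI * M_PI)) * dv * dv;
  double alpha = (v == 0.0) ? 0.0 : v / (1.0 - iou + v);
  return 1.0 - iou + (c2 > 0 ? rho2 / c2 : 0.0) + alpha * v;
}

// [[Rcpp::export]]
List loc_grad_scale(NumericMatrix t4s, NumericMatrix anchors_wh,
                    double stride, NumericVector rows0, NumericVector cols0,
                    NumericMatrix gts, double gamma, double fd_step,
                    bool vbar_iou) {
  int n = t4s.nrow();
  NumericMatrix g4(n, 4);
  NumericVector vbar(n), loss(n), wfocal(n);
  double box[4], boxp[4], gt[4], tp[4];
  for (int i = 0; i < n; ++i) {
    double t4[4] = {t4s(i, 0), t4s(i, 1), t4s(i, 2), t4s(i, 3)};
    double aw = anchors_wh(i, 0), ah = anchors_wh(i, 1);
    for (int k = 0; k < 4; ++k) gt[k] = gts(i, k);
    decode_slot_c(t4, aw, ah, stride, rows0[i], cols0[i], box);
    double iou0 = iou_c(box, gt);
    double w_focal = (gamma > 0) ? std::pow(iou0, gamma) : 1.0;
    wfocal[i] = w_focal;
    loss[i] = w_focal * ciou_c(box, gt);
    vbar[i] = vbar_iou ? iou0 : 1.0;
    if (w_focal > 0) {
      for (int k = 0; k < 4; ++k) {
        for (int j = 0; j < 4; ++j) tp[j] = t4[j];
        tp[k] = t4[k] + fd_step;
        decode_slot_c(tp, aw, ah, stride, rows0[i], cols0[i], boxp);
        double lp = ciou_c(boxp, gt);
        tp[k] = t4[k] - fd_step;
        decode_slot_c(tp, aw, ah, stride, rows0[i], cols0[i], boxp);
        double lm = ciou_c(boxp, gt);
        g4(i, k) = w_focal * (lp - lm) / (2.0 * fd_step);
      }
    }
  }
  return List::create(_["loss"] = loss, _["g4"] = g4, _["vbar"] = vbar,
                      _["wfocal"] = wfocal);
}
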