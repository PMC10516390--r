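// Fused elementwise (pointwise) kernels for the ConvLSTM cell update.
// Splitting the cell step into {gate convolution} -> {cnew} -> {hout}
// keeps the tape small: all sigmoid/tanh/Hadamard work happens here in two
// calls instead of ~20 R-level array ops.
//
// Layout: z is (h, w, 4*ch, n) holding the gate pre-activations in order
// i, f, g, o; states are (h, w, ch, n); peephole grids are (h, w, ch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-axis array");
  for (int k = 0; k < 4; ++k) d[k] = dd[k];
}

static NumericVector alloc4(int h, int w, int c, int n) {
  NumericVector v((size_t)h * w * c * n);
  v.attr("dim") = IntegerVector::create(h, w, c, n);
  return v;
}

// c_new = f ( z_f + Pcf.c_prev ) * c_prev + i ( z_i + Pci.c_prev ) * tanh(z_g)
// [[Rcpp::export(name = ".lstm_cnew_fwd")]]
List lstm_cnew_fwd(NumericVector z, NumericVector cprev,
                   Nullable<NumericVector> pci, Nullable<NumericVector> pcf) {
  int dz[4], dc[4];
  dims4(z, dz);
  dims4(cprev, dc);
  const int ch = dc[2], n = dc[3];
  const size_t hw = (size_t)dc[0] * dc[1];
  if (dz[2] != 4 * ch) stop("z must have 4*ch channels");
  const bool peep = pci.isNotNull();
  const double *P_i = peep ? REAL(pci.get()) : nullptr;
  const double *P_f = peep ? REAL(pcf.get()) : nullptr;
  NumericVector cn = alloc4(dc[0], dc[1], ch, n);
  NumericVector iv = alloc4(dc[0], dc[1], ch, n);
  NumericVector fv = alloc4(dc[0], dc[1], ch, n);
  NumericVector gv = alloc4(dc[0], dc[1], ch, n);
  const double *zp = REAL(z), *cp = REAL(cprev);
  double *cnp = REAL(cn), *ip = REAL(iv), *fp = REAL(fv), *gp = REAL(gv);
  for (int s = 0; s < n; ++s) {
    const double *zs = zp + hw * 4 * ch * s;
    for (int c = 0; c < ch; ++c) {
      const double *zi = zs + hw * c;
      const double *zf = zs + hw * (ch + c);
      const double *zg = zs + hw * (2 * ch + c);
      const size_t off = hw * (c + (size_t)ch * s);
      const size_t poff = hw * c;
      for (size_t p = 0; p < hw; ++p) {
        const double cprev_v = cp[off + p];
        const double i_ = sigmoid(zi[p] + (peep ? P_i[poff + p] * cprev_v : 0.0));
        const double f_ = sigmoid(zf[p] + (peep ? P_f[poff + p] * cprev_v : 0.0));
        const double g_ = std::tanh(zg[p]);
        ip[off + p] = i_;
        fp[off + p] = f_;
        gp[off + p] = g_;
        cnp[off + p] = f_ * cprev_v + i_ * g_;
      }
    }
  }
  return List::create(_["c"] = cn, _["i"] = iv, _["f"] = fv, _["g"] = gv);
}

// [[Rcpp::export(name = ".lstm_cnew_bwd")]]
List lstm_cnew_bwd(NumericVector gc, NumericVector iv, NumericVector fv,
                   NumericVector gv, NumericVector cprev,
                   Nullable<NumericVector> pci, Nullable<NumericVector> pcf) {
  int dc[4];
  dims4(cprev, dc);
  const int ch = dc[2], n = dc[3];
  const size_t hw = (size_t)dc[0] * dc[1];
  const bool peep = pci.isNotNull();
  const double *P_i = peep ? REAL(pci.get()) : nullptr;
  const double *P_f = peep ? REAL(pcf.get()) : nullptr;
  NumericVector dz = alloc4(dc[0], dc[1], 4 * ch, n); // o-slice stays zero
  NumericVector dcprev = alloc4(dc[0], dc[1], ch, n);
  NumericVector dpci(peep ? hw * ch : 0), dpcf(peep ? hw * ch : 0);
  if (peep) {
    dpci.attr("dim") = IntegerVector::create(dc[0], dc[1], ch);
    dpcf.attr("dim") = IntegerVector::create(dc[0], dc[1], ch);
  }
  const double *gcp = REAL(gc), *ip = REAL(iv), *fp = REAL(fv), *gp = REAL(gv),
               *cp = REAL(cprev);
  double *dzp = REAL(dz), *dcp = REAL(dcprev);
  double *dpi = peep ? REAL(dpci) : nullptr, *dpf = peep ? REAL(dpcf) : nullptr;
  for (int s = 0; s < n; ++s) {
    double *dzs = dzp + hw * 4 * ch * s;
    for (int c = 0; c < ch; ++c) {
      double *dzi = dzs + hw * c;
      double *dzf = dzs + hw * (ch + c);
      double *dzg = dzs + hw * (2 * ch + c);
      const size_t off = hw * (c + (size_t)ch * s);
      const size_t poff = hw * c;
      for (size_t p = 0; p < hw; ++p) {
        const double g_out = gcp[off + p];
        const double i_ = ip[off + p], f_ = fp[off + p], g_ = gp[off + p];
        const double cprev_v = cp[off + p];
        const double dzi_ = g_out * g_ * i_ * (1.0 - i_);
        const double dzf_ = g_out * cprev_v * f_ * (1.0 - f_);
        dzi[p] = dzi_;
        dzf[p] = dzf_;
        dzg[p] = g_out * i_ * (1.0 - g_ * g_);
        double dc_ = g_out * f_;
        if (peep) {
          dc_ += dzi_ * P_i[poff + p] + dzf_ * P_f[poff + p];
          dpi[poff + p] += dzi_ * cprev_v;
          dpf[poff + p] += dzf_ * cprev_v;
        }
        dcp[off + p] = dc_;
      }
    }
  }
  return List::create(
    _["dz"] = dz, _["dcprev"] = dcprev,
    _["dpci"] = peep ? (SEXP)dpci : R_NilValue,
    _["dpcf"] = peep ? (SEXP)dpcf : R_NilValue
  );
}

// h = o ( z_o + Pco.c_new + zo_extra ) * tanh(c_new)
// [[Rcpp::export(name = ".lstm_hout_fwd")]]
List lstm_hout_fwd(NumericVector z, NumericVector cnew,
                   Nullable<NumericVector> pco, Nullable<NumericVector> zo_extra) {
  int dc[4];
  dims4(cnew, dc);
  const int ch = dc[2], n = dc[3];
  const size_t hw = (size_t)dc[0] * dc[1];
  const bool peep = pco.isNotNull();
  const bool extra = zo_extra.isNotNull();
  const double *P_o = peep ? REAL(pco.get()) : nullptr;
  const double *ze = extra ? REAL(zo_extra.get()) : nullptr;
  NumericVector hv = alloc4(dc[0], dc[1], ch, n);
  NumericVector ov = alloc4(dc[0], dc[1], ch, n);
  const double *zp = REAL(z), *cp = REAL(cnew);
  double *hp = REAL(hv), *op = REAL(ov);
  for (int s = 0; s < n; ++s) {
    const double *zs = zp + hw * 4 * ch * s;
    for (int c = 0; c < ch; ++c) {
      const double *zo = zs + hw * (3 * ch + c);
      const size_t off = hw * (c + (size_t)ch * s);
      const size_t poff = hw * c;
      for (size_t p = 0; p < hw; ++p) {
        const double c_ = cp[off + p];
        double pre = zo[p];
        if (peep) pre += P_o[poff + p] * c_;
        if (extra) pre += ze[off + p];
        const double o_ = sigmoid(pre);
        op[off + p] = o_;
        hp[off + p] = o_ * std::tanh(c_);
      }
    }
  }
  return List::create(_["h"] = hv, _["o"] = ov);
}

// [[Rcpp::export(name = ".lstm_hout_bwd")]]
List lstm_hout_bwd(NumericVector gh, NumericVector ov, NumericVector cnew,
                   Nullable<NumericVector> pco, bool want_dzo_extra) {
  int dc[4];
  dims4(cnew, dc);
  const int ch = dc[2], n = dc[3];
  const size_t hw = (size_t)dc[0] * dc[1];
  const bool peep = pco.isNotNull();
  const double *P_o = peep ? REAL(pco.get()) : nullptr;
  NumericVector dz = alloc4(dc[0], dc[1], 4 * ch, n); // only o-slice filled
  NumericVector dcnew = alloc4(dc[0], dc[1], ch, n);
  NumericVector dpco(peep ? hw * ch : 0);
  if (peep) dpco.attr("dim") = IntegerVector::create(dc[0], dc[1], ch);
  NumericVector dzo(want_dzo_extra ? hw * ch * n : 0);
  if (want_dzo_extra) dzo.attr("dim") = IntegerVector::create(dc[0], dc[1], ch, n);
  const double *ghp = REAL(gh), *op = REAL(ov), *cp = REAL(cnew);
  double *dzp = REAL(dz), *dcp = REAL(dcnew);
  double *dpo = peep ? REAL(dpco) : nullptr;
  double *dze = want_dzo_extra ? REAL(dzo) : nullptr;
  for (int s = 0; s < n; ++s) {
    double *dzs = dzp + hw * 4 * ch * s;
    for (int c = 0; c < ch; ++c) {
      double *dzo_slice = dzs + hw * (3 * ch + c);
      const size_t off = hw * (c + (size_t)ch * s);
      const size_t poff = hw * c;
      for (size_t p = 0; p < hw; ++p) {
        const double g_ = ghp[off + p];
        const double o_ = op[off + p];
        const double c_ = cp[off + p];
        const double th = std::tanh(c_);
        const double dzo_ = g_ * th * o_ * (1.0 - o_);
        dzo_slice[p] = dzo_;
        double dc_ = g_ * o_ * (1.0 - th * th);
        if (peep) {
          dc_ += dzo_ * P_o[poff + p];
          dpo[poff + p] += dzo_ * c_;
        }
        dcp[off + p] = dc_;
        if (want_dzo_extra) dze[off + p] = dzo_;
      }
    }
  }
  return List::create(
    _["dz"] = dz, _["dcnew"] = dcnew,
    _["dpco"] = peep ? (SEXP)dpco : R_NilValue,
    _["dzo_extra"] = want_dzo_extra ? (SEXP)dzo : R_NilValue
  );
}
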