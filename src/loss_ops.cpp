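// Loss kernels on class-probability matrices (C x V). These mirror the
// documented formulas in R/losses.R; the R wrappers there are the public
// surface and keep the documentation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List ce_loss_cpp(const arma::mat& P, const arma::ivec& y, double clampv) {
  const uword V = P.n_cols;
  mat dP(P.n_rows, V, fill::zeros);
  double acc = 0;
  for (uword v = 0; v < V; ++v) {
    double p = P(y[v], v);
    double pc = p > clampv ? p : clampv;
    acc += -std::log(pc);
    if (p > clampv) dP(y[v], v) = -1.0 / (pc * V);
  }
  return Rcpp::List::create(Rcpp::Named("value") = acc / V, Rcpp::Named("dP") = dP);
}

// [[Rcpp::export]]
Rcpp::List dice_loss_cpp(const arma::mat& P, const arma::ivec& y, double eps,
                         const arma::ivec& fg) {
  const uword V = P.n_cols;
  mat dP(P.n_rows, V, fill::zeros);
  double value = 0;
  for (uword k = 0; k < fg.n_elem; ++k) {
    int r = fg[k];
    double inter = 0, psum = 0, ysum = 0;
    for (uword v = 0; v < V; ++v) {
      psum += P(r, v);
      if (y[v] == r) { inter += P(r, v); ysum += 1; }
    }
    double denom = psum + ysum + eps, num = 2 * inter + eps;
    value += 1 - num / denom;
    double d2 = denom * denom;
    for (uword v = 0; v < V; ++v)
      dP(r, v) += (num - (y[v] == r ? 2 * denom : 0)) / d2;
  }
  double n = fg.n_elem;
  return Rcpp::List::create(Rcpp::Named("value") = value / n,
                            Rcpp::Named("dP") = dP / n);
}

// Uncertainty-rectified pyramid consistency (see unsupervised_loss in R).
// kl_dir: 0 = KL(pc || ps), 1 = KL(ps || pc).

// [[Rcpp::export]]
Rcpp::List lu_loss_cpp(Rcpp::List probs, double eps, double clampv, int kl_dir,
                       bool grad) {
  const int S = probs.size();
  std::vector<mat> ps(S);
  for (int s = 0; s < S; ++s) ps[s] = Rcpp::as<mat>(probs[s]);
  const int C = ps[0].n_rows;
  const long V = ps[0].n_cols;
  const double E = (double)C * V;

  mat pc(C, V);
  {
    double* pcp = pc.memptr();
    const double* p0 = ps[0].memptr();
    for (long i = 0; i < (long)C * V; ++i) pcp[i] = p0[i];
    for (int s = 1; s < S; ++s) {
      const double* pp = ps[s].memptr();
      for (long i = 0; i < (long)C * V; ++i) pcp[i] += pp[i];
    }
    for (long i = 0; i < (long)C * V; ++i) pcp[i] /= S;
  }

  // per-voxel discrepancy D, weight w = exp(-D), squared diff q
  mat Dm(S, V), Wm(S, V), Qm(S, V);
  vec A(S, fill::zeros), B(S), Cs(S);
  {
    const double* pcp = pc.memptr();
    for (int s = 0; s < S; ++s) {
      const double* pp = ps[s].memptr();
      double asum = 0, bsum = 0, csum = 0;
      for (long v = 0; v < V; ++v) {
        const double* pcv = pcp + (long)C * v;
        const double* psv = pp + (long)C * v;
        double dsum = 0, qsum = 0;
        for (int c = 0; c < C; ++c) {
          double diff = psv[c] - pcv[c];
          qsum += diff * diff;
          double pcc = pcv[c] > clampv ? pcv[c] : clampv;
          double pss = psv[c] > clampv ? psv[c] : clampv;
          if (kl_dir == 0) dsum += pcv[c] * (std::log(pcc) - std::log(pss));
          else             dsum += psv[c] * (std::log(pss) - std::log(pcc));
        }
        if (dsum < 0) dsum = 0;
        double w = std::exp(-dsum);
        Dm(s, v) = dsum; Wm(s, v) = w; Qm(s, v) = qsum;
        asum += w * qsum; bsum += w; csum += dsum;
      }
      A[s] = asum / E;
      B[s] = bsum / V + eps;
      Cs[s] = csum / V;
    }
  }
  double value = mean(A / B + Cs);
  if (!grad) return Rcpp::List::create(Rcpp::Named("value") = value);

  // m_s(v) = dLu/dD_s(v)
  mat M(S, V);
  for (int s = 0; s < S; ++s)
    for (long v = 0; v < V; ++v)
      M(s, v) = (1.0 / S) * (-Wm(s, v) * Qm(s, v) / (E * B[s]) +
                             A[s] * Wm(s, v) / (V * B[s] * B[s]) + 1.0 / V);

  std::vector<mat> G(S, mat(C, V));
  const double* pcp = pc.memptr();
  std::vector<const double*> pp(S);
  std::vector<double*> gp(S);
  for (int s = 0; s < S; ++s) { pp[s] = ps[s].memptr(); gp[s] = G[s].memptr(); }
  std::vector<double> cross(C), lgterm(C);
  for (long v = 0; v < V; ++v) {
    const double* pcv = pcp + (long)C * v;
    // shared cross term of the squared-difference part, and (for kl_dir 0)
    // the shared sum over s of m_s (log(pc/ps)+1)/S
    for (int c = 0; c < C; ++c) { cross[c] = 0; lgterm[c] = 0; }
    for (int s = 0; s < S; ++s) {
      const double* psv = pp[s] + (long)C * v;
      double wb = Wm(s, v) / B[s];
      double ms = M(s, v);
      for (int c = 0; c < C; ++c) {
        double diff = psv[c] - pcv[c];
        cross[c] += diff * wb;
        double pcc = pcv[c] > clampv ? pcv[c] : clampv;
        double pss = psv[c] > clampv ? psv[c] : clampv;
        if (kl_dir == 0)
          lgterm[c] += ms * (std::log(pcc) - std::log(pss) + 1.0) / S;
        else
          lgterm[c] += ms * (psv[c] / pcc) / S;
      }
    }
    for (int t = 0; t < S; ++t) {
      const double* ptv = pp[t] + (long)C * v;
      double* gtv = gp[t] + (long)C * v;
      double wbt = Wm(t, v) / B[t];
      double mt = M(t, v);
      for (int c = 0; c < C; ++c) {
        double diff = ptv[c] - pcv[c];
        double g = -2.0 / (E * S * S) * cross[c] + 2.0 / (E * S) * wbt * diff;
        double pcc = pcv[c] > clampv ? pcv[c] : clampv;
        double ptt = ptv[c] > clampv ? ptv[c] : clampv;
        if (kl_dir == 0) {
          g += lgterm[c];
          g -= mt * (pcv[c] / ptt);
        } else {
          g += mt * (std::log(ptt) - std::log(pcc) + 1.0);
          g -= lgterm[c];
        }
        gtv[c] = g;
      }
    }
  }
  Rcpp::List dP(S);
  for (int s = 0; s < S; ++s) dP[s] = G[s];
  return Rcpp::List::create(Rcpp::Named("value") = value, Rcpp::Named("dP") = dP);
}

// Column-wise softmax and its backward (p .* (dp - <p, dp>)).

// [[Rcpp::export]]
arma::mat softmax_cols_cpp(const arma::mat& Z) {
  mat P(Z.n_rows, Z.n_cols);
  for (uword v = 0; v < Z.n_cols; ++v) {
    double mx = Z.col(v).max();
    double sum = 0;
    for (uword c = 0; c < Z.n_rows; ++c) { P(c, v) = std::exp(Z(c, v) - mx); sum += P(c, v); }
    P.col(v) /= sum;
  }
  return P;
}

// [[Rcpp::export]]
arma::mat softmax_backward_cpp(const arma::mat& P, const arma::mat& dP) {
  mat dZ(P.n_rows, P.n_cols);
  for (uword v = 0; v < P.n_cols; ++v) {
    double s = dot(P.col(v), dP.col(v));
    dZ.col(v) = P.col(v) % (dP.col(v) - s);
  }
  return dZ;
}
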