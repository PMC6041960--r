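// Continuous-time layered sigmoid network: forward settling dynamics with
// time-integrated net inputs, cross-entropy error with a zero-error radius,
// and backpropagation through the unrolled dynamics (online updates).
//
// Layers live in one concatenated activation vector; each directed connection
// block k maps layer conn_from[k] -> conn_to[k] with weight matrix
// W[k] (n_to x n_from). All indices arriving from R are 0-based.
//
// The core is templated on the scalar type: training runs in single
// precision for speed (the trial stream is long and online updates tolerate
// it); gradient inspection and forward evaluation run in double precision so
// finite-difference checks and dynamics oracles hold to tight tolerances.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

template <typename T>
struct Net {
  std::vector<arma::Mat<T>> W;
  std::vector<arma::Col<T>> b;    // per layer
  arma::ivec from, to, sizes, off;
  int n_layers, n_conn, total;
  int T_steps;
  T rate, gain;

  arma::span sp(int l) const {
    return arma::span(off[l], off[l] + sizes[l] - 1);
  }
};

template <typename T>
Net<T> build_net(List weights, List biases, IntegerVector sizes,
                 IntegerVector conn_from, IntegerVector conn_to,
                 int n_timesteps, double rate, double gain) {
  Net<T> net;
  net.n_layers = sizes.size();
  net.n_conn = conn_from.size();
  net.sizes = as<arma::ivec>(sizes);
  net.from = as<arma::ivec>(conn_from);
  net.to = as<arma::ivec>(conn_to);
  net.off.set_size(net.n_layers);
  int acc = 0;
  for (int l = 0; l < net.n_layers; ++l) { net.off[l] = acc; acc += net.sizes[l]; }
  net.total = acc;
  net.W.reserve(net.n_conn);
  for (int k = 0; k < net.n_conn; ++k)
    net.W.push_back(arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(weights[k])));
  net.b.reserve(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l)
    net.b.push_back(arma::conv_to<arma::Col<T>>::from(as<arma::vec>(biases[l])));
  net.T_steps = n_timesteps;
  net.rate = static_cast<T>(rate);
  net.gain = static_cast<T>(gain);
  return net;
}

// free = neither clamped nor lesioned: these units integrate and squash.
template <typename T>
void make_free_mask(const Net<T>& net, int clamp_layer,
                    const arma::uvec& lesion_units, int lesion_layer,
                    arma::Col<T>& free_mask) {
  free_mask.ones(net.total);
  free_mask(net.sp(clamp_layer)).zeros();
  if (lesion_layer >= 0)
    for (arma::uword i = 0; i < lesion_units.n_elem; ++i)
      free_mask[net.off[lesion_layer] + lesion_units[i]] = T(0);
}

// Forward pass. A has net.total rows and T+1 columns (column 0 = initial
// state).
template <typename T>
void forward(const Net<T>& net, int clamp_layer, const arma::Col<T>& input,
             int lesion_layer, const arma::uvec& lesion_units,
             arma::Mat<T>& A) {
  arma::Col<T> free_mask;
  make_free_mask(net, clamp_layer, lesion_units, lesion_layer, free_mask);

  A.set_size(net.total, net.T_steps + 1);
  arma::Col<T> a0(net.total);
  a0.fill(T(0.5));  // sigmoid(0)
  a0(net.sp(clamp_layer)) = input;
  if (lesion_layer >= 0)
    for (arma::uword i = 0; i < lesion_units.n_elem; ++i)
      a0[net.off[lesion_layer] + lesion_units[i]] = T(0);
  A.col(0) = a0;

  arma::Col<T> x(net.total, arma::fill::zeros);
  arma::Col<T> s(net.total);
  const T* fm = free_mask.memptr();
  const T* a0p = A.colptr(0);
  for (int t = 1; t <= net.T_steps; ++t) {
    for (int l = 0; l < net.n_layers; ++l)
      std::copy(net.b[l].memptr(), net.b[l].memptr() + net.sizes[l],
                s.memptr() + net.off[l]);
    const T* aprev = A.colptr(t - 1);
    for (int k = 0; k < net.n_conn; ++k) {
      // s[to] += W_k * a_prev[from]  (gemv on aliased slices, no copies)
      arma::Col<T> sv(s.memptr() + net.off[net.to[k]], net.sizes[net.to[k]],
                      false, true);
      const arma::Col<T> av(const_cast<T*>(aprev) + net.off[net.from[k]],
                            net.sizes[net.from[k]], false, true);
      sv += net.W[k] * av;
    }
    T* xp = x.memptr();
    const T* sp_ = s.memptr();
    T* ap = A.colptr(t);
    for (int i = 0; i < net.total; ++i) {
      xp[i] += net.rate * (sp_[i] - xp[i]);
      // clamped/lesioned units keep their fixed value
      ap[i] = fm[i] != T(0) ? T(1) / (T(1) + std::exp(-net.gain * xp[i]))
                            : a0p[i];
    }
  }
}

// Cross-entropy loss and dE/da over target units at one time step.
template <typename T>
double ce_and_deriv(const arma::Col<T>& a, const arma::Col<T>& tgt,
                    T radius, arma::Col<T>& da) {
  const double eps = 1e-12;
  double loss = 0.0;
  da.zeros(a.n_elem);
  for (arma::uword j = 0; j < a.n_elem; ++j) {
    double aj = std::min(std::max(double(a[j]), eps), 1.0 - eps);
    double tj = tgt[j];
    loss -= tj * std::log(aj) + (1.0 - tj) * std::log(1.0 - aj);
    if (std::abs(tj - aj) >= double(radius))
      da[j] = T((aj - tj) / (aj * (1.0 - aj)));
  }
  return loss;
}

// BPTT through the exact forward recurrence. Fills gW (only blocks with
// skip_block[k] == false) and gb. Returns the trial loss; sets *any_grad =
// false (skipping the sweep) when every target unit sits inside the
// zero-error radius at every window step.
template <typename T>
double backward(const Net<T>& net, const arma::Mat<T>& A, int clamp_layer,
                int target_layer, const arma::Col<T>& target,
                const arma::uvec& window,  // 1-based step indices in 1..T
                T radius, int lesion_layer, const arma::uvec& lesion_units,
                std::vector<arma::Mat<T>>& gW, arma::Col<T>& gb,
                bool* any_grad, const std::vector<bool>& skip_block) {
  arma::Col<T> free_mask;
  make_free_mask(net, clamp_layer, lesion_units, lesion_layer, free_mask);

  std::vector<bool> in_window(net.T_steps + 1, false);
  for (arma::uword i = 0; i < window.n_elem; ++i) in_window[window[i]] = true;

  // output-error derivatives per window step, computed up front
  double loss = 0.0;
  std::vector<arma::Col<T>> err(net.T_steps + 1);
  bool nonzero = false;
  arma::Col<T> dtgt;
  for (int t = 1; t <= net.T_steps; ++t) {
    if (!in_window[t]) continue;
    arma::Col<T> a_t = A(net.sp(target_layer), t);
    loss += ce_and_deriv(a_t, target, radius, dtgt);
    if (arma::any(dtgt != T(0))) nonzero = true;
    err[t] = dtgt;
  }
  *any_grad = nonzero;
  if (!nonzero) return loss;

  // reverse sweep storing dE/ds_t for every step (column t-1 of DS)
  arma::Mat<T> DS(net.total, net.T_steps);
  arma::Col<T> dX_next(net.total, arma::fill::zeros);
  arma::Col<T> da(net.total), ds_next(net.total);
  const T* fm = free_mask.memptr();
  for (int t = net.T_steps; t >= 1; --t) {
    da.zeros();
    if (in_window[t]) da(net.sp(target_layer)) += err[t];
    if (t < net.T_steps) {
      ds_next = net.rate * dX_next;
      for (int k = 0; k < net.n_conn; ++k) {
        arma::Col<T> dv(da.memptr() + net.off[net.from[k]],
                        net.sizes[net.from[k]], false, true);
        const arma::Col<T> sv(ds_next.memptr() + net.off[net.to[k]],
                              net.sizes[net.to[k]], false, true);
        dv += net.W[k].t() * sv;
      }
    }
    const T* ap = A.colptr(t);
    T* dXn = dX_next.memptr();
    T* dap = da.memptr();
    T* dsp = DS.colptr(t - 1);
    for (int i = 0; i < net.total; ++i) {
      // dX_t = sigma' * dE/da + carry-over of the integrated input
      T dX = fm[i] * (dap[i] * net.gain * ap[i] * (T(1) - ap[i]) +
                      (T(1) - net.rate) * dXn[i]);
      dXn[i] = dX;            // becomes dX_t for the next (earlier) step
      dsp[i] = net.rate * dX; // dE/ds_t
    }
  }
  // per-step rank-1 accumulation: gW_k += ds_t[to] x a_{t-1}[from]^T with a
  // skip of zero input activations (common with binary patterns)
  for (int t = net.T_steps; t >= 1; --t) {
    const T* dsp = DS.colptr(t - 1);
    const T* aprev = A.colptr(t - 1);
    for (int k = 0; k < net.n_conn; ++k) {
      if (skip_block[k]) continue;
      const int nt = net.sizes[net.to[k]], nf = net.sizes[net.from[k]];
      const T* d = dsp + net.off[net.to[k]];
      const T* av = aprev + net.off[net.from[k]];
      T* g = gW[k].memptr();
      for (int j = 0; j < nf; ++j) {
        const T aj = av[j];
        if (aj == T(0)) continue;
        T* gc = g + static_cast<size_t>(j) * nt;
        for (int i = 0; i < nt; ++i) gc[i] += d[i] * aj;
      }
    }
  }
  gb = arma::sum(DS, 1);
  return loss;
}

arma::uvec window_uvec(IntegerVector window) { return as<arma::uvec>(window); }

}  // namespace

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_forward_traj(List weights, List biases, IntegerVector sizes,
                           IntegerVector conn_from, IntegerVector conn_to,
                           int clamp_layer, arma::vec input,
                           int lesion_layer, arma::uvec lesion_units,
                           int n_timesteps, double rate, double gain) {
  Net<double> net = build_net<double>(weights, biases, sizes, conn_from,
                                      conn_to, n_timesteps, rate, gain);
  arma::mat A;
  forward(net, clamp_layer, input, lesion_layer, lesion_units, A);
  return A;
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_forward_batch(List weights, List biases, IntegerVector sizes,
                            IntegerVector conn_from, IntegerVector conn_to,
                            int clamp_layer, arma::mat inputs,
                            int out_layer, int lesion_layer,
                            arma::uvec lesion_units,
                            int n_timesteps, double rate, double gain) {
  Net<double> net = build_net<double>(weights, biases, sizes, conn_from,
                                      conn_to, n_timesteps, rate, gain);
  arma::mat out(inputs.n_rows, net.sizes[out_layer]);
  arma::mat A;
  for (arma::uword i = 0; i < inputs.n_rows; ++i) {
    forward(net, clamp_layer, arma::vec(inputs.row(i).t()), lesion_layer,
            lesion_units, A);
    out.row(i) = A(net.sp(out_layer), net.T_steps).t();
  }
  return out;
}

namespace {

template <typename T>
List run_trials_impl(List weights, List biases, IntegerVector sizes,
                     IntegerVector conn_from, IntegerVector conn_to,
                     LogicalVector frozen, LogicalVector bias_free,
                     IntegerVector trial_word, IntegerVector trial_clamp,
                     IntegerVector trial_target, List layer_patterns,
                     NumericVector freq_scale,
                     double lr, double weight_decay, double radius,
                     IntegerVector window, int n_timesteps, double rate,
                     double gain, bool apply_updates) {
  Net<T> net = build_net<T>(weights, biases, sizes, conn_from, conn_to,
                            n_timesteps, rate, gain);
  int n_trials = trial_word.size();
  arma::uvec win = window_uvec(window);
  arma::uvec no_lesion;

  std::vector<arma::Mat<T>> pats(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    if (!Rf_isNull(layer_patterns[l]))
      pats[l] = arma::conv_to<arma::Mat<T>>::from(
          as<arma::mat>(layer_patterns[l]));
  }

  std::vector<bool> skip_block(net.n_conn, false);
  if (apply_updates)
    for (int k = 0; k < net.n_conn; ++k) skip_block[k] = frozen[k];
  std::vector<arma::Mat<T>> gW(net.n_conn);
  for (int k = 0; k < net.n_conn; ++k)
    gW[k].zeros(net.W[k].n_rows, net.W[k].n_cols);
  arma::Col<T> gb(net.total, arma::fill::zeros);
  arma::Mat<T> A;
  NumericVector losses(n_trials);
  int n_updates = 0;

  for (int i = 0; i < n_trials; ++i) {
    int w = trial_word[i], cl = trial_clamp[i], tl = trial_target[i];
    arma::Col<T> input = pats[cl].row(w).t();
    arma::Col<T> target = pats[tl].row(w).t();

    forward(net, cl, input, -1, no_lesion, A);
    for (int k = 0; k < net.n_conn; ++k)
      if (!skip_block[k]) gW[k].zeros();
    bool any_grad = false;
    double loss = backward(net, A, cl, tl, target, win, T(radius), -1,
                           no_lesion, gW, gb, &any_grad, skip_block);
    losses[i] = loss;
    if (!std::isfinite(loss))
      stop("non-finite loss at trial %d; training aborted", i + 1);

    if (apply_updates && any_grad && lr > 0) {
      ++n_updates;
      T flr = T(lr), fs = T(freq_scale[i]), wd = T(weight_decay);
      for (int k = 0; k < net.n_conn; ++k) {
        if (frozen[k]) continue;
        net.W[k] -= flr * (fs * gW[k] + wd * net.W[k]);
      }
      for (int l = 0; l < net.n_layers; ++l) {
        if (!bias_free[l]) continue;  // all incoming blocks frozen
        arma::Col<T> gbl(gb.memptr() + net.off[l], net.sizes[l], false, true);
        net.b[l] -= flr * (fs * gbl + wd * net.b[l]);
      }
    }
  }

  List outW(net.n_conn), outB(net.n_layers);
  for (int k = 0; k < net.n_conn; ++k)
    outW[k] = wrap(arma::conv_to<arma::mat>::from(net.W[k]));
  for (int l = 0; l < net.n_layers; ++l)
    outB[l] = wrap(arma::conv_to<arma::vec>::from(net.b[l]));
  List grads = R_NilValue;
  if (!apply_updates) {
    List gWl(net.n_conn);
    for (int k = 0; k < net.n_conn; ++k)
      gWl[k] = wrap(arma::conv_to<arma::mat>::from(gW[k]));
    grads = List::create(_["weights"] = gWl,
                         _["biases"] = wrap(arma::conv_to<arma::vec>::from(gb)));
  }
  return List::create(_["weights"] = outW, _["biases"] = outB,
                      _["loss"] = losses, _["grads"] = grads,
                      _["n_updates"] = n_updates);
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_run_trials(List weights, List biases, IntegerVector sizes,
                    IntegerVector conn_from, IntegerVector conn_to,
                    LogicalVector frozen, LogicalVector bias_free,
                    IntegerVector trial_word, IntegerVector trial_clamp,
                    IntegerVector trial_target, List layer_patterns,
                    NumericVector freq_scale,
                    double lr, double weight_decay, double radius,
                    IntegerVector window, int n_timesteps, double rate,
                    double gain, bool apply_updates, bool single_precision) {
  if (single_precision) {
    return run_trials_impl<float>(weights, biases, sizes, conn_from, conn_to,
                                  frozen, bias_free, trial_word, trial_clamp,
                                  trial_target, layer_patterns, freq_scale,
                                  lr, weight_decay, radius, window,
                                  n_timesteps, rate, gain, apply_updates);
  }
  return run_trials_impl<double>(weights, biases, sizes, conn_from, conn_to,
                                 frozen, bias_free, trial_word, trial_clamp,
                                 trial_target, layer_patterns, freq_scale,
                                 lr, weight_decay, radius, window,
                                 n_timesteps, rate, gain, apply_updates);
}
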