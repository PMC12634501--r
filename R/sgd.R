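#' Surrogate pseudo-derivative of the spike nonlinearity
#'
#' Fast-sigmoid pseudo-derivative \code{1 / (1 + slope * |v - v_peak|)^2}:
#' smooth, nonnegative, unimodal with maximum 1 at the spike cutoff, and
#' integrable. Used in place of the derivative of the hard threshold during
#' backpropagation.
#'
#' @param v membrane potential (mV), vectorized.
#' @param v_peak spike cutoff (mV).
#' @param slope sharpness (1/mV), \code{> 0}.
#' @return Pseudo-derivative values in \code{(0, 1]}.
#' @export
surrogate_grad <- function(v, v_peak, slope = 0.8) {
  if (slope <= 0) stop("surrogate_grad: slope must be > 0", call. = FALSE)
  1 / (1 + slope * abs(v - v_peak))^2
}

# Spike nonlinearity and its backward factor.
# mode "spike":  hard threshold forward, surrogate_grad backward.
# mode "smooth": the smoothed spike 0.5 * (1 + x / (1 + slope|x|)) whose
#   exact derivative is 0.5 * surrogate_grad; the analytic gradient of the
#   smooth forward then matches finite differences, which is what the
#   gradient check exercises.
spike_fn <- function(v_pre, v_peak, slope, mode) {
  x <- v_pre - v_peak
  if (mode == "spike") {
    list(z = (x >= 0) * 1, sg = 1 / (1 + slope * abs(x))^2)
  } else {
    d <- 1 + slope * abs(x)
    list(z = 0.5 * (1 + x / d), sg = 0.5 / d^2)
  }
}

#' Configuration of the surrogate-gradient classifier
#'
#' A discrete-time feed-forward network of Izhikevich units: input event
#' channels project to one or more hidden spiking layers; class scores are
#' the time-sum of a leaky integrator of the last layer's spikes, trained
#' with softmax cross-entropy. Heterogeneity (sampled once, frozen by
#' default) enters per hidden unit as a bias current (\code{eta} channel),
#' a multiplicative input gain (network channel, center 1, relative width
#' \code{delta_g / g_bar}), and the partial reset coefficient
#' (\code{theta} channel).
#'
#' @param n_in number of input channels.
#' @param n_classes number of classes.
#' @param layer_sizes integer vector of hidden layer sizes (\code{>= 1}
#'   layer).
#' @param steps time steps per sample (\code{>= 2}).
#' @param dt integration step (ms).
#' @param slope surrogate slope (1/mV).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param w_scale input-weight initialization scale (pA); weights are drawn
#'   \code{N(0, (w_scale / sqrt(fan_in))^2)}.
#' @param out_decay leaky-integrator decay of the readout per step, in
#'   \code{[0, 1)}.
#' @param params a [neuron_params()] object.
#' @param het a [het_spec()] object; zero widths give the homogeneous
#'   control.
#' @param trainable_eta train the per-unit bias currents by gradient
#'   descent (heterogeneous parameters are frozen by default).
#' @param train_fraction fraction of samples used for training (stratified).
#' @param seed integer seed.
#' @return An object of class \code{"sgd_config"}.
#' @export
sgd_config <- function(n_in, n_classes, layer_sizes = 200, steps = 100,
                       dt = 1, slope = 0.8, lr = 2e-3, epochs = 20,
                       batch_size = 32, w_scale = 3000, out_decay = 0.9,
                       params = ca3_params(),
                       het = het_spec(eta_bar = 0, delta_eta = 0,
                                      g_bar = 1, delta_g = 0,
                                      theta_bar = 0, delta_theta = 0),
                       trainable_eta = FALSE, train_fraction = 0.7,
                       seed = 1L) {
  if (length(layer_sizes) < 1) stop("sgd_config: need >= 1 hidden layer",
                                    call. = FALSE)
  if (steps < 2) stop("sgd_config: steps must be >= 2", call. = FALSE)
  stopifnot(inherits(params, "neuron_params"), inherits(het, "het_spec"))
  if (!(out_decay >= 0 && out_decay < 1))
    stop("sgd_config: out_decay must be in [0, 1)", call. = FALSE)
  cfg <- list(n_in = as.integer(n_in), n_classes = as.integer(n_classes),
              layer_sizes = as.integer(layer_sizes),
              steps = as.integer(steps), dt = dt, slope = slope, lr = lr,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), w_scale = w_scale,
              out_decay = out_decay, params = params, het = het,
              trainable_eta = trainable_eta,
              train_fraction = train_fraction, seed = as.integer(seed))
  class(cfg) <- "sgd_config"
  cfg
}

# Sample weights and per-unit heterogeneity for every hidden layer.
sgd_init <- function(cfg) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  sizes <- c(cfg$n_in, cfg$layer_sizes)
  L <- length(cfg$layer_sizes)
  het <- cfg$het
  W <- eta <- gain <- theta <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * fan_in,
                                  0, cfg$w_scale / sqrt(fan_in)),
                     nrow = sizes[l + 1])
    eta[[l]] <- sample_lorentzian(sizes[l + 1], het$eta_bar, het$delta_eta,
                                  het$eta_bounds)
    gain[[l]] <- if (het$delta_g > 0)
      sample_lorentzian(sizes[l + 1], het$g_bar, het$delta_g,
                        het$g_bounds) / het$g_bar
    else rep(1, sizes[l + 1])
    theta[[l]] <- sample_lorentzian(sizes[l + 1], het$theta_bar,
                                    het$delta_theta, het$theta_bounds)
  }
  W_out <- matrix(stats::rnorm(cfg$n_classes * cfg$layer_sizes[L],
                               0, 1 / sqrt(cfg$layer_sizes[L])),
                  nrow = cfg$n_classes)
  list(W = W, W_out = W_out, eta = eta, gain = gain, theta = theta)
}

# Events -> per-step input matrices (list over steps of batch x channels
# spike-count matrices).
events_to_steps <- function(dataset, idx, steps) {
  b <- length(idx)
  out <- lapply(seq_len(steps), function(t)
    matrix(0, b, dataset$n_channels))
  for (j in seq_along(idx)) {
    e <- dataset$events[[idx[j]]]
    if (nrow(e) == 0) next
    tb <- pmin(floor(e$time_ms / dataset$duration * steps) + 1L, steps)
    for (q in seq_len(nrow(e)))
      out[[tb[q]]][j, e$channel[q]] <- out[[tb[q]]][j, e$channel[q]] + 1
  }
  out
}

#' Forward pass of the spiking classifier
#'
#' Runs the discrete-time Izhikevich layers over an input batch and returns
#' per-sample class scores (time-summed leaky-integrated spikes of the last
#' layer). With \code{mode = "spike"} the spike nonlinearity is a hard
#' threshold (the operating mode); \code{mode = "smooth"} replaces it with
#' the smoothed spike function whose exact derivative is the surrogate,
#' making the analytic gradient equal to the finite-difference gradient.
#'
#' @param net a network as returned by the internal initializer (weights,
#'   heterogeneity vectors); obtained from a fitted model as
#'   \code{fit$net}.
#' @param cfg an [sgd_config()] object.
#' @param X_steps list (length \code{steps}) of batch x channels input
#'   spike-count matrices (see [make_rate_task()] datasets and the internal
#'   encoder), or an \code{"event_dataset"} together with \code{idx}.
#' @param idx sample indices when \code{X_steps} is a dataset.
#' @param mode \code{"spike"} or \code{"smooth"}.
#' @param keep_cache keep intermediate states (needed for the backward
#'   pass).
#' @return List with \code{scores} (batch x classes) and, if requested,
#'   the backward \code{cache}.
#' @export
sgd_forward <- function(net, cfg, X_steps, idx = NULL, mode = "spike",
                        keep_cache = FALSE) {
  if (inherits(X_steps, "event_dataset")) {
    if (is.null(idx)) idx <- seq_along(X_steps$labels)
    X_steps <- events_to_steps(X_steps, idx, cfg$steps)
  }
  mode <- match.arg(mode, c("spike", "smooth"))
  p <- cfg$params
  Tn <- cfg$steps
  L <- length(cfg$layer_sizes)
  b <- nrow(X_steps[[1]])
  v <- w <- vector("list", L)
  for (l in seq_len(L)) {
    v[[l]] <- matrix(p$v_r, b, cfg$layer_sizes[l])
    w[[l]] <- matrix(0, b, cfg$layer_sizes[l])
  }
  lam <- cfg$out_decay
  a_t <- (1 - lam^(Tn - seq_len(Tn) + 1)) / (1 - lam)
  scores <- matrix(0, b, cfg$n_classes)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  if (any(!is.finite(unlist(X_steps))))
    stop("sgd_forward: non-finite input", call. = FALSE)
  for (t in seq_len(Tn)) {
    zin <- X_steps[[t]]
    ct <- if (keep_cache) vector("list", L) else NULL
    for (l in seq_len(L)) {
      I <- sweep(zin %*% t(net$W[[l]]), 2, net$gain[[l]], "*")
      I <- sweep(I, 2, net$eta[[l]], "+")
      vp <- v[[l]]
      v_pre <- vp + (cfg$dt / p$C) *
        (p$k * (vp - p$v_r) * (vp - p$v_t) - w[[l]] + I)
      if (any(!is.finite(v_pre)))
        stop(sprintf("sgd_forward: non-finite activation (layer %d, step %d)",
                     l, t), call. = FALSE)
      sp <- spike_fn(v_pre, p$v_peak, cfg$slope, mode)
      z <- sp$z
      th <- net$theta[[l]]
      x <- v_pre - p$v_peak
      v_new <- (1 - z) * v_pre +
        z * sweep(x, 2, th, "*") + z * p$v_reset
      w_new <- w[[l]] + (cfg$dt / p$tau_w) * (p$beta * (vp - p$v_r) - w[[l]]) +
        z * p$w_jump
      if (keep_cache)
        ct[[l]] <- list(v_prev = vp, v_pre = v_pre, z = z, sg = sp$sg,
                        zin = zin)
      v[[l]] <- v_new
      w[[l]] <- w_new
      zin <- z
    }
    scores <- scores + a_t[t] * (zin %*% t(net$W_out))
    if (keep_cache) cache[[t]] <- ct
  }
  list(scores = scores, cache = cache, a_t = a_t)
}

# Softmax cross-entropy loss and gradient wrt scores (mean over batch).
softmax_xent <- function(scores, labels) {
  m <- apply(scores, 1, max)
  es <- exp(scores - m)
  pr <- es / rowSums(es)
  b <- nrow(scores)
  pick <- cbind(seq_len(b), labels + 1L)
  loss <- -mean(log(pmax(pr[pick], 1e-300)))
  d <- pr
  d[pick] <- d[pick] - 1
  list(loss = loss, dscores = d / b, prob = pr)
}

# Backpropagation through time; returns gradients for W, W_out and eta.
sgd_backward <- function(net, cfg, fw, dscores) {
  p <- cfg$params
  Tn <- cfg$steps
  L <- length(cfg$layer_sizes)
  b <- nrow(dscores)
  gW <- lapply(net$W, function(m) m * 0)
  geta <- lapply(net$eta, function(e) e * 0)
  gW_out <- net$W_out * 0
  gv <- gw <- vector("list", L)
  for (l in seq_len(L)) {
    gv[[l]] <- matrix(0, b, cfg$layer_sizes[l])
    gw[[l]] <- matrix(0, b, cfg$layer_sizes[l])
  }
  dtC <- cfg$dt / p$C
  for (t in rev(seq_len(Tn))) {
    ct <- fw$cache[[t]]
    gz_down <- fw$a_t[t] * (dscores %*% net$W_out)  # into layer L at step t
    gW_out <- gW_out + fw$a_t[t] * crossprod(dscores, ct[[L]]$z)
    for (l in rev(seq_len(L))) {
      cc <- ct[[l]]
      th <- net$theta[[l]]
      x <- cc$v_pre - p$v_peak
      # explicit dependence of the post-reset voltage on the spike variable
      dv_dz <- sweep(x, 2, th, "*") + p$v_reset - cc$v_pre
      dz_total <- gz_down + gv[[l]] * dv_dz + gw[[l]] * p$w_jump
      thz <- sweep(cc$z, 2, th, "*")
      g_vpre <- gv[[l]] * (1 - cc$z + thz) + dz_total * cc$sg
      g_I <- g_vpre * dtC
      g_Iw <- sweep(g_I, 2, net$gain[[l]], "*")
      gW[[l]] <- gW[[l]] + crossprod(g_Iw, cc$zin)
      geta[[l]] <- geta[[l]] + colSums(g_I)
      if (l > 1) gz_down <- g_Iw %*% net$W[[l]]
      gw_old <- gw[[l]]
      gv[[l]] <- g_vpre *
        (1 + dtC * p$k * (2 * cc$v_prev - p$v_r - p$v_t)) +
        gw_old * (cfg$dt / p$tau_w) * p$beta
      gw[[l]] <- g_vpre * (-dtC) + gw_old * (1 - cfg$dt / p$tau_w)
    }
  }
  list(W = gW, W_out = gW_out, eta = geta)
}

#' Loss and analytic gradient on a batch
#'
#' Convenience wrapper combining [sgd_forward()], the softmax
#' cross-entropy, and backpropagation through time. Used for training and
#' for the finite-difference gradient check (in \code{"smooth"} mode the
#' analytic gradient is the exact gradient of the forward loss).
#'
#' @inheritParams sgd_forward
#' @param labels integer class labels in \code{0 .. n_classes - 1}.
#' @return List with \code{loss}, gradients (\code{W}, \code{W_out},
#'   \code{eta}), and \code{scores}.
#' @export
sgd_loss_grad <- function(net, cfg, X_steps, labels, mode = "spike") {
  fw <- sgd_forward(net, cfg, X_steps, mode = mode, keep_cache = TRUE)
  sx <- softmax_xent(fw$scores, labels)
  gr <- sgd_backward(net, cfg, fw, sx$dscores)
  list(loss = sx$loss, W = gr$W, W_out = gr$W_out, eta = gr$eta,
       scores = fw$scores)
}

# Minimal Adam optimizer state/step over a flat list of arrays.
adam_step <- function(theta, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (k in seq_along(theta)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * grad[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * grad[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    theta[[k]] <- theta[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, st = st)
}

#' Train the spiking classifier by surrogate gradient descent
#'
#' Stratified train/test split, minibatch Adam on the softmax
#' cross-entropy of the time-summed scores, hard-threshold forward with
#' surrogate backward. Heterogeneous per-unit parameters are sampled once
#' from the configured Lorentzian channels and frozen (unless
#' \code{trainable_eta}).
#'
#' @param cfg an [sgd_config()] object.
#' @param dataset an \code{"event_dataset"} with \code{>= 2} classes.
#' @return An object of class \code{"sgd_fit"}: \code{history} (per-epoch
#'   train/test accuracy, %), \code{final_test_accuracy} (%), the trained
#'   \code{net}, split indices, and config echo.
#' @export
train_sgd <- function(cfg, dataset) {
  stopifnot(inherits(cfg, "sgd_config"), inherits(dataset, "event_dataset"))
  if (length(unique(dataset$labels)) < 2)
    stop("train_sgd: dataset needs >= 2 classes", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  net <- sgd_init(cfg)
  # stratified split
  idx_train <- idx_test <- integer(0)
  for (k in unique(dataset$labels)) {
    ik <- which(dataset$labels == k)
    ik <- sample(ik)
    ntr <- max(1L, round(length(ik) * cfg$train_fraction))
    idx_train <- c(idx_train, ik[seq_len(ntr)])
    idx_test <- c(idx_test, ik[-seq_len(ntr)])
  }
  # pre-encode once
  enc <- function(idx) events_to_steps(dataset, idx, cfg$steps)
  X_test <- enc(idx_test)
  y_test <- dataset$labels[idx_test]
  X_train_all <- enc(idx_train)
  y_train <- dataset$labels[idx_train]
  pick_rows <- function(X, rows) lapply(X, function(m) m[rows, , drop = FALSE])
  pars <- c(net$W, list(net$W_out))
  if (cfg$trainable_eta) pars <- c(pars, net$eta)
  st <- list(t = 0, m = lapply(pars, function(x) x * 0),
             v = lapply(pars, function(x) x * 0))
  L <- length(cfg$layer_sizes)
  acc <- function(X, y) {
    sc <- sgd_forward(net, cfg, X, mode = "spike")$scores
    100 * mean(max.col(sc, ties.method = "first") - 1L == y)
  }
  hist_rows <- list()
  ntr <- length(idx_train)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(ntr)
    for (start in seq(1, ntr, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1, ntr)]
      lg <- sgd_loss_grad(net, cfg,
                          pick_rows(X_train_all, rows), y_train[rows],
                          mode = "spike")
      if (!is.finite(lg$loss))
        stop("train_sgd: non-finite loss at epoch ", ep, call. = FALSE)
      grads <- c(lg$W, list(lg$W_out))
      pars <- c(net$W, list(net$W_out))
      if (cfg$trainable_eta) {
        grads <- c(grads, lg$eta)
        pars <- c(pars, net$eta)
      }
      upd <- adam_step(pars, grads, st, cfg$lr)
      st <- upd$st
      net$W <- upd$theta[seq_len(L)]
      net$W_out <- upd$theta[[L + 1]]
      if (cfg$trainable_eta) net$eta <- upd$theta[(L + 2):(2 * L + 1)]
    }
    hist_rows[[ep]] <- data.frame(
      epoch = ep,
      train_accuracy = acc(X_train_all, y_train),
      test_accuracy = acc(X_test, y_test))
  }
  history <- do.call(rbind, hist_rows)
  out <- list(history = history,
              final_test_accuracy = history$test_accuracy[cfg$epochs],
              net = net, idx_train = idx_train, idx_test = idx_test,
              config = cfg)
  class(out) <- "sgd_fit"
  out
}

#' @export
print.sgd_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sgd_fit: %d->%s->%d, %d steps, %d epochs\n", cfg$n_in,
              paste(cfg$layer_sizes, collapse = "-"), cfg$n_classes,
              cfg$steps, cfg$epochs))
  cat(sprintf("  final train accuracy: %.1f%%\n",
              x$history$train_accuracy[nrow(x$history)]))
  cat(sprintf("  final test accuracy:  %.1f%%\n", x$final_test_accuracy))
  invisible(x)
}

#' @export
predict.sgd_fit <- function(object, dataset, idx = NULL, ...) {
  if (is.null(idx)) idx <- seq_along(dataset$labels)
  sc <- sgd_forward(object$net, object$config, dataset, idx = idx,
                    mode = "spike")$scores
  max.col(sc, ties.method = "first") - 1L
}
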