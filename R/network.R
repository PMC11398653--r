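# Feedforward moment neural network: linear moment propagation
# (mu_bar = W mu + mu_ext, Sigma_bar = W Sigma W^T + Sigma_ext), moment
# batch-normalization, moment activation, and a linear moment readout
# (mu_hat = W_out mu' + b, Sigma_hat = W_out Sigma' W_out^T).
#
# The normalization standardizes the mean channel per feature using the total
# variability of the current across the batch (variance of the per-example
# means plus the mean per-example variance) and applies the matching diagonal
# congruence to the covariance channel, so that it can be absorbed exactly
# into the summation layer after training. The mean-channel batch variance
# alone would be degenerate here: the input mean carries no stimulus
# information by design, so it is identical across a batch.

#' Construct a feedforward moment neural network
#'
#' @param input_size Number of input neurons (length of the input mean).
#' @param hidden_sizes Integer vector of hidden layer widths (>= 1 layer).
#' @param output_size Readout dimension (2 for the direction task).
#' @param params A [lif_params()] object shared by all hidden layers.
#' @param seed Optional seed for weight initialization.
#' @param readout_bias Include a trainable readout bias (default `TRUE`).
#' @return An object of class `mnn_network`.
#' @examples
#' net <- mnn_network(10, 8, 2, seed = 1)
#' @export
mnn_network <- function(input_size, hidden_sizes, output_size,
                        params = lif_params(), seed = NULL,
                        readout_bias = TRUE) {
  stopifnot(input_size >= 1, length(hidden_sizes) >= 1,
            all(hidden_sizes >= 1), output_size >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sizes <- c(input_size, hidden_sizes)
  layers <- lapply(seq_along(hidden_sizes), function(l) {
    fan_in <- sizes[l]
    h <- sizes[l + 1L]
    list(
      W = matrix(stats::rnorm(h * fan_in, sd = 1 / sqrt(fan_in)), h, fan_in),
      mu_ext = numeric(h),
      bn = list(gamma = rep(1, h), beta = rep(1, h),
                running_mean = numeric(h), running_var = rep(1, h),
                eps = 1e-5, momentum = 0.1, initialized = FALSE)
    )
  })
  h_last <- hidden_sizes[length(hidden_sizes)]
  structure(list(
    layers = layers,
    W_out = matrix(stats::rnorm(output_size * h_last, sd = 1 / sqrt(h_last)),
                   output_size, h_last),
    b_out = if (readout_bias) numeric(output_size) else NULL,
    input_size = input_size, hidden_sizes = hidden_sizes,
    output_size = output_size, params = params
  ), class = "mnn_network")
}

#' @export
print.mnn_network <- function(x, ...) {
  cat(sprintf("moment neural network: %d -> %s -> %d%s\n",
              x$input_size, paste(x$hidden_sizes, collapse = " -> "),
              x$output_size,
              if (is.null(x$layers[[1]]$bn)) " (normalization absorbed)" else ""))
  invisible(x)
}

#' Synaptic summation of spike moments into current moments
#'
#' Linear moment propagation: `mu_bar = W mu + mu_ext`,
#' `Sigma_bar = W Sigma W' + Sigma_ext`, with the output symmetrized.
#'
#' @param W Weight matrix (mV per spike), post x pre.
#' @param input A [spike_moments()] object, or any list with `mu` and `Sigma`.
#' @param mu_ext External current mean (mV/ms), scalar or length-post vector.
#' @param Sigma_ext External current covariance (mV^2/ms); scalar 0 (default)
#'   or a post x post matrix.
#' @return A [current_moments()] object.
#' @export
synaptic_summation <- function(W, input, mu_ext = 0, Sigma_ext = 0) {
  W <- as.matrix(W)
  if (length(input$mu) != ncol(W))
    stop("synaptic_summation: weight/input shape mismatch", call. = FALSE)
  mu_bar <- drop(W %*% input$mu) + mu_ext
  S <- W %*% input$Sigma %*% t(W)
  if (!identical(Sigma_ext, 0)) S <- S + Sigma_ext
  current_moments(mu_bar, (S + t(S)) / 2)
}

# batch-normalization forward on raw moments.
# m1: B x H matrix of current means; Slist: list of B H x H covariances.
# Returns normalized moments plus the cache needed for the backward pass.
.bn_forward <- function(m1, Slist, bn, training) {
  B <- nrow(m1)
  if (training) {
    mb <- colMeans(m1)
    ce <- sweep(m1, 2L, mb)
    Sdiag <- vapply(Slist, diag, numeric(ncol(m1)))   # H x B
    vb <- colMeans(ce^2) + rowMeans(Sdiag)
  } else {
    if (!bn$initialized)
      stop("moment_batchnorm: no running statistics available", call. = FALSE)
    mb <- bn$running_mean
    vb <- bn$running_var
    ce <- sweep(m1, 2L, mb)
  }
  s <- sqrt(vb + bn$eps)
  xhat <- sweep(ce, 2L, s, `/`)
  m2 <- sweep(xhat, 2L, bn$gamma, `*`)
  m2 <- sweep(m2, 2L, bn$beta, `+`)
  d <- bn$gamma / s
  dd <- tcrossprod(d)
  S2 <- lapply(Slist, function(S) S * dd)
  state <- bn
  if (training) {
    mom <- bn$momentum
    if (!bn$initialized) {
      state$running_mean <- mb
      state$running_var <- vb
    } else {
      state$running_mean <- (1 - mom) * bn$running_mean + mom * mb
      state$running_var <- (1 - mom) * bn$running_var + mom * vb
    }
    state$initialized <- TRUE
  }
  list(m2 = m2, S2 = S2, state = state,
       cache = list(ce = ce, s = s, xhat = xhat, d = d, Slist = Slist,
                    training = training))
}

# backward through .bn_forward. dm2: B x H; dS2: list of symmetric H x H.
# Returns grads w.r.t. inputs (dm1, dS) and parameters (dgamma, dbeta).
.bn_backward <- function(dm2, dS2, bn, cache) {
  B <- nrow(dm2)
  s <- cache$s; d <- cache$d; ce <- cache$ce; xhat <- cache$xhat
  H <- length(s)
  # covariance-channel contributions
  ddv <- numeric(H)                      # dL/dd
  dS <- vector("list", B)
  for (e in seq_len(B)) {
    G <- dS2[[e]]
    ddv <- ddv + 2 * (G * cache$Slist[[e]]) %*% d
    dS[[e]] <- G * tcrossprod(d)
  }
  ddv <- drop(ddv)
  dgamma <- colSums(dm2 * xhat) + ddv / s
  dbeta <- colSums(dm2)
  dxhat <- sweep(dm2, 2L, bn$gamma, `*`)
  if (cache$training) {
    ds <- -colSums(dxhat * ce) / s^2 - ddv * bn$gamma / s^2
    dv <- ds / (2 * s)
    dce <- sweep(dxhat, 2L, s, `/`) +
      sweep(ce, 2L, 2 * dv / B, `*`)
    dm1 <- sweep(dce, 2L, colMeans(dce))
    for (e in seq_len(B)) {
      diag(dS[[e]]) <- diag(dS[[e]]) + dv / B
    }
  } else {
    dm1 <- sweep(dxhat, 2L, s, `/`)
  }
  list(dm1 = dm1, dS = dS, dgamma = dgamma, dbeta = dbeta)
}

#' Moment batch-normalization
#'
#' Standardizes the mean channel of a batch of current moments per feature
#' and applies the matching diagonal congruence `D Sigma D` (with
#' `D = diag(gamma / s)`) to the covariance channel, so that the transform is
#' an affine map of the current moments and can be absorbed exactly into the
#' preceding summation layer. The per-feature scale `s` is the square root of
#' the total current variability across the batch: the variance of the
#' per-example means plus the mean per-example variance (epsilon-stabilized).
#'
#' @param input List of [current_moments()] objects (a batch; >= 2 in train
#'   mode) or a single `current_moments` in eval mode.
#' @param state Normalization state: list with `gamma`, `beta`,
#'   `running_mean`, `running_var`, `eps`, `momentum`, `initialized`.
#' @param mode `"train"` (use and update batch statistics) or `"eval"` (use
#'   running statistics).
#' @return List with `output` (same shape as `input`) and the updated `state`.
#' @export
moment_batchnorm <- function(input, state, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  single <- inherits(input, "current_moments")
  if (single) input <- list(input)
  if (mode == "train" && length(input) < 2L)
    stop("moment_batchnorm: need a batch of >= 2 in train mode", call. = FALSE)
  m1 <- do.call(rbind, lapply(input, `[[`, "mu"))
  Slist <- lapply(input, `[[`, "Sigma")
  fw <- .bn_forward(m1, Slist, state, training = (mode == "train"))
  out <- lapply(seq_along(input), function(e)
    current_moments(fw$m2[e, ], fw$S2[[e]]))
  if (single) out <- out[[1L]]
  list(output = out, state = fw$state)
}

#' Absorb the normalization into the summation layer
#'
#' Folds each layer's trained normalization (in eval mode, i.e. its running
#' statistics) into the synaptic weights and external current:
#' `W <- D W`, `mu_ext <- D mu_ext + (beta - gamma * m / s)` with
#' `D = diag(gamma / s)`, `s = sqrt(running_var + eps)`. The returned network
#' has no normalization layers and produces identical outputs in eval mode;
#' absorbing twice is a no-op.
#'
#' @param net A trained [mnn_network()].
#' @return An equivalent `mnn_network` with `bn = NULL` in every layer.
#' @export
absorb_batchnorm <- function(net) {
  stopifnot(inherits(net, "mnn_network"))
  for (l in seq_along(net$layers)) {
    bn <- net$layers[[l]]$bn
    if (is.null(bn)) next
    if (!bn$initialized)
      stop("absorb_batchnorm: no training statistics to absorb", call. = FALSE)
    s <- sqrt(bn$running_var + bn$eps)
    d <- bn$gamma / s
    net$layers[[l]]$W <- net$layers[[l]]$W * d
    net$layers[[l]]$mu_ext <- d * net$layers[[l]]$mu_ext +
      bn$beta - bn$gamma * bn$running_mean / s
    net$layers[[l]]$bn <- NULL
  }
  net
}

#' Forward pass of the moment network
#'
#' Propagates input moments through summation, normalization (eval mode) and
#' moment activation in each hidden layer, then applies the linear moment
#' readout. Deterministic.
#'
#' @param net An [mnn_network()].
#' @param input An `encoded_stimulus`, [spike_moments()], or list with `mu`
#'   and `Sigma`.
#' @param return_hidden Also return the hidden-layer [spike_moments()].
#' @return List of class `mnn_output` with `mu_hat`, `Sigma_hat`, `theta_hat`
#'   (`atan2` of the first two readout means) and optionally `hidden`.
#' @export
mnn_forward <- function(net, input, return_hidden = FALSE) {
  stopifnot(inherits(net, "mnn_network"))
  cur <- list(mu = input$mu, Sigma = input$Sigma)
  hidden <- if (return_hidden) vector("list", length(net$layers)) else NULL
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    cm <- synaptic_summation(lay$W, cur, lay$mu_ext)
    if (!is.null(lay$bn))
      cm <- moment_batchnorm(cm, lay$bn, mode = "eval")$output
    sm <- moment_activate(cm, net$params)
    if (return_hidden) hidden[[l]] <- sm
    cur <- sm
  }
  mu_hat <- drop(net$W_out %*% cur$mu)
  if (!is.null(net$b_out)) mu_hat <- mu_hat + net$b_out
  Sigma_hat <- net$W_out %*% cur$Sigma %*% t(net$W_out)
  Sigma_hat <- (Sigma_hat + t(Sigma_hat)) / 2
  out <- list(mu_hat = mu_hat, Sigma_hat = Sigma_hat,
              theta_hat = atan2(mu_hat[2], mu_hat[1]))
  if (return_hidden) out$hidden <- hidden
  structure(out, class = "mnn_output")
}

#' Tuning curves of the hidden neurons
#'
#' Evaluates the trained network over a grid of motion directions and
#' contrasts and tabulates, for each hidden neuron of the last hidden layer,
#' the mean firing rate and the Fano factor (`sigma^2/mu`, with `0/0`
#' defined as 0). The preferred direction of each neuron is the grid argmax
#' of its mean rate at the highest contrast (ties broken by lowest index).
#'
#' @param net A trained [mnn_network()].
#' @param array Detector array used to encode the probe gratings.
#' @param directions Vector of directions (rad); default a 100-point grid.
#' @param contrasts Vector of contrasts.
#' @param ... Passed to [grating_stimulus()].
#' @return List with arrays `rate` and `fano` (`direction x contrast x
#'   neuron`), `preferred` (per-neuron rad), and the probe grids.
#' @export
tuning_curves <- function(net, array,
                          directions = seq(-pi, pi, length.out = 101)[-101],
                          contrasts = c(0.25, 0.5, 0.75), ...) {
  nh <- net$hidden_sizes[length(net$hidden_sizes)]
  rate <- fano <- array(0, c(length(directions), length(contrasts), nh))
  for (ci in seq_along(contrasts)) {
    for (di in seq_along(directions)) {
      enc <- encode_grating(
        grating_stimulus(contrasts[ci], directions[di], ...), array)
      h <- mnn_forward(net, enc, return_hidden = TRUE)$hidden
      sm <- h[[length(h)]]
      rate[di, ci, ] <- sm$mu
      f <- sm$sigma^2
      fano[di, ci, ] <- ifelse(sm$mu > 0, f / sm$mu, 0)
    }
  }
  pref <- directions[apply(rate[, length(contrasts), , drop = FALSE], 3,
                           which.max)]
  list(rate = rate, fano = fano, preferred = pref,
       directions = directions, contrasts = contrasts)
}
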