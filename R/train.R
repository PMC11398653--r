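# Training loops: the Monte-Carlo angular loss for the motion-direction task
# and softmax cross-entropy (on the readout means) for classification.
# Stimuli are encoded on the fly batch by batch, so no dataset of dense
# covariance matrices is ever held in memory.

.net_get_params <- function(net) {
  list(layers = lapply(net$layers, function(l)
    list(W = l$W, mu_ext = l$mu_ext,
         gamma = if (is.null(l$bn)) NULL else l$bn$gamma,
         beta = if (is.null(l$bn)) NULL else l$bn$beta)),
    W_out = net$W_out, b_out = net$b_out)
}

.net_set_params <- function(net, p) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- p$layers[[l]]$W
    net$layers[[l]]$mu_ext <- p$layers[[l]]$mu_ext
    if (!is.null(net$layers[[l]]$bn)) {
      net$layers[[l]]$bn$gamma <- p$layers[[l]]$gamma
      net$layers[[l]]$bn$beta <- p$layers[[l]]$beta
    }
  }
  net$W_out <- p$W_out
  if (!is.null(net$b_out)) net$b_out <- p$b_out
  net
}

# batch loss + parameter grads for the direction task
.direction_batch <- function(net, MU, Slist, theta, mc_samples, jitter,
                             training = TRUE) {
  B <- nrow(MU)
  fw <- .mnn_fwd(net, MU, Slist, training = training)
  z <- matrix(stats::rnorm(2 * mc_samples), mc_samples, 2)
  loss <- 0
  dmu <- matrix(0, B, 2)
  dSig <- vector("list", B)
  for (e in seq_len(B)) {
    r <- .angular_loss_1(fw$mu_hat[e, ], fw$Sig_hat[[e]], theta[e], z,
                         jitter, grad = training)
    loss <- loss + r$loss / B
    if (training) {
      dmu[e, ] <- r$dmu / B
      dSig[[e]] <- r$dSig / B
    }
  }
  if (!training) return(list(loss = loss))
  bn_states <- lapply(fw$caches, function(ca)
    if (is.null(ca$bnf)) NULL else ca$bnf$state)
  list(loss = loss, grads = .mnn_bwd(net, fw, dmu, dSig),
       bn_states = bn_states)
}

.encode_batch <- function(theta, contrast, array, dt = 1, ...) {
  B <- length(theta)
  MU <- NULL
  Slist <- vector("list", B)
  for (e in seq_len(B)) {
    enc <- encode_grating(grating_stimulus(contrast[e], theta[e], ...),
                          array, dt)
    if (is.null(MU)) MU <- matrix(0, B, length(enc$mu))
    MU[e, ] <- enc$mu
    Slist[[e]] <- enc$Sigma
  }
  list(MU = MU, Slist = Slist)
}

#' Train a moment network on the motion-direction task
#'
#' Gradient-based training with the Monte-Carlo angular loss and AdamW.
#' Each epoch draws fresh gratings with directions uniform on `[-pi, pi)` and
#' contrasts uniform over `contrast_range`, encodes them analytically, and
#' backpropagates through the moment mappings. Validation stimuli are
#' regenerated from a fixed seed each epoch.
#'
#' @param net An [mnn_network()] whose input size matches `2 * array$n_sites`.
#' @param array Detector array from [make_hexagonal_grid()].
#' @param epochs Training epochs.
#' @param samples_per_epoch Stimuli drawn per epoch.
#' @param batch_size Mini-batch size.
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param contrast_range Contrast sampling range, within `[0, 1]`.
#' @param mc_samples Monte-Carlo samples per example in the angular loss.
#' @param jitter Diagonal jitter on the readout covariance.
#' @param val_size Held-out validation stimuli (regenerated per epoch from
#'   `seed + 1`).
#' @param seed Seed controlling stimulus draws, loss sampling and
#'   initialization state.
#' @param warm_start Initialize the readout by a noise-aware (ridge-GLS) fit
#'   of the direction targets on the hidden rates over one warm-up batch
#'   (also initializes the normalization statistics). At desk scale the
#'   angular loss cannot bootstrap a random readout, so this is on by
#'   default; set `FALSE` for a fully cold start.
#' @param verbose Print per-epoch losses.
#' @return Object of class `trained_mnn`: `network` (normalization absorbed),
#'   `network_raw`, and `history` (data frame with epoch, train and
#'   validation loss).
#' @export
train_direction_task <- function(net, array, epochs = 20,
                                 samples_per_epoch = 2000, batch_size = 32,
                                 lr = 1e-3, weight_decay = 1e-2,
                                 contrast_range = c(0, 0.8),
                                 mc_samples = 32, jitter = 1e-6,
                                 val_size = 200, seed = 1, warm_start = TRUE,
                                 verbose = FALSE) {
  stopifnot(inherits(net, "mnn_network"),
            net$input_size == 2L * array$n_sites)
  set.seed(seed)
  if (warm_start) {
    n_warm <- max(4L * batch_size, 128L)
    theta <- stats::runif(n_warm, -pi, pi)
    cr <- stats::runif(n_warm, contrast_range[1], contrast_range[2])
    b <- .encode_batch(theta, cr, array)
    fw <- .mnn_fwd(net, b$MU, b$Slist, training = TRUE)
    for (l in seq_along(net$layers))
      if (!is.null(net$layers[[l]]$bn))
        net$layers[[l]]$bn <- fw$caches[[l]]$bnf$state
    rates <- fw$MU_last
    H <- ncol(rates)
    Xc <- scale(rates, scale = FALSE)
    G <- crossprod(Xc) / n_warm
    lam <- 1e-4 * mean(diag(G)) + 1e-12
    Byx <- crossprod(cbind(cos(theta), sin(theta)), Xc) / n_warm
    net$W_out <- Byx %*% solve(G + diag(lam, H))
    if (!is.null(net$b_out))
      net$b_out <- -drop(net$W_out %*% colMeans(rates))
  }
  params <- .net_get_params(net)
  opt <- .adamw_init(params)
  n_batches <- max(1L, floor(samples_per_epoch / batch_size))
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  val_loss <- function(network) {
    set.seed(seed + 1L)
    theta <- stats::runif(val_size, -pi, pi)
    cr <- stats::runif(val_size, contrast_range[1], contrast_range[2])
    tot <- 0
    chunk <- 50L
    for (i0 in seq(1L, val_size, by = chunk)) {
      ii <- i0:min(i0 + chunk - 1L, val_size)
      b <- .encode_batch(theta[ii], cr[ii], array)
      tot <- tot + .direction_batch(network, b$MU, b$Slist, theta[ii],
                                    mc_samples, jitter,
                                    training = FALSE)$loss * length(ii)
    }
    tot / val_size
  }
  for (ep in seq_len(epochs)) {
    set.seed(seed + 1000L + ep)
    tr_loss <- 0
    for (bi in seq_len(n_batches)) {
      theta <- stats::runif(batch_size, -pi, pi)
      cr <- stats::runif(batch_size, contrast_range[1], contrast_range[2])
      b <- .encode_batch(theta, cr, array)
      r <- .direction_batch(net, b$MU, b$Slist, theta, mc_samples, jitter)
      if (!is.finite(r$loss))
        stop(sprintf("training diverged at epoch %d batch %d (loss = %g)",
                     ep, bi, r$loss), call. = FALSE)
      tr_loss <- tr_loss + r$loss / n_batches
      if (lr > 0) {
        r$grads <- .clip_grads(r$grads, 1)
        upd <- .adamw_step(params, r$grads, opt, lr = lr,
                           weight_decay = weight_decay)
        params <- upd$params
        opt <- upd$state
        # running statistics were advanced by the training forward pass
        for (l in seq_along(net$layers))
          if (!is.null(net$layers[[l]]$bn))
            net$layers[[l]]$bn <- r$bn_states[[l]]
        net <- .net_set_params(net, params)
      }
    }
    vl <- val_loss(net)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tr_loss, vl))
  }
  structure(list(network = absorb_batchnorm(net), network_raw = net,
                 history = hist, array = array,
                 config = list(epochs = epochs,
                               samples_per_epoch = samples_per_epoch,
                               batch_size = batch_size, lr = lr,
                               weight_decay = weight_decay,
                               contrast_range = contrast_range,
                               mc_samples = mc_samples, seed = seed)),
            class = "trained_mnn")
}

#' Train a moment-network classifier on feature moments
#'
#' Trains an MNN (or, in `mean_only` mode, a rate network with ReLU
#' activation) on a dataset of per-example channel moments with class labels,
#' using softmax cross-entropy on the readout means as logits. Mode
#' `correlated` uses the full input covariance, `uncorrelated` zeroes its
#' off-diagonal entries, and `mean_only` discards the covariance entirely.
#'
#' @param net An [mnn_network()] (its architecture is reused for the
#'   `mean_only` rate network).
#' @param dataset A [make_feature_moments()] dataset, or any list with
#'   elements `examples` (list of `mu`, `Sigma`, `label`) and `K` classes.
#' @param mode Input-masking mode.
#' @param epochs,batch_size,lr,weight_decay Optimization settings.
#' @param seed Seed for shuffling and initialization state.
#' @param verbose Print per-epoch loss.
#' @return Object of class `trained_classifier` with the trained model,
#'   `mode`, and `history`.
#' @export
train_classifier <- function(net, dataset,
                             mode = c("correlated", "uncorrelated",
                                      "mean_only"),
                             epochs = 30, batch_size = 32, lr = 1e-3,
                             weight_decay = 1e-2, seed = 1,
                             verbose = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  ex <- dataset$examples
  n <- length(ex)
  stopifnot(n >= 2)
  labels <- vapply(ex, `[[`, integer(1), "label")
  MU <- t(vapply(ex, `[[`, numeric(length(ex[[1]]$mu)), "mu"))
  mask_sigma <- function(S) {
    if (mode == "uncorrelated") diag(diag(S)) else S
  }
  for (e in seq_len(n)) .assert_psd(ex[[e]]$Sigma)

  if (mode == "mean_only") {
    model <- .ann_init(net$input_size, net$hidden_sizes, net$output_size)
    opt <- .adamw_init(model)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (i0 in seq(1L, n, by = batch_size)) {
        ii <- ord[i0:min(i0 + batch_size - 1L, n)]
        fw <- .ann_fwd(model, MU[ii, , drop = FALSE])
        ls <- .xent_loss(fw$logits, labels[ii])
        gr <- .ann_bwd(model, fw, ls$dlogits)
        upd <- .adamw_step(model, gr, opt, lr = lr,
                           weight_decay = weight_decay)
        model <- upd$params; opt <- upd$state
        tot <- tot + ls$loss; nb <- nb + 1
      }
      hist[ep] <- tot / nb
      if (verbose) message(sprintf("epoch %3d  xent %.4f", ep, hist[ep]))
    }
    return(structure(list(model = model, mode = mode, history = hist,
                          type = "ann"), class = "trained_classifier"))
  }

  params <- .net_get_params(net)
  opt <- .adamw_init(params)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (i0 in seq(1L, n, by = batch_size)) {
      ii <- ord[i0:min(i0 + batch_size - 1L, n)]
      if (length(ii) < 2L) next
      Slist <- lapply(ex[ii], function(x) mask_sigma(x$Sigma))
      fw <- .mnn_fwd(net, MU[ii, , drop = FALSE], Slist, training = TRUE)
      ls <- .xent_loss(fw$mu_hat, labels[ii])
      gr <- .mnn_bwd(net, fw, ls$dlogits, NULL)
      upd <- .adamw_step(params, gr, opt, lr = lr,
                         weight_decay = weight_decay)
      params <- upd$params; opt <- upd$state
      net <- .net_set_params(net, params)
      for (l in seq_along(net$layers))
        if (!is.null(net$layers[[l]]$bn))
          net$layers[[l]]$bn <- fw$caches[[l]]$bnf$state
      tot <- tot + ls$loss; nb <- nb + 1
    }
    hist[ep] <- tot / nb
    if (verbose) message(sprintf("epoch %3d  xent %.4f", ep, hist[ep]))
  }
  structure(list(model = absorb_batchnorm(net), model_raw = net,
                 mode = mode, history = hist, type = "mnn"),
            class = "trained_classifier")
}

#' Classification accuracy of a trained classifier
#'
#' @param clf A `trained_classifier` from [train_classifier()].
#' @param dataset Dataset in the same format used for training.
#' @return Fraction of correctly classified examples.
#' @export
classifier_accuracy <- function(clf, dataset) {
  ex <- dataset$examples
  labels <- vapply(ex, `[[`, integer(1), "label")
  MU <- t(vapply(ex, `[[`, numeric(length(ex[[1]]$mu)), "mu"))
  if (clf$type == "ann") {
    logits <- .ann_fwd(clf$model, MU)$logits
  } else {
    mask <- clf$mode == "uncorrelated"
    logits <- t(vapply(seq_along(ex), function(e) {
      S <- ex[[e]]$Sigma
      if (mask) S <- diag(diag(S))
      mnn_forward(clf$model, list(mu = ex[[e]]$mu, Sigma = S))$mu_hat
    }, numeric(length(clf$model$W_out[, 1]))))
  }
  mean(max.col(logits, ties.method = "first") == labels)
}

# minimal ReLU rate network used as the mean-only reference model
.ann_init <- function(input_size, hidden_sizes, output_size) {
  sizes <- c(input_size, hidden_sizes, output_size)
  lapply(seq_len(length(sizes) - 1L), function(l)
    list(W = matrix(stats::rnorm(sizes[l + 1] * sizes[l],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l + 1], sizes[l]),
         b = numeric(sizes[l + 1])))
}

.ann_fwd <- function(model, X) {
  acts <- list(X)
  n <- length(model)
  for (l in seq_len(n)) {
    Z <- acts[[l]] %*% t(model[[l]]$W)
    Z <- sweep(Z, 2L, model[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < n) pmax(Z, 0) else Z
  }
  list(logits = acts[[n + 1]], acts = acts)
}

.ann_bwd <- function(model, fw, dlogits) {
  n <- length(model)
  grads <- vector("list", n)
  dZ <- dlogits
  for (l in rev(seq_len(n))) {
    grads[[l]] <- list(W = t(dZ) %*% fw$acts[[l]], b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% model[[l]]$W
      dZ <- dA * (fw$acts[[l]] > 0)
    }
  }
  grads
}
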