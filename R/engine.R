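# Internal batched forward/backward engine used for training. All gradients
# are analytic: the moment activation contributes its closed-form partials
# (including the second derivative of the rate map that backs the correlation
# gain), normalization is differentiated through its batch statistics, and
# the loss supplies gradients w.r.t. the readout mean and covariance. The
# correlation PSD repair is not applied inside the engine: the linear
# perturbation map stays PSD for the weakly correlated currents encountered
# in training, and the loss jitters the 2x2 readout covariance before
# factorization.

# forward pass over a batch, keeping the caches needed by .mnn_bwd.
# MU: B x n_in matrix; Slist: list of B input covariance matrices.
.mnn_fwd <- function(net, MU, Slist, training = TRUE) {
  B <- nrow(MU)
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    m1 <- MU %*% t(lay$W)
    m1 <- sweep(m1, 2L, lay$mu_ext, `+`)
    S1 <- lapply(Slist, function(S) {
      A <- lay$W %*% S %*% t(lay$W)
      (A + t(A)) / 2
    })
    if (!is.null(lay$bn)) {
      bnf <- .bn_forward(m1, S1, lay$bn, training = training)
      m2 <- bnf$m2; S2 <- bnf$S2
    } else {
      bnf <- NULL
      m2 <- m1; S2 <- S1
    }
    H <- ncol(m2)
    sbar <- sqrt(pmax(t(vapply(S2, diag, numeric(H))), 0))  # B x H
    r <- .ma_core(as.vector(m2), as.vector(sbar), net$params)
    r <- lapply(r, matrix, nrow = B)
    SP <- vector("list", B)
    for (e in seq_len(B)) {
      kk <- tcrossprod(r$k[e, ])
      Sp <- kk * S2[[e]]
      diag(Sp) <- r$sigma[e, ]^2
      SP[[e]] <- Sp
    }
    caches[[l]] <- list(MU_in = MU, S_in = Slist, m1 = m1, S1 = S1,
                        bnf = bnf, S2 = S2, sbar = sbar, act = r)
    MU <- r$mu
    Slist <- SP
  }
  mu_hat <- MU %*% t(net$W_out)
  if (!is.null(net$b_out)) mu_hat <- sweep(mu_hat, 2L, net$b_out, `+`)
  Sig_hat <- lapply(Slist, function(S) {
    A <- net$W_out %*% S %*% t(net$W_out)
    (A + t(A)) / 2
  })
  list(mu_hat = mu_hat, Sig_hat = Sig_hat, MU_last = MU, S_last = Slist,
       caches = caches)
}

# backward pass. dmu_hat: B x K; dSig_hat: list of symmetric K x K (or NULL
# for a mean-only loss). Returns parameter gradients mirroring the trainable
# parameter structure.
.mnn_bwd <- function(net, fw, dmu_hat, dSig_hat = NULL) {
  B <- nrow(dmu_hat)
  K <- ncol(dmu_hat)
  zeroS <- is.null(dSig_hat)
  dW_out <- matrix(0, K, ncol(net$W_out))
  dMU <- dmu_hat %*% net$W_out
  dSl <- vector("list", B)
  if (!zeroS) {
    for (e in seq_len(B)) {
      G <- dSig_hat[[e]]
      dW_out <- dW_out + 2 * G %*% net$W_out %*% fw$S_last[[e]]
      dSl[[e]] <- t(net$W_out) %*% G %*% net$W_out
    }
  }
  dW_out <- dW_out + t(dmu_hat) %*% fw$MU_last
  db_out <- if (is.null(net$b_out)) NULL else colSums(dmu_hat)

  grads <- list(layers = vector("list", length(net$layers)),
                W_out = dW_out, b_out = db_out)

  for (l in rev(seq_along(net$layers))) {
    ca <- fw$caches[[l]]
    lay <- net$layers[[l]]
    r <- ca$act
    H <- ncol(r$mu)
    dm2 <- matrix(0, B, H)
    dsb <- matrix(0, B, H)
    dS2 <- vector("list", B)
    for (e in seq_len(B)) {
      k <- r$k[e, ]
      if (is.null(dSl[[e]])) {
        M <- matrix(0, H, H)
        dk <- numeric(H)
        dsig <- numeric(H)
      } else {
        G <- dSl[[e]]
        M <- G
        diag(M) <- 0
        dk <- 2 * drop((M * ca$S2[[e]]) %*% k)
        dsig <- 2 * r$sigma[e, ] * diag(G)
      }
      dmu_p <- dMU[e, ]
      dm2[e, ] <- dmu_p * r$k[e, ] + dsig * r$dsig_dm[e, ] +
        dk * r$dk_dm[e, ]
      dsb[e, ] <- dmu_p * r$dmu_ds[e, ] + dsig * r$dsig_ds[e, ] +
        dk * r$dk_ds[e, ]
      D2 <- M * tcrossprod(k)
      sb <- ca$sbar[e, ]
      dd <- ifelse(sb > 0, dsb[e, ] / (2 * sb), 0)
      diag(D2) <- dd
      dS2[[e]] <- D2
    }
    if (!is.null(lay$bn)) {
      bb <- .bn_backward(dm2, dS2, lay$bn, ca$bnf$cache)
      dm1 <- bb$dm1; dS1 <- bb$dS
      dgamma <- bb$dgamma; dbeta <- bb$dbeta
    } else {
      dm1 <- dm2; dS1 <- dS2
      dgamma <- dbeta <- NULL
    }
    dW <- t(dm1) %*% ca$MU_in
    dMU_in <- dm1 %*% lay$W
    dSl_in <- vector("list", B)
    for (e in seq_len(B)) {
      dW <- dW + 2 * dS1[[e]] %*% lay$W %*% ca$S_in[[e]]
      if (l > 1L)
        dSl_in[[e]] <- t(lay$W) %*% dS1[[e]] %*% lay$W
    }
    grads$layers[[l]] <- list(W = dW, mu_ext = colSums(dm1),
                              gamma = dgamma, beta = dbeta)
    dMU <- dMU_in
    dSl <- dSl_in
  }
  grads
}
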