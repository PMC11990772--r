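#' Fit the expression decoder
#'
#' Trains a two-layer perceptron, symmetric to the encoder
#' (`h -> 2h -> m` with a PReLU between the layers), that maps the frozen
#' integration embeddings back to the normalized expression space by
#' minimizing the mean squared reconstruction error summed over slices.
#' The embeddings are inputs, not trainable.
#'
#' @param Z_all list of per-slice n x h embedding matrices (or one matrix).
#' @param X_all list of matching n x m normalized expression matrices.
#' @param epochs Adam epochs (default 500).
#' @param lr learning rate.
#' @param seed integer seed for the weight initialization.
#' @param verbose print the loss every 100 epochs.
#' @return `decoder_params`: `W1`, `b1`, `a`, `W2`, `b2`, plus the per-epoch
#'   `loss` trace.
#' @export
fit_decoder <- function(Z_all, X_all, epochs = 500, lr = 1e-3, seed = 0,
                        verbose = FALSE) {
  if (is.matrix(Z_all)) Z_all <- list(Z_all)
  if (is.matrix(X_all)) X_all <- list(X_all)
  stopifnot(length(Z_all) == length(X_all))
  for (t in seq_along(Z_all)) {
    if (nrow(Z_all[[t]]) != nrow(X_all[[t]]))
      stop("shape error: slice ", t, " embeddings and expression disagree")
  }
  h <- ncol(Z_all[[1]])
  m <- ncol(X_all[[1]])
  set.seed(seed)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  params <- list(W1 = glorot(h, 2 * h), b1 = rep(0, 2 * h), a = 0.25,
                 W2 = glorot(2 * h, m), b2 = rep(0, m))
  opt <- adam_init(params, lr = lr)
  ntot <- sum(vapply(Z_all, nrow, integer(1)))
  trace <- numeric(max(epochs, 1))

  eval_loss <- function(params) {
    tot <- 0
    for (t in seq_along(Z_all)) {
      R <- decoder_forward(Z_all[[t]], params)$Xhat - X_all[[t]]
      tot <- tot + sum(R^2)
    }
    tot / (ntot * m)
  }

  if (epochs == 0) {
    params$loss <- eval_loss(params)
    class(params) <- "decoder_params"
    return(params)
  }
  for (ep in seq_len(epochs)) {
    grads <- zero_grads(params)
    tot <- 0
    for (t in seq_along(Z_all)) {
      fw <- decoder_forward(Z_all[[t]], params)
      R <- fw$Xhat - X_all[[t]]
      tot <- tot + sum(R^2)
      dX <- (2 / (ntot * m)) * R
      grads <- add_grads(grads, decoder_backward(dX, fw, params))
    }
    trace[ep] <- tot / (ntot * m)
    st <- adam_step(opt, params, grads)
    opt <- st$opt
    params <- st$params
    if (verbose && ep %% 100 == 0)
      message("decoder epoch ", ep, " mse ", signif(trace[ep], 5))
  }
  params$loss <- eval_loss(params)
  params$trace <- trace
  class(params) <- "decoder_params"
  params
}

decoder_forward <- function(Z, params) {
  H1 <- sweep(Z %*% params$W1, 2, params$b1, "+")
  A1 <- prelu(H1, params$a)
  Xhat <- sweep(A1 %*% params$W2, 2, params$b2, "+")
  list(Xhat = Xhat, H1 = H1, A1 = A1, Z = Z)
}

decoder_backward <- function(dX, cache, params) {
  dW2 <- crossprod(cache$A1, dX)
  db2 <- colSums(dX)
  dA1 <- dX %*% t(params$W2)
  neg <- cache$H1 < 0
  dH1 <- dA1 + (params$a - 1) * (dA1 * neg)
  da <- sum(dA1 * cache$H1 * neg)
  dW1 <- crossprod(cache$Z, dH1)
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, a = da, W2 = dW2, b2 = db2)
}

#' Denoise expression from embeddings
#'
#' Applies the fitted decoder to an embedding matrix, producing a denoised
#' expression matrix in the normalized (log) space. Deterministic given the
#' parameters.
#'
#' @param Z n x h embedding matrix.
#' @param params fitted `decoder_params`.
#' @return n x m denoised expression matrix.
#' @export
denoise <- function(Z, params) {
  stopifnot(inherits(params, "decoder_params"))
  if (ncol(Z) != nrow(params$W1))
    stop("shape error: embedding dimension does not match the decoder")
  decoder_forward(as.matrix(Z), params)$Xhat
}
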