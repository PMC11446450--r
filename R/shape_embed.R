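#' Configuration for the shape-constrained autoencoder
#'
#' The adversarial embedder trains a small multilayer-perceptron autoencoder
#' whose 2D bottleneck codes are pulled onto a target contour. The loss is
#' `mean squared reconstruction error + shape_weight * squared symmetric
#' Chamfer distance` between the mini-batch codes and the shape's points. The
#' Chamfer term both attracts codes to the contour and forces each batch to
#' cover the whole contour, so the trained embedding fills the shape.
#'
#' @param hidden_widths Encoder hidden-layer widths (mirrored in the decoder).
#' @param shape_weight Positive weight of the Chamfer term.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size (must not exceed the number of cells).
#' @param seed Integer seed; fixes initialisation and batch shuffling.
#' @return A list of class `shape_embed_config`.
#' @export
shape_embed_config <- function(hidden_widths = c(128, 32), shape_weight = 10,
                               epochs = 150, learning_rate = 1e-3,
                               batch_size = 256, seed = 0L) {
  cfg <- list(hidden_widths = as.integer(hidden_widths),
              shape_weight = shape_weight, epochs = as.integer(epochs),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (any(cfg$hidden_widths < 1)) abort("hidden_widths must be positive")
  if (cfg$shape_weight <= 0) abort("shape_weight must be > 0")
  if (cfg$epochs < 1) abort("epochs must be >= 1")
  if (cfg$learning_rate <= 0) abort("learning_rate must be > 0")
  if (cfg$batch_size < 1) abort("batch_size must be >= 1")
  structure(cfg, class = "shape_embed_config")
}

#' Fit a shape-constrained adversarial 2D embedding
#'
#' Trains an autoencoder (features -> 2D code -> features, tanh hidden layers,
#' linear code and output layers, Adam optimiser) whose codes are forced onto
#' an arbitrary predefined contour. This is the purposefully adversarial
#' baseline of the benchmark: it can render any dataset as, say, an elephant
#' outline while retaining only as much data structure as the reconstruction
#' term salvages.
#'
#' If after training the mean distance from codes to their nearest shape point
#' exceeds 5% of the shape diameter (for a degenerate single-point shape, 5%
#' of the RMS norm of the standardised data), a warning is recorded on the
#' result rather than raising an error.
#'
#' @param x An `expression_matrix` or numeric matrix (cells in rows).
#' @param shape A [make_shape()] `shape_spec`.
#' @param config A [shape_embed_config()].
#' @return An `embedding2d` (method `"shape"`) with attributes
#'   `training_log` (tibble: epoch, recon, chamfer), `shape_distance`
#'   (mean nearest-shape-point distance of the final codes), and `converged`.
#' @export
fit_shape_embedding <- function(x, shape, config = shape_embed_config()) {
  stopifnot(inherits(shape, "shape_spec"),
            inherits(config, "shape_embed_config"))
  inp <- embed_input(x)
  X <- inp$m
  n <- nrow(X)
  if (n < config$batch_size) {
    abort(sprintf("batch_size (%d) exceeds number of cells (%d)",
                  config$batch_size, n))
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  S <- shape$points
  d_in <- ncol(Xs)
  sizes <- c(d_in, config$hidden_widths, 2L,
             rev(config$hidden_widths), d_in)
  n_layers <- length(sizes) - 1L
  code_layer <- length(config$hidden_widths) + 1L
  # tanh on hidden layers; linear at the 2D code and at the output
  is_linear <- seq_len(n_layers) %in% c(code_layer, n_layers)

  fit <- with_seed(config$seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      a <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -a, a),
                       nrow = sizes[l])
      b[[l]] <- numeric(sizes[l + 1])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    log_epoch <- numeric(config$epochs)
    log_recon <- numeric(config$epochs)
    log_chamfer <- numeric(config$epochs)

    forward <- function(Xb) {
      A <- vector("list", n_layers + 1L)
      A[[1]] <- Xb
      for (l in seq_len(n_layers)) {
        z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (is_linear[l]) z else tanh(z)
      }
      A
    }

    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      n_batches <- floor(n / config$batch_size)
      ep_recon <- 0; ep_chamfer <- 0
      for (bi in seq_len(n_batches)) {
        rows <- perm[((bi - 1L) * config$batch_size + 1L):(bi * config$batch_size)]
        Xb <- Xs[rows, , drop = FALSE]
        B <- nrow(Xb)
        A <- forward(Xb)
        codes <- A[[code_layer + 1L]]
        Xhat <- A[[n_layers + 1L]]

        R <- Xhat - Xb
        recon <- mean(R^2)
        dXhat <- 2 * R / length(R)

        # squared symmetric Chamfer between codes and shape points
        D2 <- outer(rowSums(codes^2), rowSums(S^2), "+") -
          2 * codes %*% t(S)
        D2[D2 < 0] <- 0
        jstar <- max.col(-D2, ties.method = "first")
        istar <- apply(D2, 2, which.min)
        chamfer <- mean(D2[cbind(seq_len(B), jstar)]) +
          mean(D2[cbind(istar, seq_len(nrow(S)))])
        Gc <- 2 * (codes - S[jstar, , drop = FALSE]) / B
        add <- 2 * (codes[istar, , drop = FALSE] - S) / nrow(S)
        for (j in seq_len(nrow(S))) {
          Gc[istar[j], ] <- Gc[istar[j], ] + add[j, ]
        }
        Gc <- config$shape_weight * Gc

        # backprop, injecting the Chamfer gradient at the code activations
        step <- step + 1L
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        dA <- dXhat
        for (l in rev(seq_len(n_layers))) {
          delta <- if (is_linear[l]) dA else dA * (1 - A[[l + 1L]]^2)
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          dA <- delta %*% t(W[[l]])
          if (l - 1L == code_layer) dA <- dA + Gc
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          W[[l]] <- W[[l]] - config$learning_rate *
            (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          b[[l]] <- b[[l]] - config$learning_rate *
            (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
        ep_recon <- ep_recon + recon
        ep_chamfer <- ep_chamfer + chamfer
      }
      log_epoch[ep] <- ep
      log_recon[ep] <- ep_recon / n_batches
      log_chamfer[ep] <- ep_chamfer / n_batches
    }
    list(W = W, b = b, forward = forward,
         log = tibble(epoch = log_epoch, recon = log_recon,
                      chamfer = log_chamfer))
  })

  codes <- fit$forward(Xs)[[code_layer + 1L]]
  D2 <- outer(rowSums(codes^2), rowSums(S^2), "+") - 2 * codes %*% t(S)
  D2[D2 < 0] <- 0
  mean_dist <- mean(sqrt(apply(D2, 1, min)))
  scale <- if (shape$diameter > 0) shape$diameter else
    sqrt(mean(rowSums(Xs^2)))
  converged <- mean_dist <= 0.05 * scale
  if (!converged) {
    warn(sprintf(
      "shape embedding did not converge: mean nearest-shape distance %.4g > 5%% of scale %.4g",
      mean_dist, scale
    ))
  }
  out <- new_embedding(codes, inp$ids, "shape", seed = config$seed,
                       source_fingerprint = inp$fp)
  attr(out, "training_log") <- fit$log
  attr(out, "shape_distance") <- mean_dist
  attr(out, "shape_name") <- shape$name
  attr(out, "converged") <- converged
  out
}
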