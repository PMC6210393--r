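#' Hyper-parameters for adversarial edge-weight learning
#'
#' Defaults follow the published training recipe: 2 epochs, batch size 1,
#' learning rate 2e-4 with Adam, a 256-unit discriminator hidden layer. The
#' epoch count is deliberately small for pipeline runs; convergence studies
#' use an extended `epochs`.
#'
#' @param epochs passes over the cohort samples.
#' @param batch_size real samples (and matched noise vectors) per update.
#' @param learning_rate Adam step size for both networks.
#' @param hidden_units discriminator hidden layer width.
#' @param beta1,beta2 Adam moment decay rates.
#' @param init_range generator weights are initialized uniformly on
#'   (0, `init_range`) over the adjacency support; values below 1 make the
#'   symmetrized product shrink towards zero, an implicit L2-like
#'   regularization that helps convergence in the many-genes/few-samples
#'   regime.
#' @param generator_activation `"relu"` (the published form) or
#'   `"identity"` (escape hatch for signed data).
#' @param seed integer seed controlling initialization, sample shuffling and
#'   noise draws.
#' @return object of class `gan_config`.
#' @export
gan_config <- function(epochs = 2L, batch_size = 1L, learning_rate = 2e-4,
                       hidden_units = 256L, beta1 = 0.9, beta2 = 0.999,
                       init_range = 0.1,
                       generator_activation = c("relu", "identity"),
                       seed = 1L) {
  generator_activation <- match.arg(generator_activation)
  cfg <- list(epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              hidden_units = as.integer(hidden_units),
              beta1 = beta1, beta2 = beta2,
              init_range = as.numeric(init_range),
              generator_activation = generator_activation,
              seed = as.integer(seed))
  if (cfg$epochs < 1L || cfg$batch_size < 1L || cfg$hidden_units < 1L)
    stop_config("gan_config: epochs, batch_size and hidden_units must be positive")
  if (cfg$learning_rate <= 0 || cfg$init_range <= 0)
    stop_config("gan_config: learning_rate and init_range must be positive")
  class(cfg) <- "gan_config"
  cfg
}

#' Generator forward pass
#'
#' The generator has no hidden layer and no bias: its only parameters are
#' edge weights, masked by the network adjacency and symmetrized, so
#' `output = act(Z (A \* w \* w^T))` where `*` is the elementwise product
#' and `act` is a rectifier by default.
#'
#' @param w n x n trainable weight matrix.
#' @param A n x n symmetric 0/1 adjacency (zero diagonal).
#' @param Z batch x n noise matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return batch x n output matrix.
#' @export
generator_forward <- function(w, A, Z, activation = "relu") {
  if (!is.matrix(Z) || ncol(Z) != nrow(A))
    stop_validation("noise batch must be batch x n with n = nrow(A)")
  if (!all(dim(w) == dim(A)))
    stop_validation("w and A dimensions differ")
  H <- Z %*% effective_weights(w, A)
  if (activation == "relu") H[H < 0] <- 0
  H
}

# symmetric masked effective weights A * w * t(w)
effective_weights <- function(w, A) A * w * t(w)

#' Extract final nonnegative edge weights
#'
#' Returns the elementwise absolute value of the effective generator weights
#' `A * w * w^T` (negative learned weights are converted to positive once,
#' after training; downstream PageRank uses magnitudes only, so converting
#' per-step or once at the end yields identical scores).
#'
#' @param gan a `trained_gan` (from [train_gan()]), or a raw `w` matrix if
#'   `A` is supplied.
#' @param A adjacency matrix, required when `gan` is a plain matrix.
#' @return symmetric nonnegative n x n weight matrix with support inside A.
#' @export
extract_weights <- function(gan, A = NULL) {
  if (inherits(gan, "trained_gan")) return(abs(effective_weights(gan$w, gan$A)))
  if (is.null(A)) stop_validation("A required when gan is a weight matrix")
  abs(effective_weights(gan, A))
}

#' Learn network edge weights adversarially
#'
#' Trains a generative adversarial pair on per-sample omics vectors: the
#' generator maps standard-normal noise through the adjacency-masked
#' symmetric weight matrix (see [generator_forward()]); the discriminator is
#' a dense net (n -> `hidden_units` -> 1, rectifier then sigmoid) estimating
#' the probability its input is a real patient vector. Updates alternate one
#' discriminator and one generator Adam step per batch on the standard
#' adversarial objective (non-saturating generator loss); each epoch is one
#' seeded shuffle pass over the cohort samples. After training, edge weights
#' are finalized as absolute effective weights.
#'
#' @param real samples x n matrix of real vectors (columns ordered like the
#'   network nodes), e.g. from [build_real_vectors()].
#' @param A symmetric 0/1 adjacency of the reconstructed network.
#' @param cfg a [gan_config()].
#' @return object of class `trained_gan`: list with `weights` (symmetric
#'   nonnegative matrix, support inside `A`), `w`, `A`, `history` (per-epoch
#'   mean losses and mean discriminator outputs), `eval` (post-training mean
#'   discriminator output on all real samples, on an equal number of fresh
#'   generated samples, and their average) and `config`.
#' @export
train_gan <- function(real, A, cfg = gan_config()) {
  if (!inherits(cfg, "gan_config")) stop_config("cfg must be a gan_config")
  if (!is.matrix(real) || nrow(real) < 2L)
    stop_validation("real must be a matrix with at least 2 samples")
  n <- ncol(real)
  if (!all(dim(A) == c(n, n)))
    stop_validation("A must be n x n with n = ncol(real)")
  h <- cfg$hidden_units
  lr <- cfg$learning_rate
  relu_gen <- cfg$generator_activation == "relu"

  set.seed(cfg$seed)
  w <- matrix(0, n, n)
  sup <- A != 0
  w[sup] <- runif(sum(sup), 0, cfg$init_range)
  # discriminator: He-scaled init, zero biases
  W1 <- matrix(rnorm(n * h, sd = sqrt(2 / n)), n, h)
  b1 <- numeric(h)
  W2 <- matrix(rnorm(h, sd = sqrt(2 / h)), h, 1)
  b2 <- 0

  adam <- function(p) list(m = p * 0, v = p * 0, t = 0L)
  st <- list(w = adam(w), W1 = adam(W1), b1 = adam(b1),
             W2 = adam(W2), b2 = adam(b2))
  step <- function(p, g, s) {
    s$t <- s$t + 1L
    s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
    s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g * g
    mh <- s$m / (1 - cfg$beta1^s$t)
    vh <- s$v / (1 - cfg$beta2^s$t)
    list(p = p - lr * mh / (sqrt(vh) + 1e-8), s = s)
  }
  d_forward <- function(x) {
    a1 <- sweep(x %*% W1, 2, b1, "+")
    h1 <- a1; h1[h1 < 0] <- 0
    a2 <- h1 %*% W2 + b2
    list(a1 = a1, h1 = h1, o = 1 / (1 + exp(-a2)))
  }

  n_s <- nrow(real)
  hist <- data.frame(epoch = seq_len(cfg$epochs), d_loss = NA_real_,
                     g_loss = NA_real_, d_real = NA_real_,
                     d_fake = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_s)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    dl <- gl <- dr <- dfk <- 0
    for (idx in batches) {
      k <- length(idx)
      x <- real[idx, , drop = FALSE]
      W_eff <- A * w * t(w)

      ## --- discriminator step ---
      Z <- matrix(rnorm(k * n), k, n)
      Hg <- Z %*% W_eff
      fake <- Hg; if (relu_gen) fake[fake < 0] <- 0
      fr <- d_forward(x)
      ff <- d_forward(fake)
      d_loss <- -(mean(log(fr$o + 1e-12)) + mean(log(1 - ff$o + 1e-12)))
      d2r <- (fr$o - 1) / k
      d2f <- ff$o / k
      gW2 <- t(fr$h1) %*% d2r + t(ff$h1) %*% d2f
      gb2 <- sum(d2r) + sum(d2f)
      da1r <- (d2r %*% t(W2)) * (fr$a1 > 0)
      da1f <- (d2f %*% t(W2)) * (ff$a1 > 0)
      gW1 <- t(x) %*% da1r + t(fake) %*% da1f
      gb1 <- colSums(da1r) + colSums(da1f)
      u <- step(W1, gW1, st$W1); W1 <- u$p; st$W1 <- u$s
      u <- step(b1, gb1, st$b1); b1 <- u$p; st$b1 <- u$s
      u <- step(W2, gW2, st$W2); W2 <- u$p; st$W2 <- u$s
      u <- step(b2, gb2, st$b2); b2 <- u$p; st$b2 <- u$s

      ## --- generator step (fresh noise, non-saturating loss) ---
      Z <- matrix(rnorm(k * n), k, n)
      Hg <- Z %*% W_eff
      fake <- Hg; if (relu_gen) fake[fake < 0] <- 0
      fg <- d_forward(fake)
      g_loss <- -mean(log(fg$o + 1e-12))
      d2 <- (fg$o - 1) / k
      da1 <- (d2 %*% t(W2)) * (fg$a1 > 0)
      dfake <- da1 %*% t(W1)
      dH <- if (relu_gen) dfake * (Hg > 0) else dfake
      dW <- crossprod(Z, dH)              # d loss / d W_eff
      # W_eff[k,l] = A[k,l] w[k,l] w[l,k], so dL/dw[i,j] =
      #   A[i,j] w[j,i] (dW[i,j] + dW[j,i])
      gw <- A * t(w) * (dW + t(dW))
      u <- step(w, gw, st$w); w <- u$p; st$w <- u$s

      if (!is.finite(d_loss) || !is.finite(g_loss))
        stop("adversarial training diverged (non-finite loss) at epoch ",
             ep, "; loss trace so far:\n",
             paste(utils::capture.output(print(head(hist, ep))), collapse = "\n"))
      dl <- dl + d_loss * k; gl <- gl + g_loss * k
      dr <- dr + sum(fr$o); dfk <- dfk + sum(ff$o)
    }
    hist[ep, -1] <- c(dl / n_s, gl / n_s, dr / n_s, dfk / n_s)
  }

  # post-training evaluation: D on all real samples and matched fresh fakes
  W_eff <- A * w * t(w)
  Zf <- matrix(rnorm(n_s * n), n_s, n)
  Hf <- Zf %*% W_eff; if (relu_gen) Hf[Hf < 0] <- 0
  d_real <- mean(d_forward(real)$o)
  d_fake <- mean(d_forward(Hf)$o)
  structure(list(weights = abs(W_eff), w = w, A = A, history = hist,
                 eval = c(d_real = d_real, d_fake = d_fake,
                          d_combined = (d_real + d_fake) / 2),
                 config = cfg),
            class = "trained_gan")
}

#' @export
print.trained_gan <- function(x, ...) {
  cat(sprintf("Adversarially learned network weights: %d genes, %d weighted edges\n",
              nrow(x$A), sum(x$A[upper.tri(x$A)] != 0)))
  cat(sprintf("  %d epochs; final D(real)=%.3f D(fake)=%.3f (combined %.3f)\n",
              x$config$epochs, x$eval["d_real"], x$eval["d_fake"],
              x$eval["d_combined"]))
  invisible(x)
}
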