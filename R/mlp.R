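#' MLP architecture settings
#'
#' The patch scorer is a three-layer perceptron: 168 input nodes, 64 hidden
#' nodes and 2 output nodes, with a leaky ReLU activation and dropout after
#' the hidden layer (rate 0.2).
#'
#' @param input,hidden,output Layer widths.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param dropout Dropout rate applied to the hidden activations while
#'   training.
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(input = 168L, hidden = 64L, output = 2L,
                     leaky_slope = 0.01, dropout = 0.2) {
  stopifnot(input >= 1, hidden >= 1, output == 2L,
            dropout >= 0, dropout < 1)
  structure(list(input = as.integer(input), hidden = as.integer(hidden),
                 output = as.integer(output), leaky_slope = leaky_slope,
                 dropout = dropout),
            class = "mlp_spec")
}

#' Training configuration for iterative draw-and-rank sampling
#'
#' Defaults follow the published protocol: per slide and epoch the training
#' pool is the `k = 5` patches currently ranked highest for the slide's own
#' label plus `r = 45` patches drawn uniformly at random, optimised in
#' minibatches of 256 with Adam under a symmetric cross-entropy loss.
#' Epoch count and learning rate are configuration choices (see the methods
#' vignette).
#'
#' @param k Top-ranked patch draw count per slide and epoch.
#' @param r Random patch draw count per slide and epoch.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param sce_alpha,sce_beta Weights of the cross-entropy and reverse
#'   cross-entropy terms.
#' @param log_clamp Finite stand-in for `log(0)` in the reverse term.
#' @param weight_decay Decoupled L2 weight decay applied to the weight
#'   matrices each optimiser step (regularises noise-feature fitting on
#'   small cohorts).
#' @param seed Integer seed fixing sampling, initialisation and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(k = 5L, r = 45L, batch_size = 256L, lr = 1e-3,
                         epochs = 30L, sce_alpha = 1, sce_beta = 1,
                         log_clamp = -4, weight_decay = 0, seed = 1L) {
  stopifnot(k >= 0, r >= 0, k + r >= 1, batch_size >= 1, epochs >= 1,
            sce_alpha >= 0, sce_beta >= 0, log_clamp < 0, weight_decay >= 0)
  structure(list(k = as.integer(k), r = as.integer(r),
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), sce_alpha = sce_alpha,
                 sce_beta = sce_beta, log_clamp = log_clamp,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Symmetric cross-entropy loss
#'
#' `loss = alpha * CE + beta * RCE` where `CE = -log p_y` and the reverse
#' term swaps predictions and the one-hot label: `RCE = -sum_c p_c log q_c`
#' with `log 0` replaced by the finite `log_clamp`, giving
#' `RCE = -log_clamp * (1 - p_y) >= 0`. With `beta = 0` the loss reduces
#' exactly to cross-entropy.
#'
#' @param p Length-2 probability vector (or n x 2 matrix) over
#'   (negative, positive).
#' @param y Label(s) in `{0, 1}`.
#' @param alpha,beta Non-negative term weights.
#' @param log_clamp Finite stand-in for `log(0)` (default -4).
#' @return Non-negative loss value(s).
#' @export
sce_loss <- function(p, y, alpha = 1, beta = 1, log_clamp = -4) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) == 2, all(y %in% c(0, 1)), alpha >= 0, beta >= 0)
  assert_that(all(abs(rowSums(p) - 1) < 1e-6),
              "probabilities must lie on the simplex",
              class = "odynr_validation_error")
  py <- p[cbind(seq_len(nrow(p)), y + 1L)]
  ce <- -log(pmax(py, 1e-300))
  rce <- -log_clamp * (1 - py)
  unname(alpha * ce + beta * rce)
}

leaky_relu <- function(h, slope) ifelse(h > 0, h, slope * h)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(spec, seed) {
  with_seed(seed, {
    list(
      W1 = matrix(rnorm(spec$input * spec$hidden, sd = sqrt(2 / spec$input)),
                  spec$input, spec$hidden),
      b1 = numeric(spec$hidden),
      W2 = matrix(rnorm(spec$hidden * spec$output, sd = sqrt(2 / spec$hidden)),
                  spec$hidden, spec$output),
      b2 = numeric(spec$output)
    )
  })
}

mlp_forward <- function(params, X, spec, dropout_mask = NULL) {
  H <- sweep(X %*% params$W1, 2, params$b1, "+")
  A <- leaky_relu(H, spec$leaky_slope)
  if (!is.null(dropout_mask)) A <- A * dropout_mask / (1 - spec$dropout)
  Z <- sweep(A %*% params$W2, 2, params$b2, "+")
  list(H = H, A = A, Z = Z, P = softmax_rows(Z))
}

# Gradient of the SCE loss w.r.t. the logits, averaged over the batch.
sce_logit_grad <- function(P, y, alpha, beta, log_clamp) {
  n <- nrow(P)
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  g_ce <- P - onehot
  # RCE: dL/dp = log_clamp * e_y; through softmax:
  # dL/dz_c = p_c * (g_c - sum_k p_k g_k), g = log_clamp * e_y
  py <- P[cbind(seq_len(n), y + 1L)]
  g <- log_clamp * onehot
  g_rce <- P * (g - py * log_clamp)
  (alpha * g_ce + beta * g_rce) / n
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nm %in% c("W1", "W2")) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, state = state)
}

mlp_backward <- function(params, cache, X, dZ, spec, dropout_mask = NULL) {
  dW2 <- t(cache$A) %*% dZ
  db2 <- colSums(dZ)
  dA <- dZ %*% t(params$W2)
  if (!is.null(dropout_mask)) dA <- dA * dropout_mask / (1 - spec$dropout)
  dH <- dA * ifelse(cache$H > 0, 1, spec$leaky_slope)
  list(W1 = t(X) %*% dH, b1 = colSums(dH), W2 = dW2, b2 = db2)
}

# Standardisation of the feature matrix, fitted on the training pool and
# stored with the model (zero-variance columns pass through unscaled).
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = mu, sd = s)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Patch-level prediction scores
#'
#' Runs the trained MLP (dropout disabled) and returns the softmax
#' probability of the positive (transformation) class per patch.
#'
#' @param model A trained model from [idars_train()].
#' @param features Numeric matrix of patch features (columns must match the
#'   model's input width) or a feature tibble from [extract_features()].
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
predict_patches <- function(model, features) {
  X <- if (is.matrix(features)) features else features_matrix(features)$X
  assert_that(ncol(X) == model$spec$input,
              sprintf("feature length %d does not match model input %d",
                      ncol(X), model$spec$input),
              class = "odynr_validation_error")
  Xs <- apply_scaler(X, model$scaler)
  fw <- mlp_forward(model$params, Xs, model$spec)
  as.numeric(fw$P[, 2])
}

# Split a feature tibble into matrix + slide ids.
features_matrix <- function(features) {
  meta <- intersect(c("slide_id", "patch_id", "x", "y", "n_nuclei",
                      "dysplastic_fraction"), names(features))
  X <- as.matrix(features[, setdiff(names(features), meta)])
  list(X = X, slide_id = features$slide_id)
}
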