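## ---------------------------------------------------------------------------
## Two-stage predictor: 2-layer GCN encoder + 3-layer feed-forward pair
## decoder with sigmoid output, plus the two no-graph baselines.
##
## The encoder follows the symmetric-normalised convolution
##   H^(l+1) = ReLU( D^-1/2 (A+I) D^-1/2  H^(l)  W^(l) + b^(l) )
## over the union of all unmasked edge types treated homogeneously, with
## hidden widths 256 and 64 and dropout 0.3 on each layer during training.
## The decoder takes the concatenated (variant, disease) embedding pair
## (2 x 64 = 128 wide), two ReLU hidden layers of 64 and 32 neurons with
## dropout on hidden layers only, and a sigmoid output neuron.
## ---------------------------------------------------------------------------

#' Symmetric-normalised adjacency with self-loops
#'
#' Computes `D^-1/2 (A + I) D^-1/2` for the binary adjacency of the unmasked
#' view (isolated nodes are covered by their self-loop, so every degree is
#' at least 1). Rows/columns follow [node_order()].
#'
#' @param graph A `hetero_graph`, or a symmetric 0/1 sparse adjacency matrix
#'   without diagonal.
#' @return Sparse symmetric matrix.
#' @export
normalized_adjacency <- function(graph) {
  A <- if (inherits(graph, "hetero_graph")) adjacency_matrix(graph) else graph
  n <- nrow(A)
  A_tilde <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(A_tilde)
  Dm <- Matrix::Diagonal(n, x = 1 / sqrt(d))
  out <- Dm %*% A_tilde %*% Dm
  dimnames(out) <- dimnames(A)
  out
}

.glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialise parameters for the GCN + decoder model
#'
#' Weights use uniform Glorot initialisation scaled by layer fan-in/out;
#' biases start at zero. The draw is governed by `seed` and does not disturb
#' the caller's RNG state.
#'
#' @param input_dim Width of the assembled feature matrix.
#' @param encoder_dims Hidden widths of the two GCN layers.
#' @param decoder_dims Hidden widths of the two decoder layers.
#' @param seed Integer seed.
#' @return List of parameter matrices
#'   (`W0`, `b0`, `W1`, `b1`, `L1`, `c1`, `L2`, `c2`, `L3`, `c3`).
#' @export
init_patho_params <- function(input_dim, encoder_dims = c(256L, 64L),
                              decoder_dims = c(64L, 32L), seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  d1 <- encoder_dims[1L]; d2 <- encoder_dims[2L]
  h1 <- decoder_dims[1L]; h2 <- decoder_dims[2L]
  list(
    W0 = .glorot(input_dim, d1), b0 = numeric(d1),
    W1 = .glorot(d1, d2),        b1 = numeric(d2),
    L1 = .glorot(2L * d2, h1),   c1 = numeric(h1),
    L2 = .glorot(h1, h2),        c2 = numeric(h2),
    L3 = .glorot(h2, 1L),        c3 = numeric(1L)
  )
}

#' Initialise parameters for a no-graph baseline network
#'
#' @param input_dim Raw embedding width fed to the network.
#' @param hidden Hidden widths (256 and 64, as for the disease-specific
#'   baseline).
#' @param seed Integer seed.
#' @return List (`L1`, `c1`, `L2`, `c2`, `L3`, `c3`).
#' @export
init_baseline_params <- function(input_dim, hidden = c(256L, 64L), seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  list(
    L1 = .glorot(input_dim, hidden[1L]), c1 = numeric(hidden[1L]),
    L2 = .glorot(hidden[1L], hidden[2L]), c2 = numeric(hidden[2L]),
    L3 = .glorot(hidden[2L], 1L), c3 = numeric(1L)
  )
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout mask drawn from the current RNG stream
.dropout_mask <- function(nr, nc, rate) {
  m <- (stats::runif(nr * nc) >= rate) / (1 - rate)
  dim(m) <- c(nr, nc)
  m
}

.addrow <- function(M, b) sweep(M, 2L, b, "+")

## -- encoder ----------------------------------------------------------------

# forward pass with cache for backprop; training enables dropout (drawn from
# the current RNG stream)
.gcn_forward <- function(X, A_hat, params, training = FALSE, dropout = 0.3) {
  Z1 <- as.matrix(A_hat %*% X)
  S1 <- .addrow(Z1 %*% params$W0, params$b0)
  H1 <- pmax(S1, 0)
  M1 <- NULL
  if (training && dropout > 0) {
    M1 <- .dropout_mask(nrow(H1), ncol(H1), dropout)
    H1 <- H1 * M1
  }
  Z2 <- as.matrix(A_hat %*% H1)
  S2 <- .addrow(Z2 %*% params$W1, params$b1)
  H2 <- pmax(S2, 0)
  M2 <- NULL
  if (training && dropout > 0) {
    M2 <- .dropout_mask(nrow(H2), ncol(H2), dropout)
    H2 <- H2 * M2
  }
  list(E = H2, Z1 = Z1, S1 = S1, M1 = M1, Z2 = Z2, S2 = S2, M2 = M2)
}

#' Encode node features with the 2-layer GCN
#'
#' @param X Feature matrix in canonical node order.
#' @param A_hat Normalised adjacency from [normalized_adjacency()].
#' @param params Parameter list from [init_patho_params()].
#' @param training Apply dropout (stochastic); evaluation mode is
#'   deterministic.
#' @param dropout Dropout rate (0.3).
#' @return Matrix of 64-wide node embeddings (rownames preserved).
#' @export
gcn_encode <- function(X, A_hat, params, training = FALSE, dropout = 0.3) {
  if (ncol(X) != nrow(params$W0)) {
    stop("feature width ", ncol(X), " does not match encoder input width ",
         nrow(params$W0), call. = FALSE)
  }
  E <- .gcn_forward(X, A_hat, params, training, dropout)$E
  rownames(E) <- rownames(X)
  E
}

## -- decoder ----------------------------------------------------------------

# generic 3-layer MLP (two ReLU hidden layers with optional dropout, sigmoid
# output); U is the m x input matrix
.mlp_forward <- function(U, params, training = FALSE, dropout = 0.3) {
  S1 <- .addrow(U %*% params$L1, params$c1)
  A1 <- pmax(S1, 0)
  M1 <- NULL
  if (training && dropout > 0) {
    M1 <- .dropout_mask(nrow(A1), ncol(A1), dropout)
    A1 <- A1 * M1
  }
  S2 <- .addrow(A1 %*% params$L2, params$c2)
  A2 <- pmax(S2, 0)
  M2 <- NULL
  if (training && dropout > 0) {
    M2 <- .dropout_mask(nrow(A2), ncol(A2), dropout)
    A2 <- A2 * M2
  }
  logit <- drop(A2 %*% params$L3) + params$c3
  list(p = .sigmoid(logit), U = U, S1 = S1, A1 = A1, M1 = M1,
       S2 = S2, A2 = A2, M2 = M2)
}

# gradient of mean BCE wrt all MLP parameters and the input U;
# dlogit = (p - y)/m
.mlp_backward <- function(cache, params, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1L)
  gL3 <- crossprod(cache$A2, dlogit)
  gc3 <- sum(dlogit)
  dA2 <- tcrossprod(dlogit, params$L3)
  if (!is.null(cache$M2)) dA2 <- dA2 * cache$M2
  dS2 <- dA2 * (cache$S2 > 0)
  gL2 <- crossprod(cache$A1, dS2)
  gc2 <- colSums(dS2)
  dA1 <- tcrossprod(dS2, params$L2)
  if (!is.null(cache$M1)) dA1 <- dA1 * cache$M1
  dS1 <- dA1 * (cache$S1 > 0)
  gL1 <- crossprod(cache$U, dS1)
  gc1 <- colSums(dS1)
  dU <- tcrossprod(dS1, params$L1)
  list(grads = list(L1 = gL1, c1 = gc1, L2 = gL2, c2 = gc2,
                    L3 = gL3, c3 = gc3),
       dU = dU)
}

#' Decode a batch of variant-disease pairs into probabilities
#'
#' Concatenates the variant embedding first and the disease embedding second
#' into a 128-wide input, applies the two hidden layers and the sigmoid
#' output neuron.
#'
#' @param Z_variant,Z_disease Matrices of 64-wide embeddings, one row per
#'   pair (a single pair may be given as plain vectors).
#' @param params Parameter list from [init_patho_params()].
#' @param training Apply dropout on hidden layers.
#' @param dropout Dropout rate.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
decode_pair <- function(Z_variant, Z_disease, params, training = FALSE,
                        dropout = 0.3) {
  if (is.null(dim(Z_variant))) Z_variant <- matrix(Z_variant, nrow = 1L)
  if (is.null(dim(Z_disease))) Z_disease <- matrix(Z_disease, nrow = 1L)
  if (ncol(Z_variant) + ncol(Z_disease) != nrow(params$L1)) {
    stop("pair width ", ncol(Z_variant) + ncol(Z_disease),
         " does not match decoder input width ", nrow(params$L1),
         call. = FALSE)
  }
  .mlp_forward(cbind(Z_variant, Z_disease), params, training, dropout)$p
}

#' No-graph baseline forward passes
#'
#' `baseline_pair_forward` is the disease-specific baseline: a 3-layer
#' network (hidden 256 and 64, sigmoid output) on the concatenated raw
#' variant and disease embeddings, with no graph involvement.
#' `baseline_variant_forward` is the non-disease-specific baseline: the same
#' architecture on the variant embedding alone.
#'
#' @param raw_variant,raw_disease Raw (pre-encoder) embedding matrices, one
#'   row per example.
#' @param params Parameter list from [init_baseline_params()].
#' @param training Apply dropout on hidden layers.
#' @param dropout Dropout rate.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
baseline_pair_forward <- function(raw_variant, raw_disease, params,
                                  training = FALSE, dropout = 0.3) {
  if (is.null(dim(raw_variant))) raw_variant <- matrix(raw_variant, nrow = 1L)
  if (is.null(dim(raw_disease))) raw_disease <- matrix(raw_disease, nrow = 1L)
  U <- cbind(raw_variant, raw_disease)
  if (ncol(U) != nrow(params$L1)) {
    stop("input width ", ncol(U), " does not match network input width ",
         nrow(params$L1), call. = FALSE)
  }
  .mlp_forward(U, params, training, dropout)$p
}

#' @rdname baseline_pair_forward
#' @export
baseline_variant_forward <- function(raw_variant, params, training = FALSE,
                                     dropout = 0.3) {
  if (is.null(dim(raw_variant))) raw_variant <- matrix(raw_variant, nrow = 1L)
  if (ncol(raw_variant) != nrow(params$L1)) {
    stop("input width ", ncol(raw_variant),
         " does not match network input width ", nrow(params$L1),
         call. = FALSE)
  }
  .mlp_forward(raw_variant, params, training, dropout)$p
}

## -- full-model loss and gradients ------------------------------------------

.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# end-to-end forward + backward over the masked graph for one full batch of
# pairs; iv/idd index rows of X (canonical node order)
.full_forward_backward <- function(X, A_hat, iv, idd, y, params,
                                   training = TRUE, dropout = 0.3,
                                   want_grads = TRUE) {
  enc <- .gcn_forward(X, A_hat, params, training, dropout)
  E <- enc$E
  U <- cbind(E[iv, , drop = FALSE], E[idd, , drop = FALSE])
  dec <- .mlp_forward(U, params, training, dropout)
  p <- dec$p
  loss <- .bce(p, y)
  if (!want_grads) return(list(loss = loss, p = p))

  m <- length(y)
  dlogit <- (p - y) / m
  back <- .mlp_backward(dec, params, dlogit)
  d2 <- ncol(E)
  dU <- back$dU
  # scatter-add decoder input gradients onto node embeddings
  dE <- matrix(0, nrow(E), d2)
  agg_v <- rowsum(dU[, seq_len(d2), drop = FALSE], group = iv)
  agg_d <- rowsum(dU[, d2 + seq_len(d2), drop = FALSE], group = idd)
  dE[as.integer(rownames(agg_v)), ] <- agg_v
  idx_d <- as.integer(rownames(agg_d))
  dE[idx_d, ] <- dE[idx_d, ] + agg_d

  dH2 <- dE
  if (!is.null(enc$M2)) dH2 <- dH2 * enc$M2
  dS2 <- dH2 * (enc$S2 > 0)
  gW1 <- crossprod(enc$Z2, dS2)
  gb1 <- colSums(dS2)
  dH1 <- as.matrix(A_hat %*% tcrossprod(dS2, params$W1))
  if (!is.null(enc$M1)) dH1 <- dH1 * enc$M1
  dS1 <- dH1 * (enc$S1 > 0)
  gW0 <- crossprod(enc$Z1, dS1)
  gb0 <- colSums(dS1)

  grads <- c(list(W0 = gW0, b0 = gb0, W1 = gW1, b1 = gb1), back$grads)
  list(loss = loss, p = p, grads = grads)
}

# baseline forward + backward (U already assembled)
.baseline_forward_backward <- function(U, y, params, training = TRUE,
                                       dropout = 0.3, want_grads = TRUE) {
  cache <- .mlp_forward(U, params, training, dropout)
  loss <- .bce(cache$p, y)
  if (!want_grads) return(list(loss = loss, p = cache$p))
  back <- .mlp_backward(cache, params, (cache$p - y) / length(y))
  list(loss = loss, p = cache$p, grads = back$grads)
}

# classic SGD with momentum and L2 weight decay coupled at the optimizer:
#   v <- mu v - lr (g + wd theta);  theta <- theta + v
.sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * g
    params[[nm]] <- params[[nm]] + velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

.zero_like <- function(params) lapply(params, function(p) p * 0)
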