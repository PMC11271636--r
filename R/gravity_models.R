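# Attention-based and MLP gravity scoring models, authored as plain matrix
# code: forward pass, analytic backprop and Adam live here. Samples are tiny
# (N <= 17 destination rows, 10 features), so dense base-R linear algebra is
# the right tool.

LN_EPS <- 1e-5
LEAKY_SLOPE <- 0.01

#' Transformer gravity model specification
#'
#' A small transformer encoder scoring destination regions for one source
#' port: a linear embedding of the 10 gravity features into `embed_dim`,
#' `encoder_layers` stacked encoder blocks (multi-head self-attention over
#' the destination set with residual + layer norm, then a position-wise
#' feed-forward network with residual + layer norm, dropout in training
#' mode), and a scalar output head. No positional encoding is used: the
#' destinations are an unordered set and the model is permutation
#' equivariant.
#'
#' @param input_dim Number of input features. Default 10.
#' @param embed_dim Embedding width d. Default 64.
#' @param heads Attention heads h (must divide d). Default 2.
#' @param encoder_layers Number of stacked encoder blocks. Default 3.
#' @param ffn_dim Feed-forward hidden width. Default 256.
#' @param dropout Dropout probability in training mode. Default 0.1.
#' @return A `transformer_gravity_spec`.
#' @export
transformer_gravity_spec <- function(input_dim = 10, embed_dim = 64,
                                     heads = 2, encoder_layers = 3,
                                     ffn_dim = 256, dropout = 0.1) {
  if (embed_dim %% heads != 0) {
    stop_shipflow("embed_dim must be divisible by heads")
  }
  structure(
    list(input_dim = input_dim, embed_dim = embed_dim, heads = heads,
         encoder_layers = encoder_layers, ffn_dim = ffn_dim,
         dropout = dropout),
    class = c("transformer_gravity_spec", "gravity_spec")
  )
}

#' Deep gravity baseline specification
#'
#' The MLP gravity baseline: each destination row is scored independently by
#' a feed-forward network with `layers` hidden layers — the first third of
#' width 256, the remaining two thirds of width 128 (the 1:2 width scheme) —
#' leaky-rectifier activations and a scalar output.
#'
#' @param layers Total hidden layers, divisible by 3 (3, 9, 12 or 15).
#' @param input_dim Number of input features. Default 10.
#' @return A `deep_gravity_spec`.
#' @export
deep_gravity_spec <- function(layers = 15, input_dim = 10) {
  if (layers %% 3 != 0 || layers < 3) {
    stop_shipflow("layers must be a positive multiple of 3")
  }
  structure(
    list(input_dim = input_dim, layers = as.integer(layers),
         widths = c(rep(256L, layers / 3), rep(128L, 2 * layers / 3))),
    class = c("deep_gravity_spec", "gravity_spec")
  )
}

#' Count trainable parameters of a gravity model
#'
#' Exact count of trainable scalars: every weight matrix, bias vector and
#' layer-norm affine parameter.
#'
#' @param spec A `gravity_spec` (or a fitted/initialised model).
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  if (inherits(spec, "gravity_model") || inherits(spec, "gravity_fit")) {
    spec <- spec$spec
  }
  params <- init_gravity_model(spec, seed = 1)$params
  sum(vapply(flatten_params(params), length, integer(1)))
}

flatten_params <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, ".", nm))
    } else {
      out[[sub("^\\.", "", prefix)]] <<- x
    }
  }
  walk(params, "")
  out
}

xavier <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialise a gravity model
#'
#' Xavier-uniform weights, zero biases, layer-norm affine at (1, 0);
#' deterministic under the seed.
#'
#' @param spec A `gravity_spec`.
#' @param seed Integer seed.
#' @return A `gravity_model` list with `spec` and `params`.
#' @export
init_gravity_model <- function(spec, seed = 1) {
  params <- withr::with_seed(as.integer(seed), {
    if (inherits(spec, "transformer_gravity_spec")) {
      d <- spec$embed_dim
      layers <- lapply(seq_len(spec$encoder_layers), function(l) {
        list(
          Wqkv = xavier(3 * d, d), bqkv = numeric(3 * d),
          Wo = xavier(d, d), bo = numeric(d),
          g1 = rep(1, d), be1 = numeric(d),
          W1 = xavier(spec$ffn_dim, d), b1 = numeric(spec$ffn_dim),
          W2 = xavier(d, spec$ffn_dim), b2 = numeric(d),
          g2 = rep(1, d), be2 = numeric(d)
        )
      })
      names(layers) <- paste0("L", seq_along(layers))
      list(
        W0 = xavier(d, spec$input_dim), b0 = numeric(d),
        layers = layers,
        w_out = as.numeric(xavier(1, d)), b_out = 0
      )
    } else if (inherits(spec, "deep_gravity_spec")) {
      widths <- c(spec$input_dim, spec$widths, 1L)
      layers <- lapply(seq_len(length(widths) - 1), function(l) {
        list(W = xavier(widths[l + 1], widths[l]),
             b = numeric(widths[l + 1]))
      })
      names(layers) <- paste0("L", seq_along(layers))
      list(layers = layers)
    } else {
      stop_shipflow("unknown gravity spec")
    }
  })
  structure(list(spec = spec, params = params), class = "gravity_model")
}

# ---- shared primitives -----------------------------------------------------

linear_fwd <- function(X, W, b) {
  sweep(X %*% t(W), 2, b, "+")
}

linear_bwd <- function(dY, X, W) {
  list(dW = t(dY) %*% X, db = colSums(dY), dX = dY %*% W)
}

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  ivar <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * ivar
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, ivar = ivar)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dX <- (cache$ivar / d) * (d * dxhat - s1 - xhat * s2)
  list(dX = dX, dg = dg, db = db)
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

dropout_mask <- function(dim, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix(stats::rbinom(prod(dim), 1, 1 - p) / (1 - p), dim[1], dim[2])
}

apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask

# ---- transformer forward / backward ---------------------------------------

transformer_forward <- function(params, spec, X, train = FALSE) {
  d <- spec$embed_dim
  h <- spec$heads
  dk <- d / h
  p <- spec$dropout
  N <- nrow(X)

  Z <- linear_fwd(X, params$W0, params$b0)
  caches <- vector("list", spec$encoder_layers)
  for (l in seq_len(spec$encoder_layers)) {
    pl <- params$layers[[l]]
    QKV <- linear_fwd(Z, pl$Wqkv, pl$bqkv)
    Q <- QKV[, 1:d, drop = FALSE]
    K <- QKV[, d + 1:d, drop = FALSE]
    V <- QKV[, 2 * d + 1:d, drop = FALSE]
    H <- matrix(0, N, d)
    A_list <- vector("list", h)
    for (hh in seq_len(h)) {
      idx <- (hh - 1) * dk + 1:dk
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
      A <- row_softmax(S)
      A_list[[hh]] <- A
      H[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    attn <- linear_fwd(H, pl$Wo, pl$bo)
    m1 <- dropout_mask(dim(attn), p, train)
    skip1 <- Z + apply_mask(attn, m1)
    ln1 <- layernorm_fwd(skip1, pl$g1, pl$be1)
    Z2 <- ln1$out

    ffn_pre <- linear_fwd(Z2, pl$W1, pl$b1)
    relu <- pmax(ffn_pre, 0)
    m2 <- dropout_mask(dim(relu), p, train)
    H1 <- apply_mask(relu, m2)
    ffn_out <- linear_fwd(H1, pl$W2, pl$b2)
    m3 <- dropout_mask(dim(ffn_out), p, train)
    skip2 <- apply_mask(ffn_out, m3) + Z2
    ln2 <- layernorm_fwd(skip2, pl$g2, pl$be2)

    caches[[l]] <- list(Z_in = Z, Q = Q, K = K, V = V, A = A_list, H = H,
                        m1 = m1, ln1 = ln1, Z2 = Z2, ffn_pre = ffn_pre,
                        H1 = H1, m2 = m2, m3 = m3, ln2 = ln2)
    Z <- ln2$out
  }
  scores <- as.numeric(Z %*% params$w_out + params$b_out)
  list(scores = scores, cache = list(X = X, Z_final = Z, layers = caches))
}

transformer_backward <- function(params, spec, cache, dscores) {
  d <- spec$embed_dim
  h <- spec$heads
  dk <- d / h
  grads <- list(W0 = NULL, b0 = NULL, layers = vector("list",
                                                      spec$encoder_layers),
                w_out = NULL, b_out = NULL)
  names(grads$layers) <- names(params$layers)

  grads$w_out <- as.numeric(t(cache$Z_final) %*% dscores)
  grads$b_out <- sum(dscores)
  dZ <- outer(dscores, params$w_out)

  for (l in rev(seq_len(spec$encoder_layers))) {
    pl <- params$layers[[l]]
    cl <- cache$layers[[l]]

    ln2b <- layernorm_bwd(dZ, cl$ln2, pl$g2)
    dskip2 <- ln2b$dX
    dffn_out <- apply_mask(dskip2, cl$m3)
    lb2 <- linear_bwd(dffn_out, cl$H1, pl$W2)
    dH1 <- lb2$dX
    drelu <- apply_mask(dH1, cl$m2)
    dffn_pre <- drelu * (cl$ffn_pre > 0)
    lb1 <- linear_bwd(dffn_pre, cl$ln1$out, pl$W1)
    dZ2 <- lb1$dX + dskip2 # residual around the FFN

    ln1b <- layernorm_bwd(dZ2, cl$ln1, pl$g1)
    dskip1 <- ln1b$dX
    dattn <- apply_mask(dskip1, cl$m1)
    lbo <- linear_bwd(dattn, cl$H, pl$Wo)
    dH <- lbo$dX

    dQ <- matrix(0, nrow(dH), d)
    dK <- matrix(0, nrow(dH), d)
    dV <- matrix(0, nrow(dH), d)
    for (hh in seq_len(h)) {
      idx <- (hh - 1) * dk + 1:dk
      A <- cl$A[[hh]]
      dHh <- dH[, idx, drop = FALSE]
      dA <- dHh %*% t(cl$V[, idx, drop = FALSE])
      dV[, idx] <- t(A) %*% dHh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cl$K[, idx, drop = FALSE] / sqrt(dk)
      dK[, idx] <- t(dS) %*% cl$Q[, idx, drop = FALSE] / sqrt(dk)
    }
    dQKV <- cbind(dQ, dK, dV)
    lbq <- linear_bwd(dQKV, cl$Z_in, pl$Wqkv)

    grads$layers[[l]] <- list(
      Wqkv = lbq$dW, bqkv = lbq$db,
      Wo = lbo$dW, bo = lbo$db,
      g1 = ln1b$dg, be1 = ln1b$db,
      W1 = lb1$dW, b1 = lb1$db,
      W2 = lb2$dW, b2 = lb2$db,
      g2 = ln2b$dg, be2 = ln2b$db
    )
    dZ <- lbq$dX + dskip1 # residual around attention
  }
  lb0 <- linear_bwd(dZ, cache$X, params$W0)
  grads$W0 <- lb0$dW
  grads$b0 <- lb0$db
  grads
}

# ---- deep gravity forward / backward --------------------------------------

deep_gravity_forward <- function(params, spec, X, train = FALSE) {
  acts <- list(X)
  Z <- X
  n_layers <- length(params$layers)
  for (l in seq_len(n_layers)) {
    pl <- params$layers[[l]]
    Z <- linear_fwd(Z, pl$W, pl$b)
    if (l < n_layers) {
      Z <- ifelse(Z > 0, Z, LEAKY_SLOPE * Z)
    }
    acts[[l + 1]] <- Z
  }
  list(scores = as.numeric(Z), cache = list(acts = acts))
}

deep_gravity_backward <- function(params, spec, cache, dscores) {
  n_layers <- length(params$layers)
  grads <- list(layers = vector("list", n_layers))
  names(grads$layers) <- names(params$layers)
  dZ <- matrix(dscores, ncol = 1)
  for (l in rev(seq_len(n_layers))) {
    pl <- params$layers[[l]]
    if (l < n_layers) {
      pre <- cache$acts[[l + 1]] # stored post-activation; slope from sign
      dZ <- dZ * ifelse(pre > 0, 1, LEAKY_SLOPE)
    }
    lb <- linear_bwd(dZ, cache$acts[[l]], pl$W)
    grads$layers[[l]] <- list(W = lb$dW, b = lb$db)
    dZ <- lb$dX
  }
  grads
}

# ---- unified scoring -------------------------------------------------------

model_forward <- function(model, X, train = FALSE) {
  if (inherits(model$spec, "transformer_gravity_spec")) {
    transformer_forward(model$params, model$spec, X, train)
  } else {
    deep_gravity_forward(model$params, model$spec, X, train)
  }
}

model_backward <- function(model, cache, dscores) {
  if (inherits(model$spec, "transformer_gravity_spec")) {
    transformer_backward(model$params, model$spec, cache, dscores)
  } else {
    deep_gravity_backward(model$params, model$spec, cache, dscores)
  }
}

#' Score destination rows with a gravity model
#'
#' Evaluation mode is deterministic (dropout off). Scores feed
#' [allocate_flows()] through a softmax, so only their differences matter.
#'
#' @param model A `gravity_model` (or the `model` inside a `gravity_fit`).
#' @param X Numeric matrix, one row per destination region, columns in the
#'   frozen feature order.
#' @param mode `"eval"` (default, deterministic) or `"train"` (dropout
#'   active; draws from the current RNG stream).
#' @return Numeric score vector, one per row of `X`.
#' @export
gravity_scores <- function(model, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_shipflow("X must be finite")
  if (ncol(X) != model$spec$input_dim) {
    stop_shipflow(sprintf("X must have %d columns", model$spec$input_dim))
  }
  model_forward(model, X, train = (mode == "train"))$scores
}

# Gradient of the cross-entropy flow loss wrt the scores:
# dL/df_k = softmax(f)_k * sum(y) - y_k.
loss_and_grad_scores <- function(scores, y) {
  p <- softmax(scores)
  list(loss = -sum(y * log_softmax(scores)), dscores = p * sum(y) - y)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0)
}

# One Adam step with decoupled-from-nothing classic L2 (gradient + wd * w).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (weight_decay > 0) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
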