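# Feed-forward pair-energy functional: standardization, network
# initialization, forward/backward passes, Adam/MAE training. The same
# engine drives base-model training and all fine-tuning methods; the only
# difference is which parameter blocks receive updates.

relu <- function(x) (x + abs(x)) / 2

# evaluate expr under a private RNG stream, restoring global state after
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fit feature/label standardization statistics
#'
#' Per-tensor-element z-scoring of the flattened feature tensors and scalar
#' z-scoring of the pair-energy labels, computed on the training split only.
#' Zero-variance elements have their scale clamped to 1 (with a warning) so
#' standardization stays invertible.
#'
#' @param x numeric matrix (n_pairs x input_dim) of flattened feature
#'   tensors.
#' @param y numeric vector of pair-energy labels (Hartree).
#' @return a `standardizer`.
#' @export
fit_standardizer <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) >= 2, nrow(x) == length(y))
  fm <- colMeans(x)
  fs <- apply(x, 2, stats::sd)
  if (any(fs <= 0 | !is.finite(fs))) {
    warning("zero-variance feature element(s); scale clamped to 1")
    fs[fs <= 0 | !is.finite(fs)] <- 1
  }
  lm_ <- mean(y)
  ls <- stats::sd(y)
  if (!is.finite(ls) || ls <= 0) {
    warning("zero-variance labels; label scale clamped to 1")
    ls <- 1
  }
  structure(list(feature_mean = fm, feature_scale = fs,
                 label_mean = lm_, label_scale = ls),
            class = "standardizer")
}

std_apply_x <- function(std, x) sweep(sweep(x, 2, std$feature_mean), 2,
                                      std$feature_scale, `/`)
std_apply_y <- function(std, y) (y - std$label_mean) / std$label_scale
std_invert_y <- function(std, y) y * std$label_scale + std$label_mean

#' Network architecture specification
#'
#' @param input_dim flattened feature dimension (`4 * n_osv^2`).
#' @param n_hidden_layers number of hidden layers (default 10).
#' @param hidden_width neurons per hidden layer (default 50).
#' @param activation only `"relu"` is implemented.
#' @param seed initialization seed.
#' @return a `network_spec`.
#' @export
network_spec <- function(input_dim, n_hidden_layers = 10L, hidden_width = 50L,
                         activation = "relu", seed = 1L) {
  stopifnot(input_dim >= 1, n_hidden_layers >= 1, hidden_width >= 1,
            activation == "relu")
  structure(list(input_dim = as.integer(input_dim),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 activation = activation, seed = as.integer(seed)),
            class = "network_spec")
}

he_uniform <- function(n_out, n_in) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# layer dimension chain input_dim -> width x n_hidden -> 1
layer_dims <- function(spec) {
  ins <- c(spec$input_dim, rep(spec$hidden_width, spec$n_hidden_layers))
  outs <- c(rep(spec$hidden_width, spec$n_hidden_layers), 1L)
  list(ins = ins, outs = outs, n = spec$n_hidden_layers + 1L)
}

init_network <- function(spec) {
  d <- layer_dims(spec)
  with_local_seed(spec$seed, {
    W <- vector("list", d$n)
    b <- vector("list", d$n)
    for (l in seq_len(d$n)) {
      W[[l]] <- he_uniform(d$outs[l], d$ins[l])
      b[[l]] <- numeric(d$outs[l])
    }
    list(W = W, b = b, A = NULL, B = NULL, headW = NULL, headb = NULL,
         res_shortcut = FALSE)
  })
}

# Forward pass. Returns predictions and, when requested, the cache of layer
# inputs/preactivations needed for backprop. The LoRA branch of layer l
# consumes x^l, or x^l + x^{l-1} when the input shortcut is active and the
# widths match (never the first layer).
forward_net <- function(net, x, keep_cache = FALSE) {
  nl <- length(net$W)
  xs <- vector("list", nl)
  cur <- x
  for (l in seq_len(nl)) {
    xs[[l]] <- cur
    z <- cur %*% t(net$W[[l]])
    z <- sweep(z, 2, net$b[[l]], `+`)
    if (!is.null(net$A)) {
      lin <- cur
      if (net$res_shortcut && l > 1 &&
          ncol(xs[[l - 1]]) == ncol(cur)) {
        lin <- cur + xs[[l - 1]]
      }
      z <- z + (lin %*% t(net$A[[l]])) %*% t(net$B[[l]])
    }
    cur <- if (l < nl) relu(z) else z
  }
  out <- cur[, 1]
  if (!is.null(net$headW)) {
    h <- xs[[nl]]
    out <- out + as.numeric(h %*% t(net$headW)) + net$headb
  }
  if (keep_cache) list(out = out, xs = xs) else out
}

# Backward pass for mean-absolute-error loss; returns gradients for every
# parameter block (update masking happens in the optimizer).
backward_net <- function(net, cache, y) {
  nl <- length(net$W)
  xs <- cache$xs
  n <- length(y)
  g <- matrix(sign(cache$out - y) / n, n, 1)
  grads <- list(W = vector("list", nl), b = vector("list", nl),
                A = if (!is.null(net$A)) vector("list", nl),
                B = if (!is.null(net$B)) vector("list", nl),
                headW = NULL, headb = NULL)
  gx <- vector("list", nl)          # gradient wrt input of each layer
  if (!is.null(net$headW)) {
    h <- xs[[nl]]
    grads$headW <- crossprod(g, h)
    grads$headb <- sum(g)
    gx[[nl]] <- g %*% net$headW     # head path into last hidden activation
  }
  dz <- g
  for (l in nl:1) {
    x_in <- xs[[l]]
    grads$W[[l]] <- crossprod(dz, x_in)
    grads$b[[l]] <- colSums(dz)
    dx <- dz %*% net$W[[l]]
    if (!is.null(net$A)) {
      lin <- x_in
      shortcut <- net$res_shortcut && l > 1 &&
        ncol(xs[[l - 1]]) == ncol(x_in)
      if (shortcut) lin <- x_in + xs[[l - 1]]
      u <- lin %*% t(net$A[[l]])
      grads$B[[l]] <- crossprod(dz, u)
      grads$A[[l]] <- t(net$B[[l]]) %*% crossprod(dz, lin)
      dlora <- (dz %*% net$B[[l]]) %*% net$A[[l]]
      dx <- dx + dlora
      if (shortcut) {
        gx[[l - 1]] <- if (is.null(gx[[l - 1]])) dlora else gx[[l - 1]] + dlora
      }
    }
    gx[[l]] <- if (is.null(gx[[l]])) dx else gx[[l]] + dx
    if (l > 1) {
      dz <- gx[[l]] * (xs[[l]] > 0)   # ReLU mask on previous activation
    }
  }
  grads
}

# trainable-block bookkeeping ------------------------------------------------

trainable_blocks <- function(method) {
  switch(method,
         base = c("W", "b"),
         full = c("W", "b"),
         head = "headW_b",
         bitfit = "b",
         bitfit_r = c("b", "headW_b"),
         lora_r = c("A", "B", "headW_b"),
         reslora_r = c("A", "B", "headW_b"),
         stop("unknown method: ", method))
}

adam_state_like <- function(x) list(m = x * 0, v = x * 0)

adam_update <- function(param, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# Train a network in place over an epoch/learning-rate schedule, updating
# only the parameter blocks selected by `blocks`. Deterministic per seed.
train_network <- function(net, x, y, blocks, epochs, learning_rates,
                          batch_size = 64L, seed = 1L,
                          x_val = NULL, y_val = NULL) {
  stopifnot(length(epochs) == length(learning_rates))
  nl <- length(net$W)
  n <- nrow(x)
  use_w <- "W" %in% blocks
  use_b <- "b" %in% blocks
  use_a <- "A" %in% blocks && !is.null(net$A)
  use_bb <- "B" %in% blocks && !is.null(net$B)
  use_head <- "headW_b" %in% blocks && !is.null(net$headW)
  st <- list()
  for (l in seq_len(nl)) {
    if (use_w) st[[paste0("W", l)]] <- adam_state_like(net$W[[l]])
    if (use_b) st[[paste0("b", l)]] <- adam_state_like(net$b[[l]])
    if (use_a) st[[paste0("A", l)]] <- adam_state_like(net$A[[l]])
    if (use_bb) st[[paste0("B", l)]] <- adam_state_like(net$B[[l]])
  }
  if (use_head) {
    st$headW <- adam_state_like(net$headW)
    st$headb <- adam_state_like(net$headb)
  }
  history <- numeric(0)
  step <- 0L
  with_local_seed(seed, {
    for (phase in seq_along(epochs)) {
      lr <- learning_rates[phase]
      for (ep in seq_len(epochs[phase])) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = batch_size)
        ep_loss <- 0.0
        for (s in starts) {
          idx <- perm[s:min(s + batch_size - 1L, n)]
          fw <- forward_net(net, x[idx, , drop = FALSE], keep_cache = TRUE)
          if (any(!is.finite(fw$out))) {
            stop(sprintf("NaN/Inf loss at epoch %d, batch starting %d", ep, s))
          }
          gr <- backward_net(net, fw, y[idx])
          step <- step + 1L
          for (l in seq_len(nl)) {
            if (use_w) {
              up <- adam_update(net$W[[l]], gr$W[[l]], st[[paste0("W", l)]],
                                lr, step)
              net$W[[l]] <- up$param; st[[paste0("W", l)]] <- up$state
            }
            if (use_b) {
              up <- adam_update(net$b[[l]], gr$b[[l]], st[[paste0("b", l)]],
                                lr, step)
              net$b[[l]] <- up$param; st[[paste0("b", l)]] <- up$state
            }
            if (use_a) {
              up <- adam_update(net$A[[l]], gr$A[[l]], st[[paste0("A", l)]],
                                lr, step)
              net$A[[l]] <- up$param; st[[paste0("A", l)]] <- up$state
            }
            if (use_bb) {
              up <- adam_update(net$B[[l]], gr$B[[l]], st[[paste0("B", l)]],
                                lr, step)
              net$B[[l]] <- up$param; st[[paste0("B", l)]] <- up$state
            }
          }
          if (use_head) {
            up <- adam_update(net$headW, gr$headW, st$headW, lr, step)
            net$headW <- up$param; st$headW <- up$state
            up <- adam_update(net$headb, gr$headb, st$headb, lr, step)
            net$headb <- up$param; st$headb <- up$state
          }
          ep_loss <- ep_loss + sum(abs(fw$out - y[idx]))
        }
        history <- c(history, ep_loss / n)
      }
    }
  })
  val_mae <- if (!is.null(x_val) && nrow(x_val) > 0) {
    mean(abs(forward_net(net, x_val) - y_val))
  } else {
    NA_real_
  }
  list(net = net, history = history, val_mae = val_mae)
}
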