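# Residual transfer learning on top of a pretrained pair-energy network:
# residual pair-correction head, low-rank weight adaptation (LoRA) with an
# optional input shortcut between the low-rank blocks, bias-only retraining
# (BitFit), and a delta-learning baseline. Every tuned model reproduces the
# base model's outputs exactly at initialization.

#' Fine-tuning specification
#'
#' @param method one of `"full"`, `"bitfit"`, `"bitfit_r"`, `"lora_r"`,
#'   `"reslora_r"`, `"delta_ml"`.
#' @param rank LoRA rank (low-rank methods only). Default 1, which on the
#'   reference 256-input, 10x50 architecture keeps the trainable fraction
#'   within a few percent of the base parameters.
#' @param epochs,learning_rates fine-tuning schedule; defaults 200 then 800
#'   epochs at 1e-5 then 1e-6.
#' @param batch_size minibatch size.
#' @param seed seed for shuffling (and delta-model initialization).
#' @export
finetune_spec <- function(method = c("lora_r", "reslora_r", "bitfit",
                                     "bitfit_r", "full", "delta_ml"),
                          rank = 1L, epochs = c(200L, 800L),
                          learning_rates = c(1e-5, 1e-6), batch_size = 64L,
                          seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(epochs) == length(learning_rates))
  if (method %in% c("lora_r", "reslora_r") && rank < 1) {
    stop("LoRA methods require rank >= 1")
  }
  structure(list(method = method, rank = as.integer(rank),
                 epochs = as.integer(epochs),
                 learning_rates = learning_rates,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "finetune_spec")
}

new_tuned_model <- function(base, net, method, rank = NA_integer_) {
  structure(list(base = base, net = net, method = method, rank = rank),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  ct <- count_trainable(x)
  cat(sprintf("tuned_model (%s%s) on %s base: %d / %d trainable (%.2f%%)\n",
              x$method, if (!is.na(x$rank)) paste0(", rank ", x$rank) else "",
              x$base$role, ct$trainable, ct$total_base, 100 * ct$fraction))
  invisible(x)
}

#' Attach a residual pair-correction head
#'
#' Adds a linear map from the last hidden activation to a pair-energy
#' correction \eqn{\Delta e_{ij}^R}; the head is zero-initialized so the
#' tuned model's output equals the base model's output exactly.
#'
#' @param base a trained `base_model`.
#' @return a `tuned_model` with method `"head"` (trainable head only).
#' @export
attach_residual_head <- function(base) {
  stopifnot(inherits(base, "base_model"))
  net <- base$net
  net$headW <- matrix(0.0, 1, base$spec$hidden_width)
  net$headb <- 0.0
  new_tuned_model(base, net, "head")
}

#' Attach low-rank adaptation blocks (LoRA-R / ResLoRA-R)
#'
#' Every weight matrix, including the output layer, gains a learnable
#' low-rank update \eqn{\Delta W = B A}; `A` is zero-initialized and `B`
#' he-uniform, so \eqn{\Delta W = 0} at the start. A zero-initialized
#' residual head is always attached (the "-R"). With `with_res_shortcut`,
#' the low-rank branch of each equal-width layer consumes the sum of the
#' previous and current layer inputs (the input layer is excluded since its
#' input width differs).
#'
#' @param base a trained `base_model`.
#' @param rank LoRA rank; at most the smallest layer dimension.
#' @param with_res_shortcut add input shortcuts between the low-rank blocks?
#' @param seed initialization seed for the `B` factors.
#' @return a `tuned_model` with method `"lora_r"` or `"reslora_r"`.
#' @export
attach_lora <- function(base, rank = 1L, with_res_shortcut = FALSE,
                        seed = 1L) {
  stopifnot(inherits(base, "base_model"))
  d <- layer_dims(base$spec)
  max_rank <- min(base$spec$input_dim, base$spec$hidden_width)
  if (rank > max_rank) {
    stop("rank ", rank, " exceeds the smallest layer dimension ", max_rank)
  }
  net <- base$net
  net$A <- vector("list", d$n)
  net$B <- vector("list", d$n)
  with_local_seed(seed, {
    for (l in seq_len(d$n)) {
      net$A[[l]] <- matrix(0.0, rank, d$ins[l])
      net$B[[l]] <- he_uniform(d$outs[l], rank)
    }
  })
  net$headW <- matrix(0.0, 1, base$spec$hidden_width)
  net$headb <- 0.0
  net$res_shortcut <- isTRUE(with_res_shortcut)
  new_tuned_model(base, net,
                  if (with_res_shortcut) "reslora_r" else "lora_r",
                  rank = as.integer(rank))
}

#' Select bias-only fine-tuning (BitFit / BitFit-R)
#'
#' Freezes all weight matrices; only the bias vectors (and, when flagged,
#' a zero-initialized residual head) are retrained.
#'
#' @param base a trained `base_model`.
#' @param with_residual_head also attach and train the residual head?
#' @return a `tuned_model` with method `"bitfit"` or `"bitfit_r"`.
#' @export
select_bitfit <- function(base, with_residual_head = FALSE) {
  stopifnot(inherits(base, "base_model"))
  net <- base$net
  if (with_residual_head) {
    net$headW <- matrix(0.0, 1, base$spec$hidden_width)
    net$headb <- 0.0
  }
  new_tuned_model(base, net,
                  if (with_residual_head) "bitfit_r" else "bitfit")
}

#' Assemble a tuned model for a fine-tuning spec
#'
#' Dispatcher over [attach_lora()], [select_bitfit()] and full fine-tuning
#' (which trains the unmodified base architecture).
#' @param base a trained `base_model`.
#' @param spec a [finetune_spec()].
#' @export
make_tuned_model <- function(base, spec) {
  stopifnot(inherits(spec, "finetune_spec"))
  switch(spec$method,
         lora_r = attach_lora(base, spec$rank, FALSE, seed = spec$seed),
         reslora_r = attach_lora(base, spec$rank, TRUE, seed = spec$seed),
         bitfit = select_bitfit(base, FALSE),
         bitfit_r = select_bitfit(base, TRUE),
         full = new_tuned_model(base, base$net, "full"),
         stop("use train_delta_ml() for the delta_ml method"))
}

#' Fine-tune a tuned model on new pair data
#'
#' Minimizes the mean absolute deviation of
#' \eqn{e_{ij}^P + \Delta e_{ij}^R} from the exact labels over the
#' method-specific trainable parameters (LoRA blocks and residual head are
#' trained simultaneously). The base standardizer is reused, never refit.
#' Parameters outside the trainable set are bitwise unchanged.
#'
#' @param model a `tuned_model`.
#' @param data a [pair_dataset()] with labels at the target level of theory.
#' @param spec a [finetune_spec()] (its `method` must match the model).
#' @return the fine-tuned `tuned_model` with a `history` field.
#' @export
finetune <- function(model, data, spec) {
  stopifnot(inherits(model, "tuned_model"), inherits(data, "pair_dataset"),
            inherits(spec, "finetune_spec"))
  if (spec$method != model$method && model$method != "head") {
    stop("spec method '", spec$method, "' does not match model method '",
         model$method, "'")
  }
  if (sum(spec$epochs) == 0) return(model)
  std <- model$base$standardizer
  xs <- std_apply_x(std, data$x[data$train_mask, , drop = FALSE])
  ys <- std_apply_y(std, data$y[data$train_mask])
  xv <- std_apply_x(std, data$x[data$val_mask, , drop = FALSE])
  yv <- std_apply_y(std, data$y[data$val_mask])
  blocks <- trainable_blocks(if (model$method == "head") "bitfit_r" else
    model$method)
  if (model$method == "head") blocks <- "headW_b"
  fit <- train_network(model$net, xs, ys, blocks = blocks,
                       epochs = spec$epochs,
                       learning_rates = spec$learning_rates,
                       batch_size = spec$batch_size, seed = spec$seed,
                       x_val = xv, y_val = yv)
  model$net <- fit$net
  model$history <- fit$history
  model$val_mae <- fit$val_mae
  model
}

#' Train a delta-learning baseline
#'
#' A fresh network is trained on residual targets
#' \eqn{e^{exact} - e^P} (exact labels minus base-model predictions); the
#' combined prediction adds the base prediction back.
#'
#' @param base the pretrained `base_model` supplying \eqn{e^P}.
#' @param data a [pair_dataset()] whose labels are the exact target
#'   energies (Hartree); residuals are formed internally.
#' @param spec a [network_spec()] for the delta network.
#' @param hyper a [train_config()].
#' @return a `delta_model`; use with [predict_pairs()] like any model.
#' @export
train_delta_ml <- function(base, data, spec, hyper = train_config()) {
  stopifnot(inherits(base, "base_model"), inherits(data, "pair_dataset"))
  resid <- data$y - predict_model_x(base, data$x)
  ddata <- data
  ddata$y <- resid
  delta <- train_pair_model(ddata, spec, hyper, role = base$role)
  structure(list(base_model = base, delta = delta, method = "delta_ml"),
            class = "delta_model")
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("delta_model on %s base (residual network)\n", x$base_model$role))
  invisible(x)
}

#' Trainable-parameter accounting
#'
#' Exact integer counts of the method's trainable parameters against the
#' base network's full parameter count.
#'
#' @param model a `tuned_model` (or `base_model`, counted as fully
#'   trainable).
#' @return list `trainable`, `total_base`, `fraction`.
#' @export
count_trainable <- function(model) {
  base <- if (inherits(model, "tuned_model")) model$base else model
  d <- layer_dims(base$spec)
  total_base <- sum(d$ins * d$outs + d$outs)
  head_n <- function(net) {
    if (is.null(net$headW)) 0L else length(net$headW) + length(net$headb)
  }
  trainable <- if (!inherits(model, "tuned_model")) {
    total_base
  } else {
    net <- model$net
    switch(model$method,
           full = total_base,
           head = head_n(net),
           bitfit = sum(d$outs),
           bitfit_r = sum(d$outs) + head_n(net),
           lora_r = ,
           reslora_r = sum(model$rank * (d$ins + d$outs)) + head_n(net),
           stop("unknown method"))
  }
  list(trainable = as.integer(trainable), total_base = as.integer(total_base),
       fraction = trainable / total_base)
}
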