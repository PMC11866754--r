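tuned_of <- function(method, base = small_trained_base(), rank = 1L) {
  switch(method,
         lora_r = attach_lora(base, rank, FALSE, seed = 7L),
         reslora_r = attach_lora(base, rank, TRUE, seed = 7L),
         bitfit = select_bitfit(base, FALSE),
         bitfit_r = select_bitfit(base, TRUE))
}

test_that("every method reproduces base outputs exactly at initialization", {
  base <- small_trained_base()
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 40, seed = 8)
  base_pred <- restdnn:::predict_model_x(base, ds$x)
  for (method in c("lora_r", "reslora_r", "bitfit", "bitfit_r")) {
    tuned <- tuned_of(method)
    expect_identical(restdnn:::predict_model_x(tuned, ds$x), base_pred,
                     info = method)
  }
  head_only <- attach_residual_head(base)
  expect_identical(restdnn:::predict_model_x(head_only, ds$x), base_pred)
})

test_that("freeze contracts hold bitwise after tuning", {
  base <- small_trained_base()
  reg <- shifted_regime(synthetic_regime())
  ds <- synthetic_pair_dataset(reg, 64, seed = 10)
  for (method in c("lora_r", "reslora_r", "bitfit", "bitfit_r")) {
    fts <- finetune_spec(method = method, rank = 1L, epochs = c(5L, 5L),
                         learning_rates = c(1e-3, 1e-4), seed = 2L)
    tuned <- finetune(tuned_of(method), ds, fts)
    if (method %in% c("lora_r", "reslora_r")) {
      expect_identical(tuned$net$W, base$net$W, info = method)
      expect_identical(tuned$net$b, base$net$b, info = method)
      expect_false(identical(tuned$net$A, lapply(tuned$net$A, `*`, 0)))
    } else {
      expect_identical(tuned$net$W, base$net$W, info = method)
      expect_false(identical(tuned$net$b, base$net$b))
    }
  }
})

test_that("zero-epoch fine-tuning returns the model unchanged", {
  base <- small_trained_base()
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 30, seed = 3)
  fts <- finetune_spec("lora_r", epochs = c(0L, 0L),
                       learning_rates = c(1e-5, 1e-6))
  tuned <- finetune(tuned_of("lora_r"), ds, fts)
  expect_identical(restdnn:::predict_model_x(tuned, ds$x),
                   restdnn:::predict_model_x(tuned_of("lora_r"), ds$x))
})

test_that("hand-set residual head shifts the output by the activation", {
  base <- small_trained_base()
  tuned <- attach_residual_head(base)
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 10, seed = 4)
  xs <- restdnn:::std_apply_x(base$standardizer, ds$x)
  fw <- restdnn:::forward_net(base$net, xs, keep_cache = TRUE)
  h <- fw$xs[[length(base$net$W)]]  # last hidden activation
  tuned$net$headW[1, 1] <- 1.0     # W^R = e1
  tuned$net$headb <- 0.1
  out <- restdnn:::forward_net(tuned$net, xs)
  expect_equal(out, fw$out + h[, 1] + 0.1, tolerance = 1e-12)
})

test_that("the shortcut feeds the sum of consecutive layer inputs to LoRA", {
  # two equal-width hidden layers with hand-set factors: forward value must
  # match an explicit computation of x^{n-1} + x^n entering the LoRA branch
  spec <- network_spec(3, n_hidden_layers = 2L, hidden_width = 3L, seed = 1L)
  net <- restdnn:::init_network(spec)
  net$A <- list(matrix(0, 1, 3), matrix(c(1, 2, 3), 1, 3), matrix(0, 1, 3))
  net$B <- list(matrix(0, 3, 1), matrix(c(0.5, -0.5, 1), 3, 1),
                matrix(0, 1, 1))
  net$headW <- matrix(0, 1, 3); net$headb <- 0
  net$res_shortcut <- TRUE
  x <- matrix(c(0.3, -0.2, 0.1), 1, 3)
  relu <- function(z) pmax(z, 0)
  x1 <- x
  z1 <- x1 %*% t(net$W[[1]]) + net$b[[1]]          # layer 1: 3 -> 3, no lora
  x2 <- relu(z1)
  lin <- x2 + x1                                    # shortcut: equal widths
  z2 <- x2 %*% t(net$W[[2]]) + net$b[[2]] +
    (lin %*% t(net$A[[2]])) %*% t(net$B[[2]])
  x3 <- relu(z2)
  out_hand <- as.numeric(x3 %*% t(net$W[[3]]) + net$b[[3]])
  expect_equal(as.numeric(restdnn:::forward_net(net, x)), out_hand,
               tolerance = 1e-12)
})

test_that("trainable parameter accounting matches construction", {
  spec <- network_spec(256L, n_hidden_layers = 10L, hidden_width = 50L)
  fake_base <- structure(list(spec = spec,
                              net = restdnn:::init_network(spec),
                              standardizer = NULL, role = "offdiagonal"),
                         class = "base_model")
  # bitfit: sum of all layer output widths (10 x 50 hidden + 1 output)
  bf <- select_bitfit(fake_base, FALSE)
  expect_equal(count_trainable(bf)$trainable, 501L)
  # rank-1 LoRA on every layer + residual head (50 + 1)
  lr <- attach_lora(fake_base, 1L, FALSE)
  ct <- count_trainable(lr)
  expect_equal(ct$trainable, (256 + 50) + 9 * (50 + 50) + (50 + 1) + 51)
  expect_equal(ct$trainable, 1308L)
  expect_lte(ct$fraction, 0.065)
  expect_equal(count_trainable(fake_base)$trainable, ct$total_base)
  full <- restdnn:::new_tuned_model(fake_base, fake_base$net, "full")
  expect_equal(count_trainable(full)$fraction, 1.0)
  bfr <- select_bitfit(fake_base, TRUE)
  expect_equal(count_trainable(bfr)$trainable, 501L + 51L)
})

test_that("oversized LoRA ranks are rejected", {
  base <- small_trained_base()
  expect_error(attach_lora(base, rank = 1000L), "rank")
})

test_that("fine-tuning on shifted data improves over the untuned base", {
  base <- small_trained_base()
  regb <- shifted_regime(synthetic_regime())
  ftd <- synthetic_molecule_set(regb, 1, 128, seed = 31)
  test_b <- synthetic_pair_dataset(regb, 200, seed = 32)
  mae <- function(m) {
    mean(abs(restdnn:::predict_model_x(m, test_b$x) - test_b$y))
  }
  fts <- finetune_spec("lora_r", rank = 1L, epochs = c(100L, 200L),
                       learning_rates = c(1e-3, 1e-4), seed = 6L)
  tuned <- finetune(make_tuned_model(base, fts), ftd, fts)
  expect_lt(mae(tuned), mae(base))
})

test_that("full-rank LoRA matches full fine-tuning capacity on a toy case", {
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 200, seed = 41, val_fraction = 0)
  spec <- network_spec(ncol(ds$x), n_hidden_layers = 1L, hidden_width = 8L,
                       seed = 2L)
  base <- train_pair_model(ds, spec,
                           train_config(epochs = 30L, learning_rates = 1e-3,
                                        repetitions = 1L, seed = 3L),
                           role = "offdiagonal")
  regb <- shifted_regime(reg)
  ftd <- synthetic_pair_dataset(regb, 128, seed = 42)
  final_loss <- function(method, rank = 8L) {
    fts <- finetune_spec(method, rank = rank, epochs = c(400L, 400L),
                         learning_rates = c(1e-3, 1e-4), seed = 5L)
    tuned <- finetune(make_tuned_model(base, fts), ftd, fts)
    utils::tail(tuned$history, 1)
  }
  l_full <- final_loss("full")
  l_lora <- final_loss("lora_r", rank = 8L)
  # with rank = width the low-rank update is unconstrained: expressivity is
  # not the limiting factor, so LoRA-R must fit at least as well as
  # adjusting every base parameter
  expect_lt(l_lora, 1.5 * l_full)
})

test_that("delta-learning adds its correction to the base prediction", {
  base <- small_trained_base()
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 200, seed = 51, val_fraction = 0.1)
  spec <- network_spec(ncol(ds$x), n_hidden_layers = 2L, hidden_width = 8L,
                       seed = 9L)
  dm <- train_delta_ml(base, ds, spec,
                       train_config(epochs = 20L, learning_rates = 1e-3,
                                    repetitions = 1L, seed = 9L))
  x <- ds$x[1:10, , drop = FALSE]
  expect_equal(restdnn:::predict_model_x(dm, x),
               restdnn:::predict_model_x(base, x) +
                 restdnn:::predict_model_x(dm$delta, x),
               tolerance = 1e-12)
})

test_that("delta-learning improves under shift but is the less stable route", {
  ex_lora <- cached("variance_lora", {
    run_transfer_experiment(method = "lora_r", molecule_counts = 1L,
                            n_seeds = 5L, seed = 3L)
  })
  base <- ex_lora$base
  ex_res <- run_transfer_experiment(method = "reslora_r",
                                    molecule_counts = 1L, n_seeds = 5L,
                                    seed = 3L, base = base)
  ex_delta <- run_transfer_experiment(method = "delta_ml",
                                      molecule_counts = 1L, n_seeds = 5L,
                                      seed = 3L, base = base)
  # delta-learning does improve over the untuned base...
  expect_lt(stats::median(ex_delta$runs$mae), ex_lora$base_mae_b)
  # ...but tends to spread more across seeds than low-rank transfer; and
  # the inter-block shortcuts tend to damp LoRA's spread. Both orderings
  # are tendencies, not guarantees: report, warn on violation, don't fail.
  v <- vapply(list(lora_r = ex_lora, reslora_r = ex_res,
                   delta_ml = ex_delta),
              function(e) stats::sd(e$runs$mae), numeric(1))
  message(sprintf(
    "seed-to-seed MAE sd: lora_r %.2e, reslora_r %.2e, delta_ml %.2e",
    v["lora_r"], v["reslora_r"], v["delta_ml"]))
  if (v["delta_ml"] <= v["lora_r"]) {
    warning("delta_ml seed variance not larger than lora_r on this fixture")
  }
  if (v["reslora_r"] > v["lora_r"]) {
    warning("reslora_r seed variance larger than lora_r on this fixture")
  }
  succeed()
})

test_that("a perfect base leaves delta-learning near zero", {
  base <- small_trained_base()
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 800, seed = 61, val_fraction = 0.1)
  # labels: exactly what the base predicts -> residuals identically zero
  ds$y <- restdnn:::predict_model_x(base, ds$x)
  spec <- network_spec(ncol(ds$x), n_hidden_layers = 2L, hidden_width = 16L,
                       seed = 3L)
  dm <- suppressWarnings(
    train_delta_ml(base, ds, spec,
                   train_config(epochs = c(150L, 150L, 100L),
                                learning_rates = c(1e-2, 1e-3, 1e-4),
                                repetitions = 1L, seed = 3L)))
  # on its own training inputs the learned correction is tiny compared to
  # the spread of the base predictions
  x <- ds$x[ds$train_mask, , drop = FALSE]
  base_pred <- restdnn:::predict_model_x(base, x)
  dev <- restdnn:::predict_model_x(dm, x) - base_pred
  expect_lt(mean(abs(dev)), 0.2 * stats::sd(base_pred))
})
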