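#' Synthetic small-to-large transfer experiment
#'
#' Scaled stand-in for the fine-tuning study on real systems: a base model
#' is trained on an unshifted regime (A), evaluated on a covariate-shifted
#' regime (B), then fine-tuned with 1, 10, 20, ... regime-B "molecules"
#' under several seeds. Reports per-pair MAEs on a held-out regime-B test
#' set for the untuned base and each (molecule count, seed) fine-tuning run.
#'
#' @param method fine-tuning method passed to [make_tuned_model()] (or
#'   `"delta_ml"`).
#' @param rank LoRA rank.
#' @param molecule_counts numbers of fine-tuning molecules.
#' @param n_seeds fine-tuning repetitions with distinct seeds.
#' @param base_regime regime A; regime B is `shifted_regime(base_regime)`.
#' @param tail_weight,mean_scale shift applied to obtain regime B.
#' @param n_train_pairs regime-A training pairs for the base model.
#' @param pairs_per_molecule pairs per synthetic molecule.
#' @param n_test_pairs regime-B test pairs.
#' @param spec network architecture (default 10x50 on the regime's input
#'   dimension).
#' @param base_hyper base-model training config.
#' @param ft_epochs,ft_lrs,ft_batch fine-tuning schedule.
#' @param seed master seed; all dataset and training seeds derive from it.
#' @param base one of `NULL` (train here) or a pretrained `base_model` on
#'   regime A with matching architecture (reused across method comparisons).
#' @return list with `base_mae_a`, `base_mae_b` (Hartree), `runs` (data
#'   frame: n_molecules, seed, mae), `median_by_count`, and the trained
#'   `base` model.
#' @export
run_transfer_experiment <- function(method = "lora_r", rank = 1L,
                                    molecule_counts = c(1L, 10L, 20L),
                                    n_seeds = 5L,
                                    base_regime = synthetic_regime(),
                                    tail_weight = 0.3, mean_scale = 0.7,
                                    n_train_pairs = 1200L,
                                    pairs_per_molecule = 256L,
                                    n_test_pairs = 400L,
                                    spec = NULL,
                                    base_hyper = NULL,
                                    ft_epochs = c(100L, 400L),
                                    ft_lrs = c(1e-3, 1e-4),
                                    ft_batch = 128L,
                                    seed = 1L,
                                    base = NULL) {
  regime_b <- shifted_regime(base_regime, tail_weight = tail_weight,
                             mean_scale = mean_scale)
  input_dim <- 4L * base_regime$n_osv^2
  if (is.null(spec)) spec <- network_spec(input_dim)
  if (is.null(base_hyper)) {
    base_hyper <- train_config(epochs = c(500L, 500L),
                               learning_rates = c(1e-3, 1e-4),
                               repetitions = 1L, seed = seed * 1000L + 1L)
  }
  train_a <- synthetic_pair_dataset(base_regime, n_train_pairs,
                                    seed = seed * 1000L + 2L,
                                    val_fraction = 0.1)
  test_a <- synthetic_pair_dataset(base_regime, n_test_pairs,
                                   seed = seed * 1000L + 3L)
  test_b <- synthetic_pair_dataset(regime_b, n_test_pairs,
                                   seed = seed * 1000L + 4L)
  if (is.null(base)) {
    base <- train_pair_model(train_a, spec, base_hyper, role = "offdiagonal")
  }
  mae_of <- function(model, ds) {
    mean(abs(predict_model_x(model, ds$x) - ds$y))
  }
  base_mae_a <- mae_of(base, test_a)
  base_mae_b <- mae_of(base, test_b)
  runs <- data.frame()
  for (cnt in molecule_counts) {
    for (s in seq_len(n_seeds)) {
      ft_seed <- seed * 1000L + 10L * cnt + s
      ft_data <- synthetic_molecule_set(regime_b, cnt, pairs_per_molecule,
                                        seed = ft_seed)
      tuned <- if (method == "delta_ml") {
        dspec <- spec; dspec$seed <- ft_seed
        train_delta_ml(base, ft_data, dspec,
                       train_config(epochs = ft_epochs,
                                    learning_rates = c(1e-3, 1e-4),
                                    batch_size = ft_batch,
                                    repetitions = 1L, seed = ft_seed))
      } else {
        fts <- finetune_spec(method = method, rank = rank,
                             epochs = ft_epochs, learning_rates = ft_lrs,
                             batch_size = ft_batch, seed = ft_seed)
        finetune(make_tuned_model(base, fts), ft_data, fts)
      }
      runs <- rbind(runs, data.frame(n_molecules = cnt, seed = s,
                                     mae = mae_of(tuned, test_b)))
    }
  }
  med <- stats::aggregate(mae ~ n_molecules, data = runs, FUN = stats::median)
  list(method = method, base = base,
       base_mae_a = base_mae_a, base_mae_b = base_mae_b,
       runs = runs, median_by_count = med)
}
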