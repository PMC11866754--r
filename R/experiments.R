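#' End-to-end conformer learning experiment
#'
#' The full pipeline at desk scale: perturbed conformers of a base geometry
#' are featurized and labeled with exact MP2 pair energies, the two pair
#' models are trained on a conformer subset, and held-out conformers'
#' correlation energies are predicted. The reference baseline predicts the
#' mean training-set correlation energy for every held-out conformer.
#'
#' @param base_geometry a [geometry()] (default: the bundled water monomer).
#' @param n_conformers total conformers.
#' @param n_test held-out conformers.
#' @param sigma_angstrom thermal displacement scale.
#' @param basis_name basis set.
#' @param n_osv OSVs per LMO.
#' @param spec network architecture; default 3 hidden layers of 24 units on
#'   the feature dimension.
#' @param hyper training config; default 150 + 150 epochs at 1e-3 / 1e-4.
#' @param seed master seed (conformers, splits, training).
#' @return list with `mae_model`, `mae_baseline` (kcal/mol over held-out
#'   conformer correlation energies), per-conformer tables and the trained
#'   models.
#' @export
run_conformer_experiment <- function(base_geometry = NULL,
                                     n_conformers = 30L, n_test = 6L,
                                     sigma_angstrom = 0.02,
                                     basis_name = "sto-3g", n_osv = 2L,
                                     spec = NULL, hyper = NULL, seed = 1L) {
  if (is.null(base_geometry)) {
    base_geometry <- read_xyz(system.file("extdata", "water_monomer.xyz",
                                          package = "restdnn"))
  }
  confs <- perturbed_conformers(base_geometry, n_conformers, sigma_angstrom,
                                seed = seed)
  mols <- lapply(confs, function(g) {
    fs <- featurize_molecule(g, basis_name, n_osv = n_osv)
    labels <- lmo_pair_energies(fs$scf, fs$lmos)
    list(features = fs, labels = labels, e_corr = attr(labels, "e_corr"))
  })
  test_idx <- with_local_seed(seed + 1L,
                              sample.int(n_conformers, n_test))
  is_test <- seq_len(n_conformers) %in% test_idx
  gather <- function(idx, diagonal) {
    feats <- list(); labs <- numeric(0)
    for (m in mols[idx]) {
      keep <- vapply(m$features$features,
                     function(f) f$is_diagonal == diagonal, logical(1))
      fs <- m$features$features[keep]
      key <- pair_label(m$labels$i, m$labels$j)
      labs <- c(labs, vapply(fs, function(f) {
        m$labels$e_ij[match(pair_label(f$i, f$j), key)]
      }, numeric(1)))
      feats <- c(feats, fs)
    }
    pair_dataset(feats, labs, val_fraction = 0.1, seed = seed + 2L)
  }
  diag_data <- gather(which(!is_test), TRUE)
  offdiag_data <- gather(which(!is_test), FALSE)
  if (is.null(spec)) {
    spec <- network_spec(ncol(diag_data$x), n_hidden_layers = 3L,
                         hidden_width = 24L, seed = seed)
  }
  if (is.null(hyper)) {
    hyper <- train_config(epochs = c(150L, 150L),
                          learning_rates = c(1e-3, 1e-4),
                          batch_size = 32L, repetitions = 1L, seed = seed)
  }
  models <- train_base(diag_data, offdiag_data, spec, hyper)
  e_ref <- vapply(mols, `[[`, numeric(1), "e_corr")
  e_pred <- vapply(mols, function(m) {
    predict_total(predict_pairs(models$diagonal, models$offdiagonal,
                                m$features))$e_corr
  }, numeric(1))
  baseline <- mean(e_ref[!is_test])
  rep_model <- mae_report(e_pred[is_test], e_ref[is_test],
                          system = which(is_test))
  rep_base <- mae_report(rep(baseline, n_test), e_ref[is_test],
                         system = which(is_test))
  list(mae_model = rep_model$mae, mae_baseline = rep_base$mae,
       table = rep_model$table, models = models,
       e_pred = e_pred, e_ref = e_ref, test_idx = sort(test_idx))
}
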