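# Shared fixtures: small water geometries and lazily cached mean-field /
# localization / featurization results so expensive quantum steps run once
# per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

water_monomer_geom <- function() {
  geometry(c("O", "H", "H"),
           matrix(c(0, 0, 0.1173,
                    0, 0.7572, -0.4696,
                    0, -0.7572, -0.4696), 3, 3, byrow = TRUE))
}

water_dimer_geom <- function(separation = NULL) {
  coords <- matrix(c(-1.551007, -0.114520, 0.000000,
                     -1.934259, 0.762503, 0.000000,
                     -0.599677, 0.040712, 0.000000,
                     1.350625, 0.111469, 0.000000,
                     1.680398, -0.373741, -0.758561,
                     1.680398, -0.373741, 0.758561), 6, 3, byrow = TRUE)
  if (!is.null(separation)) {
    coords[4:6, 1] <- coords[4:6, 1] + separation
  }
  geometry(rep(c("O", "H", "H"), 2), coords)
}

h2_geom <- function() {
  geometry(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 0.7414), 2, 3, byrow = TRUE))
}

scf_monomer_sto3g <- function() cached("scf_m_sto", {
  run_mean_field(water_monomer_geom(), "sto-3g")
})
scf_monomer_631g <- function() cached("scf_m_631", {
  run_mean_field(water_monomer_geom(), "6-31g")
})
scf_dimer_sto3g <- function() cached("scf_d_sto", {
  run_mean_field(water_dimer_geom(), "sto-3g")
})
lmos_monomer_sto3g <- function() cached("lmo_m_sto", {
  localize_occupied(scf_monomer_sto3g())
})
lmos_monomer_631g <- function() cached("lmo_m_631", {
  localize_occupied(scf_monomer_631g())
})
lmos_dimer_sto3g <- function() cached("lmo_d_sto", {
  localize_occupied(scf_dimer_sto3g())
})

# small trained base model on synthetic data, shared by fine-tuning and
# analysis tests
small_trained_base <- function() cached("small_base", {
  reg <- synthetic_regime()
  ds <- synthetic_pair_dataset(reg, 300, seed = 5, val_fraction = 0.1)
  spec <- network_spec(ncol(ds$x), n_hidden_layers = 3L, hidden_width = 16L,
                       seed = 2L)
  train_pair_model(ds, spec,
                   train_config(epochs = c(30L, 30L),
                                learning_rates = c(1e-3, 1e-4),
                                repetitions = 1L, seed = 3L),
                   role = "offdiagonal")
})
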