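test_that("semicanonical diagonal amplitudes match a brute-force loop", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  i <- 2L
  t_fast <- diagonal_semicanonical_amplitudes(scf, lmos, i, k_ovov)
  nv <- scf$n_virt
  f_ii <- lmos$fock_lmo[i, i]
  t_loop <- matrix(0, nv, nv)
  for (a in seq_len(nv)) {
    for (b in seq_len(nv)) {
      t_loop[a, b] <- -k_ovov[i, a, i, b] /
        (scf$eps_virt[a] + scf$eps_virt[b] - 2 * f_ii)
    }
  }
  expect_lt(max(abs(t_fast - t_loop)), 1e-12)
  expect_lt(max(abs(t_fast - t(t_fast))), 1e-12)
})

test_that("OSV domains: orthonormality, ordering, dense-SVD agreement", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  t11 <- diagonal_semicanonical_amplitudes(scf, lmos, 1L)
  dom <- build_osv_domain(t11, 4L, scf, lmos, 1L)
  expect_lt(max(abs(crossprod(dom$q) - diag(4))), 1e-10)
  expect_true(all(diff(dom$singular_values) <= 1e-12))
  expect_equal(dom$singular_values, svd(t11)$d[1:4], tolerance = 1e-10)
  expect_error(build_osv_domain(t11, scf$n_virt + 1L, scf, lmos, 1L),
               "n_osv")
})

test_that("full-rank SVD reconstructs the amplitude matrix", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  t11 <- diagonal_semicanonical_amplitudes(scf, lmos, 1L)
  dec <- svd(t11)
  expect_lt(max(abs(dec$u %*% diag(dec$d) %*% t(dec$v) - t11)), 1e-10)
})

test_that("rank-1 amplitudes give exactly one significant singular value", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  v <- seq_len(scf$n_virt) / scf$n_virt
  t_rank1 <- outer(v, v)
  dom <- build_osv_domain(t_rank1, scf$n_virt, scf, lmos, 1L)
  expect_gt(dom$singular_values[1], 0.1)
  expect_lt(max(dom$singular_values[-1]), 1e-12)
  # leading vector spans v
  expect_lt(min(max(abs(dom$q[, 1] - v / sqrt(sum(v^2)))),
                max(abs(dom$q[, 1] + v / sqrt(sum(v^2))))), 1e-10)
})

test_that("pair screening keeps diagonal pairs and drops orthogonal domains", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  t11 <- diagonal_semicanonical_amplitudes(scf, lmos, 1L)
  dom1 <- build_osv_domain(t11, 4L, scf, lmos, 1L)
  expect_true(pair_keep_decision(dom1, dom1, scf, cutoff = 0.5))
  # orthogonal OSV spaces: zero cross-overlap block
  dom2 <- dom1
  dom2$lmo_index <- 2L
  set.seed(11); dom2$q <- svd(matrix(stats::rnorm(64), 8))$u[, 5:8]  # orthocomplement-ish
  dom2$q <- dom2$q - dom1$q %*% crossprod(dom1$q, dom2$q)
  dom2$q <- qr.Q(qr(dom2$q))
  expect_false(pair_keep_decision(dom1, dom2, scf, cutoff = 1e-12))
})

test_that("remote inter-fragment pairs are screened out (brute force)", {
  far <- water_dimer_geom(separation = 48)
  fs <- featurize_molecule(far, "sto-3g", n_osv = 2L, cutoff = 3.2e-5)
  scf <- fs$scf
  n_frag1 <- scf$n_occ / 2  # LMOs sit on one fragment each at 50 Angstrom
  frag_of <- vapply(seq_len(scf$n_occ), function(i) {
    pops <- restdnn:::mulliken_populations(scf, fs$lmos$c_lmo[, i])
    if (which.max(pops) <= 3) 1L else 2L
  }, integer(1))
  inter <- fs$keys[frag_of[fs$keys$i] != frag_of[fs$keys$j], ]
  expect_equal(nrow(inter), 0L)
  # brute-force all-pairs oracle: recompute every keep decision directly
  kept_brute <- data.frame()
  for (i in seq_len(scf$n_occ)) {
    for (j in i:scf$n_occ) {
      if (pair_keep_decision(fs$domains[[i]], fs$domains[[j]], scf,
                             3.2e-5)) {
        kept_brute <- rbind(kept_brute, data.frame(i = i, j = j))
      }
    }
  }
  expect_equal(fs$keys[, c("i", "j")], kept_brute)
})

test_that("identity rotation over the full OSV space returns raw integrals", {
  scf <- scf_monomer_sto3g()
  lmos <- lmos_monomer_sto3g()
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  nv <- scf$n_virt
  dom_id <- structure(list(lmo_index = 1L, q = diag(nv),
                           singular_values = rep(1, nv),
                           fock_osv_diag = scf$eps_virt),
                      class = "osv_domain")
  dom_id2 <- dom_id; dom_id2$lmo_index <- 2L
  kch <- channel_exchange_integrals(scf, lmos, dom_id, dom_id2, k_ovov)
  expect_equal(kch$vt, k_ovov[1, , 2, ], tolerance = 1e-12)
  expect_equal(kch$ex, k_ovov[1, , 2, ], tolerance = 1e-12)
})

test_that("exchange-integral channels match a dense contraction oracle", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  fs <- featurize_molecule(water_monomer_geom(), "6-31g", n_osv = 4L,
                           scf = scf, lmos = lmos)
  di <- fs$domains[[1]]; dj <- fs$domains[[3]]
  kch <- channel_exchange_integrals(scf, lmos, di, dj, k_ovov)
  n <- 4L
  oracle <- matrix(0, n, n)
  for (m in seq_len(n)) {
    for (p in seq_len(n)) {
      oracle[m, p] <- sum(outer(di$q[, m], dj$q[, p]) * k_ovov[1, , 3, ])
    }
  }
  expect_lt(max(abs(kch$vt - oracle)), 1e-12)
  # diagonal pair: all four channels coincide, vt symmetric
  kdd <- channel_exchange_integrals(scf, lmos, di, di, k_ovov)
  expect_equal(kdd$vt, kdd$ex, tolerance = 1e-14)
  expect_equal(kdd$vt, kdd$ct1, tolerance = 1e-14)
  expect_lt(max(abs(kdd$vt - t(kdd$vt))), 1e-12)
})

test_that("pseudo-amplitude arithmetic and degeneracy guard", {
  dom_a <- list(lmo_index = 1L, fock_osv_diag = 0.5)
  dom_b <- list(lmo_index = 2L, fock_osv_diag = 0.5)
  kch <- list(vt = matrix(-0.1), ex = matrix(-0.1),
              ct1 = matrix(-0.1), ct2 = matrix(-0.1))
  tch <- channel_pseudo_amplitudes(kch, f_ii = -0.5, f_jj = -0.5,
                                   dom_a, dom_b)
  # gap = 0.5 + 0.5 - (-0.5) - (-0.5) = 2; t = -(-0.1)/2
  expect_equal(tch$vt[1, 1], 0.05, tolerance = 1e-15)
  zero <- list(vt = matrix(0), ex = matrix(0), ct1 = matrix(0),
               ct2 = matrix(0))
  expect_equal(channel_pseudo_amplitudes(zero, -0.5, -0.5, dom_a,
                                         dom_b)$vt[1, 1], 0)
  dg <- list(lmo_index = 3L, fock_osv_diag = -0.5)
  expect_error(channel_pseudo_amplitudes(kch, -0.5, -0.5, dg, dg),
               "near-degenerate")
})

test_that("pseudo-amplitudes are exact when the Fock matrix is OSV-diagonal", {
  # synthetic one-pair fixture with a diagonal virtual Fock: the
  # semicanonical form is then the exact first-order amplitude equation
  n <- 3L
  f_osv <- c(0.4, 0.7, 1.1)
  f_ii <- -0.6; f_jj <- -0.4
  set.seed(4); k <- matrix(stats::rnorm(n * n, 0, 0.05), n, n)
  dom_i <- list(lmo_index = 1L, fock_osv_diag = f_osv)
  dom_j <- list(lmo_index = 2L, fock_osv_diag = f_osv)
  kch <- list(vt = k, ex = t(k), ct1 = k, ct2 = k)
  tch <- channel_pseudo_amplitudes(kch, f_ii, f_jj, dom_i, dom_j)
  t_exact <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      t_exact[a, b] <- -k[a, b] / (f_osv[a] + f_osv[b] - f_ii - f_jj)
    }
  }
  expect_lt(max(abs(tch$vt - t_exact)), 1e-14)
})

test_that("feature tensor: symmetry, loop oracle, and channel order", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  fs <- featurize_molecule(water_monomer_geom(), "6-31g", n_osv = 4L,
                           scf = scf, lmos = lmos)
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  di <- fs$domains[[2]]; dj <- fs$domains[[4]]
  kch <- channel_exchange_integrals(scf, lmos, di, dj, k_ovov)
  tch <- channel_pseudo_amplitudes(kch, lmos$fock_lmo[2, 2],
                                   lmos$fock_lmo[4, 4], di, dj)
  pf <- pair_feature_tensor(kch, tch, 2L, 4L)
  # loop-nest oracle for the vt channel
  n <- 4L
  for (m in seq_len(n)) {
    for (p in seq_len(n)) {
      cont <- 2 * tch$vt[m, p] - tch$ex[p, m]
      expect_equal(pf$tensor[1, m, p], kch$vt[m, p] * cont,
                   tolerance = 1e-14)
    }
  }
  # symmetric amplitudes: contravariant reduces to the amplitude itself
  tsym <- list(vt = (tch$ct1 + t(tch$ct1)) / 2, ex = (tch$ct1 + t(tch$ct1)) / 2,
               ct1 = (tch$ct1 + t(tch$ct1)) / 2,
               ct2 = (tch$ct1 + t(tch$ct1)) / 2)
  pf2 <- pair_feature_tensor(kch, tsym, 2L, 2L)
  expect_equal(pf2$tensor[3, , ], kch$ct1 * tsym$ct1, tolerance = 1e-14)
})

test_that("feature tensors are gauge invariant under OSV sign flips", {
  scf <- scf_monomer_631g()
  lmos <- lmos_monomer_631g()
  fs <- featurize_molecule(water_monomer_geom(), "6-31g", n_osv = 4L,
                           scf = scf, lmos = lmos)
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  di <- fs$domains[[1]]; dj <- fs$domains[[3]]
  flip <- function(dom, cols) {
    dom$q[, cols] <- -dom$q[, cols]
    dom
  }
  for (flip_cols in list(1L, c(2L, 4L), 1:4)) {
    di2 <- flip(di, flip_cols)
    dj2 <- flip(dj, c(1L, 3L))
    build <- function(a, b) {
      kch <- channel_exchange_integrals(scf, lmos, a, b, k_ovov)
      tch <- channel_pseudo_amplitudes(kch, lmos$fock_lmo[1, 1],
                                       lmos$fock_lmo[3, 3], a, b)
      pair_feature_tensor(kch, tch, 1L, 3L)$tensor
    }
    expect_lt(max(abs(build(di, dj) - build(di2, dj2))), 1e-12)
  }
})

test_that("featurize_molecule is deterministic and counts pairs correctly", {
  fs1 <- featurize_molecule(water_monomer_geom(), "sto-3g", n_osv = 2L)
  fs2 <- featurize_molecule(water_monomer_geom(), "sto-3g", n_osv = 2L)
  no <- fs1$scf$n_occ
  expect_equal(nrow(fs1$keys), no * (no + 1) / 2)  # nothing screened
  expect_identical(lapply(fs1$features, `[[`, "tensor"),
                   lapply(fs2$features, `[[`, "tensor"))
})

test_that("kept pairs at a looser cutoff are a superset of a tighter one", {
  far <- water_dimer_geom(separation = 3)
  scf <- run_mean_field(far, "sto-3g")
  lmos <- localize_occupied(scf)
  keys_of <- function(cutoff) {
    fs <- featurize_molecule(far, "sto-3g", n_osv = 2L, cutoff = cutoff,
                             scf = scf, lmos = lmos)
    restdnn:::pair_label(fs$keys$i, fs$keys$j)
  }
  loose <- keys_of(1e-6)
  mid <- keys_of(3.2e-5)
  tight <- keys_of(1e-2)
  expect_true(all(tight %in% mid))
  expect_true(all(mid %in% loose))
})

test_that("diagonal vt-channel sums track exact pair energies", {
  confs <- perturbed_conformers(water_monomer_geom(), 6, 0.02, seed = 7)
  s_vt <- numeric(0); e_diag <- numeric(0)
  for (g in confs) {
    fs <- featurize_molecule(g, "sto-3g", n_osv = 2L)
    tab <- lmo_pair_energies(fs$scf, fs$lmos)
    dd <- Filter(function(f) f$is_diagonal, fs$features)
    s_vt <- c(s_vt, vapply(dd, function(f) sum(f$tensor[1, , ]), numeric(1)))
    e_diag <- c(e_diag, tab$e_ij[tab$i == tab$j])
  }
  expect_true(all(s_vt < 0))  # bound system: crude pair-energy estimates
  expect_gte(suppressWarnings(stats::cor(s_vt, e_diag, method = "spearman")),
             0.8)
})
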