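#' Run a restricted Hartree-Fock mean field
#'
#' Converges an RHF wavefunction for a closed-shell molecule and packages all
#' mean-field quantities the OSV featurizer and the MP2 oracle need: orbital
#' coefficient blocks, canonical orbital energies, AO Fock and overlap
#' matrices, and an MO integral provider. All energies are in Hartree.
#'
#' @param geom a [geometry()].
#' @param basis_name basis-set name, see [available_bases()].
#' @param frozen_core freeze the standard chemical core (1s on C, N, O)?
#' @param conv_tol SCF energy convergence threshold (Hartree).
#' @param max_iter maximum SCF iterations.
#' @return an object of class `scf_context` with fields `n_occ` (correlated
#'   occupied count), `n_virt`, `mo_coeff_occ`, `mo_coeff_virt`, `eps_occ`,
#'   `eps_virt`, `fock_ao`, `overlap_ao`, `e_hf`, `frozen_core` and
#'   `eri_provider(c1, c2, c3, c4)` returning chemist's-notation MO integrals.
#' @export
run_mean_field <- function(geom, basis_name = "sto-3g", frozen_core = TRUE,
                           conv_tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(geom, "geometry"))
  if (geom$spin_multiplicity != 1L) {
    stop("only closed-shell (multiplicity 1) systems are supported")
  }
  z <- .element_numbers[geom$atoms]
  n_elec <- sum(z) - geom$charge
  if (n_elec %% 2 != 0) stop("odd electron count for a closed-shell molecule")
  e_nuc <- nuclear_repulsion(geom)  # errors on overlapping atoms

  bas <- build_basis_functions(geom, basis_name)
  fns <- bas$functions
  centers <- geom$coords * BOHR_PER_ANGSTROM
  one <- one_electron_integrals(fns, as.numeric(z), centers)
  S <- one$S
  hcore <- one$T + one$V
  eri <- two_electron_integrals(fns)
  n <- nrow(S)
  n_occ_tot <- n_elec %/% 2L
  if (n_occ_tot > n) stop("basis too small for electron count")

  # symmetric orthogonalizer
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8) stop("AO overlap matrix is near-singular")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)

  eri_mat <- matrix(eri, n * n, n * n)                      # (pq|rs)
  eri_k <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)  # (pr|qs)

  fock_of <- function(D) {
    J <- matrix(eri_mat %*% as.vector(D), n, n)
    K <- matrix(eri_k %*% as.vector(D), n, n)
    hcore + J - 0.5 * K
  }
  solve_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)  # eigen() sorts decreasing; want ascending energy
    list(C = X %*% ef$vectors[, ord, drop = FALSE], eps = ef$values[ord])
  }

  # core-Hamiltonian guess, then DIIS-accelerated iterations
  mo <- solve_fock(hcore)
  C <- mo$C
  D <- 2 * tcrossprod(C[, seq_len(n_occ_tot), drop = FALSE])
  e_old <- Inf
  diis_f <- list(); diis_e <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    F <- fock_of(D)
    err <- F %*% D %*% S - S %*% D %*% F
    diis_f[[length(diis_f) + 1L]] <- F
    diis_e[[length(diis_e) + 1L]] <- err
    if (length(diis_f) > 8L) { diis_f <- diis_f[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_f)
    if (m > 1L) {
      B <- matrix(0, m + 1, m + 1)
      for (a in 1:m) for (b in 1:m) B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        F <- Reduce(`+`, Map(`*`, diis_f, cf))
      }
    }
    mo <- solve_fock(F)
    C <- mo$C
    D <- 2 * tcrossprod(C[, seq_len(n_occ_tot), drop = FALSE])
    F_d <- fock_of(D)
    e_el <- 0.5 * sum(D * (hcore + F_d))
    de <- abs(e_el - e_old)
    rms <- sqrt(mean((F_d %*% D %*% S - S %*% D %*% F_d)^2))
    e_old <- e_el
    if (de < conv_tol && rms < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("SCF did not converge for %s in %d iterations (dE=%.3e)",
                 paste(geom$atoms, collapse = ""), max_iter, de))
  }
  fock_ao <- fock_of(D)
  mo <- solve_fock(fock_ao)
  e_hf <- 0.5 * sum(D * (hcore + fock_ao)) + e_nuc

  n_frozen <- if (frozen_core) sum(z >= 3 & z <= 10) else 0L
  occ_idx <- seq_len(n_occ_tot)
  corr_idx <- occ_idx[occ_idx > n_frozen]
  virt_idx <- seq(n_occ_tot + 1L, n)

  C_all <- mo$C
  ctx <- list(
    n_occ = length(corr_idx),
    n_virt = length(virt_idx),
    frozen_core = as.integer(n_frozen),
    mo_coeff_occ = C_all[, corr_idx, drop = FALSE],
    mo_coeff_virt = C_all[, virt_idx, drop = FALSE],
    eps_occ = mo$eps[corr_idx],
    eps_virt = mo$eps[virt_idx],
    fock_ao = fock_ao,
    hcore_ao = hcore,
    overlap_ao = S,
    e_hf = e_hf,
    e_nuc = e_nuc,
    geometry = geom,
    basis_name = tolower(basis_name),
    atom_of = bas$atom_of,
    eri_ao = eri
  )
  ctx$eri_provider <- function(c1, c2, c3, c4) {
    transform_eri(ctx$eri_ao, c1, c2, c3, c4)
  }
  structure(ctx, class = "scf_context")
}

#' @export
print.scf_context <- function(x, ...) {
  cat(sprintf(paste0("scf_context: %s/%s  E_HF = %.10f Eh\n",
                     "  correlated occ %d (frozen %d), virt %d\n"),
              paste(x$geometry$atoms, collapse = ""), x$basis_name, x$e_hf,
              x$n_occ, x$frozen_core, x$n_virt))
  invisible(x)
}

# Four-index MO transformation of chemist's-notation AO integrals:
# (pq|rs) -> (c1 c2 | c3 c4), one index at a time.
transform_eri <- function(eri_ao, c1, c2, c3, c4) {
  n <- dim(eri_ao)[1]
  contract_first <- function(arr, C) {
    d <- dim(arr)
    out <- crossprod(C, matrix(arr, d[1], prod(d[-1])))
    array(out, c(ncol(C), d[-1]))
  }
  # rotate index 1, then cycle axes so each AO index comes first in turn
  a <- contract_first(eri_ao, c1)
  a <- aperm(a, c(2, 3, 4, 1))
  a <- contract_first(a, c2)
  a <- aperm(a, c(2, 3, 4, 1))
  a <- contract_first(a, c3)
  a <- aperm(a, c(2, 3, 4, 1))
  a <- contract_first(a, c4)
  aperm(a, c(2, 3, 4, 1))
}
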