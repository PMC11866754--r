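#' Diagonal semicanonical MP2 amplitudes for one LMO
#'
#' \deqn{t_{ii}^{ab} = -\frac{(ia|ib)}{\epsilon_a + \epsilon_b - 2 f_{ii}}}
#' with canonical virtual energies \eqn{\epsilon_a} and the diagonal LMO
#' Fock element \eqn{f_{ii}}. The SVD of this matrix defines the OSV space
#' of LMO `i`.
#'
#' @param scf an `scf_context`.
#' @param lmos a `localized_orbitals` from the same context.
#' @param i LMO index (1-based).
#' @param k_ovov optional precomputed `(i a | j b)` array over LMOs and
#'   canonical virtuals (from [lmo_virtual_integrals()]); avoids repeated
#'   transforms.
#' @return symmetric `n_virt x n_virt` amplitude matrix.
#' @export
diagonal_semicanonical_amplitudes <- function(scf, lmos, i, k_ovov = NULL) {
  stopifnot(i >= 1, i <= scf$n_occ)
  if (is.null(k_ovov)) k_ovov <- lmo_virtual_integrals(scf, lmos)
  k_ii <- k_ovov[i, , i, ]
  f_ii <- lmos$fock_lmo[i, i]
  denom <- outer(scf$eps_virt, scf$eps_virt, `+`) - 2 * f_ii
  if (min(abs(denom)) < 1e-10) {
    stop("near-degenerate denominator in semicanonical amplitudes for LMO ", i)
  }
  t_ii <- -k_ii / denom
  (t_ii + t(t_ii)) / 2
}

#' MO integrals (i a | j b) over LMOs and canonical virtuals
#' @param scf an `scf_context`.
#' @param lmos a `localized_orbitals`.
#' @return array indexed `[i, a, j, b]` (chemist's notation, Hartree).
#' @export
lmo_virtual_integrals <- function(scf, lmos) {
  scf$eri_provider(lmos$c_lmo, scf$mo_coeff_virt,
                   lmos$c_lmo, scf$mo_coeff_virt)
}

#' Build the OSV domain of one LMO
#'
#' SVD of the diagonal semicanonical amplitudes; the `n_osv` singular vectors
#' of largest singular value rotate the canonical virtual space into the
#' compact orbital-specific virtual basis. Deterministic convention: columns
#' ordered by descending singular value and each vector's sign fixed so its
#' first significant component is positive.
#'
#' @param t_ii amplitude matrix from [diagonal_semicanonical_amplitudes()].
#' @param n_osv number of OSVs to retain (1..n_virt).
#' @param scf an `scf_context`.
#' @param lmos a `localized_orbitals`.
#' @param lmo_index which LMO this domain belongs to.
#' @return an `osv_domain` with `q` (n_virt x n_osv rotation),
#'   `singular_values` (descending) and `fock_osv_diag` (Hartree).
#' @export
build_osv_domain <- function(t_ii, n_osv, scf, lmos, lmo_index) {
  n_virt <- nrow(t_ii)
  if (n_osv < 1 || n_osv > n_virt) {
    stop("n_osv must be between 1 and n_virt = ", n_virt)
  }
  dec <- svd(t_ii)
  ord <- order(-dec$d)
  q <- dec$u[, ord[seq_len(n_osv)], drop = FALSE]
  for (m in seq_len(ncol(q))) {
    k <- which(abs(q[, m]) > 1e-8)[1]
    if (is.na(k)) k <- which.max(abs(q[, m]))
    if (q[k, m] < 0) q[, m] <- -q[, m]
  }
  # virtual-block Fock is diagonal with entries eps_virt (canonical virtuals)
  fock_osv_diag <- colSums(q^2 * scf$eps_virt)
  structure(list(lmo_index = lmo_index, q = q,
                 singular_values = dec$d[ord][seq_len(n_osv)],
                 fock_osv_diag = fock_osv_diag),
            class = "osv_domain")
}

#' @export
print.osv_domain <- function(x, ...) {
  cat(sprintf("osv_domain for LMO %d: %d OSVs, leading singular value %.3e\n",
              x$lmo_index, ncol(x$q), x$singular_values[1]))
  invisible(x)
}

#' Decide whether an orbital pair is kept
#'
#' Off-diagonal pairs are screened on the OSV cross-overlap block
#' \eqn{q_i^T S_{virt} q_j}; the pair is kept when the chosen overlap
#' statistic reaches `cutoff`. Diagonal pairs are always kept.
#'
#' @param dom_i,dom_j `osv_domain`s built from the same context.
#' @param scf the shared `scf_context`.
#' @param cutoff screening threshold (default the tight value 3.2e-5).
#' @param statistic `"max_sv"` (largest singular value, default) or
#'   `"frobenius"` (Frobenius norm of the block).
#' @return logical.
#' @export
pair_keep_decision <- function(dom_i, dom_j, scf, cutoff = 3.2e-5,
                               statistic = c("max_sv", "frobenius")) {
  statistic <- match.arg(statistic)
  if (dom_i$lmo_index == dom_j$lmo_index) return(TRUE)
  s_virt <- crossprod(scf$mo_coeff_virt, scf$overlap_ao %*% scf$mo_coeff_virt)
  m <- crossprod(dom_i$q, s_virt %*% dom_j$q)
  val <- switch(statistic,
                max_sv = svd(m, nu = 0, nv = 0)$d[1],
                frobenius = sqrt(sum(m^2)))
  val >= cutoff
}

#' OSV-basis exchange integrals for one pair (four channels)
#'
#' Rotates the canonical-virtual integral block \eqn{(ia|jb)} into the OSV
#' bases of the pair. Channel order and OSV index pattern:
#' `vt` \eqn{(i\bar\mu_i | j\bar\nu_j)}, `ex` \eqn{(i\bar\mu_j | j\bar\nu_i)},
#' `ct1` \eqn{(i\bar\mu_i | j\bar\nu_i)}, `ct2`
#' \eqn{(i\bar\mu_j | j\bar\nu_j)}.
#'
#' @inheritParams diagonal_semicanonical_amplitudes
#' @param dom_i,dom_j the pair's `osv_domain`s.
#' @return named list of four `n_osv x n_osv` matrices
#'   `(vt, ex, ct1, ct2)`.
#' @export
channel_exchange_integrals <- function(scf, lmos, dom_i, dom_j,
                                       k_ovov = NULL) {
  if (is.null(k_ovov)) k_ovov <- lmo_virtual_integrals(scf, lmos)
  i <- dom_i$lmo_index; j <- dom_j$lmo_index
  k_ij <- k_ovov[i, , j, ]                       # rows a (for i), cols b (j)
  qi <- dom_i$q; qj <- dom_j$q
  list(vt  = crossprod(qi, k_ij %*% qj),
       ex  = crossprod(qj, k_ij %*% qi),
       ct1 = crossprod(qi, k_ij %*% qi),
       ct2 = crossprod(qj, k_ij %*% qj))
}

#' OSV-basis pseudo-amplitudes for one pair (four channels)
#'
#' Semicanonical MP2-like amplitudes in the pair's OSV bases,
#' \deqn{\tilde t = -\tilde K / (f_{\bar\mu\bar\mu} + f_{\bar\nu\bar\nu}
#'   - f_{ii} - f_{jj}),}
#' with the two OSV Fock diagonals drawn from the domains matching each
#' channel's OSV index pattern. The denominator is the positive
#' particle-hole excitation gap, the same sign convention as the diagonal
#' semicanonical amplitudes, so that the resulting pseudo-energy tensor sums
#' to a (crude) approximation of the negative pair correlation energy.
#'
#' @param k_channels output of [channel_exchange_integrals()].
#' @param f_ii,f_jj diagonal LMO Fock elements (Hartree).
#' @param dom_i,dom_j the pair's `osv_domain`s.
#' @return named list of four matrices `(vt, ex, ct1, ct2)`.
#' @export
channel_pseudo_amplitudes <- function(k_channels, f_ii, f_jj, dom_i, dom_j) {
  fi <- dom_i$fock_osv_diag; fj <- dom_j$fock_osv_diag
  denoms <- list(vt  = outer(fi, fj, `+`) - f_ii - f_jj,
                 ex  = outer(fj, fi, `+`) - f_ii - f_jj,
                 ct1 = outer(fi, fi, `+`) - f_ii - f_jj,
                 ct2 = outer(fj, fj, `+`) - f_ii - f_jj)
  out <- lapply(names(denoms), function(ch) {
    d <- denoms[[ch]]
    if (min(abs(d)) < 1e-10) {
      stop("near-degenerate pseudo-amplitude denominator in channel ", ch)
    }
    -k_channels[[ch]] / d
  })
  names(out) <- names(denoms)
  out
}

#' Four-channel pseudo-energy feature tensor for one pair
#'
#' Per channel the Hadamard product of the exchange integrals with the
#' contravariant pseudo-amplitudes \eqn{2\tilde T - \tilde T^\dagger}. The
#' transpose partner follows the OSV index pattern: swapping the two OSV
#' indices of `vt` yields the `ex` pattern (and vice versa), while `ct1` and
#' `ct2` transpose within themselves.
#'
#' @param k_channels,t_channels outputs of [channel_exchange_integrals()] and
#'   [channel_pseudo_amplitudes()].
#' @param i,j LMO indices of the pair (metadata).
#' @return a `pair_feature`: list with `i`, `j`, `is_diagonal` and `tensor`,
#'   a `(4, n_osv, n_osv)` array in channel order `(vt, ex, ct1, ct2)`.
#' @export
pair_feature_tensor <- function(k_channels, t_channels, i = NA_integer_,
                                j = NA_integer_) {
  tc <- list(vt  = 2 * t_channels$vt  - t(t_channels$ex),
             ex  = 2 * t_channels$ex  - t(t_channels$vt),
             ct1 = 2 * t_channels$ct1 - t(t_channels$ct1),
             ct2 = 2 * t_channels$ct2 - t(t_channels$ct2))
  n <- nrow(k_channels$vt)
  tensor <- array(0.0, c(4, n, n))
  for (c_idx in seq_along(osv_channel_order)) {
    ch <- osv_channel_order[c_idx]
    tensor[c_idx, , ] <- k_channels[[ch]] * tc[[ch]]
  }
  stopifnot(all(is.finite(tensor)))
  structure(list(i = as.integer(i), j = as.integer(j),
                 is_diagonal = isTRUE(i == j), tensor = tensor),
            class = "pair_feature")
}

#' Fixed channel ordering of the feature tensor
#' @export
osv_channel_order <- c("vt", "ex", "ct1", "ct2")

#' Featurize a molecule end to end
#'
#' Runs (or reuses) the mean field, localizes the occupied orbitals, builds
#' per-LMO OSV domains, screens orbital pairs, and emits the four-channel
#' pseudo-energy tensor for every kept pair. Deterministic for a fixed
#' geometry, basis, `n_osv`, `cutoff` and the package's ordering conventions.
#'
#' @param geom a [geometry()].
#' @param basis_name basis-set name.
#' @param n_osv OSVs retained per LMO (default 8, clipped at `n_virt`).
#' @param cutoff pair-screening threshold.
#' @param frozen_core freeze chemical core orbitals?
#' @param statistic pair-screening statistic, see [pair_keep_decision()].
#' @param scf,lmos optionally reuse precomputed mean-field/localization
#'   results.
#' @return a `pair_feature_set`: list with `features` (list of
#'   `pair_feature`), `keys` (data frame `i`, `j`, `is_diagonal` of kept
#'   pairs), `meta`, and the underlying `scf` and `lmos`.
#' @export
featurize_molecule <- function(geom, basis_name = "sto-3g", n_osv = 8L,
                               cutoff = 3.2e-5, frozen_core = TRUE,
                               statistic = "max_sv", scf = NULL,
                               lmos = NULL) {
  if (is.null(scf)) {
    scf <- run_mean_field(geom, basis_name, frozen_core = frozen_core)
  }
  if (is.null(lmos)) lmos <- localize_occupied(scf)
  n_osv <- as.integer(min(n_osv, scf$n_virt))
  k_ovov <- lmo_virtual_integrals(scf, lmos)
  domains <- lapply(seq_len(scf$n_occ), function(i) {
    t_ii <- diagonal_semicanonical_amplitudes(scf, lmos, i, k_ovov)
    build_osv_domain(t_ii, n_osv, scf, lmos, i)
  })
  features <- list()
  keys <- data.frame(i = integer(0), j = integer(0), is_diagonal = logical(0))
  for (i in seq_len(scf$n_occ)) {
    for (j in i:scf$n_occ) {
      if (!pair_keep_decision(domains[[i]], domains[[j]], scf, cutoff,
                              statistic)) {
        next
      }
      kch <- channel_exchange_integrals(scf, lmos, domains[[i]],
                                        domains[[j]], k_ovov)
      tch <- channel_pseudo_amplitudes(kch, lmos$fock_lmo[i, i],
                                       lmos$fock_lmo[j, j], domains[[i]],
                                       domains[[j]])
      features[[length(features) + 1L]] <- pair_feature_tensor(kch, tch, i, j)
      keys <- rbind(keys,
                    data.frame(i = i, j = j, is_diagonal = (i == j)))
    }
  }
  structure(list(features = features, keys = keys,
                 meta = list(basis = scf$basis_name, n_osv = n_osv,
                             cutoff = cutoff, statistic = statistic,
                             frozen_core = scf$frozen_core,
                             channel_order = osv_channel_order,
                             flattening = "channel-major, then row-major"),
                 scf = scf, lmos = lmos, domains = domains),
            class = "pair_feature_set")
}

#' @export
print.pair_feature_set <- function(x, ...) {
  cat(sprintf("pair_feature_set: %d kept pairs (%d diagonal), n_osv = %d, %s\n",
              nrow(x$keys), sum(x$keys$is_diagonal), x$meta$n_osv,
              x$meta$basis))
  invisible(x)
}

# flatten a (4, n, n) tensor channel-major then row-major; fixed, versioned
# ordering shared by the dataset container and the network input layer
flatten_feature <- function(tensor) {
  n <- dim(tensor)[2]
  as.numeric(aperm(tensor, c(3, 2, 1)))  # fastest: col, then row, then channel
}
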