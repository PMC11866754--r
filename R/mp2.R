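#' Canonical MP2 correlation energy
#'
#' Exact second-order correlation energy over the correlated occupied space,
#' \deqn{E_c = \sum_{ijab} \frac{(ia|jb)[2(ia|jb) - (ib|ja)]}
#'   {\epsilon_i + \epsilon_j - \epsilon_a - \epsilon_b}.}
#' Serves as the exact-label oracle for the pair-energy decomposition.
#'
#' @param scf an `scf_context`.
#' @return list with `e_corr` (Hartree), `t2` and `k` arrays indexed
#'   `[i, a, j, b]` over canonical occupied/virtual orbitals.
#' @export
canonical_mp2 <- function(scf) {
  stopifnot(inherits(scf, "scf_context"))
  k <- scf$eri_provider(scf$mo_coeff_occ, scf$mo_coeff_virt,
                        scf$mo_coeff_occ, scf$mo_coeff_virt)
  no <- scf$n_occ; nv <- scf$n_virt
  denom <- outer(scf$eps_occ, -scf$eps_virt, `+`)       # eps_i - eps_a
  denom4 <- outer(denom, denom, `+`)                    # [i,a,j,b]
  if (min(abs(denom4)) < 1e-8) {
    stop("near-degenerate occupied-virtual gap; MP2 denominator vanishes")
  }
  t2 <- k / denom4
  e_corr <- sum(t2 * (2 * k - aperm(k, c(1, 4, 3, 2))))
  list(e_corr = e_corr, t2 = t2, k = k)
}

#' Exact LMO pair correlation energies
#'
#' Rotates the canonical MP2 amplitude and integral tensors into the
#' localized occupied basis and accumulates the exact per-pair contributions
#' \eqn{e_{ij}}. Invariance of MP2 under occupied rotations guarantees
#' \eqn{\sum_{i \le j} e_{ij} = E_c} (off-diagonal entries carry the summed
#' ij + ji contribution).
#'
#' @param scf an `scf_context`.
#' @param lmos a `localized_orbitals` from the same context.
#' @return a `pair_energy_table`: data frame with columns `i`, `j` (1-based
#'   LMO indices, i <= j) and `e_ij` (Hartree); attributes `e_corr` and
#'   `level`.
#' @export
lmo_pair_energies <- function(scf, lmos) {
  stopifnot(inherits(lmos, "localized_orbitals"))
  mp2 <- canonical_mp2(scf)
  u <- crossprod(scf$mo_coeff_occ, scf$overlap_ao %*% lmos$c_lmo)
  rot_occ <- function(arr) {
    d <- dim(arr)
    contract1 <- function(a) {
      dd <- dim(a)
      array(crossprod(u, matrix(a, dd[1], prod(dd[-1]))), c(ncol(u), dd[-1]))
    }
    a <- contract1(arr)                       # (k, a, j, b)
    a <- aperm(a, c(3, 4, 1, 2))              # (j, b, k, a)
    a <- contract1(a)                         # (l, b, k, a)
    aperm(a, c(3, 4, 1, 2))                   # (k, a, l, b)
  }
  t_l <- rot_occ(mp2$t2)
  k_l <- rot_occ(mp2$k)
  contrib <- k_l * (2 * t_l - aperm(t_l, c(1, 4, 3, 2)))
  e_mat <- apply(contrib, c(1, 3), sum)
  no <- scf$n_occ
  idx <- which(upper.tri(e_mat, diag = TRUE), arr.ind = TRUE)
  e_ij <- ifelse(idx[, 1] == idx[, 2], e_mat[idx],
                 e_mat[idx] + t(e_mat)[idx])
  pair_energy_table(data.frame(i = idx[, 1], j = idx[, 2], e_ij = e_ij),
                    e_corr = mp2$e_corr, level = "mp2-internal")
}

#' Construct a pair-energy table
#'
#' @param entries data frame with columns `i`, `j` (i <= j) and `e_ij`
#'   (Hartree; off-diagonal entries carry the full two-sided ij + ji weight).
#' @param e_corr total correlation energy (Hartree); defaults to the entry
#'   sum.
#' @param level provenance tag, `"mp2-internal"` or `"external-file"`.
#' @export
pair_energy_table <- function(entries, e_corr = sum(entries$e_ij),
                              level = "mp2-internal") {
  stopifnot(all(c("i", "j", "e_ij") %in% names(entries)),
            all(entries$i <= entries$j))
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, e_corr = e_corr, level = level,
            class = c("pair_energy_table", "data.frame"))
}

#' @export
print.pair_energy_table <- function(x, ...) {
  cat(sprintf("pair_energy_table (%s): %d pairs, E_c = %.10f Eh\n",
              attr(x, "level"), nrow(x), attr(x, "e_corr")))
  invisible(x)
}

pair_label <- function(i, j) paste0(i, "_", j)

#' Write a pair-energy table as tab-separated text
#'
#' Columns `i`, `j`, `e_ij_hartree`, followed by a footer line
#' `# E_corr <value>`; full double precision, bit-faithful round trip via
#' [load_external_labels()].
#' @param table a `pair_energy_table`.
#' @param path output path.
#' @export
write_pair_energy_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("i\tj\te_ij_hartree", con)
  writeLines(sprintf("%d\t%d\t%.17g", table$i, table$j, table$e_ij), con)
  writeLines(sprintf("# E_corr\t%.17g", attr(table, "e_corr")), con)
  invisible(path)
}

#' Load an externally computed pair-energy label table
#'
#' Ingests pair energies from higher levels of theory computed elsewhere
#' (e.g. coupled-cluster labels); keys must follow the featurizer's LMO
#' ordering convention.
#'
#' @param path TSV file written in the [write_pair_energy_table()] schema.
#' @return a `pair_energy_table` with level `"external-file"`.
#' @export
load_external_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1 || !startsWith(lines[1], "i\tj")) {
    stop("malformed label table: expected header 'i\\tj\\te_ij_hartree'")
  }
  footer <- grep("^#", lines, value = TRUE)
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0) stop("label table is empty")
  toks <- strsplit(body, "\t")
  df <- data.frame(i = as.integer(vapply(toks, `[[`, "", 1L)),
                   j = as.integer(vapply(toks, `[[`, "", 2L)),
                   e_ij = as.numeric(vapply(toks, `[[`, "", 3L)))
  e_corr <- if (length(footer)) {
    as.numeric(sub(".*\t", "", footer[1]))
  } else {
    sum(df$e_ij)
  }
  pair_energy_table(df, e_corr = e_corr, level = "external-file")
}

#' Check that a label table covers a set of pair keys
#'
#' @param table a `pair_energy_table`.
#' @param keys data frame with columns `i`, `j` (the featurizer's kept pairs).
#' @return invisibly `TRUE`; errors listing the offending pairs otherwise.
#' @export
validate_labels <- function(table, keys) {
  have <- pair_label(table$i, table$j)
  want <- pair_label(keys$i, keys$j)
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("label table is missing pair(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
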