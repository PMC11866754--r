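#' Per-layer Frobenius update ratios
#'
#' For each weight-bearing layer, \eqn{\|\Delta W\|_F / \|W_0\|_F}: the
#' low-rank update \eqn{BA} for LoRA methods, the weight difference for full
#' fine-tuning, and zero for bias-only methods. A final residual-head slot
#' reports \eqn{\|W^R\|_F / \|W_{out,0}\|_F} against the base output layer.
#'
#' @param tuned a `tuned_model`.
#' @return data frame with `layer` (1..n_layers, then `"head"`), `ratio`,
#'   and the pair-type `role` of the base model.
#' @export
layer_frobenius_ratios <- function(tuned) {
  stopifnot(inherits(tuned, "tuned_model"))
  base_net <- tuned$base$net
  nl <- length(base_net$W)
  fro <- function(m) sqrt(sum(m^2))
  ratios <- numeric(nl)
  for (l in seq_len(nl)) {
    w0 <- base_net$W[[l]]
    dw <- if (!is.null(tuned$net$A)) {
      tuned$net$B[[l]] %*% tuned$net$A[[l]]
    } else if (tuned$method == "full") {
      tuned$net$W[[l]] - w0
    } else {
      w0 * 0
    }
    ratios[l] <- fro(dw) / fro(w0)
  }
  head_ratio <- if (!is.null(tuned$net$headW)) {
    fro(tuned$net$headW) / fro(base_net$W[[nl]])
  } else {
    0.0
  }
  data.frame(layer = c(as.character(seq_len(nl)), "head"),
             ratio = c(ratios, head_ratio),
             role = tuned$base$role)
}

#' Pair-error distribution
#'
#' Signed deviations of predicted from reference pair energies, with a
#' kernel density estimate (Scott's bandwidth) and exact summary statistics.
#' A symmetric zero-mean deviation distribution is what lets per-pair errors
#' cancel in the total-energy sum.
#'
#' @param pred data frame from [predict_pairs()] (columns `i`, `j`,
#'   `e_pred`).
#' @param ref a `pair_energy_table` with matching keys.
#' @return an `error_density`: list with `deviations` (Hartree),
#'   `density`, `bandwidth` and `summary` (mean, median, skewness).
#' @export
pair_error_density <- function(pred, ref) {
  key_p <- pair_label(pred$i, pred$j)
  key_r <- pair_label(ref$i, ref$j)
  if (!setequal(key_p, key_r) || length(key_p) != length(key_r)) {
    stop("pair keys of predictions and reference do not match: ",
         paste(union(setdiff(key_p, key_r), setdiff(key_r, key_p)),
               collapse = ", "))
  }
  dev <- pred$e_pred - ref$e_ij[match(key_p, key_r)]
  dens <- if (length(dev) >= 2 && stats::sd(dev) > 0) {
    bw <- stats::bw.nrd(dev)  # Scott's rule
    stats::density(dev, bw = bw)
  } else {
    NULL
  }
  m <- mean(dev)
  s <- stats::sd(dev)
  skew <- if (length(dev) > 2 && is.finite(s) && s > 0) {
    mean((dev - m)^3) / s^3
  } else {
    0.0
  }
  structure(list(deviations = dev, density = dens,
                 bandwidth = if (is.null(dens)) NA_real_ else dens$bw,
                 summary = list(mean = m, median = stats::median(dev),
                                skew = skew)),
            class = "error_density")
}

#' @export
print.error_density <- function(x, ...) {
  cat(sprintf(paste0("error_density: %d pairs, mean %.3e, median %.3e Eh, ",
                     "skew %.3f\n"), length(x$deviations), x$summary$mean,
              x$summary$median, x$summary$skew))
  invisible(x)
}

#' Mean-absolute-error report over systems
#'
#' Converts Hartree deviations to kcal/mol (1 Eh = 627.509474 kcal/mol) and
#' reports the MAE, the maximum absolute error, and a per-system table.
#'
#' @param pred_totals,ref_totals numeric vectors of predicted / reference
#'   total (or correlation) energies in Hartree, aligned by system.
#' @param system optional system labels.
#' @return list with `mae`, `max_error` (kcal/mol) and `table`.
#' @export
mae_report <- function(pred_totals, ref_totals, system = NULL) {
  stopifnot(length(pred_totals) == length(ref_totals))
  if (is.null(system)) system <- seq_along(pred_totals)
  err <- (pred_totals - ref_totals) * hartree_to_kcalmol
  list(mae = mean(abs(err)), max_error = max(abs(err)),
       table = data.frame(system = system,
                          e_pred_hartree = pred_totals,
                          e_ref_hartree = ref_totals,
                          error_kcalmol = err))
}
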