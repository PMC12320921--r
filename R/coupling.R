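# Regional SC-FC coupling.

#' Regional structure-function coupling
#'
#' For each region, the Spearman rank correlation between that region's SC
#' connectivity profile and its FC profile over the N - 1 off-diagonal
#' entries (the self-entry is structurally zero and excluded; all other
#' entries including zeros are ranked, ties receiving average ranks).
#' Regions whose SC or FC profile has zero variance get a missing value and
#' are reported in a message.
#'
#' @param sc SC `connectome_matrix`.
#' @param fc FC `connectome_matrix` with identical region labels and order.
#' @return Named numeric vector of per-region coupling values in
#'   \[-1, 1\], `NA` where undefined.
#' @export
regional_scfc_coupling <- function(sc, fc) {
  wsc <- conn_weights(sc)
  wfc <- conn_weights(fc)
  if (!all(dim(wsc) == dim(wfc))) {
    stop("SC and FC matrices have different dimensions", call. = FALSE)
  }
  if (inherits(sc, "connectome_matrix") && inherits(fc, "connectome_matrix") &&
      !identical(sc$region_labels, fc$region_labels)) {
    stop("SC and FC region labels do not match", call. = FALSE)
  }
  check_symmetric(wsc, what = "SC")
  check_symmetric(wfc, what = "FC")
  n <- nrow(wsc)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- wsc[i, -i]
    b <- wfc[i, -i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    out[i] <- stats::cor(a, b, method = "spearman")
  }
  labels <- if (inherits(sc, "connectome_matrix")) sc$region_labels else
    rownames(wsc) %||% paste0("R", seq_len(n))
  if (anyNA(out)) {
    message(sprintf("SC-FC coupling undefined (zero-variance profile) for %d region(s)",
                    sum(is.na(out))))
  }
  stats::setNames(out, labels)
}
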