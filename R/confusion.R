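#' Joint integer reconstruction of confusion matrices from printed metrics
#'
#' Given the sensitivities and specificities of several models evaluated on
#' one shared test split of known size (all printed rounded to the same
#' number of decimals), enumerates the class splits `P + N = n_total` and,
#' for each model, the integer confusion counts whose rounded sensitivity
#' and specificity reproduce the printed values. A solution exists for a
#' class split only when every model admits counts under it.
#'
#' @param sens,spec numeric vectors of printed per-model values (same
#'   length, same model order).
#' @param n_total test-set size.
#' @param digits printed rounding, default 2.
#' @return list of solutions; each has `n_pos`, `n_neg` and a data frame
#'   `models` with columns tp, fn, tn, fp, sensitivity, specificity,
#'   accuracy, balanced_accuracy. A unique joint reconstruction gives a
#'   length-1 list.
#' @export
reconstruct_confusion <- function(sens, spec, n_total = 20L, digits = 2L) {
  stopifnot(length(sens) == length(spec), n_total >= 2L)
  solutions <- list()
  for (P in seq_len(n_total - 1L)) {
    N <- n_total - P
    per_model <- vector("list", length(sens))
    ok <- TRUE
    for (m in seq_along(sens)) {
      tp <- which(round(0:P / P, digits) == round(sens[m], digits)) - 1L
      tn <- which(round(0:N / N, digits) == round(spec[m], digits)) - 1L
      if (!length(tp) || !length(tn)) { ok <- FALSE; break }
      if (length(tp) > 1L || length(tn) > 1L) { ok <- FALSE; break }
      per_model[[m]] <- data.frame(
        tp = tp, fn = P - tp, tn = tn, fp = N - tn,
        sensitivity = tp / P, specificity = tn / N,
        accuracy = (tp + tn) / n_total,
        balanced_accuracy = (tp / P + tn / N) / 2)
    }
    if (ok)
      solutions[[length(solutions) + 1L]] <-
        list(n_pos = P, n_neg = N, models = do.call(rbind, per_model))
  }
  solutions
}
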