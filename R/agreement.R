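#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement from the 2x2 contingency of two raters' 0/1
#' labels. Pairs where either label is missing are dropped listwise and the
#' dropped count reported. With observed agreement \eqn{p_o = (a+d)/n} and
#' chance agreement \eqn{p_e} from the marginals,
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}.
#'
#' When both raters are constant (\eqn{p_e = 1}) kappa is undefined; an error
#' of class `screensim_undefined_kappa` carrying the contingency is raised
#' rather than fabricating a value — [kappa_table()] reports such corpora as
#' `NA`.
#'
#' @param labels_a,labels_b Equal-length vectors of 0/1/NA labels.
#' @return A `kappa_result`: list with `kappa`, `p_o`, `p_e`, `contingency`
#'   (named counts `a` both-relevant, `b` A-only, `c` B-only, `d`
#'   both-irrelevant), `n_pairs`, `n_dropped`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a_vec <- coerce_label(labels_a, "labels_a")
  b_vec <- coerce_label(labels_b, "labels_b")
  if (length(a_vec) != length(b_vec)) {
    abort_validation("label vectors must have equal length")
  }
  keep <- !is.na(a_vec) & !is.na(b_vec)
  n_dropped <- sum(!keep)
  a_vec <- a_vec[keep]
  b_vec <- b_vec[keep]
  n <- length(a_vec)
  if (n == 0L) abort_validation("no jointly labeled pairs after dropping missing labels")

  cont <- c(a = sum(a_vec == 1L & b_vec == 1L),
            b = sum(a_vec == 1L & b_vec == 0L),
            c = sum(a_vec == 0L & b_vec == 1L),
            d = sum(a_vec == 0L & b_vec == 0L))
  p_o <- (cont[["a"]] + cont[["d"]]) / n
  p_a1 <- (cont[["a"]] + cont[["b"]]) / n
  p_b1 <- (cont[["a"]] + cont[["c"]]) / n
  p_e <- p_a1 * p_b1 + (1 - p_a1) * (1 - p_b1)
  if (p_e >= 1) {
    abort("kappa undefined: both raters are constant (chance agreement = 1)",
          class = "screensim_undefined_kappa", contingency = cont)
  }
  structure(
    list(kappa = (p_o - p_e) / (1 - p_e),
         p_o = p_o, p_e = p_e,
         contingency = cont,
         n_pairs = n, n_dropped = n_dropped),
    class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f  (p_o = %.4f, p_e = %.4f, n = %d, dropped = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n_pairs, x$n_dropped))
  print(matrix(x$contingency, 2, 2, byrow = TRUE,
               dimnames = list(A = c("relevant", "irrelevant"),
                               B = c("relevant", "irrelevant"))))
  invisible(x)
}

#' Per-corpus kappa table with mean agreement
#'
#' Computes Cohen's kappa between two rater columns for each corpus and the
#' unweighted arithmetic mean across corpora. Corpora where kappa is
#' undefined (constant raters) are reported as `NA` and excluded from the
#' mean.
#'
#' @param corpora A list of [corpus()] objects, optionally named.
#' @param rater_columns Length-2 character vector of label column names.
#' @return List with `per_corpus` (tibble: dataset, kappa, n_pairs,
#'   n_dropped) and `mean_kappa`.
#' @export
kappa_table <- function(corpora,
                        rater_columns = c("label_clinician1", "label_clinician2")) {
  stopifnot(length(rater_columns) == 2L)
  if (inherits(corpora, "corpus")) corpora <- list(corpora)
  nm <- names(corpora) %||% sprintf("dataset%02d", seq_along(corpora))
  rows <- lapply(seq_along(corpora), function(i) {
    cx <- corpora[[i]]
    la <- stage_labels(cx, rater_columns[[1L]])
    lb <- stage_labels(cx, rater_columns[[2L]])
    res <- tryCatch(cohens_kappa(la, lb),
                    screensim_undefined_kappa = function(e) NULL)
    tibble::tibble(
      dataset = nm[[i]],
      kappa = if (is.null(res)) NA_real_ else res$kappa,
      n_pairs = if (is.null(res)) sum(!is.na(la) & !is.na(lb)) else res$n_pairs,
      n_dropped = if (is.null(res)) sum(is.na(la) | is.na(lb)) else res$n_dropped)
  })
  tbl <- do.call(rbind, rows)
  list(per_corpus = tbl, mean_kappa = mean(tbl$kappa, na.rm = TRUE))
}
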