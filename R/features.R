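#' TF-IDF features for a set of record texts
#'
#' Bag-of-words featurization used by the screening simulation. Tokens are
#' lowercased unigrams of at least two word characters. Weights use the
#' smoothed inverse document frequency
#' \eqn{tf(t,d) \times (\ln((1+D)/(1+df(t))) + 1)} and each document row is
#' then L2-normalized. The vocabulary is fixed over the whole corpus: fit
#' once, before any simulation — the pool's text is available to a screener
#' from the start, so no information leaks.
#'
#' @param texts Character vector of record texts (see [record_texts()]).
#' @param ids Optional record ids used as row names; defaults to the names of
#'   `texts` or a running index.
#' @return A `tfidf_features` object: list with `matrix` (sparse dgCMatrix,
#'   rows = documents, columns = vocabulary) and `vocabulary`.
#' @export
fit_features <- function(texts, ids = NULL) {
  if (length(texts) < 1L) abort_config("need at least one text")
  ids <- ids %||% names(texts) %||% sprintf("doc%05d", seq_along(texts))
  toks <- tokenize(texts)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (!length(vocab)) {
    abort("empty vocabulary: no token of >= 2 word characters in any text",
          class = "screensim_feature_error")
  }
  flat <- unlist(toks, use.names = FALSE)
  tf <- sparseMatrix(
    i = rep.int(seq_along(toks), lengths(toks)),
    j = match(flat, vocab),
    x = 1,
    dims = c(length(texts), length(vocab)))
  n_docs <- length(texts)
  df <- colSums(tf > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  x <- tf %*% Diagonal(x = idf)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x <- Diagonal(x = 1 / nrm) %*% x
  x <- as(x, "CsparseMatrix")
  dimnames(x) <- list(ids, vocab)
  structure(list(matrix = x, vocabulary = vocab), class = "tfidf_features")
}

tokenize <- function(texts) {
  regmatches(tolower(texts), gregexpr("\\w{2,}", tolower(texts), perl = TRUE))
}

#' @export
print.tfidf_features <- function(x, ...) {
  cat(sprintf("<tfidf_features> %d documents x %d terms\n",
              nrow(x$matrix), length(x$vocabulary)))
  invisible(x)
}
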