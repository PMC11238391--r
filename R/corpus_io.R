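#' Read a labeled bibliographic corpus
#'
#' Reads a corpus from CSV (canonical schema: `record_id`, `title`,
#' `abstract`, plus label columns `truth`/`label_*`) or from an RIS export
#' (`TI`/`T1` title, `AB`/`N2` abstract, `ID`/`AN` identifier; RIS carries no
#' relevance labels, so every label is missing). Input order is preserved and
#' no filtering is applied — see [preprocess_corpus()].
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"ris"`.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical ones, e.g. `c(title = "Article.Title", label_fulltext = "incl")`
#'   (names = canonical, values = names in the file). CSV only.
#' @return A [corpus()].
#' @export
read_corpus <- function(path, format = c("csv", "ris"), column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  records <- switch(format,
    csv = read_corpus_csv(path, column_map),
    ris = parse_ris(path))
  corpus(records, source = path)
}

read_corpus_csv <- function(path, column_map) {
  df <- readr::read_csv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(df))
    if (length(missing)) {
      abort_config(sprintf("mapped column(s) not in file: %s",
                           paste(missing, collapse = ", ")))
    }
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }
  for (col in c("title", "abstract")) {
    if (!col %in% names(df)) {
      abort_config(sprintf("CSV is missing required column `%s`", col))
    }
  }
  if (!"record_id" %in% names(df)) {
    df$record_id <- sprintf("rec%05d", seq_len(nrow(df)))
  }
  df[, c("record_id", "title", "abstract", label_column_names(df)), drop = FALSE]
}

# Minimal RIS reader: tagged "XX  - value" lines, records closed by ER.
# Untagged lines continue the previous tag's value.
parse_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tag_re <- "^([A-Z][A-Z0-9])  ?- ?"
  entries <- list()
  current <- list()
  last_tag <- NULL
  flush <- function(current) {
    if (!length(current)) return(NULL)
    list(record_id = current[["ID"]] %||% current[["AN"]] %||% NA_character_,
         title = current[["TI"]] %||% current[["T1"]] %||% "",
         abstract = current[["AB"]] %||% current[["N2"]] %||% "")
  }
  for (line in lines) {
    if (grepl(tag_re, line)) {
      tag <- sub(paste0(tag_re, ".*$"), "\\1", line)
      val <- sub(tag_re, "", line)
      if (tag == "ER") {
        e <- flush(current)
        if (!is.null(e)) entries[[length(entries) + 1L]] <- e
        current <- list()
        last_tag <- NULL
      } else {
        current[[tag]] <- if (is.null(current[[tag]])) val else
          paste(current[[tag]], val)
        last_tag <- tag
      }
    } else if (!is.null(last_tag) && nzchar(trimws(line))) {
      current[[last_tag]] <- paste(current[[last_tag]], trimws(line))
    }
  }
  e <- flush(current)
  if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  if (!length(entries)) abort_validation("no RIS entries found")
  ids <- vapply(entries, `[[`, "", "record_id")
  ids[is.na(ids)] <- sprintf("rec%05d", which(is.na(ids)))
  tibble::tibble(
    record_id = ids,
    title = vapply(entries, `[[`, "", "title"),
    abstract = vapply(entries, `[[`, "", "abstract"))
}

normalize_title <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(x)
}

#' Preprocess a corpus for simulation
#'
#' Applies the screening-study preprocessing rules: records whose abstract is
#' empty or whitespace-only are dropped (the feature extractor needs text),
#' and among records sharing a normalized title (case-folded, punctuation and
#' whitespace collapsed) only the first occurrence is kept. Removals are
#' appended to the provenance log. The operation is idempotent.
#'
#' @param x A [corpus()].
#' @return The filtered `corpus`.
#' @export
preprocess_corpus <- function(x) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  log <- x$provenance$log

  blank <- !nzchar(trimws(rec$abstract))
  if (any(blank)) {
    log <- c(log, sprintf("removed %d record(s) with missing abstract: %s",
                          sum(blank),
                          paste(rec$record_id[blank], collapse = ", ")))
    rec <- rec[!blank, , drop = FALSE]
  }
  if (nrow(rec)) {
    dup <- duplicated(normalize_title(rec$title))
    if (any(dup)) {
      log <- c(log, sprintf("removed %d duplicate-title record(s): %s",
                            sum(dup),
                            paste(rec$record_id[dup], collapse = ", ")))
      rec <- rec[!dup, , drop = FALSE]
    }
  }
  if (!nrow(rec)) {
    abort_validation("preprocessing removed every record (no usable abstracts)")
  }
  new_corpus(rec, provenance = list(source = x$provenance$source, log = log))
}

#' Write a corpus to CSV
#'
#' Writes the canonical CSV schema. Missing labels become empty cells (never
#' `"0"`), so a write/read round trip reproduces records, order and the
#' three-state labels exactly.
#'
#' @param x A [corpus()].
#' @param path Output path.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = "csv") {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format, "csv")
  readr::write_csv(x$records, path, na = "", progress = FALSE)
  invisible(path)
}
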