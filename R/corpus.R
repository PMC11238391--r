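#' Labeled bibliographic corpora
#'
#' A `corpus` holds one record per publication (identifier, title, abstract)
#' together with any number of three-state relevance label columns
#' (`1` = relevant, `0` = irrelevant, `NA` = missing). Label columns play the
#' adjudication-stage roles used throughout the package: two independent
#' clinician raters, the consolidated clinician triage, the research
#' methodologist's reduction of it, and the final full-text inclusion.
#'
#' @param records A data frame with character columns `record_id`, `title`,
#'   `abstract` and zero or more label columns named `truth` or `label_*`,
#'   each coercible to 0/1/NA.
#' @param source Provenance string recorded with the corpus.
#' @return An object of class `corpus`: a list with elements `records`
#'   (a tibble), `stage_columns` (the label column names present) and
#'   `provenance` (source plus a preprocessing log).
#' @examples
#' corpus(data.frame(
#'   record_id = c("a", "b"),
#'   title = c("Radial fixation", "Plate fixation"),
#'   abstract = c("randomized trial", "cohort study"),
#'   label_fulltext = c(1, 0)
#' ))
#' @export
corpus <- function(records, source = "<in-memory>") {
  records <- tibble::as_tibble(records)
  for (col in c("record_id", "title", "abstract")) {
    if (!col %in% names(records)) {
      abort_config(sprintf("corpus records need a `%s` column", col))
    }
    records[[col]] <- as.character(records[[col]])
  }
  for (col in label_column_names(records)) {
    records[[col]] <- coerce_label(records[[col]], col)
  }
  new_corpus(records, provenance = list(source = source, log = character()))
}

# canonical label roles, in adjudication order
CANONICAL_LABELS <- c("truth", "label_clinician1", "label_clinician2",
                      "label_clinician", "label_methodologist",
                      "label_fulltext")

label_column_names <- function(records) {
  names(records)[names(records) == "truth" | startsWith(names(records), "label_")]
}

coerce_label <- function(x, col) {
  if (is.logical(x)) x <- as.integer(x)
  if (is.character(x)) {
    x <- trimws(x)
    x[x %in% c("", "NA")] <- NA_character_
    bad <- !is.na(x) & !x %in% c("0", "1")
    if (any(bad)) {
      abort_validation(sprintf(
        "column `%s` has unparseable label %s at row %d (expected 0, 1, empty or NA)",
        col, deparse(x[bad][1L]), which(bad)[1L]))
    }
    x <- as.integer(x)
  }
  x <- as.integer(x)
  bad <- !is.na(x) & !x %in% c(0L, 1L)
  if (any(bad)) {
    abort_validation(sprintf(
      "column `%s` has unparseable label %s at row %d (expected 0, 1, empty or NA)",
      col, deparse(x[bad][1L]), which(bad)[1L]))
  }
  x
}

new_corpus <- function(records, provenance) {
  x <- structure(
    list(records = records,
         stage_columns = label_column_names(records),
         provenance = provenance),
    class = "corpus")
  validate_corpus(x)
}

validate_corpus <- function(x) {
  rec <- x$records
  if (nrow(rec) < 1L) abort_validation("corpus has no records")
  dup <- duplicated(rec$record_id)
  if (any(dup)) {
    abort_validation(sprintf("duplicate record_id: %s",
                             paste(unique(rec$record_id[dup]), collapse = ", ")))
  }
  x
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d records from %s\n", nrow(x$records),
              x$provenance$source))
  if (length(x$stage_columns)) {
    cat("  label columns:", paste(x$stage_columns, collapse = ", "), "\n")
  } else {
    cat("  label columns: none\n")
  }
  if (length(x$provenance$log)) {
    cat("  preprocessing:\n")
    for (line in x$provenance$log) cat("   -", line, "\n")
  }
  invisible(x)
}

#' Number of records in a corpus
#' @param x A `corpus`.
#' @return Integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "corpus"))
  nrow(x$records)
}

#' Record identifiers of a corpus
#' @param x A `corpus`.
#' @return Character vector of record ids, in corpus order.
#' @export
record_ids <- function(x) {
  stopifnot(inherits(x, "corpus"))
  x$records$record_id
}

#' Modeling text of each record
#'
#' The text a screener reads and the feature extractor consumes: the title
#' and abstract concatenated with a single space.
#'
#' @param x A `corpus`.
#' @return Named character vector (names are record ids).
#' @export
record_texts <- function(x) {
  stopifnot(inherits(x, "corpus"))
  setNames(paste(x$records$title, x$records$abstract), x$records$record_id)
}

#' Ground-truth labels for an adjudication stage
#'
#' Resolves a stage name to a label vector. `"clinician"` uses the
#' consolidated `label_clinician` column when present and otherwise the union
#' (logical OR) of the two clinician raters — over-inclusive triage, matching
#' how disagreements feed the next stage. `"methodologist"` and `"fulltext"`
#' map to their columns; any existing label column name is also accepted.
#'
#' @param x A `corpus`.
#' @param stage `"clinician"`, `"methodologist"`, `"fulltext"`, `"truth"`, or
#'   a label column name.
#' @return Named integer vector of 0/1/NA labels, one per record.
#' @export
stage_labels <- function(x, stage) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  get <- function(col) {
    if (!col %in% names(rec)) {
      abort_config(sprintf("corpus has no `%s` column (available: %s)",
                           col, paste(x$stage_columns, collapse = ", ")))
    }
    rec[[col]]
  }
  lab <- switch(stage,
    clinician = {
      if ("label_clinician" %in% names(rec)) {
        get("label_clinician")
      } else {
        a <- get("label_clinician1")
        b <- get("label_clinician2")
        # OR with three states: 1 dominates, then 0, both-missing stays NA
        out <- ifelse(!is.na(a) & a == 1L | !is.na(b) & b == 1L, 1L,
                      ifelse(!is.na(a) | !is.na(b), 0L, NA_integer_))
        as.integer(out)
      }
    },
    methodologist = get("label_methodologist"),
    fulltext = get("label_fulltext"),
    truth = get("truth"),
    get(stage))
  setNames(as.integer(lab), rec$record_id)
}
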