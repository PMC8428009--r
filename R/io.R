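#' Read a corpus of clinical notes
#'
#' Accepts three layouts, all UTF-8:
#' \itemize{
#'   \item JSONL (`.jsonl` / `.ndjson`): one object per line with keys
#'     `note_id`, `text`, `note_type`;
#'   \item CSV with those columns;
#'   \item a directory of `.txt` files (filename stem becomes `note_id`,
#'     `note_type = "other"`).
#' }
#' Malformed JSONL lines are skipped with a warning that reports the
#' count.
#'
#' @param path File or directory path.
#' @return data.frame with columns `note_id`, `text`, `note_type`.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(data.frame(
      note_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n"), ""),
      note_type = "other", stringsAsFactors = FALSE, row.names = NULL))
  }
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    bad <- sum(vapply(recs, is.null, logical(1)))
    if (bad > 0L) {
      warning(bad, " malformed JSONL line(s) skipped", call. = FALSE)
    }
    recs <- Filter(Negate(is.null), recs)
    return(data.frame(
      note_id = vapply(recs, function(r) as.character(r$note_id), ""),
      text = vapply(recs, function(r)
        if (is.null(r$text)) "" else as.character(r$text), ""),
      note_type = vapply(recs, function(r)
        if (is.null(r$note_type)) "other" else as.character(r$note_type), ""),
      stringsAsFactors = FALSE))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8")
    if (!all(c("note_id", "text") %in% names(df))) {
      stop("notes CSV needs note_id and text columns", call. = FALSE)
    }
    if (!"note_type" %in% names(df)) df$note_type <- "other"
    return(df[, c("note_id", "text", "note_type")])
  }
  stop("unrecognized notes format: ", path,
       " (expected .jsonl, .csv, or a directory of .txt files)",
       call. = FALSE)
}

#' Write a corpus of notes as JSONL
#'
#' @param notes data.frame with `note_id`, `text`, `note_type`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(
      list(note_id = notes$note_id[i], text = notes$text[i],
           note_type = notes$note_type[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write corpus annotations
#'
#' JSONL carries one object per sentence-level reference (debug level:
#' `note_id`, `sentence_index`, `char_span`, `pattern_id`, `output_id`,
#' `category`); the flat CSV (`note_id`, `concept`, `subcategory`,
#' `sentence_index`, `char_start`, `char_end`, `pattern_id`) is meant for
#' spreadsheet review.
#'
#' @param annotations A `corpus_annotations` from [extract_corpus()].
#' @param jsonl_path,csv_path Output paths (either may be `NULL`).
#' @return invisibly `NULL`.
#' @export
write_annotations <- function(annotations, jsonl_path = NULL,
                              csv_path = NULL) {
  s <- annotations$sentences
  if (!is.null(jsonl_path)) {
    con <- file(jsonl_path, open = "w", encoding = "UTF-8")
    for (i in seq_len(nrow(s))) {
      writeLines(jsonlite::toJSON(
        list(note_id = s$note_id[i], sentence_index = s$sentence_index[i],
             char_span = c(s$char_start[i], s$char_end[i]),
             pattern_id = s$pattern_id[i], output_id = s$output_id[i],
             category = s$category[i]), auto_unbox = TRUE), con)
    }
    close(con)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      s[, c("note_id", "concept", "subcategory", "sentence_index",
            "char_start", "char_end", "pattern_id")],
      csv_path, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read an adjudicated gold-standard table
#'
#' CSV with columns `note_id`, `adjudicator_id`, `concept`,
#' `subcategory`, `sentence_index` (blank for note-level-only rows).
#' Categories are validated against the taxonomy.
#'
#' @param path CSV path.
#' @return data.frame with `sentence_index` as integer (`NA` when blank).
#' @export
read_gold <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("note_id", "concept", "subcategory")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("gold CSV (", path, ") is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"adjudicator_id" %in% names(df)) df$adjudicator_id <- "adjudicator1"
  if (!"sentence_index" %in% names(df)) df$sentence_index <- NA_character_
  df$sentence_index <- suppressWarnings(as.integer(df$sentence_index))
  check_categories(paste(df$concept, df$subcategory, sep = "."))
  df[, c("note_id", "adjudicator_id", "concept", "subcategory",
         "sentence_index")]
}

#' Read a secondary-review corrections table
#'
#' CSV with columns `note_id`, `concept`, `subcategory`,
#' `sentence_index` (blank for note-level items), `confirmed`
#' (true/false: confirmed truly positive on secondary review).
#'
#' @param path CSV path.
#' @return data.frame with logical `confirmed`.
#' @export
read_corrections <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("note_id", "concept", "subcategory", "confirmed")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("corrections CSV (", path, ") is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"sentence_index" %in% names(df)) df$sentence_index <- NA_character_
  df$sentence_index <- suppressWarnings(as.integer(df$sentence_index))
  df$confirmed <- tolower(df$confirmed) %in% c("true", "t", "1", "yes")
  check_categories(paste(df$concept, df$subcategory, sep = "."))
  df[, c("note_id", "concept", "subcategory", "sentence_index", "confirmed")]
}

#' Write a gold table as CSV
#'
#' @param gold Gold data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  utils::write.csv(gold, path, row.names = FALSE, na = "")
  invisible(path)
}
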