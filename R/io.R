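#' Read and write ratings matrices
#'
#' A ratings CSV has one row per case and one column per rater, with a
#' leading `case_id` column; cells hold causality tokens
#' (unlikely/possible/probable/definite, case-insensitive, numeric codes
#' 1--4 also accepted) or are blank for missing ratings. Reading and
#' writing round-trip categories and missingness losslessly.
#'
#' @param path File path.
#' @return `read_ratings()`: a tibble with `case_id` and one ordered
#'   factor column per rater.
#' @export
read_ratings <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!nrow(raw)) stop("no data rows in ", path, call. = FALSE)
  if (!"case_id" %in% names(raw)) {
    names(raw)[1] <- "case_id"
  }
  for (col in setdiff(names(raw), "case_id")) {
    raw[[col]] <- tryCatch(
      as_causality(raw[[col]]),
      error = function(e) {
        stop("column ", sQuote(col), " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  raw
}

#' @param ratings A ratings tibble as returned by [read_ratings()] or
#'   [simulate_ratings()].
#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path) {
  out <- tibble::as_tibble(ratings)
  for (col in setdiff(names(out), "case_id")) {
    out[[col]] <- as.character(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read instrument answer sheets
#'
#' Reads a CSV of per-case, per-rater answer sheets: columns `case_id`,
#' `rater_id`, then one column per question (Naranjo `Q1`..`Q10`) or per
#' tree node id (Liverpool), blank meaning unanswered/unvisited. Values
#' are returned as character for the scoring engines to validate.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_answer_sheets <- function(path) {
  sheets <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("case_id", "rater_id") %in% names(sheets))) {
    stop(path, " must have case_id and rater_id columns", call. = FALSE)
  }
  sheets
}

#' Write an agreement report to disk
#'
#' Serialises an [agreement_report()] either as schema-versioned JSON
#' (machine-readable, full precision) or as a Markdown pairwise matrix
#' in the layout of published reliability tables: the %EA/%ED line with
#' the weighted kappa and its CI beneath, one cell per rater pair, plus
#' the global kappa line.
#'
#' @param report An `agreement_report`.
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      schema = "adrcat/agreement-report/v1",
      global = as.list(dplyr::mutate(report$global,
                                     band = as.character(.data$band))),
      pairwise = dplyr::mutate(report$pairwise,
                               band = as.character(.data$band))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c(
      "# Inter-rater agreement",
      "",
      sprintf("Global kappa %.2f (95%% CI %.2f, %.2f) - %s agreement; %d raters, %d complete cases.",
              report$global$kappa, report$global$lower,
              report$global$upper, as.character(report$global$band),
              report$global$n_raters, report$global$n_cases),
      "",
      paste0("| | ", paste(report$raters[-1], collapse = " | "), " |"),
      paste0("|", strrep("---|", length(report$raters)))
    )
    for (r1 in report$raters[-length(report$raters)]) {
      cells <- vapply(report$raters[-1], function(r2) {
        row <- report$pairwise[report$pairwise$rater1 == r1 &
                                 report$pairwise$rater2 == r2, ]
        if (!nrow(row)) return("")
        sprintf("%.1f/%.1f%%<br>%.2f (%.2f, %.2f)",
                row$pct_exact, row$pct_extreme,
                row$kappa, row$lower, row$upper)
      }, character(1))
      lines <- c(lines, paste0("| **", r1, "** | ",
                               paste(cells, collapse = " | "), " |"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
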