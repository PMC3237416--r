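answer_tokens <- c("yes", "no", "unknown")

# normalise a vector of yes/no/unknown tokens; `where` names the question in
# error messages
parse_answer <- function(x, where = "answer") {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("dont know", "don't know", "dk", "na")] <- "unknown"
  bad <- is.na(x) | !(x %in% answer_tokens)
  if (any(bad)) {
    stop(where, ": invalid answer token(s) ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         " (expected yes/no/unknown)", call. = FALSE)
  }
  x
}

#' Naranjo weight table
#'
#' The ten-question weight matrix of the Naranjo adverse-drug-reaction
#' probability scale, together with the score boundaries that map a total
#' score onto the four-point causality scale. The packaged default carries
#' the original 1981 weights (each question scored for yes / no / don't
#' know) and the conventional boundaries: total <= 0 unlikely, 1--4
#' possible, 5--8 probable, >= 9 definite. The table is data, not code:
#' variant dialects can be loaded from JSON with [read_naranjo_weights()].
#'
#' @param path Optional path to a JSON weight document; default uses the
#'   packaged table.
#' @return An object of class `naranjo_weights`: a list with `questions`
#'   (tibble of question id, text and the three per-answer weights),
#'   `boundaries` (upper score bounds for unlikely/possible/probable) and
#'   `range` (the achievable total-score range).
#' @export
#' @examples
#' w <- naranjo_weights()
#' w$range
read_naranjo_weights <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  q <- tibble::as_tibble(doc$questions)
  need <- c("id", "yes", "no", "unknown")
  if (!all(need %in% names(q))) {
    stop("weight document must define ", paste(need, collapse = ", "),
         " for every question", call. = FALSE)
  }
  if (anyDuplicated(q$id)) stop("duplicate question ids", call. = FALSE)
  if (any(is.na(q$yes) | is.na(q$no) | is.na(q$unknown))) {
    stop("weight must be defined for all (question, answer) pairs",
         call. = FALSE)
  }
  b <- unlist(doc$boundaries)
  if (length(b) != 3 || any(diff(b) <= 0)) {
    stop("boundaries must be three strictly increasing score thresholds",
         call. = FALSE)
  }
  rng <- c(
    sum(pmin(q$yes, q$no, q$unknown)),
    sum(pmax(q$yes, q$no, q$unknown))
  )
  structure(
    list(
      name = doc$name %||% "naranjo",
      questions = q,
      boundaries = c(unlikely_max = unname(b[1]),
                     possible_max = unname(b[2]),
                     probable_max = unname(b[3])),
      range = rng
    ),
    class = "naranjo_weights"
  )
}

#' @rdname read_naranjo_weights
#' @export
naranjo_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "naranjo_weights.json", package = "adrcat")
  }
  read_naranjo_weights(path)
}

#' @export
print.naranjo_weights <- function(x, ...) {
  cat(x$name, "\n", sep = "")
  print(x$questions[, c("id", "yes", "no", "unknown")])
  cat("boundaries: unlikely <= ", x$boundaries[["unlikely_max"]],
      " < possible <= ", x$boundaries[["possible_max"]],
      " < probable <= ", x$boundaries[["probable_max"]],
      " < definite\n", sep = "")
  invisible(x)
}

#' Score one Naranjo answer sheet
#'
#' Sums the per-question weights of the given answers. All ten questions
#' must be answered (with yes, no or unknown); anything else is rejected
#' with the offending question named.
#'
#' @param answers Named character vector or list mapping question id
#'   (`Q1`..`Q10`) to an answer token (`yes`/`no`/`unknown`,
#'   case-insensitive).
#' @param weights A [naranjo_weights()] table.
#' @return Integer total score.
#' @export
#' @examples
#' naranjo_score(setNames(rep("yes", 10), paste0("Q", 1:10)))
naranjo_score <- function(answers, weights = naranjo_weights()) {
  answers <- unlist(answers)
  q <- weights$questions
  missing <- setdiff(q$id, names(answers))
  if (length(missing)) {
    stop("missing answer for question(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(answers), q$id)
  if (length(extra)) {
    stop("unknown question id(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  tot <- 0L
  for (i in seq_len(nrow(q))) {
    a <- parse_answer(answers[[q$id[i]]], where = q$id[i])
    tot <- tot + as.integer(q[[a]][i])
  }
  tot
}

#' Map a Naranjo total score to a causality category
#'
#' @param total Integer total score(s), within the achievable range of the
#'   weight table.
#' @param weights A [naranjo_weights()] table supplying the boundaries.
#' @return Ordered factor on the causality scale.
#' @export
#' @examples
#' naranjo_categorise(c(-2, 3, 6, 11))
naranjo_categorise <- function(total, weights = naranjo_weights()) {
  rng <- weights$range
  if (any(total < rng[1] | total > rng[2], na.rm = TRUE)) {
    stop("total score outside achievable range [", rng[1], ", ", rng[2],
         "]", call. = FALSE)
  }
  b <- weights$boundaries
  lv <- causality_levels()
  idx <- 1L + (total > b[["unlikely_max"]]) + (total > b[["possible_max"]]) +
    (total > b[["probable_max"]])
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Score a table of Naranjo answer sheets
#'
#' Tidy entry point for scoring many case-by-rater answer sheets at once.
#' The input mirrors the CSV answer-sheet layout: one row per case and
#' rater, columns `Q1`..`Q10` holding `yes`/`no`/`unknown`.
#'
#' @param sheets Data frame with columns `case_id`, `rater_id` and
#'   `Q1`..`Q10` (or whatever ids the weight table defines).
#' @param weights A [naranjo_weights()] table.
#' @return A tibble with `case_id`, `rater_id`, the integer `total` and
#'   the assigned `category`.
#' @export
#' @examples
#' sheets <- tibble::tibble(case_id = "c1", rater_id = "r1",
#'   Q1 = "yes", Q2 = "yes", Q3 = "yes", Q4 = "no", Q5 = "no",
#'   Q6 = "unknown", Q7 = "no", Q8 = "no", Q9 = "yes", Q10 = "yes")
#' score_naranjo(sheets)
score_naranjo <- function(sheets, weights = naranjo_weights()) {
  sheets <- tibble::as_tibble(sheets)
  qids <- weights$questions$id
  missing <- setdiff(qids, names(sheets))
  if (length(missing)) {
    stop("answer sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("case_id", "rater_id") %in% names(sheets))) {
    stop("answer sheet needs case_id and rater_id columns", call. = FALSE)
  }
  totals <- purrr::map_int(seq_len(nrow(sheets)), function(i) {
    ans <- as.character(unlist(sheets[i, qids]))
    names(ans) <- qids
    tryCatch(
      naranjo_score(ans, weights),
      error = function(e) {
        stop("row ", i, " (case ", sheets$case_id[i], ", rater ",
             sheets$rater_id[i], "): ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  dplyr::mutate(
    sheets[, c("case_id", "rater_id")],
    total = totals,
    category = naranjo_categorise(totals, weights)
  )
}
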