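#' Collate causality category counts across assessors
#'
#' Builds the per-assessor category count table of a study arm: counts
#' of unlikely/possible/probable/definite per rater, column totals, and
#' the totals as percentages of all assessments.
#'
#' Accepted inputs: a long assessment table (`rater_id`, `category`, as
#' produced by [score_naranjo()] or [assess_liverpool()]); a wide
#' ratings table (`case_id` plus one rater column each); or an already
#' counted table (`rater_id` plus the four category count columns) such
#' as a published summary, in which case counts are re-totalled rather
#' than recounted.
#'
#' @param x Assessments in one of the forms above.
#' @param pct_digits Decimal places for the displayed percentages
#'   (default 1); full precision is retained in `percentages_raw`.
#' @return Object of class `category_counts`: list with `by_rater`
#'   (tibble of per-rater counts), `totals` (named integer 4-vector),
#'   `percentages` (named rounded 4-vector), `percentages_raw`, and `n`
#'   (grand total of assessments).
#' @export
#' @examples
#' panel <- simulate_ratings(n_cases = 10, n_raters = 3, seed = 2)
#' collate_categories(panel$ratings)
collate_categories <- function(x, pct_digits = 1) {
  lv <- causality_levels()
  x <- tibble::as_tibble(x)
  if (all(lv %in% names(x))) {
    # pre-counted rows (published tables, collated prose counts)
    by_rater <- x
    if (!"rater_id" %in% names(by_rater)) {
      by_rater <- dplyr::mutate(by_rater,
                                rater_id = as.character(dplyr::row_number()),
                                .before = 1)
    }
    counts <- by_rater[, lv]
    if (any(is.na(counts)) || any(counts < 0)) {
      stop("counts must be non-negative and complete", call. = FALSE)
    }
    by_rater <- dplyr::bind_cols(
      by_rater[, "rater_id"],
      tibble::as_tibble(lapply(counts, as.integer))
    )
  } else {
    if ("category" %in% names(x)) {
      if (!"rater_id" %in% names(x)) {
        stop("long input needs rater_id and category columns",
             call. = FALSE)
      }
      long <- x[, c("rater_id", "category")]
    } else if ("case_id" %in% names(x) || ncol(x) >= 1) {
      long <- tidyr::pivot_longer(
        x, -dplyr::any_of("case_id"),
        names_to = "rater_id", values_to = "category"
      )
    } else {
      stop("cannot interpret input as assessments", call. = FALSE)
    }
    long$category <- as_causality(long$category)
    long <- long[!is.na(long$category), ]
    if (!nrow(long)) stop("no assessments to collate", call. = FALSE)
    by_rater <- long |>
      dplyr::count(.data$rater_id, .data$category) |>
      tidyr::pivot_wider(names_from = "category", values_from = "n",
                         values_fill = 0L,
                         names_expand = TRUE)
    by_rater <- by_rater[, c("rater_id", lv)]
  }
  totals <- vapply(by_rater[lv], function(v) sum(as.integer(v)), integer(1))
  n <- sum(totals)
  pct_raw <- 100 * totals / n
  structure(
    list(by_rater = by_rater, totals = totals,
         percentages = round(pct_raw, pct_digits),
         percentages_raw = pct_raw, n = n, pct_digits = pct_digits),
    class = "category_counts"
  )
}

#' @export
print.category_counts <- function(x, ...) {
  cat("Causality category assignments (", x$n, " assessments)\n", sep = "")
  print(as.data.frame(x$by_rater), row.names = FALSE)
  tot <- sprintf("%d (%.*f)", x$totals, x$pct_digits, x$percentages)
  cat("Totals: ", paste(paste0(causality_levels(), " ", tot),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.category_counts <- function(x, ...) {
  long <- tidyr::pivot_longer(x$by_rater, -"rater_id",
                              names_to = "category", values_to = "n")
  long$category <- as_causality(long$category)
  long
}

#' @exportS3Method ggplot2::autoplot
autoplot.category_counts <- function(object, ...) {
  long <- tidy.category_counts(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rater_id, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = NULL) +
    ggplot2::labs(x = "assessor", y = "cases",
                  title = "Causality category assignments") +
    ggplot2::theme_minimal()
}
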