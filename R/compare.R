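#' Compare two instruments on the same case-by-rater grid
#'
#' Lines up the assessments of two causality instruments applied by the
#' same raters to the same cases: per-instrument category count tables
#' and global Fleiss kappas, plus the distribution of per-assessment
#' category shifts (instrument B code minus instrument A code, -3..+3).
#' Both grids must cover exactly the same case-rater pairs.
#'
#' @param a,b Long assessment tables with `case_id`, `rater_id`,
#'   `category` (as returned by [score_naranjo()] or
#'   [assess_liverpool()]).
#' @param names Length-2 character vector naming the instruments.
#' @return Object of class `instrument_comparison`: list with `counts`
#'   (named list of two [collate_categories()] tables), `global` (tibble
#'   of per-instrument Fleiss kappa rows), `shifts` (tibble of shift,
#'   n, pct), `n_assessments` (per instrument) and `n_unique_pairs`
#'   (distinct case-rater pairs, counted once).
#' @export
#' @examples
#' study <- simulate_study(n_cases = 8, n_raters = 3, seed = 11)
#' lv <- assess_liverpool(study$sheets)
#' compare_instruments(lv, lv, names = c("A", "B"))
compare_instruments <- function(a, b, names = c("A", "B")) {
  need <- c("case_id", "rater_id", "category")
  a <- tibble::as_tibble(a)[, need]
  b <- tibble::as_tibble(b)[, need]
  a$category <- as_causality(a$category)
  b$category <- as_causality(b$category)
  key <- function(d) paste(d$case_id, d$rater_id, sep = "\r")
  missing_b <- setdiff(key(a), key(b))
  missing_a <- setdiff(key(b), key(a))
  if (length(missing_a) || length(missing_b)) {
    fmt <- function(k) paste(utils::head(gsub("\r", "/", k), 5),
                             collapse = ", ")
    stop("instrument grids are misaligned; ",
         if (length(missing_b))
           paste0("missing from ", names[2], ": ", fmt(missing_b), ". "),
         if (length(missing_a))
           paste0("missing from ", names[1], ": ", fmt(missing_a), "."),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::rename(a, cat_a = "category"),
    dplyr::rename(b, cat_b = "category"),
    by = c("case_id", "rater_id")
  )
  shifts <- joined |>
    dplyr::mutate(shift = as.integer(.data$cat_b) -
                    as.integer(.data$cat_a)) |>
    dplyr::count(.data$shift) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))

  to_wide <- function(d) {
    tidyr::pivot_wider(d, names_from = "rater_id",
                       values_from = "category")
  }
  global <- dplyr::bind_rows(
    dplyr::mutate(fleiss_kappa(to_wide(a)), instrument = names[1],
                  .before = 1),
    dplyr::mutate(fleiss_kappa(to_wide(b)), instrument = names[2],
                  .before = 1)
  )
  structure(
    list(
      counts = stats::setNames(
        list(collate_categories(a), collate_categories(b)), names),
      global = global,
      shifts = shifts,
      n_assessments = stats::setNames(c(nrow(a), nrow(b)), names),
      n_unique_pairs = nrow(joined)
    ),
    class = "instrument_comparison"
  )
}

#' @export
print.instrument_comparison <- function(x, ...) {
  nms <- names(x$counts)
  cat("Instrument comparison: ", nms[1], " vs ", nms[2], " (",
      x$n_unique_pairs, " case-rater pairs; ",
      sum(x$n_assessments), " instrument-assessments)\n\n", sep = "")
  for (nm in nms) {
    cat("[", nm, "] ", sep = "")
    print(x$counts[[nm]])
  }
  cat("\nGlobal kappa by instrument:\n")
  print(as.data.frame(x$global[, c("instrument", "kappa", "lower",
                                   "upper", "band")]),
        row.names = FALSE)
  cat("\nCategory shifts (", nms[2], " - ", nms[1], "):\n", sep = "")
  print(as.data.frame(x$shifts), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.instrument_comparison <- function(x, ...) x$shifts

#' @exportS3Method generics::glance
glance.instrument_comparison <- function(x, ...) x$global
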