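# linear agreement weights on the k-point ordinal scale: w_ij = 1 - |i-j|/(k-1)
linear_weights <- function(k = 4L) {
  outer(seq_len(k), seq_len(k), function(i, j) 1 - abs(i - j) / (k - 1))
}

# drop cases where either rating is missing; returns integer codes 1..4
complete_codes <- function(x, y) {
  cx <- causality_code(x)
  cy <- causality_code(y)
  keep <- !is.na(cx) & !is.na(cy)
  list(x = cx[keep], y = cy[keep], n = sum(keep))
}

#' Linear weighted kappa for two raters
#'
#' Chance-corrected agreement between two raters on the four-point
#' causality scale, giving partial credit for near misses through linear
#' distance weights `w_ij = 1 - |i - j|/3`. The estimate is computed
#' case by case (mean observed weight against the marginal expected
#' weight); the asymptotic standard error uses the non-null large-sample
#' variance of the weighted kappa, and the 95% confidence interval
#' (estimate +/- 1.96 SE) is truncated to `[-1, 1]`.
#'
#' Cases missing either rating are dropped. When the chance-corrected
#' denominator is zero (both raters degenerate on one category) the
#' result is flagged degenerate with `NA` estimates rather than an error.
#'
#' @param x,y Rating vectors (anything [as_causality()] accepts).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `n`, `kappa`, `se`, `lower`, `upper`,
#'   `degenerate`.
#' @export
#' @examples
#' kappa_linear(c(1, 2, 3, 4), c(1, 2, 4, 3))
kappa_linear <- function(x, y, conf_level = 0.95) {
  cc <- complete_codes(x, y)
  if (cc$n < 2) {
    stop("need at least 2 cases rated by both raters (have ", cc$n, ")",
         call. = FALSE)
  }
  k <- 4L
  w <- linear_weights(k)
  # case-by-case observed agreement
  po <- mean(w[cbind(cc$x, cc$y)])
  px <- tabulate(cc$x, k) / cc$n
  py <- tabulate(cc$y, k) / cc$n
  pe <- sum(outer(px, py) * w)
  if (abs(1 - pe) < 1e-12) {
    return(tibble::tibble(n = cc$n, kappa = NA_real_, se = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          degenerate = TRUE))
  }
  kap <- (po - pe) / (1 - pe)
  # non-null large-sample variance from the joint proportion table
  p <- table(factor(cc$x, 1:k), factor(cc$y, 1:k)) / cc$n
  wbar_row <- as.vector(w %*% py)     # E over y-marginal, per row i
  wbar_col <- as.vector(px %*% w)     # E over x-marginal, per column j
  term <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      term <- term + p[i, j] *
        (w[i, j] * (1 - pe) - (wbar_row[i] + wbar_col[j]) * (1 - po))^2
    }
  }
  v <- (term - (po * pe - 2 * pe + po)^2) / (cc$n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    n = cc$n, kappa = kap, se = se,
    lower = max(kap - z * se, -1), upper = min(kap + z * se, 1),
    degenerate = FALSE
  )
}

# same estimate straight from a k x k contingency table of counts;
# used for the two-implementations-agree invariant
kappa_linear_from_table <- function(tab) {
  tab <- as.matrix(tab)
  k <- nrow(tab)
  stopifnot(ncol(tab) == k)
  w <- linear_weights(k)
  n <- sum(tab)
  p <- tab / n
  po <- sum(p * w)
  pe <- sum(outer(rowSums(p), colSums(p)) * w)
  (po - pe) / (1 - pe)
}

#' Exact agreement and extreme disagreement percentages
#'
#' `exact_agreement_pct()` is the percentage of complete cases on which
#' two raters assign identical categories. `extreme_disagreement_pct()`
#' is the percentage on which their categories lie more than one ordinal
#' step apart (for example definite for one rater and possible for the
#' other). Together with the one-step disagreement percentage these
#' always sum to 100.
#'
#' @param x,y Rating vectors (anything [as_causality()] accepts).
#' @return A single percentage in `[0, 100]`.
#' @export
#' @examples
#' exact_agreement_pct(c(1, 2, 3), c(1, 2, 4))
#' extreme_disagreement_pct(c("possible", "probable"),
#'                          c("definite", "definite"))
exact_agreement_pct <- function(x, y) {
  cc <- complete_codes(x, y)
  if (cc$n < 1) stop("no cases rated by both raters", call. = FALSE)
  100 * mean(cc$x == cc$y)
}

#' @rdname exact_agreement_pct
#' @export
extreme_disagreement_pct <- function(x, y) {
  cc <- complete_codes(x, y)
  if (cc$n < 1) stop("no cases rated by both raters", call. = FALSE)
  100 * mean(abs(cc$x - cc$y) >= 2)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement across all raters of a panel, treating the
#' four causality categories as nominal. Cases with any missing rating
#' are excluded so every retained case carries the same number of
#' ratings; the exclusion count is reported. The standard error is the
#' large-sample category-sum form, and the 95% confidence interval is
#' truncated to `[-1, 1]`. The verbal interpretation band (poor / fair /
#' moderate / good / very good) is attached via [altman_band()].
#'
#' @param ratings A ratings table: data frame with optional `case_id`
#'   column and one column per rater, or a cases x raters matrix.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `n_cases`, `n_raters`, `n_excluded`, `kappa`,
#'   `se`, `lower`, `upper`, `band`.
#' @export
#' @examples
#' r <- simulate_ratings(n_cases = 30, seed = 7)
#' fleiss_kappa(r$ratings)
fleiss_kappa <- function(ratings, conf_level = 0.95) {
  m <- ratings_codes(ratings)
  if (ncol(m) < 2) stop("need at least 2 raters", call. = FALSE)
  complete <- stats::complete.cases(m)
  n_excluded <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) {
    stop("need at least 2 complete cases (have ", nrow(m), ")",
         call. = FALSE)
  }
  k <- 4L
  n <- ncol(m)          # raters per case
  N <- nrow(m)          # cases
  counts <- t(apply(m, 1, tabulate, nbins = k))
  p_j <- colSums(counts) / (N * n)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12) {
    stop("all ratings fall in a single category; kappa undefined",
         call. = FALSE)
  }
  kap <- (Pbar - Pe) / (1 - Pe)
  se <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(max(Pe - (2 * n - 3) * Pe^2 + 2 * (n - 2) * sum(p_j^3), 0)) /
    (1 - Pe)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    n_cases = N, n_raters = n, n_excluded = n_excluded,
    kappa = kap, se = se,
    lower = max(kap - z * se, -1), upper = min(kap + z * se, 1),
    band = altman_band(kap)
  )
}

#' Verbal interpretation of a kappa value
#'
#' Conventional banding of agreement strength: poor, fair, moderate,
#' good, very good. Bands are applied to the full-precision value as
#' half-open intervals on the upper edge (<= 0.20 poor, <= 0.40 fair,
#' <= 0.60 moderate, <= 0.80 good, otherwise very good), so published
#' band gaps such as (0.20, 0.21) cannot swallow a value; banding always
#' precedes display rounding.
#'
#' @param kappa Numeric kappa value(s), each at most 1.
#' @param edges Upper band edges (poor, fair, moderate, good).
#' @return Ordered factor of band labels.
#' @export
#' @examples
#' altman_band(c(0.45, 0.48, 0.75))
altman_band <- function(kappa,
                        edges = c(poor = 0.20, fair = 0.40,
                                  moderate = 0.60, good = 0.80)) {
  if (any(kappa > 1 + 1e-12, na.rm = TRUE)) {
    stop("kappa cannot exceed 1", call. = FALSE)
  }
  labs <- c(names(edges), "very good")
  idx <- 1L + rowSums(outer(kappa, unname(edges), `>`))
  factor(labs[idx], levels = labs, ordered = TRUE)
}

# coerce a ratings table (df with optional case_id / matrix) to an
# integer code matrix with case ids as rownames
ratings_codes <- function(ratings) {
  if (is.matrix(ratings)) {
    m <- apply(ratings, 2, causality_code)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
    return(m)
  }
  ratings <- tibble::as_tibble(ratings)
  case_id <- if ("case_id" %in% names(ratings)) {
    as.character(ratings$case_id)
  } else {
    as.character(seq_len(nrow(ratings)))
  }
  cols <- setdiff(names(ratings), "case_id")
  if (!length(cols)) stop("no rater columns found", call. = FALSE)
  m <- vapply(ratings[cols], causality_code, integer(nrow(ratings)))
  m <- matrix(m, nrow = nrow(ratings),
              dimnames = list(case_id, cols))
  m
}

#' Full inter-rater agreement report
#'
#' Runs the complete reliability battery on a cases x raters matrix of
#' causality categories: for every rater pair the exact-agreement and
#' extreme-disagreement percentages and the linear weighted kappa with
#' 95% CI (complete pairs only), plus the panel-level Fleiss kappa with
#' 95% CI and Altman band (complete cases only).
#'
#' @param ratings A ratings table (see [fleiss_kappa()]).
#' @param conf_level Confidence level for all intervals.
#' @return Object of class `agreement_report`: list with `pairwise`
#'   (tibble, one row per rater pair) and `global` (one-row tibble).
#'   [generics::tidy()] returns the pairwise table, [generics::glance()]
#'   the global row, and `autoplot()` draws the pairwise kappa matrix.
#' @export
#' @examples
#' panel <- simulate_ratings(seed = 42)
#' rep <- agreement_report(panel$ratings)
#' rep
#' generics::glance(rep)
agreement_report <- function(ratings, conf_level = 0.95) {
  m <- ratings_codes(ratings)
  raters <- colnames(m)
  if (length(raters) < 2) stop("need at least 2 raters", call. = FALSE)
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    x <- m[, pr[1]]
    y <- m[, pr[2]]
    kw <- kappa_linear(x, y, conf_level = conf_level)
    ea <- exact_agreement_pct(x, y)
    ed <- extreme_disagreement_pct(x, y)
    tibble::tibble(
      rater1 = pr[1], rater2 = pr[2], n = kw$n,
      pct_exact = ea, pct_one_step = 100 - ea - ed, pct_extreme = ed,
      kappa = kw$kappa, se = kw$se, lower = kw$lower, upper = kw$upper,
      band = altman_band(kw$kappa), degenerate = kw$degenerate
    )
  })
  structure(
    list(pairwise = pairwise,
         global = fleiss_kappa(m, conf_level = conf_level),
         raters = raters),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  g <- x$global
  cat("Inter-rater agreement: ", g$n_raters, " raters, ", g$n_cases,
      " complete cases", sep = "")
  if (g$n_excluded > 0) cat(" (", g$n_excluded, " excluded)", sep = "")
  cat("\nGlobal kappa ", sprintf("%.2f", g$kappa), " (95% CI ",
      sprintf("%.2f", g$lower), ", ", sprintf("%.2f", g$upper), "), ",
      as.character(g$band), " agreement\n\n", sep = "")
  p <- x$pairwise
  disp <- tibble::tibble(
    pair = paste(p$rater1, p$rater2, sep = "-"),
    `%EA/%ED` = sprintf("%.1f/%.1f", p$pct_exact, p$pct_extreme),
    kappa = sprintf("%.2f (%.2f, %.2f)", p$kappa, p$lower, p$upper)
  )
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) x$global

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  p <- object$pairwise
  both <- dplyr::bind_rows(
    p,
    dplyr::rename(p, rater1 = "rater2", rater2 = "rater1")
  )
  both$rater1 <- factor(both$rater1, levels = object$raters)
  both$rater2 <- factor(both$rater2, levels = object$raters)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$rater2, y = .data$rater1,
                                     fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n%.0f%%", .data$kappa, .data$pct_exact)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0.5,
                                  limits = c(-1, 1), name = "weighted\nkappa") +
    ggplot2::scale_y_discrete(limits = rev(object$raters)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise agreement (weighted kappa, %EA)") +
    ggplot2::theme_minimal()
}
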