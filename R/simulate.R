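#' Simulate a panel of raters assessing ADR cases
#'
#' Generates synthetic multi-rater causality data with known latent
#' truth. Each case draws a latent true category i.i.d. from
#' `prevalence`; each rater independently reports the latent category
#' with probability `fidelity`, otherwise a different category at
#' ordinal distance `d` with probability proportional to
#' `spillover_decay^d` (renormalised over the other three categories).
#' `spillover_decay < 1` concentrates errors one category away from the
#' truth, the pattern typical of causality panels; `spillover_decay = 1`
#' spreads errors uniformly.
#'
#' Defaults emulate a study arm of seven investigators independently
#' assessing 40 case reports, with prevalence set to the collated
#' category distribution such panels typically produce (heavy in
#' probable/definite, essentially no unlikely).
#'
#' @param n_cases Number of cases.
#' @param n_raters Number of raters.
#' @param prevalence Probability vector over the four categories
#'   (unlikely, possible, probable, definite); must sum to 1.
#' @param fidelity Probability a rater reports the latent category
#'   exactly, in `[0, 1]`.
#' @param spillover_decay Per-step multiplicative decay of
#'   misclassification probability with ordinal distance, in `(0, 1]`.
#' @param seed Optional integer seed; when given, the panel is a pure
#'   function of the arguments (the global RNG state is restored).
#' @return Object of class `simulated_panel`: list with `latent`
#'   (tibble `case_id`, `latent`), `ratings` (tibble `case_id` plus one
#'   category column per rater) and `config`.
#' @export
#' @examples
#' panel <- simulate_ratings(n_cases = 10, n_raters = 3, seed = 1)
#' panel$ratings
simulate_ratings <- function(n_cases = 40, n_raters = 7,
                             prevalence = c(1, 62, 92, 125) / 280,
                             fidelity = 0.8, spillover_decay = 0.5,
                             seed = NULL) {
  cfg <- sim_config(n_cases, n_raters, prevalence, fidelity,
                    spillover_decay, seed)
  draw <- function() {
    lv <- causality_levels()
    latent <- sample.int(4L, cfg$n_cases, replace = TRUE,
                         prob = cfg$prevalence)
    # 4x4 row-stochastic misclassification kernel, rows = latent category
    kern <- t(vapply(1:4, function(tr) {
      p <- numeric(4)
      p[tr] <- cfg$fidelity
      others <- setdiff(1:4, tr)
      wts <- cfg$spillover_decay^abs(others - tr)
      p[others] <- (1 - cfg$fidelity) * wts / sum(wts)
      p
    }, numeric(4)))
    ratings <- matrix(NA_integer_, cfg$n_cases, cfg$n_raters)
    for (r in seq_len(cfg$n_raters)) {
      u <- stats::runif(cfg$n_cases)
      cum <- t(apply(kern[latent, , drop = FALSE], 1, cumsum))
      ratings[, r] <- 1L + rowSums(cum < u)
    }
    case_id <- sprintf("case%03d", seq_len(cfg$n_cases))
    rt <- tibble::as_tibble(
      stats::setNames(
        lapply(seq_len(cfg$n_raters),
               function(r) as_causality(ratings[, r])),
        sprintf("R%d", seq_len(cfg$n_raters))
      )
    )
    structure(
      list(
        latent = tibble::tibble(case_id = case_id,
                                latent = as_causality(latent)),
        ratings = dplyr::bind_cols(tibble::tibble(case_id = case_id), rt),
        config = cfg
      ),
      class = "simulated_panel"
    )
  }
  if (is.null(cfg$seed)) draw() else withr::with_seed(cfg$seed, draw())
}

# validate and normalise simulation parameters
sim_config <- function(n_cases, n_raters, prevalence, fidelity,
                       spillover_decay, seed = NULL) {
  if (n_cases < 1 || n_raters < 1) {
    stop("n_cases and n_raters must be positive", call. = FALSE)
  }
  if (length(prevalence) != 4 || any(prevalence < 0)) {
    stop("prevalence must be 4 non-negative probabilities", call. = FALSE)
  }
  if (abs(sum(prevalence) - 1) > 1e-12) {
    stop("prevalence must sum to 1 (got ", sum(prevalence), ")",
         call. = FALSE)
  }
  if (fidelity < 0 || fidelity > 1) {
    stop("fidelity must lie in [0, 1]", call. = FALSE)
  }
  if (spillover_decay <= 0 || spillover_decay > 1) {
    stop("spillover_decay must lie in (0, 1]", call. = FALSE)
  }
  list(n_cases = as.integer(n_cases), n_raters = as.integer(n_raters),
       prevalence = as.numeric(prevalence), fidelity = fidelity,
       spillover_decay = spillover_decay,
       seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' @export
print.simulated_panel <- function(x, ...) {
  cfg <- x$config
  cat("Simulated rater panel: ", cfg$n_cases, " cases x ", cfg$n_raters,
      " raters (fidelity ", cfg$fidelity, ", spillover decay ",
      cfg$spillover_decay, ")\n", sep = "")
  if (!is.null(x$sheets)) {
    cat("with ", nrow(x$sheets), " decision-tree answer sheets\n", sep = "")
  }
  invisible(x)
}

#' Simulate a full decision-tree study
#'
#' Extends [simulate_ratings()] to the answer-sheet level: for every
#' simulated rating a decision-tree answer sheet is drawn by inverse
#' path sampling ([sample_answer_sheet()]) on the reported category, so
#' that re-assessing every sheet with [assess_liverpool()] reproduces
#' the ratings matrix cell for cell. The result feeds directly into
#' [agreement_report()] for an end-to-end study replay.
#'
#' @inheritParams simulate_ratings
#' @param tree A `decision_tree`; default the packaged Liverpool tool.
#' @return A `simulated_panel` whose `sheets` element is a tibble with
#'   `case_id`, `rater_id` and one column per visited tree node.
#' @export
#' @examples
#' study <- simulate_study(n_cases = 5, n_raters = 2, seed = 3)
#' study$sheets
simulate_study <- function(n_cases = 40, n_raters = 7,
                           prevalence = c(1, 62, 92, 125) / 280,
                           fidelity = 0.8, spillover_decay = 0.5,
                           seed = NULL, tree = liverpool_tree()) {
  run <- function() {
    panel <- simulate_ratings(n_cases, n_raters, prevalence, fidelity,
                              spillover_decay, seed = NULL)
    paths <- enumerate_paths(tree)
    long <- tidyr::pivot_longer(panel$ratings, -"case_id",
                                names_to = "rater_id",
                                values_to = "category")
    sheet_rows <- purrr::map(seq_len(nrow(long)), function(i) {
      ans <- sample_answer_sheet(tree, long$category[i], paths = paths)
      tibble::as_tibble(as.list(ans))
    })
    sheets <- dplyr::bind_cols(
      long[, c("case_id", "rater_id")],
      dplyr::bind_rows(sheet_rows)
    )
    panel$sheets <- sheets
    panel
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$config$seed <- if (is.null(seed)) NULL else as.integer(seed)
  out
}
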