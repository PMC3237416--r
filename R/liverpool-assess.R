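#' Assess one case with a decision tree
#'
#' Deterministic traversal from the root: at each question node the
#' recorded answer selects the next node, until a leaf is reached.
#' Answers for questions off the taken path may be absent (a flowchart
#' only asks along the path); a missing or disallowed answer at a node
#' actually visited is an error naming the node and its prompt.
#'
#' @param tree A `decision_tree`.
#' @param answers Named character vector or list, node id -> answer token.
#' @return A list of class `liverpool_assessment` with `category` (ordered
#'   factor) and `path` (tibble of `node`, `prompt`, `answer` in visit
#'   order).
#' @export
#' @examples
#' tree <- liverpool_tree()
#' assess(tree, c(temporal = "yes", alt_cause = "no", withdrawn = "yes",
#'                improved = "yes", rechallenge = "yes"))
assess <- function(tree, answers) {
  answers <- unlist(answers)
  if (!is.null(names(answers))) {
    names(answers) <- trimws(names(answers))
  }
  id <- tree$root
  steps <- list()
  while (!id %in% names(tree$leaves)) {
    nd <- tree$nodes[[id]]
    a <- if (id %in% names(answers)) answers[[id]] else NA_character_
    a <- tolower(trimws(as.character(a)))
    if (is.na(a) || a == "") {
      stop("no answer for visited node ", sQuote(id), " (",
           nd$prompt, ")", call. = FALSE)
    }
    if (!a %in% names(nd$routes)) {
      stop("answer ", sQuote(a), " not allowed at node ", sQuote(id),
           " (", nd$prompt, "); expected one of ",
           paste(names(nd$routes), collapse = "/"), call. = FALSE)
    }
    steps[[length(steps) + 1]] <- tibble::tibble(
      node = id, prompt = nd$prompt, answer = a
    )
    id <- nd$routes[[a]]
  }
  structure(
    list(
      category = as_causality(unname(tree$leaves[[id]])),
      leaf = id,
      path = if (length(steps)) dplyr::bind_rows(steps)
             else tibble::tibble(node = character(0), prompt = character(0),
                                 answer = character(0))
    ),
    class = "liverpool_assessment"
  )
}

#' @export
print.liverpool_assessment <- function(x, ...) {
  cat("category: ", as.character(x$category), "\n", sep = "")
  for (i in seq_len(nrow(x$path))) {
    cat("  ", x$path$node[i], " = ", x$path$answer[i], "\n", sep = "")
  }
  invisible(x)
}

#' Assess a table of decision-tree answer sheets
#'
#' Tidy entry point mirroring the CSV answer-sheet layout: one row per
#' case and rater, one column per question node id, blank/NA meaning the
#' question was not visited.
#'
#' @param sheets Data frame with `case_id`, `rater_id` and one column per
#'   node id of the tree (columns for unvisited nodes may be absent).
#' @param tree A `decision_tree`; default the packaged Liverpool tool.
#' @param explain If `TRUE`, append a `path` column with the traversal
#'   rendered as `node=answer` steps separated by `" -> "`.
#' @return Tibble with `case_id`, `rater_id`, `category` (and `path`).
#' @export
#' @examples
#' sheets <- tibble::tibble(case_id = "c1", rater_id = "r1",
#'   temporal = "yes", alt_cause = "yes")
#' assess_liverpool(sheets)
assess_liverpool <- function(sheets, tree = liverpool_tree(),
                             explain = FALSE) {
  sheets <- tibble::as_tibble(sheets)
  if (!all(c("case_id", "rater_id") %in% names(sheets))) {
    stop("answer sheet needs case_id and rater_id columns", call. = FALSE)
  }
  qcols <- intersect(names(sheets), names(tree$nodes))
  res <- purrr::map(seq_len(nrow(sheets)), function(i) {
    ans <- as.character(unlist(sheets[i, qcols]))
    names(ans) <- qcols
    ans <- ans[!is.na(ans) & trimws(ans) != ""]
    tryCatch(
      assess(tree, ans),
      error = function(e) {
        stop("row ", i, " (case ", sheets$case_id[i], ", rater ",
             sheets$rater_id[i], "): ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  out <- dplyr::mutate(
    sheets[, c("case_id", "rater_id")],
    category = as_causality(vapply(res, function(r) as.character(r$category),
                                   character(1)))
  )
  if (explain) {
    out$path <- vapply(res, function(r) {
      paste(paste0(r$path$node, "=", r$path$answer), collapse = " -> ")
    }, character(1))
  }
  out
}

#' Sample an answer sheet that yields a given category
#'
#' Inverse of [assess()]: draws uniformly one of the enumerated
#' root-to-leaf paths ending in the target category and returns the
#' answers along it. Uses R's random number generator; seed it (or wrap
#' in `withr::with_seed()`) for reproducibility.
#'
#' @param tree A `decision_tree`.
#' @param target A causality category (token or factor).
#' @param paths Optional pre-computed [enumerate_paths()] table, to avoid
#'   re-enumeration in tight loops.
#' @return Named character vector, node id -> answer.
#' @export
#' @examples
#' withr::with_seed(1, sample_answer_sheet(liverpool_tree(), "definite"))
sample_answer_sheet <- function(tree, target, paths = NULL) {
  target <- as.character(as_causality(as.character(target)))
  if (is.null(paths)) paths <- enumerate_paths(tree)
  hits <- which(paths$category == target)
  if (!length(hits)) {
    stop("category ", sQuote(target), " is not reachable in this tree",
         call. = FALSE)
  }
  pick <- if (length(hits) == 1L) hits else hits[sample.int(length(hits), 1L)]
  paths$answers[[pick]]
}
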