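#' Construct a causality decision tree
#'
#' A decision tree routes an assessor through a sequence of prompts, each
#' with two or three admissible answers, to a leaf labelled with one of
#' the four causality categories. Trees are data: the packaged Liverpool
#' tool is one such document ([liverpool_tree()]), and variants can be
#' built programmatically or loaded from JSON with [read_tree()].
#'
#' Structural requirements (enforced when `validate = TRUE`, with every
#' violation listed): unique ids, a root that exists, every route target
#' existing, at least two answers per node, no directed cycles, every
#' node reachable from the root, every leaf labelled with a scale
#' category. Semantic diagnostics beyond these (full category range,
#' the definite gate) are reported by [validate_tree()] but do not block
#' construction.
#'
#' @param nodes List of node definitions; each a list with `id`, `prompt`,
#'   `routes` (named list answer -> target id) and optional `tags`.
#' @param leaves List of leaf definitions; each a list with `id` and
#'   `category`.
#' @param root Id of the root node.
#' @param metadata Optional list (name, version, notes).
#' @param validate If `TRUE` (default), abort on structural violations.
#' @return An object of class `decision_tree`.
#' @export
decision_tree <- function(nodes, leaves, root, metadata = list(),
                          validate = TRUE) {
  node_list <- list()
  for (nd in nodes) {
    node_list[[nd$id]] <- list(
      id = nd$id,
      prompt = nd$prompt %||% nd$id,
      routes = lapply(nd$routes, as.character),
      tags = nd$tags %||% list()
    )
  }
  leaf_cat <- character(0)
  for (lf in leaves) leaf_cat[[lf$id]] <- tolower(as.character(lf$category))
  tree <- structure(
    list(root = root, nodes = node_list, leaves = leaf_cat,
         metadata = metadata),
    class = "decision_tree"
  )
  if (validate) {
    diag <- validate_tree(tree)
    hard <- diag[diag$structural & !diag$pass, , drop = FALSE]
    if (nrow(hard)) {
      stop("invalid decision tree:\n",
           paste0("  - ", hard$check, ": ", hard$detail, collapse = "\n"),
           call. = FALSE)
    }
  }
  tree
}

#' Load a decision tree from a JSON document
#'
#' @param path Path to a JSON file with `root`, `nodes[]` (id, prompt,
#'   routes, optional tags) and `leaves[]` (id, category).
#' @return A validated `decision_tree`; structural violations abort with
#'   all of them listed.
#' @export
#' @examples
#' tree <- liverpool_tree()
#' tree
read_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$root) || is.null(doc$nodes) || is.null(doc$leaves)) {
    stop("tree document must define root, nodes[] and leaves[]",
         call. = FALSE)
  }
  ids <- c(
    vapply(doc$nodes, function(n) as.character(n$id), character(1)),
    vapply(doc$leaves, function(l) as.character(l$id), character(1))
  )
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("invalid decision tree:\n  - unique ids: duplicate id(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  decision_tree(doc$nodes, doc$leaves, doc$root,
                metadata = doc$metadata %||% list())
}

#' @rdname read_tree
#' @export
liverpool_tree <- function() {
  read_tree(system.file("extdata", "liverpool_cat.json", package = "adrcat"))
}

#' @export
print.decision_tree <- function(x, ...) {
  nm <- x$metadata$name %||% "decision tree"
  cat(nm, "\n", sep = "")
  cat(length(x$nodes), " question nodes, ", length(x$leaves),
      " leaves, root: ", x$root, "\n", sep = "")
  pt <- enumerate_paths(x)
  cat(nrow(pt), " root-to-leaf paths; categories reachable: ",
      paste(sort(unique(as.character(pt$category))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# depth-first reachability over node routes; returns visited node/leaf ids
reachable_ids <- function(tree) {
  seen <- character(0)
  stack <- tree$root
  while (length(stack)) {
    id <- stack[[1]]
    stack <- stack[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    if (!is.null(tree$nodes[[id]])) {
      stack <- c(stack, unlist(tree$nodes[[id]]$routes, use.names = FALSE))
    }
  }
  seen
}

# TRUE if a directed cycle exists among the question nodes
has_cycle <- function(tree) {
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  visit <- function(id) {
    if (is.null(tree$nodes[[id]])) return(FALSE) # leaf
    st <- state[[id]]
    if (!is.null(st)) return(st == 1L)
    state[[id]] <- 1L
    for (tgt in unlist(tree$nodes[[id]]$routes, use.names = FALSE)) {
      if (visit(tgt)) return(TRUE)
    }
    state[[id]] <- 2L
    FALSE
  }
  any(vapply(names(tree$nodes), visit, logical(1)))
}

#' Validate a decision tree
#'
#' Runs the full battery of structural and semantic checks and returns a
#' diagnostics table (no exception is thrown, whatever the outcome).
#' Structural checks: the root exists, ids are unique, every route target
#' exists, every node offers at least two answers, the graph is acyclic,
#' every node and leaf is reachable from the root, every leaf carries one
#' of the four scale categories. Semantic checks: all four causality
#' categories label at least one reachable leaf (`full_range`), and every
#' path to a `definite` leaf passes through an affirmative answer at a
#' node tagged `rechallenge_gate` (`definite_gate`) -- the design rule
#' that a definite verdict requires a positive re-challenge or a previous
#' reaction to the same drug.
#'
#' @param tree A `decision_tree` (possibly built with `validate = FALSE`).
#' @return A tibble with columns `check`, `structural`, `pass`, `detail`.
#' @export
#' @examples
#' validate_tree(liverpool_tree())
validate_tree <- function(tree) {
  checks <- list()
  add <- function(check, structural, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, structural = structural, pass = pass, detail = detail
    )
  }

  all_ids <- c(names(tree$nodes), names(tree$leaves))
  add("root_exists", TRUE, tree$root %in% names(tree$nodes),
      if (!tree$root %in% names(tree$nodes))
        paste0("root ", sQuote(tree$root), " is not a node") else "")

  dup <- unique(all_ids[duplicated(all_ids)])
  add("unique_ids", TRUE, length(dup) == 0,
      if (length(dup)) paste("duplicate id(s):", paste(dup, collapse = ", "))
      else "")

  dangling <- character(0)
  thin <- character(0)
  for (nd in tree$nodes) {
    if (length(nd$routes) < 2) thin <- c(thin, nd$id)
    miss <- setdiff(unlist(nd$routes, use.names = FALSE), all_ids)
    if (length(miss)) {
      dangling <- c(dangling, paste0(nd$id, " -> ", miss))
    }
  }
  add("route_targets_exist", TRUE, length(dangling) == 0,
      if (length(dangling)) paste("dangling route(s):",
                                  paste(dangling, collapse = "; ")) else "")
  add("min_two_answers", TRUE, length(thin) == 0,
      if (length(thin)) paste("node(s) with <2 answers:",
                              paste(thin, collapse = ", ")) else "")

  bad_leaf <- names(tree$leaves)[!tree$leaves %in% causality_levels()]
  add("leaves_labelled", TRUE, length(bad_leaf) == 0,
      if (length(bad_leaf)) paste("leaf/leaves with unknown category:",
                                  paste(bad_leaf, collapse = ", ")) else "")

  structural_ok <- all(vapply(checks, function(x) x$pass, logical(1)))
  cyc <- if (structural_ok) has_cycle(tree) else NA
  add("acyclic", TRUE, isFALSE(cyc),
      if (isTRUE(cyc)) "directed cycle among question nodes"
      else if (is.na(cyc)) "not evaluated (earlier structural failure)"
      else "")

  if (structural_ok && isFALSE(cyc)) {
    seen <- reachable_ids(tree)
    unreach <- setdiff(all_ids, seen)
    add("all_reachable", TRUE, length(unreach) == 0,
        if (length(unreach)) paste("unreachable:",
                                   paste(unreach, collapse = ", ")) else "")

    paths <- enumerate_paths(tree)
    cats <- unique(as.character(paths$category))
    missing_cat <- setdiff(causality_levels(), cats)
    add("full_range", FALSE, length(missing_cat) == 0,
        if (length(missing_cat)) paste("unreachable category/ies:",
                                       paste(missing_cat, collapse = ", "))
        else "")

    def_paths <- paths[paths$category == "definite", , drop = FALSE]
    gate_nodes <- names(tree$nodes)[vapply(
      tree$nodes, function(nd) isTRUE(nd$tags$rechallenge_gate), logical(1)
    )]
    gated <- vapply(def_paths$answers, function(a) {
      any(names(a) %in% gate_nodes & tolower(unlist(a)) == "yes")
    }, logical(1))
    add("definite_gate", FALSE,
        nrow(def_paths) == 0 || all(gated),
        if (nrow(def_paths) && !all(gated))
          paste(sum(!gated),
                "path(s) reach definite without an affirmative",
                "re-challenge/previous-reaction answer") else "")
  } else {
    add("all_reachable", TRUE, NA, "not evaluated (structural failure)")
    add("full_range", FALSE, NA, "not evaluated (structural failure)")
    add("definite_gate", FALSE, NA, "not evaluated (structural failure)")
  }

  dplyr::bind_rows(checks)
}

#' Enumerate all root-to-leaf paths of a decision tree
#'
#' @param tree A structurally valid `decision_tree`.
#' @return A tibble with one row per path: `path_id`, the leaf `category`,
#'   the path `length` (number of questions answered), and `answers`, a
#'   list-column of named character vectors (node id -> answer) tracing
#'   the path.
#' @export
#' @examples
#' paths <- enumerate_paths(liverpool_tree())
#' dplyr::count(paths, category)
enumerate_paths <- function(tree) {
  acc <- list()
  walk <- function(id, answers) {
    if (id %in% names(tree$leaves)) {
      acc[[length(acc) + 1]] <<- list(category = unname(tree$leaves[[id]]),
                                      answers = answers)
      return(invisible())
    }
    nd <- tree$nodes[[id]]
    for (ans in names(nd$routes)) {
      walk(nd$routes[[ans]], c(answers, stats::setNames(ans, nd$id)))
    }
  }
  walk(tree$root, character(0))
  tibble::tibble(
    path_id = seq_along(acc),
    category = as_causality(vapply(acc, `[[`, character(1), "category")),
    length = vapply(acc, function(p) length(p$answers), integer(1)),
    answers = lapply(acc, `[[`, "answers")
  )
}
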