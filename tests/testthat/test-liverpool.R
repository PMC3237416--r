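test_that("a minimal one-question tree loads, assesses and enumerates", {
  tr <- one_node_tree()
  expect_s3_class(tr, "decision_tree")
  res <- assess(tr, c(q1 = "yes"))
  expect_identical(as.character(res$category), "definite")
  expect_identical(nrow(res$path), 1L)
  expect_identical(as.character(assess(tr, c(q1 = "no"))$category),
                   "unlikely")
  expect_identical(nrow(enumerate_paths(tr)), 2L)
})

test_that("structural defects abort construction with all violations listed", {
  expect_error(
    decision_tree(
      nodes = list(list(id = "a", prompt = "p",
                        routes = list(yes = "nowhere", no = "u"))),
      leaves = list(list(id = "u", category = "unlikely")),
      root = "a"
    ),
    "dangling"
  )
  # a document with a duplicated id
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"root":"a",
    "nodes":[{"id":"a","prompt":"p","routes":{"yes":"u","no":"u"}}],
    "leaves":[{"id":"u","category":"unlikely"},
              {"id":"u","category":"possible"}]}', tmp)
  expect_error(read_tree(tmp), "duplicate")
  # unlabeled leaf
  expect_error(
    decision_tree(
      nodes = list(list(id = "a", prompt = "p",
                        routes = list(yes = "u", no = "v"))),
      leaves = list(list(id = "u", category = "unlikely"),
                    list(id = "v", category = "plausible")),
      root = "a"
    ),
    "unknown category"
  )
})

test_that("validate_tree reports cycles, gate failures and range gaps", {
  # route back to an ancestor
  cyclic <- decision_tree(
    nodes = list(
      list(id = "a", prompt = "p", routes = list(yes = "b", no = "u")),
      list(id = "b", prompt = "q", routes = list(yes = "a", no = "u"))
    ),
    leaves = list(list(id = "u", category = "unlikely")),
    root = "a", validate = FALSE
  )
  diag <- validate_tree(cyclic)
  expect_false(diag$pass[diag$check == "acyclic"])

  # definite directly under the root with no gated node
  ungated <- one_node_tree(gate = FALSE)
  diag <- validate_tree(ungated)
  expect_false(diag$pass[diag$check == "definite_gate"])
  expect_false(diag$pass[diag$check == "full_range"])

  # same shape but with the gate tag set: gate passes, range still short
  gated <- one_node_tree(gate = TRUE)
  diag <- validate_tree(gated)
  expect_true(diag$pass[diag$check == "definite_gate"])
})

test_that("the packaged tree passes the full battery and spans the scale", {
  tree <- liverpool_tree()
  diag <- validate_tree(tree)
  expect_true(all(diag$pass))
  paths <- enumerate_paths(tree)
  expect_setequal(unique(as.character(paths$category)), causality_levels())
  # ternary routing appears exactly at the alternative-cause question
  n_answers <- vapply(tree$nodes, function(nd) length(nd$routes), integer(1))
  expect_identical(names(n_answers)[n_answers == 3], "alt_cause")
})

test_that("enumeration and assessment round-trip on the packaged tree", {
  tree <- liverpool_tree()
  paths <- enumerate_paths(tree)
  for (i in seq_len(nrow(paths))) {
    res <- assess(tree, paths$answers[[i]])
    expect_identical(as.character(res$category),
                     as.character(paths$category[i]))
    # the recorded path is exactly the enumerated answer sequence
    expect_identical(stats::setNames(res$path$answer, res$path$node),
                     paths$answers[[i]])
    # purity: a second call agrees
    expect_identical(assess(tree, paths$answers[[i]])$category,
                     res$category)
  }
  # every path to definite carries the affirmative gated answer
  def <- paths[paths$category == "definite", ]
  expect_gt(nrow(def), 0)
  for (a in def$answers) expect_identical(unname(a[["rechallenge"]]), "yes")
})

test_that("path counts follow the routing structure", {
  chained <- decision_tree(
    nodes = list(
      list(id = "a", prompt = "p", routes = list(yes = "b", no = "u")),
      list(id = "b", prompt = "q", routes = list(yes = "d", no = "u2"),
           tags = list(rechallenge_gate = TRUE))
    ),
    leaves = list(list(id = "u", category = "unlikely"),
                  list(id = "u2", category = "possible"),
                  list(id = "d", category = "definite")),
    root = "a"
  )
  expect_identical(nrow(enumerate_paths(chained)), 3L)
})

test_that("assessment errors name the node where the sheet falls short", {
  tree <- liverpool_tree()
  expect_error(assess(tree, c(temporal = "yes")), "alt_cause")
  expect_error(assess(tree, c(temporal = "sometimes")),
               "not allowed.*temporal")
  # off-path answers may be absent: alt_cause=yes ends at unlikely
  res <- assess(tree, c(temporal = "yes", alt_cause = "yes"))
  expect_identical(as.character(res$category), "unlikely")
})

test_that("assess_liverpool handles sheet tables, blanks and --explain", {
  sheets <- tibble::tibble(
    case_id = c("c1", "c2"), rater_id = "r1",
    temporal = c("yes", "no"), alt_cause = c("yes", NA)
  )
  res <- assess_liverpool(sheets, explain = TRUE)
  expect_identical(as.character(res$category), c("unlikely", "unlikely"))
  expect_match(res$path[1], "temporal=yes -> alt_cause=yes")
  sheets$temporal[2] <- "yes"
  sheets$alt_cause[2] <- NA
  expect_error(assess_liverpool(sheets), "case c2.*alt_cause")
})

test_that("inverse path sampling always reproduces the target category", {
  tree <- liverpool_tree()
  paths <- enumerate_paths(tree)
  withr::with_seed(99, {
    for (target in causality_levels()) {
      for (k in 1:5) {
        ans <- sample_answer_sheet(tree, target, paths = paths)
        expect_identical(as.character(assess(tree, ans)$category), target)
      }
    }
  })
  # unique path on the one-node tree
  ans <- sample_answer_sheet(one_node_tree(), "definite")
  expect_identical(ans, c(q1 = "yes"))
  expect_error(sample_answer_sheet(one_node_tree(), "probable"),
               "not reachable")
  # the gate answer is present on every sampled definite sheet
  withr::with_seed(7, {
    for (k in 1:10) {
      ans <- sample_answer_sheet(tree, "definite", paths = paths)
      expect_identical(unname(ans[["rechallenge"]]), "yes")
    }
  })
})
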