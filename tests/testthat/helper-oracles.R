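# Independent brute-force oracles: plain-loop evaluations of the agreement
# formulas, written against the definitions, not the package internals.

# weighted kappa with linear weights from a k x k contingency table
oracle_weighted_kappa <- function(tab) {
  tab <- as.matrix(tab)
  k <- nrow(tab)
  n <- sum(tab)
  ri <- rowSums(tab) / n
  cj <- colSums(tab) / n
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- 1 - abs(i - j) / (k - 1)
      po <- po + w * tab[i, j] / n
      pe <- pe + w * ri[i] * cj[j]
    }
  }
  unname((po - pe) / (1 - pe))
}

# unweighted Cohen's kappa from a contingency table
oracle_cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  unname((po - pe) / (1 - pe))
}

# Fleiss' multi-rater kappa from an N x k matrix of per-case category
# counts (constant row sum = number of raters)
oracle_fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  N <- nrow(counts)
  n <- sum(counts[1, ])
  stopifnot(all(rowSums(counts) == n))
  pj <- colSums(counts) / (N * n)
  Pi <- numeric(N)
  for (i in seq_len(N)) {
    Pi[i] <- (sum(counts[i, ]^2) - n) / (n * (n - 1))
  }
  unname((mean(Pi) - sum(pj^2)) / (1 - sum(pj^2)))
}

# deterministic ratings table realising a per-case count matrix:
# case i gets its categories in nondecreasing order across raters
ratings_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  m <- t(apply(counts, 1, function(cnt) rep(seq_len(k), times = cnt)))
  out <- tibble::as_tibble(
    stats::setNames(
      lapply(seq_len(ncol(m)), function(r) adrcat::as_causality(m[, r])),
      sprintf("R%d", seq_len(ncol(m)))
    )
  )
  dplyr::bind_cols(tibble::tibble(case_id = seq_len(nrow(m))), out)
}

# two-rater ratings tibble from code vectors
wide_ratings <- function(x, y) {
  tibble::tibble(case_id = seq_along(x),
                 R1 = adrcat::as_causality(x),
                 R2 = adrcat::as_causality(y))
}

# a minimal well-formed one-question tree: yes -> definite, no -> unlikely
one_node_tree <- function(gate = FALSE) {
  adrcat::decision_tree(
    nodes = list(list(
      id = "q1", prompt = "did it recur on re-exposure?",
      routes = list(yes = "d", no = "u"),
      tags = if (gate) list(rechallenge_gate = TRUE) else list()
    )),
    leaves = list(list(id = "d", category = "definite"),
                  list(id = "u", category = "unlikely")),
    root = "q1"
  )
}
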