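test_that("weighted kappa: perfect agreement, symmetry, frozen example", {
  x <- c(1, 2, 3, 4, 2, 3)
  expect_identical(kappa_linear(x, x)$kappa, 1)

  # 4 cases rated (1,1),(2,2),(3,4),(4,3): closed form 0.6, var 27/625
  kw <- kappa_linear(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(kw$kappa, 0.6, tolerance = 1e-12)
  expect_equal(kw$se, sqrt(27 / 625), tolerance = 1e-12)
  expect_equal(kw$lower, 0.6 - stats::qnorm(0.975) * sqrt(27 / 625),
               tolerance = 1e-12)

  # swapping raters changes nothing
  set.seed(21)
  a <- sample(1:4, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(kappa_linear(a, b), kappa_linear(b, a), tolerance = 1e-12)
})

test_that("weighted kappa matches the direct-formula oracle on random tables", {
  set.seed(1234)
  for (rep in 1:20) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- pmin(pmax(a + sample(-2:2, 50, replace = TRUE), 1), 4)
    tab <- table(factor(a, 1:4), factor(b, 1:4))
    expect_equal(kappa_linear(a, b)$kappa, oracle_weighted_kappa(tab),
                 tolerance = 1e-12)
    # contingency-table route agrees with the case-by-case route
    expect_equal(adrcat:::kappa_linear_from_table(tab),
                 kappa_linear(a, b)$kappa, tolerance = 1e-12)
  }
})

test_that("with only the two extreme categories the linear weights
           degenerate to unweighted Cohen's kappa", {
  set.seed(55)
  a <- sample(c(1, 4), 60, replace = TRUE)
  b <- ifelse(stats::runif(60) < 0.7, a, sample(c(1, 4), 60, replace = TRUE))
  tab <- table(factor(a, 1:4), factor(b, 1:4))
  expect_equal(kappa_linear(a, b)$kappa,
               oracle_cohen_kappa(table(a, b)), tolerance = 1e-12)
})

test_that("degenerate and insufficient inputs are handled as contracts", {
  expect_error(kappa_linear(1, 1), "at least 2")
  # both raters constant on one category: flagged, not thrown
  kw <- kappa_linear(rep("probable", 5), rep("probable", 5))
  expect_true(kw$degenerate)
  expect_true(is.na(kw$kappa))
  # missing entries drop to complete pairs
  kw <- kappa_linear(c(1, 2, NA, 4), c(1, NA, 3, 4))
  expect_identical(kw$n, 2L)
})

test_that("exact agreement and extreme disagreement percentages", {
  x <- rep(c("possible", "probable"), 20)
  expect_identical(exact_agreement_pct(x, x), 100)
  y <- x
  y[seq_len(23)] <- ifelse(x[seq_len(23)] == "possible", "probable",
                           "possible")
  expect_equal(exact_agreement_pct(x, y), 42.5, tolerance = 1e-12)
  expect_identical(exact_agreement_pct(rep(1, 10), rep(2, 10)), 0)

  expect_identical(extreme_disagreement_pct("possible", "definite"), 100)
  expect_identical(extreme_disagreement_pct("probable", "definite"), 0)
  x <- rep("possible", 40)
  y <- x
  x[40] <- "unlikely"
  y[40] <- "probable"
  expect_equal(extreme_disagreement_pct(x, y), 2.5, tolerance = 1e-12)
})

test_that("%EA + one-step% + %ED = 100 for any two raters", {
  set.seed(777)
  for (rep in 1:10) {
    a <- sample(1:4, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    total <- exact_agreement_pct(a, b) + extreme_disagreement_pct(a, b) +
      (100 - exact_agreement_pct(a, b) - extreme_disagreement_pct(a, b))
    expect_equal(total, 100, tolerance = 1e-12)
    mid <- mean(abs(a - b) == 1) * 100
    expect_equal(exact_agreement_pct(a, b) + mid +
                   extreme_disagreement_pct(a, b), 100, tolerance = 1e-12)
  }
})

test_that("Fleiss kappa matches the oracle on a fixed count table and is
           invariant to row and column permutation", {
  set.seed(31)
  counts <- t(stats::rmultinom(20, size = 7, prob = c(0.1, 0.3, 0.4, 0.2)))
  ratings <- ratings_from_counts(counts)
  fk <- fleiss_kappa(ratings)
  expect_equal(fk$kappa, oracle_fleiss_kappa(counts), tolerance = 1e-12)
  expect_identical(fk$n_cases, 20L)
  expect_identical(fk$n_raters, 7L)

  perm_rows <- ratings[sample(nrow(ratings)), ]
  perm_cols <- ratings[, c("case_id", sample(paste0("R", 1:7)))]
  expect_equal(fleiss_kappa(perm_rows)$kappa, fk$kappa, tolerance = 1e-12)
  expect_equal(fleiss_kappa(perm_cols)$kappa, fk$kappa, tolerance = 1e-12)
})

test_that("Fleiss kappa is exactly 1 under unanimous raters", {
  ratings <- wide_ratings(c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 2))
  ratings$R3 <- ratings$R1
  expect_identical(fleiss_kappa(ratings)$kappa, 1)
})

test_that("Fleiss kappa excludes incomplete cases and errors when starved", {
  ratings <- wide_ratings(c(1, 2, 3, 4, NA), c(1, 2, 3, 4, 2))
  fk <- fleiss_kappa(ratings)
  expect_identical(fk$n_excluded, 1L)
  expect_identical(fk$n_cases, 4L)
  expect_error(fleiss_kappa(wide_ratings(c(1, NA), c(1, 2))),
               "at least 2 complete")
  expect_error(fleiss_kappa(wide_ratings(rep(2, 5), rep(2, 5))),
               "single category")
})

test_that("Altman bands are half-open on the full-precision value", {
  expect_identical(as.character(altman_band(0.45)), "moderate")
  expect_identical(as.character(altman_band(0.48)), "moderate")
  expect_identical(as.character(altman_band(0.75)), "good")
  expect_identical(
    as.character(altman_band(c(-0.3, 0.2, 0.205, 0.6, 0.605, 1.0))),
    c("poor", "poor", "fair", "moderate", "good", "very good")
  )
  expect_error(altman_band(1.2), "exceed")
})

test_that("agreement_report assembles the full battery", {
  panel <- simulate_ratings(n_cases = 40, n_raters = 7, seed = 2024)
  rep7 <- agreement_report(panel$ratings)
  expect_identical(nrow(rep7$pairwise), 21L)
  expect_identical(rep7$pairwise$band,
                   altman_band(rep7$pairwise$kappa))
  expect_identical(rep7$global$band, altman_band(rep7$global$kappa))

  two <- agreement_report(panel$ratings[, c("case_id", "R1", "R2")])
  expect_identical(nrow(two$pairwise), 1L)
  expect_false(is.na(two$global$kappa))

  # identical matrix: full marks everywhere
  same <- panel$ratings
  for (r in paste0("R", 2:7)) same[[r]] <- same$R1
  full <- agreement_report(same)
  expect_true(all(full$pairwise$pct_exact == 100))
  expect_true(all(full$pairwise$pct_extreme == 0))
  expect_true(all(full$pairwise$kappa == 1))
  expect_identical(full$global$kappa, 1)
})

test_that("tidy, glance and autoplot expose report pieces", {
  panel <- simulate_ratings(n_cases = 20, n_raters = 3, seed = 5)
  rep3 <- agreement_report(panel$ratings)
  expect_identical(generics::tidy(rep3), rep3$pairwise)
  expect_identical(generics::glance(rep3), rep3$global)
  p <- ggplot2::autoplot(rep3)
  expect_s3_class(p, "ggplot")
})
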