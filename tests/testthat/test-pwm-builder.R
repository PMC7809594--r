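test_that("site filtering removes duplicates, activation-segment sites and redundant windows", {
  w1 <- "AAAAASAAAAA"
  w2 <- "AAAAASAAAAC"  # 10/11 identity = 0.909 > 0.85
  w3 <- "AAAAASAAACC"  # 9/11 identity = 0.818 <= 0.85

  dup <- sites_from_windows(c(w1, w1), substrate = c("S1", "S1"))
  dup$site_position <- c(10L, 10L)
  expect_equal(nrow(filter_sites(dup)), 1)

  act <- sites_from_windows(c(w1, w3))
  act$in_activation_segment <- c(FALSE, TRUE)
  expect_equal(filter_sites(act)$window, w1)

  expect_equal(nrow(filter_sites(sites_from_windows(c(w1, w2)))), 1)
  expect_equal(nrow(filter_sites(sites_from_windows(c(w1, w3)))), 2)

  # greedy and in input order: the first window is always kept
  expect_equal(filter_sites(sites_from_windows(c(w2, w1)))$window, w2)
})

test_that("tyrosine-type kinases are flagged by majority acceptor", {
  wy <- "AAAAAYAAAAA"
  ws <- "AAAAASAAAAA"
  sites <- dplyr::bind_rows(
    sites_from_windows(c(wy, wy, ws), kinase = "TK1"),
    sites_from_windows(c(ws, ws, wy), kinase = "STK1")
  )
  flags <- tyrosine_type_kinases(sites)
  expect_equal(flags$tyrosine_type[flags$kinase_id == "TK1"], TRUE)
  expect_equal(flags$tyrosine_type[flags$kinase_id == "STK1"], FALSE)
})

test_that("PWM construction matches hand-counted frequencies and enforces the site minimum", {
  # 10 windows all carrying R at -3 (window index 3)
  w <- paste0("AA", "R", "AA", "S", "AAAAA")
  pwm <- build_pwm(sites_from_windows(rep(w, 10)))
  expect_equal(pwm$matrix["R", "-3"], 1.0)
  expect_equal(pwm$n_sites, 10L)

  # 12 windows, 6 with P and 6 with A at +1 (window index 7)
  wp <- paste0("AAAAA", "S", "P", "AAAA")
  wa <- paste0("AAAAA", "S", "A", "AAAA")
  pwm2 <- build_pwm(sites_from_windows(c(rep(wp, 6), rep(wa, 6))))
  expect_equal(pwm2$matrix["P", "1"], 0.5)
  expect_equal(pwm2$matrix["A", "1"], 0.5)

  expect_error(build_pwm(sites_from_windows(rep(w, 9))),
               "insufficient sites \\(9 < 10\\)")

  # '_' padding is not an observation: 5 padded + 5 R windows at -5
  wpad <- paste0("_", "AAAA", "S", "AAAAA")
  wr <- paste0("R", "AAAA", "S", "AAAAA")
  pwm3 <- build_pwm(sites_from_windows(c(rep(wpad, 5), rep(wr, 5))))
  expect_equal(pwm3$matrix["R", "-5"], 1.0)
})

test_that("PWMs are column-stochastic for any valid input", {
  for (seed in 1:8) {
    sites <- sample_sites(random_pwm(seed), 25, seed = 100 + seed)
    pwm <- build_pwm(sites)
    expect_lt(max(abs(colSums(pwm$matrix) - 1)), 1e-9)
    expect_true(all(pwm$matrix >= 0 & pwm$matrix <= 1))
  }
})

test_that("match scores hit the min-max extremes and the degenerate convention", {
  pwm <- random_pwm(11)
  flank <- setdiff(-5:5, 0)
  best <- vapply(as.character(flank),
                 function(p) names(which.max(pwm$matrix[, p])), "")
  worst <- vapply(as.character(flank),
                  function(p) names(which.min(pwm$matrix[, p])), "")
  mk <- function(res) paste(c(res[1:5], "S", res[6:10]), collapse = "")
  expect_equal(match_score(pwm, mk(best)), 1.0)
  expect_equal(match_score(pwm, mk(worst)), 0.0)

  uniform <- new_pwm(matrix(1 / 20, 20, 11), kinase_id = "UNI")
  expect_equal(match_score(uniform, mk(best)), 0.5)

  expect_error(match_score(pwm, "TOOSHORT"), "invalid")
  # padded positions are skipped, score still defined
  padded <- paste0("__", paste(c(best[3:5], "S", best[6:10]), collapse = ""))
  expect_equal(match_score(pwm, padded), 1.0)
})

test_that("column information content matches closed forms", {
  uniform <- new_pwm(matrix(1 / 20, 20, 11), kinase_id = "UNI")
  expect_equal(column_bits(uniform, -3), 0)
  expect_equal(column_bits(one_hot_pwm("A"), 2), log2(20))
  two <- matrix(1 / 20, 20, 11, dimnames = list(AMINO_ACIDS, as.character(-5:5)))
  two[, "1"] <- 0
  two[c("P", "A"), "1"] <- 0.5
  expect_equal(column_bits(new_pwm(two, kinase_id = "TWO"), 1), log2(20) - 1)
})

test_that("Frobenius distance matches closed forms and the triangle inequality", {
  a <- random_pwm(21)
  expect_equal(frobenius_distance(a, a), 0)

  b <- a
  # shift 0.1 between two cells of one column: two squared terms
  stopifnot(b$matrix["A", "2"] <= 0.9, b$matrix["C", "2"] >= 0)
  b$matrix["A", "2"] <- b$matrix["A", "2"] + 0.1
  b$matrix["C", "2"] <- b$matrix["C", "2"] - 0.1
  expect_equal(frobenius_distance(a, b), sqrt(0.02))

  # disjoint one-hot columns at all 11 positions: each contributes 2
  oh1 <- one_hot_pwm("A", center = "S")
  oh2 <- one_hot_pwm("R", center = "T")
  expect_equal(frobenius_distance(oh1, oh2), sqrt(22))

  for (seed in 1:5) {
    x <- random_pwm(seed + 30)
    y <- random_pwm(seed + 40)
    z <- random_pwm(seed + 50)
    expect_lte(frobenius_distance(x, z),
               frobenius_distance(x, y) + frobenius_distance(y, z) + 1e-12)
  }

  expect_error(frobenius_distance(a$matrix, a$matrix[, 1:5]), "shape|labeled")
})

test_that("cross-validation separates a sharp model and respects the AUC cutoff", {
  pos <- sample_sites(one_hot_pwm("A"), 50, seed = 61)
  neg <- random_windows(500, seed = 62)
  cv <- crossval_auc(pos, neg, seed = 63)
  expect_gte(cv$mean_auc, 0.95)
  expect_true(cv$passed)
  expect_length(cv$per_fold_auc, 10)

  expect_error(crossval_auc(pos, character(0), seed = 1), "empty negative")
  expect_error(crossval_auc(pos[1:5, ], neg, seed = 1), "at least 10")

  # the pass flag is exactly the mean-AUC >= 0.60 rule
  null_cv <- crossval_auc(
    sample_sites(make_archetype_pwm("P+1", 0, kinase_id = "NULL1"), 30, seed = 64),
    neg, seed = 65
  )
  expect_equal(null_cv$passed, null_cv$mean_auc >= 0.60)
})

test_that("null cross-validation AUC is calibrated around 0.5", {
  aucs <- vapply(1:5, function(i) {
    pos <- sample_sites(make_archetype_pwm("P+1", 0, kinase_id = "NULLK"),
                        50, seed = 300 + i)
    crossval_auc(pos, random_windows(300, seed = 400 + i), seed = 500 + i)$mean_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  withr::with_seed(71, {
    x <- runif(30)
    y <- runif(40)
  })
  base <- kinsdr:::auc_from_scores(x, y)
  expect_equal(kinsdr:::auc_from_scores(exp(x), exp(y)), base)
  expect_equal(kinsdr:::auc_from_scores(10 * x - 3, 10 * y - 3), base)
  expect_equal(kinsdr:::auc_from_scores(x^3, y^3), base)
})

test_that("empirical PWMs converge to their generator", {
  gen <- make_archetype_pwm("R-3", 0.7, kinase_id = "GEN")
  sites <- sample_sites(gen, 10000, seed = 81)
  emp <- build_pwm(sites)
  flank <- as.character(setdiff(-5:5, 0))  # position 0 is forced to S/T
  expect_lt(max(abs(emp$matrix[, flank] - gen$matrix[, flank])), 0.05)
})
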