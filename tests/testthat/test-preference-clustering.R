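test_that("affinity propagation separates distinct archetypes into pure clusters", {
  pwms <- c(
    lapply(1:12, function(i) make_archetype_pwm("P+1", 1, kinase_id = sprintf("P%02d", i))),
    lapply(1:12, function(i) make_archetype_pwm("R+1", 1, kinase_id = sprintf("R%02d", i)))
  )
  raw <- cluster_position(pwms, 1)
  expect_length(unique(raw$exemplar), 2)
  groups <- split(raw$kinase_id, raw$exemplar)
  purity <- vapply(groups, function(g) length(unique(substr(g, 1, 1))), 0L)
  expect_true(all(purity == 1))
  expect_true(attr(raw, "converged"))

  # brute-force check: every kinase sits with its nearest exemplar
  vmat <- t(vapply(pwms, function(p) p$matrix[, "1"], numeric(20)))
  rownames(vmat) <- vapply(pwms, function(p) p$kinase_id, "")
  exemplars <- unique(raw$exemplar)
  for (i in seq_len(nrow(raw))) {
    d <- vapply(exemplars, function(e) {
      sqrt(sum((vmat[raw$kinase_id[i], ] - vmat[e, ])^2))
    }, 0)
    expect_equal(raw$exemplar[i], exemplars[which.min(d)])
  }
})

test_that("identical preference vectors collapse to a single cluster, deterministically", {
  pwms <- lapply(1:8, function(i) make_archetype_pwm("P+1", 0.8, kinase_id = sprintf("K%02d", i)))
  raw <- cluster_position(pwms, 1)
  expect_length(unique(raw$exemplar), 1)

  again <- cluster_position(pwms, 1)
  expect_identical(raw, again)
})

test_that("negative squared Euclidean similarity is available as an option", {
  pwms <- c(
    lapply(1:8, function(i) make_archetype_pwm("P+1", 1, kinase_id = sprintf("P%02d", i))),
    lapply(1:8, function(i) make_archetype_pwm("R+1", 1, kinase_id = sprintf("R%02d", i)))
  )
  raw <- cluster_position(pwms, 1, squared = TRUE)
  expect_length(unique(raw$exemplar), 2)
})

test_that("nonspecific clusters (top-two mean weight < 0.30) are dropped", {
  weak <- lapply(1:8, function(i) make_archetype_pwm("P+1", 0.2, kinase_id = sprintf("W%02d", i)))
  strong <- lapply(1:8, function(i) make_archetype_pwm("R+1", 0.8, kinase_id = sprintf("S%02d", i)))
  pwms <- c(weak, strong)
  # weak cluster top-two sum = 0.28 < 0.30
  assignment <- c(stats::setNames(rep("W01", 8), sprintf("W%02d", 1:8)),
                  stats::setNames(rep("S01", 8), sprintf("S%02d", 1:8)))
  out <- refine_clusters(raw_clusters(assignment, 1), pwms)
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "R+1")
  expect_true(all(out$top2_sum >= 0.30))
})

test_that("clusters smaller than 6 members are dropped", {
  small <- lapply(1:5, function(i) make_archetype_pwm("G+1", 0.9, kinase_id = sprintf("G%02d", i)))
  big <- lapply(1:7, function(i) make_archetype_pwm("P+1", 0.9, kinase_id = sprintf("P%02d", i)))
  pwms <- c(small, big)
  assignment <- c(stats::setNames(rep("G01", 5), sprintf("G%02d", 1:5)),
                  stats::setNames(rep("P01", 7), sprintf("P%02d", 1:7)))
  out <- refine_clusters(raw_clusters(assignment, 1), pwms)
  expect_equal(out$label, "P+1")
  expect_true(all(out$n_members >= 6))
})

test_that("clusters preferring the same or chemically similar residues merge", {
  r_pref <- lapply(1:6, function(i) make_archetype_pwm("R-3", 0.8, kinase_id = sprintf("R%02d", i)))
  k_pref <- lapply(1:6, function(i) make_archetype_pwm("K-3", 0.8, kinase_id = sprintf("K%02d", i)))
  pwms <- c(r_pref, k_pref)
  assignment <- c(stats::setNames(rep("R01", 6), sprintf("R%02d", 1:6)),
                  stats::setNames(rep("K01", 6), sprintf("K%02d", 1:6)))
  out <- refine_clusters(raw_clusters(assignment, -3), pwms)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_members, 12)
})

test_that("false-negative kinases above the 40th-percentile member weight are rescued", {
  members <- lapply(seq(0.45, 0.70, by = 0.05), function(s) {
    make_archetype_pwm("P+1", s, kinase_id = sprintf("M%.2f", s))
  })
  outsider <- make_archetype_pwm("P+1", 0.79, kinase_id = "OUTP")  # weight ~0.80
  # uniform-at-+1 companions make the outsider's own cluster nonspecific,
  # so it is dropped and OUTP can only re-enter through the rescue rule
  faraway <- lapply(1:5, function(i) make_archetype_pwm("R-3", 0.8, kinase_id = sprintf("FAR%02d", i)))
  pwms <- c(members, list(outsider), faraway)
  member_ids <- vapply(members, function(p) p$kinase_id, "")
  assignment <- c(stats::setNames(rep(member_ids[1], 6), member_ids),
                  stats::setNames(rep("FAR01", 6), c("OUTP", sprintf("FAR%02d", 1:5))))
  out <- refine_clusters(raw_clusters(assignment, 1), pwms)
  expect_equal(nrow(out), 1)
  expect_true("OUTP" %in% out$members[[1]])
  expect_false(any(sprintf("FAR%02d", 1:5) %in% out$members[[1]]))
})

test_that("members whose own preference is outside the cluster top-3 are purged", {
  # members prefer P with secondary G/T preferences at +1, so the cluster's
  # top-3 mean residues are P, G, T; the stray's preferred E ranks 4th and
  # it is purged
  member_pwm <- function(id) {
    m <- matrix(1 / 20, 20, 11, dimnames = list(AMINO_ACIDS, as.character(-5:5)))
    m[, "1"] <- (1 - 0.9) / 17
    m[c("P", "G", "T"), "1"] <- c(0.5, 0.2, 0.2)
    new_pwm(m, kinase_id = id)
  }
  p_members <- lapply(sprintf("P%02d", 1:12), member_pwm)
  stray <- make_archetype_pwm("E+1", 0.6, kinase_id = "STRAY")
  pwms <- c(p_members, list(stray))
  ids <- c(sprintf("P%02d", 1:12), "STRAY")
  assignment <- stats::setNames(rep("P01", 13), ids)
  out <- refine_clusters(raw_clusters(assignment, 1), pwms)
  expect_false("STRAY" %in% out$members[[1]])
  expect_equal(out$n_members, 12)
})

test_that("refinement is idempotent on a clean synthetic cohort", {
  coh <- simulate_pwm_cohort(c("P+1", "R+1"), 10, 0.7, seed = 91)
  raw <- cluster_position(coh$pwms, 1)
  once <- refine_clusters(raw, coh$pwms)
  assignment <- unlist(lapply(seq_len(nrow(once)), function(i) {
    stats::setNames(rep(once$exemplar[i], once$n_members[i]), once$members[[i]])
  }))
  twice <- refine_clusters(raw_clusters(assignment, 1), coh$pwms)
  expect_equal(twice$label, once$label)
  expect_equal(twice$members, once$members)
})

test_that("planted preference classes are recovered with high Rand index", {
  for (seed in 1:3) {
    coh <- simulate_pwm_cohort(c("P+1", "R+1", "L+1"), 10, 0.5, seed = 200 + seed)
    raw <- cluster_position(coh$pwms, 1)
    expect_gte(rand_index(raw$exemplar, coh$truth$class), 0.95)
  }
})

test_that("surviving clusters always satisfy the size and specificity invariants", {
  coh <- simulate_pwm_cohort(c("P+1", "R-3", "L-5"), 8, 0.6, seed = 97)
  out <- cluster_preferences(coh$pwms, positions = c(-5, -3, 1))
  expect_gt(nrow(out), 0)
  expect_true(all(out$n_members >= 6))
  expect_true(all(out$top2_sum >= 0.30))
  for (i in seq_len(nrow(out))) {
    expect_equal(sum(sort(out$mean_vector[[i]], decreasing = TRUE)[1:2]),
                 out$top2_sum[i])
  }
})
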