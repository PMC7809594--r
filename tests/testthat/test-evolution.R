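test_that("subsample null distances behave combinatorially and sit below cross-archetype distances", {
  gen <- make_archetype_pwm("R-3", 0.9, kinase_id = "SHARP")
  sites <- sample_sites(gen, 60, seed = 501)

  expect_length(subsample_null(sites, replicates = 2, seed = 502), 1)
  expect_length(subsample_null(sites, replicates = 10, seed = 503), choose(10, 2))
  expect_error(subsample_null(sites[1:5, ], seed = 504), "at least 10")

  null_d <- subsample_null(sites, seed = 505)  # n defaults to 23
  expect_true(all(null_d > 0))
  cross <- frobenius_distance(make_archetype_pwm("R-3", 0.9),
                              make_archetype_pwm("P+1", 0.9))
  expect_lt(stats::median(null_d), cross)
})

test_that("divergence calls use a strict comparison to the random-pair median", {
  same <- make_archetype_pwm("P+1", 0.8, kinase_id = "A")
  rand <- lapply(1:10, function(i) {
    list(random_pwm(600 + i), random_pwm(650 + i))
  })
  calls <- call_divergence(list(list(same, same)), rand)
  expect_equal(calls$distance, 0)
  expect_false(calls$divergent)

  far <- list(one_hot_pwm("A", kinase_id = "X"), one_hot_pwm("R", center = "T", kinase_id = "Y"))
  expect_true(call_divergence(list(far), rand)$divergent)

  # invariance to the order of both lists
  pairs <- c(list(far), list(list(same, same)))
  a <- call_divergence(pairs, rand)
  b <- call_divergence(rev(pairs), rev(rand))
  expect_equal(a[order(a$kinase_a), ], b[order(b$kinase_a), ], ignore_attr = TRUE)
})

test_that("a planted fraction of divergent ortholog pairs is recovered", {
  # 27 conserved pairs (subsamples of one kinase) + 3 strongly divergent
  gen <- make_archetype_pwm("R-3", 0.9, kinase_id = "K0")
  sites <- sample_sites(gen, 80, seed = 510)
  seeds <- withr::with_seed(511, sample.int(1e6, 60))
  sub_pwm <- function(i) {
    take <- withr::with_seed(seeds[i], sample.int(nrow(sites), 23))
    build_pwm(sites[take, ], min_sites = 0)
  }
  conserved <- lapply(1:27, function(i) list(sub_pwm(2 * i - 1), sub_pwm(2 * i)))
  divergent <- lapply(1:3, function(i) {
    list(one_hot_pwm("A", kinase_id = paste0("D", i)),
         one_hot_pwm("R", center = "T", kinase_id = paste0("E", i)))
  })
  rand <- lapply(1:20, function(i) list(random_pwm(700 + i), random_pwm(750 + i)))
  calls <- call_divergence(c(conserved, divergent), rand)
  expect_true(abs(sum(calls$divergent) - 3) <= 1)
})

test_that("conservation is 1 for identical orthologs and highest where substitution is blocked", {
  ref <- paste(rep(AMINO_ACIDS, length.out = 250), collapse = "")
  ident <- simulate_orthologs(ref, n = 8, substitution_rate = 0, seed = 520)
  cats <- domain_categories(250)
  cons <- conservation_by_category(ident, cats)
  expect_true(all(abs(cons$mean_conservation - 1) < 1e-12))

  # SDR columns held fixed while the rest mutates at 0.3
  sdr_cols <- c(86L, 159L, 189L)
  flip <- stats::setNames(rep("A", 3), as.character(sdr_cols))
  drift <- simulate_orthologs(ref, n = 12, substitution_rate = 0.3,
                              sdr_flip = flip, flip_prob = 0, seed = 521)
  cats2 <- dplyr::mutate(cats, category = dplyr::case_when(
    pfam_position %in% sdr_cols ~ "SDR",
    category == "Catalytic" ~ "Catalytic",
    TRUE ~ "Domain"
  ))
  cons2 <- conservation_by_category(drift, cats2)
  get <- function(cat) cons2$mean_conservation[cons2$category == cat]
  expect_gt(get("SDR"), get("Domain"))
})

test_that("column conservation equals a brute-force pairwise computation", {
  sim <- simulate_alignment(n_positive = 5, n_negative = 5, n_columns = 12,
                            gap_fraction = 0.1, seed = 522)
  aln <- sim$alignment
  fast <- kinsdr:::column_conservation(aln)
  S <- blosum62_similarity()
  n <- nrow(aln$mat)
  for (cc in c("1", "5", "12")) {
    res <- aln$mat[, cc]
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + S[res[i], res[j]]
    expect_equal(unname(fast[cc]), tot / choose(n, 2))
  }
})

test_that("specificity conservation tracks the reference and flags planted flips", {
  sim <- simulate_alignment(seed = 530)
  labels <- sim$labels
  model <- train_nb(sim$alignment, labels, sim$sdr_columns, specificity = "synthetic")
  ref_seq <- paste(sim$alignment$mat["POS001", ], collapse = "")
  ref_post <- predict(model, sim$alignment, sequence_ids = "POS001")$posterior

  ident <- simulate_orthologs(ref_seq, n = 10, substitution_rate = 0, seed = 531)
  sc <- specificity_conservation(model, ident)
  expect_equal(sc$mean_posterior, ref_post)
  expect_false(sc$divergent)

  flip <- stats::setNames(rep("E", 3), as.character(sim$sdr_columns))
  flipped <- simulate_orthologs(ref_seq, n = 10, substitution_rate = 0,
                                sdr_flip = flip, flip_prob = 1, seed = 532)
  scf <- specificity_conservation(model, flipped)
  expect_lt(scf$mean_posterior, 0.5)
  expect_true(scf$divergent)
})

test_that("divergence rate is 0 at zero rate and non-decreasing in flip probability", {
  sim <- simulate_alignment(seed = 540)
  labels <- sim$labels
  model <- train_nb(sim$alignment, labels, sim$sdr_columns)
  ref_seq <- paste(sim$alignment$mat["POS002", ], collapse = "")
  flip <- stats::setNames(rep("E", 3), as.character(sim$sdr_columns))
  rate_at <- function(fp, base_seed) {
    mean(vapply(1:8, function(g) {
      grp <- simulate_orthologs(ref_seq, n = 8, substitution_rate = 0,
                                sdr_flip = flip, flip_prob = fp,
                                seed = base_seed + g)
      specificity_conservation(model, grp)$divergent
    }, TRUE))
  }
  rates <- c(rate_at(0, 550), rate_at(0.5, 560), rate_at(1, 570))
  expect_equal(rates[1], 0)
  expect_equal(rates[3], 1)
  expect_true(all(diff(rates) >= 0))
})

test_that("pseudokinases are flagged by substitutions or gaps at the catalytic triad", {
  # positions 30/123/141 carry K/D/D in the canonical sequence
  base <- rep("A", 150)
  base[30] <- "K"; base[123] <- "D"; base[141] <- "D"
  canonical <- paste(base, collapse = "")
  sub30 <- base; sub30[30] <- "R"
  gap141 <- base; gap141[141] <- "-"
  aln <- make_aln(c(canonical, paste(sub30, collapse = ""),
                    paste(gap141, collapse = "")),
                  ids = c("OK", "SUB30", "GAP141"))
  flags <- flag_pseudokinases(aln)
  expect_equal(flags$pseudokinase, c(FALSE, TRUE, TRUE))

  unmapped <- aln
  unmapped$column_to_pfam <- stats::setNames(1:29, as.character(1:29))
  expect_error(flag_pseudokinases(unmapped), "30")
})

test_that("external matrices with extra phosphoresidue rows renormalize cleanly", {
  m <- rbind(random_pwm(580)$matrix * 0.9,
             pS = rep(0.05, 11), pT = rep(0.05, 11))
  pwm <- normalize_external_matrix(m, "EXT1")
  expect_s3_class(pwm, "kinase_pwm")
  expect_lt(max(abs(colSums(pwm$matrix) - 1)), 1e-9)
})
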