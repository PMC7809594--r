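# Synthetic-data generators with planted ground truth: archetype PWMs,
# phosphosite samples, kinase-domain alignments with planted determinant
# columns, ortholog families under per-site substitution with optional SDR
# flips, and mutation tables with category-level enrichment. Every
# generator is a pure function of its arguments and seed.

#' Uniform amino-acid background
#'
#' @return Named numeric vector with probability 1/20 per amino acid.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AMINO_ACIDS)
}

parse_specificity_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)([+-][0-9]+)$", label))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("unknown specificity label '%s' (expected e.g. 'P+1', 'R-3')", label))
  }
  residues <- strsplit(m[2], "")[[1]]
  position <- as.integer(m[3])
  if (!all(residues %in% AMINO_ACIDS) || !position %in% setdiff(-5:5, 0L)) {
    abort(sprintf("unknown specificity label '%s'", label))
  }
  list(residues = residues, position = position)
}

#' Build an archetype PWM for a named preference
#'
#' At the preference position each preferred residue receives weight
#' `strength + (1 - strength) * b(a)` and every other residue
#' `(1 - strength) * b(a)`, after which the column is renormalized; all
#' other columns equal the background. `strength = 0` therefore gives the
#' background everywhere and `strength = 1` a one-hot preference column.
#'
#' @param label Specificity label such as `"P+1"` or `"R-3"`.
#' @param strength Preference strength in \[0, 1\].
#' @param background Named background frequency vector (default uniform).
#' @param kinase_id Identifier for the PWM (default the label).
#' @return A `kinase_pwm`.
#' @export
make_archetype_pwm <- function(label, strength, background = uniform_background(),
                               kinase_id = label) {
  if (strength < 0 || strength > 1) abort("strength must lie in [0, 1]")
  spec <- parse_specificity_label(label)
  b <- background[AMINO_ACIDS]
  m <- matrix(rep(b, 11), 20L, 11L,
              dimnames = list(AMINO_ACIDS, as.character(WINDOW_POSITIONS)))
  p <- as.character(spec$position)
  col <- (1 - strength) * b
  col[spec$residues] <- strength + (1 - strength) * b[spec$residues]
  m[, p] <- col / sum(col)
  new_pwm(m, kinase_id = kinase_id)
}

#' Sample phosphosite windows from a PWM
#'
#' Windows are drawn column-independently from the PWM; position 0 is set
#' to S or T according to `acceptor_ratio`. Deterministic per seed.
#'
#' @param pwm Generator `kinase_pwm`.
#' @param n Number of sites.
#' @param seed Integer seed.
#' @param acceptor_ratio Probability of S (vs T) at position 0
#'   (default 0.7).
#' @return Phosphosite tibble (see [read_phosphosites()]).
#' @export
sample_sites <- function(pwm, n, seed, acceptor_ratio = 0.7) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    chars <- vapply(as.character(WINDOW_POSITIONS), function(p) {
      sample(AMINO_ACIDS, n, replace = TRUE, prob = pwm$matrix[, p])
    }, character(n))
    if (n == 1L) chars <- matrix(chars, nrow = 1)
    acceptor <- ifelse(runif(n) < acceptor_ratio, "S", "T")
    chars[, 6] <- acceptor
    tibble(
      kinase_id = pwm$kinase_id,
      substrate_id = sprintf("SUB%05d", seq_len(n)),
      site_position = sample(6:500, n, replace = TRUE),
      acceptor = acceptor,
      window = apply(chars, 1, paste, collapse = ""),
      in_activation_segment = FALSE,
      source = "synthetic"
    )
  })
}

#' Random background windows (negative pool)
#'
#' @param n Number of windows.
#' @param seed Integer seed.
#' @param background Named amino-acid frequency vector (default uniform).
#' @return Character vector of 11-mers centered on S/T.
#' @export
random_windows <- function(n, seed, background = uniform_background()) {
  withr::with_seed(seed, {
    chars <- matrix(sample(AMINO_ACIDS, n * 11, replace = TRUE,
                           prob = background[AMINO_ACIDS]), n, 11)
    chars[, 6] <- ifelse(runif(n) < 0.7, "S", "T")
    apply(chars, 1, paste, collapse = "")
  })
}

#' Simulate a cohort of empirical PWMs from preference archetypes
#'
#' For each class label, draws `n_per_class` kinases: each samples
#' `n_sites` phosphosite windows from the class archetype and rebuilds its
#' empirical PWM, giving realistic within-class sampling noise.
#'
#' @param classes Character vector of specificity labels (e.g.
#'   `c("P+1", "R-3")`).
#' @param n_per_class Kinases per class.
#' @param strength Archetype preference strength.
#' @param n_sites Phosphosites sampled per kinase (default 50).
#' @param seed Integer seed.
#' @param background Background frequencies (default uniform).
#' @return List with `pwms` (list of `kinase_pwm`) and `truth`
#'   (tibble `kinase_id`, `class`).
#' @export
simulate_pwm_cohort <- function(classes, n_per_class, strength, n_sites = 50,
                                seed, background = uniform_background()) {
  combos <- tidyr::expand_grid(class = classes, rep = seq_len(n_per_class))
  seeds <- withr::with_seed(seed, sample.int(2^30, nrow(combos)))
  pwms <- purrr::map(seq_len(nrow(combos)), function(i) {
    kid <- sprintf("%s_K%02d", gsub("[^A-Za-z0-9]", "", combos$class[i]),
                   combos$rep[i])
    arch <- make_archetype_pwm(combos$class[i], strength,
                               background = background, kinase_id = kid)
    sites <- sample_sites(arch, n_sites, seed = seeds[i])
    build_pwm(sites, min_sites = 0)
  })
  list(
    pwms = pwms,
    truth = tibble(
      kinase_id = vapply(pwms, function(p) p$kinase_id, ""),
      class = combos$class
    )
  )
}

#' Simulate a kinase-domain alignment with planted determinant columns
#'
#' Every column receives a background residue profile drawn from a
#' symmetric Dirichlet whose concentration controls conservation (small
#' values give strongly conserved columns). At each planted column the
#' background is drawn over the 19 non-determinant residues, positive
#' sequences carry the determinant residue with probability `q`, and
#' negative sequences draw from the background - so the planted columns
#' are the only systematically class-discriminating columns. Gaps are
#' introduced per cell with probability `gap_fraction`.
#'
#' @param n_positive,n_negative Class sizes (defaults 30 and 90).
#' @param n_columns Alignment length (default 250).
#' @param sdr_columns Planted determinant columns (default: 3 drawn at
#'   random).
#' @param determinant_residue Residue carried by positives at planted
#'   columns (default "K").
#' @param q Determinant probability in positives (default 0.9).
#' @param concentration Dirichlet concentration for background columns
#'   (default 0.5).
#' @param gap_fraction Per-cell gap probability (default 0; keep below
#'   0.2 so columns survive trimming).
#' @param seed Integer seed.
#' @return List with `alignment` (a `kinase_alignment` with an identity
#'   Pfam map), `labels` (tibble `sequence_id`, `label`) and
#'   `sdr_columns` (the planted truth).
#' @export
simulate_alignment <- function(n_positive = 30, n_negative = 90,
                               n_columns = 250, sdr_columns = NULL,
                               determinant_residue = "K", q = 0.9,
                               concentration = 0.5, gap_fraction = 0, seed) {
  n <- n_positive + n_negative
  withr::with_seed(seed, {
    if (is.null(sdr_columns)) sdr_columns <- sort(sample.int(n_columns, 3))
    stopifnot(all(sdr_columns >= 1 & sdr_columns <= n_columns))
    mat <- matrix("", n, n_columns)
    for (j in seq_len(n_columns)) {
      alpha <- rgamma(20, concentration)
      if (j %in% sdr_columns) alpha[match(determinant_residue, AMINO_ACIDS)] <- 0
      profile <- alpha / sum(alpha)
      mat[, j] <- sample(AMINO_ACIDS, n, replace = TRUE, prob = profile)
      if (j %in% sdr_columns) {
        carry <- runif(n_positive) < q
        mat[seq_len(n_positive)[carry], j] <- determinant_residue
      }
    }
    if (gap_fraction > 0) {
      mat[matrix(runif(n * n_columns) < gap_fraction, n, n_columns)] <- GAP
    }
    ids <- c(sprintf("POS%03d", seq_len(n_positive)),
             sprintf("NEG%03d", seq_len(n_negative)))
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
    aln <- kinase_alignment(
      seqs,
      column_to_pfam = setNames(seq_len(n_columns),
                                as.character(seq_len(n_columns)))
    )
    list(
      alignment = aln,
      labels = tibble(
        sequence_id = ids,
        label = rep(c("positive", "negative"), c(n_positive, n_negative))
      ),
      sdr_columns = sdr_columns,
      determinant_residue = determinant_residue
    )
  })
}

#' Simulate an ortholog family by star-phylogeny substitution
#'
#' Each ortholog is derived independently from the reference: every
#' non-SDR position mutates to a random other residue with probability
#' `substitution_rate`; every SDR position (the names of `sdr_flip`)
#' switches to its specified flip residue with probability `flip_prob` and
#' otherwise stays fixed.
#'
#' @param reference Ungapped reference domain sequence (string).
#' @param n Number of orthologs (default 20).
#' @param substitution_rate Per-site substitution probability in \[0, 1\].
#' @param sdr_flip Named character vector: names are alignment columns of
#'   SDR positions, values the residues they flip to (may be `NULL`).
#' @param flip_prob Probability of the SDR flip per ortholog (default 0).
#' @param seed Integer seed.
#' @param reference_id Sequence id of the reference (default "REF").
#' @return A `kinase_alignment` of the reference plus orthologs with an
#'   identity Pfam map and species labels in `$group_labels`.
#' @export
simulate_orthologs <- function(reference, n = 20, substitution_rate = 0.1,
                               sdr_flip = NULL, flip_prob = 0, seed,
                               reference_id = "REF") {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1)
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  sdr_cols <- if (is.null(sdr_flip)) integer() else as.integer(names(sdr_flip))
  stopifnot(all(sdr_cols >= 1 & sdr_cols <= L))
  free <- setdiff(seq_len(L), sdr_cols)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      s <- ref
      mut <- free[runif(length(free)) < substitution_rate]
      if (length(mut) > 0) {
        s[mut] <- vapply(s[mut], function(a) {
          sample(setdiff(AMINO_ACIDS, a), 1)
        }, "")
      }
      if (length(sdr_cols) > 0 && flip_prob > 0) {
        do_flip <- runif(length(sdr_cols)) < flip_prob
        s[sdr_cols[do_flip]] <- sdr_flip[do_flip]
      }
      paste(s, collapse = "")
    })
    ids <- c(reference_id, sprintf("ORTH%03d", seq_len(n)))
    seqs <- setNames(c(paste(ref, collapse = ""), unlist(rows)), ids)
    kinase_alignment(
      seqs,
      column_to_pfam = setNames(seq_len(L), as.character(seq_len(L))),
      group_labels = setNames(c("reference", sprintf("species%03d", seq_len(n))), ids)
    )
  })
}

#' Simulate kinase-domain mutation tables with category enrichment
#'
#' Per kinase, `total_per_kinase` mutations are distributed multinomially
#' over the domain positions with probability mass proportional to
#' `enrichment` for SDR positions and 1 for all others; `enrichment = 1`
#' is the uniform null.
#'
#' @param kinase_ids Character vector of kinases.
#' @param categories Category tibble (see [domain_categories()]).
#' @param total_per_kinase Mutations per kinase (default 30).
#' @param enrichment Relative per-site mutation mass of SDR positions
#'   (must be > 0; default 1).
#' @param seed Integer seed.
#' @return Mutation record tibble (`kinase_id`, `pfam_position`, `count`).
#' @export
simulate_mutations <- function(kinase_ids, categories, total_per_kinase = 30,
                               enrichment = 1, seed) {
  stopifnot(enrichment > 0)
  w <- ifelse(categories$category == "SDR", enrichment, 1)
  withr::with_seed(seed, {
    purrr::map(kinase_ids, function(k) {
      counts <- as.vector(stats::rmultinom(1, total_per_kinase, w))
      keep <- counts > 0
      tibble(
        kinase_id = k,
        pfam_position = categories$pfam_position[keep],
        count = counts[keep]
      )
    }) |>
      dplyr::bind_rows()
  })
}
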