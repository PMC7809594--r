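# Conservation and divergence of kinase specificity across orthologs:
# subsampled same-kinase null distances, divergence calls against a
# random-pair median, per-category sequence conservation, posterior-based
# specificity conservation, and pseudokinase filtering.

#' Null distribution of PWM distances from phosphosite subsampling
#'
#' Builds `replicates` PWMs from seeded subsamples of `n` phosphosites of
#' the same kinase (without replacement when enough sites are available,
#' with replacement otherwise) and returns all pairwise Frobenius
#' distances. This models the specificity-distance expected between
#' biological replicates of one kinase. `n = 23` matches the median number
#' of sites behind the curated kinase models.
#'
#' @param sites Phosphosite tibble for one kinase (at least 10 rows).
#' @param n Subsample size (default 23).
#' @param replicates Number of subsampled PWMs (default 100).
#' @param seed Integer seed.
#' @return Numeric vector of `choose(replicates, 2)` distances.
#' @export
subsample_null <- function(sites, n = 23, replicates = 100, seed) {
  if (nrow(sites) < 10L) {
    abort(sprintf("subsample_null needs at least 10 sites (have %d)", nrow(sites)))
  }
  pwms <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      take <- sample.int(nrow(sites), n, replace = nrow(sites) < n)
      build_pwm(sites[take, , drop = FALSE], min_sites = 0)
    })
  })
  pairs <- combn(replicates, 2)
  vapply(seq_len(ncol(pairs)), function(j) {
    frobenius_distance(pwms[[pairs[1, j]]], pwms[[pairs[2, j]]])
  }, 0)
}

#' Call specificity divergence against a random-pair null
#'
#' The null median is the median Frobenius distance over random kinase
#' pairs; a pair is divergent when its distance strictly exceeds that
#' median.
#'
#' @param pairs List of PWM pairs (each a list of two `kinase_pwm`s),
#'   e.g. ortholog pairs.
#' @param random_pairs Non-empty list of random PWM pairs defining the
#'   null.
#' @return Tibble with `kinase_a`, `kinase_b`, `distance`, `null_median`,
#'   `divergent`.
#' @export
call_divergence <- function(pairs, random_pairs) {
  if (length(random_pairs) == 0L) abort("random_pairs must be non-empty")
  null_d <- vapply(random_pairs, function(p) frobenius_distance(p[[1]], p[[2]]), 0)
  null_median <- stats::median(null_d)
  purrr::map(pairs, function(p) {
    d <- frobenius_distance(p[[1]], p[[2]])
    tibble(
      kinase_a = p[[1]]$kinase_id,
      kinase_b = p[[2]]$kinase_id,
      distance = d,
      null_median = null_median,
      divergent = d > null_median
    )
  }) |>
    dplyr::bind_rows()
}

# per-column conservation: mean pairwise normalized-BLOSUM62 similarity
# across sequences (any pair involving a gap contributes 0)
column_conservation <- function(aln) {
  S <- blosum62_similarity()
  C <- symbol_counts(aln$mat)
  n <- nrow(aln$mat)
  tot <- colSums(C * (S %*% C)) - colSums(C * diag(S))
  setNames(tot / (n * (n - 1)), colnames(aln$mat))
}

#' Mean sequence conservation by functional position category
#'
#' Computes, for every alignment column with a Pfam coordinate, the mean
#' pairwise residue similarity across the aligned orthologs
#' ([blosum62_similarity()]; gap pairs count 0), then averages within the
#' given position categories (typically SDR / Catalytic / Domain).
#'
#' @param aln A `kinase_alignment` of orthologs with a Pfam map.
#' @param categories Tibble with `pfam_position` and `category` covering
#'   the mapped positions.
#' @return Tibble with `category`, `mean_conservation`, `n_positions`;
#'   categories without any mapped position are reported with a warning
#'   and dropped.
#' @export
conservation_by_category <- function(aln, categories) {
  if (is.null(aln$column_to_pfam)) {
    abort("alignment has no Pfam map; conservation is summarized in Pfam space")
  }
  cons <- column_conservation(aln)
  mapped <- tibble(
    column = as.integer(names(aln$column_to_pfam)),
    pfam_position = unname(aln$column_to_pfam)
  )
  mapped$conservation <- unname(cons[as.character(mapped$column)])
  df <- dplyr::inner_join(mapped, categories, by = "pfam_position")
  empty <- setdiff(unique(categories$category), unique(df$category))
  if (length(empty) > 0) {
    warn(sprintf("no mapped positions for category: %s",
                 paste(empty, collapse = ", ")))
  }
  df |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_conservation = mean(.data$conservation),
      n_positions = dplyr::n(),
      .groups = "drop"
    )
}

#' Conservation of predicted specificity across an ortholog group
#'
#' Scores every ortholog with a trained specificity model and averages the
#' posterior probabilities: 1 means the specificity is fully conserved
#' across the group; a mean below 0.5 is called divergent.
#'
#' @param model A `specificity_model`.
#' @param aln A `kinase_alignment` of orthologs whose columns resolve the
#'   model's feature columns (matched via Pfam positions when the model
#'   carries them).
#' @return List with `mean_posterior`, `divergent`, and the per-sequence
#'   `posteriors` tibble.
#' @export
specificity_conservation <- function(model, aln) {
  cols <- model$feature_columns
  if (!is.null(aln$column_to_pfam) && !anyNA(model$feature_pfam)) {
    mapped <- alignment_column_of_pfam(aln, model$feature_pfam)
    if (anyNA(mapped)) {
      abort(sprintf(
        "feature Pfam position(s) %s not resolvable in the ortholog alignment",
        paste(model$feature_pfam[is.na(mapped)], collapse = ", ")
      ))
    }
    cols <- mapped
  }
  m2 <- model
  m2$feature_columns <- cols
  names(m2$tables) <- as.character(cols)
  post <- predict(m2, aln)
  list(
    mean_posterior = mean(post$posterior),
    divergent = mean(post$posterior) < 0.5,
    posteriors = post
  )
}

#' Flag pseudokinases by their catalytic triad
#'
#' A sequence is flagged as a (candidate) pseudokinase when it lacks the
#' canonical catalytic residues lysine at domain position 30, aspartate at
#' 123, or aspartate at 141; a gap at any of the three also flags it.
#'
#' @param aln A `kinase_alignment` whose Pfam map covers positions 30, 123
#'   and 141.
#' @return Tibble with `sequence_id` and logical `pseudokinase`.
#' @export
flag_pseudokinases <- function(aln) {
  pfam_pos <- as.integer(names(PSEUDOKINASE_TRIAD))
  cols <- alignment_column_of_pfam(aln, pfam_pos)
  if (anyNA(cols)) {
    abort(sprintf("canonical position(s) %s not mapped in the alignment",
                  paste(pfam_pos[is.na(cols)], collapse = ", ")))
  }
  flagged <- rep(FALSE, nrow(aln$mat))
  for (j in seq_along(cols)) {
    res <- aln$mat[, as.character(cols[j])]
    flagged <- flagged | res != PSEUDOKINASE_TRIAD[j]
  }
  tibble(sequence_id = alignment_ids(aln), pseudokinase = unname(flagged))
}

#' Renormalize an externally supplied specificity matrix
#'
#' Peptide-library matrices sometimes carry extra phosphoresidue rows
#' (pS/pT/pY). Rows outside the 20 standard amino acids are dropped and
#' every column renormalized to sum to 1.
#'
#' @param m Numeric matrix with amino-acid row names and 11 position
#'   columns labeled -5..5.
#' @param kinase_id Kinase identifier for the resulting PWM.
#' @return A `kinase_pwm`.
#' @export
normalize_external_matrix <- function(m, kinase_id) {
  m <- m[rownames(m) %in% AMINO_ACIDS, , drop = FALSE]
  if (!setequal(rownames(m), AMINO_ACIDS)) {
    abort("matrix must contain all 20 standard amino-acid rows")
  }
  m <- m[AMINO_ACIDS, , drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  new_pwm(m, kinase_id = kinase_id)
}
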