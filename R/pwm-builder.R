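# PWM construction, matrix-based site scoring, cross-validation quality
# filtering, information content, and PWM comparison.

# rank-based AUC (Mann-Whitney U / (n1*n2), ties counted 0.5)
auc_from_scores <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  if (n1 == 0L || n2 == 0L) abort("AUC needs scores from both classes")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

window_chars <- function(windows) {
  do.call(rbind, strsplit(windows, ""))
}

# pairwise identity of two 11-mers: matches / 11, '_' never matches
window_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca == cb & ca != WINDOW_PAD) / 11
}

#' Filter phosphosites for PWM construction
#'
#' Applies, in order: removal of exact duplicate (kinase, substrate, site)
#' records; removal of sites in the substrate's activation segment; and a
#' greedy per-kinase redundancy filter in input order that keeps a window
#' only if its identity (matching positions / 11, `_` never matches) to
#' every previously kept window of that kinase is at most `identity_cutoff`.
#'
#' @param sites Phosphosite tibble (see [read_phosphosites()]).
#' @param identity_cutoff Maximum allowed pairwise window identity
#'   (default 0.85).
#' @return Filtered phosphosite tibble.
#' @export
filter_sites <- function(sites, identity_cutoff = 0.85) {
  sites <- dplyr::distinct(sites, .data$kinase_id, .data$substrate_id,
                           .data$site_position, .keep_all = TRUE)
  sites <- dplyr::filter(sites, !.data$in_activation_segment)
  keep_kinase <- function(df) {
    kept <- integer()
    for (i in seq_len(nrow(df))) {
      ok <- TRUE
      for (j in kept) {
        if (window_identity(df$window[i], df$window[j]) > identity_cutoff) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    df[kept, , drop = FALSE]
  }
  sites |>
    dplyr::group_by(.data$kinase_id) |>
    dplyr::group_modify(~ keep_kinase(.x)) |>
    dplyr::ungroup()
}

#' Identify tyrosine-type kinases
#'
#' A kinase is called tyrosine-type when more than half of its phosphosites
#' have acceptor Y; such kinases are excluded from serine/threonine
#' analyses.
#'
#' @param sites Phosphosite tibble.
#' @return A tibble with `kinase_id` and logical `tyrosine_type`.
#' @export
tyrosine_type_kinases <- function(sites) {
  sites |>
    dplyr::group_by(.data$kinase_id) |>
    dplyr::summarise(tyrosine_type = mean(.data$acceptor == "Y") > 0.5,
                     .groups = "drop")
}

#' Build a PWM from phosphosite windows
#'
#' Each matrix cell is the relative frequency of an amino acid at a
#' substrate position: `(count + pseudocount) / (n_observed +
#' 20 * pseudocount)`, where `_` padding characters are not observations.
#'
#' @param sites Phosphosite tibble for a single kinase.
#' @param min_sites Minimum usable sites (default 10); fewer is an error.
#' @param pseudocount Added to every cell count (default 0).
#' @return A `kinase_pwm`.
#' @export
build_pwm <- function(sites, min_sites = 10, pseudocount = 0) {
  kid <- unique(sites$kinase_id)
  if (length(kid) > 1L) abort("build_pwm expects sites of a single kinase")
  if (length(kid) == 0L) kid <- NA_character_
  n <- nrow(sites)
  if (n < min_sites) {
    abort(sprintf("insufficient sites (%d < %d) for kinase %s", n, min_sites, kid))
  }
  chars <- window_chars(sites$window)
  m <- matrix(0, 20L, 11L, dimnames = list(AMINO_ACIDS, as.character(WINDOW_POSITIONS)))
  for (p in seq_len(11L)) {
    obs <- chars[, p]
    obs <- obs[obs != WINDOW_PAD]
    counts <- table(factor(obs, levels = AMINO_ACIDS))
    denom <- length(obs) + 20 * pseudocount
    if (denom == 0) {
      m[, p] <- 1 / 20  # column entirely beyond the termini
    } else {
      m[, p] <- (as.numeric(counts) + pseudocount) / denom
    }
  }
  new_pwm(m, kinase_id = kid, n_sites = n)
}

#' Score a substrate window against a PWM
#'
#' Sum of log frequencies `ln(M[w_p, p] + 1e-4)` over the ten flanking
#' positions (position 0 and `_` padding are skipped), min-max normalized
#' to \[0, 1\] using the per-column minima and maxima of the log matrix over
#' the same positions. A fully degenerate case (max = min) returns 0.5.
#'
#' @param pwm A `kinase_pwm`.
#' @param window 11-character substrate window.
#' @param epsilon Guard added before taking logs (default 1e-4).
#' @return Score in \[0, 1\].
#' @export
match_score <- function(pwm, window, epsilon = 1e-4) {
  if (length(window) != 1L || !valid_window(window)) {
    abort(sprintf("invalid substrate window '%s'", window))
  }
  chars <- strsplit(window, "")[[1]]
  logm <- log(pwm$matrix + epsilon)
  use <- which(WINDOW_POSITIONS != 0L & chars != WINDOW_PAD)
  if (length(use) == 0L) return(0.5)
  s <- sum(logm[cbind(match(chars[use], AMINO_ACIDS), use)])
  smin <- sum(apply(logm[, use, drop = FALSE], 2, min))
  smax <- sum(apply(logm[, use, drop = FALSE], 2, max))
  if (smax == smin) return(0.5)
  (s - smin) / (smax - smin)
}

#' Cross-validate a kinase PWM against negative windows
#'
#' 10-fold cross-validation of the matrix scoring function: positives are
#' split into seeded shuffled folds; for each fold a PWM is rebuilt on the
#' remaining positives, and held-out positives plus an equal-sized seeded
#' sample of negative windows are scored with [match_score()]. The fold AUC
#' is the Mann-Whitney U statistic over the two score sets, ties counted
#' 0.5. A kinase model passes when the mean AUC is at least `auc_cutoff`.
#'
#' @param positives Phosphosite tibble for one kinase (at least `folds`
#'   rows).
#' @param negatives Character vector pool of negative 11-mer windows.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and negative sampling.
#' @param auc_cutoff Pass threshold on the mean AUC (default 0.60).
#' @return An object of class `cv_report` with `per_fold_auc`, `mean_auc`
#'   and `passed`.
#' @export
crossval_auc <- function(positives, negatives, folds = 10, seed, auc_cutoff = 0.60) {
  n <- nrow(positives)
  if (n < folds) abort(sprintf("need at least %d positives for %d folds", folds, folds))
  if (length(negatives) == 0L) abort("empty negative window pool")
  per_fold <- withr::with_seed(seed, {
    idx <- sample.int(n)
    fold_of <- rep(seq_len(folds), length.out = n)[order(idx)]
    vapply(seq_len(folds), function(f) {
      hold <- which(fold_of == f)
      train <- positives[-hold, , drop = FALSE]
      pwm <- build_pwm(train, min_sites = 0)
      neg <- if (length(negatives) >= length(hold)) {
        sample(negatives, length(hold))
      } else {
        sample(negatives, length(hold), replace = TRUE)
      }
      pos_scores <- vapply(positives$window[hold], function(w) match_score(pwm, w), 0)
      neg_scores <- vapply(neg, function(w) match_score(pwm, w), 0)
      auc_from_scores(pos_scores, neg_scores)
    }, 0)
  })
  structure(
    list(
      per_fold_auc = per_fold,
      mean_auc = mean(per_fold),
      passed = mean(per_fold) >= auc_cutoff
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> mean AUC %.3f over %d folds - %s\n",
              x$mean_auc, length(x$per_fold_auc),
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Information content of a PWM column
#'
#' `IC = log2(20) + sum_a M[a, p] * log2(M[a, p])` with `0 * log2(0) = 0`;
#' ranges from 0 bits (uniform column) to `log2(20) ~ 4.32` bits (one-hot).
#'
#' @param pwm A `kinase_pwm`.
#' @param position Substrate position in -5..+5.
#' @return Bit value, non-negative.
#' @export
column_bits <- function(pwm, position) {
  v <- pwm_column(pwm, position)
  nz <- v[v > 0]
  log2(20) + sum(nz * log2(nz))
}

#' Frobenius distance between two PWMs
#'
#' The square root of the summed squared element-wise differences between
#' two equally labeled matrices; used to compare kinase specificity models.
#'
#' @param a,b `kinase_pwm` objects (or plain matrices of equal shape).
#' @return Non-negative distance.
#' @export
frobenius_distance <- function(a, b) {
  ma <- if (inherits(a, "kinase_pwm")) a$matrix else a
  mb <- if (inherits(b, "kinase_pwm")) b$matrix else b
  if (!identical(dim(ma), dim(mb)) ||
      !identical(dimnames(ma), dimnames(mb))) {
    abort("frobenius_distance requires identically labeled matrices")
  }
  sqrt(sum((ma - mb)^2))
}
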