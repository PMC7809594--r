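# Ensemble SDR detection: score alignment columns for their ability to
# discriminate a specificity class (positives) from all other kinases
# (negatives) with three independent scorers - a GroupSim-style similarity
# contrast, a two-class Relief weighting, and a SPEER-style combination of
# relative entropy and physicochemical shift - then intersect the top-k
# ranks of all three to call SDRs.

check_labels <- function(aln, labels, min_per_class = 2L) {
  if (!all(c("sequence_id", "label") %in% names(labels))) {
    abort("labels must be a tibble with columns sequence_id and label")
  }
  if (!all(labels$label %in% c("positive", "negative"))) {
    abort("labels must be 'positive' or 'negative'")
  }
  ids <- alignment_ids(aln)
  labels <- labels[match(ids, labels$sequence_id), , drop = FALSE]
  if (anyNA(labels$label)) {
    abort("every aligned sequence needs a class label")
  }
  n_pos <- sum(labels$label == "positive")
  n_neg <- sum(labels$label == "negative")
  if (n_pos < min_per_class || n_neg < min_per_class) {
    abort(sprintf("need at least %d sequences per class (have %d positive, %d negative)",
                  min_per_class, n_pos, n_neg))
  }
  labels$label == "positive"
}

symbol_counts <- function(mat) {
  # 21 x L counts of alignment symbols per column
  out <- vapply(ALPHABET21, function(s) colSums(mat == s), numeric(ncol(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, ALPHABET21))
  t(out)
}

#' Remove heavily gapped alignment columns
#'
#' Drops columns whose gap fraction strictly exceeds `max_gap_fraction`
#' (a column at exactly the threshold is kept). Original column indices
#' and the Pfam map are preserved for the retained columns.
#'
#' @param aln A `kinase_alignment`.
#' @param max_gap_fraction Maximum tolerated gap fraction (default 0.20).
#' @return A trimmed `kinase_alignment`.
#' @export
trim_gapped_columns <- function(aln, max_gap_fraction = 0.20) {
  gap_frac <- colMeans(aln$mat == GAP)
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) abort("all alignment columns exceed the gap threshold")
  out <- aln
  out$mat <- aln$mat[, keep, drop = FALSE]
  if (!is.null(aln$column_to_pfam)) {
    out$column_to_pfam <-
      aln$column_to_pfam[names(aln$column_to_pfam) %in% colnames(out$mat)]
  }
  out
}

#' GroupSim-style column scores
#'
#' For each column, `W_pos` and `W_neg` are the mean pairwise residue
#' similarities within the positive and negative class and `B` the mean
#' similarity across classes, using the unit-diagonal normalized BLOSUM62
#' similarity of [blosum62_similarity()] (gap pairs score 0). The column
#' score is `((W_pos + W_neg) / 2) * (1 - B)`: high for columns conserved
#' within each class but different between classes, and 0 for a column
#' with a single residue in every sequence.
#'
#' @param aln A (trimmed) `kinase_alignment`.
#' @param labels Tibble with `sequence_id` and `label`
#'   (positive/negative), both classes with at least 2 sequences.
#' @return Named numeric vector of scores in \[0, 1\] keyed by alignment
#'   column.
#' @export
groupsim_scores <- function(aln, labels) {
  pos <- check_labels(aln, labels)
  S <- blosum62_similarity()
  cp <- symbol_counts(aln$mat[pos, , drop = FALSE])
  cn <- symbol_counts(aln$mat[!pos, , drop = FALSE])
  np <- sum(pos)
  nn <- sum(!pos)
  within_mean <- function(C, n) {
    tot <- colSums(C * (S %*% C)) - colSums(C * diag(S))
    tot / (n * (n - 1))
  }
  w_pos <- within_mean(cp, np)
  w_neg <- within_mean(cn, nn)
  b <- colSums(cp * (S %*% cn)) / (np * nn)
  scores <- ((w_pos + w_neg) / 2) * (1 - b)
  setNames(scores, colnames(aln$mat))
}

#' Relief feature weights for alignment columns
#'
#' Classic two-class Relief adapted to alignment columns: repeatedly draw
#' a random sequence, find its nearest same-class neighbor (hit) and
#' nearest other-class neighbor (miss) by Hamming distance over all
#' columns (gap vs residue is a mismatch; ties broken by lowest sequence
#' index), and reward columns where the sequence differs from the miss but
#' matches the hit. Scores are averaged over iterations and lie in
#' \[-1, 1\].
#'
#' @inheritParams groupsim_scores
#' @param iterations Number of sampling iterations (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector of scores keyed by alignment column.
#' @export
relief_scores <- function(aln, labels, iterations = 1000, seed) {
  pos <- check_labels(aln, labels)
  mat <- aln$mat
  n <- nrow(mat)
  L <- ncol(mat)
  idx <- matrix(match(mat, ALPHABET21), n, L)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- rowSums(idx != matrix(idx[i, ], n, L, byrow = TRUE))
  }
  # per-sequence hit/miss contribution; the Relief average is then a
  # weighted sum over the seeded draws
  contrib <- matrix(0, n, L)
  for (x in seq_len(n)) {
    same <- setdiff(which(pos == pos[x]), x)
    other <- which(pos != pos[x])
    h <- same[which.min(D[x, same])]
    m <- other[which.min(D[x, other])]
    contrib[x, ] <- (idx[x, ] != idx[m, ]) - (idx[x, ] != idx[h, ])
  }
  draws <- withr::with_seed(seed, sample.int(n, iterations, replace = TRUE))
  counts <- tabulate(draws, nbins = n)
  w <- as.vector(crossprod(contrib, counts)) / iterations
  setNames(w, colnames(mat))
}

#' SPEER-style column scores
#'
#' Combines, per column, (i) the symmetrized Kullback-Leibler divergence
#' between the class amino-acid distributions (pseudocount 0.5 over the
#' 21-symbol alphabet) and (ii) the Euclidean distance between class mean
#' physicochemical vectors (z-normalized Kyte-Doolittle hydropathy, net
#' charge at pH 7 and van der Waals volume; gap = zero vector), scaled by
#' the pooled within-class standard deviation of the sequences' projections
#' onto the between-class direction (+ 1e-6). The final score is the mean
#' of the across-column z-scores of the two components (defined as 0 when
#' a component has zero variance, e.g. a single-column alignment).
#'
#' @inheritParams groupsim_scores
#' @return Named numeric vector of combined z-scale scores keyed by
#'   alignment column.
#' @export
speer_scores <- function(aln, labels) {
  pos <- check_labels(aln, labels)
  mat <- aln$mat
  n <- nrow(mat)
  L <- ncol(mat)
  cp <- symbol_counts(mat[pos, , drop = FALSE])
  cn <- symbol_counts(mat[!pos, , drop = FALSE])
  np <- sum(pos)
  nn <- sum(!pos)
  p1 <- (cp + 0.5) / (np + 21 * 0.5)
  p2 <- (cn + 0.5) / (nn + 21 * 0.5)
  re <- colSums((p1 - p2) * log(p1 / p2))

  P <- physchem_scales()
  idx <- matrix(match(mat, ALPHABET21), n, L)
  m_pos <- crossprod(P, cp) / np  # 3 x L class mean physchem vectors
  m_neg <- crossprod(P, cn) / nn
  dvec <- m_pos - m_neg
  ed_raw <- sqrt(colSums(dvec^2))
  u <- dvec
  nonzero <- ed_raw > 0
  u[, nonzero] <- sweep(dvec[, nonzero, drop = FALSE], 2,
                        ed_raw[nonzero], "/")
  proj <- matrix(0, n, L)
  for (k in 1:3) {
    proj <- proj + matrix(P[idx, k], n, L) *
      matrix(u[k, ], n, L, byrow = TRUE)
  }
  ss_within <- function(rows) {
    pr <- proj[rows, , drop = FALSE]
    colSums(sweep(pr, 2, colMeans(pr))^2)
  }
  pooled_sd <- sqrt((ss_within(which(pos)) + ss_within(which(!pos))) /
                      max(n - 2, 1))
  ed <- ifelse(nonzero, ed_raw / (pooled_sd + 1e-6), 0)

  zscore <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  setNames((zscore(re) + zscore(ed)) / 2, colnames(mat))
}

#' Intersect top-ranked columns of the three scorers into an SDR call
#'
#' Each method ranks columns by descending score (ties broken by ascending
#' column index); the SDR set is the columns ranked within the top `k` by
#' all three methods.
#'
#' @param scores Named list with elements `groupsim`, `relief`, `speer`,
#'   each a named numeric score vector over the same columns.
#' @param k Rank cutoff (default 15).
#' @param column_to_pfam Optional domain map used to attach Pfam positions.
#' @return An object of class `sdr_result` with a per-column score/rank
#'   table (`$table`), the SDR columns (`$sdr_columns`) and their Pfam
#'   positions (`$sdr_pfam_positions`).
#' @export
ensemble_sdrs <- function(scores, k = 15, column_to_pfam = NULL) {
  methods <- c("groupsim", "relief", "speer")
  if (!all(methods %in% names(scores))) {
    abort("scores must contain elements groupsim, relief and speer")
  }
  cols <- sort(as.integer(names(scores$groupsim)))
  for (m in methods) {
    if (!setequal(as.integer(names(scores[[m]])), cols)) {
      abort("all three score maps must cover the same columns")
    }
  }
  tab <- tibble(column = cols)
  for (m in methods) {
    sc <- scores[[m]][as.character(cols)]
    rk <- integer(length(cols))
    rk[order(-sc, cols)] <- seq_along(cols)
    tab[[m]] <- unname(sc)
    tab[[paste0("rank_", m)]] <- rk
  }
  tab$is_sdr <- tab$rank_groupsim <= k & tab$rank_relief <= k &
    tab$rank_speer <= k
  tab$pfam_position <- pfam_position(column_to_pfam, tab$column)
  sdr_cols <- tab$column[tab$is_sdr]
  structure(
    list(
      table = tab,
      k = as.integer(k),
      sdr_columns = sdr_cols,
      sdr_pfam_positions = sort(tab$pfam_position[tab$is_sdr & !is.na(tab$pfam_position)])
    ),
    class = "sdr_result"
  )
}

#' @export
print.sdr_result <- function(x, ...) {
  cat(sprintf("<sdr_result> %d columns scored, %d SDR call(s) at top-%d intersection\n",
              nrow(x$table), length(x$sdr_columns), x$k))
  if (length(x$sdr_columns) > 0) {
    cat("  columns:", paste(x$sdr_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detect SDRs for a labeled kinase-domain alignment
#'
#' Convenience pipeline: trims gapped columns, runs the three column
#' scorers, and intersects their top-`k` ranks.
#'
#' @inheritParams groupsim_scores
#' @inheritParams relief_scores
#' @param k Rank cutoff for the ensemble intersection (default 15).
#' @param max_gap_fraction Gap-trimming threshold (default 0.20).
#' @return An `sdr_result` (see [ensemble_sdrs()]).
#' @export
detect_sdrs <- function(aln, labels, k = 15, iterations = 1000, seed,
                        max_gap_fraction = 0.20) {
  trimmed <- trim_gapped_columns(aln, max_gap_fraction)
  scores <- list(
    groupsim = groupsim_scores(trimmed, labels),
    relief = relief_scores(trimmed, labels, iterations = iterations, seed = seed),
    speer = speer_scores(trimmed, labels)
  )
  ensemble_sdrs(scores, k = k, column_to_pfam = trimmed$column_to_pfam)
}
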