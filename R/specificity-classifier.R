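# Naive Bayes prediction of kinase target-motif specificity from residues
# at SDR alignment columns: fold-enrichment labeling against proteome
# background, training with a fixed 0.5 class prior and Laplace 0.5 over
# the 21-symbol alphabet, exhaustive LOOCV feature-subset selection, and
# multi-model prediction with separate CMGC / non-CMGC R-3 models.

#' Label kinases by PWM fold enrichment over background
#'
#' A kinase is a positive example for a specificity (e.g. arginine at -3)
#' when the summed PWM frequency of the preferred residue(s) at the
#' preference position is at least `fold` times the summed background
#' frequency; all other kinases are negatives. Raising `fold` shrinks the
#' positive set monotonically.
#'
#' @param pwms List of `kinase_pwm` objects.
#' @param residues Character vector of preferred amino acids (usually one).
#' @param position Substrate position in -5..+5.
#' @param background Named numeric vector of proteome background
#'   frequencies over the 20 amino acids.
#' @param fold Enrichment threshold (default 3; the published models use
#'   3, 4 or 5).
#' @return Tibble with `kinase_id`, `fold_enrichment`, `label`.
#' @export
label_kinases <- function(pwms, residues, position, background, fold = 3) {
  if (!all(residues %in% AMINO_ACIDS)) abort("residues must be amino acids")
  b <- sum(background[residues])
  purrr::map(pwms, function(p) {
    fe <- sum(pwm_column(p, position)[residues]) / b
    tibble(
      kinase_id = p$kinase_id,
      fold_enrichment = fe,
      label = ifelse(fe >= fold, "positive", "negative")
    )
  }) |>
    dplyr::bind_rows()
}

feature_residues <- function(aln, ids, feature_columns) {
  cols <- as.character(as.integer(feature_columns))
  missing <- setdiff(cols, colnames(aln$mat))
  if (length(missing) > 0) {
    abort(sprintf("feature column(s) %s not resolvable in the alignment",
                  paste(missing, collapse = ", ")))
  }
  aln$mat[ids, cols, drop = FALSE]
}

#' Train a two-class naive Bayes specificity model
#'
#' Features are the residues (21-symbol alphabet, gap included so gapped
#' orthologs remain scorable) at the given alignment columns. Conditional
#' probabilities use a Laplace correction:
#' `P(s | class, column) = (count + laplace) / (N_class + 21 * laplace)`.
#' The class prior is fixed (default 0.5) regardless of class imbalance,
#' and posteriors are computed in log space and renormalized.
#'
#' @param aln A `kinase_alignment` containing the training kinases.
#' @param labels Tibble with `sequence_id` (or `kinase_id`) and `label`
#'   in positive/negative; both classes must be non-empty.
#' @param feature_columns Alignment columns used as features.
#' @param prior Prior probability of the positive class (default 0.5).
#' @param laplace Laplace correction factor (default 0.5).
#' @param specificity Optional name of the modeled specificity
#'   (e.g. "P+1").
#' @param label_threshold_fold Optional record of the fold-enrichment
#'   threshold used for labeling.
#' @return An object of class `specificity_model`.
#' @export
train_nb <- function(aln, labels, feature_columns, prior = 0.5, laplace = 0.5,
                     specificity = NA_character_,
                     label_threshold_fold = NA_real_) {
  if ("kinase_id" %in% names(labels) && !"sequence_id" %in% names(labels)) {
    labels <- dplyr::rename(labels, sequence_id = "kinase_id")
  }
  ids <- labels$sequence_id
  if (!all(ids %in% alignment_ids(aln))) {
    abort("all labeled kinases must be present in the alignment")
  }
  pos_ids <- ids[labels$label == "positive"]
  neg_ids <- ids[labels$label == "negative"]
  if (length(pos_ids) == 0L || length(neg_ids) == 0L) {
    abort("both classes must be non-empty")
  }
  cols <- as.integer(feature_columns)
  tables <- purrr::map(as.character(cols), function(cc) {
    res <- alignment_column_residues(aln, cc)
    tab <- function(who) {
      counts <- table(factor(res[who], levels = ALPHABET21))
      (as.numeric(counts) + laplace) / (length(who) + 21 * laplace)
    }
    m <- cbind(positive = tab(pos_ids), negative = tab(neg_ids))
    rownames(m) <- ALPHABET21
    m
  })
  names(tables) <- as.character(cols)
  structure(
    list(
      specificity = specificity,
      feature_columns = cols,
      feature_pfam = pfam_position(aln, cols),
      prior = prior,
      laplace = laplace,
      tables = tables,
      n_positive = length(pos_ids),
      n_negative = length(neg_ids),
      label_threshold_fold = label_threshold_fold,
      loocv_auc = NA_real_
    ),
    class = "specificity_model"
  )
}

#' @export
print.specificity_model <- function(x, ...) {
  cat(sprintf(
    "<specificity_model> %s: columns %s (prior %.2f, laplace %.2f, %d+/%d-)%s\n",
    ifelse(is.na(x$specificity), "unnamed", x$specificity),
    paste(x$feature_columns, collapse = ","),
    x$prior, x$laplace, x$n_positive, x$n_negative,
    ifelse(is.na(x$loocv_auc), "", sprintf(", LOOCV AUC %.3f", x$loocv_auc))
  ))
  invisible(x)
}

#' Posterior probabilities of the positive specificity class
#'
#' @param object A `specificity_model`.
#' @param aln A `kinase_alignment` sharing the model's feature columns.
#' @param sequence_ids Sequences to score (default all).
#' @param ... Unused.
#' @return Tibble with `sequence_id` and `posterior` (probability of the
#'   positive class; the two class posteriors sum to 1).
#' @export
predict.specificity_model <- function(object, aln, sequence_ids = NULL, ...) {
  ids <- sequence_ids %||% alignment_ids(aln)
  res <- feature_residues(aln, ids, object$feature_columns)
  lp <- log(object$prior)
  ln <- log(1 - object$prior)
  for (j in seq_along(object$feature_columns)) {
    tab <- object$tables[[j]]
    sym <- res[, j]
    lp <- lp + log(tab[sym, "positive"])
    ln <- ln + log(tab[sym, "negative"])
  }
  m <- pmax(lp, ln)
  post <- exp(lp - m) / (exp(lp - m) + exp(ln - m))
  tibble(sequence_id = ids, posterior = unname(post))
}

loocv_posteriors <- function(aln, labels, feature_columns, prior = 0.5,
                             laplace = 0.5) {
  if ("kinase_id" %in% names(labels) && !"sequence_id" %in% names(labels)) {
    labels <- dplyr::rename(labels, sequence_id = "kinase_id")
  }
  purrr::map_dbl(seq_len(nrow(labels)), function(i) {
    train <- labels[-i, , drop = FALSE]
    if (!all(c("positive", "negative") %in% train$label)) {
      return(NA_real_)
    }
    model <- train_nb(aln, train, feature_columns, prior = prior,
                      laplace = laplace)
    predict(model, aln, sequence_ids = labels$sequence_id[i])$posterior
  })
}

#' Select the SDR feature subset maximizing leave-one-out AUC
#'
#' Exhaustively evaluates every non-empty subset of the candidate columns:
#' for each subset, every kinase is scored by a model retrained on the
#' remaining kinases, and the AUC over the pooled held-out posteriors is
#' recorded. Ties favor fewer features, then lexicographic column order.
#'
#' @inheritParams train_nb
#' @param candidate_columns Candidate alignment columns (at most 8).
#' @return List with `columns` (best subset), `auc` (its LOOCV AUC) and
#'   `search` (tibble of every subset with its AUC).
#' @export
loocv_select <- function(aln, labels, candidate_columns, prior = 0.5,
                         laplace = 0.5) {
  cand <- sort(as.integer(candidate_columns))
  if (length(cand) > 8L) abort("exhaustive search supports at most 8 candidate columns")
  if ("kinase_id" %in% names(labels) && !"sequence_id" %in% names(labels)) {
    labels <- dplyr::rename(labels, sequence_id = "kinase_id")
  }
  subsets <- unlist(
    lapply(seq_along(cand), function(k) combn(cand, k, simplify = FALSE)),
    recursive = FALSE
  )
  is_pos <- labels$label == "positive"
  search <- purrr::map(subsets, function(cols) {
    post <- loocv_posteriors(aln, labels, cols, prior = prior, laplace = laplace)
    ok <- !is.na(post)
    tibble(
      columns = list(cols),
      n_features = length(cols),
      auc = auc_from_scores(post[is_pos & ok], post[!is_pos & ok])
    )
  }) |>
    dplyr::bind_rows()
  ord <- order(
    -search$auc, search$n_features,
    vapply(search$columns, function(x) paste(sprintf("%06d", x), collapse = "-"), "")
  )
  best <- search[ord[1], ]
  list(columns = best$columns[[1]], auc = best$auc, search = search)
}

#' Predict specificities for all kinases with a set of models
#'
#' Applies a list of independent binary specificity models to an
#' alignment. R-3 uses separate models for CMGC and non-CMGC kinases
#' (named `R-3_CMGC` / `R-3_nonCMGC`): each kinase is scored by the model
#' matching its group label and reported under the single specificity
#' `R-3`. A specificity is called when the posterior strictly exceeds
#' `threshold`; a kinase may carry several calls.
#'
#' @param models Named list of `specificity_model`s (names are
#'   specificities, e.g. `P+1`, `R-3_CMGC`).
#' @param aln A `kinase_alignment` of query kinases.
#' @param group_labels Named character vector kinase -> group (needed when
#'   an R-3 model pair is supplied; missing labels are an error naming the
#'   kinase).
#' @param threshold Posterior call threshold (default 0.9).
#' @return Tibble with `kinase_id`, `specificity`, `posterior`, `call`.
#' @export
predict_specificities <- function(models, aln, group_labels = NULL,
                                  threshold = 0.9) {
  ids <- alignment_ids(aln)
  group_labels <- group_labels %||% aln$group_labels
  r3 <- grepl("^R-3_", names(models))
  out <- list()
  for (nm in names(models)[!r3]) {
    p <- predict(models[[nm]], aln)
    out[[nm]] <- tibble(kinase_id = p$sequence_id, specificity = nm,
                        posterior = p$posterior)
  }
  if (any(r3)) {
    needed <- c("R-3_CMGC", "R-3_nonCMGC")
    if (!all(needed %in% names(models))) {
      abort("R-3 prediction needs both R-3_CMGC and R-3_nonCMGC models")
    }
    missing <- ids[!ids %in% names(group_labels) | is.na(group_labels[ids])]
    if (length(missing) > 0) {
      abort(sprintf("missing kinase group label for R-3 query: %s",
                    paste(missing, collapse = ", ")))
    }
    is_cmgc <- group_labels[ids] == "CMGC"
    rows <- list()
    if (any(is_cmgc)) {
      p <- predict(models[["R-3_CMGC"]], aln, sequence_ids = ids[is_cmgc])
      rows <- c(rows, list(tibble(kinase_id = p$sequence_id,
                                  specificity = "R-3", posterior = p$posterior)))
    }
    if (any(!is_cmgc)) {
      p <- predict(models[["R-3_nonCMGC"]], aln, sequence_ids = ids[!is_cmgc])
      rows <- c(rows, list(tibble(kinase_id = p$sequence_id,
                                  specificity = "R-3", posterior = p$posterior)))
    }
    out[["R-3"]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(call = .data$posterior > threshold) |>
    dplyr::arrange(.data$specificity, .data$kinase_id)
}
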