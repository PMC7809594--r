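# broom-style tidiers for the package's result objects.

#' Tidy a kinase PWM into long format
#'
#' @param x A `kinase_pwm`.
#' @param ... Unused.
#' @return Tibble with `kinase_id`, `residue`, `position`, `frequency`.
#' @method tidy kinase_pwm
#' @export
tidy.kinase_pwm <- function(x, ...) {
  as_tibble(x$matrix, rownames = "residue") |>
    tidyr::pivot_longer(-"residue", names_to = "position",
                        values_to = "frequency") |>
    dplyr::mutate(position = as.integer(.data$position),
                  kinase_id = x$kinase_id, .before = 1) |>
    dplyr::relocate("kinase_id", "residue", "position", "frequency")
}

#' One-row summary of a kinase PWM
#'
#' @param x A `kinase_pwm`.
#' @param ... Unused.
#' @return Tibble with identifier, site count, CV AUC and the total
#'   information content over the flanking positions.
#' @method glance kinase_pwm
#' @export
glance.kinase_pwm <- function(x, ...) {
  flank <- setdiff(WINDOW_POSITIONS, 0L)
  tibble(
    kinase_id = x$kinase_id,
    n_sites = x$n_sites,
    mean_cv_auc = x$mean_cv_auc,
    total_bits = sum(vapply(flank, function(p) column_bits(x, p), 0))
  )
}

#' Tidy per-fold cross-validation AUCs
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `fold` and `auc`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble(fold = seq_along(x$per_fold_auc), auc = x$per_fold_auc)
}

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `mean_auc`, `folds`, `passed`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, folds = length(x$per_fold_auc),
         passed = x$passed)
}

#' Tidy per-column SDR scores and ranks
#'
#' @param x An `sdr_result`.
#' @param ... Unused.
#' @return The per-column score/rank table with the SDR flag.
#' @method tidy sdr_result
#' @export
tidy.sdr_result <- function(x, ...) {
  x$table
}

#' One-row summary of an SDR detection result
#'
#' @param x An `sdr_result`.
#' @param ... Unused.
#' @return Tibble with column counts, the rank cutoff and the number of
#'   SDR calls.
#' @method glance sdr_result
#' @export
glance.sdr_result <- function(x, ...) {
  tibble(
    n_columns = nrow(x$table),
    k = x$k,
    n_sdrs = length(x$sdr_columns)
  )
}

#' Tidy the conditional probability tables of a specificity model
#'
#' @param x A `specificity_model`.
#' @param ... Unused.
#' @return Tibble with `column`, `pfam_position`, `symbol`, `class`,
#'   `probability`.
#' @method tidy specificity_model
#' @export
tidy.specificity_model <- function(x, ...) {
  purrr::map(seq_along(x$feature_columns), function(j) {
    as_tibble(x$tables[[j]], rownames = "symbol") |>
      tidyr::pivot_longer(c("positive", "negative"), names_to = "class",
                          values_to = "probability") |>
      dplyr::mutate(column = x$feature_columns[j],
                    pfam_position = x$feature_pfam[j], .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a specificity model
#'
#' @param x A `specificity_model`.
#' @param ... Unused.
#' @return Tibble with the modeled specificity, feature count, class
#'   sizes, labeling threshold and LOOCV AUC.
#' @method glance specificity_model
#' @export
glance.specificity_model <- function(x, ...) {
  tibble(
    specificity = x$specificity,
    n_features = length(x$feature_columns),
    n_positive = x$n_positive,
    n_negative = x$n_negative,
    prior = x$prior,
    laplace = x$laplace,
    label_threshold_fold = x$label_threshold_fold,
    loocv_auc = x$loocv_auc
  )
}

#' Tidy per-site mutation means with categories
#'
#' @param x A `mutation_enrichment`.
#' @param ... Unused.
#' @return The per-site mean-fraction table with categories.
#' @method tidy mutation_enrichment
#' @export
tidy.mutation_enrichment <- function(x, ...) {
  x$site_means
}

#' Category means and the SDR-vs-Other test in one row
#'
#' @param x A `mutation_enrichment`.
#' @param ... Unused.
#' @return Tibble with per-category means (wide) and the SDR vs Other
#'   Mann-Whitney p-value.
#' @method glance mutation_enrichment
#' @export
glance.mutation_enrichment <- function(x, ...) {
  wide <- x$category_means |>
    dplyr::select("category", "mean_fraction") |>
    tidyr::pivot_wider(names_from = "category", values_from = "mean_fraction",
                       names_prefix = "mean_")
  sdr <- dplyr::filter(
    x$tests,
    (.data$category_a == "Other" & .data$category_b == "SDR") |
      (.data$category_a == "SDR" & .data$category_b == "Other")
  )
  wide$p_sdr_vs_other <- if (nrow(sdr) == 1) sdr$p_value else NA_real_
  wide
}
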