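# Cancer-mutation enrichment over kinase-domain position categories:
# per-kinase per-site mutation fractions, category contrasts by
# Mann-Whitney rank test, and per-site comparison between specificity
# classes.

#' Per-kinase fractions of domain mutations by site
#'
#' For each kinase with at least one mutation, the fraction of its domain
#' mutations mapping to each Pfam position (duplicated records for the
#' same position are summed, so splitting a record's count across two rows
#' changes nothing). Kinases with zero mutations are excluded; per-kinase
#' fractions sum to 1.
#'
#' @param mutations Mutation tibble with `kinase_id`, `pfam_position`,
#'   `count` (see [read_mutations()]).
#' @return Tibble with `kinase_id`, `pfam_position`, `fraction`.
#' @export
site_mutation_fractions <- function(mutations) {
  if (any(mutations$count < 0)) abort("mutation counts must be non-negative")
  mutations |>
    dplyr::group_by(.data$kinase_id, .data$pfam_position) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > 0, .data$count > 0) |>
    dplyr::mutate(fraction = .data$count / .data$total) |>
    dplyr::select("kinase_id", "pfam_position", "fraction")
}

# mean per-site fraction across a kinase cohort; sites a kinase never hits
# contribute 0 for that kinase
mean_site_fractions <- function(table, positions, kinases = NULL) {
  kinases <- kinases %||% unique(table$kinase_id)
  n_k <- length(kinases)
  if (n_k == 0L) abort("no kinases with mutations in the requested set")
  sums <- table |>
    dplyr::filter(.data$kinase_id %in% kinases) |>
    dplyr::group_by(.data$pfam_position) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  out <- tibble(pfam_position = positions)
  out$mean_fraction <- sums$s[match(out$pfam_position, sums$pfam_position)]
  out$mean_fraction[is.na(out$mean_fraction)] <- 0
  out$mean_fraction <- out$mean_fraction / n_k
  out
}

#' Category-level mutation enrichment with rank tests
#'
#' Averages per-site mutation fractions across kinases (so hotspot kinases
#' cannot dominate), groups sites by functional category, and compares
#' every category pair with a two-sided Mann-Whitney test (normal
#' approximation with tie correction). The headline contrast is SDR vs
#' Other.
#'
#' @param table Output of [site_mutation_fractions()].
#' @param categories Tibble with `pfam_position` and `category`
#'   (disjoint), e.g. [domain_categories()].
#' @return An object of class `mutation_enrichment` with `site_means`
#'   (per-site mean fraction + category), `category_means`, and `tests`
#'   (pairwise comparisons with p-values).
#' @export
category_enrichment <- function(table, categories) {
  if (length(unique(table$kinase_id)) < 2L) {
    abort("category_enrichment needs at least 2 kinases")
  }
  site_means <- mean_site_fractions(table, categories$pfam_position)
  site_means <- dplyr::inner_join(site_means, categories, by = "pfam_position")
  cats <- unique(site_means$category)
  category_means <- site_means |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_fraction = mean(.data$mean_fraction),
      n_sites = dplyr::n(),
      .groups = "drop"
    )
  pairs <- if (length(cats) >= 2L) combn(sort(cats), 2, simplify = FALSE) else list()
  tests <- purrr::map(pairs, function(pr) {
    x <- site_means$mean_fraction[site_means$category == pr[1]]
    y <- site_means$mean_fraction[site_means$category == pr[2]]
    if (length(x) == 0L || length(y) == 0L) {
      warn(sprintf("category %s has no sites; comparison skipped",
                   pr[c(length(x) == 0L, length(y) == 0L)][1]))
      return(NULL)
    }
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE, correct = TRUE)
    )
    p <- wt$p.value
    # all observations tied across both groups: zero rank variance, no
    # evidence against the null
    if (is.na(p) || is.nan(p)) p <- 1
    tibble(
      category_a = pr[1], category_b = pr[2],
      n_a = length(x), n_b = length(y),
      statistic = unname(wt$statistic), p_value = p
    )
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  structure(
    list(site_means = site_means, category_means = category_means, tests = tests),
    class = "mutation_enrichment"
  )
}

#' @export
print.mutation_enrichment <- function(x, ...) {
  cat("<mutation_enrichment>\n")
  print(x$category_means)
  sdr <- dplyr::filter(x$tests,
                       .data$category_a == "Other" & .data$category_b == "SDR" |
                         .data$category_a == "SDR" & .data$category_b == "Other")
  if (nrow(sdr) == 1) {
    cat(sprintf("SDR vs Other: Mann-Whitney p = %.3g\n", sdr$p_value))
  }
  invisible(x)
}

#' Per-site mutation frequency contrast between two specificity classes
#'
#' For every domain position, the mean per-kinase mutation fraction among
#' kinases called for `spec_a` and among those called for `spec_b`
#' (a kinase called for both contributes to both). SDR sites are flagged.
#'
#' @param table Output of [site_mutation_fractions()].
#' @param calls Specificity call tibble with `kinase_id`, `specificity`,
#'   `call` (see [predict_specificities()]).
#' @param spec_a,spec_b Specificity labels to contrast (e.g. "R-3",
#'   "P+1").
#' @param categories Category tibble used to flag SDR sites and define
#'   the position universe (default [domain_categories()]).
#' @return Tibble with `pfam_position`, `mean_a`, `mean_b`, `is_sdr`.
#' @export
specificity_contrast <- function(table, calls, spec_a, spec_b,
                                 categories = domain_categories()) {
  called <- function(spec) {
    k <- calls$kinase_id[calls$specificity == spec & calls$call]
    k <- intersect(k, unique(table$kinase_id))
    if (length(k) == 0L) {
      abort(sprintf("no kinase called %s has mutation data", spec))
    }
    k
  }
  ka <- called(spec_a)
  kb <- called(spec_b)
  positions <- categories$pfam_position
  a <- mean_site_fractions(table, positions, ka)
  b <- mean_site_fractions(table, positions, kb)
  tibble(
    pfam_position = positions,
    mean_a = a$mean_fraction,
    mean_b = b$mean_fraction,
    is_sdr = categories$category == "SDR"
  )
}
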