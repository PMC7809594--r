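# Position-wise clustering of kinase target preferences: affinity
# propagation over single PWM columns, followed by the refinement rules
# (specificity filter, merge of like preferences, size filter, rescue of
# false negatives, purge of false positives).

# Affinity propagation by responsibility/availability message passing.
# s: n x n similarity matrix with self-preferences already on the diagonal.
# Returns list(exemplars, assignment, converged, iterations).
affinity_propagation <- function(s, damping = 0.9, max_iter = 1000,
                                 convergence_window = 100) {
  n <- nrow(s)
  r <- matrix(0, n, n)
  a <- matrix(0, n, n)
  exemplars_prev <- integer()
  stable <- 0L
  converged <- FALSE
  iter_done <- 0L
  for (iter in seq_len(max_iter)) {
    iter_done <- iter
    # responsibilities
    as_ <- a + s
    max1_idx <- max.col(as_, ties.method = "first")
    max1 <- as_[cbind(seq_len(n), max1_idx)]
    as2 <- as_
    as2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- apply(as2, 1, max)
    rnew <- s - max1
    rnew[cbind(seq_len(n), max1_idx)] <- s[cbind(seq_len(n), max1_idx)] - max2
    r <- damping * r + (1 - damping) * rnew
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- r[cbind(seq_len(n), seq_len(n))]
    colsums <- colSums(rp)
    anew <- matrix(colsums, n, n, byrow = TRUE) - rp
    danew <- colsums - diag(rp)  # sum over i' != k of max(0, r(i',k))
    anew <- pmin(anew, 0)
    anew[cbind(seq_len(n), seq_len(n))] <- danew
    a <- damping * a + (1 - damping) * anew
    exemplars <- which(diag(a) + diag(r) > 0)
    if (identical(exemplars, exemplars_prev) && length(exemplars) > 0L) {
      stable <- stable + 1L
      if (stable >= convergence_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    exemplars_prev <- exemplars
  }
  exemplars <- which(diag(a) + diag(r) > 0)
  if (length(exemplars) == 0L) {
    # degenerate input (e.g. all points identical): a single exemplar
    crit <- diag(a) + diag(r)
    exemplars <- which.max(crit)
    converged <- TRUE
  }
  assignment <- exemplars[max.col(s[, exemplars, drop = FALSE],
                                  ties.method = "first")]
  assignment[exemplars] <- exemplars
  list(exemplars = exemplars, assignment = assignment,
       converged = converged, iterations = iter_done)
}

pwm_position_matrix <- function(pwms, position) {
  v <- t(vapply(pwms, function(p) pwm_column(p, position), numeric(20)))
  rownames(v) <- vapply(pwms, function(p) p$kinase_id, "")
  v
}

#' Cluster kinases by their preference vector at one substrate position
#'
#' Each kinase contributes the 20-vector of amino-acid frequencies from one
#' PWM column; pairwise similarity is the negative Euclidean distance
#' between vectors (negative squared distance available via `squared`),
#' and clusters plus exemplars are found by affinity propagation with the
#' self-preference set to the median off-diagonal similarity. A tiny
#' index-ordered offset on the preferences breaks exact symmetry so the
#' result is deterministic for a fixed input.
#'
#' @param pwms List of `kinase_pwm` objects (at least 2).
#' @param position Substrate position in -5..+5 (0 excluded from analysis).
#' @param damping Message damping factor in \[0.5, 1) (default 0.9).
#' @param max_iter Maximum message-passing iterations (default 1000).
#' @param convergence_window Iterations of stable exemplars required to
#'   declare convergence (default 100).
#' @param squared Use negative squared Euclidean distance instead of the
#'   default negative Euclidean distance.
#' @return A tibble with columns `kinase_id`, `exemplar` and attributes
#'   `position` and `converged`.
#' @export
cluster_position <- function(pwms, position, damping = 0.9, max_iter = 1000,
                             convergence_window = 100, squared = FALSE) {
  if (length(pwms) < 2L) abort("clustering needs at least 2 PWMs")
  v <- pwm_position_matrix(pwms, position)
  d <- as.matrix(stats::dist(v, method = "euclidean"))
  s <- if (squared) -(d^2) else -d
  off <- s[row(s) != col(s)]
  pref <- stats::median(off)
  spread <- max(s) - min(s)
  eps <- if (spread > 0) spread * 1e-9 else 1e-12
  diag(s) <- pref - (seq_len(nrow(s)) - 1L) * eps
  ap <- affinity_propagation(s, damping = damping, max_iter = max_iter,
                             convergence_window = convergence_window)
  if (!ap$converged) {
    warn(sprintf("affinity propagation did not converge at position %+d; returning current assignment", position))
  }
  out <- tibble(
    kinase_id = rownames(v),
    exemplar = rownames(v)[ap$assignment]
  )
  attr(out, "position") <- as.integer(position)
  attr(out, "converged") <- ap$converged
  out
}

residue_group <- function(aa) {
  for (g in names(RESIDUE_SIMILARITY_GROUPS)) {
    if (aa %in% RESIDUE_SIMILARITY_GROUPS[[g]]) return(g)
  }
  aa
}

cluster_stats <- function(members, vmat) {
  mv <- colMeans(vmat[members, , drop = FALSE])
  ranked <- names(sort(mv, decreasing = TRUE))
  list(mean_vector = mv, top = ranked[1], ranked = ranked,
       top2sum = sum(sort(mv, decreasing = TRUE)[1:2]))
}

#' Refine raw preference clusters into specificity classes
#'
#' Applies, in order: (1) drop clusters whose summed mean probability of
#' the top two residues is below `min_specificity`; (2) merge clusters
#' preferring the same residue or residues of the same chemical group
#' (R/K, D/E, I/L/V/M, F/Y/W, S/T); (3) drop clusters smaller than
#' `min_size`; (4) rescue false negatives: any non-member kinase whose own
#' weight for the cluster's preferred residue exceeds the
#' `rescue_percentile` quantile of the member weights joins the cluster;
#' (5) purge false positives: members whose own preferred residue is not
#' among the cluster's top three mean-ranked residues are removed. Size and
#' specificity are re-checked after (4)+(5).
#'
#' @param raw Output of [cluster_position()].
#' @param pwms The list of `kinase_pwm` objects that were clustered.
#' @param min_specificity Minimum summed top-two mean probability
#'   (default 0.30).
#' @param min_size Minimum cluster size (default 6).
#' @param rescue_percentile Quantile of member weights a rescue candidate
#'   must exceed (default 0.40; linear interpolation).
#' @return A tibble with one row per surviving cluster: `position`,
#'   `label`, `exemplar`, `members` (list column), `n_members`,
#'   `preferred_residues` (list column, mean-ranked), `top2_sum` and
#'   `mean_vector` (list column).
#' @export
refine_clusters <- function(raw, pwms, min_specificity = 0.30, min_size = 6,
                            rescue_percentile = 0.40) {
  position <- attr(raw, "position")
  if (is.null(position)) abort("raw clusters must carry a position attribute")
  vmat <- pwm_position_matrix(pwms, position)
  clusters <- split(raw$kinase_id, raw$exemplar)
  exemplars <- names(clusters)

  # (1) specificity filter
  keep <- vapply(clusters, function(m) {
    cluster_stats(m, vmat)$top2sum >= min_specificity
  }, TRUE)
  clusters <- clusters[keep]
  exemplars <- exemplars[keep]
  if (length(clusters) == 0L) return(empty_cluster_tibble())

  # (2) merge same or chemically similar top preferences
  keys <- vapply(seq_along(clusters), function(i) {
    residue_group(cluster_stats(clusters[[i]], vmat)$top)
  }, "")
  merged <- list()
  merged_ex <- character()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    members <- unique(unlist(clusters[idx]))
    sizes <- lengths(clusters[idx])
    merged[[length(merged) + 1L]] <- members
    merged_ex <- c(merged_ex, exemplars[idx][which.max(sizes)])
  }
  clusters <- merged
  exemplars <- merged_ex

  # (3) size filter
  keep <- lengths(clusters) >= min_size
  clusters <- clusters[keep]
  exemplars <- exemplars[keep]
  if (length(clusters) == 0L) return(empty_cluster_tibble())

  all_kinases <- rownames(vmat)
  refined <- purrr::map(seq_along(clusters), function(i) {
    members <- clusters[[i]]
    st <- cluster_stats(members, vmat)
    # (4) rescue false negatives
    member_w <- vmat[members, st$top]
    thresh <- stats::quantile(member_w, rescue_percentile, names = FALSE, type = 7)
    candidates <- setdiff(all_kinases, members)
    rescued <- candidates[vmat[candidates, st$top] > thresh]
    members <- c(members, rescued)
    # (5) purge false positives
    st <- cluster_stats(members, vmat)
    own_top <- colnames(vmat)[max.col(vmat[members, , drop = FALSE],
                                      ties.method = "first")]
    members <- members[own_top %in% st$ranked[1:3]]
    if (length(members) == 0L) return(NULL)
    st <- cluster_stats(members, vmat)
    if (length(members) < min_size || st$top2sum < min_specificity) return(NULL)
    n_mem <- length(members)
    tibble(
      position = as.integer(position),
      label = sprintf("%s%+d", st$top, position),
      exemplar = exemplars[[i]],
      members = list(sort(members)),
      n_members = n_mem,
      preferred_residues = list(st$ranked),
      top2_sum = st$top2sum,
      mean_vector = list(st$mean_vector)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(refined))
  if (nrow(out) == 0L) empty_cluster_tibble() else out
}

empty_cluster_tibble <- function() {
  tibble(
    position = integer(), label = character(), exemplar = character(),
    members = list(), n_members = integer(), preferred_residues = list(),
    top2_sum = numeric(), mean_vector = list()
  )
}

#' Cluster kinase preferences at every flanking substrate position
#'
#' Runs [cluster_position()] and [refine_clusters()] for each position in
#' `positions` and binds the surviving specificity classes.
#'
#' @inheritParams cluster_position
#' @inheritParams refine_clusters
#' @param positions Substrate positions to analyze (default -5..-1, +1..+5).
#' @return Tibble of refined clusters over all positions.
#' @export
cluster_preferences <- function(pwms, positions = setdiff(-5:5, 0L), ...,
                                min_specificity = 0.30, min_size = 6,
                                rescue_percentile = 0.40) {
  purrr::map(positions, function(p) {
    raw <- cluster_position(pwms, p, ...)
    refine_clusters(raw, pwms, min_specificity = min_specificity,
                    min_size = min_size,
                    rescue_percentile = rescue_percentile)
  }) |>
    dplyr::bind_rows()
}
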