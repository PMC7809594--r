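# Domain types and file IO: phosphosite tables, kinase-domain alignments,
# alignment-column <-> Pfam PF00069 position maps, background frequencies,
# mutation tables, and PWM round-tripping.
#
# File conventions: tab-separated text with '#' comment lines, UTF-8,
# '.' decimal separator; aligned FASTA for domain alignments; a JSON
# sidecar (<path>.json) carries PWM metadata.

valid_window <- function(window) {
  nchar(window) == 11L &
    grepl(paste0("^_*[", paste(AMINO_ACIDS, collapse = ""), "]+_*$"), window)
}

# ---- PWM class ---------------------------------------------------------

#' Construct a kinase specificity PWM
#'
#' A position weight matrix is a 20 x 11 column-stochastic matrix of
#' relative amino-acid frequencies at substrate positions -5..+5 around the
#' phosphoacceptor (position 0).
#'
#' @param matrix Numeric 20 x 11 matrix; rows named by the 20 amino acids,
#'   columns by positions `-5`..`5`. Columns must each sum to 1.
#' @param kinase_id Kinase identifier.
#' @param n_sites Number of phosphosites the matrix was built from.
#' @param mean_cv_auc Mean cross-validation AUC, or `NA` if not assessed.
#' @return An object of class `kinase_pwm`.
#' @export
new_pwm <- function(matrix, kinase_id, n_sites = NA_integer_, mean_cv_auc = NA_real_) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(20L, 11L))) {
    abort("PWM matrix must be 20 amino-acid rows x 11 position columns")
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- AMINO_ACIDS
  if (is.null(colnames(matrix))) colnames(matrix) <- as.character(WINDOW_POSITIONS)
  if (!identical(rownames(matrix), AMINO_ACIDS)) {
    if (!setequal(rownames(matrix), AMINO_ACIDS)) {
      abort("PWM rows must be exactly the 20 standard amino acids")
    }
    matrix <- matrix[AMINO_ACIDS, , drop = FALSE]
  }
  if (!identical(colnames(matrix), as.character(WINDOW_POSITIONS))) {
    abort("PWM columns must be labeled -5..5")
  }
  if (any(matrix < -1e-12) || any(matrix > 1 + 1e-12)) {
    abort("PWM entries must lie in [0, 1]")
  }
  bad <- abs(colSums(matrix) - 1) > 1e-9
  if (any(bad)) {
    abort(sprintf(
      "PWM columns must sum to 1 (off at position %s)",
      paste(colnames(matrix)[bad], collapse = ", ")
    ))
  }
  structure(
    list(
      kinase_id = as.character(kinase_id),
      matrix = matrix,
      n_sites = as.integer(n_sites),
      mean_cv_auc = as.numeric(mean_cv_auc)
    ),
    class = "kinase_pwm"
  )
}

#' @export
print.kinase_pwm <- function(x, ...) {
  cat(sprintf(
    "<kinase_pwm> %s  (n_sites = %s, mean_cv_auc = %s)\n",
    x$kinase_id,
    ifelse(is.na(x$n_sites), "?", x$n_sites),
    ifelse(is.na(x$mean_cv_auc), "NA", sprintf("%.3f", x$mean_cv_auc))
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

# one PWM column as a named 20-vector
pwm_column <- function(pwm, position) {
  p <- as.character(as.integer(position))
  if (!p %in% colnames(pwm$matrix)) {
    abort(sprintf("position %s outside the substrate window -5..+5", p))
  }
  pwm$matrix[, p]
}

# ---- alignment class ---------------------------------------------------

#' Construct a kinase-domain alignment
#'
#' Holds equal-length gapped domain sequences together with the (partial,
#' injective) map from 1-based alignment columns to 1-based Pfam PF00069
#' match-state positions, and optional kinase group labels (AGC, CMGC, ...).
#'
#' @param sequences Named character vector of equal-length gapped sequences
#'   over the 20 amino acids and `-`.
#' @param column_to_pfam Optional named integer vector: names are alignment
#'   columns, values Pfam domain positions. Must be injective.
#' @param group_labels Optional named character vector of kinase groups.
#' @return An object of class `kinase_alignment`.
#' @export
kinase_alignment <- function(sequences, column_to_pfam = NULL, group_labels = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("alignment sequence ids must be present and unique")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort(sprintf(
      "alignment rows have unequal lengths (%s)",
      paste(sort(unique(widths)), collapse = ", ")
    ))
  }
  sequences <- toupper(sequences)
  ok <- paste0("^[", paste(AMINO_ACIDS, collapse = ""), "\\-]*$")
  bad <- !grepl(ok, sequences)
  if (any(bad)) {
    abort(sprintf(
      "sequence %s contains characters outside the 20 amino acids + '-' (ambiguity codes U/B/Z/X are rejected)",
      ids[which(bad)[1]]
    ))
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- ids
  colnames(mat) <- as.character(seq_len(ncol(mat)))
  if (!is.null(column_to_pfam)) {
    column_to_pfam <- validate_domain_map(column_to_pfam)
    if (any(as.integer(names(column_to_pfam)) > ncol(mat))) {
      abort("domain map refers to columns beyond the alignment length")
    }
  }
  structure(
    list(
      mat = mat,
      column_to_pfam = column_to_pfam,
      group_labels = group_labels
    ),
    class = "kinase_alignment"
  )
}

#' @export
print.kinase_alignment <- function(x, ...) {
  cat(sprintf(
    "<kinase_alignment> %d sequences x %d columns (%d mapped to Pfam positions)\n",
    nrow(x$mat), ncol(x$mat), length(x$column_to_pfam)
  ))
  invisible(x)
}

#' @export
dim.kinase_alignment <- function(x) dim(x$mat)

alignment_ids <- function(aln) rownames(aln$mat)
alignment_columns <- function(aln) as.integer(colnames(aln$mat))

# residues of one alignment column (by original column id)
alignment_column_residues <- function(aln, column) {
  cc <- as.character(as.integer(column))
  if (!cc %in% colnames(aln$mat)) {
    abort(sprintf("column %s is not present in the alignment", cc))
  }
  setNames(aln$mat[, cc], rownames(aln$mat))
}

validate_domain_map <- function(map) {
  map <- setNames(as.integer(map), names(map))
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    abort("domain map: duplicate or missing alignment columns")
  }
  if (anyDuplicated(map)) {
    abort("domain map is not injective: duplicate Pfam positions")
  }
  if (any(map < 1L) || any(as.integer(names(map)) < 1L)) {
    abort("domain map coordinates are 1-based positive integers")
  }
  map
}

#' Pfam domain position of alignment columns
#'
#' @param aln A `kinase_alignment` (or a named map as returned by
#'   [load_domain_map()]).
#' @param columns Integer vector of alignment columns.
#' @return Integer vector of Pfam PF00069 positions, `NA` where a column is
#'   unmapped (not an error).
#' @export
pfam_position <- function(aln, columns) {
  map <- if (inherits(aln, "kinase_alignment")) aln$column_to_pfam else aln
  if (is.null(map)) {
    return(rep(NA_integer_, length(columns)))
  }
  unname(map[as.character(as.integer(columns))])
}

# alignment column carrying a given Pfam position (NA if absent)
alignment_column_of_pfam <- function(aln, pfam_positions) {
  map <- aln$column_to_pfam
  if (is.null(map)) {
    return(rep(NA_integer_, length(pfam_positions)))
  }
  idx <- match(as.integer(pfam_positions), map)
  as.integer(names(map))[idx]
}

# ---- readers -----------------------------------------------------------

#' Read a kinase-phosphosite table
#'
#' Expects a tab-separated file with header columns `kinase_id`,
#' `substrate_id`, `site_position`, `acceptor`, `window`,
#' `in_activation_segment`, `source`. The 11-character window spans
#' substrate positions -5..+5 with `_` padding past the protein termini;
#' its center must equal the acceptor (one of S, T, Y). Records flagged
#' `in_activation_segment` are retained here; filtering is a pipeline step
#' (see [filter_sites()]).
#'
#' @param path Path to the TSV file (`#` comment lines allowed).
#' @return A tibble with one validated phosphosite per row.
#' @export
read_phosphosites <- function(path) {
  df <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("kinase_id", "substrate_id", "site_position", "acceptor",
                "window", "in_activation_segment", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("phosphosite table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[required]
  df$site_position <- suppressWarnings(as.integer(df$site_position))
  df$in_activation_segment <-
    df$in_activation_segment %in% c("1", "TRUE", "true", "T", "yes")
  problems <- character()
  bad_row <- function(i, why) sprintf("row %d: %s", i, why)
  for (i in seq_len(nrow(df))) {
    w <- df$window[i]
    if (is.na(w) || !valid_window(w)) {
      problems <- c(problems, bad_row(
        i, sprintf("invalid window '%s' (length 11 over amino acids with contiguous '_' padding required; ambiguity codes rejected)", w)))
      next
    }
    if (!df$acceptor[i] %in% c("S", "T", "Y")) {
      problems <- c(problems, bad_row(i, sprintf("acceptor '%s' not one of S/T/Y", df$acceptor[i])))
      next
    }
    if (substr(w, 6L, 6L) != df$acceptor[i]) {
      problems <- c(problems, bad_row(
        i, sprintf("window center '%s' does not match acceptor '%s'",
                   substr(w, 6L, 6L), df$acceptor[i])))
    }
    if (is.na(df$site_position[i]) || df$site_position[i] < 1L) {
      problems <- c(problems, bad_row(i, "site_position must be a positive integer"))
    }
  }
  if (length(problems) > 0) {
    abort(paste0(
      "malformed phosphosite record(s):\n",
      paste(head(problems, 10), collapse = "\n"),
      if (length(problems) > 10) sprintf("\n... and %d more", length(problems) - 10) else ""
    ))
  }
  df
}

#' Read an aligned FASTA kinase-domain alignment
#'
#' @param path Path to an aligned FASTA file with `-` gaps. Lowercase
#'   residues are uppercased on read.
#' @param column_to_pfam Optional domain map from [load_domain_map()].
#' @param group_labels Optional named character vector of kinase groups.
#' @return A [kinase_alignment()] object.
#' @export
read_alignment <- function(path, column_to_pfam = NULL, group_labels = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  kinase_alignment(
    setNames(as.character(seqs), names(seqs)),
    column_to_pfam = column_to_pfam,
    group_labels = group_labels
  )
}

#' Read an alignment-column to Pfam-position map
#'
#' Two-column TSV (`alignment_column`, `pfam_position`), both 1-based. The
#' map must be injective; columns absent from the file simply have no Pfam
#' coordinate (query with [pfam_position()] returns `NA`).
#'
#' @param path Path to the TSV file.
#' @return Named integer vector (names = alignment columns).
#' @export
load_domain_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("alignment_column", "pfam_position")
  if (!all(required %in% names(df))) {
    abort("domain map requires columns alignment_column and pfam_position")
  }
  validate_domain_map(setNames(as.integer(df$pfam_position),
                               as.character(as.integer(df$alignment_column))))
}

#' Read a background amino-acid frequency table
#'
#' TSV with columns `amino_acid` and `frequency`; frequencies must cover
#' all 20 amino acids, be positive, and sum to 1 (renormalized exactly
#' after a 1e-6 tolerance check).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of probabilities over the 20 amino acids.
#' @export
read_background <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("amino_acid", "frequency") %in% names(df))) {
    abort("background table requires columns amino_acid and frequency")
  }
  freq <- setNames(as.numeric(df$frequency), df$amino_acid)
  if (!setequal(names(freq), AMINO_ACIDS)) {
    abort("background frequencies must cover exactly the 20 amino acids")
  }
  freq <- freq[AMINO_ACIDS]
  if (any(freq <= 0)) abort("background frequencies must all be positive")
  if (abs(sum(freq) - 1) > 1e-6) {
    abort(sprintf("background frequencies sum to %.6f, not 1", sum(freq)))
  }
  freq / sum(freq)
}

#' Read a kinase domain-position mutation table
#'
#' TSV with columns `kinase_id`, `pfam_position`, `count` (non-negative
#' integer counts of mutations mapped to Pfam PF00069 domain positions).
#'
#' @param path Path to the TSV file.
#' @return A tibble of mutation records.
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("kinase_id", "pfam_position", "count")
  if (!all(required %in% names(df))) {
    abort("mutation table requires columns kinase_id, pfam_position, count")
  }
  df <- as_tibble(df)[required]
  df$pfam_position <- as.integer(df$pfam_position)
  df$count <- as.integer(df$count)
  if (any(is.na(df$count)) || any(df$count < 0L)) {
    abort("mutation counts must be non-negative integers")
  }
  if (any(is.na(df$pfam_position)) || any(df$pfam_position < 1L)) {
    abort("pfam_position must be a positive integer")
  }
  df
}

# ---- PWM round trip ----------------------------------------------------

#' Write a PWM to TSV with a JSON metadata sidecar
#'
#' The matrix goes to `path` as a `residue` column plus one column per
#' substrate position; `kinase_id`, `n_sites` and `mean_cv_auc` go to
#' `<path>.json`. Writing a non-column-stochastic matrix is refused.
#'
#' @param pwm A `kinase_pwm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "kinase_pwm"))
  if (any(abs(colSums(pwm$matrix) - 1) > 1e-6)) {
    abort("refusing to write a non-column-stochastic PWM")
  }
  df <- as_tibble(pwm$matrix)
  df <- dplyr::bind_cols(tibble(residue = rownames(pwm$matrix)), df)
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(
    kinase_id = pwm$kinase_id,
    n_sites = if (is.na(pwm$n_sites)) NULL else pwm$n_sites,
    mean_cv_auc = if (is.na(pwm$mean_cv_auc)) NULL else pwm$mean_cv_auc
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#'
#' @param path TSV path (the `<path>.json` sidecar is read if present).
#' @return A `kinase_pwm`.
#' @export
read_pwm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, as.character(WINDOW_POSITIONS)])
  rownames(m) <- df$residue
  meta <- list(kinase_id = NA_character_, n_sites = NULL, mean_cv_auc = NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar))
  }
  new_pwm(
    m,
    kinase_id = meta$kinase_id,
    n_sites = meta$n_sites %||% NA_integer_,
    mean_cv_auc = meta$mean_cv_auc %||% NA_real_
  )
}
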