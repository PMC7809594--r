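# Shared alphabets, substitution-matrix similarity, physicochemical scales,
# and the published kinase-domain position sets used across the pipeline.

#' The 20 standard amino acids, alphabetical by one-letter code
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# substrate window coordinates, position 0 = phosphoacceptor
WINDOW_POSITIONS <- -5:5
WINDOW_PAD <- "_"
GAP <- "-"

# 21-symbol alignment-column alphabet: 20 amino acids + gap
ALPHABET21 <- c(AMINO_ACIDS, GAP)

.kinsdr_env <- new.env(parent = emptyenv())

#' Normalized BLOSUM62 residue similarity
#'
#' Returns a 21 x 21 similarity matrix over the 20 amino acids plus the gap
#' symbol `-`. BLOSUM62 scores are min-max normalized to \[0, 1\] over the
#' 20 x 20 substitution block and then rescaled by
#' `sim(a, b) / sqrt(sim(a, a) * sim(b, b))` (clamped to \[0, 1\]) so that
#' every identical residue pair has similarity exactly 1. Any pair involving
#' a gap has similarity 0. Used both by the GroupSim-style column scorer and
#' by ortholog conservation.
#'
#' @return A numeric matrix with dimnames over the 21-symbol alphabet.
#' @export
blosum62_similarity <- function() {
  if (!is.null(.kinsdr_env$blosum_sim)) {
    return(.kinsdr_env$blosum_sim)
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[AMINO_ACIDS, AMINO_ACIDS]
  s <- (s - min(s)) / (max(s) - min(s))
  d <- sqrt(diag(s))
  s <- s / outer(d, d)
  s <- pmin(pmax(s, 0), 1)
  sim <- matrix(0, 21L, 21L, dimnames = list(ALPHABET21, ALPHABET21))
  sim[AMINO_ACIDS, AMINO_ACIDS] <- s
  .kinsdr_env$blosum_sim <- sim
  sim
}

# Kyte-Doolittle hydropathy, net side-chain charge at pH 7, and van der
# Waals volume (A^3); each scale z-normalized over the 20 amino acids.
# The gap symbol maps to the zero vector.
physchem_scales <- function() {
  if (!is.null(.kinsdr_env$physchem)) {
    return(.kinsdr_env$physchem)
  }
  hydropathy <- c(
    A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
  )
  charge <- c(
    A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1,
    L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
    W = 0, Y = 0
  )
  volume <- c(
    A = 67, C = 86, D = 91, E = 109, F = 135, G = 48, H = 118, I = 124,
    K = 135, L = 124, M = 124, N = 96, P = 90, Q = 114, R = 148, S = 73,
    T = 93, V = 105, W = 163, Y = 141
  )
  m <- cbind(
    hydropathy = scale(hydropathy[AMINO_ACIDS])[, 1],
    charge     = scale(charge[AMINO_ACIDS])[, 1],
    volume     = scale(volume[AMINO_ACIDS])[, 1]
  )
  rownames(m) <- AMINO_ACIDS
  m <- rbind(m, `-` = c(0, 0, 0))
  .kinsdr_env$physchem <- m
  m
}

# chemically similar residue groups used when merging preference clusters
RESIDUE_SIMILARITY_GROUPS <- list(
  basic       = c("R", "K"),
  acidic      = c("D", "E"),
  aliphatic   = c("I", "L", "V", "M"),
  aromatic    = c("F", "Y", "W"),
  hydroxyl    = c("S", "T")
)

#' Published SDR feature sets for specificity prediction
#'
#' The kinase-domain (Pfam PF00069 match-state) positions used as classifier
#' features for each of the five predictable target-motif preferences.
#' R-3 has separate feature sets for CMGC and non-CMGC kinases because their
#' binding modes differ; R-2 additionally carries positions 127 and 189,
#' which are supported as cooperative determinants even though single-column
#' scoring cannot detect them.
#'
#' @return Named list of integer vectors of domain positions.
#' @export
default_feature_sets <- function() {
  list(
    "P+1"        = c(159L, 188L, 196L),
    "P-2"        = c(82L, 162L, 188L),
    "R-2"        = c(127L, 162L, 189L),
    "R-3_nonCMGC" = c(82L, 86L, 127L, 162L),
    "R-3_CMGC"   = c(86L, 127L, 189L),
    "L-5"        = c(86L, 189L)
  )
}

#' Functional categories of kinase-domain positions
#'
#' Default assignment of Pfam PF00069 domain positions to the categories
#' used in mutation-enrichment and conservation analyses: `Catalytic`,
#' `Regulatory`, `SDR` (substrate-proximal specificity-determining
#' residues), with every other position in `1..n_positions` labeled
#' `Other`. Positions 157 and 158 appear in both the regulatory and SDR
#' literature lists; because a two-group test needs disjoint categories
#' they are assigned to `SDR` by default (set `sdr_overlap = "Regulatory"`
#' to flip them).
#'
#' @param n_positions Length of the domain coordinate system (default 260).
#' @param sdr_overlap Category receiving the ambiguous positions 157/158,
#'   `"SDR"` (default) or `"Regulatory"`.
#' @return A tibble with columns `pfam_position` and `category`.
#' @export
domain_categories <- function(n_positions = 260L, sdr_overlap = c("SDR", "Regulatory")) {
  sdr_overlap <- match.arg(sdr_overlap)
  catalytic <- c(8L, 10L, 13L, 15L, 28L, 30L, 48L, 85L, 123L, 125L, 128L,
                 129L, 130L, 131L, 140L, 141L, 186L, 190L)
  regulatory <- c(44L, 52L, 63L, 121L, 122L, 142L, 144L, 145L, 146L, 147L,
                  148L, 149L, 150L, 151L, 152L, 155L, 156L, 157L, 158L,
                  165L, 166L, 167L)
  sdr <- c(86L, 126L, 127L, 157L, 158L, 159L, 161L, 162L, 164L, 189L)
  if (sdr_overlap == "SDR") {
    regulatory <- setdiff(regulatory, c(157L, 158L))
  } else {
    sdr <- setdiff(sdr, c(157L, 158L))
  }
  pos <- seq_len(n_positions)
  category <- rep("Other", n_positions)
  category[pos %in% catalytic] <- "Catalytic"
  category[pos %in% regulatory] <- "Regulatory"
  category[pos %in% sdr] <- "SDR"
  tibble(pfam_position = pos, category = category)
}

# canonical catalytic triad used for pseudokinase flagging:
# K at 30 (VAIK lysine), D at 123 (HRD aspartate), D at 141 (DFG aspartate)
PSEUDOKINASE_TRIAD <- c("30" = "K", "123" = "D", "141" = "D")
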