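# Small in-code fixtures shared across tests.

# alignment from bare sequence strings, identity Pfam map by default
make_aln <- function(seqs, ids = NULL, map = TRUE, groups = NULL) {
  ids <- ids %||% sprintf("SEQ%02d", seq_along(seqs))
  L <- nchar(seqs[1])
  kinase_alignment(
    stats::setNames(seqs, ids),
    column_to_pfam = if (map) stats::setNames(seq_len(L), as.character(seq_len(L))) else NULL,
    group_labels = groups
  )
}

make_labels <- function(aln, n_positive) {
  ids <- rownames(aln$mat)
  tibble::tibble(
    sequence_id = ids,
    label = rep(c("positive", "negative"),
                c(n_positive, length(ids) - n_positive))
  )
}

# phosphosite tibble from raw windows
sites_from_windows <- function(windows, kinase = "KIN1",
                               substrate = NULL, in_as = FALSE) {
  tibble::tibble(
    kinase_id = kinase,
    substrate_id = substrate %||% sprintf("SUB%03d", seq_along(windows)),
    site_position = 50L + seq_along(windows),
    acceptor = substr(windows, 6, 6),
    window = windows,
    in_activation_segment = in_as,
    source = "test"
  )
}

# deterministic one-hot PWM: residue `aa` at every flanking position
one_hot_pwm <- function(aa = "A", center = "S", kinase_id = "ONEHOT") {
  m <- matrix(0, 20, 11, dimnames = list(AMINO_ACIDS, as.character(-5:5)))
  m[aa, ] <- 1
  m[, "0"] <- 0
  m[center, "0"] <- 1
  new_pwm(m, kinase_id = kinase_id)
}

# random column-stochastic PWM (Dirichlet columns)
random_pwm <- function(seed, kinase_id = paste0("RND", seed)) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(220, 1), 20, 11,
                dimnames = list(AMINO_ACIDS, as.character(-5:5)))
    m <- sweep(m, 2, colSums(m), "/")
    new_pwm(m, kinase_id = kinase_id)
  })
}

# brute-force Rand index over all pairs
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# raw-cluster tibble in the cluster_position output format
raw_clusters <- function(assignment, position) {
  out <- tibble::tibble(
    kinase_id = names(assignment),
    exemplar = unname(assignment)
  )
  attr(out, "position") <- as.integer(position)
  attr(out, "converged") <- TRUE
  out
}

`%||%` <- rlang::`%||%`
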