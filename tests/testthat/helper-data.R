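# Small in-code fixtures shared across tests.

# A count_matrix with the given counts (proteins x samples), default
# 2 treatments x 3 replicates.
make_counts <- function(counts, lengths = NULL,
                        treatments = NULL, n_replicates = 3) {
  counts <- as.matrix(counts)
  np <- nrow(counts); ns <- ncol(counts)
  if (is.null(treatments)) {
    stopifnot(ns %% n_replicates == 0)
    treatments <- rep(LETTERS[seq_len(ns / n_replicates)], each = n_replicates)
  }
  design <- data.frame(
    sample_id = paste0("S", seq_len(ns)),
    treatment = treatments,
    replicate = stats::ave(seq_len(ns), treatments, FUN = seq_along))
  rownames(counts) <- sprintf("P%03d", seq_len(np))
  colnames(counts) <- design$sample_id
  if (is.null(lengths)) lengths <- rep(100, np)
  count_matrix(counts, lengths, design)
}

# Random integer count matrix, seeded.
random_counts <- function(np, ns, seed, n_replicates = 3, max_count = 50) {
  set.seed(seed)
  counts <- matrix(rpois(np * ns, lambda = max_count / 3), np, ns)
  make_counts(counts, lengths = sample(100:2000, np, replace = TRUE),
              n_replicates = n_replicates)
}

# An nsaf_matrix built directly from given values (for tests that need
# exact NSAF replicates rather than count-derived ones).
make_nsaf <- function(values, treatments = NULL, n_replicates = 3,
                      scale_factor = 1) {
  cm <- make_counts(matrix(1, nrow(values), ncol(values)),
                    treatments = treatments, n_replicates = n_replicates)
  x <- nsaf(cm, scale_factor = scale_factor)
  values <- as.matrix(values)
  dimnames(values) <- dimnames(x$values)
  x$values <- values
  x
}
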