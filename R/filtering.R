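#' Configuration for the replicate-presence filter
#'
#' @param min_replicates `"all"` (a protein must be detected in every
#'   replicate of at least one treatment — the "max count 3" rule of a
#'   three-replicate design) or a positive integer threshold on the
#'   number of detected replicates within a treatment.
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_replicates = "all") {
  if (!(identical(min_replicates, "all") ||
        (is.numeric(min_replicates) && length(min_replicates) == 1 &&
         min_replicates >= 1 && min_replicates == round(min_replicates)))) {
    stop("min_replicates must be \"all\" or a positive integer")
  }
  structure(list(min_replicates = min_replicates), class = "filter_config")
}

#' Replicate-presence filter
#'
#' Retains a protein iff there exists a treatment in which it was
#' detected (PSM count > 0) in all replicates (mode `"all"`), or in at
#' least `min_replicates` replicates (integer mode). Detection in every
#' replicate of at least one condition guards against one-off spectral
#' identifications while still admitting proteins that are genuinely
#' absent in other conditions — which the differential-expression rule
#' later exploits.
#'
#' @param counts a [count_matrix()].
#' @param cfg a [filter_config()].
#' @return list with `retained` (character vector of accessions, input
#'   order) and `qualifying` (logical matrix proteins x treatments:
#'   which treatments satisfy the criterion for each protein).
#' @export
presence_filter <- function(counts, cfg = filter_config()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cfg, "filter_config"))
  design <- counts$design
  treatments <- unique(design$treatment)
  n_reps <- table(design$treatment)
  if (is.numeric(cfg$min_replicates) && cfg$min_replicates > min(n_reps)) {
    stop("min_replicates exceeds the smallest treatment replicate count (",
         min(n_reps), ")")
  }
  detected <- counts$counts > 0
  qualifying <- vapply(treatments, function(tr) {
    cols <- design$sample_id[design$treatment == tr]
    ndet <- rowSums(detected[, cols, drop = FALSE])
    if (identical(cfg$min_replicates, "all")) ndet == length(cols)
    else ndet >= cfg$min_replicates
  }, logical(nrow(counts$counts)))
  qualifying <- matrix(qualifying, nrow = nrow(counts$counts),
                       dimnames = list(rownames(counts$counts), treatments))
  list(retained = rownames(counts$counts)[rowSums(qualifying) > 0],
       qualifying = qualifying)
}

#' Per-treatment detection sets
#'
#' The set of proteins detected (PSM count > 0) in at least one
#' replicate of each treatment; the input to Venn partitioning of
#' treatment groups.
#'
#' @param counts a [count_matrix()].
#' @return named list, treatment -> sorted character vector of accessions.
#' @export
detection_sets <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  design <- counts$design
  detected <- counts$counts > 0
  sets <- lapply(unique(design$treatment), function(tr) {
    cols <- design$sample_id[design$treatment == tr]
    sort(rownames(counts$counts)[rowSums(detected[, cols, drop = FALSE]) > 0])
  })
  names(sets) <- unique(design$treatment)
  sets
}
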