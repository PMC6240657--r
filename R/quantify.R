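#' Normalized spectral abundance factors (NSAF)
#'
#' For protein k in sample s, the raw NSAF is
#' \deqn{NSAF_k = (PSM_k / L_k) / \sum_{i=1}^{N} (PSM_i / L_i)}
#' where PSM is the protein's spectral count in that sample and L its
#' length in amino acids. Dividing by length corrects for the larger
#' number of peptides (hence spectra) a long protein can yield; the
#' sample-wise denominator makes values comparable across samples. Raw
#' values in each sample sum to 1 over all proteins.
#'
#' Stored values are `raw * scale_factor`. The default reporting scale
#' of 1000 puts typical values for a ~1,000-protein experiment in the
#' 0.1–10 range, convenient for tables; the sum-to-one contract always
#' holds for `values / scale_factor`.
#'
#' Zeros propagate exactly: a protein with no spectra has NSAF 0, never
#' a pseudocount. A sample with no nonzero count at all gets an all-zero
#' column and a warning (it cannot be normalized).
#'
#' @param counts a [count_matrix()].
#' @param scale_factor positive reporting scale; default 1000.
#' @return an `nsaf_matrix`: list with `values` (proteins x samples, on
#'   the reporting scale), `scale_factor`, `design`, `lengths`.
#' @export
nsaf <- function(counts, scale_factor = 1000) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 || scale_factor <= 0) {
    stop("scale_factor must be a single positive number")
  }
  spl <- counts$counts / counts$lengths  # recycles lengths down rows
  denom <- colSums(spl)
  empty <- denom == 0
  if (any(empty)) {
    warning("sample(s) with no detected protein, NSAF column set to zero: ",
            paste(colnames(counts$counts)[empty], collapse = ", "))
    denom[empty] <- 1
  }
  values <- sweep(spl, 2, denom, "/") * scale_factor
  structure(list(values = values,
                 scale_factor = scale_factor,
                 design = counts$design,
                 lengths = counts$lengths),
            class = "nsaf_matrix")
}

#' @export
print.nsaf_matrix <- function(x, ...) {
  cat(sprintf("nsaf_matrix: %d proteins x %d samples, scale_factor = %g\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Per-treatment mean NSAF profiles
#'
#' Arithmetic mean of NSAF values over each treatment's replicates,
#' zeros included: a protein seen in one of three replicates at 0.3
#' averages to 0.1, reflecting that non-detection is evidence of low
#' abundance, not missing data.
#'
#' @param x an `nsaf_matrix` (from [nsaf()]).
#' @param treatments optional subset/order of treatment labels; default
#'   all treatments in design order.
#' @return numeric matrix, proteins x treatments.
#' @export
treatment_means <- function(x, treatments = NULL) {
  stopifnot(inherits(x, "nsaf_matrix"))
  all_tr <- unique(x$design$treatment)
  if (is.null(treatments)) treatments <- all_tr
  unknown <- setdiff(treatments, all_tr)
  if (length(unknown)) {
    stop("unknown treatment label(s): ", paste(unknown, collapse = ", "))
  }
  out <- vapply(treatments, function(tr) {
    cols <- x$design$sample_id[x$design$treatment == tr]
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), treatments))
  out
}
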