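#' Configuration for the three-condition differential-expression rule
#'
#' @param alpha t-test significance level (default 0.05).
#' @param min_fold minimum absolute fold change, >= 1 (default 1.5).
#' @param test `"student"` (two-sample equal-variance, the default — the
#'   classical choice at n = 3 per group) or `"welch"`.
#' @return a `de_config` object.
#' @export
de_config <- function(alpha = 0.05, min_fold = 1.5, test = c("student", "welch")) {
  test <- match.arg(test)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.numeric(min_fold), length(min_fold) == 1, min_fold >= 1)
  structure(list(alpha = alpha, min_fold = min_fold, test = test),
            class = "de_config")
}

#' Signed fold change between two treatment means
#'
#' Fold changes are reported on a signed scale with magnitude always
#' >= 1: an increase from `mean_a` (reference) to `mean_b` is
#' `+mean_b/mean_a`, a decrease is `-mean_a/mean_b`, so that a protein
#' dropping from 1.2 to 0.1 reports -12 rather than 0.083. Equal nonzero
#' means give +1. When exactly one mean is zero (presence/absence), the
#' fold is the sentinel `Inf` (present only in b) or `-Inf` (present
#' only in a), keeping tables numeric-sortable. Both means zero is an
#' error: such a protein carries no abundance information and should
#' have been filtered out.
#'
#' @param mean_a reference treatment mean(s), >= 0.
#' @param mean_b treatment-of-interest mean(s), >= 0.
#' @return signed fold(s); `Inf`/`-Inf` mark presence/absence cases.
#' @export
#' @examples
#' signed_fold(1.2, 0.1)  # -12
#' signed_fold(0.5, 0.5)  # +1
signed_fold <- function(mean_a, mean_b) {
  stopifnot(is.numeric(mean_a), is.numeric(mean_b))
  n <- max(length(mean_a), length(mean_b))
  mean_a <- rep_len(mean_a, n); mean_b <- rep_len(mean_b, n)
  if (any(mean_a < 0 | mean_b < 0)) stop("means must be non-negative")
  both_zero <- mean_a == 0 & mean_b == 0
  if (any(both_zero)) {
    stop("both means zero at position ", which(both_zero)[1],
         "; protein should have been filtered")
  }
  out <- ifelse(mean_b >= mean_a, mean_b / mean_a, -(mean_a / mean_b))
  out[mean_a == 0] <- Inf
  out[mean_b == 0] <- -Inf
  out
}

# Two-sided two-sample t-test p-value with deterministic limits for the
# zero-variance-in-both-groups case (p = 1 for equal means, p = 0 for a
# deterministic difference).
two_sample_p <- function(a, b, test) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = (test == "student"))$p.value
}

#' Call differential expression between two treatments
#'
#' A protein is called differentially expressed between treatments `a`
#' (reference) and `b` iff three conditions hold:
#' \enumerate{
#'   \item it was detected in every replicate of at least one of the two
#'     treatments;
#'   \item a two-sided t-test on per-replicate NSAF values gives
#'     p <= `alpha`, \emph{or} the protein was detected in no replicate
#'     of one of the two treatments (presence/absence evidence, for
#'     which no test is possible);
#'   \item the absolute signed fold change of the treatment means is at
#'     least `min_fold` (the infinite presence/absence fold always
#'     qualifies).
#' }
#' The tested universe is `retained` (typically the presence-filtered
#' set over the whole design) extended by any protein fully detected in
#' one of the two treatments. No multiple-testing correction enters the
#' call; a Benjamini-Hochberg `q_value` column is emitted for reference
#' only.
#'
#' @param x an `nsaf_matrix`.
#' @param treat_a,treat_b reference and treatment-of-interest labels.
#' @param retained character vector of accessions defining the DE
#'   universe; default: presence-qualified proteins within the two
#'   treatments.
#' @param cfg a [de_config()].
#' @return data.frame of class `de_result`, sorted by decreasing |fold|
#'   (presence/absence sentinels first, ties by accession), with columns
#'   accession, mean_a, mean_b, p_value, q_value, fold, call, reason
#'   (`ttest_fc`, `absence` or `not_de`), cond1, cond2, cond3 and rank.
#' @export
de_call <- function(x, treat_a, treat_b, retained = NULL, cfg = de_config()) {
  stopifnot(inherits(x, "nsaf_matrix"), inherits(cfg, "de_config"))
  design <- x$design
  for (tr in c(treat_a, treat_b)) {
    if (!tr %in% design$treatment) stop("unknown treatment: ", tr)
  }
  cols_a <- design$sample_id[design$treatment == treat_a]
  cols_b <- design$sample_id[design$treatment == treat_b]
  va <- x$values[, cols_a, drop = FALSE]
  vb <- x$values[, cols_b, drop = FALSE]
  det_a <- rowSums(va > 0); det_b <- rowSums(vb > 0)
  full_a <- det_a == length(cols_a)
  full_b <- det_b == length(cols_b)

  universe <- union(if (is.null(retained)) character(0) else retained,
                    rownames(x$values)[full_a | full_b])
  universe <- intersect(rownames(x$values), universe)  # keep matrix order
  if (!length(universe)) {
    return(empty_de_result(treat_a, treat_b))
  }

  va <- va[universe, , drop = FALSE]
  vb <- vb[universe, , drop = FALSE]
  ma <- rowMeans(va); mb <- rowMeans(vb)
  both_zero <- ma == 0 & mb == 0
  cond1 <- unname(full_a[universe] | full_b[universe])
  absent_one <- unname(det_a[universe] == 0 | det_b[universe] == 0) & !both_zero

  p <- rep(NA_real_, length(universe))
  need_p <- which(!absent_one & !both_zero)
  if (length(need_p)) {
    if (length(cols_a) < 2 || length(cols_b) < 2) {
      stop("t-test branch requires >= 2 replicates per treatment")
    }
    p[need_p] <- vapply(need_p, function(i)
      two_sample_p(va[i, ], vb[i, ], cfg$test), 0)
  }
  fold <- rep(NA_real_, length(universe))
  fold[!both_zero] <- signed_fold(ma[!both_zero], mb[!both_zero])
  cond2 <- absent_one | (!is.na(p) & p <= cfg$alpha)
  cond3 <- !is.na(fold) & (is.infinite(fold) | abs(fold) >= cfg$min_fold)
  call <- cond1 & cond2 & cond3
  reason <- ifelse(!call, "not_de", ifelse(absent_one, "absence", "ttest_fc"))

  res <- data.frame(accession = universe, mean_a = unname(ma), mean_b = unname(mb),
                    p_value = p, fold = fold, call = call, reason = reason,
                    cond1 = cond1, cond2 = cond2, cond3 = cond3,
                    stringsAsFactors = FALSE)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  ord <- order(-abs(res$fold), res$accession, na.last = TRUE)
  res <- res[ord, c("accession", "mean_a", "mean_b", "p_value", "q_value",
                    "fold", "call", "reason", "cond1", "cond2", "cond3")]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "treat_a") <- treat_a
  attr(res, "treat_b") <- treat_b
  class(res) <- c("de_result", "data.frame")
  res
}

empty_de_result <- function(treat_a, treat_b) {
  res <- data.frame(accession = character(0), mean_a = numeric(0),
                    mean_b = numeric(0), p_value = numeric(0),
                    q_value = numeric(0), fold = numeric(0),
                    call = logical(0), reason = character(0),
                    cond1 = logical(0), cond2 = logical(0), cond3 = logical(0),
                    rank = integer(0), stringsAsFactors = FALSE)
  attr(res, "treat_a") <- treat_a
  attr(res, "treat_b") <- treat_b
  class(res) <- c("de_result", "data.frame")
  res
}

#' Up/down summary of a differential-expression result
#'
#' Counts called proteins by direction (up = higher in the treatment of
#' interest: positive finite fold or `Inf` sentinel) and reports integer
#' percentages rounded half-away-from-zero, the convention of summary
#' statements such as "38 (29%) up- and 92 (71%) down-regulated".
#'
#' @param results a `de_result` from [de_call()], or any data.frame with
#'   logical `call` and signed `fold` columns.
#' @return list with `n_total`, `n_up`, `n_down`, `pct_up`, `pct_down`
#'   (percentages are `NA` when nothing was called).
#' @export
updown_summary <- function(results) {
  stopifnot(is.data.frame(results), all(c("call", "fold") %in% names(results)))
  called <- results[results$call, , drop = FALSE]
  n <- nrow(called)
  n_up <- sum(called$fold > 0)
  n_down <- n - n_up
  list(n_total = n, n_up = n_up, n_down = n_down,
       pct_up = if (n) percent_int(n_up, n) else NA_integer_,
       pct_down = if (n) percent_int(n_down, n) else NA_integer_)
}

#' One-way ANOVA across all treatments
#'
#' Classical fixed-effects one-way ANOVA of per-replicate NSAF values
#' against the treatment factor, per protein. Degenerate cases are
#' resolved deterministically: when the within-group sum of squares is
#' zero the protein is flagged (`flagged = TRUE`, p `NA`) with F = 0 if
#' the group means are also identical and F = `Inf` otherwise.
#'
#' @param x an `nsaf_matrix`.
#' @param retained accessions to test; default all proteins.
#' @return data.frame with accession, f_stat, p_value, flagged.
#' @export
anova_scan <- function(x, retained = NULL) {
  stopifnot(inherits(x, "nsaf_matrix"))
  design <- x$design
  if (length(unique(design$treatment)) < 2) stop("need >= 2 treatments")
  if (min(table(design$treatment)) < 2) stop("need >= 2 replicates per treatment")
  if (is.null(retained)) retained <- rownames(x$values)
  g <- factor(design$treatment, levels = unique(design$treatment))
  res <- lapply(retained, function(acc) {
    v <- x$values[acc, design$sample_id]
    gm <- tapply(v, g, mean)
    ssb <- sum(table(g) * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    if (ssw < .Machine$double.eps * sum(v^2 + 1)) {
      f <- if (ssb <= .Machine$double.eps * sum(v^2 + 1)) 0 else Inf
      return(data.frame(accession = acc, f_stat = f, p_value = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
    data.frame(accession = acc, f_stat = unname(ht$statistic),
               p_value = ht$p.value, flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
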