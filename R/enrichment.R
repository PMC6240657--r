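#' Functional-bin categorization
#'
#' Assigns every protein exactly one top-level functional category: the
#' first dot-component of its MapMan-style bin path (e.g.
#' `"protein.synthesis.ribosomal protein"` categorises as `"protein"`).
#' Proteins absent from the annotation map get the bin
#' `"not assigned.unknown"`.
#'
#' @param accessions character vector of protein accessions.
#' @param annotations an `annotation_map` (see [read_annotations()]).
#' @return list with `table` (data.frame accession, bin, top_bin),
#'   `counts` (named integer vector per top-level bin, decreasing) and
#'   `members` (named list of accessions per top-level bin).
#' @export
categorize <- function(accessions, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  bin <- annotations$bin[accessions]
  bin[is.na(bin) | !nzchar(bin)] <- "not assigned.unknown"
  top <- vapply(strsplit(unname(bin), ".", fixed = TRUE), `[[`, "", 1)
  tab <- data.frame(accession = accessions, bin = unname(bin), top_bin = top,
                    stringsAsFactors = FALSE)
  counts <- sort(table(top), decreasing = TRUE)
  members <- split(accessions, top)
  members <- lapply(members, sort)
  list(table = tab,
       counts = stats::setNames(as.integer(counts), names(counts)),
       members = members[names(counts)])
}

#' GO-term over-representation analysis
#'
#' For every GO term annotated to at least one background protein, tests
#' over-representation in the foreground with the upper-tail
#' hypergeometric probability of observing at least the seen number of
#' annotated proteins in a foreground-sized draw from the background,
#' then controls the FDR across terms with Benjamini-Hochberg. Only
#' directly annotated terms are tested (no GO-graph ancestor
#' propagation). Results are sorted by q-value, then p, then term id.
#'
#' @param foreground character vector of accessions (e.g. a DE list);
#'   must be a subset of `background`.
#' @param background character vector of accessions defining the
#'   annotation universe (e.g. the whole annotated genome, or the
#'   detected dataset).
#' @param annotations an `annotation_map` carrying GO terms.
#' @param fdr FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame of class `enrichment_result`: term, n_fg, n_bg,
#'   fg_size, bg_size, p_value, q_value, enriched.
#' @export
go_enrich <- function(foreground, background, annotations, fdr = 0.05) {
  stopifnot(inherits(annotations, "annotation_map"))
  foreground <- unique(foreground); background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground is not a subset of background: ",
         paste(utils::head(setdiff(foreground, background), 3), collapse = ", "))
  }
  go <- annotations$go[intersect(background, names(annotations$go))]
  term2bg <- split(rep(names(go), lengths(go)), unlist(go, use.names = FALSE))
  if (!length(term2bg)) {
    return(structure(data.frame(term = character(0), n_fg = integer(0),
                                n_bg = integer(0), fg_size = integer(0),
                                bg_size = integer(0), p_value = numeric(0),
                                q_value = numeric(0), enriched = logical(0)),
                     class = c("enrichment_result", "data.frame")))
  }
  fg_size <- length(foreground); bg_size <- length(background)
  n_bg <- lengths(term2bg)
  n_fg <- vapply(term2bg, function(m) sum(m %in% foreground), 0L)
  p <- stats::phyper(n_fg - 1L, n_bg, bg_size - n_bg, fg_size, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(term2bg), n_fg = n_fg, n_bg = n_bg,
                    fg_size = fg_size, bg_size = bg_size,
                    p_value = unname(p), q_value = unname(q),
                    enriched = unname(q <= fdr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Venn partition of 2-4 sets
#'
#' Computes all `2^n - 1` exclusive intersection regions of the input
#' sets exactly, with member lists, sizes and the percentage each region
#' makes of the union (rounded half-away-from-zero). The four-set limit
#' mirrors what a Venn diagram can display; pass `allow_many = TRUE` to
#' partition more sets without drawing in mind.
#'
#' @param sets named list of character vectors.
#' @param allow_many allow more than 4 sets.
#' @return a `venn_partition`: list with `table` (data.frame region,
#'   size, pct_union) where `region` names the member sets joined by
#'   `"&"`, `members` (named list) and `union_size`.
#' @export
venn <- function(sets, allow_many = FALSE) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("sets must be named")
  if (length(sets) < 2) stop("need at least 2 sets")
  if (length(sets) > 4 && !allow_many) {
    stop("more than 4 sets: a Venn diagram cannot display this; ",
         "pass allow_many = TRUE for the computation alone")
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  key <- apply(membership, 1, function(row) paste(names(sets)[row], collapse = "&"))
  labels <- unlist(lapply(seq_along(sets), function(m) {
    combn(names(sets), m, paste, collapse = "&")
  }))
  members <- lapply(labels, function(lb) universe[key == lb])
  names(members) <- labels
  tab <- data.frame(region = labels, size = lengths(members),
                    pct_union = if (length(universe))
                      percent_int(lengths(members), length(universe))
                    else rep(NA_integer_, length(labels)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, members = members,
                 union_size = length(universe)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: %d regions over a union of %d elements\n",
              nrow(x$table), x$union_size))
  print(x$table[x$table$size > 0, ], row.names = FALSE)
  invisible(x)
}

#' Terms unique to each of several comparisons
#'
#' Given the enriched term sets of several comparisons, reports for each
#' comparison the terms enriched only there, plus the full Venn
#' partition of the term sets.
#'
#' @param term_sets named list (comparison -> character vector of terms).
#' @return list with `unique` (named list of terms exclusive to each
#'   comparison) and `partition` (a [venn()] result).
#' @export
unique_terms <- function(term_sets) {
  if (length(term_sets) < 2) stop("need >= 2 comparisons")
  uniq <- lapply(seq_along(term_sets), function(i) {
    sort(setdiff(term_sets[[i]], unlist(term_sets[-i], use.names = FALSE)))
  })
  names(uniq) <- names(term_sets)
  list(unique = uniq,
       partition = venn(term_sets, allow_many = length(term_sets) > 4))
}
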