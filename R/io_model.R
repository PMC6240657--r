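#' Construct a spectral-count matrix
#'
#' The raw input of the pipeline: protein-level PSM (peptide-spectrum
#' match) counts for a set of proteins across the samples of a designed
#' experiment, together with protein lengths (amino acids) needed for
#' NSAF normalization and the sample design (treatment and replicate per
#' sample).
#'
#' Missing cells are not allowed: absence of detection must be an
#' explicit zero, because the differential-expression rule gives
#' presence/absence semantic weight.
#'
#' @param counts integer matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids). All entries must be
#'   non-negative integers.
#' @param lengths numeric vector of protein lengths in amino acids, named
#'   by accession or in row order; all >= 1.
#' @param design data.frame with columns `sample_id`, `treatment`,
#'   `replicate`; one row per sample, `(treatment, replicate)` unique.
#' @param descriptions optional character vector of free-text protein
#'   descriptions (same order/names as `lengths`).
#' @return an object of class `count_matrix`: a list with elements
#'   `counts`, `lengths`, `design` and `proteins` (a data.frame of
#'   accession, length, description).
#' @export
count_matrix <- function(counts, lengths, design, descriptions = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"  # integral values, type-stable round-trips
  lengths <- as.double(lengths)
  if (is.null(rownames(counts))) stop("counts must have accession rownames")
  if (is.null(colnames(counts))) stop("counts must have sample id colnames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate accession(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  design <- validate_design(design)
  if (!identical(colnames(counts), design$sample_id)) {
    if (!setequal(colnames(counts), design$sample_id)) {
      missing_des <- setdiff(colnames(counts), design$sample_id)
      if (length(missing_des)) {
        stop("sample(s) in counts absent from design: ",
             paste(missing_des, collapse = ", "))
      }
      stop("sample(s) in design absent from counts: ",
           paste(setdiff(design$sample_id, colnames(counts)), collapse = ", "))
    }
    counts <- counts[, design$sample_id, drop = FALSE]  # design order wins
  }
  if (!is.null(names(lengths))) {
    if (!setequal(names(lengths), rownames(counts))) {
      stop("names(lengths) do not match count matrix accessions")
    }
    lengths <- lengths[rownames(counts)]
  } else {
    if (length(lengths) != nrow(counts)) stop("lengths has wrong length")
    names(lengths) <- rownames(counts)
  }
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    bad <- names(lengths)[!is.finite(lengths) | lengths < 1][1]
    stop("protein length must be >= 1; offending accession: ", bad)
  }
  validate_counts(counts)
  if (is.null(descriptions)) {
    descriptions <- rep("", nrow(counts))
  } else if (!is.null(names(descriptions))) {
    descriptions <- unname(descriptions[rownames(counts)])
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(
    counts = counts,
    lengths = lengths,
    design = design,
    proteins = data.frame(accession = rownames(counts),
                          length = unname(lengths),
                          description = descriptions,
                          stringsAsFactors = FALSE)
  ), class = "count_matrix")
}

validate_design <- function(design) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  design$sample_id <- as.character(design$sample_id)
  design$treatment <- as.character(design$treatment)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  key <- paste(design$treatment, design$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (treatment, replicate) pair: ", key[duplicated(key)][1])
  }
  if (any(is.na(design$replicate)) || any(design$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  design[c("sample_id", "treatment", "replicate")]
}

# Reject non-integral or negative entries, naming the first offending cell.
validate_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("invalid PSM count %s at protein '%s', sample '%s' (must be a non-negative integer)",
                 format(counts[bad[1]]), rownames(counts)[i[1]], colnames(counts)[i[2]]))
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d proteins x %d samples (%d treatments)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$treatment))))
  cat("treatments:", paste(unique(x$design$treatment), collapse = ", "), "\n")
  invisible(x)
}

#' Read PSM counts and a sample design from TSV files
#'
#' The counts file is a strict TSV (tab-delimited, no quoting, header
#' required) whose first columns are `accession` and `length`, followed
#' by one column of integer PSM counts per sample. An optional
#' `description` column may sit between `length` and the sample columns.
#' The design file has columns `sample_id`, `treatment`, `replicate`.
#' Sample column order in the returned object follows the design file.
#'
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, design_path) {
  tab <- read_tsv_strict(path)
  if (!"accession" %in% names(tab)) stop("counts file lacks 'accession' column: ", path)
  if (!"length" %in% names(tab)) stop("counts file lacks 'length' column: ", path)
  design <- validate_design(read_tsv_strict(design_path))
  meta_cols <- intersect(c("accession", "length", "description"), names(tab))
  sample_cols <- setdiff(names(tab), meta_cols)
  extra <- setdiff(sample_cols, design$sample_id)
  if (length(extra)) {
    stop("sample column(s) in counts header absent from design: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(design$sample_id, sample_cols)
  if (length(missing)) {
    stop("design sample(s) missing from counts header: ",
         paste(missing, collapse = ", "))
  }
  lengths <- suppressWarnings(as.numeric(tab$length))
  if (any(is.na(lengths))) {
    stop("non-numeric length at row ", which(is.na(lengths))[1], " of ", path)
  }
  counts <- matrix(0, nrow(tab), length(design$sample_id),
                   dimnames = list(tab$accession, design$sample_id))
  for (s in design$sample_id) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("invalid PSM count '%s' at protein '%s', sample '%s' in %s",
                   tab[[s]][bad[1]], tab$accession[bad[1]], s, path))
    }
    counts[, s] <- v
  }
  count_matrix(counts, lengths, design,
               descriptions = if ("description" %in% names(tab)) tab$description)
}

#' Write a count matrix (and its design) back to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x))` reproduces
#' `x` exactly.
#'
#' @param x a `count_matrix`.
#' @param path counts TSV output path.
#' @param design_path design TSV output path (omit to skip).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(accession = rownames(x$counts),
                   length = unname(x$lengths),
                   description = x$proteins$description,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  write_tsv_strict(df, path)
  if (!is.null(design_path)) write_tsv_strict(x$design, design_path)
  invisible(path)
}

#' Read a protein annotation map (functional bins and GO terms)
#'
#' A MapMan-style mapping: one row per protein with a dot-separated
#' functional-bin path and a semicolon-separated list of GO identifiers,
#' either of which may be empty. Duplicate rows that agree are collapsed;
#' duplicates with conflicting bins are an error. Proteins absent from
#' the file default downstream to the bin `"not assigned.unknown"`.
#'
#' @param path TSV with columns `accession`, `bin`, `go_terms`.
#' @return an `annotation_map`: list with `bin` (named character) and
#'   `go` (named list of character vectors of GO ids).
#' @export
read_annotations <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("accession", "bin", "go_terms")
  if (!all(need %in% names(tab))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  dup <- unique(tab$accession[duplicated(tab$accession)])
  for (acc in dup) {
    rows <- tab[tab$accession == acc, , drop = FALSE]
    if (length(unique(rows$bin)) > 1) {
      stop("conflicting bins for duplicated accession: ", acc)
    }
  }
  tab <- tab[!duplicated(tab$accession), , drop = FALSE]
  go <- lapply(strsplit(tab$go_terms, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    sort(unique(v[nzchar(v)]))
  })
  names(go) <- tab$accession
  annotation_map(stats::setNames(tab$bin, tab$accession), go)
}

#' Build an annotation map in memory
#'
#' @param bin named character vector, accession -> dot-separated bin path.
#' @param go named list, accession -> character vector of GO ids.
#' @return an `annotation_map` object.
#' @export
annotation_map <- function(bin, go = NULL) {
  if (is.null(names(bin))) stop("bin must be named by accession")
  if (is.null(go)) go <- stats::setNames(rep(list(character(0)), length(bin)), names(bin))
  if (!setequal(names(go), names(bin))) stop("bin and go must cover the same accessions")
  structure(list(bin = bin, go = go[names(bin)]), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d proteins, %d with GO terms\n",
              length(x$bin), sum(lengths(x$go) > 0)))
  invisible(x)
}

#' Write an annotation map to TSV
#'
#' @param x an `annotation_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "annotation_map"))
  ord <- order(names(x$bin))
  df <- data.frame(accession = names(x$bin)[ord],
                   bin = unname(x$bin)[ord],
                   go_terms = vapply(x$go[ord], paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  invisible(path)
}

#' Write a result table deterministically
#'
#' TSV, UTF-8, `.` decimal separator. Rows are sorted by a `rank` column
#' if one exists, otherwise by `accession`, so the same input always
#' yields a byte-identical file. An empty table yields a header-only
#' file.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records)) {
    if ("rank" %in% names(records)) {
      records <- records[order(records$rank), , drop = FALSE]
    } else if ("accession" %in% names(records)) {
      records <- records[order(records$accession), , drop = FALSE]
    }
  }
  is_list <- vapply(records, is.list, TRUE)
  records[is_list] <- lapply(records[is_list],
                             function(col) vapply(col, paste, "", collapse = ";"))
  write_tsv_strict(records, path)
  invisible(path)
}
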