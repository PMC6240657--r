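#' Configuration of the full analysis pipeline
#'
#' @param comparisons list of 2-vectors `c(reference, treatment)` of
#'   treatment labels; defaults to the four study comparisons when the
#'   design carries the pollen labels, otherwise all pairs against the
#'   first treatment.
#' @param scale_factor NSAF reporting scale (see [nsaf()]).
#' @param filter a [filter_config()].
#' @param de a [de_config()].
#' @param k,n_restarts k-means settings (see [kmeans_fit()]).
#' @param n_top_loadings proteins per side for [loading_sum_profile()].
#' @param fdr enrichment FDR threshold.
#' @param background `"detected"` (enrich against the retained dataset)
#'   or `"annotation"` (against every annotated protein).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(comparisons = NULL, scale_factor = 1000,
                            filter = filter_config(), de = de_config(),
                            k = 30, n_restarts = 50, n_top_loadings = 100,
                            fdr = 0.05, background = c("detected", "annotation"),
                            seed = 1) {
  background <- match.arg(background)
  structure(list(comparisons = comparisons, scale_factor = scale_factor,
                 filter = filter, de = de, k = k, n_restarts = n_restarts,
                 n_top_loadings = n_top_loadings, fdr = fdr,
                 background = background, seed = as.integer(seed)),
            class = "pipeline_config")
}

default_comparisons <- function(treatments) {
  if (all(c("P-C", "P-HS", "P-E-C", "P-E-HS") %in% treatments)) {
    list(c("P-C", "P-HS"), c("P-HS", "P-E-HS"),
         c("P-C", "P-E-C"), c("P-C", "P-E-HS"))
  } else {
    lapply(treatments[-1], function(tr) c(treatments[1], tr))
  }
}

#' Run the full spectral-count analysis pipeline
#'
#' Executes, in order: NSAF quantification, the replicate-presence
#' filter, per-comparison differential-expression calls with up/down
#' summaries, one-way ANOVA across treatments, PCA with high/low
#' loading-sum profiles for PC1, proportion-normalized treatment
#' profiles with k-means clustering, and — when annotations are given —
#' functional-bin categorization of each DE list, GO enrichment of the
#' up- and down-regulated lists separately, the Venn partition of the
#' per-treatment detection sets, and the unique-term comparison of
#' enriched GO sets. Every stage logs its parameters via `message()`.
#'
#' @param counts a [count_matrix()].
#' @param annotations optional `annotation_map`.
#' @param cfg a [pipeline_config()].
#' @param outdir optional directory; when given, all result tables are
#'   written there as deterministic TSVs via [write_table()].
#' @return a report list with elements `nsaf`, `retained`,
#'   `detection_sets`, `de` (per comparison: `result`, `summary`,
#'   `bins`, `enrichment_up`, `enrichment_down`), `anova`, `pca`,
#'   `loading_profiles`, `clusters`, `venn_detected`, `unique_terms_up`,
#'   `unique_terms_down` and `summary` (the headline numbers).
#' @export
run_pipeline <- function(counts, annotations = NULL, cfg = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cfg, "pipeline_config"))
  treatments <- unique(counts$design$treatment)
  comparisons <- cfg$comparisons
  if (is.null(comparisons)) comparisons <- default_comparisons(treatments)
  for (cp in comparisons) {
    if (!all(cp %in% treatments)) {
      stop("comparison references unknown treatment(s): ",
           paste(setdiff(cp, treatments), collapse = ", "))
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log_stage <- function(...) message("[nsafpipe] ", sprintf(...))

  log_stage("quantify: NSAF, scale_factor = %g", cfg$scale_factor)
  nsafm <- nsaf(counts, scale_factor = cfg$scale_factor)

  log_stage("filter: replicate-presence, mode = %s",
            paste(cfg$filter$min_replicates, collapse = ""))
  filt <- presence_filter(counts, cfg$filter)
  retained <- filt$retained
  dsets <- detection_sets(counts)
  log_stage("filter: %d of %d proteins retained", length(retained),
            nrow(counts$counts))

  de_results <- list()
  for (cp in comparisons) {
    label <- paste0(cp[2], "_vs_", cp[1])
    log_stage("de: %s vs %s (alpha = %g, min_fold = %g, %s t-test)",
              cp[2], cp[1], cfg$de$alpha, cfg$de$min_fold, cfg$de$test)
    res <- de_call(nsafm, cp[1], cp[2], retained = retained, cfg = cfg$de)
    smry <- updown_summary(res)
    log_stage("de: %s: %d called (%d up, %d down)", label,
              smry$n_total, smry$n_up, smry$n_down)
    entry <- list(treat_a = cp[1], treat_b = cp[2],
                  result = res, summary = smry)
    if (!is.null(annotations)) {
      called <- res$accession[res$call]
      up <- res$accession[res$call & res$fold > 0]
      down <- res$accession[res$call & res$fold < 0]
      bg <- if (cfg$background == "detected") retained
            else union(retained, names(annotations$bin))
      entry$bins <- categorize(called, annotations)
      entry$enrichment_up <- go_enrich(up, bg, annotations, fdr = cfg$fdr)
      entry$enrichment_down <- go_enrich(down, bg, annotations, fdr = cfg$fdr)
    }
    de_results[[label]] <- entry
  }

  log_stage("anova: one-way across %d treatments", length(treatments))
  anova_tab <- anova_scan(nsafm, retained)

  log_stage("pca: %d retained proteins as variables", length(retained))
  pca <- pca_fit(nsafm, retained)
  loading_profiles <- list(
    high = loading_sum_profile(pca, nsafm, component = 1,
                               n = min(cfg$n_top_loadings, length(retained)),
                               side = "high"),
    low = loading_sum_profile(pca, nsafm, component = 1,
                              n = min(cfg$n_top_loadings, length(retained)),
                              side = "low"))

  log_stage("cluster: k = %d, %d restarts, seed = %d",
            cfg$k, cfg$n_restarts, cfg$seed + 101L)
  tm <- treatment_means(nsafm)
  profiles <- suppressWarnings(profile_normalize(tm[retained, , drop = FALSE]))
  clusters <- kmeans_fit(profiles, k = min(cfg$k, nrow(profiles)),
                         seed = cfg$seed + 101L, n_restarts = cfg$n_restarts)

  # Venn over the retained dataset: core-common percentages are quoted
  # relative to the filtered protein set
  dsets_ret <- lapply(dsets, intersect, retained)
  venn_detected <- if (length(dsets_ret) >= 2) venn(dsets_ret) else NULL

  uniq_up <- uniq_down <- NULL
  if (!is.null(annotations) && length(de_results) >= 2) {
    term_sets_up <- lapply(de_results, function(e)
      e$enrichment_up$term[e$enrichment_up$enriched])
    term_sets_down <- lapply(de_results, function(e)
      e$enrichment_down$term[e$enrichment_down$enriched])
    if (sum(lengths(term_sets_up)) > 0) uniq_up <- unique_terms(term_sets_up)
    if (sum(lengths(term_sets_down)) > 0) uniq_down <- unique_terms(term_sets_down)
  }

  summary <- list(
    n_identified = nrow(counts$counts),
    identified_per_treatment = lengths(dsets),
    n_retained = length(retained),
    de_totals = lapply(de_results, `[[`, "summary"),
    core_common_pct = if (!is.null(venn_detected)) {
      all_reg <- paste(names(dsets_ret), collapse = "&")
      percent_int(venn_detected$table$size[venn_detected$table$region == all_reg],
                  length(retained))
    } else NA_integer_,
    seed = cfg$seed)

  report <- list(nsaf = nsafm, retained = retained, qualifying = filt$qualifying,
                 detection_sets = dsets, de = de_results, anova = anova_tab,
                 pca = pca, loading_profiles = loading_profiles,
                 clusters = clusters, venn_detected = venn_detected,
                 unique_terms_up = uniq_up, unique_terms_down = uniq_down,
                 summary = summary, config = cfg)

  if (!is.null(outdir)) write_report_tables(report, counts, outdir)
  report
}

write_report_tables <- function(report, counts, outdir) {
  nv <- report$nsaf$values
  write_table(cbind(data.frame(accession = rownames(nv)),
                    as.data.frame(nv, check.names = FALSE)),
              file.path(outdir, "nsaf.tsv"))
  write_table(data.frame(accession = report$retained),
              file.path(outdir, "retained.tsv"))
  for (label in names(report$de)) {
    e <- report$de[[label]]
    write_table(as.data.frame(e$result), file.path(outdir, paste0("de_", label, ".tsv")))
    if (!is.null(e$enrichment_up)) {
      write_table(as.data.frame(e$enrichment_up),
                  file.path(outdir, paste0("enrich_up_", label, ".tsv")))
      write_table(as.data.frame(e$enrichment_down),
                  file.path(outdir, paste0("enrich_down_", label, ".tsv")))
    }
  }
  write_table(report$anova, file.path(outdir, "anova.tsv"))
  sc <- as.data.frame(report$pca$scores, check.names = FALSE)
  write_table(cbind(data.frame(accession = rownames(sc)), sc),
              file.path(outdir, "pca_scores.tsv"))
  cl <- data.frame(accession = names(report$clusters$assignments),
                   cluster = unname(report$clusters$assignments))
  write_table(cl, file.path(outdir, "clusters.tsv"))
  if (!is.null(report$venn_detected)) {
    write_table(report$venn_detected$table, file.path(outdir, "venn_detected.tsv"))
  }
  invisible(outdir)
}

#' Fold ratios of per-flower pollen-quality counts
#'
#' Ratios between treatment-level pollen counts (e.g. germinating pollen
#' grains per flower), reported unrounded with a 1-decimal display
#' value. A ratio of treatments (a, b) is `count[b] / count[a]`.
#'
#' @param counts named numeric vector of per-flower counts (> 0 for any
#'   treatment used as a denominator).
#' @param pairs list of 2-vectors `c(a, b)`; default all ordered pairs.
#' @return data.frame with columns denominator, numerator, ratio,
#'   display.
#' @export
#' @examples
#' quality_ratios(c(untreated = 0.2e4, pretreated = 2.3e4),
#'                list(c("untreated", "pretreated")))
quality_ratios <- function(counts, pairs = NULL) {
  if (is.null(names(counts))) stop("counts must be named by treatment")
  if (is.null(pairs)) {
    pairs <- list()
    for (a in names(counts)) for (b in setdiff(names(counts), a)) {
      pairs[[length(pairs) + 1]] <- c(a, b)
    }
  }
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% names(counts))) stop("unknown treatment in pair: ",
                                         paste(p, collapse = ", "))
    if (counts[p[1]] <= 0) stop("zero or negative denominator count for ", p[1])
    r <- unname(counts[p[2]] / counts[p[1]])
    data.frame(denominator = p[1], numerator = p[2], ratio = r,
               display = round(r, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
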