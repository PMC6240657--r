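#' Principal-component analysis of NSAF profiles
#'
#' Samples are observations, retained proteins are variables. Data are
#' mean-centered; variance scaling and a log transform (with a small
#' offset, since NSAF contains exact zeros) are optional and off by
#' default — centering-only is the common choice for spectral-count
#' abundances, where the large-abundance proteins carry the treatment
#' signal. Component signs are fixed so that each loading vector's
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param x an `nsaf_matrix`.
#' @param retained accessions to use as variables; default all.
#' @param scale. logical, unit-variance scaling (default `FALSE`).
#' @param log_transform logical, apply `log(v + offset)` first.
#' @param log_offset offset for the log transform (default: half the
#'   smallest nonzero value).
#' @return a `pca_model`: list with `scores` (samples x components),
#'   `loadings` (proteins x components), `explained_variance`,
#'   `center`, `scale`, `design`.
#' @export
pca_fit <- function(x, retained = NULL, scale. = FALSE,
                    log_transform = FALSE, log_offset = NULL) {
  stopifnot(inherits(x, "nsaf_matrix"))
  if (is.null(retained)) retained <- rownames(x$values)
  mat <- t(x$values[retained, , drop = FALSE])  # samples x proteins
  if (nrow(mat) < 2) stop("PCA needs >= 2 samples")
  if (log_transform) {
    if (is.null(log_offset)) {
      nz <- mat[mat > 0]
      log_offset <- if (length(nz)) min(nz) / 2 else 1
    }
    mat <- log(mat + log_offset)
  }
  if (scale.) {
    keep <- apply(mat, 2, stats::sd) > 0
    mat <- mat[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  # canonical sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 explained_variance = pc$sdev^2,
                 center = pc$center,
                 scale = if (scale.) pc$scale else FALSE,
                 design = x$design),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  pv <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("pca_model: %d samples, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores), pv[1],
              if (length(pv) > 1) pv[2] else NA))
  invisible(x)
}

#' Summed NSAF of the extreme-loading proteins, per treatment
#'
#' Selects the `n` proteins with the largest (side `"high"`) or most
#' negative (side `"low"`) loadings on one component and sums their
#' per-treatment mean NSAF. The resulting profile shows which treatment
#' drives that end of the component: a treatment whose proteome lost
#' those proteins dips, one that gained them peaks. Ties are broken by
#' accession order for determinism.
#'
#' @param pca a `pca_model`.
#' @param x the `nsaf_matrix` the model was fitted to.
#' @param component component index (default 1).
#' @param n number of proteins to select (default 100).
#' @param side `"high"` or `"low"`.
#' @return named numeric vector of summed treatment-mean NSAF, one entry
#'   per treatment; the selected accessions in attribute `"accessions"`.
#' @export
loading_sum_profile <- function(pca, x, component = 1, n = 100,
                                side = c("high", "low")) {
  side <- match.arg(side)
  stopifnot(inherits(pca, "pca_model"), inherits(x, "nsaf_matrix"))
  if (n <= 0) stop("n must be positive")
  ld <- pca$loadings[, component]
  if (n > length(ld)) stop("n exceeds the number of proteins in the model")
  accs <- names(ld)
  ord <- if (side == "high") order(-ld, accs) else order(ld, accs)
  sel <- accs[ord[seq_len(n)]]
  tm <- treatment_means(x)
  out <- colSums(tm[sel, , drop = FALSE])
  attr(out, "accessions") <- sel
  out
}

#' Proportion-normalize treatment profiles
#'
#' Rescales each protein's per-treatment mean abundances to sum to 1, so
#' a profile represents the protein's proportional distribution across
#' conditions irrespective of its absolute abundance — the
#' representation under which expression-shape clustering is meaningful.
#' All-zero rows cannot be profiled and are dropped with a warning.
#'
#' @param means numeric matrix, proteins x treatments (from
#'   [treatment_means()]).
#' @return matrix of the same shape (minus dropped rows), rows sum to 1.
#' @export
profile_normalize <- function(means) {
  means <- as.matrix(means)
  if (any(means < 0)) stop("treatment means must be non-negative")
  rs <- rowSums(means)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero profile(s) dropped: ",
            paste(utils::head(rownames(means)[zero], 5), collapse = ", "))
    means <- means[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  means / rs
}

# k-means++ initial centers (D^2-weighted sampling); consumes the RNG.
kmeanspp_init <- function(mat, k) {
  n <- nrow(mat)
  centers <- matrix(NA_real_, k, ncol(mat))
  idx <- sample.int(n, 1)
  centers[1, ] <- mat[idx, ]
  d2 <- rowSums((mat - matrix(centers[1, ], n, ncol(mat), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    pick <- if (all(d2 == 0)) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- mat[pick, ]
    nd <- rowSums((mat - matrix(centers[j + 1, ], n, ncol(mat), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' k-means clustering of proportion-normalized profiles
#'
#' Euclidean k-means on profile rows with k-means++ initialisation, best
#' inertia (total within-cluster sum of squares) over `n_restarts`
#' restarts, fully deterministic given `seed`. Profiles are
#' canonicalised by sorting rows by accession before seeding, so cluster
#' assignments do not depend on input order. A restart whose
#' initialisation collapses to an empty cluster is re-seeded from the
#' point farthest from its nearest center.
#'
#' @param profiles matrix from [profile_normalize()] (rows sum to 1).
#' @param k number of clusters (default 30, the conventional choice for
#'   surveying ~700 profiles at this granularity).
#' @param seed integer RNG seed (required: restarts are stochastic).
#' @param n_restarts number of k-means++ restarts (default 50).
#' @return a `cluster_model`: list with `profiles`, `k`, `assignments`
#'   (named integer vector), `centroids` (k x treatments), `inertia`,
#'   `seed`, `n_restarts`.
#' @export
kmeans_fit <- function(profiles, k = 30, seed, n_restarts = 50) {
  profiles <- as.matrix(profiles)
  if (missing(seed)) stop("seed is required for reproducible clustering")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(profiles)) stop("k exceeds the number of profiles")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(profiles, k)
      km <- tryCatch(
        stats::kmeans(profiles, centers = centers, iter.max = 100),
        error = function(e) NULL)
      if (is.null(km)) {
        # empty-cluster failure: replace duplicated centers with the
        # farthest points and retry once
        centers <- fix_empty_centers(profiles, centers)
        km <- tryCatch(stats::kmeans(profiles, centers = centers, iter.max = 100),
                       error = function(e) NULL)
        if (is.null(km)) next
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on all restarts")
  structure(list(profiles = profiles,
                 k = k,
                 assignments = stats::setNames(best$cluster, rownames(profiles)),
                 centroids = best$centers,
                 inertia = best$tot.withinss,
                 seed = seed,
                 n_restarts = n_restarts),
            class = "cluster_model")
}

fix_empty_centers <- function(mat, centers) {
  dup <- duplicated(centers)
  if (!any(dup)) dup[1] <- TRUE
  for (j in which(dup)) {
    d2 <- apply(centers, 1, function(ct)
      rowSums((mat - matrix(ct, nrow(mat), ncol(mat), byrow = TRUE))^2))
    far <- which.max(apply(d2, 1, min))
    centers[j, ] <- mat[far, ]
  }
  centers
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d profiles in k = %d clusters, inertia %.4g (seed %d, %d restarts)\n",
              nrow(x$profiles), x$k, x$inertia, x$seed, x$n_restarts))
  invisible(x)
}

#' Mean profile and membership of selected clusters
#'
#' @param model a `cluster_model`.
#' @param clusters cluster ids to summarise; default all.
#' @return list with `profile` (clusters x treatments matrix of mean
#'   normalized profiles), `size` (named sizes) and `members` (named
#'   list of accession vectors).
#' @export
cluster_profile_plot_data <- function(model, clusters = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(clusters)) clusters <- sort(unique(model$assignments))
  unknown <- setdiff(clusters, model$assignments)
  if (length(unknown)) stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  prof <- t(vapply(clusters, function(cl) {
    colMeans(model$profiles[model$assignments == cl, , drop = FALSE])
  }, numeric(ncol(model$profiles))))
  rownames(prof) <- as.character(clusters)
  members <- lapply(clusters, function(cl)
    sort(names(model$assignments)[model$assignments == cl]))
  names(members) <- as.character(clusters)
  list(profile = prof,
       size = stats::setNames(lengths(members), as.character(clusters)),
       members = members)
}
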