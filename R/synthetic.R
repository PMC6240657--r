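#' Configuration of the spectral-count simulator
#'
#' Defaults emulate a label-free GeLC-MS/MS pollen experiment: four
#' treatments (control, heat stress, ethephon + control, ethephon +
#' heat stress) with three biological replicates, ~1,000 proteins with
#' log-uniform lengths between 100 and 3,000 amino acids, a fixed
#' spectral budget of 20,000 PSMs per sample, log-normal baseline
#' relative abundances (sdlog 1.2, a realistic dynamic range of roughly
#' three orders of magnitude), 10% of proteins carrying a 4-fold
#' treatment effect, log-normal replicate jitter (sdlog 0.2) and
#' abundance-dependent detection dropout (logistic in the expected
#' per-sample PSM count, midpoint 1 PSM) that produces the all-replicate
#' absences the differential-expression rule exploits.
#'
#' @param n_proteins number of proteins.
#' @param treatments character vector of treatment labels.
#' @param n_replicates biological replicates per treatment.
#' @param length_range log-uniform bounds of protein length (aa).
#' @param total_psm total PSM count per sample (spectral budget).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline relative abundances.
#' @param de_fraction fraction of proteins given a treatment effect.
#' @param effect_fold fold magnitude of each effect (direction and
#'   affected treatment are drawn per protein; the first treatment is
#'   the unaffected reference).
#' @param replicate_sdlog sdlog of the multiplicative replicate noise.
#' @param dropout list: `enabled`, `midpoint` (expected PSM count at 50%
#'   detection) and `width` of the logistic.
#' @param effects optional explicit proteins x treatments fold matrix
#'   overriding the random effect assignment (used e.g. for bin-wise
#'   designs).
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_proteins = 1000,
                       treatments = c("P-C", "P-HS", "P-E-C", "P-E-HS"),
                       n_replicates = 3,
                       length_range = c(100, 3000),
                       total_psm = 20000,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.2,
                       de_fraction = 0.1,
                       effect_fold = 4,
                       replicate_sdlog = 0.2,
                       dropout = list(enabled = TRUE, midpoint = 1, width = 0.5),
                       effects = NULL) {
  stopifnot(n_proteins >= 1, n_replicates >= 1, length(treatments) >= 1,
            total_psm >= 1, de_fraction >= 0, de_fraction <= 1,
            effect_fold >= 1, replicate_sdlog >= 0,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  structure(list(n_proteins = n_proteins, treatments = treatments,
                 n_replicates = n_replicates, length_range = length_range,
                 total_psm = total_psm, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, de_fraction = de_fraction,
                 effect_fold = effect_fold, replicate_sdlog = replicate_sdlog,
                 dropout = dropout, effects = effects),
            class = "sim_config")
}

#' Simulate a spectral-count dataset with known ground truth
#'
#' Protein lengths are log-uniform; each treatment's expected relative
#' abundance is the log-normal baseline times the protein's fold effect
#' for that treatment. Per sample, protein sampling weights are
#' abundance x length x log-normal replicate jitter (length enters the
#' weight because longer proteins yield more spectra — this is exactly
#' what the NSAF length division undoes, so NSAF estimates relative
#' abundance). Detection is Bernoulli with a logistic probability in the
#' expected per-sample PSM count; counts are then multinomial over the
#' detected proteins with the full spectral budget as trial count, so
#' each sample's counts sum exactly to `total_psm`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   exactly.
#' @return list with `counts` (a [count_matrix()]) and `truth` (a
#'   `synthetic_truth`: `abundance` — proteins x treatments true
#'   relative-abundance shares; `effects` — the fold matrix;
#'   `detected` — realized proteins x samples detection mask;
#'   `de` — data.frame of designed effects: accession, treatment, fold).
#' @export
simulate_counts <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    np <- cfg$n_proteins
    accs <- sprintf("SIM%04dg%05d", seq_len(np) %% 13, seq_len(np) * 10)
    lengths <- round(exp(stats::runif(np, log(cfg$length_range[1]),
                                      log(cfg$length_range[2]))))
    baseline <- stats::rlnorm(np, cfg$baseline_meanlog, cfg$baseline_sdlog)

    effects <- cfg$effects
    if (is.null(effects)) {
      effects <- matrix(1, np, length(cfg$treatments),
                        dimnames = list(accs, cfg$treatments))
      n_de <- round(cfg$de_fraction * np)
      if (n_de > 0 && length(cfg$treatments) > 1) {
        hit <- sample.int(np, n_de)
        aff <- sample(cfg$treatments[-1], n_de, replace = TRUE)
        up <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
        for (i in seq_len(n_de)) {
          effects[hit[i], aff[i]] <- if (up[i]) cfg$effect_fold else 1 / cfg$effect_fold
        }
      }
    } else {
      effects <- as.matrix(effects)
      if (nrow(effects) != np || ncol(effects) != length(cfg$treatments)) {
        stop("effects matrix must be n_proteins x n_treatments")
      }
      rownames(effects) <- accs
      colnames(effects) <- cfg$treatments
    }

    design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          treatment = cfg$treatments,
                          stringsAsFactors = FALSE)[2:1]
    design$sample_id <- paste0(design$treatment, "_R", design$replicate)
    design <- design[c("sample_id", "treatment", "replicate")]

    counts <- matrix(0L, np, nrow(design),
                     dimnames = list(accs, design$sample_id))
    detected <- matrix(TRUE, np, nrow(design),
                       dimnames = list(accs, design$sample_id))
    for (s in seq_len(nrow(design))) {
      tr <- design$treatment[s]
      w <- baseline * effects[, tr] * lengths *
        stats::rlnorm(np, 0, cfg$replicate_sdlog)
      expected <- cfg$total_psm * w / sum(w)
      keep <- rep(TRUE, np)
      if (isTRUE(cfg$dropout$enabled)) {
        p_det <- stats::plogis((expected - cfg$dropout$midpoint) / cfg$dropout$width)
        keep <- stats::runif(np) < p_det
        if (!any(keep)) stop("infeasible config: all proteins dropped in sample ",
                             design$sample_id[s])
      }
      detected[, s] <- keep
      counts[keep, s] <- as.integer(
        stats::rmultinom(1, cfg$total_psm, w[keep] / sum(w[keep])))
    }

    abundance <- sweep(baseline * effects, 2,
                       colSums(baseline * effects), "/")
    de_idx <- which(effects != 1, arr.ind = TRUE)
    de <- data.frame(accession = accs[de_idx[, 1]],
                     treatment = colnames(effects)[de_idx[, 2]],
                     fold = effects[de_idx],
                     stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, lengths, design),
         truth = structure(list(abundance = abundance, effects = effects,
                                detected = detected, de = de, seed = seed),
                           class = "synthetic_truth"))
  })
}

#' True signed fold between two treatments from simulation ground truth
#'
#' Computed on the true relative-abundance shares (the quantity NSAF
#' estimates), so it includes the small compositional shifts that a
#' strong effect in one protein induces in all others.
#'
#' @param truth a `synthetic_truth`.
#' @param treat_a,treat_b treatment labels (a = reference).
#' @return named numeric vector of signed folds per protein.
#' @export
true_signed_fold <- function(truth, treat_a, treat_b) {
  stopifnot(inherits(truth, "synthetic_truth"))
  stats::setNames(signed_fold(truth$abundance[, treat_a], truth$abundance[, treat_b]),
                  rownames(truth$abundance))
}

#' The canonical pollen heat-stress fixture
#'
#' A reproducible synthetic dataset shaped like the tomato developing
#' pollen heat-stress / ethephon experiment: 1,000 proteins, four
#' treatments x three replicates, and bin-structured effects. Heat
#' stress (`P-HS`) down-shifts the `protein.synthesis` and `TCA` bins
#' 4-fold and up-shifts a small `stress` bin 4-fold; ethephon
#' pre-treatment before heat stress (`P-E-HS`) halves those shifts in
#' log space (2-fold), moving the proteome back toward control; ethephon
#' alone (`P-E-C`) is neutral. About 72% of proteins carry a functional
#' bin, and each themed bin carries a toy GO term (e.g. translation for
#' `protein.synthesis`, tricarboxylic acid cycle for `TCA`, response to
#' heat for `stress`) so designed effects are recoverable by enrichment.
#'
#' @param seed integer RNG seed (default 2026).
#' @return list with `counts`, `truth` (see [simulate_counts()]) and
#'   `annotations` (an `annotation_map`).
#' @export
pollen_fixture <- function(seed = 2026) {
  n <- 1000
  treatments <- c("P-C", "P-HS", "P-E-C", "P-E-HS")
  bin_pool <- c("protein.synthesis.ribosomal protein" = 120,
                "TCA.carbonic anhydrases"             = 60,
                "stress.abiotic.heat"                  = 40,
                "RNA.RNA binding"                      = 80,
                "transport.p- and v-ATPases"           = 60,
                "redox.ascorbate and glutathione"      = 40,
                "signalling.G-proteins"                = 50,
                "cell.organisation"                    = 70,
                "misc.protease inhibitor"              = 40,
                "development.unspecified"              = 60)
  bin_go <- c("protein.synthesis.ribosomal protein" = "GO:0006412",
              "TCA.carbonic anhydrases"             = "GO:0006099",
              "stress.abiotic.heat"                  = "GO:0009408",
              "RNA.RNA binding"                      = "GO:0003723",
              "transport.p- and v-ATPases"           = "GO:0006810",
              "redox.ascorbate and glutathione"      = "GO:0045454",
              "signalling.G-proteins"                = "GO:0007264",
              "cell.organisation"                    = "GO:0016043",
              "misc.protease inhibitor"              = "GO:0010951",
              "development.unspecified"              = "GO:0032502")

  with_seed(seed + 1L, {
    bins <- rep(names(bin_pool), bin_pool)            # 620 annotated
    bins <- c(bins, rep(NA_character_, n - length(bins)))
    bins <- sample(bins)                              # random assignment
    # an extra 10% of the unannotated get a bin-less GO annotation so the
    # annotated fraction is ~72% of the proteome
    extra_go <- sample(which(is.na(bins)), round(0.1 * n))

    effects <- matrix(1, n, length(treatments),
                      dimnames = list(NULL, treatments))
    down <- !is.na(bins) & bins %in% c("protein.synthesis.ribosomal protein",
                                       "TCA.carbonic anhydrases")
    up <- !is.na(bins) & bins == "stress.abiotic.heat"
    effects[down, "P-HS"] <- 1 / 4
    effects[down, "P-E-HS"] <- 1 / 2
    effects[up, "P-HS"] <- 4
    effects[up, "P-E-HS"] <- 2
  })

  cfg <- sim_config(n_proteins = n, treatments = treatments, effects = effects)
  sim <- simulate_counts(cfg, seed = seed)
  accs <- rownames(sim$counts$counts)

  annotated <- which(!is.na(bins))
  bin_vec <- stats::setNames(bins[annotated], accs[annotated])
  go_vec <- lapply(bin_vec, function(b) unname(bin_go[b]))
  if (length(extra_go)) {
    extra <- stats::setNames(rep("not assigned.unknown", length(extra_go)),
                             accs[extra_go])
    bin_vec <- c(bin_vec, extra)
    go_vec <- c(go_vec, stats::setNames(rep(list("GO:0008150"), length(extra_go)),
                                        accs[extra_go]))
  }
  list(counts = sim$counts,
       truth = sim$truth,
       annotations = annotation_map(bin_vec, go_vec))
}
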