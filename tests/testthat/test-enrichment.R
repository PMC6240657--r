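test_that("categorization uses the top-level bin and defaults the unannotated", {
  ann <- annotation_map(
    c(p1 = "protein.synthesis.ribosomal protein.eukaryotic.60S subunit.L21",
      p2 = "TCA.carbonic anhydrases",
      p3 = "protein.degradation"))
  cat <- categorize(c("p1", "p2", "p3", "p4"), ann)
  expect_identical(cat$table$top_bin, c("protein", "TCA", "protein", "not assigned"))
  expect_identical(cat$table$bin[4], "not assigned.unknown")
  expect_identical(unname(cat$counts["protein"]), 2L)
})

test_that("bin counts partition the protein list", {
  set.seed(61)
  bins <- paste0(sample(c("protein", "TCA", "RNA", "stress", "misc"), 80, TRUE),
                 ".sub")
  ann <- annotation_map(stats::setNames(bins, sprintf("q%03d", 1:80)))
  accs <- c(sprintf("q%03d", 1:80), sprintf("x%02d", 1:20))
  cat <- categorize(accs, ann)
  expect_identical(sum(cat$counts), 100L)
  expect_identical(sort(unname(unlist(cat$members))), sort(accs))
})

test_that("go_enrich gives the exact combinatorial p on the textbook toy", {
  # background of 20, a term annotating 5, a foreground of 5 holding all 5:
  # p = 1 / choose(20, 5)
  bg <- sprintf("g%02d", 1:20)
  ann <- annotation_map(
    stats::setNames(rep("misc", 20), bg),
    stats::setNames(c(rep(list("GO:1"), 5), rep(list(character(0)), 15)), bg))
  res <- go_enrich(bg[1:5], bg, ann)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$enriched)
})

test_that("foreground equal to background cannot be enriched", {
  bg <- sprintf("g%02d", 1:12)
  ann <- annotation_map(
    stats::setNames(rep("misc", 12), bg),
    stats::setNames(c(rep(list("GO:1"), 4), rep(list("GO:2"), 8)), bg))
  res <- go_enrich(bg, bg, ann)
  expect_equal(res$p_value, c(1, 1))
  expect_error(go_enrich(c(bg, "zz"), bg, ann), "not a subset")
})

test_that("hypergeometric p equals exhaustive enumeration on small backgrounds", {
  # independent oracle: closed-form tail sum with choose()
  tail_p <- function(k, m, N, K) {
    js <- k:min(m, K)
    sum(choose(m, js) * choose(N - m, K - js)) / choose(N, K)
  }
  set.seed(63)
  for (rep in 1:25) {
    N <- sample(5:25, 1)
    bg <- sprintf("g%02d", 1:N)
    m <- sample(1:N, 1)
    go <- stats::setNames(c(rep(list("GO:1"), m), rep(list(character(0)), N - m)),
                          sample(bg))
    ann <- annotation_map(stats::setNames(rep("misc", N), names(go)), go)
    K <- sample(1:N, 1)
    fg <- sample(bg, K)
    res <- go_enrich(fg, bg, ann)
    k <- sum(fg %in% names(go)[vapply(go, length, 1L) > 0])
    expect_equal(res$p_value, tail_p(k, m, N, K), tolerance = 1e-12)
  }
})

test_that("null foregrounds reject at most at the nominal rate", {
  set.seed(65)
  N <- 200
  bg <- sprintf("g%03d", 1:N)
  go <- lapply(1:N, function(i) {
    terms <- character(0)
    if (i <= 40) terms <- c(terms, "GO:A")
    if (i %% 5 == 0) terms <- c(terms, "GO:B")
    terms
  })
  ann <- annotation_map(stats::setNames(rep("misc", N), bg),
                        stats::setNames(go, bg))
  hits <- c("GO:A" = 0, "GO:B" = 0)
  draws <- 1000
  for (d in seq_len(draws)) {
    fg <- sample(bg, 30)
    res <- go_enrich(fg, bg, ann)
    for (tm in names(hits)) {
      if (res$p_value[res$term == tm] <= 0.05) hits[tm] <- hits[tm] + 1
    }
  }
  # the discrete test is conservative: empirical rate <= 0.05 + MC slack
  expect_true(all(hits / draws <= 0.05 + 2 * sqrt(0.05 * 0.95 / draws)))
})

test_that("BH ordering by q never inverts ordering by p", {
  set.seed(67)
  N <- 60
  bg <- sprintf("g%03d", 1:N)
  go <- lapply(1:N, function(i) paste0("GO:", sample(1:8, sample(0:3, 1))))
  ann <- annotation_map(stats::setNames(rep("misc", N), bg),
                        stats::setNames(go, bg))
  res <- go_enrich(sample(bg, 20), bg, ann)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(diff(res$q_value) >= -1e-12))
  expect_true(all(res$n_fg <= res$fg_size), all(res$n_fg <= res$n_bg))
})

test_that("venn regions partition the union for 2-4 sets", {
  same <- venn(list(A = c("x", "y"), B = c("y", "x")))
  expect_identical(same$members[["A&B"]], c("x", "y"))
  expect_identical(sum(same$table$size), 2L)

  disj <- venn(list(A = "x", B = "y", C = "z"))
  expect_identical(disj$table$size[disj$table$region %in% c("A", "B", "C")],
                   rep(1L, 3))
  expect_identical(sum(disj$table$size), 3L)

  set.seed(69)
  sets <- lapply(1:4, function(i) sample(sprintf("e%04d", 1:1000), 300))
  names(sets) <- c("W", "X", "Y", "Z")
  vp <- venn(sets)
  # bitmask oracle
  universe <- sort(unique(unlist(sets)))
  mask <- sapply(sets, function(s) universe %in% s)
  oracle_key <- apply(mask, 1, function(r) paste(names(sets)[r], collapse = "&"))
  for (i in seq_len(nrow(vp$table))) {
    expect_identical(vp$table$size[i],
                     sum(oracle_key == vp$table$region[i]))
  }
  expect_identical(sum(vp$table$size), length(universe))
  expect_identical(vp$union_size, length(universe))
  # percentages of union sum to 100 up to integer rounding
  expect_lte(abs(sum(vp$table$pct_union) - 100), nrow(vp$table) / 2)
  expect_error(venn(c(sets, list(V = "e0001"))), "allow_many")
  expect_silent(venn(c(sets, list(V = "e0001")), allow_many = TRUE))
})

test_that("unique_terms isolates comparison-specific terms", {
  ts <- list(c1 = c("a", "b"), c2 = c("a", "b"))
  u <- unique_terms(ts)
  expect_identical(lengths(u$unique), c(c1 = 0L, c2 = 0L))

  ts2 <- list(c1 = character(0), c2 = c("a", "b"))
  u2 <- unique_terms(ts2)
  expect_identical(u2$unique$c2, c("a", "b"))
  expect_length(u2$unique$c1, 0)

  set.seed(71)
  ts3 <- lapply(1:3, function(i) sample(letters, 10))
  names(ts3) <- paste0("c", 1:3)
  u3 <- unique_terms(ts3)
  for (i in 1:3) {
    expect_identical(u3$unique[[i]],
                     sort(setdiff(ts3[[i]], unlist(ts3[-i]))))
  }
})
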