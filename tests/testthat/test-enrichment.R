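make_ranked <- function(n = 200, seed = 81, scores = NULL) {
  set.seed(seed)
  if (is.null(scores)) scores <- sort(rexp(n), decreasing = TRUE)
  structure(tibble::tibble(window = seq_len(n), chr = 1L,
                           start = seq_len(n) * 1e5, score = scores,
                           rank = seq_len(n)),
            class = c("ranked_windows", "tbl_df", "tbl", "data.frame"))
}

test_that("window libraries apply size bounds with set semantics", {
  gw <- tibble::tibble(gene = sprintf("g%02d", 1:30), window = rep(1:15, 2))
  terms <- dplyr::bind_rows(
    tibble::tibble(gene = sprintf("g%02d", 1:10), term = "small"),   # 10 windows
    tibble::tibble(gene = sprintf("g%02d", 1:11), term = "kept"),    # 11 windows
    tibble::tibble(gene = c("g01", "g16"), term = "dup")             # same window twice
  )
  lib <- build_window_library(gw, terms, bounds = c(11, 8999))
  expect_false("small" %in% names(lib))
  expect_true("kept" %in% names(lib))
  expect_equal(length(lib$kept), 11)
  # two genes of one term in one window count once
  lib2 <- build_window_library(gw, terms, bounds = c(1, 8999))
  expect_equal(lib2$dup, 1)
  expect_error(build_window_library(gw, terms[terms$term == "small", ],
                                    bounds = c(11, 8999)), "survive")
})

test_that("library sizes match an independent tally on a randomised table", {
  set.seed(82)
  gw <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                       window = sample(1:60, 200, replace = TRUE))
  gt <- tibble::tibble(gene = sample(gw$gene, 600, replace = TRUE),
                       term = sample(paste0("T", 1:12), 600, replace = TRUE))
  lib <- build_window_library(gw, gt, bounds = c(1, 8999))
  # oracle: plain merge + tapply tally
  merged <- merge(as.data.frame(gt), as.data.frame(gw), by = "gene")
  sizes <- tapply(merged$window, merged$term,
                  function(w) length(unique(w)))
  expect_equal(unname(lengths(lib)[names(sizes)]), as.vector(sizes))
})

test_that("rank_windows orders by score with exclusion and deterministic ties", {
  ws <- tibble::tibble(window = 1:6, chr = c(2, 1, 1, 2, 1, 2),
                       start = c(3, 1, 2, 1, 3, 2) * 1e6,
                       pct_egv = c(0.5, 0.9, 2.0, 0.5, 0, 0.5))
  rk <- rank_windows(ws, exclude_threshold = 1)
  expect_false(3 %in% rk$window)            # above threshold: excluded
  expect_equal(attr(rk, "excluded"), 3)
  expect_equal(rk$window[1], 2)             # highest retained score
  # ties at 0.5 break by (chr, start)
  tied <- rk$window[rk$score == 0.5]
  expect_equal(tied, c(4, 6, 1))
  # all-zero scores: purely positional order
  ws0 <- dplyr::mutate(ws, pct_egv = 0)
  rk0 <- rank_windows(ws0)
  expect_equal(rk0$window, ws0$window[order(ws0$chr, ws0$start)])
  # random scores: ordering equals an independent sort oracle
  set.seed(83)
  wsr <- tibble::tibble(window = 1:50, chr = 1, start = (1:50) * 1e5,
                        pct_egv = runif(50))
  rkr <- rank_windows(wsr, exclude_threshold = Inf)
  expect_equal(rkr$window, wsr$window[order(-wsr$pct_egv)])
})

test_that("combined rankings follow best-rank aggregation", {
  r1 <- make_ranked(20, seed = 84)
  expect_equal(combine_rankings(list(r1, r1))$window, r1$window)
  # disjointly-top lists: both tops reach the combined top
  sc <- rep(0, 20)
  r_a <- make_ranked(20, scores = c(10, 9, rep(0, 18)))
  r_b <- make_ranked(20, scores = c(rep(0, 18), 9, 10))
  r_b <- dplyr::arrange(r_b, -score, chr, start)
  r_b$rank <- 1:20
  class(r_b) <- class(r_a)
  comb <- combine_rankings(list(r_a, r_b))
  expect_true(all(c(r_a$window[1], r_b$window[1]) %in% comb$window[1:4]))
  # brute-force oracle on random lists
  set.seed(85)
  l1 <- make_ranked(30, seed = 86)
  shuffled <- l1[sample(30), ]
  shuffled$score <- sort(runif(30), decreasing = TRUE)
  shuffled$rank <- 1:30
  class(shuffled) <- class(l1)
  comb2 <- combine_rankings(list(l1, shuffled))
  best <- pmin(l1$rank[match(1:30, l1$window)],
               shuffled$rank[match(1:30, shuffled$window)])
  pos <- l1[match(1:30, l1$window), ]
  oracle <- (1:30)[order(best, pos$chr, pos$start)]
  expect_equal(comb2$window, oracle)
  expect_error(combine_rankings(list(l1)), ">= 2")
})

test_that("the enrichment score equals the brute-force running sum extremum", {
  rk <- make_ranked(150, seed = 87)
  for (hp in list(1:10, c(5, 50, 120), sort(sample(150, 25)))) {
    run <- oracle_gsea_running(rk$score, hp, p = 1)
    es <- hairqtl:::.gsea_es(rk$score, hp, p = 1)
    expect_equal(es, run[which.max(abs(run))], tolerance = 1e-12)
  }
  # a term made of the top k windows scores higher than random same-size sets
  top <- hairqtl:::.gsea_es(rk$score, 1:12, 1)
  expect_gt(top, 0)
  set.seed(88)
  rand_es <- replicate(200, hairqtl:::.gsea_es(rk$score,
                                               sort(sample(150, 12)), 1))
  expect_true(all(top >= rand_es))
})

test_that("the enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  rk <- make_ranked(120, seed = 89)
  stats <- setNames(rk$score, as.character(rk$window))
  for (hp in list(1:8, sort(sample(120, 20)))) {
    expect_equal(hairqtl:::.gsea_es(rk$score, hp, 1),
                 fgsea::calcGseaStat(stats, selectedStats = hp,
                                     gseaParam = 1),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and rescaled score vectors are handled", {
  # all scores zero with p = 1 falls back to the unweighted statistic
  rk0 <- make_ranked(60, scores = rep(0, 60))
  es0 <- hairqtl:::.gsea_es(rk0$score, 1:6, 1)
  es0_p0 <- hairqtl:::.gsea_es(rk0$score, 1:6, 0)
  expect_equal(es0, es0_p0)
  # all scores equal and positive: weighting is uniform, so p=1 equals p=0
  rk1 <- make_ranked(60, scores = rep(2, 60))
  expect_equal(hairqtl:::.gsea_es(rk1$score, c(2, 10, 30), 1),
               hairqtl:::.gsea_es(rk1$score, c(2, 10, 30), 0))
  # multiplying all scores by a positive constant leaves ES unchanged
  rk <- make_ranked(100, seed = 90)
  hp <- sort(sample(100, 15))
  expect_equal(hairqtl:::.gsea_es(rk$score * 7.3, hp, 1),
               hairqtl:::.gsea_es(rk$score, hp, 1), tolerance = 1e-12)
})

test_that("preranked GSEA flags a planted term and keeps FDR flags nested", {
  rk <- make_ranked(250, seed = 91)
  set.seed(91)
  lib <- structure(list(planted = 1:15,
                        noise1 = sort(sample(250, 15)),
                        noise2 = sort(sample(250, 20)),
                        noise3 = sort(sample(250, 12))),
                   class = "window_library")
  res <- gsea_preranked(rk, lib, n_perm = 400, seed = 92)
  expect_true(res$flagged[res$term == "planted"])
  expect_lt(res$p.value[res$term == "planted"], 0.02)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$q.value >= 0 & res$q.value <= 1, na.rm = TRUE))
  # flags at q <= 0.25 are a superset of flags at q <= 0.1
  f25 <- res$term[res$q.value <= 0.25]
  f10 <- res$term[res$q.value <= 0.10]
  expect_true(all(f10 %in% f25))
  expect_error(gsea_preranked(rk, structure(list(all = 1:250),
                                            class = "window_library")),
               "whole ranked list")
})

test_that("GMT files round-trip a window library", {
  lib <- structure(list(A = c(1, 5, 9), B = c(2, 3, 4, 8)),
                   class = "window_library")
  path <- file.path(tempdir(), "lib.gmt")
  write_gmt(lib, path)
  lib2 <- read_gmt(path)
  expect_equal(lib2$A, lib$A)
  expect_equal(lib2$B, lib$B)
})
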