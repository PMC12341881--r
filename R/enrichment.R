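#' Build a window-level gene-set library
#'
#' Assigns annotation terms (e.g. GO) to genomic windows through the genes
#' each window contains: a term's window set is the union of the windows of
#' its member genes. Terms mapping to fewer than `bounds[1]` or more than
#' `bounds[2]` windows are dropped (defaults 11 and 8,999), so that
#' near-empty and near-genome-wide terms do not enter the enrichment.
#'
#' @param gene_windows Data frame with columns `gene`, `window` (window id
#'   per gene; a gene may span several windows via repeated rows).
#' @param gene_terms Data frame with columns `gene`, `term`.
#' @param bounds Length-2 numeric: minimum and maximum windows per term.
#' @return A `window_library`: named list term -> sorted unique window ids,
#'   with the gene-window provenance table as attribute `provenance`.
#' @export
build_window_library <- function(gene_windows, gene_terms,
                                 bounds = c(11, 8999)) {
  stopifnot(all(c("gene", "window") %in% names(gene_windows)),
            all(c("gene", "term") %in% names(gene_terms)))
  merged <- dplyr::inner_join(gene_terms, gene_windows, by = "gene",
                              relationship = "many-to-many")
  lib <- lapply(split(merged$window, merged$term),
                function(w) sort(unique(w)))
  sizes <- lengths(lib)
  lib <- lib[sizes >= bounds[1] & sizes <= bounds[2]]
  if (!length(lib)) stop("no terms survive the size bounds")
  structure(lib, class = "window_library",
            provenance = tibble::as_tibble(gene_windows))
}

#' Rank genomic windows by an association score
#'
#' Orders windows by decreasing score (%EGV for single-trait rankings, Ad
#' for pleiotropy rankings), excluding windows already significant in the
#' GWAS (score above `exclude_threshold`; the enrichment targets the
#' sub-significant tail of the architecture). Ties are broken by
#' chromosome and start position so rankings are deterministic.
#'
#' @param summaries A `window_summary` or `pleiotropy_windows` tibble (or
#'   any tibble with `window`, `chr`, `start`, and the score column).
#' @param score_col Column to rank by (default `pct_egv`).
#' @param exclude_threshold Windows with score strictly above this are
#'   excluded (default 1, the %EGV QTL threshold; use `Inf` to keep all,
#'   e.g. for Ad rankings).
#' @return A `ranked_windows` tibble: `window`, `chr`, `start`, `score`,
#'   `rank`, ordered by decreasing score; attribute `excluded` holds the
#'   excluded window ids.
#' @export
rank_windows <- function(summaries, score_col = "pct_egv",
                         exclude_threshold = 1) {
  stopifnot(score_col %in% names(summaries))
  s <- summaries[[score_col]]
  excl <- summaries$window[!is.na(s) & s > exclude_threshold]
  keep <- summaries[is.na(s) | s <= exclude_threshold, , drop = FALSE]
  ord <- order(-keep[[score_col]], keep$chr, keep$start)
  out <- tibble::tibble(window = keep$window[ord], chr = keep$chr[ord],
                        start = keep$start[ord],
                        score = keep[[score_col]][ord],
                        rank = seq_along(ord))
  structure(out, excluded = excl,
            class = c("ranked_windows", class(out)))
}

#' Combine per-trait window rankings
#'
#' Aggregates two or more rankings over the same window tiling by giving
#' each window its best (minimum) rank across traits, then reranking by
#' that statistic with the positional tie-break. Best-rank aggregation
#' keeps any window that ranks highly for at least one trait near the top
#' of the combined list; the aggregation rule is isolated here so
#' alternatives (mean rank, interleaving) can be swapped in.
#'
#' @param lists List of `ranked_windows` over the same tiling.
#' @return A `ranked_windows` tibble ordered by the combined statistic;
#'   `score` is the negated best rank (so scores are non-increasing).
#' @export
combine_rankings <- function(lists) {
  stopifnot(length(lists) >= 2L)
  ids <- lapply(lists, function(l) sort(l$window))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("rankings cover different window sets")
  }
  first <- lists[[1]]
  best <- Reduce(pmin, lapply(lists, function(l) l$rank[match(first$window,
                                                              l$window)]))
  ord <- order(best, first$chr, first$start)
  out <- tibble::tibble(window = first$window[ord], chr = first$chr[ord],
                        start = first$start[ord], score = -best[ord],
                        rank = seq_along(ord))
  structure(out, excluded = unique(unlist(lapply(lists, attr, "excluded"))),
            class = c("ranked_windows", class(out)))
}

# classic weighted Kolmogorov-Smirnov running-sum enrichment score.
# scores must be in ranked (descending) order; hit_pos are positions in
# that order. Returns the signed maximum deviation.
.gsea_es <- function(scores, hit_pos, p = 1) {
  n <- length(scores)
  k <- length(hit_pos)
  w <- abs(scores[hit_pos])^p
  if (sum(w) == 0) w <- rep(1, k)   # degenerate scores: unweighted KS
  hit_step <- numeric(n)
  hit_step[hit_pos] <- w / sum(w)
  miss_step <- rep(1 / (n - k), n)
  miss_step[hit_pos] <- 0
  running <- cumsum(hit_step - miss_step)
  i <- which.max(abs(running))
  running[i]
}

#' Preranked gene-set enrichment of genomic windows
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: walking down the ranked
#' window list, the running sum rises by the window's normalised
#' `|score|^p` at members of the term and falls uniformly otherwise; the
#' enrichment score (ES) is the maximum deviation with its sign. The null
#' is term-size-matched random window sets (no phenotype permutation is
#' possible on preranked input); the normalised ES (NES) divides by the
#' mean same-sign null ES, nominal p-values are same-sign permutation
#' tail frequencies, and FDR q-values follow the standard positive /
#' negative NES-pool procedure (Benjamini-Hochberg over nominal p is
#' available via `fdr_method`). Terms are flagged at `FDR <= 0.25`, the
#' conventional exploratory GSEA cutoff.
#'
#' @param ranked A `ranked_windows` list.
#' @param library A `window_library`.
#' @param p Weighting exponent on |score| (default 1; 0 gives the
#'   unweighted KS statistic).
#' @param n_perm Random window sets per term size (default 1000).
#' @param seed Seed for the permutation null.
#' @param fdr_method `"pool"` (GSEA NES-pool) or `"bh"`.
#' @param fdr_threshold Significance flag threshold (default 0.25).
#' @return An `enrichment_result` tibble: `term`, `size`, `es`, `nes`,
#'   `p.value`, `q.value`, `flagged`.
#' @export
gsea_preranked <- function(ranked, library, p = 1, n_perm = 1000L,
                           seed = 1L, fdr_method = c("pool", "bh"),
                           fdr_threshold = 0.25) {
  fdr_method <- match.arg(fdr_method)
  scores <- ranked$score
  n <- length(scores)
  pos_of_window <- setNames(seq_len(n), ranked$window)
  lib <- lapply(library, function(w) {
    wp <- pos_of_window[as.character(w)]
    miss <- sum(is.na(wp))
    if (miss > 0) {
      warning(sprintf("%d window(s) of a term absent from the ranked list", miss))
    }
    sort(unname(wp[!is.na(wp)]))
  })
  lib <- lib[lengths(lib) > 0]
  if (any(lengths(lib) >= n)) stop("a term covers the whole ranked list")
  set.seed(seed)
  es <- vapply(lib, function(hp) .gsea_es(scores, hp, p), numeric(1))
  sizes <- lengths(lib)
  # permutation null per distinct term size
  null_by_size <- lapply(sort(unique(sizes)), function(k) {
    vapply(seq_len(n_perm), function(b) {
      .gsea_es(scores, sort(sample.int(n, k)), p)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))
  norm_one <- function(e, null) {
    mp <- mean(null[null > 0]); mn <- mean(abs(null[null < 0]))
    if (e >= 0) {
      list(nes = if (is.finite(mp) && mp > 0) e / mp else NA_real_,
           null_nes = c(null[null > 0] / mp, null[null < 0] / mn),
           p = (1 + sum(null >= e)) / (1 + sum(null >= 0)))
    } else {
      list(nes = if (is.finite(mn) && mn > 0) e / mn else NA_real_,
           null_nes = c(null[null > 0] / mp, null[null < 0] / mn),
           p = (1 + sum(null <= e)) / (1 + sum(null < 0)))
    }
  }
  res <- lapply(seq_along(lib), function(i) {
    norm_one(es[i], null_by_size[[as.character(sizes[i])]])
  })
  nes <- vapply(res, `[[`, numeric(1), "nes")
  pval <- vapply(res, `[[`, numeric(1), "p")
  if (fdr_method == "bh") {
    qval <- p.adjust(pval, "BH")
  } else {
    pool <- unlist(lapply(res, `[[`, "null_nes"))
    pool <- pool[is.finite(pool)]
    qval <- vapply(nes, function(nn) {
      if (!is.finite(nn)) return(NA_real_)
      if (nn >= 0) {
        num <- mean(pool >= nn)
        den <- mean(nes >= nn, na.rm = TRUE)
      } else {
        num <- mean(pool <= nn)
        den <- mean(nes <= nn, na.rm = TRUE)
      }
      min(1, num / max(den, 1e-12))
    }, numeric(1))
    # enforce q non-increasing in |NES| within each sign: sweep from the
    # least extreme term upward, carrying the running minimum
    for (sgn in c(1, -1)) {
      ix <- which(sign(nes) == sgn | (sgn == 1 & nes == 0))
      if (length(ix) > 1) {
        ord <- ix[order(abs(nes[ix]))]
        qval[ord] <- cummin(qval[ord])
      }
    }
  }
  out <- tibble::tibble(term = names(lib), size = sizes, es = unname(es),
                        nes = unname(nes), p.value = unname(pval),
                        q.value = unname(qval),
                        flagged = !is.na(qval) & qval <= fdr_threshold)
  out <- out[order(out$p.value, -abs(out$nes)), ]
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Write / read a window library in GMT format
#'
#' One term per line: term id, description, then window ids, tab-separated.
#'
#' @param library A `window_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library), function(tm) {
    paste(c(tm, "na", library[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lib <- lapply(parts, function(x) sort(unique(x[-(1:2)])))
  names(lib) <- vapply(parts, `[[`, character(1), 1)
  # restore numeric window ids where possible
  lib <- lapply(lib, function(w) {
    wn <- suppressWarnings(as.numeric(w))
    if (!anyNA(wn)) sort(wn) else w
  })
  structure(lib, class = "window_library")
}
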