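#' VanRaden method-1 genomic relationship matrix
#'
#' Computes \eqn{G = ZZ'/(2\sum_j p_j(1-p_j))} where `Z` is the dosage
#' matrix centred at twice the allele frequency. Monomorphic SNPs are
#' dropped; missing dosages are mean-imputed to `2p` before centring (so
#' they contribute zero to `Z`).
#'
#' @param M Dosage matrix, pigs x SNPs, values in \{0, 1, 2\} or `NA`.
#' @param freqs Optional per-SNP allele frequencies; computed from the
#'   observed dosages when omitted.
#' @param ridge Small value added to the diagonal so the matrix stays
#'   numerically invertible for REML (default `1e-6`); a numerical, not
#'   statistical, device.
#' @return A symmetric pigs x pigs matrix with the input row names.
#' @export
vanraden_g <- function(M, freqs = NULL, ridge = 1e-6) {
  if (is.null(freqs)) freqs <- colMeans(M, na.rm = TRUE) / 2
  keep <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(keep)) stop("all SNPs are monomorphic")
  M <- M[, keep, drop = FALSE]
  freqs <- freqs[keep]
  Z <- sweep(M, 2, 2 * freqs)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (2 * sum(freqs * (1 - freqs)))
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  G
}

#' Combine per-company GRMs block-diagonally
#'
#' Assembles per-company genomic relationship matrices into one matrix over
#' all pigs, with relationships between pigs of different companies set to
#' exactly zero, so REML on the combined matrix pools within-company genetic
#' variance.
#'
#' @param blocks Named list of per-company matrices (names = company ids,
#'   dimnames = pig ids).
#' @param company Named character vector mapping pig id to company id, in
#'   the desired pig order.
#' @return A `grm_set`: list with `combined` (block-diagonal matrix in pig
#'   order), `blocks`, and `company`.
#' @export
block_combine <- function(blocks, company) {
  pigs <- names(company)
  covered <- unlist(lapply(blocks, rownames), use.names = FALSE)
  if (anyDuplicated(covered)) stop("a pig appears in more than one block")
  if (!setequal(covered, pigs)) {
    stop("blocks must cover every pig exactly once")
  }
  G <- matrix(0, length(pigs), length(pigs), dimnames = list(pigs, pigs))
  for (cc in names(blocks)) {
    ids <- rownames(blocks[[cc]])
    G[ids, ids] <- blocks[[cc]]
  }
  structure(list(combined = G, blocks = blocks, company = company),
            class = "grm_set")
}

#' Per-company VanRaden GRMs with block-diagonal combination
#'
#' Builds one method-1 GRM per company, using allele frequencies observed
#' within that company, then combines them with [block_combine()].
#'
#' @param geno A `genotype_matrix` (see [simulate_genotypes()]) or a dosage
#'   matrix with a `company` argument.
#' @param company Per-pig company labels (taken from `geno` if absent).
#' @param ridge Diagonal ridge per block, see [vanraden_g()].
#' @return A `grm_set` (see [block_combine()]) with per-company allele
#'   frequencies attached as `freqs`.
#' @export
company_grm <- function(geno, company = NULL, ridge = 1e-6) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  if (is.null(company)) company <- geno$company
  company <- setNames(as.character(company), rownames(M))
  blocks <- list(); freqs <- list()
  for (cc in unique(company)) {
    ids <- names(company)[company == cc]
    f <- colMeans(M[ids, , drop = FALSE], na.rm = TRUE) / 2
    blocks[[cc]] <- vanraden_g(M[ids, , drop = FALSE], ridge = ridge)
    freqs[[cc]] <- f
  }
  out <- block_combine(blocks, company)
  out$freqs <- freqs
  out
}

#' @export
print.grm_set <- function(x, ...) {
  cat(sprintf("grm_set: %d pigs, %d company block(s): %s\n",
              nrow(x$combined), length(x$blocks),
              paste(names(x$blocks), collapse = ", ")))
  invisible(x)
}

#' Write a GRM in GCTA binary layout
#'
#' Writes `<prefix>.grm.bin` (lower triangle including the diagonal,
#' row-major, 4-byte floats), `<prefix>.grm.N.bin` (number of SNPs used, as
#' floats), and `<prefix>.grm.id` (family and within-family id columns).
#'
#' @param G Symmetric relationship matrix with pig ids as dimnames.
#' @param prefix Output path prefix.
#' @param n_snps Number of SNPs the matrix was built from.
#' @return `prefix`, invisibly.
#' @export
write_grm_bin <- function(G, prefix, n_snps = NA_integer_) {
  ids <- rownames(G)
  n <- nrow(G)
  lower <- G[upper.tri(G, diag = TRUE)]   # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L); close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(lower)), con, size = 4L); close(con)
  write.table(data.frame(fid = ids, iid = ids),
              paste0(prefix, ".grm.id"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM written by [write_grm_bin()]
#'
#' @param prefix Path prefix used when writing.
#' @return A symmetric matrix with pig ids as dimnames.
#' @export
read_grm_bin <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), sep = "\t",
                    colClasses = "character")[[2]]
  n <- length(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, numeric(), n = m, size = 4L); close(con)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[upper.tri(G, diag = TRUE)] <- vals
  G[lower.tri(G)] <- t(G)[lower.tri(G)]
  G
}
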