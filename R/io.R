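# External-interface writers. PLINK bed/bim/fam is written with the
# standard SNP-major 2-bit codec (no installed package covers PLINK
# binary); VCF export goes through vcfR when available.

#' Write genotypes as PLINK bed/bim/fam
#'
#' SNP-major bed with the usual magic bytes; dosages count the A1 allele
#' (2 -> homozygous A1). Alleles are labelled A (counted) and B.
#'
#' @param geno A `genotype_matrix` or dosage matrix with dimnames.
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  map <- if (inherits(geno, "genotype_matrix")) geno$map else
    tibble::tibble(id = colnames(M), chr = 1L, pos = seq_len(ncol(M)))
  n <- nrow(M); p <- ncol(M)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # PLINK 2-bit codes, NA -> 1
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nbytes <- ceiling(n / 4)
  for (j in seq_len(p)) {
    g <- M[, j]
    two <- ifelse(is.na(g), 1L, code[as.character(g)])
    length(two) <- nbytes * 4L
    two[is.na(two)] <- 0L
    m <- matrix(two, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  write.table(data.frame(chr = map$chr, id = map$id, cm = 0, pos = map$pos,
                         a1 = "A", a2 = "B"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(fid = rownames(M), iid = rownames(M),
                         pat = 0, mat = 0, sex = 0, phe = -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from PLINK bed/bim/fam
#'
#' @param prefix Path prefix written by [write_plink()] (or any SNP-major
#'   PLINK 1 fileset).
#' @return A dosage matrix (pigs x SNPs, A1 counted) with a `map` attribute.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t",
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), sep = "\t",
                    colClasses = "character")
  n <- nrow(fam); p <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file")
  }
  nbytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", nbytes * p)
  ints <- as.integer(raw)
  two <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
               (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  decode <- c(2L, NA, 1L, 0L)  # 00,01,10,11 -> dosage of A1
  M <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    chunk <- two[, ((j - 1) * nbytes + 1):(j * nbytes)]
    M[, j] <- decode[chunk[seq_len(n)] + 1L]
  }
  dimnames(M) <- list(fam[[2]], bim$id)
  attr(M, "map") <- tibble::tibble(snp = seq_len(p), id = bim$id,
                                   chr = bim$chr, pos = bim$pos)
  M
}

#' Write genotypes as VCF (via vcfR)
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file; vcfR writes gzipped VCF, so use a `.vcf.gz`
#'   name.
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF export requires the vcfR package")
  }
  M <- geno$dosage
  map <- geno$map
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- cbind(FORMAT = "GT",
              t(matrix(gtcode[as.character(M)], nrow = nrow(M),
                       dimnames = dimnames(M))))
  fix <- cbind(CHROM = as.character(map$chr), POS = as.character(map$pos),
               ID = map$id, REF = "A", ALT = "B", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Write a phenotype/design table as TSV
#'
#' Columns follow the package data dictionary
#' (`system.file("extdata", "data_dictionary.tsv", package = "hairqtl")`).
#'
#' @param phenotypes Tibble of phenotypes and design covariates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' Export a simulated study to plain-text files
#'
#' Writes genotypes as PLINK bed/bim/fam, phenotypes and design as a TSV
#' (see the data dictionary), and the simulation truths (effect vectors,
#' realized variance fractions, planted-QTL records) as a JSON sidecar.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write a VCF (`genotypes.vcf.gz`, requires vcfR)?
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, vcf = FALSE) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(study$genotypes, file.path(dir, "genotypes"))
  if (vcf) write_geno_vcf(study$genotypes, file.path(dir, "genotypes.vcf.gz"))
  write_phenotypes(study$phenotypes, file.path(dir, "phenotypes.tsv"))
  tr <- study$truths
  sidecar <- list(
    realized = tr$realized,
    qtl = study$genotypes$qtl,
    qtl_effect_scale = tr$qtl_effect_scale,
    g1 = unname(tr$g1), g2 = unname(tr$g2),
    litter_eff = as.list(tr$litter_eff), pen_eff = as.list(tr$pen_eff),
    batch_eff = as.list(tr$batch_eff),
    poly_snps = tr$poly_snps, seed = study$params$seed
  )
  jsonlite::write_json(sidecar, file.path(dir, "truths.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
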