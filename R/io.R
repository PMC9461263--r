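#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' Variant-major .bed with the standard 2-bit encoding (00 = homozygous
#' allele1, 10 = heterozygous, 11 = homozygous allele2, 01 = missing); the
#' .bim preserves allele order (allele1 = A1, the counted allele) and the
#' .fam carries sample ids with unknown sex/phenotype.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$id, cm = 0,
                    bp = g$variants$bp, a1 = g$variants$allele1,
                    a2 = g$variants$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$samples$id, iid = g$samples$id, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$dosage)
  # dosage (count of allele1) -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(3L, n, ncol(g$dosage))
  code[g$dosage == 1] <- 2L
  code[g$dosage == 2] <- 0L
  code[is.na(g$dosage)] <- 1L
  n_bytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * n_bytes - n
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(code))) {
    v <- c(code[, j], rep(0L, pad))
    bytes <- colSums(matrix(v * rep(mult, n_bytes), nrow = 4))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype matrix
#'
#' @param prefix path prefix of a variant-major PLINK 1 fileset.
#' @return A [geno_matrix()] with dosage counting the .bim A1 allele.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "bp",
                                         "allele1", "allele2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a variant-major PLINK .bed file")
  }
  n_bytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", n_bytes * m)
  ints <- as.integer(raw)
  # unpack 4 two-bit codes per byte, variant-major
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * n_bytes, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  d <- matrix(lut[codes + 1L], n, m)
  geno_matrix(d,
              tibble(id = bim$id, chrom = bim$chrom, bp = bim$bp,
                     allele1 = bim$allele1, allele2 = bim$allele2),
              tibble(id = fam$V2))
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Minimal VCFv4.2 with GT genotypes.  REF is `allele2` and ALT is
#' `allele1`, so the stored dosage (count of allele1) equals the ALT
#' allele count in the genotype strings.
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=giabank",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples$id), collapse = "\t"))
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- vapply(seq_len(ncol(g$dosage)), function(j) {
    d <- g$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt[as.character(d)])
    paste(c(g$variants$chrom[j], g$variants$bp[j], g$variants$id[j],
            g$variants$allele2[j], g$variants$allele1[j], ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses the vcfR parser; genotypes are converted to counts of the ALT
#' allele (stored as `allele1`).
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|."), NA_real_,
           stringr::str_count(s, "1"))
  }
  d_vm <- matrix(alt_count(gt), nrow(gt), ncol(gt))   # variants x samples
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- tibble(id = fix$ID, chrom = as.integer(fix$CHROM),
                     bp = as.integer(fix$POS),
                     allele1 = fix$ALT, allele2 = fix$REF)
  geno_matrix(t(d_vm), variants, tibble(id = colnames(gt)))
}
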