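#' Write genotype dosages as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT fields only. The dosage counts the panel's
#' effect allele `a1`, which is written as ALT (REF = `a2`), so dosage equals
#' the number of ALT alleles in GT.
#'
#' @param genotypes n x m dosage matrix in `{0,1,2}` (rows subjects).
#' @param variants data.table with `snp_id, chrom, pos, a1, a2`.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(nrow(variants) == ncol(genotypes))
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gt <- matrix(gt_codes[t(genotypes) + 1L], nrow = ncol(genotypes))
  lines <- paste(variants$chrom, variants$pos, variants$snp_id, variants$a2,
                 variants$a1, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses vcfR to parse the file; dosage counts ALT alleles, and the returned
#' variant table sets `a1 = ALT` (the scored/effect allele), `a2 = REF`,
#' matching [write_vcf()].
#'
#' @param path VCF file (plain or gzipped).
#' @return list with `genotypes` (integer dosage matrix, NA for missing) and
#'   `variants`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  counts <- vapply(c("0/0", "0|0", "0/1", "0|1", "1/0", "1|0", "1/1", "1|1"),
                   identity, "")
  alt_count <- c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L)
  for (i in seq_along(counts)) dos[t(gt) == counts[i]] <- alt_count[i]
  fix <- as.data.table(vcfR::getFIX(v))
  variants <- data.table(snp_id = fix$ID, chrom = as.integer(fix$CHROM),
                         pos = as.integer(fix$POS),
                         a1 = fix$ALT, a2 = fix$REF)
  list(genotypes = dos, variants = variants)
}

# PLINK 2-bit codes (SNP-major bed): 00 = hom a1 (dosage 2), 10 = het,
# 11 = hom a2 (dosage 0), 01 = missing.
.plink_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' SNP-major binary bed with the standard magic bytes; `a1` in the bim file
#' is the counted (effect) allele.
#'
#' @inheritParams write_vcf
#' @param prefix path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @export
write_plink <- function(genotypes, variants, prefix) {
  n <- nrow(genotypes)
  fam <- data.table(fid = rownames(genotypes), iid = rownames(genotypes),
                    pat = 0L, mat = 0L, sex = 0L, phe = -9L)
  fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim <- data.table(chrom = variants$chrom, snp_id = variants$snp_id, cm = 0,
                    pos = variants$pos, a1 = variants$a1, a2 = variants$a2)
  fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(ncol(genotypes))) {
    code <- .plink_code(genotypes[, j])
    length(code) <- bytes_per_snp * 4L          # pad with 0 (= hom a1)
    code[is.na(code)] <- 0L
    mat <- matrix(code, nrow = 4)
    byte <- mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' @param prefix path prefix of the fileset.
#' @return list with `genotypes` (dosage of bim `a1`, NA for missing) and
#'   `variants`.
#' @export
read_plink <- function(prefix) {
  fam <- fread(paste0(prefix, ".fam"), header = FALSE)
  bim <- fread(paste0(prefix, ".bim"), header = FALSE,
               col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  .assert(identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)),
          "not a SNP-major PLINK bed file")
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  .assert(length(raw) == bytes_per_snp * m, "truncated bed file")
  b <- as.integer(raw)
  # unpack 2-bit codes, lowest bits first
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dosage_of <- c(2L, NA_integer_, 1L, 0L)       # index = code + 1
  G <- matrix(NA_integer_, n, m,
              dimnames = list(fam$V2, bim$snp_id))
  for (j in seq_len(m)) {
    cj <- codes[, ((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    G[, j] <- dosage_of[as.vector(cj)[seq_len(n)] + 1L]
  }
  variants <- data.table(snp_id = bim$snp_id, chrom = bim$chrom,
                         pos = bim$pos, a1 = bim$a1, a2 = bim$a2)
  list(genotypes = G, variants = variants)
}

#' Write gene coordinates as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented on the way out.
#'
#' @param genes data.table `gene_id, chrom, start, end`.
#' @param path output file.
#' @export
write_gene_bed <- function(genes, path) {
  fwrite(data.table(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene coordinates from BED
#'
#' Converts BED's 0-based half-open intervals to the package's 1-based
#' inclusive convention at the boundary (`start + 1`, `end` unchanged).
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.table `gene_id, chrom, start, end`.
#' @export
read_gene_bed <- function(path) {
  b <- fread(path, header = FALSE)
  .assert(ncol(b) >= 4, "BED file needs chrom, start, end, name columns")
  g <- data.table(gene_id = as.character(b$V4), chrom = as.integer(b$V1),
                  start = as.integer(b$V2) + 1L, end = as.integer(b$V3))
  .assert(all(g$start <= g$end), "gene start > end after BED conversion")
  .assert(!anyDuplicated(g$gene_id), "duplicate gene_id in BED")
  g
}

#' Write gene sets as GMT
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#' @param path GMT file (set name, description, genes...).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else
    character(0))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write summary statistics with conventional column headers
#' @param ss internal summary-statistics table.
#' @param path output TSV.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.table(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    BETA = ss$beta, SE = ss$se, P = ss$pval)
  if (!is.null(ss$maf)) out$MAF <- ss$maf
  if (!is.null(ss$info)) out$INFO <- ss$info
  fwrite(out, path, sep = "\t")
  invisible(path)
}
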