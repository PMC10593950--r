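#' Map SNPs to genes by genomic interval
#'
#' A SNP maps to a gene iff they share a chromosome and the SNP position lies
#' in `[start - window_kb * 1000, end + window_kb * 1000]` (1-based inclusive
#' gene bodies, symmetric flanking window). A SNP may map to several genes.
#'
#' @param variants data.table `snp_id, chrom, pos`.
#' @param genes data.table `gene_id, chrom, start, end` (1-based inclusive).
#' @param window_kb symmetric flank in kilobases (>= 0).
#' @return data.table `snp_id, gene_id`, one row per (SNP, gene) pair.
#' @export
map_snps_to_genes <- function(variants, genes, window_kb = 0) {
  .assert(window_kb >= 0, "window_kb must be non-negative")
  .assert(all(genes$start <= genes$end), "gene with start > end")
  w <- as.integer(round(window_kb * 1000))
  gi <- data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                   start = genes$start - w, end = genes$end + w)
  vi <- data.table(snp_id = variants$snp_id, chrom = variants$chrom,
                   start = variants$pos, end = variants$pos)
  setkey(gi, chrom, start, end)
  hits <- foverlaps(vi, gi, type = "within", nomatch = NULL)
  hits[, .(snp_id, gene_id)]
}

#' Partition the SNP universe by gene set
#'
#' For each named gene set, splits the post-QC harmonized SNP universe into
#' the SNPs mapping to at least one of the set's genes and the complement
#' ("whole genome minus set"). Sets may overlap; each gets its own
#' independent partition.
#'
#' @param snp_gene_map data.table `snp_id, gene_id` from
#'   [map_snps_to_genes()].
#' @param sets named list of gene-id vectors.
#' @param universe character vector of harmonized SNP ids.
#' @return named list; per set a list with `in_set` and `complement`
#'   (character vectors, disjoint, union = universe).
#' @export
partition_by_geneset <- function(snp_gene_map, sets, universe) {
  known_genes <- unique(snp_gene_map$gene_id)
  out <- lapply(names(sets), function(nm) {
    gs <- sets[[nm]]
    if (length(gs) && !any(gs %in% known_genes))
      warning(sprintf("gene set '%s' references no known gene", nm))
    snps <- unique(snp_gene_map$snp_id[snp_gene_map$gene_id %in% gs])
    in_set <- intersect(universe, snps)
    list(in_set = in_set, complement = setdiff(universe, in_set))
  })
  names(out) <- names(sets)
  out
}
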