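#' Mean brain association pattern of one SNP cluster
#'
#' Arithmetic mean, per ROI, of the normalized association rows of the
#' cluster's member SNPs — the cluster's averaged effect pattern across
#' the brain, suitable for atlas rendering or upload to annotation
#' services.
#'
#' @param map a row-normalized `association_map`.
#' @param assignment named cluster labels over the map's SNPs.
#' @param cluster_index cluster to summarize (1-based).
#' @return Named numeric vector, one nonnegative value per ROI.
#' @export
mean_brain_pattern <- function(map, assignment, cluster_index) {
  members <- names(assignment)[assignment == cluster_index]
  if (length(members) == 0) stop("cluster ", cluster_index, " is empty")
  colMeans(map[members, , drop = FALSE])
}

#' Per-cluster gene lists from a SNP-to-gene map
#'
#' Maps each cluster's SNPs through the annotation table (each SNP to its
#' closest gene) and returns deduplicated, lexicographically sorted gene
#' symbols per cluster, ready to paste into a gene-set enrichment tool.
#' SNPs absent from the map are reported separately, never silently
#' dropped.
#'
#' @param assignment named cluster labels.
#' @param snp_gene_map named character vector from [read_snp_gene_map()].
#' @return List with `genes` (list of character vectors per cluster) and
#'   `unmapped` (list of SNP ids per cluster).
#' @export
cluster_gene_list <- function(assignment, snp_gene_map) {
  K <- max(assignment)
  genes <- vector("list", K)
  unmapped <- vector("list", K)
  for (k in seq_len(K)) {
    members <- names(assignment)[assignment == k]
    hit <- members %in% names(snp_gene_map)
    genes[[k]] <- sort(unique(unname(snp_gene_map[members[hit]])))
    unmapped[[k]] <- members[!hit]
  }
  list(genes = genes, unmapped = unmapped)
}

#' Export per-cluster annotations
#'
#' Writes, for each cluster, a plain-text gene list (one symbol per line,
#' paste-ready for enrichment tools) and a mean-pattern CSV
#' (`roi_id,mean_value`), plus a single report of unmapped SNPs.
#'
#' @param map a row-normalized `association_map`.
#' @param assignment named cluster labels.
#' @param snp_gene_map named character vector (may be empty).
#' @param dir output directory.
#' @return Invisibly, the character vector of files written.
#' @export
export_annotations <- function(map, assignment, snp_gene_map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- max(assignment)
  gl <- cluster_gene_list(assignment, snp_gene_map)
  files <- character(0)
  for (k in seq_len(K)) {
    gf <- file.path(dir, sprintf("cluster%d_genes.txt", k))
    writeLines(gl$genes[[k]], gf)
    pat <- mean_brain_pattern(map, assignment, k)
    pf <- file.path(dir, sprintf("cluster%d_pattern.csv", k))
    utils::write.csv(data.frame(roi_id = names(pat),
                                mean_value = sprintf("%.17g", pat)),
                     pf, row.names = FALSE, quote = FALSE)
    files <- c(files, gf, pf)
  }
  uf <- file.path(dir, "unmapped_snps.txt")
  writeLines(unlist(lapply(seq_len(K), function(k) {
    sprintf("cluster%d\t%s", k, gl$unmapped[[k]])
  })), uf)
  invisible(c(files, uf))
}
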