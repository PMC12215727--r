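## Expression consequences of copy-number variants.
##
## For each CNV the carrier's mean expression z-score over the covered
## (expressed) genes is compared against every other sample's mean over the
## same genes; dosage-responsive outlier genes are counted in the direction
## matching the copy-number change. Per-gene z and fold change are kept:
## real CNVs do not affect covered genes uniformly.

#' Expressed genes overlapping a CNV interval
#'
#' Strand-agnostic 1-bp-minimum overlap between gene [start, end] intervals
#' and the CNV interval, restricted to genes present in `expressed_genes`
#' (the post-filter gene set of the expression stage).
#'
#' @param chrom,start_bp,end_bp CNV interval, 1-based inclusive.
#' @param annotation Gene annotation.
#' @param expressed_genes Character vector of gene ids that survived
#'   expression filtering.
#' @return Character vector of covered gene ids (possibly empty).
#' @export
genes_in_cnv <- function(chrom, start_bp, end_bp, annotation,
                         expressed_genes) {
  ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (!nrow(ann)) return(character(0))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = start_bp, end = end_bp),
    IRanges::IRanges(start = ann$start_bp, end = ann$end_bp),
    minoverlap = 1L)
  covered <- ann$gene_id[S4Vectors::subjectHits(hits)]
  intersect(covered, expressed_genes)
}

#' Dosage summary for one CNV
#'
#' Computes, over the covered genes with complete z-scores in all samples
#' (complete-case; genes with any missing z are dropped for every sample),
#' each sample's mean z, the carrier's rank (ascending for deletions,
#' descending for duplications; rank 1 = most extreme in the dosage
#' direction), and the number of dosage-direction outlier genes in the
#' carrier (z <= -3 for deletions / z >= 3 for duplications, or adjusted
#' p < 0.05).
#'
#' @param cnv One-row data.frame (sample_id, chrom, start_bp, end_bp,
#'   copy_number).
#' @param fit An `expression_fit` for the same cohort.
#' @param annotation Gene annotation.
#' @param z_cutoff Outlier-gene threshold on |z|.
#' @return list of class `cnv_summary`: assessable, covered_gene_ids,
#'   mean_z (named per sample), carrier_rank, n_outlier_genes, carrier_genes
#'   (per-gene z and fold change in the carrier).
#' @export
cnv_dosage_summary <- function(cnv, fit, annotation, z_cutoff = 3) {
  stopifnot(inherits(fit, "expression_fit"))
  if (cnv$copy_number == 2) stopf("copy number 2 is not a CNV")
  z <- fit$z
  covered <- genes_in_cnv(cnv$chrom, cnv$start_bp, cnv$end_bp, annotation,
                          rownames(z))
  base <- list(cnv = cnv, covered_gene_ids = covered)
  if (!length(covered)) {
    return(structure(c(base, list(assessable = FALSE)),
                     class = "cnv_summary"))
  }
  zz <- z[covered, , drop = FALSE]
  complete <- rowSums(is.na(zz)) == 0
  dropped <- covered[!complete]
  zz <- zz[complete, , drop = FALSE]
  if (!nrow(zz)) {
    return(structure(c(base, list(assessable = FALSE,
                                  dropped_genes = dropped)),
                     class = "cnv_summary"))
  }
  mean_z <- colMeans(zz)
  is_del <- cnv$copy_number < 2
  if (!cnv$sample_id %in% names(mean_z)) {
    ## carrier was excluded by sample QC (or never analyzed): the CNV
    ## cannot be assessed against the cohort
    return(structure(c(base, list(assessable = FALSE,
                                  dropped_genes = dropped,
                                  reason = "carrier not analyzed")),
                     class = "cnv_summary"))
  }
  ranks <- if (is_del) rank(mean_z, ties.method = "min") else
    rank(-mean_z, ties.method = "min")
  carrier_z <- zz[, cnv$sample_id]

  calls <- fit$calls
  carrier_calls <- calls[calls$sample_id == cnv$sample_id &
                           calls$gene_id %in% rownames(zz), ]
  carrier_calls <- carrier_calls[match(rownames(zz), carrier_calls$gene_id), ]
  dir_out <- if (is_del) carrier_z <= -z_cutoff else carrier_z >= z_cutoff
  n_outlier <- sum(dir_out | carrier_calls$adjusted_p < fit$padj_cutoff,
                   na.rm = TRUE)
  structure(c(base, list(
    assessable = TRUE,
    dropped_genes = dropped,
    mean_z = mean_z,
    carrier_rank = unname(ranks[cnv$sample_id]),
    n_outlier_genes = n_outlier,
    carrier_genes = data.frame(gene_id = rownames(zz), z_score = carrier_z,
                               fold_change = carrier_calls$fold_change,
                               row.names = NULL, stringsAsFactors = FALSE))),
    class = "cnv_summary")
}

#' Run the CNV dosage stage over a CNV call set
#' @param cnv_set CNV table (internal coordinates).
#' @param fit An `expression_fit` for the same cohort.
#' @param annotation Gene annotation.
#' @param z_cutoff Outlier-gene threshold.
#' @return An object of class `cnv_dosage`: list of `cnv_summary` plus a
#'   flat summary table.
#' @export
run_cnv_stage <- function(cnv_set, fit, annotation, z_cutoff = 3) {
  summaries <- lapply(seq_len(nrow(cnv_set)), function(i)
    cnv_dosage_summary(cnv_set[i, ], fit, annotation, z_cutoff = z_cutoff))
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample_id = s$cnv$sample_id, chrom = s$cnv$chrom,
               start_bp = s$cnv$start_bp, end_bp = s$cnv$end_bp,
               copy_number = s$cnv$copy_number,
               n_covered_genes = length(s$covered_gene_ids),
               assessable = s$assessable,
               carrier_mean_z = if (s$assessable)
                 unname(s$mean_z[s$cnv$sample_id]) else NA_real_,
               carrier_rank = if (s$assessable) s$carrier_rank else NA_integer_,
               n_outlier_genes = if (s$assessable) s$n_outlier_genes else
                 NA_integer_, stringsAsFactors = FALSE)
  }))
  structure(list(summaries = summaries, table = tab), class = "cnv_dosage")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat(sprintf("CNV %s:%d-%d x%d in %s\n", x$cnv$chrom, x$cnv$start_bp,
              x$cnv$end_bp, x$cnv$copy_number, x$cnv$sample_id))
  if (!x$assessable) {
    cat("  not assessable (no covered expressed genes)\n")
    return(invisible(x))
  }
  cat(sprintf("  covered expressed genes: %d; carrier mean z: %.2f (rank %d of %d)\n",
              nrow(x$carrier_genes), x$mean_z[x$cnv$sample_id],
              x$carrier_rank, length(x$mean_z)))
  cat(sprintf("  dosage-direction outlier genes: %d\n", x$n_outlier_genes))
  invisible(x)
}

#' @export
print.cnv_dosage <- function(x, ...) {
  cat(sprintf("CNV dosage stage: %d CNV(s), %d assessable\n",
              nrow(x$table), sum(x$table$assessable)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
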