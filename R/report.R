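## Phenotype-driven candidate prioritization.
##
## Flagged calls from the three modalities are merged per gene for one
## sample and ranked: tier 1 genes share an HPO term with the participant,
## tier 2 have any disease association, tier 3 have none. Within tier the
## sort key is (minimum adjusted p ascending, maximum |z| descending,
## gene id ascending) - a fixed, documented tiebreak chain so the report is
## a pure function of its inputs.

#' Assign a phenotype tier to a gene
#'
#' Tier 1: the gene's HPO term set intersects the sample's terms
#' (exact-term matching, no ontology propagation); tier 2: no intersection
#' but the gene has a disease association; tier 3: neither.
#' @param gene_hpo Character vector of the gene's HPO terms.
#' @param disease_associated Logical; any known disease association.
#' @param sample_hpo Character vector of the participant's HPO terms.
#' @return Integer tier (1, 2 or 3).
#' @export
assign_tier <- function(gene_hpo, disease_associated, sample_hpo) {
  if (length(intersect(gene_hpo, sample_hpo))) return(1L)
  if (isTRUE(disease_associated)) return(2L)
  3L
}

## collect per-modality evidence rows (one data.frame with unified columns)
gather_evidence <- function(sample_id, expression_fit, splice_screen,
                            ase_screen, cnv_dosage) {
  ev <- list()
  if (!is.null(expression_fit)) {
    calls <- expression_fit$calls
    sel <- calls[calls$sample_id == sample_id & calls$is_outlier, ]
    if (nrow(sel))
      ev$expression <- data.frame(gene_id = sel$gene_id,
                                  modality = "expression",
                                  feature = sel$gene_id,
                                  statistic = sel$fold_change,
                                  z = sel$z_score, padj = sel$adjusted_p,
                                  event_class = NA_character_,
                                  stringsAsFactors = FALSE)
  }
  if (!is.null(splice_screen) && nrow(splice_screen$calls)) {
    calls <- splice_screen$calls
    sel <- calls[calls$sample_id == sample_id & calls$is_outlier &
                   !is.na(calls$gene_id), ]
    if (nrow(sel))
      ev$splicing <- data.frame(gene_id = sel$gene_id, modality = "splicing",
                                feature = sel$junction,
                                statistic = sel$coverage_score,
                                z = sel$z_score, padj = NA_real_,
                                event_class = sel$event_class,
                                stringsAsFactors = FALSE)
  }
  if (!is.null(ase_screen) && nrow(ase_screen$calls)) {
    calls <- ase_screen$calls
    sel <- calls[calls$sample_id == sample_id & calls$is_flagged &
                   !is.na(calls$gene_id), ]
    if (nrow(sel))
      ev$ase <- data.frame(gene_id = sel$gene_id, modality = "ase",
                           feature = sprintf("%s:%d:%s>%s", sel$chrom,
                                             sel$pos, sel$ref, sel$alt),
                           statistic = sel$alt_ratio, z = NA_real_,
                           padj = sel$adjusted_p,
                           event_class = NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(cnv_dosage)) {
    for (s in cnv_dosage$summaries) {
      if (!identical(s$cnv$sample_id, sample_id) || !s$assessable) next
      is_del <- s$cnv$copy_number < 2
      g <- s$carrier_genes
      out <- if (is_del) g$z_score <= -3 else g$z_score >= 3
      g <- g[out & !is.na(out), , drop = FALSE]
      if (nrow(g))
        ev[[paste0("cnv_", s$cnv$chrom, s$cnv$start_bp)]] <-
          data.frame(gene_id = g$gene_id, modality = "cnv",
                     feature = sprintf("%s:%d-%d:x%d", s$cnv$chrom,
                                       s$cnv$start_bp, s$cnv$end_bp,
                                       s$cnv$copy_number),
                     statistic = g$fold_change, z = g$z_score,
                     padj = NA_real_, event_class = NA_character_,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) return(NULL)
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Assemble the per-sample candidate report
#'
#' Merges flagged calls from all modalities for one sample, groups evidence
#' per gene (a gene flagged by several modalities yields one record with
#' several evidence rows), assigns phenotype tiers, and orders records by
#' (tier, min adjusted p, max |z| descending, gene id).
#'
#' @param sample_id Sample to report on.
#' @param expression_fit,splice_screen,ase_screen,cnv_dosage Stage outputs
#'   (any may be NULL); all must come from the same cohort.
#' @param annotation Gene annotation with hpo_terms and disease_associated.
#' @param metadata Sample metadata with hpo_terms.
#' @return An object of class `candidate_report`: data.frame `candidates`
#'   (one row per gene) plus `evidence` (one row per flagged call).
#' @export
assemble_report <- function(sample_id, expression_fit = NULL,
                            splice_screen = NULL, ase_screen = NULL,
                            cnv_dosage = NULL, annotation, metadata) {
  check_same_cohort(expression_fit, splice_screen, ase_screen)
  if (!sample_id %in% metadata$sample_id)
    stopf("sample '%s' not in metadata", sample_id)
  sample_hpo <- metadata$hpo_terms[[match(sample_id, metadata$sample_id)]]

  ev <- gather_evidence(sample_id, expression_fit, splice_screen, ase_screen,
                        cnv_dosage)
  if (is.null(ev)) {
    return(structure(list(sample_id = sample_id,
                          candidates = data.frame(), evidence = data.frame()),
                     class = "candidate_report"))
  }
  genes <- unique(ev$gene_id)
  ann_idx <- match(genes, annotation$gene_id)
  cand <- data.frame(sample_id = sample_id, gene_id = genes,
                     stringsAsFactors = FALSE)
  cand$tier <- vapply(seq_along(genes), function(i) {
    if (is.na(ann_idx[i])) return(3L)
    assign_tier(annotation$hpo_terms[[ann_idx[i]]],
                annotation$disease_associated[ann_idx[i]], sample_hpo)
  }, integer(1))
  cand$n_modalities <- vapply(genes, function(g)
    length(unique(ev$modality[ev$gene_id == g])), integer(1))
  cand$min_padj <- vapply(genes, function(g) {
    v <- ev$padj[ev$gene_id == g]
    if (all(is.na(v))) Inf else min(v, na.rm = TRUE)
  }, numeric(1))
  cand$max_abs_z <- vapply(genes, function(g) {
    v <- abs(ev$z[ev$gene_id == g])
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  }, numeric(1))
  ord <- order(cand$tier, cand$min_padj, -cand$max_abs_z, cand$gene_id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- stats::ave(seq_len(nrow(cand)), cand$tier, FUN = seq_along)
  rownames(cand) <- NULL
  structure(list(sample_id = sample_id, candidates = cand,
                 evidence = data.frame(sample_id = sample_id, ev,
                                       stringsAsFactors = FALSE)),
            class = "candidate_report")
}

## modality outputs must describe the same cohort; the splicing screen's
## score columns carry the full sample universe, the expression stage may
## only drop QC-failed samples and the ASE stage samples without rare sites
check_same_cohort <- function(expression_fit, splice_screen, ase_screen) {
  ref <- if (!is.null(splice_screen) && !is.null(splice_screen$scores))
    colnames(splice_screen$scores) else NULL
  if (is.null(ref)) return(invisible(TRUE))
  if (!is.null(expression_fit)) {
    extra <- setdiff(unique(expression_fit$calls$sample_id), ref)
    if (length(extra))
      stopf("expression and splicing stages come from different cohorts (e.g. sample '%s')",
            extra[1])
  }
  if (!is.null(ase_screen) && nrow(ase_screen$calls)) {
    extra <- setdiff(unique(ase_screen$calls$sample_id), ref)
    if (length(extra))
      stopf("ASE and splicing stages come from different cohorts (e.g. sample '%s')",
            extra[1])
  }
  invisible(TRUE)
}

#' @export
print.candidate_report <- function(x, n = 15, ...) {
  cat(sprintf("Candidate report for %s\n", x$sample_id))
  if (!nrow(x$candidates)) {
    cat("  no flagged candidates\n")
    return(invisible(x))
  }
  cat(sprintf("  %d candidate gene(s); %d tier-1 (HPO-matched)\n",
              nrow(x$candidates), sum(x$candidates$tier == 1)))
  print(utils::head(x$candidates, n), row.names = FALSE)
  invisible(x)
}

#' Run every stage of the diagnostic pipeline on a cohort
#'
#' Convenience orchestrator: expression outliers, splicing screen, ASE
#' screen, CNV dosage summaries, then one candidate report per analyzed
#' sample. Deterministic given its inputs.
#'
#' @param cohort A list shaped like the output of [simulate_cohort()]:
#'   counts, junctions, ase, cnv, metadata, annotation.
#' @param n_confounders,stratify_by_sex Passed to the expression stage.
#' @param ... Further arguments to [run_expression_stage()].
#' @return An object of class `cohort_analysis`: stage objects plus
#'   `reports`, a named list of `candidate_report`s.
#' @export
run_cohort_analysis <- function(cohort, n_confounders = 5,
                                stratify_by_sex = FALSE, ...) {
  expr <- run_expression_stage(cohort$counts, cohort$annotation,
                               metadata = cohort$metadata,
                               n_confounders = n_confounders,
                               stratify_by_sex = stratify_by_sex, ...)
  spl <- run_splicing_stage(cohort$junctions, annotation = cohort$annotation)
  ase <- run_ase_stage(cohort$ase)
  cnv <- if (!is.null(cohort$cnv) && nrow(cohort$cnv))
    run_cnv_stage(cohort$cnv, expr, cohort$annotation) else NULL
  samples <- setdiff(colnames(cohort$counts), expr$excluded_samples)
  reports <- stats::setNames(lapply(samples, function(s)
    assemble_report(s, expr, spl, ase, cnv, cohort$annotation,
                    cohort$metadata)), samples)
  structure(list(expression = expr, splicing = spl, ase = ase, cnv = cnv,
                 reports = reports), class = "cohort_analysis")
}

#' Write every per-sample candidate report to one TSV
#' @param analysis A `cohort_analysis`.
#' @param path Output path.
#' @export
write_reports_tsv <- function(analysis, path) {
  rows <- do.call(rbind, lapply(analysis$reports, function(r) r$candidates))
  if (is.null(rows)) rows <- data.frame()
  write_outliers_tsv(rows, path)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis\n\n")
  print(x$expression); cat("\n")
  print(x$splicing); cat("\n")
  print(x$ase)
  if (!is.null(x$cnv)) { cat("\n"); print(x$cnv) }
  n_cand <- sum(vapply(x$reports, function(r) nrow(r$candidates), integer(1)))
  cat(sprintf("\n%d candidate records across %d sample reports\n",
              n_cand, length(x$reports)))
  invisible(x)
}
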