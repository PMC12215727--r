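## Cohort-based gene-expression outlier detection.
##
## The screen compares each sample's count for each gene against a cohort
## expectation: counts are normalized by median-of-ratios size factors,
## log-transformed, the dominant shared (confounder) structure is removed
## with a truncated PCA reconstruction, and each observed count is tested
## against a per-gene negative-binomial model around the reconstructed
## expectation. A gene in a sample is reported as an outlier when its
## BH-adjusted p-value is < 0.05 or its |z| >= 3 (disjunctive rule; both
## sub-criteria are recorded separately for audit).

#' The nine hemoglobin genes removed before outlier analysis
#'
#' Whole-blood libraries are dominated by hemoglobin transcripts whose
#' fraction varies strongly between samples; their genes are removed before
#' fitting.
#' @export
hemoglobin_genes <- function() HEMOGLOBIN_SYMBOLS

#' Filter genes for expression outlier analysis
#'
#' Applies the two pre-filters in order: (1) remove the nine hemoglobin
#' genes by symbol; (2) keep only genes whose 95th-percentile RPKM across
#' samples exceeds 1, where RPKM_gs = count_gs * 1e9 / (library_size_s *
#' exonic_length_g).
#'
#' @param counts Counts matrix (genes x samples).
#' @param annotation Gene annotation providing symbol and exonic_length_bp.
#' @param rpkm_cutoff Detectability cutoff on the 95th-percentile RPKM.
#' @return list(counts = filtered matrix, report = filter report with
#'   n_input_genes, removed_hemoglobin, removed_low_expression, n_retained).
#' @export
filter_genes <- function(counts, annotation, rpkm_cutoff = 1) {
  validate_counts(counts)
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  missing_len <- rownames(counts)[is.na(ann$exonic_length_bp)]
  if (length(missing_len))
    stopf("missing exonic length for gene(s): %s",
          paste(utils::head(missing_len, 5), collapse = ", "))
  is_hb <- ann$symbol %in% HEMOGLOBIN_SYMBOLS
  removed_hb <- rownames(counts)[is_hb]
  kept <- counts[!is_hb, , drop = FALSE]
  len <- ann$exonic_length_bp[!is_hb]
  lib <- colSums(counts)  # library size before gene removal
  rpkm <- sweep(kept * 1e9, 2, lib, "/") / len
  q95 <- apply(rpkm, 1, stats::quantile, probs = 0.95, names = FALSE)
  low <- q95 <= rpkm_cutoff
  removed_low <- rownames(kept)[low]
  out <- kept[!low, , drop = FALSE]
  report <- list(n_input_genes = nrow(counts),
                 removed_hemoglobin = removed_hb,
                 removed_low_expression = removed_low,
                 n_retained = nrow(out))
  list(counts = out, report = report)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with a
#' positive count in every sample) of the ratio of the sample's count to the
#' gene's geometric mean across samples; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Counts matrix with >= 2 samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stopf("size factors need >= 2 samples")
  lg <- log(counts)
  loggeo <- rowMeans(lg)
  use <- is.finite(loggeo)
  if (!any(use))
    stopf(paste("no gene has positive counts in every sample;",
                "add a pseudocount or filter samples"))
  sf <- apply(lg[use, , drop = FALSE], 2,
              function(x) exp(stats::median(x - loggeo[use])))
  sf <- sf / geomean(sf)
  sf
}

log_normalized <- function(counts, sf) {
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Flag degraded samples by PCA
#'
#' Computes principal components of the centered log-normalized counts and
#' flags samples whose Euclidean distance from the cohort centroid in the
#' leading-component space is an extreme outlier of the cohort's distance
#' distribution, by the leave-one-out standardization
#' (d_i - mean(d_-i)) / sd(d_-i) > threshold_sd. The PCA runs on the
#' gene-wise winsorized matrix (as in [fit_expected()]) so heavy-tailed
#' single-gene noise does not dominate the distance, and the leave-one-out
#' form keeps the criterion comparable across cohort sizes (a gross outlier
#' cannot mask itself by inflating the scale). Global library degradation
#' displaces a sample across thousands of genes and stands out; a genuine
#' biological outlier (even a large CNV carrier, displaced on a few dozen
#' genes) does not.
#'
#' @param counts Counts matrix.
#' @param n_components Number of leading components used.
#' @param threshold_sd Leave-one-out SD threshold on the centroid distance.
#'   The default 7 sits between the extreme of healthy cohorts in
#'   simulation (max around 5.7, including cohorts carrying large CNVs)
#'   and the signature of a degraded library (8 and above).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_sample_outliers <- function(counts, n_components = 5,
                                   threshold_sd = 7) {
  if (n_components >= ncol(counts))
    stopf("n_components (%d) must be < number of samples (%d)",
          n_components, ncol(counts))
  if (!is.finite(threshold_sd)) return(character(0))
  sf <- size_factors(counts)
  l <- log_normalized(counts, sf)
  centered <- winsorize_rows(l - rowMeans(l))
  pc <- stats::prcomp(t(centered), center = FALSE, rank. = n_components)
  d <- sqrt(rowSums(pc$x[, seq_len(n_components), drop = FALSE]^2))
  z <- vapply(seq_along(d), function(i) {
    s <- stats::sd(d[-i])
    if (!is.finite(s) || s == 0) return(0)
    (d[i] - mean(d[-i])) / s
  }, numeric(1))
  colnames(counts)[z > threshold_sd]
}

## cap each gene's centered log values at median +/- k robust SDs so that
## the aberrations being tested cannot contaminate the confounder fit
winsorize_rows <- function(m, k = 3) {
  med <- apply(m, 1, stats::median)
  s <- apply(m, 1, stats::mad)
  s0 <- s == 0 | !is.finite(s)
  if (any(s0)) s[s0] <- apply(m[s0, , drop = FALSE], 1, stats::sd)
  pmin(pmax(m, med - k * s), med + k * s)
}

#' Fit cohort expectations and per-gene NB dispersions
#'
#' Expected log-normalized counts are the per-gene mean plus the
#' reconstruction from the leading `n_confounders` principal components of
#' the centered log-count matrix. The components and the reconstruction are
#' computed on a gene-wise winsorized copy of the matrix (values capped at
#' 3 robust SDs), so single-sample aberrations - the signal being screened
#' for - do not get absorbed into their own expectation. Expected counts
#' invert the log transform and rescale by the size factor. Per-gene NB
#' dispersions are maximum-likelihood estimates around the expected counts
#' over the uncapped cells, bounded to [1e-8, 1e3]; genes where the
#' likelihood optimization fails fall back to method-of-moments with a
#' warning.
#'
#' @param counts Filtered counts matrix.
#' @param n_confounders Number of principal components removed as shared
#'   (technical/biological) structure. 0 reduces the expectation to the
#'   per-gene mean.
#' @param sf Size factors; computed from `counts` when omitted.
#' @param winsor_sd Winsorization width in robust SDs.
#' @return list(expected = expected-count matrix, expected_log = expected
#'   log2-normalized matrix, dispersion = named per-gene phi, sf, log_norm,
#'   resid_center, resid_scale).
#' @export
fit_expected <- function(counts, n_confounders = 5, sf = NULL,
                         winsor_sd = 3) {
  if (is.null(sf)) sf <- size_factors(counts)
  l <- log_normalized(counts, sf)
  m <- rowMeans(l)
  centered <- l - m
  cw <- winsorize_rows(centered, k = winsor_sd)
  if (n_confounders > 0) {
    k <- min(n_confounders, ncol(counts) - 1L, nrow(counts))
    sv <- svd(cw, nu = k, nv = k)
    recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    lhat <- m + recon
  } else {
    lhat <- matrix(m, nrow = nrow(l), ncol = ncol(l))
  }
  dimnames(lhat) <- dimnames(l)
  mu_norm <- pmax(2^lhat - 1, 1e-8)
  mu <- sweep(mu_norm, 2, sf, "*")

  ## z-score location/scale from winsorized residuals: the scale of the
  ## cohort's typical variation, not inflated by the outliers under test
  resid_w <- cw - (lhat - m)
  resid_center <- rowMeans(resid_w)
  resid_scale <- apply(resid_w, 1, stats::sd)

  uncapped <- centered == cw
  phi <- numeric(nrow(counts))
  names(phi) <- rownames(counts)
  n_fallback <- 0L
  for (g in seq_len(nrow(counts))) {
    use <- uncapped[g, ]
    x <- counts[g, use]
    mg <- mu[g, use]
    nll <- function(lp) -sum(stats::dnbinom(x, size = 1 / exp(lp), mu = mg,
                                            log = TRUE))
    fit <- tryCatch(stats::optimize(nll, interval = log(c(1e-8, 1e3))),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) {
      n_fallback <- n_fallback + 1L
      v <- mean((x - mg)^2 - mg)
      phi[g] <- min(max(v / mean(mg^2), 1e-8), 1e3)
    } else {
      phi[g] <- exp(fit$minimum)
    }
  }
  if (n_fallback > 0)
    warnf("dispersion MLE failed for %d gene(s); used method-of-moments",
          n_fallback)
  list(expected = mu, expected_log = lhat, dispersion = phi, sf = sf,
       log_norm = l, resid_center = resid_center, resid_scale = resid_scale)
}

#' Two-sided negative-binomial tail p-value
#'
#' Doubles the smaller of the lower and upper tail probabilities of the
#' observed count under NB(mu, phi), capped at 1. Both tails include the
#' observed count.
#' @param x Observed counts.
#' @param mu Expected counts.
#' @param phi Dispersions (size = 1/phi).
#' @return p-values in (0, 1].
#' @export
nb_tail_pvalue <- function(x, mu, phi) {
  size <- 1 / phi
  lower <- stats::pnbinom(x, size = size, mu = mu)
  upper <- stats::pnbinom(x - 1, size = size, mu = mu, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Test every gene x sample cell for expression outliers
#'
#' z-scores are computed on confounder-corrected log values (residual from
#' the reconstructed expectation, standardized per gene); fold change is
#' 2^(observed log - expected log); p-values are two-sided NB tail
#' probabilities, BH-adjusted across genes within each sample. Zero-variance
#' genes are skipped with a warning.
#'
#' @param counts Filtered counts matrix.
#' @param fit Output of [fit_expected()].
#' @param padj_cutoff,z_cutoff Outlier rule: adjusted p < padj_cutoff OR
#'   |z| >= z_cutoff.
#' @return list(calls = data.frame of per-cell calls, z = z matrix).
#' @export
test_outliers <- function(counts, fit, padj_cutoff = 0.05, z_cutoff = 3) {
  l <- fit$log_norm
  resid <- l - fit$expected_log
  rm_ <- fit$resid_center
  rs <- fit$resid_scale
  zero_sd <- rs == 0 | !is.finite(rs)
  if (any(zero_sd))
    warnf("skipping %d gene(s) with zero residual variance", sum(zero_sd))
  z <- (resid - rm_) / rs
  z[zero_sd, ] <- NA_real_

  p <- matrix(nb_tail_pvalue(counts, fit$expected,
                             rep(fit$dispersion, ncol(counts))),
              nrow = nrow(counts), dimnames = dimnames(counts))
  padj <- apply(p, 2, stats::p.adjust, method = "BH")
  fc <- 2^(l - fit$expected_log)

  keep <- !zero_sd
  gene_ids <- rownames(counts)[keep]
  n_g <- sum(keep); n_s <- ncol(counts)
  calls <- data.frame(
    sample_id = rep(colnames(counts), each = n_g),
    gene_id = rep(gene_ids, n_s),
    observed_count = as.vector(counts[keep, ]),
    expected_count = as.vector(fit$expected[keep, ]),
    log2_normalized_count = as.vector(l[keep, ]),
    z_score = as.vector(z[keep, ]),
    fold_change = as.vector(fc[keep, ]),
    p_value = as.vector(p[keep, ]),
    adjusted_p = as.vector(padj[keep, ]),
    stringsAsFactors = FALSE)
  calls$outlier_by_p <- calls$adjusted_p < padj_cutoff
  calls$outlier_by_z <- abs(calls$z_score) >= z_cutoff
  calls$is_outlier <- calls$outlier_by_p | calls$outlier_by_z
  list(calls = calls, z = z)
}

#' Run the gene-expression outlier stage
#'
#' Full pipeline: gene filters, PCA sample QC (flagged samples are excluded
#' from the analysis), size factors, confounder fit, NB outlier test. With
#' `stratify_by_sex = TRUE` the entire pipeline reruns inside each sex
#' stratum (each needs >= `min_stratum` samples), which controls for
#' X-chromosome dosage.
#'
#' @param counts Counts matrix.
#' @param annotation Gene annotation.
#' @param metadata Sample metadata (required when stratifying).
#' @param n_confounders Principal components removed; default 5.
#' @param stratify_by_sex Rerun the pipeline per sex stratum.
#' @param qc_components,qc_threshold_sd Sample-QC parameters
#'   (see [detect_sample_outliers()]).
#' @param padj_cutoff,z_cutoff Outlier rule thresholds.
#' @param min_stratum Minimum samples per stratum.
#' @return An object of class `expression_fit` with elements calls, z,
#'   expected, dispersion, size_factors, filter_report, excluded_samples.
#' @export
run_expression_stage <- function(counts, annotation, metadata = NULL,
                                 n_confounders = 5, stratify_by_sex = FALSE,
                                 qc_components = 5, qc_threshold_sd = 7,
                                 padj_cutoff = 0.05, z_cutoff = 3,
                                 min_stratum = 10) {
  if (stratify_by_sex) {
    if (is.null(metadata)) stopf("stratified analysis requires metadata")
    sexes <- unique(metadata$sex[metadata$sample_id %in% colnames(counts)])
    fits <- list()
    for (sx in sexes) {
      ids <- metadata$sample_id[metadata$sex == sx]
      ids <- intersect(colnames(counts), ids)
      if (length(ids) < min_stratum)
        stopf("sex stratum '%s' has %d samples; need >= %d for stable z-scores",
              sx, length(ids), min_stratum)
      fit <- run_expression_stage(counts[, ids, drop = FALSE], annotation,
                                  metadata = NULL,
                                  n_confounders = n_confounders,
                                  stratify_by_sex = FALSE,
                                  qc_components = qc_components,
                                  qc_threshold_sd = qc_threshold_sd,
                                  padj_cutoff = padj_cutoff,
                                  z_cutoff = z_cutoff)
      fit$calls$stratum <- sx
      fits[[sx]] <- fit
    }
    out <- fits[[1]]
    out$calls <- do.call(rbind, lapply(fits, `[[`, "calls"))
    rownames(out$calls) <- NULL
    out$strata <- fits
    out$stratified <- TRUE
    class(out) <- "expression_fit"
    return(out)
  }

  fl <- filter_genes(counts, annotation)
  excluded <- detect_sample_outliers(fl$counts, n_components = qc_components,
                                     threshold_sd = qc_threshold_sd)
  use <- setdiff(colnames(fl$counts), excluded)
  cts <- fl$counts[, use, drop = FALSE]
  sf <- size_factors(cts)
  fit <- fit_expected(cts, n_confounders = n_confounders, sf = sf)
  tst <- test_outliers(cts, fit, padj_cutoff = padj_cutoff,
                       z_cutoff = z_cutoff)
  structure(list(calls = tst$calls, z = tst$z, expected = fit$expected,
                 expected_log = fit$expected_log, dispersion = fit$dispersion,
                 size_factors = sf, log_norm = fit$log_norm,
                 filter_report = fl$report, excluded_samples = excluded,
                 stratified = FALSE, n_confounders = n_confounders,
                 padj_cutoff = padj_cutoff, z_cutoff = z_cutoff),
            class = "expression_fit")
}

#' @export
print.expression_fit <- function(x, ...) {
  cat("Expression outlier fit\n")
  cat(sprintf("  genes: %d retained (of %d; %d hemoglobin, %d low-expression removed)\n",
              x$filter_report$n_retained, x$filter_report$n_input_genes,
              length(x$filter_report$removed_hemoglobin),
              length(x$filter_report$removed_low_expression)))
  cat(sprintf("  samples: %d analyzed, %d excluded by PCA QC\n",
              length(x$size_factors), length(x$excluded_samples)))
  cat(sprintf("  confounders removed: %d\n", x$n_confounders))
  cat(sprintf("  outliers: %d of %d gene x sample tests (padj < %g or |z| >= %g)\n",
              sum(x$calls$is_outlier), nrow(x$calls), x$padj_cutoff,
              x$z_cutoff))
  invisible(x)
}

#' @export
summary.expression_fit <- function(object, n = 10, ...) {
  out <- object$calls[object$calls$is_outlier, ]
  out <- out[order(out$adjusted_p, -abs(out$z_score)), ]
  print(object)
  cat(sprintf("\nTop %d outlier calls:\n", min(n, nrow(out))))
  print(utils::head(out[, c("sample_id", "gene_id", "z_score", "fold_change",
                            "p_value", "adjusted_p")], n), row.names = FALSE)
  invisible(out)
}

#' @export
fitted.expression_fit <- function(object, ...) object$expected

#' Residual z-scores of an expression fit
#' @param object An `expression_fit`.
#' @param ... Unused.
#' @return Gene x sample matrix of z-scores.
#' @export
residuals.expression_fit <- function(object, ...) object$z

#' @export
as.data.frame.expression_fit <- function(x, ...) x$calls
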