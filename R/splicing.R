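## Aberrant-splicing screen based on junction coverage scores.
##
## For each splice junction the coverage score is the fraction of the local
## splicing traffic it carries: its read count divided by the total reads on
## junctions sharing its donor or acceptor site (the junction itself
## included, which bounds the score in [0, 1]). Scores are z-standardized
## per junction across the cohort; |z| >= 2 is the screening threshold.

#' Filter junction tables by unique-read support
#'
#' Keeps junctions with strictly more than `min_unique_reads` uniquely
#' mapped reads (default > 5).
#' @param junctions A junction table or a list of per-sample tables.
#' @param min_unique_reads Strict lower bound on unique reads.
#' @return Same shape as the input, filtered.
#' @export
filter_junctions <- function(junctions, min_unique_reads = 5) {
  one <- function(jt) jt[jt$unique_reads > min_unique_reads, , drop = FALSE]
  if (is.data.frame(junctions)) return(one(junctions))
  lapply(junctions, one)
}

junction_key <- function(jt) {
  sprintf("%s:%d-%d:%d", jt$chrom, jt$intron_start, jt$intron_end,
          jt$strand_code)
}

## donor/acceptor site of each junction by strand: on '+' (code 1) the donor
## is the intron start, on '-' (code 2) the intron end; strand-unknown
## junctions (code 0) get role "unknown" at both ends
junction_sites <- function(universe) {
  donor_pos <- ifelse(universe$strand_code == 2, universe$intron_end,
                      universe$intron_start)
  acceptor_pos <- ifelse(universe$strand_code == 2, universe$intron_start,
                         universe$intron_end)
  donor_role <- ifelse(universe$strand_code == 0, "unknown", "donor")
  acceptor_role <- ifelse(universe$strand_code == 0, "unknown", "acceptor")
  list(donor = paste(universe$chrom, donor_pos, donor_role),
       acceptor = paste(universe$chrom, acceptor_pos, acceptor_role))
}

#' Build donor/acceptor-sharing junction groups
#'
#' The junction universe is the union over samples; each junction belongs to
#' exactly two groups, keyed by (chromosome, site position, role) for its
#' donor and acceptor ends. Strand determines which intron end is the donor;
#' strand-unknown junctions are grouped by both ends with role "unknown".
#'
#' @param universe data.frame of distinct junctions (chrom, intron_start,
#'   intron_end, strand_code).
#' @return list(universe, donor_group, acceptor_group, groups) where
#'   donor/acceptor_group are integer group indices per junction and
#'   `groups` maps group index to member junction indices.
#' @export
build_junction_groups <- function(universe) {
  sites <- junction_sites(universe)
  all_keys <- unique(c(sites$donor, sites$acceptor))
  donor_group <- match(sites$donor, all_keys)
  acceptor_group <- match(sites$acceptor, all_keys)
  members <- split(c(seq_len(nrow(universe)), seq_len(nrow(universe))),
                   c(donor_group, acceptor_group))
  members <- lapply(members, unique)
  groups <- stats::setNames(members, all_keys[as.integer(names(members))])
  list(universe = universe, donor_group = donor_group,
       acceptor_group = acceptor_group, groups = groups)
}

## For each junction, indices of junctions sharing either of its ends
## (itself included once)
shared_partners <- function(grp) {
  lapply(seq_len(nrow(grp$universe)), function(j) {
    union(grp$groups[[grp$donor_group[j]]], grp$groups[[grp$acceptor_group[j]]])
  })
}

#' Junction coverage scores across a cohort
#'
#' score_js = n_js / sum over junctions sharing junction j's donor or
#' acceptor site (pooled over both ends without double counting) of n_ks.
#' With `include_self = TRUE` (default, matching the worked arithmetic of
#' a 65-of-74-read event) the junction itself is in the denominator and the
#' score lies in [0, 1]; `include_self = FALSE` gives the literal
#' "other junctions" reading. Samples where the denominator is 0 get NA.
#'
#' @param count_matrix Junction x sample matrix of unique-read counts.
#' @param grp Output of [build_junction_groups()] on the matching universe.
#' @param include_self Include the junction itself in the denominator.
#' @return Junction x sample matrix of scores in [0, 1] (or ratios when
#'   `include_self = FALSE`).
#' @export
junction_coverage_score <- function(count_matrix, grp, include_self = TRUE) {
  partners <- shared_partners(grp)
  denom <- matrix(0, nrow(count_matrix), ncol(count_matrix))
  for (j in seq_along(partners)) {
    idx <- partners[[j]]
    if (!include_self) idx <- setdiff(idx, j)
    denom[j, ] <- if (length(idx))
      colSums(count_matrix[idx, , drop = FALSE]) else 0
  }
  score <- count_matrix / denom
  score[denom == 0] <- NA_real_
  dimnames(score) <- dimnames(count_matrix)
  score
}

#' Cohort z-scores of junction coverage scores
#'
#' z_js = (score_js - mean_j) / sd_j over samples with a defined score;
#' junctions with fewer than `min_samples` defined scores or zero variance
#' are skipped (all-NA row).
#'
#' @param scores Junction x sample score matrix.
#' @param min_samples Minimum samples with a defined score.
#' @return Junction x sample matrix of z-scores.
#' @export
junction_zscores <- function(scores, min_samples = 10) {
  mean_j <- rowMeans(scores, na.rm = TRUE)
  sd_j <- apply(scores, 1, stats::sd, na.rm = TRUE)
  n_j <- rowSums(!is.na(scores))
  z <- (scores - mean_j) / sd_j
  z[n_j < min_samples | sd_j == 0 | !is.finite(sd_j), ] <- NA_real_
  dimnames(z) <- dimnames(scores)
  z
}

#' Classify a splice junction against an exon model
#'
#' Deterministic annotation-aware rules over the reduced exon model (one row
#' per exon: gene_id, chrom, start, end, 1-based inclusive):
#' both intron ends at annotated exon boundaries with >= 1 annotated exon
#' inside the intron -> "exon_skip"; matching a single annotated intron ->
#' "intron_retention_flank" when elevated intronic coverage is flagged, else
#' "unclassified"; one end annotated and the other inside an exon ->
#' "alt_donor"/"alt_acceptor" by the role of the unannotated end; both ends
#' strictly inside one intron -> "novel_exon"; anything else (including
#' junctions in genes without an exon model) -> "unclassified".
#'
#' @param chrom,intron_start,intron_end,strand_code Junction coordinates
#'   (intron first/last base, 1-based inclusive).
#' @param exons Exon model data.frame(gene_id, chrom, start, end).
#' @param elevated_intronic Logical; evidence of elevated intronic coverage
#'   (needed to call intron retention from junction data alone).
#' @return One of "exon_skip", "alt_acceptor", "alt_donor",
#'   "intron_retention_flank", "novel_exon", "unclassified".
#' @export
classify_event <- function(chrom, intron_start, intron_end, strand_code,
                           exons, elevated_intronic = FALSE) {
  ex <- exons[exons$chrom == chrom, , drop = FALSE]
  if (!nrow(ex)) return("unclassified")
  ## genes whose span contains the junction
  gene_hit <- vapply(unique(ex$gene_id), function(g) {
    gg <- ex[ex$gene_id == g, ]
    min(gg$start) <= intron_end && max(gg$end) >= intron_start
  }, logical(1))
  if (!any(gene_hit)) return("unclassified")
  ex <- ex[ex$gene_id %in% names(gene_hit)[gene_hit], , drop = FALSE]

  start_annotated <- any(ex$end == intron_start - 1)   # exon ends before intron
  end_annotated <- any(ex$start == intron_end + 1)     # exon starts after intron
  inside <- ex$start > intron_start & ex$end < intron_end
  in_exon <- function(pos) any(ex$start < pos & pos < ex$end)

  if (start_annotated && end_annotated) {
    if (any(inside)) return("exon_skip")
    ## no exon inside: the junction matches one annotated intron
    if (elevated_intronic) return("intron_retention_flank")
    return("unclassified")
  }
  if (xor(start_annotated, end_annotated)) {
    unann_pos <- if (start_annotated) intron_end else intron_start
    if (in_exon(unann_pos)) {
      ## role of the unannotated end by strand (strand 0 treated as '+')
      unann_is_start <- !start_annotated
      donor_at_start <- strand_code != 2
      is_donor_end <- (unann_is_start & donor_at_start) |
        (!unann_is_start & !donor_at_start)
      return(if (is_donor_end) "alt_donor" else "alt_acceptor")
    }
    return("unclassified")
  }
  ## neither end annotated: novel exon if both ends are strictly inside one
  ## annotated intron (not within any exon, touching no exon boundary, no
  ## exon between them)
  touches <- function(pos) any(ex$start == pos | ex$end == pos)
  if (!in_exon(intron_start) && !in_exon(intron_end) &&
      !touches(intron_start) && !touches(intron_end) && !any(inside) &&
      any(ex$end < intron_start) && any(ex$start > intron_end))
    return("novel_exon")
  "unclassified"
}

## gene assignment by interval overlap of the intron with gene spans
assign_gene <- function(chrom, start, end, annotation) {
  hit <- annotation$chrom == chrom & annotation$start_bp <= end &
    annotation$end_bp >= start
  if (!any(hit)) return(NA_character_)
  annotation$gene_id[which(hit)[1]]
}

#' Run the aberrant-splicing screen
#'
#' Builds the junction universe (union over samples of junctions passing
#' the strict read filter in at least one sample), computes coverage scores
#' per sample (counts from each sample's own table, 0 when absent), cohort
#' z-scores, and flags junction x sample pairs with |z| >= `z_cutoff` where
#' the junction also passed the read filter in that sample.
#'
#' @param junctions List of per-sample junction tables.
#' @param annotation Optional gene annotation for gene assignment.
#' @param exons Optional exon model for event classification.
#' @param min_unique_reads Strict read filter (default > 5).
#' @param z_cutoff Screening threshold on |z| (default 2).
#' @param min_samples_scored Minimum samples with defined scores per
#'   junction.
#' @param include_self Denominator convention, see
#'   [junction_coverage_score()].
#' @return An object of class `splice_screen` with elements calls (one row
#'   per scored junction x sample), universe, scores, z.
#' @export
run_splicing_stage <- function(junctions, annotation = NULL, exons = NULL,
                               min_unique_reads = 5, z_cutoff = 2,
                               min_samples_scored = 10, include_self = TRUE) {
  sample_ids <- names(junctions)
  if (is.null(sample_ids)) stopf("junctions must be a named per-sample list")
  filtered <- filter_junctions(junctions, min_unique_reads)
  universe <- unique(do.call(rbind, lapply(filtered, function(jt)
    jt[, c("chrom", "intron_start", "intron_end", "strand_code")])))
  if (is.null(universe) || !nrow(universe)) {
    return(structure(list(calls = data.frame(), universe = universe,
                          scores = NULL, z = NULL, z_cutoff = z_cutoff),
                     class = "splice_screen"))
  }
  rownames(universe) <- NULL
  ukey <- junction_key(universe)

  cnt <- matrix(0L, nrow(universe), length(sample_ids),
                dimnames = list(ukey, sample_ids))
  for (s in sample_ids) {
    jt <- junctions[[s]]
    idx <- match(junction_key(jt), ukey)
    ok <- !is.na(idx)
    cnt[idx[ok], s] <- jt$unique_reads[ok]
  }

  grp <- build_junction_groups(universe)
  scores <- junction_coverage_score(cnt, grp, include_self = include_self)
  z <- junction_zscores(scores, min_samples = min_samples_scored)

  passed <- cnt > min_unique_reads
  scored <- which(!is.na(z), arr.ind = TRUE)
  calls <- data.frame(
    sample_id = sample_ids[scored[, 2]],
    chrom = universe$chrom[scored[, 1]],
    intron_start = universe$intron_start[scored[, 1]],
    intron_end = universe$intron_end[scored[, 1]],
    strand_code = universe$strand_code[scored[, 1]],
    junction = ukey[scored[, 1]],
    reads_in_sample = cnt[scored],
    coverage_score = scores[scored],
    z_score = z[scored],
    passed_filter = passed[scored],
    stringsAsFactors = FALSE)
  calls$is_outlier <- abs(calls$z_score) >= z_cutoff & calls$passed_filter

  calls$gene_id <- NA_character_
  calls$event_class <- "unclassified"
  if (!is.null(annotation)) {
    need <- which(calls$is_outlier)
    for (i in need)
      calls$gene_id[i] <- assign_gene(calls$chrom[i], calls$intron_start[i],
                                      calls$intron_end[i], annotation)
  }
  if (!is.null(exons)) {
    need <- which(calls$is_outlier)
    for (i in need)
      calls$event_class[i] <- classify_event(calls$chrom[i],
                                             calls$intron_start[i],
                                             calls$intron_end[i],
                                             calls$strand_code[i], exons)
  }
  structure(list(calls = calls, universe = universe, scores = scores, z = z,
                 z_cutoff = z_cutoff), class = "splice_screen")
}

#' @export
print.splice_screen <- function(x, ...) {
  cat("Aberrant-splicing screen\n")
  if (!nrow(x$calls)) {
    cat("  no scorable junctions\n")
    return(invisible(x))
  }
  cat(sprintf("  junction universe: %d junctions\n", nrow(x$universe)))
  cat(sprintf("  flagged: %d of %d scored junction x sample pairs (|z| >= %g)\n",
              sum(x$calls$is_outlier), nrow(x$calls), x$z_cutoff))
  invisible(x)
}

#' @export
summary.splice_screen <- function(object, n = 10, ...) {
  print(object)
  out <- object$calls[object$calls$is_outlier, ]
  out <- out[order(-abs(out$z_score)), ]
  cat(sprintf("\nTop %d flagged junctions:\n", min(n, nrow(out))))
  print(utils::head(out[, c("sample_id", "junction", "reads_in_sample",
                            "coverage_score", "z_score", "event_class")], n),
        row.names = FALSE)
  invisible(out)
}
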