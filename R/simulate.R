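## Synthetic whole-blood RNA-seq cohort generator.
##
## Emulates the statistical structure the diagnostic screens assume:
## negative-binomial gene counts with per-sample size factors and a
## hemoglobin-dominated library composition, splice-junction read counts
## drawn multinomially within donor/acceptor-sharing groups, beta-binomial
## allelic counts at rare heterozygous sites, and incompletely penetrant
## CNV dosage effects. Every planted aberration is recorded in a truth
## ledger so downstream sensitivity and calibration are measurable.

#' Simulation parameters for a synthetic cohort
#'
#' Defaults mirror the shape of a mid-size whole-blood diagnostic cohort at
#' desk scale: 60 samples by 5,000 genes, nine hemoglobin-like genes
#' consuming ~40% of each library, log-normal gene means and dispersions,
#' and modest size-factor spread.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param n_female Number of female samples (the rest are male).
#' @param mean_log Location/scale of the log-normal distribution of per-gene
#'   base mean counts.
#' @param dispersion_log Location/scale of the log-normal distribution of
#'   per-gene NB dispersions (variance = mu + phi * mu^2).
#' @param size_factor_sdlog Log-normal sd of per-sample size factors
#'   (rescaled to geometric mean 1).
#' @param n_hemoglobin_like Number of hemoglobin-like genes; they carry the
#'   nine real hemoglobin symbols so the expression filter is exercised.
#' @param hemoglobin_fraction Fraction of each library consumed by the
#'   hemoglobin-like genes (typical whole-blood figure ~0.4).
#' @param x_male_ratio Relative expression of X-linked genes in males
#'   (emulates incomplete dosage compensation; motivates sex stratification).
#' @param n_junction_groups Number of donor/acceptor-sharing junction groups.
#' @param junctions_per_group Possible group sizes (sampled uniformly).
#' @param junction_group_depth Mean per-sample read depth of a group.
#' @param n_ase_sites Heterozygous sites per sample.
#' @param ase_depth Mean read depth at a site.
#' @param ase_overdispersion Beta-binomial intraclass correlation of null
#'   allelic counts around 0.5.
#' @param ase_shared_fraction Fraction of sites duplicated into a second
#'   sample (removed by the rare-het filter; exercises it).
#' @param expression_outliers Planted expression outliers: either a
#'   data.frame(gene, sample, fold_change) or list(n, log2fc, min_mean) for
#'   automatic placement on autosomal non-hemoglobin genes with base mean >=
#'   min_mean.
#' @param splice_outliers Planted splice events: data.frame(group, junction,
#'   sample, target_usage) or list(n, target_usage).
#' @param ase_outliers Planted allelic imbalance: data.frame(sample, site,
#'   alt_ratio) or list(n, alt_ratio, depth).
#' @param cnvs Planted CNVs: data.frame(sample, chrom, start_bp, end_bp,
#'   copy_number, penetrance).
#' @param seed Integer seed; the cohort is fully reproducible given
#'   (params, seed).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 60L, n_genes = 5000L, n_female = 30L,
                       mean_log = c(location = log(50), scale = 1.6),
                       dispersion_log = c(location = log(0.01), scale = 1),
                       size_factor_sdlog = 0.25,
                       n_hemoglobin_like = 9L, hemoglobin_fraction = 0.4,
                       x_male_ratio = 0.8,
                       n_junction_groups = 200L, junctions_per_group = 2:3,
                       junction_group_depth = 100,
                       n_ase_sites = 200L, ase_depth = 30,
                       ase_overdispersion = 0.02, ase_shared_fraction = 0.05,
                       expression_outliers = NULL, splice_outliers = NULL,
                       ase_outliers = NULL, cnvs = NULL, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_samples > 0, p$n_genes > 0, p$n_female >= 0,
            p$n_female <= p$n_samples,
            p$hemoglobin_fraction >= 0, p$hemoglobin_fraction < 1,
            p$ase_shared_fraction >= 0, p$ase_shared_fraction <= 1,
            p$ase_overdispersion >= 0, p$ase_overdispersion < 0.5,
            p$x_male_ratio > 0, p$junction_group_depth > 0,
            p$size_factor_sdlog >= 0)
  structure(p, class = "sim_params")
}

HEMOGLOBIN_SYMBOLS <- c("HBB", "HBD", "HBG1", "HBG2", "HBZ", "HBM",
                        "HBA2", "HBA1", "HBQ1")

## genes laid out in contiguous blocks per chromosome so CNV intervals can
## cover runs of adjacent genes
sim_annotation <- function(p) {
  chroms <- c(as.character(1:22), "X")
  per_chrom <- ceiling(p$n_genes / length(chroms))
  gene_ids <- sprintf("G%05d", seq_len(p$n_genes))
  idx <- seq_len(p$n_genes) - 1L
  chrom <- chroms[idx %/% per_chrom + 1L]
  start <- (idx %% per_chrom) * 100000L + 1L
  end <- start + 49999L
  symbol <- gene_ids
  n_hb <- min(p$n_hemoglobin_like, length(HEMOGLOBIN_SYMBOLS), p$n_genes)
  if (n_hb > 0) symbol[seq_len(n_hb)] <- HEMOGLOBIN_SYMBOLS[seq_len(n_hb)]
  exonic_length <- pmax(200L, as.integer(round(stats::rlnorm(p$n_genes,
                                                             log(2000), 0.6))))
  disease <- stats::runif(p$n_genes) < 0.3
  pool <- sprintf("HP:%07d", 1:50)
  hpo <- vector("list", p$n_genes)
  for (i in seq_len(p$n_genes)) {
    hpo[[i]] <- if (disease[i]) sample(pool, sample(1:3, 1)) else character(0)
  }
  data.frame(gene_id = gene_ids, symbol = symbol, chrom = chrom,
             start_bp = start, end_bp = end,
             strand = sample(c("+", "-"), p$n_genes, replace = TRUE),
             exonic_length_bp = exonic_length, biotype = "protein_coding",
             disease_associated = disease,
             hpo_terms = I(hpo), stringsAsFactors = FALSE)
}

#' Plant a CNV dosage effect into a count (or mean) matrix
#'
#' Scales the carrier sample's values for a random `penetrance` fraction of
#' the genes covered by the CNV interval by `copy_number / 2`; the remaining
#' covered genes are left unchanged, reflecting the non-uniform expression
#' impact observed inside real pathogenic CNVs. The number of affected genes
#' is `round(penetrance * n_covered)` (default penetrance 24/34, the
#' observed fraction of dosage-responsive protein-coding genes in a 22q11.2
#' deletion carrier).
#'
#' @param counts Numeric matrix (genes x samples); counts or expected means.
#' @param annotation Gene annotation with coordinates.
#' @param sample_id Carrier sample (must be a column of `counts`).
#' @param chrom,start_bp,end_bp CNV interval, 1-based inclusive.
#' @param copy_number Integer copy number in 0,1,3,4 (2 is not a CNV).
#' @param penetrance Fraction of covered genes that respond to dosage.
#' @return list(counts = modified matrix, truth = data.frame of affected
#'   genes with modality "cnv" and effect = copy_number/2).
#' @export
plant_cnv_effect <- function(counts, annotation, sample_id, chrom, start_bp,
                             end_bp, copy_number, penetrance = 24 / 34) {
  if (penetrance < 0 || penetrance > 1)
    stopf("penetrance must be in [0, 1], got %s", penetrance)
  if (copy_number == 2)
    stopf("copy number 2 is not a CNV")
  if (!sample_id %in% colnames(counts))
    stopf("sample '%s' not in counts matrix", sample_id)
  covered <- annotation$gene_id[annotation$chrom == chrom &
                                  annotation$start_bp <= end_bp &
                                  annotation$end_bp >= start_bp]
  covered <- intersect(covered, rownames(counts))
  if (!length(covered))
    stopf("CNV %s:%d-%d overlaps no annotated gene", chrom, start_bp, end_bp)
  n_aff <- round(penetrance * length(covered))
  affected <- if (n_aff > 0) sample(covered, n_aff) else character(0)
  fc <- copy_number / 2
  counts[affected, sample_id] <- counts[affected, sample_id] * fc
  truth <- data.frame(modality = rep("cnv", length(affected)),
                      sample_id = rep(sample_id, length(affected)),
                      feature_id = affected,
                      effect = rep(fc, length(affected)),
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

## round a vector of non-negative expectations to integers preserving their
## (integer) sum: largest-remainder method, deterministic tie-break by index
round_preserve_sum <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Redistribute a junction group's reads to a target usage proportion
#'
#' Deterministically reassigns one sample's reads within a
#' donor/acceptor-sharing junction group so the target junction carries
#' `target_usage` of the group total (largest-remainder rounding); the other
#' junctions keep their relative proportions. The group total is preserved
#' exactly.
#'
#' @param group_counts Named or unnamed non-negative integer vector of reads
#'   per junction in the group for one sample.
#' @param target_junction Index (or name) of the junction to shift.
#' @param target_usage Target usage proportion, strictly in (0, 1).
#' @return Integer vector with the same total.
#' @export
plant_splice_event <- function(group_counts, target_junction, target_usage) {
  if (target_usage <= 0 || target_usage >= 1)
    stopf("target usage must be strictly inside (0, 1), got %s", target_usage)
  if (is.character(target_junction))
    target_junction <- match(target_junction, names(group_counts))
  if (is.na(target_junction) || target_junction < 1 ||
      target_junction > length(group_counts))
    stopf("target junction not found in group")
  total <- sum(group_counts)
  if (total == 0) return(group_counts)
  n_target <- round(target_usage * total)
  others <- group_counts[-target_junction]
  w <- if (sum(others) > 0) others / sum(others) else
    rep(1 / length(others), length(others))
  out <- group_counts
  out[target_junction] <- n_target
  if (length(others))
    out[-target_junction] <- round_preserve_sum(w * (total - n_target),
                                                total - n_target)
  as.integer(out)
}

## normalize a planted-event spec: data.frame passes through, list triggers
## automatic placement, NULL gives an empty frame
resolve_expr_spec <- function(spec, mu, annotation, sample_ids) {
  if (is.null(spec))
    return(data.frame(gene = character(0), sample = character(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE))
  if (is.data.frame(spec)) return(spec)
  min_mean <- if (is.null(spec$min_mean)) 100 else spec$min_mean
  log2fc <- if (is.null(spec$log2fc)) c(-1, 1) else spec$log2fc
  eligible <- names(mu)[mu >= min_mean &
                          !annotation$symbol %in% HEMOGLOBIN_SYMBOLS &
                          annotation$chrom != "X"]
  if (length(eligible) < spec$n)
    stopf("only %d genes eligible for %d planted expression outliers",
          length(eligible), spec$n)
  data.frame(gene = sample(eligible, spec$n),
             sample = sample(sample_ids, spec$n, replace = TRUE),
             fold_change = 2^sample(log2fc, spec$n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic diagnostic cohort
#'
#' Draws the full input set of the diagnostic pipeline from a single seeded
#' generative model: a gene annotation, NB gene counts, per-sample STAR-style
#' junction tables, per-sample allele-count tables at rare heterozygous
#' sites, CNV calls, and sample metadata, together with a truth ledger of
#' every planted aberration.
#'
#' @param params A [sim_params()] object.
#' @return list with elements counts, junctions (list per sample), ase
#'   (list per sample), cnv, metadata, annotation, junction_groups, truth.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  sample_ids <- sprintf("S%03d", seq_len(p$n_samples))
  annotation <- sim_annotation(p)
  gene_ids <- annotation$gene_id

  sex <- c(rep("female", p$n_female), rep("male", p$n_samples - p$n_female))
  pool <- sprintf("HP:%07d", 1:50)
  sample_hpo <- lapply(seq_len(p$n_samples),
                       function(i) sample(pool, sample(2:5, 1)))
  metadata <- data.frame(sample_id = sample_ids, sex = sex,
                         hpo_terms = I(sample_hpo), batch = "B1",
                         stringsAsFactors = FALSE)

  ## per-gene base means; hemoglobin-like genes consume a fixed fraction of
  ## the library, split evenly among them
  mu <- stats::rlnorm(p$n_genes, p$mean_log[["location"]],
                      p$mean_log[["scale"]])
  names(mu) <- gene_ids
  n_hb <- min(p$n_hemoglobin_like, length(HEMOGLOBIN_SYMBOLS), p$n_genes)
  if (n_hb > 0 && p$hemoglobin_fraction > 0) {
    hb_idx <- seq_len(n_hb)
    mu[hb_idx] <- p$hemoglobin_fraction / (1 - p$hemoglobin_fraction) *
      sum(mu[-hb_idx]) / n_hb
  }
  phi <- stats::rlnorm(p$n_genes, p$dispersion_log[["location"]],
                       p$dispersion_log[["scale"]])
  names(phi) <- gene_ids
  sf <- stats::rlnorm(p$n_samples, 0, p$size_factor_sdlog)
  sf <- sf / geomean(sf)
  names(sf) <- sample_ids

  ## expected mean matrix with sex effect on X and planted fold changes
  mu_mat <- outer(mu, sf)
  dimnames(mu_mat) <- list(gene_ids, sample_ids)
  on_x <- annotation$chrom == "X"
  if (any(on_x) && p$x_male_ratio != 1)
    mu_mat[on_x, sex == "male"] <- mu_mat[on_x, sex == "male"] * p$x_male_ratio

  truth <- list()
  expr_spec <- resolve_expr_spec(p$expression_outliers, mu, annotation,
                                 sample_ids)
  if (nrow(expr_spec)) {
    bad_g <- setdiff(expr_spec$gene, gene_ids)
    bad_s <- setdiff(expr_spec$sample, sample_ids)
    if (length(bad_g) || length(bad_s))
      stopf("planted expression event references unknown gene/sample: %s",
            paste(c(bad_g, bad_s), collapse = ", "))
    for (i in seq_len(nrow(expr_spec)))
      mu_mat[expr_spec$gene[i], expr_spec$sample[i]] <-
        mu_mat[expr_spec$gene[i], expr_spec$sample[i]] * expr_spec$fold_change[i]
    truth$expression <- data.frame(modality = "expression",
                                   sample_id = expr_spec$sample,
                                   feature_id = expr_spec$gene,
                                   effect = expr_spec$fold_change,
                                   stringsAsFactors = FALSE)
  }

  ## CNVs scale the carrier's expected means for a penetrant subset of
  ## covered genes
  cnv_rows <- list()
  if (!is.null(p$cnvs) && nrow(p$cnvs)) {
    for (i in seq_len(nrow(p$cnvs))) {
      cv <- p$cnvs[i, ]
      if (!cv$sample %in% sample_ids)
        stopf("planted CNV references unknown sample '%s'", cv$sample)
      pen <- if ("penetrance" %in% names(cv) && !is.na(cv$penetrance))
        cv$penetrance else 24 / 34
      res <- plant_cnv_effect(mu_mat, annotation, cv$sample, cv$chrom,
                              cv$start_bp, cv$end_bp, cv$copy_number, pen)
      mu_mat <- res$counts
      truth[[paste0("cnv", i)]] <- res$truth
      cnv_rows[[i]] <- data.frame(sample_id = cv$sample, chrom = cv$chrom,
                                  start_bp = as.integer(cv$start_bp),
                                  end_bp = as.integer(cv$end_bp),
                                  copy_number = as.integer(cv$copy_number),
                                  stringsAsFactors = FALSE)
    }
  }
  cnv_set <- if (length(cnv_rows)) do.call(rbind, cnv_rows) else
    data.frame(sample_id = character(0), chrom = character(0),
               start_bp = integer(0), end_bp = integer(0),
               copy_number = integer(0), stringsAsFactors = FALSE)

  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = rep(1 / phi, p$n_samples)),
                   nrow = p$n_genes, dimnames = dimnames(mu_mat))
  storage.mode(counts) <- "integer"

  junc <- sim_junctions(p, annotation, sample_ids, truth)
  truth <- junc$truth
  ase <- sim_ase(p, annotation, sample_ids, truth)
  truth <- ase$truth

  truth_df <- if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE))) else
    data.frame(modality = character(0), sample_id = character(0),
               feature_id = character(0), effect = numeric(0),
               stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL

  list(counts = counts, junctions = junc$tables, ase = ase$tables,
       cnv = cnv_set, metadata = metadata, annotation = annotation,
       junction_groups = junc$groups, truth = truth_df)
}

## junction groups: members share a donor (or acceptor) site; per-sample
## depths Poisson around the group mean, reads multinomial over baseline
## usage, planted samples get a shifted usage vector
sim_junctions <- function(p, annotation, sample_ids, truth) {
  n_g <- p$n_junction_groups
  if (n_g == 0)
    return(list(tables = stats::setNames(
      lapply(sample_ids, empty_junction_table), sample_ids),
      groups = NULL, truth = truth))
  host <- annotation[sample.int(nrow(annotation), n_g, replace = TRUE), ]
  sizes <- sample(rep(p$junctions_per_group, length.out = max(2, n_g)), n_g,
                  replace = TRUE)
  strand <- sample(1:2, n_g, replace = TRUE)

  groups <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    k <- sizes[g]
    shared <- host$start_bp[g] + 1000L
    ends <- shared + sort(sample(2000:40000, k))
    usage <- stats::rgamma(k, 5, 1)
    usage <- usage / sum(usage)
    groups[[g]] <- data.frame(group = g, chrom = host$chrom[g],
                              intron_start = shared, intron_end = ends,
                              strand_code = strand[g],
                              junction = seq_len(k), baseline_usage = usage,
                              stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, groups)

  spec <- p$splice_outliers
  if (is.list(spec) && !is.data.frame(spec) && !is.null(spec)) {
    n_ev <- spec$n
    tgt <- if (is.null(spec$target_usage)) 0.88 else spec$target_usage
    if (n_ev > n_g) stopf("more planted splice events than groups")
    spec <- data.frame(group = sample(n_g, n_ev),
                       junction = 1L,
                       sample = sample(sample_ids, n_ev, replace = TRUE),
                       target_usage = tgt, stringsAsFactors = FALSE)
  }
  if (!is.null(spec) && nrow(spec)) {
    if (any(!spec$sample %in% sample_ids) || any(spec$group > n_g))
      stopf("planted splice event references unknown group/sample")
    if (any(spec$target_usage <= 0 | spec$target_usage >= 1))
      stopf("target usage must be strictly inside (0, 1)")
    feat <- vapply(seq_len(nrow(spec)), function(i) {
      gg <- groups[groups$group == spec$group[i] &
                     groups$junction == spec$junction[i], ]
      sprintf("%s:%d-%d:%d", gg$chrom, gg$intron_start, gg$intron_end,
              gg$strand_code)
    }, character(1))
    truth$splicing <- data.frame(modality = "splicing",
                                 sample_id = spec$sample, feature_id = feat,
                                 effect = spec$target_usage,
                                 stringsAsFactors = FALSE)
  }

  tables <- stats::setNames(vector("list", length(sample_ids)), sample_ids)
  counts_by_sample <- lapply(sample_ids, function(s) integer(nrow(groups)))
  names(counts_by_sample) <- sample_ids
  for (g in seq_len(n_g)) {
    rows <- which(groups$group == g)
    usage <- groups$baseline_usage[rows]
    depth <- stats::rpois(length(sample_ids), p$junction_group_depth)
    for (si in seq_along(sample_ids)) {
      u <- usage
      if (!is.null(spec) && nrow(spec)) {
        hit <- which(spec$group == g & spec$sample == sample_ids[si])
        for (h in hit) {
          j <- spec$junction[h]
          u <- u * (1 - spec$target_usage[h]) / sum(u[-j])
          u[j] <- spec$target_usage[h]
        }
      }
      if (depth[si] > 0)
        counts_by_sample[[si]][rows] <-
          as.integer(stats::rmultinom(1, depth[si], u))
    }
  }
  for (si in seq_along(sample_ids)) {
    cnt <- counts_by_sample[[si]]
    keep <- cnt > 0
    tables[[si]] <- data.frame(sample_id = sample_ids[si],
                               chrom = groups$chrom[keep],
                               intron_start = groups$intron_start[keep],
                               intron_end = groups$intron_end[keep],
                               strand_code = groups$strand_code[keep],
                               unique_reads = cnt[keep],
                               stringsAsFactors = FALSE)
  }
  list(tables = tables, groups = groups, truth = truth)
}

## beta-binomial draw around prob with intraclass correlation rho
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 / rho - 1)
  b <- (1 - prob) * (1 / rho - 1)
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

sim_ase <- function(p, annotation, sample_ids, truth) {
  n_s <- length(sample_ids)
  n_sites <- p$n_ase_sites
  tables <- stats::setNames(vector("list", n_s), sample_ids)
  if (n_sites == 0) {
    for (s in sample_ids)
      tables[[s]] <- data.frame(sample_id = character(0), chrom = character(0),
                                pos = integer(0), ref = character(0),
                                alt = character(0), ref_count = integer(0),
                                alt_count = integer(0), gene_id = character(0),
                                stringsAsFactors = FALSE)
    return(list(tables = tables, truth = truth))
  }
  bases <- c("A", "C", "G", "T")

  ## sites duplicated into a second sample occupy the head of each table;
  ## automatic planting avoids them so planted events stay cohort-unique
  n_shared <- if (p$ase_shared_fraction > 0 && n_s > 1)
    max(1L, round(p$ase_shared_fraction * n_sites)) else 0L
  spec <- p$ase_outliers
  if (is.list(spec) && !is.data.frame(spec) && !is.null(spec)) {
    if (n_shared + 1L > n_sites) stopf("no unique ASE sites left to plant in")
    spec <- data.frame(sample = sample(sample_ids, spec$n, replace = TRUE),
                       site = sample((n_shared + 1L):n_sites, spec$n,
                                     replace = TRUE),
                       alt_ratio = if (is.null(spec$alt_ratio)) 0.95 else
                         spec$alt_ratio,
                       depth = if (is.null(spec$depth)) 60 else spec$depth,
                       stringsAsFactors = FALSE)
    spec <- spec[!duplicated(spec[c("sample", "site")]), ]
  }
  if (!is.null(spec) && nrow(spec) && any(!spec$sample %in% sample_ids))
    stopf("planted ASE event references unknown sample")

  pos_counter <- 0L
  truth_rows <- list()
  for (si in seq_len(n_s)) {
    s <- sample_ids[si]
    gene_idx <- sample.int(nrow(annotation), n_sites, replace = TRUE)
    pos <- annotation$start_bp[gene_idx] + pos_counter + seq_len(n_sites)
    pos_counter <- pos_counter + n_sites
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    total <- stats::rnbinom(n_sites, mu = p$ase_depth, size = 10) + 2L
    alt_n <- rbetabinom(n_sites, total, 0.5, p$ase_overdispersion)
    if (!is.null(spec) && nrow(spec)) {
      hit <- which(spec$sample == s)
      for (h in hit) {
        i <- spec$site[h]
        dp <- if ("depth" %in% names(spec) && !is.na(spec$depth[h]))
          as.integer(spec$depth[h]) else total[i]
        total[i] <- dp
        alt_n[i] <- stats::rbinom(1, dp, spec$alt_ratio[h])
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          modality = "ase", sample_id = s,
          feature_id = sprintf("%s:%d:%s>%s", annotation$chrom[gene_idx[i]],
                               pos[i], ref[i], alt[i]),
          effect = spec$alt_ratio[h], stringsAsFactors = FALSE)
      }
    }
    tables[[s]] <- data.frame(sample_id = s,
                              chrom = annotation$chrom[gene_idx], pos = pos,
                              ref = ref, alt = alt,
                              ref_count = as.integer(total - alt_n),
                              alt_count = as.integer(alt_n),
                              gene_id = annotation$gene_id[gene_idx],
                              stringsAsFactors = FALSE)
  }
  ## duplicate a fraction of sites into a second sample so the rare-het
  ## filter has shared sites to remove
  if (n_shared > 0) {
    for (si in seq_len(n_s)) {
      other <- if (si < n_s) si + 1L else 1L
      donor <- tables[[si]][seq_len(min(n_shared, nrow(tables[[si]]))), ]
      donor$sample_id <- sample_ids[other]
      donor$ref_count <- as.integer(stats::rpois(nrow(donor), p$ase_depth / 2))
      donor$alt_count <- as.integer(stats::rpois(nrow(donor), p$ase_depth / 2))
      tables[[other]] <- rbind(tables[[other]], donor)
    }
  }
  if (length(truth_rows))
    truth$ase <- do.call(rbind, truth_rows)
  list(tables = tables, truth = truth)
}

#' Write a simulated cohort to a directory in the package's file formats
#'
#' Emits counts.tsv, one SJ-style junction file and one allele-count file per
#' sample, cnvs.bed, annotation.tsv, metadata.tsv and truth.tsv.
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_table(cohort$counts, file.path(dir, "counts.tsv"))
  jdir <- file.path(dir, "junctions"); dir.create(jdir, showWarnings = FALSE)
  adir <- file.path(dir, "ase"); dir.create(adir, showWarnings = FALSE)
  for (s in names(cohort$junctions))
    write_star_junctions(cohort$junctions[[s]],
                         file.path(jdir, paste0(s, ".SJ.out.tab")))
  for (s in names(cohort$ase))
    write_allele_counts(cohort$ase[[s]], file.path(adir, paste0(s, ".tsv")))
  write_cnv_bed(cohort$cnv, file.path(dir, "cnvs.bed"))
  write_gene_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(dir)
}
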