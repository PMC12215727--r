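## Allele-specific expression at rare heterozygous sites.
##
## Sites seen in exactly one sample of the cohort (rare in the internal
## batch) are tested for allelic imbalance against a balanced beta-binomial
## null: alt_count ~ BB(total, mean 0.5, intraclass correlation rho), with
## rho estimated from the cohort's presumed-null sites. rho = 0 reduces to
## the exact binomial test (doubled smaller tail).

#' Beta-binomial probability mass
#'
#' Parameterized by mean probability `prob` and intraclass correlation
#' `rho`; `rho = 0` is the binomial mass.
#' @param x Successes.
#' @param size Trials.
#' @param prob Mean probability.
#' @param rho Intraclass correlation in [0, 0.5).
#' @param log Return log density.
#' @return Probability mass.
#' @export
dbetabinom <- function(x, size, prob = 0.5, rho = 0, log = FALSE) {
  if (rho <= 0) return(stats::dbinom(x, size, prob, log = log))
  a <- prob * (1 / rho - 1)
  b <- (1 - prob) * (1 / rho - 1)
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

## lower-tail CDF P(X <= q) by direct summation (totals are read depths,
## small enough for exact summation)
pbetabinom <- function(q, size, prob = 0.5, rho = 0) {
  if (rho <= 0) return(stats::pbinom(q, size, prob))
  vapply(seq_along(q), function(i) {
    if (q[i] < 0) return(0)
    sum(dbetabinom(0:min(q[i], size[i]), size[i], prob, rho))
  }, numeric(1))
}

#' Two-sided beta-binomial test for allelic imbalance
#'
#' Doubled smaller-tail probability of the alternate-allele count given the
#' site total, balanced mean 0.5 and overdispersion `rho`, capped at 1.
#' Symmetric in (ref, alt).
#' @param ref_count,alt_count Allele read counts (vectors).
#' @param rho Beta-binomial intraclass correlation; 0 gives the exact
#'   binomial test.
#' @return Two-sided p-values.
#' @export
ase_test <- function(ref_count, alt_count, rho = 0) {
  total <- ref_count + alt_count
  if (any(total < 1)) stopf("each site needs >= 1 read")
  if (rho <= 0) {
    lower <- stats::pbinom(alt_count, total, 0.5)
    upper <- stats::pbinom(alt_count - 1, total, 0.5, lower.tail = FALSE)
    return(pmin(1, 2 * pmin(lower, upper)))
  }
  ## both tails by direct summation: total is a read depth, and summation
  ## avoids the cancellation of 1 - CDF for extreme counts
  vapply(seq_along(total), function(i) {
    mass <- dbetabinom(0:total[i], total[i], 0.5, rho)
    lower <- sum(mass[seq_len(alt_count[i] + 1)])
    upper <- sum(mass[(alt_count[i] + 1):(total[i] + 1)])
    min(1, 2 * min(lower, upper))
  }, numeric(1))
}

#' Restrict to rare heterozygous sites
#'
#' Keeps sites (identity chrom:pos:ref>alt) present in exactly one sample's
#' table across the cohort, then applies a total-coverage floor.
#' @param ase_tables List of per-sample allele-count tables.
#' @param min_total Minimum ref+alt coverage (default 10).
#' @return Filtered list of tables.
#' @export
filter_rare_het_sites <- function(ase_tables, min_total = 10) {
  site_key <- function(t) sprintf("%s:%d:%s>%s", t$chrom, t$pos, t$ref, t$alt)
  all_keys <- unlist(lapply(ase_tables, site_key), use.names = FALSE)
  counts <- table(all_keys)
  rare <- names(counts)[counts == 1]
  lapply(ase_tables, function(t) {
    keep <- site_key(t) %in% rare & (t$ref_count + t$alt_count) >= min_total
    t[keep, , drop = FALSE]
  })
}

#' Estimate the null allelic overdispersion
#'
#' Maximum-likelihood beta-binomial intraclass correlation over sites with
#' alternate-allele ratio in [0.2, 0.8] (presumed null), mean fixed at 0.5.
#' Falls back to the binomial (rho = 0) with a warning when fewer than
#' `min_sites` eligible sites exist.
#' @param sites data.frame with ref_count and alt_count (pooled cohort
#'   sites, e.g. rbind of [filter_rare_het_sites()] output).
#' @param min_sites Minimum eligible sites for a stable estimate.
#' @param ratio_range Alt-ratio window regarded as null.
#' @return Estimated rho (scalar).
#' @export
estimate_ase_overdispersion <- function(sites, min_sites = 50,
                                        ratio_range = c(0.2, 0.8)) {
  total <- sites$ref_count + sites$alt_count
  ratio <- sites$alt_count / total
  ok <- total >= 10 & ratio >= ratio_range[1] & ratio <= ratio_range[2]
  if (sum(ok) < min_sites) {
    warnf("only %d presumed-null sites (need >= %d); using binomial null (rho = 0)",
          sum(ok), min_sites)
    return(0)
  }
  x <- sites$alt_count[ok]; n <- total[ok]
  nll <- function(lrho) -sum(dbetabinom(x, n, 0.5, exp(lrho), log = TRUE))
  fit <- stats::optimize(nll, interval = log(c(1e-6, 0.4)))
  rho <- exp(fit$minimum)
  ## boundary at the lower end means no detectable overdispersion
  if (rho <= 1.5e-6) rho <- 0
  rho
}

#' Run the allele-specific expression stage
#'
#' Filters to rare heterozygous sites, estimates (or takes) the null
#' overdispersion, tests every site two-sidedly, BH-adjusts within each
#' sample, and flags sites with allele ratio > `ratio_cutoff` in either
#' direction and adjusted p < `padj_cutoff`. Sites with ratio >
#' `review_cutoff` are additionally marked for review regardless of
#' significance.
#'
#' @param ase_tables List of per-sample allele-count tables.
#' @param rho Null overdispersion; estimated from the cohort when `NULL`.
#' @param min_total Coverage floor for testable sites.
#' @param ratio_cutoff Allele-ratio component of the flag rule (default
#'   0.8, either direction).
#' @param review_cutoff Ratio threshold for the review tier (default 0.7).
#' @param padj_cutoff BH-adjusted significance cutoff.
#' @return An object of class `ase_screen` with elements calls, rho.
#' @export
run_ase_stage <- function(ase_tables, rho = NULL, min_total = 10,
                          ratio_cutoff = 0.8, review_cutoff = 0.7,
                          padj_cutoff = 0.05) {
  filtered <- filter_rare_het_sites(ase_tables, min_total = min_total)
  pooled <- do.call(rbind, filtered)
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(list(calls = data.frame(), rho = if (is.null(rho)) 0
                          else rho), class = "ase_screen"))
  }
  if (is.null(rho)) rho <- estimate_ase_overdispersion(pooled)

  calls <- do.call(rbind, lapply(filtered, function(t) {
    if (!nrow(t)) return(NULL)
    total <- t$ref_count + t$alt_count
    p <- ase_test(t$ref_count, t$alt_count, rho)
    data.frame(t, total = total, alt_ratio = t$alt_count / total,
               p_value = p, adjusted_p = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls$direction <- ifelse(calls$alt_ratio >= 0.5, "alt_biased", "ref_biased")
  major <- pmax(calls$alt_ratio, 1 - calls$alt_ratio)
  calls$ratio_extreme <- major > ratio_cutoff
  calls$significant <- calls$adjusted_p < padj_cutoff
  calls$is_flagged <- calls$ratio_extreme & calls$significant
  calls$review <- major > review_cutoff
  structure(list(calls = calls, rho = rho, ratio_cutoff = ratio_cutoff,
                 padj_cutoff = padj_cutoff), class = "ase_screen")
}

#' @export
print.ase_screen <- function(x, ...) {
  cat("Allele-specific expression screen\n")
  cat(sprintf("  null overdispersion rho: %.4g\n", x$rho))
  if (nrow(x$calls)) {
    cat(sprintf("  sites tested: %d; flagged: %d; review tier: %d\n",
                nrow(x$calls), sum(x$calls$is_flagged), sum(x$calls$review)))
  } else cat("  no testable rare heterozygous sites\n")
  invisible(x)
}

#' @export
summary.ase_screen <- function(object, n = 10, ...) {
  print(object)
  out <- object$calls[object$calls$is_flagged | object$calls$review, ]
  out <- out[order(out$adjusted_p), ]
  cat(sprintf("\nTop %d imbalanced sites:\n", min(n, nrow(out))))
  print(utils::head(out[, c("sample_id", "chrom", "pos", "gene_id",
                            "ref_count", "alt_count", "alt_ratio",
                            "adjusted_p", "direction", "is_flagged")], n),
        row.names = FALSE)
  invisible(out)
}
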