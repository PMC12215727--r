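test_that("read filter is strictly greater-than", {
  t1 <- jt("S1", 1, c(100, 300, 500), c(200, 400, 600), 1, c(5, 6, 0))
  out <- filter_junctions(t1)
  expect_identical(out$intron_start, 300L)  # 5 removed, 6 kept, 0 removed
  expect_identical(nrow(filter_junctions(jt("S1", 1, 100, 200, 1, 0))), 0L)

  set.seed(40)
  tbl <- jt("S1", 1, 1:1000, 2001:3000, 1, sample(0:20, 1000, TRUE))
  expect_identical(filter_junctions(tbl)$intron_start,
                   tbl$intron_start[tbl$unique_reads > 5])
})

test_that("junction groups match brute-force shared-end computation", {
  ## A(100-200), B(100-300), same + strand: one shared donor group at 100
  u <- jt("x", 1, c(100, 100), c(200, 300), 1, c(1, 1))[-1][-5]
  grp <- build_junction_groups(u)
  donor_members <- grp$groups[[grp$donor_group[1]]]
  expect_setequal(donor_members, c(1, 2))
  expect_identical(grp$groups[[grp$acceptor_group[1]]], 1L)
  expect_identical(grp$groups[[grp$acceptor_group[2]]], 2L)

  ## disjoint junctions: all groups singletons
  u2 <- jt("x", 1, c(100, 500), c(200, 900), 1, c(1, 1))[-1][-5]
  grp2 <- build_junction_groups(u2)
  expect_true(all(lengths(grp2$groups) == 1))

  ## brute force: j and k share a group iff they share an end with the same
  ## role (donor/acceptor by strand; both roles for strand 0)
  set.seed(41)
  n <- 500
  u3 <- data.frame(chrom = sample(c("1", "2"), n, TRUE),
                   intron_start = sample(100:150, n, TRUE) * 10L,
                   intron_end = integer(n), strand_code = sample(0:2, n, TRUE))
  u3$intron_end <- u3$intron_start + sample(100:150, n, TRUE) * 10L
  u3 <- unique(u3)
  grp3 <- build_junction_groups(u3)
  partners <- rnadx:::shared_partners(grp3)
  ends_of <- function(i) {
    s <- u3$strand_code[i]
    if (s == 0)
      return(list(c(u3$intron_start[i], "unknown"),
                  c(u3$intron_end[i], "unknown")))
    donor <- if (s == 2) u3$intron_end[i] else u3$intron_start[i]
    acceptor <- if (s == 2) u3$intron_start[i] else u3$intron_end[i]
    list(c(donor, "donor"), c(acceptor, "acceptor"))
  }
  for (i in sample(nrow(u3), 50)) {
    ei <- ends_of(i)
    brute <- which(vapply(seq_len(nrow(u3)), function(k) {
      if (u3$chrom[k] != u3$chrom[i]) return(FALSE)
      ek <- ends_of(k)
      any(vapply(ei, function(a) any(vapply(ek, function(b)
        identical(a, b), logical(1))), logical(1)))
    }, logical(1)))
    expect_setequal(partners[[i]], brute)
  }
})

test_that("coverage scores reproduce the worked ratio and brute force", {
  ## 65 reads on the junction of interest, 9 on its sole partner -> 65/74
  u <- jt("x", 1, c(100, 100), c(200, 300), 1, c(1, 1))[-1][-5]
  grp <- build_junction_groups(u)
  cnt <- matrix(c(65, 9), nrow = 2, dimnames = list(NULL, "S1"))
  sc <- junction_coverage_score(cnt, grp)
  expect_equal(unname(sc[1, 1]), 65 / 74, tolerance = 1e-12)
  expect_equal(unname(round(sc[1, 1], 2)), 0.88)
  ## literal "other junctions" mode excludes the junction itself
  sc_lit <- junction_coverage_score(cnt, grp, include_self = FALSE)
  expect_equal(unname(sc_lit[1, 1]), 65 / 9, tolerance = 1e-12)

  ## a junction alone at both sites scores 1
  u1 <- jt("x", 1, 100, 200, 1, 1)[-1][-5]
  g1 <- build_junction_groups(u1)
  expect_equal(junction_coverage_score(matrix(7, 1, 1), g1)[1, 1], 1)
  ## denominator 0 -> NA
  expect_true(is.na(junction_coverage_score(matrix(0, 1, 1), g1)[1, 1]))

  set.seed(42)
  n <- 80
  u4 <- data.frame(chrom = "1",
                   intron_start = sample(10:25, n, TRUE) * 100L,
                   intron_end = integer(n), strand_code = 1L)
  u4$intron_end <- u4$intron_start + sample(10:25, n, TRUE) * 100L
  u4 <- unique(u4)
  grp4 <- build_junction_groups(u4)
  cnt4 <- matrix(rpois(nrow(u4) * 12, 20), nrow = nrow(u4),
                 dimnames = list(NULL, sprintf("S%02d", 1:12)))
  sc4 <- junction_coverage_score(cnt4, grp4)
  for (rep in 1:1000) {
    j <- sample(nrow(u4), 1); s <- sample(12, 1)
    shared <- which((u4$intron_start == u4$intron_start[j]) |
                      (u4$intron_end == u4$intron_end[j]))
    expect_equal(sc4[j, s], cnt4[j, s] / sum(cnt4[shared, s]))
  }
  expect_true(all(sc4 >= 0 & sc4 <= 1, na.rm = TRUE))
})

test_that("scores over a closed group sum to 1 and ignore depth scaling", {
  ## all members share the donor site; acceptor groups are singletons
  u <- jt("x", 1, c(100, 100, 100), c(200, 300, 400), 1, 1)[-1][-5]
  grp <- build_junction_groups(u)
  cnt <- matrix(c(10, 30, 60, 2, 3, 5), nrow = 3,
                dimnames = list(NULL, c("S1", "S2")))
  sc <- junction_coverage_score(cnt, grp)
  expect_equal(colSums(sc), c(S1 = 1, S2 = 1))
  sc_scaled <- junction_coverage_score(cnt * 5, grp)
  expect_equal(sc, sc_scaled)
})

test_that("cohort z-scores match brute force and skip degenerate junctions", {
  set.seed(43)
  scores <- matrix(runif(20 * 15), nrow = 20)
  scores[3, ] <- 0.5  # constant -> sd 0 -> skipped
  scores[4, 1:10] <- NA  # only 5 defined -> below min_samples
  z <- junction_zscores(scores, min_samples = 10)
  expect_true(all(is.na(z[3, ])))
  expect_true(all(is.na(z[4, ])))
  for (j in c(1, 2, 5, 20)) {
    expect_equal(z[j, ], (scores[j, ] - mean(scores[j, ])) / sd(scores[j, ]))
  }
})

test_that("planted usage shifts are flagged at |z| >= 2", {
  p <- sim_params(n_samples = 60, n_genes = 300, n_ase_sites = 0,
                  n_junction_groups = 120,
                  splice_outliers = list(n = 50, target_usage = 0.88),
                  seed = 44)
  coh <- simulate_cohort(p)
  scr <- run_splicing_stage(coh$junctions)
  tr <- coh$truth[coh$truth$modality == "splicing", ]
  key <- paste(scr$calls$sample_id, scr$calls$junction)
  hit <- scr$calls$is_outlier[match(paste(tr$sample_id, tr$feature_id), key)]
  ## restrict to events that actually shift usage by >= 0.25
  baseline <- coh$junction_groups$baseline_usage[
    match(tr$feature_id,
          sprintf("%s:%d-%d:%d", coh$junction_groups$chrom,
                  coh$junction_groups$intron_start,
                  coh$junction_groups$intron_end,
                  coh$junction_groups$strand_code))]
  big <- abs(0.88 - baseline) >= 0.25
  expect_gt(sum(big), 25)
  expect_gte(mean(hit[big], na.rm = TRUE), 0.8)
})

test_that("null cohorts flag few junction x sample pairs", {
  p <- sim_params(n_samples = 60, n_genes = 300, n_ase_sites = 0,
                  n_junction_groups = 120, seed = 45)
  scr <- run_splicing_stage(simulate_cohort(p)$junctions)
  expect_lte(mean(abs(scr$calls$z_score) >= 2), 0.05)
})

test_that("event classification follows the annotation rules", {
  ex <- six_exon_model()
  ## skip exons 4 and 5: exon3 end (600) to exon6 start (1100)
  expect_identical(classify_event("1", 601, 1099, 1, ex), "exon_skip")
  ## acceptor 5 bp into exon 4
  expect_identical(classify_event("1", 601, 704, 1, ex), "alt_acceptor")
  ## same geometry on the minus strand: the unannotated end is the donor
  expect_identical(classify_event("1", 601, 704, 2, ex), "alt_donor")
  ## canonical intron 3: unclassified unless intronic coverage is elevated
  expect_identical(classify_event("1", 601, 699, 1, ex), "unclassified")
  expect_identical(classify_event("1", 601, 699, 1, ex,
                                  elevated_intronic = TRUE),
                   "intron_retention_flank")
  ## cryptic exon inside intron 3 (601-699 region has no annotated exon)
  expect_identical(classify_event("1", 610, 680, 1, ex), "novel_exon")
  ## both ends exactly at one exon's boundaries: degenerate, not an event
  expect_identical(classify_event("1", 700, 800, 1, ex), "unclassified")
  ## no exon model for the chromosome
  expect_identical(classify_event("2", 601, 1099, 1, ex), "unclassified")
})

test_that("the splicing stage is robust to empty input", {
  empty <- list(S1 = jt("S1", 1, 100, 200, 1, 2)[0, ],
                S2 = jt("S2", 1, 100, 200, 1, 2)[0, ])
  scr <- run_splicing_stage(empty)
  expect_s3_class(scr, "splice_screen")
  expect_identical(nrow(scr$calls), 0L)
})
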