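test_that("null cohort has empty truth and is seed-reproducible", {
  p <- sim_params(n_samples = 10, n_genes = 200, n_female = 5,
                  n_junction_groups = 20, n_ase_sites = 30, seed = 42)
  coh1 <- simulate_cohort(p)
  expect_identical(nrow(coh1$truth), 0L)

  coh2 <- simulate_cohort(p)
  expect_identical(coh1$counts, coh2$counts)
  expect_identical(coh1$junctions, coh2$junctions)
  expect_identical(coh1$ase, coh2$ase)
  expect_identical(coh1$annotation, coh2$annotation)

  p3 <- sim_params(n_samples = 10, n_genes = 200, n_female = 5,
                   n_junction_groups = 20, n_ase_sites = 30, seed = 43)
  coh3 <- simulate_cohort(p3)
  expect_false(identical(coh1$counts, coh3$counts))
})

test_that("simulated counts match the NB generating model by moments", {
  ## 30 x 2000 null cohort: per-gene variance of normalized counts should
  ## exceed the Poisson floor and the excess CV^2 should recover the median
  ## planted dispersion
  p <- sim_params(n_samples = 30, n_genes = 2000, n_female = 15,
                  n_junction_groups = 0, n_ase_sites = 0,
                  hemoglobin_fraction = 0, x_male_ratio = 1,
                  size_factor_sdlog = 0, seed = 7)
  coh <- simulate_cohort(p)
  m <- rowMeans(coh$counts)
  v <- apply(coh$counts, 1, var)
  hi <- m > 100
  expect_gt(sum(hi), 300)
  phi_hat <- (v[hi] - m[hi]) / m[hi]^2
  ## median planted phi is exp(location) = 0.01 with lognormal scale 1
  expect_gt(median(phi_hat), 0.01 / 3)
  expect_lt(median(phi_hat), 0.01 * 3)
  ## overdispersion present in the clear majority of well-expressed genes
  expect_gt(mean(v[hi] > m[hi]), 0.7)
})

test_that("hemoglobin-like genes consume the configured library fraction", {
  p <- sim_params(n_samples = 20, n_genes = 1000, n_female = 10,
                  hemoglobin_fraction = 0.4, n_junction_groups = 0,
                  n_ase_sites = 0, seed = 8)
  coh <- simulate_cohort(p)
  hb <- coh$annotation$gene_id[coh$annotation$symbol %in% hemoglobin_genes()]
  frac <- colSums(coh$counts[hb, ]) / colSums(coh$counts)
  expect_true(all(abs(frac - 0.4) < 0.05))
})

test_that("plant_cnv_effect scales a penetrant subset and records truth", {
  set.seed(9)
  ann <- tiny_annotation(sprintf("G%02d", 1:40), chrom = "5")
  m <- matrix(1000, nrow = 40, ncol = 3,
              dimnames = list(ann$gene_id, c("S1", "S2", "S3")))
  ## interval covering the first 34 genes
  end_bp <- ann$end_bp[34]
  res <- plant_cnv_effect(m, ann, "S2", "5", 1, end_bp, copy_number = 1,
                          penetrance = 1)
  expect_true(all(res$counts[1:34, "S2"] == 500))
  expect_true(all(res$counts[35:40, "S2"] == 1000))
  expect_true(all(res$counts[, c("S1", "S3")] == 1000))

  ## penetrance 0.7 of 34 covered genes -> 24 affected genes in truth
  res2 <- plant_cnv_effect(m, ann, "S2", "5", 1, end_bp, copy_number = 1,
                           penetrance = 0.7)
  expect_identical(nrow(res2$truth), 24L)
  expect_identical(sum(res2$counts[, "S2"] == 500), 24L)
  expect_setequal(res2$truth$feature_id,
                  rownames(m)[res2$counts[, "S2"] == 500])

  expect_error(plant_cnv_effect(m, ann, "S2", "5", 1, end_bp, 2), "not a CNV")
  expect_error(plant_cnv_effect(m, ann, "S2", "5", 1, end_bp, 1,
                                penetrance = 1.2), "penetrance")
  expect_error(plant_cnv_effect(m, ann, "S2", "9", 1, end_bp, 1),
               "no annotated gene")
})

test_that("plant_splice_event hits the target usage and conserves reads", {
  ## 74 reads in a 2-junction group shifted to 88% usage -> 65 reads
  out <- plant_splice_event(c(40L, 34L), 1, 0.88)
  expect_identical(out, c(65L, 9L))
  expect_identical(sum(out), 74L)

  expect_error(plant_splice_event(c(10L, 10L), 1, 1.2), "strictly inside")
  expect_error(plant_splice_event(c(10L, 10L), 1, 0), "strictly inside")

  set.seed(10)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    counts <- as.integer(rpois(k, 40))
    tgt <- runif(1, 0.05, 0.95)
    j <- sample(k, 1)
    out <- plant_splice_event(counts, j, tgt)
    expect_identical(sum(out), sum(counts))
    expect_true(all(out >= 0))
    expect_equal(out[j], round(tgt * sum(counts)))
  }
})

test_that("planted events reference real features or fail loudly", {
  p <- sim_params(n_samples = 5, n_genes = 50, n_female = 2,
                  n_junction_groups = 5, n_ase_sites = 10,
                  expression_outliers = data.frame(gene = "NOPE",
                                                   sample = "S001",
                                                   fold_change = 2),
                  seed = 1)
  expect_error(simulate_cohort(p), "unknown gene")
  p2 <- sim_params(n_samples = 5, n_genes = 50, n_female = 2,
                   n_junction_groups = 5, n_ase_sites = 10,
                   cnvs = data.frame(sample = "S099", chrom = "1",
                                     start_bp = 1, end_bp = 1e6,
                                     copy_number = 1, penetrance = 1),
                   seed = 1)
  expect_error(simulate_cohort(p2), "unknown sample")
})

test_that("planted truth ledger is complete and unique", {
  p <- sim_params(n_samples = 20, n_genes = 500, n_female = 10,
                  n_junction_groups = 30, n_ase_sites = 50,
                  expression_outliers = list(n = 6, log2fc = c(-1, 1),
                                             min_mean = 50),
                  splice_outliers = list(n = 4, target_usage = 0.9),
                  ase_outliers = list(n = 5, alt_ratio = 0.95, depth = 60),
                  seed = 11)
  coh <- simulate_cohort(p)
  expect_identical(sum(coh$truth$modality == "expression"), 6L)
  expect_identical(sum(coh$truth$modality == "splicing"), 4L)
  expect_lte(sum(coh$truth$modality == "ase"), 5L)
  key <- with(coh$truth, paste(modality, sample_id, feature_id))
  expect_identical(anyDuplicated(key), 0L)
})

test_that("a cohort writes to disk and reads back through core readers", {
  p <- sim_params(n_samples = 6, n_genes = 100, n_female = 3,
                  n_junction_groups = 10, n_ase_sites = 15,
                  cnvs = data.frame(sample = "S002", chrom = "1",
                                    start_bp = 1, end_bp = 400000,
                                    copy_number = 1, penetrance = 1),
                  seed = 12)
  coh <- simulate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  counts <- read_counts_table(file.path(dir, "counts.tsv"))
  expect_identical(counts, coh$counts)
  ann <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann$gene_id, coh$annotation$gene_id)
  cnv <- read_cnv_bed(file.path(dir, "cnvs.bed"))
  expect_identical(cnv$start_bp, coh$cnv$start_bp)
  expect_identical(cnv$end_bp, coh$cnv$end_bp)
  j <- read_star_junctions(file.path(dir, "junctions", "S001.SJ.out.tab"),
                           "S001")
  expect_equal(j[-1], coh$junctions$S001[-1], ignore_attr = TRUE)
  a <- read_allele_counts(file.path(dir, "ase", "S001.tsv"))
  expect_equal(a$ref_count, coh$ase$S001$ref_count)
})
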