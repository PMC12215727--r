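# Small in-code fixtures shared across test files.

tiny_annotation <- function(gene_ids, chrom = "1", len = 1000L,
                            symbol = gene_ids) {
  n <- length(gene_ids)
  data.frame(gene_id = gene_ids, symbol = symbol,
             chrom = rep_len(chrom, n),
             start_bp = seq(1L, by = 100000L, length.out = n),
             end_bp = seq(1L, by = 100000L, length.out = n) + 49999L,
             strand = "+", exonic_length_bp = rep_len(len, n),
             biotype = "protein_coding", disease_associated = FALSE,
             hpo_terms = I(replicate(n, character(0), simplify = FALSE)),
             stringsAsFactors = FALSE)
}

random_counts <- function(n_genes, n_samples, mu = 50, phi = 0.05) {
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / phi),
              nrow = n_genes,
              dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

## six-exon gene model on chromosome "1" for junction classification tests
six_exon_model <- function() {
  data.frame(gene_id = "GENE1", chrom = "1",
             start = c(100, 300, 500, 700, 900, 1100),
             end = c(200, 400, 600, 800, 1000, 1200),
             stringsAsFactors = FALSE)
}

## minimal one-sample junction table
jt <- function(sample_id, chrom, start, end, strand, reads) {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             intron_start = as.integer(start), intron_end = as.integer(end),
             strand_code = as.integer(strand),
             unique_reads = as.integer(reads), stringsAsFactors = FALSE)
}

## minimal allele-count table
ase_table <- function(sample_id, chrom, pos, ref, alt, ref_count, alt_count,
                      gene_id = "G00001") {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             pos = as.integer(pos), ref = ref, alt = alt,
             ref_count = as.integer(ref_count),
             alt_count = as.integer(alt_count),
             gene_id = gene_id, stringsAsFactors = FALSE)
}
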