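## Readers and writers for every external format the pipeline touches.
##
## Coordinate convention: 1-based inclusive everywhere inside the package
## (matching STAR SJ.out.tab and cytogenetic interval notation). BED is the
## only 0-based half-open surface and is converted on read/write.
## All writers emit UTF-8, LF line endings, tab-delimited, deterministically.

#' Read a gene-by-sample read-count matrix
#'
#' Parses a TSV whose header row holds sample identifiers and whose first
#' column holds gene identifiers. Counts must be non-negative and integral;
#' fractional expected counts (e.g. from RSEM) are accepted only with
#' `round = TRUE`, in which case they are rounded to the nearest integer on
#' ingest.
#'
#' @param path Path to a tab-delimited counts file.
#' @param round Round fractional counts to integers instead of rejecting
#'   them. Default `FALSE`.
#' @return An integer matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_counts_table <- function(path, round = FALSE) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = ""),
    error = function(e) io_stop(path, "?", "table", "unreadable counts TSV: %s",
                                conditionMessage(e)))
  if (ncol(df) < 2)
    io_stop(path, 1, "header", "expected gene id column plus >=1 sample column")
  gene_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    io_stop(path, "multiple", "gene_id", "duplicated gene id(s): %s",
            paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    io_stop(path, 1, "sample_id", "duplicated sample id(s): %s",
            paste(dup_s, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    io_stop(path, "?", "counts", "non-numeric count cells present")
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    io_stop(path, bad[1, 1] + 1, sample_ids[bad[1, 2]],
            "negative or non-finite count for gene '%s'", gene_ids[bad[1, 1]])
  if (!all(is_wholenumber(m))) {
    if (round) {
      m <- round(m)
    } else {
      frac <- which(!is_wholenumber(m), arr.ind = TRUE)
      io_stop(path, frac[1, 1] + 1, sample_ids[frac[1, 2]],
              "non-integer count for gene '%s' (use round = TRUE for expected counts)",
              gene_ids[frac[1, 1]])
    }
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, sample_ids)
  validate_counts(m)
}

#' Validate a counts matrix
#'
#' Checks the invariants every downstream stage assumes: unique gene and
#' sample identifiers, non-negative integral counts, consistent dimensions.
#' Returns the matrix invisibly unchanged so it can be chained.
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene ids in counts matrix")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample ids in counts matrix")
  if (any(counts < 0) || !all(is_wholenumber(counts)))
    stopf("counts must be non-negative integers")
  invisible(counts)
}

#' Write a counts matrix as TSV
#' @param counts Validated counts matrix.
#' @param path Output path.
#' @export
write_counts_table <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a STAR SJ.out.tab junction file
#'
#' Parses the 9-column whitespace-delimited STAR splice-junction dialect:
#' chromosome, intron first base (1-based), intron last base (1-based),
#' strand code (0 undefined, 1 plus, 2 minus), intron motif, annotation flag,
#' uniquely mapping reads, multimapping reads, maximum overhang. Columns
#' 1-4 and 7 are kept; multimapping reads are discarded (uniquely mapped
#' reads are the unit of all downstream statistics).
#'
#' @param path Path to an SJ.out.tab-style file.
#' @param sample_id Sample identifier to attach to every row.
#' @return A data.frame with columns sample_id, chrom, intron_start,
#'   intron_end, strand_code, unique_reads. Empty file gives zero rows.
#' @export
read_star_junctions <- function(path, sample_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_junction_table(sample_id))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 9))
    io_stop(path, which(nf < 9)[1], "columns",
            "expected 9 whitespace-delimited columns, found %d", min(nf))
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (any(!is.finite(num)))
    io_stop(path, which(rowSums(!is.finite(num)) > 0)[1], "numeric",
            "non-numeric value in numeric column")
  jt <- data.frame(sample_id = sample_id,
                   chrom = m[, 1],
                   intron_start = as.integer(num[, 1]),
                   intron_end = as.integer(num[, 2]),
                   strand_code = as.integer(num[, 3]),
                   unique_reads = as.integer(num[, 6]),
                   stringsAsFactors = FALSE)
  if (any(jt$unique_reads < 0))
    io_stop(path, which(jt$unique_reads < 0)[1], "unique_reads",
            "negative unique read count")
  if (any(jt$intron_start > jt$intron_end))
    io_stop(path, which(jt$intron_start > jt$intron_end)[1], "intron_start",
            "intron start exceeds intron end")
  if (!all(jt$strand_code %in% 0:2))
    io_stop(path, which(!jt$strand_code %in% 0:2)[1], "strand_code",
            "strand code must be 0, 1 or 2")
  key <- paste(jt$chrom, jt$intron_start, jt$intron_end, jt$strand_code)
  if (anyDuplicated(key))
    io_stop(path, which(duplicated(key))[1], "junction",
            "duplicated junction row")
  jt
}

empty_junction_table <- function(sample_id = character(0)) {
  data.frame(sample_id = character(0), chrom = character(0),
             intron_start = integer(0), intron_end = integer(0),
             strand_code = integer(0), unique_reads = integer(0),
             stringsAsFactors = FALSE)
}

#' Write a junction table in the STAR SJ.out.tab dialect
#'
#' Columns the package does not track (motif, annotation flag, multimapping
#' reads, overhang) are written as zeros.
#' @param junctions Junction table as returned by [read_star_junctions()].
#' @param path Output path.
#' @export
write_star_junctions <- function(junctions, path) {
  out <- data.frame(junctions$chrom, junctions$intron_start,
                    junctions$intron_end, junctions$strand_code,
                    0L, 0L, junctions$unique_reads, 0L, 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read CNV calls from a BED-like file
#'
#' Expects 5 columns without header: chrom, start (0-based), end (half-open),
#' sample id, copy number. Intervals are converted to the internal 1-based
#' inclusive convention on read. Copy number 2 is rejected: a reported CNV is
#' by definition a departure from the diploid state.
#'
#' @param path Path to BED-like CNV file.
#' @param annotation Optional gene annotation; when given, chromosome labels
#'   are normalized to the annotation's convention and unknown chromosomes
#'   are rejected.
#' @return data.frame with columns sample_id, chrom, start_bp, end_bp,
#'   copy_number (1-based inclusive coordinates).
#' @export
read_cnv_bed <- function(path, annotation = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      copy_number = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 5))
    io_stop(path, which(nf < 5)[1], "columns", "expected 5 columns, found %d",
            min(nf))
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  cn <- suppressWarnings(as.numeric(m[, 5]))
  if (any(!is.finite(start0)) || any(!is.finite(end0)))
    io_stop(path, which(!is.finite(start0) | !is.finite(end0))[1], "start/end",
            "non-numeric interval bound")
  bad <- which(end0 < start0)
  if (length(bad))
    io_stop(path, bad[1], "end", "interval end %d < start %d",
            end0[bad[1]], start0[bad[1]])
  if (any(!is.finite(cn) | !is_wholenumber(cn) | cn < 0 | cn > 4))
    io_stop(path, which(!cn %in% 0:4)[1], "copy_number",
            "copy number must be an integer in 0..4")
  if (any(cn == 2))
    io_stop(path, which(cn == 2)[1], "copy_number",
            "copy number 2 is not a CNV")
  conv <- bed_to_internal(as.integer(start0), as.integer(end0))
  chrom <- m[, 1]
  if (!is.null(annotation)) {
    chrom <- normalize_chrom(chrom, annotation$chrom)
    unknown <- setdiff(unique(chrom), unique(annotation$chrom))
    if (length(unknown))
      io_stop(path, "?", "chrom", "chromosome(s) absent from annotation: %s",
              paste(unknown, collapse = ", "))
  }
  data.frame(sample_id = m[, 4], chrom = chrom,
             start_bp = conv$start, end_bp = conv$end,
             copy_number = as.integer(cn), stringsAsFactors = FALSE)
}

#' Write CNV calls as BED
#' @param cnv CNV table in internal coordinates.
#' @param path Output path.
#' @export
write_cnv_bed <- function(cnv, path) {
  conv <- internal_to_bed(cnv$start_bp, cnv$end_bp)
  out <- data.frame(cnv$chrom, conv$start, conv$end, cnv$sample_id,
                    cnv$copy_number)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read per-site allele counts
#'
#' TSV with header CHROM, POS, REF, ALT, REF_COUNT, ALT_COUNT, GENE, SAMPLE
#' (the shape produced by tabulating GATK ASEReadCounter output per sample).
#' @param path Path to allele-count TSV.
#' @return data.frame with columns sample_id, chrom, pos, ref, alt,
#'   ref_count, alt_count, gene_id.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "REF_COUNT", "ALT_COUNT", "GENE",
            "SAMPLE")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    io_stop(path, 1, paste(miss, collapse = ","), "missing required column(s)")
  if (any(df$REF == df$ALT))
    io_stop(path, which(df$REF == df$ALT)[1] + 1, "REF/ALT",
            "reference and alternate allele identical")
  for (col in c("REF_COUNT", "ALT_COUNT", "POS")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is_wholenumber(v)) || any(v < 0))
      io_stop(path, "?", col, "must be non-negative integers")
  }
  data.frame(sample_id = as.character(df$SAMPLE), chrom = as.character(df$CHROM),
             pos = as.integer(df$POS), ref = df$REF, alt = df$ALT,
             ref_count = as.integer(df$REF_COUNT),
             alt_count = as.integer(df$ALT_COUNT),
             gene_id = as.character(df$GENE), stringsAsFactors = FALSE)
}

#' Write allele counts as TSV
#' @param sites Allele-count table as from [read_allele_counts()].
#' @param path Output path.
#' @export
write_allele_counts <- function(sites, path) {
  out <- data.frame(CHROM = sites$chrom, POS = sites$pos, REF = sites$ref,
                    ALT = sites$alt, REF_COUNT = sites$ref_count,
                    ALT_COUNT = sites$alt_count, GENE = sites$gene_id,
                    SAMPLE = sites$sample_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read the reduced gene annotation table
#'
#' TSV with header gene_id, symbol, chrom, start_bp, end_bp, strand,
#' exonic_length_bp, biotype, disease_associated, hpo_terms. Coordinates are
#' 1-based inclusive; hpo_terms is a `;`-separated list of HP:NNNNNNN
#' identifiers (may be empty).
#' @param path Path to annotation TSV.
#' @return data.frame, one row per gene; `hpo_terms` is a list column of
#'   character vectors.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(hpo_terms = "character"))
  need <- c("gene_id", "symbol", "chrom", "start_bp", "end_bp", "strand",
            "exonic_length_bp", "biotype", "disease_associated", "hpo_terms")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    io_stop(path, 1, paste(miss, collapse = ","), "missing required column(s)")
  if (anyDuplicated(df$gene_id))
    io_stop(path, "?", "gene_id", "duplicated gene id(s): %s",
            paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- which(df$start_bp > df$end_bp)
  if (length(bad))
    io_stop(path, bad[1] + 1, "start_bp", "gene '%s' has start > end",
            df$gene_id[bad[1]])
  if (any(df$exonic_length_bp < 1))
    io_stop(path, which(df$exonic_length_bp < 1)[1] + 1, "exonic_length_bp",
            "exonic length must be >= 1")
  if (!all(df$strand %in% c("+", "-")))
    io_stop(path, which(!df$strand %in% c("+", "-"))[1] + 1, "strand",
            "strand must be '+' or '-'")
  terms <- split_hpo(df$hpo_terms)
  bad_terms <- unique(unlist(terms)[!is_hpo_id(unlist(terms))])
  if (length(bad_terms))
    io_stop(path, "?", "hpo_terms", "malformed HPO id(s): %s",
            paste(bad_terms, collapse = ", "))
  df$hpo_terms <- terms
  df$disease_associated <- as.logical(df$disease_associated)
  df
}

#' Write a gene annotation table
#' @param annotation Annotation data.frame (hpo_terms may be a list column).
#' @param path Output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- annotation
  if (is.list(out$hpo_terms)) out$hpo_terms <- collapse_hpo(out$hpo_terms)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with header sample_id, sex, hpo_terms, batch. Sex must be one of
#' male/female/unknown.
#' @param path Path to metadata TSV.
#' @param counts Optional counts matrix; when given, sample ids must match.
#' @return data.frame with `hpo_terms` as a list column.
#' @export
read_sample_metadata <- function(path, counts = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(hpo_terms = "character"))
  need <- c("sample_id", "sex", "hpo_terms", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    io_stop(path, 1, paste(miss, collapse = ","), "missing required column(s)")
  if (!all(df$sex %in% c("male", "female", "unknown")))
    io_stop(path, which(!df$sex %in% c("male", "female", "unknown"))[1] + 1,
            "sex", "sex must be male, female or unknown")
  df$hpo_terms <- split_hpo(df$hpo_terms)
  if (!is.null(counts)) {
    if (!setequal(df$sample_id, colnames(counts)))
      io_stop(path, "?", "sample_id",
              "metadata sample ids do not match counts matrix")
  }
  df
}

#' Write sample metadata
#' @param metadata Metadata data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  if (is.list(out$hpo_terms)) out$hpo_terms <- collapse_hpo(out$hpo_terms)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write outlier calls as TSV
#'
#' One row per call with a fixed column order; byte-identical output for
#' identical input.
#' @param calls data.frame of calls from any modality.
#' @param path Output path.
#' @export
write_outliers_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
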