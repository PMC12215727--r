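## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Formatted stop()/warning() without call noise
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Error for malformed external files: always names file, line and field.
io_stop <- function(file, line, field, fmt, ...) {
  stopf("%s (file '%s', line %s, field '%s')", sprintf(fmt, ...),
        file, as.character(line), field)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

geomean <- function(x) exp(mean(log(x)))

## BED (0-based half-open) <-> internal (1-based inclusive) conversion.
## The single conversion point for the whole package; a bijection on
## non-degenerate intervals.
bed_to_internal <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}
internal_to_bed <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

## Normalize chromosome labels to the convention used by a reference set
## ("chr1" vs "1"). Mixed dialects are the most common silent join failure.
normalize_chrom <- function(x, reference) {
  x <- as.character(x)
  ref_has_prefix <- any(startsWith(as.character(reference), "chr"))
  bare <- sub("^chr", "", x)
  if (ref_has_prefix) paste0("chr", bare) else bare
}

## HPO identifier syntax
is_hpo_id <- function(x) grepl("^HP:[0-9]{7}$", x)

## "HP:0000001;HP:0000002" -> character vector; "" -> character(0)
split_hpo <- function(x) {
  out <- strsplit(as.character(x), "[;,]\\s*")
  lapply(out, function(v) v[nzchar(v)])
}
collapse_hpo <- function(terms) {
  vapply(terms, function(v) paste(v, collapse = ";"), character(1))
}
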