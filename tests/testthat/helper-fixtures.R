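# Fixture builders shared across test files. Everything is generated in
# code at test time; GenBank texts are written to tempfiles.

# Formats a raw sequence string as GenBank ORIGIN lines.
originBlock <- function(seqTxt) {
  seqTxt <- tolower(seqTxt)
  out <- character()
  for (p in seq(1L, nchar(seqTxt), by = 60L)) {
    chunk <- substr(seqTxt, p, min(p + 59L, nchar(seqTxt)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out
}

# One LOCUS entry with arbitrary feature lines.
genbankEntry <- function(accession, organismName, seqTxt,
                         featureLines = character(), circular = FALSE) {
  c(sprintf("LOCUS       %-16s %d bp    DNA     %s   BCT 01-JAN-2000",
            accession, nchar(seqTxt), if (circular) "circular" else "linear"),
    sprintf("DEFINITION  %s chromosome, complete sequence.", organismName),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organismName),
    sprintf("  ORGANISM  %s", organismName),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seqTxt)),
    featureLines,
    "ORIGIN",
    originBlock(seqTxt),
    "//")
}

writeGenBankText <- function(lines) {
  path <- tempfile(fileext = ".gbk")
  writeLines(lines, path)
  path
}

cdsFeature <- function(location, product = "hypothetical protein",
                       codonStart = NULL, pseudo = FALSE) {
  out <- c(sprintf("     CDS             %s", location),
           sprintf('                     /product="%s"', product))
  if (!is.null(codonStart))
    out <- c(out, sprintf("                     /codon_start=%d", codonStart))
  if (pseudo) out <- c(out, "                     /pseudo")
  out
}

# Deterministic random DNA string.
randomDna <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# A grouping TSV on disk.
writeGroupingTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal record without file round-trip.
makeRecord <- function(seqTxt, cdsList = list(), accession = "TST_1",
                       organismName = "Testus exampli", circular = FALSE) {
  if (length(cdsList)) {
    cds <- S4Vectors::DataFrame(
      start = vapply(cdsList, function(x) min(x$parts[, 1]), numeric(1)),
      end = vapply(cdsList, function(x) max(x$parts[, 2]), numeric(1)),
      strand = vapply(cdsList, function(x) x$strand %||% "+", character(1)),
      product = vapply(cdsList, function(x) x$product %||% "hypothetical protein",
                       character(1)),
      codonStart = vapply(cdsList, function(x) as.integer(x$codonStart %||% 1L),
                          integer(1)),
      pseudo = vapply(cdsList, function(x) isTRUE(x$pseudo), logical(1)),
      parts = IRanges::IRangesList(lapply(cdsList, function(x)
        IRanges::IRanges(x$parts[, 1], x$parts[, 2])))
    )
  } else cds <- NULL
  ChromosomeRecord(accession, organismName, seqTxt,
                   topology = if (circular) "circular" else "linear",
                   cds = cds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
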