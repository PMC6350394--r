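#' @include AllGenerics.R
NULL

#' Construct a ChromosomeRecord
#'
#' Low-level constructor; most users obtain records from [readGenBank()] or
#' [generateChromosome()].
#'
#' @param accession replicon identifier.
#' @param organism organism name.
#' @param sequence a [Biostrings::DNAString] or a character string.
#' @param genus genus label; defaults to the first whitespace-delimited token
#'   of `organism`.
#' @param topology "linear" or "circular".
#' @param isPlasmid logical flag.
#' @param cds a DataFrame of CDS features (see [ChromosomeRecord-class]);
#'   `NULL` for none.
#' @param skippedFeatures count of features skipped during parsing.
#' @return a [ChromosomeRecord-class] object.
#' @examples
#' rec <- ChromosomeRecord("X1", "Examplea demo", "ATGCATGC")
#' genomeSize(rec)
#' @export
ChromosomeRecord <- function(accession, organism, sequence,
                             genus = NULL, topology = "linear",
                             isPlasmid = FALSE, cds = NULL,
                             skippedFeatures = 0L) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  if (is.null(genus)) {
    genus <- strsplit(trimws(organism), "\\s+")[[1]][1]
    if (is.na(genus)) genus <- ""
  }
  if (is.null(cds)) cds <- emptyCdsTable()
  new("ChromosomeRecord",
      accession = as.character(accession), organism = as.character(organism),
      genus = as.character(genus), sequence = sequence,
      topology = topology, isPlasmid = isPlasmid, cds = cds,
      skippedFeatures = as.integer(skippedFeatures))
}

emptyCdsTable <- function() {
  S4Vectors::DataFrame(
    start = integer(), end = integer(), strand = character(),
    product = character(), codonStart = integer(), pseudo = logical(),
    parts = IRanges::IRangesList()
  )
}

#' Accessors for beGenomics classes
#'
#' Read-only accessors for the slots of [ChromosomeRecord-class],
#' [AlignedSet-class] and [SkewProfile-class] objects.
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("accession", "ChromosomeRecord", function(x) x@accession)
#' @rdname accessors
#' @export
setMethod("organism", "ChromosomeRecord", function(x) x@organism)
#' @rdname accessors
#' @export
setMethod("genus", "ChromosomeRecord", function(x) x@genus)
#' @rdname accessors
#' @export
setMethod("dnaSequence", "ChromosomeRecord", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("topology", "ChromosomeRecord", function(x) x@topology)
#' @rdname accessors
#' @export
setMethod("isPlasmid", "ChromosomeRecord", function(x) x@isPlasmid)
#' @rdname accessors
#' @export
setMethod("cdsTable", "ChromosomeRecord", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("skippedFeatures", "ChromosomeRecord", function(x) x@skippedFeatures)

setMethod("show", "ChromosomeRecord", function(object) {
  cat("ChromosomeRecord", object@accession, "\n")
  cat("  organism:", object@organism, sprintf("(genus %s)", object@genus), "\n")
  cat(sprintf("  sequence: %d bp, %s%s\n", length(object@sequence),
              object@topology, if (object@isPlasmid) ", plasmid" else ""))
  cat(sprintf("  CDS features: %d (%d pseudo)\n", nrow(object@cds),
              sum(object@cds$pseudo)))
  if (object@skippedFeatures > 0L)
    cat("  skipped malformed features:", object@skippedFeatures, "\n")
})

#' @rdname accessors
#' @export
setMethod("length", "ChromosomeRecord", function(x) length(x@sequence))

#' Extract strand-resolved coding sequences
#'
#' Concatenates the ordered location parts of each CDS and reverse-complements
#' the result for minus-strand features, so the returned sequences read
#' 5'->3' in the coding direction. The `codonStart` offset is *not* applied
#' here; codon-level routines ([countCodonFamilies()]) honor it.
#'
#' @param record a [ChromosomeRecord-class].
#' @param which integer indices of rows of `cdsTable(record)`; default all.
#' @return a [Biostrings::DNAStringSet], one element per requested CDS,
#'   named by product.
#' @examples
#' rec <- ChromosomeRecord("X1", "Examplea demo", "ATGAAATTTTAA",
#'   cds = S4Vectors::DataFrame(start = 1L, end = 12L, strand = "+",
#'     product = "demo", codonStart = 1L, pseudo = FALSE,
#'     parts = IRanges::IRangesList(IRanges::IRanges(1, 12))))
#' codingSequences(rec)
#' @export
codingSequences <- function(record, which = seq_len(nrow(cdsTable(record)))) {
  stopifnot(is(record, "ChromosomeRecord"))
  cds <- record@cds
  nParts <- lengths(cds$parts[which])
  single <- nParts == 1L

  out <- Biostrings::DNAStringSet(rep("", length(which)))
  if (any(single)) {
    idx <- which[single]
    out[single] <- Biostrings::DNAStringSet(
      Biostrings::Views(record@sequence, start = cds$start[idx],
                        end = cds$end[idx]))
  }
  for (j in seq_along(which)[!single]) {
    parts <- cds$parts[[which[j]]]
    pieces <- lapply(seq_along(parts), function(p)
      Biostrings::subseq(record@sequence,
                         IRanges::start(parts)[p], IRanges::end(parts)[p]))
    out[j] <- Biostrings::DNAStringSet(do.call(Biostrings::xscat, pieces))
  }
  minus <- cds$strand[which] == "-"
  if (any(minus))
    out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- cds$product[which]
  out
}
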