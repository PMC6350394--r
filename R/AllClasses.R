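#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IRanges IRangesList
NULL

#' ChromosomeRecord: one annotated replicon
#'
#' Container for a single replicon (chromosome or plasmid): its DNA sequence
#' plus the CDS annotations needed downstream (strand-aware coding-sequence
#' extraction, highly-expressed-gene selection, codon counting).
#'
#' Coordinates are 1-based inclusive throughout, the GenBank convention.
#' Ambiguous bases (N, R, Y, ...) are retained in the sequence; composition
#' statistics exclude them from their denominators.
#'
#' @slot accession character(1), replicon identifier (e.g. an NC_ accession).
#' @slot organism character(1), organism name.
#' @slot genus character(1). Defaults to the first whitespace-delimited token
#'   of the organism name; may be overridden (e.g. for "Candidatus" names).
#' @slot sequence a [Biostrings::DNAString].
#' @slot topology character(1), "linear" or "circular".
#' @slot isPlasmid logical(1), TRUE when the record is annotated as a plasmid.
#' @slot cds a [S4Vectors::DataFrame] with one row per CDS feature and columns
#'   `start`, `end` (1-based inclusive over the whole feature), `strand`
#'   ("+"/"-"), `product` (free text), `codonStart` (1, 2 or 3), `pseudo`
#'   (logical) and `parts` (an [IRanges::IRangesList] holding the ordered
#'   exon-like parts of joined locations).
#' @slot skippedFeatures integer(1), count of malformed features skipped while
#'   parsing the source file.
#'
#' @seealso [readGenBank()], [genomeSize()], [gcContent()], [gcsi()],
#'   [identifyHeg()]
#' @export
setClass("ChromosomeRecord",
  representation(
    accession = "character",
    organism = "character",
    genus = "character",
    sequence = "ANY",
    topology = "character",
    isPlasmid = "logical",
    cds = "DataFrame",
    skippedFeatures = "integer"
  ),
  prototype(
    accession = NA_character_, organism = "", genus = "",
    topology = "linear", isPlasmid = FALSE, skippedFeatures = 0L
  )
)

setValidity("ChromosomeRecord", function(object) {
  msg <- character()
  if (length(object@accession) != 1L) msg <- c(msg, "accession must be length 1")
  if (!is(object@sequence, "DNAString"))
    msg <- c(msg, "sequence must be a DNAString")
  if (!nzchar(object@genus)) msg <- c(msg, "genus must be non-empty")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  n <- length(object@sequence)
  cds <- object@cds
  if (nrow(cds)) {
    need <- c("start", "end", "strand", "product", "codonStart", "pseudo", "parts")
    if (!all(need %in% colnames(cds))) {
      msg <- c(msg, paste("cds must have columns:", paste(need, collapse = ", ")))
    } else {
      if (any(cds$start > cds$end & object@topology != "circular"))
        msg <- c(msg, "CDS start > end on a non-circular record")
      hi <- max(cds$end)
      if (hi > n && object@topology != "circular")
        msg <- c(msg, sprintf("CDS interval exceeds sequence length (%d > %d)", hi, n))
      if (!all(cds$strand %in% c("+", "-")))
        msg <- c(msg, "CDS strand must be '+' or '-'")
      if (!all(cds$codonStart %in% 1:3))
        msg <- c(msg, "codonStart must be 1, 2 or 3")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CodonFamilyCounts: two-codon family usage for HEG and whole-genome sets
#'
#' Counts of C-ending and T-ending codons for the four two-codon amino-acid
#' families Phe (TTC/TTT), Tyr (TAC/TAT), Ile (ATC/ATT) and Asn (AAC/AAT),
#' held separately for the highly expressed gene (HEG) set and for the whole
#' set of annotated (non-pseudo) CDS. These are the sufficient statistics for
#' the selected codon usage bias estimate S (see [estimateS()]).
#'
#' @slot heg 4 x 2 numeric matrix (rows Phe/Tyr/Ile/Asn, columns c/t): counts
#'   over the HEG set.
#' @slot genome 4 x 2 numeric matrix, same layout: counts over all CDS.
#' @slot hegGeneCount integer(1), number of genes in the HEG set.
#' @slot skippedGenes integer(1), genes dropped (internal stop codons).
#' @export
setClass("CodonFamilyCounts",
  representation(heg = "matrix", genome = "matrix",
                 hegGeneCount = "integer", skippedGenes = "integer"),
  prototype(hegGeneCount = 0L, skippedGenes = 0L)
)

setValidity("CodonFamilyCounts", function(object) {
  msg <- character()
  fam <- c("Phe", "Tyr", "Ile", "Asn")
  for (nm in c("heg", "genome")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(4L, 2L)) ||
        !identical(rownames(m), fam) || !identical(colnames(m), c("c", "t")))
      msg <- c(msg, sprintf("%s must be a 4x2 matrix with rows %s and columns c,t",
                            nm, paste(fam, collapse = "/")))
    else if (any(m < 0)) msg <- c(msg, sprintf("%s counts must be >= 0", nm))
  }
  if (!length(msg) && any(object@heg > object@genome))
    msg <- c(msg, "HEG counts cannot exceed whole-genome counts (HEG is a subset)")
  if (length(msg)) msg else TRUE
})

#' AlignedSet: genus-labeled aligned 16S-like sequences
#'
#' An aligned set of rRNA gene sequences (equal gapped length) with a taxon
#' identifier and a genus label per sequence, the input to the intra-genus
#' diversity computations ([dmean()], [genusDiversity()]).
#'
#' @slot sequences a [Biostrings::DNAStringSet] of equal-width gapped
#'   sequences (alphabet A/C/G/T, gaps `-`, IUPAC ambiguity codes allowed).
#' @slot taxon character vector of per-sequence identifiers.
#' @slot genus character vector of per-sequence genus labels.
#' @export
setClass("AlignedSet",
  representation(sequences = "ANY", taxon = "character", genus = "character")
)

setValidity("AlignedSet", function(object) {
  msg <- character()
  if (!is(object@sequences, "DNAStringSet"))
    msg <- c(msg, "sequences must be a DNAStringSet")
  else {
    n <- length(object@sequences)
    if (n < 1L) msg <- c(msg, "at least one sequence required")
    if (n >= 1L && length(unique(Biostrings::width(object@sequences))) != 1L)
      msg <- c(msg, "all sequences must have the same aligned length")
    if (length(object@taxon) != n || length(object@genus) != n)
      msg <- c(msg, "taxon and genus labels must match the number of sequences")
  }
  if (length(msg)) msg else TRUE
})

#' SkewProfile: windowed GC skew of one chromosome
#'
#' Per-window GC skew (C-G)/(C+G) and its cumulative sum. The sequence is
#' truncated to `nWindows * floor(L/nWindows)` bases so windows are
#' equal-sized; windows devoid of C and G get skew 0.
#'
#' @slot nWindows integer(1), number of windows (default 4096 upstream).
#' @slot windowSize integer(1), bases per window after truncation.
#' @slot windowSkews numeric vector of per-window skews, each in [-1, 1].
#' @slot cumulative numeric vector, running sum of `windowSkews`.
#' @export
setClass("SkewProfile",
  representation(nWindows = "integer", windowSize = "integer",
                 windowSkews = "numeric", cumulative = "numeric")
)

setValidity("SkewProfile", function(object) {
  msg <- character()
  if (length(object@windowSkews) != object@nWindows)
    msg <- c(msg, "windowSkews length must equal nWindows")
  if (length(object@cumulative) != length(object@windowSkews))
    msg <- c(msg, "cumulative must have the same length as windowSkews")
  if (any(abs(object@windowSkews) > 1 + 1e-12))
    msg <- c(msg, "window skews must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
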