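#' @include ChromosomeRecord-methods.R
NULL

FAMILIES <- list(
  Phe = c(c = "TTC", t = "TTT"),
  Tyr = c(c = "TAC", t = "TAT"),
  Ile = c(c = "ATC", t = "ATT"),
  Asn = c(c = "AAC", t = "AAT")
)
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default product patterns for highly expressed genes
#'
#' Case-insensitive regular expressions selecting ribosomal-protein and
#' translation-elongation-factor products (the constitutively highly
#' expressed gene set used as the reference for selected codon usage bias),
#' together with negative patterns excluding enzymes that merely act on
#' ribosomal proteins (methyltransferases, kinases, ...).
#'
#' @return list with character vectors `positive` and `negative`.
#' @export
hegPatterns <- function() {
  list(
    positive = c(
      "ribosomal protein",
      "elongation factor (tu|g|ts|p)\\b"
    ),
    negative = c(
      "methyltransferase", "hydroxylase", "kinase", "pseudouridine",
      "acetyltransferase", "arginyltransferase"
    )
  )
}

#' Identify highly expressed genes (HEG)
#'
#' Selects the non-pseudo CDS whose product annotation matches the
#' ribosomal-protein / elongation-factor patterns and none of the negative
#' patterns, case-insensitively.
#'
#' @param cds a CDS DataFrame (from [cdsTable()]).
#' @param patterns pattern list as returned by [hegPatterns()].
#' @return integer vector of row indices into `cds` forming the HEG set.
#' @examples
#' rec <- generateChromosome(genomeSpec(length = 60000, nHeg = 3, nOther = 5,
#'                                      seed = 1))
#' length(identifyHeg(cdsTable(rec)))  # 3
#' @export
identifyHeg <- function(cds, patterns = hegPatterns()) {
  if (!nrow(cds)) return(integer())
  prod <- cds$product
  pos <- Reduce(`|`, lapply(patterns$positive, grepl, x = prod,
                            ignore.case = TRUE))
  neg <- if (length(patterns$negative))
    Reduce(`|`, lapply(patterns$negative, grepl, x = prod,
                       ignore.case = TRUE))
  else rep(FALSE, nrow(cds))
  which(pos & !neg & !cds$pseudo)
}

## Splits one coding sequence (already strand-resolved, 5'->3') into codons:
## honors codonStart, truncates a trailing partial codon, drops the terminal
## stop codon. Returns NULL when the gene has an internal stop (skipped).
codonsOfCds <- function(seqChar, codonStart) {
  s <- substr(seqChar, codonStart, nchar(seqChar))
  n <- nchar(s)
  if (n < 3L) return(character())
  n3 <- n - n %% 3L
  codons <- substring(s, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  if (any(codons %in% STOP_CODONS)) return(NULL)
  codons
}

## Vectorized codon walk over many coding sequences at once: returns a
## data.frame of (gene, codon) rows after terminal-stop removal, plus the
## ids of genes carrying internal stops (to be skipped) and whether any
## gene needed trailing-codon truncation.
codonWalk <- function(seqChars, codonStarts) {
  lens <- nchar(seqChars)
  eff <- pmax(lens - codonStarts + 1L, 0L)
  nCod <- eff %/% 3L
  truncated <- any(eff %% 3L != 0L & nCod > 0L)
  geneId <- rep.int(seq_along(seqChars), nCod)
  off <- sequence(nCod) - 1L
  starts <- codonStarts[geneId] + off * 3L
  codons <- substring(seqChars[geneId], starts, starts + 2L)
  ## terminal stop exclusion: last codon of each gene
  lastAt <- cumsum(nCod)[nCod > 0L]
  isStop <- codons %in% STOP_CODONS
  dropTerm <- lastAt[isStop[lastAt]]
  if (length(dropTerm)) {
    keep <- rep(TRUE, length(codons)); keep[dropTerm] <- FALSE
    internalStop <- unique(geneId[isStop & keep])
  } else {
    internalStop <- unique(geneId[isStop])
    keep <- rep(TRUE, length(codons))
  }
  if (length(dropTerm)) { codons <- codons[keep]; geneId <- geneId[keep] }
  list(geneId = geneId, codons = codons, internalStop = internalStop,
       truncated = truncated)
}

#' Count two-codon-family codons over a gene set
#'
#' Accumulates C-ending and T-ending codon counts for the Phe/Tyr/Ile/Asn
#' families over a whole CDS set and over its HEG subset, reading each CDS
#' strand-correctly in the frame given by its `codonStart`. Codons containing
#' ambiguous bases are ignored; a trailing partial codon is truncated with a
#' warning; the terminal stop codon is excluded; genes with internal stop
#' codons are skipped with a warning (they are presumed misannotated).
#' Pseudo-genes are excluded from both sets.
#'
#' @param record a [ChromosomeRecord-class].
#' @param hegIdx integer row indices of the HEG subset (default: computed via
#'   [identifyHeg()]).
#' @param patterns HEG product patterns, see [hegPatterns()].
#' @return a [CodonFamilyCounts-class].
#' @export
countCodonFamilies <- function(record, hegIdx = NULL,
                               patterns = hegPatterns()) {
  cds <- cdsTable(record)
  keep <- which(!cds$pseudo)
  if (is.null(hegIdx)) hegIdx <- identifyHeg(cds, patterns)
  hegIdx <- intersect(hegIdx, keep)

  emptyMat <- matrix(0, 4, 2, dimnames = list(names(FAMILIES), c("c", "t")))
  if (!length(keep))
    return(new("CodonFamilyCounts", heg = emptyMat, genome = emptyMat,
               hegGeneCount = 0L, skippedGenes = 0L))

  seqs <- as.character(codingSequences(record, keep))
  walk <- codonWalk(seqs, cds$codonStart[keep])
  if (length(walk$internalStop)) {
    warning(length(walk$internalStop),
            " CDS with internal stop codons skipped (e.g. '",
            cds$product[keep[walk$internalStop[1]]], "')", call. = FALSE)
    ok <- !(walk$geneId %in% walk$internalStop)
    walk$geneId <- walk$geneId[ok]
    walk$codons <- walk$codons[ok]
  }
  if (walk$truncated)
    warning("one or more CDS lengths were not divisible by 3; ",
            "trailing partial codons truncated", call. = FALSE)

  famLevels <- unlist(lapply(FAMILIES, unname), use.names = FALSE)
  countSet <- function(inSet) {
    tab <- table(factor(walk$codons[inSet], levels = famLevels))
    m <- emptyMat
    for (f in names(FAMILIES)) {
      m[f, "c"] <- tab[[FAMILIES[[f]][["c"]]]]
      m[f, "t"] <- tab[[FAMILIES[[f]][["t"]]]]
    }
    m
  }
  inHeg <- walk$geneId %in% match(hegIdx, keep)
  new("CodonFamilyCounts",
      heg = countSet(inHeg),
      genome = countSet(rep(TRUE, length(walk$codons))),
      hegGeneCount = length(hegIdx),
      skippedGenes = length(walk$internalStop))
}

#' Construct CodonFamilyCounts from matrices
#'
#' @param heg,genome 4 x 2 count matrices (rows Phe/Tyr/Ile/Asn in that
#'   order, columns C-ending then T-ending).
#' @param hegGeneCount number of genes behind the HEG counts.
#' @return a [CodonFamilyCounts-class].
#' @export
CodonFamilyCounts <- function(heg, genome, hegGeneCount = NA_integer_) {
  dn <- list(names(FAMILIES), c("c", "t"))
  heg <- matrix(as.numeric(heg), 4, 2, dimnames = dn)
  genome <- matrix(as.numeric(genome), 4, 2, dimnames = dn)
  new("CodonFamilyCounts", heg = heg, genome = genome,
      hegGeneCount = as.integer(hegGeneCount), skippedGenes = 0L)
}

setMethod("show", "CodonFamilyCounts", function(object) {
  cat("CodonFamilyCounts (", object@hegGeneCount, "HEG genes )\n")
  m <- cbind(heg_c = object@heg[, "c"], heg_t = object@heg[, "t"],
             genome_c = object@genome[, "c"], genome_t = object@genome[, "t"])
  print(m)
})

#' Estimate the strength of selected codon usage bias (S)
#'
#' Maximum-likelihood estimate of the log-scale shift S in C-ending codon
#' preference of highly expressed genes relative to the whole-genome
#' background, over the four two-codon families (Phe, Tyr, Ile, Asn). Both
#' codons of each family are read by the same tRNA, the C-ending codon more
#' efficiently, so translational selection inflates C-ending usage in highly
#' expressed genes.
#'
#' Model: with background C-ending proportion `c_f` (whole-genome counts),
#' the HEG C-ending count `k_f` of `n_f` family codons is
#' Binomial(`n_f`, `p_f`) with `p_f = c_f e^S / (1 - c_f + c_f e^S)` — a
#' single S shared across families, maximized over `[-10, 10]`.
#'
#' Families with zero whole-genome usage (or a degenerate background
#' proportion of exactly 0 or 1) are dropped; a family whose HEG count is 0
#' or `n_f` gets a 0.5 pseudocount on both its HEG codon counts so the
#' estimate stays finite. If no family has HEG usage the result is missing
#' (`s = NA`) with a warning.
#'
#' @param counts a [CodonFamilyCounts-class].
#' @param interval search interval for S.
#' @param tol optimizer tolerance.
#' @return list with `s`, `hegGeneCount`, `background` (per-family c_f),
#'   `familyLogOdds` (per-family diagnostic log-odds differences),
#'   `logLikelihood`, `familiesUsed`.
#' @examples
#' cc <- CodonFamilyCounts(heg = cbind(c(73, 0, 0, 0), c(27, 0, 0, 0)),
#'                         genome = cbind(c(500, 0, 0, 0), c(500, 0, 0, 0)))
#' estimateS(cc)$s  # ~ log(73/27)
#' @export
estimateS <- function(counts, interval = c(-10, 10), tol = 1e-6) {
  stopifnot(is(counts, "CodonFamilyCounts"))
  gen <- counts@genome
  heg <- counts@heg
  tot <- gen[, "c"] + gen[, "t"]
  cf <- ifelse(tot > 0, gen[, "c"] / tot, NA_real_)
  use <- which(tot > 0 & cf > 0 & cf < 1 & (heg[, "c"] + heg[, "t"]) > 0)
  if (!length(use)) {
    warning("no usable family counts in the HEG set; S is missing")
    return(list(s = NA_real_, hegGeneCount = counts@hegGeneCount,
                background = cf, familyLogOdds = rep(NA_real_, 4),
                logLikelihood = NA_real_, familiesUsed = character()))
  }
  k <- heg[use, "c"]
  n <- heg[use, "c"] + heg[use, "t"]
  degenerate <- k == 0 | k == n
  k[degenerate] <- k[degenerate] + 0.5
  n[degenerate] <- n[degenerate] + 1
  cfu <- cf[use]

  negLogLik <- function(s) {
    p <- cfu * exp(s) / (1 - cfu + cfu * exp(s))
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  opt <- stats::optimize(negLogLik, interval = interval, tol = tol)

  logOdds <- rep(NA_real_, 4)
  names(logOdds) <- rownames(gen)
  logOdds[use] <- log(k / (n - k)) - log(cfu / (1 - cfu))

  list(s = opt$minimum, hegGeneCount = counts@hegGeneCount,
       background = cf, familyLogOdds = logOdds,
       logLikelihood = -opt$objective,
       familiesUsed = rownames(gen)[use])
}

#' Per-chromosome S value
#'
#' Convenience wrapper: identify the HEG set, count the two-codon families
#' and estimate S for one chromosome.
#'
#' @param record a [ChromosomeRecord-class].
#' @param patterns HEG product patterns.
#' @return as [estimateS()].
#' @export
sValue <- function(record, patterns = hegPatterns()) {
  counts <- countCodonFamilies(record, patterns = patterns)
  if (counts@hegGeneCount == 0L) {
    warning("no highly expressed genes found in ", accession(record),
            "; S is missing")
    return(list(s = NA_real_, hegGeneCount = 0L,
                background = rep(NA_real_, 4),
                familyLogOdds = rep(NA_real_, 4),
                logLikelihood = NA_real_, familiesUsed = character()))
  }
  estimateS(counts)
}
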