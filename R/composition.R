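#' @include ChromosomeRecord-methods.R
NULL

baseCounts <- function(x) {
  f <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  f[c("A", "C", "G", "T")]
}

#' Genome size in unambiguous bases
#'
#' The total number of A + T + G + C characters of the sequence. Ambiguous
#' bases (N, R, Y, ...) are excluded: they carry no compositional
#' information and would otherwise inflate the denominator of GC content.
#'
#' @param x a [ChromosomeRecord-class] or [Biostrings::DNAString].
#' @return integer count in bp.
#' @examples
#' genomeSize(ChromosomeRecord("X", "Examplea sp.", "ATGCNN"))  # 4
#' @rdname genomeSize
#' @export
setMethod("genomeSize", "ChromosomeRecord", function(x) genomeSize(x@sequence))

#' @rdname genomeSize
#' @export
setMethod("genomeSize", "ANY", function(x) {
  if (is.character(x)) x <- Biostrings::DNAString(x)
  if (length(x) == 0L) stop("genomeSize: empty sequence")
  as.integer(sum(baseCounts(x)))
})

#' GC content in percent
#'
#' 100 * (G + C) / (A + T + G + C), ambiguous bases excluded from the
#' denominator.
#'
#' @param x a [ChromosomeRecord-class] or [Biostrings::DNAString].
#' @return numeric percentage in [0, 100].
#' @examples
#' gcContent(ChromosomeRecord("X", "Examplea sp.", "ATGC"))  # 50
#' @rdname gcContent
#' @export
setMethod("gcContent", "ChromosomeRecord", function(x) gcContent(x@sequence))

#' @rdname gcContent
#' @export
setMethod("gcContent", "ANY", function(x) {
  if (is.character(x)) x <- Biostrings::DNAString(x)
  f <- baseCounts(x)
  tot <- sum(f)
  if (tot == 0) stop("gcContent: no unambiguous bases in sequence")
  100 * (f[["G"]] + f[["C"]]) / tot
})

#' Windowed GC skew profile
#'
#' Divides the sequence into `nWindows` equal windows (the trailing
#' `L mod nWindows` bases are truncated) and computes the per-window GC skew
#' (C - G) / (C + G), counting only C and G; a window with no C or G gets
#' skew 0. The fixed window number (default 4096) keeps the profile
#' comparable across genome sizes and damps local coding-region composition.
#'
#' @param x a [ChromosomeRecord-class] or [Biostrings::DNAString].
#' @param nWindows number of windows; sequence must be at least this long.
#' @return a [SkewProfile-class].
#' @rdname windowedGcSkew
#' @export
setMethod("windowedGcSkew", "ChromosomeRecord",
          function(x, nWindows = 4096L) windowedGcSkew(x@sequence, nWindows))

#' @rdname windowedGcSkew
#' @export
setMethod("windowedGcSkew", "ANY", function(x, nWindows = 4096L) {
  if (is.character(x)) x <- Biostrings::DNAString(x)
  nWindows <- as.integer(nWindows)
  L <- length(x)
  if (L < nWindows)
    stop("sequence length (", L, ") is shorter than nWindows (", nWindows,
         "); use a smaller window number")
  w <- L %/% nWindows
  views <- Biostrings::Views(x, start = (seq_len(nWindows) - 1L) * w + 1L,
                             width = w)
  cg <- Biostrings::letterFrequency(views, c("C", "G"))
  denom <- cg[, "C"] + cg[, "G"]
  skew <- ifelse(denom == 0, 0, (cg[, "C"] - cg[, "G"]) / denom)
  new("SkewProfile", nWindows = nWindows, windowSize = as.integer(w),
      windowSkews = as.numeric(skew), cumulative = cumsum(as.numeric(skew)))
})

#' @rdname accessors
#' @export
setMethod("windowSkews", "SkewProfile", function(x) x@windowSkews)
#' @rdname accessors
#' @export
setMethod("cumulativeSkew", "SkewProfile", function(x) x@cumulative)

setMethod("show", "SkewProfile", function(object) {
  cat(sprintf("SkewProfile: %d windows of %d bp\n",
              object@nWindows, object@windowSize))
  cat(sprintf("  skew range [%.4f, %.4f], cumulative amplitude %.2f\n",
              min(object@windowSkews), max(object@windowSkews),
              max(object@cumulative) - min(object@cumulative)))
})

## Spectral ratio of a skew vector: power at the fundamental frequency
## (1 cycle per genome -- the signature of a single origin/terminus pair)
## over the mean power across frequencies 1..n/2 (DC excluded).
spectralRatio <- function(skews) {
  n <- length(skews)
  p <- Mod(stats::fft(skews))^2
  half <- p[2:(n %/% 2 + 1L)]
  m <- mean(half)
  if (m == 0) return(0)
  p[2] / m
}

#' GC skew index (GCSI)
#'
#' Strength of replication-strand GC skew of a chromosome, combining two
#' views of the windowed skew vector: `sr`, the spectral ratio (power of the
#' once-per-genome oscillation over the mean spectral power), and `dist`,
#' the amplitude (max minus min) of the cumulative skew curve. The index is
#' their normalized geometric mean,
#' `gcsi = sqrt((sr/srNorm) * (dist/distNorm))`, ranging from 0 (no
#' replication skew) to approximately 1 (strong skew).
#'
#' @param x a [ChromosomeRecord-class] or [Biostrings::DNAString].
#' @param nWindows window number (default 4096).
#' @param srNorm,distNorm normalization constants for the spectral ratio and
#'   the cumulative amplitude (defaults 6000 and 600).
#' @return list with elements `gcsi`, `sr`, `dist`.
#' @rdname gcsi
#' @export
setMethod("gcsi", "ChromosomeRecord",
          function(x, nWindows = 4096L, srNorm = 6000, distNorm = 600)
            gcsi(x@sequence, nWindows, srNorm, distNorm))

#' @rdname gcsi
#' @export
setMethod("gcsi", "ANY", function(x, nWindows = 4096L, srNorm = 6000,
                                  distNorm = 600) {
  prof <- windowedGcSkew(x, nWindows)
  gcsiFromProfile(prof, srNorm, distNorm)
})

#' @rdname gcsi
#' @param profile a [SkewProfile-class] (already-windowed skews).
#' @export
gcsiFromProfile <- function(profile, srNorm = 6000, distNorm = 600) {
  stopifnot(is(profile, "SkewProfile"))
  sr <- spectralRatio(profile@windowSkews)
  dist <- max(profile@cumulative) - min(profile@cumulative)
  val <- sqrt((sr / srNorm) * (dist / distNorm))
  if (!is.finite(val) || val < 0) val <- 0
  list(gcsi = val, sr = sr, dist = dist)
}
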