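#' @include genbank-io.R
NULL

#' Read a genus grouping table
#'
#' Reads the TSV mapping each genus to its built-environment publication
#' count and environment flags. Expected header:
#' `genus<TAB>publication_count<TAB>group<TAB>env_flags`, with `env_flags`
#' semicolon-separated (may be empty). The `group` column is recomputed from
#' `publication_count` at assignment time, so it may be left blank.
#'
#' @param path TSV file path.
#' @return data.frame with columns `genus`, `publication_count`, `group`,
#'   `env_flags` (list column of character vectors).
#' @export
readGroupingTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genus", "publication_count")
  if (!all(need %in% names(df)))
    stop("grouping table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$genus))
    stop("grouping table maps a genus more than once: ",
         paste(unique(df$genus[duplicated(df$genus)]), collapse = ", "))
  if (is.null(df$group)) df$group <- NA_character_
  flags <- if (is.null(df$env_flags)) rep("", nrow(df)) else df$env_flags
  df$env_flags <- lapply(flags, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  df
}

#' Select the representative replicon of an organism
#'
#' Among the replicons of one organism, returns the largest one not annotated
#' as a plasmid (if every record is a plasmid, the largest overall). Ties are
#' broken by lexicographically smallest accession. Idempotent and
#' order-independent.
#'
#' @param records non-empty list of [ChromosomeRecord-class] objects for one
#'   organism.
#' @return a single [ChromosomeRecord-class].
#' @export
selectLargestReplicon <- function(records) {
  if (is(records, "ChromosomeRecord")) records <- list(records)
  if (!length(records)) stop("selectLargestReplicon: empty record list")
  chrom <- Filter(function(r) !isPlasmid(r), records)
  pool <- if (length(chrom)) chrom else records
  lens <- vapply(pool, length, integer(1))
  accs <- vapply(pool, accession, character(1))
  best <- which(lens == max(lens))
  pool[[best[order(accs[best])[1]]]]
}

#' Assign genomes to comparison groups
#'
#' Labels each record "Common BE" when its genus has at least `threshold`
#' built-environment publications in the grouping table, else "Other".
#' Genera absent from the table default to "Other" with a warning. The
#' returned skeleton table is the input to the feature computations.
#'
#' @param records list of [ChromosomeRecord-class] objects.
#' @param grouping data.frame from [readGroupingTable()].
#' @param threshold minimum publication count for "Common BE" (default 6).
#' @return data.frame with columns `accession`, `organism`, `genus`,
#'   `publication_count`, `group`.
#' @export
assignGroups <- function(records, grouping, threshold = 6L) {
  stopifnot(threshold >= 1)
  gen <- vapply(records, genus, character(1))
  idx <- match(gen, grouping$genus)
  if (anyNA(idx)) {
    warning("genera absent from grouping table default to 'Other': ",
            paste(unique(gen[is.na(idx)]), collapse = ", "))
  }
  counts <- ifelse(is.na(idx), 0L, grouping$publication_count[idx])
  data.frame(
    accession = vapply(records, accession, character(1)),
    organism = vapply(records, organism, character(1)),
    genus = gen,
    publication_count = as.integer(counts),
    group = ifelse(counts >= threshold, "Common BE", "Other"),
    stringsAsFactors = FALSE
  )
}
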