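#' @include grouping.R
#' @include composition.R
#' @include codon-selection.R
#' @include group-stats.R
NULL

#' Per-chromosome feature vector
#'
#' Computes the four genomic features of one record: genome size (bp of
#' unambiguous bases), GC content (%), GCSI (with its `sr` and `dist`
#' intermediates) and the S value (with its HEG gene count).
#'
#' @param record a [ChromosomeRecord-class].
#' @param nWindows GCSI window number (default 4096).
#' @param srNorm,distNorm GCSI normalization constants.
#' @param patterns HEG product patterns for the S value.
#' @return one-row data.frame with columns `accession genus size_bp
#'   gc_percent gcsi sr dist s_value heg_gene_count`.
#' @export
featureVector <- function(record, nWindows = 4096L, srNorm = 6000,
                          distNorm = 600, patterns = hegPatterns()) {
  g <- gcsi(record, nWindows = nWindows, srNorm = srNorm, distNorm = distNorm)
  s <- suppressWarnings(sValue(record, patterns = patterns))
  data.frame(
    accession = accession(record), genus = genus(record),
    size_bp = genomeSize(record), gc_percent = gcContent(record),
    gcsi = g$gcsi, sr = g$sr, dist = g$dist,
    s_value = s$s, heg_gene_count = s$hegGeneCount,
    stringsAsFactors = FALSE
  )
}

#' Feature table for a set of records
#'
#' @param records list of [ChromosomeRecord-class] objects.
#' @param grouping optional data.frame from [readGroupingTable()]; when
#'   given, a `group` column is added via [assignGroups()].
#' @param threshold publication-count threshold for "Common BE".
#' @param ... passed to [featureVector()].
#' @return data.frame, one row per record (Table "S8" shape: accession,
#'   genus, group, size, GC%, GCSI, S and intermediates).
#' @export
featureTable <- function(records, grouping = NULL, threshold = 6L, ...) {
  feats <- do.call(rbind, lapply(records, featureVector, ...))
  if (!is.null(grouping)) {
    grp <- assignGroups(records, grouping, threshold)
    feats$publication_count <- grp$publication_count
    feats$group <- grp$group
  }
  feats
}

#' Five-number box-plot summary per genus
#'
#' Minimum, quartiles, maximum and 1.5 IQR outliers of one feature within
#' each genus — the numbers behind a box-and-whisker panel.
#'
#' @param featureTab data.frame with `genus` and the feature column.
#' @param feature feature column name.
#' @return data.frame `genus n min q25 median q75 max n_outliers`.
#' @export
genusBoxSummary <- function(featureTab, feature) {
  stopifnot(feature %in% names(featureTab))
  out <- lapply(split(featureTab[[feature]], featureTab$genus), function(v) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    iqr <- q[4] - q[2]
    data.frame(n = length(v), min = q[1], q25 = q[2], median = q[3],
               q75 = q[4], max = q[5],
               n_outliers = sum(v < q[2] - 1.5 * iqr | v > q[4] + 1.5 * iqr))
  })
  res <- do.call(rbind, out)
  res <- cbind(genus = names(out), res)
  rownames(res) <- NULL
  res
}

#' Environment-category comparison battery
#'
#' For each environment category, compares the flagged versus non-flagged
#' "Common BE" genomes on every feature, with BH adjustment across the whole
#' battery (all category x feature tests of this call). Categories with
#' fewer than 2 genomes on either side are skipped with a notice.
#'
#' @param featureTab feature table with `genus` and `group` columns.
#' @param grouping data.frame from [readGroupingTable()] (its `env_flags`
#'   column supplies the per-genus category flags).
#' @param features feature column names to compare.
#' @return data.frame like [compareGroups()] output with an extra leading
#'   `category` column, sorted by q.
#' @export
environmentBattery <- function(featureTab, grouping,
                               features = c("size_bp", "gc_percent",
                                            "gcsi", "s_value")) {
  be <- featureTab[featureTab$group == "Common BE", , drop = FALSE]
  if (!nrow(be)) stop("no 'Common BE' genomes in the feature table")
  flags <- grouping$env_flags
  names(flags) <- grouping$genus
  categories <- sort(unique(unlist(flags)))
  rows <- list()
  for (cat in categories) {
    flagged <- vapply(be$genus, function(g)
      g %in% names(flags) && cat %in% flags[[g]], logical(1))
    if (sum(flagged) < 2 || sum(!flagged) < 2) {
      message("category ", cat, " skipped: fewer than 2 genomes on one side")
      next
    }
    for (f in features) {
      v <- be[[f]]
      x <- v[flagged & !is.na(v)]; y <- v[!flagged & !is.na(v)]
      if (length(x) < 2 || length(y) < 2) next
      wt <- wilcoxonRankSum(x, y)
      cd <- cliffsDelta(x, y)
      rows[[paste(cat, f)]] <- data.frame(
        category = cat, feature = f, n1 = length(x), n2 = length(y),
        median1 = stats::median(x), median2 = stats::median(y),
        U = wt$u, p = wt$p, q = NA_real_, delta = cd$delta,
        magnitude = cd$magnitude, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no category had enough genomes on both sides")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bhFdr(out$p)
  out[order(out$q, out$p), , drop = FALSE]
}

## Tiny FNV-1a hash of a character scalar, for config fingerprints in run
## manifests (stable across sessions, no external dependency).
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte since b < 256; stay in doubles to
    ## avoid 32-bit integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    ## 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Assemble a run configuration
#'
#' @param genbankDir directory of GenBank flat files (`.gb`/`.gbk`).
#' @param groupingFile grouping TSV path (see [readGroupingTable()]).
#' @param alignmentFile optional aligned 16S multi-FASTA.
#' @param treeFile optional newick tree.
#' @param outDir output directory.
#' @param threshold publication-count threshold (default 6).
#' @param nWindows GCSI window number (default 4096).
#' @param features feature columns entering the comparison battery.
#' @param runEnvironmentBattery compare within environment categories too?
#' @param seed run seed, recorded in the manifest.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(genbankDir, groupingFile, alignmentFile = NULL,
                      treeFile = NULL, outDir = "begenomics_run",
                      threshold = 6L, nWindows = 4096L,
                      features = c("size_bp", "gc_percent", "gcsi", "s_value"),
                      runEnvironmentBattery = FALSE, seed = 1L) {
  for (p in c(genbankDir, groupingFile, alignmentFile, treeFile))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  cfg <- list(genbankDir = genbankDir, groupingFile = groupingFile,
              alignmentFile = alignmentFile, treeFile = treeFile,
              outDir = outDir, threshold = as.integer(threshold),
              nWindows = as.integer(nWindows), features = features,
              runEnvironmentBattery = isTRUE(runEnvironmentBattery),
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()].
#'
#' @param path YAML file path.
#' @return list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

writeTsvWithHeader <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beGenomics %s | config %s | seed %d",
                     manifest$version, manifest$config_hash, manifest$seed),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole comparative-genomics pipeline
#'
#' Orchestrates ingest (GenBank parsing, largest-replicon selection per
#' organism, group assignment), feature computation, optional 16S diversity,
#' the two-group statistical battery and per-genus box-plot summaries into
#' one reproducible run. Writes `features.tsv`, `comparison.tsv`, optional
#' `diversity.tsv` and `environment_comparison.tsv`, per-feature
#' `boxplot_<feature>.tsv`, plus `run_manifest.tsv` and a verbatim copy of
#' the configuration. All tables carry a header comment with the package
#' version, a config hash and the seed; a rerun with identical inputs and
#' config is byte-identical.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return list with elements `features`, `comparison`, `diversity`,
#'   `environment`, `boxplots`, `manifest` (tables also written to
#'   `config$outDir`).
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("beGenomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    ## fingerprint of the scientific configuration: the output location
    ## does not alter results, so it stays out of the hash
    config_hash = fnv1a(paste(
      deparse(unclass(config)[setdiff(names(config), "outDir")]),
      collapse = ""))
  )
  stage <- "ingest"
  result <- tryCatch({
    files <- sort(list.files(config$genbankDir,
                             pattern = "\\.(gb|gbk|genbank)$",
                             full.names = TRUE))
    if (!length(files)) stop("no GenBank files in ", config$genbankDir)
    records <- unlist(lapply(files, readGenBank), recursive = FALSE)
    byOrg <- split(records, vapply(records, organism, character(1)))
    records <- lapply(byOrg, selectLargestReplicon)
    records <- records[order(vapply(records, accession, character(1)))]
    grouping <- readGroupingTable(config$groupingFile)

    stage <- "features"
    feats <- featureTable(records, grouping, threshold = config$threshold,
                          nWindows = config$nWindows)
    if (!any(feats$group == "Common BE"))
      stop("assignGroups produced an empty 'Common BE' group ",
           "(threshold ", config$threshold, ")")

    stage <- "diversity"
    divTab <- NULL
    if (!is.null(config$alignmentFile)) {
      aligned <- readAlignedFasta(config$alignmentFile)
      tree <- if (!is.null(config$treeFile))
        ape::read.tree(config$treeFile) else NULL
      divTab <- genusDiversity(aligned, tree = tree)
    }

    stage <- "comparison"
    comp <- compareGroups(feats, config$features)
    envTab <- NULL
    if (config$runEnvironmentBattery)
      envTab <- environmentBattery(feats, grouping, config$features)

    stage <- "summaries"
    boxes <- lapply(config$features, function(f) genusBoxSummary(feats, f))
    names(boxes) <- config$features

    stage <- "write"
    writeTsvWithHeader(feats, file.path(config$outDir, "features.tsv"), manifest)
    writeTsvWithHeader(comp, file.path(config$outDir, "comparison.tsv"), manifest)
    if (!is.null(divTab))
      writeTsvWithHeader(divTab, file.path(config$outDir, "diversity.tsv"),
                         manifest)
    if (!is.null(envTab))
      writeTsvWithHeader(envTab,
                         file.path(config$outDir, "environment_comparison.tsv"),
                         manifest)
    for (f in names(boxes))
      writeTsvWithHeader(boxes[[f]],
                         file.path(config$outDir, paste0("boxplot_", f, ".tsv")),
                         manifest)
    writeTsvWithHeader(
      data.frame(key = names(manifest),
                 value = unlist(lapply(manifest, as.character))),
      file.path(config$outDir, "run_manifest.tsv"), manifest)
    writeLines(paste(deparse(unclass(config)), collapse = "\n"),
               file.path(config$outDir, "run_config.txt"))
    list(features = feats, comparison = comp, diversity = divTab,
         environment = envTab, boxplots = boxes, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
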