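#' Read a PPI edge list
#'
#' Parses a tab- or whitespace-delimited edge list (BioGRID/HPRD-style
#' gene-symbol pairs) into a [ReliabilityNetwork-class]. Identifiers are
#' uppercased, self-loops dropped and duplicate undirected edges merged
#' keeping the maximum score. Without a score column every edge gets
#' reliability 1.
#'
#' @param path path to the edge-list file.
#' @param scoreColumn optional 1-based column index holding a numeric score
#'   in \[0, 1\]; `NULL` (default) assigns reliability 1 to every edge.
#' @param comment lines starting with this character are skipped.
#' @return A [ReliabilityNetwork-class].
#' @export
readPPIEdgelist <- function(path, scoreColumn = NULL, comment = "#") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty PPI edge list: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad))
    stop(sprintf("malformed edge list line %d in %s (need >= 2 columns)",
                 lineNo[bad[1]], path))
  from <- vapply(fields, `[`, character(1), 1L)
  to <- vapply(fields, `[`, character(1), 2L)
  if (is.null(scoreColumn)) {
    rel <- rep(1, length(from))
  } else {
    short <- which(nf < scoreColumn)
    if (length(short))
      stop(sprintf("line %d in %s lacks score column %d",
                   lineNo[short[1]], path, scoreColumn))
    rel <- suppressWarnings(
      as.numeric(vapply(fields, `[`, character(1), scoreColumn)))
    badScore <- which(!is.finite(rel))
    if (length(badScore))
      stop(sprintf("non-numeric score on line %d in %s",
                   lineNo[badScore[1]], path))
  }
  ReliabilityNetwork(from, to, rel)
}

#' Write a PPI edge list
#'
#' Inverse of [readPPIEdgelist()]: writes `from`, `to` and the score column
#' as a tab-delimited file without header.
#'
#' @param net a [ReliabilityNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePPIEdgelist <- function(net, path) {
  stopifnot(is(net, "ReliabilityNetwork"))
  write.table(networkEdges(net)[, c("from", "to", "reliability")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a condition's expression matrix
#'
#' Reads a TSV whose header row lists sample identifiers and whose first
#' column holds gene identifiers. Duplicate gene rows (e.g. multiple probes
#' mapping to the same symbol) are collapsed by the per-cell mean of the
#' available values; missing cells stay missing.
#'
#' @param path TSV path.
#' @param conditionLabel label for the condition measured in this file.
#' @return A [ConditionExpression-class].
#' @export
readExpression <- function(path, conditionLabel) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expression file needs a header and data: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # tolerate both "gene<TAB>s1..." and a header starting directly with samples
  samples <- header[-1L]
  nc <- length(samples)
  if (nc < 1L) stop("no sample columns in ", path)
  body <- fields[-1L]
  nf <- lengths(body)
  ragged <- which(nf != nc + 1L)
  if (length(ragged))
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 ragged[1] + 1L, path, nf[ragged[1]], nc + 1L))
  genes <- toupper(vapply(body, `[`, character(1), 1L))
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))),
    nrow = length(body), ncol = nc, byrow = TRUE)
  if (anyDuplicated(genes)) {
    agg <- rowsum(ifelse(is.na(vals), 0, vals), genes, na.rm = FALSE)
    cnt <- rowsum((!is.na(vals)) * 1, genes)
    vals <- agg / cnt           # 0/0 -> NaN where all duplicates missing
    vals[cnt == 0] <- NA
    genes <- rownames(agg)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (nc < 3L)
    warning("fewer than 3 samples in ", path,
            "; pairwise correlations will be unstable")
  ConditionExpression(vals, conditionLabel)
}

#' Write a condition's expression matrix
#'
#' @param expr a [ConditionExpression-class] or genes-x-samples matrix.
#' @param path output TSV path.
#' @param idColumn header name of the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, idColumn = "gene") {
  m <- .exprMatrix(expr)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Members
#' are uppercased and de-duplicated preserving order; sets with fewer than
#' two unique members are skipped with a warning.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  skipped <- 0L
  for (f in fields) {
    if (length(f) < 3L) { skipped <- skipped + 1L; next }
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) < 2L) { skipped <- skipped + 1L; next }
    out[[f[1L]]] <- members
  }
  if (skipped)
    warning(skipped, " gene set(s) with < 2 unique members skipped")
  out
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TF identifier list (one per line)
#'
#' @param path input path.
#' @return character vector of unique uppercased TF identifiers.
#' @export
readTFList <- function(path) {
  ids <- trimws(readLines(path))
  ids <- unique(toupper(ids[nzchar(ids)]))
  if (!length(ids)) stop("empty TF list: ", path)
  ids
}

#' Write / read a conditional network as an annotated edge TSV
#'
#' The table has columns `from`, `to`, `reliability`, `rho`, `z`,
#' `clusterWeight`, `rhoUndefined`, so a conditioned network can round-trip
#' through the command-line interface.
#'
#' @param net a [ConditionalNetwork-class].
#' @param path file path.
#' @return `path` (writer) or a [ConditionalNetwork-class] (reader).
#' @export
writeConditionalNetwork <- function(net, path) {
  stopifnot(is(net, "ConditionalNetwork"))
  df <- networkEdges(net)
  attr(df, "conditionLabel") <- NULL
  cat(sprintf("# condition=%s\n", conditionLabel(net)), file = path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname writeConditionalNetwork
#' @export
readConditionalNetwork <- function(path) {
  first <- readLines(path, n = 1L)
  label <- sub("^# condition=", "", first)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  new("ConditionalNetwork", edges = df, conditionLabel = label)
}
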