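## Readers and writers for every external file format the toolkit touches.
## Coordinates in all files are 0-based, half-open (BED convention); the
## in-memory representation is GRanges (1-based, closed), converted at the
## boundary. Chromosome names are taken verbatim: no "chr" normalization.

fmtNum <- function(x) sprintf("%.12g", x)

splitLines <- function(path, what, ncolMin, ncolMax = Inf) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < ncolMin | lengths(fields) > ncolMax)
  if (length(bad))
    stop("malformed ", what, " line ", bad[1], ": expected ",
         if (is.finite(ncolMax) && ncolMax != ncolMin)
           paste(ncolMin, "to", ncolMax) else paste0(ncolMin, "+"),
         " tab-separated fields, got ", length(fields[[bad[1]]]))
  fields
}

parseCoord <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) || any(v != floor(v)))
    stop("non-integer ", what, " coordinate on line ",
         lineno[which(is.na(v) | v != floor(v))][1])
  v
}

#' Read a gene annotation table
#'
#' Reads a BED-like tab-separated file with at least four columns: chrom,
#' start, end, gene symbol (no header, 0-based half-open coordinates).
#' Extra columns are ignored. Entries are returned sorted by
#' (chrom, start).
#'
#' @param path path to the annotation file.
#' @return A [GenomicRanges::GRanges] with a `symbol` metadata column;
#'   symbols are guaranteed unique.
#' @examples
#' f <- tempfile()
#' writeLines("chr7\t156000000\t156100000\tMNX1", f)
#' readGeneAnnotation(f)
#' @export
readGeneAnnotation <- function(path) {
  fields <- splitLines(path, "annotation", 4L)
  if (!length(fields)) return(emptyAnnotation())
  chrom <- vapply(fields, `[[`, "", 1L)
  lineno <- seq_along(fields)
  start0 <- parseCoord(vapply(fields, `[[`, "", 2L), "start", lineno)
  end0 <- parseCoord(vapply(fields, `[[`, "", 3L), "end", lineno)
  symbol <- vapply(fields, `[[`, "", 4L)
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) on line ", bad[1])
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  dup <- symbol[duplicated(symbol)]
  if (length(dup))
    stop("duplicate gene symbol: ", dup[1])
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               symbol = symbol)
  sortAnnotation(gr)
}

emptyAnnotation <- function() {
  GenomicRanges::GRanges(character(), IRanges::IRanges(),
                         symbol = character())
}

sortAnnotation <- function(gr) {
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), gr$symbol)
  gr[ord]
}

#' Write a gene annotation table
#'
#' Inverse of [readGeneAnnotation()]: 4-column BED-like TSV, 0-based
#' half-open, sorted by (chrom, start).
#'
#' @param annotation a `GRanges` with a `symbol` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  annotation <- sortAnnotation(annotation)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(annotation)),
                   GenomicRanges::start(annotation) - 1L,
                   GenomicRanges::end(annotation),
                   annotation$symbol)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-tissue expression matrix
#'
#' Tab-separated, one header row (first field a label such as "gene",
#' remaining fields tissue names), one row per gene with the symbol in the
#' first column. Values must be non-negative. A single-tissue file loads
#' with a warning; specificity scoring will refuse it.
#'
#' @param path path to the TSV file.
#' @return A [TissueExpression-class] with genes and tissues in file order.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs a gene column plus tissues")
  genes <- as.character(df[[1L]])
  tissues <- colnames(df)[-1L]
  if (anyDuplicated(tissues))
    stop("duplicate tissue name: ", tissues[duplicated(tissues)][1])
  if (anyDuplicated(genes))
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value")
  if (anyNA(m)) stop("missing expression value")
  if (any(m < 0)) stop("negative expression value")
  dimnames(m) <- list(genes, tissues)
  if (ncol(m) == 1L)
    warning("only one tissue column; specificity scoring requires >= 2")
  TissueExpression(m)
}

#' Write a gene-by-tissue expression matrix
#'
#' @param expr a [TissueExpression-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  m <- exprValues(expr)
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmtNum(m[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an interaction network from a two-column edge list
#'
#' Tab-separated, two symbols per line, no header (SIF-like with the
#' relation column omitted). Self-loops are dropped with a message giving
#' their count; duplicate edges are collapsed.
#'
#' @param path path to the edge-list file.
#' @return An [InteractionNetwork-class].
#' @export
readNetwork <- function(path) {
  fields <- splitLines(path, "edge-list", 2L, 2L)
  if (!length(fields)) return(InteractionNetwork())
  em <- do.call(rbind, fields)
  InteractionNetwork(em)
}

#' Write an interaction network as a two-column edge list
#'
#' Edges are written with each pair alphabetically ordered and rows
#' lexicographically sorted, so output is deterministic. Isolated nodes
#' are not representable in an edge list and are dropped with a message.
#'
#' @param network an [InteractionNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  em <- networkEdges(network)
  iso <- setdiff(networkGenes(network), unique(as.vector(em)))
  if (length(iso))
    message("edge list cannot carry ", length(iso), " isolated node(s)")
  writeLines(sprintf("%s\t%s", em[, 1], em[, 2]), path)
  invisible(path)
}

#' Read pathway gene sets in GMT format
#'
#' Each line: pathway name, description, then one gene symbol per field.
#'
#' @param path path to the GMT file.
#' @return A [PathwaySet-class].
#' @export
readGeneSetsGmt <- function(path) {
  fields <- splitLines(path, "GMT", 3L)
  if (!length(fields)) return(PathwaySet())
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate pathway name: ", nm[duplicated(nm)][1])
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  PathwaySet(sets, desc)
}

#' Write pathway gene sets in GMT format
#'
#' @param pathways a [PathwaySet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSetsGmt <- function(pathways, path) {
  nm <- sort(pathwayNames(pathways))
  sets <- pathwayGenes(pathways)
  desc <- pathways@description
  lines <- vapply(nm, function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

dosageTokens <- c("gain", "loss")

#' Read CNV calls
#'
#' Tab-separated with header `patient_id  chrom  start  end  dosage`
#' (0-based half-open; dosage one of `gain`/`loss`).
#'
#' @param path path to the segment TSV.
#' @return A `GRanges` with `patient_id` and `dosage` metadata columns,
#'   sorted by (patient, chrom, start).
#' @export
readCnvCalls <- function(path) {
  fields <- splitLines(path, "CNV", 5L, 5L)
  if (!length(fields)) return(emptyCnv())
  hdr <- fields[[1L]]
  if (!identical(hdr, c("patient_id", "chrom", "start", "end", "dosage")))
    stop("CNV file must start with header ",
         "'patient_id\tchrom\tstart\tend\tdosage'")
  fields <- fields[-1L]
  if (!length(fields)) return(emptyCnv())
  lineno <- seq_along(fields) + 1L
  patient <- vapply(fields, `[[`, "", 1L)
  chrom <- vapply(fields, `[[`, "", 2L)
  start0 <- parseCoord(vapply(fields, `[[`, "", 3L), "start", lineno)
  end0 <- parseCoord(vapply(fields, `[[`, "", 4L), "end", lineno)
  dosage <- vapply(fields, `[[`, "", 5L)
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) on line ", lineno[bad[1]])
  badDos <- which(!dosage %in% dosageTokens)
  if (length(badDos))
    stop("unknown dosage token '", dosage[badDos[1]], "' on line ",
         lineno[badDos[1]])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               patient_id = patient, dosage = dosage)
  sortCnv(gr)
}

emptyCnv <- function() {
  GenomicRanges::GRanges(character(), IRanges::IRanges(),
                         patient_id = character(), dosage = character())
}

sortCnv <- function(gr) {
  ord <- order(gr$patient_id,
               as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

#' Write CNV calls
#'
#' @param calls a `GRanges` with `patient_id` and `dosage` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCnvCalls <- function(calls, path) {
  calls <- sortCnv(calls)
  lines <- sprintf("%s\t%s\t%d\t%d\t%s",
                   calls$patient_id,
                   as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls) - 1L,
                   GenomicRanges::end(calls),
                   calls$dosage)
  writeLines(c("patient_id\tchrom\tstart\tend\tdosage", lines), path)
  invisible(path)
}

#' Read a benign-variant catalog
#'
#' Tab-separated with header `chrom  start  end  frequency` (0-based
#' half-open; frequency a population frequency in `[0, 1]`). This is the
#' local stand-in for a DGV-like catalog of variants observed in
#' apparently healthy populations.
#'
#' @param path path to the catalog TSV.
#' @return A `GRanges` with a `frequency` metadata column, sorted by
#'   (chrom, start).
#' @export
readVariantCatalog <- function(path) {
  fields <- splitLines(path, "catalog", 4L, 4L)
  if (!length(fields)) return(emptyCatalog())
  hdr <- fields[[1L]]
  if (!identical(hdr, c("chrom", "start", "end", "frequency")))
    stop("catalog file must start with header 'chrom\tstart\tend\tfrequency'")
  fields <- fields[-1L]
  if (!length(fields)) return(emptyCatalog())
  lineno <- seq_along(fields) + 1L
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- parseCoord(vapply(fields, `[[`, "", 2L), "start", lineno)
  end0 <- parseCoord(vapply(fields, `[[`, "", 3L), "end", lineno)
  freq <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) on line ", lineno[bad[1]])
  badF <- which(is.na(freq) | freq < 0 | freq > 1)
  if (length(badF))
    stop("frequency outside [0, 1] on line ", lineno[badF[1]])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               frequency = freq)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

emptyCatalog <- function() {
  GenomicRanges::GRanges(character(), IRanges::IRanges(),
                         frequency = numeric())
}

#' Write a benign-variant catalog
#'
#' @param catalog a `GRanges` with a `frequency` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantCatalog <- function(catalog, path) {
  ord <- order(as.character(GenomicRanges::seqnames(catalog)),
               GenomicRanges::start(catalog))
  catalog <- catalog[ord]
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(catalog)),
                   GenomicRanges::start(catalog) - 1L,
                   GenomicRanges::end(catalog),
                   fmtNum(catalog$frequency))
  writeLines(c("chrom\tstart\tend\tfrequency", lines), path)
  invisible(path)
}

#' Read a phenotype seed-gene list
#'
#' One gene symbol per line; blank lines and duplicates are dropped.
#'
#' @param path path to the list.
#' @return Character vector of unique seed symbols, in file order.
#' @export
readSeeds <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Write a phenotype seed-gene list
#' @param seeds character vector of symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeeds <- function(seeds, path) {
  writeLines(sort(unique(seeds)), path)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a report (any nested list of results, e.g. the value of
#' [runAll()]) as JSON, and optionally flattens tabular sections to TSV.
#' Output is byte-identical across runs for identical inputs: ordering is
#' deterministic and no timestamps enter the payload (the manifest's
#' `created` field is excluded from the payload digest, see
#' [payloadDigest()]).
#'
#' @param report a named list.
#' @param path output path; for `format = "tsv"` the report must contain a
#'   data frame under the name given by `section`.
#' @param format `"json"` or `"tsv"`.
#' @param section for TSV output, the name of the data-frame element to
#'   flatten.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "tsv"),
                        section = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null", na = "null")
    writeLines(json, path)
  } else {
    if (is.null(section)) stop("TSV output needs a 'section' name")
    df <- report[[section]]
    if (!is.data.frame(df)) stop("report section '", section,
                                 "' is not a data frame")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path path written by [writeReport()].
#' @return The report as a nested list / data frames.
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Digest of a report payload
#'
#' MD5 of the canonical JSON serialization with volatile manifest fields
#' (`created`) removed; two runs on identical inputs yield identical
#' digests.
#'
#' @param report a named list.
#' @return A length-1 character MD5 digest.
#' @export
payloadDigest <- function(report) {
  if (!is.null(report$manifest)) report$manifest$created <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE, null = "null", na = "null"), f)
  unname(tools::md5sum(f))
}
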