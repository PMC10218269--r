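# Readers/writers for the external formats: per-cytosine bisulfite reports,
# BED feature files, GMT gene-set collections and TPM expression tables.
# Internal coordinates are 0-based half-open everywhere; the file dialects
# convert at this boundary (cytosine reports are 1-based, BED is 0-based).

#' Read a per-cytosine bisulfite count report
#'
#' The report dialect is a headerless tab-separated table with columns
#' `chrom`, `pos` (1-based position of the cytosine on its strand), `strand`
#' (`+`/`-`), `count_m` (methylated basecalls), `count_u` (unmethylated
#' basecalls) and `context` (`CG`, `CA`, `CC` or `CT`). Positions are
#' converted to 0-based on read; rows with zero total calls are retained
#' (they contribute positions but no calls).
#'
#' @param path path to the report file.
#' @return `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `count_m`, `count_total`.
#' @export
read_cytosine_report <- function(path) {
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  count_m = integer(), count_total = integer())
  if (file.size(path) == 0L) return(empty)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character", fill = TRUE,
                      showProgress = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) != 6L)
    stop(sprintf("parse error in %s: expected 6 columns, found %d",
                 path, ncol(dt)))
  data.table::setnames(dt, c("chrom", "pos", "strand", "count_m",
                             "count_u", "context"))
  pos <- suppressWarnings(as.integer(dt$pos))
  count_m <- suppressWarnings(as.integer(dt$count_m))
  count_u <- suppressWarnings(as.integer(dt$count_u))
  bad <- which(is.na(pos) | is.na(count_m) | is.na(count_u) |
                 count_m < 0L | count_u < 0L)
  if (length(bad) > 0L)
    stop(sprintf("parse error in %s at line %d: malformed row",
                 path, bad[1L]))
  bad_ctx <- which(!dt$context %in% .BASE_CONTEXTS)
  if (length(bad_ctx) > 0L)
    stop(sprintf("parse error in %s at line %d: unknown context token '%s'",
                 path, bad_ctx[1L], dt$context[bad_ctx[1L]]))
  bad_str <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_str) > 0L)
    stop(sprintf("parse error in %s at line %d: bad strand '%s'",
                 path, bad_str[1L], dt$strand[bad_str[1L]]))
  data.table::data.table(chrom = dt$chrom, pos = pos - 1L,
                         strand = dt$strand, context = dt$context,
                         count_m = count_m, count_total = count_m + count_u)
}

#' Write a per-cytosine bisulfite count report
#'
#' Inverse of [read_cytosine_report()]: positions are written 1-based and the
#' unmethylated count is reconstructed as `count_total - count_m`. Reading a
#' canonical report and writing it back is byte-identical.
#'
#' @param records cytosine record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  records <- data.table::as.data.table(records)
  validate_records(records)
  out <- records[, list(chrom, pos = pos + 1L, strand, count_m,
                        count_u = count_total - count_m, context)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BED3+ feature file
#'
#' Accepts BED3 through BED6; intervals are kept 0-based half-open exactly as
#' stored. A missing name column is auto-assigned `"chrom:start-end"`, a
#' missing strand becomes `"."`.
#'
#' @param path path to a BED file.
#' @param feature_type label attached to every interval (e.g. `"gene"`,
#'   `"enhancer"`, `"DMR"`).
#' @return `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `feature_type`, `strand`.
#' @export
read_bed <- function(path, feature_type = "feature") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  feature_type = character(),
                                  strand = character()))
  }
  if (ncol(dt) < 3L)
    stop(sprintf("parse error in %s: BED needs at least 3 columns", path))
  chrom <- as.character(dt[[1L]])
  start <- as.integer(dt[[2L]])
  end <- as.integer(dt[[3L]])
  if (anyNA(start) || anyNA(end))
    stop(sprintf("parse error in %s: non-numeric coordinates", path))
  if (any(start >= end))
    stop(sprintf("invalid interval in %s at line %d: start >= end",
                 path, which(start >= end)[1L]))
  name <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else
    sprintf("%s:%d-%d", chrom, start, end)
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else
    rep(".", nrow(dt))
  strand[!strand %in% c("+", "-")] <- "."
  data.table::data.table(chrom = chrom, start = start, end = end,
                         name = name, feature_type = feature_type,
                         strand = strand)
}

#' Write features as BED6
#'
#' @param features feature table as returned by [read_bed()]; an optional
#'   `score` column is written to the BED score field (default 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  features <- data.table::as.data.table(features)
  score <- if ("score" %in% names(features)) features$score else 0L
  strand <- if ("strand" %in% names(features)) features$strand else "."
  out <- features[, list(chrom, start, end, name)]
  out[, `:=`(score = score, strand = strand)]
  data.table::setcolorder(out, c("chrom", "start", "end", "name", "score",
                                 "strand"))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene names. Duplicate genes within one set are removed with a
#' warning; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (set name to unique gene names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short) > 0L)
    stop(sprintf("parse error in %s at line %d: GMT lines need >= 3 fields",
                 path, short[1L]))
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate gene-set name(s) in %s: %s", path,
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup))
    warning(sprintf("duplicate genes removed in set(s): %s",
                    paste(nms[dup], collapse = ", ")))
  sets <- lapply(sets, unique)
  names(sets) <- nms
  sets
}

#' Write a GMT gene-set collection
#'
#' @param collection named list of gene name vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  description <- rep_len(description, length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], description[i], collection[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression (TPM) table
#'
#' Tab-separated with header columns `gene` and `tpm`. TPM values must be
#' finite and non-negative.
#'
#' @param path path to the TSV file.
#' @return `data.table` with columns `gene`, `tpm`.
#' @export
read_expression_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          showProgress = FALSE)
  if (!all(c("gene", "tpm") %in% names(dt)))
    stop(sprintf("parse error in %s: need columns 'gene' and 'tpm'", path))
  dt <- dt[, list(gene = as.character(gene), tpm = as.numeric(tpm))]
  if (any(!is.finite(dt$tpm)) || any(dt$tpm < 0))
    stop(sprintf("invalid TPM values in %s: must be finite and >= 0", path))
  dt[]
}

#' Write a gene expression (TPM) table
#'
#' @param expression table with columns `gene`, `tpm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  expression <- data.table::as.data.table(expression)
  data.table::fwrite(expression[, list(gene, tpm)], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
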