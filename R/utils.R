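# Internal helpers shared across modules.

# Base sequence contexts stored on records; CH is the derived union and is
# never stored as a token (it would double count CA/CC/CT).
.BASE_CONTEXTS <- c("CG", "CA", "CC", "CT")
.CH_CONTEXTS <- c("CA", "CC", "CT")
.ALL_CONTEXTS <- c(.BASE_CONTEXTS, "CH")

#' Expand a context token into the base contexts it covers
#'
#' `CH` is the union of `CA`, `CC` and `CT`; all other tokens map to
#' themselves.
#'
#' @param context one of `"CG"`, `"CA"`, `"CC"`, `"CT"`, `"CH"`.
#' @return character vector of base context tokens.
#' @export
expand_context <- function(context) {
  context <- match.arg(context, .ALL_CONTEXTS)
  if (context == "CH") .CH_CONTEXTS else context
}

# Deterministic 31-bit stream seed from a master seed plus labels, so each
# (sample, chromosome) pair gets its own reproducible stream regardless of
# generation order.
derive_seed <- function(seed, ...) {
  labs <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(labs)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

# Validate a cytosine record table (see read_cytosine_report for the schema).
validate_records <- function(records, what = "records") {
  need <- c("chrom", "pos", "strand", "context", "count_m", "count_total")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")))
  bad_ctx <- setdiff(unique(records$context), .BASE_CONTEXTS)
  if (length(bad_ctx) > 0L)
    stop(sprintf("%s has unknown context token(s): %s", what,
                 paste(bad_ctx, collapse = ", ")))
  if (any(records$count_m < 0L) || any(records$count_total < records$count_m))
    stop(sprintf("%s violates 0 <= count_m <= count_total", what))
  invisible(records)
}

#' Bundle a sample's cytosine records with its spike-in control
#'
#' A methylome sample holds the genome-wide cytosine record table for one
#' named sample plus its unmethylated spike-in records, from which the
#' per-context bisulfite nonconversion rates are estimated (see
#' [estimate_nonconversion()]).
#'
#' @param name sample name.
#' @param group biological group label (e.g. `"neuron_invitro"`).
#' @param records cytosine record `data.table` (0-based positions).
#' @param spikein spike-in cytosine records from the fully unmethylated
#'   control genome, or `NULL`.
#' @param nonconversion optional precomputed nonconversion rates; estimated
#'   from `spikein` when `NULL` and spike-in records are present.
#' @return object of class `methylome_sample`.
#' @export
methylome_sample <- function(name, group, records, spikein = NULL,
                             nonconversion = NULL) {
  records <- data.table::as.data.table(records)
  validate_records(records, sprintf("sample '%s'", name))
  if (!is.null(spikein)) {
    spikein <- data.table::as.data.table(spikein)
    validate_records(spikein, sprintf("spike-in of '%s'", name))
  }
  if (is.null(nonconversion) && !is.null(spikein))
    nonconversion <- estimate_nonconversion(spikein)
  structure(list(name = name, group = group, records = records,
                 spikein = spikein, nonconversion = nonconversion),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("<methylome_sample> %s (group %s): %d cytosines on %d sequence(s)\n",
              x$name, x$group, nrow(x$records),
              length(unique(x$records$chrom))))
  if (!is.null(x$nonconversion)) {
    nc <- x$nonconversion$rates
    cat("  nonconversion:",
        paste(sprintf("%s=%.4g", names(nc), nc), collapse = " "), "\n")
  }
  invisible(x)
}

# Nonconversion rate lookup for a (possibly pooled) context; NULL model -> 0.
nc_rate <- function(nonconversion, context) {
  if (is.null(nonconversion)) return(0)
  rates <- if (is.list(nonconversion)) nonconversion$rates else nonconversion
  if (!context %in% names(rates))
    stop(sprintf("no nonconversion rate for context %s", context))
  unname(rates[[context]])
}
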