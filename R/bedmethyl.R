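# bedMethyl (modkit dialect) I/O and strand handling.
#
# Coordinates are BED: 0-based, half-open. One row per modified-base position
# per strand; for a CpG dinucleotide the forward-strand C sits at position p
# and the reverse-strand C at p+1. Internally everything is keyed at p.

#' Read a bedMethyl file (modkit dialect)
#'
#' Parses tab-separated bedMethyl rows: column 1 chrom, 2 start (0-based),
#' 3 end, 4 modified-base code, 5 valid coverage, 6 strand, 11 percent
#' modified, 12 count modified. Rows for other modification codes (e.g. "h",
#' 5hmC) are excluded; only the requested code (default `"m"`, 5mC) is kept.
#'
#' The percent-modified column is normalized to a fraction in \[0, 1\]: if any
#' retained value exceeds 1 the whole column is treated as percentages and
#' divided by 100. The normalization is idempotent, so files already on the
#' fraction scale pass through unchanged.
#'
#' Gzip-compressed files (`.gz`) are read transparently.
#'
#' @param path bedMethyl file path.
#' @param mod_code modified-base code to retain (default `"m"`).
#' @return A data frame of class `methylation_calls` with columns `chrom`
#'   (normalized, no "chr" prefix), `start`, `end`, `mod_code`, `strand`,
#'   `n_valid`, `n_mod`, `percent_mod` (fraction).
#' @export
read_bedmethyl <- function(path, mod_code = "m") {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mod_code = character(), strand = character(),
                      n_valid = integer(), n_mod = integer(),
                      percent_mod = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("methylation_calls", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  keep_code <- vapply(fields, function(f) length(f) >= 4 && f[4] == mod_code,
                      logical(1))
  short <- which(keep_code & nf < 12)
  if (length(short) > 0) {
    stop("short bedMethyl row (", nf[short[1]], " fields, need >= 12) at line ",
         short[1], " of ", path)
  }
  fields <- fields[keep_code]
  lineno <- which(keep_code)
  n <- length(fields)

  get <- function(i) vapply(fields, `[[`, character(1), i)
  to_int <- function(x, what) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("non-integer ", what, " at line ", lineno[bad[1]], " of ", path)
    }
    v
  }
  if (n == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mod_code = character(), strand = character(),
                      n_valid = integer(), n_mod = integer(),
                      percent_mod = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("methylation_calls", "data.frame")
    return(out)
  }

  start <- to_int(get(2), "start")
  end <- to_int(get(3), "end")
  n_valid <- to_int(get(5), "valid coverage")
  n_mod <- to_int(get(12), "modified count")
  strand <- get(6)
  pct <- suppressWarnings(as.numeric(get(11)))
  if (anyNA(pct)) {
    stop("non-numeric percent-modified at line ", lineno[which(is.na(pct))[1]],
         " of ", path)
  }
  if (any(n_valid < 0) || any(n_mod < 0)) {
    bad <- which(n_valid < 0 | n_mod < 0)[1]
    stop("negative count at line ", lineno[bad], " of ", path)
  }
  over <- which(n_mod > n_valid)
  if (length(over) > 0) {
    stop("n_mod > n_valid (", n_mod[over[1]], " > ", n_valid[over[1]],
         ") at line ", lineno[over[1]], " of ", path)
  }
  if (any(end != start + 1L)) {
    bad <- which(end != start + 1L)[1]
    stop("bedMethyl interval is not a single base at line ", lineno[bad],
         " of ", path)
  }
  if (!all(strand %in% c("+", "-", "."))) {
    bad <- which(!strand %in% c("+", "-", "."))[1]
    stop("invalid strand '", strand[bad], "' at line ", lineno[bad], " of ", path)
  }
  pct <- normalize_percent(pct)

  out <- data.frame(chrom = norm_chrom(get(1)), start = start, end = end,
                    mod_code = get(4), strand = strand, n_valid = n_valid,
                    n_mod = n_mod, percent_mod = pct, stringsAsFactors = FALSE)
  class(out) <- c("methylation_calls", "data.frame")
  out
}

#' Normalize a percent-modified column to fractions
#'
#' If any value exceeds 1 the vector is taken to be on the 0-100 percent scale
#' and divided by 100; otherwise it is returned unchanged. Idempotent.
#'
#' @param x numeric vector of percentages or fractions.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
normalize_percent <- function(x) {
  if (length(x) > 0 && any(x > 1, na.rm = TRUE)) x <- x / 100
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("percent-modified values outside [0, 100]")
  }
  x
}

#' Collapse per-strand methylation calls into CpG sites
#'
#' Array probes interrogate a CpG regardless of read strand, so the
#' forward-strand call at position p and the reverse-strand call at p+1 are
#' pooled into one site keyed at p (the forward-strand C). An unpartnered
#' reverse-strand call at q forms a site keyed at q-1; an unpartnered forward
#' call keeps its own position. Calls with strand `"."` are treated as already
#' pooled and keyed at their own position (counted on the forward strand).
#' Counts are summed exactly; nothing is averaged.
#'
#' @param calls a `methylation_calls` data frame.
#' @return A data frame of class `cpg_sites` with per-strand and pooled
#'   counts (`n_valid_plus`, `n_mod_plus`, `n_valid_minus`, `n_mod_minus`,
#'   `n_valid_total`, `n_mod_total`), one row per CpG, ordered by chromosome
#'   then position.
#' @export
collapse_strands <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) > 0) {
    dup_key <- paste(calls$chrom, calls$start, calls$strand)
    if (anyDuplicated(dup_key)) {
      d <- dup_key[duplicated(dup_key)][1]
      stop("duplicate call (same chrom, position and strand): ", d)
    }
  }
  cpg_pos <- ifelse(calls$strand == "-", calls$start - 1L, calls$start)
  if (any(cpg_pos < 0)) stop("reverse-strand call at position 0 has no forward partner position")
  key <- paste(calls$chrom, cpg_pos, sep = "\r")
  is_minus <- calls$strand == "-"

  agg <- function(v) {
    out <- rowsum(as.numeric(v), key)
    out[, 1]
  }
  n_valid_plus <- agg(ifelse(is_minus, 0L, calls$n_valid))
  n_mod_plus <- agg(ifelse(is_minus, 0L, calls$n_mod))
  n_valid_minus <- agg(ifelse(is_minus, calls$n_valid, 0L))
  n_mod_minus <- agg(ifelse(is_minus, calls$n_mod, 0L))

  ukeys <- names(n_valid_plus)
  parts <- strsplit(ukeys, "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1),
    cpg_pos = as.integer(vapply(parts, `[[`, character(1), 2)),
    n_valid_plus = as.integer(n_valid_plus),
    n_mod_plus = as.integer(n_mod_plus),
    n_valid_minus = as.integer(n_valid_minus),
    n_mod_minus = as.integer(n_mod_minus),
    stringsAsFactors = FALSE
  )
  out$n_valid_total <- out$n_valid_plus + out$n_valid_minus
  out$n_mod_total <- out$n_mod_plus + out$n_mod_minus
  out <- out[order(out$chrom, out$cpg_pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_sites", "data.frame")
  out
}

#' Filter CpG sites by pooled coverage
#'
#' @param sites a `cpg_sites` data frame.
#' @param min_valid minimum pooled valid coverage to retain a site.
#' @return The retained sites; the number removed is reported via `message()`.
#' @export
filter_coverage <- function(sites, min_valid) {
  stopifnot(is.numeric(min_valid), length(min_valid) == 1, min_valid >= 0)
  keep <- sites$n_valid_total >= min_valid
  if (sum(!keep) > 0) {
    message("filter_coverage: removed ", sum(!keep), " of ", nrow(sites),
            " sites below ", min_valid, "x")
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write calls or CpG sites as bedMethyl
#'
#' Emits modkit-dialect rows. `cpg_sites` are written per strand: a row at the
#' CpG position for the forward-strand counts and one at position+1 for the
#' reverse-strand counts; strands with zero valid coverage are omitted.
#' `read_bedmethyl()` composed with `write_bedmethyl()` is the identity on
#' positions, strands and counts.
#'
#' @param x a `methylation_calls` or `cpg_sites` data frame.
#' @param path output file; an empty input produces an empty file.
#' @param mod_code modification code to write for `cpg_sites` input.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(x, path, mod_code = "m") {
  if (inherits(x, "cpg_sites")) {
    rows <- sites_to_call_rows(x, mod_code)
  } else {
    rows <- data.frame(chrom = x$chrom, start = x$start, mod_code = x$mod_code,
                       strand = x$strand, n_valid = x$n_valid, n_mod = x$n_mod,
                       stringsAsFactors = FALSE)
  }
  if (nrow(rows) == 0) {
    file.create(path)
    return(invisible(path))
  }
  pct <- ifelse(rows$n_valid > 0, 100 * rows$n_mod / rows$n_valid, 0)
  lines <- paste(denorm_chrom(rows$chrom), rows$start, rows$start + 1L,
                 rows$mod_code, rows$n_valid, rows$strand,
                 rows$start, rows$start + 1L, "255,0,0", rows$n_valid,
                 sprintf("%.2f", pct), rows$n_mod,
                 rows$n_valid - rows$n_mod,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

sites_to_call_rows <- function(sites, mod_code) {
  plus <- sites[sites$n_valid_plus > 0, , drop = FALSE]
  minus <- sites[sites$n_valid_minus > 0, , drop = FALSE]
  rows <- rbind(
    data.frame(chrom = plus$chrom, start = plus$cpg_pos,
               mod_code = rep(mod_code, nrow(plus)),
               strand = rep("+", nrow(plus)), n_valid = plus$n_valid_plus,
               n_mod = plus$n_mod_plus, stringsAsFactors = FALSE),
    data.frame(chrom = minus$chrom, start = minus$cpg_pos + 1L,
               mod_code = rep(mod_code, nrow(minus)),
               strand = rep("-", nrow(minus)),
               n_valid = minus$n_valid_minus, n_mod = minus$n_mod_minus,
               stringsAsFactors = FALSE)
  )
  rows[order(rows$chrom, rows$start, rows$strand), , drop = FALSE]
}
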