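#' @keywords internal
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' @keywords internal
denorm_chrom <- function(x) paste0("chr", as.character(x))

as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) {
    stop("column '", col, "' contains values that are not interpretable as logical")
  }
  out
}

#' Read a probe manifest
#'
#' Reads a CSV/TSV probe manifest with columns `probe_id`, `chrom`, `position`
#' (1-based, array-manifest convention), `strand`, `in_v1`, `in_v2` and an
#' optional `v2_id`. Positions are converted to the package's internal 0-based
#' convention (`cpg_pos` is the forward-strand C of the CpG dinucleotide) and
#' chromosome names are normalized by stripping any `"chr"` prefix.
#'
#' For probes flagged `in_v2` with no explicit `v2_id`, the v2 identifier
#' defaults to the probe's own ID. A `v2_id` on a probe with `in_v2 = FALSE`
#' is rejected as inconsistent, as is any duplicated `probe_id` or duplicated
#' `v2_id` (one-to-many v1 to v2 mappings are not representable).
#'
#' @param path path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) manifest file.
#' @return A data frame of class `probe_manifest` with columns `probe_id`,
#'   `chrom`, `cpg_pos` (0-based integer), `strand`, `in_v1`, `in_v2`, `v2_id`
#'   (`NA` when absent from v2).
#' @seealso [write_manifest()], [map_probe_set_v1_to_v2()]
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("probe_id", "chrom", "position", "strand", "in_v1", "in_v2")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!"v2_id" %in% names(df)) df$v2_id <- NA_character_
  df$v2_id[!is.na(df$v2_id) & trimws(df$v2_id) == ""] <- NA_character_

  pos <- suppressWarnings(as.numeric(df$position))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0) {
    stop("non-integer position at line ", bad[1] + 1L,
         " of ", path, ": '", df$position[bad[1]], "'")
  }
  if (any(pos < 1)) stop("manifest positions must be >= 1 (1-based convention)")

  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup) > 0) {
    stop("duplicate probe_id in manifest: ", paste(dup, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("manifest strand must be '+' or '-'")
  }

  out <- data.frame(
    probe_id = df$probe_id,
    chrom = norm_chrom(df$chrom),
    cpg_pos = as.integer(pos - 1L),
    strand = df$strand,
    in_v1 = as_flag(df$in_v1, "in_v1"),
    in_v2 = as_flag(df$in_v2, "in_v2"),
    v2_id = df$v2_id,
    stringsAsFactors = FALSE
  )
  if (any(!out$in_v2 & !is.na(out$v2_id))) {
    bad_id <- out$probe_id[!out$in_v2 & !is.na(out$v2_id)][1]
    stop("probe '", bad_id, "' has a v2_id but in_v2 = FALSE")
  }
  out$v2_id[out$in_v2 & is.na(out$v2_id)] <-
    out$probe_id[out$in_v2 & is.na(out$v2_id)]
  dup2 <- unique(out$v2_id[!is.na(out$v2_id) & duplicated(out$v2_id, incomparables = NA)])
  if (length(dup2) > 0) {
    stop("one-to-many v1 to v2 mapping: v2_id ", paste(dup2, collapse = ", "),
         " assigned to multiple probes")
  }
  class(out) <- c("probe_manifest", "data.frame")
  out
}

#' Write a probe manifest
#'
#' Inverse of [read_manifest()]: internal 0-based `cpg_pos` is written back as
#' a 1-based `position` and chromosome names regain their `"chr"` prefix, so a
#' normalized manifest round-trips byte-stably.
#'
#' @param manifest a `probe_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "probe_manifest"))
  out <- data.frame(
    probe_id = manifest$probe_id,
    chrom = denorm_chrom(manifest$chrom),
    position = manifest$cpg_pos + 1L,
    strand = manifest$strand,
    in_v1 = manifest$in_v1,
    in_v2 = manifest$in_v2,
    v2_id = ifelse(is.na(manifest$v2_id), "", manifest$v2_id),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a probe set
#'
#' An ordered, de-duplicated collection of probe identifiers tagged with the
#' manifest version it was defined on (episignature probe lists are published
#' against a specific array manifest).
#'
#' @param probe_ids character vector of probe IDs; duplicates are removed with
#'   a warning, order of first occurrence is preserved.
#' @param name label for the set (e.g. the syndrome the signature detects).
#' @param source_version `"v1"` or `"v2"`.
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(probe_ids, name = "probe_set", source_version = "v1") {
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) == 0) stop("probe set '", name, "' is empty")
  source_version <- match.arg(source_version, c("v1", "v2"))
  if (anyDuplicated(probe_ids)) {
    dups <- unique(probe_ids[duplicated(probe_ids)])
    warning("probe set '", name, "': removed duplicate ID(s): ",
            paste(dups, collapse = ", "))
    probe_ids <- probe_ids[!duplicated(probe_ids)]
  }
  structure(list(name = name, probe_ids = probe_ids,
                 source_version = source_version),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("Probe set '", x$name, "' (", x$source_version, "): ",
      length(x$probe_ids), " probes\n", sep = "")
  invisible(x)
}

#' @export
length.probe_set <- function(x) length(x$probe_ids)

#' Read a probe set from a text file
#'
#' One probe ID per line; blank lines and `#` comments (whole-line or
#' trailing) are skipped. Duplicate IDs are dropped with a warning.
#'
#' @param path input file.
#' @param name set label; defaults to the file name without extension.
#' @param source_version manifest version the IDs refer to.
#' @return A [probe_set].
#' @export
read_probe_set <- function(path, name = NULL, source_version = "v1") {
  if (!file.exists(path)) stop("probe set file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("probe set file '", path, "' contains no probe IDs")
  probe_set(lines, name = name, source_version = source_version)
}

#' Write a probe set to a text file
#' @param x a [probe_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_set <- function(x, path) {
  stopifnot(inherits(x, "probe_set"))
  writeLines(x$probe_ids, path)
  invisible(path)
}

#' Harmonize a v1 probe set to manifest version v2
#'
#' Episignatures published against the MethylationEPIC v1 manifest must be
#' carried over to v2 before v2-based profiles can be scored. Each input ID
#' present in the manifest with `in_v2 = TRUE` maps to its v2 identifier; IDs
#' absent from v2 (or from the manifest altogether) are dropped. The mapped
#' and dropped sets always partition the input.
#'
#' @param probes a [probe_set] with `source_version = "v1"`.
#' @param manifest a `probe_manifest` from [read_manifest()].
#' @return A list with elements `mapped` (a v2 [probe_set]), `dropped`
#'   (character vector of v1 IDs that could not be mapped) and `map` (a data
#'   frame of `v1_id`, `v2_id` for the mapped probes).
#' @examples
#' m <- data.frame(probe_id = c("A", "B", "C"), chrom = "1",
#'                 cpg_pos = c(10L, 20L, 30L), strand = "+",
#'                 in_v1 = TRUE, in_v2 = c(TRUE, FALSE, TRUE),
#'                 v2_id = c("A", NA, "C2"))
#' class(m) <- c("probe_manifest", "data.frame")
#' map_probe_set_v1_to_v2(probe_set(c("A", "B", "C")), m)
#' @export
map_probe_set_v1_to_v2 <- function(probes, manifest) {
  stopifnot(inherits(probes, "probe_set"), inherits(manifest, "probe_manifest"))
  if (probes$source_version != "v1") {
    stop("probe set '", probes$name, "' is not a v1 set")
  }
  idx <- match(probes$probe_ids, manifest$probe_id)
  mappable <- !is.na(idx) & manifest$in_v2[idx]
  v2 <- ifelse(mappable, manifest$v2_id[idx], NA_character_)
  dropped <- probes$probe_ids[!mappable]
  if (!any(mappable)) {
    stop("no probe of '", probes$name, "' maps to the v2 manifest")
  }
  mapped <- probe_set(v2[mappable], name = probes$name, source_version = "v2")
  list(mapped = mapped,
       dropped = dropped,
       map = data.frame(v1_id = probes$probe_ids[mappable],
                        v2_id = v2[mappable],
                        stringsAsFactors = FALSE))
}

# Resolve probe-set IDs against a manifest: an ID matches the record whose
# v2_id equals it, falling back to probe_id. Returns row indices; unresolved
# IDs raise an error naming the first offender.
resolve_probes <- function(ids, manifest) {
  idx <- match(ids, manifest$v2_id)
  fallback <- is.na(idx)
  idx[fallback] <- match(ids[fallback], manifest$probe_id)
  if (anyNA(idx)) {
    stop("probe ID(s) not present in manifest: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  idx
}
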