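# Probe-level beta values.
#
# The beta value of a probe is the fraction of methylated reads over total
# valid reads at the probe's CpG, computed from strand-pooled counts. No
# array-style normalization (background correction, BMIQ, dye bias) is
# applied: sequencing-derived fractions are compared to array betas as-is.

#' Extract probe-level beta values for one sample
#'
#' Intersects strand-collapsed CpG sites with the genomic coordinates of the
#' requested probes and computes, for every probe whose site has pooled
#' coverage of at least `min_valid`, beta = n_mod_total / n_valid_total.
#' Probes with no site or insufficient coverage are reported in
#' `missing_probes`; together with the betas they always cover the requested
#' set exactly.
#'
#' Probe IDs are resolved against the manifest by `v2_id` first, then
#' `probe_id`, so both v1 and harmonized v2 sets work. A probe's design strand
#' is a manifest attribute only; pooled counts are used regardless.
#'
#' @param sites a `cpg_sites` data frame from [collapse_strands()].
#' @param manifest a `probe_manifest`.
#' @param probes a [probe_set]; every ID must resolve in the manifest.
#' @param min_valid minimum pooled coverage for a beta call (default 5).
#' @param sample_id sample label attached to the profile.
#' @param platform `"nanopore"` or `"array"`.
#' @param group `"case"`, `"control"` or `"unknown"`.
#' @return An object of class `beta_profile`: a list with `sample_id`,
#'   `platform`, `group`, `betas` (named numeric, values in \[0, 1\]),
#'   `coverage` (named integer, pooled depth per called probe) and
#'   `missing_probes` (character).
#' @export
extract_probe_betas <- function(sites, manifest, probes, min_valid = 5,
                                sample_id = "sample", platform = "nanopore",
                                group = "unknown") {
  stopifnot(inherits(probes, "probe_set"), inherits(manifest, "probe_manifest"))
  platform <- match.arg(platform, c("nanopore", "array"))
  group <- match.arg(group, c("case", "control", "unknown"))
  idx <- resolve_probes(probes$probe_ids, manifest)

  site_key <- paste(sites$chrom, sites$cpg_pos, sep = "\r")
  probe_key <- paste(manifest$chrom[idx], manifest$cpg_pos[idx], sep = "\r")
  hit <- match(probe_key, site_key)

  depth <- ifelse(is.na(hit), 0L, sites$n_valid_total[hit])
  called <- !is.na(hit) & depth >= min_valid & depth > 0
  betas <- sites$n_mod_total[hit[called]] / sites$n_valid_total[hit[called]]
  names(betas) <- probes$probe_ids[called]
  coverage <- sites$n_valid_total[hit[called]]
  names(coverage) <- probes$probe_ids[called]

  structure(list(
    sample_id = sample_id,
    platform = platform,
    group = group,
    betas = betas,
    coverage = coverage,
    missing_probes = probes$probe_ids[!called]
  ), class = "beta_profile")
}

#' @export
print.beta_profile <- function(x, ...) {
  cat("Beta profile '", x$sample_id, "' (", x$platform, ", ", x$group, "): ",
      length(x$betas), " probes called, ", length(x$missing_probes),
      " missing\n", sep = "")
  invisible(x)
}

#' Construct a beta matrix
#'
#' Probes-by-samples matrix of beta values with per-sample annotations.
#'
#' @param values numeric matrix (probes in rows, samples in columns) with
#'   dimnames; all entries in \[0, 1\], no missing values.
#' @param samples data frame with columns `sample_id`, `group`, `platform`,
#'   one row per column of `values`, in order.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  if (anyNA(values)) stop("beta matrix contains undefined entries")
  if (any(values < 0 | values > 1)) stop("beta values must lie in [0, 1]")
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group", "platform") %in% names(samples)),
            nrow(samples) == ncol(values))
  if (!identical(as.character(samples$sample_id), colnames(values))) {
    stop("sample annotation order does not match matrix columns")
  }
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples (", sum(x$samples$group == "case"), " case, ",
      sum(x$samples$group == "control"), " control)\n", sep = "")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
as.matrix.beta_matrix <- function(x, ...) x$values

#' Subset a beta matrix
#'
#' @param x a `beta_matrix`.
#' @param i probe selector (row). @param j sample selector (column).
#' @param ... ignored.
#' @export
`[.beta_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  beta_matrix(v, x$samples[match(colnames(v), x$samples$sample_id), , drop = FALSE])
}

#' Merge beta profiles (and an optional reference) into one matrix
#'
#' Columns are merged over the intersection of probes defined in every column;
#' probes missing from any column are dropped with a warning attributing the
#' loss to the offending sample(s). No imputation is performed by default:
#' missingness at signature probes is a data-quality signal, and imputing
#' would fabricate it away. Setting `impute_mean = TRUE` instead fills each
#' column's missing probes with that probe's cross-column mean (computed over
#' the columns that did measure it) and keeps the union of probes.
#'
#' @param profiles list of `beta_profile` objects.
#' @param reference optional `beta_matrix` (e.g. array reference samples)
#'   whose columns are appended.
#' @param impute_mean fill missing probe values with cross-sample probe means
#'   instead of intersecting (default `FALSE`).
#' @return A [beta_matrix]. Probe order follows the reference when supplied,
#'   else the first profile's requested order.
#' @export
merge_beta_profiles <- function(profiles, reference = NULL,
                                impute_mean = FALSE) {
  if (inherits(profiles, "beta_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "beta_profile")))
  n_cols <- length(profiles) + if (is.null(reference)) 0L else ncol(reference$values)
  if (n_cols < 2) stop("merge needs at least two columns in total")

  if (!is.null(reference)) {
    order_probes <- rownames(reference$values)
  } else {
    order_probes <- c(names(profiles[[1]]$betas), profiles[[1]]$missing_probes)
  }
  defined <- lapply(profiles, function(p) names(p$betas))
  if (!is.null(reference)) defined <- c(list(rownames(reference$values)), defined)
  all_probes <- unique(c(order_probes, unlist(defined)))
  common <- Reduce(intersect, defined)

  keep <- if (impute_mean) all_probes else order_probes[order_probes %in% common]
  if (length(keep) == 0) stop("empty probe intersection across columns")

  dropped <- setdiff(all_probes, common)
  if (length(dropped) > 0 && !impute_mean) {
    culprits <- vapply(dropped, function(p) {
      miss <- vapply(profiles, function(pr) !p %in% names(pr$betas), logical(1))
      who <- vapply(profiles[miss], `[[`, character(1), "sample_id")
      if (!is.null(reference) && !p %in% rownames(reference$values)) {
        who <- c(who, "reference")
      }
      paste(who, collapse = "/")
    }, character(1))
    warning("dropped ", length(dropped), " probe(s) missing from some column: ",
            paste(utils::head(paste0(dropped, " (", culprits, ")"), 10),
                  collapse = ", "))
  }

  cols <- lapply(profiles, function(p) unname(p$betas[match(keep, names(p$betas))]))
  values <- do.call(cbind, cols)
  rownames(values) <- keep
  colnames(values) <- vapply(profiles, `[[`, character(1), "sample_id")
  samples <- data.frame(
    sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
    group = vapply(profiles, `[[`, character(1), "group"),
    platform = vapply(profiles, `[[`, character(1), "platform"),
    stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    ref_vals <- reference$values[match(keep, rownames(reference$values)), ,
                                 drop = FALSE]
    rownames(ref_vals) <- keep
    values <- cbind(ref_vals, values)
    samples <- rbind(reference$samples[, c("sample_id", "group", "platform")],
                     samples)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs across merged columns: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (impute_mean) {
    for (i in which(apply(is.na(values), 2, any))) {
      miss <- is.na(values[, i])
      fill <- rowMeans(values[miss, , drop = FALSE], na.rm = TRUE)
      if (anyNA(fill)) stop("probe measured in no column; cannot impute")
      values[miss, i] <- fill
    }
  }
  beta_matrix(values, samples)
}

#' Write a beta matrix to CSV
#'
#' The matrix file has a `probe_id` column followed by one column per sample,
#' values rounded to 6 decimal places (the round-trip precision of
#' [read_beta_matrix()]). Sample annotations go to a sidecar CSV.
#'
#' @param x a `beta_matrix`.
#' @param path matrix CSV path.
#' @param annotation_path sidecar CSV (default: `path` with `_samples.csv`).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path,
                              annotation_path = default_annotation_path(path)) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(probe_id = rownames(x$values),
                   round(x$values, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$samples, annotation_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_annotation_path <- function(path) {
  sub("\\.csv$", "_samples.csv", path)
}

#' Read a beta matrix written by [write_beta_matrix()]
#'
#' @param path matrix CSV. @param annotation_path sidecar annotation CSV.
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path,
                             annotation_path = default_annotation_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  samples <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  beta_matrix(values, samples)
}
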