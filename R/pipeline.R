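# End-to-end orchestration: bedMethyl files -> beta matrix -> analytics.

pkg_version <- function() {
  as.character(utils::packageVersion("nanoepisign"))
}

write_result_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nanoepisign ", pkg_version(), " seed=", seed,
                    " date=", format(Sys.Date())), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run the full episignature analysis
#'
#' Reads per-sample bedMethyl files, strand-collapses the calls, extracts
#' probe-level betas over the signature probe set, merges them with the
#' labeled array reference into one matrix, and runs the analytics stack:
#' cross-platform correlations, hierarchical clustering (Newick dendrogram),
#' classical MDS and UMAP embeddings, nearest-centroid + SVM classification
#' of the sequenced samples, leave-one-out validation of the reference, and
#' an optional probe-set specificity check.
#'
#' @param bedmethyl_files named character vector: sample ID -> bedMethyl
#'   path.
#' @param manifest a `probe_manifest` (or path to a manifest file).
#' @param probes the signature [probe_set] (or path; assumed v2 when loaded
#'   from file here).
#' @param reference labeled reference [beta_matrix] (or path to its CSV).
#' @param groups optional named character vector of sample groups for the
#'   sequenced samples (default `"unknown"`).
#' @param out_dir optional output directory; when given, result CSVs (with a
#'   header comment recording package version and seed) and the Newick
#'   dendrogram are written there.
#' @param min_valid minimum pooled coverage for a beta call (default 5).
#' @param seed seed for the UMAP embedding (default 15).
#' @param pairs optional data frame of sample pairs for
#'   [platform_correlations()]; by default each sequenced sample is paired
#'   with the reference column of the same individual when the sample ID is
#'   `"<reference id>_np"`.
#' @param decoy_sets optional list of decoy [probe_set]s for
#'   [specificity_check()].
#' @return List with `matrix`, `profiles`, `classification`, `centroid_loo`,
#'   `svm_loo`, `correlations`, `umap`, `mds`, `hclust`, `newick`,
#'   `specificity` (or `NULL` where not computed), and `missing_report`.
#' @export
run_episignature_analysis <- function(bedmethyl_files, manifest, probes,
                                      reference, groups = NULL,
                                      out_dir = NULL, min_valid = 5,
                                      seed = 15, pairs = NULL,
                                      decoy_sets = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(probes)) probes <- read_probe_set(probes, source_version = "v2")
  if (is.character(reference)) reference <- read_beta_matrix(reference)
  if (is.null(names(bedmethyl_files)) || any(!nzchar(names(bedmethyl_files)))) {
    stop("bedmethyl_files must be a named vector (sample_id = path)")
  }

  profiles <- lapply(names(bedmethyl_files), function(sid) {
    calls <- read_bedmethyl(bedmethyl_files[[sid]])
    if (nrow(calls) == 0) stop("bedMethyl file for sample '", sid, "' is empty")
    sites <- collapse_strands(calls)
    grp <- if (!is.null(groups) && sid %in% names(groups)) groups[[sid]] else "unknown"
    extract_probe_betas(sites, manifest, probes, min_valid = min_valid,
                        sample_id = sid, platform = "nanopore", group = grp)
  })
  missing_report <- data.frame(
    sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
    n_called = vapply(profiles, function(p) length(p$betas), integer(1)),
    n_missing = vapply(profiles, function(p) length(p$missing_probes), integer(1)),
    stringsAsFactors = FALSE
  )
  ref_sub <- reference[rownames(reference$values) %in% probes$probe_ids, ]
  mat <- merge_beta_profiles(profiles, reference = ref_sub)

  if (is.null(pairs)) {
    np_ids <- names(bedmethyl_files)
    ref_ids <- sub("_np$", "", np_ids)
    keep <- ref_ids %in% colnames(reference$values) & ref_ids != np_ids
    pairs <- data.frame(sample_a = ref_ids[keep], sample_b = np_ids[keep],
                        stringsAsFactors = FALSE)
  }
  correlations <- if (nrow(pairs) > 0) platform_correlations(mat, pairs) else NULL

  hc <- beta_hclust(mat)
  newick <- dendrogram_newick(hc)
  mds <- beta_mds(mat, k = 2)
  um <- if (ncol(mat$values) >= 4) umap_embed(mat, seed = seed) else NULL

  fit <- episign_fit(reference, probes)
  classification <- predict(fit, profiles)
  loo <- centroid_loo(reference, probes)
  svm_loo <- svm_loo_validate(reference, probes)

  specificity <- if (!is.null(decoy_sets)) {
    specificity_check(mat, probes, decoy_sets)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_beta_matrix(mat, file.path(out_dir, "beta_matrix.csv"))
    write_result_csv(classification, file.path(out_dir, "classification.csv"), seed)
    write_result_csv(loo, file.path(out_dir, "centroid_loo.csv"), seed)
    write_result_csv(svm_loo$predictions, file.path(out_dir, "svm_loo.csv"), seed)
    if (!is.null(correlations)) {
      write_result_csv(correlations, file.path(out_dir, "correlations.csv"), seed)
    }
    emb <- data.frame(sample_id = rownames(mds$coordinates),
                      dim1 = mds$coordinates[, 1], dim2 = mds$coordinates[, 2],
                      method = "mds", seed = NA_integer_)
    if (!is.null(um)) {
      emb <- rbind(emb, data.frame(sample_id = rownames(um$coordinates),
                                   dim1 = um$coordinates[, 1],
                                   dim2 = um$coordinates[, 2],
                                   method = "umap", seed = seed))
    }
    write_result_csv(emb, file.path(out_dir, "embedding.csv"), seed)
    writeLines(newick, file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(specificity)) {
      write_result_csv(specificity, file.path(out_dir, "specificity.csv"), seed)
    }
  }

  list(matrix = mat, profiles = profiles, classification = classification,
       centroid_loo = loo, svm_loo = svm_loo, correlations = correlations,
       umap = um, mds = mds, hclust = hc, newick = newick,
       specificity = specificity, missing_report = missing_report)
}
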