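# Reference-based episignature classification.
#
# The fitted object holds two decision rules over the signature probes:
#   * a nearest-centroid score s = (d_control - d_case) / (d_control + d_case),
#     where d_* is the Euclidean distance to the labeled reference centroid
#     (parameter-free, exactly anti-symmetric under label swap); and
#   * a linear soft-margin SVM with inverse class weights.
# The centroid score is the primary rule; a sample is called positive iff
# s > 0 (a tie at s = 0 is conservatively negative).

#' Fit an episignature classification model
#'
#' Builds case and control reference centroids and a linear support-vector
#' machine over the signature probes of a labeled reference beta matrix.
#'
#' @param reference a [beta_matrix] whose sample annotations include both
#'   `"case"` and `"control"` groups.
#' @param probes a [probe_set] naming the signature probes; IDs absent from
#'   the reference are dropped with a warning.
#' @param cost SVM soft-margin cost (default 1).
#' @param svm fit the SVM component (default `TRUE`); with `FALSE` the model
#'   is centroid-only.
#' @return An object of class `episign_model` with components `probes`
#'   (character), `centroids` (probes x 2 matrix, columns `case`/`control`),
#'   `reference`, `svm` (an [e1071::svm] fit or `NULL`), `probe_set_name`.
#' @seealso [predict.episign_model()], [centroid_classify()],
#'   [svm_loo_validate()]
#' @export
episign_fit <- function(reference, probes, cost = 1, svm = TRUE) {
  stopifnot(inherits(reference, "beta_matrix"), inherits(probes, "probe_set"))
  groups <- reference$samples$group
  if (!all(c("case", "control") %in% groups)) {
    stop("reference must contain both 'case' and 'control' samples")
  }
  ids <- probes$probe_ids[probes$probe_ids %in% rownames(reference$values)]
  if (length(ids) < length(probes$probe_ids)) {
    warning("probe set '", probes$name, "': ",
            length(probes$probe_ids) - length(ids),
            " probe(s) absent from the reference were dropped")
  }
  if (length(ids) < 3) stop("fewer than 3 signature probes found in the reference")
  vals <- reference$values[ids, , drop = FALSE]
  centroids <- cbind(
    case = rowMeans(vals[, groups == "case", drop = FALSE]),
    control = rowMeans(vals[, groups == "control", drop = FALSE])
  )
  svm_fit <- NULL
  if (svm) {
    svm_fit <- fit_linear_svm(t(vals), groups, cost)
  }
  structure(list(probes = ids, centroids = centroids, reference = reference,
                 svm = svm_fit, cost = cost, probe_set_name = probes$name,
                 call = match.call()),
            class = "episign_model")
}

fit_linear_svm <- function(x, groups, cost) {
  y <- factor(groups, levels = c("control", "case"))
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE,
             class.weights = "inverse")
}

# Signed SVM margin, oriented so positive favors "case".
svm_margin <- function(fit, x) {
  pr <- stats::predict(fit, newdata = x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "case") as.numeric(dv) else -as.numeric(dv)
}

#' @export
print.episign_model <- function(x, ...) {
  s <- x$reference$samples
  cat("Episignature model '", x$probe_set_name, "'\n", sep = "")
  cat("  ", length(x$probes), " signature probes; reference: ",
      sum(s$group == "case"), " case / ", sum(s$group == "control"),
      " control samples\n", sep = "")
  cat("  rules: nearest-centroid score",
      if (!is.null(x$svm)) paste0(" + linear SVM (cost ", x$cost, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Per-probe signature contrast of a fitted model
#'
#' @param object an `episign_model`.
#' @param ... ignored.
#' @return Named numeric vector of case-minus-control centroid differences,
#'   one per signature probe.
#' @export
coef.episign_model <- function(object, ...) {
  object$centroids[, "case"] - object$centroids[, "control"]
}

#' Classify samples against an episignature model
#'
#' For each sample the nearest-centroid score is computed over the model's
#' signature probes; a sample must cover at least `min_coverage` of them. The
#' SVM margin is reported when every signature probe is present (the linear
#' decision function needs the full feature vector), `NA` otherwise.
#'
#' @param object an [episign_fit()] model.
#' @param newdata a `beta_profile`, a list of them, or a [beta_matrix].
#' @param min_coverage minimum fraction of signature probes a sample must
#'   cover (default 0.9); below it classification aborts, naming the missing
#'   probes.
#' @param ... ignored.
#' @return Data frame with columns `sample_id`, `centroid_score`,
#'   `svm_margin`, `label` (`"positive"` iff `centroid_score > 0`),
#'   `n_probes_used`, `probe_set`.
#' @export
predict.episign_model <- function(object, newdata, min_coverage = 0.9, ...) {
  cols <- newdata_columns(newdata)
  res <- lapply(names(cols), function(sid) {
    betas <- cols[[sid]]
    present <- object$probes[object$probes %in% names(betas)]
    coverage <- length(present) / length(object$probes)
    if (coverage < min_coverage) {
      miss <- setdiff(object$probes, names(betas))
      stop("sample '", sid, "' covers only ", round(100 * coverage, 1),
           "% of the signature probes (need >= ", 100 * min_coverage,
           "%); missing: ", paste(utils::head(miss, 10), collapse = ", "),
           if (length(miss) > 10) ", ...")
    }
    v <- betas[present]
    s <- centroid_score(v, object$centroids[present, , drop = FALSE])
    margin <- NA_real_
    if (!is.null(object$svm) && coverage == 1) {
      xm <- matrix(betas[object$probes], nrow = 1,
                   dimnames = list(sid, object$probes))
      margin <- svm_margin(object$svm, xm)
    }
    data.frame(sample_id = sid, centroid_score = s, svm_margin = margin,
               label = if (s > 0) "positive" else "negative",
               n_probes_used = length(present), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$probe_set <- object$probe_set_name
  rownames(out) <- NULL
  out
}

centroid_score <- function(v, centroids) {
  d_case <- sqrt(sum((v - centroids[, "case"])^2))
  d_ctrl <- sqrt(sum((v - centroids[, "control"])^2))
  if (d_case + d_ctrl == 0) return(0)
  (d_ctrl - d_case) / (d_ctrl + d_case)
}

newdata_columns <- function(newdata) {
  if (inherits(newdata, "beta_profile")) newdata <- list(newdata)
  if (inherits(newdata, "beta_matrix")) {
    cols <- lapply(seq_len(ncol(newdata$values)), function(j) newdata$values[, j])
    names(cols) <- colnames(newdata$values)
    return(cols)
  }
  stopifnot(all(vapply(newdata, inherits, logical(1), "beta_profile")))
  cols <- lapply(newdata, `[[`, "betas")
  names(cols) <- vapply(newdata, `[[`, character(1), "sample_id")
  cols
}

#' Nearest-centroid episignature classification
#'
#' Parameter-free primary decision rule: the sample's Euclidean distances to
#' the case and control reference centroids over the signature probes give
#' the score s = (d_control - d_case) / (d_control + d_case) in \[-1, 1\].
#' Positive label iff s > 0; swapping the case and control reference labels
#' negates s exactly.
#'
#' @param profile a `beta_profile` (or a [beta_matrix] of samples to score).
#' @param reference labeled reference [beta_matrix].
#' @param probes signature [probe_set].
#' @param min_coverage minimum signature coverage (default 0.9).
#' @return Data frame as in [predict.episign_model()] (with `svm_margin`
#'   always `NA`; this rule is SVM-free).
#' @export
centroid_classify <- function(profile, reference, probes, min_coverage = 0.9) {
  fit <- episign_fit(reference, probes, svm = FALSE)
  predict(fit, profile, min_coverage = min_coverage)
}

#' Leave-one-out nearest-centroid validation of a reference set
#'
#' Each reference sample is scored against centroids rebuilt from the
#' remaining samples.
#'
#' @param reference labeled reference [beta_matrix].
#' @param probes signature [probe_set].
#' @return Data frame with `sample_id`, `group`, `centroid_score`, `label`.
#' @export
centroid_loo <- function(reference, probes) {
  stopifnot(inherits(reference, "beta_matrix"))
  n <- ncol(reference$values)
  res <- lapply(seq_len(n), function(i) {
    train <- reference[, -i]
    if (length(unique(train$samples$group[train$samples$group %in%
                                          c("case", "control")])) < 2) {
      stop("leave-one-out fold lacks a class; need >= 2 samples per class")
    }
    fit <- episign_fit(train, probes, svm = FALSE)
    held <- reference$values[, i]
    names(held) <- rownames(reference$values)
    prof <- structure(list(sample_id = colnames(reference$values)[i],
                           platform = reference$samples$platform[i],
                           group = reference$samples$group[i],
                           betas = held, coverage = NULL,
                           missing_probes = character(0)),
                      class = "beta_profile")
    cbind(predict(fit, prof)[, c("sample_id", "centroid_score", "label")],
          group = reference$samples$group[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("sample_id", "group", "centroid_score", "label")]
}

#' Leave-one-out validation of the linear SVM rule
#'
#' Refits the linear soft-margin SVM with each reference sample held out in
#' turn and reports the held-out signed margin (positive favors case), the
#' predicted group, and overall accuracy. Deterministic: the quadratic
#' program has a unique solution for fixed inputs, and no randomness enters.
#'
#' With `balance_folds = TRUE` (the default) each fold additionally drops one
#' sample of the *opposite* class (chosen by deterministic cycling), so the
#' class-size decrement is the same whichever class the held-out sample
#' belongs to. Plain leave-one-out on high-dimensional data has a
#' well-documented anti-learning bias: the held-out sample's class is
#' under-represented by one, and with many more probes than samples the
#' max-margin boundary then systematically places the held-out sample on the
#' wrong side, driving null accuracy far below chance. Balancing the fold
#' restores the symmetry under which null accuracy sits at 1/2.
#'
#' @param reference labeled reference [beta_matrix] with at least 3 samples
#'   per class.
#' @param probes signature [probe_set].
#' @param cost SVM soft-margin cost (default 1).
#' @param balance_folds drop one opposite-class sample per fold (default
#'   `TRUE`); `FALSE` gives plain leave-one-out.
#' @return List with `predictions` (data frame: `sample_id`, `group`,
#'   `margin`, `predicted`) and `accuracy`.
#' @export
svm_loo_validate <- function(reference, probes, cost = 1,
                             balance_folds = TRUE) {
  stopifnot(inherits(reference, "beta_matrix"), inherits(probes, "probe_set"))
  groups <- reference$samples$group
  if (length(unique(groups)) < 2) stop("single-class reference; need case and control")
  if (min(table(groups)) < 3) {
    stop("need at least 3 samples per class for leave-one-out SVM validation")
  }
  ids <- probes$probe_ids[probes$probe_ids %in% rownames(reference$values)]
  if (length(ids) < 2) stop("signature probes not found in reference")
  x <- t(reference$values[ids, , drop = FALSE])
  n <- nrow(x)
  margin <- numeric(n)
  rank_in_class <- stats::ave(seq_len(n), groups, FUN = seq_along)
  for (i in seq_len(n)) {
    drop <- i
    if (balance_folds) {
      other <- which(groups != groups[i])
      partner <- other[(rank_in_class[i] - 1L) %% length(other) + 1L]
      drop <- c(i, partner)
    }
    fit <- fit_linear_svm(x[-drop, , drop = FALSE], groups[-drop], cost)
    margin[i] <- svm_margin(fit, x[i, , drop = FALSE])
  }
  predicted <- ifelse(margin > 0, "case", "control")
  preds <- data.frame(sample_id = rownames(x), group = groups,
                      margin = margin, predicted = predicted,
                      stringsAsFactors = FALSE)
  list(predictions = preds, accuracy = mean(predicted == groups), cost = cost)
}

#' Summarize an episignature model by leave-one-out validation
#'
#' @param object an `episign_model`.
#' @param ... ignored.
#' @return An object of class `summary.episign_model` carrying the centroid
#'   leave-one-out table and, when the model has an SVM component, the SVM
#'   leave-one-out accuracy.
#' @export
summary.episign_model <- function(object, ...) {
  ps <- probe_set(object$probes, name = object$probe_set_name,
                  source_version = "v2")
  loo <- centroid_loo(object$reference, ps)
  loo_acc <- mean((loo$group == "case") == (loo$label == "positive"))
  svm_acc <- if (!is.null(object$svm)) {
    svm_loo_validate(object$reference, ps, cost = object$cost)$accuracy
  } else NA_real_
  structure(list(model = object, centroid_loo = loo,
                 centroid_loo_accuracy = loo_acc, svm_loo_accuracy = svm_acc),
            class = "summary.episign_model")
}

#' @export
print.summary.episign_model <- function(x, ...) {
  print(x$model)
  cat("  leave-one-out (centroid) accuracy: ",
      round(x$centroid_loo_accuracy, 3), "\n", sep = "")
  if (!is.na(x$svm_loo_accuracy)) {
    cat("  leave-one-out (SVM) accuracy:      ",
        round(x$svm_loo_accuracy, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Plot an episignature model
#'
#' Classical MDS of the reference samples (and optional new profiles) over
#' the signature probes, colored by group, plotting symbol by platform.
#'
#' @param x an `episign_model`.
#' @param newdata optional `beta_profile` list or [beta_matrix] to project
#'   alongside the reference.
#' @param ... passed to [graphics::plot()].
#' @export
plot.episign_model <- function(x, newdata = NULL, ...) {
  mat <- x$reference
  if (!is.null(newdata)) {
    if (inherits(newdata, "beta_profile")) newdata <- list(newdata)
    if (is.list(newdata) && !inherits(newdata, "beta_matrix")) {
      mat <- merge_beta_profiles(newdata, reference = x$reference)
    } else {
      stop("newdata must be beta_profile(s)")
    }
  }
  keep <- rownames(mat$values) %in% x$probes
  emb <- beta_mds(mat[keep, ], k = 2)
  grp <- mat$samples$group
  plt <- mat$samples$platform
  graphics::plot(emb$coordinates, col = ifelse(grp == "case", 2, 4),
                 pch = ifelse(plt == "nanopore", 17, 19),
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("case", "control", "array", "nanopore"),
                   col = c(2, 4, 1, 1), pch = c(15, 15, 19, 17))
  invisible(emb)
}

#' Specificity of an episignature across probe sets
#'
#' Restricts the matrix to each probe set in turn and reports the
#' case/control silhouette over the full Euclidean geometry of the restricted
#' probes (equivalently, over all metric-MDS coordinates). A genuine
#' episignature separates on its own (target) probe set and not on decoy
#' sets from unrelated syndromes.
#'
#' The silhouette is deliberately not computed on a 2-D embedding: projecting
#' exchangeable samples onto their two leading axes manufactures chance
#' grouping structure, giving the null statistic a heavy upper tail, whereas
#' in the full restricted-probe geometry distances concentrate and a
#' signal-free probe set scores near zero. The 2-D plots remain the
#' visualization companion ([beta_mds()], [umap_embed()]).
#'
#' @param x a [beta_matrix] with case/control groups.
#' @param target_set the signature [probe_set] under test.
#' @param decoy_sets list of decoy [probe_set]s; overlap with the target set
#'   is allowed but warned about.
#' @return Data frame with `set_name`, `is_target`, `n_probes`,
#'   `silhouette`, target first.
#' @export
specificity_check <- function(x, target_set, decoy_sets) {
  stopifnot(inherits(x, "beta_matrix"), inherits(target_set, "probe_set"))
  if (inherits(decoy_sets, "probe_set")) decoy_sets <- list(decoy_sets)
  for (d in decoy_sets) {
    ov <- intersect(d$probe_ids, target_set$probe_ids)
    if (length(ov) > 0) {
      warning("decoy set '", d$name, "' overlaps the target set (",
              length(ov), " probe(s))")
    }
  }
  sets <- c(list(target_set), decoy_sets)
  res <- lapply(seq_along(sets), function(i) {
    ids <- intersect(sets[[i]]$probe_ids, rownames(x$values))
    if (length(ids) < 2) {
      stop("probe set '", sets[[i]]$name, "' has fewer than 2 probes in the matrix")
    }
    pts <- t(x$values[rownames(x$values) %in% ids, , drop = FALSE])
    data.frame(set_name = sets[[i]]$name, is_target = i == 1,
               n_probes = length(ids),
               silhouette = group_silhouette(pts, x$samples$group),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
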