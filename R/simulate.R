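# Synthetic study generator.
#
# Emulates the statistical structure the analysis assumes, at the scale of a
# small episignature study: a probe manifest with version drift (a v1-defined
# signature partly absent from v2), per-probe bimodal control methylation, a
# uniform case-specific mean shift at signature probes, and per-CpG
# sequencing counts drawn binomially at a target depth and split across
# strands. Every stage is deterministic under the config seed and retains
# truth records so downstream estimates can be checked against exact
# recounting.

#' Simulation configuration
#'
#' @param n_probes_total total probes on the synthetic manifest.
#' @param n_signature_probes size of the v1-defined signature (default 203).
#' @param n_v1_only_probes signature probes absent from the v2 manifest
#'   (default 24, so 179 survive harmonization).
#' @param delta case-minus-control mean beta shift at signature probes.
#' @param mean_depth target pooled reads per CpG for sequencing samples.
#' @param n_controls,n_cases reference cohort sizes.
#' @param mix_low,mix_high Beta(shape1, shape2) parameters of the low- and
#'   high-methylation modes of the control mixture (defaults give modes with
#'   means 0.1 and 0.85).
#' @param mix_weight probability of the low mode.
#' @param noise_sd per-sample Gaussian beta noise (default 0.03).
#' @param depth_model `"poisson"` (default), `"fixed"` (every CpG exactly at
#'   `mean_depth`) or `"nbinom"` (overdispersed).
#' @param nb_size negative-binomial size when `depth_model = "nbinom"`.
#' @param rename_frac fraction of v2-present signature probes carrying a
#'   different identifier on v2 (exercises the ID-harmonization path).
#' @param seed integer master seed; all generator stages derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes_total = 1000, n_signature_probes = 203,
                       n_v1_only_probes = 24, delta = 0.15, mean_depth = 30,
                       n_controls = 20, n_cases = 5,
                       mix_low = c(2, 18), mix_high = c(17, 3),
                       mix_weight = 0.5, noise_sd = 0.03,
                       depth_model = c("poisson", "fixed", "nbinom"),
                       nb_size = 5, rename_frac = 0.1, seed = 1) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_signature_probes <= n_probes_total,
            n_v1_only_probes <= n_signature_probes,
            delta >= -1, delta <= 1, mean_depth > 0,
            n_controls >= 1, n_cases >= 1,
            mix_weight >= 0, mix_weight <= 1, noise_sd >= 0,
            rename_frac >= 0, rename_frac <= 1)
  structure(list(
    n_probes_total = as.integer(n_probes_total),
    n_signature_probes = as.integer(n_signature_probes),
    n_v1_only_probes = as.integer(n_v1_only_probes),
    delta = delta, mean_depth = mean_depth,
    n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
    mix_low = mix_low, mix_high = mix_high, mix_weight = mix_weight,
    noise_sd = noise_sd, depth_model = depth_model, nb_size = nb_size,
    rename_frac = rename_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clip_prob <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Simulate a probe manifest with version drift
#'
#' Draws `n_probes_total` probes with distinct CpG positions on synthetic
#' contigs. A random subset of `n_signature_probes` forms the v1 signature;
#' `n_v1_only_probes` of those are marked absent from v2, and `rename_frac`
#' of the remaining signature probes carry a changed v2 identifier.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config].
#' @return List with `manifest` (a `probe_manifest`) and `signature` (the v1
#'   [probe_set]).
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_probes_total
    ids <- sprintf("cg%07d", seq_len(n))
    chroms <- as.character(sample(1:22, n, replace = TRUE))
    pos <- integer(n)
    for (ch in unique(chroms)) {
      sel <- chroms == ch
      p <- sample.int(20000000L, sum(sel))
      tries <- 0
      while (anyDuplicated(p)) {         # distinct CpG positions per contig
        p[duplicated(p)] <- sample.int(20000000L, sum(duplicated(p)))
        tries <- tries + 1
        if (tries > 100) stop("could not draw distinct probe positions")
      }
      pos[sel] <- p
    }
    sig_idx <- sort(sample.int(n, config$n_signature_probes))
    v1_only <- sort(sample(sig_idx, config$n_v1_only_probes))
    in_v2 <- rep(TRUE, n)
    in_v2[v1_only] <- FALSE
    v2_id <- ifelse(in_v2, ids, NA_character_)
    renameable <- setdiff(sig_idx, v1_only)
    n_ren <- floor(config$rename_frac * length(renameable))
    if (n_ren > 0) {
      ren <- sort(sample(renameable, n_ren))
      v2_id[ren] <- paste0(ids[ren], "_v2")
    }
    manifest <- data.frame(
      probe_id = ids, chrom = chroms, cpg_pos = pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      in_v1 = TRUE, in_v2 = in_v2, v2_id = v2_id,
      stringsAsFactors = FALSE
    )
    class(manifest) <- c("probe_manifest", "data.frame")
    list(manifest = manifest,
         signature = probe_set(ids[sig_idx], name = "signature",
                               source_version = "v1"))
  })
}

#' Simulate labeled reference beta values (array platform)
#'
#' Per-probe control means are drawn from the bimodal Beta mixture; each
#' control column adds Gaussian noise (`noise_sd`) to the probe mean, and
#' each case column additionally shifts the mean by `delta` at the
#' harmonized signature probes. All values are clipped to \[0.01, 0.99\]
#' before any later binomial sampling.
#'
#' @param config a [sim_config].
#' @param sim a [simulate_manifest()] result (manifest plus v1 signature).
#' @return List with `reference` (a [beta_matrix] keyed by v2 probe IDs,
#'   platform `"array"`), `signature_v2` (harmonized [probe_set]), `truth`
#'   (long data frame: `sample_id`, `probe_id`, `true_beta`) and
#'   `probe_means` (the noiseless control means).
#' @export
simulate_reference_betas <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- sim$manifest
  mapping <- map_probe_set_v1_to_v2(sim$signature, manifest)
  probe_ids <- manifest$v2_id[manifest$in_v2]
  is_sig <- probe_ids %in% mapping$mapped$probe_ids

  with_seed(config$seed + 1L, {
    m <- length(probe_ids)
    low <- stats::rbeta(m, config$mix_low[1], config$mix_low[2])
    high <- stats::rbeta(m, config$mix_high[1], config$mix_high[2])
    mu <- clip_prob(ifelse(stats::runif(m) < config$mix_weight, low, high))

    sample_ids <- c(sprintf("control_%02d", seq_len(config$n_controls)),
                    sprintf("case_%02d", seq_len(config$n_cases)))
    group <- rep(c("control", "case"), c(config$n_controls, config$n_cases))
    values <- vapply(seq_along(sample_ids), function(j) {
      shift <- if (group[j] == "case") config$delta * is_sig else 0
      clip_prob(mu + shift + stats::rnorm(m, 0, config$noise_sd))
    }, numeric(m))
    dimnames(values) <- list(probe_ids, sample_ids)
    truth <- data.frame(
      sample_id = rep(sample_ids, each = m),
      probe_id = rep(probe_ids, length(sample_ids)),
      true_beta = as.vector(values),
      stringsAsFactors = FALSE
    )
    samples <- data.frame(sample_id = sample_ids, group = group,
                          platform = "array", stringsAsFactors = FALSE)
    list(reference = beta_matrix(values, samples),
         signature_v2 = mapping$mapped, truth = truth, probe_means = mu)
  })
}

#' Simulate per-sample bedMethyl files from truth betas
#'
#' For every probe of a truth sample the pooled depth is drawn from the
#' configured depth model, split binomially between strands, and methylated
#' reads are drawn per strand as Binomial(strand depth, true beta) — so the
#' pooled methylated count is Binomial(depth, beta). Rows are written in
#' modkit dialect, one per strand; a depth draw of 0 writes no row and the
#' probe surfaces later as missing. Byte-identical output under a fixed
#' seed.
#'
#' @param truth long truth data frame (`sample_id`, `probe_id`, `true_beta`).
#' @param manifest the `probe_manifest` the probe IDs resolve against.
#' @param config a [sim_config].
#' @param dir output directory (created if needed).
#' @param truth_samples which truth sample IDs to sequence (default: the
#'   case samples).
#' @param suffix appended to the truth sample ID to name the sequencing
#'   sample (default `"_np"`), keeping array and nanopore columns of the
#'   same individual distinct.
#' @return List with `files` (data frame: `sample_id`, `truth_sample_id`,
#'   `path`) and `truth` (realized records: `sample_id`, `probe_id`,
#'   `true_beta`, `depth`, `n_mod`).
#' @export
simulate_bedmethyl <- function(truth, manifest, config, dir,
                               truth_samples = NULL, suffix = "_np") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth_samples)) {
    truth_samples <- unique(truth$sample_id[grepl("^case", truth$sample_id)])
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draw_depth <- switch(config$depth_model,
    poisson = function(m) stats::rpois(m, config$mean_depth),
    fixed = function(m) rep(as.integer(round(config$mean_depth)), m),
    nbinom = function(m) stats::rnbinom(m, mu = config$mean_depth,
                                        size = config$nb_size))
  with_seed(config$seed + 2L, {
    out_truth <- vector("list", length(truth_samples))
    files <- vector("list", length(truth_samples))
    for (k in seq_along(truth_samples)) {
      ts <- truth_samples[k]
      tt <- truth[truth$sample_id == ts, , drop = FALSE]
      idx <- resolve_probes(tt$probe_id, manifest)
      m <- nrow(tt)
      depth <- draw_depth(m)
      n_plus <- stats::rbinom(m, depth, 0.5)
      n_minus <- depth - n_plus
      mod_plus <- stats::rbinom(m, n_plus, tt$true_beta)
      mod_minus <- stats::rbinom(m, n_minus, tt$true_beta)
      sites <- data.frame(
        chrom = manifest$chrom[idx], cpg_pos = manifest$cpg_pos[idx],
        n_valid_plus = n_plus, n_mod_plus = mod_plus,
        n_valid_minus = n_minus, n_mod_minus = mod_minus,
        n_valid_total = depth, n_mod_total = mod_plus + mod_minus,
        stringsAsFactors = FALSE
      )
      sites <- sites[sites$n_valid_total > 0, , drop = FALSE]
      sites <- sites[order(sites$chrom, sites$cpg_pos), , drop = FALSE]
      class(sites) <- c("cpg_sites", "data.frame")
      sid <- paste0(ts, suffix)
      path <- file.path(dir, paste0(sid, ".bedmethyl"))
      write_bedmethyl(sites, path)
      files[[k]] <- data.frame(sample_id = sid, truth_sample_id = ts,
                               path = path, stringsAsFactors = FALSE)
      out_truth[[k]] <- data.frame(sample_id = sid, probe_id = tt$probe_id,
                                   true_beta = tt$true_beta, depth = depth,
                                   n_mod = mod_plus + mod_minus,
                                   stringsAsFactors = FALSE)
    }
    list(files = do.call(rbind, files), truth = do.call(rbind, out_truth))
  })
}

#' Generate a complete synthetic study fixture
#'
#' Runs the full generator: manifest + v1 signature, harmonization to v2,
#' labeled array reference matrix, and per-case nanopore bedMethyl files,
#' writing every artifact to `dir` (manifest CSV, probe-set text files,
#' reference matrix + annotation CSVs, bedMethyl files, truth CSV).
#'
#' @param config a [sim_config].
#' @param dir output directory.
#' @return Invisibly, a list with the in-memory objects (`manifest`,
#'   `signature_v1`, `signature_v2`, `reference`, `files`, `truth`,
#'   `config`) and `paths` to everything written.
#' @export
simulate_study <- function(config = sim_config(), dir = tempfile("episim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_manifest(config)
  ref <- simulate_reference_betas(config, sim)
  np <- simulate_bedmethyl(ref$truth, sim$manifest, config,
                           file.path(dir, "bedmethyl"))
  paths <- list(
    manifest = file.path(dir, "manifest.csv"),
    signature_v1 = file.path(dir, "signature_v1.txt"),
    signature_v2 = file.path(dir, "signature_v2.txt"),
    reference = file.path(dir, "reference_betas.csv"),
    truth = file.path(dir, "truth.csv"),
    bedmethyl = np$files$path
  )
  write_manifest(sim$manifest, paths$manifest)
  write_probe_set(sim$signature, paths$signature_v1)
  write_probe_set(ref$signature_v2, paths$signature_v2)
  write_beta_matrix(ref$reference, paths$reference)
  utils::write.csv(np$truth, paths$truth, row.names = FALSE)
  invisible(list(manifest = sim$manifest, signature_v1 = sim$signature,
                 signature_v2 = ref$signature_v2, reference = ref$reference,
                 probe_means = ref$probe_means, files = np$files,
                 truth = np$truth, array_truth = ref$truth,
                 config = config, dir = dir, paths = paths))
}
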