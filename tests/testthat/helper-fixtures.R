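# In-code fixtures shared across test files.

toy_manifest <- function() {
  m <- data.frame(
    probe_id = c("cg000001", "cg000002", "cg000003"),
    chrom = c("1", "1", "X"),
    cpg_pos = c(99L, 199L, 49L),
    strand = c("+", "-", "+"),
    in_v1 = TRUE,
    in_v2 = c(TRUE, FALSE, TRUE),
    v2_id = c("cg000001", NA, "cg000003_v2"),
    stringsAsFactors = FALSE
  )
  class(m) <- c("probe_manifest", "data.frame")
  m
}

write_toy_manifest_csv <- function(path,
                                   probe_id = c("cg000001", "cg000002", "cg000003"),
                                   position = c(100L, 200L, 50L)) {
  df <- data.frame(probe_id = probe_id,
                   chrom = c("chr1", "chr1", "chrX"),
                   position = position,
                   strand = c("+", "-", "+"),
                   in_v1 = TRUE,
                   in_v2 = c(TRUE, FALSE, TRUE),
                   v2_id = c("", "", "cg000003_v2"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# One bedMethyl row in the modkit dialect (13 tab-separated fields).
bm_row <- function(chrom = "chr1", start = 99, code = "m", n_valid = 20,
                   strand = "+", pct = NULL, n_mod = 15) {
  if (is.null(pct)) {
    pct <- sprintf("%.2f", if (n_valid > 0) 100 * n_mod / n_valid else 0)
  }
  paste(chrom, start, start + 1, code, n_valid, strand, start, start + 1,
        "255,0,0", n_valid, pct, n_mod, n_valid - n_mod, sep = "\t")
}

write_bm <- function(lines, path = tempfile(fileext = ".bedmethyl")) {
  writeLines(lines, path)
  path
}

# Random valid methylation calls on distinct (position, strand) keys.
random_calls <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(100000L, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_valid <- rpois(n, 20) + 1L
  n_mod <- rbinom(n, n_valid, runif(n))
  out <- data.frame(chrom = "1", start = start, end = start + 1L,
                    mod_code = "m", strand = strand, n_valid = n_valid,
                    n_mod = n_mod,
                    percent_mod = ifelse(n_valid > 0, n_mod / n_valid, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("methylation_calls", "data.frame")
  out
}

# Small labeled beta matrix: per-probe means with an optional case shift.
toy_beta_matrix <- function(n_probes = 40, n_controls = 6, n_cases = 4,
                            delta = 0.2, noise_sd = 0.03, seed = 7) {
  set.seed(seed)
  mu <- pmin(pmax(rbeta(n_probes, 2, 2), 0.01), 0.99)
  ids <- sprintf("p%03d", seq_len(n_probes))
  samples <- data.frame(
    sample_id = c(sprintf("ctl%02d", seq_len(n_controls)),
                  sprintf("cas%02d", seq_len(n_cases))),
    group = rep(c("control", "case"), c(n_controls, n_cases)),
    platform = "array", stringsAsFactors = FALSE
  )
  vals <- vapply(seq_len(nrow(samples)), function(j) {
    shift <- if (samples$group[j] == "case") delta else 0
    pmin(pmax(mu + shift + rnorm(n_probes, 0, noise_sd), 0), 1)
  }, numeric(n_probes))
  dimnames(vals) <- list(ids, samples$sample_id)
  beta_matrix(vals, samples)
}

# Exhaustive O(n^3) complete-linkage reference used as clustering oracle.
naive_complete_linkage <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    members[[step]] <- merged
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  list(heights = heights, members = members)
}

# Member sets of each merge in an hclust tree, in merge order.
hclust_members <- function(hc) {
  n <- length(hc$order)
  out <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    grab <- function(v) {
      unlist(lapply(v, function(e) if (e < 0) -e else out[[e]]))
    }
    out[[k]] <- sort(grab(hc$merge[k, ]))
  }
  out
}
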