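test_that("probe beta is methylated reads over total reads at the probe CpG", {
  m <- toy_manifest()
  sites <- data.frame(chrom = "1", cpg_pos = 99L,
                      n_valid_plus = 12L, n_mod_plus = 9L,
                      n_valid_minus = 8L, n_mod_minus = 6L,
                      n_valid_total = 20L, n_mod_total = 15L)
  class(sites) <- c("cpg_sites", "data.frame")
  prof <- extract_probe_betas(sites, m, probe_set("cg000001"), min_valid = 5,
                              sample_id = "s1")
  expect_equal(unname(prof$betas["cg000001"]), 0.75)
  expect_equal(unname(prof$coverage["cg000001"]), 20L)
  expect_length(prof$missing_probes, 0)

  # probe with no site lands in missing_probes; betas + missing cover the set
  prof2 <- extract_probe_betas(sites, m, probe_set(c("cg000001", "cg000002")),
                               min_valid = 5, sample_id = "s1")
  expect_equal(prof2$missing_probes, "cg000002")
  expect_setequal(c(names(prof2$betas), prof2$missing_probes),
                  c("cg000001", "cg000002"))

  # coverage below min_valid is treated as missing
  prof3 <- extract_probe_betas(sites, m, probe_set("cg000001"), min_valid = 21)
  expect_equal(prof3$missing_probes, "cg000001")

  expect_error(extract_probe_betas(sites, m, probe_set("cg_absent")),
               "cg_absent")
})

test_that("probe IDs resolve through v2 identifiers", {
  m <- toy_manifest()
  sites <- data.frame(chrom = "X", cpg_pos = 49L,
                      n_valid_plus = 10L, n_mod_plus = 2L,
                      n_valid_minus = 0L, n_mod_minus = 0L,
                      n_valid_total = 10L, n_mod_total = 2L)
  class(sites) <- c("cpg_sites", "data.frame")
  prof <- extract_probe_betas(sites, m, probe_set("cg000003_v2",
                                                  source_version = "v2"))
  expect_equal(unname(prof$betas), 0.2)
})

test_that("extracted betas match exact recounting from simulator truth", {
  cfg <- sim_config(n_probes_total = 250, n_signature_probes = 50,
                    n_v1_only_probes = 5, mean_depth = 25, seed = 5)
  sim <- simulate_manifest(cfg)
  ref <- simulate_reference_betas(cfg, sim)
  np <- simulate_bedmethyl(ref$truth, sim$manifest, cfg, tempfile("bm"),
                           truth_samples = c("case_01", "control_01"))
  all_v2 <- probe_set(sim$manifest$v2_id[sim$manifest$in_v2],
                      source_version = "v2")
  for (i in seq_len(nrow(np$files))) {
    sid <- np$files$sample_id[i]
    sites <- collapse_strands(read_bedmethyl(np$files$path[i]))
    prof <- extract_probe_betas(sites, sim$manifest, all_v2, min_valid = 1,
                                sample_id = sid)
    tr <- np$truth[np$truth$sample_id == sid, ]
    tr <- tr[tr$depth > 0, ]
    oracle <- tr$n_mod / tr$depth
    names(oracle) <- tr$probe_id
    expect_identical(sort(names(prof$betas)), sort(names(oracle)))
    expect_identical(prof$betas[names(oracle)], oracle)
    expect_identical(unname(prof$coverage[tr$probe_id]), tr$depth)
  }
})

test_that("beta estimates converge to truth at high depth", {
  cfg <- sim_config(n_probes_total = 200, n_signature_probes = 40,
                    n_v1_only_probes = 0, mean_depth = 10000,
                    depth_model = "fixed", n_cases = 1, seed = 17)
  sim <- simulate_manifest(cfg)
  ref <- simulate_reference_betas(cfg, sim)
  np <- simulate_bedmethyl(ref$truth, sim$manifest, cfg, tempfile("bm"),
                           truth_samples = "case_01")
  sites <- collapse_strands(read_bedmethyl(np$files$path[1]))
  all_v2 <- probe_set(sim$manifest$v2_id[sim$manifest$in_v2],
                      source_version = "v2")
  prof <- extract_probe_betas(sites, sim$manifest, all_v2, min_valid = 1)
  truth <- np$truth$true_beta
  names(truth) <- np$truth$probe_id
  err <- abs(prof$betas - truth[names(prof$betas)])
  expect_lt(max(err), 0.02)
})

test_that("merging intersects probes and attributes drops to samples", {
  mk_prof <- function(id, probes, betas) {
    structure(list(sample_id = id, platform = "nanopore", group = "unknown",
                   betas = setNames(betas, probes), coverage = NULL,
                   missing_probes = character(0)), class = "beta_profile")
  }
  p1 <- mk_prof("s1", c("A", "B", "C"), c(0.1, 0.5, 0.9))
  p2 <- mk_prof("s2", c("A", "C"), c(0.2, 0.8))
  expect_warning(mat <- merge_beta_profiles(list(p1, p2)), "B \\(s2\\)")
  expect_equal(rownames(mat$values), c("A", "C"))
  expect_equal(ncol(mat$values), 2)

  p3 <- mk_prof("s3", c("A", "B", "C"), c(0.3, 0.4, 0.5))
  mat2 <- merge_beta_profiles(list(p1, p3))
  expect_equal(dim(mat2$values), c(3L, 2L))

  p4 <- mk_prof("s4", "D", 0.5)
  expect_error(suppressWarnings(merge_beta_profiles(list(p1, p4))),
               "empty probe intersection")
  expect_error(merge_beta_profiles(list(p1)), "at least two columns")
})

test_that("profiles merge against an array reference over the signature set", {
  study <- simulate_study(sim_config(n_probes_total = 400, seed = 23),
                          dir = tempfile("study"))
  files <- setNames(study$files$path, study$files$sample_id)
  profiles <- lapply(names(files), function(sid) {
    extract_probe_betas(collapse_strands(read_bedmethyl(files[[sid]])),
                        study$manifest, study$signature_v2, min_valid = 1,
                        sample_id = sid)
  })
  ref <- study$reference[rownames(study$reference$values) %in%
                           study$signature_v2$probe_ids, ]
  mat <- merge_beta_profiles(profiles, reference = ref)
  expect_equal(nrow(mat$values), 179)
  expect_equal(ncol(mat$values), 30)  # 25 array + 5 nanopore columns
  expect_false(anyNA(mat$values))
})

test_that("beta matrix CSV round-trips at 6 decimal places", {
  mat <- toy_beta_matrix(seed = 31)
  path <- tempfile(fileext = ".csv")
  write_beta_matrix(mat, path)
  back <- read_beta_matrix(path)
  expect_equal(back$values, round(mat$values, 6))
  expect_equal(back$samples, mat$samples)
  # second round-trip is exact
  path2 <- tempfile(fileext = ".csv")
  write_beta_matrix(back, path2)
  expect_identical(read_beta_matrix(path2)$values, back$values)
})

test_that("beta matrix constructor enforces its invariants", {
  v <- matrix(c(0.2, 0.4, 0.6, 0.8), 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  s <- data.frame(sample_id = c("s1", "s2"), group = "control",
                  platform = "array")
  expect_s3_class(beta_matrix(v, s), "beta_matrix")
  v_bad <- v; v_bad[1, 1] <- 1.2
  expect_error(beta_matrix(v_bad, s), "\\[0, 1\\]")
  v_na <- v; v_na[2, 1] <- NA
  expect_error(beta_matrix(v_na, s), "undefined")
  expect_error(beta_matrix(v, s[2:1, ]), "order")
})
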