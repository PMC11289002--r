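test_that("the generator is deterministic and validates its configuration", {
  f1 <- generate_family(generator_config(seed = 42))
  f2 <- generate_family(generator_config(seed = 42))
  expect_identical(f1$alignment$seq, f2$alignment$seq)
  expect_identical(f1$topology$tm_intervals, f2$topology$tm_intervals)
  f3 <- generate_family(generator_config(seed = 43))
  expect_false(identical(f1$alignment$seq, f3$alignment$seq))

  bad <- stats::setNames(rep(0.06, 20), AA_LETTERS)  # sums to 1.2
  expect_error(generator_config(region_compositions = list(TM = bad)),
               "config error")
  expect_error(generator_config(region_rates = c(TM = 1.0)), "config error")
  expect_error(generator_config(architecture = list(loop_lengths = c(5, 5))),
               "loop_lengths")
})

test_that("zero substitution rates reproduce the ancestor exactly", {
  cfg <- generator_config(
    seed = 5,
    phyla = data.frame(name = "fish", n_species = 6L, branch_scale = 1),
    architecture = list(n_tail = c(fish = 50L), c_tail = c(fish = 40L),
                        tail_jitter = 0L),
    region_rates = c(TM = 0, LWI_inner = 0, LWI_outer = 0, loop = 0, tail = 0),
    tail_overrides = list())
  fam <- generate_family(cfg)
  expect_length(unique(fam$alignment$seq), 1L)
  s <- region_distance_summary(fam$alignment, seq_len(alignment_width(fam$alignment)),
                               bootstrap_reps = 0)
  expect_true(all(s$pairs$distance == 0))
})

test_that("planted ground truth agrees with the extraction module", {
  for (fx in c("catsper_like", "null_uniform")) {
    fam <- make_fixture(fx)
    seg <- extract_segments(fam$alignment, fam$topology)
    expect_identical(pooled_columns(seg, "LWI_inner"),
                     fam$truth$lwi_columns$inner)
    expect_identical(pooled_columns(seg, "LWI_outer"),
                     fam$truth$lwi_columns$outer)
    tm_cols <- which(fam$truth$column_class == "TM")
    expect_identical(pooled_columns(seg, "TM_total"), tm_cols)
  }
})

test_that("planted inner-interface composition is recovered within its exact sampling interval", {
  # pooled Phe frequency across independently seeded families; the interval
  # uses the star-model variance (shared ancestors correlate species, so the
  # effective sample size is set by ancestor sites, not residues)
  seeds <- c(301, 302, 303)
  tot_f <- 0; tot_n <- 0; tot_sites <- 0
  for (s in seeds) {
    fam <- make_fixture("catsper_like", seed = s)
    inner <- fam$truth$lwi_columns$inner
    p <- region_frequencies(fam$alignment, inner)
    tot_f <- tot_f + p$counts[["F"]]
    tot_n <- tot_n + p$n_residues
    tot_sites <- tot_sites + length(inner)
  }
  freq <- tot_f / tot_n
  n_species <- 50L
  sd_exact <- star_freq_sd(0.20, r = 0.20, S = tot_sites, N = n_species)
  expect_lt(abs(freq - 0.20), 2.576 * sd_exact)
  expect_gte(tot_n, 2000)
})

test_that("planted Cys exclusion is reported as absence at every flank", {
  fam <- make_fixture("catsper_like")
  seg <- extract_segments(fam$alignment, fam$topology)
  bg <- load_background("swissprot")
  for (flank in names(seg$flanks)) {
    p <- region_frequencies(fam$alignment, pooled_columns(seg, flank), "all",
                            region_name = flank)
    cmp <- compare_to_background(p, bg)
    expect_equal(cmp$direction[cmp$letter == "C"], "absent")
  }
})

test_that("mammal N-tails are long and His-rich, fish tails short", {
  fam <- make_fixture("catsper_like")
  seg <- extract_segments(fam$alignment, fam$topology)
  # N-terminal tail columns: everything before the first LWI flank
  first_lwi <- min(pooled_columns(seg, "N-TM1"))
  tail_cols <- seq_len(first_lwi - 1L)
  his <- region_residue_content(fam$alignment, tail_cols, "H", "mammal")
  sd_exact <- star_freq_sd(0.17, r = 0.10, S = 350, N = 10L)
  expect_lt(abs(his$summary$mean - 0.17), 2.576 * sd_exact)

  his_fish <- region_residue_content(fam$alignment, tail_cols, "H", "fish")
  expect_lt(his_fish$summary$mean, 0.10)

  lens <- summarize_lengths(fam$alignment, fam$topology)$by_stratum
  expect_gt(lens$median_n_tail[lens$phylum == "mammal"] -
              lens$median_n_tail[lens$phylum == "fish"], 150)
})

test_that("family bundles round-trip through the standard file formats", {
  fam <- generate_family(small_config(11))
  dir <- tempfile("bundle")
  paths <- write_family_bundle(fam, dir)
  expect_true(all(file.exists(paths)))
  back <- read_labeled_alignment(paths[["alignment"]], paths[["metadata"]])
  expect_identical(back$seq, fam$alignment$seq)
  expect_identical(back$metadata, fam$alignment$metadata)
  topo <- read_topology(paths[["topology"]])
  expect_identical(topo$tm_intervals, fam$topology$tm_intervals)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$lwi_columns$inner, fam$truth$lwi_columns$inner)
})

test_that("per-region empirical frequencies converge to the stationary targets", {
  cfg <- generator_config(
    seed = 77,
    phyla = data.frame(name = "fish", n_species = 100L, branch_scale = 1),
    architecture = list(n_tail = c(fish = 60L), c_tail = c(fish = 60L),
                        tail_jitter = 5L),
    region_rates = c(TM = 0.9, LWI_inner = 0.9, LWI_outer = 0.9,
                     loop = 0.9, tail = 0.9),
    tail_overrides = list())
  fam <- generate_family(cfg)
  for (cl in c("TM", "LWI_inner", "LWI_outer")) {
    cols <- which(fam$truth$class_key == cl)
    p <- region_frequencies(fam$alignment, cols)
    target <- cfg$region_compositions[[cl]]
    sds <- vapply(AA_LETTERS, function(a)
      star_freq_sd(max(target[[a]], 1e-3), r = 0.9, S = length(cols), N = 100L), 0)
    expect_true(all(abs(p$frequency - target) < 4 * sds + 0.01))
  }
})
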