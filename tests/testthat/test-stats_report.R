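test_that("chi-square independence matches closed forms and the O/E oracle", {
  res0 <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$df, 1)

  res <- chi_square_independence(rbind(c(20, 0), c(0, 20)))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)

  set.seed(123)
  for (k in 1:20) {
    x <- matrix(rpois(12, 30) + 1, 3, 4)
    res_k <- chi_square_independence(x)
    expect_lt(abs(res_k$statistic - oracle_chisq(x)), 1e-9)
    expect_equal(res_k$df, 6)
    # invariant under row/column permutation
    xp <- x[sample(3), sample(4)]
    expect_equal(chi_square_independence(xp)$statistic, res_k$statistic)
    # scales linearly with the counts
    expect_equal(chi_square_independence(5 * x)$statistic, 5 * res_k$statistic)
  }

  expect_error(chi_square_independence(rbind(c(1, 2), c(0, 0))), "degenerate table")
  expect_error(chi_square_independence(matrix(1:4, 1)), "degenerate table")
})

test_that("contingency tables assemble from composition profiles", {
  p1 <- region_frequencies(toy_alignment(c(a = "FFFFF")), 1:5, region_name = "r1")
  p2 <- region_frequencies(toy_alignment(c(a = "FFFFFLLLLL")), 1:10, region_name = "r2")
  tab <- build_group_contingency(list(p1, p2), "letters_by_region")
  expect_equal(dim(tab), c(20L, 2L))
  expect_equal(unname(tab["F", ]), c(5L, 5L))
  expect_equal(unname(tab["L", ]), c(0L, 5L))
  # single region: degenerate at test time after dropping empty margins
  expect_error(chi_square_independence(tab[, 1, drop = FALSE], drop_empty = TRUE),
               "degenerate table")

  p_m <- region_frequencies(toy_alignment(c(a = "FFFFF"), "mammal"), 1:5,
                            stratum = "mammal", region_name = "r1")
  expect_error(build_group_contingency(list(p1, p_m), "letters_by_region"),
               "single stratum")
})

test_that("chi-square p-values are calibrated on identical-composition strata", {
  # three phyla with the same stationary composition everywhere, evolved near
  # saturation so residues are effectively independent draws
  unif <- stats::setNames(rep(0.05, 20), AA_LETTERS)
  pvals <- vapply(1:200, function(k) {
    cfg <- generator_config(
      seed = 9000 + k,
      phyla = data.frame(name = c("mammal", "reptile", "fish"),
                         n_species = 4L, branch_scale = 1),
      architecture = list(n_tail = c(mammal = 150L, reptile = 150L, fish = 150L),
                          c_tail = c(mammal = 80L, reptile = 80L, fish = 80L),
                          tail_jitter = 0L),
      region_rates = c(TM = 0.95, LWI_inner = 0.95, LWI_outer = 0.95,
                       loop = 0.95, tail = 0.95),
      region_compositions = list(TM = unif, LWI_inner = unif, LWI_outer = unif,
                                 loop = unif, tail = unif),
      tail_overrides = list())
    fam <- generate_family(cfg)
    tail_cols <- which(fam$truth$class_key == "tail")
    profs <- lapply(c("mammal", "reptile", "fish"), function(ph)
      region_frequencies(fam$alignment, tail_cols, ph, region_name = "tail"))
    tab <- build_group_contingency(profs, "letters_by_stratum")
    chi_square_independence(tab)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("length summaries recover per-stratum tail and total lengths", {
  aln <- toy_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  topo <- reference_topology("a", rbind(c(3, 6)), "inner", flank_width = 2)
  ls0 <- suppressWarnings(summarize_lengths(aln, topo))
  expect_true(all(ls0$per_sequence$ungapped_length == 10))
  expect_equal(ls0$by_stratum$min_length, ls0$by_stratum$max_length)
  expect_warning(summarize_lengths(aln, topo), "omitting empty strata")

  fam <- make_fixture("catsper_like")
  ls <- summarize_lengths(fam$alignment, fam$topology)
  bs <- ls$by_stratum
  expect_gt(bs$median_n_tail[bs$phylum == "mammal"], 300)
  expect_lt(bs$median_n_tail[bs$phylum == "fish"], 150)
  expect_gt(bs$median_length[bs$phylum == "mammal"],
            bs$median_length[bs$phylum == "fish"])
})

test_that("the pipeline validates its configuration", {
  expect_error(run_pipeline(list(alignment = "x")), "missing key 'metadata'")
  expect_error(run_pipeline(list(alignment = "a", metadata = "b", topology = "c",
                                 background = "d", seed = 1)),
               "missing key 'out'")
})

test_that("the pipeline runs end to end on a small family", {
  fam <- generate_family(small_config(7))
  dir <- tempfile("pipeline")
  dir.create(dir)
  paths <- write_family_bundle(fam, file.path(dir, "in"))
  cfg <- list(alignment = paths[["alignment"]], metadata = paths[["metadata"]],
              topology = paths[["topology"]], background = "swissprot",
              seed = 3, out = file.path(dir, "out"), bootstrap_reps = 20)
  res <- suppressMessages(run_pipeline(cfg))
  produced <- list.files(res$out)
  expect_true(all(c("segments.tsv", "composition_profiles.tsv", "group_ratios.tsv",
                    "distance_stats.tsv", "logo_heights.tsv", "chi_square.tsv",
                    "lengths_by_stratum.tsv", "manifest.json") %in% produced))
  man <- jsonlite::read_json(file.path(res$out, "manifest.json"))
  expect_equal(man$parameters$seed, 3)
  expect_equal(man$parameters$bootstrap_reps, 20)
  seg <- utils::read.delim(file.path(res$out, "segments.tsv"))
  expect_equal(sum(seg$membrane_side %in% c("inner", "outer")), 12)
})
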