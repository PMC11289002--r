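test_that("p-distance handles identity, mismatches and gap exclusion", {
  expect_equal(p_distance("ACDE", "ACDE"), 0)
  expect_equal(p_distance("ACDE", "ACDF"), 0.25)
  expect_equal(p_distance("AC-E", "ACDE"), 0)      # gap column excluded: 0/3
  expect_equal(p_distance("ACXE", "ACDE"), 0)      # X treated as missing
  expect_equal(p_distance("ACDE", "FGHI"), 1)
  expect_true(is.na(p_distance("--", "AA")))
  expect_error(p_distance("ACD", "AC"), "equal aligned length")
})

test_that("p-distance matches the naive character-loop oracle on random gapped pairs", {
  set.seed(77)
  for (k in 1:100) {
    L <- sample(10:60, 1)
    a <- paste(sample(c(AA_LETTERS, "-", "X"), L, replace = TRUE,
                      prob = c(rep(1, 20), 4, 1)), collapse = "")
    b <- paste(sample(c(AA_LETTERS, "-", "X"), L, replace = TRUE,
                      prob = c(rep(1, 20), 4, 1)), collapse = "")
    expect_identical(p_distance(a, b), oracle_p_distance(a, b))
    expect_identical(p_distance(a, b), p_distance(b, a))  # symmetry
  }
})

test_that("complete deletion removes gap columns and drops gappy sequences", {
  aln <- toy_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKF",
                         c = "AC-EFGHIKL", d = "A---------"))
  s <- region_distance_summary(aln, 1:10, bootstrap_reps = 0)
  expect_equal(s$dropped$sequence_id, "d")         # 90% gaps: dropped
  expect_equal(s$n_columns_used, 9L)               # column 3 removed
  expect_equal(nrow(s$pairs), 3L)
  dab <- s$pairs$distance[s$pairs$id_a == "a" & s$pairs$id_b == "b"]
  expect_equal(dab, 1 / 9)

  # pairwise deletion keeps all columns and compares per-pair
  sp <- region_distance_summary(aln, 1:10, deletion = "pairwise",
                                bootstrap_reps = 0)
  expect_equal(sp$n_columns_used, 10L)
  dab_p <- sp$pairs$distance[sp$pairs$id_a == "a" & sp$pairs$id_b == "b"]
  expect_equal(dab_p, 0.1)

  expect_error(region_distance_summary(
    toy_alignment(c(a = "AAAA", b = "----")), 1:4), "insufficient data")
})

test_that("identical sequences give zero distances and zero bootstrap variance", {
  aln <- toy_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFGHIKL"))
  s <- region_distance_summary(aln, 1:10, bootstrap_reps = 100, seed = 5)
  expect_true(all(s$pairs$distance == 0))
  expect_true(all(s$pairs$bootstrap_variance == 0))
})

test_that("bootstrap resampling is bit-reproducible under a fixed seed", {
  fam <- make_fixture("catsper_like")
  seg <- extract_segments(fam$alignment, fam$topology)
  cols <- pooled_columns(seg, "LWI_total")
  s1 <- region_distance_summary(fam$alignment, cols, "mammal",
                                bootstrap_reps = 200, seed = 99)
  s2 <- region_distance_summary(fam$alignment, cols, "mammal",
                                bootstrap_reps = 200, seed = 99)
  expect_identical(s1$pairs$bootstrap_variance, s2$pairs$bootstrap_variance)
  s3 <- region_distance_summary(fam$alignment, cols, "mammal",
                                bootstrap_reps = 200, seed = 100)
  expect_false(identical(s1$pairs$bootstrap_variance, s3$pairs$bootstrap_variance))
})

test_that("mean pairwise distance matches an independent site-level simulation", {
  # one phylum, long single-class tails: the pooled tail region is a clean
  # homogeneous-site test bed for the star model
  cfg <- generator_config(
    seed = 404,
    phyla = data.frame(name = "mammal", n_species = 20L, branch_scale = 1),
    architecture = list(n_tail = c(mammal = 500L), c_tail = c(mammal = 100L),
                        tail_jitter = 0L),
    region_rates = c(TM = 0.05, LWI_inner = 0.2, LWI_outer = 0.2,
                     loop = 0.3, tail = 0.1),
    tail_overrides = list())
  fam <- generate_family(cfg)
  tail_cols <- which(fam$truth$class_key == "tail")
  s <- region_distance_summary(fam$alignment, tail_cols, bootstrap_reps = 0)
  observed <- mean(s$pairs$distance)

  # independent oracle: simulate single star-tree sites directly
  set.seed(505)
  comp <- cfg$region_compositions$tail
  n_sites <- 40000L
  anc <- sample(AA_LETTERS, n_sites, replace = TRUE, prob = comp)
  evolve <- function() {
    x <- anc
    hit <- runif(n_sites) < 0.1
    x[hit] <- sample(AA_LETTERS, sum(hit), replace = TRUE, prob = comp)
    x
  }
  mc <- mean(evolve() != evolve())
  analytic <- expected_star_distance(0.1, comp)
  expect_equal(mc, analytic, tolerance = 0.02)
  # generator mean within 3 SE of the oracle (SE dominated by the finite
  # number of ancestor sites in the generated family)
  se <- sqrt(analytic * (1 - analytic) / length(tail_cols))
  expect_lt(abs(observed - mc), 3 * se)
})

test_that("mean pairwise distance is monotone in the planted substitution rate", {
  for (seed in c(1, 2, 3)) {
    means <- vapply(c(0.02, 0.10, 0.30), function(r) {
      cfg <- generator_config(
        seed = seed,
        phyla = data.frame(name = "mammal", n_species = 30L, branch_scale = 1),
        architecture = list(n_tail = c(mammal = 60L), c_tail = c(mammal = 60L),
                            tail_jitter = 5L),
        region_rates = c(TM = 0.05, LWI_inner = r, LWI_outer = r,
                         loop = 0.3, tail = 0.1),
        tail_overrides = list())
      fam <- generate_family(cfg)
      seg <- extract_segments(fam$alignment, fam$topology)
      s <- region_distance_summary(fam$alignment,
                                   pooled_columns(seg, "LWI_total"),
                                   bootstrap_reps = 0)
      mean(s$pairs$distance)
    }, 0)
    expect_true(all(diff(means) > 0))
  }
})

test_that("region comparison emits boxplot statistics and median orderings", {
  aln <- toy_alignment(c(a = "AAAACDEF", b = "AAAACDGG", c = "AAAAFFFF"))
  s_tm <- region_distance_summary(aln, 1:4, bootstrap_reps = 0, region_name = "TM")
  s_lwi <- region_distance_summary(aln, 5:8, bootstrap_reps = 0, region_name = "LWI")
  cmp <- compare_regions(list(s_tm, s_lwi))
  expect_equal(cmp$stats$median[cmp$stats$region == "TM"], 0)
  ord <- cmp$ordering
  expect_equal(ord$relation[ord$region_a == "TM" & ord$region_b == "LWI"], "<")

  cmp_tie <- compare_regions(list(s_tm, {
    s2 <- s_tm; s2$region_name <- "TM-copy"; s2
  }))
  expect_equal(cmp_tie$ordering$relation, "=")
})

test_that("distance matrices are symmetric with zero diagonal", {
  aln <- toy_alignment(c(a = "ACDEFG", b = "ACDEFF", c = "AAAAAA"))
  m <- distance_matrix(region_distance_summary(aln, 1:6, bootstrap_reps = 0))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
})
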