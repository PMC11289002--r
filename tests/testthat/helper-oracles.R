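# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive re-derivation (linear scans, double
# loops, closed forms) kept separate from the package's implementation paths.

# Brute-force flank labeling: walk every reference position once and decide
# its membership in each flank from the TM intervals alone.
oracle_flank_positions <- function(tm, L, fw, n_side = "inner") {
  in_tm <- rep(FALSE, L)
  for (i in seq_len(nrow(tm))) in_tm[tm[i, 1]:tm[i, 2]] <- TRUE
  flip <- function(s) if (s == "inner") "outer" else "inner"
  flanks <- list()
  sides <- character(0)
  side <- n_side
  for (i in seq_len(nrow(tm))) {
    np <- integer(0)
    cp <- integer(0)
    for (p in seq_len(L)) {
      if (!in_tm[p] && p < tm[i, 1] && p >= tm[i, 1] - fw) np <- c(np, p)
      if (!in_tm[p] && p > tm[i, 2] && p <= tm[i, 2] + fw) cp <- c(cp, p)
    }
    flanks[[paste0("N-TM", i)]] <- np
    sides[[paste0("N-TM", i)]] <- side
    side <- flip(side)
    flanks[[paste0("C-TM", i)]] <- cp
    sides[[paste0("C-TM", i)]] <- side
  }
  list(flanks = flanks, sides = sides)
}

# Naive character-loop p-distance under pairwise deletion.
oracle_p_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mism <- 0L
  comp <- 0L
  for (k in seq_along(av)) {
    ok_a <- av[k] %in% lwiscan::AA_LETTERS
    ok_b <- bv[k] %in% lwiscan::AA_LETTERS
    if (ok_a && ok_b) {
      comp <- comp + 1L
      if (av[k] != bv[k]) mism <- mism + 1L
    }
  }
  if (comp == 0L) NA_real_ else mism / comp
}

# Pearson chi-square by explicit O/E double loop.
oracle_chisq <- function(x) {
  n <- sum(x)
  stat <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      e <- sum(x[i, ]) * sum(x[, j]) / n
      stat <- stat + (x[i, j] - e)^2 / e
    }
  }
  stat
}

# Direct KL divergence in bits by an explicit loop.
oracle_kl <- function(p, q) {
  s <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) s <- s + p[k] * (log(p[k]) - log(q[k])) / log(2)
  }
  s
}

# Expected p-distance between two star-tree branches with substitution
# probability r to a common stationary composition: both must have
# substituted (or collided) to differ.
expected_star_distance <- function(r, comp) {
  (1 - (1 - r)^2) * (1 - sum(comp^2))
}

# Standard deviation of a pooled class frequency under the star model:
# S iid ancestor sites, N species each retaining the ancestor w.p. (1 - r).
star_freq_sd <- function(p, r, S, N) {
  sqrt(p * (1 - p) * (1 + (N - 1) * (1 - r)^2) / (S * N))
}

# Minimal labeled alignment from bare sequences.
toy_alignment <- function(seqs, phylum = "mammal") {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  phylum <- rep_len(phylum, length(seqs))
  labeled_alignment(seqs, data.frame(
    sequence_id = names(seqs), species = names(seqs), phylum = phylum,
    stringsAsFactors = FALSE))
}

# Random roomy 6-TM topology (loops >= 2 * flank width, tails >= flank
# width) over a gapless two-sequence alignment.
random_roomy_topology <- function(fw = 5L) {
  tm_len <- sample(15:25, 6, replace = TRUE)
  loops <- sample((2 * fw):40, 5, replace = TRUE)
  n_tail <- sample(fw:50, 1)
  c_tail <- sample(fw:50, 1)
  starts <- integer(6)
  pos <- n_tail + 1L
  for (i in 1:6) {
    starts[i] <- pos
    pos <- pos + tm_len[i]
    if (i < 6) pos <- pos + loops[i]
  }
  L <- pos - 1L + c_tail
  seq1 <- paste(sample(lwiscan::AA_LETTERS, L, replace = TRUE), collapse = "")
  aln <- toy_alignment(c(ref = seq1, other = seq1))
  topo <- reference_topology("ref", cbind(starts, starts + tm_len - 1L),
                             sample(c("inner", "outer"), 1), flank_width = fw)
  list(aln = aln, topo = topo, L = L)
}

# A small, fast generator configuration (two phyla, short tails) for smoke
# tests that do not need the full study conditions.
small_config <- function(seed, ...) {
  generator_config(
    seed = seed,
    phyla = data.frame(name = c("mammal", "fish"), n_species = 3L,
                       branch_scale = 1, stringsAsFactors = FALSE),
    architecture = list(
      n_tail = c(mammal = 40L, fish = 40L),
      c_tail = c(mammal = 30L, fish = 30L),
      tail_jitter = 5L),
    ...)
}
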