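# Star-phylogeny simulator for multi-species membrane-protein families with
# planted topology, region-specific substitution rates and stationary
# compositions.
#
# Every species descends independently from a common ancestor. At each site a
# species substitutes with the site-class probability, replacing the residue
# by a fresh draw from that class's stationary distribution, so planted
# compositions are exact stationary targets while pairwise distances grow
# with the rate. The TM/LWI/loop core is gapless (trivially aligned); the
# terminal tails are length-jittered per species and gap-padded outward.

.REGION_CLASSES <- c("TM", "LWI_inner", "LWI_outer", "loop", "tail")

# composition with some letters pinned exactly and the rest proportional to
# the given weights, filling the remaining probability mass
.scaled_composition <- function(fixed = numeric(0), weights) {
  out <- stats::setNames(rep(0, 20L), AA_LETTERS)
  out[names(fixed)] <- fixed
  rest <- setdiff(AA_LETTERS, names(fixed))
  w <- weights[rest]
  w[is.na(w)] <- 0
  out[rest] <- w / sum(w) * (1 - sum(fixed))
  out
}

.check_distribution <- function(p, what) {
  if (is.null(names(p)) || !setequal(names(p), AA_LETTERS)) {
    stop("config error: ", what, " must be named over the 20 amino-acid letters")
  }
  p <- p[AA_LETTERS]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("config error: ", what, " must be non-negative and sum to 1")
  }
  p
}

.default_compositions <- function() {
  bg <- unclass(load_background("swissprot"))
  tm_w <- c(L = 18, I = 12, V = 12, F = 12, A = 10, M = 5, G = 7, W = 3,
            Y = 4, T = 5, S = 5, C = 2, P = 1, N = 1, Q = 1, H = 1,
            K = 0.5, R = 0.5, D = 0.5, E = 0.5)
  inner_w <- c(W = 8, Y = 8, L = 12, I = 5, V = 4, M = 3, A = 5, G = 5,
               S = 6, T = 4, R = 6, K = 5, H = 3, N = 2, Q = 2, P = 2,
               D = 3, E = 4)
  outer_w <- c(W = 5, Y = 6, F = 6, L = 7, I = 4, V = 5, M = 2, A = 7,
               G = 7, S = 8, T = 6, R = 5, K = 5, H = 3, N = 4, Q = 5,
               P = 4, D = 5, E = 6)
  list(
    TM = .scaled_composition(weights = tm_w),
    # aromatic enrichment (Phe pinned at 0.20) and Cys exclusion at the
    # cytoplasmic interface
    LWI_inner = .scaled_composition(fixed = c(F = 0.20, C = 0), weights = inner_w),
    LWI_outer = .scaled_composition(fixed = c(C = 0), weights = outer_w),
    loop = .scaled_composition(weights = bg),
    tail = .scaled_composition(weights = bg)
  )
}

#' Configuration for the star-phylogeny family generator
#'
#' The defaults are the reference study conditions used throughout the test
#' suite: five vertebrate phyla of ten species each; a 6-TM architecture with
#' 21-residue helices and loop lengths 12, 8, 16, 10, 24 (the 8- and
#' 10-residue loops exercise overlapping and exactly-abutting flanks);
#' region-specific substitution probabilities TM 0.05 < LWI 0.20 < loop 0.30,
#' with terminal tails at 0.10; aromatic-enriched (Phe pinned at 0.20) and
#' Cys-free stationary compositions at the inner interface, Cys-free at the
#' outer interface; and long His-rich (His 0.17) mammalian N-terminal tails
#' versus short fish tails.
#'
#' @param seed Integer seed; the same seed reproduces the family byte for
#'   byte.
#' @param phyla Data frame with columns `name`, `n_species`, `branch_scale`
#'   (multiplier on the region substitution probabilities for that phylum).
#' @param architecture List with `tm_count`, `tm_length`, `loop_lengths`
#'   (length `tm_count - 1`), `n_tail` and `c_tail` (named per-phylum base
#'   tail lengths), `tail_jitter` (uniform +/- jitter on tail lengths).
#' @param region_rates Named numeric substitution probabilities per site for
#'   classes `TM`, `LWI_inner`, `LWI_outer`, `loop`, `tail`; each in `[0, 1)`.
#' @param region_compositions Named list of stationary distributions (over
#'   [AA_LETTERS]) for the same five classes.
#' @param tail_overrides Optional named list (by phylum) of tail stationary
#'   distributions replacing the shared tail composition for that phylum's
#'   tails (tails are lineage-specific expansions, so each phylum has its own
#'   tail ancestor).
#' @param n_terminus_side Membrane side of the N-terminus.
#' @param flank_width LWI flank width in residues.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             phyla = NULL,
                             architecture = NULL,
                             region_rates = NULL,
                             region_compositions = NULL,
                             tail_overrides = NULL,
                             n_terminus_side = "inner",
                             flank_width = 5L) {
  if (is.null(phyla)) {
    phyla <- data.frame(
      name = c("mammal", "bird", "reptile", "amphibian", "fish"),
      n_species = 10L, branch_scale = 1, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "n_species") %in% names(phyla)))
  if (is.null(phyla$branch_scale)) phyla$branch_scale <- 1
  if (!all(phyla$name %in% .PHYLA)) {
    stop("config error: phyla must be drawn from ", paste(.PHYLA, collapse = ", "))
  }

  arch_default <- list(
    tm_count = 6L, tm_length = 21L,
    loop_lengths = c(12L, 8L, 16L, 10L, 24L),
    n_tail = c(mammal = 350L, bird = 200L, reptile = 220L,
               amphibian = 180L, fish = 120L),
    c_tail = c(mammal = 100L, bird = 100L, reptile = 150L,
               amphibian = 100L, fish = 80L),
    tail_jitter = 15L
  )
  architecture <- utils::modifyList(arch_default, architecture %||% list())
  if (length(architecture$loop_lengths) != architecture$tm_count - 1L) {
    stop("config error: loop_lengths must have tm_count - 1 entries")
  }
  if (any(architecture$loop_lengths < 0L)) {
    stop("config error: loop lengths must be non-negative")
  }

  rates_default <- c(TM = 0.05, LWI_inner = 0.20, LWI_outer = 0.20,
                     loop = 0.30, tail = 0.10)
  region_rates <- utils::modifyList(as.list(rates_default),
                                    as.list(region_rates %||% numeric(0)))
  region_rates <- unlist(region_rates)[.REGION_CLASSES]
  if (any(is.na(region_rates)) || any(region_rates < 0) || any(region_rates >= 1)) {
    stop("config error: region_rates must lie in [0, 1) for all classes")
  }

  comp_default <- .default_compositions()
  region_compositions <- utils::modifyList(comp_default,
                                           region_compositions %||% list())
  region_compositions <- region_compositions[.REGION_CLASSES]
  for (cl in .REGION_CLASSES) {
    region_compositions[[cl]] <- .check_distribution(region_compositions[[cl]],
                                                     paste0(cl, " composition"))
  }

  if (is.null(tail_overrides)) {
    bg <- unclass(load_background("swissprot"))
    tail_overrides <- list(
      mammal = .scaled_composition(fixed = c(H = 0.17), weights = bg))
  }
  for (ph in names(tail_overrides)) {
    tail_overrides[[ph]] <- .check_distribution(tail_overrides[[ph]],
                                                paste0(ph, " tail override"))
  }

  tails_needed <- setdiff(phyla$name,
                          intersect(names(architecture$n_tail), names(architecture$c_tail)))
  if (length(tails_needed)) {
    stop("config error: missing tail lengths for phyla ",
         paste(tails_needed, collapse = ", "))
  }
  min_tail <- flank_width + architecture$tail_jitter
  if (any(architecture$n_tail[phyla$name] < min_tail) ||
      any(architecture$c_tail[phyla$name] < min_tail)) {
    stop("config error: base tail lengths must be at least flank_width + tail_jitter")
  }

  structure(list(
    seed = as.integer(seed),
    phyla = phyla,
    architecture = architecture,
    region_rates = region_rates,
    region_compositions = region_compositions,
    tail_overrides = tail_overrides,
    n_terminus_side = match.arg(n_terminus_side, c("inner", "outer")),
    flank_width = as.integer(flank_width)
  ), class = "generator_config")
}

# class/side labelling of the gapless TM+loop core by linear scan
.core_layout <- function(arch, flank_width, n_terminus_side) {
  tm_count <- arch$tm_count; tm_len <- arch$tm_length
  loops <- arch$loop_lengths
  starts <- integer(tm_count)
  pos <- 1L
  for (i in seq_len(tm_count)) {
    starts[i] <- pos
    pos <- pos + tm_len
    if (i < tm_count) pos <- pos + loops[i]
  }
  core_len <- pos - 1L
  ends <- starts + tm_len - 1L

  flip <- function(s, k) if (k %% 2L == 0L) s else setdiff(c("inner", "outer"), s)
  class <- rep("loop", core_len)
  side <- rep(NA_character_, core_len)
  for (i in seq_len(tm_count)) class[starts[i]:ends[i]] <- "TM"
  for (i in seq_len(tm_count)) {
    n_fl <- (starts[i] - flank_width):(starts[i] - 1L)
    n_fl <- n_fl[n_fl >= 1L & n_fl <= core_len]
    n_fl <- n_fl[class[n_fl] != "TM"]
    if (length(n_fl)) {
      class[n_fl] <- "LWI"
      side[n_fl] <- flip(n_terminus_side, i - 1L)
    }
    c_fl <- (ends[i] + 1L):(ends[i] + flank_width)
    c_fl <- c_fl[c_fl >= 1L & c_fl <= core_len]
    c_fl <- c_fl[class[c_fl] != "TM"]
    if (length(c_fl)) {
      class[c_fl] <- "LWI"
      side[c_fl] <- flip(n_terminus_side, i)
    }
  }
  list(class = class, side = side, tm_starts = starts, tm_ends = ends,
       core_len = core_len)
}

#' Generate a labeled multi-species family with known ground truth
#'
#' Simulates one protein family under a star phylogeny (see the package
#' vignette for the model): a shared ancestor for the TM/LWI/loop core and the
#' membrane-adjacent flank positions, per-phylum ancestors for the terminal
#' tails, and independent per-species substitution at the class-specific
#' rates. The first species of the first phylum is the designated reference.
#'
#' @param cfg A [generator_config()].
#' @return List with `alignment` (a [labeled_alignment()]), `topology` (a
#'   [reference_topology()] for the reference sequence), and `truth` (planted
#'   ground truth: per-column class and membrane side, rates, compositions,
#'   core TM intervals and the per-species tail lengths).
#' @export
generate_family <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, .generate_family_impl(cfg))
}

.generate_family_impl <- function(cfg) {
  arch <- cfg$architecture
  fw <- cfg$flank_width
  layout <- .core_layout(arch, fw, cfg$n_terminus_side)
  tm_count <- arch$tm_count

  phyla <- cfg$phyla
  species <- do.call(rbind, lapply(seq_len(nrow(phyla)), function(i) {
    data.frame(phylum = phyla$name[i],
               idx = seq_len(phyla$n_species[i]),
               branch_scale = phyla$branch_scale[i],
               stringsAsFactors = FALSE)
  }))
  species$sequence_id <- sprintf("%s_%02d", species$phylum, species$idx)
  n_sp <- nrow(species)

  jit <- arch$tail_jitter
  jitter_draw <- function(n) if (jit > 0L) sample(-jit:jit, n, replace = TRUE) else integer(n)
  species$n_tail <- arch$n_tail[species$phylum] + jitter_draw(n_sp)
  species$c_tail <- arch$c_tail[species$phylum] + jitter_draw(n_sp)

  wn <- max(species$n_tail)
  wc <- max(species$c_tail)
  core_len <- layout$core_len
  width <- wn + core_len + wc

  # column classes: tail blocks end in an LWI flank abutting TM1 / TM6
  col_class <- rep("tail", width)
  col_side <- rep(NA_character_, width)
  core_cols <- wn + seq_len(core_len)
  col_class[core_cols] <- ifelse(layout$class == "LWI", "LWI", layout$class)
  col_side[core_cols] <- layout$side
  n_lwi_cols <- (wn - fw + 1L):wn
  c_lwi_cols <- (wn + core_len + 1L):(wn + core_len + fw)
  flip_k <- function(s, k) if (k %% 2L == 0L) s else setdiff(c("inner", "outer"), s)
  col_class[n_lwi_cols] <- "LWI"
  col_side[n_lwi_cols] <- cfg$n_terminus_side
  col_class[c_lwi_cols] <- "LWI"
  col_side[c_lwi_cols] <- flip_k(cfg$n_terminus_side, tm_count)

  class_key <- ifelse(col_class == "LWI", paste0("LWI_", col_side), col_class)

  comp_of <- function(key, phylum = NULL) {
    if (key == "tail" && !is.null(phylum) &&
        phylum %in% names(cfg$tail_overrides)) {
      return(cfg$tail_overrides[[phylum]])
    }
    cfg$region_compositions[[key]]
  }
  draw <- function(n, comp) sample(AA_LETTERS, n, replace = TRUE, prob = comp)

  # shared ancestor: core block plus the two membrane-adjacent flank stripes
  shared_cols <- c(n_lwi_cols, core_cols, c_lwi_cols)
  shared_anc <- character(width)
  for (key in unique(class_key[shared_cols])) {
    idx <- shared_cols[class_key[shared_cols] == key]
    shared_anc[idx] <- draw(length(idx), comp_of(key))
  }

  # per-phylum tail ancestors over the full tail stripes
  tail_cols_n <- seq_len(wn - fw)
  tail_cols_c <- if (wc > fw) (wn + core_len + fw + 1L):width else integer(0)
  tail_anc <- list()
  for (ph in phyla$name) {
    anc <- character(width)
    comp <- comp_of("tail", ph)
    anc[tail_cols_n] <- draw(length(tail_cols_n), comp)
    anc[tail_cols_c] <- draw(length(tail_cols_c), comp)
    tail_anc[[ph]] <- anc
  }

  seqs <- character(n_sp)
  for (s in seq_len(n_sp)) {
    ph <- species$phylum[s]
    occupied_n <- (wn - species$n_tail[s] + 1L):wn
    occupied_c <- (wn + core_len + 1L):(wn + core_len + species$c_tail[s])
    occupied <- c(occupied_n, core_cols, occupied_c)
    occupied <- sort(unique(occupied))

    chars <- rep("-", width)
    anc <- shared_anc
    tail_idx <- occupied[class_key[occupied] == "tail"]
    anc[tail_idx] <- tail_anc[[ph]][tail_idx]

    chars[occupied] <- anc[occupied]
    for (key in unique(class_key[occupied])) {
      idx <- occupied[class_key[occupied] == key]
      rate <- min(cfg$region_rates[[key]] * species$branch_scale[s], 0.999)
      hit <- idx[stats::runif(length(idx)) < rate]
      if (length(hit)) chars[hit] <- draw(length(hit), comp_of(key, ph))
    }
    seqs[s] <- paste(chars, collapse = "")
  }
  names(seqs) <- species$sequence_id

  metadata <- data.frame(
    sequence_id = species$sequence_id,
    species = sprintf("%s_sp%02d", species$phylum, species$idx),
    phylum = species$phylum,
    stringsAsFactors = FALSE
  )
  aln <- labeled_alignment(seqs, metadata)

  ref_row <- 1L
  ref_n_tail <- species$n_tail[ref_row]
  tm_intervals <- cbind(start = ref_n_tail + layout$tm_starts,
                        end = ref_n_tail + layout$tm_ends)
  topo <- reference_topology(species$sequence_id[ref_row], tm_intervals,
                             cfg$n_terminus_side, flank_width = fw)

  truth <- list(
    column_class = col_class,
    column_side = col_side,
    class_key = class_key,
    lwi_columns = list(
      inner = which(class_key == "LWI_inner"),
      outer = which(class_key == "LWI_outer")
    ),
    region_rates = cfg$region_rates,
    region_compositions = cfg$region_compositions,
    tail_overrides = cfg$tail_overrides,
    core_columns = core_cols,
    tail_lengths = species[, c("sequence_id", "phylum", "n_tail", "c_tail")],
    seed = cfg$seed
  )
  list(alignment = aln, topology = topo, truth = truth)
}

#' Bundled reference datasets
#'
#' Generates one of the named study datasets with a fixed default seed:
#' * `catsper_like` — the default [generator_config()] conditions: 5 phyla x
#'   10 species, TM rate 0.05 < LWI rate 0.20 < loop rate 0.30,
#'   aromatic-enriched Cys-free inner LWI, long His-rich mammal N-tails.
#' * `null_uniform` — uniform stationary composition in every region, equal
#'   substitution probability 0.15 everywhere, equal tail lengths: no planted
#'   structure of any kind.
#' * `high_divergence` — the catsper-like compositions evolved at substitution
#'   probability 0.95 in every region: per-column residue usage is close to
#'   the stationary distributions (phylogenetic memory essentially erased).
#'
#' @param name One of `"catsper_like"`, `"null_uniform"`, `"high_divergence"`.
#' @param seed Optional seed overriding the fixture default.
#' @return As [generate_family()], plus the `config` used.
#' @export
make_fixture <- function(name = c("catsper_like", "null_uniform", "high_divergence"),
                         seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    catsper_like = generator_config(seed = seed %||% 101L),
    null_uniform = {
      unif <- stats::setNames(rep(0.05, 20L), AA_LETTERS)
      generator_config(
        seed = seed %||% 202L,
        region_rates = c(TM = 0.15, LWI_inner = 0.15, LWI_outer = 0.15,
                         loop = 0.15, tail = 0.15),
        region_compositions = list(TM = unif, LWI_inner = unif,
                                   LWI_outer = unif, loop = unif, tail = unif),
        tail_overrides = list(),
        architecture = list(
          n_tail = c(mammal = 120L, bird = 120L, reptile = 120L,
                     amphibian = 120L, fish = 120L),
          c_tail = c(mammal = 80L, bird = 80L, reptile = 80L,
                     amphibian = 80L, fish = 80L))
      )
    },
    high_divergence = generator_config(
      seed = seed %||% 303L,
      region_rates = c(TM = 0.95, LWI_inner = 0.95, LWI_outer = 0.95,
                       loop = 0.95, tail = 0.95))
  )
  out <- generate_family(cfg)
  out$config <- cfg
  out$name <- name
  out
}

#' Write a family as the standard input bundle
#'
#' Writes aligned FASTA + metadata TSV + topology YAML + ground-truth JSON,
#' the input form every downstream stage (and [run_pipeline()]) consumes.
#'
#' @param family Result of [generate_family()] or [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_family_bundle <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    topology = file.path(dir, "topology.yml"),
    truth = file.path(dir, "truth.json")
  )
  write_labeled_alignment(family$alignment, paths[["alignment"]], paths[["metadata"]])
  write_topology(family$topology, paths[["topology"]])
  jsonlite::write_json(family$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}
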