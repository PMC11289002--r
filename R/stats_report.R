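# Chi-square independence testing, length summaries, and the end-to-end
# pipeline that writes all machine-readable outputs.

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on a contingency table of counts,
#' without continuity correction, with `(r - 1)(c - 1)` degrees of freedom and
#' the p-value from the chi-square distribution.
#'
#' @param table Matrix of non-negative counts (at least 2 x 2 after optional
#'   empty-margin dropping).
#' @param drop_empty Drop all-zero rows/columns before testing instead of
#'   erroring on them.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(table, drop_empty = FALSE) {
  x <- as.matrix(table)
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be finite and non-negative")
  if (drop_empty) {
    x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("degenerate table: need at least 2 rows and 2 columns with data")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("degenerate table: all-zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p_value = unname(res$p.value),
       expected = res$expected)
}

#' Assemble a letters-by-groups contingency table from composition profiles
#'
#' @param profiles List of [region_frequencies()] profiles sharing the
#'   amino-acid alphabet.
#' @param mode `"letters_by_region"` (profiles must share one stratum; columns
#'   are regions) or `"letters_by_stratum"` (profiles must share one region;
#'   columns are strata).
#' @return 20-row integer matrix of counts with letter rownames.
#' @export
build_group_contingency <- function(profiles,
                                    mode = c("letters_by_region", "letters_by_stratum")) {
  mode <- match.arg(mode)
  strata <- vapply(profiles, `[[`, "", "stratum")
  regions <- vapply(profiles, `[[`, "", "region_name")
  if (mode == "letters_by_region") {
    if (length(unique(strata)) != 1L) {
      stop("assembly error: letters_by_region needs profiles from a single stratum")
    }
    if (anyDuplicated(regions)) stop("assembly error: duplicated region profiles")
    labels <- regions
  } else {
    if (length(unique(regions)) != 1L) {
      stop("assembly error: letters_by_stratum needs profiles for a single region")
    }
    if (anyDuplicated(strata)) stop("assembly error: duplicated stratum profiles")
    labels <- strata
  }
  counts <- vapply(profiles, function(p) p$counts[AA_LETTERS], numeric(20L))
  colnames(counts) <- labels
  rownames(counts) <- AA_LETTERS
  storage.mode(counts) <- "integer"
  counts
}

#' Sequence- and region-length summary per stratum
#'
#' Per-sequence ungapped lengths and the length of the N-terminal tail
#' (non-gap characters in the alignment columns preceding TM1), summarized
#' per phylum with median and range. Phyla with no sequences are omitted with
#' a warning.
#'
#' @param aln A [labeled_alignment()].
#' @param topo A [reference_topology()].
#' @return List with `per_sequence` (data frame: sequence_id, species, phylum,
#'   ungapped_length, n_tail_length) and `by_stratum` (data frame of medians
#'   and ranges).
#' @export
summarize_lengths <- function(aln, topo) {
  pos2col <- map_reference_to_columns(aln, topo)
  tm1_col <- pos2col[topo$tm_intervals[1L, "start"]]
  m <- alignment_matrix(aln)
  nongap <- m != "-"
  per_sequence <- data.frame(
    sequence_id = names(aln$seq),
    species = aln$metadata$species,
    phylum = aln$metadata$phylum,
    ungapped_length = rowSums(nongap),
    n_tail_length = if (tm1_col > 1L)
      rowSums(nongap[, seq_len(tm1_col - 1L), drop = FALSE]) else 0L,
    stringsAsFactors = FALSE
  )
  rownames(per_sequence) <- NULL
  present <- intersect(.PHYLA, unique(per_sequence$phylum))
  absent <- setdiff(.PHYLA, present)
  if (length(absent)) {
    warning("omitting empty strata: ", paste(absent, collapse = ", "))
  }
  by_stratum <- do.call(rbind, lapply(present, function(ph) {
    g <- per_sequence[per_sequence$phylum == ph, ]
    data.frame(phylum = ph, n = nrow(g),
               median_length = stats::median(g$ungapped_length),
               min_length = min(g$ungapped_length),
               max_length = max(g$ungapped_length),
               median_n_tail = stats::median(g$n_tail_length),
               min_n_tail = min(g$n_tail_length),
               max_n_tail = max(g$n_tail_length),
               stringsAsFactors = FALSE)
  }))
  rownames(by_stratum) <- NULL
  list(per_sequence = per_sequence, by_stratum = by_stratum)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reads the input bundle (aligned FASTA, metadata TSV, topology YAML,
#' background table), derives the LWI segment map, and writes every
#' machine-readable output: segment table, length summaries, per-region
#' composition profiles versus background, grouped totals/ratios/hydropathy,
#' pairwise-distance boxplot statistics and pair tables, KL logo height
#' tables, chi-square reports, and a JSON run manifest. Given identical
#' inputs and seed the TSV/JSON outputs are byte-identical across runs.
#'
#' @param config Either a YAML file path or a named list with required keys
#'   `alignment`, `metadata`, `topology`, `background`, `seed`, `out`, and
#'   optional keys `bootstrap_reps` (default 100), `deletion`
#'   (`"complete"`), `pseudocount` (1), `pooling` (`"residues"`),
#'   `max_gap_fraction` (0.5), `figures` (FALSE).
#' @return Invisibly, a list with the output directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  required <- c("alignment", "metadata", "topology", "background", "seed", "out")
  for (key in required) {
    if (is.null(config[[key]])) stop("config error: missing key '", key, "'")
  }
  bootstrap_reps <- config$bootstrap_reps %||% 100L
  deletion <- config$deletion %||% "complete"
  pseudocount <- config$pseudocount %||% 1
  pooling <- config$pooling %||% "residues"
  max_gap_fraction <- config$max_gap_fraction %||% 0.5
  figures <- isTRUE(config$figures)
  seed <- as.integer(config$seed)

  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  aln <- stage("read", read_labeled_alignment(config$alignment, config$metadata))
  topo <- read_topology(config$topology)
  bg <- load_background(config$background)
  strata <- c("all", intersect(.PHYLA, unique(aln$metadata$phylum)))

  segmap <- stage("extract", extract_segments(aln, topo))
  .write_tsv(segment_table(segmap), file.path(out, "segments.tsv"))

  lengths <- stage("lengths", suppressWarnings(summarize_lengths(aln, topo)))
  .write_tsv(lengths$per_sequence, file.path(out, "lengths_per_sequence.tsv"))
  .write_tsv(lengths$by_stratum, file.path(out, "lengths_by_stratum.tsv"))

  pooled_regions <- c("LWI_total", "LWI_inner", "LWI_outer", "TM_total")
  flank_regions <- names(segmap$flanks)
  tm_regions <- names(segmap$tm)

  profiles <- stage("compose", {
    out_list <- list()
    for (stratum in strata) {
      for (region in c(pooled_regions, flank_regions)) {
        p <- region_frequencies(aln, pooled_columns(segmap, region), stratum,
                                region_name = region, pooling = pooling)
        if (!p$degenerate) out_list[[paste(region, stratum, sep = "|")]] <- p
      }
    }
    out_list
  })
  .write_tsv(composition_table(profiles, bg), file.path(out, "composition_profiles.tsv"))

  ratios <- stage("ratios", {
    rows <- lapply(profiles, function(p) {
      g <- grouped_profile(p)
      data.frame(region = p$region_name, stratum = p$stratum,
                 n_residues = p$n_residues,
                 hydrophobic = g$group_totals[["hydrophobic"]],
                 hydrophilic = g$group_totals[["hydrophilic"]],
                 positive = g$group_totals[["positive"]],
                 negative = g$group_totals[["negative"]],
                 positive_to_negative = g$ratios[["positive_to_negative"]],
                 hydrophobic_to_hydrophilic = g$ratios[["hydrophobic_to_hydrophilic"]],
                 mean_hydropathy = g$mean_hydropathy,
                 snorkeling_total = g$snorkeling_total,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows); rownames(df) <- NULL; df
  })
  .write_tsv(ratios, file.path(out, "group_ratios.tsv"))

  conserve_regions <- c("full_length", "TM_total", "LWI_total", "LWI_inner",
                        "LWI_outer", tm_regions, flank_regions)
  summaries <- stage("conserve", {
    res <- list()
    for (stratum in strata) {
      for (region in conserve_regions) {
        res[[paste(region, stratum, sep = "|")]] <- region_distance_summary(
          aln, pooled_columns(segmap, region), stratum,
          deletion = deletion, bootstrap_reps = bootstrap_reps,
          seed = seed + .region_seed_offset(region, stratum),
          max_gap_fraction = max_gap_fraction, region_name = region)
      }
    }
    res
  })
  cmp <- compare_regions(summaries)
  .write_tsv(cmp$stats, file.path(out, "distance_stats.tsv"))
  .write_tsv(cmp$ordering, file.path(out, "distance_orderings.tsv"))
  pair_df <- do.call(rbind, lapply(summaries, function(s)
    cbind(region = s$region_name, stratum = s$stratum, s$pairs,
          stringsAsFactors = FALSE)))
  rownames(pair_df) <- NULL
  .write_tsv(pair_df, file.path(out, "distance_pairs.tsv"))

  logos <- stage("logo", {
    regs <- c("LWI_inner", "LWI_outer", "LWI_total", flank_regions)
    tabs <- lapply(regs, function(region)
      logo_table(kl_logo(aln, pooled_columns(segmap, region), "all", bg,
                         pseudocount_weight = pseudocount, region_name = region)))
    df <- do.call(rbind, tabs); rownames(df) <- NULL; df
  })
  .write_tsv(logos, file.path(out, "logo_heights.tsv"))

  chi <- stage("chi_square", {
    rows <- lapply(strata, function(stratum) {
      keys <- paste(c("TM_total", "LWI_inner", "LWI_outer"), stratum, sep = "|")
      prof <- profiles[intersect(keys, names(profiles))]
      if (length(prof) < 2L) return(NULL)
      tab <- build_group_contingency(prof, "letters_by_region")
      res <- chi_square_independence(tab, drop_empty = TRUE)
      data.frame(stratum = stratum, mode = "letters_by_region",
                 regions = paste(vapply(prof, `[[`, "", "region_name"), collapse = ","),
                 statistic = res$statistic, df = res$df, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows); rownames(df) <- NULL; df
  })
  .write_tsv(chi, file.path(out, "chi_square.tsv"))

  if (figures) {
    stage("figures", {
      grDevices::pdf(file.path(out, "figures.pdf"), width = 9, height = 6)
      on.exit(grDevices::dev.off(), add = TRUE)
      keep <- cmp$stats$region %in% c("full_length", "TM_total", "LWI_total",
                                      "LWI_inner", "LWI_outer")
      print(ggplot2::ggplot(cmp$stats[keep, ],
                            ggplot2::aes(region, median, fill = stratum)) +
              ggplot2::geom_col(position = "dodge") +
              ggplot2::labs(y = "median pairwise p-distance") +
              ggplot2::theme_minimal())
      print(plot_logo(kl_logo(aln, pooled_columns(segmap, "LWI_inner"), "all",
                              bg, pseudocount, region_name = "LWI_inner")))
      invisible(NULL)
    })
  }

  manifest <- list(
    package = "lwiscan",
    version = as.character(utils::packageVersion("lwiscan")),
    inputs = config[c("alignment", "metadata", "topology", "background")],
    parameters = list(seed = seed, bootstrap_reps = bootstrap_reps,
                      deletion = deletion, pseudocount = pseudocount,
                      pooling = pooling, max_gap_fraction = max_gap_fraction,
                      flank_width = topo$flank_width,
                      contingency_mode = "letters_by_region"),
    strata = strata,
    outputs = list.files(out, pattern = "\\.(tsv)$")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out = out, manifest = manifest, segmap = segmap,
                 profiles = profiles, ratios = ratios, summaries = summaries,
                 comparison = cmp, chi_square = chi, lengths = lengths))
}

# deterministic per-(region, stratum) seed offset so bootstrap streams are
# independent but reproducible
.region_seed_offset <- function(region, stratum) {
  key <- paste(region, stratum, sep = "|")
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100000L
}
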