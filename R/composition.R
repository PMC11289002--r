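# Region-wise amino-acid composition: frequencies, grouped totals and ratios,
# hydropathy, background comparison, per-sequence residue content.

.stratum_ids <- function(aln, stratum) {
  if (identical(stratum, "all")) return(names(aln$seq))
  ids <- aln$metadata$sequence_id[aln$metadata$phylum == stratum]
  if (!length(ids)) stop("stratum error: no sequences in stratum '", stratum, "'")
  ids
}

#' Amino-acid frequencies of an alignment region
#'
#' Counts every non-gap, non-`X` character at the given alignment columns over
#' all sequences of the stratum. With `pooling = "residues"` (the default)
#' each residue is one observation; with `pooling = "per_sequence"` per-sequence
#' frequency vectors are computed first and then averaged with equal weight per
#' sequence (sequences contributing no residues are dropped).
#'
#' @param aln A [labeled_alignment()].
#' @param columns Alignment columns of the region.
#' @param stratum A phylum name or `"all"`.
#' @param region_name Optional label stored in the profile.
#' @param pooling `"residues"` or `"per_sequence"`.
#' @return An object of class `composition_profile`: a list with `counts`
#'   (named integer over [AA_LETTERS]), `n_residues`, `frequency`,
#'   `n_sequences`, `degenerate` (TRUE when no residues were observed, in
#'   which case `frequency` is `NA`), plus the region/stratum labels.
#' @export
region_frequencies <- function(aln, columns, stratum = "all",
                               region_name = NULL,
                               pooling = c("residues", "per_sequence")) {
  pooling <- match.arg(pooling)
  columns <- as.integer(columns)
  w <- alignment_width(aln)
  if (length(columns) && (min(columns) < 1L || max(columns) > w)) {
    stop("columns out of range 1..", w)
  }
  ids <- .stratum_ids(aln, stratum)
  m <- alignment_matrix(aln)[ids, columns, drop = FALSE]
  counts <- table(factor(m, levels = AA_LETTERS))
  counts <- stats::setNames(as.integer(counts), AA_LETTERS)
  n <- sum(counts)
  if (pooling == "residues" || n == 0L) {
    frequency <- if (n > 0L) counts / n else stats::setNames(rep(NA_real_, 20L), AA_LETTERS)
  } else {
    per_seq <- t(apply(m, 1L, function(row) {
      tab <- table(factor(row, levels = AA_LETTERS))
      k <- sum(tab)
      if (k == 0L) rep(NA_real_, 20L) else as.numeric(tab) / k
    }))
    keep <- stats::complete.cases(per_seq)
    frequency <- stats::setNames(colMeans(per_seq[keep, , drop = FALSE]), AA_LETTERS)
  }
  structure(list(
    region_name = region_name %||% "region",
    stratum = stratum,
    pooling = pooling,
    counts = counts,
    n_residues = n,
    n_sequences = length(ids),
    frequency = frequency,
    degenerate = n == 0L
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> region '%s', stratum '%s': %d residues from %d sequences%s\n",
              x$region_name, x$stratum, x$n_residues, x$n_sequences,
              if (x$degenerate) " [degenerate]" else ""))
  if (!x$degenerate) print(round(x$frequency, 3))
  invisible(x)
}

#' Grouped composition totals and ratios
#'
#' Adds hydrophobic/hydrophilic and positive/negative group totals, the
#' positive-to-negative and hydrophobic-to-hydrophilic ratios, and the
#' frequency-weighted mean Kyte-Doolittle hydropathy to a composition profile.
#' A zero denominator with a non-zero numerator yields `Inf`; `0/0` yields
#' `NaN`. Because the hydrophobic and hydrophilic sets partition the twenty
#' letters, their totals sum to exactly 1 for any non-degenerate profile.
#'
#' @param profile A [region_frequencies()] profile.
#' @param scales Grouping scheme from [aa_scales()].
#' @return The profile with elements `group_totals` (named numeric:
#'   hydrophobic, hydrophilic, positive, negative), `ratios` (named numeric:
#'   positive_to_negative, hydrophobic_to_hydrophilic), `mean_hydropathy`, and
#'   `snorkeling_total` (combined frequency of snorkeling-capable residues).
#' @export
grouped_profile <- function(profile, scales = aa_scales()) {
  if (profile$degenerate) stop("cannot group a degenerate (empty) profile")
  f <- profile$frequency
  totals <- c(
    hydrophobic = sum(f[scales$hydrophobic]),
    hydrophilic = sum(f[scales$hydrophilic]),
    positive    = sum(f[scales$positive]),
    negative    = sum(f[scales$negative])
  )
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NaN
  }
  profile$group_totals <- totals
  profile$ratios <- c(
    positive_to_negative = ratio(totals[["positive"]], totals[["negative"]]),
    hydrophobic_to_hydrophilic = ratio(totals[["hydrophobic"]], totals[["hydrophilic"]])
  )
  profile$mean_hydropathy <- mean_hydropathy(profile, scales)
  profile$snorkeling_total <- sum(f[scales$snorkeling])
  profile
}

#' Frequency-weighted mean Kyte-Doolittle hydropathy
#'
#' @param profile A non-degenerate [region_frequencies()] profile.
#' @param scales Scales from [aa_scales()].
#' @return Mean hydropathy in Kyte-Doolittle units.
#' @export
mean_hydropathy <- function(profile, scales = aa_scales()) {
  if (profile$degenerate) stop("cannot compute hydropathy of a degenerate profile")
  sum(profile$frequency * scales$kd[names(profile$frequency)])
}

#' Compare regional frequencies to a background composition
#'
#' For every amino acid, reports observed vs expected (background) frequency,
#' the log2 observed/expected ratio, and a direction flag: `absent` when the
#' residue is unobserved (log2 ratio `-Inf`), otherwise `enriched`
#' (observed > expected), `depleted` (observed < expected) or `equal`.
#'
#' @param profile A non-degenerate [region_frequencies()] profile.
#' @param bg A [background_composition()].
#' @return Data frame with columns `letter`, `observed`, `expected`,
#'   `log2_ratio`, `direction`.
#' @export
compare_to_background <- function(profile, bg) {
  if (profile$degenerate) stop("cannot compare a degenerate profile to background")
  stopifnot(inherits(bg, "background_composition"))
  obs <- profile$frequency[AA_LETTERS]
  exp <- as.numeric(unclass(bg)[AA_LETTERS])
  direction <- ifelse(obs == 0, "absent",
                      ifelse(obs > exp, "enriched",
                             ifelse(obs < exp, "depleted", "equal")))
  data.frame(
    letter = AA_LETTERS,
    observed = as.numeric(obs),
    expected = exp,
    log2_ratio = ifelse(obs == 0, -Inf, log2(obs / exp)),
    direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Per-sequence content of one residue in a region
#'
#' Proportion of a given amino acid among the non-gap, non-`X` characters each
#' sequence contributes at the region columns (e.g. the histidine content of
#' N-terminal tails). Sequences with no residues in the region are excluded
#' from the summary and listed.
#'
#' @param aln A [labeled_alignment()].
#' @param columns Alignment columns of the region (non-empty).
#' @param letter Single amino-acid letter.
#' @param stratum A phylum name or `"all"`.
#' @return List with `per_sequence` (data frame: `sequence_id`, `phylum`,
#'   `n_sites`, `proportion`), `summary` (mean/min/max over retained
#'   sequences), and `dropped` (ids with no residues in the region).
#' @export
region_residue_content <- function(aln, columns, letter, stratum = "all") {
  stopifnot(length(columns) >= 1L, letter %in% AA_LETTERS)
  ids <- .stratum_ids(aln, stratum)
  m <- alignment_matrix(aln)[ids, as.integer(columns), drop = FALSE]
  valid <- matrix(m %in% AA_LETTERS, nrow = nrow(m))
  n_sites <- rowSums(valid)
  hits <- rowSums(m == letter)
  proportion <- ifelse(n_sites > 0L, hits / n_sites, NA_real_)
  per_sequence <- data.frame(
    sequence_id = ids,
    phylum = aln$metadata$phylum[match(ids, aln$metadata$sequence_id)],
    n_sites = n_sites,
    proportion = proportion,
    stringsAsFactors = FALSE
  )
  keep <- !is.na(proportion)
  list(
    per_sequence = per_sequence,
    summary = list(
      stratum = stratum, letter = letter, n = sum(keep),
      mean = if (any(keep)) mean(proportion[keep]) else NA_real_,
      min = if (any(keep)) min(proportion[keep]) else NA_real_,
      max = if (any(keep)) max(proportion[keep]) else NA_real_
    ),
    dropped = ids[!keep]
  )
}

#' Tidy export of composition profiles versus background
#'
#' Binds [compare_to_background()] rows for several profiles into one long
#' table suitable for TSV export.
#'
#' @param profiles List of non-degenerate profiles.
#' @param bg A [background_composition()].
#' @return Data frame with columns `region`, `stratum`, `letter`, `count`,
#'   `frequency`, `background`, `log2_ratio`, `direction`.
#' @export
composition_table <- function(profiles, bg) {
  out <- lapply(profiles, function(p) {
    cmp <- compare_to_background(p, bg)
    data.frame(region = p$region_name, stratum = p$stratum,
               letter = cmp$letter, count = as.integer(p$counts[cmp$letter]),
               frequency = cmp$observed, background = cmp$expected,
               log2_ratio = cmp$log2_ratio, direction = cmp$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
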