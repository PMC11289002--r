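# Pairwise p-distance conservation scoring with bootstrap variances.
#
# Distances follow the proportion-of-differing-sites model with uniform rates
# among sites: restricted to compared positions, distance = mismatches /
# compared positions, always in [0, 1] (0 = identical, 1 = fully diverged).

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pairwise p-distance between two aligned sequences
#'
#' Restricts to the columns where *both* sequences carry a non-gap, non-`X`
#' character (pairwise-complete positions) and returns the proportion of
#' mismatches among them. When no position can be compared the distance is
#' undefined and `NA` is returned.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings).
#' @param columns Optional column subset; default all columns.
#' @return Numeric in `[0, 1]`, or `NA` if no comparable positions.
#' @examples
#' p_distance("ACDE", "ACDF")  # 0.25
#' p_distance("AC-E", "ACDE")  # 0 (gap column excluded)
#' @export
p_distance <- function(seq_a, seq_b, columns = NULL) {
  a <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  if (!is.null(columns)) {
    a <- a[columns]; b <- b[columns]
  }
  ok <- a %in% AA_LETTERS & b %in% AA_LETTERS
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' Region-wise pairwise distance summary with bootstrap variances
#'
#' Computes all unordered pairwise p-distances among the sequences of a
#' stratum over a region, after two data-treatment steps: (1) sequences whose
#' region is more than `max_gap_fraction` gaps/`X` are dropped (and listed
#' with the reason); (2) under `deletion = "complete"` every column still
#' containing a gap or `X` in any retained sequence is removed before distance
#' computation, while `deletion = "pairwise"` keeps all columns and compares
#' each pair over its pairwise-complete positions.
#'
#' Bootstrap variances resample the retained region columns with replacement
#' `bootstrap_reps` times (independently across replicates); the recorded
#' statistic is the per-pair variance of the replicate distances. A fixed
#' `seed` makes the resampling bit-reproducible.
#'
#' @param aln A [labeled_alignment()].
#' @param columns Alignment columns of the region.
#' @param stratum A phylum name or `"all"`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @param bootstrap_reps Number of bootstrap replicates (0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap resampling.
#' @param max_gap_fraction Drop a sequence from the region when more than this
#'   fraction of its region columns are gaps/`X`.
#' @param region_name Optional label.
#' @param store_replicates Keep the full pair-by-replicate distance matrix
#'   (for diagnostics).
#' @return Object of class `distance_summary`: list with `pairs` (data frame:
#'   `id_a`, `id_b`, `distance`, `bootstrap_variance`), `dropped` (data frame
#'   of dropped sequences with reasons), `n_columns_used`, and the parameters.
#' @export
region_distance_summary <- function(aln, columns, stratum = "all",
                                    deletion = c("complete", "pairwise"),
                                    bootstrap_reps = 1000L, seed = NULL,
                                    max_gap_fraction = 0.5,
                                    region_name = NULL,
                                    store_replicates = FALSE) {
  deletion <- match.arg(deletion)
  columns <- as.integer(columns)
  ids <- .stratum_ids(aln, stratum)
  m <- alignment_matrix(aln)[ids, columns, drop = FALSE]
  missing <- matrix(!(m %in% AA_LETTERS), nrow = nrow(m),
                    dimnames = dimnames(m))

  gap_frac <- rowMeans(missing)
  drop_mask <- gap_frac > max_gap_fraction
  dropped <- data.frame(
    sequence_id = ids[drop_mask],
    reason = sprintf("gap fraction %.2f above threshold %.2f",
                     gap_frac[drop_mask], max_gap_fraction),
    stringsAsFactors = FALSE
  )
  keep_ids <- ids[!drop_mask]
  if (length(keep_ids) < 2L) {
    stop("insufficient data: fewer than 2 sequences retained in region '",
         region_name %||% "region", "', stratum '", stratum, "'")
  }
  m <- m[keep_ids, , drop = FALSE]
  missing <- missing[keep_ids, , drop = FALSE]

  if (deletion == "complete") {
    col_keep <- colSums(missing) == 0L
    m <- m[, col_keep, drop = FALSE]
    missing <- missing[, col_keep, drop = FALSE]
  }
  n <- length(keep_ids)
  n_cols <- ncol(m)

  ia <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- sequence((n - 1L):1L) + ia

  # pair-by-column mismatch and validity indicators
  if (n_cols > 0L) {
    valid <- (!missing[ia, , drop = FALSE]) & (!missing[ib, , drop = FALSE])
    mism <- (m[ia, , drop = FALSE] != m[ib, , drop = FALSE]) & valid
    storage.mode(valid) <- "double"
    storage.mode(mism) <- "double"
    compared <- rowSums(valid)
    distance <- ifelse(compared > 0, rowSums(mism) / compared, NA_real_)
  } else {
    compared <- rep(0, length(ia))
    distance <- rep(NA_real_, length(ia))
  }

  boot_var <- rep(NA_real_, length(ia))
  replicates <- NULL
  if (bootstrap_reps > 0L && n_cols > 0L) {
    draws <- with_seed(seed,
      stats::rmultinom(bootstrap_reps, n_cols, rep(1 / n_cols, n_cols)))
    storage.mode(draws) <- "double"
    num <- mism %*% draws
    den <- valid %*% draws
    repl <- num / den  # 0/0 -> NaN for pairs with no comparable draw
    mu <- rowMeans(repl)
    boot_var <- rowSums((repl - mu)^2) / (bootstrap_reps - 1L)
    if (store_replicates) replicates <- repl
  }

  structure(list(
    region_name = region_name %||% "region",
    stratum = stratum,
    deletion = deletion,
    pairs = data.frame(id_a = keep_ids[ia], id_b = keep_ids[ib],
                       distance = distance,
                       compared_positions = compared,
                       bootstrap_variance = boot_var,
                       stringsAsFactors = FALSE),
    dropped = dropped,
    n_columns_used = n_cols,
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = seed,
    replicates = replicates
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  d <- x$pairs$distance
  cat(sprintf("<distance_summary> region '%s', stratum '%s' (%s deletion): %d pairs over %d columns\n",
              x$region_name, x$stratum, x$deletion, nrow(x$pairs), x$n_columns_used))
  if (any(!is.na(d)))
    cat(sprintf("  median %.4f  IQR [%.4f, %.4f]\n",
                stats::median(d, na.rm = TRUE),
                stats::quantile(d, 0.25, na.rm = TRUE),
                stats::quantile(d, 0.75, na.rm = TRUE)))
  invisible(x)
}

#' Boxplot statistics and median orderings across regions
#'
#' Collapses a set of [region_distance_summary()] results into the per-region
#' box-and-whisker statistics (median, quartiles, min, max) per stratum, plus
#' the pairwise ordering of region medians within each stratum (ties
#' reported as ties).
#'
#' @param summaries List of `distance_summary` objects.
#' @return List with `stats` (data frame: region, stratum, n_pairs, median,
#'   q1, q3, min, max, mean) and `ordering` (data frame: stratum, region_a,
#'   region_b, relation in `<`, `>`, `=`).
#' @export
compare_regions <- function(summaries) {
  stats_df <- do.call(rbind, lapply(summaries, function(s) {
    d <- s$pairs$distance[!is.na(s$pairs$distance)]
    data.frame(region = s$region_name, stratum = s$stratum,
               n_pairs = length(d),
               median = stats::median(d), q1 = unname(stats::quantile(d, 0.25)),
               q3 = unname(stats::quantile(d, 0.75)),
               min = min(d), max = max(d), mean = mean(d),
               stringsAsFactors = FALSE)
  }))
  rownames(stats_df) <- NULL
  ordering <- do.call(rbind, lapply(split(stats_df, stats_df$stratum), function(g) {
    if (nrow(g) < 2L) return(NULL)
    idx <- utils::combn(nrow(g), 2L)
    data.frame(
      stratum = g$stratum[idx[1L, ]],
      region_a = g$region[idx[1L, ]],
      region_b = g$region[idx[2L, ]],
      relation = ifelse(g$median[idx[1L, ]] < g$median[idx[2L, ]], "<",
                        ifelse(g$median[idx[1L, ]] > g$median[idx[2L, ]], ">", "=")),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ordering) <- NULL
  list(stats = stats_df, ordering = ordering)
}

#' Square p-distance matrix for a region
#'
#' Convenience wrapper returning the full symmetric distance matrix (zero
#' diagonal) from a [region_distance_summary()].
#'
#' @param summary A `distance_summary`.
#' @return Square numeric matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(summary) {
  ids <- unique(c(summary$pairs$id_a, summary$pairs$id_b))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(summary$pairs))) {
    a <- summary$pairs$id_a[k]; b <- summary$pairs$id_b[k]
    d[a, b] <- d[b, a] <- summary$pairs$distance[k]
  }
  d
}
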