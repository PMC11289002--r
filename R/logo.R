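# Kullback-Leibler enrichment/depletion logos.
#
# Letter heights are the signed per-letter KL contributions
# h_a = p_a * log2(p_a / q_a): positive for letters enriched over the
# background q, negative for depleted letters, zero at p_a = q_a. The signed
# heights of a position sum to the position's KL divergence (>= 0 whenever p
# is a proper distribution).

#' Pseudocounted residue distribution of one alignment column
#'
#' Counts the non-gap, non-`X` residues at the column over the stratum and
#' mixes in background-weighted pseudocounts:
#' `p_a = (count_a + w * q_a) / (n + w)` with `w = pseudocount_weight`.
#' With `w = 0` the raw frequencies are returned; a column with no residues
#' and `w = 0` is degenerate and yields `NA` with a `degenerate` attribute.
#'
#' @param aln A [labeled_alignment()].
#' @param column Single alignment column.
#' @param stratum A phylum name or `"all"`.
#' @param bg A [background_composition()] (required when
#'   `pseudocount_weight > 0`).
#' @param pseudocount_weight Non-negative pseudocount mass.
#' @return Named numeric probability vector over [AA_LETTERS].
#' @export
column_distribution <- function(aln, column, stratum = "all", bg = NULL,
                                pseudocount_weight = 1) {
  stopifnot(length(column) == 1L, pseudocount_weight >= 0)
  ids <- .stratum_ids(aln, stratum)
  chars <- alignment_matrix(aln)[ids, as.integer(column)]
  counts <- table(factor(chars[chars %in% AA_LETTERS], levels = AA_LETTERS))
  counts <- stats::setNames(as.numeric(counts), AA_LETTERS)
  n <- sum(counts)
  w <- pseudocount_weight
  if (w > 0) {
    if (is.null(bg)) stop("a background composition is required when pseudocount_weight > 0")
    q <- as.numeric(unclass(bg)[AA_LETTERS])
    return(stats::setNames((counts + w * q) / (n + w), AA_LETTERS))
  }
  if (n == 0) {
    out <- stats::setNames(rep(NA_real_, 20L), AA_LETTERS)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  counts / n
}

#' Signed per-letter KL contributions
#'
#' The elementary logo computation: `h_a = p_a * log2(p_a / q_a)`, with the
#' `p_a = 0` limit giving height 0. The background must be strictly positive.
#'
#' @param p Named probability vector over [AA_LETTERS].
#' @param q Background probability vector (strictly positive).
#' @return Named numeric vector of signed heights in bits; their sum is the
#'   KL divergence of `p` from `q`.
#' @export
kl_heights <- function(p, q) {
  p <- as.numeric(p[AA_LETTERS]); q <- as.numeric(unclass(q)[AA_LETTERS])
  if (any(q <= 0)) {
    stop("configuration error: background must be strictly positive for all letters")
  }
  h <- ifelse(p > 0, p * log2(p / q), 0)
  stats::setNames(h, AA_LETTERS)
}

#' Kullback-Leibler enrichment/depletion logo over a set of columns
#'
#' Builds, for each position (alignment column) of a region, the signed
#' per-letter KL heights against the background: letters over-represented
#' relative to the background stack on the positive axis, under-represented
#' letters on the negative axis, and each position's signed heights sum to its
#' KL divergence.
#'
#' @param aln A [labeled_alignment()].
#' @param columns Alignment columns of the region, in order.
#' @param stratum A phylum name or `"all"`.
#' @param bg A [background_composition()].
#' @param pseudocount_weight Non-negative pseudocount mass passed to
#'   [column_distribution()]; the default 1 keeps unobserved letters off the
#'   `log(0)` singularity by shrinking towards the background.
#' @param region_name Optional label.
#' @return Object of class `enrichment_logo`: list with `heights` (position x
#'   letter matrix, bits), `kl` (per-position KL divergence, bits), `columns`,
#'   `n_residues` (per-position residue counts), and parameters.
#' @export
kl_logo <- function(aln, columns, stratum = "all", bg,
                    pseudocount_weight = 1, region_name = NULL) {
  stopifnot(inherits(bg, "background_composition"))
  columns <- as.integer(columns)
  ids <- .stratum_ids(aln, stratum)
  m <- alignment_matrix(aln)[ids, columns, drop = FALSE]
  heights <- matrix(0, nrow = length(columns), ncol = 20L,
                    dimnames = list(NULL, AA_LETTERS))
  n_res <- integer(length(columns))
  for (k in seq_along(columns)) {
    chars <- m[, k]
    counts <- table(factor(chars[chars %in% AA_LETTERS], levels = AA_LETTERS))
    counts <- stats::setNames(as.numeric(counts), AA_LETTERS)
    n <- sum(counts)
    n_res[k] <- n
    w <- pseudocount_weight
    p <- if (w > 0) (counts + w * unclass(bg)[AA_LETTERS]) / (n + w)
         else if (n > 0) counts / n
         else stats::setNames(rep(0, 20L), AA_LETTERS)  # empty, weight 0: flat zero logo
    heights[k, ] <- kl_heights(p, bg)
  }
  structure(list(
    region_name = region_name %||% "region",
    stratum = stratum,
    columns = columns,
    heights = heights,
    kl = rowSums(heights),
    n_residues = n_res,
    pseudocount_weight = pseudocount_weight
  ), class = "enrichment_logo")
}

#' @export
print.enrichment_logo <- function(x, ...) {
  cat(sprintf("<enrichment_logo> region '%s', stratum '%s': %d positions, total KL %.3f bits\n",
              x$region_name, x$stratum, length(x$columns), sum(x$kl)))
  invisible(x)
}

#' Logo as a tidy height table
#'
#' @param logo An [kl_logo()] result.
#' @return Data frame with columns `region`, `stratum`, `position`, `column`,
#'   `letter`, `height_bits`, `kl_bits` (one row per position/letter).
#' @export
logo_table <- function(logo) {
  k <- length(logo$columns)
  out <- data.frame(
    region = logo$region_name,
    stratum = logo$stratum,
    position = rep(seq_len(k), each = 20L),
    column = rep(logo$columns, each = 20L),
    letter = rep(AA_LETTERS, times = k),
    height_bits = as.vector(t(logo$heights)),
    kl_bits = rep(logo$kl, each = 20L),
    stringsAsFactors = FALSE
  )
  out
}

#' Plot an enrichment/depletion logo
#'
#' Best-effort graphical rendering: letters stack by absolute height, largest
#' nearest the axis, enrichment above zero and depletion below. The tested
#' surface of the logo module is the height table ([logo_table()]); the plot
#' is for visual inspection.
#'
#' @param logo An [kl_logo()] result.
#' @param min_height Letters with |height| below this are not drawn.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo, min_height = 0.005) {
  df <- logo_table(logo)
  df <- df[abs(df$height_bits) >= min_height, , drop = FALSE]
  pieces <- lapply(split(df, df$position), function(g) {
    up <- g[g$height_bits > 0, , drop = FALSE]
    dn <- g[g$height_bits < 0, , drop = FALSE]
    up <- up[order(-abs(up$height_bits)), , drop = FALSE]
    dn <- dn[order(-abs(dn$height_bits)), , drop = FALSE]
    up$ymax <- cumsum(up$height_bits); up$ymin <- up$ymax - up$height_bits
    dn$ymin <- cumsum(dn$height_bits); dn$ymax <- dn$ymin - dn$height_bits
    rbind(up, dn)
  })
  df <- do.call(rbind, pieces)
  df$mid <- (df$ymin + df$ymax) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = position - 0.45, xmax = position + 0.45,
      ymin = ymin, ymax = ymax),
      fill = NA, colour = "grey85", linewidth = 0.1) +
    ggplot2::geom_text(ggplot2::aes(
      x = position, y = mid, label = letter,
      colour = height_bits > 0,
      size = abs(ymax - ymin)), fontface = "bold",
      show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1.5, 6)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "flank position", y = "signed KL contribution (bits)",
                  title = sprintf("%s (%s)", logo$region_name, logo$stratum)) +
    ggplot2::theme_minimal()
}
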