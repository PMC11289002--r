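# Derivation of lipid-water-interface (LWI) flank regions and TM regions as
# alignment-column sets from a reference topology.

#' Extract TM and lipid-water-interface segments
#'
#' Derives, from the reference topology, the alignment-column sets of each TM
#' segment and of the two LWI flanks of each TM: the `flank_width` residues on
#' the N-terminal side (`N-TMi`) and on the C-terminal side (`C-TMi`) of the
#' helix, defined on the ungapped reference and transferred to all sequences
#' through the alignment columns of the reference.
#'
#' Flanks are clipped at the sequence termini and never enter a TM segment;
#' clipped flanks carry a truncation flag. When the loop between two
#' consecutive TMs is shorter than `2 * flank_width`, the two facing flanks
#' overlap: the shared reference positions belong to *both* flanks and are
#' recorded in each flank's `overlap_ref`. Membrane sides (inner/outer)
#' alternate at every TM crossing starting from the side of the N-terminus.
#'
#' @param aln A [labeled_alignment()].
#' @param topo A [reference_topology()].
#' @return An object of class `lwi_segment_map`: a list with `tm` (per-TM
#'   reference positions and alignment columns), `flanks` (per-flank reference
#'   positions, columns, membrane side, overlap positions, truncation flag),
#'   and the topology attributes used.
#' @export
extract_segments <- function(aln, topo) {
  pos2col <- map_reference_to_columns(aln, topo)
  L <- length(pos2col)
  fw <- topo$flank_width
  tm <- topo$tm_intervals
  n_tm <- nrow(tm)

  tm_mask <- rep(FALSE, L)
  tm_list <- vector("list", n_tm)
  names(tm_list) <- paste0("TM", seq_len(n_tm))
  for (i in seq_len(n_tm)) {
    pos <- tm[i, "start"]:tm[i, "end"]
    tm_mask[pos] <- TRUE
    tm_list[[i]] <- list(ref_positions = pos, columns = pos2col[pos])
  }

  clip <- function(raw) {
    raw <- raw[raw >= 1L & raw <= L]
    raw[!tm_mask[raw]]
  }

  flanks <- list()
  for (i in seq_len(n_tm)) {
    s <- tm[i, "start"]; e <- tm[i, "end"]
    n_raw <- if (s > 1L) (s - fw):(s - 1L) else integer(0)
    c_raw <- if (e < L) (e + 1L):(e + fw) else integer(0)
    n_pos <- clip(n_raw)
    c_pos <- clip(c_raw)
    flanks[[paste0("N-TM", i)]] <- list(
      name = paste0("N-TM", i), tm_index = i, tm_side = "N",
      ref_positions = n_pos, columns = pos2col[n_pos],
      membrane_side = NA_character_,
      overlap_ref = integer(0), overlap_columns = integer(0),
      truncated = length(n_pos) < fw)
    flanks[[paste0("C-TM", i)]] <- list(
      name = paste0("C-TM", i), tm_index = i, tm_side = "C",
      ref_positions = c_pos, columns = pos2col[c_pos],
      membrane_side = NA_character_,
      overlap_ref = integer(0), overlap_columns = integer(0),
      truncated = length(c_pos) < fw)
  }

  # Overlap between the C-flank of TM i and the N-flank of TM i+1: shared
  # positions are counted for both flanks.
  for (i in seq_len(max(0L, n_tm - 1L))) {
    a <- paste0("C-TM", i); b <- paste0("N-TM", i + 1L)
    ov <- intersect(flanks[[a]]$ref_positions, flanks[[b]]$ref_positions)
    if (length(ov)) {
      for (nm in c(a, b)) {
        flanks[[nm]]$overlap_ref <- sort(ov)
        flanks[[nm]]$overlap_columns <- pos2col[sort(ov)]
      }
    }
  }

  # canonical order: N-TM1, C-TM1, N-TM2, ...
  ord <- as.vector(rbind(paste0("N-TM", seq_len(n_tm)),
                         paste0("C-TM", seq_len(n_tm))))
  map <- structure(list(
    tm = tm_list,
    flanks = flanks[ord],
    reference_id = topo$reference_id,
    flank_width = fw,
    n_terminus_side = topo$n_terminus_side,
    reference_length = L,
    alignment_width = alignment_width(aln)
  ), class = "lwi_segment_map")
  assign_sides(map, topo)
}

#' Assign inner/outer membrane sides to LWI flanks
#'
#' The membrane side alternates at every TM crossing: the N-side flank of TM1
#' lies on the side of the N-terminus, the C-side flank of TM1 on the opposite
#' side, and so on. For a 6-TM topology with an inner N-terminus the inner
#' flanks are N-TM1, C-TM2, N-TM3, C-TM4, N-TM5, C-TM6. Flipping
#' `n_terminus_side` swaps every assignment (the operation is an involution).
#'
#' @param map An `lwi_segment_map`.
#' @param topo A `reference_topology` supplying `n_terminus_side`; defaults to
#'   the side stored in `map`.
#' @return The map with `membrane_side` filled in for every flank.
#' @export
assign_sides <- function(map, topo = NULL) {
  n0 <- if (is.null(topo)) map$n_terminus_side else topo$n_terminus_side
  flip <- function(side) if (side == "inner") "outer" else "inner"
  for (nm in names(map$flanks)) {
    fl <- map$flanks[[nm]]
    # crossings before this flank: i - 1 for the N-side flank of TM i, i for
    # the C-side flank of TM i
    crossings <- fl$tm_index - (fl$tm_side == "N")
    side <- n0
    if (crossings %% 2L == 1L) side <- flip(side)
    map$flanks[[nm]]$membrane_side <- side
  }
  map$n_terminus_side <- n0
  map
}

#' @export
print.lwi_segment_map <- function(x, ...) {
  cat(sprintf("<lwi_segment_map> %d TM segments, %d flanks (flank width %d), reference '%s'\n",
              length(x$tm), length(x$flanks), x$flank_width, x$reference_id))
  print(segment_table(x))
  invisible(x)
}

#' Pool alignment columns for a named region selector
#'
#' Region selectors mirror the comparative analyses: `"LWI_total"`,
#' `"LWI_inner"` and `"LWI_outer"` pool flank columns *deduplicated* (a column
#' shared by two overlapping flanks is counted once); a single flank selector
#' such as `"C-TM1"` returns that flank's own columns including any overlap,
#' so overlapping residues contribute to both flanks in per-flank statistics;
#' `"TM_total"` pools all TM columns; a single TM selector such as `"TM3"`
#' returns one helix; `"full_length"` returns every alignment column.
#'
#' @param map An `lwi_segment_map`.
#' @param selector Region selector (see Details).
#' @return Sorted integer vector of alignment columns.
#' @export
pooled_columns <- function(map, selector) {
  stopifnot(length(selector) == 1L)
  flank_union <- function(flanks)
    sort(unique(unlist(lapply(flanks, `[[`, "columns"), use.names = FALSE)))
  if (selector == "LWI_total") {
    flank_union(map$flanks)
  } else if (selector %in% c("LWI_inner", "LWI_outer")) {
    side <- sub("^LWI_", "", selector)
    flank_union(Filter(function(f) f$membrane_side == side, map$flanks))
  } else if (selector == "TM_total") {
    sort(unique(unlist(lapply(map$tm, `[[`, "columns"), use.names = FALSE)))
  } else if (selector == "full_length") {
    seq_len(map$alignment_width)
  } else if (selector %in% names(map$flanks)) {
    map$flanks[[selector]]$columns
  } else if (selector %in% names(map$tm)) {
    map$tm[[selector]]$columns
  } else {
    stop("unknown region selector: ", selector)
  }
}

#' Segment map as a BED-like table
#'
#' One row per TM segment and per flank, in reference coordinates, for
#' inspection and export.
#'
#' @param map An `lwi_segment_map`.
#' @return Data frame with columns `name`, `ref_start`, `ref_end`,
#'   `n_positions`, `membrane_side`, `overlap_length`, `truncated`.
#' @export
segment_table <- function(map) {
  row_of <- function(name, pos, side, ov, trunc) {
    data.frame(name = name,
               ref_start = if (length(pos)) min(pos) else NA_integer_,
               ref_end = if (length(pos)) max(pos) else NA_integer_,
               n_positions = length(pos),
               membrane_side = side,
               overlap_length = ov,
               truncated = trunc,
               stringsAsFactors = FALSE)
  }
  rows <- c(
    lapply(names(map$tm), function(nm)
      row_of(nm, map$tm[[nm]]$ref_positions, "membrane", 0L, FALSE)),
    lapply(map$flanks, function(f)
      row_of(f$name, f$ref_positions, f$membrane_side,
             length(f$overlap_ref), f$truncated))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
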