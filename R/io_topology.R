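# Input/output: labeled alignments, reference topologies, background tables,
# and the reference-coordinate -> alignment-column mapping.

.PHYLA <- c("mammal", "bird", "reptile", "amphibian", "fish")
.ALLOWED_CHARS <- c(AA_LETTERS, "X", "-")

#' Construct a labeled alignment
#'
#' A labeled alignment couples an aligned set of protein sequences with
#' per-sequence species and phylum metadata. All sequences must have the same
#' (aligned) length and may contain only the twenty uppercase amino-acid
#' letters, `X` for an unknown residue, and `-` for a gap.
#'
#' @param sequences Named character vector of aligned sequences; names are
#'   sequence identifiers.
#' @param metadata Data frame with columns `sequence_id`, `species`, `phylum`;
#'   every sequence identifier must appear exactly once and `phylum` must be
#'   one of `"mammal"`, `"bird"`, `"reptile"`, `"amphibian"`, `"fish"`.
#' @return An object of class `labeled_alignment`: a list with elements `seq`
#'   (named character vector, original order preserved) and `metadata`
#'   (data frame reordered to match `seq`).
#' @seealso [read_labeled_alignment()], [write_labeled_alignment()]
#' @export
labeled_alignment <- function(sequences, metadata) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all sequences must be named with a sequence identifier")
  }
  sequences <- stats::setNames(toupper(as.character(sequences)), names(sequences))
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence identifiers: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L) {
    stop(sprintf(
      "alignment shape error: sequences have unequal lengths (%s)",
      paste(unique(widths), collapse = ", ")))
  }
  .check_alignment_chars(sequences)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sequence_id", "species", "phylum")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  missing_ids <- setdiff(names(sequences), metadata$sequence_id)
  if (length(missing_ids)) {
    stop("metadata error: no metadata for sequence(s) ",
         paste(missing_ids, collapse = ", "))
  }
  if (anyDuplicated(metadata$sequence_id)) {
    stop("metadata error: duplicated sequence_id entries")
  }
  bad_phylum <- setdiff(unique(metadata$phylum), .PHYLA)
  if (length(bad_phylum)) {
    stop("metadata error: unknown phylum ", paste(bad_phylum, collapse = ", "),
         " (expected one of ", paste(.PHYLA, collapse = ", "), ")")
  }
  metadata <- metadata[match(names(sequences), metadata$sequence_id),
                       required, drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(seq = sequences, metadata = metadata),
            class = "labeled_alignment")
}

.check_alignment_chars <- function(sequences) {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX-]", sequences)
  offender <- which(bad > 0L)
  if (length(offender)) {
    i <- offender[[1L]]
    stop(sprintf(
      "parse error: illegal character '%s' in record '%s' at column %d",
      substr(sequences[[i]], bad[[i]], bad[[i]]), names(sequences)[[i]], bad[[i]]))
  }
  invisible(TRUE)
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("<labeled_alignment> %d sequences, width %d\n",
              length(x$seq), alignment_width(x)))
  print(table(factor(x$metadata$phylum, levels = .PHYLA)))
  invisible(x)
}

#' Alignment width (number of columns)
#' @param aln A `labeled_alignment`.
#' @return Integer alignment width.
#' @export
alignment_width <- function(aln) {
  if (!length(aln$seq)) return(0L)
  nchar(aln$seq[[1L]])
}

#' Alignment as a character matrix
#'
#' @param aln A `labeled_alignment`.
#' @return Character matrix, one row per sequence (rownames are sequence
#'   identifiers), one column per alignment column.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- names(aln$seq)
  m
}

#' Read an aligned FASTA plus metadata table
#'
#' Reads an aligned FASTA file (via Biostrings) together with a tab-separated
#' metadata table with columns `sequence_id`, `species` and `phylum`, and
#' returns a validated [labeled_alignment()]. FASTA record order is preserved;
#' the identifier is the first whitespace-delimited token of the header.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the metadata TSV (header required).
#' @return A `labeled_alignment`.
#' @export
read_labeled_alignment <- function(fasta_path, metadata_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  labeled_alignment(seqs, metadata)
}

#' Write a labeled alignment to FASTA + metadata TSV
#'
#' Inverse of [read_labeled_alignment()]: round-tripping through these two
#' functions reproduces the alignment exactly.
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, a character vector with the two paths.
#' @export
write_labeled_alignment <- function(aln, fasta_path, metadata_path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$seq), fasta_path)
  utils::write.table(aln$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}

#' Construct a reference topology
#'
#' Describes the transmembrane architecture of one reference sequence:
#' the TM segment intervals in 1-based inclusive *ungapped* reference
#' coordinates, the membrane side of the N-terminus, and the width of the
#' lipid-water-interface flank taken on either side of each TM segment
#' (5 residues by default).
#'
#' @param reference_id Identifier of the reference sequence.
#' @param tm_intervals Two-column matrix or data frame of `(start, end)` pairs,
#'   sorted, non-overlapping, each `start <= end`.
#' @param n_terminus_side `"inner"` (cytoplasmic) or `"outer"` (extracellular).
#' @param flank_width Positive integer flank width in residues.
#' @return An object of class `reference_topology`.
#' @export
reference_topology <- function(reference_id, tm_intervals,
                               n_terminus_side = c("inner", "outer"),
                               flank_width = 5L) {
  n_terminus_side <- match.arg(n_terminus_side)
  tm <- as.matrix(tm_intervals)
  if (is.data.frame(tm_intervals)) tm <- as.matrix(tm_intervals[, 1:2])
  storage.mode(tm) <- "integer"
  if (ncol(tm) != 2L || nrow(tm) < 1L) {
    stop("tm_intervals must be a two-column (start, end) table with >= 1 row")
  }
  colnames(tm) <- c("start", "end")
  if (any(tm[, "start"] > tm[, "end"]) || any(tm < 1L)) {
    stop("topology error: each TM interval needs 1 <= start <= end")
  }
  if (nrow(tm) > 1L && any(tm[-1L, "start"] <= tm[-nrow(tm), "end"])) {
    stop("topology error: TM intervals must be sorted and non-overlapping")
  }
  flank_width <- as.integer(flank_width)
  if (length(flank_width) != 1L || is.na(flank_width) || flank_width < 1L) {
    stop("flank_width must be a positive integer")
  }
  structure(list(reference_id = as.character(reference_id),
                 tm_intervals = tm,
                 n_terminus_side = n_terminus_side,
                 flank_width = flank_width),
            class = "reference_topology")
}

#' @export
print.reference_topology <- function(x, ...) {
  cat(sprintf("<reference_topology> reference '%s', %d TM segments, N-terminus %s, flank width %d\n",
              x$reference_id, nrow(x$tm_intervals), x$n_terminus_side, x$flank_width))
  invisible(x)
}

#' Read / write a topology config file
#'
#' The topology is stored as a small YAML key-value file with keys
#' `reference_id`, `tm` (list of `[start, end]` pairs), `n_terminus_side`
#' and `flank_width`.
#'
#' @param path File path.
#' @return `read_topology()` returns a `reference_topology`.
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("reference_id", "tm", "n_terminus_side")) {
    if (is.null(cfg[[key]])) {
      stop("topology config error: missing key '", key, "'")
    }
  }
  tm <- do.call(rbind, lapply(cfg$tm, function(iv) as.integer(iv[1:2])))
  reference_topology(cfg$reference_id, tm, cfg$n_terminus_side,
                     flank_width = cfg$flank_width %||% 5L)
}

#' @rdname read_topology
#' @param topo A `reference_topology` to write.
#' @export
write_topology <- function(topo, path) {
  yaml::write_yaml(list(
    reference_id = topo$reference_id,
    n_terminus_side = topo$n_terminus_side,
    flank_width = topo$flank_width,
    tm = lapply(seq_len(nrow(topo$tm_intervals)), function(i)
      as.integer(topo$tm_intervals[i, ]))
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map ungapped reference positions to alignment columns
#'
#' For the reference sequence named by the topology, returns the strictly
#' increasing map from 1-based ungapped reference position to 1-based
#' alignment column: position `p` maps to the column holding the reference's
#' `p`-th non-gap character.
#'
#' @param aln A `labeled_alignment`.
#' @param topo A `reference_topology` (or a single sequence id).
#' @return Integer vector `v` of length equal to the reference's ungapped
#'   length, with `v[p]` the alignment column of reference position `p`.
#' @export
map_reference_to_columns <- function(aln, topo) {
  ref_id <- if (inherits(topo, "reference_topology")) topo$reference_id else topo
  if (!ref_id %in% names(aln$seq)) {
    stop("lookup error: reference '", ref_id, "' not present in the alignment")
  }
  chars <- strsplit(aln$seq[[ref_id]], "", fixed = TRUE)[[1L]]
  cols <- which(chars != "-")
  if (inherits(topo, "reference_topology") &&
      max(topo$tm_intervals) > length(cols)) {
    stop(sprintf(
      "topology error: TM coordinates exceed the reference's ungapped length (%d)",
      length(cols)))
  }
  cols
}

#' Construct a background amino-acid composition
#'
#' @param frequency Named numeric vector over all twenty amino-acid letters;
#'   entries must be strictly between 0 and 1 and sum to 1 within `1e-3`
#'   (the vector is renormalized to sum exactly to 1).
#' @return Object of class `background_composition` (named numeric, ordered
#'   as [AA_LETTERS]).
#' @export
background_composition <- function(frequency) {
  if (is.null(names(frequency))) stop("composition error: frequencies must be named")
  missing <- setdiff(AA_LETTERS, names(frequency))
  extra <- setdiff(names(frequency), AA_LETTERS)
  if (length(missing) || length(extra)) {
    stop("composition error: background must cover exactly the 20 amino acids",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  frequency <- frequency[AA_LETTERS]
  if (any(!is.finite(frequency)) || any(frequency <= 0) || any(frequency >= 1)) {
    stop("composition error: each background frequency must lie in (0, 1)")
  }
  s <- sum(frequency)
  if (abs(s - 1) > 1e-3) {
    stop(sprintf("composition error: background frequencies sum to %.6f, not 1", s))
  }
  structure(frequency / s, class = "background_composition")
}

#' Load a background ("natural abundance") composition
#'
#' Accepts either the name of a packaged table or a path to a two-column TSV
#' (`letter`, `frequency`). Available names: `"swissprot"`, the
#' UniProtKB/Swiss-Prot proteome-average amino-acid composition (the packaged
#' default natural-abundance baseline), and `"uniform"` (all letters 0.05).
#'
#' @param source Table name or file path.
#' @return A [background_composition()].
#' @export
load_background <- function(source = "swissprot") {
  if (identical(source, "uniform")) {
    return(background_composition(stats::setNames(rep(0.05, 20L), AA_LETTERS)))
  }
  path <- if (identical(source, "swissprot")) {
    system.file("extdata", "background_swissprot.tsv", package = "lwiscan",
                mustWork = TRUE)
  } else {
    source
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("letter", "frequency") %in% names(tab))) {
    stop("composition error: background table needs columns 'letter' and 'frequency'")
  }
  background_composition(stats::setNames(tab$frequency, tab$letter))
}
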