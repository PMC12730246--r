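#' Select one ortholog per species from a homology hit table
#'
#' Implements the ortholog selection rule used before conservation scoring:
#' per species, keep hits with percent identity strictly above 20 and
#' query coverage of at least 60%, then take the hit with the highest
#' percent identity; ties are broken by higher bitscore, then by the
#' lexicographically smallest subject id. Species with no surviving record
#' are simply absent from the result.
#'
#' @param records Tibble with columns `query_id`, `subject_id`, `species`,
#'   `percent_identity` (0-100), `coverage_fraction` (0-1), `bitscore`,
#'   all for a single query protein.
#' @param min_identity Identity cutoff, exclusive (default 20).
#' @param min_coverage Coverage cutoff, inclusive (default 0.6).
#' @return Tibble with one row per retained species (`species`,
#'   `subject_id`, plus the record's metrics).
#' @export
select_orthologs <- function(records, min_identity = 20,
                             min_coverage = 0.6) {
  if (n_distinct(records$query_id) > 1L) {
    abort("`records` must describe hits for a single query protein.")
  }
  records |>
    filter(.data$percent_identity > min_identity,
           .data$coverage_fraction >= min_coverage) |>
    group_by(.data$species) |>
    arrange(dplyr::desc(.data$percent_identity),
            dplyr::desc(.data$bitscore), .data$subject_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Read a tabular homology hit table
#'
#' Expects named columns `query`, `subject`, `species`, `pident`, `qstart`,
#' `qend`, `bitscore` (BLAST outfmt-6-like with headers). Coverage of the
#' query is computed as `(qend - qstart + 1) / query_length`.
#'
#' @param path TSV path.
#' @param query_length Length of the query (human) sequence, used for the
#'   coverage fraction.
#' @return Tibble in the [select_orthologs()] input format.
#' @export
read_homology_hits <- function(path, query_length) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    query = readr::col_character(), subject = readr::col_character(),
    species = readr::col_character(), pident = readr::col_double(),
    qstart = readr::col_integer(), qend = readr::col_integer(),
    bitscore = readr::col_double()
  ), progress = FALSE)
  tibble(
    query_id = raw$query, subject_id = raw$subject, species = raw$species,
    percent_identity = raw$pident,
    coverage_fraction = (raw$qend - raw$qstart + 1) / query_length,
    bitscore = raw$bitscore
  )
}

#' Construct an alignment block
#'
#' A thin container for a multiple sequence alignment: a tibble of rows
#' (`row_id`, `species`, `aligned_seq`, all gapped sequences the same
#' length) plus the id of the reference (human) row.
#'
#' @param rows Tibble with `row_id`, `species`, `aligned_seq`.
#' @param reference_row `row_id` of the reference sequence.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(rows, reference_row) {
  stopifnot(is.data.frame(rows),
            all(c("row_id", "species", "aligned_seq") %in% names(rows)))
  widths <- unique(nchar(rows$aligned_seq))
  if (length(widths) != 1L) {
    abort("All gapped sequences in an alignment block must have equal length.")
  }
  if (!reference_row %in% rows$row_id) {
    abort(sprintf("Reference row '%s' not present in the alignment.",
                  reference_row))
  }
  structure(list(rows = as_tibble(rows), reference_row = reference_row),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d rows x %d columns (reference: %s)\n",
              nrow(x$rows), nchar(x$rows$aligned_seq[1]), x$reference_row))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' `read_alignment_fasta()` reads an aligned FASTA file;
#' `read_alignment_clustal()` reads Clustal format (via
#' [seqinr::read.alignment()]). Species labels default to the row ids
#' unless a `species` vector is given.
#'
#' @param path Alignment file.
#' @param reference_row Row id of the reference (human) sequence; defaults
#'   to the first row.
#' @param species Optional character vector of species labels, parallel to
#'   the alignment rows.
#' @return An [alignment_block()].
#' @name alignment_readers
NULL

#' @rdname alignment_readers
#' @export
read_alignment_fasta <- function(path, reference_row = NULL, species = NULL) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  build_alignment(ids, toupper(as.character(set)), reference_row, species)
}

#' @rdname alignment_readers
#' @export
read_alignment_clustal <- function(path, reference_row = NULL,
                                   species = NULL) {
  aln <- seqinr::read.alignment(path, format = "clustal")
  build_alignment(aln$nam, toupper(unlist(aln$seq)), reference_row, species)
}

build_alignment <- function(ids, seqs, reference_row, species) {
  rows <- tibble(
    row_id = unname(ids),
    species = unname(species %||% ids),
    aligned_seq = unname(seqs)
  )
  alignment_block(rows, reference_row %||% ids[1])
}

#' Map between ungapped residue positions and alignment columns
#'
#' `map_position_to_column()` returns the alignment column holding the
#' residue at a given 1-based ungapped position of a row;
#' `map_column_to_position()` is the inverse (for a gap column, the
#' position of the last residue at or before it, or 0 if none).
#'
#' @param block An [alignment_block()].
#' @param row_id Row identifier.
#' @param position 1-based ungapped residue position.
#' @param column 1-based alignment column.
#' @return An integer scalar.
#' @export
map_position_to_column <- function(block, row_id, position) {
  gapped <- aligned_row(block, row_id)
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-")
  if (position < 1L || position > length(residue_cols)) {
    abort(sprintf(
      "Position %d out of range for row '%s' (ungapped length %d).",
      position, row_id, length(residue_cols)
    ))
  }
  residue_cols[position]
}

#' @rdname map_position_to_column
#' @export
map_column_to_position <- function(block, row_id, column) {
  gapped <- aligned_row(block, row_id)
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  if (column < 1L || column > length(chars)) {
    abort(sprintf("Column %d out of range (alignment width %d).",
                  column, length(chars)))
  }
  sum(chars[seq_len(column)] != "-")
}

aligned_row <- function(block, row_id) {
  i <- match(row_id, block$rows$row_id)
  if (is.na(i)) abort(sprintf("Row '%s' not found in alignment.", row_id))
  block$rows$aligned_seq[i]
}

ungap <- function(gapped) gsub("-", "", gapped, fixed = TRUE)

#' Score ortholog conservation of a motif hit
#'
#' For a motif hit at a known ungapped position of the reference (human)
#' row, decides for each ortholog row whether the motif is conserved: the
#' ortholog's ungapped sequence is scanned with the definition, each hit's
#' core start is mapped to its alignment column, and the row counts as
#' conserved iff some hit column lies within `window` columns of the
#' reference hit column. The +/-50-column default absorbs the indel drift
#' typical of disordered regions, where alignments are least reliable.
#'
#' @param block An [alignment_block()].
#' @param definition [motif_definition()] used to scan the orthologs
#'   (defaults to the strong definition).
#' @param human_core_start 1-based ungapped core start of the motif in the
#'   reference row; the reference must actually carry a hit there.
#' @param window Tolerance (default 50).
#' @param space `"column"` measures the tolerance in alignment columns
#'   (default); `"residue"` measures it in the ortholog's own ungapped
#'   residue coordinates instead.
#' @return Object of class `conservation_result`: a list with `per_row`
#'   (tibble: `row_id`, `species`, `conserved`, `column_distance`),
#'   `conserved_fraction` (over non-reference rows), `reference_column`,
#'   `human_core_start`, `window`.
#' @export
conservation_score <- function(block, definition = tsh3_motif("strong"),
                               human_core_start, window = 50L,
                               space = c("column", "residue")) {
  space <- match.arg(space)
  stopifnot(inherits(block, "alignment_block"))
  ref_seq <- ungap(aligned_row(block, block$reference_row))
  ref_hits <- scan_sequence(ref_seq, definition, block$reference_row)
  if (!human_core_start %in% ref_hits$core_start) {
    abort(sprintf(
      "Reference row '%s' has no '%s' hit with core start %d.",
      block$reference_row, definition$name, human_core_start
    ))
  }
  ref_col <- map_position_to_column(block, block$reference_row,
                                    human_core_start)
  others <- filter(block$rows, .data$row_id != block$reference_row)
  per_row <- purrr::pmap(
    list(others$row_id, others$species),
    function(rid, sp) {
      seq <- ungap(aligned_row(block, rid))
      hits <- scan_sequence(seq, definition, rid)
      if (nrow(hits) == 0L) {
        return(tibble(row_id = rid, species = sp, conserved = FALSE,
                      column_distance = NA_integer_))
      }
      dists <- if (space == "column") {
        vapply(hits$core_start, function(p) {
          abs(map_position_to_column(block, rid, p) - ref_col)
        }, numeric(1))
      } else {
        ref_pos_in_row <- map_column_to_position(block, rid, ref_col)
        abs(hits$core_start - ref_pos_in_row)
      }
      best <- min(dists)
      tibble(row_id = rid, species = sp, conserved = best <= window,
             column_distance = as.integer(best))
    }
  ) |> bind_rows()
  structure(
    list(
      per_row = per_row,
      conserved_fraction = if (nrow(per_row)) mean(per_row$conserved) else NA_real_,
      reference_column = ref_col,
      human_core_start = as.integer(human_core_start),
      window = as.integer(window)
    ),
    class = "conservation_result"
  )
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(
    "<conservation_result> core start %d (column %d), window %d: %.2f conserved over %d orthologs\n",
    x$human_core_start, x$reference_column, x$window,
    x$conserved_fraction, nrow(x$per_row)
  ))
  invisible(x)
}

#' @export
tidy.conservation_result <- function(x, ...) {
  x$per_row
}

#' @export
glance.conservation_result <- function(x, ...) {
  tibble(
    human_core_start = x$human_core_start,
    reference_column = x$reference_column,
    window = x$window,
    n_orthologs = nrow(x$per_row),
    conserved_fraction = x$conserved_fraction
  )
}

#' @rdname conservation_score
#' @param x A `conservation_result`.
#' @export
conserved_fraction <- function(x) {
  stopifnot(inherits(x, "conservation_result"))
  x$conserved_fraction
}

#' Write a conservation result to TSV
#'
#' @param x A `conservation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(x, path) {
  out <- tidy(x) |>
    mutate(conserved_fraction = x$conserved_fraction,
           human_core_start = x$human_core_start)
  write_tsv_dot(out, path)
}
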