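#' Scan a sequence for matches to a motif definition
#'
#' Slides a window over the sequence and reports every match of the
#' positional character classes, including overlapping matches. Coordinates
#' are 1-based inclusive and reported in absolute (anchor-based) numbering,
#' so a fragment excised from a longer protein can be scanned in its native
#' coordinate system (UniProt-style).
#'
#' For definitions with `requires_full_window = TRUE`, matches whose flank
#' positions 6-7 would fall beyond the sequence end are not reported.
#' The ambiguity code `X` never satisfies any residue class.
#'
#' @param sequence Amino-acid sequence (single string). May be empty.
#' @param definition A [motif_definition()].
#' @param protein_id Identifier recorded in the output.
#' @param anchor 1-based absolute position of the first residue of
#'   `sequence` (default 1).
#' @return A tibble of hits ordered by `core_start`, with columns
#'   `protein_id`, `definition`, `core_start`, `core_end`, `window_start`,
#'   `window_end`, `matched_core`, `flank_residues`, `position0_residue`
#'   (`NA` when the core starts at the first residue).
#' @examples
#' scan_sequence("SNPPPRPPA", tsh3_motif("strong"), "CYBA", anchor = 153)
#' @export
scan_sequence <- function(sequence, definition, protein_id = "query",
                          anchor = 1L) {
  stopifnot(inherits(definition, "motif_definition"))
  if (!is.numeric(anchor) || length(anchor) != 1L || anchor < 1 ||
      anchor != floor(anchor)) {
    abort("`anchor` must be a single integer >= 1.")
  }
  anchor <- as.integer(anchor)
  if (!nzchar(sequence)) {
    return(empty_hit_table())
  }
  chars <- aa_check(sequence, sprintf("sequence of '%s'", protein_id))
  starts <- match_core_starts(chars, definition)
  if (length(starts) == 0L) {
    return(empty_hit_table())
  }
  L <- length(chars)
  flank1 <- ifelse(starts + 5L <= L, chars[pmin(starts + 5L, L)], NA_character_)
  flank2 <- ifelse(starts + 6L <= L, chars[pmin(starts + 6L, L)], NA_character_)
  pos0 <- ifelse(starts > 1L, chars[pmax(starts - 1L, 1L)], NA_character_)
  tibble(
    protein_id = protein_id,
    definition = definition$name,
    core_start = starts + anchor - 1L,
    core_end = starts + anchor + 3L,
    window_start = starts + anchor - 1L,
    window_end = pmin(starts + 6L, L) + anchor - 1L,
    matched_core = vapply(starts, function(s) {
      paste(chars[s:(s + 4L)], collapse = "")
    }, character(1)),
    flank_residues = paste0(
      ifelse(is.na(flank1), "", flank1), ifelse(is.na(flank2), "", flank2)
    ),
    position0_residue = pos0
  )
}

empty_hit_table <- function() {
  tibble(
    protein_id = character(), definition = character(),
    core_start = integer(), core_end = integer(),
    window_start = integer(), window_end = integer(),
    matched_core = character(), flank_residues = character(),
    position0_residue = character()
  )
}

# Core matcher over a residue character vector; returns 1-based (local)
# start positions of windows satisfying the definition.
match_core_starts <- function(chars, definition) {
  L <- length(chars)
  if (L < 5L) return(integer())
  n <- L - 4L
  ok <- rep(TRUE, n)
  idx <- seq_len(n)
  for (j in 1:5) {
    ok <- ok & (chars[idx + j - 1L] %in% definition$core_classes[[j]])
  }
  if (definition$requires_full_window) {
    # flanks must exist and avoid the exclusion sets
    ok <- ok & (idx + 6L <= L)
    for (j in 1:2) {
      excl <- definition$flank_exclusions[[j]]
      pos <- idx + 4L + j
      inbounds <- pos <= L
      viol <- inbounds & (chars[pmin(pos, L)] %in% c(excl, "X"))
      # X at a flank position of a full-window definition fails the match:
      # it cannot be shown to satisfy the constraint.
      ok <- ok & !viol
    }
  }
  idx[ok]
}

count_matches <- function(chars, definition) {
  length(match_core_starts(chars, definition))
}

#' Classify a motif window
#'
#' Given the residues of a motif window (core positions 1-5, optional flanks
#' 6-7 and optional position-0 context), assigns the class label used
#' throughout the pipeline:
#' * `strong`    - all seven positions satisfy the strong definition;
#' * `weak_only` - satisfies the weak 7-mer definition but not the strong;
#' * `core_only` - positions 1-5 match the strong core but a flank
#'   constraint fails (or flanks are truncated).
#'
#' Two annotations are set alongside the label: `reverse_candidate` is
#' `TRUE` only when an Arg occupies position 0 *and* at least one flank
#' residue is acidic (the conjunction observed for the motifs predicted to
#' bind in the reverse orientation); `phospho_flank` is `TRUE` when a flank
#' residue is Ser or Thr (potential phospho-regulation; Thr is an extension
#' beyond the Ser cases discussed for the known instances).
#'
#' A window whose core matches only the weak core while a flank constraint
#' fails receives no label (`NA`): the classification scheme reserves
#' `core_only` for strong-core matches.
#'
#' @param core 5-residue core string or character vector.
#' @param flanks Up to 2 flank residues (string or vector; may be empty).
#' @param position0 Residue preceding the core, or `NA` if absent.
#' @return A list with `class_label`, `reverse_candidate`, `phospho_flank`.
#' @examples
#' classify_hit("PPPRR", "DM", position0 = "R") # core_only, reverse candidate
#' classify_hit("VPTRP", "SP")                  # weak_only, phospho flank
#' @export
classify_hit <- function(core, flanks = character(), position0 = NA) {
  core <- unlist(strsplit(paste(core, collapse = ""), "", fixed = TRUE))
  flanks <- unlist(strsplit(paste(flanks, collapse = ""), "", fixed = TRUE))
  if (length(core) != 5L) {
    abort("`core` must contain exactly 5 residues.")
  }
  strong <- tsh3_motif("strong")
  weak <- tsh3_motif("weak")
  core_ok <- function(def) {
    all(vapply(1:5, function(j) core[j] %in% def$core_classes[[j]],
               logical(1)))
  }
  if (!core_ok(weak) && !core_ok(strong)) {
    abort("Core does not match the strong or weak core classes.")
  }
  flank_ok <- function(def) {
    length(flanks) == 2L &&
      !any(vapply(1:2, function(j) {
        flanks[j] %in% c(def$flank_exclusions[[j]], "X")
      }, logical(1)))
  }
  label <- if (core_ok(strong) && flank_ok(strong)) {
    "strong"
  } else if (core_ok(weak) && flank_ok(weak)) {
    "weak_only"
  } else if (core_ok(strong)) {
    "core_only"
  } else {
    NA_character_
  }
  acidic_flank <- any(flanks %in% c("D", "E"))
  list(
    class_label = label,
    reverse_candidate = identical(position0, "R") && acidic_flank,
    phospho_flank = any(flanks %in% c("S", "T"))
  )
}

#' Scan and classify tandem-SH3 motif candidates in one call
#'
#' Finds every window matching the weak core classes (a superset of the
#' strong core), classifies each with [classify_hit()], and drops windows
#' that receive no class label. This is the scanner used by the
#' proteome-level pipeline.
#'
#' @inheritParams scan_sequence
#' @return The [scan_sequence()] hit tibble with additional columns
#'   `class_label`, `reverse_candidate` and `phospho_flank`.
#' @examples
#' scan_motifs("QRPPPRRDM", protein_id = "TKS4", anchor = 344)
#' @export
scan_motifs <- function(sequence, protein_id = "query", anchor = 1L) {
  candidates <- scan_sequence(
    sequence,
    motif_definition(
      "candidate_core",
      core_classes = tsh3_motif("weak")$core_classes,
      requires_full_window = FALSE
    ),
    protein_id = protein_id, anchor = anchor
  )
  if (nrow(candidates) == 0L) {
    return(mutate(candidates,
                  class_label = character(),
                  reverse_candidate = logical(),
                  phospho_flank = logical()))
  }
  cls <- purrr::pmap(
    list(candidates$matched_core, candidates$flank_residues,
         candidates$position0_residue),
    function(core, flanks, pos0) {
      classify_hit(core, flanks, position0 = if (is.na(pos0)) NA else pos0)
    }
  )
  candidates |>
    mutate(
      definition = "tsh3",
      class_label = vapply(cls, `[[`, character(1), "class_label"),
      reverse_candidate = vapply(cls, `[[`, logical(1), "reverse_candidate"),
      phospho_flank = vapply(cls, `[[`, logical(1), "phospho_flank")
    ) |>
    filter(!is.na(.data$class_label))
}

#' Find Px\[PAV\]xPR sites (individual CIN85-SH3 preference)
#'
#' Scans for the 6-residue pattern `P x [PAV] x P R` (x = any standard
#' residue) recognised by individual SH3 domains of the CIN85 adaptor, used
#' to annotate overlap between tandem-SH3 motifs and individual-SH3 binding
#' sites.
#'
#' @inheritParams scan_sequence
#' @return Integer vector of 1-based (anchor-adjusted) match start positions.
#' @examples
#' match_px_pav_x_pr("QRPVVPPRRPPPP") # 3
#' @export
match_px_pav_x_pr <- function(sequence, anchor = 1L) {
  if (!nzchar(sequence)) return(integer())
  chars <- aa_check(sequence)
  L <- length(chars)
  if (L < 6L) return(integer())
  idx <- seq_len(L - 5L)
  any_aa <- AA_STANDARD
  ok <- chars[idx] == "P" &
    chars[idx + 1L] %in% any_aa &
    chars[idx + 2L] %in% c("P", "A", "V") &
    chars[idx + 3L] %in% any_aa &
    chars[idx + 4L] == "P" &
    chars[idx + 5L] == "R"
  idx[ok] + as.integer(anchor) - 1L
}

#' Write a motif hit table to TSV
#'
#' Fixed column order; missing values are written as `"."`.
#'
#' @param hits Hit tibble from [scan_motifs()] or [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("protein_id", "definition", "class_label", "core_start",
            "core_end", "window_start", "window_end", "matched_core",
            "flank_residues", "position0_residue", "reverse_candidate",
            "phospho_flank")
  out <- hits
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out <- out[, cols]
  write_tsv_dot(out, path)
  invisible(path)
}

# TSV writer with '.' for missing values and deterministic formatting.
write_tsv_dot <- function(df, path) {
  df <- as_tibble(df)
  df[] <- lapply(df, function(col) {
    if (is.list(col)) {
      col <- vapply(col, function(x) {
        if (length(x) == 0L) "." else paste(x, collapse = ",")
      }, character(1))
    }
    col <- as.character(col)
    col[is.na(col) | !nzchar(col)] <- "."
    col
  })
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
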