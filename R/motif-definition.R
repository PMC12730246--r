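#' Construct a tandem-SH3 motif definition
#'
#' A tSH3-binding motif is described as a positional character-class pattern
#' over an eight-position window numbered 0 to 7: position 0 is the residue
#' immediately preceding the core, positions 1-5 form the polyproline-II core
#' (each constrained to an allowed residue set), and positions 6-7 are
#' C-terminal flanks constrained by *forbidden* residue sets (acidic residues
#' there abolish binding).
#'
#' @param name Identifier for the definition.
#' @param core_classes List of exactly 5 character vectors, the allowed
#'   residues at core positions 1-5. Each must be a non-empty subset of the
#'   20 standard amino acids.
#' @param flank_exclusions List of exactly 2 character vectors, the residues
#'   forbidden at flank positions 6 and 7. Either may be empty
#'   (unconstrained).
#' @param requires_full_window If `TRUE` (the default for the 7-mer
#'   definitions) matches whose flank positions fall beyond the end of the
#'   sequence are not reported; core-only definitions set this to `FALSE`.
#' @return An object of class `motif_definition`.
#' @seealso [tsh3_motif()] for the built-in strong/weak/core definitions.
#' @examples
#' strong <- tsh3_motif("strong")
#' motif_definition(
#'   name = "custom",
#'   core_classes = list("P", "P", "P", "R", c("P", "R")),
#'   flank_exclusions = list(c("D", "E"), character())
#' )
#' @export
motif_definition <- function(name, core_classes,
                             flank_exclusions = list(character(), character()),
                             requires_full_window = TRUE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  if (!is.list(core_classes) || length(core_classes) != 5L) {
    abort("`core_classes` must be a list of exactly 5 residue sets.")
  }
  core_classes <- lapply(core_classes, normalise_class, allow_empty = FALSE)
  if (!is.list(flank_exclusions) || length(flank_exclusions) != 2L) {
    abort("`flank_exclusions` must be a list of exactly 2 residue sets.")
  }
  flank_exclusions <- lapply(flank_exclusions, normalise_class,
                             allow_empty = TRUE)
  structure(
    list(
      name = name,
      core_classes = core_classes,
      flank_exclusions = flank_exclusions,
      requires_full_window = isTRUE(requires_full_window)
    ),
    class = "motif_definition"
  )
}

normalise_class <- function(x, allow_empty) {
  x <- unique(toupper(unlist(strsplit(as.character(x), "", fixed = TRUE))))
  x <- x[nzchar(x)]
  if (!allow_empty && length(x) == 0L) {
    abort("Core residue classes must be non-empty.")
  }
  bad <- setdiff(x, AA_STANDARD)
  if (length(bad)) {
    abort(sprintf(
      "Residue class contains non-standard amino acid(s): %s.",
      paste(bad, collapse = ", ")
    ))
  }
  sort(x)
}

#' @export
print.motif_definition <- function(x, ...) {
  core <- vapply(x$core_classes, function(cl) {
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1))
  flank <- vapply(x$flank_exclusions, function(cl) {
    if (length(cl) == 0L) "." else paste0("[^", paste(cl, collapse = ""), "]")
  }, character(1))
  pat <- paste(core, collapse = "")
  if (x$requires_full_window) pat <- paste0(pat, paste(flank, collapse = ""))
  cat(sprintf("<motif_definition> %s: %s%s\n", x$name, pat,
              if (x$requires_full_window) "" else " (core only)"))
  invisible(x)
}

#' Built-in tandem-SH3 motif definitions
#'
#' Three definitions ship with the package:
#' * `"strong"` - `[PAVIL]PPR[PR][^DE][^DE]`, the strict tSH3-binding motif;
#' * `"weak"`   - `[PAVIL]P[PTAV]R[RP][^DE][^DE]`, the relaxed variant that
#'   admits Thr/Ala/Val at core position 3 (as in the weak-binding NOXO1
#'   C-terminal autoregulatory motif);
#' * `"core"`   - `[PAVIL]PPR[PR]`, the strong 5-residue core with no flank
#'   constraints, used to pick up matches whose flanks fail the acidic
#'   exclusion (candidates for the reverse binding mode) or are truncated.
#'
#' The strong match language is a position-wise subset of the weak one.
#'
#' @param name One of `"strong"`, `"weak"`, `"core"`.
#' @return A [motif_definition()].
#' @examples
#' tsh3_motif("strong")
#' @export
tsh3_motif <- function(name = c("strong", "weak", "core")) {
  name <- match.arg(name)
  switch(name,
    strong = motif_definition(
      "strong",
      core_classes = list(c("P", "A", "V", "I", "L"), "P", "P", "R",
                          c("P", "R")),
      flank_exclusions = list(c("D", "E"), c("D", "E"))
    ),
    weak = motif_definition(
      "weak",
      core_classes = list(c("P", "A", "V", "I", "L"), "P",
                          c("P", "T", "A", "V"), "R", c("R", "P")),
      flank_exclusions = list(c("D", "E"), c("D", "E"))
    ),
    core = motif_definition(
      "core",
      core_classes = list(c("P", "A", "V", "I", "L"), "P", "P", "R",
                          c("P", "R")),
      flank_exclusions = list(character(), character()),
      requires_full_window = FALSE
    )
  )
}

#' Read motif definitions from a plain-text config file
#'
#' The file is YAML: a named list of definitions, each with a `core` entry
#' (five class strings) and optionally `exclude` (two strings of forbidden
#' flank residues; empty string means unconstrained) and `full_window`
#' (logical, default `TRUE`).
#'
#' ```yaml
#' strong:
#'   core: [PAVIL, P, P, R, PR]
#'   exclude: [DE, DE]
#' ```
#'
#' @param path Path to the config file.
#' @return Named list of [motif_definition()] objects.
#' @export
read_motif_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    abort("Motif config must be a named mapping of definitions.")
  }
  defs <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    core <- as.list(as.character(entry$core))
    if (length(core) != 5L) {
      abort(sprintf("Definition '%s' must list 5 core class strings.", nm))
    }
    excl <- entry$exclude %||% list("", "")
    excl <- lapply(as.character(excl), identity)
    if (length(excl) != 2L) {
      abort(sprintf("Definition '%s' must list 2 exclusion strings.", nm))
    }
    motif_definition(
      name = nm, core_classes = core,
      flank_exclusions = excl,
      requires_full_window = entry$full_window %||% TRUE
    )
  })
  setNames(defs, names(raw))
}
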