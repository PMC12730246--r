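# Shared fixtures built in code.

# The eight unique validated/proposed tSH3-binding peptides with their
# UniProt-style window anchors and expected classifications.
tsh3_peptides <- function() {
  tibble::tribble(
    ~protein,  ~peptide,     ~anchor, ~expected_class, ~expected_reverse,
    "NCF1",    "RGAPPRRSS",  296L,    "strong",        FALSE,
    "CYBA",    "SNPPPRPPA",  153L,    "strong",        FALSE,
    "NOXO1",   "PTVPTRPSP",  329L,    "weak_only",     FALSE,
    "TKS4",    "QRPPPRRDM",  344L,    "core_only",     TRUE,
    "SOS1",    "PPVPPRRRP",  1151L,   "strong",        FALSE,
    "NCF1b",   "PAVPPRPSA",  363L,    "strong",        FALSE,
    "TKS4b",   "PVVPPRRPP",  755L,    "strong",        FALSE,
    "TKS5",    "TRPPPRRES",  398L,    "core_only",     TRUE
  )
}

# A small alignment block where one ortholog's motif sits exactly `shift`
# columns from the reference motif column. Both rows are gapless Gly
# backgrounds with a PPPRPAA window placed at the controlled offsets, so
# column distance equals the offset difference by construction. Returns the
# block plus the reference (ungapped) core start.
shifted_motif_block <- function(shift) {
  bg <- function(n) strrep("G", n)
  motif <- "PPPRPAA"
  ref_pad <- 10L + max(0L, -shift)
  oth_pad <- ref_pad + shift
  width <- ref_pad + max(0L, shift) + nchar(motif) + 10L
  ref <- paste0(bg(ref_pad), motif,
                bg(width - ref_pad - nchar(motif)))
  oth <- paste0(bg(oth_pad), motif,
                bg(width - oth_pad - nchar(motif)))
  stopifnot(nchar(ref) == nchar(oth))
  list(
    block = tsh3scan::alignment_block(
      tibble::tibble(
        row_id = c("human", "orth"),
        species = c("human", "orth"),
        aligned_seq = c(ref, oth)
      ),
      reference_row = "human"
    ),
    core_start = ref_pad + 1L
  )
}
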