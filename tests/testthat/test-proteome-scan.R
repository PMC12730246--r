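no_arg_comp <- c(A = 0.5, G = 0.3, S = 0.2) # no P/R: no chance motifs

test_that("planted motifs are recovered with exact coordinates", {
  planted <- tibble::tibble(
    protein_id = c("SYN0001", "SYN0003", "SYN0007"),
    peptide = c("SNPPPRPPA", "PPVPPRRRP", "PAVPPRPSA"),
    peptide_start = c(153L, 40L, 90L),
    core_offset = 3L
  )
  gen <- gen_proteome(10, composition = no_arg_comp, planted = planted,
                      seed = 5)
  hits <- scan_proteome(gen$proteins)
  expect_equal(n_hit_proteins(hits), 3L)
  expect_equal(attr(hits, "n_proteins_with_hits"), 3L)
  got <- dplyr::arrange(hits, protein_id)
  expect_equal(got$protein_id, sort(planted$protein_id))
  expect_equal(sort(got$core_start), sort(gen$manifest$core_start))
  # no hit outside the planted windows (the background lacks Arg)
  expect_equal(nrow(hits), 3L)
})

test_that("proteome scans equal per-sequence oracle counts", {
  withr::local_seed(9)
  proteins <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:20),
    sequence = replicate(20, random_aa_string(
      60, alphabet = c("P", "R", "A", "S", "D")
    ))
  )
  hits <- scan_proteome(proteins, definition = tsh3_motif("strong"))
  oracle_total <- sum(vapply(proteins$sequence, function(s) {
    length(oracle_scan_starts(s, "strong"))
  }, numeric(1)))
  expect_equal(nrow(hits), oracle_total)
})

test_that("duplicate protein ids are rejected", {
  proteins <- tibble::tibble(protein_id = c("A", "A"),
                             sequence = c("PPPRPAA", "PPPRPAA"))
  expect_error(scan_proteome(proteins), "Duplicate")
})

test_that("shuffle null on a homopolymer is flat with p = 1", {
  res <- shuffle_null("AAAAAAAAAA", tsh3_motif("strong"), "homo", seed = 1)
  expect_true(all(res$shuffled_counts == 0))
  expect_equal(res$empirical_p, 1.0)
  expect_equal(res$observed_count, 0L)
})

test_that("a planted motif in a P/R-free background is shuffle-significant", {
  gen <- gen_proteome(
    1, length_range = c(1000L, 1000L), composition = no_arg_comp,
    planted = tibble::tibble(protein_id = "SYN0001",
                             peptide = "SNPPPRPPA",
                             peptide_start = 400L, core_offset = 3L),
    seed = 2
  )
  res <- shuffle_null(gen$proteins$sequence[1], tsh3_motif("strong"),
                      "SYN0001", n_shuffles = 100, seed = 2)
  expect_equal(res$observed_count, 1L)
  expect_lte(res$empirical_p, 0.05)
})

test_that("empirical p follows the add-one estimator and its bounds", {
  withr::local_seed(13)
  for (i in 1:10) {
    seq <- random_aa_string(40, alphabet = c("P", "R", "A"))
    res <- shuffle_null(seq, tsh3_motif("strong"), paste0("p", i),
                        n_shuffles = 50, seed = i)
    expect_equal(
      res$empirical_p,
      (1 + sum(res$shuffled_counts >= res$observed_count)) / 51
    )
    expect_gte(res$empirical_p, 1 / 51)
    expect_lte(res$empirical_p, 1)
    # monotone non-increasing in the observed count, counts fixed
    p_at <- function(obs) (1 + sum(res$shuffled_counts >= obs)) / 51
    obs_grid <- 0:5
    expect_true(all(diff(vapply(obs_grid, p_at, numeric(1))) <= 0))
  }
})

test_that("shuffle streams are seed-stable and order-independent", {
  seqs <- c(A1 = "PPPRPAAPPPRPAAGGG", B2 = "PRPRPRPRAAAAAGGGG")
  proteins <- tibble::tibble(protein_id = names(seqs), sequence = seqs)
  r1 <- shuffle_null_proteome(proteins, tsh3_motif("strong"),
                              n_shuffles = 30, seed = 99)
  r2 <- shuffle_null_proteome(proteins[2:1, ], tsh3_motif("strong"),
                              n_shuffles = 30, seed = 99)
  expect_identical(
    dplyr::arrange(r1, protein_id),
    dplyr::arrange(r2, protein_id)
  )
  # bit-for-bit reproducibility of the shuffled counts
  s1 <- shuffle_null(seqs[1], tsh3_motif("strong"), "A1", 30, seed = 99)
  s2 <- shuffle_null(seqs[1], tsh3_motif("strong"), "A1", 30, seed = 99)
  expect_identical(s1$shuffled_counts, s2$shuffled_counts)
})

test_that("disorder filter averages the window and never passes silently", {
  hits <- scan_motifs("PPPRPAA", protein_id = "D1")
  mk_scores <- function(vals) {
    tibble::tibble(protein_id = "D1", position = seq_along(vals),
                   score = vals)
  }
  all1 <- disorder_filter(hits, mk_scores(rep(1, 7)))
  expect_equal(all1$mean_disorder_over_window, 1)
  expect_true(all1$passes_disorder)
  all0 <- disorder_filter(hits, mk_scores(rep(0, 7)))
  expect_false(all0$passes_disorder)
  alt <- disorder_filter(hits, mk_scores(rep(c(0.6, 0.4), length.out = 7)))
  expect_equal(alt$mean_disorder_over_window, 3.6 / 7, tolerance = 1e-12)
  expect_true(alt$passes_disorder)
  # no scores for the protein: explicit not-evaluable status
  other <- tibble::tibble(protein_id = "ZZ", position = 1:7, score = 1)
  ne <- disorder_filter(hits, other)
  expect_equal(ne$disorder_status, "not_evaluable")
  expect_true(is.na(ne$passes_disorder))
})

test_that("partner overlap annotates family partners and self-interactions", {
  hits <- dplyr::bind_rows(
    scan_motifs("PPPRPAA", protein_id = "X"),
    scan_motifs("PPPRPAA", protein_id = "NCF1"),
    scan_motifs("PPPRPAA", protein_id = "LONER")
  )
  pairs <- tibble::tibble(id_a = c("NCF1", "NCF1", "TKS4"),
                          id_b = c("X", "NCF1", "X"))
  fam <- c("NCF1", "NOXO1", "TKS4", "TKS5")
  ann <- overlap_partners(hits, pairs, fam)
  expect_equal(ann$partner_of[[1]], c("NCF1", "TKS4"))
  expect_true(ann$is_partner[1])
  expect_false(ann$self_interaction[1])
  expect_equal(ann$partner_of[[2]], "NCF1")
  expect_true(ann$self_interaction[2])
  expect_equal(ann$partner_of[[3]], character())
  expect_false(ann$is_partner[3])
})

test_that("partner overlap equals a nested-loop oracle on random tables", {
  withr::local_seed(21)
  ids <- sprintf("PR%02d", 1:12)
  fam <- c("FAMA", "FAMB")
  pairs <- tibble::tibble(
    id_a = sample(c(fam, ids), 30, replace = TRUE),
    id_b = sample(c(fam, ids), 30, replace = TRUE)
  )
  hits <- dplyr::bind_rows(lapply(ids, function(id) {
    scan_motifs("PPPRPAA", protein_id = id)
  }))
  ann <- overlap_partners(hits, pairs, fam)
  for (k in seq_len(nrow(ann))) {
    expected <- character()
    for (f in fam) {
      hit_id <- ann$protein_id[k]
      linked <- any((pairs$id_a == f & pairs$id_b == hit_id) |
                      (pairs$id_b == f & pairs$id_a == hit_id))
      if (linked) expected <- c(expected, f)
    }
    expect_equal(ann$partner_of[[k]], sort(expected))
  }
})

test_that("MITAB identifiers are extracted from the first two columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "uniprotkb:P14598\tuniprotkb:P13498\tmore\tcolumns",
    "uniprotkb:Q8NFA2\tintact:EBI-12345\tx\ty"
  ), path)
  tab <- read_mitab(path)
  expect_equal(tab$id_a, c("P14598", "Q8NFA2"))
  expect_equal(tab$id_b, c("P13498", "EBI-12345"))
})
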