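sh3_dom <- function(id, start, end) {
  tibble::tibble(protein_id = id, domain_class = "SH3",
                 source_id = "PF00018", start = start, end = end)
}

test_that("the linker rule is a strict 60-residue cutoff", {
  d59 <- dplyr::bind_rows(sh3_dom("p", 10L, 70L), sh3_dom("p", 130L, 190L))
  p59 <- find_tandem_pairs(d59)
  expect_equal(p59$linker_length, 59L)
  expect_true(p59$is_tandem)
  d60 <- dplyr::bind_rows(sh3_dom("p", 10L, 70L), sh3_dom("p", 131L, 191L))
  p60 <- find_tandem_pairs(d60)
  expect_equal(p60$linker_length, 60L)
  expect_false(p60$is_tandem)
})

test_that("linker net charge counts basic minus acidic residues", {
  seq <- paste0(strrep("A", 10), "DEDE", strrep("A", 10))
  doms <- dplyr::bind_rows(sh3_dom("p", 1L, 10L), sh3_dom("p", 15L, 24L))
  expect_equal(find_tandem_pairs(doms, seq)$linker_net_charge, -4L)
  seq2 <- paste0(strrep("A", 10), "KRKR", strrep("A", 10))
  expect_equal(find_tandem_pairs(doms, seq2)$linker_net_charge, 4L)
})

test_that("pair finding rejects overlaps and is translation-invariant", {
  bad <- dplyr::bind_rows(sh3_dom("p", 10L, 70L), sh3_dom("p", 60L, 120L))
  expect_error(find_tandem_pairs(bad), "Overlapping")
  doms <- dplyr::bind_rows(sh3_dom("p", 10L, 70L), sh3_dom("p", 100L, 160L))
  base <- find_tandem_pairs(doms)
  shifted <- dplyr::mutate(doms, start = start + 500L, end = end + 500L)
  moved <- find_tandem_pairs(shifted)
  expect_equal(moved$linker_length, base$linker_length)
  expect_equal(moved$is_tandem, base$is_tandem)
})

test_that("signature detection flags GWW, C-[DE][DE] and the PxxPhiL tail", {
  n_dom <- paste0(strrep("A", 20), "GWW", strrep("A", 20), "QQPEFYL")
  c_dom <- paste0(strrep("A", 10), "GWW", strrep("A", 10), "EE",
                  strrep("A", 10))
  sig <- detect_signatures(n_dom, c_dom)
  expect_true(sig$gww_n); expect_true(sig$gww_c)
  expect_true(sig$c_double_negative)
  expect_true(sig$n_pxx_phi_l); expect_true(sig$n_pxx_phi_l_relaxed)
  expect_equal(sig$gww_n_pos, 21L)
  expect_equal(sig$c_double_negative_pos, 24L)
  # the disease-associated Gly-to-Ser change removes the GWW signature
  sww <- detect_signatures(sub("GWW", "SWW", n_dom), c_dom)
  expect_false(sww$gww_n)
  expect_true(sww$gww_c)
})

test_that("the PxxPhiL tail requires an aromatic and tolerates Val only when relaxed", {
  base <- strrep("A", 30)
  # Val in the aromatic slot: neither strict nor relaxed
  v_phi <- detect_signatures(paste0(base, "PAAVL"), "GWWEE")
  expect_false(v_phi$n_pxx_phi_l)
  expect_false(v_phi$n_pxx_phi_l_relaxed)
  # Val in the final slot: relaxed only (the CIN85-style variant)
  v_last <- detect_signatures(paste0(base, "PAAYV"), "GWWEE")
  expect_false(v_last$n_pxx_phi_l)
  expect_true(v_last$n_pxx_phi_l_relaxed)
  # the strict signature implies the relaxed one
  strict <- detect_signatures(paste0(base, "PAAYL"), "GWWEE")
  expect_true(strict$n_pxx_phi_l && strict$n_pxx_phi_l_relaxed)
  # tail window: a patch before the last tail_window residues is not seen
  far <- detect_signatures(paste0("PAAYL", strrep("A", 30)), "GWWEE")
  expect_false(far$n_pxx_phi_l)
})

test_that("the screen reproduces planted architecture tiers", {
  arch <- gen_domain_architectures(default_architecture_specs(), seed = 4)
  screen <- screen_multi_sh3(arch$proteins, arch$domains)
  # tier a: all multi-SH3 proteins, not the single-domain one
  expect_setequal(
    screen$multi_sh3$protein_id,
    arch$protein_labels$protein_id[arch$protein_labels$expected_tier_a]
  )
  got <- dplyr::arrange(screen$pairs, protein_id, n_start)
  lab <- dplyr::arrange(arch$pair_labels, protein_id, pair_index)
  expect_equal(got$in_tier_b, lab$expected_tier_b)
  expect_equal(got$in_tier_c, lab$expected_tier_c)
  # only the fully signed tandem reaches tier c among two-domain proteins
  expect_true(got$in_tier_c[got$protein_id == "ARCH_TANDEM"])
  expect_false(any(got$in_tier_c[got$protein_id == "ARCH_LONGLINK"]))
  # three-domain contrast: short linker pair in tier c, long one tier b only
  triple <- got[got$protein_id == "ARCH_TRIPLE", ]
  expect_equal(triple$in_tier_b, c(TRUE, TRUE))
  expect_equal(triple$in_tier_c, c(TRUE, FALSE))
})

test_that("screen tiers equal a brute-force rule oracle on random specs", {
  withr::local_seed(55)
  n <- 30
  specs <- tibble::tibble(
    protein_id = sprintf("RND%02d", seq_len(n)),
    gww = replicate(n, sample(c(TRUE, FALSE), sample(2:4, 1),
                              replace = TRUE), simplify = FALSE),
    linkers = NA, cdd = NA, tail = NA
  )
  specs$linkers <- lapply(specs$gww, function(g) {
    sample(c(20, 59, 60, 120), length(g) - 1L, replace = TRUE)
  })
  specs$cdd <- lapply(specs$gww, function(g) {
    sample(c(TRUE, FALSE), length(g), replace = TRUE)
  })
  specs$tail <- lapply(specs$gww, function(g) {
    sample(c("strict", "relaxed", "none"), length(g), replace = TRUE)
  })
  arch <- gen_domain_architectures(specs, seed = 8)
  screen <- screen_multi_sh3(arch$proteins, arch$domains)
  # nested-loop oracle over consecutive pairs of each protein's spec
  oracle_b <- 0L; oracle_c <- 0L
  for (i in seq_len(n)) {
    g <- specs$gww[[i]]; l <- specs$linkers[[i]]
    for (k in seq_len(length(g) - 1L)) {
      if (g[k] && g[k + 1L]) {
        oracle_b <- oracle_b + 1L
        if (l[k] < 60) oracle_c <- oracle_c + 1L
      }
    }
  }
  expect_equal(sum(screen$pairs$in_tier_b), oracle_b)
  expect_equal(sum(screen$pairs$in_tier_c), oracle_c)
  # tier nesting
  expect_true(all(!screen$pairs$in_tier_c | screen$pairs$in_tier_b))
  expect_true(all(screen$pairs$protein_id %in% screen$multi_sh3$protein_id))
})

test_that("proteins missing from the proteome are skipped with a warning", {
  arch <- gen_domain_architectures(default_architecture_specs(), seed = 4)
  doms <- dplyr::bind_rows(arch$domains,
                           sh3_dom("GHOST", 1L, 60L), sh3_dom("GHOST", 80L, 140L))
  expect_warning(screen <- screen_multi_sh3(arch$proteins, doms), "GHOST")
  expect_false("GHOST" %in% screen$pairs$protein_id)
})

test_that("a supplementary domain table repairs missing annotations", {
  arch <- gen_domain_architectures(default_architecture_specs(), seed = 4)
  # drop one domain of the tandem protein, as if absent from the export
  broken <- dplyr::filter(
    arch$domains,
    !(protein_id == "ARCH_TANDEM" & start == min(start[protein_id == "ARCH_TANDEM"]))
  )
  s_broken <- screen_multi_sh3(arch$proteins, broken)
  expect_false("ARCH_TANDEM" %in% s_broken$multi_sh3$protein_id)
  repair <- dplyr::anti_join(arch$domains, broken,
                             by = c("protein_id", "start"))
  s_fixed <- screen_multi_sh3(arch$proteins, broken,
                              extra_domains = repair)
  expect_true("ARCH_TANDEM" %in% s_fixed$multi_sh3$protein_id)
  expect_true(any(s_fixed$pairs$in_tier_c[
    s_fixed$pairs$protein_id == "ARCH_TANDEM"
  ]))
})

test_that("domain TSV reader enforces required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sh3_dom("p", 1L, 60L), path)
  tab <- read_domain_tsv(path)
  expect_equal(tab$start, 1L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tstart", "p\t1"), bad)
  expect_error(read_domain_tsv(bad), "missing column")
})
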