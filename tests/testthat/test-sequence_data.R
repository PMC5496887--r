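test_that("extract_windows takes the lysine-centered L-mer and drops overhanging sites", {
  prot <- toy_proteome()

  # Window spanning exactly the whole 21-aa protein.
  s1 <- extract_windows(prot, toy_sites("P1", 11), L = 21)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$window, unname(prot["P1"]))
  expect_equal(attr(s1, "dropped"), 0L)

  # K at position 5 of a 21-aa protein: full 21-mer does not fit.
  expect_message(
    s2 <- extract_windows(prot, toy_sites("P2", 5), L = 21),
    "dropped")
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "dropped"), 1L)

  # Three internal lysines, each >= 10 residues from both termini.
  seq3 <- random_protein(80, k_at = c(20, 40, 60), seed = 3)
  s3 <- extract_windows(c(Q1 = seq3), toy_sites("Q1", c(20, 40, 60)), L = 21)
  expect_equal(nrow(s3), 3)
  expect_equal(nchar(s3$window), rep(21, 3))
  expect_equal(substring(s3$window, 11, 11), rep("K", 3))
})

test_that("extract_windows round-trips against the source proteome", {
  fx <- generate_fixture(small_config(seed = 8))
  ws <- extract_windows(fx$proteome, fx$positives, L = 21)
  flank <- 10
  again <- substring(fx$proteome[ws$protein_id], ws$position - flank,
                     ws$position + flank)
  expect_equal(unname(again), ws$window)
})

test_that("extract_windows validates ids, residues, and duplicates", {
  prot <- toy_proteome()
  expect_error(extract_windows(prot, toy_sites("NOPE", 11), L = 21),
               "NOPE")
  expect_error(extract_windows(prot, toy_sites("P1", 10), L = 21),
               "not lysine")
  expect_warning(
    s <- extract_windows(prot, toy_sites(c("P1", "P1"), c(11, 11)), L = 21),
    "duplicate")
  expect_equal(nrow(s), 1)
  expect_error(extract_windows(prot, toy_sites("P1", 11), L = 20),
               "odd")
})

test_that("pad_char keeps overhanging sites with padded windows", {
  prot <- toy_proteome()
  s <- extract_windows(prot, toy_sites("P4", 1), L = 21, pad_char = "X")
  expect_equal(nrow(s), 1)
  expect_equal(s$window, paste0(strrep("X", 10), substring(prot["P4"], 1, 11)))
})

test_that("build_background enumerates full-window lysines outside excluded proteins", {
  prot <- toy_proteome()
  # P4 = "KAAAAAAAAAAKAAAAAAAAAK" (22 aa): only the K at 12 has full flanks.
  bg <- build_background(prot["P4"], L = 21)
  expect_equal(bg$position, 12L)
  expect_equal(bg$label, "unlabeled")

  # Excluding a protein removes all of its sites.
  bg2 <- build_background(prot, excluded_proteins = "P4", L = 11)
  expect_false("P4" %in% bg2$protein_id)
  # Hand count at L=11 (flank 5): P1 has K11 in 21 aa -> fits; P2 has K5
  # (no: 5-5<1) and K12 in 22 aa -> fits; P3 none.
  expect_equal(bg2$protein_id, c("P1", "P2"))
  expect_equal(bg2$position, c(11L, 12L))

  # Deterministic order: protein id then position.
  bg3 <- build_background(prot, L = 11)
  expect_equal(order(bg3$protein_id, bg3$position), seq_len(nrow(bg3)))

  expect_error(build_background(prot["P3"], L = 11), "empty")
})

test_that("filter_redundancy keeps the first of any pair above the identity threshold", {
  w <- strrep("A", 10)
  base <- paste0(w, "K", w)                       # 21-mer
  mutate_at <- function(x, pos, ch) {
    for (p in pos) substr(x, p, p) <- ch
    x
  }
  # Two identical windows -> one kept.
  s <- windows_site_set(c(base, base))
  expect_equal(nrow(filter_redundancy(s)), 1)

  # Differing at 7 positions: identity 14/21 = 0.667 <= 0.70 -> both kept.
  w7 <- mutate_at(base, c(1:4, 15:17), "C")
  expect_equal(nrow(filter_redundancy(windows_site_set(c(base, w7)))), 2)

  # Differing at 6 positions: identity 15/21 = 0.714 > 0.70 -> one kept,
  # and the first in input order survives.
  w6 <- mutate_at(base, c(1:3, 15:17), "C")
  kept <- filter_redundancy(windows_site_set(c(base, w6)))
  expect_equal(kept$window, base)
})

test_that("filter_redundancy output has no pair above the threshold", {
  fx <- generate_fixture(small_config(seed = 4))
  ws <- extract_windows(fx$proteome, fx$positives, L = 21)
  out <- filter_redundancy(ws, 0.70)
  mat <- do.call(rbind, strsplit(out$window, ""))
  n <- nrow(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_lte(mean(mat[i, ] == mat[j, ]), 0.70)
    }
  }
})

test_that("position_frequency reports per-position residue fractions", {
  base <- paste0(strrep("A", 10), "K", strrep("A", 10))
  w2 <- paste0("C", strrep("A", 9), "K", strrep("A", 10))

  # All windows identical: every occupied cell is 1.
  f1 <- position_frequency(windows_site_set(c(base, base)))
  expect_equal(unname(f1["A", "-10"]), 1)
  expect_equal(unname(f1["K", "0"]), 1)
  expect_true(all(colSums(f1) == 1))

  # A/C split at offset -10 gives 0.5 each.
  f2 <- position_frequency(windows_site_set(c(base, w2)))
  expect_equal(unname(f2["A", "-10"]), 0.5)
  expect_equal(unname(f2["C", "-10"]), 0.5)

  # Ambiguity codes are excluded from numerator and denominator.
  wx <- paste0("X", strrep("A", 9), "K", strrep("A", 10))
  f3 <- position_frequency(windows_site_set(c(base, wx)))
  expect_equal(unname(f3["A", "-10"]), 1)

  expect_error(position_frequency(windows_site_set(character(0), L = 21)))
})

test_that("proteome and site-set I/O round-trip through files", {
  dir <- withr::local_tempdir()
  prot <- toy_proteome()
  fa <- file.path(dir, "p.fasta")
  write_proteome(prot, fa)
  expect_equal(read_proteome(fa), prot)

  s <- extract_windows(prot, toy_sites(c("P1", "P2"), c(11, 12)), L = 11)
  tsv <- file.path(dir, "s.tsv")
  write_site_set(s, tsv)
  s2 <- read_site_set(tsv)
  expect_equal(as.data.frame(s2), as.data.frame(s), ignore_attr = TRUE)
  expect_equal(site_length(s2), 11L)
})
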