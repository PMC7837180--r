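test_that("the packaged matrix parses, is symmetric, and matches the field standard", {
  B <- blosum62()
  expect_true(all(B == t(B)))
  expect_equal(B["W", "W"], 11L)
  expect_equal(B["M", "M"], 5L)
  # 20-residue block agrees with an independent distribution of BLOSUM62
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_true(all(B[aa, aa] == BLOSUM62[aa, aa]))
})

test_that("local alignment scores match hand-derived values", {
  expect_equal(smith_waterman_score("MKV", "MKV"), 14)   # 5 + 5 + 4
  expect_equal(smith_waterman_score("AAAA", "WWWW"), 0)  # local floor
  # single W-W pair (11) beats aligning MK (10) plus a costly gap
  expect_equal(smith_waterman_score("MKVW", "MKW"), 11)
  expect_error(smith_waterman_score("", "MKV"))
})

test_that("local alignment equals the exhaustive enumeration oracle", {
  B <- blosum62()
  sch <- scoring_scheme()
  alpha <- c("A", "R", "N", "D")
  seqs <- unlist(lapply(1:2, function(L)
    apply(expand.grid(rep(list(alpha), L)), 1, paste, collapse = "")))
  for (a in seqs) for (b in seqs)
    expect_equal(smith_waterman_score(a, b, sch),
                 brute_local_affine(a, b, B, 11, 1))
  set.seed(71)
  for (i in 1:15) {
    a <- random_protein(sample(3:4, 1), alpha)
    b <- random_protein(sample(3:4, 1), alpha)
    expect_equal(smith_waterman_score(a, b, sch),
                 brute_local_affine(a, b, B, 11, 1))
  }
})

test_that("local alignment score is symmetric in its arguments", {
  set.seed(72)
  for (i in 1:25) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    expect_equal(smith_waterman_score(a, b), smith_waterman_score(b, a))
  }
})

test_that("E-values follow the Karlin-Altschul formula and decrease in score", {
  expect_equal(evalue(0, 100, 100), 410)
  expect_equal(evalue(40, 100, 100), 0.041 * 1e4 * exp(-0.267 * 40),
               tolerance = 1e-12)
  expect_equal(evalue(40, 100, 100), 9.43e-3, tolerance = 1e-3)
  e <- evalue(0:100, 50, 80)
  expect_true(all(diff(e) < 0))
})

test_that("best_hit picks the top-scoring subject under the cutoff", {
  target <- toy_proteome("T", c(p1 = "MKVLMKVLMKVLMKVLMKVL",
                                p2 = "WWWWHHHHWWWWHHHHWWWW",
                                p3 = "ACDEFGHIKLMNPQRSTVWY"))
  h <- best_hit("MKVLMKVLMKVLMKVLMKVL", "q", target)
  expect_equal(h$subject_id, "p1")
  expect_true(h$evalue <= 1e-5)
  # nothing passes an absurdly strict cutoff
  expect_null(best_hit("MKVLMKVLMKVLMKVLMKVL", "q", target,
                       e_cutoff = 1e-300))
  # equal scores resolve to the lexicographically smaller subject id
  twin <- toy_proteome("T", c(pB = "MKVLMKVLMKVLMKVLMKVL",
                              pA = "MKVLMKVLMKVLMKVLMKVL"))
  expect_equal(best_hit("MKVLMKVLMKVLMKVLMKVL", "q", twin)$subject_id, "pA")
})

test_that("self-comparison yields the identity RBH mapping", {
  set.seed(73)
  seqs <- setNames(vapply(1:5, function(i) random_protein(40), ""),
                   paste0("p", 1:5))
  p <- toy_proteome("A", seqs)
  q <- toy_proteome("B", seqs)
  m <- reciprocal_best_hits(p, q)
  expect_equal(sort(names(m)), sort(names(seqs)))
  expect_true(all(m == names(m)))
})

test_that("non-reciprocal best hits are excluded", {
  set.seed(74)
  x <- random_protein(30)
  # r2 is identical to s; r1 is a corrupted copy whose best hit is still s,
  # but s's best hit is r2, so r1 gains no partner
  r1 <- paste0(substr(x, 1, 24), "WWWWWW")
  ref <- toy_proteome("R", c(r1 = r1, r2 = x))
  oth <- toy_proteome("O", c(s = x))
  m <- reciprocal_best_hits(ref, oth)
  expect_equal(m, c(r2 = "s"))
})

test_that("RBH mappings are one-to-one on simulated proteomes", {
  sim <- simulate_proteomes(sim_config(n_taxa = 4, n_core_genes = 8,
                                       gene_length = 60, n_decoy_genes = 3,
                                       seed = 5))
  m <- reciprocal_best_hits(sim$proteomes[[1]], sim$proteomes[[2]])
  expect_false(anyDuplicated(m) > 0)
  expect_false(anyDuplicated(names(m)) > 0)
})

test_that("core groups require a partner in every proteome", {
  set.seed(75)
  seqs <- setNames(vapply(1:3, function(i) random_protein(40), ""),
                   paste0("r", 1:3))
  ref <- toy_proteome("R", seqs)
  full <- toy_proteome("A", setNames(seqs, paste0("a", 1:3)))
  partial <- toy_proteome("B", setNames(seqs[c(1, 3)], c("b1", "b3")))
  groups <- extract_core_groups(ref, list(full, partial))
  expect_equal(vapply(groups, `[[`, "", "reference_protein_id"),
               c("r1", "r3"))
  expect_equal(groups[[1]]$members,
               c(A = "a1", B = "b1", R = "r1"))
  # against a copy of itself every protein forms a group
  groups2 <- extract_core_groups(ref, list(toy_proteome("C", seqs)))
  expect_length(groups2, 3L)
})

test_that("raising the E-value cutoff never removes a group", {
  sim <- simulate_proteomes(sim_config(n_taxa = 4, n_core_genes = 6,
                                       gene_length = 50, n_decoy_genes = 2,
                                       seed = 6))
  ref <- sim$proteomes[[1]]
  others <- sim$proteomes[-1]
  ids <- function(gr) vapply(gr, `[[`, "", "reference_protein_id")
  strict <- ids(extract_core_groups(ref, others, e_cutoff = 1e-12))
  loose <- ids(extract_core_groups(ref, others, e_cutoff = 1e-2))
  expect_true(all(strict %in% loose))
})

test_that("simulated decoy genes never enter core groups", {
  sim <- simulate_proteomes(sim_config(n_taxa = 5, n_core_genes = 10,
                                       gene_length = 60, n_decoy_genes = 3,
                                       seed = 8))
  ref <- sim$proteomes[[1]]
  groups <- extract_core_groups(ref, sim$proteomes[-1])
  expect_length(groups, 10L)
  truth <- sim$truth$ortholog_map
  for (g in groups) {
    gene <- truth$gene[truth$strain_id == ref$strain_id &
                       truth$protein_id == g$reference_protein_id]
    expect_length(gene, 1L)
    for (s in names(g$members))
      expect_equal(g$members[[s]],
                   truth$protein_id[truth$strain_id == s &
                                    truth$gene == gene])
  }
})
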