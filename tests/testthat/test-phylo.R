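test_that("p-distance uses pairwise deletion over masked columns", {
  expect_equal(p_distance("MMMM", "MMMM"), 0)
  expect_equal(p_distance("MMMM", "MMMK"), 0.25)
  expect_equal(p_distance("M-MM", "MKMA"), 1 / 3)
  expect_equal(p_distance("MXMM", "MKMA"), 1 / 3)
  expect_equal(p_distance("MMMM", "MMKK", mask = c(TRUE, TRUE, FALSE, FALSE)),
               0)
  expect_error(p_distance("--", "MK"), "comparable")
  expect_error(p_distance("MK", "MKV"), "length")
})

test_that("the Kimura protein correction matches its closed form", {
  expect_equal(kimura_correct(0), 0)
  expect_equal(kimura_correct(0.2), -log(1 - 0.2 - 0.2 * 0.04))
  expect_equal(kimura_correct(0.2), 0.23319, tolerance = 1e-4)
  expect_warning(d <- kimura_correct(0.86), "capped")
  expect_equal(d, 10)
  # strictly increasing and never below p on its domain
  p <- seq(0, 0.85, by = 0.005)
  d <- kimura_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("hand-counted distances populate the matrix symmetrically", {
  sa <- toy_super(c(A = "MMMMMMMMMM", B = "MMMMMMMMKK", C = "MMMMMKKKKK"))
  D <- distance_matrix(sa)
  expect_equal(D["A", "B"], kimura_correct(0.2))
  expect_equal(D["A", "C"], kimura_correct(0.5))
  expect_equal(D["B", "C"], kimura_correct(0.3))
  expect_equal(D, t(D))
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
})

test_that("three-taxon NJ solves the closed-form star", {
  taxa <- c("A", "B", "C")
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(taxa, taxa))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers the additive four-taxon tree exactly", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(robinson_foulds(tr, truth), 0L)
  expect_equal(ape::cophenetic.phylo(tr)[taxa, taxa], D, tolerance = 1e-9)
  # independent implementation agrees on the topology
  expect_equal(robinson_foulds(tr, ape::nj(D)), 0L)
})

test_that("NJ is exact on path-length matrices of random trees", {
  for (seed in 1:10) {
    n <- 4 + (seed %% 9)
    tr <- sample_tree(n, 0.5, seed = 100 + seed)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(robinson_foulds(est, tr), 0L)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                        D)), 1e-9)
  }
})

test_that("NJ validates its input matrix", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(D))
  D3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
  D3[1, 2] <- D3[2, 1] <- Inf
  expect_error(neighbor_joining(D3), "finite")
})

test_that("Robinson-Foulds counts symmetric split differences", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
  expect_equal(robinson_foulds(t1, t1), 0L)
  expect_equal(robinson_foulds(t1, t2), 2L)
  t3 <- ape::read.tree(text = "(D:1,C:1,(B:1,A:1):1);")
  expect_equal(robinson_foulds(t1, t3), 0L)
  bad <- ape::read.tree(text = "((A:1,B:1):1,C:1,E:1);")
  expect_error(robinson_foulds(t1, bad), "leaf")
})

test_that("Robinson-Foulds agrees with an independent implementation", {
  for (seed in 1:8) {
    t1 <- ape::unroot(sample_tree(10, 0.5, seed = 200 + seed))
    t2 <- ape::unroot(sample_tree(10, 0.5, seed = 300 + seed))
    expect_equal(robinson_foulds(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("bootstrap supports are reproducible percentages on [0, 100]", {
  sim <- simulate_proteomes(sim_config(n_taxa = 6, n_core_genes = 4,
                                       gene_length = 80, n_decoy_genes = 0,
                                       seed = 21))
  aln <- lapply(seq_len(4), function(g) {
    rows <- vapply(sort(names(sim$proteomes)), function(s) {
      p <- sim$proteomes[[s]]
      tm <- sim$truth$ortholog_map
      pid <- tm$protein_id[tm$strain_id == s & tm$gene == sprintf("g%03d", g)]
      p$records$residues[p$records$ids == pid]
    }, "")
    new_alignment(names(rows), unname(rows))
  })
  names(aln) <- sprintf("g%03d", 1:4)
  sa <- concatenate(aln)
  tr <- neighbor_joining(distance_matrix(sa))
  b1 <- bootstrap_support(sa, tr, replicates = 30, seed = 5)
  b2 <- bootstrap_support(sa, tr, replicates = 30, seed = 5)
  expect_identical(write_newick(b1), write_newick(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # one replicate: support is all-or-nothing
  b3 <- bootstrap_support(sa, tr, replicates = 1, seed = 9)
  s3 <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("unanimous signal earns 100 percent support", {
  # every informative column supports the same AB|CD split
  rows <- c(A = strrep("K", 30), B = strrep("K", 30),
            C = paste0(strrep("K", 15), strrep("D", 15)),
            D = paste0(strrep("K", 15), strrep("D", 15)))
  sa <- toy_super(rows)
  tr <- neighbor_joining(distance_matrix(sa))
  b <- bootstrap_support(sa, tr, replicates = 50, seed = 3)
  sup <- suppressWarnings(as.numeric(b$node.label))
  expect_equal(sup[!is.na(sup)], 100)
})

test_that("bootstrap refuses fewer than four taxa", {
  sa <- toy_super(c(A = "MKVLM", B = "MKVAM", C = "MAVAM"))
  tr <- neighbor_joining(distance_matrix(sa))
  expect_error(bootstrap_support(sa, tr, replicates = 5, seed = 1),
               "4 taxa")
})

test_that("PHYLIP distance export is square and parseable", {
  sa <- toy_super(c(A = "MMMMMMMMMM", B = "MMMMMMMMKK", C = "MMMMMKKKKK"))
  D <- distance_matrix(sa)
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(D, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
})
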