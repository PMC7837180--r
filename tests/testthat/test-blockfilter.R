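# the published default parameters for N sequences:
# IS = floor(N/2)+1, FS = ceil(0.85 N), CP = 8, BL = 10, no gaps

test_that("default parameter arithmetic pins the rounding direction", {
  p <- block_filter_params(10)
  expect_equal(p$min_conserved, 6L)   # floor(10/2) + 1
  expect_equal(p$min_flank, 9L)       # ceil(8.5)
  expect_equal(p$max_contig_nonconserved, 8L)
  expect_equal(p$min_block_length, 10L)
  p <- block_filter_params(147)
  expect_equal(p$min_conserved, 74L)
  expect_equal(p$min_flank, 125L)
  expect_error(block_filter_params(10, min_conserved = 5))
  expect_error(block_filter_params(10, min_block_length = 1))
})

test_that("columns classify by gap presence and majority-residue count", {
  p <- block_filter_params(10)
  rows <- vapply(1:10, function(i) {
    paste0(
      if (i <= 6) "M" else c("A", "C", "D", "E")[i - 6],  # 6 identical
      if (i <= 9) "W" else "A",                           # 9 identical
      if (i == 1) "-" else "K",                           # one gap
      if (i <= 5) "H" else c("A", "C", "D", "E", "F")[i - 5])  # 5 identical
  }, "")
  sa <- toy_super(setNames(rows, paste0("S", 1:10)))
  expect_equal(classify_columns(sa, p),
               c("conserved", "highly_conserved", "gap", "nonconserved"))
})

test_that("X counts as its own residue and cannot look conserved", {
  p <- block_filter_params(4, min_block_length = 2)
  sa <- toy_super(setNames(c("MX", "MX", "MX", "KX"), paste0("S", 1:4)))
  cls <- classify_columns(sa, p)
  expect_equal(cls[1], "conserved")          # 3 of 4 M, below FS = 4
  # col2 is four X's: c = 4 >= FS, so formally highly conserved by count;
  # realistic data never reaches IS on X, which is why this is permissible
  expect_equal(cls[2], "highly_conserved")
})

test_that("the 40-column toy retains exactly its hand-derived blocks", {
  status <- c(rep("highly_conserved", 10), rep("nonconserved", 9),
              rep("highly_conserved", 10), "gap", "nonconserved",
              rep("highly_conserved", 9))
  p <- block_filter_params(10)
  blocks <- select_blocks(status, p)
  # hand application: gap col 29 (0-based) and its adjacent nonconserved
  # col 30 go; the 9-long nonconserved run 10..18 exceeds CP = 8 and goes;
  # survivors [0,10) and [19,29) pass BL = 10; trailing [31,40) is 9 < BL
  expect_equal(blocks$start, c(0L, 19L))
  expect_equal(blocks$end, c(10L, 29L))
  mask <- attr(blocks, "mask")
  expect_equal(sum(mask), 20L)
  expect_equal(which(mask), c(1:10, 20:29))
})

test_that("edge cases: all highly conserved, all nonconserved", {
  p <- block_filter_params(10)
  b <- select_blocks(rep("highly_conserved", 25), p)
  expect_equal(b$start, 0L)
  expect_equal(b$end, 25L)
  b <- select_blocks(rep("nonconserved", 25), p)
  expect_equal(nrow(b), 0L)
  expect_false(any(attr(b, "mask")))
})

test_that("block selection invariants hold on random status strings", {
  p <- block_filter_params(10)
  set.seed(61)
  for (i in 1:300) {
    status <- random_status(sample(30:120, 1))
    blocks <- select_blocks(status, p)
    mask <- attr(blocks, "mask")
    if (nrow(blocks) == 0) next
    for (k in seq_len(nrow(blocks))) {
      idx <- (blocks$start[k] + 1):blocks$end[k]
      expect_false(any(status[idx] == "gap"))
      expect_equal(status[idx[1]], "highly_conserved")
      expect_equal(status[idx[length(idx)]], "highly_conserved")
      expect_gte(length(idx), p$min_block_length)
      runs <- rle(status[idx] == "nonconserved")
      expect_true(all(runs$lengths[runs$values] <=
                        p$max_contig_nonconserved))
    }
    # monotonicity: a larger BL never grows the retained set
    stricter <- select_blocks(status, block_filter_params(
      10, min_block_length = p$min_block_length + 5))
    expect_true(all(which(attr(stricter, "mask")) %in% which(mask)))
  }
})

test_that("apply_block_filter writes the mask into the super-alignment", {
  set.seed(62)
  base <- random_protein(60)
  # rows 6..10 get private residues in columns 21..29: a 9-column
  # nonconserved stretch (majority count 5 < IS = 6) exceeding CP = 8
  rows <- vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[21:29] <- if (i > 5) c("A", "C", "D", "E", "F")[i - 5] else "M"
    paste(ch, collapse = "")
  }, "")
  sa <- toy_super(setNames(rows, paste0("S", 1:10)))
  sa <- apply_block_filter(sa)
  blocks <- attr(sa, "blocks")
  expect_equal(sum(sa$mask), sum(blocks$end - blocks$start))
  expect_false(any(sa$mask[21:29]))
  expect_true(all(sa$mask[c(1:20, 30:60)]))
})
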