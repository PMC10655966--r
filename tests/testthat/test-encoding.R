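test_that("the 3-leaf caterpillar encodes to the known F/W/R matrices", {
  # leaves 1,2 coalesce at t1 = 1; root joins leaf 3 at t2 = 3
  cat3 <- function(derived) genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                                      node_time = c(0, 0, 0, 1, 3),
                                      derived_leaves = derived)
  enc <- encode_genealogy(cat3(3L))  # mutation on the long external branch
  expect_identical(enc$F, rbind(c(2L, 0L), c(1L, 3L)))
  expect_equal(enc$W, rbind(c(2, 0), c(3, 1)))
  expect_identical(enc$R, rbind(c(1L, 0L), c(1L, 1L)))
  # mutation on the stem of the (1,2) cherry: values frozen from the
  # brute-force branch-lifespan oracle
  enc2 <- encode_genealogy(cat3(c(1L, 2L)))
  expect_identical(enc2$R, oracle_encode(cat3(c(1L, 2L)))$R)
  expect_identical(enc2$R, rbind(c(1L, 0L), c(0L, 2L)))
})

test_that("the 2-leaf tree is forced by the definitions", {
  g <- genealogy(parent = c(3L, 3L, NA), node_time = c(0, 0, 2.5),
                 derived_leaves = 1L)
  enc <- encode_genealogy(g)
  expect_identical(enc$F, matrix(2L))
  expect_equal(enc$W, matrix(2.5))
  expect_identical(enc$R, matrix(1L))
})

test_that("encoding agrees with the brute-force oracle on random trees", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:40, 1L)
    g <- with_random_focal(rand_tree(n))
    enc <- encode_genealogy(g)
    orc <- oracle_encode(g)
    expect_identical(enc$F, orc$F)
    expect_identical(enc$R, orc$R)
    expect_equal(enc$W, orc$W)
  }
})

test_that("encoding invariants hold on random simulated genealogies", {
  set.seed(202)
  for (rep in 1:120) {
    n <- sample(2:64, 1L)
    g <- with_random_focal(rand_tree(n))
    enc <- encode_genealogy(g)
    expect_true(check_encoding_invariants(enc))
    # TMRCA and all coalescent times are recoverable from the W diagonal
    expect_equal(sum(diag(enc$W)), tmrca(g))
    expect_equal(cumsum(rev(diag(enc$W))), coalescent_times(g))
  }
})

test_that("a 128-taxon genealogy yields three stacked 127 x 127 channels", {
  set.seed(7)
  g <- with_random_focal(rand_tree(128L))
  te <- encoding_tensor(encode_genealogy(g))
  expect_identical(dim(te), c(127L, 127L, 3L))
  for (ch in 1:3) {
    expect_true(all(te[, , ch][upper.tri(te[, , ch])] == 0))
  }
})

test_that("branch_span_count matches exhaustive checks on the caterpillar", {
  g <- genealogy(parent = c(4L, 4L, 5L, 5L, NA), node_time = c(0, 0, 0, 1, 3),
                 derived_leaves = 3L)
  expect_identical(branch_span_count(g, 0, 0), 3L)          # all leaf branches
  expect_identical(branch_span_count(g, 0, 3), 1L)          # only leaf 3 spans
  expect_identical(branch_span_count(g, 0, 3, derived_only = TRUE), 1L)
  expect_identical(branch_span_count(g, 1, 3), 2L)
  expect_error(branch_span_count(g, -1, 2), "domain error")
  expect_error(branch_span_count(g, 0, 4), "domain error")
})

test_that("encode/decode is the identity over all ranked shapes up to n = 6", {
  for (n in 2:6) {
    shapes <- ranked_tree_shapes(n)
    keys <- vapply(shapes, function(s) s$key, character(1))
    Fs <- lapply(shapes, function(s) s$F)
    # bijectivity: distinct shapes have distinct F matrices
    expect_identical(anyDuplicated(lapply(Fs, as.vector)), 0L)
    for (s in shapes) {
      expect_identical(decode_F(s$F)$key, s$key)
    }
    # decode o encode on fresh random trees of the same size
    set.seed(n)
    for (r in 1:5) {
      g <- rand_tree(n)
      expect_identical(decode_F(encode_genealogy(g, "F")$F)$key,
                       popdann:::ranked_shape_key(g))
    }
  }
})

test_that("decode_F rejects invalid encodings", {
  expect_error(decode_F(matrix(c(3L, 0L, 1L, 3L), 2, 2, byrow = TRUE)),
               "invalid-encoding")
  # valid diagonal but impossible off-diagonal entry
  bad <- rbind(c(2L, 0L), c(2L, 3L))
  expect_error(decode_F(bad), "invalid-encoding|no ranked tree shape")
})

test_that("structural and encoding errors are reported", {
  # non-binary: node 5 with 3 children
  expect_error(genealogy(parent = c(5L, 5L, 5L, 5L, NA, NA, NA),
                         node_time = c(0, 0, 0, 0, 1, 2, 3)),
               "structural error")
  # non-ultrametric leaf
  expect_error(genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                         node_time = c(0, 0.5, 0, 1, 3)),
               "structural error")
  # derived set not a clade
  expect_error(genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                         node_time = c(0, 0, 0, 1, 3),
                         derived_leaves = c(1L, 3L)),
               "encoding error.*2")
  # derived set must be proper and non-empty
  expect_error(genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                         node_time = c(0, 0, 0, 1, 3),
                         derived_leaves = 1:3),
               "proper")
})

test_that("tied coalescent times are resolved deterministically", {
  g <- genealogy(parent = c(5L, 5L, 6L, 7L, 6L, 7L, NA),
                 node_time = c(0, 0, 0, 0, 1, 1, 2))
  expect_true(all(diff(coalescent_times(g)) > 0))
  expect_silent(check_encoding_invariants(encode_genealogy(g, c("F", "W"))))
})
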