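test_that("p-distance uses pairwise deletion", {
  expect_equal(as.numeric(p_distance("AAAA", "AAAA")), 0)
  expect_equal(as.numeric(p_distance("AAAA", "AAAT")), 0.25)
  p <- p_distance("AA-A", "AATA")
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "n_sites"), 3)
  expect_error(p_distance("A-A", "T-G"), NA)
  expect_error(p_distance("--", "AA"), "zero comparable")
  expect_error(p_distance("AAA", "AA"), "unequal")
})

test_that("JC correction matches closed-form hand values", {
  expect_equal(as.numeric(jc_distance(0, 20)), 0)
  expect_equal(as.numeric(jc_distance(0.1, 20)),
               -0.95 * log(1 - 0.1 / 0.95))          # 0.105664
  expect_equal(as.numeric(jc_distance(0.3, 4)), -0.75 * log(0.6))
  expect_equal(round(as.numeric(jc_distance(0.1, 20)), 5), 0.10566)
})

test_that("JC is increasing, asymptotically linear, and caps at saturation", {
  p <- seq(0, 0.7, by = 0.05)
  d <- as.numeric(jc_distance(p, 4, cap = 5))
  expect_true(all(diff(d[p < 0.75]) > 0))
  expect_lt(abs(as.numeric(jc_distance(1e-4, 4)) / 1e-4 - 1), 0.01)
  sat <- jc_distance(c(0.2, 0.8), 4, cap = 5)
  expect_equal(as.numeric(sat)[2], 5)
  expect_equal(attr(sat, "saturated"), c(FALSE, TRUE))
  expect_equal(attr(jc_distance(0.95, 20), "saturated"), TRUE)
})

test_that("NJ solves the 3-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("NJ reconstructs the additive 4-taxon worked example exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d)
  expect_equal(splits_of_phylo(tr), "A|B")        # topology AB|CD
  bl <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[LETTERS[1:4]]), c(1, 2, 3, 4))
  internal <- tr$edge.length[!tr$edge[, 2] %in% 1:4]
  expect_equal(internal, 1)
})

test_that("NJ rejects malformed matrices and resolves equidistant stars", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(LETTERS[1:4], LETTERS[1:4])
  tr <- neighbor_joining(d)
  internal <- tr$edge.length[!tr$edge[, 2] %in% 1:4]
  expect_equal(internal, 0)
  bad <- d; bad[1, 2] <- 3
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "negative")
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ is exact on random additive matrices (ground-truth trees)", {
  for (s in 1:15) {
    n <- sample(4:8, 1)
    ra <- random_additive(n, seed = 1000 + s)
    tr <- neighbor_joining(ra$d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
    expect_equal(splits_of_phylo(tr), splits_of_phylo(ra$tree))
  }
})

test_that("NJ agrees with the exhaustive least-squares topology oracle", {
  for (s in 1:8) {
    n <- sample(5:6, 1)
    ra <- random_additive(n, seed = 2000 + s)
    oracle <- ls_best_tree(ra$d)
    expect_lt(oracle$rss, 1e-12)        # additive: true topology fits exactly
    expect_equal(splits_of_phylo(neighbor_joining(ra$d)), oracle$splits)
  }
})

test_that("NJ matches the reference implementation on noisy matrices", {
  # non-additive input: compare against ape::nj as an independent check
  for (s in 1:5) {
    ra <- random_additive(6, seed = 3000 + s)
    set.seed(s)
    noise <- matrix(runif(36, 0, 0.02), 6, 6)
    d <- ra$d + (noise + t(noise)) / 2
    diag(d) <- 0
    ours <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(splits_of_phylo(ours), splits_of_phylo(ref))
    expect_equal(sort(ours$edge.length[ours$edge.length > 1e-6]),
                 sort(ref$edge.length[ref$edge.length > 1e-6]),
                 tolerance = 1e-6)
  }
})

test_that("perfect-signal bipartitions get full bootstrap support", {
  aln <- rbind(A = rep(c("A", "C"), 25), B = rep(c("A", "C"), 25),
               C = rep(c("G", "T"), 25), D = rep(c("G", "T"), 25))
  bt <- bootstrap_support(aln, n_reps = 50, seed = 1, alphabet_size = 4)
  supp <- suppressWarnings(as.integer(bt$node.label))
  expect_true(all(supp[-1] == 50, na.rm = TRUE))
  bt1 <- bootstrap_support(aln, n_reps = 1, seed = 2, alphabet_size = 4)
  s1 <- suppressWarnings(as.integer(bt1$node.label))
  expect_true(all(s1[-1] %in% c(0, 1)))
})

test_that("bootstrap recovers all bipartitions of a well-resolved tree", {
  tr <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3,(E:0.1,F:0.1):0.3);")
  aln <- evolve_alignment(tr, 2000, "protein", seed = 7)
  bt <- bootstrap_support(aln, n_reps = 100, seed = 11)
  expect_equal(splits_of_phylo(bt), splits_of_phylo(tr))
  supp <- suppressWarnings(as.integer(bt$node.label))
  expect_true(all(supp[-1] >= 95, na.rm = TRUE))
  # determinism
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 11)
  expect_identical(bt$node.label, bt2$node.label)
})

test_that("Newick serialization round-trips topology, lengths, supports", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(neighbor_joining(d))
  expect_true(grepl("^\\(", txt) && grepl(";$", txt))
  back <- read_newick(txt)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  set.seed(4)
  tr <- ape::rtree(10)
  tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1)))
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back2 <- read_newick(path = f)
  expect_equal(splits_of_phylo(back2), splits_of_phylo(tr))
  expect_equal(sort(back2$edge.length), sort(tr$edge.length),
               tolerance = 1e-5)
  expect_identical(back2$node.label, tr$node.label)
  expect_error(read_newick("((A,B);"))      # unbalanced parentheses
})

test_that("distances from simulated alignments recover branch lengths", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.25,C:0.05);")
  aln <- evolve_alignment(tr, 10000, "nucleotide", seed = 17)
  dm <- jc_distance_matrix(aln, alphabet_size = 4)
  p <- as.numeric(p_distance(aln["A", ], aln["B", ]))
  se <- sqrt(p * (1 - p) / 10000) / abs(1 - (4 / 3) * p)
  expect_lt(abs(dm$d["A", "B"] - 0.4), 3 * se)
  expect_true(!any(dm$saturated))
  f <- tempfile()
  write_phylip_dist(dm, f)
  expect_equal(as.integer(trimws(readLines(f)[1])), 3)
})
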