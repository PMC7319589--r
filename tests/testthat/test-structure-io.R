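test_that("PDB write/read round-trip is lossless for retained fields", {
  cx <- fix_complex()
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, tmp)
  cx2 <- read_pdb(tmp, "H", "A")
  expect_equal(nrow(cx2), nrow(cx))
  expect_identical(cx2$chain, cx$chain)
  expect_identical(cx2$resno, cx$resno)
  expect_identical(cx2$icode, cx$icode)
  expect_identical(cx2$resname, cx$resname)
  expect_identical(cx2$atom, cx$atom)
  expect_lt(max(abs(cbind(cx$x, cx$y, cx$z) - cbind(cx2$x, cx2$y, cx2$z))), 1e-3)
})

test_that("altloc resolution keeps the highest-occupancy record", {
  lines <- c(
    "ATOM      1  N   ALA H   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA H   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA H   1       9.458   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA H   1       2.005  -1.091   0.915  1.00  0.00           C",
    "ATOM      5  O   ALA H   1       1.528  -2.225   0.888  1.00  0.00           O",
    "ATOM      6  N   GLY A   1       0.000   4.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   1       1.458   4.000   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   1       2.005   2.909   0.915  1.00  0.00           C",
    "ATOM      9  O   GLY A   1       1.528   1.775   0.888  1.00  0.00           O",
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  cx <- read_pdb(tmp, "H", "A")
  ca <- cx[cx$atom == "CA" & cx$chain == "H", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458)
})

test_that("writing an empty complex errors", {
  cx <- fix_complex()
  expect_error(write_pdb(cx[0, ], withr::local_tempfile()), "empty")
})

test_that("mutation grammar parses numbers, insertion codes and multi-sets", {
  sp <- parse_mutation_list("H.Y33A;L.S52W")
  expect_equal(nrow(sp), 2)
  expect_equal(sp$set, c(1L, 1L))
  expect_equal(sp$wt, c("Y", "S"))
  expect_equal(sp$mt, c("A", "W"))
  # grammar oracle: enumerate number/icode splits over generated tokens
  set.seed(42)
  for (i in 1:25) {
    chain <- sample(c(LETTERS, 0:9), 1)
    wt <- sample(names(abddg:::AA3), 1)
    mt <- sample(setdiff(names(abddg:::AA3), wt), 1)
    number <- sample(1:999, 1)
    icode <- sample(c("", sample(LETTERS, 1)), 1)
    token <- paste0(chain, ".", wt, number, icode, mt)
    sp <- parse_mutation_list(token)
    expect_equal(sp$resno, number)
    expect_equal(sp$icode, icode)
    expect_equal(sp$wt, wt)
    expect_equal(sp$mt, mt)
  }
  sp <- parse_mutation_list("H.A100BY")
  expect_equal(sp$resno, 100L)
  expect_equal(sp$icode, "B")
})

test_that("malformed, identity and duplicate-site mutation lists are rejected", {
  expect_error(parse_mutation_list("H.Y33"), "malformed")
  expect_error(parse_mutation_list("HY33A"), "malformed")
  expect_error(parse_mutation_list("H.Y33Y"), "wild-type equals mutant")
  expect_error(parse_mutation_list("H.Y33A;H.Y33F"), "duplicate")
})

test_that("build_mutant preserves the backbone and composes sequentially", {
  cx <- fix_complex()
  sp <- parse_mutation_list("H.K2A;H.W4G")
  mt <- build_mutant(cx, sp)
  bb_wt <- cx[cx$is_backbone, ]
  bb_mt <- mt[mt$is_backbone, ]
  expect_identical(bb_wt$atom, bb_mt$atom)
  expect_equal(max(abs(cbind(bb_wt$x, bb_wt$y, bb_wt$z) -
                         cbind(bb_mt$x, bb_mt$y, bb_mt$z))), 0)
  # glycine mutant has no side-chain atoms beyond CA
  expect_setequal(mt$atom[mt$key == "H.4"], c("N", "CA", "C", "O"))
  # compositionality: double mutant equals sequential singles, atom-wise
  m1 <- build_mutant(cx, sp[1, ])
  m12 <- build_mutant(m1, sp[2, ])
  expect_identical(as.data.frame(mt), as.data.frame(m12))
})

test_that("build_mutant reports wild-type mismatches with expected vs found", {
  cx <- fix_complex()
  expect_error(build_mutant(cx, parse_mutation_list("H.Y2A")),
               "expected Y.*found K")
  expect_error(build_mutant(cx, parse_mutation_list("H.K99A")), "not found")
})

test_that("interface_residues matches a brute-force all-pairs scan", {
  cx <- fix_complex()
  cutoff <- 5.5
  ir <- interface_residues(cx, cutoff)
  # brute force over all residue pairs across the partition
  res <- complex_residues(cx)
  brute <- character()
  for (i in which(res$side == "antibody")) for (j in which(res$side == "antigen")) {
    if (min_heavy_distance(cx, res$key[i], res$key[j]) <= cutoff)
      brute <- c(brute, res$key[i], res$key[j])
  }
  expect_setequal(ir$key, unique(brute))
  # symmetric in the partition labels
  swapped <- as_complex(tibble::as_tibble(cx), "A", "H")
  expect_setequal(interface_residues(swapped, cutoff)$key, ir$key)
})

test_that("interface set is empty beyond the cutoff", {
  cx <- make_toy_complex(c(H = "AAAAA", A = "AAAAA"), "H", "A",
                         approach = 10, seed = 2)
  expect_equal(nrow(interface_residues(cx, 5)), 0)
})

test_that("min_heavy_distance: identity, 3-4-5 triangle, symmetry, oracle", {
  cx <- fix_complex()
  expect_equal(min_heavy_distance(cx, "H.3", "H.3"), 0)
  pair <- as_complex(tibble::tibble(
    chain = c("H", "A"), resno = 1L, icode = "", resname = "ALA",
    atom = "CB", element = "C", x = c(0, 3), y = c(0, 4), z = 0), "H", "A")
  expect_equal(min_heavy_distance(pair, "H.1", "A.1"), 5)
  keys <- sample(unique(cx$key), 4)
  for (a in keys) for (b in keys) {
    dab <- min_heavy_distance(cx, a, b)
    expect_equal(dab, min_heavy_distance(cx, b, a))
    # exhaustive oracle
    xa <- cx[cx$key == a, ]; xb <- cx[cx$key == b, ]
    if (a != b) {
      dd <- Inf
      for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
        dd <- min(dd, sqrt((xa$x[i] - xb$x[j])^2 + (xa$y[i] - xb$y[j])^2 +
                             (xa$z[i] - xb$z[j])^2))
      expect_equal(dab, dd)
    }
  }
  expect_error(min_heavy_distance(cx, "H.99", "A.1"), "unknown site")
})
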