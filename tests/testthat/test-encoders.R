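# Sequence-window encoders against hand counts and brute-force oracles.

test_that("AAC handles homopolymers, pads, and matches letter counting", {
  v <- encode_aac("KKKKK")
  expect_identical(unname(v["K"]), 1)
  expect_identical(sum(v), 1)

  v <- encode_aac("---KA")
  expect_identical(unname(v[c("K", "A")]), c(0.5, 0.5))

  set.seed(31)
  seg <- rand_seg(21)
  expect_equal(encode_aac(seg), oracle_aac(seg), tolerance = 1e-15)

  expect_error(encode_aac("---"), "no real residues")
})

test_that("AAPC counts ordered distinct-position pairs over D(D-1)", {
  v <- encode_aapc("AA")
  expect_identical(unname(v["AA"]), 1)

  v <- encode_aapc("AC")
  expect_identical(unname(v[c("AC", "CA")]), c(0.5, 0.5))

  set.seed(32)
  for (rep in 1:5) {
    seg <- rand_seg(sample(5:25, 1), pad = 4)
    v <- encode_aapc(seg)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(v, oracle_aapc(seg), tolerance = 1e-12)
  }
  expect_error(encode_aapc("-A-"), "fewer than 2")
})

test_that("binary encoding is one-hot with zero blocks at pads and X", {
  v <- encode_binary("K")
  expect_identical(length(v), 20L)
  expect_identical(unname(v["p1.K"]), 1)
  expect_identical(sum(v), 1)

  v <- encode_binary("-K-")
  expect_identical(length(v), 60L)
  expect_identical(sum(v[1:20]), 0)
  expect_identical(sum(v[21:40]), 1)
  expect_identical(sum(v[41:60]), 0)

  set.seed(33)
  seg <- rand_seg(15, pad = 4, x_prob = 0.2)
  v <- encode_binary(seg)
  ch <- strsplit(seg, "")[[1]]
  for (p in seq_along(ch)) {
    blk <- v[((p - 1) * 20 + 1):(p * 20)]
    expect_identical(sum(blk), if (ch[p] %in% AAs) 1 else 0)
  }
})

test_that("CKSAAP counts k-spaced pairs and normalizes per gap", {
  v <- encode_cksaap("AKA", gaps = 1)
  expect_identical(unname(v["k1.AA"]), 1)
  expect_identical(sum(v), 1)

  v <- encode_cksaap("AAAAA", gaps = c(1, 2, 3))
  for (k in 1:3) expect_identical(unname(v[paste0("k", k, ".AA")]), 1)

  set.seed(34)
  for (rep in 1:5) {
    seg <- rand_seg(sample(10:25, 1), pad = 4)
    v <- encode_cksaap(seg, gaps = c(1, 2, 3))
    expect_equal(v, oracle_cksaap(seg, c(1, 2, 3)), tolerance = 1e-12)
    for (k in 1:3) {
      blk <- v[grepl(paste0("^k", k, "\\."), names(v))]
      expect_true(abs(sum(blk) - 1) < 1e-12 || sum(blk) == 0)
    }
  }
  expect_error(encode_cksaap("AKA", gaps = integer(0)), "non-empty")
  expect_error(encode_cksaap("AKA", gaps = 5), "too large")
})

test_that("EAAC slides sub-window AAC blocks", {
  v <- encode_eaac("KKKKK", subwindow = 5)
  expect_identical(length(v), 20L)
  expect_identical(unname(v["w1.K"]), 1)

  v <- encode_eaac("AAKAA", subwindow = 3)
  for (w in 1:3) {
    expect_equal(unname(v[paste0("w", w, ".A")]), 2 / 3)
    expect_equal(unname(v[paste0("w", w, ".K")]), 1 / 3)
  }

  set.seed(35)
  seg <- rand_seg(15, pad = 6)
  expect_equal(encode_eaac(seg, 5), oracle_eaac(seg, 5), tolerance = 1e-12)
  expect_error(encode_eaac("AK", subwindow = 0), ">= 1")
})

test_that("EGAAC maps residues to the five physicochemical groups", {
  v <- encode_egaac("KRHKR", subwindow = 5)
  expect_identical(unname(v["w1.g3.positive"]), 1)

  v <- encode_egaac("GADES", subwindow = 5)
  expect_equal(unname(v[c("w1.g1.aliphatic", "w1.g4.negative",
                          "w1.g5.uncharged")]), c(2/5, 2/5, 1/5))

  set.seed(36)
  seg <- rand_seg(12, pad = 4)
  got <- encode_egaac(seg, 5)
  ora <- oracle_egaac(seg, 5)
  expect_equal(unname(got), unname(ora), tolerance = 1e-12)
})

test_that("PSSM windows index the profile by position with zero pad rows", {
  set.seed(37)
  prot <- paste(c("K", sample(AAs, 9, TRUE)), collapse = "")
  m <- matrix(rnorm(nchar(prot) * 20), ncol = 20,
              dimnames = list(NULL, AAs))
  attr(m, "protein_id") <- "p1"
  seg <- extract_segment(prot, 1, 3, protein_id = "p1")  # 3 left pads
  v <- encode_pssm_window(seg, m)
  expect_identical(unname(v[1:60]), rep(0, 60))
  expect_identical(unname(v[61:80]), unname(m[1, ]))
  expect_identical(unname(v[81:100]), unname(m[2, ]))

  seg2 <- extract_segment(prot, 1, 3, protein_id = "other")
  expect_error(encode_pssm_window(seg2, m), "belongs")
})

test_that("AAC equals the mean of binary blocks over real residues", {
  set.seed(38)
  for (rep in 1:10) {
    seg <- rand_seg(sample(9:25, 1), pad = 6)
    ch <- strsplit(seg, "")[[1]]
    nreal <- sum(ch %in% AAs)
    b <- matrix(encode_binary(seg), ncol = 20, byrow = TRUE)
    expect_equal(unname(encode_aac(seg)), colSums(b) / nreal,
                 tolerance = 1e-12)
  }
})

test_that("encoders are pure and composition blocks are distributions", {
  set.seed(39)
  seg <- rand_seg(21, pad = 5, x_prob = 0.1)
  expect_identical(encode_aac(seg), encode_aac(seg))
  expect_identical(encode_cksaap(seg), encode_cksaap(seg))
  for (f in list(encode_aac, encode_aapc)) {
    v <- f(seg)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("build_feature_matrix concatenates encoders with prefixed names", {
  prot <- c(p1 = "AAAKAAAKAA")
  sites <- data.frame(protein_id = "p1", position = c(4L, 8L),
                      label = c("positive", "negative"))
  fm <- build_feature_matrix(prot, sites, "aac", n = 3)
  expect_identical(dim(fm$x), c(2L, 20L))
  expect_identical(fm$sample_id, c("p1_4", "p1_8"))

  fm2 <- build_feature_matrix(prot, sites, c("aac", "aapc"), n = 3)
  expect_identical(ncol(fm2$x), 420L)
  expect_true(all(grepl("^(aac|aapc)\\.", colnames(fm2$x))))

  expect_error(build_feature_matrix(prot, sites[0, ], "aac"), "no samples")
  expect_error(build_feature_matrix(prot, sites, "nope"), "unknown encoder")
  # encoding failures carry the sample id
  bad <- data.frame(protein_id = "p1", position = 4L, label = "positive")
  expect_error(build_feature_matrix(prot, bad, "rrpc", n = 3), "contact")
})
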