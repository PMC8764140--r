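# Contact thresholding, window qualification, segment expansion,
# RRC and RRPC.

cmap_of <- function(i, j, p, id = "p1") {
  contact_map(data.frame(i = i, j = j, prob = p), protein_id = id)
}

test_that("thresholding is strict: only probabilities above 0.80 survive", {
  cm <- cmap_of(c(1, 2, 3), c(10, 20, 30), c(0.79, 0.80, 0.81))
  kept <- filter_contacts(cm, 0.8)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$prob, 0.81)

  expect_identical(nrow(filter_contacts(cm, 0)), 3L)
  expect_identical(nrow(filter_contacts(cm, 1)), 0L)
})

test_that("window qualification needs at least one endpoint inside", {
  prot <- paste(rep("A", 60), collapse = "")
  prot <- paste0(substr(prot, 1, 9), "K", substr(prot, 11, 60))
  seg <- extract_segment(prot, 10, 5)  # covers 5..15
  cm <- cmap_of(c(7, 20, 6), c(40, 40, 14), c(0.9, 0.9, 0.9))
  q <- select_window_contacts(cm, seg)
  expect_identical(nrow(q), 2L)              # (7,40) and (6,14); not (20,40)
  expect_true(all(q$i %in% c(6, 7)))
})

test_that("expansion appends outside endpoints, deduplicated and ordered", {
  set.seed(41)
  ch <- sample(AAs, 60, TRUE)
  ch[10] <- "K"
  prot <- paste(ch, collapse = "")
  seg <- extract_segment(prot, 10, 5)

  ex <- expand_segment(seg, cmap_of(7, 40, 0.9), prot)
  expect_identical(ex$appended_positions, 40L)
  expect_identical(ex$appended_residues, ch[40])

  # duplicate outside position appended once; both-inside appends nothing
  ex <- expand_segment(seg, cmap_of(c(7, 9, 6), c(40, 40, 14),
                                    c(0.9, 0.9, 0.9)), prot)
  expect_identical(ex$appended_positions, 40L)

  # appended order is ascending sequence position
  ex <- expand_segment(seg, cmap_of(c(7, 9), c(55, 30), c(0.9, 0.9)), prot)
  expect_identical(ex$appended_positions, c(30L, 55L))

  # no qualifying contacts: identical to the base
  ex <- expand_segment(seg, cmap_of(integer(0), integer(0), numeric(0)),
                       prot)
  expect_identical(ex$appended_residues, character(0))
  expect_identical(encode_rrc(ex), encode_aac(seg))

  expect_error(expand_segment(seg, cmap_of(7, 99, 0.9), prot), "beyond")
})

test_that("RRC counts window plus appended residues", {
  prot <- paste(c(rep("K", 5), rep("C", 30), "A", rep("C", 24)),
                collapse = "")
  seg <- extract_segment(prot, 3, 2)          # "KKKKK"
  ex <- expand_segment(seg, cmap_of(3, 36, 0.9), prot)  # appends the A
  v <- encode_rrc(ex)
  expect_equal(unname(v["K"]), 5 / 6)
  expect_equal(unname(v["A"]), 1 / 6)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("RRC reduces to AAC on an empty map and ignores record order", {
  set.seed(42)
  for (rep in 1:10) {
    ch <- sample(AAs, 80, TRUE)
    ks <- which(ch == "K")
    if (!length(ks)) next
    prot <- paste(ch, collapse = "")
    seg <- extract_segment(prot, ks[sample.int(length(ks), 1)], 10)

    empty <- filter_contacts(cmap_of(c(1, 5), c(30, 40), c(0.5, 0.7)), 0.8)
    ex <- expand_segment(seg, select_window_contacts(empty, seg), prot)
    expect_identical(encode_rrc(ex), encode_aac(seg))

    cm1 <- cmap_of(c(seg$center, 2, seg$center), c(60, 70, 75),
                   c(0.9, 0.95, 0.85))
    cm2 <- cm1[c(3, 1, 2), ]
    q1 <- select_window_contacts(cm1, seg)
    q2 <- select_window_contacts(contact_map(as.data.frame(cm2), "p1"), seg)
    expect_identical(encode_rrc(expand_segment(seg, q1, prot)),
                     encode_rrc(expand_segment(seg, q2, prot)))
  }
})

test_that("raising the threshold never gains qualifying contacts", {
  set.seed(43)
  ch <- sample(AAs, 100, TRUE); ch[50] <- "K"
  prot <- paste(ch, collapse = "")
  seg <- extract_segment(prot, 50, 10)
  cm <- cmap_of(sample(1:49, 40, TRUE), sample(51:100, 40, TRUE),
                runif(40))
  prev <- Inf
  for (thr in seq(0, 1, by = 0.1)) {
    nq <- nrow(select_window_contacts(filter_contacts(cm, thr), seg))
    expect_lte(nq, prev)
    prev <- nq
  }
})

test_that("RRPC orients pairs by ascending index and normalizes by count", {
  prot <- paste(c("A", rep("G", 8), "K", rep("G", 9), "C",
                  rep("G", 40)), collapse = "")
  seg <- extract_segment(prot, 10, 5)
  # contact (10, 20): residue 10 = 'K', residue 20 = 'C'
  v <- encode_rrpc(seg, cmap_of(10, 20, 0.9), prot)
  expect_identical(unname(v["KC"]), 1)

  v <- encode_rrpc(seg, cmap_of(1, 10, 0.9), prot)
  expect_identical(unname(v["AK"]), 1)
  expect_identical(unname(v["KA"]), 0)

  # duplicates of one pair type concentrate mass
  v <- encode_rrpc(seg, cmap_of(c(1, 1), c(10, 12), c(0.9, 0.9)), prot)
  expect_identical(sum(v), 1)

  # no contacts: a 400-dim zero vector
  v <- encode_rrpc(seg, cmap_of(integer(0), integer(0), numeric(0)), prot)
  expect_identical(length(v), 400L)
  expect_identical(sum(v), 0)
})

test_that("RRPC sums to one iff at least one contact qualifies", {
  set.seed(44)
  for (rep in 1:10) {
    ch <- sample(AAs, 90, TRUE); ch[45] <- "K"
    prot <- paste(ch, collapse = "")
    seg <- extract_segment(prot, 45, 10)
    m <- sample(0:6, 1)
    cm <- cmap_of(sample(35:55, m, TRUE), sample(60:90, m, TRUE),
                  rep(0.9, m))
    q <- select_window_contacts(cm, seg)
    v <- encode_rrpc(seg, q, prot)
    expect_equal(sum(v), if (nrow(q) > 0) 1 else 0, tolerance = 1e-12)
  }
})

test_that("planted contact signal shows up in the RRPC dimensions", {
  d <- generate_dataset(synth_config(n_proteins = 40, motif_tilt = 0,
                                     seed = 9))
  fm <- build_feature_matrix(d$proteins, d$sites, "rrpc", n = 10,
                             contacts = d$contacts)
  pos <- fm$label == "positive"
  pairs <- sub("rrpc\\.", "", colnames(fm$x))
  lmass <- rowSums(fm$x[, grepl("L", pairs)])
  expect_gt(mean(lmass[pos]), mean(lmass[!pos]))
})
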