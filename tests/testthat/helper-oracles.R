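# Independent brute-force oracles used to cross-check the package's
# vectorized implementations.  Everything here is written as plain
# loops over definitions, deliberately sharing no code with R/.

AAs <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAIRS <- as.vector(vapply(AAs, function(a) paste0(a, AAs), character(20)))

GROUPS <- list(g1 = c("G", "A", "V", "L", "M", "I"),
               g2 = c("F", "Y", "W"),
               g3 = c("K", "R", "H"),
               g4 = c("D", "E"),
               g5 = c("S", "T", "C", "P", "N", "Q"))

# random segment string over the amino-acid alphabet with optional pads
# at the termini and occasional unknown residues
rand_seg <- function(len, pad = 0, x_prob = 0) {
  ch <- sample(AAs, len, replace = TRUE)
  if (x_prob > 0) ch[runif(len) < x_prob] <- "X"
  if (pad > 0) {
    left <- sample(0:pad, 1)
    right <- pad - left
    ch <- c(rep("-", left), ch, rep("-", right))
  }
  paste(ch, collapse = "")
}

oracle_aac <- function(seg) {
  ch <- strsplit(seg, "")[[1]]
  real <- ch[ch %in% AAs]
  v <- numeric(20)
  names(v) <- AAs
  for (a in AAs) {
    cnt <- 0
    for (c in real) if (c == a) cnt <- cnt + 1
    v[a] <- cnt / length(real)
  }
  v
}

oracle_aapc <- function(seg) {
  ch <- strsplit(seg, "")[[1]]
  real <- ch[ch %in% AAs]
  D <- length(real)
  v <- numeric(400)
  names(v) <- PAIRS
  for (p in seq_len(D)) for (q in seq_len(D)) {
    if (p != q) {
      key <- paste0(real[p], real[q])
      v[key] <- v[key] + 1
    }
  }
  v / (D * (D - 1))
}

oracle_cksaap <- function(seg, gaps) {
  ch <- strsplit(seg, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (k in gaps) {
    block <- numeric(400)
    names(block) <- paste0("k", k, ".", PAIRS)
    valid <- 0
    for (p in seq_len(L - k - 1)) {
      a <- ch[p]; b <- ch[p + k + 1]
      if (a %in% AAs && b %in% AAs) {
        valid <- valid + 1
        block[paste0("k", k, ".", a, b)] <-
          block[paste0("k", k, ".", a, b)] + 1
      }
    }
    if (valid > 0) block <- block / valid
    out <- c(out, block)
  }
  out
}

oracle_eaac <- function(seg, sub) {
  ch <- strsplit(seg, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (w in seq_len(L - sub + 1)) {
    piece <- ch[w:(w + sub - 1)]
    real <- piece[piece %in% AAs]
    block <- numeric(20)
    names(block) <- paste0("w", w, ".", AAs)
    if (length(real) > 0) {
      for (a in AAs) block[paste0("w", w, ".", a)] <-
          sum(real == a) / length(real)
    }
    out <- c(out, block)
  }
  out
}

oracle_egaac <- function(seg, sub) {
  ch <- strsplit(seg, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (w in seq_len(L - sub + 1)) {
    piece <- ch[w:(w + sub - 1)]
    gs <- character(0)
    for (c in piece) {
      for (g in names(GROUPS)) if (c %in% GROUPS[[g]]) gs <- c(gs, g)
    }
    block <- numeric(5)
    names(block) <- names(GROUPS)
    if (length(gs) > 0) {
      for (g in names(GROUPS)) block[g] <- sum(gs == g) / length(gs)
    }
    out <- c(out, block)
  }
  out
}

# chi-square statistic per dimension from class-wise value sums
oracle_chi2 <- function(x, is_pos) {
  n <- length(is_pos)
  p_pos <- sum(is_pos) / n
  vapply(seq_len(ncol(x)), function(j) {
    o_pos <- sum(x[is_pos, j]); o_neg <- sum(x[!is_pos, j])
    tot <- o_pos + o_neg
    if (tot == 0) return(0)
    e_pos <- p_pos * tot; e_neg <- (1 - p_pos) * tot
    (o_pos - e_pos)^2 / e_pos + (o_neg - e_neg)^2 / e_neg
  }, numeric(1))
}

# information gain (bits) of the class given a feature binned at the
# median (2 equal-frequency bins)
oracle_ig <- function(v, is_pos) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(v)
  hy <- ent(c(sum(is_pos), sum(!is_pos)) / n)
  med <- median(v)
  if (min(v) == max(v)) return(0)
  lo <- v <= med
  if (all(lo) || !any(lo)) return(0)
  h <- 0
  for (b in list(lo, !lo)) {
    if (sum(b) == 0) next
    h <- h + (sum(b) / n) *
      ent(c(sum(is_pos & b), sum(!is_pos & b)) / sum(b))
  }
  hy - h
}

oracle_metrics <- function(TP, FP, TN, FN) {
  list(Sn = TP / (TP + FN),
       Sp = TN / (TN + FP),
       Acc = (TP + TN) / (TP + FP + TN + FN),
       MCC = (TP * TN - FN * FP) /
         sqrt((TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)),
       Recall = TP / (TP + FN),
       Precision = 1 - FP / (TP + FP),
       F1 = 1 - (FP + FN) / (2 * TP + FP + FN))
}

# AUC as the fraction of (positive, negative) pairs correctly ordered,
# half credit for ties
oracle_auc <- function(scores, is_pos) {
  ps <- scores[is_pos]; ns <- scores[!is_pos]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# tiny labeled feature matrix for selection / model tests
toy_features <- function(n = 40, p = 5, seed = 1, signal = 2) {
  set.seed(seed)
  lab <- rep(c("positive", "negative"), length.out = n)
  x <- matrix(abs(rnorm(n * p)), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[lab == "positive", 1] <- x[lab == "positive", 1] + signal
  kcr_features(x, lab)
}
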