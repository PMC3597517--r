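# Independent brute-force oracles. These re-derive expected results from
# first principles (naive enumeration, regex expansion, direct DP) and are
# deliberately written without reuse of the package's internal machinery.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

chars <- function(s) strsplit(s, "")[[1]]

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
oracle_rc <- function(s) paste(rev(oracle_comp[chars(s)]), collapse = "")

omatch <- function(a, b) a == b & a != "N" & b != "N"

# ---- microhomology oracle -------------------------------------------------
# Enumerates every clean (split) parse of the junction: junction[1..s] must
# equal the proximal prefix and junction[(s+1)..n] the distal suffix; the
# two-sided match at a valid split s is the number of bases adjacent to s
# matching BOTH references. If no clean split exists, the middle segment
# unexplained by either reference is an insertion (microhomology 0).
oracle_mh <- function(prox, p, dist, d, junction) {
  P <- chars(prox); D <- chars(dist); J <- chars(junction)
  n <- length(J); ld <- length(D)
  best <- -1L
  for (s in 0:n) {
    pre_ok <- s == 0L || all(omatch(J[1:s], P[1:s]))
    k <- n - s
    suf_ok <- k == 0L || (k <= ld && all(omatch(J[(s + 1L):n],
                                                D[(ld - k + 1L):ld])))
    if (!pre_ok || !suf_ok) next
    left <- 0L
    while (s - left >= 1L) {
      dpos <- ld - k - left
      if (dpos < 1L || !omatch(J[s - left], D[dpos])) break
      left <- left + 1L
    }
    right <- 0L
    while (s + right + 1L <= n) {
      ppos <- s + right + 1L
      if (ppos > length(P) || !omatch(J[ppos], P[ppos])) break
      right <- right + 1L
    }
    best <- max(best, left + right)
  }
  if (best < 0L) {
    # insertion parse: longest exact prefix + suffix, middle inserted
    mp <- 0L
    while (mp < n && mp < length(P) && omatch(J[mp + 1L], P[mp + 1L])) {
      mp <- mp + 1L
    }
    ms <- 0L
    while (ms < n && ms < ld && omatch(J[n - ms], D[ld - ms])) ms <- ms + 1L
    list(mh = 0L, insert = paste(J[(mp + 1L):(n - ms)], collapse = ""))
  } else {
    list(mh = best, insert = "")
  }
}

# ---- paired-repeat oracles ------------------------------------------------
# Naive per-pair extension implementing the documented feature semantics
# (see R/architecture.R): maximal disjoint arm pairs, entropy > 1 bit.
oracle_entropy <- function(s) {
  p <- table(chars(s)); p <- p / sum(p)
  -sum(p * log2(p))
}

oracle_direct <- function(s, min_arm = 8L, max_spacer = 120L) {
  ch <- chars(s); n <- length(ch)
  out <- list()
  for (a in seq_len(max(0L, n - 1L))) {
    for (c0 in seq(a + 1L, n)) {
      L <- 0L
      while (a + L <= n && c0 + L <= n && L + 1L <= c0 - a &&
             omatch(ch[a + L], ch[c0 + L])) L <- L + 1L
      if (L < min_arm) next
      spacer <- c0 - a - L
      if (spacer > max_spacer) next
      if (a > 1L && spacer > 0L && omatch(ch[a - 1L], ch[c0 - 1L])) next
      if (oracle_entropy(substr(s, a, a + L - 1L)) <= 1.0) next
      out[[length(out) + 1L]] <- c(a - 1L, a + L - 1L, c0 - 1L, c0 + L - 1L)
    }
  }
  out
}

# inverted: f = complement; mirror: f = identity. Arm1 ends at b and grows
# leftwards, arm2 starts at c0 and grows rightwards.
oracle_two_arm <- function(s, f, min_arm = 8L, max_spacer = 120L) {
  ch <- chars(s); n <- length(ch)
  out <- list()
  for (b in seq_len(n)) {
    for (c0 in seq_len(n)) {
      if (c0 <= b) next
      L <- 0L
      while (b - L >= 1L && c0 + L <= n &&
             omatch(ch[c0 + L], f(ch[b - L]))) L <- L + 1L
      if (L < min_arm) next
      spacer <- c0 - b - 1L
      if (spacer > max_spacer) next
      if (c0 >= b + 3L && c0 - 1L >= 1L && b + 1L <= n &&
          omatch(ch[c0 - 1L], f(ch[b + 1L]))) next
      if (oracle_entropy(substr(s, b - L + 1L, b)) <= 1.0) next
      out[[length(out) + 1L]] <- c(b - L, b, c0 - 1L, c0 + L - 1L)
    }
  }
  out
}

oracle_inverted <- function(s, min_arm = 8L, max_spacer = 120L) {
  oracle_two_arm(s, function(x) oracle_comp[x], min_arm, max_spacer)
}
oracle_mirror <- function(s, min_arm = 8L, max_spacer = 120L) {
  oracle_two_arm(s, identity, min_arm, max_spacer)
}

int_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  unname(m)
}

arm_matrix <- function(feats) {
  if (nrow(feats) == 0L) return(int_matrix(matrix(integer(), ncol = 4)))
  m <- int_matrix(feats[c("arm1_start", "arm1_end",
                          "arm2_start", "arm2_end")])
  m[order(m[, 1], m[, 3], m[, 2]), , drop = FALSE]
}

oracle_sorted <- function(lst) {
  if (length(lst) == 0L) return(int_matrix(matrix(integer(), ncol = 4)))
  m <- int_matrix(do.call(rbind, lst))
  m[order(m[, 1], m[, 3], m[, 2]), , drop = FALSE]
}

# ---- tetraplex oracle -----------------------------------------------------
oracle_g4_score <- function(x, l1, l2, l3, min_run = 2L) {
  spread <- abs(l1 - l2) + abs(l2 - l3) + abs(l1 - l3)
  20 * (x - min_run) + max(0, 10 - spread) + max(0, 10 - max(l1, l2, l3))
}

# exhaustive enumeration of all (s1, s2, s3, s4, x) decompositions followed
# by the same greedy per-locus reduction (score desc, start asc, x desc)
oracle_g4 <- function(s, min_run = 2L, max_span = 30L) {
  ch <- chars(s); n <- length(ch)
  cand <- list()
  for (x in seq(min_run, max(min_run, (max_span - 3L) %/% 4L))) {
    ok <- vapply(seq_len(n), function(i) {
      i + x - 1L <= n && all(ch[i:(i + x - 1L)] == "G")
    }, logical(1))
    starts <- which(ok)
    for (s1 in starts) for (s2 in starts) for (s3 in starts)
      for (s4 in starts) {
        if (s2 < s1 + x + 1L || s3 < s2 + x + 1L || s4 < s3 + x + 1L) next
        if (s4 + x - s1 > max_span) next
        cand[[length(cand) + 1L]] <- c(
          s1 = s1, s4 = s4, x = x,
          score = oracle_g4_score(x, s2 - s1 - x, s3 - s2 - x, s4 - s3 - x,
                                  min_run))
      }
  }
  if (length(cand) == 0L) return(matrix(numeric(), ncol = 3))
  m <- do.call(rbind, cand)
  m <- m[order(-m[, "score"], m[, "s1"], -m[, "x"]), , drop = FALSE]
  occupied <- rep(FALSE, n)
  keep <- list()
  for (i in seq_len(nrow(m))) {
    span <- seq(m[i, "s1"], m[i, "s4"] + m[i, "x"] - 1L)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    keep[[length(keep) + 1L]] <- c(m[i, "s1"] - 1L,
                                   m[i, "s4"] + m[i, "x"] - 1L,
                                   m[i, "score"])
  }
  m2 <- do.call(rbind, keep)
  m2[order(m2[, 1]), , drop = FALSE]
}

# ---- Z-tract oracle -------------------------------------------------------
oracle_zdna <- function(s, min_len = 12L) {
  ch <- chars(s); n <- length(ch)
  okv <- vapply(seq_len(max(0L, n - 1L)), function(i) {
    paste(sort(c(ch[i], ch[i + 1L])), collapse = "") %in% c("GT", "CG", "AC")
  }, logical(1))
  out <- list()
  for (i in seq_len(max(0L, n - 1L))) for (j in seq(i, n - 1L)) {
    if (!all(okv[i:j])) next
    if (i > 1L && okv[i - 1L]) next                # maximal left
    if (j < n - 1L && okv[j + 1L]) next            # maximal right
    if (j - i + 2L < min_len) next
    out[[length(out) + 1L]] <- c(i - 1L, j + 1L, j - i + 2L)
  }
  if (length(out) == 0L) return(matrix(integer(), ncol = 3))
  do.call(rbind, out)
}

# ---- IUPAC motif oracle ---------------------------------------------------
oracle_iupac_class <- c(
  A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]", S = "[CG]",
  W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]")

oracle_motif_starts <- function(s, pattern) {
  rx <- paste0("(?=", paste(oracle_iupac_class[chars(pattern)],
                            collapse = ""), ")")
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# all (start, end, strand) hits, 0-based half-open forward coordinates
oracle_motif_hits <- function(s, pattern, both) {
  plen <- nchar(pattern)
  fwd <- oracle_motif_starts(s, pattern)
  out <- if (length(fwd)) cbind(fwd - 1L, fwd + plen - 1L, 1L) else
    matrix(integer(), ncol = 3)
  if (both) {
    rev <- oracle_motif_starts(oracle_rc(s), pattern)
    if (length(rev)) {
      L <- nchar(s)
      out <- rbind(out, cbind(L - (rev + plen - 1L), L - rev + 1L, 2L))
    }
  }
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}

# ---- Fisher oracle --------------------------------------------------------
# full enumeration over all 2x2 tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(c1, r1)
  prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }
  ps <- vapply(xs, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# ---- global-alignment score oracle ---------------------------------------
# affine Needleman-Wunsch, score only: match +1, mismatch -2, a gap of
# length g costs open + g * extend
oracle_nw_score <- function(sa, sb, match = 1, mismatch = -2,
                            open = 5, extend = 2) {
  A <- chars(sa); B <- chars(sb)
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - extend * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sub
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}
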