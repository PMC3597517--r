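region_of <- function(seq, bp = nchar(seq) %/% 2L, id = "r") {
  tibble::tibble(id = id, seq = seq, breakpoint_offset = as.integer(bp))
}

test_that("motif scanning finds literal and degenerate matches", {
  cat <- tibble::tibble(motif_id = c("chi", "rry"),
                        name = c("chi", "rry"),
                        pattern = c("GCTGGTGG", "RRY"),
                        search_both_strands = c(FALSE, FALSE))
  hits <- scan_motifs(region_of("GCTGGTGGAA", 5), cat)
  expect_equal(hits$start[hits$motif_id == "chi"], 0L)
  hits2 <- scan_motifs(region_of("AGT", 1), cat)
  expect_equal(hits2$motif_id, "rry")  # A=R, G=R, T=Y
  bad <- cat; bad$pattern[1] <- "GCX"
  expect_error(scan_motifs(region_of("ACGTACGT", 4), bad), "IUPAC")
})

test_that("motif hit coordinates agree with an independent regex oracle", {
  set.seed(11)
  cat <- default_motif_catalogue()
  for (i in 1:120) {
    s <- rand_seq(sample(60:150, 1), gc = runif(1, 0.3, 0.7))
    hits <- scan_motifs(region_of(s), cat)
    for (k in seq_len(nrow(cat))) {
      got <- hits[hits$motif_id == cat$motif_id[k], ]
      gotm <- int_matrix(got[order(got$start, got$strand),
                             c("start", "end")])
      exp <- oracle_motif_hits(s, cat$pattern[k], cat$search_both_strands[k])
      expect_equal(gotm, int_matrix(exp[, 1:2, drop = FALSE]),
                   info = paste("string", i, cat$motif_id[k]))
    }
  }
})

test_that("motif scanning is strand-consistent under reverse complement", {
  set.seed(12)
  cat <- default_motif_catalogue()
  cat <- cat[cat$search_both_strands, ]
  for (i in 1:25) {
    s <- rand_seq(120)
    rc <- oracle_rc(s)
    h1 <- scan_motifs(region_of(s), cat)
    h2 <- scan_motifs(region_of(rc), cat)
    m1 <- h1[order(h1$start, h1$motif_id), c("motif_id", "start", "end")]
    # mirror the rc hits back onto forward coordinates
    h2$start2 <- nchar(s) - h2$end
    h2$end2 <- nchar(s) - h2$start
    m2 <- tibble::tibble(motif_id = h2$motif_id, start = h2$start2,
                         end = h2$end2)
    m2 <- m2[order(m2$start, m2$motif_id), ]
    expect_equal(as.data.frame(m1), as.data.frame(m2), info = i)
  }
})

test_that("a planted direct repeat is found at its exact arms", {
  set.seed(21)
  repeat {
    s <- rand_seq(80)
    arm <- rand_seq(10)
    seq <- paste0(substr(s, 1, 20), arm, substr(s, 21, 40), arm,
                  substr(s, 41, 80))
    if (length(oracle_direct(seq)) == 1L) break
  }
  found <- find_direct_repeats(region_of(seq))
  expect_equal(nrow(found), 1L)
  expect_equal(unname(arm_matrix(found)), unname(oracle_sorted(
    oracle_direct(seq))))
  # the maximal arms contain the planted 10-mers (they may extend into
  # coincidentally matching background)
  expect_lte(found$arm1_start, 20L); expect_gte(found$arm1_end, 30L)
  expect_lte(found$arm2_start, 50L); expect_gte(found$arm2_end, 60L)
})

test_that("homopolymer-derived arm pairs are suppressed", {
  seq <- paste0(rand_seq(30), strrep("A", 40), rand_seq(30))
  expect_equal(nrow(find_direct_repeats(region_of(seq))), 0L)
  expect_equal(nrow(find_mirror_repeats(region_of(seq))), 0L)
})

test_that("planted inverted and mirror repeats are recovered", {
  set.seed(22)
  repeat {
    bg <- rand_seq(90)
    arm <- rand_seq(12)
    inv <- paste0(substr(bg, 1, 25), arm, substr(bg, 26, 45),
                  oracle_rc(arm), substr(bg, 46, 90))
    if (length(oracle_inverted(inv)) == 1L) break
  }
  f <- find_inverted_repeats(region_of(inv))
  expect_equal(unname(arm_matrix(f)), unname(oracle_sorted(
    oracle_inverted(inv))))

  repeat {
    bg <- rand_seq(90)
    arm <- rand_seq(12)
    mir <- paste0(substr(bg, 1, 25), arm, substr(bg, 26, 45),
                  paste(rev(chars(arm)), collapse = ""), substr(bg, 46, 90))
    if (length(oracle_mirror(mir)) == 1L) break
  }
  f2 <- find_mirror_repeats(region_of(mir))
  expect_equal(unname(arm_matrix(f2)), unname(oracle_sorted(
    oracle_mirror(mir))))
})

test_that("arms shorter than min_arm are not reported", {
  set.seed(23)
  bg <- rand_seq(80)
  arm <- rand_seq(6)  # below the minimum of 8
  seq <- paste0(substr(bg, 1, 20), arm, substr(bg, 21, 40),
                oracle_rc(arm), substr(bg, 41, 80))
  f <- find_inverted_repeats(region_of(seq))
  expect_true(all(f$score >= 8))
})

test_that("paired-repeat detectors match brute force on random strings", {
  set.seed(24)
  for (i in 1:60) {
    s <- rand_seq(sample(30:90, 1), gc = runif(1, 0.25, 0.75))
    r <- region_of(s)
    expect_equal(unname(arm_matrix(find_direct_repeats(r))),
                 unname(oracle_sorted(oracle_direct(s))), info = i)
    expect_equal(unname(arm_matrix(find_inverted_repeats(r))),
                 unname(oracle_sorted(oracle_inverted(s))), info = i)
    expect_equal(unname(arm_matrix(find_mirror_repeats(r))),
                 unname(oracle_sorted(oracle_mirror(s))), info = i)
  }
})

test_that("the canonical telomeric repeat is a maximal-evenness quadruplex", {
  f <- find_tetraplex(region_of("GGGTTAGGGTTAGGGTTAGGG", 10))
  expect_equal(nrow(f), 1L)
  expect_equal(f$arm1_start, 0L)
  expect_equal(f$arm1_end, 21L)
  # 3-tetrads, perfectly even loops of 3: 20 + 10 + 7
  expect_equal(f$score, 37)
  f2 <- find_tetraplex(region_of("GGTTGGTTGGTTGG", 7))
  expect_equal(nrow(f2), 1L)
  expect_lt(f2$score, f$score)  # score increases with G-run length
})

test_that("quadruplex calls equal the exhaustive decomposition oracle", {
  set.seed(25)
  for (i in 1:60) {
    s <- rand_seq(sample(35:55, 1), gc = 0.7)  # G-rich
    f <- find_tetraplex(region_of(s))
    o <- oracle_g4(s)
    expect_equal(nrow(f), nrow(o), info = i)
    if (nrow(f)) {
      expect_equal(unname(as.matrix(f[c("arm1_start", "arm1_end", "score")])),
                   unname(o), info = i)
    }
  }
})

test_that("Z-compatible tracts respect step alphabet and minimum length", {
  f <- find_zdna(region_of("GTGTGTGTGTGTGT", 7))
  expect_equal(nrow(f), 1L)
  expect_equal(f$score, 14)
  expect_equal(nrow(find_zdna(region_of("GAGAGAGAGAGA", 6))), 0L)
  # interruption splits the tract into two sub-threshold halves
  s <- paste0("GTGTGTGTGT", "AA", "GTGTGTGTGT")
  expect_equal(nrow(find_zdna(region_of(s, 11))), 0L)
  set.seed(26)
  for (i in 1:100) {
    s <- rand_seq(sample(30:120, 1), gc = runif(1, 0.3, 0.7))
    f <- find_zdna(region_of(s))
    o <- oracle_zdna(s)
    expect_equal(nrow(f), nrow(o), info = i)
    if (nrow(f)) {
      expect_equal(unname(as.matrix(f[c("arm1_start", "arm1_end", "score")])),
                   unname(o), info = i)
    }
  }
})

test_that("the flanking filter keeps exactly breakpoint-spanning features", {
  r <- region_of(strrep("A", 150), 75)
  feats <- tibble::tibble(
    kind = c("direct_repeat", "direct_repeat", "tetraplex", "tetraplex"),
    arm1_start = c(10L, 40L, 70L, 100L),
    arm1_end = c(25L, 60L, 90L, 120L),
    arm2_start = c(30L, 90L, NA, NA),
    arm2_end = c(45L, 110L, NA, NA),
    score = c(15, 20, 30, 20))
  kept <- filter_flanking(feats, r)
  # both arms 5' of the breakpoint -> removed; straddling pair kept;
  # G4 spanning 70-90 kept; G4 at 100-120 removed
  expect_equal(kept$arm1_start, c(40L, 70L))
  expect_true(all(kept$flanks_breakpoint))
  expect_lte(nrow(kept), nrow(feats))  # the filter never adds features
  expect_equal(filter_flanking(feats, r), filter_flanking(feats, r))
})

test_that("arm pairs overlapping the breakpoint itself pass the filter", {
  r <- region_of(strrep("A", 150), 75)
  feats <- tibble::tibble(kind = "inverted_repeat",
                          arm1_start = 70L, arm1_end = 85L,
                          arm2_start = 100L, arm2_end = 115L, score = 15)
  expect_equal(nrow(filter_flanking(feats, r)), 1L)
})

test_that("repeat_at_breakpoint honors containment and tie-breaks", {
  feats <- tibble::tibble(
    chrom = "c", start = c(100L, 150L, 400L), end = c(300L, 250L, 500L),
    name = c("AluY", "AluSx", "L1PA2"), family = c("Alu", "Alu", "L1"),
    strand = "+")
  hit <- repeat_at_breakpoint(200L, feats)
  expect_equal(hit$name, "AluY")  # larger overlap with the 150-bp window
  expect_equal(repeat_at_breakpoint(301L, feats) |> nrow(), 0L)
  expect_equal(repeat_at_breakpoint(401L, feats)$name, "L1PA2")
  # first base inside vs 1 bp outside the half-open interval
  expect_equal(nrow(repeat_at_breakpoint(101L, feats[1, ])), 1L)
  expect_equal(nrow(repeat_at_breakpoint(100L, feats[1, ])), 0L)
  expect_equal(nrow(repeat_at_breakpoint(501L, feats)), 0L)
})

test_that("percent identity is exact for substitution-only divergence", {
  a <- rand_seq(300)
  expect_equal(pairwise_identity(a, a), 100L)
  set.seed(31)
  ch <- chars(a)
  pos <- sample(300, 30)
  ch[pos] <- vapply(ch[pos], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  b <- paste(ch, collapse = "")
  expect_equal(pairwise_identity(a, b), 90L)
  expect_error(pairwise_identity("ACGT", a), "50-10,000")
})

test_that("alignment scores match an independent affine NW implementation", {
  set.seed(32)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  for (i in 1:15) {
    a <- rand_seq(sample(50:80, 1))
    b <- rand_seq(sample(50:80, 1))
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(Biostrings::score(aln), oracle_nw_score(a, b), info = i)
  }
})

test_that("same-family decoy identity lands in the published regime", {
  # two L1-like copies diverged ~2% each from their consensus: ~96%,
  # the regime of the most similar published repeat pair
  set.seed(33)
  cons <- rand_seq(1200)
  c1 <- junctionsig::mutate_sequence(cons, 0.02)
  c2 <- junctionsig::mutate_sequence(cons, 0.02)
  id <- pairwise_identity(c1, c2)
  expect_gte(id, 93L); expect_lte(id, 99L)
})

test_that("region profiles are deterministic and internally consistent", {
  set.seed(34)
  regions <- tibble::tibble(id = c("a", "b"),
                            seq = c(rand_seq(150), rand_seq(150)),
                            breakpoint_offset = 75L)
  p1 <- scan_regions(regions)
  p2 <- scan_regions(regions)
  expect_equal(p1, p2)
  expect_equal(p1$motif_count, vapply(p1$motif_hits, nrow, integer(1)))
  expect_equal(p1$nonb_count, vapply(p1$nonb_features, nrow, integer(1)))
})
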