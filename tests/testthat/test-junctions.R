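# Hand-constructed junction fixtures use 20-nt flanks sharing no sequence
# unless stated; the breakpoint sits after position 10 in both references.

make_case <- function(junction, prox = "GGATCCGTAATTTTTTTTTT",
                      dist = "CCCCCCCCCCACGTACGTAC",
                      p = 10L, d = 10L, id = "t") {
  junction_case(id, prox, p, dist, d, junction)
}

test_that("a perfect transition is called blunt with microhomology 0", {
  call <- call_microhomology(make_case("GGATCCGTAAACGTACGTAC"))
  expect_equal(call$mh_len, 0L)
  expect_true(call$blunt)
  expect_equal(call$inserted_seq, "")
  expect_equal(nrow(call$scar_events[[1]]), 0L)
})

test_that("microhomology abutting both breakpoints is recovered", {
  # "ACG" precedes the breakpoint in both references
  prox <- "GGATCCGACGTTTTTTTTTT"   # flank ...GACG | deleted T...
  dist <- "CCCCCCCACGAGTCAGTCAG"   # deleted ...ACG | flank AGT...
  junction <- "GGATCCGACGAGTCAGTCAG"
  call <- call_microhomology(make_case(junction, prox, dist))
  expect_equal(call$mh_len, 3L)
  expect_false(call$blunt)
})

test_that("a lost nucleotide at the switch point is an information scar", {
  # junction identical to the blunt parse but missing the final proximal T
  prox <- "GGATCCGTAGGCATTCCCCC"   # flank = P[1..15], P[15] = "T" is lost
  dist <- "AAAAAGGGGGACGTACGTAC"   # deleted = D[1..10]
  junction <- "GGATCCGTAGGCATACGTACGTAC"  # 24 nt: P[1..14] + D[11..20]
  call <- call_microhomology(make_case(junction, prox, dist, p = 15L))
  expect_equal(call$mh_len, 0L)
  ev <- call$scar_events[[1]]
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$ref_allele, "T")
})

test_that("substitutions near the switch point are scars, not mismatches", {
  # P ends ...TCG | with "TC" replaced by "AA" in the junction; the G
  # immediately 5' of the switch matches both references (mh 1)
  prox <- "GGATCCGGCCAATCGTTTTT"   # flank = P[1..15], P[13..14] = "TC"
  dist <- "CCCCCCCCCGACGTACGTAC"   # D[10] = "G" = P[15]
  junction <- "GGATCCGGCCAAAAGACGTACGTAC"
  call <- call_microhomology(make_case(junction, prox, dist, p = 15L))
  expect_equal(call$mh_len, 1L)
  ev <- call$scar_events[[1]]
  expect_equal(ev$kind, c("substitution", "substitution"))
  expect_equal(ev$ref_allele, c("T", "C"))
  expect_equal(ev$alt_allele, c("A", "A"))
})

test_that("inserted nucleotides imply microhomology 0", {
  junction <- "GGATCCGTAAGGGACGTACGTAC"  # "GGG" inserted at the switch
  call <- call_microhomology(make_case(junction))
  expect_equal(call$mh_len, 0L)
  expect_equal(call$inserted_seq, "GGG")
  expect_false(call$blunt)
})

test_that("junctions without anchored flank alignment are rejected", {
  expect_error(
    call_microhomology(make_case("TTTTTTTTTTGGGGGGGGGG")),
    "unmappable")
  # two substitutions exceed a scar budget of one
  expect_error(
    call_microhomology(
      make_case("GGATCCGGCCAAAAGACGTACGTAC", "GGATCCGGCCAATCGTTTTT",
                "CCCCCCCCCGACGTACGTAC", p = 15L),
      max_scar_mismatches = 1L),
    "unmappable")
})

test_that("the caller agrees with the enumeration oracle on random cases", {
  set.seed(101)
  n_cases <- 400
  for (i in seq_len(n_cases)) {
    p <- sample(15:40, 1)
    dlen <- sample(30:60, 1)
    d <- sample(10:(dlen - 15), 1)
    prox <- rand_seq(p + sample(10:30, 1))
    dist <- rand_seq(dlen)
    mode <- sample(c("clean", "insert"), 1, prob = c(0.8, 0.2))
    junction <- paste0(substr(prox, 1, p), substr(dist, d + 1, dlen))
    if (mode == "insert") {
      ins <- chars(rand_seq(sample(1:6, 1)))
      L <- length(ins)
      # block boundary coincidences so the insert parse is unambiguous
      p_next <- substr(prox, p + 1, p + 1)
      d_last <- substr(dist, d, d)
      if (ins[1] == p_next) {
        ins[1] <- setdiff(c("A", "C", "G", "T"),
                          c(p_next, if (L == 1L) d_last))[1]
      }
      if (ins[L] == d_last) {
        ins[L] <- setdiff(c("A", "C", "G", "T"),
                          c(d_last, if (L == 1L) p_next))[1]
      }
      junction <- paste0(substr(prox, 1, p), paste(ins, collapse = ""),
                         substr(dist, d + 1, dlen))
    }
    anchored <- isTRUE(tryCatch({
      cl <- call_microhomology(
        junction_case("o", prox, p, dist, d, junction), 0L)
      TRUE
    }, error = function(e) FALSE))
    if (!anchored) next  # oracle precondition (10-nt anchors) not met
    orc <- oracle_mh(prox, p, dist, d, junction)
    expect_equal(cl$mh_len, orc$mh, info = paste("case", i))
    expect_equal(cl$inserted_seq, orc$insert, info = paste("case", i))
  }
})

test_that("breakpoints flank the microhomology stretch", {
  # blunt junction, breakpoint offsets 75
  set.seed(7)
  P <- rand_seq(150); D <- rand_seq(150)
  Pch <- chars(P); Dch <- chars(D)
  if (Pch[76] == Dch[76]) Dch[76] <- setdiff(c("A","C","G","T"), Pch[76])[1]
  if (Pch[75] == Dch[75]) Dch[75] <- setdiff(c("A","C","G","T"), Pch[75])[1]
  P <- paste(Pch, collapse = ""); D <- paste(Dch, collapse = "")
  J <- paste0(substr(P, 1, 75), substr(D, 76, 150))
  call <- call_microhomology(junction_case("b", P, 75, D, 75, J))
  expect_equal(call$proximal_bp, 75L)
  expect_equal(call$distal_bp, 76L)

  # 30-nt example with a planted 4-bp stretch, worked once by hand:
  # P[12..15] == D[12..15], so the leftmost switch sits at 11 and the
  # first distal base 3' of the stretch is 16 = offset + 1
  set.seed(8)
  P <- chars(rand_seq(30)); D <- chars(rand_seq(30))
  D[12:15] <- P[12:15]
  if (D[11] == P[11]) D[11] <- setdiff(c("A","C","G","T"), P[11])[1]
  if (D[16] == P[16]) D[16] <- setdiff(c("A","C","G","T"), P[16])[1]
  P <- paste(P, collapse = ""); D <- paste(D, collapse = "")
  J <- paste0(substr(P, 1, 15), substr(D, 16, 30))
  call <- call_microhomology(junction_case("mh4", P, 15, D, 15, J))
  expect_equal(call$mh_len, 4L)
  expect_equal(call$proximal_bp, 11L)
  expect_equal(call$distal_bp, 16L)
  lb <- locate_breakpoints(call, junction_case("mh4", P, 15, D, 15, J))
  expect_equal(lb$distal_bp - 15L, 1L)
})

test_that("deletion sizes reproduce published values and reject start >= end", {
  out <- deletion_size(tibble::tibble(start_hg19 = c(138664845, 136887730),
                                      end_hg19 = c(138666255, 142397685)))
  expect_equal(out$size_bp, c(1410L, 5509955L))
  expect_equal(out$size_kb_rounded, c(1L, 5510L))
  expect_error(deletion_size(tibble::tibble(start_hg19 = 5, end_hg19 = 5)),
               "non-positive")
})

test_that("random blunt constructions follow the geometric two-sided law", {
  # For iid uniform flanks joined at the midpoint, mh = X + Y with
  # X, Y ~ Geom(3/4): P(mh = 0) = 0.5625, P(mh <= 1) = 0.84375.
  set.seed(202)
  n <- 2000
  mh <- vapply(seq_len(n), function(i) {
    P <- rand_seq(60); D <- rand_seq(60)
    J <- paste0(substr(P, 1, 30), substr(D, 31, 60))
    call_microhomology(junction_case("r", P, 30, D, 30, J), 0L)$mh_len
  }, integer(1))
  ci0 <- qbinom(c(0.005, 0.995), n, 0.5625) / n
  ci1 <- qbinom(c(0.005, 0.995), n, 0.84375) / n
  expect_gte(mean(mh == 0), ci0[1]); expect_lte(mean(mh == 0), ci0[2])
  expect_gte(mean(mh <= 1), ci1[1]); expect_lte(mean(mh <= 1), ci1[2])
})
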