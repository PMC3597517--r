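# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over A/C/G/T/N in all user-facing tibbles;
# Biostrings objects exist only transiently at I/O and alignment boundaries.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

`%||%` <- rlang::`%||%`

assert_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop(what, " contains non-ACGTN characters: '",
         substr(bad, 1, 5), "'", call. = FALSE)
  }
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  ch <- rev(seq_chars(seq))
  paste(COMPLEMENT[ch], collapse = "")
}

rev_seq <- function(seq) paste(rev(seq_chars(seq)), collapse = "")

# Longest common prefix of two character vectors (split sequences).
# N never matches anything (conservative, applies everywhere).
base_match <- function(a, b) a == b & a != "N" & b != "N"

common_prefix_len <- function(x, y) {
  n <- min(length(x), length(y))
  if (n == 0L) return(0L)
  m <- base_match(x[seq_len(n)], y[seq_len(n)])
  first_false <- match(FALSE, m)
  if (is.na(first_false)) n else first_false - 1L
}

common_suffix_len <- function(x, y) {
  common_prefix_len(rev(x), rev(y))
}

# Shannon entropy (bits) of the base composition of a sequence.
seq_entropy <- function(seq) {
  p <- table(seq_chars(seq))
  p <- p / sum(p)
  -sum(p * log2(p))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Validate a region tibble (id, seq, breakpoint_offset). The breakpoint lies
# between positions breakpoint_offset and breakpoint_offset + 1 (1-based).
validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("id", "seq", "breakpoint_offset") %in% names(regions)))
  purrr::pwalk(regions[c("id", "seq", "breakpoint_offset")],
    function(id, seq, breakpoint_offset) {
      assert_seq(seq, paste0("region '", id, "'"))
      if (breakpoint_offset < 1L || breakpoint_offset >= nchar(seq)) {
        stop("region '", id, "': breakpoint_offset must satisfy ",
             "1 <= offset < length(seq)", call. = FALSE)
      }
    })
  invisible(regions)
}
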