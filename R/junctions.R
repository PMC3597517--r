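# Junction calling. A junction case consists of:
#   * the proximal reference region: non-deleted 5' flank, then deleted
#     sequence, with the breakpoint after `prox_offset` bases;
#   * the distal reference region: deleted sequence, then non-deleted 3'
#     flank, with the breakpoint after `dist_offset` bases;
#   * the sequenced junction fragment, which aligns to the proximal region
#     at its 5' end and to the distal region at its 3' end.
#
# Microhomology is counted by two-sided extension across the switch point:
# bases assigned to the proximal segment that also match the distal
# reference, plus bases assigned to the distal segment that also match the
# proximal reference. With exact prefix/suffix match lengths mp and ms this
# is mp + ms - n (n = junction length), independent of where the switch is
# placed inside the ambiguous stretch; the leftmost switch point is reported
# for determinism.

ANCHOR_LEN <- 10L
SCAR_WINDOW <- 10L

#' Construct junction cases
#'
#' Builds the one-row-per-deletion table consumed by
#' [call_microhomology()]. All sequences must be at least 20 nt and the
#' junction no longer than the two references combined.
#'
#' @param case_id Character vector of case labels.
#' @param prox_seq,dist_seq Proximal / distal reference region sequences.
#' @param prox_offset,dist_offset 1-based count of bases 5' of the
#'   breakpoint in each reference region (the breakpoint lies between
#'   `offset` and `offset + 1`).
#' @param junction Sequenced junction fragment.
#' @return A tibble with one row per case.
#' @export
junction_case <- function(case_id, prox_seq, prox_offset,
                          dist_seq, dist_offset, junction) {
  out <- tibble(case_id = as.character(case_id),
                prox_seq = toupper(prox_seq),
                prox_offset = as.integer(prox_offset),
                dist_seq = toupper(dist_seq),
                dist_offset = as.integer(dist_offset),
                junction = toupper(junction))
  purrr::pwalk(out, function(case_id, prox_seq, prox_offset,
                             dist_seq, dist_offset, junction) {
    assert_seq(prox_seq, paste0("case '", case_id, "' proximal reference"))
    assert_seq(dist_seq, paste0("case '", case_id, "' distal reference"))
    assert_seq(junction, paste0("case '", case_id, "' junction"))
    if (min(nchar(c(prox_seq, dist_seq, junction))) < 20L) {
      stop("case '", case_id, "': all sequences must be >= 20 nt",
           call. = FALSE)
    }
    if (nchar(junction) > nchar(prox_seq) + nchar(dist_seq)) {
      stop("case '", case_id, "': junction longer than both references ",
           "combined", call. = FALSE)
    }
    if (prox_offset < 1L || prox_offset >= nchar(prox_seq) ||
        dist_offset < 1L || dist_offset >= nchar(dist_seq)) {
      stop("case '", case_id, "': breakpoint offsets out of range",
           call. = FALSE)
    }
  })
  out
}

# Core single-case parse. Returns a list; errors with "unmappable junction"
# when no anchored parse within the scar budget exists.
call_one_junction <- function(prox_seq, prox_offset, dist_seq, dist_offset,
                              junction, max_scar_mismatches = 2L) {
  P <- seq_chars(prox_seq)
  D <- seq_chars(dist_seq)
  J <- seq_chars(junction)
  p <- prox_offset
  n <- length(J)
  n_exp <- p + (length(D) - dist_offset)

  mp <- common_prefix_len(J, P)
  ms <- common_suffix_len(J, D)
  if (mp < ANCHOR_LEN || ms < ANCHOR_LEN) {
    stop("unmappable junction: needs >= ", ANCHOR_LEN,
         " exactly matching anchor bases on each side", call. = FALSE)
  }

  scar <- tibble(kind = character(), offset = integer(),
                 ref_allele = character(), alt_allele = character())
  inserted <- ""

  if (mp + ms >= n) {
    n_del <- n_exp - n
    if (n_del > 0L) {
      # junction shorter than a scar-free parse: 1-bp deletion scar(s),
      # attributed leftmost (immediately after the matched prefix)
      if (n_del > max_scar_mismatches) {
        stop("unmappable junction: ", n_del,
             " deleted bases exceed the scar budget", call. = FALSE)
      }
      if (abs(mp + 1L - p) > SCAR_WINDOW) {
        stop("unmappable junction: length deficit outside the scar window",
             call. = FALSE)
      }
      scar <- tibble(kind = "deletion",
                     offset = (mp + seq_len(n_del)) - (n - ms),
                     ref_allele = P[mp + seq_len(n_del)],
                     alt_allele = "")
    }
  } else if (n > n_exp && mp + ms >= n_exp) {
    # length surplus not explained by the references: inserted nucleotides
    inserted <- paste(J[(mp + 1L):(n - ms)], collapse = "")
  } else {
    # interior mismatch(es): extend the prefix match through isolated
    # substitutions near the expected switch point
    if (n != n_exp) {
      stop("unmappable junction: mismatches combined with a length change",
           call. = FALSE)
    }
    i <- mp
    events <- list()
    while (i < n - ms && length(events) < max_scar_mismatches) {
      q <- i + 1L
      if (q > length(P) || abs(q - p) > SCAR_WINDOW) break
      events[[length(events) + 1L]] <-
        list(pos = q, ref = P[q], alt = J[q])
      i <- q
      while (i < n && i < length(P) && base_match(J[i + 1L], P[i + 1L])) {
        i <- i + 1L
      }
    }
    if (i < n - ms) {
      stop("unmappable junction: mismatches exceed the scar budget or lie ",
           "outside the scar window", call. = FALSE)
    }
    mp <- i
    scar <- tibble(kind = "substitution",
                   offset = purrr::map_int(events, "pos") - (n - ms),
                   ref_allele = purrr::map_chr(events, "ref"),
                   alt_allele = purrr::map_chr(events, "alt"))
  }

  mh <- if (nzchar(inserted)) 0L else max(0L, mp + ms - n)
  s <- n - ms  # leftmost switch point (junction == proximal coordinates)
  list(mh_len = mh,
       inserted_seq = inserted,
       scar_events = scar,
       proximal_bp = s,
       distal_bp = (length(D) - n) + s + mh + 1L,
       blunt = mh == 0L && !nzchar(inserted) && nrow(scar) == 0L)
}

#' Call microhomology, insertions and scars at deletion junctions
#'
#' Parses each junction fragment as a prefix of the proximal reference plus
#' (optionally) inserted nucleotides plus a suffix of the distal reference,
#' and reports the maximal microhomology: the number of bases immediately
#' flanking the switch point that match *both* references. Isolated
#' substitutions and 1-bp deletions within 10 bp of the switch point are
#' emitted as scar events ("information scars") instead of terminating the
#' extension; junctions needing more than `max_scar_mismatches` such events
#' are rejected as unmappable. Among equal-microhomology parses the leftmost
#' switch point is reported. `N` bases never match anything.
#'
#' @param cases A tibble from [junction_case()].
#' @param max_scar_mismatches Maximum number of scar events tolerated
#'   (default 2, matching the 1-2 nt scars seen at real junctions).
#' @return A tibble with one row per case: `case_id`, `mh_len`,
#'   `inserted_seq`, `scar_events` (list column of event tibbles with
#'   columns `kind`, `offset` relative to the switch point, `ref_allele`,
#'   `alt_allele`), refined region-local `proximal_bp` / `distal_bp`
#'   (see [locate_breakpoints()]), and `blunt`.
#' @examples
#' case <- junction_case("ex", "AAAACCCCTTTTGGGGAAAC", 8,
#'                       "CCCTAGGGGTTTTACGCGCG", 12,
#'                       "AAAACCCCTTACGCGCG")
#' call_microhomology(case)
#' @export
call_microhomology <- function(cases, max_scar_mismatches = 2L) {
  calls <- purrr::pmap(
    cases[c("prox_seq", "prox_offset", "dist_seq", "dist_offset",
            "junction")],
    call_one_junction, max_scar_mismatches = max_scar_mismatches)
  dplyr::bind_cols(
    tibble(case_id = cases$case_id),
    dplyr::bind_rows(purrr::map(calls, function(x) {
      tibble(mh_len = x$mh_len, inserted_seq = x$inserted_seq,
             scar_events = list(x$scar_events),
             proximal_bp = x$proximal_bp, distal_bp = x$distal_bp,
             blunt = x$blunt)
    }))
  )
}

#' Refine breakpoint positions from a microhomology call
#'
#' The proximal breakpoint is the last proximal-reference nucleotide
#' 5'-adjacent to the microhomology stretch and the distal breakpoint the
#' first distal-reference nucleotide 3'-adjacent to it; for blunt junctions
#' the two positions flank the switch point directly. Positions are 1-based
#' and local to each reference region; add the genomic start of a region
#' minus one to lift them to genomic coordinates.
#'
#' @param calls Output of [call_microhomology()].
#' @param cases The matching input of [call_microhomology()].
#' @return A tibble with `case_id`, `proximal_bp`, `distal_bp`.
#' @export
locate_breakpoints <- function(calls, cases) {
  stopifnot(identical(calls$case_id, cases$case_id))
  calls[c("case_id", "proximal_bp", "distal_bp")]
}

#' Deletion sizes from breakpoint coordinates
#'
#' Size is defined as `end - start` in bp (the convention that reproduces
#' every published kb value of the packaged fixture), with `size_kb` the
#' bp size rounded to the nearest kb.
#'
#' @param records A data frame with columns `start_hg19` and `end_hg19`
#'   (1-based breakpoint positions), e.g. [load_foxl2_deletions()].
#' @return The input with `size_bp` and `size_kb_rounded` columns added.
#' @examples
#' deletion_size(load_foxl2_deletions())[, c("patient_code", "size_bp")]
#' @export
deletion_size <- function(records) {
  stopifnot(all(c("start_hg19", "end_hg19") %in% names(records)))
  bp <- records$end_hg19 - records$start_hg19
  if (any(bp <= 0)) {
    stop("non-positive deletion size (end_hg19 must exceed start_hg19)",
         call. = FALSE)
  }
  dplyr::mutate(as_tibble(records),
                size_bp = as.integer(bp),
                size_kb_rounded = as.integer(round(bp / 1000)))
}
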