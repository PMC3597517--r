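# Mechanism classification from the junction signature. The decision rules
# follow the three observed signature groups:
#   group 1 - perfect transition (mh 0, possibly with an information
#             scar): classic NHEJ.
#   group 2 - microhomology plus same-superfamily repeat elements at both
#             breakpoints: NAHR candidate, with replicative template
#             switching and (for mh >= 5) MMEJ as alternatives.
#   group 3 - microhomology without matching repeat context: replicative
#             mechanisms favoured, with NHEJ (mh 1-4) or MMEJ (mh >= 5)
#             as end-joining alternatives.
# "Replicative" pools FoSTeS, MMBIR, SRS and BISRS, which share the
# microhomology signature and cannot be told apart from sequence alone.

MH_MMEJ_MIN <- 5L    # >= 5 bp of microhomology is MMEJ-compatible
MEPS_IDENTITY <- 90  # identity (%) treated as MEPS-compatible for NAHR

#' Classify the candidate repair mechanism of one junction signature
#'
#' @param mh_len Microhomology length in bp (>= 0).
#' @param scar_present Whether an information scar (small substitution /
#'   deletion / insertion) was observed at the junction.
#' @param repeat_prox_family,repeat_dist_family Repeat superfamily bucket
#'   at each breakpoint (see [repeat_family()]), or `NA` when the
#'   breakpoint is repeat-free.
#' @param identity_pct Percent identity between the two repeat elements
#'   (same-family cases), or `NA`.
#' @return A one-row tibble: `group` (1/2/3), `candidates` (list column,
#'   ordered), `mechanism` (the serialized candidate string, e.g.
#'   `"NAHR/Replicative/MMEJ"`), `rationale`.
#' @examples
#' classify_mechanism(15, FALSE, "Alu", "Alu", 85)
#' classify_mechanism(1, FALSE, "Alu", "DNA", NA)
#' @export
classify_mechanism <- function(mh_len, scar_present = FALSE,
                               repeat_prox_family = NA_character_,
                               repeat_dist_family = NA_character_,
                               identity_pct = NA_real_) {
  mh_len <- as.integer(mh_len)
  if (is.na(mh_len) || mh_len < 0L) {
    stop("mh_len must be a non-negative integer", call. = FALSE)
  }
  same_family <- !is.na(repeat_prox_family) && !is.na(repeat_dist_family) &&
    repeat_prox_family == repeat_dist_family
  long_mh <- mh_len >= MH_MMEJ_MIN
  if (mh_len == 0L) {
    group <- 1L
    candidates <- "NHEJ"
    rationale <- paste0("perfect transition at the junction",
                        if (scar_present)
                          "; information scar supports NHEJ" else "")
  } else if (same_family) {
    group <- 2L
    candidates <- c("NAHR", "Replicative", if (long_mh) "MMEJ" else "NHEJ")
    rationale <- paste0(
      repeat_prox_family, " elements at both breakpoints make NAHR a ",
      "candidate; ", mh_len, " bp of microhomology also fits ",
      if (long_mh) "replicative mechanisms or MMEJ"
      else "replicative mechanisms or NHEJ (same-family context with ",
      "short microhomology: NHEJ alternative extrapolated from the ",
      "microhomology-length rule)")
  } else {
    group <- 3L
    candidates <- c("Replicative", if (long_mh) "MMEJ" else "NHEJ")
    rationale <- paste0(
      mh_len, " bp of microhomology without same-family repeats at both ",
      "breakpoints; replicative mechanisms favoured",
      if (scar_present) " (scar noted)" else "",
      ", with ", if (long_mh) "MMEJ (mh >= 5 bp)"
      else "NHEJ (mh 1-4 bp)", " as the end-joining alternative")
  }
  if (!is.na(identity_pct)) {
    rationale <- paste0(rationale, "; repeat identity ", identity_pct, "%",
                        if (identity_pct >= MEPS_IDENTITY)
                          " (MEPS-compatible)" else "")
  }
  mech <- paste(candidates, collapse = "/")
  tibble(group = group, candidates = list(candidates),
         mechanism = mech, rationale = rationale)
}

#' Classify all deletions of a fixture-shaped table
#'
#' Applies [classify_mechanism()] to every record of a table shaped like
#' [load_foxl2_deletions()] (columns `mh_len`, `scar`, `repeat_prox`,
#' `repeat_dist`, `identity_pct`).
#'
#' @param fixture A deletion record tibble.
#' @return A `mechanism_calls` tibble: the input plus `group`,
#'   `candidates`, `call` (serialized candidate string) and `rationale`.
#'   [glance()] gives the per-group counts.
#' @examples
#' calls <- classify_all(load_foxl2_deletions())
#' glance(calls)
#' @export
classify_all <- function(fixture) {
  calls <- purrr::pmap(
    list(fixture$mh_len, fixture$scar,
         repeat_family(fixture$repeat_prox),
         repeat_family(fixture$repeat_dist),
         fixture$identity_pct),
    function(mh, scar, fp, fd, id_pct) {
      classify_mechanism(mh, scar_present = !is.na(scar),
                         repeat_prox_family = fp, repeat_dist_family = fd,
                         identity_pct = id_pct)
    })
  out <- dplyr::bind_cols(
    as_tibble(fixture),
    dplyr::rename(dplyr::bind_rows(calls), call = "mechanism"))
  class(out) <- c("mechanism_calls", class(out))
  out
}

#' @rdname classify_all
#' @param x A `mechanism_calls` object.
#' @param ... Unused.
#' @method glance mechanism_calls
#' @export
glance.mechanism_calls <- function(x, ...) {
  tibble(n = nrow(x),
         group1 = sum(x$group == 1L),
         group2 = sum(x$group == 2L),
         group3 = sum(x$group == 3L),
         nahr_candidates = sum(purrr::map_lgl(x$candidates,
                                              ~ "NAHR" %in% .x)),
         with_microhomology = sum(x$mh_len > 0L))
}

#' @rdname classify_all
#' @method tidy mechanism_calls
#' @export
tidy.mechanism_calls <- function(x, ...) {
  cols <- intersect(c("patient_code", "case_id", "mh_len", "group",
                      "call", "rationale"), names(x))
  out <- x[cols]
  class(out) <- class(tibble())
  out
}
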