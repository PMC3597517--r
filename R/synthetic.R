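# Synthetic locus and deletion-allele generator. Everything is seeded and
# self-contained: decoy repeat cassettes are consensus-derived random
# sequences (no copied genomic DNA); their per-copy substitution load
# controls the identity regime of same-family repeat pairs. Planted
# junctions are guaranteed recoverable: the bases immediately outside the
# planted microhomology stretch are edited so no accidental extension
# exists, making exact recovery a deterministic property rather than a
# probabilistic one.

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Decoy family cassettes: name prefix feeds repeat_family(), length is
# loosely modelled on the real element classes.
SYN_FAMILIES <- tibble::tibble(
  family = c("Alu", "L1", "MIR", "LTR", "DNA"),
  prefix = c("AluSyn", "L1Syn", "MIRSyn", "LTRSyn", "TiggerSyn"),
  cons_len = c(300L, 1500L, 180L, 450L, 300L),
  weight = c(0.40, 0.35, 0.10, 0.10, 0.05)
)

#' Substitute a fraction of bases in a sequence
#'
#' Per-position Bernoulli substitutions to a uniformly chosen different
#' base; no indels, so coordinates are preserved. Used to derive diverged
#' repeat copies from a consensus.
#'
#' @param seq Nucleotide sequence.
#' @param rate Per-base substitution probability.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic locus with annotated decoy repeats
#'
#' Builds an iid background sequence at the given GC content and plants
#' non-overlapping decoy repeat cassettes (Alu-like ~300 nt, L1-like
#' ~1.5 knt, MIR-, LTR- and DNA-transposon-like) until about
#' `repeat_density` of the locus is repeat-derived. Each copy is the family
#' consensus carrying its own random substitution load drawn from
#' `mut_range`, so same-family copy pairs span the identity regime seen
#' between real repeat elements at deletion breakpoints. The annotation
#' table exactly describes the planted copies.
#'
#' @param length Locus length in bp (default 1e6; >= 1e5 recommended for
#'   the default workflows).
#' @param gc GC fraction of the background (default 0.41, human-like).
#' @param repeat_density Target fraction of repeat-derived sequence
#'   (default 0.25; must be <= 0.5).
#' @param seed Integer seed; the locus is byte-identical under the same
#'   seed.
#' @param mut_range Range of per-copy substitution rates.
#' @return A list with `reference` (tibble `id`, `seq`), `repeats`
#'   (annotation tibble as from [read_repeatmasker()]) and `consensus`
#'   (named list of family consensus sequences).
#' @export
generate_locus <- function(length = 1e6, gc = 0.41, repeat_density = 0.25,
                           seed = 1L, mut_range = c(0.02, 0.15)) {
  if (repeat_density > 0.5) {
    stop("repeat_density must be <= 0.5", call. = FALSE)
  }
  length <- as.integer(length)
  with_seed(seed, {
    consensus <- setNames(
      purrr::map(SYN_FAMILIES$cons_len, random_dna, gc = 0.5),
      SYN_FAMILIES$family)
    mean_len <- sum(SYN_FAMILIES$cons_len * SYN_FAMILIES$weight)
    n_copies <- if (repeat_density > 0)
      ceiling(repeat_density * length / mean_len) else 0L
    fams <- if (n_copies > 0)
      sample(SYN_FAMILIES$family, n_copies, replace = TRUE,
             prob = SYN_FAMILIES$weight) else character()
    # place copies left to right with background gaps sized to hit the
    # target density in expectation
    copies <- list()
    ann <- list()
    pos <- 0L
    counter <- setNames(integer(nrow(SYN_FAMILIES)), SYN_FAMILIES$family)
    total_rep <- sum(SYN_FAMILIES$cons_len[match(fams, SYN_FAMILIES$family)])
    gap_mean <- max(50, (length - total_rep) / (length(fams) + 1L))
    chunks <- list()
    for (f in fams) {
      gap <- max(30L, as.integer(stats::rexp(1, 1 / gap_mean)))
      if (pos + gap + nchar(consensus[[f]]) + 200L > length) break
      chunks[[length(chunks) + 1L]] <- random_dna(gap, gc)
      pos <- pos + gap
      counter[f] <- counter[f] + 1L
      rate <- stats::runif(1, mut_range[1], mut_range[2])
      copy <- mutate_sequence(consensus[[f]], rate)
      strand <- sample(c("+", "-"), 1L)
      chunks[[length(chunks) + 1L]] <-
        if (strand == "-") revcomp(copy) else copy
      prefix <- SYN_FAMILIES$prefix[SYN_FAMILIES$family == f]
      ann[[length(ann) + 1L]] <- tibble(
        chrom = "synthetic_locus", start = pos,
        end = pos + nchar(copy),
        name = paste0(prefix, "_", counter[f]),
        family = f, strand = strand)
      pos <- pos + nchar(copy)
    }
    if (pos < length) chunks[[length(chunks) + 1L]] <-
      random_dna(length - pos, gc)
    list(reference = tibble(id = "synthetic_locus",
                            seq = paste(unlist(chunks), collapse = "")),
         repeats = dplyr::bind_rows(ann) %||%
           tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), family = character(),
                  strand = character()),
         consensus = consensus)
  })
}

#' Specify a deletion allele to plant
#'
#' @param size_bp Target deletion size (realized size may differ when the
#'   breakpoints must fall inside repeats; it is echoed in the truth
#'   record). Must exceed `mh_len + 20`.
#' @param mh_len Planted microhomology length, 0-70.
#' @param insert_seq Inserted nucleotides at the junction (requires
#'   `mh_len = 0`).
#' @param scar Scar descriptor string as printed in junction tables:
#'   `"del(T)"` (1-bp deletion) or `"TC>AA"` (substitution), or `NA`.
#' @param repeat_prox,repeat_dist Repeat superfamily required at each
#'   breakpoint (`"Alu"`, `"L1"`, `"MIR"`, `"LTR"`, `"DNA"`) or `NA` for a
#'   repeat-free breakpoint.
#' @param repeat_context Convenience shorthand overriding the two family
#'   fields: one of `"none"`, `"same_family_alu"`, `"same_family_l1"`,
#'   `"different_family"`, `"one_side"`.
#' @param arm_divergence_pct For same-family contexts: target percent
#'   divergence between the two repeat copies (identity ~ 100 - this).
#' @param seed Integer seed for the planting randomness.
#' @return A one-row spec tibble.
#' @export
deletion_spec <- function(size_bp = 5000L, mh_len = 0L, insert_seq = "",
                          scar = NA_character_,
                          repeat_prox = NA_character_,
                          repeat_dist = NA_character_,
                          repeat_context = NULL,
                          arm_divergence_pct = NA_real_, seed = 1L) {
  if (!is.null(repeat_context)) {
    ctx <- match.arg(repeat_context,
                     c("none", "same_family_alu", "same_family_l1",
                       "different_family", "one_side"))
    fams <- switch(ctx,
      none = c(NA, NA),
      same_family_alu = c("Alu", "Alu"),
      same_family_l1 = c("L1", "L1"),
      different_family = c("Alu", "DNA"),
      one_side = c("L1", NA))
    repeat_prox <- fams[1]; repeat_dist <- fams[2]
  }
  mh_len <- as.integer(mh_len)
  if (mh_len < 0L || mh_len > 70L) {
    stop("mh_len must be in 0-70", call. = FALSE)
  }
  if (nzchar(insert_seq) && mh_len > 0L) {
    stop("an inserted sequence requires mh_len = 0", call. = FALSE)
  }
  if (size_bp <= mh_len + 20L) {
    stop("size_bp must exceed mh_len + 20", call. = FALSE)
  }
  tibble(size_bp = as.integer(size_bp), mh_len = mh_len,
         insert_seq = insert_seq, scar = scar,
         repeat_prox = repeat_prox, repeat_dist = repeat_dist,
         arm_divergence_pct = arm_divergence_pct, seed = as.integer(seed))
}

parse_scar <- function(scar) {
  if (is.na(scar) || !nzchar(scar)) return(NULL)
  if (grepl("^del\\(([ACGT])\\)$", scar)) {
    list(kind = "deletion", ref = sub("^del\\(([ACGT])\\)$", "\\1", scar),
         alt = "")
  } else if (grepl("^[ACGT]+>[ACGT]+$", scar)) {
    parts <- strsplit(scar, ">", fixed = TRUE)[[1]]
    if (nchar(parts[1]) != nchar(parts[2])) {
      stop("substitution scar must preserve length: ", scar, call. = FALSE)
    }
    list(kind = "substitution", ref = parts[1], alt = parts[2])
  } else {
    stop("unrecognized scar descriptor: ", scar, call. = FALSE)
  }
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

# Pick a 1-based breakpoint position honoring a family constraint.
pick_position <- function(repeats, fam, locus_len, margin, near = NULL,
                          min_pos = NULL, exclude_name = NULL) {
  if (!is.na(fam)) {
    cand <- repeats[repeats$family == fam &
                      repeats$start > margin &
                      repeats$end < locus_len - margin, , drop = FALSE]
    if (!is.null(min_pos)) cand <- cand[cand$end > min_pos, , drop = FALSE]
    if (!is.null(exclude_name)) {
      cand <- cand[cand$name != exclude_name, , drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      stop("no ", fam, " repeat available for planting", call. = FALSE)
    }
    if (!is.null(near)) {
      mid <- (cand$start + cand$end) / 2
      cand <- cand[order(abs(mid - near)), , drop = FALSE]
      cand <- cand[seq_len(min(3L, nrow(cand))), , drop = FALSE]
    }
    row <- cand[sample.int(nrow(cand), 1L), ]
    lo <- max(row$start + 1L, (min_pos %||% 0L) + 1L)
    if (lo > row$end) stop("planting window empty", call. = FALSE)
    list(pos = sample_one(seq(lo, row$end)), repeat_row = row)
  } else {
    for (i in seq_len(1000L)) {
      # widen the search window progressively so a repeat-dense
      # neighbourhood of the target position cannot trap the sampler
      jitter <- 200L + 20L * i
      pos <- if (!is.null(near)) {
        max(margin, min(locus_len - margin,
                        as.integer(near + sample_one(-jitter:jitter))))
      } else sample_one(seq(margin, locus_len - margin))
      if (!is.null(min_pos) && pos <= min_pos) next
      inside <- any(repeats$start < pos & repeats$end >= pos)
      if (!inside) return(list(pos = pos, repeat_row = NULL))
    }
    stop("could not place a repeat-free breakpoint", call. = FALSE)
  }
}

set_base_different <- function(current, avoid) {
  sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
}

#' Plant a deletion allele with a known junction signature
#'
#' Chooses breakpoints in the locus honoring the requested repeat context,
#' enforces exactly `mh_len` bases of identity immediately 5' of both
#' breakpoints by local editing of the emitted flanks (editing the bases
#' just outside the stretch so that no longer accidental microhomology
#' exists), applies any requested scar or insertion to the emitted junction
#' fragment, and verifies that [call_microhomology()] recovers the planted
#' signature exactly.
#'
#' @param locus A locus from [generate_locus()].
#' @param spec A one-row tibble from [deletion_spec()].
#' @param case_id Label for the planted case.
#' @return A list with `case` (a [junction_case()] row) and `truth` (spec
#'   echo plus realized coordinates, realized repeat identity, and the
#'   expected mechanism call).
#' @export
plant_deletion <- function(locus, spec, case_id = "sim") {
  ref <- locus$reference$seq[[1]]
  locus_len <- nchar(ref)
  repeats <- locus$repeats
  margin <- 200L
  half <- 75L
  with_seed(spec$seed, {
    same_fam <- !is.na(spec$repeat_prox) && !is.na(spec$repeat_dist) &&
      spec$repeat_prox == spec$repeat_dist
    dist <- NULL
    for (attempt in seq_len(50L)) {
      prox <- pick_position(repeats, spec$repeat_prox, locus_len, margin)
      dist <- tryCatch(
        pick_position(repeats, spec$repeat_dist, locus_len, margin,
                      near = prox$pos + spec$size_bp,
                      min_pos = prox$pos + spec$mh_len + 20L,
                      exclude_name = if (same_fam)
                        prox$repeat_row$name else NULL),
        error = function(e) NULL)
      if (!is.null(dist)) break
    }
    if (is.null(dist)) {
      stop("could not satisfy the repeat context after 50 site draws",
           call. = FALSE)
    }
    s <- prox$pos
    e <- dist$pos

    # synthesize diverged same-family arm copies when an identity target
    # is requested; overwrite the local working sequence at both footprints
    identity_real <- NA_integer_
    arm_seqs <- NULL
    if (same_fam && !is.null(prox$repeat_row) && !is.null(dist$repeat_row)) {
      if (!is.na(spec$arm_divergence_pct)) {
        cons <- locus$consensus[[spec$repeat_prox]]
        r <- spec$arm_divergence_pct / 200
        c1 <- mutate_sequence(cons, r)
        c2 <- mutate_sequence(cons, r)
        or1 <- if (prox$repeat_row$strand == "-") revcomp(c1) else c1
        or2 <- if (dist$repeat_row$strand == "-") revcomp(c2) else c2
        substr(ref, prox$repeat_row$start + 1L, prox$repeat_row$end) <- or1
        substr(ref, dist$repeat_row$start + 1L, dist$repeat_row$end) <- or2
        arm_seqs <- c(c1, c2)
      } else {
        arm_seqs <- c(
          substr(ref, prox$repeat_row$start + 1L, prox$repeat_row$end),
          substr(ref, dist$repeat_row$start + 1L, dist$repeat_row$end))
        if (prox$repeat_row$strand == "-") arm_seqs[1] <- revcomp(arm_seqs[1])
        if (dist$repeat_row$strand == "-") arm_seqs[2] <- revcomp(arm_seqs[2])
      }
      identity_real <- pairwise_identity(arm_seqs[1], arm_seqs[2])
    }

    P <- substr(ref, s - half + 1L, s + half)
    D <- substr(ref, e - half + 1L, e + half)
    mh <- spec$mh_len
    scar <- parse_scar(spec$scar)

    # pre-scar reference edits so scar ref alleles are truly present
    if (!is.null(scar)) {
      k <- nchar(scar$ref)
      tgt <- (half - mh - k + 1L):(half - mh)
      if (scar$kind == "deletion") tgt <- (half - mh):(half - mh) + mh
      substr(P, min(tgt), max(tgt)) <- scar$ref
    }

    # copy the microhomology stretch onto the distal flank
    if (mh > 0L) {
      substr(D, half - mh + 1L, half) <- substr(P, half - mh + 1L, half)
    }
    Pch <- seq_chars(P); Dch <- seq_chars(D)
    # block accidental extension on both sides of the planted stretch
    if (base_match(Pch[half - mh], Dch[half - mh])) {
      Dch[half - mh] <- set_base_different(Dch[half - mh],
                                           c(Pch[half - mh]))
    }
    if (base_match(Pch[half + 1L], Dch[half + 1L])) {
      Dch[half + 1L] <- set_base_different(Dch[half + 1L],
                                           c(Pch[half + 1L]))
    }
    P <- paste(Pch, collapse = ""); D <- paste(Dch, collapse = "")

    junction <- paste0(substr(P, 1L, half), substr(D, half + 1L, 2L * half))
    if (nzchar(spec$insert_seq)) {
      ins <- seq_chars(spec$insert_seq)
      if (base_match(ins[1], seq_chars(P)[half + 1L])) {
        ins[1] <- set_base_different(ins[1], seq_chars(P)[half + 1L])
      }
      if (base_match(ins[length(ins)], seq_chars(D)[half])) {
        ins[length(ins)] <- set_base_different(ins[length(ins)],
                                               seq_chars(D)[half])
      }
      junction <- paste0(substr(P, 1L, half), paste(ins, collapse = ""),
                         substr(D, half + 1L, 2L * half))
      spec$insert_seq <- paste(ins, collapse = "")
    }
    if (!is.null(scar)) {
      if (scar$kind == "deletion") {
        junction <- paste0(substr(junction, 1L, half - 1L),
                           substr(junction, half + 1L, nchar(junction)))
        # the base replacing the lost one must not resurrect the match
        Jch <- seq_chars(junction)
        if (base_match(Jch[half], seq_chars(P)[half])) {
          Dch <- seq_chars(D)
          Dch[half + 1L] <- set_base_different(Dch[half + 1L],
                                               c(seq_chars(P)[half],
                                                 seq_chars(P)[half + 1L]))
          D <- paste(Dch, collapse = "")
          junction <- paste0(substr(P, 1L, half - 1L),
                             substr(D, half + 1L, 2L * half))
        }
        # and the new junction boundary must not extend the suffix match
        if (base_match(seq_chars(P)[half - 1L], seq_chars(D)[half])) {
          Dch <- seq_chars(D)
          Dch[half] <- set_base_different(Dch[half],
                                          seq_chars(P)[half - 1L])
          D <- paste(Dch, collapse = "")
        }
      } else {
        k <- nchar(scar$ref)
        pos <- (half - mh - k + 1L):(half - mh)
        Jch <- seq_chars(junction)
        alt <- seq_chars(scar$alt)
        for (t in seq_along(pos)) {
          # alt must differ from both references at the scarred position
          bad <- c(seq_chars(P)[pos[t]], seq_chars(D)[pos[t]])
          Jch[pos[t]] <- if (alt[t] %in% bad[1]) {
            stop("scar alt equals the reference allele: ", spec$scar,
                 call. = FALSE)
          } else if (base_match(alt[t], bad[2])) {
            # distal flank edited instead so the alt allele is preserved
            Dch <- seq_chars(D)
            Dch[pos[t]] <- set_base_different(Dch[pos[t]],
                                              c(alt[t], seq_chars(P)[pos[t]]))
            D <- paste(Dch, collapse = "")
            alt[t]
          } else alt[t]
        }
        junction <- paste(Jch, collapse = "")
      }
    }

    case <- junction_case(case_id, P, half, D, half, junction)
    call <- call_microhomology(case)
    if (call$mh_len != mh ||
        !identical(call$inserted_seq, spec$insert_seq %||% "")) {
      stop("planting failed verification (accidental homology survived)",
           call. = FALSE)
    }
    fam_p <- spec$repeat_prox; fam_d <- spec$repeat_dist
    expected <- classify_mechanism(mh, scar_present = !is.na(spec$scar),
                                   repeat_prox_family = fam_p,
                                   repeat_dist_family = fam_d,
                                   identity_pct = identity_real)
    truth <- dplyr::bind_cols(
      tibble(case_id = case_id, start = s, end = e,
             size_bp_realized = e - s, identity_pct_realized = identity_real,
             expected_group = expected$group,
             expected_mechanism = expected$mechanism),
      spec)
    list(case = case, truth = truth)
  })
}

#' Generate a 24-deletion cohort mirroring the packaged fixture
#'
#' For every row of [load_foxl2_deletions()] a deletion is planted whose
#' junction realizes that row's microhomology length, scar and
#' repeat-superfamily context (with the printed repeat identity as the
#' divergence target for same-family pairs). Running the junction caller
#' and mechanism classifier on the cohort reproduces the fixture's
#' microhomology and mechanism columns; sequence context and deletion
#' sizes are synthetic.
#'
#' @param seed Integer seed.
#' @param locus Optional pre-built locus from [generate_locus()]; by
#'   default a 300-kb human-like locus is generated from `seed`.
#' @return A list with `cases` (24 junction cases), `truth` (one row per
#'   case) and `locus`.
#' @export
make_fixture_cohort <- function(seed = 1L, locus = NULL) {
  fx <- load_foxl2_deletions()
  if (is.null(locus)) {
    locus <- generate_locus(length = 3e5, gc = 0.41, repeat_density = 0.25,
                            seed = seed)
  }
  rows <- purrr::map(seq_len(nrow(fx)), function(i) {
    r <- fx[i, ]
    fam_p <- repeat_family(r$repeat_prox)
    fam_d <- repeat_family(r$repeat_dist)
    same <- !is.na(fam_p) && !is.na(fam_d) && fam_p == fam_d
    spec <- deletion_spec(
      size_bp = 5000L + 137L * i, mh_len = r$mh_len, scar = r$scar,
      repeat_prox = fam_p, repeat_dist = fam_d,
      arm_divergence_pct = if (same && !is.na(r$identity_pct))
        100 - r$identity_pct else NA_real_,
      seed = seed * 1000L + i)
    plant_deletion(locus, spec, case_id = r$patient_code)
  })
  list(cases = dplyr::bind_rows(purrr::map(rows, "case")),
       truth = dplyr::bind_rows(purrr::map(rows, "truth")),
       locus = locus)
}
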