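# Random control population and enrichment statistics. The control design
# follows the breakpoint-region convention: 150-bp sequences with an
# artificial breakpoint between nucleotides 75 and 76. Control
# microhomology needs two flanks, so region i is paired with region i + 1
# (cyclically) to form n pseudo-junctions with zero scar tolerance.

#' Sample a random control population of artificial breakpoint regions
#'
#' Draws `n` windows of `region_len` bp at uniform random positions from a
#' reference sequence set, rejecting windows containing `N`. Each window
#' becomes an artificial breakpoint region with the breakpoint at its
#' midpoint.
#'
#' @param reference A tibble with columns `id` and `seq` (e.g.
#'   `generate_locus()$reference`), or the locus list itself.
#' @param n Number of control regions (default 500).
#' @param seed Integer seed; the same seed reproduces the same regions.
#' @param region_len Region length (default 150).
#' @return A tibble of regions (`id`, `seq`, `breakpoint_offset`) with
#'   attributes `seed` and `source`.
#' @export
sample_control_regions <- function(reference, n = 500L, seed = 1L,
                                   region_len = 150L) {
  if (is.list(reference) && !is.data.frame(reference) &&
      !is.null(reference$reference)) {
    reference <- reference$reference
  }
  stopifnot(is.data.frame(reference),
            all(c("id", "seq") %in% names(reference)))
  lens <- nchar(reference$seq)
  if (sum(lens) < 10 * n * region_len) {
    stop("reference too short: need >= ", 10 * n * region_len,
         " bp to sample ", n, " control regions", call. = FALSE)
  }
  offset <- as.integer(region_len %/% 2L)
  with_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    tries <- 0L
    starts_ok <- pmax(lens - region_len + 1L, 0L)
    while (got < n) {
      tries <- tries + 1L
      if (tries > 50L * n) {
        stop("could not sample N-free control regions from the reference",
             call. = FALSE)
      }
      si <- sample_one(seq_along(lens))
      if (starts_ok[si] < 1L) next
      pos <- sample_one(seq_len(starts_ok[si]))
      win <- substr(reference$seq[si], pos, pos + region_len - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      got <- got + 1L
      out[[got]] <- tibble(id = sprintf("ctrl_%04d", got), seq = win,
                           breakpoint_offset = offset)
    }
    res <- dplyr::bind_rows(out)
    attr(res, "seed") <- seed
    attr(res, "source") <- paste(reference$id, collapse = ",")
    res
  })
}

#' Microhomology of control pseudo-junctions
#'
#' Joins the left flank of region i to the right flank of region i + 1
#' (cyclically) at the artificial breakpoint and calls microhomology with
#' zero scar tolerance, mirroring the treatment of the observed junctions.
#' For iid uniform sequence the microhomology length is the sum of two
#' geometric extensions, so P(mh = 0) = (3/4)^2 = 0.5625 and
#' P(mh <= 1) ~ 0.84 - the control distribution clusters at 0-1 bp.
#'
#' @param controls A region tibble from [sample_control_regions()].
#' @return Integer vector of microhomology lengths, one per pseudo-junction.
#' @export
control_microhomology <- function(controls) {
  n <- nrow(controls)
  stopifnot(n >= 2L)
  ob <- controls$breakpoint_offset
  vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    junction <- paste0(substr(controls$seq[i], 1L, ob[i]),
                       substr(controls$seq[j], ob[j] + 1L,
                              nchar(controls$seq[j])))
    call_one_junction(controls$seq[i], ob[i], controls$seq[j], ob[j],
                      junction, max_scar_mismatches = 0L)$mh_len
  }, integer(1))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p computed directly from the hypergeometric definition:
#' the sum over all tables with the observed margins whose point
#' probability does not exceed that of the observed table, accumulated in
#' log space. The odds ratio is the sample estimate `(a d) / (b c)`.
#'
#' @param a,b Observed population: count with / without the feature.
#' @param c,d Control population: count with / without the feature.
#' @return A one-row tibble: `odds_ratio`, `p_two_sided`.
#' @examples
#' fisher_exact_2x2(31, 17, 236, 264)  # repeat-element enrichment
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(tibble(odds_ratio = NA_real_, p_two_sided = 1))
  }
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  logd <- dhyper(support, m, n2, k, log = TRUE)
  lobs <- dhyper(a, m, n2, k, log = TRUE)
  p <- sum(exp(logd[logd <= lobs + 1e-7]))
  tibble(odds_ratio = or, p_two_sided = min(1, p))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. For combined sample sizes up
#' to 20 the p-value is computed by exact enumeration of all label
#' permutations (valid under ties); above that, the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) return(1)
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  if (n <= 20L) {
    mu <- length(x) * (n + 1) / 2
    sums <- colSums(matrix(r[utils::combn(n, length(x))],
                           nrow = length(x)))
    mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Bonferroni correction
#'
#' @param p P-value(s).
#' @param k Number of tests (>= 1).
#' @return `min(1, p * k)`, vectorized over `p`.
#' @export
bonferroni <- function(p, k) {
  stopifnot(k >= 1)
  pmin(1, p * k)
}

contingency_row <- function(label, a, b, c, d, correction = "none", k = 1) {
  ft <- fisher_exact_2x2(a, b, c, d)
  tibble(label = label, a = a, b = b, c = c, d = d,
         odds_ratio = ft$odds_ratio, p_two_sided = ft$p_two_sided,
         p_corrected = if (correction == "none") NA_real_
                       else bonferroni(ft$p_two_sided, k),
         correction = if (correction == "none") "none"
                      else paste0("bonferroni x", k))
}

# Distinct motif ids present per region, from a profile's motif_hits
# list-column (NULL when the profile has no nested hits).
motif_presence <- function(profiles) {
  if (!"motif_hits" %in% names(profiles)) return(NULL)
  purrr::map(profiles$motif_hits, function(h) unique(h$motif_id))
}

nonb_kinds <- function(profiles) {
  if (!"nonb_features" %in% names(profiles)) return(NULL)
  purrr::map(profiles$nonb_features, function(h) unique(h$kind))
}

#' Enrichment report: observed breakpoint regions vs random controls
#'
#' Runs the full battery of comparisons between an observed breakpoint
#' population and a random control population:
#' microhomology presence (Fisher) and distribution (Wilcoxon); repeat
#' intersection overall and per family (Alu, L1; Bonferroni over the
#' families tested); per-motif presence (Fisher, Bonferroni over the
#' catalogue size) and motif density (Wilcoxon); non-B-conformation
#' presence overall and per kind; and - when the observed profiles carry a
#' `deletion_class` column - the gene-encompassing vs regulatory subgroup
#' comparison of non-B presence.
#'
#' Profile tables need `motif_count` and `nonb_count` columns (one row per
#' breakpoint region); optional columns unlock further tests:
#' `repeat_family` (`NA` = no repeat at that breakpoint), `motif_hits` /
#' `nonb_features` list columns (from [scan_regions()]), `deletion_class`.
#'
#' @param profiles_observed,profiles_control Per-region profile tibbles.
#' @param mh_observed,mh_control Integer microhomology lengths per
#'   junction (observed) / pseudo-junction (control).
#' @return A `junction_enrichment` object: list with `tests` (contingency
#'   results), `densities` (rank-sum comparisons) and `mh` (the two
#'   microhomology samples). Use [tidy()], [glance()], [autoplot()].
#' @export
enrichment_report <- function(profiles_observed, profiles_control,
                              mh_observed, mh_control) {
  stopifnot(nrow(profiles_observed) > 0, nrow(profiles_control) > 0,
            length(mh_observed) > 0, length(mh_control) > 0)
  no <- nrow(profiles_observed); nc <- nrow(profiles_control)
  tests <- list()
  dens <- list()

  safe_ranksum <- function(x, y) {
    tryCatch(wilcoxon_rank_sum(x, y), error = function(e) NA_real_)
  }
  a <- sum(mh_observed >= 1); c0 <- sum(mh_control >= 1)
  tests$mh <- contingency_row("microhomology_presence",
                              a, length(mh_observed) - a,
                              c0, length(mh_control) - c0)
  dens$mh <- tibble(label = "microhomology_distribution",
                    p_two_sided = safe_ranksum(mh_observed, mh_control))

  if (all(c("repeat_family") %in% names(profiles_observed)) &&
      "repeat_family" %in% names(profiles_control)) {
    ro <- profiles_observed$repeat_family
    rc <- profiles_control$repeat_family
    tests$rep <- contingency_row("repeat_any",
                                 sum(!is.na(ro)), sum(is.na(ro)),
                                 sum(!is.na(rc)), sum(is.na(rc)))
    fam_tests <- c("Alu", "L1")
    for (f in fam_tests) {
      tests[[paste0("rep_", f)]] <- contingency_row(
        paste0("repeat_", f),
        sum(ro == f, na.rm = TRUE), sum(ro != f | is.na(ro)),
        sum(rc == f, na.rm = TRUE), sum(rc != f | is.na(rc)),
        correction = "bonferroni", k = length(fam_tests))
    }
  }

  mp_o <- motif_presence(profiles_observed)
  mp_c <- motif_presence(profiles_control)
  if (!is.null(mp_o) && !is.null(mp_c)) {
    ids <- sort(unique(c(unlist(mp_o), unlist(mp_c))))
    for (id in ids) {
      ao <- sum(purrr::map_lgl(mp_o, ~ id %in% .x))
      ac <- sum(purrr::map_lgl(mp_c, ~ id %in% .x))
      tests[[paste0("motif_", id)]] <- contingency_row(
        paste0("motif_", id), ao, no - ao, ac, nc - ac,
        correction = "bonferroni", k = length(ids))
    }
  }
  dens$motif <- tibble(label = "motif_density",
                       p_two_sided = safe_ranksum(
                         profiles_observed$motif_count,
                         profiles_control$motif_count))

  ao <- sum(profiles_observed$nonb_count >= 1)
  ac <- sum(profiles_control$nonb_count >= 1)
  tests$nonb <- contingency_row("nonb_any", ao, no - ao, ac, nc - ac)
  ko <- nonb_kinds(profiles_observed)
  kc <- nonb_kinds(profiles_control)
  if (!is.null(ko) && !is.null(kc)) {
    for (kind in sort(unique(c(unlist(ko), unlist(kc))))) {
      a1 <- sum(purrr::map_lgl(ko, ~ kind %in% .x))
      c1 <- sum(purrr::map_lgl(kc, ~ kind %in% .x))
      tests[[paste0("nonb_", kind)]] <- contingency_row(
        paste0("nonb_", kind), a1, no - a1, c1, nc - c1)
    }
  }

  if ("deletion_class" %in% names(profiles_observed)) {
    enc <- profiles_observed$deletion_class == "foxl2_encompassing"
    nb <- profiles_observed$nonb_count >= 1
    tests$subgroup <- contingency_row(
      "nonb_encompassing_vs_regulatory",
      sum(nb & enc), sum(!nb & enc), sum(nb & !enc), sum(!nb & !enc))
  }

  structure(list(tests = dplyr::bind_rows(tests),
                 densities = dplyr::bind_rows(dens),
                 mh = list(observed = mh_observed, control = mh_control)),
            class = "junction_enrichment")
}

#' @export
print.junction_enrichment <- function(x, ...) {
  cat("Breakpoint-region enrichment report\n")
  cat("  observed junctions:", length(x$mh$observed),
      " control pseudo-junctions:", length(x$mh$control), "\n\n")
  print(x$tests, n = nrow(x$tests))
  cat("\nDistribution comparisons (Wilcoxon rank-sum):\n")
  print(x$densities, n = nrow(x$densities))
  invisible(x)
}

#' @rdname enrichment_report
#' @param x A `junction_enrichment` object.
#' @param ... Unused.
#' @method tidy junction_enrichment
#' @export
tidy.junction_enrichment <- function(x, ...) x$tests

#' @rdname enrichment_report
#' @method glance junction_enrichment
#' @export
glance.junction_enrichment <- function(x, ...) {
  tibble(n_observed = length(x$mh$observed),
         n_control = length(x$mh$control),
         n_tests = nrow(x$tests),
         n_significant = sum(
           dplyr::coalesce(x$tests$p_corrected, x$tests$p_two_sided) < 0.05),
         mh_presence_p = x$tests$p_two_sided[
           x$tests$label == "microhomology_presence"],
         mh_distribution_p = x$densities$p_two_sided[
           x$densities$label == "microhomology_distribution"])
}

#' Per-breakpoint-region view of the packaged deletion fixture
#'
#' Reshapes the 24-deletion fixture into one row per breakpoint region
#' (48 rows): proximal and distal sides with their repeat element, repeat
#' superfamily, and the published motif and non-B counts. This is the
#' observed-side profile table for [enrichment_report()] when working from
#' the published values rather than from sequence.
#'
#' @param fixture The tibble from [load_foxl2_deletions()].
#' @return A 48-row tibble.
#' @export
fixture_breakpoint_profiles <- function(fixture = load_foxl2_deletions()) {
  long <- dplyr::bind_rows(
    dplyr::transmute(fixture,
      region_id = paste0(.data$patient_code, "_prox"),
      patient_code = .data$patient_code, side = "proximal",
      deletion_class = .data$deletion_class,
      repeat_name = .data$repeat_prox,
      motif_count = .data$motifs_prox, nonb_count = .data$nonb_prox),
    dplyr::transmute(fixture,
      region_id = paste0(.data$patient_code, "_dist"),
      patient_code = .data$patient_code, side = "distal",
      deletion_class = .data$deletion_class,
      repeat_name = .data$repeat_dist,
      motif_count = .data$motifs_dist, nonb_count = .data$nonb_dist))
  dplyr::mutate(long, repeat_family = repeat_family(.data$repeat_name))
}
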