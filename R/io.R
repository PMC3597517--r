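#' Read breakpoint regions from a FASTA file
#'
#' Reads nucleotide sequences and returns one row per record. The position of
#' the breakpoint inside each region can be encoded in the FASTA header as
#' `bp=K` (the breakpoint then lies between bases `K` and `K + 1`, 1-based);
#' when absent it defaults to `floor(length / 2)`, matching the convention of
#' a 150-bp region with the breakpoint between nucleotides 75 and 76.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` (uppercase, A/C/G/T/N) and
#'   `breakpoint_offset`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 bp=4", "ACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  },
                  # invalid sequence codes only warn in Biostrings; treat
                  # them as a format error rather than dropping bases
                  warning = function(w) {
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(w), call. = FALSE)
                  })
  if (length(set) == 0L) {
    return(tibble(id = character(), seq = character(),
                  breakpoint_offset = integer()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(set))
  bp <- stringr::str_match(headers, "\\bbp=(\\d+)\\b")[, 2]
  offset <- ifelse(is.na(bp), nchar(seqs) %/% 2L, as.integer(bp))
  out <- tibble(id = ids, seq = unname(seqs),
                breakpoint_offset = as.integer(offset))
  validate_regions(out)
  out
}

#' Write breakpoint regions to a FASTA file
#'
#' The inverse of [read_fasta()]: the breakpoint offset is stored in the
#' header as `bp=K` so that a round trip preserves all fields.
#'
#' @param regions A tibble with columns `id`, `seq`, `breakpoint_offset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(regions, path) {
  validate_regions(regions)
  set <- Biostrings::DNAStringSet(regions$seq)
  names(set) <- paste0(regions$id, " bp=", regions$breakpoint_offset)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Map a repeat name to its superfamily bucket
#'
#' Repeat names are bucketed into the superfamilies used for same-family
#' comparisons at deletion breakpoints: names beginning `Alu` -> `"Alu"`;
#' `L1` -> `"L1"`; `MIR` -> `"MIR"`; `LTR`, `MLT` or `THE` -> `"LTR"`;
#' `Tigger`, `Charlie` or `MER` (DNA transposons) -> `"DNA"`; anything else
#' -> `"Other"`. Under this mapping AluJo and AluSz are the *same* family
#' while L1PA4 and MIRb are different, which is the granularity at which
#' NAHR candidacy is judged.
#'
#' @param name Character vector of repeat names (e.g. `"AluSx3"`, `"L1PA4"`).
#' @return Character vector over `{Alu, L1, MIR, LTR, DNA, Other}`, `NA` for
#'   `NA` input.
#' @examples
#' repeat_family(c("AluSx3", "L1PA4", "Tigger15a", "Charlie1a", "FLAM"))
#' @export
repeat_family <- function(name) {
  dplyr::case_when(
    is.na(name) ~ NA_character_,
    stringr::str_starts(name, "Alu") ~ "Alu",
    stringr::str_starts(name, "L1") ~ "L1",
    stringr::str_starts(name, "MIR") ~ "MIR",
    stringr::str_starts(name, "LTR|MLT|THE") ~ "LTR",
    stringr::str_starts(name, stringr::regex("Tigger|Charlie|MER",
                                             ignore_case = FALSE)) ~ "DNA",
    TRUE ~ "Other"
  )
}

#' Read repeat annotations (RepeatMasker `.out` or BED6)
#'
#' Parses either the standard 15-column RepeatMasker `.out` format (three
#' header lines, 1-based inclusive coordinates) or 6-column BED (0-based
#' half-open, repeat name in column 4). Coordinates are returned 0-based
#' half-open in both cases; the superfamily bucket is assigned with
#' [repeat_family()].
#'
#' @param path Path to a `.out` or BED file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `family`, `strand`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), family = character(),
                  strand = character()))
  }
  first <- trimws(lines[nonempty[1]])
  is_out <- grepl("^SW\\b|^score\\b", first, ignore.case = TRUE)
  if (is_out) {
    body <- nonempty[-seq_len(min(2L, length(nonempty)))]
    rows <- purrr::map(body, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 14L || is.na(suppressWarnings(as.integer(f[6]))) ||
          is.na(suppressWarnings(as.integer(f[7])))) {
        stop("unparseable RepeatMasker line ", i, ": '", lines[i], "'",
             call. = FALSE)
      }
      tibble(chrom = f[5],
             start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
             name = f[10],
             strand = if (f[9] %in% c("C", "-")) "-" else "+")
    })
    out <- dplyr::bind_rows(rows)
  } else {
    rows <- purrr::map(nonempty, function(i) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) == 1L) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 4L || is.na(suppressWarnings(as.integer(f[2]))) ||
          is.na(suppressWarnings(as.integer(f[3])))) {
        stop("unparseable BED line ", i, ": '", lines[i], "'", call. = FALSE)
      }
      tibble(chrom = f[1],
             start = as.integer(f[2]), end = as.integer(f[3]),
             name = f[4],
             strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6]
                      else "+")
    })
    out <- dplyr::bind_rows(rows)
  }
  if (any(out$end <= out$start)) {
    stop("repeat feature with end <= start in ", path, call. = FALSE)
  }
  has_chr <- stringr::str_starts(out$chrom, "chr")
  if (length(unique(has_chr)) > 1L) {
    warning("mixed chromosome naming styles in ", path,
            " (possible mixed assemblies)", call. = FALSE)
  }
  out$family <- repeat_family(out$name)
  out[c("chrom", "start", "end", "name", "family", "strand")]
}

# Byte-level checksum of the packaged fixture (sum of UTF-8 code points of
# the file contents). Guards against silent edits to the curated table.
.fixture_checksum <- 154236L

#' Load the curated table of 24 fine-mapped FOXL2-locus microdeletions
#'
#' Returns the packaged fixture describing 24 non-recurrent microdeletions
#' of the FOXL2 locus delineated at base-pair resolution: 8 deletions of the
#' upstream regulatory domain (patient codes A-H) and 16 deletions
#' encompassing FOXL2 itself (codes 1-16). Per deletion it records the hg19
#' breakpoint positions, junction microhomology length (`mh_len`, 0 for a
#' perfect transition), any information scar (`scar`, e.g. `"del(T)"`,
#' `"TC>AA"`), the repeat element intersecting each breakpoint, per-region
#' sequence-motif and non-B-conformation counts, the percent identity
#' between same-family repeats, and the published candidate mechanism
#' string.
#'
#' @param path Path to the fixture TSV; defaults to the packaged copy.
#' @return A tibble with 24 rows.
#' @examples
#' fx <- load_foxl2_deletions()
#' table(fx$deletion_class)
#' @export
load_foxl2_deletions <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    path <- system.file("extdata", "foxl2_deletions.tsv",
                        package = "junctionsig", mustWork = TRUE)
  }
  if (default) {
    chk <- sum(utf8ToInt(paste(readLines(path, warn = FALSE),
                               collapse = "\n"))) %% 1000000L
    if (chk != .fixture_checksum) {
      stop("packaged deletion fixture failed its checksum (",
           chk, " != ", .fixture_checksum, "); the file was modified",
           call. = FALSE)
    }
  }
  fx <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = "character")
  fx <- as_tibble(fx)
  int_cols <- c("start_hg19", "end_hg19", "size_kb", "mh_len",
                "motifs_prox", "nonb_prox", "motifs_dist", "nonb_dist",
                "identity_pct")
  fx[int_cols] <- lapply(fx[int_cols], as.integer)
  stopifnot(nrow(fx) == 24L, all(fx$end_hg19 > fx$start_hg19))
  if (!all(round((fx$end_hg19 - fx$start_hg19) / 1000) == fx$size_kb)) {
    stop("fixture sizes inconsistent with coordinates", call. = FALSE)
  }
  alpha <- grepl("^[A-Z]$", fx$patient_code)
  if (!all(alpha == (fx$deletion_class == "regulatory"))) {
    stop("fixture deletion_class inconsistent with patient codes",
         call. = FALSE)
  }
  fx
}

#' Load a sequence-motif catalogue
#'
#' Reads a TSV catalogue of IUPAC motif patterns used by [scan_motifs()].
#' The packaged default is a documented catalogue of well-known
#' rearrangement-associated motifs (chi-like element, translin target sites,
#' immunoglobulin class-switch repeats, V(D)J recombination signal
#' sequences, topoisomerase I/II cleavage consensi, polymerase pause and
#' deletion-hotspot consensi, A-tract, alternating purine-pyrimidine tract,
#' minisatellite core). Any catalogue in the same schema can be supplied, so
#' a different published motif set can be dropped in unchanged.
#'
#' @param path Path to a catalogue TSV; defaults to the packaged catalogue.
#' @return A tibble with columns `motif_id`, `name`, `pattern` (IUPAC) and
#'   `search_both_strands` (logical).
#' @examples
#' default_motif_catalogue()
#' @export
read_motif_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_catalogue.tsv",
                        package = "junctionsig", mustWork = TRUE)
  }
  cat <- as_tibble(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
  stopifnot(all(c("motif_id", "name", "pattern",
                  "search_both_strands") %in% names(cat)))
  cat$search_both_strands <- as.logical(cat$search_both_strands)
  bad <- !grepl(paste0("^[", paste(names(IUPAC_CODES), collapse = ""), "]+$"),
                cat$pattern)
  if (any(bad)) {
    stop("motif pattern(s) with non-IUPAC characters: ",
         paste(cat$motif_id[bad], collapse = ", "), call. = FALSE)
  }
  cat
}

#' @rdname read_motif_catalogue
#' @export
default_motif_catalogue <- function() read_motif_catalogue()
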