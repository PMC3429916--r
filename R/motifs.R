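#' Canonical representation of microsatellite repeat motifs
#'
#' Microsatellite loci are conventionally named by a single representative of
#' the equivalence class a repeat unit belongs to: a motif, all of its cyclic
#' rotations, and all rotations of its reverse complement describe the same
#' duplex repeat (an `(AC)n` tract is the same locus as a `(GT)n` tract read
#' from the other strand).  `canonical_motif()` maps every unit to the
#' lexicographically smallest string (A < C < G < T) among those candidates,
#' which is the class representative used throughout the package.
#'
#' @param motif Character vector of repeat units over the alphabet A/C/G/T,
#'   each 1 to 6 bases long.
#'
#' @return Character vector of canonical class representatives, same length
#'   as the input.
#'
#' @details The canonical form is idempotent and strand-symmetric:
#'   `canonical_motif(x) == canonical_motif(reverse_complement(x))` for every
#'   valid unit.
#'
#' @examples
#' canonical_motif(c("GT", "AC", "TC"))
#' @export
canonical_motif <- function(motif) {
  check_dna(motif, max_len = 6L)
  vapply(motif, function(m) {
    cands <- c(rotations(m), rotations(revcomp(m)))
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether a repeat unit is primitive
#'
#' A motif is primitive when it is not a whole-number power of a shorter
#' motif: `"AAC"` is primitive, `"ATAT"` is not (it is `"AT"` squared).
#' Tandem-repeat class counts are defined over primitive units only, so
#' non-primitive scanner hits are reduced to their primitive unit before
#' classification.
#'
#' @param motif Character vector of DNA strings.
#' @return Logical vector.
#' @examples
#' is_primitive(c("ATAT", "AAC", "AAAA"))
#' @export
is_primitive <- function(motif) {
  check_dna(motif)
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k %/% d) == m) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Reduce a motif to its primitive unit
#'
#' @param motif Character vector of DNA strings.
#' @return Character vector of the shortest unit whose tandem power equals
#'   the input.
#' @examples
#' primitive_unit("ACAC")
#' @export
primitive_unit <- function(motif) {
  check_dna(motif)
  vapply(motif, function(m) {
    k <- nchar(m)
    for (d in seq_len(k)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k %/% d) == m) {
        return(substr(m, 1L, d))
      }
    }
    m
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate the canonical motif classes of a given unit length
#'
#' Builds the complete, duplicate-free list of canonical primitive motifs of
#' length `unit_length` by exhaustive enumeration: every string over A/C/G/T
#' is generated, non-primitive strings are dropped, and the survivors are
#' bucketed by [canonical_motif()].  For unit lengths 2, 3 and 4 this yields
#' the familiar 4, 10 and 33 unique repeat-unit classes.
#'
#' @param unit_length Integer between 1 and 6.
#'
#' @return A tibble with one row per class: `canonical` (the representative),
#'   `at_count` (number of A/T bases) and `at_category` (the
#'   `[(A/T)_p, X_q]` composition label).
#'
#' @examples
#' enumerate_motif_classes(2)
#' nrow(enumerate_motif_classes(4))
#' @export
enumerate_motif_classes <- function(unit_length) {
  if (length(unit_length) != 1L || is.na(unit_length) ||
      unit_length != as.integer(unit_length) ||
      unit_length < 1L || unit_length > 6L) {
    abort("`unit_length` must be a single integer between 1 and 6.")
  }
  unit_length <- as.integer(unit_length)
  alph <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(alph), unit_length),
                    list(stringsAsFactors = FALSE)))
  all_strings <- do.call(paste0, grid)
  prim <- all_strings[is_primitive(all_strings)]
  classes <- sort(unique(canonical_motif(prim)))
  ar <- at_richness(classes)
  tibble::tibble(canonical = classes,
                 at_count = ar$at_count,
                 at_category = ar$at_category)
}

#' A/T content category of a repeat unit
#'
#' Labels a motif by its base composition in the `[(A/T)_p, X_q]` notation,
#' where `p` is the number of A or T bases and `q` the number of C or G
#' bases.  AT-rich classes (at most one C/G base) dominate the
#' tri- to hexanucleotide repeat landscape of AT-rich genomes.
#'
#' @param motif Character vector of DNA strings.
#' @return A tibble with columns `motif`, `at_count` and `at_category`.
#' @examples
#' at_richness(c("AAC", "CCG", "AAT"))
#' @export
at_richness <- function(motif) {
  check_dna(motif)
  p <- vapply(strsplit(motif, "", fixed = TRUE),
              function(b) sum(b %in% c("A", "T")), integer(1))
  q <- nchar(motif) - p
  tibble::tibble(
    motif = motif,
    at_count = p,
    at_category = sprintf("[(A/T)_%d, X_%d]", p, q)
  )
}

# -- internal helpers --------------------------------------------------------

rotations <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(s)
  ss <- paste0(s, s)
  vapply(seq_len(k), function(i) substr(ss, i, i + k - 1L), character(1))
}

revcomp <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

check_dna <- function(x, max_len = NULL, arg = "motif") {
  if (!is.character(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty character vector.", arg))
  }
  bad <- is.na(x) | !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    abort(sprintf(
      "Invalid alphabet in `%s`: %s (only A, C, G, T are allowed).",
      arg, paste(unique(x[bad])[seq_len(min(3, length(unique(x[bad]))))],
                 collapse = ", ")
    ))
  }
  if (!is.null(max_len) && any(nchar(x) > max_len)) {
    abort(sprintf("`%s` must be at most %d bases long.", arg, max_len))
  }
  invisible(x)
}
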