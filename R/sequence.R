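#' Validate and canonicalize a DNA sequence
#'
#' Sequences are plain 5'->3' strings over the DNA alphabet ACGT
#' (case-insensitive; canonicalized to upper case). The nearest-neighbor
#' extinction model requires at least two bases. RNA (U) and IUPAC ambiguity
#' codes are rejected: the packaged parameter tables are DNA-only.
#'
#' @param x A single character string, or a character vector of length 1.
#' @return The canonical upper-case sequence string.
#' @examples
#' nt_seq("agGGttaGGG")
#' @export
nt_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`x` must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]", "", x))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid base '%s' at position %d (alphabet is ACGT; DNA only)",
      chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  if (nchar(s) < 2L) {
    stop("sequence must contain at least 2 bases", call. = FALSE)
  }
  s
}

#' Read a DNA sequence from a FASTA file
#'
#' @param path Path to a FASTA file. If the file holds several records, `which`
#'   selects one by index or name.
#' @param which Record index or name (default: first record).
#' @return A canonical sequence string (named with the FASTA header).
#' @export
read_sequence <- function(path, which = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  rec <- recs[[which]]
  out <- nt_seq(as.character(rec))
  names(out) <- attr(rec, "name")
  out
}

#' Enumerate nearest-neighbor doublets of a sequence
#'
#' Counts every adjacent base pair of the sequence plus the two terminal
#' doublets: the 5' terminus pairs as `E` + first base, the 3' terminus as
#' last base + `E` (e.g. a 3'-end A gives the doublet `AE`). A sequence of
#' `N_b` bases therefore yields `N_b + 1` doublets in total: `N_b - 1`
#' internal ones and the two terminal ones.
#'
#' @param seq A DNA sequence (string; validated with [nt_seq()]).
#' @return A tibble with columns `doublet` and `count`; the counts sum to
#'   `nchar(seq) + 1`.
#' @examples
#' enumerate_doublets("GGG") # EG:1, GG:2, GE:1
#' @export
enumerate_doublets <- function(seq) {
  s <- nt_seq(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  padded <- c("E", chars, "E")
  doublets <- paste0(padded[-length(padded)], padded[-1])
  tab <- table(doublets)
  tibble::tibble(
    doublet = names(tab),
    count = as.integer(tab)
  ) |>
    dplyr::arrange(.data$doublet)
}
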