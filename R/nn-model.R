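#' Extinction coefficient at 260 nm by the doublet-sum nearest-neighbor model
#'
#' Computes `eps260 = sum_ij N_ij * eps_ij` over all doublets of the
#' sequence, including the two terminal doublets with the terminus symbol
#' `E` (a 3'-end A contributes the doublet `AE`). `N_ij` are the doublet
#' counts from [enumerate_doublets()].
#'
#' @param seq DNA sequence (string).
#' @param table An `nn_table` (default: the packaged table).
#' @return Extinction coefficient at 260 nm (M^-1 cm^-1).
#' @seealso [eps260_classic()] for the traditional doublet-minus-monomer
#'   form; the two agree exactly when the table is built with
#'   [build_table_from_classic()].
#' @export
eps260_nn <- function(seq, table = default_nn_table()) {
  stopifnot(inherits(table, "nn_table"))
  counts <- enumerate_doublets(seq)
  missing <- setdiff(counts$doublet, names(table$eps260))
  if (length(missing) > 0) {
    stop("parameter table lacks doublet(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(counts$count * table$eps260[counts$doublet])
}

#' Extinction coefficient at 260 nm by the classic formula
#'
#' The traditional single-strand formula: sum of the 16 internal doublet
#' coefficients along the sequence minus the sum of the monomer coefficients
#' of all bases except the two termini.
#'
#' @param seq DNA sequence (string).
#' @param doublet_eps Named numeric vector of 16 internal doublet
#'   coefficients at 260 nm (M^-1 cm^-1).
#' @param monomer_eps Named numeric vector of 4 monomer coefficients.
#' @return Extinction coefficient at 260 nm (M^-1 cm^-1).
#' @export
eps260_classic <- function(seq, doublet_eps, monomer_eps) {
  s <- nt_seq(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  doublets <- paste0(chars[-n], chars[-1])
  missing <- setdiff(doublets, names(doublet_eps))
  if (length(missing) > 0) {
    stop("doublet_eps lacks doublet(s): ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  inner <- chars[seq.int(2L, max(2L, n - 1L))]
  if (n == 2L) inner <- character(0)
  if (!all(inner %in% names(monomer_eps))) {
    stop("monomer_eps must cover all bases in the sequence", call. = FALSE)
  }
  sum(doublet_eps[doublets]) - sum(monomer_eps[inner])
}

#' Calculated unfolded-state extinction spectrum
#'
#' Produces the full unfolded-state (single-strand) molar extinction
#' spectrum of a sequence by scaling its nearest-neighbor `eps260` with the
#' doublet ratio curves, weighted by the doublet fractions:
#' `eps(lambda) = eps260 * sum_ij (N_ij / (N_b + 1)) * R_ij(lambda)`,
#' where `N_b` is the sequence length and `N_b + 1` the total doublet count.
#' Because every `R_ij(260) = 1` after table validation, the value at
#' 260 nm equals [eps260_nn()] exactly.
#'
#' @param seq DNA sequence (string).
#' @param table An `nn_table`.
#' @param wavelengths Numeric grid (nm) within the table's ratio grid;
#'   default 220-350 nm in 1 nm steps.
#' @return A [spectrum_tbl] in molar extinction units.
#' @examples
#' sp <- unfolded_spectrum("AGGGTTAGGGTTAGGGTTAGGG")
#' sp[sp$wavelength == 260, ]
#' @export
unfolded_spectrum <- function(seq, table = default_nn_table(),
                              wavelengths = 220:350) {
  stopifnot(inherits(table, "nn_table"))
  s <- nt_seq(seq)
  counts <- enumerate_doublets(s)
  e260 <- eps260_nn(s, table)
  nb <- nchar(s)
  R <- ratio_at(table, wavelengths)          # doublets x lambda
  # dividing the integer-weighted ratio sum once keeps eps(260) == eps260
  # exactly: sum_ij N_ij * R_ij(260) = N_b + 1 with no rounding
  weighted <- as.numeric(crossprod(R[counts$doublet, , drop = FALSE],
                                   counts$count))
  values <- e260 * (weighted / (nb + 1))
  spectrum_tbl(wavelengths, values, unit = "molar_extinction",
               name = if (!is.null(names(seq))) names(seq) else s)
}
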