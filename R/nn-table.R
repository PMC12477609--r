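#' @keywords internal
nn_bases <- c("A", "C", "G", "T")

#' All 24 doublet labels of the nearest-neighbor model
#'
#' The 16 internal doublets over ACGT plus the 8 terminal doublets involving
#' the terminus symbol `E` (`EA` ... `ET`, `AE` ... `TE`). `EE` does not occur.
#'
#' @return Character vector of 24 doublet labels.
#' @export
nn_doublets <- function() {
  internal <- as.vector(outer(nn_bases, nn_bases, paste0))
  c(internal, paste0("E", nn_bases), paste0(nn_bases, "E"))
}

#' Classic nucleotide extinction coefficients at 260 nm
#'
#' The published single-strand DNA nearest-neighbor extinction parameters
#' at 260 nm (M^-1 cm^-1): 16 doublet coefficients and 4 monomer
#' coefficients, as used in the traditional doublet-minus-monomer formula.
#'
#' @return A list with named numeric vectors `doublet` (16 values) and
#'   `monomer` (4 values).
#' @export
classic_dna_extinctions <- function() {
  doublet <- c(
    AA = 27400, AC = 21200, AG = 25000, AT = 22800,
    CA = 21200, CC = 14600, CG = 18000, CT = 15200,
    GA = 25200, GC = 17600, GG = 21600, GT = 20000,
    TA = 23400, TC = 16200, TG = 19000, TT = 16800
  )
  monomer <- c(A = 15400, C = 7400, G = 11500, T = 8700)
  list(doublet = doublet, monomer = monomer)
}

#' Construct a nearest-neighbor parameter table
#'
#' Builds and validates the table used by [eps260_nn()] and
#' [unfolded_spectrum()]: one extinction coefficient at 260 nm per doublet
#' (including terminal `E` doublets) and one wavelength-dependent,
#' dimensionless scaling ratio curve R(lambda) per doublet.
#'
#' Validation normalizes each ratio curve so that R(260) = 1 exactly (this
#' preserves the 260 nm extinction for any drop-in table); a warning is
#' emitted if the input deviates from 1 by more than 1%.
#'
#' @param eps260 Named numeric vector over all 24 doublets (M^-1 cm^-1).
#' @param wavelength Strictly increasing numeric grid (nm) covering at least
#'   220-350 nm.
#' @param ratios Numeric matrix, one row per doublet (rownames = doublet
#'   labels), one column per wavelength.
#' @param monomer_eps260 Optional named numeric vector of the 4 classic
#'   monomer coefficients (kept for reference).
#' @return An object of class `nn_table`.
#' @export
new_nn_table <- function(eps260, wavelength, ratios, monomer_eps260 = NULL) {
  need <- nn_doublets()
  missing <- setdiff(need, names(eps260))
  if (length(missing) > 0) {
    stop("missing eps260 parameter for doublet(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eps260 <- eps260[need]
  internal <- need[!grepl("E", need)]
  if (any(eps260[internal] < 0)) {
    stop("internal doublet eps260 values must be >= 0", call. = FALSE)
  }
  wavelength <- as.numeric(wavelength)
  if (any(diff(wavelength) <= 0)) {
    stop("ratio wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (min(wavelength) > 220 || max(wavelength) < 350) {
    stop("ratio grid must cover at least 220-350 nm", call. = FALSE)
  }
  if (!all(need %in% rownames(ratios))) {
    stop("ratio matrix must have one row per doublet", call. = FALSE)
  }
  ratios <- ratios[need, , drop = FALSE]
  if (ncol(ratios) != length(wavelength)) {
    stop("ratio matrix columns must match the wavelength grid", call. = FALSE)
  }
  if (any(!is.finite(ratios)) || any(ratios < 0)) {
    stop("ratio values must be finite and non-negative", call. = FALSE)
  }
  # normalize so R(260) = 1 exactly for every doublet
  r260 <- apply(ratios, 1L, function(r) stats::approx(wavelength, r, 260)$y)
  if (any(abs(r260 - 1) > 0.01)) {
    warning("ratio curves deviate from 1 at 260 nm by more than 1%; ",
            "renormalizing so R(260) = 1", call. = FALSE)
  }
  ratios <- sweep(ratios, 1L, r260, "/")
  structure(
    list(eps260 = eps260, wavelength = wavelength, ratios = ratios,
         monomer_eps260 = monomer_eps260),
    class = "nn_table"
  )
}

#' @export
print.nn_table <- function(x, ...) {
  cat(sprintf(
    "<nn_table> 24 doublets, ratio grid %g-%g nm (%d points)\n",
    min(x$wavelength), max(x$wavelength), length(x$wavelength)
  ))
  invisible(x)
}

#' Bridge classic 260 nm parameters to the doublet-sum form
#'
#' The traditional 260 nm formula sums doublet coefficients and subtracts the
#' inner monomer coefficients. The equivalent pure doublet-sum form (with
#' terminal `E` doublets) uses
#' `eps'_ij = eps_ij - (eps_i + eps_j)/2` for internal doublets and
#' `eps'_Ei = eps'_iE = eps_i / 2` for terminal ones; the two formulas agree
#' exactly for every sequence.
#'
#' @param doublet_eps Named numeric vector of the 16 internal doublet
#'   coefficients at 260 nm.
#' @param monomer_eps Named numeric vector of the 4 monomer coefficients.
#' @param wavelength,ratios Ratio grid and matrix as in [new_nn_table()].
#' @param monomer_keep Keep the monomer coefficients on the table (default
#'   TRUE), so the classic formula can be re-derived.
#' @return An `nn_table`.
#' @export
build_table_from_classic <- function(doublet_eps, monomer_eps,
                                     wavelength, ratios,
                                     monomer_keep = TRUE) {
  internal <- nn_doublets()[!grepl("E", nn_doublets())]
  if (!all(internal %in% names(doublet_eps))) {
    stop("doublet_eps must provide all 16 internal doublets", call. = FALSE)
  }
  if (!all(nn_bases %in% names(monomer_eps))) {
    stop("monomer_eps must provide A, C, G and T", call. = FALSE)
  }
  eps <- numeric(0)
  for (d in internal) {
    i <- substr(d, 1, 1); j <- substr(d, 2, 2)
    eps[d] <- doublet_eps[[d]] - (monomer_eps[[i]] + monomer_eps[[j]]) / 2
  }
  for (b in nn_bases) {
    eps[paste0("E", b)] <- monomer_eps[[b]] / 2
    eps[paste0(b, "E")] <- monomer_eps[[b]] / 2
  }
  new_nn_table(eps, wavelength, ratios,
               monomer_eps260 = if (monomer_keep) monomer_eps[nn_bases])
}

#' Read a nearest-neighbor parameter table from delimited text
#'
#' Expected layout (tab- or comma-separated, autodetected): one row per
#' doublet; first column the doublet label, second column the 260 nm
#' extinction coefficient, then one column per wavelength (numeric nm
#' header) holding the scaling ratio R(lambda). This mirrors the layout of
#' publicly deposited parameter tables, which can be dropped in unchanged.
#'
#' @param path Path to the table file.
#' @return An `nn_table`.
#' @export
read_nn_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("parameter table needs doublet, eps260 and ratio columns",
                         call. = FALSE)
  doublet <- as.character(df[[1]])
  eps260 <- as.numeric(df[[2]])
  names(eps260) <- doublet
  wl_names <- names(df)[-(1:2)]
  wavelength <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wavelength))) {
    stop("ratio column headers must be numeric wavelengths (nm)", call. = FALSE)
  }
  ratios <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(ratios) <- doublet
  new_nn_table(eps260, wavelength, ratios)
}

#' Write a nearest-neighbor parameter table to delimited text
#'
#' @param table An `nn_table`.
#' @param path Output path (tab-separated).
#' @export
write_nn_table <- function(table, path) {
  stopifnot(inherits(table, "nn_table"))
  df <- data.frame(doublet = names(table$eps260),
                   eps260 = unname(table$eps260),
                   check.names = FALSE)
  rat <- as.data.frame(table$ratios)
  names(rat) <- as.character(table$wavelength)
  utils::write.table(cbind(df, rat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.quadsig_cache <- new.env(parent = emptyenv())

#' The packaged default nearest-neighbor table
#'
#' Built from the published classic monomer/doublet 260 nm extinction
#' coefficients (see [classic_dna_extinctions()]) combined with synthetic
#' ratio curves derived from Gaussian band models of the four
#' deoxynucleotide absorption spectra, normalized to 1 at 260 nm. The ratio
#' shapes are a constructed stand-in, adequate for method development and
#' simulation; for quantitative work, drop in an experimentally derived
#' table via [read_nn_table()].
#'
#' @return An `nn_table`.
#' @export
default_nn_table <- function() {
  if (is.null(.quadsig_cache$default_table)) {
    path <- system.file("extdata", "nn_table_synthetic.tsv",
                        package = "quadsig", mustWork = TRUE)
    .quadsig_cache$default_table <- read_nn_table(path)
  }
  .quadsig_cache$default_table
}

# Interpolate ratio curves at arbitrary wavelengths (linear; errors outside
# the tabulated grid).
ratio_at <- function(table, lambda) {
  rng <- range(table$wavelength)
  if (any(lambda < rng[1] - 1e-9) || any(lambda > rng[2] + 1e-9)) {
    stop(sprintf("wavelength outside the ratio grid (%g-%g nm)",
                 rng[1], rng[2]), call. = FALSE)
  }
  out <- apply(table$ratios, 1L, function(r) {
    stats::approx(table$wavelength, r, lambda, rule = 1)$y
  })
  # apply() returns a vector when length(lambda) == 1
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(out)))
  t(out) # doublets x lambda
}
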