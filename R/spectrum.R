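#' Spectrum containers
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly
#' increasing) and `value`, carrying a unit tag plus acquisition metadata
#' (pathlength in cm, strand concentration in M, analyte name, salt
#' condition) as attributes. Unit-aware conversions refuse mismatched tags.
#'
#' @param wavelength Numeric vector (nm).
#' @param value Numeric vector, same length.
#' @param unit One of `"absorbance"` (AU), `"molar_extinction"`
#'   (M^-1 cm^-1), `"ellipticity"` (mdeg), `"molar_ellipticity"`
#'   (delta-epsilon, M^-1 cm^-1).
#' @param pathlength_cm,conc_M,name,salt Optional metadata.
#' @return A tibble of class `spectrum_tbl`.
#' @export
spectrum_tbl <- function(wavelength, value,
                         unit = c("absorbance", "molar_extinction",
                                  "ellipticity", "molar_ellipticity"),
                         pathlength_cm = NULL, conc_M = NULL,
                         name = NULL, salt = NULL) {
  unit <- match.arg(unit)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (anyNA(wavelength) || anyNA(value)) {
    stop("spectra must not contain missing values", call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    o <- order(wavelength)
    wavelength <- wavelength[o]
    value <- value[o]
    if (anyDuplicated(wavelength)) {
      stop("duplicated wavelengths in spectrum", call. = FALSE)
    }
  }
  out <- tibble::tibble(wavelength = wavelength, value = value)
  class(out) <- c("spectrum_tbl", class(out))
  attr(out, "unit") <- unit
  attr(out, "pathlength_cm") <- pathlength_cm
  attr(out, "conc_M") <- conc_M
  attr(out, "name") <- name
  attr(out, "salt") <- salt
  out
}

#' @rdname spectrum_tbl
#' @param x A spectrum.
#' @export
spec_unit <- function(x) attr(x, "unit")

#' @export
print.spectrum_tbl <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %g-%g nm (%d points)%s\n",
              spec_unit(x), min(x$wavelength), max(x$wavelength), nrow(x),
              if (!is.null(attr(x, "name"))) paste0(" - ", attr(x, "name")) else ""))
  NextMethod()
}

# carry a spectrum's class/attributes onto new values (same grid)
respec <- function(x, value, unit = spec_unit(x)) {
  out <- spectrum_tbl(x$wavelength, value, unit = unit,
                      pathlength_cm = attr(x, "pathlength_cm"),
                      conc_M = attr(x, "conc_M"),
                      name = attr(x, "name"), salt = attr(x, "salt"))
  out
}

check_unit <- function(x, unit) {
  if (!identical(spec_unit(x), unit)) {
    stop(sprintf("spectrum unit is '%s' but '%s' is required",
                 spec_unit(x), unit), call. = FALSE)
  }
  invisible(x)
}

check_lc <- function(l, C) {
  if (!is.numeric(l) || length(l) != 1 || !is.finite(l) || l <= 0) {
    stop("pathlength l must be a single positive number (cm)", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1 || !is.finite(C) || C <= 0) {
    stop("concentration C must be a single positive number (M)", call. = FALSE)
  }
}

#' Convert an absorbance spectrum to molar extinction coefficients
#'
#' `eps(lambda) = A(lambda) / (l * C)` with pathlength `l` (cm) and strand
#' concentration `C` (M). This puts spectra of different concentrations and
#' cells on a common molar scale.
#'
#' @param spec A spectrum in absorbance units.
#' @param l Pathlength (cm); defaults to the spectrum metadata.
#' @param C Strand concentration (M); defaults to the spectrum metadata.
#' @return A spectrum in molar extinction units (M^-1 cm^-1).
#' @export
absorbance_to_molar <- function(spec, l = attr(spec, "pathlength_cm"),
                                C = attr(spec, "conc_M")) {
  check_unit(spec, "absorbance")
  check_lc(l, C)
  out <- respec(spec, spec$value / (l * C), unit = "molar_extinction")
  attr(out, "pathlength_cm") <- l
  attr(out, "conc_M") <- C
  out
}

#' Convert molar extinction back to absorbance
#'
#' Inverse of [absorbance_to_molar()]: `A = eps * l * C`.
#'
#' @inheritParams absorbance_to_molar
#' @param spec A spectrum in molar extinction units.
#' @export
molar_to_absorbance <- function(spec, l = attr(spec, "pathlength_cm"),
                                C = attr(spec, "conc_M")) {
  check_unit(spec, "molar_extinction")
  check_lc(l, C)
  out <- respec(spec, spec$value * l * C, unit = "absorbance")
  attr(out, "pathlength_cm") <- l
  attr(out, "conc_M") <- C
  out
}

#' Convert CD ellipticities to molar ellipticities
#'
#' `delta_eps = theta / (32980 * l * C)` with `theta` in millidegrees
#' (standard spectropolarimeter output), pathlength `l` (cm) and strand
#' concentration `C` (M).
#'
#' @param spec A spectrum in ellipticity (mdeg) units.
#' @inheritParams absorbance_to_molar
#' @return A spectrum in molar ellipticity units (M^-1 cm^-1).
#' @export
cd_to_molar <- function(spec, l = attr(spec, "pathlength_cm"),
                        C = attr(spec, "conc_M")) {
  check_unit(spec, "ellipticity")
  check_lc(l, C)
  out <- respec(spec, spec$value / (32980 * l * C), unit = "molar_ellipticity")
  attr(out, "pathlength_cm") <- l
  attr(out, "conc_M") <- C
  out
}

#' Subtract a flat baseline estimated from a transparent window
#'
#' Subtracts the mean signal over a wavelength window where nucleic acids do
#' not absorb (default 320-350 nm) from the whole spectrum. Idempotent.
#'
#' @param spec A spectrum.
#' @param window Length-2 numeric range (nm) inside the spectrum range.
#' @return The baseline-corrected spectrum (same unit).
#' @export
baseline_correct <- function(spec, window = c(320, 350)) {
  stopifnot(inherits(spec, "spectrum_tbl"))
  window <- sort(as.numeric(window))
  sel <- spec$wavelength >= window[1] & spec$wavelength <= window[2]
  if (!any(sel)) {
    stop(sprintf("baseline window %g-%g nm contains no data points",
                 window[1], window[2]), call. = FALSE)
  }
  respec(spec, spec$value - mean(spec$value[sel]))
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; exact at shared nodes. Extrapolation outside the
#' spectrum range is refused. Used to put e.g. 0.5 nm pitch CD data and
#' 1 nm step UV data onto a common grid.
#'
#' @param spec A spectrum.
#' @param grid Numeric target grid (nm), inside the spectrum range.
#' @return The resampled spectrum (same unit and metadata).
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum_tbl"))
  grid <- as.numeric(grid)
  if (min(grid) < min(spec$wavelength) - 1e-9 ||
      max(grid) > max(spec$wavelength) + 1e-9) {
    stop("resampling grid extends beyond the spectrum range (no extrapolation)",
         call. = FALSE)
  }
  v <- stats::approx(spec$wavelength, spec$value, grid, rule = 1)$y
  spectrum_tbl(grid, v, unit = spec_unit(spec),
               pathlength_cm = attr(spec, "pathlength_cm"),
               conc_M = attr(spec, "conc_M"),
               name = attr(spec, "name"), salt = attr(spec, "salt"))
}

#' Estimate strand concentration from 260 nm absorbance
#'
#' Convenience estimate `C = A260 / (eps260 * l)` using the
#' nearest-neighbor `eps260` of the sequence. Valid only for spectra of the
#' unfolded state (no folding cation present); the returned value is an
#' estimate, and determining the effective concentration remains the user's
#' responsibility.
#'
#' @param spec An absorbance spectrum containing 260 nm.
#' @param seq DNA sequence (string).
#' @param l Pathlength (cm).
#' @param table An `nn_table`.
#' @return Estimated concentration (M).
#' @export
estimate_concentration <- function(spec, seq, l = attr(spec, "pathlength_cm"),
                                   table = default_nn_table()) {
  check_unit(spec, "absorbance")
  if (is.null(l)) stop("pathlength l is required", call. = FALSE)
  a260 <- stats::approx(spec$wavelength, spec$value, 260, rule = 1)$y
  if (is.na(a260)) stop("spectrum does not cover 260 nm", call. = FALSE)
  a260 / (eps260_nn(seq, table) * l)
}

#' Read spectra from delimited text
#'
#' Supports two layouts (comma or tab separated, autodetected):
#' long — two columns, wavelength and value; wide — first column wavelength,
#' one column per sample. Header comment lines of the form `# key: value`
#' supply metadata (`unit`, `pathlength_cm`, `conc_M`, `name`, `salt`).
#' Descending wavelength input is sorted ascending.
#'
#' @param path Input file.
#' @param unit Unit tag applied if the file does not declare one.
#' @return A single spectrum (long layout) or a named list of spectra
#'   (wide layout).
#' @export
read_spectrum <- function(path, unit = "absorbance") {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells in spectrum file ", path, call. = FALSE)
  }
  unit <- meta$unit %||% unit
  l <- if (!is.null(meta$pathlength_cm)) as.numeric(meta$pathlength_cm)
  C <- if (!is.null(meta$conc_M)) as.numeric(meta$conc_M)
  mk <- function(vals, nm) {
    spectrum_tbl(df[[1]], vals, unit = unit, pathlength_cm = l, conc_M = C,
                 name = nm, salt = meta$salt)
  }
  if (ncol(df) == 2) {
    mk(df[[2]], meta$name %||% names(df)[2])
  } else {
    out <- lapply(names(df)[-1], function(nm) mk(df[[nm]], nm))
    stats::setNames(out, names(df)[-1])
  }
}

#' Write a spectrum to delimited text (long layout)
#'
#' Metadata are written as `# key: value` header comments; a write/read
#' round trip preserves values exactly.
#'
#' @param spec A spectrum.
#' @param path Output file.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_tbl"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", spec_unit(spec)), con)
  for (key in c("pathlength_cm", "conc_M", "name", "salt")) {
    v <- attr(spec, key)
    if (!is.null(v)) writeLines(sprintf("# %s: %s", key, format(v, digits = 17)), con)
  }
  writeLines("wavelength\tvalue", con)
  writeLines(sprintf("%s\t%s",
                     format(spec$wavelength, digits = 17, trim = TRUE),
                     format(spec$value, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Bind several spectra into one long tibble
#'
#' @param spectra A (named) list of spectra on a common grid.
#' @param names Optional sample names (default: list names or spectrum
#'   `name` attributes).
#' @return Tibble with columns `sample`, `wavelength`, `value`.
#' @export
bind_spectra <- function(spectra, names = NULL) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  nms <- names %||% base::names(spectra) %||%
    vapply(spectra, function(s) attr(s, "name") %||% NA_character_, character(1))
  if (anyNA(nms)) stop("every spectrum needs a name", call. = FALSE)
  purrr::map2_dfr(spectra, nms, function(s, nm) {
    tibble::tibble(sample = nm, wavelength = s$wavelength, value = s$value)
  })
}
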