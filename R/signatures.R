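#' Difference signature between unfolded and folded molar spectra
#'
#' `delta_eps(lambda) = eps_unfolded(lambda) - eps_folded(lambda)`. Both
#' spectra must share the wavelength grid and be in molar extinction units;
#' resample explicitly first if the grids differ.
#'
#' @param unfolded,folded Spectra in molar extinction units on a common
#'   grid.
#' @return A spectrum in molar ellipticity-style difference units
#'   (delta-epsilon, M^-1 cm^-1).
#' @export
difference_signature <- function(unfolded, folded) {
  check_unit(unfolded, "molar_extinction")
  check_unit(folded, "molar_extinction")
  if (nrow(unfolded) != nrow(folded) ||
      any(abs(unfolded$wavelength - folded$wavelength) > 1e-9)) {
    stop("wavelength grids differ; resample() one spectrum first",
         call. = FALSE)
  }
  spectrum_tbl(unfolded$wavelength, unfolded$value - folded$value,
               unit = "molar_ellipticity",
               name = attr(folded, "name"), salt = attr(folded, "salt"))
}

#' Folding signature from a single folded-state spectrum (Eps2Fold)
#'
#' Subtracts the measured folded-state spectrum from the unfolded-state
#' spectrum *calculated* from sequence by the nearest-neighbor model,
#' yielding an isothermal-difference-like signature from one measurement.
#' G4 signatures share a positive band near 245 nm and a negative band near
#' 295 nm; parallel topologies add a specific negative band near 265 nm.
#'
#' @param seq DNA sequence (string).
#' @param folded Folded-state spectrum, either in molar extinction units or
#'   in absorbance units with pathlength/concentration metadata (converted
#'   automatically).
#' @param table An `nn_table`.
#' @param range Analysis range (nm) the output is restricted to; default
#'   220-310 nm (the chemometrics range). Use `NULL` to keep the full
#'   overlap of the grids.
#' @return A delta-epsilon spectrum.
#' @export
eps2fold <- function(seq, folded, table = default_nn_table(),
                     range = c(220, 310)) {
  stopifnot(inherits(folded, "spectrum_tbl"))
  if (identical(spec_unit(folded), "absorbance")) {
    folded <- absorbance_to_molar(folded)
  }
  check_unit(folded, "molar_extinction")
  unf <- unfolded_spectrum(seq, table, wavelengths = folded$wavelength)
  sig <- difference_signature(unf, folded)
  if (!is.null(range)) {
    keep <- sig$wavelength >= min(range) & sig$wavelength <= max(range)
    sig <- respec(sig[keep, ], sig$value[keep])
  }
  sig
}

#' Isothermal difference spectrum (IDS)
#'
#' Same subtraction as [eps2fold()] but with an *experimentally measured*
#' unfolded-state spectrum (e.g. recorded in a cation-free or Li+ buffer).
#' If that reference is contaminated by residual folding, the IDS is
#' attenuated proportionally.
#'
#' @param folded,unfolded_experimental Spectra in molar extinction units on
#'   a common grid.
#' @param range Analysis range (nm); default 220-310. `NULL` keeps all.
#' @return A delta-epsilon spectrum.
#' @export
ids <- function(folded, unfolded_experimental, range = c(220, 310)) {
  sig <- difference_signature(unfolded_experimental, folded)
  if (!is.null(range)) {
    keep <- sig$wavelength >= min(range) & sig$wavelength <= max(range)
    sig <- respec(sig[keep, ], sig$value[keep])
  }
  sig
}

#' Per-group mean and standard deviation of signatures
#'
#' Pointwise mean and sample (n-1) standard deviation of signatures grouped
#' by a label, as used to summarize signature families by topology group.
#'
#' @param data Long tibble with columns `sample`, `wavelength`, `value`
#'   (see [bind_spectra()]), or a list of spectra if `labels` is given
#'   per-spectrum.
#' @param labels Group label per sample: either a column name in `data`
#'   (string) or a named/plain vector aligned with the samples.
#' @return Tibble with columns `label`, `wavelength`, `mean`, `sd`, `n`.
#'   Singleton groups report `sd = 0` with a warning.
#' @export
group_summary <- function(data, labels) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- bind_spectra(data)
  }
  stopifnot(is.data.frame(data),
            all(c("sample", "wavelength", "value") %in% names(data)))
  if (is.character(labels) && length(labels) == 1 && labels %in% names(data)) {
    data$label <- data[[labels]]
  } else {
    samples <- unique(data$sample)
    if (!is.null(names(labels))) {
      lab <- labels[match(samples, names(labels))]
    } else {
      if (length(labels) != length(samples)) {
        stop("labels must align with the samples", call. = FALSE)
      }
      lab <- labels
    }
    data$label <- lab[match(data$sample, samples)]
  }
  singletons <- data |>
    dplyr::distinct(.data$sample, .data$label) |>
    dplyr::count(.data$label) |>
    dplyr::filter(.data$n == 1)
  if (nrow(singletons) > 0) {
    warning("singleton group(s) ", paste(singletons$label, collapse = ", "),
            ": sd reported as 0", call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$label, .data$wavelength) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Optional signature normalizations
#'
#' Off by default everywhere in the package (molar units already remove
#' concentration and pathlength effects, and further normalization did not
#' improve class resolution); provided for exploration.
#'
#' @param spec A spectrum.
#' @param method `"minmax"` rescales to `[-1, 1]` by the maximum absolute
#'   value; `"unit_variance"` divides by the standard deviation.
#' @return The normalized spectrum (same unit tag).
#' @export
normalize_signature <- function(spec, method = c("minmax", "unit_variance")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "spectrum_tbl"))
  denom <- switch(method,
    minmax = max(abs(spec$value)),
    unit_variance = stats::sd(spec$value)
  )
  if (denom == 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  respec(spec, spec$value / denom)
}
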