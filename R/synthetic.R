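# run code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Construct a class template of Gaussian signature bands
#'
#' @param label Class label.
#' @param bands Data frame with columns `center` (nm, within 220-310),
#'   `amplitude` (signed, M^-1 cm^-1) and `width` (Gaussian sd, nm, > 0).
#' @param noise_sd Gaussian noise sd applied by [generate_signature()]
#'   (M^-1 cm^-1).
#' @return An object of class `class_template`.
#' @export
class_template <- function(label, bands, noise_sd = 2000) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("center", "amplitude", "width") %in% names(bands)))
  if (any(bands$center < 220 | bands$center > 310)) {
    stop("band centers must lie within 220-310 nm", call. = FALSE)
  }
  if (any(bands$width <= 0)) stop("band widths must be > 0", call. = FALSE)
  structure(list(label = label, bands = bands, noise_sd = noise_sd),
            class = "class_template")
}

#' Evaluate a template's noise-free band sum
#'
#' @param template A `class_template`.
#' @param wavelengths Numeric grid (nm).
#' @return Numeric vector of the Gaussian band mixture.
#' @export
eval_template <- function(template, wavelengths) {
  stopifnot(inherits(template, "class_template"))
  vals <- rep(0, length(wavelengths))
  for (i in seq_len(nrow(template$bands))) {
    b <- template$bands[i, ]
    vals <- vals + b$amplitude * exp(-(wavelengths - b$center)^2 /
                                       (2 * b$width^2))
  }
  vals
}

#' Default topology-class signature templates
#'
#' Emulates the band structure of G4 folding difference signatures: every
#' class shares a positive band at 245 nm and a negative band at 295 nm;
#' parallel topologies add the class-specific negative band around 265 nm
#' (near zero for the other classes); the hybrid template sits between
#' parallel and antiparallel with a shallow negative shoulder near 275 nm.
#' Band positions and signs follow the observed signatures; amplitudes are
#' free generator parameters chosen to give extrema of order
#' 10^4 M^-1 cm^-1, the delta-epsilon scale of typical G4-forming
#' oligonucleotides.
#'
#' @param noise_sd Gaussian noise sd (M^-1 cm^-1; default 2000, i.e. 5% of
#'   the dominant band amplitude).
#' @return Named list of `class_template`s (`parallel`, `antiparallel`,
#'   `hybrid`).
#' @export
default_templates <- function(noise_sd = 2000) {
  list(
    parallel = class_template("parallel", data.frame(
      center = c(245, 265, 295),
      amplitude = c(40000, -35000, -10000),
      width = c(8, 9, 6)
    ), noise_sd),
    antiparallel = class_template("antiparallel", data.frame(
      center = c(245, 295),
      amplitude = c(40000, -28000),
      width = c(8, 6)
    ), noise_sd),
    hybrid = class_template("hybrid", data.frame(
      center = c(245, 275, 295),
      amplitude = c(40000, -12000, -18000),
      width = c(8, 10, 6)
    ), noise_sd)
  )
}

#' Generate one synthetic signature from a template
#'
#' Band sum plus i.i.d. Gaussian noise; the same seed always yields the
#' identical spectrum, and the caller's RNG state is left untouched.
#'
#' @param template A `class_template`.
#' @param seed Integer seed.
#' @param wavelengths Numeric grid (nm; default 220-350, 1 nm).
#' @return A delta-epsilon [spectrum_tbl].
#' @export
generate_signature <- function(template, seed, wavelengths = 220:350) {
  stopifnot(inherits(template, "class_template"))
  vals <- eval_template(template, wavelengths)
  if (template$noise_sd > 0) {
    noise <- with_local_seed(seed,
                             stats::rnorm(length(wavelengths), 0,
                                          template$noise_sd))
    vals <- vals + noise
  }
  spectrum_tbl(wavelengths, vals, unit = "molar_ellipticity",
               name = template$label)
}

#' Generate a synthetic folded-state UV spectrum for a sequence
#'
#' Inverts the folding-signature definition: the folded spectrum is the
#' calculated unfolded spectrum minus a generated signature, so that
#' [eps2fold()] on the result recovers the injected signature exactly (and
#' the template exactly at zero noise).
#'
#' @param seq DNA sequence (string).
#' @param template A `class_template`.
#' @param table An `nn_table`.
#' @param seed Integer seed for the signature noise.
#' @param wavelengths Numeric grid (nm).
#' @return A folded-state spectrum in molar extinction units.
#' @export
generate_folded_uv <- function(seq, template, table = default_nn_table(),
                               seed = 1, wavelengths = 220:350) {
  unf <- unfolded_spectrum(seq, table, wavelengths)
  if (any(unf$value - eval_template(template, wavelengths) <= 0)) {
    stop("template amplitudes too large: negative folded-state extinction",
         call. = FALSE)
  }
  sig <- generate_signature(template, seed, wavelengths)
  vals <- unf$value - sig$value
  spectrum_tbl(wavelengths, vals, unit = "molar_extinction",
               name = template$label)
}

#' Simulate a labelled panel of class signatures
#'
#' Draws `n_per_class` noisy signatures per template, on a fixed seed, as a
#' long tibble ready for [fit_pca()] and [loo_label_recovery()].
#'
#' @param templates Named list of `class_template`s.
#' @param n_per_class Samples per class (default 5).
#' @param seed Integer seed.
#' @param wavelengths Numeric grid (nm; default the 220-310 nm analysis
#'   range).
#' @return Long tibble with columns `sample`, `label`, `wavelength`,
#'   `value`.
#' @export
simulate_panel <- function(templates = default_templates(), n_per_class = 5,
                           seed = 1, wavelengths = 220:310) {
  stopifnot(length(templates) > 0, n_per_class >= 1)
  idx <- 0L
  purrr::map_dfr(templates, function(tpl) {
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      idx <<- idx + 1L
      sig <- generate_signature(tpl, seed * 1000L + idx, wavelengths)
      tibble::tibble(
        sample = sprintf("%s_%02d", tpl$label, i),
        label = tpl$label,
        wavelength = sig$wavelength,
        value = sig$value
      )
    })
  })
}

# Idealized planar guanine geometry (standard base reference frame, Angstrom;
# base plane at z = 0, C1' in plane).
guanine_frame <- function() {
  m <- rbind(
    "C1'" = c(-2.477, 5.399),
    "N9"  = c(-1.289, 4.551),
    "C8"  = c( 0.023, 4.962),
    "N7"  = c( 0.870, 3.969),
    "C5"  = c( 0.071, 2.833),
    "C6"  = c( 0.424, 1.460),
    "N1"  = c(-0.700, 0.641),
    "C2"  = c(-1.999, 1.087),
    "N3"  = c(-2.342, 2.364),
    "C4"  = c(-1.265, 3.177)
  )
  m <- cbind(m, 0)
  colnames(m) <- c("x", "y", "z")
  m
}

# Place atom D with |CD| = bond, angle(B,C,D) = angle_deg and
# dihedral(A,B,C,D) = torsion_deg (natural extension reference frame).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  angle <- angle_deg * pi / 180
  torsion <- torsion_deg * pi / 180
  b2 <- c - b
  b2h <- b2 / vnorm(b2)
  n <- vcross(b - a, b2)
  nh <- n / vnorm(n)
  mh <- vcross(nh, b2h)
  d_local <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                      sin(angle) * sin(torsion))
  c + b2h * d_local[1] + mh * d_local[2] + nh * d_local[3]
}

#' Construct an idealized stacked guanine pair with a prescribed twist
#'
#' Builds two planar guanines: the lower (5') base in a canonical frame
#' (plane z = 0) and the upper (3') base rotated by `twist_deg` about the
#' lower plane normal (right-hand rule) and translated by `rise_A` along
#' it. O4' is placed so the glycosidic chi torsion matches the requested
#' syn (+60 deg) or anti (-120 deg) conformation. [twist_angle()] on the
#' pair recovers `twist_deg` to numerical precision, which makes the
#' fixture an independent oracle for the twist convention.
#'
#' @param gba5,gba3 `"syn"` or `"anti"` for the lower and upper guanine.
#' @param twist_deg Prescribed signed twist, |twist| <= 180.
#' @param rise_A Stacking rise (Angstrom, > 0; default 3.4).
#' @return List with elements `lower` and `upper`, each an 11 x 3 atom
#'   coordinate matrix.
#' @export
generate_stack_fixture <- function(gba5 = "anti", gba3 = "anti", twist_deg,
                                   rise_A = 3.4) {
  stopifnot(abs(twist_deg) <= 180, rise_A > 0)
  chi_for <- function(gba) {
    switch(match.arg(tolower(gba), c("syn", "anti")), syn = 60, anti = -120)
  }
  build <- function(gba) {
    base <- guanine_frame()
    o4p <- place_atom(base["C4", ], base["N9", ], base["C1'", ],
                      bond = 1.42, angle_deg = 108,
                      torsion_deg = chi_for(gba))
    rbind(base, "O4'" = o4p)
  }
  lower <- build(gba5)
  upper0 <- build(gba3)
  th <- twist_deg * pi / 180
  # rotate about +z (right-hand rule), then rise along +z
  upper <- t(apply(upper0, 1, function(p) {
    c(cos(th) * p[1] - sin(th) * p[2],
      sin(th) * p[1] + cos(th) * p[2],
      p[3] + rise_A)
  }))
  rownames(upper) <- rownames(upper0)
  colnames(upper) <- colnames(upper0)
  list(lower = lower[guanine_geom_atoms, ], upper = upper[guanine_geom_atoms, ])
}

#' Write residue geometries as a (multi-model) PDB file
#'
#' @param models Either a single model or a list of models; a model is a
#'   list of residue coordinate matrices (rows named by atom), one per
#'   residue, written as DG residues on chain A in list order. The output
#'   of [generate_stack_fixture()] is a valid model.
#' @param path Output path.
#' @return `path`, invisibly. Coordinates are written with 3 decimals (PDB
#'   precision).
#' @export
write_structure_pdb <- function(models, path) {
  if (!is.list(models[[1]]) || is.matrix(models[[1]])) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (r in seq_along(models[[m]])) {
      res <- models[[m]][[r]]
      for (an in rownames(res)) {
        serial <- serial + 1L
        name4 <- if (nchar(an) < 4) sprintf("%-4s", paste0(" ", an)) else an
        writeLines(sprintf(
          "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name4, "DG", "A", r,
          res[an, 1], res[an, 2], res[an, 3]), con)
      }
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
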