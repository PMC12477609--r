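#' @keywords internal
guanine_ring_atoms <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
#' @keywords internal
guanine_geom_atoms <- c(guanine_ring_atoms, "O4'", "C1'")

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

# Signed dihedral A-B-C-D in degrees, range (-180, 180]
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  ang <- atan2(sum(vcross(n1, n2) * b2) / vnorm(b2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

check_residue_geom <- function(res, need = guanine_geom_atoms) {
  if (!is.matrix(res) || ncol(res) != 3) {
    stop("residue geometry must be an atoms x 3 coordinate matrix",
         call. = FALSE)
  }
  missing <- setdiff(need, rownames(res))
  if (length(missing) > 0) {
    stop("missing atom(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(res[need, ]))) {
    stop("non-finite coordinates in residue geometry", call. = FALSE)
  }
  invisible(res)
}

#' Glycosidic chi torsion of a purine residue
#'
#' The standard glycosidic dihedral O4'-C1'-N9-C4 in degrees, range
#' (-180, 180].
#'
#' @param res Residue geometry: a numeric matrix with rows named by atom
#'   (at least O4', C1', N9, C4) and columns x, y, z in Angstrom.
#' @return Torsion angle in degrees.
#' @export
chi_torsion <- function(res) {
  check_residue_geom(res, c("O4'", "C1'", "N9", "C4"))
  dihedral4(res["O4'", ], res["C1'", ], res["N9", ], res["C4", ])
}

#' Classify a chi torsion as syn or anti
#'
#' `syn` iff chi lies in (-90, +90] degrees; `anti` otherwise. The boundary
#' chi = -90 is assigned `anti` (open interval), a deterministic convention
#' at a physically unpopulated boundary.
#'
#' @param chi Torsion angle(s) in degrees, in (-180, 180].
#' @return Character vector of `"syn"` / `"anti"`.
#' @export
classify_gba <- function(chi) {
  stopifnot(is.numeric(chi), all(chi > -180 - 1e-9 & chi <= 180 + 1e-9))
  ifelse(chi > -90 & chi <= 90, "syn", "anti")
}

# Least-squares plane normal of a point set (unit vector), plus centroid
plane_fit <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  n <- sv$v[, 3]
  if (sv$d[2] < 1e-8) {
    stop("degenerate (collinear) ring atoms; cannot fit a plane",
         call. = FALSE)
  }
  list(centroid = ctr, normal = n / vnorm(n))
}

#' Signed twist angle between two stacked guanines
#'
#' The stacking axis is the unit normal of the least-squares plane through
#' the lower (5') residue's nine ring atoms, oriented toward the upper (3')
#' residue's ring centroid. The twist is the signed angle (right-hand rule
#' about that axis) from the projection of the lower residue's C1'->N9
#' vector to the projection of the upper residue's C1'->N9 vector onto the
#' plane perpendicular to the axis. Right-handed parallel G4 cores give
#' positive twists; left-handed (Z-G4) cores give negative twists.
#'
#' @param lower,upper Residue geometries (see [chi_torsion()]) of the 5'
#'   and 3' stacking partner.
#' @return Signed twist in degrees, range (-180, 180]. A warning is issued
#'   if the ring centroids are more than 6 Angstrom apart (not a plausible
#'   stack).
#' @export
twist_angle <- function(lower, upper) {
  check_residue_geom(lower)
  check_residue_geom(upper)
  ring_lo <- lower[guanine_ring_atoms, , drop = FALSE]
  ring_up <- upper[guanine_ring_atoms, , drop = FALSE]
  pf <- plane_fit(ring_lo)
  ctr_up <- colMeans(ring_up)
  axis <- pf$normal
  if (sum(axis * (ctr_up - pf$centroid)) < 0) axis <- -axis
  sep <- vnorm(ctr_up - pf$centroid)
  if (sep > 6) {
    warning(sprintf("ring centroid separation %.1f A exceeds 6 A; not a ",
                    sep), "plausible stack", call. = FALSE)
  }
  v_lo <- lower["N9", ] - lower["C1'", ]
  v_up <- upper["N9", ] - upper["C1'", ]
  proj <- function(v) v - sum(v * axis) * axis
  p_lo <- proj(v_lo)
  p_up <- proj(v_up)
  if (vnorm(p_lo) < 1e-9 || vnorm(p_up) < 1e-9) {
    stop("degenerate geometry: C1'->N9 vector parallel to the stacking axis",
         call. = FALSE)
  }
  ang <- atan2(sum(axis * vcross(p_lo, p_up)), sum(p_lo * p_up)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Stacking overlap class of a guanine pair
#'
#' Within a G4 core, the glycosidic conformations of a stacked guanine pair
#' determine the ring overlap geometry: `aa` and `ss` give partial overlap
#' of the 5- and 6-membered rings with both guanines running in the same
#' direction ("same 5/6-ring"); `sa` overlaps the 5-membered rings
#' ("5-ring"); `as` partially overlaps the 6-membered rings ("partial
#' 6-ring"). At dimerization or unit interfaces, `aa` stacks of guanines
#' running in opposite directions occur in four annotated variants
#' (`5/6r`, `6r`, `5r`, `p6r`).
#'
#' @param gba5,gba3 `"syn"`/`"anti"` (or `"s"`/`"a"`) of the 5' and 3'
#'   partner.
#' @param polarity `"same"` or `"opposite"` tetrad H-bond directionality.
#' @param context `"core"` or `"interface"`.
#' @param annotation For interface `aa` stacks: which annotated variant,
#'   one of `"5/6r"`, `"6r"`, `"5r"`, `"p6r"` (not derivable from the GBAs
#'   alone).
#' @return The overlap class string.
#' @export
classify_overlap <- function(gba5, gba3, polarity = c("same", "opposite"),
                             context = c("core", "interface"),
                             annotation = NULL) {
  polarity <- match.arg(polarity)
  context <- match.arg(context)
  shorten <- function(x) {
    x <- match.arg(tolower(x), c("syn", "anti", "s", "a"))
    substr(x, 1, 1)
  }
  pair <- paste0(shorten(gba5), shorten(gba3))
  if (context == "core") {
    if (polarity == "opposite" && pair %in% c("aa", "ss")) {
      stop("core aa/ss stacks have same-direction tetrads; use ",
           "context = 'interface' for opposite-polarity aa stacks",
           call. = FALSE)
    }
    return(switch(pair,
      aa = "same 5/6-ring",
      ss = "same 5/6-ring",
      sa = "5-ring",
      as = "partial 6-ring"
    ))
  }
  # interface
  if (pair == "sa") return("5-ring")
  if (pair == "as") return("partial 6-ring")
  if (pair == "aa") {
    if (polarity != "opposite") {
      stop("interface aa stacks have opposite tetrad polarity", call. = FALSE)
    }
    if (is.null(annotation)) {
      stop("interface aa stack requires an overlap annotation ",
           "('5/6r', '6r', '5r' or 'p6r')", call. = FALSE)
    }
    annotation <- match.arg(annotation, c("5/6r", "6r", "5r", "p6r"))
    return(switch(annotation,
      "5/6r" = "5/6-ring", "6r" = "6-ring",
      "5r" = "5-ring", "p6r" = "partial 6-ring"
    ))
  }
  stop("no interface overlap class for ", pair, " stacks", call. = FALSE)
}

#' Read guanine geometries from a PDB file
#'
#' Parses all MODEL blocks of a PDB file and extracts, per model, the nine
#' purine ring atoms plus O4' and C1' of every guanine residue (residue
#' names G, DG, GUA). Non-guanine residues are skipped (with a message);
#' guanines missing required atoms are reported and dropped. Residues with
#' insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @return A tibble of class `g4_structure` with columns `model`, `chain`,
#'   `resno`, `atom`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(nzchar(trimws(as.character(at$insert))) &
          !is.na(at$insert))) {
    stop("insertion codes are not supported; renumber the structure first",
         call. = FALSE)
  }
  is_g <- at$resid %in% c("G", "DG", "GUA")
  skipped <- unique(at$resid[!is_g & at$type == "ATOM"])
  if (length(skipped) > 0) {
    message("skipping non-guanine residue type(s): ",
            paste(skipped, collapse = ", "))
  }
  sel <- which(is_g & at$elety %in% guanine_geom_atoms)
  if (length(sel) == 0) stop("no guanine atoms found in ", path, call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  out <- purrr::map_dfr(seq_len(n_models), function(m) {
    tibble::tibble(
      model = m,
      chain = as.character(at$chain[sel]),
      resno = at$resno[sel],
      atom = at$elety[sel],
      x = xyz[m, 3 * (sel - 1) + 1],
      y = xyz[m, 3 * (sel - 1) + 2],
      z = xyz[m, 3 * (sel - 1) + 3]
    )
  })
  # drop residues missing required atoms, reporting them
  counts <- out |>
    dplyr::filter(.data$model == 1) |>
    dplyr::count(.data$chain, .data$resno)
  bad <- counts |> dplyr::filter(.data$n < length(guanine_geom_atoms))
  if (nrow(bad) > 0) {
    message("dropping guanine(s) with missing atoms: ",
            paste(sprintf("%s%d", bad$chain, bad$resno), collapse = ", "))
    out <- out |>
      dplyr::anti_join(bad, by = c("chain", "resno"))
  }
  class(out) <- c("g4_structure", class(out))
  out
}

#' Extract one residue's geometry matrix from a structure table
#'
#' @param struct A `g4_structure` tibble (see [read_structure()]).
#' @param model Model index.
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @return An atoms x 3 coordinate matrix with atom-name rownames.
#' @export
residue_geometry <- function(struct, model, chain, resno) {
  sub <- struct[struct$model == model & struct$chain == chain &
                  struct$resno == resno, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("residue %s%d not found in model %d", chain, resno, model),
         call. = FALSE)
  }
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$atom
  check_residue_geom(m)
  m
}

#' Twist statistics over an NMR/ensemble structure
#'
#' Computes the signed twist of each annotated guanine stack in every
#' deposited model, then summarizes per stack (mean over models) and per
#' GBA class (pooled over all stacks and models, sample sd). With a single
#' model, sd is reported as `NA`.
#'
#' @param struct A `g4_structure` tibble.
#' @param stacks Data frame with columns `chain5`, `res5`, `chain3`,
#'   `res3`, `gba5`, `gba3` and optionally `context` (default `"core"`)
#'   and `topology`.
#' @return A list of two tibbles: `stacks` (per-stack mean/sd/n over
#'   models) and `classes` (per GBA-class pooled mean/sd, number of stacks
#'   and observations).
#' @export
ensemble_twist_summary <- function(struct, stacks) {
  stopifnot(inherits(struct, "g4_structure"))
  stacks <- tibble::as_tibble(stacks)
  if (nrow(stacks) == 0) stop("empty stack list", call. = FALSE)
  if (!"context" %in% names(stacks)) stacks$context <- "core"
  if (!"topology" %in% names(stacks)) stacks$topology <- NA_character_
  models <- sort(unique(struct$model))
  obs <- purrr::pmap_dfr(
    stacks[, c("chain5", "res5", "chain3", "res3", "gba5", "gba3",
               "context", "topology")],
    function(chain5, res5, chain3, res3, gba5, gba3, context, topology) {
      tw <- vapply(models, function(m) {
        twist_angle(residue_geometry(struct, m, chain5, res5),
                    residue_geometry(struct, m, chain3, res3))
      }, numeric(1))
      tibble::tibble(
        stack = sprintf("%s%d/%s%d", chain5, res5, chain3, res3),
        class = paste0(substr(gba5, 1, 1), substr(gba3, 1, 1)),
        context = context, topology = topology,
        model = models, twist = tw
      )
    }
  )
  per_stack <- obs |>
    dplyr::group_by(.data$stack, .data$class, .data$context,
                    .data$topology) |>
    dplyr::summarise(
      mean_twist = mean(.data$twist),
      sd_twist = if (dplyr::n() > 1) stats::sd(.data$twist) else NA_real_,
      n_models = dplyr::n(),
      .groups = "drop"
    )
  per_class <- obs |>
    dplyr::group_by(.data$class, .data$context, .data$topology) |>
    dplyr::summarise(
      mean_twist = mean(.data$twist),
      sd_twist = if (dplyr::n() > 1) stats::sd(.data$twist) else NA_real_,
      n_stacks = dplyr::n_distinct(.data$stack),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  list(stacks = per_stack, classes = per_class)
}
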