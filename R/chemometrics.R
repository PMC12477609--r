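#' Fit a PCA model to a set of signatures
#'
#' Centers (and by default standardizes) the samples x wavelengths matrix
#' and computes its principal components. The default analysis range is
#' 220-310 nm, the region carrying the conformation-dependent bands.
#' Component signs are fixed deterministically: the largest-magnitude
#' loading element of each component is made positive, so scores and plots
#' are reproducible across platforms.
#'
#' @param data Either a long tibble with columns `sample`, `wavelength`,
#'   `value` (plus optional per-sample metadata columns such as labels),
#'   or a numeric samples x wavelengths matrix with numeric column names.
#' @param scale_unit_variance Standardize each wavelength to unit variance
#'   (correlation PCA, default) or only center (covariance PCA).
#' @param range Wavelength range (nm) used for the fit; `NULL` keeps all.
#' @return An object of class `g4_pca` with elements `center`, `scale`,
#'   `loadings` (orthonormal columns), `scores`, `var_fraction`,
#'   `wavelengths` and per-sample `meta`.
#' @export
fit_pca <- function(data, scale_unit_variance = TRUE, range = c(220, 310)) {
  if (is.matrix(data)) {
    x <- data
    wl <- as.numeric(colnames(x))
    if (anyNA(wl)) stop("matrix column names must be numeric wavelengths",
                        call. = FALSE)
    meta <- tibble::tibble(sample = rownames(x) %||%
                             paste0("s", seq_len(nrow(x))))
  } else {
    stopifnot(is.data.frame(data),
              all(c("sample", "wavelength", "value") %in% names(data)))
    meta_cols <- setdiff(names(data), c("wavelength", "value"))
    meta <- data |>
      dplyr::distinct(dplyr::across(dplyr::all_of(meta_cols)))
    if (anyDuplicated(meta$sample)) {
      stop("per-sample metadata columns must be constant within a sample",
           call. = FALSE)
    }
    wide <- data |>
      dplyr::select("sample", "wavelength", "value") |>
      tidyr::pivot_wider(names_from = "wavelength", values_from = "value")
    x <- as.matrix(wide[, -1, drop = FALSE])
    rownames(x) <- wide$sample
    wl <- as.numeric(colnames(x))
    meta <- meta[match(wide$sample, meta$sample), , drop = FALSE]
  }
  if (anyNA(x)) stop("missing values in the spectra matrix (grids differ?)",
                     call. = FALSE)
  if (!is.null(range)) {
    keep <- wl >= min(range) & wl <= max(range)
    x <- x[, keep, drop = FALSE]
    wl <- wl[keep]
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("PCA needs at least 2 samples and 2 wavelengths", call. = FALSE)
  }
  if (scale_unit_variance) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance wavelength(s) with scaling on: ",
           paste(wl[sds == 0], collapse = ", "), " nm", call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_unit_variance)
  # deterministic component signs
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      center = pc$center,
      scale = if (scale_unit_variance) pc$scale else
        stats::setNames(rep(1, ncol(x)), colnames(x)),
      loadings = pc$rotation,
      scores = pc$x,
      var_fraction = var_fraction,
      wavelengths = wl,
      meta = meta,
      scaled = scale_unit_variance
    ),
    class = "g4_pca"
  )
}

#' @export
print.g4_pca <- function(x, ...) {
  cat(sprintf(
    "<g4_pca> %d samples x %d wavelengths (%g-%g nm), %s; PC1+PC2 = %.1f%%\n",
    nrow(x$scores), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    if (x$scaled) "standardized" else "centered only",
    explained_variance(x, min(2, ncol(x$scores)))
  ))
  invisible(x)
}

#' Cumulative explained variance
#'
#' @param model A `g4_pca` model.
#' @param k Number of leading components.
#' @return Cumulative explained variance of the first `k` components, in
#'   percent.
#' @export
explained_variance <- function(model, k) {
  stopifnot(inherits(model, "g4_pca"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > length(model$var_fraction)) {
    stop("k must be between 1 and the number of components", call. = FALSE)
  }
  100 * sum(model$var_fraction[seq_len(k)])
}

#' Project spectra into a fitted PC space
#'
#' Applies the model's centering/scaling and loadings:
#' `scores = ((x - center) / scale) %*% loadings`. The query must be on the
#' model's wavelength grid.
#'
#' @param model A `g4_pca` model.
#' @param spectrum A [spectrum_tbl], a numeric vector on the model grid, or
#'   a samples x wavelengths matrix.
#' @return A tibble with a `sample` column and one column per component.
#' @export
project <- function(model, spectrum) {
  stopifnot(inherits(model, "g4_pca"))
  if (inherits(spectrum, "spectrum_tbl")) {
    keep <- spectrum$wavelength >= min(model$wavelengths) - 1e-9 &
      spectrum$wavelength <= max(model$wavelengths) + 1e-9
    sub <- spectrum[keep, ]
    if (nrow(sub) != length(model$wavelengths) ||
        any(abs(sub$wavelength - model$wavelengths) > 1e-9)) {
      stop("spectrum grid does not match the model grid; resample() first",
           call. = FALSE)
    }
    x <- matrix(sub$value, nrow = 1,
                dimnames = list(attr(spectrum, "name") %||% "query", NULL))
  } else if (is.matrix(spectrum)) {
    if (ncol(spectrum) != length(model$wavelengths)) {
      stop("matrix columns do not match the model grid", call. = FALSE)
    }
    x <- spectrum
  } else {
    if (length(spectrum) != length(model$wavelengths)) {
      stop("vector length does not match the model grid", call. = FALSE)
    }
    x <- matrix(as.numeric(spectrum), nrow = 1,
                dimnames = list("query", NULL))
  }
  sc <- sweep(sweep(x, 2, model$center), 2, model$scale, "/") %*% model$loadings
  tibble::tibble(sample = rownames(sc) %||% paste0("q", seq_len(nrow(sc)))) |>
    dplyr::bind_cols(tibble::as_tibble(sc))
}

#' Predict a structural descriptor label by k-NN in PC score space
#'
#' Projects the query into the reference PC space and takes a majority vote
#' among its `k` nearest reference samples (Euclidean distance in the first
#' `n_pc` score dimensions). Ties are broken by the smallest mean neighbor
#' distance, then lexicographically. The full ranked distance table is
#' returned for transparency.
#'
#' @param model A `g4_pca` model fitted on the reference panel, whose
#'   `meta` carries the descriptor column.
#' @param query A spectrum or numeric vector on the model grid.
#' @param descriptor Name of the metadata column holding the labels
#'   (default `"label"`).
#' @param k Number of neighbors (default 3).
#' @param n_pc Number of leading components used (default 2; the
#'   interpreted plane).
#' @return A list of class `g4_prediction`: `label` (the prediction) and
#'   `neighbors` (tibble with sample, label, distance, rank for all
#'   reference samples).
#' @export
predict_label <- function(model, query, descriptor = "label", k = 3,
                          n_pc = 2) {
  stopifnot(inherits(model, "g4_pca"))
  if (!descriptor %in% names(model$meta)) {
    stop("descriptor '", descriptor, "' not present in the reference metadata",
         call. = FALSE)
  }
  n_ref <- nrow(model$scores)
  if (k > n_ref) stop("k exceeds the reference panel size", call. = FALSE)
  n_pc <- min(n_pc, ncol(model$scores))
  q <- project(model, query)
  qs <- as.numeric(q[1, paste0("PC", seq_len(n_pc))])
  ref <- model$scores[, seq_len(n_pc), drop = FALSE]
  d <- sqrt(rowSums(sweep(ref, 2, qs)^2))
  neighbors <- tibble::tibble(
    sample = model$meta$sample,
    label = as.character(model$meta[[descriptor]]),
    distance = unname(d)
  ) |>
    dplyr::arrange(.data$distance) |>
    dplyr::mutate(rank = dplyr::row_number())
  top <- neighbors[seq_len(k), ]
  votes <- top |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean_dist = mean(.data$distance),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$mean_dist, .data$label)
  structure(list(label = votes$label[1], votes = votes,
                 neighbors = neighbors, k = k, n_pc = n_pc),
            class = "g4_prediction")
}

#' @export
print.g4_prediction <- function(x, ...) {
  cat(sprintf("<g4_prediction> %s (k = %d, %d PCs)\n", x$label, x$k, x$n_pc))
  print(utils::head(x$neighbors, x$k))
  invisible(x)
}

#' Leave-one-out label recovery on a labelled signature set
#'
#' For each sample, refits the PCA on the remaining samples and predicts
#' the held-out sample's label by [predict_label()].
#'
#' @param data Long tibble with `sample`, `wavelength`, `value` and the
#'   descriptor column.
#' @param descriptor Label column name (default `"label"`).
#' @inheritParams predict_label
#' @inheritParams fit_pca
#' @return Tibble with columns `sample`, `truth`, `predicted`, `correct`.
#' @export
loo_label_recovery <- function(data, descriptor = "label", k = 3, n_pc = 2,
                               scale_unit_variance = TRUE,
                               range = c(220, 310)) {
  stopifnot(is.data.frame(data), descriptor %in% names(data))
  samples <- unique(data$sample)
  purrr::map_dfr(samples, function(s) {
    train <- data[data$sample != s, , drop = FALSE]
    test <- data[data$sample == s, , drop = FALSE]
    m <- fit_pca(train, scale_unit_variance = scale_unit_variance,
                 range = range)
    keep <- test$wavelength %in% m$wavelengths
    v <- test$value[keep][order(test$wavelength[keep])]
    pred <- predict_label(m, v, descriptor = descriptor, k = k, n_pc = n_pc)
    tibble::tibble(
      sample = s,
      truth = as.character(test[[descriptor]][1]),
      predicted = pred$label,
      correct = pred$label == as.character(test[[descriptor]][1])
    )
  })
}

#' Tidy a fitted PCA model
#'
#' @param x A `g4_pca` model.
#' @param matrix Which quantity to return: `"scores"` (per sample, with
#'   metadata), `"loadings"` (per wavelength and component) or
#'   `"eigenvalues"` (variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy g4_pca
#' @export
tidy.g4_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                        ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = dplyr::bind_cols(x$meta, tibble::as_tibble(x$scores)),
    loadings = tibble::as_tibble(x$loadings) |>
      dplyr::mutate(wavelength = x$wavelengths, .before = 1) |>
      tidyr::pivot_longer(-"wavelength", names_to = "component",
                          values_to = "loading"),
    eigenvalues = tibble::tibble(
      component = paste0("PC", seq_along(x$var_fraction)),
      var_fraction = x$var_fraction,
      cumulative_percent = 100 * cumsum(x$var_fraction)
    )
  )
}

#' One-row summary of a fitted PCA model
#'
#' @param x A `g4_pca` model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance g4_pca
#' @export
glance.g4_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_wavelengths = length(x$wavelengths),
    scaled = x$scaled,
    pc1_percent = 100 * x$var_fraction[1],
    pc2_percent = 100 * x$var_fraction[2],
    pc12_percent = explained_variance(x, min(2, length(x$var_fraction)))
  )
}
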