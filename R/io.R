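## Image and manifest I/O, normalization, resizing, stratified splitting.

#' Load one radiograph from disk
#'
#' Reads an 8- or 16-bit TIFF or PNG. Multi-channel images are collapsed to
#' a single channel by luminance (0.299 R + 0.587 G + 0.114 B). By default,
#' intensities are min-max scaled to `[0, 1]`; a constant image maps to all
#' zeros by convention.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param label class label, 0 (healthy) or 1 (lesion).
#' @param id identifier; defaults to the file name without extension.
#' @param normalize apply per-image min-max scaling (default `TRUE`). With
#'   `FALSE` the stored intensity scale (already in `[0, 1]` for 8/16-bit
#'   images) is kept, e.g. to check write/read quantization error.
#' @return A [radiograph_sample()].
#' @export
load_sample <- function(path, label, id = NULL, normalize = TRUE) {
  if (!file.exists(path)) abort_io(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      abort_io(sprintf("unsupported image format '%s' for '%s'", ext, path))
    ),
    error = function(e) abort_io(sprintf("cannot read image '%s': %s", path, conditionMessage(e)))
  )
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    px <- if (nch >= 3L) {
      0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else px[, , 1]
  }
  px <- as.matrix(px)
  if (normalize) px <- normalize_minmax(px)
  radiograph_sample(id = id %||% tools::file_path_sans_ext(basename(path)),
                    pixels = clip01(px), label = label, source_path = path)
}

## min-max to [0,1]; constant images map to zeros
normalize_minmax <- function(px) {
  rng <- range(px)
  if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(px), ncol(px))
}

#' Load a dataset from a manifest CSV
#'
#' The manifest must have columns `id`, `path`, `label` (and optionally
#' `split`). Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the CSV.
#' @inheritParams load_sample
#' @return A list of [radiograph_sample()] objects.
#' @export
load_dataset <- function(manifest_path, normalize = TRUE) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  if (!all(c("id", "path", "label") %in% names(man)))
    abort_io("manifest must have columns id, path, label")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    load_sample(p, label = man$label[i], id = man$id[i], normalize = normalize)
  })
}

## --- bilinear sampling core (shared by resize and geometric transforms) ---

## Sample img at fractional (row, col) coordinates (1-based pixel centers).
## oob = "clamp" extends edge pixels; "fill" returns `fill` outside [1, n].
bilinear_sample <- function(img, r, c, oob = c("clamp", "fill"), fill = 0) {
  oob <- match.arg(oob)
  nr <- nrow(img); nc <- ncol(img)
  outside <- r < 1 | r > nr | c < 1 | c > nc
  if (oob == "clamp" || any(!outside)) {
    rc <- pmin(pmax(r, 1), nr)
    cc <- pmin(pmax(c, 1), nc)
    r0 <- pmin(floor(rc), nr - 1L); r0[nr == 1L] <- 1L
    c0 <- pmin(floor(cc), nc - 1L); c0[nc == 1L] <- 1L
    fr <- rc - r0; fc <- cc - c0
    r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
    v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
         (1 - fr) * fc       * img[cbind(r0, c1)] +
         fr       * (1 - fc) * img[cbind(r1, c0)] +
         fr       * fc       * img[cbind(r1, c1)]
  } else {
    v <- rep(fill, length(r))
  }
  if (oob == "fill") v[outside] <- fill
  v
}

## Bilinear resize of a plain matrix to nr_out x nc_out, center-aligned so
## that equal input/output sizes reproduce the input exactly.
resize_matrix <- function(img, nr_out, nc_out = nr_out) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr == nr_out && nc == nc_out) return(img)
  rr <- (seq_len(nr_out) - 0.5) * (nr / nr_out) + 0.5
  cc <- (seq_len(nc_out) - 0.5) * (nc / nc_out) + 0.5
  grid_r <- rep(rr, times = nc_out)
  grid_c <- rep(cc, each = nr_out)
  matrix(bilinear_sample(img, grid_r, grid_c, oob = "clamp"), nr_out, nc_out)
}

#' Resize a sample to a square side with bilinear interpolation
#'
#' @param sample a [radiograph_sample()].
#' @param side output side in pixels (>= 8).
#' @return The resized sample, values clipped to `[0, 1]`.
#' @export
resize_sample <- function(sample, side) {
  side <- assert_count(side, "side", min = 8L)
  out <- sample
  out$pixels <- clip01(resize_matrix(sample$pixels, side, side))
  out
}

## --- stratified split -----------------------------------------------------

#' Stratified train/validation/test split
#'
#' Partitions sample ids into train/val/test so that per-class proportions
#' in each partition are within one sample of the requested fractions.
#' Deterministic given `seed`.
#'
#' @param labels named integer vector (id -> class in `{0, 1}`), or a data
#'   frame with columns `id` and `label`.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return A `split_assignment` tibble with columns `id`, `label`, `split`
#'   (factor train/val/test); fractions and seed stored as attributes.
#' @export
stratified_split <- function(labels, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$id)
  if (is.null(names(labels))) abort_config("`labels` must be named by sample id")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    abort_config("`fractions` must be three non-negative numbers summing to 1")
  classes <- sort(unique(labels))
  if (any(table(labels) < 1L)) abort_config("every class needs at least one sample")
  parts <- c("train", "val", "test")
  out <- with_seed(seed, {
    pieces <- lapply(classes, function(cl) {
      ids <- sample(names(labels)[labels == cl])
      ncl <- length(ids)
      counts <- diff(c(0L, round(cumsum(fractions) * ncl)))
      tibble::tibble(id = ids, label = as.integer(cl),
                     split = rep(parts, times = counts))
    })
    dplyr::bind_rows(pieces)
  })
  out <- out[match(names(labels), out$id), ]
  out$split <- factor(out$split, levels = parts)
  structure(out, class = c("split_assignment", class(out)),
            fractions = fractions, seed = seed)
}

split_ids <- function(assignment, part) {
  assignment$id[assignment$split == part]
}
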