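#' Region-of-interest definitions and masks
#'
#' An ROI is either a rectangle `roi_rect(x, y, w, h)` or a polygon
#' `roi_polygon(x, y)` in pixel coordinates (origin top-left, 0-based,
#' `x` along columns, `y` along rows). `roi_mask()` rasterizes it to a
#' logical matrix matching an image; `read_roi()` loads the JSON form
#' (`{"rect": {"x":..,"y":..,"w":..,"h":..}}` or
#' `{"polygon": [[x1,y1], [x2,y2], ...]}`).
#'
#' @param x,y rectangle corner or polygon vertex coordinates, pixels
#' @param w,h rectangle width and height, pixels
#' @return an object of class `roi`
#' @export
roi_rect <- function(x, y, w, h) {
  stopifnot(w > 0, h > 0, x >= 0, y >= 0)
  structure(list(type = "rect", x = x, y = y, w = w, h = h), class = "roi")
}

#' @rdname roi_rect
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

#' @rdname roi_rect
#' @param path JSON file path
#' @export
read_roi <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(spec$rect)) {
    with(spec$rect, roi_rect(x, y, w, h))
  } else if (!is.null(spec$polygon)) {
    v <- spec$polygon
    if (is.list(v)) v <- do.call(rbind, v)
    roi_polygon(v[, 1], v[, 2])
  } else {
    abort("ROI JSON must contain a `rect` or `polygon` entry")
  }
}

#' @rdname roi_rect
#' @param roi an `roi` object
#' @param dim image dimensions `c(rows, cols)`
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi"), length(dim) == 2)
  nr <- dim[1]; nc <- dim[2]
  if (roi$type == "rect") {
    if (roi$x + roi$w > nc || roi$y + roi$h > nr) {
      abort("ROI rectangle extends beyond the image bounds")
    }
    m <- matrix(FALSE, nr, nc)
    m[(roi$y + 1):(roi$y + roi$h), (roi$x + 1):(roi$x + roi$w)] <- TRUE
    m
  } else {
    if (any(roi$x < 0) || any(roi$x > nc) || any(roi$y < 0) || any(roi$y > nr)) {
      abort("ROI polygon extends beyond the image bounds")
    }
    centers <- cbind(x = rep(seq_len(nc) - 0.5, each = nr),
                     y = rep(seq_len(nr) - 0.5, times = nc))
    bnd <- cbind(c(roi$x, roi$x[1]), c(roi$y, roi$y[1]))
    matrix(mgcv::in.out(bnd, centers), nr, nc)
  }
}

#' Mean background-subtracted ROI signal
#'
#' Subtracts the dark frame pixelwise, clips negative pixels at zero, and
#' averages over the ROI.
#'
#' @param img image matrix, detector counts
#' @param dark dark frame, same shape
#' @param roi an [roi_rect()]/[roi_polygon()] or a logical mask matrix
#' @return mean background-subtracted signal (counts); attributes `sd` and
#'   `n_pixels` carry the ROI spread and size
#' @export
roi_response <- function(img, dark, roi) {
  if (!all(dim(img) == dim(dark))) abort("image and dark frame shapes differ")
  mask <- if (inherits(roi, "roi")) roi_mask(roi, dim(img)) else roi
  if (!all(dim(mask) == dim(img))) abort("ROI mask shape differs from the image")
  if (!any(mask)) abort("ROI is empty")
  v <- pmax(img[mask] - dark[mask], 0)
  structure(mean(v), sd = stats::sd(v), n_pixels = sum(mask))
}

#' Dual-wavelength ratio measurement
#'
#' Bundles a blue/red image pair with its dark frame, ROI, excitation
#' intensities and calibration reference.
#'
#' @param img_blue,img_red monochrome fluorescence images (counts), blue/red
#'   excitation
#' @param dark dark frame, same shape
#' @param roi an [roi_rect()]/[roi_polygon()]
#' @param I_ex1,I_ex2 excitation intensities at the blue and red wavelengths,
#'   mW/cm^2
#' @param R_ref calibration ratio measured on a reference object (a thin PS
#'   layer with no depth structure); dividing by it removes the source
#'   intensities, quantum yields and PS absorption amplitudes from the
#'   measured ratio
#' @return an object of class `ratio_measurement`
#' @export
ratio_measurement <- function(img_blue, img_red, dark, roi,
                              I_ex1 = 1.4, I_ex2 = 2.2, R_ref = 1) {
  if (!all(dim(img_blue) == dim(img_red)) || !all(dim(img_blue) == dim(dark))) {
    abort("all images must have the same shape")
  }
  if (I_ex1 <= 0 || I_ex2 <= 0) abort("excitation intensities must be > 0")
  if (R_ref <= 0) abort("`R_ref` must be > 0")
  structure(list(img_blue = img_blue, img_red = img_red, dark = dark,
                 roi = roi, I_ex1 = I_ex1, I_ex2 = I_ex2, R_ref = R_ref),
            class = "ratio_measurement")
}

#' Calibrated fluorescence ratio from an image pair
#'
#' Computes the intensity-normalized ratio
#' `R_lambda = (S_red / I_ex2) / (S_blue / I_ex1)` of the mean
#' background-subtracted ROI signals and the calibrated ratio
#' `R_c = R_lambda / R_ref`.
#'
#' @param meas a [ratio_measurement()]
#' @return an object of class `calibrated_ratio`; `tidy()` gives a one-row
#'   tibble including per-channel ROI statistics
#' @export
measured_ratio <- function(meas) {
  stopifnot(inherits(meas, "ratio_measurement"))
  s_blue <- roi_response(meas$img_blue, meas$dark, meas$roi)
  s_red <- roi_response(meas$img_red, meas$dark, meas$roi)
  if (s_blue <= 0) abort("blue-channel ROI response is zero; ratio undefined")
  R_lambda <- (as.numeric(s_red) / meas$I_ex2) /
    (as.numeric(s_blue) / meas$I_ex1)
  structure(list(
    R_lambda = R_lambda, R_c = R_lambda / meas$R_ref, R_ref = meas$R_ref,
    roi_stats = tibble::tibble(
      channel = c("blue", "red"),
      mean = c(as.numeric(s_blue), as.numeric(s_red)),
      sd = c(attr(s_blue, "sd"), attr(s_red, "sd")),
      n_pixels = c(attr(s_blue, "n_pixels"), attr(s_red, "n_pixels"))
    )
  ), class = "calibrated_ratio")
}

#' @export
print.calibrated_ratio <- function(x, ...) {
  cat(sprintf("<calibrated_ratio> R_lambda = %.4g, R_c = %.4g (R_ref = %.4g)\n",
              x$R_lambda, x$R_c, x$R_ref))
  invisible(x)
}

#' @export
tidy.calibrated_ratio <- function(x, ...) {
  tibble::tibble(R_lambda = x$R_lambda, R_c = x$R_c, R_ref = x$R_ref,
                 mean_blue = x$roi_stats$mean[1], mean_red = x$roi_stats$mean[2],
                 sd_blue = x$roi_stats$sd[1], sd_red = x$roi_stats$sd[2],
                 n_pixels = x$roi_stats$n_pixels[1])
}

#' Depth report from calibrated ratios
#'
#' Turns a calibrated pre-treatment ratio (and optionally a post-treatment
#' one) into PS localization depths: the exponential 1/e depth for topical
#' administration, the PS-free cover depth for intravenous administration,
#' and -- when a post ratio is present -- the bleaching-induced depth change
#' from the pre/post pair.
#'
#' When `calibrated = TRUE` (the default) the ratios are assumed to be
#' normalized by the reference-object ratio, which cancels the quantum
#' yields and PS amplitudes: the inversion then uses a unit amplitude/yield
#' ratio, i.e. the thin-layer asymptote reduces to the backscatter-factor
#' ratio `k_ex2 / k_ex1`. Set `calibrated = FALSE` to invert raw
#' `R_lambda` values with the tissue model's own amplitudes.
#'
#' @param pre a [measured_ratio()] result (pre-treatment)
#' @param post optional post-treatment [measured_ratio()] result
#' @param administration `"topical"` or `"intravenous"`
#' @param tissue a [tissue_model()]
#' @param calibrated interpret ratios as reference-normalized (see Details)
#' @param clamp clamp slightly out-of-range ratios for the exponential
#'   inverse (see [invert_exp()])
#' @return an object of class `depth_report`; `tidy()` gives a tibble with
#'   one row per reported quantity
#' @export
depth_report <- function(pre, post = NULL,
                         administration = c("topical", "intravenous"),
                         tissue, calibrated = TRUE, clamp = TRUE) {
  administration <- match.arg(administration)
  stopifnot(inherits(pre, "calibrated_ratio"))
  amp <- if (calibrated) c(blue = 1, red = 1) else NULL
  phi <- if (calibrated) c(blue = 1, red = 1) else NULL
  R_pre <- if (calibrated) pre$R_c else pre$R_lambda
  rows <- list()
  flag <- function(ok) if (ok) "ok" else "out_of_range"
  est <- tryCatch(
    switch(administration,
      topical = suppressWarnings(
        invert_exp(R_pre, tissue, amp, phi, clamp = clamp)),
      intravenous = invert_bottom(R_pre, tissue, amp, phi)
    ),
    error = function(e) NA_real_
  )
  rows$depth <- tibble::tibble(
    quantity = switch(administration, topical = "d_1e", intravenous = "d_b"),
    value = est, unit = "mm", R = R_pre, flag = flag(!is.na(est))
  )
  if (!is.null(post)) {
    stopifnot(inherits(post, "calibrated_ratio"))
    R_post <- if (calibrated) post$R_c else post$R_lambda
    rows$delta <- tibble::tibble(
      quantity = "delta_d_b",
      value = bleach_depth(R_post, R_pre, tissue),
      unit = "mm", R = R_post / R_pre, flag = "ok"
    )
  }
  structure(list(
    administration = administration, calibrated = calibrated,
    table = dplyr::bind_rows(rows),
    R_pre = R_pre, R_post = if (!is.null(post)) {
      if (calibrated) post$R_c else post$R_lambda
    } else NA_real_
  ), class = "depth_report")
}

#' @export
print.depth_report <- function(x, ...) {
  cat("<depth_report>", x$administration, "administration",
      if (x$calibrated) "(calibrated ratios)" else "(raw ratios)", "\n")
  df <- as.data.frame(x$table)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s %8.4g %s  [R = %.4g, %s]\n", df$quantity[i],
                df$value[i], df$unit[i], df$R[i], df$flag[i]))
  }
  invisible(x)
}

#' @export
tidy.depth_report <- function(x, ...) {
  dplyr::mutate(x$table, administration = x$administration,
                calibrated = x$calibrated)
}

#' Read and write 16-bit grayscale images
#'
#' Thin wrappers around the `tiff` and `png` readers returning/consuming
#' integer count matrices in `[0, 65535]`. The format is chosen from the
#' file extension. Reading handles 8- and 16-bit files of either format;
#' writing is lossless 16-bit for TIFF, while the PNG writer stores 8 bits
#' per sample (a limitation of the underlying encoder), so TIFF is the
#' format of choice for synthetic fixtures.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`)
#' @param img integer matrix of counts
#' @return `read_gray16()`: a numeric matrix of counts;
#'   `write_gray16()`: `path`, invisibly
#' @export
read_gray16 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste0("unsupported image extension '", ext, "'"))
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}

#' @rdname read_gray16
#' @export
write_gray16 <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(img, 0), 65535) / 65535
  switch(ext,
    tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16),
    png = png::writePNG(scaled, path),
    abort(paste0("unsupported image extension '", ext, "'"))
  )
  invisible(path)
}
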