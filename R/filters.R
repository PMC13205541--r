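# Step 1 of the detection pipeline: collapse the RGB channels of a
# Wood's-light photograph into one monochrome image that maximises the
# contrast between fluorescing depigmented patches and background skin,
# optionally followed by contrast-limited adaptive histogram equalisation
# (CLAHE).

COMBINER_CATALOGUE <- c("red", "green", "blue", "luminance",
                        "blue_minus_red", "blue_over_sum")

#' Filter specification
#'
#' Settings for the contrast-enhancement stage. Under Wood's light,
#' depigmented skin fluoresces bluish-white, so the default combiner is the
#' blue channel; CLAHE then equalises contrast locally. The clip limit is
#' expressed as a fraction of the tile pixel count (the convention of the
#' common reference implementations of the method), so `0.01` means each
#' histogram bin may hold at most 1% of the tile's pixels before the excess
#' is redistributed.
#'
#' @param combiner one of `"red"`, `"green"`, `"blue"`, `"luminance"`
#'   (0.299R + 0.587G + 0.114B), `"blue_minus_red"` (B - R),
#'   `"blue_over_sum"` (B / (R + G + B + 1), one intensity unit of
#'   regularisation).
#' @param clahe_enabled apply CLAHE after channel combination?
#' @param clahe_clip_limit positive clip limit, fraction of tile pixel count.
#' @param clahe_tiles integer `(rows, cols)` tile grid, each `>= 1`.
#' @param clahe_bins number of histogram bins.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(combiner = "blue", clahe_enabled = TRUE,
                        clahe_clip_limit = 0.01, clahe_tiles = c(8L, 8L),
                        clahe_bins = 256L) {
  if (!is.character(combiner) || length(combiner) != 1L ||
      !combiner %in% COMBINER_CATALOGUE)
    stop_config(sprintf("unknown channel combiner '%s'; valid names: %s",
                        as.character(combiner)[1],
                        paste(COMBINER_CATALOGUE, collapse = ", ")))
  if (!isTRUE(clahe_enabled) && !isFALSE(clahe_enabled))
    stop_config("'clahe_enabled' must be TRUE or FALSE")
  if (!is.numeric(clahe_clip_limit) || length(clahe_clip_limit) != 1L ||
      clahe_clip_limit <= 0)
    stop_config("CLAHE clip limit must be a single positive number")
  clahe_tiles <- as.integer(clahe_tiles)
  if (length(clahe_tiles) != 2L || any(clahe_tiles < 1L))
    stop_config("CLAHE tiles must be two integers >= 1 (rows, cols)")
  clahe_bins <- as.integer(clahe_bins)
  if (length(clahe_bins) != 1L || clahe_bins < 2L)
    stop_config("CLAHE bin count must be an integer >= 2")
  structure(list(combiner = combiner, clahe_enabled = clahe_enabled,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tiles = clahe_tiles, clahe_bins = clahe_bins),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> combiner '%s', CLAHE %s",
              x$combiner, if (x$clahe_enabled) "on" else "off"))
  if (x$clahe_enabled)
    cat(sprintf(" (clip %.4g, %dx%d tiles, %d bins)",
                x$clahe_clip_limit, x$clahe_tiles[1], x$clahe_tiles[2],
                x$clahe_bins))
  cat("\n")
  invisible(x)
}

#' List the available channel combiners
#' @return Character vector of combiner names accepted by [combine_channels()].
#' @export
fviq_combiners <- function() COMBINER_CATALOGUE

#' Combine RGB channels into a monochrome image
#'
#' Applies one of the catalogue combiners and rescales the result to
#' `[0, 1]` by min-max normalisation over the whole image. A constant image
#' (no contrast at all, hence no patch evidence) maps to all zeros.
#'
#' @param img a [woods_image()].
#' @param combiner combiner name, see [fviq_combiners()].
#' @return Numeric `height x width` matrix with values in `[0, 1]`.
#' @export
combine_channels <- function(img, combiner = "blue") {
  stopifnot(inherits(img, "woods_image"))
  if (!combiner %in% COMBINER_CATALOGUE)
    stop_config(sprintf("unknown channel combiner '%s'; valid names: %s",
                        as.character(combiner)[1],
                        paste(COMBINER_CATALOGUE, collapse = ", ")))
  r <- img$pixels[, , 1]; g <- img$pixels[, , 2]; b <- img$pixels[, , 3]
  v <- switch(combiner,
    red            = r * 1.0,
    green          = g * 1.0,
    blue           = b * 1.0,
    luminance      = 0.299 * r + 0.587 * g + 0.114 * b,
    blue_minus_red = b - r * 1.0,
    blue_over_sum  = b / (r + g + b + 1)
  )
  rng <- range(v)
  if (rng[2] == rng[1]) {
    message("constant combined image; returning all-zero monochrome output")
    return(matrix(0, nrow = img$height, ncol = img$width))
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Tile-wise histogram equalisation with a clip limit that bounds noise
#' amplification, the standard CLAHE construction: the image is divided into
#' a grid of tiles, each tile's intensity histogram is clipped at
#' `clip_limit * tile_pixels` with the excess redistributed uniformly over
#' all bins, and every pixel is mapped through the bilinearly interpolated
#' cumulative distributions of its four neighbouring tiles. With a single
#' tile and a clip limit too large to bite, the operation reduces to global
#' histogram equalisation (each level maps to its empirical CDF value).
#'
#' @param mono numeric matrix with values in `[0, 1]`.
#' @param clip_limit positive clip limit as a fraction of tile pixel count;
#'   values `>= 1` disable clipping.
#' @param tiles integer `(rows, cols)` tile grid.
#' @param bins number of histogram bins.
#' @return Numeric matrix of the same dimensions, values in `[0, 1]`.
#' @export
clahe_enhance <- function(mono, clip_limit = 0.01, tiles = c(8L, 8L),
                          bins = 256L) {
  if (!is.matrix(mono) || !is.numeric(mono))
    stop_validation("'mono' must be a numeric matrix")
  if (anyNA(mono) || min(mono) < 0 || max(mono) > 1)
    stop_validation("'mono' values must lie in [0, 1]")
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0)
    stop_config("CLAHE clip limit must be a single positive number")
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L))
    stop_config("CLAHE tiles must be two integers >= 1 (rows, cols)")
  bins <- as.integer(bins)

  h <- nrow(mono); w <- ncol(mono)
  tr <- min(tiles[1], h); tc <- min(tiles[2], w)
  # tile edges (0-based continuous coordinates) and centres
  ye <- round(seq(0, h, length.out = tr + 1L))
  xe <- round(seq(0, w, length.out = tc + 1L))
  ycen <- (ye[-1] + ye[-(tr + 1L)]) / 2
  xcen <- (xe[-1] + xe[-(tc + 1L)]) / 2

  bin <- pmin(floor(mono * bins), bins - 1L) + 1L  # 1-based bin index matrix

  # per-tile clipped, renormalised CDF mappings
  maps <- matrix(0, nrow = tr * tc, ncol = bins)
  for (ti in seq_len(tr)) {
    rows <- (ye[ti] + 1L):ye[ti + 1L]
    for (tj in seq_len(tc)) {
      cols <- (xe[tj] + 1L):xe[tj + 1L]
      tb <- bin[rows, cols]
      n <- length(tb)
      hist <- tabulate(tb, nbins = bins)
      cl <- clip_limit * n
      if (max(hist) > cl) hist <- clip_histogram(hist, cl)
      maps[(ti - 1L) * tc + tj, ] <- cumsum(hist) / n
    }
  }

  # bilinear interpolation between the four surrounding tile mappings
  py <- seq_len(h) - 0.5
  px <- seq_len(w) - 0.5
  y0 <- pmin(pmax(findInterval(py, ycen), 1L), tr)
  y1 <- pmin(y0 + 1L, tr)
  wy <- ifelse(y1 > y0, (py - ycen[y0]) / (ycen[y1] - ycen[y0]), 0)
  wy <- pmin(pmax(wy, 0), 1)
  x0 <- pmin(pmax(findInterval(px, xcen), 1L), tc)
  x1 <- pmin(x0 + 1L, tc)
  wx <- ifelse(x1 > x0, (px - xcen[x0]) / (xcen[x1] - xcen[x0]), 0)
  wx <- pmin(pmax(wx, 0), 1)

  Y0 <- matrix(y0, h, w); Y1 <- matrix(y1, h, w)
  X0 <- matrix(x0, h, w, byrow = TRUE); X1 <- matrix(x1, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)

  gather <- function(ty, tx) {
    matrix(maps[cbind(as.vector((ty - 1L) * tc + tx), as.vector(bin))], h, w)
  }
  out <- (1 - WY) * (1 - WX) * gather(Y0, X0) +
         (1 - WY) * WX       * gather(Y0, X1) +
         WY       * (1 - WX) * gather(Y1, X0) +
         WY       * WX       * gather(Y1, X1)
  pmin(pmax(out, 0), 1)
}

# Clip a histogram at 'cl' counts per bin and redistribute the excess
# uniformly; iterate because redistribution can push bins back over the
# limit. Total mass is preserved.
clip_histogram <- function(hist, cl, max_iter = 20L) {
  nb <- length(hist)
  for (i in seq_len(max_iter)) {
    excess <- sum(pmax(hist - cl, 0))
    if (excess <= 1e-9) break
    hist <- pmin(hist, cl) + excess / nb
  }
  hist
}

#' Apply a full filter specification
#'
#' Channel combination followed, if enabled, by CLAHE. With
#' `clahe_enabled = FALSE` the result is exactly [combine_channels()].
#'
#' @param img a [woods_image()].
#' @param spec a [filter_spec()].
#' @return Numeric `height x width` matrix in `[0, 1]`.
#' @export
apply_filter <- function(img, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  mono <- combine_channels(img, spec$combiner)
  if (spec$clahe_enabled)
    mono <- clahe_enhance(mono, clip_limit = spec$clahe_clip_limit,
                          tiles = spec$clahe_tiles, bins = spec$clahe_bins)
  mono
}
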