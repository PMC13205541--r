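# Small fixtures built in code at test time.

# A flat-colour RGB image of the given size.
flat_image <- function(r, g, b, w = 8L, h = 8L, view = "frontal") {
  px <- array(0, dim = c(h, w, 3L))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  woods_image(px, view = view)
}

# An image whose blue channel carries two bright rectangles on dark skin,
# with a full-frame square face outline; used for hand-countable
# segmentation cases. Rectangles are (x0, y0, x1, y1) in pixel coords.
two_patch_image <- function(w = 40L, h = 40L,
                            rect1 = c(5, 5, 15, 10),
                            rect2 = c(25, 25, 35, 30)) {
  px <- array(0, dim = c(h, w, 3L))
  px[, , 3] <- 40
  fill <- function(px, rect, value) {
    rows <- (rect[2] + 1L):rect[4]
    cols <- (rect[1] + 1L):rect[3]
    px[rows, cols, 3] <- value
    px
  }
  px <- fill(px, rect1, 220)
  px <- fill(px, rect2, 220)
  img <- woods_image(px, view = "frontal")
  face <- polygon_roi(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
                      kind = "face_outline")
  roi_of <- function(rect, pad = 2) {
    polygon_roi(rbind(c(rect[1] - pad, rect[2] - pad),
                      c(rect[3] + pad, rect[2] - pad),
                      c(rect[3] + pad, rect[4] + pad),
                      c(rect[1] - pad, rect[4] + pad)),
                kind = "patch")
  }
  list(img = img,
       ann = view_annotation("frontal", face,
                             list(roi_of(rect1), roi_of(rect2))),
       rect_px = c(prod(rect1[3:4] - rect1[1:2]),
                   prod(rect2[3:4] - rect2[1:2])))
}

# Minimal valid annotation JSON written to a temp file; returns the path.
write_minimal_annotation <- function(patch_threshold = NULL) {
  doc <- list(
    view = "frontal",
    face = list(vertices = list(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
    patches = list(local({
      p <- list(vertices = list(c(2, 2), c(6, 2), c(4, 6)))
      if (!is.null(patch_threshold)) p$threshold <- patch_threshold
      p
    }))
  )
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  path
}
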