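# Glyph images: a character as a binary raster.
#
# The image channel views each Chinese character as a square 14x14
# black-and-white picture (1 = ink) whose shape carries pictographic
# information. Images come from one of two sources:
#   * font_raster   — rasterized from a font at run time (requires a CJK
#     font on the system; the reference choice is NotoSansCJKsc-Regular)
#   * fixture_bitmap — loaded from a bundled plain-text bitmap archive, so
#     tests and offline runs never need a font. The bundled archive is
#     synthetic (procedurally generated shapes, not real glyph outlines).

GLYPH_SIZE <- 14L

#' Construct a glyph image
#'
#' @param char The character the image depicts.
#' @param pixels 14x14 matrix with entries in `{0, 1}` (1 = ink).
#' @param source `"font_raster"` or `"fixture_bitmap"`.
#' @return A `glyph_image` object.
#' @export
glyph_image <- function(char, pixels, source = c("fixture_bitmap", "font_raster")) {
  source <- match.arg(source)
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == c(GLYPH_SIZE, GLYPH_SIZE))) {
    abort(sprintf("glyph for %s must be %dx%d, got %dx%d",
                  dQuote(char), GLYPH_SIZE, GLYPH_SIZE, nrow(pixels), ncol(pixels)))
  }
  if (!all(pixels %in% c(0, 1))) {
    abort(sprintf("glyph for %s has non-binary pixels", dQuote(char)))
  }
  storage.mode(pixels) <- "double"
  structure(list(char = char, pixels = pixels, source = source),
            class = "glyph_image")
}

#' @export
print.glyph_image <- function(x, ...) {
  cat(sprintf("<glyph_image> %s (%s), ink %.2f\n",
              dQuote(x$char), x$source, mean(x$pixels)))
  for (r in seq_len(nrow(x$pixels))) {
    cat(paste(ifelse(x$pixels[r, ] == 1, "#", "."), collapse = ""), "\n")
  }
  invisible(x)
}

#' Load a fixture bitmap archive
#'
#' The archive is plain text: blocks of a `CHAR U+XXXX` line followed by 14
#' lines of 14 characters in `{0, 1}`.
#'
#' @param path Archive path.
#' @return Named list of [glyph_image()] objects keyed by character.
#' @export
load_fixture_bitmaps <- function(path) {
  if (!file.exists(path)) abort(sprintf("bitmap archive not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- lines[i]
    if (!grepl("^CHAR U\\+[0-9A-Fa-f]+$", hdr)) {
      abort(sprintf("malformed block header: %s", dQuote(hdr)))
    }
    cp <- strtoi(sub("^CHAR U\\+", "", hdr), base = 16L)
    ch <- intToUtf8(cp)
    rows <- lines[seq(i + 1L, length.out = GLYPH_SIZE)]
    if (length(rows) < GLYPH_SIZE || anyNA(rows) ||
        any(!grepl(sprintf("^[01]{%d}$", GLYPH_SIZE), rows))) {
      abort(sprintf("glyph block for %s is not %d rows of %d binary digits",
                    dQuote(ch), GLYPH_SIZE, GLYPH_SIZE))
    }
    px <- do.call(rbind, lapply(rows, function(r) as.integer(chars_of(r))))
    out[[ch]] <- glyph_image(ch, px, source = "fixture_bitmap")
    i <- i + 1L + GLYPH_SIZE
  }
  out
}

#' Load the bundled synthetic bitmap archive
#'
#' Covers the reference characters and the synthetic-corpus character set.
#' The bitmaps are procedurally generated stand-ins, not rasterizations of a
#' real font: deterministic, distinct, binary, with realistic ink fractions.
#'
#' @return Named list of [glyph_image()] objects.
#' @export
bundled_glyph_bitmaps <- function() {
  load_fixture_bitmaps(mscner_file("glyph_bitmaps_synthetic.txt"))
}

#' Render one character as a 14x14 binary image
#'
#' With `font = NULL` (the default) the character is taken from the fixture
#' bitmap archive. With a font family name, the glyph is rasterized on a
#' cairo bitmap device, greyscale is binarized at `threshold`, and rendering
#' is deterministic for fixed font and settings; if rasterization is
#' unavailable the bundled bitmap is used as fallback, and an error is
#' raised only when the character is in neither source. Whitespace always
#' yields the all-zero image.
#'
#' @param char Single character.
#' @param font Font family name, or `NULL` to use fixture bitmaps.
#' @param size Canvas side in pixels (default 14; minimum 4).
#' @param threshold Grey level in `(0, 1)` above which a pixel is ink.
#' @param bitmaps Fixture bitmaps to consult (default: the bundled archive).
#' @return A [glyph_image()].
#' @export
render_glyph <- function(char, font = NULL, size = GLYPH_SIZE, threshold = 0.5,
                         bitmaps = NULL) {
  if (length(char) != 1L || is.na(char) || nchar(char) != 1L) {
    abort("`char` must be a single character.")
  }
  if (size < 4L) abort("`size` must be at least 4.")
  if (grepl("^\\s$", char)) {
    return(glyph_image(char, matrix(0, size, size), source = "fixture_bitmap"))
  }
  if (!is.null(font)) {
    px <- try(rasterize_glyph(char, font, size, threshold), silent = TRUE)
    if (!inherits(px, "try-error") && !is.null(px) && any(px == 1)) {
      out <- glyph_image(char, px, source = "font_raster")
      return(out)
    }
  }
  bitmaps <- bitmaps %||% bundled_glyph_bitmaps()
  if (!is.null(bitmaps[[char]])) {
    img <- bitmaps[[char]]
    if (nrow(img$pixels) != size) {
      abort(sprintf("fixture bitmap for %s is %dx%d, requested size %d",
                    dQuote(char), nrow(img$pixels), ncol(img$pixels), size))
    }
    return(img)
  }
  abort(sprintf("no glyph source for %s: font unavailable and not in fixture bitmaps",
                dQuote(char)))
}

# Rasterize on a cairo png device; returns binary size x size matrix or NULL.
rasterize_glyph <- function(char, font, size, threshold) {
  if (!capabilities("cairo") || !requireNamespace("png", quietly = TRUE)) return(NULL)
  scale <- 8L # supersample, then average down for crisper small rasters
  big <- size * scale
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp), add = TRUE)
  grDevices::png(tmp, width = big, height = big, type = "cairo", bg = "white")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::text(0.5, 0.5, char, cex = big / 12, family = font, col = "black")
  grDevices::dev.off()
  arr <- png::readPNG(tmp)
  grey <- if (length(dim(arr)) == 3) apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean) else arr
  # average-pool the supersampled raster down to size x size, ink = dark
  px <- matrix(0, size, size)
  for (r in seq_len(size)) {
    for (c in seq_len(size)) {
      blk <- grey[((r - 1) * scale + 1):(r * scale), ((c - 1) * scale + 1):(c * scale)]
      px[r, c] <- as.numeric((1 - mean(blk)) >= threshold)
    }
  }
  px
}
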