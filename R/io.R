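#' Read a glyph image from a PNG or PBM/PGM file
#'
#' Grayscale or color input is collapsed to a binary mask: a pixel is
#' foreground when its intensity lies on the character's side of 50% of
#' the file's dynamic range. Which side that is depends on the ink
#' convention of the source (\code{"dark"} characters on a light
#' background, the usual raster convention, or \code{"light"} on dark).
#'
#' @param path file path; format is inferred from the extension
#'   (\code{.png}, \code{.pbm}, \code{.pgm}, \code{.pnm}).
#' @param ink \code{"dark"} (default) or \code{"light"}: which intensity
#'   side carries the character.
#' @param stage stage label to attach, default \code{"raw"}.
#' @param script,codepoint optional provenance labels; when missing they
#'   are parsed from a \code{<script>_<codepoint>} file name if possible.
#' @return a [GlyphImage-class].
#' @export
readGlyph <- function(path, ink = c("dark", "light"), stage = "raw",
                      script = NULL, codepoint = NULL) {
  ink <- match.arg(ink)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  inten <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE], c(1L, 2L), mean)
      # readPNG: rows = y top-to-bottom, cols = x; transpose to x-major
      t(a)[, , drop = TRUE]
    },
    pbm = , pgm = , pnm = .readPNM(path),
    stop("unsupported image extension: ", ext)
  )
  fg <- if (ink == "dark") inten < 0.5 else inten >= 0.5
  if (is.null(script) || is.null(codepoint)) {
    nm <- tools::file_path_sans_ext(basename(path))
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    if (is.null(script)) script <- if (length(parts) >= 2L) parts[1L] else NA_character_
    if (is.null(codepoint)) {
      codepoint <- if (length(parts) >= 2L) paste(parts[-1L], collapse = "_") else NA_character_
    }
  }
  GlyphImage(fg, stage = stage, script = script, codepoint = codepoint)
}

#' Write a glyph image
#'
#' PBM output is plain-text P1 (1 = foreground); PNG output is black
#' character on white background.
#'
#' @param glyph a [GlyphImage-class].
#' @param path output path; format from extension (\code{.png},
#'   \code{.pbm}).
#' @return \code{path}, invisibly.
#' @export
writeGlyph <- function(glyph, path) {
  stopifnot(is(glyph, "GlyphImage"))
  ext <- tolower(tools::file_ext(path))
  px <- glyph@pixels
  switch(ext,
    png = {
      # black-on-white; transpose back to row = y
      png::writePNG(t(1 - px * 1), path)
    },
    pbm = .writePBM(px, path),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

# Plain (ASCII) netpbm reader: P1 (bitmap) and P2 (graymap).
# Returns intensity in [0, 1] with 1 = white, matrix indexed [x, y].
.readPNM <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  magic <- toks[1L]
  if (!magic %in% c("P1", "P2")) {
    stop("only plain P1/P2 netpbm files are supported, got ", magic)
  }
  w <- as.integer(toks[2L])
  h <- as.integer(toks[3L])
  if (magic == "P1") {
    vals <- as.integer(toks[-(1:3)])
    if (length(vals) != w * h) stop("corrupt PBM: wrong pixel count")
    # P1: 1 = black; row-major top-to-bottom
    inten <- 1 - vals
  } else {
    maxv <- as.integer(toks[4L])
    vals <- as.integer(toks[-(1:4)])
    if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
    inten <- vals / maxv
  }
  matrix(inten, nrow = w, ncol = h)[, seq_len(h), drop = FALSE]
}

.writePBM <- function(px, path) {
  w <- nrow(px)
  h <- ncol(px)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(w, h)), con)
  # row-major top-to-bottom: iterate y, emit x across
  for (y in seq_len(h)) {
    writeLines(paste(as.integer(px[, y]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a directory of glyph images
#'
#' Files are expected to be named \code{<script>_<codepoint>.<ext>}.
#'
#' @param dir directory containing PNG and/or PBM files.
#' @param ink see [readGlyph()].
#' @param stage stage label to attach to every image.
#' @return a named list of [GlyphImage-class] (names
#'   \code{script_codepoint}), sorted by name.
#' @export
readGlyphDir <- function(dir, ink = "dark", stage = "raw") {
  files <- list.files(dir, pattern = "\\.(png|pbm|pgm|pnm)$", full.names = TRUE,
                      ignore.case = TRUE)
  files <- sort(files)
  out <- lapply(files, readGlyph, ink = ink, stage = stage)
  names(out) <- vapply(out, function(g) {
    paste(g@script, g@codepoint, sep = "_")
  }, character(1L))
  out
}
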