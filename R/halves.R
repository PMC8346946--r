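#' Split a standardized glyph into left and right halves
#'
#' Cuts a 500x500 picture at the vertical midline: columns 1-250 of the
#' canvas become the left half, columns 251-500 the right half, a clean
#' partition with no pixel lost or duplicated.
#'
#' @param glyph [GlyphImage-class], 500 pixels wide.
#' @return list with elements \code{left} and \code{right}, each a
#'   250x500 [GlyphImage-class].
#' @export
splitVertical <- function(glyph) {
  stopifnot(is(glyph, "GlyphImage"))
  px <- glyph@pixels
  if (nrow(px) != .CANVAS) {
    stop("splitVertical: input must be ", .CANVAS, " pixels wide, got ",
         nrow(px))
  }
  mk <- function(m) {
    GlyphImage(m, stage = glyph@stage, script = glyph@script,
               codepoint = glyph@codepoint)
  }
  list(
    left = mk(px[seq_len(.HALF_WIDTH), , drop = FALSE]),
    right = mk(px[(.HALF_WIDTH + 1L):.CANVAS, , drop = FALSE])
  )
}

#' Pad a half on its inner (cut) side
#'
#' Appends 50 background columns on the side where the character was
#' cut - the right edge of a left half, the left edge of a right half -
#' bringing each half to 300x500. Padding keeps the character away from
#' the picture border, where contour measurement misbehaves.
#'
#' @param half a 250x500 [GlyphImage-class] from [splitVertical()].
#' @param which_side \code{"left"} or \code{"right"}: which half this is.
#' @return a 300x500 [GlyphImage-class].
#' @export
padInner <- function(half, which_side = c("left", "right")) {
  which_side <- match.arg(which_side)
  stopifnot(is(half, "GlyphImage"))
  px <- half@pixels
  if (nrow(px) != .HALF_WIDTH || ncol(px) != .CANVAS) {
    stop(sprintf("padInner: input must be %dx%d, got %dx%d",
                 .HALF_WIDTH, .CANVAS, nrow(px), ncol(px)))
  }
  pad <- matrix(FALSE, .PADDED_WIDTH - .HALF_WIDTH, .CANVAS)
  out <- if (which_side == "left") rbind(px, pad) else rbind(pad, px)
  GlyphImage(out, stage = half@stage, script = half@script,
             codepoint = half@codepoint)
}

#' Build the padded half pair of one character
#'
#' @param glyph standardized 500x500 [GlyphImage-class].
#' @param directionality \code{"LR"} or \code{"RL"} (may be NA when only
#'   laterality, not order, is of interest).
#' @return a [HalfPair-class].
#' @export
halfPair <- function(glyph, directionality = NA_character_) {
  halves <- splitVertical(glyph)
  new("HalfPair",
    left = padInner(halves$left, "left"),
    right = padInner(halves$right, "right"),
    directionality = as.character(directionality),
    script = glyph@script, codepoint = glyph@codepoint
  )
}

#' Undo the inner padding of a half
#'
#' @param padded a 300x500 [GlyphImage-class].
#' @param which_side which half it is.
#' @return the 250x500 unpadded half.
#' @export
unpadInner <- function(padded, which_side = c("left", "right")) {
  which_side <- match.arg(which_side)
  px <- padded@pixels
  if (nrow(px) != .PADDED_WIDTH) stop("unpadInner: input must be 300 wide")
  keep <- if (which_side == "left") seq_len(.HALF_WIDTH) else
    (.PADDED_WIDTH - .HALF_WIDTH + 1L):.PADDED_WIDTH
  GlyphImage(px[keep, , drop = FALSE], stage = padded@stage,
             script = padded@script, codepoint = padded@codepoint)
}

#' Rejoin unpadded halves into the original image
#'
#' @param pair a [HalfPair-class].
#' @return the reconstructed 500x500 [GlyphImage-class].
#' @export
rejoinHalves <- function(pair) {
  stopifnot(is(pair, "HalfPair"))
  l <- unpadInner(pair@left, "left")
  r <- unpadInner(pair@right, "right")
  GlyphImage(rbind(l@pixels, r@pixels), stage = l@stage,
             script = pair@script, codepoint = pair@codepoint)
}

#' Complexity of both halves of a character
#'
#' Perimetric and algorithmic complexity computed on the padded halves.
#' A blank half has no defined perimetric complexity (recorded as NA and
#' dropped from perimetric differential analyses downstream) but a valid
#' algorithmic complexity (the blank-canvas baseline).
#'
#' @param pair a [HalfPair-class].
#' @param metrics subset of \code{c("pc", "ac")}.
#' @return data.frame, one row per half, columns script, codepoint,
#'   side, order, C, AC.
#' @export
halfComplexities <- function(pair, metrics = c("pc", "ac")) {
  stopifnot(is(pair, "HalfPair"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  one <- function(g, side) {
    C <- NA_real_
    AC <- NA_real_
    if ("pc" %in% metrics && any(g@pixels)) C <- perimetricComplexity(g)@C
    if ("ac" %in% metrics) AC <- as.numeric(algorithmicComplexity(g))
    ord <- if (is.na(pair@directionality)) {
      NA_character_
    } else if ((side == "left") == (pair@directionality == "LR")) {
      "first"
    } else {
      "last"
    }
    data.frame(script = pair@script, codepoint = pair@codepoint,
               side = side, order = ord, C = C, AC = AC,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(pair@left, "left"), one(pair@right, "right"))
  rownames(out) <- NULL
  out
}

#' First-half minus last-half complexity differential
#'
#' The first half is the half coming first in writing order: left in a
#' left-to-right script, right in a right-to-left script.
#'
#' @param c_left,c_right complexity of the left and right half (any one
#'   metric; vectors allowed).
#' @param directionality \code{"LR"} or \code{"RL"} (scalar or vector).
#' @return first-half minus last-half differential.
#' @export
firstLastDifferential <- function(c_left, c_right, directionality) {
  if (any(!directionality %in% c("LR", "RL"))) {
    stop("firstLastDifferential: directionality must be 'LR' or 'RL' ",
         "(other-direction scripts are excluded upstream)")
  }
  ifelse(directionality == "LR", c_left - c_right, c_right - c_left)
}

#' Per-half discrepancy scores between the two metrics
#'
#' Each complexity measure is z-normalized over the full population of
#' analyzed halves, and the discrepancy D = z(PC) - z(AC) is returned
#' per half. D diagnoses metric-specific laterality bias: positive D
#' means perimetric complexity rates that half as relatively more
#' complex than algorithmic complexity does.
#'
#' @param halves data.frame with columns \code{C} and \code{AC} (one row
#'   per half, as from stacking [halfComplexities()] results).
#' @return the input with a new column \code{D} (NA where either metric
#'   is missing).
#' @export
discrepancyScores <- function(halves) {
  stopifnot(all(c("C", "AC") %in% names(halves)))
  ok <- stats::complete.cases(halves[, c("C", "AC")])
  if (sum(ok) < 2L) stop("discrepancyScores: need at least 2 complete halves")
  zc <- halves$C[ok]
  zac <- halves$AC[ok]
  if (stats::sd(zc) == 0 || stats::sd(zac) == 0) {
    stop("discrepancyScores: zero variance in a metric")
  }
  halves$D <- NA_real_
  halves$D[ok] <- as.numeric(scale(zc)) - as.numeric(scale(zac))
  halves
}

#' Half-level and character-level tables for the order analyses
#'
#' Runs split/pad/measure over a corpus and assembles the two tables the
#' order and laterality models consume: one row per half (with
#' discrepancy scores) and one row per character (with first/last and
#' left/right differentials per metric).
#'
#' @param glyphs list of standardized [GlyphImage-class] objects.
#' @param inventory data.frame with \code{code}, \code{directionality}
#'   and (optionally) \code{family}; scripts with directionality
#'   \code{"other"} are dropped with a message.
#' @param metrics subset of \code{c("pc", "ac")}.
#' @return list with data.frames \code{halves} (script, family,
#'   codepoint, side, order, C, AC, D) and \code{characters} (script,
#'   family, directionality, codepoint, dFL_pc, dFL_ac, dLR_pc, dLR_ac).
#' @export
halvesTable <- function(glyphs, inventory, metrics = c("pc", "ac")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  keep <- orderAnalysisSubset(inventory)
  dropped <- setdiff(inventory$code, keep$code)
  if (length(dropped)) {
    message("halvesTable: dropping script(s) outside the order subset: ",
            paste(dropped, collapse = ", "))
  }
  dir_of <- stats::setNames(keep$directionality, keep$code)
  fam_of <- if ("family" %in% names(keep)) {
    stats::setNames(keep$family, keep$code)
  } else {
    stats::setNames(rep(NA_character_, nrow(keep)), keep$code)
  }
  rows <- list()
  for (g in glyphs) {
    d <- dir_of[g@script]
    if (is.na(d)) next
    pair <- halfPair(g, directionality = unname(d))
    h <- halfComplexities(pair, metrics = metrics)
    h$family <- unname(fam_of[g@script])
    h$directionality <- unname(d)
    rows[[length(rows) + 1L]] <- h
  }
  if (!length(rows)) stop("halvesTable: no glyphs in the order subset")
  halves <- do.call(rbind, rows)
  rownames(halves) <- NULL
  if (all(c("pc", "ac") %in% metrics)) {
    halves <- discrepancyScores(halves)
  }
  wide <- function(metric_col) {
    l <- halves[halves$side == "left", c("script", "codepoint", metric_col)]
    r <- halves[halves$side == "right", c("script", "codepoint", metric_col)]
    names(l)[3L] <- "left"
    names(r)[3L] <- "right"
    merge(l, r, by = c("script", "codepoint"), sort = FALSE)
  }
  chars <- NULL
  for (m in metrics) {
    col <- if (m == "pc") "C" else "AC"
    w <- wide(col)
    w[[paste0("dLR_", m)]] <- w$left - w$right
    w[[paste0("dFL_", m)]] <- firstLastDifferential(
      w$left, w$right, unname(dir_of[w$script])
    )
    w$left <- NULL
    w$right <- NULL
    chars <- if (is.null(chars)) w else merge(chars, w,
                                              by = c("script", "codepoint"),
                                              sort = FALSE)
  }
  chars$directionality <- unname(dir_of[chars$script])
  chars$family <- unname(fam_of[chars$script])
  list(halves = halves, characters = chars)
}
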