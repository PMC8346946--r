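# Analytic raster fixtures, built in code at test time.

mkDisk <- function(r, ox = 0, oy = 0, margin = 10L) {
  n <- 2L * r + 2L * margin + 1L
  cx <- (n + 1) / 2
  px <- outer(seq_len(n), seq_len(n), function(i, j) {
    sqrt((i - cx - ox)^2 + (j - cx - oy)^2) <= r
  })
  GlyphImage(px)
}

mkSquare <- function(s, margin = 20L) {
  n <- s + 2L * margin
  px <- matrix(FALSE, n, n)
  px[margin + seq_len(s), margin + seq_len(s)] <- TRUE
  GlyphImage(px)
}

mkAnnulus <- function(R, r, margin = 10L) {
  n <- 2L * R + 2L * margin + 1L
  cx <- (n + 1) / 2
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    sqrt((i - cx)^2 + (j - cx)^2)
  })
  GlyphImage(d <= R & d > r)
}

# a horizontal 5-px-thick bar on the standard canvas
mkBarGlyph <- function(x0 = 100L, x1 = 400L, yc = 250L,
                       stage = "skeleton-standardized") {
  px <- matrix(FALSE, 500L, 500L)
  px[x0:x1, (yc - 2L):(yc + 2L)] <- TRUE
  GlyphImage(px, stage = stage)
}

# small inventory fixture
mkInventory <- function(codes, directionality, family = "Phoenician",
                        type = "alphabet", n_missing = 0L,
                        ancestor = NA_character_) {
  n <- length(codes)
  data.frame(
    code = codes,
    family = rep_len(family, n),
    type = rep_len(type, n),
    directionality = rep_len(directionality, n),
    inventory_size = rep_len(10L, n),
    idiosyncratic = rep_len(FALSE, n),
    ancestor = rep_len(ancestor, n),
    n_missing = rep_len(n_missing, n),
    stringsAsFactors = FALSE
  )
}
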