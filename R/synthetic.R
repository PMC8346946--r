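#' Specification for the synthetic corpus generator
#'
#' Bundles every controlled parameter of the generator: the grouping
#' structure (families, scripts, characters), the hierarchical
#' stroke-count model (a type-level mean, a log-normal script effect and
#' character noise), the directionality mix, the share of strokes
#' falling in the reading-order first half, and the ancestry rules.
#' Given the same spec and seed the generated corpus is bit-reproducible.
#'
#' @param n_families number of script families.
#' @param scripts_per_family scripts per family.
#' @param chars_per_script characters per script.
#' @param type_strokes named numeric: mean stroke count per writing
#'   system type; scripts cycle deterministically through these types
#'   within each family.
#' @param script_sd standard deviation of the script-level log
#'   stroke-count effect.
#' @param char_sd standard deviation of the character-level log noise.
#' @param share_LR share of scripts written left-to-right (the rest are
#'   right-to-left).
#' @param first_half_share probability that a stroke lands in the half
#'   read first; 0.5 is the symmetric null.
#' @param delta_drift added to descendant scripts' log stroke-count
#'   effect (0 = no complexity change at branching).
#' @param seed integer root seed.
#' @return an object of class \code{GlyphGeneratorSpec} (a validated
#'   list).
#' @export
generatorSpec <- function(n_families = 7L, scripts_per_family = 4L,
                          chars_per_script = 20L,
                          type_strokes = c(alphabet = 3, abjad = 3,
                                           abugida = 4, syllabary = 5,
                                           logosyllabary = 9, featural = 4),
                          script_sd = 0.25, char_sd = 0.35,
                          share_LR = 0.78, first_half_share = 0.5,
                          delta_drift = 0, seed = 1L) {
  spec <- list(
    n_families = as.integer(n_families),
    scripts_per_family = as.integer(scripts_per_family),
    chars_per_script = as.integer(chars_per_script),
    type_strokes = type_strokes, script_sd = script_sd, char_sd = char_sd,
    share_LR = share_LR, first_half_share = first_half_share,
    delta_drift = delta_drift, seed = as.integer(seed)
  )
  if (spec$n_families < 1L || spec$scripts_per_family < 1L ||
      spec$chars_per_script < 1L) {
    stop("generatorSpec: all counts must be >= 1")
  }
  if (spec$first_half_share < 0 || spec$first_half_share > 1) {
    stop("generatorSpec: first_half_share must be in [0, 1]")
  }
  if (spec$share_LR < 0 || spec$share_LR > 1) {
    stop("generatorSpec: share_LR must be in [0, 1]")
  }
  if (is.null(names(spec$type_strokes)) ||
      !all(names(spec$type_strokes) %in% .TYPES)) {
    stop("generatorSpec: type_strokes must be named with known types")
  }
  if (any(spec$type_strokes < 1) || spec$script_sd < 0 || spec$char_sd < 0) {
    stop("generatorSpec: stroke means must be >= 1 and sds >= 0")
  }
  class(spec) <- "GlyphGeneratorSpec"
  spec
}

#' @export
print.GlyphGeneratorSpec <- function(x, ...) {
  cat(sprintf(
    "GlyphGeneratorSpec: %d families x %d scripts x %d chars, first_half_share=%.2f, seed=%d\n",
    x$n_families, x$scripts_per_family, x$chars_per_script,
    x$first_half_share, x$seed
  ))
  invisible(x)
}

.GEN_MARGIN <- 24
.MAX_STROKES <- 200L

# One random stroke: a straight segment or circular arc, returned as a
# dense polyline (columns x, y).
.strokePoints <- function() {
  if (stats::runif(1) < 0.6) {
    len <- stats::runif(1, 40, 110)
    ang <- stats::runif(1, 0, 2 * pi)
    t <- seq(0, 1, length.out = max(8L, ceiling(len * 2)))
    cbind(t * len * cos(ang), t * len * sin(ang))
  } else {
    rho <- stats::runif(1, 18, 55)
    a0 <- stats::runif(1, 0, 2 * pi)
    da <- stats::runif(1, pi / 2, 3 * pi / 2)
    a <- seq(a0, a0 + da, length.out = max(8L, ceiling(rho * da * 2)))
    cbind(rho * cos(a), rho * sin(a))
  }
}

#' Generate one synthetic glyph
#'
#' Draws \code{n_strokes} random straight or arc strokes of ~5 px
#' thickness on the canvas. Each stroke independently lands in the
#' reading-order first half (left for LR, right for RL) with probability
#' \code{first_half_share}, which is the generator's ground-truth handle
#' on within-character complexity asymmetry. The glyph need not be
#' connected. Uses the current RNG stream unless \code{seed} is given.
#'
#' @param n_strokes number of strokes (>= 1).
#' @param first_half_share probability a stroke lands in the first half.
#' @param directionality \code{"LR"} or \code{"RL"}.
#' @param canvas canvas side in pixels (default 500).
#' @param seed optional integer seed for a self-contained draw.
#' @return a [GlyphImage-class] at stage \code{"skeleton-standardized"}
#'   (strokes are drawn at the standardized thickness directly).
#' @export
generateGlyph <- function(n_strokes, first_half_share = 0.5,
                          directionality = c("LR", "RL"), canvas = 500L,
                          seed = NULL) {
  directionality <- match.arg(directionality)
  if (n_strokes < 1L) stop("generateGlyph: n_strokes must be >= 1")
  if (n_strokes > .MAX_STROKES) {
    stop("generateGlyph: n_strokes = ", n_strokes,
         " would saturate the canvas (max ", .MAX_STROKES, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  canvas <- as.integer(canvas)
  half <- canvas %/% 2L
  m <- .GEN_MARGIN
  sk <- matrix(FALSE, canvas, canvas)
  first_is_left <- directionality == "LR"
  for (s in seq_len(n_strokes)) {
    in_first <- stats::runif(1) < first_half_share
    in_left <- (in_first & first_is_left) | (!in_first & !first_is_left)
    xlo <- if (in_left) 1L + m else half + 1L + m
    xhi <- if (in_left) half - m else canvas - m
    pts <- .strokePoints()
    # translate the stroke into its half, preserving its shape
    bx <- range(pts[, 1L])
    by <- range(pts[, 2L])
    wx <- bx[2L] - bx[1L]
    wy <- by[2L] - by[1L]
    ox <- stats::runif(1, xlo, max(xlo, xhi - wx)) - bx[1L]
    oy <- stats::runif(1, 1 + m, max(1 + m, canvas - m - wy)) - by[1L]
    xs <- as.integer(round(pts[, 1L] + ox))
    ys <- as.integer(round(pts[, 2L] + oy))
    keep <- xs >= 1L & xs <= canvas & ys >= 1L & ys <= canvas
    sk[cbind(xs[keep], ys[keep])] <- TRUE
  }
  px <- .boxDilate(sk, 2L)
  if (mean(px) > 0.5) stop("generateGlyph: canvas saturated")
  GlyphImage(px, stage = "skeleton-standardized")
}

#' Generate a full synthetic corpus
#'
#' Emits the data structures the rest of the pipeline consumes: an
#' inventory table (with family, type, directionality, ancestry and
#' idiosyncratic flags), a character table, the glyph images, and a
#' ground-truth sidecar recording every latent quantity the generator
#' controlled (type of each script, script-level effects, realized
#' stroke counts, the drift and the first-half share), so recovery tests
#' never re-derive truth from generator internals.
#'
#' Stroke counts follow a hierarchical log-normal model:
#' \code{log n = log(type mean) + script effect + character noise}.
#' Within each family the first script is the ancestor of its siblings;
#' descendant script effects get \code{delta_drift} added, so a nonzero
#' drift makes descendants systematically more (or less) complex.
#'
#' @param spec a [generatorSpec()].
#' @return list with \code{inventory}, \code{characters}, \code{glyphs}
#'   (named list of [GlyphImage-class]), and \code{truth}.
#' @export
generateCorpus <- function(spec) {
  stopifnot(inherits(spec, "GlyphGeneratorSpec"))
  set.seed(spec$seed)
  fam_pool <- rep_len(.FAMILIES, spec$n_families)
  fam_ids <- if (spec$n_families <= length(.FAMILIES)) {
    fam_pool
  } else {
    paste0(fam_pool, rep(seq_len(ceiling(spec$n_families / length(.FAMILIES))),
                         each = length(.FAMILIES))[seq_len(spec$n_families)])
  }
  types <- names(spec$type_strokes)
  n_scripts <- spec$n_families * spec$scripts_per_family
  inv <- data.frame(
    code = sprintf("Sy%02d", seq_len(n_scripts)),
    family = rep(fam_ids, each = spec$scripts_per_family),
    type = rep_len(types, n_scripts),
    directionality = NA_character_,
    inventory_size = spec$chars_per_script,
    idiosyncratic = FALSE,
    ancestor = NA_character_,
    n_missing = 0L,
    stringsAsFactors = FALSE
  )
  n_lr <- round(n_scripts * spec$share_LR)
  dirs <- sample(c(rep("LR", n_lr), rep("RL", n_scripts - n_lr)))
  inv$directionality <- dirs
  within_idx <- rep(seq_len(spec$scripts_per_family), times = spec$n_families)
  first_of_family <- inv$code[within_idx == 1L]
  inv$ancestor <- ifelse(within_idx == 1L, NA_character_,
                         rep(first_of_family, each = spec$scripts_per_family)[
                           seq_len(n_scripts)])
  recent <- inv$family == "RecentInventions"
  inv$idiosyncratic[recent] <- seq_len(sum(recent)) %% 2L == 1L
  script_eff <- stats::rnorm(n_scripts, 0, spec$script_sd)
  script_eff <- script_eff + ifelse(is.na(inv$ancestor), 0, spec$delta_drift)
  names(script_eff) <- inv$code
  glyphs <- list()
  char_rows <- list()
  stroke_counts <- list()
  for (i in seq_len(n_scripts)) {
    code <- inv$code[i]
    mu <- log(spec$type_strokes[[inv$type[i]]]) + script_eff[i]
    n_str <- pmax(1L, as.integer(round(exp(
      mu + stats::rnorm(spec$chars_per_script, 0, spec$char_sd)
    ))))
    stroke_counts[[code]] <- n_str
    for (j in seq_len(spec$chars_per_script)) {
      cp <- sprintf("%04X", 0x4000L + j)
      g <- generateGlyph(n_str[j], spec$first_half_share,
                         inv$directionality[i])
      g@script <- code
      g@codepoint <- cp
      glyphs[[paste(code, cp, sep = "_")]] <- g
      char_rows[[length(char_rows) + 1L]] <- data.frame(
        script_code = code, codepoint_id = cp, stringsAsFactors = FALSE
      )
    }
  }
  characters <- do.call(rbind, char_rows)
  rownames(characters) <- NULL
  truth <- list(
    type_of_script = stats::setNames(inv$type, inv$code),
    script_effect = script_eff,
    stroke_counts = stroke_counts,
    first_half_share = spec$first_half_share,
    delta_drift = spec$delta_drift,
    type_strokes = spec$type_strokes,
    seed = spec$seed
  )
  list(inventory = inv, characters = characters, glyphs = glyphs,
       truth = truth)
}

#' Write a generated corpus to disk
#'
#' Emits exactly the file formats the corpus loaders read: an inventory
#' CSV, a character CSV, one image file per character named
#' \code{<script>_<codepoint>.<format>}, and the ground-truth sidecar as
#' JSON.
#'
#' @param corpus list from [generateCorpus()].
#' @param dir output directory (created if needed).
#' @param format \code{"pbm"} (plain text, default) or \code{"png"}.
#' @return \code{dir}, invisibly.
#' @export
writeCorpus <- function(corpus, dir, format = c("pbm", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeInventory(corpus$inventory, file.path(dir, "inventory.csv"))
  utils::write.table(corpus$characters, file.path(dir, "characters.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (nm in names(corpus$glyphs)) {
    writeGlyph(corpus$glyphs[[nm]],
               file.path(img_dir, paste0(nm, ".", format)))
  }
  jsonlite::write_json(
    corpus$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
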