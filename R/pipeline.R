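#' Pipeline configuration
#'
#' One validated object carrying every tunable of an end-to-end run,
#' each defaulting to the pipeline's standard value: branch pruning at
#' 35 px, dilation half-width 2 (5 px strokes), starting point size 60,
#' JZS prior scale sqrt(2)/2, and the 200-character threshold for the
#' large-script sensitivity exclusion. All randomness flows from the one
#' root seed. The configuration round-trips losslessly through JSON.
#'
#' @param stages character subset of
#'   \code{c("synth", "standardize", "measure", "halves", "analyze")}.
#' @param out_dir artifact directory.
#' @param in_dir input corpus directory (ignored when \code{"synth"} is
#'   among the stages).
#' @param spec a [generatorSpec()] for the synth stage (its seed is
#'   overridden by \code{seed}).
#' @param prune_len,dilation_radius,point_size imaging parameters.
#' @param prior_scale JZS Cauchy prior scale.
#' @param skeletonize run thinning/pruning/dilation during
#'   standardization (synthetic strokes are already at target thickness,
#'   so synth runs may skip it).
#' @param drop_large_scripts exclude scripts at or above
#'   \code{large_threshold} characters from the size analyses.
#' @param large_threshold default 200.
#' @param order_subset_only restrict half analyses to LR/RL scripts.
#' @param seed root seed.
#' @return a validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(stages = c("synth", "measure", "halves", "analyze"),
                           out_dir = tempfile("glyphrun"),
                           in_dir = NULL, spec = generatorSpec(),
                           prune_len = 35, dilation_radius = 2L,
                           point_size = 60, prior_scale = sqrt(2) / 2,
                           skeletonize = FALSE, drop_large_scripts = FALSE,
                           large_threshold = 200L, order_subset_only = TRUE,
                           seed = 1L) {
  stages <- match.arg(stages, c("synth", "standardize", "measure", "halves",
                                "analyze"), several.ok = TRUE)
  cfg <- list(
    stages = stages, out_dir = out_dir, in_dir = in_dir, spec = spec,
    prune_len = prune_len, dilation_radius = as.integer(dilation_radius),
    point_size = point_size, prior_scale = prior_scale,
    skeletonize = isTRUE(skeletonize),
    drop_large_scripts = isTRUE(drop_large_scripts),
    large_threshold = as.integer(large_threshold),
    order_subset_only = isTRUE(order_subset_only), seed = as.integer(seed)
  )
  if (cfg$prune_len < 0) stop("pipelineConfig: prune_len must be >= 0")
  if (cfg$dilation_radius < 0) stop("pipelineConfig: dilation_radius must be >= 0")
  if (cfg$point_size <= 0) stop("pipelineConfig: point_size must be > 0")
  if (cfg$prior_scale <= 0) stop("pipelineConfig: prior_scale must be > 0")
  if (!"synth" %in% stages && is.null(cfg$in_dir)) {
    stop("pipelineConfig: in_dir is required when the synth stage is not run")
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:", paste(x$stages, collapse = " -> "),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order - corpus synthesis (or
#' loading), raster standardization, complexity measurement,
#' half-splitting, and the statistical analyses - writing tidy delimited
#' tables plus a JSON manifest recording parameters, seed, and row
#' counts at every filter. Rerunning an identical configuration
#' reproduces all outputs.
#'
#' @param config a [pipelineConfig()].
#' @return invisible list with the in-memory results (\code{inventory},
#'   \code{measures}, \code{halves}, \code{analysis}, \code{manifest}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("glyphmetry")),
    seed = config$seed,
    parameters = config[c("prune_len", "dilation_radius", "point_size",
                          "prior_scale", "skeletonize",
                          "drop_large_scripts", "large_threshold",
                          "order_subset_only")],
    stages = config$stages,
    counts = list()
  )
  glyphs <- NULL
  inventory <- NULL
  res <- list()

  if ("synth" %in% config$stages) {
    spec <- config$spec
    spec$seed <- config$seed
    corpus <- generateCorpus(spec)
    glyphs <- corpus$glyphs
    inventory <- corpus$inventory
    res$truth <- corpus$truth
    manifest$counts$characters_generated <- length(glyphs)
  } else {
    inventory <- loadInventory(file.path(config$in_dir, "inventory.csv"))
    glyphs <- readGlyphDir(file.path(config$in_dir, "images"))
    manifest$counts$characters_loaded <- length(glyphs)
  }
  inventory <- applyScriptInclusion(inventory)
  manifest$counts$scripts_included <- nrow(inventory)
  manifest$counts$scripts_excluded_missing <-
    nrow(attr(inventory, "exclusions"))
  glyphs <- glyphs[vapply(glyphs, function(g) g@script %in% inventory$code,
                          logical(1L))]

  if ("standardize" %in% config$stages) {
    by_script <- split(glyphs, vapply(glyphs, scriptCode, character(1L)))
    glyphs <- unlist(lapply(by_script, standardizeScript,
                            prune_len = config$prune_len,
                            dilation_radius = config$dilation_radius,
                            skeletonize = config$skeletonize),
                     recursive = FALSE)
    manifest$counts$characters_standardized <- length(glyphs)
  }

  measures <- NULL
  if ("measure" %in% config$stages) {
    measures <- measureGlyphs(glyphs)
    utils::write.table(measures, file.path(config$out_dir, "measures.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    manifest$counts$characters_measured <- nrow(measures)
    res$measures <- measures
  }

  halves <- NULL
  if ("halves" %in% config$stages) {
    tab_inv <- if (config$order_subset_only) inventory else
      transform(inventory, directionality = ifelse(
        directionality %in% c("LR", "RL"), directionality, "LR"))
    halves <- suppressMessages(halvesTable(glyphs, tab_inv))
    utils::write.table(halves$halves, file.path(config$out_dir, "halves.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(halves$characters,
                       file.path(config$out_dir, "half_differentials.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    manifest$counts$halves_measured <- nrow(halves$halves)
    manifest$counts$characters_order_subset <- nrow(halves$characters)
    res$halves <- halves
  }

  if ("analyze" %in% config$stages) {
    if (is.null(measures)) stop("analyze stage requires the measure stage")
    analysis <- list()
    meas <- merge(measures, inventory, by.x = "script", by.y = "code")
    if (config$drop_large_scripts) {
      keep <- excludeLargeScripts(inventory, config$large_threshold)$code
      meas <- meas[meas$script %in% keep, , drop = FALSE]
    }
    manifest$counts$characters_analyzed <- nrow(meas)
    meas$log_size <- log(meas$inventory_size)
    meas$log_AC <- log(meas$AC)
    size_null <- fitRandomIntercept(meas, "C", random = c("family/script", "type"))
    size_test <- fitRandomIntercept(meas, "C", fixed = "log_size",
                                    random = c("family/script", "type"))
    analysis$size <- list(
      null = size_null, test = size_test,
      delta_aic = deltaAIC(size_null, size_test)
    )
    analysis$icc <- data.frame(
      level = c("script", "family", "type"),
      pc = c(
        intraclassCorrelation(meas$C, meas$script),
        intraclassCorrelation(meas$C, meas$family),
        intraclassCorrelation(meas$C, meas$type)
      ),
      ac = c(
        intraclassCorrelation(meas$AC, meas$script, log_transform = TRUE),
        intraclassCorrelation(meas$AC, meas$family, log_transform = TRUE),
        intraclassCorrelation(meas$AC, meas$type, log_transform = TRUE)
      )
    )
    analysis$concordance <- metricConcordance(measures)
    if (any(!is.na(inventory$ancestor))) {
      pc_means <- tapply(measures$C, measures$script, mean)
      analysis$ancestry_pc <- ancestryDifferentials(
        inventory, pc_means, prior_scale = config$prior_scale
      )
      ac_means <- tapply(measures$AC, measures$script, mean)
      analysis$ancestry_ac <- ancestryDifferentials(
        inventory, ac_means, prior_scale = config$prior_scale
      )
    }
    if (!is.null(halves)) {
      analysis$order_pc <- orderModels(halves, "pc")
      analysis$order_ac <- orderModels(halves, "ac")
    }
    utils::write.table(analysis$icc, file.path(config$out_dir, "icc.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    res$analysis <- analysis
  }

  res$inventory <- inventory
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
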