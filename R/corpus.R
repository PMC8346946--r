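.FAMILIES <- c(
  "MiddleEastern", "Phoenician", "IndianBrahmic", "MainlandSEA",
  "InsularSEA", "RecentInventions", "EastAsian"
)
.TYPES <- c(
  "alphabet", "abjad", "abugida", "syllabary", "logosyllabary", "featural"
)
.DIRECTIONS <- c("LR", "RL", "other")

.INV_REQUIRED <- c("code", "family", "type", "directionality")
.INV_OPTIONAL <- c("inventory_size", "idiosyncratic", "ancestor", "n_missing")

#' Load a script inventory table
#'
#' Reads a UTF-8 delimited-text inventory with one row per script. The
#' required columns are \code{code} (4-letter ISO 15924 tag),
#' \code{family}, \code{type} and \code{directionality}; optional columns
#' are \code{inventory_size}, \code{idiosyncratic}, \code{ancestor} and
#' \code{n_missing}. Family and type values are validated against the
#' declared enums. Any directionality other than \code{LR}/\code{RL}
#' (e.g. vertical, boustrophedon, uncertain) is mapped to \code{"other"},
#' which excludes the script from reading-order analyses.
#'
#' @param path delimited-text file with a header row.
#' @param sep field separator, default \code{","}.
#' @return a data.frame of validated script records.
#' @export
loadInventory <- function(path, sep = ",") {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          encoding = "UTF-8")
  missing_cols <- setdiff(.INV_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("inventory schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    for (col in setdiff(.INV_OPTIONAL, names(df))) df[[col]] <- logical(0)
    return(df[, c(.INV_REQUIRED, .INV_OPTIONAL)])
  }
  if (anyDuplicated(df$code)) {
    stop("inventory validation error: duplicate script code(s): ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  }
  bad_family <- setdiff(unique(df$family), .FAMILIES)
  if (length(bad_family)) {
    stop("inventory validation error: unknown family value(s): ",
         paste(bad_family, collapse = ", "))
  }
  bad_type <- setdiff(unique(df$type), .TYPES)
  if (length(bad_type)) {
    stop("inventory validation error: unknown type value(s): ",
         paste(bad_type, collapse = ", "))
  }
  df$directionality <- ifelse(df$directionality %in% c("LR", "RL"),
                              df$directionality, "other")
  if (!"inventory_size" %in% names(df)) df$inventory_size <- NA_integer_
  if (!"idiosyncratic" %in% names(df)) df$idiosyncratic <- FALSE
  if (!"ancestor" %in% names(df)) df$ancestor <- NA_character_
  if (!"n_missing" %in% names(df)) df$n_missing <- 0L
  df$idiosyncratic <- as.logical(df$idiosyncratic)
  df$ancestor[!is.na(df$ancestor) & df$ancestor == ""] <- NA_character_
  self_anc <- !is.na(df$ancestor) & df$ancestor == df$code
  if (any(self_anc)) {
    stop("inventory validation error: script(s) listed as own ancestor: ",
         paste(df$code[self_anc], collapse = ", "))
  }
  if (any(!is.na(df$inventory_size) & df$inventory_size < 1)) {
    stop("inventory validation error: inventory_size must be >= 1")
  }
  df[, c(.INV_REQUIRED, .INV_OPTIONAL)]
}

#' Load a character table
#'
#' One row per character: \code{script_code}, \code{codepoint_id}, and an
#' optional logical \code{included} column carrying upstream curation
#' decisions (punctuation, diacritics, numerals and similar marks are
#' excluded by the curator, not classified here).
#'
#' @param path delimited-text file.
#' @param sep field separator.
#' @param apply_included if \code{TRUE} (default), rows with
#'   \code{included == FALSE} are dropped.
#' @return a data.frame with columns \code{script_code},
#'   \code{codepoint_id} (and \code{included} if present and not applied).
#' @export
loadCharacters <- function(path, sep = ",", apply_included = TRUE) {
  if (!file.exists(path)) stop("character file not found: ", path)
  # identifiers are hexadecimal strings ("0041"): never numbers
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  if ("included" %in% names(df)) {
    df$included <- as.logical(df$included)
  }
  need <- c("script_code", "codepoint_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("character schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if ("included" %in% names(df) && apply_included) {
    df <- df[as.logical(df$included), , drop = FALSE]
    df$included <- NULL
  }
  dup <- duplicated(df[, c("script_code", "codepoint_id")])
  if (any(dup)) {
    stop("character validation error: duplicate codepoint within script: ",
         paste(unique(paste(df$script_code[dup], df$codepoint_id[dup],
                            sep = "_")), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Graph inventory size of one script
#'
#' The number of unique characters: distinct codepoint identifiers, with
#' positional variants (e.g. upper and lower case) counted separately.
#'
#' @param codepoints character vector of codepoint identifiers for one
#'   script (repetitions allowed).
#' @return integer count of distinct codepoints.
#' @examples
#' inventorySize(c("0041", "0061", "0041")) # 2
#' @export
inventorySize <- function(codepoints) {
  if (length(codepoints) == 0L) {
    stop("inventorySize: empty character list")
  }
  length(unique(codepoints))
}

#' Apply the script-level inclusion rule
#'
#' Scripts with more than \code{max_missing} characters lacking images are
#' excluded (the bundled default keeps scripts with up to 5 missing
#' symbols). Exclusions are reported via the \code{"exclusions"}
#' attribute and a message.
#'
#' @param inventory data.frame from [loadInventory()] with
#'   \code{n_missing} populated.
#' @param max_missing inclusion threshold, default 5.
#' @return the filtered inventory; excluded rows (with a \code{reason}
#'   column) in \code{attr(, "exclusions")}.
#' @export
applyScriptInclusion <- function(inventory, max_missing = 5L) {
  stopifnot(is.data.frame(inventory), "n_missing" %in% names(inventory))
  nm <- inventory$n_missing
  nm[is.na(nm)] <- 0L
  drop <- nm > max_missing
  excl <- inventory[drop, , drop = FALSE]
  if (nrow(excl)) {
    excl$reason <- sprintf("n_missing = %d > %d", nm[drop], max_missing)
    message(sprintf("excluding %d script(s) with more than %d missing symbols: %s",
                    nrow(excl), max_missing, paste(excl$code, collapse = ", ")))
  } else {
    excl$reason <- character(0)
  }
  out <- inventory[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Restrict an inventory to the reading-order analysis subset
#'
#' Scripts written top-to-bottom, bottom-to-top, in boustrophedon style,
#' or with uncertain/variable direction (all coded \code{"other"}) are
#' excluded; only LR and RL scripts enter order/laterality analyses.
#'
#' @param inventory data.frame with a \code{directionality} column.
#' @return the filtered inventory (LR and RL rows, order preserved).
#' @export
orderAnalysisSubset <- function(inventory) {
  stopifnot(is.data.frame(inventory), "directionality" %in% names(inventory))
  out <- inventory[inventory$directionality %in% c("LR", "RL"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-script missing-image counts
#'
#' Compares a character table against the images actually present and
#' fills \code{n_missing} per script. Inventory size can be counted
#' before exclusion of missing characters (all curated characters, the
#' default) or after (only characters with an image).
#'
#' @param inventory inventory data.frame.
#' @param characters character table ([loadCharacters()]).
#' @param have_image logical vector parallel to \code{characters} rows.
#' @param size_counts \code{"all"} (count every curated character toward
#'   inventory_size) or \code{"imaged"} (count only characters with an
#'   image).
#' @return the inventory with \code{n_missing} and \code{inventory_size}
#'   updated.
#' @export
tallyMissing <- function(inventory, characters, have_image,
                         size_counts = c("all", "imaged")) {
  size_counts <- match.arg(size_counts)
  stopifnot(length(have_image) == nrow(characters))
  miss <- tapply(!have_image, characters$script_code, sum)
  tot <- tapply(characters$codepoint_id, characters$script_code,
                function(x) length(unique(x)))
  got <- tapply(characters$codepoint_id[have_image],
                factor(characters$script_code[have_image],
                       levels = names(tot)),
                function(x) length(unique(x)))
  got[is.na(got)] <- 0L
  idx <- match(inventory$code, names(miss))
  inventory$n_missing <- ifelse(is.na(idx), 0L, as.integer(miss[idx]))
  inventory$inventory_size <- as.integer(
    if (size_counts == "all") tot[idx] else got[idx]
  )
  inventory
}

#' Write an inventory back to delimited text
#'
#' @param inventory data.frame.
#' @param path output file.
#' @param sep separator.
#' @return \code{path}, invisibly.
#' @export
writeInventory <- function(inventory, path, sep = ",") {
  utils::write.table(inventory, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
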