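.wrapFit <- function(fit, method) {
  sm <- suppressWarnings(summary(fit))
  co <- as.data.frame(sm$coefficients)
  # lmerTest columns: Estimate, Std. Error, df, t value, Pr(>|t|)
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    estimate = co[, "Estimate"],
    ci_lower = co[, "Estimate"] - z * co[, "Std. Error"],
    ci_upper = co[, "Estimate"] + z * co[, "Std. Error"],
    df = if ("df" %in% names(co)) co[, "df"] else NA_real_,
    t = co[, "t value"],
    p = if ("Pr(>|t|)" %in% names(co)) co[, "Pr(>|t|)"] else NA_real_,
    row.names = rownames(co)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2), ]
  plain <- is.na(vc$var1) | vc$var1 == "(Intercept)"
  varcomp <- stats::setNames(vc$vcov, ifelse(plain, vc$grp,
                                             paste(vc$grp, vc$var1, sep = ".")))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular fit: some variance component estimated at zero",
            call. = FALSE)
  }
  new("ModelFit",
    formula = stats::formula(fit), coefficients = coefs,
    varcomp = pmax(varcomp, 0), logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit), method = method, singular = singular, fit = fit
  )
}

.fitLmer <- function(formula, data, reml = TRUE) {
  fit <- suppressMessages(lmerTest::lmer(
    formula, data = data, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  .wrapFit(fit, if (reml) "REML" else "ML")
}

#' Fit a random-intercept linear mixed model
#'
#' Builds and fits \code{outcome ~ fixed + (1 | g)} terms with REML (by
#' default) and Satterthwaite-approximate degrees of freedom for the
#' fixed-effect t-tests. Grouping terms may be crossed
#' (\code{c("family", "type")}) or nested (\code{"family/script"}).
#'
#' @param data data.frame.
#' @param outcome name of the outcome column.
#' @param fixed character vector of fixed-effect terms (may be empty for
#'   an intercept-only model).
#' @param random character vector of grouping terms, each becoming a
#'   random intercept \code{(1 | term)}.
#' @param reml logical, REML (default) or ML.
#' @return a [ModelFit-class].
#' @examples
#' \donttest{
#' df <- data.frame(y = rnorm(100), g = rep(letters[1:10], each = 10))
#' fitRandomIntercept(df, "y", random = "g")
#' }
#' @export
fitRandomIntercept <- function(data, outcome, fixed = character(),
                               random, reml = TRUE) {
  stopifnot(is.data.frame(data), length(random) >= 1L)
  for (g in unlist(strsplit(random, "/", fixed = TRUE))) {
    g <- trimws(g)
    if (g %in% names(data) && length(unique(data[[g]])) < 2L) {
      stop("fitRandomIntercept: grouping factor '", g,
           "' has fewer than 2 levels")
    }
  }
  rhs <- paste(c("1", fixed, sprintf("(1 | %s)", random)), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  .fitLmer(f, data, reml = reml)
}

#' AIC difference between nested models
#'
#' Both fits are refit with maximum likelihood (AIC comparison of
#' REML fits with different fixed structures is not meaningful), and
#' \code{AIC(null) - AIC(test)} is returned: positive values favor the
#' test model; a useless extra predictor costs about 2 (the parameter
#' penalty).
#'
#' @param null_fit,test_fit [ModelFit-class] objects on the same
#'   outcome data.
#' @return scalar delta-AIC.
#' @export
deltaAIC <- function(null_fit, test_fit) {
  stopifnot(is(null_fit, "ModelFit"), is(test_fit, "ModelFit"))
  y0 <- lme4::getME(null_fit@fit, "y")
  y1 <- lme4::getME(test_fit@fit, "y")
  if (length(y0) != length(y1) || !isTRUE(all.equal(y0, y1))) {
    stop("deltaAIC: models were fit to different outcome data")
  }
  ml0 <- if (null_fit@method == "ML") null_fit@fit else
    suppressMessages(lme4::refitML(null_fit@fit))
  ml1 <- if (test_fit@method == "ML") test_fit@fit else
    suppressMessages(lme4::refitML(test_fit@fit))
  stats::AIC(ml0) - stats::AIC(ml1)
}

#' Intraclass correlation from a one-way random-intercept model
#'
#' ICC = between-group variance / (between + within), from a REML fit of
#' \code{value ~ 1 + (1 | group)}. For algorithmic complexity the
#' convention is to compute the ICC on log-transformed values
#' (\code{log_transform = TRUE}).
#'
#' @param values numeric vector.
#' @param group grouping factor (same length).
#' @param log_transform log-transform values first.
#' @return ICC in [0, 1].
#' @export
intraclassCorrelation <- function(values, group, log_transform = FALSE) {
  stopifnot(length(values) == length(group))
  if (log_transform) values <- log(values)
  df <- data.frame(y = values, g = factor(group))
  if (nlevels(df$g) < 2L) stop("intraclassCorrelation: need >= 2 groups")
  fit <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | g), data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- max(0, vc$vcov[vc$grp == "g"])
  ve <- vc$vcov[vc$grp == "Residual"]
  vb / (vb + ve)
}

#' Drop large scripts for the size-model sensitivity analysis
#'
#' @param inventory inventory data.frame with \code{inventory_size}.
#' @param threshold scripts with \code{inventory_size >= threshold} are
#'   dropped (default 200).
#' @return filtered inventory.
#' @export
excludeLargeScripts <- function(inventory, threshold = 200L) {
  stopifnot("inventory_size" %in% names(inventory))
  out <- inventory[is.na(inventory$inventory_size) |
                     inventory$inventory_size < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.nestedScriptTerm <- function(df) {
  if ("family" %in% names(df) && length(unique(stats::na.omit(df$family))) >= 2L &&
      !anyNA(df$family)) {
    "family/script"
  } else {
    "script"
  }
}

#' The order/laterality model suite
#'
#' Fits, for one complexity metric, the regression suite probing whether
#' complexity concentrates in the half read first:
#' \itemize{
#'   \item \code{intercept}: first-minus-last differential ~ 1 with
#'     script (nested in family) random intercepts; a positive intercept
#'     means first halves are more complex.
#'   \item \code{intercept_dir}: the same model plus script
#'     directionality as a fixed effect.
#'   \item \code{order_fit}/\code{side_fit} and
#'     \code{order_vs_side_daic}: half-level complexity modeled with
#'     reading order (first/last) vs. laterality (left/right) as the
#'     fixed effect, compared by ML AIC (positive favors order).
#'   \item \code{discrepancy}: the z(PC) - z(AC) discrepancy score
#'     modeled with side and order fixed effects (only when both metrics
#'     are present), diagnosing metric-specific laterality bias.
#'   \item \code{lateral_dir}: left-minus-right differential ~
#'     directionality; a negative directionality (RL) estimate means the
#'     left-half advantage shrinks when the right half is read first.
#' }
#'
#' @param tables list from [halvesTable()].
#' @param metric \code{"pc"} or \code{"ac"}.
#' @return named list of [ModelFit-class] objects and
#'   \code{order_vs_side_daic}.
#' @export
orderModels <- function(tables, metric = c("pc", "ac")) {
  metric <- match.arg(metric)
  chars <- tables$characters
  halves <- tables$halves
  dcol <- paste0("dFL_", metric)
  lcol <- paste0("dLR_", metric)
  vcol <- if (metric == "pc") "C" else "AC"
  cc <- chars[stats::complete.cases(chars[, c(dcol, lcol)]), , drop = FALSE]
  if (!nrow(cc)) stop("orderModels: no complete characters for metric ", metric)
  nest <- .nestedScriptTerm(cc)
  out <- list()
  out$intercept <- fitRandomIntercept(cc, dcol, random = nest)
  out$intercept_dir <- fitRandomIntercept(cc, dcol, fixed = "directionality",
                                          random = nest)
  hh <- halves[!is.na(halves[[vcol]]) & !is.na(halves$order), , drop = FALSE]
  hh$char <- paste(hh$script, hh$codepoint, sep = "_")
  hnest <- if (.nestedScriptTerm(hh) == "family/script") {
    "family/script/char"
  } else {
    "script/char"
  }
  out$order_fit <- fitRandomIntercept(hh, vcol, fixed = "order", random = hnest)
  out$side_fit <- fitRandomIntercept(hh, vcol, fixed = "side", random = hnest)
  out$order_vs_side_daic <- deltaAIC(out$side_fit, out$order_fit)
  if ("D" %in% names(halves)) {
    hd <- halves[!is.na(halves$D) & !is.na(halves$order), , drop = FALSE]
    hd$char <- paste(hd$script, hd$codepoint, sep = "_")
    out$discrepancy <- fitRandomIntercept(hd, "D", fixed = c("side", "order"),
                                          random = "script/char")
  }
  out$lateral_dir <- fitRandomIntercept(cc, lcol, fixed = "directionality",
                                        random = nest)
  out
}
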