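#' JZS Bayes factor for a one-sample t-test
#'
#' Bayes factor in favor of the null hypothesis that the population mean
#' is zero, against the Jeffreys-Zellner-Siow alternative: a Cauchy
#' prior of scale \code{prior_scale} on the standardized effect size and
#' the Jeffreys prior on the variance. Computed by numerical quadrature
#' of the Zellner-Siow g-mixture representation (the Cauchy written as a
#' scale mixture of normals with an inverse-chi-square mixing density),
#' which depends on the data only through the t statistic and n.
#'
#' @param x numeric vector of observations, or \code{NULL} when
#'   \code{t} and \code{n} are given directly.
#' @param t,n t statistic and sample size (used when \code{x} is NULL).
#' @param prior_scale Cauchy prior scale on the standardized effect;
#'   default \code{sqrt(2)/2}, the conventional "medium" scale.
#' @param rel_tol relative tolerance of the quadrature.
#' @return a [BayesTestResult-class]; \code{BF_null > 1} favors the null.
#' @examples
#' jzsBayesFactor(t = 1.0, n = 29)
#' @export
jzsBayesFactor <- function(x = NULL, t = NULL, n = NULL,
                           prior_scale = sqrt(2) / 2, rel_tol = 1e-10) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) stop("jzsBayesFactor: need at least 2 observations")
    if (stats::sd(x) == 0) {
      if (mean(x) != 0) stop("jzsBayesFactor: zero variance")
      t <- 0  # data sit exactly on the null point
    } else {
      t <- mean(x) / (stats::sd(x) / sqrt(n))
    }
  } else {
    if (is.null(t) || is.null(n)) stop("supply either x, or both t and n")
    if (n < 2L) stop("jzsBayesFactor: need n >= 2")
  }
  r <- prior_scale
  nu <- n - 1
  # marginal likelihood ratio: alternative / null, integrated over
  # g ~ inverse-chi-square(1) scaled by r^2
  log_null <- -((nu + 1) / 2) * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(
      -0.5 * log1p(n * g) -
        ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) -
        log_null +
        log(r) - 0.5 * log(2 * pi) - 1.5 * log(g) - r^2 / (2 * g)
    )
  }
  bf10 <- stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                           subdivisions = 500L)$value
  new("BayesTestResult", BF_null = 1 / bf10, t = as.numeric(t),
      n = as.numeric(n), prior_scale = r)
}

#' Ancestor-descendant complexity differentials
#'
#' For every documented branching-out event, the ancestor script's mean
#' character complexity is subtracted from the descendant's. To avoid
#' giving prolific ancestors more weight, differentials are averaged per
#' ancestor before testing; the ancestor-averaged values then enter a
#' JZS Bayesian one-sample t-test of "no systematic change at branching"
#' and a random-intercept regression of the pair-level differentials
#' controlling for ancestor.
#'
#' @param inventory data.frame with \code{code} and \code{ancestor}
#'   columns (ancestor NA when undocumented).
#' @param script_means named numeric: mean complexity per script code.
#' @param prior_scale passed to [jzsBayesFactor()].
#' @return list with \code{pairs} (descendant, ancestor, differential),
#'   \code{per_ancestor} (ancestor, mean differential, n descendants),
#'   \code{bayes} ([BayesTestResult-class]),
#'   \code{model} ([ModelFit-class] of differential ~ 1 + (1|ancestor),
#'   NULL when ancestors < 2), and \code{skipped} (pairs without
#'   measured scripts).
#' @export
ancestryDifferentials <- function(inventory, script_means,
                                  prior_scale = sqrt(2) / 2) {
  stopifnot(all(c("code", "ancestor") %in% names(inventory)))
  linked <- inventory[!is.na(inventory$ancestor), c("code", "ancestor")]
  if (!nrow(linked)) stop("ancestryDifferentials: no ancestor links")
  have <- function(s) s %in% names(script_means) & !is.na(script_means[s])
  ok <- have(linked$code) & have(linked$ancestor)
  skipped <- linked[!ok, , drop = FALSE]
  if (nrow(skipped)) {
    message("ancestryDifferentials: skipping ", nrow(skipped),
            " pair(s) without measured characters: ",
            paste(skipped$code, collapse = ", "))
  }
  pairs <- linked[ok, , drop = FALSE]
  if (!nrow(pairs)) stop("ancestryDifferentials: no measurable pairs")
  pairs$differential <- as.numeric(script_means[pairs$code] -
                                     script_means[pairs$ancestor])
  agg <- stats::aggregate(differential ~ ancestor, data = pairs, FUN = mean)
  agg$n_descendants <- as.integer(table(pairs$ancestor)[agg$ancestor])
  bayes <- if (nrow(agg) >= 2L) {
    tryCatch(jzsBayesFactor(agg$differential, prior_scale = prior_scale),
             error = function(e) NULL)
  } else {
    NULL
  }
  model <- if (length(unique(pairs$ancestor)) >= 2L &&
               nrow(pairs) > length(unique(pairs$ancestor))) {
    # degenerate worlds (e.g. all differentials identical) cannot be fit
    tryCatch(fitRandomIntercept(pairs, "differential", random = "ancestor"),
             error = function(e) NULL)
  } else {
    NULL
  }
  names(pairs)[names(pairs) == "code"] <- "descendant"
  rownames(pairs) <- NULL
  rownames(skipped) <- NULL
  list(pairs = pairs, per_ancestor = agg, bayes = bayes, model = model,
       skipped = skipped)
}
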