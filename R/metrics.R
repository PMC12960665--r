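# Screening-performance evaluation with exact binomial intervals.

#' Build a screening confusion matrix
#'
#' @param expected named vector of `positive`/`negative` per case.
#' @param observed named vector of `high_chance`/`low_chance` per case;
#'   names must match `expected` exactly.
#' @return A `confusion_matrix` object (list with tp, fp, fn, tn).
#' @export
build_matrix <- function(expected, observed) {
  missing_obs <- setdiff(names(expected), names(observed))
  missing_exp <- setdiff(names(observed), names(expected))
  if (length(missing_obs) || length(missing_exp)) {
    stop("case key mismatch; missing from observed: ",
         paste(missing_obs, collapse = ", "),
         "; missing from expected: ",
         paste(missing_exp, collapse = ", "), call. = FALSE)
  }
  observed <- observed[names(expected)]
  stopifnot(all(expected %in% c("positive", "negative")),
            all(observed %in% c("high_chance", "low_chance")))
  pos <- expected == "positive"
  hi <- observed == "high_chance"
  structure(list(tp = sum(pos & hi), fp = sum(!pos & hi),
                 fn = sum(pos & !hi), tn = sum(!pos & !hi)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("screen positive", "screen negative"),
                              c("known positive", "known negative")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed-form interval from the beta quantile function: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n). These bounds
#' satisfy the binomial tail conditions `P(X >= x | p = lower) = alpha/2`
#' and `P(X <= x | p = upper) = alpha/2`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, n >= x)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

round_half_up <- function(x) floor(x + 0.5)

#' Screening metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as integer percent
#' (rounded half-up), each with a Clopper-Pearson interval whose bounds
#' are floored to integer percent — the convention that reproduces
#' intervals as printed on screening validation reports (e.g. 15/16
#' giving 94% with CI 69-99%). A metric with a zero denominator is
#' flagged undefined (`NA`), never fabricated.
#'
#' @param m a `confusion_matrix` from [build_matrix()].
#' @param config a [gnbs_config()] (uses `ci_level`).
#' @return A `screening_metrics` data.frame with columns metric, x, n,
#'   point, ci_low, ci_high.
#' @export
screening_metrics <- function(m, config = gnbs_config()) {
  defs <- list(
    sensitivity = c(m$tp, m$tp + m$fn),
    specificity = c(m$tn, m$tn + m$fp),
    ppv = c(m$tp, m$tp + m$fp),
    npv = c(m$tn, m$tn + m$fn),
    accuracy = c(m$tp + m$tn, m$tp + m$fp + m$fn + m$tn)
  )
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]
    n <- defs[[nm]][2]
    if (n == 0) {
      return(data.frame(metric = nm, x = x, n = n, point = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ci <- clopper_pearson(x, n, config$ci_level)
    data.frame(metric = nm, x = x, n = n,
               point = round_half_up(100 * x / n),
               ci_low = floor(100 * ci[1]),
               ci_high = floor(100 * ci[2]),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("screening_metrics", "data.frame"))
}

#' @export
print.screening_metrics <- function(x, ...) {
  df <- as.data.frame(x)
  df$value <- ifelse(is.na(df$point), "undefined (0 denominator)",
                     sprintf("%d%% (95%% CI: %d-%d%%)",
                             df$point, df$ci_low, df$ci_high))
  print(df[, c("metric", "x", "n", "value")], row.names = FALSE)
  invisible(x)
}
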