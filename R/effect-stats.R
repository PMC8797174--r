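#' Hedges' g standardized mean difference
#'
#' The bias-corrected standardized difference between the means of two
#' samples:
#' \deqn{g = J \cdot \frac{\bar a - \bar b}{s_p}, \qquad
#'       J = 1 - \frac{3}{4(n_a + n_b) - 9},}
#' where \eqn{s_p} is the pooled standard deviation. The standard error uses
#' the conventional large-sample variance
#' \eqn{(n_a + n_b)/(n_a n_b) + g^2 / (2 (n_a + n_b))}, and the confidence
#' interval is normal-based. Magnitude classes on `|g|`: negligible
#' (< 0.2), small (>= 0.2), medium (>= 0.5), large (>= 0.8).
#'
#' Two identical degenerate samples (zero pooled variance, zero mean
#' difference) yield g = 0 by convention -- the case of an unperturbed
#' network compared with itself; a nonzero mean difference with zero pooled
#' variance is an error.
#'
#' @param a,b Numeric samples (each of length >= 2); `a` is the focal
#'   (e.g. targeted) sample, `b` the reference (e.g. random).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An object of class `"hedges_g"`; see [tidy.hedges_g()].
#' @examples
#' hedges_g(c(2, 4), c(0, 2))
#' @export
hedges_g <- function(a, b, conf_level = 0.95) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 2 || n_b < 2) abort("Both samples need at least two values.")
  md <- mean(a) - mean(b)
  sp2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) / (n_a + n_b - 2)
  correction <- 1 - 3 / (4 * (n_a + n_b) - 9)
  if (sp2 <= 0) {
    if (abs(md) > 0) {
      abort("Undefined effect size: zero pooled variance with a nonzero mean difference.")
    }
    g <- 0
  } else {
    g <- correction * md / sqrt(sp2)
  }
  se <- sqrt((n_a + n_b) / (n_a * n_b) + g^2 / (2 * (n_a + n_b)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      g = g, se = se, ci_lo = g - z * se, ci_hi = g + z * se,
      magnitude = g_magnitude(g),
      mean_a = mean(a), mean_b = mean(b), n_a = n_a, n_b = n_b,
      sd_pooled = sqrt(max(sp2, 0)), correction = correction,
      conf_level = conf_level
    ),
    class = "hedges_g"
  )
}

g_magnitude <- function(g) {
  cut(abs(g), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |>
    as.character()
}

#' @export
print.hedges_g <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f (%s), %d%% CI [%.4f, %.4f]\n",
              x$g, x$magnitude, round(100 * x$conf_level), x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Tidy a Hedges' g result
#'
#' @param x A `"hedges_g"` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `magnitude`. `glance()`: a one-row tibble with
#'   the sample summaries (`n_a`, `n_b`, `mean_a`, `mean_b`, `sd_pooled`,
#'   `correction`, `conf_level`).
#' @export
tidy.hedges_g <- function(x, ...) {
  tibble(
    estimate = x$g, std_error = x$se,
    conf_low = x$ci_lo, conf_high = x$ci_hi, magnitude = x$magnitude
  )
}

#' @rdname tidy.hedges_g
#' @export
glance.hedges_g <- function(x, ...) {
  tibble(
    n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
    sd_pooled = x$sd_pooled, correction = x$correction,
    conf_level = x$conf_level
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' t-based confidence interval of a sample mean
#'
#' @param x Numeric sample of length >= 2 (NAs dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `mean`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' ci95_mean(rnorm(100))
#' @export
ci95_mean <- function(x, conf_level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("Need at least two values for a confidence interval.")
  m <- mean(x)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  tibble(mean = m, ci_lo = m - half, ci_hi = m + half, n = n)
}

#' Targeted-versus-random effect-size summary of a deletion experiment
#'
#' For every combination of deletion metric, network index and deletion
#' proportion (plus any extra grouping columns present, e.g.
#' `threshold_pct`), contrasts the targeted sample against the random sample
#' with Hedges' g and reports both samples' means with t-based confidence
#' intervals. Proportion-zero cells contrast identical distributions and
#' yield g = 0.
#'
#' @param results A `"deletion_results"` tibble from
#'   [run_deletion_experiment()].
#' @param indices Index columns to contrast (default the four global
#'   indices).
#' @param by Extra grouping columns (beyond `metric` and `proportion`)
#'   present in `results`, e.g. `"network_id"` for per-network contrasts or
#'   `"threshold_pct"` after a filtered study. By default replicates are
#'   pooled across networks.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `"contrast_results"`: one row per contrast
#'   cell with columns `metric`, `proportion`, `index`, `g`, `se_g`,
#'   `ci_lo`, `ci_hi`, `magnitude`, `mean_targeted`, `targeted_lo`,
#'   `targeted_hi`, `mean_random`, `random_lo`, `random_hi`, `n_targeted`,
#'   `n_random`.
#' @export
summarize_contrasts <- function(results,
                                indices = c("clustering", "diameter",
                                            "efficiency", "modularity"),
                                by = character(), conf_level = 0.95) {
  keys <- c("metric", "proportion", by)
  missing <- setdiff(c(keys, "type", indices), names(results))
  if (length(missing)) {
    abort(sprintf("`results` is missing columns: %s", paste(missing, collapse = ", ")))
  }
  long <- results |>
    as_tibble() |>
    tidyr::pivot_longer(all_of(indices), names_to = "index", values_to = "value")

  cells <- long |>
    group_by(across(all_of(c(keys, "index")))) |>
    group_modify(function(d, key) {
      a <- d$value[d$type == "targeted"]
      b <- d$value[d$type == "random"]
      if (length(a) < 2 || length(b) < 2) {
        abort(sprintf(
          "Missing targeted or random replicates in cell: %s",
          paste(sprintf("%s=%s", names(key), unlist(key)), collapse = ", ")
        ))
      }
      es <- hedges_g(a, b, conf_level)
      ca <- ci95_mean(a, conf_level)
      cb <- ci95_mean(b, conf_level)
      tibble(
        g = es$g, se_g = es$se, ci_lo = es$ci_lo, ci_hi = es$ci_hi,
        magnitude = es$magnitude,
        mean_targeted = ca$mean, targeted_lo = ca$ci_lo, targeted_hi = ca$ci_hi,
        mean_random = cb$mean, random_lo = cb$ci_lo, random_hi = cb$ci_hi,
        n_targeted = length(a), n_random = length(b)
      )
    }) |>
    ungroup()
  class(cells) <- c("contrast_results", class(cells))
  cells
}
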