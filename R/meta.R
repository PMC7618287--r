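#' Male-female coverage effect for one survey
#'
#' Computes sex-restricted, age-adjusted coverage for men and women
#' ([coverage_estimate()] with `sex = "M"` / `"F"`) and derives the
#' between-sex effect:
#'
#' * `measure = "RD"`: risk difference `male% - female%` on the percent
#'   scale, with standard error `sqrt(se_M^2 + se_F^2)` (independent
#'   strata);
#' * `measure = "RR"`: risk ratio `male% / female%`, with log-scale
#'   standard error `sqrt((se_M/v_M)^2 + (se_F/v_F)^2)` by the delta
#'   method. A female value of 0 leaves the ratio undefined.
#'
#' @inheritParams coverage_estimate
#' @param indicator `"eCSC"` (default) or `"CSC"`.
#' @param measure `"RD"`, `"RR"`, or both (default).
#' @param ... passed to [coverage_estimate()] (e.g. `empty_stratum`).
#' @return a tibble with one row per measure: `measure`, `effect`,
#'   `se` (on the log scale for RR), `male_value`, `male_se`,
#'   `female_value`, `female_se`, `config`.
#' @export
sex_effect <- function(survey, population, cfg = indicator_config(),
                       indicator = c("eCSC", "CSC"),
                       measure = c("RD", "RR"), ...) {
  indicator <- match.arg(indicator)
  measure <- match.arg(measure, several.ok = TRUE)
  em <- coverage_estimate(survey, population, cfg, indicator = indicator,
                          sex = "M", ...)
  ef <- coverage_estimate(survey, population, cfg, indicator = indicator,
                          sex = "F", ...)
  if (is.na(em$value) || is.na(ef$value)) {
    stop("a sex has an undefined estimate (zero denominator); ",
         "survey cannot contribute a sex effect", call. = FALSE)
  }
  rows <- lapply(measure, function(ms) {
    if (ms == "RD") {
      effect <- em$value - ef$value
      se <- sqrt(em$se^2 + ef$se^2)
    } else {
      if (ef$value <= 0) {
        stop("risk ratio undefined: female coverage is 0", call. = FALSE)
      }
      effect <- em$value / ef$value
      se <- sqrt((em$se / em$value)^2 + (ef$se / ef$value)^2)
    }
    tibble::tibble(measure = ms, effect = effect, se = se,
                   male_value = em$value, male_se = em$se,
                   female_value = ef$value, female_se = ef$se,
                   config = em$config)
  })
  dplyr::bind_rows(rows)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study effects with the moment-based DerSimonian-Laird
#' estimator of between-study variance. With fixed-effect weights
#' `u_k = 1/se_k^2` and their weighted mean effect `e_bar`,
#' `Q = sum(u_k (e_k - e_bar)^2)` and
#' `tau^2 = max(0, (Q - (k-1)) / (sum(u) - sum(u^2)/sum(u)))`; the pooled
#' effect uses random-effects weights `1 / (se_k^2 + tau^2)` with a
#' normal-approximation 95% CI. When `tau^2 = 0` this reduces exactly to
#' fixed-effect inverse-variance pooling.
#'
#' Risk differences are pooled on the percent scale. Risk ratios must be
#' pooled on the log scale: pass `effect = log(RR)` with the log-scale
#' `se` (as produced by [sex_effect()]) and `log_scale = TRUE`, and the
#' pooled effect and CI are exponentiated back to the ratio scale.
#'
#' @param effects a tibble with columns `effect` and `se` (one row per
#'   study); for `log_scale = TRUE`, `effect` may be on the ratio scale
#'   (it is logged internally). All `se` must be positive.
#' @param log_scale pool on the log scale and exponentiate the result?
#'   Default `FALSE` (appropriate for risk differences).
#' @return an object of class `eyecover_meta`: a list with elements
#'   `pooled`, `ci_low`, `ci_high`, `se`, `tau2`, `q`, `k`, `log_scale`
#'   and the per-study `data`. Use [tidy()]/[glance()] for tibble views
#'   and [ggplot2::autoplot()] for a forest plot.
#' @examples
#' m <- pool_random_effects(tibble::tibble(effect = c(2, 6), se = c(1, 1)))
#' glance(m)   # pooled 4, se 2, tau2 7
#' @export
pool_random_effects <- function(effects, log_scale = FALSE) {
  est <- tibble::as_tibble(effects)
  stopifnot(all(c("effect", "se") %in% names(est)))
  if (any(is.na(est$effect) | is.na(est$se) | est$se <= 0)) {
    stop("all effects must be defined with se > 0", call. = FALSE)
  }
  e <- if (log_scale) log(est$effect) else est$effect
  k <- length(e)
  if (k < 2) {
    warning("fewer than 2 studies: passthrough, tau2 undefined",
            call. = FALSE)
    tau2 <- 0
  }
  u <- 1 / est$se^2
  e_bar <- sum(u * e) / sum(u)
  q <- sum(u * (e - e_bar)^2)
  if (k >= 2) {
    tau2 <- max(0, (q - (k - 1)) / (sum(u) - sum(u^2) / sum(u)))
  }
  w <- 1 / (est$se^2 + tau2)
  pooled <- sum(w * e) / sum(w)
  se <- sqrt(1 / sum(w))
  lo <- pooled - 1.96 * se
  hi <- pooled + 1.96 * se
  if (log_scale) {
    pooled <- exp(pooled); lo <- exp(lo); hi <- exp(hi)
  }
  structure(
    list(pooled = pooled, ci_low = lo, ci_high = hi, se = se,
         tau2 = tau2, q = q, k = k, log_scale = log_scale, data = est),
    class = "eyecover_meta"
  )
}

#' @export
print.eyecover_meta <- function(x, ...) {
  cat("Random-effects (DerSimonian-Laird) pooled effect\n")
  cat(sprintf("  pooled: %.3f (95%% CI %.3f-%.3f)%s\n", x$pooled,
              x$ci_low, x$ci_high,
              if (x$log_scale) " [ratio scale]" else ""))
  cat(sprintf("  k = %d studies, tau^2 = %.4f, Q = %.3f\n",
              x$k, x$tau2, x$q))
  invisible(x)
}

#' Tidy the per-study table of a pooled meta-analysis
#'
#' @param x an `eyecover_meta` object.
#' @param ... unused.
#' @return a tibble with one row per study: `effect`, `se`, `ci_low`,
#'   `ci_high`, `weight` (normalised random-effects weight) and any
#'   identifying columns present in the input.
#' @export
tidy.eyecover_meta <- function(x, ...) {
  d <- x$data
  e <- if (x$log_scale) log(d$effect) else d$effect
  w <- 1 / (d$se^2 + x$tau2)
  lo <- e - 1.96 * d$se
  hi <- e + 1.96 * d$se
  if (x$log_scale) {
    lo <- exp(lo); hi <- exp(hi)
  }
  dplyr::mutate(d, ci_low = lo, ci_high = hi, weight = w / sum(w))
}

#' One-row summary of a pooled meta-analysis
#'
#' @inheritParams tidy.eyecover_meta
#' @return a one-row tibble: `pooled`, `se`, `ci_low`, `ci_high`, `tau2`,
#'   `q`, `k`, `log_scale`.
#' @export
glance.eyecover_meta <- function(x, ...) {
  tibble::tibble(pooled = x$pooled, se = x$se, ci_low = x$ci_low,
                 ci_high = x$ci_high, tau2 = x$tau2, q = x$q, k = x$k,
                 log_scale = x$log_scale)
}

#' Forest plot of a pooled meta-analysis
#'
#' @param object an `eyecover_meta` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eyecover_meta <- function(object, ...) {
  d <- tidy(object)
  d$study <- if ("survey_id" %in% names(d)) d$survey_id
             else paste("study", seq_len(nrow(d)))
  null_line <- if (object$log_scale) 1 else 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$study)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$pooled, colour = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                        shape = 15, show.legend = FALSE) +
    ggplot2::labs(
      x = if (object$log_scale) "risk ratio" else
        "risk difference (percentage points)",
      y = NULL,
      title = sprintf("Pooled effect %.2f (95%% CI %.2f to %.2f), k = %d",
                      object$pooled, object$ci_low, object$ci_high,
                      object$k)) +
    ggplot2::theme_minimal()
}
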