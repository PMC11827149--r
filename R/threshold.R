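#' Threshold test configuration
#'
#' @param negative_label Label (in the frame's label table) of the
#'   negative-control group.
#' @param percentile Quantile of the negative-control activity distribution
#'   defining the upper threshold; strictly between 0.5 and 1
#'   (default 0.975, i.e. upper threshold at the 97.5th and lower at the
#'   2.5th percentile).
#' @param direction \code{"activating"} (default), \code{"repressing"} or
#'   \code{"both"}.
#' @param min_controls Minimum number of negative-control oligos required
#'   (default 20).
#' @return A list of class \code{mpra_threshold_config}.
#' @export
threshold_config <- function(negative_label, percentile = 0.975,
                             direction = c("activating", "repressing",
                                           "both"),
                             min_controls = 20L) {
  direction <- match.arg(direction)
  if (percentile <= 0.5 || percentile >= 1) {
    stop_mprabc("percentile must lie strictly between 0.5 and 1",
                class = "mprabc_param_error")
  }
  structure(list(negative_label = negative_label, percentile = percentile,
                 direction = direction, min_controls = as.integer(min_controls)),
            class = "mpra_threshold_config")
}

#' Derive activity thresholds from negative controls
#'
#' Upper threshold = the configured percentile of the negative-control
#' fitted activities; lower threshold = the (1 - percentile) quantile;
#' shift = the mean of the negative-control activities (used to centre the
#' tested coefficients, which keeps the test correct when the thresholds
#' are negative). Quantiles use linear interpolation.
#'
#' @param fit An element-design \code{\link{mpra_fit}}.
#' @param labels Optional \code{\link{label_table}}; defaults to the labels
#'   carried by the fit.
#' @param cfg An \code{\link{threshold_config}}.
#' @return List with \code{upper}, \code{lower}, \code{shift} and the
#'   control activities \code{controls}.
#' @export
derive_thresholds <- function(fit, cfg, labels = NULL) {
  lab <- fit_labels(fit, labels)
  available <- sort(unique(lab[!is.na(lab)]))
  if (!(cfg$negative_label %in% available)) {
    stop_mprabc("label '%s' not found; available labels: %s",
                cfg$negative_label,
                if (length(available)) paste(available, collapse = ", ")
                else "(none)",
                class = "mprabc_lookup_error")
  }
  act <- fit$coef[!is.na(lab) & lab == cfg$negative_label]
  act <- act[!is.na(act)]
  if (length(act) < cfg$min_controls) {
    stop_mprabc("only %d negative-control oligo(s) with a fitted activity; %d required",
                length(act), cfg$min_controls,
                class = "mprabc_param_error")
  }
  list(upper = interp_quantile(act, cfg$percentile),
       lower = interp_quantile(act, 1 - cfg$percentile),
       shift = mean(act),
       controls = act)
}

fit_labels <- function(fit, labels) {
  if (is.null(labels)) {
    if (is.null(fit$labels)) {
      stop_mprabc("no labels available; supply a label table",
                  class = "mprabc_lookup_error")
    }
    return(fit$labels)
  }
  labels <- label_table(labels)
  labels$label[match(fit$row_ids, labels$oligo)]
}

#' Threshold t-test of element activity
#'
#' Tests each element's activity against the negative-control threshold
#' rather than against zero (a TREAT-style test). Coefficients are first
#' shifted to be centred at the negative-control mean; the effective
#' threshold is the distance from that centre to the control percentile.
#' With shifted coefficient b, threshold tau and moderated standard error
#' se, the p-values are: activating, \code{P(T >= (b - tau)/se)};
#' repressing, \code{P(T >= (-b - tau)/se)}; both,
#' \code{P(T >= (|b| - tau)/se) + P(T >= (|b| + tau)/se)}, with T on
#' (residual + prior) degrees of freedom. Reported activities stay
#' unshifted. BH adjustment is applied over all tested rows.
#'
#' @param fit An element-design \code{\link{mpra_fit}}.
#' @param cfg An \code{\link{threshold_config}}.
#' @param labels Optional \code{\link{label_table}} (defaults to the fit's
#'   labels).
#' @param thresholds Optional precomputed \code{\link{derive_thresholds}}
#'   result.
#' @return An \code{mpra_fit} with threshold-test \code{t},
#'   \code{p_value}, \code{adj_p_value} and an attached \code{threshold}
#'   element.
#' @export
treat_test <- function(fit, cfg, labels = NULL, thresholds = NULL) {
  stopifnot(inherits(fit, "mpra_fit"))
  if (fit$design != "element") {
    stop_mprabc("treat_test requires an element-design fit")
  }
  if (is.null(thresholds)) thresholds <- derive_thresholds(fit, cfg, labels)
  tau_up <- thresholds$upper - thresholds$shift
  tau_dn <- thresholds$shift - thresholds$lower
  tau <- switch(cfg$direction,
                activating = tau_up,
                repressing = tau_dn,
                both = max(tau_up, tau_dn))
  if (tau < 0) {
    stop_mprabc(paste0(
      "effective threshold is not positive after centring (tau = %.4g); ",
      "the percentile is too low for the control spread"), tau,
      class = "mprabc_param_error")
  }
  b <- fit$coef - thresholds$shift
  se <- sqrt(fit$s2_post) * fit$stdev_unscaled
  df_total <- fit$df_residual + fit$df_prior
  upper_tail <- function(q) {
    ifelse(is.infinite(df_total), stats::pnorm(q, lower.tail = FALSE),
           stats::pt(q, df = df_total, lower.tail = FALSE))
  }
  p <- switch(cfg$direction,
    activating = upper_tail((b - tau) / se),
    repressing = upper_tail((-b - tau) / se),
    both = pmin(upper_tail((abs(b) - tau) / se) +
                  upper_tail((abs(b) + tau) / se), 1)
  )
  t_stat <- switch(cfg$direction,
    activating = (b - tau) / se,
    repressing = (-b - tau) / se,
    both = sign(b) * (abs(b) - tau) / se
  )
  adj <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- fit
  out$t <- t_stat
  out$p_value <- p
  out$adj_p_value <- adj
  out$threshold <- c(thresholds[c("upper", "lower", "shift")],
                     list(tau = tau, direction = cfg$direction,
                          percentile = cfg$percentile))
  out
}

#' Plot per-group activity distributions
#'
#' Box-and-strip display of fitted activities per label group; when a
#' threshold configuration is given, the derived upper (and, for two-sided
#' or repressing directions, lower) thresholds are drawn as horizontal
#' lines.
#'
#' @param fit An element-design \code{\link{mpra_fit}}.
#' @param labels Optional \code{\link{label_table}} (defaults to the fit's
#'   labels).
#' @param cfg Optional \code{\link{threshold_config}}.
#' @param ... Passed to \code{\link[graphics]{boxplot}}.
#' @return Invisibly, a list with the per-group activity vectors and the
#'   threshold line positions (NULL when no cfg given).
#' @export
plot_group_activities <- function(fit, labels = NULL, cfg = NULL, ...) {
  lab <- fit_labels(fit, labels)
  lab[is.na(lab)] <- "(unlabelled)"
  groups <- split(fit$coef, lab)
  thresholds <- NULL
  graphics::boxplot(groups, ylab = expression(log[2] ~ "activity"),
                    las = 2, ...)
  if (!is.null(cfg)) {
    thr <- derive_thresholds(fit, cfg, labels)
    lines_at <- switch(cfg$direction,
                       activating = thr$upper,
                       repressing = thr$lower,
                       both = c(thr$lower, thr$upper))
    graphics::abline(h = lines_at, lty = 2, col = "firebrick")
    thresholds <- list(upper = thr$upper, lower = thr$lower,
                       shift = thr$shift, lines = lines_at)
  }
  invisible(list(groups = groups, thresholds = thresholds))
}
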