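#' Two-group labels from signature scores
#'
#' Deterministic split of tumors by a signature score: either at the median
#' (scores strictly above the median are `high`) or at a supplied
#' threshold. Each resulting group must have at least 2 samples.
#'
#' @param scores a `signature_scores` object.
#' @param rule `"median"` or `"threshold"`.
#' @param threshold cut point when `rule = "threshold"`.
#' @return named character vector of `"high"`/`"low"` labels with
#'   attribute `rule` describing the split.
#' @export
group_by_signature <- function(scores, rule = c("median", "threshold"),
                               threshold = 0) {
  stopifnot(inherits(scores, "signature_scores"))
  rule <- match.arg(rule)
  s <- scores$per_sample_score
  cut <- if (rule == "median") stats::median(s) else threshold
  if (rule == "median" && all(s == s[1])) {
    stop("degenerate median split: all scores equal")
  }
  lab <- ifelse(s > cut, "high", "low")
  tab <- table(lab)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("each survival group needs >= 2 samples (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  }
  structure(stats::setNames(lab, names(s)),
            rule = sprintf("%s split at %.6g of '%s'", rule, cut,
                           scores$signature))
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param time positive event/censoring times (months).
#' @param event 1 = event, 0 = censored.
#' @return a `km_fit`: `time` and `surv` (right-continuous step values at
#'   the observed times) plus `surv_fun`, a step function with S(0) = 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need >= 1 record")
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 surv_fun = sf),
            class = "km_fit")
}

#' Log-rank comparison of two survival groups
#'
#' Standard log-rank chi-square on 1 degree of freedom. With a horizon,
#' records beyond it are administratively censored at the horizon before
#' testing (the follow-up truncation used when significance is reported at
#' a stated number of months).
#'
#' @param records data.frame with columns `time`, `event`, `group`
#'   (exactly 2 group labels).
#' @param horizon_months optional truncation horizon.
#' @return a `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `horizon_months`, `group_sizes`, `n_events`.
#' @export
logrank_test <- function(records, horizon_months = NULL) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) != 2) stop("log-rank here compares exactly 2 groups")
  if (any(!is.finite(records$time) | records$time <= 0)) {
    stop("times must be positive")
  }
  time <- records$time
  event <- records$event
  if (!is.null(horizon_months)) {
    over <- time > horizon_months
    event[over] <- 0
    time[over] <- horizon_months
  }
  if (sum(event) == 0) stop("no events (after truncation); test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time, event,
                                             group = records$group))
  chi <- unname(sd$chisq)
  df <- length(groups) - 1L
  structure(list(
    chi_square = chi, df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE),
    horizon_months = if (is.null(horizon_months)) NA_real_ else horizon_months,
    group_sizes = table(records$group),
    n_events = sum(event)
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  hz <- if (is.na(x$horizon_months)) "full follow-up"
        else sprintf("at %g months", x$horizon_months)
  cat(sprintf("<logrank_result> chi-square = %.4g on %d df, p = %.4g (%s)\n",
              x$chi_square, x$df, x$p_value, hz))
  invisible(x)
}
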