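#' Median dichotomization of a marker
#'
#' The sample median is the cut-off separating putative good and poor
#' prognostic groups: `"above"` means strictly greater than the threshold,
#' `"below"` means less than or equal to it (values tied with the median go
#' below). Missing values are excluded and reported. A marker whose
#' non-missing values are all identical cannot be split and is flagged
#' degenerate.
#'
#' @param values per-patient marker values (may contain `NA`).
#' @return List: `threshold`, `group` (factor `below`/`above`, `NA` where the
#'   value is missing), `n_missing`, `degenerate`.
#' @export
dichotomize_at_median <- function(values) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need >= 2 non-missing values")
  thr <- stats::median(values[ok])
  degenerate <- length(unique(values[ok])) == 1L
  group <- factor(ifelse(values > thr, "above", "below"),
                  levels = c("below", "above"))
  list(threshold = thr, group = group, n_missing = sum(!ok),
       degenerate = degenerate)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and reports the survival curve on the grid of
#' observed times, with the median survival defined as the smallest event
#' time at which S(t) falls to 0.5 or below, or "not reached" (`NA`) when
#' the curve never does.
#'
#' @param times follow-up times (>= 0), months.
#' @param events 1/TRUE = event, 0/FALSE = censored.
#' @return Object of class `texhist_km`: `time`, `surv`, `n_risk`,
#'   `n_event`, `n`, `median` (`NA` = not reached).
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.integer(as.logical(events))
  if (length(times) < 1L) stop("need >= 1 subject")
  if (any(times < 0)) stop("negative time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = TRUE)
  med <- km_median(s$time, s$surv, s$n.event)
  structure(list(time = s$time, surv = s$surv, n_risk = s$n.risk,
                 n_event = s$n.event, n = length(times), median = med),
            class = "texhist_km")
}

km_median <- function(time, surv, n_event) {
  drop <- which(surv <= 0.5 + 1e-12 & n_event > 0)
  if (length(drop) == 0L) NA_real_ else time[min(drop)]
}

#' @export
print.texhist_km <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%g", x$median)
  cat(sprintf("<texhist_km> n = %d, events = %d, median survival = %s\n",
              x$n, sum(x$n_event), med))
  invisible(x)
}

#' @export
plot.texhist_km <- function(x, xlab = "Time (months)", ylab = "S(t)", ...) {
  t <- c(0, x$time); s <- c(1, x$surv)
  graphics::plot(t, s, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic from observed-minus-expected events over
#' the pooled event times (via [survival::survdiff()]); p from chi-square(1).
#'
#' @param times_a,events_a follow-up and event indicator, group A.
#' @param times_b,events_b follow-up and event indicator, group B.
#' @return List `chisq`, `p`, `n` (per group), `obs`, `exp`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be nonempty")
  ev <- c(as.integer(as.logical(events_a)), as.integer(as.logical(events_b)))
  if (sum(ev) == 0L) stop("no events in either group")
  tt <- c(as.numeric(times_a), as.numeric(times_b))
  g <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = unname(sd$n), obs = unname(sd$obs), exp = unname(sd$exp))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are the usual step-up quantities
#' (min over j >= rank of p_(j) * m / j, capped at 1); a marker is
#' significant when its raw p is at or below rank * q / m for the largest
#' rank where that holds -- equivalently, adjusted p <= q.
#'
#' @param p raw p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.30).
#' @return List `adjusted`, `significant` (logical), `q`.
#' @export
bh_adjust <- function(p, q = 0.30) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, significant = adj <= q, q = q)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with Breslow (default) or
#' Efron tie handling; 95% CI as exp(coef +/- 1.96 SE), Wald p from
#' (coef/SE)^2 on chi-square(1). Monotone-likelihood (separation) fits are
#' flagged with a diverging-coefficient warning.
#'
#' @param x matrix or data.frame of covariates (binary or real, no
#'   constant column).
#' @param times,events survival outcome.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `texhist_cox`: data.frame with one row per
#'   covariate (`coef`, `se`, `hr`, `ci_lo`, `ci_hi`, `wald`, `p`) plus the
#'   fit in attribute `fit`.
#' @export
fit_cox <- function(x, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("no covariates")
  if (any(vapply(x, function(v) length(unique(v[!is.na(v)])) < 2L, TRUE)))
    stop("constant covariate")
  events <- as.integer(as.logical(events))
  if (sum(events) < ncol(x) + 1L)
    stop("too few events for the number of covariates")
  dat <- cbind(.time = as.numeric(times), .event = events, x)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  coefs <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.na(coefs) & abs(coefs) > 15))
    warning("diverging coefficient: possible monotone likelihood (separation)")
  if (any(is.na(coefs)))
    warning("singular fit: collinear covariate dropped (NA coefficient)")
  res <- data.frame(covariate = names(coefs), coef = unname(coefs),
                    se = unname(se), hr = exp(unname(coefs)),
                    ci_lo = exp(unname(coefs) - 1.96 * unname(se)),
                    ci_hi = exp(unname(coefs) + 1.96 * unname(se)),
                    wald = unname(coefs / se)^2,
                    p = stats::pchisq(unname(coefs / se)^2, 1,
                                      lower.tail = FALSE),
                    row.names = NULL)
  structure(res, class = c("texhist_cox", "data.frame"), fit = fit, ties = ties)
}

#' @export
print.texhist_cox <- function(x, ...) {
  cat(sprintf("<texhist_cox> %d covariate(s), ties = %s\n",
              nrow(x), attr(x, "ties")))
  df <- as.data.frame(x)
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_lo, df$ci_hi)
  print(df[, c("covariate", "coef", "se", "hr", "p")], digits = 3)
  invisible(x)
}

#' Stepwise forward-Wald Cox covariate selection
#'
#' Starting from the empty model, repeatedly adds the candidate covariate
#' with the largest Wald statistic (given the covariates already in the
#' model) among those whose conditional Wald p is below `entry_p`; stops
#' when no candidate qualifies. Pure forward selection: no removal step.
#' Candidates are intended to be the markers significant after BH
#' correction, median-dichotomized to 0/1.
#'
#' @param candidates data.frame of candidate covariates.
#' @param times,events survival outcome.
#' @param entry_p Wald entry threshold (default 0.05).
#' @param ties tie method for [fit_cox()].
#' @return List of class `texhist_cox_selection`: `model` (a `texhist_cox`
#'   on the selected covariates, or `NULL` if none entered), `selected`
#'   (names in entry order), `trace` (per-step Wald statistics for every
#'   candidate examined).
#' @export
forward_wald_select <- function(candidates, times, events, entry_p = 0.05,
                                ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  candidates <- as.data.frame(candidates)
  selected <- character(0)
  remaining <- names(candidates)
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    stats_tab <- lapply(remaining, function(cand) {
      cols <- c(selected, cand)
      res <- tryCatch(
        suppressWarnings(fit_cox(candidates[, cols, drop = FALSE],
                                 times, events, ties = ties)),
        error = function(e) NULL)
      if (is.null(res)) return(c(NA_real_, NA_real_))
      i <- match(make.names(cand), res$covariate)
      if (is.na(i)) i <- nrow(res)
      c(res$wald[i], res$p[i])
    })
    tab <- data.frame(step = step, candidate = remaining,
                      wald = vapply(stats_tab, `[`, 0, 1),
                      p = vapply(stats_tab, `[`, 0, 2))
    trace[[step]] <- tab
    ok <- which(!is.na(tab$p) & tab$p < entry_p)
    if (length(ok) == 0L) break
    enter <- ok[which.max(tab$wald[ok])]
    selected <- c(selected, remaining[enter])
    remaining <- remaining[-enter]
  }
  model <- if (length(selected))
    fit_cox(candidates[, selected, drop = FALSE], times, events, ties = ties)
  else NULL
  structure(list(model = model, selected = selected,
                 trace = do.call(rbind, trace)),
            class = "texhist_cox_selection")
}

#' @export
print.texhist_cox_selection <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("<texhist_cox_selection> no covariate met the entry criterion\n")
  } else {
    cat("<texhist_cox_selection> entered:",
        paste(x$selected, collapse = ", "), "\n")
    print(x$model)
  }
  invisible(x)
}

km_group_summary <- function(times, events) {
  km <- km_estimate(times, events)
  # restricted mean (area under the curve up to the last observed time),
  # used only to break ties when both medians are equal or not reached
  t <- c(0, km$time); s <- c(1, km$surv)
  rmean <- sum(diff(t) * s[-length(s)])
  list(km = km, rmean = rmean)
}

#' Univariate prognostic screen over a marker family
#'
#' For every marker: median dichotomization, per-group Kaplan-Meier curves
#' and median survivals, two-group log-rank test; then one
#' Benjamini-Hochberg family per endpoint across all tested markers. The
#' poor-prognosis direction reports which side of the cut-off has the
#' shorter median survival ("not reached" counts as longer; exact ties are
#' broken by the smaller restricted mean). Markers with fewer than two
#' distinct values, or whose split leaves a group empty or event-free
#' overall, are skipped and logged.
#'
#' @param tbl patient-level analysis table (see [build_analysis_table()]).
#' @param endpoint `"pfs"` or `"os"`; uses columns `<endpoint>_months` and
#'   `<endpoint>_event`.
#' @param markers character vector of marker column names (the BH family).
#' @param q false discovery rate (default 0.30).
#' @return Object of class `texhist_screen`: `results` data.frame (marker,
#'   threshold, direction of poor prognosis, group sizes, per-group median
#'   survival, raw and adjusted p, significance flag), `skipped` data.frame,
#'   `endpoint`, `q`, and per-marker KM curves in `curves`.
#' @export
run_univariate_screen <- function(tbl, endpoint = c("pfs", "os"), markers,
                                  q = 0.30) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  stopifnot(all(c(tcol, ecol) %in% names(tbl)), all(markers %in% names(tbl)))
  rows <- list(); skipped <- list(); curves <- list()
  for (mk in markers) {
    v <- as.numeric(tbl[[mk]])
    if (sum(!is.na(v)) < 2L) {
      skipped[[mk]] <- "fewer than 2 non-missing values"; next
    }
    d <- dichotomize_at_median(v)
    if (d$degenerate) { skipped[[mk]] <- "degenerate split (all values equal)"; next }
    ok <- !is.na(d$group)
    grp <- d$group[ok]; tt <- tbl[[tcol]][ok]; ev <- tbl[[ecol]][ok]
    if (min(table(grp)) == 0L) { skipped[[mk]] <- "empty group after split"; next }
    if (sum(ev) == 0L) { skipped[[mk]] <- "no events"; next }
    lr <- logrank_test(tt[grp == "above"], ev[grp == "above"],
                       tt[grp == "below"], ev[grp == "below"])
    ab <- km_group_summary(tt[grp == "above"], ev[grp == "above"])
    be <- km_group_summary(tt[grp == "below"], ev[grp == "below"])
    med_a <- ab$km$median; med_b <- be$km$median
    cmp_a <- if (is.na(med_a)) Inf else med_a
    cmp_b <- if (is.na(med_b)) Inf else med_b
    direction <- if (cmp_a < cmp_b) "above"
                 else if (cmp_b < cmp_a) "below"
                 else if (ab$rmean <= be$rmean) "above" else "below"
    rows[[mk]] <- data.frame(
      marker = mk, threshold = d$threshold, direction = direction,
      n_below = sum(grp == "below"), n_above = sum(grp == "above"),
      median_below = med_b, median_above = med_a, p = lr$p,
      row.names = NULL)
    curves[[mk]] <- list(above = ab$km, below = be$km)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), threshold = numeric(0),
               direction = character(0), n_below = integer(0),
               n_above = integer(0), median_below = numeric(0),
               median_above = numeric(0), p = numeric(0))
  if (nrow(results)) {
    bh <- bh_adjust(results$p, q)
    results$p_adj <- bh$adjusted
    results$significant <- bh$significant
    rownames(results) <- NULL
  } else {
    results$p_adj <- numeric(0); results$significant <- logical(0)
  }
  skipped <- data.frame(marker = names(skipped),
                        reason = unlist(skipped, use.names = FALSE))
  structure(list(results = results, skipped = skipped, endpoint = endpoint,
                 q = q, curves = curves),
            class = "texhist_screen")
}

#' @export
print.texhist_screen <- function(x, digits = 3, ...) {
  cat(sprintf("<texhist_screen> endpoint %s, %d markers tested, %d skipped, FDR q = %g\n",
              toupper(x$endpoint), nrow(x$results), nrow(x$skipped), x$q))
  if (nrow(x$results)) {
    df <- x$results
    fmt_med <- function(m) ifelse(is.na(m), "Not reached", sprintf("%g", m))
    show <- data.frame(
      marker = df$marker,
      cutoff = sprintf("%s%.3g", ifelse(df$direction == "above", ">", "<="),
                       df$threshold),
      `median below (n)` = sprintf("%s (%d)", fmt_med(df$median_below), df$n_below),
      `median above (n)` = sprintf("%s (%d)", fmt_med(df$median_above), df$n_above),
      p = signif(df$p, digits), p_adj = signif(df$p_adj, digits),
      sig = ifelse(df$significant, "*", ""),
      check.names = FALSE)
    print(show[order(df$p), ], row.names = FALSE)
  }
  invisible(x)
}
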