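LESION_LEVELS <- c("CR", "PR", "SD", "PD", "NONE", "NE")

#' Composite overall response over intra- and extrahepatic lesions
#'
#' Combines per-compartment mRECIST evaluations into one overall response
#' for patients who may have hepatic tumors, extrahepatic lesions, or
#' both. `"NONE"` means the patient has no lesion in that compartment; a
#' patient with a single involved compartment takes that compartment's
#' response. For patients with both compartments involved: PD in either
#' compartment dominates; CR requires CR in both; PR requires at least one
#' PR with the other compartment CR or PR; SD requires all compartments in
#' \{CR, PR, SD\} with at least one SD; a non-PD combination that needs an
#' unevaluable compartment to decide is NE.
#'
#' @param intrahepatic,extrahepatic Character vectors (recycled to common
#'   length) with values in `CR`, `PR`, `SD`, `PD`, `NONE`, `NE`.
#' @return Character vector of overall responses in `CR`, `PR`, `SD`,
#'   `PD`, `NE`.
#' @export
combine_lesion_responses <- function(intrahepatic, extrahepatic) {
  n <- max(length(intrahepatic), length(extrahepatic))
  intra <- rep_len(as.character(intrahepatic), n)
  extra <- rep_len(as.character(extrahepatic), n)
  bad <- setdiff(unique(c(intra, extra)), LESION_LEVELS)
  if (length(bad)) stop("invalid lesion response: ", paste(bad, collapse = ", "))
  if (any(intra == "NONE" & extra == "NONE")) {
    stop("at least one compartment must have a lesion (both are NONE)")
  }
  one <- function(a, b) {
    if (a == "NONE") return(b)
    if (b == "NONE") return(a)
    if (a == "PD" || b == "PD") return("PD")
    if (a == "NE" || b == "NE") return("NE")
    if (a == "CR" && b == "CR") return("CR")
    if ((a == "PR" || b == "PR") && all(c(a, b) %in% c("CR", "PR"))) return("PR")
    if (all(c(a, b) %in% c("CR", "PR", "SD"))) return("SD")
    stop("unreachable lesion combination: ", a, "/", b) # nocov
  }
  vapply(seq_len(n), function(i) one(intra[i], extra[i]), character(1))
}

#' Build a per-arm response count table
#'
#' @param counts Named list or matrix of per-arm counts over the response
#'   categories `CR`, `PR`, `SD`, `PD`, `NE`. For the list form, each
#'   element is a named integer vector and the element names are the arm
#'   labels.
#' @return A `response_table`: integer matrix (arms x categories) with an
#'   `n` attribute of arm sizes.
#' @export
response_table <- function(counts) {
  cats <- c("CR", "PR", "SD", "PD", "NE")
  if (is.list(counts)) {
    m <- do.call(rbind, lapply(counts, function(x) x[cats]))
    rownames(m) <- names(counts)
  } else {
    m <- as.matrix(counts)[, cats, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative over CR, PR, SD, PD, NE")
  if (nrow(m) < 1) stop("at least one arm required")
  structure(m, n = rowSums(m), class = c("response_table", class(m)))
}

#' Objective response and disease control rates
#'
#' ORR = (CR + PR) / n and DCR = (CR + PR + SD) / n per arm over the
#' intention-to-treat denominator (not-evaluable patients stay in `n`),
#' with exact Clopper-Pearson binomial confidence intervals.
#'
#' @param table A [response_table].
#' @param conf_level Confidence level for the exact intervals.
#' @return A data frame with one row per arm: `arm`, `n`, `responders`,
#'   `orr`, `orr_lo`, `orr_hi`, `controlled`, `dcr`, `dcr_lo`, `dcr_hi`
#'   (rates as proportions).
#' @export
response_rates <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "response_table"))
  n <- attr(table, "n")
  if (any(n == 0)) stop("arm with zero patients")
  resp <- table[, "CR"] + table[, "PR"]
  ctrl <- resp + table[, "SD"]
  ci <- function(x, n) stats::binom.test(x, n, conf.level = conf_level)$conf.int
  out <- data.frame(
    arm = rownames(table), n = as.integer(n),
    responders = as.integer(resp), orr = resp / n,
    controlled = as.integer(ctrl), dcr = ctrl / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  cis_orr <- t(mapply(ci, resp, n))
  cis_dcr <- t(mapply(ci, ctrl, n))
  out$orr_lo <- cis_orr[, 1]; out$orr_hi <- cis_orr[, 2]
  out$dcr_lo <- cis_dcr[, 1]; out$dcr_hi <- cis_dcr[, 2]
  out
}

#' Compare a response endpoint between two arms
#'
#' Collapses the table to responder vs non-responder (ORR) or controlled
#' vs not (DCR) and compares the two arms with a continuity-corrected
#' chi-square test, falling back to Fisher's exact test when any expected
#' cell count is below 5 or a margin is degenerate.
#'
#' @param table A two-arm [response_table].
#' @param endpoint `"ORR"` or `"DCR"`.
#' @param correct Apply the Yates continuity correction to the chi-square
#'   statistic (default TRUE; uncorrected chi-square is closer to the
#'   Mantel-Haenszel-type tests some trial reports print).
#' @return List with `method` (`"chisq"` or `"fisher"`), `statistic`
#'   (chi-square only), `p_value`, and the collapsed 2x2 `table`.
#' @export
compare_rates <- function(table, endpoint = c("ORR", "DCR"), correct = TRUE) {
  stopifnot(inherits(table, "response_table"))
  endpoint <- match.arg(endpoint)
  if (nrow(table) != 2) stop("exactly two arms required")
  n <- attr(table, "n")
  hit <- table[, "CR"] + table[, "PR"] +
    if (endpoint == "DCR") table[, "SD"] else 0L
  tab <- cbind(yes = hit, no = n - hit)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- any(expected < 5) || any(colSums(tab) == 0)
  if (use_fisher) {
    ft <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p_value = ft$p.value,
         table = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(method = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value, table = tab)
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return A `km_fit`: data frame component `steps` with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `surv`), plus
#'   `median` (earliest time with survival <= 0.5, `NA` with
#'   `median_defined = FALSE` if the curve never reaches 0.5) and `n`.
#' @export
km_estimate <- function(time, event) {
  event <- as.integer(event)
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% 0:1))
  if (sum(event) < 1 && length(event) > 0) {
    steps <- data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), surv = numeric(0))
    return(structure(list(steps = steps, median = NA_real_,
                          median_defined = FALSE, n = length(time)),
                     class = "km_fit"))
  }
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  med_idx <- which(surv <= 0.5)
  median <- if (length(med_idx)) ut[min(med_idx)] else NA_real_
  structure(list(
    steps = data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       surv = surv),
    median = median, median_defined = length(med_idx) > 0, n = length(time)
  ), class = "km_fit")
}

#' Survival probability at a time point
#'
#' Reads the right-continuous step function of a [km_estimate] fit.
#'
#' @param fit A `km_fit`.
#' @param t Time(s) at which to evaluate the curve.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(t, function(tt) {
    i <- which(fit$steps$time <= tt)
    if (length(i)) fit$steps$surv[max(i)] else 1
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n", x$n,
              sum(x$steps$n_event),
              if (x$median_defined) format(x$median) else "not reached"))
  invisible(x)
}

#' Two-arm log-rank test with approximate hazard ratio
#'
#' Standard observed-minus-expected log-rank computation over the pooled
#' distinct event times, with the (O1/E1)/(O2/E2) hazard-ratio
#' approximation and a log-scale confidence interval using
#' `sqrt(1/E1 + 1/E2)` as the standard error of log HR. Optionally also
#' fits a Cox proportional-hazards regression.
#'
#' @param time,event As in [km_estimate].
#' @param arm Two-level factor or character vector of arm labels; the
#'   hazard ratio is reported for the second level relative to the first
#'   (alphabetical order if not a factor).
#' @param conf_level Confidence level for the HR interval.
#' @param cox Also fit `survival::coxph` and report its HR (`cox_hr`).
#' @return List with `statistic` (chi-square, 1 df), `p_value`,
#'   `observed`, `expected` (length-2 vectors in arm-level order), `hr`,
#'   `hr_lo`, `hr_hi`, `arms`, and optionally `cox_hr`.
#' @export
logrank_and_hr <- function(time, event, arm, conf_level = 0.95, cox = FALSE) {
  event <- as.integer(event)
  arm <- factor(arm)
  if (nlevels(arm) != 2) stop("exactly two arms required")
  stopifnot(length(time) == length(event), length(arm) == length(time))
  g2 <- arm == levels(arm)[2]
  if (sum(event[g2]) < 1 || sum(event[!g2]) < 1) {
    stop("each arm needs at least one event")
  }
  ut <- sort(unique(time[event == 1]))
  # vectorized O-E over distinct event times
  at_risk <- function(keep) vapply(ut, function(t) sum(time[keep] >= t), numeric(1))
  events_at <- function(keep) {
    vapply(ut, function(t) sum(time[keep] == t & event[keep] == 1), numeric(1))
  }
  n1 <- at_risk(!g2); n2 <- at_risk(g2)
  d1 <- events_at(!g2); d2 <- events_at(g2)
  n <- n1 + n2; d <- d1 + d2
  e1 <- d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (n2 / n) * (n - d) / (n - 1), 0)
  O <- c(sum(d1), sum(d2))
  E <- c(sum(e1), sum(d) - sum(e1))
  V <- sum(v)
  stat <- if (V > 0) (O[1] - E[1])^2 / V else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se_log <- sqrt(1 / E[1] + 1 / E[2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(statistic = stat, p_value = p, observed = O, expected = E,
              hr = hr, hr_lo = exp(log(hr) - z * se_log),
              hr_hi = exp(log(hr) + z * se_log), arms = levels(arm))
  if (cox) {
    cf <- survival::coxph(survival::Surv(time, event) ~ arm)
    out$cox_hr <- unname(exp(stats::coef(cf)))
  }
  out
}

#' Log-rank sample size for a two-arm survival trial
#'
#' Events by the Freedman formula
#' \deqn{d = (z_{1-\alpha/2} + z_{power})^2 \left(\frac{1+HR}{1-HR}\right)^2}
#' with the hazard ratio taken from the ratio of exponential medians
#' (`HR = median_control / median_treatment`), or by the Schoenfeld
#' formula \eqn{d = 4 (z_{1-\alpha/2}+z_{power})^2 / (\log HR)^2}.
#' Total events are rounded up, halved (1:1 allocation) and rounded up
#' again, then inflated by the event probability and the anticipated loss
#' to follow-up, each stage rounding up to whole patients.
#'
#' @param median_control,median_treatment Exponential survival medians
#'   (months) under control and treatment; must differ.
#' @param alpha Two-sided type I error.
#' @param power Target power (1 - beta).
#' @param loss_fraction Anticipated fraction lost to follow-up, in [0, 1).
#' @param event_probability Probability a recruited patient yields an
#'   event during the study, in (0, 1].
#' @param method `"freedman"` (default) or `"schoenfeld"`.
#' @return List with `hr`, `events_total`, `events_per_group`,
#'   `n_per_group`, `n_total`, and `method`.
#' @export
freedman_sample_size <- function(median_control, median_treatment,
                                 alpha = 0.05, power = 0.80,
                                 loss_fraction = 0.10,
                                 event_probability = 1,
                                 method = c("freedman", "schoenfeld")) {
  method <- match.arg(method)
  stopifnot(median_control > 0, median_treatment > 0,
            alpha > 0, alpha < 1, power > 0, power < 1,
            loss_fraction >= 0, loss_fraction < 1,
            event_probability > 0, event_probability <= 1)
  hr <- median_control / median_treatment
  if (hr == 1) stop("equal medians: hazard ratio 1 gives an undefined design")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  d <- if (method == "freedman") {
    (za + zb)^2 * ((1 + hr) / (1 - hr))^2
  } else {
    4 * (za + zb)^2 / log(hr)^2
  }
  events_total <- ceiling(d)
  events_per_group <- ceiling(events_total / 2)
  n_per_group <- ceiling(events_per_group / event_probability /
                           (1 - loss_fraction))
  list(hr = hr, events_total = events_total,
       events_per_group = events_per_group, n_per_group = n_per_group,
       n_total = 2L * n_per_group, method = method)
}

#' Monte-Carlo power of the log-rank test under exponential survival
#'
#' Simulates two-arm trials with exponential event times at the given
#' medians and full follow-up (no censoring), applies the unstratified
#' log-rank test to each, and reports the rejection fraction at the given
#' two-sided level.
#'
#' @param n_per_arm Patients per arm actually analyzed.
#' @param median_control,median_treatment Exponential medians (months).
#' @param n_sim Number of simulated trials.
#' @param alpha Two-sided significance level.
#' @param seed Optional integer seed.
#' @return List with `power` (rejection fraction), `n_sim`, `n_per_arm`.
#' @export
logrank_power_mc <- function(n_per_arm, median_control, median_treatment,
                             n_sim = 2000, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm <- factor(rep(c("control", "treatment"), each = n_per_arm))
  rc <- log(2) / median_control
  rt <- log(2) / median_treatment
  rej <- vapply(seq_len(n_sim), function(i) {
    tt <- c(stats::rexp(n_per_arm, rc), stats::rexp(n_per_arm, rt))
    logrank_and_hr(tt, rep(1L, 2 * n_per_arm), arm)$p_value < alpha
  }, logical(1))
  list(power = mean(rej), n_sim = n_sim, n_per_arm = n_per_arm)
}
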