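#' Assemble survival data from clinical annotations and risk calls
#'
#' Joins risk labels onto the clinical table for one endpoint. Samples
#' treated with adjuvant therapy (`adjuvant == "yes"`) are excluded by
#' default since post-surgical treatment confounds outcome; samples with
#' `adjuvant == "unknown"` are retained. Samples missing the endpoint or a
#' risk label are dropped.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param calls Risk-call data.frame from [classify_samples()].
#' @param endpoint `"os"` (overall survival) or `"rfs"` (recurrence-free).
#' @param exclude_adjuvant Drop adjuvant-treated samples (default TRUE).
#' @return data.frame with columns sample_id, time, event, group and any
#'   of age, gender, stage present in the clinical table.
#' @export
build_survival_data <- function(clinical, calls, endpoint = c("os", "rfs"),
                                exclude_adjuvant = TRUE) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% colnames(clinical)))
    stop("clinical table lacks ", endpoint, " columns")
  df <- merge(clinical, calls[, c("sample_id", "label")], by = "sample_id")
  if (exclude_adjuvant) df <- df[df$adjuvant != "yes", , drop = FALSE]
  df <- df[!is.na(df[[tcol]]) & !is.na(df[[ecol]]) & !is.na(df$label), ]
  out <- data.frame(sample_id = df$sample_id, time = df[[tcol]],
                    event = df[[ecol]], group = df$label,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("age", "gender", "stage"), colnames(df)))
    out[[col]] <- df[[col]]
  out
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Follow-up times (months).
#' @param event Event indicators (1 = event, 0 = censored). Censoring at an
#'   event time is handled events-first, as in the product-limit estimator.
#' @return data.frame: time, n_risk, n_event, n_censor, survival.
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("need >= 1 sample")
  if (all(time == 0) && all(event == 0))
    warning("degenerate curve: all samples censored at time zero")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test between two groups
#'
#' @param time,event Survival data.
#' @param group Two-level group labels.
#' @return list(stat, p): the 1-df chi-squared statistic and two-sided p.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank needs exactly 2 non-empty groups")
  if (sum(event) < 1L) stop("need >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(stat = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional hazards fit (Efron ties)
#'
#' Wraps `survival::coxph` and reports, per covariate, the hazard ratio,
#' Wald 95% confidence interval and p-value. With a single covariate this
#' is the univariate model; supply age/gender/stage columns for the
#' adjusted model.
#'
#' @param time,event Survival data.
#' @param covariates data.frame of covariates (factors or numeric).
#' @param ties Tie handling, default `"efron"`.
#' @return data.frame: term, coef, hr, ci_lo, ci_hi, p.
#' @export
cox_fit <- function(time, event, covariates, ties = "efron") {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                  TRUE)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[const], collapse = ", "))
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox fit did not converge: ", fit$info)
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$coefficients[, "exp(coef)"],
             ci_lo = s$conf.int[, "lower .95"],
             ci_hi = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs (the sample with the shorter follow-up time
#' had an event), a pair is concordant when that sample also has the higher
#' risk score; tied scores count 1/2. Equal follow-up times are not
#' comparable under this definition.
#'
#' @param scores Numeric risk scores, higher = predicted worse outcome.
#' @param time,event Survival data aligned with `scores`.
#' @return C-index in [0, 1]; 0.5 is uninformative.
#' @export
c_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  # comparable: i failed strictly before j's follow-up ended
  comp <- outer(time, time, "<") & matrix(event == 1L, n, n)
  diag(comp) <- FALSE
  npairs <- sum(comp)
  if (npairs == 0L) stop("no comparable pairs")
  si <- matrix(scores, n, n)           # score of the earlier-failing sample
  sj <- t(si)
  wt <- ifelse(si > sj, 1, ifelse(si == sj, 0.5, 0))
  sum(wt[comp]) / npairs
}

#' Event rate at a horizon from the Kaplan-Meier curve
#'
#' Returns `1 - S(horizon)` using the last estimate at or before the
#' horizon (default 60 months = 5 years). If follow-up does not reach the
#' horizon a coverage warning is issued.
#'
#' @param time,event Survival data.
#' @param horizon Horizon in months, default 60.
#' @export
rate_at <- function(time, event, horizon = 60) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (max(time) < horizon)
    warning("follow-up does not reach the horizon; rate is extrapolated")
  km <- km_fit(time, event)
  idx <- which(km$time <= horizon)
  s <- if (length(idx)) km$survival[max(idx)] else 1
  1 - s
}

#' Compare survival between high- and low-risk groups
#'
#' Bundles the per-group Kaplan-Meier curves, the log-rank test, the
#' univariate hazard ratio of high vs low (Cox, Efron ties), Harrell's
#' C-index of the binary risk indicator, and the event rate at the horizon
#' per group.
#'
#' @param surv data.frame from [build_survival_data()].
#' @param horizon Months, default 60.
#' @return list with elements km (per group), logrank, hr, ci, cox_p,
#'   c_index, rate_at_horizon, n (per group).
#' @export
survival_comparison <- function(surv, horizon = 60) {
  stopifnot(all(c("time", "event", "group") %in% colnames(surv)))
  groups <- split(surv, surv$group)
  km <- lapply(groups, function(g) km_fit(g$time, g$event))
  lr <- logrank_test(surv$time, surv$event, surv$group)
  risk <- as.integer(surv$group == "high")
  cox <- cox_fit(surv$time, surv$event, data.frame(risk_high = risk))
  list(km = km,
       logrank = lr,
       hr = cox$hr, ci = c(cox$ci_lo, cox$ci_hi), cox_p = cox$p,
       c_index = c_index(risk, surv$time, surv$event),
       rate_at_horizon = vapply(groups, function(g)
         suppressWarnings(rate_at(g$time, g$event, horizon)), 0),
       n = vapply(groups, nrow, 0L))
}
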