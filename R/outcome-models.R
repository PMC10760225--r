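# Outcome models on CLR composition vectors: 3-fold cross-validated
# elastic-net logistic (good vs poor outcome) and Cox (disease-free survival)
# regressions, concordance metrics, Kaplan-Meier risk stratification at the
# train-median hazard threshold, and the Wald/Fisher significance machinery.
#
# Elastic-net parameterization: `alpha` is the overall penalty strength and
# `l1_ratio` the L1 share (so glmnet is called with lambda = alpha and
# glmnet-alpha = l1_ratio). The penalty is scaled per observation, so
# duplicating every row leaves coefficients unchanged.

km_step <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  stats::stepfun(fit$time, c(1, fit$surv))
}

max_km_gap <- function(time1, event1, time2, event2) {
  ts <- sort(unique(c(time1[event1 == 1], time2[event2 == 1])))
  if (!length(ts)) return(0)
  s1 <- km_step(time1, event1)
  s2 <- km_step(time2, event2)
  max(abs(s1(ts) - s2(ts)))
}

#' Build cross-validation folds with matched survival profiles
#'
#' Patients are split into `n_folds` test sets at random, then each fold's
#' non-test patients into 80% train / 20% validation. Splits are
#' rejection-sampled until, in every fold, the maximum vertical gap between
#' the train and test Kaplan-Meier curves (evaluated at pooled event times)
#' is at most `km_tolerance`; after `max_attempts` the best split found is
#' returned with a warning.
#'
#' @param records Patient-level tibble with `patient_id`, `dfs_months`,
#'   `event`.
#' @param n_folds Number of folds (default 3: one third of patients tests).
#' @param seed Integer seed.
#' @param km_tolerance Maximum allowed KM gap (default 0.15).
#' @param max_attempts Rejection-sampling budget.
#' @return Tibble `patient_id`, `fold` (0-based), `split`
#'   (`train`/`validation`/`test`), `n_folds * n_patients` rows, with
#'   attribute `km_gap` (the achieved worst-fold gap).
#' @export
make_folds <- function(records, n_folds = 3L, seed = 1L, km_tolerance = 0.15,
                       max_attempts = 200L) {
  records <- distinct(records, patient_id, dfs_months, event)
  n <- nrow(records)
  if (n < n_folds) abort("Need at least as many patients as folds.")
  best <- NULL
  best_gap <- Inf
  for (attempt in seq_len(max_attempts)) {
    asg <- with_seed(substream_seed(seed, "folds", attempt), {
      sample(rep(seq_len(n_folds) - 1L, length.out = n))
    })
    gap <- max(vapply(seq_len(n_folds) - 1L, function(f) {
      te <- asg == f
      max_km_gap(records$dfs_months[!te], records$event[!te],
                 records$dfs_months[te], records$event[te])
    }, 0))
    if (gap < best_gap) {
      best_gap <- gap
      best <- asg
    }
    if (gap <= km_tolerance) break
  }
  if (best_gap > km_tolerance) {
    warn(sprintf("No split reached KM tolerance %.3f after %d attempts; best gap %.3f.",
                 km_tolerance, max_attempts, best_gap))
  }
  out <- purrr::map(seq_len(n_folds) - 1L, function(f) {
    split <- ifelse(best == f, "test", "train")
    non_test <- which(split == "train")
    n_val <- max(1L, round(0.2 * length(non_test)))
    val <- with_seed(substream_seed(seed, "val", f),
                     sample(non_test, n_val))
    split[val] <- "validation"
    tibble(patient_id = records$patient_id, fold = f, split = split)
  })
  out <- bind_rows(out)
  attr(out, "km_gap") <- best_gap
  out
}

glmnet_xy <- function(X) {
  if (is.data.frame(X)) composition_matrix(X) else as.matrix(X)
}

#' Elastic-net logistic regression (good vs poor outcome)
#'
#' Penalized maximum likelihood via glmnet at a single penalty strength.
#' `alpha` follows the strength/share convention documented above (the
#' emulated analysis reports a single tuned alpha of 0.25, interpreted as the
#' penalty strength; `l1_ratio` defaults to 0.5).
#'
#' @param X Feature matrix or CLR tibble (columns `hpc_*`).
#' @param y Binary outcome; `"good"`/`"poor"` (poor is the positive class) or
#'   0/1.
#' @param alpha Overall penalty strength (glmnet lambda).
#' @param l1_ratio L1 share in `[0, 1]` (glmnet alpha).
#' @param standardize Standardize features before fitting (off by default:
#'   CLR features are already centred per sample).
#' @return A list of class `hpl_logistic_fit` with `coefficients`,
#'   `intercept`, `alpha`, `l1_ratio`, `terms`.
#' @export
fit_logistic_en <- function(X, y, alpha = 0.25, l1_ratio = 0.5,
                            standardize = FALSE) {
  Xm <- glmnet_xy(X)
  if (is.character(y) || is.factor(y)) {
    y <- as.integer(as.character(y) == "poor")
  }
  if (length(unique(y)) < 2) abort("Both outcome classes must be present.")
  fit <- glmnet::glmnet(Xm, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = l1_ratio, lambda = alpha,
                        standardize = standardize)
  cf <- as.numeric(coef(fit, s = alpha))
  structure(list(coefficients = setNames(cf[-1], colnames(Xm)),
                 intercept = cf[1], alpha = alpha, l1_ratio = l1_ratio,
                 terms = colnames(Xm), family = "logistic"),
            class = "hpl_logistic_fit")
}

#' Elastic-net Cox proportional hazards regression
#'
#' Penalized partial likelihood via glmnet (`family = "cox"`); the linear
#' predictor is the hazard score. Default penalty strength 0.35 and L1 share
#' 0.01 (the tuned values of the emulated analysis).
#'
#' @inheritParams fit_logistic_en
#' @param time,event Survival times (months) and event indicators.
#' @return A list of class `hpl_cox_fit`.
#' @export
fit_cox_en <- function(X, time, event, alpha = 0.35, l1_ratio = 0.01,
                       standardize = FALSE) {
  Xm <- glmnet_xy(X)
  if (sum(event) < 1) abort("At least one event is required.")
  fit <- glmnet::glmnet(Xm, survival::Surv(time, event), family = "cox",
                        alpha = l1_ratio, lambda = alpha,
                        standardize = standardize)
  cf <- as.numeric(coef(fit, s = alpha))
  structure(list(coefficients = setNames(cf, colnames(Xm)),
                 intercept = 0, alpha = alpha, l1_ratio = l1_ratio,
                 terms = colnames(Xm), family = "cox"),
            class = "hpl_cox_fit")
}

#' @export
predict.hpl_logistic_fit <- function(object, newdata,
                                     type = c("link", "response"), ...) {
  type <- match.arg(type)
  lp <- drop(glmnet_xy(newdata)[, object$terms, drop = FALSE] %*%
               object$coefficients) + object$intercept
  if (type == "response") stats::plogis(lp) else lp
}

#' @export
predict.hpl_cox_fit <- function(object, newdata, ...) {
  drop(glmnet_xy(newdata)[, object$terms, drop = FALSE] %*%
         object$coefficients)
}

#' @export
print.hpl_logistic_fit <- function(x, ...) {
  cat(sprintf("<elastic-net %s fit> %d terms, %d active (alpha %.3g, l1_ratio %.3g)\n",
              x$family, length(x$coefficients),
              sum(abs(x$coefficients) > 1e-8), x$alpha, x$l1_ratio))
  invisible(x)
}

#' @export
print.hpl_cox_fit <- print.hpl_logistic_fit

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative, ties
#' counted one half (rank/Wilcoxon form).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1/`"poor"` = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "poor")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's concordance index
#'
#' Fraction of admissible pairs (the earlier time is an event) in which the
#' higher risk score belongs to the patient with the earlier event; score ties
#' count one half.
#'
#' @param scores Risk scores (higher = shorter expected survival).
#' @param time,event Survival data.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, time, event) {
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  n_pairs <- sum(cf$count[1:4])
  if (n_pairs == 0 || is.na(cf$concordance)) {
    abort("No comparable pairs for concordance.")
  }
  unname(cf$concordance)
}

#' Uno's IPCW concordance index
#'
#' Inverse-probability-of-censoring-weighted concordance truncated at `tau`:
#' admissible pairs are weighted by `1 / G(t_i-)^2`, `G` the Kaplan-Meier
#' estimator of the censoring distribution.
#'
#' @inheritParams harrell_c
#' @param tau Truncation time; pairs with the earlier time beyond `tau` are
#'   excluded. Defaults to the largest event time.
#' @param censor_time,censor_event Optional data from which to estimate `G`
#'   (e.g. the training split); defaults to `time`/`event` themselves.
#' @return Concordance in `[0, 1]`.
#' @export
uno_c <- function(scores, time, event, tau = NULL,
                  censor_time = time, censor_event = event) {
  if (is.null(tau)) {
    if (!any(event == 1)) abort("No events; cannot set a default tau.")
    tau <- max(time[event == 1])
  }
  Gfit <- survival::survfit(survival::Surv(censor_time, 1 - censor_event) ~ 1)
  Gstep <- stats::stepfun(Gfit$time, c(1, Gfit$surv))
  # left limit G(t-): value just before t
  Gminus <- function(t) Gstep(t - 1e-9)
  n <- length(time)
  admiss <- outer(time, time, "<") & matrix(event == 1, n, n) &
    matrix(time <= tau, n, n)
  if (!any(admiss)) abort("No admissible pairs at this tau.")
  g <- Gminus(time)
  if (any(g[event == 1 & time <= tau & rowSums(admiss) > 0] <= 0)) {
    abort("Censoring survival is zero at a needed event time; weights undefined.")
  }
  w <- matrix(1 / g^2, n, n)
  conc <- outer(scores, scores, ">") + 0.5 * outer(scores, scores, "==")
  sum(w * admiss * conc) / sum(w * admiss)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time,event Survival data with right censoring.
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic with 1 degree of
#' freedom.
#'
#' @param time,event Survival data.
#' @param group Two-level grouping vector.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) abort("Exactly two non-empty groups required.")
  if (sum(event) < 1) abort("At least one event is required.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(statistic = sd$chisq, df = 1,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Per-coefficient Wald tests
#'
#' Wald tests on a penalized fit are ill-defined, so the model is refit
#' unpenalized on the active set (`|coef| > 1e-8`) and p-values are taken from
#' the observed information of that refit: `p = 2 * pnorm(-|coef / se|)`.
#' Inactive terms and terms with singular information get `NA`.
#'
#' @param fit An `hpl_logistic_fit` or `hpl_cox_fit`.
#' @param X Feature matrix or CLR tibble used for the refit.
#' @param y Binary outcome (logistic fits).
#' @param time,event Survival data (Cox fits).
#' @return Tibble `term`, `estimate` (penalized), `refit_estimate`, `se`,
#'   `statistic`, `p_value`.
#' @export
wald_pvalues <- function(fit, X, y = NULL, time = NULL, event = NULL) {
  Xm <- glmnet_xy(X)[, fit$terms, drop = FALSE]
  active <- which(abs(fit$coefficients) > 1e-8)
  out <- tibble(term = fit$terms, estimate = unname(fit$coefficients),
                refit_estimate = NA_real_, se = NA_real_,
                statistic = NA_real_, p_value = NA_real_)
  if (!length(active)) return(out)
  Xa <- Xm[, active, drop = FALSE]
  res <- tryCatch({
    if (fit$family == "logistic") {
      if (is.character(y) || is.factor(y)) {
        y <- as.integer(as.character(y) == "poor")
      }
      g <- suppressWarnings(glm(y ~ Xa, family = binomial()))
      s <- summary(g)$coefficients
      rows <- match(paste0("Xa", colnames(Xa)), rownames(s))
      list(est = s[rows, 1], se = s[rows, 2])
    } else {
      cp <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ Xa))
      s <- summary(cp)$coefficients
      rows <- match(paste0("Xa", colnames(Xa)), rownames(s))
      list(est = s[rows, 1], se = s[rows, 3])
    }
  }, error = function(e) NULL)
  if (is.null(res)) return(out)
  out$refit_estimate[active] <- res$est
  out$se[active] <- res$se
  out$statistic[active] <- res$est / res$se
  out$p_value[active] <- 2 * pnorm(-abs(out$statistic[active]))
  out
}

#' Fisher's combined probability test
#'
#' `X = -2 * sum(log(p))` referred to a chi-square with `2 * length(p)`
#' degrees of freedom.
#'
#' @param pvalues Numeric p-values in `(0, 1]`; `NA`s are dropped.
#' @return Combined p-value.
#' @export
fisher_combine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) return(NA_real_)
  if (any(pvalues <= 0 | pvalues > 1)) abort("p-values must lie in (0, 1].")
  x <- -2 * sum(log(pvalues))
  pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

# lower-median convention: for even n the lower of the two middle order stats
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Median-split risk stratification
#'
#' The threshold is the (lower) median of the training hazard predictions —
#' fixed before any test outcome is seen; test patients above it form the
#' high-risk group. Kaplan-Meier curves per group and the log-rank test are
#' computed on the test set.
#'
#' @param train_scores Hazard scores of the training split.
#' @param test_scores Hazard scores of the test split.
#' @param test_time,test_event Test-split survival data.
#' @return A list of class `hpl_risk_groups`: `threshold`, `groups` (tibble
#'   with `score`, `group`, `time`, `event`), `km` (per-group curves),
#'   `logrank` (or `NULL` with a warning when one group is empty).
#' @export
stratify_risk <- function(train_scores, test_scores, test_time, test_event) {
  threshold <- lower_median(train_scores)
  group <- ifelse(test_scores > threshold, "high", "low")
  groups <- tibble(score = test_scores, group = group,
                   time = test_time, event = test_event)
  km <- groups %>% group_by(group) %>%
    dplyr::group_modify(function(d, g) kaplan_meier(d$time, d$event)) %>%
    ungroup()
  lr <- NULL
  if (length(unique(group)) == 2 && sum(test_event) >= 1) {
    lr <- logrank_test(test_time, test_event, group)
  } else {
    warn("All test scores fall on one side of the threshold (or no events); log-rank skipped.")
  }
  structure(list(threshold = threshold, groups = groups, km = km,
                 logrank = lr),
            class = "hpl_risk_groups")
}

#' @export
print.hpl_risk_groups <- function(x, ...) {
  p <- if (is.null(x$logrank)) NA_real_ else x$logrank$p_value
  cat(sprintf("<risk groups> threshold %.4f; %d high / %d low; log-rank p %s\n",
              x$threshold, sum(x$groups$group == "high"),
              sum(x$groups$group == "low"),
              ifelse(is.na(p), "NA", format.pval(p, digits = 3))))
  invisible(x)
}

#' Cross-validated outcome modelling
#'
#' Fits the chosen elastic-net family on each fold's training patients and
#' evaluates on its validation and test patients: AUROC for the logistic
#' family; Harrell's and Uno's concordance plus median-split risk
#' stratification (with log-rank) for the Cox family. Coefficients are
#' averaged across folds for reporting.
#'
#' @param data Patient-level tibble: `patient_id`, `hpc_*` feature columns
#'   (CLR values), `outcome`, and for Cox `dfs_months`, `event`.
#' @param folds Fold table from [make_folds()].
#' @param family `"logistic"` or `"cox"`.
#' @param alpha,l1_ratio Elastic-net parameters (defaults: 0.25/0.5 logistic,
#'   0.35/0.01 Cox).
#' @param uno_tau Truncation for Uno's c; default the largest train event
#'   time per fold.
#' @return A list of class `hpl_cv`: `metrics` (fold x split x metric),
#'   `coefficients`, `mean_coefficients`, `fits`, `risk_groups`, `wald`
#'   (per-fold Wald tables on the training split), `family`.
#' @export
cross_validate <- function(data, folds, family = c("logistic", "cox"),
                           alpha = NULL, l1_ratio = NULL, uno_tau = NULL) {
  family <- match.arg(family)
  alpha <- alpha %||% if (family == "logistic") 0.25 else 0.35
  l1_ratio <- l1_ratio %||% if (family == "logistic") 0.5 else 0.01
  fold_ids <- sort(unique(folds$fold))
  feat <- grep("^hpc_", names(data), value = TRUE)
  metrics <- list(); coefs <- list(); fits <- list(); rgs <- list()
  walds <- list()
  for (f in fold_ids) {
    fmap <- filter(folds, fold == f)
    d <- left_join(data, fmap, by = "patient_id")
    tr <- filter(d, split == "train")
    va <- filter(d, split == "validation")
    te <- filter(d, split == "test")
    Xtr <- as.matrix(tr[feat])
    fit <- if (family == "logistic") {
      fit_logistic_en(Xtr, tr$outcome, alpha, l1_ratio)
    } else {
      fit_cox_en(Xtr, tr$dfs_months, tr$event, alpha, l1_ratio)
    }
    fits[[as.character(f)]] <- fit
    coefs[[as.character(f)]] <- tibble(fold = f, term = fit$terms,
                                       estimate = unname(fit$coefficients))
    score <- function(dd) predict(fit, as.matrix(dd[feat]))
    if (family == "logistic") {
      walds[[as.character(f)]] <- mutate(
        wald_pvalues(fit, Xtr, y = tr$outcome), fold = f)
      for (sp in list(c("validation", "va"), c("test", "te"))) {
        dd <- if (sp[2] == "va") va else te
        metrics[[paste(f, sp[1])]] <- tibble(
          fold = f, split = sp[1], metric = "auroc",
          value = tryCatch(auroc(score(dd), dd$outcome), error = function(e) {
            warn(sprintf("AUROC undefined on fold %d %s split: %s",
                         f, sp[1], conditionMessage(e)))
            NA_real_
          }))
      }
    } else {
      walds[[as.character(f)]] <- mutate(
        wald_pvalues(fit, Xtr, time = tr$dfs_months, event = tr$event),
        fold = f)
      tau <- uno_tau %||% if (any(tr$event == 1)) {
        max(tr$dfs_months[tr$event == 1])
      } else {
        max(tr$dfs_months)
      }
      for (sp in list(c("validation", "va"), c("test", "te"))) {
        dd <- if (sp[2] == "va") va else te
        s <- score(dd)
        safe <- function(expr) tryCatch(expr, error = function(e) {
          warn(sprintf("Concordance undefined on fold %d %s split: %s",
                       f, sp[1], conditionMessage(e)))
          NA_real_
        })
        metrics[[paste(f, sp[1])]] <- tibble(
          fold = f, split = sp[1],
          metric = c("harrell_c", "uno_c"),
          value = c(safe(harrell_c(s, dd$dfs_months, dd$event)),
                    safe(uno_c(s, dd$dfs_months, dd$event, tau = tau,
                               censor_time = tr$dfs_months,
                               censor_event = tr$event))))
      }
      rg <- stratify_risk(score(tr), score(te), te$dfs_months, te$event)
      rgs[[as.character(f)]] <- rg
      if (!is.null(rg$logrank)) {
        metrics[[paste(f, "lr")]] <- tibble(
          fold = f, split = "test", metric = "logrank_p",
          value = rg$logrank$p_value)
      }
    }
  }
  coefficients <- bind_rows(coefs)
  mean_coefficients <- coefficients %>% group_by(term) %>%
    summarise(estimate = mean(estimate), .groups = "drop")
  structure(list(metrics = bind_rows(metrics), coefficients = coefficients,
                 mean_coefficients = mean_coefficients, fits = fits,
                 risk_groups = rgs, wald = bind_rows(walds), family = family,
                 alpha = alpha, l1_ratio = l1_ratio),
            class = "hpl_cv")
}

#' @export
print.hpl_cv <- function(x, ...) {
  agg <- x$metrics %>% group_by(split, metric) %>%
    summarise(mean = mean(value), .groups = "drop")
  cat(sprintf("<hpl_cv> %s elastic net (alpha %.3g, l1_ratio %.3g), %d folds\n",
              x$family, x$alpha, x$l1_ratio,
              dplyr::n_distinct(x$metrics$fold)))
  print(as.data.frame(agg), row.names = FALSE)
  invisible(x)
}
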