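# parse a reference/positivity rule: "fv<400", "ri>0.6", "group",
# "hvsi<=121" -> logical vector over records
parse_rule <- function(rule, records) {
  rule <- gsub(" ", "", rule)
  if (rule %in% c("group", "group=stenosis", "group==stenosis"))
    return(records$group == "stenosis")
  m <- regmatches(rule, regexec("^(fv|ri|hvsi)(<=|>=|<|>)([0-9.]+)$", rule))[[1]]
  if (length(m) != 4)
    stop("cannot parse rule: '", rule,
         "' (expected e.g. 'fv<400', 'hvsi<=121', or 'group')", call. = FALSE)
  col <- c(fv = "flow_volume", ri = "resistance_index", hvsi = "hvsi")[m[2]]
  if (is.null(records[[col]]))
    stop("rule references missing column: ", col, call. = FALSE)
  get(m[3])(records[[col]], as.numeric(m[4]))
}

#' Classify a score against a cutoff
#'
#' A *low* index signals disease: positive iff `hvsi <= cutoff` (the boundary
#' itself is positive). The orientation is recorded in the result so the
#' convention stays visible.
#'
#' @param hvsi Score(s) in \[0, 999\].
#' @param cutoff Decision cutoff in the same units.
#' @return A logical vector (`TRUE` = positive) with attribute
#'   `orientation = "lower_is_positive"`.
#' @export
classify_hvsi <- function(hvsi, cutoff) {
  if (any(hvsi < 0 | hvsi > 999))
    stop("hvsi scores must lie in [0, 999]", call. = FALSE)
  structure(hvsi <= cutoff, orientation = "lower_is_positive",
            cutoff = cutoff)
}

#' Confusion counts of a test rule against a reference rule
#'
#' @param records Patient-record data frame (`hvsi`, `flow_volume`,
#'   `resistance_index`, `group`, ...).
#' @param positivity_rule Test rule string (e.g. `"hvsi<=121"`) or a logical
#'   vector of test positives.
#' @param reference_rule Reference-standard rule (e.g. `"fv<400"`, `"group"`)
#'   or a logical vector.
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`, `total`.
#' @export
confusion <- function(records, positivity_rule, reference_rule) {
  if (NROW(records) == 0L) stop("no records to evaluate", call. = FALSE)
  test <- if (is.logical(positivity_rule)) positivity_rule
          else parse_rule(positivity_rule, records)
  ref <- if (is.logical(reference_rule)) reference_rule
         else parse_rule(reference_rule, records)
  structure(list(tp = sum(test & ref), fp = sum(test & !ref),
                 fn = sum(!test & ref), tn = sum(!test & !ref),
                 total = length(ref)),
            class = "confusion_counts")
}

round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, PPV and NPV in percent, rounded half-up to one
#' decimal. A metric with a zero denominator is reported as `NA` (absent), not
#' as 0 or 100.
#'
#' @param counts A [confusion()] result (or list with `tp`, `fp`, `fn`, `tn`).
#' @return Named numeric vector (percent): `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
accuracy_metrics <- function(counts) {
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den) else NA_real_
  c(sensitivity = pct(counts$tp, counts$tp + counts$fn),
    specificity = pct(counts$tn, counts$tn + counts$fp),
    ppv = pct(counts$tp, counts$tp + counts$fp),
    npv = pct(counts$tn, counts$tn + counts$fn))
}

#' Concordance of test and reference classifications
#'
#' @inheritParams confusion
#' @return List with `agree`, `total`, `pct` (percent, one decimal).
#' @export
concordance <- function(records, positivity_rule, reference_rule) {
  cc <- confusion(records, positivity_rule, reference_rule)
  agree <- cc$tp + cc$tn
  list(agree = agree, total = cc$total,
       pct = round_half_up(100 * agree / cc$total))
}

# DeLong variance of the empirical AUC (placement-value form)
delong_auc_var <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  # placements: for each positive, fraction of negatives it beats (ties 1/2)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                numeric(1))
  stats::var(v10) / m + stats::var(v01) / n
}

#' Empirical ROC analysis
#'
#' Sweeps all distinct score thresholds, computing sensitivity and specificity
#' for the oriented score (default: lower scores are positive-leaning, the
#' screening convention for this index). The AUC is the trapezoid of the
#' empirical curve, identical to the rank statistic (probability a random
#' positive scores more positive-leaning than a random negative, ties 1/2).
#' The 95% CI uses the asymptotic DeLong variance; for fewer than 30 per class
#' a stratified bootstrap percentile interval is substituted.
#'
#' @param records Patient-record data frame.
#' @param reference_rule Reference rule string or logical vector.
#' @param score Column name of the score (default `"hvsi"`).
#' @param orientation `"lower"` if small scores indicate disease (default),
#'   `"higher"` otherwise.
#' @param ci_method `"auto"` (DeLong for >= 30 per class, else bootstrap),
#'   `"delong"`, `"boot"`, or `"none"` to skip the interval.
#' @param ci_boot_n Bootstrap replicates for the small-sample CI.
#' @param seed Seed for the bootstrap CI.
#' @return An `roc_result`: `thresholds`, `sensitivities`, `specificities`,
#'   `auc`, `auc_ci`, and the Youden fields filled by [youden_cutoff()].
#' @export
hvsi_roc <- function(records, reference_rule, score = "hvsi",
                     orientation = c("lower", "higher"),
                     ci_method = c("auto", "delong", "boot", "none"),
                     ci_boot_n = 2000, seed = 1L) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  ref <- if (is.logical(reference_rule)) reference_rule
         else parse_rule(reference_rule, records)
  s <- records[[score]]
  if (is.null(s)) stop("missing score column: ", score, call. = FALSE)
  if (!any(ref) || all(ref))
    stop("ROC requires both classes present in the reference", call. = FALSE)
  # orient so that LARGER oriented score = more positive-leaning
  z <- if (orientation == "lower") -s else s
  pos <- z[ref]; neg <- z[!ref]
  # thresholds at midpoints between adjacent distinct scores, plus sentinels
  u <- sort(unique(z))
  thr <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  # trapezoid over (FPR, TPR)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  m <- length(pos); n <- length(neg)
  if (ci_method == "auto")
    ci_method <- if (min(m, n) >= 30) "delong" else "boot"
  if (ci_method == "none") {
    ci <- c(NA_real_, NA_real_)
  } else if (ci_method == "delong") {
    se <- sqrt(delong_auc_var(pos, neg))
    ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  } else {
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(ci_boot_n), function(i) {
        pb <- sample(pos, m, TRUE); nb <- sample(neg, n, TRUE)
        (sum(outer(pb, nb, ">")) + 0.5 * sum(outer(pb, nb, "=="))) / (m * n)
      }, numeric(1))
      stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    })
  }
  # report thresholds on the original score scale
  res <- structure(
    list(thresholds = if (orientation == "lower") -thr else thr,
         sensitivities = sens, specificities = spec,
         auc = auc, auc_ci = ci, orientation = orientation,
         n_pos = m, n_neg = n,
         youden_cutoff = NA_real_, youden_sens = NA_real_,
         youden_spec = NA_real_),
    class = "roc_result")
  yj <- youden_cutoff(res)
  res$youden_cutoff <- yj$cutoff; res$youden_sens <- yj$sens
  res$youden_spec <- yj$spec
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\nYouden cutoff %.1f (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg,
    x$youden_cutoff, 100 * x$youden_sens, 100 * x$youden_spec))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC sweep; ties are
#' broken toward higher sensitivity (a screening index should not miss
#' stenosis). The reported cutoff is the midpoint between adjacent distinct
#' observed scores, so perfectly separated data yield the midpoint of the
#' separating gap.
#'
#' @param r An `roc_result` from [hvsi_roc()].
#' @return List with `cutoff` (score units), `sens`, `spec` (fractions).
#' @export
youden_cutoff <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  j <- r$sensitivities + r$specificities - 1
  cand <- which(j >= max(j) - 1e-12)
  best <- cand[which.max(r$sensitivities[cand])]
  cutoff <- r$thresholds[best]
  if (!is.finite(cutoff)) cutoff <- if (cutoff > 0) 999 else 0
  list(cutoff = cutoff, sens = r$sensitivities[best],
       spec = r$specificities[best])
}

#' Linear association between two record fields
#'
#' Ordinary least-squares fit `y ~ x` with Pearson correlation and its test.
#'
#' @param records Data frame.
#' @param x,y Column names.
#' @return List with `slope`, `intercept`, `r2`, `pearson_r`, `p`, `n`.
#' @export
association <- function(records, x, y) {
  xv <- records[[x]]; yv <- records[[y]]
  if (is.null(xv) || is.null(yv))
    stop("missing column(s): ", paste(setdiff(c(x, y), names(records)),
                                      collapse = ", "), call. = FALSE)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("association needs n >= 3", call. = FALSE)
  if (stats::var(xv) == 0) stop("zero variance in ", x, call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  ct <- stats::cor.test(xv, yv)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = unname(ct$estimate)^2,
       pearson_r = unname(ct$estimate),
       p = ct$p.value, n = length(xv))
}
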