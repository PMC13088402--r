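#' Fit a propensity-score model
#'
#' Logistic regression (fit by iteratively reweighted least squares) of group
#' membership on the matching covariates; returns the per-record probability
#' of being a case. Perfect separation and non-convergence are errors, not
#' silent results.
#'
#' @param records Patient-record data frame with a `group` factor
#'   (control/stenosis) and the covariates.
#' @param covariates Character vector of covariate column names.
#' @return Numeric vector of propensity scores with attribute `model`
#'   (the fitted `glm`).
#' @export
fit_propensity <- function(records, covariates) {
  if (length(unique(records$group)) < 2)
    stop("both groups must be present", call. = FALSE)
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat <- records[, c("group", covariates), drop = FALSE]
  dat$.y <- as.integer(dat$group == "stenosis")
  fml <- stats::reformulate(covariates, response = ".y")
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial()))
  # complete separation drives the deviance to zero; quasi-separation shows
  # as non-convergence of the IRLS iterations
  if (fit$deviance < 1e-4 || !fit$converged) {
    big <- names(which(abs(stats::coef(fit)[-1]) ==
                         max(abs(stats::coef(fit)[-1]))))
    stop("propensity model did not converge (separation suspected in: ",
         paste(big, collapse = ", "), ")", call. = FALSE)
  }
  structure(unname(stats::fitted(fit)), model = fit)
}

smd <- function(x, g) {
  x <- as.numeric(x)
  m1 <- mean(x[g]); m0 <- mean(x[!g])
  s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
  if (s == 0) return(0)
  (m1 - m0) / s
}

#' Greedy 1:1 nearest-neighbor propensity matching
#'
#' Matches each case to the nearest unused control on the logit-propensity
#' scale, processing cases in descending propensity order; pairs farther apart
#' than the caliper are discarded (the case stays unmatched). Equidistant
#' controls break ties toward the lower record id. Deterministic.
#'
#' @param records Patient-record data frame (`id`, `group`).
#' @param scores Propensity scores from [fit_propensity()] (probabilities).
#' @param caliper Maximum |logit difference|; default 0.2 x SD of the logit
#'   scores. `Inf` disables it.
#' @param covariates Optional covariate names for the balance table.
#' @return A `match_result`: `pairs` (case_id, control_id), `unmatched`,
#'   `propensity_scores`, `balance_table` (standardized mean differences
#'   before/after).
#' @export
match_1to1 <- function(records, scores, caliper = NULL, covariates = NULL) {
  stopifnot(length(scores) == nrow(records))
  is_case <- records$group == "stenosis"
  if (!any(is_case) || all(is_case))
    stop("need at least one case and one control", call. = FALSE)
  lp <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  if (is.null(caliper)) caliper <- 0.2 * stats::sd(lp)
  case_idx <- which(is_case)[order(scores[is_case], decreasing = TRUE)]
  ctrl_idx <- which(!is_case)
  used <- logical(length(ctrl_idx))
  pairs <- list()
  for (ci in case_idx) {
    avail <- which(!used)
    if (!length(avail)) break
    d <- abs(lp[ctrl_idx[avail]] - lp[ci])
    best <- avail[d <= min(d) + 1e-12]
    best <- best[which.min(records$id[ctrl_idx[best]])]
    if (min(d) <= caliper) {
      used[best] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(case_id = records$id[ci],
                                       control_id = records$id[ctrl_idx[best]])
    }
  }
  pairs <- if (length(pairs)) as.data.frame(do.call(rbind, pairs))
           else data.frame(case_id = integer(), control_id = integer())
  matched_ids <- c(pairs$case_id, pairs$control_id)
  balance <- NULL
  if (!is.null(covariates)) {
    mi <- records$id %in% matched_ids
    num <- function(v) if (is.factor(v) || is.character(v))
      as.numeric(factor(v)) else as.numeric(v)
    balance <- data.frame(
      covariate = covariates,
      smd_before = vapply(covariates, function(v)
        smd(num(records[[v]]), is_case), numeric(1)),
      smd_after = vapply(covariates, function(v)
        smd(num(records[[v]][mi]), is_case[mi]), numeric(1)),
      row.names = NULL)
  }
  structure(list(pairs = pairs,
                 unmatched = setdiff(records$id, matched_ids),
                 propensity_scores = scores,
                 caliper = caliper,
                 balance_table = balance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs, %d unmatched, caliper %.4f (logit)>\n",
              nrow(x$pairs), length(x$unmatched), x$caliper))
  invisible(x)
}

#' Adjusted odds ratios from multivariable logistic regression
#'
#' Fits `outcome ~ hvsi + covariates` with the score scaled by `hvsi_step`
#' units per odds-ratio step (default 100, i.e. "per 100-unit increase"), and
#' reports Wald 95% confidence intervals. The AVF-type factor uses brachial as
#' the reference level.
#'
#' @param records Patient-record data frame.
#' @param outcome_rule Outcome rule string (e.g. `"group"`, `"fv<400"`) or a
#'   logical vector.
#' @param covariates Adjustment covariate names (may be empty).
#' @param hvsi_step Score units per odds-ratio step.
#' @return An `adjusted_or` result: `terms` data frame (`name`, `odds_ratio`,
#'   `ci_lo`, `ci_hi`, `p`), `outcome_definition`, `hvsi_scaling`, `model`.
#' @export
fit_adjusted_or <- function(records, outcome_rule, covariates = character(),
                            hvsi_step = 100) {
  y <- if (is.logical(outcome_rule)) outcome_rule
       else parse_rule(outcome_rule, records)
  if (!any(y) || all(y)) stop("outcome has a single class", call. = FALSE)
  dat <- records[, intersect(c("hvsi", covariates), names(records)),
                 drop = FALSE]
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat$hvsi_scaled <- records$hvsi / hvsi_step
  dat$hvsi <- NULL
  dat$.y <- as.integer(y)
  if (nrow(dat) <= ncol(dat))
    stop("more model terms than records", call. = FALSE)
  fml <- stats::reformulate(c("hvsi_scaled", covariates), response = ".y")
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial()))
  if (fit$deviance < 1e-4 || !fit$converged)
    stop("logistic model did not converge (separation suspected)",
         call. = FALSE)
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  terms <- data.frame(
    name = sub("^hvsi_scaled$", sprintf("hvsi_per_%g", hvsi_step),
               rownames(sm)[keep]),
    odds_ratio = exp(sm[keep, 1]),
    ci_lo = exp(sm[keep, 1] - stats::qnorm(0.975) * sm[keep, 2]),
    ci_hi = exp(sm[keep, 1] + stats::qnorm(0.975) * sm[keep, 2]),
    p = sm[keep, 4],
    row.names = NULL)
  structure(list(terms = terms,
                 outcome_definition = if (is.logical(outcome_rule))
                   "custom logical" else outcome_rule,
                 hvsi_scaling = hvsi_step,
                 model = fit),
            class = "adjusted_or")
}

#' @export
print.adjusted_or <- function(x, ...) {
  cat(sprintf("Adjusted logistic model (outcome: %s, HVSI per %g units)\n",
              x$outcome_definition, x$hvsi_scaling))
  print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}
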