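# independent oracles used by unit and acceptance tests; these deliberately
# avoid the package's own code paths

# rank-statistic AUC by exhaustive pair counting (ties count 1/2);
# `pos`/`neg` are oriented so that larger values lean positive
auc_pair_count <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# closed-form OLS via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = b[1], slope = b[2])
}

# logistic regression by damped Newton iteration on the log-likelihood
logistic_newton_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- drop(t(X) %*% (y - p))
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# greedy 1:1 nearest-neighbor replay on the logit scale: cases in descending
# propensity order, nearest unused control, lowest-id tie-break, caliper cut
greedy_match_oracle <- function(ids, groups, ps, caliper) {
  lp <- qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
  cases <- ids[groups == "stenosis"]
  cases <- cases[order(ps[match(cases, ids)], decreasing = TRUE)]
  ctrls <- ids[groups == "control"]
  used <- character()
  pairs <- NULL
  for (cid in cases) {
    avail <- setdiff(ctrls, used)
    if (!length(avail)) break
    d <- abs(lp[match(avail, ids)] - lp[match(cid, ids)])
    best <- avail[d <= min(d) + 1e-12]
    best <- min(best)
    if (min(d) <= caliper) {
      used <- c(used, best)
      pairs <- rbind(pairs, data.frame(case_id = cid, control_id = best))
    }
  }
  pairs
}

# pure sine test tone
tone <- function(freq, duration = 5, fs = 4000, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (seq_len(duration * fs) - 1) / fs),
               fs)
}

# minimal patient-record frame for diagnostics tests
toy_records <- function(hvsi, fv = NULL, group = NULL) {
  n <- length(hvsi)
  data.frame(id = seq_len(n), hvsi = hvsi,
             flow_volume = fv %||% rep(600, n),
             resistance_index = rep(0.5, n),
             bifurcation = rep(FALSE, n),
             group = factor(group %||% rep("control", n),
                            levels = c("control", "stenosis")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
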