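# Retained records of a trace: post burn-in; rejection duplicates are kept
# by default (they are part of the MCMC sample), `accepted_only` gives the
# diagnostic accepted-moves view.
retained_records <- function(trace, accepted_only = FALSE) {
  df <- trace[!trace$burnin, , drop = FALSE]
  if (accepted_only) df <- df[which(df$accepted), , drop = FALSE]
  df
}

# Hard-indicator satisfaction of every constraint, per record.
satisfies_all <- function(df, specs) {
  ok <- rep(TRUE, nrow(df))
  for (s in specs) {
    yj <- df[[paste0("y_", s$statistic)]]
    if (is.null(yj)) stop("trace lacks column y_", s$statistic)
    v <- switch(s$direction,
                LE = yj <= s$threshold,
                GE = yj >= s$threshold,
                INTERVAL = yj >= s$threshold[1] & yj <= s$threshold[2])
    ok <- ok & v
  }
  ok
}

#' Posterior-predictive summary of a trace statistic
#'
#' Mean, median, and mode of one simulator statistic over the retained
#' (post burn-in) records, together with the probability of improvement
#' `p_improve`: the fraction of retained records whose statistics satisfy
#' every constraint as a hard indicator, regardless of the (possibly
#' soft) kernels used during sampling — violating samples can always be
#' discarded in the analysis.  The mode is the maximizer of a Gaussian
#' kernel density (Silverman bandwidth) on a 512-point grid over the
#' sample range.
#'
#' @param trace a `pope_trace`.
#' @param statistic index of the statistic to summarize.
#' @param specs list of [constraint_spec()] defining `p_improve`.
#' @param accepted_only diagnostic view using only accepted moves.
#' @return a `posterior_summary` list with `mean`, `median`, `mode`,
#'   `p_improve`, `n_samples`.
#' @export
posterior_predictive_summary <- function(trace, statistic = 1, specs,
                                         accepted_only = FALSE) {
  df <- retained_records(trace, accepted_only)
  if (nrow(df) == 0) stop("no retained records after the burn-in filter")
  y <- df[[paste0("y_", statistic)]]
  if (is.null(y)) stop("trace lacks column y_", statistic)
  mode <- if (length(unique(y)) > 1) {
    dens <- stats::density(y, bw = "nrd0", n = 512, from = min(y),
                           to = max(y))
    dens$x[which.max(dens$y)]
  } else y[1]
  structure(list(mean = mean(y), median = stats::median(y), mode = mode,
                 p_improve = mean(satisfies_all(df, specs)),
                 n_samples = length(y)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior predictive> mean %.4g | median %.4g | mode %.4g | P(improve) %.3f | n = %d\n",
              x$mean, x$median, x$mode, x$p_improve, x$n_samples))
  invisible(x)
}

#' Condition a trace on the value of a statistic
#'
#' Returns the sub-trace of retained records where statistic `j` equals
#' `value` — exactly for integer-valued statistics, within `tol`
#' otherwise.  Conditioning on the spot count, for instance, splits the
#' posterior into its per-pattern mixture components.
#'
#' @param trace a `pope_trace`.
#' @param statistic statistic index.
#' @param value value to condition on.
#' @param tol half-width of the matching window for real-valued
#'   statistics (0 means exact matching).
#' @return the matching sub-trace; empty (zero rows) with attribute
#'   `empty = TRUE` when the value never occurs.
#' @export
condition_on_statistic <- function(trace, statistic, value, tol = 0) {
  df <- retained_records(trace)
  y <- df[[paste0("y_", statistic)]]
  if (is.null(y)) stop("trace lacks column y_", statistic)
  keep <- if (tol > 0) abs(y - value) <= tol else y == value
  out <- df[which(keep), , drop = FALSE]
  attr(out, "empty") <- nrow(out) == 0
  out
}

#' Mixture weights of an integer-valued statistic
#'
#' Normalized empirical frequencies of the observed values of statistic
#' `j` in the retained trace: the weights of the constraint-conditional
#' mixture (e.g. the posterior split over spot counts).
#'
#' @inheritParams condition_on_statistic
#' @return named numeric vector of weights summing to one.
#' @export
#' @examples
#' # counts 505/185/310 over values 2/3/4 give weights .505/.185/.310
mixture_weights <- function(trace, statistic) {
  df <- retained_records(trace)
  if (nrow(df) == 0) stop("empty trace: no retained records")
  y <- df[[paste0("y_", statistic)]]
  if (is.null(y)) stop("trace lacks column y_", statistic)
  tab <- table(y)
  w <- as.numeric(tab) / length(y)
  names(w) <- names(tab)
  w
}

#' Joint input-output posterior sample
#'
#' Aligned `(theta_d, y_j)` pairs from the retained records, preserving
#' record order — the raw material of joint input-output density plots.
#'
#' @param trace a `pope_trace`.
#' @param parameter parameter column name or index.
#' @param statistic statistic index.
#' @return data frame with columns `theta` and `y` (one row per retained
#'   record).
#' @export
joint_posterior_table <- function(trace, parameter, statistic) {
  df <- retained_records(trace)
  pcols <- setdiff(colnames(df),
                   c("iteration", "log_lik", "accepted", "burnin",
                     grep("^(y|eps|thr)_", colnames(df), value = TRUE)))
  pcol <- if (is.numeric(parameter)) pcols[parameter] else parameter
  if (is.na(pcol) || !pcol %in% colnames(df))
    stop("unknown parameter: ", parameter)
  ycol <- paste0("y_", statistic)
  if (!ycol %in% colnames(df)) stop("trace lacks column ", ycol)
  data.frame(theta = df[[pcol]], y = df[[ycol]])
}
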