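#' Likelihood-ratio statistic from two deviances
#'
#' The LR statistic of a nested reduction is the deviance difference
#' `dev_sub - dev_full` (deviance being twice the minimized negative log
#' likelihood, constants cancelling).  A negative value beyond numerical
#' tolerance indicates an optimisation failure in the larger model and
#' triggers a warning.
#'
#' @param dev_sub deviance of the restricted (sub) model
#' @param dev_full deviance of the more general model
#' @param tol tolerance for slightly negative statistics
#' @return non-negative chi-squared statistic
#' @export
lr_statistic <- function(dev_sub, dev_full, tol = 1e-4) {
  chisq <- dev_sub - dev_full
  if (chisq < -tol)
    warning("negative LR statistic (", format(chisq),
            "): the general model appears under-optimised")
  chisq
}

#' Upper-tail chi-squared probability
#'
#' @param chisq non-negative statistic
#' @param df positive integer degrees of freedom
#' @return `P(X >= chisq)` for `X ~ chi-squared(df)`
#' @export
chisq_pvalue <- function(chisq, df) {
  if (any(df < 1) || any(df != round(df))) stop("'df' must be a positive integer")
  if (any(chisq < 0)) stop("'chisq' must be non-negative")
  stats::pchisq(chisq, df = df, lower.tail = FALSE)
}

#' Hierarchical likelihood-ratio model comparison
#'
#' Builds a comparison table for a sequence of fits ordered from the most
#' general to the most restricted model, following the nested hierarchy
#' (`SS2`/`SS3`/`SS4` each against `SS1`; `*2`, `*3`, `*4` each against the
#' previous member for the joint families).  Each row reports the deviance
#' difference against its reference model, the difference in free
#' covariance parameters, and the chi-squared tail probability.  Under the
#' nested testing procedure a reduction that follows a rejected one cannot
#' be interpreted, and is flagged in the `note` column.
#'
#' @param fits list of [lgcp_fit()] objects ordered general to restricted,
#'   or a data frame with columns `model`, `total_df`, `deviance` (e.g.
#'   published values)
#' @param alpha rejection level used for flagging downstream reductions
#' @return data frame of class `lgcp_comparison` with columns `model`,
#'   `total_df`, `deviance`, `chisq`, `df`, `p_value`, `note`
#' @export
lgcp_compare <- function(fits, alpha = 0.05) {
  if (is.data.frame(fits)) {
    tab <- fits
    req <- c("model", "total_df", "deviance")
    if (!all(req %in% names(tab)))
      stop("data-frame input needs columns ", paste(req, collapse = ", "))
  } else {
    if (!all(vapply(fits, inherits, TRUE, "lgcp_fit")))
      stop("'fits' must be lgcp_fit objects or a data frame")
    tab <- data.frame(
      model = vapply(fits, function(f) f$spec$family, ""),
      total_df = vapply(fits, function(f) f$total_df, 0L),
      deviance = vapply(fits, function(f) f$deviance, 0)
    )
  }
  n <- nrow(tab)
  if (n < 2L) stop("need at least two models to compare")
  out <- data.frame(tab, chisq = NA_real_, df = NA_integer_,
                    p_value = NA_real_, note = "")
  rejected <- FALSE
  for (i in 2:n) {
    ref <- NA_integer_
    for (j in (i - 1):1)
      if (is_nested(tab$model[i], tab$model[j])) { ref <- j; break }
    if (is.na(ref))
      stop("model ", tab$model[i], " is not nested in any preceding model")
    out$chisq[i] <- lr_statistic(tab$deviance[i], tab$deviance[ref])
    out$df[i] <- tab$total_df[ref] - tab$total_df[i]
    if (out$df[i] <= 0) stop("improper reduction: no parameters removed")
    out$p_value[i] <- chisq_pvalue(max(out$chisq[i], 0), out$df[i])
    if (rejected) out$note[i] <- "untestable (earlier reduction rejected)"
    else if (out$p_value[i] < alpha) {
      out$note[i] <- "rejected"
      rejected <- TRUE
    }
  }
  class(out) <- c("lgcp_comparison", "data.frame")
  out
}

#' @export
print.lgcp_comparison <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$deviance <- sprintf("%.2f", y$deviance)
  y$chisq <- ifelse(is.na(y$chisq), "", sprintf("%.2f", y$chisq))
  y$df <- ifelse(is.na(y$df), "", y$df)
  y$p_value <- ifelse(is.na(y$p_value), "",
                      sprintf(paste0("%.", digits, "f"), y$p_value))
  names(y) <- c("Model", "Tot Df", "Deviance", "Chisq", "Df", "Pr(>Chisq)",
                "Note")
  print(y, row.names = FALSE, right = TRUE)
  invisible(x)
}
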