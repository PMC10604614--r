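#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile()` type 7) by default; `type = 2` gives the
#' Tukey-hinge-style convention.
#'
#' @param x Non-empty numeric vector.
#' @param type Quantile type passed to [stats::quantile()].
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x, type = 7) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("`x` is empty", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' @noRd
test_result <- function(statistic, p_value, method, n_per_group) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n_per_group = n_per_group),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of a continuous variable between two groups: exact
#' enumeration when the combined sample is small (`nA + nB <= 12`) and free
#' of ties, otherwise the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A `test_result` with the U statistic (for group `a`).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  use_exact <- (length(a) + length(b) <= 12L) &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  test_result(
    statistic = wt$statistic,
    p_value = wt$p.value,
    method = if (use_exact) "Mann-Whitney U (exact)"
             else "Mann-Whitney U (normal approximation)",
    n_per_group = c(length(a), length(b))
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param continuity_correction Apply Yates correction (default `FALSE`,
#'   plain Pearson statistic).
#' @return A `test_result` (df = 1).
#' @examples
#' chi_square_2x2(matrix(c(4, 1, 7, 30), nrow = 2))
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be 2x2", call. = FALSE)
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = continuity_correction)
  )
  test_result(
    statistic = ct$statistic,
    p_value = ct$p.value,
    method = if (continuity_correction) {
      "Pearson chi-square (Yates-corrected)"
    } else {
      "Pearson chi-square"
    },
    n_per_group = rowSums(table)
  )
}

#' ROC curve, AUC and confidence interval
#'
#' AUC via the Mann-Whitney/trapezoidal identity with a 95% confidence
#' interval by the DeLong method (default) or the Hanley-McNeil formula.
#' The score direction is fixed so that cases are expected to score higher;
#' an AUC below 0.5 therefore reports genuine anti-discrimination rather
#' than being silently flipped.
#'
#' @param scores Numeric scores (e.g. dd-cfDNA%).
#' @param labels Binary outcome (logical, or coercible 0/1); both classes
#'   must be present.
#' @param ci_method `"delong"` or `"hanley"`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc_ci <- function(scores, labels, ci_method = c("delong", "hanley"),
                       conf = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  resp <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(resp, scores, levels = c("neg", "pos"), direction = "<",
                 quiet = TRUE)
  auc <- as.numeric(r$auc)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (ci_method == "delong") {
    ci <- as.numeric(suppressWarnings(
      pROC::ci.auc(r, conf.level = conf, method = "delong")
    ))
    ci_low <- ci[1L]
    ci_high <- ci[3L]
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                  (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci_low <- max(0, auc - z * se)
    ci_high <- min(1, auc + z * se)
  }
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  structure(
    list(auc = auc, ci_low = ci_low, ci_high = ci_high,
         n_pos = n_pos, n_neg = n_neg, curve = curve,
         ci_method = ci_method),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.1f%% (95%%CI %.1f-%.1f, %s; %d cases / %d controls)\n",
    100 * x$auc, 100 * x$ci_low, 100 * x$ci_high, x$ci_method,
    x$n_pos, x$n_neg
  ))
  invisible(x)
}

# Firth-penalized logistic regression via modified-score IRLS.
#' @noRd
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  Iinv <- NULL
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    Iinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(Iinv)) {
      stop("information matrix is singular; fit is not identifiable",
           call. = FALSE)
    }
    h <- rowSums((X %*% Iinv) * X) * w  # leverages of the weighted fit
    score <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(Iinv %*% score)
    # damp absurd steps near separation
    if (max(abs(delta)) > 5) {
      delta <- delta * 5 / max(abs(delta))
    }
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, se = sqrt(diag(Iinv)), converged = converged)
}

#' Covariate-adjusted association with an elevated dd-cfDNA result
#'
#' Fits a Firth-penalized logistic regression of a binary outcome on the
#' elevated-result flag plus one covariate (typically eGFR) and reports the
#' exposure effect as an odds ratio with a Wald confidence interval. The
#' penalty keeps the fit finite under the quasi-separation that small
#' transplant cohorts routinely produce. This is an association analogue,
#' not a hazard model: no follow-up time enters.
#'
#' @param outcome Binary outcome vector (logical or 0/1), not constant.
#' @param exposure Binary exposure (e.g. dd-cfDNA >= 1.0%).
#' @param covariate Numeric covariate, e.g. eGFR (mL/min/1.73 m2).
#' @param conf Confidence level (default 0.95).
#' @return List of class `association_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `beta`, `se`, `converged`, `method`.
#' @export
adjusted_association <- function(outcome, exposure, covariate, conf = 0.95) {
  y <- as.numeric(as.logical(outcome))
  x <- as.numeric(as.logical(exposure))
  z <- as.numeric(covariate)
  keep <- stats::complete.cases(y, x, z)
  y <- y[keep]; x <- x[keep]; z <- z[keep]
  if (length(y) < 10L) {
    stop("at least 10 complete observations are required", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; association is undefined", call. = FALSE)
  }
  X <- cbind(intercept = 1, exposure = x, covariate = z)
  fit <- firth_logistic(X, y)
  if (!fit$converged) {
    warning("Firth fit did not converge; estimates may be unstable",
            call. = FALSE)
  }
  b <- fit$beta[2L]
  se <- fit$se[2L]
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(
      odds_ratio = exp(b),
      ci_low = exp(b - zq * se),
      ci_high = exp(b + zq * se),
      p_value = 2 * stats::pnorm(-abs(b / se)),
      beta = b, se = se, converged = fit$converged,
      method = "Firth-penalized logistic regression (association analogue)"
    ),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> OR %.2f (95%%CI %.2f-%.2f), p = %.3f [%s]\n",
    x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$method
  ))
  invisible(x)
}

#' @noRd
fmt_median_iqr <- function(x, digits = 1) {
  m <- median_iqr(x)
  sprintf("%.*f [%.*f-%.*f]", digits, m$median, digits, m$q1, digits, m$q3)
}

#' Group-comparison table at a dd-cfDNA cutoff
#'
#' Splits patients at the cutoff and compares each variable between the
#' elevated and non-elevated groups: continuous variables with the
#' Mann-Whitney U test (summarised as median \[IQR\]), binary variables
#' with the uncorrected Pearson chi-square on the 2x2 table (summarised as
#' percentages).
#'
#' @param data Per-patient `data.frame`.
#' @param variables Character vector of column names to compare; defaults
#'   to every column except `patient_id` and the score column. Logical
#'   columns are treated as binary, numeric as continuous.
#' @param score_col Column holding the dd-cfDNA percentage.
#' @param cutoff Cutoff in percent (default 1.0, inclusive for elevated).
#' @param digits Digits for continuous summaries.
#' @return A `data.frame` of class `group_comparison` with columns
#'   `variable`, `overall`, `elevated`, `not_elevated`, `p_value`, `test`;
#'   group sizes are stored in the `group_n` attribute and shown by the
#'   print method as "(n = K)" headers.
#' @export
build_group_comparison <- function(data, variables = NULL,
                                   score_col = "dd_fraction_percent",
                                   cutoff = 1.0, digits = 1) {
  if (!score_col %in% names(data)) {
    stop(sprintf("score column '%s' is missing", score_col), call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), c("patient_id", score_col))
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    stop(sprintf("variable(s) missing from data: %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  }
  hi <- classify_cutoff(data[[score_col]], cutoff) == "elevated"
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.logical(x)) {
      tab <- matrix(
        c(sum(x[hi]), sum(x[!hi]), sum(!x[hi]), sum(!x[!hi])),
        nrow = 2L
      )
      p <- tryCatch(chi_square_2x2(tab)$p_value, error = function(e) NA_real_)
      data.frame(
        variable = v,
        overall = sprintf("%.1f%%", 100 * mean(x)),
        elevated = sprintf("%.1f%%", 100 * mean(x[hi])),
        not_elevated = sprintf("%.1f%%", 100 * mean(x[!hi])),
        p_value = p,
        test = "chi-square",
        stringsAsFactors = FALSE
      )
    } else {
      p <- tryCatch(mann_whitney(x[hi], x[!hi])$p_value,
                    error = function(e) NA_real_)
      data.frame(
        variable = v,
        overall = fmt_median_iqr(x, digits),
        elevated = fmt_median_iqr(x[hi], digits),
        not_elevated = fmt_median_iqr(x[!hi], digits),
        p_value = p,
        test = "Mann-Whitney",
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "group_n") <- c(total = length(hi), elevated = sum(hi),
                            not_elevated = sum(!hi))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  n <- attr(x, "group_n")
  cat(sprintf(
    "Group comparison at dd-cfDNA >= %.1f%%: total (n = %d), elevated (n = %d), not elevated (n = %d)\n",
    attr(x, "cutoff"), n["total"], n["elevated"], n["not_elevated"]
  ))
  df <- as.data.frame(x)
  df$p_value <- ifelse(is.na(df$p_value), "-", sprintf("%.3f", df$p_value))
  print(df, row.names = FALSE)
  invisible(x)
}
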