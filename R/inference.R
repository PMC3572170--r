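.model_terms <- c("g", "x_acquaintance", "x_friend", "x_best_friend")

# Students with no neighbours at a tier have NA x under the "exclude"
# policy; the regression keeps them with x = 0 (no neighbours, no
# environment pull) rather than discarding the whole row, and says so.
# Rows with NA g or y are dropped.
.model_frame <- function(scores, terms = .model_terms) {
  stopifnot(is.data.frame(scores), all(c(terms, "y") %in% names(scores)))
  d <- scores[, c("y", terms), drop = FALSE]
  x_terms <- grep("^x_", terms, value = TRUE)
  n_na <- sum(is.na(d[x_terms]))
  if (n_na > 0) {
    warning(n_na, " missing environment score(s) treated as x = 0 in the regression")
    d[x_terms] <- lapply(d[x_terms], function(v) ifelse(is.na(v), 0, v))
  }
  keep <- stats::complete.cases(d)
  if (!any(keep)) stop("no complete cases in the score table")
  d[keep, , drop = FALSE]
}

.check_full_rank <- function(d, terms) {
  X <- as.matrix(cbind(`(Intercept)` = 1, d[, terms, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
}

#' Fit the four-predictor academic-progress regression
#'
#' Ordinary least squares of progress y on the student's own ranking g and
#' the three tier environment scores:
#' y = b0 + b_g g + b_xa x_acquaintance + b_xf x_friend + b_xb x_best_friend.
#' The own-ranking term g is included because x and y are inherently
#' coupled through it: a student ranked low has both high x (most
#' classmates outrank them) and more room to rise.
#'
#' @param scores Score table from [score_table()] (columns `g`,
#'   `x_acquaintance`, `x_friend`, `x_best_friend`, `y`); rows with any
#'   `NA` are dropped.
#' @return An object of class `progress_fit`: list with `coefficients`
#'   (named `beta0`, `beta_g`, `beta_xa`, `beta_xf`, `beta_xb`),
#'   `residuals`, `rss`, `n`, `equation` (formatted model string) and the
#'   underlying `lm` fit.
#' @export
fit_progress_model <- function(scores) {
  d <- .model_frame(scores)
  if (nrow(d) < 6L) stop("need at least 6 complete rows to fit 5 parameters")
  .check_full_rank(d, .model_terms)
  fit <- stats::lm(y ~ g + x_acquaintance + x_friend + x_best_friend, data = d)
  beta <- stats::coef(fit)
  names(beta) <- c("beta0", "beta_g", "beta_xa", "beta_xf", "beta_xb")
  eq <- sprintf("y = %s + %s g + %s x_acquaintance + %s x_friend + %s x_best_friend",
                signif(beta[1], 6), signif(beta[2], 6), signif(beta[3], 6),
                signif(beta[4], 6), signif(beta[5], 6))
  structure(list(coefficients = beta,
                 residuals = stats::residuals(fit),
                 rss = sum(stats::residuals(fit)^2),
                 n = nrow(d),
                 equation = gsub("\\+ -", "- ", eq),
                 lm = fit),
            class = "progress_fit")
}

#' @export
print.progress_fit <- function(x, ...) {
  cat("Progress regression (n =", x$n, ")\n ", x$equation, "\n")
  cat("  RSS:", format(x$rss), "\n")
  invisible(x)
}

#' Sequential (Type I) ANOVA of the progress regression
#'
#' Decomposes the total sum of squares of y into one-degree-of-freedom
#' contributions of the predictors added in a fixed order, plus an error
#' row. The sum of squares of the k-th term is the drop in residual sum of
#' squares when that term joins a model already containing the preceding
#' terms and the intercept; F is the term mean square over the error mean
#' square and p its upper F tail with (1, error DF) degrees of freedom.
#' Term sums of squares and the error sum of squares add up to the total
#' (corrected) sum of squares.
#'
#' @param scores Score table (see [fit_progress_model()]).
#' @param term_order Character vector ordering the predictors; defaults to
#'   own ranking first, then the environment scores from weakest to
#'   strongest tie.
#' @return A `data.frame` of class `sequential_anova_table` with columns
#'   `term`, `DF`, `SS`, `MS`, `F`, `p`, including `Error` and `Total`
#'   rows (whose `F`/`p` are `NA`).
#' @export
sequential_anova <- function(scores, term_order = .model_terms) {
  stopifnot(is.character(term_order), length(term_order) >= 1,
            !anyDuplicated(term_order))
  d <- .model_frame(scores, term_order)
  if (nrow(d) < length(term_order) + 2L) stop("too few rows for the requested terms")
  .check_full_rank(d, term_order)
  form <- stats::reformulate(term_order, response = "y")
  fit <- stats::lm(form, data = d)
  a <- stats::anova(fit)
  terms_idx <- seq_along(term_order)
  err <- which(rownames(a) == "Residuals")
  ss_terms <- a$`Sum Sq`[terms_idx]
  out <- data.frame(
    term = c(term_order, "Error", "Total"),
    DF = c(a$Df[terms_idx], a$Df[err], nrow(d) - 1L),
    SS = c(ss_terms, a$`Sum Sq`[err], sum(a$`Sum Sq`)),
    MS = c(a$`Mean Sq`[terms_idx], a$`Mean Sq`[err], NA_real_),
    F = c(a$`F value`[terms_idx], NA_real_, NA_real_),
    p = c(a$`Pr(>F)`[terms_idx], NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sequential_anova_table", "data.frame")
  attr(out, "n") <- nrow(d)
  out
}

.p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", "")))
}

#' @export
print.sequential_anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 6)
  df$MS <- signif(df$MS, 6)
  df$F <- signif(df$F, 6)
  df$sig <- .p_stars(df$p)
  df$p <- signif(df$p, 6)
  print.data.frame(df, row.names = FALSE, na.print = "")
  cat("---\nSignif.: '*' p<0.05, '***' p<0.001\n")
  invisible(x)
}

#' Pearson correlation between two series
#'
#' Product-moment correlation with pairwise deletion of missing values.
#' Errors (rather than returning `NA`) when either series is constant,
#' since the correlation is then undefined.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Object of class `correlation_result`: list with `r` and `n`
#'   (number of complete pairs used).
#' @export
pearson_r <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("series lengths differ")
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant series")
  }
  structure(list(r = stats::cor(a, b), n = length(a)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d)\n", x$r, x$n))
  invisible(x)
}
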