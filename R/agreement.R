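#' Two-way mixed-effects intraclass correlation
#'
#' Single-rater ICC from the two-way ANOVA decomposition of a complete
#' subjects x raters matrix, with 95% confidence bounds from the exact
#' F-distribution formulas. Two variants are available: `"consistency"`
#' (rater main effects excluded from the error term; insensitive to a
#' constant shift of any rater) and `"absolute"` (agreement in absolute
#' value; rater effects penalize the coefficient).
#'
#' @param table Numeric matrix or data frame, subjects in rows and raters in
#'   columns, no missing cells, at least 2 x 2.
#' @param agreement_type `"consistency"` (default) or `"absolute"`.
#' @param conf_level Confidence level of the interval.
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high` (raw),
#'   `ci_low_clipped` (negative lower bound clipped at 0, the usual display
#'   convention), `model_label`, `F`, `df1`, `df2`, `p_value`.
#' @export
icc_two_way <- function(table, agreement_type = c("consistency", "absolute"),
                        conf_level = 0.95) {
  agreement_type <- match.arg(agreement_type)
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("rater table must be numeric")
  if (anyNA(x)) stop("rater table has missing cells; ICC needs a complete matrix")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (stats::sd(as.vector(x)) == 0)
    stop("ICC undefined: no between-subject variance in the rater table")

  gm <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (agreement_type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      fv <- Inf; lo <- 1; hi <- 1; p <- 0
    } else {
      fv <- msr / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- fv / stats::qf(1 - alpha / 2, df1, df2)
      fu <- fv * stats::qf(1 - alpha / 2, df2, df1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
      p <- stats::pf(fv, df1, df2, lower.tail = FALSE)
    }
    label <- "two-way mixed effects, consistency, single rater"
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse == 0 && msc == 0) {
      fv <- Inf; lo <- 1; hi <- 1; p <- 0
    } else {
      fv <- msr / mse
      # Satterthwaite df for the absolute-agreement interval
      fj <- msc / mse
      vn <- (k - 1) * (n - 1) *
        (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
      vd <- (n - 1) * k^2 * icc^2 * fj^2 +
        (n * (1 + (k - 1) * icc) - k * icc)^2
      v <- vn / vd
      fu_star <- stats::qf(1 - alpha / 2, n - 1, v)
      fl_star <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fu_star * mse) /
        (fu_star * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fl_star * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fl_star * msr)
      p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    }
    label <- "two-way mixed effects, absolute agreement, single rater"
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 ci_low_clipped = max(0, lo),
                 model_label = label, F = fv,
                 df1 = n - 1, df2 = (n - 1) * (k - 1), p_value = p,
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (95%% CI, %.2f-%.2f)  [%s]\n",
              x$icc, x$ci_low_clipped, x$ci_high, x$model_label))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g; %d subjects x %d raters\n",
              x$df1, x$df2, x$F, x$p_value, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Pearson correlation between two score lists
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform (wraps [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return List with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for a constant score list")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Ordinary least-squares fit of one score list on another
#'
#' @param x Predictor scores (e.g. algorithm estimates).
#' @param y Response scores (e.g. a pathologist's estimates).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("least squares undefined for constant x")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(y) == 0) 0 else unname(stats::cor(x, y))^2
  list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2)
}

#' Count subjects with clinically discrepant scores around a threshold
#'
#' A subject (image or slide) is counted when at least one rater scores it
#' strictly above the threshold and at least one scores it at or below — the
#' situation in which the accept/decline decision depends on which rater is
#' asked. The conventional transplant cutoff is 30% macrosteatosis.
#'
#' @param table Numeric matrix/data frame, subjects x raters.
#' @param threshold_percent Decision threshold on the 0-100 scale.
#' @return Integer count of discrepant subjects.
#' @export
threshold_disagreement_count <- function(table, threshold_percent = 30) {
  x <- as.matrix(table)
  if (ncol(x) < 2L) stop("need at least 2 raters")
  above <- x > threshold_percent
  sum(apply(above, 1L, function(a) any(a) && !all(a)))
}

#' Read a rater table from CSV
#'
#' First column: subject identifier; remaining columns: one percent-estimate
#' column per rater. Missing cells are reported by position.
#'
#' @param path CSV path.
#' @return Numeric matrix with subject ids as row names.
#' @export
read_rater_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("rater CSV needs a subject column plus >= 2 raters")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing cell(s) in rater table: ",
         paste(sprintf("subject '%s' rater '%s'",
                       rownames(m)[bad[, 1]], colnames(m)[bad[, 2]]),
               collapse = "; "))
  }
  m
}

#' Packaged control-image estimate table
#'
#' Ten manually generated control images were scored by the pixel-counting
#' algorithm and by three expert liver pathologists, each giving a strict
#' (area-ratio) and a gestalt estimate. This fixture ships with the package
#' and drives the agreement analyses.
#'
#' @return Data frame with columns `image`, `algorithm`, and
#'   `LP<i>_strict` / `LP<i>_gestalt` for i = 1..3.
#' @export
lp_estimates_table <- function() {
  path <- system.file("extdata", "control_image_estimates.csv",
                      package = "steatoscope", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
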