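#' Pearson correlation between estimates and references
#'
#' Thin wrapper over the product-moment correlation that turns the
#' degenerate zero-variance case into an explicit error instead of an
#' `NA`: a constant estimator has no defined correlation with anything.
#'
#' @param est,ref equal-length numeric vectors (length >= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("est and ref must have equal length", call. = FALSE)
  }
  if (length(est) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(est) == 0 || stats::sd(ref) == 0) {
    stop("correlation is undefined for a zero-variance input", call. = FALSE)
  }
  stats::cor(est, ref)
}

#' Signed mean error, error SD and mean absolute error
#'
#' Errors are `est - ref`. The SD uses the sample (n-1) convention.
#'
#' @param est,ref equal-length numeric vectors (length >= 2).
#' @return list with `me`, `sd`, `mae`, all in the units of the inputs.
#' @export
error_stats <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("est and ref must have equal length", call. = FALSE)
  }
  if (length(est) < 2L) stop("need at least 2 pairs", call. = FALSE)
  e <- est - ref
  list(me = mean(e), sd = stats::sd(e), mae = mean(abs(e)))
}

#' AAMI-style mean-error / SD check
#'
#' Passes when the absolute mean error and the error SD are both within
#' the configured thresholds (inclusive boundaries). The default
#' thresholds, |ME| <= 5 mmHg and SD <= 8 mmHg, follow the AAMI
#' sphygmomanometer standard; they are parameters, not constants.
#'
#' @param me signed mean error (mmHg).
#' @param sd error standard deviation (mmHg).
#' @param thresholds numeric pair `c(me_max, sd_max)`.
#' @return logical pass flag.
#' @export
aami_check <- function(me, sd, thresholds = c(5, 8)) {
  stopifnot(is.finite(me), is.finite(sd))
  abs(me) <= thresholds[1] && sd <= thresholds[2]
}

default_bhs_table <- function() {
  rbind(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
}

#' BHS-style cumulative-percentage grading
#'
#' Computes the percentage of absolute errors within each band (5, 10,
#' 15 mmHg by default) and assigns the best letter grade whose three
#' cutoffs are all met. The default grade table is the British
#' Hypertension Society protocol: A = (60, 85, 95), B = (50, 75, 90),
#' C = (40, 65, 85), else D. Both bands and table are configurable.
#'
#' @param errors numeric vector of signed errors in mmHg (non-empty).
#' @param bands increasing absolute-error bands in mmHg.
#' @param grade_table matrix with one row per letter grade (rownames) and
#'   one cumulative-percentage cutoff per band.
#' @return list with `percentages` (named by band) and `grade` (single
#'   letter, `"D"` when no row is met).
#' @export
bhs_grade <- function(errors, bands = c(5, 10, 15),
                      grade_table = default_bhs_table()) {
  if (!length(errors)) stop("empty error list", call. = FALSE)
  stopifnot(ncol(grade_table) == length(bands))
  pct <- vapply(bands, function(b) 100 * mean(abs(errors) <= b), numeric(1))
  names(pct) <- paste0("within_", bands)
  grade <- "D"
  for (g in rownames(grade_table)) {
    if (all(pct >= grade_table[g, ])) { grade <- g; break }
  }
  list(percentages = pct, grade = grade)
}

#' Bland-Altman agreement summary
#'
#' @param est,ref equal-length numeric vectors (length >= 2).
#' @return list with `bias` (mean difference) and `lower`/`upper` 95%
#'   limits of agreement (`bias +- 1.96 * sd(differences)`).
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("est and ref must have equal length", call. = FALSE)
  }
  if (length(est) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- est - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

eval_channel <- function(est, ref, aami_thresholds, bhs_bands, bhs_table) {
  es <- error_stats(est, ref)
  r <- tryCatch(pearson_r(est, ref), error = function(e) NA_real_)
  bhs <- bhs_grade(est - ref, bands = bhs_bands, grade_table = bhs_table)
  list(
    pearson_r = r,
    degenerate = is.na(r),
    me = es$me, sd = es$sd, mae = es$mae,
    aami_pass = aami_check(es$me, es$sd, aami_thresholds),
    bhs = bhs,
    bland_altman = bland_altman(est, ref)
  )
}

#' Evaluate paired BP estimates against references
#'
#' Lower-level companion of [evaluate_model()] taking estimates that are
#' already computed — from the network, an oracle, or any other estimator.
#'
#' @param est_sbp,ref_sbp,est_dbp,ref_dbp equal-length numeric vectors in
#'   mmHg.
#' @param aami_thresholds,bhs_bands,bhs_table threshold configuration, see
#'   [aami_check()] and [bhs_grade()].
#' @return an object of class `eval_report`.
#' @export
evaluate_pairs <- function(est_sbp, ref_sbp, est_dbp, ref_dbp,
                           aami_thresholds = c(5, 8),
                           bhs_bands = c(5, 10, 15),
                           bhs_table = default_bhs_table()) {
  structure(list(
    n = length(est_sbp),
    sbp = eval_channel(est_sbp, ref_sbp, aami_thresholds, bhs_bands, bhs_table),
    dbp = eval_channel(est_dbp, ref_dbp, aami_thresholds, bhs_bands, bhs_table),
    pairs = data.frame(est_sbp = est_sbp, ref_sbp = ref_sbp,
                       est_dbp = est_dbp, ref_dbp = ref_dbp)
  ), class = "eval_report")
}

#' Evaluate a trained model on labeled frames
#'
#' Runs [predict.bp_cnn()] on the valid frames, then summarizes each
#' pressure channel with correlation, error statistics, the AAMI-style
#' check, BHS-style grading and a Bland-Altman analysis. A constant
#' (degenerate) estimator is flagged rather than reported with a
#' meaningless correlation.
#'
#' @param model a trained `bp_cnn`.
#' @param frames a labeled `frame_set`.
#' @param aami_thresholds,bhs_bands,bhs_table threshold configuration, see
#'   [aami_check()] and [bhs_grade()].
#' @return an object of class `eval_report` with fields `n`, `sbp`, `dbp`
#'   (per-channel summaries), and the paired values under `pairs`.
#' @export
evaluate_model <- function(model, frames, aami_thresholds = c(5, 8),
                           bhs_bands = c(5, 10, 15),
                           bhs_table = default_bhs_table()) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(frames$labels)) {
    stop("frames carry no labels; run label_frames() first", call. = FALSE)
  }
  keep <- frames$labels$valid
  if (!any(keep)) stop("no valid labeled frames to evaluate on", call. = FALSE)
  pred <- stats::predict(model, frames$ecg[keep, , drop = FALSE])
  evaluate_pairs(pred$sbp, frames$labels$sbp[keep],
                 pred$dbp, frames$labels$dbp[keep],
                 aami_thresholds = aami_thresholds, bhs_bands = bhs_bands,
                 bhs_table = bhs_table)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d frame pairs\n", x$n))
  for (ch in c("sbp", "dbp")) {
    s <- x[[ch]]
    cat(sprintf(
      "  %s: r = %s, ME = %.2f, SD = %.2f, MAE = %.2f mmHg | AAMI %s | BHS %s (%.0f/%.0f/%.0f%%)\n",
      toupper(ch),
      if (s$degenerate) "undefined (degenerate estimator)" else sprintf("%.3f", s$pearson_r),
      s$me, s$sd, s$mae,
      if (s$aami_pass) "pass" else "fail", s$bhs$grade,
      s$bhs$percentages[1], s$bhs$percentages[2], s$bhs$percentages[3]))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes the scalar summary (not the raw pairs) with stable field order,
#' so identical reports produce byte-identical files.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @param include_pairs also embed the paired estimates/references.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, include_pairs = FALSE) {
  stopifnot(inherits(report, "eval_report"))
  strip <- function(ch) list(
    pearson_r = ch$pearson_r, degenerate = ch$degenerate,
    me = ch$me, sd = ch$sd, mae = ch$mae, aami_pass = ch$aami_pass,
    bhs_grade = ch$bhs$grade,
    bhs_percentages = as.list(ch$bhs$percentages),
    bland_altman = ch$bland_altman
  )
  out <- list(n = report$n, sbp = strip(report$sbp), dbp = strip(report$dbp))
  if (include_pairs) out$pairs <- report$pairs
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Scatter and Bland-Altman plots for an evaluation report
#'
#' Requires ggplot2 (in Suggests). Returns a list of ggplot objects:
#' estimated-vs-reference scatter and Bland-Altman agreement plot per
#' channel.
#'
#' @param report an `eval_report`.
#' @return named list of ggplot objects.
#' @export
plot_eval_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  p <- report$pairs
  out <- list()
  for (ch in c("sbp", "dbp")) {
    est <- p[[paste0("est_", ch)]]; ref <- p[[paste0("ref_", ch)]]
    df <- data.frame(est = est, ref = ref,
                     mean = (est + ref) / 2, diff = est - ref)
    ba <- report[[ch]]$bland_altman
    out[[paste0(ch, "_scatter")]] <-
      ggplot2::ggplot(df, ggplot2::aes(x = ref, y = est)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = sprintf("Reference %s (mmHg)", toupper(ch)),
                    y = sprintf("Estimated %s (mmHg)", toupper(ch)),
                    title = sprintf("%s: r = %.3f", toupper(ch),
                                    report[[ch]]$pearson_r))
    out[[paste0(ch, "_bland_altman")]] <-
      ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = c(ba$bias, ba$lower, ba$upper),
                          linetype = c(1, 2, 2)) +
      ggplot2::labs(x = sprintf("Mean of estimate and reference (mmHg)"),
                    y = "Difference (mmHg)",
                    title = sprintf("%s Bland-Altman", toupper(ch)))
  }
  out
}
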