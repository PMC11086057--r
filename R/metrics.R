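#' Density levels
#'
#' Per-image counts are binned into four density levels:
#' Low `[0, 249]`, Medium `[250, 499]`, High `[500, 749]`,
#' Higher `[750, 1000]`.  Counts above 1000 extend into Higher.
#'
#' @param count non-negative numeric vector of (possibly fractional) counts.
#' @return a factor with levels Low, Medium, High, Higher.
#' @export
assign_density_level <- function(count) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and non-negative")
  lv <- ifelse(count < 250, "Low",
        ifelse(count < 500, "Medium",
        ifelse(count < 750, "High", "Higher")))
  factor(lv, levels = c("Low", "Medium", "High", "Higher"))
}

#' Bin ranges of the density levels
#' @return a data frame with columns `level`, `lo`, `hi`.
#' @export
density_level_ranges <- function() {
  data.frame(level = c("Low", "Medium", "High", "Higher"),
             lo = c(0L, 250L, 500L, 750L),
             hi = c(249L, 499L, 749L, 1000L))
}

#' Build an evaluation report from count pairs
#'
#' @param truth,predicted numeric vectors of per-image true and predicted
#'   counts.
#' @param image optional image identifiers.
#' @return an object of class `eval_report` with fields `per_image`
#'   (data frame: image, true_count, predicted_count, absolute_error,
#'   level), `mae`, `rmse`, `n_images`, and `per_level` (level breakdown).
#' @export
eval_report <- function(truth, predicted, image = NULL) {
  .check_pairs(truth, predicted)
  if (is.null(image)) image <- sprintf("image_%03d", seq_along(truth))
  per_image <- data.frame(
    image = image,
    true_count = truth,
    predicted_count = predicted,
    absolute_error = abs(truth - predicted),
    level = assign_density_level(truth),
    stringsAsFactors = FALSE)
  per_level <- do.call(rbind, lapply(split(per_image, per_image$level),
    function(d) {
      if (nrow(d) == 0L) return(NULL)
      data.frame(level = d$level[1L], n_images = nrow(d),
                 mae = count_mae(d$true_count, d$predicted_count),
                 rmse = count_rmse(d$true_count, d$predicted_count))
    }))
  rownames(per_level) <- NULL
  structure(list(per_image = per_image,
                 mae = count_mae(truth, predicted),
                 rmse = count_rmse(truth, predicted),
                 n_images = length(truth),
                 per_level = per_level),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d image(s): MAE %.3f, RMSE %.3f\n",
              x$n_images, x$mae, x$rmse))
  if (!is.null(x$per_level) && nrow(x$per_level) > 0L) {
    for (i in seq_len(nrow(x$per_level)))
      cat(sprintf("  %-6s n=%3d  MAE %.3f  RMSE %.3f\n",
                  x$per_level$level[i], x$per_level$n_images[i],
                  x$per_level$mae[i], x$per_level$rmse[i]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-image rows go to CSV; the MAE/RMSE summary (with the per-level
#' breakdown) goes to JSON.
#'
#' @param report an [eval_report].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(mae = report$mae, rmse = report$rmse,
           n_images = report$n_images, per_level = report$per_level),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
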