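#' Correlation map of a winter index against gridded seasonal temperature
#'
#' Correlates an annual winter circulation index (e.g. DJFM-mean PNA or NAM,
#' labelled by January's year) with the seasonal mean of every grid cell
#' over their overlapping years. Spearman's rank correlation is the default;
#' p-values come from [stats::cor.test()] (exact permutation distribution
#' for small samples without ties, asymptotic otherwise). Cells with
#' constant temperature, or fewer than `min_years` overlapping years, are
#' returned missing with a reason.
#'
#' @param index_annual Tibble with columns `year`, `value` (the winter-mean
#'   index).
#' @param grid Long-format monthly grid tibble: `lat`, `lon`, `year`,
#'   `month`, `value`.
#' @param months Season months for the grid side (default MAM).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param level Confidence level for the significance mask (default 0.95).
#' @param min_years Minimum overlapping years per cell (default 10).
#' @param detrend Linearly detrend both series over the overlap before
#'   correlating (default off).
#' @return Tibble with one row per cell: `lat`, `lon`, `r`, `p`, `sig`
#'   (p <= 1 - level), `n_years`, `reason` (`NA` when computed).
#' @export
correlation_map <- function(index_annual, grid, months = 3:5,
                            method = c("spearman", "pearson"),
                            level = 0.95, min_years = 10, detrend = FALSE) {
  method <- match.arg(method)
  stopifnot_cols(index_annual, c("year", "value"), "index_annual")
  stopifnot_cols(grid, c("lat", "lon", "year", "month", "value"), "grid")
  idx <- index_annual %>% filter(!is.na(.data$value))
  out <- grid %>%
    group_by(.data$lat, .data$lon) %>%
    dplyr::group_modify(function(cell, key) {
      ann <- seasonal_mean(cell, months = months)
      m <- dplyr::inner_join(ann, idx, by = "year",
                             suffix = c("_temp", "_idx")) %>%
        filter(!is.na(.data$value_temp), !is.na(.data$value_idx))
      if (nrow(m) < min_years) {
        return(tibble(r = NA_real_, p = NA_real_, sig = NA,
                      n_years = nrow(m), reason = "insufficient overlap"))
      }
      x <- m$value_idx
      y <- m$value_temp
      if (detrend) {
        x <- stats::resid(lm(x ~ m$year))
        y <- stats::resid(lm(y ~ m$year))
      }
      if (stats::sd(y) == 0 || stats::sd(x) == 0) {
        return(tibble(r = NA_real_, p = NA_real_, sig = NA,
                      n_years = nrow(m), reason = "constant series"))
      }
      ct <- suppressWarnings(cor.test(x, y, method = method))
      tibble(r = unname(ct$estimate), p = ct$p.value,
             sig = ct$p.value <= (1 - level), n_years = nrow(m),
             reason = NA_character_)
    }) %>%
    ungroup()
  if (all(out$reason %in% "insufficient overlap")) {
    abort("no grid cell had sufficient overlap with the index")
  }
  out
}
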