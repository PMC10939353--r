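# Cross-dataset anchor QC. Anchor platforms are built from a fixed
# protein copy number, so across well-behaved datasets the mean anchor
# brightness and the mean second momentum move together (a global gain
# change shifts both along the same trend). A dataset falling off that
# trend signals an artefactual acquisition (e.g. altered platform
# structure or imaging drift).

#' Anchor-spot consistency check across PICT datasets
#'
#' Computes per-dataset mean brightness (mass) and mean second momentum of
#' the channel-1 (anchor) spots, fits a robust linear trend across
#' datasets in that plane and flags datasets whose standardized residual
#' exceeds `flag_threshold` robust SDs. With a single dataset only the
#' means are reported; with two, the trend is reported with a low-n
#' warning and no flags are raised.
#'
#' @param spot_tables named list of anchor spot tables (post-selection
#'   channel-1 spots), each with `mass` and `m2` columns.
#' @param flag_threshold residual threshold in robust SDs.
#' @return an object of class `dataset_qc`: a data.frame with
#'   `dataset_id`, `n_anchor_spots`, `mean_mass`, `mean_m2`, `residual`,
#'   `flagged`; the trend fit is attached as attributes.
#' @export
dataset_qc <- function(spot_tables, flag_threshold = 3) {
  if (!is.list(spot_tables) || length(spot_tables) < 1L) {
    stop("'spot_tables' must be a non-empty list of spot tables",
         call. = FALSE)
  }
  ids <- names(spot_tables)
  if (is.null(ids)) ids <- paste0("dataset_", seq_along(spot_tables))
  rec <- data.frame(
    dataset_id = ids,
    n_anchor_spots = vapply(spot_tables, nrow, integer(1)),
    mean_mass = vapply(spot_tables, function(s) mean(s$mass), numeric(1)),
    mean_m2 = vapply(spot_tables, function(s) mean(s$m2), numeric(1)),
    residual = NA_real_,
    flagged = FALSE)
  if (any(rec$n_anchor_spots < 1L)) {
    stop("every dataset needs at least one anchor spot", call. = FALSE)
  }
  n <- nrow(rec)
  trend <- NULL
  if (n >= 2L) {
    # robust trend in (mean_mass, mean_m2); ordered by id so the fit is
    # invariant to the input order
    o <- order(rec$dataset_id)
    fit <- tryCatch(
      MASS::rlm(mean_m2 ~ mean_mass, data = rec[o, ], maxit = 100),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- stats::lm(mean_m2 ~ mean_mass, data = rec[o, ])
      scale <- stats::sd(stats::resid(fit))
    } else {
      scale <- fit$s
    }
    res <- rep(NA_real_, n)
    res[o] <- stats::resid(fit)
    scale <- max(scale, stats::mad(res), .Machine$double.eps)
    rec$residual <- res / scale
    trend <- stats::coef(fit)
    if (n == 2L) {
      warning("only 2 datasets: trend reported, consistency not scored")
    } else {
      rec$flagged <- abs(rec$residual) > flag_threshold
    }
  }
  structure(rec, class = c("dataset_qc", "data.frame"),
            trend = trend, flag_threshold = flag_threshold)
}

#' @export
print.dataset_qc <- function(x, ...) {
  cat("Anchor-spot consistency across", nrow(x), "datasets\n")
  tr <- attr(x, "trend")
  if (!is.null(tr)) {
    cat(sprintf("  trend: mean_m2 = %.4g + %.4g * mean_mass\n",
                tr[1], tr[2]))
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$flagged)) {
    cat("Flagged as artefactual:",
        paste(x$dataset_id[x$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}
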