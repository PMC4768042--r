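#' Aggregate monthly query volumes to annual totals
#'
#' Sums counts and total-volume proxies over the 12 calendar months of each
#' region-year-role cell. In strict mode every cell must have all 12 months;
#' in permissive mode partial cells are summed over the months present and a
#' warning names the gaps.
#'
#' @param volumes Monthly volume table as produced by
#'   [generate_query_volumes()].
#' @param strict Error on missing months (default) instead of warning.
#' @return Annual volume table: `region`, `year`, `term`, `role`, `count`,
#'   `total_volume`.
#' @examples
#' cfg <- generator_config(regions = "AA", years = 2010, deterministic = TRUE)
#' annualize_volumes(generate_query_volumes(cfg))
#' @export
annualize_volumes <- function(volumes, strict = TRUE) {
  req <- c("region", "year", "month", "role", "count", "total_volume")
  stopifnot(all(req %in% names(volumes)))
  key <- interaction(volumes$region, volumes$year, volumes$role, drop = TRUE)
  n_months <- tapply(volumes$month, key, function(m) length(unique(m)))
  gaps <- names(n_months)[n_months < 12L]
  if (length(gaps)) {
    msg <- paste0("cells with missing months: ",
                  paste(utils::head(gaps, 10L), collapse = "; "),
                  if (length(gaps) > 10L) sprintf(" (and %d more)", length(gaps) - 10L))
    if (strict) stop(msg) else warning(msg)
  }
  agg <- stats::aggregate(
    cbind(count, total_volume) ~ region + year + role + term,
    data = volumes, FUN = sum)
  agg <- agg[, c("region", "year", "term", "role", "count", "total_volume")]
  agg[order(agg$region, agg$year, agg$role), , drop = FALSE]
}

#' Normalize query volumes to a Trends-style 0-100 index
#'
#' Rescales query volumes so that, within each comparison slice, the largest
#' cell scores 100. A slice is one `(year, role)` combination; its cells are
#' all regions (and, for monthly input, all region-months, so within-year
#' seasonal variation survives normalization). In `"counts"` mode the index
#' is `100 * count / max(count)` over the slice. In `"share"` mode each count
#' is first divided by the region-period total query volume, mirroring public
#' Trends semantics where indices are shares of a region's total search
#' activity; the shares are then rescaled so the slice maximum is 100.
#' Regions tied at the slice maximum all receive 100.
#'
#' @param volumes Annual or monthly volume table with columns `region`,
#'   `year`, `role`, `count` and (for share mode) `total_volume`; a `month`
#'   column is carried through when present.
#' @param mode `"share"` (default) or `"counts"`.
#' @return Index cells: `region`, `year`, (`month`,) `role`, `index_value`
#'   with values in \[0, 100\].
#' @examples
#' v <- data.frame(region = c("A", "B", "C"), year = 2009, role = "past",
#'                 count = c(10, 40, 20), total_volume = 1)
#' trends_normalize(v, mode = "counts")$index_value # 25 100 50
#' @export
trends_normalize <- function(volumes, mode = c("share", "counts")) {
  mode <- match.arg(mode)
  stopifnot(all(c("region", "year", "role", "count") %in% names(volumes)))
  if (any(volumes$count < 0)) stop("negative counts are invalid")
  value <- if (mode == "share") {
    if (!"total_volume" %in% names(volumes)) {
      stop("share mode requires a total_volume column")
    }
    if (any(volumes$total_volume <= 0)) {
      stop("share mode requires positive total_volume")
    }
    volumes$count / volumes$total_volume
  } else {
    volumes$count
  }
  slice <- interaction(volumes$year, volumes$role, drop = TRUE)
  slice_max <- stats::ave(value, slice, FUN = max)
  bad <- unique(paste0(volumes$year, "/", volumes$role)[slice_max == 0])
  if (length(bad)) {
    stop("index undefined: all counts zero in slice(s) ",
         paste(bad, collapse = ", "))
  }
  keep <- intersect(c("region", "year", "month", "role"), names(volumes))
  out <- volumes[, keep, drop = FALSE]
  # ratio first: guarantees the slice maximum scores exactly 100
  out$index_value <- 100 * (value / slice_max)
  row.names(out) <- NULL
  out
}

#' Past- and future-orientation ratio statistics
#'
#' `past_orientation()` returns `scale * past_index / future_index`: the
#' normalized search interest in the previous-year phrase relative to the
#' next-year phrase, so values above `scale` mark regions whose residents
#' search disproportionately for the year just gone. `future_orientation()`
#' is the mirror-image ratio (next-year over previous-year); the two satisfy
#' `past_orientation * future_orientation == scale^2` exactly when computed
#' from the same index cells.
#'
#' The default `scale = 1` keeps the statistic on the natural ratio scale
#' (typical observed values fall roughly between 0.78 and 1.52); pass
#' `scale = 100` for a percent-style variant.
#'
#' @param past_index,future_index Positive index values (vectorized).
#' @param scale Positive multiplier on the ratio; default 1.
#' @return Numeric vector of orientation values.
#' @examples
#' past_orientation(50, 40) # 1.25
#' future_orientation(50, 40) # 0.8
#' @export
past_orientation <- function(past_index, future_index, scale = 1) {
  if (any(future_index == 0)) {
    stop("past orientation undefined: future index is zero")
  }
  scale * past_index / future_index
}

#' @rdname past_orientation
#' @export
future_orientation <- function(past_index, future_index, scale = 1) {
  if (any(past_index == 0)) {
    stop("future orientation undefined: past index is zero")
  }
  scale * future_index / past_index
}

#' Region-year orientation table from raw monthly volumes
#'
#' Runs the full index pipeline: monthly volumes are summed to annual counts
#' ([annualize_volumes()]), normalized to Trends-style indices per
#' `(year, role)` slice ([trends_normalize()]), and combined into the
#' orientation ratios. Region-years whose future (or past) index is zero are
#' an error in strict mode; in permissive mode they are dropped with a
#' message per dropped row.
#'
#' @param volumes Monthly volume table.
#' @param mode Normalization mode, `"share"` (default) or `"counts"`.
#' @param scale Orientation scale factor, see [past_orientation()].
#' @param strict Propagate errors for undefined ratios and missing months.
#' @return A data.frame `region`, `year`, `past_index`, `future_index`,
#'   `past_orientation`, `future_orientation`.
#' @export
orientation_table <- function(volumes, mode = c("share", "counts"),
                              scale = 1, strict = TRUE) {
  mode <- match.arg(mode)
  annual <- annualize_volumes(volumes, strict = strict)
  cells <- trends_normalize(annual, mode = mode)
  past <- cells[cells$role == "past",
                c("region", "year", "index_value")]
  names(past)[3] <- "past_index"
  fut <- cells[cells$role == "future",
               c("region", "year", "index_value")]
  names(fut)[3] <- "future_index"
  tab <- merge(past, fut, by = c("region", "year"))
  undefined <- tab$future_index == 0 | tab$past_index == 0
  if (any(undefined)) {
    labels <- paste0(tab$region[undefined], "/", tab$year[undefined])
    if (strict) {
      stop("orientation undefined (zero index) for: ",
           paste(labels, collapse = ", "))
    }
    for (lab in labels) message("dropping region-year with zero index: ", lab)
    tab <- tab[!undefined, , drop = FALSE]
  }
  tab$past_orientation <- past_orientation(tab$past_index, tab$future_index,
                                           scale)
  tab$future_orientation <- future_orientation(tab$past_index,
                                               tab$future_index, scale)
  tab <- tab[order(tab$region, tab$year), , drop = FALSE]
  row.names(tab) <- NULL
  tab
}

#' Mean monthly index profile by role
#'
#' Averages monthly index values per calendar month and role across all
#' regions and years: the seasonal signature of year-phrase search interest
#' (past-phrase interest highest in January and declining; future-phrase
#' interest rising to a December peak).
#'
#' @param cells Monthly index cells from [trends_normalize()] (must retain
#'   the `month` column).
#' @return A data.frame `month`, `role`, `mean_index`, sorted by role then
#'   month; only months present in the input appear.
#' @export
monthly_profile <- function(cells) {
  if (is.null(cells) || nrow(cells) == 0L) {
    stop("monthly profile undefined for empty input")
  }
  if (!"month" %in% names(cells)) {
    stop("monthly profile requires monthly index cells (month column)")
  }
  prof <- stats::aggregate(index_value ~ month + role, data = cells,
                           FUN = mean)
  names(prof)[3] <- "mean_index"
  prof <- prof[order(prof$role, prof$month), , drop = FALSE]
  row.names(prof) <- NULL
  prof
}
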