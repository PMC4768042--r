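# Small configurations and hand-built tables shared across test files.

tiny_config <- function(..., regions = c("AA", "BB", "CC"),
                        years = 2009:2010, seed = 1L) {
  generator_config(regions = regions, years = years, seed = seed, ...)
}

# A flat, noiseless query model: unit latents and sizes, no monthly trend.
flat_config <- function(..., latents = NULL,
                        regions = c("AA", "BB", "CC"), years = 2009L) {
  if (is.null(latents)) {
    latents <- stats::setNames(rep(1, length(regions)), regions)
  }
  generator_config(regions = regions, years = years,
                   past_decay = 0, future_rise = 0,
                   orientation_latents = latents,
                   region_sizes = stats::setNames(rep(1, length(regions)),
                                                  regions),
                   deterministic = TRUE, ...)
}

# Monthly volume table carrying given annual totals (all volume in January,
# zeros elsewhere) so annualization is trivially checkable by hand.
monthly_from_annual <- function(past, future, regions = names(past),
                                year = 2009L, total = 1) {
  rows <- list()
  for (r in regions) {
    for (role in c("past", "future")) {
      count1 <- if (role == "past") past[[r]] else future[[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, year = year, month = 1:12,
        term = as.character(if (role == "past") year - 1L else year + 1L),
        role = role, count = c(count1, rep(0, 11)), total_volume = total,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random annual volume table for property-style checks.
random_annual_volumes <- function(n_regions, years = 2009L) {
  regions <- sprintf("R%02d", seq_len(n_regions))
  grid <- expand.grid(region = regions, year = years,
                      role = c("past", "future"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$term <- as.character(ifelse(grid$role == "past",
                                   grid$year - 1L, grid$year + 1L))
  grid$count <- stats::rpois(nrow(grid), 50) + 1L
  grid$total_volume <- stats::runif(nrow(grid), 500, 2000)
  grid
}
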