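# Pooling smoothed daily posteriors into Utilization Distributions and
# highest-posterior-density (HPD) region extraction / validation.

#' Maturity classification from lower-jaw fork length
#'
#' Mature at and above 179 cm LJFL (ICCAT convention for this stock),
#' immature below.
#'
#' @param ljfl_cm lower-jaw fork length, cm (> 0); vectorized.
#' @return character vector, "immature" or "mature".
#' @export
classify_maturity <- function(ljfl_cm) {
  if (any(is.na(ljfl_cm)) || any(ljfl_cm <= 0))
    stop("ljfl_cm must be positive and non-missing")
  ifelse(ljfl_cm >= 179, "mature", "immature")
}

quarter_of <- function(date) (as.POSIXlt(as.Date(date))$mon %/% 3) + 1L

#' Pool smoothed tracks into a Utilization Distribution
#'
#' Equal-weight mean of all daily smoothed probability fields whose date
#' falls in the stratum's quarter and whose fish matches the stratum's
#' maturity class, renormalized to 1.
#'
#' @param tracks list of entries, each `list(track = smoothed_track,
#'   dep = deployment)`. Track day i corresponds to `dep$release_date + i - 1`.
#' @param quarter one of 1:4 or "all".
#' @param maturity "immature", "mature", or "all".
#' @param weighting "fish-day" (default: every day weighs equally) or
#'   "fish" (each fish's within-stratum mean weighs equally).
#' @return list of class `ud`: `m` (normalized surface), `grid`,
#'   `n_fish_days`, `quarter`, `maturity`.
#' @export
pool_ud <- function(tracks, quarter = "all", maturity = "all",
                    weighting = c("fish-day", "fish")) {
  weighting <- match.arg(weighting)
  stopifnot(length(tracks) >= 1)
  grid <- tracks[[1]]$track$grid
  acc <- matrix(0, grid$ny, grid$nx)
  n_days <- 0L
  for (entry in tracks) {
    st <- entry$track; dep <- entry$dep
    if (maturity != "all" && classify_maturity(dep$ljfl_cm) != maturity) next
    dates <- deployment_dates(dep)
    sel <- if (identical(quarter, "all")) seq_along(dates) else
      which(quarter_of(dates) == quarter)
    if (!length(sel)) next
    fish_acc <- matrix(0, grid$ny, grid$nx)
    for (i in sel) fish_acc <- fish_acc + st$fields[[i]]
    acc <- acc + if (weighting == "fish") fish_acc / length(sel) else fish_acc
    n_days <- n_days + length(sel)
  }
  if (n_days == 0L)
    stop("no fish-days in stratum (quarter=", quarter, ", maturity=", maturity, ")")
  structure(list(m = acc / sum(acc), grid = grid, n_fish_days = n_days,
                 quarter = quarter, maturity = maturity),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("ud: quarter %s, %s, %d fish-days, %d x %d grid\n",
              format(x$quarter), x$maturity, x$n_fish_days,
              x$grid$ny, x$grid$nx))
  invisible(x)
}

# Smallest prefix of density-ranked cells reaching `level` total mass.
# Ties broken by cell index for determinism.
hpd_mask <- function(m, level) {
  o <- order(m, seq_along(m), decreasing = c(TRUE, FALSE), method = "radix")
  cs <- cumsum(m[o])
  k <- which(cs >= level * sum(m))[1]
  if (is.na(k)) k <- length(o)
  mask <- matrix(FALSE, nrow(m), ncol(m))
  mask[o[seq_len(k)]] <- TRUE
  mask
}

#' Highest-posterior-density regions of a UD
#'
#' Nested masks of the densest cells capturing at least each requested mass
#' level (cells ranked by density, ties by index).
#'
#' @param ud a [pool_ud()] result (or any `ud`-like list with `m`).
#' @param levels mass levels (default 0.50, 0.75, 0.95).
#' @return list of class `hpd_regions`: `masks` (named list of logical
#'   matrices), `levels`.
#' @export
hpd_regions <- function(ud, levels = c(0.5, 0.75, 0.95)) {
  stopifnot(all(levels > 0 & levels < 1))
  levels <- sort(levels)
  masks <- lapply(levels, function(L) hpd_mask(ud$m, L))
  names(masks) <- sprintf("%g", levels)
  structure(list(masks = masks, levels = levels, grid = ud$grid),
            class = "hpd_regions")
}

#' Coverage of independent point data by HPD regions
#'
#' Fraction of points whose containing grid cell lies inside the level-region
#' of their calendar quarter. Points falling off the grid (or whose quarter
#' lacks a region) are excluded from the denominator and reported.
#'
#' @param points data.frame `lon`, `lat`, `date`.
#' @param regions_by_quarter list indexed 1..4 of `hpd_regions` (or of single
#'   logical masks).
#' @param level which level's mask to use (matched against region levels).
#' @param grid the model grid.
#' @return list: `fraction` overall, `table` per-quarter data.frame
#'   (`quarter`, `n`, `covered`, `fraction`), `n_off_grid`.
#' @export
point_coverage <- function(points, regions_by_quarter, level = 0.95, grid) {
  q <- quarter_of(points$date)
  rc <- cell_at(grid, points$lon, points$lat)
  off <- is.na(rc$row)
  covered <- rep(NA, nrow(points))
  for (i in which(!off)) {
    reg <- regions_by_quarter[[q[i]]]
    mask <- if (inherits(reg, "hpd_regions"))
      reg$masks[[sprintf("%g", level)]] else reg
    if (is.null(mask)) { off[i] <- TRUE; next }
    covered[i] <- mask[rc$row[i], rc$col[i]]
  }
  tab <- do.call(rbind, lapply(1:4, function(qq) {
    sel <- !off & q == qq
    data.frame(quarter = qq, n = sum(sel), covered = sum(covered[sel], na.rm = TRUE),
               fraction = if (any(sel)) mean(covered[sel]) else NA_real_)
  }))
  list(fraction = mean(covered[!off]), table = tab, n_off_grid = sum(off))
}

#' Total-variation distance between two probability surfaces
#'
#' @param p,q `ud` or `prob_field` objects, or bare matrices summing to 1.
#' @return half the L1 distance, in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  mp <- if (is.matrix(p)) p else p$m
  mq <- if (is.matrix(q)) q else q$m
  sum(abs(mp - mq)) / 2
}
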