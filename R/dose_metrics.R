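# DVH statistics (D0.1cc, D5cc, mean) and the dosimetric robustness report:
# counts and sums of statistics falling more than 0.5 Gy below a reference,
# and median increases above the baseline mapped dose.

#' Dose-volume statistic D_Vcc
#'
#' The dose such that exactly `v_cc` cubic centimetres of the structure
#' receive at least that dose: voxel doses are sorted descending, voxel
#' volumes accumulated, and the dose linearly interpolated between the
#' bracketing voxels. Requests exceeding the structure volume are flagged
#' undefined (`NA`), mirroring the exclusion of small organs from D5cc
#' reporting.
#'
#' @param doses numeric vector of structure voxel doses (Gy).
#' @param voxel_cc volume of one voxel (cc).
#' @param v_cc requested volume (cc), e.g. 0.1 or 5.
#' @return Dose (Gy), or `NA` when the structure is smaller than `v_cc`.
#' @export
d_vcc <- function(doses, voxel_cc, v_cc) {
  stopifnot(length(doses) > 0L, voxel_cc > 0, v_cc > 0)
  total <- length(doses) * voxel_cc
  if (v_cc > total) return(NA_real_)
  s <- sort(doses, decreasing = TRUE)
  k <- ceiling(v_cc / voxel_cc - 1e-12)
  if (k <= 1L) return(s[1L])
  frac <- (v_cc - (k - 1L) * voxel_cc) / voxel_cc
  s[k - 1L] + frac * (s[k] - s[k - 1L])
}

#' DVH statistics for one structure
#'
#' @param dose [scalar_volume()] (Gy) on the structure's grid.
#' @param mask [binary_mask()] (non-empty) on the same grid.
#' @param v_cc volumes (cc) at which to report D_Vcc (default 0.1 and 5).
#' @return An object of class `dvh_statistics`: `d_vcc` (named, `NA` where
#'   the structure is too small), `mean` (Gy), `volume_cc`, `defined`
#'   (logical flags per D_Vcc).
#' @export
dvh_statistics <- function(dose, mask, v_cc = c(0.1, 5)) {
  if (!same_geometry(dose$geometry, mask$geometry)) {
    stop("dose and mask must share a grid")
  }
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("dvh_statistics: empty mask")
  voxel_cc <- voxel_volume_cc(mask$geometry)
  doses <- dose$values[idx]
  dv <- vapply(v_cc, function(v) d_vcc(doses, voxel_cc, v), numeric(1L))
  names(dv) <- vapply(v_cc, function(v) {
    paste0("D", sub("^0\\.", "0p", format(v)), "cc")
  }, character(1L))
  structure(list(d_vcc = dv, mean = mean(doses),
                 volume_cc = length(doses) * voxel_cc, defined = !is.na(dv),
                 v_cc = v_cc),
            class = "dvh_statistics")
}

#' @export
print.dvh_statistics <- function(x, ...) {
  cat(sprintf("dvh_statistics: volume %.2f cc, mean %.2f Gy\n",
              x$volume_cc, x$mean))
  for (i in seq_along(x$d_vcc)) {
    cat(sprintf("  %s = %s\n", names(x$d_vcc)[i],
                if (is.na(x$d_vcc[i])) "undefined (structure too small)"
                else sprintf("%.2f Gy", x$d_vcc[i])))
  }
  invisible(x)
}

#' Dosimetric deficit and increase report
#'
#' Compares DVH statistics of each mapped-dose mode against a reference
#' (the original dose, as reported, or the baseline mapped dose) per organ:
#' the count of statistics more than `threshold` Gy below the reference, the
#' (negative) sum of those deficits, and the median increase above the
#' baseline mapped dose. Undefined statistics (structure too small) are
#' excluded pairwise.
#'
#' @param stats long data.frame with columns `oar`, `mode`, `statistic`,
#'   `value`; must contain rows for the reference mode and for `"baseline"`.
#' @param reference `"original"` (default) or `"baseline"`.
#' @param threshold deficit threshold (Gy), default 0.5.
#' @return data.frame with one row per mode x statistic: `deficit_count`,
#'   `deficit_sum` (Gy, <= 0), `median_increase` (Gy above baseline).
#' @export
deficit_report <- function(stats, reference = c("original", "baseline"),
                           threshold = 0.5) {
  reference <- match.arg(reference)
  needed <- c("oar", "mode", "statistic", "value")
  if (!all(needed %in% names(stats))) {
    stop("stats must have columns oar, mode, statistic, value")
  }
  if (!reference %in% stats$mode) {
    stop("reference mode '", reference, "' not present in stats")
  }
  modes <- setdiff(unique(stats$mode), "original")
  statistics <- unique(stats$statistic)
  ref <- stats[stats$mode == reference, ]
  base <- stats[stats$mode == "baseline", ]
  out <- list()
  for (mode in modes) {
    cur <- stats[stats$mode == mode, ]
    for (st in statistics) {
      r <- ref[ref$statistic == st, ]
      b <- base[base$statistic == st, ]
      m <- cur[cur$statistic == st, ]
      if (!setequal(m$oar, r$oar) || !setequal(m$oar, b$oar)) {
        stop("mismatched organ sets between modes for statistic ", st)
      }
      rv <- r$value[match(m$oar, r$oar)]
      bv <- b$value[match(m$oar, b$oar)]
      ok <- !is.na(m$value) & !is.na(rv)
      diff <- m$value[ok] - rv[ok]
      deficit <- diff < -threshold
      okb <- !is.na(m$value) & !is.na(bv)
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, statistic = st,
        n = sum(ok),
        deficit_count = sum(deficit),
        deficit_sum = if (any(deficit)) sum(diff[deficit]) else 0,
        median_increase = stats::median(m$value[okb] - bv[okb]))
    }
  }
  do.call(rbind, out)
}

#' Cumulative DVH curve
#'
#' Cumulative volume (cc) receiving at least each dose level, from the full
#' structure volume at 0 Gy, monotone non-increasing, consistent with
#' [d_vcc()] at queried points.
#'
#' @inheritParams dvh_statistics
#' @param bin_width dose bin width (Gy), default 0.5.
#' @return data.frame with columns `dose_gy`, `volume_cc`, `volume_pct`.
#' @export
dvh_curve <- function(dose, mask, bin_width = 0.5) {
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("dvh_curve: empty mask")
  doses <- dose$values[idx]
  voxel_cc <- voxel_volume_cc(mask$geometry)
  top <- max(doses, 0)
  breaks <- seq(0, top + bin_width, by = bin_width)
  vol <- vapply(breaks, function(d) sum(doses >= d) * voxel_cc, numeric(1L))
  data.frame(dose_gy = breaks, volume_cc = vol,
             volume_pct = 100 * vol / (length(doses) * voxel_cc))
}

#' DVH statistics for every organ and mode of a pipeline result
#'
#' Builds the long table consumed by [deficit_report()]: per organ, the
#' original-dose statistics (on the source grid) and the statistics of every
#' mapped mode (on the destination grid).
#'
#' @param map a `road_dose_map` from [road_map()].
#' @param dose_src source [scalar_volume()] (Gy).
#' @param oar_src named list of source organ [binary_mask()]s (same names as
#'   in the pipeline call).
#' @param oar_dst named list of destination organ [binary_mask()]s.
#' @param v_cc D_Vcc volumes (cc), default `c(0.1, 5)`.
#' @return Long data.frame with columns `oar`, `mode`, `statistic`, `value`.
#' @export
collect_dvh_stats <- function(map, dose_src, oar_src, oar_dst,
                              v_cc = c(0.1, 5)) {
  rows <- list()
  add <- function(oar, mode, st) {
    vals <- c(st$d_vcc, mean = st$mean)
    labels <- c(names(st$d_vcc), "mean")
    for (i in seq_along(vals)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        oar = oar, mode = mode, statistic = labels[i], value = unname(vals[i]))
    }
  }
  nms <- names(oar_src)
  if (is.null(nms)) nms <- paste0("oar", seq_along(oar_src))
  for (k in seq_along(oar_src)) {
    add(nms[k], "original", dvh_statistics(dose_src, oar_src[[k]], v_cc))
    for (mode in names(map$dose)) {
      add(nms[k], mode, dvh_statistics(map$dose[[mode]], oar_dst[[k]], v_cc))
    }
  }
  do.call(rbind, rows)
}
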