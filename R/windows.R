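# Chromosome-scale sliding-window profiles: fixed megabase binning of summed
# gene expression, scaling against a reference cell, and moving-average
# smoothing along each chromosome.

#' Windowed expression sums for one (sex, group) cell
#'
#' Each chromosome is tiled into non-overlapping `window_bp` windows
#' (0-based half-open). Every mapped gene is assigned to exactly one window
#' by its start coordinate, and the cell's per-gene mean FPKMs are summed
#' within each window, so window sums conserve the chromosome's total mean
#' expression.
#'
#' @param dataset `xdg_dataset`
#' @param cell named vector `c(sex=, group=)` selecting the cell
#' @param window_bp window size in base pairs
#' @param chrom_lengths optional named vector of chromosome lengths; default
#'   is inferred from the annotation's max end coordinate
#' @return object of class `xdg_profile`: data.frame `chrom, window_index,
#'   window_start_bp, raw_sum` with attribute `window_bp`
#' @export
window_sums <- function(dataset, cell = c(sex = "female", group = "IVF"),
                        window_bp = 1e6, chrom_lengths = NULL) {
  stopifnot(inherits(dataset, "xdg_dataset"), window_bp >= 1)
  s <- dataset$samples
  ids <- s$sample_id[s$sex == cell[["sex"]] & s$group == cell[["group"]]]
  if (!length(ids)) stop("no samples in cell ", paste(cell, collapse = "."))
  gm <- rowMeans(dataset$matrix[, ids, drop = FALSE])
  ann <- dataset$annotation
  mapped <- !ann$is_unmapped & ann$chrom_class != "mito"
  ann <- ann[mapped, ]; gm <- gm[mapped]

  chroms <- unique(ann$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(ann$end_bp[ann$chrom == ch]),
                            numeric(1))
  }
  out <- lapply(chroms, function(ch) {
    sel <- ann$chrom == ch
    idx <- floor((ann$start_bp[sel] - 1) / window_bp)  # 1-based -> 0-based
    n_win <- max(ceiling(chrom_lengths[[ch]] / window_bp), max(idx) + 1L)
    if (any(ann$start_bp[sel] > chrom_lengths[[ch]])) {
      warning("gene(s) beyond declared length of chromosome ", ch,
              "; assigned by coordinate anyway")
    }
    sums <- vapply(split(gm[sel], factor(idx, levels = 0:(n_win - 1L))),
                   sum, numeric(1))
    data.frame(chrom = ch, window_index = 0:(n_win - 1L),
               window_start_bp = as.numeric(0:(n_win - 1L)) * window_bp,
               raw_sum = unname(sums), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), window_bp = window_bp, cell = cell,
            class = c("xdg_profile", "data.frame"))
}

#' Relative window profile against a reference cell
#'
#' `rel = raw_sum / reference raw_sum` per window; windows where the
#' reference is zero are flagged missing rather than infinite. Both profiles
#' must share the same window grid.
#'
#' @param profile,reference_profile `xdg_profile` objects on the same grid
#'   (reference conventionally the male IVF cell)
#' @return `xdg_profile` with an added `rel` column
#' @export
relative_profile <- function(profile, reference_profile) {
  if (!isTRUE(attr(profile, "window_bp") == attr(reference_profile, "window_bp")) ||
      nrow(profile) != nrow(reference_profile) ||
      !all(profile$chrom == reference_profile$chrom) ||
      !all(profile$window_index == reference_profile$window_index)) {
    stop("window grids of profile and reference do not match")
  }
  profile$rel <- ifelse(reference_profile$raw_sum > 0,
                        profile$raw_sum / reference_profile$raw_sum, NA_real_)
  profile
}

moving_average <- function(v, k) {
  n <- length(v)
  h1 <- floor((k - 1) / 2); h2 <- ceiling((k - 1) / 2)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - h1):min(n, i + h2)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Smooth a relative profile by a centred moving average
#'
#' Average of `k` windows moving along each chromosome, centred, with the
#' window shrinking at chromosome edges; missing windows are skipped within
#' the average. `k = 1` returns the profile unchanged.
#'
#' @param profile `xdg_profile` with a `rel` column (falls back to
#'   `raw_sum` when absent)
#' @param k number of windows averaged
#' @return `xdg_profile` with an added `smoothed` column
#' @export
smooth_profile <- function(profile, k = 30) {
  stopifnot(k >= 1)
  src <- if (!is.null(profile$rel)) profile$rel else profile$raw_sum
  parts <- split(seq_len(nrow(profile)), profile$chrom)
  sm <- numeric(nrow(profile))
  for (idx in parts) {
    if (k > length(idx)) {
      warning("k exceeds window count on chromosome ",
              profile$chrom[idx[1]], "; using the global mean")
      sm[idx] <- mean(src[idx], na.rm = TRUE)
    } else {
      sm[idx] <- moving_average(src[idx], k)
    }
  }
  profile$smoothed <- sm
  profile
}
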