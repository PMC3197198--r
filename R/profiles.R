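## T-RFLP profile handling: peak-table IO, the single-pass fluorescence
## normalization with a 25-RFU detection cutoff, and cross-sample fragment
## binning into a relative-abundance feature matrix.

peak_table_cols <- c("sample_id", "dye", "enzyme", "size_bp", "height_rfu")

#' Read peak tables from CSV
#'
#' Expects columns `sample_id`, `dye`, `enzyme`, `size_bp`, `height_rfu`
#' (GeneMapper-style size-called peaks, one row per peak). Malformed rows
#' raise a format error naming the offending line. Samples present in the
#' file but with no peaks are not representable in this layout; an empty
#' file yields an empty list.
#'
#' @param path CSV file path.
#' @return Named list of `peak_table` data frames, one per sample.
#' @export
read_peak_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(peak_table_cols, names(raw))
  if (length(missing)) {
    stop_scatyper(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      "scatyper_format_error"
    )
  }
  for (col in c("size_bp", "height_rfu")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_scatyper(
        sprintf("non-numeric %s at line %d", col, bad[1] + 1L),
        "scatyper_format_error", line = bad[1] + 1L
      )
    }
    raw[[col]] <- v
  }
  if (any(raw$size_bp <= 0 | !is.finite(raw$size_bp))) {
    bad <- which(raw$size_bp <= 0 | !is.finite(raw$size_bp))[1]
    stop_scatyper(sprintf("non-positive fragment size at line %d", bad + 1L),
                  "scatyper_format_error", line = bad + 1L)
  }
  split_tabs <- split(raw, raw$sample_id)
  lapply(split_tabs, function(t) {
    rownames(t) <- NULL
    class(t) <- c("peak_table", "data.frame")
    t
  })
}

#' Write peak tables to CSV
#'
#' @param tables list of peak tables (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(tables)
  all <- do.call(rbind, lapply(tables, function(t) t[peak_table_cols]))
  write.csv(all, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize T-RFLP profiles across samples
#'
#' Single-pass total-fluorescence normalization with a detection cutoff:
#' (1) total fluorescence per sample is the sum of its peak heights;
#' (2) the smallest total is the reference; (3) each sample's adjustment
#' ratio is reference / total; (4) all heights are scaled by the sample's
#' ratio; (5) scaled peaks below `cutoff_rfu` are removed (25 RFU is the
#' theoretical limit of detection); (6) new totals are computed; (7) the
#' corrected relative peak height is scaled height / new total. Samples
#' with zero total fluorescence are excluded with a warning entry in the
#' report. There is no second scaling pass after peak removal.
#'
#' @param tables named list of peak tables.
#' @param cutoff_rfu detection cutoff in RFU after scaling (default 25).
#' @return List with `profiles` (normalized peak tables gaining
#'   `scaled_height` and `relative_height` columns) and `report` (per-sample
#'   totals, ratios, removed/kept peak counts, excluded flag).
#' @export
normalize_profiles <- function(tables, cutoff_rfu = 25) {
  stopifnot(length(tables) >= 1L)
  totals <- vapply(tables, function(t) sum(t$height_rfu), numeric(1))
  if (all(totals == 0)) {
    stop_scatyper("all samples have zero total fluorescence",
                  "scatyper_invalid_input")
  }
  excluded <- totals == 0
  if (any(excluded)) {
    warning(sprintf("excluding %d sample(s) with zero total fluorescence: %s",
                    sum(excluded),
                    paste(names(tables)[excluded], collapse = ", ")))
  }
  reference <- min(totals[!excluded])
  ratios <- ifelse(excluded, NA_real_, reference / totals)
  profiles <- list()
  removed <- kept <- integer(length(tables))
  for (i in seq_along(tables)) {
    if (excluded[i]) next
    t <- tables[[i]]
    t$scaled_height <- t$height_rfu * ratios[i]
    drop <- t$scaled_height < cutoff_rfu
    removed[i] <- sum(drop)
    t <- t[!drop, , drop = FALSE]
    kept[i] <- nrow(t)
    new_total <- sum(t$scaled_height)
    t$relative_height <- if (new_total > 0) t$scaled_height / new_total else
      numeric(nrow(t))
    rownames(t) <- NULL
    class(t) <- c("peak_table", "data.frame")
    profiles[[names(tables)[i]]] <- t
  }
  report <- data.frame(
    sample_id = names(tables),
    total_fluorescence = totals,
    ratio = ratios,
    peaks_removed = removed,
    peaks_kept = kept,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(profiles = profiles, report = report,
       cutoff_rfu = cutoff_rfu, reference_total = reference)
}

#' Build a samples x fragment-bins feature matrix
#'
#' Fragment sizes are assigned to half-open bins `[k*w, (k+1)*w)` by floor
#' division; relative heights are summed within a bin; the union of bins
#' across samples forms the feature set, absent bins being 0; rows are
#' re-normalized to sum to 1 (rows with no surviving peaks stay all-zero).
#'
#' @param normalized output of [normalize_profiles()], or a list of peak
#'   tables that already carry a `relative_height` column.
#' @param bin_width_bp bin width in bp (> 0, default 1).
#' @return A `feature_matrix`: numeric matrix (samples x bins) with bin
#'   labels `"B<lower edge>"` and attributes recording the binning and
#'   normalization provenance.
#' @export
build_feature_matrix <- function(normalized, bin_width_bp = 1.0) {
  stopifnot(bin_width_bp > 0)
  profiles <- if (!is.null(normalized$profiles)) normalized$profiles else
    normalized
  binned <- lapply(profiles, function(t) {
    if (nrow(t) == 0L) return(numeric(0))
    b <- floor(t$size_bp / bin_width_bp)
    tapply(t$relative_height, b, sum)
  })
  all_bins <- sort(unique(as.numeric(unlist(lapply(binned, names)))))
  m <- matrix(0, length(profiles), length(all_bins),
              dimnames = list(names(profiles),
                              sprintf("B%g", all_bins * bin_width_bp)))
  for (i in seq_along(binned)) {
    v <- binned[[i]]
    if (!length(v)) next
    m[i, match(as.numeric(names(v)), all_bins)] <- v
  }
  rs <- rowSums(m)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  structure(m, class = c("feature_matrix", class(m)),
            bin_width_bp = bin_width_bp,
            cutoff_rfu = normalized$cutoff_rfu %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
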