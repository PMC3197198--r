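## Clone-library typing: ORF trimming, pairwise global-alignment identity,
## FastGroup-style greedy binning in input order, the identity-threshold
## sweep that defines marker gene types, and universal-type summaries
## across animals.

#' Trim a clone sequence to its open reading frame
#'
#' Locates the longest open reading frame across the forward frames and
#' trims the sequence to its first start codon (default ATG; GTG/TTG can be
#' allowed) through the codon preceding a stop, or the sequence end when no
#' stop follows. Records that fail to yield an ORF of at least
#' `min_orf_nt` are rejected with a reason rather than raising an error,
#' so a library trim can report its rejects.
#'
#' @param sequence nucleotide string (>= 60 nt).
#' @param start_codons allowed start codons (default `"ATG"`).
#' @param min_orf_nt minimum ORF length in nt (default 60).
#' @return List with `status` (`"ok"` or `"rejected"`), `sequence` (trimmed
#'   ORF when ok), `frame` (0-based frame of the ORF) and `reason` (for
#'   rejections).
#' @export
#' @examples
#' trim_to_orf("CCATGAAATTTTAA")$sequence  # "ATGAAATTT"
trim_to_orf <- function(sequence, start_codons = "ATG", min_orf_nt = 60L) {
  sequence <- toupper(sequence)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  n <- nchar(sequence)
  for (frame in 0:2) {
    codon_starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(codon_starts)) next
    codons <- substring(sequence, codon_starts, codon_starts + 2L)
    is_start <- codons %in% start_codons
    is_stop <- codons %in% stops
    for (s in which(is_start)) {
      nxt_stop <- which(is_stop & seq_along(codons) > s)
      e <- if (length(nxt_stop)) min(nxt_stop) - 1L else length(codons)
      len <- (e - s + 1L) * 3L
      if (is.null(best) || len > best$len) {
        best <- list(start = codon_starts[s], len = len, frame = frame)
      }
    }
  }
  if (is.null(best) || best$len < min_orf_nt) {
    return(list(status = "rejected", sequence = NA_character_,
                frame = NA_integer_,
                reason = if (is.null(best)) "no start codon in any frame"
                         else sprintf("longest ORF %d nt < %d nt",
                                      best$len, min_orf_nt)))
  }
  list(status = "ok",
       sequence = substr(sequence, best$start, best$start + best$len - 1L),
       frame = best$frame, reason = NA_character_)
}

#' Trim a whole clone library
#'
#' Applies [trim_to_orf()] to every record and splits the library into
#' trimmed sequences and a rejection report.
#'
#' @param records data frame with `clone_id` and `sequence` columns (e.g.
#'   from [simulate_clone_library()]), or a named character vector.
#' @param ... passed to [trim_to_orf()].
#' @return List with `records` (input rows with `sequence` replaced by the
#'   trimmed ORF and a `frame` column) and `rejected` (data frame of
#'   `clone_id`, `reason`).
#' @export
trim_library <- function(records, ...) {
  if (!is.data.frame(records)) {
    records <- data.frame(clone_id = names(records),
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  res <- lapply(records$sequence, trim_to_orf, ...)
  ok <- vapply(res, function(r) r$status == "ok", logical(1))
  out <- records[ok, , drop = FALSE]
  out$sequence <- vapply(res[ok], `[[`, character(1), "sequence")
  out$frame <- vapply(res[ok], `[[`, integer(1), "frame")
  rownames(out) <- NULL
  rejected <- data.frame(
    clone_id = records$clone_id[!ok],
    reason = vapply(res[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  list(records = out, rejected = rejected)
}

## Vectorized identity of one query against many references via the
## compiled Gotoh aligner; exact string equality short-circuits.
identity_to_many <- function(query, refs, scoring) {
  .nw_identity_many(query, refs, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
}

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 5, gap_extend = 2)
}

#' Pairwise percent identity from global alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults: match +1,
#' mismatch -1, gap open 5, gap extend 2, as costs; a gap run of length k
#' costs open + k * extend), identity computed as matching columns over
#' alignment columns excluding end-gap runs. The result is symmetric: the
#' two sequences are ordered canonically before alignment so
#' `pairwise_identity(a, b) == pairwise_identity(b, a)`.
#'
#' @param a,b nucleotide strings (non-empty).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param details if `TRUE`, return a list with `score`, `identity` and
#'   `columns` (alignment columns kept after end-gap exclusion) instead of
#'   the bare identity.
#' @return Identity fraction in \[0, 1\], or a detail list.
#' @export
pairwise_identity <- function(a, b, scoring = default_scoring(),
                              details = FALSE) {
  if (!nzchar(a) || !nzchar(b)) {
    stop_scatyper("sequences must be non-empty", "scatyper_invalid_input")
  }
  if (a > b) { tmp <- a; a <- b; b <- tmp }   # canonical order for symmetry
  res <- .nw_align(a, b, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  if (details) res else res$identity
}

#' Greedy percent-identity clustering (FastGroup dialect)
#'
#' Processes records in input order. Each record is compared to the
#' founders of existing bins in bin-creation order and joins the FIRST bin
#' whose founder identity meets the threshold; otherwise it founds a new
#' bin. Bins are named by their founder's clone id. Deterministic for a
#' fixed input order; exact duplicate sequences are memoized so identical
#' clones never re-align.
#'
#' @param records data frame with `clone_id` and `sequence`, or a named
#'   character vector of sequences.
#' @param threshold percent identity in (0, 100].
#' @param scoring alignment scoring, see [pairwise_identity()].
#' @param identity_fun optional function `(query, founders) -> numeric`
#'   returning identities in \[0, 1\]; replaces the aligner (used for
#'   testing the greedy rule in isolation).
#' @return Object of class `cluster_set`: `threshold`, `bins` (list of
#'   `name`, `founder_id`, `members`), `s_obs`, `sizes`, `assignments`
#'   (named bin per clone id).
#' @export
greedy_cluster <- function(records, threshold, scoring = default_scoring(),
                           identity_fun = NULL) {
  if (!(threshold > 0 && threshold <= 100)) {
    stop_scatyper("threshold must lie in (0, 100]",
                  "scatyper_invalid_parameter")
  }
  if (!is.data.frame(records)) {
    records <- data.frame(clone_id = names(records),
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  thr <- threshold / 100
  founders <- character(0)
  founder_ids <- character(0)
  members <- list()
  memo <- new.env(parent = emptyenv())
  assignments <- character(nrow(records))
  idfun <- if (is.null(identity_fun)) {
    function(q) identity_to_many(q, founders, scoring)
  } else {
    function(q) identity_fun(q, founders)
  }
  for (r in seq_len(nrow(records))) {
    seq_r <- records$sequence[r]
    bin <- memo[[seq_r]]
    if (is.null(bin)) {
      if (length(founders)) {
        ident <- idfun(seq_r)
        hit <- which(ident >= thr - 1e-12)
        bin <- if (length(hit)) hit[1] else 0L
      } else {
        bin <- 0L
      }
      if (bin == 0L) {
        founders <- c(founders, seq_r)
        founder_ids <- c(founder_ids, records$clone_id[r])
        members[[length(members) + 1L]] <- character(0)
        bin <- length(founders)
      }
      memo[[seq_r]] <- bin
    }
    members[[bin]] <- c(members[[bin]], records$clone_id[r])
    assignments[r] <- founder_ids[bin]
  }
  names(assignments) <- records$clone_id
  bins <- lapply(seq_along(founders), function(b) {
    list(name = founder_ids[b], founder_id = founder_ids[b],
         founder_sequence = founders[b], members = members[[b]])
  })
  structure(list(
    threshold = threshold, bins = bins, s_obs = length(bins),
    sizes = vapply(bins, function(b) length(b$members), integer(1)),
    assignments = assignments
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Greedy clustering at %g%% identity: %d bins / %d sequences\n",
              x$threshold, x$s_obs, sum(x$sizes)))
  invisible(x)
}

#' Identity-threshold sweep with diversity estimates
#'
#' Runs [greedy_cluster()] at each threshold on the same input order and
#' attaches Chao1 (classic, with bias-corrected fallback), the
#' bias-corrected Chao1, and the Shannon-Wiener index computed on the bin
#' size distribution, yielding the familiar clustering-statistics summary
#' (thresholds as columns in the printed form).
#'
#' @param records as for [greedy_cluster()].
#' @param thresholds percent identities (default 99, 90, 80, 70, 60, 50, 40).
#' @param scoring alignment scoring.
#' @param identity_fun see [greedy_cluster()].
#' @return List with `table` (data frame: threshold, n_sequences, s_obs,
#'   chao1, chao1_bc, shannon) and `clusters` (named list of `cluster_set`
#'   objects keyed by threshold).
#' @export
threshold_sweep <- function(records,
                            thresholds = c(99, 90, 80, 70, 60, 50, 40),
                            scoring = default_scoring(),
                            identity_fun = NULL) {
  if (!is.data.frame(records)) {
    records <- data.frame(clone_id = names(records),
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  if (nrow(records) < 1L) {
    stop_scatyper("need at least one record", "scatyper_invalid_input")
  }
  clusters <- list()
  rows <- lapply(thresholds, function(t) {
    cs <- greedy_cluster(records, t, scoring, identity_fun)
    clusters[[as.character(t)]] <<- cs
    data.frame(
      threshold = t,
      n_sequences = nrow(records),
      s_obs = cs$s_obs,
      chao1 = chao1(cs$sizes),
      chao1_bc = chao1(cs$sizes, bias_corrected = TRUE),
      shannon = shannon_index(cs$sizes)
    )
  })
  list(table = do.call(rbind, rows), clusters = clusters)
}

#' Universal-type summary across animals
#'
#' Maps every clustered clone to its sample and animal, counts each type
#' per animal and per design factor, and identifies the universal types:
#' those observed in every animal. Also reports, per animal, the fraction
#' of its clones accounted for by universal types.
#'
#' @param clusters a `cluster_set` from [greedy_cluster()].
#' @param clone_samples named vector mapping clone id to sample id (e.g.
#'   built from the clone library's `clone_id`/`sample_id` columns).
#' @param metadata sample metadata data frame with `sample_id`, `animal`
#'   and optionally `week`, `hour`, `fraction`.
#' @return Object of class `universal_summary`: `type_by_animal` count
#'   matrix, `universal_types`, `universal_share` per animal, and
#'   `type_by_factor` (list of count matrices per available factor).
#' @export
universal_types <- function(clusters, clone_samples, metadata) {
  stopifnot(inherits(clusters, "cluster_set"))
  clone_ids <- unlist(lapply(clusters$bins, `[[`, "members"))
  type_of <- rep(vapply(clusters$bins, `[[`, character(1), "name"),
                 clusters$sizes)
  missing <- setdiff(clone_ids, names(clone_samples))
  if (length(missing)) {
    stop_scatyper(
      sprintf("clone id(s) with no sample mapping: %s",
              paste(head(missing, 5), collapse = ", ")),
      "scatyper_consistency_error", offenders = missing
    )
  }
  samp <- clone_samples[clone_ids]
  meta_missing <- setdiff(unique(samp), metadata$sample_id)
  if (length(meta_missing)) {
    stop_scatyper(
      sprintf("sample(s) missing from metadata: %s",
              paste(meta_missing, collapse = ", ")),
      "scatyper_consistency_error", offenders = meta_missing
    )
  }
  idx <- match(samp, metadata$sample_id)
  animal <- as.character(metadata$animal[idx])
  type_by_animal <- table(type = type_of, animal = animal)
  universal <- rownames(type_by_animal)[
    apply(type_by_animal > 0, 1, all)
  ]
  share <- vapply(colnames(type_by_animal), function(a) {
    tot <- sum(type_by_animal[, a])
    if (tot == 0) return(NA_real_)
    sum(type_by_animal[universal, a]) / tot
  }, numeric(1))
  factors <- intersect(c("fraction", "week", "hour"), names(metadata))
  type_by_factor <- lapply(factors, function(f) {
    table(type = type_of, level = as.character(metadata[[f]][idx]))
  })
  names(type_by_factor) <- factors
  structure(list(
    threshold = clusters$threshold,
    type_by_animal = type_by_animal,
    universal_types = universal,
    universal_share = share,
    type_by_factor = type_by_factor
  ), class = "universal_summary")
}

#' @export
print.universal_summary <- function(x, ...) {
  cat(sprintf("Universal-type summary at %g%% identity\n", x$threshold))
  cat(sprintf("  %d types, %d universal (seen in all %d animals)\n",
              nrow(x$type_by_animal), length(x$universal_types),
              ncol(x$type_by_animal)))
  cat("  universal share per animal:\n")
  print(round(x$universal_share, 3))
  invisible(x)
}
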