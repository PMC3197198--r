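## End-to-end workflows: the T-RFLP community analysis (normalize ->
## feature matrix -> square root -> Bray-Curtis -> NMDS/ANOSIM/SIMPER per
## week), the clone-library typing workflow (trim -> threshold sweep ->
## universal types -> translation and motif scan), and a UPGMA dendrogram
## for heatmap row ordering. All CSV/JSON outputs are optional: pass an
## output directory to persist the result bundle and a JSON run manifest.

check_metadata <- function(sample_ids, metadata) {
  missing <- setdiff(sample_ids, metadata$sample_id)
  if (length(missing)) {
    stop_scatyper(
      sprintf("sample(s) missing from metadata: %s",
              paste(missing, collapse = ", ")),
      "scatyper_consistency_error", offenders = missing
    )
  }
  invisible(TRUE)
}

write_manifest <- function(out_dir, params) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the T-RFLP community analysis workflow
#'
#' For each enzyme's peak tables: normalize profiles across all samples
#' (single-pass scaling with the detection cutoff), bin into a feature
#' matrix, square-root transform, then per week build the 12-sample
#' Bray-Curtis matrix and run NMDS, one-way ANOSIM for each factor
#' (pairwise breakdown for the animal factor) and SIMPER between
#' fractions. Deterministic for a fixed seed.
#'
#' @param peak_tables named list: one entry per enzyme, each a named list
#'   of peak tables (or a path to a peak-table CSV).
#' @param metadata sample metadata with `sample_id`, `animal`, `week`,
#'   `hour`, `fraction`.
#' @param cutoff_rfu detection cutoff (default 25).
#' @param bin_width_bp fragment bin width (default 1).
#' @param n_permutations ANOSIM permutations (default 999; the 16S analyses
#'   in the source design used 10000).
#' @param n_starts NMDS random starts (default 200).
#' @param factors factors to test (default animal, hour, fraction).
#' @param seed integer seed.
#' @param output_dir optional directory for CSV outputs and the manifest.
#' @return Nested list `results[[enzyme]][[week]]` with `distance`, `nmds`,
#'   `anosim` (per factor), `simper` (fraction contrast), plus per-enzyme
#'   `feature_matrix` and `normalization` report, and an `anosim_table`
#'   data frame shaped week x factor x enzyme.
#' @export
run_trflp_pipeline <- function(peak_tables, metadata, cutoff_rfu = 25,
                               bin_width_bp = 1.0, n_permutations = 999,
                               n_starts = 200,
                               factors = c("animal", "hour", "fraction"),
                               seed = 1L, output_dir = NULL) {
  results <- list()
  anosim_rows <- list()
  for (enzyme in names(peak_tables)) {
    tabs <- peak_tables[[enzyme]]
    if (is.character(tabs) && length(tabs) == 1L) {
      tabs <- read_peak_table(tabs)
    }
    check_metadata(names(tabs), metadata)
    norm <- normalize_profiles(tabs, cutoff_rfu)
    fm <- build_feature_matrix(norm, bin_width_bp)
    fm_t <- sqrt_transform(fm)
    meta <- metadata[match(rownames(fm), metadata$sample_id), ]
    enz_res <- list(feature_matrix = fm, normalization = norm$report)
    for (wk in sort(unique(meta$week))) {
      keep <- meta$week == wk
      sub <- fm_t[keep, colSums(fm_t[keep, , drop = FALSE]) > 0,
                  drop = FALSE]
      sub_meta <- meta[keep, ]
      d <- bray_curtis(sub)
      ord <- nmds(d, n_starts = n_starts,
                  seed = substream_seed(seed, paste0("nmds/", enzyme, wk)))
      an <- lapply(factors, function(f) {
        anosim(d, setNames(as.character(sub_meta[[f]]), sub_meta$sample_id),
               n_permutations = n_permutations,
               seed = substream_seed(seed, paste0("anosim/", enzyme, wk, f)),
               pairwise = f == "animal")
      })
      names(an) <- factors
      sp <- simper(sub, sub_meta$fraction,
                   pair = sort(unique(sub_meta$fraction)))
      enz_res[[paste0("week", wk)]] <- list(
        distance = d, nmds = ord, anosim = an, simper = sp
      )
      for (f in factors) {
        anosim_rows[[length(anosim_rows) + 1L]] <- data.frame(
          enzyme = enzyme, week = wk, factor = f,
          R = an[[f]]$statistic, p_value = an[[f]]$p_value,
          stringsAsFactors = FALSE
        )
      }
    }
    results[[enzyme]] <- enz_res
  }
  anosim_table <- do.call(rbind, anosim_rows)
  out <- list(results = results, anosim_table = anosim_table,
              parameters = list(cutoff_rfu = cutoff_rfu,
                                bin_width_bp = bin_width_bp,
                                n_permutations = n_permutations,
                                n_starts = n_starts, seed = seed))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(anosim_table, file.path(output_dir, "anosim_results.csv"),
              row.names = FALSE)
    for (enzyme in names(results)) {
      write.csv(as.data.frame(results[[enzyme]]$feature_matrix),
                file.path(output_dir, sprintf("feature_matrix_%s.csv",
                                              enzyme)))
      for (wk in grep("^week", names(results[[enzyme]]), value = TRUE)) {
        r <- results[[enzyme]][[wk]]
        write.csv(r$nmds$points,
                  file.path(output_dir,
                            sprintf("nmds_%s_%s.csv", enzyme, wk)))
        write.csv(r$simper$top10,
                  file.path(output_dir,
                            sprintf("simper_%s_%s.csv", enzyme, wk)),
                  row.names = FALSE)
      }
    }
    write_manifest(output_dir, out$parameters)
  }
  out
}

#' Run the clone-library typing workflow
#'
#' Chains ORF trimming, the identity-threshold sweep, the universal-type
#' summary at the focal threshold, and translation plus dockerin repeat
#' detection of each type's founder sequence.
#'
#' @param records clone records (data frame with `clone_id`, `sample_id`,
#'   `sequence`) or a path to a clone FASTA whose ids encode the sample as
#'   `<sample_id>_<serial>`.
#' @param metadata sample metadata (see [universal_types()]).
#' @param thresholds sweep thresholds (default 99...40).
#' @param focal_threshold threshold defining the types (default 70).
#' @param scoring alignment scoring for identity.
#' @param output_dir optional output directory.
#' @return List with `trim` (rejection report), `sweep` (threshold table),
#'   `clusters` (the focal `cluster_set`), `universal` (summary),
#'   `founders` (translated founder proteins) and `motifs` (per-type
#'   dockerin hit table).
#' @export
run_clone_pipeline <- function(records, metadata,
                               thresholds = c(99, 90, 80, 70, 60, 50, 40),
                               focal_threshold = 70,
                               scoring = default_scoring(),
                               output_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    seqs <- read_fasta(records)
    ids <- sub("\\s.*$", "", names(seqs))
    records <- data.frame(
      clone_id = ids,
      sample_id = sub("_[0-9]+$", "", ids),
      sequence = unname(seqs),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(records) == 0L) {
    stop_scatyper("no clone sequences supplied", "scatyper_empty_input")
  }
  check_metadata(unique(records$sample_id), metadata)
  trim <- trim_library(records)
  if (nrow(trim$records) == 0L) {
    stop_scatyper("all sequences rejected at ORF trimming",
                  "scatyper_empty_input")
  }
  if (!focal_threshold %in% thresholds) {
    thresholds <- sort(c(thresholds, focal_threshold), decreasing = TRUE)
  }
  sweep <- threshold_sweep(trim$records, thresholds, scoring)
  focal <- sweep$clusters[[as.character(focal_threshold)]]
  clone_samples <- setNames(trim$records$sample_id, trim$records$clone_id)
  universal <- universal_types(focal, clone_samples, metadata)
  founders <- vapply(focal$bins, function(b) {
    s <- b$founder_sequence
    translate_orf(substr(s, 1, 3 * (nchar(s) %/% 3)))
  }, character(1))
  names(founders) <- vapply(focal$bins, `[[`, character(1), "name")
  motif_rows <- lapply(names(founders), function(ty) {
    hit <- find_dockerin_repeats(founders[[ty]])
    data.frame(type = ty, found = isTRUE(hit$found),
               repeat1 = hit$repeat1 %||% NA_integer_,
               repeat2 = hit$repeat2 %||% NA_integer_,
               score = if (is.finite(hit$score %||% NA)) hit$score else NA,
               stringsAsFactors = FALSE)
  })
  motifs <- do.call(rbind, motif_rows)
  out <- list(trim = trim$rejected, sweep = sweep$table,
              clusters = focal, universal = universal,
              founders = founders, motifs = motifs)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sweep$table, file.path(output_dir, "threshold_sweep.csv"),
              row.names = FALSE)
    members <- data.frame(
      clone_id = names(focal$assignments),
      type = unname(focal$assignments), stringsAsFactors = FALSE
    )
    write.csv(members, file.path(output_dir, "cluster_members.csv"),
              row.names = FALSE)
    write.csv(as.data.frame.matrix(universal$type_by_animal),
              file.path(output_dir, "type_by_animal.csv"))
    write.csv(motifs, file.path(output_dir, "dockerin_hits.csv"),
              row.names = FALSE)
    write_manifest(output_dir, list(
      thresholds = thresholds, focal_threshold = focal_threshold,
      n_input = nrow(records), n_trimmed = nrow(trim$records)
    ))
  }
  out
}

#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted pair-group agglomeration giving an ultrametric
#' tree (all root-to-leaf path lengths equal). Leaves are pre-sorted
#' lexicographically so equal-distance merges resolve deterministically.
#'
#' @param d symmetric distance matrix with row/col names.
#' @param file optional path; when given the tree is also written as
#'   Newick.
#' @return An `ape::phylo` tree.
#' @export
upgma_tree <- function(d, file = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) {
    stop_scatyper("need at least 2 leaves", "scatyper_invalid_input")
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(file)) ape::write.tree(tree, file)
  tree
}
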