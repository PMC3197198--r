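## Scaffoldin motif analysis: ORF translation, detection of the duplicated
## 22-residue dockerin repeat within a ~70-residue module, and per-column
## conservation profiling of aligned protein families.

#' Translate a trimmed open reading frame
#'
#' Standard-genetic-code translation of an in-frame nucleotide sequence.
#' Codons containing any non-ACGT character translate to `X`. A stop codon
#' anywhere in the frame is an error naming the codon position, since
#' trimmed ORFs must be stop-free.
#'
#' @param sequence nucleotide string with length divisible by 3.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_orf("ATGAAA")  # "MK"
translate_orf <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop_scatyper("sequence length must be a positive multiple of 3",
                  "scatyper_invalid_input")
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(codons %in% names(code), code[codons], "X")
  stops <- which(aa == "*")
  if (length(stops)) {
    stop_scatyper(
      sprintf("internal stop codon at codon %d", stops[1]),
      "scatyper_translation_error", codon = stops[1]
    )
  }
  paste(aa, collapse = "")
}

## Default repeat-pair score threshold: the score a pair of 22-mers with
## 40% identical positions achieves in expectation under BLOSUM62, using
## the mean diagonal (match) and mean off-diagonal (mismatch) over the 20
## standard residues.
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

default_repeat_threshold <- function(repeat_length = 22L,
                                     identity_fraction = 0.4) {
  m <- blosum62_matrix()
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  m <- m[aa, aa]
  mean_match <- mean(diag(m))
  mean_mismatch <- mean(m[row(m) != col(m)])
  round(repeat_length * (identity_fraction * mean_match +
                           (1 - identity_fraction) * mean_mismatch))
}

#' Detect the duplicated 22-residue dockerin repeat
#'
#' Dockerin modules carry a duplicated ~22-amino-acid repeat within a
#' module of roughly 70 residues. This scans all pairs of 22-residue
#' windows whose start-to-start spacing lies in `spacing` (default 22-48,
#' so both repeats fit inside ~70 residues), scores each pair by the
#' summed BLOSUM62 similarity of aligned positions, and returns the best
#' pair if it meets `min_score`.
#'
#' @param protein amino-acid string.
#' @param spacing integer pair: allowed start-to-start spacing range.
#' @param min_score score threshold; the default is the expected BLOSUM62
#'   score of a 22-mer pair with 40% identical residues.
#' @param repeat_length repeat window length (default 22).
#' @return Object of class `dockerin_hit`: `found` flag, `repeat1` and
#'   `repeat2` (1-based start positions), `spacing`, `score`, `threshold`;
#'   or `found = FALSE` with reason `"too short"` when the protein cannot
#'   hold two windows at the minimum spacing.
#' @export
find_dockerin_repeats <- function(protein, spacing = c(22L, 48L),
                                  min_score = NULL, repeat_length = 22L) {
  if (is.null(min_score)) min_score <- default_repeat_threshold(repeat_length)
  L <- nchar(protein)
  need <- spacing[1] + repeat_length
  if (L < need) {
    return(structure(list(found = FALSE, reason = "too short",
                          protein_length = L, threshold = min_score),
                     class = "dockerin_hit"))
  }
  m <- blosum62_matrix()
  chars <- strsplit(protein, "")[[1]]
  chars[!chars %in% rownames(m)] <- "X"
  best <- list(score = -Inf)
  for (i in seq_len(L - need + 1L)) {
    j_max <- min(i + spacing[2], L - repeat_length + 1L)
    j_min <- i + spacing[1]
    if (j_min > j_max) next
    w1 <- chars[i:(i + repeat_length - 1L)]
    for (j in j_min:j_max) {
      w2 <- chars[j:(j + repeat_length - 1L)]
      sc <- sum(m[cbind(w1, w2)])
      if (sc > best$score) best <- list(score = sc, i = i, j = j)
    }
  }
  structure(list(
    found = is.finite(best$score) && best$score >= min_score,
    repeat1 = best$i, repeat2 = best$j,
    spacing = if (!is.null(best$j)) best$j - best$i else NA_integer_,
    score = best$score, threshold = min_score,
    repeat_length = repeat_length
  ), class = "dockerin_hit")
}

#' @export
print.dockerin_hit <- function(x, ...) {
  if (isTRUE(x$found)) {
    cat(sprintf(
      "Dockerin repeat pair: positions %d and %d (spacing %d), score %g (>= %g)\n",
      x$repeat1, x$repeat2, x$spacing, x$score, x$threshold))
  } else {
    cat(sprintf("No dockerin repeat pair found (%s)\n",
                if (!is.null(x$reason)) x$reason else
                  sprintf("best score %g < %g", x$score, x$threshold)))
  }
  invisible(x)
}

#' Per-column conservation of an aligned protein family
#'
#' For each alignment column, conservation is the frequency of the modal
#' non-gap residue among non-gap rows. Columns that are all gaps are
#' `NA` (undefined).
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (gaps as `-`), or an `AAStringSet`.
#' @return Numeric vector of conservation values in \[0, 1\] (or `NA`).
#' @export
conservation_profile <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop_scatyper("ragged alignment: rows differ in length",
                  "scatyper_invalid_input")
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  apply(mat, 2, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(NA_real_)
    max(table(res)) / length(res)
  })
}

#' Mean conservation per region and contrasts
#'
#' Averages the defined (non-`NA`) columns of a conservation profile over
#' labeled regions and reports all pairwise differences -- e.g. the
#' cohesin-conserved versus dockerin-second-repeat contrast.
#'
#' @param profile output of [conservation_profile()].
#' @param regions named list of 1-based inclusive `c(start, end)` pairs.
#' @return List with `means` (named numeric) and `contrasts` (data frame
#'   of region pairs and mean differences).
#' @export
region_conservation_contrast <- function(profile, regions) {
  stopifnot(length(regions) >= 1L, !is.null(names(regions)))
  means <- vapply(names(regions), function(nm) {
    r <- regions[[nm]]
    if (r[1] < 1 || r[2] > length(profile) || r[1] > r[2]) {
      stop_scatyper(sprintf("region '%s' outside profile or empty", nm),
                    "scatyper_invalid_parameter")
    }
    mean(profile[r[1]:r[2]], na.rm = TRUE)
  }, numeric(1))
  contrasts <- NULL
  if (length(means) >= 2L) {
    combos <- combn(names(means), 2L, simplify = FALSE)
    contrasts <- do.call(rbind, lapply(combos, function(p) {
      data.frame(region1 = p[1], region2 = p[2],
                 difference = means[[p[1]]] - means[[p[2]]],
                 stringsAsFactors = FALSE)
    }))
  }
  list(means = means, contrasts = contrasts)
}
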