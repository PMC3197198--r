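## In-silico digestion: degenerate-primer amplicon detection, restriction-site
## scanning, labeled-end terminal restriction fragment (TRF) prediction and
## multi-enzyme fragment-to-taxon assignment in the style of the phylogenetic
## assignment tool (PAT) used for T-RFLP community fingerprints.

#' Construct a labeled primer
#'
#' A primer is an IUPAC nucleotide string optionally carrying a fluorescent
#' dye on its 5' end. In the T-RFLP design modeled here the forward primer is
#' NED-labeled and the reverse primer 6FAM-labeled, so each electropherogram
#' dye channel reads out one labeled end of the amplicon.
#'
#' @param name primer name.
#' @param sequence IUPAC nucleotide string (degenerate codes allowed).
#' @param label dye name (e.g. `"NED"`, `"6FAM"`) or `NA` for unlabeled.
#' @return An object of class `primer`.
#' @export
#' @examples
#' primer("ScaFwd", "AGACARGRTATAATHAAAGGGGC", "NED")
primer <- function(name, sequence, label = NA_character_) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop_scatyper("primer sequence must be non-empty", "scatyper_format_error")
  }
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% names(Biostrings::IUPAC_CODE_MAP))) {
    stop_scatyper(
      sprintf("primer '%s' contains non-IUPAC characters", name),
      "scatyper_format_error"
    )
  }
  structure(list(name = name, sequence = sequence, label = label),
            class = "primer")
}

#' Built-in primer pairs
#'
#' The two marker systems supported out of the box: the bacterial 16S rRNA
#' gene (8F/926R) and the scaC scaffoldin gene (ScaFwd/ScaRev). Forward
#' primers carry NED, reverse primers 6FAM.
#'
#' @return A named list with elements `fwd` and `rev`, each a [primer()].
#' @export
scac_primers <- function() {
  list(
    fwd = primer("ScaFwd", "AGACARGRTATAATHAAAGGGGC", "NED"),
    rev = primer("ScaRev", "GGGTTTKTATTCCTTTGTAAG", "6FAM")
  )
}

#' @rdname scac_primers
#' @export
rrna16s_primers <- function() {
  list(
    fwd = primer("8F", "AGAGTTTGATCCTGGCTCAG", "NED"),
    rev = primer("926R", "CCGTCAATTCCTTTRAGTTT", "6FAM")
  )
}

#' Built-in restriction enzyme table
#'
#' The five 4-cutters used for T-RFLP of the 16S rRNA gene (AluI, HhaI, MspI)
#' and the scaC gene (AluI, HaeIII, MspI, RsaI). Cut offsets are the standard
#' top-strand positions: AluI AG^CT, HhaI GCG^C, MspI C^CGG, HaeIII GG^CC,
#' RsaI GT^AC. All five sites are palindromic, so a single-strand scan finds
#' every cut.
#'
#' @param name optional enzyme name; if given, the single matching row is
#'   returned as a list.
#' @return A data frame with columns `enzyme`, `site`, `cut_offset`, or a
#'   single-enzyme list when `name` is supplied.
#' @export
restriction_enzymes <- function(name = NULL) {
  tab <- data.frame(
    enzyme = c("AluI", "HhaI", "MspI", "HaeIII", "RsaI"),
    site = c("AGCT", "GCGC", "CCGG", "GGCC", "GTAC"),
    cut_offset = c(2L, 3L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$enzyme == name, ]
  if (nrow(row) != 1L) {
    stop_scatyper(sprintf("unknown enzyme '%s'", name),
                  "scatyper_invalid_parameter")
  }
  as.list(row)
}

#' Match a degenerate primer against a template strand
#'
#' Scans the given strand only (the caller reverse-complements for the other
#' strand). A primer base matches a template base when their IUPAC sets
#' intersect, so primer degeneracy (R, H, K, ...) is honored and template
#' `N`s match everything. Up to `max_mismatches` incompatible positions are
#' tolerated.
#'
#' @param sequence template nucleotide string.
#' @param primer a [primer()] object (or plain IUPAC string).
#' @param max_mismatches maximum number of incompatible positions (>= 0).
#' @return Integer vector of 0-based match start positions.
#' @export
match_degenerate_primer <- function(sequence, primer, max_mismatches = 0L) {
  if (is.character(primer)) primer <- primer("ad-hoc", primer)
  stopifnot(max_mismatches >= 0)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq_chars %in% names(Biostrings::IUPAC_CODE_MAP))) {
    stop_scatyper("template contains non-IUPAC characters",
                  "scatyper_format_error")
  }
  if (nchar(primer$sequence) > nchar(sequence)) return(integer(0))
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer$sequence),
    Biostrings::DNAString(toupper(sequence)),
    max.mismatch = max_mismatches, fixed = FALSE
  )
  as.integer(Biostrings::start(hits) - 1L)
}

#' Extract the amplicon delimited by a labeled primer pair
#'
#' Finds the forward primer on the given strand and the reverse primer as its
#' reverse complement, and returns the span from the 5' end of the forward
#' match through the 3' end of the reverse-primer site. When several primer
#' placements yield a valid amplicon the shortest is returned and the result
#' is flagged as multiple.
#'
#' @param sequence template nucleotide string.
#' @param fwd,rev forward and reverse [primer()]s.
#' @param max_mismatches mismatches tolerated per primer site.
#' @return An object of class `amplicon`: list with `sequence`, `start`
#'   (0-based on the template), `length`, dye labels for either end, and
#'   `multiple` flag.
#' @export
extract_amplicon <- function(sequence, fwd, rev, max_mismatches = 0L) {
  f_hits <- match_degenerate_primer(sequence, fwd, max_mismatches)
  if (length(f_hits) == 0L) {
    stop_scatyper(
      sprintf("no match for forward primer '%s'", fwd$name),
      "scatyper_no_amplicon_error", primer = fwd$name
    )
  }
  rev_rc <- primer(rev$name, reverse_complement(rev$sequence), rev$label)
  r_hits <- match_degenerate_primer(sequence, rev_rc, max_mismatches)
  if (length(r_hits) == 0L) {
    stop_scatyper(
      sprintf("no match for reverse primer '%s'", rev$name),
      "scatyper_no_amplicon_error", primer = rev$name
    )
  }
  r_len <- nchar(rev$sequence)
  f_len <- nchar(fwd$sequence)
  cand <- expand.grid(f = f_hits, r = r_hits)
  cand$end <- cand$r + r_len                    # 0-based half-open end
  cand <- cand[cand$end - cand$f >= f_len + r_len, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop_scatyper(
      sprintf("primers '%s'/'%s' do not delimit an amplicon",
              fwd$name, rev$name),
      "scatyper_no_amplicon_error", primer = rev$name
    )
  }
  cand$len <- cand$end - cand$f
  best <- cand[which.min(cand$len), ]
  structure(list(
    sequence = substr(sequence, best$f + 1L, best$end),
    start = as.integer(best$f),
    length = as.integer(best$len),
    forward_label = fwd$label,
    reverse_label = rev$label,
    multiple = nrow(cand) > 1L
  ), class = "amplicon")
}

#' Restriction cut positions on one strand
#'
#' Returns the sorted 0-based between-base cut coordinates for every
#' (possibly overlapping) occurrence of the recognition site. All built-in
#' sites are palindromic, so scanning the given strand finds all cuts.
#'
#' @param sequence nucleotide string.
#' @param enzyme enzyme name (see [restriction_enzymes()]) or a list with
#'   `site` and `cut_offset`.
#' @return Sorted integer vector of cut coordinates (may be empty).
#' @export
#' @examples
#' cut_positions("TTAGCTTT", "AluI")  # 4
cut_positions <- function(sequence, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzymes(enzyme)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$site),
    Biostrings::DNAString(toupper(sequence))
  )
  sort(as.integer(Biostrings::start(hits) - 1L + enzyme$cut_offset))
}

#' Predict labeled-end terminal restriction fragments
#'
#' For a dye-labeled amplicon, the observable T-RFLP signal in each channel
#' is the distance from the labeled 5' base to the first restriction cut.
#' The forward TRF is measured from position 0 of the amplicon; the reverse
#' TRF from the 5' end of its reverse complement. An end with no cut reports
#' the full amplicon length and is flagged uncut.
#'
#' @param amplicon an [extract_amplicon()] result, or a plain nucleotide
#'   string (treated as labeled on both ends).
#' @param enzyme enzyme name or list (see [cut_positions()]).
#' @return A one-row data frame with `enzyme`, `forward_trf`, `reverse_trf`,
#'   `forward_uncut`, `reverse_uncut`, `amplicon_length`.
#' @export
predict_trf <- function(amplicon, enzyme) {
  seq <- if (inherits(amplicon, "amplicon")) amplicon$sequence else amplicon
  if (!nzchar(seq)) {
    stop_scatyper("empty amplicon", "scatyper_invalid_input")
  }
  if (is.character(enzyme)) enzyme <- restriction_enzymes(enzyme)
  len <- nchar(seq)
  cuts <- cut_positions(seq, enzyme)
  fwd <- if (length(cuts)) min(cuts) else len
  rev <- if (length(cuts)) len - max(cuts) else len
  data.frame(
    enzyme = enzyme$enzyme,
    forward_trf = as.integer(fwd),
    reverse_trf = as.integer(rev),
    forward_uncut = length(cuts) == 0L,
    reverse_uncut = length(cuts) == 0L,
    amplicon_length = as.integer(len),
    stringsAsFactors = FALSE
  )
}

#' Predict TRFs for a reference library
#'
#' Runs primer matching, amplicon extraction and TRF prediction for every
#' reference sequence over a set of enzymes. References in which either
#' primer fails to match are reported in the `skipped` attribute rather than
#' raising an error, mirroring how in-silico digest libraries are built from
#' heterogeneous full-length sequence collections.
#'
#' @param references named character vector (or `DNAStringSet`) of reference
#'   sequences; names may carry a taxonomy string after the first space.
#' @param fwd,rev primers.
#' @param enzymes character vector of enzyme names.
#' @param max_mismatches primer mismatches tolerated.
#' @return Data frame with one row per reference x enzyme: `reference_id`,
#'   `taxon`, `enzyme`, `forward_trf`, `reverse_trf`, uncut flags and
#'   amplicon length. Attribute `skipped` lists unamplified references.
#' @export
predict_trf_library <- function(references, fwd, rev,
                                enzymes = restriction_enzymes()$enzyme,
                                max_mismatches = 0L) {
  if (methods::is(references, "DNAStringSet")) {
    refs <- as.character(references)
  } else {
    refs <- references
  }
  ids <- sub("\\s.*$", "", names(refs))
  taxa <- ifelse(grepl("\\s", names(refs)),
                 sub("^\\S+\\s+", "", names(refs)), ids)
  out <- list()
  skipped <- character(0)
  for (i in seq_along(refs)) {
    amp <- tryCatch(
      extract_amplicon(refs[[i]], fwd, rev, max_mismatches),
      scatyper_no_amplicon_error = function(e) NULL
    )
    if (is.null(amp)) {
      skipped <- c(skipped, ids[i])
      next
    }
    rows <- do.call(rbind, lapply(enzymes, function(e) predict_trf(amp, e)))
    rows <- cbind(reference_id = ids[i], taxon = taxa[i], rows)
    out[[length(out) + 1L]] <- rows
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(reference_id = character(0), taxon = character(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Assign observed T-RFLP fragments to reference taxa
#'
#' A fragment matches a reference when the observed size is within
#' `tolerance_bp` of the predicted TRF for the same enzyme and dye channel.
#' Equidistant or multiply-matching fragments keep their full candidate
#' taxon set (ambiguity is preserved, not resolved). A taxon enters the
#' profile-level consensus only when it is matched in every enzyme present
#' in the observations (multi-enzyme consensus).
#'
#' @param observed data frame with columns `enzyme`, `size_bp` and optionally
#'   `dye` (default forward/NED channel).
#' @param library output of [predict_trf_library()].
#' @param tolerance_bp half-width of the match window in bp (default 1.0).
#' @return List with `fragments` (per-fragment candidate taxa, comma
#'   separated; `"unclassified"` when none), `matched_fraction`, and
#'   `consensus_taxa`.
#' @export
assign_fragments <- function(observed, library, tolerance_bp = 1.0) {
  stopifnot(tolerance_bp >= 0)
  if (is.null(library) || nrow(library) == 0L) {
    stop_scatyper("empty TRF reference library", "scatyper_invalid_input")
  }
  if (is.null(observed$dye)) observed$dye <- "NED"
  pred_size <- function(rows, dye) {
    if (all(dye == "6FAM")) rows$reverse_trf else rows$forward_trf
  }
  frag_taxa <- vector("list", nrow(observed))
  for (k in seq_len(nrow(observed))) {
    rows <- library[library$enzyme == observed$enzyme[k], , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop_scatyper(
        sprintf("no TRF predictions for enzyme '%s'", observed$enzyme[k]),
        "scatyper_consistency_error"
      )
    }
    sizes <- if (observed$dye[k] == "6FAM") rows$reverse_trf else rows$forward_trf
    hit <- abs(sizes - observed$size_bp[k]) <= tolerance_bp
    frag_taxa[[k]] <- sort(unique(rows$taxon[hit]))
  }
  matched <- vapply(frag_taxa, length, integer(1)) > 0L
  enzymes_used <- unique(observed$enzyme)
  per_enzyme_taxa <- lapply(enzymes_used, function(e) {
    unique(unlist(frag_taxa[observed$enzyme == e & matched]))
  })
  consensus <- Reduce(intersect, per_enzyme_taxa)
  list(
    fragments = data.frame(
      enzyme = observed$enzyme,
      dye = observed$dye,
      size_bp = observed$size_bp,
      taxa = vapply(frag_taxa, function(x) {
        if (length(x)) paste(x, collapse = ",") else "unclassified"
      }, character(1)),
      matched = matched,
      stringsAsFactors = FALSE
    ),
    matched_fraction = mean(matched),
    consensus_taxa = sort(consensus)
  )
}
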