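## Synthetic-community generator: ground-truth type abundances under a
## crossed animal x week x hour x fraction design, type sequence families
## with a conserved cohesin region and a variable second dockerin repeat,
## multinomial clone libraries, and noisy electropherogram peak tables.
## The generator is first-class, tested code: it defines the statistical
## structure every downstream stage is validated against.

#' Full-crossing sampling design
#'
#' Enumerates the default rumen sampling design: 3 animals x 3 weeks x
#' 2 hours post-feeding x 2 fractions = 36 samples.
#'
#' @param animals,weeks,hours,fractions factor levels.
#' @return Data frame with `sample_id`, `animal`, `week`, `hour`, `fraction`.
#' @export
rumen_design <- function(animals = c(8, 64, 71), weeks = c(2, 5, 8),
                         hours = c(1, 9), fractions = c("fiber", "liquid")) {
  d <- expand.grid(animal = animals, week = weeks, hour = hours,
                   fraction = fractions, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d <- d[order(d$animal, d$week, d$hour, d$fraction), , drop = FALSE]
  d <- data.frame(
    sample_id = sprintf("A%s_W%s_H%s_%s", d$animal, d$week, d$hour,
                        substr(d$fraction, 1, 3)),
    d, stringsAsFactors = FALSE
  )
  rownames(d) <- NULL
  d
}

#' Simulate a ground-truth community
#'
#' Draws per-sample relative abundances for `k_types` marker gene types over
#' a crossed sampling design. Base abundances follow a geometric series with
#' decay `decay` (a few types dominate, as observed for real scaC
#' communities). Three effect layers act multiplicatively on the simplex,
#' followed by renormalization: a per-animal Dirichlet perturbation
#' (concentration `animal_concentration`; smaller = more between-animal
#' variation, and rare types can drop to effectively zero in an animal), a
#' per-type fraction-enrichment log-fold factor applied in fiber samples,
#' and a per-type week-succession log-slope applied per week index.
#'
#' @param k_types number of types (>= 1).
#' @param design sampling design data frame (see [rumen_design()]).
#' @param effects list with any of: `fraction_lfc` (numeric length-k vector,
#'   natural-log fold enrichment in fiber; drawn `N(0, fraction_lfc_sd)` if
#'   `NULL`), `fraction_lfc_sd` (default 2), `week_slope` (length-k vector or
#'   `NULL` to draw `N(0, week_slope_sd)`), `week_slope_sd` (default 0.5),
#'   `animal_concentration` (Dirichlet concentration, default 50).
#' @param decay geometric series decay in (0, 1]; 1 gives uniform base
#'   abundances (default 0.7).
#' @param seed integer master seed.
#' @return Object of class `community_truth`: list with `types`, `abundance`
#'   (samples x types matrix, rows on the simplex), `design`, `effects`
#'   (with the drawn values filled in) and `seed`.
#' @export
simulate_community <- function(k_types, design = rumen_design(),
                               effects = list(), decay = 0.7, seed = 1L) {
  if (!is_count(k_types)) {
    stop_scatyper("k_types must be a positive integer",
                  "scatyper_invalid_parameter")
  }
  stopifnot(decay > 0, decay <= 1)
  eff <- modifyList(list(
    fraction_lfc = NULL, fraction_lfc_sd = 2,
    week_slope = NULL, week_slope_sd = 0.5,
    animal_concentration = 50
  ), effects)
  if (!all(vapply(eff, function(x) is.null(x) || all(is.finite(x)),
                  logical(1)))) {
    stop_scatyper("effect sizes must be finite", "scatyper_invalid_parameter")
  }
  types <- sprintf("T%02d", seq_len(k_types))
  base <- decay ^ (seq_len(k_types) - 1)
  base <- base / sum(base)

  with_substream(seed, "community/effects", {
    if (is.null(eff$fraction_lfc)) {
      eff$fraction_lfc <- rnorm(k_types, 0, eff$fraction_lfc_sd)
    }
    if (is.null(eff$week_slope)) {
      eff$week_slope <- rnorm(k_types, 0, eff$week_slope_sd)
    }
  })
  stopifnot(length(eff$fraction_lfc) == k_types,
            length(eff$week_slope) == k_types)

  animals <- unique(design$animal)
  weeks <- sort(unique(design$week))
  animal_w <- with_substream(seed, "community/animals", {
    w <- vapply(animals, function(a) {
      g <- rgamma(k_types, shape = eff$animal_concentration * base)
      if (sum(g) == 0) g <- base          # degenerate draw guard
      g / sum(g)
    }, numeric(k_types))
    matrix(w, nrow = k_types, dimnames = list(types, as.character(animals)))
  })

  ab <- matrix(0, nrow(design), k_types,
               dimnames = list(design$sample_id, types))
  for (s in seq_len(nrow(design))) {
    wi <- match(design$week[s], weeks) - 1L
    a <- animal_w[, as.character(design$animal[s])] *
      exp(eff$fraction_lfc * (design$fraction[s] == "fiber")) *
      exp(eff$week_slope * wi)
    ab[s, ] <- a / sum(a)
  }
  structure(list(types = types, abundance = ab, design = design,
                 effects = eff, decay = decay, seed = seed),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("Simulated community truth\n")
  cat(sprintf("  %d types x %d samples (seed %d)\n",
              length(x$types), nrow(x$design), x$seed))
  cat(sprintf("  dominant type share (mean over samples): %.3f\n",
              mean(apply(x$abundance, 1, max))))
  invisible(x)
}

#' Sequence model for a family of marker gene types
#'
#' Defines the base amplicon all types are derived from: a concrete
#' realization of the forward primer, a conserved region (the N-terminal
#' cohesin module in the scaC interpretation), a variable region (the second
#' dockerin repeat), and the reverse complement of the reverse primer.
#' Coordinates are 0-based half-open on the amplicon.
#'
#' @param base_sequence amplicon nucleotide string; generated randomly
#'   between the primer realizations if `NULL`.
#' @param fwd,rev primers flanking the amplicon.
#' @param conserved_span,variable_span integer pairs `c(start, end)`;
#'   defaults place the conserved region right after the forward primer and
#'   the variable region downstream, disjoint from it.
#' @param between_type_substitution_rate per-site substitution probability
#'   in the variable span between types; the conserved span mutates at one
#'   tenth of this rate.
#' @param within_type_error_rate per-site substitution probability applied
#'   to individual clones (PCR/sequencing noise).
#' @param length total amplicon length when `base_sequence` is generated.
#' @param seed seed for base-sequence generation.
#' @return Object of class `type_sequence_model`.
#' @export
type_sequence_model <- function(base_sequence = NULL,
                                fwd = scac_primers()$fwd,
                                rev = scac_primers()$rev,
                                conserved_span = NULL,
                                variable_span = NULL,
                                between_type_substitution_rate = 0.3,
                                within_type_error_rate = 0.005,
                                length = 330L, seed = 1L) {
  rates <- c(between_type_substitution_rate, within_type_error_rate)
  if (any(rates < 0 | rates > 0.5)) {
    stop_scatyper("substitution rates must lie in [0, 0.5]",
                  "scatyper_invalid_parameter")
  }
  f_len <- nchar(fwd$sequence)
  r_len <- nchar(rev$sequence)
  orf_offset <- NULL
  if (is.null(base_sequence)) {
    ## Generated base amplicons are coding: ATG right after the forward
    ## primer, then stop-free sense codons up to the reverse-primer site,
    ## so ORF trimming recovers the amplicon body deterministically.
    base_sequence <- with_substream(seed, "model/base", {
      mid <- length - f_len - r_len - 3L
      stopifnot(mid > 3)
      body <- substr(random_codons(ceiling(mid / 3)), 1L, mid)
      paste0(instantiate_iupac(fwd$sequence), "ATG", body,
             reverse_complement(instantiate_iupac(rev$sequence)))
    })
    orf_offset <- f_len
  }
  len <- nchar(base_sequence)
  start_pad <- if (is.null(orf_offset)) 0L else 3L
  if (is.null(conserved_span)) {
    conserved_span <- c(f_len + start_pad,
                        min(f_len + start_pad + 90L, len - r_len))
  }
  if (is.null(variable_span)) {
    variable_span <- c(conserved_span[2] + 10L, len - r_len)
  }
  spans_ok <- function(sp) sp[1] >= 0 && sp[2] <= len && sp[1] < sp[2]
  if (!spans_ok(conserved_span) || !spans_ok(variable_span) ||
      max(conserved_span[1], variable_span[1]) <
      min(conserved_span[2], variable_span[2])) {
    stop_scatyper("spans must be disjoint intervals within the amplicon",
                  "scatyper_invalid_parameter")
  }
  if (length(match_degenerate_primer(base_sequence, fwd)) == 0L ||
      match_degenerate_primer(base_sequence, fwd)[1] != 0L) {
    stop_scatyper("base sequence must begin with the forward primer",
                  "scatyper_invalid_parameter")
  }
  rc <- primer(rev$name, reverse_complement(rev$sequence), rev$label)
  tail_hit <- match_degenerate_primer(base_sequence, rc)
  if (!length(tail_hit) || max(tail_hit) != len - r_len) {
    stop_scatyper(
      "base sequence must end with the reverse complement of the reverse primer",
      "scatyper_invalid_parameter"
    )
  }
  structure(list(
    base_sequence = base_sequence, fwd = fwd, rev = rev,
    conserved_span = as.integer(conserved_span),
    variable_span = as.integer(variable_span),
    orf_offset = if (is.null(orf_offset)) NA_integer_ else
      as.integer(orf_offset),
    between_type_substitution_rate = between_type_substitution_rate,
    within_type_error_rate = within_type_error_rate
  ), class = "type_sequence_model")
}

## Substitute each flagged site with a uniformly chosen different base.
## When orf_offset is given (0-based position of the start codon), a
## substitution that would create an in-frame stop codon is re-drawn from
## the remaining alternatives, so the reading frame stays stop-free
## (nonsense substitutions are rejected, as under purifying selection on a
## functional gene).
mutate_sites <- function(chars, idx, orf_offset = NULL) {
  if (!length(idx)) return(chars)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  for (i in idx) {
    alts <- sample(setdiff(bases, chars[i]))
    if (is.null(orf_offset) || (i - 1L) < orf_offset) {
      chars[i] <- alts[1L]
      next
    }
    c0 <- orf_offset + 3L * ((i - 1L - orf_offset) %/% 3L)  # codon start, 0-based
    pos <- c0 + 1:3
    if (max(pos) > length(chars)) {           # partial terminal codon
      chars[i] <- alts[1L]
      next
    }
    for (a in alts) {
      cand <- chars
      cand[i] <- a
      if (!paste(cand[pos], collapse = "") %in% stops) {
        chars[i] <- a
        break
      }
    }
  }
  chars
}

## Random in-frame coding sequence: n_codons draws from the 61 sense codons.
random_codons <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Simulate the sequences of each community type
#'
#' Each type is an independently mutated copy of the model's base amplicon:
#' sites in the variable span substitute with probability
#' `between_type_substitution_rate`, sites in the conserved span at one
#' tenth of that rate, and all other positions -- including both primer
#' sites -- are left intact.
#'
#' @param model a [type_sequence_model()].
#' @param k_types number of types.
#' @param seed integer seed.
#' @return Named character vector, one sequence per type id.
#' @export
simulate_type_sequences <- function(model, k_types, seed = 1L) {
  stopifnot(inherits(model, "type_sequence_model"), is_count(k_types))
  base_chars <- strsplit(model$base_sequence, "")[[1]]
  v_idx <- seq.int(model$variable_span[1] + 1L, model$variable_span[2])
  c_idx <- seq.int(model$conserved_span[1] + 1L, model$conserved_span[2])
  r <- model$between_type_substitution_rate
  off <- if (is.na(model$orf_offset)) NULL else model$orf_offset
  out <- with_substream(seed, "types/sequences", {
    vapply(seq_len(k_types), function(t) {
      chars <- base_chars
      chars <- mutate_sites(chars, v_idx[runif(length(v_idx)) < r], off)
      chars <- mutate_sites(chars, c_idx[runif(length(c_idx)) < r / 10], off)
      paste(chars, collapse = "")
    }, character(1))
  })
  names(out) <- sprintf("T%02d", seq_len(k_types))
  out
}

#' Simulate a clone library from a community
#'
#' For each sample, `depth` clones are drawn multinomially from the sample's
#' true type abundances, then per-site substitution errors are applied
#' (substitutions only; no indels, no chimeras). When a
#' [type_sequence_model()] is supplied, errors hit the model's mutable
#' spans at its `within_type_error_rate` and avoid creating in-frame stop
#' codons, so ORF trimming of the clones stays well defined; otherwise a
#' plain uniform per-site `error_rate` is applied across the whole
#' sequence. Clone ids encode the sample id as `<sample_id>_<serial>`.
#'
#' @param truth a [simulate_community()] result.
#' @param type_seqs named sequences from [simulate_type_sequences()].
#' @param depth clones per sample (>= 1).
#' @param model optional [type_sequence_model()]; when given its
#'   `within_type_error_rate`, spans and reading frame drive the error
#'   process.
#' @param error_rate per-site error probability for the plain mode
#'   (ignored when `model` is given; default 0).
#' @param seed integer seed.
#' @return Data frame with `clone_id`, `sample_id`, `type_id` (ground truth
#'   annotation) and `sequence`.
#' @export
simulate_clone_library <- function(truth, type_seqs, depth, model = NULL,
                                   error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"), is_count(depth))
  if (!all(truth$types %in% names(type_seqs))) {
    stop_scatyper("type_seqs is missing sequences for some community types",
                  "scatyper_consistency_error")
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "type_sequence_model"))
    error_rate <- model$within_type_error_rate
    site_idx <- c(seq.int(model$conserved_span[1] + 1L,
                          model$conserved_span[2]),
                  seq.int(model$variable_span[1] + 1L,
                          model$variable_span[2]))
    off <- if (is.na(model$orf_offset)) NULL else model$orf_offset
  } else {
    site_idx <- NULL                   # whole sequence
    off <- NULL
  }
  if (error_rate < 0 || error_rate > 0.5) {
    stop_scatyper("error_rate must lie in [0, 0.5]",
                  "scatyper_invalid_parameter")
  }
  samples <- rownames(truth$abundance)
  out <- with_substream(seed, "clones/library", {
    rows <- vector("list", length(samples))
    for (s in seq_along(samples)) {
      counts <- as.vector(rmultinom(1, depth, truth$abundance[s, ]))
      type_of <- rep(truth$types, counts)
      seqs <- vapply(type_of, function(t) {
        chars <- strsplit(type_seqs[[t]], "")[[1]]
        idx <- if (is.null(site_idx)) seq_along(chars) else site_idx
        hit <- idx[runif(length(idx)) < error_rate]
        paste(mutate_sites(chars, hit, off), collapse = "")
      }, character(1))
      rows[[s]] <- data.frame(
        clone_id = sprintf("%s_%03d", samples[s], seq_len(depth)),
        sample_id = samples[s],
        type_id = type_of,
        sequence = unname(seqs),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Simulate noisy T-RFLP peak tables
#'
#' Produces one electropherogram peak table per sample for a single enzyme
#' and the forward (NED) dye channel. The expected height of a type's peak
#' is its abundance times the per-sample total fluorescence (lognormal
#' multiplicative noise, mean-corrected); the observed size is the predicted
#' TRF plus Gaussian jitter; spurious baseline peaks are added at a Poisson
#' rate. Heights are rounded to positive integers (RFU); types whose
#' expected height rounds to zero emit no peak.
#'
#' @param truth a [simulate_community()] result.
#' @param trfs TRF predictions for the community types: output of
#'   [predict_trf_library()] (reference ids must be the type ids), or a data
#'   frame with `reference_id`, `enzyme`, `forward_trf`.
#' @param enzyme enzyme name to simulate.
#' @param noise list: `size_sd` (bp jitter, default 0.3), `height_sd`
#'   (lognormal sigma, default 0.3), `baseline_rate` (expected spurious
#'   peaks per sample, default 2), `total_fluorescence` (default 50000).
#' @param seed integer seed.
#' @return Named list of peak tables (data frames with `sample_id`, `dye`,
#'   `enzyme`, `size_bp`, `height_rfu`), one per sample.
#' @export
simulate_peak_tables <- function(truth, trfs, enzyme, noise = list(),
                                 seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  nz <- modifyList(list(size_sd = 0.3, height_sd = 0.3, baseline_rate = 2,
                        total_fluorescence = 50000), noise)
  if (any(unlist(nz) < 0)) {
    stop_scatyper("noise parameters must be non-negative",
                  "scatyper_invalid_parameter")
  }
  pred <- trfs[trfs$enzyme == enzyme, , drop = FALSE]
  if (nrow(pred) == 0L) {
    stop_scatyper(sprintf("no TRF predictions for enzyme '%s'", enzyme),
                  "scatyper_consistency_error")
  }
  trf_of <- stats::setNames(pred$forward_trf, pred$reference_id)
  if (!all(truth$types %in% names(trf_of))) {
    stop_scatyper("TRF predictions missing for some community types",
                  "scatyper_consistency_error")
  }
  samples <- rownames(truth$abundance)
  with_substream(seed, paste0("peaks/", enzyme), {
    out <- lapply(samples, function(s) {
      a <- truth$abundance[s, ]
      keep <- a > 0
      n <- sum(keep)
      mu <- a[keep] * nz$total_fluorescence
      h <- if (nz$height_sd > 0) {
        mu * exp(rnorm(n, -nz$height_sd^2 / 2, nz$height_sd))
      } else mu
      h <- round(h)
      sz <- trf_of[truth$types[keep]] + rnorm(n, 0, nz$size_sd)
      emit <- h >= 1
      tab <- data.frame(
        sample_id = s, dye = "NED", enzyme = enzyme,
        size_bp = unname(sz[emit]), height_rfu = unname(h[emit]),
        stringsAsFactors = FALSE
      )
      n_base <- rpois(1, nz$baseline_rate)
      if (n_base > 0) {
        tab <- rbind(tab, data.frame(
          sample_id = s, dye = "NED", enzyme = enzyme,
          size_bp = runif(n_base, 50, 500),
          height_rfu = pmax(1, round(rexp(n_base, 1 / 60))),
          stringsAsFactors = FALSE
        ))
      }
      class(tab) <- c("peak_table", "data.frame")
      tab
    })
    names(out) <- samples
    out
  })
}

#' Simulate a 16S-style reference library
#'
#' Random full-length sequences carrying the 8F/926R primer pair sites so
#' that in-silico digestion applies, each with a synthetic taxonomy string
#' in Greengenes style. Deterministic for a fixed seed.
#'
#' @param n_taxa number of reference taxa (>= 1).
#' @param length sequence length in nt.
#' @param seed integer seed.
#' @return Named character vector; names are `"<id> <taxonomy>"`.
#' @export
simulate_reference_library <- function(n_taxa, length = 900L, seed = 1L) {
  if (!is_count(n_taxa)) {
    stop_scatyper("n_taxa must be a positive integer",
                  "scatyper_invalid_parameter")
  }
  pr <- rrna16s_primers()
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "TM7",
             "Fibrobacteres", "Actinobacteria")
  with_substream(seed, "reference/library", {
    f_len <- nchar(pr$fwd$sequence)
    r_len <- nchar(pr$rev$sequence)
    mid <- length - f_len - r_len
    stopifnot(mid > 0)
    seqs <- vapply(seq_len(n_taxa), function(i) {
      paste0(instantiate_iupac(pr$fwd$sequence), random_dna(mid),
             reverse_complement(instantiate_iupac(pr$rev$sequence)))
    }, character(1))
    names(seqs) <- sprintf("ref_%03d k__Bacteria;p__%s;g__Genus%03d",
                           seq_len(n_taxa),
                           sample(phyla, n_taxa, replace = TRUE),
                           seq_len(n_taxa))
    seqs
  })
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector (full description lines as names).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
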