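#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist rnorm runif rgamma rpois rbinom rmultinom rexp
#'   isoreg cmdscale as.dist hclust
#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv combn head modifyList
#' @importFrom methods is
#' @importFrom Rcpp sourceCpp
#' @useDynLib scatyper, .registration = TRUE
NULL

## Deterministic sub-seed for a named random substream.  Every stochastic
## operation derives its own seed from (master seed, operation name) so that
## changing the draw order inside one operation never perturbs another.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in seq_along(codes)) h <- (h * 31 + codes[k]) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}

stop_scatyper <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "scatyper_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Pick one concrete ACGT realization of an IUPAC-degenerate string.
instantiate_iupac <- function(x) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- !chars %in% names(map)
  if (any(bad)) {
    stop_scatyper(
      sprintf("invalid IUPAC character(s): %s",
              paste(unique(chars[bad]), collapse = ", ")),
      "scatyper_format_error"
    )
  }
  picked <- vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(picked, collapse = "")
}
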