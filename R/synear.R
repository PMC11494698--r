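# Synthetic EAR (SynEAR) generation: random concatenation of class n-grams
# under the natural library's length distribution, with a longer length
# distribution for the "strongest" class.

SYNEAR_CLASSES <- c("weak", "moderate", "strong", "strongest")

#' Specification for a SynEAR library
#'
#' @param counts Named integer vector of requested motifs per predicted
#'   class (`weak`, `moderate`, `strong`, `strongest`); all >= 0.
#' @param natural_lengths Non-empty integer vector: the empirical length
#'   list of the natural library, sampled uniformly for the first three
#'   classes.
#' @param length_factor Multiplier applied (then rounded) to a sampled
#'   natural length for the `strongest` class.
#' @param seed Integer seed.
#' @param max_retries Retry budget per motif when enforcing uniqueness.
#' @return Object of class `synear_spec`.
#' @export
synear_spec <- function(counts = c(weak = 20, moderate = 20, strong = 20,
                                   strongest = 20),
                        natural_lengths, length_factor = 1.5, seed = 1L,
                        max_retries = 100L) {
  if (!all(SYNEAR_CLASSES %in% names(counts))) {
    stop("counts must name all of: ", paste(SYNEAR_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(natural_lengths) == 0) {
    stop("natural_lengths must be non-empty", call. = FALSE)
  }
  structure(
    list(counts = counts[SYNEAR_CLASSES], natural_lengths = natural_lengths,
         length_factor = length_factor, seed = as.integer(seed),
         max_retries = as.integer(max_retries)),
    class = "synear_spec"
  )
}

#' Sample a target length for a SynEAR class
#'
#' `weak`, `moderate` and `strong` draw uniformly from the empirical natural
#' lengths; `strongest` draws from the transformed (longer) distribution
#' `round(length_factor * natural length)`, reflecting the observed
#' correlation between motif length and repression strength.
#'
#' @param class One of `weak`, `moderate`, `strong`, `strongest`.
#' @param spec A `synear_spec`.
#' @return Integer length. Uses the current RNG stream (callers seed it).
#' @export
sample_length <- function(class, spec) {
  class <- match.arg(class, SYNEAR_CLASSES)
  lens <- spec$natural_lengths
  L <- if (length(lens) == 1L) lens else sample(lens, 1L)
  if (class == "strongest") L <- as.integer(round(spec$length_factor * L))
  as.integer(L)
}

#' Assemble one SynEAR by random gram concatenation
#'
#' Uniformly samples grams from the class set and concatenates them until
#' the target length is reached; the final gram is truncated so the output
#' length is exact. The assembly trace (every full gram drawn, plus how many
#' residues of the last one survive) is attached as attribute `units`.
#'
#' @param grams Non-empty character vector: the class's gram set.
#' @param target_length Target peptide length (>= shortest gram).
#' @return Peptide string of exactly `target_length` residues, with
#'   attributes `units` (grams drawn, in order) and `kept_last` (residues of
#'   the final gram retained). Uses the current RNG stream.
#' @export
assemble_synear <- function(grams, target_length) {
  if (length(grams) == 0) stop("empty gram set: cannot assemble", call. = FALSE)
  if (target_length < min(nchar(grams))) {
    stop("target_length shorter than the shortest gram", call. = FALSE)
  }
  units <- character(0)
  out <- ""
  while (nchar(out) < target_length) {
    g <- grams[[sample.int(length(grams), 1L)]]
    units <- c(units, g)
    out <- paste0(out, g)
  }
  kept_last <- nchar(g) - (nchar(out) - target_length)
  out <- substr(out, 1L, target_length)
  structure(out, units = units, kept_last = kept_last)
}

#' Generate a SynEAR library with predicted strength classes
#'
#' Builds the requested number of unique motifs per predicted class by
#' random concatenation ([assemble_synear()]) at class-specific lengths
#' ([sample_length()]). The `strongest` class uses the *strong* gram set.
#' Duplicate sequences are regenerated within a bounded retry budget; if a
#' class cannot reach its requested count, the partial library is returned
#' with a warning and an `incomplete` attribute.
#'
#' @param spec A `synear_spec`.
#' @param class_sets Named list with gram sets `strong`, `moderate`, `weak`
#'   (e.g. from [ngram_class_sets()]); each requested class needs >= 1 gram.
#' @return Data frame of class `motif_library` with columns `id`, `sequence`,
#'   `library` (= "SynEAR"), `predicted_class` (ordered factor).
#' @export
generate_synear_library <- function(spec, class_sets) {
  stopifnot(inherits(spec, "synear_spec"))
  gram_source <- list(weak = class_sets$weak, moderate = class_sets$moderate,
                      strong = class_sets$strong, strongest = class_sets$strong)
  requested <- names(spec$counts)[spec$counts > 0]
  for (cl in requested) {
    if (length(gram_source[[cl]]) == 0) {
      stop("no grams available for requested class '", cl, "'", call. = FALSE)
    }
  }
  with_seed(spec$seed, {
    rows <- list()
    incomplete <- character(0)
    seen <- character(0)
    for (cl in SYNEAR_CLASSES) {
      k <- spec$counts[[cl]]
      if (k == 0) next
      made <- 0L
      tries <- 0L
      while (made < k && tries < spec$max_retries * k) {
        tries <- tries + 1L
        L <- sample_length(cl, spec)
        s <- as.character(assemble_synear(gram_source[[cl]], L))
        if (s %in% seen) next
        seen <- c(seen, s)
        made <- made + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("SynEAR_%s_%02d", cl, made),
          sequence = s, library = "SynEAR", predicted_class = cl,
          stringsAsFactors = FALSE
        )
      }
      if (made < k) incomplete <- c(incomplete, cl)
    }
    out <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(id = character(0), sequence = character(0),
                 library = character(0), predicted_class = character(0),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out$predicted_class <- factor(out$predicted_class, levels = SYNEAR_CLASSES,
                                  ordered = TRUE)
    if (length(incomplete) > 0) {
      warning("retry budget exhausted before reaching requested counts for: ",
              paste(incomplete, collapse = ", "), call. = FALSE)
      attr(out, "incomplete") <- incomplete
    }
    class(out) <- c("motif_library", "data.frame")
    out
  })
}
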