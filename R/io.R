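# FASTA and CSV interchange for motif libraries and assay tables.

#' Write a motif library as FASTA
#'
#' Headers carry the id followed by whitespace-separated `key=value` pairs
#' for `library` and, when present, `true_strength` and `predicted_class`.
#'
#' @param motifs A `motif_library` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motif_fasta <- function(motifs, path) {
  headers <- vapply(seq_len(nrow(motifs)), function(i) {
    h <- motifs$id[i]
    if (!is.null(motifs$library)) h <- paste0(h, " library=", motifs$library[i])
    if (!is.null(motifs$true_strength) && !is.na(motifs$true_strength[i])) {
      h <- paste0(h, " true_strength=",
                  sprintf("%.10g", motifs$true_strength[i]))
    }
    if (!is.null(motifs$predicted_class) && !is.na(motifs$predicted_class[i])) {
      h <- paste0(h, " predicted_class=", as.character(motifs$predicted_class[i]))
    }
    h
  }, character(1))
  x <- Biostrings::AAStringSet(motifs$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Read a motif library from FASTA
#'
#' Inverse of [write_motif_fasta()]: parses `key=value` pairs from the
#' headers back into columns.
#'
#' @param path FASTA file path.
#' @return A `motif_library` data frame.
#' @export
read_motif_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  headers <- names(x)
  parse_field <- function(h, key) {
    m <- regmatches(h, regexpr(sprintf("%s=\\S+", key), h))
    if (length(m) == 0) NA_character_ else sub(sprintf("^%s=", key), "", m)
  }
  out <- data.frame(
    id = vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L),
    sequence = as.character(x),
    library = vapply(headers, parse_field, character(1), key = "library",
                     USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  ts <- vapply(headers, parse_field, character(1), key = "true_strength",
               USE.NAMES = FALSE)
  if (any(!is.na(ts))) out$true_strength <- as.numeric(ts)
  pc <- vapply(headers, parse_field, character(1), key = "predicted_class",
               USE.NAMES = FALSE)
  if (any(!is.na(pc))) {
    out$predicted_class <- factor(pc, levels = SYNEAR_CLASSES, ordered = TRUE)
  }
  rownames(out) <- NULL
  class(out) <- c("motif_library", "data.frame")
  out
}

#' Read a plate table from CSV
#'
#' Validates the tidy long format the quantification expects.
#'
#' @param path CSV with columns `construct_id`, `plant_id`, `disk_id`,
#'   `fluorescence`.
#' @return Data frame.
#' @export
read_plate_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("construct_id", "plant_id", "disk_id", "fluorescence")
  if (!all(required %in% names(out))) {
    stop("plate CSV must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(out$fluorescence <= 0)) {
    stop("fluorescence values must be positive", call. = FALSE)
  }
  out
}
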