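#' The 96 trinucleotide substitution channels
#'
#' Standard single-base-substitution channels in conventional (COSMIC)
#' ordering: the six pyrimidine substitution classes C>A, C>G, C>T, T>A,
#' T>C, T>G, each expanded over the sixteen 5'/3' flanking-base contexts,
#' written as e.g. `"A[C>A]A"`.
#'
#' @return character vector of length 96
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p, q) paste0(p, "[", s, "]", q))))
  }))
}

#' Load a reference signature matrix
#'
#' Reads a TSV whose first column (`channel`) holds the 96 trinucleotide
#' channels and whose remaining columns are signatures, each a probability
#' vector over channels. The packaged default is a six-signature synthetic
#' reference set; genuine COSMIC matrices in the same layout are drop-in
#' replacements.
#'
#' @param path TSV path; `NULL` loads the packaged synthetic reference set
#' @return numeric matrix, 96 rows (channel names) x signatures
#' @export
load_reference_signatures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_signatures.tsv",
                        package = "somafoot", mustWork = TRUE)
  }
  tab <- read_tsv(path)
  if (names(tab)[1] != "channel") {
    stopf("reference signature file must have a leading 'channel' column")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$channel
  if (nrow(m) != 96L || !identical(rownames(m), sbs_channels())) {
    stopf("reference signatures must cover the 96 channels in standard order")
  }
  bad <- abs(colSums(m) - 1) > 1e-6
  if (any(bad)) {
    stopf("reference signature column(s) not summing to 1: %s",
          paste(colnames(m)[bad], collapse = ", "))
  }
  m
}
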