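#' Genome models for binned copy-number analysis
#'
#' A genome model is a tibble with columns `chrom` (character) and `length`
#' (base pairs). [toy_genome()] returns a small two-chromosome genome used
#' throughout the simulation defaults; [hg19_genome()] loads the hg19
#' chromosome sizes bundled with the package for realistically scaled runs.
#'
#' @param n_chrom Number of chromosomes in the toy genome.
#' @param chrom_length Length of each toy chromosome in base pairs.
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' toy_genome()
#' head(hg19_genome())
#' @export
toy_genome <- function(n_chrom = 2, chrom_length = 50e6) {
  stopifnot(n_chrom >= 1, chrom_length > 0)
  tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = as.numeric(chrom_length)
  )
}

#' @rdname toy_genome
#' @export
hg19_genome <- function() {
  path <- system.file("extdata", "hg19_chrom_sizes.tsv", package = "methyldx")
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length = readr::col_double()
  ))
}

validate_genome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome))) {
    abort("genome model must have columns 'chrom' and 'length'")
  }
  if (anyDuplicated(genome$chrom) > 0) abort("duplicate chromosome in genome model")
  if (any(genome$length <= 0)) abort("chromosome lengths must be positive")
  invisible(genome)
}
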