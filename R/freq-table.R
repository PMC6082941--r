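#' Population x locus insertion-allele frequency table
#'
#' Holds insertion-allele frequencies for a set of populations at a shared
#' locus set; the deletion frequency is always `1 - p` by construction, so a
#' single number per cell is stored. This is the interface through which
#' published reference-population frequencies enter distance calculations.
#'
#' @param freq numeric matrix in \[0, 1\]; rows are populations, columns loci.
#' @param sample_size optional named integer vector of per-population sample
#'   sizes (individuals), required when allele counts must be reconstructed.
#' @return an object of class `freq_table`
#' @export
freq_table <- function(freq, sample_size = NULL) {
  if (!is.matrix(freq)) freq <- as.matrix(freq)
  storage.mode(freq) <- "double"
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("pop", seq_len(nrow(freq)))
  if (is.null(colnames(freq)))
    colnames(freq) <- paste0("locus", seq_len(ncol(freq)))
  if (any(!is.na(freq) & (freq < 0 | freq > 1)))
    stop("insertion frequencies must lie in [0, 1]")
  if (!is.null(sample_size)) {
    sample_size <- sample_size[rownames(freq)]
    if (anyNA(sample_size))
      stop("sample_size must be named for every population")
  }
  structure(list(freq = freq, sample_size = sample_size),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Insertion-allele frequency table:", nrow(x$freq), "populations x",
      ncol(x$freq), "loci\n")
  print(utils::head(round(x$freq, 4), 5))
  invisible(x)
}

#' @rdname freq_table
#' @param ft a `freq_table`
#' @export
population_ids <- function(ft) rownames(ft$freq)

#' Insertion/deletion frequency pair for one population
#'
#' @param ft a `freq_table`
#' @param population population id
#' @return a 2-row matrix (rows `insertion`, `deletion`) over loci
#' @export
allele_freq_pair <- function(ft, population) {
  p <- ft$freq[population, ]
  rbind(insertion = p, deletion = 1 - p)
}
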