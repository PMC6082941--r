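#' Construct a diallelic InDel genotype matrix
#'
#' The central data container of the package: unphased genotype calls at
#' diallelic insertion/deletion loci for a set of individuals grouped into
#' populations. Calls are coded `"II"` (insertion homozygote), `"ID"`
#' (heterozygote), `"DD"` (deletion homozygote) or `NA` (missing / dropout).
#'
#' @param calls character matrix of calls; rows are samples, columns are loci.
#'   Row names are taken as sample ids and column names as locus ids when
#'   `sample_ids` / `locus_ids` are not given. The code `"MISSING"` and the
#'   empty string are normalised to `NA`.
#' @param populations character vector of population labels, one per sample.
#' @param sample_ids,locus_ids optional explicit ids (must be unique).
#' @param rs optional character vector of rs-number annotations per locus.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls` (character matrix with dimnames), `populations`, and `rs`.
#' @examples
#' calls <- matrix(c("II", "ID", "DD", NA), 2, 2,
#'                 dimnames = list(c("s1", "s2"), c("HLD77", "HLD45")))
#' gm <- genotype_matrix(calls, populations = c("popA", "popA"))
#' n_loci(gm)
#' @export
genotype_matrix <- function(calls, populations, sample_ids = NULL,
                            locus_ids = NULL, rs = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (!is.null(sample_ids)) rownames(calls) <- sample_ids
  if (!is.null(locus_ids)) colnames(calls) <- locus_ids
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  calls[calls %in% c("MISSING", "", "NA")] <- NA_character_
  gm <- structure(
    list(calls = calls,
         populations = as.character(populations),
         rs = rs),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
validate_genotype_matrix <- function(gm) {
  calls <- gm$calls
  if (length(gm$populations) != nrow(calls))
    stop("need one population label per sample (", nrow(calls),
         " samples, ", length(gm$populations), " labels)")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate locus ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% c("II", "ID", "DD"))
  if (any(bad))
    stop("invalid genotype code(s): ",
         paste(unique(calls[bad]), collapse = ", "),
         " (admitted: II, ID, DD, MISSING)")
  if (!is.null(gm$rs) && length(gm$rs) != ncol(calls))
    stop("rs annotation length must equal the number of loci")
  gm
}

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(gm) colnames(gm$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Diallelic InDel genotype matrix:",
      n_samples(x), "samples x", n_loci(x), "loci\n")
  tab <- table(x$populations)
  cat("Populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("Missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Insertion-allele dosage matrix
#'
#' Recode calls as the per-genotype count of insertion alleles:
#' `DD` = 0, `ID` = 1, `II` = 2, missing stays `NA`.
#'
#' @param gm a `genotype_matrix`
#' @return integer matrix with the same dimnames as `gm$calls`
#' @export
dosage_matrix <- function(gm) {
  d <- matrix(NA_integer_, n_samples(gm), n_loci(gm),
              dimnames = dimnames(gm$calls))
  d[gm$calls == "DD"] <- 0L
  d[gm$calls == "ID"] <- 1L
  d[gm$calls == "II"] <- 2L
  d
}

#' Restrict a genotype matrix to selected populations
#'
#' @param gm a `genotype_matrix`
#' @param pops character vector of population labels to keep
#' @return a `genotype_matrix` containing only those samples
#' @export
subset_populations <- function(gm, pops) {
  missing_pops <- setdiff(pops, unique(gm$populations))
  if (length(missing_pops))
    stop("unknown population(s): ", paste(missing_pops, collapse = ", "))
  keep <- gm$populations %in% pops
  genotype_matrix(gm$calls[keep, , drop = FALSE],
                  populations = gm$populations[keep], rs = gm$rs)
}

#' Combine genotype matrices over the same loci
#'
#' @param ... `genotype_matrix` objects sharing an identical locus set
#' @return a single `genotype_matrix` stacking all samples
#' @export
bind_genotypes <- function(...) {
  gms <- list(...)
  ids <- locus_ids(gms[[1]])
  for (g in gms[-1])
    if (!identical(locus_ids(g), ids))
      stop("genotype matrices must share an identical locus set")
  genotype_matrix(do.call(rbind, lapply(gms, function(g) g$calls)),
                  populations = unlist(lapply(gms, function(g) g$populations)),
                  rs = gms[[1]]$rs)
}

#' Per-population insertion-allele frequencies
#'
#' Complete-case allele frequencies per locus within each population,
#' assembled into a [freq_table()].
#'
#' @param gm a `genotype_matrix`
#' @return a `freq_table` with one row per population
#' @export
population_freqs <- function(gm) {
  pops <- unique(gm$populations)
  dos <- dosage_matrix(gm)
  freq <- matrix(NA_real_, length(pops), n_loci(gm),
                 dimnames = list(pops, locus_ids(gm)))
  nn <- integer(length(pops))
  for (i in seq_along(pops)) {
    d <- dos[gm$populations == pops[i], , drop = FALSE]
    freq[i, ] <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
    nn[i] <- nrow(d)
  }
  freq_table(freq, sample_size = stats::setNames(nn, pops))
}
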