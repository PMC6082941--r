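#' Read a genotype table
#'
#' Reads diallelic InDel genotypes from a delimited table or a GenePop file.
#' In the `csv`/`tsv` dialects the header names the loci and the first two
#' columns hold the sample id and population label; calls are `II`, `ID`,
#' `DD` or `MISSING`. In the `genepop` dialect two-digit allele codes are
#' used with `01` = insertion, `02` = deletion and `00` = missing; unphased
#' heterozygotes `0102` and `0201` both map to `ID`.
#'
#' @param path file to read
#' @param dialect one of `"csv"`, `"tsv"`, `"genepop"`
#' @return a [genotype_matrix()]
#' @export
read_genotype_table <- function(path, dialect = c("csv", "tsv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "genepop") return(read_genepop(path))
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character())
  if (ncol(df) < 2)
    stop("genotype table needs sample id and population columns")
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(calls) <- df[[1]]
  bad <- !is.na(calls) & !(calls %in% c("II", "ID", "DD", "MISSING", "", "NA"))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", calls[bad][1], "' at data line ",
         ij[1], ", locus ", colnames(calls)[ij[2]])
  }
  genotype_matrix(calls, populations = df[[2]])
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("truncated GenePop file: ", path)
  body <- lines[-1]                       # first line is a title
  pop_idx <- which(toupper(trimws(body)) %in% c("POP"))
  if (!length(pop_idx)) stop("GenePop file has no POP separator")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  code_map <- c("0101" = "II", "0102" = "ID", "0201" = "ID",
                "0202" = "DD", "0000" = NA_character_)
  ids <- character(); pops <- character(); rows <- list()
  pop_no <- 0L
  for (k in seq(pop_idx[1], length(body))) {
    line <- trimws(body[k])
    if (toupper(line) == "POP") { pop_no <- pop_no + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2)
      stop("malformed GenePop sample line ", k + 1, ": ", line)
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop line ", k + 1, ": expected ", length(loci),
           " loci, found ", length(codes))
    unknown <- !(codes %in% names(code_map))
    if (any(unknown))
      stop("unknown allele code '", codes[unknown][1],
           "' at GenePop line ", k + 1)
    ids <- c(ids, trimws(parts[1]))
    pops <- c(pops, paste0("pop", pop_no))
    rows[[length(rows) + 1L]] <- unname(code_map[codes])
  }
  calls <- do.call(rbind, rows)
  dimnames(calls) <- list(ids, loci)
  genotype_matrix(calls, populations = pops)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: any file written here is re-read to an
#' identical in-memory object. Missing calls are written as `MISSING`
#' (`0000` in GenePop). Output is UTF-8 with LF line endings.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file
#' @param dialect one of `"csv"`, `"tsv"`, `"genepop"`
#' @export
write_genotype_table <- function(gm, path,
                                 dialect = c("csv", "tsv", "genepop")) {
  dialect <- match.arg(dialect)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (dialect == "genepop") {
    rev_map <- c(II = "0101", ID = "0102", DD = "0202")
    out <- c("indelpanel genotype export", locus_ids(gm))
    for (pop in unique(gm$populations)) {
      out <- c(out, "POP")
      for (i in which(gm$populations == pop)) {
        codes <- rev_map[gm$calls[i, ]]
        codes[is.na(codes)] <- "0000"
        out <- c(out, paste0(sample_ids(gm)[i], " , ",
                             paste(codes, collapse = " ")))
      }
    }
    writeLines(out, con, sep = "\n", useBytes = TRUE)
    return(invisible(NULL))
  }
  sep <- if (dialect == "csv") "," else "\t"
  calls <- gm$calls
  calls[is.na(calls)] <- "MISSING"
  header <- paste(c("sample_id", "population", locus_ids(gm)), collapse = sep)
  body <- vapply(seq_len(n_samples(gm)), function(i) {
    paste(c(sample_ids(gm)[i], gm$populations[i], calls[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Read / write an insertion-allele frequency table
#'
#' Delimited text with one row per population: a `population` column, an
#' optional `n` column of sample sizes, then one column per locus holding the
#' insertion-allele frequency. Round-trips are stable to 6 decimals.
#'
#' @param path file to read or write
#' @return [read_freq_table()] returns a [freq_table()]
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "population")
    stop("frequency table must start with a 'population' column")
  nn <- NULL
  if (ncol(df) >= 2 && names(df)[2] == "n") {
    nn <- stats::setNames(as.integer(df[["n"]]), df[["population"]])
    df <- df[, -2, drop = FALSE]
  }
  freq <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(freq) <- "double"
  rownames(freq) <- df[["population"]]
  if (any(!is.na(freq) & (freq < 0 | freq > 1)))
    stop("frequency outside [0, 1] in ", path)
  freq_table(freq, sample_size = nn)
}

#' @rdname read_freq_table
#' @param ft a [freq_table()]
#' @export
write_freq_table <- function(ft, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  loci <- colnames(ft$freq)
  has_n <- !is.null(ft$sample_size)
  header <- paste(c("population", if (has_n) "n", loci), collapse = ",")
  body <- vapply(seq_len(nrow(ft$freq)), function(i) {
    paste(c(rownames(ft$freq)[i],
            if (has_n) ft$sample_size[i],
            sprintf("%.6f", ft$freq[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Labelled symmetric distance matrix
#'
#' Light validation wrapper used by every distance producer/consumer:
#' square, symmetric to 1e-12, zero diagonal, non-negative entries.
#'
#' @param values square numeric matrix
#' @param labels optional labels (default: dimnames of `values`)
#' @return the validated matrix with class `distance_matrix`
#' @export
as_distance_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("label count must equal matrix size")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix must be symmetric (tolerance 1e-12)")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be 0")
  if (any(values < 0)) stop("distances must be non-negative")
  dimnames(values) <- list(labels, labels)
  class(values) <- c("distance_matrix", "matrix", "array")
  values
}

#' Write a PHYLIP distance matrix
#'
#' Square PHYLIP dialect: a line with the taxon count, then one row per
#' taxon with the (up to 10-character) name field followed by all distances.
#' Longer labels are truncated and disambiguated with a numeric suffix,
#' with a warning.
#'
#' @param dm a matrix accepted by [as_distance_matrix()]
#' @param path output file
#' @export
write_phylip_distance <- function(dm, path) {
  dm <- as_distance_matrix(dm)
  labs <- rownames(dm)
  long <- nchar(labs) > 10
  if (any(long)) {
    warning("truncating ", sum(long), " label(s) to the 10-character ",
            "PHYLIP name field")
    short <- substr(labs, 1, 10)
    for (i in which(duplicated(short) | short %in% short[duplicated(short)])) {
      sfx <- as.character(i)
      short[i] <- paste0(substr(labs[i], 1, 10 - nchar(sfx)), sfx)
    }
    labs <- short
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  rows <- vapply(seq_len(nrow(dm)), function(i) {
    paste0(formatC(labs[i], width = -10),
           paste(sprintf("%.6f", dm[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(dm)), rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(NULL)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` `phylo` object
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(NULL)
}

#' Read a Newick tree
#'
#' @param path file containing one Newick tree
#' @return an `ape` `phylo` object
#' @export
read_newick <- function(path) ape::read.tree(path)
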