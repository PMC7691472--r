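#' Construct a diploid genotype dataset
#'
#' The container used throughout the package for diploid multilocus
#' genotypes of one or more named populations. Each population is an integer
#' matrix with one row per individual and two columns per locus (locus `l`
#' occupies columns `2l - 1` and `2l`); `NA` marks a missing allele. A
#' genotype is either fully scored or fully missing at a locus.
#'
#' @param pops named list of integer matrices, all with `2 * length(loci)`
#'   columns.
#' @param loci character vector of locus names.
#' @return an object of class `genotype_dataset`.
#' @examples
#' up <- matrix(c(1L, 1L, 1L, 2L), nrow = 2, byrow = TRUE)
#' dn <- matrix(c(2L, 2L, 1L, 2L), nrow = 2, byrow = TRUE)
#' genotype_dataset(list(UP = up, DOWN = dn), loci = "LocA")
#' @export
genotype_dataset <- function(pops, loci) {
  if (is.null(names(pops)) || any(!nzchar(names(pops))))
    stop("all populations must be named")
  loci <- as.character(loci)
  for (nm in names(pops)) {
    p <- pops[[nm]]
    if (!is.matrix(p) || ncol(p) != 2 * length(loci))
      stop("population '", nm, "' must be a matrix with 2 columns per locus")
    storage.mode(p) <- "integer"
    # enforce all-or-nothing scoring per genotype
    for (l in seq_along(loci)) {
      cols <- c(2 * l - 1, 2 * l)
      miss <- is.na(p[, cols[1]]) | is.na(p[, cols[2]])
      p[miss, cols] <- NA_integer_
    }
    pops[[nm]] <- p
  }
  structure(list(pops = pops, loci = loci), class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d population(s), %d loci\n",
              length(x$pops), length(x$loci)))
  for (nm in names(x$pops))
    cat(sprintf("  %s: %d individuals\n", nm, nrow(x$pops[[nm]])))
  invisible(x)
}

#' Keep a subset of populations
#'
#' @param dataset a [genotype_dataset()].
#' @param pop_names populations to keep, in order.
#' @return a [genotype_dataset()] restricted to `pop_names`.
#' @export
subset_populations <- function(dataset, pop_names) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  missing <- setdiff(pop_names, names(dataset$pops))
  if (length(missing))
    stop("population(s) not found: ", paste(missing, collapse = ", "),
         "; available: ", paste(names(dataset$pops), collapse = ", "))
  genotype_dataset(dataset$pops[pop_names], dataset$loci)
}

#' Read a genepop file
#'
#' Parses the standard genepop text format: a title line, one locus name per
#' line (or several separated by commas), then one `POP` block per
#' population with lines of the form `label , 001002 003004 ...`. Both
#' 2-digit and 3-digit allele codings are accepted; allele code 0 marks a
#' missing allele and the whole genotype at that locus is treated as missing.
#' Following the genepop convention, each population is named after the label
#' of the last individual in its block.
#'
#' @param path path to a genepop file.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed genepop file: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("malformed genepop file: no POP line after the locus list (line ",
         if (is.na(first_pop)) length(lines) else first_pop, ")")
  loci <- unlist(strsplit(lines[2:(first_pop - 1)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("malformed genepop file: empty locus list")
  L <- length(loci)

  pop_starts <- which(is_pop)
  pop_ends <- c(pop_starts[-1] - 1, length(lines))
  pops <- list()
  for (b in seq_along(pop_starts)) {
    rows <- list()
    label <- NULL
    for (ln in seq(pop_starts[b] + 1, pop_ends[b])) {
      if (ln > length(lines)) break
      line <- trimws(lines[ln])
      if (!nzchar(line)) next
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2)
        stop("malformed individual line ", ln, ": missing ',' separator")
      label <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "[[:space:]]+")[[1]]
      if (length(genos) != L)
        stop("line ", ln, ": expected ", L, " genotypes, found ",
             length(genos))
      row <- integer(2 * L)
      for (l in seq_len(L)) {
        g <- genos[l]
        w <- nchar(g)
        if (!(w %in% c(4, 6)) || grepl("[^0-9]", g))
          stop("line ", ln, ", locus ", loci[l],
               ": genotype '", g, "' is not 2x2- or 2x3-digit")
        half <- w / 2
        a1 <- as.integer(substr(g, 1, half))
        a2 <- as.integer(substr(g, half + 1, w))
        if (a1 == 0 || a2 == 0) a1 <- a2 <- NA_integer_
        row[2 * l - 1] <- a1
        row[2 * l] <- a2
      }
      rows[[length(rows) + 1]] <- row
    }
    if (!length(rows))
      stop("POP block ", b, " (line ", pop_starts[b], ") has no individuals")
    mat <- do.call(rbind, rows)
    nm <- label
    if (nm %in% names(pops)) nm <- sprintf("%s_%d", nm, b)
    pops[[nm]] <- mat
  }
  genotype_dataset(pops, loci)
}

#' Write a genepop file
#'
#' Writes 3-digit allele coding, one POP block per population, every
#' individual of a population labelled with the population name (so the
#' genepop convention of naming populations after their last individual
#' round-trips). Missing genotypes are written as `000000`.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path,
                          title = "findex simulated genotypes") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!length(dataset$pops)) stop("dataset has no populations")
  L <- length(dataset$loci)
  out <- c(title, dataset$loci)
  for (nm in names(dataset$pops)) {
    p <- dataset$pops[[nm]]
    if (!nrow(p)) stop("population '", nm, "' is empty")
    if (any(p > 999, na.rm = TRUE))
      stop("allele codes > 999 cannot be written in 3-digit coding")
    out <- c(out, "POP")
    codes <- p
    codes[is.na(codes)] <- 0L
    for (i in seq_len(nrow(p))) {
      g <- vapply(seq_len(L), function(l)
        sprintf("%03d%03d", codes[i, 2 * l - 1], codes[i, 2 * l]),
        character(1))
      out <- c(out, paste0(nm, " , ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
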