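#' Diploid multilocus genotype container
#'
#' Holds unordered diploid allele calls for a set of individuals at a set of
#' loci, together with a deme (population) label per individual. Allele codes
#' are positive integers — microsatellite repeat counts or arbitrary codes —
#' and a missing call is stored as a pair of `NA`s.
#'
#' @param calls integer array of dimension `n_individuals x n_loci x 2`;
#'   both gene copies of a missing call must be `NA`.
#' @param individuals character vector of individual identifiers.
#' @param loci character vector of locus names.
#' @param pop factor or character vector of per-individual deme labels.
#' @return An object of class `genotype_matrix` with fields `calls`,
#'   `individuals`, `loci`, `pop`.
#' @examples
#' calls <- array(c(1L, 1L, 1L, 2L), dim = c(1, 2, 2))
#' g <- genotype_matrix(calls, "ind1", c("locA", "locB"), "CB")
#' missing_fraction(g)
#' @export
genotype_matrix <- function(calls, individuals, loci, pop) {
  stopifnot(length(dim(calls)) == 3, dim(calls)[3] == 2)
  storage.mode(calls) <- "integer"
  n <- dim(calls)[1]; L <- dim(calls)[2]
  if (length(individuals) != n) stop("individuals must match dim(calls)[1]")
  if (length(loci) != L) stop("loci must match dim(calls)[2]")
  if (length(pop) != n) stop("every individual needs a pop label")
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half)) stop("half-missing calls: a call is a pair of alleles or fully missing")
  if (any(calls <= 0, na.rm = TRUE)) stop("allele codes must be positive integers")
  dimnames(calls) <- list(individuals, loci, NULL)
  structure(list(calls = calls,
                 individuals = as.character(individuals),
                 loci = as.character(loci),
                 pop = factor(pop)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals,",
      length(x$loci), "loci\n")
  cat("demes:", paste(sprintf("%s (%d)", levels(x$pop), table(x$pop)),
                      collapse = ", "), "\n")
  cat(sprintf("missing calls: %.2f%%\n", 100 * missing_fraction(x)))
  invisible(x)
}

#' Fraction of missing genotype calls
#' @param g a [genotype_matrix()].
#' @return proportion of individual-by-locus calls that are missing.
#' @export
missing_fraction <- function(g) {
  mean(is.na(g$calls[, , 1]))
}

#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP dialect: a title line, one locus name per line (or a
#' single comma-separated line), populations delimited by lines equal to
#' "Pop" (case-insensitive), and per-individual rows `id , a1a2 a1a2 ...`
#' with 2- or 3-digit allele encoding; all-zero codes are missing. The
#' digit width is auto-detected per file and mixed widths are rejected.
#' Demes are labelled `Pop1`, `Pop2`, ... in file order (use
#' [relabel_pops()] to attach geographic names).
#'
#' @param file path to a GENEPOP file, or a character vector of lines.
#' @return a [genotype_matrix()].
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) stop("not a GENEPOP file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GENEPOP format error: zero populations (no 'Pop' line)")
  header <- trimws(lines[2:(first_pop - 1)])
  header <- header[nzchar(header)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("GENEPOP format error: no locus names")

  ids <- character(); pops <- integer(); rows <- list()
  pop_idx <- 0L; width <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    if (toupper(raw) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(raw, ",")[[1]]
    if (length(parts) < 2) stop("GENEPOP parse error at line ", ln,
                                ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci))
      stop("GENEPOP parse error at line ", ln, ": ", length(toks),
           " genotypes for ", length(loci), " loci (ragged row)")
    w <- unique(nchar(toks)) / 2
    if (length(unique(nchar(toks))) != 1 || !(w[1] %in% c(2, 3)))
      stop("GENEPOP format error at line ", ln,
           ": genotype tokens must be uniformly 4 or 6 digits (ploidy 2)")
    if (is.na(width)) width <- as.integer(w)
    else if (width != w) stop("GENEPOP format error: mixed 2- and 3-digit ",
                              "allele widths in one file (line ", ln, ")")
    a1 <- as.integer(substr(toks, 1, width))
    a2 <- as.integer(substr(toks, width + 1, 2 * width))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    miss_mismatch <- xor(is.na(a1), is.na(a2))
    if (any(miss_mismatch)) {
      # one named zero allele: treat whole call as missing
      a1[miss_mismatch] <- NA_integer_; a2[miss_mismatch] <- NA_integer_
    }
    ids <- c(ids, id); pops <- c(pops, pop_idx)
    rows[[length(rows) + 1L]] <- cbind(a1, a2)
  }
  if (length(rows) == 0) stop("GENEPOP format error: no individuals")
  calls <- array(NA_integer_, dim = c(length(rows), length(loci), 2))
  for (i in seq_along(rows)) {
    calls[i, , 1] <- rows[[i]][, 1]
    calls[i, , 2] <- rows[[i]][, 2]
  }
  g <- genotype_matrix(calls, make.unique(ids), loci, paste0("Pop", pops))
  attr(g, "allele_width") <- width
  g
}

#' Write a GENEPOP genotype file
#'
#' @param g a [genotype_matrix()].
#' @param file output path; if `NULL` the lines are returned invisibly.
#' @param title title line (first line of the file).
#' @return the file lines, invisibly.
#' @export
write_genepop <- function(g, file = NULL, title = "gagconnect export") {
  width <- attr(g, "allele_width")
  if (is.null(width)) width <- if (max(g$calls, na.rm = TRUE) > 99) 3L else 2L
  if (max(g$calls, 0L, na.rm = TRUE) >= 10^width)
    stop("allele codes exceed the ", width, "-digit GENEPOP encoding")
  fmt <- function(a) sprintf(paste0("%0", width, "d"), ifelse(is.na(a), 0L, a))
  lines <- c(title, g$loci)
  for (p in levels(g$pop)) {
    lines <- c(lines, "Pop")
    for (i in which(g$pop == p)) {
      gt <- paste0(fmt(g$calls[i, , 1]), fmt(g$calls[i, , 2]))
      lines <- c(lines, paste(g$individuals[i], ",", paste(gt, collapse = " ")))
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Rename deme labels
#'
#' @param g a [genotype_matrix()].
#' @param map named character vector, old label -> new label, e.g.
#'   `c(Pop1 = "SWFS", Pop2 = "NWFS", Pop3 = "CB")`.
#' @return the relabelled `genotype_matrix`.
#' @export
relabel_pops <- function(g, map) {
  old <- levels(g$pop)
  if (!all(old %in% names(map))) stop("map must cover all current pop labels")
  g$pop <- factor(unname(map[as.character(g$pop)]))
  g
}

#' Sample grouping scheme
#'
#' A grouping scheme assigns every individual to exactly one deme. The three
#' canonical schemes for the Gulf-of-Mexico design are `three_pop`
#' (CB / SWFS / NWFS, the West Florida Shelf split at latitude 28 N),
#' `two_pop` (CB / WFS), and `pooled` (everything as GOM).
#'
#' @param name scheme name.
#' @param assignment named character vector, individual id -> deme.
#' @return object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(name, assignment) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be a named vector (individual -> deme)")
  if (anyDuplicated(names(assignment)))
    stop("every individual must be assigned exactly once")
  structure(list(name = name, assignment = assignment),
            class = "grouping_scheme")
}

#' Build a canonical grouping scheme from deme labels
#'
#' Assumes the genotype (or haplotype) object carries the three-deme labels
#' CB / SWFS / NWFS; `two_pop` merges SWFS and NWFS into WFS and `pooled`
#' merges everything into GOM.
#'
#' @param x a [genotype_matrix()] or [haplotype_set()].
#' @param name one of `"three_pop"`, `"two_pop"`, `"pooled"`.
#' @return a [grouping_scheme()].
#' @export
make_grouping <- function(x, name = c("three_pop", "two_pop", "pooled")) {
  name <- match.arg(name)
  ids <- if (inherits(x, "genotype_matrix")) x$individuals else names(x$sequences)
  labs <- as.character(if (inherits(x, "genotype_matrix")) x$pop else x$labels)
  demes <- switch(name,
    three_pop = labs,
    two_pop   = ifelse(labs %in% c("SWFS", "NWFS"), "WFS", labs),
    pooled    = rep("GOM", length(labs)))
  grouping_scheme(name, setNames(demes, ids))
}

#' Deme assignment of each individual under a scheme
#'
#' @param x a [genotype_matrix()] or [haplotype_set()].
#' @param scheme a [grouping_scheme()], or `NULL` to use the object's own
#'   labels.
#' @return factor of deme labels, one per individual/sequence.
#' @export
deme_of <- function(x, scheme = NULL) {
  ids <- if (inherits(x, "genotype_matrix")) x$individuals else names(x$sequences)
  if (is.null(scheme))
    return(factor(as.character(
      if (inherits(x, "genotype_matrix")) x$pop else x$labels)))
  miss <- setdiff(ids, names(scheme$assignment))
  if (length(miss))
    stop("scheme '", scheme$name, "' does not assign: ",
         paste(head(miss, 5), collapse = ", "))
  factor(unname(scheme$assignment[ids]))
}

#' Subset a genotype matrix by individual index
#' @param g a [genotype_matrix()].
#' @param idx integer or logical index over individuals.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_individuals <- function(g, idx) {
  gm <- genotype_matrix(g$calls[idx, , , drop = FALSE],
                        g$individuals[idx], g$loci,
                        as.character(g$pop)[idx])
  attr(gm, "allele_width") <- attr(g, "allele_width")
  gm
}

#' Balanced random subsample per deme
#'
#' Draws exactly `n` individuals without replacement from every deme of the
#' active scheme (the design used before migration-model fitting, where all
#' demes are reduced to the size of the smallest, n = 85).
#'
#' @param g a [genotype_matrix()].
#' @param scheme a [grouping_scheme()] (or `NULL` for the object's labels).
#' @param n individuals to keep per deme.
#' @param seed integer seed; the same seed reproduces the same selection.
#' @return a [genotype_matrix()] with `n` individuals in every deme, labelled
#'   by scheme deme.
#' @export
subsample_balanced <- function(g, scheme = NULL, n, seed = NULL) {
  demes <- deme_of(g, scheme)
  sizes <- table(demes)
  if (any(sizes < n))
    stop("deme ", names(sizes)[which(sizes < n)[1]], " has only ",
         min(sizes), " individuals (< n = ", n, ")")
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(levels(demes), function(d) {
    i <- which(demes == d)
    sort(sample(i, n))
  }))
  out <- subset_individuals(g, keep)
  out$pop <- factor(as.character(demes)[keep])
  out
}

#' Export genotype calls as a long data frame
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return data frame with columns individual, pop, locus, allele1, allele2.
#' @export
as.data.frame.genotype_matrix <- function(x, ...) {
  n <- length(x$individuals); L <- length(x$loci)
  data.frame(individual = rep(x$individuals, times = L),
             pop = rep(as.character(x$pop), times = L),
             locus = rep(x$loci, each = n),
             allele1 = as.vector(x$calls[, , 1]),
             allele2 = as.vector(x$calls[, , 2]),
             stringsAsFactors = FALSE)
}
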