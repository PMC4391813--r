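#' Aligned mtDNA haplotype container
#'
#' Holds equal-length aligned control-region sequences over `{A,C,G,T,-}`
#' plus, optionally, per-sequence copy numbers for tandem-repeat indel
#' loci (the 9-bp and 40-bp control-region motifs), and a deme label per
#' sequence. Duplicate sequences are retained: haplotype frequencies matter
#' for mismatch analysis.
#'
#' @param sequences named character vector of aligned sequences.
#' @param labels per-sequence deme labels.
#' @param repeat_counts `NULL`, or an integer matrix (sequences x motifs)
#'   of repeat copy numbers; column names name the motif loci.
#' @param motif_max integer vector of maximum copy numbers per motif
#'   (defaults taken from `repeat_counts` column maxima).
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(sequences, labels, repeat_counts = NULL,
                          motif_max = NULL) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  bad <- grepl("[^ACGT-]", toupper(sequences))
  if (any(bad)) stop("sequences must be over {A,C,G,T,-}: ",
                     paste(head(names(sequences)[bad], 3), collapse = ", "))
  if (length(labels) != length(sequences))
    stop("one label per sequence required")
  if (!is.null(repeat_counts)) {
    repeat_counts <- as.matrix(repeat_counts)
    storage.mode(repeat_counts) <- "integer"
    if (nrow(repeat_counts) != length(sequences))
      stop("repeat_counts must have one row per sequence")
    if (is.null(motif_max)) motif_max <- apply(repeat_counts, 2, max)
    if (any(repeat_counts < 0) ||
        any(sweep(repeat_counts, 2, motif_max, ">")))
      stop("repeat counts outside [0, max] bounds")
    rownames(repeat_counts) <- names(sequences)
    if (is.null(colnames(repeat_counts)))
      colnames(repeat_counts) <- paste0("motif", seq_len(ncol(repeat_counts)))
  }
  structure(list(sequences = setNames(toupper(sequences), names(sequences)),
                 labels = factor(labels),
                 repeat_counts = repeat_counts,
                 motif_max = motif_max),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$sequences), "sequences, aligned length",
      nchar(x$sequences[1]), "\n")
  cat("demes:", paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
                      collapse = ", "), "\n")
  if (!is.null(x$repeat_counts))
    cat("repeat motifs:", paste(colnames(x$repeat_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Control-region tandem-repeat motifs
#'
#' The two perfect-repeat indels of the Gag mitochondrial control region:
#' a 9-bp motif repeated at most seven times and a 40-bp motif repeated at
#' most thirteen times.
#' @return list of motif descriptors (`motif`, `max`, `name`).
#' @export
control_region_motifs <- function() {
  list(list(name = "motif_9bp", motif = "CATTAATTA", max = 7L),
       list(name = "motif_40bp",
            motif = "TCTGTACAATGGTTCAAATACGCAATATGTTCCATCATCA", max = 13L))
}

#' Read aligned haplotypes from FASTA
#'
#' Headers carry the deme of origin in a delimited field, e.g. `>h12|CB`.
#'
#' @param file FASTA path or character vector of FASTA lines.
#' @param delim delimiter separating the identifier from the region tag.
#' @param field 1-based index of the region field after splitting on `delim`.
#' @param regions optional vector of admissible region tags; unknown tags
#'   raise an error listing the offending headers.
#' @return a [haplotype_set()] (no repeat counts; see [recode_indels()]).
#' @export
read_fasta_haplotypes <- function(file, delim = "|", field = 2,
                                  regions = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    dna <- ape::read.FASTA(file)
  } else {
    tf <- tempfile(fileext = ".fasta")
    writeLines(file, tf)
    on.exit(unlink(tf))
    dna <- ape::read.FASTA(tf)
  }
  seqs <- vapply(as.character(dna),
                 function(s) paste(toupper(s), collapse = ""), character(1))
  headers <- names(seqs)
  parts <- strsplit(headers, delim, fixed = TRUE)
  labs <- vapply(parts, function(p)
    if (length(p) >= field) trimws(p[field]) else NA_character_, character(1))
  bad <- is.na(labs) | !nzchar(labs)
  if (!is.null(regions)) bad <- bad | !(labs %in% regions)
  if (any(bad))
    stop("label error: cannot extract a region tag from header(s): ",
         paste(head(headers[bad], 5), collapse = "; "))
  ids <- vapply(parts, function(p) trimws(p[1]), character(1))
  names(seqs) <- make.unique(ids)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1 && !any(grepl("-", seqs, fixed = TRUE)))
    stop("alignment error: unequal sequence lengths and no gaps present")
  haplotype_set(seqs, labs)
}

#' Write a haplotype set to FASTA
#' @param hs a [haplotype_set()].
#' @param file output path; `NULL` returns the lines.
#' @param delim delimiter between identifier and region tag in the header.
#' @return FASTA lines, invisibly.
#' @export
write_fasta_haplotypes <- function(hs, file = NULL, delim = "|") {
  lines <- as.vector(rbind(
    paste0(">", names(hs$sequences), delim, as.character(hs$labels)),
    unname(hs$sequences)))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# locate the tandem array of `motif` in one sequence: c(start, copies),
# start is NA when absent
locate_tandem <- function(seq, motif) {
  pos <- regexpr(motif, seq, fixed = TRUE)[1]
  if (pos < 0) return(c(NA_integer_, 0L))
  w <- nchar(motif); copies <- 1L
  while (substr(seq, pos + copies * w, pos + (copies + 1) * w - 1) == motif)
    copies <- copies + 1L
  c(as.integer(pos), copies)
}

#' Recode tandem-repeat indels as single-site characters
#'
#' Each perfect tandem array of `n` motif copies is replaced, in place, by
#' `n` adenosines followed by `max - n` single-site gaps, so a copy-number
#' difference of `|n - m|` between two sequences becomes exactly `|n - m|`
#' single-site steps. A sequence with two 9-bp and seven 40-bp repeats is
#' thus recoded with segments `AA-----` and `AAAAAAA------`. The combined
#' alignment length is the repeat-free length plus the sum of motif maxima.
#'
#' @param sequences character vector of raw sequences with the repeats in
#'   place (equal-length outside the repeat arrays).
#' @param motifs list of motif descriptors as in [control_region_motifs()];
#'   an optional `at` field fixes the array start (1-based, in the
#'   coordinates seen when the motif is processed) for sequence sets in
#'   which some sequences carry zero copies.
#' @param labels per-sequence deme labels.
#' @return a [haplotype_set()] with recoded sequences, `repeat_counts`
#'   recovered per motif, and the recoded segment positions stored in
#'   `attr(, "motif_info")`.
#' @export
recode_indels <- function(sequences, motifs = control_region_motifs(),
                          labels = rep("GOM", length(sequences))) {
  seqs <- toupper(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  counts <- matrix(0L, length(seqs), length(motifs),
                   dimnames = list(names(seqs),
                                   vapply(motifs, `[[`, "", "name")))
  info <- list()
  for (m in seq_along(motifs)) {
    mot <- motifs[[m]]
    loc <- t(vapply(seqs, locate_tandem, integer(2), motif = mot$motif))
    if (any(loc[, 2] > mot$max))
      stop("bounds error: ", mot$name, " repeated ", max(loc[, 2]),
           " times, more than the stated maximum ", mot$max)
    found <- !is.na(loc[, 1])
    if (any(found)) {
      start <- as.integer(names(sort(table(loc[found, 1]), decreasing = TRUE))[1])
      off <- found & loc[, 1] != start
      if (any(off))
        stop("recode error: ", mot$name, " array found at position ",
             loc[which(off)[1], 1], " in ", names(seqs)[which(off)[1]],
             " but at ", start, " in the other sequences")
    } else if (!is.null(mot$at)) {
      start <- as.integer(mot$at)
    } else {
      stop("recode error: motif ", mot$name,
           " absent from every sequence and no 'at' position given")
    }
    w <- nchar(mot$motif)
    seg <- function(n) paste0(strrep("A", n), strrep("-", mot$max - n))
    seqs <- vapply(seq_along(seqs), function(i) {
      n <- loc[i, 2]
      paste0(substr(seqs[i], 1, start - 1), seg(n),
             substr(seqs[i], start + n * w, nchar(seqs[i])))
    }, character(1), USE.NAMES = FALSE)
    names(seqs) <- rownames(counts)
    counts[, m] <- loc[, 2]
    info[[mot$name]] <- list(start = start, max = mot$max, motif = mot$motif)
  }
  hs <- haplotype_set(seqs, labels, counts,
                      motif_max = vapply(motifs, `[[`, 0L, "max"))
  attr(hs, "motif_info") <- info
  hs
}

#' Columns of the recoded alignment occupied by indel segments
#' @param hs a recoded [haplotype_set()] carrying `motif_info`.
#' @return integer vector of column indices (empty if no motif info).
#' @keywords internal
indel_columns <- function(hs) {
  info <- attr(hs, "motif_info")
  if (is.null(info)) return(integer(0))
  cols <- integer(0); shift <- 0L
  # segments were inserted sequentially; starts recorded in the coordinates
  # at processing time, so later segments already include earlier shifts
  for (m in info) {
    cols <- c(cols, seq(m$start, length.out = m$max))
  }
  cols
}

#' Alignment as a character matrix restricted to a data view
#'
#' The three mtDNA data views mirror the analysis design: `sequence_only`
#' drops the recoded indel segments and any residual gap-bearing columns;
#' `sequence_plus_indels` keeps the full recoded alignment (each indel site
#' is a standard site); `indels_as_rflp` uses only the repeat-count loci.
#'
#' @param hs a [haplotype_set()].
#' @param view one of `"sequence_only"`, `"sequence_plus_indels"`,
#'   `"indels_as_rflp"`.
#' @return character matrix (sequences x sites); for `indels_as_rflp` the
#'   repeat-count matrix is returned instead.
#' @export
view_matrix <- function(hs, view = c("sequence_only", "sequence_plus_indels",
                                     "indels_as_rflp")) {
  view <- match.arg(view)
  if (view == "indels_as_rflp") {
    if (is.null(hs$repeat_counts)) stop("no repeat-count loci in this set")
    return(hs$repeat_counts)
  }
  m <- do.call(rbind, strsplit(unname(hs$sequences), ""))
  rownames(m) <- names(hs$sequences)
  if (view == "sequence_only") {
    drop <- indel_columns(hs)
    if (length(drop)) m <- m[, -drop, drop = FALSE]
    gapcol <- apply(m == "-", 2, any)
    m <- m[, !gapcol, drop = FALSE]
  }
  m
}

#' Pairwise step distances between haplotypes
#'
#' Counts differing sites and indel copy-number steps separately, so each
#' step of a distance is attributable to a base change, a 9-bp repeat
#' change, or a 40-bp repeat change.
#'
#' @param hs a [haplotype_set()].
#' @param view data view as in [view_matrix()].
#' @return list with `total` distance matrix and per-component matrices
#'   `base` and one per repeat motif (zero matrices where not applicable).
#' @export
pairwise_steps <- function(hs, view = c("sequence_plus_indels",
                                        "sequence_only", "indels_as_rflp")) {
  view <- match.arg(view)
  n <- length(hs$sequences)
  base <- matrix(0, n, n)
  if (view != "indels_as_rflp") {
    m <- view_matrix(hs, "sequence_only")
    if (ncol(m) > 0) {
      codes <- matrix(match(m, c("A", "C", "G", "T", "-")), n)
      for (i in seq_len(n - 1)) {
        di <- colSums(t(codes[(i + 1):n, , drop = FALSE]) != codes[i, ])
        base[i, (i + 1):n] <- di; base[(i + 1):n, i] <- di
      }
    }
  }
  comps <- list(base = base)
  if (view != "sequence_only" && !is.null(hs$repeat_counts)) {
    for (j in seq_len(ncol(hs$repeat_counts))) {
      cj <- hs$repeat_counts[, j]
      comps[[colnames(hs$repeat_counts)[j]]] <- abs(outer(cj, cj, "-"))
    }
  }
  total <- Reduce(`+`, comps)
  dimnames(total) <- list(names(hs$sequences), names(hs$sequences))
  c(list(total = total), comps)
}

#' Subset a haplotype set
#' @param hs a [haplotype_set()].
#' @param idx index over sequences.
#' @return the subsetted `haplotype_set`.
#' @export
subset_haplotypes <- function(hs, idx) {
  out <- haplotype_set(hs$sequences[idx], as.character(hs$labels)[idx],
                       if (!is.null(hs$repeat_counts))
                         hs$repeat_counts[idx, , drop = FALSE],
                       motif_max = hs$motif_max)
  attr(out, "motif_info") <- attr(hs, "motif_info")
  out
}
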