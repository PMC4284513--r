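#' Read a sequence alignment (aligned FASTA or Clustal)
#'
#' Thin wrapper over [Biostrings::readAAMultipleAlignment()] producing a
#' light alignment object with named column-range region annotations (e.g.
#' `"PD"`, `"VSD"`, `"S2-S3 loop"`).
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @param regions named list of `c(start, end)` column ranges (closed,
#'   1-based alignment columns).
#' @return object of class `"seq_alignment"`: list with `sequences` (named
#'   uppercase gapped strings, equal length) and `regions`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           regions = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seq_alignment(as.character(msa), regions = regions)
}

#' Construct an alignment object from gapped strings
#' @param sequences named character vector of gapped sequences (equal length).
#' @param regions named list of `c(start, end)` column ranges.
#' @return object of class `"seq_alignment"`.
#' @export
seq_alignment <- function(sequences, regions = list()) {
  sequences <- toupper(sequences)
  if (length(sequences) < 2) stop("an alignment needs at least two sequences")
  len <- unique(nchar(sequences))
  if (length(len) != 1)
    stop("gapped sequences must have equal length (got ",
         paste(nchar(sequences), collapse = ", "), ")")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2 || r[1] < 1 || r[2] > len || r[1] > r[2])
      stop("region '", nm, "' out of alignment bounds [1, ", len, "]")
  }
  structure(list(sequences = sequences, length = len, regions = regions),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("Alignment:", length(x$sequences), "sequences x", x$length, "columns\n")
  if (length(x$regions))
    cat("Regions:", paste(sprintf("%s[%d-%d]", names(x$regions),
                                  vapply(x$regions, `[`, 1, 1),
                                  vapply(x$regions, `[`, 1, 2)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Percent sequence identity over an alignment region
#'
#' Identity = 100 x (columns where both residues are identical and neither is
#' a gap) / (denominator columns). With the default `"reference"` convention
#' the denominator is the columns (within the region, after exclusion) where
#' the *reference* (first of `seqs`) is not a gap; `"both"` counts only
#' columns where neither sequence is gapped, which makes the measure symmetric
#' under swapping the two sequences.
#'
#' @param aln a [seq_alignment()].
#' @param region region name (from `aln$regions`), or `NULL` for the full
#'   alignment length.
#' @param exclude optional region name whose columns are removed first.
#' @param seqs indices or names of the two sequences to compare.
#' @param denominator `"reference"` or `"both"`.
#' @return percentage (full precision); the integer-rounded value customary in
#'   reports is attached as attribute `"rounded"`.
#' @examples
#' aln <- seq_alignment(c(a = "AC-T", b = "AG-T"))
#' percent_identity(aln)  # 66.67% over 3 reference non-gap columns
#' @export
percent_identity <- function(aln, region = NULL, exclude = NULL,
                             seqs = c(1, 2),
                             denominator = c("reference", "both")) {
  stopifnot(inherits(aln, "seq_alignment"))
  denominator <- match.arg(denominator)
  if (length(seqs) != 2) stop("exactly two sequences must be selected")
  s1 <- strsplit(aln$sequences[[seqs[1]]], "")[[1]]
  s2 <- strsplit(aln$sequences[[seqs[2]]], "")[[1]]
  cols <- seq_len(aln$length)
  if (!is.null(region)) {
    r <- aln$regions[[region]]
    if (is.null(r)) stop("region '", region, "' is not annotated")
    cols <- r[1]:r[2]
  }
  if (!is.null(exclude)) {
    x <- aln$regions[[exclude]]
    if (is.null(x)) stop("exclude region '", exclude, "' is not annotated")
    cols <- setdiff(cols, x[1]:x[2])
  }
  gap <- c("-", ".")
  g1 <- s1[cols] %in% gap
  g2 <- s2[cols] %in% gap
  denom_cols <- if (denominator == "reference") !g1 else (!g1 & !g2)
  n_denom <- sum(denom_cols)
  if (n_denom == 0) stop("zero denominator: no usable columns in region")
  n_match <- sum(denom_cols & !g1 & !g2 & s1[cols] == s2[cols])
  pct <- 100 * n_match / n_denom
  attr(pct, "rounded") <- round(pct)
  attr(pct, "n_columns") <- n_denom
  pct
}
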