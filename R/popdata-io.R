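#' Read an aligned FASTA file
#'
#' Reads an equal-length nucleotide alignment (one mitochondrial marker) into
#' a `dna_alignment` object: a character matrix with one row per sample and
#' one column per site, normalised to uppercase IUPAC codes.
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @param marker Marker label (e.g. `"COI"`), stored with the alignment.
#' @return A `dna_alignment`: character matrix (samples x sites) with
#'   attribute `marker`. Record order follows file order.
#' @export
read_alignment <- function(path, marker = "marker") {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  new_alignment(seqs, names(recs), marker)
}

# Construct and validate a dna_alignment from raw sequence strings.
new_alignment <- function(seqs, ids, marker) {
  ids <- as.character(ids)
  if (any(!nzchar(ids))) stop("empty sample id in alignment")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (!length(seqs) || lens[1L] == 0L) stop("empty alignment")
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != stats::median(lens)]
    stop("alignment error: sequences of unequal length (offending ids: ",
         paste(bad, collapse = ", "), ")")
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  illegal <- !(mat %in% IUPAC_CODES)
  if (any(illegal)) {
    idx <- which(illegal)[1L]
    r <- (idx - 1L) %% nrow(mat) + 1L
    s <- (idx - 1L) %/% nrow(mat) + 1L
    stop(sprintf("parse error: illegal character '%s' in sequence '%s' at site %d",
                 mat[idx], ids[r], s))
  }
  structure(mat, marker = marker, class = c("dna_alignment", "matrix", "array"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences of %d bp (marker %s)\n",
              nrow(x), ncol(x), attr(x, "marker")))
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated table with columns `sample`, `population`, `region`,
#' `lat`, `lon` describing the sampling hierarchy (each population belongs to
#' exactly one region) and decimal-degree WGS84 coordinates.
#'
#' @param path Path to the TSV file.
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  as_sample_metadata(df)
}

#' Validate a metadata data frame
#'
#' @param df Data frame with columns `sample`, `population`, `region`,
#'   `lat`, `lon`.
#' @return A validated `sample_metadata` data frame.
#' @export
as_sample_metadata <- function(df) {
  need <- c("sample", "population", "region", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  df$region <- as.character(df$region)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  if (anyDuplicated(df$sample))
    stop("schema error: duplicate sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  p2r <- unique(df[c("population", "region")])
  if (anyDuplicated(p2r$population)) {
    bad <- unique(p2r$population[duplicated(p2r$population)])
    stop("hierarchy error: population(s) assigned to more than one region: ",
         paste(bad, collapse = ", "))
  }
  if (any(is.na(df$lat)) || any(df$lat < -90 | df$lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(is.na(df$lon)) || any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range [-180, 180]")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Concatenate two marker alignments per individual
#'
#' Joins two alignments sample-by-sample (sequences of `a` followed by
#' sequences of `b`), as for completely linked mitochondrial markers analysed
#' as combined data. Samples present in only one input are dropped with a
#' warning.
#'
#' @param a,b `dna_alignment` objects.
#' @return A `dna_alignment` of length `ncol(a) + ncol(b)` over the shared
#'   samples, in the sample order of `a`.
#' @export
concatenate_loci <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared))
    stop("empty intersection: no sample present in both alignments")
  dropped <- c(setdiff(rownames(a), shared), setdiff(rownames(b), shared))
  if (length(dropped))
    warning("dropping samples absent from one marker: ",
            paste(dropped, collapse = ", "))
  shared <- rownames(a)[rownames(a) %in% shared]   # keep a's order
  mat <- cbind(unclass(a)[shared, , drop = FALSE],
               unclass(b)[shared, , drop = FALSE])
  structure(mat,
            marker = paste(attr(a, "marker"), attr(b, "marker"), sep = "+"),
            class = c("dna_alignment", "matrix", "array"))
}

#' Assemble a validated population-genetic dataset
#'
#' Joins an alignment with its sample metadata (strict: every sequence must
#' have a metadata row) and determines the analyzed-site set: columns that
#' carry only unambiguous bases (A/C/G/T) in every sample. All downstream
#' statistics (S, haplotypes, k, pi, distances, networks) operate on this
#' common site set, mirroring the complete-deletion convention, so that the
#' different summaries are mutually consistent.
#'
#' @param aln A `dna_alignment`.
#' @param meta A `sample_metadata` data frame (or coercible via
#'   [as_sample_metadata()]).
#' @return A `popgen_data` list with elements `seq` (character matrix),
#'   `meta` (metadata rows aligned to the sequences), `analyzed`
#'   (integer indices of analyzed sites), `n_sites` (alignment length) and
#'   `marker`.
#' @export
popgen_data <- function(aln, meta) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (!inherits(meta, "sample_metadata")) meta <- as_sample_metadata(meta)
  orphans <- setdiff(rownames(aln), meta$sample)
  if (length(orphans))
    stop("samples missing from metadata: ", paste(orphans, collapse = ", "))
  extra <- setdiff(meta$sample, rownames(aln))
  if (length(extra))
    warning("metadata rows without sequences are ignored: ",
            paste(extra, collapse = ", "))
  meta <- meta[match(rownames(aln), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- unclass(aln)
  clean <- apply(mat, 2L, function(col) all(col %in% BASES))
  structure(list(seq = mat,
                 meta = meta,
                 analyzed = which(clean),
                 n_sites = ncol(mat),
                 marker = attr(aln, "marker")),
            class = "popgen_data")
}

#' @export
print.popgen_data <- function(x, ...) {
  cat(sprintf("popgen_data: %d samples, %d sites (%d analyzed), marker %s\n",
              nrow(x$seq), x$n_sites, length(x$analyzed), x$marker))
  cat(sprintf("  %d populations in %d regions\n",
              length(unique(x$meta$population)), length(unique(x$meta$region))))
  invisible(x)
}

# Subset a popgen_data to a set of samples (character ids or logical/integer).
pg_subset <- function(x, samples) {
  if (is.character(samples)) samples <- match(samples, x$meta$sample)
  x$seq <- x$seq[samples, , drop = FALSE]
  x$meta <- x$meta[samples, , drop = FALSE]
  x
}

# Analyzed-site sequence matrix.
pg_mat <- function(x) x$seq[, x$analyzed, drop = FALSE]
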