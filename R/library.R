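#' Construct a regional barcode library
#'
#' A region library bundles an aligned set of COI barcode sequences with the
#' specimen metadata (taxonomy, region, optional coordinates) the downstream
#' analyses need.  All sequences must share the same alignment length.
#'
#' @param region Region label (e.g. `"Nearctic"`).
#' @param records Data frame with columns `specimen_id`, `species`, `genus`,
#'   `family` (and optionally `lat`, `lon`).  Species names are binomials;
#'   the genus must equal the first token of the species name.
#' @param sequences Named character vector of aligned sequences (names are
#'   specimen ids) over `A,C,G,T,-,N` and IUPAC ambiguity letters.
#' @return An object of class `region_library`: a list with elements
#'   `region`, `records`, `sequences` and `alignment_length`.
#' @export
region_library <- function(region, records, sequences) {
  stopifnot(is.character(region), length(region) == 1L)
  required <- c("specimen_id", "species", "genus", "family")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("metadata missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in required) records[[col]] <- squish(as.character(records[[col]]))
  if (anyDuplicated(records$specimen_id))
    stop("duplicated specimen_id in metadata: ",
         paste(unique(records$specimen_id[duplicated(records$specimen_id)]),
               collapse = ", "))
  sequences <- toupper(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by specimen id")
  if (!setequal(names(sequences), records$specimen_id))
    stop("sequence names and metadata specimen_id do not match")
  sequences <- sequences[records$specimen_id]
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence(s)")
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned to a common length (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  first_token <- sub("[[:space:]].*$", "", records$species)
  bad <- records$genus != first_token
  if (any(bad))
    stop("genus does not match first token of species for: ",
         paste(records$specimen_id[bad], collapse = ", "))
  structure(
    list(region = region, records = records, sequences = sequences,
         alignment_length = unname(lens[1L])),
    class = "region_library")
}

# collapse internal whitespace runs and trim; keeps name matching deterministic
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' @export
print.region_library <- function(x, ...) {
  cat("Barcode library:", x$region, "\n")
  cat("  specimens:", nrow(x$records),
      " species:", length(unique(x$records$species)),
      " genera:", length(unique(x$records$genus)), "\n")
  cat("  alignment length:", x$alignment_length, "sites\n")
  invisible(x)
}

#' Read a barcode library from FASTA plus a metadata table
#'
#' Joins each aligned FASTA record to its row in a tab-separated metadata
#' table by specimen id.  The metadata must carry columns `specimen_id`,
#' `species`, `genus` and `family`; `lat`/`lon` are kept when present.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the TSV metadata table (with header).
#' @param region Region label attached to the library.
#' @return A [region_library()].
#' @details FASTA ids with no metadata row are a hard error (all offending
#'   ids are listed); metadata rows with no sequence are dropped with a
#'   warning.
#' @export
read_barcode_library <- function(fasta_path, metadata_path, region) {
  seqs <- seqinr::read.fasta(fasta_path, seqtype = "DNA",
                             as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- vapply(seqs, function(s) toupper(as.character(s)[1L]), character(1))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!"specimen_id" %in% names(meta))
    stop("metadata has no specimen_id column")
  meta$specimen_id <- squish(meta$specimen_id)
  unmatched <- setdiff(names(seqs), meta$specimen_id)
  if (length(unmatched))
    stop("FASTA id(s) missing from metadata: ",
         paste(unmatched, collapse = ", "))
  extra <- setdiff(meta$specimen_id, names(seqs))
  if (length(extra)) {
    warning(length(extra), " metadata row(s) without a sequence dropped: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ...")
    meta <- meta[meta$specimen_id %in% names(seqs), , drop = FALSE]
  }
  for (col in c("lat", "lon"))
    if (col %in% names(meta)) meta[[col]] <- as.numeric(meta[[col]])
  region_library(region, meta, seqs)
}

#' Write a barcode library as FASTA plus a metadata table
#'
#' Inverse of [read_barcode_library()]: round-tripping preserves every field.
#'
#' @param lib A [region_library()].
#' @param fasta_path,metadata_path Output paths (FASTA and TSV).
#' @export
write_barcode_library <- function(lib, fasta_path, metadata_path) {
  stopifnot(inherits(lib, "region_library"))
  seqinr::write.fasta(as.list(lib$sequences), names = names(lib$sequences),
                      file.out = fasta_path, nbchar = 80)
  utils::write.table(lib$records, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' Remove low-quality sequences by ambiguous-site fraction
#'
#' Drops every record whose fraction of ambiguous sites (anything other than
#' `A`, `C`, `G`, `T` or the gap character `-`) exceeds
#' `max_ambiguous_fraction` of the alignment length.  Gaps are not counted as
#' ambiguous: aligned barcode ends are routinely padded with them.  The
#' boundary is not removed (strictly greater than).
#'
#' @param lib A [region_library()].
#' @param max_ambiguous_fraction Removal threshold, default `0.01` (1%
#'   ambiguous sites).
#' @return The filtered library; the number of removed records is in
#'   attribute `n_removed` and reported via `message()`.  Filtering is
#'   idempotent.
#' @export
filter_ambiguous <- function(lib, max_ambiguous_fraction = 0.01) {
  stopifnot(inherits(lib, "region_library"),
            max_ambiguous_fraction >= 0, max_ambiguous_fraction <= 1)
  n_amb <- vapply(strsplit(lib$sequences, ""), function(s)
    sum(!s %in% c("A", "C", "G", "T", "-")), integer(1))
  frac <- n_amb / lib$alignment_length
  drop <- frac > max_ambiguous_fraction
  out <- lib
  if (any(drop)) {
    message(sum(drop), " of ", length(drop),
            " sequences removed (> ", 100 * max_ambiguous_fraction,
            "% ambiguous sites): ",
            paste(utils::head(lib$records$specimen_id[drop], 5L),
                  collapse = ", "),
            if (sum(drop) > 5L) ", ...")
    out$records <- lib$records[!drop, , drop = FALSE]
    out$sequences <- lib$sequences[!drop]
  }
  if (!nrow(out$records)) warning("all sequences removed by ambiguity filter")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Subset a library to a set of specimens
#'
#' @param lib A [region_library()].
#' @param specimen_ids Ids to keep (order preserved from the library).
#' @return A [region_library()] with only those records.
#' @export
subset_library <- function(lib, specimen_ids) {
  stopifnot(inherits(lib, "region_library"))
  keep <- lib$records$specimen_id %in% specimen_ids
  if (!any(keep)) stop("no matching specimens")
  out <- lib
  out$records <- lib$records[keep, , drop = FALSE]
  out$sequences <- lib$sequences[keep]
  out
}
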