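#' Assemble a dataset bundle from in-memory tables
#'
#' A bundle holds one row per transcript: `species`, `gene_name`,
#' `gene_id`, `transcript_id`, `upstream_seq` (DNA immediately 5' of the
#' start codon, expected 120 bp but shorter windows are accepted and
#' scanned as-is), `protein_seq` (first residue expected to be the
#' initiator methionine).  `transcript_id` must be unique.
#'
#' @param records Data.frame with the six columns above.
#' @param reference_species Species playing the reference role (the
#'   study's "human"); must occur in `records$species`.
#' @param report Optional load report (list), kept as-is.
#' @return An object of class `tr_bundle`.
#' @export
tr_bundle <- function(records, reference_species, report = list()) {
  need <- c("species", "gene_name", "gene_id", "transcript_id",
            "upstream_seq", "protein_seq")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)[need]
  for (cl in need) records[[cl]] <- as.character(records[[cl]])
  dup <- records$transcript_id[duplicated(records$transcript_id)]
  if (length(dup)) stop("duplicate transcript_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$upstream_seq))) stop("empty upstream_seq")
  if (any(!nzchar(records$species))) stop("empty species")
  if (!reference_species %in% records$species)
    stop("reference_species '", reference_species, "' not present in records")
  rownames(records) <- NULL
  structure(list(records = records, reference_species = reference_species,
                 report = report), class = "tr_bundle")
}

#' @export
print.tr_bundle <- function(x, ...) {
  cat("TIS-upstream dataset bundle\n")
  cat("  transcripts:", nrow(x$records), "\n")
  cat("  species:    ", length(unique(x$records$species)),
      sprintf("(reference: %s)", x$reference_species), "\n")
  cat("  gene names: ", length(unique(x$records$gene_name)), "\n")
  if (length(x$report$dropped))
    cat("  dropped at load:", length(x$report$dropped), "\n")
  invisible(x)
}

# first whitespace-delimited token of a FASTA header
.fasta_ids <- function(x) sub("\\s.*$", "", names(x))

#' Read a dataset bundle from TSV metadata plus two FASTA files
#'
#' The metadata TSV must have header columns `species`, `gene_name`,
#' `gene_id`, `transcript_id`; FASTA record ids (first header token) must
#' equal `transcript_id`.  Rows lacking either sequence are dropped and
#' listed in the load report; FASTA records with no metadata row produce a
#' warning and are ignored; duplicate `transcript_id` is fatal.
#'
#' @param metadata_path Path to the TSV.
#' @param upstream_path Path to the upstream DNA FASTA.
#' @param protein_path Path to the protein FASTA.
#' @param reference_species Reference species identifier.
#' @return A `tr_bundle`; `$report$dropped` lists dropped transcript ids
#'   with the missing side.
#' @export
read_bundle <- function(metadata_path, upstream_path, protein_path,
                        reference_species) {
  for (p in c(metadata_path, upstream_path, protein_path))
    if (!file.exists(p)) stop("file not found: ", p)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("species", "gene_name", "gene_id", "transcript_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  dup <- meta$transcript_id[duplicated(meta$transcript_id)]
  if (length(dup)) stop("duplicate transcript_id in metadata: ",
                        paste(unique(dup), collapse = ", "))

  up <- Biostrings::readDNAStringSet(upstream_path)
  pr <- Biostrings::readAAStringSet(protein_path)
  up_ids <- .fasta_ids(up); pr_ids <- .fasta_ids(pr)
  if (anyDuplicated(up_ids)) stop("duplicate record id in upstream FASTA")
  if (anyDuplicated(pr_ids)) stop("duplicate record id in protein FASTA")
  extra <- c(setdiff(up_ids, meta$transcript_id), setdiff(pr_ids, meta$transcript_id))
  if (length(extra))
    warning("ignoring ", length(extra), " FASTA record(s) with no metadata row: ",
            paste(utils::head(unique(extra), 5), collapse = ", "))

  iu <- match(meta$transcript_id, up_ids)
  ip <- match(meta$transcript_id, pr_ids)
  has_both <- !is.na(iu) & !is.na(ip)
  dropped <- data.frame(
    transcript_id = meta$transcript_id[!has_both],
    missing = ifelse(is.na(iu[!has_both]),
                     ifelse(is.na(ip[!has_both]), "both", "upstream"),
                     "protein"),
    stringsAsFactors = FALSE
  )
  recs <- meta[has_both, , drop = FALSE]
  recs$upstream_seq <- as.character(up)[iu[has_both]]
  recs$protein_seq <- as.character(pr)[ip[has_both]]
  tr_bundle(recs, reference_species,
            report = list(n_rows = nrow(meta), n_loaded = nrow(recs),
                          dropped = dropped$transcript_id,
                          dropped_detail = dropped))
}

#' Write a bundle back to TSV + FASTA
#'
#' Emits `metadata.tsv`, `upstream.fa` and `protein.fa` into `dir` in the
#' exact formats [read_bundle()] consumes (round trip is the identity on
#' record content).
#'
#' @param bundle A `tr_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "tr_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- bundle$records[order(bundle$records$transcript_id), , drop = FALSE]
  paths <- c(metadata = file.path(dir, "metadata.tsv"),
             upstream = file.path(dir, "upstream.fa"),
             protein = file.path(dir, "protein.fa"))
  write_table(r[c("species", "gene_name", "gene_id", "transcript_id")],
              paths[["metadata"]], key = "transcript_id")
  up <- Biostrings::DNAStringSet(r$upstream_seq); names(up) <- r$transcript_id
  pr <- Biostrings::AAStringSet(r$protein_seq); names(pr) <- r$transcript_id
  Biostrings::writeXStringSet(up, paths[["upstream"]])
  Biostrings::writeXStringSet(pr, paths[["protein"]])
  invisible(paths)
}

#' Group a bundle's transcripts by gene name
#'
#' The grouping key is the gene name after uppercasing and whitespace
#' trimming (annotation sources differ in case).  Records with an empty
#' gene name are excluded and reported.  Groups without any
#' reference-species transcript are retained — they still inform
#' specificity — and flagged.
#'
#' @param bundle A `tr_bundle`.
#' @return An object of class `gene_groups`: list with `records` (the
#'   grouped records plus `gene_key` and `is_reference` columns),
#'   `reference_species`, `excluded` (records dropped for empty gene
#'   name), and `flagged` (gene keys with no reference transcript).
#' @export
group_by_gene_name <- function(bundle) {
  stopifnot(inherits(bundle, "tr_bundle"))
  r <- bundle$records
  key <- toupper(trimws(r$gene_name))
  empty <- !nzchar(key)
  excluded <- r[empty, , drop = FALSE]
  if (nrow(excluded))
    message("excluding ", nrow(excluded), " record(s) with empty gene_name")
  r <- r[!empty, , drop = FALSE]
  r$gene_key <- key[!empty]
  r$is_reference <- r$species == bundle$reference_species
  flagged <- setdiff(unique(r$gene_key), unique(r$gene_key[r$is_reference]))
  rownames(r) <- NULL
  structure(list(records = r, reference_species = bundle$reference_species,
                 excluded = excluded, flagged = flagged),
            class = "gene_groups")
}

#' @export
print.gene_groups <- function(x, ...) {
  cat("Gene groups:", length(unique(x$records$gene_key)), "groups,",
      nrow(x$records), "transcripts (reference:", x$reference_species, ")\n")
  if (length(x$flagged))
    cat("  ", length(x$flagged), "group(s) lack a reference transcript\n")
  invisible(x)
}

#' Write a flat result table as deterministic TSV
#'
#' UTF-8, tab-separated, '.' decimal point, header line, rows sorted by
#' the key column so repeated writes are byte-identical.
#'
#' @param rows Data.frame.
#' @param path Output path.
#' @param key Column to sort by (default: first column).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, key = names(rows)[1]) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) && !is.null(key) && key %in% names(rows))
    rows <- rows[order(rows[[key]]), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
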