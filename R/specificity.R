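.filter_category <- function(hits, category) {
  if (identical(category, "all") || is.null(category)) return(hits)
  category <- as.integer(category)
  if (is.na(category) || !category %in% 1:4) stop("category must be 1..4 or \"all\"")
  hits[hits$category == category, , drop = FALSE]
}

#' Classify TR types as species-specific or shared within gene groups
#'
#' For every gene group, each TR type — the `(core, n_repeats)` pair — is
#' assigned the set of species it was observed in across the group's
#' transcripts.  Types seen in two or more species are `SHARED`; types
#' seen in exactly one species are `SPECIFIC` to it.  Specificity is a
#' per-group notion: the same type can be specific in one group and
#' shared in another.
#'
#' @param groups A `gene_groups` object from [group_by_gene_name()].
#' @param hits TR hit table from [find_tandem_repeats()].
#' @param category Restrict to one core-length category (1–4) or `"all"`.
#' @return Class `tr_specificity`: data.frame with one row per observed
#'   `(gene_key, core, n_repeats)` with columns `n_species`, `species`
#'   (comma-joined), `label` (`"SPECIFIC"`/`"SHARED"`) and
#'   `specific_species` (`NA` for shared types).  The `category` used is
#'   kept as an attribute.
#' @export
build_specificity <- function(groups, hits, category = "all") {
  stopifnot(inherits(groups, "gene_groups"))
  hits <- .filter_category(hits, category)
  r <- groups$records
  idx <- match(hits$transcript_id, r$transcript_id)
  if (anyNA(idx))
    stop("hit with unknown transcript_id: ",
         paste(utils::head(unique(hits$transcript_id[is.na(idx)]), 5), collapse = ", "))
  if (nrow(hits) == 0L) {
    out <- data.frame(gene_key = character(), core = character(),
                      n_repeats = integer(), category = integer(),
                      n_species = integer(), species = character(),
                      label = character(), specific_species = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("tr_specificity", "data.frame"),
                     category = category))
  }
  d <- data.frame(gene_key = r$gene_key[idx], species = r$species[idx],
                  core = hits$core, n_repeats = hits$n_repeats,
                  category = hits$category, stringsAsFactors = FALSE)
  typekey <- paste(d$gene_key, d$core, d$n_repeats, sep = "\r")
  sp_by_type <- lapply(split(d$species, typekey), unique)
  first <- d[!duplicated(typekey), , drop = FALSE]
  k <- paste(first$gene_key, first$core, first$n_repeats, sep = "\r")
  sp_by_type <- sp_by_type[k]  # align to first-occurrence order
  n_sp <- vapply(sp_by_type, length, integer(1))
  out <- data.frame(
    gene_key = first$gene_key, core = first$core,
    n_repeats = first$n_repeats, category = first$category,
    n_species = unname(n_sp),
    species = vapply(sp_by_type, function(s) paste(sort(s), collapse = ","),
                     character(1)),
    label = ifelse(n_sp >= 2L, "SHARED", "SPECIFIC"),
    specific_species = ifelse(n_sp == 1L,
                              vapply(sp_by_type, `[[`, character(1), 1L), NA),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_key, out$core, out$n_repeats), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tr_specificity", "data.frame"), category = category)
}

#' Global specificity summary
#'
#' Reporting view complementing the per-group labels: a TR type counts as
#' globally reference-specific only if it is never observed in a
#' non-reference species in any group.
#'
#' @param spec A `tr_specificity` table.
#' @param reference_species Reference species identifier.
#' @return Data.frame with one row per distinct `(core, n_repeats)` type:
#'   `globally_reference_specific` flag and per-category counts attribute.
#' @export
specificity_summary <- function(spec, reference_species) {
  if (nrow(spec) == 0L)
    return(data.frame(core = character(), n_repeats = integer(),
                      category = integer(),
                      globally_reference_specific = logical()))
  tkey <- paste(spec$core, spec$n_repeats, sep = "\r")
  seen_in_ref <- tapply(spec$label == "SPECIFIC" &
                          spec$specific_species == reference_species,
                        tkey, any)
  seen_elsewhere <- tapply(
    spec$label == "SHARED" |
      (spec$label == "SPECIFIC" & spec$specific_species != reference_species),
    tkey, any)
  first <- spec[!duplicated(tkey), c("core", "n_repeats", "category")]
  k <- paste(first$core, first$n_repeats, sep = "\r")
  out <- data.frame(first,
    globally_reference_specific =
      unname(seen_in_ref[k] & !seen_elsewhere[k]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag transcripts by their TR content
#'
#' Every transcript gets `has_any_tr` (at least one qualifying TR in the
#' active category); reference transcripts additionally get
#' `has_ref_specific_tr` (at least one TR whose type is, within the
#' transcript's gene group, specific to the reference species).  These are
#' the membership flags behind the co-occurrence analysis: group A =
#' reference transcripts with a reference-specific TR, group B = reference
#' transcripts with TRs but none reference-specific.
#'
#' @param spec A `tr_specificity` built on the same hits.
#' @param groups The `gene_groups` object.
#' @param hits The TR hit table the table was built on.
#' @param reference_species Defaults to the groups' reference.
#' @return Data.frame, one row per grouped transcript: `transcript_id`,
#'   `species`, `gene_key`, `is_reference`, `has_any_tr`,
#'   `has_ref_specific_tr` (always `FALSE` for non-reference transcripts).
#' @export
flag_transcripts <- function(spec, groups, hits,
                             reference_species = groups$reference_species) {
  stopifnot(inherits(groups, "gene_groups"))
  hits <- .filter_category(hits, attr(spec, "category"))
  r <- groups$records
  flags <- data.frame(transcript_id = r$transcript_id, species = r$species,
                      gene_key = r$gene_key, is_reference = r$is_reference,
                      stringsAsFactors = FALSE)
  flags$has_any_tr <- flags$transcript_id %in% hits$transcript_id
  flags$has_ref_specific_tr <- FALSE
  if (nrow(spec)) {
    sp_types <- spec[spec$label == "SPECIFIC" &
                       spec$specific_species == reference_species, , drop = FALSE]
    if (nrow(sp_types) && nrow(hits)) {
      idx <- match(hits$transcript_id, r$transcript_id)
      hkey <- paste(r$gene_key[idx], hits$core, hits$n_repeats, sep = "\r")
      skey <- paste(sp_types$gene_key, sp_types$core, sp_types$n_repeats, sep = "\r")
      carriers <- unique(hits$transcript_id[hkey %in% skey])
      flags$has_ref_specific_tr <- flags$is_reference &
        flags$transcript_id %in% carriers
    }
  }
  flags
}
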