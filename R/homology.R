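#' Position weight vectors for TIS prefix scoring
#'
#' Two published weightings of the six N-terminal residue positions.  The
#' initiator methionine (position 1) always carries weight 0; the five
#' following positions carry `W1 = (25, 25, 25, 12.5, 12.5)` or
#' `W2 = (20, 20, 20, 20, 20)`.  Weights sum to 100 so a score is a
#' percentage.
#'
#' @param label `"W1"` or `"W2"`, or a numeric vector of six weights
#'   (first element 0, sum 100) for a custom weighting.
#' @return Numeric vector of length 6, class `tis_weights`, with a
#'   `label` attribute.
#' @export
weight_vector <- function(label = c("W1", "W2")) {
  if (is.numeric(label)) {
    w <- as.numeric(label)
    lab <- "custom"
  } else {
    lab <- match.arg(label)
    w <- switch(lab, W1 = c(0, 25, 25, 25, 12.5, 12.5),
                     W2 = c(0, 20, 20, 20, 20, 20))
  }
  if (length(w) != 6L || any(w < 0)) stop("weights must be six non-negative numbers")
  if (w[1] != 0) stop("position 1 (initiator methionine) must have weight 0")
  if (abs(sum(w) - 100) > 1e-9) stop("weights must sum to 100")
  structure(w, class = "tis_weights", label = lab)
}

.as_weights <- function(w) {
  if (inherits(w, "tis_weights")) w else weight_vector(w)
}

#' Six-residue TIS prefix of a protein
#'
#' Returns the first six residues (the initiator methionine plus the five
#' positions that carry weight), or `NA` when the protein is shorter than
#' six residues — such transcripts are excluded from homology events.
#'
#' @param protein_seq Character vector of amino-acid sequences.
#' @return Character vector of 6-residue prefixes or `NA`.
#' @examples
#' tis_prefix(c("MALWMRLLPL", "MALW"))  # "MALWMR", NA
#' @export
tis_prefix <- function(protein_seq) {
  protein_seq <- as.character(protein_seq)
  out <- ifelse(!is.na(protein_seq) & nchar(protein_seq) >= 6L,
                substr(protein_seq, 1L, 6L), NA_character_)
  out
}

#' Weighted TIS prefix similarity score
#'
#' `S = sum_{i=2..6} w_i * [a_i == b_i]`: exact character identity per
#' position, weighted and summed over the five positions after the
#' initiator methionine.  Since weights sum to 100 the score is a
#' percentage in `[0, 100]`.
#'
#' @param prefix_a,prefix_b Character vectors of 6-residue prefixes
#'   (recycled to a common length).
#' @param w A weight vector (`"W1"`, `"W2"`, or [weight_vector()] output).
#' @return Numeric vector of scores.
#' @export
similarity_score <- function(prefix_a, prefix_b, w = "W1") {
  w <- .as_weights(w)
  n <- max(length(prefix_a), length(prefix_b))
  prefix_a <- rep_len(as.character(prefix_a), n)
  prefix_b <- rep_len(as.character(prefix_b), n)
  if (any(nchar(prefix_a) != 6L) || any(nchar(prefix_b) != 6L))
    stop("prefixes must be exactly 6 residues (see tis_prefix())")
  s <- numeric(n)
  for (i in 2:6)
    s <- s + w[i] * (substr(prefix_a, i, i) == substr(prefix_b, i, i))
  s
}

#' Homology call from a similarity score
#'
#' A transcript pair is called homologous when its weighted prefix
#' similarity reaches 50 of 100 — the boundary is inclusive.
#'
#' @param score Numeric vector in `[0, 100]`.
#' @return Logical vector.
#' @export
is_homologous <- function(score) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) stop("score must be in [0, 100]")
  score >= 50
}

#' Count homologous and non-homologous TIS pair events
#'
#' Iterates all pairs `(t_a, t_b)` where `t_a` is a reference-species
#' transcript in the selected group (`"specific"`: carries a
#' reference-specific TR; `"nonspecific"`: carries TRs but none
#' reference-specific) and `t_b` is a non-reference transcript of the same
#' gene group carrying at least one TR.  Each pair is one event, scored
#' with [similarity_score()] and called with [is_homologous()].
#' Transcripts with proteins shorter than six residues are excluded and
#' counted.
#'
#' @param groups A `gene_groups` object.
#' @param flags Output of [flag_transcripts()] on the same grouping.
#' @param w Weight vector (`"W1"`/`"W2"`/[weight_vector()]).
#' @param ref_group `"specific"` or `"nonspecific"`.
#' @param gene_subset Optional character vector of gene keys to restrict
#'   the reference side to (used by fold subsampling).
#' @return List: `n_homologous`, `n_non_homologous`, `events` (data.frame
#'   with `gene_key`, `ref_transcript_id`, `other_transcript_id`,
#'   `other_species`, `score`, `homologous`), and `n_excluded_short`.
#' @export
count_events <- function(groups, flags, w = "W1",
                         ref_group = c("specific", "nonspecific"),
                         gene_subset = NULL) {
  stopifnot(inherits(groups, "gene_groups"))
  ref_group <- match.arg(ref_group)
  w <- .as_weights(w)
  r <- groups$records
  prefix <- tis_prefix(r$protein_seq)
  n_short <- sum(is.na(prefix))
  f <- flags[match(r$transcript_id, flags$transcript_id), , drop = FALSE]

  sel_a <- f$is_reference & !is.na(prefix) &
    (if (ref_group == "specific") f$has_ref_specific_tr
     else f$has_any_tr & !f$has_ref_specific_tr)
  sel_b <- !f$is_reference & f$has_any_tr & !is.na(prefix)
  if (!is.null(gene_subset)) {
    sel_a <- sel_a & r$gene_key %in% gene_subset
    sel_b <- sel_b & r$gene_key %in% gene_subset
  }
  ta <- data.frame(gene_key = r$gene_key[sel_a],
                   ref_transcript_id = r$transcript_id[sel_a],
                   prefix_a = prefix[sel_a], stringsAsFactors = FALSE)
  tb <- data.frame(gene_key = r$gene_key[sel_b],
                   other_transcript_id = r$transcript_id[sel_b],
                   other_species = r$species[sel_b],
                   prefix_b = prefix[sel_b], stringsAsFactors = FALSE)
  ev <- merge(ta, tb, by = "gene_key", sort = FALSE)
  if (nrow(ev)) {
    ev$score <- similarity_score(ev$prefix_a, ev$prefix_b, w)
    ev$homologous <- is_homologous(ev$score)
    ev <- ev[order(ev$gene_key, ev$ref_transcript_id, ev$other_transcript_id), ]
    rownames(ev) <- NULL
  } else {
    ev$score <- numeric(0); ev$homologous <- logical(0)
  }
  events <- ev[c("gene_key", "ref_transcript_id", "other_transcript_id",
                 "other_species", "score", "homologous")]
  list(n_homologous = sum(ev$homologous),
       n_non_homologous = sum(!ev$homologous),
       events = events, n_excluded_short = n_short)
}

#' Per-TIS homology roll-up
#'
#' Reporting view: a reference TIS counts as homologous when at least one
#' of its cross-species partners is homologous.  The co-occurrence test
#' itself consumes pair events, not this roll-up.
#'
#' @param events Event data.frame from [count_events()].
#' @return Data.frame with one row per `ref_transcript_id`: `n_partners`,
#'   `n_homologous_partners`, `tis_homologous`.
#' @export
tis_rollup <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(ref_transcript_id = character(), n_partners = integer(),
                      n_homologous_partners = integer(),
                      tis_homologous = logical()))
  sp <- split(events$homologous, events$ref_transcript_id)
  data.frame(ref_transcript_id = names(sp),
             n_partners = vapply(sp, length, integer(1)),
             n_homologous_partners = vapply(sp, sum, integer(1)),
             tis_homologous = vapply(sp, any, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
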