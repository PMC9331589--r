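.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.DNA4 <- c("A", "C", "G", "T")

# core-length band per category for planted repeats; category 4 capped at
# 24 bp so two copies fit comfortably in a 120-bp window
.CAT_BANDS <- list(c(1L, 6L), c(7L, 9L), c(10L, 15L), c(16L, 24L))

#' Configuration for the synthetic multi-species generator
#'
#' Defaults emulate the study conditions: 120-bp upstream windows, a mean
#' of 1.19 tandem repeats per transcript, and a core-length category mix
#' proportional to the reported per-category abundance of
#' reference-specific TR types (660:101:339:404).  The planted
#' association between reference-specific TRs and TIS divergence is
#' encoded by two conditional probabilities whose implied gene-level odds
#' ratio is [expected_odds_ratio()].
#'
#' @param n_species Number of species (>= 2); the first is the reference.
#' @param n_genes Number of gene groups.
#' @param transcripts_per_gene Mean transcripts per gene and species
#'   (counts are `1 + Poisson(mean - 1)`).
#' @param upstream_len Upstream window length (default 120).
#' @param tr_rate Target mean TRs per transcript (default 1.19).
#' @param category_mix Four probabilities (sum 1) for planted core-length
#'   categories.
#' @param p_diverged Probability a gene's non-reference TIS prefixes are
#'   drawn independently (diverged) rather than copied with substitutions
#'   (conserved).
#' @param p_specific_tr_given_diverged,p_specific_tr_given_conserved
#'   Probability of planting a reference-specific TR given the gene's
#'   divergence label.
#' @param prefix_sub_rate Per-position substitution probability applied
#'   when copying conserved prefixes (and protein tails) across species.
#' @param protein_len Protein length (>= 6).
#' @param couple_protein_divergence When `TRUE`, diverged genes also get
#'   independently drawn protein tails, coupling full-protein divergence
#'   to the prefix label (used by the alignment check).
#' @param shared_species_prob Probability each species joins a planted
#'   shared TR type (conditioned on at least two joining).
#' @param seed Integer seed; the generator is deterministic under it.
#' @return Class `sim_config` list.
#' @export
sim_config <- function(n_species = 10L, n_genes = 500L,
                       transcripts_per_gene = 1.6, upstream_len = 120L,
                       tr_rate = 1.19,
                       category_mix = c(660, 101, 339, 404) / 1504,
                       p_diverged = 0.5,
                       p_specific_tr_given_diverged = 0.5,
                       p_specific_tr_given_conserved = 0.25,
                       prefix_sub_rate = 0.05, protein_len = 30L,
                       couple_protein_divergence = FALSE,
                       shared_species_prob = 0.5, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), n_genes = as.integer(n_genes),
              transcripts_per_gene = transcripts_per_gene,
              upstream_len = as.integer(upstream_len), tr_rate = tr_rate,
              category_mix = category_mix, p_diverged = p_diverged,
              p_specific_tr_given_diverged = p_specific_tr_given_diverged,
              p_specific_tr_given_conserved = p_specific_tr_given_conserved,
              prefix_sub_rate = prefix_sub_rate,
              protein_len = as.integer(protein_len),
              couple_protein_divergence = isTRUE(couple_protein_divergence),
              shared_species_prob = shared_species_prob,
              seed = as.integer(seed))
  if (cfg$n_species < 2L) stop("n_species must be >= 2")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$transcripts_per_gene < 1) stop("transcripts_per_gene must be >= 1")
  if (cfg$protein_len < 6L) stop("protein_len must be >= 6")
  if (length(cfg$category_mix) != 4L || any(cfg$category_mix < 0))
    stop("category_mix must be four non-negative probabilities")
  if (abs(sum(cfg$category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1")
  probs <- c(cfg$p_diverged, cfg$p_specific_tr_given_diverged,
             cfg$p_specific_tr_given_conserved, cfg$prefix_sub_rate,
             cfg$shared_species_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  max_core <- max(vapply(which(cfg$category_mix > 0),
                         function(i) .CAT_BANDS[[i]][2], integer(1)))
  if (cfg$upstream_len < 2L * max_core)
    stop("upstream_len (", cfg$upstream_len, ") must be at least twice the ",
         "largest planted core length (", max_core, ")")
  cfg$species <- sprintf("species%02d", seq_len(cfg$n_species))
  cfg$reference_species <- cfg$species[1]
  structure(cfg, class = "sim_config")
}

#' Planted gene-level odds ratio of a configuration
#'
#' Closed form for the odds ratio of carrying a reference-specific TR
#' between diverged and conserved genes:
#' `p_d (1 - p_c) / (p_c (1 - p_d))`.
#'
#' @param config A `sim_config`.
#' @return Positive number.
#' @examples
#' expected_odds_ratio(sim_config(p_specific_tr_given_diverged = 0.6,
#'                                p_specific_tr_given_conserved = 0.2))  # 6
#' @export
expected_odds_ratio <- function(config) {
  p_d <- config$p_specific_tr_given_diverged
  p_c <- config$p_specific_tr_given_conserved
  p_d * (1 - p_c) / (p_c * (1 - p_d))
}

# substitute each position with probability rate, always to a different
# symbol: shift the alphabet index by a uniform non-zero offset
.mutate_chars <- function(ch, rate, alphabet) {
  m <- length(alphabet)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    off <- sample.int(m - 1L, length(hit), replace = TRUE)
    ch[hit] <- alphabet[(match(ch[hit], alphabet) - 1L + off) %% m + 1L]
  }
  ch
}

# one random primitive core of the given category band
.rand_core <- function(category) {
  band <- .CAT_BANDS[[category]]
  repeat {
    L <- if (band[1] == band[2]) band[1] else sample(band[1]:band[2], 1L)
    core <- paste(sample(.DNA4, L, replace = TRUE), collapse = "")
    if (.is_primitive_core(core)) return(core)
  }
}

# a block is clean when the repeated core, scanned on its own, yields
# exactly the intended hit (random long cores can contain qualifying
# sub-repeats, which would make detection-verified planting impossible)
.block_clean <- function(core, count) {
  h <- .tr_scan(strrep(core, count), 60L)
  length(h$start) == 1L && h$start == 0L &&
    h$core_length == nchar(core) && h$n_repeats == count
}

.is_primitive_core <- function(core) {
  L <- nchar(core)
  if (L == 1L) return(TRUE)
  for (d in seq_len(L %/% 2)) {
    if (L %% d != 0L) next
    if (strrep(substr(core, 1L, d), L %/% d) == core) return(FALSE)
  }
  TRUE
}

# minimal qualifying counts; mononucleotides get a small spread so that
# planted (T)6..(T)8 style types occur.  Counts above the minimum for
# multi-base cores would create phase duplicates, so they stay minimal.
.rand_count <- function(core_length) {
  if (core_length == 1L) sample(6:8, 1L)
  else if (core_length <= 9L) 3L
  else 2L
}

# Assemble one upstream sequence containing exactly the planted blocks
# (core/count vectors) and no other qualifying TR.  Background is i.i.d.
# ACGT; draws whose detected hit set differs from the plant are rejected.
# Returns NULL when the blocks cannot fit the window.
.build_upstream <- function(cores, counts, W, max_tries = 500L) {
  .build_upstream_cpp(as.character(cores), as.integer(counts),
                      as.integer(W), 60L, as.integer(max_tries))
}

#' Simulate a multi-species dataset bundle with planted ground truth
#'
#' For each gene: a divergence label is drawn; non-reference TIS prefixes
#' are either substituted copies of the reference prefix (conserved) or
#' independent draws (diverged); a reference-specific TR is planted on one
#' reference transcript with probability `p_d` or `p_c` by label; shared
#' TR types (same core and count in two or more species of the group) are
#' planted at a rate solved so the overall mean TR count per transcript
#' matches `tr_rate`.  Every emitted upstream window is verified with the
#' detector: it contains exactly the planted repeats and nothing else
#' (background draws producing accidental qualifying TRs are rejected and
#' counted).  Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Class `tr_sim`: list with `bundle` (a `tr_bundle`), `truth`
#'   (lists `genes`, `repeats`, `prefixes`), `config`, and `stats`
#'   (rejection counts and solved planting rates).
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_species
  q <- cfg$shared_species_prob
  p_ge2 <- 1 - (1 - q)^n - n * q * (1 - q)^(n - 1)
  q_incl <- q * (1 - (1 - q)^(n - 1)) / p_ge2
  p_bar <- cfg$p_diverged * cfg$p_specific_tr_given_diverged +
    (1 - cfg$p_diverged) * cfg$p_specific_tr_given_conserved
  spec_per_tx <- p_bar / (n * cfg$transcripts_per_gene)
  lambda_shared <- max(0, cfg$tr_rate - spec_per_tx) / q_incl

  ref <- cfg$reference_species
  tail_len <- cfg$protein_len - 6L
  gene_rows <- vector("list", cfg$n_genes)
  rec_rows <- vector("list", cfg$n_genes)
  rep_rows <- vector("list", cfg$n_genes)
  pre_rows <- vector("list", cfg$n_genes)
  empty_rep <- list(transcript_id = character(0), gene_name = character(0),
                    species = character(0), core = character(0),
                    n_repeats = integer(0), start = integer(0),
                    category = integer(0), kind = character(0))
  total_tries <- 0L; total_seqs <- 0L

  for (g in seq_len(cfg$n_genes)) {
    gene <- sprintf("GENE%05d", g)
    diverged <- stats::runif(1) < cfg$p_diverged
    has_specific <- stats::runif(1) <
      if (diverged) cfg$p_specific_tr_given_diverged
      else cfg$p_specific_tr_given_conserved

    # transcript counts per species
    n_tx <- 1L + stats::rpois(n, cfg$transcripts_per_gene - 1)

    # TR plan: shared types with species subsets, plus the specific type;
    # redrawn wholesale if a species' blocks cannot fit the window
    for (plan_try in 1:50) {
      m_shared <- stats::rpois(1L, lambda_shared)
      n_types <- m_shared + as.integer(has_specific)
      cats <- cores <- counts <- NULL
      if (n_types > 0L) {
        repeat {
          cats <- sample.int(4L, n_types, replace = TRUE,
                             prob = cfg$category_mix)
          cores <- vapply(cats, .rand_core, character(1))
          counts <- vapply(nchar(cores), .rand_count, integer(1))
          if (!anyDuplicated(paste(cores, counts)) &&
              all(mapply(.block_clean, cores, counts))) break
        }
      }
      incl <- matrix(FALSE, n, m_shared)
      if (m_shared > 0L) for (t in seq_len(m_shared)) {
        repeat {
          v <- stats::runif(n) < q
          if (sum(v) >= 2L) break
        }
        incl[, t] <- v
      }
      # feasibility: heaviest species load must fit
      loads <- if (m_shared > 0L)
        as.numeric(incl %*% (nchar(cores[seq_len(m_shared)]) *
                               counts[seq_len(m_shared)])) +
        rowSums(incl) - 1L
      else rep(-1, n)
      if (has_specific) {
        sp_len <- nchar(cores[n_types]) * counts[n_types]
        loads[1] <- loads[1] + sp_len + 1L
      }
      if (all(loads + 1L <= cfg$upstream_len)) break
      if (plan_try == 50L) stop("could not draw a feasible TR plan for gene ",
                                gene, "; lower tr_rate or enlarge the window")
    }
    spec_core <- if (has_specific) cores[n_types] else NA_character_
    spec_count <- if (has_specific) counts[n_types] else NA_integer_
    carrier <- sample.int(n_tx[1], 1L)  # which reference transcript

    # prefixes and proteins per species
    ref_pref_tail <- c("M", sample(.AA20, 5L, replace = TRUE))
    ref_tail <- sample(.AA20, tail_len, replace = TRUE)
    prefs <- character(n); prots <- character(n)
    for (s in seq_len(n)) {
      if (s == 1L) {
        pc <- ref_pref_tail; tc <- ref_tail
      } else if (diverged) {
        pc <- c("M", sample(.AA20, 5L, replace = TRUE))
        tc <- if (cfg$couple_protein_divergence)
          sample(.AA20, tail_len, replace = TRUE)
        else .mutate_chars(ref_tail, cfg$prefix_sub_rate, .AA20)
      } else {
        pc <- c("M", .mutate_chars(ref_pref_tail[-1], cfg$prefix_sub_rate, .AA20))
        tc <- .mutate_chars(ref_tail, cfg$prefix_sub_rate, .AA20)
      }
      prefs[s] <- paste(pc, collapse = "")
      prots[s] <- paste(c(pc, tc), collapse = "")
    }

    # sequences per transcript (column-wise accumulation, no per-transcript
    # data.frame construction)
    n_all <- sum(n_tx)
    tx_id <- tx_sp <- tx_up <- character(n_all)
    rl <- empty_rep
    idx <- 0L
    for (s in seq_len(n)) {
      shared_idx <- if (m_shared > 0L) which(incl[s, ]) else integer(0)
      for (i in seq_len(n_tx[s])) {
        idx <- idx + 1L
        id <- paste0(gene, "_", cfg$species[s], "_t", i)
        bl <- shared_idx
        kinds <- rep("shared", length(bl))
        if (has_specific && s == 1L && i == carrier) {
          bl <- c(bl, n_types); kinds <- c(kinds, "specific")
        }
        built <- .build_upstream(cores[bl], counts[bl], cfg$upstream_len)
        if (is.null(built)) stop("internal: infeasible plan slipped through")
        total_tries <- total_tries + built$tries
        total_seqs <- total_seqs + 1L
        tx_id[idx] <- id; tx_sp[idx] <- cfg$species[s]
        tx_up[idx] <- built$seq
        if (length(bl)) {
          rl$transcript_id <- c(rl$transcript_id, rep(id, length(bl)))
          rl$gene_name <- c(rl$gene_name, rep(gene, length(bl)))
          rl$species <- c(rl$species, rep(cfg$species[s], length(bl)))
          rl$core <- c(rl$core, cores[bl])
          rl$n_repeats <- c(rl$n_repeats, counts[bl])
          rl$start <- c(rl$start, built$starts)
          rl$category <- c(rl$category, cats[bl])
          rl$kind <- c(rl$kind, kinds)
        }
      }
    }

    gene_rows[[g]] <- list(gene_name = gene, diverged = diverged,
                           specific_planted = has_specific,
                           specific_core = spec_core,
                           specific_n_repeats = spec_count,
                           specific_category =
                             if (has_specific) cats[n_types] else NA_integer_)
    rec_rows[[g]] <- list(species = tx_sp, gene_name = rep(gene, n_all),
                          gene_id = rep(sprintf("GID%05d", g), n_all),
                          transcript_id = tx_id, upstream_seq = tx_up,
                          protein_seq = prots[match(tx_sp, cfg$species)])
    rep_rows[[g]] <- rl
    pre_rows[[g]] <- list(gene_name = rep(gene, n), species = cfg$species,
                          prefix = prefs)
  }

  bind_cols <- function(rows, names) {
    out <- lapply(names, function(nm) unlist(lapply(rows, `[[`, nm),
                                             use.names = FALSE))
    names(out) <- names
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  records <- bind_cols(rec_rows, c("species", "gene_name", "gene_id",
                                   "transcript_id", "upstream_seq",
                                   "protein_seq"))
  repeats <- bind_cols(rep_rows, names(empty_rep))
  genes <- bind_cols(gene_rows, c("gene_name", "diverged", "specific_planted",
                                  "specific_core", "specific_n_repeats",
                                  "specific_category"))
  prefixes <- bind_cols(pre_rows, c("gene_name", "species", "prefix"))
  structure(list(
    bundle = tr_bundle(records, ref),
    truth = list(genes = genes, repeats = repeats, prefixes = prefixes),
    config = cfg,
    stats = list(n_transcripts = nrow(records),
                 n_rejected_draws = total_tries - total_seqs,
                 rejection_rate = (total_tries - total_seqs) / total_tries,
                 q_incl = q_incl, lambda_shared = lambda_shared)),
    class = "tr_sim")
}

#' @export
print.tr_sim <- function(x, ...) {
  cat("Synthetic TIS-upstream bundle\n")
  print(x$bundle)
  cat(sprintf("  planted repeats: %d (%d specific, %d shared)\n",
              nrow(x$truth$repeats), sum(x$truth$repeats$kind == "specific"),
              sum(x$truth$repeats$kind == "shared")))
  cat(sprintf("  background rejection rate: %.1f%%\n",
              100 * x$stats$rejection_rate))
  invisible(x)
}

#' Write a simulation's ground truth as TSV files
#'
#' @param sim A `tr_sim` object.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "tr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "truth_genes.tsv"),
             repeats = file.path(dir, "truth_repeats.tsv"),
             prefixes = file.path(dir, "truth_prefixes.tsv"))
  write_table(sim$truth$genes, paths[["genes"]], key = "gene_name")
  write_table(sim$truth$repeats, paths[["repeats"]], key = "transcript_id")
  write_table(sim$truth$prefixes, paths[["prefixes"]], key = "gene_name")
  invisible(paths)
}
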