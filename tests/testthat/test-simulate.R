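test_that("configurations are validated before any work happens", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(category_mix = c(1, 1, 1, 1)), "sum to 1")
  expect_error(sim_config(p_diverged = 1.5), "probabilities")
  expect_error(sim_config(upstream_len = 30), "twice the")
  # a window too small for category-4 cores is fine if category 4 is off
  cfg <- sim_config(upstream_len = 40, category_mix = c(1, 0, 0, 0))
  expect_s3_class(cfg, "sim_config")
})

test_that("expected odds ratio has its closed form", {
  f <- function(pd, pc) expected_odds_ratio(
    sim_config(p_specific_tr_given_diverged = pd,
               p_specific_tr_given_conserved = pc))
  expect_equal(f(0.6, 0.2), 6)
  expect_equal(f(0.3, 0.3), 1)
  expect_equal(f(0.5, 0.25), 3)
})

test_that("simulation is deterministic under seed", {
  cfg <- sim_config(n_species = 4, n_genes = 30, seed = 202)
  s1 <- simulate_bundle(cfg)
  s2 <- simulate_bundle(cfg)
  expect_identical(s1$bundle$records, s2$bundle$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_bundle(sim_config(n_species = 4, n_genes = 30, seed = 203))
  expect_false(identical(s1$bundle$records, s3$bundle$records))
})

test_that("the detector recovers every planted repeat exactly and nothing else", {
  sim <- simulate_bundle(sim_config(n_species = 6, n_genes = 120, seed = 55))
  hits <- detect_bundle(sim$bundle)
  tr <- sim$truth$repeats
  key_h <- paste(hits$transcript_id, hits$core, hits$n_repeats, hits$start)
  key_t <- paste(tr$transcript_id, tr$core, tr$n_repeats, tr$start)
  expect_setequal(key_h, key_t)
  expect_gte(mean(key_t %in% key_h), 0.99)
  # planted repeats all qualify and sit inside the window
  expect_true(all(tr_qualifies(nchar(tr$core), tr$n_repeats)))
  expect_true(all(tr$start + nchar(tr$core) * tr$n_repeats <= 120))
})

test_that("shared planted types occupy at least two species; specific types only the reference", {
  sim <- simulate_bundle(sim_config(n_species = 6, n_genes = 100, seed = 56))
  tr <- sim$truth$repeats
  sh <- tr[tr$kind == "shared", ]
  nsp <- tapply(sh$species, paste(sh$gene_name, sh$core, sh$n_repeats),
                function(s) length(unique(s)))
  expect_true(all(nsp >= 2))
  spf <- tr[tr$kind == "specific", ]
  expect_true(all(spf$species == sim$bundle$reference_species))
  # pipeline classifies every planted specific type as reference-specific
  g <- group_by_gene_name(sim$bundle)
  sp <- build_specificity(g, detect_bundle(sim$bundle))
  k_spec <- paste(spf$gene_name, spf$core, spf$n_repeats)
  k_tab <- paste(sp$gene_key, sp$core, sp$n_repeats)
  lab <- sp$label[match(k_spec, k_tab)]
  who <- sp$specific_species[match(k_spec, k_tab)]
  expect_true(all(lab == "SPECIFIC" & who == sim$bundle$reference_species))
})

test_that("mean detected TR count per transcript tracks the configured rate", {
  # ~10,600 transcripts at the default 1.19 rate
  sim <- simulate_bundle(sim_config(n_species = 10, n_genes = 660, seed = 77))
  hits <- detect_bundle(sim$bundle)
  ntx <- nrow(sim$bundle$records)
  expect_gte(ntx, 10000)
  rate <- nrow(hits) / ntx
  expect_lt(abs(rate - 1.19) / 1.19, 0.10)
})

test_that("a null configuration plants no association by construction", {
  cfg <- sim_config(n_species = 5, n_genes = 200,
                    p_specific_tr_given_diverged = 0.3,
                    p_specific_tr_given_conserved = 0.3, seed = 60)
  expect_equal(expected_odds_ratio(cfg), 1)
  sim <- simulate_bundle(cfg)
  tg <- sim$truth$genes
  # specific planting is independent of the divergence label: the sample
  # log-odds-ratio stays near zero (3 SE band)
  a <- sum(tg$diverged & tg$specific_planted) + 0.5
  b <- sum(tg$diverged & !tg$specific_planted) + 0.5
  c <- sum(!tg$diverged & tg$specific_planted) + 0.5
  d <- sum(!tg$diverged & !tg$specific_planted) + 0.5
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_lt(abs(lor), 3 * se)
})

test_that("the gene-level odds ratio is recovered within 25% at scale", {
  cfg <- sim_config(n_species = 3, n_genes = 2000, transcripts_per_gene = 1,
                    seed = 70)  # planted OR 3 under the default p_d/p_c
  sim <- simulate_bundle(cfg)
  g <- group_by_gene_name(sim$bundle)
  sp <- build_specificity(g, detect_bundle(sim$bundle))
  fl <- flag_transcripts(sp, g, detect_bundle(sim$bundle))
  rf <- fl[fl$is_reference, ]
  spec_gene <- tapply(rf$has_ref_specific_tr, rf$gene_key, any)
  div <- sim$truth$genes$diverged[match(names(spec_gene),
                                        sim$truth$genes$gene_name)]
  a <- sum(div & spec_gene); b <- sum(div & !spec_gene)
  c <- sum(!div & spec_gene); d <- sum(!div & !spec_gene)
  or_hat <- (a * d) / (b * c)
  expect_lt(abs(or_hat - expected_odds_ratio(cfg)) / expected_odds_ratio(cfg),
            0.25)
})

test_that("ground truth files are written as readable TSV", {
  d <- withr::local_tempdir()
  sim <- simulate_bundle(sim_config(n_species = 3, n_genes = 10, seed = 5))
  paths <- write_truth(sim, d)
  tg <- read.delim(paths[["genes"]])
  expect_equal(nrow(tg), 10L)
  expect_true(all(c("gene_name", "diverged", "specific_planted") %in% names(tg)))
})
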