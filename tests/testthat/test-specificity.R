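# a small cross-species group with controllable planted repeats
spec_fixture <- function() {
  rows <- list(
    list(species = "human", gene = "A", upstream = "GGACTCTCTGAGG",
         protein = "MABCDEFGH"),                      # (CT)3
    list(species = "mouse", gene = "A", upstream = "GGACTCTCTGAGG",
         protein = "MABCDEFGH"),                      # (CT)3 shared
    list(species = "human", gene = "A", upstream = "GGCGGCGGCGGCGAA",
         protein = "MABCDEFGH"),                      # (CGG)x specific-ish
    list(species = "rat",   gene = "A", upstream = "GACCACCACCAGTT",
         protein = "MABCDEFGH"),                      # (ACC)3 rat-only
    list(species = "human", gene = "B", upstream = "GGACTCTCTGAGG",
         protein = "MABCDEFGH"),                      # (CT)3 human-only in B
    list(species = "mouse", gene = "B", upstream = "GATTTGGCCAAGG",
         protein = "MABCDEFGH"))                      # no TR
  b <- toy_bundle(rows, "human")
  g <- group_by_gene_name(b)
  h <- detect_bundle(b)
  list(bundle = b, groups = g, hits = h)
}

test_that("types seen in two species are SHARED, single-species types SPECIFIC", {
  fx <- spec_fixture()
  sp <- build_specificity(fx$groups, fx$hits)
  ct_a <- sp[sp$gene_key == "A" & sp$core == "CT", ]
  expect_equal(ct_a$label, "SHARED")
  expect_equal(ct_a$n_species, 2L)
  acc <- sp[sp$gene_key == "A" & sp$core == "ACC", ]
  expect_equal(acc$label, "SPECIFIC")
  expect_equal(acc$specific_species, "rat")
})

test_that("specificity is per gene group: one type can be shared in A and specific in B", {
  fx <- spec_fixture()
  sp <- build_specificity(fx$groups, fx$hits)
  ct <- sp[sp$core == "CT" & sp$n_repeats == 3, ]
  expect_setequal(ct$label, c("SHARED", "SPECIFIC"))
  expect_equal(ct$label[ct$gene_key == "A"], "SHARED")
  expect_equal(ct$specific_species[ct$gene_key == "B"], "human")
  # the global summary counts (CT,3) as non-reference-specific because
  # a non-reference species carries it somewhere
  gl <- specificity_summary(sp, "human")
  expect_false(gl$globally_reference_specific[gl$core == "CT"])
})

test_that("transcript flags encode TR presence and reference-specific carriage", {
  fx <- spec_fixture()
  sp <- build_specificity(fx$groups, fx$hits)
  fl <- flag_transcripts(sp, fx$groups, fx$hits)
  rec <- fx$groups$records
  # human transcript with only the shared (CT)3 in group A
  tx_shared <- rec$transcript_id[rec$gene_key == "A" & rec$species == "human" &
                                   grepl("CTCT", rec$upstream_seq)]
  expect_true(fl$has_any_tr[fl$transcript_id == tx_shared])
  expect_false(fl$has_ref_specific_tr[fl$transcript_id == tx_shared])
  # human transcript in B carries a human-specific type
  tx_spec <- rec$transcript_id[rec$gene_key == "B" & rec$species == "human"]
  expect_true(fl$has_ref_specific_tr[fl$transcript_id == tx_spec])
  # mouse transcript in B has no TR at all
  tx_none <- rec$transcript_id[rec$gene_key == "B" & rec$species == "mouse"]
  expect_false(fl$has_any_tr[fl$transcript_id == tx_none])
  expect_false(fl$has_ref_specific_tr[fl$transcript_id == tx_none])
})

test_that("hits with unknown transcript ids are rejected", {
  fx <- spec_fixture()
  bad <- fx$hits
  bad$transcript_id[1] <- "nonexistent"
  expect_error(build_specificity(fx$groups, bad), "unknown transcript_id")
})

test_that("category filter restricts both specificity and flags", {
  fx <- spec_fixture()
  sp1 <- build_specificity(fx$groups, fx$hits, category = 1)
  expect_true(all(sp1$category == 1L))
  # all planted repeats here are category 1, so category 4 empties the table
  sp4 <- build_specificity(fx$groups, fx$hits, category = 4)
  expect_equal(nrow(sp4), 0L)
  fl4 <- flag_transcripts(sp4, fx$groups, fx$hits)
  expect_false(any(fl4$has_any_tr))
})

test_that("adding a species carrying a type can only move it toward SHARED", {
  set.seed(21)
  for (rep in 1:10) {
    sim <- simulate_bundle(sim_config(n_species = 4, n_genes = 20,
                                      seed = 100 + rep))
    g <- group_by_gene_name(sim$bundle)
    h <- detect_bundle(sim$bundle)
    sp <- build_specificity(g, h)
    # duplicate one random TR-carrying transcript into a brand-new species
    if (!nrow(h)) next
    pick <- sim$bundle$records[sim$bundle$records$transcript_id ==
                                 sample(unique(h$transcript_id), 1), ]
    pick$species <- "newspecies"; pick$transcript_id <- "tx_new"
    b2 <- tr_bundle(rbind(sim$bundle$records, pick),
                    sim$bundle$reference_species)
    sp2 <- build_specificity(group_by_gene_name(b2), detect_bundle(b2))
    k1 <- paste(sp$gene_key, sp$core, sp$n_repeats)
    k2 <- paste(sp2$gene_key, sp2$core, sp2$n_repeats)
    shared_before <- k1[sp$label == "SHARED"]
    expect_true(all(sp2$label[k2 %in% shared_before] == "SHARED"))
    # every (group, type) pair is labelled exactly once
    expect_false(anyDuplicated(k2) > 0)
  }
})
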