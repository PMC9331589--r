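test_that("prefix extraction takes six residues or excludes the transcript", {
  expect_equal(tis_prefix("MALWMRLLPL"), "MALWMR")
  expect_true(is.na(tis_prefix("MALW")))
  expect_true(is.na(tis_prefix("")))
  expect_equal(tis_prefix(c("MABCDE", "MX")), c("MABCDE", NA))
})

test_that("weight vectors are validated and carry zero at the initiator position", {
  expect_equal(as.numeric(weight_vector("W1")), c(0, 25, 25, 25, 12.5, 12.5))
  expect_equal(as.numeric(weight_vector("W2")), c(0, 20, 20, 20, 20, 20))
  expect_error(weight_vector(c(10, 20, 20, 20, 20, 10)), "methionine")
  expect_error(weight_vector(c(0, 10, 10, 10, 10, 10)), "sum")
})

test_that("similarity scores match the printed weightings position by position", {
  expect_equal(similarity_score("MABCDE", "MABCDE", "W1"), 100)
  expect_equal(similarity_score("MABCDE", "MABCDE", "W2"), 100)
  # matches only at positions 2 and 3
  expect_equal(similarity_score("MABXXX", "MABYYY", "W1"), 50)
  expect_equal(similarity_score("MABXXX", "MABYYY", "W2"), 40)
  # matches only at positions 5 and 6
  expect_equal(similarity_score("MXXXDE", "MYYYDE", "W1"), 25)
  expect_equal(similarity_score("MXXXDE", "MYYYDE", "W2"), 40)
  # initiator position is ignored (weight 0)
  expect_equal(similarity_score("MABCDE", "XABCDE", "W1"), 100)
  expect_error(similarity_score("MAB", "MABCDE", "W1"), "6 residues")
})

test_that("the homology call is inclusive at the 50 boundary", {
  expect_true(is_homologous(50))
  expect_false(is_homologous(49.9))
  expect_true(is_homologous(100))
  expect_error(is_homologous(101))
})

test_that("all 32 match patterns reproduce the direct weighted sum and the threshold characterizations", {
  w1 <- weight_vector("W1"); w2 <- weight_vector("W2")
  base <- c("A", "C", "D", "E", "F")
  for (bits in 0:31) {
    m <- as.logical(bitwAnd(bits, 2^(0:4)))
    pa <- paste(c("M", base), collapse = "")
    pb <- paste(c("M", ifelse(m, base, "Y")), collapse = "")
    s1 <- similarity_score(pa, pb, w1)
    s2 <- similarity_score(pa, pb, w2)
    expect_equal(s1, sum(c(25, 25, 25, 12.5, 12.5)[m]))
    expect_equal(s2, sum(rep(20, 5)[m]))
    # W1 homology <=> >=2 matches in positions 2-4, or 1 such match plus
    # both of positions 5-6; W2 homology <=> >=3 matches overall
    expect_equal(is_homologous(s1),
                 sum(m[1:3]) >= 2 || (sum(m[1:3]) == 1 && all(m[4:5])))
    expect_equal(is_homologous(s2), sum(m) >= 3)
  }
})

test_that("count_events enumerates reference x partner pairs within gene groups", {
  rows <- list(
    # gene A: human ref transcript carries a human-specific TR
    list(species = "human", gene = "A", upstream = "AACGGCGGCGGCGGTT",
         protein = "MABCDEZZZZ"),
    list(species = "mouse", gene = "A", upstream = "GGACTCTCTGAGG",
         protein = "MABCYYZZZZ"),    # score W1: pos2,3 match +25+25 -> 50+... see below
    list(species = "rat",   gene = "A", upstream = "GGACTCTCTGAGG",
         protein = "MYYYYYZZZZ"),    # no matches -> 0
    # mouse carries (CT)3, rat carries (CT)3: shared; human's (GGC)4 specific
    list(species = "pig",   gene = "A", upstream = "GGTTAACCGGTTAA",
         protein = "MABCDEZZZZ"))    # no TR -> excluded from pairs
  b <- toy_bundle(rows, "human")
  g <- group_by_gene_name(b)
  h <- detect_bundle(b)
  sp <- build_specificity(g, h)
  fl <- flag_transcripts(sp, g, h)
  ev <- count_events(g, fl, "W1", "specific")
  # partners: mouse (score 75: pos 2,3,4? MABC vs MABC -> pos2,3,4 match ->
  # 25+25+25 = 75) and rat (0); pig has no TR
  expect_equal(nrow(ev$events), 2L)
  expect_equal(ev$n_homologous, 1L)
  expect_equal(ev$n_non_homologous, 1L)
  expect_setequal(ev$events$other_species, c("mouse", "rat"))
  # no nonspecific reference transcripts -> empty sum
  ev0 <- count_events(g, fl, "W1", "nonspecific")
  expect_equal(ev0$n_homologous + ev0$n_non_homologous, 0L)
})

test_that("count_events equals a naive triple loop on random bundles", {
  for (sd in 1:4) {
    sim <- simulate_bundle(sim_config(n_species = 4, n_genes = 25, seed = sd))
    g <- group_by_gene_name(sim$bundle)
    h <- detect_bundle(sim$bundle)
    sp <- build_specificity(g, h)
    fl <- flag_transcripts(sp, g, h)
    for (grp in c("specific", "nonspecific")) {
      got <- count_events(g, fl, "W1", grp)
      # naive oracle: loop genes, then ref transcripts, then partners
      r <- g$records
      w <- c(0, 25, 25, 25, 12.5, 12.5)
      n_hom <- 0L; n_non <- 0L
      for (gene in unique(r$gene_key)) {
        rg <- r[r$gene_key == gene, ]
        for (ta in rg$transcript_id[rg$is_reference]) {
          fa <- fl[fl$transcript_id == ta, ]
          ok_a <- if (grp == "specific") fa$has_ref_specific_tr
                  else fa$has_any_tr && !fa$has_ref_specific_tr
          pa <- rg$protein_seq[rg$transcript_id == ta]
          if (!ok_a || nchar(pa) < 6) next
          for (tb in rg$transcript_id[!rg$is_reference]) {
            fb <- fl[fl$transcript_id == tb, ]
            pb <- rg$protein_seq[rg$transcript_id == tb]
            if (!fb$has_any_tr || nchar(pb) < 6) next
            s <- sum(w[2:6] * (strsplit(substr(pa, 2, 6), "")[[1]] ==
                                 strsplit(substr(pb, 2, 6), "")[[1]]))
            if (s >= 50) n_hom <- n_hom + 1L else n_non <- n_non + 1L
          }
        }
      }
      expect_equal(got$n_homologous, n_hom)
      expect_equal(got$n_non_homologous, n_non)
    }
  }
})

test_that("per-TIS roll-up marks a TIS homologous when any partner is", {
  ev <- data.frame(gene_key = "A",
                   ref_transcript_id = c("t1", "t1", "t2"),
                   other_transcript_id = c("x", "y", "x"),
                   other_species = "m",
                   score = c(75, 25, 0), homologous = c(TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  ru <- tis_rollup(ev)
  expect_equal(ru$tis_homologous[ru$ref_transcript_id == "t1"], TRUE)
  expect_equal(ru$tis_homologous[ru$ref_transcript_id == "t2"], FALSE)
  expect_equal(ru$n_partners, c(2L, 1L))
})
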