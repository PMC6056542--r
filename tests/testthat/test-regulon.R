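test_that("specificity rules reproduce the in-text motif logic", {
  rules <- ct_specificity_rules()
  # the universal -35 nonad CCCCTCAAA: CTC immediately upstream of the
  # tract (sigI1) and CCC two nt upstream (sigI3)
  uni <- data.frame(specificity_seq = "CCCCTC", atract_seq = "AAA",
                    minus10_seq = "CGAA", downstream_seq = "TTAATG")
  k1 <- apply_specificity_rule(uni, rules$sigI1)
  expect_equal(nrow(k1), 1L)
  expect_equal(k1$matched_offset, 0L)
  k3 <- apply_specificity_rule(uni, rules$sigI3)
  expect_equal(nrow(k3), 1L)
  expect_equal(k3$matched_offset, 2L)
  # no C-triad: fails sigI3
  no_ccc <- data.frame(specificity_seq = "GTGATG", atract_seq = "AAA",
                       minus10_seq = "CGAA", downstream_seq = "TTAATG")
  expect_equal(nrow(apply_specificity_rule(no_ccc, rules$sigI3)), 0L)
  # the sigI3-promoter-like candidate: CGTA tetrad and GT dyad fail the
  # sigI1 rule (CGAA + AT) but pass the sigI3 rule (CGWA + RT)
  sig3like <- data.frame(specificity_seq = "CCCCTC", atract_seq = "AAAA",
                         minus10_seq = "CGTA", downstream_seq = "GCAGTT")
  expect_equal(nrow(apply_specificity_rule(sig3like, rules$sigI1)), 0L)
  expect_equal(nrow(apply_specificity_rule(sig3like, rules$sigI3)), 1L)
})

test_that("the count-based cytosine-enrichment alternative works", {
  rules <- ct_specificity_rules()
  cand <- data.frame(specificity_seq = "CCTCCG", atract_seq = "AAA",
                     minus10_seq = "CGAA", downstream_seq = "TTAATG")
  # 3 C in the last 5 nt, but no positional CCC triad
  expect_equal(nrow(apply_specificity_rule(cand, rules$sigI3)), 0L)
  expect_equal(nrow(apply_specificity_rule(cand, rules$sigI3,
                                           count_based = TRUE)), 1L)
})

test_that("rule filtering is monotone and dyads only shrink the kept set", {
  set.seed(41)
  cand <- scan_genome(c(c1 = rand_seq(30000, 0.45)))
  expect_gt(nrow(cand), 0)
  rule_nodyad <- specificity_rule("x", "CCC", 0L, 2L, "CGHH", NULL)
  rule_dyad <- specificity_rule("x", "CCC", 0L, 2L, "CGHH", "AT")
  k1 <- apply_specificity_rule(cand, rule_nodyad)
  k2 <- apply_specificity_rule(cand, rule_dyad)
  expect_lte(nrow(k1), nrow(cand))
  expect_lte(nrow(k2), nrow(k1))
  key <- function(d) paste(d$atract_start, d$m10_start)
  expect_true(all(key(k2) %in% key(k1)))
  expect_true(all(key(k1) %in% key(cand)))
})

test_that("planted promoters are recovered with gene assignment and utr5", {
  gens <- disjoint_generators()
  ss <- synthetic_spec(40000, 0.38,
                       per_sigma_plants = c(sigI1 = 4L, sigI3 = 4L),
                       generators = gens, seed = 77)
  sim <- simulate_genome(ss)
  cand <- predict_promoters(sim$genome, sim$annotations, window = 600,
                            scope = "upstream_only")
  # every planted promoter is found in its gene's upstream window with the
  # exact planted coordinates, gene and 5'-UTR
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    hit <- cand[cand$atract_end == tr$atract_end &
                cand$m10_start == tr$m10_start &
                cand$strand == tr$strand, , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$assigned_gene, tr$locus_tag)
    expect_equal(hit$utr5, tr$utr5)
  }
})

test_that("upstream-only candidates are a subset of the whole-genome scan", {
  gens <- disjoint_generators()
  ss <- synthetic_spec(40000, 0.38,
                       per_sigma_plants = c(sigI3 = 5L),
                       generators = gens, n_decoys = 3L, seed = 13)
  sim <- simulate_genome(ss)
  up <- predict_promoters(sim$genome, sim$annotations, window = 400,
                          scope = "upstream_only")
  whole <- predict_promoters(sim$genome, sim$annotations, window = 400,
                             scope = "whole_genome")
  key <- function(d) paste(d$contig, d$strand, d$atract_start, d$m10_start)
  expect_true(all(key(up) %in% key(whole)))
})

test_that("overlapping upstream windows report a shared site once", {
  # two plus-strand genes close together share the same upstream promoter
  plant <- paste0("TAGCTC", "AAAA", "GGTGGTGGTGGT", "CGAA", "TTAATG")
  sq <- paste0(rand_seq(200, 0.5), plant, strrep("G", 50),
               rand_seq(400, 0.5))
  g <- c(c1 = sq)
  p0 <- 200L + nchar(plant)
  ann <- data.frame(contig = "c1",
                    start = c(p0 + 30L, p0 + 90L),
                    end = c(p0 + 80L, p0 + 140L),
                    strand = "+", locus_tag = c("gA", "gB"),
                    product = NA, stringsAsFactors = FALSE)
  set.seed(55)
  cand <- predict_promoters(g, ann, window = 300, scope = "upstream_only")
  in_plant <- cand[cand$atract_start > 200 & cand$atract_start <= p0, ,
                   drop = FALSE]
  expect_equal(nrow(in_plant), 1L)
  # the nearer gene wins the assignment
  expect_equal(in_plant$assigned_gene, "gA")
})

test_that("genes without a motif yield no candidate", {
  g <- c(c1 = strrep("GC", 500))
  ann <- data.frame(contig = "c1", start = 800L, end = 950L, strand = "+",
                    locus_tag = "g1", product = NA)
  cand <- predict_promoters(g, ann, window = 600, scope = "upstream_only")
  expect_equal(nrow(cand), 0L)
})

test_that("classification assigns sampled candidates to their own sigma", {
  recs <- ct_records()
  profiles <- list(sigI1 = promoter_profile(recs, sigma_label = "sigI1"),
                   sigI3 = promoter_profile(recs, sigma_label = "sigI3"))
  rules <- ct_specificity_rules()[c("sigI1", "sigI3")]
  # near-deterministic sigI3-style generating profile
  gen_recs <- data.frame(sigma_label = "sigI3", gene_label = "canon",
                         specificity_seq = "ACCCCT", atract_seq = "AAAA",
                         spacer_seq = "GTTGTCGGTTGTG",
                         minus10_seq = "CGAATACATG", utr5 = NA)
  gen <- promoter_profile(gen_recs[rep(1, 4), ], pseudocount = 0.001)
  draws <- sample_promoter_set(gen, 500, seed = 303)
  cl <- classify_regulon(draws, profiles, rules)
  expect_gte(mean(cl$assigned == "sigI3"), 0.95)
})

test_that("a single profile with min_score -Inf assigns the rule-passing set", {
  set.seed(61)
  cand <- scan_genome(c(c1 = rand_seq(20000, 0.45)))
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  rule <- ct_specificity_rules()$sigI3
  cl <- classify_regulon(cand, list(sigI3 = pf), list(sigI3 = rule),
                         min_score = -Inf)
  kept <- apply_specificity_rule(cand, rule)
  expect_equal(sum(cl$assigned == "sigI3"), nrow(kept))
})

test_that("the universal promoter is flagged as cross-talk", {
  recs <- ct_records()
  labs <- c("sigI1", "sigI2", "sigI3", "sigI4", "sigI6")
  profiles <- setNames(lapply(labs, function(l)
    promoter_profile(recs, sigma_label = l)), labs)
  uni <- data.frame(specificity_seq = "CCCCTC", atract_seq = "AAA",
                    minus10_seq = "CGAA", downstream_seq = "TTAATG")
  cl <- classify_regulon(uni, profiles, ct_specificity_rules())
  assigned <- strsplit(cl$assigned, ",")[[1]]
  expect_true(all(c("sigI1", "sigI3") %in% assigned))
  expect_true(cl$crosstalk)
})

test_that("crosstalk_matrix tabulates assignments and degrees", {
  recs <- ct_records()
  labs <- c("sigI1", "sigI3")
  profiles <- setNames(lapply(labs, function(l)
    promoter_profile(recs, sigma_label = l)), labs)
  rules <- ct_specificity_rules()[labs]
  cands <- data.frame(
    gene_label = c("universal", "own3"),
    specificity_seq = c("CCCCTC", "ACCCCT"),
    atract_seq = c("AAA", "AAA"),
    minus10_seq = c("CGAA", "CGAA"),
    downstream_seq = c("TTAATG", "TACATG"))
  cl <- classify_regulon(cands, profiles, rules)
  xm <- crosstalk_matrix(cl)
  expect_equal(xm$degree, c(2, 1))
  expect_true(xm$sigI3[2] && !xm$sigI1[2])
  # empty assignment list gives an empty matrix with the header intact
  xm0 <- crosstalk_matrix(cl[0, ])
  expect_equal(nrow(xm0), 0L)
  expect_true(all(labs %in% names(xm0)))
})

test_that("regulon transfer keeps exactly the rule-conforming plants", {
  sig3_gen <- sigma_generator("sigI3", "CCC", offset = 0L, tetrad = "CGAA",
                              dyad = "AT")
  decoy_gen <- sigma_generator("decoy", "GTG", offset = 0L, tetrad = "CGAA",
                               forbid_triads = "CCC")
  ss <- synthetic_spec(60000, 0.38,
                       per_sigma_plants = c(sigI3 = 5L, decoy = 50L),
                       generators = list(sigI3 = sig3_gen, decoy = decoy_gen),
                       seed = 909)
  sim <- simulate_genome(ss)
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  rule <- ct_specificity_rules()$sigI3
  res <- transfer_regulon(pf, rule, sim$genome, sim$annotations,
                          window = 400, scope = "upstream_only")
  truth3 <- sim$truth[sim$truth$sigma_label == "sigI3", ]
  expect_true(all(truth3$locus_tag %in% res$assigned_gene))
  # none of the 50 CCC-free decoy plants survive the rule stage
  decoys <- sim$truth$locus_tag[sim$truth$sigma_label == "decoy"]
  expect_false(any(decoys %in% res$assigned_gene))
  # report is sorted by decreasing source-profile score
  expect_true(!is.unsorted(rev(res$score_sigI3)))
})

test_that("the sigma-I11 collection passes its own rule and profile anatomy", {
  recs <- read_promoter_sets(pc_fixture_path())
  rule <- pc_sigI11_rule()
  kept <- apply_specificity_rule(recs, rule)
  # every curated record has CCC immediately upstream of the tract and the
  # CGCA tetrad of the conserved CGCAT pentad
  expect_equal(nrow(kept), nrow(recs))
  expect_true(all(kept$matched_offset == 0L))
  pf <- promoter_profile(recs, sigma_label = "sigI11")
  U <- pf$anchor$U
  argmax <- rownames(pf$freq)[apply(pf$freq, 2, which.max)]
  expect_match(paste(argmax[1:U], collapse = ""), "CCC")
  expect_equal(argmax[U + 1:5], c("C", "G", "C", "A", "T"))
  # the curated records themselves score well above background
  expect_true(all(predict(pf, recs) > 0))
})

test_that("transfer on an empty genome gives an empty report", {
  g <- c(c1 = strrep("GC", 300))
  ann <- data.frame(contig = "c1", start = 500L, end = 590L, strand = "+",
                    locus_tag = "g1", product = NA)
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  res <- transfer_regulon(pf, ct_specificity_rules()$sigI3, g, ann)
  expect_equal(nrow(res), 0L)
})
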