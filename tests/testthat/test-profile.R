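make_records <- function(spec_seq, atract, spacer, m10, n = 4,
                         sigma = "sigX") {
  data.frame(sigma_label = sigma,
             gene_label = sprintf("r%d", seq_len(n)),
             specificity_seq = spec_seq, atract_seq = atract,
             spacer_seq = spacer, minus10_seq = m10,
             utr5 = NA_integer_, stringsAsFactors = FALSE)
}

test_that("profile columns are normalized and IC is bounded", {
  recs <- ct_records()
  for (lab in unique(recs$sigma_label)) {
    pf <- promoter_profile(recs, sigma_label = lab)
    expect_true(all(abs(colSums(pf$freq) - 1) < 1e-9))
    expect_true(all(pf$ic >= 0 - 1e-12 & pf$ic <= 2 + 1e-12))
  }
})

test_that("unanimous and half-split columns give the closed-form IC", {
  recs <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT", "CGAA")
  pf <- promoter_profile(recs, pseudocount = 0)
  # every counted column is unanimous: IC = 2 bits
  counted <- pf$n_eff > 0
  expect_true(all(abs(pf$ic[counted] - 2) < 1e-9))
  # half A / half T column: IC = 1 bit
  recs2 <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT",
                        c("CGAA", "CGAT", "CGAA", "CGAT"))
  pf2 <- promoter_profile(recs2, pseudocount = 0)
  j <- pf2$anchor$minus10[4]  # 4th -10 column: A,T,A,T
  expect_equal(unname(pf2$ic[j]), 1)
})

test_that("stacking is anchored on the A-tract 3' end and the -10 start", {
  recs <- make_records(c("GTCGTC", "GTCGTC"), c("AAA", "AAAAA"),
                       "GGTGGTGGTGGT", "CGAA", n = 2)
  mat <- stack_promoters(recs)
  U <- attr(mat, "anchor")$U
  # 3' tract ends coincide at the upstream block's last column
  expect_true(all(mat[, U] == "A"))
  # tract-3 record: columns U-2..U are its tract; tract-5 spills further left
  expect_equal(paste(mat[1, (U - 3):U], collapse = ""), "CAAA")
  expect_equal(paste(mat[2, (U - 4):U], collapse = ""), "AAAAA")
  # -10 block is left-aligned at the core start
  expect_equal(paste(mat[1, U + 1:4], collapse = ""), "CGAA")
  expect_error(stack_promoters(make_records("GTCGTC", "", "G", "CGAA", 1)),
               "atract_seq")
})

test_that("fixture stack width equals the sum of the window widths", {
  recs <- ct_records()
  sp <- motif_spec()
  mat <- stack_promoters(recs[recs$sigma_label == "sigI3", ], sp)
  expect_equal(ncol(mat),
               sp$specificity_window + sp$atract_width +
                 nchar(sp$minus10_core) + sp$downstream_window)
})

test_that("the sigI3 profile consensus shows the described motif anatomy", {
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  U <- pf$anchor$U
  argmax <- rownames(pf$freq)[apply(pf$freq, 2, which.max)]
  upstream <- paste(argmax[1:U], collapse = "")
  # C-triad in the region of specificity, A-tract at the block 3' end
  expect_match(upstream, "CCC")
  expect_match(upstream, "AAA$")
  # -10 columns begin C, G
  expect_equal(argmax[U + 1:2], c("C", "G"))
})

test_that("consensus_string applies threshold, IUPAC cover and N fallback", {
  recs <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT", "CGAA")
  pf <- promoter_profile(recs, pseudocount = 0)
  expect_equal(substr(consensus_string(pf, 0.8), pf$anchor$U + 1, pf$anchor$U + 4),
               "CGAA")
  recs2 <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT",
                        c("CGAA", "CGAT", "CGAA", "CGAT"))
  pf2 <- promoter_profile(recs2, pseudocount = 0)
  # half A / half T column falls back to the IUPAC cover W
  expect_equal(substr(consensus_string(pf2, 0.8), pf2$anchor$U + 4,
                      pf2$anchor$U + 4), "W")
  recs3 <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT",
                        c("CGAA", "CGAT", "CGAC", "CGAG"))
  pf3 <- promoter_profile(recs3, pseudocount = 0)
  expect_equal(substr(consensus_string(pf3, 0.8), pf3$anchor$U + 4,
                      pf3$anchor$U + 4), "N")
  expect_error(consensus_string(pf, 0.2), "threshold")
})

test_that("the unanimous consensus attains the maximum log-odds score", {
  recs <- make_records("GTCGTC", "AAAA", "GGTGGTGGTGGT", "CGAATTCATG")
  pf <- promoter_profile(recs, pseudocount = 0.01)
  cons <- data.frame(specificity_seq = "GTCGTC", atract_seq = "AAAA",
                     minus10_seq = "CGAATTCATG")
  s_cons <- predict(pf, cons)
  fmax <- apply(pf$freq, 2, max)
  expect_equal(s_cons, sum(log2(fmax / 0.25)))
  # random candidates never beat the consensus on average
  set.seed(31)
  rand <- data.frame(
    specificity_seq = vapply(1:50, function(i) rand_seq(6), character(1)),
    atract_seq = "AAAA",
    minus10_seq = vapply(1:50, function(i) rand_seq(10), character(1)))
  expect_lt(mean(predict(pf, rand)), s_cons)
})

test_that("scores depend only on element sequences, not coordinates", {
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  cand <- data.frame(specificity_seq = "ACCCCT", atract_seq = "AAA",
                     minus10_seq = "CGAA", downstream_seq = "TACATG")
  cand_coord <- cbind(cand, contig = "cX", strand = "-",
                      atract_start = 1000L, atract_end = 1002L)
  expect_equal(predict(pf, cand), predict(pf, cand_coord))
})

test_that("single-base variants never outscore a majority consensus base", {
  pf <- promoter_profile(ct_records(), sigma_label = "sigI1")
  U <- pf$anchor$U
  argmax <- rownames(pf$freq)[apply(pf$freq, 2, which.max)]
  cons_up <- paste(argmax[1:U], collapse = "")
  cons_m10 <- paste(argmax[(U + 1):ncol(pf$freq)], collapse = "")
  s0 <- score_window(pf, cons_up, cons_m10)
  for (j in c(1, 4, U)) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cons_up, j, j))) {
      var <- cons_up
      substr(var, j, j) <- b
      expect_lte(score_window(pf, var, cons_m10), s0)
    }
  }
})

test_that("profiles rebuilt from profile samples recover the generator", {
  gen_recs <- make_records("ACCCCT", "AAAA", "GTTGTCGGTTGTG", "CGAATACATG")
  gen <- promoter_profile(gen_recs, pseudocount = 0.02)
  samp <- sample_promoter_set(gen, 200, seed = 101)
  expect_equal(nrow(samp), 200L)
  refit <- promoter_profile(samp, pseudocount = 0.02)
  expect_lt(max(abs(refit$freq - gen$freq)), 0.05)
  # spacer lengths come from the fitted distribution
  expect_true(all(nchar(samp$spacer_seq) %in% 12:15))
})

test_that("a single sampled record reproduces itself at pseudocount 0", {
  gen_recs <- make_records("ACCCCT", "AAAA", "GTTGTCGGTTGTG", "CGAATACATG")
  gen <- promoter_profile(gen_recs, pseudocount = 0.001)
  one <- sample_promoter_set(gen, 1, seed = 9)
  pf1 <- promoter_profile(one, pseudocount = 0)
  # every counted column is that record's base with frequency 1
  counted <- pf1$n_eff > 0
  expect_true(all(apply(pf1$freq[, counted, drop = FALSE], 2, max) == 1))
})

test_that("two seeds give different samples with the same convergence", {
  gen_recs <- make_records("ACCCCT", "AAAA", "GTTGTCGGTTGTG", "CGAATACATG")
  gen <- promoter_profile(gen_recs, pseudocount = 0.02)
  s1 <- sample_promoter_set(gen, 150, seed = 1)
  s2 <- sample_promoter_set(gen, 150, seed = 2)
  expect_false(identical(s1$minus10_seq, s2$minus10_seq))
  for (s in list(s1, s2)) {
    refit <- promoter_profile(s, pseudocount = 0.02)
    expect_lt(max(abs(refit$freq - gen$freq)), 0.07)
  }
})

test_that("profile S3 surface works: print, summary, coef, plot, export", {
  pf <- promoter_profile(ct_records(), sigma_label = "sigI3")
  expect_output(print(pf), "sigI3")
  sm <- summary(pf)
  expect_s3_class(sm, "summary.promoter_profile")
  expect_equal(nrow(sm), ncol(pf$freq))
  expect_identical(coef(pf), pf$freq)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(pf))
  f <- tempfile(fileext = ".tsv")
  write_profile(pf, f)
  back <- read.delim(f)
  expect_equal(nrow(back), ncol(pf$freq))
  expect_equal(back$A, unname(pf$freq["A", ]), tolerance = 1e-12)
})

test_that("record validation rejects malformed promoter records", {
  bad <- make_records("GTCGTC", "AAT", "GGT", "CGAA", 1)
  expect_error(promoter_profile(bad), "atract_seq")
  short <- make_records("GTCGTC", "AAA", "GGT", "CGA", 1)
  expect_error(promoter_profile(short), "minus10_seq")
  recs <- make_records("GTCGTC", "AAA", "GGT", "CGAA", 1)
  expect_error(promoter_profile(recs, pseudocount = -1), "pseudocount")
})
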