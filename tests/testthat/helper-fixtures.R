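# Shared fixtures for the test suite.

ct_fixture_path <- function() {
  system.file("extdata", "ct_sigI_promoters.synthetic.tsv",
              package = "sigiscan")
}

pc_fixture_path <- function() {
  system.file("extdata", "pc_sigI11_promoters.synthetic.tsv",
              package = "sigiscan")
}

ct_records <- function() read_promoter_sets(ct_fixture_path())

# canonical sigI3-style wild-type promoter window used by the mutagenesis
# tests: flank | specificity (CCC two nt upstream of the tract, the
# CCCCTAAA context) | AAA tract | 13-nt spacer | CGAA | downstream with the
# AT dyad | flank
rgl_wt_window <- function() {
  paste0("TG", "ACCCCT", "AAA", "GTTGTCGGTTGTG", "CGAA", "TACATG", "CT")
}

# five parametric generators with pairwise-distinct specificity triads at
# offset 0, used for planted-recovery and misassignment checks
disjoint_generators <- function() {
  tri <- c(sigI1 = "CTC", sigI2 = "TGT", sigI3 = "CCC",
           sigI4 = "GAG", sigI6 = "TAC")
  setNames(lapply(names(tri), function(lab) {
    sigma_generator(lab, tri[[lab]], offset = 0L, tetrad = "CGAA")
  }), names(tri))
}

# rules matching disjoint_generators(): triad at offset 0 only, CGAA tetrad
disjoint_rules <- function() {
  tri <- c(sigI1 = "CTC", sigI2 = "TGT", sigI3 = "CCC",
           sigI4 = "GAG", sigI6 = "TAC")
  setNames(lapply(names(tri), function(lab) {
    specificity_rule(lab, tri[[lab]], 0L, 0L, "CGAA", NULL)
  }), names(tri))
}
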