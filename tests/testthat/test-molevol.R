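sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

test_that("per-codon site counts match enumeration of single-base mutants", {
  # hand-checkable cases, frozen from the enumeration oracle
  expect_equal(ng_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_sites("GGG"), c(s = 1, n = 2))
  expect_equal(ng_sites("ATG"), c(s = 0, n = 3))
  for (cd in sense_codons)
    expect_equal(ng_sites(cd), oracle_ng_sites(cd), tolerance = 1e-12)
  # every codon contributes exactly 3 sites; 61 codons contribute 183
  total <- sum(vapply(sense_codons, function(cd) sum(ng_sites(cd)),
                      numeric(1)))
  expect_equal(total, 183)
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("ANT"), "ambiguous")
})

test_that("pathway-averaged difference counts match the oracle", {
  expect_equal(ng_differences("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng_differences("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(ng_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  # two pathways: TTT->GTT->GTA (1 syn + 1 nonsyn) and TTT->TTA->GTA (2 nonsyn)
  expect_equal(ng_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  for (a in sample(sense_codons, 12)) for (b in sample(sense_codons, 12))
    expect_equal(ng_differences(a, b), oracle_ng_diffs(a, b),
                 tolerance = 1e-12)
  expect_error(ng_differences("TAA", "TTT"), "stop")
})

test_that("Jukes-Cantor correction has the closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.10), 0.10733, tolerance = 1e-4)
  expect_equal(jukes_cantor(0.10), -0.75 * log(1 - 0.4 / 3))
  expect_error(jukes_cantor(0.75), "saturates")
  expect_error(jukes_cantor(-0.1), "non-negative")
  # never shrinks, strictly increasing
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1]))
})

test_that("ka_ks composes sites, differences and correction; symmetric", {
  expect_equal(ka_ks("ATGGGGTAA", "ATGGGGTAA")$Ks, 0)
  expect_equal(ka_ks("ATGGGGTAA", "ATGGGGTAA")$Ka, 0)
  # single synonymous difference, composed by hand from the parts
  x <- "TTTGGGAAACCC"; y <- "TTCGGGAAACCC"
  kk <- ka_ks(x, y)
  S <- (ng_sites("TTT")[["s"]] + ng_sites("TTC")[["s"]] +
          2 * (ng_sites("GGG")[["s"]] + ng_sites("AAA")[["s"]] +
                 ng_sites("CCC")[["s"]])) / 2
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$S, S)
  expect_equal(kk$Ks, jukes_cantor(1 / S))
  expect_equal(kk$Ka, 0)
  set.seed(51)
  for (i in 1:5) {
    a_cod <- sample(sense_codons, 80, replace = TRUE)
    b_cod <- a_cod
    mut <- sample(80, 8)                 # moderately diverged pair
    b_cod[mut] <- sample(sense_codons, 8, replace = TRUE)
    a <- paste(a_cod, collapse = ""); b <- paste(b_cod, collapse = "")
    kab <- ka_ks(a, b)
    kba <- ka_ks(b, a)
    expect_equal(kab$Ks, kba$Ks, tolerance = 1e-12)
    expect_equal(kab$Ka, kba$Ka, tolerance = 1e-12)
  }
  # ambiguous codons are skipped and counted
  kk2 <- ka_ks("TTTNNNGGGAAACCC", "TTCNNNGGGAAACCC")
  expect_equal(kk2$codons_skipped, 1)
  expect_equal(kk2$Sd, 1)
  expect_error(ka_ks("TTT", "TT"), "equal length")
  expect_error(ka_ks("NNN", "NNN"), "no analyzable codons")
})

test_that("ORF finding returns the longest ATG-to-stop frame, any strand", {
  orf <- find_orf("ATGAAATAG", min_len = 9)
  expect_equal(orf[c("strand", "frame", "start", "end")],
               list(strand = "+", frame = 0, start = 0, end = 9))
  expect_null(find_orf("CCCCCCCCCCCC", min_len = 9))
  expect_null(find_orf("ATGAAA", min_len = 9))      # no stop: not an ORF
  # embed a long ORF on the reverse strand of a random background
  set.seed(52)
  inner <- paste(c("ATG", sample(sense_codons, 40, replace = TRUE), "TAA"),
                 collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(inner)))
  seq <- paste0("CCTCC", rc, "CCTCC")
  orf <- find_orf(seq, min_len = 30)
  expect_equal(orf$strand, "-")
  expect_equal(orf$cds, inner)
  # length agrees with a brute-force 6-frame scan on random sequences
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    got <- find_orf(s, min_len = 30)
    expect_equal(if (is.null(got)) 0 else nchar(got$cds),
                 oracle_longest_orf(s, 30))
  }
  expect_error(find_orf(""), "empty")
})

test_that("allele phasing substitutes SNP bases into the reference CDS", {
  ph <- phase_alleles("ATGTTTTAA",
                      data.frame(pos = 6, x_base = "T", y_base = "A"))
  expect_equal(ph$seq_x, "ATGTTTTAA")
  expect_equal(ph$seq_y, "ATGTTATAA")
  ph0 <- phase_alleles("ATGTTTTAA", NULL)
  expect_equal(ph0$seq_x, ph0$seq_y)
  ph2 <- phase_alleles("ATGTTTTAA",
                       data.frame(pos = c(4, 6), x_base = c("T", "T"),
                                  y_base = c("C", "A")))
  expect_equal(ph2$seq_y, "ATGCTATAA")   # both substitutions in one codon
  expect_error(phase_alleles("ATG", data.frame(pos = 9, x_base = "A",
                                               y_base = "C")), "outside")
  expect_error(phase_alleles("ATGTTTTAA",
                             data.frame(pos = c(6, 6), x_base = c("T", "T"),
                                        y_base = c("A", "G"))),
               "conflicting")
})

test_that("the molecular clock converts rates to time", {
  expect_equal(signif(divergence_time(0.0736) / 1e6, 3), 5.66)
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.0057), 0.0057 / (2 * 6.5e-9))
  expect_equal(signif(divergence_time(0.0057), 3), 4.38e5)
  expect_equal(divergence_time(0.1, r = 1e-8, generation_years = 2), 1e7)
  expect_error(divergence_time(0.1, r = 0), "positive")
  expect_error(divergence_time(-0.1), "non-negative")
})

test_that("exact rank-sum test equals permutation enumeration", {
  rs <- rank_sum_exact(c(1, 2), c(3, 4))
  expect_equal(rs$p, 1 / 3)
  expect_equal(rs$W, 3)
  expect_equal(rank_sum_exact(c(5, 5, 5), c(5, 5, 5))$p, 1)
  set.seed(53)
  for (i in 1:30) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- sample(1:6, na, replace = TRUE)   # replacement forces ties
    b <- sample(1:6, nb, replace = TRUE)
    got <- rank_sum_exact(a, b)
    ref <- oracle_rank_sum(a, b)
    expect_equal(got$W, ref$W)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
  # agrees with stats::wilcox.test exact p in the tie-free case
  a <- c(1.2, 3.4, 5.1, 2.2); b <- c(6.3, 7.7, 0.5, 8.8, 9.1)
  expect_equal(rank_sum_exact(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
  expect_error(rank_sum_exact(numeric(0), 1), "empty")
})

test_that("per-gene divergence pipeline handles reverse-strand ORFs", {
  # forward gene: CDS is the whole unigene
  cds <- paste(c("ATG", rep("GGT", 60), "TAA"), collapse = "")
  sheet <- test_sheet(c(paste0("F", 1:4), paste0("M", 1:4)),
                      rep(c("female", "male"), each = 4))
  # one P1 SNP at position 10 (first base of codon 4): ref G, alt A
  sites <- data.frame(unigene = "u1", pos = 10L, ref = "G", alt = "A",
                      stringsAsFactors = FALSE)
  ad <- matrix(rep(c("30,0", "15,15"), each = 4), nrow = 1)
  vt <- structure(list(sites = sites, ad = ad, samples = sheet),
                  class = "variant_table")
  cl <- data.frame(unigene = "u1", pos = 10L, pattern = "P1",
                   x_allele = 0L, y_allele = 1L,
                   hemizygosity_unknown = FALSE, stringsAsFactors = FALSE)
  fwd <- xy_divergence(c(u1 = cds), cl, vt)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$Nd, 1)   # GGT -> AGT is Gly -> Ser
  # same gene presented on the opposite strand: identical rates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  L <- nchar(cds)
  sites_rc <- data.frame(unigene = "u1", pos = L - 10L + 1L, ref = "C",
                         alt = "T", stringsAsFactors = FALSE)
  vt_rc <- structure(list(sites = sites_rc, ad = ad, samples = sheet),
                     class = "variant_table")
  cl_rc <- transform(cl, pos = L - 10L + 1L)
  rev <- xy_divergence(c(u1 = rc), cl_rc, vt_rc)
  expect_equal(rev$Ka, fwd$Ka)
  expect_equal(rev$Ks, fwd$Ks)
})
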