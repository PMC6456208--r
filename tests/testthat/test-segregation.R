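f8 <- function(gt) rep(gt, 8)

test_that("the three diagnostic patterns and their allele assignments", {
  # all females one homozygote, all males heterozygous for it + one more
  p1 <- classify_site(f8("0/0"), f8("0/1"))
  expect_equal(p1[c("pattern", "x_allele", "y_allele")],
               list(pattern = "P1", x_allele = 0L, y_allele = 1L))
  # all females heterozygous, all males the same homozygote
  p2 <- classify_site(f8("0/1"), f8("1/1"))
  expect_equal(p2$pattern, "P2")
  expect_equal(p2$y_allele, 1L)
  expect_true(p2$hemizygosity_unknown)
  # triallelic: females a/b, males a/c
  p3 <- classify_site(f8("0/1"), f8("0/2"))
  expect_equal(p3[c("pattern", "x_allele", "y_allele")],
               list(pattern = "P3", x_allele = 0L, y_allele = 2L))
})

test_that("inconsistent or uninformative configurations give NONE", {
  expect_equal(classify_site(c(rep("0/0", 7), "0/1"), f8("0/1"))$pattern,
               "NONE")                       # one discordant female
  expect_equal(classify_site(f8("0/0"), f8("0/0"))$pattern, "NONE")
  expect_equal(classify_site(f8("0/0"), f8("1/1"))$pattern, "NONE")
  expect_equal(classify_site(f8("0/1"), f8("0/1"))$pattern, "NONE")
  expect_equal(classify_site(f8("0/1"), f8("2/3"))$pattern, "NONE")
  # a missing call disqualifies the site when completeness is required
  expect_equal(classify_site(c(f8("0/0")[-1], NA), f8("0/1"))$pattern, "NONE")
  # ... but not when it is disabled and enough calls per sex remain
  expect_equal(classify_site(c(f8("0/0")[-1], NA), f8("0/1"),
                             require_complete = FALSE)$pattern, "P1")
  expect_equal(classify_site(c("0/0", "0/0", NA, NA, NA, NA, NA, NA),
                             f8("0/1"), require_complete = FALSE)$pattern,
               "NONE")                       # below min_per_sex
  expect_error(classify_site(character(0), f8("0/1")), "at least one")
})

test_that("relabelling REF and ALT leaves the pattern invariant", {
  relabel <- function(gt) {  # swap allele indices 0 and 1
    chartr("01", "10", gt)
  }
  sort_gt <- function(gt) vapply(strsplit(gt, "/"), function(p)
    paste(sort(p), collapse = "/"), character(1))
  cases <- list(list(f8("0/0"), f8("0/1")), list(f8("0/1"), f8("1/1")),
                list(f8("0/1"), f8("0/2")), list(f8("0/0"), f8("0/0")),
                list(c(f8("0/0")[-1], "0/1"), f8("0/1")))
  for (cs in cases) {
    a <- classify_site(cs[[1]], cs[[2]])
    b <- classify_site(sort_gt(relabel(cs[[1]])), sort_gt(relabel(cs[[2]])))
    expect_equal(a$pattern, b$pattern)
  }
})

test_that("unigene aggregation counts a two-pattern gene once", {
  cl <- data.frame(
    unigene = c("u1", "u2", "u3", "u3", "u4"),
    pos = c(1L, 1L, 1L, 5L, 1L),
    pattern = c("P1", "P2", "P1", "P2", "NONE"),
    stringsAsFactors = FALSE)
  agg <- aggregate_unigenes(cl)
  expect_equal(unname(agg$unigene_counts[c("P1", "P2")]), c(2L, 2L))
  expect_equal(agg$total_snps, 4L)
  expect_equal(agg$total_distinct_unigenes, 3L)   # u3 counted once
  # union oracle
  sets <- lapply(c("P1", "P2", "P3"), function(p)
    unique(cl$unigene[cl$pattern == p]))
  expect_equal(agg$total_distinct_unigenes, length(unique(unlist(sets))))

  none <- aggregate_unigenes(cl[cl$pattern == "NONE", ])
  expect_equal(none$total_snps, 0L)
  expect_equal(none$total_distinct_unigenes, 0L)
})

test_that("chance sex-pattern calls at autosomal sites match the binomial rate", {
  # maternal-heterozygous site, father homozygous: each progeny is het with
  # probability 1/2, so a spurious P1 (all 8 females hom, all 8 males het)
  # or P2 (the reverse) each occurs with probability (1/2)^16
  set.seed(123)
  n_sites <- 2e5
  het_f <- matrix(runif(n_sites * 8) < 0.5, n_sites)
  het_m <- matrix(runif(n_sites * 8) < 0.5, n_sites)
  spurious <- (rowSums(het_f) == 0 & rowSums(het_m) == 8) |
              (rowSums(het_f) == 8 & rowSums(het_m) == 0)
  lambda <- n_sites * 2 * 0.5^16
  expect_gte(sum(spurious), qpois(0.0005, lambda))
  expect_lte(sum(spurious), qpois(0.9995, lambda))
  # and the classifier agrees with the direct configuration check
  idx <- c(which(spurious)[1], which(!spurious)[1])
  for (i in idx) {
    fc <- ifelse(het_f[i, ], "0/1", "0/0")
    mc <- ifelse(het_m[i, ], "0/1", "0/0")
    got <- classify_site(fc, mc)$pattern
    expect_equal(got != "NONE", spurious[i])
  }
})

test_that("simulated fixed X-Y differences classify as pattern 1", {
  cfg <- sim_config(n_msy = 15, n_par = 0, n_auto = 0, n_ortholog = 0,
                    gene_length = 600, error_rate = 0, seed = 21)
  sim <- generate_dataset(cfg, tempfile("seg"))
  cl <- suppressMessages(sexlink_pipeline(sim$variants)$classifications)
  truth <- do.call(rbind, lapply(sim$truth, function(g)
    if (nrow(g$diffs)) data.frame(unigene = g$id, pos = g$diffs$pos) else NULL))
  got <- merge(truth, cl, by = c("unigene", "pos"))
  expect_equal(nrow(got), nrow(truth))
  expect_true(all(got$pattern == "P1"))
})
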