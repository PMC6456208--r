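tiny_cfg <- function(...) sim_config(n_msy = 4, n_par = 3, n_auto = 3,
                                     n_ortholog = 2, gene_length = 300, ...)

test_that("reference generation is deterministic, coding and stop-free", {
  set.seed(71); a <- generate_reference(20, 300)
  set.seed(71); b <- generate_reference(20, 300)
  expect_identical(a, b)
  for (s in a) {
    expect_equal(nchar(s), 300)
    expect_equal(substr(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, 298, 3), seq(3, 300, 3))
    expect_true(codons[100] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-100] %in% c("TAA", "TAG", "TGA")))
  }
  gc <- mean(strsplit(paste(a, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.35); expect_lt(gc, 0.65)
  expect_error(generate_reference(2, 301), "multiple of 3")
})

test_that("sequence-pair evolution respects time, rate and Ka/Ks target", {
  cds <- paste(c("ATG", rep(c("GGT", "CTC", "AAA"), 99), "TAA"), collapse = "")
  set.seed(72)
  same <- evolve_pair(cds, years = 0, r = 6.5e-9, ka_ks_target = 0.27)
  expect_equal(same$seq_a, same$seq_b)
  expect_equal(nrow(same$diffs), 0L)
  # ka_ks_target 0: every fixed difference is synonymous
  set.seed(73)
  for (i in 1:5) {
    ev <- evolve_pair(cds, 2e6, 6.5e-9, ka_ks_target = 0)
    if (nrow(ev$diffs)) expect_true(all(ev$diffs$class == "syn"))
  }
  expect_error(evolve_pair(cds, 1e12, 6.5e-9, 0.27), "saturates")
  # realized synonymous divergence matches the 2 r T expectation
  set.seed(74)
  ks <- replicate(150, {
    ev <- evolve_pair(cds, 4e5, 6.5e-9, 1)   # all proposals accepted
    ka_ks(ev$seq_a, ev$seq_b)$Ks
  })
  expect_lt(abs(mean(ks) - 2 * 6.5e-9 * 4e5),
            2 * sd(ks) / sqrt(length(ks)) + 1e-4)
})

test_that("cross simulation follows XY inheritance by compartment", {
  cfg <- sim_config(n_msy = 10, n_par = 10, n_auto = 10, n_ortholog = 0,
                    gene_length = 600, pi = 0.004, seed = 75)
  set.seed(75)
  truth <- simulate_truth(cfg)
  cross <- simulate_cross(truth, cfg)
  comp <- setNames(vapply(truth, `[[`, character(1), "compartment"),
                   vapply(truth, `[[`, character(1), "id"))
  sex <- cross$samples$sex
  # fixed X-Y sites: all daughters homozygous, all sons heterozygous
  fixed <- which(cross$sites$is_xy_fixed)
  expect_gt(length(fixed), 0)
  for (i in fixed) {
    g <- cross$geno[i, ]
    expect_true(all(gt_is_het_vec(g[sex == "male"])))
    expect_false(any(gt_is_het_vec(g[sex == "female"])))
  }
  # autosomal maternal-het sites segregate ~1:1 het:hom in the progeny
  auto <- cross$sites$unigene %in% names(comp)[comp == "AUTO"]
  het_frac <- mean(gt_is_het_vec(as.vector(cross$geno[auto, ])))
  n_calls <- sum(auto) * length(sex)
  expect_gt(n_calls, 100)
  # each polymorphic site carries the derived allele on 1-3 of 4 haplotypes;
  # expected progeny het fraction is 1/2 on average
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / n_calls) + 0.05)
})

test_that("read-depth simulation is faithful at zero error and unbiased", {
  cfg <- sim_config(n_msy = 20, n_par = 0, n_auto = 0, n_ortholog = 0,
                    gene_length = 600, error_rate = 0, depth_mean = 60,
                    seed = 76)
  set.seed(76)
  truth <- simulate_truth(cfg)
  cross <- simulate_cross(truth, cfg)
  dep <- simulate_depths(cross, truth, cfg)
  ad <- dep$variants$ad
  hom <- !gt_is_het_vec(as.vector(cross$geno))
  depths <- strsplit(as.vector(ad), ",")
  # homozygous samples: every read on the single true allele
  for (k in which(hom)) {
    d <- as.integer(depths[[k]])
    expect_lte(sum(d > 0), 1L)
  }
  # heterozygous: allele balance centred on 1/2
  hets <- which(!hom)
  alt_frac <- vapply(depths[hets], function(d) {
    d <- as.integer(d); d[d > 0][1] / sum(d)
  }, numeric(1))
  expect_lt(abs(mean(alt_frac) - 0.5), 2 * sd(alt_frac) / sqrt(length(hets)) + 0.02)
})

test_that("datasets are byte-identical under one seed, different across seeds", {
  d1 <- tempfile("s1"); d2 <- tempfile("s2"); d3 <- tempfile("s3")
  generate_dataset(tiny_cfg(seed = 77), d1)
  generate_dataset(tiny_cfg(seed = 77), d2)
  generate_dataset(tiny_cfg(seed = 78), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  v1 <- read.delim(file.path(d1, "variants.vcf"), comment.char = "#",
                   header = FALSE)
  v3 <- read.delim(file.path(d3, "variants.vcf"), comment.char = "#",
                   header = FALSE)
  expect_false(identical(paste(v1$V1, v1$V2), paste(v3$V1, v3$V2)))
})

test_that("generated datasets are self-consistent and run end-to-end", {
  sim <- generate_dataset(tiny_cfg(seed = 79), tempfile("e2e"))
  truth <- read.delim(file.path(sim$dir, "truth.tsv"))
  expect_equal(nrow(truth), 4 + 3 + 3)
  expect_equal(sum(truth$compartment == "MSY"), 4)
  expect_equal(sort(list.files(sim$dir)),
               sort(c("reference.fasta", "variants.vcf", "counts.tsv",
                      "samples.tsv", "truth.tsv", "truth_sites.tsv",
                      "orthologs_sp1.fasta", "orthologs_sp2.fasta")))
  res <- suppressMessages(run_all(sim$dir, tempfile("out")))
  expect_s3_class(res$sexlink$summary, "segregation_summary")
  expect_equal(nrow(res$de), nrow(truth))
  # truth sites with fixed differences exist for MSY genes only
  ts <- read.delim(file.path(sim$dir, "truth_sites.tsv"))
  if (nrow(ts))
    expect_true(all(ts$gene_id %in% truth$gene_id[truth$compartment == "MSY"]))
})

test_that("PAR genes at recombination fraction 0.5 behave autosomally", {
  cfg <- sim_config(n_msy = 0, n_par = 60, n_auto = 60, n_ortholog = 0,
                    gene_length = 600, pi = 0.004, par_recomb = 0.5,
                    seed = 80)
  set.seed(80)
  truth <- simulate_truth(cfg)
  cross <- simulate_cross(truth, cfg)
  comp <- setNames(vapply(truth, `[[`, character(1), "compartment"),
                   vapply(truth, `[[`, character(1), "id"))
  sex <- cross$samples$sex
  p_of <- function(rows) vapply(rows, function(i)
    fisher_exact_2xk(sex_genotype_table(cross$geno[i, ], sex)), numeric(1))
  par_rows <- which(comp[cross$sites$unigene] == "PAR")
  auto_rows <- which(comp[cross$sites$unigene] == "AUTO")
  p_par <- p_of(par_rows); p_auto <- p_of(auto_rows)
  # same sex-association p distribution as autosomal sites
  ks <- suppressWarnings(ks.test(p_par, p_auto))
  expect_gt(ks$p.value, 0.01)
  expect_gt(median(p_par), 0.2)
})
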