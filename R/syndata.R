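#' Simulation configuration for a synthetic XY cross
#'
#' Defaults describe the emulated study design: 8 female + 8 male progeny of
#' a single dioecious cross, three genomic compartments (male-specific Y
#' region, pseudoautosomal region, autosome), X-Y divergence of 0.4 million
#' years under a neutral rate of 6.5e-9 per site per year, read depth around
#' 50x and a 0.5% per-read miscall rate.
#'
#' @param ... named overrides of the default keys.
#' @details Keys: \code{n_msy}, \code{n_par}, \code{n_auto} (genes per
#'   compartment: 50 / 100 / 200); \code{gene_length} (coding nt, multiple
#'   of 3, default 900); \code{xy_divergence_years} (4e5);
#'   \code{n_ortholog} (interspecific ortholog pairs, default 100) and
#'   \code{interspecific_divergence_years} (5.66e6); \code{r} (6.5e-9 per
#'   site per year); \code{ka_ks_target} (acceptance probability of
#'   non-synonymous changes, 0.27); \code{n_progeny_per_sex} (8);
#'   \code{depth_mean} (50); \code{error_rate} (0.005); \code{pi} (per-site
#'   heterozygosity of segregating polymorphism, 0.002); \code{par_recomb}
#'   (recombination fraction between a PAR gene and the sex-determining
#'   locus, 0.2); \code{allelic_bias} (Y/X expression ratio at heterozygous
#'   X-Y sites in males, 1.0); \code{expr_mean}, \code{nb_size},
#'   \code{expr_de_frac}, \code{expr_lfc} (expression counts: negative
#'   binomial mean 200, size 10, 5\% of genes with a log2 fold change of 1
#'   between sexes); \code{seed} (1).
#' @return Named list of class \code{"sim_config"}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_msy = 50L, n_par = 100L, n_auto = 200L,
    gene_length = 900L,
    xy_divergence_years = 4e5,
    n_ortholog = 100L,
    interspecific_divergence_years = 5.66e6,
    r = 6.5e-9,
    ka_ks_target = 0.27,
    n_progeny_per_sex = 8L,
    depth_mean = 50,
    error_rate = 0.005,
    pi = 0.002,
    par_recomb = 0.2,
    allelic_bias = 1.0,
    expr_mean = 200,
    nb_size = 10,
    expr_de_frac = 0.05,
    expr_lfc = 1,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown sim_config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (cfg$gene_length %% 3L != 0L || cfg$gene_length < 300L)
    stop("gene_length must be a multiple of 3 and at least 300")
  structure(cfg, class = "sim_config")
}

.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

#' Generate random coding sequences
#'
#' Each gene is ATG, then uniformly sampled sense codons, then a random stop
#' codon; no internal stops can occur by construction.  Uses the current RNG
#' state (seed it, or call via \code{\link{generate_dataset}}).
#'
#' @param n_genes number of sequences.
#' @param gene_length length in nt, a multiple of 3 (>= 9).
#' @return Character vector of sequences (unnamed).
#' @export
generate_reference <- function(n_genes, gene_length) {
  if (gene_length %% 3L != 0L || gene_length < 9L)
    stop("gene_length must be a multiple of 3 and at least 9")
  n_mid <- gene_length %/% 3L - 2L
  vapply(seq_len(n_genes), function(i) {
    paste0("ATG",
           paste(sample(.SENSE_CODONS, n_mid, replace = TRUE), collapse = ""),
           sample(.STOP_CODONS, 1L))
  }, character(1L))
}

#' Evolve a pair of sequences from a common ancestor
#'
#' Each lineage receives a Poisson number of proposed substitutions with
#' mean \code{length * r * years}; a proposal is accepted always when
#' synonymous and with probability \code{ka_ks_target} when
#' non-synonymous, and never when it would create a stop codon.  The
#' expected realised synonymous divergence between the two sequences is
#' therefore \code{2 * r * years} per synonymous site.
#'
#' @param cds ancestral coding sequence (ATG...stop, no internal stop).
#' @param years divergence time in years (per lineage).
#' @param r neutral substitution rate per site per year.
#' @param ka_ks_target acceptance probability for non-synonymous proposals.
#' @return List: \code{seq_a}, \code{seq_b} and \code{diffs}, a data frame
#'   of fixed differences (\code{pos} 1-based, \code{base_a}, \code{base_b},
#'   \code{class} \code{"syn"}/\code{"nonsyn"}).
#' @export
evolve_pair <- function(cds, years, r, ka_ks_target) {
  if (years < 0) stop("years must be non-negative")
  if (2 * r * years >= 0.75)
    stop("expected divergence saturates the Jukes-Cantor correction")
  L <- nchar(cds)
  anc <- strsplit(toupper(cds), "")[[1L]]
  mut_class <- matrix(NA_character_, nrow = 2L, ncol = L)  # last event class
  seqs <- list(anc, anc)
  for (lin in 1:2) {
    s <- seqs[[lin]]
    n_prop <- stats::rpois(1L, L * r * years)
    if (n_prop > 0L) for (k in seq_len(n_prop)) {
      pos <- sample.int(L - 3L, 1L)      # terminal stop codon not mutated
      new <- sample(setdiff(.BASES, s[pos]), 1L)
      ci <- (pos - 1L) %/% 3L
      cod_from <- paste(s[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      mut <- s
      mut[pos] <- new
      cod_to <- paste(mut[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      if (is_stop_codon(cod_to)) next
      syn <- translate_codon(cod_from) == translate_codon(cod_to)
      if (!syn && stats::runif(1L) >= ka_ks_target) next
      s <- mut
      mut_class[lin, pos] <- if (syn) "syn" else "nonsyn"
    }
    seqs[[lin]] <- s
  }
  a <- seqs[[1L]]; b <- seqs[[2L]]
  pos <- which(a != b)
  cls <- vapply(pos, function(p) {
    v <- stats::na.omit(mut_class[, p])
    v[length(v)]
  }, character(1L))
  list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
       diffs = data.frame(pos = pos, base_a = a[pos], base_b = b[pos],
                          class = cls, stringsAsFactors = FALSE))
}

# non-empty proper subsets of the four parental haplotype slots
.HAP_SUBSETS <- Filter(function(s) length(s) > 0L && length(s) < 4L,
                       unlist(lapply(1:3, function(k)
                         utils::combn(4L, k, simplify = FALSE)),
                         recursive = FALSE))

#' Simulate the true genes and parental haplotypes of an XY cross
#'
#' Genes in the MSY compartment carry fixed X-Y differences produced by
#' \code{\link{evolve_pair}} (mother and father X copies identical to the X
#' lineage, father Y the diverged Y lineage).  PAR and autosomal genes carry
#' segregating polymorphism only: each site is polymorphic with probability
#' \code{pi} and its derived allele is placed on a uniformly drawn
#' non-empty proper subset of the four parental haplotypes.  Uses the
#' current RNG state.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List of class \code{"sim_truth"}: per gene \code{id},
#'   \code{compartment} (\code{"MSY"}, \code{"PAR"}, \code{"AUTO"}),
#'   \code{ref}, haplotypes \code{hap} (list of 4 character vectors:
#'   mother 1, mother 2, father X, father Y), \code{diffs} (X-Y fixed
#'   differences, MSY only), \code{divergence_years}.
#' @export
simulate_truth <- function(config = sim_config()) {
  n <- c(MSY = config$n_msy, PAR = config$n_par, AUTO = config$n_auto)
  ids <- sprintf("gene%04d", seq_len(sum(n)))
  comp <- rep(names(n), n)
  refs <- generate_reference(sum(n), config$gene_length)
  genes <- vector("list", sum(n))
  for (i in seq_along(ids)) {
    ref <- refs[i]
    L <- nchar(ref)
    if (comp[i] == "MSY") {
      ev <- evolve_pair(ref, config$xy_divergence_years, config$r,
                        config$ka_ks_target)
      x <- strsplit(ev$seq_a, "")[[1L]]
      y <- strsplit(ev$seq_b, "")[[1L]]
      hap <- list(x, x, x, y)
      diffs <- ev$diffs
      dy <- config$xy_divergence_years
    } else {
      base <- strsplit(ref, "")[[1L]]
      hap <- list(base, base, base, base)
      vpos <- which(stats::runif(L - 3L) < config$pi)  # stop codon untouched
      for (p in vpos) {
        derived <- sample(setdiff(.BASES, base[p]), 1L)
        carriers <- .HAP_SUBSETS[[sample.int(length(.HAP_SUBSETS), 1L)]]
        for (h in carriers) hap[[h]][p] <- derived
      }
      diffs <- data.frame(pos = integer(), base_a = character(),
                          base_b = character(), class = character(),
                          stringsAsFactors = FALSE)
      dy <- 0
    }
    genes[[i]] <- list(id = ids[i], compartment = comp[i], ref = ref,
                       hap = hap, diffs = diffs, divergence_years = dy)
  }
  structure(genes, class = "sim_truth")
}

#' Simulate progeny genotypes of the cross
#'
#' Each progeny receives one maternal X per gene (a recombination-free draw
#' between the two maternal haplotypes) and the paternal X (daughters) or Y
#' (sons).  MSY genes never recombine with the sex-determining locus; PAR
#' genes switch between the paternal X and Y haplotypes with probability
#' \code{par_recomb}; autosomal genes segregate independently of sex.
#' Progeny sex counts are fixed at \code{n_progeny_per_sex} each.  Uses the
#' current RNG state.
#'
#' @param truth a \code{\link{simulate_truth}} result.
#' @param config a \code{\link{sim_config}}.
#' @return List of class \code{"sim_cross"}: \code{sites} (data frame:
#'   \code{unigene}, \code{pos}, \code{ref}, \code{alt}, \code{is_xy_fixed},
#'   \code{x_allele}, \code{y_allele} 0-based indices), \code{geno}
#'   (character matrix sites x samples of \code{"i/j"} codes),
#'   \code{samples} (a \code{\link{sample_sheet}}).
#' @export
simulate_cross <- function(truth, config = sim_config()) {
  np <- config$n_progeny_per_sex
  samp_ids <- c(sprintf("F%d", seq_len(np)), sprintf("M%d", seq_len(np)))
  sexes <- rep(c("female", "male"), each = np)
  n_samp <- 2L * np
  site_rows <- list()
  geno_rows <- list()
  for (g in truth) {
    hapm <- do.call(rbind, g$hap)      # 4 x L
    ref <- strsplit(g$ref, "")[[1L]]
    vpos <- which(colSums(hapm != rep(ref, each = 4L)) > 0L)
    if (!length(vpos)) next
    # inheritance draws, one per progeny per gene
    mat <- sample.int(2L, n_samp, replace = TRUE)
    pat <- switch(g$compartment,
      MSY = ifelse(sexes == "female", 3L, 4L),
      PAR = {
        intended <- ifelse(sexes == "female", 3L, 4L)
        flip <- stats::runif(n_samp) < config$par_recomb
        ifelse(flip, 7L - intended, intended)
      },
      AUTO = sample(c(3L, 4L), n_samp, replace = TRUE))
    for (p in vpos) {
      bases <- hapm[, p]
      alts <- sort(setdiff(unique(bases), ref[p]))
      alleles <- c(ref[p], alts)
      ai <- match(bases, alleles) - 1L      # per-haplotype allele index
      a_mat <- ai[mat]; a_pat <- ai[cbind(pat)]
      gt <- paste(pmin(a_mat, a_pat), pmax(a_mat, a_pat), sep = "/")
      is_fixed <- g$compartment == "MSY" && p %in% g$diffs$pos
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        unigene = g$id, pos = p, ref = ref[p],
        alt = paste(alts, collapse = ","),
        is_xy_fixed = is_fixed,
        x_allele = ai[3L], y_allele = ai[4L],
        stringsAsFactors = FALSE)
      geno_rows[[length(geno_rows) + 1L]] <- gt
    }
  }
  sites <- do.call(rbind, site_rows)
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- samp_ids
  sheet <- sample_sheet(data.frame(
    sample_id = samp_ids, sex = sexes, role = "progeny", group = "cross",
    stringsAsFactors = FALSE))
  structure(list(sites = sites, geno = geno, samples = sheet),
            class = "sim_cross")
}

#' Simulate per-sample allele read depths and expression counts
#'
#' Per site and sample the total depth is Poisson(\code{depth_mean}); reads
#' split Binomially between the two alleles of a heterozygote (probability
#' 0.5, shifted to \code{bias/(1+bias)} for the Y allele at fixed X-Y sites
#' in males), then each read is miscalled to another listed allele with
#' probability \code{error_rate}.  Expression counts per gene and sample are
#' negative binomial with an optional sex effect on a random subset of
#' genes.  Uses the current RNG state.
#'
#' @param cross a \code{\link{simulate_cross}} result.
#' @param truth the matching \code{\link{simulate_truth}} result.
#' @param config a \code{\link{sim_config}}.
#' @return List: \code{variants} (a \code{variant_table}), \code{counts}
#'   (data frame \code{unigene}, \code{sample}, \code{mapped_reads}),
#'   \code{de_genes} (ids simulated with a sex effect).
#' @export
simulate_depths <- function(cross, truth, config = sim_config()) {
  sites <- cross$sites
  geno <- cross$geno
  n_sites <- nrow(sites); n_samp <- ncol(geno)
  male <- cross$samples$sex == "male"
  bias_p <- config$allelic_bias / (1 + config$allelic_bias)
  ad <- matrix("", n_sites, n_samp, dimnames = dimnames(geno))
  for (i in seq_len(n_sites)) {
    n_alleles <- 1L + length(strsplit(sites$alt[i], ",", fixed = TRUE)[[1L]])
    for (j in seq_len(n_samp)) {
      al <- gt_alleles(geno[i, j])
      depth <- stats::rpois(1L, config$depth_mean)
      counts <- integer(n_alleles)
      if (al[1L] == al[2L]) {
        counts[al[1L] + 1L] <- depth
      } else {
        # Y-allele read share at fixed X-Y heterozygotes in males
        p2 <- if (sites$is_xy_fixed[i] && male[j] &&
                  setequal(al, c(sites$x_allele[i], sites$y_allele[i]))) {
          if (al[2L] == sites$y_allele[i]) bias_p else 1 - bias_p
        } else 0.5
        n2 <- stats::rbinom(1L, depth, p2)
        counts[al[1L] + 1L] <- depth - n2
        counts[al[2L] + 1L] <- n2
      }
      if (config$error_rate > 0) {
        # a miscalled read lands uniformly on one of the 3 other bases;
        # reads on bases outside the allele list are not depth-counted
        site_bases <- c(sites$ref[i],
                        strsplit(sites$alt[i], ",", fixed = TRUE)[[1L]])
        moved <- integer(n_alleles)
        for (a in seq_len(n_alleles)) {
          if (counts[a] == 0L) next
          k <- stats::rbinom(1L, counts[a], config$error_rate)
          if (k == 0L) next
          counts[a] <- counts[a] - k
          dest <- sample(rep(setdiff(.BASES, site_bases[a]), 2L), k,
                         replace = TRUE)
          hit <- match(dest, site_bases)
          for (d in hit[!is.na(hit)]) moved[d] <- moved[d] + 1L
        }
        counts <- counts + moved
      }
      ad[i, j] <- paste(counts, collapse = ",")
    }
  }
  variants <- variant_table(sites[, c("unigene", "pos", "ref", "alt")],
                            ad, cross$samples)

  ids <- vapply(truth, `[[`, character(1L), "id")
  de <- ids[stats::runif(length(ids)) < config$expr_de_frac]
  mu <- matrix(config$expr_mean, length(ids), n_samp,
               dimnames = list(ids, colnames(geno)))
  mu[de, male] <- mu[de, male] * 2^config$expr_lfc
  counts_df <- data.frame(
    unigene = rep(ids, n_samp),
    sample = rep(colnames(geno), each = length(ids)),
    mapped_reads = stats::rnbinom(length(ids) * n_samp,
                                  mu = as.vector(mu), size = config$nb_size),
    stringsAsFactors = FALSE)
  list(variants = variants, counts = counts_df, de_genes = de)
}

#' Simulate genotypes of an unrelated association panel
#'
#' Reuses the simulated X and Y haplotypes: each male is an independent
#' X draw plus the Y, each female (or monoecious plant) two independent X
#' draws, where X draws are uniform over the three parental X haplotypes.
#' This reproduces exact-test behaviour at large panel sizes without a
#' coalescent model.  Uses the current RNG state.
#'
#' @param truth a \code{\link{simulate_truth}} result.
#' @param n_male,n_female,n_monoecious panel composition (defaults 104, 102,
#'   6).
#' @param compartment which compartment's genes to type (default
#'   \code{"MSY"}).
#' @return Data frame: \code{marker}, \code{sample}, \code{genotype},
#'   \code{sex} — the input layout of \code{\link{association_scan}}.
#' @export
simulate_panel <- function(truth, n_male = 104L, n_female = 102L,
                           n_monoecious = 6L, compartment = "MSY") {
  genes <- Filter(function(g) g$compartment == compartment, truth)
  n <- n_male + n_female + n_monoecious
  sexes <- rep(c("male", "female", "monoecious"),
               c(n_male, n_female, n_monoecious))
  ids <- sprintf("P%03d", seq_len(n))
  out <- list()
  for (g in genes) {
    hapm <- do.call(rbind, g$hap)
    ref <- strsplit(g$ref, "")[[1L]]
    vpos <- which(colSums(hapm != rep(ref, each = 4L)) > 0L)
    if (!length(vpos)) next
    p <- vpos[1L]                      # one marker SNP per gene
    bases <- hapm[, p]
    alts <- sort(setdiff(unique(bases), ref[p]))
    ai <- match(bases, c(ref[p], alts)) - 1L
    h1 <- ai[sample.int(3L, n, replace = TRUE)]          # X draw
    h2 <- ifelse(sexes == "male", ai[4L],
                 ai[sample.int(3L, n, replace = TRUE)])  # Y or second X
    gt <- paste(pmin(h1, h2), pmax(h1, h2), sep = "/")
    out[[g$id]] <- data.frame(marker = g$id, sample = ids, genotype = gt,
                              sex = sexes, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic dataset on disk
#'
#' Seeds the RNG from \code{config$seed} (restoring the previous RNG state
#' on exit), simulates truth, cross, depths and expression, and writes
#' \code{reference.fasta}, \code{variants.vcf}, \code{counts.tsv},
#' \code{samples.tsv}, \code{truth.tsv}, \code{truth_sites.tsv} and, when
#' \code{n_ortholog > 0}, the interspecific ortholog pair FASTAs
#' \code{orthologs_sp1.fasta} / \code{orthologs_sp2.fasta}.  Identical
#' seeds give byte-identical files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects: \code{truth},
#'   \code{cross}, \code{variants}, \code{counts}, \code{de_genes},
#'   \code{reference}, \code{orthologs}, \code{dir}.
#' @export
generate_dataset <- function(config = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  truth <- simulate_truth(config)
  cross <- simulate_cross(truth, config)
  depths <- simulate_depths(cross, truth, config)

  ids <- vapply(truth, `[[`, character(1L), "id")
  reference <- stats::setNames(vapply(truth, `[[`, character(1L), "ref"), ids)
  write_fasta(reference, file.path(dir, "reference.fasta"))
  write_variants(depths$variants, file.path(dir, "variants.vcf"))
  write_results(depths$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cross$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth_genes <- data.frame(
    gene_id = ids,
    compartment = vapply(truth, `[[`, character(1L), "compartment"),
    divergence_years = vapply(truth, `[[`, numeric(1L), "divergence_years"),
    n_fixed_diffs = vapply(truth, function(g) nrow(g$diffs), integer(1L)),
    expr_de = ids %in% depths$de_genes,
    stringsAsFactors = FALSE)
  utils::write.table(truth_genes, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_sites <- do.call(rbind, lapply(truth, function(g)
    if (nrow(g$diffs)) cbind(gene_id = g$id, g$diffs) else NULL))
  if (is.null(truth_sites))
    truth_sites <- data.frame(gene_id = character(), pos = integer(),
                              base_a = character(), base_b = character(),
                              class = character())
  utils::write.table(truth_sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  orthologs <- NULL
  if (config$n_ortholog > 0L) {
    oref <- generate_reference(config$n_ortholog, config$gene_length)
    oids <- sprintf("orth%04d", seq_len(config$n_ortholog))
    pairs <- lapply(oref, evolve_pair,
                    years = config$interspecific_divergence_years,
                    r = config$r, ka_ks_target = config$ka_ks_target)
    sp1 <- stats::setNames(vapply(pairs, `[[`, character(1L), "seq_a"), oids)
    sp2 <- stats::setNames(vapply(pairs, `[[`, character(1L), "seq_b"), oids)
    write_fasta(sp1, file.path(dir, "orthologs_sp1.fasta"))
    write_fasta(sp2, file.path(dir, "orthologs_sp2.fasta"))
    orthologs <- list(sp1 = sp1, sp2 = sp2)
  }

  invisible(list(truth = truth, cross = cross, variants = depths$variants,
                 counts = depths$counts, de_genes = depths$de_genes,
                 reference = reference, orthologs = orthologs, dir = dir))
}
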