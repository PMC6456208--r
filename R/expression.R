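#' Reads per kilobase per million aligned reads
#'
#' @param mapped_reads reads mapped to the unigene in one sample.
#' @param length_nt unigene length in nucleotides (> 0).
#' @param total_mapped total aligned reads in the sample (> 0).
#' @return RPKM value(s); vectorised over \code{mapped_reads}.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6)
rpkm <- function(mapped_reads, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("unigene length must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  mapped_reads / (length_nt / 1000) / (total_mapped / 1e6)
}

#' One-way ANOVA F-test of sex-biased expression for one unigene
#'
#' Compares log2(RPKM + pseudocount) between the female and male sample
#' groups.  With n_f and n_m samples the degrees of freedom are
#' (1, n_f + n_m - 2); with 4 samples per sex this is (1, 6).
#'
#' @param female_rpkm,male_rpkm RPKM values per sample (at least 2 each).
#' @param pseudocount added before log2 (default 0.01 RPKM) so zero
#'   expression is representable.
#' @return List: \code{F}, \code{df} (length 2), \code{p},
#'   \code{log2_ratio} (male minus female group mean).
#' @export
sex_de_test <- function(female_rpkm, male_rpkm, pseudocount = 0.01) {
  if (length(female_rpkm) < 2L || length(male_rpkm) < 2L)
    stop("need at least 2 samples per group")
  y <- log2(c(female_rpkm, male_rpkm) + pseudocount)
  g <- factor(rep(c("female", "male"), c(length(female_rpkm),
                                         length(male_rpkm))))
  df <- c(1L, length(y) - 2L)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  if (ssb == 0)  # identical group means (e.g. identical groups): F = 0
    return(list(F = 0, df = df, p = 1,
                log2_ratio = 0))
  fit <- stats::anova(stats::lm(y ~ g))
  list(F = fit[["F value"]][1L], df = df, p = fit[["Pr(>F)"]][1L],
       log2_ratio = mean(y[g == "male"]) - mean(y[g == "female"]))
}

#' Sex-biased expression scan
#'
#' Computes per-sample RPKM from a counts table and tests every unigene for
#' differential expression between female and male progeny samples
#' (monoecious samples are excluded).
#'
#' @param counts data frame with columns \code{unigene}, \code{sample},
#'   \code{mapped_reads}.
#' @param lengths named vector of unigene lengths in nt (e.g.
#'   \code{nchar(read_fasta(path))}).
#' @param samples a \code{\link{sample_sheet}}.
#' @param config analysis configuration (\code{pseudocount}).
#' @return Data frame: \code{unigene}, \code{length}, \code{F}, \code{p},
#'   \code{log2_ratio}, \code{mean_rpkm_female}, \code{mean_rpkm_male}.
#' @export
sex_de_scan <- function(counts, lengths, samples,
                        config = spinsex_config()) {
  lib <- tapply(counts$mapped_reads, counts$sample, sum)
  counts$rpkm <- rpkm(counts$mapped_reads, lengths[counts$unigene],
                      lib[counts$sample])
  sex <- stats::setNames(samples$sex, samples$sample_id)
  fem <- counts$sample %in% samples$sample_id[samples$sex == "female"]
  mal <- counts$sample %in% samples$sample_id[samples$sex == "male"]
  genes <- unique(counts$unigene)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    rows <- counts$unigene == genes[i]
    fr <- counts$rpkm[rows & fem]; mr <- counts$rpkm[rows & mal]
    t <- sex_de_test(fr, mr, config$pseudocount)
    out[[i]] <- data.frame(unigene = genes[i],
                           length = unname(lengths[genes[i]]),
                           F = t$F, p = t$p, log2_ratio = t$log2_ratio,
                           mean_rpkm_female = mean(fr),
                           mean_rpkm_male = mean(mr))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of unigenes differentially expressed between sexes
#'
#' @param results data frame from \code{\link{sex_de_scan}} (columns
#'   \code{p} and \code{length}).
#' @param p_cutoff p-value cutoff (default 0.01).
#' @param min_length_nt unigenes this long or shorter are excluded
#'   (default 400 nt, i.e. the scan covers unigenes > 400 nt).
#' @return List: \code{n_tested}, \code{n_de}, \code{fraction}.
#' @export
de_fraction <- function(results, p_cutoff = 0.01, min_length_nt = 400L) {
  tested <- results[results$length > min_length_nt, , drop = FALSE]
  n_de <- sum(tested$p < p_cutoff)
  list(n_tested = nrow(tested), n_de = n_de,
       fraction = if (nrow(tested)) n_de / nrow(tested) else 0)
}

#' Y/X allele expression ratio for one gene
#'
#' Pools read depths over the qualifying SNPs and the male samples: the
#' ratio is (total Y-allele depth) / (total X-allele depth).  Only SNPs
#' heterozygous in every male sample qualify, and a gene needs at least
#' \code{min_snps} of them.
#'
#' @param y_depths,x_depths numeric matrices (qualifying SNPs x male
#'   samples) of Y- and X-allele read depths.
#' @param min_snps minimum qualifying SNPs (default 2).
#' @return List: \code{ratio} (NA with \code{undefined = TRUE} when the
#'   pooled X depth is 0, or \code{skipped = TRUE} when there are fewer
#'   than \code{min_snps} SNPs), \code{pooled_y_depth},
#'   \code{pooled_x_depth}, \code{per_snp_ratio}.
#' @export
yx_ratio <- function(y_depths, x_depths, min_snps = 2L) {
  y_depths <- rbind(y_depths); x_depths <- rbind(x_depths)
  if (!all(dim(y_depths) == dim(x_depths))) stop("depth matrices differ")
  if (nrow(y_depths) < min_snps)
    return(list(ratio = NA_real_, skipped = TRUE, undefined = FALSE,
                pooled_y_depth = NA_real_, pooled_x_depth = NA_real_,
                per_snp_ratio = NULL))
  py <- sum(y_depths); px <- sum(x_depths)
  if (px == 0)
    return(list(ratio = NA_real_, skipped = FALSE, undefined = TRUE,
                pooled_y_depth = py, pooled_x_depth = 0,
                per_snp_ratio = NULL))
  list(ratio = py / px, skipped = FALSE, undefined = FALSE,
       pooled_y_depth = py, pooled_x_depth = px,
       per_snp_ratio = rowSums(y_depths) / rowSums(x_depths))
}

#' Y/X allele expression ratios across all pattern-1 genes
#'
#' For every unigene with pattern-1 SNPs, pools Y- and X-allele read depths
#' over the male samples at SNPs called heterozygous in all of them, and
#' returns the per-gene pooled Y/X ratio.
#'
#' @param variants a \code{variant_table}.
#' @param gm the matching \code{genotype_matrix}.
#' @param classifications data frame from \code{\link{classify_sites}}.
#' @param config analysis configuration (\code{min_snps}).
#' @return Data frame: \code{unigene}, \code{n_snps}, \code{pooled_y_depth},
#'   \code{pooled_x_depth}, \code{ratio}.
#' @export
yx_scan <- function(variants, gm, classifications,
                    config = spinsex_config()) {
  males <- gm$samples$role == "progeny" & gm$samples$sex == "male"
  p1 <- which(classifications$pattern == "P1")
  out <- list()
  for (u in unique(classifications$unigene[p1])) {
    rows <- p1[classifications$unigene[p1] == u]
    # qualifying SNPs: heterozygous in every male sample
    ok <- vapply(rows, function(i) all(gt_is_het(gm$gt[i, males])),
                 logical(1L))
    rows <- rows[ok]
    if (length(rows) < config$min_snps) next
    ydep <- matrix(0, length(rows), sum(males))
    xdep <- ydep
    for (r in seq_along(rows)) {
      i <- rows[r]
      dep <- vapply(strsplit(variants$ad[i, males], ",", fixed = TRUE),
                    function(v) as.integer(v)[
                      c(classifications$y_allele[i],
                        classifications$x_allele[i]) + 1L],
                    integer(2L))
      ydep[r, ] <- dep[1L, ]; xdep[r, ] <- dep[2L, ]
    }
    yr <- yx_ratio(ydep, xdep, config$min_snps)
    out[[u]] <- data.frame(unigene = u, n_snps = length(rows),
                           pooled_y_depth = yr$pooled_y_depth,
                           pooled_x_depth = yr$pooled_x_depth,
                           ratio = yr$ratio)
  }
  if (!length(out))
    return(data.frame(unigene = character(), n_snps = integer(),
                      pooled_y_depth = numeric(), pooled_x_depth = numeric(),
                      ratio = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$unigene), , drop = FALSE]
}
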