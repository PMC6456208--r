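#' Classify one site into a sex-chromosomal segregation pattern
#'
#' Progeny of an XY cross show three diagnostic configurations:
#' \describe{
#'   \item{P1}{every female the same homozygote (allele a), every male
#'     heterozygous a/b: the X allele is a, the Y allele b.}
#'   \item{P2}{every female heterozygous a/b, every male the same homozygote
#'     for a or b: the Y allele is the male allele.  A hemizygous male
#'     (X allele with no Y copy) is indistinguishable, so
#'     \code{hemizygosity_unknown} is set.}
#'   \item{P3}{every female heterozygous a/b, every male heterozygous a/c
#'     with a third allele c: X allele a, Y allele c.}
#' }
#' Any other configuration is \code{NONE}.
#'
#' @param female_calls,male_calls character vectors of \code{"i/j"} genotype
#'   codes (see \code{\link{call_genotype}}); NA entries are missing calls.
#' @param require_complete if TRUE (default) any missing call gives
#'   \code{NONE}; if FALSE missing calls are dropped and at least
#'   \code{min_per_sex} calls per sex are required.
#' @param min_per_sex minimum called samples per sex when
#'   \code{require_complete} is FALSE.
#' @return List: \code{pattern} (\code{"P1"}, \code{"P2"}, \code{"P3"},
#'   \code{"NONE"}), \code{x_allele}, \code{y_allele} (0-based indices or
#'   NA), \code{hemizygosity_unknown}.
#' @export
classify_site <- function(female_calls, male_calls, require_complete = TRUE,
                          min_per_sex = 4L) {
  if (!length(female_calls) || !length(male_calls))
    stop("need at least one call per sex")
  none <- list(pattern = "NONE", x_allele = NA_integer_,
               y_allele = NA_integer_, hemizygosity_unknown = FALSE)
  if (require_complete) {
    if (anyNA(female_calls) || anyNA(male_calls)) return(none)
  } else {
    female_calls <- female_calls[!is.na(female_calls)]
    male_calls <- male_calls[!is.na(male_calls)]
    if (length(female_calls) < min_per_sex || length(male_calls) < min_per_sex)
      return(none)
  }
  f_same <- length(unique(female_calls)) == 1L
  m_same <- length(unique(male_calls)) == 1L
  if (!f_same || !m_same) return(none)
  f <- gt_alleles(female_calls[1L])
  m <- gt_alleles(male_calls[1L])
  f_hom <- f[1L] == f[2L]
  m_hom <- m[1L] == m[2L]

  if (f_hom && !m_hom) {
    a <- f[1L]
    if (a %in% m)
      return(list(pattern = "P1", x_allele = a,
                  y_allele = setdiff(m, a),
                  hemizygosity_unknown = FALSE))
    return(none)
  }
  if (!f_hom && m_hom) {
    if (m[1L] %in% f)  # male X carries the same allele as (or no) Y copy
      return(list(pattern = "P2", x_allele = m[1L],
                  y_allele = m[1L], hemizygosity_unknown = TRUE))
    return(none)
  }
  if (!f_hom && !m_hom) {
    shared <- intersect(f, m)
    if (length(shared) == 1L) {
      c_allele <- setdiff(m, shared)
      if (!c_allele %in% f)
        return(list(pattern = "P3", x_allele = shared, y_allele = c_allele,
                    hemizygosity_unknown = FALSE))
    }
    return(none)
  }
  none
}

#' Classify every complete site of a genotype matrix
#'
#' Monoecious samples and non-progeny roles are excluded; only progeny with
#' sex \code{male} or \code{female} enter the classification.
#'
#' @param gm a \code{genotype_matrix}.
#' @param config analysis configuration (\code{require_complete},
#'   \code{min_per_sex}).
#' @return Data frame: \code{unigene}, \code{pos}, \code{pattern},
#'   \code{x_allele}, \code{y_allele}, \code{hemizygosity_unknown}.
#' @export
classify_sites <- function(gm, config = spinsex_config()) {
  sm <- gm$samples
  fem <- sm$role == "progeny" & sm$sex == "female"
  mal <- sm$role == "progeny" & sm$sex == "male"
  if (!any(fem) || !any(mal))
    stop("classification needs male and female progeny samples")
  n <- nrow(gm$gt)
  pattern <- character(n); xa <- integer(n); ya <- integer(n); hz <- logical(n)
  for (i in seq_len(n)) {
    cl <- classify_site(gm$gt[i, fem], gm$gt[i, mal],
                        require_complete = config$require_complete,
                        min_per_sex = config$min_per_sex)
    pattern[i] <- cl$pattern
    xa[i] <- cl$x_allele
    ya[i] <- cl$y_allele
    hz[i] <- cl$hemizygosity_unknown
  }
  res <- data.frame(unigene = gm$sites$unigene, pos = gm$sites$pos,
                    pattern = pattern, x_allele = xa, y_allele = ya,
                    hemizygosity_unknown = hz, stringsAsFactors = FALSE)
  message(sprintf(
    "classify_sites: %d site(s): %d P1, %d P2, %d P3, %d unclassified",
    n, sum(pattern == "P1"), sum(pattern == "P2"), sum(pattern == "P3"),
    sum(pattern == "NONE")))
  res
}

#' Aggregate site classifications to unigene level
#'
#' Counts SNPs and unigenes per segregation pattern.  The distinct-unigene
#' total counts a gene carrying SNPs of several patterns once (the union of
#' the per-pattern gene sets).
#'
#' @param classifications data frame from \code{\link{classify_sites}}.
#' @return List of class \code{"segregation_summary"}: \code{per_unigene}
#'   (data frame unigene x pattern SNP counts), \code{snp_counts},
#'   \code{unigene_counts} (named by pattern), \code{total_snps},
#'   \code{total_distinct_unigenes}.
#' @export
aggregate_unigenes <- function(classifications) {
  pats <- c("P1", "P2", "P3")
  cl <- classifications[classifications$pattern %in% pats, , drop = FALSE]
  snp_counts <- vapply(pats, function(p) sum(cl$pattern == p), integer(1L))
  gene_sets <- lapply(pats, function(p) unique(cl$unigene[cl$pattern == p]))
  names(gene_sets) <- pats
  unigene_counts <- vapply(gene_sets, length, integer(1L))
  per <- if (nrow(cl)) {
    tab <- table(cl$unigene, factor(cl$pattern, levels = pats))
    df <- as.data.frame.matrix(tab)
    df <- cbind(unigene = rownames(df), df, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  } else {
    data.frame(unigene = character(), P1 = integer(), P2 = integer(),
               P3 = integer(), stringsAsFactors = FALSE)
  }
  structure(list(per_unigene = per,
                 snp_counts = snp_counts,
                 unigene_counts = unigene_counts,
                 total_snps = sum(snp_counts),
                 total_distinct_unigenes =
                   length(unique(unlist(gene_sets)))),
            class = "segregation_summary")
}

#' @export
print.segregation_summary <- function(x, ...) {
  cat("Sex-chromosomal SNP segregation summary\n")
  cat(sprintf("  pattern   SNPs  unigenes\n"))
  for (p in names(x$snp_counts))
    cat(sprintf("  %-8s %5d %9d\n", p, x$snp_counts[[p]],
                x$unigene_counts[[p]]))
  cat(sprintf("  total    %5d %9d (distinct unigenes)\n", x$total_snps,
              x$total_distinct_unigenes))
  invisible(x)
}
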