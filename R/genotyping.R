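# Genotype calls are encoded as character strings "i/j" of 0-based allele
# indices with i <= j (0 = REF), or NA for MISSING.  Helper predicates below.

gt_is_hom <- function(gt) {
  p <- strsplit(gt, "/", fixed = TRUE)
  !is.na(gt) & vapply(p, function(x) x[1L] == x[2L], logical(1L))
}

gt_is_het <- function(gt) !is.na(gt) & !gt_is_hom(gt)

gt_alleles <- function(gt) as.integer(strsplit(gt, "/", fixed = TRUE)[[1L]])

#' Call one genotype from allele depths (depth-fraction rule)
#'
#' A sample is homozygous when the minor of the two best-supported alleles
#' carries strictly less than \code{hom_fraction} of the total site depth:
#' with REF below the threshold the call is homozygous for the major ALT
#' allele, with the minor allele below it (REF major) homozygous REF;
#' otherwise heterozygous for the two best-supported alleles.  Total depth
#' below \code{min_total_depth} gives MISSING.
#'
#' @param depths integer vector of per-allele read depths, REF first.
#' @param min_total_depth minimum total depth to call (default 10).
#' @param hom_fraction homozygosity threshold, in (0, 0.5) (default 0.10).
#' @return List with \code{state} (\code{"HOM_REF"}, \code{"HET"},
#'   \code{"HOM_ALT"}, \code{"MISSING"}), \code{gt} (index pair
#'   \code{"i/j"} or NA), and \code{ambiguous} (TRUE when a third allele
#'   also exceeds the threshold at a multiallelic site).
#' @export
#' @examples
#' call_genotype(c(1, 19))   # REF at 5% of depth: homozygous ALT
#' call_genotype(c(18, 2))   # 10% is not below 10%: heterozygous
call_genotype <- function(depths, min_total_depth = 10L, hom_fraction = 0.10) {
  if (any(depths < 0)) stop("negative allele depth")
  if (hom_fraction <= 0 || hom_fraction >= 0.5)
    stop("hom_fraction must be in (0, 0.5)")
  total <- sum(depths)
  if (total < min_total_depth)
    return(list(state = "MISSING", gt = NA_character_, ambiguous = FALSE))
  # two best-supported alleles; depth ties broken by allele index (REF first)
  ord <- order(-depths, seq_along(depths))
  a1 <- ord[1L]; a2 <- if (length(depths) > 1L) ord[2L] else NA_integer_
  minor_frac <- if (is.na(a2)) 0 else depths[a2] / total
  ambiguous <- length(depths) > 2L &&
    any(depths[-c(a1, a2)] / total >= hom_fraction)
  if (is.na(a2) || minor_frac < hom_fraction) {
    idx <- a1 - 1L
    state <- if (idx == 0L) "HOM_REF" else "HOM_ALT"
    return(list(state = state, gt = paste(idx, idx, sep = "/"),
                ambiguous = ambiguous))
  }
  pair <- sort(c(a1, a2) - 1L)
  list(state = "HET", gt = paste(pair[1L], pair[2L], sep = "/"),
       ambiguous = ambiguous)
}

#' Genotype every site and sample of a variant table
#'
#' @param variants a \code{variant_table} from \code{\link{read_variants}}.
#' @param config analysis configuration (\code{min_total_depth},
#'   \code{hom_fraction}); see \code{\link{spinsex_config}}.
#' @return List of class \code{"genotype_matrix"}: \code{gt} (character
#'   matrix sites x samples of \code{"i/j"} codes, NA = missing),
#'   \code{ambiguous} (logical matrix), \code{complete} (logical per site:
#'   all progeny samples called), \code{sites}, \code{samples}.
#' @export
genotype_matrix <- function(variants, config = spinsex_config()) {
  ad <- variants$ad
  n_sites <- nrow(ad); n_samp <- ncol(ad)
  gt <- matrix(NA_character_, n_sites, n_samp,
               dimnames = dimnames(ad))
  amb <- matrix(FALSE, n_sites, n_samp, dimnames = dimnames(ad))
  for (i in seq_len(n_sites)) {
    for (j in seq_len(n_samp)) {
      d <- as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1L]])
      call <- call_genotype(d, config$min_total_depth, config$hom_fraction)
      gt[i, j] <- call$gt
      amb[i, j] <- call$ambiguous
    }
  }
  progeny <- variants$samples$role == "progeny"
  complete <- if (any(progeny))
    rowSums(is.na(gt[, progeny, drop = FALSE])) == 0L
  else rep(TRUE, n_sites)
  structure(list(gt = gt, ambiguous = amb, complete = complete,
                 sites = variants$sites, samples = variants$samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d site(s) x %d sample(s); %d complete site(s)\n",
    nrow(x$gt), ncol(x$gt), sum(x$complete)))
  invisible(x)
}

#' Export a genotype matrix in long TSV layout
#'
#' @param gm a \code{genotype_matrix}.
#' @return Data frame: unigene, pos, sample, state, alleles.
#' @export
genotype_long <- function(gm) {
  n_sites <- nrow(gm$gt); n_samp <- ncol(gm$gt)
  gt <- as.vector(gm$gt)
  state <- ifelse(is.na(gt), "MISSING",
                  ifelse(gt_is_hom(gt),
                         ifelse(gt == "0/0", "HOM_REF", "HOM_ALT"), "HET"))
  data.frame(unigene = rep(gm$sites$unigene, n_samp),
             pos = rep(gm$sites$pos, n_samp),
             sample = rep(colnames(gm$gt), each = n_sites),
             state = state, alleles = gt, stringsAsFactors = FALSE)
}
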