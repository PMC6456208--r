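#' Read a sample sheet
#'
#' Tab-separated file with columns \code{sample_id}, \code{sex}
#' (\code{male} / \code{female} / \code{monoecious}), \code{role}
#' (\code{progeny} / \code{parent} / \code{unrelated}) and \code{group}.
#'
#' @param path path to the TSV file.
#' @return Data frame of class \code{"sample_sheet"}.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Construct and validate a sample sheet
#'
#' @param df data frame with columns \code{sample_id}, \code{sex},
#'   \code{role}, \code{group}.
#' @return The validated data frame, classed \code{"sample_sheet"}.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "sex", "role", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sample sheet")
  bad <- setdiff(unique(df$sex), c("male", "female", "monoecious"))
  if (length(bad)) stop("invalid sex label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$role), c("progeny", "parent", "unrelated"))
  if (length(bad)) stop("invalid role label(s): ", paste(bad, collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

variant_table <- function(sites, ad, samples) {
  stopifnot(nrow(sites) == nrow(ad), ncol(ad) == nrow(samples))
  colnames(ad) <- samples$sample_id
  structure(list(sites = sites, ad = ad, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNP site(s) x %d sample(s), %d unigene(s)\n",
              nrow(x$sites), nrow(x$samples), length(unique(x$sites$unigene))))
  invisible(x)
}

#' Read a variant table with per-sample allele depths
#'
#' Two dialects are accepted and yield identical tables:
#' \itemize{
#'   \item VCF 4.x with FORMAT field \code{AD} (parsed with \pkg{vcfR});
#'   \item TSV with columns \code{unigene}, \code{pos}, \code{ref},
#'     \code{alt} and, per sample, \code{<sample>_refdepth} and
#'     \code{<sample>_altdepth} (comma-separated for multiallelic sites).
#' }
#' Indel records (any allele longer than one base) are skipped; the number
#' skipped is reported on stderr.  Multiallelic SNP records are kept.
#'
#' @param path input file.  Files whose first line starts with
#'   \code{##fileformat} (or with a \code{.vcf} extension) are treated as
#'   VCF, anything else as TSV.
#' @param samples a \code{\link{sample_sheet}}; every sample column in the
#'   file must appear in it.
#' @param min_qual optional minimum QUAL (VCF only); records below it are
#'   dropped.  Default \code{NA} disables the filter.
#' @return A \code{variant_table}: list with \code{sites} (data frame:
#'   \code{unigene}, \code{pos} 1-based, \code{ref}, \code{alt}
#'   comma-separated), \code{ad} (character matrix sites x samples of
#'   comma-separated depths, REF first) and \code{samples}.
#' @export
read_variants <- function(path, samples, min_qual = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat", first) || grepl("\\.vcf(\\.gz)?$", path)
  vt <- if (is_vcf) read_variants_vcf(path, samples, min_qual)
        else read_variants_tsv(path, samples)
  vt
}

read_variants_vcf <- function(path, samples, min_qual = NA) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(vcf@gt)[-1L]
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown))
    stop("sample(s) in VCF absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  fmt <- vcf@gt[, "FORMAT"]
  no_ad <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1L))
  if (any(no_ad))
    stop("record without AD information: ", fix[which(no_ad)[1L], "CHROM"],
         ":", fix[which(no_ad)[1L], "POS"])
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1L,
                                     dimnames = list(NULL, names(ad)))
  if (any(is.na(ad))) {
    bad <- which(rowSums(is.na(ad)) > 0)[1L]
    stop("record with missing AD value: ", fix[bad, "CHROM"], ":",
         fix[bad, "POS"])
  }

  alleles <- paste(fix[, "REF"], fix[, "ALT"], sep = ",")
  is_snp <- vapply(strsplit(alleles, ",", fixed = TRUE),
                   function(a) all(nchar(a) == 1L) && all(a %in% .BASES),
                   logical(1L))
  keep <- is_snp
  if (!is.na(min_qual)) {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    keep <- keep & !is.na(qual) & qual >= min_qual
  }
  n_skipped <- sum(is_snp == FALSE)
  if (n_skipped > 0)
    message(sprintf("read_variants: skipped %d indel/non-SNP record(s)",
                    n_skipped))
  sites <- data.frame(unigene = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"],
                      alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  sheet <- samples[match(vcf_samples, samples$sample_id), , drop = FALSE]
  class(sheet) <- class(samples)
  variant_table(sites, ad[keep, , drop = FALSE], sheet)
}

read_variants_tsv <- function(path, samples) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("unigene", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  refcols <- grep("_refdepth$", names(df), value = TRUE)
  ids <- sub("_refdepth$", "", refcols)
  unknown <- setdiff(ids, samples$sample_id)
  if (length(unknown))
    stop("sample(s) in variant TSV absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  altcols <- paste0(ids, "_altdepth")
  miss <- setdiff(altcols, names(df))
  if (length(miss)) stop("record without AD information: missing column(s) ",
                         paste(miss, collapse = ", "))
  alleles <- paste(df$ref, df$alt, sep = ",")
  is_snp <- vapply(strsplit(alleles, ",", fixed = TRUE),
                   function(a) all(nchar(a) == 1L) && all(a %in% .BASES),
                   logical(1L))
  if (any(!is_snp))
    message(sprintf("read_variants: skipped %d indel/non-SNP record(s)",
                    sum(!is_snp)))
  df <- df[is_snp, , drop = FALSE]
  ad <- matrix("", nrow = nrow(df), ncol = length(ids))
  for (j in seq_along(ids))
    ad[, j] <- paste(df[[refcols[j]]], df[[altcols[j]]], sep = ",")
  sites <- data.frame(unigene = df$unigene, pos = as.integer(df$pos),
                      ref = df$ref, alt = df$alt, stringsAsFactors = FALSE)
  sheet <- samples[match(ids, samples$sample_id), , drop = FALSE]
  class(sheet) <- class(samples)
  variant_table(sites, ad, sheet)
}

#' Write a variant table as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 file with a single FORMAT field \code{AD}
#' (genotype omitted; depths carry the information the pipeline uses).
#'
#' @param variants a \code{variant_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(variants, path) {
  s <- variants$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", variants$samples$sample_id),
                 collapse = "\t"))
  body <- paste(s$unigene, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "AD",
                sep = "\t")
  if (nrow(s) > 0)
    body <- paste(body, apply(variants$ad, 1L, paste, collapse = "\t"),
                  sep = "\t")
  writeLines(c(hdr, if (nrow(s) > 0) body), path)
  invisible(path)
}

#' Read unigene sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ID: ", ids[duplicated(ids)][1L])
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Columns keep their order; rows are sorted by \code{unigene} then
#' \code{pos} when those columns exist, so output is deterministic and
#' re-reading yields identical records.
#'
#' @param records data frame (may have zero rows; the header is still
#'   written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(records, path) {
  if (nrow(records) > 0) {
    if (all(c("unigene", "pos") %in% names(records)))
      records <- records[order(records$unigene, records$pos), , drop = FALSE]
    else if ("unigene" %in% names(records))
      records <- records[order(records$unigene), , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{write_results}}
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
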